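#' Percent normalized change
#'
#' Bounded pre/post change score `(post - pre) * 100 / (post + pre)`,
#' antisymmetric under pre/post swap and invariant to common rescaling.
#' Lies in (-100, 100) whenever both raw values are positive.
#'
#' @param pre,post Numeric vectors (recycled), with `pre + post != 0`.
#' @return Percent normalized change; NA (with warning) where the
#'   denominator vanishes.
#' @export
percent_normalized_change <- function(pre, post) {
  denom <- pre + post
  bad <- !is.na(denom) & denom == 0
  if (any(bad)) {
    warn_gd("pre + post = 0 for ", sum(bad), " cell(s): change undefined")
  }
  out <- (post - pre) * 100 / denom
  out[bad] <- NA_real_
  out
}

# Exact null distribution of the group-A rank sum by enumeration of all
# choose(n, n_a) assignments of the pooled ranks to group A.
ranksum_enumerate <- function(ranks, n_a) {
  sums <- utils::combn(ranks, n_a, FUN = sum)
  sums
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Mid-ranks are assigned to ties. With combined sample size at most
#' `exact_limit` and no ties, the two-sided p-value is exact:
#' `min(1, 2 * min(P(W <= w), P(W >= w)))` under full enumeration of all
#' rank assignments. Otherwise a normal approximation with tie correction
#' and continuity correction is used.
#'
#' @param group_a,group_b Numeric vectors, each non-empty.
#' @param exact_limit Largest combined n for the exact enumeration.
#' @return Object of class `ranksum_result`: list with `statistic` (rank
#'   sum of group A), `p_value`, `n_a`, `n_b`, `method`.
#' @export
ranksum_test <- function(group_a, group_b, exact_limit = 20L) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  n_a <- length(group_a); n_b <- length(group_b)
  if (n_a < 1L || n_b < 1L) stop_invalid("both groups must be non-empty")
  pooled <- c(group_a, group_b)
  ranks <- rank(pooled)  # mid-ranks for ties
  w <- sum(ranks[seq_len(n_a)])
  n <- n_a + n_b
  has_ties <- anyDuplicated(pooled) > 0L

  if (!has_ties && n <= exact_limit) {
    sums <- ranksum_enumerate(ranks, n_a)
    p <- min(1, 2 * min(mean(sums <= w), mean(sums >= w)))
    method <- "exact"
  } else {
    mu <- n_a * (n + 1) / 2
    tie_tab <- table(ranks)
    sigma2 <- n_a * n_b / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approximation"
  }
  structure(list(statistic = w, p_value = p, n_a = n_a, n_b = n_b,
                 method = method),
            class = "ranksum_result")
}

#' @export
print.ranksum_result <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum (%s): W = %g, n = (%d, %d), p = %.4g\n",
              x$method, x$statistic, x$n_a, x$n_b, x$p_value))
  invisible(x)
}

#' Compare two montages per gait parameter
#'
#' One two-sided Wilcoxon rank-sum test per gait parameter between the two
#' montages' percent-normalized-change distributions, flagged at the given
#' significance level. No multiplicity correction is applied by default; a
#' Benjamini-Hochberg adjustment is available behind `adjust = "BH"`.
#'
#' @param changes Change table: data.frame with `subject`, `montage` and
#'   one numeric column per gait parameter.
#' @param alpha Significance level in (0, 1).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with one row per parameter: `parameter`,
#'   `statistic`, `p_value`, `method`, `significant` (plus `p_adjusted`
#'   when `adjust = "BH"`). Parameters lacking data in either montage are
#'   skipped with a warning.
#' @export
compare_montages <- function(changes, alpha = 0.05,
                             adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (alpha <= 0 || alpha >= 1) stop_invalid("alpha must lie in (0, 1)")
  montages <- unique(changes$montage)
  if (length(montages) != 2L) {
    stop_invalid("change table must contain exactly two montages, found ",
                 length(montages))
  }
  params <- setdiff(names(changes), c("subject", "montage"))
  rows <- list()
  for (p in params) {
    a <- changes[[p]][changes$montage == montages[1]]
    b <- changes[[p]][changes$montage == montages[2]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 1L || length(b) < 1L) {
      warn_gd("parameter ", p, " lacks data in one montage: skipped")
      next
    }
    r <- ranksum_test(a, b)
    rows[[p]] <- data.frame(parameter = p, statistic = r$statistic,
                            p_value = r$p_value, method = r$method,
                            stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(parameter = character(), statistic = numeric(),
                      p_value = numeric(), method = character(),
                      significant = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- out$p_adjusted < alpha
  } else {
    out$significant <- out$p_value < alpha
  }
  attr(out, "montages") <- montages
  out
}

#' Build a change table from per-trial gait indices
#'
#' Pairs pre/post index rows per subject and montage and applies
#' [percent_normalized_change()] to every gait parameter.
#'
#' @param indices data.frame stacking [compute_index_set()] rows, with
#'   `subject_id`, `session` (`"pre"`/`"post"`), `montage` columns.
#' @param parameters Parameter columns to difference; defaults to the 17
#'   canonical gait parameters.
#' @return Change table data.frame (`subject`, `montage`, parameters).
#' @export
change_table_from_indices <- function(indices,
                                      parameters = gait_parameter_names()) {
  need <- c("subject_id", "session", "montage")
  if (!all(need %in% names(indices))) {
    stop_schema("indices must have columns: ", paste(need, collapse = ", "))
  }
  keys <- unique(indices[, c("subject_id", "montage")])
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    pre <- indices[indices$subject_id == keys$subject_id[i] &
                     indices$montage == keys$montage[i] &
                     indices$session == "pre", , drop = FALSE]
    post <- indices[indices$subject_id == keys$subject_id[i] &
                      indices$montage == keys$montage[i] &
                      indices$session == "post", , drop = FALSE]
    if (nrow(pre) != 1L || nrow(post) != 1L) {
      warn_gd("subject ", keys$subject_id[i], " montage ", keys$montage[i],
              ": need exactly one pre and one post trial, skipped")
      next
    }
    ch <- vapply(parameters, function(p) {
      suppressWarnings(percent_normalized_change(pre[[p]], post[[p]]))
    }, numeric(1))
    rows[[i]] <- cbind(data.frame(subject = keys$subject_id[i],
                                  montage = keys$montage[i],
                                  stringsAsFactors = FALSE),
                       as.data.frame(as.list(ch), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
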