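#' Centre the columns of a matrix
#'
#' Subtracts each column's mean; no scaling to unit variance.
#'
#' @param x Numeric matrix (or coercible) with at least two rows.
#' @return List with `centered` (matrix) and `means` (named numeric).
#' @export
center_columns <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop_invalid("centering requires at least 2 rows")
  mu <- colMeans(x)
  list(centered = sweep(x, 2, mu), means = mu)
}

#' Partial least squares regression (two-block deflation)
#'
#' Regression-mode PLS (PLS2) on column-centred, unscaled data. At each
#' component the predictor weight vector is the dominant left singular
#' vector of the current cross-covariance `t(X) %*% Y`; the X score is the
#' projection of the deflated predictors onto that weight; X loadings and
#' Y loadings are regressions of the deflated blocks on the score; both
#' blocks are then deflated by the score. Successive X scores are mutually
#' orthogonal. Weight signs are fixed so the largest-magnitude element of
#' each weight vector is positive, making loadings reproducible.
#'
#' @param X Predictor matrix/data.frame (observations x predictors), e.g.
#'   the lobule columns of an E-field matrix.
#' @param Y Response matrix/data.frame (observations x responses), e.g. a
#'   percent-normalized-change table.
#' @param n_components Number of latent components; capped at
#'   `min(nrow - 1, ncol(X))`. A rank-deficient cross-covariance truncates
#'   the model with a warning.
#' @return Object of class `plsr_model`: weights `W`, scores `T`,
#'   X loadings `P`, Y loadings `Q`, `coefficient_matrix`, column means,
#'   per-component percent variance explained in X and Y, `fitted`,
#'   `r_squared`.
#' @export
fit_pls <- function(X, Y, n_components = 10L) {
  x_names <- colnames(X) %||% paste0("x", seq_len(ncol(as.matrix(X))))
  y_names <- colnames(Y) %||% paste0("y", seq_len(ncol(as.matrix(Y))))
  X <- as.matrix(X); Y <- as.matrix(Y)
  storage.mode(X) <- "double"; storage.mode(Y) <- "double"
  if (nrow(X) != nrow(Y)) stop_schema("X and Y must have matching rows")
  kmax <- min(nrow(X) - 1L, ncol(X))
  if (n_components < 1L) stop_invalid("n_components must be >= 1")
  n_components <- min(as.integer(n_components), kmax)

  cx <- center_columns(X); cy <- center_columns(Y)
  Xd <- cx$centered; Yd <- cy$centered
  ssx_tot <- sum(Xd^2); ssy_tot <- sum(Yd^2)
  if (ssy_tot == 0) stop_invalid("response matrix has zero variance")

  p <- ncol(X); q <- ncol(Y); n <- nrow(X)
  W <- P <- matrix(0, p, 0); Q <- matrix(0, q, 0); Tm <- matrix(0, n, 0)
  pct_var_x <- pct_var_y <- numeric(0)
  tol <- 1e-12 * max(1, sum(abs(crossprod(cx$centered, cy$centered))))

  for (k in seq_len(n_components)) {
    S <- crossprod(Xd, Yd)
    sv <- svd(S, nu = 1, nv = 0)
    if (sv$d[1] <= tol) {
      warn_gd("cross-covariance rank-deficient at component ", k,
              ": model truncated to ", k - 1L, " components")
      break
    }
    w <- sv$u[, 1]
    j <- which.max(abs(w))
    if (w[j] < 0) w <- -w
    t_k <- drop(Xd %*% w)
    tt <- sum(t_k^2)
    if (tt <= .Machine$double.eps * ssx_tot) {
      warn_gd("degenerate score at component ", k, ": model truncated")
      break
    }
    p_k <- drop(crossprod(Xd, t_k)) / tt
    q_k <- drop(crossprod(Yd, t_k)) / tt
    Xd <- Xd - tcrossprod(t_k, p_k)
    Yd <- Yd - tcrossprod(t_k, q_k)
    W <- cbind(W, w); P <- cbind(P, p_k); Q <- cbind(Q, q_k)
    Tm <- cbind(Tm, t_k)
    pct_var_x <- c(pct_var_x, 100 * tt * sum(p_k^2) / ssx_tot)
    pct_var_y <- c(pct_var_y, 100 * tt * sum(q_k^2) / ssy_tot)
  }
  if (ncol(W) == 0L) stop_invalid("no PLS component could be extracted")
  dimnames(W) <- dimnames(P) <- list(x_names, paste0("comp", seq_len(ncol(W))))
  dimnames(Q) <- list(y_names, colnames(W))
  colnames(Tm) <- colnames(W)

  # B = W (P'W)^{-1} Q'
  B <- W %*% solve(crossprod(P, W), t(Q))
  dimnames(B) <- list(x_names, y_names)
  fitted <- cx$centered %*% B +
    matrix(cy$means, n, q, byrow = TRUE)
  colnames(fitted) <- y_names
  r2 <- response_r2(Y, fitted)

  structure(list(n_components = ncol(W),
                 x_names = x_names, y_names = y_names,
                 x_means = cx$means, y_means = cy$means,
                 x_weights = W, x_scores = Tm,
                 x_loadings = P, y_loadings = Q,
                 coefficient_matrix = B,
                 pct_var_x = pct_var_x, pct_var_y = pct_var_y,
                 fitted = fitted, r_squared = r2),
            class = "plsr_model")
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d components, %d predictors, %d responses\n",
              x$n_components, length(x$x_names), length(x$y_names)))
  cat(sprintf("  R^2 = %.4f; cumulative %%var(Y) = %.1f\n",
              x$r_squared, sum(x$pct_var_y)))
  invisible(x)
}

#' Per-component variance explained
#'
#' Percentage of the total centred sum of squares of the predictor and
#' response blocks captured by each latent component, with cumulative sums.
#' At full rank the cumulative response percentage equals `100 * R^2`.
#'
#' @param model A fitted `plsr_model`.
#' @return data.frame: `component`, `pct_var_x`, `pct_var_y`,
#'   `cum_pct_var_x`, `cum_pct_var_y`.
#' @export
explained_variance <- function(model) {
  if (!inherits(model, "plsr_model")) stop_invalid("model must be a plsr_model")
  data.frame(component = seq_len(model$n_components),
             pct_var_x = model$pct_var_x,
             pct_var_y = model$pct_var_y,
             cum_pct_var_x = cumsum(model$pct_var_x),
             cum_pct_var_y = cumsum(model$pct_var_y))
}

#' Predict responses for new predictor rows
#'
#' `(X_new - x_means) %*% B + y_means`, with columns aligned by predictor
#' name when `X_new` carries column names.
#'
#' @param model A fitted `plsr_model`.
#' @param X_new Matrix/data.frame of new predictor rows.
#' @return Fitted response matrix.
#' @export
predict_responses <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  if (!is.null(colnames(X_new))) {
    if (!setequal(colnames(X_new), model$x_names)) {
      stop_schema("X_new columns do not match training predictor labels")
    }
    X_new <- X_new[, model$x_names, drop = FALSE]
  } else if (ncol(X_new) != length(model$x_names)) {
    stop_schema("X_new has ", ncol(X_new), " columns; model expects ",
                length(model$x_names))
  }
  out <- sweep(X_new, 2, model$x_means) %*% model$coefficient_matrix +
    matrix(model$y_means, nrow(X_new), length(model$y_names), byrow = TRUE)
  colnames(out) <- model$y_names
  out
}

#' @export
predict.plsr_model <- function(object, newdata, ...) {
  predict_responses(object, newdata)
}

#' Pooled response R-squared
#'
#' `1 - SS_residual / SS_total`, pooled over all response columns about
#' their column means.
#'
#' @param Y_observed,Y_fitted Matrices of matching shape.
#' @return R-squared (dimensionless).
#' @export
response_r2 <- function(Y_observed, Y_fitted) {
  Y_observed <- as.matrix(Y_observed); Y_fitted <- as.matrix(Y_fitted)
  if (!identical(dim(Y_observed), dim(Y_fitted))) {
    stop_invalid("observed and fitted shapes differ")
  }
  mu <- colMeans(Y_observed)
  ss_tot <- sum(sweep(Y_observed, 2, mu)^2)
  if (ss_tot == 0) stop_invalid("zero total sum of squares: R^2 undefined")
  1 - sum((Y_observed - Y_fitted)^2) / ss_tot
}

#' Tidy loading tables and montage field contrast
#'
#' Long-format predictor and response loading tables per component, plus,
#' when an E-field matrix is supplied, the per-lobule difference of the
#' two montages' mean field strengths.
#'
#' @param model A fitted `plsr_model`.
#' @param efield Optional E-field data.frame (`subject`, `montage`,
#'   lobule columns) for the montage contrast.
#' @return List with `predictor_loadings`, `response_loadings` (long
#'   data.frames: `component`, `variable`, `loading`) and `contrast`
#'   (`lobule`, one mean column per montage, `difference`; NULL when no
#'   E-field matrix is given).
#' @export
extract_loadings <- function(model, efield = NULL) {
  long <- function(M) {
    data.frame(component = rep(seq_len(ncol(M)), each = nrow(M)),
               variable = rep(rownames(M), ncol(M)),
               loading = as.vector(M),
               stringsAsFactors = FALSE)
  }
  contrast <- NULL
  if (!is.null(efield)) {
    montages <- unique(efield$montage)
    if (length(montages) != 2L) {
      stop_invalid("E-field matrix must contain exactly two montages")
    }
    lob <- intersect(model$x_names, names(efield))
    m1 <- colMeans(efield[efield$montage == montages[1], lob, drop = FALSE])
    m2 <- colMeans(efield[efield$montage == montages[2], lob, drop = FALSE])
    contrast <- data.frame(lobule = lob, stringsAsFactors = FALSE)
    contrast[[montages[1]]] <- as.numeric(m1)
    contrast[[montages[2]]] <- as.numeric(m2)
    contrast$difference <- as.numeric(m1 - m2)
  }
  list(predictor_loadings = long(model$x_loadings),
       response_loadings = long(model$y_loadings),
       contrast = contrast)
}

#' Rank predictors by overall coefficient magnitude
#'
#' Orders predictors by the Euclidean norm of their rows of the PLS
#' coefficient matrix, i.e. by total strength of their estimated linear
#' effect across all responses. Used to check recovery of planted active
#' lobules.
#'
#' @param model A fitted `plsr_model`.
#' @return Character vector of predictor names, strongest first.
#' @export
rank_predictors <- function(model) {
  strength <- sqrt(rowSums(model$coefficient_matrix^2))
  names(sort(strength, decreasing = TRUE))
}

#' Serialize a PLS model to JSON
#'
#' @param model A fitted `plsr_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_plsr_json <- function(model, path) {
  payload <- list(
    n_components = model$n_components,
    x_names = model$x_names, y_names = model$y_names,
    x_means = as.list(model$x_means), y_means = as.list(model$y_means),
    x_weights = model$x_weights, x_loadings = model$x_loadings,
    y_loadings = model$y_loadings,
    coefficient_matrix = model$coefficient_matrix,
    pct_var_x = model$pct_var_x, pct_var_y = model$pct_var_y,
    r_squared = model$r_squared)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
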