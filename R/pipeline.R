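#' Analysis configuration
#'
#' Bundles every knob of an end-to-end run: cohort size, gait generator
#' settings for the pre-intervention walk, per-montage post-intervention
#' effect multipliers, PLS component count, significance level and seeds.
#' Stimulation metadata (current, duration, electrode labels) is carried
#' as annotation only and affects no computation.
#'
#' @param n_subjects Cohort size.
#' @param seed Master seed; stage seeds are derived deterministically.
#' @param out_dir Output directory for artifacts (created if absent).
#' @param gait Baseline [gait_gen_config()] parameter overrides (list).
#' @param montage_effects Named list per montage of mean multiplicative
#'   post-intervention effects on `cycle_time`, `stance_fraction_affected`
#'   and `stance_fraction_unaffected` plus `sd`, the between-subject SD of
#'   the cycle-time multiplier.
#' @param n_components PLS components (default 10).
#' @param alpha Significance level in (0, 1).
#' @param use_planted_changes If TRUE the change table is produced by a
#'   [planted_association()] applied to the E-field matrix instead of by
#'   pre/post gait trials (regression ground-truth demo mode).
#' @param planted_noise_sd Noise SD for the planted association.
#' @param stim_metadata Annotation list (never used in computation).
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(n_subjects = 10L, seed = 1L, out_dir = tempfile("gaitdose_"),
                            gait = list(),
                            montage_effects = list(
                              dentate = list(cycle_time = 0.96,
                                             stance_fraction_affected = 1.00,
                                             stance_fraction_unaffected = 0.98,
                                             sd = 0.03),
                              leg = list(cycle_time = 1.03,
                                         stance_fraction_affected = 1.00,
                                         stance_fraction_unaffected = 1.02,
                                         sd = 0.03)),
                            n_components = 10L, alpha = 0.05,
                            use_planted_changes = FALSE,
                            planted_noise_sd = 0,
                            stim_metadata = list(current_mA = 2,
                                                 duration_min = 15,
                                                 electrode_area_cm2 = 3.14,
                                                 montage_electrodes = list(
                                                   dentate = "PO9h-PO10h",
                                                   leg = "Exx7-Exx8"))) {
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must lie in (0, 1)")
  if (n_subjects < 1) stop_config("n_subjects must be >= 1")
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 out_dir = out_dir, gait = gait,
                 montage_effects = montage_effects,
                 n_components = as.integer(n_components), alpha = alpha,
                 use_planted_changes = isTRUE(use_planted_changes),
                 planted_noise_sd = planted_noise_sd,
                 stim_metadata = stim_metadata),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the [analysis_config()]
#'   arguments.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop_config("config file does not exist: ", path)
  vals <- yaml::read_yaml(path)
  do.call(analysis_config, vals)
}

#' Minimal clinically important difference assessment
#'
#' Flags pre-to-post improvement against the published MCID thresholds:
#' ten-metre walk test speed gain of at least 0.10 m/s, timed-up-and-go
#' reduction of at least 8 s, Berg Balance Scale gain of at least 12.5
#' points.
#'
#' @param record List or one-row data.frame with `tmwt_speed_pre`,
#'   `tmwt_speed_post` (m/s), `tug_pre`, `tug_post` (s), `bbs_pre`,
#'   `bbs_post` (points in \[0, 56\]).
#' @return Named logical vector: `tmwt`, `tug`, `bbs`.
#' @export
mcid_assessment <- function(record) {
  need <- c("tmwt_speed_pre", "tmwt_speed_post", "tug_pre", "tug_post",
            "bbs_pre", "bbs_post")
  miss <- setdiff(need, names(record))
  if (length(miss)) stop_schema("clinical record missing: ",
                                paste(miss, collapse = ", "))
  for (f in c("bbs_pre", "bbs_post")) {
    if (record[[f]] < 0 || record[[f]] > 56) {
      stop_invalid(f, " out of the BBS range [0, 56]")
    }
  }
  for (f in c("tmwt_speed_pre", "tmwt_speed_post", "tug_pre", "tug_post")) {
    if (record[[f]] <= 0) stop_invalid(f, " must be positive")
  }
  c(tmwt = (record$tmwt_speed_post - record$tmwt_speed_pre) >= 0.10,
    tug = (record$tug_pre - record$tug_post) >= 8,
    bbs = (record$bbs_post - record$bbs_pre) >= 12.5)
}

#' MCID constants
#' @return Named numeric vector of the three MCID thresholds.
#' @export
mcid_thresholds <- function() c(tmwt_m_per_s = 0.10, tug_s = 8, bbs_points = 12.5)

# synthetic pre/post clinical scores for the demo pipeline
generate_clinical_records <- function(cohort, montages, seed) {
  set.seed(seed)
  rows <- list()
  for (s in cohort$subject_id) for (m in montages) {
    tmwt_pre <- max(0.2, stats::rnorm(1, 0.8, 0.1))
    tug_pre <- max(10, stats::rnorm(1, 30, 5))
    bbs_pre <- min(56, max(0, round(stats::rnorm(1, 44, 5))))
    rows[[length(rows) + 1L]] <- data.frame(
      subject = s, montage = m,
      tmwt_speed_pre = tmwt_pre,
      tmwt_speed_post = max(0.2, tmwt_pre + stats::rnorm(1, 0.08, 0.05)),
      tug_pre = tug_pre,
      tug_post = max(5, tug_pre - stats::rnorm(1, 5, 3)),
      bbs_pre = bbs_pre,
      bbs_post = min(56, max(0, bbs_pre + round(stats::rnorm(1, 4, 3)))),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Synthetic end-to-end run: cohort generation, pre/post walk trials per
#' montage, gait index extraction, percent-normalized-change table,
#' montage comparison by exact rank-sum test, E-field generation, PLS
#' regression of change on lobular field strength, and clinical MCID
#' flagging. Every intermediate artifact is written under
#' `config$out_dir`; the run is deterministic given `config$seed`.
#'
#' @param config An [analysis_config()].
#' @return Object of class `analysis_report`: list with `indices`,
#'   `changes`, `ranksum`, `pls` (model), `efield`, `clinical`,
#'   `mcid_flags`, `metadata` (seeds, config hash, failures).
#' @export
run_full_analysis <- function(config) {
  if (!inherits(config, "analysis_config")) {
    stop_config("config must be an analysis_config")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  failures <- character()
  report <- list()
  montages <- names(config$montage_effects)

  cfg_path <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))

  cohort <- generate_cohort(config$n_subjects,
                            seed = derive_seed(config$seed, "cohort"))
  report$cohort <- cohort

  # --- gait trials and indices -------------------------------------------
  indices <- tryCatch({
    rows <- list()
    for (i in seq_len(nrow(cohort))) {
      prof <- cohort[i, ]
      base <- utils::modifyList(
        list(seed = derive_seed(config$seed, paste0("gait", i))),
        config$gait)
      for (m in montages) {
        eff <- config$montage_effects[[m]]
        set.seed(derive_seed(config$seed, paste0("effect", i, m)))
        mult <- stats::rnorm(1, eff$cycle_time, eff$sd %||% 0)
        for (sess in c("pre", "post")) {
          g <- base
          if (sess == "post") {
            g$cycle_time <- (g$cycle_time %||% 1.25) * mult
            g$stance_fraction_affected <-
              min(0.95, (g$stance_fraction_affected %||% 0.62) *
                    eff$stance_fraction_affected)
            g$stance_fraction_unaffected <-
              min(0.95, (g$stance_fraction_unaffected %||% 0.68) *
                    eff$stance_fraction_unaffected)
            g$walking_speed <- (g$walking_speed %||% 0.8) / mult
            g$seed <- derive_seed(config$seed, paste0("post", i, m))
          }
          trial <- generate_gait_events(prof, do.call(gait_gen_config, g),
                                        session = sess, montage = m)
          rows[[length(rows) + 1L]] <- compute_index_set(trial)
        }
      }
    }
    out <- do.call(rbind, lapply(rows, as.data.frame))
    utils::write.csv(out, file.path(config$out_dir, "gait_indices.csv"),
                     row.names = FALSE)
    out
  }, error = function(e) { failures <<- c(failures, paste("indices:", conditionMessage(e))); NULL })
  report$indices <- indices

  # --- E-field matrix -----------------------------------------------------
  efield <- tryCatch({
    profs <- default_montage_profiles()[montages]
    ef <- generate_efield_matrix(profs, cohort,
                                 seed = derive_seed(config$seed, "efield"))
    write_efield_csv(ef, file.path(config$out_dir, "efield.csv"))
    ef
  }, error = function(e) { failures <<- c(failures, paste("efield:", conditionMessage(e))); NULL })
  report$efield <- efield

  # --- change table -------------------------------------------------------
  changes <- tryCatch({
    if (config$use_planted_changes) {
      assoc <- planted_association(noise_sd = config$planted_noise_sd,
                                   seed = derive_seed(config$seed, "assoc"))
      ch <- plant_gait_change(efield, assoc)
      report$planted_association <- assoc
      ch
    } else {
      change_table_from_indices(indices)
    }
  }, error = function(e) { failures <<- c(failures, paste("changes:", conditionMessage(e))); NULL })
  if (!is.null(changes)) {
    utils::write.csv(changes, file.path(config$out_dir, "changes.csv"),
                     row.names = FALSE)
  }
  report$changes <- changes

  # --- montage comparison -------------------------------------------------
  report$ranksum <- tryCatch({
    rs <- compare_montages(changes, alpha = config$alpha)
    utils::write.csv(rs, file.path(config$out_dir, "ranksum.csv"),
                     row.names = FALSE)
    rs
  }, error = function(e) { failures <<- c(failures, paste("ranksum:", conditionMessage(e))); NULL })

  # --- PLS regression -----------------------------------------------------
  report$pls <- tryCatch({
    merged <- merge(efield, changes, by = c("subject", "montage"),
                    sort = TRUE)
    lob <- setdiff(names(efield), c("subject", "montage"))
    params <- setdiff(names(changes), c("subject", "montage"))
    model <- fit_pls(merged[, lob, drop = FALSE],
                     merged[, params, drop = FALSE],
                     n_components = config$n_components)
    write_plsr_json(model, file.path(config$out_dir, "pls_model.json"))
    loads <- extract_loadings(model, efield)
    utils::write.csv(loads$predictor_loadings,
                     file.path(config$out_dir, "predictor_loadings.csv"),
                     row.names = FALSE)
    utils::write.csv(loads$response_loadings,
                     file.path(config$out_dir, "response_loadings.csv"),
                     row.names = FALSE)
    utils::write.csv(loads$contrast,
                     file.path(config$out_dir, "montage_contrast.csv"),
                     row.names = FALSE)
    model
  }, error = function(e) { failures <<- c(failures, paste("pls:", conditionMessage(e))); NULL })

  # --- clinical MCID ------------------------------------------------------
  report$clinical <- tryCatch({
    cl <- generate_clinical_records(cohort, montages,
                                    derive_seed(config$seed, "clinical"))
    flags <- do.call(rbind, lapply(seq_len(nrow(cl)), function(i) {
      mcid_assessment(as.list(cl[i, ]))
    }))
    cl$mcid_tmwt <- flags[, "tmwt"]
    cl$mcid_tug <- flags[, "tug"]
    cl$mcid_bbs <- flags[, "bbs"]
    utils::write.csv(cl, file.path(config$out_dir, "clinical.csv"),
                     row.names = FALSE)
    cl
  }, error = function(e) { failures <<- c(failures, paste("clinical:", conditionMessage(e))); NULL })
  report$mcid_flags <- report$clinical[, c("subject", "montage", "mcid_tmwt",
                                           "mcid_tug", "mcid_bbs")]

  report$metadata <- list(seed = config$seed, config_hash = cfg_hash,
                          package_version = as.character(utils::packageVersion("gaitdose")),
                          failures = failures,
                          timestamp = format(Sys.time(), tz = "UTC"))
  class(report) <- "analysis_report"

  json_report <- list(
    r_squared = if (!is.null(report$pls)) report$pls$r_squared else NULL,
    cum_pct_var_y = if (!is.null(report$pls)) sum(report$pls$pct_var_y) else NULL,
    significant_parameters =
      if (!is.null(report$ranksum)) report$ranksum$parameter[report$ranksum$significant] else NULL,
    n_mcid_tmwt = if (!is.null(report$clinical)) sum(report$clinical$mcid_tmwt) else NULL,
    metadata = report$metadata)
  jsonlite::write_json(json_report, file.path(config$out_dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  writeLines(utils::capture.output(print(report)),
             file.path(config$out_dir, "summary.txt"))
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("gaitdose analysis report\n")
  cat("========================\n")
  cat(sprintf("seed %d  config %s\n", x$metadata$seed, x$metadata$config_hash))
  if (length(x$metadata$failures)) {
    cat("FAILED stages:\n")
    for (f in x$metadata$failures) cat("  - ", f, "\n", sep = "")
  }
  if (!is.null(x$indices)) {
    cat(sprintf("gait indices: %d trial rows\n", nrow(x$indices)))
  }
  if (!is.null(x$ranksum)) {
    sig <- x$ranksum[x$ranksum$significant, "parameter"]
    cat(sprintf("rank-sum: %d/%d parameters significant%s\n",
                length(sig), nrow(x$ranksum),
                if (length(sig)) paste0(" (", paste(sig, collapse = ", "), ")")
                else ""))
  }
  if (!is.null(x$pls)) {
    cat(sprintf("PLS: %d components, R^2 = %.4f, cum %%var(Y) = %.1f\n",
                x$pls$n_components, x$pls$r_squared, sum(x$pls$pct_var_y)))
  }
  if (!is.null(x$clinical)) {
    cat(sprintf("MCID flags: TMWT %d, TUG %d, BBS %d of %d records\n",
                sum(x$clinical$mcid_tmwt), sum(x$clinical$mcid_tug),
                sum(x$clinical$mcid_bbs), nrow(x$clinical)))
  }
  invisible(x)
}
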