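#' Run the full cue-integration analysis pipeline
#'
#' Reproduces the analysis sequence of a categorical audio-visual
#' cue-integration experiment on a trial table (simulated or supplied):
#' \enumerate{
#'   \item fit lapse-corrected unimodal psychometric functions per
#'     participant (audio-only; video-only per blur level), giving the
#'     single-cue sensory variances;
#'   \item predict sensory-only normative visual weights per blur from
#'     those variances (reliability weighting);
#'   \item fit the bimodal surface per participant and blur level, giving
#'     the observed weights and the combined bimodal variance, with
#'     bootstrap CIs on the visual weight;
#'   \item invert the bimodal variance identity to estimate the visual
#'     variance operating during cue combination;
#'   \item flag participants whose combination-task visual variance is
#'     grossly inconsistent with their single-cue visual variance;
#'   \item recompute ("corrected") predicted weights from the
#'     combination-task visual variances, excluding flagged participants
#'     from cohort summaries;
#'   \item optionally fit the environmental variances of the
#'     Gaussian-category model to the cohort's observed weights.
#' }
#'
#' All randomness (simulation and bootstraps) derives from `seed`, so a
#' rerun with the same configuration reproduces the report exactly.
#'
#' @param trials trial table (see [simulate_cohort()]); if `NULL`, a cohort
#'   is simulated from `observers` over `design`.
#' @param observers list of [observer_params()] used when `trials` is
#'   `NULL` (ground truth is then retained in the report for recovery
#'   checks).
#' @param design an [build_design()] object (default: the canonical
#'   26-repetition, 4-blur design).
#' @param seed master integer seed.
#' @param n_boot bootstrap replicates for per-fit CIs (default 200).
#' @param outlier_threshold variance-ratio threshold for
#'   [flag_outliers()] (default 4).
#' @param env_fit logical: fit environmental variances (default TRUE).
#' @param env_fit_scope `"pooled"` (fit once to cohort-mean weights;
#'   default) or `"per_participant"` (fit per participant, then average).
#' @param env_variance_source `"bimodal"` (default; combination-task
#'   visual variances, the corrected procedure) or `"unimodal"`
#'   (single-cue visual variances, the uncorrected comparison).
#' @return object of class `"cue_analysis"`: list with `weights` (data
#'   frame, one row per participant x blur: sensory-predicted, corrected-
#'   predicted and observed visual weights with CI bounds and outlier
#'   flag), `variances` (per participant x blur variance ledger as a data
#'   frame), `ledgers`, `outliers`, `cohort` (per-blur means over included
#'   participants), `env` (an `env_fit` or NULL), `fits` (all fit
#'   objects), `config`.
#' @examples
#' \donttest{
#' d <- build_design(repetitions = 26, blur_levels = 4, seed = 1)
#' obs <- lapply(1:2, function(i) observer_params(paste0("P", i)))
#' res <- run_cue_analysis(observers = obs, design = d, seed = 1,
#'                         n_boot = 100)
#' summary(res)
#' }
#' @export
run_cue_analysis <- function(trials = NULL, observers = NULL, design = NULL,
                             seed = 1, n_boot = 200, outlier_threshold = 4,
                             env_fit = TRUE,
                             env_fit_scope = c("pooled", "per_participant"),
                             env_variance_source = c("bimodal", "unimodal")) {
  env_fit_scope <- match.arg(env_fit_scope)
  env_variance_source <- match.arg(env_variance_source)
  if (is.null(design)) design <- build_design(seed = seed)
  if (is.null(trials)) {
    if (is.null(observers))
      stop("supply either a trial table or a list of observers",
           call. = FALSE)
    trials <- simulate_cohort(observers, design, seed = seed)
  }
  stopifnot(all(c("participant", "kind", "blur", "a_step", "v_step",
                  "response") %in% names(trials)))
  participants <- unique(trials$participant)
  blurs <- sort(unique(trials$blur[trials$kind != "audio_only"]))

  stage <- function(name, who, expr)
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed for %s: %s",
                   name, who, conditionMessage(e)), call. = FALSE))

  fits <- list()
  ledgers <- list()
  wt_rows <- list()
  for (p in participants) {
    tp <- trials[trials$participant == p, ]

    fa <- stage("unimodal_fit", paste0(p, "/audio_only"),
                fit_unimodal(tp[tp$kind == "audio_only", ]))
    s2a <- unname(coef(fa)["sigma"]^2)
    fv <- lapply(blurs, function(b)
      stage("unimodal_fit", sprintf("%s/video_only/blur%d", p, b),
            fit_unimodal(tp[tp$kind == "video_only" & tp$blur == b, ])))
    s2v_uni <- vapply(fv, function(f) unname(coef(f)["sigma"]^2), 1)

    fb <- lapply(blurs, function(b) {
      f <- stage("bimodal_fit", sprintf("%s/bimodal/blur%d", p, b),
                 fit_bimodal(tp[tp$kind == "bimodal" & tp$blur == b, ]))
      bseed <- (seed + 104729L * match(p, participants) + 13L * b) %%
        .Machine$integer.max
      stage("bootstrap", sprintf("%s/bimodal/blur%d", p, b),
            bootstrap_ci(f, n_boot = n_boot, seed = bseed))
    })
    s2av <- vapply(fb, function(f) unname(coef(f)["sigma_av"]^2), 1)
    w_a_obs <- vapply(fb, function(f) unname(coef(f)["w_a"]), 1)
    w_v_obs <- 1 - w_a_obs

    s2v_bim <- vapply(seq_along(blurs), function(i)
      tryCatch(infer_bimodal_visual_variance(s2av[i], s2a, w_a_obs[i],
                                             w_v_obs[i]),
               error = function(e) NA_real_), 1)

    ledgers[[p]] <- variance_ledger(p, s2a, s2v_uni, s2av, s2v_bim)
    fits[[p]] <- list(audio = fa, video = fv, bimodal = fb)

    w_sens <- vapply(s2v_uni, function(s2v)
      predict_weights_sensory(s2a, s2v)[["w_v"]], 1)
    w_corr <- vapply(s2v_bim, function(s2v)
      if (is.na(s2v)) NA_real_
      else predict_weights_sensory(s2a, s2v)[["w_v"]], 1)
    ci <- t(vapply(fb, function(f) f$ci$intervals["w_v", ], numeric(2)))

    wt_rows[[p]] <- data.frame(
      participant = p, blur = blurs,
      predicted_sensory_w_v = w_sens,
      predicted_corrected_w_v = w_corr,
      observed_w_v = w_v_obs,
      observed_w_v_lo = ci[, 1], observed_w_v_hi = ci[, 2],
      sigma2_a_uni = s2a, sigma2_v_uni = s2v_uni,
      sigma2_av = s2av, sigma2_v_bimodal = s2v_bim)
  }

  outliers <- stage("outlier_qc", "cohort",
                    flag_outliers(ledgers, outlier_threshold))
  weights <- do.call(rbind, wt_rows)
  rownames(weights) <- NULL
  weights$outlier <- weights$participant %in%
    outliers$participant[outliers$outlier]

  keep <- weights[!weights$outlier, ]
  cohort <- do.call(rbind, lapply(blurs, function(b) {
    kb <- keep[keep$blur == b, ]
    data.frame(blur = b, n = nrow(kb),
               mean_predicted_sensory = mean(kb$predicted_sensory_w_v),
               mean_predicted_corrected = mean(kb$predicted_corrected_w_v,
                                               na.rm = TRUE),
               mean_observed = mean(kb$observed_w_v))
  }))

  env <- NULL
  if (env_fit) {
    s2v_src <- if (env_variance_source == "bimodal") "sigma2_v_bimodal"
               else "sigma2_v_uni"
    env <- stage("environmental_fit", "cohort", {
      if (env_fit_scope == "pooled") {
        s2v <- vapply(blurs, function(b)
          mean(keep[[s2v_src]][keep$blur == b], na.rm = TRUE), 1)
        s2a <- mean(keep$sigma2_a_uni[!duplicated(keep$participant)])
        fit_environmental_variance(cohort$mean_observed, s2a, s2v)
      } else {
        per <- lapply(unique(keep$participant), function(p) {
          kp <- keep[keep$participant == p, ]
          fit_environmental_variance(kp$observed_w_v, kp$sigma2_a_uni[1],
                                     kp[[s2v_src]])
        })
        avg <- per[[1]]
        avg$sigma2_a_env <- mean(vapply(per, `[[`, 1, "sigma2_a_env"))
        avg$sigma2_v_env <- mean(vapply(per, `[[`, 1, "sigma2_v_env"))
        avg$mse <- mean(vapply(per, `[[`, 1, "mse"))
        avg$per_participant <- per
        avg
      }
    })
  }

  structure(
    list(weights = weights, ledgers = ledgers, outliers = outliers,
         cohort = cohort, env = env, fits = fits,
         config = list(seed = seed, n_boot = n_boot,
                       outlier_threshold = outlier_threshold,
                       env_fit_scope = env_fit_scope,
                       env_variance_source = env_variance_source,
                       design = design, observers = observers)),
    class = "cue_analysis")
}

#' @export
print.cue_analysis <- function(x, ...) {
  cat(sprintf(paste0(
    "<cue_analysis> %d participants (%d flagged as outliers), ",
    "%d blur levels\n"),
    length(x$ledgers), sum(x$outliers$outlier), nrow(x$cohort)))
  print(x$cohort, digits = 3)
  if (!is.null(x$env)) print(x$env)
  invisible(x)
}

#' @export
summary.cue_analysis <- function(object, ...) {
  out <- list(cohort = object$cohort, outliers = object$outliers,
              env = object$env, n_participants = length(object$ledgers),
              comparison = tryCatch(compare_weights(object),
                                    error = function(e) NULL))
  class(out) <- "summary.cue_analysis"
  out
}

#' @export
print.summary.cue_analysis <- function(x, ...) {
  cat("Categorical cue-integration analysis\n")
  cat(sprintf("Participants: %d (%d flagged by variance-ratio QC)\n\n",
              x$n_participants, sum(x$outliers$outlier)))
  cat("Cohort mean visual weights per blur level:\n")
  print(x$cohort, digits = 3)
  if (!is.null(x$comparison)) {
    cat("\nPredicted (corrected) - observed, with bootstrap CIs:\n")
    print(x$comparison$table, digits = 3)
    cat(sprintf("Observed mean w_v monotone decreasing in blur: %s\n",
                x$comparison$monotone_decreasing))
  }
  if (!is.null(x$env)) {
    cat("\n"); print(x$env)
  }
  invisible(x)
}

#' Compare predicted and observed cue weights across the cohort
#'
#' For each blur level, computes the mean difference between predicted and
#' observed visual weights over included (non-outlier) participants, with
#' percentile bootstrap CIs obtained by resampling participants, plus a
#' monotonicity check of the mean observed visual weight against blur.
#' This is the pipeline's cohort-level summary of model agreement: the
#' normative account is supported when every per-blur CI covers zero and
#' the observed weight falls as blur rises.
#'
#' @param report a `"cue_analysis"` object.
#' @param which compare `"corrected"` (default) or `"sensory"` predicted
#'   weights.
#' @param n_boot participant-resampling bootstrap replicates (default
#'   2000).
#' @param level confidence level (default 0.95).
#' @return list with `table` (data frame: blur, mean_diff, lo, hi,
#'   covers_zero), `monotone_decreasing` (logical), `which`.
#' @export
compare_weights <- function(report, which = c("corrected", "sensory"),
                            n_boot = 2000, level = 0.95) {
  stopifnot(inherits(report, "cue_analysis"))
  which <- match.arg(which)
  keep <- report$weights[!report$weights$outlier, ]
  ids <- unique(keep$participant)
  if (length(ids) < 2)
    stop("need >= 2 included participants to compare cohort weights",
         call. = FALSE)
  pred_col <- if (which == "corrected") "predicted_corrected_w_v"
              else "predicted_sensory_w_v"
  blurs <- sort(unique(keep$blur))

  diff_mat <- vapply(blurs, function(b) {
    kb <- keep[keep$blur == b, ]
    kb[[pred_col]][match(ids, kb$participant)] -
      kb$observed_w_v[match(ids, kb$participant)]
  }, numeric(length(ids)))
  diff_mat <- matrix(diff_mat, nrow = length(ids))

  set.seed((report$config$seed + 524287L) %% .Machine$integer.max)
  alpha <- (1 - level) / 2
  boot_means <- matrix(NA_real_, n_boot, length(blurs))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(length(ids), replace = TRUE)
    boot_means[b, ] <- colMeans(diff_mat[idx, , drop = FALSE], na.rm = TRUE)
  }
  lo <- apply(boot_means, 2, stats::quantile, alpha, na.rm = TRUE)
  hi <- apply(boot_means, 2, stats::quantile, 1 - alpha, na.rm = TRUE)
  tab <- data.frame(blur = blurs,
                    mean_diff = colMeans(diff_mat, na.rm = TRUE),
                    lo = lo, hi = hi,
                    covers_zero = lo <= 0 & hi >= 0)
  rownames(tab) <- NULL
  obs_means <- vapply(blurs, function(b)
    mean(keep$observed_w_v[keep$blur == b]), 1)
  list(table = tab,
       monotone_decreasing = all(diff(obs_means) < 0),
       which = which)
}

#' Write the weight report tables
#'
#' Writes the per-participant weight table as CSV and the cohort summary
#' (means, outliers, environmental fit) as JSON.
#'
#' @param report a `"cue_analysis"`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "cue_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "weights.csv")
  utils::write.csv(report$weights, p1, row.names = FALSE)
  p2 <- file.path(dir, "summary.json")
  summ <- list(cohort = report$cohort, outliers = report$outliers,
               seed = report$config$seed)
  if (!is.null(report$env))
    summ$environmental_fit <- list(
      sigma2_a_env = report$env$sigma2_a_env,
      sigma2_v_env = report$env$sigma2_v_env,
      mse = report$env$mse)
  jsonlite::write_json(summ, p2, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(p1, p2))
}

#' Run the pipeline from a YAML or list configuration
#'
#' Thin configuration front end over [run_cue_analysis()]: accepts either
#' a list or a YAML file path with fields `design` (repetitions,
#' blur_levels, sessions, seed), `observers` (list of [observer_params()]
#' argument lists), `seed`, `n_boot`, `outlier_threshold`, `env_fit`,
#' `trials` (CSV path of an external trial table), `out_dir`.
#'
#' @param config list or path to a YAML file.
#' @return the `"cue_analysis"` report (written to `out_dir` when given).
#' @export
run_config <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  des <- do.call(build_design, config$design %||% list())
  obs <- if (!is.null(config$observers))
    lapply(config$observers, function(o) do.call(observer_params, o))
  trials <- if (!is.null(config$trials)) read_trials(config$trials)
  res <- run_cue_analysis(
    trials = trials, observers = obs, design = des,
    seed = config$seed %||% 1, n_boot = config$n_boot %||% 200,
    outlier_threshold = config$outlier_threshold %||% 4,
    env_fit = config$env_fit %||% TRUE)
  if (!is.null(config$out_dir)) write_report(res, config$out_dir)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
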