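#' Define a simulated 2AFC observer
#'
#' Parameterizes a synthetic participant in the phoneme-labeling task. On
#' each trial the observer forms noisy internal estimates of the presented
#' auditory and/or visual continuum positions, combines them linearly, and
#' responds /da/ when the decision variable exceeds a criterion; with
#' probability `lapse` the response is instead a fair coin flip
#' (stimulus-independent guessing).
#'
#' Weighting schemes:
#' \describe{
#'   \item{`sensory_optimal`}{weights inversely proportional to the sensory
#'     variances (reliability weighting), recomputed per blur level.}
#'   \item{`categorical_optimal`}{Fisher linear-discriminant weights for two
#'     Gaussian categories with equal diagonal covariance: each weight is
#'     proportional to the category-mean separation divided by the total
#'     (sensory + environmental) variance of that cue.}
#'   \item{`fixed`}{constant weights regardless of blur, for testing that
#'     downstream weight estimation does not assume optimality.}
#' }
#'
#' Defaults emulate the canonical study conditions: auditory noise constant
#' across blur, visual noise rising with blur from well below to equal to
#' the auditory level, a small lapse rate, and a criterion at the continuum
#' midpoint so the unimodal PSEs of the two modalities are matched.
#'
#' @param participant identifier string.
#' @param sigma_a auditory sensory SD (step units).
#' @param sigma_v visual sensory SD per blur level (step units), vector of
#'   length `length(blur levels)`; indexed by `blur + 1`.
#' @param lapse lapse (guessing) probability, in `[0, 0.5)`.
#' @param criterion decision threshold in step units (default 5.5, the
#'   continuum midpoint).
#' @param weight_scheme `"sensory_optimal"`, `"categorical_optimal"` or
#'   `"fixed"`.
#' @param fixed_weights length-2 numeric `(w_a, w_v)` summing to 1;
#'   required when `weight_scheme = "fixed"`.
#' @param sigma2_a_env,sigma2_v_env environmental (production) variances in
#'   step^2, used by `categorical_optimal`.
#' @param delta_a,delta_v category-mean separations in step units (default
#'   9, the full continuum span).
#' @param bimodal_v_sd_scale multiplier applied to the visual sensory SD on
#'   bimodal trials only (default 1). Values above 1 emulate observers whose
#'   visual noise during cue combination exceeds their single-cue visual
#'   noise — the signature the outlier QC is designed to catch.
#' @return object of class `"observer_params"`.
#' @examples
#' obs <- observer_params("P1")
#' observer_weights(obs, blur = 0)
#' @export
observer_params <- function(participant = "P1",
                            sigma_a = 2.0,
                            sigma_v = c(0.8, 1.2, 1.6, 2.0),
                            lapse = 0.04,
                            criterion = 5.5,
                            weight_scheme = c("sensory_optimal",
                                              "categorical_optimal",
                                              "fixed"),
                            fixed_weights = NULL,
                            sigma2_a_env = 0,
                            sigma2_v_env = 0,
                            delta_a = 9,
                            delta_v = 9,
                            bimodal_v_sd_scale = 1) {
  weight_scheme <- match.arg(weight_scheme)
  stopifnot(sigma_a > 0, all(sigma_v > 0),
            lapse >= 0, lapse < 0.5,
            sigma2_a_env >= 0, sigma2_v_env >= 0,
            delta_a >= 0, delta_v >= 0,
            bimodal_v_sd_scale > 0)
  if (weight_scheme == "fixed") {
    if (is.null(fixed_weights) || length(fixed_weights) != 2)
      stop("fixed_weights = c(w_a, w_v) required for the fixed scheme",
           call. = FALSE)
    if (abs(sum(fixed_weights) - 1) > 1e-8)
      stop("fixed_weights must sum to 1", call. = FALSE)
  }
  structure(
    list(participant = participant, sigma_a = sigma_a, sigma_v = sigma_v,
         lapse = lapse, criterion = criterion,
         weight_scheme = weight_scheme, fixed_weights = fixed_weights,
         sigma2_a_env = sigma2_a_env, sigma2_v_env = sigma2_v_env,
         delta_a = delta_a, delta_v = delta_v,
         bimodal_v_sd_scale = bimodal_v_sd_scale),
    class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf(
    "<observer_params> %s: sigma_a=%.3g, sigma_v=(%s), lapse=%.3g, %s\n",
    x$participant, x$sigma_a, paste(signif(x$sigma_v, 3), collapse = ", "),
    x$lapse, x$weight_scheme))
  invisible(x)
}

#' Effective cue weights of an observer at a blur level
#'
#' Returns the (w_a, w_v) the observer applies on bimodal trials, as
#' dictated by its weighting scheme. Note the weights are computed from
#' the *unimodal* sensory SDs (the observer's beliefs about its noise),
#' not from any bimodal noise inflation.
#'
#' @param params an `observer_params`.
#' @param blur blur level (0-based).
#' @return named numeric `c(w_a, w_v)` summing to 1.
#' @export
observer_weights <- function(params, blur) {
  stopifnot(inherits(params, "observer_params"))
  sv <- params$sigma_v[blur + 1L]
  if (is.na(sv)) stop("blur level ", blur, " not parameterized", call. = FALSE)
  w <- switch(params$weight_scheme,
    sensory_optimal = predict_weights_sensory(params$sigma_a^2, sv^2),
    categorical_optimal = predict_weights_categorical(categorical_model(
      delta_a = params$delta_a, delta_v = params$delta_v,
      sigma2_a_sens = params$sigma_a^2, sigma2_v_sens = sv^2,
      sigma2_a_env = params$sigma2_a_env,
      sigma2_v_env = params$sigma2_v_env)),
    fixed = c(w_a = params$fixed_weights[1], w_v = params$fixed_weights[2]))
  c(w_a = unname(w[1]), w_v = unname(w[2]))
}

#' Analytic response probability of an observer
#'
#' Closed-form probability of a /da/ response for a given stimulus
#' condition: `lapse/2 + (1 - lapse) * pnorm((E[D] - criterion) / sd(D))`,
#' where for bimodal trials `E[D] = w_a * a + w_v * v` and
#' `sd(D)^2 = w_a^2 sigma_a^2 + w_v^2 sigma_v^2`, and for unimodal trials D
#' is the single noisy estimate. Serves as the independent oracle for the
#' trial-level Monte-Carlo simulator.
#'
#' @param params an `observer_params`.
#' @param kind `"audio_only"`, `"video_only"` or `"bimodal"`.
#' @param blur blur level (0-based; ignored for audio_only).
#' @param a_step,v_step stimulus continuum positions (whichever the kind
#'   requires).
#' @return probability of responding /da/ (response = 1).
#' @export
response_prob <- function(params, kind, blur = 0, a_step = NA, v_step = NA) {
  stopifnot(inherits(params, "observer_params"))
  lam <- params$lapse
  z <- switch(kind,
    audio_only = (a_step - params$criterion) / params$sigma_a,
    video_only = (v_step - params$criterion) / params$sigma_v[blur + 1L],
    bimodal = {
      w <- observer_weights(params, blur)
      sv <- params$sigma_v[blur + 1L] * params$bimodal_v_sd_scale
      mu_d <- w["w_a"] * a_step + w["w_v"] * v_step
      sd_d <- sqrt(w["w_a"]^2 * params$sigma_a^2 + w["w_v"]^2 * sv^2)
      (mu_d - params$criterion) / sd_d
    },
    stop("unknown condition kind: ", kind, call. = FALSE))
  unname(lam / 2 + (1 - lam) * stats::pnorm(z))
}

#' Simulate a single 2AFC trial
#'
#' Mechanistic single-trial draw: with probability `lapse` the response is
#' a fair coin flip; otherwise Gaussian internal estimates are drawn around
#' the presented step(s), combined by the observer's weights into a
#' decision variable D, and the response is 1 (/da/) iff D exceeds the
#' criterion.
#'
#' @inheritParams response_prob
#' @return integer response, 0 (/ba/) or 1 (/da/).
#' @export
simulate_trial <- function(params, kind, blur = 0, a_step = NA, v_step = NA) {
  if (stats::runif(1) < params$lapse)
    return(as.integer(stats::runif(1) < 0.5))
  d <- switch(kind,
    audio_only = stats::rnorm(1, a_step, params$sigma_a),
    video_only = stats::rnorm(1, v_step, params$sigma_v[blur + 1L]),
    bimodal = {
      w <- observer_weights(params, blur)
      a_hat <- stats::rnorm(1, a_step, params$sigma_a)
      v_hat <- stats::rnorm(1, v_step,
                            params$sigma_v[blur + 1L] * params$bimodal_v_sd_scale)
      w["w_a"] * a_hat + w["w_v"] * v_hat
    },
    stop("unknown condition kind: ", kind, call. = FALSE))
  as.integer(d > params$criterion)
}

# Vectorized trial generation over a schedule for one observer; same
# generative mechanism as simulate_trial, drawn column-wise for speed.
.simulate_schedule <- function(params, schedule) {
  n <- nrow(schedule)
  resp <- integer(n)
  kind <- schedule$kind
  blur <- schedule$blur

  is_a <- kind == "audio_only"
  is_v <- kind == "video_only"
  is_b <- kind == "bimodal"

  d <- numeric(n)
  if (any(is_a))
    d[is_a] <- stats::rnorm(sum(is_a), schedule$a_step[is_a], params$sigma_a)
  if (any(is_v))
    d[is_v] <- stats::rnorm(sum(is_v), schedule$v_step[is_v],
                            params$sigma_v[blur[is_v] + 1L])
  if (any(is_b)) {
    wb <- vapply(sort(unique(blur[is_b])), function(b)
      observer_weights(params, b), numeric(2))
    colnames(wb) <- sort(unique(blur[is_b]))
    w_a <- wb["w_a", as.character(blur[is_b])]
    w_v <- wb["w_v", as.character(blur[is_b])]
    sv <- params$sigma_v[blur[is_b] + 1L] * params$bimodal_v_sd_scale
    a_hat <- stats::rnorm(sum(is_b), schedule$a_step[is_b], params$sigma_a)
    v_hat <- stats::rnorm(sum(is_b), schedule$v_step[is_b], sv)
    d[is_b] <- w_a * a_hat + w_v * v_hat
  }
  resp <- as.integer(d > params$criterion)

  lapse_trial <- stats::runif(n) < params$lapse
  if (any(lapse_trial))
    resp[lapse_trial] <- as.integer(stats::runif(sum(lapse_trial)) < 0.5)
  resp
}

#' Simulate a cohort of observers over a design
#'
#' Generates one trial record per (observer x scheduled trial). Each
#' observer draws from an independent substream derived from `seed`, so the
#' full table is reproducible and adding or removing observers does not
#' perturb the others' data.
#'
#' @param params_list list of `observer_params` (or a single one).
#' @param design an `experiment_design` from [build_design()].
#' @param seed integer seed.
#' @return data frame of trial records: `participant`, `session`, `block`,
#'   `kind`, `blur`, `a_step`, `v_step`, `response`.
#' @examples
#' d <- build_design(repetitions = 1, blur_levels = 1, seed = 1)
#' trials <- simulate_cohort(list(observer_params("P1")), d, seed = 1)
#' nrow(trials)  # 52
#' @export
simulate_cohort <- function(params_list, design, seed = 1) {
  if (inherits(params_list, "observer_params"))
    params_list <- list(params_list)
  stopifnot(length(params_list) >= 1, inherits(design, "experiment_design"))
  ids <- vapply(params_list, `[[`, "", "participant")
  if (anyDuplicated(ids))
    stop("duplicate participant identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)

  out <- vector("list", length(params_list))
  for (i in seq_along(params_list)) {
    set.seed((seed + 7919L * i) %% .Machine$integer.max)
    tab <- design$schedule[, c("session", "block", "kind", "blur",
                               "a_step", "v_step")]
    tab$response <- .simulate_schedule(params_list[[i]], design$schedule)
    tab <- cbind(participant = ids[i], tab)
    out[[i]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write / read a simulated trial table as CSV
#'
#' The companion JSON sidecar stores the generating observer parameters so
#' recovery tests can compare fitted values against ground truth.
#'
#' @param trials trial data frame from [simulate_cohort()].
#' @param path CSV file path.
#' @param params_list optional list of `observer_params` written alongside
#'   as `<path>.params.json`.
#' @return `read_trials()` returns the trial data frame.
#' @export
write_trials <- function(trials, path, params_list = NULL) {
  utils::write.csv(trials, path, row.names = FALSE)
  if (!is.null(params_list)) {
    if (inherits(params_list, "observer_params"))
      params_list <- list(params_list)
    jsonlite::write_json(lapply(params_list, unclass),
                         paste0(path, ".params.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
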