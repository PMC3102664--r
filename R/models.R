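#' Normative cue weights from sensory variance
#'
#' Reliability weighting for a linear combination of two Gaussian cues:
#' each cue's weight is proportional to its inverse variance,
#' `w_a = (1/s2_a) / (1/s2_a + 1/s2_v)`, `w_v = 1 - w_a`. This is the
#' provisional normative predictor that accounts for sensory uncertainty
#' only; it is the minimum-variance unbiased combination rule for
#' continuous estimation.
#'
#' @param sigma2_a,sigma2_v cue variances (step^2), both > 0.
#' @return named numeric `c(w_a, w_v)` summing to 1.
#' @examples
#' predict_weights_sensory(4, 1)  # w_v = 0.8
#' @export
predict_weights_sensory <- function(sigma2_a, sigma2_v) {
  if (sigma2_a <= 0 || sigma2_v <= 0)
    stop("variances must be positive", call. = FALSE)
  w_a <- unname((1 / sigma2_a) / (1 / sigma2_a + 1 / sigma2_v))
  c(w_a = w_a, w_v = 1 - w_a)
}

#' Variance of the optimally combined estimate
#'
#' Harmonic combination `s2_a * s2_v / (s2_a + s2_v)` — the variance of the
#' product of two Gaussian likelihoods, always strictly smaller than either
#' single-cue variance (fusion never hurts).
#'
#' @inheritParams predict_weights_sensory
#' @return combined variance (step^2).
#' @examples
#' combined_variance(4, 1)  # 0.8
#' @export
combined_variance <- function(sigma2_a, sigma2_v) {
  if (sigma2_a <= 0 || sigma2_v <= 0)
    stop("variances must be positive", call. = FALSE)
  sigma2_a * sigma2_v / (sigma2_a + sigma2_v)
}

#' Linear decision variable
#'
#' `D = w_a * a + w_v * v`; the observer labels the stimulus /da/ when D
#' exceeds a criterion. Vectorized over `a` and `v`.
#'
#' @param a,v auditory and visual continuum positions (step units).
#' @param weights length-2 numeric `(w_a, w_v)`, summing to 1.
#' @return numeric decision variable(s).
#' @export
decision_variable <- function(a, v, weights) {
  if (abs(sum(weights) - 1) > 1e-8)
    stop("weights must be normalized (sum to 1)", call. = FALSE)
  unname(weights[1] * a + weights[2] * v)
}

#' Gaussian-category model parameters
#'
#' Bundles the parameters of the two-category (/ba/ vs /da/) Gaussian
#' model in joint audio-visual feature space: category-mean separations
#' per cue, sensory variances (observer noise), and environmental
#' (production) variances — the within-category variability of exemplars
#' in the world, which blurring the stimulus does not change.
#'
#' @param delta_a,delta_v category-mean separations (step units), >= 0.
#' @param sigma2_a_sens,sigma2_v_sens sensory variances (step^2), > 0.
#' @param sigma2_a_env,sigma2_v_env environmental variances (step^2), >= 0.
#' @return object of class `"categorical_model"`.
#' @export
categorical_model <- function(delta_a = 9, delta_v = 9,
                              sigma2_a_sens, sigma2_v_sens,
                              sigma2_a_env = 0, sigma2_v_env = 0) {
  stopifnot(delta_a >= 0, delta_v >= 0,
            sigma2_a_sens > 0, sigma2_v_sens > 0,
            sigma2_a_env >= 0, sigma2_v_env >= 0)
  structure(
    list(delta_a = delta_a, delta_v = delta_v,
         sigma2_a_sens = sigma2_a_sens, sigma2_v_sens = sigma2_v_sens,
         sigma2_a_env = sigma2_a_env, sigma2_v_env = sigma2_v_env),
    class = "categorical_model")
}

#' Optimal weights for categorical (two-Gaussian) discrimination
#'
#' Fisher linear-discriminant weights for two Gaussian categories with
#' equal diagonal covariance and uncorrelated cue noise: each cue's weight
#' is proportional to its category-mean separation divided by its total
#' variance, `w_a ~ delta_a / (s2_a_sens + s2_a_env)` (and likewise for
#' the visual cue), normalized to sum to 1. With equal separations and
#' zero environmental variance this collapses exactly to the sensory-only
#' reliability weighting of [predict_weights_sensory()]. Because the
#' environmental term is unaffected by stimulus degradation, a nonzero
#' environmental variance compresses ("flattens") the range of predicted
#' weights across blur levels relative to the sensory-only prediction.
#'
#' @param model a [categorical_model()].
#' @return named numeric `c(w_a, w_v)` summing to 1.
#' @examples
#' m <- categorical_model(sigma2_a_sens = 4, sigma2_v_sens = 1)
#' predict_weights_categorical(m)  # equals predict_weights_sensory(4, 1)
#' @export
predict_weights_categorical <- function(model) {
  stopifnot(inherits(model, "categorical_model"))
  num_a <- model$delta_a / (model$sigma2_a_sens + model$sigma2_a_env)
  num_v <- model$delta_v / (model$sigma2_v_sens + model$sigma2_v_env)
  if (num_a + num_v <= 0)
    stop("no discriminative signal: both weight numerators are zero",
         call. = FALSE)
  w_a <- unname(num_a / (num_a + num_v))
  c(w_a = w_a, w_v = 1 - w_a)
}

#' Invert the bimodal variance identity for the visual cue
#'
#' For any linear integrator — optimal or not — the variance of the
#' combined estimate satisfies
#' `s2_av = w_a^2 * s2_a + w_v^2 * s2_v`. Given the fitted bimodal
#' variance, the unimodal auditory variance, and the observed weights,
#' this solves for the visual variance operating *during cue combination*:
#' `s2_v = (s2_av - w_a^2 * s2_a) / w_v^2`. This estimate does not assume
#' the observer weights cues optimally, and it need not match the
#' single-cue visual variance — comparing the two is the basis of the
#' outlier QC.
#'
#' @param sigma2_av fitted combined bimodal variance (step^2).
#' @param sigma2_a unimodal auditory variance (step^2).
#' @param w_a,w_v observed cue weights (sum to 1, `w_v > 0`).
#' @return inferred visual variance during combination (step^2).
#' @examples
#' infer_bimodal_visual_variance(0.8, 4, 0.2, 0.8)  # 1
#' @export
infer_bimodal_visual_variance <- function(sigma2_av, sigma2_a, w_a, w_v) {
  if (w_v <= 0)
    stop("w_v must be positive to recover the visual variance", call. = FALSE)
  if (sigma2_av <= w_a^2 * sigma2_a)
    stop("infeasible: bimodal variance (", signif(sigma2_av, 4),
         ") does not exceed the auditory contribution (",
         signif(w_a^2 * sigma2_a, 4), ")", call. = FALSE)
  (sigma2_av - w_a^2 * sigma2_a) / w_v^2
}

#' Build a per-participant variance ledger
#'
#' Collects, per blur level, the unimodal visual variance, the fitted
#' combined bimodal variance, and the inferred bimodal visual variance,
#' together with the unimodal auditory variance.
#'
#' @param participant identifier.
#' @param sigma2_a_uni unimodal auditory variance (step^2).
#' @param sigma2_v_uni numeric vector, unimodal visual variance per blur.
#' @param sigma2_av numeric vector, fitted combined bimodal variance per
#'   blur.
#' @param sigma2_v_bimodal numeric vector, inferred bimodal visual variance
#'   per blur (NA where the inversion was infeasible).
#' @return object of class `"variance_ledger"`.
#' @export
variance_ledger <- function(participant, sigma2_a_uni, sigma2_v_uni,
                            sigma2_av, sigma2_v_bimodal) {
  stopifnot(length(sigma2_v_uni) == length(sigma2_av),
            length(sigma2_av) == length(sigma2_v_bimodal),
            sigma2_a_uni > 0, all(sigma2_v_uni > 0))
  structure(
    list(participant = participant, sigma2_a_uni = sigma2_a_uni,
         sigma2_v_uni = sigma2_v_uni, sigma2_av = sigma2_av,
         sigma2_v_bimodal = sigma2_v_bimodal),
    class = "variance_ledger")
}

#' Flag observers whose bimodal visual noise is inconsistent with their
#' single-cue visual noise
#'
#' A participant is flagged when their mean (across blur levels) inferred
#' bimodal visual variance exceeds `ratio_threshold` times their mean
#' unimodal visual variance. The threshold is a ratio because the
#' continuum step scale is arbitrary. Participants missing the inferred
#' estimates are skipped with a warning.
#'
#' @param ledgers list of [variance_ledger()] objects (one per
#'   participant).
#' @param ratio_threshold flag when mean bimodal / mean unimodal variance
#'   exceeds this (default 4).
#' @return data frame: `participant`, `mean_uni`, `mean_bimodal`, `ratio`,
#'   `outlier` (logical).
#' @export
flag_outliers <- function(ledgers, ratio_threshold = 4) {
  stopifnot(ratio_threshold > 0)
  if (inherits(ledgers, "variance_ledger")) ledgers <- list(ledgers)
  rows <- lapply(ledgers, function(l) {
    if (all(is.na(l$sigma2_v_bimodal))) {
      warning("participant ", l$participant,
              " has no usable bimodal visual variance estimate; skipped",
              call. = FALSE)
      return(NULL)
    }
    mu <- mean(l$sigma2_v_uni, na.rm = TRUE)
    mb <- mean(l$sigma2_v_bimodal, na.rm = TRUE)
    data.frame(participant = l$participant, mean_uni = mu, mean_bimodal = mb,
               ratio = mb / mu, outlier = mb > ratio_threshold * mu)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit environmental variances to observed cue weights
#'
#' Fits the two environmental-variance parameters of the Gaussian-category
#' model by least squares: finds `(s2_a_env, s2_v_env) >= 0` minimizing the
#' mean squared difference between the model's predicted visual weights
#' (via [predict_weights_categorical()]) and the observed visual weights
#' across blur levels, with the per-blur sensory variances held at their
#' measured values. Bounded L-BFGS-B from a 5 x 5 log-spaced multi-start
#' grid (plus the zero-variance corner); nonnegativity enforced by
#' optimizing on a sqrt scale.
#'
#' @param w_v_obs observed visual weights per blur, each in `[0, 1]`.
#' @param sigma2_a_sens auditory sensory variance (scalar or per blur).
#' @param sigma2_v_sens visual sensory variance per blur.
#' @param delta_a,delta_v category-mean separations (default 9).
#' @return object of class `"env_fit"`: list with `sigma2_a_env`,
#'   `sigma2_v_env`, `mse`, `w_v_pred` (per blur), `w_v_obs`.
#' @examples
#' s2v <- c(0.64, 1.44, 2.56, 4)
#' m <- lapply(s2v, function(s) categorical_model(
#'   sigma2_a_sens = 4, sigma2_v_sens = s,
#'   sigma2_a_env = 2, sigma2_v_env = 1))
#' w_obs <- vapply(m, function(mi) predict_weights_categorical(mi)["w_v"], 1)
#' fit_environmental_variance(w_obs, 4, s2v)  # recovers (2, 1)
#' @export
fit_environmental_variance <- function(w_v_obs, sigma2_a_sens, sigma2_v_sens,
                                       delta_a = 9, delta_v = 9) {
  n <- length(w_v_obs)
  if (n < 2)
    stop("need >= 2 blur levels to constrain 2 environmental variances",
         call. = FALSE)
  if (any(w_v_obs < 0 | w_v_obs > 1))
    stop("observed weights must lie in [0, 1]", call. = FALSE)
  sigma2_a_sens <- rep_len(sigma2_a_sens, n)
  stopifnot(length(sigma2_v_sens) == n,
            all(sigma2_a_sens > 0), all(sigma2_v_sens > 0))

  pred <- function(e_a, e_v)
    vapply(seq_len(n), function(i)
      predict_weights_categorical(categorical_model(
        delta_a = delta_a, delta_v = delta_v,
        sigma2_a_sens = sigma2_a_sens[i], sigma2_v_sens = sigma2_v_sens[i],
        sigma2_a_env = e_a, sigma2_v_env = e_v))[["w_v"]], 1)
  obj <- function(par) mean((pred(par[1]^2, par[2]^2) - w_v_obs)^2)

  scale <- mean(c(sigma2_a_sens, sigma2_v_sens))
  grid <- sqrt(scale) * sqrt(c(0.1, 0.5, 1, 4, 16))
  starts <- rbind(expand.grid(a = grid, v = grid), c(0, 0))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(as.numeric(starts[i, ]), obj, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-14))
    # polish, Nelder-Mead from a degenerate simplex at the origin can stall
    fit <- stats::optim(fit$par, obj, method = "BFGS",
                        control = list(maxit = 200, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  structure(
    list(sigma2_a_env = best$par[1]^2, sigma2_v_env = best$par[2]^2,
         mse = best$value, w_v_pred = pred(best$par[1]^2, best$par[2]^2),
         w_v_obs = w_v_obs,
         sigma2_a_sens = sigma2_a_sens, sigma2_v_sens = sigma2_v_sens,
         delta_a = delta_a, delta_v = delta_v),
    class = "env_fit")
}

#' @export
print.env_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "<env_fit> environmental variances: auditory %.4g, visual %.4g ",
    "(step^2)\n  mse = %.3g over %d blur levels\n"),
    x$sigma2_a_env, x$sigma2_v_env, x$mse, length(x$w_v_obs)))
  invisible(x)
}
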