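## Lapse-corrected psychometric likelihoods.
##
## Unimodal model:  p(1 | x) = lapse/2 + (1 - lapse) * Phi((x - mu) / sigma)
## Bimodal surface: p(1 | a, v) = lapse/2 +
##                    (1 - lapse) * Phi((w_a*a + (1-w_a)*v - c) / sigma_av)
##
## Both are binomial likelihoods over aggregated stimulus cells. The lapse
## mixture models stimulus-independent guessing: with probability lapse the
## observer responds at random (fair coin), which compresses the asymptotes
## of the psychometric function away from 0 and 1.

.PF_BOUNDS <- list(mu = c(-5, 16), sigma = c(0.05, 20), lapse = c(0, 0.35))

.clamp_p <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)

.binom_nll <- function(p, k, n) -sum(k * log(p) + (n - k) * log(1 - p))

.pf1d_p <- function(par, x) {
  # par = (mu, sigma, lapse)
  par[3] / 2 + (1 - par[3]) * stats::pnorm((x - par[1]) / par[2])
}

.pf1d_nll <- function(par, x, k, n) .binom_nll(.clamp_p(.pf1d_p(par, x)), k, n)

.pf2d_p <- function(par, a, v) {
  # par = (w_a, c, sigma_av, lapse)
  d <- par[1] * a + (1 - par[1]) * v
  par[4] / 2 + (1 - par[4]) * stats::pnorm((d - par[2]) / par[3])
}

.pf2d_nll <- function(par, a, v, k, n)
  .binom_nll(.clamp_p(.pf2d_p(par, a, v)), k, n)

## Analytic gradients of the negative log-likelihoods (chain rule through
## p = lapse/2 + (1 - lapse) * Phi(z)); keeps the quasi-Newton fits and the
## bootstrap refits off finite differences.
.pf1d_grad <- function(par, x, k, n) {
  z <- (x - par[1]) / par[2]
  phi <- stats::dnorm(z)
  p <- .clamp_p(par[3] / 2 + (1 - par[3]) * stats::pnorm(z))
  dldp <- -(k / p - (n - k) / (1 - p))
  c(sum(dldp * (1 - par[3]) * phi * (-1 / par[2])),
    sum(dldp * (1 - par[3]) * phi * (-z / par[2])),
    sum(dldp * (0.5 - stats::pnorm(z))))
}

.pf2d_grad <- function(par, a, v, k, n) {
  z <- (par[1] * a + (1 - par[1]) * v - par[2]) / par[3]
  phi <- stats::dnorm(z)
  p <- .clamp_p(par[4] / 2 + (1 - par[4]) * stats::pnorm(z))
  dldp <- -(k / p - (n - k) / (1 - p))
  c(sum(dldp * (1 - par[4]) * phi * (a - v) / par[3]),
    sum(dldp * (1 - par[4]) * phi * (-1 / par[3])),
    sum(dldp * (1 - par[4]) * phi * (-z / par[3])),
    sum(dldp * (0.5 - stats::pnorm(z))))
}

# Aggregate binary trials into binomial cells over the given stimulus keys.
.aggregate_cells <- function(df, keys) {
  stopifnot(all(c(keys, "response") %in% names(df)),
            all(df$response %in% c(0, 1)))
  agg_k <- stats::aggregate(df["response"], by = df[keys], FUN = sum)
  agg_n <- stats::aggregate(df["response"], by = df[keys], FUN = length)
  cells <- agg_k[keys]
  cells$k <- agg_k$response
  cells$n <- agg_n$response
  cells[do.call(order, cells[keys]), , drop = FALSE]
}

.multi_start_optim <- function(starts, nll, lower, upper, gr = NULL) {
  fits <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    st <- pmin(pmax(as.numeric(starts[i, ]), lower), upper)
    fits[[i]] <- tryCatch(
      stats::optim(st, nll, gr = gr, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(factr = 1e7, maxit = 500)),
      error = function(e) list(value = Inf, par = st, convergence = 99L))
  }
  vals <- vapply(fits, `[[`, 1, "value")
  # among fits tied at the optimum (within the 1e-8 objective tolerance),
  # prefer one that terminated cleanly
  near <- which(vals <= min(vals) + 1e-8)
  conv <- near[vapply(fits[near], `[[`, 0L, "convergence") == 0L]
  best_i <- if (length(conv)) conv[1] else which.min(vals)
  list(best = fits[[best_i]], start_nll = vapply(
    seq_len(nrow(starts)),
    function(i) nll(pmin(pmax(as.numeric(starts[i, ]), lower), upper)),
    1))
}

# Crude moment-style initial values from the empirical proportions.
.pf1d_guess <- function(x, k, n) {
  p <- (k + 0.5) / (n + 1)
  mu0 <- tryCatch(stats::approx(p, x, xout = 0.5, ties = mean)$y,
                  error = function(e) NA_real_)
  if (!is.finite(mu0)) mu0 <- stats::weighted.mean(x, n * p * (1 - p) + 1e-6)
  if (!is.finite(mu0)) mu0 <- mean(x)
  # distance between the 25% and 75% crossings ~ 1.35 sigma
  q <- tryCatch(stats::approx(p, x, xout = c(0.25, 0.75), ties = mean)$y,
                error = function(e) c(NA, NA))
  s0 <- if (all(is.finite(q))) max(abs(diff(q)) / 1.349, 0.1) else 1
  c(mu0, s0)
}

#' Fit a lapse-corrected cumulative-Gaussian psychometric function
#'
#' Maximum-likelihood fit of
#' `p(1 | x) = lapse/2 + (1 - lapse) * pnorm((x - mu) / sigma)` to binary
#' 2AFC responses over stimulus values `x`. `mu` is the point of subjective
#' equality (PSE, the category boundary) and `sigma` the SD of the
#' underlying Gaussian discrimination process (inverse slope); the lapse
#' term absorbs stimulus-independent guessing so that sensory variance
#' estimates are not biased by attentional errors. The binomial likelihood
#' is maximized by bounded quasi-Newton optimization from 8 starting
#' points (a coarse mu x sigma grid plus data-driven moment estimates),
#' because the likelihood can be multimodal in (sigma, lapse).
#'
#' Fits whose `sigma` lands on the lower bound (e.g. perfectly separated
#' step-function data) are flagged `degenerate` rather than silently
#' accepted.
#'
#' @param formula model formula `response ~ stimulus` (response binary 0/1).
#' @param data data frame holding the formula variables, one row per trial.
#' @param sigma_bounds,lapse_max,mu_bounds box constraints for the
#'   optimizer, in step units (defaults: sigma in \[0.05, 20\], lapse in
#'   \[0, 0.35\], mu in \[-5, 16\]).
#' @return object of class `"psychfit"` with components `coefficients`
#'   (`mu`, `sigma`, `lapse`), `logLik`, `n_trials`, `converged`,
#'   `degenerate`, `cells` (aggregated binomial data), `start_logLik`
#'   (log-likelihood at each multi-start initialization), `ci` (filled by
#'   [bootstrap_ci()]).
#' @examples
#' set.seed(1)
#' x <- rep(1:10, each = 26)
#' p <- 0.02 + 0.96 * pnorm((x - 5.5) / 1.2)
#' d <- data.frame(step = x, response = rbinom(length(x), 1, p))
#' fit <- fit_psychometric(response ~ step, d)
#' coef(fit)
#' @export
fit_psychometric <- function(formula, data,
                             sigma_bounds = .PF_BOUNDS$sigma,
                             lapse_max = .PF_BOUNDS$lapse[2],
                             mu_bounds = .PF_BOUNDS$mu) {
  mf <- stats::model.frame(formula, data)
  df <- data.frame(response = mf[[1]], x = mf[[2]])
  cells <- .aggregate_cells(df, "x")
  .fit_pf1d(cells, sigma_bounds, lapse_max, mu_bounds)
}

.fit_pf1d <- function(cells, sigma_bounds = .PF_BOUNDS$sigma,
                      lapse_max = .PF_BOUNDS$lapse[2],
                      mu_bounds = .PF_BOUNDS$mu) {
  x <- cells$x; k <- cells$k; n <- cells$n
  if (length(unique(x)) < 2)
    stop("need trials at >= 2 distinct stimulus steps", call. = FALSE)

  lower <- c(mu_bounds[1], sigma_bounds[1], 0)
  upper <- c(mu_bounds[2], sigma_bounds[2], lapse_max)
  g <- .pf1d_guess(x, k, n)
  starts <- rbind(
    expand.grid(mu = c(3, 5.5, 8), sigma = c(0.5, 2), lapse = 0.02),
    c(g[1], g[2], 0.02),
    c(g[1], 1, 0.1))
  nll <- function(par) .pf1d_nll(par, x, k, n)
  gr <- function(par) .pf1d_grad(par, x, k, n)
  opt <- .multi_start_optim(starts, nll, lower, upper, gr)
  best <- opt$best

  degenerate <- best$par[2] <= sigma_bounds[1] + 1e-6 ||
    length(unique(k / n)) == 1
  structure(
    list(coefficients = c(mu = best$par[1], sigma = best$par[2],
                          lapse = best$par[3]),
         logLik = -best$value, n_trials = sum(n),
         converged = best$convergence == 0, degenerate = degenerate,
         cells = cells, start_logLik = -opt$start_nll,
         bounds = list(lower = lower, upper = upper), ci = NULL),
    class = "psychfit")
}

#' Fit the bimodal psychometric surface and extract cue weights
#'
#' Maximum-likelihood fit of the two-dimensional lapse-corrected surface
#' `p(1 | a, v) = lapse/2 + (1 - lapse) *
#'   pnorm((w_a * a + (1 - w_a) * v - c) / sigma_av)`
#' to audio-visual 2AFC responses at one blur level, jointly estimating
#' the auditory weight `w_a` (visual weight `1 - w_a`), the criterion `c`,
#' the combined SD `sigma_av`, and the lapse rate. The weights are
#' constrained to sum to 1: the linear decision rule is scale-invariant,
#' so normalization fixes the gauge and matches how weights are reported.
#'
#' The weights are identified only by cue-conflict stimuli: on the
#' no-conflict diagonal (`a == v`) the weights enter solely through their
#' sum, so the fit refuses diagonal-only data.
#'
#' @param trials data frame with columns `a_step`, `v_step`, `response`
#'   (binary), typically the bimodal trials of one participant at one blur
#'   level.
#' @param sigma_bounds,lapse_max,c_bounds box constraints (defaults as in
#'   [fit_psychometric()], criterion in \[-5, 16\]).
#' @return object of class `"bimodal_fit"` with `coefficients` (`w_a`,
#'   `w_v`, `criterion`, `sigma_av`, `lapse`), `logLik`, `n_trials`,
#'   `converged`, `degenerate`, `cells`, `start_logLik`, `ci`.
#' @examples
#' d <- build_design(repetitions = 8, blur_levels = 1, seed = 2)
#' tr <- simulate_cohort(observer_params("P1"), d, seed = 2)
#' fit_bimodal(tr[tr$kind == "bimodal", ])
#' @export
fit_bimodal <- function(trials, sigma_bounds = .PF_BOUNDS$sigma,
                        lapse_max = .PF_BOUNDS$lapse[2],
                        c_bounds = .PF_BOUNDS$mu) {
  cells <- .aggregate_cells(
    data.frame(a = trials$a_step, v = trials$v_step,
               response = trials$response), c("a", "v"))
  .fit_pf2d(cells, sigma_bounds, lapse_max, c_bounds)
}

.fit_pf2d <- function(cells, sigma_bounds = .PF_BOUNDS$sigma,
                      lapse_max = .PF_BOUNDS$lapse[2],
                      c_bounds = .PF_BOUNDS$mu) {
  a <- cells$a; v <- cells$v; k <- cells$k; n <- cells$n
  offsets <- unique(a - v)
  if (length(offsets) < 2)
    stop("cue weights are unidentifiable: trials span only conflict ",
         "offset(s) {", paste(sort(offsets), collapse = ", "),
         "}; include stimuli at >= 2 distinct a - v offsets", call. = FALSE)

  lower <- c(0, c_bounds[1], sigma_bounds[1], 0)
  upper <- c(1, c_bounds[2], sigma_bounds[2], lapse_max)
  g <- .pf1d_guess((a + v) / 2, k, n)
  starts <- rbind(
    expand.grid(w_a = c(0.2, 0.5, 0.8), c = 5.5, sigma = c(0.7, 2),
                lapse = 0.02),
    c(0.5, g[1], g[2], 0.02),
    c(0.5, g[1], 1, 0.1))
  nll <- function(par) .pf2d_nll(par, a, v, k, n)
  gr <- function(par) .pf2d_grad(par, a, v, k, n)
  opt <- .multi_start_optim(starts, nll, lower, upper, gr)
  best <- opt$best

  degenerate <- best$par[3] <= sigma_bounds[1] + 1e-6 ||
    length(unique(k / n)) == 1
  structure(
    list(coefficients = c(w_a = best$par[1], w_v = 1 - best$par[1],
                          criterion = best$par[2], sigma_av = best$par[3],
                          lapse = best$par[4]),
         logLik = -best$value, n_trials = sum(n),
         converged = best$convergence == 0, degenerate = degenerate,
         cells = cells, start_logLik = -opt$start_nll,
         bounds = list(lower = lower, upper = upper), ci = NULL),
    class = "bimodal_fit")
}

#' Fit a unimodal condition family from a trial table
#'
#' Convenience wrapper around the cumulative-Gaussian engine: selects the
#' stimulus axis implied by the condition kind (`a_step` for audio-only,
#' `v_step` for video-only) and fits the trials as one condition family.
#'
#' @param trials data frame of trials from a single `kind` x `blur`
#'   condition family, with columns `kind`, `a_step`/`v_step`, `response`.
#' @param ... passed to the fitting engine (bounds).
#' @return a `"psychfit"` object.
#' @export
fit_unimodal <- function(trials, ...) {
  kind <- unique(trials$kind)
  if (length(kind) != 1)
    stop("trials must come from a single condition kind", call. = FALSE)
  xcol <- switch(kind, audio_only = "a_step", video_only = "v_step",
                 stop("fit_unimodal expects unimodal trials; got kind ",
                      kind, call. = FALSE))
  fit_psychometric(stats::reformulate(xcol, "response"), trials, ...)
}

## ---- S3 methods -----------------------------------------------------------

#' @export
coef.psychfit <- function(object, ...) object$coefficients

#' @export
coef.bimodal_fit <- function(object, ...) object$coefficients

#' @export
logLik.psychfit <- function(object, ...)
  structure(object$logLik, df = 3, nobs = object$n_trials, class = "logLik")

#' @export
logLik.bimodal_fit <- function(object, ...)
  structure(object$logLik, df = 4, nobs = object$n_trials, class = "logLik")

#' @export
print.psychfit <- function(x, ...) {
  cf <- coef(x)
  cat(sprintf(paste0(
    "<psychfit> PSE = %.3f, sigma = %.3f, lapse = %.3f ",
    "(n = %d, logLik = %.2f%s%s)\n"),
    cf["mu"], cf["sigma"], cf["lapse"], x$n_trials, x$logLik,
    if (x$converged) "" else ", NOT CONVERGED",
    if (x$degenerate) ", DEGENERATE" else ""))
  invisible(x)
}

#' @export
print.bimodal_fit <- function(x, ...) {
  cf <- coef(x)
  cat(sprintf(paste0(
    "<bimodal_fit> w_a = %.3f, w_v = %.3f, criterion = %.3f, ",
    "sigma_av = %.3f, lapse = %.3f (n = %d%s%s)\n"),
    cf["w_a"], cf["w_v"], cf["criterion"], cf["sigma_av"], cf["lapse"],
    x$n_trials,
    if (x$converged) "" else ", NOT CONVERGED",
    if (x$degenerate) ", DEGENERATE" else ""))
  invisible(x)
}

#' @export
summary.psychfit <- function(object, ...) {
  cells <- object$cells
  cells$p_obs <- cells$k / cells$n
  cells$p_fit <- .pf1d_p(coef(object), cells$x)
  out <- list(coefficients = coef(object), logLik = object$logLik,
              n_trials = object$n_trials, converged = object$converged,
              degenerate = object$degenerate, cells = cells,
              ci = object$ci)
  class(out) <- "summary.psychfit"
  out
}

#' @export
print.summary.psychfit <- function(x, ...) {
  cat("Lapse-corrected cumulative-Gaussian psychometric fit\n\n")
  cat("Coefficients:\n")
  print(round(x$coefficients, 4))
  if (!is.null(x$ci)) {
    cat("\nBootstrap percentile CIs:\n")
    print(round(x$ci$intervals, 4))
  }
  cat(sprintf("\nlogLik: %.2f on %d trials%s%s\n", x$logLik, x$n_trials,
              if (x$converged) "" else " (not converged)",
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Predicted response probabilities from a psychometric fit
#'
#' @param object a `"psychfit"`.
#' @param newdata numeric vector of stimulus values, or data frame with
#'   column `x`; defaults to the fitted stimulus values.
#' @param ... unused.
#' @return numeric vector of P(response = 1).
#' @export
predict.psychfit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$cells$x
       else if (is.data.frame(newdata)) newdata$x else newdata
  .pf1d_p(coef(object), x)
}

#' Predicted response probabilities from a bimodal surface fit
#'
#' @param object a `"bimodal_fit"`.
#' @param newdata data frame with columns `a`, `v` (or `a_step`, `v_step`);
#'   defaults to the fitted cells.
#' @param ... unused.
#' @return numeric vector of P(response = 1).
#' @export
predict.bimodal_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$cells
  a <- if ("a" %in% names(newdata)) newdata$a else newdata$a_step
  v <- if ("v" %in% names(newdata)) newdata$v else newdata$v_step
  cf <- coef(object)
  .pf2d_p(c(cf["w_a"], cf["criterion"], cf["sigma_av"], cf["lapse"]), a, v)
}

#' @export
residuals.psychfit <- function(object, type = c("pearson", "deviance"), ...) {
  type <- match.arg(type)
  with(object$cells, {
    p <- predict(object)
    if (type == "pearson") (k - n * p) / sqrt(n * p * (1 - p))
    else sign(k / n - p) * sqrt(2 * (ifelse(k > 0, k * log(k / (n * p)), 0) +
      ifelse(k < n, (n - k) * log((n - k) / (n * (1 - p))), 0)))
  })
}

#' @export
residuals.bimodal_fit <- function(object, ...) {
  with(object$cells, {
    p <- predict(object)
    (k - n * p) / sqrt(n * p * (1 - p))
  })
}

#' Simulate binomial response data from a fitted psychometric function
#'
#' Parametric simulation at the fitted parameters over the fit's own
#' stimulus cells (same trial counts), e.g. for parametric bootstrap or
#' posterior-predictive style checks.
#'
#' @param object a `"psychfit"`.
#' @param nsim number of simulated datasets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return list of data frames with columns `x`, `k`, `n`.
#' @export
simulate.psychfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- predict(object)
  lapply(seq_len(nsim), function(i)
    data.frame(x = object$cells$x,
               k = stats::rbinom(nrow(object$cells), object$cells$n, p),
               n = object$cells$n))
}

#' Plot a psychometric fit
#'
#' Observed response proportions per stimulus step with the fitted
#' lapse-corrected cumulative Gaussian overlaid.
#'
#' @param x a `"psychfit"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.psychfit <- function(x, ...) {
  cells <- x$cells
  xx <- seq(min(cells$x), max(cells$x), length.out = 200)
  graphics::plot(cells$x, cells$k / cells$n, ylim = c(0, 1),
                 xlab = "stimulus step (/ba/ -> /da/)",
                 ylab = "P(respond /da/)", pch = 19, ...)
  graphics::lines(xx, predict(x, xx))
  cf <- coef(x)
  graphics::abline(v = cf["mu"], lty = 3)
  invisible(x)
}

## ---- bootstrap ------------------------------------------------------------

#' Nonparametric bootstrap confidence intervals for a psychometric fit
#'
#' Resamples trials with replacement within each stimulus condition
#' (equivalently, redraws each binomial cell count `k* ~ Binomial(n, k/n)`),
#' refits from a warm start at the point estimate, and returns percentile
#' intervals for every fitted parameter. Replicates whose refit is
#' degenerate (sigma pinned at its bound) are dropped and counted; a
#' warning is issued when more than 20% are dropped.
#'
#' @param object a `"psychfit"` or `"bimodal_fit"`.
#' @param n_boot number of bootstrap replicates (>= 100).
#' @param seed integer seed (intervals are deterministic given the seed).
#' @param level confidence level (default 0.95).
#' @param ... unused.
#' @return the fitted object with `$ci` set: a list with `intervals`
#'   (matrix, rows = parameters, columns = lower/upper), `level`,
#'   `n_boot`, `n_dropped`, `replicates` (matrix of refitted parameters).
#' @export
bootstrap_ci <- function(object, n_boot = 1000, seed = 1, level = 0.95, ...)
  UseMethod("bootstrap_ci")

.boot_engine <- function(object, n_boot, seed, level, refit) {
  if (n_boot < 100) stop("n_boot must be >= 100", call. = FALSE)
  set.seed(seed)
  cells <- object$cells
  p_hat <- cells$k / cells$n
  reps <- matrix(NA_real_, n_boot, length(coef(object)),
                 dimnames = list(NULL, names(coef(object))))
  dropped <- 0L
  for (b in seq_len(n_boot)) {
    kb <- stats::rbinom(nrow(cells), cells$n, p_hat)
    fb <- refit(kb)
    if (fb$degenerate) dropped <- dropped + 1L else reps[b, ] <- coef(fb)
  }
  if (dropped > 0.2 * n_boot)
    warning(sprintf("%d/%d bootstrap replicates degenerate and dropped",
                    dropped, n_boot), call. = FALSE)
  alpha <- (1 - level) / 2
  ints <- t(apply(reps, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                  na.rm = TRUE))
  object$ci <- list(intervals = ints, level = level, n_boot = n_boot,
                    n_dropped = dropped, replicates = reps)
  object
}

# Warm-started single refit used inside the bootstrap loop: one quasi-Newton
# run from the original optimum (plus a default-grid rescue if it fails).
.warm_refit <- function(nll, start, lower, upper, degen_idx, degen_bound,
                        gr = NULL) {
  fit <- tryCatch(
    stats::optim(start, nll, gr = gr, method = "L-BFGS-B", lower = lower,
                 upper = upper, control = list(factr = 1e7, maxit = 300)),
    error = function(e) NULL)
  if (is.null(fit))
    fit <- stats::optim((lower + upper) / 2, nll, gr = gr,
                        method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(factr = 1e7, maxit = 300))
  list(par = fit$par, degenerate = fit$par[degen_idx] <= degen_bound + 1e-6)
}

#' @rdname bootstrap_ci
#' @export
bootstrap_ci.psychfit <- function(object, n_boot = 1000, seed = 1,
                                  level = 0.95, ...) {
  cells <- object$cells
  lower <- object$bounds$lower; upper <- object$bounds$upper
  start <- unname(coef(object))
  refit <- function(kb) {
    w <- .warm_refit(function(par) .pf1d_nll(par, cells$x, kb, cells$n),
                     start, lower, upper, 2, lower[2],
                     function(par) .pf1d_grad(par, cells$x, kb, cells$n))
    list(coefficients = c(mu = w$par[1], sigma = w$par[2], lapse = w$par[3]),
         degenerate = w$degenerate)
  }
  .boot_engine(object, n_boot, seed, level,
               function(kb) structure(refit(kb), class = "psychfit"))
}

#' @rdname bootstrap_ci
#' @export
bootstrap_ci.bimodal_fit <- function(object, n_boot = 1000, seed = 1,
                                     level = 0.95, ...) {
  cells <- object$cells
  lower <- object$bounds$lower; upper <- object$bounds$upper
  cf <- coef(object)
  start <- unname(cf[c("w_a", "criterion", "sigma_av", "lapse")])
  refit <- function(kb) {
    w <- .warm_refit(function(par) .pf2d_nll(par, cells$a, cells$v, kb,
                                             cells$n),
                     start, lower, upper, 3, lower[3],
                     function(par) .pf2d_grad(par, cells$a, cells$v, kb,
                                              cells$n))
    list(coefficients = c(w_a = w$par[1], w_v = 1 - w$par[1],
                          criterion = w$par[2], sigma_av = w$par[3],
                          lapse = w$par[4]),
         degenerate = w$degenerate)
  }
  .boot_engine(object, n_boot, seed, level,
               function(kb) structure(refit(kb), class = "bimodal_fit"))
}
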