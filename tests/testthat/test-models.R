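test_that("sensory-variance weights follow inverse-variance weighting", {
  expect_equal(predict_weights_sensory(1, 1), c(w_a = 0.5, w_v = 0.5))
  expect_equal(predict_weights_sensory(4, 1)[["w_v"]], 0.8)
  # a vanishing-reliability cue loses its weight
  expect_lt(predict_weights_sensory(1, 1e8)[["w_v"]], 1e-6)
  expect_error(predict_weights_sensory(0, 1), "positive")
  expect_error(predict_weights_sensory(1, -2), "positive")
  # scale invariance: step units are arbitrary
  set.seed(1)
  for (i in 1:20) {
    s2 <- rexp(2) + 0.1
    cc <- rexp(1) + 0.1
    expect_equal(predict_weights_sensory(s2[1], s2[2]),
                 predict_weights_sensory(cc * s2[1], cc * s2[2]))
  }
})

test_that("combined variance is the harmonic combination and equals the
          weight-squared sum under optimal weights", {
  expect_equal(combined_variance(1, 1), 0.5)
  expect_equal(combined_variance(4, 1), 0.8)
  expect_error(combined_variance(-1, 1))
  set.seed(2)
  for (i in 1:50) {
    s2 <- rexp(2) + 0.05
    cv <- combined_variance(s2[1], s2[2])
    expect_lt(cv, min(s2))
    w <- predict_weights_sensory(s2[1], s2[2])
    expect_equal(cv, w[["w_a"]]^2 * s2[1] + w[["w_v"]]^2 * s2[2],
                 tolerance = 1e-12)
  }
})

test_that("the decision variable is the weighted cue average", {
  expect_equal(decision_variable(5.5, 5.5, c(0.3, 0.7)), 5.5)
  expect_equal(decision_variable(4, 7, c(0.5, 0.5)), 5.5)
  expect_equal(decision_variable(4, 7, c(1, 0)), 4)
  expect_error(decision_variable(4, 7, c(0.5, 0.6)), "normalized")
})

test_that("categorical weights collapse to sensory weights without
          environmental variance and flatten with it", {
  set.seed(3)
  for (i in 1:20) {
    s2 <- rexp(2) + 0.05
    m <- categorical_model(sigma2_a_sens = s2[1], sigma2_v_sens = s2[2])
    expect_equal(predict_weights_categorical(m),
                 predict_weights_sensory(s2[1], s2[2]), tolerance = 1e-12)
  }
  # symmetric totals -> equal weights
  m_eq <- categorical_model(sigma2_a_sens = 2, sigma2_v_sens = 1,
                            sigma2_a_env = 1, sigma2_v_env = 2)
  expect_equal(predict_weights_categorical(m_eq), c(w_a = 0.5, w_v = 0.5))
  # sweeping the visual sensory variance over the blur range moves the
  # weights less when environmental variance is present
  s2v_range <- c(0.64, 4)
  wv <- function(e_v) vapply(s2v_range, function(s)
    predict_weights_categorical(categorical_model(
      sigma2_a_sens = 4, sigma2_v_sens = s,
      sigma2_a_env = 0, sigma2_v_env = e_v))[["w_v"]], 1)
  expect_lt(diff(range(wv(2))), diff(range(wv(0))))
  expect_lt(diff(range(wv(8))), diff(range(wv(2))))
  expect_error(predict_weights_categorical(
    categorical_model(delta_a = 0, delta_v = 0,
                      sigma2_a_sens = 1, sigma2_v_sens = 1)),
    "discriminative")
})

test_that("the bimodal variance identity inverts exactly", {
  expect_equal(infer_bimodal_visual_variance(0.8, 4, 0.2, 0.8), 1.0)
  set.seed(4)
  for (i in 1:50) {
    s2a <- rexp(1) + 0.05
    s2v <- rexp(1) + 0.05
    w_a <- runif(1, 0.05, 0.95)
    s2av <- w_a^2 * s2a + (1 - w_a)^2 * s2v
    expect_equal(infer_bimodal_visual_variance(s2av, s2a, w_a, 1 - w_a),
                 s2v, tolerance = 1e-10)
  }
  expect_error(infer_bimodal_visual_variance(0.8, 4, 1, 0), "positive")
  expect_error(infer_bimodal_visual_variance(0.1, 4, 0.5, 0.5),
               "infeasible")
})

test_that("variance-ratio QC flags planted inconsistencies only", {
  mk <- function(id, scale) variance_ledger(
    id, sigma2_a_uni = 4, sigma2_v_uni = c(0.6, 1.4, 2.5, 4),
    sigma2_av = rep(1, 4), sigma2_v_bimodal = c(0.6, 1.4, 2.5, 4) * scale)
  cohort <- c(lapply(1:6, function(i) mk(paste0("C", i), 1.1)),
              list(mk("X1", 9), mk("X2", 10)))
  flags <- flag_outliers(cohort)
  expect_equal(flags$participant[flags$outlier], c("X1", "X2"))
  expect_equal(sum(flags$outlier), 2)
  # all consistent -> nothing flagged
  expect_false(any(flag_outliers(lapply(1:5, function(i)
    mk(paste0("C", i), 0.9)))$outlier))
  # missing bimodal estimates -> skipped with a warning
  gone <- mk("G", 1)
  gone$sigma2_v_bimodal <- rep(NA_real_, 4)
  expect_warning(f2 <- flag_outliers(list(mk("C1", 1), gone)), "skipped")
  expect_equal(nrow(f2), 1)
})

test_that("a parity threshold on noisy but consistent variances flags about
          half the cohort (degenerate setting)", {
  set.seed(6)
  cohort <- lapply(1:40, function(i) {
    base <- c(0.6, 1.4, 2.5, 4)
    variance_ledger(paste0("P", i), 4, base, rep(1, 4),
                    base * exp(rnorm(4, 0, 0.3)))
  })
  frac <- mean(flag_outliers(cohort, ratio_threshold = 1)$outlier)
  expect_gt(frac, 0.2)
  expect_lt(frac, 0.8)
})

test_that("environmental-variance fit recovers noiseless generators exactly
          and hits the zero bound for sensory-only data", {
  s2v <- c(0.64, 1.44, 2.56, 4)
  truth <- c(a = 2.1, v = 0.9)
  wv <- vapply(s2v, function(s) predict_weights_categorical(
    categorical_model(sigma2_a_sens = 4, sigma2_v_sens = s,
                      sigma2_a_env = unname(truth["a"]),
                      sigma2_v_env = unname(truth["v"])))[["w_v"]], 1)
  fit <- fit_environmental_variance(wv, 4, s2v)
  expect_lt(fit$mse, 1e-10)
  expect_equal(fit$sigma2_a_env, unname(truth["a"]), tolerance = 1e-3)
  expect_equal(fit$sigma2_v_env, unname(truth["v"]), tolerance = 1e-3)
  # weights that already match the sensory-only model need no
  # environmental variance
  wv0 <- vapply(s2v, function(s)
    predict_weights_sensory(4, s)[["w_v"]], 1)
  fit0 <- fit_environmental_variance(wv0, 4, s2v)
  expect_lt(fit0$mse, 1e-10)
  expect_lt(fit0$sigma2_a_env + fit0$sigma2_v_env, 1e-4)
  # flatter-than-sensory weights demand visual environmental variance
  w_flat <- 0.5 * wv0 + 0.5 * mean(wv0)
  fit_f <- fit_environmental_variance(w_flat, 4, s2v)
  expect_gt(fit_f$sigma2_v_env, 0.01)
  expect_error(fit_environmental_variance(wv0[1], 4, s2v[1]), ">= 2")
  expect_error(fit_environmental_variance(c(0.5, 1.2), 4, s2v[1:2]),
               "\\[0, 1\\]")
})
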