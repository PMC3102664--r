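test_that("unimodal fit recovers generating parameters and bias shrinks
          with repetitions", {
  gen <- c(mu = 5.5, sigma = 1.2, lapse = 0.04)
  est <- function(reps, n_subj, seed0) {
    t(vapply(seq_len(n_subj), function(i)
      coef(cuecat:::.fit_pf1d(fx_pf_cells(gen["mu"], gen["sigma"],
                                          gen["lapse"], reps,
                                          seed = seed0 + i))),
      numeric(3)))
  }
  e26 <- est(26, 60, 100)
  e260 <- est(260, 60, 700)
  # mean recovery close at the protocol's 26 repetitions
  expect_lt(abs(mean(e26[, "mu"]) - gen["mu"]) / gen["mu"], 0.05)
  expect_lt(abs(mean(e26[, "sigma"]) - gen["sigma"]) / gen["sigma"], 0.10)
  # bias decreases as repetitions grow tenfold
  expect_lt(abs(mean(e260[, "sigma"]) - gen["sigma"]),
            abs(mean(e26[, "sigma"]) - gen["sigma"]))
  expect_lt(abs(mean(e260[, "mu"]) - gen["mu"]) / gen["mu"], 0.01)
})

test_that("returned optimum dominates every multi-start initialization", {
  for (seed in 1:5) {
    f <- cuecat:::.fit_pf1d(fx_pf_cells(seed = seed))
    expect_true(all(f$logLik >= f$start_logLik - 1e-8))
    expect_lte(f$logLik, 0)
  }
  tr <- fx_p1_trials()
  fb <- fit_bimodal(tr[tr$kind == "bimodal" & tr$blur == 0, ])
  expect_true(all(fb$logLik >= fb$start_logLik - 1e-8))
})

test_that("fitted probabilities stay inside the lapse-compressed range", {
  f <- cuecat:::.fit_pf1d(fx_pf_cells(lapse = 0.2, seed = 8))
  lam <- coef(f)["lapse"]
  p <- predict(f, seq(-20, 30, by = 0.5))
  expect_true(all(p >= lam / 2 - 1e-12))
  expect_true(all(p <= 1 - lam / 2 + 1e-12))
})

test_that("relabeling the categories and reflecting the continuum maps the
          PSE and leaves slope and lapse fixed", {
  cells <- fx_pf_cells(mu = 4.8, sigma = 1.5, lapse = 0.06, seed = 13)
  f1 <- cuecat:::.fit_pf1d(cells)
  refl <- data.frame(x = 11 - cells$x, k = cells$n - cells$k, n = cells$n)
  f2 <- cuecat:::.fit_pf1d(refl[order(refl$x), ])
  expect_equal(unname(coef(f2)["mu"]), 11 - unname(coef(f1)["mu"]),
               tolerance = 1e-3)
  expect_equal(unname(coef(f2)["sigma"]), unname(coef(f1)["sigma"]),
               tolerance = 1e-3)
  expect_equal(unname(coef(f2)["lapse"]), unname(coef(f1)["lapse"]),
               tolerance = 1e-3)
})

test_that("degenerate and underdetermined inputs are flagged or refused", {
  # perfectly separated step-function data: slope pinned at its bound
  step_cells <- data.frame(x = 1:10, k = c(rep(0, 5), rep(26, 5)), n = 26)
  f <- cuecat:::.fit_pf1d(step_cells)
  expect_true(f$degenerate)
  expect_equal(unname(coef(f)["sigma"]), 0.05, tolerance = 1e-4)
  # constant responses
  flat <- data.frame(x = 1:10, k = rep(26, 10), n = 26)
  expect_true(cuecat:::.fit_pf1d(flat)$degenerate)
  # fewer than two stimulus levels
  expect_error(
    fit_psychometric(response ~ x,
                     data.frame(x = rep(5, 20), response = rbinom(20, 1, 0.5))),
    "2 distinct")
})

test_that("bimodal surface fit recovers weights without assuming
          optimality", {
  d <- fx_full_design()
  # reliability-weighting observer: sigma_a = 2, sigma_v = 1 -> w_v = 0.8
  opt <- observer_params("OPT", sigma_a = 2, sigma_v = c(1, 1, 1, 1))
  tr <- simulate_cohort(opt, d, seed = 31)
  f <- fit_bimodal(tr[tr$kind == "bimodal" & tr$blur == 0, ])
  f <- bootstrap_ci(f, n_boot = 200, seed = 32)
  ci <- f$ci$intervals["w_v", ]
  expect_true(ci[1] <= 0.8 && 0.8 <= ci[2])
  expect_equal(unname(coef(f)["w_v"]), 0.8, tolerance = 0.08)
  # mis-weighted observer: equal fixed weights despite unequal noise
  mis <- observer_params("MIS", sigma_a = 2, sigma_v = c(1, 1, 1, 1),
                         weight_scheme = "fixed",
                         fixed_weights = c(0.5, 0.5))
  tr2 <- simulate_cohort(mis, d, seed = 33)
  f2 <- fit_bimodal(tr2[tr2$kind == "bimodal" & tr2$blur == 0, ])
  expect_equal(unname(coef(f2)["w_v"]), 0.5, tolerance = 0.08)
})

test_that("no-conflict-only data are rejected as weight-unidentifiable", {
  tr <- fx_p1_trials()
  bi <- tr[tr$kind == "bimodal" & tr$blur == 0, ]
  diag_only <- bi[bi$a_step == bi$v_step, ]
  expect_error(fit_bimodal(diag_only), "unidentifiable")
})

test_that("bootstrap intervals are deterministic, bracket the estimate, and
          insist on enough replicates", {
  f <- cuecat:::.fit_pf1d(fx_pf_cells(seed = 5))
  b1 <- bootstrap_ci(f, n_boot = 120, seed = 77)
  b2 <- bootstrap_ci(f, n_boot = 120, seed = 77)
  expect_identical(b1$ci$intervals, b2$ci$intervals)
  cf <- coef(f)
  for (par in c("mu", "sigma")) {
    expect_lte(b1$ci$intervals[par, 1], cf[par])
    expect_gte(b1$ci$intervals[par, 2], cf[par])
  }
  expect_error(bootstrap_ci(f, n_boot = 50), ">= 100")
})

test_that("model methods behave like standard fitted-model accessors", {
  d <- cells_to_trials(fx_pf_cells(seed = 3), "step")
  f <- fit_psychometric(response ~ step, d)
  expect_named(coef(f), c("mu", "sigma", "lapse"))
  expect_s3_class(f, "psychfit")
  expect_equal(attr(logLik(f), "df"), 3)
  expect_length(predict(f, 1:10), 10)
  expect_true(all(is.finite(residuals(f))))
  expect_true(all(is.finite(residuals(f, type = "deviance"))))
  sims <- simulate(f, nsim = 2, seed = 9)
  sims2 <- simulate(f, nsim = 2, seed = 9)
  expect_identical(sims, sims2)
  expect_output(print(summary(f)), "Coefficients")
  tr <- fx_p1_trials()
  fb <- fit_bimodal(tr[tr$kind == "bimodal" & tr$blur == 1, ])
  expect_named(coef(fb), c("w_a", "w_v", "criterion", "sigma_av", "lapse"))
  expect_equal(unname(coef(fb)["w_a"] + coef(fb)["w_v"]), 1)
  expect_length(predict(fb), nrow(fb$cells))
  expect_equal(attr(logLik(fb), "df"), 4)
})
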