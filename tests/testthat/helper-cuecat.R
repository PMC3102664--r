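# Shared fixtures, built lazily and cached for the duration of the run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# Full canonical design: 178 conditions, 26 repetitions, 4 blur levels.
fx_full_design <- function() cached("full_design", build_design(seed = 5))

# Compact design for fast unit tests: 94 conditions, 20 repetitions.
fx_small_design <- function()
  cached("small_design",
         build_design(repetitions = 20, blur_levels = 2, seed = 11))

# One default reliability-weighting observer simulated over the full design.
fx_p1_trials <- function() cached("p1_trials", {
  simulate_cohort(observer_params("P1"), fx_full_design(), seed = 2)
})

# Small three-observer analysis used by the pipeline unit tests.
fx_small_analysis <- function() cached("small_analysis", {
  obs <- lapply(1:3, function(i) observer_params(paste0("P", i)))
  run_cue_analysis(observers = obs, design = fx_small_design(), seed = 21,
                   n_boot = 100)
})

# Six-observer reliability-weighting cohort analyzed on the full design;
# shared between the pipeline-recovery and prediction-agreement tests.
fx_cohort6_analysis <- function() cached("cohort6", {
  obs <- lapply(1:6, function(i) observer_params(paste0("P", i)))
  run_cue_analysis(observers = obs, design = fx_full_design(), seed = 42,
                   n_boot = 200)
})

# Binomial cells drawn from a known unimodal psychometric function.
fx_pf_cells <- function(mu = 5.5, sigma = 1.2, lapse = 0.04, reps = 26,
                        seed = 1) {
  set.seed(seed)
  x <- 1:10
  p <- lapse / 2 + (1 - lapse) * pnorm((x - mu) / sigma)
  data.frame(x = x, k = rbinom(10, reps, p), n = reps)
}

cells_to_trials <- function(cells, xname = "x") {
  out <- data.frame(
    x = rep(cells$x, cells$n),
    response = unlist(lapply(seq_len(nrow(cells)), function(i)
      c(rep(1L, cells$k[i]), rep(0L, cells$n[i] - cells$k[i])))))
  names(out)[1] <- xname
  out
}
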