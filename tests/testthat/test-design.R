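test_that("continua have ten ordered steps with phoneme endpoint labels", {
  for (m in c("auditory", "visual")) {
    cont <- build_continuum(m)
    expect_identical(cont$steps, 1:10)
    expect_true(all(diff(cont$steps) > 0))
    expect_identical(unname(cont$labels), c("/ba/", "/da/"))
  }
  expect_error(build_continuum("tactile"))
})

test_that("bimodal pair set has the canonical composition", {
  bp <- build_bimodal_pairs()
  expect_equal(nrow(bp), 32)
  expect_equal(sum(bp$conflict == 0), 10)
  expect_equal(sum(bp$conflict != 0), 22)
  expect_true(all(abs(bp$conflict) <= 3))
  # sign-balanced conflicts, concentrated on the informative central steps
  expect_equal(sum(bp$conflict > 0), 11)
  expect_equal(sum(bp$conflict < 0), 11)
  off <- bp[bp$conflict != 0, ]
  expect_true(all(off$a >= 3 & off$a <= 8 & off$v >= 3 & off$v <= 8))
  # each diagonal pair appears exactly once
  expect_equal(sort(bp$a[bp$conflict == 0]), 1:10)
  expect_false(any(duplicated(bp[c("a", "v")])))
})

test_that("conflict limit shapes or refuses the pair set", {
  expect_equal(nrow(build_bimodal_pairs(conflict_limit = 0)), 10)
  bp2 <- build_bimodal_pairs(conflict_limit = 2)
  expect_true(all(abs(bp2$conflict) <= 2))
  expect_equal(nrow(bp2), 32)
  # |a - v| <= 1 admits only 9 upper-triangle pairs, not the 11 needed
  expect_error(build_bimodal_pairs(conflict_limit = 1), "off-diagonal")
  expect_error(build_bimodal_pairs(conflict_limit = -1))
  expect_error(build_bimodal_pairs(n_conflicts = 21), "even")
  expect_error(
    build_bimodal_pairs(pairs = data.frame(a = c(1, 4), v = c(1, 5))),
    "off-diagonal")
  expect_error(
    build_bimodal_pairs(pairs = data.frame(a = 1, v = 9)),
    "conflict_limit")
})

test_that("design enumeration reproduces the trial accounting", {
  d <- fx_full_design()
  expect_equal(nrow(d$conditions), 178)
  expect_equal(nrow(d$schedule), 4628)
  expect_true(all(table(d$schedule$session) == 1157))
  # audio-only never blurred; bimodal pairs respect the conflict bound
  expect_true(all(d$conditions$blur[d$conditions$kind == "audio_only"] == 0))
  bi <- d$schedule[d$schedule$kind == "bimodal", ]
  expect_true(all(abs(bi$a_step - bi$v_step) <= 3))
  # condition count formula 10 + 10 B + 32 B
  for (B in c(1, 2)) {
    dB <- build_design(repetitions = 1, blur_levels = B, sessions = 1,
                       seed = 3)
    expect_equal(nrow(dB$conditions), 10 + 42 * B)
    expect_equal(nrow(dB$schedule), nrow(dB$conditions))
  }
})

test_that("every condition receives exactly its repetition count", {
  d <- fx_small_design()
  key <- with(d$schedule, paste(kind, blur, a_step, v_step))
  expect_true(all(table(key) == d$repetitions))
})

test_that("scheduling is deterministic in the seed and random otherwise", {
  d1 <- build_design(repetitions = 2, blur_levels = 2, seed = 9)
  d2 <- build_design(repetitions = 2, blur_levels = 2, seed = 9)
  d3 <- build_design(repetitions = 2, blur_levels = 2, seed = 10)
  expect_identical(d1$schedule, d2$schedule)
  expect_false(identical(d1$schedule, d3$schedule))
  # same trials as a multiset regardless of seed
  srt <- function(d) {
    s <- d$schedule[c("kind", "blur", "a_step", "v_step")]
    s <- s[do.call(order, s), ]
    rownames(s) <- NULL
    s
  }
  expect_equal(srt(d1), srt(d3))
})

test_that("block structure alternates and counterbalances across sessions", {
  d <- fx_small_design()
  first_block <- vapply(seq_len(d$sessions), function(s)
    d$schedule$block[d$schedule$session == s][1], "")
  expect_equal(first_block, c("unimodal", "bimodal", "unimodal", "bimodal"))
  expect_true(all(d$schedule$block[d$schedule$kind == "bimodal"] ==
                    "bimodal"))
})

test_that("uneven session division warns and still assigns all trials", {
  expect_warning(
    d <- build_design(repetitions = 1, blur_levels = 1, sessions = 3,
                      seed = 1),
    "divide evenly")
  expect_equal(nrow(d$schedule), 52)
  expect_true(max(table(d$schedule$session)) -
                min(table(d$schedule$session)) <= 1)
})

test_that("design JSON round trip reconstructs the identical design", {
  d <- fx_small_design()
  path <- tempfile(fileext = ".json")
  write_design(d, path)
  d2 <- read_design(path)
  expect_identical(d$conditions, d2$conditions)
  expect_identical(d$schedule, d2$schedule)
  csv <- tempfile(fileext = ".csv")
  write_schedule(d, csv)
  sched <- utils::read.csv(csv)
  expect_equal(nrow(sched), nrow(d$schedule))
  expect_equal(names(sched), names(d$schedule))
})
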