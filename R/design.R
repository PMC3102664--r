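#' Build a 10-step phoneme continuum
#'
#' Constructs the stimulus continuum for one modality: ten ordered steps
#' between the /ba/ endpoint (step 1) and the /da/ endpoint (step 10).
#' Step indices are dimensionless continuum units; all downstream variances,
#' PSEs and criteria are expressed on this scale. Optional physical anchors
#' (e.g. F2 onset frequency in Hz) are carried as labels only and play no
#' role in any computation.
#'
#' @param modality `"auditory"` or `"visual"`.
#' @param anchors optional named list of physical metadata labels.
#' @return An object of class `"continuum"`: a list with `modality`,
#'   integer `steps` 1..10, endpoint `labels`, and `anchors`.
#' @examples
#' build_continuum("auditory")
#' @export
build_continuum <- function(modality = c("auditory", "visual"),
                            anchors = NULL) {
  modality <- match.arg(modality)
  structure(
    list(modality = modality,
         steps = 1:10,
         labels = c(`1` = "/ba/", `10` = "/da/"),
         anchors = anchors),
    class = "continuum")
}

#' @export
print.continuum <- function(x, ...) {
  cat(sprintf("<continuum> %s, %d steps (%s = step 1 ... %s = step %d)\n",
              x$modality, length(x$steps), x$labels[["1"]],
              x$labels[["10"]], max(x$steps)))
  invisible(x)
}

# Deterministic conflict-pair generator: upper-triangle (v > a) candidates
# ordered by distance of the pair midpoint from the continuum center, then
# by conflict size, then by auditory step; mirrored to the lower triangle.
# Central pairs are preferred because the psychometric surface is steepest
# (most informative about the weights) near the category boundary.
.conflict_pairs_upper <- function(conflict_limit, n_upper) {
  cand <- expand.grid(a = 1:10, v = 1:10)
  cand <- cand[cand$v > cand$a & (cand$v - cand$a) <= conflict_limit, ]
  cand$center_dist <- abs((cand$a + cand$v) / 2 - 5.5)
  cand$offset <- cand$v - cand$a
  cand <- cand[order(cand$center_dist, cand$offset, cand$a), ]
  if (nrow(cand) < n_upper)
    stop("conflict_limit ", conflict_limit, " admits only ", 2 * nrow(cand),
         " off-diagonal pairs; ", 2 * n_upper, " requested", call. = FALSE)
  cand[seq_len(n_upper), c("a", "v")]
}

#' Enumerate the bimodal stimulus pairs
#'
#' Builds the set of (auditory step, visual step) pairs presented as
#' audio-visual stimuli: the 10 no-conflict diagonal pairs (a == v) plus
#' cue-conflict pairs whose auditory and visual continuum positions differ
#' by at most `conflict_limit` steps. Conflicts are kept small so that
#' observers remain unaware of the discrepancy and integrate rather than
#' segregate the cues. The default reproduces the canonical 32-pair set:
#' 10 no-conflict plus 22 conflicts, balanced in sign (11 with a > v, 11
#' with a < v) and concentrated on central steps 3..8 where psychometric
#' slopes are informative.
#'
#' @param conflict_limit maximum absolute step offset |a - v| permitted
#'   (default 3). `0` yields the diagonal only.
#' @param n_conflicts number of off-diagonal pairs (default 22; must be
#'   even so signs balance). Ignored when `conflict_limit = 0`.
#' @param pairs optional data frame with columns `a`, `v` overriding the
#'   generated conflict set (the diagonal is always included).
#' @return data frame with columns `a`, `v` (integer steps) and `conflict`
#'   (signed offset `a - v`).
#' @examples
#' p <- build_bimodal_pairs()
#' nrow(p)                 # 32
#' sum(p$conflict == 0)    # 10
#' @export
build_bimodal_pairs <- function(conflict_limit = 3, n_conflicts = 22,
                                pairs = NULL) {
  if (conflict_limit < 0) stop("conflict_limit must be >= 0", call. = FALSE)
  diag <- data.frame(a = 1:10, v = 1:10)
  if (is.null(pairs)) {
    if (conflict_limit == 0 || n_conflicts == 0) {
      off <- diag[0, ]
    } else {
      if (n_conflicts %% 2 != 0)
        stop("n_conflicts must be even (sign-balanced)", call. = FALSE)
      up <- .conflict_pairs_upper(conflict_limit, n_conflicts / 2)
      off <- rbind(up, data.frame(a = up$v, v = up$a))
    }
  } else {
    off <- pairs[, c("a", "v")]
    if (any(off$a == off$v))
      stop("override `pairs` must be off-diagonal", call. = FALSE)
    if (any(abs(off$a - off$v) > conflict_limit))
      stop("override `pairs` exceed conflict_limit", call. = FALSE)
  }
  out <- rbind(diag, off)
  out$conflict <- out$a - out$v
  rownames(out) <- NULL
  out
}

#' Build the full experimental design and randomized trial schedule
#'
#' Enumerates all stimulus conditions of the phoneme-labeling experiment —
#' 10 audio-only, 10 video-only per blur level, and the bimodal pairs per
#' blur level — and lays out a randomized trial schedule. With the default
#' 4 blur levels and the 32-pair bimodal set this gives
#' 10 + 40 + 128 = 178 conditions; at 26 repetitions, 4628 trials
#' (1157 per session over 4 sessions).
#'
#' Each session holds one unimodal and one bimodal block; block order is
#' counterbalanced across sessions (odd sessions unimodal-first). Within a
#' block, trial order is randomized by `seed`. Repetitions of each condition
#' are spread round-robin across sessions; a warning is issued when the
#' total trial count does not divide evenly across sessions. Audio-only
#' conditions are never blurred (blur fixed at 0); blur applies to the
#' visual stream, including the visual component of bimodal stimuli.
#'
#' @param repetitions trials per condition (default 26).
#' @param blur_levels number of visual blur levels (default 4, coded 0..3).
#' @param sessions number of sessions (default 4).
#' @param seed integer seed for schedule randomization.
#' @param conflict_limit,n_conflicts,pairs passed to [build_bimodal_pairs()].
#' @return An object of class `"experiment_design"`: list with `conditions`
#'   (data frame: kind, blur, a_step, v_step), `bimodal_pairs`, `schedule`
#'   (data frame: trial_index, session, block, kind, blur, a_step, v_step),
#'   `repetitions`, `sessions`, `seed`.
#' @examples
#' d <- build_design(repetitions = 1, blur_levels = 1, seed = 1)
#' nrow(d$schedule)  # 52
#' @export
build_design <- function(repetitions = 26, blur_levels = 4, sessions = 4,
                         seed = 1, conflict_limit = 3, n_conflicts = 22,
                         pairs = NULL) {
  stopifnot(repetitions >= 1, blur_levels >= 1, sessions >= 1)
  bp <- build_bimodal_pairs(conflict_limit, n_conflicts, pairs)
  blurs <- seq_len(blur_levels) - 1L

  conditions <- rbind(
    data.frame(kind = "audio_only", blur = 0L, a_step = 1:10,
               v_step = NA_integer_),
    do.call(rbind, lapply(blurs, function(b)
      data.frame(kind = "video_only", blur = b, a_step = NA_integer_,
                 v_step = 1:10))),
    do.call(rbind, lapply(blurs, function(b)
      data.frame(kind = "bimodal", blur = b, a_step = bp$a, v_step = bp$v)))
  )
  rownames(conditions) <- NULL
  n_trials <- nrow(conditions) * repetitions
  if (n_trials %% sessions != 0)
    warning("total trials (", n_trials, ") do not divide evenly across ",
            sessions, " sessions; assigning round-robin", call. = FALSE)

  # Round-robin session assignment: each condition contributes
  # floor(reps/sessions) trials to every session; leftover repetitions are
  # dealt one at a time from a global cyclic counter so session totals stay
  # balanced.
  base <- repetitions %/% sessions
  extra <- repetitions %% sessions
  cond_idx <- rep(seq_len(nrow(conditions)), each = repetitions)
  sess <- integer(n_trials)
  pos <- 1L
  counter <- 0L
  for (i in seq_len(nrow(conditions))) {
    s <- rep(seq_len(sessions), times = base)
    if (extra > 0L) {
      s <- c(s, ((counter + seq_len(extra) - 1L) %% sessions) + 1L)
      counter <- (counter + extra) %% sessions
    }
    sess[pos:(pos + repetitions - 1L)] <- s
    pos <- pos + repetitions
  }

  sched <- conditions[cond_idx, ]
  sched$session <- sess
  sched$block <- ifelse(sched$kind == "bimodal", "bimodal", "unimodal")

  # Randomize order within (session, block); counterbalance block order.
  set.seed(seed)
  out <- vector("list", sessions * 2L)
  k <- 0L
  for (s in seq_len(sessions)) {
    order_blocks <- if (s %% 2 == 1) c("unimodal", "bimodal")
                    else c("bimodal", "unimodal")
    for (b in order_blocks) {
      k <- k + 1L
      rows <- sched[sched$session == s & sched$block == b, ]
      out[[k]] <- rows[sample.int(nrow(rows)), ]
    }
  }
  schedule <- do.call(rbind, out)
  schedule$trial_index <- seq_len(nrow(schedule))
  rownames(schedule) <- NULL
  schedule <- schedule[, c("trial_index", "session", "block", "kind",
                           "blur", "a_step", "v_step")]

  structure(
    list(conditions = conditions, bimodal_pairs = bp, schedule = schedule,
         repetitions = repetitions, blur_levels = blur_levels,
         sessions = sessions, seed = seed),
    class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(paste0(
    "<experiment_design> %d conditions x %d repetitions = %d trials\n",
    "  %d session(s), %d blur level(s), %d bimodal pairs (%d no-conflict)\n"),
    nrow(x$conditions), x$repetitions, nrow(x$schedule), x$sessions,
    x$blur_levels, nrow(x$bimodal_pairs),
    sum(x$bimodal_pairs$conflict == 0)))
  invisible(x)
}

#' Write / read an experimental design as JSON
#'
#' Serializes the design parameters and bimodal pair set (not the trial
#' schedule, which is reconstructed deterministically from the seed).
#'
#' @param design an `experiment_design`.
#' @param path file path.
#' @return `read_design()` returns the reconstructed `experiment_design`.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "experiment_design"))
  obj <- list(repetitions = design$repetitions,
              blur_levels = design$blur_levels,
              sessions = design$sessions,
              seed = design$seed,
              bimodal_pairs = design$bimodal_pairs[, c("a", "v")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  bp <- as.data.frame(obj$bimodal_pairs)
  off <- bp[bp$a != bp$v, ]
  build_design(repetitions = obj$repetitions, blur_levels = obj$blur_levels,
               sessions = obj$sessions, seed = obj$seed,
               conflict_limit = max(abs(off$a - off$v), 0),
               pairs = if (nrow(off)) off else NULL)
}

#' Write the trial schedule as CSV
#'
#' @param design an `experiment_design`.
#' @param path file path.
#' @export
write_schedule <- function(design, path) {
  stopifnot(inherits(design, "experiment_design"))
  utils::write.csv(design$schedule, path, row.names = FALSE)
  invisible(path)
}
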