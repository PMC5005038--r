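# Counterbalanced trial design: 4 blocks x 24 trials from the 48 retained
# combinations, with per-block direction/start balance, catch trials and
# onsets.

#' Trial timing parameters
#'
#' @param cue_s Duration of the building-name cue (s).
#' @param imagination_s Duration of the eyes-closed imagination period (s).
#' @param iti_s Set of inter-trial intervals sampled uniformly (s).
#' @param n_catch_per_block Number of snapshot catch trials per block.
#' @return A list of timing parameters.
#' @export
design_timing <- function(cue_s = 2, imagination_s = 10,
                          iti_s = c(1.8, 3.6, 5.4), n_catch_per_block = 3L) {
  stopifnot_scalar_number(cue_s, "cue_s", 0)
  stopifnot_scalar_number(imagination_s, "imagination_s", 0)
  if (any(iti_s <= 0)) abort("`iti_s` values must be positive.")
  list(cue_s = cue_s, imagination_s = imagination_s, iti_s = iti_s,
       n_catch_per_block = as.integer(n_catch_per_block))
}

# Split the 48 combinations into two 24-trial blocks so that each block holds
# every direction twice and every start four times. Greedy weighted sampling
# over directions with retry on dead ends.
split_half_balanced <- function(combos, max_tries = 10000L) {
  starts <- combos$start_id
  start_levels <- sort(unique(starts))
  dir_groups <- split(seq_len(nrow(combos)), combos$direction_deg)
  per_start <- length(starts) / length(start_levels) / 2
  for (tries in seq_len(max_tries)) {
    rem <- stats::setNames(rep(per_start, length(start_levels)), start_levels)
    sel <- integer(0)
    ok <- TRUE
    for (g in sample(dir_groups)) {
      cand <- g[rem[as.character(starts[g])] > 0]
      if (length(cand) < 2L) { ok <- FALSE; break }
      w <- rem[as.character(starts[cand])]
      pick <- if (length(cand) == 2L) cand else sample(cand, 2L, prob = w)
      sel <- c(sel, pick)
      rem[as.character(starts[pick])] <- rem[as.character(starts[pick])] - 1
    }
    if (ok && all(rem == 0)) return(sel)
  }
  abort(paste0(
    "solver error: could not split combinations into balanced blocks after ",
    max_tries, " tries; check that each direction appears 4x and each start 8x."
  ))
}

#' Generate a counterbalanced 96-trial design
#'
#' Draws the four 24-trial blocks from the 48 retained building combinations.
#' The 48 combinations fill blocks 1-2 once each and blocks 3-4 once each, so
#' every combination occurs exactly twice over the experiment; within every
#' block each direction is sampled exactly twice and each start building
#' serves four times. Trial order is randomized within block. Three catch
#' trials per block (never the first trial) present a snapshot probe, correct
#' in half of all catch trials; catch trials carry normal direction labels.
#' Onsets accumulate per block from cue + imagination + a random ITI.
#'
#' @param combinations48 The 48-row tibble from [apply_exclusions()].
#' @param timing Timing parameters from [design_timing()].
#' @param seed Optional integer seed.
#' @return A 96-row trial tibble: `trial_id`, `block`, `within_block_index`,
#'   `start_id`, `target_id`, `direction_deg`, `distance`, `target_ring`,
#'   `is_catch`, `catch_view_correct`, `cue_onset_s`, `imagination_end_s`.
#' @export
generate_design <- function(combinations48, timing = design_timing(), seed = NULL) {
  if (nrow(combinations48) != 48L ||
      !all(table(combinations48$direction_deg) == 4L) ||
      !all(table(combinations48$start_id) == 8L)) {
    abort("solver error: need 48 combinations with each direction 4x and each start 8x.")
  }
  with_seed(seed, {
    blocks <- vector("list", 4L)
    for (pair in c(0L, 2L)) {
      selA <- split_half_balanced(combinations48)
      blocks[[pair + 1L]] <- combinations48[selA, ]
      blocks[[pair + 2L]] <- combinations48[-selA, ]
    }
    n_catch <- 4L * timing$n_catch_per_block
    correct_flags <- sample(rep(c(TRUE, FALSE), length.out = n_catch))
    trials <- purrr::map2(blocks, seq_along(blocks), function(bk, b) {
      bk <- bk[sample(nrow(bk)), ]
      nb <- nrow(bk)
      catch_idx <- sample(2:nb, timing$n_catch_per_block)
      iti <- sample(timing$iti_s, nb, replace = TRUE)
      trial_len <- timing$cue_s + timing$imagination_s
      cue_onset <- cumsum(c(0, head(trial_len + iti, -1)))
      mutate(bk,
        block = b,
        within_block_index = seq_len(nb),
        is_catch = .data$within_block_index %in% catch_idx,
        cue_onset_s = cue_onset,
        imagination_end_s = cue_onset + trial_len
      )
    })
    trials <- bind_rows(trials)
    trials$catch_view_correct <- NA
    trials$catch_view_correct[trials$is_catch] <- correct_flags
    trials <- mutate(trials, trial_id = dplyr::row_number())
    attr(trials, "excluded") <- NULL
    select(trials, "trial_id", "block", "within_block_index", "start_id",
           "target_id", "direction_deg", "distance", "target_ring",
           "is_catch", "catch_view_correct", "cue_onset_s", "imagination_end_s")
  })
}

#' Validate a trial design against the counterbalancing constraints
#'
#' Checks the 96-trial structure: 4 blocks of 24 trials, each direction twice
#' and each start four times per block, each building combination exactly
#' twice overall, the per-block catch-trial count, and that inner-ring targets
#' occur only on 30-mod-60 directions.
#'
#' @param trials A trial tibble from [generate_design()] or read from disk.
#' @return Invisibly `TRUE`; otherwise an error describing the first violated
#'   constraint.
#' @export
validate_design <- function(trials) {
  check <- function(cond, msg) if (!cond) abort(paste0("invalid design: ", msg))
  check(nrow(trials) == 96L, "expected 96 trials.")
  check(all(table(trials$block) == 24L), "expected 4 blocks of 24 trials.")
  bydir <- table(trials$block, trials$direction_deg)
  check(all(bydir == 2L), "each direction must occur twice per block.")
  bystart <- table(trials$block, trials$start_id)
  check(all(bystart == 4L), "each start must occur four times per block.")
  combo <- paste(trials$start_id, trials$target_id)
  check(all(table(combo) == 2L), "each combination must occur exactly twice.")
  check(all(table(trials$block, trials$is_catch)[, "TRUE"] == 3L),
        "expected 3 catch trials per block.")
  inner <- trials$target_ring == "inner"
  check(all(trials$direction_deg[inner] %% 60 == 30),
        "inner-ring targets must lie on 30-mod-60 directions.")
  invisible(TRUE)
}
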