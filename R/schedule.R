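#' Task design constants
#'
#' The probabilistic Pavlovian task presents two auditory cues for 10 s each,
#' 56 presentations per session (28 per cue), with reward delivered
#' immediately at cue offset on exactly 75% of CS_High and 25% of CS_Low
#' trials and inter-trial intervals drawn uniformly from 30-60 s
#' (mean 45 s).
#'
#' @name task_design
#' @keywords internal
NULL

TRIALS_PER_SESSION <- 56L
TRIALS_PER_CUE <- 28L
REWARDS_HIGH <- 21L # 0.75 * 28, exact per session
REWARDS_LOW <- 7L # 0.25 * 28
CUE_DURATION_S <- 10
ITI_RANGE_S <- c(30, 60)

CUES <- c("CS_High", "CS_Low")
COUNTERBALANCES <- c("CL1_T2", "T1_CL2")
REGIMES <- c("training", "pre_drug", "vehicle", "amphetamine")

#' Map cues to sounds for a counterbalance group
#'
#' In group `CL1_T2` the clicker is the CS_High and the tone the CS_Low; in
#' group `T1_CL2` the assignment is reversed.
#'
#' @param cue character vector of `"CS_High"` / `"CS_Low"`.
#' @param counterbalance `"CL1_T2"` or `"T1_CL2"`.
#' @return character vector of `"clicker"` / `"tone"`.
#' @export
cue_sound <- function(cue, counterbalance) {
  counterbalance <- match_enum(counterbalance, COUNTERBALANCES, "counterbalance")
  if (counterbalance == "CL1_T2") {
    ifelse(cue == "CS_High", "clicker", "tone")
  } else {
    ifelse(cue == "CS_High", "tone", "clicker")
  }
}

match_enum <- function(x, choices, what) {
  if (length(x) != 1 || !is.character(x) || !x %in% choices) {
    abort(
      sprintf(
        "`%s` must be one of %s, not %s", what,
        paste0('"', choices, '"', collapse = ", "),
        paste0(deparse(x), collapse = "")
      ),
      class = "pavlovo2_invalid_enum"
    )
  }
  x
}

#' Generate one session schedule
#'
#' Draws a seeded random interleaving of the two cues (28 presentations
#' each), assigns rewards under the exact-proportion policy (exactly 21 of
#' 28 CS_High and 7 of 28 CS_Low trials rewarded, in seeded random
#' positions), and lays the trials out on a session clock with uniform
#' 30-60 s inter-trial intervals. The outcome (reward or omission) occurs at
#' cue offset, 10 s after cue onset.
#'
#' @param session_index integer 1-10.
#' @param counterbalance `"CL1_T2"` (clicker = CS_High) or `"T1_CL2"`.
#' @param regime one of `"training"`, `"pre_drug"`, `"vehicle"`,
#'   `"amphetamine"`. The regime does not change the schedule itself; it is
#'   carried so downstream behavioural and neural simulation know whether
#'   drug effects apply.
#' @param seed integer seed; identical seeds give identical schedules.
#' @return a tibble with one row per trial and columns `trial`, `cue`,
#'   `sound`, `rewarded`, `iti_s`, `cue_onset_s`, `outcome_onset_s`, plus
#'   attributes `session_index`, `counterbalance`, `regime`.
#' @export
#' @examples
#' sched <- generate_schedule(1, "CL1_T2", "training", seed = 7)
#' table(sched$cue, sched$rewarded)
generate_schedule <- function(session_index, counterbalance, regime, seed) {
  stopifnot(is.numeric(session_index), length(session_index) == 1)
  counterbalance <- match_enum(counterbalance, COUNTERBALANCES, "counterbalance")
  regime <- match_enum(regime, REGIMES, "regime")
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    abort("`seed` must be a single integer", class = "pavlovo2_invalid_seed")
  }

  with_seed(as.integer(seed), {
    cue <- sample(rep(CUES, each = TRIALS_PER_CUE))
    rewarded <- logical(TRIALS_PER_SESSION)
    rewarded[sample(which(cue == "CS_High"), REWARDS_HIGH)] <- TRUE
    rewarded[sample(which(cue == "CS_Low"), REWARDS_LOW)] <- TRUE
    iti <- runif(TRIALS_PER_SESSION, ITI_RANGE_S[1], ITI_RANGE_S[2])
  })

  # session clock: each trial is ITI then 10 s of cue, outcome at cue offset
  cue_onset <- cumsum(iti + CUE_DURATION_S) - CUE_DURATION_S
  out <- tibble::tibble(
    trial = seq_len(TRIALS_PER_SESSION),
    cue = cue,
    sound = cue_sound(cue, counterbalance),
    rewarded = rewarded,
    iti_s = iti,
    cue_onset_s = cue_onset,
    outcome_onset_s = cue_onset + CUE_DURATION_S
  )
  attr(out, "session_index") <- as.integer(session_index)
  attr(out, "counterbalance") <- counterbalance
  attr(out, "regime") <- regime
  out
}

schedule_regime <- function(schedule) attr(schedule, "regime") %||% "training"
schedule_session <- function(schedule) attr(schedule, "session_index") %||% NA_integer_

#' Regimes for the standard 10-session experiment
#'
#' Sessions 1-8 are training, session 9 is the pre-drug reference day (the
#' final training day), and session 10 is the drug challenge under the
#' animal's assigned drug group.
#'
#' @param drug_group `"vehicle"` or `"amphetamine"` for session 10.
#' @return character vector of length 10.
#' @export
session_regimes <- function(drug_group = c("vehicle", "amphetamine")) {
  drug_group <- match.arg(drug_group)
  c(rep("training", 8), "pre_drug", drug_group)
}
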