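# AGF scoring: mean absolute tracking error between the target line and
# the measured grip force, computed separately over the random half
# (samples n1+1..n1+n) and the repeat half (n1+n+1..n1+2n). The 30
# preparation samples never enter any score.

trial_measured <- function(trial) {
  if (is.list(trial) && !is.null(trial$measured)) trial$measured else trial
}

check_trial_spec <- function(measured, spec, trial = NULL) {
  stopifnot(inherits(spec, "task_spec"))
  if (length(measured) != length(spec$samples)) {
    stop("measured trace has ", length(measured), " samples, task has ",
         length(spec$samples))
  }
  if (is.list(trial) && !is.null(trial$task_id) &&
      trial$task_id != spec$task_id) {
    stop("trial was recorded on task ", trial$task_id,
         " but scored against task ", spec$task_id)
  }
  invisible(measured)
}

#' AGF tracking-error score for the random half of a trial
#'
#' Mean absolute difference between target and measured force over the
#' 100 random-half samples, in kg. Lower is better.
#'
#' @param trial Numeric length-230 measured force trace (kg), or a
#'   `trial_record` list with fields `measured` and `task_id`.
#' @param spec The `task_spec` the trial tracked.
#' @return AGF score in kg.
#' @export
agf_random <- function(trial, spec) {
  measured <- trial_measured(trial)
  check_trial_spec(measured, spec, trial)
  idx <- (spec$n1 + 1L):(spec$n1 + spec$n)
  mean(abs(spec$samples[idx] - measured[idx]))
}

#' AGF tracking-error score for the repeat half of a trial
#'
#' As [agf_random()], over the 100 repeat-half samples.
#'
#' @inheritParams agf_random
#' @export
agf_repeat <- function(trial, spec) {
  measured <- trial_measured(trial)
  check_trial_spec(measured, spec, trial)
  idx <- (spec$n1 + spec$n + 1L):(spec$n1 + 2L * spec$n)
  mean(abs(spec$samples[idx] - measured[idx]))
}

#' Block means of trial AGF scores
#'
#' Averages the two AGF components over each block of five consecutive
#' trials. All 50 trials must be present, in trial order; partial
#' blocks are refused rather than imputed.
#'
#' @param scores data.frame with columns `trial_index`, `agf_ran`,
#'   `agf_rep` (one row per trial, 50 rows).
#' @return data.frame with `block_index` (1..10), `mean_agf_ran`,
#'   `mean_agf_rep` (kg).
#' @export
block_means <- function(scores) {
  stopifnot(is.data.frame(scores),
            all(c("trial_index", "agf_ran", "agf_rep") %in% names(scores)))
  if (nrow(scores) != 50L || !setequal(scores$trial_index, 1:50)) {
    stop("block_means() needs exactly the 50 trial scores (got ",
         nrow(scores), " rows)")
  }
  scores <- scores[order(scores$trial_index), ]
  block <- rep(1:10, each = 5L)
  data.frame(
    block_index = 1:10,
    mean_agf_ran = as.numeric(tapply(scores$agf_ran, block, mean)),
    mean_agf_rep = as.numeric(tapply(scores$agf_rep, block, mean))
  )
}

#' Motor learning rates from block-wise mean AGF
#'
#' `LR = (mean_block1 - mean_block10) / mean_block10 * 100` (percent),
#' computed separately for the random and repeat halves. Positive
#' values indicate improvement (error reduction); negative values are
#' admissible and indicate worsening. A zero block-10 mean (perfect
#' tracking) leaves the rate undefined and is an error, not a clamped
#' value.
#'
#' @param blocks data.frame from [block_means()] (10 rows).
#' @return List with `lr_ran` and `lr_rep` (percent).
#' @export
learning_rates <- function(blocks) {
  stopifnot(is.data.frame(blocks), nrow(blocks) == 10L,
            all(c("block_index", "mean_agf_ran", "mean_agf_rep") %in%
                  names(blocks)))
  blocks <- blocks[order(blocks$block_index), ]
  b1 <- blocks[1, ]; b10 <- blocks[10, ]
  if (b10$mean_agf_ran <= 0 || b10$mean_agf_rep <= 0) {
    stop("block-10 mean AGF is zero: learning rate undefined ",
         "(degenerate perfect tracking)")
  }
  list(
    lr_ran = (b1$mean_agf_ran - b10$mean_agf_ran) / b10$mean_agf_ran * 100,
    lr_rep = (b1$mean_agf_rep - b10$mean_agf_rep) / b10$mean_agf_rep * 100
  )
}

#' Score a participant's full 50-trial session
#'
#' Computes both AGF components per trial, the ten block means, and the
#' two learning rates.
#'
#' @param participant A `participant_trials` object from
#'   [simulate_participant()], or a list with `measured` (230 x 50
#'   matrix, kg) and `schedule` (data.frame with `trial_index`,
#'   `block_index`, `task_id`).
#' @param specs List of five `task_spec`s indexed by task id.
#' @return List with `trial_scores` (50-row data.frame), `block_scores`
#'   (10-row data.frame), `lr` (list `lr_ran`, `lr_rep`).
#' @export
score_participant <- function(participant, specs) {
  stopifnot(is.list(participant), !is.null(participant$measured),
            !is.null(participant$schedule), length(specs) == 5L)
  m <- participant$measured
  sch <- participant$schedule
  if (!is.matrix(m) || nrow(m) != 230L || ncol(m) != 50L) {
    stop("participant$measured must be a 230 x 50 matrix of forces")
  }
  if (nrow(sch) != 50L || !setequal(sch$trial_index, 1:50)) {
    stop("participant schedule must cover trials 1..50")
  }
  sch <- sch[order(sch$trial_index), ]
  scores <- data.frame(
    trial_index = sch$trial_index,
    block_index = sch$block_index,
    task_id = sch$task_id,
    agf_ran = vapply(1:50, function(t) {
      agf_random(m[, t], specs[[sch$task_id[t]]])
    }, numeric(1)),
    agf_rep = vapply(1:50, function(t) {
      agf_repeat(m[, t], specs[[sch$task_id[t]]])
    }, numeric(1))
  )
  blocks <- block_means(scores)
  list(trial_scores = scores, block_scores = blocks,
       lr = learning_rates(blocks))
}

#' Score every participant of a simulated or recorded cohort
#'
#' @param cohort A `cohort` object ([simulate_cohort()]) or plain list
#'   of participants accepted by [score_participant()].
#' @param specs List of five `task_spec`s.
#' @return List with `lr` (one row per participant: `participant_id`,
#'   `group`, `lr_ran`, `lr_rep`), `block_scores` (long data.frame with
#'   participant and group columns), `trial_scores` (long data.frame).
#' @export
score_cohort <- function(cohort, specs) {
  stopifnot(length(cohort) >= 1L)
  per <- lapply(cohort, function(p) {
    sc <- score_participant(p, specs)
    id <- p$participant_id %||% NA_character_
    grp <- p$group %||% NA_character_
    sc$trial_scores <- cbind(participant_id = id, group = grp,
                             sc$trial_scores)
    sc$block_scores <- cbind(participant_id = id, group = grp,
                             sc$block_scores)
    sc$lr_row <- data.frame(participant_id = id, group = grp,
                            lr_ran = sc$lr$lr_ran, lr_rep = sc$lr$lr_rep,
                            stringsAsFactors = FALSE)
    sc
  })
  list(
    lr = do.call(rbind, lapply(per, `[[`, "lr_row")),
    block_scores = do.call(rbind, lapply(per, `[[`, "block_scores")),
    trial_scores = do.call(rbind, lapply(per, `[[`, "trial_scores"))
  )
}
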