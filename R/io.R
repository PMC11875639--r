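# File dialects. All CSV is UTF-8, comma-separated, '.' decimal, with a
# mandatory header row. Forces are exported at 4 decimals (kg) and
# learning rates at 1 decimal (%); coefficient tables keep full double
# precision so a written run can be re-loaded bit-exactly.

fmt_full <- function(x) sprintf("%.17g", x)

read_csv_checked <- function(path, required, numeric_cols = required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  for (col in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      stop("file ", path, ", column '", col, "': non-numeric value at row ",
           bad[1], " ('", df[[col]][bad[1]], "')")
    }
    df[[col]] <- v
  }
  df
}

#' Write a solved coefficient table
#'
#' One row per target line (five random, one repeat): role, task id,
#' b0, a1..a6, b1..b6, scale factor; a comment header records the
#' solver seed and slope tolerance. Full double precision.
#'
#' @param lines `task_lines` from [solve_coefficients()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_coefficients <- function(lines, path) {
  stopifnot(inherits(lines, "task_lines"))
  all_lines <- c(lines$random, list(lines$repeat_line))
  rows <- lapply(all_lines, function(cf) {
    data.frame(role = cf$role, task_id = cf$task_id,
               b0 = fmt_full(cf$b0),
               t(stats::setNames(fmt_full(cf$a), paste0("a", 1:6))),
               t(stats::setNames(fmt_full(cf$b), paste0("b", 1:6))),
               scale_factor = fmt_full(cf$scale),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# solver_seed=%d slope_tol=%s",
                     attr(lines, "seed") %||% NA_integer_,
                     format(attr(lines, "slope_tol") %||% NA_real_)), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a coefficient table written by [write_coefficients()]
#'
#' @param path CSV path.
#' @return `task_lines` object.
#' @export
read_coefficients <- function(path) {
  num <- c("b0", paste0("a", 1:6), paste0("b", 1:6), "scale_factor")
  df <- read_csv_checked(path, c("role", "task_id", num), num)
  if (sum(df$role == "repeat") != 1L || sum(df$role == "random") != 5L) {
    stop("coefficient table must hold 5 random lines and 1 repeat line")
  }
  mk <- function(row) {
    target_coefs(row$role, row$b0,
                 as.numeric(row[paste0("a", 1:6)]),
                 as.numeric(row[paste0("b", 1:6)]),
                 task_id = if (row$role == "random") row$task_id else
                   NA_integer_,
                 scale = row$scale_factor)
  }
  ran <- df[df$role == "random", ]
  ran <- ran[order(ran$task_id), ]
  hdr <- readLines(path, n = 1L)
  seed <- suppressWarnings(
    as.integer(sub(".*solver_seed=([0-9]+).*", "\\1", hdr))
  )
  structure(
    list(random = lapply(seq_len(5), function(i) mk(ran[i, ])),
         repeat_line = mk(df[df$role == "repeat", ][1, ])),
    class = "task_lines", seed = seed,
    slope_tol = suppressWarnings(
      as.numeric(sub(".*slope_tol=([0-9.eE+-]+).*", "\\1", hdr))
    )
  )
}

#' Export composed task trajectories
#'
#' Long CSV: `task_id`, `k` (1-based sample index), `t_seconds`
#' (`(k-1) * delta_t`), `force_kg` (4 decimals).
#'
#' @param specs List of `task_spec`s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_task_specs <- function(specs, path) {
  rows <- lapply(specs, function(sp) {
    k <- seq_along(sp$samples)
    data.frame(task_id = sp$task_id, k = k,
               t_seconds = round((k - 1) * sp$delta_t, 4),
               force_kg = round(sp$samples, 4))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read an exported task-trajectory table
#'
#' @param path CSV path.
#' @return data.frame with `task_id`, `k`, `t_seconds`, `force_kg`.
#' @export
read_task_specs <- function(path) {
  df <- read_csv_checked(path, c("task_id", "k", "t_seconds", "force_kg"))
  if (any(df$force_kg < 0 | df$force_kg > 0.5)) {
    stop("task table holds forces outside the device range [0, 0.5] kg")
  }
  df
}

#' Flatten a simulated cohort to the long trial CSV dialect
#'
#' @param cohort `cohort` from [simulate_cohort()].
#' @return data.frame: `participant_id`, `group`, `trial_index`,
#'   `block_index`, `task_id`, `k`, `force_kg`.
#' @export
cohort_to_trials_df <- function(cohort) {
  do.call(rbind, lapply(cohort, function(p) {
    sch <- p$schedule
    data.frame(
      participant_id = p$participant_id, group = p$group,
      trial_index = rep(sch$trial_index, each = 230L),
      block_index = rep(sch$block_index, each = 230L),
      task_id = rep(sch$task_id, each = 230L),
      k = rep(1:230, times = 50L),
      force_kg = round(as.vector(p$measured), 4),
      stringsAsFactors = FALSE
    )
  }))
}

#' Write trial traces in the long CSV dialect
#'
#' @param x `cohort` or a data.frame already in the dialect of
#'   [cohort_to_trials_df()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(x, path) {
  df <- if (inherits(x, "cohort")) cohort_to_trials_df(x) else x
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read trial traces and rebuild per-participant records
#'
#' Validates the schema (numeric columns, 230 samples per trial, 50
#' trials per participant, forces within the device range) and reports
#' the first offending row on failure.
#'
#' @param path CSV path.
#' @return List of participant records accepted by
#'   [score_participant()].
#' @export
read_trials <- function(path) {
  num <- c("trial_index", "block_index", "task_id", "k", "force_kg")
  df <- read_csv_checked(path, c("participant_id", "group", num), num)
  bad <- which(df$force_kg < 0 | df$force_kg > 0.5)
  if (length(bad)) {
    stop("file ", path, ": force outside device range at row ", bad[1])
  }
  split_df <- split(df, df$participant_id)
  lapply(split_df, function(pd) {
    pd <- pd[order(pd$trial_index, pd$k), ]
    if (nrow(pd) != 50L * 230L) {
      stop("participant ", pd$participant_id[1], " has ", nrow(pd),
           " samples; expected 50 trials x 230 samples")
    }
    sch <- unique(pd[, c("trial_index", "block_index", "task_id")])
    list(participant_id = pd$participant_id[1], group = pd$group[1],
         schedule = sch,
         measured = matrix(pd$force_kg, nrow = 230L, ncol = 50L))
  })
}

#' Write participant learning rates (1-decimal percent)
#'
#' @param lr data.frame with `participant_id`, `group`, `lr_ran`,
#'   `lr_rep` (the `lr` element of [score_cohort()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_learning_rates <- function(lr, path) {
  out <- lr
  out$lr_ran <- round(out$lr_ran, 1)
  out$lr_rep <- round(out$lr_rep, 1)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a learning-rate table
#'
#' @param path CSV path.
#' @return data.frame with `participant_id`, `group`, `lr_ran`,
#'   `lr_rep`.
#' @export
read_learning_rates <- function(path) {
  read_csv_checked(path, c("participant_id", "group", "lr_ran", "lr_rep"),
                   c("lr_ran", "lr_rep"))
}

#' Write per-trial and per-block AGF scores (4-decimal kg)
#'
#' @param scores data.frame of scores (trial or block level).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  out <- scores
  for (col in intersect(c("agf_ran", "agf_rep", "mean_agf_ran",
                          "mean_agf_rep"), names(out))) {
    out[[col]] <- round(out[[col]], 4)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the analysis report as JSON
#'
#' @param report List from [run_full_analysis()] (or any
#'   JSON-serializable structure).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null")
  invisible(path)
}
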