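# Group-comparison statistics on scored cohorts: Shapiro-Wilk
# screening, mixed repeated-measures ANOVA on block-wise mean AGF
# (within: block, task; between: group) with Mauchly's sphericity test
# and the Greenhouse-Geisser correction, and rank tests on the
# learning rates with bootstrap percentile intervals.

#' Shapiro-Wilk normality screen
#'
#' Report-only: downstream test selection is configuration-driven, not
#' branched on these p-values.
#'
#' @param x Numeric vector, or data.frame / named list of numeric
#'   variables.
#' @return data.frame with `variable`, `n`, `statistic` (W),
#'   `p_value`.
#' @export
normality_check <- function(x) {
  if (is.numeric(x)) x <- list(value = x)
  stopifnot(is.list(x), length(x) >= 1)
  rows <- lapply(names(x), function(nm) {
    v <- x[[nm]]
    v <- v[!is.na(v)]
    if (length(v) < 3) {
      stop("normality_check() needs n >= 3 for '", nm, "' (got ",
           length(v), ")")
    }
    if (stats::sd(v) == 0) {
      stop("variable '", nm, "' is constant: normality test degenerate")
    }
    sw <- stats::shapiro.test(v)
    data.frame(variable = nm, n = length(v),
               statistic = unname(sw$statistic),
               p_value = sw$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assemble the repeated-measures design table
#'
#' One row per participant x block x task half, with the block-mean AGF
#' as response: the complete balanced within-subject design (20 rows
#' per participant).
#'
#' @param block_scores Long data.frame with `participant_id`, `group`,
#'   `block_index`, `mean_agf_ran`, `mean_agf_rep` (e.g. the
#'   `block_scores` element of [score_cohort()], rbind-ed over groups).
#' @return data.frame with `participant_id`, `group`, `block`
#'   (factor 1..10), `task` (factor ran/rep), `agf` (kg).
#' @export
build_anova_table <- function(block_scores) {
  need <- c("participant_id", "group", "block_index",
            "mean_agf_ran", "mean_agf_rep")
  miss <- setdiff(need, names(block_scores))
  if (length(miss)) {
    stop("block_scores missing column(s): ", paste(miss, collapse = ", "))
  }
  long <- rbind(
    data.frame(participant_id = block_scores$participant_id,
               group = block_scores$group,
               block = block_scores$block_index, task = "ran",
               agf = block_scores$mean_agf_ran, stringsAsFactors = FALSE),
    data.frame(participant_id = block_scores$participant_id,
               group = block_scores$group,
               block = block_scores$block_index, task = "rep",
               agf = block_scores$mean_agf_rep, stringsAsFactors = FALSE)
  )
  long$block <- factor(long$block, levels = 1:10)
  long$task <- factor(long$task, levels = c("ran", "rep"))
  counts <- table(long$participant_id)
  if (any(counts != 20L)) {
    stop("design is unbalanced: every participant needs 10 blocks x 2 tasks")
  }
  long[order(long$participant_id, long$task, long$block), ]
}

#' Mixed repeated-measures ANOVA with sphericity handling
#'
#' Within-subject factors block (10) and task half (2), between-subject
#' factor group; type-III tests via a multivariate linear model.
#' Mauchly's sphericity test and the Greenhouse-Geisser correction are
#' reported for every within-subject effect with more than one degree
#' of freedom; the corrected p-value is the headline value
#' (single-degree-of-freedom effects are sphericity-exempt, epsilon 1).
#' The correction rescales both degrees of freedom by the epsilon
#' estimate, which is conservative (larger p) whenever F exceeds 1;
#' for F below 1 the corrected p can fall under the uncorrected one, a
#' known property of the standard correction.
#'
#' @param tbl Design table from [build_anova_table()]. Missing or
#'   duplicated cells are refused, not imputed.
#' @return `effect_report` data.frame: one row per effect with `df`,
#'   `df_error`, `statistic` (F), `p_uncorrected`, `mauchly_W`,
#'   `mauchly_p`, `gg_epsilon`, `p_gg`.
#' @export
rm_anova <- function(tbl) {
  need <- c("participant_id", "group", "block", "task", "agf")
  stopifnot(all(need %in% names(tbl)))
  ids <- unique(tbl$participant_id)
  cell <- table(tbl$participant_id, tbl$block, tbl$task)
  if (any(cell != 1L)) {
    stop("design is not complete and balanced: each participant needs ",
         "exactly one value per block x task cell")
  }

  # wide response matrix, columns ordered task-major then block
  idata <- expand.grid(block = factor(1:10), task = factor(c("ran", "rep")),
                       KEEP.OUT.ATTRS = FALSE)
  idata <- idata[, c("task", "block")]
  y <- matrix(NA_real_, nrow = length(ids), ncol = 20L,
              dimnames = list(ids, paste0("t", idata$task, "_b", idata$block)))
  for (j in seq_len(20L)) {
    sub <- tbl[tbl$task == idata$task[j] & tbl$block == idata$block[j], ]
    y[as.character(sub$participant_id), j] <- sub$agf
  }
  group <- factor(vapply(ids, function(id) {
    as.character(tbl$group[tbl$participant_id == id][1])
  }, character(1)))

  effects_within <- c("block", "task", "block:task")
  if (stats::var(as.vector(y)) == 0) {
    # degenerate flat data: nothing to test
    eff <- c(if (nlevels(group) > 1) "group", effects_within,
             if (nlevels(group) > 1)
               paste("group", effects_within, sep = ":"))
    out <- data.frame(effect = eff, df = NA_real_, df_error = NA_real_,
                      statistic = 0, p_uncorrected = 1, mauchly_W = NA_real_,
                      mauchly_p = NA_real_, gg_epsilon = 1, p_gg = 1,
                      stringsAsFactors = FALSE)
    class(out) <- c("effect_report", "data.frame")
    return(out)
  }

  dat <- data.frame(group = group)
  mod <- if (nlevels(group) > 1) {
    stats::lm(y ~ group, data = dat)
  } else {
    stats::lm(y ~ 1)
  }
  av <- car::Anova(mod, idata = idata, idesign = ~ block * task, type = 3)
  # summary() warns when the (unused) Huynh-Feldt epsilon exceeds 1
  s <- suppressWarnings(summary(av, multivariate = FALSE))

  ut <- s$univariate.tests
  adj <- s$pval.adjustments
  sph <- s$sphericity.tests
  rows <- setdiff(rownames(ut), "(Intercept)")
  out <- do.call(rbind, lapply(rows, function(ef) {
    f_val <- ut[ef, "F value"]
    p_unc <- ut[ef, "Pr(>F)"]
    in_adj <- !is.null(adj) && ef %in% rownames(adj)
    eps <- if (in_adj) adj[ef, "GG eps"] else 1
    p_gg <- if (in_adj) adj[ef, "Pr(>F[GG])"] else p_unc
    in_sph <- !is.null(sph) && ef %in% rownames(sph)
    data.frame(
      effect = ef,
      df = ut[ef, "num Df"], df_error = ut[ef, "den Df"],
      statistic = f_val, p_uncorrected = p_unc,
      mauchly_W = if (in_sph) sph[ef, "Test statistic"] else NA_real_,
      mauchly_p = if (in_sph) sph[ef, "p-value"] else NA_real_,
      gg_epsilon = eps, p_gg = p_gg,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  class(out) <- c("effect_report", "data.frame")
  out
}

boot_ci <- function(stat, n_boot, seed, conf = 0.95) {
  reps <- with_seed(seed, vapply(seq_len(n_boot), function(i) stat(),
                                 numeric(1)))
  alpha <- (1 - conf) / 2
  unname(stats::quantile(reps, c(alpha, 1 - alpha)))
}

#' Between-group comparison of a learning-rate variable
#'
#' Two-sided Mann-Whitney rank-sum test ([rank_sum_test()]) plus a
#' seeded bootstrap percentile interval (default `1e4` resamples) for
#' the difference in group means, `mean(x) - mean(y)`.
#'
#' @param x,y Participant-level values for the two groups.
#' @param conf Interval coverage (default 0.95).
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed for the bootstrap.
#' @return `comparison_result`: list with `statistic`, `p.value`,
#'   `estimate`, `ci`, `conf`, `n`, `test`, `method`.
#' @export
compare_between <- function(x, y, conf = 0.95, n_boot = 1e4, seed = 1) {
  rt <- rank_sum_test(x, y)
  ci <- boot_ci(function() {
    mean(sample(x, replace = TRUE)) - mean(sample(y, replace = TRUE))
  }, n_boot, seed, conf)
  structure(
    list(statistic = rt$statistic, p.value = rt$p.value,
         estimate = mean(x) - mean(y), ci = ci, conf = conf,
         n = c(length(x), length(y)), test = "mann-whitney",
         method = rt$method),
    class = "comparison_result"
  )
}

#' Within-group paired comparison of two learning-rate variables
#'
#' Two-sided Wilcoxon signed-rank test on paired differences `x - y`
#' ([signed_rank_test()]) plus a seeded bootstrap percentile interval
#' for the paired mean difference (pairs resampled jointly).
#'
#' @param x,y Paired participant-level values (equal length, same
#'   participant order).
#' @inheritParams compare_between
#' @return `comparison_result` (see [compare_between()]).
#' @export
compare_within <- function(x, y, conf = 0.95, n_boot = 1e4, seed = 1) {
  stopifnot(length(x) == length(y))
  d <- x - y
  rt <- signed_rank_test(d)
  ci <- boot_ci(function() mean(sample(d, replace = TRUE)),
                n_boot, seed, conf)
  structure(
    list(statistic = rt$statistic, p.value = rt$p.value,
         estimate = mean(d), ci = ci, conf = conf,
         n = c(length(x), length(y)), test = "wilcoxon-signed-rank",
         method = rt$method),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s (%s): statistic = %.3g, p = %.4g\n", x$test, x$method,
              x$statistic, x$p.value))
  cat(sprintf("mean difference = %.3f, %d%% CI [%.3f, %.3f], n = %d/%d\n",
              x$estimate, round(100 * x$conf), x$ci[1], x$ci[2],
              x$n[1], x$n[2]))
  invisible(x)
}

#' Full statistical analysis of two scored cohorts
#'
#' Composes the analysis plan: Shapiro-Wilk screening of the four
#' learning-rate variables, the mixed RM-ANOVA on block-wise mean AGF,
#' between-group Mann-Whitney tests on both learning rates, and
#' within-group signed-rank tests of repeat vs random learning.
#'
#' @param nc,mci [score_cohort()] outputs for the two groups.
#' @param seed Integer seed (drives the bootstrap intervals).
#' @param n_boot Bootstrap resamples per interval.
#' @return List (JSON-serializable): `normality`, `rm_anova`,
#'   `between` (per variable), `within` (per group), `group_summary`.
#' @export
run_full_analysis <- function(nc, mci, seed = 1, n_boot = 1e4) {
  stopifnot(is.data.frame(nc$lr), is.data.frame(mci$lr))
  seeds <- derive_seeds(seed, c("b_ran", "b_rep", "w_nc", "w_mci"))
  normality <- normality_check(list(
    nc_lr_ran = nc$lr$lr_ran, nc_lr_rep = nc$lr$lr_rep,
    mci_lr_ran = mci$lr$lr_ran, mci_lr_rep = mci$lr$lr_rep
  ))
  tbl <- build_anova_table(rbind(nc$block_scores, mci$block_scores))
  anova_report <- rm_anova(tbl)
  between <- list(
    lr_ran = compare_between(nc$lr$lr_ran, mci$lr$lr_ran,
                             n_boot = n_boot, seed = seeds[["b_ran"]]),
    lr_rep = compare_between(nc$lr$lr_rep, mci$lr$lr_rep,
                             n_boot = n_boot, seed = seeds[["b_rep"]])
  )
  within <- list(
    nc = compare_within(nc$lr$lr_rep, nc$lr$lr_ran,
                        n_boot = n_boot, seed = seeds[["w_nc"]]),
    mci = compare_within(mci$lr$lr_rep, mci$lr$lr_ran,
                         n_boot = n_boot, seed = seeds[["w_mci"]])
  )
  summarize <- function(lr) {
    data.frame(
      n = nrow(lr),
      lr_ran_mean = mean(lr$lr_ran), lr_ran_sd = stats::sd(lr$lr_ran),
      lr_rep_mean = mean(lr$lr_rep), lr_rep_sd = stats::sd(lr$lr_rep)
    )
  }
  list(
    group_summary = list(nc = summarize(nc$lr), mci = summarize(mci$lr)),
    normality = normality,
    rm_anova = anova_report,
    between = lapply(between, unclass),
    within = lapply(within, unclass)
  )
}
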