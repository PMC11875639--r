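test_that("normality screening behaves across distributions", {
  # normal samples rarely rejected
  p_norm <- vapply(1:100, function(s) {
    with_seed(3000 + s, normality_check(rnorm(50))$p_value)
  }, numeric(1))
  expect_gte(mean(p_norm > 0.05), 0.9)
  # heavily skewed samples usually rejected
  p_exp <- vapply(1:100, function(s) {
    with_seed(4000 + s, normality_check(rexp(50))$p_value)
  }, numeric(1))
  expect_gte(mean(p_exp < 0.05), 0.8)
  expect_error(normality_check(c(1, 2)), "n >= 3")
  expect_error(normality_check(rep(1, 10)), "constant")
  multi <- normality_check(list(a = rnorm(20), b = rexp(20)))
  expect_equal(multi$variable, c("a", "b"))
})

make_flat_table <- function(n_per_group = 4, value = 0.05) {
  ids <- c(sprintf("nc%02d", 1:n_per_group),
           sprintf("mci%02d", 1:n_per_group))
  grp <- rep(c("NC", "MCI"), each = n_per_group)
  bs <- expand.grid(participant_id = ids, block_index = 1:10,
                    stringsAsFactors = FALSE)
  bs$group <- grp[match(bs$participant_id, ids)]
  bs$mean_agf_ran <- value
  bs$mean_agf_rep <- value
  build_anova_table(bs)
}

test_that("identical values everywhere produce no significant effect", {
  rep <- rm_anova(make_flat_table())
  expect_true(all(rep$p_uncorrected == 1))
  expect_true(all(rep$p_gg == 1))
})

test_that("compound-symmetric data keep the sphericity correction near one", {
  tbl <- make_flat_table(n_per_group = 10)
  with_seed(71, {
    subj <- rnorm(length(unique(tbl$participant_id)), 0, 0.01)
    names(subj) <- unique(tbl$participant_id)
    tbl$agf <- 0.05 + subj[tbl$participant_id] + rnorm(nrow(tbl), 0, 0.005)
  })
  rep <- rm_anova(tbl)
  eps <- rep$gg_epsilon[rep$effect == "block"]
  expect_gt(eps, 0.6)
  expect_true(all(rep$gg_epsilon > 0 & rep$gg_epsilon <= 1 + 1e-9))
  # the correction is conservative wherever F exceeds 1
  big <- rep$statistic >= 1
  expect_true(all(rep$p_gg[big] >= rep$p_uncorrected[big] - 1e-12))
})

test_that("unbalanced designs are refused", {
  tbl <- make_flat_table()
  expect_error(rm_anova(tbl[-1, ]), "balanced")
  expect_error(build_anova_table(data.frame(participant_id = "a",
                                            group = "NC", block_index = 1,
                                            mean_agf_ran = 1,
                                            mean_agf_rep = 1)),
               "10 blocks")
})

test_that("between-group comparison reports test, estimate and interval", {
  x <- c(10, 12, 9, 14, 11)
  same <- compare_between(x, x, n_boot = 500, seed = 2)
  expect_equal(same$p.value, 1)
  expect_true(same$ci[1] <= 0 && same$ci[2] >= 0)
  expect_warning(compare_between(rep(1, 4), rep(1, 4), n_boot = 50, seed = 2),
                 "tied")

  with_seed(72, {
    a <- rnorm(60); b <- rnorm(60, 2)
    res <- compare_between(a, b, n_boot = 2000, seed = 3)
    expect_lt(res$p.value, 0.01)
    expect_lt(res$ci[2], 0)   # a - b clearly negative
    expect_equal(res$estimate, mean(a) - mean(b))
  })
  # bootstrap interval is seed-reproducible
  r1 <- compare_between(x, x + 1, n_boot = 200, seed = 9)
  r2 <- compare_between(x, x + 1, n_boot = 200, seed = 9)
  expect_identical(r1$ci, r2$ci)
})

test_that("within-group comparison matches hand-enumerated signed ranks", {
  x <- c(5, 8, 4, 9, 7)
  y <- c(3, 9, 1, 4, 2)
  res <- compare_within(x, y, n_boot = 500, seed = 4)
  # |d| = 2,1,3,5,5 -> ranks 2,1,3,4.5,4.5; negatives: d = -1 (rank 1)
  expect_equal(res$statistic, 2 + 3 + 4.5 + 4.5)
  expect_error(compare_within(x, x), "degenerate")
  expect_error(compare_within(x, y[1:4]))
})

test_that("the full analysis report is complete and reproducible", {
  pair <- with_seed(73, {
    mk <- function(n, shift, grp) {
      ids <- sprintf("%s%02d", tolower(grp), 1:n)
      bs <- expand.grid(participant_id = ids, block_index = 1:10,
                        stringsAsFactors = FALSE)
      bs$group <- grp
      bs$mean_agf_ran <- 0.05 + rnorm(nrow(bs), 0, 0.01)
      bs$mean_agf_rep <- 0.05 + shift * bs$block_index / 100 +
        rnorm(nrow(bs), 0, 0.01)
      lr <- data.frame(participant_id = ids, group = grp,
                       lr_ran = rnorm(n, 30, 20), lr_rep = rnorm(n, 60, 20))
      list(lr = lr, block_scores = bs)
    }
    list(nc = mk(12, -1, "NC"), mci = mk(10, 0, "MCI"))
  })
  rep1 <- run_full_analysis(pair$nc, pair$mci, seed = 5, n_boot = 500)
  expect_named(rep1, c("group_summary", "normality", "rm_anova",
                       "between", "within"))
  expect_equal(nrow(rep1$normality), 4L)
  expect_true(all(c("lr_ran", "lr_rep") %in% names(rep1$between)))
  expect_true(all(rep1$rm_anova$gg_epsilon <= 1 + 1e-9))
  rep2 <- run_full_analysis(pair$nc, pair$mci, seed = 5, n_boot = 500)
  expect_identical(rep1, rep2)
})
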