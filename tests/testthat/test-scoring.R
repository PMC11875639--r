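test_that("AGF is zero for perfect tracking and equals a constant offset", {
  sp <- fix_specs()[[1]]
  expect_equal(agf_random(sp$samples, sp), 0)
  expect_equal(agf_repeat(sp$samples, sp), 0)
  expect_equal(agf_random(sp$samples + 0.05, sp), 0.05, tolerance = 1e-12)
  expect_equal(agf_repeat(sp$samples - 0.02, sp), 0.02, tolerance = 1e-12)
})

test_that("AGF equals a brute-force loop over the half's samples", {
  sp <- fix_specs()[[3]]
  measured <- with_seed(41, sp$samples + rnorm(230, 0, 0.02))
  acc_ran <- 0
  for (k in 31:130) acc_ran <- acc_ran + abs(sp$samples[k] - measured[k])
  acc_rep <- 0
  for (k in 131:230) acc_rep <- acc_rep + abs(sp$samples[k] - measured[k])
  expect_equal(agf_random(measured, sp), acc_ran / 100, tolerance = 1e-12)
  expect_equal(agf_repeat(measured, sp), acc_rep / 100, tolerance = 1e-12)
})

test_that("AGF ignores the 30 preparation samples and scales with the residual", {
  sp <- fix_specs()[[2]]
  measured <- with_seed(42, sp$samples + rnorm(230, 0, 0.02))
  perturbed <- measured
  perturbed[1:30] <- 0.49
  expect_equal(agf_random(perturbed, sp), agf_random(measured, sp))
  expect_equal(agf_repeat(perturbed, sp), agf_repeat(measured, sp))
  # residual scale equivariance
  lambda <- 2.5
  scaled <- sp$samples + lambda * (measured - sp$samples)
  expect_equal(agf_random(scaled, sp), lambda * agf_random(measured, sp),
               tolerance = 1e-12)
  expect_equal(agf_repeat(scaled, sp), lambda * agf_repeat(measured, sp),
               tolerance = 1e-12)
})

test_that("length and task mismatches are contract violations", {
  sp <- fix_specs()[[1]]
  expect_error(agf_random(sp$samples[1:229], sp), "229")
  trial <- list(measured = sp$samples, task_id = 2L)
  expect_error(agf_random(trial, sp), "task 2")
})

test_that("block means average exactly five trials in trial order", {
  scores <- data.frame(trial_index = 1:50,
                       agf_ran = rep(0.04, 50), agf_rep = rep(0.03, 50))
  scores$agf_ran[1:5] <- c(1, 2, 3, 4, 5) * 1e-2
  bm <- block_means(scores)
  expect_equal(nrow(bm), 10L)
  expect_equal(bm$mean_agf_ran[1], 0.03)
  expect_equal(bm$mean_agf_ran[2:10], rep(0.04, 9))
  expect_equal(bm$mean_agf_rep, rep(0.03, 10))
  # permuting trials within a block leaves its mean unchanged
  shuffled <- scores[c(3, 1, 5, 4, 2, 6:50), ]
  expect_equal(block_means(shuffled), bm)
  expect_error(block_means(scores[1:49, ]), "50")
})

test_that("learning rates follow the block-1 vs block-10 relative change", {
  mk <- function(b1, b10) {
    data.frame(block_index = 1:10,
               mean_agf_ran = c(b1, rep(0.06, 8), b10),
               mean_agf_rep = c(b1, rep(0.06, 8), b10))
  }
  expect_equal(learning_rates(mk(0.05, 0.05))$lr_ran, 0)
  expect_equal(learning_rates(mk(0.080, 0.050))$lr_ran, 60)
  expect_equal(learning_rates(mk(0.050, 0.080))$lr_rep, -37.5)
  # dimensionless: rescaling all block means leaves LR unchanged
  b <- mk(0.08, 0.05)
  b2 <- b
  b2$mean_agf_ran <- b2$mean_agf_ran * 3.7
  b2$mean_agf_rep <- b2$mean_agf_rep * 3.7
  expect_equal(learning_rates(b2), learning_rates(b))
  expect_error(learning_rates(mk(0.05, 0)), "undefined")
})

test_that("participant scoring composes the stages and is order-invariant", {
  specs <- fix_specs()
  sch <- fix_schedule()
  p <- simulate_participant(specs, sch, fix_params(), seed = 77)
  sc <- score_participant(p, specs)
  # hand-composed pipeline on the same traces
  hand <- data.frame(
    trial_index = 1:50, agf_ran = NA_real_, agf_rep = NA_real_
  )
  for (t in 1:50) {
    sp <- specs[[sch$task_id[t]]]
    hand$agf_ran[t] <- mean(abs(sp$samples[31:130] - p$measured[31:130, t]))
    hand$agf_rep[t] <- mean(abs(sp$samples[131:230] - p$measured[131:230, t]))
  }
  hb <- block_means(hand)
  expect_equal(sc$block_scores$mean_agf_ran, hb$mean_agf_ran)
  expect_equal(sc$block_scores$mean_agf_rep, hb$mean_agf_rep)
  expect_equal(sc$lr$lr_ran,
               (hb$mean_agf_ran[1] - hb$mean_agf_ran[10]) /
                 hb$mean_agf_ran[10] * 100)

  # cohort scoring does not depend on participant order
  p2 <- simulate_participant(specs, sch, fix_params(), seed = 78,
                             participant_id = "p02")
  a <- score_cohort(list(p, p2), specs)
  b <- score_cohort(list(p2, p), specs)
  expect_equal(a$lr[order(a$lr$participant_id), ]$lr_rep,
               b$lr[order(b$lr$participant_id), ]$lr_rep)
})

test_that("a perfect tracker yields zero AGF everywhere and an undefined rate", {
  specs <- fix_specs()
  sch <- fix_schedule()
  measured <- vapply(1:50, function(t) specs[[sch$task_id[t]]]$samples,
                     numeric(230))
  p <- list(participant_id = "ideal", group = "NC",
            schedule = sch, measured = measured)
  expect_error(score_participant(p, specs), "undefined")
})
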