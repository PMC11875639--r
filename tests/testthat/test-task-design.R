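cc <- task_constants()
N1 <- cc$n1
N <- cc$n

test_that("line evaluation matches a term-by-term summation oracle", {
  lines <- fix_lines()
  for (i in 1:5) {
    k <- (N1 + 1):(N1 + N)
    expect_equal(eval_random_line(lines$random[[i]], k),
                 oracle_line(lines$random[[i]], (k - N1) * cc$delta_t),
                 tolerance = 1e-12)
  }
  k <- (N1 + N + 1):(N1 + 2 * N)
  expect_equal(eval_repeat_line(lines$repeat_line, k),
               oracle_line(lines$repeat_line, (k - N1 - N) * cc$delta_t),
               tolerance = 1e-12)
})

test_that("phase-0 value is b0 plus the cosine sum, and zero harmonics give a constant", {
  lines <- fix_lines()
  rc <- lines$random[[1]]
  expect_equal(eval_random_line(rc, N1),
               rc$scale * (rc$b0 + sum(rc$b)), tolerance = 1e-12)
  pc <- lines$repeat_line
  expect_equal(eval_repeat_line(pc, N1 + N),
               pc$scale * (pc$b0 + sum(pc$b)), tolerance = 1e-12)
  flat <- target_coefs("random", b0 = 25, a = rep(0, 6), b = rep(0, 6),
                       task_id = 1)
  expect_equal(eval_random_line(flat, N1 + 0:50), rep(0.25, 51))
  flat_rep <- target_coefs("repeat", b0 = 20, a = rep(0, 6), b = rep(0, 6))
  expect_equal(eval_repeat_line(flat_rep, (N1 + N) + 0:20), rep(0.2, 21))
})

test_that("the repeat line is periodic with the 18 s fundamental", {
  pc <- fix_lines()$repeat_line
  k <- N1 + N + 7
  expect_equal(eval_repeat_line(pc, k),
               eval_repeat_line(pc, k + 18 / cc$delta_t), tolerance = 1e-10)
})

test_that("role mismatch is a contract violation", {
  lines <- fix_lines()
  expect_error(eval_random_line(lines$repeat_line, 40), "role 'random'")
  expect_error(eval_repeat_line(lines$random[[1]], 140), "role 'repeat'")
  expect_error(compose_task(2, lines$random[[1]], lines$repeat_line),
               "task 1")
})

test_that("the solver is deterministic and its output satisfies every boundary condition", {
  lines <- fix_lines()
  again <- solve_coefficients(20260922)
  expect_identical(lines$random, again$random)
  expect_identical(lines$repeat_line, again$repeat_line)

  # independent constraint checks, straight from the coefficients
  pc <- lines$repeat_line
  v_rep0 <- oracle_line(pc, 0)
  d_rep <- v_rep0 - oracle_line(pc, cc$delta_t)
  for (i in 1:5) {
    rc <- lines$random[[i]]
    # start value 0.25 kg
    expect_equal(oracle_line(rc, 0), 0.25, tolerance = 1e-10)
    # junction continuity: random at 10 s equals repeat at phase 0
    expect_equal(oracle_line(rc, N * cc$delta_t), v_rep0, tolerance = 1e-10)
    # junction slope match within tolerance
    d_ran <- oracle_line(rc, (N - 1) * cc$delta_t) -
      oracle_line(rc, N * cc$delta_t)
    expect_lt(abs(d_ran - d_rep), attr(lines, "slope_tol") + 1e-12)
    # harmonic box
    expect_true(all(abs(c(rc$a, rc$b)) <= cc$coef_box))
  }
  expect_true(all(abs(c(pc$a, pc$b)) <= cc$coef_box))
})

test_that("composed tasks pass the independent validator", {
  specs <- fix_specs()
  for (i in 1:5) {
    rep <- validate_task(specs[[i]], others = specs[-i])
    expect_true(attr(rep, "pass"), info = paste("task", i))
  }
})

test_that("composed trajectories have the documented shape", {
  specs <- fix_specs()
  rep_half <- specs[[1]]$samples[(N1 + N + 1):(N1 + 2 * N)]
  for (sp in specs) {
    expect_length(sp$samples, 230L)
    expect_equal(sp$samples[1], 0.25, tolerance = 1e-10)
    expect_equal(sp$samples[N1], 0.25, tolerance = 1e-10)
    body <- sp$samples[(N1 + 1):(N1 + 2 * N)]
    expect_true(all(body >= 0.06 & body <= 0.4))
    # repeat half bitwise identical across tasks
    expect_identical(sp$samples[(N1 + N + 1):(N1 + 2 * N)], rep_half)
    # junction continuity against the repeat line's first instant
    expect_equal(sp$samples[N1 + N],
                 eval_repeat_line(sp$repeat_coefs, N1 + N),
                 tolerance = 1e-12)
    # both junctions are step-continuous
    expect_lt(abs(sp$samples[N1] - sp$samples[N1 + 1]), 0.03)
    expect_lt(abs(sp$samples[N1 + N] - sp$samples[N1 + N + 1]), 0.03)
  }
})

test_that("the validator reports violated constraints", {
  specs <- fix_specs()
  broken <- specs[[1]]
  broken$samples[50] <- 0.5
  rep <- validate_task(broken)
  expect_false(rep$pass[rep$constraint == "range_0.06_0.4_kg"])

  tweaked <- specs[[2]]
  tweaked$samples[200] <- tweaked$samples[200] + 1e-4
  rep2 <- validate_task(tweaked, others = specs[-2])
  expect_false(
    rep2$pass[rep2$constraint == "repeat_half_identical_across_tasks"]
  )
  # the unmodified spec still passes against the others
  expect_true(attr(validate_task(specs[[1]], others = specs[2:5]), "pass"))
})

test_that("the 50-trial schedule honors the fixed opening blocks and the seed", {
  sch <- make_schedule(11)
  expect_equal(nrow(sch), 50L)
  expect_true(all(sch$task_id %in% 1:5))
  expect_equal(sch$block_index, rep(1:10, each = 5))
  expect_equal(sch$task_id[1:5], c(4, 3, 1, 3, 4))
  expect_equal(sch$task_id[6:10], c(1, 2, 2, 4, 1))
  expect_equal(sch$task_id[11:15], c(5, 1, 5, 4, 4))
  expect_identical(make_schedule(11), sch)
  expect_false(identical(make_schedule(12)$task_id, sch$task_id))
  expect_equal(attr(sch, "rest_s"), 30)
  free <- make_schedule(11, prefix = NULL)
  expect_equal(nrow(free), 50L)
})
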