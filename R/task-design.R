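# Target-line geometry. Each 23 s trial is 230 samples at 0.1 s:
# 30 preparation samples holding 0.25 kg, 100 "random"-half samples
# (one of five waveforms), 100 "repeat"-half samples (same waveform in
# every trial). Waveforms are 6-harmonic truncated Fourier series on a
# fundamental of 2*pi/18 rad/s, bounded to [0.06, 0.4] kg.

#' Protocol and waveform constants
#'
#' @return Named list: `n1` (preparation samples, 30), `n` (samples per
#'   task half, 100), `delta_t` (sampling interval, s), `omega`
#'   (fundamental frequency, rad/s), `n_harmonics` (6), `coef_scale`
#'   (display-unit to kg factor for Fourier coefficients), `coef_box`
#'   (admissible half-width for harmonic coefficients, display units),
#'   `hold_kg` (preparation force), `range_kg` (waveform force bounds).
#' @export
task_constants <- function() {
  list(
    n1 = 30L, n = 100L, delta_t = 0.1, omega = 2 * pi / 18,
    n_harmonics = 6L, coef_scale = 1e-2, coef_box = 5,
    hold_kg = 0.25, range_kg = c(0.06, 0.4)
  )
}

#' Construct a target-line coefficient set
#'
#' A target line is `scale * (b0 + sum_n a_n sin(n w t) + b_n cos(n w t))`
#' in kg, with 6 harmonics. Harmonic coefficients live in display units
#' inside the admissible box `[-5, 5]`; the offset `b0` is solved freely
#' in the range-feasible band (a box-bounded offset cannot place the
#' waveform mean near 0.23 kg under the fixed display scale).
#'
#' @param role `"random"` or `"repeat"`.
#' @param b0 Offset (display units).
#' @param a,b Numeric length-6 sine / cosine harmonic amplitudes
#'   (display units).
#' @param task_id Task number 1..5 for random lines, `NA` for the
#'   repeat line.
#' @param scale Display-unit to kg factor (default `1e-2`).
#' @return Object of class `target_coefs`.
#' @export
target_coefs <- function(role = c("random", "repeat"), b0, a, b,
                         task_id = NA_integer_, scale = 1e-2) {
  role <- match.arg(role)
  stopifnot(length(a) == 6L, length(b) == 6L, length(b0) == 1L,
            is.numeric(a), is.numeric(b), is.numeric(b0), scale > 0)
  if (role == "random" && !is.na(task_id)) {
    stopifnot(task_id %in% 1:5)
  }
  structure(
    list(role = role, task_id = as.integer(task_id), b0 = as.numeric(b0),
         a = as.numeric(a), b = as.numeric(b), scale = as.numeric(scale)),
    class = "target_coefs"
  )
}

# Fourier evaluation at phase t (seconds); returns kg.
eval_fourier <- function(coefs, t) {
  cc <- task_constants()
  n <- seq_len(cc$n_harmonics)
  arg <- outer(t, n * cc$omega)
  harm <- drop(sin(arg) %*% coefs$a + cos(arg) %*% coefs$b)
  coefs$scale * (coefs$b0 + harm)
}

#' Evaluate a random-task target line at sample indices
#'
#' Phase is referenced to the end of the preparation hold: the argument
#' of the trigonometric terms is `(k - n1) * delta_t`.
#'
#' @param coefs `target_coefs` with role `"random"`.
#' @param k Integer sample indices (intended domain `k >= n1`).
#' @return Forces in kg.
#' @export
eval_random_line <- function(coefs, k) {
  stopifnot(inherits(coefs, "target_coefs"))
  if (coefs$role != "random") {
    stop("eval_random_line() requires coefficients with role 'random', got '",
         coefs$role, "'")
  }
  cc <- task_constants()
  eval_fourier(coefs, (k - cc$n1) * cc$delta_t)
}

#' Evaluate the repeat-task target line at sample indices
#'
#' Same functional form as [eval_random_line()] with phase referenced to
#' the start of the repeat half: argument `(k - n1 - n) * delta_t`.
#'
#' @inheritParams eval_random_line
#' @export
eval_repeat_line <- function(coefs, k) {
  stopifnot(inherits(coefs, "target_coefs"))
  if (coefs$role != "repeat") {
    stop("eval_repeat_line() requires coefficients with role 'repeat', got '",
         coefs$role, "'")
  }
  cc <- task_constants()
  eval_fourier(coefs, (k - cc$n1 - cc$n) * cc$delta_t)
}

#' Assemble one 230-sample composite target trajectory
#'
#' Piecewise assembly: the preparation hold equals the random line's
#' phase-0 value (0.25 kg by the start-value constraint) for samples
#' `1..n1`; the random line covers `n1+1 .. n1+n`; the shared repeat
#' line covers `n1+n+1 .. n1+2n`.
#'
#' @param task_id Task number 1..5.
#' @param random_coefs `target_coefs`, role `"random"`, matching
#'   `task_id`.
#' @param repeat_coefs `target_coefs`, role `"repeat"`.
#' @param validate Run [validate_task()] and fail on any violated
#'   constraint (default `TRUE`).
#' @param slope_tol Junction slope-match tolerance in kg per sample step
#'   passed to validation.
#' @return Object of class `task_spec` with fields `task_id`, `n1`,
#'   `n`, `delta_t`, `omega`, `samples` (length 230, kg), and the two
#'   coefficient sets.
#' @export
compose_task <- function(task_id, random_coefs, repeat_coefs,
                         validate = TRUE, slope_tol = 0.005) {
  cc <- task_constants()
  stopifnot(task_id %in% 1:5,
            inherits(random_coefs, "target_coefs"),
            inherits(repeat_coefs, "target_coefs"))
  if (random_coefs$role != "random" || repeat_coefs$role != "repeat") {
    stop("compose_task() needs one 'random' and one 'repeat' coefficient set")
  }
  if (!is.na(random_coefs$task_id) && random_coefs$task_id != task_id) {
    stop("random coefficients are for task ", random_coefs$task_id,
         ", not task ", task_id)
  }
  k_ran <- (cc$n1 + 1L):(cc$n1 + cc$n)
  k_rep <- (cc$n1 + cc$n + 1L):(cc$n1 + 2L * cc$n)
  samples <- c(
    rep(eval_random_line(random_coefs, cc$n1), cc$n1),
    eval_random_line(random_coefs, k_ran),
    eval_repeat_line(repeat_coefs, k_rep)
  )
  spec <- structure(
    list(task_id = as.integer(task_id), n1 = cc$n1, n = cc$n,
         delta_t = cc$delta_t, omega = cc$omega, samples = samples,
         random_coefs = random_coefs, repeat_coefs = repeat_coefs),
    class = "task_spec"
  )
  if (validate) {
    rep_ok <- validate_task(spec, slope_tol = slope_tol)
    if (!all(rep_ok$pass)) {
      bad <- rep_ok$constraint[!rep_ok$pass]
      stop("composed task ", task_id, " violates constraint(s): ",
           paste(bad, collapse = ", "))
    }
  }
  spec
}

#' Compose all five task trajectories from a solved coefficient set
#'
#' @param lines A `task_lines` object from [solve_coefficients()].
#' @inheritParams compose_task
#' @return List of five `task_spec` objects, indexed by task id.
#' @export
compose_tasks <- function(lines, validate = TRUE,
                          slope_tol = attr(lines, "slope_tol") %||% 0.005) {
  stopifnot(inherits(lines, "task_lines"))
  lapply(1:5, function(i) {
    compose_task(i, lines$random[[i]], lines$repeat_line,
                 validate = validate, slope_tol = slope_tol)
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Validate a composed task against its design constraints
#'
#' Report-only checker, independent of the solver: measures the residual
#' of every trajectory constraint (length, preparation hold value and
#' constancy, force range, junction continuity against the repeat
#' line's first instant, junction slope match, harmonic-coefficient
#' box) plus, when `others` is supplied, bitwise identity of the repeat
#' half across tasks.
#'
#' @param spec A `task_spec`.
#' @param others Optional list of other `task_spec`s for the cross-task
#'   repeat-half identity check.
#' @param slope_tol Slope-match tolerance (kg per sample step).
#' @return `data.frame` with columns `constraint`, `pass`, `residual`,
#'   `tolerance`; attribute `pass` gives the overall verdict.
#' @export
validate_task <- function(spec, others = NULL, slope_tol = 0.005) {
  stopifnot(inherits(spec, "task_spec"))
  cc <- task_constants()
  s <- spec$samples
  n1 <- cc$n1; n <- cc$n
  eps <- 1e-9

  res <- list()
  add <- function(constraint, residual, tolerance) {
    res[[length(res) + 1L]] <<- data.frame(
      constraint = constraint, pass = residual <= tolerance,
      residual = residual, tolerance = tolerance,
      stringsAsFactors = FALSE
    )
  }

  add("length_230", abs(length(s) - (n1 + 2L * n)), 0)
  add("hold_constant", max(abs(s[1:n1] - s[n1])), eps)
  add("hold_value_0.25_kg", abs(s[1] - cc$hold_kg), eps)
  body <- s[(n1 + 1L):(n1 + 2L * n)]
  add("range_0.06_0.4_kg",
      max(cc$range_kg[1] - min(body), max(body) - cc$range_kg[2], 0), eps)
  rep0 <- eval_repeat_line(spec$repeat_coefs, n1 + n)     # repeat phase 0
  add("junction_continuity", abs(s[n1 + n] - rep0), eps)
  d_ran <- s[n1 + n - 1L] - s[n1 + n]
  d_rep <- rep0 - s[n1 + n + 1L]
  add("junction_slope_match", abs(d_ran - d_rep), slope_tol)
  box_dev <- max(abs(c(spec$random_coefs$a, spec$random_coefs$b,
                       spec$repeat_coefs$a, spec$repeat_coefs$b))) - cc$coef_box
  add("harmonic_coefficient_box", max(box_dev, 0), eps)
  if (!is.null(others)) {
    idx <- (n1 + n + 1L):(n1 + 2L * n)
    ident <- vapply(others, function(o) identical(o$samples[idx], s[idx]),
                    logical(1))
    add("repeat_half_identical_across_tasks", sum(!ident), 0)
  }

  out <- do.call(rbind, res)
  attr(out, "pass") <- all(out$pass)
  out
}

#' Solve feasible Fourier coefficients for the five tasks
#'
#' The start-value constraint (phase-0 value of every random line equals
#' 0.25 kg) and the junction continuity constraint (random line at phase
#' `n * delta_t` equals the repeat line at phase 0) are enforced exactly
#' by solving linearly for `b0` and the first cosine amplitude `b1` of
#' each random line. The junction slope match, the force range, and the
#' coefficient box are satisfied by seeded rejection sampling over the
#' remaining harmonics, with amplitudes drawn from a `1/n`-decaying
#' envelope so the lines are smooth.
#'
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param slope_tol Junction slope-match tolerance in kg per sample
#'   step (default 0.005).
#' @param max_iter Total rejection-sampling budget (default `1e5`).
#' @return Object of class `task_lines`: `$random` (list of five
#'   `target_coefs`) and `$repeat_line` (one `target_coefs`), with
#'   attributes `seed` and `slope_tol`.
#' @export
solve_coefficients <- function(seed, slope_tol = 0.005, max_iter = 1e5) {
  stopifnot(slope_tol > 0, max_iter >= 1)
  cc <- task_constants()
  sc <- cc$coef_scale
  hold_raw <- cc$hold_kg / sc                 # 25 display units
  lo_raw <- cc$range_kg[1] / sc
  hi_raw <- cc$range_kg[2] / sc
  amp <- 3 / seq_len(cc$n_harmonics)          # draw envelope, inside the box
  n_h <- cc$n_harmonics
  nn <- seq_len(n_h)
  phases <- seq(0, cc$n * cc$delta_t, by = cc$delta_t)   # 0..10 s grid
  sin_mat <- sin(outer(phases, nn * cc$omega))
  cos_mat <- cos(outer(phases, nn * cc$omega))
  n_ph <- length(phases)
  cos_end <- cos_mat[n_ph, ]                  # phase n*delta_t (10 s)
  sin_end <- sin_mat[n_ph, ]

  with_seed(seed, {
    iter <- 0L
    fails <- c(box = 0L, range = 0L, slope = 0L)
    draw <- function() runif(n_h, -amp, amp)

    # repeat line: only range feasibility over its sampled phases
    repeat_raw <- NULL
    while (is.null(repeat_raw)) {
      iter <- iter + 1L
      if (iter > max_iter) {
        stop("coefficient solver exhausted its iteration budget on the ",
             "repeat line (", max_iter, " draws)")
      }
      b0 <- runif(1, 20, 26)
      a <- draw(); b <- draw()
      vals <- b0 + drop(sin_mat %*% a + cos_mat %*% b)
      if (min(vals) >= lo_raw && max(vals) <= hi_raw) {
        repeat_raw <- list(b0 = b0, a = a, b = b, vals = vals)
      } else {
        fails["range"] <- fails["range"] + 1L
      }
    }
    v0_rep <- repeat_raw$vals[1]                       # repeat phase-0 value
    d_rep <- repeat_raw$vals[1] - repeat_raw$vals[2]   # raw slope step

    solve_random <- function(task_id) {
      while (TRUE) {
        iter <<- iter + 1L
        if (iter > max_iter) {
          stop("coefficient solver exhausted its iteration budget on random ",
               "line ", task_id, " (", max_iter, " draws); rejections: ",
               paste(names(fails), fails, sep = "=", collapse = ", "))
        }
        a <- draw()
        b <- draw()
        # exact equalities: start value and junction continuity
        c1 <- sum(b[2:n_h])
        c2 <- sum(a * sin_end) + sum(b[2:n_h] * cos_end[2:n_h])
        b[1] <- ((hold_raw - c1) - (v0_rep - c2)) / (1 - cos_end[1])
        b0 <- hold_raw - c1 - b[1]
        if (abs(b[1]) > cc$coef_box) {
          fails["box"] <- fails["box"] + 1L
          next
        }
        vals <- b0 + drop(sin_mat %*% a + cos_mat %*% b)
        if (min(vals) < lo_raw || max(vals) > hi_raw) {
          fails["range"] <- fails["range"] + 1L
          next
        }
        d_ran <- vals[n_ph - 1L] - vals[n_ph]
        if (abs(d_ran - d_rep) * sc > slope_tol) {
          fails["slope"] <- fails["slope"] + 1L
          next
        }
        return(target_coefs("random", b0, a, b, task_id = task_id, scale = sc))
      }
    }

    random <- lapply(1:5, solve_random)
    structure(
      list(
        random = random,
        repeat_line = target_coefs("repeat", repeat_raw$b0, repeat_raw$a,
                                   repeat_raw$b, scale = sc)
      ),
      class = "task_lines", seed = as.integer(seed), slope_tol = slope_tol,
      iterations = iter
    )
  })
}

#' Standard opening blocks of the trial schedule
#'
#' The first three 5-trial blocks of the protocol are fixed
#' (4-3-1-3-4, 1-2-2-4-1, 5-1-5-4-4); later blocks are drawn at random.
#'
#' @return 3 x 5 integer matrix of task ids.
#' @export
schedule_prefix <- function() {
  matrix(c(4L, 3L, 1L, 3L, 4L,
           1L, 2L, 2L, 4L, 1L,
           5L, 1L, 5L, 4L, 4L), nrow = 3, byrow = TRUE)
}

#' Build the 50-trial protocol schedule
#'
#' Ten blocks of five trials; every trial presents one of the five
#' tasks; a 30 s rest separates blocks. With the default `prefix`, the
#' first three blocks follow the fixed protocol opening
#' ([schedule_prefix()]); remaining blocks are seeded-uniform over the
#' task ids. The schedule is identical for every participant in a run.
#'
#' @param seed Integer seed for the random blocks.
#' @param prefix Integer matrix of fixed leading blocks (rows = blocks,
#'   5 columns), or `NULL` for a fully random schedule.
#' @return `protocol_schedule`: data.frame with `trial_index` (1..50),
#'   `block_index` (1..10), `task_id` (1..5); attribute `rest_s = 30`.
#' @export
make_schedule <- function(seed, prefix = schedule_prefix()) {
  n_blocks <- 10L; per_block <- 5L
  fixed <- if (is.null(prefix)) integer(0) else as.integer(t(prefix))
  stopifnot(length(fixed) %% per_block == 0L,
            length(fixed) <= n_blocks * per_block,
            all(fixed %in% 1:5))
  task_id <- with_seed(seed, {
    c(fixed, sample(1:5, n_blocks * per_block - length(fixed),
                    replace = TRUE))
  })
  out <- data.frame(
    trial_index = 1:(n_blocks * per_block),
    block_index = rep(1:n_blocks, each = per_block),
    task_id = task_id
  )
  class(out) <- c("protocol_schedule", "data.frame")
  attr(out, "rest_s") <- 30
  out
}
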