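#' Derive named child seeds from a master seed
#'
#' All stochastic stages draw their seeds from one master seed through
#' this function, so a whole pipeline run is reproducible from a single
#' integer while stages stay statistically independent.
#'
#' @param master Single integer master seed.
#' @param names Character vector naming the child streams.
#' @return Named integer vector of child seeds (all < 2^31).
#' @examples
#' derive_seeds(1, c("tasks", "cohort"))
#' @export
derive_seeds <- function(master, names) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  stopifnot(is.character(names), length(names) >= 1L, !anyDuplicated(names))
  seeds <- with_seed(as.integer(master), {
    sample.int(.Machine$integer.max - 1L, length(names))
  })
  stats::setNames(seeds, names)
}

#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG seed, runs `code`, and restores the caller's RNG state,
#' so library internals never perturb user-level random streams.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
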