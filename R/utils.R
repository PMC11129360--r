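#' Single-year age grid used throughout the package
#'
#' All schedules, panels and life tables are indexed on closed single-year
#' ages 0 to 99. Deaths reported at ages 100+ are collapsed into age 99 by
#' the readers.
#'
#' @return Integer vector `0:99`.
#' @export
age_grid <- function() 0:99

#' @rdname age_grid
#' @export
sexes <- function() c("female", "male")

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Deterministic child seeds for sub-generators, kept inside 32-bit range.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k) %% 2147483647)
}

#' Map single-year ages to coverage age blocks
#'
#' @param breaks lower endpoints of the blocks (first must be 0); default
#'   `c(0, 5)` gives the child (0-4) / adult (5+) split.
#' @param ages ages to classify.
#' @return integer block index per age.
#' @export
age_blocks <- function(breaks = c(0, 5), ages = age_grid()) {
  stopifnot(breaks[1] == 0, !is.unsorted(breaks, strictly = TRUE))
  findInterval(ages, breaks)
}
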