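#' Smoothing neighbourhoods from the geographic hierarchy
#'
#' The default neighbourhood of a municipality is the set of all
#' municipalities sharing its microregion, itself included — consistent with
#' the pipeline's within-microregion homogeneity assumption and requiring no
#' contiguity data. A custom map (e.g. queen contiguity) can be supplied to
#' [marshall_smooth()] directly as a named list.
#'
#' @param hierarchy a [geo_hierarchy()].
#' @return named list: per municipality, the character vector of neighbour
#'   ids (self-inclusive).
#' @export
neighborhoods_from_hierarchy <- function(hierarchy) {
  members <- split(hierarchy$municipality_id, hierarchy$microregion_id)
  stats::setNames(members[hierarchy$microregion_id], hierarchy$municipality_id)
}

#' Marshall local empirical-Bayes smoothing of area rates
#'
#' Shrinks each area's rate toward its neighbourhood mean by a data-driven
#' factor. With neighbourhood `N(i)`: the exposure-weighted mean
#' `m_i = sum d_j / sum n_j`, the exposure-weighted variance
#' `s_i^2 = sum n_j (r_j - m_i)^2 / sum n_j`, the between-area variance
#' estimate `A_i = s_i^2 - m_i / nbar_i` (with `nbar_i` the mean
#' neighbourhood exposure), and the shrinkage weight
#' `C_i = A_i / (A_i + m_i / n_i)` when `A_i > 0`, else 0 (Marshall's
#' truncation: apparent under-dispersion means full shrinkage to the
#' neighbourhood mean). The smoothed rate is `m_i + C_i (r_i - m_i)`.
#'
#' Applied independently per sex and single age, on the rate scale, so the
#' moment identities above are exact.
#'
#' @param rates named non-negative rate vector (one sex and age, all areas).
#' @param exposures named positive exposures, same areas.
#' @param neighborhoods named list of self-inclusive neighbour id vectors,
#'   e.g. from [neighborhoods_from_hierarchy()].
#' @return named vector of smoothed rates.
#' @export
marshall_smooth <- function(rates, exposures, neighborhoods) {
  stopifnot(length(rates) == length(exposures))
  if (any(exposures <= 0)) stop("exposures must be positive")
  if (any(rates < 0)) stop("rates must be non-negative")
  ids <- names(rates)
  if (is.null(ids)) stop("rates must be named by area id")
  out <- rates
  for (i in seq_along(ids)) {
    nb <- neighborhoods[[ids[i]]]
    if (is.null(nb) || length(nb) == 0L) stop("empty neighborhood for ", ids[i])
    j <- match(nb, ids)
    if (anyNA(j)) stop("neighborhood of ", ids[i], " contains unknown areas")
    n <- exposures[j]
    r <- rates[j]
    m <- sum(r * n) / sum(n)
    s2 <- sum(n * (r - m)^2) / sum(n)
    A <- s2 - m / mean(n)
    C <- if (A > 0) A / (A + m / exposures[i]) else 0
    out[i] <- m + C * (rates[i] - m)
  }
  out
}
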