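#' Geographic hierarchy table
#'
#' A three-level nesting of areas: municipalities group into microregions,
#' microregions into macroregions. Municipalities are the smallest
#' registration units; the microregion is both the level at which the
#' Bayesian completeness model is fit and the default smoothing
#' neighbourhood; macroregions carry the historical rate series used for
#' forecasting. Extra columns (mesoregion, state) are carried as metadata
#' and never used computationally.
#'
#' @param municipality_id,microregion_id,macroregion_id character vectors of
#'   equal length; each municipality must appear once and map to exactly one
#'   microregion, each microregion to exactly one macroregion.
#' @param ... optional metadata columns of the same length.
#' @return a `geo_hierarchy` data frame.
#' @export
geo_hierarchy <- function(municipality_id, microregion_id, macroregion_id, ...) {
  h <- data.frame(
    municipality_id = as.character(municipality_id),
    microregion_id = as.character(microregion_id),
    macroregion_id = as.character(macroregion_id),
    ...,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(h$municipality_id)) {
    stop("duplicate municipality ids in hierarchy")
  }
  m2micro <- unique(h[, c("municipality_id", "microregion_id")])
  if (anyDuplicated(m2micro$municipality_id)) {
    stop("a municipality maps to more than one microregion")
  }
  micro2macro <- unique(h[, c("microregion_id", "macroregion_id")])
  if (anyDuplicated(micro2macro$microregion_id)) {
    stop("a microregion maps to more than one macroregion")
  }
  class(h) <- c("geo_hierarchy", "data.frame")
  h
}

#' Demographic panel of deaths and exposures
#'
#' Deaths and person-years of exposure indexed by area, sex and single-year
#' age 0-99, at one geographic level. Internally stored as two
#' `area x sex x age` arrays.
#'
#' @param deaths,exposures numeric arrays of dimension
#'   `(n_areas, 2, 100)` with dimnames `(area ids, c("female","male"),
#'   0:99)`, or long data frames with columns `area_id, sex, age` and
#'   `deaths` / `exposure`.
#' @param level one of `"municipality"`, `"microregion"`, `"macroregion"`.
#' @return a `demographic_panel` object.
#' @export
demographic_panel <- function(deaths, exposures, level = "municipality") {
  level <- match.arg(level, c("municipality", "microregion", "macroregion"))
  if (is.data.frame(deaths)) deaths <- .long_to_array(deaths, "deaths", fill = 0)
  if (is.data.frame(exposures)) exposures <- .long_to_array(exposures, "exposure", fill = NA)
  stopifnot(identical(dim(deaths), dim(exposures)),
            identical(dimnames(deaths), dimnames(exposures)))
  if (anyNA(exposures)) {
    bad <- which(is.na(exposures), arr.ind = TRUE)[1, ]
    dn <- dimnames(exposures)
    stop(sprintf("missing exposure for (%s, %s, age %s)",
                 dn[[1]][bad[1]], dn[[2]][bad[2]], dn[[3]][bad[3]]))
  }
  if (any(exposures <= 0)) {
    bad <- which(exposures <= 0, arr.ind = TRUE)[1, ]
    dn <- dimnames(exposures)
    stop(sprintf("non-positive exposure for (%s, %s, age %s)",
                 dn[[1]][bad[1]], dn[[2]][bad[2]], dn[[3]][bad[3]]))
  }
  if (any(deaths < 0)) stop("negative death counts")
  structure(
    list(deaths = deaths, exposures = exposures, level = level,
         areas = dimnames(deaths)[[1]]),
    class = "demographic_panel"
  )
}

.long_to_array <- function(df, value_col, fill) {
  need <- c("area_id", "sex", "age", value_col)
  if (!all(need %in% names(df))) {
    stop("table must have columns: ", paste(need, collapse = ", "))
  }
  df$age <- as.integer(df$age)
  # ages beyond the grid are collapsed into the open-ended last age
  if (any(df$age < 0)) stop("age outside 0-99: negative age in input")
  over <- df$age > 99
  if (value_col == "deaths") {
    df$age[over] <- 99L
  } else if (any(over)) {
    stop("age outside 0-99 in exposure table")
  }
  df$sex <- as.character(df$sex)
  if (!all(df$sex %in% sexes())) stop("sex must be 'female' or 'male'")
  key <- paste(df$area_id, df$sex, df$age, sep = "\r")
  if (value_col != "deaths" && anyDuplicated(key)) {
    stop("duplicate (area, sex, age) keys in ", value_col, " table")
  }
  areas <- sort(unique(as.character(df$area_id)))
  arr <- array(fill, dim = c(length(areas), 2L, 100L),
               dimnames = list(areas, sexes(), age_grid()))
  i <- cbind(match(df$area_id, areas), match(df$sex, sexes()), df$age + 1L)
  if (value_col == "deaths") {
    # duplicates (incl. collapsed 100+) accumulate
    for (r in seq_len(nrow(df))) {
      arr[i[r, 1], i[r, 2], i[r, 3]] <- arr[i[r, 1], i[r, 2], i[r, 3]] + df[[value_col]][r]
    }
  } else {
    arr[i] <- df[[value_col]]
  }
  arr
}

#' Read a demographic panel from CSV tables
#'
#' `deaths.csv` needs columns `area_id, sex, age, deaths`; `exposures.csv`
#' needs `area_id, sex, age, exposure`. Missing death cells are treated as
#' zero deaths; missing exposure cells are an error. Deaths at reported ages
#' 100+ are collapsed into age 99.
#'
#' @param deaths_path,exposures_path CSV paths.
#' @param geo_path optional geography CSV (`municipality_id, microregion_id,
#'   macroregion_id`); when given, the hierarchy is attached as attribute
#'   `"hierarchy"`.
#' @param level geographic level of the panel.
#' @return a [demographic_panel()].
#' @export
read_panel <- function(deaths_path, exposures_path, geo_path = NULL,
                       level = "municipality") {
  de <- utils::read.csv(deaths_path, stringsAsFactors = FALSE)
  ex <- utils::read.csv(exposures_path, stringsAsFactors = FALSE)
  p <- demographic_panel(de, ex, level = level)
  # deaths table may omit areas present in exposures only if exposures define
  # the area set; enforce same area set by rebuilding deaths on exposure grid
  if (!is.null(geo_path)) {
    g <- utils::read.csv(geo_path, stringsAsFactors = FALSE)
    attr(p, "hierarchy") <- geo_hierarchy(g$municipality_id, g$microregion_id,
                                          g$macroregion_id)
  }
  p
}

#' Write a demographic panel to CSV tables
#'
#' @param panel a [demographic_panel()].
#' @param deaths_path,exposures_path output CSV paths.
#' @export
write_panel <- function(panel, deaths_path, exposures_path) {
  long <- function(arr, name) {
    g <- expand.grid(area_id = panel$areas, sex = sexes(), age = age_grid(),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g[[name]] <- as.vector(arr)
    g
  }
  de <- long(panel$deaths, "deaths")
  ex <- long(panel$exposures, "exposure")
  # >= 10 significant digits so the round trip is value-preserving
  de$deaths <- formatC(de$deaths, digits = 12, format = "g")
  ex$exposure <- formatC(ex$exposure, digits = 12, format = "g")
  utils::write.csv(de, deaths_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(ex, exposures_path, row.names = FALSE, quote = FALSE)
  invisible(panel)
}

#' Aggregate a panel to a coarser geographic level
#'
#' Deaths and exposures are summed over member areas; totals are conserved
#' exactly.
#'
#' @param panel a municipality- or microregion-level [demographic_panel()].
#' @param hierarchy a [geo_hierarchy()].
#' @param to_level target level, coarser than `panel$level`.
#' @return a [demographic_panel()] at `to_level`.
#' @export
aggregate_panel <- function(panel, hierarchy, to_level) {
  levels_order <- c(municipality = 1L, microregion = 2L, macroregion = 3L)
  to_level <- match.arg(to_level, names(levels_order))
  if (levels_order[to_level] <= levels_order[panel$level]) {
    stop("to_level must be coarser than the panel's level")
  }
  from_col <- paste0(ifelse(panel$level == "municipality", "municipality",
                            "microregion"), "_id")
  to_col <- paste0(sub("region$", "region", to_level), "_id")
  to_col <- paste0(to_level, "_id")
  map_tab <- unique(hierarchy[, c(from_col, to_col)])
  idx <- match(panel$areas, map_tab[[from_col]])
  if (anyNA(idx)) {
    stop("areas absent from hierarchy: ",
         paste(panel$areas[is.na(idx)], collapse = ", "))
  }
  parent <- map_tab[[to_col]][idx]
  out_areas <- sort(unique(parent))
  g <- match(parent, out_areas)
  agg <- function(arr) {
    out <- array(0, dim = c(length(out_areas), 2L, 100L),
                 dimnames = list(out_areas, sexes(), age_grid()))
    for (a in seq_along(panel$areas)) {
      out[g[a], , ] <- out[g[a], , ] + arr[a, , ]
    }
    out
  }
  demographic_panel(agg(panel$deaths), agg(panel$exposures), level = to_level)
}

#' @export
print.demographic_panel <- function(x, ...) {
  cat(sprintf("<demographic_panel> %d %s areas x 2 sexes x 100 ages\n",
              length(x$areas), x$level))
  cat(sprintf("  total deaths %.1f, total exposure %.1f\n",
              sum(x$deaths), sum(x$exposures)))
  invisible(x)
}

# Extract the (deaths, exposures) age vectors for one area and sex.
panel_cell <- function(panel, area, sex) {
  list(deaths = panel$deaths[area, sex, ],
       exposures = panel$exposures[area, sex, ])
}
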