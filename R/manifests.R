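#' Desikan-Killiany region manifest
#'
#' The fixed order of the 68 cortical regions (34 left-hemisphere, then 34
#' right-hemisphere) used throughout the package.  Inputs whose region labels
#' do not match this manifest exactly are rejected rather than silently
#' reordered.
#'
#' @param hemisphere `"both"` (default), `"L"` or `"R"`.
#' @return A data frame with columns `region` and `hemisphere`.
#' @export
dk_regions <- function(hemisphere = c("both", "L", "R")) {
  hemisphere <- match.arg(hemisphere)
  path <- system.file("extdata", "dk_regions_68.csv", package = "morphosim",
                      mustWork = TRUE)
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (hemisphere != "both") reg <- reg[reg$hemisphere == hemisphere, , drop = FALSE]
  rownames(reg) <- NULL
  reg
}

#' von Economo cytoarchitectonic class manifest
#'
#' An editable region-to-class lookup assigning each Desikan-Killiany region
#' to one of seven cytoarchitectonic classes (primary motor, association,
#' association2, secondary sensory, primary sensory, limbic, insular).  The
#' shipped file is a conventional-style assignment intended for aggregation
#' mechanics; substitute your own CSV for atlas-faithful analyses.
#'
#' @param path Optional path to a replacement CSV with columns
#'   `region, class`.
#' @return A data frame with columns `region` and `class`.
#' @export
von_economo_classes <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dk_von_economo_classes.csv",
                        package = "morphosim", mustWork = TRUE)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Spherical parcel centroid geometry
#'
#' Reads a parcel geometry CSV (`region, x, y, z, hemisphere`) and validates
#' it for use with the spin test.  Coordinates are renormalised to the unit
#' sphere and must already be unit-norm to within `1e-3`.
#'
#' The shipped default, `dk_centroids_synthetic.csv`, is a synthetic
#' Fibonacci-lattice layout over each hemisphere's sphere (the right
#' hemisphere is the x-mirror of the left).  It is a stand-in with plausible
#' spatial spread, not fsaverage-derived coordinates.
#'
#' @param path CSV path; `NULL` (default) loads the shipped synthetic
#'   Desikan-Killiany layout.
#' @return A `parcel_geometry` data frame with unit-norm coordinates.
#' @export
read_parcel_geometry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dk_centroids_synthetic.csv",
                        package = "morphosim", mustWork = TRUE)
  }
  geo <- utils::read.csv(path, stringsAsFactors = FALSE)
  parcel_geometry(geo)
}

#' Construct a validated parcel geometry
#'
#' @param df Data frame with columns `region, x, y, z, hemisphere`
#'   (`hemisphere` in `{"L","R"}`); coordinates must be unit-norm within 1e-3.
#' @return The validated data frame, classed `parcel_geometry`.
#' @export
parcel_geometry <- function(df) {
  need <- c("region", "x", "y", "z", "hemisphere")
  if (!all(need %in% names(df))) {
    stop("geometry needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) stop("empty geometry", call. = FALSE)
  if (!all(df$hemisphere %in% c("L", "R"))) {
    stop("hemisphere labels must be 'L' or 'R'", call. = FALSE)
  }
  xyz <- as.matrix(df[, c("x", "y", "z")])
  storage.mode(xyz) <- "double"
  nrm <- sqrt(rowSums(xyz^2))
  if (any(abs(nrm - 1) > 1e-3)) {
    stop("centroid coordinates must lie on the unit sphere", call. = FALSE)
  }
  df$x <- xyz[, 1] / nrm
  df$y <- xyz[, 2] / nrm
  df$z <- xyz[, 3] / nrm
  class(df) <- c("parcel_geometry", "data.frame")
  df
}
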