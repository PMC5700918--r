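#' Build a contaminated cotton landscape
#'
#' A rectangular lattice in which every cell grows one cotton plant of the
#' dominant variety (`"BT"` or `"NONBT"`), except for a fixed number of
#' cells of the opposite variety representing seed contamination. Exactly
#' `round(fraction * width * height)` cells (round half away from zero)
#' are switched, placed uniformly at random without replacement. The crop
#' map is immutable during a simulation run.
#'
#' @param width,height lattice dimensions in cells (default 100 x 100).
#' @param dominant dominant crop, `"BT"` or `"NONBT"`.
#' @param fraction contamination fraction in `[0, 0.5]`.
#' @param seed optional integer seed for reproducible placement.
#' @return object of class `landscape`: list with `crop` (character
#'   matrix of `"BT"`/`"NONBT"`), `crop_bt` (integer matrix, 1 = Bt),
#'   `width`, `height`, `dominant`, `fraction`.
#' @export
build_landscape <- function(width = 100, height = 100,
                            dominant = c("BT", "NONBT"), fraction = 0,
                            seed = NULL) {
  dominant <- match.arg(dominant)
  if (width < 1 || height < 1) abort("lattice dimensions must be >= 1")
  if (fraction < 0 || fraction > 0.5)
    abort("`fraction` must be in [0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  other <- if (dominant == "BT") "NONBT" else "BT"
  n <- as.integer(width) * as.integer(height)
  n_contam <- floor(fraction * n + 0.5) # round half away from zero
  crop <- matrix(dominant, nrow = height, ncol = width)
  if (n_contam > 0)
    crop[sample.int(n, n_contam, replace = FALSE)] <- other
  structure(
    list(crop = crop,
         crop_bt = matrix(as.integer(crop == "BT"),
                          nrow = height, ncol = width),
         width = as.integer(width), height = as.integer(height),
         dominant = dominant, fraction = fraction),
    class = "landscape")
}

#' Larval dispersal neighbourhood of a cell
#'
#' The candidate destination cells of a larva: the square Chebyshev ball
#' whose radius depends on the crop of the larva's current cell (radius 3,
#' a 7 x 7 region, on Bt cotton; radius 1, a 3 x 3 region, on non-Bt
#' cotton, by default), clipped at the lattice edges and excluding the
#' origin cell itself.
#'
#' @param cell integer vector `c(row, col)` (1-based).
#' @param landscape a [build_landscape()] object.
#' @param radii named vector `c(BT = 3, NONBT = 1)` of Chebyshev radii.
#' @return two-column integer matrix of candidate `row`, `col` positions.
#' @export
dispersal_neighbourhood <- function(cell, landscape,
                                    radii = c(BT = 3, NONBT = 1)) {
  stopifnot(inherits(landscape, "landscape"), length(cell) == 2)
  i <- cell[1]; j <- cell[2]
  if (i < 1 || i > landscape$height || j < 1 || j > landscape$width)
    abort("`cell` is outside the lattice")
  if (any(radii < 0)) abort("radii must be >= 0")
  r <- unname(radii[[landscape$crop[i, j]]])
  rows <- max(1, i - r):min(landscape$height, i + r)
  cols <- max(1, j - r):min(landscape$width, j + r)
  cand <- as.matrix(expand.grid(row = rows, col = cols,
                                KEEP.OUT.ATTRS = FALSE))
  cand[!(cand[, 1] == i & cand[, 2] == j), , drop = FALSE]
}
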