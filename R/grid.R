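#' The Humphrey 10-2 test-point grid
#'
#' Generates the 68 test-point locations of the HFA 10-2 pattern as an
#' odd-degree lattice: both coordinates lie in \{-9, -7, ..., 7, 9\} degrees
#' and a point is included when x^2 + y^2 <= 82, the unique circular cutoff
#' on that lattice that yields exactly 68 points.  Points are indexed 0-67 in
#' a fixed canonical order: rows from superior (y = +9) to inferior
#' (y = -9), and within a row from temporal to nasal.  For a right eye
#' temporal is negative x, so rows run in ascending x; the left-eye grid is
#' the right-eye grid with x negated pointwise (same index, mirrored
#' location), which keeps index i anatomically aligned across lateralities.
#'
#' @param laterality `"right"` (canonical) or `"left"`.
#' @return A data frame of class `vf_grid` with columns `point_index`
#'   (0-67), `x`, `y` (degrees) and `eccentricity` (degrees,
#'   `sqrt(x^2 + y^2)`), plus a `laterality` attribute.
#' @examples
#' g <- vf_grid()
#' nrow(g)                  # 68
#' max(g$eccentricity)      # sqrt(82) ~ 9.06 degrees
#' @export
vf_grid <- function(laterality = "right") {
  laterality <- match.arg(laterality, c("right", "left"))
  odd <- seq(-9L, 9L, by = 2L)
  pts <- expand.grid(x = odd, y = odd)
  pts <- pts[pts$x^2 + pts$y^2 <= 82L, ]
  # canonical order: superior rows first, temporal -> nasal within a row
  pts <- pts[order(-pts$y, pts$x), ]
  if (laterality == "left") pts$x <- -pts$x
  out <- data.frame(
    point_index = seq_len(nrow(pts)) - 1L,
    x = pts$x,
    y = pts$y,
    eccentricity = sqrt(pts$x^2 + pts$y^2)
  )
  rownames(out) <- NULL
  attr(out, "laterality") <- laterality
  class(out) <- c("vf_grid", "data.frame")
  out
}

#' Index permutation that mirrors the grid across the vertical midline
#'
#' For the canonical right-eye grid, returns the permutation `p` such that
#' point `i` maps to the point at `(-x_i, y_i)`; used to mirror sector maps
#' and to express laterality symmetry.  0-based on input and output, returned
#' as a 1-based R index vector (`p[i]` is the 1-based row of the mirror
#' partner of 1-based row `i`).
#'
#' @return Integer vector of length 68.
#' @keywords internal
grid_mirror_permutation <- function() {
  g <- vf_grid("right")
  match(paste(-g$x, g$y), paste(g$x, g$y))
}
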