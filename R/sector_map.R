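#' Construct a sector map of the 10-2 grid
#'
#' A sector map partitions the 68 canonical (right-eye) test points into
#' `K` labelled sectors.
#'
#' @param assignment Integer vector of length 68: `assignment[i]` is the
#'   sector id (1..K) of point index `i - 1`.  Sector ids must be the
#'   contiguous range `1..K` with every sector non-empty.
#' @param name Map label (e.g. `"S1"`).
#' @param laterality `"right"` (canonical) or `"left"` (a mirrored map).
#' @return Object of class `sector_map`.
#' @export
sector_map <- function(assignment, name = "custom", laterality = "right") {
  laterality <- match.arg(laterality, c("right", "left"))
  assignment <- as.integer(assignment)
  if (length(assignment) != 68L) {
    stop("sector map must assign all 68 points, got ", length(assignment))
  }
  if (any(is.na(assignment))) stop("sector map has unassigned points")
  K <- max(assignment)
  if (!setequal(unique(assignment), seq_len(K))) {
    stop("sector ids must be contiguous 1..K with no empty sector; got ids ",
         paste(sort(unique(assignment)), collapse = ","))
  }
  structure(list(name = name, assignment = assignment, K = K,
                 laterality = laterality),
            class = "sector_map")
}

#' @export
print.sector_map <- function(x, ...) {
  cat("sector_map '", x$name, "': ", x$K, " sectors over 68 points (",
      x$laterality, " eye)\n", sep = "")
  invisible(x)
}

#' Built-in sector maps
#'
#' Loads one of the two reference maps shipped with the package:
#' `"S1"`, a 24-sector concentric map for retinitis pigmentosa whose
#' mid-peripheral band of sectors straddles the horizontal midline, and
#' `"S2"`, a 29-sector glaucoma map that follows retinal-nerve-fibre-layer
#' anatomy and therefore has no sector crossing the horizontal midline.
#' Both shipped files are synthetic reconstructions that reproduce the
#' documented structural properties of the published maps (sector counts,
#' concentricity, horizontal-crossing pattern); the original point-by-point
#' figures are not redistributable, so these are labelled synthetic in the
#' data files.
#'
#' @param name `"S1"` or `"S2"`.
#' @return A [sector_map].
#' @export
builtin_sector_map <- function(name = c("S1", "S2")) {
  name <- match.arg(name)
  path <- system.file("extdata",
                      sprintf("sector_map_%s_synthetic.csv", name),
                      package = "vfsector", mustWork = TRUE)
  read_sector_map(path)
}

#' Read / write a sector map CSV
#'
#' Format: columns `point_index`, `x_deg`, `y_deg`, `sector_id`, with
#' `# key: value` header comments (`name`, `laterality`, free-form
#' `provenance`).  Coordinates must match the canonical grid of the stated
#' laterality.
#'
#' @param path CSV path.
#' @return A [sector_map] (`read_sector_map`) or `path` invisibly
#'   (`write_sector_map`).
#' @export
read_sector_map <- function(path) {
  head_lines <- readLines(path, n = 50L)
  meta <- list(name = basename(path), laterality = "right")
  for (ln in grep("^#", head_lines, value = TRUE)) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("point_index", "x_deg", "y_deg", "sector_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("map file missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(df) != 68L || !setequal(df$point_index, 0:67)) {
    stop("map must assign each of the 68 point indices exactly once (got ",
         nrow(df), " rows)")
  }
  df <- df[order(df$point_index), ]
  g <- vf_grid(meta$laterality)
  if (any(df$x_deg != g$x) || any(df$y_deg != g$y)) {
    stop("map coordinates disagree with the canonical ", meta$laterality,
         "-eye grid")
  }
  sector_map(df$sector_id, name = meta$name, laterality = meta$laterality)
}

#' @rdname read_sector_map
#' @param map A [sector_map].
#' @param provenance Free-form provenance string written as a header comment.
#' @export
write_sector_map <- function(map, path, provenance = NULL) {
  stopifnot(inherits(map, "sector_map"))
  g <- vf_grid(map$laterality)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# name: %s", map$name),
               sprintf("# laterality: %s", map$laterality)), con)
  if (!is.null(provenance)) writeLines(sprintf("# provenance: %s", provenance), con)
  writeLines("point_index,x_deg,y_deg,sector_id", con)
  writeLines(sprintf("%d,%d,%d,%d", g$point_index, g$x, g$y, map$assignment),
             con)
  invisible(path)
}

#' Structural report of a sector map
#'
#' Summarises per-sector point counts, which sectors contain points on both
#' sides of the horizontal midline (`y > 0` and `y < 0`; "crossing"
#' sectors), and per-sector eccentricity ranges.  In a map that follows
#' nerve-fibre anatomy (glaucoma) no sector crosses the midline, whereas a
#' concentric map for outer-retinal disease has a band of crossing sectors
#' along the horizontal meridian.
#'
#' @param map A [sector_map].
#' @return List with `sizes` (named integer vector), `crossing_sectors`
#'   (integer ids), and `eccentricity_range` (K x 2 matrix).
#' @export
sector_structure <- function(map) {
  stopifnot(inherits(map, "sector_map"))
  g <- vf_grid(map$laterality)
  sizes <- tabulate(map$assignment, nbins = map$K)
  names(sizes) <- seq_len(map$K)
  crossing <- which(vapply(seq_len(map$K), function(k) {
    ys <- g$y[map$assignment == k]
    any(ys > 0) && any(ys < 0)
  }, logical(1)))
  ecc <- t(vapply(seq_len(map$K), function(k) {
    range(g$eccentricity[map$assignment == k])
  }, numeric(2)))
  colnames(ecc) <- c("min", "max")
  list(sizes = sizes, crossing_sectors = as.integer(crossing),
       eccentricity_range = ecc)
}

#' Mirror a sector map to the other eye
#'
#' Composes the assignment with the x-negation permutation of the grid, so
#' a right-canonical map can be displayed or applied in left-eye point
#' order.  Mirroring twice restores the original map.
#'
#' @param map A [sector_map].
#' @return A [sector_map] of the opposite laterality with the same K.
#' @export
mirror_sector_map <- function(map) {
  stopifnot(inherits(map, "sector_map"))
  perm <- grid_mirror_permutation()
  sector_map(map$assignment[perm], name = map$name,
             laterality = if (map$laterality == "right") "left" else "right")
}

#' Convert a HOPACH main partition into a sector map
#'
#' Requires a clustering of exactly the 68 grid points.  Sectors are
#' renumbered `1..K` in reading order of their medoid's position on the
#' right-eye grid (descending y, then ascending x), giving a stable,
#' figure-like numbering.
#'
#' @param result A [hopach()] result on the 68 test points.
#' @param name Label for the new map.
#' @return A [sector_map].
#' @export
map_from_hopach <- function(result, name = "learned") {
  stopifnot(inherits(result, "hopach_result"))
  part <- result$main_partition
  if (length(part$labels) != 68L) {
    stop("expected a clustering of the 68 grid points, got ",
         length(part$labels), " items")
  }
  g <- vf_grid("right")
  med <- part$medoids
  ord <- order(-g$y[med], g$x[med])
  relabel <- match(part$labels, ord)
  sector_map(relabel, name = name, laterality = "right")
}
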