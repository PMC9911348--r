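#' Integer lattice coordinates for a square grid
#'
#' Returns all (row, col) lattice points of a `grid_side` x `grid_side`
#' grid in row-major order, 0-based. These are the spatial coordinates used
#' by the synthetic pattern libraries and simulations.
#'
#' @param grid_side side length of the grid (>= 2).
#' @return a `grid_side^2` x 2 integer matrix with columns `row`, `col`.
#' @export
make_grid_coords <- function(grid_side) {
  if (!is.numeric(grid_side) || length(grid_side) != 1 || grid_side < 2 ||
      grid_side != round(grid_side)) {
    stop("grid_side must be a single integer >= 2")
  }
  g <- as.integer(grid_side)
  coords <- cbind(
    row = rep(0:(g - 1L), each = g),
    col = rep(0:(g - 1L), times = g)
  )
  storage.mode(coords) <- "integer"
  coords
}

# The four "ggblocks" motifs on a 6x6 cell canvas, one per quadrant of the
# grid: a solid block, a horizontal bar, a vertical bar and a cross. Cells
# are scaled up so each motif fills an 18x18 quadrant at grid_side = 36.
# Versioned constant: changing these masks changes every ggblocks simulation.
.ggblocks_motifs <- local({
  motif <- function(f) {
    m <- matrix(FALSE, 6, 6)
    for (r in 0:5) for (c in 0:5) m[r + 1, c + 1] <- f(r, c)
    m
  }
  list(
    block = motif(function(r, c) r >= 1 && r <= 4 && c >= 1 && c <= 4),
    hbar  = motif(function(r, c) r >= 2 && r <= 3),
    vbar  = motif(function(r, c) c >= 2 && c <= 3),
    cross = motif(function(r, c) (r >= 2 && r <= 3 && c >= 1 && c <= 4) ||
                                 (c >= 2 && c <= 3 && r >= 1 && r <= 4))
  )
})

# Evaluate a 6x6 motif placed in one quadrant of the grid.
# quadrant: 1 = top-left, 2 = top-right, 3 = bottom-left, 4 = bottom-right.
.ggblocks_column <- function(coords, grid_side, motif, quadrant) {
  q <- grid_side / 2
  r0 <- if (quadrant %in% c(3, 4)) q else 0
  c0 <- if (quadrant %in% c(2, 4)) q else 0
  r <- coords[, 1]; c <- coords[, 2]
  inside <- r >= r0 & r < r0 + q & c >= c0 & c < c0 + q
  out <- logical(nrow(coords))
  lr <- floor((r[inside] - r0) * 6 / q)
  lc <- floor((c[inside] - c0) * 6 / q)
  out[inside] <- motif[cbind(lr + 1, lc + 1)]
  out
}

# Four overlapping axis-aligned "quilt" patches, each covering roughly 20%
# of the grid: a top band, a left band, a centred square and a bottom-right
# square. The bands overlap each other in the top-left corner; the two
# squares overlap each other. Versioned constant.
.quilt_columns <- function(coords, grid_side) {
  g <- grid_side
  r <- coords[, 1]; c <- coords[, 2]
  b  <- round(2 * g / 9)        # band thickness  (8 at g = 36)
  s3 <- round(4 * g / 9)        # centre square side (16)
  r3 <- round(g / 3)            # centre square top row (12)
  c3 <- round(5 * g / 18)       # centre square left col (10)
  r4 <- round(5 * g / 9)        # bottom-right square origin (20)
  cbind(
    top_band     = r < b,
    left_band    = c < b,
    centre_sq    = r >= r3 & r < r3 + s3 & c >= c3 & c < c3 + s3,
    bottomright  = r >= r4 & c >= r4
  )
}

#' Binary spatial pattern libraries for simulations
#'
#' Deterministic libraries of binary spatial factors on a square grid.
#' `"ggblocks"` gives four pairwise-disjoint shapes (block, horizontal bar,
#' vertical bar, cross), one per quadrant, in the style of Indian buffet
#' process features. `"quilt"` gives four axis-aligned patches that overlap
#' in space. `"both"` concatenates the two (eight columns).
#'
#' @param name one of `"ggblocks"`, `"quilt"`, `"both"`.
#' @param grid_side side length of the square grid (>= 12; default 36).
#' @return An object of class `pattern_library`: list with `name`,
#'   `grid_side`, `coords` (N x 2) and `factors` (N x T binary matrix).
#' @export
pattern_library <- function(name = c("ggblocks", "quilt", "both"), grid_side = 36) {
  name <- match.arg(name)
  if (!is.numeric(grid_side) || grid_side < 12 || grid_side %% 2 != 0) {
    stop("grid_side must be an even integer >= 12")
  }
  coords <- make_grid_coords(grid_side)
  gg <- function() {
    m <- .ggblocks_motifs
    cols <- cbind(
      block = .ggblocks_column(coords, grid_side, m$block, 1),
      hbar  = .ggblocks_column(coords, grid_side, m$hbar, 2),
      vbar  = .ggblocks_column(coords, grid_side, m$vbar, 3),
      cross = .ggblocks_column(coords, grid_side, m$cross, 4)
    )
    cols
  }
  factors <- switch(name,
    ggblocks = gg(),
    quilt = .quilt_columns(coords, grid_side),
    both = cbind(gg(), .quilt_columns(coords, grid_side))
  )
  storage.mode(factors) <- "double"
  if (any(colSums(factors) == 0)) stop("internal error: empty pattern column")
  structure(
    list(name = name, grid_side = grid_side, coords = coords, factors = factors),
    class = "pattern_library"
  )
}

#' @method print pattern_library
#' @export
print.pattern_library <- function(x, ...) {
  cat(sprintf("<pattern_library> '%s': %d locations x %d patterns (grid %dx%d)\n",
              x$name, nrow(x$factors), ncol(x$factors), x$grid_side, x$grid_side))
  cat("  active cells per pattern:", paste(colSums(x$factors), collapse = ", "), "\n")
  invisible(x)
}
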