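# Low-level grid / RNG helpers shared by the scene generator, the land-cover
# engine and the flux model.

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed, runs `expr`, and restores the caller's RNG state so
#' package functions never perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Disk offsets for a Euclidean buffer
#'
#' All integer (dy, dx) offsets whose centre-to-centre distance is at most
#' `radius_px` pixels (inclusive, matching an "up to" buffer distance).
#'
#' @param radius_px Buffer radius in pixels (may be fractional).
#' @return Two-column integer matrix of (dy, dx) offsets.
#' @keywords internal
disk_offsets <- function(radius_px) {
  r <- floor(radius_px + 1e-9)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g <- g[g$dy^2 + g$dx^2 <= radius_px^2 + 1e-9, , drop = FALSE]
  as.matrix(g)
}

#' Binary dilation of a logical matrix by a Euclidean disk
#'
#' @param m Logical matrix.
#' @param radius_px Disk radius in pixels (inclusive).
#' @return Logical matrix: TRUE where any TRUE cell of `m` lies within
#'   `radius_px` (Euclidean, pixel centres).
#' @keywords internal
dilate_disk <- function(m, radius_px) {
  offs <- disk_offsets(radius_px)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  for (k in seq_len(nrow(offs))) {
    dy <- offs[k, 1L]; dx <- offs[k, 2L]
    r_dst <- max(1L, 1L + dy):min(nr, nr + dy)
    c_dst <- max(1L, 1L + dx):min(nc, nc + dx)
    r_src <- r_dst - dy
    c_src <- c_dst - dx
    out[r_dst, c_dst] <- out[r_dst, c_dst] | m[r_src, c_src]
  }
  out
}

#' Block sums of a fine matrix over a coarse grid
#'
#' Sums `f` x `f` blocks of a fine matrix, yielding one value per coarse cell.
#'
#' @param m Numeric or logical fine matrix, dimensions multiples of `f`.
#' @param f Subdivision factor (fine pixels per coarse cell edge).
#' @return Matrix of block sums, dim = dim(m) / f.
#' @keywords internal
block_sum <- function(m, f) {
  nr <- nrow(m); nc <- ncol(m)
  stopifnot(nr %% f == 0L, nc %% f == 0L)
  ncy <- nr %/% f; ncx <- nc %/% f
  Ay <- matrix(0, nr, ncy)
  Ay[cbind(seq_len(nr), rep(seq_len(ncy), each = f))] <- 1
  Ax <- matrix(0, nc, ncx)
  Ax[cbind(seq_len(nc), rep(seq_len(ncx), each = f))] <- 1
  crossprod(Ay, m + 0) %*% Ax
}

# Coarse cells are numbered row-major: cell_id = (row - 1) * ncx + col.
cell_id_grid <- function(ncy, ncx) {
  matrix(seq_len(ncy * ncx), nrow = ncy, ncol = ncx, byrow = TRUE)
}

# Coarse cell id of every fine pixel, as a fine-sized integer matrix.
pixel_cell_ids <- function(ncy, ncx, f) {
  ids <- cell_id_grid(ncy, ncx)
  ids[rep(seq_len(ncy), each = f), rep(seq_len(ncx), each = f)]
}

#' Coarse cell centre coordinates in degrees
#'
#' Planar degree coordinates on a regular grid of `cell_deg`-sized cells with
#' origin at (0, 0); used by the circular median filters.
#'
#' @param ncy,ncx Coarse grid dimensions (rows, cols).
#' @param cell_deg Coarse cell size in degrees.
#' @return data.table with cell_id, x_deg, y_deg.
#' @keywords internal
cell_centers_deg <- function(ncy, ncx, cell_deg = 0.25) {
  g <- data.table::CJ(row = seq_len(ncy), col = seq_len(ncx))
  g[, `:=`(
    cell_id = (row - 1L) * ncx + col,
    x_deg = (col - 0.5) * cell_deg,
    y_deg = (row - 0.5) * cell_deg
  )]
  data.table::setkey(g, cell_id)
  g[, .(cell_id, x_deg, y_deg)]
}

#' Circular focal median over a cell-value field
#'
#' For each target cell, the median of `values` over the eligible cells whose
#' centre lies within `radius_deg` (planar degrees, inclusive) of the target's
#' centre. Cells with no eligible neighbour in range get NA.
#'
#' @param centers data.table from [cell_centers_deg()].
#' @param values Named numeric vector (names = cell_id) of eligible-cell
#'   values; only these cells enter the medians.
#' @param radius_deg Filter radius in degrees.
#' @return Numeric vector over all cells in `centers` (names = cell_id).
#' @keywords internal
circular_median <- function(centers, values, radius_deg) {
  src <- centers[cell_id %in% as.integer(names(values))]
  out <- rep(NA_real_, nrow(centers))
  names(out) <- centers$cell_id
  if (nrow(src) == 0L) return(out)
  v <- values[as.character(src$cell_id)]
  for (i in seq_len(nrow(centers))) {
    d2 <- (src$x_deg - centers$x_deg[i])^2 + (src$y_deg - centers$y_deg[i])^2
    sel <- d2 <= radius_deg^2 + 1e-12
    if (any(sel)) out[i] <- stats::median(v[sel])
  }
  out
}

# silence R CMD check notes for data.table NSE
utils::globalVariables(c(
  ".", "cell_id", "row", "col", "x_deg", "y_deg"
))
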