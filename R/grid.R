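#' Electrode grid geometry
#'
#' Describes a rectangular multi-electrode array. Electrodes are numbered
#' row-major from 1 (\code{n_rows * n_cols} in total) and sit on a regular
#' lattice with the given pitch, so all inter-electrode distances are
#' Euclidean center-to-center distances in micrometers.
#'
#' @param n_rows number of electrode rows (default 6).
#' @param n_cols number of electrode columns (default 10).
#' @param pitch_um center-to-center electrode spacing in micrometers
#'   (default 500).
#' @return An object of class \code{"grid_geometry"}: a list with
#'   \code{n_rows}, \code{n_cols}, \code{pitch_um}, integer
#'   \code{electrode_ids} and a \code{positions} data frame (\code{electrode},
#'   \code{row}, \code{col}, \code{x_um}, \code{y_um}).
#' @examples
#' g <- grid_geometry()
#' electrode_distance(g, 1, 2)   # one pitch apart
#' @export
grid_geometry <- function(n_rows = 6L, n_cols = 10L, pitch_um = 500) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1L, n_cols >= 1L, pitch_um > 0)
  ids <- seq_len(n_rows * n_cols)
  row <- ((ids - 1L) %/% n_cols) + 1L
  col <- ((ids - 1L) %% n_cols) + 1L
  g <- list(
    n_rows = n_rows, n_cols = n_cols, pitch_um = pitch_um,
    electrode_ids = ids,
    positions = data.frame(
      electrode = ids, row = row, col = col,
      x_um = (col - 1L) * pitch_um, y_um = (row - 1L) * pitch_um
    )
  )
  class(g) <- "grid_geometry"
  g
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("MEA grid: %d x %d electrodes, %g um pitch (%d electrodes)\n",
              x$n_rows, x$n_cols, x$pitch_um, length(x$electrode_ids)))
  invisible(x)
}

#' Pairwise electrode distances
#'
#' @param grid a \code{\link{grid_geometry}} object.
#' @return Symmetric matrix of Euclidean distances in micrometers, with
#'   dimnames equal to the electrode ids.
#' @export
electrode_distance_matrix <- function(grid) {
  stopifnot(inherits(grid, "grid_geometry"))
  xy <- as.matrix(grid$positions[, c("x_um", "y_um")])
  d <- as.matrix(stats::dist(xy))
  dimnames(d) <- list(grid$electrode_ids, grid$electrode_ids)
  d
}

#' Distance between two electrodes in micrometers
#'
#' @param grid a \code{\link{grid_geometry}} object.
#' @param a,b electrode ids.
#' @export
electrode_distance <- function(grid, a, b) {
  p <- grid$positions
  ia <- match(a, p$electrode)
  ib <- match(b, p$electrode)
  if (anyNA(ia) || anyNA(ib)) {
    bad <- c(a[is.na(ia)], b[is.na(ib)])
    stop("electrode id(s) not on grid: ", paste(bad, collapse = ", "))
  }
  sqrt((p$x_um[ia] - p$x_um[ib])^2 + (p$y_um[ia] - p$y_um[ib])^2)
}
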