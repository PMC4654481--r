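#' Build a periodic hexagonal cell lattice
#'
#' Cells are arranged row-major on a `rows x cols` grid with an axial offset
#' on every other row and periodic (toroidal) boundary conditions, so that
#' every cell has exactly six neighbours and the neighbour relation is
#' symmetric.  `rows` must be even for the periodic hex tiling to close.
#'
#' @param rows,cols Lattice dimensions; both at least 2, `rows` even.
#' @return An object of class `hex_lattice`: list with `rows`, `cols`,
#'   `n_cells` and `neighbours`, an `n_cells x 6` matrix of 1-based indices.
#' @export
#' @examples
#' lat <- build_hex_lattice(8, 8)   # the 64-cell tissue patch
#' rowSums(table(row(lat$neighbours), lat$neighbours) > 0)
build_hex_lattice <- function(rows, cols) {
  if (rows < 2 || cols < 2) stop("rows and cols must be at least 2")
  if (rows %% 2 != 0) stop("rows must be even for a periodic hex tiling")
  n <- rows * cols
  idx <- function(r, c) {
    r <- ((r - 1) %% rows) + 1
    c <- ((c - 1) %% cols) + 1
    (r - 1) * cols + c
  }
  nb <- matrix(0L, n, 6)
  for (r in seq_len(rows)) {
    # axial offset: odd rows shift left, even rows shift right
    off <- if (r %% 2 == 1) c(-1L, 0L) else c(0L, 1L)
    for (c in seq_len(cols)) {
      i <- idx(r, c)
      nb[i, ] <- c(idx(r, c - 1), idx(r, c + 1),
                   idx(r - 1, c + off[1]), idx(r - 1, c + off[2]),
                   idx(r + 1, c + off[1]), idx(r + 1, c + off[2]))
    }
  }
  if (any(apply(nb, 1, anyDuplicated) > 0))
    stop("degenerate lattice: fewer than 6 distinct neighbours per cell")
  structure(list(rows = rows, cols = cols, n_cells = n, neighbours = nb),
            class = "hex_lattice")
}

#' @export
print.hex_lattice <- function(x, ...) {
  cat("periodic hexagonal lattice:", x$rows, "x", x$cols, "=", x$n_cells,
      "cells, 6 neighbours each\n")
  invisible(x)
}

#' Delayed mean neighbour Delta level seen by one cell
#'
#' The Notch input of a cell is the arithmetic mean of its six neighbours'
#' Delta protein levels evaluated `tau_pN` minutes in the past (the Notch
#' activation delay), read off a recorded Delta history by linear
#' interpolation.
#'
#' @param lattice A [build_hex_lattice()] object.
#' @param times Sample times (min) of the Delta history, strictly increasing.
#' @param p_d Matrix of Delta protein levels, `length(times)` rows, one
#'   column per cell.
#' @param cell Cell index (1-based).
#' @param t Query time (min).
#' @param tau_pN Notch activation delay (min).
#' @return Mean neighbour Delta level at `t - tau_pN` (molecules).
#' @export
notch_input <- function(lattice, times, p_d, cell, t, tau_pN) {
  tq <- t - tau_pN
  if (tq < times[1] || tq > times[length(times)])
    stop("history does not cover the delayed query time")
  nbr <- lattice$neighbours[cell, ]
  vals <- vapply(nbr, function(j) stats::approx(times, p_d[, j], xout = tq)$y,
                 numeric(1))
  mean(vals)
}
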