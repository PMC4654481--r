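#' Simulate an ensemble of segmentation-clock cells
#'
#' Runs the hybrid stochastic-deterministic model (or its fully deterministic
#' variant) for an ensemble of cells.  mRNA and protein levels follow delay
#' differential equations integrated with a fixed-step explicit Euler scheme;
#' in the hybrid variant the occupancy of the four her1/7 gene copies per
#' cell changes through an exact delayed direct-method Gillespie sampler
#' whose propensities vary continuously between events.  In `"notch"` mode
#' cells sit on a periodic hexagonal lattice and each cell's NICD production
#' is driven by the delayed mean Delta level of its six neighbours.
#'
#' @param params A `clock_params` list from [make_default_params()], or a
#'   data.frame of per-cell parameter rows from [draw_cell_params()].  The
#'   presence of `koff` selects the hybrid variant.
#' @param n_cells Number of cells (for `"notch"` mode inferred from
#'   `lattice`).
#' @param mode `"uncoupled"` (independent cells) or `"notch"`
#'   (Delta-Notch coupling on a hexagonal lattice).
#' @param t_end Simulated time, minutes.
#' @param record_dt Output sampling interval, minutes (default 1).
#' @param init `"identical"` (all molecular counts zero, all gene copies
#'   free, history equal to the initial state for t < 0 - cells start their
#'   oscillation synchronously) or `"random"` (per-cell random molecular
#'   counts and gene occupancies, used to demonstrate Notch-driven
#'   resynchronisation).
#' @param seed Integer master seed; the same seed gives a bit-identical
#'   trajectory.  Per-cell initialisation streams are derived from it so
#'   that changing `n_cells` does not reshuffle existing cells' draws.
#' @param dt Integration step, minutes (default 0.01); must not exceed the
#'   smallest positive delay.
#' @param lattice A [build_hex_lattice()] object (required for `"notch"`).
#' @param record Which species to record: `"p_h1"` (Her1 protein only) or
#'   `"all"`.
#' @param record_genes Record the number of active her1/her7 copies per cell
#'   at each sample time (hybrid variant only)?
#' @param return_events Also return the full gene-regulatory event log?
#' @param init_occupancy Optional length-4 vector of initial occupancy
#'   states (values from [occupancy_states]) used with
#'   `init = "identical"`.
#' @param init_state Optional named numeric vector of initial molecular
#'   counts (any of `m_h1`, `m_h7`, `p_h1`, `p_h7`, `m_d`, `p_d`, `p_N`;
#'   unnamed species start at 0) used with `init = "identical"`.
#' @return An object of class `clock_trajectory`: list with `time` (minutes),
#'   `species` (named list of time-by-cell matrices, always containing
#'   `p_h1`), optionally `genes_active` (`g_h1`, `g_h7` integer matrices) and
#'   `events`, plus metadata (`mode`, `variant`, `seed`, `dt`, `record_dt`,
#'   `lattice`, `params`).
#' @export
#' @examples
#' p <- make_default_params("deterministic")
#' tr <- simulate_ensemble(p, n_cells = 1, t_end = 300, seed = 1)
#' range(tr$species$p_h1)
simulate_ensemble <- function(params, n_cells = 1,
                              mode = c("uncoupled", "notch"),
                              t_end = 700, record_dt = 1,
                              init = c("identical", "random"), seed = 1,
                              dt = 0.01, lattice = NULL, record = "p_h1",
                              record_genes = TRUE, return_events = FALSE,
                              init_occupancy = NULL, init_state = NULL) {
  mode <- match.arg(mode)
  init <- match.arg(init)
  if (t_end <= 0) stop("t_end must be positive")
  if (is.data.frame(params)) {
    n_cells <- nrow(params)
    plist <- as.list(params)
    variant <- if (!is.null(plist$koff)) "hybrid" else "deterministic"
  } else {
    plist <- unclass(params)
    variant <- attr(params, "variant")
    if (is.null(variant))
      variant <- if (!is.null(plist$koff)) "hybrid" else "deterministic"
  }
  hybrid <- variant == "hybrid"
  if (mode == "notch") {
    if (is.null(lattice))
      lattice <- infer_lattice(n_cells)
    n_cells <- lattice$n_cells
    nbr <- lattice$neighbours
  } else {
    nbr <- matrix(0L, 1, 6)
  }
  if (n_cells < 1) stop("n_cells must be >= 1")
  occ <- integer(0)
  if (!is.null(init_occupancy)) {
    init_occupancy <- match.arg(init_occupancy, occupancy_states,
                                several.ok = TRUE)
    if (length(init_occupancy) != 4)
      stop("init_occupancy must give the state of all 4 gene copies")
    occ <- match(init_occupancy, occupancy_states) - 1L
  }
  st <- numeric(0)
  if (!is.null(init_state)) {
    sp_names <- c("m_h1", "m_h7", "p_h1", "p_h7", "m_d", "p_d", "p_N")
    bad <- setdiff(names(init_state), sp_names)
    if (length(bad)) stop("unknown species in init_state: ",
                          paste(bad, collapse = ", "))
    st <- stats::setNames(numeric(7), sp_names)
    st[names(init_state)] <- init_state
  }
  raw <- cpp_simulate(plist, as.integer(n_cells), as.integer(hybrid),
                      as.integer(mode == "notch"), nbr, t_end, dt, record_dt,
                      as.integer(init == "random"), occ, st, as.integer(seed),
                      as.integer(identical(record, "all")),
                      as.integer(record_genes), as.integer(return_events))
  species <- list(p_h1 = raw$p_h1)
  for (nm in c("m_h1", "m_h7", "p_h7", "m_d", "p_d", "p_N"))
    if (!is.null(raw[[nm]])) species[[nm]] <- raw[[nm]]
  out <- list(time = raw$time, species = species,
              mode = mode, variant = variant, seed = seed, dt = dt,
              record_dt = record_dt, n_cells = n_cells,
              lattice = if (mode == "notch") lattice else NULL,
              params = plist)
  if (!is.null(raw$g_h1)) {
    # engine records per-copy activity bitmasks; expose both the mask and
    # the active-copy count
    cnt <- function(m) (m %% 2L) + (m %/% 2L)
    out$genes_active <- list(g_h1 = cnt(raw$g_h1), g_h7 = cnt(raw$g_h7),
                             g_h1_mask = raw$g_h1, g_h7_mask = raw$g_h7)
  }
  if (!is.null(raw$events))
    out$events <- as.data.frame(raw$events)
  class(out) <- "clock_trajectory"
  out
}

# 64 cells -> 8 x 8 and similar near-square even-row factorisations
infer_lattice <- function(n_cells) {
  r <- floor(sqrt(n_cells))
  while (r >= 2) {
    if (n_cells %% r == 0 && r %% 2 == 0 && n_cells / r >= 2)
      return(build_hex_lattice(r, n_cells / r))
    r <- r - 1
  }
  stop("n_cells does not tile an even-row hexagonal lattice; pass `lattice`")
}

#' @export
print.clock_trajectory <- function(x, ...) {
  cat("clock_trajectory:", x$n_cells, "cells,", x$variant, "variant,",
      x$mode, "mode\n")
  cat("  time: 0 ..", max(x$time), "min at record_dt =", x$record_dt,
      "min; species:", paste(names(x$species), collapse = ", "), "\n")
  invisible(x)
}

#' Extract one recorded observable from a trajectory
#'
#' @param traj A `clock_trajectory`.
#' @param observable Species name (e.g. `"p_h1"`) or `"g_h1"`/`"g_h7"` for
#'   active gene-copy counts.
#' @return Time-by-cell numeric matrix.
#' @export
trajectory_observable <- function(traj, observable = "p_h1") {
  if (observable %in% names(traj$species)) return(traj$species[[observable]])
  if (!is.null(traj$genes_active) &&
      observable %in% names(traj$genes_active))
    return(traj$genes_active[[observable]])
  stop("observable '", observable, "' was not recorded")
}

#' Draw event times from a time-varying total hazard
#'
#' Samples first-event times of an inhomogeneous point process whose total
#' propensity is given piecewise-linearly on a time grid, by inverting the
#' cumulative hazard at an exponential threshold (the delayed direct-method
#' rule used inside the simulator: the integral of the total propensity is
#' accumulated until it reaches `-log(u)`).
#'
#' @param times Strictly increasing time grid (min), starting at the current
#'   time.
#' @param hazard Total propensity at each grid time (per minute).
#' @param n Number of independent draws.
#' @param seed Integer seed.
#' @return Vector of `n` event times; `Inf` where the cumulative hazard over
#'   the grid never reaches the threshold.
#' @export
#' @examples
#' # constant hazard 2/min: exponential with mean 0.5 min
#' mean(sample_next_event(c(0, 100), c(2, 2), n = 1000, seed = 1))
sample_next_event <- function(times, hazard, n = 1, seed = 1) {
  cpp_sample_event_times(as.numeric(times), as.numeric(hazard),
                         as.integer(n), as.integer(seed))
}
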