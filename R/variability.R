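#' Specify inter-cellular variability for one model parameter
#'
#' Each cell of an ensemble receives its own fixed value of the target
#' parameter, drawn once at the start of the simulation.  Gaussian draws are
#' truncated by resampling (not clipping, which would create probability
#' atoms at the bounds) to the declared oscillation-preserving bounds;
#' the generalised Pareto option reproduces heavily right-skewed delay
#' distributions (mean `location + scale/(1-shape)`, variance
#' `scale^2 / ((1-shape)^2 (1-2 shape))`).
#'
#' Default truncation bounds follow the oscillation-regime limits of the
#' single-cell model: translation rate >= 4.6/min and degradation
#' rate >= 0.15/min (severe damping below), transcription delay >= 5 min
#' (damping below), and strictly positive rates elsewhere.
#'
#' @param param Name of a `clock_params` field (e.g. `"alpha_h1"`), or a
#'   vector of field names that share a single draw per cell (the her1 and
#'   her7 genes share one transcription-rate symbol, for instance).
#' @param dist `"gaussian"` or `"gpd"` (generalised Pareto).
#' @param mean,sd Gaussian parameters.
#' @param location,scale,shape Generalised Pareto parameters.
#' @param lower,upper Truncation bounds (resample-until-valid).
#' @return A `variability_spec` list.
#' @export
variability_spec <- function(param, dist = c("gaussian", "gpd"),
                             mean = NULL, sd = NULL, location = NULL,
                             scale = NULL, shape = NULL,
                             lower = NULL, upper = Inf) {
  dist <- match.arg(dist)
  if (dist == "gaussian") {
    if (is.null(mean) || is.null(sd)) stop("gaussian spec needs mean and sd")
    if (sd < 0) stop("sd must be non-negative")
  } else {
    if (is.null(location) || is.null(scale) || is.null(shape))
      stop("gpd spec needs location, scale and shape")
    if (scale <= 0) stop("scale must be positive")
  }
  if (is.null(lower)) lower <- default_lower_bound(param[1])
  structure(list(param = param, dist = dist, mean = mean, sd = sd,
                 location = location, scale = scale, shape = shape,
                 lower = lower, upper = upper),
            class = "variability_spec")
}

default_lower_bound <- function(param) {
  switch(param,
         beta_h1 = 4.6, beta_h7 = 4.6,
         lambda_mh = 0.15, lambda_ph = 0.15,
         tau_mh = 5,
         tau_ph1 = 0.1, tau_ph7 = 0.1,
         alpha_h1 = 1, alpha_h7 = 1,
         p_h6 = 1,
         0)
}

#' Generalised Pareto quantile function
#'
#' Inverse CDF `location + scale * ((1-u)^(-shape) - 1) / shape` (the
#' exponential limit is taken for `shape == 0`).
#' @param u Probabilities in `[0, 1)`.
#' @param location,scale,shape Distribution parameters.
#' @return Quantiles.
#' @export
qgpareto <- function(u, location, scale, shape) {
  if (any(u < 0 | u >= 1)) stop("u must be in [0, 1)")
  if (abs(shape) < 1e-12) location + scale * (-log1p(-u))
  else location + scale * ((1 - u)^(-shape) - 1) / shape
}

#' Moments of the generalised Pareto distribution
#' @inheritParams qgpareto
#' @return List with `mean` (finite for `shape < 1`) and `variance`
#'   (finite for `shape < 1/2`).
#' @export
gpareto_moments <- function(location, scale, shape) {
  list(mean = location + scale / (1 - shape),
       variance = scale^2 / ((1 - shape)^2 * (1 - 2 * shape)))
}

#' Draw per-cell parameter sets for an inter-cellular variability experiment
#'
#' @param base A `clock_params` list giving the values of all non-varied
#'   parameters.
#' @param specs A single [variability_spec()] or a list of them.
#' @param n_cells Number of cells.
#' @param seed Integer seed.
#' @return A data.frame with one row per cell and one column per model
#'   parameter, suitable for [simulate_ensemble()].
#' @export
#' @examples
#' base <- make_default_params("deterministic")
#' sp <- variability_spec("alpha_h1", "gaussian", mean = 33, sd = 9)
#' cp <- draw_cell_params(base, sp, n_cells = 100, seed = 1)
#' mean(cp$alpha_h1)
draw_cell_params <- function(base, specs, n_cells, seed = 1) {
  if (inherits(specs, "variability_spec")) specs <- list(specs)
  plist <- unclass(base)
  for (sp in specs)
    if (!all(sp$param %in% names(plist)))
      stop("unknown parameter: ",
           paste(setdiff(sp$param, names(plist)), collapse = ", "))
  df <- as.data.frame(lapply(plist, function(v) rep(v[1], n_cells)))
  set.seed(seed)
  for (sp in specs) {
    vals <- numeric(n_cells)
    for (i in seq_len(n_cells)) {
      repeat {
        x <- if (sp$dist == "gaussian") {
          stats::rnorm(1, sp$mean, sp$sd)
        } else {
          qgpareto(stats::runif(1), sp$location, sp$scale, sp$shape)
        }
        if (x >= sp$lower && x <= sp$upper) break
      }
      vals[i] <- x
    }
    for (nm in sp$param) df[[nm]] <- vals
  }
  attr(df, "variant") <-
    if (!is.null(plist$koff)) "hybrid" else "deterministic"
  df
}
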