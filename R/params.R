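#' Default parameter set for the segmentation-clock model
#'
#' Returns the fitted mean rate, delay and binding constants for a single
#' posterior-PSM cell.  Rates are per minute, delays in minutes, molecular
#' quantities in molecules per cell.  The `hybrid` variant carries the
#' stochastic gene-regulation constants (`koff`, `kon_rep`, `kon_nicd`); the
#' `deterministic` variant replaces them with the half-occupancy scales
#' `P0_h1`/`P0_h7` of the smooth repression function (the scales are present
#' in both variants because the delta promoter is always modelled smoothly).
#'
#' Core her1/7 values: transcription rate 33 mRNA/min (fully active gene),
#' translation rates 9.2 protein/mRNA/min, mRNA and protein turnover
#' 0.23/min, transcription delay 7 min, translation delays 1.1 min (her1)
#' and 0.7 min (her7), 100 Hes6 molecules per cell, and repressor/DNA
#' dissociation rate 1/3 per minute.  The association coefficients and the
#' Delta/Notch branch constants are calibration choices documented in the
#' methods vignette.
#'
#' @param variant `"hybrid"` (stochastic gene copies) or `"deterministic"`
#'   (smooth repression function).
#' @return A named list of class `clock_params` with attribute `variant`.
#' @export
#' @examples
#' p <- make_default_params("hybrid")
#' p$alpha_h1
make_default_params <- function(variant = c("hybrid", "deterministic")) {
  variant <- match.arg(variant)
  p <- list(
    # her1/7 autorepression loop (fitted means)
    alpha_h1 = 33, alpha_h7 = 33,
    beta_h1 = 9.2, beta_h7 = 9.2,
    lambda_mh = 0.23, lambda_ph = 0.23,
    tau_mh = 7, tau_ph1 = 1.1, tau_ph7 = 0.7,
    p_h6 = 100,
    # repression scales (used directly by the deterministic variant and by
    # the delta promoter in both variants)
    P0_h1 = 100, P0_h7 = 100, p_h6_ref = 100,
    # delta / Notch branch
    alpha_d = 33, beta_d = 9.2,
    lambda_md = 0.23, lambda_pd = 0.23,
    tau_md = 7, tau_pd = 1.1,
    k_N = 0.8, lambda_N = 0.23, tau_pN = 24,
    # stochastic gene regulation
    koff = 1 / 3,
    kon_rep = 1e-05,
    kon_nicd = 8e-05
  )
  if (variant == "deterministic") {
    p$koff <- NULL
    p$kon_rep <- NULL
    p$kon_nicd <- NULL
  }
  structure(p, class = "clock_params", variant = variant)
}

#' @export
print.clock_params <- function(x, ...) {
  cat("segmentation clock parameters (", attr(x, "variant"), " variant)\n",
      sep = "")
  df <- data.frame(parameter = names(x),
                   value = vapply(x, function(v) v[1], numeric(1)))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Print all model parameter defaults
#'
#' Convenience wrapper mirroring a `params show` command: prints both
#' variants' defaults.
#' @return Invisibly, a list with both parameter sets.
#' @export
params_show <- function() {
  h <- make_default_params("hybrid")
  d <- make_default_params("deterministic")
  print(h)
  cat("\n")
  print(d)
  invisible(list(hybrid = h, deterministic = d))
}

#' Smooth repression factor of the deterministic regulation variant
#'
#' Fraction of maximal transcription as a function of the Her1 and Her7
#' repressor levels: `1 / (1 + (p_h1/P0_h1)^2 + (p_h7*p_h6/(P0_h7*p_h6_ref))^2)`.
#' Her1 represses as a homodimer and Her7 as a heterodimer with Hes6, hence
#' the quadratic dimer-occupancy terms in a competitive-sum denominator.
#' Equals 1 with no repressor and decreases monotonically in both arguments;
#' `regulation_factor(P0_h1, 0, p)` is exactly 1/2.
#'
#' @param p_h1,p_h7 Her1 / Her7 protein copy numbers (non-negative, may be
#'   vectors).
#' @param params A `clock_params` list (needs `P0_h1`, `P0_h7`, `p_h6`,
#'   `p_h6_ref`).
#' @return Dimensionless factor in `[0, 1]`.
#' @export
regulation_factor <- function(p_h1, p_h7, params) {
  if (any(p_h1 < 0) || any(p_h7 < 0))
    stop("protein levels must be non-negative")
  a <- p_h1 / params$P0_h1
  b <- (p_h7 * params$p_h6) / (params$P0_h7 * params$p_h6_ref)
  1 / (1 + a^2 + b^2)
}

#' Gene occupancy codes
#'
#' The four her1/7 gene copies of a cell are each in exactly one occupancy
#' state: `"FREE"`, `"REP_H1"` (Her1 homodimer bound), `"REP_H7"` (Her7:Hes6
#' heterodimer pair bound) or `"NICD"` (Notch intracellular domain bound).
#' A copy is transcriptionally active iff it is `"FREE"` or `"NICD"`.
#' @format A character vector of the four state names.
#' @export
occupancy_states <- c("FREE", "REP_H1", "REP_H7", "NICD")

#' Enumerate the stochastic gene-regulation reaction channels of one cell
#'
#' For every FREE gene copy there are association channels for the Her1
#' homodimer (propensity `kon_rep * p_h1^2`), the Her7:Hes6 heterodimer pair
#' (`kon_rep * (p_h7 * p_h6 / p_h6_ref)^2`) and, in Notch mode, the NICD
#' homodimer (`kon_nicd * p_N^2`).  Every bound copy has one dissociation
#' channel with propensity `koff` regardless of what is bound.
#'
#' @param occupancy Character vector of length 4 (copies 1-2 = her1,
#'   3-4 = her7) with values from [occupancy_states].
#' @param p_h1,p_h7,p_N current protein copy numbers.
#' @param params A hybrid-variant `clock_params`.
#' @param notch Logical; include NICD association channels?
#' @return A data.frame with columns `copy`, `reaction`
#'   (`"bind_her1"`, `"bind_her7"`, `"bind_nicd"`, `"unbind"`) and
#'   `propensity` (per minute).
#' @export
reaction_channels <- function(occupancy, p_h1, p_h7, p_N = 0, params,
                              notch = FALSE) {
  occupancy <- match.arg(occupancy, occupancy_states, several.ok = TRUE)
  if (length(occupancy) != 4)
    stop("a cell has exactly 2 her1 + 2 her7 gene copies")
  r1 <- params$kon_rep * p_h1^2
  r7 <- params$kon_rep * (p_h7 * params$p_h6 / params$p_h6_ref)^2
  rN <- if (notch) params$kon_nicd * p_N^2 else NULL
  rows <- list()
  for (k in seq_len(4)) {
    if (occupancy[k] == "FREE") {
      rows[[length(rows) + 1]] <-
        data.frame(copy = k, reaction = "bind_her1", propensity = r1)
      rows[[length(rows) + 1]] <-
        data.frame(copy = k, reaction = "bind_her7", propensity = r7)
      if (notch)
        rows[[length(rows) + 1]] <-
          data.frame(copy = k, reaction = "bind_nicd", propensity = rN)
    } else {
      rows[[length(rows) + 1]] <-
        data.frame(copy = k, reaction = "unbind", propensity = params$koff)
    }
  }
  do.call(rbind, rows)
}
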