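# shared helpers: small, fast model configurations

hybrid_params <- function(koff = 1 / 3, ...) {
  p <- make_default_params("hybrid")
  p$koff <- koff
  dots <- list(...)
  for (nm in names(dots)) p[[nm]] <- dots[[nm]]
  p
}

det_params <- function(...) {
  p <- make_default_params("deterministic")
  dots <- list(...)
  for (nm in names(dots)) p[[nm]] <- dots[[nm]]
  p
}

# brute-force oracle for first-event times of an inhomogeneous process:
# exact enumeration of the fine-grid Bernoulli approximation (step dt),
# sampled by inverse CDF
bernoulli_grid_event_times <- function(times, hazard, dt, n, seed) {
  grid <- seq(times[1], times[length(times)], by = dt)
  a <- stats::approx(times, hazard, xout = grid)$y
  p_fire <- pmin(1, a * dt)
  surv <- cumprod(1 - p_fire)
  pmf <- c(p_fire[1], surv[-length(surv)] * p_fire[-1])
  set.seed(seed)
  idx <- sample.int(length(grid), n, replace = TRUE, prob = pmf)
  grid[idx] + dt * stats::runif(n)  # uniform within the firing step
}
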