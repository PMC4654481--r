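test_that("periodic hexagonal lattices are 6-regular and symmetric", {
  for (dims in list(c(8, 8), c(4, 4), c(6, 10))) {
    lat <- build_hex_lattice(dims[1], dims[2])
    expect_equal(lat$n_cells, prod(dims))
    expect_true(all(apply(lat$neighbours, 1, function(r)
      length(unique(r)) == 6)))
    A <- matrix(0L, lat$n_cells, lat$n_cells)
    for (i in seq_len(lat$n_cells)) A[i, lat$neighbours[i, ]] <- 1L
    expect_true(all(A == t(A)))
    expect_true(all(rowSums(A) == 6))
  }
  expect_error(build_hex_lattice(5, 8), "even")
  expect_error(build_hex_lattice(1, 8))
  expect_error(build_hex_lattice(2, 2))  # degenerate: duplicated neighbours
})

test_that("every cell is reachable on the lattice (connected graph)", {
  lat <- build_hex_lattice(4, 4)
  seen <- rep(FALSE, lat$n_cells)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue)) {
    i <- queue[1]
    queue <- queue[-1]
    for (j in lat$neighbours[i, ]) {
      if (!seen[j]) {
        seen[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  expect_true(all(seen))
})

test_that("notch input is the delayed mean of the six neighbours", {
  lat <- build_hex_lattice(4, 4)
  times <- 0:50
  pd <- matrix(0, length(times), lat$n_cells)
  expect_equal(notch_input(lat, times, pd, cell = 1, t = 30, tau_pN = 10), 0)
  pd[] <- 70
  expect_equal(notch_input(lat, times, pd, cell = 5, t = 30, tau_pN = 10), 70)
  nbr <- lat$neighbours[1, ]
  for (k in seq_along(nbr)) pd[, nbr[k]] <- (k - 1) * 60
  expect_equal(notch_input(lat, times, pd, cell = 1, t = 30, tau_pN = 10),
               mean(c(0, 60, 120, 180, 240, 300)))
  expect_error(notch_input(lat, times, pd, cell = 1, t = 5, tau_pN = 10),
               "cover")
})

test_that("lattice runs accept only tileable cell counts", {
  p <- hybrid_params()
  expect_error(simulate_ensemble(p, n_cells = 7, mode = "notch",
                                 t_end = 10, seed = 1), "lattice")
})
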