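test_that("simulate honors the output grid and initial condition", {
  m <- branched_model()
  tr <- simulate(m, c(3, 1, 0.5, 2), 0)
  expect_equal(nrow(tr$states), 1)
  expect_equal(unname(tr$states[1, ]), c(3, 1, 0.5, 2))

  tr <- simulate(m, c(3, 1, 0.5, 2), seq(0, 5, 0.5))
  expect_equal(tr$times, seq(0, 5, 0.5))
  expect_equal(unname(tr$states[1, ]), c(3, 1, 0.5, 2))
  expect_false(anyNA(tr$states))
  expect_error(simulate(m, c(3, 1, 0.5, 2), c(1, 0.5)),
               "strictly increasing")
})

test_that("perturbed branched model relaxes back to its steady state", {
  m <- branched_model()
  ss <- find_steady_state(m)
  tr <- simulate(m, ss$state * c(3, 1, 0.5, 2), seq(0, 30, 0.1))
  final <- tr$states[nrow(tr$states), ]
  expect_lt(max_rel_dev(final, ss$state), 1e-3)  # within 0.1% relative
  norm <- normalize(tr, ss$state)
  expect_lt(max(abs(norm$states[nrow(norm$states), ] - 1)), 1e-3)
})

test_that("steady states: Newton, relaxation and algebraic oracles agree", {
  # unit linear chain: every balance is 1 - X = 0
  lin <- builtin_fixture("linear3")
  ml <- compile_model(lin, unity_parameters(lin))
  ss <- find_steady_state(ml, c(0.3, 2, 5))
  expect_equal(unname(ss$state), c(1, 1, 1), tolerance = 1e-9)

  # branched GMA model vs elimination oracle
  m <- branched_model()
  ss <- find_steady_state(m)
  expect_lt(ss$residual, 1e-9)
  expect_lt(max_rel_dev(ss$state, branched_steady_oracle()), 1e-6)

  # U-system branched model vs closed form X1 = 0.5^0.8
  um <- unity_branched_model()
  ssu <- find_steady_state(um)
  expect_lt(max_rel_dev(ssu$state, branched_unity_steady_oracle()), 1e-6)
  expect_equal(unname(ssu$state["X1"]), 0.5^0.8, tolerance = 1e-8)

  # relaxation route agrees with Newton route
  for (model in list(m, um)) {
    nt <- find_steady_state(model)
    tr <- simulate(model, initial_state(model$network, "dependent"),
                   c(0, 200, 400))
    expect_lt(max_rel_dev(tr$states[3, ], nt$state), 1e-6)
  }

  # accumulator system has no steady state
  acc <- network_spec(
    species = list(species_decl("A")),
    fluxes = list(flux_decl("vin", products = c(A = 1))))
  expect_error(find_steady_state(compile_model(acc, unity_parameters(acc))),
               "did not converge")
})

test_that("adaptive integration matches the fixed-step RK4 oracle", {
  m <- branched_model()
  grid <- seq(0, 20, 0.5)
  tr <- simulate(m, c(3, 1, 0.5, 2), grid)
  ref <- rk4_oracle(branched_rhs_oracle, c(3, 1, 0.5, 2), grid, dt = 1e-3)
  expect_lt(max_rel_dev(tr$states, ref), 1e-5)
})

test_that("scaling all rate constants rescales time exactly", {
  m <- branched_model()
  ss <- find_steady_state(m)
  init <- ss$state * c(3, 1, 0.5, 2)
  grid <- seq(0, 10, 0.25)
  base <- simulate(m, init, grid)
  for (c_fac in c(0.1, 10)) {
    p <- m$params
    p$rate_constant <- p$rate_constant * c_fac
    mc <- compile_model(m$network, p)
    scaled <- simulate(mc, init, grid / c_fac)
    expect_lt(max_rel_dev(scaled$states, base$states), 1e-4)
  }
})

test_that("normalization divides by the reference and rejects bad input", {
  m <- branched_model()
  tr <- simulate(m, c(2, 2, 2, 2), c(0, 1))
  expect_equal(normalize(tr, rep(1, 4))$states, tr$states)
  expect_equal(unname(normalize(tr, c(2, 2, 2, 2))$states[1, ]),
               rep(1, 4))
  expect_error(normalize(tr, c(1, 0, 1, 1)), "positive")
  expect_error(normalize(tr, c(1, 1)), "length")
})

test_that("comparison scaling maps to [0,1], flags degenerates, inverts", {
  tr <- new_traj <- structure(list(
    times = seq(0, 4, 1),
    states = cbind(rise = 0:4, flat = rep(2, 5)),
    species = c("rise", "flat")), class = "usys_trajectory")
  sc <- scale_for_comparison(tr)
  expect_equal(unname(sc$states[, "rise"]), c(0, 0.25, 0.5, 0.75, 1))
  expect_true(all(sc$states[, "flat"] == 0.5))
  expect_true(sc$records$degenerate[sc$records$species == "flat"])
  back <- unscale_comparison(sc)
  expect_equal(back$states, tr$states, tolerance = 1e-12)
  expect_equal(back$times, tr$times, tolerance = 1e-12)
})

test_that("relaxation statistics capture amplitude and settling time", {
  # analytic decay 1 + e^-t toward steady state 1
  times <- seq(0, 12, 0.01)
  tr <- structure(list(times = times,
                       states = matrix(1 + exp(-times), ncol = 1,
                                       dimnames = list(NULL, "A")),
                       species = "A"), class = "usys_trajectory")
  st <- relaxation_stats(tr, c(A = 1))
  expect_equal(st$normalized_amplitude, 1)
  expect_equal(st$time_of_extremum, 0)
  expect_equal(st$time_to_band, -log(0.02), tolerance = 0.01)

  # constant trajectory at steady state: zero amplitude, already in band
  trc <- structure(list(times = c(0, 1), states = matrix(1, 2, 1,
                        dimnames = list(NULL, "A")), species = "A"),
                   class = "usys_trajectory")
  stc <- relaxation_stats(trc, c(A = 1))
  expect_equal(stc$normalized_amplitude, 0)
  expect_equal(stc$time_to_band, 0)

  # branched fixture started at the reference folds: X1 amplitude 2 at t=0
  m <- branched_model()
  ss <- find_steady_state(m)
  trb <- simulate(m, ss$state * c(3, 1, 0.5, 2), seq(0, 40, 0.05))
  stb <- relaxation_stats(trb, ss$state)
  expect_equal(stb$normalized_amplitude[stb$species == "X1"], 2,
               tolerance = 1e-8)
  expect_equal(stb$time_of_extremum[stb$species == "X1"], 0)

  # non-convergent trajectory is rejected
  trn <- structure(list(times = c(0, 1), states = matrix(c(3, 2.9), 2, 1,
                        dimnames = list(NULL, "A")), species = "A"),
                   class = "usys_trajectory")
  expect_error(relaxation_stats(trn, c(A = 1)), "not converged")
})

test_that("trajectory TSV round trip is tidy and deterministic", {
  m <- branched_model()
  tr <- simulate(m, c(3, 1, 0.5, 2), seq(0, 2, 0.5))
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_trajectory(tr, f1)
  write_trajectory(tr, f2)
  expect_identical(readLines(f1), readLines(f2))
  df <- utils::read.delim(f1)
  expect_equal(names(df), c("time", "species", "value"))
  back <- read_trajectory(f1)
  expect_equal(back$states, tr$states, tolerance = 1e-10)
})
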