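test_that("knockdown scales one flux and inverts exactly", {
  m <- branched_model()
  kd <- apply_knockdown(m, "v14", 1.0)
  expect_equal(kd$model$params, m$params)             # identity fraction

  kd <- apply_knockdown(m, "v14", 0.1)
  expect_equal(unname(kd$model$params$rate_constant["v14"]), 0.2)
  expect_equal(unname(m$params$rate_constant["v14"]), 2)  # original untouched
  restored <- invert_knockdown(kd$model, kd$record)
  expect_identical(restored$params$rate_constant, m$params$rate_constant)

  expect_error(apply_knockdown(m, "v14", 1.2), "\\[0, 1\\]")
  expect_error(apply_knockdown(m, "nope", 0.5), "unknown flux")
})

test_that("middle-flux knockdown of the unit chain shifts only the substrate", {
  # with unit influx, steady flux through the chain is 1; cutting vBC to
  # fraction f forces B to (1/f)^(1/h) = 10, C stays at 1
  lin <- builtin_fixture("linear3")
  m <- compile_model(lin, unity_parameters(lin))
  kd <- apply_knockdown(m, "vBC", 0.1)
  ss <- find_steady_state(kd$model)
  expect_equal(unname(ss$state), c(1, 10, 1), tolerance = 1e-8)
  dir_v <- predict_direction(m, kd$model)
  expect_equal(unname(dir_v), c("0", "+", "0"))
})

test_that("uptake term follows the gradient and its start time", {
  lin <- builtin_fixture("linear3")
  m <- compile_model(lin, unity_parameters(lin))
  up <- uptake_spec("A", medium_concentration = 10, permeability = 0.3,
                    start_time = 2)
  ma <- attach_uptake(m, up)
  d0 <- evaluate_derivatives(m, c(1, 1, 1))
  # before start time: no uptake
  expect_equal(evaluate_derivatives(ma, c(1, 1, 1), t = 1), d0)
  # after: + k (Cm - X)
  expect_equal(unname(evaluate_derivatives(ma, c(1, 1, 1), t = 3)["A"]),
               unname(d0["A"]) + 0.3 * 9)
  # zero gradient: term vanishes along a whole trajectory state
  expect_equal(unname(evaluate_derivatives(ma, c(10, 1, 1), t = 5)["A"]),
               unname(evaluate_derivatives(m, c(10, 1, 1))["A"]))
  expect_error(attach_uptake(m, uptake_spec("Z", 10, 0.3)), "not a dependent")
  expect_error(uptake_spec("A", 10, -1), "positive")
})

test_that("supplemented steady state solves the augmented balance", {
  # 1 + 0.3 (10 - A) - A = 0  =>  A = 4 / 1.3; downstream carries the flux
  lin <- builtin_fixture("linear3")
  m <- compile_model(lin, unity_parameters(lin))
  ma <- attach_uptake(m, uptake_spec("A", 10, 0.3))
  ss <- find_steady_state(ma)
  expect_equal(unname(ss$state["A"]), 4 / 1.3, tolerance = 1e-9)
  base <- find_steady_state(m)
  expect_gt(ss$state["A"], base$state["A"])
  # long integration oracle agrees
  tr <- simulate(ma, base$state, c(0, 100, 200))
  expect_lt(max_rel_dev(tr$states[3, ], ss$state), 1e-6)
})

test_that("medium depletion drains the reservoir symmetrically", {
  lin <- builtin_fixture("linear3")
  m <- compile_model(lin, unity_parameters(lin))
  ma <- attach_uptake(m, uptake_spec("A", 5, 0.5, medium_depletion = TRUE))
  tr <- simulate(ma, c(1, 1, 1), seq(0, 50, 1))
  med <- attr(tr, "medium")
  expect_false(is.null(med))
  # the reservoir falls toward the cell concentration
  expect_lt(med[nrow(med), "A"], 5)
  expect_lt(abs(med[nrow(med), "A"] - tr$states[nrow(tr$states), "A"]), 0.05)
})

test_that("uptake parameters are recovered from clean and noisy data", {
  lin <- builtin_fixture("linear3")
  m <- compile_model(lin, unity_parameters(lin))
  true_spec <- uptake_spec("A", 10, 0.3)
  ma <- attach_uptake(m, true_spec)
  base <- find_steady_state(m)
  times <- c(0, 2, 6, 12, 24, 36, 48, 60, 72, 84, 96)
  traj <- simulate(ma, base$state, seq(0, 96, 0.5))

  # noiseless: exact model class, near-exact recovery
  clean <- synth_observations(traj, base$state, species = "A",
                              times = times, cv_percent = 0, seed = 1)
  obs <- observed_series("A", times,
                         matrix(clean$value[clean$group == "treated"],
                                ncol = 3)[, 1, drop = FALSE])
  fit <- fit_uptake(m, obs, medium_concentration = 10)
  expect_lt(abs(fit$spec$permeability - 0.3) / 0.3, 1e-4)

  # 5% replicate noise: within 10%
  noisy <- synth_observations(traj, base$state, species = "A",
                              times = times, cv_percent = 5,
                              n_replicates = 3, seed = 7)
  tv <- noisy[noisy$group == "treated", ]
  obs_n <- observed_series("A", times,
                           matrix(tv$value, nrow = length(times)))
  fit_n <- fit_uptake(m, obs_n, medium_concentration = 10)
  expect_lt(abs(fit_n$spec$permeability - 0.3) / 0.3, 0.10)

  short <- observed_series("A", c(0, 2), matrix(c(1, 2), 2, 1))
  expect_error(fit_uptake(m, short, 10), "at least 4")
})

test_that("recovery error shrinks with replicate noise (in expectation)", {
  lin <- builtin_fixture("linear3")
  m <- compile_model(lin, unity_parameters(lin))
  ma <- attach_uptake(m, uptake_spec("A", 10, 0.3))
  base <- find_steady_state(m)
  times <- c(0, 2, 6, 12, 24, 36, 48, 60, 72, 84, 96)
  traj <- simulate(ma, base$state, seq(0, 96, 0.5))
  err_at_cv <- function(cv, seeds) {
    median(vapply(seeds, function(s) {
      d <- synth_observations(traj, base$state, species = "A",
                              times = times, cv_percent = cv,
                              n_replicates = 3, seed = s)
      tv <- d[d$group == "treated", ]
      obs <- observed_series("A", times, matrix(tv$value,
                                                nrow = length(times)))
      f <- fit_uptake(m, obs, medium_concentration = 10)
      abs(f$spec$permeability - 0.3) / 0.3
    }, numeric(1)))
  }
  seeds <- 1:8
  expect_lt(err_at_cv(0, seeds), err_at_cv(20, seeds))
})

test_that("branch adjustment recovers a known rate constant from the grid", {
  um <- unity_branched_model()
  # generate observations from the model with v14 group constant = 5
  p_true <- um$params
  p_true$rate_constant["v14"] <- 5
  m_true <- compile_model(um$network, p_true)
  ss <- find_steady_state(m_true)
  t_grid <- seq(0, 12, length.out = 101)
  traj <- simulate(m_true, ss$state * c(3, 1, 0.5, 2), t_grid)
  times <- seq(0.5, 10, length.out = 11)
  obs <- lapply(um$dependent, function(sp) {
    y <- stats::approx(traj$times, traj$states[, sp], xout = times)$y
    observed_series(sp, times, matrix(y, ncol = 1))
  })
  res <- adjust_branch_constants(um, list("v14"), obs,
                                 fold = c(3, 1, 0.5, 2), t_grid = t_grid)
  expect_equal(unname(res$best_values), 5)
  expect_equal(nrow(res$score_table), 9)   # one row per (group, value)
  # grid restricted to the identity leaves the model unchanged
  res1 <- adjust_branch_constants(um, list("v14"), obs, grid = 1,
                                  fold = c(3, 1, 0.5, 2), t_grid = t_grid)
  expect_equal(res1$model$params$rate_constant, um$params$rate_constant)
  # two groups: score table has one row per (group, value) pair
  res2 <- adjust_branch_constants(um, list("v14", "v12"), obs,
                                  grid = c(0.5, 1, 5),
                                  fold = c(3, 1, 0.5, 2), t_grid = t_grid)
  expect_equal(nrow(res2$score_table), 6)
  expect_error(adjust_branch_constants(
    um, list("v14"),
    list(observed_series("ZZ", times, matrix(1:11, ncol = 1)))),
    "overlaps")
})

test_that("direction predictions match brute-force integration signs", {
  set.seed(123)
  n_checked <- 0
  for (i in 1:12) {
    net <- random_network(n_species = sample(3:5, 1), seed = 1000 + i)
    model <- compile_model(net, unity_parameters(net))
    ss0 <- tryCatch(find_steady_state(model), error = function(e) NULL)
    if (is.null(ss0)) next
    fluxes <- names(model$params$rate_constant)
    for (fl in sample(fluxes, min(5, length(fluxes)))) {
      kd <- apply_knockdown(model, fl, 0.1)
      pred <- tryCatch(predict_direction(model, kd$model),
                       error = function(e) NULL)
      if (is.null(pred)) next
      tr <- tryCatch(simulate(kd$model, ss0$state, c(0, 500, 1000)),
                     error = function(e) NULL)
      if (is.null(tr)) next
      end <- tr$states[3, ]
      rel <- (end - ss0$state) / ss0$state
      oracle <- ifelse(abs(rel) <= 0.01, "0", ifelse(rel > 0, "+", "-"))
      expect_equal(unname(pred), unname(oracle))
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 20)
})
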