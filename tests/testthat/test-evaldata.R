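make_tidy_fixture <- function(n_sp = 2, n_rep = 3,
                              times = c(0, 2, 6, 12, 24, 36, 48, 60, 72,
                                        84, 96)) {
  rows <- expand.grid(time = times, replicate = seq_len(n_rep),
                      species = paste0("X", seq_len(n_sp)),
                      group = c("treated", "control"),
                      stringsAsFactors = FALSE)
  rows$value <- 1 + rows$time / 100 + 0.01 * rows$replicate
  rows[, c("time", "species", "replicate", "group", "value")]
}

test_that("tidy TSV loading builds one series per (species, group)", {
  df <- make_tidy_fixture()
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  series <- load_timeseries(f)
  expect_length(series, 4)   # 2 species x 2 groups
  expect_true(all(vapply(series, function(s)
    length(s$times) == 11 && ncol(s$replicate_values) == 3, logical(1))))

  # treated-only file loads fine
  f2 <- tempfile(fileext = ".tsv")
  utils::write.table(df[df$group == "treated", ], f2, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_length(load_timeseries(f2), 2)

  # duplicated (time, species, replicate, group) row is rejected
  f3 <- tempfile(fileext = ".tsv")
  utils::write.table(rbind(df, df[1, ]), f3, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(load_timeseries(f3), "duplicated")

  # missing column is named
  f4 <- tempfile(fileext = ".tsv")
  utils::write.table(df[, -4], f4, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(load_timeseries(f4), "group")
})

test_that("relative concentration is treated minus control on shared times", {
  t1 <- observed_series("X1", c(0, 2, 6), matrix(5, 3, 3))
  c1 <- observed_series("X1", c(0, 2, 6), matrix(2, 3, 3), group = "control")
  rel <- relative_concentration(t1, c1)
  expect_equal(rel$values, rep(3, 3))
  expect_equal(relative_concentration(t1, t1)$values, rep(0, 3))
  c2 <- observed_series("X1", c(10, 20, 30), matrix(2, 3, 3),
                        group = "control")
  expect_error(relative_concentration(t1, c2), "shared time")
  t2 <- observed_series("X2", c(0, 2, 6), matrix(5, 3, 3))
  expect_error(relative_concentration(t2, c1), "different species")
})

test_that("CV flags use sample sd and a strict threshold", {
  s <- observed_series("X1", c(0, 1, 2),
                       rbind(c(1, 1, 1), c(1, 2, 3), c(8, 10, 12)))
  expect_equal(s$cv, c(0, 50, 20), tolerance = 1e-12)
  expect_equal(cv_flags(s), c(FALSE, TRUE, FALSE))  # 20% boundary not flagged
  single <- observed_series("X1", c(0, 1), matrix(c(1, 2), 2, 1))
  expect_error(cv_flags(single), "cv undefined")
})

test_that("correlation, t statistic and p-value follow the exact transform", {
  m <- branched_model()
  ss <- find_steady_state(m)
  tr <- simulate(m, ss$state * c(3, 1, 0.5, 2), seq(0, 10, 0.1))
  times <- seq(0.5, 9.5, 1)
  y <- stats::approx(tr$times, tr$states[, "X2"], xout = times)$y
  obs <- observed_series("X2", times, matrix(y, ncol = 1))
  cr <- correlate(tr, obs)
  expect_equal(cr$r, 1.0, tolerance = 1e-12)
  expect_lt(cr$p, 1e-12)
  obs_neg <- observed_series("X2", times, matrix(-y, ncol = 1))
  expect_equal(correlate(tr, obs_neg)$r, -1.0, tolerance = 1e-12)

  obs_const <- observed_series("X2", times, matrix(1, length(times), 1))
  expect_error(correlate(tr, obs_const), "constant")

  # affine invariance (what licenses comparing arbitrary units)
  obs_aff <- observed_series("X2", times, matrix(3.7 * y + 11, ncol = 1))
  expect_equal(correlate(tr, obs_aff)$r, 1.0, tolerance = 1e-12)
})

test_that("p-values match numerical integration of the t density", {
  # oracle: two-sided tail mass of the t density, integrated numerically
  t_density <- function(x, df)
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  p_oracle <- function(tt, df)
    2 * stats::integrate(t_density, abs(tt), Inf, df = df,
                         rel.tol = 1e-13)$value
  for (n in c(5, 11, 30)) {
    for (r in c(0.3, 0.6, 0.9)) {
      tt <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
      expect_lt(abs(p - p_oracle(tt, n - 2)), 1e-10)
    }
  }
  # the reference case: r = 0.9 at n = 11
  tt <- 0.9 * sqrt(9 / (1 - 0.81))
  expect_equal(tt, 6.19, tolerance = 1e-2)
  p <- 2 * stats::pt(tt, df = 9, lower.tail = FALSE)
  expect_equal(p, 1.6e-4, tolerance = 0.05)
  expect_lt(abs(p - p_oracle(tt, 9)), 1e-10)
})

test_that("direction agreement counts matches and is symmetric", {
  a <- c("+", "-", "0", "+", "+", "-", "0")
  b <- c("+", "-", "0", "+", "+", "-", "+")
  res <- direction_agreement(a, b)
  expect_equal(res$fraction, 6 / 7)
  expect_equal(res$matches, 6)
  expect_equal(direction_agreement(b, a)$fraction, res$fraction)
  expect_equal(direction_agreement(a, a)$fraction, 1.0)
  expect_error(direction_agreement(character(0), character(0)), "non-empty")
  expect_error(direction_agreement(a, b[-1]), "length")
})

test_that("synthetic observations have the requested noise structure", {
  m <- branched_model()
  ss <- find_steady_state(m)
  tr <- simulate(m, ss$state * c(3, 1, 0.5, 2), seq(0, 96, 0.5))

  # cv = 0: treated replicates equal the simulated values exactly
  d0 <- synth_observations(tr, ss$state, cv_percent = 0, seed = 1)
  tv <- d0[d0$group == "treated" & d0$species == "X2" & d0$replicate == 1, ]
  y <- stats::approx(tr$times, tr$states[, "X2"], xout = tv$time)$y
  expect_equal(tv$value, y, tolerance = 1e-12)
  cv0 <- d0[d0$group == "control", ]
  expect_true(all(cv0$value[cv0$species == "X3"] == ss$state[["X3"]]))

  # determinism per seed, and the global RNG stream is untouched
  set.seed(500); before <- stats::runif(1)
  d1 <- synth_observations(tr, ss$state, cv_percent = 10, seed = 42)
  d2 <- synth_observations(tr, ss$state, cv_percent = 10, seed = 42)
  expect_identical(d1, d2)
  set.seed(500); expect_identical(stats::runif(1), before)

  # empirical CV approaches the requested 10% (many replicates)
  dd <- synth_observations(tr, ss$state, species = "X1",
                           times = c(0, 2, 6, 12, 24),
                           cv_percent = 10, n_replicates = 400, seed = 3)
  tvals <- dd[dd$group == "treated", ]
  emp_cv <- vapply(split(tvals$value, tvals$time), function(v)
    100 * stats::sd(v) / mean(v), numeric(1))
  expect_true(all(abs(emp_cv - 10) < 2))

  expect_error(synth_observations(tr, ss$state, species = "nope"),
               "not in trajectory")
})

test_that("model -> noisy data -> relative series -> correlation loop closes", {
  m <- branched_model()
  ss <- find_steady_state(m)
  tr <- simulate(m, ss$state * c(3, 1, 0.5, 2), seq(0, 96, 0.5))
  times <- c(0, 2, 6, 12, 24, 36, 48, 60, 72, 84, 96)

  # noiseless: relative concentration equals sim minus steady state exactly
  d0 <- synth_observations(tr, ss$state, species = "X2", times = times,
                           cv_percent = 0, seed = 1)
  f <- tempfile(fileext = ".tsv")
  write_timeseries(d0, f)
  series <- load_timeseries(f)
  groups <- vapply(series, `[[`, character(1), "group")
  rel <- relative_concentration(series[[which(groups == "treated")]],
                                series[[which(groups == "control")]])
  y <- stats::approx(tr$times, tr$states[, "X2"], xout = times)$y
  expect_equal(rel$values, y - ss$state[["X2"]], tolerance = 1e-9)

  # 10% noise, sampling the transient window: median correlation stays high
  times2 <- seq(0, 10, 1)
  rs <- vapply(1:10, function(s) {
    d <- synth_observations(tr, ss$state, species = "X1", times = times2,
                            cv_percent = 10, seed = s)
    treated <- d[d$group == "treated", ]
    obs <- observed_series("X1", times2,
                           matrix(treated$value, nrow = length(times2)))
    correlate(tr, obs)$r
  }, numeric(1))
  expect_gt(median(rs), 0.95)
})
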