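# Independent oracles: hand-coded reference equations and brute-force solvers.
# These deliberately avoid the package's compiled-model machinery.

# Reference branched-pathway right-hand side, coded term by term:
#   dX1/dt = 12 X3^-0.8 - 8 X1^0.5 - 2 X1^0.5
#   dX2/dt =  8 X1^0.5  - 3 X2^0.75
#   dX3/dt =  3 X2^0.75 - 5 X3^0.5 X4^0.2
#   dX4/dt =  2 X1^0.5  - 6 X4^0.8
branched_rhs_oracle <- function(x) {
  c(12 * x[3]^-0.8 - 8 * x[1]^0.5 - 2 * x[1]^0.5,
    8 * x[1]^0.5 - 3 * x[2]^0.75,
    3 * x[2]^0.75 - 5 * x[3]^0.5 * x[4]^0.2,
    2 * x[1]^0.5 - 6 * x[4]^0.8)
}

# Fixed-step classical RK4 over a dense grid; records states at record_times.
rk4_oracle <- function(rhs, y0, record_times, dt = 1e-3) {
  t_end <- max(record_times)
  n_steps <- ceiling(t_end / dt)
  out <- matrix(NA_real_, length(record_times), length(y0))
  y <- y0
  t <- 0
  next_rec <- 1L
  if (record_times[1] == 0) { out[1, ] <- y0; next_rec <- 2L }
  for (s in seq_len(n_steps)) {
    h <- min(dt, t_end - t)
    k1 <- rhs(y)
    k2 <- rhs(y + h / 2 * k1)
    k3 <- rhs(y + h / 2 * k2)
    k4 <- rhs(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
    while (next_rec <= length(record_times) &&
           record_times[next_rec] <= t + 1e-12) {
      out[next_rec, ] <- y   # grid chosen as a multiple of dt in callers
      next_rec <- next_rec + 1L
    }
    if (next_rec > length(record_times)) break
  }
  out
}

# Steady state of the reference branched GMA model by algebraic elimination:
# express X2, X3, X4 through X1 from the flux balances, close with the influx
# balance, and solve the single scalar equation by bisection.
branched_steady_oracle <- function() {
  x4_of <- function(x1) (2 * sqrt(x1) / 6)^(1 / 0.8)
  x2_of <- function(x1) (8 * sqrt(x1) / 3)^(1 / 0.75)
  x3_of <- function(x1) {
    x2 <- x2_of(x1); x4 <- x4_of(x1)
    (3 * x2^0.75 / (5 * x4^0.2))^2
  }
  f <- function(x1) 12 * x3_of(x1)^-0.8 - 10 * sqrt(x1)
  x1 <- uniroot(f, c(1e-6, 100), tol = 1e-14)$root
  c(X1 = x1, X2 = x2_of(x1), X3 = x3_of(x1), X4 = x4_of(x1))
}

# U-system branched steady state in closed form: X1 = X2 = X4 = 0.5^0.8,
# X3 = sqrt(X1).
branched_unity_steady_oracle <- function() {
  x1 <- 0.5^0.8
  c(X1 = x1, X2 = x1, X3 = sqrt(x1), X4 = x1)
}

# compiled model for the reference branched system with printed parameters
branched_model <- function() {
  net <- builtin_fixture("branched_gma")
  compile_model(net, attr(net, "params"))
}

unity_branched_model <- function() {
  net <- builtin_fixture("branched_topology")
  compile_model(net, unity_parameters(net))
}

max_rel_dev <- function(a, b, floor = 1e-10) {
  max(abs(a - b) / pmax(abs(b), floor))
}
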