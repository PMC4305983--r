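# Integration, steady states, normalization ----------------------------------

new_trajectory <- function(times, states, species) {
  structure(list(times = as.numeric(times),
                 states = states, species = species),
            class = "usys_trajectory")
}

#' @export
print.usys_trajectory <- function(x, ...) {
  cat("usys_trajectory: ", length(x$times), " time points x ",
      length(x$species), " species, t in [",
      format(min(x$times)), ", ", format(max(x$times)), "]\n", sep = "")
  invisible(x)
}

#' Integrate a compiled model
#'
#' Solves the balance ODEs with `deSolve::lsoda` (automatic stiff/non-stiff
#' switching), using the analytic Jacobian. Independent species are held at
#' their declared values. Attached depleting uptakes add one medium state per
#' uptake, integrated alongside and stripped from the returned trajectory
#' (kept in attribute `"medium"`).
#'
#' @param model A `usys_model`.
#' @param init Initial dependent-species vector (positive where a species
#'   carries a negative kinetic order).
#' @param t_grid Strictly increasing, non-negative output times; results are
#'   reported exactly at these points.
#' @param rtol,atol Integrator tolerances (defaults 1e-8 / 1e-10).
#' @param maxsteps Maximum internal steps between output points.
#' @return A `usys_trajectory` whose first row equals `init`.
#' @export
simulate <- function(model, init, t_grid, rtol = 1e-8, atol = 1e-10,
                     maxsteps = 50000) {
  stopifnot(inherits(model, "usys_model"))
  nd <- length(model$dependent)
  init <- full_state(model, init)[model$dependent]
  t_grid <- as.numeric(t_grid)
  if (!length(t_grid)) stop("t_grid must be non-empty", call. = FALSE)
  if (any(t_grid < 0) || is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must be strictly increasing and non-negative",
         call. = FALSE)
  if (length(t_grid) == 1L) {
    states <- matrix(init, 1, nd, dimnames = list(NULL, model$dependent))
    return(new_trajectory(t_grid, states, model$dependent))
  }
  dep_up <- Filter(function(u) isTRUE(u$medium_depletion), model$uptakes)
  n_med <- length(dep_up)
  y0 <- c(init, vapply(dep_up, `[[`, numeric(1), "medium_concentration"))
  func <- function(t, y, parms) {
    med <- if (n_med) stats::setNames(
      y[nd + seq_len(n_med)],
      vapply(dep_up, `[[`, character(1), "species")) else NULL
    d <- rhs_dependent(model, y[seq_len(nd)], t, medium = med)
    if (n_med) {
      dm <- numeric(n_med)
      for (i in seq_len(n_med)) {
        up <- dep_up[[i]]
        if (t >= up$start_time)
          dm[i] <- -up$permeability * (y[nd + i] - y[[up$species]])
      }
      d <- c(d, dm)
    }
    list(d)
  }
  jac <- if (!n_med) function(t, y, parms)
    analytic_jacobian(model, y[seq_len(nd)], t) else NULL
  out <- deSolve::lsoda(y = y0, times = t_grid, func = func, parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = maxsteps,
                        jacfunc = jac,
                        jactype = if (is.null(jac)) "fullint" else "fullusr")
  if (nrow(out) < length(t_grid) || any(!is.finite(out[, -1])))
    stop("integration failed (last valid time ",
         format(out[nrow(out), 1]), ")", call. = FALSE)
  states <- out[, 1 + seq_len(nd), drop = FALSE]
  if (any(states < -1e-9))
    stop("non-physical state: concentration below -1e-9 during integration",
         call. = FALSE)
  states[states < 0] <- 0
  colnames(states) <- model$dependent
  traj <- new_trajectory(t_grid, states, model$dependent)
  if (n_med) {
    med <- out[, 1 + nd + seq_len(n_med), drop = FALSE]
    colnames(med) <- vapply(dep_up, `[[`, character(1), "species")
    attr(traj, "medium") <- med
  }
  traj
}

#' Locate a positive steady state
#'
#' Damped Newton iteration in log-concentration space (which keeps every
#' iterate strictly positive): with z = log X, solves f(exp(z)) = 0 using the
#' analytic Jacobian, halving the step while the residual norm does not
#' decrease. If Newton stalls, falls back to relaxation: long-horizon
#' integration with doubling horizons until the residual settles, then a final
#' Newton polish.
#'
#' @param model A `usys_model`.
#' @param guess Positive starting vector (default: declared initial values).
#' @param tol Absolute residual tolerance on max |dX/dt| (default 1e-9).
#' @param max_iter Maximum Newton iterations (default 200).
#' @return A `usys_steady` list: `state` (named positive vector), `residual`,
#'   `method` ("newton" or "relaxation").
#' @export
find_steady_state <- function(model, guess = NULL, tol = 1e-9,
                              max_iter = 200) {
  stopifnot(inherits(model, "usys_model"))
  nd <- length(model$dependent)
  if (is.null(guess)) guess <- initial_state(model$network, "dependent")
  guess <- full_state(model, guess)[model$dependent]
  if (any(guess <= 0))
    stop("steady-state guess must be strictly positive", call. = FALSE)
  t_eval <- max(c(0, vapply(model$uptakes, `[[`, numeric(1), "start_time")))
  resid <- function(x) rhs_dependent(model, x, t = t_eval)

  newton <- function(x0) {
    z <- log(x0)
    f <- resid(exp(z))
    for (it in seq_len(max_iter)) {
      if (max(abs(f)) < tol)
        return(list(state = exp(z), residual = max(abs(f)), ok = TRUE))
      x <- exp(z)
      J <- analytic_jacobian(model, x, t = t_eval)
      Jz <- J * rep(x, each = nd)        # d f / d z = J diag(x)
      step <- tryCatch(solve(Jz, f), error = function(e) NULL)
      if (is.null(step)) return(list(ok = FALSE, state = exp(z)))
      lam <- 1
      repeat {
        z_new <- z - lam * step
        if (max(abs(z_new - z)) > 50) { lam <- lam / 2; next }
        f_new <- resid(exp(z_new))
        if (all(is.finite(f_new)) && max(abs(f_new)) < max(abs(f))) break
        lam <- lam / 2
        if (lam < 1e-10) return(list(ok = FALSE, state = exp(z)))
      }
      z <- z_new; f <- f_new
    }
    list(ok = FALSE, state = exp(z))
  }

  nt <- newton(guess)
  if (isTRUE(nt$ok))
    return(structure(list(state = nt$state, residual = nt$residual,
                          method = "newton"), class = "usys_steady"))
  # relaxation fallback: integrate until the system settles
  x <- guess; horizon <- 50
  for (round in 1:6) {
    traj <- tryCatch(
      simulate(model, x, c(0, horizon / 2, horizon)),
      error = function(e) NULL)
    if (is.null(traj)) break
    x_end <- pmax(traj$states[nrow(traj$states), ], 1e-300)
    if (any(x_end <= 0)) break
    r <- max(abs(resid(x_end)))
    if (r < tol)
      return(structure(list(state = x_end, residual = r,
                            method = "relaxation"), class = "usys_steady"))
    nt <- newton(x_end)
    if (isTRUE(nt$ok))
      return(structure(list(state = nt$state, residual = nt$residual,
                            method = "relaxation"), class = "usys_steady"))
    x <- x_end; horizon <- horizon * 2
  }
  stop("did not converge: no steady state found by Newton or relaxation",
       call. = FALSE)
}

#' @export
print.usys_steady <- function(x, ...) {
  cat("usys_steady (", x$method, "), residual ", format(x$residual), "\n",
      sep = "")
  print(x$state)
  invisible(x)
}

#' Normalize a trajectory by a reference state
#'
#' Divides each species column by its reference entry (typically the steady
#' state), so a trajectory at steady state normalizes to all ones.
#'
#' @param traj A `usys_trajectory`.
#' @param reference Strictly positive vector, one entry per species.
#' @return A normalized `usys_trajectory`.
#' @export
normalize <- function(traj, reference) {
  stopifnot(inherits(traj, "usys_trajectory"))
  if (length(reference) != length(traj$species))
    stop("reference length must equal the species count", call. = FALSE)
  if (any(!is.finite(reference)) || any(reference <= 0))
    stop("reference must be strictly positive", call. = FALSE)
  if (!is.null(names(reference))) reference <- reference[traj$species]
  traj$states <- sweep(traj$states, 2, reference, "/")
  traj
}

#' Min-max scale a trajectory for cross-model comparison
#'
#' Per species, values are mapped by (y - min) / (max - min) onto [0, 1]
#' (constant series map to 0.5 and are flagged degenerate), and the time axis
#' is divided by the time of maximal absolute deviation from the final value,
#' so dynamics from models with different time scales can be overlaid. Scale
#' records retain min, max and the time factor for exact inversion via
#' [unscale_comparison()].
#'
#' @param traj A `usys_trajectory` with at least two time points.
#' @return A `usys_scaled` list: `times` (time x species matrix of scaled
#'   times), `states` (scaled values), `species`, `records` (data frame with
#'   min, max, time_factor, degenerate).
#' @export
scale_for_comparison <- function(traj) {
  stopifnot(inherits(traj, "usys_trajectory"))
  if (length(traj$times) < 2)
    stop("scaling needs at least two time points", call. = FALSE)
  ns <- length(traj$species)
  nt <- length(traj$times)
  times <- matrix(0, nt, ns, dimnames = list(NULL, traj$species))
  states <- matrix(0, nt, ns, dimnames = list(NULL, traj$species))
  rec <- data.frame(species = traj$species, min = NA_real_, max = NA_real_,
                    time_factor = NA_real_, degenerate = FALSE)
  for (j in seq_len(ns)) {
    y <- traj$states[, j]
    lo <- min(y); hi <- max(y)
    dev <- abs(y - y[nt])
    tpk <- traj$times[which.max(dev)]
    tf <- if (tpk > 0) tpk else 1      # flat or end-peaked: keep time axis
    degen <- hi == lo
    states[, j] <- if (degen) rep(0.5, nt) else (y - lo) / (hi - lo)
    times[, j] <- traj$times / tf
    rec$min[j] <- lo; rec$max[j] <- hi; rec$time_factor[j] <- tf
    rec$degenerate[j] <- degen
  }
  structure(list(times = times, states = states, species = traj$species,
                 records = rec), class = "usys_scaled")
}

#' Invert a comparison scaling
#'
#' @param scaled A `usys_scaled` from [scale_for_comparison()].
#' @return The original `usys_trajectory` (exactly, up to floating round-off).
#' @export
unscale_comparison <- function(scaled) {
  stopifnot(inherits(scaled, "usys_scaled"))
  rec <- scaled$records
  nt <- nrow(scaled$states)
  states <- scaled$states
  for (j in seq_along(scaled$species)) {
    states[, j] <- if (rec$degenerate[j]) rep(rec$min[j], nt)
      else scaled$states[, j] * (rec$max[j] - rec$min[j]) + rec$min[j]
  }
  new_trajectory(scaled$times[, 1] * rec$time_factor[1], states,
                 scaled$species)
}

#' Relaxation statistics of a trajectory
#'
#' Quantifies how a perturbed system returns to steady state: per species, the
#' time and size of the largest normalized deviation |X(t)/X_ss - 1| and the
#' last time the normalized trajectory exits a +/-`band` envelope around 1.
#' Rate-constant changes mainly stretch trajectories along the time axis
#' (moving `time_to_band`), kinetic-order changes mainly rescale amplitudes.
#'
#' @param traj A `usys_trajectory` (typically already in raw concentrations).
#' @param steady Strictly positive steady-state vector.
#' @param band Convergence band half-width in normalized units (default 0.02).
#' @return Data frame: species, time_of_extremum, normalized_amplitude,
#'   time_to_band.
#' @export
relaxation_stats <- function(traj, steady, band = 0.02) {
  stopifnot(inherits(traj, "usys_trajectory"))
  if (!is.null(names(steady))) steady <- steady[traj$species]
  if (any(steady <= 0)) stop("steady must be strictly positive", call. = FALSE)
  dev <- abs(sweep(traj$states, 2, steady, "/") - 1)
  nt <- nrow(dev)
  if (any(dev[nt, ] > band))
    stop("trajectory has not converged into the +/-", band * 100,
         "% band by its end", call. = FALSE)
  out <- data.frame(species = traj$species, time_of_extremum = NA_real_,
                    normalized_amplitude = NA_real_, time_to_band = NA_real_)
  for (j in seq_along(traj$species)) {
    i <- which.max(dev[, j])
    out$time_of_extremum[j] <- traj$times[i]
    out$normalized_amplitude[j] <- dev[i, j]
    outside <- which(dev[, j] > band)
    out$time_to_band[j] <- if (length(outside))
      traj$times[max(outside)] else 0
  }
  out
}

#' Write / read a trajectory as tidy TSV
#'
#' Long format with columns time, species, value; rows time-major with species
#' in declared order, numbers at 12 significant digits for byte-stable diffs.
#'
#' @param traj A `usys_trajectory`.
#' @param path Output file path.
#' @return Invisibly `path`.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(
    time = rep(traj$times, each = length(traj$species)),
    species = rep(traj$species, times = length(traj$times)),
    value = as.vector(t(traj$states)))
  df$time <- sprintf("%.12g", df$time)
  df$value <- sprintf("%.12g", df$value)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  sp <- unique(df$species)
  times <- unique(df$time)
  states <- matrix(df$value[order(match(df$time, times),
                                  match(df$species, sp))],
                   nrow = length(times), ncol = length(sp), byrow = TRUE,
                   dimnames = list(NULL, sp))
  new_trajectory(times, states, sp)
}
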