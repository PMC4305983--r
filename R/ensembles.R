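# Monte-Carlo parameter ensembles, stability filtering, sweeps ---------------

#' Sampling ranges for Monte-Carlo ensembles
#'
#' Defaults follow the reference protocol: rate constants uniform on
#' [0.5, 20], kinetic-order magnitudes uniform on [0.2, 0.8] with sign forced
#' by role (substrate positive, inhibitor negative, activator positive),
#' 1000 draws.
#'
#' @param rate_constant_range Length-2 positive (low, high), low < high.
#' @param kinetic_order_magnitude_range Length-2 in (0, 1], low < high.
#' @param n_draws Positive integer.
#' @param seed Integer RNG seed; identical seeds give identical draws.
#' @return A `usys_ranges` list.
#' @export
sampling_ranges <- function(rate_constant_range = c(0.5, 20),
                            kinetic_order_magnitude_range = c(0.2, 0.8),
                            n_draws = 1000, seed = 1) {
  stopifnot(length(rate_constant_range) == 2,
            length(kinetic_order_magnitude_range) == 2)
  if (rate_constant_range[1] <= 0 ||
      rate_constant_range[1] >= rate_constant_range[2])
    stop("rate_constant_range must be positive with low < high",
         call. = FALSE)
  k <- kinetic_order_magnitude_range
  if (k[1] <= 0 || k[2] > 1 || k[1] >= k[2])
    stop("kinetic_order_magnitude_range must lie in (0, 1] with low < high",
         call. = FALSE)
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  structure(list(rate_constant_range = as.numeric(rate_constant_range),
                 kinetic_order_magnitude_range = as.numeric(k),
                 n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "usys_ranges")
}

# role sign per required (flux,species) pair: +1 substrate/activator,
# -1 inhibitor; combined roles take the sign of the summed unity default
order_signs <- function(net) {
  d <- required_orders(net)
  s <- sign(d)
  s[s == 0] <- 1
  s
}

#' Draw random parameter sets
#'
#' Rate constants are iid uniform in the rate-constant range; kinetic-order
#' magnitudes iid uniform in the magnitude range with the sign dictated by the
#' species' role on the flux. Reproducible: the seed in `ranges` is applied
#' locally (the global RNG stream is untouched).
#'
#' @param net A `usys_network`.
#' @param ranges A `usys_ranges`.
#' @return List of `usys_params`, length `ranges$n_draws`.
#' @export
sample_parameters <- function(net, ranges = sampling_ranges()) {
  stopifnot(inherits(net, "usys_network"), inherits(ranges, "usys_ranges"))
  fid <- flux_ids(net)
  signs <- order_signs(net)
  rcr <- ranges$rate_constant_range
  kor <- ranges$kinetic_order_magnitude_range
  with_local_seed(ranges$seed, {
    lapply(seq_len(ranges$n_draws), function(i) {
      rc <- stats::setNames(stats::runif(length(fid), rcr[1], rcr[2]), fid)
      mag <- stats::runif(length(signs), kor[1], kor[2])
      parameter_set(rc, stats::setNames(mag * signs, names(signs)))
    })
  })
}

#' Stability check by settling
#'
#' A parameter combination is kept when integration over the horizon completes
#' with finite, positive states and the end state has settled:
#' max |dX/dt| / (1 + |X|) below `tol`. This matches the observable used to
#' filter Monte-Carlo draws (runs that do not return to a steady state are
#' removed); an eigenvalue diagnostic at the end state is reported as well.
#'
#' @param model A `usys_model`.
#' @param init Initial dependent vector (default: declared initial values).
#' @param horizon Integration horizon (default 100 time units).
#' @param tol Settling tolerance on the scaled residual (default 1e-4).
#' @return List: `stable` (logical), `diagnosis` (character), `end_state`,
#'   `max_eigenvalue_real` (NA when the run failed).
#' @export
is_stable <- function(model, init = NULL, horizon = 100, tol = 1e-4) {
  stopifnot(inherits(model, "usys_model"))
  if (is.null(init)) init <- initial_state(model$network, "dependent")
  t_grid <- seq(0, horizon, length.out = 21)
  traj <- tryCatch(simulate(model, init, t_grid), error = function(e) e)
  if (inherits(traj, "error"))
    return(list(stable = FALSE,
                diagnosis = paste0("integration failed: ",
                                   conditionMessage(traj)),
                end_state = NULL, max_eigenvalue_real = NA_real_))
  x_end <- traj$states[nrow(traj$states), ]
  if (any(!is.finite(x_end)) || any(x_end < 0))
    return(list(stable = FALSE, diagnosis = "non-finite or negative state",
                end_state = x_end, max_eigenvalue_real = NA_real_))
  d <- tryCatch(evaluate_derivatives(model, x_end, t = horizon),
                error = function(e) NULL)
  if (is.null(d))
    return(list(stable = FALSE, diagnosis = "derivative undefined at end",
                end_state = x_end, max_eigenvalue_real = NA_real_))
  r <- max(abs(d) / (1 + abs(x_end)))
  eig <- if (all(x_end > 0))
    max(Re(eigen(analytic_jacobian(model, x_end, t = horizon),
                 only.values = TRUE)$values)) else NA_real_
  if (r >= tol)
    return(list(stable = FALSE, diagnosis = "no settling", end_state = x_end,
                max_eigenvalue_real = eig))
  list(stable = TRUE, diagnosis = "settled", end_state = x_end,
       max_eigenvalue_real = eig)
}

#' Run a Monte-Carlo ensemble
#'
#' For each random draw: compile the model, locate its own steady state, start
#' from the fold-initial condition relative to that steady state (the
#' reference protocol uses folds 3, 1, 0.5, 2 for the branched fixture),
#' simulate over `t_grid`, and store the trajectory normalized by the draw's
#' steady state. Draws whose steady state cannot be found, or that fail the
#' settling check, are flagged unstable (their parameters are kept for audit,
#' no trajectory is stored).
#'
#' @param net A `usys_network`.
#' @param ranges A `usys_ranges`.
#' @param init_mode Either list(type = "steady_fold", fold = numeric vector)
#'   or list(type = "absolute", values = numeric vector). A bare numeric
#'   vector is interpreted as steady-state folds.
#' @param t_grid Output time grid (default `seq(0, 10, 0.1)`).
#' @return A `usys_ensemble`: `ranges`, `draws`, `stable` (logical vector),
#'   `trajectories` (normalized; NULL where unstable), `steady_states`,
#'   `t_grid`, `species`.
#' @export
run_ensemble <- function(net, ranges = sampling_ranges(),
                         init_mode = c(3, 1, 0.5, 2),
                         t_grid = seq(0, 10, 0.1)) {
  stopifnot(inherits(net, "usys_network"))
  if (is.numeric(init_mode))
    init_mode <- list(type = "steady_fold", fold = init_mode)
  draws <- sample_parameters(net, ranges)
  nd <- n_dependent(net)
  stable <- logical(length(draws))
  trajs <- vector("list", length(draws))
  steadies <- vector("list", length(draws))
  for (i in seq_along(draws)) {
    model <- compile_model(net, draws[[i]])
    ss <- tryCatch(find_steady_state(model), error = function(e) NULL)
    if (is.null(ss)) { stable[i] <- FALSE; next }
    init <- switch(init_mode$type,
      steady_fold = {
        if (length(init_mode$fold) != nd)
          stop("fold vector length must equal the dependent species count",
               call. = FALSE)
        ss$state * init_mode$fold
      },
      absolute = init_mode$values,
      stop("unknown init_mode type '", init_mode$type, "'", call. = FALSE))
    chk <- is_stable(model, init, horizon = max(100, max(t_grid)))
    traj <- tryCatch(simulate(model, init, t_grid), error = function(e) NULL)
    if (!chk$stable || is.null(traj)) { stable[i] <- FALSE; next }
    stable[i] <- TRUE
    steadies[[i]] <- ss$state
    trajs[[i]] <- normalize(traj, ss$state)
  }
  structure(list(ranges = ranges, draws = draws, stable = stable,
                 trajectories = trajs, steady_states = steadies,
                 t_grid = t_grid,
                 species = species_ids(net)[species_kinds(net) == "dependent"]),
            class = "usys_ensemble")
}

#' @export
print.usys_ensemble <- function(x, ...) {
  cat("usys_ensemble: ", length(x$draws), " draws, ", sum(x$stable),
      " stable (", round(100 * mean(x$stable), 1), "%)\n", sep = "")
  invisible(x)
}

#' Min/max envelope of an ensemble
#'
#' @param ens A `usys_ensemble` with at least one stable draw.
#' @return List of two time x species matrices, `min` and `max`, the
#'   elementwise extremes over the stable normalized trajectories.
#' @export
envelope <- function(ens) {
  stopifnot(inherits(ens, "usys_ensemble"))
  keep <- which(ens$stable)
  if (!length(keep)) stop("no stable draws in ensemble", call. = FALSE)
  lo <- ens$trajectories[[keep[1]]]$states
  hi <- lo
  for (i in keep[-1]) {
    s <- ens$trajectories[[i]]$states
    lo <- pmin(lo, s)
    hi <- pmax(hi, s)
  }
  list(min = lo, max = hi)
}

# shared sweep machinery: run the model with a modification applied, restore
run_sweep_point <- function(net, params, fold, t_grid) {
  model <- compile_model(net, params)
  ss <- find_steady_state(model)
  traj <- simulate(model, ss$state * fold, t_grid)
  list(trajectory = normalize(traj, ss$state), steady = ss$state)
}

#' Sweep one parameter over a value grid
#'
#' For each value: the parameter is set, the steady state recomputed, the
#' fold-initial condition applied relative to the new steady state, and the
#' trajectory normalized by it. The model's own parameters are never mutated.
#'
#' @param model A `usys_model`.
#' @param target Either `list(rate_constant = "<flux>")` or
#'   `list(kinetic_order = c("<flux>", "<species>"))`.
#' @param values Numeric grid (the reference rate-constant grid is 0.5, 1, 5,
#'   10, 15, 20, 25, 50, 75, 100).
#' @param fold Fold-initial condition relative to each steady state
#'   (default c(3, 1, 0.5, 2)).
#' @param t_grid Output times.
#' @return A `usys_sweep`: `values`, `trajectories` (normalized),
#'   `steady_states`, `target`.
#' @export
sweep_parameter <- function(model, target, values,
                            fold = c(3, 1, 0.5, 2),
                            t_grid = seq(0, 10, 0.1)) {
  stopifnot(inherits(model, "usys_model"))
  params <- model$params
  if (!is.null(target$rate_constant)) {
    key <- target$rate_constant
    if (!key %in% names(params$rate_constant))
      stop("unknown flux '", key, "' in sweep target", call. = FALSE)
    setter <- function(p, v) { p$rate_constant[[key]] <- v; p }
  } else if (!is.null(target$kinetic_order)) {
    key <- ko_key(target$kinetic_order[1], target$kinetic_order[2])
    if (!key %in% names(params$kinetic_order))
      stop("unknown (flux, species) pair '", key, "' in sweep target",
           call. = FALSE)
    setter <- function(p, v) { p$kinetic_order[[key]] <- v; p }
  } else stop("target must name a rate_constant or kinetic_order",
              call. = FALSE)
  runs <- lapply(values, function(v)
    run_sweep_point(model$network, setter(params, v), fold, t_grid))
  structure(list(values = values,
                 trajectories = lapply(runs, `[[`, "trajectory"),
                 steady_states = lapply(runs, `[[`, "steady"),
                 target = target),
            class = "usys_sweep")
}

#' Sweep a group of branch-point rate constants jointly
#'
#' Sets every flux in the group to the same rate constant per grid value,
#' re-simulating each time. The reference grid for branch-point adjustment is
#' 0.005, 0.01, 0.05, 0.1, 0.5, 1, 5, 10, 50.
#'
#' @param model A `usys_model`.
#' @param flux_group Non-empty character vector of flux ids.
#' @param values Numeric grid.
#' @inheritParams sweep_parameter
#' @return A `usys_sweep` (target records the group).
#' @export
branch_sweep <- function(model, flux_group, values,
                         fold = c(3, 1, 0.5, 2), t_grid = seq(0, 10, 0.1)) {
  stopifnot(inherits(model, "usys_model"))
  if (!length(flux_group)) stop("flux_group must be non-empty", call. = FALSE)
  bad <- setdiff(flux_group, names(model$params$rate_constant))
  if (length(bad))
    stop("unknown flux id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  runs <- lapply(values, function(v) {
    p <- model$params
    p$rate_constant[flux_group] <- v
    run_sweep_point(model$network, p, fold, t_grid)
  })
  structure(list(values = values,
                 trajectories = lapply(runs, `[[`, "trajectory"),
                 steady_states = lapply(runs, `[[`, "steady"),
                 target = list(flux_group = flux_group)),
            class = "usys_sweep")
}

#' Write ensemble summary and envelope TSVs
#'
#' @param ens A `usys_ensemble`.
#' @param summary_path Path for the per-draw summary (draw index, stable flag,
#'   parameter values in wide form).
#' @param envelope_path Optional path for the envelope TSV (time, species,
#'   min, max).
#' @return Invisibly `summary_path`.
#' @export
write_ensemble <- function(ens, summary_path, envelope_path = NULL) {
  p1 <- ens$draws[[1]]
  cols <- c(names(p1$rate_constant),
            paste0("ko.", names(p1$kinetic_order)))
  mat <- t(vapply(ens$draws, function(p)
    c(p$rate_constant, p$kinetic_order), numeric(length(cols))))
  df <- data.frame(draw = seq_along(ens$draws), stable = ens$stable)
  mat_fmt <- apply(mat, 2, function(x) sprintf("%.12g", x))
  df <- cbind(df, as.data.frame(mat_fmt, stringsAsFactors = FALSE))
  names(df) <- c("draw", "stable", cols)
  utils::write.table(df, summary_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(envelope_path)) {
    env <- envelope(ens)
    out <- data.frame(
      time = rep(ens$t_grid, each = length(ens$species)),
      species = rep(ens$species, times = length(ens$t_grid)),
      min = sprintf("%.12g", as.vector(t(env$min))),
      max = sprintf("%.12g", as.vector(t(env$max))))
    utils::write.table(out, envelope_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(summary_path)
}
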