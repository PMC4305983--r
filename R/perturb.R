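# Perturbations: knockdown, diffusion uptake, branch adjustment --------------

#' In-silico knockdown of a flux
#'
#' Multiplies the flux's rate constant by the remaining fraction (0.1 models a
#' 90% reduction of the enzyme-controlled flux). The input model is untouched;
#' the returned record carries the original value, so applying then inverting
#' a knockdown restores the original parameters exactly.
#'
#' @param model A `usys_model`.
#' @param flux Flux id.
#' @param remaining_fraction Value in [0, 1]; 1 leaves the model unchanged.
#' @return List: `model` (perturbed), `record` (a `usys_perturbation`).
#' @export
apply_knockdown <- function(model, flux, remaining_fraction) {
  stopifnot(inherits(model, "usys_model"))
  if (!flux %in% names(model$params$rate_constant))
    stop("unknown flux '", flux, "'", call. = FALSE)
  if (!is.numeric(remaining_fraction) || length(remaining_fraction) != 1L ||
      remaining_fraction < 0 || remaining_fraction > 1)
    stop("remaining_fraction must be in [0, 1]", call. = FALSE)
  original <- model$params$rate_constant[[flux]]
  p <- model$params
  p$rate_constant[[flux]] <- original * remaining_fraction
  new_model <- compile_model(model$network, p)
  new_model$uptakes <- model$uptakes
  record <- structure(list(kind = "knockdown", flux = flux,
                           remaining_fraction = remaining_fraction,
                           original_rate_constant = original,
                           note = paste0(round(100 * (1 - remaining_fraction)),
                                         "% knockdown of ", flux)),
                      class = "usys_perturbation")
  list(model = new_model, record = record)
}

#' Invert a knockdown
#'
#' @param model The perturbed `usys_model`.
#' @param record The `usys_perturbation` returned by [apply_knockdown()].
#' @return The model with the original rate constant restored bit-exactly.
#' @export
invert_knockdown <- function(model, record) {
  stopifnot(inherits(record, "usys_perturbation"),
            record$kind == "knockdown")
  p <- model$params
  p$rate_constant[[record$flux]] <- record$original_rate_constant
  new_model <- compile_model(model$network, p)
  new_model$uptakes <- model$uptakes
  new_model
}

#' Specify diffusion uptake of a supplemented metabolite
#'
#' Fick's-law transport from the culture medium into the cell, reduced to a
#' linear gradient term `permeability * (medium_concentration - X)` added to
#' the species balance for t >= `start_time`. By default the medium is a
#' constant reservoir (bulk supplementation dwarfs cellular uptake); with
#' `medium_depletion = TRUE` a medium state variable is added and drained
#' symmetrically.
#'
#' @param species Dependent species id.
#' @param medium_concentration Positive medium concentration (same arbitrary
#'   units as the states).
#' @param permeability Positive rate per unit time.
#' @param start_time Supplementation time (default 0).
#' @param medium_depletion Logical (default FALSE).
#' @return A `usys_uptake` list.
#' @export
uptake_spec <- function(species, medium_concentration, permeability,
                        start_time = 0, medium_depletion = FALSE) {
  if (!is.numeric(medium_concentration) || medium_concentration <= 0)
    stop("medium_concentration must be positive", call. = FALSE)
  if (!is.numeric(permeability) || permeability <= 0)
    stop("permeability must be positive", call. = FALSE)
  structure(list(species = species,
                 medium_concentration = as.numeric(medium_concentration),
                 permeability = as.numeric(permeability),
                 start_time = as.numeric(start_time),
                 medium_depletion = isTRUE(medium_depletion)),
            class = "usys_uptake")
}

#' Attach an uptake term to a model
#'
#' @param model A `usys_model`.
#' @param spec A `usys_uptake`; its species must be dependent.
#' @return The augmented model (input untouched).
#' @export
attach_uptake <- function(model, spec) {
  stopifnot(inherits(model, "usys_model"), inherits(spec, "usys_uptake"))
  if (!spec$species %in% model$dependent)
    stop("uptake species '", spec$species,
         "' is not a dependent species of the model", call. = FALSE)
  model$uptakes[[length(model$uptakes) + 1L]] <- spec
  model
}

#' Fit uptake parameters to observed data
#'
#' Least-squares fit of the simulated supplemented-species trajectory to an
#' observed series: the model starts from its unsupplemented steady state,
#' gains the uptake term at `start_time`, and is compared at the observation
#' times. `permeability` is always fitted; `medium_concentration` optionally.
#' Minimization uses Brent (one parameter) or Nelder-Mead (two) on log-scaled
#' parameters, which keeps them positive.
#'
#' @param model A `usys_model` (without the uptake attached).
#' @param observed A `usys_obs` (see [load_timeseries()]) for the supplemented
#'   species with at least 4 time points.
#' @param medium_concentration Fixed medium concentration, or `NA` to fit it.
#' @param start_time Supplementation time (default 0).
#' @param init_permeability Starting value (default 0.1).
#' @return List: `spec` (fitted `usys_uptake`), `residual_sum_sq`,
#'   `iterations`, `converged`.
#' @export
fit_uptake <- function(model, observed, medium_concentration = NA,
                       start_time = 0, init_permeability = 0.1) {
  stopifnot(inherits(model, "usys_model"), inherits(observed, "usys_obs"))
  if (!observed$species %in% model$dependent)
    stop("observed species '", observed$species,
         "' is not in the model", call. = FALSE)
  if (length(observed$times) < 4)
    stop("fit_uptake needs at least 4 time points", call. = FALSE)
  y_obs <- observed$mean
  t_obs <- observed$times
  base_ss <- find_steady_state(model)
  t_grid <- sort(unique(c(0, t_obs)))
  fit_medium <- is.na(medium_concentration)
  objective <- function(theta) {
    perm <- exp(theta[1])
    cm <- if (fit_medium) exp(theta[2]) else medium_concentration
    m <- attach_uptake(model, uptake_spec(observed$species, cm, perm,
                                          start_time))
    traj <- tryCatch(simulate(m, base_ss$state, t_grid),
                     error = function(e) NULL)
    if (is.null(traj)) return(1e12)
    y_sim <- stats::approx(traj$times, traj$states[, observed$species],
                           xout = t_obs)$y
    sum((y_sim - y_obs)^2)
  }
  if (fit_medium) {
    start <- c(log(init_permeability), log(max(y_obs)))
    opt <- stats::optim(start, objective, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-12))
    perm <- exp(opt$par[1]); cm <- exp(opt$par[2])
    iters <- opt$counts[["function"]]
    conv <- opt$convergence == 0
    rss <- opt$value
  } else {
    opt <- stats::optimize(function(th) objective(th),
                           interval = log(c(1e-6, 1e3)), tol = 1e-12)
    perm <- exp(opt$minimum); cm <- medium_concentration
    iters <- NA_integer_
    rss <- opt$objective
    conv <- TRUE
  }
  if (!conv)
    stop("fit_uptake did not converge; best so far: permeability = ",
         format(perm), ", rss = ", format(rss), call. = FALSE)
  list(spec = uptake_spec(observed$species, cm, perm, start_time),
       residual_sum_sq = rss, iterations = iters, converged = conv)
}

#' Adjust branch-point rate constants against observed series
#'
#' The modified-U-system step: coordinate-wise (greedy, in declared group
#' order) grid search over rate-constant values for each group of branch-point
#' fluxes. For each candidate value the whole group is set to it, the model is
#' re-simulated from its steady state at the given fold-initial condition (or
#' with the attached uptakes from the steady state), and the mean Pearson
#' correlation against all observed series (matched by species) is scored;
#' the best value per group is kept. Deterministic given its inputs.
#'
#' @param model A `usys_model`.
#' @param flux_groups List of character vectors of flux ids.
#' @param observed List of `usys_obs` / `usys_relative` objects whose species
#'   occur in the model (at least one must).
#' @param grid Candidate rate constants (default the reference grid 0.005,
#'   0.01, 0.05, 0.1, 0.5, 1, 5, 10, 50).
#' @param fold Optional fold-initial condition relative to the steady state;
#'   `NULL` starts at the steady state itself (sensible when uptake terms
#'   drive the dynamics).
#' @param t_grid Simulation output times (default covers the observation
#'   span).
#' @return List: `model` (best), `best_values` (named per group),
#'   `score_table` (data frame group, value, score), `score` (final mean
#'   correlation).
#' @export
adjust_branch_constants <- function(model, flux_groups, observed,
                                    grid = c(0.005, 0.01, 0.05, 0.1, 0.5, 1,
                                             5, 10, 50),
                                    fold = NULL, t_grid = NULL) {
  stopifnot(inherits(model, "usys_model"), length(grid) >= 1)
  if (!is.list(flux_groups) || !length(flux_groups))
    stop("flux_groups must be a non-empty list of flux-id vectors",
         call. = FALSE)
  obs_species <- vapply(observed, `[[`, character(1), "species")
  usable <- obs_species %in% model$dependent
  if (!any(usable))
    stop("no observed series overlaps the model species", call. = FALSE)
  observed <- observed[usable]
  obs_species <- obs_species[usable]
  if (is.null(t_grid)) {
    t_max <- max(vapply(observed, function(o) max(o$times), numeric(1)))
    t_grid <- seq(0, t_max, length.out = 101)
  }
  score_model <- function(m) {
    ss <- tryCatch(find_steady_state(m), error = function(e) NULL)
    if (is.null(ss)) return(-Inf)
    init <- if (is.null(fold)) ss$state else ss$state * fold
    traj <- tryCatch(simulate(m, init, t_grid), error = function(e) NULL)
    if (is.null(traj)) return(-Inf)
    rs <- vapply(observed, function(o) {
      cr <- tryCatch(correlate(traj, o, o$species), error = function(e) NULL)
      if (is.null(cr)) NA_real_ else cr$r
    }, numeric(1))
    if (all(is.na(rs))) return(-Inf)
    mean(rs, na.rm = TRUE)
  }
  current <- model$params
  rows <- list()
  best_values <- numeric(length(flux_groups))
  for (gi in seq_along(flux_groups)) {
    group <- flux_groups[[gi]]
    bad <- setdiff(group, names(current$rate_constant))
    if (length(bad))
      stop("unknown flux id(s) in group ", gi, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    scores <- vapply(grid, function(v) {
      p <- current
      p$rate_constant[group] <- v
      m <- compile_model(model$network, p)
      m$uptakes <- model$uptakes
      s <- score_model(m)
      rows[[length(rows) + 1L]] <<- data.frame(
        group = gi, value = v, score = s)
      s
    }, numeric(1))
    best <- grid[which.max(scores)]
    best_values[gi] <- best
    current$rate_constant[group] <- best
  }
  best_model <- compile_model(model$network, current)
  best_model$uptakes <- model$uptakes
  list(model = best_model, best_values = best_values,
       score_table = do.call(rbind, rows),
       score = score_model(best_model))
}

#' Qualitative direction of a perturbation's steady-state shift
#'
#' Compares the steady states of a base and a perturbed model species by
#' species: relative changes within `threshold` give 0, larger ones the sign
#' of the change. The perturbed steady state is the one the system actually
#' reaches: the search is seeded by a short relaxation from the base steady
#' state, so when the perturbed system has several fixed points the
#' dynamically selected one is compared (a cold-started root search could land
#' on a branch the perturbation never visits).
#'
#' @param base,perturbed `usys_model`s over the same species.
#' @param threshold Relative-change dead band (default 0.01, i.e. 1%).
#' @return Named vector over dependent species with values "+", "-", "0".
#' @export
predict_direction <- function(base, perturbed, threshold = 0.01) {
  stopifnot(inherits(base, "usys_model"), inherits(perturbed, "usys_model"))
  if (!identical(base$dependent, perturbed$dependent))
    stop("models do not share the same dependent species", call. = FALSE)
  ss0 <- find_steady_state(base)$state
  guess <- tryCatch({
    tr <- simulate(perturbed, ss0, c(0, 100, 200))
    x_end <- pmax(tr$states[3, ], 1e-12)
    r <- max(abs(evaluate_derivatives(perturbed, x_end, t = 200)) /
               (1 + abs(x_end)))
    if (r >= 1e-4)
      stop("perturbed system does not settle to a steady state",
           call. = FALSE)
    x_end
  }, error = function(e)
    stop("steady state not found for the perturbed model: ",
         conditionMessage(e), call. = FALSE))
  ss1 <- find_steady_state(perturbed, guess)$state
  rel <- (ss1 - ss0) / ss0
  out <- ifelse(abs(rel) <= threshold, "0", ifelse(rel > 0, "+", "-"))
  stats::setNames(out, base$dependent)
}
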