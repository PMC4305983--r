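# GMA parameterization and model compilation ---------------------------------

ko_key <- function(flux, species) paste0(flux, ":", species)

#' Construct a parameter set
#'
#' A GMA model is parameterized flux-centrically: one positive rate constant
#' per flux (the alpha/beta of the balance equations; a conversion flux shares
#' its term between the producer and consumer equations, which enforces mass
#' consistency automatically) and one real kinetic order per (flux, species)
#' pair where the species is a substrate or regulation effector of that flux.
#'
#' @param rate_constant Named numeric vector, names = flux ids, values > 0.
#' @param kinetic_order Named numeric vector, names `"flux:species"`.
#' @return A `usys_params` object.
#' @export
parameter_set <- function(rate_constant, kinetic_order = numeric(0)) {
  if (length(rate_constant) && (is.null(names(rate_constant)) ||
                                any(!nzchar(names(rate_constant)))))
    stop("rate_constant must be a named vector", call. = FALSE)
  if (any(!is.finite(rate_constant)) || any(rate_constant <= 0))
    stop("rate constants must be positive and finite", call. = FALSE)
  if (length(kinetic_order) && (is.null(names(kinetic_order)) ||
                                any(!grepl(":", names(kinetic_order)))))
    stop("kinetic_order names must have the form 'flux:species'",
         call. = FALSE)
  structure(list(rate_constant = rate_constant,
                 kinetic_order = kinetic_order),
            class = "usys_params")
}

#' @export
print.usys_params <- function(x, ...) {
  cat("usys_params: ", length(x$rate_constant), " rate constants, ",
      length(x$kinetic_order), " kinetic orders\n", sep = "")
  invisible(x)
}

#' Serialize / parse a parameter set as JSON
#'
#' @param params A `usys_params`.
#' @param path Optional output path.
#' @return `write_parameters`: the JSON string (invisibly);
#'   `parse_parameters`: a `usys_params`.
#' @export
write_parameters <- function(params, path = NULL) {
  rc <- params$rate_constant[order(names(params$rate_constant))]
  ko <- params$kinetic_order[order(names(params$kinetic_order))]
  json <- jsonlite::toJSON(list(rate_constant = as.list(rc),
                                kinetic_order = as.list(ko)),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) writeLines(json, path)
  invisible(as.character(json))
}

#' @rdname write_parameters
#' @param path_or_text File path or JSON string.
#' @export
parse_parameters <- function(path_or_text) {
  doc <- jsonlite::fromJSON(path_or_text, simplifyVector = TRUE)
  parameter_set(rate_constant = unlist(doc$rate_constant),
                kinetic_order = if (length(doc$kinetic_order))
                  unlist(doc$kinetic_order) else numeric(0))
}

# the (flux, species) pairs that require a kinetic order, with default values
# under the unity convention; a substrate that also regulates the same flux
# gets a single combined exponent (orders add)
required_orders <- function(net) {
  keys <- character(0); vals <- numeric(0)
  for (fl in net$fluxes) {
    acc <- numeric(0)
    for (s in names(fl$substrates))
      acc[s] <- (if (s %in% names(acc)) acc[[s]] else 0) + 1
    for (r in fl$regulations) {
      d <- if (r$sign == "inhibition") -0.5 else 0.5
      acc[r$effector] <- (if (r$effector %in% names(acc))
        acc[[r$effector]] else 0) + d
    }
    if (length(acc)) {
      keys <- c(keys, ko_key(fl$id, names(acc)))
      vals <- c(vals, unname(acc))
    }
  }
  stats::setNames(vals, keys)
}

#' Unity-convention (U-system) parameters for a network
#'
#' Lays down the structure-only parameterization: every rate constant 1, every
#' substrate kinetic order 1, inhibitor orders -0.5, activator orders +0.5
#' (for independent effectors the same convention applies). A species that is
#' both substrate and regulator of one flux carries the algebraic sum as a
#' single exponent. Overrides, if supplied, replace matching entries after the
#' defaults are laid down.
#'
#' @param net A `usys_network`.
#' @param overrides Optional partial `usys_params` (or list with elements
#'   `rate_constant`, `kinetic_order`) replacing individual defaults.
#' @return A complete `usys_params`.
#' @export
unity_parameters <- function(net, overrides = NULL) {
  rc <- stats::setNames(rep(1, length(net$fluxes)), flux_ids(net))
  ko <- required_orders(net)
  if (!is.null(overrides)) {
    orc <- overrides$rate_constant
    oko <- overrides$kinetic_order
    if (length(orc)) {
      bad <- setdiff(names(orc), names(rc))
      if (length(bad))
        stop("rate-constant override for unknown flux: ",
             paste(bad, collapse = ", "), call. = FALSE)
      rc[names(orc)] <- orc
    }
    if (length(oko)) {
      bad <- setdiff(names(oko), names(ko))
      if (length(bad))
        stop("kinetic-order override for unknown (flux, species) pair: ",
             paste(bad, collapse = ", "), call. = FALSE)
      ko[names(oko)] <- oko
    }
  }
  parameter_set(rc, ko)
}

#' Compile a network and parameters into an executable GMA model
#'
#' Builds the signed stoichiometric matrix (dependent species x fluxes) and a
#' per-flux exponent table, giving the balance equations
#' \deqn{dX_i/dt = \sum_k S_{ik}\, \alpha_k \prod_j X_j^{f_{kj}}}
#' where the product ranges over all species (dependent and independent) with a
#' declared kinetic order on flux k. Independent species enter flux terms but
#' have no balance row.
#'
#' @param net A `usys_network`.
#' @param params A `usys_params` covering every flux and exactly the required
#'   (flux, species) pairs.
#' @return A `usys_model`.
#' @export
compile_model <- function(net, params) {
  stopifnot(inherits(net, "usys_network"), inherits(params, "usys_params"))
  sid <- species_ids(net)
  fid <- flux_ids(net)
  kinds <- species_kinds(net)
  dep <- sid[kinds == "dependent"]
  miss <- setdiff(fid, names(params$rate_constant))
  if (length(miss))
    stop("missing rate constant for flux: ", paste(miss, collapse = ", "),
         call. = FALSE)
  req <- required_orders(net)
  miss <- setdiff(names(req), names(params$kinetic_order))
  if (length(miss))
    stop("missing kinetic order for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(params$kinetic_order), names(req))
  if (length(extra))
    stop("kinetic order given for pairs not in the network: ",
         paste(extra, collapse = ", "), call. = FALSE)

  nf <- length(fid); ns <- length(sid); nd <- length(dep)
  S <- matrix(0, nd, nf, dimnames = list(dep, fid))
  E <- matrix(0, nf, ns, dimnames = list(fid, sid))
  for (k in seq_along(net$fluxes)) {
    fl <- net$fluxes[[k]]
    for (s in names(fl$substrates))
      if (s %in% dep) S[s, k] <- S[s, k] - fl$substrates[[s]]
    for (s in names(fl$products))
      if (s %in% dep) S[s, k] <- S[s, k] + fl$products[[s]]
  }
  for (key in names(params$kinetic_order)) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    E[parts[1], parts[2]] <- params$kinetic_order[[key]]
  }
  structure(list(
    network = net, params = params,
    stoichiometry = S, exponents = E,
    rate = stats::setNames(as.numeric(params$rate_constant[fid]), fid),
    species = sid, dependent = dep,
    independent = sid[kinds == "independent"],
    independent_values = initial_state(net, "independent"),
    uptakes = list()
  ), class = "usys_model")
}

#' @export
print.usys_model <- function(x, ...) {
  cat("usys_model: ", length(x$dependent), " dependent species, ",
      length(x$independent), " independent, ", length(x$rate), " fluxes",
      if (length(x$uptakes)) paste0(", ", length(x$uptakes), " uptake term(s)")
      else "", "\n", sep = "")
  invisible(x)
}

# full species state (dependent values merged with stored independent values)
full_state <- function(model, state) {
  x <- stats::setNames(numeric(length(model$species)), model$species)
  if (length(model$independent))
    x[model$independent] <- model$independent_values
  if (!is.null(names(state)) && all(names(state) %in% model$species)) {
    x[names(state)] <- state
  } else {
    if (length(state) == length(model$dependent)) {
      x[model$dependent] <- state
    } else if (length(state) == length(model$species)) {
      x[] <- state
    } else stop("state length matches neither the dependent nor the full ",
                "species vector", call. = FALSE)
  }
  x
}

#' Evaluate the power-law flux vector
#'
#' \eqn{v_k = \alpha_k \prod_j X_j^{f_{kj}}}. A zero concentration is legal
#' only where its exponent is non-negative (0^positive = 0); a zero state with
#' a negative exponent is a domain error.
#'
#' @param model A `usys_model`.
#' @param state Dependent-species vector (declared order or named) or full
#'   species vector.
#' @return Named numeric flux vector, in flux declaration order.
#' @export
evaluate_fluxes <- function(model, state) {
  x <- full_state(model, state)
  if (any(!is.finite(x)) || any(x < 0))
    stop("state must be finite and non-negative", call. = FALSE)
  E <- model$exponents
  if (any(x == 0)) {
    zero <- which(x == 0)
    if (any(E[, zero, drop = FALSE] < 0))
      stop("domain error: zero concentration raised to a negative ",
           "kinetic order", call. = FALSE)
    v <- model$rate
    for (k in seq_len(nrow(E))) {
      nz <- which(E[k, ] != 0)
      v[k] <- v[k] * prod(x[nz]^E[k, nz])
    }
    return(v)
  }
  v <- as.vector(model$rate * exp(E %*% log(x)))
  stats::setNames(v, rownames(E))
}

# internal RHS over dependent states; medium: named vector of medium
# concentrations for depleting uptakes (NULL = use spec values)
rhs_dependent <- function(model, state, t = 0, medium = NULL) {
  v <- evaluate_fluxes(model, state)
  d <- as.vector(model$stoichiometry %*% v)
  names(d) <- model$dependent
  for (up in model$uptakes) {
    if (t < up$start_time) next
    cm <- if (!is.null(medium) && up$medium_depletion)
      medium[[up$species]] else up$medium_concentration
    xs <- full_state(model, state)[[up$species]]
    d[up$species] <- d[up$species] + up$permeability * (cm - xs)
  }
  d
}

#' Evaluate the balance-equation derivatives
#'
#' Returns \eqn{dX/dt} for the dependent species: the stoichiometric matrix
#' times the flux vector, plus any attached diffusion-uptake terms active at
#' time `t` (the bare GMA system is autonomous; `t` is accepted for interface
#' uniformity).
#'
#' @inheritParams evaluate_fluxes
#' @param t Time (used only by uptake terms with a start time).
#' @return Named derivative vector over dependent species.
#' @export
evaluate_derivatives <- function(model, state, t = 0) {
  rhs_dependent(model, state, t)
}

#' Analytic Jacobian of the GMA right-hand side
#'
#' Entry (i, j) = sum_k S_ik v_k f_kj / X_j over dependent species j; requires
#' a strictly positive state. Attached uptake terms active at `t` contribute
#' -permeability on the diagonal (constant-reservoir form).
#'
#' @inheritParams evaluate_derivatives
#' @return Dense n_dependent x n_dependent matrix.
#' @export
analytic_jacobian <- function(model, state, t = 0) {
  x <- full_state(model, state)
  if (any(x <= 0))
    stop("analytic_jacobian requires a strictly positive state",
         call. = FALSE)
  v <- evaluate_fluxes(model, x)
  Ed <- model$exponents[, model$dependent, drop = FALSE]
  # d v_k / d X_j = v_k * E_kj / X_j
  dv <- (v * Ed) %*% diag(1 / x[model$dependent],
                          nrow = length(model$dependent))
  J <- model$stoichiometry %*% dv
  dimnames(J) <- list(model$dependent, model$dependent)
  for (up in model$uptakes) {
    if (t < up$start_time) next
    J[up$species, up$species] <- J[up$species, up$species] - up$permeability
  }
  J
}
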