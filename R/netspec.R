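# Network specification: species, fluxes, regulations ------------------------

ID_RE <- "^[A-Za-z][A-Za-z0-9_]*$"

#' Declare a species
#'
#' A species is either a dependent variable (a metabolite concentration that is
#' integrated over time) or an independent variable (an external substrate or
#' enzyme activity held constant during simulation).
#'
#' @param id Short unique token matching `[A-Za-z][A-Za-z0-9_]*` (case
#'   sensitive).
#' @param kind `"dependent"` or `"independent"`.
#' @param name Free-text label; defaults to `id`.
#' @param initial_value Non-negative concentration in arbitrary units
#'   (default 1).
#' @return A `usys_species` list.
#' @export
species_decl <- function(id, kind = c("dependent", "independent"),
                         name = id, initial_value = 1.0) {
  kind <- match.arg(kind)
  if (!is.character(id) || length(id) != 1L || !grepl(ID_RE, id))
    stop("species id must be a single token matching ", ID_RE, call. = FALSE)
  if (!is.numeric(initial_value) || length(initial_value) != 1L ||
      is.na(initial_value) || initial_value < 0)
    stop("initial_value must be a single non-negative number", call. = FALSE)
  structure(list(id = id, name = as.character(name), kind = kind,
                 initial_value = as.numeric(initial_value)),
            class = "usys_species")
}

#' Declare a regulation
#'
#' A signed regulatory modifier on a flux: the effector species enters the
#' power-law flux term with a negative kinetic order (inhibition) or a positive
#' one (activation).
#'
#' @param effector Species id of the modifier.
#' @param sign `"inhibition"` or `"activation"`.
#' @return A `usys_regulation` list.
#' @export
regulation_decl <- function(effector, sign = c("inhibition", "activation")) {
  sign <- match.arg(sign)
  if (!is.character(effector) || length(effector) != 1L || !grepl(ID_RE, effector))
    stop("effector must be a single species id token", call. = FALSE)
  structure(list(effector = effector, sign = sign), class = "usys_regulation")
}

#' Declare a flux
#'
#' One power-law process term. Substrates and products carry integer
#' stoichiometric coefficients (>= 1). A flux with no substrates and no
#' regulations is a constant influx of magnitude equal to its rate constant;
#' a flux with no products is a drain.
#'
#' @param id Short unique token.
#' @param substrates,products Named integer vectors (`c(X1 = 1)`), or `NULL`.
#' @param regulations List of [regulation_decl()] objects.
#' @return A `usys_flux` list.
#' @export
flux_decl <- function(id, substrates = NULL, products = NULL,
                      regulations = list()) {
  if (!is.character(id) || length(id) != 1L || !grepl(ID_RE, id))
    stop("flux id must be a single token matching ", ID_RE, call. = FALSE)
  chk_side <- function(x, what) {
    if (is.null(x) || length(x) == 0L) return(numeric(0))
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop(what, " of flux '", id, "' must be a named vector", call. = FALSE)
    if (any(x < 1) || any(x != round(x)))
      stop("stoichiometric coefficients of flux '", id,
           "' must be integers >= 1", call. = FALSE)
    stats::setNames(as.numeric(x), names(x))
  }
  substrates <- chk_side(substrates, "substrates")
  products <- chk_side(products, "products")
  if (length(intersect(names(substrates), names(products))))
    stop("flux '", id, "': substrates and products must be disjoint",
         call. = FALSE)
  if (!is.list(regulations) ||
      !all(vapply(regulations, inherits, logical(1), "usys_regulation")))
    stop("regulations must be a list of regulation_decl objects", call. = FALSE)
  structure(list(id = id, substrates = substrates, products = products,
                 regulations = regulations),
            class = "usys_flux")
}

#' Assemble a network specification
#'
#' @param species List of [species_decl()] objects (declaration order defines
#'   the state-vector order).
#' @param fluxes List of [flux_decl()] objects (declaration order defines the
#'   flux-vector order).
#' @param metadata Named list of free-form annotations.
#' @param check If `TRUE` (default) raise an error on any validation finding of
#'   severity "error".
#' @return A `usys_network` object.
#' @export
network_spec <- function(species, fluxes, metadata = list(), check = TRUE) {
  if (!is.list(species) ||
      !all(vapply(species, inherits, logical(1), "usys_species")))
    stop("species must be a list of species_decl objects", call. = FALSE)
  if (!is.list(fluxes) ||
      !all(vapply(fluxes, inherits, logical(1), "usys_flux")))
    stop("fluxes must be a list of flux_decl objects", call. = FALSE)
  net <- structure(list(species = species, fluxes = fluxes,
                        metadata = metadata),
                   class = "usys_network")
  if (check) {
    f <- validate_network(net)
    errs <- f[vapply(f, function(x) x$severity == "error", logical(1))]
    if (length(errs))
      stop("invalid network: ",
           paste(vapply(errs, `[[`, character(1), "message"), collapse = "; "),
           call. = FALSE)
  }
  net
}

species_ids <- function(net) vapply(net$species, `[[`, character(1), "id")
flux_ids <- function(net) vapply(net$fluxes, `[[`, character(1), "id")
species_kinds <- function(net) vapply(net$species, `[[`, character(1), "kind")

#' Number of dependent species
#' @param net A `usys_network`.
#' @return Integer count.
#' @export
n_dependent <- function(net) sum(species_kinds(net) == "dependent")

#' Initial state of a network
#'
#' @param net A `usys_network`.
#' @param which `"all"`, `"dependent"` or `"independent"`.
#' @return Named numeric vector of declared initial values.
#' @export
initial_state <- function(net, which = c("all", "dependent", "independent")) {
  which <- match.arg(which)
  v <- stats::setNames(vapply(net$species, `[[`, numeric(1), "initial_value"),
                       species_ids(net))
  if (which == "all") v
  else v[species_kinds(net) == which]
}

#' Validate a network specification
#'
#' Checks referential integrity and structural sanity. Findings are returned,
#' never raised: each is a list with `severity` ("error" or "warning"),
#' `message`, and `where`.
#'
#' Errors: duplicate species or flux ids, malformed ids, references to
#' undeclared species, negative initial values, empty species/flux lists.
#' Warnings: a dependent species with an influx but no efflux (a pure
#' accumulator, which cannot reach steady state under positive influx).
#'
#' @param net A `usys_network`.
#' @return A list of findings; empty when the network is fully valid.
#' @export
validate_network <- function(net) {
  findings <- list()
  add <- function(severity, message, where = NA_character_) {
    findings[[length(findings) + 1L]] <<-
      list(severity = severity, message = message, where = where)
  }
  sid <- species_ids(net)
  fid <- flux_ids(net)
  if (length(net$species) == 0L) add("error", "no species declared")
  if (length(net$fluxes) == 0L) add("error", "no fluxes declared")
  if (anyDuplicated(sid))
    add("error", paste0("duplicate species id(s): ",
                        paste(unique(sid[duplicated(sid)]), collapse = ", ")))
  if (anyDuplicated(fid))
    add("error", paste0("duplicate flux id(s): ",
                        paste(unique(fid[duplicated(fid)]), collapse = ", ")))
  if (!any(species_kinds(net) == "dependent"))
    add("error", "network has no dependent species")
  bad <- character(0)
  for (fl in net$fluxes) {
    refs <- c(names(fl$substrates), names(fl$products),
              vapply(fl$regulations, `[[`, character(1), "effector"))
    bad <- c(bad, setdiff(refs, sid))
  }
  if (length(bad))
    add("error", paste0("undeclared species referenced: ",
                        paste(unique(bad), collapse = ", ")))
  for (sp in net$species) {
    if (sp$initial_value < 0)
      add("error", paste0("negative initial value for ", sp$id), sp$id)
  }
  # accumulator warning: dependent species consumed by no flux but produced
  if (!length(bad)) {
    for (sp in net$species) {
      if (sp$kind != "dependent") next
      has_in <- any(vapply(net$fluxes, function(fl)
        sp$id %in% names(fl$products), logical(1)))
      has_out <- any(vapply(net$fluxes, function(fl)
        sp$id %in% names(fl$substrates), logical(1)))
      if (has_in && !has_out)
        add("warning", paste0("species ", sp$id,
                              " has influx but no efflux (pure accumulator)"),
            sp$id)
    }
  }
  findings
}

#' @export
print.usys_network <- function(x, ...) {
  nd <- n_dependent(x)
  cat("usys_network: ", length(x$species), " species (", nd, " dependent), ",
      length(x$fluxes), " fluxes\n", sep = "")
  for (fl in x$fluxes) {
    lhs <- if (length(fl$substrates))
      paste(ifelse(fl$substrates > 1, paste0(fl$substrates, " "), ""),
            names(fl$substrates), sep = "", collapse = " + ") else "(influx)"
    rhs <- if (length(fl$products))
      paste(ifelse(fl$products > 1, paste0(fl$products, " "), ""),
            names(fl$products), sep = "", collapse = " + ") else "(drain)"
    mods <- if (length(fl$regulations))
      paste0(" [", paste(vapply(fl$regulations, function(r)
        paste0(if (r$sign == "inhibition") "-" else "+", r$effector),
        character(1)), collapse = ", "), "]") else ""
    cat("  ", fl$id, ": ", lhs, " -> ", rhs, mods, "\n", sep = "")
  }
  invisible(x)
}

# JSON dialect ----------------------------------------------------------------

#' Serialize a network to its JSON dialect
#'
#' The document has top-level keys `species`, `fluxes`, `metadata`. Key order
#' is canonical and regulation lists are sorted by effector, so output is
#' diff-stable; species and flux arrays keep declaration order (which carries
#' meaning: state and flux vector order).
#'
#' @param net A `usys_network`.
#' @param path Optional file path; when `NULL` the JSON text is returned.
#' @return Invisibly the JSON string (also written to `path` if given).
#' @export
write_network <- function(net, path = NULL) {
  sp <- lapply(net$species, function(s)
    list(id = s$id, name = s$name, kind = s$kind,
         initial_value = s$initial_value))
  fl <- lapply(net$fluxes, function(f) {
    regs <- f$regulations
    if (length(regs) > 1L)
      regs <- regs[order(vapply(regs, `[[`, character(1), "effector"))]
    list(
      id = f$id,
      substrates = unname(Map(function(n, c) list(n, c),
                              names(f$substrates), f$substrates)),
      products = unname(Map(function(n, c) list(n, c),
                            names(f$products), f$products)),
      regulations = lapply(regs, function(r)
        list(effector = r$effector, sign = r$sign))
    )
  })
  md <- net$metadata
  if (length(md) > 1L) md <- md[order(names(md))]
  doc <- list(species = sp, fluxes = fl, metadata = md)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) writeLines(json, path)
  invisible(as.character(json))
}

#' Parse a network from its JSON dialect
#'
#' @param path_or_text A file path or a JSON string.
#' @return A validated `usys_network`; `parse_network(write_network(x))` is
#'   structurally identical to `x`.
#' @export
parse_network <- function(path_or_text) {
  doc <- tryCatch(
    jsonlite::fromJSON(path_or_text, simplifyVector = FALSE),
    error = function(e) stop("malformed network document: ",
                             conditionMessage(e), call. = FALSE))
  for (key in c("species", "fluxes"))
    if (is.null(doc[[key]]))
      stop("malformed network document: missing key '", key, "'",
           call. = FALSE)
  species <- lapply(doc$species, function(s) {
    if (is.null(s$id)) stop("species entry without 'id'", call. = FALSE)
    species_decl(id = s$id,
                 kind = if (is.null(s$kind)) "dependent" else s$kind,
                 name = if (is.null(s$name)) s$id else s$name,
                 initial_value = if (is.null(s$initial_value)) 1.0
                                 else s$initial_value)
  })
  side <- function(entries, fid, what) {
    if (is.null(entries) || !length(entries)) return(NULL)
    nm <- vapply(entries, function(e) as.character(e[[1]]), character(1))
    co <- vapply(entries, function(e) as.numeric(e[[2]]), numeric(1))
    stats::setNames(co, nm)
  }
  fluxes <- lapply(doc$fluxes, function(f) {
    if (is.null(f$id)) stop("flux entry without 'id'", call. = FALSE)
    flux_decl(id = f$id,
              substrates = side(f$substrates, f$id, "substrates"),
              products = side(f$products, f$id, "products"),
              regulations = lapply(f$regulations, function(r)
                regulation_decl(r$effector, r$sign)))
  })
  md <- if (is.null(doc$metadata)) list() else doc$metadata
  net <- structure(list(species = species, fluxes = fluxes, metadata = md),
                   class = "usys_network")
  f <- validate_network(net)
  errs <- f[vapply(f, function(x) x$severity == "error", logical(1))]
  if (length(errs))
    stop("network failed validation: ",
         paste(vapply(errs, `[[`, character(1), "message"), collapse = "; "),
         call. = FALSE)
  net
}

# Built-in fixtures -----------------------------------------------------------

#' Built-in fixture networks
#'
#' \describe{
#'   \item{`linear3`}{A -> B -> C chain with a constant influx and a drain;
#'     no regulation.}
#'   \item{`branched_topology`}{The four-metabolite branched reference pathway:
#'     an influx to X1 inhibited by X3; X1 -> X2 and X1 -> X4 branch; X2 -> X3;
#'     an X3 drain activated by X4; an X4 drain. No attached parameters.}
#'   \item{`branched_gma`}{Same topology with the reference GMA parameter set
#'     attached as attribute `"params"` (rate constants 12, 8, 2, 3, 5, 6;
#'     kinetic orders -0.8, 0.5, 0.5, 0.75, 0.5, 0.2, 0.8).}
#'   \item{`linear_inhibited`}{X1 -> X2 chain with end-product inhibition of the
#'     X1 influx by X2 and enzyme activities Y1, Y2 as independent species
#'     multiplying the influx and the X2 efflux; no attached parameters.}
#' }
#'
#' @param name Fixture identifier.
#' @return A `usys_network`; for `branched_gma` the attached `usys_params` is
#'   available via `attr(net, "params")`.
#' @export
builtin_fixture <- function(name) {
  avail <- c("linear3", "branched_topology", "branched_gma",
             "linear_inhibited")
  if (!is.character(name) || length(name) != 1L || !name %in% avail)
    stop("unknown fixture '", name, "'; available: ",
         paste(avail, collapse = ", "), call. = FALSE)
  if (name == "linear3") {
    return(network_spec(
      species = list(species_decl("A"), species_decl("B"), species_decl("C")),
      fluxes = list(
        flux_decl("vin", products = c(A = 1)),
        flux_decl("vAB", substrates = c(A = 1), products = c(B = 1)),
        flux_decl("vBC", substrates = c(B = 1), products = c(C = 1)),
        flux_decl("vout", substrates = c(C = 1))),
      metadata = list(description = "linear 3-species chain, constant influx")))
  }
  if (name %in% c("branched_topology", "branched_gma")) {
    net <- network_spec(
      species = list(species_decl("X1"), species_decl("X2"),
                     species_decl("X3"), species_decl("X4")),
      fluxes = list(
        flux_decl("vin", products = c(X1 = 1),
                  regulations = list(regulation_decl("X3", "inhibition"))),
        flux_decl("v12", substrates = c(X1 = 1), products = c(X2 = 1)),
        flux_decl("v14", substrates = c(X1 = 1), products = c(X4 = 1)),
        flux_decl("v23", substrates = c(X2 = 1), products = c(X3 = 1)),
        flux_decl("v3out", substrates = c(X3 = 1),
                  regulations = list(regulation_decl("X4", "activation"))),
        flux_decl("v4out", substrates = c(X4 = 1))),
      metadata = list(description =
        "branched pathway with end-product inhibition and activation"))
    if (name == "branched_gma") {
      attr(net, "params") <- parameter_set(
        rate_constant = c(vin = 12, v12 = 8, v14 = 2, v23 = 3, v3out = 5,
                          v4out = 6),
        kinetic_order = c("vin:X3" = -0.8, "v12:X1" = 0.5, "v14:X1" = 0.5,
                          "v23:X2" = 0.75, "v3out:X3" = 0.5, "v3out:X4" = 0.2,
                          "v4out:X4" = 0.8))
    }
    return(net)
  }
  # linear_inhibited: X1 -> X2 with end-product inhibition of the influx,
  # enzyme activities Y1 (influx) and Y2 (X2 efflux) as independent species
  network_spec(
    species = list(species_decl("X1"), species_decl("X2"),
                   species_decl("Y1", kind = "independent"),
                   species_decl("Y2", kind = "independent")),
    fluxes = list(
      flux_decl("vin", products = c(X1 = 1),
                regulations = list(regulation_decl("X2", "inhibition"),
                                   regulation_decl("Y1", "activation"))),
      flux_decl("v12", substrates = c(X1 = 1), products = c(X2 = 1)),
      flux_decl("vout", substrates = c(X2 = 1),
                regulations = list(regulation_decl("Y2", "activation")))),
    metadata = list(description =
      "linear chain with end-product inhibition and enzyme activities"))
}

#' Generate a random valid network
#'
#' Draws a random pathway: a main chain of dependent species fed by a constant
#' influx, with optional branch drains and randomly placed signed regulations.
#' Every dependent species has an efflux, so the topology admits a steady
#' state. Intended for property tests and robustness experiments.
#'
#' @param n_species Number of dependent species (>= 2).
#' @param p_branch Probability a non-terminal species gets an extra drain.
#' @param p_regulation Probability a flux receives one random signed modifier.
#' @param seed Integer seed (local to this call).
#' @return A `usys_network`.
#' @export
random_network <- function(n_species = 4, p_branch = 0.3, p_regulation = 0.3,
                           seed = 1) {
  stopifnot(n_species >= 2)
  with_local_seed(seed, {
    ids <- paste0("X", seq_len(n_species))
    species <- lapply(ids, species_decl)
    fluxes <- list(flux_decl("vin", products = stats::setNames(1, ids[1])))
    for (i in seq_len(n_species - 1)) {
      fluxes[[length(fluxes) + 1L]] <- flux_decl(
        paste0("v", i, "_", i + 1),
        substrates = stats::setNames(1, ids[i]),
        products = stats::setNames(1, ids[i + 1]))
      if (stats::runif(1) < p_branch)
        fluxes[[length(fluxes) + 1L]] <- flux_decl(
          paste0("vbr", i), substrates = stats::setNames(1, ids[i]))
    }
    fluxes[[length(fluxes) + 1L]] <- flux_decl(
      "vout", substrates = stats::setNames(1, ids[n_species]))
    fluxes <- lapply(fluxes, function(fl) {
      if (stats::runif(1) < p_regulation) {
        cand <- setdiff(ids, c(names(fl$substrates), names(fl$products)))
        if (length(cand)) {
          eff <- sample(cand, 1)
          sgn <- sample(c("inhibition", "activation"), 1)
          fl$regulations <- list(regulation_decl(eff, sgn))
        }
      }
      fl
    })
    network_spec(species, fluxes,
                 metadata = list(description = "random chain network"))
  })
}

# evaluate expr with a local RNG seed, restoring global RNG state afterwards
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
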