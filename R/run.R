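# Run-spec execution: reproducible, file-driven workflows --------------------

fmt12 <- function(x) sprintf("%.12g", x)

resolve_network <- function(spec, base_dir) {
  if (!is.null(spec$fixture)) return(builtin_fixture(spec$fixture))
  if (is.null(spec$network))
    stop("run spec needs a 'network' path or a 'fixture' name", call. = FALSE)
  path <- spec$network
  if (!file.exists(path) && !is.null(base_dir))
    path <- file.path(base_dir, spec$network)
  if (!file.exists(path))
    stop("network file not found: ", spec$network, call. = FALSE)
  parse_network(path)
}

resolve_params <- function(spec, net) {
  mode <- if (is.null(spec$parameter_mode)) "unity" else spec$parameter_mode
  if (mode == "unity") {
    ov <- NULL
    if (!is.null(spec$overrides))
      ov <- list(rate_constant = unlist(spec$overrides$rate_constant),
                 kinetic_order = unlist(spec$overrides$kinetic_order))
    unity_parameters(net, ov)
  } else if (mode == "attached") {
    p <- attr(net, "params")
    if (is.null(p)) stop("fixture has no attached parameters", call. = FALSE)
    p
  } else if (mode == "file") {
    parse_parameters(spec$parameter_file)
  } else stop("unknown parameter_mode '", mode, "'", call. = FALSE)
}

resolve_tgrid <- function(spec) {
  horizon <- if (is.null(spec$horizon)) 100 else spec$horizon
  n_out <- if (is.null(spec$n_out)) 201 else spec$n_out
  seq(0, horizon, length.out = n_out)
}

# wide trajectory table (time + one column per species), 12 significant digits
write_wide_trajectory <- function(traj, path) {
  df <- data.frame(time = fmt12(traj$times))
  for (sp in traj$species) df[[sp]] <- fmt12(traj$states[, sp])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Execute a run specification
#'
#' A run spec is a JSON-serializable list: `subcommand` plus the keys that
#' subcommand needs (`fixture` or `network` path, `parameter_mode` =
#' unity/attached/file with optional `overrides`, `horizon`/`n_out`,
#' `init_fold` or `init`, `seed`, ensemble/sweep/perturbation/comparison
#' blocks). Every artifact is written under `out_dir` with 12-significant-
#' digit numbers, together with the resolved spec (`runspec.json`) and a log;
#' a run is reproducible from its spec and seed alone.
#'
#' Subcommands: `simulate`, `steady`, `ensemble`, `sweep`, `knockdown`,
#' `synth`, `compare`, `fixtures`.
#'
#' @param spec A named list, or path to a JSON run-spec file (relative paths
#'   inside the spec resolve against the file's directory).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly a list of the artifacts produced.
#' @export
run_spec <- function(spec, out_dir) {
  base_dir <- NULL
  if (is.character(spec)) {
    if (!file.exists(spec))
      stop("run spec file not found: ", spec, call. = FALSE)
    base_dir <- dirname(normalizePath(spec))
    spec <- jsonlite::fromJSON(spec, simplifyVector = TRUE)
  }
  if (is.null(spec$subcommand)) stop("spec$subcommand missing", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(paste0("usystem ",
                        as.character(utils::packageVersion("usystem"))),
                 paste0("R ", R.version.string),
                 paste0("subcommand: ", spec$subcommand),
                 paste0("seed: ", if (is.null(spec$seed)) "none"
                        else spec$seed))
  artifacts <- list()
  emit <- function(name, value) artifacts[[name]] <<- value

  sub <- spec$subcommand
  if (sub == "fixtures") {
    writeLines(c("linear3", "branched_topology", "branched_gma",
                 "linear_inhibited"), file.path(out_dir, "fixtures.txt"))
    emit("fixtures", file.path(out_dir, "fixtures.txt"))
  } else if (sub %in% c("simulate", "steady", "knockdown", "sweep",
                        "compare")) {
    net <- resolve_network(spec, base_dir)
    params <- resolve_params(spec, net)
    model <- compile_model(net, params)
    if (!is.null(spec$uptakes)) {
      ups <- spec$uptakes
      if (is.data.frame(ups)) ups <- split(ups, seq_len(nrow(ups)))
      for (u in ups)
        model <- attach_uptake(model, uptake_spec(
          u$species, u$medium, u$permeability,
          start_time = if (is.null(u$start_time)) 0 else u$start_time))
    }
    if (sub == "knockdown") {
      kd <- apply_knockdown(model, spec$knockdown$flux,
                            spec$knockdown$fraction)
      dir_v <- predict_direction(model, kd$model,
        threshold = if (is.null(spec$threshold)) 0.01 else spec$threshold)
      utils::write.table(
        data.frame(species = names(dir_v), direction = unname(dir_v)),
        file.path(out_dir, "directions.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      emit("directions", file.path(out_dir, "directions.tsv"))
      model <- kd$model
    }
    ss <- find_steady_state(model)
    utils::write.table(
      data.frame(species = names(ss$state), value = fmt12(ss$state),
                 residual = fmt12(rep(ss$residual, length(ss$state))),
                 method = ss$method),
      file.path(out_dir, "steady_state.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    emit("steady_state", file.path(out_dir, "steady_state.tsv"))
    if (sub %in% c("simulate", "knockdown", "compare")) {
      init <- if (!is.null(spec[["init"]])) unlist(spec[["init"]])
        else if (!is.null(spec[["init_fold"]]))
          ss$state * unlist(spec[["init_fold"]])
        else initial_state(net, "dependent")
      traj <- simulate(model, init, resolve_tgrid(spec))
      write_wide_trajectory(traj, file.path(out_dir, "trajectory.tsv"))
      emit("trajectory", file.path(out_dir, "trajectory.tsv"))
      if (sub == "compare") {
        obs <- load_timeseries(
          if (!is.null(base_dir) && !file.exists(spec$observed))
            file.path(base_dir, spec$observed) else spec$observed)
        rows <- lapply(obs, function(o) {
          cr <- tryCatch(correlate(traj, o, o$species),
                         error = function(e) NULL)
          if (is.null(cr)) return(NULL)
          data.frame(species = o$species, group = o$group,
                     r = fmt12(cr$r), n = cr$n, p = fmt12(cr$p))
        })
        tab <- do.call(rbind, rows)
        utils::write.table(tab, file.path(out_dir, "comparison.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        emit("comparison", file.path(out_dir, "comparison.tsv"))
      }
    }
    if (sub == "sweep") {
      sw <- spec$sweep
      values <- unlist(sw$values)
      fold <- if (is.null(sw$fold)) rep(1, length(model$dependent))
        else unlist(sw$fold)
      res <- if (!is.null(sw$flux_group))
        branch_sweep(model, unlist(sw$flux_group), values, fold = fold,
                     t_grid = resolve_tgrid(spec))
      else sweep_parameter(model,
        target = if (!is.null(sw$rate_constant))
          list(rate_constant = sw$rate_constant)
        else list(kinetic_order = unlist(sw$kinetic_order)),
        values, fold = fold, t_grid = resolve_tgrid(spec))
      for (i in seq_along(values)) {
        f <- file.path(out_dir, sprintf("sweep_%03d.tsv", i))
        write_wide_trajectory(res$trajectories[[i]], f)
      }
      emit("sweep", out_dir)
    }
  } else if (sub == "ensemble") {
    net <- resolve_network(spec, base_dir)
    en <- spec$ensemble
    ranges <- sampling_ranges(
      rate_constant_range = if (is.null(en$rate_constant_range)) c(0.5, 20)
        else unlist(en$rate_constant_range),
      kinetic_order_magnitude_range =
        if (is.null(en$kinetic_order_magnitude_range)) c(0.2, 0.8)
        else unlist(en$kinetic_order_magnitude_range),
      n_draws = if (is.null(en$n_draws)) 1000 else en$n_draws,
      seed = if (is.null(spec$seed)) 1 else spec$seed)
    fold <- if (is.null(en$fold)) c(3, 1, 0.5, 2) else unlist(en$fold)
    ens <- run_ensemble(net, ranges, init_mode = fold,
                        t_grid = resolve_tgrid(spec))
    write_ensemble(ens, file.path(out_dir, "ensemble_summary.tsv"),
                   file.path(out_dir, "envelope.tsv"))
    emit("ensemble_summary", file.path(out_dir, "ensemble_summary.tsv"))
    emit("envelope", file.path(out_dir, "envelope.tsv"))
  } else if (sub == "synth") {
    net <- resolve_network(spec, base_dir)
    params <- resolve_params(spec, net)
    model <- compile_model(net, params)
    ss <- find_steady_state(model)
    sy <- spec$synth
    fold <- if (is.null(sy$fold)) rep(2, length(model$dependent))
      else unlist(sy$fold)
    traj <- simulate(model, ss$state * fold, resolve_tgrid(spec))
    df <- synth_observations(
      traj, ss$state,
      cv_percent = if (is.null(sy$cv_percent)) 10 else sy$cv_percent,
      n_replicates = if (is.null(sy$n_replicates)) 3 else sy$n_replicates,
      seed = if (is.null(spec$seed)) 1 else spec$seed)
    write_timeseries(df, file.path(out_dir, "observations.tsv"))
    emit("observations", file.path(out_dir, "observations.tsv"))
  } else stop("unknown subcommand '", sub, "'", call. = FALSE)

  writeLines(as.character(jsonlite::toJSON(spec, auto_unbox = TRUE,
                                           digits = NA, pretty = TRUE)),
             file.path(out_dir, "runspec.json"))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(artifacts)
}
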