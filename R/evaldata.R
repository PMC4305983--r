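# Observed data, preprocessing, statistics, synthetic observations -----------

new_obs <- function(species, group, times, values) {
  values <- as.matrix(values)
  m <- rowMeans(values)
  s <- if (ncol(values) >= 2) apply(values, 1, stats::sd) else rep(NA_real_,
                                                                   nrow(values))
  cv <- ifelse(m == 0, NA_real_, 100 * s / m)
  structure(list(species = species, group = group, times = as.numeric(times),
                 replicate_values = values, mean = m, sd = s, cv = cv),
            class = "usys_obs")
}

#' Construct an observed series directly
#'
#' @param species Species id.
#' @param times Increasing numeric times (hours).
#' @param replicate_values Numeric time x replicate matrix (a vector is taken
#'   as a single replicate).
#' @param group `"treated"` or `"control"`.
#' @return A `usys_obs` with derived per-time mean, sample sd and CV (%).
#' @export
observed_series <- function(species, times, replicate_values,
                            group = c("treated", "control")) {
  group <- match.arg(group)
  replicate_values <- as.matrix(replicate_values)
  if (length(times) != nrow(replicate_values))
    stop("times and replicate_values rows differ", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  new_obs(species, group, times, replicate_values)
}

#' @export
print.usys_obs <- function(x, ...) {
  cat("usys_obs: ", x$species, " (", x$group, "), ", length(x$times),
      " times x ", ncol(x$replicate_values), " replicates\n", sep = "")
  invisible(x)
}

#' Load replicated time-series observations from tidy TSV
#'
#' Expects columns `time`, `species`, `replicate`, `group`, `value` (the
#' standard layout: e.g. 11 sampling times, triplicate, treated vs control
#' groups). One series is returned per (species, group), ordered by species
#' then group, with a time x replicate value matrix and derived mean, sample
#' standard deviation (n - 1 denominator) and CV (%) per time.
#'
#' @param path TSV file path.
#' @return List of `usys_obs`.
#' @export
load_timeseries <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("time", "species", "replicate", "group", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (!is.numeric(df$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$value))))
    stop("non-numeric value at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(df$time)) stop("time column must be numeric", call. = FALSE)
  key <- paste(df$time, df$species, df$replicate, df$group, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (time, species, replicate, group) row(s)", call. = FALSE)
  out <- list()
  for (sp in unique(df$species)) {
    for (g in unique(df$group[df$species == sp])) {
      sub <- df[df$species == sp & df$group == g, ]
      times <- sort(unique(sub$time))
      reps <- sort(unique(sub$replicate))
      vals <- matrix(NA_real_, length(times), length(reps),
                     dimnames = list(NULL, as.character(reps)))
      for (i in seq_len(nrow(sub)))
        vals[match(sub$time[i], times),
             match(sub$replicate[i], reps)] <- sub$value[i]
      if (anyNA(vals))
        stop("unbalanced replicates for species ", sp, " group ", g,
             call. = FALSE)
      out[[length(out) + 1L]] <- new_obs(sp, g, times, vals)
    }
  }
  out
}

#' Write tidy observations to TSV
#'
#' @param df Data frame with columns time, species, replicate, group, value
#'   (as produced by [synth_observations()]).
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_timeseries <- function(df, path) {
  df$time <- sprintf("%.12g", df$time)
  df$value <- sprintf("%.12g", df$value)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Relative concentration of a treated vs control pair
#'
#' Treated mean minus control mean at the shared time points. Subtracting the
#' control series removes growth and other common-mode trends from the peak
#' intensities, leaving the perturbation response. Reliability per time point
#' is flagged from the treated series' CV.
#'
#' @param treated,control `usys_obs` for the same species.
#' @param cv_threshold CV reliability threshold in percent (default 20).
#' @return A `usys_relative`: species, times (intersection of grids), values,
#'   `mean` (alias of values, for uniform downstream handling), `flagged`
#'   (TRUE where treated CV exceeds the threshold).
#' @export
relative_concentration <- function(treated, control, cv_threshold = 20) {
  stopifnot(inherits(treated, "usys_obs"), inherits(control, "usys_obs"))
  if (treated$species != control$species)
    stop("treated and control series are for different species",
         call. = FALSE)
  times <- intersect(treated$times, control$times)
  if (!length(times)) stop("no shared time points", call. = FALSE)
  times <- sort(times)
  it <- match(times, treated$times)
  ic <- match(times, control$times)
  vals <- treated$mean[it] - control$mean[ic]
  flagged <- if (ncol(treated$replicate_values) >= 2)
    !is.na(treated$cv[it]) & treated$cv[it] > cv_threshold
  else rep(NA, length(times))
  structure(list(species = treated$species, times = times, values = vals,
                 mean = vals, flagged = flagged),
            class = "usys_relative")
}

#' @export
print.usys_relative <- function(x, ...) {
  cat("usys_relative: ", x$species, ", ", length(x$times), " times\n",
      sep = "")
  invisible(x)
}

#' Flag high-variation time points
#'
#' A point is flagged when its coefficient of variation strictly exceeds the
#' threshold (the boundary value itself is not flagged).
#'
#' @param series A `usys_obs` with >= 2 replicates.
#' @param threshold_percent CV threshold in percent (default 20).
#' @return Logical vector per time point (NA where the mean is zero).
#' @export
cv_flags <- function(series, threshold_percent = 20) {
  stopifnot(inherits(series, "usys_obs"))
  if (ncol(series$replicate_values) < 2)
    stop("cv undefined: at least 2 replicates required", call. = FALSE)
  ifelse(is.na(series$cv), NA, series$cv > threshold_percent)
}

#' Correlate a simulation with an observed series
#'
#' The simulated trajectory is linearly interpolated at the observation times;
#' Pearson's r is computed against the observed means (or relative values),
#' with significance from the exact t transform
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} referred to Student's t with n - 2 degrees
#' of freedom (two-sided, via the survival function). Pearson correlation is
#' invariant to affine rescaling of either series, which is what justifies
#' comparing arbitrary-unit simulations with relative peak intensities.
#'
#' @param sim A `usys_trajectory`.
#' @param obs A `usys_obs` or `usys_relative`.
#' @param species Species id (default: the observed series' species).
#' @return A `usys_comparison`: `r`, `n`, `t`, `p`, `alignment`.
#' @export
correlate <- function(sim, obs, species = obs$species) {
  stopifnot(inherits(sim, "usys_trajectory"))
  if (!species %in% sim$species)
    stop("species '", species, "' not in the simulation", call. = FALSE)
  t_obs <- obs$times
  keep <- t_obs >= min(sim$times) & t_obs <= max(sim$times)
  t_obs <- t_obs[keep]
  y_obs <- obs$mean[keep]
  if (length(t_obs) < 3)
    stop("need at least 3 observation times inside the simulation span",
         call. = FALSE)
  y_sim <- stats::approx(sim$times, sim$states[, species], xout = t_obs)$y
  if (stats::sd(y_obs) == 0 || stats::sd(y_sim) == 0)
    stop("correlation undefined: constant series", call. = FALSE)
  r <- stats::cor(y_sim, y_obs)
  n <- length(t_obs)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  structure(list(r = r, n = n, t = tt, p = p,
                 alignment = "simulation linearly interpolated at observation times"),
            class = "usys_comparison")
}

#' @export
print.usys_comparison <- function(x, ...) {
  cat("usys_comparison: r = ", format(x$r, digits = 4), ", n = ", x$n,
      ", p = ", format(x$p, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Agreement between predicted and observed direction vectors
#'
#' @param predicted,observed Equal-length vectors over \{"+", "-", "0"\}.
#' @return List: `fraction` of agreeing entries, `n`, `matches`, and a
#'   3 x 3 contingency `table`.
#' @export
direction_agreement <- function(predicted, observed) {
  if (!length(predicted))
    stop("direction vectors must be non-empty", call. = FALSE)
  if (length(predicted) != length(observed))
    stop("direction vectors differ in length", call. = FALSE)
  lv <- c("-", "0", "+")
  predicted <- factor(as.character(predicted), levels = lv)
  observed <- factor(as.character(observed), levels = lv)
  if (anyNA(predicted) || anyNA(observed))
    stop("directions must be '+', '-' or '0'", call. = FALSE)
  matches <- sum(predicted == observed)
  list(fraction = matches / length(predicted), n = length(predicted),
       matches = matches, table = table(predicted, observed))
}

#' Generate synthetic replicated observations from a simulation
#'
#' Emulates the structure of a supplementation experiment: the treated group
#' is the simulated trajectory sampled at the requested times, the control
#' group is the steady state, both multiplied by lognormal noise whose
#' coefficient of variation equals `cv_percent` (multiplicative error is the
#' standard model for positive MS peak intensities; the noise factor has
#' mean 1). Deterministic per seed; the global RNG stream is untouched.
#'
#' @param traj A `usys_trajectory` (the treated dynamics).
#' @param steady Named steady-state vector (control level).
#' @param species Character vector of species to emit (default: all in
#'   `traj`).
#' @param times Sampling times within the trajectory span (default: the
#'   reference design 0, 2, 6, 12, 24, 36, 48, 60, 72, 84, 96 h when the
#'   span allows, otherwise the trajectory grid).
#' @param cv_percent Noise CV in percent (default 10; 0 = exact values).
#' @param n_replicates Replicates per group (default 3).
#' @param seed Integer seed.
#' @return Tidy data frame: time, species, replicate, group, value.
#' @export
synth_observations <- function(traj, steady, species = traj$species,
                               times = NULL, cv_percent = 10,
                               n_replicates = 3, seed = 1) {
  stopifnot(inherits(traj, "usys_trajectory"))
  if (cv_percent < 0) stop("cv_percent must be >= 0", call. = FALSE)
  bad <- setdiff(species, traj$species)
  if (length(bad))
    stop("species not in trajectory: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(times)) {
    design <- c(0, 2, 6, 12, 24, 36, 48, 60, 72, 84, 96)
    times <- if (max(traj$times) >= max(design)) design else traj$times
  }
  if (min(times) < min(traj$times) || max(times) > max(traj$times))
    stop("times must lie within the trajectory span", call. = FALSE)
  if (!is.null(names(steady))) steady <- steady[traj$species]
  cv <- cv_percent / 100
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- -sdlog^2 / 2            # noise factor has expectation 1
  noise <- function(n) if (cv == 0) rep(1, n)
    else stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog)
  with_local_seed(seed, {
    rows <- list()
    for (sp in species) {
      j <- match(sp, traj$species)
      y_t <- stats::approx(traj$times, traj$states[, j], xout = times)$y
      y_c <- rep(steady[[j]], length(times))
      for (rep_i in seq_len(n_replicates)) {
        rows[[length(rows) + 1L]] <- data.frame(
          time = times, species = sp, replicate = rep_i, group = "treated",
          value = y_t * noise(length(times)))
        rows[[length(rows) + 1L]] <- data.frame(
          time = times, species = sp, replicate = rep_i, group = "control",
          value = y_c * noise(length(times)))
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
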