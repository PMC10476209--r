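## Orchestration: one reproducible configuration-driven run of
## geometry -> bath -> Hamiltonian -> response -> anisotropy, with all
## artifacts written as delimited text plus a checksummed manifest.

#' Assemble a pipeline configuration
#'
#' All physical constants live here with their standard defaults (monomer
#' energy 15390 cm^-1, dipole 5.48 D, 4 fs timestep, 300/166 fs
#' apodization times, waiting times 0..336 fs in 24 fs steps) so that no
#' stage hard-codes them.  Any field can be overridden; configurations
#' can also be read from YAML with [read_pipeline_config()].
#'
#' @param preset geometry preset name (see [preset_cylinder()]), or
#'   `NULL` when `cylinder` is given.
#' @param cylinder an explicit [cylinder_spec()] (overrides `preset`).
#' @param n_molecules approximate aggregate size for presets.
#' @param bath named list of [bath_spec()] overrides.
#' @param grid named list of [grid_spec()] overrides.
#' @param apodization named list of [apodization_spec()] overrides.
#' @param pathways 2DES pathways to include.
#' @param n_samples trajectory start points per realization.
#' @param n_realizations independent disorder/bath realizations.
#' @param trace_point `c(omega1, omega3)` for the decay trace, cm^-1, or
#'   `NULL` to use the maximum of the parallel t2 = 0 map.
#' @param omega0 monomer transition energy, cm^-1.
#' @param dipole_magnitude transition dipole magnitude, debye.
#' @param seed global integer seed; every stochastic stage derives its
#'   own sub-seed from it.
#' @param out_dir output directory for [run_pipeline()].
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = "system2-like", cylinder = NULL,
                            n_molecules = 60,
                            bath = list(), grid = list(),
                            apodization = list(),
                            pathways = c("GSB", "SE"),
                            n_samples = 8, n_realizations = 8,
                            trace_point = NULL,
                            omega0 = OMEGA0_CM,
                            dipole_magnitude = DIPOLE_MAGNITUDE_D,
                            seed = 1L, out_dir = tempfile("excitube_run_")) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  cfg <- structure(list(preset = preset, cylinder = cylinder,
                        n_molecules = n_molecules,
                        bath = bath, grid = grid, apodization = apodization,
                        pathways = pathways, n_samples = n_samples,
                        n_realizations = n_realizations,
                        trace_point = trace_point,
                        omega0 = omega0,
                        dipole_magnitude = dipole_magnitude,
                        seed = as.integer(seed), out_dir = out_dir),
                   class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$cylinder) && is.null(cfg$preset))
    stop("config needs either a preset name or an explicit cylinder spec")
  stopifnot(cfg$n_samples >= 1, cfg$n_realizations >= 1)
  invisible(do.call(grid_spec, cfg$grid))
  invisible(do.call(apodization_spec, cfg$apodization))
  invisible(TRUE)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, y)
}

## deterministic sub-seeds derived from the global seed
derive_seed <- function(seed, stage, k = 0L) {
  offs <- c(geometry = 101L, bath = 211L, response = 307L)
  (as.integer(seed) * 1000L + offs[[stage]] + as.integer(k)) %% .Machine$integer.max
}

#' Run the full pipeline
#'
#' Executes geometry, bath, Hamiltonian, linear response, 2DES (both
#' polarization schemes), and anisotropy analysis; averages the
#' third-order response over bath/disorder realizations; writes every
#' artifact as delimited text into `config$out_dir` and returns a
#' manifest with MD5 checksums.  Identical configuration and seed give
#' bit-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage progress messages.
#' @return a manifest data.frame (invisible fields: `results` attribute
#'   carrying the in-memory objects).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  validate_pipeline_config(config)
  t_start <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  files <- character(0)

  ## --- geometry ------------------------------------------------------
  spec <- config$cylinder %||%
    preset_cylinder(config$preset, n_molecules = config$n_molecules,
                    seed = derive_seed(config$seed, "geometry"))
  agg <- build_cylinder(spec, dipole_magnitude = config$dipole_magnitude)
  n <- nrow(agg$positions)
  bsum <- summarize_beta(beta_angles(agg))
  say("geometry: %d molecules, <beta> = %.1f deg (sigma %.1f)", n,
      bsum$mean_beta, bsum$sigma_beta)
  f <- file.path(config$out_dir, "geometry.tsv")
  write_geometry(agg, f); files <- c(files, f)

  grid <- do.call(grid_spec, config$grid)
  apod <- do.call(apodization_spec, config$apodization)
  nt1 <- grid$t1_max / grid$dt
  nt3 <- grid$t3_max / grid$dt
  n_keep <- nt1 + max(grid$t2_values) / grid$dt + nt3
  stride <- max(ceiling((do.call(bath_spec, config$bath)$tau_corr) / grid$dt), 8)
  n_steps_needed <- (config$n_samples - 1) * stride + n_keep + 1

  lin_acc <- NULL
  resp_acc <- NULL
  first_traj <- NULL
  for (k in seq_len(config$n_realizations)) {
    bspec <- do.call(bath_spec, modifyList(
      config$bath, list(n_steps = max(n_steps_needed,
                                      config$bath$n_steps %||% 0),
                        seed = derive_seed(config$seed, "bath", k))))
    traj <- generate_site_energies(agg, bspec)
    if (k == 1) first_traj <- traj
    ht <- build_hamiltonian_trajectory(agg, traj, omega0 = config$omega0)
    U <- prop_array(ht)
    lin <- linear_response(ht, t1_max = min(grid$t1_max, 128), apod = apod,
                           n_samples = config$n_samples, stride = stride,
                           U = U)
    lin_acc <- if (is.null(lin_acc)) lin else {
      lin$channels <- lin$channels + lin_acc$channels; lin
    }
    resp <- twod_response(ht, grid, pathways = config$pathways,
                          n_samples = config$n_samples, stride = stride,
                          U = U)
    resp_acc <- if (is.null(resp_acc)) resp else {
      resp$data <- Map(function(a, b) Map(`+`, a, b), resp_acc$data, resp$data)
      resp
    }
    say("realization %d/%d done", k, config$n_realizations)
  }
  lin_acc$channels <- lin_acc$channels / config$n_realizations
  resp_acc$data <- lapply(resp_acc$data, function(d)
    lapply(d, function(m) m / config$n_realizations))

  f <- file.path(config$out_dir, "site_energies_realization1.tsv")
  write_site_energies(first_traj, f); files <- c(files, f)
  f <- file.path(config$out_dir, "linear.tsv")
  write_spectrum1d(lin_acc, f); files <- c(files, f)

  ## --- 2DES + anisotropy --------------------------------------------
  resp_acc <- apodize(resp_acc, apod)
  maps <- list()
  for (i in seq_along(grid$t2_values)) {
    t2 <- grid$t2_values[i]
    sp <- spectrum_2d(resp_acc, t2 = t2, scheme = "parallel")
    ss <- spectrum_2d(resp_acc, t2 = t2, scheme = "perpendicular")
    maps[[i]] <- anisotropy_map(sp, ss)
    if (t2 == grid$t2_values[1]) {
      for (obj in list(sp, ss)) {
        f <- file.path(config$out_dir,
                       sprintf("twod_%s_t2_%03.0f.tsv", obj$scheme, t2))
        write_spectrum2d(obj, f); files <- c(files, f)
      }
      sp0 <- sp
    }
  }
  diag0 <- anisotropy_spectrum_diagonal(maps[[1]])
  f <- file.path(config$out_dir, "anisotropy_diagonal_t2_0.tsv")
  write.table(diag0, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  point <- config$trace_point
  if (is.null(point)) {
    ij <- which(sp0$map == max(sp0$map), arr.ind = TRUE)[1, ]
    point <- c(sp0$omega1[ij[1]], sp0$omega3[ij[2]])
  }
  ## short demonstration grids may not leave 4 points past the
  ## pulse-overlap region; fall back to the full trace, or skip the fit
  t2min_use <- if (sum(grid$t2_values >= 24) >= 4) 24 else 0
  trace <- anisotropy_trace(maps, point)
  if (length(grid$t2_values) >= 4) {
    trace <- fit_exponential(trace, t2_min = t2min_use)
  } else {
    trace$fit <- list(r0 = trace$r_values[1], r_inf = NA_real_,
                      tau = NA_real_, fit_ok = FALSE,
                      reason = "too few waiting times to fit")
  }
  say("trace at (%.0f, %.0f): r(0) = %.3f%s", point[1], point[2],
      trace$r_values[1],
      if (trace$fit$fit_ok) sprintf(", tau = %.0f fs", trace$fit$tau)
      else " (no decay)")
  f <- file.path(config$out_dir, "anisotropy_trace.tsv")
  tr_df <- data.frame(t2_fs = trace$t2_values, r = trace$r_values)
  con <- file(f, "w")
  writeLines(c(sprintf("# point_omega1_cm1 %.6g", trace$point[1]),
               sprintf("# point_omega3_cm1 %.6g", trace$point[2]),
               sprintf("# fit_ok %s", trace$fit$fit_ok),
               sprintf("# fit_r0 %.6g", trace$fit$r0),
               sprintf("# fit_r_inf %.6g", trace$fit$r_inf),
               sprintf("# fit_tau_fs %.6g", trace$fit$tau %||% NA)), con)
  write.table(tr_df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  files <- c(files, f)

  ## --- resolved config + manifest -----------------------------------
  f <- file.path(config$out_dir, "config.yml")
  yaml::write_yaml(lapply(unclass(config), function(x)
    if (inherits(x, "cylinder_spec")) unclass(x) else x), f)
  files <- c(files, f)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write.table(manifest, file.path(config$out_dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  say("pipeline finished in %.1f s", as.numeric(Sys.time() - t_start, units = "secs"))
  attr(manifest, "results") <- list(aggregate = agg, beta = bsum,
                                    linear = lin_acc, response = resp_acc,
                                    maps = maps, trace = trace)
  invisible(manifest)
}

#' Write / read a 1D spectrum as delimited text
#'
#' Two or more columns (frequency then channels); `#` header carries the
#' channel names.  Round trips to 1e-12.
#' @param s a `spectrum1d`.
#' @param path file path.
#' @export
write_spectrum1d <- function(s, path) {
  stopifnot(inherits(s, "spectrum1d"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# excitube spectrum1d",
               paste("# channels", paste(colnames(s$channels), collapse = " "))),
             con)
  write.table(format(cbind(s$frequency, s$channels), digits = 17, trim = TRUE),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum1d
#' @export
read_spectrum1d <- function(path) {
  lines <- readLines(path)
  ch <- grep("^# channels ", lines, value = TRUE)
  if (!length(ch)) stop("malformed spectrum file (missing channel header) at line 1")
  nms <- strsplit(sub("^# channels ", "", ch[1]), " ")[[1]]
  df <- read.table(text = lines[!grepl("^#", lines)], sep = "\t")
  if (ncol(df) != length(nms) + 1)
    stop("malformed spectrum file: ", ncol(df), " columns for ",
         length(nms), " channels")
  structure(list(frequency = df[[1]],
                 channels = `colnames<-`(as.matrix(df[, -1]), nms)),
            class = "spectrum1d")
}

#' Write / read a 2D spectrum as delimited text
#'
#' Long format: `omega1`, `omega3`, `value` triplets with a `#` header
#' carrying the waiting time and scheme.  Round trips to 1e-12.
#' @param s a `spectrum2d`.
#' @param path file path.
#' @export
write_spectrum2d <- function(s, path) {
  stopifnot(inherits(s, "spectrum2d"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# excitube spectrum2d",
               sprintf("# t2_fs %.8g", s$t2),
               sprintf("# scheme %s", s$scheme)), con)
  df <- expand.grid(omega1 = s$omega1, omega3 = s$omega3)
  df$value <- as.vector(s$map)
  write.table(format(df, digits = 17, trim = TRUE), con, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum2d
#' @export
read_spectrum2d <- function(path) {
  lines <- readLines(path)
  t2ln <- grep("^# t2_fs ", lines)
  schln <- grep("^# scheme ", lines)
  if (!length(t2ln) || !length(schln))
    stop("malformed spectrum2d file: missing header near line ",
         if (length(t2ln)) schln[1] %||% 1 else t2ln[1] %||% 1)
  t2 <- as.numeric(sub("^# t2_fs ", "", lines[t2ln[1]]))
  scheme <- sub("^# scheme ", "", lines[schln[1]])
  df <- read.table(text = lines[!grepl("^#", lines)], sep = "\t")
  o1 <- sort(unique(df[[1]]))
  o3 <- sort(unique(df[[2]]))
  map <- matrix(NA_real_, length(o1), length(o3))
  map[cbind(match(df[[1]], o1), match(df[[2]], o3))] <- df[[3]]
  structure(list(omega1 = o1, omega3 = o3, map = map, t2 = t2,
                 scheme = scheme),
            class = "spectrum2d")
}
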