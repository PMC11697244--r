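#' Directory-based acquisition container
#'
#' A sweep stack and its derived products are stored in one directory:
#' `meta.json` (grid, sweep, noise and mode metadata), `data.csv` (pixels
#' by acquisitions, depth-major rows), `thetas.csv`, `energies.csv`,
#' `truth/` (the generating phantom maps, when simulated), and the
#' `spectral/` and `estimate/` groups written by the analysis stages. All
#' files are plain text.
#'
#' @name container
NULL

write_matrix_csv <- function(m, path) {
  data.table::fwrite(data.table::as.data.table(m), path)
  invisible(path)
}

read_matrix_csv <- function(path) {
  m <- as.matrix(data.table::fread(path))
  dimnames(m) <- NULL
  m
}

#' Write a sweep stack to a container directory
#'
#' @param stack a `sweep_stack`.
#' @param dir container directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_stack_container <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- stack$grid
  T <- length(stack$thetas)
  meta <- list(format = "dspai-container-1",
               grid = unclass(g)[c("n_depth", "n_lateral", "dz", "dx")],
               units = list(length = "cm", angle = "deg"),
               mode = stack$mode, mus_prime = stack$mus_prime,
               sweep = unclass(stack$sweep),
               noise = if (!is.null(stack$noise))
                 unclass(stack$noise)[c("additive_sigma", "energy_jitter_cv", "seed")],
               n_acquisitions = T)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_matrix_csv(matrix(stack$data, g$n_depth * g$n_lateral, T),
                   file.path(dir, "data.csv"))
  utils::write.csv(data.frame(theta = stack$thetas, energy = stack$energies),
                   file.path(dir, "acquisitions.csv"), row.names = FALSE)
  if (!is.null(stack$truth)) {
    td <- file.path(dir, "truth")
    dir.create(td, showWarnings = FALSE)
    write_matrix_csv(stack$truth$mu_a_mean_map, file.path(td, "mu_a_mean.csv"))
    write_matrix_csv(stack$truth$delta_mu_a_map, file.path(td, "delta_mu_a.csv"))
    write_matrix_csv(stack$truth$phi_map, file.path(td, "phi.csv"))
    cat(stack$truth$grueneisen_eta, file = file.path(td, "grueneisen_eta.txt"))
  }
  invisible(dir)
}

read_container_meta <- function(dir) {
  mp <- file.path(dir, "meta.json")
  if (!file.exists(mp))
    stop("no acquisition container at '", dir, "': run simulate first",
         call. = FALSE)
  jsonlite::read_json(mp, simplifyVector = TRUE)
}

#' Read a sweep stack from a container directory
#'
#' @param dir container directory written by [write_stack_container()].
#' @return a `sweep_stack`.
#' @export
read_stack_container <- function(dir) {
  meta <- read_container_meta(dir)
  g <- grid_spec(meta$grid$n_depth, meta$grid$n_lateral, meta$grid$dz, meta$grid$dx)
  acq <- utils::read.csv(file.path(dir, "acquisitions.csv"))
  flat <- read_matrix_csv(file.path(dir, "data.csv"))
  data <- array(flat, dim = c(g$n_depth, g$n_lateral, nrow(acq)))
  truth <- NULL
  td <- file.path(dir, "truth")
  if (dir.exists(td)) {
    ge <- as.numeric(readLines(file.path(td, "grueneisen_eta.txt"), warn = FALSE))
    truth <- structure(list(grid = g,
                            mu_a_mean_map = read_matrix_csv(file.path(td, "mu_a_mean.csv")),
                            delta_mu_a_map = read_matrix_csv(file.path(td, "delta_mu_a.csv")),
                            phi_map = read_matrix_csv(file.path(td, "phi.csv")),
                            grueneisen_eta = ge, layers = NULL),
                       class = "tissue_phantom")
  }
  sweep <- if (!is.null(meta$sweep))
    do.call(sweep_config, meta$sweep[c("theta_start", "theta_end", "theta_step",
                                       "n_averages", "fluence_0")])
  noise <- if (!is.null(meta$noise) && length(meta$noise))
    noise_config(meta$noise$additive_sigma %||% 0,
                 meta$noise$energy_jitter_cv %||% 0,
                 meta$noise$seed)
  structure(list(data = data, thetas = acq$theta, energies = acq$energy,
                 grid = g, truth = truth, sweep = sweep, noise = noise,
                 mode = meta$mode, mus_prime = meta$mus_prime %||% 0),
            class = "sweep_stack")
}

#' Write spectral maps into a container's `spectral/` group
#' @param spectral a `spectral_maps`.
#' @param dir container directory.
#' @return `dir`, invisibly.
#' @export
write_spectral_group <- function(spectral, dir) {
  sd <- file.path(dir, "spectral")
  dir.create(sd, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("p_mean", "h1_amp", "h1_phase", "h2_amp", "h2_phase", "xi"))
    write_matrix_csv(spectral[[nm]], file.path(sd, paste0(nm, ".csv")))
  jsonlite::write_json(list(n_cycles = spectral$n_cycles,
                            n_samples = spectral$n_samples,
                            units = list(phase = "deg, doubled-angle")),
                       file.path(sd, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read spectral maps from a container's `spectral/` group
#' @param dir container directory.
#' @return a `spectral_maps`.
#' @export
read_spectral_group <- function(dir) {
  stack_meta <- read_container_meta(dir)
  g <- grid_spec(stack_meta$grid$n_depth, stack_meta$grid$n_lateral,
                 stack_meta$grid$dz, stack_meta$grid$dx)
  sd <- file.path(dir, "spectral")
  if (!dir.exists(sd)) stop("container has no spectral group: run analyze first",
                            call. = FALSE)
  meta <- jsonlite::read_json(file.path(sd, "meta.json"), simplifyVector = TRUE)
  maps <- lapply(c("p_mean", "h1_amp", "h1_phase", "h2_amp", "h2_phase", "xi"),
                 function(nm) read_matrix_csv(file.path(sd, paste0(nm, ".csv"))))
  names(maps) <- c("p_mean", "h1_amp", "h1_phase", "h2_amp", "h2_phase", "xi")
  truth <- read_stack_truth(dir, g)
  structure(c(maps, list(n_cycles = meta$n_cycles, n_samples = meta$n_samples,
                         grid = g, truth = truth,
                         mode = stack_meta$mode)),
            class = "spectral_maps")
}

read_stack_truth <- function(dir, g) {
  td <- file.path(dir, "truth")
  if (!dir.exists(td)) return(NULL)
  ge <- as.numeric(readLines(file.path(td, "grueneisen_eta.txt"), warn = FALSE))
  structure(list(grid = g,
                 mu_a_mean_map = read_matrix_csv(file.path(td, "mu_a_mean.csv")),
                 delta_mu_a_map = read_matrix_csv(file.path(td, "delta_mu_a.csv")),
                 phi_map = read_matrix_csv(file.path(td, "phi.csv")),
                 grueneisen_eta = ge, layers = NULL),
            class = "tissue_phantom")
}

#' Write estimate maps into a container's `estimate/` group
#' @param est an `estimate_maps`.
#' @param dir container directory.
#' @return `dir`, invisibly.
#' @export
write_estimate_group <- function(est, dir) {
  ed <- file.path(dir, "estimate")
  dir.create(ed, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("phi_map", "psi_map", "alpha_map", "beta_map",
               "objective_map"))
    write_matrix_csv(est[[nm]], file.path(ed, paste0(nm, ".csv")))
  write_matrix_csv(est$valid * 1L, file.path(ed, "valid.csv"))
  write_matrix_csv(est$scenario_map, file.path(ed, "scenario.csv"))
  if (!is.null(est$phi_interp))
    write_matrix_csv(est$phi_interp, file.path(ed, "phi_interp.csv"))
  jsonlite::write_json(list(config = unclass(est$config),
                            units = list(angle = "deg")),
                       file.path(ed, "meta.json"), auto_unbox = TRUE,
                       null = "null")
  invisible(dir)
}

#' Read estimate maps from a container's `estimate/` group
#' @param dir container directory.
#' @return an `estimate_maps`.
#' @export
read_estimate_group <- function(dir) {
  stack_meta <- read_container_meta(dir)
  g <- grid_spec(stack_meta$grid$n_depth, stack_meta$grid$n_lateral,
                 stack_meta$grid$dz, stack_meta$grid$dx)
  ed <- file.path(dir, "estimate")
  if (!dir.exists(ed)) stop("container has no estimate group: run recover first",
                            call. = FALSE)
  maps <- lapply(c("phi_map", "psi_map", "alpha_map", "beta_map",
                   "objective_map"),
                 function(nm) read_matrix_csv(file.path(ed, paste0(nm, ".csv"))))
  names(maps) <- c("phi_map", "psi_map", "alpha_map", "beta_map", "objective_map")
  valid <- read_matrix_csv(file.path(ed, "valid.csv")) > 0
  scen <- read_matrix_csv(file.path(ed, "scenario.csv"))
  pi_path <- file.path(ed, "phi_interp.csv")
  phi_interp <- if (file.exists(pi_path)) read_matrix_csv(pi_path)
  structure(c(maps, list(valid = valid, scenario_map = scen,
                         phi_interp = phi_interp, grid = g,
                         truth = read_stack_truth(dir, g), config = NULL)),
            class = "estimate_maps")
}

# Reproducibility manifest: configuration, seed and versions of every run.
write_manifest <- function(dir, command, config, seed = NULL) {
  jsonlite::write_json(
    list(command = command, config = config, seed = seed,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         r_version = R.version.string,
         package_version = as.character(utils::packageVersion("dspai"))),
    file.path(dir, paste0("manifest_", command, ".json")),
    auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  invisible(dir)
}
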