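#' Validate a pipeline run configuration
#'
#' Configurations are flat named lists (usually read from YAML). Unknown
#' keys are rejected and every stochastic stage requires an explicit
#' `seed`, so a config fully determines its outputs.
#'
#' @param config named list (see [run_pipeline()] for the keys).
#' @return the config, with defaults filled in.
#' @export
validate_config <- function(config) {
  known <- c("stages", "seed", "output_dir", "n_specimens", "bvtv_range",
             "spacing", "shape", "true_conversion_factor", "noise_sd_frac",
             "edge_length", "edge_length_push", "mu_true", "mu_grid_bb",
             "mu_grid_cb", "n_push_pairs", "flexion", "cases", "axial_load",
             "pitch", "threshold", "downsample_factor", "stiffness_window",
             "push_steps", "joint_steps")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (is.null(config$seed))
    stop("config validation: `seed` is required")
  if (is.null(config$stages)) stop("config validation: `stages` is required")
  defaults <- list(output_dir = "ocgraft_run", n_specimens = 4L,
                   bvtv_range = c(0.45, 0.82), spacing = 0.164,
                   shape = c(40L, 40L, 64L), true_conversion_factor = 100.5,
                   noise_sd_frac = 0, edge_length = 1.0,
                   edge_length_push = 1.8, mu_true = c(0.6, 0.3),
                   mu_grid_bb = c(0.3, 0.6, 0.9),
                   mu_grid_cb = c(0.1, 0.3, 0.5), n_push_pairs = 3L,
                   flexion = 0, cases = list(medial = "intact",
                                             lateral = "intact"),
                   axial_load = 500, pitch = 1.27, threshold = 0.5,
                   downsample_factor = NULL,
                   stiffness_window = c(50, 80),
                   push_steps = 4L, joint_steps = 5L)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  config
}

#' Run the pipeline stages of a configuration
#'
#' Realises the three experiment arms as named stages:
#' \describe{
#'   \item{phantom}{generate the trabecular phantom specimens and write
#'     them out (MetaImage + provenance YAML).}
#'   \item{map_calibrate}{virtual compression of every specimen, noisy
#'     pseudo-observations from the forward model, conversion-factor
#'     calibration by stiffness RMS error.}
#'   \item{friction_calibrate}{forward push-in tests at the true friction
#'     pair, pseudo-observations, CCC grid search.}
#'   \item{joint}{one tibiofemoral scenario; writes the sensel pressure
#'     map and compartment summary.}
#' }
#' Stages run in dependency order; a manifest records the config, seeds
#' and per-output checksums so identical configs reproduce identical
#' outputs.
#'
#' @param config named list or path to a YAML file.
#' @return (invisibly) list of stage results; files under
#'   `config$output_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  stages <- config$stages
  seed <- as.integer(config$seed)

  bvtvs <- seq(config$bvtv_range[1], config$bvtv_range[2],
               length.out = config$n_specimens)
  make_specimens <- function() {
    lapply(seq_along(bvtvs), function(i)
      generate_condyle_specimen(
        trabecular_params(bvtvs[i], seed = seed + i),
        endcap_thickness = 2, shape = config$shape,
        spacing = config$spacing))
  }

  if ("phantom" %in% stages) {
    specs <- make_specimens()
    for (i in seq_along(specs)) {
      write_mha(specs[[i]]$micro,
                file.path(config$output_dir,
                          sprintf("phantom_%02d.mha", i)))
      write_provenance(c(unclass(specs[[i]]$params),
                         list(shape = config$shape,
                              spacing = config$spacing)),
                       file.path(config$output_dir,
                                 sprintf("phantom_%02d.yaml", i)))
    }
    out$phantom <- list(n = length(specs), bvtv = bvtvs)
  }

  if ("map_calibrate" %in% stages) {
    specs <- make_specimens()
    preps <- lapply(specs, prepare_compression_model,
                    settings = mesh_settings(config$edge_length),
                    threshold = config$threshold)
    protocol <- compression_protocol(window = config$stiffness_window)
    map_true <- material_map(config$true_conversion_factor)
    k_true <- vapply(preps, function(p)
      run_compression_test(p, map_true, protocol)$stiffness, numeric(1))
    obs <- generate_pseudo_observations(
      k_true, noise_sd = config$noise_sd_frac * mean(k_true),
      seed = seed + 100L, unit = "N/mm")
    cal <- calibrate_conversion_factor(preps, obs$value,
                                       protocol = protocol)
    utils::write.csv(obs, file.path(config$output_dir,
                                    "stiffness_observations.csv"),
                     row.names = FALSE)
    utils::write.csv(cal$trace, file.path(config$output_dir,
                                          "conversion_trace.csv"),
                     row.names = FALSE)
    yaml::write_yaml(list(conversion_factor = cal$conversion_factor,
                          rms_percent_error = cal$objective,
                          true_conversion_factor =
                            config$true_conversion_factor),
                     file.path(config$output_dir, "map_calibration.yaml"))
    out$map_calibrate <- cal
  }

  if ("friction_calibrate" %in% stages) {
    geomg <- graft_geometry()
    hostv <- seq(0.45, 0.8, length.out = config$n_push_pairs)
    graftv <- seq(0.8, 0.6, length.out = config$n_push_pairs)
    pairs <- lapply(seq_len(config$n_push_pairs), function(i)
      generate_graft_host_pair(
        trabecular_params(hostv[i], seed = seed + 200L + i),
        trabecular_params(graftv[i], seed = seed + 300L + i),
        geomg, spacing = config$spacing))
    map <- material_map(config$true_conversion_factor)
    prot_true <- push_in_protocol(mu_bone_bone = config$mu_true[1],
                                  mu_cartilage_bone = config$mu_true[2])
    st <- mesh_settings(config$edge_length_push)
    f_true <- vapply(pairs, function(p) {
      pim <- build_push_in_model(p, map, prot_true, st,
                                 materials = linearised_materials())
      run_push_in_test(pim, prot_true,
                       n_steps = config$push_steps)$force_at_full
    }, numeric(1))
    obs <- generate_pseudo_observations(
      f_true, noise_sd = config$noise_sd_frac * mean(f_true),
      seed = seed + 400L)
    grid <- expand.grid(mu_bb = config$mu_grid_bb,
                        mu_cb = config$mu_grid_cb)
    cal <- calibrate_friction(pairs, obs$value, grid = grid, map = map,
                              settings = st, n_steps = config$push_steps)
    utils::write.csv(cal$ccc_table,
                     file.path(config$output_dir, "ccc_grid.csv"),
                     row.names = FALSE)
    yaml::write_yaml(list(mu_bone_bone = cal$mu_bone_bone,
                          mu_cartilage_bone = cal$mu_cartilage_bone,
                          ccc = cal$objective,
                          mu_true = config$mu_true),
                     file.path(config$output_dir,
                               "friction_calibration.yaml"))
    out$friction_calibrate <- cal
  }

  if ("joint" %in% stages) {
    sc <- joint_scenario(config$flexion, config$cases, config$axial_load)
    res <- run_joint_scenario(sc, joint_geometry(),
                              n_steps = config$joint_steps,
                              pitch = config$pitch,
                              settings = mesh_settings(1.5),
                              mu = config$mu_true)
    write_pressure_map(res$map,
                       file.path(config$output_dir, "pressure_map.csv"))
    comp <- data.frame(
      compartment = names(res$compartments),
      force_N = vapply(res$compartments, function(x) x$force, numeric(1)),
      area_mm2 = vapply(res$compartments, function(x) x$area_loaded,
                        numeric(1)),
      peak_MPa = vapply(res$compartments, function(x) x$peak_pressure,
                        numeric(1)))
    utils::write.csv(comp, file.path(config$output_dir,
                                     "compartments.csv"),
                     row.names = FALSE)
    out$joint <- res
  }

  # manifest: config echo + checksums of everything written
  files <- setdiff(list.files(config$output_dir, full.names = TRUE),
                   file.path(config$output_dir, "manifest.yaml"))
  manifest <- list(config = config,
                   files = as.list(tools::md5sum(files)))
  yaml::write_yaml(manifest, file.path(config$output_dir, "manifest.yaml"))
  invisible(out)
}
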