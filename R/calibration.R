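#' Lin's concordance correlation coefficient
#'
#' Agreement statistic combining precision (correlation) and accuracy
#' (location/scale shift):
#' `CCC = 2 cov(x,y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`,
#' with population (1/n) moments. Equals 1 iff the two vectors are
#' identical (and non-constant); always `|CCC| <= |Pearson r|`.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return scalar in \[-1, 1\].
#' @export
ccc <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs")
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom == 0)
    stop("degenerate input: both variances and the mean difference are zero")
  2 * cxy / denom
}

#' Root-mean-square percentage error
#'
#' `sqrt(mean(((pred - obs)/obs)^2)) * 100`, the objective of the
#' stiffness-based conversion-factor calibration.
#'
#' @param predicted,observed numeric vectors of equal length >= 1;
#'   `observed` must be non-zero.
#' @return percentage (>= 0).
#' @export
rms_percent_error <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("`predicted` and `observed` must have equal length")
  if (any(observed == 0)) stop("observed values must be non-zero")
  sqrt(mean(((predicted - observed) / observed)^2)) * 100
}

#' Squared Pearson correlation between site BV/TV and force
#'
#' @param bvtv,force numeric vectors of equal length >= 3.
#' @return r^2 in \[0, 1\].
#' @export
bvtv_force_correlation <- function(bvtv, force) {
  if (length(bvtv) != length(force)) stop("inputs must have equal length")
  if (length(bvtv) < 3) stop("need at least 3 pairs")
  if (stats::sd(bvtv) == 0 || stats::sd(force) == 0)
    stop("zero variance in input")
  stats::cor(bvtv, force)^2
}

#' Calibrate the BV/TV-to-modulus conversion factor
#'
#' One-dimensional bounded minimisation of the stiffness RMS percentage
#' error over the conversion factor `c`, each evaluation running the
#' virtual platen compression of every specimen. Compression models are
#' prepared once and reused across evaluations.
#'
#' @param specimens list of `oc_specimen`s (or prepared models from
#'   [prepare_compression_model()]).
#' @param observed observed stiffnesses, N/mm (one per specimen), e.g. a
#'   pseudo-observation table's `value` column.
#' @param bounds search interval for `c`, MPa (default c(10, 1000),
#'   bracketing literature values for human trabecular bone).
#' @param protocol a [compression_protocol()].
#' @param map_template [material_map()] supplying floor and Poisson ratio.
#' @param tol relative convergence tolerance of the golden-section search.
#' @return `calibration_result`: list with `conversion_factor` (MPa),
#'   `objective` (RMS %), `table` (predicted vs observed), `trace`
#'   (every evaluated candidate).
#' @export
calibrate_conversion_factor <- function(specimens, observed,
                                        bounds = c(10, 1000),
                                        protocol = compression_protocol(),
                                        map_template = material_map(),
                                        tol = 1e-3) {
  if (length(specimens) < 1) stop("need at least one specimen")
  if (length(observed) != length(specimens))
    stop("one observation per specimen required")
  if (any(bounds <= 0)) stop("bounds must be positive")
  preps <- lapply(specimens, function(s)
    if (inherits(s, "oc_specimen")) prepare_compression_model(s) else s)
  trace_c <- numeric(0); trace_obj <- numeric(0)
  predict_all <- function(cf) {
    map <- material_map(cf, map_template$modulus_floor,
                        map_template$poisson_ratio)
    # candidates far from the optimum routinely leave the stiffness
    # window; the attained-range fallback is intended during the sweep
    suppressWarnings(vapply(preps, function(p)
      run_compression_test(p, map, protocol)$stiffness, numeric(1)))
  }
  objective <- function(cf) {
    obj <- rms_percent_error(predict_all(cf), observed)
    trace_c <<- c(trace_c, cf); trace_obj <<- c(trace_obj, obj)
    obj
  }
  if (!is.finite(objective(bounds[1])) && !is.finite(objective(bounds[2])))
    stop("objective non-finite at both bounds")
  opt <- stats::optimize(objective, interval = bounds,
                         tol = tol * diff(bounds))
  pred <- predict_all(opt$minimum)
  structure(list(conversion_factor = opt$minimum,
                 objective = opt$objective,
                 table = data.frame(specimen = seq_along(observed),
                                    predicted = pred, observed = observed),
                 trace = data.frame(conversion_factor = trace_c,
                                    objective = trace_obj)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  if (!is.null(x$conversion_factor))
    cat(sprintf("<calibration_result> c = %.4g MPa, RMS error %.3g%%\n",
                x$conversion_factor, x$objective))
  else
    cat(sprintf("<calibration_result> mu = (%.2g, %.2g), CCC = %.4g\n",
                x$mu_bone_bone, x$mu_cartilage_bone, x$objective))
  invisible(x)
}

#' Calibrate the friction pair by concordance grid search
#'
#' For every candidate `(mu_bone_bone, mu_cartilage_bone)` pair, runs all
#' push-in simulations and computes Lin's CCC between model forces and
#' observed forces; returns the arg-max pair. Ties break toward the
#' smaller pair (lexicographic). Non-convergent cells are marked failed
#' and excluded with a warning.
#'
#' @param pairs list of graft/host pairs from [generate_graft_host_pair()].
#' @param observed observed push-in forces, N (one per pair).
#' @param grid data.frame with columns `mu_bb`, `mu_cb`; default the
#'   0.1-stepped rectangle mu_bb in 0.1..0.9, mu_cb in 0.1..0.7.
#' @param map a [material_map()].
#' @param settings a [mesh_settings()] for the push-in models.
#' @param materials region materials (linearised cartilage by default:
#'   strains in these tests stay small and the calibration sweep is large).
#' @param n_steps push increments per simulation.
#' @param protocol_template [push_in_protocol()] supplying indenter size
#'   and displacement.
#' @return `calibration_result` with `mu_bone_bone`, `mu_cartilage_bone`,
#'   `objective` (best CCC), `ccc_table` (full grid), `forces` (model
#'   forces at the optimum).
#' @export
calibrate_friction <- function(pairs, observed,
                               grid = expand.grid(
                                 mu_bb = seq(0.1, 0.9, by = 0.1),
                                 mu_cb = seq(0.1, 0.7, by = 0.1)),
                               map = material_map(),
                               settings = mesh_settings(1.5),
                               materials = linearised_materials(),
                               n_steps = 4L,
                               protocol_template = push_in_protocol()) {
  if (length(pairs) < 3) stop("need at least 3 push-in cases")
  if (nrow(grid) < 1) stop("empty friction grid")
  if (length(observed) != length(pairs))
    stop("one observation per push-in case required")
  results <- data.frame(mu_bb = grid$mu_bb, mu_cb = grid$mu_cb,
                        ccc = NA_real_, failed = FALSE)
  force_tab <- matrix(NA_real_, nrow(grid), length(pairs))
  for (g in seq_len(nrow(grid))) {
    prot <- push_in_protocol(protocol_template$indenter_diameter,
                             protocol_template$displacement,
                             mu_bone_bone = grid$mu_bb[g],
                             mu_cartilage_bone = grid$mu_cb[g])
    forces <- rep(NA_real_, length(pairs))
    ok <- TRUE
    for (p in seq_along(pairs)) {
      res <- tryCatch({
        pim <- build_push_in_model(pairs[[p]], map, prot, settings,
                                   materials = materials)
        run_push_in_test(pim, prot, n_steps = n_steps)$force_at_full
      }, error = function(e) e)
      if (inherits(res, "error")) { ok <- FALSE; break }
      forces[p] <- res
    }
    if (!ok) {
      results$failed[g] <- TRUE
      warning(sprintf("grid cell (%.2g, %.2g) failed and was excluded",
                      grid$mu_bb[g], grid$mu_cb[g]))
      next
    }
    force_tab[g, ] <- forces
    results$ccc[g] <- ccc(forces, observed)
  }
  valid <- which(!results$failed)
  if (!length(valid)) stop("every friction grid cell failed")
  # arg-max CCC; ties toward the smaller (mu_bb, mu_cb) lexicographically
  ord <- valid[order(-results$ccc[valid], results$mu_bb[valid],
                     results$mu_cb[valid])]
  best <- ord[1]
  structure(list(mu_bone_bone = results$mu_bb[best],
                 mu_cartilage_bone = results$mu_cb[best],
                 objective = results$ccc[best],
                 ccc_table = results,
                 forces = force_tab[best, ],
                 observed = observed),
            class = "calibration_result")
}
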