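# End-to-end experiment recipes: build the phantom, reconstruct, evaluate,
# and write a run manifest with configuration, seeds and output checksums.

#' Named end-to-end experiments
#'
#' Reproducible recipes combining the phantom, the reconstructions and the
#' evaluation metrics:
#' \describe{
#'   \item{`"fig3a_ns_sweep"`}{CV of the smallest/weakest vein ROI as a
#'     function of the early-stopping count `n_s` in 1..10 (argmin rule).}
#'   \item{`"fig3bc_kth_sweep"`}{CV of the smallest-vein ROI and mean
#'     susceptibility of the largest-diameter veins versus `k_th`;
#'     selection by the smallest `k_th` whose large-vein mean has dropped
#'     by at most 10% relative to the no-replacement reconstruction.}
#'   \item{`"fig4_artifacts"`}{TKD / MEDI-style / MUDICK maps and their
#'     artifact-ROI means near the largest nucleus.}
#'   \item{`"fig6_vein_accuracy"`}{vein-ROI means, SDs and calculation
#'     errors for the three methods against the reference map.}
#'   \item{`"lambda_sweep"`}{RMSE of the regularized map against the
#'     reference over the `lambda` grid `10^(-3..0)` in factor-`10^0.25`
#'     steps (argmin rule).}
#'   \item{`"tkd_threshold_sweep"`}{TKD RMSE over thresholds 0.05..0.40
#'     (step 0.01), minimized subject to a nucleus regression slope > 0.8.}
#' }
#'
#' @param name experiment identifier (see above).
#' @param config `NULL` for defaults, a YAML path, or a list as returned
#'   by [load_config()].
#' @param seed integer seed for the simulated noise.
#' @param out_dir output directory (created if needed); NIfTI maps and a
#'   JSON manifest are written there.
#' @param full if `TRUE` (and no phantom config is given), run on the
#'   full-size 800 x 640 x 640 phantom instead of the scaled one.
#' @return The run manifest, invisibly: configuration snapshot, seed,
#'   per-stage timings, results, and output files with MD5 checksums.
#' @export
run_experiment <- function(name = c("fig3a_ns_sweep", "fig3bc_kth_sweep",
                                    "fig4_artifacts", "fig6_vein_accuracy",
                                    "lambda_sweep", "tkd_threshold_sweep"),
                           config = NULL, seed = 1L,
                           out_dir = tempfile("mudick-run-"),
                           full = FALSE) {
  name <- match.arg(name)
  if (is.character(config)) config <- load_config(config)
  if (is.null(config)) {
    config <- list(phantom = phantom_spec(full = full),
                   recon = recon_config())
  }
  spec <- config$phantom
  cfg <- config$recon
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  timings <- list()
  clock <- function(label, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    timings[[label]] <<- proc.time()[["elapsed"]] - t0
    val
  }

  sim <- clock("simulate", simulate_acquisition(spec, seed = seed))
  delta <- vol_like(vol_data(sim$delta) * sim$brain_mask, sim$delta)
  w <- sim$brain_mask
  kernel <- make_dipole_kernel(dim(vol_data(delta)), vox_of(sim$delta))
  outputs <- character(0)
  results <- list()

  save_map <- function(v, file) {
    p <- file.path(out_dir, file)
    write_volume(as_vol3d(vol_data(v), vox_of(sim$delta)), p)
    outputs <<- c(outputs, p)
  }
  small_key <- "d0.25_chi0.10"
  pooled_large <- function(rois) {
    unique(unlist(rois$vein[startsWith(names(rois$vein), "d0.70")]))
  }

  if (name == "fig3a_ns_sweep") {
    chi_l <- clock("chi_l", wls_cg(delta, w, kernel, cfg$n_l))
    sweep <- clock("sweep", sweep_parameter(function(ns) {
      cfg_i <- cfg
      cfg_i$n_s <- as.integer(ns)
      chi <- mudick(delta, w, cfg_i, kernel, chi_l = chi_l)
      cv(chi, sim$rois$vein[[small_key]])
    }, grid = 1:10, rule = "argmin"))
    results$sweep <- sweep
  } else if (name == "fig3bc_kth_sweep") {
    chi_l <- clock("chi_l", wls_cg(delta, w, kernel, cfg$n_l))
    chi_s <- wls_cg(delta, w, kernel, cfg$n_s)
    edges <- build_edge_masks(chi_s, w > 0, cfg$alpha_rule)
    m_nma <- make_magic_angle_mask(kernel, cfg$m_th)
    chi_p <- clock("chi_prime",
                   solve_masked_l1(chi_l, m_nma, edges, cfg$lambda, cfg))
    large <- pooled_large(sim$rois)
    baseline <- mean(vol_data(chi_p)[large]) # m_H == 0: no replacement
    grid <- seq(0.2, 1.4, by = 0.2)
    eval_kth <- function(kth) {
      m_h <- make_highfreq_weight(dim(vol_data(delta)), vox_of(sim$delta),
                                  kth, cfg$k_cur, cfg$kth_scale)
      chi <- combine_highfreq(chi_p, chi_s, m_h)
      list(metric = mean(vol_data(chi)[large]),
           constraint = cv(chi, sim$rois$vein[[small_key]]))
    }
    sweep <- clock("sweep", sweep_parameter(
      eval_kth, grid, rule = "smallest_within_decrease",
      baseline = baseline, max_decrease = 0.1))
    results$sweep <- sweep
    results$baseline_mean <- baseline
  } else if (name %in% c("fig4_artifacts", "fig6_vein_accuracy")) {
    chi_tkd <- clock("tkd", tkd_invert(delta, kernel, cfg$tkd_threshold,
                                       cfg$tkd_mode))
    chi_medi <- clock("medi", medi_baseline(delta, w, sim$magnitude,
                                            cfg$medi_lambda, cfg, kernel))
    chi_mud <- clock("mudick", mudick(delta, w, cfg, kernel))
    save_map(chi_tkd, "chi_tkd.nii.gz")
    save_map(chi_medi, "chi_medi.nii.gz")
    save_map(chi_mud, "chi_mudick.nii.gz")
    maps <- list(TKD = chi_tkd, MEDI = chi_medi, MUDICK = chi_mud)
    if (name == "fig4_artifacts") {
      results$artifact_means <- data.frame(
        method = names(maps),
        roi_a = vapply(maps, function(m) {
          mean(vol_data(m)[sim$rois$artifact$A])
        }, numeric(1)),
        roi_b = vapply(maps, function(m) {
          mean(vol_data(m)[sim$rois$artifact$B])
        }, numeric(1)),
        row.names = NULL
      )
    } else {
      results$vein_stats <- lapply(maps, roi_stats, rois = sim$rois,
                                   reference = sim$reference)
    }
  } else if (name == "lambda_sweep") {
    chi_l <- clock("chi_l", wls_cg(delta, w, kernel, cfg$n_l))
    chi_s <- wls_cg(delta, w, kernel, cfg$n_s)
    edges <- build_edge_masks(chi_s, w > 0, cfg$alpha_rule)
    m_nma <- make_magic_angle_mask(kernel, cfg$m_th)
    grid <- 10^seq(-3, 0, by = 0.25)
    sweep <- clock("sweep", sweep_parameter(function(lam) {
      chi_p <- solve_masked_l1(chi_l, m_nma, edges, lam, cfg)
      rmse(chi_p, sim$reference, sim$brain_mask)
    }, grid, rule = "argmin"))
    results$sweep <- sweep
  } else if (name == "tkd_threshold_sweep") {
    grid <- seq(0.05, 0.40, by = 0.01)
    sweep <- clock("sweep", sweep_parameter(function(thr) {
      chi <- tkd_invert(delta, kernel, thr, cfg$tkd_mode)
      list(metric = rmse(chi, sim$reference, sim$brain_mask),
           constraint = regression_slope(chi, sim$reference,
                                         sim$rois$nucleus))
    }, grid, rule = "argmin_constrained", constraint_min = 0.8))
    results$sweep <- sweep
  }

  manifest <- list(
    experiment = name,
    package = "mudick",
    version = as.character(utils::packageVersion("mudick")),
    seed = as.integer(seed),
    config = list(
      phantom = spec[c("n", "voxel_size", "shrink", "b0", "te", "snr")],
      recon = unclass(cfg)
    ),
    timings = timings,
    results = results,
    outputs = if (length(outputs)) {
      data.frame(file = basename(outputs),
                 md5 = unname(tools::md5sum(outputs)))
    } else NULL
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(strip_classes(manifest), manifest_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

# recursively drop S3 classes so jsonlite serializes plain structures
strip_classes <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) {
    x <- unclass(x)
    x[!vapply(x, is.null, logical(1))] <- lapply(
      x[!vapply(x, is.null, logical(1))], strip_classes)
    return(x)
  }
  x
}
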