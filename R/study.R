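#' Configuration of the synthetic six-arm study
#'
#' Mirrors a two-protocol, three-reconstruction chest-CT comparison on
#' synthetic data. The six arms are the crossing of two acquisition
#' protocols -- a full-dose protocol and an ultra-low-dose (ULD)
#' protocol with substantially higher noise -- with three
#' reconstruction styles:
#'
#' * `asirv` -- hybrid-iterative-like: sharp kernel, high noise
#'   (band-pass spectrum peaked at mid frequency);
#' * `dlir`  -- deep-learning-like: smooth kernel, low noise
#'   (low-pass spectrum);
#' * `dlir_e2` -- `dlir` followed by unsharp-mask edge enhancement.
#'
#' Noise magnitudes: `sigma_asirv` and `sigma_dlir` are the full-dose
#' noise SDs in HU; the ULD arms share the spectral shapes but use a
#' relative dose `uld_noise_dose` chosen so the noise scales like the
#' protocols' noise-index ratio (default `(31/85)^2 ~ 0.133`, i.e.
#' noise 2.74x higher). Dose records are drawn around mean DLPs that
#' correspond to 2.5 mSv (full dose) and 0.05 mSv (ULD) through the
#' chest coefficient 0.015 mSv/(mGy cm).
#'
#' Observer ratings compare `dlir` (test) against `asirv` (reference)
#' within each protocol, with a larger latent benefit for the ULD
#' protocol (`delta_uld > delta_full`), emulating denoising being most
#' valuable where noise is worst.
#'
#' @param n_patients Patients per protocol (paired across arms).
#' @param image_size,pixel_spacing,n_slices Phantom geometry per
#'   examination.
#' @param sigma_asirv,sigma_dlir Full-dose noise SDs (HU).
#' @param uld_noise_dose Relative dose governing ULD noise scaling.
#' @param blur_sharp,blur_smooth In-plane system/reconstruction
#'   resolution (Gaussian PSF SD, mm) of the sharp- and smooth-kernel
#'   arms; applied to the noiseless anatomy so edges are not perfect
#'   steps, as in any real reconstruction. The sharp kernel resolves
#'   better (smaller PSF) at the price of its higher noise.
#' @param edge_gain,edge_radius Unsharp-mask parameters of the
#'   `dlir_e2` arm.
#' @param patient_noise_cv Log-normal coefficient of variation of a
#'   per-patient noise multiplier, emulating habitus-driven noise
#'   differences between patients; the multiplier is shared by every
#'   arm of a patient (one acquisition feeds all reconstructions).
#'   With the default 0.15 the cohort power-spectrum relative standard
#'   error comes out at a few percent for 25 patients, the order seen
#'   in patient cohorts.
#' @param delta_full,delta_uld Latent rating shifts (test vs
#'   reference) per protocol.
#' @param rating_model A [latent_rating_model()] supplying the
#'   variance components and thresholds (its `delta` is overridden per
#'   protocol).
#' @param n_boot Bootstrap replicates for the VGC stage.
#' @param seed Global seed; all stage seeds derive from it.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_patients = 25, image_size = 512,
                         pixel_spacing = 0.75, n_slices = 6,
                         sigma_asirv = 35, sigma_dlir = 12,
                         uld_noise_dose = (31 / 85)^2,
                         blur_sharp = 0.6, blur_smooth = 1.0,
                         edge_gain = 0.6, edge_radius = 1.0,
                         patient_noise_cv = 0.15,
                         delta_full = 0.6, delta_uld = 1.0,
                         rating_model = latent_rating_model(),
                         n_boot = 2000, seed = 1) {
  check_scalar_num(n_patients, "n_patients", positive = TRUE)
  structure(
    list(n_patients = as.integer(n_patients), image_size = image_size,
         pixel_spacing = pixel_spacing, n_slices = n_slices,
         sigma_asirv = sigma_asirv, sigma_dlir = sigma_dlir,
         uld_noise_dose = uld_noise_dose,
         blur_sharp = blur_sharp, blur_smooth = blur_smooth,
         edge_gain = edge_gain, edge_radius = edge_radius,
         patient_noise_cv = patient_noise_cv,
         delta_full = delta_full, delta_uld = delta_uld,
         rating_model = rating_model,
         n_boot = n_boot, seed = as.integer(seed)),
    class = "study_config")
}

## Per-patient, arm-independent anatomy jitter and habitus noise multiplier.
## The same acquisition feeds every reconstruction of a patient, so these are
## deliberately shared across arms.
patient_geometry <- function(config, patient) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(derive_seed(config$seed, paste0("patient/", patient)))
  list(vessel_shift = stats::runif(2, -3, 3),
       noise_mult = exp(stats::rnorm(1, 0, config$patient_noise_cv)))
}

study_arms <- function(config) {
  list(
    full_asirv   = list(protocol = "full_dose", recon = "asirv",
                        shape = "sharp_kernel", sigma = config$sigma_asirv,
                        dose = 1, edge = FALSE),
    full_dlir    = list(protocol = "full_dose", recon = "dlir",
                        shape = "smooth_kernel", sigma = config$sigma_dlir,
                        dose = 1, edge = FALSE),
    full_dlir_e2 = list(protocol = "full_dose", recon = "dlir_e2",
                        shape = "smooth_kernel", sigma = config$sigma_dlir,
                        dose = 1, edge = TRUE),
    uld_asirv    = list(protocol = "uld", recon = "asirv",
                        shape = "sharp_kernel", sigma = config$sigma_asirv,
                        dose = config$uld_noise_dose, edge = FALSE),
    uld_dlir     = list(protocol = "uld", recon = "dlir",
                        shape = "smooth_kernel", sigma = config$sigma_dlir,
                        dose = config$uld_noise_dose, edge = FALSE),
    uld_dlir_e2  = list(protocol = "uld", recon = "dlir_e2",
                        shape = "smooth_kernel", sigma = config$sigma_dlir,
                        dose = config$uld_noise_dose, edge = TRUE)
  )
}

#' Generate one synthetic examination arm
#'
#' Builds the per-patient phantom (vessel placement jittered by
#' patient), adds arm-specific shaped noise, and applies edge
#' enhancement for the `*_e2` arms. All randomness derives from the
#' global seed, the arm name and the patient index.
#'
#' @param config A [study_config()].
#' @param arm_name One of the six arm names (e.g. `"full_dlir"`).
#' @param patient Patient index in `1..n_patients`.
#' @return A `ct_stack` labelled with protocol/reconstruction/patient.
#' @export
simulate_arm <- function(config, arm_name, patient) {
  arms <- study_arms(config)
  arm <- arms[[arm_name]]
  if (is.null(arm)) stopf("unknown arm '%s'", arm_name)
  geo <- patient_geometry(config, patient)
  cfg <- default_phantom_config(image_size = config$image_size,
                                pixel_spacing = config$pixel_spacing,
                                n_slices = config$n_slices,
                                vessel_shift = geo$vessel_shift)
  stk <- generate_phantom_stack(cfg)
  # finite reconstruction resolution: blur the (slice-identical) anatomy once
  psf <- if (arm$shape == "sharp_kernel") config$blur_sharp else config$blur_smooth
  if (psf > 0) {
    sl <- gaussian_blur(get_slice(stk, 1), psf / config$pixel_spacing)
    stk$voxels <- array(sl, dim = dim(stk$voxels))
  }
  nm <- noise_model(arm$shape, sigma_ref = arm$sigma * geo$noise_mult,
                    dose_factor = arm$dose)
  # same noise seed for every reconstruction of a protocol+patient is NOT
  # wanted: reconstructions differ in noise realisation as well as texture
  nseed <- derive_seed(config$seed, paste0("noise/", arm_name, "/", patient))
  stk <- apply_noise(stk, nm, seed = nseed)
  if (arm$edge)
    stk <- apply_edge_enhancement(stk, gain = config$edge_gain,
                                  radius = config$edge_radius)
  stk$labels$protocol <- arm$protocol
  stk$labels$reconstruction <- arm$recon
  stk$labels$patient <- patient
  stk
}

#' Run the full synthetic study
#'
#' Executes the whole pipeline on synthetic data: for every patient
#' and arm it generates the examination, accumulates the
#' power-spectrum curve, measures aorta/fat CNR and a vessel line
#' profile; it then forms cohort PS curves, paired CNR comparisons
#' between reconstructions within each protocol, simulates the paired
#' observer study per protocol (`dlir` vs `asirv`) and analyses it
#' with fixed- and random-reader bootstrap VGC, tabulates answer
#' proportions, and summarises doses. Fully reproducible from
#' `config$seed`.
#'
#' @param config A [study_config()].
#' @param out Optional output directory; when given, curves and tables
#'   are written as CSV/JSON.
#' @param verbose Narrate stage boundaries.
#' @return An object of class `ctiq_study`: list with `ps`
#'   (per-arm cohort `ps_curve`), `cnr` (per-arm per-patient CNR
#'   matrix), `cnr_comparisons` (within-protocol paired analyses),
#'   `profiles` (per-arm mean vessel profile), `vgc` (per-protocol
#'   fixed/random [vgc_table()]s), `proportions`, `dose` (records and
#'   [protocol_summary()]), `config`.
#' @export
run_study <- function(config = study_config(), out = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  arms <- study_arms(config)
  extent <- config$image_size * config$pixel_spacing
  cx <- extent / 2
  # ROI placement matches default_phantom_config(): aorta disk at
  # (cx, cx + 12), fat disk at (cx, cx - 24)
  roi_aorta <- roi_spec(c(cx, cx + 12), diameter = 15)
  roi_fat <- roi_spec(c(cx, cx - 24), diameter = 15)
  vessel <- c(cx - 55, cx + 20)  # 2 mm vessel (before jitter)
  curves <- list(); cnr_tab <- list(); profiles <- list()
  for (an in names(arms)) {
    say("arm %s: %d patients", an, config$n_patients)
    pc <- vector("list", config$n_patients)
    cn <- numeric(config$n_patients)
    prof_acc <- NULL
    for (p in seq_len(config$n_patients)) {
      stk <- simulate_arm(config, an, p)
      pc[[p]] <- radial_average(examination_ps(stk))
      sl <- get_slice(stk, 1)
      cn[p] <- cnr(roi_stats(sl, roi_aorta, config$pixel_spacing),
                   roi_stats(sl, roi_fat, config$pixel_spacing))
      v <- vessel + patient_geometry(config, p)$vessel_shift
      pr <- line_profile(sl, v - c(6, 0), v + c(6, 0),
                         pixel_spacing = config$pixel_spacing)
      prof_acc <- if (is.null(prof_acc)) pr$value else prof_acc + pr$value
    }
    curves[[an]] <- cohort_ps(pc)
    cnr_tab[[an]] <- cn
    profiles[[an]] <- data.frame(position = seq(0, 12, length.out = length(prof_acc)),
                                 value = prof_acc / config$n_patients)
  }
  say("CNR paired comparisons")
  cnr_cmp <- list(
    full_dlir_vs_asirv = cnr_difference_analysis(cnr_tab$full_dlir, cnr_tab$full_asirv),
    full_dlir_vs_e2 = cnr_difference_analysis(cnr_tab$full_dlir, cnr_tab$full_dlir_e2),
    uld_dlir_vs_asirv = cnr_difference_analysis(cnr_tab$uld_dlir, cnr_tab$uld_asirv),
    uld_dlir_vs_e2 = cnr_difference_analysis(cnr_tab$uld_dlir, cnr_tab$uld_dlir_e2))
  say("observer study + VGC")
  vgc_res <- list(); ratings <- list(); props <- list()
  for (prot in c("full_dose", "uld")) {
    mdl <- config$rating_model
    mdl$delta <- if (prot == "full_dose") config$delta_full else config$delta_uld
    des <- rating_design(n_cases = config$n_patients,
                         conditions = c("asirv", "dlir"))
    rs <- generate_ratings(des, mdl,
                           seed = derive_seed(config$seed, paste0("ratings/", prot)))
    ratings[[prot]] <- rs
    vgc_res[[prot]] <- list(
      fixed = vgc_table(rs, mode = "fixed_reader", n_boot = config$n_boot,
                        seed = derive_seed(config$seed, paste0("vgcF/", prot))),
      random = vgc_table(rs, mode = "random_reader", n_boot = config$n_boot,
                         seed = derive_seed(config$seed, paste0("vgcR/", prot))))
    props[[prot]] <- proportion_table(rs)
  }
  say("dose accounting")
  dseed <- derive_seed(config$seed, "dose")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(dseed)
  n <- config$n_patients
  dlp_full <- 2.5 / 0.015 * exp(stats::rnorm(n, 0, 0.15))
  dlp_full <- dlp_full * (2.5 / 0.015) / mean(dlp_full)  # cohort mean fixed
  dlp_uld <- 0.05 / 0.015 * exp(stats::rnorm(n, 0, 0.15))
  dlp_uld <- dlp_uld * (0.05 / 0.015) / mean(dlp_uld)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  recs <- dose_records(
    patient_id = rep(seq_len(n), 2),
    protocol = rep(c("full_dose", "uld"), each = n),
    ctdi_vol = c(dlp_full, dlp_uld) / 37,  # ~37 cm scan length
    dlp = c(dlp_full, dlp_uld))
  res <- structure(
    list(ps = curves, cnr = cnr_tab, cnr_comparisons = cnr_cmp,
         profiles = profiles, vgc = vgc_res, ratings = ratings,
         proportions = props,
         dose = list(records = recs, summary = protocol_summary(recs)),
         config = config),
    class = "ctiq_study")
  if (!is.null(out)) write_study(res, out)
  res
}

write_study <- function(res, out) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  for (an in names(res$ps))
    write_ps_curve(res$ps[[an]], file.path(out, paste0("ps_", an, ".csv")))
  utils::write.csv(as.data.frame(res$cnr),
                   file.path(out, "cnr_per_patient.csv"), row.names = FALSE)
  cmp <- do.call(rbind, lapply(names(res$cnr_comparisons), function(nm) {
    x <- res$cnr_comparisons[[nm]]
    data.frame(comparison = nm, mean_diff = x$mean_diff, sem = x$sem,
               t = x$t_statistic, p = x$p_value)
  }))
  utils::write.csv(cmp, file.path(out, "cnr_comparisons.csv"), row.names = FALSE)
  for (prot in names(res$vgc)) {
    utils::write.csv(res$vgc[[prot]]$fixed,
                     file.path(out, paste0("vgc_", prot, "_fixed.csv")),
                     row.names = FALSE)
    utils::write.csv(res$vgc[[prot]]$random,
                     file.path(out, paste0("vgc_", prot, "_random.csv")),
                     row.names = FALSE)
    write_ratings(res$ratings[[prot]],
                  file.path(out, paste0("ratings_", prot, ".csv")))
    utils::write.csv(res$proportions[[prot]],
                     file.path(out, paste0("proportions_", prot, ".csv")),
                     row.names = FALSE)
  }
  for (an in names(res$profiles))
    utils::write.csv(res$profiles[[an]],
                     file.path(out, paste0("profile_", an, ".csv")),
                     row.names = FALSE)
  write_dose_records(res$dose$records, file.path(out, "dose_records.csv"))
  jsonlite::write_json(res$dose$summary, file.path(out, "dose_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out)
}

#' @export
print.ctiq_study <- function(x, ...) {
  cat(sprintf("<ctiq_study> %d patients x 6 arms, seed %d\n",
              x$config$n_patients, x$config$seed))
  cat("  mean CNR by arm:\n")
  for (an in names(x$cnr))
    cat(sprintf("    %-14s %6.2f\n", an, mean(x$cnr[[an]])))
  cat("  VGC (dlir vs asirv, fixed reader): significant questions",
      sprintf("full %d/10, uld %d/10\n",
              sum(x$vgc$full_dose$fixed$significant),
              sum(x$vgc$uld$fixed$significant)))
  cat(sprintf("  mean effective dose: full %.2f mSv, uld %.3f mSv (%.3g%%)\n",
              x$dose$summary$per_protocol$mean_effective_dose[
                x$dose$summary$per_protocol$protocol == "full_dose"],
              x$dose$summary$per_protocol$mean_effective_dose[
                x$dose$summary$per_protocol$protocol == "uld"],
              x$dose$summary$dose_ratio_pct))
  invisible(x)
}
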