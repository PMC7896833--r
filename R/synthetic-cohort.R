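#' Built-in scanner acquisition profiles
#'
#' Three preset profiles emulating the reconstruction geometry of the PET
#' scanners a mixed-scanner cohort is drawn from. Reconstruction itself is
#' not modelled; each profile reduces to a voxel grid spacing, a Gaussian
#' point-spread blur and an additive noise level.
#'
#' @param name Optional profile name; omit to get the list of all three
#'   presets (`"discovery_vct"`, `"discovery_mi"`, `"biograph_vision"`).
#' @return A `scanner_profile` (list with `name`, `voxel_size` in mm,
#'   `psf_fwhm` in mm, `noise_sd` in SUV), or a named list of the presets.
#' @examples
#' scanner_profiles("biograph_vision")$voxel_size
#' @export
scanner_profiles <- function(name = NULL) {
  presets <- list(
    discovery_vct = new_scanner_profile(
      "discovery_vct", voxel_size = c(5.47, 5.47, 5.47),
      psf_fwhm = 6, noise_sd = 0.15),
    discovery_mi = new_scanner_profile(
      "discovery_mi", voxel_size = c(2.7, 2.7, 2.79),
      psf_fwhm = 4, noise_sd = 0.10),
    biograph_vision = new_scanner_profile(
      "biograph_vision", voxel_size = c(1.6, 1.6, 1.5),
      psf_fwhm = 3, noise_sd = 0.08)
  )
  if (is.null(name)) return(presets)
  if (!name %in% names(presets))
    stop("unknown scanner profile '", name, "'")
  presets[[name]]
}

new_scanner_profile <- function(name, voxel_size, psf_fwhm, noise_sd) {
  stopifnot(length(voxel_size) == 3, all(voxel_size > 0),
            psf_fwhm >= 0, noise_sd >= 0)
  structure(list(name = name, voxel_size = as.numeric(voxel_size),
                 psf_fwhm = psf_fwhm, noise_sd = noise_sd),
            class = "scanner_profile")
}

#' Cohort simulation configuration
#'
#' Defines the statistical structure of a synthetic PET/CT survival cohort:
#' a labeled subset with complete (>= 2 year) follow-up split into training
#' and test sets with the relapse ratio preserved, and an unlabeled pool
#' with short or missing follow-up drawn from three scanner profiles.
#'
#' @param n_labeled Number of patients with usable follow-up.
#' @param n_unlabeled Number of patients with missing/incomplete follow-up.
#' @param train_fraction Fraction of labeled patients assigned to training.
#' @param relapse_prevalence Proportion of relapse-prone patients in the
#'   labeled cohort.
#' @param unlabeled_prevalence Relapse-prone proportion in the unlabeled
#'   pool; defaults to `relapse_prevalence` (the class-prior assumption the
#'   semi-supervised stage makes), configurable to study misspecification.
#' @param hazard_relapse,hazard_nonrelapse Exponential progression hazards
#'   (events per month) of the two latent classes.
#' @param censor_horizon_labeled Minimum follow-up (months) of labeled
#'   patients; must be >= 24.
#' @param followup_max_labeled Upper end of the labeled follow-up window.
#' @param unlabeled_followup_max Maximum follow-up (months, < 24) of
#'   unlabeled patients.
#' @param effect_size Dimensionless separation (in log-scale standard
#'   deviations) between the class-conditional lesion phenotype
#'   distributions; 0 makes the classes indistinguishable on imaging.
#' @param scanner_mix Proportions of the three scanner presets in the
#'   unlabeled pool (must sum to 1).
#' @param clin_assoc Strength of the association between latent class and
#'   the simulated clinical covariates (logit / log-scale shift).
#' @param grid_voxels Simulated grid side length in voxels.
#' @param texture_corr_mm Correlation length of the intra-lesion texture
#'   random field.
#' @param seed Integer seed; every simulator output is a pure function of
#'   the configuration including this seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_labeled = 84, n_unlabeled = 83,
                          train_fraction = 64 / 84,
                          relapse_prevalence = 0.3,
                          unlabeled_prevalence = NULL,
                          hazard_relapse = 0.08,
                          hazard_nonrelapse = 0.005,
                          censor_horizon_labeled = 24,
                          followup_max_labeled = 60,
                          unlabeled_followup_max = 24,
                          effect_size = 1.5,
                          scanner_mix = c(39, 29, 15) / 83,
                          clin_assoc = 0.8,
                          grid_voxels = 48,
                          texture_corr_mm = 6,
                          seed = 1) {
  if (!(relapse_prevalence > 0 && relapse_prevalence < 1))
    stop("relapse_prevalence must lie strictly between 0 and 1")
  if (!(hazard_relapse > hazard_nonrelapse && hazard_nonrelapse > 0))
    stop("hazards must satisfy hazard_relapse > hazard_nonrelapse > 0")
  if (abs(sum(scanner_mix) - 1) > 1e-8)
    stop("scanner_mix must sum to 1")
  if (censor_horizon_labeled < 24)
    stop("labeled patients must be followed for at least 24 months")
  if (unlabeled_followup_max > 24)
    stop("unlabeled_followup_max must be < 24 months")
  structure(list(
    n_labeled = n_labeled, n_unlabeled = n_unlabeled,
    train_fraction = train_fraction,
    relapse_prevalence = relapse_prevalence,
    unlabeled_prevalence = if (is.null(unlabeled_prevalence))
      relapse_prevalence else unlabeled_prevalence,
    hazard_relapse = hazard_relapse, hazard_nonrelapse = hazard_nonrelapse,
    censor_horizon_labeled = censor_horizon_labeled,
    followup_max_labeled = followup_max_labeled,
    unlabeled_followup_max = unlabeled_followup_max,
    effect_size = effect_size, scanner_mix = scanner_mix,
    clin_assoc = clin_assoc, grid_voxels = grid_voxels,
    texture_corr_mm = texture_corr_mm, seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Draw class-conditional lesion phenotype parameters
#'
#' The latent relapse class shifts the log-normal distributions of lesion
#' mean uptake, size and texture variability by `effect_size` (uptake) and
#' half of it (size, texture) in units of the log-scale SD. Exposed so that
#' the generator's class separation can be checked directly on the sampled
#' parameters without rendering voxel volumes.
#'
#' @param latent_class `"relapse"` or `"nonrelapse"`.
#' @param effect_size Class separation, see [cohort_config()].
#' @return List with `suv_mean` (SUV), `radii_mm` (3 semi-axes, mm) and
#'   `texture_sd` (log-scale SD of the multiplicative texture field).
#' @export
simulate_lesion_params <- function(latent_class, effect_size) {
  latent_class <- match.arg(latent_class, c("relapse", "nonrelapse"))
  cls <- as.numeric(latent_class == "relapse")
  suv_sdlog <- 0.35
  rad_sdlog <- 0.20
  tex_sdlog <- 0.30
  list(
    suv_mean = rlnorm(1, log(6) + cls * effect_size * suv_sdlog, suv_sdlog),
    radii_mm = rlnorm(3, log(9) + cls * 0.5 * effect_size * rad_sdlog,
                      rad_sdlog),
    texture_sd = rlnorm(1, log(0.15) + cls * 0.5 * effect_size * tex_sdlog,
                        tex_sdlog)
  )
}

smooth_field <- function(dim3, spacing, corr_mm, target_sd) {
  f <- array(rnorm(prod(dim3)), dim3)
  f <- .gauss_blur3d(f, as.integer(dim3), corr_mm / (2.3548 * spacing))
  s <- sd(f)
  if (s < 1e-12) return(array(0, dim3))
  f / s * target_sd
}

#' Simulate one patient's PET/CT volume
#'
#' Renders a single ellipsoidal FDG-avid lesion on a smooth background:
#' lesion mean uptake, semi-axes and multiplicative texture variance are
#' drawn from class-conditional distributions, the volume is blurred by the
#' scanner's point-spread FWHM and corrupted by additive Gaussian noise.
#' The CT channel carries soft-tissue contrast at the lesion. The binary
#' mask is the noise-free ground-truth ellipsoid.
#'
#' @param latent_class `"relapse"` or `"nonrelapse"`.
#' @param scanner A [scanner_profiles()] preset.
#' @param rng_seed Integer seed; identical seeds give bit-identical output.
#' @param config A [cohort_config()] (controls effect size, grid, texture).
#' @param patient_id Identifier stored in the volume.
#' @return A `simulated_patient`: list with `patient_id`, `latent_class`,
#'   `volume` (a [patient_volume()]) and the sampled `lesion_params`.
#' @export
simulate_patient <- function(latent_class, scanner, rng_seed,
                             config = cohort_config(),
                             patient_id = "p001") {
  latent_class <- match.arg(latent_class, c("relapse", "nonrelapse"))
  stopifnot(inherits(scanner, "scanner_profile"))
  with_seed(rng_seed, {
    n <- config$grid_voxels
    dim3 <- c(n, n, n)
    sp <- scanner$voxel_size
    extent <- dim3 * sp

    par <- simulate_lesion_params(latent_class, config$effect_size)
    center <- extent / 2 + runif(3, -4, 4)
    margin <- par$radii_mm + 2 * sp     # leave a voxel of air around it
    bad <- which(center - margin < 0 | center + margin > extent)
    if (length(bad))
      stop("lesion does not fit the simulated grid along axis ",
           paste(c("x", "y", "z")[bad], collapse = ", "),
           " (radius ", paste(round(par$radii_mm[bad], 1), collapse = ", "),
           " mm, grid extent ", paste(round(extent[bad], 1), collapse = ", "),
           " mm)")

    ax <- lapply(1:3, function(a) ((seq_len(n) - 0.5) * sp[a] - center[a]) /
                   par$radii_mm[a])
    d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
    mask <- d2 <= 1
    if (!any(mask)) stop("lesion covers no voxel at this grid resolution")

    pet <- 0.7 + smooth_field(dim3, sp, 20, 0.08)
    tex <- smooth_field(dim3, sp, config$texture_corr_mm, par$texture_sd)
    pet[mask] <- par$suv_mean * exp(tex[mask] - par$texture_sd^2 / 2)
    pet <- .gauss_blur3d(pet, as.integer(dim3),
                         rep(scanner$psf_fwhm, 3) / (2.3548 * sp))
    pet <- pet + rnorm(prod(dim3), 0, scanner$noise_sd)
    pet[pet < 0] <- 0

    ct <- 0.35 + smooth_field(dim3, sp, 25, 0.05)
    ct[mask] <- ct[mask] + 0.25
    ct <- .gauss_blur3d(ct, as.integer(dim3), rep(3, 3) / (2.3548 * sp))
    ct <- ct + rnorm(prod(dim3), 0, 0.02)

    vol <- patient_volume(pet = array(pet, dim3), ct = array(ct, dim3),
                          mask = array(mask * 1L, dim3), spacing = sp,
                          patient_id = patient_id)
    structure(list(patient_id = patient_id, latent_class = latent_class,
                   volume = vol, lesion_params = par,
                   scanner = scanner$name),
              class = "simulated_patient")
  })
}

#' Simulate progression-free survival for one patient
#'
#' Event times are exponential with a class-specific hazard. Labeled
#' patients have their administrative follow-up drawn uniformly between the
#' labeled censoring horizon (>= 24 months) and its upper end; unlabeled
#' patients get short follow-up (< 24 months).
#'
#' @inheritParams simulate_patient
#' @param labeled Logical; labeled patients have complete follow-up.
#' @return List with `pfs_months` (observed time, i.e. min of event and
#'   follow-up), `event_flag` (1 if progression observed) and
#'   `followup_months`.
#' @export
simulate_survival <- function(latent_class, config = cohort_config(),
                              rng_seed = 1, labeled = TRUE) {
  latent_class <- match.arg(latent_class, c("relapse", "nonrelapse"))
  stopifnot(config$hazard_relapse > 0, config$hazard_nonrelapse > 0)
  with_seed(rng_seed, {
    h <- if (latent_class == "relapse") config$hazard_relapse
         else config$hazard_nonrelapse
    t_event <- rexp(1, h)
    followup <- if (labeled)
      runif(1, config$censor_horizon_labeled, config$followup_max_labeled)
    else
      runif(1, 1, config$unlabeled_followup_max)
    list(pfs_months = min(t_event, followup),
         event_flag = as.integer(t_event <= followup),
         followup_months = followup)
  })
}

simulate_clinical <- function(latent_class, config, rng_seed) {
  cls <- as.numeric(latent_class == "relapse")
  a <- config$clin_assoc
  with_seed(rng_seed, {
    list(
      age = round(runif(1, 18, 75)),
      gender = sample(c("M", "F"), 1, prob = c(0.7, 0.3)),
      ldh = rlnorm(1, log(180) + cls * a * 0.3, 0.3),
      ecog = sample(0:2, 1, prob = exp(c(1.2, 0, -1.5) + cls * a * c(-1, 0, 1))),
      ebv_dna = rbinom(1, 1, plogis(qlogis(0.35) + cls * a)),
      b2m = rlnorm(1, log(2.0) + cls * a * 0.25, 0.25),
      ann_arbor = c("I-II", "III-IV")[1 + rbinom(1, 1, plogis(qlogis(0.25) + cls * a))],
      b_symptoms = rbinom(1, 1, plogis(qlogis(0.4) + cls * 0.5 * a))
    )
  })
}

# Largest-remainder apportionment of n into integer counts ~ n * prop.
apportion <- function(n, prop) {
  raw <- n * prop
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  as.integer(k)
}

#' Simulate a complete multi-scanner survival cohort
#'
#' Generates the labeled cohort (split into training and test sets with the
#' relapse ratio preserved up to integer rounding) and the unlabeled pool
#' (scanner presets allocated by `scanner_mix`). Labeled patients are
#' acquired on the first scanner preset; the unlabeled pool spans all
#' three. The latent class and the unlabeled patients' simulated outcomes
#' are stored only in the withheld `truth` table, which downstream pipeline
#' stages never read (it exists for oracle evaluation of the simulator).
#'
#' @param config A [cohort_config()].
#' @param keep_volumes Set `FALSE` to skip voxel rendering (clinical and
#'   survival structure only; useful for fast statistical checks).
#' @return A `pet_cohort`: list with `patients` (named list of
#'   `simulated_patient`), `clinical` (one row per patient: identifiers,
#'   split, scanner, covariates, and follow-up fields that are `NA` for the
#'   unlabeled pool), `truth` (withheld latent classes and uncensored
#'   outcomes) and `config`.
#' @examples
#' \donttest{
#' coh <- simulate_cohort(cohort_config(grid_voxels = 24))
#' table(coh$clinical$split)
#' }
#' @export
simulate_cohort <- function(config = cohort_config(), keep_volumes = TRUE) {
  n_lab <- config$n_labeled
  n_unl <- config$n_unlabeled
  n_train <- round(config$train_fraction * n_lab)
  n_test <- n_lab - n_train
  n_pos <- round(config$relapse_prevalence * n_lab)
  if (n_pos == 0 || n_pos == n_lab)
    stop("cannot stratify: labeled cohort would contain a single class")
  n_pos_train <- round(n_pos * config$train_fraction)
  n_pos_test <- n_pos - n_pos_train
  if (min(n_pos_train, n_pos_test, n_train - n_pos_train,
          n_test - n_pos_test) < 0)
    stop("cannot stratify labeled cohort with these counts")

  presets <- scanner_profiles()
  unl_counts <- apportion(n_unl, config$scanner_mix)
  unl_scanner <- rep(names(presets), unl_counts)
  n_pos_unl <- round(config$unlabeled_prevalence * n_unl)

  plan <- with_seed(config$seed, {
    lab_class <- c(rep("relapse", n_pos), rep("nonrelapse", n_lab - n_pos))
    split <- c(
      sample(c(rep("train", n_pos_train), rep("test", n_pos_test))),
      sample(c(rep("train", n_train - n_pos_train),
               rep("test", n_test - n_pos_test))))
    unl_class <- sample(c(rep("relapse", n_pos_unl),
                          rep("nonrelapse", n_unl - n_pos_unl)))
    list(lab_class = lab_class, split = split, unl_class = unl_class)
  })

  ids <- sprintf("pt%03d", seq_len(n_lab + n_unl))
  rows <- vector("list", n_lab + n_unl)
  patients <- vector("list", n_lab + n_unl)
  truth <- vector("list", n_lab + n_unl)

  for (i in seq_len(n_lab + n_unl)) {
    labeled <- i <= n_lab
    cls <- if (labeled) plan$lab_class[i] else plan$unl_class[i - n_lab]
    scn <- if (labeled) "discovery_vct" else unl_scanner[i - n_lab]
    sd_i <- derive_seed(config$seed, i)
    surv <- simulate_survival(cls, config, derive_seed(sd_i, 1), labeled)
    clin <- simulate_clinical(cls, config, derive_seed(sd_i, 2))
    if (keep_volumes)
      patients[[i]] <- simulate_patient(cls, presets[[scn]],
                                        derive_seed(sd_i, 3), config, ids[i])
    rows[[i]] <- data.frame(
      patient_id = ids[i],
      split = if (labeled) plan$split[i] else "unlabeled",
      scanner = scn, labeled = labeled,
      age = clin$age, gender = clin$gender, ldh = clin$ldh,
      ecog = clin$ecog, ebv_dna = clin$ebv_dna, b2m = clin$b2m,
      ann_arbor = clin$ann_arbor, b_symptoms = clin$b_symptoms,
      pfs_months = if (labeled) surv$pfs_months else NA_real_,
      event = if (labeled) surv$event_flag else NA_integer_,
      followup_months = if (labeled) surv$followup_months else NA_real_,
      stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      patient_id = ids[i], latent_class = cls,
      pfs_months = surv$pfs_months, event = surv$event_flag,
      followup_months = surv$followup_months, stringsAsFactors = FALSE)
  }
  names(patients) <- ids
  structure(list(
    patients = if (keep_volumes) patients else NULL,
    clinical = do.call(rbind, rows),
    truth = do.call(rbind, truth),
    config = config
  ), class = "pet_cohort")
}

#' @export
print.pet_cohort <- function(x, ...) {
  tab <- table(x$clinical$split)
  cat("Synthetic PET/CT survival cohort\n")
  cat("  patients:", nrow(x$clinical),
      sprintf("(train %d / test %d / unlabeled %d)\n",
              tab[["train"]], tab[["test"]],
              if ("unlabeled" %in% names(tab)) tab[["unlabeled"]] else 0L))
  lab <- x$clinical$labeled
  cat("  labeled events observed:", sum(x$clinical$event[lab]), "\n")
  cat("  grid:", x$config$grid_voxels, "^3 voxels; effect size",
      x$config$effect_size, "\n")
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes per-patient PET, CT and mask volumes as compressed NIfTI with the
#' voxel spacing encoded in the header, the clinical table as CSV, and a
#' JSON manifest mapping patient ids to file paths, split and scanner.
#' The withheld truth table is not written.
#'
#' @param cohort A [simulate_cohort()] result with volumes.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pet_cohort"), !is.null(cohort$patients))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(cohort$patients, function(p) {
    base <- file.path(dir, p$patient_id)
    paths <- list(pet = paste0(base, "_pet.nii.gz"),
                  ct = paste0(base, "_ct.nii.gz"),
                  mask = paste0(base, "_mask.nii.gz"))
    write_patient(p$volume, paths)
    ci <- cohort$clinical[cohort$clinical$patient_id == p$patient_id, ]
    list(patient_id = p$patient_id, split = ci$split, scanner = ci$scanner,
         pet = paths$pet, ct = paths$ct, mask = paths$mask)
  })
  write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
            row.names = FALSE)
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(unname(entries), manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
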