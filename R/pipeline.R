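#' Preprocess a cohort into network input tensors
#'
#' Crops and resamples every patient's lesion ROI, computes the PET/CT
#' normalization statistics on the labeled training patients only, and
#' applies them to all patients (training statistics are frozen and reused
#' at test time).
#'
#' @param cohort A [simulate_cohort()] result with volumes.
#' @param side_mm,out_voxels ROI geometry, see [crop_resample()].
#' @param pet_only Single-channel (PET) tensors.
#' @return List with `tensors` (named list of normalized `roi_tensor`s),
#'   `norm_stats`, and `meta` (patient_id, split, label, time, event);
#'   `label` is `NA` for the unlabeled pool.
#' @export
preprocess_cohort <- function(cohort, side_mm = 96, out_voxels = 32,
                              pet_only = FALSE) {
  stopifnot(inherits(cohort, "pet_cohort"), !is.null(cohort$patients))
  cl <- cohort$clinical
  raw <- lapply(cohort$patients, function(p)
    crop_resample(p$volume, side_mm, out_voxels, pet_only = pet_only))
  train_ids <- cl$patient_id[cl$split == "train"]
  stats <- roi_norm_stats(raw[train_ids])
  tensors <- lapply(raw, normalize_roi, norm_stats = stats)
  meta <- data.frame(patient_id = cl$patient_id, split = cl$split,
                     label = ifelse(cl$labeled, cl$event, NA_integer_),
                     time = cl$pfs_months, event = cl$event,
                     stringsAsFactors = FALSE)
  list(tensors = tensors, norm_stats = stats, meta = meta)
}

#' Prediction similarity index
#'
#' PSI is the ratio of the positive to the negative predicted probability;
#' patients with PSI above 1 form the high (predicted relapse) group.
#' Because the two probabilities sum to one, PSI > 1 is equivalent to
#' p_pos > 0.5; a PSI of exactly 1 (equal probabilities) falls in the low
#' group under the strict inequality. A small epsilon guard (1e-12) keeps
#' the ratio finite when the negative probability is zero.
#'
#' @param p_pos,p_neg Predicted probabilities of the positive and negative
#'   class, or a data frame with columns `p_pos`, `p_neg` (and optionally
#'   `patient_id`) as returned by [predict_probabilities()].
#' @return Data frame with `patient_id`, `p_pos`, `p_neg`, `psi`, `group`
#'   (`"high"` / `"low"`).
#' @examples
#' compute_psi(0.5, 0.5)   # boundary: psi = 1, low group
#' compute_psi(0.8, 0.2)   # psi = 4, high group
#' @export
compute_psi <- function(p_pos, p_neg = NULL) {
  if (is.data.frame(p_pos)) {
    df <- p_pos
    stopifnot(all(c("p_pos", "p_neg") %in% names(df)))
    ids <- if ("patient_id" %in% names(df)) df$patient_id
           else sprintf("sample%03d", seq_len(nrow(df)))
    p_neg <- df$p_neg; p_pos <- df$p_pos
  } else {
    stopifnot(!is.null(p_neg), length(p_pos) == length(p_neg))
    ids <- sprintf("sample%03d", seq_along(p_pos))
  }
  stopifnot(all(p_pos >= 0 & p_pos <= 1), all(p_neg >= 0 & p_neg <= 1))
  psi <- p_pos / pmax(p_neg, 1e-12)
  data.frame(patient_id = ids, p_pos = p_pos, p_neg = p_neg, psi = psi,
             group = ifelse(psi > 1, "high", "low"),
             stringsAsFactors = FALSE)
}

run_manifest <- function(mode, cohort, configs, psi) {
  list(mode = mode,
       cohort_hash = object_hash(cohort$config),
       config_hash = object_hash(configs),
       psi_hash = object_hash(psi),
       seeds = list(cohort = cohort$config$seed,
                    network = configs$net_config$seed))
}

#' Conventional deep-learning (fully supervised) prognosis run
#'
#' Preprocesses the cohort, trains the network on the labeled training
#' patients only (the unlabeled pool is ignored), predicts class
#' probabilities for the labeled training and test patients, and computes
#' PSI.
#'
#' @param cohort A [simulate_cohort()] result with volumes.
#' @param net_config A [network_config()].
#' @param side_mm,out_voxels ROI geometry.
#' @param prep Optional precomputed [preprocess_cohort()] result (reused
#'   across runs to avoid recropping).
#' @return A `wsdl_run` with `mode = "CDL"`, the trained `fit`, and the
#'   `psi` table over train and test patients.
#' @export
run_cdl <- function(cohort, net_config = network_config(), side_mm = 96,
                    out_voxels = 32, prep = NULL) {
  if (is.null(prep))
    prep <- preprocess_cohort(cohort, side_mm, out_voxels,
                              pet_only = net_config$input_channels == 1)
  meta <- prep$meta
  tr <- meta$patient_id[meta$split == "train"]
  te <- meta$patient_id[meta$split == "test"]
  fit <- train_dcnn(prep$tensors[tr],
                    meta$label[match(tr, meta$patient_id)],
                    config = net_config)
  probs <- predict_probabilities(fit, prep$tensors[c(tr, te)])
  psi <- compute_psi(probs)
  psi$split <- meta$split[match(psi$patient_id, meta$patient_id)]
  configs <- list(net_config = net_config, side_mm = side_mm,
                  out_voxels = out_voxels)
  structure(list(mode = "CDL", fit = fit, psi = psi,
                 implicit_labels = NULL,
                 manifest = run_manifest("CDL", cohort, configs, psi)),
            class = "wsdl_run")
}

#' Weakly supervised deep-learning prognosis run
#'
#' The four-step procedure: (1) train a baseline network on the labeled
#' training patients; (2) extract the 128 average-pooling features for the
#' labeled training and unlabeled patients; (3) fit the PNU classifier on
#' those features and assign implicit labels to the unlabeled pool;
#' (4) retrain the network from a fresh initialization (same seed family)
#' on the labeled patients (true labels, weight 1) together with the
#' unlabeled patients (implicit labels, weight `w_unlabeled`). PSI is
#' computed from the retrained network.
#'
#' @inheritParams run_cdl
#' @param pnu_cfg A [pnu_config()]; its prior defaults to the relapse
#'   prevalence among labeled training patients.
#' @param w_unlabeled Sample weight of implicitly labeled patients in the
#'   retraining stage (samples with weight 0 are dropped, making the run
#'   identical to [run_cdl()]).
#' @param confidence_weight Scale each implicit sample's weight by its PNU
#'   confidence.
#' @param finetune Continue training from the baseline parameters instead
#'   of retraining from a fresh initialization.
#' @param oracle_labels Replace implicit labels by the generator's hidden
#'   latent classes (upper-bound experiment; reads the cohort's withheld
#'   truth table).
#' @param baseline Optional pre-trained baseline `dcnn` (e.g. the fit from
#'   a same-seed [run_cdl()], which is identical to step 1).
#' @return A `wsdl_run` with `mode = "WSDL"`, the `baseline` and final
#'   `fit`, the `implicit_labels` table and the `psi` table.
#' @export
run_wsdl <- function(cohort, net_config = network_config(),
                     pnu_cfg = pnu_config(), side_mm = 96,
                     out_voxels = 32, w_unlabeled = 1,
                     confidence_weight = FALSE, finetune = FALSE,
                     oracle_labels = FALSE, prep = NULL,
                     baseline = NULL) {
  if (is.null(prep))
    prep <- preprocess_cohort(cohort, side_mm, out_voxels,
                              pet_only = net_config$input_channels == 1)
  meta <- prep$meta
  tr <- meta$patient_id[meta$split == "train"]
  te <- meta$patient_id[meta$split == "test"]
  un <- meta$patient_id[meta$split == "unlabeled"]
  if (length(un) == 0)
    stop("the unlabeled pool is empty; use run_cdl() for a fully ",
         "supervised run")
  y_tr <- meta$label[match(tr, meta$patient_id)]

  # step 1: baseline supervised training (identical to the CDL fit)
  if (is.null(baseline))
    baseline <- train_dcnn(prep$tensors[tr], y_tr, config = net_config)

  # step 2: deep features for labeled and unlabeled patients
  feats_tr <- extract_features(baseline, prep$tensors[tr])
  feats_un <- extract_features(baseline, prep$tensors[un])

  # step 3: PNU classifier -> implicit labels
  if (is.null(pnu_cfg$prior_pos))
    pnu_cfg$prior_pos <- max(min(mean(y_tr), 0.95), 0.05)
  pnu <- fit_pnu(feats_tr[y_tr == 1, , drop = FALSE],
                 feats_tr[y_tr == 0, , drop = FALSE],
                 feats_un, pnu_cfg)
  implicit <- assign_implicit_labels(pnu, feats_un, un)
  if (oracle_labels) {
    truth_cls <- cohort$truth$latent_class[match(un,
                                                 cohort$truth$patient_id)]
    implicit$label <- ifelse(truth_cls == "relapse", "positive",
                             "negative")
  }

  # step 4: retrain on labeled (weight 1) + implicitly labeled patients
  y_un <- as.integer(implicit$label == "positive")
  w_un <- rep(w_unlabeled, length(un))
  if (confidence_weight) w_un <- w_un * implicit$confidence
  keep <- w_un > 0
  x_all <- c(prep$tensors[tr], prep$tensors[un[keep]])
  y_all <- c(y_tr, y_un[keep])
  w_all <- c(rep(1, length(tr)), w_un[keep])
  # early stopping validates only on patients with trusted labels
  fit <- train_dcnn(x_all, y_all, sample_weights = w_all,
                    config = net_config,
                    net = if (finetune) baseline else NULL,
                    val_pool = c(rep(TRUE, length(tr)),
                                 rep(FALSE, sum(keep))))

  probs <- predict_probabilities(fit, prep$tensors[c(tr, te)])
  psi <- compute_psi(probs)
  psi$split <- meta$split[match(psi$patient_id, meta$patient_id)]
  configs <- list(net_config = net_config, pnu_config = pnu_cfg,
                  side_mm = side_mm, out_voxels = out_voxels,
                  w_unlabeled = w_unlabeled,
                  confidence_weight = confidence_weight,
                  finetune = finetune, oracle_labels = oracle_labels)
  structure(list(mode = "WSDL", baseline = baseline, fit = fit,
                 pnu = pnu, implicit_labels = implicit, psi = psi,
                 manifest = run_manifest("WSDL", cohort, configs, psi)),
            class = "wsdl_run")
}

#' @export
print.wsdl_run <- function(x, ...) {
  cat(x$mode, "prognosis run\n")
  tab <- table(x$psi$split, x$psi$group)
  print(tab)
  if (!is.null(x$implicit_labels))
    cat("implicit labels:",
        sum(x$implicit_labels$label == "positive"), "positive /",
        sum(x$implicit_labels$label == "negative"), "negative\n")
  cat("manifest psi hash:", x$manifest$psi_hash, "\n")
  invisible(x)
}

#' Evaluate a prognosis run against follow-up
#'
#' Computes the time-dependent AUC of PSI at the evaluation horizon, the
#' log-rank comparison of the high/low PSI groups, and classification
#' metrics against the dichotomous outcome at the horizon (patients
#' censored before the horizon are excluded from the classification
#' metrics).
#'
#' @param psi PSI table (rows of [compute_psi()] output) for one split.
#' @param time,event Matching follow-up records.
#' @param t_eval Horizon in months.
#' @return List with `auc`, `logrank`, `metrics`.
#' @export
evaluate_prognosis <- function(psi, time, event, t_eval = 24) {
  stopifnot(nrow(psi) == length(time))
  auc <- time_dependent_auc(psi$psi, time, event, t_eval)
  hi <- psi$group == "high"
  lr <- if (length(unique(hi)) == 2)
    logrank_test(time[hi], event[hi], time[!hi], event[!hi])
  else NULL
  known <- (time <= t_eval & event == 1) | time > t_eval
  met <- tryCatch(
    classification_metrics(hi[known],
                           (time <= t_eval & event == 1)[known]),
    error = function(e) NULL)
  list(auc = auc$auc, logrank = lr, metrics = met)
}

#' Compare weakly supervised and fully supervised training across seeds
#'
#' For each seed, simulates a cohort, trains the fully supervised (CDL)
#' model, reuses it as the weakly supervised baseline, completes the
#' weakly supervised (WSDL) run, and scores both by the test-set
#' time-dependent AUC of PSI at 24 months.
#'
#' @param seeds Integer vector of cohort/network seeds.
#' @param config Base [cohort_config()]; its seed is replaced per run.
#' @param out_voxels,side_mm ROI geometry.
#' @param epochs Training epoch cap for both runs.
#' @param t_eval Evaluation horizon (months).
#' @param verbose Print one line per seed.
#' @return A `wsdl_experiment` data frame with columns `seed`, `auc_cdl`,
#'   `auc_wsdl`.
#' @export
wsdl_experiment <- function(seeds = 1:10, config = cohort_config(),
                            out_voxels = 32, side_mm = 96, epochs = 8,
                            t_eval = 24, verbose = FALSE) {
  rows <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    cohort <- simulate_cohort(cfg)
    ncfg <- network_config(input_voxels = out_voxels, max_epochs = epochs,
                           seed = as.integer(s))
    prep <- preprocess_cohort(cohort, side_mm, out_voxels)
    cdl <- run_cdl(cohort, ncfg, prep = prep)
    wsdl <- run_wsdl(cohort, ncfg, prep = prep, baseline = cdl$fit)
    te <- prep$meta[prep$meta$split == "test", ]
    auc_of <- function(run) {
      p <- run$psi[match(te$patient_id, run$psi$patient_id), ]
      time_dependent_auc(p$psi, te$time, te$event, t_eval)$auc
    }
    out <- data.frame(seed = s, auc_cdl = auc_of(cdl),
                      auc_wsdl = auc_of(wsdl))
    if (verbose)
      message(sprintf("seed %d: AUC CDL %.3f, WSDL %.3f", s,
                      out$auc_cdl, out$auc_wsdl))
    rm(cohort, prep, cdl, wsdl); gc(FALSE)
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("wsdl_experiment", "data.frame")
  out
}

#' @export
summary.wsdl_experiment <- function(object, ...) {
  cat("WSDL vs CDL over", nrow(object), "seeds (test-set",
      "time-dependent AUC of PSI)\n")
  cat(sprintf("  mean AUC: WSDL %.3f, CDL %.3f (delta %+.3f)\n",
              mean(object$auc_wsdl), mean(object$auc_cdl),
              mean(object$auc_wsdl) - mean(object$auc_cdl)))
  cat(sprintf("  WSDL >= CDL in %d/%d seeds\n",
              sum(object$auc_wsdl >= object$auc_cdl), nrow(object)))
  invisible(object)
}
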