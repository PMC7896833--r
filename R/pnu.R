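#' Margin losses for PNU risk estimation
#'
#' `"logistic"`: l(z) = log(1 + exp(-z)) (probabilistic link, l(0) = ln 2);
#' `"squared"`: l(z) = (1 - z)^2 / 4 (closed-form cross-checks).
#'
#' @param name Loss name.
#' @return List with elements `fn(z)` and `grad(z)` (derivative in z).
#' @export
pnu_loss <- function(name = c("logistic", "squared")) {
  name <- match.arg(name)
  if (name == "logistic")
    list(name = name,
         fn = function(z) ifelse(z > 0, log1p(exp(-z)), -z + log1p(exp(z))),
         grad = function(z) -1 / (1 + exp(z)))
  else
    list(name = name,
         fn = function(z) (1 - z)^2 / 4,
         grad = function(z) (z - 1) / 2)
}

resolve_loss <- function(loss) {
  if (is.character(loss)) pnu_loss(loss) else loss
}

#' Positive-negative (supervised) classification risk
#'
#' The class-prior-weighted empirical risk
#' pi_p mean l(s_p) + (1 - pi_p) mean l(-s_n).
#'
#' @param scores_pos,scores_neg Classifier scores of the positive and
#'   negative samples.
#' @param prior_pos Positive class prior pi_p in (0, 1).
#' @param loss `"logistic"`, `"squared"`, or a [pnu_loss()] object.
#' @return The risk value.
#' @export
pn_risk <- function(scores_pos, scores_neg, prior_pos,
                    loss = "logistic") {
  if (length(scores_pos) == 0) stop("no positive scores supplied")
  if (length(scores_neg) == 0) stop("no negative scores supplied")
  stopifnot(prior_pos > 0, prior_pos < 1)
  l <- resolve_loss(loss)
  prior_pos * mean(l$fn(scores_pos)) +
    (1 - prior_pos) * mean(l$fn(-scores_neg))
}

#' Positive-unlabeled classification risk
#'
#' Unbiased decomposition of the negative-class term through the unlabeled
#' marginal: pi_p mean l(s_p) + [mean l(-s_u) - pi_p mean l(-s_p)]. With
#' `nonneg_correction` the bracketed term is clamped at zero (consistent,
#' stabilizes small samples); without it the estimator is exactly unbiased.
#'
#' @param scores_pos,scores_unl Scores of positive and unlabeled samples.
#' @inheritParams pn_risk
#' @param nonneg_correction Clamp the implicit negative-class term at 0.
#' @return The risk value.
#' @export
pu_risk <- function(scores_pos, scores_unl, prior_pos, loss = "logistic",
                    nonneg_correction = TRUE) {
  if (length(scores_pos) == 0) stop("no positive scores supplied")
  if (length(scores_unl) == 0) stop("no unlabeled scores supplied")
  stopifnot(prior_pos > 0, prior_pos < 1)
  l <- resolve_loss(loss)
  neg_term <- mean(l$fn(-scores_unl)) - prior_pos * mean(l$fn(-scores_pos))
  if (nonneg_correction) neg_term <- max(0, neg_term)
  prior_pos * mean(l$fn(scores_pos)) + neg_term
}

#' Negative-unlabeled classification risk
#'
#' Mirror image of [pu_risk()]:
#' (1 - pi_p) mean l(-s_n) + [mean l(s_u) - (1 - pi_p) mean l(s_n)], the
#' bracket clamped at zero under the non-negative correction.
#'
#' @param scores_neg,scores_unl Scores of negative and unlabeled samples.
#' @inheritParams pu_risk
#' @return The risk value.
#' @export
nu_risk <- function(scores_neg, scores_unl, prior_pos, loss = "logistic",
                    nonneg_correction = TRUE) {
  if (length(scores_neg) == 0) stop("no negative scores supplied")
  if (length(scores_unl) == 0) stop("no unlabeled scores supplied")
  stopifnot(prior_pos > 0, prior_pos < 1)
  l <- resolve_loss(loss)
  pos_term <- mean(l$fn(scores_unl)) -
    (1 - prior_pos) * mean(l$fn(scores_neg))
  if (nonneg_correction) pos_term <- max(0, pos_term)
  (1 - prior_pos) * mean(l$fn(-scores_neg)) + pos_term
}

#' Combined positive-negative-unlabeled risk
#'
#' Convex combination of the supervised and semi-supervised risks: for
#' gamma in [0, 1], (1 - gamma) PN + gamma PU; for gamma in [-1, 0),
#' (1 + gamma) PN + (-gamma) NU. The endpoints gamma = 0, 1, -1 reproduce
#' the PN, PU and NU risks exactly.
#'
#' @param scores_pos,scores_neg,scores_unl Scores per sample pool; the
#'   unlabeled pool may be empty only when `gamma = 0`.
#' @param gamma Combination weight in [-1, 1].
#' @inheritParams pu_risk
#' @return The risk value.
#' @export
pnu_risk <- function(scores_pos, scores_neg, scores_unl, gamma, prior_pos,
                     loss = "logistic", nonneg_correction = TRUE) {
  stopifnot(gamma >= -1, gamma <= 1)
  if (gamma == 0)
    return(pn_risk(scores_pos, scores_neg, prior_pos, loss))
  if (length(scores_unl) == 0)
    stop("unlabeled scores are required when gamma != 0")
  pn <- pn_risk(scores_pos, scores_neg, prior_pos, loss)
  if (gamma > 0) {
    if (gamma == 1)
      return(pu_risk(scores_pos, scores_unl, prior_pos, loss,
                     nonneg_correction))
    (1 - gamma) * pn + gamma * pu_risk(scores_pos, scores_unl, prior_pos,
                                       loss, nonneg_correction)
  } else {
    if (gamma == -1)
      return(nu_risk(scores_neg, scores_unl, prior_pos, loss,
                     nonneg_correction))
    (1 + gamma) * pn + (-gamma) * nu_risk(scores_neg, scores_unl,
                                          prior_pos, loss,
                                          nonneg_correction)
  }
}

#' PNU classifier configuration
#'
#' @param gamma Fixed combination weight in [-1, 1], or `NULL` to select it
#'   from `gamma_grid` by cross-validated PN risk on the labeled samples.
#' @param prior_pos Positive class prior; `NULL` uses the labeled
#'   proportion.
#' @param loss `"logistic"` or `"squared"`.
#' @param l2_penalty Ridge penalty on the weight vector.
#' @param nonneg_correction Clamp the implicit risk terms at 0.
#' @param cv_folds Folds for gamma selection.
#' @param gamma_grid Candidate gamma values.
#' @param max_iter,step,tol Deterministic full-batch gradient descent
#'   controls (step halves whenever the penalized risk increases;
#'   convergence at relative risk change below `tol`).
#' @param seed Seed for fold assignment.
#' @return A `pnu_config` list.
#' @export
pnu_config <- function(gamma = NULL, prior_pos = NULL, loss = "logistic",
                       l2_penalty = 1e-2, nonneg_correction = TRUE,
                       cv_folds = 5,
                       gamma_grid = c(-0.5, -0.25, 0, 0.25, 0.5, 0.75, 1),
                       max_iter = 2000, step = 0.1, tol = 1e-8, seed = 1) {
  if (!is.null(gamma)) stopifnot(gamma >= -1, gamma <= 1)
  if (!is.null(prior_pos)) stopifnot(prior_pos > 0, prior_pos < 1)
  stopifnot(l2_penalty >= 0, all(gamma_grid >= -1), all(gamma_grid <= 1))
  structure(list(gamma = gamma, prior_pos = prior_pos, loss = loss,
                 l2_penalty = l2_penalty,
                 nonneg_correction = nonneg_correction,
                 cv_folds = as.integer(cv_folds), gamma_grid = gamma_grid,
                 max_iter = as.integer(max_iter), step = step, tol = tol,
                 seed = as.integer(seed)),
            class = "pnu_config")
}

as_feature_matrix <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  storage.mode(x) <- "double"
  x
}

# Penalized PNU risk and its gradient for a linear scorer on standardized
# features; clamped terms contribute zero (sub)gradient.
pnu_objective <- function(theta, Xp, Xn, Xu, gamma, prior, l,
                          nonneg, l2) {
  d <- ncol(Xp)
  wvec <- theta[seq_len(d)]; b <- theta[d + 1]
  sp <- drop(Xp %*% wvec) + b
  sn <- drop(Xn %*% wvec) + b
  su <- if (!is.null(Xu) && nrow(Xu)) drop(Xu %*% wvec) + b else numeric(0)

  acc_g <- numeric(d + 1)
  add_term <- function(S, X, sign, coeff) {
    # coeff * mean l(sign * s); returns value, accumulates gradient
    if (coeff == 0 || length(S) == 0) return(0)
    gz <- l$grad(sign * S) * sign
    acc_g <<- acc_g + coeff * c(drop(crossprod(X, gz)), sum(gz)) / length(S)
    coeff * mean(l$fn(sign * S))
  }

  pn_w <- if (gamma >= 0) 1 - gamma else 1 + gamma
  pu_w <- max(gamma, 0)
  nu_w <- max(-gamma, 0)

  val <- 0
  val <- val + add_term(sp, Xp, +1, pn_w * prior)
  val <- val + add_term(sn, Xn, -1, pn_w * (1 - prior))
  if (pu_w > 0) {
    val <- val + add_term(sp, Xp, +1, pu_w * prior)
    neg_val <- mean(l$fn(-su)) - prior * mean(l$fn(-sp))
    if (!(nonneg && neg_val < 0)) {    # clamped bracket contributes zero
      val <- val + add_term(su, Xu, -1, pu_w)
      val <- val + add_term(sp, Xp, -1, -pu_w * prior)
    }
  }
  if (nu_w > 0) {
    pos_val <- mean(l$fn(su)) - (1 - prior) * mean(l$fn(sn))
    val <- val + add_term(sn, Xn, -1, nu_w * (1 - prior))
    if (!(nonneg && pos_val < 0)) {
      val <- val + add_term(su, Xu, +1, nu_w)
      val <- val + add_term(sn, Xn, +1, -nu_w * (1 - prior))
    }
  }
  val <- val + l2 * sum(wvec^2)
  acc_g[seq_len(d)] <- acc_g[seq_len(d)] + 2 * l2 * wvec
  list(value = val, grad = acc_g)
}

pnu_descend <- function(Xp, Xn, Xu, gamma, prior, l, nonneg, l2,
                        max_iter, step, tol) {
  d <- ncol(Xp)
  theta <- numeric(d + 1)
  ob <- pnu_objective(theta, Xp, Xn, Xu, gamma, prior, l, nonneg, l2)
  trace <- ob$value
  step0 <- step
  for (it in seq_len(max_iter)) {
    cand <- theta - step * ob$grad
    obc <- pnu_objective(cand, Xp, Xn, Xu, gamma, prior, l, nonneg, l2)
    if (obc$value > ob$value) {        # halve on risk increase
      step <- step / 2
      if (step < 1e-12) break
      next
    }
    rel <- abs(ob$value - obc$value) / max(abs(ob$value), 1e-12)
    theta <- cand; ob <- obc
    trace <- c(trace, ob$value)
    if (rel < tol) break
    step <- min(step * 1.1, 10 * step0)  # recover after cautious phases
  }
  list(theta = theta, value = ob$value, trace = trace)
}

#' Fit a linear PNU classifier
#'
#' Minimizes the gamma-combined PNU risk plus a ridge penalty over a linear
#' scorer by deterministic full-batch gradient descent. Features are
#' standardized internally (the returned coefficients are on the original
#' scale). When `config$gamma` is `NULL` and unlabeled samples are
#' present, gamma is selected from `gamma_grid` by `cv_folds`-fold
#' cross-validated PN risk on the labeled samples.
#'
#' @param x_pos,x_neg Feature matrices (rows = samples) of the labeled
#'   positive and negative pools.
#' @param x_unl Feature matrix of the unlabeled pool (may be `NULL`).
#' @param config A [pnu_config()].
#' @return A `pnu_fit` with `coefficients` (`weights`, `bias`), the fitted
#'   `gamma`, `prior`, `risk` (final penalized risk), `risk_trace`, and
#'   the gamma cross-validation table.
#' @export
fit_pnu <- function(x_pos, x_neg, x_unl = NULL, config = pnu_config()) {
  Xp <- as_feature_matrix(x_pos); Xn <- as_feature_matrix(x_neg)
  Xu <- as_feature_matrix(x_unl)
  stopifnot(nrow(Xp) > 0, nrow(Xn) > 0, ncol(Xp) == ncol(Xn))
  if (!is.null(Xu) && nrow(Xu) == 0) Xu <- NULL
  d <- ncol(Xp)
  pooled <- rbind(Xp, Xn, Xu)
  ctr <- colMeans(pooled)
  # population SD keeps the fit exactly invariant to sample duplication
  sds <- sqrt(colMeans(sweep(pooled, 2, ctr)^2))
  if (all(sds < 1e-12))
    stop("degenerate features: zero variance in every coordinate")
  scl <- ifelse(sds < 1e-12, 1, sds)
  std <- function(X) if (is.null(X)) NULL
        else sweep(sweep(X, 2, ctr), 2, scl, "/")
  Zp <- std(Xp); Zn <- std(Xn); Zu <- std(Xu)

  prior <- if (is.null(config$prior_pos))
    nrow(Xp) / (nrow(Xp) + nrow(Xn)) else config$prior_pos
  l <- resolve_loss(config$loss)

  cv_tab <- NULL
  gamma <- config$gamma
  if (is.null(gamma)) {
    grid <- config$gamma_grid
    if (is.null(Zu)) grid <- 0
    if (length(grid) > 1) {
      folds_p <- with_seed(config$seed, {
        list(p = sample(rep_len(seq_len(config$cv_folds), nrow(Zp))),
             n = sample(rep_len(seq_len(config$cv_folds), nrow(Zn))))
      })
      cv_risk <- sapply(grid, function(g) {
        fold_r <- vapply(seq_len(config$cv_folds), function(k) {
          trp <- Zp[folds_p$p != k, , drop = FALSE]
          trn <- Zn[folds_p$n != k, , drop = FALSE]
          tep <- Zp[folds_p$p == k, , drop = FALSE]
          ten <- Zn[folds_p$n == k, , drop = FALSE]
          if (!nrow(trp) || !nrow(trn) || !nrow(tep) || !nrow(ten))
            return(NA_real_)
          ft <- pnu_descend(trp, trn, Zu, g, prior, l,
                            config$nonneg_correction, config$l2_penalty,
                            min(config$max_iter, 500L), config$step,
                            config$tol)
          wv <- ft$theta[seq_len(d)]; b <- ft$theta[d + 1]
          pn_risk(drop(tep %*% wv) + b, drop(ten %*% wv) + b, prior, l)
        }, numeric(1))
        mean(fold_r, na.rm = TRUE)
      })
      cv_tab <- data.frame(gamma = grid, cv_pn_risk = cv_risk)
      gamma <- grid[which.min(cv_risk)]
    } else gamma <- grid[1]
  }

  fit <- pnu_descend(Zp, Zn, Zu, gamma, prior, l,
                     config$nonneg_correction, config$l2_penalty,
                     config$max_iter, config$step, config$tol)
  w_std <- fit$theta[seq_len(d)]; b_std <- fit$theta[d + 1]
  weights <- w_std / scl
  bias <- b_std - sum(w_std * ctr / scl)
  structure(list(coefficients = list(weights = weights, bias = bias),
                 gamma = gamma, prior = prior, loss = l$name,
                 risk = fit$value, risk_trace = fit$trace,
                 cv_table = cv_tab, config = config,
                 d = d),
            class = "pnu_fit")
}

#' @export
print.pnu_fit <- function(x, ...) {
  cat("Linear PNU classifier (", x$loss, " loss)\n", sep = "")
  cat(sprintf("  gamma %.2f  prior %.3f  final penalized risk %.5f\n",
              x$gamma, x$prior, x$risk))
  cat("  features:", x$d, "\n")
  invisible(x)
}

#' @export
coef.pnu_fit <- function(object, ...) {
  c(bias = object$coefficients$bias, object$coefficients$weights)
}

#' Score new samples with a PNU classifier
#'
#' @param object A `pnu_fit`.
#' @param newdata Feature matrix.
#' @param type `"score"` (linear), `"label"` (sign rule, ties negative) or
#'   `"confidence"` (|score| through the logistic link).
#' @param ... Unused.
#' @export
predict.pnu_fit <- function(object, newdata,
                            type = c("score", "label", "confidence"),
                            ...) {
  type <- match.arg(type)
  X <- as_feature_matrix(newdata)
  s <- drop(X %*% object$coefficients$weights) + object$coefficients$bias
  switch(type,
         score = s,
         label = ifelse(s > 0, "positive", "negative"),
         confidence = 1 / (1 + exp(-abs(s))))
}

#' Persist a PNU model as JSON
#'
#' Writes the weights, bias, fitted gamma, prior, loss name and a content
#' hash of the configuration; `read_pnu()` restores a scoring-capable
#' model.
#'
#' @param model A [fit_pnu()] result.
#' @param path JSON file path.
#' @return `read_pnu()` returns a `pnu_fit` usable with [predict.pnu_fit()].
#' @export
write_pnu <- function(model, path) {
  stopifnot(inherits(model, "pnu_fit"))
  jsonlite::write_json(list(
    weights = model$coefficients$weights,
    bias = model$coefficients$bias,
    gamma = model$gamma, prior = model$prior, loss = model$loss,
    config_hash = object_hash(model$config)), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_pnu
#' @export
read_pnu <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(coefficients = list(weights = j$weights, bias = j$bias),
                 gamma = j$gamma, prior = j$prior, loss = j$loss,
                 config_hash = j$config_hash, d = length(j$weights)),
            class = "pnu_fit")
}

#' Assign implicit labels to the unlabeled pool
#'
#' Hard labels by the sign of the fitted linear score (a score of exactly
#' zero is labeled negative), with confidence |score| mapped through the
#' logistic link.
#'
#' @param model A [fit_pnu()] result.
#' @param x_unl Feature matrix of unlabeled samples.
#' @param patient_ids Optional identifiers.
#' @return Data frame with `patient_id`, `label`, `score`, `confidence`.
#' @export
assign_implicit_labels <- function(model, x_unl, patient_ids = NULL) {
  X <- as_feature_matrix(x_unl)
  if (is.null(patient_ids))
    patient_ids <- rownames(X)
  if (is.null(patient_ids))
    patient_ids <- sprintf("unl%03d", seq_len(nrow(X)))
  s <- predict(model, X, type = "score")
  data.frame(patient_id = patient_ids,
             label = ifelse(s > 0, "positive", "negative"),
             score = s,
             confidence = 1 / (1 + exp(-abs(s))),
             stringsAsFactors = FALSE)
}
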