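#' Network configuration for the 3D residual feature extractor
#'
#' A compact 18-layer-style residual topology moved to 3D with reduced
#' stage widths. The last stage width must be 128 so that global average
#' pooling emits exactly 128 deep features.
#'
#' @param input_voxels Input side length (voxels, multiple of 4).
#' @param input_channels 2 for PET+CT, 1 for PET only.
#' @param stage_widths Channel counts of the four residual stages.
#' @param blocks_per_stage Residual blocks per stage.
#' @param dropout_rate Dropout on the pooled 128-feature vector (training
#'   only).
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Training epoch cap.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping.
#' @param val_fraction Fraction of training patients held out for early
#'   stopping (stratified); set 0 to disable.
#' @param augment Random axial flips / small translations during training.
#' @param seed Seed controlling initialization, shuffling and dropout.
#' @return A `network_config` list.
#' @export
network_config <- function(input_voxels = 32, input_channels = 2,
                           stage_widths = c(16, 32, 64, 128),
                           blocks_per_stage = 2, dropout_rate = 0.1,
                           learning_rate = 1e-3, batch_size = 8,
                           max_epochs = 60, early_stop_patience = 10,
                           val_fraction = 0.15, augment = FALSE,
                           seed = 1) {
  if (length(stage_widths) != 4 || any(stage_widths <= 0))
    stop("stage_widths must be four positive channel counts")
  if (stage_widths[4] != 128)
    stop("the last stage width must be 128 so that average pooling yields ",
         "exactly 128 features (got ", stage_widths[4], ")")
  if (input_voxels %% 4 != 0 || input_voxels < 8)
    stop("input_voxels must be a multiple of 4 and at least 8")
  if (!input_channels %in% 1:2)
    stop("input_channels must be 1 (PET) or 2 (PET+CT)")
  stopifnot(blocks_per_stage >= 1, dropout_rate >= 0, dropout_rate < 1,
            learning_rate > 0, batch_size >= 1, max_epochs >= 1)
  structure(list(input_voxels = as.integer(input_voxels),
                 input_channels = as.integer(input_channels),
                 stage_widths = as.integer(stage_widths),
                 blocks_per_stage = as.integer(blocks_per_stage),
                 dropout_rate = dropout_rate,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 val_fraction = val_fraction, augment = augment,
                 seed = as.integer(seed)),
            class = "network_config")
}

# Architecture walk: stem -> maxpool -> 4 stages of residual blocks
# (3x3x3 convs, stride 2 at the head of stages 2-4, projection shortcut on
# channel/stride change) -> global average pool -> 2-way softmax head.
network_arch <- function(config) {
  w <- config$stage_widths
  blocks <- list()
  cin <- w[1]
  for (s in 1:4) {
    for (b in seq_len(config$blocks_per_stage)) {
      stride <- if (s > 1 && b == 1) 2L else 1L
      cout <- w[s]
      blocks[[length(blocks) + 1]] <-
        list(name = sprintf("s%db%d", s, b), cin = cin, cout = cout,
             stride = stride, proj = (stride != 1L || cin != cout))
      cin <- cout
    }
  }
  list(stem = list(cin = config$input_channels, cout = w[1]),
       blocks = blocks)
}

he_init <- function(nrow, ncol, fan_in, scale = 1) {
  matrix(rnorm(nrow * ncol, 0, scale * sqrt(2 / fan_in)), nrow, ncol)
}

#' Build a 3D residual network
#'
#' Instantiates the network with deterministic He-style initialization
#' given the configuration seed. The residual-branch closing convolutions
#' are down-scaled at initialization (in lieu of batch normalization) and
#' the softmax head starts at zero, so an untrained network predicts both
#' classes at probability 0.5.
#'
#' @param config A [network_config()].
#' @return A `dcnn` object (untrained).
#' @export
build_network <- function(config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  arch <- network_arch(config)
  params <- with_seed(config$seed, {
    p <- list()
    p[["stem.W"]] <- he_init(arch$stem$cin * 27, arch$stem$cout,
                             arch$stem$cin * 27)
    p[["stem.b"]] <- numeric(arch$stem$cout)
    for (bl in arch$blocks) {
      p[[paste0(bl$name, ".W1")]] <- he_init(bl$cin * 27, bl$cout,
                                             bl$cin * 27)
      p[[paste0(bl$name, ".b1")]] <- numeric(bl$cout)
      p[[paste0(bl$name, ".W2")]] <- he_init(bl$cout * 27, bl$cout,
                                             bl$cout * 27, scale = 0.25)
      p[[paste0(bl$name, ".b2")]] <- numeric(bl$cout)
      if (bl$proj)
        p[[paste0(bl$name, ".P")]] <- he_init(bl$cin, bl$cout, bl$cin)
    }
    p[["fc.W"]] <- matrix(0, 128, 2)
    p[["fc.b"]] <- numeric(2)
    p
  })
  structure(list(params = params, config = config, arch = arch,
                 trained = FALSE, history = NULL),
            class = "dcnn")
}

# Strided spatial subsampling indices matching a pad-1 stride-s 3x3x3 conv.
sub_idx <- function(n, stride) seq(1, n, by = stride)[seq_len((n - 1) %/% stride + 1)]

proj_forward <- function(x, P, stride) {
  d <- dim(x)
  sx <- sub_idx(d[2], stride); sy <- sub_idx(d[3], stride)
  sz <- sub_idx(d[4], stride)
  sub <- x[, sx, sy, sz, drop = FALSE]
  m <- matrix(sub, d[1])
  out <- crossprod(P, m)
  array(out, c(ncol(P), length(sx), length(sy), length(sz)))
}

proj_backward <- function(x, P, dout, stride) {
  d <- dim(x)
  sx <- sub_idx(d[2], stride); sy <- sub_idx(d[3], stride)
  sz <- sub_idx(d[4], stride)
  sub <- x[, sx, sy, sz, drop = FALSE]
  m <- matrix(sub, d[1])
  dO <- matrix(dout, dim(dout)[1])
  dP <- m %*% t(dO)
  dsub <- P %*% dO
  dx <- array(0, d)
  dx[, sx, sy, sz] <- array(dsub, c(d[1], length(sx), length(sy),
                                    length(sz)))
  dx
}

# Forward pass for one sample; returns probabilities, the 128 pooled
# features, and (optionally) the caches needed for backpropagation.
dcnn_forward <- function(net, x, train = FALSE, keep_cache = FALSE,
                         drop_mask = NULL, ws = NULL) {
  p <- net$params
  cache <- if (keep_cache) list() else NULL
  oe <- function(n, s) (n + 2L - 3L) %/% s + 1L
  conv <- function(z, W, b, stride, key) {
    # training passes keep the im2col matrix for reuse in backprop; with a
    # workspace environment the (shape-constant) buffers are also reused
    # across samples, since their zero padding positions are never written
    if (!keep_cache)
      return(list(out = .conv3d_forward(z, dim(z), W, b, stride),
                  cols = NULL))
    if (is.null(ws))
      return(.conv3d_forward_cols(z, dim(z), W, b, stride))
    buf <- ws[[key]]
    if (is.null(buf)) {
      d <- dim(z)
      buf <- matrix(0, prod(oe(d[2], stride), oe(d[3], stride),
                            oe(d[4], stride)), d[1] * 27L)
      ws[[key]] <- buf
    }
    list(out = .conv3d_forward_ws(z, dim(z), W, b, stride, buf),
         cols = buf)
  }
  cs <- conv(x, p[["stem.W"]], p[["stem.b"]], 2L, "stem")
  a <- cs$out
  r <- a * (a > 0)
  mp <- .maxpool3d_forward(r, dim(r))
  h <- mp$out
  if (keep_cache)
    cache$stem <- list(x_dim = dim(x), cols = cs$cols, a = a,
                       r_dim = dim(r), mp_idx = mp$idx)
  for (bl in net$arch$blocks) {
    nm <- bl$name
    c1 <- conv(h, p[[paste0(nm, ".W1")]], p[[paste0(nm, ".b1")]],
               bl$stride, paste0(nm, ".1"))
    a1 <- c1$out
    r1 <- a1 * (a1 > 0)
    c2 <- conv(r1, p[[paste0(nm, ".W2")]], p[[paste0(nm, ".b2")]], 1L,
               paste0(nm, ".2"))
    a2 <- c2$out
    sc <- if (bl$proj) proj_forward(h, p[[paste0(nm, ".P")]], bl$stride)
          else h
    o <- a2 + sc
    out <- o * (o > 0)
    if (keep_cache)
      cache[[nm]] <- list(h = h, a1 = a1, r1_dim = dim(r1), o = o,
                          cols1 = c1$cols, cols2 = c2$cols)
    h <- out
  }
  d <- dim(h)
  V <- prod(d[2:4])
  feats <- rowMeans(matrix(h, d[1]))
  feats_d <- feats
  if (train && !is.null(drop_mask)) feats_d <- feats_d * drop_mask
  z <- drop(crossprod(p[["fc.W"]], feats_d)) + p[["fc.b"]]
  zs <- z - max(z)
  ez <- exp(zs)
  prob <- ez / sum(ez)
  if (keep_cache) {
    cache$pool <- list(dim = d, V = V, feats = feats, feats_d = feats_d,
                       drop_mask = drop_mask)
  }
  list(prob = prob, features = feats, logits = z, cache = cache)
}

# Backpropagation from the softmax gradient dz (length 2, already weighted)
# through the whole network. Returns a per-parameter gradient list, or --
# when `layout` and a flat accumulator `acc` are supplied -- writes each
# parameter's gradient into its segment of `acc` (adding unless
# `overwrite`), avoiding per-sample gradient allocations.
dcnn_backward <- function(net, fwd, dz, layout = NULL, acc = NULL,
                          overwrite = FALSE) {
  p <- net$params
  cache <- fwd$cache
  if (is.null(layout)) {
    g <- list()
    assign_g <- function(nm, val) g[[nm]] <<- val
  } else {
    g <- acc
    assign_g <- function(nm, val)
      .acc_segment(acc, layout$start[[nm]], val, overwrite)
  }
  pool <- cache$pool
  assign_g("fc.W", pool$feats_d %o% dz)
  assign_g("fc.b", dz)
  df <- drop(p[["fc.W"]] %*% dz)
  if (!is.null(pool$drop_mask)) df <- df * pool$drop_mask
  d <- pool$dim
  dh <- array(rep(df / pool$V, prod(d[2:4])), d)
  for (bl in rev(net$arch$blocks)) {
    nm <- bl$name
    cb <- cache[[nm]]
    do_ <- dh * (cb$o > 0)
    bw2 <- .conv3d_backward_cols(cb$cols2, cb$r1_dim,
                                 p[[paste0(nm, ".W2")]], do_, 1L)
    assign_g(paste0(nm, ".W2"), bw2$dW)
    assign_g(paste0(nm, ".b2"), bw2$db)
    da1 <- bw2$dx * (cb$a1 > 0)
    bw1 <- .conv3d_backward_cols(cb$cols1, dim(cb$h),
                                 p[[paste0(nm, ".W1")]], da1, bl$stride)
    assign_g(paste0(nm, ".W1"), bw1$dW)
    assign_g(paste0(nm, ".b1"), bw1$db)
    if (bl$proj) {
      assign_g(paste0(nm, ".P"), {
        dO <- matrix(do_, dim(do_)[1])
        sxs <- lapply(2:4, function(i) sub_idx(dim(cb$h)[i], bl$stride))
        sub <- cb$h[, sxs[[1]], sxs[[2]], sxs[[3]], drop = FALSE]
        matrix(sub, dim(cb$h)[1]) %*% t(dO)
      })
      dh <- bw1$dx + proj_backward_dx(cb$h, p[[paste0(nm, ".P")]], do_,
                                      bl$stride)
    } else {
      dh <- bw1$dx + do_
    }
  }
  st <- cache$stem
  dr <- .maxpool3d_backward(dh, st$mp_idx, st$r_dim)
  da <- dr * (st$a > 0)
  bws <- .conv3d_backward_cols(st$cols, st$x_dim, p[["stem.W"]], da, 2L)
  assign_g("stem.W", bws$dW)
  assign_g("stem.b", bws$db)
  g
}

proj_backward_dx <- function(x, P, dout, stride) {
  d <- dim(x)
  sxs <- lapply(2:4, function(i) sub_idx(d[i], stride))
  dO <- matrix(dout, dim(dout)[1])
  dsub <- P %*% dO
  dx <- array(0, d)
  dx[, sxs[[1]], sxs[[2]], sxs[[3]]] <-
    array(dsub, c(d[1], lengths(sxs)))
  dx
}

as_input_tensor <- function(x, config) {
  if (inherits(x, "roi_tensor")) x <- x$data
  d <- dim(x)
  if (length(d) != 4 || d[1] != config$input_channels ||
      any(d[2:4] != config$input_voxels))
    stop("input tensor shape (", paste(d, collapse = "x"),
         ") does not match the network configuration (",
         config$input_channels, "x", config$input_voxels, "^3)")
  x
}

augment_tensor <- function(x) {
  d <- dim(x)
  for (ax in 2:3) {                      # axial flips
    if (runif(1) < 0.5) {
      idx <- rev(seq_len(d[ax]))
      x <- if (ax == 2) x[, idx, , , drop = FALSE]
           else x[, , idx, , drop = FALSE]
    }
  }
  sh <- sample(-3:3, 3, replace = TRUE)  # small translation, zero fill
  if (any(sh != 0)) {
    y <- array(0, d)
    src <- lapply(1:3, function(a) {
      i <- seq_len(d[a + 1]) - sh[a]
      i[i >= 1 & i <= d[a + 1]]
    })
    dst <- lapply(1:3, function(a) {
      i <- seq_len(d[a + 1])
      i[(i + sh[a]) >= 1 & (i + sh[a]) <= d[a + 1]] + sh[a]
    })
    y[, dst[[1]], dst[[2]], dst[[3]]] <- x[, src[[1]], src[[2]], src[[3]]]
    x <- y
  }
  x
}

#' Train the 3D residual network with supervision
#'
#' Minimizes weighted softmax cross-entropy with Adam. Per-class loss
#' weights are inversely proportional to class frequency; per-sample
#' weights multiply them (a zero weight removes a sample's gradient
#' contribution entirely). A stratified fraction of the training patients
#' is held out for early stopping, and the returned model carries the
#' parameters of the best validation epoch.
#'
#' @param x List of input tensors ([crop_resample()] outputs or arrays of
#'   dim `(channels, v, v, v)`).
#' @param labels Binary vector (1 = positive/relapse class).
#' @param sample_weights Optional non-negative per-sample weights.
#' @param config A [network_config()].
#' @param net Optional pre-built or pre-trained [build_network()] model to
#'   continue from; defaults to a fresh deterministic initialization.
#' @param val_pool Optional logical vector marking the samples eligible
#'   for the early-stopping holdout (e.g. only patients with trusted
#'   labels when part of the training set is implicitly labeled).
#' @param verbose Print per-epoch losses.
#' @return A trained `dcnn` with a `history` data frame (per-epoch train
#'   and validation loss).
#' @export
train_dcnn <- function(x, labels, sample_weights = NULL,
                       config = network_config(), net = NULL,
                       val_pool = NULL, verbose = FALSE) {
  x <- lapply(x, as_input_tensor, config = config)
  n <- length(x)
  labels <- as.integer(labels)
  stopifnot(length(labels) == n, all(labels %in% 0:1))
  if (is.null(sample_weights)) sample_weights <- rep(1, n)
  stopifnot(length(sample_weights) == n, all(sample_weights >= 0))
  if (length(unique(labels[sample_weights > 0])) < 2)
    stop("training set contains a single class; both classes are required")
  if (is.null(val_pool)) val_pool <- rep(TRUE, n)
  stopifnot(length(val_pool) == n)
  if (is.null(net)) net <- build_network(config)

  eff <- sample_weights > 0            # zero-weight samples carry no
  nc <- table(factor(labels[eff], levels = 0:1))  # influence at all
  class_w <- as.numeric(sum(eff) / (2 * pmax(nc, 1)))  # inverse-frequency
  w <- sample_weights * class_w[labels + 1]

  lr <- config$learning_rate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  params <- net$params
  # Adam runs on one flat parameter vector; the list view is rebuilt for
  # the forward/backward passes after each update
  pnames <- names(params)
  plens <- vapply(params, length, integer(1))
  pends <- cumsum(plens)
  pstarts <- pends - plens + 1
  theta <- unlist(params, use.names = FALSE)
  glayout <- list(start = as.list(setNames(pstarts, pnames)),
                  len = as.list(setNames(plens, pnames)),
                  total = length(theta))
  gacc <- numeric(length(theta))        # persistent gradient accumulator
  mstate <- numeric(length(theta))
  vstate <- numeric(length(theta))
  tstep <- 0
  relist_params <- function(th) {
    for (i in seq_along(pnames)) params[[i]][] <<- th[pstarts[i]:pends[i]]
    params
  }

  conv_ws <- new.env(parent = emptyenv())   # reused im2col buffers
  sample_loss <- function(i, train, drop_mask = NULL, keep_cache = FALSE,
                          xi = x[[i]]) {
    fwd <- dcnn_forward(net, xi, train = train, keep_cache = keep_cache,
                        drop_mask = drop_mask,
                        ws = if (keep_cache) conv_ws else NULL)
    y <- labels[i]
    ce <- -log(max(fwd$prob[y + 1], 1e-300))
    list(fwd = fwd, loss = w[i] * ce,
         dz = w[i] * (fwd$prob - c(1 - y, y)))
  }

  history <- NULL
  with_seed(derive_seed(config$seed, 977L), {
    # stratified early-stopping split
    val_idx <- integer(0)
    if (config$val_fraction > 0) {
      for (cl in 0:1) {
        cl_idx <- which(labels == cl & sample_weights > 0 & val_pool)
        k <- round(config$val_fraction * length(cl_idx))
        if (k >= 1 && length(cl_idx) - k >= 1)
          val_idx <- c(val_idx, sample(cl_idx, k))
      }
    }
    train_idx <- setdiff(which(sample_weights >= 0), val_idx)
    if (length(unique(labels[intersect(train_idx,
                                       which(sample_weights > 0))])) < 2) {
      train_idx <- seq_len(n)
      val_idx <- integer(0)
    }
    use_val <- length(val_idx) >= 2

    best <- list(loss = Inf, params = params, epoch = 0)
    patience_left <- config$early_stop_patience
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(train_idx)
      ep_loss <- 0; ep_wsum <- 0
      for (start in seq(1, length(ord), by = config$batch_size)) {
        batch <- ord[start:min(start + config$batch_size - 1, length(ord))]
        nacc <- 0L
        for (i in batch) {
          xi <- x[[i]]
          if (config$augment) xi <- augment_tensor(xi)
          dmask <- if (config$dropout_rate > 0)
            (runif(128) >= config$dropout_rate) / (1 - config$dropout_rate)
          else NULL
          sl <- sample_loss(i, train = TRUE, drop_mask = dmask,
                            keep_cache = TRUE, xi = xi)
          ep_loss <- ep_loss + sl$loss; ep_wsum <- ep_wsum + 1
          if (w[i] == 0) next        # no gradient contribution
          dcnn_backward(net, sl$fwd, sl$dz, layout = glayout, acc = gacc,
                        overwrite = nacc == 0L)
          nacc <- nacc + 1L
        }
        if (nacc == 0L) next
        gflat <- gacc / length(batch)
        tstep <- tstep + 1
        mstate <- b1 * mstate + (1 - b1) * gflat
        vstate <- b2 * vstate + (1 - b2) * gflat^2
        theta <- theta - lr * (mstate / (1 - b1^tstep)) /
          (sqrt(vstate / (1 - b2^tstep)) + eps)
        params <- relist_params(theta)
        net$params <- params
      }
      train_loss <- ep_loss / max(ep_wsum, 1)
      val_loss <- NA_real_
      if (use_val) {
        vl <- vapply(val_idx, function(i) sample_loss(i, FALSE)$loss,
                     numeric(1))
        val_loss <- mean(vl)
        if (val_loss < best$loss - 1e-6) {
          best <- list(loss = val_loss, params = params, epoch = epoch)
          patience_left <- config$early_stop_patience
        } else {
          patience_left <- patience_left - 1
        }
      }
      history <- rbind(history,
                       data.frame(epoch = epoch, train_loss = train_loss,
                                  val_loss = val_loss))
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %s", epoch, train_loss,
                        ifelse(is.na(val_loss), "-",
                               sprintf("%.4f", val_loss))))
      if (use_val && patience_left <= 0) break
    }
    if (use_val && best$epoch > 0) {
      net$params <- best$params
      net$best_epoch <- best$epoch
    } else {
      net$params <- params
      net$best_epoch <- nrow(history)
    }
  })
  net$trained <- TRUE
  net$history <- history
  net
}

#' @export
print.dcnn <- function(x, ...) {
  cfg <- x$config
  cat("3D residual network (", cfg$input_channels, "ch x ",
      cfg$input_voxels, "^3 input; stage widths ",
      paste(cfg$stage_widths, collapse = "/"), ")\n", sep = "")
  cat("  parameters:", format(sum(vapply(x$params, length, 1L)),
                              big.mark = ","), "\n")
  if (x$trained)
    cat("  trained:", nrow(x$history), "epochs; best epoch",
        x$best_epoch, "\n")
  else cat("  untrained\n")
  invisible(x)
}

#' Save / load a network checkpoint
#'
#' The model is written in R's native serialization alongside a JSON
#' sidecar describing the network configuration, so checkpoints are
#' self-describing.
#'
#' @param net A `dcnn`.
#' @param path Checkpoint path (`.rds`); the sidecar is written next to it
#'   as `<path>.json`.
#' @return `load_dcnn()` returns the restored `dcnn`.
#' @export
save_dcnn <- function(net, path) {
  stopifnot(inherits(net, "dcnn"))
  saveRDS(net, path)
  jsonlite::write_json(unclass(net$config), paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_dcnn
#' @export
load_dcnn <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "dcnn"))
  net
}

#' Predict from a trained network
#'
#' @param object A `dcnn`.
#' @param newdata List of ROI tensors or arrays.
#' @param type `"prob"` for class probabilities, `"features"` for the 128
#'   average-pooling features, `"class"` for hard labels.
#' @param ... Unused.
#' @return A data frame (`"prob"`), matrix (`"features"`), or integer
#'   vector (`"class"`). Inference is deterministic (no dropout).
#' @export
predict.dcnn <- function(object, newdata,
                         type = c("prob", "features", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "roi_tensor") || (is.array(newdata) &&
      length(dim(newdata)) == 4))
    newdata <- list(newdata)
  ids <- vapply(seq_along(newdata), function(i) {
    nd <- newdata[[i]]
    if (inherits(nd, "roi_tensor") && !is.null(nd$patient_id))
      nd$patient_id else sprintf("sample%03d", i)
  }, character(1))
  xs <- lapply(newdata, as_input_tensor, config = object$config)
  out <- lapply(xs, function(xi) dcnn_forward(object, xi))
  if (type == "features") {
    m <- do.call(rbind, lapply(out, `[[`, "features"))
    rownames(m) <- ids
    colnames(m) <- sprintf("f%03d", 0:127)
    return(m)
  }
  probs <- do.call(rbind, lapply(out, `[[`, "prob"))
  if (type == "class") return(as.integer(probs[, 2] > 0.5))
  data.frame(patient_id = ids, p_pos = probs[, 2], p_neg = probs[, 1],
             stringsAsFactors = FALSE)
}

#' Extract the 128 deep features
#'
#' Convenience wrapper around `predict(net, type = "features")`: the
#' output of the global average-pooling layer, one length-128 row per
#' input, in input order.
#'
#' @param net A `dcnn`.
#' @param rois List of ROI tensors.
#' @return Numeric matrix, `length(rois)` x 128.
#' @export
extract_features <- function(net, rois) predict(net, rois, type = "features")

#' Predicted class probabilities
#'
#' @param net A `dcnn`.
#' @param rois List of ROI tensors.
#' @return Data frame with `patient_id`, `p_pos`, `p_neg` (summing to 1).
#' @export
predict_probabilities <- function(net, rois) predict(net, rois, type = "prob")

#' Arrange 128 deep features as a 16 x 8 strip
#'
#' Row-major layout: the value at row r, column c (0-based) is feature
#' 8 r + c, so flattening the raw grid row-major recovers the original
#' vector. A copy rescaled to [0, 1] is included for rendering.
#'
#' @param values Numeric vector of length 128 (or a 1-row feature matrix).
#' @param patient_id Optional identifier for the plot title.
#' @return A `feature_strip`: list with `raw` and `scaled` 16 x 8 matrices.
#' @export
feature_strip <- function(values, patient_id = NULL) {
  values <- as.numeric(values)
  if (length(values) != 128)
    stop("feature vector must have length 128, got ", length(values))
  raw <- matrix(values, nrow = 16, ncol = 8, byrow = TRUE)
  rng <- range(raw)
  scaled <- if (diff(rng) > 0) (raw - rng[1]) / diff(rng)
            else matrix(0.5, 16, 8)
  structure(list(raw = raw, scaled = scaled, patient_id = patient_id),
            class = "feature_strip")
}

#' @export
plot.feature_strip <- function(x, ...) {
  graphics::image(t(x$scaled[16:1, ]), axes = FALSE, col = grDevices::gray.colors(64),
                  main = if (is.null(x$patient_id)) "feature strip"
                         else paste("feature strip:", x$patient_id), ...)
  invisible(x)
}
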