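# Semi-supervised convolutional autoencoder for tonic concentration
# regression, with a three-phase transfer-learning scheme:
#   phase 1 - joint regression + reconstruction training on labeled
#             in-vitro heatmaps;
#   phase 2 - reconstruction-only adaptation of the encoder/decoder on
#             unlabeled in-vivo heatmaps (weights transferred from phase 1,
#             regression head removed);
#   phase 3 - prediction with the phase-2 encoder and the phase-1 head.

#' Autoencoder architecture configuration
#'
#' Encoder: `length(enc_filters)` blocks of separable 2D convolution
#' (depthwise `kernel x kernel` + pointwise) -> batch normalization -> ReLU
#' -> `pool x pool` max pooling, ending in a low-dimensional 2D latent grid.
#' Head: dropout on the flattened latent, then dense layers of widths
#' `head_units` (ReLU between, linear final; the last width must be 3 — one
#' output per analyte). Decoder: mirrored 2D convolution + ReLU + nearest-
#' neighbour upsampling blocks, closing with a 1-channel convolution squashed
#' to \[0, 1\] by a sigmoid so the reconstruction is comparable to normalized
#' input pixels.
#'
#' The defaults are sized so a full three-phase run trains in minutes on one
#' CPU core at the desk-scale 64 x 32 heatmap geometry; all sizes scale by
#' configuration.
#'
#' @param input_shape `(rows, cols)` of input heatmaps; each must be
#'   divisible by `pool^length(enc_filters)`.
#' @param enc_filters filters per encoder block.
#' @param dec_filters filters per decoder block (same count as encoder).
#' @param head_units dense widths, ending in 3.
#' @param kernel convolution kernel size (odd).
#' @param pool pooling / upsampling factor.
#' @param dropout dropout rate on the flattened latent.
#' @param depth_multiplier spatial filters learned per input channel in each
#'   separable convolution (the depthwise stage); more than one matters most
#'   in the first block, where a single-channel input would otherwise yield
#'   only one spatial feature map.
#' @return an `arch_config`.
#' @export
arch_config <- function(input_shape = c(64, 32), enc_filters = c(8, 16, 32),
                        dec_filters = c(16, 8, 8), head_units = c(64, 3),
                        kernel = 3, pool = 2, dropout = 0.2,
                        depth_multiplier = 4) {
  nb <- length(enc_filters)
  if (length(dec_filters) != nb)
    stop("arch_config: decoder must mirror encoder block count so the ",
         "reconstruction returns to input_shape")
  red <- pool^nb
  if (any(input_shape %% red != 0))
    stop("arch_config: input_shape ", paste(input_shape, collapse = "x"),
         " is not divisible by pool^blocks = ", red,
         "; decoder cannot return to the input shape")
  if (utils::tail(head_units, 1) != 3)
    stop("arch_config: final head width must be 3 (DA, NE, 5-HT)")
  latent_grid <- input_shape %/% red
  if (prod(latent_grid) >= prod(input_shape))
    stop("arch_config: latent grid must have fewer elements than the input")
  if (kernel %% 2 != 1) stop("arch_config: kernel must be odd")
  if (depth_multiplier < 1) stop("arch_config: depth_multiplier must be >= 1")
  if (dropout < 0 || dropout >= 1) stop("arch_config: dropout must be in [0, 1)")
  structure(list(input_shape = as.integer(input_shape),
                 enc_filters = as.integer(enc_filters),
                 dec_filters = as.integer(dec_filters),
                 head_units = as.integer(head_units),
                 kernel = as.integer(kernel), pool = as.integer(pool),
                 dropout = dropout,
                 depth_multiplier = as.integer(depth_multiplier),
                 latent_shape = as.integer(c(latent_grid,
                                             utils::tail(enc_filters, 1)))),
            class = "arch_config")
}

#' Training schedule configuration
#'
#' Adam optimization with a reduce-on-plateau learning-rate schedule: after
#' `lr_patience` epochs without validation-loss reduction the learning rate
#' is divided by `lr_factor` (floored at `lr_min`); training runs at most
#' `max_epochs` epochs and stops early after `stop_patience` epochs without
#' validation-loss reduction. The weights returned are those of the best
#' validation epoch.
#'
#' @param initial_lr initial Adam learning rate; the 3e-3 default gives the
#'   optimizer enough headroom to keep making validation progress before the
#'   aggressive 10-fold plateau reductions set in.
#' @param lr_patience epochs of no improvement before an LR reduction.
#' @param lr_factor reduction factor (LR is divided by this).
#' @param lr_min learning-rate floor.
#' @param max_epochs maximum training epochs.
#' @param stop_patience early-stopping patience (epochs).
#' @param batch_size minibatch size; small batches (default 8) give the
#'   desk-scale datasets enough optimizer steps per epoch for the
#'   epoch-granular plateau schedule to see steady improvement.
#' @param val_fraction fraction of the phase's data held out (seeded) for
#'   validation loss.
#' @param loss_weights `(regression, reconstruction)` loss weights.
#' @param seed integer seed for initialization, shuffling, dropout and the
#'   validation split.
#' @return a `training_config`.
#' @export
training_config <- function(initial_lr = 3e-3, lr_patience = 3,
                            lr_factor = 10, lr_min = 1e-6, max_epochs = 50,
                            stop_patience = 20, batch_size = 8,
                            val_fraction = 0.15, loss_weights = c(1, 1),
                            seed = 1) {
  if (lr_min > initial_lr) stop("training_config: lr_min must be <= initial_lr")
  if (lr_patience < 1 || stop_patience < 1)
    stop("training_config: patiences must be >= 1")
  structure(list(initial_lr = initial_lr, lr_patience = as.integer(lr_patience),
                 lr_factor = lr_factor, lr_min = lr_min,
                 max_epochs = as.integer(max_epochs),
                 stop_patience = as.integer(stop_patience),
                 batch_size = as.integer(batch_size),
                 val_fraction = val_fraction, loss_weights = loss_weights,
                 seed = as.integer(seed)),
            class = "training_config")
}

# Label-scaling record: concentrations are centered at the training-label
# mean and divided by a fixed 1000 nM full-scale before the RMSE loss (so
# both losses have comparable magnitude and the network starts at the
# mean-predictor solution); the affine map is inverted at prediction.
LABEL_SCALE_NM <- 1000

glorot <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  stats::runif(n, -lim, lim)
}

init_weights <- function(arch, seed = 1, with_head = TRUE) {
  with_local_seed(derive_seed(seed, "init"), {
    w <- list()
    k <- arch$kernel
    cin <- 1L
    for (l in seq_along(arch$enc_filters) - 1L) {
      cout <- arch$enc_filters[l + 1L]
      dm <- arch$depth_multiplier
      w[[sprintf("enc%d_dw", l)]] <-
        array(glorot(k * k, k * k * dm, k * k * cin * dm),
              dim = c(k, k, cin * dm))
      w[[sprintf("enc%d_pw", l)]] <-
        matrix(glorot(cin * dm, cout, cin * dm * cout), cin * dm, cout)
      w[[sprintf("enc%d_b", l)]] <- numeric(cout)
      w[[sprintf("enc%d_gamma", l)]] <- rep(1, cout)
      w[[sprintf("enc%d_beta", l)]] <- numeric(cout)
      w[[sprintf("enc%d_rm", l)]] <- numeric(cout)
      w[[sprintf("enc%d_rv", l)]] <- rep(1, cout)
      cin <- cout
    }
    if (with_head) {
      din <- prod(arch$latent_shape)
      for (j in seq_along(arch$head_units) - 1L) {
        dout <- arch$head_units[j + 1L]
        w[[sprintf("head%d_W", j)]] <-
          matrix(glorot(din, dout, din * dout), din, dout)
        w[[sprintf("head%d_b", j)]] <- numeric(dout)
        din <- dout
      }
    }
    cin <- utils::tail(arch$enc_filters, 1)
    for (l in seq_along(arch$dec_filters) - 1L) {
      cout <- arch$dec_filters[l + 1L]
      w[[sprintf("dec%d_W", l)]] <-
        array(glorot(k * k * cin, k * k * cout, k * k * cin * cout),
              dim = c(k, k, cin * cout))
      w[[sprintf("dec%d_b", l)]] <- numeric(cout)
      cin <- cout
    }
    w[["out_W"]] <- array(glorot(k * k * cin, k * k, k * k * cin),
                          dim = c(k, k, cin))
    w[["out_b"]] <- numeric(1)
    w
  })
}

#' Build an autoencoder network
#'
#' Instantiates the architecture with seeded random (Glorot-uniform) weight
#' initialization. With `with_head = FALSE` the network carries no dense
#' regression blocks (the reconstruction-only phase-2 form).
#'
#' @param arch an [arch_config()].
#' @param with_head include the dropout + dense concentration head.
#' @param seed initialization seed.
#' @return a `dn_network`.
#' @export
build_autoencoder <- function(arch, with_head = TRUE, seed = 1) {
  stopifnot(inherits(arch, "arch_config"))
  structure(list(arch = arch, with_head = with_head,
                 weights = init_weights(arch, seed, with_head),
                 norm_map = NULL, label_scale = LABEL_SCALE_NM),
            class = "dn_network")
}

arch_identical <- function(a, b) {
  identical(a[c("input_shape", "enc_filters", "dec_filters", "head_units",
                "kernel", "pool")],
            b[c("input_shape", "enc_filters", "dec_filters", "head_units",
                "kernel", "pool")])
}

cfg_list <- function(t, use_head, use_decoder, seed_offset = 0L) {
  list(use_head = use_head, use_decoder = use_decoder,
       w_reg = t$loss_weights[1], w_rec = t$loss_weights[2],
       initial_lr = t$initial_lr, lr_patience = t$lr_patience,
       lr_factor = t$lr_factor, lr_min = t$lr_min,
       max_epochs = t$max_epochs, stop_patience = t$stop_patience,
       batch_size = t$batch_size,
       seed = derive_seed(t$seed + seed_offset, "train"))
}

history_df <- function(h, phase) {
  df <- data.frame(epoch = seq_along(h$lr), lr = h$lr,
                   train_total = h$train_total, val_total = h$val_total)
  if (phase == 1) {
    df$train_reg <- h$train_reg; df$val_reg <- h$val_reg
    df$train_rec <- h$train_rec; df$val_rec <- h$val_rec
  } else {
    df$train_rec <- h$train_rec; df$val_rec <- h$val_rec
  }
  df
}

split_val <- function(n, val_fraction, seed) {
  n_val <- max(1L, floor(val_fraction * n))
  if (n_val >= n) stop("validation split leaves no training data")
  val <- with_local_seed(derive_seed(seed, "valsplit"), sample.int(n, n_val))
  list(train = setdiff(seq_len(n), val), val = val)
}

#' Phase 1: joint supervised + reconstruction training
#'
#' Minimizes `loss_weights[1] * RMSE(scaled labels) + loss_weights[2] *
#' binary cross-entropy(pixels)` on labeled, normalized in-vitro heatmaps,
#' with the plateau LR schedule and early stopping of the
#' [training_config()]. Returns the best-validation-epoch weights.
#'
#' @param net a `dn_network` built with a head.
#' @param train a normalized `vg_dataset` with labels.
#' @param t a [training_config()].
#' @return list with `weights` (a `trained_weights`, phase 1) and `history`
#'   (per-epoch data frame: learning rate, regression RMSE and binary
#'   cross-entropy, training and validation).
#' @export
train_phase1 <- function(net, train, t = training_config()) {
  stopifnot(inherits(net, "dn_network"), inherits(train, "vg_dataset"))
  if (!net$with_head) stop("train_phase1: network has no regression head")
  if (!train$normalized)
    stop("train_phase1: heatmaps must be normalized to [0, 1] ",
         "(binary cross-entropy requires it); see fit_normalization()")
  if (anyNA(train$labels)) stop("train_phase1: all records must be labeled")
  X <- to_heatmap_array(train)
  label_center <- c(0, 0, 0)   # raw-scale regression, as in the loss curves
  Y <- sweep(train$labels, 2, label_center) / net$label_scale
  idx <- split_val(length(train), t$val_fraction, t$seed)
  res <- dn_train_cpp(net$weights, unclass(net$arch),
                      X[, , idx$train, drop = FALSE],
                      Y[idx$train, , drop = FALSE],
                      X[, , idx$val, drop = FALSE],
                      Y[idx$val, , drop = FALSE],
                      cfg_list(t, TRUE, TRUE))
  tw <- structure(list(phase = 1L, weights = res$weights, arch = net$arch,
                       norm_map = train$norm_map,
                       label_scale = net$label_scale,
                       label_center = label_center),
                  class = "trained_weights")
  list(weights = tw, history = history_df(res$history, 1))
}

#' Transfer trained weights into a compatible network
#'
#' Copies every weight block whose name exists in both the source and the
#' target; shared blocks end up bitwise-equal to the source. Blocks absent
#' from the target (the regression head, when the target was built
#' `with_head = FALSE`) are simply not transferred. Shape mismatches are an
#' error naming the offending layers.
#'
#' @param source a `trained_weights`.
#' @param target a `dn_network` with the same architecture.
#' @return the target network with transferred weights; the source's
#'   normalization map and label scaling travel with it.
#' @export
transfer_weights <- function(source, target) {
  stopifnot(inherits(source, "trained_weights"), inherits(target, "dn_network"))
  if (!arch_identical(source$arch, target$arch))
    stop("transfer_weights: architecture mismatch")
  shared <- intersect(names(target$weights), names(source$weights))
  bad <- shared[vapply(shared, function(nm)
    !identical(dim2(source$weights[[nm]]), dim2(target$weights[[nm]])),
    logical(1))]
  if (length(bad))
    stop("transfer_weights: shape mismatch in layer(s): ",
         paste(bad, collapse = ", "))
  for (nm in shared) target$weights[[nm]] <- source$weights[[nm]]
  target$norm_map <- source$norm_map
  target$label_scale <- source$label_scale
  target$label_center <- source$label_center
  target
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Phase 2: reconstruction-only adaptation on unlabeled data
#'
#' Continues training the encoder/decoder (no head) on unlabeled in-vivo
#' heatmaps under the same schedule, minimizing binary cross-entropy only.
#' Any labels present on the input are ignored with a notice — they must not
#' influence this phase. Heatmaps must be normalized with the phase-1 map.
#'
#' @param net a head-less `dn_network` initialized by [transfer_weights()].
#' @param unlabeled a normalized `vg_dataset` (labels ignored) or list of
#'   normalized heatmaps.
#' @param t a [training_config()].
#' @return list with `weights` (a `trained_weights`, phase 2) and `history`
#'   (reconstruction loss only).
#' @export
train_phase2 <- function(net, unlabeled, t = training_config()) {
  stopifnot(inherits(net, "dn_network"))
  if (net$with_head) stop("train_phase2: build the phase-2 network without a head")
  if (!inherits(unlabeled, "vg_dataset")) unlabeled <- as_dataset(unlabeled)
  if (!unlabeled$normalized)
    stop("train_phase2: heatmaps must be normalized with the phase-1 map")
  if (!all(is.na(unlabeled$labels)) && any(!unlabeled$latent))
    message("train_phase2: input carries labels; they are ignored ",
            "(reconstruction-only phase)")
  X <- to_heatmap_array(unlabeled)
  empty_y <- matrix(numeric(0), 0, 3)
  if (t$max_epochs == 0) {
    res <- list(weights = net$weights,
                history = list(lr = numeric(0), train_total = numeric(0),
                               train_reg = numeric(0), train_rec = numeric(0),
                               val_total = numeric(0), val_reg = numeric(0),
                               val_rec = numeric(0)))
  } else {
    idx <- split_val(dim(X)[3], t$val_fraction, t$seed)
    res <- dn_train_cpp(net$weights, unclass(net$arch),
                        X[, , idx$train, drop = FALSE], empty_y,
                        X[, , idx$val, drop = FALSE], empty_y,
                        cfg_list(t, FALSE, TRUE, seed_offset = 1L))
  }
  tw <- structure(list(phase = 2L, weights = res$weights, arch = net$arch,
                       norm_map = net$norm_map, label_scale = net$label_scale,
                       label_center = net$label_center),
                  class = "trained_weights")
  h <- history_df(res$history, 2)
  h$train_reg <- NULL; h$val_reg <- NULL
  list(weights = tw, history = h)
}

#' Phase 3: assemble the in-vivo predictor
#'
#' Encoder blocks (including batch-norm statistics) take their phase-2
#' values — they have seen both labeled in-vitro and unlabeled in-vivo data
#' — while the regression head keeps its phase-1 values (the only phase in
#' which a head was trained). The phase-1 normalization map and label
#' scaling are bundled so prediction is self-contained.
#'
#' @param phase1 `trained_weights` from [train_phase1()].
#' @param phase2 `trained_weights` from [train_phase2()].
#' @return a `dn_predictor`.
#' @export
build_predictor <- function(phase1, phase2) {
  stopifnot(inherits(phase1, "trained_weights"),
            inherits(phase2, "trained_weights"))
  if (phase1$phase != 1L || phase2$phase != 2L)
    stop("build_predictor: expects phase-1 and phase-2 weights, in order")
  if (!arch_identical(phase1$arch, phase2$arch))
    stop("build_predictor: architecture mismatch between phases")
  w <- list()
  for (nm in names(phase1$weights)) {
    w[[nm]] <- if (startsWith(nm, "enc") && nm %in% names(phase2$weights))
      phase2$weights[[nm]] else phase1$weights[[nm]]
  }
  w <- w[!startsWith(names(w), "dec") & !startsWith(names(w), "out_")]
  structure(list(phase = 3L, weights = w, arch = phase1$arch,
                 norm_map = phase1$norm_map,
                 label_scale = phase1$label_scale,
                 label_center = phase1$label_center),
            class = "dn_predictor")
}

#' Predict tonic concentrations from heatmaps
#'
#' Applies the predictor's stored normalization (raw heatmaps are normalized
#' with the phase-1 map; already-normalized input is used as is), runs the
#' encoder + head deterministically (dropout inactive, batch-norm running
#' statistics), inverts the label scaling, and clamps negative outputs to
#' 0 nM (concentrations are physical).
#'
#' @param predictor a `dn_predictor` from [build_predictor()] (or phase-1
#'   `trained_weights`, for within-domain use).
#' @param heatmaps a `vg_dataset` or list of `vg_heatmap`s.
#' @return matrix `n x 3` of concentrations (nM), columns (da, ne, ht5).
#' @export
predict_discrimnet <- function(predictor, heatmaps) {
  if (inherits(predictor, "trained_weights") && predictor$phase == 1L) {
    predictor <- structure(list(phase = 3L, weights = predictor$weights,
                                arch = predictor$arch,
                                norm_map = predictor$norm_map,
                                label_scale = predictor$label_scale,
                                label_center = predictor$label_center),
                           class = "dn_predictor")
  }
  stopifnot(inherits(predictor, "dn_predictor"))
  if (!inherits(heatmaps, "vg_dataset")) heatmaps <- as_dataset(heatmaps)
  if (!all(dim(heatmaps$heatmaps[[1]]$grid) == predictor$arch$input_shape))
    stop("predict_discrimnet: heatmap shape ",
         paste(dim(heatmaps$heatmaps[[1]]$grid), collapse = "x"),
         " does not match network input ",
         paste(predictor$arch$input_shape, collapse = "x"))
  if (!heatmaps$normalized) {
    if (is.null(predictor$norm_map))
      stop("predict_discrimnet: raw input but no stored normalization map")
    heatmaps <- normalize_dataset(heatmaps, predictor$norm_map)
  }
  X <- to_heatmap_array(heatmaps)
  out <- dn_forward_cpp(predictor$weights, unclass(predictor$arch), X,
                        use_head = TRUE, use_decoder = FALSE)
  center <- predictor$label_center %||% c(0, 0, 0)
  pred <- pmax(sweep(out$pred * predictor$label_scale, 2, center, FUN = "+"), 0)
  colnames(pred) <- c("da", "ne", "ht5")
  pred
}

#' Reconstruct heatmaps through the autoencoder
#'
#' Runs encoder + decoder in inference mode; used for inspecting what the
#' reconstruction branch has learned.
#'
#' @param tw `trained_weights` (phase 1 or 2) or a `dn_network`.
#' @param heatmaps normalized `vg_dataset` or heatmap list.
#' @return array rows x cols x n of reconstructed pixel values in \[0, 1\].
#' @export
reconstruct_heatmaps <- function(tw, heatmaps) {
  if (!inherits(heatmaps, "vg_dataset")) heatmaps <- as_dataset(heatmaps)
  if (!heatmaps$normalized) stop("reconstruct_heatmaps: normalized input required")
  X <- to_heatmap_array(heatmaps)
  arch <- if (inherits(tw, "dn_network")) tw$arch else tw$arch
  dn_forward_cpp(tw$weights, unclass(arch), X,
                 use_head = FALSE, use_decoder = TRUE)$recon
}
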