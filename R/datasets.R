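#' Assemble heatmaps into a dataset
#'
#' A dataset is an ordered collection of (heatmap, label, electrode id)
#' records sharing one grid shape and one normalization state. Labels always
#' carry all three analytes (zeros for absent ones); latent labels (emulated
#' in-vivo truth) are retained but flagged.
#'
#' @param heatmaps list of `vg_heatmap`s.
#' @param split_tag optional `"train"` or `"test"`.
#' @return a `vg_dataset`.
#' @export
as_dataset <- function(heatmaps, split_tag = NULL) {
  if (length(heatmaps) == 0) stop("as_dataset: no records")
  shp <- dim(heatmaps[[1]]$grid)
  norm <- heatmaps[[1]]$normalized
  for (h in heatmaps) {
    if (!identical(dim(h$grid), shp))
      stop("as_dataset: heatmaps have mixed grid shapes")
    if (!identical(h$normalized, norm))
      stop("as_dataset: heatmaps have mixed normalization state")
  }
  labels <- t(vapply(heatmaps, function(h) {
    if (is.null(h$label)) c(da = NA_real_, ne = NA_real_, ht5 = NA_real_)
    else unclass(h$label)
  }, numeric(3)))
  if (any(labels < 0, na.rm = TRUE)) stop("as_dataset: negative label")
  structure(list(
    heatmaps = heatmaps,
    labels = labels,
    electrode_ids = vapply(heatmaps, function(h) h$electrode_id, character(1)),
    latent = vapply(heatmaps, function(h) isTRUE(h$latent), logical(1)),
    shape = shp, normalized = norm, split_tag = split_tag,
    norm_map = attr(heatmaps, "norm_map")),
    class = "vg_dataset")
}

#' @export
length.vg_dataset <- function(x) length(x$heatmaps)

#' @exportS3Method base::print
print.vg_dataset <- function(x, ...) {
  cat("<vg_dataset> ", length(x), " records, grid ", x$shape[1], "x",
      x$shape[2], ", ", length(unique(x$electrode_ids)), " electrode(s), ",
      if (x$normalized) "normalized" else "raw",
      if (!is.null(x$split_tag)) paste0(", split=", x$split_tag) else "",
      "\n", sep = "")
  invisible(x)
}

dataset_subset <- function(d, idx, split_tag = NULL) {
  out <- d
  out$heatmaps <- d$heatmaps[idx]
  out$labels <- d$labels[idx, , drop = FALSE]
  out$electrode_ids <- d$electrode_ids[idx]
  out$latent <- d$latent[idx]
  out$split_tag <- split_tag
  out
}

#' Normalize every heatmap in a dataset with one map
#' @param d a `vg_dataset`.
#' @param m a `norm_map`; the map is stored on the dataset for downstream
#'   model training.
#' @return the normalized dataset.
#' @export
normalize_dataset <- function(d, m) {
  d$heatmaps <- lapply(d$heatmaps, normalize_heatmap, m = m)
  d$normalized <- TRUE
  d$norm_map <- m
  d
}

#' Train/test split specification
#'
#' `"within"` mode shuffles records by seed and sends the first
#' `floor(train_fraction * N)` to training — test records share electrodes
#' with training. `"across"` mode holds out whole electrodes: every record
#' from `held_out_electrodes` seed-chosen electrodes goes to test, so test
#' electrodes are entirely unseen during training.
#'
#' @param mode `"within"` or `"across"`.
#' @param train_fraction training proportion (within mode), default 0.8.
#' @param held_out_electrodes number of electrodes held out (across mode).
#' @param seed integer seed.
#' @return a `split_spec`.
#' @export
split_spec <- function(mode = c("within", "across"), train_fraction = 0.8,
                       held_out_electrodes = 1, seed = 1) {
  mode <- match.arg(mode)
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("split_spec: train_fraction must be in (0, 1)")
  structure(list(mode = mode, train_fraction = train_fraction,
                 held_out_electrodes = as.integer(held_out_electrodes),
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Split a dataset into train and test sets
#'
#' @param d a `vg_dataset`.
#' @param s a [split_spec()].
#' @return list with elements `train` and `test` (both `vg_dataset`s); the
#'   two partition the input records exactly.
#' @export
split_dataset <- function(d, s) {
  stopifnot(inherits(d, "vg_dataset"), inherits(s, "split_spec"))
  n <- length(d)
  if (n == 0) stop("split_dataset: empty dataset")
  if (s$mode == "within") {
    ord <- with_local_seed(s$seed, sample.int(n))
    n_train <- floor(s$train_fraction * n)
    train_idx <- ord[seq_len(n_train)]
    test_idx <- ord[-seq_len(n_train)]
  } else {
    ids <- unique(d$electrode_ids)
    if (length(ids) < s$held_out_electrodes + 1L)
      stop("split_dataset: across mode needs at least ",
           s$held_out_electrodes + 1L, " distinct electrodes, got ",
           length(ids))
    held <- with_local_seed(s$seed,
                            sample(ids, s$held_out_electrodes))
    test_idx <- which(d$electrode_ids %in% held)
    train_idx <- which(!(d$electrode_ids %in% held))
  }
  list(train = dataset_subset(d, train_idx, "train"),
       test = dataset_subset(d, test_idx, "test"))
}

#' Flatten a dataset into feature and label matrices
#'
#' @param d a `vg_dataset` with uniform grid shape.
#' @return list with `X` (records x pixels; row i is the row-major flattening
#'   of heatmap i) and `Y` (records x 3, column order fixed (da, ne, ht5)).
#' @export
to_feature_matrix <- function(d) {
  stopifnot(inherits(d, "vg_dataset"))
  p <- prod(d$shape)
  X <- t(vapply(d$heatmaps, flatten_heatmap, numeric(p)))
  Y <- d$labels
  colnames(Y) <- c("da", "ne", "ht5")
  list(X = X, Y = Y)
}

#' Stack a dataset's heatmaps into a 3D array
#' @param d a `vg_dataset`.
#' @return array rows x cols x records (the layout consumed by the network).
#' @export
to_heatmap_array <- function(d) {
  arr <- array(0, dim = c(d$shape[1], d$shape[2], length(d)))
  for (i in seq_along(d$heatmaps)) arr[, , i] <- d$heatmaps[[i]]$grid
  arr
}

#' Write a split manifest as CSV
#' @param splits list with `train`/`test` datasets (from [split_dataset()]).
#' @param path output CSV path.
#' @return the manifest data frame, invisibly.
#' @export
write_split_manifest <- function(splits, path) {
  man <- rbind(
    data.frame(record = seq_along(splits$train$heatmaps),
               electrode_id = splits$train$electrode_ids, split_tag = "train"),
    data.frame(record = seq_along(splits$test$heatmaps),
               electrode_id = splits$test$electrode_ids, split_tag = "test"))
  utils::write.csv(man, path, row.names = FALSE)
  invisible(man)
}
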