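CONTAINER_SCHEMA <- "tonicnet-container-1"

#' Write a dataset container
#'
#' Persists a dataset as a single versioned, R-native serialized container
#' holding the heatmap stack (`n x rows x cols`), the `n x 3` label matrix
#' (NaN where a record is unlabeled/latent), electrode ids, and metadata
#' (waveform spec, normalization map, seeds, schema version).
#'
#' @param d a `vg_dataset`.
#' @param path output file path.
#' @param waveform optional [waveform_spec()] stored in `meta`.
#' @param seeds optional named seed record stored in `meta`.
#' @return `path`, invisibly.
#' @export
write_container <- function(d, path, waveform = NULL, seeds = NULL) {
  stopifnot(inherits(d, "vg_dataset"))
  n <- length(d)
  hm <- array(0, dim = c(n, d$shape[1], d$shape[2]))
  for (i in seq_len(n)) hm[i, , ] <- d$heatmaps[[i]]$grid
  obj <- list(schema_version = CONTAINER_SCHEMA,
              heatmaps = hm,
              labels = d$labels,
              latent = d$latent,
              electrode_ids = d$electrode_ids,
              t = vapply(d$heatmaps, function(h) h$t %||% 0, numeric(1)),
              meta = list(waveform = waveform, normalized = d$normalized,
                          norm_map = d$norm_map, seeds = seeds,
                          split_tag = d$split_tag))
  saveRDS(obj, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a dataset container
#'
#' @param path a container written by [write_container()].
#' @return a `vg_dataset`; records whose label row is all-NaN are flagged
#'   unlabeled.
#' @export
read_container <- function(path) {
  if (!file.exists(path)) stop("read_container: no such file: ", path)
  obj <- readRDS(path)
  if (!identical(obj$schema_version, CONTAINER_SCHEMA))
    stop("read_container: unsupported schema version '",
         obj$schema_version %||% "<missing>", "' (supported: ",
         CONTAINER_SCHEMA, ")")
  n <- dim(obj$heatmaps)[1]
  for (field in c("labels", "electrode_ids")) {
    len <- if (field == "labels") nrow(obj$labels) else length(obj[[field]])
    if (len != n)
      stop("read_container: length mismatch: heatmaps has ", n,
           " records but ", field, " has ", len)
  }
  hms <- lapply(seq_len(n), function(i) {
    lab <- obj$labels[i, ]
    structure(list(grid = obj$heatmaps[i, , ],
                   electrode_id = obj$electrode_ids[i],
                   label = if (all(is.na(lab))) NULL
                           else conc_triple(lab[1], lab[2], lab[3]),
                   latent = isTRUE(obj$latent[i]),
                   t = obj$t[i],
                   normalized = isTRUE(obj$meta$normalized)),
              class = "vg_heatmap")
  })
  d <- as_dataset(hms, split_tag = obj$meta$split_tag)
  d$norm_map <- obj$meta$norm_map
  d
}

#' Save / load trained models with their preprocessing state
#'
#' Models are serialized together with whatever normalization map and label
#' scaling they carry, so later predictions reproduce training-time
#' preprocessing bit-exactly.
#'
#' @param model a `shallow_model`, `trained_weights`, or `dn_predictor`.
#' @param path file path.
#' @return `path` ([save_model()]) or the model ([load_model()]).
#' @export
save_model <- function(model, path) {
  saveRDS(list(schema_version = CONTAINER_SCHEMA, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema_version, CONTAINER_SCHEMA))
    stop("load_model: unsupported schema version")
  obj$model
}

#' Write a machine-readable evaluation report
#'
#' Serializes an evaluation report (data frame or list) as JSON keyed by the
#' run's config hash and seed.
#'
#' @param report data frame or list.
#' @param path output JSON path.
#' @param meta optional named list (seeds, config hash) stored alongside.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path, meta = list()) {
  jsonlite::write_json(list(meta = meta, report = report), path,
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
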