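# Desk-scale study protocols: end-to-end seeded runs of the simulation ->
# preprocessing -> split -> fit -> evaluate pipeline, used by the examples,
# the evaluation reports, and the reproduction script. Problem sizes (a few
# in-vitro electrodes x 25 solutions x a few scans, 64 x 32 heatmaps) are
# chosen so a full run completes in minutes on one CPU core; every count
# scales by argument.

#' Simulate and preprocess a labeled in-vitro study dataset
#'
#' @param seed integer seed.
#' @param n_electrodes in-vitro electrode count.
#' @param scans_per_solution scans per (electrode, solution).
#' @param spec waveform geometry.
#' @param solutions calibration solutions (default [training_solutions()]).
#' @return an unnormalized labeled `vg_dataset` of background-subtracted
#'   heatmaps.
#' @export
prepare_invitro_dataset <- function(seed = 1, n_electrodes = 6,
                                    scans_per_solution = 3,
                                    spec = waveform_spec(),
                                    solutions = training_solutions()) {
  electrodes <- sample_electrodes(n_electrodes, "in_vitro", seed = seed)
  scans <- simulate_invitro_dataset(electrodes, solutions, spec,
                                    scans_per_solution, seed = seed)
  as_dataset(preprocess_scans(scans))
}

#' RMSE of the predict-the-training-mean baseline
#' @param train_labels training label matrix (n x 3).
#' @param truth test label matrix (m x 3).
#' @return per-analyte RMSE of predicting the constant training mean.
#' @export
baseline_mean_rmse <- function(train_labels, truth) {
  mu <- colMeans(train_labels)
  pred <- matrix(mu, nrow = nrow(truth), ncol = 3, byrow = TRUE)
  rmse_per_analyte(pred, truth)
}

fit_protocol_models <- function(train, families, seed, training, arch_seed) {
  models <- list()
  histories <- list()
  for (fam in setdiff(families, "discrimnet"))
    models[[fam]] <- fit_shallow(train, fam, seed = seed)
  if ("discrimnet" %in% families) {
    arch <- arch_config(input_shape = train$shape)
    net <- build_autoencoder(arch, with_head = TRUE, seed = arch_seed)
    ph1 <- train_phase1(net, train, training)
    models[["discrimnet"]] <- ph1$weights
    histories[["discrimnet_phase1"]] <- ph1$history
  }
  list(models = models, histories = histories)
}

#' Within- or across-electrode evaluation protocol
#'
#' Simulates a labeled in-vitro dataset, splits it (within-electrode 80/20
#' shuffle or across-electrode hold-out), fits the training-split
#' normalization map, fits the requested model families, and reports
#' per-analyte test RMSE alongside the predict-the-training-mean baseline.
#'
#' @param seed integer seed driving every stage.
#' @param mode `"within"` or `"across"`.
#' @param families model families; any of `"svr"`, `"pcr"`, `"plsr"`,
#'   `"lasso"`, `"ridge"`, `"enet"`, `"discrimnet"`.
#' @param n_electrodes,scans_per_solution dataset plan.
#' @param held_out_electrodes electrodes held out in across mode.
#' @param training a [training_config()] for the autoencoder (its seed is
#'   re-derived from `seed`).
#' @param spec waveform geometry.
#' @return list: `report` (model, analyte, rmse, n), `baseline` (per-analyte
#'   mean-prediction RMSE), `models`, `norm_map`, `splits`, `spec`.
#' @export
run_protocol <- function(seed = 1, mode = c("within", "across"),
                         families = c("svr", "pcr", "plsr", "lasso",
                                      "ridge", "enet", "discrimnet"),
                         n_electrodes = 6, scans_per_solution = 3,
                         held_out_electrodes = 2,
                         training = training_config(),
                         spec = waveform_spec()) {
  mode <- match.arg(mode)
  d <- prepare_invitro_dataset(derive_seed(seed, "data"), n_electrodes,
                               scans_per_solution, spec)
  sp <- split_dataset(d, split_spec(mode,
                                    held_out_electrodes = held_out_electrodes,
                                    seed = derive_seed(seed, "split")))
  m <- fit_normalization(sp$train$heatmaps)
  train <- normalize_dataset(sp$train, m)
  test <- normalize_dataset(sp$test, m)
  training$seed <- derive_seed(seed, "nn")
  fitted <- fit_protocol_models(train, families, derive_seed(seed, "fit"),
                                training, derive_seed(seed, "arch"))
  Xte <- to_feature_matrix(test)
  report <- do.call(rbind, lapply(names(fitted$models), function(nm) {
    pred <- predict_any(fitted$models[[nm]], test)
    r <- rmse_per_analyte(pred, Xte$Y)
    data.frame(model = nm, analyte = names(r), rmse = unname(r),
               n = nrow(pred), mode = mode)
  }))
  list(report = report,
       baseline = baseline_mean_rmse(train$labels, Xte$Y),
       models = fitted$models, histories = fitted$histories,
       norm_map = m, splits = sp, spec = spec, seed = seed)
}

#' Simulate the unlabeled in-vivo corpus
#'
#' Pre-manipulation baseline recordings from distinct in-vivo electrodes:
#' for each electrode a drug-free session at the scenario baseline
#' concentrations. Labels are latent (evaluation only).
#'
#' @param seed integer seed.
#' @param n_electrodes distinct in-vivo electrodes (sessions).
#' @param minutes_per_session baseline recording length per session (min).
#' @param spec waveform geometry.
#' @return unnormalized `vg_dataset` of latent-labeled in-vivo heatmaps.
#' @export
prepare_invivo_corpus <- function(seed = 1, n_electrodes = 4,
                                  minutes_per_session = 10,
                                  spec = waveform_spec()) {
  electrodes <- sample_electrodes(n_electrodes, "in_vivo", seed = seed)
  scans <- list()
  for (i in seq_along(electrodes)) {
    sc <- pharm_scenario("none", session_length = minutes_per_session)
    scans <- c(scans, simulate_session(sc, electrodes[[i]], spec,
                                       seed = derive_seed(seed, paste0("vivo", i))))
  }
  as_dataset(preprocess_scans(scans))
}

#' Full three-phase semi-supervised protocol
#'
#' Phase 1 trains the autoencoder (head + decoder) on the labeled in-vitro
#' dataset; phase 2 adapts the transferred encoder/decoder to the unlabeled
#' in-vivo corpus by reconstruction only; phase 3 assembles the in-vivo
#' predictor (phase-2 encoder, phase-1 head). The predictor is then scored
#' on a held-out in-vivo drug session (latent labels) against the
#' predict-the-training-mean baseline.
#'
#' @param seed integer seed.
#' @param n_electrodes in-vitro electrode count for phase 1.
#' @param scans_per_solution in-vitro scans per solution.
#' @param vivo_electrodes unlabeled in-vivo sessions for phase 2.
#' @param eval_sessions number of held-out in-vivo drug sessions (distinct
#'   electrodes) pooled for the evaluation.
#' @param training a [training_config()] for phase 1.
#' @param adapt_initial_lr initial learning rate for the phase-2
#'   adaptation; resuming at a reduced rate keeps the encoder close to the
#'   solution the frozen phase-1 head was calibrated against while still
#'   absorbing the in-vivo image statistics.
#' @param spec waveform geometry.
#' @param eval_scenario drug scenario for the held-out evaluation session.
#' @return list: `predictor`, `phase1`, `phase2`, `norm_map`, `rmse`
#'   (per-analyte on the held-out in-vivo session), `baseline`
#'   (mean-prediction RMSE there), `spec`.
#' @export
run_three_phase_protocol <- function(seed = 1, n_electrodes = 6,
                                     scans_per_solution = 3,
                                     vivo_electrodes = 4, eval_sessions = 3,
                                     training = training_config(),
                                     adapt_initial_lr = 1e-3,
                                     spec = waveform_spec(),
                                     eval_scenario = pharm_scenario("cocaine")) {
  d <- prepare_invitro_dataset(derive_seed(seed, "data"), n_electrodes,
                               scans_per_solution, spec)
  m <- fit_normalization(d$heatmaps)
  train <- normalize_dataset(d, m)
  training$seed <- derive_seed(seed, "nn")
  arch <- arch_config(input_shape = train$shape)
  ph1 <- train_phase1(build_autoencoder(arch, TRUE,
                                        seed = derive_seed(seed, "arch")),
                      train, training)
  vivo <- prepare_invivo_corpus(derive_seed(seed, "vivo"), vivo_electrodes,
                                spec = spec)
  vivo_n <- normalize_dataset(vivo, m)
  net2 <- transfer_weights(ph1$weights,
                           build_autoencoder(arch, FALSE,
                                             seed = derive_seed(seed, "arch2")))
  adapt <- training
  adapt$initial_lr <- adapt_initial_lr
  ph2 <- train_phase2(net2, vivo_n, adapt)
  predictor <- build_predictor(ph1$weights, ph2$weights)

  hold <- list()
  for (k in seq_len(eval_sessions)) {
    el <- sample_electrodes(1, "in_vivo",
                            seed = derive_seed(seed, paste0("holdout", k)))[[1]]
    hold <- c(hold,
              preprocess_scans(simulate_session(
                eval_scenario, el, spec,
                seed = derive_seed(seed, paste0("holdrun", k)))))
  }
  hd <- as_dataset(hold)
  pred <- predict_discrimnet(predictor, hd)
  list(predictor = predictor, phase1 = ph1, phase2 = ph2, norm_map = m,
       rmse = rmse_per_analyte(pred, hd$labels),
       baseline = baseline_mean_rmse(train$labels, hd$labels),
       holdout = hd, spec = spec)
}
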