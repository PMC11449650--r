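#' Per-analyte root mean square error
#'
#' @param pred,truth matrices `n x 3` (columns da, ne, ht5) with equal row
#'   counts, in nM.
#' @return named numeric vector of RMSEs (nM) per analyte.
#' @export
rmse_per_analyte <- function(pred, truth) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (nrow(pred) == 0) stop("rmse_per_analyte: empty input")
  if (nrow(pred) != nrow(truth) || ncol(pred) != 3 || ncol(truth) != 3)
    stop("rmse_per_analyte: pred and truth must both be n x 3")
  out <- sqrt(colMeans((pred - truth)^2))
  names(out) <- c("da", "ne", "ht5")
  out
}

#' Compare model error distributions
#'
#' Fixed-effects ANOVA on absolute errors: one-way across models (`groups`
#' is a named list of error vectors) or two-way model x analyte (`groups` is
#' a data frame with columns `error`, `model`, `analyte`). Optionally adds
#' Brown-Forsythe/Levene's test (absolute deviations from the group median)
#' for variance homogeneity. Both tests are computed from their standard
#' sums-of-squares definitions via [stats::aov()].
#'
#' @param groups named list of numeric vectors (one-way) or a data frame
#'   (two-way); at least 2 groups of at least 2 values.
#' @param design `"one_way"` or `"two_way"`.
#' @param variance_test add Levene's test (one-way designs).
#' @return list with `anova` (data frame of F and p per term) and optionally
#'   `levene` (statistic and p).
#' @export
compare_errors <- function(groups, design = c("one_way", "two_way"),
                           variance_test = FALSE) {
  design <- match.arg(design)
  if (design == "one_way") {
    if (!is.list(groups) || length(groups) < 2)
      stop("compare_errors: need >= 2 groups")
    sizes <- lengths(groups)
    if (any(sizes < 2)) stop("compare_errors: every group needs >= 2 values")
    df <- data.frame(error = abs(unlist(groups, use.names = FALSE)),
                     group = factor(rep(names(groups), sizes)))
    fit <- stats::aov(error ~ group, data = df)
    tab <- summary(fit)[[1]]
    out <- list(anova = data.frame(term = "group",
                                   F = tab[["F value"]][1],
                                   p = tab[["Pr(>F)"]][1]))
    if (variance_test) {
      med <- tapply(df$error, df$group, stats::median)
      df$adev <- abs(df$error - med[as.character(df$group)])
      lv <- summary(stats::aov(adev ~ group, data = df))[[1]]
      out$levene <- list(statistic = lv[["F value"]][1], p = lv[["Pr(>F)"]][1])
    }
    out
  } else {
    df <- as.data.frame(groups)
    if (!all(c("error", "model", "analyte") %in% names(df)))
      stop("compare_errors: two-way design needs columns error, model, analyte")
    df$error <- abs(df$error)
    df$model <- factor(df$model); df$analyte <- factor(df$analyte)
    if (nlevels(df$model) < 2) stop("compare_errors: need >= 2 models")
    fit <- stats::aov(error ~ model * analyte, data = df)
    tab <- summary(fit)[[1]]
    terms <- trimws(rownames(tab))
    keep <- terms != "Residuals"
    list(anova = data.frame(term = terms[keep], F = tab[["F value"]][keep],
                            p = tab[["Pr(>F)"]][keep]))
  }
}

#' The eight three-analyte validation mixtures
#'
#' The standard three-monoamine validation solution set: mixtures never seen
#' in training (training solutions contain at most two monoamines).
#'
#' @return matrix 8 x 3 (columns da, ne, ht5), nM.
#' @export
validation_mixtures <- function() {
  m <- rbind(c(100, 250, 500), c(300, 250, 500), c(100, 500, 250),
             c(300, 500, 250), c(500, 100, 250), c(500, 300, 250),
             c(500, 250, 100), c(500, 250, 300))
  colnames(m) <- c("da", "ne", "ht5")
  m
}

# Simulate scans of given solutions on fresh electrodes and preprocess them
# with the pipeline's stored normalization map.
simulate_condition_heatmaps <- function(solutions, spec, norm_map, seed,
                                        n_electrodes = 3, scans = 20,
                                        domain = "in_vitro") {
  electrodes <- sample_electrodes(n_electrodes, domain,
                                  seed = derive_seed(seed, "val_electrodes"))
  out <- list()
  for (ei in seq_along(electrodes)) {
    for (si in seq_along(solutions)) {
      for (r in seq_len(scans)) {
        v <- simulate_voltammogram(
          solutions[[si]], electrodes[[ei]], spec,
          seed = derive_seed(seed, sprintf("val:%d:%d:%d", ei, si, r)))
        out[[length(out) + 1L]] <- c(list(v), ei, si)
      }
    }
  }
  hm <- preprocess_scans(lapply(out, `[[`, 1))
  hm <- lapply(hm, normalize_heatmap, m = norm_map)
  list(heatmaps = hm,
       electrode = vapply(out, function(x) x[[2]], numeric(1)),
       solution = vapply(out, function(x) x[[3]], numeric(1)))
}

predict_any <- function(model, d) {
  if (inherits(model, "dn_predictor") || inherits(model, "trained_weights"))
    predict_discrimnet(model, d)
  else predict_shallow(model, to_feature_matrix(d)$X)
}

#' Three-analyte mixture validation
#'
#' Simulates `scans` voltammograms of each validation mixture on
#' `n_electrodes` fresh in-vitro electrodes, preprocesses with the stored
#' normalization map, and reports per-analyte RMSE for every model.
#'
#' @param models named list of trained models (`shallow_model`,
#'   `trained_weights`, or `dn_predictor`).
#' @param norm_map the training pipeline's `norm_map`.
#' @param spec the [waveform_spec()] used for training data.
#' @param mixtures matrix of mixtures (default [validation_mixtures()]).
#' @param n_electrodes,scans validation recording plan (default 3 fresh
#'   electrodes x 20 scans per mixture).
#' @param seed integer seed.
#' @return data frame: model, analyte, rmse (nM), n.
#' @export
mixture_validation <- function(models, norm_map, spec = waveform_spec(),
                               mixtures = validation_mixtures(),
                               n_electrodes = 3, scans = 20, seed = 1) {
  sols <- lapply(seq_len(nrow(mixtures)), function(i)
    solution_spec(conc_triple(mixtures[i, 1], mixtures[i, 2], mixtures[i, 3])))
  sim <- simulate_condition_heatmaps(sols, spec, norm_map, seed,
                                     n_electrodes, scans)
  d <- as_dataset(sim$heatmaps)
  truth <- d$labels
  out <- list()
  for (nm in names(models)) {
    pred <- predict_any(models[[nm]], d)
    r <- rmse_per_analyte(pred, truth)
    out[[nm]] <- data.frame(model = nm, analyte = names(r), rmse = unname(r),
                            n = nrow(pred))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "abs_errors") <- lapply(models, function(m)
    abs(predict_any(m, d) - truth))
  res
}

#' Interferent selectivity validation
#'
#' Experiment 1: 20 scans each of 500 nM DA alone and with each of the six
#' interferents (adenosine 1 uM, ascorbic acid 200 uM, HVA 20 uM, DOPAC
#' 20 uM, uric acid 100 uM, pH -0.2) — 7 conditions. Experiment 2: 20 scans
#' of each of four three-analyte mixtures, each with one interferent
#' (adenosine, pH, DOPAC, uric acid). Reports per-condition prediction RMSE
#' and a one-way ANOVA of absolute DA errors across experiment-1 conditions:
#' because the waveform excludes interferents from the Faradaic signal
#' (they only perturb the background slightly, which subtraction removes),
#' the ANOVA is expected to be non-significant.
#'
#' @param predictor a trained predictor (`dn_predictor` or phase-1 weights).
#' @param norm_map the training pipeline's `norm_map`.
#' @param spec the training [waveform_spec()].
#' @param seed integer seed.
#' @param n_electrodes,scans recording plan per condition.
#' @return list with `experiment1` / `experiment2` RMSE tables and `anova`
#'   (one-way across experiment-1 conditions).
#' @export
selectivity_validation <- function(predictor, norm_map,
                                   spec = waveform_spec(), seed = 1,
                                   n_electrodes = 3, scans = 20) {
  panel <- interferent_panel()
  da500 <- conc_triple(500, 0, 0)
  sols1 <- c(list(none = solution_spec(da500)),
             lapply(panel, function(args)
               do.call(solution_spec, c(list(conc = da500), args))))
  sim1 <- simulate_condition_heatmaps(sols1, spec, norm_map,
                                      derive_seed(seed, "sel1"),
                                      n_electrodes, scans)
  d1 <- as_dataset(sim1$heatmaps)
  pred1 <- predict_any(predictor, d1)
  err_da <- pred1[, "da"] - d1$labels[, 1]
  cond1 <- names(sols1)[sim1$solution]
  exp1 <- data.frame(
    condition = names(sols1),
    rmse_da = vapply(names(sols1), function(cn)
      sqrt(mean(err_da[cond1 == cn]^2)), numeric(1)),
    n = as.vector(table(cond1)[names(sols1)]))
  groups <- split(abs(err_da), cond1)
  an <- compare_errors(groups, "one_way")

  mix <- validation_mixtures()[1:4, , drop = FALSE]
  inter2 <- panel[c("adenosine", "delta_ph", "dopac", "uric_acid")]
  sols2 <- lapply(seq_len(4), function(i)
    do.call(solution_spec,
            c(list(conc = conc_triple(mix[i, 1], mix[i, 2], mix[i, 3])),
              inter2[[i]])))
  names(sols2) <- paste0("mix", seq_len(4), "_", names(inter2))
  sim2 <- simulate_condition_heatmaps(sols2, spec, norm_map,
                                      derive_seed(seed, "sel2"),
                                      n_electrodes, scans)
  d2 <- as_dataset(sim2$heatmaps)
  pred2 <- predict_any(predictor, d2)
  exp2 <- do.call(rbind, lapply(seq_len(4), function(i) {
    idx <- sim2$solution == i
    r <- rmse_per_analyte(pred2[idx, , drop = FALSE],
                          d2$labels[idx, , drop = FALSE])
    data.frame(condition = names(sols2)[i], analyte = names(r),
               rmse = unname(r), n = sum(idx))
  }))
  rownames(exp2) <- NULL
  list(experiment1 = exp1, experiment2 = exp2, anova = an$anova)
}

#' Simulated pharmacology scenario validation
#'
#' Simulates one in-vivo session per scenario on a fresh in-vivo electrode,
#' predicts every scan, and compares window means: pre-administration
#' minutes `[5, t_admin)` vs post-administration `[t_admin + 10,
#' t_admin + 30]`. A drug scenario passes when (i) DA rises, (ii) 5-HT
#' rises, (iii) the DA rise exceeds the 5-HT rise, and (iv) the NE change
#' stays below twice the pre-administration per-scan prediction standard
#' deviation (the noise-floor "no change" criterion).
#'
#' @param predictor a trained `dn_predictor`.
#' @param norm_map the training pipeline's `norm_map`.
#' @param scenarios list of [pharm_scenario()]s; defaults to cocaine and
#'   oxycodone administered at t = 27 min.
#' @param spec the training [waveform_spec()].
#' @param seed integer seed.
#' @return data frame per scenario: pre/post window means per analyte, the
#'   admin time used, and the four pass flags.
#' @export
scenario_validation <- function(predictor, norm_map,
                                scenarios = list(
                                  cocaine = pharm_scenario("cocaine"),
                                  oxycodone = pharm_scenario("oxycodone")),
                                spec = waveform_spec(), seed = 1) {
  out <- list()
  for (nm in names(scenarios)) {
    sc <- scenarios[[nm]]
    el <- sample_electrodes(1, "in_vivo",
                            seed = derive_seed(seed, paste0("scen:", nm)))[[1]]
    scans <- simulate_session(sc, el, spec,
                              seed = derive_seed(seed, paste0("scenrun:", nm)))
    hm <- preprocess_scans(scans)
    d <- as_dataset(hm)
    pred <- predict_any(predictor, normalize_dataset(d, norm_map))
    t_min <- vapply(scans, function(s) s$t, numeric(1)) / 60
    pre <- t_min >= 5 & t_min < sc$t_admin
    post <- t_min >= sc$t_admin + 10 & t_min <= sc$t_admin + 30
    pre_m <- colMeans(pred[pre, , drop = FALSE])
    post_m <- colMeans(pred[post, , drop = FALSE])
    ne_floor <- 2 * stats::sd(pred[pre, "ne"])
    d_da <- post_m["da"] - pre_m["da"]
    d_ht5 <- post_m["ht5"] - pre_m["ht5"]
    d_ne <- post_m["ne"] - pre_m["ne"]
    out[[nm]] <- data.frame(
      scenario = nm, drug = sc$drug, t_admin = sc$t_admin,
      pre_da = pre_m["da"], pre_ne = pre_m["ne"], pre_ht5 = pre_m["ht5"],
      post_da = post_m["da"], post_ne = post_m["ne"],
      post_ht5 = post_m["ht5"],
      da_surge = d_da > 0, ht5_surge = d_ht5 > 0,
      da_gt_ht5 = d_da > d_ht5,
      ne_flat = abs(d_ne) < ne_floor)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
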