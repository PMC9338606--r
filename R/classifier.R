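# Model training tuned for the clinical high-sensitivity regime: fivefold
# stratified cross-validation selects hyperparameters (and optionally
# features) by mean out-of-fold hsr-AUROC, the final model is refit on the
# full training set, and the 95%-sensitivity decision threshold is
# calibrated on pooled out-of-fold predictions so the test set stays
# untouched.

#' Default hyperparameter grid
#'
#' Small desk-scale grid; the published method does not disclose its chosen
#' settings, so these defaults are the package's own.
#' @export
default_grid <- function() {
  list(list(max_depth = 2L, eta = 0.1, n_trees = 150L, min_child_weight = 5),
       list(max_depth = 3L, eta = 0.1, n_trees = 150L, min_child_weight = 5))
}

#' Cross-validation plan
#'
#' @param n_folds Number of stratified folds (default 5).
#' @param seed Seed for fold assignment (all training randomness flows from
#'   here).
#' @param grid List of hyperparameter lists (see [gbt_default_params()]).
#' @param objective `"hsr_auroc"` (default, the clinical regime) or `"auroc"`.
#' @param target_sensitivity Sensitivity for threshold calibration and the
#'   hsr floor.
#' @param rebalance Optional benign:pathogenic subsampling ratio (e.g. 1 for
#'   balanced classes); `NULL` (default) keeps the natural imbalance.
#' @param select_features If `TRUE`, greedy backward elimination on the CV
#'   objective after the grid search (off by default).
#' @export
cv_plan <- function(n_folds = 5L, seed = 1L, grid = default_grid(),
                    objective = c("hsr_auroc", "auroc"),
                    target_sensitivity = 0.95, rebalance = NULL,
                    select_features = FALSE) {
  objective <- match.arg(objective)
  stopifnot(n_folds >= 2L, length(grid) >= 1L)
  structure(list(n_folds = n_folds, seed = seed, grid = grid,
                 objective = objective,
                 target_sensitivity = target_sensitivity,
                 rebalance = rebalance, select_features = select_features),
            class = "cv_plan")
}

make_folds <- function(y, n_folds, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  folds
}

objective_fun <- function(name, floor) {
  switch(name,
         hsr_auroc = function(s, y) hsr_auroc(s, y, floor),
         auroc = function(s, y) auroc(s, y))
}

cv_oof_scores <- function(X, y, folds, params) {
  oof <- rep(NA_real_, length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L)
      stop("degenerate single-class fold; use more data or fewer folds")
    fit <- gbt_fit(X[tr, , drop = FALSE], y[tr], params)
    oof[!tr] <- gbt_predict(fit, X[!tr, , drop = FALSE])
  }
  oof
}

#' Train the stopgain pathogenicity classifier
#'
#' @param features Feature `data.frame` from [featurize()] (or a numeric
#'   matrix with schema column names).
#' @param labels Character `{pathogenic, benign}` or 0/1 vector.
#' @param plan A [cv_plan()].
#' @return A `stopgain_model`: the fitted GBT, the feature schema and
#'   selected-feature mask, the calibrated threshold `theta` (score above
#'   which a variant is called pathogenic at the plan's target sensitivity),
#'   the sorted out-of-fold score vector used as the default percentile
#'   reference, per-configuration CV results, and training metadata.
#' @export
train_classifier <- function(features, labels, plan = cv_plan()) {
  X <- if (is.matrix(features)) features else features_to_matrix(features)
  if (is.null(colnames(X)) && ncol(X) > 0L)
    colnames(X) <- paste0("V", seq_len(ncol(X)))
  y <- if (is.numeric(labels)) as.numeric(labels)
       else as.numeric(labels == "pathogenic")
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (!is.null(plan$rebalance)) {
    keep_b <- with_seed(plan$seed + 1L, {
      nb <- round(sum(y == 1) * plan$rebalance)
      sample(which(y == 0), min(nb, sum(y == 0)))
    })
    keep <- sort(c(which(y == 1), keep_b))
    X <- X[keep, , drop = FALSE]; y <- y[keep]
  }
  folds <- make_folds(y, plan$n_folds, plan$seed)
  obj <- objective_fun(plan$objective, plan$target_sensitivity)
  cv <- lapply(seq_along(plan$grid), function(ci) {
    oof <- cv_oof_scores(X, y, folds, plan$grid[[ci]])
    per_fold <- vapply(sort(unique(folds)), function(f)
      obj(oof[folds == f], y[folds == f]), 0)
    list(config = ci, mean_objective = mean(per_fold),
         per_fold = per_fold, oof = oof)
  })
  means <- vapply(cv, `[[`, 0, "mean_objective")
  best <- which.max(means)  # ties: first config wins, deterministically
  params <- plan$grid[[best]]
  selected <- colnames(X)
  if (isTRUE(plan$select_features)) {
    current <- selected
    best_obj <- means[best]
    repeat {
      if (length(current) <= 2L) break
      trial <- vapply(current, function(drop_col) {
        Xs <- X[, setdiff(current, drop_col), drop = FALSE]
        oof <- cv_oof_scores(Xs, y, folds, params)
        mean(vapply(sort(unique(folds)), function(f)
          obj(oof[folds == f], y[folds == f]), 0))
      }, 0)
      if (max(trial) <= best_obj + 1e-9) break
      worst <- names(trial)[which.max(trial)]
      current <- setdiff(current, worst)
      best_obj <- max(trial)
    }
    selected <- current
  }
  Xs <- X[, selected, drop = FALSE]
  oof <- if (identical(selected, colnames(X))) cv[[best]]$oof
         else cv_oof_scores(Xs, y, folds, params)
  fit <- gbt_fit(Xs, y, params)
  theta <- calibrate_threshold(oof, y, plan$target_sensitivity)
  structure(list(
    gbt = fit,
    schema = colnames(X), schema_version = FEATURE_SCHEMA_VERSION,
    selected = selected,
    theta = theta, target_sensitivity = plan$target_sensitivity,
    percentile_reference = sort(oof),
    cv = data.frame(config = seq_along(means), mean_objective = means),
    metadata = list(seed = plan$seed, objective = plan$objective,
                    params = params, n = length(y), n_pathogenic = sum(y),
                    fingerprint = dataset_fingerprint(Xs, y))),
    class = "stopgain_model")
}

dataset_fingerprint <- function(X, y) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(list(dim(X), colnames(X), sum(y), round(sum(X, na.rm = TRUE), 6)),
          f, version = 2)
  unname(tools::md5sum(f))
}

#' @export
print.stopgain_model <- function(x, ...) {
  cat(sprintf(paste0("<stopgain_model: %d feature(s), %d tree(s), ",
                     "theta[%d%% sens] = %.4f>\n"),
              length(x$selected), length(x$gbt$trees),
              round(100 * x$target_sensitivity), x$theta))
  invisible(x)
}

#' Score variants with a trained model
#'
#' @param model A `stopgain_model`.
#' @param features Feature `data.frame` or matrix; columns must match the
#'   training schema exactly (a mismatch is fatal and lists the differing
#'   columns). Missing feature values are routed by the trees; an all-missing
#'   row still scores.
#' @return Pathogenicity scores in `[0, 1]`.
#' @export
score_variants <- function(model, features) {
  stopifnot(inherits(model, "stopgain_model"))
  X <- if (is.matrix(features)) features else features_to_matrix(features)
  miss <- setdiff(model$schema, colnames(X))
  extra <- setdiff(colnames(X), model$schema)
  if (length(miss) || length(extra))
    stop("feature schema mismatch; missing: [",
         paste(miss, collapse = ", "), "]; unexpected: [",
         paste(extra, collapse = ", "), "]")
  gbt_predict(model$gbt, X[, model$selected, drop = FALSE])
}

#' Calibrate the clinical decision threshold
#'
#' Returns the largest score threshold `theta` such that the fraction of
#' pathogenic calibration variants scoring `>= theta` is at least
#' `target_sensitivity` — i.e. the k-th largest pathogenic score with
#' `k = ceiling(target * n_pathogenic)`. Applying `theta` back to the
#' calibration scores achieves the target sensitivity by construction.
#'
#' @param scores Calibration scores (pooled out-of-fold training predictions
#'   in the shipped pipeline).
#' @param labels 0/1 or `{pathogenic, benign}` labels.
#' @param target_sensitivity Required sensitivity in (0, 1]; a target of 0
#'   returns the top threshold (everything may be called benign).
#' @export
calibrate_threshold <- function(scores, labels, target_sensitivity = 0.95) {
  y <- if (is.numeric(labels)) as.numeric(labels)
       else as.numeric(labels == "pathogenic")
  pos <- sort(scores[y == 1], decreasing = TRUE)
  if (!length(pos)) stop("at least one pathogenic example required")
  stopifnot(target_sensitivity >= 0, target_sensitivity <= 1)
  k <- ceiling(target_sensitivity * length(pos))
  if (k == 0L) return(max(scores))
  pos[k]
}

#' Percentile-normalise raw scores against a reference set
#'
#' `percentile = 100 * (#reference < raw + 0.5 * #reference == raw) / n`,
#' the mid-rank convention; monotone non-decreasing in the raw score and
#' invariant under any strictly increasing transform applied jointly to raw
#' and reference scores.
#'
#' @param raw_scores Scores to normalise.
#' @param reference_scores Non-empty reference distribution (classifier
#'   scores on a named reference set, typically the test split).
#' @export
percentile_normalize <- function(raw_scores, reference_scores) {
  stopifnot(length(reference_scores) > 0L)
  ref <- sort(reference_scores)
  below <- findInterval(raw_scores, ref, left.open = TRUE)  # ref < raw
  at_or_below <- findInterval(raw_scores, ref)              # ref <= raw
  100 * (below + 0.5 * (at_or_below - below)) / length(ref)
}

#' Ablation experiment
#'
#' Reruns the identical training pipeline with named feature columns
#' removed; used to reproduce the zygosity-ablation and benign-subsampling
#' experiment shapes on synthetic cohorts.
#'
#' @param features,labels,plan As in [train_classifier()].
#' @param drop Character vector of schema names to remove (may be empty).
#' @return List with the refit `model` and its CV `mean_objective`.
#' @export
ablate_features <- function(features, labels, plan, drop = character(0)) {
  X <- if (is.matrix(features)) features else features_to_matrix(features)
  bad <- setdiff(drop, colnames(X))
  if (length(bad)) stop("unknown feature(s): ", paste(bad, collapse = ", "))
  Xd <- X[, setdiff(colnames(X), drop), drop = FALSE]
  model <- train_classifier(Xd, labels, plan)
  list(model = model,
       mean_objective = max(model$cv$mean_objective))
}

#' Permutation importance of each feature
#'
#' Mean drop in a metric when one column is permuted (3 repeats, seeded).
#' @param model A `stopgain_model`.
#' @param features,labels Evaluation data.
#' @param metric Function `(scores, labels01) -> numeric` (default [auroc()]).
#' @param seed RNG seed; `n_rep` permutations are averaged.
#' @export
permutation_importance <- function(model, features, labels, metric = auroc,
                                   seed = 1L, n_rep = 3L) {
  X <- if (is.matrix(features)) features else features_to_matrix(features)
  y <- if (is.numeric(labels)) as.numeric(labels)
       else as.numeric(labels == "pathogenic")
  base <- metric(score_variants(model, X), y)
  drops <- with_seed(seed, {
    vapply(model$selected, function(col) {
      mean(vapply(seq_len(n_rep), function(r) {
        Xp <- X
        Xp[, col] <- sample(Xp[, col])
        base - metric(score_variants(model, Xp), y)
      }, 0))
    }, 0)
  })
  sort(drops, decreasing = TRUE)
}

#' Save / load a trained model
#'
#' The artifact is an RDS of the full model plus a JSON sidecar
#' (`<path>.json`) with the schema, threshold, seed and dataset fingerprint
#' so mismatched inputs are refused loudly at scoring time.
#' @param model A `stopgain_model`; `path` file path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path, version = 2)
  sidecar <- list(schema = model$schema, schema_version = model$schema_version,
                  selected = model$selected, theta = model$theta,
                  target_sensitivity = model$target_sensitivity,
                  metadata = model$metadata[c("seed", "objective", "n",
                                              "n_pathogenic", "fingerprint")])
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model artifact not found: ", path)
  model <- readRDS(path)
  stopifnot(inherits(model, "stopgain_model"))
  model
}
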