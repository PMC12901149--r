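#' Build a covariate feature table from metadata columns
#'
#' Lifts physicochemical metadata columns (pH, TTA, CFU, sugars, acids, DNA
#' concentration) into a `feature_table` with domain `"covariate"` so they
#' can enter designs next to omics layers.
#'
#' @param metadata A `sample_metadata`.
#' @param cols Columns to use; default every numeric column beyond the
#'   design columns (`sample_id`, `temperature`, `day`, `replicate`,
#'   `phase`).
#' @return A `feature_table`.
#' @export
covariate_table <- function(metadata, cols = NULL) {
  design_cols <- c("sample_id", "temperature", "day", "replicate", "phase")
  if (is.null(cols)) {
    cols <- setdiff(names(metadata)[vapply(metadata, is.numeric, logical(1))],
                    design_cols)
  }
  if (!length(cols)) stop("no covariate columns found")
  v <- t(as.matrix(metadata[, cols, drop = FALSE]))
  colnames(v) <- metadata$sample_id
  feature_table(v, "covariate", "raw")
}

#' Assemble a supervised design matrix from omics layers
#'
#' Column-binds the (transposed) feature tables over their shared samples,
#' tagging every column with its provenance (source domain) for importance
#' reporting, and derives the prediction target from metadata.
#'
#' @param tables List of `feature_table`s.
#' @param metadata A `sample_metadata`.
#' @param target `"day"`, `"temperature"`, or `"phase_temp"` (phase crossed
#'   with temperature, e.g. `"4.1"`).
#' @return List with `X` (samples x features matrix), `y` (factor),
#'   `provenance` (per-column domain) and `samples`.
#' @export
build_design <- function(tables, metadata,
                         target = c("phase_temp", "day", "temperature")) {
  target <- match.arg(target)
  if (inherits(tables, "feature_table")) tables <- list(tables)
  shared <- Reduce(intersect, lapply(tables, sample_ids))
  if (length(shared) < 2) stop("fewer than 2 shared samples across tables")
  dropped <- setdiff(Reduce(union, lapply(tables, sample_ids)), shared)
  if (length(dropped)) {
    message("dropping sample(s) absent from some table: ",
            paste(dropped, collapse = ", "))
  }
  blocks <- lapply(tables, function(t) t(ft_subset(t, samples = shared)$values))
  X <- do.call(cbind, blocks)
  if (anyDuplicated(colnames(X))) stop("duplicate feature ids across tables")
  provenance <- unlist(lapply(tables, function(t) t$domain))
  md <- align_metadata(metadata, shared)
  y <- switch(target,
    day = factor(md$day),
    temperature = factor(md$temperature),
    phase_temp = factor(sprintf("%g.%d", md$temperature, md$phase)))
  if (anyNA(y)) stop("label missing for sample(s): ",
                     paste(shared[is.na(y)], collapse = ", "))
  list(X = X, y = y, provenance = provenance, samples = shared)
}

stratified_folds <- function(y, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

macro_ovr_auc <- function(y_true, prob) {
  aucs <- vapply(colnames(prob), function(cl) {
    resp <- as.integer(y_true == cl)
    if (length(unique(resp)) < 2) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(resp, prob[, cl], quiet = TRUE,
                                   levels = c(0, 1), direction = "<")))
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Random-forest cross-validated classification
#'
#' A nested pipeline: inside each training fold a random forest ranks
#' features by impurity importance, features above the median importance are
#' retained, and a second forest is fit on the selected features only;
#' held-out samples are scored with class probabilities. Evaluation uses
#' stratified k-fold cross-validation and the macro-averaged one-vs-rest
#' AUC, both averaged over folds and on the pooled out-of-fold predictions.
#' Selection happening strictly inside folds prevents information leakage.
#'
#' @param X Samples x features numeric matrix.
#' @param y Factor of class labels; every class needs at least `n_folds`
#'   members.
#' @param n_estimators Trees per forest (default 100).
#' @param n_folds Folds (default 5).
#' @param seed Integer seed; per-fold seeds are derived from it.
#' @param provenance Optional per-feature provenance tags.
#' @return List of class `rf_cv_result`: `macro_auc` (mean of per-fold
#'   macro AUCs), `pooled_auc` (macro AUC on pooled out-of-fold
#'   predictions), `fold_auc`, `per_class_auc`, `importances` (data.frame,
#'   mean first-stage importance per feature with provenance),
#'   `oof_prob`, `y`.
#' @export
rf_cross_validate <- function(X, y, n_estimators = 100, n_folds = 5, seed = 1,
                              provenance = NULL) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nrow(X) != length(y)) stop("X rows must match labels")
  if (any(table(y) < n_folds)) {
    stop("class smaller than the fold count; reduce n_folds")
  }
  if (is.null(provenance)) provenance <- rep("feature", ncol(X))
  fold <- stratified_folds(y, n_folds, seed)
  imp_sum <- numeric(ncol(X))
  names(imp_sum) <- colnames(X)
  oof <- matrix(NA_real_, nrow(X), nlevels(y),
                dimnames = list(rownames(X), levels(y)))
  fold_auc <- numeric(n_folds)
  per_class <- matrix(NA_real_, n_folds, nlevels(y),
                      dimnames = list(NULL, levels(y)))
  for (f in seq_len(n_folds)) {
    fold_seed <- seed * 1000L + f
    tr <- fold != f
    sel_fit <- ranger::ranger(x = X[tr, , drop = FALSE], y = y[tr],
                              num.trees = n_estimators,
                              importance = "impurity", seed = fold_seed)
    imp <- sel_fit$variable.importance
    imp_sum <- imp_sum + imp
    keep <- imp > stats::median(imp)
    if (!any(keep)) keep <- rep(TRUE, ncol(X))
    fit <- ranger::ranger(x = X[tr, keep, drop = FALSE], y = y[tr],
                          num.trees = n_estimators, probability = TRUE,
                          seed = fold_seed)
    prob <- stats::predict(fit, X[!tr, keep, drop = FALSE])$predictions
    oof[!tr, colnames(prob)] <- prob
    fold_auc[f] <- macro_ovr_auc(y[!tr], prob)
    for (cl in levels(y)) {
      resp <- as.integer(y[!tr] == cl)
      if (length(unique(resp)) == 2) {
        per_class[f, cl] <- as.numeric(
          pROC::auc(pROC::roc(resp, prob[, cl], quiet = TRUE,
                              levels = c(0, 1), direction = "<")))
      }
    }
  }
  structure(list(
    macro_auc = mean(fold_auc),
    pooled_auc = macro_ovr_auc(y, oof),
    fold_auc = fold_auc,
    per_class_auc = colMeans(per_class, na.rm = TRUE),
    importances = data.frame(feature = names(imp_sum),
                             provenance = provenance,
                             importance = unname(imp_sum) / n_folds),
    oof_prob = oof, y = y),
    class = "rf_cv_result")
}

#' @export
print.rf_cv_result <- function(x, ...) {
  cat(sprintf("<rf_cv_result> macro AUC %.3f (pooled %.3f) over %d folds\n",
              x$macro_auc, x$pooled_auc, length(x$fold_auc)))
  invisible(x)
}

#' Top predictive features with per-condition means
#'
#' Ranks features by mean cross-validated importance and builds the
#' phase x temperature mean-abundance matrix for the top k, hierarchically
#' clustered by feature-profile correlation (reusing the
#' [correlation_matrix_clustered()] machinery); reports the provenance
#' shares among the top k.
#'
#' @param cv An `rf_cv_result`.
#' @param X The design matrix used for the fit.
#' @param metadata A `sample_metadata` aligned with `X` rows.
#' @param k Number of features to report (default 25; truncated with a
#'   message if fewer exist).
#' @return List with `table` (ranked features), `heat` (features x
#'   condition means, rows in clustered order) and `provenance_fractions`.
#' @export
top_features_report <- function(cv, X, metadata, k = 25) {
  stopifnot(inherits(cv, "rf_cv_result"))
  imp <- cv$importances[order(-cv$importances$importance), , drop = FALSE]
  if (k > nrow(imp)) {
    message("only ", nrow(imp), " features available; truncating k")
    k <- nrow(imp)
  }
  top <- utils::head(imp, k)
  md <- align_metadata(metadata, rownames(X))
  cond <- sprintf("%g.%d", md$temperature, md$phase)
  heat <- vapply(sort(unique(cond)), function(cc) {
    colMeans(X[cond == cc, top$feature, drop = FALSE])
  }, numeric(k))
  if (k >= 3 && ncol(heat) >= 3) {
    ord <- suppressMessages(correlation_matrix_clustered(t(heat))$order)
    heat <- heat[c(ord, setdiff(rownames(heat), ord)), , drop = FALSE]
  }
  rownames(top) <- NULL
  list(table = top, heat = heat,
       provenance_fractions = prop.table(table(top$provenance)))
}
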