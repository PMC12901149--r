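procrustes_configs <- function(A, B, k_axes) {
  ca <- if (inherits(A, "ordination")) A$coordinates else as.matrix(A)
  cb <- if (inherits(B, "ordination")) B$coordinates else as.matrix(B)
  if (nrow(ca) != nrow(cb) ||
      (!is.null(rownames(ca)) && !is.null(rownames(cb)) &&
       !identical(rownames(ca), rownames(cb)))) {
    stop("ordinations must cover the same samples in the same order")
  }
  k <- min(k_axes, ncol(ca), ncol(cb))
  norm_cfg <- function(x) {
    x <- sweep(x[, seq_len(k), drop = FALSE], 2L, colMeans(x[, seq_len(k), drop = FALSE]))
    x / sqrt(sum(x^2))
  }
  list(X = norm_cfg(ca), Y = norm_cfg(cb), k = k)
}

m2_stat <- function(X, Y) {
  # both centred and scaled to unit sum of squares
  1 - sum(svd(crossprod(X, Y))$d)^2
}

#' Procrustes residual between two ordinations
#'
#' Centres both configurations, scales each to unit sum of squares, applies
#' the optimal rotation/reflection and scaling, and returns the symmetric
#' Procrustes statistic M^2 (residual sum of squared differences, 0 =
#' perfect concordance, values in \[0, 1\]).
#'
#' @param A,B `ordination` objects (or coordinate matrices) over the same
#'   samples in the same order.
#' @param k_axes Number of leading axes compared (default 2); truncated to
#'   the axes available in both inputs.
#' @return The M^2 statistic.
#' @export
procrustes_m2 <- function(A, B, k_axes = 2) {
  cfg <- procrustes_configs(A, B, k_axes)
  max(0, m2_stat(cfg$X, cfg$Y))
}

#' Procrustes permutation test
#'
#' The null distribution of M^2 is generated by permuting the sample rows of
#' the second configuration (by convention the metabolome) and realigning;
#' `p = (number of permuted M^2 <= observed + 1) / (n_perm + 1)`.
#'
#' @inheritParams procrustes_m2
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return List with `m2`, `p`, `n_perm`.
#' @export
procrustes_permutation_test <- function(A, B, k_axes = 2, n_perm = 1000,
                                        seed = 1) {
  cfg <- procrustes_configs(A, B, k_axes)
  obs <- max(0, m2_stat(cfg$X, cfg$Y))
  n <- nrow(cfg$X)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(b) {
    Yp <- cfg$Y[sample.int(n), , drop = FALSE]
    Yp <- sweep(Yp, 2L, colMeans(Yp))
    m2_stat(cfg$X, Yp / sqrt(sum(Yp^2)))
  }, numeric(1))
  list(m2 = obs, p = (sum(perm <= obs) + 1) / (n_perm + 1), n_perm = n_perm)
}

#' Microbiome-metabolome concordance, globally and per stratum
#'
#' For each stratum (the global sample set, each temperature, each day),
#' builds a Bray-Curtis PCoA of the microbiome and the configured metabolome
#' ordination, and runs the Procrustes permutation test. Strata with fewer
#' than 4 samples are skipped with a message.
#'
#' @param micro Raw microbial `feature_table` (counts).
#' @param metab Raw metabolite `feature_table` (intensities).
#' @param metadata A `sample_metadata` covering the shared samples.
#' @param strata Any of `"global"`, `"temperature"`, `"day"`.
#' @param metab_mode Metabolome ordination: `"pcoa-braycurtis"` (PCoA of
#'   Bray-Curtis on TSS), `"pca-tss"`, or `"pca-zscore"`.
#' @param k_axes,n_perm,seed Passed to [procrustes_permutation_test()].
#' @return Data.frame: `stratum_type`, `stratum`, `n`, `m2`, `p`.
#' @export
stratified_concordance <- function(micro, metab, metadata,
                                   strata = c("global", "temperature", "day"),
                                   metab_mode = c("pcoa-braycurtis", "pca-tss",
                                                  "pca-zscore"),
                                   k_axes = 2, n_perm = 1000, seed = 1) {
  metab_mode <- match.arg(metab_mode)
  strata <- match.arg(strata, several.ok = TRUE)
  shared <- intersect(sample_ids(micro), sample_ids(metab))
  micro <- ft_subset(micro, samples = shared)
  metab <- ft_subset(metab, samples = shared)
  md <- align_metadata(metadata, shared)
  run_one <- function(type, label, ids) {
    if (length(ids) < 4) {
      message("skipping ", type, " stratum '", label, "' (n = ", length(ids), ")")
      return(NULL)
    }
    mi <- ft_subset(micro, samples = ids)
    me <- ft_subset(metab, samples = ids)
    ord_mi <- pcoa(beta_diversity(mi, "braycurtis"))
    ord_me <- switch(metab_mode,
      "pcoa-braycurtis" = pcoa(beta_diversity(tss_normalize(me), "braycurtis")),
      "pca-tss" = pca(tss_normalize(me)),
      "pca-zscore" = pca(zscore_normalize(me)))
    res <- procrustes_permutation_test(ord_mi, ord_me, k_axes = k_axes,
                                       n_perm = n_perm, seed = seed)
    data.frame(stratum_type = type, stratum = label, n = length(ids),
               m2 = res$m2, p = res$p)
  }
  rows <- list()
  if ("global" %in% strata) {
    rows[[length(rows) + 1L]] <- run_one("global", "global", shared)
  }
  for (col in intersect(strata, c("temperature", "day"))) {
    for (lev in unique(md[[col]])) {
      rows[[length(rows) + 1L]] <-
        run_one(col, as.character(lev), md$sample_id[md[[col]] == lev])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
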