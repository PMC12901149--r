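#' Alpha diversity per sample
#'
#' @param t A `feature_table` of non-negative counts or proportions.
#' @param metric One of `"richness"` (features with value > 0), `"shannon"`
#'   (entropy, natural log) or `"pielou_evenness"` (Shannon / log richness;
#'   `NA` when richness <= 1, where evenness is undefined).
#' @return Named numeric vector, one value per sample.
#' @export
alpha_diversity <- function(t, metric = c("richness", "shannon", "pielou_evenness")) {
  stopifnot(inherits(t, "feature_table"))
  metric <- match.arg(metric)
  v <- t$values
  if (any(v < 0)) stop("alpha diversity needs non-negative abundances")
  rich <- colSums(v > 0)
  if (metric == "richness") return(rich)
  p <- sweep(v, 2L, colSums(v), "/")
  plogp <- p * log(p)
  plogp[p == 0] <- 0
  sh <- -colSums(plogp)
  if (metric == "shannon") return(sh)
  ev <- ifelse(rich > 1, sh / log(rich), NA_real_)
  stats::setNames(ev, colnames(v))
}

#' Beta diversity between samples
#'
#' Bray-Curtis dissimilarity on abundances or Jaccard distance on
#' presence/absence. Pairs of all-zero samples, where the quotient is
#' undefined, are set to 0 with a warning.
#'
#' @param t A non-negative `feature_table`.
#' @param metric `"braycurtis"` or `"jaccard"`.
#' @return A `distance_matrix`.
#' @export
beta_diversity <- function(t, metric = c("braycurtis", "jaccard")) {
  stopifnot(inherits(t, "feature_table"))
  metric <- match.arg(metric)
  x <- t(t$values)
  if (any(x < 0)) stop("beta diversity needs non-negative abundances")
  # vegdist warns about empty rows / NA results; both are handled explicitly
  # below, so its warnings are redundant here
  d <- suppressWarnings(if (metric == "braycurtis") {
    vegan::vegdist(x, method = "bray")
  } else {
    vegan::vegdist(x, method = "jaccard", binary = TRUE)
  })
  m <- as.matrix(d)
  if (anyNA(m)) {
    warning("all-zero sample pair(s); their distance is defined as 0")
    m[is.na(m)] <- 0
  }
  distance_matrix(m)
}

gower_center <- function(d) {
  a <- -0.5 * d^2
  n <- nrow(a)
  rm <- rowMeans(a)
  a - matrix(rm, n, n) - matrix(rm, n, n, byrow = TRUE) + mean(a)
}

#' Principal coordinate analysis
#'
#' Classical metric MDS via eigendecomposition of the Gower-centred matrix.
#' Axes with positive eigenvalues are retained; explained proportions are
#' each positive eigenvalue over the sum of positive eigenvalues. Negative
#' eigenvalues (possible for semimetric dissimilarities such as Bray-Curtis)
#' are kept in the `eig` field for dispersion analyses.
#'
#' @param d A `distance_matrix` (or square symmetric matrix / `dist`).
#' @return An object of class `ordination`: `coordinates` (samples x axes),
#'   `explained`, `eig`, `method`.
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("need at least 3 samples")
  e <- eigen(gower_center(d), symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-10
  pos <- e$values > tol
  if (!any(pos)) stop("no positive eigenvalues; degenerate distance matrix")
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(list(coordinates = coords,
                 explained = e$values[pos] / sum(e$values[pos]),
                 eig = e$values, method = "pcoa"),
            class = "ordination")
}

#' Principal component analysis
#'
#' PCA of samples over (centred) features via [stats::prcomp()].
#'
#' @param t A `feature_table`.
#' @param scale Scale features to unit variance (correlation-matrix PCA).
#' @return An `ordination` (see [pcoa()]).
#' @export
pca <- function(t, scale = FALSE) {
  stopifnot(inherits(t, "feature_table"))
  if (ncol(t$values) < 3) stop("need at least 3 samples")
  x <- t(t$values)
  if (scale) x <- x[, apply(x, 2, stats::sd) > 0, drop = FALSE]
  pr <- stats::prcomp(x, center = TRUE, scale. = scale)
  keep <- pr$sdev^2 > max(pr$sdev^2) * 1e-12
  coords <- pr$x[, keep, drop = FALSE]
  structure(list(coordinates = coords,
                 explained = pr$sdev[keep]^2 / sum(pr$sdev^2),
                 eig = pr$sdev^2, method = "pca"),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("<ordination:%s> %d samples, %d axes; axis 1-2 explain %.1f%% + %.1f%%\n",
              x$method, nrow(x$coordinates), ncol(x$coordinates),
              100 * x$explained[1], 100 * ifelse(length(x$explained) > 1, x$explained[2], 0)))
  invisible(x)
}

#' Correlation biplot vectors for an ordination
#'
#' For each variable, the Pearson correlations with the first two ordination
#' axes give the arrow direction; the arrow is scaled by the sum of absolute
#' correlations.
#'
#' @param ord An `ordination`.
#' @param vars Data.frame or matrix of variables (rows = the ordination's
#'   samples, in the same order).
#' @param top_k Keep only the `top_k` variables by scale (default all).
#' @return Data.frame `variable`, `r1`, `r2`, `scale`, sorted by `scale`
#'   descending. Constant variables are skipped with a message.
#' @export
biplot_vectors <- function(ord, vars, top_k = NULL) {
  stopifnot(inherits(ord, "ordination"))
  m <- as.matrix(vars)
  if (nrow(m) != nrow(ord$coordinates)) stop("variables must align with samples")
  if (nrow(m) < 3) stop("need at least 3 samples")
  if (ncol(ord$coordinates) < 2) stop("need at least 2 ordination axes")
  keep <- apply(m, 2L, function(v) stats::sd(v) > 0)
  if (any(!keep)) {
    message("skipping constant variable(s): ", paste(colnames(m)[!keep], collapse = ", "))
  }
  m <- m[, keep, drop = FALSE]
  r1 <- as.vector(stats::cor(m, ord$coordinates[, 1]))
  r2 <- as.vector(stats::cor(m, ord$coordinates[, 2]))
  out <- data.frame(variable = colnames(m), r1 = r1, r2 = r2,
                    scale = abs(r1) + abs(r2))
  out <- out[order(-out$scale), , drop = FALSE]
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  rownames(out) <- NULL
  out
}

permanova_ss <- function(D2, groups) {
  n <- nrow(D2)
  sst <- sum(D2) / (2 * n)
  M <- rowsum(D2, groups)         # levels x n sums
  ssw <- 0
  for (l in rownames(M)) {
    idx <- groups == l
    ssw <- ssw + sum(M[l, idx]) / (2 * sum(idx))
  }
  c(sst = sst, ssw = ssw)
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Partitions the total sum of squared dissimilarities into among- and
#' within-group components; significance of the pseudo-F statistic is
#' assessed by permuting group labels.
#'
#' @param d A `distance_matrix` (or square symmetric matrix / `dist`).
#' @param groups Group labels, one per sample; every group needs >= 2
#'   samples.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @param factor_name Label recorded in the result.
#' @return Data.frame of class `permanova_result` with `factor`, `n`,
#'   `pseudo_F`, `R2`, `p`, `n_perm`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1, factor_name = "group") {
  d <- as.matrix(d)
  groups <- as.factor(as.character(groups))
  n <- nrow(d)
  if (length(groups) != n) stop("one group label per sample required")
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 samples")
  a <- nlevels(groups)
  D2 <- d^2
  ss <- permanova_ss(D2, groups)
  ssa <- ss["sst"] - ss["ssw"]
  f_obs <- (ssa / (a - 1)) / (ss["ssw"] / (n - a))
  r2 <- unname(ssa / ss["sst"])
  set.seed(seed)
  f_perm <- vapply(seq_len(n_perm), function(b) {
    gp <- groups[sample.int(n)]
    ssb <- permanova_ss(D2, gp)
    unname(((ssb["sst"] - ssb["ssw"]) / (a - 1)) / (ssb["ssw"] / (n - a)))
  }, numeric(1))
  p <- (sum(f_perm >= f_obs) + 1) / (n_perm + 1)
  structure(data.frame(factor = factor_name, n = n, pseudo_F = unname(f_obs),
                       R2 = r2, p = p, n_perm = n_perm),
            class = c("permanova_result", "data.frame"))
}

centroid_distances <- function(d, groups) {
  # Anderson's PERMDISP distances: principal coordinates incl. imaginary axes
  d <- as.matrix(d)
  e <- eigen(gower_center(d), symmetric = TRUE)
  tol <- max(abs(e$values), 1e-300) * 1e-9
  pos <- e$values > tol
  neg <- e$values < -tol
  Cp <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), sum(pos))
  Cn <- e$vectors[, neg, drop = FALSE] %*% diag(sqrt(-e$values[neg]), sum(neg))
  z <- numeric(nrow(d))
  for (l in levels(groups)) {
    idx <- which(groups == l)
    dp <- sweep(Cp[idx, , drop = FALSE], 2L, colMeans(Cp[idx, , drop = FALSE]))
    dn <- sweep(Cn[idx, , drop = FALSE], 2L, colMeans(Cn[idx, , drop = FALSE]))
    z[idx] <- sqrt(pmax(0, rowSums(dp^2) - rowSums(dn^2)))
  }
  z
}

anova_f <- function(y, groups) {
  n <- length(y); a <- nlevels(groups)
  gm <- tapply(y, groups, mean)
  ng <- tabulate(groups)
  ssb <- sum(ng * (gm - mean(y))^2)
  ssw <- sum((y - gm[groups])^2)
  (ssb / (a - 1)) / (ssw / (n - a))
}

#' PERMDISP: homogeneity of multivariate dispersions
#'
#' Computes each sample's distance to its group centroid in principal
#' coordinate space (real and imaginary axes handled by subtracting squared
#' imaginary distances), then tests group differences in mean distance with
#' an ANOVA F whose null distribution is obtained by permuting the
#' distances among groups (the least-squares residual permutation).
#'
#' @inheritParams permanova
#' @return List of class `permdisp_result`: `F`, `p`, `group_means` (named
#'   mean distance to centroid per group), `distances`, `n_perm`.
#' @export
permdisp <- function(d, groups, n_perm = 999, seed = 1) {
  d <- as.matrix(d)
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 samples")
  z <- centroid_distances(d, groups)
  f_obs <- anova_f(z, groups)
  set.seed(seed)
  n <- length(z)
  f_perm <- vapply(seq_len(n_perm), function(b) {
    anova_f(z[sample.int(n)], groups)
  }, numeric(1))
  p <- (sum(f_perm >= f_obs) + 1) / (n_perm + 1)
  structure(list(F = f_obs, p = p,
                 group_means = tapply(z, groups, mean),
                 distances = stats::setNames(z, rownames(d)),
                 n_perm = n_perm),
            class = "permdisp_result")
}

#' Two-level nested PERMANOVA
#'
#' A global PERMANOVA on the primary factor, followed by within-stratum
#' PERMANOVA tests of the secondary factor restricted to each primary level,
#' with Benjamini-Hochberg correction across the secondary tests of the
#' call. Each stratum's test is bit-identical to subsetting the distance
#' matrix to that stratum and calling [permanova()] with the same seed.
#'
#' @param d A `distance_matrix`.
#' @param primary,secondary Label vectors, one per sample.
#' @param n_perm Permutations per test.
#' @param seed Integer seed, reused for every stratum.
#' @return Data.frame with `test` (`"global"` or `"within"`), `stratum`,
#'   `factor`, `n`, `pseudo_F`, `R2`, `p`, `q` (BH-corrected, secondary
#'   tests only), `n_perm`. Strata where the secondary factor has fewer than
#'   2 usable levels are skipped with a message.
#' @export
nested_permanova <- function(d, primary, secondary, n_perm = 999, seed = 1) {
  d <- as.matrix(d)
  primary <- as.character(primary)
  secondary <- as.character(secondary)
  glob <- permanova(d, primary, n_perm = n_perm, seed = seed,
                    factor_name = "primary")
  rows <- list(data.frame(test = "global", stratum = NA_character_,
                          factor = "primary", n = glob$n,
                          pseudo_F = glob$pseudo_F, R2 = glob$R2,
                          p = glob$p, q = NA_real_, n_perm = n_perm))
  for (lev in unique(primary)) {
    idx <- which(primary == lev)
    sec <- secondary[idx]
    ok_levels <- names(which(table(sec) >= 2))
    keep <- idx[sec %in% ok_levels]
    if (length(ok_levels) < 2) {
      message("skipping stratum '", lev, "': secondary factor has <2 usable levels")
      next
    }
    res <- permanova(d[keep, keep, drop = FALSE], secondary[keep],
                     n_perm = n_perm, seed = seed, factor_name = "secondary")
    rows[[length(rows) + 1L]] <-
      data.frame(test = "within", stratum = lev, factor = "secondary",
                 n = res$n, pseudo_F = res$pseudo_F, R2 = res$R2,
                 p = res$p, q = NA_real_, n_perm = n_perm)
  }
  out <- do.call(rbind, rows)
  within <- out$test == "within"
  out$q[within] <- stats::p.adjust(out$p[within], method = "BH")
  rownames(out) <- NULL
  out
}
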