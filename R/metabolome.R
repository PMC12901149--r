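anova_p_value <- function(y, g) {
  g <- as.factor(g)
  a <- nlevels(g)
  n <- length(y)
  if (a < 2 || n - a < 1) return(NA_real_)
  gm <- tapply(y, g, mean)
  ng <- tabulate(g)
  ssb <- sum(ng * (gm - mean(y))^2)
  ssw <- sum((y - gm[g])^2)
  if (ssw == 0) return(if (ssb == 0) 1 else 0)
  f <- (ssb / (a - 1)) / (ssw / (n - a))
  stats::pf(f, a - 1, n - a, lower.tail = FALSE)
}

#' Keep time-responsive metabolite features
#'
#' Per feature and temperature group, a one-way ANOVA across time points;
#' features significant (p < alpha, uncorrected) in at least one temperature
#' group are retained. Temperature groups with a single time point are
#' skipped with a message.
#'
#' @param t A z-scored `feature_table`.
#' @param metadata A `sample_metadata`.
#' @param alpha Per-test significance level (default 0.05).
#' @return The filtered `feature_table`; dropped ids in attribute
#'   `"dropped"`.
#' @export
anova_responsiveness_filter <- function(t, metadata, alpha = 0.05) {
  stopifnot(inherits(t, "feature_table"))
  md <- align_metadata(metadata, t)
  temps <- unique(md$temperature)
  usable <- temps[vapply(temps, function(tt) {
    length(unique(md$day[md$temperature == tt])) >= 2
  }, logical(1))]
  skipped <- setdiff(temps, usable)
  if (length(skipped)) {
    message("skipping temperature group(s) with one time point: ",
            paste(skipped, collapse = ", "))
  }
  if (!length(usable)) stop("no temperature group with >=2 time points")
  keep <- rep(FALSE, nrow(t$values))
  for (tt in usable) {
    idx <- md$temperature == tt
    g <- md$day[idx]
    p <- apply(t$values[, idx, drop = FALSE], 1L, anova_p_value, g = g)
    keep <- keep | (!is.na(p) & p < alpha)
  }
  if (!any(keep)) stop("no responsive features at alpha = ", alpha)
  out <- ft_subset(t, features = which(keep))
  attr(out, "dropped") <- feature_ids(t)[!keep]
  out
}

run_kmeans <- function(x, k, nstart, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stats::kmeans(x, centers = k, nstart = nstart, iter.max = 100)
}

#' Choose the number of trajectory clusters
#'
#' Evaluates silhouette score, within-cluster sum of squares (elbow by the
#' largest second difference) and the gap statistic (B uniform-box reference
#' sets, first-SE-max rule) over `k_range`, and picks the k supported by a
#' majority of the three criteria; ties go to the smallest candidate k.
#'
#' @param t Filtered, z-scored `feature_table`; features are the points,
#'   their sample-ordered trajectories the coordinates.
#' @param k_range Candidate cluster counts (within `[2, f - 1]`).
#' @param seed Integer seed.
#' @param B Reference sets for the gap statistic (default 20).
#' @param nstart Restarts per k-means run (default 25).
#' @return List with `k`, `votes` (per-criterion choice) and `diagnostics`
#'   (per-k silhouette, WCSS, gap and gap SE).
#' @export
select_k <- function(t, k_range = 2:6, seed = 1, B = 20, nstart = 25) {
  stopifnot(inherits(t, "feature_table"))
  x <- t$values
  if (max(k_range) >= nrow(x)) stop("fewer features than the largest k")
  if (min(k_range) < 2) stop("k must be at least 2")
  k_range <- sort(unique(as.integer(k_range)))
  set.seed(seed)
  dx <- stats::dist(x)
  sil <- wcss <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    km <- run_kmeans(x, k_range[i], nstart)
    wcss[i] <- km$tot.withinss
    sil[i] <- mean(cluster::silhouette(km$cluster, dx)[, "sil_width"])
  }
  k_sil <- k_range[which.max(sil)]
  k_elbow <- if (length(k_range) >= 3) {
    curv <- diff(diff(wcss))  # positive where the decrease flattens
    k_range[which.max(curv) + 1L]
  } else min(k_range)
  gap <- cluster::clusGap(x, FUNcluster = function(xx, kk) {
    run_kmeans(xx, kk, nstart)
  }, K.max = max(k_range), B = B, verbose = FALSE)
  gt <- gap$Tab
  k_gap_all <- cluster::maxSE(gt[, "gap"], gt[, "SE.sim"], method = "firstSEmax")
  k_gap <- if (k_gap_all < min(k_range)) min(k_range) else
    max(k_range[k_range <= k_gap_all])
  votes <- c(silhouette = k_sil, elbow = k_elbow, gap = k_gap)
  tab <- table(votes)
  winners <- as.integer(names(tab)[tab == max(tab)])
  list(k = min(winners), votes = votes,
       diagnostics = data.frame(k = k_range, silhouette = sil, wcss = wcss,
                                gap = gt[k_range, "gap"],
                                gap_se = gt[k_range, "SE.sim"]))
}

#' Cluster metabolite trajectories with k-means
#'
#' Features are clustered by their sample-ordered (z-scored) trajectories
#' using k-means with multiple restarts; empty clusters trigger a logged
#' restart. Per-cluster mean curves per temperature-day cell are returned
#' when metadata are supplied.
#'
#' @param t A z-scored `feature_table`.
#' @param k Number of clusters (>= 2).
#' @param seed Integer seed.
#' @param metadata Optional `sample_metadata` for the mean curves.
#' @param nstart Restarts (default 50).
#' @return List with `labels` (named integer vector, clusters numbered from
#'   0), `centers`, `curves` (data.frame cluster x temperature x day mean,
#'   or `NULL`).
#' @export
cluster_trajectories <- function(t, k, seed = 1, metadata = NULL, nstart = 50) {
  stopifnot(inherits(t, "feature_table"), k >= 2)
  x <- t$values
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = nstart, iter.max = 100)
  attempt <- 0
  while (length(unique(km$cluster)) < k && attempt < 5) {
    attempt <- attempt + 1
    message("empty cluster; restarting k-means (attempt ", attempt, ")")
    km <- stats::kmeans(x, centers = k, nstart = nstart, iter.max = 100)
  }
  labels <- stats::setNames(km$cluster - 1L, rownames(x))
  curves <- NULL
  if (!is.null(metadata)) {
    md <- align_metadata(metadata, t)
    cells <- expand.grid(cluster = sort(unique(labels)),
                         temperature = sort(unique(md$temperature)),
                         day = sort(unique(md$day)), KEEP.OUT.ATTRS = FALSE)
    cells$mean <- mapply(function(cl, tt, dd) {
      mean(x[labels == cl, md$temperature == tt & md$day == dd, drop = FALSE])
    }, cells$cluster, cells$temperature, cells$day)
    curves <- cells
  }
  list(labels = labels, centers = km$centers, curves = curves)
}

#' Per-cluster, per-day temperature tests
#'
#' Kruskal-Wallis tests of member-feature values across temperatures for
#' every cluster x day cell, Benjamini-Hochberg corrected within cluster.
#' Cells where any temperature group has fewer than 3 observations are
#' skipped with a message.
#'
#' @param t The (z-scored) `feature_table` used for clustering.
#' @param labels Per-feature cluster labels (as from
#'   [cluster_trajectories()]).
#' @param metadata A `sample_metadata`.
#' @return Data.frame: `cluster`, `day`, `n`, `p`, `q`.
#' @export
kruskal_temperature_tests <- function(t, labels, metadata) {
  stopifnot(inherits(t, "feature_table"))
  md <- align_metadata(metadata, t)
  labels <- labels[feature_ids(t)]
  rows <- list()
  for (cl in sort(unique(labels))) {
    feats <- names(labels)[labels == cl]
    for (dd in sort(unique(md$day))) {
      idx <- md$day == dd
      if (length(unique(md$temperature[idx])) < 2) next
      vals <- as.vector(t$values[feats, idx, drop = FALSE])
      grp <- factor(rep(md$temperature[idx], each = length(feats)))
      if (any(table(grp) < 3)) {
        message("skipping cluster ", cl, ", day ", dd, ": group with <3 observations")
        next
      }
      p <- stats::kruskal.test(vals, grp)$p.value
      rows[[length(rows) + 1L]] <- data.frame(cluster = cl, day = dd,
                                              n = length(vals), p = p)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (cl in unique(out$cluster)) {
    sel <- out$cluster == cl
    out$q[sel] <- stats::p.adjust(out$p[sel], method = "BH")
  }
  rownames(out) <- NULL
  out
}

#' Class enrichment across phase x temperature conditions
#'
#' Conditions are phase x temperature cells labelled
#' `"<temperature>.<phase>"` (e.g. `"4.1"` is phase 1 at 4 degC). Per
#' metabolite class and condition, enrichment is the natural log of the mean
#' member-feature value inside the condition over the global mean, and
#' significance comes from a two-sided Mann-Whitney U test of member-feature
#' values in-condition versus all other samples, Benjamini-Hochberg
#' corrected over the whole table. Classes with fewer than 2 features are
#' skipped with a message.
#'
#' @param t A positive-valued `feature_table` (raw or TSS intensities).
#' @param metadata A `sample_metadata`.
#' @param classes Named per-feature class labels.
#' @param alpha FDR level used for the `significant` flag (default 0.05).
#' @return Data.frame: `class`, `condition`, `n_features`, `enrichment`,
#'   `p`, `q`, `significant`.
#' @export
class_enrichment <- function(t, metadata, classes, alpha = 0.05) {
  stopifnot(inherits(t, "feature_table"))
  md <- align_metadata(metadata, t)
  cond <- sprintf("%g.%d", md$temperature, md$phase)
  classes <- classes[feature_ids(t)]
  rows <- list()
  for (cl in sort(unique(stats::na.omit(classes)))) {
    feats <- names(classes)[!is.na(classes) & classes == cl]
    if (length(feats) < 2) {
      message("skipping class '", cl, "' with <2 features")
      next
    }
    vals <- t$values[feats, , drop = FALSE]
    gmean <- mean(vals)
    for (cc in sort(unique(cond))) {
      inside <- as.vector(vals[, cond == cc, drop = FALSE])
      outside <- as.vector(vals[, cond != cc, drop = FALSE])
      enr <- log(mean(inside) / gmean)
      p <- stats::wilcox.test(inside, outside, exact = FALSE)$p.value
      rows[[length(rows) + 1L]] <- data.frame(class = cl, condition = cc,
                                              n_features = length(feats),
                                              enrichment = enr, p = p)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < alpha
  rownames(out) <- NULL
  out
}

#' Annotate observed masses against a reference table
#'
#' Exact-mass matching: every reference entry whose monoisotopic mass lies
#' within `tol` of the observed m/z is reported, nearest first. Features
#' with no match are labelled `"unannotated"`. A small fermentation-relevant
#' reference table ships with the package
#' (`system.file("extdata", "reference_masses.tsv", package = "sourstore")`).
#'
#' @param mz Named numeric vector of observed m/z values (names = feature
#'   ids; unnamed vectors are numbered).
#' @param reference Data.frame with columns `name`, `mass`, `class`;
#'   default: the bundled reference table.
#' @param tol Mass tolerance in Da (default 0.002).
#' @return Data.frame: `feature`, `mz`, `name`, `class`, `ref_mass`,
#'   `delta`.
#' @export
mass_annotate <- function(mz, reference = NULL, tol = 0.002) {
  if (tol < 0) stop("tolerance must be non-negative")
  if (is.null(reference)) {
    reference <- utils::read.table(
      system.file("extdata", "reference_masses.tsv", package = "sourstore"),
      header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  }
  stopifnot(all(c("name", "mass", "class") %in% names(reference)))
  if (is.null(names(mz))) names(mz) <- sprintf("feature_%03d", seq_along(mz))
  rows <- list()
  for (i in seq_along(mz)) {
    m_i <- unname(mz[i])
    d <- abs(reference$mass - m_i)
    hit <- which(d <= tol)
    if (!length(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        feature = names(mz)[i], mz = m_i, name = "unannotated",
        class = NA_character_, ref_mass = NA_real_, delta = NA_real_)
    } else {
      hit <- hit[order(d[hit])]
      rows[[length(rows) + 1L]] <- data.frame(
        feature = names(mz)[i], mz = m_i, name = reference$name[hit],
        class = reference$class[hit], ref_mass = reference$mass[hit],
        delta = unname(d[hit]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Day-wise ANOVA with Tukey post hoc and Levene diagnostic
#'
#' For a continuous per-sample variable: at each day, a one-way ANOVA across
#' temperatures (BH-corrected across days), Tukey HSD pairwise contrasts,
#' and Levene's test for variance homogeneity reported alongside. Days
#' without at least 2 temperatures holding >= 2 replicates are skipped with
#' a message.
#'
#' @param values Per-sample numeric vector, aligned with `metadata` rows
#'   (or named by sample id).
#' @param metadata A `sample_metadata`.
#' @return List with `table` (day, n, levene_p, anova_p, q) and `tukey`
#'   (day, contrast, diff, p_adj).
#' @export
daywise_anova_tukey <- function(values, metadata) {
  md <- metadata
  if (!is.null(names(values))) values <- values[md$sample_id]
  if (length(values) != nrow(md)) stop("values must align with metadata samples")
  rows <- list(); tk <- list()
  for (dd in sort(unique(md$day))) {
    idx <- which(md$day == dd)
    g <- factor(md$temperature[idx])
    ok <- sum(table(g) >= 2) >= 2
    if (!ok) {
      message("skipping day ", dd, ": needs >=2 temperatures with >=2 replicates")
      next
    }
    y <- values[idx]
    # with 2 replicates per group the Levene ANOVA can be a perfect fit;
    # its warning is noise here, the p-value is still reported as diagnostic
    lev_p <- tryCatch(suppressWarnings(car::leveneTest(y, g)[1, "Pr(>F)"]),
                      error = function(e) NA_real_)
    fit <- stats::aov(y ~ g)
    an_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    th <- stats::TukeyHSD(fit)$g
    rows[[length(rows) + 1L]] <- data.frame(day = dd, n = length(idx),
                                            levene_p = lev_p, anova_p = an_p)
    tk[[length(tk) + 1L]] <- data.frame(day = dd, contrast = rownames(th),
                                        diff = th[, "diff"],
                                        p_adj = th[, "p adj"])
  }
  tab <- do.call(rbind, rows)
  tab$q <- stats::p.adjust(tab$anova_p, method = "BH")
  tukey <- do.call(rbind, tk)
  rownames(tab) <- rownames(tukey) <- NULL
  list(table = tab, tukey = tukey)
}
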