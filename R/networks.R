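#' Abundance-weighted co-occurrence score
#'
#' For two CLR-transformed feature vectors over the same samples, the score
#' is `sum(x * y * w) / sum(w)` with weights `w = |x * y|`: an
#' abundance-weighted average of the signed products that upweights
#' high-magnitude co-variation and suppresses low-abundance noise. The score
#' is not bounded by 1 (a single dominant product can exceed it); if every
#' product is zero the score is 0 by convention.
#'
#' @param x,y Numeric vectors of equal length (CLR values over samples).
#' @return A single signed real score.
#' @export
cooccurrence_score <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  p <- x * y
  w <- abs(p)
  sw <- sum(w)
  if (sw == 0) return(0)
  sum(p * w) / sw
}

# chain raw/tss tables into CLR; already-clr tables pass through
prepare_clr_tables <- function(tables, delta = 1e-8) {
  stopifnot(length(tables) >= 1)
  sids <- lapply(tables, sample_ids)
  shared <- Reduce(intersect, sids)
  bad <- setdiff(Reduce(union, sids), shared)
  if (length(bad)) {
    stop("tables do not share identical sample sets; unshared: ",
         paste(bad, collapse = ", "))
  }
  clr_list <- list(); abund <- list()
  for (t in tables) {
    t <- ft_subset(t, samples = shared)
    if (t$transform == "clr") {
      clr_list[[length(clr_list) + 1L]] <- t
      abund[[length(abund) + 1L]] <- rep(NA_real_, nrow(t$values))
    } else {
      rel <- if (t$transform == "tss") t else tss_normalize(t)
      clr_list[[length(clr_list) + 1L]] <-
        clr_transform(multiplicative_replacement(rel, delta = delta))
      abund[[length(abund) + 1L]] <- rowMeans(rel$values)
    }
  }
  values <- do.call(rbind, lapply(clr_list, function(t) t$values))
  domain <- unlist(lapply(clr_list, function(t) t$domain))
  if (anyDuplicated(rownames(values))) stop("duplicate feature ids across tables")
  list(values = values, domain = domain, mean_abundance = unlist(abund),
       samples = shared)
}

new_network <- function(nodes, edges, kind, condition = NA_character_) {
  structure(list(nodes = nodes, edges = edges, kind = kind,
                 condition = condition), class = "omics_network")
}

#' @export
print.omics_network <- function(x, ...) {
  cat(sprintf("<omics_network:%s> %d nodes, %d edges%s\n", x$kind,
              nrow(x$nodes), nrow(x$edges),
              if (!is.na(x$condition)) paste0(" [", x$condition, "]") else ""))
  invisible(x)
}

#' Abundance-weighted co-occurrence network
#'
#' Scores every unordered feature pair across the concatenated
#' (CLR-transformed) tables with [cooccurrence_score()] and keeps edges with
#' `|score| >= threshold`. Raw tables are transformed internally
#' (TSS, multiplicative replacement, CLR); metabolite intensity tables thus
#' enter after TSS normalisation. Because the score is unbounded, a
#' rank-based cut (`top_q`, the fraction of highest-|score| pairs) is
#' offered as an alternative to the absolute threshold.
#'
#' @param tables List of `feature_table`s sharing identical samples.
#' @param threshold Absolute score threshold for edges (default 0.2).
#' @param top_q Optional fraction in (0, 1]; if given, overrides
#'   `threshold` and keeps the top-q fraction of pairs by |score|.
#' @param delta Multiplicative-replacement delta (default 1e-8).
#' @param condition Optional condition label stored on the network.
#' @return An `omics_network` with nodes (id, domain, mean relative
#'   abundance) and signed co-occurrence edges (u < v).
#' @export
cooccurrence_network <- function(tables, threshold = 0.2, top_q = NULL,
                                 delta = 1e-8, condition = NA_character_) {
  if (inherits(tables, "feature_table")) tables <- list(tables)
  prep <- prepare_clr_tables(tables, delta = delta)
  X <- prep$values
  f <- nrow(X)
  us <- integer(0); vs <- integer(0); sc <- numeric(0)
  for (a in seq_len(max(0, f - 1))) {
    rest <- (a + 1L):f
    M <- sweep(X[rest, , drop = FALSE], 2L, X[a, ], "*")
    W <- abs(M)
    den <- rowSums(W)
    s <- ifelse(den == 0, 0, rowSums(M * W) / den)
    us <- c(us, rep.int(a, length(rest)))
    vs <- c(vs, rest)
    sc <- c(sc, s)
  }
  keep <- if (!is.null(top_q)) {
    stopifnot(top_q > 0, top_q <= 1)
    rank(-abs(sc), ties.method = "first") <= ceiling(top_q * length(sc))
  } else {
    abs(sc) >= threshold
  }
  nodes <- data.frame(id = rownames(X), domain = prep$domain,
                      mean_abundance = prep$mean_abundance)
  edges <- data.frame(u = rownames(X)[us[keep]], v = rownames(X)[vs[keep]],
                      weight = sc[keep],
                      kind = rep("cooccurrence", sum(keep)))
  new_network(nodes, edges, "cooccurrence", condition)
}

#' Conditional-dependence network via the graphical lasso
#'
#' CLR-transforms each table, z-score standardises features, concatenates
#' them, and estimates a sparse precision matrix with [glasso_cv()]. Edges
#' are the non-zero off-diagonal precision entries, weighted by the
#' regularised partial correlation `-theta_uv / sqrt(theta_uu * theta_vv)`.
#'
#' @inheritParams cooccurrence_network
#' @param n_alphas,n_folds Penalty-grid size and CV folds for [glasso_cv()].
#' @param min_partial_corr Magnitude below which a precision entry is
#'   treated as numerically zero (default 1e-8).
#' @param seed Integer seed for CV fold assignment.
#' @return An `omics_network` with partial-correlation edges.
#' @export
glasso_network <- function(tables, n_alphas = 20, n_folds = 5,
                           min_partial_corr = 1e-8, delta = 1e-8, seed = 1,
                           condition = NA_character_) {
  if (inherits(tables, "feature_table")) tables <- list(tables)
  prep <- prepare_clr_tables(tables, delta = delta)
  zt <- zscore_normalize(feature_table(prep$values,
                                       domain = prep$domain,
                                       transform = "clr"))
  X <- t(zt$values)
  fit <- glasso_cv(X, n_alphas = n_alphas, n_folds = n_folds, seed = seed)
  pc <- partial_correlations(fit$theta)
  ids <- colnames(X)
  ut <- which(upper.tri(pc), arr.ind = TRUE)
  keep <- abs(fit$theta[ut]) > min_partial_corr
  kept_dom <- prep$domain[match(ids, rownames(prep$values))]
  nodes <- data.frame(id = ids, domain = kept_dom,
                      mean_abundance =
                        prep$mean_abundance[match(ids, rownames(prep$values))])
  edges <- data.frame(u = ids[ut[keep, 1L]], v = ids[ut[keep, 2L]],
                      weight = pc[ut][keep],
                      kind = rep("partial_correlation", sum(keep)))
  net <- new_network(nodes, edges, "partial_correlation", condition)
  net$rho <- fit$rho
  net
}

#' Node centralities of a network
#'
#' Degree, betweenness, closeness and eigenvector centrality on the
#' unweighted topology (set `weighted = TRUE` to use `|weight|` as edge
#' strength for betweenness/closeness path lengths, with `1/|weight|` as
#' distance). Closeness is computed within each connected component and
#' scaled by component size (Wasserman-Faust scaling); isolated nodes get
#' closeness 0. Eigenvector centrality is normalised to max = 1 and is 0 for
#' every node of an edgeless graph.
#'
#' @param net An `omics_network`.
#' @param weighted Use absolute edge weights (default `FALSE`).
#' @return Data.frame: `node`, `domain`, `degree`, `betweenness`,
#'   `closeness`, `eigenvector`.
#' @export
centralities <- function(net, weighted = FALSE) {
  stopifnot(inherits(net, "omics_network"))
  if (nrow(net$nodes) == 0) stop("empty graph")
  g <- igraph::graph_from_data_frame(
    net$edges[, c("u", "v", "weight")], directed = FALSE,
    vertices = net$nodes$id)
  n <- igraph::vcount(g)
  ew <- if (weighted && nrow(net$edges)) abs(net$edges$weight) else NULL
  # igraph interprets NULL as "use the weight attribute"; NA = unweighted
  dist_w <- if (is.null(ew)) NA else 1 / ew
  deg <- if (is.null(ew)) igraph::degree(g) else igraph::strength(g, weights = ew)
  deg_c <- if (n > 1) deg / (n - 1) else deg * 0
  btw <- igraph::betweenness(g, weights = dist_w, normalized = TRUE)
  comp <- igraph::components(g)
  dmat <- igraph::distances(g, weights = dist_w)
  clo <- vapply(seq_len(n), function(i) {
    members <- which(comp$membership == comp$membership[i])
    ni <- length(members)
    if (ni < 2) return(0)
    tot <- sum(dmat[i, members])
    ((ni - 1) / tot) * ((ni - 1) / (n - 1))
  }, numeric(1))
  eig <- if (igraph::ecount(g) == 0) {
    rep(0, n)
  } else {
    igraph::eigen_centrality(g, weights = if (is.null(ew)) NA else ew)$vector
  }
  data.frame(node = igraph::V(g)$name,
             domain = net$nodes$domain[match(igraph::V(g)$name, net$nodes$id)],
             degree = unname(deg_c), betweenness = unname(btw),
             closeness = clo, eigenvector = unname(eig))
}

#' Networks and centralities per storage condition
#'
#' Splits the samples by a metadata factor (typically temperature), builds
#' the requested network type(s) independently per stratum, and profiles
#' node centralities, returning a cross-stratum comparison table. Strata
#' with fewer than 4 samples are skipped with a message.
#'
#' @param tables List of `feature_table`s (raw counts/intensities).
#' @param metadata A `sample_metadata` data.frame covering all samples.
#' @param stratify_by Metadata column to stratify on (default
#'   `"temperature"`).
#' @param method `"cooccurrence"`, `"glasso"` or `"both"`.
#' @param threshold,top_q Passed to [cooccurrence_network()].
#' @param seed Passed to [glasso_network()].
#' @param ... Further arguments to [glasso_network()].
#' @return List with `networks` (per condition, per method) and
#'   `centrality_table` (long data.frame with `condition` and `method`
#'   columns).
#' @export
per_condition_networks <- function(tables, metadata,
                                   stratify_by = "temperature",
                                   method = c("both", "cooccurrence", "glasso"),
                                   threshold = 0.2, top_q = NULL, seed = 1,
                                   ...) {
  method <- match.arg(method)
  if (inherits(tables, "feature_table")) tables <- list(tables)
  md <- align_metadata(metadata, tables[[1L]])
  levels_ <- unique(md[[stratify_by]])
  nets <- list()
  cent <- list()
  for (lev in levels_) {
    sel <- md$sample_id[md[[stratify_by]] == lev]
    if (length(sel) < 4) {
      message("skipping stratum '", lev, "' with ", length(sel), " samples")
      next
    }
    sub <- lapply(tables, ft_subset, samples = sel)
    out <- list()
    if (method %in% c("both", "cooccurrence")) {
      out$cooccurrence <- cooccurrence_network(sub, threshold = threshold,
                                               top_q = top_q,
                                               condition = as.character(lev))
      ct <- centralities(out$cooccurrence)
      ct$condition <- as.character(lev); ct$method <- "cooccurrence"
      cent[[length(cent) + 1L]] <- ct
    }
    if (method %in% c("both", "glasso")) {
      out$glasso <- glasso_network(sub, seed = seed,
                                   condition = as.character(lev), ...)
      ct <- centralities(out$glasso)
      ct$condition <- as.character(lev); ct$method <- "glasso"
      cent[[length(cent) + 1L]] <- ct
    }
    nets[[as.character(lev)]] <- out
  }
  if (!length(nets)) stop("no stratum had enough samples")
  list(networks = nets, centrality_table = do.call(rbind, cent))
}

#' Write a network edge list as TSV
#'
#' @param net An `omics_network`.
#' @param path Output path.
#' @export
write_edge_list <- function(net, path) {
  df <- net$edges
  df$condition <- rep(net$condition, nrow(df))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
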