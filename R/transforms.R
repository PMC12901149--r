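#' Total sum scaling
#'
#' Divides each sample (column) by its total so that relative abundances sum
#' to one per sample.
#'
#' @param t A raw non-negative `feature_table`.
#' @return A `feature_table` tagged `"tss"`.
#' @export
tss_normalize <- function(t) {
  stopifnot(inherits(t, "feature_table"))
  if (any(t$values < 0)) stop("tss_normalize expects a non-negative table")
  tot <- colSums(t$values)
  zero <- tot == 0
  if (any(zero)) {
    stop("all-zero sample(s): ", paste(colnames(t$values)[zero], collapse = ", "))
  }
  feature_table(sweep(t$values, 2L, tot, "/"), t$domain, "tss")
}

#' Per-feature z-score standardisation
#'
#' Each feature (row) is centred and scaled to unit variance across samples.
#' The population standard deviation (divisor n, ddof = 0) is used; constant
#' features are dropped with a message rather than producing NaNs.
#'
#' @param t A `feature_table` with at least two samples.
#' @return A `feature_table` tagged `"zscore"`.
#' @export
zscore_normalize <- function(t) {
  stopifnot(inherits(t, "feature_table"))
  v <- t$values
  if (ncol(v) < 2L) stop("z-scoring needs at least 2 samples")
  mu <- rowMeans(v)
  sdev <- sqrt(rowMeans((v - mu)^2))  # population sd
  keep <- sdev > 0
  if (any(!keep)) {
    message("dropping constant feature(s): ",
            paste(rownames(v)[!keep], collapse = ", "))
  }
  if (!any(keep)) stop("no non-constant features left")
  z <- (v[keep, , drop = FALSE] - mu[keep]) / sdev[keep]
  feature_table(z, t$domain[keep], "zscore")
}

#' Shifted log transform
#'
#' Elementwise `log(x + pseudo)` (natural log).
#'
#' @param t A non-negative `feature_table`.
#' @param pseudo Pseudocount added before the log; must be positive when the
#'   table contains zeros.
#' @return A `feature_table` tagged `"log"`.
#' @export
log_transform <- function(t, pseudo = 1) {
  stopifnot(inherits(t, "feature_table"))
  if (any(t$values < 0)) stop("log_transform expects a non-negative table")
  if (pseudo <= 0 && any(t$values == 0)) {
    stop("pseudo must be > 0 when the table contains zeros")
  }
  feature_table(log(t$values + pseudo), t$domain, "log")
}

#' Multiplicative zero replacement
#'
#' Replaces zeros in a composition with a small `delta` and rescales the
#' non-zero parts so every sample still sums to one; the standard
#' zero-handling step before a log-ratio transform. Raw count tables are
#' TSS-normalised first.
#'
#' @param t A `feature_table` (raw counts or tss).
#' @param delta Replacement value for zeros (default `1e-8`).
#' @return A strictly positive `feature_table` tagged `"tss"`.
#' @export
multiplicative_replacement <- function(t, delta = 1e-8) {
  stopifnot(inherits(t, "feature_table"))
  if (delta <= 0) stop("delta must be positive")
  if (t$transform == "raw") t <- tss_normalize(t)
  if (t$transform != "tss") stop("multiplicative replacement needs a compositional table")
  v <- t$values
  nzero <- colSums(v == 0)
  if (any(delta * nzero >= 1)) {
    stop("delta * number-of-zeros >= 1 for sample(s): ",
         paste(colnames(v)[delta * nzero >= 1], collapse = ", "))
  }
  out <- sweep(v, 2L, 1 - delta * nzero, "*")
  out[v == 0] <- delta
  # renormalise away accumulated floating-point drift
  out <- sweep(out, 2L, colSums(out), "/")
  feature_table(out, t$domain, "tss")
}

#' Centred log-ratio transform
#'
#' Per sample, `log(x_i / geometric mean(x))`; maps strictly positive
#' compositions into unconstrained real space with per-sample sums of zero.
#' Zeros must be handled first via [multiplicative_replacement()].
#'
#' @param t A strictly positive `feature_table`.
#' @return A `feature_table` tagged `"clr"`.
#' @export
clr_transform <- function(t) {
  stopifnot(inherits(t, "feature_table"))
  if (any(t$values <= 0)) {
    stop("clr_transform needs strictly positive values; apply multiplicative_replacement() first")
  }
  lv <- log(t$values)
  clr <- sweep(lv, 2L, colMeans(lv), "-")
  feature_table(clr, t$domain, "clr")
}

#' Prevalence filter
#'
#' Removes features detected (value > 0) in fewer than `min_prevalence`
#' samples.
#'
#' @param t A raw `feature_table`.
#' @param min_prevalence Minimum number of samples with a non-zero value
#'   (default 3, one replicate triplet).
#' @return A filtered `feature_table`; the dropped ids are attached as
#'   attribute `"dropped"`.
#' @export
prevalence_filter <- function(t, min_prevalence = 3) {
  stopifnot(inherits(t, "feature_table"))
  prev <- rowSums(t$values > 0)
  keep <- prev >= min_prevalence
  if (!any(keep)) stop("prevalence filter removed every feature")
  out <- feature_table(t$values[keep, , drop = FALSE], t$domain[keep], t$transform)
  attr(out, "dropped") <- rownames(t$values)[!keep]
  out
}

#' Rarefy counts to even depth
#'
#' Subsamples each sample's reads without replacement to a common depth
#' (single draw per sample). Samples whose total is below the depth are
#' dropped; their ids are recorded in the `"dropped"` attribute.
#'
#' @param t A `feature_table` of integer counts.
#' @param depth Target reads per sample (> 0).
#' @param seed Integer seed; the same seed reproduces the draw exactly.
#' @return A rarefied `feature_table` whose column sums all equal `depth`.
#' @export
rarefy <- function(t, depth, seed = 1) {
  stopifnot(inherits(t, "feature_table"))
  if (depth <= 0) stop("depth must be positive")
  v <- t$values
  if (max(abs(v - round(v))) > 1e-8) stop("rarefy needs integer counts")
  v <- round(v)
  keep <- colSums(v) >= depth
  if (!any(keep)) stop("no sample reaches the rarefaction depth")
  dropped <- colnames(v)[!keep]
  if (length(dropped)) {
    message("dropping sample(s) below depth ", depth, ": ",
            paste(dropped, collapse = ", "))
  }
  v <- v[, keep, drop = FALSE]
  set.seed(seed)
  # inputs are validated above; rrarefy's smallest-count>1 heuristic warning
  # does not apply
  rar <- t(suppressWarnings(vegan::rrarefy(t(v), sample = depth)))
  out <- feature_table(rar, t$domain, "raw")
  attr(out, "dropped") <- dropped
  out
}

#' Scale relative abundances to absolute cell counts via qPCR totals
#'
#' Converts per-sample DNA concentrations into total cell-equivalents using a
#' marker-gene copy model (copies per ng of DNA divided by copies per cell)
#' and distributes the total over taxa by their relative abundance.
#'
#' @param rel A `feature_table` of per-sample relative abundances (tss).
#' @param dna_conc Per-sample DNA concentration in ng/uL (named or aligned).
#' @param copies_per_cell Marker copies per cell (default 5, a typical 16S
#'   rRNA operon count for lactic acid bacteria).
#' @param copies_per_ng Marker copies per ng of DNA (default 1.58e9).
#' @return A `feature_table` of absolute abundances; column sums equal
#'   `dna_conc * copies_per_ng / copies_per_cell`.
#' @export
absolute_abundance <- function(rel, dna_conc, copies_per_cell = 5,
                               copies_per_ng = 1.58e9) {
  stopifnot(inherits(rel, "feature_table"))
  if (rel$transform != "tss") rel <- tss_normalize(rel)
  if (!is.null(names(dna_conc))) dna_conc <- dna_conc[sample_ids(rel)]
  if (length(dna_conc) != ncol(rel$values) || anyNA(dna_conc)) {
    stop("dna_conc must provide one value per sample")
  }
  if (any(dna_conc < 0)) stop("negative DNA concentration")
  total <- dna_conc * copies_per_ng / copies_per_cell
  feature_table(sweep(rel$values, 2L, total, "*"), rel$domain, "raw")
}
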