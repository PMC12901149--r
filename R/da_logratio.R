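#' Read a differential-abundance result table
#'
#' The documented contract for externally computed differential-abundance
#' results (e.g. bias-corrected compositional models run elsewhere): a TSV
#' with columns `taxon`, `condition`, `logFC`, `q`.
#'
#' @param path TSV path.
#' @return Data.frame of class `da_result`.
#' @export
read_da_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("taxon", "condition", "logFC", "q")
  if (!all(need %in% names(df))) {
    stop("DA table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(df$q < 0 | df$q > 1, na.rm = TRUE)) stop("q must lie in [0, 1]")
  class(df) <- c("da_result", "data.frame")
  df
}

#' Classify taxa as enriched or outcompeted
#'
#' Taxa whose (condition-averaged) log-fold change exceeds `threshold` are
#' enriched; below `-threshold`, outcompeted; others stay unassigned.
#' Typical thresholds are 0.75 for bacterial (16S) and 0.1 for fungal (ITS)
#' tables.
#'
#' @param da A `da_result` data.frame (`taxon`, `condition`, `logFC`, `q`).
#' @param threshold Positive log-fold-change threshold.
#' @param conditions Optional subset of conditions to average over (default:
#'   all non-reference conditions, i.e. rows with non-zero logFC or q given).
#' @return List with `enriched` and `outcompeted` character vectors; taxa in
#'   neither set are unassigned.
#' @export
classify_enriched_outcompeted <- function(da, threshold, conditions = NULL) {
  if (threshold <= 0) stop("threshold must be positive")
  df <- as.data.frame(da)
  if (!is.null(conditions)) df <- df[df$condition %in% conditions, , drop = FALSE]
  lfc <- tapply(df$logFC, df$taxon, mean)
  list(enriched = names(lfc)[lfc > threshold],
       outcompeted = names(lfc)[lfc < -threshold])
}

#' Sample-wise enriched/outcompeted log-ratio
#'
#' Per sample, the natural log of the geometric mean abundance of the
#' enriched taxa over the geometric mean of the outcompeted taxa - a single
#' trajectory summarising community turnover.
#'
#' @param t A non-negative `feature_table`.
#' @param enriched,outcompeted Disjoint, non-empty feature-id sets.
#' @param pseudo Pseudocount applied to zeros inside the geometric means;
#'   default half the smallest non-zero value in the table.
#' @param zero_handling `"pseudocount"` (default) or `"drop"` (zero taxa are
#'   removed from their geometric mean; samples where a whole set is zero
#'   give `NA` with a warning).
#' @return Named per-sample numeric vector.
#' @export
sample_logratio <- function(t, enriched, outcompeted, pseudo = NULL,
                            zero_handling = c("pseudocount", "drop")) {
  stopifnot(inherits(t, "feature_table"))
  zero_handling <- match.arg(zero_handling)
  if (length(intersect(enriched, outcompeted))) {
    stop("enriched and outcompeted sets overlap")
  }
  if (!length(enriched) || !length(outcompeted)) {
    stop("both enriched and outcompeted sets must be non-empty")
  }
  miss <- setdiff(c(enriched, outcompeted), feature_ids(t))
  if (length(miss)) stop("unknown taxa: ", paste(miss, collapse = ", "))
  v <- t$values
  if (any(v < 0)) stop("needs non-negative abundances")
  if (is.null(pseudo)) {
    nz <- v[v > 0]
    if (!length(nz)) stop("table is all zero")
    pseudo <- min(nz) / 2
  }
  gm <- function(rows, j) {
    x <- v[rows, j]
    if (zero_handling == "pseudocount") {
      x[x == 0] <- pseudo
    } else {
      x <- x[x > 0]
      if (!length(x)) return(NA_real_)
    }
    mean(log(x))
  }
  out <- vapply(seq_len(ncol(v)), function(j) {
    gm(enriched, j) - gm(outcompeted, j)
  }, numeric(1))
  if (anyNA(out)) {
    warning("log-ratio undefined (whole set zero) for sample(s): ",
            paste(colnames(v)[is.na(out)], collapse = ", "))
  }
  stats::setNames(out, colnames(v))
}

#' Naive CLR-difference differential abundance
#'
#' A transparent stand-in estimator with the same output contract as
#' [read_da_table()]: per taxon and condition (temperature x day cell), the
#' log-fold change is the mean CLR difference versus the reference
#' condition, with Welch-test p-values corrected by Benjamini-Hochberg over
#' the whole table. It performs no bias correction and is clearly labelled
#' as such in its `estimator` attribute.
#'
#' @param t A raw `feature_table` of counts.
#' @param metadata A `sample_metadata`.
#' @param reference Named list/vector with the reference `day` and
#'   `temperature` (default day 1 at 4 degC).
#' @param delta Multiplicative-replacement delta before CLR.
#' @return A `da_result` data.frame; reference-condition rows carry
#'   logFC = 0.
#' @export
naive_clr_da <- function(t, metadata, reference = c(day = 1, temperature = 4),
                         delta = 1e-8) {
  stopifnot(inherits(t, "feature_table"))
  md <- align_metadata(metadata, t)
  cond <- sprintf("T%g_D%d", md$temperature, md$day)
  ref_label <- sprintf("T%g_D%d", reference[["temperature"]], reference[["day"]])
  ref_idx <- which(cond == ref_label)
  if (length(ref_idx) < 2) stop("reference condition missing or has <2 replicates")
  clr <- clr_transform(multiplicative_replacement(tss_normalize(t), delta))$values
  taxa <- rownames(clr)
  rows <- list()
  for (cc in unique(cond)) {
    idx <- which(cond == cc)
    for (tx in taxa) {
      if (cc == ref_label) {
        rows[[length(rows) + 1L]] <- data.frame(
          taxon = tx, condition = cc, logFC = 0, p = NA_real_)
      } else {
        a <- clr[tx, idx]; b <- clr[tx, ref_idx]
        p <- if (length(a) >= 2 && stats::sd(c(a, b)) > 0) {
          tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
        } else 1
        rows[[length(rows) + 1L]] <- data.frame(
          taxon = tx, condition = cc, logFC = mean(a) - mean(b), p = p)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  est <- !is.na(out$p)
  out$q[est] <- stats::p.adjust(out$p[est], method = "BH")
  out$p <- NULL
  attr(out, "estimator") <- "naive-clr (no bias correction)"
  class(out) <- c("da_result", "data.frame")
  out
}
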