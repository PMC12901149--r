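#' Construct a feature table
#'
#' A `feature_table` holds a features x samples matrix of abundances together
#' with a per-feature domain tag and a transform tag recording which
#' normalisation has been applied. Raw tables must be non-negative; transformed
#' tables (`clr`, `zscore`, `log`) may contain negative values.
#'
#' @param values Numeric matrix, features in rows, samples in columns. Row and
#'   column names are used as feature and sample identifiers and must be
#'   unique and non-empty.
#' @param domain Per-feature domain tag, one of `"bacteria"`, `"fungi"`,
#'   `"metabolite"`, `"covariate"`. A single value is recycled.
#' @param transform Transform tag, one of `"raw"`, `"tss"`, `"log"`,
#'   `"zscore"`, `"clr"`.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, domain = "bacteria", transform = "raw") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (features x samples)")
  }
  if (nrow(values) == 0L) stop("no features")
  if (ncol(values) == 0L) stop("no samples")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have feature row names and sample column names")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  }
  if (any(!is.finite(values))) stop("all values must be finite")
  domain <- match.arg(domain, c("bacteria", "fungi", "metabolite", "covariate"),
                      several.ok = TRUE)
  if (length(domain) == 1L) domain <- rep(domain, nrow(values))
  if (length(domain) != nrow(values)) {
    stop("`domain` must have length 1 or nrow(values)")
  }
  transform <- match.arg(transform, c("raw", "tss", "log", "zscore", "clr"))
  if (transform %in% c("raw", "tss") && any(values < 0)) {
    stop("raw/tss feature tables must be non-negative")
  }
  if (transform == "clr") {
    colsum <- colSums(values)
    if (any(abs(colsum) >= 1e-8 * nrow(values))) {
      stop("clr-tagged table has per-sample sums away from zero")
    }
  }
  structure(
    list(values = values, domain = domain, transform = transform),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d samples [%s, domains: %s]\n",
              nrow(x$values), ncol(x$values), x$transform,
              paste(names(table(x$domain)), collapse = "/")))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Feature and sample identifiers
#' @param t A `feature_table`.
#' @return Character vector of ids.
#' @export
feature_ids <- function(t) rownames(t$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(t) colnames(t$values)

#' Subset a feature table
#'
#' @param t A `feature_table`.
#' @param features,samples Character ids or indices; `NULL` keeps all.
#' @return A `feature_table`.
#' @export
ft_subset <- function(t, features = NULL, samples = NULL) {
  v <- t$values
  dom <- t$domain
  if (!is.null(features)) {
    idx <- if (is.character(features)) match(features, rownames(v)) else features
    if (anyNA(idx)) stop("unknown feature id(s)")
    v <- v[idx, , drop = FALSE]
    dom <- dom[idx]
  }
  if (!is.null(samples)) {
    idx <- if (is.character(samples)) match(samples, colnames(v)) else samples
    if (anyNA(idx)) stop("unknown sample id(s)")
    v <- v[, idx, drop = FALSE]
  }
  feature_table(v, dom, t$transform)
}

#' Read a feature table from TSV/CSV
#'
#' First column holds feature ids, header holds sample ids. Lines starting
#' with `#` are ignored. Missing values (`NA` cells) are rejected for
#' bacteria/fungi/covariate tables; for metabolite tables they are imputed as
#' zeros at read time, mirroring common untargeted-MS practice.
#'
#' @param path File path; delimiter inferred from the extension
#'   (`.csv` = comma, otherwise tab).
#' @param domain Domain tag (single value or per-feature vector).
#' @param transform Transform tag of the stored table (default `"raw"`).
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path, domain = "bacteria", transform = "raw") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0L || ncol(df) < 2L) stop("no features")
  ids <- df[[1L]]
  cells <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells),
                                 dimnames = dimnames(cells)))
  bad <- which(is.na(num) & !(is.na(cells) | cells %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric cell at feature '%s', sample '%s': '%s'",
                 ids[bad[1L, 1L]], colnames(cells)[bad[1L, 2L]],
                 cells[bad[1L, 1L], bad[1L, 2L]]))
  }
  miss <- which(is.na(num), arr.ind = TRUE)
  if (nrow(miss) > 0L) {
    if (all(domain == "metabolite")) {
      num[is.na(num)] <- 0
    } else {
      stop(sprintf("missing value at feature '%s', sample '%s'",
                   ids[miss[1L, 1L]], colnames(num)[miss[1L, 2L]]))
    }
  }
  rownames(num) <- ids
  feature_table(num, domain = domain, transform = transform)
}

#' Write a feature table as TSV
#'
#' Round-trips with [read_feature_table()]: full-precision values, feature ids
#' in the first column (`feature_id`), sample ids in the header.
#'
#' @param t A `feature_table`.
#' @param path Output path.
#' @export
write_feature_table <- function(t, path) {
  df <- data.frame(feature_id = rownames(t$values),
                   format(t$values, digits = 17, trim = TRUE, scientific = NA),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assign the storage phase for a sampling day
#'
#' Days 1-4 are phase 1 (early), 5-10 phase 2 (mid), 14 onwards phase 3
#' (late storage). The phase-3 lower bound is configurable because sampled
#' days jump from 10 to 14.
#'
#' @param day Integer day(s) of storage.
#' @param phase3_from First day of phase 3 (default 14).
#' @return Integer phase in `{1, 2, 3}`.
#' @export
phase_bin <- function(day, phase3_from = 14) {
  day <- as.integer(day)
  if (anyNA(day) || any(day < 1)) stop("unknown day")
  ifelse(day <= 4, 1L, ifelse(day <= 10, 2L, ifelse(day >= phase3_from, 3L, NA_integer_))) ->
    ph
  if (anyNA(ph)) stop("unknown day: ", paste(day[is.na(ph)], collapse = ", "))
  ph
}

#' Construct per-sample metadata
#'
#' @param sample_id Unique sample identifiers.
#' @param temperature Storage temperature in deg C (typically 4, 17 or 30).
#' @param day Storage day.
#' @param replicate Replicate number (>= 1).
#' @param covariates Optional data.frame of per-sample physicochemical
#'   measurements (pH, TTA, CFU, sugar/acid concentrations, dna_conc).
#' @return A data.frame with class `sample_metadata`; a `phase` column is
#'   derived from `day` via [phase_bin()].
#' @export
sample_metadata <- function(sample_id, temperature, day, replicate,
                            covariates = NULL) {
  if (anyDuplicated(sample_id)) stop("duplicate sample ids in metadata")
  md <- data.frame(sample_id = as.character(sample_id),
                   temperature = as.numeric(temperature),
                   day = as.integer(day),
                   replicate = as.integer(replicate),
                   stringsAsFactors = FALSE)
  md$phase <- phase_bin(md$day)
  if (!is.null(covariates)) {
    if (nrow(covariates) != nrow(md)) stop("covariates must align with samples")
    if (anyNA(covariates)) stop("missing values in metadata covariates")
    md <- cbind(md, covariates)
  }
  class(md) <- c("sample_metadata", "data.frame")
  md
}

#' Align metadata rows to a feature table's samples
#'
#' @param md A `sample_metadata` data.frame.
#' @param t A `feature_table` (or character vector of sample ids).
#' @return Metadata reordered to the table's samples; errors if any sample
#'   lacks metadata.
#' @export
align_metadata <- function(md, t) {
  ids <- if (inherits(t, "feature_table")) sample_ids(t) else as.character(t)
  idx <- match(ids, md$sample_id)
  if (anyNA(idx)) {
    stop("samples without metadata: ", paste(ids[is.na(idx)], collapse = ", "))
  }
  out <- md[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Validate and construct a sample-sample distance matrix
#'
#' @param values Square numeric matrix with matching dimnames, symmetric
#'   within 1e-12, zero diagonal, non-negative.
#' @return A matrix of class `distance_matrix`.
#' @export
distance_matrix <- function(values) {
  if (inherits(values, "dist")) values <- as.matrix(values)
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    stop("distance matrix must be square")
  }
  if (is.null(rownames(values))) stop("distance matrix needs sample ids")
  if (max(abs(values - t(values))) > 1e-12) stop("distance matrix not symmetric")
  if (any(diag(values) != 0)) stop("distance matrix diagonal must be zero")
  if (any(values < 0)) stop("distances must be non-negative")
  colnames(values) <- rownames(values)
  class(values) <- c("distance_matrix", "matrix")
  values
}

#' Pairwise-correlation matrix with hierarchical leaf ordering
#'
#' Pearson correlations between variables, hierarchically clustered
#' (average linkage on `1 - r`) so that correlated variables are adjacent;
#' the substrate of correlation heat maps.
#'
#' @param vars Data.frame or matrix, samples in rows, variables in columns.
#' @return List with `correlation` (reordered r matrix), `order` (leaf order
#'   as variable names) and `hclust` (the dendrogram object).
#' @export
correlation_matrix_clustered <- function(vars) {
  m <- as.matrix(vars)
  if (nrow(m) < 3L) stop("need at least 3 samples")
  keep <- apply(m, 2L, function(v) stats::sd(v) > 0)
  if (any(!keep)) {
    message("dropping zero-variance variable(s): ",
            paste(colnames(m)[!keep], collapse = ", "))
    m <- m[, keep, drop = FALSE]
  }
  r <- stats::cor(m)
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  ord <- hc$labels[hc$order]
  list(correlation = r[ord, ord, drop = FALSE], order = ord, hclust = hc)
}
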