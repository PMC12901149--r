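# small deterministic builders used across the suite

make_ft <- function(values, domain = "bacteria", transform = "raw",
                    features = NULL, samples = NULL) {
  if (!is.matrix(values)) values <- matrix(values, nrow = length(values))
  if (is.null(features)) features <- sprintf("f%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(features, samples)
  feature_table(values, domain, transform)
}

# a tiny balanced design: temps x days x reps
make_md <- function(temps = c(4, 17, 30), days = c(1, 5, 14), reps = 2) {
  g <- expand.grid(replicate = seq_len(reps), day = days, temperature = temps,
                   KEEP.OUT.ATTRS = FALSE)
  sample_metadata(sprintf("T%g_D%d_R%d", g$temperature, g$day, g$replicate),
                  g$temperature, g$day, g$replicate)
}

# random strictly positive composition table
random_composition <- function(f, n, seed) {
  set.seed(seed)
  make_ft(matrix(stats::rexp(f * n) + 1e-3, f, n))
}

# random CLR-like vectors
random_clr_vec <- function(n, seed) {
  set.seed(seed)
  stats::rnorm(n, sd = 2)
}

# literal element-by-element implementation of the co-occurrence score,
# kept deliberately naive as the independent oracle
score_loop_oracle <- function(x, y) {
  num <- 0
  den <- 0
  for (i in seq_along(x)) {
    w <- abs(x[i] * y[i])
    num <- num + x[i] * y[i] * w
    den <- den + w
  }
  if (den == 0) 0 else num / den
}

# hand-built network for centrality closed-form checks
new_network_for_test <- function(nodes, edges) {
  structure(list(nodes = data.frame(id = nodes,
                                    domain = rep("bacteria", length(nodes)),
                                    mean_abundance = rep(NA_real_,
                                                         length(nodes))),
                 edges = edges, kind = "cooccurrence",
                 condition = NA_character_),
            class = "omics_network")
}

# Euclidean distance matrix from a point cloud
dist_from_points <- function(P) {
  d <- as.matrix(stats::dist(P))
  rownames(d) <- colnames(d) <- sprintf("s%02d", seq_len(nrow(P)))
  distance_matrix(d)
}
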