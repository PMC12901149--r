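#' Configuration of the synthetic storage experiment
#'
#' Describes a temperature x time x replicate storage design: a small
#' bacterial community with temperature-dependent succession (one cold
#' specialist declining under warm storage, one acetic-acid-bacterium-like
#' warm specialist expanding), a near-monoculture fungal community,
#' metabolite features drawn from three planted temporal archetypes, and
#' physicochemical covariates coupled to the warm-specialist trajectory.
#'
#' @param temperatures Storage temperatures in deg C.
#' @param days Sampling days.
#' @param replicates Replicates per temperature x day cell.
#' @param n_taxa_bact,n_taxa_fungi Number of bacterial / fungal taxa (>= 2).
#' @param n_metabolites Number of metabolite features.
#' @param cluster_proportions Proportions of the three metabolite archetypes;
#'   must sum to 1.
#' @param effect_size Scale of every planted temperature-time effect; 0 makes
#'   all conditions statistically exchangeable.
#' @param noise_sd Gaussian noise sd on the log/linear-predictor scale.
#' @param depth_bact,depth_fungi Multinomial sequencing depths for the count
#'   tables (defaults 380 and 3500 reads per sample).
#' @param seed Integer seed; all randomness flows through it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(temperatures = c(4, 17, 30),
                              days = c(1:7, 10, 14, 21, 28),
                              replicates = 3,
                              n_taxa_bact = 5,
                              n_taxa_fungi = 5,
                              n_metabolites = 150,
                              cluster_proportions = c(1, 1, 1) / 3,
                              effect_size = 1,
                              noise_sd = 0.5,
                              depth_bact = 380,
                              depth_fungi = 3500,
                              seed = 1) {
  stopifnot(length(temperatures) >= 1, length(days) >= 1, replicates >= 1,
            n_taxa_bact >= 2, n_taxa_fungi >= 2, n_metabolites >= 3,
            effect_size >= 0, noise_sd > 0, depth_bact >= 1, depth_fungi >= 1)
  if (length(cluster_proportions) != 3 ||
      abs(sum(cluster_proportions) - 1) > 1e-9) {
    stop("cluster_proportions must be 3 values summing to 1")
  }
  structure(as.list(environment()), class = "simulation_config")
}

softmax_cols <- function(eta) {
  e <- exp(sweep(eta, 2L, apply(eta, 2L, max), "-"))
  sweep(e, 2L, colSums(e), "/")
}

# archetype mean curves on the z-score scale; warm01 in [0,1] maps the
# temperature range, day in storage days
archetype_mean <- function(cluster, warm01, day) {
  switch(as.character(cluster),
    "0" = 2 * warm01 * day / 28,
    "1" = 2 * warm01 * exp(-((day - (25 - 18 * warm01))^2) / (2 * 4^2)) -
          (1 - warm01) * day / 28,
    "2" = -2 * warm01 * day / 28 +
          0.3 * (1 - warm01) * exp(-((day - 3)^2) / (2 * 3^2)),
    stop("unknown archetype"))
}

#' Simulate the full storage experiment
#'
#' Generates bacterial and fungal count tables (multinomial sampling of
#' softmax-of-linear-predictor compositions), a metabolite intensity table
#' drawn from three temporal archetypes, sample metadata with
#' physicochemical covariates, and a ground-truth ledger.
#'
#' The bacterial linear predictor for taxon k is
#' `b_k + r_k * day * g(T) * effect_size` with the warmth ramp `g(T)` scaled
#' to \[0, 1\] over the temperature range: at the coldest temperature the
#' community is static (cold storage preserves it), while under warm storage
#' the taxon with strongly negative `r` declines (cold specialist) and the
#' one with strongly positive `r` expands (warm specialist), reproducing the
#' succession crossover.
#'
#' @param cfg A [simulation_config()].
#' @return List with elements `bacteria`, `fungi`, `metabolites`
#'   (`feature_table`s), `metadata` (`sample_metadata`) and `truth`
#'   (ground-truth ledger: taxon trajectory parameters, metabolite cluster
#'   labels, per-cluster phase effects).
#' @export
simulate_experiment <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  design <- expand.grid(replicate = seq_len(cfg$replicates),
                        day = cfg$days,
                        temperature = cfg$temperatures,
                        KEEP.OUT.ATTRS = FALSE)
  n <- nrow(design)
  ids <- sprintf("T%g_D%d_R%d", design$temperature, design$day, design$replicate)
  t_rng <- range(cfg$temperatures)
  # warmth ramp g(T) in [0, 1]: dynamics vanish at the coldest temperature
  # (cold storage preserves the community) and scale up with warmth
  warm01 <- if (diff(t_rng) > 0) {
    (design$temperature - t_rng[1]) / diff(t_rng)
  } else rep(0.5, n)
  g <- warm01

  ## bacteria: cold specialist, warm specialist, subdominants
  nb <- cfg$n_taxa_bact
  b_base <- c(3, -1, rep(0, max(0, nb - 2)))[seq_len(nb)]
  b_rate <- c(-0.12, 0.22, 0.05, 0.03, 0)[seq_len(min(nb, 5))]
  if (nb > 5) b_rate <- c(b_rate, rep(0, nb - 5))
  bact_names <- c("bact_cold_specialist", "bact_warm_specialist",
                  paste0("bact_sub", seq_len(max(0, nb - 2))))[seq_len(nb)]
  eta_b <- outer(b_base, rep(1, n)) +
    cfg$effect_size * outer(b_rate, design$day * g, "*") +
    matrix(stats::rnorm(nb * n, sd = cfg$noise_sd), nb, n)
  p_bact <- softmax_cols(eta_b)
  bact <- sapply(seq_len(n), function(j) {
    stats::rmultinom(1, cfg$depth_bact, p_bact[, j])
  })
  dimnames(bact) <- list(bact_names, ids)

  ## fungi: near-monoculture, weak temperature response of subdominants
  nf <- cfg$n_taxa_fungi
  f_base <- c(6, rep(0, nf - 1))
  f_rate <- c(0, 0.02, 0.01, 0, -0.01)[seq_len(min(nf, 5))]
  if (nf > 5) f_rate <- c(f_rate, rep(0, nf - 5))
  fungi_names <- c("fungi_dominant", paste0("fungi_sub", seq_len(nf - 1)))
  eta_f <- outer(f_base, rep(1, n)) +
    cfg$effect_size * outer(f_rate, design$day * g, "*") +
    matrix(stats::rnorm(nf * n, sd = cfg$noise_sd), nf, n)
  p_fun <- softmax_cols(eta_f)
  fung <- sapply(seq_len(n), function(j) {
    stats::rmultinom(1, cfg$depth_fungi, p_fun[, j])
  })
  dimnames(fung) <- list(fungi_names, ids)

  ## metabolites: three planted archetypes on the log-intensity scale
  nm <- cfg$n_metabolites
  cl_sizes <- diff(round(cumsum(c(0, cfg$cluster_proportions)) * nm))
  cl_sizes[3] <- nm - sum(cl_sizes[1:2])
  met_cluster <- rep(0:2, times = cl_sizes)
  met_names <- sprintf("met_%03d_c%d", seq_len(nm), met_cluster)
  base_f <- stats::rnorm(nm, mean = 8, sd = 1)
  scale_f <- stats::runif(nm, 0.8, 1.2)
  mu <- matrix(0, nm, n)
  for (cl in 0:2) {
    rows <- which(met_cluster == cl)
    if (length(rows)) {
      curve <- archetype_mean(cl, warm01, design$day)
      mu[rows, ] <- outer(scale_f[rows], cfg$effect_size * curve, "*")
    }
  }
  log_int <- base_f + mu + matrix(stats::rnorm(nm * n, sd = cfg$noise_sd), nm, n)
  met <- exp(log_int)
  dimnames(met) <- list(met_names, ids)

  ## covariates coupled to the expected warm-specialist share
  w <- softmax_cols(outer(b_base, rep(1, n)) +
                      cfg$effect_size * outer(b_rate, design$day * g, "*"))[2, ]
  es <- cfg$effect_size
  nz <- function(s) stats::rnorm(n, sd = s)
  cov_df <- data.frame(
    pH          = 4.0 - es * (0.9 * w + 0.2 * design$day / 28) + nz(0.05),
    TTA         = 8 + es * (12 * w + 2 * design$day / 28) + nz(0.3),
    CFU         = 10^(9 - es * 1.5 * w + nz(0.15)),
    maltose     = pmax(0.05, 20 * (1 - es * 0.8 * warm01 * design$day / 28) + nz(0.5)),
    glucose     = pmax(0.05, 6 * (1 - es * 0.7 * warm01 * design$day / 28) + nz(0.3)),
    sucrose     = pmax(0.05, 3 * (1 - es * 0.5 * warm01 * design$day / 28) + nz(0.2)),
    ethanol     = pmax(0.05, 2 + es * (1 - warm01) * design$day / 28 + nz(0.1)),
    acetic_acid = pmax(0.01, 0.3 + es * 4 * w + nz(0.1)),
    lactic_acid = pmax(0.01, 5 + es * 3 * design$day / 28 + nz(0.2)),
    dna_conc    = exp(stats::rnorm(n, mean = 0, sd = 0.3))
  )

  md <- sample_metadata(ids, design$temperature, design$day, design$replicate,
                        covariates = cov_df)

  phase_effects <- do.call(rbind, lapply(0:2, function(cl) {
    do.call(rbind, lapply(unique(design$temperature), function(tt) {
      w01 <- if (diff(t_rng) > 0) (tt - t_rng[1]) / diff(t_rng) else 0.5
      data.frame(cluster = cl, temperature = tt, phase = 1:3,
                 mean_shift = sapply(1:3, function(ph) {
                   dd <- cfg$days[phase_bin(cfg$days) == ph]
                   if (!length(dd)) return(NA_real_)
                   mean(cfg$effect_size * archetype_mean(cl, w01, dd))
                 }))
    }))
  }))

  truth <- list(
    taxon_trajectories = data.frame(
      taxon = c(bact_names, fungi_names),
      domain = rep(c("bacteria", "fungi"), c(nb, nf)),
      baseline = c(b_base, f_base),
      rate = c(b_rate, f_rate),
      role = c(c("cold_specialist", "warm_specialist",
                 rep("subdominant", nb - 2)),
               c("dominant", rep("subdominant", nf - 1)))),
    metabolite_cluster = stats::setNames(met_cluster, met_names),
    planted_edges = NULL,
    phase_effects = phase_effects
  )

  list(
    bacteria = feature_table(bact, "bacteria", "raw"),
    fungi = feature_table(fung, "fungi", "raw"),
    metabolites = feature_table(met, "metabolite", "raw"),
    metadata = md,
    truth = truth
  )
}

#' Simulate a null dataset with exchangeable group labels
#'
#' Features are i.i.d. lognormal intensities carrying no group effect; the
#' attached metadata assigns balanced temperature and day labels so that any
#' test run against them is calibrated under its null.
#'
#' @param n_samples Number of samples (must be divisible by
#'   `n_groups * n_days`).
#' @param n_features Number of features.
#' @param seed Integer seed.
#' @param n_groups Number of temperature levels (default 3).
#' @param n_days Number of day levels (default 5).
#' @return List with `table` (a `feature_table`) and `metadata`.
#' @export
simulate_null_dataset <- function(n_samples = 30, n_features = 20, seed = 1,
                                  n_groups = 3, n_days = 5) {
  if (n_samples < 6) stop("need at least 6 samples")
  if (n_samples %% (n_groups * n_days) != 0) {
    stop("n_samples must be divisible by n_groups * n_days for balance")
  }
  set.seed(seed)
  reps <- n_samples / (n_groups * n_days)
  design <- expand.grid(replicate = seq_len(reps),
                        temperature = c(4, 17, 30, 10, 22, 37)[seq_len(n_groups)],
                        day = seq_len(n_days), KEEP.OUT.ATTRS = FALSE)
  ids <- sprintf("N%03d", seq_len(n_samples))
  v <- matrix(exp(stats::rnorm(n_features * n_samples)), n_features, n_samples,
              dimnames = list(sprintf("feat_%03d", seq_len(n_features)), ids))
  md <- sample_metadata(ids, design$temperature, design$day, design$replicate)
  list(table = feature_table(v, "metabolite", "raw"), metadata = md)
}

#' Simulate multivariate-normal data with a planted sparse precision matrix
#'
#' Builds a symmetric positive-definite precision matrix by diagonal
#' dominance (each off-diagonal pair is an edge with probability `sparsity`,
#' magnitude 0.3-0.6, random sign; the diagonal is 1 plus the absolute row
#' sum), then draws samples from the corresponding multivariate normal. The
#' non-zero off-diagonal entries are the ground-truth conditional-dependence
#' edges.
#'
#' @param p_nodes Number of variables.
#' @param n_samples Number of samples.
#' @param sparsity Probability that a pair is connected.
#' @param seed Integer seed.
#' @return List with `table` (a `feature_table`, variables as features),
#'   `precision` (the planted matrix) and `edges` (data.frame `u`, `v`,
#'   `sign` of the planted edges, u < v).
#' @export
simulate_network_dataset <- function(p_nodes = 20, n_samples = 500,
                                     sparsity = 0.1, seed = 1) {
  stopifnot(p_nodes >= 2, n_samples >= 2, sparsity >= 0, sparsity <= 1)
  set.seed(seed)
  P <- matrix(0, p_nodes, p_nodes)
  ut <- which(upper.tri(P), arr.ind = TRUE)
  on <- stats::runif(nrow(ut)) < sparsity
  val <- stats::runif(nrow(ut), 0.3, 0.6) * sample(c(-1, 1), nrow(ut), TRUE) * on
  P[ut] <- val
  P <- P + t(P)
  diag(P) <- 1 + rowSums(abs(P))  # strict diagonal dominance => PD
  Sigma <- solve(P)
  L <- chol(Sigma)
  X <- matrix(stats::rnorm(n_samples * p_nodes), n_samples, p_nodes) %*% L
  nodes <- sprintf("node_%02d", seq_len(p_nodes))
  dimnames(P) <- list(nodes, nodes)
  v <- t(X)
  dimnames(v) <- list(nodes, sprintf("S%04d", seq_len(n_samples)))
  edges <- data.frame(u = nodes[ut[on, 1]], v = nodes[ut[on, 2]],
                      sign = sign(val[on]))
  # canonical u < v order
  swap <- edges$u > edges$v
  tmp <- edges$u[swap]; edges$u[swap] <- edges$v[swap]; edges$v[swap] <- tmp
  list(table = feature_table(v, "metabolite", "zscore"),
       precision = P, edges = edges)
}
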