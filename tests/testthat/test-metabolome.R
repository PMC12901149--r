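test_that("the responsiveness filter keeps planted dynamics and obeys alpha", {
  sim <- simulate_experiment(simulation_config(seed = 8))
  mz <- zscore_normalize(prevalence_filter(sim$metabolites))
  filt <- anova_responsiveness_filter(mz, sim$metadata)
  truth <- sim$truth$metabolite_cluster
  # the planted mid-phase surge features (archetype 1) are almost all kept
  kept1 <- mean(names(truth)[truth == 1] %in% feature_ids(filt))
  expect_gte(kept1, 0.95)
  # alpha = 1 keeps everything
  all_kept <- anova_responsiveness_filter(mz, sim$metadata, alpha = 1)
  expect_identical(feature_ids(all_kept), feature_ids(mz))
  # a temperature group with a single time point is skipped, not fatal
  md1 <- sim$metadata
  one_tp <- md1$temperature != 4 | md1$day == 1
  sub <- ft_subset(mz, samples = md1$sample_id[one_tp])
  expect_message(anova_responsiveness_filter(sub, md1[one_tp, ]),
                 "one time point")
})

test_that("select_k finds three well-separated archetypes", {
  # three duplicated template trajectories with tiny jitter: silhouette ~ 1
  set.seed(20)
  templates <- matrix(rnorm(3 * 24, sd = 2), 3, 24)
  x <- templates[rep(1:3, each = 10), ] + matrix(rnorm(30 * 24, sd = 0.05), 30)
  ft <- make_ft(x, transform = "zscore")
  res <- select_k(ft, k_range = 2:5, seed = 1, B = 10)
  expect_equal(res$k, 3L)
  expect_gt(res$diagnostics$silhouette[res$diagnostics$k == 3], 0.9)
  expect_true(all(c("silhouette", "elbow", "gap") %in% names(res$votes)))
  expect_error(select_k(make_ft(matrix(rnorm(8), 2, 4), transform = "zscore"),
                        k_range = 2:3), "fewer features")
})

test_that("k-means clustering is deterministic, label-invariant and twin-safe", {
  sim <- simulate_experiment(simulation_config(seed = 9, n_metabolites = 60))
  mz <- zscore_normalize(sim$metabolites)
  cl1 <- cluster_trajectories(mz, 3, seed = 5, metadata = sim$metadata)
  cl2 <- cluster_trajectories(mz, 3, seed = 5)
  expect_identical(cl1$labels, cl2$labels)
  # reordering features only relabels clusters (ARI = 1)
  perm <- sample(seq_len(nrow(mz$values)))
  mzp <- ft_subset(mz, features = perm)
  cl3 <- cluster_trajectories(mzp, 3, seed = 5)
  expect_equal(mclust::adjustedRandIndex(cl1$labels[names(cl3$labels)],
                                         cl3$labels), 1)
  # a duplicated feature always lands with its twin
  dup <- mz
  dup$values <- rbind(dup$values, twin = dup$values[1, ])
  dup$domain <- c(dup$domain, "metabolite")
  rownames(dup$values)[nrow(dup$values)] <- "twin"
  cld <- cluster_trajectories(feature_table(dup$values, dup$domain, "zscore"),
                              3, seed = 5)
  expect_equal(cld$labels[["twin"]], cld$labels[[feature_ids(mz)[1]]])
  # per-cluster curves cover every cluster x temperature x day cell
  expect_equal(nrow(cl1$curves), 3 * 3 * 11)
})

test_that("Kruskal-Wallis tables flag planted temperature effects with BH per cluster", {
  sim <- simulate_experiment(simulation_config(seed = 10))
  mz <- zscore_normalize(sim$metabolites)
  labels <- sim$truth$metabolite_cluster[feature_ids(mz)]
  kw <- kruskal_temperature_tests(mz, labels, sim$metadata)
  expect_true(all(kw$p >= 0 & kw$p <= 1))
  # BH within cluster: q reconstructible from the cluster's p family
  for (cl in unique(kw$cluster)) {
    sel <- kw$cluster == cl
    expect_equal(kw$q[sel], p.adjust(kw$p[sel], "BH"))
  }
  # the rising archetype separates temperatures from mid-storage onwards
  late0 <- kw[kw$cluster == 0 & kw$day >= 14, ]
  expect_true(all(late0$q < 0.05))
  # identical groups sit in the p ~ 1 region
  md <- make_md(days = 1, reps = 3)
  flat <- make_ft(matrix(rep(c(1, 2, 3, 4, 5, 6), times = 9), 6, 9),
                  transform = "zscore", samples = md$sample_id)
  lab <- setNames(rep(0L, 6), feature_ids(flat))
  kw_flat <- kruskal_temperature_tests(flat, lab, md)
  expect_gt(kw_flat$p[1], 0.9)
})

test_that("class enrichment recovers a planted 2x elevation as ln 2", {
  md <- make_md(temps = c(4, 17), days = c(1, 14), reps = 3)
  n <- nrow(md)
  v <- matrix(1, 4, n, dimnames = list(paste0("m", 1:4), md$sample_id))
  cell <- md$temperature == 4 & md$phase == 1
  v[1:2, cell] <- 2   # class A uniformly doubled in condition "4.1"
  ft <- feature_table(v, "metabolite", "tss")
  classes <- setNames(c("A", "A", "B", "B"), rownames(v))
  en <- class_enrichment(ft, md, classes)
  a41 <- en[en$class == "A" & en$condition == "4.1", ]
  gmean <- mean(v[1:2, ])
  expect_equal(a41$enrichment, log(2 / gmean), tolerance = 1e-12)
  # class B is flat everywhere
  expect_true(all(abs(en$enrichment[en$class == "B"]) < 1e-12))
  expect_equal(en$q, p.adjust(en$p, "BH"))
  # a singleton class is skipped
  cl2 <- setNames(c("A", "A", "B", "C"), rownames(v))
  expect_message(class_enrichment(ft, md, cl2), "skipping class 'B'")
})

test_that("mass annotation honours the 0.002 Da window and ranks by distance", {
  hit <- mass_annotate(c(glc = 180.0634))
  expect_setequal(hit$name, c("glucose", "fructose"))  # isobaric pair
  expect_equal(hit$delta, c(0, 0))
  miss <- mass_annotate(c(x = 180.0634 + 0.0021))
  expect_identical(miss$name, "unannotated")
  near <- mass_annotate(c(y = 180.0634 + 0.0015))
  expect_true(all(near$delta <= 0.002))
  # nearest first when several references fall in the window
  two <- mass_annotate(c(z = 131.0946 + 0.001))
  expect_true(all(diff(two$delta) >= 0))
  expect_error(mass_annotate(100, tol = -1), "non-negative")
})

test_that("day-wise ANOVA + Tukey isolates a shifted group and nulls flatten", {
  md <- make_md(temps = c(4, 17, 30), days = c(1, 5), reps = 4)
  set.seed(30)
  y <- rnorm(nrow(md), sd = 1)
  y[md$temperature == 30 & md$day == 5] <- y[md$temperature == 30 & md$day == 5] + 15
  res <- daywise_anova_tukey(setNames(y, md$sample_id), md)
  d5 <- res$table[res$table$day == 5, ]
  expect_lt(d5$anova_p, 0.001)
  tk5 <- res$tukey[res$tukey$day == 5, ]
  expect_true(all(tk5$p_adj[grepl("30", tk5$contrast)] < 0.01))
  expect_gt(tk5$p_adj[tk5$contrast == "17-4"], 0.05)
  # identical group means give p = 1
  yid <- rep(c(1, 2, 3, 4), times = 6)
  res_id <- daywise_anova_tukey(setNames(yid, md$sample_id), md)
  expect_true(all(res_id$table$anova_p > 0.99))
  # single-replicate days are skipped
  md1 <- make_md(days = c(1, 5), reps = 1)
  expect_message(daywise_anova_tukey(setNames(rnorm(6), md1$sample_id), md1),
                 "skipping day")
})
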