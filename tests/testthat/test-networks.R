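test_that("the co-occurrence score matches its closed forms", {
  expect_equal(cooccurrence_score(c(1, 1), c(1, 1)), 1)
  expect_equal(cooccurrence_score(c(1, 1), c(1, -1)), 0)
  # the score is not bounded by 1: a single dominant product carries it
  expect_equal(cooccurrence_score(c(2, 0), c(3, 5)), 6)
  expect_equal(cooccurrence_score(c(0, 0), c(1, 2)), 0)
  expect_error(cooccurrence_score(1:3, 1:2), "equal length")
})

test_that("the vectorised score equals the literal loop oracle", {
  for (s in 1:50) {
    x <- random_clr_vec(20, seed = s)
    y <- random_clr_vec(20, seed = s + 1000)
    expect_equal(cooccurrence_score(x, y), score_loop_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("score symmetry and positive homogeneity hold", {
  for (s in 1:100) {
    x <- random_clr_vec(15, seed = 2000 + s)
    y <- random_clr_vec(15, seed = 3000 + s)
    c_pos <- abs(rnorm(1)) + 0.1
    expect_equal(cooccurrence_score(x, y), cooccurrence_score(y, x),
                 tolerance = 1e-12)
    expect_equal(cooccurrence_score(c_pos * x, y),
                 c_pos * cooccurrence_score(x, y), tolerance = 1e-10)
  }
})

test_that("co-occurrence networks threshold pairs as documented", {
  t1 <- random_composition(6, 12, seed = 41)
  t2 <- random_composition(4, 12, seed = 42)
  t2$domain <- rep("metabolite", 4)
  rownames(t2$values) <- paste0("m", 1:4)
  net_inf <- cooccurrence_network(list(t1, t2), threshold = Inf)
  expect_equal(nrow(net_inf$edges), 0L)
  expect_equal(nrow(net_inf$nodes), 10L)
  net_0 <- cooccurrence_network(list(t1, t2), threshold = 0)
  expect_equal(nrow(net_0$edges), choose(10, 2))
  # canonical order, no self edges
  expect_true(all(net_0$edges$u != net_0$edges$v))
  # rank-based alternative cut
  net_q <- cooccurrence_network(list(t1, t2), top_q = 0.1)
  expect_equal(nrow(net_q$edges), ceiling(0.1 * choose(10, 2)))
  # mismatched samples are reported
  t3 <- ft_subset(t2, samples = 1:10)
  expect_error(cooccurrence_network(list(t1, t3)), "s11")
})

test_that("graphical lasso matches the p = 2 closed form", {
  # for p = 2 the solution soft-thresholds the off-diagonal covariance
  S <- matrix(c(1.3, 0.6, 0.6, 0.9), 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  for (rho in c(0.1, 0.3, 0.5)) {
    fit <- glasso_fit(S, rho)
    expect_equal(fit$w[1, 2], max(0.6 - rho, 0), tolerance = 1e-6)
    W <- matrix(c(1.3 + rho, max(0.6 - rho, 0), max(0.6 - rho, 0), 0.9 + rho), 2)
    expect_equal(unname(fit$theta), solve(W), tolerance = 1e-5)
  }
  # penalty above the largest covariance empties the graph
  fit0 <- glasso_fit(S, 0.61)
  expect_equal(fit0$theta[1, 2], 0)
})

test_that("the glasso edge set shrinks monotonically along the penalty ladder", {
  nd <- simulate_network_dataset(10, 200, sparsity = 0.2, seed = 6)
  X <- t(nd$table$values)
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / nrow(X)
  edges <- sapply(c(0.02, 0.05, 0.1, 0.2, 0.4), function(rho) {
    th <- glasso_fit(S, rho)$theta
    sum(abs(th[upper.tri(th)]) > 1e-8)
  })
  expect_true(all(diff(edges) <= 0))
})

test_that("independent features give a near-empty conditional network", {
  set.seed(13)
  # independent variables straight into the estimator (the CLR closure step
  # would itself induce weak real dependencies)
  fit_ind <- glasso_cv(matrix(rnorm(300 * 10), 300, 10), seed = 1)
  expect_lt(sum(abs(fit_ind$theta[upper.tri(fit_ind$theta)]) > 1e-8), 5)
  # partial correlations: symmetric with unit diagonal
  nd <- simulate_network_dataset(8, 100, 0.2, seed = 2)
  fit <- glasso_cv(t(nd$table$values), seed = 2)
  pc <- partial_correlations(fit$theta)
  expect_equal(pc, t(pc))
  expect_equal(unname(diag(pc)), rep(1, 8))
})

test_that("centralities match textbook closed forms", {
  star <- new_network_for_test(
    nodes = c("c", "l1", "l2", "l3", "l4"),
    edges = data.frame(u = "c", v = c("l1", "l2", "l3", "l4"),
                       weight = 1, kind = "cooccurrence"))
  cs <- centralities(star)
  expect_equal(cs$degree[cs$node == "c"], 1)
  expect_equal(cs$degree[cs$node == "l1"], 0.25)
  expect_equal(cs$betweenness[cs$node == "c"], 1)
  expect_equal(cs$betweenness[cs$node == "l2"], 0)
  expect_equal(cs$eigenvector[cs$node == "c"], 1)

  path <- new_network_for_test(
    nodes = c("a", "b", "c"),
    edges = data.frame(u = c("a", "b"), v = c("b", "c"),
                       weight = 1, kind = "cooccurrence"))
  cp <- centralities(path)
  expect_equal(cp$betweenness[cp$node == "b"], 1)
  expect_equal(cp$closeness[cp$node == "b"], 1)

  cyc <- new_network_for_test(
    nodes = letters[1:5],
    edges = data.frame(u = letters[1:5], v = letters[c(2:5, 1)],
                       weight = 1, kind = "cooccurrence"))
  cc <- centralities(cyc)
  for (col in c("degree", "betweenness", "closeness", "eigenvector")) {
    expect_equal(diff(range(cc[[col]])), 0, tolerance = 1e-8)
  }

  empty <- new_network_for_test(nodes = character(0),
                                edges = data.frame(u = character(0),
                                                   v = character(0),
                                                   weight = numeric(0),
                                                   kind = character(0)))
  expect_error(centralities(empty), "empty graph")
})

test_that("stratified networks are built per condition and small strata skipped", {
  sim <- simulate_experiment(simulation_config(
    seed = 2, days = c(1, 7, 28), n_metabolites = 10))
  res <- per_condition_networks(list(sim$bacteria, sim$fungi),
                                sim$metadata, method = "cooccurrence")
  expect_setequal(names(res$networks), c("4", "17", "30"))
  expect_true(all(c("condition", "method", "eigenvector") %in%
                    names(res$centrality_table)))
  # a stratum with fewer than 4 samples is skipped
  md_small <- sim$metadata
  keep <- md_small$temperature != 4 |
    md_small$sample_id %in% md_small$sample_id[md_small$temperature == 4][1:2]
  tabs <- lapply(list(sim$bacteria, sim$fungi), ft_subset,
                 samples = md_small$sample_id[keep])
  expect_message(
    res2 <- per_condition_networks(tabs, md_small[keep, ],
                                   method = "cooccurrence"),
    "skipping stratum '4'")
  expect_setequal(names(res2$networks), c("17", "30"))
})
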