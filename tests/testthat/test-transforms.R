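test_that("TSS yields unit column sums, is idempotent, names offenders", {
  ft <- make_ft(matrix(c(2, 2, 4, 1, 0, 1), 3, 2))
  rel <- tss_normalize(ft)
  expect_equal(unname(rel$values[, 1]), c(0.25, 0.25, 0.5))
  expect_equal(unname(colSums(rel$values)), c(1, 1), tolerance = 1e-12)
  expect_equal(tss_normalize(rel)$values, rel$values)
  zero <- make_ft(matrix(c(1, 1, 0, 0), 2, 2))
  expect_error(tss_normalize(zero), "all-zero sample.*s02")
})

test_that("z-scoring uses the population sd and drops constant features", {
  ft <- make_ft(matrix(c(1, 5, 2, 5, 3, 5), 2, 3, byrow = FALSE))
  # row 1 is 1,2,3; row 2 constant 5
  expect_message(z <- zscore_normalize(ft), "constant feature")
  expect_equal(nrow(z$values), 1L)
  expect_equal(unname(z$values[1, ]), c(-1, 0, 1) / sqrt(2 / 3),
               tolerance = 1e-12)
  # population convention: sd([1,2,3]) = sqrt(2/3), so values are +-sqrt(1.5)
  set.seed(1)
  big <- zscore_normalize(make_ft(matrix(rnorm(60), 6, 10), transform = "log"))
  expect_true(all(abs(rowMeans(big$values)) < 1e-10))
  expect_true(all(abs(sqrt(rowMeans(big$values^2)) - 1) < 1e-10))
})

test_that("log transform matches closed forms and keeps order", {
  ft <- make_ft(matrix(c(0, exp(1) - 1, 7, 2), 2, 2))
  lt <- log_transform(ft, pseudo = 1)
  expect_equal(unname(lt$values[1, 1]), 0)
  expect_equal(unname(lt$values[2, 1]), 1)
  expect_true(all(diff(order(ft$values)) == diff(order(lt$values))))
  expect_error(log_transform(ft, pseudo = 0), "pseudo")
})

test_that("multiplicative replacement preserves unit sums and rescales", {
  ft <- make_ft(matrix(c(0.5, 0.5, 0), 3, 1), transform = "tss")
  mr <- multiplicative_replacement(ft, delta = 1e-8)
  expect_equal(unname(mr$values[3, 1]), 1e-8, tolerance = 1e-20)
  expect_equal(unname(mr$values[1, 1]), 0.5 * (1 - 1e-8), tolerance = 1e-12)
  expect_equal(sum(mr$values[, 1]), 1, tolerance = 1e-15)
  nz <- make_ft(matrix(c(0.3, 0.7), 2, 1), transform = "tss")
  expect_equal(multiplicative_replacement(nz)$values, nz$values)
  many0 <- make_ft(matrix(c(1, rep(0, 9)), 10, 1), transform = "tss")
  expect_error(multiplicative_replacement(many0, delta = 0.2), "delta")
})

test_that("CLR matches closed forms, sums to zero, is scale invariant", {
  ft <- make_ft(matrix(c(1, 2, 4), 3, 1), transform = "tss")
  ft$values <- ft$values / sum(ft$values)
  clr <- clr_transform(ft)
  expect_equal(unname(clr$values[, 1]), c(-log(2), 0, log(2)), tolerance = 1e-12)
  unif <- make_ft(matrix(rep(0.25, 4), 4, 1), transform = "tss")
  expect_equal(unname(clr_transform(unif)$values[, 1]), rep(0, 4))
  expect_error(clr_transform(make_ft(matrix(c(0, 1), 2, 1), transform = "tss")),
               "strictly positive")
  for (s in 1:10) {
    t1 <- random_composition(8, 4, seed = s)
    t2 <- t1
    t2$values <- t2$values * 7.3
    c1 <- clr_transform(t1)$values
    expect_equal(clr_transform(t2)$values, c1, tolerance = 1e-10)
    expect_true(all(abs(colSums(c1)) < 1e-8 * nrow(c1)))
  }
})

test_that("prevalence filter drops rare features, thresholds 0/1 are identity", {
  v <- matrix(c(1, 1, 0, 0,
                2, 0, 0, 0,
                1, 1, 1, 0), 3, 4, byrow = TRUE)
  ft <- make_ft(v)
  f3 <- prevalence_filter(ft, 3)
  expect_identical(feature_ids(f3), "f03")
  expect_identical(attr(f3, "dropped"), c("f01", "f02"))
  expect_identical(feature_ids(prevalence_filter(ft, 1)), feature_ids(ft))
  expect_identical(feature_ids(prevalence_filter(ft, 0)), feature_ids(ft))
})

test_that("rarefaction hits the depth exactly, reproducibly, dropping shallow samples", {
  set.seed(5)
  v <- matrix(rpois(40, 30), 4, 10)
  v[, 10] <- c(1, 1, 0, 0)  # total 2, below depth
  ft <- make_ft(v)
  expect_message(r1 <- rarefy(ft, depth = 50, seed = 11), "below depth")
  expect_identical(attr(r1, "dropped"), "s10")
  expect_true(all(colSums(r1$values) == 50))
  r2 <- suppressMessages(rarefy(ft, depth = 50, seed = 11))
  expect_identical(r1$values, r2$values)
  r3 <- suppressMessages(rarefy(ft, depth = 50, seed = 12))
  expect_false(identical(r1$values, r3$values))
  expect_error(rarefy(ft, depth = 0), "positive")
  expect_error(rarefy(make_ft(matrix(c(1.5, 1), 2, 1)), 1), "integer")
})

test_that("absolute abundance conserves qPCR-derived totals", {
  rel <- make_ft(matrix(c(0.5, 0.3, 0.2), 3, 1), transform = "tss")
  abs1 <- absolute_abundance(rel, dna_conc = 1)
  total <- 1 * 1.58e9 / 5
  expect_equal(unname(colSums(abs1$values)), total, tolerance = 1e-6 * total)
  expect_equal(unname(abs1$values[1, 1]), 1.58e8)
  expect_error(absolute_abundance(rel, dna_conc = -1), "negative")
  # conservation across several samples and concentrations
  rel2 <- tss_normalize(random_composition(5, 4, seed = 2))
  conc <- c(0.5, 1, 2, 3.3)
  ab <- absolute_abundance(rel2, conc)
  expect_equal(unname(colSums(ab$values)), conc * 1.58e9 / 5,
               tolerance = 1e-6)
})
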