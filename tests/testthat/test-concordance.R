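test_that("bray_curtis: identity, disjoint support, metric bounds, symmetry", {
  expect_equal(bray_curtis(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  set.seed(7)
  for (i in 1:25) {
    p <- runif(5); p <- p / sum(p)
    q <- runif(5); q <- q / sum(q)
    bc <- bray_curtis(p, q)
    # brute force, element by element
    num <- 0; den <- 0
    for (j in 1:5) {
      num <- num + abs(p[j] - q[j])
      den <- den + p[j] + q[j]
    }
    expect_equal(bc, num / den)
    expect_equal(bc, bray_curtis(q, p))
    expect_gte(bc, 0)
    expect_lte(bc, 1)
  }
})

test_that("bray_curtis agrees with vegan::vegdist", {
  skip_if_not_installed("vegan")
  set.seed(11)
  for (i in 1:10) {
    p <- runif(8); q <- runif(8)
    expected <- as.numeric(vegan::vegdist(rbind(p, q), method = "bray"))
    expect_equal(bray_curtis(p, q), expected)
  }
})

test_that("fold_deviation: identity is exactly zero, arithmetic is plain", {
  tab <- make_abund(c(Lactobacillus = 400, Gardnerella = 50), 1000)
  pairs <- paired_abundance(tab, tab)
  fd <- fold_deviation(pairs)
  expect_true(all(fd$folds$fold == 1))
  expect_true(all(fd$per_stratum$mean_abs_dev == 0))
  expect_equal(fd$mean_fold, 1)

  p2 <- data.table::data.table(
    taxon = c("A", "B"), count_a = c(200L, 100L), count_b = c(100L, 200L),
    proportion_a = c(0.2, 0.1), proportion_b = c(0.1, 0.2),
    stratum = "[100,500)")
  fd2 <- fold_deviation(p2)
  expect_setequal(fd2$folds$fold, c(0.5, 2))

  # zero-in-control taxa are reported, never divided
  p3 <- rbind(p2, data.table::data.table(
    taxon = "C", count_a = 0L, count_b = 50L,
    proportion_a = 0, proportion_b = 0.05, stratum = "[30,100)"))
  fd3 <- fold_deviation(p3)
  expect_equal(fd3$zero_in_a, "C")
  expect_equal(fd3$n_pairs, 2L)
})

test_that("count strata are binned on the larger member", {
  a <- make_abund(c(w = 35, x = 120, y = 600, z = 1500), 5000)
  b <- make_abund(c(w = 40, x = 110, y = 550, z = 1400), 5000)
  pairs <- paired_abundance(a, b)
  expect_equal(pairs[pairs$taxon == "w", ]$stratum, "[30,100)")
  expect_equal(pairs[pairs$taxon == "x", ]$stratum, "[100,500)")
  expect_equal(pairs[pairs$taxon == "y", ]$stratum, "[500,1000)")
  expect_equal(pairs[pairs$taxon == "z", ]$stratum, "[1000,Inf)")
  # a taxon retained in only one table enters with count 0 in the other
  c2 <- make_abund(c(w = 35), 100)
  d2 <- make_abund(c(v = 45), 100)
  pairs2 <- paired_abundance(c2, d2)
  expect_setequal(pairs2$taxon, c("v", "w"))
  expect_equal(pairs2[pairs2$taxon == "v", ]$count_a, 0L)
})

test_that("spearman exclusion rule and exact permutation p-values", {
  # one shared taxon -> excluded
  one <- data.table::data.table(
    taxon = c("A", "B"), count_a = c(100L, 40L), count_b = c(90L, 0L),
    proportion_a = c(0.1, 0.04), proportion_b = c(0.09, 0),
    stratum = "[30,100)")
  sp <- spearman_with_exclusion(one)
  expect_true(sp$excluded)
  expect_match(sp$reason, "1 pairwise case")

  # perfectly monotone -> rho 1
  mono <- data.table::data.table(
    taxon = letters[1:5], count_a = c(50L, 100L, 200L, 400L, 800L),
    count_b = c(60L, 120L, 240L, 480L, 960L),
    proportion_a = c(0.05, 0.1, 0.2, 0.4, 0.8) / 2,
    proportion_b = c(0.06, 0.12, 0.24, 0.48, 0.96) / 2,
    stratum = "[30,100)")
  sp2 <- spearman_with_exclusion(mono)
  expect_false(sp2$excluded)
  expect_equal(sp2$rho, 1)
  expect_true(sp2$few_pairwise_cases)

  # n = 6, no ties: exact permutation p equals an independent brute-force
  # enumeration of all 720 permutations, and cor.test's exact p
  set.seed(3)
  x <- runif(6); y <- runif(6)
  p6 <- data.table::data.table(
    taxon = letters[1:6], count_a = 31:36, count_b = 31:36,
    proportion_a = x, proportion_b = y, stratum = "[30,100)")
  sp3 <- spearman_with_exclusion(p6)
  rx <- rank(x); ry <- rank(y)
  rho_obs <- cor(rx, ry)
  # brute-force permutation generator, written independently here
  perm_gen <- function(n) {
    if (n == 1L) return(list(1L))
    out <- list()
    for (p in perm_gen(n - 1L)) {
      for (pos in 0:(n - 1L)) out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
    out
  }
  rhos <- vapply(perm_gen(6L), function(p) cor(rx, ry[p]), numeric(1))
  expect_equal(length(rhos), factorial(6))
  expect_equal(sp3$p_value, mean(abs(rhos) >= abs(rho_obs) - 1e-12))
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = TRUE))
  expect_equal(sp3$rho, unname(ct$estimate))
  expect_equal(sp3$p_value, ct$p.value)
})

test_that("t-approximation path matches cor.test above n = 8", {
  set.seed(5)
  x <- runif(12); y <- x + rnorm(12, sd = 0.3)
  pl <- data.table::data.table(
    taxon = letters[1:12], count_a = 31:42, count_b = 31:42,
    proportion_a = x, proportion_b = y, stratum = "[30,100)")
  sp <- spearman_with_exclusion(pl)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(sp$rho, unname(ct$estimate))
  expect_equal(sp$p_value, ct$p.value, tolerance = 1e-10)
  expect_false(sp$few_pairwise_cases)
})

test_that("depletion-invariant pairs: mean fold near 1, BC shrinks with depth", {
  pairs <- invariant_pair(50000, seed_a = 101, seed_b = 202)
  fd <- fold_deviation(pairs)
  expect_lt(abs(fd$mean_fold - 1), 0.05)

  bc5 <- bc50 <- numeric(5)
  for (i in 1:5) {
    bc5[i] <- bray_curtis_pair(invariant_pair(5000, 1000 + i, 2000 + i))
    bc50[i] <- bray_curtis_pair(invariant_pair(50000, 3000 + i, 4000 + i))
  }
  expect_lt(mean(bc50), mean(bc5))
})

test_that("pair_report produces one machine-readable row per sample", {
  a <- make_abund(c(Lactobacillus = 800, Gardnerella = 150, Prevotella = 40), 5000)
  b <- make_abund(c(Lactobacillus = 760, Gardnerella = 170, Prevotella = 35), 5000)
  rep <- pair_report(list(s1 = paired_abundance(a, b),
                          s2 = paired_abundance(a, a)))
  expect_equal(nrow(rep), 2L)
  expect_equal(rep$sample, c("s1", "s2"))
  expect_equal(rep$bray_curtis[2], 0)
  expect_equal(rep$mean_fold[2], 1)
  expect_false(any(rep$excluded))
})
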