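lin <- example_lineage()

test_that("minimum-read filter drops taxa below threshold and reports mass", {
  ids <- paste0("r", 1:69)
  cats <- make_cat_reads(ids, 1000, "control")
  # 40 Lactobacillus, 29 Gardnerella
  asg <- make_assignments(ids, c(rep(147802L, 40), rep(2702L, 29)))
  tab <- abundance_table(cats, asg, lin, rank = "genus", min_reads = 30)
  expect_equal(tab$taxon, "Lactobacillus")
  expect_equal(tab$count, 40L)
  expect_equal(attr(tab, "dropped_reads"), 29L)
  expect_equal(attr(tab, "dropped_taxa"), 1L)
  expect_equal(tab$proportion, 40 / 69)
})

test_that("min_reads = 0 proportions sum to the classified fraction", {
  sim <- simulate_run("single_sample_control", n_reads = 5000, seed = 21)
  res <- analyze_sim_run(sim)
  tab <- abundance_table(res$cat_reads, res$assignments, lin,
                         rank = "superkingdom", min_reads = 0,
                         denominator_policy = "category_reads")
  expect_equal(sum(tab$proportion),
               classified_fraction(res$assignments, lin))
})

test_that("genus proportions recover the preset composition", {
  # averaged over 5 replicate runs so the check targets bias, not one
  # seed's tail; per-genus envelope at the Bonferroni-adjusted 3-SD level
  # for 4 simultaneous comparisons, plus a pooled goodness-of-fit check
  n <- 50000
  seeds <- 1:5
  split <- c(Lactobacillus = 0.5385, Gardnerella = 0.2900,
             Ureaplasma = 0.0829, Prevotella = 0.0414)
  # expected: (1 - 0.8793) x relative split of the non-human mass
  # (the split constants, with the 0.0472 yeast share, sum to 1)
  expected <- (1 - 0.8793) * split
  counts <- matrix(0L, length(seeds), length(split),
                   dimnames = list(NULL, names(split)))
  for (k in seq_along(seeds)) {
    res <- analyze_sim_run(simulate_run("single_sample_control", n_reads = n,
                                        seed = seeds[k]))
    tab <- abundance_table(res$cat_reads, res$assignments, lin, rank = "genus",
                           superkingdoms = "Bacteria", min_reads = 30)
    expect_true(all(diff(tab$count) <= 0))  # sorted by count descending
    counts[k, ] <- tab$count[match(names(split), tab$taxon)]
  }
  zcrit <- qnorm(1 - pnorm(-3) / length(expected))
  for (g in names(expected)) {
    p <- expected[[g]]
    got <- mean(counts[, g]) / n
    se_mean <- sqrt(p * (1 - p) / n) / sqrt(length(seeds))
    expect_lt(abs(got - p), zcrit * se_mean, label = g)
  }
  pooled_n <- n * length(seeds)
  pooled <- colSums(counts)
  gof <- chisq.test(c(pooled, pooled_n - sum(pooled)),
                    p = c(expected, other = 1 - sum(expected)))
  expect_gt(gof$p.value, 0.001)
})

test_that("category_content percentages are complete and consistent", {
  cats <- make_cat_reads(paste0("h", 1:10), 1000, "rejected")
  asg <- make_assignments(paste0("h", 1:10), rep(9606L, 10))
  cc <- category_content(cats, asg, lin)
  expect_equal(cc$human_pct[cc$category == "rejected"], 100)
  expect_true(cc$flagged[cc$category == "rejected"])  # only 10 reads

  sim <- simulate_run("single_sample_depletion", n_reads = 20000, seed = 4)
  res <- analyze_sim_run(sim)
  cc2 <- res$content
  sums <- cc2$human_pct + cc2$bacterial_pct + cc2$other_pct + cc2$unclassified_pct
  expect_true(all(abs(sums - 100) < 0.05))
  # the kept row aggregates accepted + no_decision exactly
  acc <- cc2[cc2$category == "accepted", ]
  nd <- cc2[cc2$category == "no_decision", ]
  kept <- cc2[cc2$category == "kept", ]
  expect_equal(kept$n_reads, acc$n_reads + nd$n_reads)
  blended <- (acc$human_pct * acc$n_reads + nd$human_pct * nd$n_reads) /
    kept$n_reads
  expect_lt(abs(kept$human_pct - blended), 0.05)
})

test_that("merging categories reproduces the whole-run table exactly", {
  sim <- simulate_run("single_sample_depletion", n_reads = 10000, seed = 8)
  res <- analyze_sim_run(sim)
  whole <- abundance_table(res$cat_reads, res$assignments, lin, rank = "genus",
                           min_reads = 0)
  parts <- lapply(c("accepted", "rejected", "no_decision"), function(cat) {
    abundance_table(res$cat_reads, res$assignments, lin, rank = "genus",
                    categories = cat, min_reads = 0)
  })
  merged <- data.table::rbindlist(parts)[, .(count = sum(count)), by = "taxon"]
  m <- merge(as.data.frame(whole)[, c("taxon", "count")],
             as.data.frame(merged), by = "taxon")
  expect_equal(m$count.x, m$count.y)
})

test_that("abundance tables round-trip through TSV with provenance", {
  sim <- simulate_run("single_sample_control", n_reads = 3000, seed = 5)
  res <- analyze_sim_run(sim)
  tab <- abundance_table(res$cat_reads, res$assignments, lin, rank = "genus",
                         superkingdoms = "Bacteria", min_reads = 30,
                         run_id = "demo")
  path <- tempfile(fileext = ".tsv")
  write_abundance_table(tab, path)
  back <- read_abundance_table(path)
  expect_equal(back$taxon, tab$taxon)
  expect_equal(back$count, tab$count)
  expect_equal(back$proportion, tab$proportion)
  expect_equal(attr(back, "denominator"), attr(tab, "denominator"))
  expect_equal(attr(back, "run_id"), "demo")
})
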