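test_that("truth table and FASTQ are bijective and ids carry no truth", {
  sim <- simulate_run("single_sample_depletion", n_reads = 3000, seed = 6)
  expect_identical(sim$reads$read_id, sim$truth$read_id)
  expect_equal(anyDuplicated(sim$reads$read_id), 0L)
  # ids are position-based only: no class or category tokens
  expect_false(any(grepl("human|bacterial|rejected|accepted", sim$reads$read_id)))
  # decision log covers every read exactly once
  expect_setequal(sim$decisions$read_id, sim$reads$read_id)
})

test_that("degenerate preset: all-human, always-reject", {
  p <- sim_preset("degenerate", mode = "category",
                  human_frac = c(rejected = 1, accepted = 1, no_decision = 1),
                  category_probs = c(rejected = 1, accepted = 0, no_decision = 0))
  sim <- simulate_run(p, n_reads = 500, seed = 2)
  expect_true(all(sim$truth$category == "rejected"))
  expect_true(all(sim$truth$class == "human"))
  expect_true(all(sim$reads$length_bp >= 400 & sim$reads$length_bp <= 800))
  # rejected reads are truncated at the decision point
  expect_equal(sim$reads$length_bp, sim$truth$bp_to_decision)
  expect_true(all(sim$truth$full_length >= sim$truth$bp_to_decision))
})

test_that("composition and category frequencies converge (3-sd envelopes)", {
  n <- 20000
  sim <- simulate_run("single_sample_control", n_reads = n, seed = 31)
  h <- mean(sim$truth$class == "human")
  expect_lt(abs(h - 0.8793), 3 * sqrt(0.8793 * (1 - 0.8793) / n))

  n2 <- 10000
  sim2 <- simulate_run("single_sample_depletion", n_reads = n2, seed = 32)
  probs <- get_preset("single_sample_depletion")$category_probs
  for (cat in names(probs)) {
    obs <- mean(sim2$truth$category == cat)
    expect_lt(abs(obs - probs[[cat]]),
              3 * sqrt(probs[[cat]] * (1 - probs[[cat]]) / n2) + 1e-9,
              label = cat)
  }
})

test_that("invalid presets fail validation before anything is written", {
  expect_error(sim_preset("x", mode = "category",
                          human_frac = c(rejected = 0.5, accepted = 0.5,
                                         no_decision = 0.5),
                          category_probs = c(rejected = 0.6, accepted = 0.6,
                                             no_decision = -0.2)),
               "sum to 1")
  expect_error(sim_preset("x", mode = "control", human_frac = 1.2), "\\[0, 1\\]")
  expect_error(sim_preset("x", mode = "control", human_frac = 0.5,
                          bp_reject = c(min = 900, max = 800, median = 850)),
               "min <= median <= max")
  expect_error(get_preset("not_a_preset"), "single_sample_control")
})

test_that("cohort parameter construction preserves the mean exactly", {
  v <- cohort_param_values(92.05, 7.42, 15, 0, 100)
  expect_equal(mean(v), 92.05)
  expect_true(all(v >= 0 & v <= 100))

  # heavy clipping at the upper bound still preserves the mean
  v2 <- cohort_param_values(97.59, 7.63, 15, 0, 100)
  expect_equal(mean(v2), 97.59)
  expect_true(any(v2 == 100))
  expect_true(all(v2 <= 100))

  expect_equal(mean(cohort_param_values(1.70, 0.27, 15, 0.1, Inf)), 1.70)

  # s = 0 -> all samples identical
  expect_true(all(cohort_param_values(50, 0, 15, 0, 100) == 50))
})

test_that("cohort pairs share composition and encode the designed fold", {
  coh <- simulate_cohort("cohort15", n_reads = 2000, seed = 5)
  expect_length(coh$samples, 15L)
  folds <- vapply(coh$samples, function(s) {
    nrow(s$depletion$reads) / nrow(s$control$reads)
  }, numeric(1))
  # depletion read counts are deterministic multiples: only rounding noise
  expect_lt(abs(mean(folds) - 1.70), 0.001)
  # paired runs share the per-sample genus split: compare bacterial genus
  # composition of a low-host sample between control and depletion kept reads
  s1 <- coh$samples[[1]]
  gen <- function(truth) {
    b <- truth$class[startsWith(truth$class, "bacterial:")]
    prop.table(table(b))
  }
  g_ctrl <- gen(s1$control$truth)
  g_depl <- gen(s1$depletion$truth)
  shared <- intersect(names(g_ctrl), names(g_depl))
  expect_gt(length(shared), 2L)
  expect_lt(max(abs(g_ctrl[shared] - g_depl[shared])), 0.15)
})

test_that("pore-time model: rejection frees pore time and raises yield", {
  common <- list(
    human_frac = 0.9,
    microbial_split = c(Lactobacillus = 0.6, Gardnerella = 0.4),
    read_length = c(median = 2500, sdlog = 0.55))
  pt <- list(enabled = TRUE, duration_s = 2000, n_channels = 64,
             speed_bp_s = 450, capture_s = 1, unblock_s = 0.5)
  ctrl <- do.call(sim_preset, c(list("pt_control", mode = "control",
                                     pore_time = pt), common))
  depl <- do.call(sim_preset, c(list("pt_depletion", mode = "class",
                                     reject_prob = c(human = 1, bacterial = 0, other = 0),
                                     accept_prob = c(human = 0, bacterial = 0.5, other = 0),
                                     pore_time = pt), common))
  n_ctrl <- nrow(simulate_run(ctrl, seed = 41)$reads)
  n_depl <- nrow(simulate_run(depl, seed = 41)$reads)
  # mean rejected cost (600 bp / 450 + overheads) << mean full read cost
  expect_gt(n_depl, n_ctrl)
  # and rejection hits only the host class
  sim <- simulate_run(depl, seed = 42)
  expect_true(all(sim$truth$class[sim$truth$category == "rejected"] == "human"))
})

test_that("simulate_run writes a complete, checksummed file set", {
  outdir <- tempfile()
  sim <- simulate_run("single_sample_depletion", n_reads = 400, seed = 12,
                      outdir = outdir)
  expect_true(all(file.exists(sim$files)))
  manifest <- jsonlite::read_json(sim$files[["manifest"]])
  expect_equal(manifest$preset, "single_sample_depletion")
  expect_equal(manifest$seed, 12L)
  expect_equal(unlist(manifest$md5[[sim$files[["fastq"]]]]),
               unname(tools::md5sum(sim$files[["fastq"]])))
  # decision CSV round-trips through the reader
  dec <- read_decision_log(sim$files[["decisions"]])
  expect_equal(nrow(dec), 400L)
  unlink(outdir, recursive = TRUE)
})

test_that("simulation is reproducible for a fixed seed", {
  a <- simulate_run("single_sample_control", n_reads = 500, seed = 77)
  b <- simulate_run("single_sample_control", n_reads = 500, seed = 77)
  expect_identical(a$truth, b$truth)
  expect_identical(a$reads, b$reads)
  c <- simulate_run("single_sample_control", n_reads = 500, seed = 78)
  expect_false(identical(a$truth$taxid, c$truth$taxid))
})
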