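# Synthetic adaptive-sampling runs: a host/bacterial read mixture with a
# configurable genus composition, the three-way decision process with
# per-category bp-to-decision distributions, an optional pore-time model
# (yield reallocation after rejection), paired control/depletion cohorts
# with deterministic per-sample parameter variation, and a mock-community
# alignment generator. Everything is seeded; no global RNG state leaks.

# ---- example taxonomy -------------------------------------------------------

.example_taxa <- data.table::data.table(
  taxon = c("human", "Lactobacillus", "Gardnerella", "Ureaplasma",
            "Prevotella", "Streptococcus", "Fannyhessea", "Aerococcus",
            "Candida"),
  taxid = c(9606L, 147802L, 2702L, 134821L, 28131L, 1311L, 82135L,
            87541L, 5476L),
  class = c("human", rep("bacterial", 7L), "other"),
  superkingdom = c("Eukaryota", rep("Bacteria", 7L), "Eukaryota"),
  genus = c("Homo", "Lactobacillus", "Gardnerella", "Ureaplasma",
            "Prevotella", "Streptococcus", "Fannyhessea", "Aerococcus",
            "Candida"),
  species = c("Homo sapiens", "Lactobacillus iners", "Gardnerella vaginalis",
              "Ureaplasma parvum", "Prevotella intermedia",
              "Streptococcus agalactiae", "Fannyhessea vaginae",
              "Aerococcus christensenii", "Candida albicans")
)

#' Example lineage map for synthetic runs
#'
#' A small vaginal-metagenome-flavoured taxonomy (human host, common
#' vaginal genera, one yeast) matching the taxids emitted by the
#' simulator's truth tables.
#'
#' @return A `lineage_map`.
#' @export
example_lineage <- function() {
  as_lineage_map(.example_taxa[, .(taxid, superkingdom, genus, species)])
}

# Relative split of the non-human read mass over taxa (illustrative values;
# never used as a numeric target).
.default_microbial_split <- c(
  Lactobacillus = 0.5385, Gardnerella = 0.2900, Ureaplasma = 0.0829,
  Prevotella = 0.0414, Candida = 0.0472
)

# ---- presets ----------------------------------------------------------------

#' Construct a simulation preset
#'
#' A preset fully parameterizes one synthetic run: the decision mode
#' (`"control"` for a run without adaptive sampling, `"category"` for
#' direct category frequencies with per-category composition), the human
#' fraction(s), the relative genus split of the non-human mass, the
#' bp-to-decision distributions, the read-length distribution, and the
#' optional pore-time model.
#'
#' @param name Preset label.
#' @param mode `"control"`, `"category"` (direct category frequencies with
#'   per-category composition) or `"class"` (per-class decision
#'   probabilities P(reject | class), P(accept | class)).
#' @param human_frac For `mode = "control"` and `mode = "class"` a single
#'   host fraction; for `mode = "category"` a named vector with entries
#'   `rejected`, `accepted`, `no_decision`.
#' @param category_probs Named probabilities (`rejected`, `accepted`,
#'   `no_decision`) summing to 1; `mode = "category"` only.
#' @param reject_prob,accept_prob For `mode = "class"`: named vectors over
#'   classes (`human`, `bacterial`, `other`) giving P(reject | class) and
#'   P(accept | class); the remainder is the no-decision probability.
#' @param microbial_split Named relative fractions of the non-human mass
#'   over taxa of [example_lineage()] (normalized internally).
#' @param microbial_split_by_category Optional list overriding
#'   `microbial_split` for individual categories.
#' @param bp_reject,bp_accept Named vectors `(min, max, median)` in bp for
#'   the rejection and acceptance decision points.
#' @param read_length Named vector `(median, sdlog)` of the log-normal
#'   full-read-length distribution (median 2500 bp by default, matching a
#'   PCR-based rapid library).
#' @param n_reads Default number of reads when `simulate_run()` is not
#'   given one.
#' @param pore_time Optional list enabling the mechanistic pore-occupancy
#'   mode: `enabled`, `duration_s`, `n_channels`, `speed_bp_s`,
#'   `capture_s`, `unblock_s`.
#' @return An object of class `sim_preset`.
#' @export
sim_preset <- function(name, mode = c("control", "category", "class"),
                       human_frac,
                       category_probs = NULL,
                       reject_prob = NULL, accept_prob = NULL,
                       microbial_split = .default_microbial_split,
                       microbial_split_by_category = NULL,
                       bp_reject = c(min = 400, max = 800, median = 600),
                       bp_accept = c(min = 3000, max = 5000, median = 4000),
                       read_length = c(median = 2500, sdlog = 0.55),
                       n_reads = 10000L,
                       pore_time = NULL) {
  mode <- match.arg(mode)
  if (any(human_frac < 0 | human_frac > 1)) {
    stop_poresift("preset '%s': human_frac must lie in [0, 1]", name)
  }
  if (mode == "category") {
    need <- c("rejected", "accepted", "no_decision")
    if (is.null(category_probs) || !all(need %in% names(category_probs))) {
      stop_poresift("preset '%s': category_probs must name %s", name,
                    paste(need, collapse = ", "))
    }
    if (any(category_probs < 0) || abs(sum(category_probs) - 1) > 1e-8) {
      stop_poresift("preset '%s': category_probs must be non-negative and sum to 1", name)
    }
    if (!all(need %in% names(human_frac))) {
      stop_poresift("preset '%s': human_frac must name %s in category mode",
                    name, paste(need, collapse = ", "))
    }
  }
  if (mode == "class") {
    classes <- c("human", "bacterial", "other")
    if (is.null(reject_prob) || is.null(accept_prob) ||
        !all(classes %in% names(reject_prob)) ||
        !all(classes %in% names(accept_prob))) {
      stop_poresift("preset '%s': class mode needs reject_prob and accept_prob named over %s",
                    name, paste(classes, collapse = ", "))
    }
    tot <- reject_prob[classes] + accept_prob[classes]
    if (any(reject_prob < 0) || any(accept_prob < 0) || any(tot > 1 + 1e-12)) {
      stop_poresift("preset '%s': per-class reject + accept probabilities must lie in [0, 1]", name)
    }
  }
  if (any(microbial_split < 0) || sum(microbial_split) <= 0) {
    stop_poresift("preset '%s': microbial_split must be non-negative, not all zero", name)
  }
  unknown <- setdiff(names(microbial_split), .example_taxa$taxon)
  if (length(unknown)) {
    stop_poresift("preset '%s': unknown taxa in microbial_split: %s", name,
                  paste(unknown, collapse = ", "))
  }
  for (v in list(bp_reject, bp_accept)) {
    if (!all(c("min", "max", "median") %in% names(v)) ||
        v["min"] > v["median"] || v["median"] > v["max"]) {
      stop_poresift("preset '%s': bp distribution needs min <= median <= max", name)
    }
  }
  structure(list(
    name = name, mode = mode, human_frac = human_frac,
    category_probs = category_probs,
    reject_prob = reject_prob, accept_prob = accept_prob,
    microbial_split = microbial_split / sum(microbial_split),
    microbial_split_by_category = microbial_split_by_category,
    bp_reject = bp_reject, bp_accept = bp_accept,
    read_length = read_length, n_reads = as.integer(n_reads),
    pore_time = pore_time
  ), class = "sim_preset")
}

#' @export
print.sim_preset <- function(x, ...) {
  cat(sprintf("sim_preset '%s' (mode %s)\n", x$name, x$mode))
  if (x$mode == "control") {
    cat(sprintf("  host fraction: %.4f\n", x$human_frac))
  } else {
    cat(sprintf("  P(category): %s\n",
                paste(sprintf("%s=%.4f", names(x$category_probs), x$category_probs),
                      collapse = " ")))
    cat(sprintf("  human | category: %s\n",
                paste(sprintf("%s=%.4f", names(x$human_frac), x$human_frac),
                      collapse = " ")))
  }
  invisible(x)
}

#' Names of the built-in presets
#' @return Character vector.
#' @export
preset_names <- function() {
  c("single_sample_control", "single_sample_depletion",
    "single_sample_enrichment", "cohort15")
}

#' Retrieve a built-in preset by name
#'
#' The single-sample presets encode the three single-run experiments
#' (control without adaptive sampling with 87.93 % host reads; human-DNA
#' depletion rejecting 81.01 % of reads with 34.73 % human among kept
#' reads; bacterial enrichment rejecting 95.93 % with 8.29 % human among
#' kept reads and a rejected fraction carrying 5.48 % Gardnerella, 2.41 %
#' Lactobacillus and 2.20 % other microbial reads). `cohort15` is handled
#' by [simulate_cohort()].
#'
#' @param name One of [preset_names()] except `"cohort15"`.
#' @return A `sim_preset`.
#' @export
get_preset <- function(name) {
  if (!name %in% preset_names()) {
    stop_poresift("unknown preset '%s'; valid presets: %s", name,
                  paste(preset_names(), collapse = ", "))
  }
  switch(name,
    single_sample_control = sim_preset(
      name, mode = "control", human_frac = 0.8793),
    single_sample_depletion = {
      kept <- 1 - 0.8101
      accepted_share <- 0.04  # most kept reads never receive a decision
      sim_preset(
        name, mode = "category",
        category_probs = c(rejected = 0.8101,
                           accepted = kept * accepted_share,
                           no_decision = kept * (1 - accepted_share)),
        human_frac = c(rejected = 0.998, accepted = 0.3473,
                       no_decision = 0.3473))
    },
    single_sample_enrichment = {
      kept <- 1 - 0.9593
      rej_microbial <- c(Gardnerella = 0.0548, Lactobacillus = 0.0241,
                         Candida = 0.0220)
      sim_preset(
        name, mode = "category",
        category_probs = c(rejected = 0.9593,
                           accepted = kept * 0.5,
                           no_decision = kept * 0.5),
        human_frac = c(rejected = 1 - sum(rej_microbial),
                       accepted = 0.0829, no_decision = 0.0829),
        microbial_split_by_category = list(
          rejected = rej_microbial / sum(rej_microbial)),
        bp_accept = c(min = 400, max = 800, median = 550))
    },
    cohort15 = stop_poresift("preset 'cohort15' is a cohort; use simulate_cohort()"))
}

# ---- low-level draws --------------------------------------------------------

# Bounded (min, max, median) draw: scaled Beta with shape1 = 2 and shape2
# solved from the median via the (a - 1/3) / (a + b - 2/3) approximation.
draw_bounded <- function(n, spec) {
  lo <- spec[["min"]]; hi <- spec[["max"]]; med <- spec[["median"]]
  if (hi == lo) return(rep(as.integer(lo), n))
  m <- (med - lo) / (hi - lo)
  a <- 2
  b <- max((a - 1/3) / m - a + 2/3, 0.2)
  as.integer(round(lo + (hi - lo) * rbeta(n, a, b)))
}

draw_lengths <- function(n, read_length) {
  pmax(as.integer(round(rlnorm(n, meanlog = log(read_length[["median"]]),
                               sdlog = read_length[["sdlog"]]))), 100L)
}

# Random nucleotide payloads via substrings of one shared random pool;
# content is never interpreted downstream.
random_payload <- function(lengths) {
  maxlen <- max(lengths, 1L)
  pool <- paste(sample(c("A", "C", "G", "T"), 2L * maxlen, replace = TRUE),
                collapse = "")
  starts <- sample.int(maxlen, length(lengths), replace = TRUE)
  list(sequence = substring(pool, starts, starts + lengths - 1L),
       quality = strrep("I", lengths))
}

draw_taxa <- function(n, human_frac, split) {
  taxa <- names(split)
  out <- character(n)
  is_h <- runif(n) < human_frac
  out[is_h] <- "human"
  n_b <- sum(!is_h)
  if (n_b > 0L) {
    out[!is_h] <- sample(taxa, n_b, replace = TRUE, prob = split)
  }
  out
}

# ---- simulate_run -----------------------------------------------------------

#' Simulate one adaptive-sampling run
#'
#' Draws reads from the preset's composition and decision model and emits
#' the three artefacts a real run produces: basecalled reads, the
#' read_until decision log (absent for control presets) and the truth
#' table. Rejected reads are truncated at their bp-to-decision draw
#' (default 400-800 bp); accepted reads are sequenced to full length with
#' the decision recorded around 4000 bp (depletion) or 400-800 bp
#' (enrichment); no-decision reads carry no decision point. With the
#' pore-time model enabled the number of emitted reads is governed by a
#' pore-seconds budget instead of `n_reads`, so rejection frees pore time
#' and increases yield.
#'
#' @param preset A `sim_preset` or a preset name.
#' @param n_reads Number of reads (overrides the preset default; ignored
#'   in pore-time mode).
#' @param seed Integer RNG seed.
#' @param outdir When given, FASTQ / decision CSV / truth TSV and a
#'   manifest JSON are written there.
#' @param payload Generate sequence/quality payloads (forced `TRUE` when
#'   `outdir` is given; default `FALSE` otherwise — the oracle never reads
#'   sequence content).
#' @param run_id Prefix for read ids and file names.
#' @return List with `reads`, `decisions` (`NULL` for control runs),
#'   `truth`, `preset`, `seed`, and `files` when written.
#' @export
simulate_run <- function(preset, n_reads = NULL, seed = 1, outdir = NULL,
                         payload = !is.null(outdir), run_id = NULL) {
  if (is.character(preset)) preset <- get_preset(preset)
  stopifnot(inherits(preset, "sim_preset"))
  if (!is.null(outdir)) payload <- TRUE
  run_id <- run_id %||% preset$name
  pt <- preset$pore_time
  pore_mode <- !is.null(pt) && isTRUE(pt$enabled)
  n <- as.integer(n_reads %||% preset$n_reads)

  out <- with_seed(seed, {
    if (pore_mode) {
      .simulate_reads_pore_time(preset, pt, run_id)
    } else {
      .simulate_reads_fixed_n(preset, n, run_id)
    }
  })
  truth <- out$truth
  reads <- out$reads

  if (payload) {
    pl <- with_seed(seed + 1L, random_payload(reads$length_bp))
    reads[, sequence := pl$sequence]
    reads[, quality := pl$quality]
  }

  decisions <- NULL
  if (preset$mode != "control") {
    map <- c(rejected = "unblock", accepted = "stop_receiving",
             no_decision = "no_decision")
    decisions <- data.table(
      read_id = truth$read_id,
      decision = unname(map[truth$category]),
      channel = with_seed(seed + 2L, sample.int(512L, nrow(truth), replace = TRUE)),
      bp_at_decision = truth$bp_to_decision
    )
  }

  files <- NULL
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    files <- c(fastq = file.path(outdir, paste0(run_id, ".fastq")),
               truth = file.path(outdir, paste0(run_id, ".truth.tsv")))
    write_fastq(reads, files[["fastq"]])
    fwrite(truth, files[["truth"]], sep = "\t", na = "")
    if (!is.null(decisions)) {
      files[["decisions"]] <- file.path(outdir, paste0(run_id, ".read_until.csv"))
      write_decision_csv(decisions, files[["decisions"]])
    }
    manifest <- file.path(outdir, paste0(run_id, ".manifest.json"))
    jsonlite::write_json(list(
      preset = preset$name, run_id = run_id, seed = seed,
      n_reads = nrow(reads),
      generator = paste0("poresift/", as.character(utils::packageVersion("poresift"))),
      md5 = as.list(tools::md5sum(unname(files)))
    ), manifest, auto_unbox = TRUE)
    files[["manifest"]] <- manifest
  }

  list(reads = reads[], decisions = decisions, truth = truth[],
       preset = preset, seed = seed, files = files)
}

.simulate_reads_fixed_n <- function(preset, n, run_id) {
  if (n < 1L) stop_poresift("n_reads must be >= 1")
  if (preset$mode == "category") {
    # category first, composition conditional on category
    category <- sample(names(preset$category_probs), n, replace = TRUE,
                       prob = preset$category_probs)
    taxon <- character(n)
    for (cat in unique(category)) {
      idx <- category == cat
      split <- preset$microbial_split
      ov <- preset$microbial_split_by_category[[cat]]
      if (!is.null(ov)) split <- ov / sum(ov)
      taxon[idx] <- draw_taxa(sum(idx), preset$human_frac[[cat]], split)
    }
  } else {
    # composition first; category from per-class decision probabilities
    taxon <- draw_taxa(n, preset$human_frac, preset$microbial_split)
    if (preset$mode == "control") {
      category <- rep("control", n)
    } else {
      cls <- .example_taxa$class[match(taxon, .example_taxa$taxon)]
      u <- runif(n)
      p_rej <- preset$reject_prob[cls]
      p_acc <- preset$accept_prob[cls]
      category <- ifelse(u < p_rej, "rejected",
                         ifelse(u < p_rej + p_acc, "accepted", "no_decision"))
    }
  }
  full_length <- draw_lengths(n, preset$read_length)
  bp <- rep(NA_integer_, n)
  rej <- category == "rejected"
  acc <- category == "accepted"
  if (any(rej)) {
    bp[rej] <- draw_bounded(sum(rej), preset$bp_reject)
    full_length[rej] <- pmax(full_length[rej], bp[rej])
  }
  if (any(acc)) {
    bp[acc] <- pmin(draw_bounded(sum(acc), preset$bp_accept), full_length[acc])
  }
  emitted <- ifelse(rej, bp, full_length)
  read_id <- sprintf("%s-%07d", run_id, seq_len(n))
  tax_idx <- match(taxon, .example_taxa$taxon)
  tax <- .example_taxa[tax_idx]
  truth <- data.table(
    read_id = read_id,
    taxid = tax$taxid,
    class = ifelse(tax$class == "bacterial",
                   paste0("bacterial:", tax$genus), tax$class),
    category = category,
    bp_to_decision = bp,
    full_length = full_length
  )
  list(reads = data.table(read_id = read_id, length_bp = as.integer(emitted)),
       truth = truth)
}

# Pore-occupancy mode: draw reads in chunks and stop once the pore-seconds
# budget (duration x channels) is spent. Each read costs capture overhead
# plus emitted_length / speed, plus the unblock overhead when rejected.
.simulate_reads_pore_time <- function(preset, pt, run_id) {
  budget <- pt$duration_s * (pt$n_channels %||% 512)
  speed <- pt$speed_bp_s %||% 450
  capture <- pt$capture_s %||% 1
  unblock <- pt$unblock_s %||% 0.5
  chunks <- list()
  used <- 0
  total <- 0L
  chunk_n <- 10000L
  while (used < budget && total < 5e6) {
    part <- .simulate_reads_fixed_n(preset, chunk_n, paste0(run_id, "c", length(chunks)))
    cost <- capture + part$reads$length_bp / speed +
      unblock * (part$truth$category == "rejected")
    cum <- used + cumsum(cost)
    keep <- cum <= budget
    if (!any(keep)) break
    part$reads <- part$reads[keep]
    part$truth <- part$truth[keep]
    chunks[[length(chunks) + 1L]] <- part
    used <- cum[max(which(keep))]
    total <- total + nrow(part$reads)
    if (!all(keep)) break
  }
  if (total == 0L) stop_poresift("pore-time budget too small to emit any read")
  reads <- rbindlist(lapply(chunks, `[[`, "reads"))
  truth <- rbindlist(lapply(chunks, `[[`, "truth"))
  ids <- sprintf("%s-%07d", run_id, seq_len(nrow(reads)))
  reads[, read_id := ids]
  truth[, read_id := ids]
  list(reads = reads, truth = truth)
}

# ---- cohort -----------------------------------------------------------------

#' Deterministic per-sample parameter values around a cohort mean
#'
#' Builds `n` values as `m + s * z_i` with `z_i` the symmetric standard
#' normal quantiles at `p = (i - 0.5) / n`, clips them to `[lo, hi]`, and
#' shifts the non-clipped values affinely (iterating if the shift clips new
#' values) so the arithmetic mean equals `m` exactly.
#'
#' @param m Target mean.
#' @param s Spread (standard-deviation-like scale).
#' @param n Number of values (default 15).
#' @param lo,hi Valid range.
#' @return Numeric vector of length `n` with mean exactly `m` (up to
#'   floating point), unless the range makes that impossible.
#' @export
cohort_param_values <- function(m, s, n = 15L, lo = -Inf, hi = Inf) {
  z <- qnorm((seq_len(n) - 0.5) / n)
  v <- m + s * z
  for (it in 1:50) {
    v <- pmin(pmax(v, lo), hi)
    free <- v > lo & v < hi
    gap <- m * n - sum(v)
    if (abs(gap) < 1e-12) break
    if (!any(free)) {
      warning("all values clipped; cohort mean cannot be preserved", call. = FALSE)
      break
    }
    v[free] <- v[free] + gap / sum(free)
  }
  v
}

# Fixed (mean, sd) pairs behind the cohort15 preset.
.cohort15_params <- list(
  control_human = c(m = 97.59, s = 7.63),
  rejected_pct = c(m = 92.05, s = 7.42),
  rejected_human = c(m = 99.80, s = 0.09),
  fold = c(m = 1.70, s = 0.27)
)

#' Simulate a paired control/depletion cohort
#'
#' Generates `n_samples` paired runs following the `cohort15` preset:
#' per-sample parameters (control human %, rejected %, rejected-fraction
#' human %, depletion/control read-count fold) are the deterministic
#' quantile constructions of [cohort_param_values()] around the cohort
#' means 97.59 (s 7.63), 92.05 (s 7.42), 99.80 (s 0.09) and 1.70 (s 0.27);
#' both members of a pair share the sample's bacterial genus composition
#' (a per-sample Dirichlet draw around the default split). The kept
#' fraction of each depletion run is split accepted : no-decision =
#' 0.041 : 0.959 with per-category human fractions 1.23 % (accepted) and
#' 25.06 % (no decision).
#'
#' @param preset Cohort preset name; only `"cohort15"` is defined.
#' @param n_reads Reads per control run (default 50000); the paired
#'   depletion run gets `round(n_reads * fold_i)` reads.
#' @param seed Integer seed; per-run child seeds are derived from it.
#' @param n_samples Number of pairs (default 15).
#' @param outdir Optional directory for per-run files.
#' @param payload Passed to [simulate_run()].
#' @return List of class `sim_cohort`: `samples` (list with `sample_id`,
#'   `params`, `control`, `depletion`), `params` (the per-sample parameter
#'   table) and `seed`.
#' @export
simulate_cohort <- function(preset = "cohort15", n_reads = 50000L, seed = 1,
                            n_samples = 15L, outdir = NULL,
                            payload = FALSE) {
  if (!identical(preset, "cohort15")) {
    stop_poresift("unknown cohort preset '%s'; valid cohort presets: cohort15", preset)
  }
  p <- .cohort15_params
  params <- data.table(
    sample_id = sprintf("s%02d", seq_len(n_samples)),
    control_human = cohort_param_values(p$control_human["m"], p$control_human["s"],
                                        n_samples, 0, 100),
    rejected_pct = cohort_param_values(p$rejected_pct["m"], p$rejected_pct["s"],
                                       n_samples, 0, 100),
    rejected_human = cohort_param_values(p$rejected_human["m"], p$rejected_human["s"],
                                         n_samples, 0, 100),
    fold = cohort_param_values(p$fold["m"], p$fold["s"], n_samples, 0.1, Inf)
  )
  seeds <- derive_seeds(seed, 3L * n_samples)
  accepted_share <- 0.041
  samples <- lapply(seq_len(n_samples), function(i) {
    sid <- params$sample_id[i]
    # shared per-sample genus composition
    split <- with_seed(seeds[3L * i - 2L], {
      alpha <- 8 * .default_microbial_split
      g <- stats::rgamma(length(alpha), shape = alpha)
      setNames(g / sum(g), names(alpha))
    })
    ctrl_preset <- sim_preset(
      paste0(sid, "_control"), mode = "control",
      human_frac = params$control_human[i] / 100,
      microbial_split = split)
    rej <- params$rejected_pct[i] / 100
    depl_preset <- sim_preset(
      paste0(sid, "_depletion"), mode = "category",
      category_probs = c(rejected = rej,
                         accepted = (1 - rej) * accepted_share,
                         no_decision = (1 - rej) * (1 - accepted_share)),
      human_frac = c(rejected = params$rejected_human[i] / 100,
                     accepted = 0.0123, no_decision = 0.2506),
      microbial_split = split)
    sub <- if (is.null(outdir)) NULL else file.path(outdir, sid)
    list(
      sample_id = sid,
      params = as.list(params[i]),
      control = simulate_run(ctrl_preset, n_reads = n_reads,
                             seed = seeds[3L * i - 1L], outdir = sub,
                             payload = payload, run_id = paste0(sid, "_control")),
      depletion = simulate_run(depl_preset,
                               n_reads = max(1L, as.integer(round(n_reads * params$fold[i]))),
                               seed = seeds[3L * i], outdir = sub,
                               payload = payload, run_id = paste0(sid, "_depletion"))
    )
  })
  structure(list(samples = samples, params = params, seed = seed),
            class = "sim_cohort")
}

# ---- mock community ---------------------------------------------------------

#' Simulate mock-community alignments
#'
#' Draws each read's organism proportionally to `expected * bias`, draws an
#' aligned span from the read-length distribution and emits one primary
#' PAF-style alignment record per read. Organisms absent from `bias`
#' default to bias 1.
#'
#' @param expected Named expected fractions (sum 1).
#' @param bias Optional named fold-bias vector.
#' @param n_reads Number of reads (default 5000).
#' @param seed Integer seed.
#' @param read_length `(median, sdlog)` of the span distribution.
#' @param outdir Optional directory; writes `mock.paf` and
#'   `mock.truth.tsv`.
#' @return List with `alignments` (usable by [representation()]), `truth`,
#'   and `files` when written.
#' @export
simulate_mock <- function(expected, bias = NULL, n_reads = 5000L, seed = 1,
                          read_length = c(median = 2500, sdlog = 0.55),
                          outdir = NULL) {
  if (abs(sum(expected) - 1) > 1e-6) {
    stop_poresift("expected fractions sum to %.6f, not 1", sum(expected))
  }
  b <- setNames(rep(1, length(expected)), names(expected))
  if (!is.null(bias)) b[names(bias)] <- bias
  w <- expected * b
  out <- with_seed(seed, {
    organism <- sample(names(expected), n_reads, replace = TRUE, prob = w)
    span <- draw_lengths(n_reads, read_length)
    data.table(
      read_id = sprintf("mock-%07d", seq_len(n_reads)),
      target = organism, target_span = span,
      is_primary = TRUE, mapq = 60L
    )
  })
  truth <- out[, .(read_id, organism = target, span = target_span)]
  files <- NULL
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    files <- c(paf = file.path(outdir, "mock.paf"),
               truth = file.path(outdir, "mock.truth.tsv"))
    write_paf(out, files[["paf"]])
    fwrite(truth, files[["truth"]], sep = "\t")
  }
  list(alignments = out[], truth = truth[], files = files)
}
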