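# Run-level accounting: total/rejected reads and bases, microbial bases in
# the kept (accepted + no-decision) fractions, fold changes between runs,
# bp-to-decision distributions, and paired-cohort summaries.

kept_categories <- c("accepted", "no_decision", "control")

#' Summarize one sequencing run
#'
#' Computes the standard yield table for one run: total reads and bases,
#' reads per decision category, rejected percentage, microbial bases, and
#' median read lengths overall and per category. Microbial bases are
#' counted only over reads in the kept fractions (`accepted`,
#' `no_decision`; all reads of a control run count as kept) whose lineage
#' matches the microbial definition.
#'
#' @param cat_reads Output of [categorize()].
#' @param assignments Optional assignment table (`read_id`, `taxid`);
#'   reads without an assignment count as unclassified.
#' @param lineage Optional `lineage_map`; required when `assignments` is
#'   given.
#' @param run_id Label stored in the summary.
#' @param microbial `"bacteria_archaea"` (default: superkingdom Bacteria or
#'   Archaea) or `"non_human_classified"` (anything classified that is not
#'   human).
#' @return A list of class `run_summary`.
#' @export
summarize_run <- function(cat_reads, assignments = NULL, lineage = NULL,
                          run_id = "run",
                          microbial = c("bacteria_archaea", "non_human_classified")) {
  microbial <- match.arg(microbial)
  dt <- as.data.table(cat_reads)
  if (nrow(dt) == 0L) stop_poresift("empty run")
  counts <- dt[, .N, by = category]
  getn <- function(cat) {
    i <- match(cat, counts$category)
    if (is.na(i)) 0L else counts$N[i]
  }
  total_reads <- nrow(dt)
  rejected_reads <- getn("rejected")
  microbial_bases <- NA_real_
  classified_frac <- NA_real_
  if (!is.null(assignments)) {
    if (is.null(lineage)) stop_poresift("'lineage' is required when assignments are given")
    a <- as.data.table(assignments)[, .(read_id, taxid)]
    m <- merge(dt, a, by = "read_id", all.x = TRUE, sort = FALSE)
    m[is.na(taxid), taxid := 0L]  # unassigned reads count as unclassified
    lin <- lookup_lineage(lineage, m$taxid)
    is_microbial <- switch(microbial,
      bacteria_archaea = lin$superkingdom %in% c("Bacteria", "Archaea"),
      non_human_classified = !lin$is_human &
        !lin$superkingdom %in% c("unclassified", "unresolved"))
    kept <- m$category %in% kept_categories
    microbial_bases <- sum(as.numeric(m$length_bp)[kept & is_microbial])
    classified_frac <-
      1 - sum(lin$superkingdom %in% c("unclassified", "unresolved")) / total_reads
  }
  med_by_cat <- dt[, .(med = as.numeric(median(length_bp))), by = category]
  structure(list(
    run_id = run_id,
    total_reads = total_reads,
    total_bases = sum(as.numeric(dt$length_bp)),
    rejected_reads = rejected_reads,
    rejected_pct = round_pct(100 * rejected_reads / total_reads),
    accepted_reads = getn("accepted"),
    no_decision_reads = getn("no_decision"),
    control_reads = getn("control"),
    microbial_bases = microbial_bases,
    microbial_definition = microbial,
    classified_fraction = classified_frac,
    median_read_length = as.numeric(median(dt$length_bp)),
    median_read_length_by_category = setNames(med_by_cat$med, med_by_cat$category)
  ), class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("Run '%s': %d reads, %.3g bases\n", x$run_id, x$total_reads, x$total_bases))
  cat(sprintf("  rejected %d (%.2f%%), accepted %d, no_decision %d, control %d\n",
              x$rejected_reads, x$rejected_pct, x$accepted_reads,
              x$no_decision_reads, x$control_reads))
  if (!is.na(x$microbial_bases)) {
    cat(sprintf("  microbial bases (kept fractions, %s): %.3g\n",
                x$microbial_definition, x$microbial_bases))
  }
  invisible(x)
}

#' Fold change of a run metric between two runs
#'
#' @param numerator,denominator `run_summary` objects or plain numbers.
#' @param field Field name used when summaries are passed
#'   (default `"total_reads"`).
#' @return The plain ratio (report layers round to 2 decimals).
#' @export
fold_change <- function(numerator, denominator, field = "total_reads") {
  val <- function(x) {
    if (inherits(x, "run_summary")) {
      v <- x[[field]]
      if (is.null(v)) stop_poresift("unknown run_summary field '%s'", field)
      v
    } else as.numeric(x)
  }
  a <- val(numerator); b <- val(denominator)
  if (!is.finite(b) || b == 0) stop_poresift("fold_change: zero or invalid denominator")
  a / b
}

#' Distribution of bases sequenced until the decision, per category
#'
#' Summarizes `bp_to_decision` per decision category as quantiles
#' (p5/p25/p50/p75/p95) and a fixed-width histogram. When no read carries
#' `bp_to_decision`, the read length of rejected reads is used as a proxy
#' (rejected reads are truncated at the decision) and the summary is
#' flagged accordingly.
#'
#' @param cat_reads Output of [categorize()].
#' @param bin_width Histogram bin width in bp (default 100).
#' @return Named list per category, each with `n`, `quantiles`,
#'   `histogram` (`breaks`, `counts`) and `proxy_used`.
#' @export
decision_length_distribution <- function(cat_reads, bin_width = 100) {
  dt <- as.data.table(cat_reads)
  proxy <- FALSE
  if (all(is.na(dt$bp_to_decision))) {
    dt <- dt[category == "rejected"]
    if (nrow(dt) == 0L) return(structure(list(), proxy_used = FALSE))
    dt[, bp_to_decision := length_bp]
    proxy <- TRUE
  }
  dt <- dt[!is.na(bp_to_decision)]
  out <- lapply(split(dt$bp_to_decision, dt$category), function(v) {
    q <- quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE, type = 7)
    breaks <- seq(0, (max(v) %/% bin_width + 1) * bin_width, by = bin_width)
    list(n = length(v),
         quantiles = setNames(q, c("p5", "p25", "p50", "p75", "p95")),
         histogram = list(breaks = breaks,
                          counts = tabulate(pmin(v %/% bin_width + 1L,
                                                 length(breaks) - 1L),
                                            nbins = length(breaks) - 1L)),
         proxy_used = proxy)
  })
  attr(out, "proxy_used") <- proxy
  out
}

#' Summarize a paired control/depletion cohort
#'
#' Takes one record per sample, each holding the control and depletion
#' [summarize_run()] outputs and (optionally) the matching
#' [category_content()] tables, and computes per-sample read-count folds
#' (rejected reads included), category percentages, and cohort aggregates
#' as mean plus/minus the sample standard deviation (n - 1). Per-category
#' human/bacterial means exclude samples whose category holds fewer than
#' `min_category_reads` reads; the excluded sample ids are reported.
#'
#' @param records List of per-sample lists with elements `sample_id`,
#'   `control` (`run_summary`), `depletion` (`run_summary`), and optionally
#'   `control_content` / `depletion_content` (from [category_content()]).
#' @param min_category_reads Exclusion threshold (default 100, reads).
#' @return A list of class `cohort_summary` with `per_sample`
#'   (a `data.table`), `aggregates` and `excluded`.
#' @export
cohort_summary <- function(records, min_category_reads = 100) {
  if (length(records) < 2L) stop_poresift("cohort_summary needs at least 2 sample pairs")
  per <- rbindlist(lapply(records, function(r) {
    stopifnot(inherits(r$control, "run_summary"), inherits(r$depletion, "run_summary"))
    d <- r$depletion
    row <- data.table(
      sample_id = as.character(r$sample_id),
      control_reads = r$control$total_reads,
      depletion_reads = d$total_reads,
      fold = fold_change(d, r$control, "total_reads"),
      rejected_pct = d$rejected_pct,
      accepted_pct = round_pct(100 * d$accepted_reads / d$total_reads),
      no_decision_pct = round_pct(100 * d$no_decision_reads / d$total_reads),
      accepted_reads = d$accepted_reads,
      no_decision_reads = d$no_decision_reads,
      rejected_reads = d$rejected_reads
    )
    grab <- function(content, cat, col) {
      if (is.null(content)) return(NA_real_)
      ct <- as.data.table(content)
      i <- match(cat, ct$category)
      if (is.na(i)) NA_real_ else ct[[col]][i]
    }
    row[, `:=`(
      control_human_pct = grab(r$control_content, "control", "human_pct"),
      control_bacterial_pct = grab(r$control_content, "control", "bacterial_pct"),
      rejected_human_pct = grab(r$depletion_content, "rejected", "human_pct"),
      rejected_bacterial_pct = grab(r$depletion_content, "rejected", "bacterial_pct"),
      accepted_human_pct = grab(r$depletion_content, "accepted", "human_pct"),
      accepted_bacterial_pct = grab(r$depletion_content, "accepted", "bacterial_pct"),
      no_decision_human_pct = grab(r$depletion_content, "no_decision", "human_pct"),
      no_decision_bacterial_pct = grab(r$depletion_content, "no_decision", "bacterial_pct")
    )]
    row
  }))
  mean_sd <- function(v) {
    v <- v[!is.na(v)]
    c(mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
      n = length(v))
  }
  excluded <- list()
  cat_mean <- function(cat) {
    keep <- per[[paste0(cat, "_reads")]] >= min_category_reads
    excluded[[cat]] <<- per$sample_id[!keep]
    list(human = mean_sd(per[[paste0(cat, "_human_pct")]][keep]),
         bacterial = mean_sd(per[[paste0(cat, "_bacterial_pct")]][keep]))
  }
  aggregates <- list(
    fold = mean_sd(per$fold),
    rejected_pct = mean_sd(per$rejected_pct),
    accepted_pct = mean_sd(per$accepted_pct),
    no_decision_pct = mean_sd(per$no_decision_pct),
    control_human_pct = mean_sd(per$control_human_pct),
    control_bacterial_pct = mean_sd(per$control_bacterial_pct),
    rejected_content = cat_mean("rejected"),
    accepted_content = cat_mean("accepted"),
    no_decision_content = cat_mean("no_decision")
  )
  structure(list(per_sample = per, aggregates = aggregates,
                 excluded = excluded,
                 min_category_reads = min_category_reads),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  a <- x$aggregates
  cat(sprintf("Cohort of %d sample pairs\n", nrow(x$per_sample)))
  cat(sprintf("  read-count fold (depletion/control): %.2f +/- %.2f\n",
              a$fold["mean"], a$fold["sd"]))
  cat(sprintf("  rejected %%: %.2f +/- %.2f\n",
              a$rejected_pct["mean"], a$rejected_pct["sd"]))
  if (!is.na(a$control_human_pct["mean"])) {
    cat(sprintf("  control human %%: %.2f +/- %.2f\n",
                a$control_human_pct["mean"], a$control_human_pct["sd"]))
    cat(sprintf("  rejected-fraction human %%: %.2f +/- %.2f (excluded: %s)\n",
                a$rejected_content$human["mean"], a$rejected_content$human["sd"],
                if (length(x$excluded$rejected)) paste(x$excluded$rejected, collapse = ",")
                else "none"))
  }
  invisible(x)
}
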