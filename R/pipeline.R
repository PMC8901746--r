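# Convenience drivers that chain the modules the way the subcommands and
# the acceptance analyses use them.

#' Analyze one simulated run with the zero-error oracle
#'
#' Chains categorize -> oracle_classify -> summarize_run ->
#' category_content for one [simulate_run()] result.
#'
#' @param sim A [simulate_run()] result.
#' @param lineage A `lineage_map` (default [example_lineage()]).
#' @param misclassification_rate,unclassified_rate Oracle corruption rates.
#' @param oracle_seed Seed for oracle corruption draws.
#' @return List with `cat_reads`, `assignments`, `summary`, `content`.
#' @export
analyze_sim_run <- function(sim, lineage = example_lineage(),
                            misclassification_rate = 0,
                            unclassified_rate = 0, oracle_seed = 1) {
  cat_reads <- categorize(sim$reads, sim$decisions)
  assignments <- oracle_classify(sim$truth,
                                 misclassification_rate = misclassification_rate,
                                 unclassified_rate = unclassified_rate,
                                 seed = oracle_seed)
  list(
    cat_reads = cat_reads,
    assignments = assignments,
    summary = summarize_run(cat_reads, assignments, lineage,
                            run_id = sim$preset$name),
    content = category_content(cat_reads, assignments, lineage)
  )
}

#' Analyze a simulated cohort end to end
#'
#' Runs every paired control/depletion run of a [simulate_cohort()] result
#' through the categorize / oracle-classify / summarize / content chain,
#' builds the cohort summary, per-sample genus abundance tables (bacteria
#' only, proportions over all reads including rejected) and the pairwise
#' concordance report.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param lineage A `lineage_map`.
#' @param min_reads Abundance-table filter (default 30 reads).
#' @param min_category_reads Cohort category exclusion threshold
#'   (default 100 reads).
#' @return List with `records` (per-sample analysis pieces), `summary`
#'   (a [cohort_summary()]) and `pair_report`.
#' @export
analyze_cohort <- function(cohort, lineage = example_lineage(),
                           min_reads = 30, min_category_reads = 100) {
  stopifnot(inherits(cohort, "sim_cohort"))
  records <- lapply(cohort$samples, function(s) {
    ctrl <- analyze_sim_run(s$control, lineage)
    depl <- analyze_sim_run(s$depletion, lineage)
    tab_ctrl <- abundance_table(ctrl$cat_reads, ctrl$assignments, lineage,
                                rank = "genus", superkingdoms = "Bacteria",
                                min_reads = min_reads,
                                run_id = paste0(s$sample_id, "_control"))
    tab_depl <- abundance_table(depl$cat_reads, depl$assignments, lineage,
                                rank = "genus", superkingdoms = "Bacteria",
                                min_reads = min_reads,
                                run_id = paste0(s$sample_id, "_depletion"))
    list(sample_id = s$sample_id,
         control = ctrl$summary, depletion = depl$summary,
         control_content = ctrl$content, depletion_content = depl$content,
         pairs = paired_abundance(tab_ctrl, tab_depl))
  })
  pairs <- setNames(lapply(records, `[[`, "pairs"),
                    vapply(records, `[[`, character(1), "sample_id"))
  list(records = records,
       summary = cohort_summary(records, min_category_reads = min_category_reads),
       pair_report = pair_report(pairs))
}
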