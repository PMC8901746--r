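# Abundance tables at a chosen rank with the minimum-read filter and
# explicit denominator policy, and per-category human/bacterial content.

#' Build a filtered abundance table at a taxonomic rank
#'
#' Counts reads per taxon at `rank` and converts them to proportions under
#' an explicit denominator policy: `all_reads_incl_rejected` divides by the
#' total number of reads in the run (rejected reads included) — the
#' convention used when comparing depletion runs with controls — while
#' `category_reads` divides by the number of reads in the selected
#' categories only. Taxa with fewer than `min_reads` reads are dropped to
#' avoid over-interpreting uncertain classifications (default 30); the
#' dropped read mass is recorded. Rows are sorted by count descending,
#' ties alphabetically.
#'
#' @param cat_reads Output of [categorize()].
#' @param assignments Assignment table (`read_id`, `taxid`).
#' @param lineage A `lineage_map`.
#' @param rank `"genus"`, `"species"` or `"superkingdom"`.
#' @param denominator_policy `"all_reads_incl_rejected"` (default) or
#'   `"category_reads"`.
#' @param categories Categories whose reads are counted (default: all
#'   categories present in the run).
#' @param superkingdoms Optional filter, e.g. `"Bacteria"` to tabulate
#'   bacterial genera only.
#' @param min_reads Minimum reads for a taxon to be listed (default 30).
#' @param run_id Label stored with the table.
#' @return A `data.table` of class `abundance_table` with columns `taxon`,
#'   `count`, `proportion`; attributes `run_id`, `rank`, `denominator`,
#'   `denominator_policy`, `min_reads`, `dropped_reads`, `dropped_taxa`.
#' @export
abundance_table <- function(cat_reads, assignments, lineage,
                            rank = c("genus", "species", "superkingdom"),
                            denominator_policy = c("all_reads_incl_rejected",
                                                   "category_reads"),
                            categories = NULL, superkingdoms = NULL,
                            min_reads = 30, run_id = "run") {
  rank <- match.arg(rank)
  denominator_policy <- match.arg(denominator_policy)
  dt <- as.data.table(cat_reads)
  if (is.null(categories)) categories <- unique(dt$category)
  total_reads <- nrow(dt)
  sel <- dt[category %in% categories]
  m <- merge(sel[, .(read_id)], as.data.table(assignments)[, .(read_id, taxid)],
             by = "read_id", all.x = TRUE, sort = FALSE)
  m[is.na(taxid), taxid := 0L]
  lin <- lookup_lineage(lineage, m$taxid)
  m[, taxon := lin[[rank]]]
  m[, superkingdom := lin$superkingdom]
  if (!is.null(superkingdoms)) m <- m[superkingdom %in% superkingdoms]
  m <- m[!is.na(taxon)]
  tab <- m[, .(count = .N), by = taxon]
  denominator <- switch(denominator_policy,
    all_reads_incl_rejected = total_reads,
    category_reads = nrow(sel))
  dropped <- tab[count < min_reads]
  tab <- tab[count >= min_reads]
  setorder(tab, -count, taxon)
  tab[, proportion := count / denominator]
  out <- tab[, .(taxon, count, proportion)]
  attr(out, "run_id") <- run_id
  attr(out, "rank") <- rank
  attr(out, "denominator") <- denominator
  attr(out, "denominator_policy") <- denominator_policy
  attr(out, "min_reads") <- min_reads
  attr(out, "dropped_reads") <- sum(dropped$count)
  attr(out, "dropped_taxa") <- nrow(dropped)
  class(out) <- c("abundance_table", class(out))
  out[]
}

#' Write an abundance table as TSV with a provenance header comment
#' @param tab An `abundance_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(tab, path) {
  hdr <- sprintf(
    "# run_id=%s rank=%s denominator=%d denominator_policy=%s min_reads=%d dropped_reads=%d",
    attr(tab, "run_id"), attr(tab, "rank"), attr(tab, "denominator"),
    attr(tab, "denominator_policy"), attr(tab, "min_reads"),
    attr(tab, "dropped_reads"))
  writeLines(hdr, path)
  fwrite(as.data.table(tab)[, .(taxon, count, proportion)], path, sep = "\t",
         append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read an abundance table written by [write_abundance_table()]
#' @param path TSV path.
#' @return An `abundance_table` (attributes restored from the header
#'   comment).
#' @export
read_abundance_table <- function(path) {
  hdr <- readLines(path, n = 1L)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  meta <- setNames(sub("^[a-z_]+=", "", kv), sub("=.*$", "", kv))
  out <- fread(path, sep = "\t", skip = 1L, header = TRUE)
  for (a in c("run_id", "denominator_policy", "rank")) attr(out, a) <- unname(meta[a])
  for (a in c("denominator", "min_reads", "dropped_reads")) {
    attr(out, a) <- as.integer(meta[a])
  }
  class(out) <- c("abundance_table", class(out))
  out[]
}

#' Human / bacterial / other / unclassified content per decision category
#'
#' For every category present in the run, computes the percentage of reads
#' whose lineage is human, bacterial, other (classified, neither human nor
#' bacterial) or unclassified, with the category's own read count as the
#' denominator. For decision-log runs a synthetic `kept` row aggregates the
#' accepted and no-decision fractions (the reads actually retained by
#' depletion). Categories holding fewer than `min_category_reads` reads are
#' flagged: their percentages rest on too few reads to be meaningful.
#'
#' @param cat_reads Output of [categorize()].
#' @param assignments Assignment table (`read_id`, `taxid`).
#' @param lineage A `lineage_map`.
#' @param min_category_reads Flagging threshold (default 100).
#' @return A `data.table` with columns `category`, `n_reads`, `human_pct`,
#'   `bacterial_pct`, `other_pct`, `unclassified_pct`, `flagged`.
#' @export
category_content <- function(cat_reads, assignments, lineage,
                             min_category_reads = 100) {
  dt <- as.data.table(cat_reads)
  m <- merge(dt[, .(read_id, category)],
             as.data.table(assignments)[, .(read_id, taxid)],
             by = "read_id", all.x = TRUE, sort = FALSE)
  m[is.na(taxid), taxid := 0L]
  lin <- lookup_lineage(lineage, m$taxid)
  m[, bucket := "other"]
  m[lin$is_human, bucket := "human"]
  m[!lin$is_human & lin$superkingdom == "Bacteria", bucket := "bacterial"]
  m[lin$superkingdom %in% c("unclassified", "unresolved"), bucket := "unclassified"]
  tally <- function(sub, label) {
    n <- nrow(sub)
    data.table(
      category = label, n_reads = n,
      human_pct = round_pct(100 * sum(sub$bucket == "human") / n),
      bacterial_pct = round_pct(100 * sum(sub$bucket == "bacterial") / n),
      other_pct = round_pct(100 * sum(sub$bucket == "other") / n),
      unclassified_pct = round_pct(100 * sum(sub$bucket == "unclassified") / n)
    )
  }
  parts <- lapply(split(m, m$category), function(s) tally(s, s$category[1L]))
  out <- rbindlist(parts)
  if (all(c("accepted", "no_decision") %in% out$category) ||
      ("rejected" %in% out$category &&
       any(c("accepted", "no_decision") %in% out$category))) {
    out <- rbind(out, tally(m[category %in% c("accepted", "no_decision")], "kept"))
  }
  out[, flagged := n_reads < min_category_reads]
  out[]
}
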