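# Shared fixture builders: everything is generated in code at test time.

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Minimal well-formed FASTQ text for given ids/sequences.
fastq_lines <- function(ids, seqs) {
  unlist(mapply(function(id, s) {
    c(paste0("@", id), s, "+", strrep("I", nchar(s)))
  }, ids, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE))
}

# Decision-log CSV text in the accepted dialect.
decision_csv_lines <- function(read_id, decision, channel = NULL, bp = NULL) {
  hdr <- "read_id,channel,decision,sequence_length"
  channel <- channel %||% rep("", length(read_id))
  bp <- bp %||% rep("", length(read_id))
  c(hdr, paste(read_id, channel, decision, bp, sep = ","))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tiny categorized-read table built directly (bypasses parsing).
make_cat_reads <- function(read_id, length_bp, category,
                           bp_to_decision = NA_integer_) {
  data.table::data.table(
    read_id = read_id, length_bp = as.integer(length_bp),
    category = category,
    bp_to_decision = as.integer(bp_to_decision)
  )
}

# Assignment table from parallel vectors.
make_assignments <- function(read_id, taxid) {
  data.table::data.table(read_id = read_id, taxid = as.integer(taxid),
                         score = NA_real_)
}

# Abundance-table-shaped object from named counts (for concordance tests).
make_abund <- function(counts, denominator = sum(counts)) {
  dt <- data.table::data.table(taxon = names(counts),
                               count = as.integer(counts),
                               proportion = as.numeric(counts) / denominator)
  data.table::setorder(dt, -count, taxon)
  attr(dt, "denominator") <- denominator
  attr(dt, "min_reads") <- 30L
  class(dt) <- c("abundance_table", class(dt))
  dt
}

# Depletion-invariant paired scenario: two independent draws of the same
# moderate-host composition, analysed as a control/depletion pair. Genus
# fractions are even and large enough that per-taxon counts are well
# powered at n = 50k.
invariant_preset <- function() {
  sim_preset("invariant", mode = "control", human_frac = 0.5,
             microbial_split = c(Lactobacillus = 0.3, Gardnerella = 0.3,
                                 Ureaplasma = 0.2, Prevotella = 0.2))
}

invariant_pair <- function(n, seed_a, seed_b, min_reads = 30) {
  lin <- example_lineage()
  tabs <- lapply(c(seed_a, seed_b), function(s) {
    res <- analyze_sim_run(simulate_run(invariant_preset(), n_reads = n, seed = s))
    abundance_table(res$cat_reads, res$assignments, lin, rank = "genus",
                    superkingdoms = "Bacteria", min_reads = min_reads)
  })
  paired_abundance(tabs[[1]], tabs[[2]])
}
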