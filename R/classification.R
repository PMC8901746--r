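# Per-read taxonomic classifications (centrifuge / kraken2 / plain TSV),
# the taxid -> lineage map, and the truth-table oracle classifier used for
# synthetic runs in place of a real classification engine.

#' Read a per-read taxonomic classification table
#'
#' Supports three dialects:
#' * `centrifuge`: header with columns `readID`, `seqID`, `taxID`, `score`,
#'   further columns ignored; a read may have several hit rows.
#' * `kraken2`: headerless, columns (C/U flag, read id, taxid, length, ...).
#' * `plain`: header with columns `read_id`, `taxid` and optionally `score`.
#'
#' Multi-row reads are resolved to one assignment: the highest-scoring row
#' wins. Equal best scores pointing at different taxids are demoted to
#' taxid 0 (unclassified) rather than inventing a consensus; the number of
#' such ties is kept in the `tie_count` attribute. Without a score column,
#' duplicate rows that disagree on the taxid are treated the same way.
#'
#' @param path Path to the TSV file.
#' @param dialect One of `"centrifuge"`, `"kraken2"`, `"plain"`.
#' @return A `data.table` with one row per read: `read_id`, `taxid`,
#'   `score` (NA when the dialect has none); attribute `tie_count`.
#' @export
read_classification <- function(path,
                                dialect = c("centrifuge", "kraken2", "plain")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_poresift("classification file not found: %s", path)
  raw <- switch(dialect,
    centrifuge = {
      dt <- fread(path, header = TRUE, sep = "\t")
      nm <- tolower(names(dt))
      need <- c("readid", "taxid")
      miss <- setdiff(need, nm)
      if (length(miss)) {
        stop_poresift("centrifuge table '%s' is missing column(s): %s", path,
                      paste(miss, collapse = ", "))
      }
      data.table(read_id = as.character(dt[[which(nm == "readid")[1L]]]),
                 taxid_raw = dt[[which(nm == "taxid")[1L]]],
                 score = if ("score" %in% nm)
                   as.numeric(dt[[which(nm == "score")[1L]]]) else NA_real_)
    },
    kraken2 = {
      dt <- fread(path, header = FALSE, sep = "\t")
      if (ncol(dt) < 3L) stop_poresift("kraken2 table '%s' has fewer than 3 columns", path)
      data.table(read_id = as.character(dt[[2L]]),
                 taxid_raw = dt[[3L]],
                 score = NA_real_)
    },
    plain = {
      dt <- fread(path, header = TRUE, sep = "\t")
      nm <- tolower(names(dt))
      miss <- setdiff(c("read_id", "taxid"), nm)
      if (length(miss)) {
        stop_poresift("plain classification table '%s' is missing column(s): %s",
                      path, paste(miss, collapse = ", "))
      }
      data.table(read_id = as.character(dt[[which(nm == "read_id")[1L]]]),
                 taxid_raw = dt[[which(nm == "taxid")[1L]]],
                 score = if ("score" %in% nm)
                   as.numeric(dt[[which(nm == "score")[1L]]]) else NA_real_)
    })
  tax_num <- suppressWarnings(as.numeric(raw$taxid_raw))
  bad <- which(is.na(tax_num) | tax_num != floor(tax_num))
  if (length(bad)) {
    stop_poresift("non-integer taxid '%s' at data row %d of '%s'",
                  as.character(raw$taxid_raw[bad[1L]]), bad[1L], path)
  }
  raw[, taxid := as.integer(tax_num)]
  resolve_assignments(raw[, .(read_id, taxid, score)])
}

# Collapse multi-hit rows to one best assignment per read; score ties across
# different taxids become taxid 0 (unclassified).
resolve_assignments <- function(hits) {
  hits <- as.data.table(hits)
  if (!"score" %in% names(hits)) hits[, score := NA_real_]
  hits[, score := ifelse(is.na(score), 0, score)]
  res <- hits[, {
    best <- max(score)
    top <- taxid[score == best]
    if (length(unique(top)) > 1L) {
      .(taxid = 0L, score = best, tied = TRUE)
    } else {
      .(taxid = top[1L], score = best, tied = FALSE)
    }
  }, by = read_id]
  ties <- sum(res$tied)
  if (ties > 0L) {
    message(sprintf("%d read(s) with tied best hits demoted to unclassified", ties))
  }
  out <- res[, .(read_id, taxid, score)]
  attr(out, "tie_count") <- as.integer(ties)
  out[]
}

.unresolved_lineage <- data.table::data.table(
  taxid = NA_integer_, superkingdom = "unresolved",
  genus = NA_character_, species = NA_character_, is_human = FALSE
)

#' Read a taxid-to-lineage map
#'
#' The map is a pre-digested 4-column TSV with header
#' (`taxid`, `superkingdom`, `genus`, `species`); empty strings mean the
#' rank is absent. `is_human` is derived from the lineage (species
#' `Homo sapiens`), never from a hard-coded taxid, so tiny synthetic
#' taxonomies work.
#'
#' @param path Path to the TSV.
#' @return A `data.table` of class `lineage_map` keyed by `taxid` with
#'   columns `taxid`, `superkingdom`, `genus`, `species`, `is_human`.
#' @export
read_lineage_map <- function(path) {
  if (!file.exists(path)) stop_poresift("lineage map not found: %s", path)
  dt <- fread(path, header = TRUE, sep = "\t",
              colClasses = list(character = 2:4))
  nm <- tolower(names(dt))
  miss <- setdiff(c("taxid", "superkingdom", "genus", "species"), nm)
  if (length(miss)) {
    stop_poresift("lineage map '%s' is missing column(s): %s", path,
                  paste(miss, collapse = ", "))
  }
  setnames(dt, nm)
  as_lineage_map(dt)
}

#' Build a lineage map from a data frame
#' @param df Data frame with columns `taxid`, `superkingdom`, `genus`,
#'   `species`.
#' @return A `lineage_map`.
#' @export
as_lineage_map <- function(df) {
  dt <- as.data.table(df)[, .(taxid = as.integer(taxid),
                              superkingdom = as.character(superkingdom),
                              genus = as.character(genus),
                              species = as.character(species))]
  for (col in c("genus", "species")) {
    dt[get(col) == "", (col) := NA_character_]
  }
  dt <- unique(dt)
  dup <- dt[duplicated(taxid), unique(taxid)]
  if (length(dup)) {
    stop_poresift("lineage map has conflicting rows for taxid(s): %s",
                  paste(head(dup, 5L), collapse = ", "))
  }
  if (dt[!is.na(species) & is.na(genus), .N] > 0L) {
    stop_poresift("lineage map has species without genus (rank order violated)")
  }
  dt[, is_human := !is.na(species) & species == "Homo sapiens"]
  setkeyv(dt, "taxid")
  class(dt) <- c("lineage_map", class(dt))
  dt[]
}

#' Write a lineage map to TSV
#' @param map A `lineage_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lineage_map <- function(map, path) {
  fwrite(as.data.table(map)[, .(taxid, superkingdom, genus, species)],
         path, sep = "\t", na = "")
  invisible(path)
}

#' Look up lineages for a vector of taxids
#'
#' Unknown taxids resolve to the sentinel "unresolved" lineage
#' (superkingdom `"unresolved"`, `is_human = FALSE`) so that lookups are
#' total; taxid 0 resolves to the "unclassified" sentinel.
#'
#' @param map A `lineage_map`.
#' @param taxids Integer vector.
#' @return A `data.table` with one row per input taxid, columns as the map.
#' @export
lookup_lineage <- function(map, taxids) {
  dt <- as.data.table(map)[data.table(taxid = as.integer(taxids)), on = "taxid"]
  dt[is.na(superkingdom) & taxid == 0L,
     `:=`(superkingdom = "unclassified", is_human = FALSE)]
  dt[is.na(superkingdom), `:=`(superkingdom = "unresolved", is_human = FALSE)]
  dt[is.na(is_human), is_human := FALSE]
  dt[]
}

#' Classify synthetic reads from their truth table
#'
#' Stand-in for a real classifier on simulator output: each read is
#' assigned its true taxid, optionally corrupted by a misclassification
#' rate (the read gets a different taxid drawn uniformly from the other
#' taxids in the truth table) and an unclassified rate (taxid 0). The two
#' corruptions are mutually exclusive per read; their rates must sum to at
#' most 1.
#'
#' @param truth Truth table from the simulator (or a path to a truth TSV):
#'   needs columns `read_id`, `taxid`.
#' @param misclassification_rate,unclassified_rate Per-read corruption
#'   probabilities (defaults 0, i.e. a perfect oracle).
#' @param seed RNG seed used when any rate is positive.
#' @param read_ids Optional vector of read ids actually present in the
#'   FASTQ; truth rows without a match trigger a warning.
#' @return Assignments `data.table` (`read_id`, `taxid`, `score = NA`).
#' @export
oracle_classify <- function(truth, misclassification_rate = 0,
                            unclassified_rate = 0, seed = NULL,
                            read_ids = NULL) {
  if (is.character(truth) && length(truth) == 1L) truth <- fread(truth, sep = "\t")
  truth <- as.data.table(truth)
  assert_scalar_number(misclassification_rate, "misclassification_rate", 0, 1)
  assert_scalar_number(unclassified_rate, "unclassified_rate", 0, 1)
  if (misclassification_rate + unclassified_rate > 1) {
    stop_poresift("misclassification_rate + unclassified_rate must be <= 1")
  }
  if (!is.null(read_ids)) {
    n_missing <- sum(!truth$read_id %in% read_ids)
    if (n_missing > 0L) {
      warning(sprintf("%d truth-table read(s) missing from the FASTQ", n_missing),
              call. = FALSE)
    }
  }
  out <- truth[, .(read_id, taxid = as.integer(taxid))]
  if (misclassification_rate > 0 || unclassified_rate > 0) {
    pool <- sort(unique(out$taxid))
    with_seed(seed, {
      u <- runif(nrow(out))
      mis <- u < misclassification_rate
      unc <- !mis & u < misclassification_rate + unclassified_rate
      if (any(mis)) {
        if (length(pool) < 2L) {
          stop_poresift("cannot misclassify: truth table holds a single taxid")
        }
        idx <- which(mis)
        # draw a replacement uniformly among the other taxids
        offs <- sample.int(length(pool) - 1L, length(idx), replace = TRUE)
        cur <- match(out$taxid[idx], pool)
        out$taxid[idx] <- pool[((cur - 1L + offs) %% length(pool)) + 1L]
      }
      out$taxid[unc] <- 0L
    })
  }
  out[, score := NA_real_]
  out[]
}

#' Fraction of reads carrying a usable classification
#'
#' One minus the unclassified (taxid 0) plus unresolved (taxid absent from
#' the lineage map) share.
#'
#' @param assignments Assignment table (`read_id`, `taxid`).
#' @param map A `lineage_map`.
#' @return A single number in `[0, 1]`.
#' @export
classified_fraction <- function(assignments, map) {
  a <- as.data.table(assignments)
  if (nrow(a) == 0L) return(NA_real_)
  lin <- lookup_lineage(map, a$taxid)
  1 - sum(lin$superkingdom %in% c("unclassified", "unresolved")) / nrow(a)
}
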