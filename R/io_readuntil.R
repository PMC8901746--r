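# Reading adaptive-sampling run inputs: FASTQ reads and MinKNOW-style
# read_until decision logs, and splitting reads into decision categories.

# Accepted decision-log header names and decision-value synonyms.
# Versioned with the package: changing these is an interface change.
.id_col_names <- c("read_id", "read-id", "id")
.decision_col_names <- c("decision", "action", "end_reason")
.decision_synonyms <- c(
  unblock = "unblock", rejected = "unblock",
  stop_receiving = "stop_receiving", accepted = "stop_receiving",
  stop = "stop_receiving",
  no_decision = "no_decision", proceed = "no_decision", none = "no_decision"
)

#' Decision and read categories
#'
#' Adaptive sampling ("Read Until") emits one of three decisions per read:
#' `unblock` (the molecule is ejected from the pore), `stop_receiving` (the
#' read is accepted and sequenced to completion) and `no_decision` (keep
#' evaluating). Reads of a run with a decision log fall into the matching
#' categories `rejected`, `accepted` and `no_decision`; reads of a run
#' without a log are `control`.
#' @name decision-categories
#' @keywords internal
NULL

decision_levels <- c("unblock", "stop_receiving", "no_decision")
category_levels <- c("accepted", "rejected", "no_decision", "control")

#' Read a FASTQ file of basecalled reads
#'
#' Parses a (optionally gzip-compressed) 4-line-record FASTQ file into a
#' table of read records. Sequence and quality strings are carried as opaque
#' payloads and never re-interpreted; no quality filtering is applied.
#'
#' @param path Path to a FASTQ or FASTQ.gz file.
#' @param payload Keep the `sequence` and `quality` columns (default `TRUE`).
#'   With `payload = FALSE` only `read_id` and `length_bp` are retained,
#'   which is enough for all downstream accounting.
#' @return A `data.table` with columns `read_id`, `length_bp` and, when
#'   `payload` is `TRUE`, `sequence` and `quality`.
#' @details Malformed input (record count not a multiple of four, a header
#'   line not starting with `@`, or sequence/quality length mismatch) raises
#'   an error naming the byte offset of the offending line. Duplicate read
#'   ids raise an error listing the ids.
#' @export
read_fastq <- function(path, payload = TRUE) {
  if (!file.exists(path)) stop_poresift("FASTQ file not found: %s", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  n <- length(lines)
  if (n == 0L) {
    out <- data.table(read_id = character(), length_bp = integer())
    if (payload) {
      out[, sequence := character()]
      out[, quality := character()]
    }
    return(out[])
  }
  if (n %% 4L != 0L) {
    stop_poresift(
      "malformed FASTQ '%s': %d lines is not a multiple of 4 (trailing partial record at byte offset %d)",
      path, n, .byte_offset(lines, (n %/% 4L) * 4L + 1L))
  }
  hdr <- lines[seq(1L, n, by = 4L)]
  seqs <- lines[seq(2L, n, by = 4L)]
  plus <- lines[seq(3L, n, by = 4L)]
  qual <- lines[seq(4L, n, by = 4L)]
  bad_hdr <- which(!startsWith(hdr, "@"))
  if (length(bad_hdr)) {
    i <- bad_hdr[1L]
    stop_poresift("malformed FASTQ '%s': record %d header does not start with '@' (byte offset %d)",
                  path, i, .byte_offset(lines, (i - 1L) * 4L + 1L))
  }
  bad_plus <- which(!startsWith(plus, "+"))
  if (length(bad_plus)) {
    i <- bad_plus[1L]
    stop_poresift("malformed FASTQ '%s': record %d separator line does not start with '+' (byte offset %d)",
                  path, i, .byte_offset(lines, (i - 1L) * 4L + 3L))
  }
  len <- nchar(seqs)
  bad_len <- which(len != nchar(qual))
  if (length(bad_len)) {
    i <- bad_len[1L]
    stop_poresift("malformed FASTQ '%s': record %d sequence/quality length mismatch (byte offset %d)",
                  path, i, .byte_offset(lines, (i - 1L) * 4L + 2L))
  }
  ids <- sub("^@", "", sub("[ \t].*$", "", hdr))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop_poresift("duplicate read_id(s) in '%s': %s", path,
                  paste(head(dup, 5L), collapse = ", "))
  }
  out <- data.table(read_id = ids, length_bp = as.integer(len))
  if (payload) {
    out[, sequence := seqs]
    out[, quality := qual]
  }
  out[]
}

.byte_offset <- function(lines, line_no) {
  if (line_no <= 1L) return(0L)
  sum(nchar(lines[seq_len(line_no - 1L)], type = "bytes") + 1L)
}

#' Write reads to a FASTQ file
#'
#' @param reads A table with `read_id`, `sequence`, `quality`.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  reads <- as.data.table(reads)
  if (!all(c("sequence", "quality") %in% names(reads))) {
    stop_poresift("write_fastq() needs 'sequence' and 'quality' columns (payload was dropped?)")
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (nrow(reads)) {
    block <- paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n", reads$quality)
    writeLines(block, con)
  }
  invisible(path)
}

#' Read an adaptive-sampling decision log
#'
#' Parses a MinKNOW read_until-style CSV. The file must have a header row
#' with a read-id column (one of `read_id`, `read-id`, `id`) and a decision
#' column (one of `decision`, `action`, `end_reason`). Decision values are
#' normalized case-insensitively: `unblock`/`rejected` to `unblock`;
#' `stop_receiving`/`accepted`/`stop` to `stop_receiving`;
#' `no_decision`/`proceed`/`none` to `no_decision`. Optional columns
#' `channel` and `sequence_length` (cumulative basecalled bases at the
#' decision, surfaced as `bp_at_decision`) are kept; other columns are
#' ignored.
#'
#' @param path Path to the CSV file.
#' @return A `data.table` with columns `read_id`, `decision`, `channel`,
#'   `bp_at_decision`, in file order.
#' @export
read_decision_log <- function(path) {
  if (!file.exists(path)) stop_poresift("decision log not found: %s", path)
  dt <- fread(path, header = TRUE, sep = ",", colClasses = list(character = 1L))
  nm <- tolower(names(dt))
  id_col <- which(nm %in% .id_col_names)[1L]
  if (is.na(id_col)) {
    stop_poresift("decision log '%s' is missing a read-id column (accepted names: %s)",
                  path, paste(.id_col_names, collapse = ", "))
  }
  dec_col <- which(nm %in% .decision_col_names)[1L]
  if (is.na(dec_col)) {
    stop_poresift("decision log '%s' is missing a decision column (accepted names: %s)",
                  path, paste(.decision_col_names, collapse = ", "))
  }
  raw <- tolower(as.character(dt[[dec_col]]))
  mapped <- .decision_synonyms[raw]
  bad <- which(is.na(mapped))
  if (length(bad)) {
    i <- bad[1L]
    stop_poresift("decision log '%s': unrecognized decision value '%s' at data row %d (accepted: %s)",
                  path, dt[[dec_col]][i], i,
                  paste(unique(names(.decision_synonyms)), collapse = ", "))
  }
  out <- data.table(
    read_id = as.character(dt[[id_col]]),
    decision = unname(mapped)
  )
  ch_col <- which(nm == "channel")[1L]
  out[, channel := if (!is.na(ch_col)) as.integer(dt[[ch_col]]) else NA_integer_]
  bp_col <- which(nm == "sequence_length")[1L]
  out[, bp_at_decision := if (!is.na(bp_col)) as.integer(dt[[bp_col]]) else NA_integer_]
  out[]
}

#' Write a decision log in the accepted CSV dialect
#' @param decisions Table with `read_id`, `decision`, optionally `channel`
#'   and `bp_at_decision`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_decision_csv <- function(decisions, path) {
  dt <- as.data.table(decisions)
  out <- data.table(
    read_id = dt$read_id,
    channel = if ("channel" %in% names(dt)) dt$channel else NA_integer_,
    decision = dt$decision,
    sequence_length = if ("bp_at_decision" %in% names(dt)) dt$bp_at_decision else NA_integer_
  )
  fwrite(out, path, sep = ",", na = "")
  invisible(path)
}

#' Assign each read its decision category
#'
#' Joins reads to their decision-log records and derives the final category.
#' When a read has several log rows (adaptive sampling re-evaluates in
#' intervals), the last row in file order wins: the log is time-ordered and
#' the final decision supersedes earlier re-evaluations. Mapping:
#' `unblock` to `rejected`, `stop_receiving` to `accepted`, `no_decision`
#' to `no_decision`. Reads present in the FASTQ but absent from the log are
#' classed `no_decision` (sequenced, never decided) with a warning; log
#' records without a matching read are counted and dropped. Without a
#' decision log every read is `control`.
#'
#' @param reads Read table from [read_fastq()] (or the simulator).
#' @param decisions Decision table from [read_decision_log()], or `NULL`
#'   for a control run.
#' @return A `data.table` (class `categorized_reads`) with columns
#'   `read_id`, `length_bp`, `category`, `bp_to_decision`, plus attributes
#'   `n_missing_from_log` and `n_orphan_decisions`.
#' @export
categorize <- function(reads, decisions = NULL) {
  reads <- as.data.table(reads)
  out <- reads[, .(read_id, length_bp)]
  if (is.null(decisions)) {
    out[, category := "control"]
    out[, bp_to_decision := NA_integer_]
    attr(out, "n_missing_from_log") <- 0L
    attr(out, "n_orphan_decisions") <- 0L
    class(out) <- c("categorized_reads", class(out))
    return(out[])
  }
  dec <- as.data.table(decisions)
  last <- dec[, .(decision = decision[.N],
                  bp_at_decision = bp_at_decision[.N]), by = read_id]
  map <- c(unblock = "rejected", stop_receiving = "accepted",
           no_decision = "no_decision")
  last[, category := unname(map[decision])]
  out <- merge(out, last[, .(read_id, category, bp_to_decision = bp_at_decision)],
               by = "read_id", all.x = TRUE, sort = FALSE)
  n_missing <- out[is.na(category), .N]
  if (n_missing > 0L) {
    warning(sprintf("%d read(s) absent from the decision log; classed 'no_decision'",
                    n_missing), call. = FALSE)
    out[is.na(category), category := "no_decision"]
  }
  n_orphan <- last[!out, on = "read_id", .N]
  if (n_orphan > 0L) {
    message(sprintf("%d decision record(s) had no matching read and were dropped", n_orphan))
  }
  attr(out, "n_missing_from_log") <- n_missing
  attr(out, "n_orphan_decisions") <- n_orphan
  class(out) <- c("categorized_reads", class(out))
  out[]
}

#' Split reads into per-category FASTQ files plus a category sidecar
#'
#' Writes one FASTQ per non-empty category and a three-column TSV
#' (`read_id`, `category`, `bp_to_decision`; header line, LF endings).
#'
#' @param cat_reads Output of [categorize()].
#' @param outdir Writable output directory (created if absent).
#' @param reads Optional table carrying `sequence`/`quality` payloads (e.g.
#'   from `read_fastq(path, payload = TRUE)`); required to emit FASTQ.
#'   When omitted and `cat_reads` has no payload, only the sidecar TSV is
#'   written.
#' @return Invisibly, a list with `files` (named paths) and `counts`
#'   (reads per category).
#' @export
split_by_category <- function(cat_reads, outdir, reads = NULL) {
  dt <- as.data.table(cat_reads)
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_poresift("cannot create output directory '%s'", outdir)
  }
  if (file.access(outdir, 2L) != 0L) {
    stop_poresift("output directory '%s' is not writable", outdir)
  }
  payload <- dt
  if (!is.null(reads)) {
    payload <- merge(dt, as.data.table(reads)[, .(read_id, sequence, quality)],
                     by = "read_id", sort = FALSE)
  }
  has_payload <- all(c("sequence", "quality") %in% names(payload))
  sidecar <- file.path(outdir, "categories.tsv")
  fwrite(dt[, .(read_id, category, bp_to_decision)], sidecar, sep = "\t",
         eol = "\n", na = "")
  files <- c(categories = sidecar)
  counts <- dt[, .N, by = category]
  for (cat in counts$category) {
    if (!has_payload) next
    f <- file.path(outdir, paste0(cat, ".fastq"))
    write_fastq(payload[category == cat], f)
    files[[cat]] <- f
  }
  invisible(list(files = files,
                 counts = setNames(counts$N, counts$category)))
}
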