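# Mock-community representation: sequenced bases per organism from PAF
# alignments, observed-versus-expected composition, fold representation and
# Gram-group summaries.

#' Read alignments from a PAF file
#'
#' Standard minimap2 PAF: the alignment block length (column 11) is taken
#' as the aligned span, the primary/secondary status from the `tp:A:` tag
#' (`S` marks secondary; records without the tag count as primary), and
#' records below `min_mapq` are dropped and counted.
#'
#' @param path PAF path.
#' @param min_mapq Minimum mapping quality (default 0, i.e. keep all).
#' @return A `data.table` with `read_id`, `target`, `target_span`,
#'   `is_primary`, `mapq`; attribute `n_dropped_mapq`.
#' @export
read_paf <- function(path, min_mapq = 0) {
  if (!file.exists(path)) stop_poresift("PAF file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    out <- data.table(read_id = character(), target = character(),
                      target_span = integer(), is_primary = logical(),
                      mapq = integer())
    attr(out, "n_dropped_mapq") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 12L)
  if (length(bad)) {
    stop_poresift("PAF '%s': line %d has %d columns (< 12)", path, bad[1L], nf[bad[1L]])
  }
  tp <- vapply(fields, function(f) {
    tag <- grep("^tp:A:", f[-(1:12)], value = TRUE)
    if (length(tag)) substring(tag[1L], 6L, 6L) else "P"
  }, character(1))
  out <- data.table(
    read_id = vapply(fields, `[[`, character(1), 1L),
    target = vapply(fields, `[[`, character(1), 6L),
    target_span = as.integer(vapply(fields, `[[`, character(1), 11L)),
    is_primary = tp != "S",
    mapq = as.integer(vapply(fields, `[[`, character(1), 12L))
  )
  dropped <- out[mapq < min_mapq, .N]
  out <- out[mapq >= min_mapq]
  attr(out, "n_dropped_mapq") <- dropped
  out[]
}

#' Write alignments as PAF (used by the simulator)
#'
#' Query/target coordinates are synthesized to be self-consistent with the
#' block length; only fields consumed by [read_paf()] carry information.
#'
#' @param alignments Table with `read_id`, `target`, `target_span`,
#'   optionally `is_primary` and `mapq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(alignments, path) {
  a <- as.data.table(alignments)
  if (!"is_primary" %in% names(a)) a[, is_primary := TRUE]
  if (!"mapq" %in% names(a)) a[, mapq := 60L]
  span <- a$target_span
  lines <- paste(a$read_id, span, 0L, span, "+", a$target, span * 10L, 0L,
                 span, span, span, a$mapq,
                 ifelse(a$is_primary, "tp:A:P", "tp:A:S"), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Observed-versus-expected representation of a mock community
#'
#' Sums the spans of primary alignments (one per read: the first primary
#' record wins) per organism, converts to the observed fraction of
#' sequenced bases, and reports the fold representation
#' `observed / expected` per organism plus mean/min/max folds per group
#' (e.g. Gram-negative / Gram-positive / yeast). Summed primary block
#' lengths stand in for per-position depth sums; the proxy is recorded in
#' the `bases_metric` attribute of the result.
#'
#' @param alignments From [read_paf()] or [simulate_mock()].
#' @param expected Named numeric vector, organism -> expected fraction
#'   (must sum to 1 within 1e-6).
#' @param groups Optional named character vector, organism -> group.
#' @return A `data.table` of class `representation` with columns
#'   `organism`, `group`, `observed_bases`, `observed_fraction`,
#'   `expected_fraction`, `fold`; attribute `group_summary`.
#' @export
representation <- function(alignments, expected, groups = NULL) {
  if (abs(sum(expected) - 1) > 1e-6) {
    stop_poresift("expected fractions sum to %.6f, not 1", sum(expected))
  }
  a <- as.data.table(alignments)[is_primary == TRUE]
  a <- a[!duplicated(read_id)]  # one primary alignment per read
  unknown <- setdiff(unique(a$target), names(expected))
  if (length(unknown)) {
    warning(sprintf("dropping alignments to %d organism(s) absent from 'expected': %s",
                    length(unknown), paste(head(unknown, 5L), collapse = ", ")),
            call. = FALSE)
    a <- a[target %in% names(expected)]
  }
  obs <- a[, .(observed_bases = sum(as.numeric(target_span))), by = .(organism = target)]
  out <- data.table(organism = names(expected),
                    expected_fraction = as.numeric(expected))
  out <- merge(out, obs, by = "organism", all.x = TRUE)
  out[is.na(observed_bases), observed_bases := 0]
  total <- sum(out$observed_bases)
  if (total == 0) stop_poresift("no usable primary alignments")
  out[, observed_fraction := observed_bases / total]
  out[, fold := observed_fraction / expected_fraction]
  out[, group := if (!is.null(groups)) unname(groups[organism]) else NA_character_]
  setorder(out, -observed_fraction)
  group_summary <- NULL
  if (!is.null(groups)) {
    group_summary <- out[!is.na(group),
                         .(mean_fold = mean(fold), min_fold = min(fold),
                           max_fold = max(fold), n = .N), by = group]
  }
  attr(out, "group_summary") <- group_summary
  attr(out, "bases_metric") <- "summed primary-alignment block lengths (PAF column 11)"
  class(out) <- c("representation", class(out))
  out[]
}

#' Compare two representation tables (e.g. two library-prep kits)
#'
#' Per-organism ratio of observed fractions, `rep_a / rep_b`.
#'
#' @param rep_a,rep_b `representation` tables over the same organisms.
#' @return A `data.table` with `organism`, `fraction_a`, `fraction_b`,
#'   `ratio`.
#' @export
kit_comparison <- function(rep_a, rep_b) {
  a <- as.data.table(rep_a)[, .(organism, fraction_a = observed_fraction)]
  b <- as.data.table(rep_b)[, .(organism, fraction_b = observed_fraction)]
  if (!setequal(a$organism, b$organism)) {
    stop_poresift("kit_comparison: organism universes differ")
  }
  out <- merge(a, b, by = "organism")
  out[, ratio := fraction_a / fraction_b]
  setorder(out, organism)
  out[]
}
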