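# Control-versus-depletion concordance: paired abundance tables, stratified
# fold deviations, Bray-Curtis dissimilarity, and Spearman correlation with
# the pairwise-case exclusion rule.

stratum_breaks <- c(0, 30, 100, 500, 1000)
stratum_labels <- c("[0,30)", "[30,100)", "[100,500)", "[500,1000)", "[1000,Inf)")

#' Pair two abundance tables over the union of retained taxa
#'
#' A taxon enters the pairing if it passed the minimum-read filter in at
#' least one of the two tables; counts absent in the other table are 0.
#' Each pair is binned into a count stratum by `max(count_a, count_b)`:
#' `[30,100)`, `[100,500)`, `[500,1000)`, `[1000,Inf)`.
#'
#' @param tab_a,tab_b `abundance_table`s (a = control, b = depletion by
#'   convention).
#' @return A `data.table` of class `paired_abundance` with columns `taxon`,
#'   `count_a`, `count_b`, `proportion_a`, `proportion_b`, `stratum`.
#' @export
paired_abundance <- function(tab_a, tab_b) {
  a <- as.data.table(tab_a)[, .(taxon, count_a = count, proportion_a = proportion)]
  b <- as.data.table(tab_b)[, .(taxon, count_b = count, proportion_b = proportion)]
  out <- merge(a, b, by = "taxon", all = TRUE)
  for (col in c("count_a", "count_b")) out[is.na(get(col)), (col) := 0L]
  for (col in c("proportion_a", "proportion_b")) out[is.na(get(col)), (col) := 0]
  out[, stratum := stratum_labels[findInterval(pmax(count_a, count_b),
                                               stratum_breaks, left.open = FALSE)]]
  class(out) <- c("paired_abundance", class(out))
  out[]
}

#' Fold deviations between paired abundances, by count stratum
#'
#' For every taxon with `proportion_a > 0` computes the fold
#' `proportion_b / proportion_a`; taxa absent from table a are reported
#' separately, never divided. Returns the overall mean fold and the mean
#' absolute deviation from 1 (`|fold - 1|`) per count stratum.
#'
#' @param pairs A `paired_abundance`.
#' @return List with `n_pairs`, `mean_fold`, `folds` (per-taxon table),
#'   `per_stratum` (`data.table`: stratum, n, mean_abs_dev), and
#'   `zero_in_a` (taxa skipped because `proportion_a = 0`).
#' @export
fold_deviation <- function(pairs) {
  p <- as.data.table(pairs)
  zero <- p[proportion_a == 0, taxon]
  ok <- p[proportion_a > 0]
  ok[, fold := proportion_b / proportion_a]
  per_stratum <- ok[, .(n = .N, mean_abs_dev = mean(abs(fold - 1))), by = stratum]
  setorder(per_stratum, stratum)
  list(
    n_pairs = nrow(ok),
    mean_fold = if (nrow(ok)) mean(ok$fold) else NA_real_,
    folds = ok[, .(taxon, count_a, count_b, fold, stratum)],
    per_stratum = per_stratum,
    zero_in_a = zero
  )
}

#' Bray-Curtis dissimilarity between two proportion vectors
#'
#' `BC = sum(|p_i - q_i|) / sum(p_i + q_i)`: 0 for identical vectors, 1 for
#' disjoint support. Vectors must be aligned element-wise over the same
#' taxon universe.
#'
#' @param p,q Non-negative numeric vectors of equal length, not both all
#'   zero.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(p, q) {
  if (length(p) != length(q)) stop_poresift("bray_curtis: vectors differ in length")
  if (any(p < 0) || any(q < 0)) stop_poresift("bray_curtis: negative abundances")
  s <- sum(p + q)
  if (s == 0) stop_poresift("bray_curtis: both vectors are all zero")
  sum(abs(p - q)) / s
}

#' Bray-Curtis dissimilarity for a taxon pairing
#'
#' Relative abundances over the union of retained taxa, each side
#' renormalized to sum 1 before applying [bray_curtis()]. Taxa with zero
#' counts on one side stay in (they contribute dissimilarity), matching
#' the role of the statistic as a whole-composition distance.
#'
#' @param pairs A `paired_abundance`.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis_pair <- function(pairs) {
  p <- as.data.table(pairs)
  sa <- sum(p$proportion_a); sb <- sum(p$proportion_b)
  if (nrow(p) == 0L || (sa == 0 && sb == 0)) return(NA_real_)
  if (sa == 0 || sb == 0) return(1)  # one side empty: disjoint support
  bray_curtis(p$proportion_a / sa, p$proportion_b / sb)
}

#' Spearman correlation with the pairwise-case exclusion rule
#'
#' A "pairwise case" is a taxon observed (count > 0) in both members of the
#' pair. With fewer than two such cases a rank correlation is undefined and
#' the sample is excluded with a reason instead of returning a number.
#' Otherwise Spearman's rho is computed on average ranks; the two-sided
#' p-value uses exact full-permutation enumeration for up to 8 pairwise
#' cases and the t approximation above that. Results with fewer than 10
#' pairwise cases carry a `few_pairwise_cases` flag: non-significant
#' p-values there say little.
#'
#' @param pairs A `paired_abundance` (or any table with `count_a`,
#'   `count_b`, `proportion_a`, `proportion_b`).
#' @return List with `excluded` (logical), and when not excluded `rho`,
#'   `p_value`, `n_pairs`, `method`, `few_pairwise_cases`; when excluded,
#'   `reason` and `n_pairs`.
#' @export
spearman_with_exclusion <- function(pairs) {
  p <- as.data.table(pairs)
  shared <- p[count_a > 0 & count_b > 0]
  n <- nrow(shared)
  if (n < 2L) {
    return(list(excluded = TRUE, n_pairs = n,
                reason = sprintf("only %d pairwise case(s); rank correlation undefined", n)))
  }
  rx <- rank(shared$proportion_a)
  ry <- rank(shared$proportion_b)
  rho <- cor(rx, ry)
  if (n <= 8L) {
    method <- "exact permutation"
    perms <- .permutations(n)
    # correlation of rx against every permutation of ry
    rho_perm <- apply(perms, 1L, function(idx) cor(rx, ry[idx]))
    p_value <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    method <- "t approximation"
    r <- min(max(rho, -1 + 1e-12), 1 - 1e-12)
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p_value <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(excluded = FALSE, rho = rho, p_value = p_value, n_pairs = n,
       method = method, few_pairwise_cases = n < 10L)
}

# All permutations of 1..n as an (n!) x n matrix; n <= 8 keeps this small.
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Concordance report for a cohort of paired samples
#'
#' The machine-readable twin of a per-sample concordance table: one row per
#' sample pair with the pairwise-case count, mean fold, per-stratum mean
#' absolute fold deviations, Bray-Curtis dissimilarity, Spearman rho and
#' p-value, and the exclusion flag.
#'
#' @param pair_list Named list of `paired_abundance` objects (names are
#'   sample ids).
#' @return A `data.table`, one row per sample.
#' @export
pair_report <- function(pair_list) {
  rows <- lapply(names(pair_list), function(id) {
    pr <- pair_list[[id]]
    fd <- fold_deviation(pr)
    sp <- spearman_with_exclusion(pr)
    dev_of <- function(lab) {
      i <- match(lab, fd$per_stratum$stratum)
      if (is.na(i)) NA_real_ else fd$per_stratum$mean_abs_dev[i]
    }
    data.table(
      sample = id,
      n_pairs = sp$n_pairs,
      mean_fold = fd$mean_fold,
      dev_30_100 = dev_of("[30,100)"),
      dev_100_500 = dev_of("[100,500)"),
      dev_500_1000 = dev_of("[500,1000)"),
      dev_1000_inf = dev_of("[1000,Inf)"),
      bray_curtis = bray_curtis_pair(pr),
      rho = if (sp$excluded) NA_real_ else sp$rho,
      p_value = if (sp$excluded) NA_real_ else sp$p_value,
      excluded = sp$excluded
    )
  })
  rbindlist(rows)
}
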