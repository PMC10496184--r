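# Evaluation metrics: pair-counting adjusted Rand index for clustering and
# recall/precision/F1 for gene selection, with median/MAD replicate summaries.

#' Pair counts between two partitions
#'
#' Counts the four kinds of cell pairs underlying the adjusted Rand index:
#' `a` same cluster in both partitions, `b` different in both, `c` together in
#' the first but split in the second, `d` together in the second but split in
#' the first. Computed from the contingency table, so `a + b + c + d`
#' always equals `choose(n, 2)`.
#'
#' @param truth,estimate Equal-length label vectors.
#' @return Named list with `a`, `b`, `c`, `d`.
#' @export
pair_counts <- function(truth, estimate) {
  if (length(truth) != length(estimate)) stop("label vectors differ in length", call. = FALSE)
  n <- length(truth)
  if (n < 2L) stop("need at least two observations", call. = FALSE)
  tab <- table(truth, estimate)
  ch2 <- function(x) x * (x - 1) / 2
  a <- sum(ch2(tab))
  same_truth <- sum(ch2(rowSums(tab)))   # a + c
  same_est <- sum(ch2(colSums(tab)))     # a + d
  total <- ch2(n)
  c_ <- same_truth - a
  d_ <- same_est - a
  list(a = a, b = total - a - c_ - d_, c = c_, d = d_)
}

#' Adjusted Rand index
#'
#' Chance-corrected pair-counting agreement between two partitions:
#' 1 for identical partitions (up to relabeling), about 0 for independent
#' ones; can be negative. Computed from the pair counts via the
#' Hubert-Arabie normalization.
#'
#' @param truth,estimate Equal-length label vectors (length `>= 2`).
#' @return A score in \[-1, 1\].
#' @export
ari <- function(truth, estimate) {
  pcn <- pair_counts(truth, estimate)
  n <- length(truth)
  n2 <- n * (n - 1) / 2
  agree <- pcn$a + pcn$b
  # expected agreements under independent partitions with the same margins
  exp_agree <- ((pcn$a + pcn$c) * (pcn$a + pcn$d) +
                  (pcn$b + pcn$d) * (pcn$b + pcn$c)) / n2
  if (n2 == exp_agree) return(ifelse(agree == n2, 1, 0))
  (agree - exp_agree) / (n2 - exp_agree)
}

#' Gene-selection recall, precision and F1
#'
#' Compares a selected gene set against ground-truth informative flags.
#' `Recall = TP / (TP + FN)`, `Precision = TP / (TP + FP)`,
#' `F1 = 2 P R / (P + R)`. An empty selection reports precision 0 by
#' convention, and F1 is 0 whenever `P + R = 0`.
#'
#' @param truth_flags Logical vector over the gene universe (or a character
#'   vector of truly informative gene ids).
#' @param selected_set Character vector of selected gene ids, or a logical /
#'   integer index into the same universe.
#' @param universe Gene identifiers; required when `truth_flags` is logical
#'   and `selected_set` is character.
#' @return A one-row tibble: `tp`, `fp`, `fn`, `recall`, `precision`, `f1`.
#' @export
selection_prf <- function(truth_flags, selected_set, universe = NULL) {
  if (is.logical(truth_flags)) {
    if (is.null(universe)) universe <- names(truth_flags)
    if (is.null(universe)) universe <- as.character(seq_along(truth_flags))
    truth_ids <- universe[truth_flags]
  } else {
    truth_ids <- as.character(truth_flags)
  }
  if (is.logical(selected_set)) {
    selected_set <- universe[selected_set]
  } else if (is.numeric(selected_set)) {
    selected_set <- universe[as.integer(selected_set)]
  }
  selected_set <- as.character(selected_set)
  tp <- length(intersect(selected_set, truth_ids))
  fp <- length(setdiff(selected_set, truth_ids))
  fn <- length(setdiff(truth_ids, selected_set))
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  tibble::tibble(tp = tp, fp = fp, fn = fn,
                 recall = recall, precision = precision, f1 = f1)
}

#' Median and median absolute deviation over replicates
#'
#' Raw (unscaled) MAD, as conventionally reported next to medians of bounded
#' scores; a single value yields MAD 0.
#'
#' @param values Numeric vector of per-replicate scores.
#' @return A one-row tibble with `median` and `mad`.
#' @export
replicate_summary <- function(values) {
  if (!length(values)) stop("need at least one value", call. = FALSE)
  med <- stats::median(values)
  tibble::tibble(median = med, mad = stats::median(abs(values - med)))
}
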