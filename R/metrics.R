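# Evaluation metrics: partition- and target-level accuracy, variant allele
# fractions, and replicate comparison against background.

#' Partition-level assignment accuracy
#'
#' Fraction of positive partitions assigned to a tag that is truly present in
#' the sample.  A partition is "positive" when its label is not the null
#' label; positives whose label matches no codebook signature (ambiguous,
#' e.g. level-3 labels) cannot be assigned.  Because it is ambiguous whether
#' such partitions belong in the denominator, both readings are reported:
#' `accuracy` uses assigned positives only, `accuracy_all_positive` uses all
#' positive partitions.
#'
#' @param labels per-partition label strings.
#' @param codebook a `dpcr_codebook`.
#' @param truth_tags character vector of tag names truly present.
#' @return list with `accuracy`, `accuracy_all_positive`, and the counts
#'   `n_correct`, `n_assigned`, `n_positive`, `n_unassigned`.
#' @export
partition_accuracy <- function(labels, codebook, truth_tags) {
  stopifnot(inherits(codebook, "dpcr_codebook"))
  unknown <- setdiff(truth_tags, codebook$tags$name)
  if (length(unknown) > 0L) {
    stop("truth tags not in the codebook: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  null_label <- strrep("0", codebook$channels)
  positive <- labels != null_label
  if (!any(positive)) {
    stop("no positive partitions: accuracy is undefined", call. = FALSE)
  }
  assigned <- assign_partitions(labels, codebook)
  is_assigned <- positive & !is.na(assigned)
  n_correct <- sum(is_assigned & assigned %in% truth_tags)
  list(
    accuracy = n_correct / sum(is_assigned),
    accuracy_all_positive = n_correct / sum(positive),
    n_correct = n_correct,
    n_assigned = sum(is_assigned),
    n_positive = sum(positive),
    n_unassigned = sum(positive) - sum(is_assigned)
  )
}

#' Target-level confusion summary
#'
#' Standard confusion counts and ratios for present/absent calls against a
#' truth table over the same target universe.  Ratios retain their raw
#' fractions so results print the way they are reported (e.g. "81/96
#' (84.4%)").
#'
#' @param calls logical vector of calls, named by target (or a character
#'   vector of called-present targets together with `universe`).
#' @param truth logical vector of truth, named by target (or a character
#'   vector of truly present targets).
#' @param universe optional character vector of all targets evaluated, needed
#'   when `calls`/`truth` are character vectors.
#' @return object of class `confusion_summary`: TP/FP/TN/FN counts plus
#'   `accuracy`, `sensitivity`, `specificity` with numerators/denominators.
#' @export
target_calls_confusion <- function(calls, truth, universe = NULL) {
  if (is.character(calls) || is.character(truth)) {
    if (is.null(universe)) {
      stop("`universe` is required when calls/truth are target-name vectors",
           call. = FALSE)
    }
    calls <- stats::setNames(universe %in% calls, universe)
    truth <- stats::setNames(universe %in% truth, universe)
  }
  if (!identical(sort(names(calls)), sort(names(truth)))) {
    stop("calls and truth must cover the same target universe", call. = FALSE)
  }
  truth <- truth[names(calls)]
  tp <- sum(calls & truth)
  fp <- sum(calls & !truth)
  tn <- sum(!calls & !truth)
  fn <- sum(!calls & truth)
  ratio <- function(num, den) {
    list(value = if (den > 0) num / den else NA_real_, num = num, den = den)
  }
  structure(
    list(TP = tp, FP = fp, TN = tn, FN = fn,
         accuracy = ratio(tp + tn, tp + tn + fp + fn),
         sensitivity = ratio(tp, tp + fn),
         specificity = ratio(tn, tn + fp)),
    class = "confusion_summary"
  )
}

#' @export
print.confusion_summary <- function(x, ...) {
  fmt <- function(r, label) {
    if (is.na(r$value)) {
      cat(sprintf("  %-12s -\n", label))
    } else {
      cat(sprintf("  %-12s %d/%d (%.1f%%)\n", label, r$num, r$den,
                  100 * r$value))
    }
  }
  cat(sprintf("Target calls: TP %d  FP %d  TN %d  FN %d\n",
              x$TP, x$FP, x$TN, x$FN))
  fmt(x$accuracy, "accuracy")
  fmt(x$sensitivity, "sensitivity")
  fmt(x$specificity, "specificity")
  invisible(x)
}

#' Variant allele fractions relative to a reference tag
#'
#' VAF of each variant = its estimated copies divided by the reference
#' amplicon's copies; the mean VAF across the variant panel is the usual
#' tumor-burden style summary.  Scale-invariant in the copy estimates.
#'
#' @param object a `dpcr_decode` fit (or a named numeric vector of copies).
#' @param reference_tag name of the reference tag (its copies must be > 0).
#' @return object of class `vaf_result`: `vaf` (named, per variant),
#'   `mean_vaf`, `reference_tag`, `reference_copies`.
#' @export
vaf <- function(object, reference_tag) {
  copies <- if (inherits(object, "dpcr_decode")) object$copies else object
  if (!is.numeric(copies) || is.null(names(copies))) {
    stop("`object` must be a dpcr_decode fit or a named copies vector",
         call. = FALSE)
  }
  if (!reference_tag %in% names(copies)) {
    stop("reference tag not found: ", reference_tag, call. = FALSE)
  }
  ref <- copies[[reference_tag]]
  if (!is.finite(ref) || ref <= 0) {
    stop("reference copies must be positive for VAF", call. = FALSE)
  }
  variants <- copies[names(copies) != reference_tag]
  v <- variants / ref
  structure(
    list(vaf = v, mean_vaf = mean(v), reference_tag = reference_tag,
         reference_copies = ref),
    class = "vaf_result"
  )
}

#' @export
print.vaf_result <- function(x, ...) {
  cat(sprintf("VAF vs reference '%s' (%.1f copies): mean VAF %.4g over %d variants\n",
              x$reference_tag, x$reference_copies, x$mean_vaf, length(x$vaf)))
  invisible(x)
}

#' Rank-sum comparison of replicate values against background
#'
#' Thin wrapper around the two-sided Mann-Whitney U / Wilcoxon rank-sum test
#' for comparing replicate-level quantities (counts, VAFs) between a sample
#' and its background.
#'
#' @param replicate_values_a,replicate_values_b numeric vectors, at least two
#'   values each.
#' @param exact compute the exact null distribution where possible (default;
#'   falls back to the normal approximation when ties are present).
#' @return the two-sided p-value.
#' @export
compare_to_background <- function(replicate_values_a, replicate_values_b,
                                  exact = TRUE) {
  if (length(replicate_values_a) < 2L || length(replicate_values_b) < 2L) {
    stop("need at least two replicate values per group", call. = FALSE)
  }
  suppressWarnings(
    stats::wilcox.test(replicate_values_a, replicate_values_b,
                       alternative = "two.sided", exact = exact)$p.value
  )
}
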