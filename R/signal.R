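# Amplitude preprocessing and partition classification.

# Coerce partition data to a plain numeric matrix of channel amplitudes.
# Accepts a matrix, or a data frame with ch1..chC columns (as written by
# write_partitions); other columns (partition_id, well) are dropped.
amplitude_matrix <- function(x) {
  if (is.data.frame(x)) {
    ch <- grep("^ch[0-9]+$", names(x), value = TRUE)
    if (length(ch) > 0L) {
      x <- x[ch[order(as.integer(sub("^ch", "", ch)))]]
    }
    x <- as.matrix(x)
  }
  if (!is.numeric(x) || !is.matrix(x)) {
    stop("amplitude data must be a numeric matrix or a data frame with ch* columns",
         call. = FALSE)
  }
  if (nrow(x) < 1L) stop("amplitude matrix is empty", call. = FALSE)
  if (any(!is.finite(x))) stop("amplitude values must be finite", call. = FALSE)
  x
}

#' Per-channel amplitude thresholds
#'
#' Three ascending cut points per channel separate the four amplitude levels
#' on the calibrated scale: below `t1` is level 0, then 1, then 2, and at or
#' above `t3` level 3.  Defaults are the midpoints between the ideal level
#' intensities 0, 1, 2, 3 (after 1i calibration).  Thresholds are fixed
#' configuration, never auto-tuned.
#'
#' @param channels number of color channels.
#' @param cuts numeric vector of 3 cut points recycled across channels, or a
#'   `channels` x 3 matrix.
#' @return a `channels` x 3 numeric matrix (columns t1, t2, t3).
#' @export
threshold_set <- function(channels, cuts = c(0.5, 1.5, 2.5)) {
  if (is.matrix(cuts)) {
    t <- cuts
    if (nrow(t) != channels || ncol(t) != 3L) {
      stop("threshold matrix must be channels x 3", call. = FALSE)
    }
  } else {
    stopifnot(length(cuts) == 3L)
    t <- matrix(cuts, nrow = channels, ncol = 3L, byrow = TRUE)
  }
  if (any(t[, 1] >= t[, 2]) || any(t[, 2] >= t[, 3])) {
    stop("thresholds must be strictly increasing within each channel",
         call. = FALSE)
  }
  dimnames(t) <- list(paste0("ch", seq_len(channels)), c("t1", "t2", "t3"))
  t
}

#' Subtract per-channel baseline
#'
#' Standardizes a well by subtracting the 3rd percentile of amplitudes in each
#' channel from all partitions, putting the no-target cluster at roughly zero.
#' Percentiles use linear interpolation between order statistics (R's default
#' quantile type 7).  Negative values after subtraction are retained, not
#' clipped; they classify as level 0.
#'
#' @param x amplitude matrix (partitions x channels) or partition data frame.
#' @param prob percentile used as the baseline (default 0.03).
#' @return baseline-corrected numeric matrix.
#' @export
subtract_baseline <- function(x, prob = 0.03) {
  m <- amplitude_matrix(x)
  base <- apply(m, 2L, stats::quantile, probs = prob, names = FALSE, type = 7)
  sweep(m, 2L, base, "-")
}

#' Compensate spectral crosstalk
#'
#' Left-multiplies every partition's amplitude vector by the inverse of the
#' crosstalk matrix, so each corrected channel reflects only its intended
#' fluorophore.  Entry (i, j) of the crosstalk matrix is the fraction of
#' channel j's true signal detected in channel i (diagonal 1).  Compensating
#' data mixed with the same matrix is the identity up to numerical tolerance.
#'
#' @param x amplitude matrix or partition data frame.
#' @param xt crosstalk matrix (C x C, nonsingular).
#' @return spectrally corrected numeric matrix.
#' @export
compensate_crosstalk <- function(x, xt) {
  m <- amplitude_matrix(x)
  xt <- as.matrix(xt)
  if (nrow(xt) != ncol(xt) || nrow(xt) != ncol(m)) {
    stop("crosstalk matrix must be square with one row per channel",
         call. = FALSE)
  }
  inv <- tryCatch(solve(xt), error = function(e) {
    stop("crosstalk matrix is singular or near-singular and cannot be inverted: ",
         conditionMessage(e), call. = FALSE)
  })
  out <- t(inv %*% t(m))
  dimnames(out) <- dimnames(m)
  out
}

#' Calibrate amplitudes to the 1i reference scale
#'
#' Divides each channel by its low-concentration ("1i") probe cluster center,
#' setting the reference intensity to 1.0 so that the default level means
#' 0/1/2/3 and midpoint thresholds apply.
#'
#' @param x amplitude matrix or partition data frame.
#' @param reference per-channel 1i cluster centers (positive).
#' @return calibrated numeric matrix.
#' @seealso [level1_reference()] for estimating the centers from data.
#' @export
calibrate <- function(x, reference) {
  m <- amplitude_matrix(x)
  reference <- as.numeric(reference)
  if (length(reference) != ncol(m)) {
    stop("need one reference intensity per channel", call. = FALSE)
  }
  if (any(!is.finite(reference)) || any(reference <= 0)) {
    stop("reference intensities must be positive", call. = FALSE)
  }
  sweep(m, 2L, reference, "/")
}

#' Estimate 1i reference centers from a provisional classification
#'
#' For each channel, takes the median amplitude of partitions provisionally
#' labeled with that channel's single-site level-1 signature (e.g. 1000 for
#' channel 1).  The provisional thresholds must be on the raw amplitude scale.
#'
#' @param x amplitude matrix or partition data frame.
#' @param thresholds raw-scale thresholds (see [threshold_set()]).
#' @return numeric vector of per-channel centers (NA where no partition holds
#'   the single-positive level-1 label).
#' @export
level1_reference <- function(x, thresholds) {
  m <- amplitude_matrix(x)
  cl <- classify_partitions(m, thresholds)
  d <- label_digits(cl$labels, ncol(m))
  vapply(seq_len(ncol(m)), function(c) {
    hit <- d[, c] == 1L & rowSums(d != 0L) == 1L
    if (!any(hit)) NA_real_ else stats::median(m[hit, c])
  }, numeric(1))
}

#' Classify partitions into amplitude labels
#'
#' Assigns each partition a per-channel amplitude level by threshold
#' comparison (value < t1 is level 0, < t2 level 1, < t3 level 2, else 3) and
#' concatenates the levels into a label string, channel 1 leftmost.
#'
#' @param x calibrated amplitude matrix or partition data frame.
#' @param thresholds numeric vector of 3 cuts, or a channels x 3 matrix
#'   (default: midpoints 0.5/1.5/2.5 in every channel).
#' @return list with `labels` (character vector, one label per partition) and
#'   `counts` (a [label_counts()] tally).
#' @examples
#' classify_partitions(rbind(c(0.15, 2.10, 0.20, 0.04)))$labels  # "0200"
#' @export
classify_partitions <- function(x, thresholds = NULL) {
  m <- amplitude_matrix(x)
  C <- ncol(m)
  t <- if (is.null(thresholds)) threshold_set(C) else threshold_set(C, thresholds)
  d <- matrix(0L, nrow = nrow(m), ncol = C)
  for (c in seq_len(C)) {
    d[, c] <- findInterval(m[, c], t[c, ])
  }
  labels <- digits_label(d)
  list(labels = labels, counts = label_counts(labels, channels = C))
}

#' Tally of partition labels
#'
#' Builds the per-label partition counts that drive Poisson deconvolution:
#' the observed count of every label plus the total partition count and the
#' null (all-zeros) count.
#'
#' @param labels character vector of per-partition labels, or a named numeric
#'   vector of counts keyed by label string.
#' @param channels channel count (inferred from the labels if omitted).
#' @return object of class `label_counts`: fields `counts` (named, sorted),
#'   `n_partitions`, `channels`, `null_label`.
#' @export
label_counts <- function(labels, channels = NULL) {
  if (!is.null(names(labels)) && is.numeric(labels)) {
    counts <- labels
    if (any(counts < 0)) stop("label counts must be non-negative", call. = FALSE)
    label_digits(names(counts), channels)   # validates
    channels <- channels %||% nchar(names(counts)[1L])
  } else {
    labels <- as.character(labels)
    label_digits(labels, channels)          # validates
    channels <- channels %||% nchar(labels[1L])
    tab <- table(labels)
    counts <- as.numeric(tab)
    names(counts) <- names(tab)
  }
  null_label <- strrep("0", channels)
  if (!null_label %in% names(counts)) {
    counts[null_label] <- 0
  }
  counts <- counts[sort(names(counts), method = "radix")]
  structure(
    list(counts = counts, n_partitions = sum(counts), channels = channels,
         null_label = null_label),
    class = "label_counts"
  )
}

#' @export
print.label_counts <- function(x, ...) {
  cat(sprintf("Partition label counts: %s partitions, %d channels, %d distinct labels (null %s: %s)\n",
              format(x$n_partitions, big.mark = ","), x$channels,
              sum(x$counts > 0), x$null_label,
              format(x$counts[[x$null_label]], big.mark = ",")))
  pos <- x$counts[names(x$counts) != x$null_label & x$counts > 0]
  if (length(pos) > 0L) {
    show <- utils::head(sort(pos, decreasing = TRUE), 10L)
    cat("  top labels:",
        paste(sprintf("%s=%g", names(show), show), collapse = " "),
        if (length(pos) > 10L) "..." else "", "\n")
  }
  invisible(x)
}

#' Call tag presence from label counts
#'
#' A tag is called present when at least `min_partitions` partitions carry a
#' label exactly equal to its signature.  The permissive default (1 partition)
#' maximizes sensitivity; 5 is the stricter alternative used for target-level
#' calling.
#'
#' @param counts a [label_counts()] object.
#' @param codebook a `dpcr_codebook`.
#' @param min_partitions minimum exact-signature partitions (>= 1).
#' @return character vector of present tag names.
#' @export
call_tags <- function(counts, codebook, min_partitions = 1) {
  stopifnot(inherits(counts, "label_counts"), inherits(codebook, "dpcr_codebook"),
            min_partitions >= 1)
  n <- counts$counts[codebook$tags$signature]
  n[is.na(n)] <- 0
  codebook$tags$name[n >= min_partitions]
}

#' Assign partitions to tags by exact signature match
#'
#' Partitions whose label equals a codebook signature are assigned to that
#' tag; null-labeled and non-signature (ambiguous, e.g. level-3) partitions
#' get NA.
#'
#' @param labels character vector of partition labels.
#' @param codebook a `dpcr_codebook`.
#' @return character vector of tag names (NA where unassigned).
#' @export
assign_partitions <- function(labels, codebook) {
  stopifnot(inherits(codebook, "dpcr_codebook"))
  codebook$tags$name[match(labels, codebook$tags$signature)]
}

#' Euclidean-distance quality score per partition
#'
#' Distance between each assigned partition's amplitude vector and its tag's
#' ideal vector (signature digits read as intensities).  To suppress baseline
#' noise, channels where the assigned signature has digit 0 are masked to
#' zero before the distance is computed; e.g. a partition measured
#' [0.15, 2.10, 0.20, 0.04] assigned to 0200 is assessed as [0, 2.10, 0, 0],
#' at distance 0.10 from [0, 2, 0, 0].
#'
#' @param x calibrated amplitude matrix or partition data frame.
#' @param assignments per-partition tag name (NA for unassigned), as from
#'   [assign_partitions()].
#' @param codebook a `dpcr_codebook`.
#' @return numeric vector of distances (NA for unassigned partitions).
#' @export
euclidean_qc <- function(x, assignments, codebook) {
  m <- amplitude_matrix(x)
  stopifnot(inherits(codebook, "dpcr_codebook"),
            length(assignments) == nrow(m))
  idx <- match(assignments, codebook$tags$name)
  bad <- !is.na(assignments) & is.na(idx)
  if (any(bad)) {
    stop("unknown tag in assignments: ", assignments[which(bad)[1L]],
         call. = FALSE)
  }
  sig_digits <- label_digits(codebook$tags$signature, ncol(m))
  out <- rep(NA_real_, nrow(m))
  ok <- which(!is.na(idx))
  if (length(ok) > 0L) {
    ideal <- sig_digits[idx[ok], , drop = FALSE]
    masked <- m[ok, , drop = FALSE] * (ideal != 0L)
    out[ok] <- sqrt(rowSums((masked - ideal)^2))
  }
  out
}
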