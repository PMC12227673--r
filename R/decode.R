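# Hierarchical Poisson deconvolution of partition-label counts into per-tag
# mean occupancies (lambda) and copy numbers.
#
# The estimator processes tags in ascending order of probe-site count.  For a
# single-site tag, lambda = ln(1 + P_sig / P_0): partitions labeled with a
# single-channel signature contain exactly that tag, and the ratio to the
# null count inverts the Poisson occupancy.  For a multi-site tag with
# signature L, the count P_L is first purged of the partitions expected to
# show L through co-presence of already-estimated contained tags
# (E_L = P_0 * sum over subsets S of contained tags with union(S) = L of
# prod (e^lambda_t - 1)), then deflated by e^{-lambda_t} for every contained
# tag t that may co-occupy the remaining partitions, and finally inverted
# with the same log formula.  Fed exact expected counts the scheme returns
# the generating lambdas exactly; see the methods vignette for the argument.

MAX_DECODE_CHANNELS <- 8L   # label lattice has 4^C states

# Precompute per-codebook quantities used by the estimator and by
# label_probabilities: packed signatures, processing order, contained sets.
decode_prepare <- function(codebook) {
  stopifnot(inherits(codebook, "dpcr_codebook"))
  C <- codebook$channels
  if (C > MAX_DECODE_CHANNELS) {
    stop(sprintf("deconvolution supports at most %d channels (4^C label states)",
                 MAX_DECODE_CHANNELS), call. = FALSE)
  }
  sig <- pack_labels(codebook$tags$signature, C)
  sites <- packed_sites(sig, C)
  ord <- order(sites, codebook$tags$signature, method = "radix")
  contained <- lapply(seq_along(sig), function(t) {
    which(packed_contained(sig, sig[t]) & seq_along(sig) != t)
  })
  list(channels = C, n_states = 4L^C, sig = sig, sites = sites, order = ord,
       contained = contained, names = codebook$tags$name,
       signatures = codebook$tags$signature)
}

# Accumulate contrib into x at (0-based) states idx, summing duplicates.
scatter_add <- function(x, idx, contrib) {
  live <- contrib != 0
  if (!any(live)) return(x)
  s <- rowsum(contrib[live], idx[live])
  u <- as.integer(rownames(s)) + 1L
  x[u] <- x[u] + s[, 1L]
  x
}

# Expected-count factor: sum over subsets S of `members` (packed signatures
# `sig`, per-tag ratios r = e^lambda - 1) whose union equals `target`, of the
# product of ratios.  Dynamic program over the label lattice; the size-2 case
# (all there is for max_sites = 2 codebooks) is special-cased for speed.
union_subset_sum <- function(sig, r, members, target, n_states) {
  m <- length(members)
  if (m == 0L) return(0)
  if (m == 1L) {
    return(if (sig[members] == target) r[members] else 0)
  }
  if (m == 2L) {
    out <- 0
    if (sig[members[1L]] == target) out <- out + r[members[1L]]
    if (sig[members[2L]] == target) out <- out + r[members[2L]]
    if (bitwOr(sig[members[1L]], sig[members[2L]]) == target) {
      out <- out + r[members[1L]] * r[members[2L]]
    }
    return(out)
  }
  f <- numeric(n_states)
  f[1L] <- 1
  states <- 0:(n_states - 1L)
  for (t in members) {
    f <- scatter_add(f, bitwOr(states, sig[t]), f * r[t])
  }
  # the empty set only contributes to state 0, never to a nonzero target
  f[target + 1L]
}

# Core numeric estimator on packed counts (length 4^C, state 0 first).
decode_core <- function(counts, prep) {
  N <- sum(counts)
  P0 <- counts[1L]
  if (P0 <= 0) {
    stop("saturated reaction: no null-label partitions, lambda is not estimable",
         call. = FALSE)
  }
  Tn <- length(prep$sig)
  lambda <- E <- Pp <- Ps <- PL <- numeric(Tn)
  for (t in prep$order) {
    L <- prep$sig[t]
    A <- prep$contained[[t]]
    E[t] <- P0 * union_subset_sum(prep$sig, expm1(lambda), A, L, prep$n_states)
    PL[t] <- counts[L + 1L]
    Pp[t] <- max(PL[t] - E[t], 0)
    Ps[t] <- Pp[t] * exp(-sum(lambda[A]))
    lambda[t] <- log1p(Ps[t] / P0)
  }
  list(lambda = lambda, copies = N * lambda, P_L = PL, E_L = E,
       P_prime = Pp, P_star = Ps, N = N, P0 = P0)
}

#' Deconvolve label counts into per-tag copy numbers
#'
#' Fits the hierarchical Poisson deconvolution to a tally of partition labels:
#' tags with one probe site are estimated directly from their exact-signature
#' counts via `lambda = ln(1 + P_sig / P_0)`; tags with more sites are
#' estimated after subtracting the partitions expected to show their signature
#' through co-presence of lower-order tags and correcting for co-occupancy
#' (the expected-count / corrected-count / occupancy-deflation ladder).
#' Labels matching no signature — including any label containing level 3 —
#' carry ambiguous tag combinations and are excluded from estimation but
#' reported with their counts.
#'
#' @param counts a [label_counts()] object, a named numeric vector of counts
#'   keyed by label string, or a character vector of per-partition labels.
#'   Counts may be non-integer (e.g. expected counts).
#' @param codebook a `dpcr_codebook`; signatures must be distinct and the
#'   channel count must match the labels.
#' @return an object of class `dpcr_decode` with per-tag estimates and
#'   intermediate quantities; see [coef.dpcr_decode()], [summary.dpcr_decode()],
#'   [fitted.dpcr_decode()], [simulate.dpcr_decode()], [vaf()].
#' @examples
#' cb <- codebook(c("1000", "0100", "1100"))
#' cts <- c("0000" = 10000, "1000" = 1000, "0100" = 500, "1100" = 120)
#' fit <- decode_dpcr(cts, cb)
#' coef(fit)
#' @export
decode_dpcr <- function(counts, codebook) {
  stopifnot(inherits(codebook, "dpcr_codebook"))
  if (is.character(counts)) counts <- label_counts(counts, codebook$channels)
  if (!inherits(counts, "label_counts")) {
    counts <- label_counts(counts, codebook$channels)
  }
  if (counts$channels != codebook$channels) {
    stop("label channel count does not match the codebook", call. = FALSE)
  }
  prep <- decode_prepare(codebook)
  packed <- numeric(prep$n_states)
  packed[pack_labels(names(counts$counts), counts$channels) + 1L] <- counts$counts
  core <- decode_core(packed, prep)

  is_sig <- logical(prep$n_states)
  is_sig[prep$sig + 1L] <- TRUE
  obs_states <- pack_labels(names(counts$counts), counts$channels)
  excl <- obs_states[!is_sig[obs_states + 1L] & obs_states != 0L &
                       counts$counts > 0]
  excluded <- data.frame(
    label = unpack_labels(excl, counts$channels),
    count = counts$counts[match(excl, obs_states)],
    row.names = NULL, stringsAsFactors = FALSE
  )

  tab <- data.frame(
    name = prep$names, signature = prep$signatures, sites = prep$sites,
    P_L = core$P_L, E_L = core$E_L, P_prime = core$P_prime,
    P_star = core$P_star, lambda = core$lambda, copies = core$copies,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(lambda = stats::setNames(core$lambda, prep$names),
         copies = stats::setNames(core$copies, prep$names),
         table = tab, n_partitions = core$N, null_count = core$P0,
         excluded = excluded, codebook = codebook, counts = counts,
         call = match.call()),
    class = "dpcr_decode"
  )
}

#' Estimate occupancy of a single-channel tag
#'
#' Direct Poisson inversion for a tag whose signature has exactly one nonzero
#' digit: partitions carrying that label contain the tag and nothing else, so
#' `lambda = ln(1 + P_sig / P_0)`.  With a one-tag codebook this equals the
#' textbook dPCR estimator `-ln(1 - P_pos / N)`.
#'
#' @param counts a [label_counts()] object.
#' @param tag signature string with exactly one nonzero digit.
#' @return lambda, the tag's mean copies per partition.
#' @export
estimate_single_channel <- function(counts, tag) {
  stopifnot(inherits(counts, "label_counts"))
  d <- label_digits(tag, counts$channels)
  if (sum(d > 0L) != 1L || any(d > 2L)) {
    stop("tag must be a single-channel signature (one nonzero digit, 1 or 2)",
         call. = FALSE)
  }
  P0 <- counts$counts[[counts$null_label]]
  if (P0 <= 0) {
    stop("saturated reaction: no null-label partitions", call. = FALSE)
  }
  Ptag <- if (tag %in% names(counts$counts)) counts$counts[[tag]] else 0
  log1p(Ptag / P0)
}

#' Exact label probabilities under independent Poisson occupancy
#'
#' Probability of every achievable partition label when each tag occupies a
#' partition independently with probability `1 - exp(-lambda)`.  Computed by
#' an exact forward recursion over the label lattice (one pass per tag), so it
#' scales to hundreds of tags; probabilities sum to 1.
#'
#' @param codebook a `dpcr_codebook`.
#' @param lambda per-tag mean copies per partition; scalar (recycled) or
#'   vector, optionally named by tag.
#' @return named numeric vector of probabilities over achievable labels
#'   (including the null label).
#' @export
label_probabilities <- function(codebook, lambda) {
  prep <- decode_prepare(codebook)
  p <- label_prob_packed(prep, prep_lambda(lambda, prep$names))
  keep <- which(p > 0)
  stats::setNames(p[keep], unpack_labels(keep - 1L, prep$channels))
}

prep_lambda <- function(lambda, tags) {
  if (!is.null(names(lambda))) {
    out <- stats::setNames(numeric(length(tags)), tags)
    unknown <- setdiff(names(lambda), tags)
    if (length(unknown) > 0L) {
      stop("lambda named for tags not in the codebook: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    out[names(lambda)] <- lambda
    lambda <- out
  } else if (length(lambda) == 1L) {
    lambda <- rep(lambda, length(tags))
  }
  if (length(lambda) != length(tags)) {
    stop("lambda must be scalar, per-tag, or named by tag", call. = FALSE)
  }
  if (any(lambda < 0)) stop("lambda must be non-negative", call. = FALSE)
  unname(lambda)
}

label_prob_packed <- function(prep, lambda) {
  v <- numeric(prep$n_states)
  v[1L] <- 1
  states <- 0:(prep$n_states - 1L)
  for (t in seq_along(prep$sig)) {
    p <- -expm1(-lambda[t])
    if (p == 0) next
    idx <- bitwOr(states, prep$sig[t])
    contrib <- v * p
    v <- v * (1 - p)
    v <- scatter_add(v, idx, contrib)
  }
  v
}

# ---- methods -------------------------------------------------------------

#' @export
print.dpcr_decode <- function(x, ...) {
  cat(sprintf("dPCR deconvolution: %d tags over %d channels; N = %s partitions, %s null\n",
              nrow(x$table), x$codebook$channels,
              format(x$n_partitions, big.mark = ","),
              format(x$null_count, big.mark = ",")))
  cat(sprintf("Total estimated copies: %.1f", sum(x$copies)))
  if (nrow(x$excluded) > 0L) {
    cat(sprintf("; %g partitions in %d non-signature labels excluded",
                sum(x$excluded$count), nrow(x$excluded)))
  }
  cat("\nPer-tag copies (head):\n")
  print(utils::head(round(x$copies, 2), 8L))
  invisible(x)
}

#' Extract estimated copy numbers or occupancies
#'
#' @param object a `dpcr_decode` fit.
#' @param type `"copies"` (N * lambda, default) or `"lambda"` (mean copies
#'   per partition).
#' @param ... unused.
#' @return named numeric vector, one entry per tag.
#' @export
coef.dpcr_decode <- function(object, type = c("copies", "lambda"), ...) {
  switch(match.arg(type), copies = object$copies, lambda = object$lambda)
}

#' @export
summary.dpcr_decode <- function(object, ...) {
  structure(
    list(table = object$table, excluded = object$excluded,
         n_partitions = object$n_partitions, null_count = object$null_count,
         total_copies = sum(object$copies)),
    class = "summary.dpcr_decode"
  )
}

#' @export
print.summary.dpcr_decode <- function(x, digits = 4, ...) {
  cat(sprintf("N = %s partitions, null count P_0 = %s, total copies %.1f\n\n",
              format(x$n_partitions, big.mark = ","),
              format(x$null_count, big.mark = ","), x$total_copies))
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], signif, digits = digits)
  print(tab, row.names = FALSE)
  if (nrow(x$excluded) > 0L) {
    cat(sprintf("\n%d ambiguous non-signature label(s) excluded from estimation (%g partitions):\n",
                nrow(x$excluded), sum(x$excluded$count)))
    print(x$excluded, row.names = FALSE)
  }
  invisible(x)
}

#' Expected label counts implied by a fit
#'
#' `N` times the exact label probabilities at the estimated lambdas.
#'
#' @param object a `dpcr_decode` fit.
#' @param ... unused.
#' @return named numeric vector of expected counts over achievable labels.
#' @export
fitted.dpcr_decode <- function(object, ...) {
  object$n_partitions * label_probabilities(object$codebook, object$lambda)
}

#' Residual label counts of a fit
#'
#' Observed minus expected label counts over the union of observed and
#' achievable labels; `"pearson"` divides by the square root of the expected
#' count (labels with zero expectation keep their raw residual).
#'
#' @param object a `dpcr_decode` fit.
#' @param type `"response"` or `"pearson"`.
#' @param ... unused.
#' @return named numeric vector.
#' @export
residuals.dpcr_decode <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  exp_counts <- fitted(object)
  obs <- object$counts$counts
  labs <- sort(union(names(exp_counts), names(obs)), method = "radix")
  e <- ifelse(labs %in% names(exp_counts), exp_counts[labs], 0)
  o <- ifelse(labs %in% names(obs), obs[labs], 0)
  r <- o - e
  if (type == "pearson") r <- ifelse(e > 0, r / sqrt(e), r)
  stats::setNames(r, labs)
}

#' Parametric bootstrap of label counts from a fit
#'
#' Draws new label tallies from the multinomial distribution implied by the
#' fitted label probabilities at the estimated lambdas — the run-to-run
#' randomness of partition loading with the fitted copy numbers.
#'
#' @param object a `dpcr_decode` fit.
#' @param nsim number of replicate tallies.
#' @param seed optional integer seed (RNG state restored on exit).
#' @param ... unused.
#' @return list of [label_counts()] objects, length `nsim`.
#' @export
simulate.dpcr_decode <- function(object, nsim = 1, seed = NULL, ...) {
  probs <- label_probabilities(object$codebook, object$lambda)
  N <- round(object$n_partitions)
  with_seed(seed, {
    draws <- stats::rmultinom(nsim, N, probs)
    lapply(seq_len(nsim), function(i) {
      label_counts(stats::setNames(as.numeric(draws[, i]), rownames(draws)),
                   channels = object$codebook$channels)
    })
  })
}

#' Predicted label distribution of a fit
#'
#' @param object a `dpcr_decode` fit.
#' @param type `"probability"` (label probabilities) or `"counts"` (expected
#'   counts, `N` times the probabilities).
#' @param ... unused.
#' @return data frame with columns `label` and `value`.
#' @export
predict.dpcr_decode <- function(object, type = c("probability", "counts"), ...) {
  type <- match.arg(type)
  p <- label_probabilities(object$codebook, object$lambda)
  if (type == "counts") p <- p * object$n_partitions
  data.frame(label = names(p), value = unname(p), stringsAsFactors = FALSE)
}

#' Diagnostic plot of observed versus fitted label counts
#'
#' @param x a `dpcr_decode` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dpcr_decode <- function(x, ...) {
  e <- fitted(x)
  obs <- x$counts$counts
  labs <- union(names(e), names(obs))
  o <- ifelse(labs %in% names(obs), obs[labs], 0)
  f <- ifelse(labs %in% names(e), e[labs], 0)
  graphics::plot(log10(1 + f), log10(1 + o),
                 xlab = "log10(1 + fitted label count)",
                 ylab = "log10(1 + observed label count)",
                 main = "Observed vs fitted partition label counts", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
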