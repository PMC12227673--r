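# Partition-level dPCR simulator: Poisson loading of tagged amplicons into
# partitions, then fluorescence rendering with configurable instrument
# artifacts.  This is both the package's fixture generator and the engine
# behind the design studies.

#' Instrument noise model for simulated fluorescence
#'
#' Collects the artifact parameters of the simulator on the calibrated
#' intensity scale (1i cluster at 1):
#' * `level_means`: ideal intensities for amplitude levels 0..3; the default
#'   0/1/2/3 reflects the 2:1 probe concentration ratio and additive signal
#'   interpretation (level 3 = 1i + 2i contributions).
#' * `cluster_sd`: Gaussian scatter of each partition cluster (scalar, one
#'   value per level, or a channels x 4 matrix).
#' * `baseline_offset`: additive per-well constant (scalar or per channel).
#' * `rain_fraction`: probability that a positive partition-channel value is
#'   drawn uniformly between its level mean and the next lower level mean
#'   (inefficient amplification/hydrolysis producing intermediate "rain").
#' * `incomplete_hydrolysis_prob` / `incomplete_hydrolysis_factor`:
#'   probability that the 2i contribution of a channel is attenuated, and the
#'   attenuation multiplier; with factor 0.75 a tag encoded [0,0,1,2] renders
#'   at [0,0,1,1.5].
#'
#' @param level_means ideal intensities for levels 0..3 (ascending), or a
#'   channels x 4 matrix.
#' @param cluster_sd Gaussian cluster standard deviation(s), >= 0.
#' @param baseline_offset additive offset(s).
#' @param rain_fraction probability in \[0, 1\].
#' @param incomplete_hydrolysis_prob probability in \[0, 1\].
#' @param incomplete_hydrolysis_factor attenuation multiplier in \[0, 1\].
#' @return object of class `dpcr_noise_model`.
#' @export
noise_model <- function(level_means = c(0, 1, 2, 3),
                        cluster_sd = 0.05,
                        baseline_offset = 0,
                        rain_fraction = 0,
                        incomplete_hydrolysis_prob = 0,
                        incomplete_hydrolysis_factor = 0.75) {
  if (!is.matrix(level_means)) {
    stopifnot(length(level_means) == 4L)
  } else {
    stopifnot(ncol(level_means) == 4L)
  }
  lm <- if (is.matrix(level_means)) level_means else rbind(level_means)
  if (any(apply(lm, 1L, diff) <= 0)) {
    stop("level means must be strictly increasing in every channel", call. = FALSE)
  }
  stopifnot(all(cluster_sd >= 0),
            rain_fraction >= 0, rain_fraction <= 1,
            incomplete_hydrolysis_prob >= 0, incomplete_hydrolysis_prob <= 1,
            incomplete_hydrolysis_factor >= 0, incomplete_hydrolysis_factor <= 1)
  structure(
    list(level_means = level_means, cluster_sd = cluster_sd,
         baseline_offset = baseline_offset, rain_fraction = rain_fraction,
         incomplete_hydrolysis_prob = incomplete_hydrolysis_prob,
         incomplete_hydrolysis_factor = incomplete_hydrolysis_factor),
    class = "dpcr_noise_model"
  )
}

#' Uniform spectral crosstalk matrix
#'
#' Mixing matrix in which every channel bleeds the fraction `alpha` of its
#' true signal into the other channels, split evenly: identity diagonal plus
#' `alpha / (C - 1)` off-diagonal.  `alpha = 0` is the identity; `alpha = 1`
#' means each channel's full signal is duplicated across the others.
#'
#' @param channels number of channels.
#' @param alpha total bleed fraction per channel, in \[0, 1\].
#' @return C x C numeric mixing matrix.
#' @export
uniform_crosstalk <- function(channels, alpha) {
  stopifnot(channels >= 2L, alpha >= 0, alpha <= 1)
  m <- matrix(alpha / (channels - 1L), channels, channels)
  diag(m) <- 1
  m
}

# Temporarily seed the RNG, restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Poisson loading of tagged molecules into partitions
#'
#' For every tag, a Poisson number of molecules (mean = expected copies in the
#' reaction) is placed independently and uniformly across the partitions; a
#' partition's occupancy is the set of distinct tags with at least one
#' molecule.  The `"bernoulli"` method samples each partition's presence
#' directly with probability 1 - exp(-copies/N), which is exact at the
#' occupancy level (Poisson thinning) and faster at high plex.
#'
#' @param codebook a `dpcr_codebook`.
#' @param copies expected copy count per tag in the whole reaction; scalar
#'   (recycled) or vector named by tag name.
#' @param n_partitions number of partitions N (e.g. 26000).
#' @param method `"molecules"` (explicit placement) or `"bernoulli"`.
#' @param seed optional integer seed (RNG state is restored on exit).
#' @return logical occupancy matrix, `n_partitions` x tags, with tag names as
#'   column names.
#' @export
load_partitions <- function(codebook, copies, n_partitions = 26000,
                            method = c("molecules", "bernoulli"), seed = NULL) {
  stopifnot(inherits(codebook, "dpcr_codebook"), n_partitions >= 1)
  method <- match.arg(method)
  tags <- codebook$tags$name
  copies <- expand_copies(copies, tags)
  if (any(copies < 0)) stop("copies must be non-negative", call. = FALSE)
  N <- as.integer(n_partitions)
  with_seed(seed, {
    presence <- matrix(FALSE, nrow = N, ncol = length(tags),
                       dimnames = list(NULL, tags))
    if (method == "molecules") {
      for (t in seq_along(tags)) {
        n_mol <- stats::rpois(1L, copies[t])
        if (n_mol > 0L) {
          presence[unique(sample.int(N, n_mol, replace = TRUE)), t] <- TRUE
        }
      }
    } else {
      p <- -expm1(-copies / N)
      for (t in seq_along(tags)) {
        presence[, t] <- stats::runif(N) < p[t]
      }
    }
    presence
  })
}

expand_copies <- function(copies, tags) {
  if (is.null(names(copies))) {
    if (length(copies) == 1L) copies <- rep(copies, length(tags))
    if (length(copies) != length(tags)) {
      stop("copies must be scalar, per-tag, or named by tag", call. = FALSE)
    }
    names(copies) <- tags
    copies
  } else {
    unknown <- setdiff(names(copies), tags)
    if (length(unknown) > 0L) {
      stop("copies named for tags not in the codebook: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    out <- stats::setNames(numeric(length(tags)), tags)
    out[names(copies)] <- copies
    out
  }
}

# True per-channel amplitude levels implied by an occupancy matrix:
# per channel, bit 1 set if any present tag carries a 1i site there, bit 2 if
# any carries a 2i site.  Extra tags sharing a probe class saturate (union).
occupancy_levels <- function(presence, codebook) {
  d <- label_digits(codebook$tags$signature, codebook$channels)
  N <- nrow(presence)
  lev <- matrix(0L, nrow = N, ncol = codebook$channels)
  for (c in seq_len(codebook$channels)) {
    has1 <- d[, c] == 1L
    has2 <- d[, c] == 2L
    bit1 <- if (any(has1)) rowSums(presence[, has1, drop = FALSE]) > 0L else FALSE
    bit2 <- if (any(has2)) rowSums(presence[, has2, drop = FALSE]) > 0L else FALSE
    lev[, c] <- bit1 + 2L * bit2
  }
  lev
}

#' Render fluorescence amplitudes from partition occupancy
#'
#' Converts true per-channel amplitude levels (the signature union of each
#' partition's occupants) into continuous observed values: ideal level mean,
#' minus incomplete-hydrolysis attenuation of the 2i contribution, rain
#' substitution, Gaussian cluster noise, spectral mixing by the crosstalk
#' matrix, and the baseline offset.  Values may be negative after noise (they
#' are not clipped).
#'
#' @param occupancy logical partitions x tags matrix from [load_partitions()].
#' @param codebook a `dpcr_codebook`.
#' @param noise a [noise_model()].
#' @param crosstalk optional C x C mixing matrix (entry (i, j) = fraction of
#'   channel j's true signal detected in channel i); identity if NULL.
#' @param seed optional integer seed.
#' @return list with `amplitudes` (N x C matrix, columns ch1..chC) and
#'   `true_labels` (character vector of signature-union labels).
#' @export
render_signal <- function(occupancy, codebook, noise = noise_model(),
                          crosstalk = NULL, seed = NULL) {
  stopifnot(inherits(codebook, "dpcr_codebook"),
            inherits(noise, "dpcr_noise_model"))
  if (ncol(occupancy) != nrow(codebook$tags)) {
    stop("occupancy has one column per codebook tag", call. = FALSE)
  }
  C <- codebook$channels
  if (!is.null(crosstalk)) {
    crosstalk <- as.matrix(crosstalk)
    if (nrow(crosstalk) != C || ncol(crosstalk) != C) {
      stop("crosstalk matrix dimension must equal the channel count",
           call. = FALSE)
    }
  }
  lev <- occupancy_levels(occupancy, codebook)
  with_seed(seed, {
    amp <- render_levels(lev, noise, crosstalk)
    list(amplitudes = amp, true_labels = digits_label(lev))
  })
}

# Core renderer shared with the crosstalk study: true levels -> amplitudes.
render_levels <- function(lev, noise, crosstalk = NULL) {
  N <- nrow(lev)
  C <- ncol(lev)
  means <- noise$level_means
  if (!is.matrix(means)) means <- matrix(means, C, 4L, byrow = TRUE)
  sds <- noise$cluster_sd
  if (!is.matrix(sds)) {
    sds <- matrix(sds, C, 4L, byrow = (length(sds) == 4L))
  }
  amp <- matrix(0, N, C, dimnames = list(NULL, paste0("ch", seq_len(C))))
  f <- noise$incomplete_hydrolysis_factor
  for (c in seq_len(C)) {
    m <- means[c, ]
    x <- m[lev[, c] + 1L]
    # incomplete hydrolysis: the 2i contribution (m2 - m0) is attenuated
    if (noise$incomplete_hydrolysis_prob > 0) {
      has2i <- bitwAnd(lev[, c], 2L) != 0L
      hit <- has2i & stats::runif(N) < noise$incomplete_hydrolysis_prob
      x[hit] <- x[hit] - (1 - f) * (m[3L] - m[1L])
    }
    if (noise$rain_fraction > 0) {
      pos <- lev[, c] > 0L
      rain <- pos & stats::runif(N) < noise$rain_fraction
      if (any(rain)) {
        lo <- m[lev[rain, c]]       # next lower level mean
        hi <- m[lev[rain, c] + 1L]
        x[rain] <- stats::runif(sum(rain), lo, hi)
      }
    }
    amp[, c] <- x + stats::rnorm(N, sd = sds[c, lev[, c] + 1L])
  }
  if (!is.null(crosstalk)) {
    amp <- amp %*% t(crosstalk)
    colnames(amp) <- paste0("ch", seq_len(C))
  }
  offset <- noise$baseline_offset
  if (length(offset) == 1L) offset <- rep(offset, C)
  sweep(amp, 2L, offset, "+")
}

#' Simulate a complete dPCR run with known ground truth
#'
#' Chains [load_partitions()] and [render_signal()] into a single reproducible
#' run: Poisson loading of every tag, signature-union labels, and observed
#' amplitudes under the given noise model and crosstalk.
#'
#' @inheritParams load_partitions
#' @inheritParams render_signal
#' @return object of class `dpcr_run`: list with `amplitudes` (N x C),
#'   `true_labels`, `occupancy` (logical N x tags), `codebook`, `copies`,
#'   `n_partitions`, `noise`, `crosstalk`, `seed`.
#' @examples
#' cb <- enumerate_codebook(4, 2, 2)
#' run <- simulate_run(cb, copies = 100, n_partitions = 5000, seed = 1)
#' table(run$true_labels)[1:3]
#' @export
simulate_run <- function(codebook, copies, n_partitions = 26000,
                         noise = noise_model(), crosstalk = NULL,
                         method = c("molecules", "bernoulli"), seed = NULL) {
  method <- match.arg(method)
  with_seed(seed, {
    occupancy <- load_partitions(codebook, copies, n_partitions, method)
    rendered <- render_signal(occupancy, codebook, noise, crosstalk)
    structure(
      list(amplitudes = rendered$amplitudes,
           true_labels = rendered$true_labels,
           occupancy = occupancy,
           codebook = codebook,
           copies = expand_copies(copies, codebook$tags$name),
           n_partitions = as.integer(n_partitions),
           noise = noise, crosstalk = crosstalk, seed = seed),
      class = "dpcr_run"
    )
  })
}

#' @export
print.dpcr_run <- function(x, ...) {
  occ <- sum(x$true_labels != strrep("0", x$codebook$channels))
  cat(sprintf("Simulated dPCR run: %s partitions, %d channels, %d tags; %s occupied (%.1f%%)\n",
              format(x$n_partitions, big.mark = ","), x$codebook$channels,
              nrow(x$codebook$tags), format(occ, big.mark = ","),
              100 * occ / x$n_partitions))
  invisible(x)
}
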