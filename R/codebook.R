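#' Encoding capacity of a combinatorial tag code
#'
#' Number of distinct tag signatures that can be built on an instrument with
#' `channels` color channels when each tag carries between one and `max_sites`
#' universal probe sites and every site can be filled with one of
#' `levels_per_site` probe classes (amplitude levels).  The count is
#' \deqn{\sum_{k=1}^{max\_sites} \binom{C}{k} L^k}
#' e.g. 4 channels with up to two sites at two levels give 32 signatures, and
#' allowing sites in every channel gives \eqn{(L+1)^C - 1} (80 for C = 4,
#' 728 for C = 6).
#'
#' @param channels number of color channels (C >= 1).
#' @param levels_per_site number of distinguishable probe classes per site
#'   (L >= 1; 2 for the 1i/2i chemistry).
#' @param max_sites maximum probe sites per tag (1 <= max_sites <= channels).
#' @return integer count of encodable targets.
#' @examples
#' capacity(4, 2, 2)  # 32
#' capacity(6, 2, 6)  # 3^6 - 1 = 728
#' @export
capacity <- function(channels, levels_per_site, max_sites) {
  stopifnot(length(channels) == 1L, length(levels_per_site) == 1L,
            length(max_sites) == 1L)
  channels <- as.integer(channels)
  levels_per_site <- as.integer(levels_per_site)
  max_sites <- as.integer(max_sites)
  if (is.na(channels) || channels < 1L ||
      is.na(levels_per_site) || levels_per_site < 1L ||
      is.na(max_sites) || max_sites < 1L) {
    stop("channels, levels_per_site and max_sites must all be >= 1",
         call. = FALSE)
  }
  if (max_sites > channels) {
    stop("max_sites cannot exceed the number of channels", call. = FALSE)
  }
  k <- seq_len(max_sites)
  sum(choose(channels, k) * levels_per_site^k)
}

#' Construct a tag codebook
#'
#' A codebook is the set of tag signatures in play for one assay.  Signatures
#' are digit strings with channel 1 leftmost; digit 0 means no probe site in
#' that channel, 1 a site for the low-concentration "1i" probe, 2 a site for
#' the high-concentration "2i" probe.  Digit 3 never appears in a signature
#' (amplitude level 3 only arises in observed labels, from co-presence).
#'
#' @param signatures character vector of distinct signature strings.
#' @param names target identifiers, one per signature (default: the
#'   signatures themselves).
#' @param levels_per_site probe classes per site; only 2 (the 1i/2i chemistry)
#'   is supported by the signature algebra.
#' @param max_sites maximum probe sites per tag; defaults to the largest
#'   number of nonzero digits observed.
#' @return an object of class `dpcr_codebook` with fields `channels`,
#'   `levels_per_site`, `max_sites` and `tags` (data frame of `name`,
#'   `signature`).
#' @seealso [enumerate_codebook()], [read_codebook()]
#' @export
codebook <- function(signatures, names = signatures, levels_per_site = 2,
                     max_sites = NULL) {
  signatures <- as.character(signatures)
  if (length(signatures) == 0L) stop("a codebook needs at least one tag",
                                     call. = FALSE)
  if (levels_per_site != 2) {
    stop("the signature algebra supports exactly two amplitude levels per site",
         call. = FALSE)
  }
  if (anyDuplicated(signatures)) {
    stop("codebook signatures must be pairwise distinct", call. = FALSE)
  }
  if (length(names) != length(signatures)) {
    stop("`names` must match `signatures` in length", call. = FALSE)
  }
  if (anyDuplicated(names)) {
    stop("tag names must be distinct", call. = FALSE)
  }
  d <- label_digits(signatures)
  channels <- ncol(d)
  if (any(d > 2L)) {
    stop("signature digits must be 0, 1 or 2 (level 3 is a label, not a signature)",
         call. = FALSE)
  }
  sites <- rowSums(d > 0L)
  if (any(sites == 0L)) {
    stop("every signature needs at least one nonzero digit", call. = FALSE)
  }
  max_sites <- as.integer(max_sites %||% max(sites))
  if (any(sites > max_sites)) {
    stop("a signature uses more probe sites than max_sites allows", call. = FALSE)
  }
  if (max_sites > channels) {
    stop("max_sites cannot exceed the number of channels", call. = FALSE)
  }
  structure(
    list(
      channels = channels,
      levels_per_site = 2L,
      max_sites = max_sites,
      tags = data.frame(name = as.character(names), signature = signatures,
                        stringsAsFactors = FALSE)
    ),
    class = "dpcr_codebook"
  )
}

#' @export
print.dpcr_codebook <- function(x, ...) {
  cat(sprintf("Tag codebook: %d tags, %d channels, %d level(s)/site, <= %d site(s)/tag\n",
              nrow(x$tags), x$channels, x$levels_per_site, x$max_sites))
  show <- utils::head(x$tags$signature, 8L)
  cat("  signatures:", paste(show, collapse = " "),
      if (nrow(x$tags) > 8L) "..." else "", "\n")
  invisible(x)
}

#' Enumerate the full canonical codebook
#'
#' Lists every admissible signature over `channels` channels with between one
#' and `max_sites` probe sites, in deterministic lexicographic order, and
#' names each tag by its signature string.  The count always equals
#' [capacity()].  This canonical enumeration serves as the reference ordering;
#' assay-specific tag-to-target assignments can be supplied via [codebook()]
#' or [read_codebook()].
#'
#' @inheritParams capacity
#' @return a `dpcr_codebook`.
#' @examples
#' enumerate_codebook(2, 2, 1)  # signatures 01, 02, 10, 20
#' @export
enumerate_codebook <- function(channels, levels_per_site = 2, max_sites = 2) {
  n <- capacity(channels, levels_per_site, max_sites)  # validates arguments
  if (levels_per_site != 2) {
    stop("the signature algebra supports exactly two amplitude levels per site",
         call. = FALSE)
  }
  grid <- expand.grid(rep(list(0:2), channels), KEEP.OUT.ATTRS = FALSE)
  # expand.grid varies the first factor fastest; column 1 is channel 1
  sig <- apply(as.matrix(grid), 1L, paste, collapse = "")
  sites <- rowSums(as.matrix(grid) > 0L)
  sig <- sort(sig[sites >= 1L & sites <= max_sites], method = "radix")
  stopifnot(length(sig) == n)
  codebook(sig, max_sites = as.integer(max_sites))
}

#' Union of tag signatures under co-presence
#'
#' When several tags occupy one partition, each channel's observed amplitude
#' level encodes the set of probe classes consumed there: 0 none, 1 only 1i,
#' 2 only 2i, 3 both.  Extra tags sharing a probe class do not raise the level
#' (probe consumption saturates), so the union is idempotent, commutative and
#' associative.
#'
#' @param signatures character vector of signatures (or labels) with a common
#'   channel count.
#' @return single label string.
#' @examples
#' signature_union(c("1000", "0100"))  # "1100"
#' signature_union(c("1000", "2000"))  # "3000"
#' @export
signature_union <- function(signatures) {
  if (length(signatures) == 0L) {
    stop("signature_union needs at least one signature", call. = FALSE)
  }
  d <- label_digits(signatures)
  p <- pack_digits(d)
  unpack_labels(Reduce(bitwOr, p), ncol(d))
}

#' Decompose a partition label into candidate tag combinations
#'
#' Lists every subset of codebook tags whose signature union reproduces the
#' label exactly.  These are the tag combinations the partition could contain:
#' e.g. with tags 1000, 0100 and 1100 in play, label 1100 admits five
#' combinations (1100; 1000+0100; 1100+1000; 1100+0100; 1100+1000+0100).
#'
#' @param label label string (digits 0-3).
#' @param codebook a `dpcr_codebook`.
#' @param max_contained guard on the subset enumeration: error if more than
#'   this many codebook tags are contained in the label (the enumeration is
#'   exponential in that count).
#' @return list of character vectors of tag names (possibly empty), ordered by
#'   combination size then lexicographically.
#' @export
decompositions <- function(label, codebook, max_contained = 20) {
  stopifnot(inherits(codebook, "dpcr_codebook"), length(label) == 1L)
  lab <- pack_labels(label, codebook$channels)
  sigs <- pack_labels(codebook$tags$signature, codebook$channels)
  cand <- which(packed_contained(sigs, lab))
  if (length(cand) > max_contained) {
    stop(sprintf("label %s contains %d codebook tags; enumeration capped at %d",
                 label, length(cand), max_contained), call. = FALSE)
  }
  out <- list()
  if (length(cand) > 0L) {
    m <- length(cand)
    for (mask in seq_len(2L^m - 1L)) {
      members <- cand[bitwAnd(mask, 2L^(seq_len(m) - 1L)) != 0L]
      if (Reduce(bitwOr, sigs[members]) == lab) {
        out[[length(out) + 1L]] <- codebook$tags$name[members]
      }
    }
    ord <- order(lengths(out),
                 vapply(out, paste, "", collapse = "+"),
                 method = "radix")
    out <- out[ord]
  }
  out
}

#' Read or write a codebook file
#'
#' JSON codebooks carry fields `channels`, `levels_per_site`, `max_sites` and
#' `tags` (array of `{name, signature}`); CSV codebooks are two columns
#' (`name`, `signature`) with channel count inferred from the signatures.
#'
#' @param path file path; format chosen by extension (`.json` or `.csv`).
#' @return `read_codebook()` returns a `dpcr_codebook`; `write_codebook()`
#'   returns `path` invisibly.
#' @export
read_codebook <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::fromJSON(path)
    cb <- codebook(as.character(x$tags$signature),
                   names = as.character(x$tags$name),
                   levels_per_site = x$levels_per_site %||% 2,
                   max_sites = x$max_sites)
    if (!is.null(x$channels) && cb$channels != x$channels) {
      stop("codebook file channel count disagrees with its signatures",
           call. = FALSE)
    }
    cb
  } else {
    x <- utils::read.csv(path, colClasses = "character")
    if (!all(c("name", "signature") %in% names(x))) {
      stop("CSV codebook needs columns `name` and `signature`", call. = FALSE)
    }
    codebook(x$signature, names = x$name)
  }
}

#' @param codebook a `dpcr_codebook` to serialize.
#' @rdname read_codebook
#' @export
write_codebook <- function(codebook, path) {
  stopifnot(inherits(codebook, "dpcr_codebook"))
  jsonlite::write_json(
    list(channels = codebook$channels,
         levels_per_site = codebook$levels_per_site,
         max_sites = codebook$max_sites,
         tags = codebook$tags),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
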