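# Internal representation of signatures and labels.
#
# A signature or label is a digit string, channel 1 leftmost ("1100").
# Signature digits are 0/1/2 (no probe site / "1i" low-concentration site /
# "2i" high-concentration site); label digits add 3 (both probe classes of a
# channel consumed).  Digits are bitmasks over probe classes (bit 1 = 1i,
# bit 2 = 2i), so the union of labels is a bitwise OR and packing a label in
# base 4 (channel 1 in the low bits) makes OR on packed integers exact:
# 2-bit fields never carry.

label_digits <- function(x, channels = NULL) {
  x <- as.character(x)
  if (length(x) == 0L) {
    return(matrix(integer(), nrow = 0L, ncol = channels %||% 0L))
  }
  nc <- nchar(x)
  if (length(unique(nc)) != 1L) {
    stop("labels must all have the same number of channels", call. = FALSE)
  }
  if (!is.null(channels) && nc[1L] != channels) {
    stop(sprintf("expected %d-channel labels, got %d digits", channels, nc[1L]),
         call. = FALSE)
  }
  d <- matrix(utf8ToInt(paste(x, collapse = "")) - utf8ToInt("0"),
              nrow = length(x), ncol = nc[1L], byrow = TRUE)
  if (any(d < 0L | d > 3L)) {
    stop("labels may only contain digits 0-3", call. = FALSE)
  }
  d
}

digits_label <- function(d) {
  if (nrow(d) == 0L) return(character())
  apply(d, 1L, paste, collapse = "")
}

pack_digits <- function(d) {
  as.integer(d %*% 4L^(seq_len(ncol(d)) - 1L))
}

pack_labels <- function(x, channels = NULL) {
  pack_digits(label_digits(x, channels))
}

unpack_digits <- function(packed, channels) {
  d <- matrix(0L, nrow = length(packed), ncol = channels)
  for (c in seq_len(channels)) {
    d[, c] <- packed %% 4L
    packed <- packed %/% 4L
  }
  d
}

unpack_labels <- function(packed, channels) {
  digits_label(unpack_digits(as.integer(packed), channels))
}

# number of nonzero digits (probe sites) of packed signatures
packed_sites <- function(packed, channels) {
  rowSums(unpack_digits(packed, channels) > 0L)
}

# is signature `a` channel-wise contained in label `b`?  Digits are probe-class
# bitmasks, so containment is a bitwise-AND test on the packed form (vectorized).
packed_contained <- function(a, b) {
  bitwAnd(a, b) == a
}

`%||%` <- function(a, b) if (is.null(a)) b else a
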