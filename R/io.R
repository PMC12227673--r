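# Readers and writers for the package's stable file formats.  Partition
# tables are generic CSV as exported from dPCR instruments after vendor
# software; labels serialize as quoted digit strings so leading zeros survive
# spreadsheet round trips.

#' Read or write a partition amplitude table
#'
#' CSV with columns `partition_id`, `well`, `ch1..chC` — one row per
#' partition, one amplitude column per color channel.
#'
#' @param path CSV file path.
#' @return `read_partitions()` returns a data frame with those columns;
#'   `write_partitions()` returns `path` invisibly.
#' @export
read_partitions <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  ch <- grep("^ch[0-9]+$", names(x), value = TRUE)
  if (length(ch) == 0L) {
    stop("partition CSV needs ch1..chC amplitude columns", call. = FALSE)
  }
  if (nrow(x) == 0L) stop("partition CSV is empty", call. = FALSE)
  if (!all(vapply(x[ch], is.numeric, logical(1)))) {
    stop("amplitude columns must be numeric", call. = FALSE)
  }
  x
}

#' @param x partition data frame (`partition_id`, `well`, `ch*`), or an
#'   amplitude matrix, or a `dpcr_run` (its amplitudes are written).
#' @param well well identifier used when `x` has no `well` column.
#' @rdname read_partitions
#' @export
write_partitions <- function(x, path, well = "A1") {
  if (inherits(x, "dpcr_run")) x <- x$amplitudes
  if (is.matrix(x)) {
    colnames(x) <- paste0("ch", seq_len(ncol(x)))
    x <- data.frame(partition_id = seq_len(nrow(x)), well = well, x)
  }
  if (!"partition_id" %in% names(x)) {
    x <- cbind(partition_id = seq_len(nrow(x)), x)
  }
  if (!"well" %in% names(x)) x <- cbind(x, well = well)
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Read or write a label-count table
#'
#' Two-column CSV (`label`, `count`); labels are read as character so
#' leading zeros are preserved.
#'
#' @param path CSV file path.
#' @param channels expected channel count (optional check on read).
#' @return `read_label_counts()` returns a [label_counts()] object;
#'   `write_label_counts()` returns `path` invisibly.
#' @export
read_label_counts <- function(path, channels = NULL) {
  x <- utils::read.csv(path, colClasses = c(label = "character"))
  if (!all(c("label", "count") %in% names(x))) {
    stop("label-count CSV needs columns `label` and `count`", call. = FALSE)
  }
  label_counts(stats::setNames(as.numeric(x$count), x$label), channels)
}

#' @param counts a [label_counts()] object.
#' @rdname read_label_counts
#' @export
write_label_counts <- function(counts, path) {
  stopifnot(inherits(counts, "label_counts"))
  utils::write.csv(
    data.frame(label = names(counts$counts), count = unname(counts$counts)),
    path, row.names = FALSE, quote = 1L
  )
  invisible(path)
}

#' Read a crosstalk matrix from CSV
#'
#' Plain numeric C x C matrix, entry (i, j) = fraction of channel j's true
#' signal detected in channel i; a header row is optional.
#'
#' @param path CSV file path.
#' @return numeric matrix.
#' @export
read_crosstalk <- function(path) {
  first <- utils::read.csv(path, header = FALSE, nrows = 1L)
  header <- !all(vapply(first, is.numeric, logical(1)))
  m <- as.matrix(utils::read.csv(path, header = header))
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) stop("crosstalk matrix must be square", call. = FALSE)
  if (any(!is.finite(m))) stop("crosstalk matrix must be numeric", call. = FALSE)
  unname(m)
}

#' Read a simulation configuration
#'
#' YAML or JSON mirroring the simulator's arguments: `partitions`, `seed`,
#' `copies` (map tag -> expected copies), `codebook` (inline
#' `{channels, max_sites}` to enumerate, or `{path}` to load), optional
#' `noise` (fields of [noise_model()]) and `crosstalk` (inline matrix or
#' `{path}`).
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return list with `codebook`, `copies`, `n_partitions`, `noise`,
#'   `crosstalk`, `seed`, ready to splice into [simulate_run()].
#' @export
read_sim_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  if (is.null(cfg$codebook)) stop("config needs a `codebook` entry", call. = FALSE)
  cb <- if (!is.null(cfg$codebook$path)) {
    read_codebook(cfg$codebook$path)
  } else {
    enumerate_codebook(cfg$codebook$channels,
                       cfg$codebook$levels_per_site %||% 2,
                       cfg$codebook$max_sites %||% 2)
  }
  copies <- cfg$copies
  if (is.list(copies)) copies <- unlist(copies)
  if (is.null(copies)) stop("config needs a `copies` entry", call. = FALSE)
  noise_args <- cfg$noise %||% list()
  noise <- do.call(noise_model, lapply(noise_args, unlist))
  xt <- NULL
  if (!is.null(cfg$crosstalk)) {
    xt <- if (!is.null(cfg$crosstalk$path)) {
      read_crosstalk(cfg$crosstalk$path)
    } else {
      m <- cfg$crosstalk
      if (is.list(m)) m <- do.call(rbind, m)
      matrix(as.numeric(m), nrow = NROW(m))
    }
  }
  list(codebook = cb, copies = copies,
       n_partitions = cfg$partitions %||% 26000,
       noise = noise, crosstalk = xt, seed = cfg$seed)
}
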