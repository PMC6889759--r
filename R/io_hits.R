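# BLAST/DIAMOND tabular (outfmt-6-like) input, partitioned into metazoan
# and non-metazoan best hits. The taxon partition travels with each hit
# record from here on: downstream code never re-derives it.

HIT_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read a taxon-partitioned best-hit table
#'
#' Parses a 12- or 13-column BLAST tabular file (`qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore
#' [staxid]`). Every hit must be assignable to the `metazoan` or
#' `non_metazoan` partition: either through `partition_map`, keyed by the
#' 13th column when present and by `sseqid` otherwise, or — when no map is
#' given — by a 13th column that itself carries the partition label.
#' Hits mapped to `excluded` or `self` (e.g. the query's own lineage) are
#' dropped.
#'
#' @param path path to the tabular file (no header).
#' @param partition_map named character vector (or two-column
#'   `data.frame`: key, partition) assigning each subject taxon to
#'   `"metazoan"`, `"non_metazoan"`, `"excluded"` or `"self"`.
#' @return `data.frame` with columns `query_id`, `subject_id`,
#'   `taxon_partition`, `evalue`, `percent_identity`, `bitscore`.
#' @export
read_hit_table <- function(path, partition_map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#")
  if (!ncol(raw) %in% c(12L, 13L)) {
    stop("expected 12 or 13 tab-separated columns, got ", ncol(raw))
  }
  names(raw)[1:12] <- HIT_COLS
  if (!is.null(partition_map)) {
    if (is.data.frame(partition_map)) {
      partition_map <- stats::setNames(as.character(partition_map[[2L]]),
                                       as.character(partition_map[[1L]]))
    }
    key <- if (ncol(raw) == 13L) as.character(raw[[13L]]) else raw$sseqid
    part <- unname(partition_map[key])
    if (anyNA(part)) {
      stop("unmapped taxon id(s): ",
           paste(unique(key[is.na(part)]), collapse = ", "))
    }
  } else {
    if (ncol(raw) != 13L) {
      stop("without a partition_map the table needs a 13th column ",
           "carrying the partition label")
    }
    part <- as.character(raw[[13L]])
  }
  valid <- c("metazoan", "non_metazoan", "excluded", "self")
  if (!all(part %in% valid)) {
    stop("invalid partition label(s): ",
         paste(unique(setdiff(part, valid)), collapse = ", "))
  }
  keep <- !part %in% c("excluded", "self")
  out <- data.frame(
    query_id = raw$qseqid[keep],
    subject_id = raw$sseqid[keep],
    taxon_partition = part[keep],
    evalue = as.numeric(raw$evalue[keep]),
    percent_identity = as.numeric(raw$pident[keep]),
    bitscore = as.numeric(raw$bitscore[keep]),
    stringsAsFactors = FALSE
  )
  if (any(out$evalue < 0)) stop("negative e-value in ", path)
  class(out) <- c("hit_table", "data.frame")
  out
}

#' Write a hit table in 13-column tabular form
#'
#' Emits the outfmt-6 columns plus the partition label as 13th column, so
#' that [read_hit_table()] round-trips without a `partition_map`. Alignment
#' coordinate columns not carried by the in-memory records are written as 0.
#'
#' @param x a hit table as returned by [read_hit_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(x, path) {
  out <- data.frame(
    qseqid = x$query_id, sseqid = x$subject_id,
    pident = x$percent_identity, length = 0L, mismatch = 0L, gapopen = 0L,
    qstart = 0L, qend = 0L, sstart = 0L, send = 0L,
    evalue = format(x$evalue, digits = 17, scientific = TRUE, trim = TRUE),
    bitscore = x$bitscore, partition = x$taxon_partition
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
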