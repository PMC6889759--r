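# Gene models from GFF3. Exon structure matters to the HGT screen in two
# ways: spliceosomal introns (intron_count = n_exons - 1) argue for
# domestication of a horizontally acquired gene, and contig co-location
# with bona fide metazoan genes argues against contamination.

#' Read gene models from a GFF3 file
#'
#' Collects the exons of each gene (resolving `exon -> mRNA -> gene` Parent
#' chains; exons attached directly to a gene are accepted). Coordinates are
#' kept 1-based inclusive as in GFF3. A gene annotated without exon
#' features is treated as a single-exon gene spanning its own record.
#'
#' @param path path to a GFF3 file.
#' @return `data.frame` with one row per gene: `gene_id`, `contig`,
#'   `strand`, `n_exons`, `intron_count`, and an `exons` list-column of
#'   two-column matrices (`start`, `end`), sorted and non-overlapping.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  g <- as.data.frame(rtracklayer::readGFF(
    path, columns = c("seqid", "type", "start", "end", "strand"),
    tags = c("ID", "Parent")))
  g$Parent <- vapply(g$Parent, function(p)
    if (length(p)) as.character(p[[1L]]) else NA_character_, character(1))
  genes <- g[g$type == "gene", , drop = FALSE]
  mrna <- g[g$type %in% c("mRNA", "transcript"), , drop = FALSE]
  exons <- g[g$type == "exon", , drop = FALSE]
  if (nrow(genes) == 0L) stop("no gene features in ", path)
  if (anyNA(genes$ID)) stop("gene feature without ID attribute in ", path)
  mrna2gene <- stats::setNames(mrna$Parent, mrna$ID)
  gene_ids <- genes$ID
  # resolve each exon to its gene
  exon_gene <- ifelse(exons$Parent %in% gene_ids, exons$Parent,
                      unname(mrna2gene[exons$Parent]))
  if (nrow(exons) && anyNA(exon_gene)) {
    bad <- exons$Parent[is.na(exon_gene)]
    stop("exon(s) with unresolvable Parent: ",
         paste(unique(bad), collapse = ", "))
  }
  exon_list <- lapply(seq_len(nrow(genes)), function(i) {
    gid <- gene_ids[i]
    ex <- exons[which(exon_gene == gid), , drop = FALSE]
    if (nrow(ex) == 0L) {
      m <- cbind(start = genes$start[i], end = genes$end[i])
    } else {
      ex <- ex[order(ex$start), , drop = FALSE]
      # distinct isoforms may repeat exons; keep the union of identical ones
      ex <- ex[!duplicated(ex[, c("start", "end")]), , drop = FALSE]
      if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)])) {
        stop("overlapping exons for gene ", gid)
      }
      m <- cbind(start = ex$start, end = ex$end)
    }
    storage.mode(m) <- "integer"
    m
  })
  n_exons <- vapply(exon_list, nrow, integer(1))
  out <- data.frame(
    gene_id = gene_ids,
    contig = as.character(genes$seqid),
    strand = as.character(genes$strand),
    n_exons = n_exons,
    intron_count = n_exons - 1L,
    stringsAsFactors = FALSE
  )
  out$exons <- exon_list
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Write gene models as GFF3
#'
#' Emits gene/mRNA/exon features so that [read_gene_models()] round-trips.
#' Used mainly to materialise synthetic annotations.
#'
#' @param x a `gene_models` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(x, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(x))) {
    gid <- x$gene_id[i]
    ex <- x$exons[[i]]
    strand <- if (x$strand[i] %in% c("+", "-")) x$strand[i] else "+"
    span <- c(min(ex[, "start"]), max(ex[, "end"]))
    lines <- c(
      lines,
      sprintf("%s\tpanagrokit\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              x$contig[i], span[1], span[2], strand, gid),
      sprintf("%s\tpanagrokit\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              x$contig[i], span[1], span[2], strand, gid, gid),
      sprintf("%s\tpanagrokit\texon\t%d\t%d\t.\t%s\t.\tParent=%s.t1",
              x$contig[i], ex[, "start"], ex[, "end"], strand, gid)
    )
  }
  writeLines(lines, path)
  invisible(path)
}
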