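# Matrix-shaped inputs: family-by-species presence/absence, pairwise
# distance matrices (PHYLIP square or TSV), and per-gene expression (TPM).

#' Read a family-by-species presence/absence matrix
#'
#' TSV with a header of species names and the family identifier in the
#' first column; cells `0/1` (or `TRUE/FALSE`).
#'
#' @param path input TSV.
#' @return logical matrix, families in rows, species in columns.
#' @export
read_presence_matrix <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                         check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(x)
  mode(m) <- "logical"
  if (anyNA(m)) stop("presence matrix has non-boolean cells")
  if (any(rowSums(m) == 0L)) {
    stop("families absent from every species: ",
         paste(rownames(m)[rowSums(m) == 0L], collapse = ", "))
  }
  m
}

#' @rdname read_presence_matrix
#' @param m logical presence matrix.
#' @export
write_presence_matrix <- function(m, path) {
  df <- data.frame(family = rownames(m), m * 1L, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pairwise distance matrix
#'
#' Accepts a PHYLIP square matrix (first line: number of taxa), a wide TSV
#' with row and column names, or a long TSV with columns
#' `taxon_a`, `taxon_b`, `distance`. Symmetry and a zero diagonal are
#' enforced; the triangle inequality is not assumed.
#'
#' @param path input file.
#' @param format `"auto"`, `"phylip"`, `"long"` or `"wide"`.
#' @return symmetric numeric matrix with taxa as dimnames.
#' @export
read_distance_matrix <- function(path, format = c("auto", "phylip", "long", "wide")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^\\s*[0-9]+\\s*$", first)) "phylip"
              else if (length(strsplit(first, "\t")[[1L]]) == 3L) "long"
              else "wide"
  }
  m <- switch(format,
    phylip = {
      lines <- readLines(path)
      n <- as.integer(trimws(lines[1L]))
      body <- lines[-1L][nzchar(lines[-1L])]
      if (length(body) != n) stop("PHYLIP matrix promises ", n, " taxa, has ",
                                  length(body), " rows")
      fields <- strsplit(trimws(body), "\\s+")
      taxa <- vapply(fields, `[`, character(1), 1L)
      vals <- t(vapply(fields, function(f) as.numeric(f[-1L]), numeric(n)))
      dimnames(vals) <- list(taxa, taxa)
      vals
    },
    long = {
      x <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
      taxa <- sort(unique(c(x[[1L]], x[[2L]])))
      m <- matrix(0, length(taxa), length(taxa), dimnames = list(taxa, taxa))
      for (i in seq_len(nrow(x))) {
        m[x[[1L]][i], x[[2L]][i]] <- x[[3L]][i]
        m[x[[2L]][i], x[[1L]][i]] <- x[[3L]][i]
      }
      m
    },
    wide = as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                       row.names = 1L, check.names = FALSE))
  )
  if (any(m < 0)) stop("negative distances")
  if (max(abs(m - t(m))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(abs(diag(m)) > 1e-12)) stop("distance matrix diagonal must be zero")
  m
}

#' Read a per-gene expression table
#'
#' TSV with columns `gene_id` and `tpm` (header required).
#'
#' @param path input TSV.
#' @return named numeric vector of TPM values.
#' @export
read_expression <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  if (!all(c("gene_id", "tpm") %in% names(x))) {
    stop("expression TSV must have columns gene_id and tpm")
  }
  if (any(x$tpm < 0)) stop("negative TPM values")
  stats::setNames(x$tpm, x$gene_id)
}

#' @rdname read_expression
#' @param tpm named numeric vector of TPM values.
#' @export
write_expression <- function(tpm, path) {
  utils::write.table(data.frame(gene_id = names(tpm), tpm = unname(tpm)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
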