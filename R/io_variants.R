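# Readers and writers for per-site allelic read counts, the raw material of
# the variant-frequency-spectrum ploidy analysis. Only biallelic SNVs are
# retained: the frequency semantics of the spectrum (modes at 1/2 for a
# diploid heterozygote, 1/3 and 2/3 for a triploid) are defined for exactly
# two segregating alleles, so triallelic and indel records are excluded at
# read time.

#' Read a variant table with per-allele read depths
#'
#' Reads either a VCF (4.x) whose FORMAT includes the allelic-depth `AD`
#' field, or a plain TSV with columns `contig`, `pos`, `ref`, `alt`,
#' `ref_count`, `alt_count`. From VCF input the allelic depths of the
#' *first* sample are used; the caller-computed `INFO/AF` is deliberately
#' ignored because `AD` is the raw read evidence.
#'
#' @param path path to the input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param min_depth minimum total depth (`ref_count + alt_count`) for a
#'   record to be kept.
#' @return a `data.frame` with columns `contig`, `pos`, `ref`, `alt`,
#'   `ref_count`, `alt_count`, one row per retained biallelic SNV, input
#'   order preserved.
#' @export
read_variant_table <- function(path, format = c("auto", "vcf", "tsv"),
                               min_depth = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  x <- if (format == "vcf") read_variants_vcf(path) else read_variants_tsv(path)
  x <- x[x$ref_count + x$alt_count >= min_depth, , drop = FALSE]
  rownames(x) <- NULL
  as_variant_table(x)
}

as_variant_table <- function(x) {
  stopifnot(all(c("contig", "pos", "ref", "alt", "ref_count", "alt_count")
                %in% names(x)))
  if (any(x$pos < 1)) stop("positions must be 1-based (>= 1)")
  if (any(x$ref == x$alt)) stop("ref and alt alleles must differ")
  class(x) <- c("variant_table", "data.frame")
  x
}

read_variants_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (nrow(fix) == 0L) {
    return(data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      ref_count = integer(), alt_count = integer()))
  }
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  biallelic <- !is.na(alt) & !grepl(",", alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  ad <- tryCatch(vcfR::extract.gt(vcf, element = "AD"),
                 error = function(e) NULL)
  if (is.null(ad)) {
    warning("no AD field in any record; all records skipped")
    ad <- matrix(NA_character_, nrow = nrow(fix), ncol = 1L)
  }
  ad1 <- ad[, 1L]  # allelic depths of the first sample
  missing_ad <- biallelic & (is.na(ad1) | !nzchar(ad1))
  if (any(missing_ad)) {
    warning(sum(missing_ad), " record(s) without an AD value were skipped")
  }
  keep <- which(biallelic & !is.na(ad1) & nzchar(ad1))
  counts <- lapply(strsplit(ad1[keep], ",", fixed = TRUE),
                   function(v) suppressWarnings(as.integer(v)))
  ok <- vapply(counts, function(v) length(v) >= 2L && !anyNA(v[1:2]), logical(1))
  keep <- keep[ok]; counts <- counts[ok]
  data.frame(
    contig = unname(fix[keep, "CHROM"]),
    pos = as.integer(fix[keep, "POS"]),
    ref = unname(ref[keep]),
    alt = unname(alt[keep]),
    ref_count = vapply(counts, `[`, integer(1), 1L),
    alt_count = vapply(counts, `[`, integer(1), 2L),
    stringsAsFactors = FALSE
  )
}

read_variants_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty variant TSV: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  want <- c("contig", "pos", "ref", "alt", "ref_count", "alt_count")
  if (!all(want %in% header)) {
    stop("variant TSV must have columns: ", paste(want, collapse = ", "))
  }
  col <- match(want, header)
  rows <- lapply(seq_along(lines)[-1L], function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < length(header)) {
      stop("malformed variant line ", i, " in ", path, ": expected ",
           length(header), " fields, got ", length(f))
    }
    f[col]
  })
  m <- do.call(rbind, rows)
  if (is.null(m)) {
    return(data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      ref_count = integer(), alt_count = integer()))
  }
  num <- suppressWarnings(cbind(pos = as.integer(m[, 2L]),
                                ref_count = as.integer(m[, 5L]),
                                alt_count = as.integer(m[, 6L])))
  bad <- which(apply(is.na(num), 1L, any))
  if (length(bad)) {
    stop("malformed variant line ", bad[1L] + 1L, " in ", path,
         ": non-integer pos or count")
  }
  data.frame(contig = m[, 1L], pos = num[, "pos"], ref = m[, 3L],
             alt = m[, 4L], ref_count = num[, "ref_count"],
             alt_count = num[, "alt_count"], stringsAsFactors = FALSE)
}

#' Write a variant table as TSV
#'
#' Inverse of the TSV branch of [read_variant_table()]: re-reading the file
#' yields identical records.
#'
#' @param x a variant table (`data.frame` with the six standard columns).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(x, path) {
  utils::write.table(
    x[, c("contig", "pos", "ref", "alt", "ref_count", "alt_count")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
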