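# Generic comparative statistics: domain (e.g. Pfam) overrepresentation by
# one-sided Fisher exact tests with Benjamini-Hochberg correction, and a
# 2x2 chi-square comparison of two proportions (e.g. lethal-phenotype
# fractions between gene-copy classes).

#' Fisher-exact domain enrichment with BH correction
#'
#' Each domain is a 2x2 table (`fg_with`, `fg_without`, `bg_with`,
#' `bg_without`): proteins in the foreground vs background set carrying at
#' least one copy of the domain or not. P values are hypergeometric
#' (Fisher exact), one-sided (`greater`, the default for
#' overrepresentation) or two-sided; q values are Benjamini-Hochberg
#' step-up across all tested domains. The odds ratio is the sample ratio
#' `(a d)/(b c)`, infinite when `b c = 0`.
#'
#' @param table `data.frame` with columns `domain`, `fg_with`,
#'   `fg_without`, `bg_with`, `bg_without`.
#' @param alternative `"greater"` or `"two_sided"`.
#' @return `data.frame` with `domain`, `odds_ratio`, `p_value`, `q_value`.
#' @export
fisher_enrichment <- function(table, alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  need <- c("domain", "fg_with", "fg_without", "bg_with", "bg_without")
  stopifnot(all(need %in% names(table)))
  a <- table$fg_with; b <- table$fg_without
  c_ <- table$bg_with; d <- table$bg_without
  if (any(c(a, b, c_, d) < 0)) stop("counts must be non-negative")
  if (any(a + b + c_ + d == 0)) stop("all-zero contingency table")
  # X = fg_with under the null: hypergeometric with `a + c_` successes,
  # `b + d` failures, `a + b` draws
  p <- if (alternative == "greater") {
    stats::phyper(a - 1, a + c_, b + d, a + b, lower.tail = FALSE)
  } else {
    vapply(seq_along(a), function(i) {
      dens <- stats::dhyper(0:min(a[i] + b[i], a[i] + c_[i]),
                            a[i] + c_[i], b[i] + d[i], a[i] + b[i])
      sum(dens[dens <= stats::dhyper(a[i], a[i] + c_[i], b[i] + d[i],
                                     a[i] + b[i]) * (1 + 1e-7)])
    }, numeric(1))
  }
  p <- pmin(p, 1)
  or <- ifelse(b * c_ == 0, Inf, (a * d) / (b * c_))
  out <- data.frame(domain = table$domain, odds_ratio = or, p_value = p,
                    q_value = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Pearson chi-square test on a 2x2 table
#'
#' @param a,b,c,d cell counts (row 1: `a`, `b`; row 2: `c`, `d`).
#' @param yates apply the Yates continuity correction.
#' @return list with `statistic`, `p_value`, `df` (= 1).
#' @export
chi2_2x2 <- function(a, b, c, d, yates = FALSE) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) < 1) stop("table total must be >= 1")
  m <- matrix(counts, nrow = 2L, byrow = TRUE)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0)) {
    stop("an expected cell count is zero; use a Fisher exact test instead")
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = yates))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       df = unname(res$parameter))
}
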