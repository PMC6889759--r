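# Variant-frequency spectra and ploidy classification. A diploid
# heterozygote reads its variants at ~1/2; a triploid with a collapsed
# reference reads most divergent sites at ~1/3 (or 2/3 when the variant is
# on two of the three copies); a homozygous genome shows only a flat
# error-driven background. Spectra are folded by default — f and 1-f carry
# the same ploidy information, and folding unifies the 1/3 and 2/3
# triploid modes into a single peak.

#' Per-site variant frequencies
#'
#' Computes `f = alt_count / (ref_count + alt_count)` for sites passing a
#' depth filter, and trims frequencies outside the open interval
#' `(trim[1], trim[2])` — near-fixed sites carry no heterozygosity signal
#' and are dominated by error.
#'
#' @param sites a variant table (see [read_variant_table()]).
#' @param min_depth minimum total read depth.
#' @param trim open-interval bounds on retained frequencies.
#' @return numeric vector of frequencies, site order preserved. May be
#'   empty; downstream code must tolerate that.
#' @export
variant_frequencies <- function(sites, min_depth = 20L, trim = c(0.05, 0.95)) {
  stopifnot(length(trim) == 2L, trim[1] < trim[2])
  depth <- sites$ref_count + sites$alt_count
  f <- sites$alt_count / depth
  f[depth >= min_depth & f > trim[1] & f < trim[2]]
}

#' Bin variant frequencies into a spectrum
#'
#' Bins are half-open `[a, b)` with the last bin closed. When `folded`,
#' each frequency is replaced by `min(f, 1 - f)` and binned over
#' `(0, 0.5]`; otherwise over `(0, 1)`.
#'
#' @param freqs numeric vector of frequencies in (0, 1).
#' @param bin_width bin width in `(0, 0.1]`; must divide the support.
#' @param folded fold the spectrum about 0.5 (default).
#' @return an object of class `freq_spectrum`: list with `bin_edges`,
#'   `counts`, `n_variants`, `folded`, `bin_width`.
#' @export
build_spectrum <- function(freqs, bin_width = 0.02, folded = TRUE) {
  stopifnot(bin_width > 0, bin_width <= 0.1)
  if (length(freqs) && (any(freqs <= 0) || any(freqs >= 1))) {
    stop("frequencies must lie strictly inside (0, 1)")
  }
  top <- if (folded) 0.5 else 1
  n_bins <- round(top / bin_width)
  if (abs(n_bins * bin_width - top) > 1e-9) {
    stop("bin_width must divide ", top)
  }
  edges <- seq(0, top, length.out = n_bins + 1L)
  f <- if (folded) pmin(freqs, 1 - freqs) else freqs
  idx <- findInterval(f, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(bin_edges = edges, counts = counts,
                 n_variants = length(f), folded = folded,
                 bin_width = bin_width),
            class = "freq_spectrum")
}

# centred moving average with shrinking windows at the edges
smooth_counts <- function(counts, window = 5L) {
  half <- window %/% 2L
  n <- length(counts)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(counts[lo:hi])
  }, numeric(1))
}

#' Classify ploidy from a folded variant-frequency spectrum
#'
#' Counts are smoothed with a 5-bin moving average. If fewer than
#' `min_variants` sites contributed, the call is `ambiguous`. Peak
#' prominence is `max(smoothed) / median(smoothed)`; below
#' `flatness_threshold` the spectrum is called `homozygous_flat`.
#' Otherwise the modal bin centre decides: inside the triploid window the
#' call is `triploid`, inside the diploid window `diploid_heterozygous`,
#' and `ambiguous` elsewhere.
#'
#' @param spectrum a folded `freq_spectrum`.
#' @param windows list with elements `triploid` and `diploid`, each a
#'   `c(lo, hi)` interval of folded frequencies.
#' @param flatness_threshold minimum prominence for a peak to count.
#' @param min_variants minimum number of binned variants for a call.
#' @return an object of class `ploidy_call`: list with `call`,
#'   `peak_location`, `peak_prominence`, `n_variants_used`.
#' @export
classify_ploidy <- function(spectrum,
                            windows = list(triploid = c(0.28, 0.40),
                                           diploid = c(0.44, 0.50)),
                            flatness_threshold = 1.5, min_variants = 200L) {
  stopifnot(inherits(spectrum, "freq_spectrum"))
  if (!spectrum$folded) stop("classify_ploidy requires a folded spectrum")
  sm <- smooth_counts(spectrum$counts, 5L)
  centers <- spectrum$bin_edges[-1L] - spectrum$bin_width / 2
  prominence <- if (stats::median(sm) > 0) max(sm) / stats::median(sm) else Inf
  res <- list(call = "ambiguous", peak_location = NA_real_,
              peak_prominence = prominence,
              n_variants_used = spectrum$n_variants)
  if (spectrum$n_variants < min_variants) {
    class(res) <- "ploidy_call"
    return(res)
  }
  if (prominence < flatness_threshold) {
    res$call <- "homozygous_flat"
  } else {
    peak <- centers[which.max(sm)]
    res$peak_location <- peak
    if (peak >= windows$triploid[1] && peak <= windows$triploid[2]) {
      res$call <- "triploid"
    } else if (peak >= windows$diploid[1] && peak <= windows$diploid[2]) {
      res$call <- "diploid_heterozygous"
    }
  }
  class(res) <- "ploidy_call"
  res
}

#' @export
print.ploidy_call <- function(x, ...) {
  cat("Ploidy call:", x$call, "\n")
  if (!is.na(x$peak_location)) {
    cat(sprintf("  modal folded frequency: %.3f\n", x$peak_location))
  }
  cat(sprintf("  peak prominence: %.2f\n  variants used: %d\n",
              x$peak_prominence, x$n_variants_used))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum distance between the two empirical CDFs. For small
#' samples (`n1 + n2 <= 12`) the p value is exact, by enumeration of all
#' `choose(n1+n2, n1)` assignments of the pooled observations (ties
#' handled naturally); otherwise it follows the asymptotic Kolmogorov
#' distribution with effective size `n1*n2/(n1+n2)`.
#'
#' @param freqs_a,freqs_b non-empty numeric samples.
#' @return an object of class `ks_result`: list with `D`, `p_value`,
#'   `n1`, `n2`, `exact`.
#' @export
ks_two_sample <- function(freqs_a, freqs_b) {
  if (length(freqs_a) == 0L || length(freqs_b) == 0L) {
    stop("both samples must be non-empty")
  }
  n1 <- length(freqs_a); n2 <- length(freqs_b)
  d_obs <- ks_statistic(freqs_a, freqs_b)
  if (n1 + n2 <= 12L) {
    pooled <- c(freqs_a, freqs_b)
    splits <- utils::combn(n1 + n2, n1)
    ds <- apply(splits, 2L, function(ix)
      ks_statistic(pooled[ix], pooled[-ix]))
    p <- mean(ds >= d_obs - 1e-12)
    exact <- TRUE
  } else {
    ne <- n1 * n2 / (n1 + n2)
    p <- kolmogorov_sf(sqrt(ne) * d_obs)
    exact <- FALSE
  }
  structure(list(D = d_obs, p_value = p, n1 = n1, n2 = n2, exact = exact),
            class = "ks_result")
}

ks_statistic <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(pts) - stats::ecdf(b)(pts)))
}

# survival function of the Kolmogorov distribution, 2*sum (-1)^(k-1) exp(-2k^2 x^2)
kolmogorov_sf <- function(x) {
  if (x <= 0) return(1)
  k <- seq_len(100L)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * x^2))
  min(max(p, 0), 1)
}
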