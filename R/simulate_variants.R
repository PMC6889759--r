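# Seeded generator of per-site allelic read counts under a known ploidy
# class. This emulates the data-generating process behind an RNA-seq
# variant-frequency spectrum: reads sampled over a site where the
# alternative allele is carried by 0, 1 of 2, or 1-or-2 of 3 genome copies.

#' Specification for a ploidy-class variant simulation
#'
#' @param ploidy_class `"homozygous"` (variants arise from sequencing error
#'   only), `"diploid_het"` (expected alternative fraction 1/2) or
#'   `"triploid"` (1/3, or 2/3 at a minority of sites).
#' @param n_sites number of variant sites to simulate.
#' @param mean_depth mean sequencing depth per site (Poisson, floored at 1).
#' @param error_rate symmetric per-read error probability in `[0, 0.05]`.
#' @param frac_two_thirds triploid only: fraction of sites where the
#'   variant allele is carried by two of the three copies. The default 0.1
#'   reflects that a collapsed reference assembly usually holds the
#'   majority allele, so most divergent triploid sites read at 1/3.
#' @param seed integer seed; the generator is a pure function of the spec.
#' @return an object of class `ploidy_sim_spec`.
#' @export
ploidy_sim_spec <- function(ploidy_class = c("homozygous", "diploid_het", "triploid"),
                            n_sites, mean_depth = 50, error_rate = 0.005,
                            frac_two_thirds = 0.1, seed = 1L) {
  ploidy_class <- match.arg(ploidy_class)
  stopifnot(n_sites >= 1, mean_depth > 0,
            error_rate >= 0, error_rate <= 0.05,
            frac_two_thirds >= 0, frac_two_thirds <= 1)
  structure(list(ploidy_class = ploidy_class, n_sites = as.integer(n_sites),
                 mean_depth = mean_depth, error_rate = error_rate,
                 frac_two_thirds = frac_two_thirds, seed = as.integer(seed)),
            class = "ploidy_sim_spec")
}

#' Simulate a variant table under a known ploidy class
#'
#' Per site, depth is Poisson(`mean_depth`) floored at 1 and the
#' alternative read count is Binomial(depth, p'), where p is 0, 1/2, or
#' 1/3 vs 2/3 according to the ploidy class and p' = p(1-e) + (1-p)e folds
#' in a symmetric error rate e (errors blur the spectrum without biasing
#' it). Deterministic for a fixed spec.
#'
#' @param spec a [ploidy_sim_spec()].
#' @return a variant table (`data.frame`) as from [read_variant_table()].
#' @export
simulate_variants <- function(spec) {
  stopifnot(inherits(spec, "ploidy_sim_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_sites
    depth <- pmax(1L, stats::rpois(n, spec$mean_depth))
    p <- switch(spec$ploidy_class,
      homozygous = rep(0, n),
      diploid_het = rep(0.5, n),
      triploid = ifelse(stats::runif(n) < spec$frac_two_thirds, 2 / 3, 1 / 3))
    e <- spec$error_rate
    p_err <- p * (1 - e) + (1 - p) * e
    alt <- stats::rbinom(n, depth, p_err)
    nucs <- c("A", "C", "G", "T")
    ref <- sample(nucs, n, replace = TRUE)
    alt_allele <- vapply(ref, function(r) sample(setdiff(nucs, r), 1L),
                         character(1))
    as_variant_table(data.frame(
      contig = sprintf("cds_%05d", seq_len(n)), pos = rep(1L, n),
      ref = ref, alt = unname(alt_allele),
      ref_count = depth - alt, alt_count = alt,
      stringsAsFactors = FALSE))
  })
}
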