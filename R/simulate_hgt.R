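# Seeded generator of best-hit tables, gene models and expression values
# mixing three designed gene classes: native metazoan genes, genuinely
# transferred genes that are domesticated in the genome (introns, strong
# expression, metazoan neighbours), and surface contaminants (intronless,
# isolated, near-identical to a non-metazoan protein, unexpressed).

#' Specification for an HGT evidence simulation
#'
#' @param n_native,n_hgt,n_contaminant number of genes of each class.
#' @param seed integer seed.
#' @return an object of class `hgt_sim_spec`.
#' @export
hgt_sim_spec <- function(n_native, n_hgt, n_contaminant, seed = 1L) {
  stopifnot(n_native >= 0, n_hgt >= 0, n_contaminant >= 0)
  structure(list(n_native = as.integer(n_native), n_hgt = as.integer(n_hgt),
                 n_contaminant = as.integer(n_contaminant),
                 seed = as.integer(seed)),
            class = "hgt_sim_spec")
}

#' Simulate hit, annotation and expression evidence for the HGT screen
#'
#' Gene classes are constructed so the downstream classification is exact:
#' native genes have a far better metazoan than non-metazoan best hit
#' (Alien Index < 0) and at least one intron; true HGT genes have a
#' non-metazoan best e-value at least e^30 smaller than the metazoan one
#' (AI > 30), identity <= 70%, introns, TPM > 100, and sit on a contig
#' shared with a native gene; contaminants have AI > 0, identity > 70%, no
#' introns, no metazoan-hitting neighbour and TPM < 10. When `n_hgt > 0`
#' but `n_native = 0`, native "anchor" genes are added so that each HGT
#' contig still carries a bona fide metazoan gene (role `anchor` in the
#' truth table).
#'
#' @param spec an [hgt_sim_spec()].
#' @return list with elements `hits` (hit table), `genes` (gene models),
#'   `expression` (named TPM vector) and `truth` (`data.frame` of
#'   `gene_id`, `role`).
#' @export
simulate_hit_evidence <- function(spec) {
  stopifnot(inherits(spec, "hgt_sim_spec"))
  withr::with_seed(spec$seed, {
    native_ids <- if (spec$n_native > 0) sprintf("native_%03d", seq_len(spec$n_native)) else character()
    hgt_ids <- if (spec$n_hgt > 0) sprintf("hgt_%03d", seq_len(spec$n_hgt)) else character()
    contam_ids <- if (spec$n_contaminant > 0) sprintf("contam_%03d", seq_len(spec$n_contaminant)) else character()

    anchor_ids <- character()
    if (spec$n_hgt > 0 && spec$n_native == 0) {
      anchor_ids <- sprintf("anchor_%03d", seq_along(hgt_ids))
    }
    host_ids <- c(native_ids, anchor_ids)  # metazoan genes that host contigs
    host_contig <- stats::setNames(sprintf("ctg_%03d", seq_along(host_ids)),
                                   host_ids)
    hgt_contig <- if (length(hgt_ids)) {
      host_contig[host_ids[(seq_along(hgt_ids) - 1L) %% length(host_ids) + 1L]]
    } else character()
    contam_contig <- if (length(contam_ids))
      sprintf("ctg_c%03d", seq_along(contam_ids)) else character()

    gene_ids <- c(host_ids, hgt_ids, contam_ids)
    contig <- c(unname(host_contig), unname(hgt_contig), contam_contig)
    role <- c(rep("native", length(native_ids)),
              rep("anchor", length(anchor_ids)),
              rep("hgt", length(hgt_ids)),
              rep("contaminant", length(contam_ids)))

    # gene models: multi-exon for hosts and HGT (>= 1 intron), single-exon
    # for contaminants; genes on a shared contig are laid out sequentially
    offset <- integer(length(gene_ids))
    for (ctg in unique(contig)) {
      idx <- which(contig == ctg)
      offset[idx] <- (seq_along(idx) - 1L) * 10000L
    }
    exon_list <- lapply(seq_along(gene_ids), function(i) {
      if (role[i] == "contaminant") {
        m <- cbind(start = offset[i] + 1L, end = offset[i] + 900L)
      } else {
        n_ex <- sample(2:4, 1L)
        starts <- offset[i] + 1L + (seq_len(n_ex) - 1L) * 500L
        m <- cbind(start = starts, end = starts + 299L)
      }
      storage.mode(m) <- "integer"
      m
    })
    n_exons <- vapply(exon_list, nrow, integer(1))
    genes <- data.frame(gene_id = gene_ids, contig = contig, strand = "+",
                        n_exons = n_exons, intron_count = n_exons - 1L,
                        stringsAsFactors = FALSE)
    genes$exons <- exon_list
    class(genes) <- c("gene_models", "data.frame")

    # hit table: one best metazoan and/or non-metazoan row per gene
    hit_rows <- list()
    add_hit <- function(q, s, part, evalue, ident, bits) {
      hit_rows[[length(hit_rows) + 1L]] <<- data.frame(
        query_id = q, subject_id = s, taxon_partition = part,
        evalue = evalue, percent_identity = ident, bitscore = bits,
        stringsAsFactors = FALSE)
    }
    for (i in seq_along(gene_ids)) {
      g <- gene_ids[i]
      if (role[i] %in% c("native", "anchor")) {
        add_hit(g, paste0("meta_", g), "metazoan",
                10^-stats::runif(1, 60, 120), stats::runif(1, 60, 90),
                stats::runif(1, 300, 600))
        if (stats::runif(1) < 0.5) {
          add_hit(g, paste0("nonmeta_", g), "non_metazoan",
                  10^-stats::runif(1, 1, 10), stats::runif(1, 25, 45),
                  stats::runif(1, 40, 80))
        }
      } else if (role[i] == "hgt") {
        u_meta <- stats::runif(1, 0, 10)
        u_gap <- stats::runif(1, 15, 60)  # > 30/ln(10) so AI > 30
        add_hit(g, paste0("meta_", g), "metazoan", 10^-u_meta,
                stats::runif(1, 25, 45), stats::runif(1, 40, 80))
        add_hit(g, paste0("donor_", g), "non_metazoan", 10^-(u_meta + u_gap),
                stats::runif(1, 35, 65), stats::runif(1, 150, 400))
      } else {  # contaminant: non-metazoan hit only, near-identical
        add_hit(g, paste0("source_", g), "non_metazoan",
                10^-stats::runif(1, 30, 100), stats::runif(1, 75, 98),
                stats::runif(1, 200, 500))
      }
    }
    hits <- do.call(rbind, hit_rows)
    class(hits) <- c("hit_table", "data.frame")

    tpm <- numeric(length(gene_ids))
    tpm[role %in% c("native", "anchor")] <-
      stats::runif(sum(role %in% c("native", "anchor")), 20, 300)
    tpm[role == "hgt"] <- stats::runif(sum(role == "hgt"), 150, 800)
    tpm[role == "contaminant"] <- stats::runif(sum(role == "contaminant"), 0, 5)
    names(tpm) <- gene_ids

    list(hits = hits, genes = genes, expression = tpm,
         truth = data.frame(gene_id = gene_ids, role = role,
                            stringsAsFactors = FALSE))
  })
}
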