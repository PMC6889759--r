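# Alien Index screening for horizontal gene transfer. The AI contrasts a
# gene's best metazoan and best non-metazoan database hits:
#   AI = ln(E_meta + e^-200) - ln(E_nonmeta + e^-200)
# with e-values capped into [0, 1] and a missing hit encoded as e-value 1.
# Positive AI means the non-metazoan hit is better; AI > 30 corresponds to
# an e-value advantage of more than e^30. Candidates that are
# near-identical (> 70%) to a non-metazoan protein are flagged as likely
# contaminants rather than transfers, and the remaining candidates are
# tiered by integration evidence: spliceosomal introns, metazoan
# neighbours on the same contig, and expression support.

#' Default thresholds of the HGT screen
#'
#' @param ai_candidate AI above which a gene is a candidate (0).
#' @param ai_strong AI above which a candidate is strong (30).
#' @param contaminant_identity percent identity to the best non-metazoan
#'   hit above which a candidate is flagged as contamination (70).
#' @param tpm_tiers expression tiers reported by [tier_report()].
#' @param evalue_floor_exponent `e^-x` added inside the logs to bound AI.
#' @param missing_hit_evalue e-value substituted for an absent best hit.
#' @return a list of class `hgt_thresholds`.
#' @export
hgt_thresholds <- function(ai_candidate = 0, ai_strong = 30,
                           contaminant_identity = 70,
                           tpm_tiers = c(10, 100, 1000),
                           evalue_floor_exponent = 200,
                           missing_hit_evalue = 1) {
  structure(list(ai_candidate = ai_candidate, ai_strong = ai_strong,
                 contaminant_identity = contaminant_identity,
                 tpm_tiers = tpm_tiers,
                 evalue_floor_exponent = evalue_floor_exponent,
                 missing_hit_evalue = missing_hit_evalue),
            class = "hgt_thresholds")
}

#' Alien Index from two best-hit e-values
#'
#' @param best_meta_evalue,best_nonmeta_evalue best e-value per partition
#'   (vectorised); use 1 for a missing hit. Values above 1 are capped to 1.
#' @param floor_exponent the `e^-x` pseudocount exponent (default 200).
#' @return numeric AI; `|AI| <= floor_exponent + ln 2`.
#' @export
alien_index <- function(best_meta_evalue, best_nonmeta_evalue,
                        floor_exponent = 200) {
  if (any(best_meta_evalue < 0) || any(best_nonmeta_evalue < 0)) {
    stop("e-values must be non-negative")
  }
  em <- pmin(best_meta_evalue, 1)
  en <- pmin(best_nonmeta_evalue, 1)
  eps <- exp(-floor_exponent)
  log(em + eps) - log(en + eps)
}

#' Per-gene best hits and Alien Index
#'
#' For each query gene the best hit per partition is the one with the
#' lowest e-value; ties are broken by highest bitscore, then by
#' lexicographic subject id, so the result is deterministic. A partition
#' with no hit contributes e-value 1. The identity and subject of the best
#' non-metazoan hit are carried along as donor evidence.
#'
#' @param hits a hit table (see [read_hit_table()]).
#' @param thresholds an [hgt_thresholds()] object.
#' @return `data.frame` with columns `gene_id`, `best_meta_evalue`,
#'   `best_nonmeta_evalue`, `ai`, `best_nonmeta_identity`, `donor_hint`.
#' @export
summarize_hits <- function(hits, thresholds = hgt_thresholds()) {
  stopifnot(is.data.frame(hits))
  genes <- unique(hits$query_id)
  best_of <- function(h) {
    if (nrow(h) == 0L) return(NULL)
    h <- h[order(h$evalue, -h$bitscore, h$subject_id), , drop = FALSE]
    h[1L, ]
  }
  rows <- lapply(genes, function(g) {
    h <- hits[hits$query_id == g, , drop = FALSE]
    bm <- best_of(h[h$taxon_partition == "metazoan", , drop = FALSE])
    bn <- best_of(h[h$taxon_partition == "non_metazoan", , drop = FALSE])
    em <- if (is.null(bm)) thresholds$missing_hit_evalue else bm$evalue
    en <- if (is.null(bn)) thresholds$missing_hit_evalue else bn$evalue
    data.frame(
      gene_id = g, best_meta_evalue = em, best_nonmeta_evalue = en,
      ai = alien_index(em, en, thresholds$evalue_floor_exponent),
      best_nonmeta_identity = if (is.null(bn)) NA_real_ else bn$percent_identity,
      donor_hint = if (is.null(bn)) NA_character_ else bn$subject_id,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("alien_index_table", "data.frame")
  out
}

#' Collect integration evidence for HGT candidates
#'
#' Intron counts come from the gene models; `on_multigene_contig` is true
#' iff at least two genes share the contig; `has_metazoan_neighbor` is
#' true iff some *other* gene on the same contig has AI < 0 (its best hit
#' is metazoan); `tpm` defaults to 0 for genes absent from the expression
#' table. Genes scored by AI but missing from the annotation produce a
#' warning and default evidence.
#'
#' @param genes a `gene_models` data.frame.
#' @param ai_records output of [summarize_hits()].
#' @param expression named numeric vector of TPM values.
#' @param pfam optional named list mapping gene ids to Pfam domain ids.
#' @return `data.frame` of class `hgt_evidence` with one row per AI record.
#' @export
collect_evidence <- function(genes, ai_records, expression = NULL,
                             pfam = NULL) {
  gidx <- match(ai_records$gene_id, genes$gene_id)
  if (anyNA(gidx)) {
    warning("gene(s) without annotation, using default evidence: ",
            paste(ai_records$gene_id[is.na(gidx)], collapse = ", "))
  }
  contig <- genes$contig[gidx]
  contig_n_genes <- table(genes$contig)
  ai_by_gene <- stats::setNames(ai_records$ai, ai_records$gene_id)
  has_neighbor <- vapply(seq_along(gidx), function(i) {
    if (is.na(gidx[i])) return(FALSE)
    mates <- genes$gene_id[genes$contig == contig[i] &
                           genes$gene_id != ai_records$gene_id[i]]
    any(ai_by_gene[mates] < 0, na.rm = TRUE)
  }, logical(1))
  tpm <- if (is.null(expression)) rep(0, nrow(ai_records)) else {
    v <- unname(expression[ai_records$gene_id])
    v[is.na(v)] <- 0
    v
  }
  out <- data.frame(
    gene_id = ai_records$gene_id,
    intron_count = ifelse(is.na(gidx), 0L, genes$intron_count[gidx]),
    on_multigene_contig = !is.na(gidx) &
      unname(contig_n_genes[contig] >= 2L & !is.na(contig)),
    has_metazoan_neighbor = has_neighbor,
    tpm = tpm,
    stringsAsFactors = FALSE)
  out$pfam_domains <- if (is.null(pfam)) {
    rep(list(character()), nrow(out))
  } else {
    lapply(out$gene_id, function(g) if (g %in% names(pfam)) pfam[[g]] else character())
  }
  class(out) <- c("hgt_evidence", "data.frame")
  out
}

#' Classify HGT candidates through the contamination and evidence screens
#'
#' Rules, applied in order per gene: AI <= 0 is not a candidate; AI > 0
#' with identity > `contaminant_identity` is a contaminant (the identity
#' rule wins over any integration evidence); AI > `ai_strong` with at
#' least one intron and TPM > 100 is high-confidence; otherwise the gene
#' is a plain candidate at its AI tier.
#'
#' @param ai_records output of [summarize_hits()].
#' @param evidence output of [collect_evidence()], one row per AI record.
#' @param thresholds an [hgt_thresholds()] object.
#' @return `data.frame` with `gene_id`, `ai`, `status`, `tier_reasons`.
#' @export
classify_candidates <- function(ai_records, evidence,
                                thresholds = hgt_thresholds()) {
  ev <- evidence[match(ai_records$gene_id, evidence$gene_id), , drop = FALSE]
  if (anyNA(ev$gene_id)) stop("missing evidence record for some genes")
  th <- thresholds
  n <- nrow(ai_records)
  status <- character(n); reasons <- vector("list", n)
  for (i in seq_len(n)) {
    ai <- ai_records$ai[i]
    ident <- ai_records$best_nonmeta_identity[i]
    r <- character()
    if (ai <= th$ai_candidate) {
      status[i] <- "not_candidate"
    } else if (!is.na(ident) && ident > th$contaminant_identity) {
      status[i] <- "contaminant"
      r <- sprintf("identity %.1f > %g", ident, th$contaminant_identity)
    } else if (ai > th$ai_strong && ev$intron_count[i] >= 1L &&
               ev$tpm[i] > 100) {
      status[i] <- "high_confidence"
      r <- c(sprintf("AI %.1f > %g", ai, th$ai_strong),
             sprintf("%d intron(s)", ev$intron_count[i]),
             sprintf("TPM %.1f > 100", ev$tpm[i]),
             if (ev$has_metazoan_neighbor[i]) "metazoan neighbor")
    } else if (ai > th$ai_strong) {
      status[i] <- "candidate_ai30"
      r <- sprintf("AI %.1f > %g", ai, th$ai_strong)
    } else {
      status[i] <- "candidate_ai0"
      r <- sprintf("AI %.1f > %g", ai, th$ai_candidate)
    }
    reasons[[i]] <- r
  }
  out <- data.frame(gene_id = ai_records$gene_id, ai = ai_records$ai,
                    status = status, stringsAsFactors = FALSE)
  out$tier_reasons <- reasons
  class(out) <- c("hgt_classification", "data.frame")
  out
}

#' Per-species summary of the HGT screen
#'
#' Reproduces the usual screening summary: candidate counts at AI > 0 (all
#' genes with positive AI, contaminants included) and at the strong AI
#' tier (contaminants excluded), the contaminant count, and — over the
#' strong non-contaminant candidates — counts on multigene contigs, with
#' metazoan neighbours, with introns, above each expression tier, and
#' with Pfam domains (genes, total and distinct domains).
#'
#' @param classifications output of [classify_candidates()].
#' @param evidence output of [collect_evidence()].
#' @param tpm_tiers expression tiers (TPM).
#' @return one-row `data.frame` of counts.
#' @export
tier_report <- function(classifications, evidence,
                        tpm_tiers = c(10, 100, 1000)) {
  ev <- evidence[match(classifications$gene_id, evidence$gene_id), ,
                 drop = FALSE]
  is_pos <- classifications$status != "not_candidate"
  is_contam <- classifications$status == "contaminant"
  strong <- is_pos & !is_contam &
    classifications$status %in% c("candidate_ai30", "high_confidence")
  pf <- ev$pfam_domains
  strong_pf <- unlist(pf[strong])
  out <- data.frame(
    n_genes = nrow(classifications),
    ai_gt0 = sum(is_pos),
    contaminants = sum(is_contam),
    ai_gt30 = sum(strong),
    high_confidence = sum(classifications$status == "high_confidence"),
    on_multigene_contig = sum(ev$on_multigene_contig[strong]),
    metazoan_neighbor = sum(ev$has_metazoan_neighbor[strong]),
    with_introns = sum(ev$intron_count[strong] >= 1L)
  )
  for (t in tpm_tiers) {
    out[[sprintf("tpm_gt%g", t)]] <- sum(ev$tpm[strong] > t)
  }
  out$with_pfam <- sum(vapply(pf[strong], length, integer(1)) > 0L)
  out$pfam_total <- length(strong_pf)
  out$pfam_distinct <- length(unique(strong_pf))
  out
}
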