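## Expression filtering/normalization, nearest-gene assignment and
## fold-change classification of TE effects on adjacent gene expression.

#' Drop genes expressed in too few samples
#'
#' A gene is kept when the fraction of samples with TPM below `min_tpm` is
#' at most `max_low_fraction` (i.e. genes below 0.01 TPM in more than 80%
#' of samples are excluded under the defaults).
#'
#' @param em Genes x accessions expression matrix (TPM).
#' @param min_tpm Detection threshold.
#' @param max_low_fraction Maximum tolerated fraction of sub-threshold
#'   samples.
#' @return The row-subset matrix; attribute `removed` gives the count
#'   dropped.
#' @export
filter_expressed <- function(em, min_tpm = 0.01, max_low_fraction = 0.8) {
  if (!nrow(em) || !ncol(em)) stop("empty expression matrix", call. = FALSE)
  if (min_tpm < 0 || max_low_fraction < 0 || max_low_fraction > 1)
    stop("invalid filter thresholds", call. = FALSE)
  low_frac <- rowMeans(em < min_tpm)
  keep <- low_frac <= max_low_fraction
  out <- em[keep, , drop = FALSE]
  attr(out, "removed") <- sum(!keep)
  out
}

#' TMM scaling factors for between-sample count normalization
#'
#' Trimmed mean of M-values: the reference sample is the one whose
#' upper-quartile (of depth-scaled counts) is closest to the mean
#' upper-quartile; per-sample log-ratios (M) are trimmed by 30% and
#' log-abundances (A) by 5%, and the factor is the inverse-variance weighted
#' mean of the retained M-values. Factors are rescaled to have geometric
#' mean 1. Computation is delegated to the standard TMM implementation in
#' \pkg{edgeR}.
#'
#' @param counts Genes x accessions matrix of non-negative counts (>= 2
#'   columns, positive library sizes).
#' @return Named numeric vector of per-accession scaling factors.
#' @export
tmm_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("TMM needs at least two libraries", call. = FALSE)
  if (any(colSums(counts) <= 0))
    stop("all-zero library: TMM undefined", call. = FALSE)
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  stats::setNames(as.numeric(f), colnames(counts))
}

#' Apply TMM factors to a TPM/count matrix
#'
#' Divides each column by its effective scaling factor.
#'
#' @param em Genes x accessions matrix.
#' @param factors Per-accession factors from [tmm_factors()].
#' @return Normalized matrix.
#' @export
apply_norm_factors <- function(em, factors) {
  stopifnot(ncol(em) == length(factors))
  sweep(em, 2L, factors, "/")
}

#' Assign each TE its nearest gene
#'
#' Distance is 0 when the TE overlaps the gene body, otherwise the gap to
#' the closest gene boundary. The sign encodes position relative to the
#' gene's transcription direction: negative = upstream of the gene,
#' positive = downstream. Ties in gap are broken by the smaller distance to
#' the transcription start site, then by lexicographic gene id. TEs on
#' contigs without genes are returned unassigned (`NA` gene).
#'
#' @param tes TE data.frame (`te_id`, `contig`, `start`, `end`; 0-based
#'   half-open).
#' @param genes Gene data.frame (`gene_id`, `contig`, `start`, `end`,
#'   `strand`).
#' @return Data.frame `te_id`, `gene_id`, `distance` (signed; NA when
#'   unassigned).
#' @export
nearest_gene <- function(tes, genes) {
  out <- data.frame(te_id = tes$te_id, gene_id = NA_character_,
                    distance = NA_real_, stringsAsFactors = FALSE)
  if (!nrow(tes) || !nrow(genes)) return(out)
  ## TEs on contigs without any gene stay unassigned
  assignable <- tes$contig %in% genes$contig
  tes <- tes[assignable, , drop = FALSE]
  if (!nrow(tes)) return(out)
  row_of <- which(assignable)
  te_gr <- GenomicRanges::GRanges(tes$contig,
                                  IRanges::IRanges(tes$start + 1L, tes$end))
  gene_gr <- GenomicRanges::GRanges(genes$contig,
                                    IRanges::IRanges(genes$start + 1L,
                                                     genes$end))
  hits <- GenomicRanges::distanceToNearest(te_gr, gene_gr, select = "all")
  if (!length(hits)) return(out)
  ti <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)

  tss <- ifelse(genes$strand == "-", genes$end, genes$start)
  ## gap from TE to the TSS coordinate (0 when the TSS falls inside the TE)
  tss_gap <- pmax(pmax(tes$start[ti] - tss[gi], tss[gi] - tes$end[ti]), 0)
  ord <- order(ti, tss_gap, genes$gene_id[gi])
  first <- !duplicated(ti[ord])
  ti <- ti[ord][first]; gi <- gi[ord][first]

  gap <- pmax(pmax(genes$start[gi] - tes$end[ti],
                   tes$start[ti] - genes$end[gi]), 0)
  ## upstream (before the TSS reading direction) is negative
  te_mid <- (tes$start[ti] + tes$end[ti]) / 2
  gene_mid <- (genes$start[gi] + genes$end[gi]) / 2
  before <- te_mid < gene_mid
  upstream <- ifelse(genes$strand[gi] == "-", !before, before)
  out$gene_id[row_of[ti]] <- genes$gene_id[gi]
  out$distance[row_of[ti]] <- ifelse(gap == 0, 0, ifelse(upstream, -gap, gap))
  out
}

#' Classify one TE's effect on its target gene's expression
#'
#' Accessions are split by TE presence (any non-zero dosage) versus absence
#' (dosage 0); the ratio of group means (with a small pseudo-offset guarding
#' zero denominators) is compared with the fold threshold: promotive when
#' carriers express at least `fold` times more, suppressive when at most
#' `1/fold` as much, otherwise none. Calls with fewer than `min_group`
#' accessions in either group are `unevaluable`.
#'
#' @param dosage TE dosage vector over accessions (0/1/2/NA).
#' @param expression Target-gene expression over the same accessions.
#' @param fold Fold threshold (default 1.5, applied inclusively).
#' @param min_group Minimum accessions per genotype group.
#' @param epsilon Pseudo-offset added to both means (TPM units).
#' @return One-row data.frame: `mean_with`, `mean_without`, `ratio`,
#'   `effect`, `n_with`, `n_without`.
#' @examples
#' classify_te_effect(rep(c(2, 0), each = 10), rep(c(3, 2), each = 10))
#' @export
classify_te_effect <- function(dosage, expression, fold = 1.5,
                               min_group = 5L, epsilon = 0.01) {
  stopifnot(length(dosage) == length(expression), fold >= 1)
  ok <- !is.na(dosage) & !is.na(expression)
  with_g <- ok & dosage > 0
  without_g <- ok & dosage == 0
  n_with <- sum(with_g); n_without <- sum(without_g)
  if (n_with < min_group || n_without < min_group)
    return(data.frame(mean_with = NA_real_, mean_without = NA_real_,
                      ratio = NA_real_, effect = "unevaluable",
                      n_with = n_with, n_without = n_without,
                      stringsAsFactors = FALSE))
  mw <- mean(expression[with_g])
  mo <- mean(expression[without_g])
  ratio <- (mw + epsilon) / (mo + epsilon)
  effect <- if (ratio >= fold) "promotive"
            else if (ratio <= 1 / fold) "suppressive"
            else "none"
  data.frame(mean_with = mw, mean_without = mo, ratio = ratio,
             effect = effect, n_with = n_with, n_without = n_without,
             stringsAsFactors = FALSE)
}

#' Classify TE effects for a whole stage
#'
#' @param gm TE x accession dosage matrix.
#' @param em Gene x accession expression matrix for one stage.
#' @param te_gene_map Data.frame `te_id`, `gene_id` linking each TE to its
#'   (nearest) target gene; pairs whose gene is absent from `em` are
#'   skipped.
#' @inheritParams classify_te_effect
#' @param stage Stage label recorded in the output.
#' @return EffectCall data.frame: `te_id`, `gene_id`, `stage` and the
#'   [classify_te_effect()] columns.
#' @export
classify_stage_effects <- function(gm, em, te_gene_map, fold = 1.5,
                                   min_group = 5L, epsilon = 0.01,
                                   stage = "stage_1") {
  acc <- intersect(colnames(gm), colnames(em))
  if (!length(acc)) stop("no shared accessions between genotypes and ",
                         "expression", call. = FALSE)
  map <- te_gene_map[te_gene_map$te_id %in% rownames(gm) &
                       te_gene_map$gene_id %in% rownames(em), , drop = FALSE]
  calls <- lapply(seq_len(nrow(map)), function(i)
    classify_te_effect(gm[map$te_id[i], acc], em[map$gene_id[i], acc],
                       fold = fold, min_group = min_group, epsilon = epsilon))
  out <- do.call(rbind, calls)
  if (is.null(out)) out <- classify_te_effect(numeric(0), numeric(0))[0, ]
  cbind(data.frame(te_id = map$te_id, gene_id = map$gene_id, stage = stage,
                   stringsAsFactors = FALSE), out)
}

#' Summarize effect calls and cross-stage consistency
#'
#' The headline promotive percentage is computed among regulatory calls
#' (promotive + suppressive), the convention behind statements such as
#' "66.74% of TEs exhibited promotive effects"; fractions over all evaluable
#' calls are reported alongside. A TE is stage-consistent when it receives
#' the same non-`none` class in every stage.
#'
#' @param calls EffectCall data.frame for one stage, or a list of them (one
#'   per stage; a `stage` column is honoured either way).
#' @return A list: `per_stage` (data.frame with counts, `promotive_pct`
#'   among regulatory calls, and fractions over evaluable calls),
#'   `consistent_promotive` / `consistent_suppressive` (TE id vectors).
#' @export
effect_summary <- function(calls) {
  if (is.data.frame(calls)) calls <- list(calls)
  calls <- lapply(seq_along(calls), function(i) {
    x <- calls[[i]]
    if (is.null(x$stage)) x$stage <- paste0("stage_", i)
    x
  })
  all_calls <- do.call(rbind, calls)
  if (!nrow(all_calls)) stop("no effect calls to summarize", call. = FALSE)

  per_stage <- do.call(rbind, lapply(split(all_calls, all_calls$stage),
                                     function(x) {
    np <- sum(x$effect == "promotive")
    ns <- sum(x$effect == "suppressive")
    nn <- sum(x$effect == "none")
    nev <- np + ns + nn
    data.frame(stage = x$stage[1L], n_promotive = np, n_suppressive = ns,
               n_none = nn, n_unevaluable = sum(x$effect == "unevaluable"),
               promotive_pct = if (np + ns > 0) 100 * np / (np + ns)
                               else NA_real_,
               suppressive_pct = if (np + ns > 0) 100 * ns / (np + ns)
                                 else NA_real_,
               none_frac_evaluable = if (nev > 0) nn / nev else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(per_stage) <- NULL

  stages <- unique(all_calls$stage)
  class_by_stage <- lapply(stages, function(s) {
    x <- all_calls[all_calls$stage == s, ]
    stats::setNames(x$effect, x$te_id)
  })
  shared <- Reduce(intersect, lapply(class_by_stage, names))
  consistent <- function(cls) {
    keep <- vapply(shared, function(te)
      all(vapply(class_by_stage, function(m) m[[te]] == cls, logical(1))),
      logical(1))
    shared[keep]
  }
  list(per_stage = per_stage,
       consistent_promotive = consistent("promotive"),
       consistent_suppressive = consistent("suppressive"))
}
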