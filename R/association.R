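## Single-variant association engine for TE-GWAS and TE-eQTL:
## OLS with covariates (typically top expression/genotype PCs), the
## -log10(1/n) significance rule, cis/trans partitioning, greedy LD
## clumping and locus merging.

#' Per-variant ordinary-least-squares association scan
#'
#' Regresses the response on each variant's dosage with optional covariates
#' (always including an intercept) and reports the Wald two-sided p-value.
#' Accessions with a missing dosage are dropped pairwise per variant. When
#' the genotype matrix has no missing entries the scan uses a vectorized
#' residualization path (Frisch-Waugh): response and dosages are projected
#' off the covariates once and per-variant statistics follow from
#' cross-products.
#'
#' @param gm Variant x accession dosage matrix.
#' @param response Numeric response vector named or ordered by the columns
#'   of `gm`.
#' @param covariates Optional accession x covariate numeric matrix (no
#'   intercept column; e.g. [expression_pcs()] output).
#' @return Data.frame: `variant_id`, `beta`, `se`, `p`, `neg_log10_p`,
#'   `n_used`, `flag` (`"ok"` or `"zero_variance"`).
#' @export
association_scan <- function(gm, response, covariates = NULL) {
  n <- ncol(gm)
  stopifnot(length(response) == n)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
  }
  X0 <- cbind(intercept = rep(1, n), covariates)
  k <- ncol(X0)

  variant_id <- rownames(gm)
  if (is.null(variant_id)) variant_id <- sprintf("v%05d", seq_len(nrow(gm)))
  beta <- se <- p <- rep(NA_real_, nrow(gm))
  n_used <- integer(nrow(gm))
  flag <- rep("ok", nrow(gm))

  complete <- !is.na(response) & stats::complete.cases(X0)
  if (!anyNA(gm[, complete, drop = FALSE])) {
    ## fast path: one QR of the covariates, vectorized over variants
    y <- response[complete]
    X <- X0[complete, , drop = FALSE]
    G <- t(gm[, complete, drop = FALSE])          # accessions x variants
    qr0 <- qr(X)
    ry <- stats::residuals(stats::lm.fit(X, y))
    RG <- qr.resid(qr0, G)
    df <- length(y) - k - 1L
    gss <- colSums(RG^2)
    zero <- gss < 1e-12
    gxy <- drop(crossprod(RG, ry))
    b <- ifelse(zero, NA_real_, gxy / gss)
    rss <- sum(ry^2) - b^2 * gss
    rss <- pmax(rss, 0)
    s <- sqrt(rss / df / gss)
    tval <- b / s
    beta <- b
    se <- s
    p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
    n_used <- rep(length(y), nrow(gm))
    flag[zero] <- "zero_variance"
    p[zero] <- se[zero] <- NA_real_
  } else {
    for (i in seq_len(nrow(gm))) {
      g <- gm[i, ]
      ok <- complete & !is.na(g)
      n_used[i] <- sum(ok)
      if (n_used[i] <= k + 1L) { flag[i] <- "zero_variance"; next }
      gi <- g[ok]
      if (stats::var(gi) < 1e-12) { flag[i] <- "zero_variance"; next }
      fit <- stats::lm.fit(cbind(X0[ok, , drop = FALSE], dosage = gi),
                           response[ok])
      df <- n_used[i] - fit$rank
      if (df <= 0) { flag[i] <- "zero_variance"; next }
      cf <- fit$coefficients["dosage"]
      if (is.na(cf)) { flag[i] <- "zero_variance"; next }
      R <- qr.R(fit$qr)[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE]
      xinv <- chol2inv(R)
      pos <- match(k + 1L, fit$qr$pivot)     # dosage column under pivoting
      s2 <- sum(fit$residuals^2) / df
      se_i <- sqrt(s2 * xinv[pos, pos])
      beta[i] <- cf
      se[i] <- se_i
      p[i] <- 2 * stats::pt(abs(cf / se_i), df, lower.tail = FALSE)
    }
  }
  data.frame(variant_id = variant_id, beta = beta, se = se, p = p,
             neg_log10_p = -log10(p), n_used = n_used, flag = flag,
             stringsAsFactors = FALSE)
}

#' Top principal components of an expression (or genotype) matrix
#'
#' Standard covariate construction for eQTL scans: accessions are the
#' observations, features are centred, and the leading PCs are returned.
#'
#' @param m Feature x accession matrix.
#' @param n_pcs Number of components (default 10).
#' @return Accession x PC score matrix.
#' @export
expression_pcs <- function(m, n_pcs = 10L) {
  x <- t(m)
  n_pcs <- min(n_pcs, nrow(x) - 1L, ncol(x))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)
  pc$x[, seq_len(n_pcs), drop = FALSE]
}

#' Genome-wide significance cutoff from the variant count
#'
#' The cutoff is `p = 1/n`, i.e. `-log10` threshold `log10(n)`, with `n`
#' the total number of variants tested.
#'
#' @param n_variants Total number of variants (>= 1).
#' @return List with `p` and `neg_log10`.
#' @examples
#' significance_cutoff(148323)$neg_log10     # about 5.17
#' @export
significance_cutoff <- function(n_variants) {
  if (length(n_variants) != 1L || is.na(n_variants) || n_variants < 1)
    stop("n_variants must be a positive count", call. = FALSE)
  list(p = 1 / n_variants, neg_log10 = log10(n_variants))
}

#' Classify a variant-gene pair as cis or trans
#'
#' Cis when variant and gene are on the same contig with a gap of at most
#' `window` bases between their intervals (overlap counts as distance 0;
#' the 1 Mb boundary is inclusive); otherwise trans.
#'
#' @param variant,gene Lists/data.frame rows with `contig`, `start`, `end`
#'   (0-based half-open). Vectorized over rows when given data.frames of
#'   equal height.
#' @param window Cis window in bases.
#' @return Character vector `"cis"`/`"trans"`, plus attribute `distance`.
#' @export
classify_cis_trans <- function(variant, gene, window = 1e6) {
  v <- as.data.frame(variant); g <- as.data.frame(gene)
  gap <- pmax(pmax(g$start - v$end, v$start - g$end), 0)
  res <- ifelse(v$contig == g$contig & gap <= window, "cis", "trans")
  attr(res, "distance") <- ifelse(v$contig == g$contig, gap, NA_real_)
  res
}

#' Squared-correlation linkage disequilibrium between two dosage vectors
#'
#' Squared Pearson correlation over pairwise-complete accessions. With
#' fewer than two complete pairs or a zero-variance vector the statistic is
#' undefined and returned as `NA` (clumping treats it as 0).
#'
#' @param dosage_a,dosage_b Dosage vectors of equal length.
#' @return r-squared in `[0, 1]`, or `NA`.
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  ok <- !is.na(dosage_a) & !is.na(dosage_b)
  if (sum(ok) < 2) return(NA_real_)
  a <- dosage_a[ok]; b <- dosage_b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' Greedy LD clumping of association records
#'
#' PLINK-style clumping: repeatedly take the unassigned variant with the
#' smallest p-value at most `p1` as the index, and absorb unassigned
#' variants on the same contig within `window_kb` of the index whose LD
#' r-squared with the index is at least `r2_min`. Ties in p are broken by
#' contig, position, then id. Variants with undefined r-squared are never
#' absorbed (r-squared treated as 0).
#'
#' @param records Association records with `variant_id`, `p`, `contig`,
#'   `pos` (anchor position in bases).
#' @param gm Dosage matrix covering all record variants (rownames = ids).
#' @param p1 Index significance threshold.
#' @param window_kb Clump window, kilobases from the index position.
#' @param r2_min Minimum LD with the index (inclusive).
#' @return Data.frame with one row per clump: `clump`, `index_variant`,
#'   `contig`, `span_start`, `span_end`, `n_members`, `members`
#'   (comma-joined, index first), `index_p`, `max_p`.
#' @export
clump <- function(records, gm, p1 = 1e-5, window_kb = 100, r2_min = 0.1) {
  stopifnot(all(c("variant_id", "p", "contig", "pos") %in% names(records)))
  if (!all(records$variant_id %in% rownames(gm)))
    stop("genotype matrix does not cover all record variants", call. = FALSE)
  r <- records[!is.na(records$p), , drop = FALSE]
  r <- r[order(r$p, r$contig, r$pos, r$variant_id), , drop = FALSE]
  assigned <- rep(FALSE, nrow(r))
  out <- list()
  repeat {
    cand <- which(!assigned & r$p <= p1)
    if (!length(cand)) break
    idx <- cand[1L]
    members <- idx
    near <- which(!assigned & seq_len(nrow(r)) != idx &
                    r$contig == r$contig[idx] &
                    abs(r$pos - r$pos[idx]) <= window_kb * 1000)
    if (length(near)) {
      r2 <- vapply(near, function(j)
        ld_r2(gm[r$variant_id[idx], ], gm[r$variant_id[j], ]), numeric(1))
      r2[is.na(r2)] <- 0
      members <- c(idx, near[r2 >= r2_min])
    }
    assigned[members] <- TRUE
    out[[length(out) + 1L]] <- data.frame(
      clump = length(out) + 1L,
      index_variant = r$variant_id[idx],
      contig = r$contig[idx],
      span_start = min(r$pos[members]),
      span_end = max(r$pos[members]),
      n_members = length(members),
      members = paste(r$variant_id[members], collapse = ","),
      index_p = r$p[idx],
      max_p = max(r$p[members]),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(clump = integer(), index_variant = character(),
                      contig = character(), span_start = numeric(),
                      span_end = numeric(), n_members = integer(),
                      members = character(), index_p = numeric(),
                      max_p = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Merge clump member anchors into trait loci
#'
#' Each clump spans the interval from the leftmost member anchor start to
#' the rightmost member anchor end; spans on one contig that overlap (or
#' touch) are merged into a single locus.
#'
#' @param spans Data.frame with `contig`, `start`, `end` (0-based
#'   half-open), e.g. one row per clump; an optional `trait` column splits
#'   the merge per trait.
#' @return Data.frame `trait` (if given), `contig`, `start`, `end`.
#' @export
merge_locus <- function(spans) {
  stopifnot(all(c("contig", "start", "end") %in% names(spans)))
  merge_one <- function(x) {
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      x$contig, IRanges::IRanges(x$start + 1L, x$end)))
    data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr),
               stringsAsFactors = FALSE)
  }
  if (!is.null(spans$trait)) {
    parts <- split(spans, spans$trait)
    out <- do.call(rbind, lapply(names(parts), function(tr)
      cbind(data.frame(trait = tr, stringsAsFactors = FALSE),
            merge_one(parts[[tr]]))))
    rownames(out) <- NULL
    out
  } else merge_one(spans)
}

#' Summarize significant eQTL records by cis/trans class
#'
#' @param records Association records with `p` and `cis` (logical or
#'   `"cis"`/`"trans"`), plus optional `target` and `variant_id` for lead
#'   reporting.
#' @param cutoff Significance threshold on p (e.g.
#'   `significance_cutoff(n)$p`); `NULL` keeps all records.
#' @return A list: `n_cis`, `n_trans`, `cis_pct`, `trans_pct` (rounded to
#'   two decimals), and `leads` (per-target smallest-p record, when targets
#'   are present).
#' @export
eqtl_summary <- function(records, cutoff = NULL) {
  cis <- records$cis
  if (!is.logical(cis)) cis <- cis == "cis"
  keep <- if (is.null(cutoff)) rep(TRUE, nrow(records)) else
    !is.na(records$p) & records$p <= cutoff
  r <- records[keep, , drop = FALSE]
  cis <- cis[keep]
  n_cis <- sum(cis); n_trans <- sum(!cis)
  tot <- n_cis + n_trans
  leads <- NULL
  if (!is.null(r$target) && nrow(r)) {
    leads <- do.call(rbind, lapply(split(r, r$target), function(x)
      x[which.min(x$p), , drop = FALSE]))
    rownames(leads) <- NULL
  }
  list(n_cis = n_cis, n_trans = n_trans,
       cis_pct = if (tot) round(100 * n_cis / tot, 2) else NA_real_,
       trans_pct = if (tot) round(100 * n_trans / tot, 2) else NA_real_,
       leads = leads)
}
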