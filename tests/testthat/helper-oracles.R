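## Independent brute-force oracles. These deliberately avoid the package's
## code paths (plain loops, exhaustive enumeration) so that agreement is a
## real cross-check and not a tautology.

## O(n^2) all-pairs TE-SV overlap scan (strict > frac of TE length)
oracle_links <- function(tes, segs, frac = 0.5) {
  out <- list()
  for (i in seq_len(nrow(tes))) {
    for (j in seq_len(nrow(segs))) {
      if (tes$genome_id[i] != segs$genome_id[j]) next
      if (tes$contig[i] != segs$contig[j]) next
      ov <- min(tes$end[i], segs$end[j]) - max(tes$start[i], segs$start[j])
      if (ov > frac * (tes$end[i] - tes$start[i]))
        out[[length(out) + 1L]] <- data.frame(
          te_id = tes$te_id[i], sv_id = segs$sv_id[j],
          carrier = segs$allele[j], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(te_id = character(), sv_id = character(),
                      carrier = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$te_id, res$sv_id), , drop = FALSE]
}

## straight-loop greedy clumping, written independently of tepan::clump
oracle_clump <- function(records, gm, p1 = 1e-5, window_kb = 100,
                         r2_min = 0.1) {
  r <- records[!is.na(records$p), , drop = FALSE]
  taken <- rep(FALSE, nrow(r))
  clumps <- list()
  repeat {
    best <- NA
    for (i in seq_len(nrow(r))) {
      if (taken[i] || r$p[i] > p1) next
      if (is.na(best)) { best <- i; next }
      if (r$p[i] < r$p[best] ||
          (r$p[i] == r$p[best] &&
           (r$contig[i] < r$contig[best] ||
            (r$contig[i] == r$contig[best] &&
             (r$pos[i] < r$pos[best] ||
              (r$pos[i] == r$pos[best] &&
               r$variant_id[i] < r$variant_id[best]))))))
        best <- i
    }
    if (is.na(best)) break
    members <- best
    ga <- gm[r$variant_id[best], ]
    for (j in seq_len(nrow(r))) {
      if (taken[j] || j == best) next
      if (r$contig[j] != r$contig[best]) next
      if (abs(r$pos[j] - r$pos[best]) > window_kb * 1000) next
      gb <- gm[r$variant_id[j], ]
      ok <- !is.na(ga) & !is.na(gb)
      if (sum(ok) < 2) next
      if (stats::sd(ga[ok]) == 0 || stats::sd(gb[ok]) == 0) next
      if (stats::cor(ga[ok], gb[ok])^2 >= r2_min) members <- c(members, j)
    }
    taken[members] <- TRUE
    clumps[[length(clumps) + 1L]] <-
      sort(r$variant_id[members])
  }
  clumps
}

## from-scratch TMM evaluation (reference by upper quartile closest to the
## mean; 30% M-trim, 5% A-trim, inverse-variance weights, geometric-mean-1
## rescaling)
oracle_tmm <- function(counts) {
  lib <- colSums(counts)
  uq <- apply(sweep(counts, 2, lib, "/"), 2, quantile, p = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  one_factor <- function(obs, nO, ref_col, nR) {
    logR <- log2((obs / nO) / (ref_col / nR))
    absE <- (log2(obs / nO) + log2(ref_col / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - ref_col) / nR / ref_col
    fin <- is.finite(logR) & is.finite(absE) & (absE > -1e10)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * 0.3) + 1; hiL <- n + 1 - loL
    loS <- floor(n * 0.05) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    2^(sum(logR[keep] / v[keep], na.rm = TRUE) /
         sum(1 / v[keep], na.rm = TRUE))
  }
  f <- vapply(seq_len(ncol(counts)), function(i)
    one_factor(counts[, i], lib[i], counts[, ref], lib[ref]), numeric(1))
  f / exp(mean(log(f)))
}

## exhaustive rule application for occupancy classes
oracle_occupancy <- function(occ, n) {
  vapply(occ, function(o) {
    if (o == 1) "private"
    else if (o >= 2 && o <= n - 3) "dispensable"
    else if (o >= n - 2 && o <= n - 1) "softcore"
    else "core"
  }, character(1))
}

## exhaustive pan/core means over all genome subsets of size k
oracle_pan_core_exact <- function(presence, k) {
  n <- ncol(presence)
  combos <- utils::combn(n, k)
  pan <- core <- numeric(ncol(combos))
  for (i in seq_len(ncol(combos))) {
    sub <- presence[, combos[, i], drop = FALSE]
    hits <- rowSums(sub > 0)
    pan[i] <- sum(hits > 0)
    core[i] <- sum(hits == k)
  }
  c(pan = mean(pan), core = mean(core))
}

## O(n^2) nearest-gene scan with the package's stated tie-break
oracle_nearest <- function(tes, genes) {
  res <- data.frame(te_id = tes$te_id, gene_id = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tes))) {
    best_gap <- Inf; best_tss <- Inf; best_id <- NA_character_
    for (j in seq_len(nrow(genes))) {
      if (genes$contig[j] != tes$contig[i]) next
      gap <- max(genes$start[j] - tes$end[i], tes$start[i] - genes$end[j], 0)
      tss <- if (genes$strand[j] == "-") genes$end[j] else genes$start[j]
      tss_gap <- max(tes$start[i] - tss, tss - tes$end[i], 0)
      better <- gap < best_gap ||
        (gap == best_gap && tss_gap < best_tss) ||
        (gap == best_gap && tss_gap == best_tss &&
           !is.na(best_id) && genes$gene_id[j] < best_id)
      if (better) {
        best_gap <- gap; best_tss <- tss_gap; best_id <- genes$gene_id[j]
      }
    }
    res$gene_id[i] <- best_id
  }
  res
}

## sweep-line interval union (touching intervals merge)
oracle_union <- function(spans) {
  out <- list()
  for (ctg in sort(unique(spans$contig))) {
    x <- spans[spans$contig == ctg, , drop = FALSE]
    x <- x[order(x$start, x$end), , drop = FALSE]
    cur_s <- x$start[1L]; cur_e <- x$end[1L]
    for (i in seq_len(nrow(x))[-1L]) {
      if (x$start[i] <= cur_e) cur_e <- max(cur_e, x$end[i])
      else {
        out[[length(out) + 1L]] <- data.frame(contig = ctg, start = cur_s,
                                              end = cur_e)
        cur_s <- x$start[i]; cur_e <- x$end[i]
      }
    }
    out[[length(out) + 1L]] <- data.frame(contig = ctg, start = cur_s,
                                          end = cur_e)
  }
  do.call(rbind, out)
}

## random interval fixture shared by association/clump oracle tests
random_te_sv_instance <- function(seed, n_tes = 50, n_segs = 30) {
  set.seed(seed)
  contigs <- c("c1", "c2")
  te_len <- sample(50:500, n_tes, replace = TRUE)
  te_start <- sample.int(50000, n_tes, replace = TRUE)
  tes <- data.frame(te_id = sprintf("te%03d", seq_len(n_tes)),
                    genome_id = "g1",
                    contig = sample(contigs, n_tes, replace = TRUE),
                    start = te_start, end = te_start + te_len,
                    stringsAsFactors = FALSE)
  seg_len <- sample(100:2000, n_segs, replace = TRUE)
  seg_start <- sample.int(50000, n_segs, replace = TRUE)
  segs <- data.frame(sv_id = sprintf("sv%03d", seq_len(n_segs)),
                     genome_id = "g1",
                     contig = sample(contigs, n_segs, replace = TRUE),
                     start = seg_start, end = seg_start + seg_len,
                     allele = sample(c("REF", "ALT"), n_segs, replace = TRUE),
                     stringsAsFactors = FALSE)
  list(tes = tes, segs = segs)
}
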