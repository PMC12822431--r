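## Pan-TE map construction: SV typing, TE-SV association by overlap,
## genotype merging, variant filtering and polymorphism summaries.
##
## All intervals are 0-based half-open internally (see the I/O helpers for
## the 1-based conversions applied to GFF3/VCF dialects).

#' Classify structural-variant alleles by REF/ALT length
#'
#' Deletion-type SVs have `length(REF) >= 50` and `length(ALT) = 1`;
#' insertion-type SVs have `length(REF) = 1` and `length(ALT) >= 50`; any
#' remaining allele with a length of at least 50 bp is complex (`MNP`);
#' everything shorter is `small` and excluded from SV genotyping.
#'
#' @param ref_len,alt_len Allele lengths in bases (>= 1), vectorized.
#' @param min_sv_len SV length threshold (bases).
#' @return Character vector in `{"INS", "DEL", "MNP", "small"}`.
#' @examples
#' classify_sv_type(c(1, 300, 10), c(120, 1, 4))
#' @export
classify_sv_type <- function(ref_len, alt_len, min_sv_len = 50L) {
  if (any(ref_len < 1 | alt_len < 1, na.rm = TRUE))
    stop("allele lengths must be >= 1 bp", call. = FALSE)
  out <- rep("small", length(ref_len))
  out[pmax(ref_len, alt_len) >= min_sv_len] <- "MNP"
  out[ref_len >= min_sv_len & alt_len == 1] <- "DEL"
  out[ref_len == 1 & alt_len >= min_sv_len] <- "INS"
  out
}

#' Link TEs to SV bubbles by allele-segment overlap
#'
#' A TE is associated with an SV when the SV's allele segment (the interval
#' occupied by one of the SV's alleles in the assembly carrying the TE
#' annotation) covers strictly more than half of the TE. The carrier allele
#' of a link is the allele whose sequence hosts the TE: `ALT` for
#' insertion-borne TEs annotated on a non-reference placement, `REF` for
#' deletion-borne TEs annotated on the reference.
#'
#' @param tes TE annotation data.frame with columns `te_id`, `genome_id`,
#'   `contig`, `start`, `end` (0-based half-open).
#' @param sv_segments SV allele placements: data.frame with `sv_id`,
#'   `genome_id`, `contig`, `start`, `end`, `allele` (`"REF"` or `"ALT"`).
#' @param min_overlap_frac Required covered fraction of the TE (strict `>`).
#' @return A data.frame of links: `te_id`, `sv_id`, `carrier`,
#'   `overlap_frac`.
#' @export
associate_te_to_sv <- function(tes, sv_segments, min_overlap_frac = 0.5) {
  stopifnot(all(c("te_id", "genome_id", "contig", "start", "end") %in%
                  names(tes)),
            all(c("sv_id", "genome_id", "contig", "start", "end", "allele")
                %in% names(sv_segments)))
  if (any(tes$end <= tes$start))
    stop("TE intervals must have positive length", call. = FALSE)
  empty <- data.frame(te_id = character(), sv_id = character(),
                      carrier = character(), overlap_frac = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(tes) || !nrow(sv_segments)) return(empty)

  ## candidate pairs via interval overlap within each (genome, contig) space
  te_gr <- GenomicRanges::GRanges(
    paste(tes$genome_id, tes$contig, sep = "\r"),
    IRanges::IRanges(tes$start + 1L, tes$end))
  sv_gr <- GenomicRanges::GRanges(
    paste(sv_segments$genome_id, sv_segments$contig, sep = "\r"),
    IRanges::IRanges(sv_segments$start + 1L, sv_segments$end))
  hits <- GenomicRanges::findOverlaps(te_gr, sv_gr)
  if (!length(hits)) return(empty)
  ti <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- pmin(tes$end[ti], sv_segments$end[si]) -
    pmax(tes$start[ti], sv_segments$start[si])
  frac <- ov / (tes$end[ti] - tes$start[ti])
  keep <- frac > min_overlap_frac
  out <- data.frame(te_id = tes$te_id[ti][keep],
                    sv_id = sv_segments$sv_id[si][keep],
                    carrier = sv_segments$allele[si][keep],
                    overlap_frac = frac[keep],
                    stringsAsFactors = FALSE)
  unique(out[order(out$te_id, out$sv_id), , drop = FALSE])
}

#' Merge SV genotypes into a single TE dosage vector
#'
#' When a TE is associated with several SVs its genotype is the per-accession
#' minimum of the carrier-allele dosages over the linked SVs (the TE is only
#' present on a haplotype carrying every hosting segment); any missing linked
#' SV call makes the merged call missing. For a `REF`-carrier link the
#' carrier-allele dosage is `2 - ALT dosage`.
#'
#' @param links Link rows for one TE (from [associate_te_to_sv()]): columns
#'   `sv_id`, `carrier`.
#' @param sv_genotypes SV x accession dosage matrix of the ALT allele
#'   (0/1/2/NA), rownames = sv ids.
#' @param rule `"min"` (default, conservative intersection) or `"max"`
#'   (any-presence union).
#' @return Integer dosage vector over accessions.
#' @export
merge_genotypes <- function(links, sv_genotypes, rule = c("min", "max")) {
  rule <- match.arg(rule)
  if (!nrow(links)) stop("empty link set for TE genotype merge", call. = FALSE)
  if (!all(links$sv_id %in% rownames(sv_genotypes)))
    stop("links refer to SVs absent from the genotype matrix", call. = FALSE)
  dos <- sv_genotypes[links$sv_id, , drop = FALSE]
  flip <- links$carrier == "REF"
  dos[flip, ] <- 2L - dos[flip, , drop = FALSE]
  agg <- if (rule == "min") {
    apply(dos, 2L, function(x) if (anyNA(x)) NA_integer_ else min(x))
  } else {
    apply(dos, 2L, function(x) if (anyNA(x)) NA_integer_ else max(x))
  }
  as.integer(agg)
}

#' Build the pan-TE map from annotations, SV segments and SV genotypes
#'
#' Runs the TE-SV association and genotype merge over all TEs and summarizes
#' each resulting pan-TE locus with its minor allele frequency and
#' conservation status (`fixed` when only one allele is observed among
#' non-missing calls).
#'
#' @inheritParams associate_te_to_sv
#' @inheritParams merge_genotypes
#' @return A list: `loci` (data.frame `te_id`, `contig`, `start`, `end`,
#'   `n_svs`, `sv_ids`, `maf`, `n_missing`, `conservation`), `genotypes`
#'   (TE x accession merged dosage matrix) and `links`.
#' @export
build_pante_map <- function(tes, sv_segments, sv_genotypes,
                            min_overlap_frac = 0.5, rule = "min") {
  links <- associate_te_to_sv(tes, sv_segments, min_overlap_frac)
  linked_tes <- unique(links$te_id)
  acc <- colnames(sv_genotypes)
  gm <- matrix(NA_integer_, length(linked_tes), length(acc),
               dimnames = list(linked_tes, acc))
  for (te in linked_tes)
    gm[te, ] <- merge_genotypes(links[links$te_id == te, , drop = FALSE],
                                sv_genotypes, rule = rule)
  maf <- row_apply_num(gm, compute_maf)
  nmiss <- rowSums(is.na(gm))
  fixed <- row_apply_lgl(gm, function(x) {
    x <- x[!is.na(x)]
    length(x) > 0L && (all(x == 2L) || all(x == 0L))
  })
  anchor <- tes[match(linked_tes, tes$te_id), c("contig", "start", "end")]
  loci <- data.frame(te_id = linked_tes, anchor,
                     n_svs = as.integer(table(links$te_id)[linked_tes]),
                     sv_ids = vapply(linked_tes, function(te)
                       paste(links$sv_id[links$te_id == te], collapse = ","),
                       character(1)),
                     maf = maf, n_missing = nmiss,
                     conservation = ifelse(fixed, "fixed", "polymorphic"),
                     row.names = NULL, stringsAsFactors = FALSE)
  loci$conservation[nmiss == length(acc)] <- "all_missing"
  list(loci = loci, genotypes = gm, links = links)
}

row_apply_num <- function(m, f)
  vapply(seq_len(nrow(m)), function(i) f(m[i, ]), numeric(1))
row_apply_lgl <- function(m, f)
  vapply(seq_len(nrow(m)), function(i) f(m[i, ]), logical(1))

## MAF from a dosage vector over non-missing calls (diploid allele counting)
compute_maf <- function(dosage) {
  d <- dosage[!is.na(dosage)]
  if (!length(d)) return(NA_real_)
  f <- sum(d) / (2 * length(d))
  min(f, 1 - f)
}

#' Filter a genotype matrix on missingness, MAF and heterozygosity
#'
#' Keeps variants with a missing ratio of at most `max_missing`, a minor
#' allele frequency strictly greater than `min_maf` (when set) and a
#' heterozygote fraction strictly below `max_het` (when set). Genotype
#' values are never altered; rows are only dropped.
#'
#' @param gm Variant x accession dosage matrix (0/1/2/NA).
#' @param max_missing Maximum tolerated missing fraction (default 0.5; use
#'   `NULL` to disable).
#' @param min_maf,max_het Optional MAF / heterozygosity thresholds (`NULL`
#'   disables each).
#' @return The row-subset matrix, with an attribute `removed` giving the
#'   count removed per criterion (applied in order: missingness, MAF,
#'   heterozygosity).
#' @export
filter_variants <- function(gm, max_missing = 0.5, min_maf = NULL,
                            max_het = NULL) {
  if (!nrow(gm) || !ncol(gm)) stop("empty genotype matrix", call. = FALSE)
  for (p in c(max_missing, min_maf, max_het))
    if (!is.null(p) && (p < 0 || p > 1))
      stop("thresholds must lie in [0, 1]", call. = FALSE)
  removed <- c(missing = 0L, maf = 0L, het = 0L)

  keep <- rep(TRUE, nrow(gm))
  if (!is.null(max_missing)) {
    miss <- rowMeans(is.na(gm))
    drop <- keep & miss > max_missing
    removed["missing"] <- sum(drop)
    keep <- keep & !drop
  }
  if (!is.null(min_maf)) {
    maf <- row_apply_num(gm, compute_maf)
    drop <- keep & (is.na(maf) | maf <= min_maf)
    removed["maf"] <- sum(drop)
    keep <- keep & !drop
  }
  if (!is.null(max_het)) {
    het <- rowMeans(gm == 1L, na.rm = TRUE)
    drop <- keep & (is.nan(het) | het >= max_het)
    removed["het"] <- sum(drop)
    keep <- keep & !drop
  }
  out <- gm[keep, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Summarize pan-TE conservation and the MAF spectrum
#'
#' @param gm TE x accession merged dosage matrix (0/1/2/NA).
#' @param breaks MAF histogram bin edges over `[0, 0.5]`.
#' @return A list: `n_loci`, `n_all_missing` (flagged separately and
#'   excluded from the fractions), `fixed_fraction`, `polymorphic_fraction`
#'   (summing to 1), `maf_histogram` (data.frame `bin`, `count`, over
#'   polymorphic loci).
#' @export
conservation_summary <- function(gm, breaks = seq(0, 0.5, by = 0.05)) {
  if (!nrow(gm)) stop("no pan-TE loci to summarize", call. = FALSE)
  all_missing <- rowSums(!is.na(gm)) == 0L
  g <- gm[!all_missing, , drop = FALSE]
  fixed <- row_apply_lgl(g, function(x) {
    x <- x[!is.na(x)]
    all(x == 2L) || all(x == 0L)
  })
  maf <- row_apply_num(g[!fixed, , drop = FALSE], compute_maf)
  bins <- cut(maf, breaks = breaks, include.lowest = TRUE, right = TRUE)
  list(n_loci = nrow(gm),
       n_all_missing = sum(all_missing),
       fixed_fraction = mean(fixed),
       polymorphic_fraction = mean(!fixed),
       maf_histogram = data.frame(bin = levels(bins),
                                  count = as.integer(table(bins))))
}
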