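## Synthetic-data generators.
##
## Every downstream stage of the pipeline (pan-TE map construction, effect
## classification, association scans, haplotype combinations, LTR dating) is
## exercised on data produced here, with a complete ground-truth channel so
## sensitivity/specificity and recovery checks are well defined.

#' Specify a minor-allele-frequency law for simulated TE polymorphisms
#'
#' Polymorphic TE insertions in resequencing panels are dominated by
#' low-frequency variants, so the default law is a Beta distribution scaled
#' onto (0, 0.5] and skewed toward small frequencies. A uniform law is
#' available for calibration work where a flat spectrum is easier to reason
#' about.
#'
#' @param dist `"beta"` or `"uniform"`.
#' @param shape1,shape2 Beta shape parameters (used when `dist = "beta"`).
#' @param min,max Bounds on the frequency (used when `dist = "uniform"`);
#'   must lie within (0, 0.5].
#' @return An object of class `maf_law`: a list with a `sample(n)` closure.
#' @examples
#' law <- maf_law("uniform", min = 0.005, max = 0.5)
#' @export
maf_law <- function(dist = c("beta", "uniform"), shape1 = 0.6, shape2 = 4,
                    min = 0.005, max = 0.5) {
  dist <- match.arg(dist)
  if (dist == "uniform") {
    if (min <= 0 || max > 0.5 || min >= max)
      stop("uniform MAF law requires 0 < min < max <= 0.5", call. = FALSE)
    sample_fun <- function(n) stats::runif(n, min, max)
  } else {
    if (shape1 <= 0 || shape2 <= 0)
      stop("beta MAF law requires positive shape parameters", call. = FALSE)
    ## scale Beta(0,1) onto (0, 0.5]; pmax guards exact zeros
    sample_fun <- function(n) pmax(stats::rbeta(n, shape1, shape2) / 2, 1e-4)
  }
  structure(list(dist = dist, sample = sample_fun,
                 params = list(shape1 = shape1, shape2 = shape2,
                               min = min, max = max)),
            class = "maf_law")
}

#' Simulate a population TE genotype matrix
#'
#' Generates a variants-by-accessions dosage matrix for a diploid, biallelic
#' presence/absence model. Dosage counts the TE-bearing allele (0 = absent on
#' both haplotypes, 2 = present on both). A configurable fraction of TEs is
#' fixed (dosage 2 in every non-missing accession); the rest are polymorphic
#' with a true minor-allele frequency drawn from `law` and genotypes sampled
#' under Hardy-Weinberg equilibrium. Entries are masked missing (`NA`)
#' independently at rate `missing_rate`.
#'
#' @param n_accessions Number of accessions (columns); at least 2.
#' @param n_tes Number of TE loci (rows).
#' @param fixed_fraction Proportion of loci fixed for the TE allele.
#' @param law A [maf_law()] object for polymorphic loci.
#' @param missing_rate Per-entry missingness probability.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A list with `genotypes` (integer matrix, rows `te_*`, columns
#'   `acc_*`, with `NA` for masked calls), `complete` (the same matrix
#'   before missingness masking — the true genotypes) and `truth`
#'   (data.frame: `te_id`, `fixed`, `true_maf`).
#' @examples
#' sim <- simulate_genotypes(50, 100, fixed_fraction = 0.8, seed = 1)
#' table(sim$truth$fixed)
#' @export
simulate_genotypes <- function(n_accessions, n_tes,
                               fixed_fraction = 0.8514,
                               law = maf_law(),
                               missing_rate = 0,
                               seed = 1L) {
  if (n_accessions < 2) stop("n_accessions must be >= 2", call. = FALSE)
  if (n_tes < 1) stop("n_tes must be >= 1", call. = FALSE)
  for (p in c(fixed_fraction = fixed_fraction, missing_rate = missing_rate))
    if (is.na(p) || p < 0 || p > 1)
      stop("proportions must lie in [0, 1]", call. = FALSE)
  if (!inherits(law, "maf_law")) stop("law must be a maf_law object", call. = FALSE)

  set.seed(seed)
  n_fixed <- round(fixed_fraction * n_tes)
  fixed <- c(rep(TRUE, n_fixed), rep(FALSE, n_tes - n_fixed))
  true_maf <- numeric(n_tes)
  if (n_tes > n_fixed) true_maf[!fixed] <- law$sample(n_tes - n_fixed)

  g <- matrix(2L, n_tes, n_accessions,
              dimnames = list(sprintf("te_%04d", seq_len(n_tes)),
                              sprintf("acc_%04d", seq_len(n_accessions))))
  if (any(!fixed)) {
    npoly <- sum(!fixed)
    g[!fixed, ] <- matrix(
      stats::rbinom(npoly * n_accessions, 2L, rep(true_maf[!fixed], n_accessions)),
      npoly, n_accessions)
  }
  g_complete <- g
  if (missing_rate > 0) {
    miss <- matrix(stats::runif(n_tes * n_accessions) < missing_rate,
                   n_tes, n_accessions)
    g[miss] <- NA_integer_
  }
  truth <- data.frame(te_id = rownames(g), fixed = fixed, true_maf = true_maf,
                      stringsAsFactors = FALSE)
  list(genotypes = g, complete = g_complete, truth = truth)
}

#' Simulate per-stage expression matrices with planted TE effects
#'
#' Each TE locus in `genotypes` is paired with one target gene (named
#' `gene_<te_id>`), emulating a nearest-gene assignment. A planted effect with
#' fold `f` multiplies the target gene's expectation by `f` in carrier
#' accessions (any non-zero dosage, i.e. dominant presence/absence coding).
#' Noise is multiplicative log-normal with coefficient of variation
#' `noise_cv`, so values are positive and right-skewed like TPM. All stages
#' share the planted effects; noise is independent per stage, which is what a
#' cross-stage consistency analysis assumes.
#'
#' @param genotypes Dosage matrix from [simulate_genotypes()].
#' @param planted_effects Named numeric vector: fold change per TE id
#'   (fold >= 0; 1 = no effect). Names must exist among the rows of
#'   `genotypes`.
#' @param baseline_mean,baseline_sdlog Log-normal law for per-gene baseline
#'   expression (mean on the TPM scale; spread on the log scale).
#' @param noise_cv Coefficient of variation of multiplicative noise.
#' @param stages Number of developmental stages to emit.
#' @param seed Integer seed.
#' @return A list with `expression` (list of stage matrices, genes x
#'   accessions), `te_gene_map` (data.frame `te_id`, `gene_id`) and `truth`
#'   (data.frame `te_id`, `gene_id`, `fold`).
#' @export
simulate_expression <- function(genotypes, planted_effects = numeric(),
                                baseline_mean = 10, baseline_sdlog = 1,
                                noise_cv = 0.2, stages = 2L, seed = 1L) {
  if (length(planted_effects)) {
    if (is.null(names(planted_effects)) ||
        !all(names(planted_effects) %in% rownames(genotypes)))
      stop("planted_effects names must all be TE ids present in genotypes",
           call. = FALSE)
    if (any(planted_effects < 0)) stop("folds must be >= 0", call. = FALSE)
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  set.seed(seed)

  te_ids <- rownames(genotypes)
  gene_ids <- paste0("gene_", te_ids)
  fold <- stats::setNames(rep(1, length(te_ids)), te_ids)
  fold[names(planted_effects)] <- planted_effects

  baseline <- stats::rlnorm(length(gene_ids),
                            meanlog = log(baseline_mean) - baseline_sdlog^2 / 2,
                            sdlog = baseline_sdlog)
  carrier <- genotypes > 0            # NA dosages give NA expression
  ## log-normal noise with E[noise] = 1 and CV = noise_cv
  sdlog <- sqrt(log(1 + noise_cv^2))
  mu <- baseline * ifelse(carrier, fold[te_ids], 1)

  mats <- lapply(seq_len(stages), function(s) {
    noise <- matrix(stats::rlnorm(length(mu), -sdlog^2 / 2, sdlog),
                    nrow(mu), ncol(mu))
    m <- mu * noise
    dimnames(m) <- list(gene_ids, colnames(genotypes))
    m
  })
  names(mats) <- paste0("stage_", seq_len(stages))

  truth <- data.frame(te_id = names(planted_effects),
                      gene_id = paste0("gene_", names(planted_effects)),
                      fold = unname(planted_effects),
                      stringsAsFactors = FALSE)
  list(expression = mats,
       te_gene_map = data.frame(te_id = te_ids, gene_id = gene_ids,
                                stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate a phenotype with planted TE QTLs
#'
#' The phenotype is the additive genetic value `sum(beta * dosage)` over the
#' planted QTLs plus Gaussian noise scaled so the genetic variance fraction
#' equals `heritability`. Missing dosages are mean-imputed per variant when
#' forming the genetic value. Ecotype labels are assigned from the dosage of
#' the first planted QTL (0 = winter, 1 = semi_winter, 2 = spring; missing
#' dosage draws a random label), giving the haplotype-combination stage
#' metadata with a known genetic basis; region and year are random metadata.
#'
#' @param genotypes Dosage matrix from [simulate_genotypes()].
#' @param qtl_effects Named numeric vector: effect per copy, names are TE
#'   ids. May be empty only when `heritability = 0`.
#' @param heritability Fraction of phenotypic variance that is genetic, in
#'   `[0, 1)`.
#' @param trait Name of the trait column in the returned table.
#' @param seed Integer seed.
#' @return A list with `phenotype` (data.frame: `accession`, trait column,
#'   `ecotype`, `region`, `year`) and `truth` (the `qtl_effects` vector and
#'   `heritability`).
#' @export
simulate_phenotype <- function(genotypes, qtl_effects = numeric(),
                               heritability = 0.5, trait = "flowering_time",
                               seed = 1L) {
  if (heritability < 0 || heritability >= 1)
    stop("heritability must lie in [0, 1)", call. = FALSE)
  if (heritability > 0 && !length(qtl_effects))
    stop("qtl_effects must be non-empty when heritability > 0", call. = FALSE)
  if (length(qtl_effects) &&
      (is.null(names(qtl_effects)) ||
       !all(names(qtl_effects) %in% rownames(genotypes))))
    stop("qtl_effects names must all be TE ids present in genotypes",
         call. = FALSE)
  set.seed(seed)

  n <- ncol(genotypes)
  if (length(qtl_effects) && heritability > 0) {
    dos <- genotypes[names(qtl_effects), , drop = FALSE]
    dos <- t(apply(dos, 1L, function(x) {
      x[is.na(x)] <- mean(x, na.rm = TRUE)
      x
    }))
    dos <- matrix(dos, ncol = n)     # qtls x accessions, robust to 1 qtl
    dos <- t(dos)                    # accessions x qtls
    genetic <- drop(dos %*% qtl_effects)
    vg <- stats::var(genetic)
    if (vg == 0)
      stop("planted QTLs are monomorphic: genetic variance is zero, ",
           "heritability is undefined", call. = FALSE)
    noise_sd <- sqrt(vg * (1 - heritability) / heritability)
    y <- genetic + stats::rnorm(n, 0, noise_sd)
    eco_dose <- genotypes[names(qtl_effects)[1L], ]
  } else {
    y <- stats::rnorm(n)
    eco_dose <- rep(NA_integer_, n)
  }
  eco_levels <- c("winter", "semi_winter", "spring")
  ecotype <- ifelse(is.na(eco_dose),
                    sample(eco_levels, n, replace = TRUE),
                    eco_levels[eco_dose + 1L])

  pheno <- data.frame(accession = colnames(genotypes), stringsAsFactors = FALSE)
  pheno[[trait]] <- y
  pheno$ecotype <- ecotype
  pheno$region <- sample(c("north", "south", "east", "west"), n, replace = TRUE)
  pheno$year <- sample(2014:2020, n, replace = TRUE)
  list(phenotype = pheno,
       truth = list(qtl_effects = qtl_effects, heritability = heritability))
}

#' Simulate gene/TE/SV interval layouts with known TE-SV links
#'
#' Lays out gene models, TE annotations and SV allele placements on the given
#' contigs so that the truth links are unambiguous by construction: SV
#' alternative-allele segments are placed on a disjoint grid; each "linked" TE
#' is contained in its SV segment (overlap = 100% of TE length), decoy TEs
#' either fall in the gaps between segments (overlap 0) or straddle a segment
#' boundary with exactly half their length inside (overlap = 50%, which the
#' strict "> half" association rule must reject). All coordinates are 0-based
#' half-open.
#'
#' @param n_genes,n_tes,n_svs Record counts (>= 0).
#' @param contig_lengths Named integer vector of contig sizes (bases).
#' @param link_fraction Fraction of TEs planted inside an SV segment.
#' @param genome_id Assembly label attached to TE and SV placements.
#' @param seed Integer seed.
#' @return A list with `genes`, `tes` (data.frames with `contig`, `start`,
#'   `end`, `strand`, ids, TE class/superfamily/family), `svs` (SV records
#'   with reference anchor and `ref_len`/`alt_len`), `sv_segments`
#'   (per-genome allele placement intervals with `allele`), and `truth_links`
#'   (data.frame `te_id`, `sv_id`).
#' @export
simulate_intervals <- function(n_genes, n_tes, n_svs,
                               contig_lengths = c(chrA01 = 2e6, chrC01 = 2e6),
                               link_fraction = 0.5,
                               genome_id = "ref",
                               seed = 1L) {
  if (!length(contig_lengths) || is.null(names(contig_lengths)))
    stop("contig_lengths must be a non-empty named vector", call. = FALSE)
  if (any(c(n_genes, n_tes, n_svs) < 0)) stop("counts must be >= 0", call. = FALSE)
  set.seed(seed)

  contigs <- names(contig_lengths)
  rand_intervals <- function(n, min_len, max_len, prefix) {
    if (n == 0)
      return(data.frame(id = character(), contig = character(),
                        start = integer(), end = integer(),
                        strand = character(), stringsAsFactors = FALSE))
    ctg <- sample(contigs, n, replace = TRUE)
    len <- sample(min_len:max_len, n, replace = TRUE)
    start <- floor(stats::runif(n) * (contig_lengths[ctg] - len))
    data.frame(id = sprintf("%s_%04d", prefix, seq_len(n)),
               contig = ctg, start = as.integer(start),
               end = as.integer(start + len),
               strand = sample(c("+", "-"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  }

  genes <- rand_intervals(n_genes, 1000L, 5000L, "gene")
  names(genes)[1L] <- "gene_id"

  ## SV segments on a disjoint grid of the first contig: slot i occupies
  ## [i*slot + gap, i*slot + gap + seg_len)
  seg_len <- 4000L
  gap <- 2000L
  slot <- seg_len + 2L * gap
  main <- contigs[1L]
  if (n_svs * slot > contig_lengths[[main]])
    stop("contig too short for the requested number of SV segments",
         call. = FALSE)
  sv_id <- sprintf("sv_%04d", seq_len(n_svs))
  seg_start <- as.integer((seq_len(n_svs) - 1L) * slot + gap)
  sv_segments <- data.frame(sv_id = sv_id, genome_id = rep(genome_id, n_svs),
                            contig = rep(main, n_svs), start = seg_start,
                            end = seg_start + seg_len,
                            allele = rep("ALT", n_svs),
                            stringsAsFactors = FALSE)
  svs <- data.frame(sv_id = sv_id, contig = rep(main, n_svs),
                    start = seg_start, end = seg_start + 1L,
                    ref_len = rep(1L, n_svs), alt_len = rep(seg_len, n_svs),
                    stringsAsFactors = FALSE)

  ## TEs: linked inside a segment, decoys in gaps or at exactly-half overlap
  te_len <- 400L
  n_link <- if (n_svs > 0) round(link_fraction * n_tes) else 0L
  te <- data.frame(te_id = sprintf("te_%04d", seq_len(n_tes)),
                   genome_id = genome_id, contig = main,
                   start = 0L, end = 0L,
                   stringsAsFactors = FALSE)
  truth_links <- data.frame(te_id = character(), sv_id = character(),
                            stringsAsFactors = FALSE)
  if (n_tes > 0) {
    if (n_link > 0) {
      host <- sample(n_svs, n_link, replace = TRUE)
      off <- floor(stats::runif(n_link) * (seg_len - te_len))
      te$start[seq_len(n_link)] <- as.integer(seg_start[host] + off)
      truth_links <- data.frame(te_id = te$te_id[seq_len(n_link)],
                                sv_id = sv_id[host], stringsAsFactors = FALSE)
    }
    n_decoy <- n_tes - n_link
    if (n_decoy > 0) {
      idx <- n_link + seq_len(n_decoy)
      half <- n_svs > 0 & (seq_len(n_decoy) %% 4L == 0L)
      ## boundary decoys: half the TE inside the segment, half in the gap
      if (any(half)) {
        host <- sample(n_svs, sum(half), replace = TRUE)
        te$start[idx[half]] <- as.integer(seg_start[host] - te_len %/% 2L)
      }
      if (any(!half)) {
        n_free <- sum(!half)
        if (n_svs > 0) {
          ## place in the trailing gap of a random slot
          host <- sample(n_svs, n_free, replace = TRUE)
          off <- floor(stats::runif(n_free) * (gap - te_len - 2L)) + 1L
          te$start[idx[!half]] <- as.integer(seg_start[host] + seg_len + off)
        } else {
          te$start[idx[!half]] <-
            as.integer(floor(stats::runif(n_free) *
                             (contig_lengths[[main]] - te_len)))
        }
      }
    }
    te$end <- te$start + te_len
    te$strand <- sample(c("+", "-"), n_tes, replace = TRUE)
    sf <- sample(c("Copia", "Gypsy", "LINE", "SINE", "TIR", "Helitron"),
                 n_tes, replace = TRUE)
    te$te_class <- ifelse(sf %in% c("TIR", "Helitron"), "II", "I")
    te$superfamily <- sf
    te$family <- paste0(sf, "_fam", sample(1:20, n_tes, replace = TRUE))
  } else {
    te$strand <- character(0); te$te_class <- character(0)
    te$superfamily <- character(0); te$family <- character(0)
  }

  list(genes = genes, tes = te, svs = svs, sv_segments = sv_segments,
       truth_links = truth_links)
}

#' Simulate LTR terminal-repeat pairs at known ages
#'
#' For each requested age the two terminal repeats of a full-length LTR
#' element start identical (they are when the element inserts) and diverge
#' under a Jukes-Cantor substitution process at rate `r` per site per year on
#' each repeat, so the pair divergence is `K = 2 * r * age` and the per-site
#' mismatch probability is `p = 3/4 * (1 - exp(-4K/3))`.
#'
#' @param ages Numeric vector of true insertion ages in years (>= 0).
#' @param r Substitution rate per site per year (> 0).
#' @param seq_len Repeat length in bases.
#' @param superfamily Optional vector recycled over elements
#'   (`Copia`/`Gypsy`/`unknown`).
#' @param subgenome Optional vector recycled over elements (e.g. `A_n`,
#'   `C_n`).
#' @param seed Integer seed.
#' @return A data.frame with `element_id`, `superfamily`, `subgenome`,
#'   `true_age`, and aligned repeat sequences `ltr5`, `ltr3`.
#' @export
simulate_ltr_pairs <- function(ages, r = 1.5e-8, seq_len = 2000L,
                               superfamily = c("Copia", "Gypsy"),
                               subgenome = c("A_n", "C_n"),
                               seed = 1L) {
  if (any(ages < 0)) stop("ages must be >= 0", call. = FALSE)
  if (r <= 0) stop("substitution rate r must be > 0", call. = FALSE)
  set.seed(seed)

  bases <- c("A", "C", "G", "T")
  n <- length(ages)
  k <- 2 * r * ages
  p <- 0.75 * (1 - exp(-4 * k / 3))
  ltr5 <- ltr3 <- character(n)
  for (i in seq_len(n)) {
    a <- sample(bases, seq_len, replace = TRUE)
    b <- a
    hit <- stats::runif(seq_len) < p[i]
    if (any(hit))
      b[hit] <- vapply(a[hit], function(x)
        sample(setdiff(bases, x), 1L), character(1))
    ltr5[i] <- paste(a, collapse = "")
    ltr3[i] <- paste(b, collapse = "")
  }
  data.frame(element_id = sprintf("ltr_%04d", seq_len(n)),
             superfamily = rep_len(superfamily, n),
             subgenome = rep_len(subgenome, n),
             true_age = ages, ltr5 = ltr5, ltr3 = ltr3,
             stringsAsFactors = FALSE)
}
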