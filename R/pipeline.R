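## Pipeline orchestration: configuration handling and an end-to-end runner
## over the synthetic-data, pan-TE, dating, effect, association and
## haplotype stages, with a reproducibility manifest.

config_defaults <- function() {
  list(
    seed = 1L,
    outdir = "tepan_out",
    simulate = list(
      n_accessions = 200L, n_tes = 300L, fixed_fraction = 0.8514,
      missing_rate = 0.02, maf_dist = "beta",
      n_effect_tes = 20L, effect_fold = 2.0,
      expression_stages = 2L, noise_cv = 0.2,
      n_qtl = 3L, qtl_beta = 1.0, heritability = 0.5,
      n_genes = 60L, n_svs = 40L, contig_length = 2e6,
      ltr_ages = c(5e4, 2e5, 5e5, 1e6, 2e6), ltr_seq_len = 2000L,
      n_genomes = 14L, n_clusters = 300L),
    thresholds = list(
      overlap_frac = 0.5, fold = 1.5, min_group = 5L, epsilon = 0.01,
      cis_window = 1e6, maf = 0.05, missing = 0.5, het = 0.5,
      tpm_min = 0.01, tpm_low_frac = 0.8,
      clump_p1 = 1e-5, clump_kb = 100, clump_r2 = 0.1,
      haplo_min_freq = 0.05, r = 1.5e-8, n_pcs = 10L,
      growth_subsets = 500L, growth_repeats = 30L))
}

#' Build and validate a pipeline configuration
#'
#' Starts from the package defaults (which carry the standard thresholds:
#' overlap fraction 0.5, fold 1.5, cis window 1 Mb, MAF 0.05, missingness
#' 0.5, heterozygosity 0.5, TPM 0.01/80%, clump p1 1e-5 / 100 kb / r2 0.1,
#' haplotype frequency 0.05, substitution rate 1.5e-8, 10 PCs, 500x30
#' growth sampling) and overrides them from a YAML file and/or a named
#' list. Unknown keys are rejected.
#'
#' @param path Optional YAML config file.
#' @param overrides Optional named list of overrides (nested, same shape as
#'   the defaults).
#' @return A validated config list of class `tepan_config`.
#' @export
pipeline_config <- function(path = NULL, overrides = NULL) {
  cfg <- config_defaults()
  merge_into <- function(base, upd, where = "") {
    for (nm in names(upd)) {
      if (!nm %in% names(base))
        stop("unknown config key: ", where, nm, call. = FALSE)
      if (is.list(base[[nm]]) && is.list(upd[[nm]]))
        base[[nm]] <- merge_into(base[[nm]], upd[[nm]],
                                 paste0(where, nm, "."))
      else base[[nm]] <- upd[[nm]]
    }
    base
  }
  if (!is.null(path)) cfg <- merge_into(cfg, yaml::read_yaml(path))
  if (!is.null(overrides)) cfg <- merge_into(cfg, overrides)
  validate_config(cfg)
  structure(cfg, class = c("tepan_config", "list"))
}

validate_config <- function(cfg) {
  th <- cfg$thresholds
  in01 <- c("overlap_frac", "maf", "missing", "het", "tpm_low_frac",
            "haplo_min_freq", "clump_r2")
  for (nm in in01)
    if (th[[nm]] < 0 || th[[nm]] > 1)
      stop("threshold '", nm, "' must lie in [0, 1]", call. = FALSE)
  if (th$fold < 1) stop("fold threshold must be >= 1", call. = FALSE)
  if (th$r <= 0) stop("substitution rate must be > 0", call. = FALSE)
  if (th$cis_window < 0 || th$clump_kb <= 0 || th$clump_p1 <= 0)
    stop("invalid association thresholds", call. = FALSE)
  sim <- cfg$simulate
  if (sim$n_accessions < 2) stop("n_accessions must be >= 2", call. = FALSE)
  if (sim$heritability < 0 || sim$heritability >= 1)
    stop("heritability must lie in [0, 1)", call. = FALSE)
  invisible(TRUE)
}

## deterministic per-stage seeds derived from the master seed
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 11L, pangene = 23L, pante = 37L, ltr = 41L,
               effects = 53L, eqtl = 67L, gwas = 79L, haplo = 97L)
  as.integer((as.numeric(seed) * 101 + offsets[[stage]]) %% 2147483647)
}

pipeline_stages <- function()
  c("simulate", "pangene", "pante", "ltr", "effects", "eqtl", "gwas", "haplo")

#' Run the pipeline end to end on synthetic data
#'
#' Executes the requested stages in dependency order (every stage after
#' `simulate` consumes its outputs), writes tab-separated outputs under
#' `config$outdir`, and records a manifest (config hash, per-stage seeds,
#' row counts, output checksums). Reruns with the same config are
#' bit-identical.
#'
#' @param config A [pipeline_config()] object.
#' @param stages Subset of stages to run (default all, in order).
#' @return Invisibly, a list with `state` (in-memory stage outputs) and
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = pipeline_stages()) {
  stages <- match.arg(stages, pipeline_stages(), several.ok = TRUE)
  stages <- pipeline_stages()[pipeline_stages() %in% stages]
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- config$simulate; th <- config$thresholds
  state <- list()
  manifest <- list(package = "tepan",
                   version = as.character(utils::packageVersion("tepan")),
                   seed = config$seed,
                   config_md5 = unname(config_hash(config)),
                   stages = list())
  outfile <- function(name) file.path(outdir, name)
  need_sim <- function(stage) {
    if (is.null(state$sim))
      stop("stage '", stage, "' requires outputs of stage 'simulate'",
           call. = FALSE)
  }
  count_note <- function(stage, counts, files = character()) {
    manifest$stages[[stage]] <<- list(
      seed = stage_seed(config$seed, stage),
      counts = as.list(counts),
      files = as.list(vapply(files, function(f)
        unname(tools::md5sum(f)), character(1))))
  }

  for (stage in stages) {
    seed <- stage_seed(config$seed, stage)
    if (stage == "simulate") {
      law <- if (sim$maf_dist == "uniform") maf_law("uniform") else maf_law()
      geno <- simulate_genotypes(sim$n_accessions, sim$n_tes,
                                 sim$fixed_fraction, law,
                                 sim$missing_rate, seed = seed)
      poly <- geno$truth$te_id[!geno$truth$fixed]
      eff_ids <- utils::head(poly, sim$n_effect_tes)
      expr <- simulate_expression(
        geno$complete,
        stats::setNames(rep(sim$effect_fold, length(eff_ids)), eff_ids),
        noise_cv = sim$noise_cv, stages = sim$expression_stages,
        seed = seed + 1L)
      qtl_ids <- utils::tail(poly, sim$n_qtl)
      phen <- simulate_phenotype(
        geno$genotypes,
        stats::setNames(rep(sim$qtl_beta, length(qtl_ids)), qtl_ids),
        heritability = sim$heritability, seed = seed + 2L)
      iv <- simulate_intervals(sim$n_genes, sim$n_tes %/% 2L, sim$n_svs,
                               c(chrA01 = sim$contig_length,
                                 chrC01 = sim$contig_length),
                               seed = seed + 3L)
      ltr <- simulate_ltr_pairs(rep(sim$ltr_ages, length.out = 40L),
                                r = th$r, seq_len = sim$ltr_seq_len,
                                seed = seed + 4L)
      set.seed(seed + 5L)
      presence <- matrix(stats::rbinom(sim$n_clusters * sim$n_genomes, 1L,
                                       stats::runif(sim$n_clusters, 0.2, 1)),
                         sim$n_clusters, sim$n_genomes,
                         dimnames = list(sprintf("cluster_%05d",
                                                 seq_len(sim$n_clusters)),
                                         sprintf("genome_%02d",
                                                 seq_len(sim$n_genomes))))
      presence[rowSums(presence) == 0, 1L] <- 1L
      state$sim <- list(geno = geno, expr = expr, phen = phen,
                        intervals = iv, ltr = ltr, presence = presence,
                        eff_ids = eff_ids, qtl_ids = qtl_ids)
      f <- c(outfile("genotypes.tsv"), outfile("phenotype.tsv"),
             outfile("te_annotations.bed"), outfile("genes.bed"))
      write_matrix_tsv(geno$genotypes, f[1L], "te_id")
      write_tsv_table(phen$phenotype, f[2L])
      write_bed(iv$tes, f[3L], "te_id")
      write_bed(iv$genes, f[4L], "gene_id")
      count_note(stage, c(tes = nrow(geno$genotypes),
                          accessions = ncol(geno$genotypes),
                          svs = nrow(iv$svs), ltr_elements = nrow(ltr)), f)
    } else if (stage == "pangene") {
      need_sim(stage)
      occ <- classify_occupancy(state$sim$presence)
      growth <- growth_curves(state$sim$presence,
                              n_subsets_per_size = th$growth_subsets,
                              n_repeats = th$growth_repeats, seed = seed)
      state$pangene <- list(occupancy = occ, growth = growth)
      f <- c(outfile("occupancy.tsv"), outfile("growth_curves.tsv"))
      write_tsv_table(occ$labels, f[1L])
      write_tsv_table(growth, f[2L])
      count_note(stage, c(clusters = nrow(occ$labels),
                          sizes = nrow(growth)), f)
    } else if (stage == "pante") {
      need_sim(stage)
      iv <- state$sim$intervals
      svg <- simulate_genotypes(config$simulate$n_accessions,
                                max(nrow(iv$svs), 1L),
                                fixed_fraction = 0.3,
                                missing_rate = config$simulate$missing_rate,
                                seed = seed)$genotypes
      rownames(svg) <- c(iv$svs$sv_id,
                         rownames(svg))[seq_len(nrow(svg))]
      pm <- build_pante_map(iv$tes, iv$sv_segments, svg,
                            min_overlap_frac = th$overlap_frac)
      filt <- filter_variants(pm$genotypes, max_missing = th$missing)
      cons <- if (nrow(pm$genotypes)) conservation_summary(pm$genotypes)
              else NULL
      state$pante <- list(map = pm, filtered = filt, conservation = cons)
      f <- outfile("pante_map.tsv")
      write_tsv_table(pm$loci, f)
      count_note(stage, c(links = nrow(pm$links), loci = nrow(pm$loci),
                          kept = nrow(filt)), f)
    } else if (stage == "ltr") {
      need_sim(stage)
      dated <- date_ltr_elements(state$sim$ltr, r = th$r)
      prof <- burst_profile(dated, bin_width = 2e5, group_by = "superfamily")
      state$ltr <- list(dated = dated, profile = prof)
      f <- outfile("ltr_ages.tsv")
      write_tsv_table(dated[, c("element_id", "superfamily", "subgenome",
                                "K", "age_years")], f)
      count_note(stage, c(elements = nrow(dated)), f)
    } else if (stage == "effects") {
      need_sim(stage)
      s <- state$sim
      calls <- lapply(names(s$expr$expression), function(st)
        classify_stage_effects(s$geno$genotypes, s$expr$expression[[st]],
                               s$expr$te_gene_map, fold = th$fold,
                               min_group = th$min_group,
                               epsilon = th$epsilon, stage = st))
      summ <- effect_summary(calls)
      state$effects <- list(calls = calls, summary = summ)
      f <- outfile("effect_calls.tsv")
      write_tsv_table(do.call(rbind, calls), f)
      count_note(stage, c(calls = sum(vapply(calls, nrow, integer(1))),
                          consistent_promotive =
                            length(summ$consistent_promotive)), f)
    } else if (stage == "eqtl") {
      need_sim(stage)
      s <- state$sim
      gm <- filter_variants(s$geno$genotypes, max_missing = th$missing,
                            min_maf = th$maf, max_het = th$het)
      em <- filter_expressed(s$expr$expression[[1L]],
                             min_tpm = th$tpm_min,
                             max_low_fraction = th$tpm_low_frac)
      pcs <- expression_pcs(log1p(em), n_pcs = th$n_pcs)
      ## synthetic anchors: TE i at i*50 kb, its target gene 1 kb away
      pos <- stats::setNames((seq_len(nrow(s$geno$genotypes))) * 5e4,
                             rownames(s$geno$genotypes))
      targets <- utils::head(intersect(paste0("gene_", s$eff_ids),
                                       rownames(em)), 5L)
      recs <- do.call(rbind, lapply(targets, function(gid) {
        sc <- association_scan(gm, em[gid, colnames(gm)], covariates = pcs)
        sc$target <- gid
        gpos <- pos[[sub("^gene_", "", gid)]] + 1000
        sc$cis <- classify_cis_trans(
          data.frame(contig = "chrA01", start = pos[sc$variant_id],
                     end = pos[sc$variant_id] + 1),
          data.frame(contig = "chrA01", start = rep(gpos, nrow(sc)),
                     end = rep(gpos + 2000, nrow(sc))),
          window = th$cis_window)
        sc
      }))
      cut <- significance_cutoff(nrow(gm))
      summ <- eqtl_summary(recs, cutoff = cut$p)
      state$eqtl <- list(records = recs, cutoff = cut, summary = summ)
      f <- outfile("eqtl_records.tsv")
      write_tsv_table(recs, f)
      count_note(stage, c(records = nrow(recs), n_cis = summ$n_cis,
                          n_trans = summ$n_trans), f)
    } else if (stage == "gwas") {
      need_sim(stage)
      s <- state$sim
      gm <- filter_variants(s$geno$genotypes, max_missing = th$missing,
                            min_maf = th$maf, max_het = th$het)
      trait <- names(s$phen$phenotype)[2L]
      y <- s$phen$phenotype[[trait]]
      recs <- association_scan(gm, y)
      recs$contig <- "chrA01"
      recs$pos <- match(recs$variant_id, rownames(s$geno$genotypes)) * 5e4
      cut <- significance_cutoff(nrow(gm))
      sig <- recs[!is.na(recs$p) & recs$p <= cut$p, , drop = FALSE]
      cl <- clump(recs, gm, p1 = th$clump_p1, window_kb = th$clump_kb,
                  r2_min = th$clump_r2)
      loci <- if (nrow(cl))
        merge_locus(data.frame(contig = cl$contig, start = cl$span_start,
                               end = cl$span_end + 1))
        else NULL
      state$gwas <- list(records = recs, cutoff = cut, significant = sig,
                         clumps = cl, loci = loci)
      f <- outfile("gwas_records.tsv")
      write_tsv_table(recs, f)
      count_note(stage, c(records = nrow(recs), significant = nrow(sig),
                          clumps = nrow(cl)), f)
    } else if (stage == "haplo") {
      need_sim(stage)
      s <- state$sim
      focal <- s$qtl_ids
      if (!length(focal)) stop("no focal QTL variants simulated", call. = FALSE)
      combos <- build_combos(s$geno$genotypes[focal, , drop = FALSE],
                             min_freq = th$haplo_min_freq)
      trait <- names(s$phen$phenotype)[2L]
      summ <- combo_summary(combos, s$phen$phenotype, trait)
      state$haplo <- list(combos = combos, summary = summ)
      f <- outfile("haplotype_combos.tsv")
      write_tsv_table(summ$per_combo, f)
      count_note(stage, c(combos = nrow(combos$combos),
                          classifiable = combos$n_classifiable,
                          excluded = combos$n_excluded), f)
    }
  }
  manifest_path <- outfile("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(state = state, manifest = manifest))
}

## md5 of the canonical JSON serialization of a config
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  tools::md5sum(tmp)
}
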