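test_that("association scan recovers planted effects and flags degenerate variants", {
  sim <- simulate_genotypes(500, 30, fixed_fraction = 0,
                            law = maf_law("uniform", min = 0.2, max = 0.5),
                            missing_rate = 0, seed = 81)
  qtl <- setNames(1.0, rownames(sim$genotypes)[1])
  ph <- simulate_phenotype(sim$genotypes, qtl, heritability = 0.5, seed = 82)
  res <- association_scan(sim$genotypes, ph$phenotype$flowering_time)
  top <- res[res$variant_id == names(qtl), ]
  expect_lt(abs(top$beta - 1), 2 * top$se)
  expect_lt(top$p, 1e-10)

  ## exact linear response: beta equals the slope, p at the floor
  y <- 3 * sim$genotypes[2, ] + 7
  res2 <- association_scan(sim$genotypes[2, , drop = FALSE], y)
  expect_equal(res2$beta, 3, tolerance = 1e-10)
  expect_lt(res2$p, 1e-200)

  ## zero-variance variant is flagged, not an error
  gm <- rbind(mono = rep(2L, 20), poly = rep(c(0L, 2L), 10))
  set.seed(83)
  res3 <- association_scan(gm, rnorm(20))
  expect_equal(res3$flag, c("zero_variance", "ok"))
  expect_true(is.na(res3$p[1]))

  ## missing-dosage path agrees with the complete path on shared accessions
  gmna <- sim$genotypes[1:5, , drop = FALSE]
  gmna[1, 1:3] <- NA
  resna <- association_scan(gmna, ph$phenotype$flowering_time)
  expect_equal(resna$n_used[1], 497)
  direct <- summary(lm(ph$phenotype$flowering_time ~ gmna[2, ]))$coefficients
  expect_equal(resna$beta[2], direct[2, 1], tolerance = 1e-10)
  expect_equal(resna$p[2], direct[2, 4], tolerance = 1e-8)
})

test_that("scan with covariates matches lm and the null is calibrated", {
  sim <- simulate_genotypes(200, 50, fixed_fraction = 0,
                            law = maf_law("uniform", min = 0.1, max = 0.5),
                            missing_rate = 0, seed = 84)
  set.seed(85)
  covar <- matrix(rnorm(200 * 3), 200, 3)
  y <- rnorm(200)
  res <- association_scan(sim$genotypes, y, covariates = covar)
  direct <- summary(lm(y ~ covar + sim$genotypes[7, ]))$coefficients
  expect_equal(res$beta[7], direct[5, 1], tolerance = 1e-10)
  expect_equal(res$se[7], direct[5, 2], tolerance = 1e-10)
  expect_equal(res$p[7], direct[5, 4], tolerance = 1e-8)
})

test_that("significance cutoff is -log10(1/n)", {
  expect_equal(significance_cutoff(10)$neg_log10, 1)
  expect_equal(significance_cutoff(148323)$neg_log10, log10(148323))
  expect_equal(significance_cutoff(148323)$neg_log10, 5.1712, tolerance = 1e-4)
  expect_equal(significance_cutoff(1)$neg_log10, 0)
  expect_error(significance_cutoff(0), "positive")
})

test_that("cis/trans classification uses an inclusive 1 Mb same-contig window", {
  gene <- data.frame(contig = "c1", start = 5e6, end = 5.01e6)
  expect_equal(classify_cis_trans(
    data.frame(contig = "c1", start = 5.002e6, end = 5.003e6), gene),
    "cis", ignore_attr = TRUE)                      # inside the gene
  expect_equal(classify_cis_trans(
    data.frame(contig = "c1", start = 4e6 - 1, end = 4e6), gene),
    "cis", ignore_attr = TRUE)                      # gap exactly 1 Mb
  expect_equal(classify_cis_trans(
    data.frame(contig = "c1", start = 4e6 - 2, end = 4e6 - 1), gene),
    "trans", ignore_attr = TRUE)                    # gap 1 Mb + 1
  expect_equal(classify_cis_trans(
    data.frame(contig = "c2", start = 5e6, end = 5.001e6), gene),
    "trans", ignore_attr = TRUE)                    # other contig
})

test_that("LD r2 is squared Pearson correlation over complete pairs", {
  a <- c(0, 1, 2, 2, 0, 1)
  expect_equal(ld_r2(a, a), 1)
  expect_equal(ld_r2(a, 2 - a), 1)      # perfect anticorrelation squares to 1
  set.seed(86)
  x <- rbinom(2000, 2, 0.3); y <- rbinom(2000, 2, 0.3)
  expect_lt(ld_r2(x, y), 0.01)
  expect_true(is.na(ld_r2(rep(1, 5), a[1:5])))
  b <- a; b[1:2] <- NA
  expect_equal(ld_r2(a, b), cor(a[3:6], b[3:6])^2)
})

test_that("greedy clumping matches an independent brute-force implementation", {
  for (seed in 1:25) {
    set.seed(seed + 1000)
    n <- 40
    gm <- matrix(rbinom(n * 60, 2, runif(n, 0.1, 0.5)), n, 60,
                 dimnames = list(sprintf("v%02d", 1:n), NULL))
    ## induce LD blocks by copying neighbours
    for (i in seq(2, n, by = 2)) if (runif(1) < 0.5) gm[i, ] <- gm[i - 1, ]
    records <- data.frame(variant_id = rownames(gm),
                          p = 10^-runif(n, 0, 8),
                          contig = sample(c("c1", "c2"), n, replace = TRUE),
                          pos = sample.int(3e5, n))
    got <- clump(records, gm)
    want <- oracle_clump(records, gm)
    expect_equal(length(got$members), length(want))
    got_sets <- lapply(strsplit(got$members, ","), sort)
    expect_equal(got_sets, want)
    ## partition: no variant in two clumps, all significant indexed
    all_members <- unlist(got_sets)
    expect_false(anyDuplicated(all_members) > 0)
  }

  ## trivial cases
  rec1 <- data.frame(variant_id = "v1", p = 1e-6, contig = "c1", pos = 100)
  gm1 <- matrix(c(0, 1, 2, 1), 1, dimnames = list("v1", NULL))
  cl1 <- clump(rec1, gm1)
  expect_equal(cl1$n_members, 1L)
  rec0 <- data.frame(variant_id = "v1", p = 0.5, contig = "c1", pos = 100)
  expect_equal(nrow(clump(rec0, gm1)), 0L)

  ## two perfectly linked significant variants 50 kb apart form one clump
  gm2 <- rbind(v1 = c(0, 1, 2, 1, 0), v2 = c(0, 1, 2, 1, 0))
  rec2 <- data.frame(variant_id = c("v1", "v2"), p = c(1e-8, 1e-6),
                     contig = "c1", pos = c(1e5, 1.5e5))
  expect_equal(clump(rec2, gm2)$n_members, 2L)
})

test_that("locus merging spans members and unions overlapping loci", {
  spans <- data.frame(contig = "c1",
                      start = c(10000, 90000), end = c(11000, 95000))
  m <- merge_locus(spans)
  expect_equal(nrow(m), 2L)
  expect_equal(m$start, c(10000, 90000))

  for (seed in 1:10) {
    set.seed(seed + 2000)
    sp <- data.frame(contig = sample(c("c1", "c2"), 30, replace = TRUE),
                     start = sample.int(1e5, 30))
    sp$end <- sp$start + sample(1000:20000, 30, replace = TRUE)
    got <- merge_locus(sp)
    want <- oracle_union(sp)
    got <- got[order(got$contig, got$start), ]
    expect_equal(unname(as.matrix(got[2:3])), unname(as.matrix(want[2:3])))
  }
})

test_that("eQTL summaries report the cis/trans split over significant records", {
  recs <- data.frame(variant_id = paste0("v", 1:4),
                     target = c("g1", "g1", "g2", "g2"),
                     p = c(1e-8, 1e-3, 1e-9, 1e-7),
                     cis = c(TRUE, FALSE, TRUE, FALSE))
  s <- eqtl_summary(recs, cutoff = 1e-5)
  expect_equal(s$n_cis, 2L)
  expect_equal(s$n_trans, 1L)
  expect_equal(s$cis_pct + s$trans_pct, 100)
  expect_equal(nrow(s$leads), 2L)
  expect_equal(s$leads$variant_id[s$leads$target == "g1"], "v1")
  expect_equal(eqtl_summary(recs[recs$cis, ], cutoff = NULL)$cis_pct, 100)
})
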