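test_that("SV typing follows the 50-bp REF/ALT length rules", {
  expect_equal(classify_sv_type(1, 120), "INS")
  expect_equal(classify_sv_type(300, 1), "DEL")
  expect_equal(classify_sv_type(10, 4), "small")
  expect_equal(classify_sv_type(80, 60), "MNP")
  expect_equal(classify_sv_type(49, 1), "small")   # below the SV bound
  expect_equal(classify_sv_type(50, 1), "DEL")     # boundary inclusive
  expect_equal(classify_sv_type(c(1, 300, 10, 80), c(120, 1, 4, 60)),
               c("INS", "DEL", "small", "MNP"))
  expect_error(classify_sv_type(0, 10), "lengths")
})

test_that("TE-SV association uses strict majority coverage of the TE", {
  tes <- data.frame(te_id = c("t1", "t2"), genome_id = "g",
                    contig = "c", start = c(100, 100), end = c(200, 200))
  segs <- data.frame(sv_id = c("s1", "s2"), genome_id = "g", contig = "c",
                     start = c(140, 150), end = c(260, 400), allele = "ALT")
  links <- associate_te_to_sv(tes, segs)
  ## 60% overlap links; exactly 50% does not (strict >)
  expect_true(any(links$te_id == "t1" & links$sv_id == "s1"))
  expect_false(any(links$sv_id == "s2"))
})

test_that("association and link recovery match the brute-force oracle and are shift-invariant", {
  inst <- random_te_sv_instance(99)
  links <- associate_te_to_sv(inst$tes, inst$segs)
  oracle <- oracle_links(inst$tes, inst$segs)
  expect_equal(links$te_id, oracle$te_id)
  expect_equal(links$sv_id, oracle$sv_id)
  expect_equal(links$carrier, oracle$carrier)

  shifted <- inst
  shifted$tes$start <- shifted$tes$start + 1234
  shifted$tes$end <- shifted$tes$end + 1234
  shifted$segs$start <- shifted$segs$start + 1234
  shifted$segs$end <- shifted$segs$end + 1234
  links2 <- associate_te_to_sv(shifted$tes, shifted$segs)
  expect_identical(links[c("te_id", "sv_id", "carrier")],
                   links2[c("te_id", "sv_id", "carrier")])

  ## on the constructive generator, recovered links equal the truth exactly
  iv <- simulate_intervals(20, 60, 15, seed = 77)
  rec <- associate_te_to_sv(iv$tes, iv$sv_segments)
  expect_identical(sort(paste(rec$te_id, rec$sv_id)),
                   sort(paste(iv$truth_links$te_id, iv$truth_links$sv_id)))
})

test_that("genotype merging takes the minimum carrier dosage and is NA-dominant", {
  svg <- matrix(c(2L, 1L, 0L,
                  1L, 2L, NA), 2, 3, byrow = TRUE,
                dimnames = list(c("s1", "s2"), c("a1", "a2", "a3")))
  links1 <- data.frame(sv_id = "s1", carrier = "ALT")
  expect_identical(merge_genotypes(links1, svg), c(2L, 1L, 0L))

  links2 <- data.frame(sv_id = c("s1", "s2"), carrier = c("ALT", "ALT"))
  expect_identical(merge_genotypes(links2, svg), c(1L, 1L, NA))

  ## REF carrier flips the dosage
  links3 <- data.frame(sv_id = "s2", carrier = "REF")
  expect_identical(merge_genotypes(links3, svg), c(1L, 0L, NA))

  ## idempotent under duplicated links, order-invariant
  links_dup <- rbind(links2, links2[1, ])
  expect_identical(merge_genotypes(links_dup, svg),
                   merge_genotypes(links2, svg))
  expect_identical(merge_genotypes(links2[2:1, ], svg),
                   merge_genotypes(links2, svg))

  ## any-presence alternative takes the maximum
  expect_identical(merge_genotypes(links2, svg, rule = "max"),
                   c(2L, 2L, NA))
  expect_error(merge_genotypes(links2[0, ], svg), "empty link")
})

test_that("variant filtering applies missingness, MAF and heterozygosity rules", {
  gm <- rbind(
    miss60 = c(NA, NA, NA, 0L, 2L),       # 60% missing -> dropped
    lowmaf = c(0L, 0L, 0L, 0L, 1L),       # MAF 0.1 > 0.05 kept; 0.04 analog below
    rare   = c(0L, 0L, 0L, 0L, 0L),       # MAF 0 -> dropped by MAF rule
    hethi  = c(1L, 1L, 1L, 1L, 0L),       # 80% het -> dropped by het rule
    good   = c(0L, 1L, 2L, 2L, 0L))
  colnames(gm) <- paste0("a", 1:5)
  out <- filter_variants(gm, max_missing = 0.5, min_maf = 0.05,
                         max_het = 0.5)
  expect_identical(rownames(out), c("lowmaf", "good"))
  expect_equal(as.vector(attr(out, "removed")), c(1L, 1L, 1L))

  ## disabled thresholds are the identity; values never altered
  id <- filter_variants(gm, max_missing = NULL)
  expect_identical(unname(id[seq_len(nrow(gm)), ]), unname(gm))

  ## variant with MAF exactly at the threshold is removed (strict >)
  gm2 <- rbind(at = c(rep(0L, 19), 2L))   # MAF 0.05
  colnames(gm2) <- paste0("a", 1:20)
  expect_equal(nrow(filter_variants(gm2, min_maf = 0.05)), 0L)
  expect_error(filter_variants(gm[0, , drop = FALSE]), "empty")
})

test_that("pan-TE map building and conservation summary recover generator truth", {
  iv <- simulate_intervals(10, 40, 10, seed = 13)
  svg <- simulate_genotypes(80, 10, fixed_fraction = 0.4, missing_rate = 0,
                            seed = 14)$genotypes
  rownames(svg) <- iv$svs$sv_id
  pm <- build_pante_map(iv$tes, iv$sv_segments, svg)
  expect_setequal(pm$loci$te_id, unique(iv$truth_links$te_id))
  ## single-link TEs inherit the SV's ALT dosage unchanged
  single <- pm$loci$te_id[pm$loci$n_svs == 1][1]
  sv <- pm$links$sv_id[pm$links$te_id == single]
  expect_identical(unname(pm$genotypes[single, ]), unname(svg[sv, ]))
  expect_true(all(pm$loci$maf <= 0.5 & pm$loci$maf >= 0, na.rm = TRUE))

  ## conservation summary on a synthetic set with known fixed fraction
  sim <- simulate_genotypes(400, 1000, fixed_fraction = 0.85,
                            law = maf_law("uniform", min = 0.05, max = 0.5),
                            seed = 15)
  cs <- conservation_summary(sim$genotypes)
  expect_equal(cs$fixed_fraction + cs$polymorphic_fraction, 1)
  expect_lt(abs(cs$fixed_fraction - 0.85), 0.02)

  ## trivial cases
  allfix <- matrix(2L, 5, 4)
  expect_equal(conservation_summary(allfix)$fixed_fraction, 1)
  half <- matrix(c(0L, 0L, 2L, 2L), 1)
  expect_equal(tepan:::compute_maf(half[1, ]), 0.5)
})
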