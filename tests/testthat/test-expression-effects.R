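test_that("expression filter drops genes below detection in too many samples", {
  em <- rbind(
    dead  = c(rep(0.001, 17), rep(5, 3)),    # low in 85% -> removed
    alive = rep(0.5, 20),                    # detected everywhere -> kept
    edge  = c(rep(0.001, 16), rep(5, 4)))    # low in exactly 80% -> kept
  colnames(em) <- paste0("a", 1:20)
  out <- filter_expressed(em)
  expect_identical(rownames(out), c("alive", "edge"))
  expect_equal(attr(out, "removed"), 1L)

  ## brute-force recount on a random matrix
  set.seed(8)
  m <- matrix(rexp(200 * 30, 10), 200, 30,
              dimnames = list(paste0("g", 1:200), paste0("a", 1:30)))
  kept <- filter_expressed(m, min_tpm = 0.05, max_low_fraction = 0.4)
  manual <- rownames(m)[vapply(seq_len(nrow(m)), function(i)
    sum(m[i, ] < 0.05) / 30 <= 0.4, logical(1))]
  expect_identical(rownames(kept), manual)
  expect_error(filter_expressed(m[0, , drop = FALSE]), "empty")
})

test_that("TMM factors match a from-scratch evaluation of the trim/weight formulas", {
  ## identical columns -> unit factors
  c0 <- matrix(rep(c(5, 10, 20, 40, 80), 3), 5, 3)
  expect_equal(unname(tmm_factors(c0)), rep(1, 3))

  ## pure depth difference -> unit factors (TMM is depth-invariant)
  c1 <- cbind(a = c(5, 10, 20, 40, 80), b = 2 * c(5, 10, 20, 40, 80))
  expect_equal(unname(tmm_factors(c1)), rep(1, 2), tolerance = 1e-12)

  ## random counts vs the independent oracle
  set.seed(9)
  cx <- matrix(rpois(50 * 4, lambda = rep(c(5, 50, 200), length.out = 50)),
               50, 4, dimnames = list(NULL, paste0("s", 1:4)))
  expect_equal(unname(tmm_factors(cx)), oracle_tmm(cx), tolerance = 1e-8)
  expect_error(tmm_factors(cbind(a = c(1, 2), b = c(0, 0))), "all-zero")

  ## normalization applies factors columnwise
  norm <- apply_norm_factors(cx, tmm_factors(cx))
  expect_equal(norm[, 1], cx[, 1] / tmm_factors(cx)[1])
})

test_that("nearest-gene assignment matches the all-pairs oracle with deterministic ties", {
  set.seed(10)
  n <- 300
  genes <- data.frame(gene_id = sprintf("g%03d", 1:60),
                      contig = sample(c("c1", "c2"), 60, replace = TRUE),
                      start = sample.int(1e5, 60))
  genes$end <- genes$start + sample(500:3000, 60, replace = TRUE)
  genes$strand <- sample(c("+", "-"), 60, replace = TRUE)
  tes <- data.frame(te_id = sprintf("t%03d", 1:n),
                    contig = sample(c("c1", "c2"), n, replace = TRUE),
                    start = sample.int(1e5, n))
  tes$end <- tes$start + sample(50:400, n, replace = TRUE)
  res <- nearest_gene(tes, genes)
  oracle <- oracle_nearest(tes, genes)
  expect_identical(res$gene_id, oracle$gene_id)

  ## TE inside a gene -> distance 0
  inside <- nearest_gene(data.frame(te_id = "t", contig = "c1",
                                    start = genes$start[1] + 10,
                                    end = genes$start[1] + 60),
                         genes[1, , drop = FALSE])
  expect_equal(inside$distance, 0)

  ## TE on a contig with no genes -> unassigned
  lonely <- nearest_gene(data.frame(te_id = "t", contig = "c9",
                                    start = 1, end = 100), genes)
  expect_true(is.na(lonely$gene_id))
})

test_that("effect classification applies the inclusive 1.5-fold rule", {
  d <- rep(c(2, 0), each = 10)
  ## means 3 vs 2: ratio (3.01)/(2.01) < 1.5 with the offset, so use
  ## epsilon = 0 to probe the inclusive boundary itself
  r <- classify_te_effect(d, rep(c(3, 2), each = 10), epsilon = 0)
  expect_equal(r$ratio, 1.5)
  expect_equal(r$effect, "promotive")

  expect_equal(classify_te_effect(d, rep(c(2, 2), each = 10))$effect, "none")

  r2 <- classify_te_effect(d, rep(c(1, 1.6), each = 10), epsilon = 0)
  expect_equal(r2$ratio, 0.625)
  expect_equal(r2$effect, "suppressive")    # 0.625 < 2/3

  ## group-size floor and constant genotype
  expect_equal(classify_te_effect(c(2, 2, 0, 0), c(1, 1, 9, 9))$effect,
               "unevaluable")
  expect_equal(classify_te_effect(rep(2, 20), rnorm(20, 5))$effect,
               "unevaluable")

  ## scale invariance: multiplying expression by c > 0 keeps the class
  set.seed(11)
  e <- rlnorm(20, 1)
  for (cc in c(0.1, 10)) {
    a <- classify_te_effect(d, e, epsilon = 0.01)
    b <- classify_te_effect(d, e * cc, epsilon = 0.01 * cc)
    expect_identical(a$effect, b$effect)
  }
})

test_that("planted promotive TEs are recovered with high sensitivity and few false calls", {
  sim <- simulate_genotypes(300, 200, fixed_fraction = 0,
                            law = maf_law("uniform", min = 0.2999,
                                          max = 0.3001),
                            missing_rate = 0, seed = 71)
  planted <- setNames(rep(2.0, 100), rownames(sim$genotypes)[1:100])
  ex <- simulate_expression(sim$genotypes, planted, noise_cv = 0.2,
                            stages = 1, seed = 72)
  calls <- classify_stage_effects(sim$genotypes, ex$expression$stage_1,
                                  ex$te_gene_map)
  planted_calls <- calls$effect[calls$te_id %in% names(planted)]
  null_calls <- calls$effect[!calls$te_id %in% names(planted)]
  expect_gte(mean(planted_calls == "promotive"), 0.95)
  expect_lte(mean(null_calls == "promotive"), 0.05)
})

test_that("effect summaries reproduce the promotive percentage convention and stage consistency", {
  calls1 <- data.frame(te_id = paste0("t", 1:6),
                       effect = c("promotive", "promotive", "suppressive",
                                  "none", "unevaluable", "promotive"),
                       stage = "s1")
  calls2 <- data.frame(te_id = paste0("t", 1:6),
                       effect = c("promotive", "suppressive", "suppressive",
                                  "none", "promotive", "promotive"),
                       stage = "s2")
  s <- effect_summary(list(calls1, calls2))
  expect_equal(s$per_stage$promotive_pct[s$per_stage$stage == "s1"],
               100 * 3 / 4)
  expect_equal(s$per_stage$promotive_pct +
                 s$per_stage$suppressive_pct, c(100, 100))
  expect_setequal(s$consistent_promotive, c("t1", "t6"))
  expect_setequal(s$consistent_suppressive, "t3")

  ## single stage: consistency sets equal that stage's class sets
  s1 <- effect_summary(calls1)
  expect_setequal(s1$consistent_promotive, c("t1", "t2", "t6"))
})
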