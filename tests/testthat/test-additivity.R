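test_that("the Venn partition reproduces the study's printed marginal arithmetic", {
  s <- marginal_sets()
  vp <- partition_sets(s$A, s$B, s$AB)
  expect_equal(vp$counts[["commonAB"]], 800)
  expect_equal(vp$counts[["A_unshared"]], 2329)
  expect_equal(vp$counts[["B_unshared"]], 994)
  expect_equal(vp$counts[["AB_only"]], 1309)
  expect_equal(vp$counts[["combo_overlap"]], 2987)
  expect_equal(unname(vp$percents["A_unshared_pct"]), 74)
  expect_equal(unname(vp$percents["B_unshared_pct"]), 55)
  expect_equal(unname(vp$percents["combo_overlap_pct"]), 70)
  # structural identities on the same partition
  expect_equal(vp$counts[["commonAB"]],
               vp$counts[["A_B_AB"]] + vp$counts[["A_B_not_AB"]])
  expect_equal(vp$counts[["combo_overlap"]] + vp$counts[["AB_only"]],
               vp$counts[["AB"]])
})

test_that("Venn regions are disjoint and exhaustive on random and degenerate sets", {
  set.seed(55)
  universe <- sprintf("g%03d", 1:120)
  for (i in 1:20) {
    A <- sample(universe, rbinom(1, 120, 0.3))
    B <- sample(universe, rbinom(1, 120, 0.3))
    AB <- sample(universe, rbinom(1, 120, 0.4))
    vp <- partition_sets(A, B, AB)
    all_regions <- unlist(vp$regions, use.names = FALSE)
    expect_equal(sort(all_regions), sort(union(union(A, B), AB)))
    expect_equal(length(all_regions), length(unique(all_regions)))
  }
  vp <- partition_sets(c("a", "b"), c("c"), c("d", "e"))
  expect_true(all(lengths(vp$regions[4:7]) == 0))
  vp2 <- partition_sets(c("x", "y"), c("x", "y"), c("x", "y"))
  expect_equal(sort(vp2$regions$A_B_AB), c("x", "y"))
  expect_true(all(lengths(vp2$regions[1:6]) == 0))
})

test_that("concordance classes partition the common targets with the study's rounding", {
  common <- c("up_up", "dn_dn", "up_dn", "dn_up")
  lfcA <- c(up_up = 1, dn_dn = -1, up_dn = 1, dn_up = -0.5)
  lfcB <- c(up_up = 2, dn_dn = -0.3, up_dn = -1, dn_up = 2)
  cc <- classify_concordance(common, lfcA, lfcB)
  expect_identical(cc$classes$both_up, "up_up")
  expect_identical(cc$classes$both_down, "dn_dn")
  expect_identical(cc$classes$A_up_B_down, "up_dn")
  expect_identical(cc$classes$A_down_B_up, "dn_up")
  expect_equal(sum(cc$counts), cc$n_common)

  # printed class sizes 219/217/228/136 over 800 genes give the 55/45 split
  # (436/800 = 54.5 rounds half-up to 55; discordant is the complement)
  ids <- sprintf("c%03d", 1:800)
  sgnA <- rep(c(1, -1, 1, -1), c(219, 217, 228, 136))
  sgnB <- rep(c(1, -1, -1, 1), c(219, 217, 228, 136))
  cc8 <- classify_concordance(ids, setNames(sgnA * 0.8, ids),
                              setNames(sgnB * 1.2, ids))
  expect_equal(unname(cc8$counts), c(219, 217, 228, 136))
  expect_equal(cc8$concordant_pct, 55)
  expect_equal(cc8$discordant_pct, 45)
  expect_equal(cc8$concordant_pct + cc8$discordant_pct, 100)

  expect_error(classify_concordance("g", c(g = 0), c(g = 1)), "exactly 0")
  expect_error(classify_concordance("g", c(g = 1), c(x = 1)), "both treatments")
})

test_that("the expected additive effect is the sum of the single-treatment effects", {
  expect_equal(expected_additive_lfc(0, 1.7), 1.7)
  expect_equal(expected_additive_lfc(2.3, -2.3), 0)
  expect_equal(expected_additive_lfc(1.5, -0.5), 1)
  expect_equal(expected_additive_lfc(c(1, 2), c(3, 4)), c(4, 6))
  expect_error(expected_additive_lfc(NaN, 1), "finite")
})

test_that("additivity regression handles exact and invariance cases", {
  ids <- sprintf("g%02d", 1:20)
  x <- setNames(seq(-2, 2, length.out = 20), ids)
  # exact fits trigger stats's "essentially perfect fit" warning; irrelevant here
  fit1 <- suppressWarnings(fit_additivity(x, x, ids, "identity"))
  expect_equal(fit1$slope, 1, tolerance = 1e-12)
  expect_equal(fit1$intercept, 0, tolerance = 1e-12)
  expect_equal(fit1$r_squared, 1, tolerance = 1e-12)

  fit2 <- suppressWarnings(fit_additivity(0.5 * x, x, ids))
  expect_equal(fit2$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit2$r_squared, 1, tolerance = 1e-12)

  set.seed(99)
  y <- x + rnorm(20, 0, 0.3)
  f_all <- fit_additivity(y, x, ids)
  expect_equal(f_all$r_squared, f_all$pearson_r^2, tolerance = 1e-12)
  shuffled <- sample(ids)
  f_shuf <- fit_additivity(y[shuffled], x[shuffled], shuffled)
  expect_equal(f_all$slope, f_shuf$slope)
  expect_equal(f_all$r_squared, f_shuf$r_squared)

  expect_error(fit_additivity(y, x, ids[1:2]), "at least 3")
  expect_error(fit_additivity(y, setNames(rep(1, 20), ids), ids), "zero variance")
})

test_that("attenuation flags significant opposite-sign combination shifts", {
  empty <- attenuation(character(), structure(data.frame(gene_id = character(),
                                                         log2fc = numeric(),
                                                         pvalue = numeric(),
                                                         padj = numeric()),
                                              class = c("contrast_result", "data.frame")),
                       structure(data.frame(gene_id = character(),
                                            log2fc = numeric(),
                                            pvalue = numeric(),
                                            padj = numeric()),
                                 class = c("contrast_result", "data.frame")))
  expect_equal(empty$n_candidates, 0)
  expect_true(is.na(empty$fraction))

  # constructed contrast pair realising 410 attenuated of 1794 candidates
  ids <- sprintf("w%04d", 1:1794)
  rB <- data.frame(gene_id = ids, log2fc = 1.5, pvalue = 1e-6, padj = 1e-5)
  rCB <- data.frame(gene_id = ids,
                    log2fc = rep(c(-1, -0.1), c(410, 1384)),
                    pvalue = rep(c(1e-8, 0.9), c(410, 1384)),
                    padj = NA_real_)
  att <- attenuation(ids, rB, rCB, alpha = 0.05)
  expect_equal(att$n_candidates, 1794)
  expect_equal(att$n_attenuated, 410)
  expect_equal(att$percent, 23)

  # a candidate without a COMBO-vs-B p-value is excluded, with a message
  rCB$pvalue[1] <- NA
  expect_message(att2 <- attenuation(ids, rB, rCB), "excluded")
  expect_equal(att2$n_excluded, 1)
  expect_equal(att2$n_candidates, 1793)
})

test_that("observed-vs-expected slope and intercept recover additivity across seeds", {
  passes <- 0L
  for (s in 1:20) {
    p <- simulation_params(n_genes = 1200, seed = 500 + s)
    sim <- simulate_counts(generate_truth(p), p)
    de <- quick_de(sim)
    rA <- wald_with(sim, de, c("TRT_A", "VEHICLE"))
    rB <- wald_with(sim, de, c("TRT_B", "VEHICLE"))
    rAB <- wald_with(sim, de, c("COMBO", "VEHICLE"))
    un <- union(select_de(rA)$genes, select_de(rB)$genes)
    expected <- expected_additive_lfc(setNames(rA$log2fc, rA$gene_id),
                                      setNames(rB$log2fc, rB$gene_id))
    fit <- fit_additivity(setNames(rAB$log2fc, rAB$gene_id), expected, un,
                          "union_singles")
    if (fit$slope >= 0.9 && fit$slope <= 1.1 &&
        fit$intercept >= -0.1 && fit$intercept <= 0.1) passes <- passes + 1L
  }
  expect_gte(passes, 18)
})

test_that("growing interaction mass strictly degrades the additivity r-squared", {
  r2 <- vapply(c(0, 0.5, 1), function(gsd) {
    p <- simulation_params(n_genes = 2000, gamma_sd = gsd, seed = 321)
    sim <- simulate_counts(generate_truth(p), p)
    de <- quick_de(sim)
    rA <- wald_with(sim, de, c("TRT_A", "VEHICLE"))
    rB <- wald_with(sim, de, c("TRT_B", "VEHICLE"))
    rAB <- wald_with(sim, de, c("COMBO", "VEHICLE"))
    un <- union(select_de(rA)$genes, select_de(rB)$genes)
    expected <- expected_additive_lfc(setNames(rA$log2fc, rA$gene_id),
                                      setNames(rB$log2fc, rB$gene_id))
    fit_additivity(setNames(rAB$log2fc, rAB$gene_id), expected, un)$r_squared
  }, numeric(1))
  expect_true(all(diff(r2) < 0))
})
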