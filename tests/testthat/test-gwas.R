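test_that("Bonferroni thresholds divide alpha by the test count", {
  expect_equal(bonferroni_threshold(111908), 0.05 / 111908)
  expect_lt(abs(bonferroni_threshold(111908) - 4.468e-7), 5e-10)
  expect_equal(bonferroni_threshold(c(10, 100)), c(0.005, 5e-4))
  expect_error(bonferroni_threshold(0), ">= 1")
})

test_that("genomic inflation is the median chi-square ratio", {
  expect_equal(suppressWarnings(
    genomic_inflation(chisq = c(0.1, 0.3, 0.4549, 1, 2))), 1,
    tolerance = 1e-4)
  set.seed(201)
  p <- runif(20000)
  expect_equal(genomic_inflation(p = p), 1, tolerance = 0.05)
  expect_gt(genomic_inflation(p = runif(20000)^2), 1.2)
  expect_warning(genomic_inflation(p = runif(10)), "100")
})

test_that("score statistics vanish when the projected phenotype is null", {
  ## y lies exactly in the column space of X -> P y = 0 -> T = 0, p = 1
  pop <- sim_population(small_config(seed = 22))
  A <- a_matrix(pop$pedigree)
  ids <- pop$phenotypes$id
  X <- cbind(1, as.numeric(pop$phenotypes$sex == "M"))
  colnames(X) <- c("(Intercept)", "sexM")
  y <- drop(X %*% c(2, 1))
  fit <- fake_fit(y, X, A[ids, ids])
  fit$kinship <- A
  fit$ids <- ids
  names(fit$y) <- ids
  scan <- grammar_scan(fit, pop$genotypes)
  tested <- !is.na(scan$stat)
  expect_true(all(abs(scan$stat[tested]) < 1e-16))
  expect_true(all(scan$p[tested] > 1 - 1e-6))
})

test_that("the scan is invariant to adding a constant to the phenotype", {
  pop <- sim_population(small_config(seed = 23))
  G <- g_matrix_vanraden(pop$genotypes)
  fit <- reml_animal(weight ~ sex, pop$phenotypes, G)
  fit2 <- fit
  fit2$y <- fit$y + 100
  s1 <- grammar_scan(fit, pop$genotypes)
  s2 <- grammar_scan(fit2, pop$genotypes)
  expect_equal(s1$stat, s2$stat, tolerance = 1e-8)
  ## p-values live in (0, 1]
  expect_true(all(s1$p[!is.na(s1$p)] > 0 & s1$p[!is.na(s1$p)] <= 1))
  ## per-chromosome thresholds use per-chromosome counts
  thr <- attr(s1, "threshold_chromosome")
  expect_equal(thr$threshold, 0.05 / thr$n)
})

test_that("a large QTL is found at or adjacent to its locus", {
  hits <- 0L
  for (r in 1:5) {
    pop <- sim_population(small_config(n_sires = 10, n_dams = 20,
                                       n_families = 20, n_offspring = 300,
                                       n_snps = 1000, n_causal = 200,
                                       qtl_frac = 0.2, seed = 500 + r))
    G <- g_matrix_vanraden(pop$genotypes)
    fit <- reml_animal(weight ~ sex, pop$phenotypes, G)
    scan <- grammar_scan(fit, pop$genotypes)
    qtl <- attr(pop$causal, "qtl")
    top <- which.min(scan$p)
    qi <- match(qtl, scan$snp)
    same_chr <- scan$chr[top] == scan$chr[qi]
    if (abs(top - qi) <= 1 && same_chr) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("SNP effects reproduce the class-mean definitions exactly", {
  ## noiseless phenotype determined by genotype class: GLS recovers the
  ## class means exactly whatever V is
  n <- 30
  d <- rep(c(0, 1, 2), each = 10)
  ids <- sprintf("i%02d", 1:n)
  K <- diag(n); dimnames(K) <- list(ids, ids)
  means <- c(`0` = 10, `1` = 8, `2` = 2)
  y <- means[as.character(d)]
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- fake_fit(unname(y), X, K)
  D <- matrix(as.integer(d), n, 1, dimnames = list(ids, "q1"))
  g <- new_genotypes(D, data.frame(snp = "q1", chr = 1L, pos = 1))
  eff <- snp_effect_fit(fit, g, "q1", V_A = 100)
  expect_equal(eff$alpha, (10 - 2) / 2, tolerance = 1e-8)   # alpha = 4
  expect_equal(eff$delta, 8 - (10 + 2) / 2, tolerance = 1e-8) # delta = 3
  expect_equal(eff$q_minor, 0.5)
  ## additive SNP: |alpha| equals the regression slope on dosage
  y2 <- 5 + 1.7 * d
  fit2 <- fake_fit(y2, X, K)
  eff2 <- snp_effect_fit(fit2, g, "q1", V_A = 100)
  expect_equal(abs(eff2$alpha), unname(coef(lm(y2 ~ d))[2]),
               tolerance = 1e-6)
  expect_equal(eff2$delta, 0, tolerance = 1e-8)
  ## two observed classes: dominance undefined and dropped from PVE
  D3 <- matrix(c(rep(0L, 15), rep(2L, 15)), n, 1,
               dimnames = list(ids, "q1"))
  g3 <- new_genotypes(D3, data.frame(snp = "q1", chr = 1L, pos = 1))
  eff3 <- snp_effect_fit(fit2, g3, "q1", V_A = 100)
  expect_true(is.na(eff3$delta))
  expect_equal(eff3$pve, 2 * 0.5 * 0.5 * eff3$alpha^2 / 100)
  ## single class errors
  D4 <- matrix(1L, n, 1, dimnames = list(ids, "q1"))
  g4 <- new_genotypes(D4, data.frame(snp = "q1", chr = 1L, pos = 1))
  expect_error(snp_effect_fit(fit2, g4, "q1"), "single")
})

test_that("PVE evaluates the quadratic form and its reductions", {
  ## worked numbers: p=0.57, q=0.43, alpha=4.42, delta=1.27, V_A=132.2
  num <- 2 * 0.57 * 0.43 * (4.42 + 1.27 * (0.43 - 0.57))^2
  expect_equal(signif(num, 3), 8.82)
  expect_equal(pve(0.57, 0.43, 4.42, 1.27, V_A = 132.2), num / 132.2,
               tolerance = 1e-12)
  expect_equal(pve(0.5, 0.5, 0, 0, V_A = 10), 0)
  expect_equal(pve(1, 0, 3, 1, V_A = 10), 0)
  ## delta = 0 reduces to 2 p q alpha^2 / V_A exactly
  expect_identical(pve(0.7, 0.3, 2, 0, V_A = 5),
                   2 * 0.7 * 0.3 * 4 / 5)
  expect_identical(pve(0.7, 0.3, 2, NULL, V_A = 5),
                   2 * 0.7 * 0.3 * 4 / 5)
  expect_error(pve(0.7, 0.3, 2, 0, V_A = 0), "positive")
  expect_error(pve(0.7, 0.4, 2, 0, V_A = 1), "equal 1")
})
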