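make_geno <- function(D) {
  colnames(D) <- sprintf("s%d", seq_len(ncol(D)))
  new_genotypes(D, data.frame(snp = colnames(D), chr = 1L,
                              pos = seq_len(ncol(D)) * 100))
}

trio_ped <- data.frame(id = c("pa", "ma", "kid"),
                       sire = c(NA, NA, "pa"), dam = c(NA, NA, "ma"))

test_that("impossible transmissions are counted, possible ones are not", {
  ## SNP1: parents 0/0, offspring 2 -> error; SNP2: parents 0/2,
  ## offspring 1 -> fine; SNP3: parents 1/1 -> uninformative
  D <- rbind(pa = c(0L, 0L, 1L), ma = c(0L, 2L, 1L), kid = c(2L, 1L, 0L))
  mer <- mendelian_error_rate(make_geno(D), trio_ped)
  expect_equal(unname(mer$per_snp), c(1, 0, NA))
  expect_equal(unname(mer$snp_tests), c(1, 1, 0))
  expect_equal(unname(mer$per_individual["kid"]), 0.5)
  expect_true(is.na(mer$per_individual["pa"]))

  ## missing genotypes are skipped
  D2 <- rbind(pa = c(NA, 0L), ma = c(0L, 0L), kid = c(2L, 0L))
  mer2 <- mendelian_error_rate(make_geno(D2), trio_ped)
  expect_equal(unname(mer2$snp_tests), c(0, 1))

  expect_warning(
    mendelian_error_rate(make_geno(D),
                         data.frame(id = c("pa", "ma", "kid"),
                                    sire = NA, dam = NA)),
    "no offspring")
})

test_that("simulated data are Mendelian-clean and pass the filters", {
  pop <- sim_population(small_config(seed = 14))
  mer <- mendelian_error_rate(pop$genotypes, pop$pedigree)
  expect_equal(max(mer$per_snp[mer$snp_tests > 0]), 0)
  fp <- filter_panel(pop$genotypes, pop$pedigree, maf_min = 0)
  expect_equal(sum(fp$report$snps$removed), 0)
  expect_equal(sum(fp$report$samples$removed), 0)
})

test_that("the MAF filter is strict at the threshold", {
  ## 50 individuals; SNP freqs 0.04, 0.05, 0.30 by construction
  n <- 50
  D <- cbind(c(rep(1L, 4), rep(0L, 46)),
             c(rep(1L, 5), rep(0L, 45)),
             c(rep(1L, 30), rep(0L, 20)))
  rownames(D) <- sprintf("i%02d", 1:n)
  g <- make_geno(D)
  ped <- data.frame(id = rownames(D), sire = NA, dam = NA)
  fp <- suppressWarnings(filter_panel(g, ped, maf_min = 0.05))
  expect_setequal(fp$genotypes$map$snp, c("s2", "s3"))  # 0.04 out, 0.05 kept
})

test_that("a corrupted sample is removed before SNP-level filtering", {
  pop <- sim_population(small_config(seed = 15))
  g <- pop$genotypes
  victim <- pop$phenotypes$id[1]
  ## violate ~10% of the victim's loci at SNPs where both parents are
  ## homozygous identical (offspring must match them)
  ped <- pop$pedigree
  s <- ped$sire[match(victim, ped$id)]; d <- ped$dam[match(victim, ped$id)]
  hom <- which(g$dosage[s, ] == 0L & g$dosage[d, ] == 0L)
  bad <- hom[seq_len(ceiling(ncol(g$dosage) * 0.1))]
  g$dosage[victim, bad] <- 2L
  fp <- filter_panel(g, ped)
  expect_false(victim %in% rownames(fp$genotypes$dosage))
  expect_equal(fp$report$samples$removed[1], 1)
  ## report reconciles: removals + survivors = input
  expect_equal(fp$report$samples$removed[1] + fp$report$samples$remaining[1],
               fp$report$input[1])
})

test_that("ld_r2 matches the direct Pearson oracle", {
  expect_equal(ld_r2(c(0, 0, 1, 2), c(0, 0, 1, 2)), 1)
  expect_equal(ld_r2(c(0, 0, 1, 2), c(0, 1, 1, 2)), 8 / 11,
               tolerance = 1e-12)
  set.seed(1)
  a <- rep(0:2, length.out = 300)
  b <- sample(a)
  expect_lt(ld_r2(a, b), 0.05)
  expect_warning(r <- ld_r2(c(0, 0, 0), c(0, 1, 2)), "monomorphic")
  expect_true(is.na(r))
  expect_warning(ld_r2(c(0, NA), c(NA, 1)), "fewer than two")
})

test_that("density reduction applies its four steps in order", {
  n <- 40
  set.seed(2)
  base <- sample(0:2, n, replace = TRUE, prob = c(.25, .5, .25))
  near <- base; flip <- sample(n, 3); near[flip] <- sample(0:2, 3, TRUE)
  lowmaf <- c(rep(1L, 6), rep(0L, n - 6))          # MAF 0.075 < 0.1
  gappy <- sample(0:2, n, TRUE, prob = c(.25, .5, .25))
  gappy[1:3] <- NA                                 # missingness 0.075
  D <- cbind(s1 = base, s2 = base, s3 = near, s4 = lowmaf, s5 = gappy,
             s6 = sample(0:2, n, TRUE, prob = c(.25, .5, .25)))
  rownames(D) <- sprintf("i%02d", 1:n)
  map <- data.frame(snp = colnames(D), chr = 1L, pos = 1:6 * 1000,
                    contig = c("c1", "c2", "c3", "c4", "c5", "c5"))
  g <- new_genotypes(D, map)
  red <- density_reduction(g, miss_max = 0.03)
  kept <- red$genotypes$map$snp
  ## s1/s2 duplicated (r2 = 1 > 0.65): later one pruned; s4 fails MAF;
  ## s6 shares contig c5 with the earlier s5, which survives to step (iv)
  ## and then fails missingness
  expect_true("s1" %in% kept)
  expect_false("s2" %in% kept)
  expect_false("s4" %in% kept)
  expect_false("s5" %in% kept)
  expect_false("s6" %in% kept)   # removed at the contig step (s5 earlier)
  ## counts reconcile
  expect_equal(red$report$input[2] - sum(red$report$snps$removed),
               red$report$output[2])
})

test_that("LD pruning is strict at the r2 threshold", {
  a <- c(0, 0, 1, 2); b <- c(0, 1, 1, 2)          # r2 = 8/11
  D <- cbind(s1 = rep(a, 10), s2 = rep(b, 10))
  rownames(D) <- sprintf("i%02d", 1:40)
  g <- new_genotypes(D, data.frame(snp = c("s1", "s2"), chr = 1L,
                                   pos = c(100, 200),
                                   contig = c("c1", "c2")))
  keep_at <- density_reduction(g, r2_max = 8 / 11 + 1e-9, maf_min = 0)
  expect_equal(nrow(keep_at$genotypes$map), 2)     # r2 not > threshold
  drop_at <- density_reduction(g, r2_max = 8 / 11 - 1e-9, maf_min = 0)
  expect_equal(drop_at$genotypes$map$snp, "s1")    # earlier SNP kept
})

test_that("random subsets are nested, reproducible and bounded", {
  pop <- sim_population(small_config(seed = 16))
  subs <- random_subsets(pop$genotypes, sizes = c(20, 50, 100), seed = 4)
  s20 <- subs[["20"]]$map$snp
  s50 <- subs[["50"]]$map$snp
  expect_true(all(s20 %in% s50))
  expect_true(all(s50 %in% subs[["100"]]$map$snp))
  subs2 <- random_subsets(pop$genotypes, sizes = c(20, 50, 100), seed = 4)
  expect_identical(s50, subs2[["50"]]$map$snp)
  full <- random_subsets(pop$genotypes, sizes = 300, seed = 4)[["300"]]
  expect_identical(full$dosage, pop$genotypes$dosage)
  expect_error(random_subsets(pop$genotypes, sizes = 301), "exceeds")
})
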