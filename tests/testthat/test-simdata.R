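test_that("configuration invariants are enforced with named errors", {
  expect_error(sim_config(n_snps = 0), "n_snps")
  expect_error(sim_config(n_causal = 6000), "n_causal")
  expect_error(sim_config(genetic_corr = 1.5), "correlations")
  expect_error(sim_config(h2_trait1 = 1.2), "heritabilities")
  expect_error(sim_config(n_sires = 28, n_dams = 60, n_families = 20),
               "n_families")
  expect_error(sim_config(n_sires = 2, n_dams = 2, n_families = 5),
               "n_families")
  dup <- data.frame(sire = c(1, 1), dam = c(1, 1))
  expect_error(sim_config(n_sires = 2, n_dams = 2, n_families = 2,
                          family_plan = dup),
               "reuses a sire-dam pair")
})

test_that("the default design matches the study layout", {
  pop <- sim_population(sim_config(n_snps = 50, n_causal = 10))
  founders <- pop$pedigree[is.na(pop$pedigree$sire), ]
  expect_equal(nrow(founders), 88)               # 28 sires + 60 dams
  expect_equal(sum(founders$sex == "M"), 28)
  offspring <- pop$pedigree[!is.na(pop$pedigree$sire), ]
  expect_equal(nrow(offspring), 534)
  expect_equal(nrow(pop$families), 61)
  expect_false(anyDuplicated(pop$families[c("sire", "dam")]) > 0)
  expect_true(all(pop$families$n_offspring >= 6))
  expect_equal(length(unique(pop$families$sire)), 28)
  expect_equal(length(unique(pop$families$dam)), 60)
  expect_equal(nrow(pop$phenotypes), 534)
})

test_that("founder allele frequencies follow the sampler", {
  cfg <- small_config(n_sires = 28, n_dams = 60, n_families = 61,
                      n_offspring = 400,
                      maf_sampler = function(n) rep(0.5, n))
  fo <- simulate_founders(cfg)
  freq <- colMeans(fo$haplotypes)              # 176 gametes per SNP
  expect_equal(mean(freq), 0.5, tolerance = 0.01)
  se <- sqrt(0.25 / nrow(fo$haplotypes))
  expect_gt(mean(abs(freq - 0.5) < 3 * se), 0.95)
})

test_that("gamete dropping is Mendelian and respects the no-crossover limit", {
  cfg <- small_config(chromosome_length = 0, seed = 21)
  fo <- simulate_founders(cfg)
  ## force a fixed SNP: both parental haplotypes reference everywhere
  fo$haplotypes[, 1] <- 0L
  os <- simulate_offspring(fo, cfg)
  d1 <- os$genotypes$dosage[, 1]
  expect_true(all(d1 == 0) || all(d1 == 2))    # minor recode may flip labels
  mer <- mendelian_error_rate(os$genotypes, os$pedigree)
  expect_true(all(mer$per_snp[mer$snp_tests > 0] == 0))
  ## L = 0: every transmitted gamete is an unrecombined parental haplotype,
  ## so each offspring dosage (up to the minor-allele flip) equals the sum
  ## of one sire haplotype and one dam haplotype per chromosome
  flip <- os$genotypes$map$allele1 == "B"
  D <- os$genotypes$dosage
  D[, flip] <- 2L - D[, flip]
  ped <- os$pedigree
  off <- which(!is.na(ped$sire))[1:10]
  for (o in off) {
    s <- match(ped$sire[o], ped$id); d <- match(ped$dam[o], ped$id)
    for (chr in unique(os$genotypes$map$chr)) {
      j <- which(os$genotypes$map$chr == chr)
      cand <- sapply(1:2, function(a) sapply(1:2, function(b)
        all(D[o, j] == fo$haplotypes[2 * s - 2 + a, j] +
              fo$haplotypes[2 * d - 2 + b, j])))
      expect_true(any(cand))
    }
  }
})

test_that("phenotypes realize the configured architecture", {
  cfg <- small_config(n_offspring = 240, n_snps = 400, n_causal = 100,
                      seed = 31)
  pop <- sim_population(cfg)
  off <- pop$phenotypes$id
  v_t <- apply(pop$tbv[off, ], 2, var)
  expect_equal(unname(v_t),
               unname(cfg$h2 * cfg$trait_sd^2), tolerance = 1e-10)
  expect_equal(cor(pop$phenotypes$weight, pop$phenotypes$length), 0.96,
               tolerance = 0.04)
  ## phenotype ~ TBV: slope ~ 1, R2 ~ h2
  fitw <- lm(pop$phenotypes$weight ~ pop$tbv[off, "weight"] +
               pop$phenotypes$sex)
  expect_equal(unname(coef(fitw)[2]), 1, tolerance = 0.1)
  r2 <- cor(pop$phenotypes$weight - mean(pop$phenotypes$weight),
            pop$tbv[off, "weight"])^2
  expect_equal(r2, cfg$h2[1], tolerance = 0.1)
})

test_that("the no-genetics limit gives pure environmental variance", {
  cfg <- small_config(h2_trait1 = 0, h2_trait2 = 0, sex_effect = c(0, 0),
                      n_offspring = 200, seed = 41)
  pop <- sim_population(cfg)
  expect_true(all(pop$tbv == 0))
  expect_equal(var(pop$phenotypes$weight), cfg$trait_sd[1]^2,
               tolerance = 1e-10)
})

test_that("identical seeds give bit-identical populations", {
  cfg <- small_config(seed = 99)
  p1 <- sim_population(cfg)
  p2 <- sim_population(cfg)
  expect_identical(p1$genotypes$dosage, p2$genotypes$dosage)
  expect_identical(p1$phenotypes, p2$phenotypes)
  expect_identical(p1$tbv, p2$tbv)
  expect_identical(p1$pedigree, p2$pedigree)
})

test_that("infinitesimal architecture leaves markers effect-free", {
  cfg <- small_config(architecture = "infinitesimal", seed = 51)
  pop <- sim_population(cfg)
  expect_equal(nrow(pop$causal), 0)
  off <- pop$phenotypes$id
  expect_gt(var(pop$tbv[off, "weight"]), 0)
})
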