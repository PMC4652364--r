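#' Configuration for a synthetic full-sib population
#'
#' Describes the mating design, marker panel and genetic architecture of a
#' simulated full-sib fish population.  The defaults reproduce a typical
#' farmed Atlantic salmon progeny test: 28 sires and 60 dams crossed into 61
#' unique full-sib families, 534 phenotyped offspring, 29 chromosomes of one
#' Morgan, a 5,000-SNP panel with 500 causal loci, and two highly correlated
#' growth traits -- weight (g; h2 = 0.60, SD 24.0) and length (mm;
#' h2 = 0.51, SD 16.1) -- with a sex fixed effect.
#'
#' @param n_sires,n_dams number of founder sires and dams.
#' @param n_families number of full-sib families; each family is one unique
#'   sire-by-dam pair, so `n_sires <= n_families <= n_sires * n_dams`.
#' @param offspring_per_family `NULL` (allocate `n_offspring` across families
#'   with at least `min_per_family` each), a single count, or a vector of
#'   length `n_families`.
#' @param n_offspring total offspring when `offspring_per_family` is `NULL`.
#' @param min_per_family minimum family size used by the default allocation.
#' @param n_chromosomes,chromosome_length chromosome count and genetic length
#'   in Morgans (crossovers per meiosis are Poisson with this mean).
#' @param n_snps,n_causal marker panel size and number of causal SNPs
#'   (`architecture = "markers"` only).
#' @param maf_sampler function of `n` returning founder allele frequencies;
#'   default uniform on (0.05, 0.5).
#' @param h2_trait1,h2_trait2 narrow-sense heritabilities of the two traits.
#' @param genetic_corr,env_corr genetic and environmental correlations
#'   between the traits, in \[-1, 1\].
#' @param sex_effect length-2 vector added to male phenotypes (trait units).
#' @param trait_mean,trait_sd length-2 vectors of phenotypic means and SDs.
#' @param architecture `"markers"` draws causal-SNP effects; SNP panels then
#'   tag the causal loci.  `"infinitesimal"` generates breeding values from
#'   the pedigree (founder draws plus Mendelian sampling) so that every
#'   genotyped marker is strictly null -- used for association-test
#'   calibration.
#' @param qtl_frac fraction of the additive variance assigned to one single
#'   large QTL (0 = fully polygenic, the default).
#' @param contig_mean_snps mean SNPs per assembly contig label (contigs are
#'   positional blocks within chromosomes; used by the density-reduction
#'   pipeline).
#' @param family_plan optional data.frame with columns `sire`/`dam` (founder
#'   indices) overriding the built-in mating design; pairs must be unique.
#' @param seed integer seed; identical configurations give bit-identical
#'   populations.
#' @return an object of class `sim_config`.
#' @seealso [sim_population()]
#' @export
sim_config <- function(n_sires = 28, n_dams = 60, n_families = 61,
                       offspring_per_family = NULL, n_offspring = 534,
                       min_per_family = 6,
                       n_chromosomes = 29, chromosome_length = 1,
                       n_snps = 5000, n_causal = 500,
                       maf_sampler = function(n) runif(n, 0.05, 0.5),
                       h2_trait1 = 0.60, h2_trait2 = 0.51,
                       genetic_corr = 0.96, env_corr = 0.96,
                       sex_effect = c(7, 5),
                       trait_mean = c(112.0, 214.1),
                       trait_sd = c(24.0, 16.1),
                       architecture = c("markers", "infinitesimal"),
                       qtl_frac = 0,
                       contig_mean_snps = 1.5,
                       family_plan = NULL,
                       seed = 1L) {
  cfg <- list(n_sires = as.integer(n_sires), n_dams = as.integer(n_dams),
              n_families = as.integer(n_families),
              offspring_per_family = offspring_per_family,
              n_offspring = as.integer(n_offspring),
              min_per_family = as.integer(min_per_family),
              n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = chromosome_length,
              n_snps = as.integer(n_snps), n_causal = as.integer(n_causal),
              maf_sampler = maf_sampler,
              h2 = c(h2_trait1, h2_trait2),
              genetic_corr = genetic_corr, env_corr = env_corr,
              sex_effect = rep_len(sex_effect, 2L),
              trait_mean = rep_len(trait_mean, 2L),
              trait_sd = rep_len(trait_sd, 2L),
              architecture = match.arg(architecture),
              qtl_frac = qtl_frac,
              contig_mean_snps = contig_mean_snps,
              family_plan = family_plan,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  bad <- function(msg) stop("invalid sim_config: ", msg, call. = FALSE)
  if (cfg$n_sires < 1L || cfg$n_dams < 1L) bad("n_sires and n_dams must be >= 1")
  if (cfg$n_families < cfg$n_sires)
    bad("n_families must be >= n_sires (every sire contributes a family)")
  if (cfg$n_families > cfg$n_sires * cfg$n_dams)
    bad("n_families must be <= n_sires * n_dams (unique sire-dam pairs)")
  if (cfg$n_snps < 1L) bad("n_snps must be >= 1")
  if (cfg$n_chromosomes < 1L) bad("n_chromosomes must be >= 1")
  if (cfg$chromosome_length < 0) bad("chromosome_length must be >= 0 Morgans")
  if (cfg$architecture == "markers" && cfg$n_causal > cfg$n_snps)
    bad("n_causal must be <= n_snps")
  if (cfg$architecture == "markers" && cfg$n_causal < 1L)
    bad("n_causal must be >= 1 for the marker architecture")
  if (any(cfg$h2 < 0 | cfg$h2 > 1)) bad("heritabilities must lie in [0, 1]")
  if (abs(cfg$genetic_corr) > 1 || abs(cfg$env_corr) > 1)
    bad("correlations must lie in [-1, 1] (2x2 covariance must be PSD)")
  if (any(cfg$trait_sd <= 0)) bad("trait_sd must be positive")
  if (cfg$qtl_frac < 0 || cfg$qtl_frac > 1) bad("qtl_frac must lie in [0, 1]")
  if (!is.null(cfg$family_plan)) {
    fp <- cfg$family_plan
    if (!all(c("sire", "dam") %in% names(fp)))
      bad("family_plan needs columns sire and dam")
    if (nrow(fp) != cfg$n_families)
      bad("family_plan must have n_families rows")
    if (anyDuplicated(fp[c("sire", "dam")]))
      bad("family plan reuses a sire-dam pair")
    if (any(fp$sire < 1 | fp$sire > cfg$n_sires) ||
        any(fp$dam < 1 | fp$dam > cfg$n_dams))
      bad("family_plan indices out of range")
  }
  opf <- cfg$offspring_per_family
  if (!is.null(opf)) {
    if (!length(opf) %in% c(1L, cfg$n_families))
      bad("offspring_per_family must be scalar or length n_families")
    if (any(opf < 1)) bad("offspring_per_family must be >= 1")
  }
  invisible(cfg)
}

## SNP map: chromosomes filled evenly, genetic positions sorted-uniform,
## contigs are positional blocks averaging contig_mean_snps SNPs.
.sim_map <- function(cfg) {
  m <- cfg$n_snps
  chr <- sort(rep_len(seq_len(cfg$n_chromosomes), m))
  pos <- numeric(m)
  contig <- character(m)
  for (c in unique(chr)) {
    i <- which(chr == c)
    pos[i] <- sort(runif(length(i), 0, max(cfg$chromosome_length, 1e-9)))
    ncont <- max(1L, round(length(i) / cfg$contig_mean_snps))
    grp <- sort(sample.int(ncont, length(i), replace = TRUE))
    contig[i] <- sprintf("ctg%02d_%04d", c, grp)
  }
  data.frame(snp = sprintf("SNP%05d", seq_len(m)),
             chr = chr,
             pos = pmax(1L, round(pos * 1e6)) + (chr - 1L) * 0L,
             cm = pos * 100,
             morgan = pos,
             contig = contig,
             allele1 = "A", allele2 = "B",
             stringsAsFactors = FALSE)
}

#' Simulate the founder broodstock
#'
#' Draws per-SNP founder allele frequencies from `maf_sampler` and two
#' gametic haplotypes per founder per chromosome.  Founders have unknown
#' parents.  Sets the RNG seed from `config$seed`; the downstream steps
#' ([simulate_offspring()], [simulate_phenotypes()]) continue the RNG stream,
#' which is what makes [sim_population()] reproducible.
#'
#' @param config a [sim_config()].
#' @return list with elements `haplotypes` (2 rows per founder), `map`,
#'   `freq` (founder frequency of the counted allele) and `pedigree`.
#' @export
simulate_founders <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  map <- .sim_map(config)
  freq <- config$maf_sampler(config$n_snps)
  if (any(freq <= 0 | freq >= 1))
    stop("maf_sampler must return frequencies strictly inside (0, 1)")
  nf <- config$n_sires + config$n_dams
  H <- matrix(rbinom(2L * nf * config$n_snps, 1L,
                     rep(freq, each = 2L * nf)),
              nrow = 2L * nf, ncol = config$n_snps)
  ids <- c(sprintf("S%02d", seq_len(config$n_sires)),
           sprintf("D%02d", seq_len(config$n_dams)))
  rownames(H) <- paste0(rep(ids, each = 2L), c("_h1", "_h2"))
  ped <- data.frame(id = ids, sire = NA_character_, dam = NA_character_,
                    sex = rep(c("M", "F"), c(config$n_sires, config$n_dams)),
                    stringsAsFactors = FALSE)
  list(haplotypes = H, map = map, freq = freq, pedigree = ped)
}

## Mating design: dam j is crossed to sire ((j-1) mod n_sires) + 1, one
## family per dam; any further families reuse a random dam with a sire she
## has not met yet.  Consumes every sire and every dam when
## n_families >= max(n_sires, n_dams).
.family_plan <- function(cfg) {
  if (!is.null(cfg$family_plan))
    return(cfg$family_plan[c("sire", "dam")])
  base <- min(cfg$n_dams, cfg$n_families)
  plan <- data.frame(sire = (seq_len(base) - 1L) %% cfg$n_sires + 1L,
                     dam = seq_len(base))
  while (nrow(plan) < cfg$n_families) {
    repeat {
      d <- sample.int(cfg$n_dams, 1L)
      free <- setdiff(seq_len(cfg$n_sires), plan$sire[plan$dam == d])
      if (length(free)) break
    }
    plan <- rbind(plan, data.frame(sire = sample(free, 1L), dam = d))
  }
  plan
}

.family_sizes <- function(cfg) {
  opf <- cfg$offspring_per_family
  if (!is.null(opf)) return(as.integer(rep_len(opf, cfg$n_families)))
  base <- rep(cfg$min_per_family, cfg$n_families)
  extra <- cfg$n_offspring - sum(base)
  if (extra < 0)
    stop("invalid sim_config: n_offspring < n_families * min_per_family")
  if (extra > 0)
    base <- base + drop(rmultinom(1L, extra, rep(1, cfg$n_families)))
  as.integer(base)
}

## One recombinant gamete: crossovers ~ Poisson(L), positions uniform,
## starting haplotype chosen at random.
.gamete <- function(h1, h2, pos, L) {
  k <- if (L > 0) rpois(1L, L) else 0L
  phase0 <- sample.int(2L, 1L) - 1L
  if (k == 0L) {
    if (phase0 == 0L) return(h1) else return(h2)
  }
  cx <- sort(runif(k, 0, L))
  ph <- (phase0 + findInterval(pos, cx)) %% 2L
  out <- h1
  sw <- ph == 1L
  out[sw] <- h2[sw]
  out
}

#' Drop gametes through the family plan
#'
#' Each offspring receives one recombinant gamete from each parent; the
#' dosage matrix is the sum of the two haplotypes and is therefore Mendelian
#' consistent by construction.  Dosages are recoded at the end so that the
#' counted allele is the sample-minor allele (ties count the alphabetically
#' later allele), matching [read_plink()]'s convention.
#'
#' @param founders output of [simulate_founders()].
#' @param config the same [sim_config()].
#' @return list with `genotypes` (a `genotypes` object covering founders and
#'   offspring), `pedigree` (founders first, then offspring), and `families`.
#' @export
simulate_offspring <- function(founders, config) {
  validate_sim_config(config)
  plan <- .family_plan(config)
  if (anyDuplicated(plan)) stop("family plan reuses a sire-dam pair")
  sizes <- .family_sizes(config)
  map <- founders$map
  n_off <- sum(sizes)
  fam_of <- rep(seq_len(config$n_families), sizes)
  sire_i <- plan$sire[fam_of]
  dam_i <- config$n_sires + plan$dam[fam_of]
  m <- config$n_snps
  Hoff <- matrix(0L, 2L * n_off, m)
  chr_idx <- split(seq_len(m), map$chr)
  for (idx in chr_idx) {
    pos <- map$morgan[idx]
    L <- config$chromosome_length
    for (o in seq_len(n_off)) {
      s <- sire_i[o]; d <- dam_i[o]
      Hoff[2L * o - 1L, idx] <-
        .gamete(founders$haplotypes[2L * s - 1L, idx],
                founders$haplotypes[2L * s, idx], pos, L)
      Hoff[2L * o, idx] <-
        .gamete(founders$haplotypes[2L * d - 1L, idx],
                founders$haplotypes[2L * d, idx], pos, L)
    }
  }
  fped <- founders$pedigree
  off_id <- sprintf("O%04d", seq_len(n_off))
  ped <- rbind(fped,
               data.frame(id = off_id,
                          sire = fped$id[sire_i],
                          dam = fped$id[dam_i],
                          sex = c("F", "M")[rbinom(n_off, 1L, 0.5) + 1L],
                          stringsAsFactors = FALSE))
  attr(ped, "sorted") <- TRUE
  Hall <- rbind(founders$haplotypes, Hoff)
  odd <- seq(1L, nrow(Hall), by = 2L)
  D <- Hall[odd, , drop = FALSE] + Hall[odd + 1L, , drop = FALSE]
  rownames(D) <- ped$id
  colnames(D) <- map$snp
  ## recode to the sample-minor allele (strict flip only; at a 0.5 tie the
  ## counted "B" allele already sorts after "A")
  f <- colMeans(D) / 2
  flip <- f > 0.5
  if (any(flip)) {
    D[, flip] <- 2L - D[, flip]
    a1 <- map$allele1[flip]
    map$allele1[flip] <- map$allele2[flip]
    map$allele2[flip] <- a1
  }
  geno <- new_genotypes(D, map[c("snp", "chr", "pos", "cm", "morgan",
                                 "contig", "allele1", "allele2")])
  fam <- data.frame(family = seq_len(config$n_families),
                    sire = fped$id[plan$sire],
                    dam = fped$id[config$n_sires + plan$dam],
                    n_offspring = sizes, stringsAsFactors = FALSE)
  list(genotypes = geno, pedigree = ped, families = fam)
}

.chol2 <- function(r) chol(matrix(c(1, r, r, 1), 2L))

## scale columns (offspring rows) to an exact target variance
.scale_to_var <- function(M, rows, target) {
  s <- rep(1, ncol(M))
  for (t in seq_len(ncol(M))) {
    if (target[t] <= 0) { M[, t] <- 0; s[t] <- 0; next }
    v <- var(M[rows, t])
    if (v <= 0) stop("degenerate draw: zero variance before scaling")
    s[t] <- sqrt(target[t] / v)
    M[, t] <- M[, t] * s[t]
  }
  list(M = M, scale = s)
}

#' Simulate correlated polygenic phenotypes
#'
#' Inverts the animal model: breeding values come either from causal-marker
#' effects (`architecture = "markers"`, optionally with one large QTL) or
#' from pedigree gene flow (`"infinitesimal"`); environmental deviations are
#' bivariate normal with the configured correlation.  For the marker
#' architecture, effects and deviations are rescaled so the realized
#' offspring variances equal `h2 * trait_sd^2` and `(1 - h2) * trait_sd^2`
#' exactly.  Only offspring are phenotyped; the sex effect is added to
#' males.
#'
#' @param genotypes,pedigree from [simulate_offspring()].
#' @param config the same [sim_config()].
#' @return list with `phenotypes` (data.frame id, sex, weight, length),
#'   `tbv` (true breeding values, all individuals x 2 traits) and `causal`
#'   (data.frame of causal SNPs and their scaled effects; empty for the
#'   infinitesimal architecture).
#' @export
simulate_phenotypes <- function(genotypes, pedigree, config) {
  validate_sim_config(config)
  off <- which(!is.na(pedigree$sire))
  n_off <- length(off)
  ids <- pedigree$id
  h2 <- config$h2
  sig_a2 <- h2 * config$trait_sd^2
  sig_e2 <- (1 - h2) * config$trait_sd^2
  tbv <- matrix(0, length(ids), 2L,
                dimnames = list(ids, c("weight", "length")))
  causal <- data.frame(snp = character(0), eff_weight = numeric(0),
                       eff_length = numeric(0))
  if (config$architecture == "markers" && any(sig_a2 > 0)) {
    D <- genotypes$dosage[ids, , drop = FALSE]
    nc <- config$n_causal
    ci <- sort(sample.int(ncol(D), nc))
    B <- matrix(rnorm(nc * 2L), nc) %*% .chol2(config$genetic_corr)
    W <- scale(D[, ci, drop = FALSE], center = TRUE, scale = FALSE)
    poly_target <- (1 - config$qtl_frac) * sig_a2
    g <- .scale_to_var(W %*% B, off, poly_target)
    tbv <- g$M
    B <- B * rep(g$scale, each = nc)
    qtl_snp <- NULL
    if (config$qtl_frac > 0) {
      qi <- sample(setdiff(seq_len(ncol(D)), ci), 1L)
      wq <- D[, qi] - mean(D[, qi])
      q <- .scale_to_var(cbind(wq, wq), off, config$qtl_frac * sig_a2)
      tbv <- tbv + q$M
      qtl_snp <- colnames(D)[qi]
      causal <- data.frame(snp = qtl_snp, eff_weight = q$scale[1],
                           eff_length = q$scale[2])
    }
    causal <- rbind(data.frame(snp = colnames(D)[ci],
                               eff_weight = B[, 1], eff_length = B[, 2]),
                    causal)
    attr(causal, "qtl") <- qtl_snp
    dimnames(tbv) <- list(ids, c("weight", "length"))
  } else if (config$architecture == "infinitesimal" && any(sig_a2 > 0)) {
    sa <- sqrt(sig_a2)
    La <- diag(sa) %*% t(.chol2(config$genetic_corr)) # lower-tri factor
    fo <- which(is.na(pedigree$sire))
    tbv[fo, ] <- matrix(rnorm(2L * length(fo)), length(fo)) %*% t(La)
    si <- match(pedigree$sire[off], ids)
    di <- match(pedigree$dam[off], ids)
    ms <- matrix(rnorm(2L * n_off), n_off) %*% t(La) * sqrt(0.5)
    tbv[off, ] <- 0.5 * (tbv[si, ] + tbv[di, ]) + ms
  }
  E <- matrix(rnorm(n_off * 2L), n_off) %*% .chol2(config$env_corr)
  E <- .scale_to_var(E, seq_len(n_off), sig_e2)$M
  sexm <- as.numeric(pedigree$sex[off] == "M")
  y <- sweep(tbv[off, , drop = FALSE] + E, 2L, config$trait_mean, "+") +
    outer(sexm, config$sex_effect)
  phen <- data.frame(id = ids[off], sex = pedigree$sex[off],
                     weight = y[, 1], length = y[, 2],
                     stringsAsFactors = FALSE)
  list(phenotypes = phen, tbv = tbv, causal = causal)
}

#' Simulate a complete full-sib study population
#'
#' Runs [simulate_founders()], [simulate_offspring()] and
#' [simulate_phenotypes()] under the configuration's seed.  Identical
#' configurations (including seed) give bit-identical output.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_population`: list with `pedigree`,
#'   `genotypes`, `phenotypes`, `tbv`, `causal`, `families` and `config`.
#' @examples
#' pop <- sim_population(sim_config(n_sires = 4, n_dams = 6, n_families = 6,
#'                                  n_offspring = 48, n_snps = 200,
#'                                  n_causal = 50, seed = 7))
#' nrow(pop$phenotypes)
#' @export
sim_population <- function(config = sim_config()) {
  fo <- simulate_founders(config)
  os <- simulate_offspring(fo, config)
  ph <- simulate_phenotypes(os$genotypes, os$pedigree, config)
  structure(list(pedigree = os$pedigree, genotypes = os$genotypes,
                 phenotypes = ph$phenotypes, tbv = ph$tbv,
                 causal = ph$causal, families = os$families,
                 config = config),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  n_off <- sum(!is.na(x$pedigree$sire))
  cat("Simulated full-sib population\n")
  cat(sprintf("  %d founders (%d sires, %d dams), %d families, %d offspring\n",
              sum(is.na(x$pedigree$sire)), x$config$n_sires, x$config$n_dams,
              nrow(x$families), n_off))
  cat(sprintf("  %d SNPs on %d chromosomes; architecture: %s\n",
              ncol(x$genotypes$dosage), x$config$n_chromosomes,
              x$config$architecture))
  cat(sprintf("  traits: weight (h2=%.2f, sd=%.1f), length (h2=%.2f, sd=%.1f)\n",
              x$config$h2[1], x$config$trait_sd[1],
              x$config$h2[2], x$config$trait_sd[2]))
  invisible(x)
}
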