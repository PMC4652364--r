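#' Mendelian error rates
#'
#' For every offspring whose sire and dam are both genotyped, counts
#' transmissions that are impossible given the parental dosages (e.g.
#' parents 0/0 with offspring 1 or 2; parents 0/2 with offspring 0 or 2).
#' The denominator counts informative tests: complete offspring/sire/dam
#' triples excluding the double-heterozygote parental pair, which can never
#' produce a detectable error.  Missing genotypes are skipped.
#'
#' @param genotypes a `genotypes` object.
#' @param pedigree pedigree data.frame.
#' @return list with `per_snp` and `per_individual` error rates (NA where no
#'   informative test exists), the matching test counts, and `n_trios`.
#' @export
mendelian_error_rate <- function(genotypes, pedigree) {
  D <- genotypes$dosage
  ids <- rownames(D)
  off <- pedigree$id %in% ids & pedigree$sire %in% ids &
    pedigree$dam %in% ids
  per_individual <- setNames(rep(NA_real_, nrow(D)), ids)
  ind_tests <- setNames(rep(0, nrow(D)), ids)
  if (!any(off)) {
    warning("no offspring with both parents genotyped; ",
            "Mendelian error rates undefined")
    return(list(per_snp = setNames(rep(NA_real_, ncol(D)), colnames(D)),
                snp_tests = setNames(rep(0, ncol(D)), colnames(D)),
                per_individual = per_individual, ind_tests = ind_tests,
                n_trios = 0L))
  }
  o <- pedigree$id[off]
  Do <- D[o, , drop = FALSE]
  Ds <- D[pedigree$sire[off], , drop = FALSE]
  Dd <- D[pedigree$dam[off], , drop = FALSE]
  complete <- !(is.na(Do) | is.na(Ds) | is.na(Dd))
  informative <- complete & !(Ds == 1L & Dd == 1L)
  informative[is.na(informative)] <- FALSE
  err <- (Ds == 0L & Dd == 0L & Do != 0L) |
    (Ds == 2L & Dd == 2L & Do != 2L) |
    (((Ds == 0L & Dd == 2L) | (Ds == 2L & Dd == 0L)) & Do != 1L) |
    (((Ds == 0L & Dd == 1L) | (Ds == 1L & Dd == 0L)) & Do == 2L) |
    (((Ds == 2L & Dd == 1L) | (Ds == 1L & Dd == 2L)) & Do == 0L)
  err[!informative | is.na(err)] <- FALSE
  snp_tests <- colSums(informative)
  per_snp <- ifelse(snp_tests > 0, colSums(err) / snp_tests, NA_real_)
  names(per_snp) <- colnames(D)
  it <- rowSums(informative)
  per_individual[o] <- ifelse(it > 0, rowSums(err) / it, NA_real_)
  ind_tests[o] <- it
  list(per_snp = per_snp, snp_tests = setNames(snp_tests, colnames(D)),
       per_individual = per_individual, ind_tests = ind_tests,
       n_trios = sum(off))
}

.qc_step <- function(report, rule, removed, remaining) {
  rbind(report, data.frame(rule = rule, removed = removed,
                           remaining = remaining,
                           stringsAsFactors = FALSE))
}

#' Quality-filter a genotype panel
#'
#' Applies, in order: (1) remove individuals with a Mendelian error rate
#' above `mendel_max`; (2) remove SNPs with a Mendelian error rate (on the
#' remaining individuals) above `mendel_max`; (3) remove SNPs with minor
#' allele frequency below `maf_min`, recomputed on the remaining
#' individuals.  All comparisons are strict (`rate > mendel_max`,
#' `MAF < maf_min`), so a SNP at exactly the MAF threshold is retained.
#'
#' @param genotypes a `genotypes` object.
#' @param pedigree pedigree used to resolve trios.
#' @param maf_min MAF removal threshold (default 0.05).
#' @param mendel_max Mendelian error-rate removal threshold (default 0.01).
#' @return list with `genotypes` (filtered) and `report` (a `qc_report`).
#' @export
filter_panel <- function(genotypes, pedigree, maf_min = 0.05,
                         mendel_max = 0.01) {
  stopifnot(maf_min >= 0, maf_min <= 1, mendel_max >= 0, mendel_max <= 1)
  g <- genotypes
  samples <- data.frame(rule = character(0), removed = integer(0),
                        remaining = integer(0))
  snps <- samples
  mer <- mendelian_error_rate(g, pedigree)
  bad_ind <- names(mer$per_individual)[
    !is.na(mer$per_individual) & mer$per_individual > mendel_max]
  if (length(bad_ind))
    g <- subset_samples(g, setdiff(rownames(g$dosage), bad_ind))
  samples <- .qc_step(samples, sprintf("mendelian > %g", mendel_max),
                      length(bad_ind), nrow(g$dosage))
  mer2 <- if (length(bad_ind)) mendelian_error_rate(g, pedigree) else mer
  bad_snp <- names(mer2$per_snp)[!is.na(mer2$per_snp) &
                                   mer2$per_snp > mendel_max]
  if (length(bad_snp))
    g <- subset_snps(g, setdiff(g$map$snp, bad_snp))
  snps <- .qc_step(snps, sprintf("mendelian > %g", mendel_max),
                   length(bad_snp), ncol(g$dosage))
  mf <- maf(g)
  low <- g$map$snp[mf < maf_min]
  if (length(low)) g <- subset_snps(g, setdiff(g$map$snp, low))
  snps <- .qc_step(snps, sprintf("MAF < %g", maf_min), length(low),
                   ncol(g$dosage))
  if (ncol(g$dosage) == 0L || nrow(g$dosage) == 0L)
    stop("no SNPs or samples survive the quality filters")
  report <- structure(list(samples = samples, snps = snps,
                           input = dim(genotypes$dosage),
                           output = dim(g$dosage)),
                      class = "qc_report")
  list(genotypes = g, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d x %d -> %d x %d (samples x SNPs)\n",
              x$input[1], x$input[2], x$output[1], x$output[2]))
  cat("sample rules:\n"); print(x$samples, row.names = FALSE)
  cat("SNP rules:\n"); print(x$snps, row.names = FALSE)
  invisible(x)
}

#' Composite linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of two dosage vectors over the complete
#' pairs.  Returns `NA` (with a warning) when fewer than two complete pairs
#' exist or either SNP is monomorphic among them.
#'
#' @param dosage_a,dosage_b dosage vectors in `{0, 1, 2, NA}`.
#' @return r-squared in \[0, 1\], or `NA`.
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  ok <- !(is.na(dosage_a) | is.na(dosage_b))
  if (sum(ok) < 2L) {
    warning("fewer than two complete pairs; r2 undefined")
    return(NA_real_)
  }
  a <- dosage_a[ok]; b <- dosage_b[ok]
  if (var(a) == 0 || var(b) == 0) {
    warning("monomorphic SNP; r2 undefined")
    return(NA_real_)
  }
  cor(a, b)^2
}

## greedy left-to-right LD pruning of one positional group; returns logical
## keep vector.  keeps the earlier SNP of an offending pair; if positions
## tie, keeps the higher-MAF SNP.
.ld_prune_group <- function(D, pos, mafs, r2_max, window, step) {
  n <- ncol(D)
  keep <- rep(TRUE, n)
  if (n < 2L) return(keep)
  starts <- unique(c(seq(1L, max(1L, n - 1L), by = step)))
  for (st in starts) {
    en <- min(n, st + window - 1L)
    idx <- (st:en)[keep[st:en]]
    if (length(idx) < 2L) next
    R2 <- suppressWarnings(cor(D[, idx, drop = FALSE],
                               use = "pairwise.complete.obs"))^2
    for (ii in seq_along(idx)) {
      i <- idx[ii]
      if (!keep[i]) next
      for (jj in seq_along(idx)) {
        if (jj <= ii) next
        j <- idx[jj]
        if (!keep[j]) next
        r2 <- R2[ii, jj]
        if (is.na(r2) || r2 <= r2_max) next
        if (pos[i] == pos[j] && mafs[j] > mafs[i]) {
          keep[i] <- FALSE
          break
        } else keep[j] <- FALSE
      }
    }
  }
  keep
}

#' Marker-density reduction pipeline
#'
#' Reduces a panel for lower-density genotyping, applying in order:
#' (i) keep only SNPs polymorphic in the sample; (ii) keep one SNP per
#' assembly contig (the first by position); (iii) greedy LD pruning within
#' chromosomes, removing one of every pair with `r2 > r2_max` (strict; the
#' earlier SNP is kept); (iv) remove SNPs with `MAF < maf_min` or
#' missingness `> miss_max`.
#'
#' @param genotypes a `genotypes` object with contig ids in `map$contig`
#'   (SNPs with `NA` contig are treated as singleton contigs).
#' @param r2_max LD pruning threshold (default 0.65, strict `>`).
#' @param maf_min MAF threshold for step (iv) (default 0.10, strict `<`).
#' @param miss_max missingness threshold for step (iv) (default 0.03,
#'   strict `>`).
#' @param window,step SNP window size and stride for the LD scan.
#' @return list with `genotypes` (reduced) and `report` (a `qc_report`).
#' @export
density_reduction <- function(genotypes, r2_max = 0.65, maf_min = 0.10,
                              miss_max = 0.03, window = 100L, step = 50L) {
  g <- genotypes
  snps <- data.frame(rule = character(0), removed = integer(0),
                     remaining = integer(0))
  m0 <- ncol(g$dosage)
  poly <- maf(g) > 0
  g <- subset_snps(g, g$map$snp[poly])
  snps <- .qc_step(snps, "monomorphic", sum(!poly), ncol(g$dosage))
  contig <- ifelse(is.na(g$map$contig),
                   paste0(".na", seq_len(ncol(g$dosage))), g$map$contig)
  ord <- order(g$map$chr, g$map$pos)
  first <- !duplicated(contig[ord])
  keep_contig <- sort(ord[first])
  removed <- ncol(g$dosage) - length(keep_contig)
  g <- subset_snps(g, g$map$snp[keep_contig])
  snps <- .qc_step(snps, "one SNP per contig", removed, ncol(g$dosage))
  mafs <- maf(g)
  grp <- ifelse(is.na(g$map$chr), "unplaced", as.character(g$map$chr))
  keep <- rep(TRUE, ncol(g$dosage))
  for (cc in unique(grp)) {
    i <- which(grp == cc)
    i <- i[order(g$map$pos[i])]
    D <- g$dosage[, i, drop = FALSE]
    storage.mode(D) <- "double"
    keep[i] <- .ld_prune_group(D, g$map$pos[i], mafs[i], r2_max,
                               window, step)
  }
  g <- subset_snps(g, g$map$snp[keep])
  snps <- .qc_step(snps, sprintf("LD r2 > %g", r2_max), sum(!keep),
                   ncol(g$dosage))
  mafs <- maf(g)
  miss <- colMeans(is.na(g$dosage))
  drop4 <- mafs < maf_min | miss > miss_max
  g <- subset_snps(g, g$map$snp[!drop4])
  snps <- .qc_step(snps, sprintf("MAF < %g or missingness > %g", maf_min,
                                 miss_max), sum(drop4), ncol(g$dosage))
  report <- structure(list(samples = data.frame(rule = character(0),
                                                removed = integer(0),
                                                remaining = integer(0)),
                           snps = snps,
                           input = c(nrow(genotypes$dosage), m0),
                           output = dim(g$dosage)),
                      class = "qc_report")
  list(genotypes = g, report = report)
}

#' Random marker subsets for a density sweep
#'
#' Draws reproducible random subsets of the panel at the requested sizes.
#' By default the subsets are nested (every smaller panel is contained in
#' each larger one), which reduces noise in density comparisons; set
#' `nested = FALSE` for independent draws.
#'
#' @param genotypes a `genotypes` object.
#' @param sizes subset sizes (default `c(500, 1000, 5000, 10000, 20000)`).
#' @param seed integer seed.
#' @param nested nested (default) or independent subsets.
#' @return named list of `genotypes` objects, one per size.
#' @export
random_subsets <- function(genotypes, sizes = c(500, 1000, 5000, 10000,
                                                20000),
                           seed = 1L, nested = TRUE) {
  m <- ncol(genotypes$dosage)
  if (any(sizes > m))
    stop(sprintf("subset size %d exceeds panel size %d",
                 max(sizes), m))
  if (any(sizes < 1L)) stop("subset sizes must be >= 1")
  set.seed(seed)
  perm <- sample.int(m)
  out <- lapply(sizes, function(sz) {
    idx <- if (nested) perm[seq_len(sz)] else sample.int(m, sz)
    subset_snps(genotypes, sort(idx))
  })
  names(out) <- as.character(sizes)
  out
}
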