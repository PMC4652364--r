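#' Bonferroni significance threshold
#'
#' `alpha / n`, the genome-wide (or chromosome-wide, with that chromosome's
#' SNP count) significance threshold.
#'
#' @param n number of tests.
#' @param alpha family-wise error rate (default 0.05).
#' @return threshold p-value (vectorized over `n`).
#' @export
bonferroni_threshold <- function(n, alpha = 0.05) {
  if (any(n < 1)) stop("n must be >= 1")
  alpha / n
}

#' Genomic inflation factor
#'
#' `lambda` = median observed 1-df chi-square statistic divided by the
#' median of the null chi-square(1) distribution (0.4549); ~1 for a
#' calibrated test.
#'
#' @param p p-values (converted to chi-square statistics), or
#' @param chisq 1-df chi-square statistics directly.
#' @return lambda.
#' @export
genomic_inflation <- function(p = NULL, chisq = NULL) {
  if (is.null(chisq)) {
    if (is.null(p)) stop("supply p or chisq")
    chisq <- qchisq(p, df = 1, lower.tail = FALSE)
  }
  chisq <- chisq[is.finite(chisq)]
  if (length(chisq) < 100)
    warning("fewer than 100 tests; lambda is unstable")
  median(chisq) / qchisq(0.5, df = 1)
}

#' GRAMMAR mixed-model association scan
#'
#' Two-step mixed-model GWAS: step one fixes the phenotypic covariance
#' `V = sigma2_a K + sigma2_e I` at the polygenic REML estimates (the fit
#' should use the genomic relationship matrix); step two score-tests each
#' SNP against the projected phenotype,
#' `T = (g' P y)^2 / (g' P g)` with
#' `P = Vinv - Vinv X (X' Vinv X)^-1 X' Vinv`, referred to chi-square with
#' 1 df (the family-based "mmscore"-type test).  Monomorphic SNPs are
#' skipped with a reason; missing dosages are mean-imputed.
#'
#' @param object an [reml_animal()] fit (G-matrix recommended).
#' @param genotypes a `genotypes` object covering the fit's individuals.
#' @param alpha family-wise error rate for the Bonferroni thresholds.
#' @return object of class `gwas_scan`: data.frame with columns `snp`,
#'   `chr`, `pos`, `stat`, `p`; attributes `n_tests`,
#'   `threshold_genomewide`, `threshold_chromosome` (data.frame),
#'   `lambda`, `skipped`.
#' @export
grammar_scan <- function(object, genotypes, alpha = 0.05) {
  if (!object$identifiable || !object$converged)
    stop("need a converged polygenic fit")
  ids <- object$ids
  missing_ids <- setdiff(ids, rownames(genotypes$dosage))
  if (length(missing_ids))
    stop("phenotyped individual(s) not genotyped: ",
         paste(head(missing_ids, 5), collapse = ", "))
  M <- genotypes$dosage[ids, , drop = FALSE]
  storage.mode(M) <- "double"
  f <- colMeans(M, na.rm = TRUE) / 2
  if (anyNA(M)) {
    nas <- which(is.na(M), arr.ind = TRUE)
    M[nas] <- 2 * f[nas[, 2]]
  }
  Ko <- object$kinship[ids, ids]
  n <- length(ids)
  V <- object$sigma2_a * Ko + diag(object$sigma2_e, n)
  Vi <- chol2inv(chol(V))
  X <- object$X
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  if (rcond(XtViX) < 1e-12)
    stop("X' Vinv X is singular; check the fixed-effect design")
  P <- Vi - ViX %*% solve(XtViX, t(ViX))
  Py <- drop(P %*% object$y)
  Mc <- sweep(M, 2L, 2 * f)
  num <- drop(crossprod(Mc, Py))^2
  den <- colSums(Mc * (P %*% Mc))
  mono <- den <= .Machine$double.eps * n
  stat <- ifelse(mono, NA_real_, num / den)
  pval <- pchisq(stat, df = 1, lower.tail = FALSE)
  res <- data.frame(snp = genotypes$map$snp, chr = genotypes$map$chr,
                    pos = genotypes$map$pos, stat = stat, p = pval,
                    stringsAsFactors = FALSE)
  n_tests <- sum(!is.na(stat))
  thr_chr <- NULL
  chr_ok <- !is.na(res$chr) & !is.na(res$stat)
  if (any(chr_ok)) {
    tab <- table(res$chr[chr_ok])
    thr_chr <- data.frame(chr = names(tab), n = as.integer(tab),
                          threshold = bonferroni_threshold(as.integer(tab),
                                                           alpha),
                          stringsAsFactors = FALSE)
  }
  skipped <- if (any(mono))
    data.frame(snp = res$snp[mono], reason = "monomorphic") else
      data.frame(snp = character(0), reason = character(0))
  lam <- if (n_tests >= 1)
    suppressWarnings(genomic_inflation(p = pval[!is.na(pval)])) else NA_real_
  structure(res, n_tests = n_tests,
            threshold_genomewide = bonferroni_threshold(max(n_tests, 1L),
                                                        alpha),
            threshold_chromosome = thr_chr, lambda = lam,
            skipped = skipped, class = c("gwas_scan", "data.frame"))
}

#' @export
print.gwas_scan <- function(x, ...) {
  cat(sprintf("GRAMMAR scan: %d SNPs tested (%d skipped)\n",
              attr(x, "n_tests"), nrow(attr(x, "skipped"))))
  cat(sprintf("  genome-wide Bonferroni threshold: %.3e   lambda = %.3f\n",
              attr(x, "threshold_genomewide"), attr(x, "lambda")))
  d <- as.data.frame(unclass(x))[c("snp", "chr", "stat", "p")]
  top <- d[order(d$p), ][seq_len(min(5, nrow(d))), ]
  cat("  top SNPs:\n")
  print(top, row.names = FALSE)
  invisible(x)
}

#' Proportion of additive genetic variance explained by a SNP
#'
#' `PVE = 2 p q (alpha + delta (q - p))^2 / V_A`, where `p` and `q` are the
#' major and minor allele frequencies, `alpha` and `delta` the additive and
#' dominance effects, and `V_A` the trait's additive genetic variance from
#' the SNP-free polygenic model.  When the marker shows only two genotype
#' classes the dominance term is dropped (`delta = NULL`), giving
#' `2 p q alpha^2 / V_A`.
#'
#' @param p,q major/minor allele frequencies (`p + q = 1`).
#' @param alpha additive effect (trait units).
#' @param delta dominance effect, or `NULL`/`NA` to omit.
#' @param V_A additive genetic variance (must be positive).
#' @return PVE (non-negative fraction).
#' @export
pve <- function(p, q, alpha, delta = NULL, V_A) {
  if (abs(p + q - 1) > 1e-6) stop("p + q must equal 1")
  if (V_A <= 0) stop("V_A must be positive")
  d <- if (is.null(delta) || is.na(delta)) 0 else delta
  2 * p * q * (alpha + d * (q - p))^2 / V_A
}

#' SNP effect estimation under the polygenic model
#'
#' Generalized-least-squares fit of the genotype-class means jointly with
#' the other fixed effects under the polygenic covariance
#' `V = sigma2_a K + sigma2_e I` -- the animal model with the SNP added as a
#' fixed effect.  The additive effect is half the difference between the
#' homozygote means, `alpha = (AA - BB) / 2` (AA = major homozygote), and
#' the dominance effect is the heterozygote deviation from the homozygote
#' midpoint, `delta = AB - (AA + BB) / 2`.  With only two observed genotype
#' classes `delta` is undefined and dropped; `alpha` is then the mean
#' difference per allele copy between the two observed classes.
#'
#' @param object an [reml_animal()] fit.
#' @param genotypes a `genotypes` object.
#' @param snp SNP id (or column index).
#' @param V_A additive variance for the PVE denominator (default: the
#'   fit's `sigma2_a`).
#' @return object of class `snp_effect`: list with the frequencies, class
#'   means, `alpha`, `delta`, their standard errors, and `pve`.
#' @export
snp_effect_fit <- function(object, genotypes, snp, V_A = NULL) {
  j <- if (is.character(snp)) match(snp, genotypes$map$snp) else snp
  if (is.na(j)) stop("unknown SNP: ", snp)
  g <- genotypes$dosage[object$ids, j]
  ok <- !is.na(g)
  g <- g[ok]
  classes <- sort(unique(g))
  if (length(classes) < 2L)
    stop("SNP has a single observed genotype class; effects undefined")
  y <- object$y[ok]
  X0 <- object$X[ok, , drop = FALSE]
  Ko <- object$kinship[object$ids[ok], object$ids[ok]]
  Gd <- outer(g, classes, `==`) * 1
  colnames(Gd) <- paste0("class", classes)
  covars <- X0[, setdiff(colnames(X0), "(Intercept)"), drop = FALSE]
  if (ncol(covars)) covars <- scale(covars, center = TRUE, scale = FALSE)
  Xe <- cbind(Gd, covars)
  V <- object$sigma2_a * Ko + diag(object$sigma2_e, length(y))
  Vi <- chol2inv(chol(V))
  A <- crossprod(Xe, Vi %*% Xe)
  if (rcond(A) < 1e-12) stop("SNP design is singular")
  bh <- solve(A, crossprod(Xe, Vi %*% y))
  Cb <- solve(A)
  means <- setNames(drop(bh)[seq_along(classes)],
                    paste0("dosage", classes))
  lc_se <- function(w) {
    wfull <- c(w, rep(0, ncol(Xe) - length(w)))
    sqrt(drop(t(wfull) %*% Cb %*% wfull))
  }
  if (length(classes) == 3L) {
    alpha <- (means[1] - means[3]) / 2
    alpha_se <- lc_se(c(0.5, 0, -0.5))
    delta <- means[2] - (means[1] + means[3]) / 2
    delta_se <- lc_se(c(-0.5, 1, -0.5))
  } else {
    per_copy <- diff(classes)
    alpha <- (means[1] - means[2]) / ifelse(all(classes == c(0, 2)), 2,
                                            per_copy)
    alpha_se <- lc_se(c(1, -1) / ifelse(all(classes == c(0, 2)), 2,
                                        per_copy))
    delta <- NA_real_
    delta_se <- NA_real_
  }
  qfreq <- mean(g) / 2
  pfreq <- 1 - qfreq
  va <- V_A %||% object$sigma2_a
  pv <- pve(pfreq, qfreq, alpha,
            if (length(classes) == 3L) delta else NULL, va)
  structure(list(snp = genotypes$map$snp[j], n = length(y),
                 n_classes = length(classes), class_means = means,
                 p_major = pfreq, q_minor = qfreq,
                 alpha = unname(alpha), alpha_se = alpha_se,
                 delta = unname(delta), delta_se = delta_se,
                 pve = unname(pv), V_A = va),
            class = "snp_effect")
}

#' @export
print.snp_effect <- function(x, ...) {
  cat(sprintf("SNP effect: %s (n = %d, %d genotype classes)\n", x$snp,
              x$n, x$n_classes))
  cat(sprintf("  p = %.3f, q = %.3f\n", x$p_major, x$q_minor))
  cat(sprintf("  alpha = %.3f (SE %.3f)", x$alpha, x$alpha_se))
  if (!is.na(x$delta))
    cat(sprintf(", delta = %.3f (SE %.3f)", x$delta, x$delta_se))
  cat(sprintf("\n  PVE = %.4f (V_A = %.2f)\n", x$pve, x$V_A))
  invisible(x)
}
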