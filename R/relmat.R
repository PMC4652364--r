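#' Pedigree numerator relationship matrix (tabular method)
#'
#' Builds the expected additive relationship matrix A by the tabular
#' recursion: for individual `i` with parents `s` and `d`,
#' `A[i, j] = (A[j, s] + A[j, d]) / 2` for earlier `j`, and
#' `A[i, i] = 1 + A[s, d] / 2`; unknown parents contribute 0.  The pedigree
#' must be topologically sorted (parents before offspring), e.g. by
#' [sort_pedigree()].
#'
#' @param pedigree sorted pedigree data.frame (`id`, `sire`, `dam`).
#' @return symmetric matrix with ids as dimnames and `attr(, "kind") = "A"`.
#' @export
a_matrix <- function(pedigree) {
  if (!.is_sorted_pedigree(pedigree))
    stop("pedigree is not topologically sorted; call sort_pedigree() first")
  ids <- pedigree$id
  n <- length(ids)
  si <- match(pedigree$sire, ids)
  di <- match(pedigree$dam, ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    Asd <- if (!is.na(s) && !is.na(d)) A[s, d] else 0
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (!is.na(s)) A[j, s] else 0
      ad_ <- if (!is.na(d)) A[j, d] else 0
      A[j, i] <- (as_ + ad_) / 2
      A[i, j] <- A[j, i]
    }
    A[i, i] <- 1 + Asd / 2
  }
  attr(A, "kind") <- "A"
  A
}

#' VanRaden genomic relationship matrix (method 1)
#'
#' `G = W W' / (2 * sum(p * (1 - p)))` where `W` is the dosage matrix with
#' `2 * p` subtracted from each SNP column.  Missing dosages are
#' mean-imputed (`2 * p`) before centering, which is neutral at the mean.
#'
#' @param genotypes a `genotypes` object (or dosage matrix with dimnames).
#' @param freqs per-SNP frequency of the counted allele; defaults to the
#'   observed sample frequency.
#' @return symmetric matrix with `attr(, "kind") = "G"`.
#' @export
g_matrix_vanraden <- function(genotypes, freqs = NULL) {
  D <- if (inherits(genotypes, "genotypes")) genotypes$dosage else genotypes
  storage.mode(D) <- "double"
  p <- freqs %||% (colMeans(D, na.rm = TRUE) / 2)
  if (length(p) != ncol(D)) stop("freqs must have one entry per SNP")
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("all SNPs monomorphic: VanRaden denominator 2*sum(p(1-p)) is zero")
  if (anyNA(D)) {
    for (j in which(colSums(is.na(D)) > 0L)) {
      nas <- is.na(D[, j])
      D[nas, j] <- 2 * p[j]
    }
  }
  W <- sweep(D, 2L, 2 * p)
  G <- tcrossprod(W) / denom
  attr(G, "kind") <- "G"
  G
}

#' Invert a relationship matrix, ridging if singular
#'
#' Returns the plain inverse when the matrix is well conditioned; otherwise
#' adds an escalating ridge to the diagonal (starting at `ridge`, growing
#' tenfold up to `max_ridge`) until the inverse exists and satisfies
#' `max|M %*% Minv - I| < tol`.  The ridge actually applied is attached as
#' `attr(, "ridge")` and reported via `message()`.
#'
#' @param K symmetric relationship matrix.
#' @param ridge initial ridge (default `1e-6`).
#' @param max_ridge largest ridge attempted before giving up.
#' @param tol residual tolerance on `max|M Minv - I|`.
#' @return the inverse matrix with attribute `ridge` (0 when unridged).
#' @export
invert_relationship <- function(K, ridge = 1e-6, max_ridge = 1e-2,
                                tol = 1e-6) {
  if (max(abs(K - t(K))) > 1e-8) stop("relationship matrix must be symmetric")
  n <- nrow(K)
  try_inv <- function(r) {
    M <- K + diag(r, n)
    Minv <- tryCatch(chol2inv(chol(M)), error = function(e) NULL)
    if (is.null(Minv)) return(NULL)
    if (max(abs(M %*% Minv - diag(n))) > tol) return(NULL)
    Minv
  }
  Minv <- try_inv(0)
  r <- 0
  if (is.null(Minv)) {
    r <- ridge
    while (r <= max_ridge) {
      Minv <- try_inv(r)
      if (!is.null(Minv)) break
      r <- r * 10
    }
    if (is.null(Minv))
      stop("matrix still singular after ridge ", max_ridge)
    message(sprintf("relationship matrix singular; applied ridge %.1e", r))
  }
  dimnames(Minv) <- dimnames(K)
  attr(Minv, "ridge") <- r
  Minv
}
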