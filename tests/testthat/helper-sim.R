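# small simulated designs shared across test files

small_config <- function(...) {
  args <- list(n_sires = 4, n_dams = 6, n_families = 6, n_offspring = 60,
               min_per_family = 6, n_chromosomes = 5, n_snps = 300,
               n_causal = 60, seed = 11)
  dots <- list(...)
  args[names(dots)] <- dots
  if (!"n_causal" %in% names(dots) && args$n_causal > args$n_snps)
    args$n_causal <- max(1L, args$n_snps %/% 5L)
  do.call(sim_config, args)
}

# a hand-built animal_reml-like object for tests that exercise the method
# functions at known variance components
fake_fit <- function(y, X, K, sigma2_a = 1, sigma2_e = 1) {
  ids <- rownames(K)[seq_along(y)]
  structure(list(sigma2_a = sigma2_a, sigma2_e = sigma2_e,
                 sigma2_p = sigma2_a + sigma2_e,
                 h2 = sigma2_a / (sigma2_a + sigma2_e), h2_se = NA_real_,
                 loglik = NA_real_, converged = TRUE, boundary = FALSE,
                 identifiable = TRUE, n = length(y), p = ncol(X),
                 beta = rep(0, ncol(X)),
                 y = setNames(y, ids), X = X, ids = ids, kinship = K,
                 kind = attr(K, "kind") %||% "K", trait = "y"),
            class = "animal_reml")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# dense REML restricted log-likelihood, computed from first principles with
# explicit inverses/determinants -- independent oracle for the eigen-based
# fit (same additive constant: -(n-p)/2 log 2pi)
dense_reml_ll <- function(sigma2_a, sigma2_e, y, X, K) {
  n <- length(y)
  V <- sigma2_a * K + diag(sigma2_e, n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  -0.5 * (as.numeric(determinant(V)$modulus) +
            as.numeric(determinant(XtViX)$modulus) +
            drop(t(y) %*% P %*% y) +
            (n - ncol(X)) * log(2 * pi))
}

# populations shared by the heavier recovery checks, generated once per
# test run
.acc_env <- new.env(parent = emptyenv())
acc_populations <- function(n) {
  key <- paste0("pops", n)
  if (is.null(.acc_env[[key]])) {
    .acc_env[[key]] <- lapply(seq_len(n), function(i)
      sim_population(sim_config(seed = 7000 + i)))
  }
  .acc_env[[key]]
}
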