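## Henderson's mixed-model equations for one record per individual.
## rec_ids: ids of the training records (rows of y / X).  Returns fixed
## effects and EBVs for every individual in K, including unrecorded ones,
## which are predicted through the relationship structure.
.solve_mme <- function(y, X, rec_ids, K, Kinv, lambda) {
  idsK <- rownames(K)
  nK <- length(idsK)
  j <- match(rec_ids, idsK)
  if (anyNA(j)) stop("training id(s) missing from the relationship matrix")
  p <- ncol(X)
  C <- matrix(0, p + nK, p + nK)
  C[seq_len(p), seq_len(p)] <- crossprod(X)
  C[seq_len(p), p + j] <- t(X)
  C[p + j, seq_len(p)] <- X
  C[p + seq_len(nK), p + seq_len(nK)] <- lambda * Kinv
  dg <- p + j
  C[cbind(dg, dg)] <- C[cbind(dg, dg)] + 1
  rhs <- c(crossprod(X, y), rep(0, nK))
  rhs[p + j] <- rhs[p + j] + y
  sol <- tryCatch(solve(C, rhs), error = function(e)
    stop("mixed-model equations singular (animal block); consider a ridge ",
         "on the relationship matrix"))
  list(beta = setNames(sol[seq_len(p)], colnames(X)),
       u = setNames(sol[p + seq_len(nK)], idsK))
}

#' Predict breeding values (BLUP) from a fitted animal model
#'
#' Solves Henderson's mixed-model equations at the fit's variance ratio
#' `lambda = sigma2_e / sigma2_a`, returning estimated breeding values for
#' every individual in the relationship matrix -- including individuals
#' without records (e.g. parents, or a masked validation set), which are
#' predicted through their relationships.
#'
#' @param object an [reml_animal()] fit.
#' @param mask ids whose phenotypes are withheld from the solve (their
#'   records never enter the right-hand side).
#' @param ids ids to return EBVs for (default: all individuals in the
#'   relationship matrix).
#' @param kinv optional pre-computed inverse of the relationship matrix
#'   (from [invert_relationship()]); computed on the fly otherwise.
#' @param ... unused.
#' @return named vector of EBVs with the fixed-effect solutions in
#'   `attr(, "beta")`.
#' @export
predict.animal_reml <- function(object, mask = NULL, ids = NULL,
                                kinv = NULL, ...) {
  if (!object$identifiable || !object$converged)
    stop("cannot predict from a non-converged fit")
  if (object$sigma2_a <= 0 || object$boundary && object$h2 < 1e-8)
    stop("additive variance is zero; breeding values undefined")
  lambda <- object$sigma2_e / object$sigma2_a
  Kinv <- kinv %||% invert_relationship(object$kinship)
  train <- setdiff(object$ids, mask)
  if (!length(train)) stop("all records masked; nothing to train on")
  ti <- match(train, object$ids)
  sol <- .solve_mme(object$y[ti], object$X[ti, , drop = FALSE], train,
                    object$kinship, Kinv, lambda)
  out <- if (is.null(ids)) sol$u else sol$u[ids]
  attr(out, "beta") <- sol$beta
  out
}

#' @export
residuals.animal_reml <- function(object, ...) {
  u <- predict(object)
  drop(object$y - object$X %*% attr(u, "beta") - u[object$ids])
}

#' @export
fitted.animal_reml <- function(object, ...) {
  u <- predict(object)
  drop(object$X %*% attr(u, "beta") + u[object$ids])
}

.make_partitions <- function(ids, k, reps) {
  n <- length(ids)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  lapply(seq_len(reps), function(r) {
    perm <- sample(ids)
    split(perm, rep(seq_len(k), sizes))
  })
}

#' Cross-validated prediction accuracy
#'
#' Replicated k-fold cross-validation of BLUP breeding values.  Per
#' replicate the phenotyped individuals are split into `k` non-overlapping
#' folds (the first `n %% k` folds take the extra individual); per fold the
#' fold's phenotypes are masked, the mixed-model equations are solved on the
#' remaining records, and accuracy is computed as
#' `cor(EBV, y) / h` with `h = sqrt(h2)` from the full-data fit (or a
#' supplied `h2`).  Variance components are reused from the full-data fit by
#' default; `refit = TRUE` re-estimates them per training set.
#'
#' @param object an [reml_animal()] fit on the full data.
#' @param k folds (default 5).
#' @param reps replicates (default 5); each redraws the partition.
#' @param seed seed for the partitions.
#' @param partitions optional list (length `reps`) of lists of fold id
#'   vectors, e.g. from a previous run's `attr(, "partitions")`, enabling
#'   paired comparisons across methods or densities.
#' @param h2 heritability for the accuracy denominator (default: the fit's).
#' @param refit re-estimate variance components per training set.
#' @return object of class `cv_accuracy`: data.frame with columns `method`,
#'   `replicate`, `fold`, `n_val`, `accuracy`; attributes `h`,
#'   `replicate_means`, `mean`, `sd`, `partitions`.
#' @export
cross_validate <- function(object, k = 5, reps = 5, seed = 1L,
                           partitions = NULL, h2 = NULL, refit = FALSE) {
  ids <- object$ids
  if (length(ids) < k) stop("fewer phenotyped individuals than folds")
  h2use <- h2 %||% object$h2
  if (is.na(h2use) || h2use <= 0)
    stop("need a positive heritability for the accuracy denominator")
  h <- sqrt(h2use)
  if (is.null(partitions)) {
    set.seed(seed)
    partitions <- .make_partitions(ids, k, reps)
  }
  reps <- length(partitions)
  Kinv <- invert_relationship(object$kinship)
  rows <- list()
  method <- switch(object$kind, G = "GBLUP", A = "PBLUP", "BLUP")
  for (r in seq_len(reps)) {
    folds <- partitions[[r]]
    for (f in seq_along(folds)) {
      val <- folds[[f]]
      train <- setdiff(ids, val)
      ti <- match(train, ids)
      if (refit) {
        rf <- .reml_core(object$y[ti], object$X[ti, , drop = FALSE],
                         object$kinship[train, train])
        lambda <- rf$sigma2_e / rf$sigma2_a
      } else lambda <- object$sigma2_e / object$sigma2_a
      sol <- .solve_mme(object$y[ti], object$X[ti, , drop = FALSE],
                        train, object$kinship, Kinv, lambda)
      yv <- object$y[val]
      if (var(yv) == 0) {
        message(sprintf("replicate %d fold %d skipped: no phenotype ",
                        r, f), "variance")
        next
      }
      rows[[length(rows) + 1L]] <-
        data.frame(method = method, replicate = r, fold = f,
                   n_val = length(val),
                   accuracy = cor(sol$u[val], yv) / h)
    }
  }
  out <- do.call(rbind, rows)
  rmeans <- tapply(out$accuracy, out$replicate, mean)
  structure(out, h = h, replicate_means = as.numeric(rmeans),
            mean = mean(out$accuracy), sd = sd(out$accuracy),
            partitions = partitions, class = c("cv_accuracy", "data.frame"))
}

#' @export
print.cv_accuracy <- function(x, ...) {
  cat(sprintf("%s cross-validation: %d replicate(s) x %d fold(s)\n",
              x$method[1], max(x$replicate), max(x$fold)))
  cat(sprintf("  mean accuracy r(EBV, y)/h = %.3f (SD %.3f), h = %.3f\n",
              attr(x, "mean"), attr(x, "sd"), attr(x, "h")))
  invisible(x)
}

#' GBLUP vs PBLUP accuracy across marker densities
#'
#' Runs the cross-validation comparison of Fig.-1 type density sweeps:
#' PBLUP (pedigree A-matrix) is computed once -- it ignores markers -- and
#' GBLUP is recomputed for nested random marker subsets of the requested
#' sizes plus the full panel, reusing the same fold partitions throughout so
#' the comparison is paired.  Each method uses a single accuracy denominator
#' `h`: the pedigree fit's for PBLUP, the full-panel genomic fit's for every
#' GBLUP density (a low-density G attenuates its own heritability estimate,
#' which would otherwise distort the sweep).
#'
#' @param formula trait model, e.g. `weight ~ sex`.
#' @param data phenotype data.frame with an id column.
#' @param genotypes full marker panel (a `genotypes` object).
#' @param pedigree sorted pedigree.
#' @param sizes marker subset sizes (clipped to the panel size).
#' @param include_full include the full panel as the top density.
#' @param k,reps folds and replicates.
#' @param seed seed for subsets and partitions.
#' @param id id column name.
#' @return data.frame of class `density_sweep` with columns `method`,
#'   `density`, `replicate`, `fold`, `accuracy`; attribute `h` records the
#'   per-method heritability used.
#' @export
density_sweep <- function(formula, data, genotypes, pedigree,
                          sizes = c(500, 1000, 5000, 10000, 20000),
                          include_full = TRUE, k = 5, reps = 5, seed = 1L,
                          id = "id") {
  m <- ncol(genotypes$dosage)
  sizes <- sort(unique(pmin(sizes, m)))
  panels <- random_subsets(genotypes, sizes, seed = seed)
  if (include_full && !m %in% sizes) {
    panels[[as.character(m)]] <- genotypes
    sizes <- c(sizes, m)
  }
  A <- a_matrix(pedigree)
  fitA <- reml_animal(formula, data, A, id = id)
  set.seed(seed)
  partitions <- .make_partitions(fitA$ids, k, reps)
  cvA <- cross_validate(fitA, partitions = partitions)
  out <- data.frame(method = "PBLUP", density = NA_integer_,
                    replicate = cvA$replicate, fold = cvA$fold,
                    accuracy = cvA$accuracy)
  hs <- c(PBLUP = attr(cvA, "h"))
  ## one heritability per method: the accuracy denominator for every GBLUP
  ## density is the full-panel G-REML estimate, so the sweep measures how
  ## marker density changes prediction, not how it attenuates h2-hat
  top <- as.character(max(sizes))
  fits <- list()
  for (sz in as.character(sizes)) {
    G <- g_matrix_vanraden(panels[[sz]])
    fits[[sz]] <- reml_animal(formula, data, G, id = id)
  }
  h2_full <- fits[[top]]$h2
  for (sz in as.character(sizes)) {
    cvG <- cross_validate(fits[[sz]], partitions = partitions,
                          h2 = h2_full)
    out <- rbind(out,
                 data.frame(method = "GBLUP", density = as.integer(sz),
                            replicate = cvG$replicate, fold = cvG$fold,
                            accuracy = cvG$accuracy))
    hs[paste0("GBLUP_", sz)] <- attr(cvG, "h")
  }
  structure(out, h = hs, partitions = partitions,
            class = c("density_sweep", "data.frame"))
}

#' @export
print.density_sweep <- function(x, ...) {
  agg <- aggregate(accuracy ~ method + density,
                   data = transform(x, density = ifelse(is.na(x$density),
                                                        0L, x$density)),
                   FUN = mean)
  agg$density <- ifelse(agg$density == 0L, "pedigree", agg$density)
  cat("Cross-validated accuracy by method and marker density:\n")
  print(agg, row.names = FALSE)
  invisible(x)
}
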