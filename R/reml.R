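## Restricted log-likelihood of the animal model after eigen-rotation.
## Convention: l = -1/2 [ log|V| + log|X'V^-1 X| + y'Py + (n-p) log 2pi ],
## evaluated for V = sigma2_a * K + sigma2_e * I on the phenotyped subset.
.reml_ll <- function(sigma2_a, sigma2_e, d, yt, Xt) {
  v <- sigma2_a * d + sigma2_e
  if (any(v <= 0)) return(-Inf)
  w <- 1 / v
  XtWX <- crossprod(Xt, Xt * w)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  b <- backsolve(ch, forwardsolve(t(ch), crossprod(Xt * w, yt)))
  r <- yt - Xt %*% b
  yPy <- sum(w * r^2)
  n <- length(yt); p <- ncol(Xt)
  -0.5 * (sum(log(v)) + 2 * sum(log(diag(ch))) + yPy +
            (n - p) * log(2 * pi))
}

## core REML fit on aligned (y, X, K_obs); shared by reml_animal() and the
## per-fold refits in cross_validate()
.reml_core <- function(y, X, K, log_ratio_bounds = c(-15, 15)) {
  n <- length(y); p <- ncol(X)
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  d <- eg$values
  U <- eg$vectors
  identifiable <- (max(d) - min(d)) > 1e-8 * max(1, abs(mean(d)))
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  neval <- 0L
  prof <- function(tau) {
    neval <<- neval + 1L
    gam <- exp(tau)
    w <- 1 / (gam * d + 1)
    XtWX <- crossprod(Xt, Xt * w)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    b <- backsolve(ch, forwardsolve(t(ch), crossprod(Xt * w, yt)))
    r <- yt - Xt %*% b
    rss <- sum(w * r^2)
    s2e <- rss / (n - p)
    -0.5 * ((n - p) * log(s2e) + sum(log(gam * d + 1)) +
              2 * sum(log(diag(ch))) + (n - p) * (1 + log(2 * pi)))
  }
  if (!identifiable) {
    warning("relationship matrix is (numerically) proportional to the ",
            "identity: additive and residual variances are not separately ",
            "identifiable (flat likelihood ridge)")
    return(list(sigma2_a = NA_real_, sigma2_e = NA_real_,
                sigma2_p = var(drop(y)), h2 = NA_real_, h2_se = NA_real_,
                se = c(sigma2_a = NA_real_, sigma2_e = NA_real_),
                vcov_varcomp = matrix(NA_real_, 2, 2),
                loglik = NA_real_, converged = FALSE, boundary = FALSE,
                identifiable = FALSE, iterations = neval,
                beta = NULL, beta_vcov = NULL, eigenvalues = d))
  }
  opt <- optimize(prof, interval = log_ratio_bounds, maximum = TRUE,
                  tol = 1e-9)
  cand <- c(opt$maximum, log_ratio_bounds)
  ll <- c(opt$objective, prof(log_ratio_bounds[1]), prof(log_ratio_bounds[2]))
  tau <- cand[which.max(ll)]
  boundary <- min(abs(tau - log_ratio_bounds)) < 1e-3
  gam <- exp(tau)
  w <- 1 / (gam * d + 1)
  XtWX <- crossprod(Xt, Xt * w)
  b <- solve(XtWX, crossprod(Xt * w, yt))
  r <- yt - Xt %*% b
  s2e <- sum(w * r^2) / (n - p)
  s2a <- gam * s2e
  loglik <- .reml_ll(s2a, s2e, d, yt, Xt)
  ## observed information by central differences on the unprofiled surface
  H <- matrix(NA_real_, 2, 2)
  se <- c(sigma2_a = NA_real_, sigma2_e = NA_real_)
  Vcov <- matrix(NA_real_, 2, 2)
  if (!boundary) {
    th <- c(s2a, s2e)
    hstep <- pmax(1e-4 * abs(th), 1e-8)
    f <- function(t1, t2) .reml_ll(t1, t2, d, yt, Xt)
    for (i in 1:2) for (j in i:2) {
      ei <- ej <- c(0, 0); ei[i] <- hstep[i]; ej[j] <- hstep[j]
      if (i == j) {
        H[i, i] <- (f(th[1] + ei[1], th[2] + ei[2]) - 2 * loglik +
                      f(th[1] - ei[1], th[2] - ei[2])) / hstep[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (f(th[1] + ei[1] + ej[1], th[2] + ei[2] + ej[2]) -
             f(th[1] + ei[1] - ej[1], th[2] + ei[2] - ej[2]) -
             f(th[1] - ei[1] + ej[1], th[2] - ei[2] + ej[2]) +
             f(th[1] - ei[1] - ej[1], th[2] - ei[2] - ej[2])) /
          (4 * hstep[i] * hstep[j])
      }
    }
    Vc <- tryCatch(solve(-H), error = function(e) NULL)
    if (!is.null(Vc) && all(diag(Vc) > 0)) {
      Vcov <- Vc
      se <- c(sigma2_a = sqrt(Vc[1, 1]), sigma2_e = sqrt(Vc[2, 2]))
    }
  }
  s2p <- s2a + s2e
  h2 <- s2a / s2p
  h2_se <- NA_real_
  if (all(is.finite(Vcov))) {
    grad <- c(s2e, -s2a) / s2p^2
    h2_se <- sqrt(drop(t(grad) %*% Vcov %*% grad))
  }
  beta_vcov <- solve(XtWX) * s2e
  dimnames(beta_vcov) <- list(colnames(X), colnames(X))
  list(sigma2_a = s2a, sigma2_e = s2e, sigma2_p = s2p,
       h2 = h2, h2_se = h2_se, se = se, vcov_varcomp = Vcov,
       loglik = loglik, converged = TRUE, boundary = boundary,
       identifiable = TRUE, iterations = neval,
       beta = setNames(drop(b), colnames(X)), beta_vcov = beta_vcov,
       eigenvalues = d)
}

#' Fit the animal model by REML
#'
#' Fits `y = Xb + Zu + e` with `u ~ N(0, K * sigma2_a)` and
#' `e ~ N(0, I * sigma2_e)` by restricted maximum likelihood, where `K` is a
#' pedigree (A) or genomic (G) relationship matrix.  The kinship submatrix
#' on the phenotyped individuals is eigendecomposed once, the model is
#' rotated to a diagonal covariance, and the restricted likelihood is
#' maximized over the log variance ratio by Brent search -- exact for a
#' single random effect.  Standard errors come from the observed information
#' at the optimum; the heritability `h2 = sigma2_a / (sigma2_a + sigma2_e)`
#' gets a delta-method standard error.
#'
#' Individuals present in `kinship` but without phenotypes (e.g. parents)
#' need no records; they still contribute relationships to [predict()]
#' solves.  A fit at the edge of the ratio search range (additive variance
#' at or near zero) is flagged `boundary`; a kinship matrix proportional to
#' the identity leaves the two components non-identifiable and is flagged
#' (with `NA` estimates) rather than returning arbitrary numbers.
#'
#' @param formula model formula, e.g. `weight ~ sex` (intercept implied).
#' @param data data.frame with the trait, covariates and an id column.
#' @param kinship relationship matrix with ids as dimnames ([a_matrix()] or
#'   [g_matrix_vanraden()]); phenotyped ids must be a subset.
#' @param id name of the id column in `data` (default `"id"`).
#' @param log_ratio_bounds search range for `log(sigma2_a / sigma2_e)`.
#' @return object of class `animal_reml` with components `sigma2_a`,
#'   `sigma2_e`, `sigma2_p`, `se`, `h2`, `h2_se`, `loglik`, `converged`,
#'   `boundary`, `identifiable`, `beta`, `beta_vcov`, plus the aligned data
#'   (`y`, `X`, `ids`) and the full `kinship` used by the method functions.
#' @examples
#' pop <- sim_population(sim_config(n_sires = 6, n_dams = 10,
#'                                  n_families = 10, n_offspring = 120,
#'                                  n_snps = 500, n_causal = 100, seed = 42))
#' A <- a_matrix(pop$pedigree)
#' fit <- reml_animal(weight ~ sex, pop$phenotypes, A)
#' summary(fit)
#' @export
reml_animal <- function(formula, data, kinship, id = "id",
                        log_ratio_bounds = c(-15, 15)) {
  if (!is.matrix(kinship) || is.null(rownames(kinship)))
    stop("kinship must be a matrix with individual ids as dimnames")
  if (max(abs(kinship - t(kinship))) > 1e-8)
    stop("kinship matrix must be symmetric")
  if (!id %in% names(data)) stop("no '", id, "' column in data")
  vars <- all.vars(formula)
  miss_var <- setdiff(vars, names(data))
  if (length(miss_var)) stop("variables not in data: ",
                             paste(miss_var, collapse = ", "))
  ids_all <- as.character(data[[id]])
  keep <- complete.cases(data[, vars, drop = FALSE]) &
    ids_all %in% rownames(kinship)
  if (sum(!keep))
    message(sprintf(paste0("dropping %d record(s) with missing data or no ",
                           "kinship entry"), sum(!keep)))
  d2 <- data[keep, , drop = FALSE]
  if (nrow(d2) < 3L) stop("fewer than 3 usable records")
  if (anyDuplicated(d2[[id]]))
    stop("one record per individual is required")
  mf <- model.frame(formula, d2)
  y <- model.response(mf)
  X <- model.matrix(attr(mf, "terms"), mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    message("dropping aliased fixed-effect column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  ids <- as.character(d2[[id]])
  fit <- .reml_core(y, X, kinship[ids, ids], log_ratio_bounds)
  fit$call <- match.call()
  fit$formula <- formula
  fit$trait <- deparse(formula[[2]])
  fit$n <- length(y)
  fit$p <- ncol(X)
  fit$y <- setNames(as.numeric(y), ids)
  fit$X <- X
  fit$ids <- ids
  fit$kinship <- kinship
  fit$kind <- attr(kinship, "kind") %||% "K"
  class(fit) <- "animal_reml"
  fit
}

#' @export
print.animal_reml <- function(x, digits = 4, ...) {
  cat(sprintf("Animal model REML fit (%s-matrix), trait: %s, n = %d\n",
              x$kind, x$trait, x$n))
  if (!x$identifiable) {
    cat("  components not identifiable (kinship ~ identity)\n")
    return(invisible(x))
  }
  cat(sprintf("  sigma2_a = %.*g (SE %.*g), sigma2_e = %.*g (SE %.*g)\n",
              digits, x$sigma2_a, digits, x$se[1],
              digits, x$sigma2_e, digits, x$se[2]))
  cat(sprintf("  h2 = %.3f (SE %.3f)   logLik = %.3f%s\n", x$h2,
              x$h2_se, x$loglik,
              if (x$boundary) "   [boundary estimate]" else ""))
  invisible(x)
}

#' @export
summary.animal_reml <- function(object, ...) {
  print(object)
  if (object$identifiable) {
    cat("Fixed effects:\n")
    tab <- cbind(estimate = object$beta,
                 se = sqrt(diag(object$beta_vcov)))
    print(round(tab, 4))
  }
  invisible(object)
}

#' @export
coef.animal_reml <- function(object, ...) object$beta

#' @export
vcov.animal_reml <- function(object, ...) object$beta_vcov

#' @export
logLik.animal_reml <- function(object, ...) {
  structure(object$loglik, df = object$p + 2L, nobs = object$n,
            class = "logLik")
}

#' Heritability from a fitted animal model or variance components
#'
#' `h2 = sigma2_a / (sigma2_a + sigma2_e)` with a delta-method standard
#' error when a component covariance is available.
#'
#' @param object an `animal_reml` fit, or the additive variance.
#' @param ... passed on to methods.
#' @return named numeric vector `c(h2 = , se = )` (se may be `NA`).
#' @export
heritability <- function(object, ...) UseMethod("heritability")

#' @rdname heritability
#' @export
heritability.animal_reml <- function(object, ...) {
  if (!isTRUE(object$converged) || !object$identifiable)
    stop("heritability undefined: fit did not converge")
  c(h2 = object$h2, se = object$h2_se)
}

#' @rdname heritability
#' @param sigma2_e residual variance (default method only).
#' @param vcov optional 2x2 covariance of `(sigma2_a, sigma2_e)`.
#' @export
heritability.default <- function(object, sigma2_e, vcov = NULL, ...) {
  sigma2_a <- object
  s2p <- sigma2_a + sigma2_e
  if (s2p <= 0) stop("total phenotypic variance is zero: h2 undefined")
  h2 <- sigma2_a / s2p
  se <- NA_real_
  if (!is.null(vcov)) {
    grad <- c(sigma2_e, -sigma2_a) / s2p^2
    se <- sqrt(drop(t(grad) %*% vcov %*% grad))
  }
  c(h2 = h2, se = se)
}

#' Simulate response vectors from a fitted animal model
#'
#' Draws `y* ~ N(X b, sigma2_a K + sigma2_e I)` on the phenotyped subset.
#'
#' @param object an `animal_reml` fit.
#' @param nsim number of vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return data.frame with one column per draw.
#' @export
simulate.animal_reml <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  Ko <- object$kinship[object$ids, object$ids]
  V <- object$sigma2_a * Ko + diag(object$sigma2_e, object$n)
  L <- chol(V + diag(1e-10 * mean(diag(V)), object$n))
  mu <- drop(object$X %*% object$beta)
  out <- as.data.frame(mu + t(L) %*%
                         matrix(rnorm(object$n * nsim), object$n))
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- object$ids
  out
}
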