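#' Fit a relationship-matrix mixed model by REML
#'
#' Fits \deqn{y = X\beta + \sum_r Z_r u_r + e, \qquad
#'   u_r \sim N(0, C_r \sigma^2_{u_r}), \quad e \sim N(0, I\sigma^2_e)}
#' where each \eqn{C_r} is a relationship matrix (NRM, GRM, CRM1/2/3, ...)
#' over animals and \eqn{Z_r} maps phenotype records to animals. Variance
#' components are estimated by direct maximization of the restricted
#' log-likelihood on the log-variance scale (Nelder--Mead with a restart
#' polish; an eigendecomposition fast path is used for single-kernel
#' models). Breeding values are the BLUP solutions at the REML estimates.
#'
#' Relationship matrices that are not positive semi-definite (possible for
#' CRM1/CRM2) are handled according to \code{bend}: eigenvalues floored at
#' \code{1e-6} with a warning (default), or an error. Random terms whose
#' record-level covariance kernels coincide are reported with an
#' identifiability warning (only their sum is estimable).
#'
#' @param formula fixed-effects formula, e.g. \code{y ~ cg + age}; the
#'   response is the trait.
#' @param data data frame with one row per record, containing the response,
#'   the covariates and an animal id column.
#' @param random named list of \code{\link{relmat}} objects, one per random
#'   term (e.g. \code{list(grm = G)} or \code{list(nrm = A, grm = G)}).
#' @param id name of the animal id column in \code{data} (default
#'   \code{"animal"}).
#' @param bend \code{"warn"} (floor eigenvalues, warn) or \code{"error"}.
#' @param init optional starting variances (length = number of terms + 1,
#'   residual last).
#' @param max_restarts maximum optimizer restarts (default 5; convergence is
#'   declared when a restart improves the restricted log-likelihood by less
#'   than \code{1e-8} and moves parameters by less than \code{1e-6}).
#' @return an object of class \code{"reml_fit"}: variance components
#'   (\code{$varcomp}, residual last), restricted log-likelihood
#'   (\code{$loglik}), convergence flag, fixed-effect estimates
#'   (\code{$beta}), per-term breeding values (\code{$ebv}), fitted values
#'   and residuals.
#' @seealso \code{\link{blup_ebv}}, \code{\link{cv_accuracy}},
#'   \code{\link{missing_heritability}}
#' @export
reml_fit <- function(formula, data, random, id = "animal",
                     bend = c("warn", "error"), init = NULL,
                     max_restarts = 5) {
  bend <- match.arg(bend)
  if (!is.list(random) || !length(random)) stop("'random' must be a non-empty list")
  if (is.null(names(random)) || any(!nzchar(names(random))))
    names(random) <- paste0("term", seq_along(random))
  if (!id %in% names(data)) stop("id column '", id, "' not found in data")

  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  keep <- !is.na(y)
  data <- data[keep, , drop = FALSE]
  mf <- mf[keep, , drop = FALSE]
  y <- y[keep]
  n <- length(y)
  X <- stats::model.matrix(formula, mf)
  qx <- qr(X)
  if (qx$rank < ncol(X)) X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  p <- ncol(X)
  if (n <= p) stop("more fixed effects than records")

  anim <- as.character(data[[id]])
  C <- lapply(names(random), function(nm) {
    cr <- random[[nm]]
    if (!inherits(cr, "relmat")) cr <- relmat(as.matrix(cr))
    missing_ids <- setdiff(anim, rownames(cr))
    if (length(missing_ids))
      stop("animals absent from relationship matrix '", nm, "': ",
           paste(utils::head(missing_ids, 5), collapse = ", "))
    ev <- eigen(unclass(cr), symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      if (bend == "error")
        stop("relationship matrix '", nm, "' is not positive semi-definite")
      warning("relationship matrix '", nm,
              "' is not PSD; bending eigenvalues to 1e-6")
      es <- eigen(unclass(cr), symmetric = TRUE)
      vals <- relmat(es$vectors %*% (pmax(es$values, 1e-6) * t(es$vectors)),
                     kind = attr(cr, "kind"), animal_ids = rownames(cr),
                     tol = 1e-6)
      cr <- vals
    }
    cr
  })
  names(C) <- names(random)
  idx <- lapply(C, function(cr) match(anim, rownames(cr)))
  K <- lapply(seq_along(C), function(r)
    unclass(C[[r]])[idx[[r]], idx[[r]], drop = FALSE])
  names(K) <- names(C)

  k <- length(K)
  if (k > 1L) {
    for (r in seq_len(k - 1L)) for (s in (r + 1L):k) {
      if (max(abs(K[[r]] - K[[s]])) < 1e-8)
        warning("random terms '", names(K)[r], "' and '", names(K)[s],
                "' have identical covariance kernels; only their sum is ",
                "estimable")
    }
  }

  vy <- stats::var(y)
  if (is.null(init)) init <- rep(vy / (k + 1), k + 1)
  theta0 <- log(pmax(init, 1e-8 * vy))

  if (k == 1L) {
    ek <- eigen(K[[1L]], symmetric = TRUE)
    lam <- pmax(ek$values, 0)
    yr <- crossprod(ek$vectors, y)
    Xr <- crossprod(ek$vectors, X)
    negll <- function(theta) {
      s2 <- exp(theta)
      d <- s2[1L] * lam + s2[2L]
      if (any(d <= 0) || any(!is.finite(d))) return(1e10)
      -reml_ll_diag(d, yr, Xr)
    }
  } else {
    negll <- function(theta) {
      s2 <- exp(theta)
      V <- diag(s2[k + 1L], n)
      for (r in seq_len(k)) V <- V + s2[r] * K[[r]]
      ll <- try(reml_ll_dense(V, y, X), silent = TRUE)
      if (inherits(ll, "try-error") || !is.finite(ll)) return(1e10)
      -ll
    }
  }

  theta <- theta0
  val <- negll(theta)
  start_val <- val
  converged <- FALSE
  iters <- 0L
  for (rs in seq_len(max_restarts)) {
    opt <- stats::optim(theta, negll, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    iters <- iters + opt$counts[1L]
    dll <- val - opt$value
    dpar <- max(abs(opt$par - theta))
    theta <- opt$par
    val <- opt$value
    if (dll >= 0 && dll < 1e-8 && dpar < 1e-6) { converged <- TRUE; break }
  }
  # the optimum is never worse than the start (likelihood monotonicity)
  if (val > start_val) { theta <- theta0; val <- start_val }

  s2 <- exp(theta)
  varcomp <- stats::setNames(s2, c(names(K), "residual"))
  fit <- list(varcomp = varcomp, loglik = -val, converged = converged,
              iterations = as.integer(iters),
              y = y, X = X, K = K, C = C, idx = idx, animal = anim,
              formula = formula, call = match.call())
  class(fit) <- "reml_fit"
  sol <- blup_solve(fit)
  fit$beta <- sol$beta
  fit$ebv <- sol$ebv
  fit$fitted <- sol$fitted
  fit$residuals <- y - sol$fitted
  fit
}

# Restricted log-likelihood with V diagonal in a rotated basis.
reml_ll_diag <- function(d, yr, Xr) {
  n <- length(yr)
  p <- ncol(Xr)
  w <- 1 / d
  XtVX <- crossprod(Xr, w * Xr)
  XtVy <- crossprod(Xr, w * yr)
  ch <- try(chol(XtVX), silent = TRUE)
  if (inherits(ch, "try-error")) return(-Inf)
  beta <- backsolve(ch, forwardsolve(t(ch), XtVy))
  yPy <- sum(w * yr^2) - sum(XtVy * beta)
  -0.5 * ((n - p) * log(2 * pi) + sum(log(d)) +
          2 * sum(log(diag(ch))) + yPy)
}

# Dense-V restricted log-likelihood (any number of kernels).
reml_ll_dense <- function(V, y, X) {
  n <- length(y)
  p <- ncol(X)
  ch <- chol(V)
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtVX <- crossprod(X, Vi_X)
  XtVy <- crossprod(X, Vi_y)
  ch2 <- chol(XtVX)
  beta <- backsolve(ch2, forwardsolve(t(ch2), XtVy))
  yPy <- sum(y * Vi_y) - sum(XtVy * beta)
  -0.5 * ((n - p) * log(2 * pi) + 2 * sum(log(diag(ch))) +
          2 * sum(log(diag(ch2))) + yPy)
}

# GLS fixed effects and BLUP breeding values at the stored variance
# components. EBVs cover every animal in each relationship matrix,
# including unphenotyped ones (information flows through C).
blup_solve <- function(fit, varcomp = fit$varcomp) {
  k <- length(fit$K)
  n <- length(fit$y)
  s2 <- varcomp
  V <- diag(s2[k + 1L], n)
  for (r in seq_len(k)) V <- V + s2[r] * fit$K[[r]]
  ch <- chol(V)
  Vi_y <- backsolve(ch, forwardsolve(t(ch), fit$y))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), fit$X))
  XtVX <- crossprod(fit$X, Vi_X)
  ch2 <- try(chol(XtVX), silent = TRUE)
  if (inherits(ch2, "try-error"))
    stop("singular fixed-effect system; confounded columns: ",
         paste(colnames(fit$X), collapse = ", "))
  beta <- drop(backsolve(ch2, forwardsolve(t(ch2), crossprod(fit$X, Vi_y))))
  names(beta) <- colnames(fit$X)
  e <- fit$y - drop(fit$X %*% beta)
  Vi_e <- backsolve(ch, forwardsolve(t(ch), e))
  ebv <- lapply(seq_len(k), function(r) {
    cr <- unclass(fit$C[[r]])
    # Z_r' V^-1 e accumulated per animal column
    zve <- numeric(nrow(cr))
    tab <- rowsum(Vi_e, fit$idx[[r]])
    zve[as.integer(rownames(tab))] <- tab
    stats::setNames(drop(s2[r] * cr %*% zve), rownames(cr))
  })
  names(ebv) <- names(fit$K)
  u_rec <- 0
  for (r in seq_len(k)) u_rec <- u_rec + ebv[[r]][fit$animal]
  list(beta = beta, ebv = ebv,
       fitted = drop(fit$X %*% beta) + unname(u_rec))
}

#' BLUP breeding values at given variance components
#'
#' Solves the generalized-least-squares / conditional-expectation equations
#' \eqn{\hat\beta = (X'V^{-1}X)^{-1}X'V^{-1}y} and
#' \eqn{\hat u_r = \sigma^2_{u_r} C_r Z_r' V^{-1}(y - X\hat\beta)} at the
#' variance components stored in the fit (or supplied). EBVs are returned
#' for every animal in each relationship matrix, including animals without
#' phenotypes.
#'
#' @param fit a \code{\link{reml_fit}} object.
#' @param varcomp optional variance components to use instead of the REML
#'   estimates (named, residual last).
#' @return list with \code{beta} (fixed effects) and \code{ebv} (a named
#'   vector per random term).
#' @export
blup_ebv <- function(fit, varcomp = fit$varcomp) {
  stopifnot(inherits(fit, "reml_fit"))
  sol <- blup_solve(fit, varcomp)
  list(beta = sol$beta, ebv = sol$ebv)
}

#' Missing heritability
#'
#' The fraction of pedigree-defined additive genetic variance not captured
#' by the marker-based relationship matrix, from a model fitting both a
#' pedigree kernel and a marker kernel:
#' \deqn{C_{miss} = 1 - \frac{\sigma^2_u}{\sigma^2_a + \sigma^2_u}}
#' with \eqn{\sigma^2_a} the pedigree (NRM) variance and \eqn{\sigma^2_u}
#' the marker (GRM/CRM) variance.
#'
#' @param var_pedigree \eqn{\sigma^2_a}.
#' @param var_marker \eqn{\sigma^2_u}.
#' @return value in \eqn{[0, 1]} for non-negative inputs.
#' @examples
#' missing_heritability(113.9303, 129.9348)  # 0.467
#' @export
missing_heritability <- function(var_pedigree, var_marker) {
  tot <- var_pedigree + var_marker
  if (any(tot <= 0)) stop("variance components sum to zero; C_miss undefined")
  1 - var_marker / tot
}

#' Cross-validation accuracy of breeding-value prediction
#'
#' Repeatedly sets a random fraction of phenotypes to missing, refits the
#' model on the remaining records, predicts breeding values for the held-out
#' animals through the relationship matrices, and correlates the predicted
#' EBV (summed over random terms) with the held-out phenotypes adjusted by
#' the training-fit fixed effects (\eqn{y - X\hat\beta}). Splits whose
#' held-out adjusted phenotypes or EBVs have zero variance are skipped and
#' counted.
#'
#' @param fit a \code{\link{reml_fit}} object.
#' @param n_splits number of random splits (default 20).
#' @param holdout fraction of records held out per split (default 0.2).
#' @param seed RNG seed; fixed seed gives identical results.
#' @return list with \code{mean}, \code{sd}, the per-split
#'   \code{accuracies}, and the number of \code{skipped} splits.
#' @export
cv_accuracy <- function(fit, n_splits = 20, holdout = 0.2, seed = 1) {
  stopifnot(inherits(fit, "reml_fit"))
  n <- length(fit$y)
  m <- max(1L, round(holdout * n))
  set.seed(seed)
  accs <- rep(NA_real_, n_splits)
  skipped <- 0L
  for (s in seq_len(n_splits)) {
    hold <- sample.int(n, m)
    train <- setdiff(seq_len(n), hold)
    sub <- subset_fit(fit, train)
    refit <- reml_core(sub)
    sol <- blup_solve(refit)
    ebv_hold <- 0
    for (r in seq_along(fit$K))
      ebv_hold <- ebv_hold + sol$ebv[[r]][fit$animal[hold]]
    Xh <- fit$X[hold, colnames(refit$X), drop = FALSE]
    adj <- fit$y[hold] - drop(Xh %*% sol$beta)
    if (stats::sd(adj) == 0 || stats::sd(ebv_hold) == 0) {
      skipped <- skipped + 1L
      message("split ", s, " skipped: zero variance in holdout")
      next
    }
    accs[s] <- stats::cor(unname(ebv_hold), adj)
  }
  ok <- !is.na(accs)
  list(mean = mean(accs[ok]), sd = stats::sd(accs[ok]),
       accuracies = accs, skipped = skipped)
}

# Restrict a fit's data objects to a subset of records (keeps the full C
# matrices so EBVs can be predicted for held-out animals).
subset_fit <- function(fit, rows) {
  X <- fit$X[rows, , drop = FALSE]
  qx <- qr(X)
  if (qx$rank < ncol(X)) X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  out <- list(y = fit$y[rows], X = X,
              K = lapply(seq_along(fit$K), function(r)
                unclass(fit$C[[r]])[fit$idx[[r]][rows], fit$idx[[r]][rows],
                                    drop = FALSE]),
              C = fit$C,
              idx = lapply(fit$idx, `[`, rows),
              animal = fit$animal[rows],
              varcomp = fit$varcomp)
  names(out$K) <- names(fit$K)
  out
}

# REML estimation on a prepared (y, X, K) system; shares the objective with
# reml_fit but skips input wrangling. Used by cross-validation refits.
reml_core <- function(sys, max_restarts = 5) {
  y <- sys$y; X <- sys$X; K <- sys$K
  n <- length(y); k <- length(K)
  vy <- stats::var(y)
  theta0 <- log(rep(vy / (k + 1), k + 1))
  if (k == 1L) {
    ek <- eigen(K[[1L]], symmetric = TRUE)
    lam <- pmax(ek$values, 0)
    yr <- crossprod(ek$vectors, y)
    Xr <- crossprod(ek$vectors, X)
    negll <- function(theta) {
      d <- exp(theta[1L]) * lam + exp(theta[2L])
      if (any(d <= 0)) return(1e10)
      -reml_ll_diag(d, yr, Xr)
    }
  } else {
    negll <- function(theta) {
      s2 <- exp(theta)
      V <- diag(s2[k + 1L], n)
      for (r in seq_len(k)) V <- V + s2[r] * K[[r]]
      ll <- try(reml_ll_dense(V, y, X), silent = TRUE)
      if (inherits(ll, "try-error") || !is.finite(ll)) return(1e10)
      -ll
    }
  }
  theta <- theta0
  val <- negll(theta)
  converged <- FALSE
  for (rs in seq_len(max_restarts)) {
    opt <- stats::optim(theta, negll, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    dll <- val - opt$value
    dpar <- max(abs(opt$par - theta))
    theta <- opt$par; val <- opt$value
    if (dll >= 0 && dll < 1e-8 && dpar < 1e-6) { converged <- TRUE; break }
  }
  out <- sys
  out$varcomp <- stats::setNames(exp(theta), c(names(K), "residual"))
  out$loglik <- -val
  out$converged <- converged
  class(out) <- "reml_fit"
  out
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("Relationship-matrix mixed model (REML)\n")
  k <- length(x$K)
  vp <- sum(x$varcomp)
  tab <- data.frame(variance = x$varcomp,
                    proportion = x$varcomp / vp)
  print(round(tab, 4))
  cat(sprintf("Phenotypic variance: %.4f\n", vp))
  cat(sprintf("Restricted log-likelihood: %.4f (%s, %d evaluations)\n",
              x$loglik, if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' @export
summary.reml_fit <- function(object, ...) {
  vp <- sum(object$varcomp)
  out <- list(varcomp = object$varcomp, vp = vp,
              h2 = object$varcomp[-length(object$varcomp)] / vp,
              beta = object$beta, loglik = object$loglik,
              converged = object$converged, n = length(object$y))
  class(out) <- "summary.reml_fit"
  out
}

#' @export
print.summary.reml_fit <- function(x, ...) {
  cat(sprintf("REML fit on %d records%s\n", x$n,
              if (x$converged) "" else " (NOT converged)"))
  cat("\nVariance components:\n")
  print(round(x$varcomp, 4))
  cat(sprintf("Phenotypic variance: %.4f\n", x$vp))
  cat("\nVariance ratios (h2 per kernel):\n")
  print(round(x$h2, 4))
  cat("\nFixed effects:\n")
  print(round(x$beta, 4))
  cat(sprintf("\nRestricted log-likelihood: %.4f\n", x$loglik))
  invisible(x)
}

#' @export
coef.reml_fit <- function(object, ...) object$beta

#' @export
logLik.reml_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$varcomp),
            nobs = length(object$y), class = "logLik")
}

#' @export
residuals.reml_fit <- function(object, ...) object$residuals

#' @export
fitted.reml_fit <- function(object, ...) object$fitted

#' Predictions from a REML fit
#'
#' @param object a \code{\link{reml_fit}}.
#' @param type \code{"response"}: fitted values \eqn{X\hat\beta + \sum_r
#'   Z_r\hat u_r} for the model records; \code{"ebv"}: total estimated
#'   breeding value (sum over random terms) for every animal known to the
#'   relationship matrices.
#' @param ... unused.
#' @export
predict.reml_fit <- function(object, type = c("response", "ebv"), ...) {
  type <- match.arg(type)
  if (type == "response") return(object$fitted)
  ids <- Reduce(union, lapply(object$ebv, names))
  tot <- stats::setNames(numeric(length(ids)), ids)
  for (u in object$ebv) tot[names(u)] <- tot[names(u)] + u
  tot
}

#' @export
ranef <- function(object, ...) UseMethod("ranef")

#' @export
ranef.reml_fit <- function(object, ...) object$ebv

#' @export
simulate.reml_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  k <- length(object$K)
  n <- length(object$y)
  V <- diag(object$varcomp[k + 1L], n)
  for (r in seq_len(k)) V <- V + object$varcomp[r] * object$K[[r]]
  ch <- chol(V + diag(1e-10, n))
  mu <- drop(object$X %*% object$beta)
  out <- as.data.frame(sapply(seq_len(nsim), function(i)
    mu + drop(crossprod(ch, rnorm(n)))))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.reml_fit <- function(x, ...) {
  adj <- x$y - drop(x$X %*% x$beta)
  u <- x$fitted - drop(x$X %*% x$beta)
  graphics::plot(u, adj, xlab = "total EBV (record level)",
                 ylab = "phenotype adjusted for fixed effects",
                 main = "BLUP fit", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
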