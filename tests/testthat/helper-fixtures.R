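# Shared fixtures and independent oracles used across test files.

# The five printed 30-SNP run-length genotype strings, expanded by hand here
# (independently of toy_fixture()) so the fixture itself is testable.
toy_strings <- c(
  A1 = "000000000011111111112222222222",
  A2 = "222000000000011111111112222222",
  A3 = "000111222000111222000111222012",
  A4 = "000112221000112221000112221012",
  A5 = "012012012012012012012012012012"
)

string_to_calls <- function(s) as.integer(strsplit(s, "")[[1]])

# Random genotype matrix in HWE at uniform frequencies.
random_genotypes <- function(n, l, seed = 1, fmin = 0.1, fmax = 0.9) {
  set.seed(seed)
  p <- runif(l, fmin, fmax)
  genotype_matrix(matrix(rbinom(n * l, 2, rep(p, each = n)), nrow = n))
}

# Independent pedigree oracle: recursive kinship coefficients, a_ij = 2*phi.
# Deliberately a different algorithm from the package's tabular method.
kinship_oracle <- function(ped) {
  ids <- ped$animal
  sire <- ped$sire; dam <- ped$dam
  phi_memo <- new.env()
  phi <- function(i, j) {
    if (i == "0" || j == "0") return(0)
    key <- paste(sort(c(i, j)), collapse = "|")
    if (!is.null(phi_memo[[key]])) return(phi_memo[[key]])
    oi <- match(i, ids); oj <- match(j, ids)
    val <- if (i == j) {
      0.5 * (1 + phi(sire[oi], dam[oi]))
    } else if (oi < oj) {
      0.5 * (phi(i, sire[oj]) + phi(i, dam[oj]))
    } else {
      0.5 * (phi(j, sire[oi]) + phi(j, dam[oi]))
    }
    phi_memo[[key]] <- val
    val
  }
  n <- length(ids)
  a <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in i:n)
    a[i, j] <- a[j, i] <- 2 * phi(ids[i], ids[j])
  a
}

# Independent dense REML restricted log-likelihood: explicit V, determinant()
# and solve() throughout (no Cholesky shortcuts shared with the package).
reml_oracle_ll <- function(varcomp, y, X, K_list) {
  n <- length(y); p <- ncol(X)
  k <- length(K_list)
  V <- diag(varcomp[k + 1], n)
  for (r in seq_len(k)) V <- V + varcomp[r] * K_list[[r]]
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  e <- y - X %*% beta
  as.numeric(-0.5 * ((n - p) * log(2 * pi) +
                     determinant(V, logarithm = TRUE)$modulus +
                     determinant(XtViX, logarithm = TRUE)$modulus +
                     t(e) %*% Vi %*% e))
}

# Direct (GLS / conditional expectation) BLUP oracle.
blup_oracle <- function(varcomp, y, X, K_list, C_list, Z_list) {
  n <- length(y)
  k <- length(K_list)
  V <- diag(varcomp[k + 1], n)
  for (r in seq_len(k)) V <- V + varcomp[r] * K_list[[r]]
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  e <- y - X %*% beta
  u <- lapply(seq_len(k), function(r)
    as.numeric(varcomp[r] * C_list[[r]] %*% t(Z_list[[r]]) %*% Vi %*% e))
  list(beta = as.numeric(beta), u = u)
}

# Weir-Cockerham two-population FST oracle: scalar transcription of the
# ANOVA estimator for samples of alleles.
wc_fst_oracle <- function(p1, p2, n1, n2) {
  r <- 2
  nbar <- mean(c(n1, n2))
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r)
  a / (a + b)
}
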