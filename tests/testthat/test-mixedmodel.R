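make_small_system <- function(n = 15, seed = 2, h2 = 0.5) {
  set.seed(seed)
  C <- crossprod(matrix(rnorm(n * n), n)) / n
  C <- C / mean(diag(C))
  ids <- paste0("A", seq_len(n))
  dimnames(C) <- list(ids, ids)
  K <- relmat(C)
  ph <- simulate_phenotype(K, h2 = h2, seed = seed)
  list(K = K, ph = ph, ids = ids)
}

test_that("restricted log-likelihood agrees with a dense oracle to 1e-6", {
  sys <- make_small_system(n = 15, seed = 3)
  fit <- reml_fit(y ~ cg, data = sys$ph, random = list(k = sys$K))
  X <- fit$X
  ll_pkg <- fit$loglik
  ll_oracle <- reml_oracle_ll(unname(fit$varcomp), fit$y, X,
                              list(unclass(sys$K)))
  expect_equal(ll_pkg, ll_oracle, tolerance = 1e-6)
  # the oracle's own optimum does not beat the package optimum materially
  opt <- optim(log(rep(var(fit$y) / 2, 2)), function(th)
    -reml_oracle_ll(exp(th), fit$y, X, list(unclass(sys$K))),
    method = "Nelder-Mead", control = list(maxit = 2000, reltol = 1e-12))
  expect_gte(ll_pkg, -opt$value - 1e-5)
})

test_that("two-kernel fits agree with the dense oracle", {
  sys <- make_small_system(n = 18, seed = 8)
  I <- relmat(diag(18), animal_ids = sys$ids)
  fit <- reml_fit(y ~ cg, data = sys$ph, random = list(k = sys$K, iid = I))
  ll_oracle <- reml_oracle_ll(unname(fit$varcomp), fit$y, fit$X,
                              list(unclass(sys$K), diag(18)))
  expect_equal(fit$loglik, ll_oracle, tolerance = 1e-6)
})

test_that("BLUP solutions match the direct matrix-inverse oracle", {
  # 5-animal system with C = identity: hand-solvable mixed-model equations
  ids <- paste0("A", 1:5)
  C <- relmat(diag(5), animal_ids = ids)
  dat <- data.frame(animal = ids, y = c(10, 12, 9, 14, 11),
                    cg = factor(c(1, 1, 2, 2, 1)))
  fit <- reml_fit(y ~ cg, data = dat, random = list(iid = C))
  vc <- c(2, 3)  # fixed variance components for the oracle comparison
  sol <- blup_ebv(fit, varcomp = setNames(vc, c("iid", "residual")))
  Z <- diag(5)
  oracle <- blup_oracle(vc, fit$y, fit$X, list(diag(5)), list(diag(5)),
                        list(Z))
  expect_equal(unname(sol$beta), oracle$beta, tolerance = 1e-8)
  expect_equal(unname(sol$ebv$iid), oracle$u[[1]], tolerance = 1e-8)
})

test_that("zero genetic variance gives zero EBVs everywhere", {
  sys <- make_small_system(n = 10, seed = 5)
  fit <- reml_fit(y ~ 1, data = sys$ph, random = list(k = sys$K))
  sol <- blup_ebv(fit, varcomp = setNames(c(0, 5), c("k", "residual")))
  expect_equal(unname(sol$ebv$k), rep(0, 10))
})

test_that("an unphenotyped animal gets a nonzero EBV through relatives", {
  sim <- simulate_pedigree_population(n_families = 8, family_size = 4,
                                      n_loci = 800, seed = 6)
  G <- grm(sim$genotypes)
  ph <- simulate_phenotype(G, h2 = 0.5, seed = 6)
  ph$y[ph$animal == sim$offspring_ids[1]] <- NA  # drop one animal's record
  fit <- reml_fit(y ~ cg, data = ph, random = list(grm = G))
  ebv <- blup_ebv(fit)$ebv$grm
  expect_false(sim$offspring_ids[1] %in% fit$animal)
  expect_gt(abs(ebv[[sim$offspring_ids[1]]]), 1e-6)
})

test_that("aliased random terms trigger an identifiability warning", {
  ids <- paste0("A", 1:12)
  I <- relmat(diag(12), animal_ids = ids)
  set.seed(1)
  dat <- data.frame(animal = ids, y = rnorm(12), cg = factor(rep(1:2, 6)))
  expect_warning(reml_fit(y ~ 1, data = dat, random = list(a = I, b = I)),
                 "identical covariance kernels")
})

test_that("non-PSD relationship matrices are bent with a warning", {
  ids <- paste0("A", 1:6)
  M <- diag(6); M[1, 2] <- M[2, 1] <- 1.2   # indefinite
  set.seed(2)
  dat <- data.frame(animal = ids, y = rnorm(6, 10))
  expect_warning(reml_fit(y ~ 1, data = dat,
                          random = list(m = relmat(M, animal_ids = ids))),
                 "bending")
  expect_error(reml_fit(y ~ 1, data = dat,
                        random = list(m = relmat(M, animal_ids = ids)),
                        bend = "error"),
               "positive semi-definite")
})

test_that("REML recovers a simulated heritability of 0.4 at n = 800", {
  h2s <- vapply(41:43, function(seed) {
    sim <- simulate_pedigree_population(n_families = 160, family_size = 5,
                                        n_loci = 2000, seed = seed)
    off <- sim$offspring_ids
    G <- grm(sim$genotypes[off, ])
    ph <- simulate_phenotype(G, h2 = 0.4, seed = seed)
    fit <- reml_fit(y ~ cg, data = ph, random = list(grm = G))
    expect_true(fit$converged)
    unname(fit$varcomp["grm"] / sum(fit$varcomp))
  }, 0)
  expect_lt(abs(mean(h2s) - 0.4), 0.08)
})

test_that("pure-noise phenotypes drive the genetic variance to the boundary", {
  set.seed(9)
  ids <- paste0("A", 1:120)
  C <- relmat(diag(120), animal_ids = ids)
  g <- random_genotypes(120, 400, seed = 9)
  G <- grm(g)
  dat <- data.frame(animal = rownames(g), y = rnorm(120, 50, 3))
  fit <- reml_fit(y ~ 1, data = dat, random = list(grm = G))
  expect_lt(fit$varcomp["grm"] / sum(fit$varcomp), 0.15)
})

test_that("optimizer never ends below its starting likelihood", {
  sys <- make_small_system(n = 12, seed = 13)
  fit <- reml_fit(y ~ cg, data = sys$ph, random = list(k = sys$K))
  vy <- var(fit$y)
  start_ll <- reml_oracle_ll(rep(vy / 2, 2), fit$y, fit$X,
                             list(unclass(sys$K)))
  expect_gte(fit$loglik, start_ll - 1e-8)
})

test_that("missing heritability reproduces the published two-kernel table", {
  # variance components printed for the NRM + marker-kernel models in the
  # two cattle populations, and the published C_miss values
  vn <- c(113.9303, 123.3128, 118.5415, 142.6249,
          143.7108, 149.6712, 146.6484, 183.6592)
  vm <- c(129.9348, 78.3912, 140.8651, 64.2163,
          159.4054, 98.5048, 165.8576, 76.0604)
  printed <- c(0.467, 0.611, 0.457, 0.689, 0.474, 0.603, 0.469, 0.707)
  got <- missing_heritability(vn, vm)
  # all entries within one unit in the third decimal (the published inputs
  # are themselves rounded)
  expect_true(all(abs(got - printed) <= 1e-3))
  expect_equal(missing_heritability(10, 10), 0.5)
  expect_equal(missing_heritability(10, 0), 1)
  expect_error(missing_heritability(0, 0), "undefined")
})

test_that("cross-validation is seeded, reproducible, and null under permutation", {
  sim <- simulate_pedigree_population(n_families = 40, family_size = 5,
                                      n_loci = 1200, seed = 23)
  off <- sim$offspring_ids
  G <- grm(sim$genotypes[off, ])
  ph <- simulate_phenotype(G, h2 = 0.4, seed = 23)
  fit <- reml_fit(y ~ cg, data = ph, random = list(grm = G))
  cv1 <- cv_accuracy(fit, n_splits = 8, seed = 101)
  cv2 <- cv_accuracy(fit, n_splits = 8, seed = 101)
  expect_identical(cv1, cv2)
  expect_gt(cv1$mean, 0)
  # permuting phenotypes against genotypes voids the accuracy
  set.seed(77)
  php <- ph
  php$y <- sample(php$y)
  fitp <- reml_fit(y ~ cg, data = php, random = list(grm = G))
  cvp <- cv_accuracy(fitp, n_splits = 10, seed = 55)
  se <- cvp$sd / sqrt(sum(!is.na(cvp$accuracies)))
  expect_lt(abs(cvp$mean), 2.5 * se + 0.05)
})

test_that("model methods expose coefficients, fits and simulations", {
  sys <- make_small_system(n = 20, seed = 30)
  fit <- reml_fit(y ~ cg, data = sys$ph, random = list(k = sys$K))
  expect_named(coef(fit))
  expect_length(fitted(fit), 20)
  expect_equal(unname(residuals(fit)), unname(fit$y - fitted(fit)))
  expect_s3_class(summary(fit), "summary.reml_fit")
  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(20L, 3L))
  ebv <- predict(fit, type = "ebv")
  expect_length(ebv, 20)
  expect_output(print(fit), "REML")
})
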