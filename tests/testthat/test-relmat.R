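toy <- toy_fixture()

test_that("allele frequencies and VanRaden denominator match hand counts", {
  p <- allele_frequencies(toy$genotypes)
  expect_equal(unname(p[1]), 0.2)     # calls 0,2,0,0,0
  expect_equal(attr(p, "denom"), 11.32, tolerance = 1e-12)
  mono <- genotype_matrix(rbind(c(0, 1), c(0, 1)))
  expect_equal(unname(allele_frequencies(mono)[1]), 0)
  allmiss <- genotype_matrix(rbind(c(-9, 1), c(-9, 1)))
  expect_error(allele_frequencies(allmiss), "locus")
})

test_that("toy GRM reproduces the worked-example anchors at 2 decimals", {
  G <- grm(toy$genotypes)
  expect_equal(round(G["A1", "A2"], 2), 0.35)
  expect_equal(round(G["A3", "A4"], 2), 0.67)
  expect_equal(round(G["A2", "A3"], 2), -0.67)
  # brute-force oracle: explicit loops over the printed strings
  m <- t(vapply(toy_strings, string_to_calls, integer(30)))
  p <- colSums(m) / (2 * nrow(m))
  denom <- 2 * sum(p * (1 - p))
  oracle <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5)
    oracle[i, j] <- sum((m[i, ] - 2 * p) * (m[j, ] - 2 * p)) / denom
  expect_equal(unclass(G), oracle, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("GRM is symmetric PSD and invariant to locus permutation", {
  g <- random_genotypes(12, 500, seed = 4)
  G <- grm(g)
  expect_identical(unclass(G), t(unclass(G)))
  expect_gte(min(eigen(unclass(G), symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  perm <- sample(ncol(g))
  expect_equal(unclass(grm(g[, perm])), unclass(G), tolerance = 1e-12)
  monog <- genotype_matrix(rbind(c(2, 2), c(2, 2)))
  expect_error(grm(monog), "monomorphic")
})

test_that("tabular NRM matches the recursive kinship oracle", {
  ped <- data.frame(
    animal = c("F1", "F2", "F3", "X", "Y", "Z", "W"),
    sire   = c("0", "0", "0", "F1", "F1", "X", "X"),
    dam    = c("0", "0", "0", "F2", "F2", "Y", "Z"),
    stringsAsFactors = FALSE
  )
  A <- nrm(ped)
  expect_equal(unclass(A), kinship_oracle(comprel:::validate_pedigree(ped)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # anchors: founders unrelated, parent-offspring 0.5, full sibs 0.5
  expect_equal(A["F1", "F2"], 0)
  expect_equal(A["F1", "X"], 0.5)
  expect_equal(A["X", "Y"], 0.5)
  # Z is the offspring of full sibs: inbred
  expect_equal(A["Z", "Z"], 1.25)
  # unrelated founders give the identity
  founders <- data.frame(animal = c("a", "b", "c"), sire = "0", dam = "0")
  expect_equal(unclass(nrm(founders)), diag(3), ignore_attr = TRUE)
})

test_that("offspring of a parent-offspring mating has diagonal 1.25", {
  ped <- data.frame(animal = c("P", "Q", "R"),
                    sire = c("0", "P", "P"),
                    dam = c("0", "0", "Q"))
  A <- nrm(ped)
  expect_equal(A["R", "R"], 1.25)
  expect_equal(A["P", "Q"], 0.5)
})

test_that("generation truncation turns distant ancestors into founders", {
  ped <- data.frame(animal = c("G0", "G1", "G2", "G3"),
                    sire = c("0", "G0", "G1", "G2"),
                    dam = c("0", "0", "0", "0"))
  full <- nrm(ped)
  expect_equal(full["G0", "G3"], 0.125)
  cut <- nrm(ped, max_generations = 2)
  expect_equal(cut["G0", "G3"], 0)          # link above the window severed
  expect_equal(cut["G2", "G3"], 0.5)        # recent links intact
})

test_that("CRM1 is the Shepard transform with strict monotonicity", {
  d <- matrix(c(0.05, 0.3, 0.3, 0.06), 2, 2)
  s <- crm1(d)
  expect_equal(unclass(s)[1, 1], 2.5 * exp(-5 * 0.05), tolerance = 1e-12)
  expect_equal(unclass(crm1(matrix(0, 1, 1)))[1, 1], 2.5)
  expect_equal(unclass(crm1(matrix(0.118, 1, 1)))[1, 1], 1.386, tolerance = 0.01)
  dd <- seq(0, 1, by = 0.05)
  ss <- 2.5 * exp(-5 * dd)
  expect_true(all(diff(ss) < 0))
})

test_that("CRM2 scales diagonals to mean 1 and bounds off-diagonals", {
  g <- random_genotypes(8, 1200, seed = 31)
  d <- ncd_matrix(g)
  s <- crm2(d)
  # mean(d)/d averages to 1 + cv^2 + o(cv^2) over the diagonal, so the
  # deviation from 1 is bounded by the spread of the self-self distances
  dd <- diag(unclass(d))
  cv2 <- stats::var(dd) / mean(dd)^2
  expect_gte(mean(diag(unclass(s))), 1)
  expect_lt(mean(diag(unclass(s))) - 1, 3 * cv2)
  # equal self-self distances give exactly 1 on every diagonal cell
  deq <- unclass(d)
  diag(deq) <- 0.1
  expect_equal(unname(diag(unclass(crm2(deq)))), rep(1, 8))
  # off-diagonal at the all-pairs maximum maps to 0
  dm <- unclass(d)
  imax <- which(dm == max(dm), arr.ind = TRUE)[1, ]
  expect_equal(unclass(s)[imax[1], imax[2]], 0, tolerance = 1e-12)
  # under off-diagonal scope, the off-diagonal minimum maps to coef
  s2 <- crm2(d, range_scope = "offdiag")
  off <- dm; diag(off) <- NA
  imin <- which(off == min(off, na.rm = TRUE), arr.ind = TRUE)[1, ]
  expect_equal(unclass(s2)[imin[1], imin[2]], 1.75, tolerance = 1e-12)
  # off-diagonal strictly decreasing in d
  ord <- order(dm[upper.tri(dm)])
  sv <- unclass(s)[upper.tri(dm)]
  expect_true(all(diff(sv[ord]) <= 0))
  expect_error(crm2(matrix(0.2, 3, 3)), "degenerate")
})

test_that("CRM3 correlates window-CE profiles", {
  g <- random_genotypes(6, 600, seed = 17)
  s <- crm3(g, window_size = 50)
  expect_equal(unname(diag(unclass(s))), rep(1, 6))
  # duplicated animal: identical window-CE vectors correlate to 1
  calls <- rbind(unclass(g), dup = unclass(g)[2, ])
  rownames(calls) <- c(rownames(g), "dup")
  s2 <- crm3(genotype_matrix(calls), window_size = 50)
  expect_equal(unclass(s2)["A2", "dup"], 1, tolerance = 1e-12)
  # window permutation applied to all animals leaves CRM3 unchanged
  ce <- window_ce_matrix(g, 50)
  perm <- sample(ncol(ce))
  expect_equal(suppressWarnings(stats::cor(t(ce[, perm]))),
               suppressWarnings(stats::cor(t(ce))), tolerance = 1e-12)
})

test_that("locus permutation changes CRM3 but not GRM", {
  # constructed contrast: two animals whose genotypes agree locus-wise but
  # whose haplotype-like block structure differs after locus shuffling
  set.seed(8)
  g <- random_genotypes(5, 400, seed = 77)
  perm <- sample(ncol(g))
  G1 <- grm(g); G2 <- grm(g[, perm])
  expect_equal(unclass(G1), unclass(G2), tolerance = 1e-12)
  s1 <- crm3(g, window_size = 40)
  s2 <- crm3(g[, perm], window_size = 40)
  expect_gt(max(abs(unclass(s1) - unclass(s2))), 1e-4)
})

test_that("anti-correlated CE profiles reach the -1 correlation bound", {
  a <- c(0.1, 0.5, 0.2, 0.6)
  expect_equal(stats::cor(a, 0.7 - a), -1)
})

test_that("pedigree-class summaries report count, mean, SD, min, max", {
  idm <- relmat(diag(3), kind = "NRM", animal_ids = c("a", "b", "c"))
  tab <- summarize_by_pedigree_class(idm, idm)
  expect_equal(tab$nrm_value, c(0, 1))
  expect_equal(tab$mean, c(0, 1))
  expect_equal(tab$sd, c(0, 0))
  # a class with a single pair reports SD 0
  n1 <- relmat(matrix(c(1, 0.5, 0.5, 1), 2), kind = "NRM",
               animal_ids = c("x", "y"))
  m1 <- relmat(matrix(c(1.02, 0.48, 0.48, 0.97), 2), animal_ids = c("x", "y"))
  tab1 <- summarize_by_pedigree_class(n1, m1)
  expect_equal(tab1$sd[tab1$nrm_value == 0.5], 0)
  expect_equal(tab1$n[tab1$nrm_value == 0.5], 1)
  bad <- relmat(diag(2), animal_ids = c("p", "q"))
  expect_error(summarize_by_pedigree_class(idm, bad), "ids")
})

test_that("simulated half-sib GRM entries centre on the 0.25 expectation", {
  sim <- simulate_pedigree_population(n_families = 20, family_size = 4,
                                      design = "halfsib", n_loci = 1500,
                                      seed = 12)
  A <- nrm(sim$pedigree)
  G <- grm(sim$genotypes)
  off <- sim$offspring_ids
  tab <- summarize_by_pedigree_class(
    relmat(unclass(A)[off, off], kind = "NRM", animal_ids = off),
    relmat(unclass(G)[off, off], animal_ids = off))
  hs <- tab[tab$nrm_value == 0.25, ]
  expect_equal(hs$n, 20 * choose(4, 2))
  expect_lt(abs(hs$mean - 0.25), 0.04)
})
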