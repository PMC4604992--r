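hwe_genotypes <- function(n, p) {
  matrix(rbinom(n * length(p), 2L, rep(p, each = n)), nrow = n)
}

# One recombinant gamete per row of the parental haplotype pair. The gamete
# follows a Markov switch process along the loci: it starts on a random
# parental haplotype and crosses over between adjacent loci with probability
# `recomb`. recomb = 0.5 reproduces independent (unlinked) transmission.
drop_gametes_hap <- function(h1, h2, recomb) {
  n <- nrow(h1); l <- ncol(h1)
  start <- sample.int(2L, n, replace = TRUE) - 1L
  if (l > 1L) {
    switches <- matrix(rbinom(n * (l - 1L), 1L, recomb), nrow = n)
    hapidx <- (start + cbind(0L, t(apply(switches, 1L, cumsum)))) %% 2L
  } else {
    hapidx <- matrix(start, ncol = 1L)
  }
  ifelse(hapidx == 0L, h1, h2)
}

#' Simulate a genotyped pedigree population by gene-dropping
#'
#' Founders are drawn in Hardy--Weinberg proportions from a uniform allele
#' frequency spectrum; offspring genotypes are the sum of one Mendelian
#' gamete from each parent (unlinked loci). Two family designs are built in:
#' half-sib families (one sire mated to \code{family_size} unrelated dams,
#' one offspring each, so offspring of a sire are half sibs) and full-sib
#' families (one sire x one dam with \code{family_size} offspring). The
#' defaults mirror a livestock half-sib structure at a reduced scale.
#'
#' @param n_families number of families (default 40).
#' @param family_size offspring per family (default 5).
#' @param design \code{"halfsib"} (default), \code{"fullsib"}, or
#'   \code{"mixed"} (each sire mated to two dams: \code{family_size}
#'   full-sib offspring from the first dam plus one half-sib offspring from
#'   the second, so one population contains full-sib, half-sib and
#'   unrelated pairs).
#' @param n_loci number of SNP loci (default 5000).
#' @param freq_range founder allele-frequency spectrum, uniform on this
#'   interval (default \code{c(0.05, 0.95)}).
#' @param n_extra_founders additional unrelated genotyped founders to
#'   include (default 0).
#' @param recomb recombination fraction between adjacent loci during
#'   transmission. The default 0.5 makes loci unlinked (minimum Monte Carlo
#'   variance for relatedness expectations); small values (e.g. 0.002)
#'   produce the long shared haplotype blocks that compression-based
#'   relatedness exploits.
#' @param seed RNG seed; fully determines the output.
#' @return list with \code{genotypes} (founders + offspring), a matching
#'   \code{pedigree}, the founder allele frequencies \code{p}, and
#'   \code{offspring_ids} / \code{family} bookkeeping.
#' @export
simulate_pedigree_population <- function(n_families = 40, family_size = 5,
                                         design = c("halfsib", "fullsib", "mixed"),
                                         n_loci = 5000,
                                         freq_range = c(0.05, 0.95),
                                         n_extra_founders = 0,
                                         recomb = 0.5,
                                         seed = 1) {
  design <- match.arg(design)
  if (n_families < 1 || family_size < 1)
    stop("invalid family design: need at least one family of size >= 1")
  stopifnot(recomb > 0, recomb <= 0.5)
  set.seed(seed)
  p <- runif(n_loci, freq_range[1L], freq_range[2L])
  n_sires <- n_families
  n_dams <- switch(design,
                   halfsib = n_families * family_size,
                   fullsib = n_families,
                   mixed = 2L * n_families)
  sire_ids <- sprintf("S%03d", seq_len(n_sires))
  dam_ids <- sprintf("D%03d", seq_len(n_dams))
  extra_ids <- if (n_extra_founders > 0)
    sprintf("F%03d", seq_len(n_extra_founders)) else character(0)
  hap <- function(n) matrix(rbinom(n * n_loci, 1L, rep(p, each = n)), nrow = n)
  sires_h1 <- hap(n_sires); sires_h2 <- hap(n_sires)
  dams_h1 <- hap(n_dams); dams_h2 <- hap(n_dams)
  sires <- sires_h1 + sires_h2
  dams <- dams_h1 + dams_h2
  extras <- if (n_extra_founders > 0) hwe_genotypes(n_extra_founders, p)
  per_fam <- if (design == "mixed") family_size + 1L else family_size
  n_off <- n_families * per_fam
  off_ids <- sprintf("O%03d", seq_len(n_off))
  off_sire <- rep(seq_len(n_sires), each = per_fam)
  off_dam <- switch(design,
    halfsib = seq_len(n_dams),
    fullsib = rep(seq_len(n_dams), each = family_size),
    # mixed: family_size offspring from dam 2f-1 (full sibs), one from dam 2f
    mixed = as.integer(sapply(seq_len(n_families), function(f)
      c(rep(2L * f - 1L, family_size), 2L * f)))
  )
  off <- drop_gametes_hap(sires_h1[off_sire, , drop = FALSE],
                          sires_h2[off_sire, , drop = FALSE], recomb) +
         drop_gametes_hap(dams_h1[off_dam, , drop = FALSE],
                          dams_h2[off_dam, , drop = FALSE], recomb)
  calls <- rbind(sires, dams, if (n_extra_founders > 0) extras, off)
  ids <- c(sire_ids, dam_ids, extra_ids, off_ids)
  g <- genotype_matrix(calls, animal_ids = ids,
                       locus_ids = paste0("L", seq_len(n_loci)))
  ped <- data.frame(
    animal = ids,
    sire = c(rep("0", n_sires + n_dams + n_extra_founders),
             sire_ids[off_sire]),
    dam = c(rep("0", n_sires + n_dams + n_extra_founders),
            dam_ids[off_dam]),
    stringsAsFactors = FALSE
  )
  list(genotypes = g, pedigree = validate_pedigree(ped), p = p,
       offspring_ids = off_ids,
       family = data.frame(animal = off_ids, family = off_sire))
}

#' Simulate two diverged populations with an optional localized sweep
#'
#' Ancestral allele frequencies are drawn uniformly from \code{freq_range};
#' each population's frequencies are then drawn Balding--Nichols style,
#' \eqn{p_k \sim Beta(p(1-F)/F, (1-p)(1-F)/F)} with \eqn{F} the target FST,
#' and genotypes are sampled in Hardy--Weinberg proportions. Within the
#' sweep region (if given) population A is pushed toward fixation of one
#' haplotype: each swept locus's frequency in A is set to
#' \code{sweep_intensity} for the ancestrally major allele (so
#' heterozygosity collapses locally in A but not in B).
#'
#' @param n_per_pop individuals per population (default 100).
#' @param n_loci number of loci (default 5000).
#' @param target_fst divergence level \eqn{F} (default 0.2; 0 = none).
#' @param sweep \code{NULL} or \code{c(start, end)} locus indices of the
#'   swept region in population A.
#' @param sweep_intensity fixation level reached by the favoured allele in
#'   the swept region (default 0.95).
#' @param freq_range ancestral frequency spectrum (default
#'   \code{c(0.05, 0.95)}).
#' @param seed RNG seed.
#' @return list with genotype matrices \code{a} and \code{b}, the ancestral
#'   frequencies \code{p_anc}, realized population frequencies \code{p_a},
#'   \code{p_b}, and the \code{sweep} span.
#' @export
simulate_two_populations <- function(n_per_pop = 100, n_loci = 5000,
                                     target_fst = 0.2, sweep = NULL,
                                     sweep_intensity = 0.95,
                                     freq_range = c(0.05, 0.95), seed = 1) {
  stopifnot(target_fst >= 0, target_fst < 1)
  set.seed(seed)
  p_anc <- runif(n_loci, freq_range[1L], freq_range[2L])
  draw_pop <- function() {
    if (target_fst == 0) return(p_anc)
    f <- target_fst
    rbeta(n_loci, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
  }
  p_a <- draw_pop()
  p_b <- draw_pop()
  if (!is.null(sweep)) {
    stopifnot(length(sweep) == 2L, sweep[1L] >= 1, sweep[2L] <= n_loci,
              sweep[1L] <= sweep[2L])
    idx <- sweep[1L]:sweep[2L]
    p_a[idx] <- ifelse(p_anc[idx] >= 0.5, sweep_intensity,
                       1 - sweep_intensity)
  }
  mk <- function(pf, prefix) {
    genotype_matrix(hwe_genotypes(n_per_pop, pf),
                    animal_ids = sprintf("%s%03d", prefix, seq_len(n_per_pop)),
                    locus_ids = paste0("L", seq_len(n_loci)))
  }
  list(a = mk(p_a, "A"), b = mk(p_b, "B"),
       p_anc = p_anc, p_a = p_a, p_b = p_b, sweep = sweep)
}

#' Simulate phenotypes with a given heritability
#'
#' \eqn{y = X\beta + u + e} with the additive values \eqn{u} drawn zero-mean
#' multivariate normal with covariance \eqn{C\sigma^2_u} for a supplied
#' relationship matrix \eqn{C} (eigenvalues floored at zero for a PSD
#' square root), or built from \code{n_causal} random loci when a genotype
#' matrix is supplied. Residuals are independent normal. Fixed effects
#' default to an intercept plus a 3-level contemporary group. The defaults
#' put the phenotype on a yearling-weight-like scale (phenotypic variance
#' 350 trait-units squared, mean 300).
#'
#' @param k a \code{\link{relmat}} (multivariate-normal route) or a
#'   \code{\link{genotype_matrix}} (causal-locus route).
#' @param h2 narrow-sense heritability in \eqn{[0, 1]} (default 0.4).
#' @param var_p phenotypic variance, trait units squared (default 350).
#' @param mu intercept (default 300).
#' @param cg_effects contemporary-group effects (default
#'   \code{c(0, 15, -10)}).
#' @param n_causal number of causal loci for the genotype route (default
#'   200).
#' @param seed RNG seed.
#' @return data frame with columns \code{animal}, \code{y}, \code{cg} and
#'   the realized components \code{u} and \code{e} (for oracle checks),
#'   with the realized variance ratio attached as attribute
#'   \code{"realized_h2"}.
#' @export
simulate_phenotype <- function(k, h2 = 0.4, var_p = 350, mu = 300,
                               cg_effects = c(0, 15, -10), n_causal = 200,
                               seed = 1) {
  stopifnot(h2 >= 0, h2 <= 1)
  set.seed(seed)
  var_u <- h2 * var_p
  var_e <- (1 - h2) * var_p
  if (inherits(k, "genotype_matrix")) {
    ids <- rownames(k)
    n <- length(ids)
    u <- if (var_u > 0) {
      cl <- sort(sample.int(ncol(k), min(n_causal, ncol(k))))
      eff <- rnorm(length(cl))
      raw_u <- unclass(k)[, cl, drop = FALSE] %*% eff
      raw_u <- raw_u - mean(raw_u)
      as.numeric(raw_u) * sqrt(var_u / max(var(as.numeric(raw_u)), 1e-12))
    } else rep(0, n)
  } else {
    ids <- rownames(k)
    n <- length(ids)
    u <- if (var_u > 0) {
      ev <- eigen(unclass(k), symmetric = TRUE)
      lam <- pmax(ev$values, 0)
      as.numeric(ev$vectors %*% (sqrt(lam) * rnorm(n))) * sqrt(var_u)
    } else rep(0, n)
  }
  cg <- factor(sample(seq_along(cg_effects), n, replace = TRUE))
  e <- rnorm(n, 0, sqrt(var_e))
  y <- mu + cg_effects[as.integer(cg)] + u + e
  out <- data.frame(animal = ids, y = y, cg = cg, u = u, e = e,
                    stringsAsFactors = FALSE)
  attr(out, "realized_h2") <- if (var(u + e) > 0) var(u) / var(u + e) else NA_real_
  out
}
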