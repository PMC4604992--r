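#' Partition loci into non-overlapping windows
#'
#' Consecutive disjoint blocks of \code{window_size} loci covering the whole
#' locus list in order; the final window holds the remainder, so the window
#' count is \code{ceiling(locus_count / window_size)}.
#'
#' @param locus_count number of loci (>= 1).
#' @param window_size loci per window (>= 2).
#' @return data frame with columns \code{window}, \code{start}, \code{end}
#'   (1-based, inclusive) and \code{partial} (is the window short).
#' @examples
#' nrow(partition_windows(71726, 50))   # 1435
#' @export
partition_windows <- function(locus_count, window_size = 50) {
  locus_count <- as.integer(locus_count)
  window_size <- as.integer(window_size)
  if (is.na(locus_count) || locus_count < 1L) stop("locus_count must be >= 1")
  if (is.na(window_size) || window_size < 2L) stop("window_size must be >= 2")
  k <- ceiling(locus_count / window_size)
  start <- (seq_len(k) - 1L) * window_size + 1L
  end <- pmin(start + window_size - 1L, locus_count)
  data.frame(window = seq_len(k), start = start, end = end,
             partial = (end - start + 1L) < window_size)
}

#' Population-level window CEh
#'
#' Pools all animals' genotype strings within a window (animals concatenated
#' in id order) and computes the compression efficiency of the pooled
#' string, divided by the window's mean observed heterozygosity (mean over
#' animals of the proportion of heterozygous calls among the window's
#' non-missing loci). A window with zero heterozygosity has an undefined
#' CEh and returns \code{NA} (flagged, never an infinite value).
#'
#' @param g_pop \code{\link{genotype_matrix}} for one population.
#' @param window integer vector of locus indices (one window).
#' @param cfg a \code{\link{compressor_config}}; net-of-overhead CE is used.
#' @return CEh value or \code{NA}.
#' @export
population_window_ceh <- function(g_pop, window, cfg = compressor_config()) {
  m <- unclass(g_pop)[, window, drop = FALSE]
  het <- window_heterozygosity(m)
  if (is.na(het) || het == 0) return(NA_real_)
  cfg$net_overhead <- TRUE
  pooled <- do.call(c, lapply(seq_len(nrow(m)), function(i)
    encode_genotype_string(m[i, ], cfg$missing_char)))
  ce_of_bytes(pooled, cfg) / het
}

window_heterozygosity <- function(m) {
  hets <- apply(m, 1L, function(r) {
    ok <- r %in% c(0L, 1L, 2L)
    if (!any(ok)) return(NA_real_)
    mean(r[ok] == 1L)
  })
  mean(hets, na.rm = TRUE)
}

#' Per-SNP two-population FST
#'
#' Vectorized over loci. The default estimator is the Weir--Cockerham
#' two-population ANOVA estimator in its allele-frequency form (samples of
#' alleles; the within-individual heterozygosity terms are not used because
#' only frequencies and allele counts enter). Negative estimates are
#' retained, not truncated. Alternatives: Hudson's estimator and Nei's
#' \eqn{G_{ST}}. Loci monomorphic for the same allele in both populations
#' are defined as 0 and flagged.
#'
#' @param p1,p2 B-allele frequencies in populations 1 and 2.
#' @param n1,n2 allele sample counts (2 x number of genotyped individuals);
#'   must be >= 2.
#' @param estimator \code{"wc"} (default), \code{"hudson"} or \code{"nei"}.
#' @return numeric vector of FST estimates with logical attribute
#'   \code{"flagged"} marking jointly monomorphic loci.
#' @export
fst_snp <- function(p1, p2, n1, n2, estimator = c("wc", "hudson", "nei")) {
  estimator <- match.arg(estimator)
  stopifnot(all(n1 >= 2), all(n2 >= 2),
            all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1))
  mono <- (p1 == p2) & (p1 == 0 | p1 == 1)
  out <- switch(estimator,
    wc = {
      r <- 2
      nbar <- (n1 + n2) / 2
      nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
      pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
      s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
      a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r) / (nbar - 1))
      b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r)
      a / (a + b)
    },
    hudson = {
      num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
      den <- p1 * (1 - p2) + p2 * (1 - p1)
      num / den
    },
    nei = {
      pbar <- (p1 + p2) / 2
      hs <- p1 * (1 - p1) + p2 * (1 - p2)
      ht <- 2 * pbar * (1 - pbar)
      1 - hs / ht
    })
  out[mono] <- 0
  attr(out, "flagged") <- mono
  out
}

#' Genome-wide FST (ratio of sums)
#'
#' The standard multi-locus Weir--Cockerham estimate: the among-population
#' variance components \eqn{a_i} and total components \eqn{a_i + b_i} are
#' summed over loci before taking the ratio. Unlike the mean of per-SNP
#' ratios (which is downward biased by noisy low-information loci), this
#' form recovers the generative divergence level.
#'
#' @inheritParams fst_snp
#' @return a single genome-wide FST estimate.
#' @export
fst_overall <- function(p1, p2, n1, n2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r)
  sum(a) / sum(a + b)
}

#' Window-average FST
#'
#' Arithmetic mean of per-SNP FST over the non-flagged SNPs of one window;
#' \code{NA} when every SNP in the window is flagged.
#'
#' @param fst_values per-SNP FST values for the window's loci.
#' @param flagged logical vector marking unusable SNPs (defaults to the
#'   \code{"flagged"} attribute of \code{fst_values}, else none).
#' @return the window FST (or \code{NA}).
#' @export
window_fst <- function(fst_values, flagged = NULL) {
  if (is.null(flagged)) {
    flagged <- attr(fst_values, "flagged")
    if (is.null(flagged)) flagged <- rep(FALSE, length(fst_values))
  }
  use <- !flagged & !is.na(fst_values)
  if (!any(use)) return(NA_real_)
  mean(fst_values[use])
}

#' Sliding-window selection-signature scan
#'
#' For two populations genotyped at the same loci: partitions the loci into
#' non-overlapping windows, computes the population-level CEh of each window
#' in each population, their difference, and the window-average per-SNP FST
#' between the populations. Windows where one or both populations have zero
#' heterozygosity are flagged and excluded from ranking. FST rank 1 is the
#' window with the largest FST.
#'
#' @param g_a,g_b \code{\link{genotype_matrix}} objects over identical loci.
#' @param window_size consecutive SNPs per window (default 50).
#' @param cfg a \code{\link{compressor_config}}.
#' @param estimator FST estimator, see \code{\link{fst_snp}}.
#' @return data frame of class \code{"sweep_scan"}: one row per window with
#'   columns \code{window}, \code{start}, \code{end}, \code{chrom} (if a
#'   locus map is present), \code{ceh_a}, \code{ceh_b}, \code{ceh_diff}
#'   (A - B), \code{fst}, \code{fst_rank}, \code{flag}.
#' @export
sweep_scan <- function(g_a, g_b, window_size = 50, cfg = compressor_config(),
                       estimator = "wc") {
  if (!identical(colnames(g_a), colnames(g_b)))
    stop("the two populations must be genotyped at identical loci")
  win <- partition_windows(ncol(g_a), window_size)
  fa <- allele_frequencies(g_a)
  fb <- allele_frequencies(g_b)
  na_ <- 2 * colSums(unclass(g_a) != MISSING_CALL)
  nb_ <- 2 * colSums(unclass(g_b) != MISSING_CALL)
  snp_fst <- fst_snp(as.numeric(fa), as.numeric(fb), na_, nb_,
                     estimator = estimator)
  flagged_snp <- attr(snp_fst, "flagged")
  k <- nrow(win)
  ceh_a <- ceh_b <- wfst <- numeric(k)
  for (w in seq_len(k)) {
    idx <- win$start[w]:win$end[w]
    ceh_a[w] <- population_window_ceh(g_a, idx, cfg)
    ceh_b[w] <- population_window_ceh(g_b, idx, cfg)
    wfst[w] <- window_fst(snp_fst[idx], flagged_snp[idx])
  }
  flag <- ifelse(is.na(ceh_a) | is.na(ceh_b), "zero_het",
                 ifelse(win$partial, "partial", ""))
  out <- data.frame(window = win$window, start = win$start, end = win$end,
                    ceh_a = ceh_a, ceh_b = ceh_b, ceh_diff = ceh_a - ceh_b,
                    fst = wfst, fst_rank = NA_integer_, flag = flag,
                    stringsAsFactors = FALSE)
  lm <- attr(g_a, "locus_map")
  if (!is.null(lm)) out$chrom <- lm$chrom[win$start]
  usable <- !is.na(out$fst)
  out$fst_rank[usable] <- rank(-out$fst[usable], ties.method = "first")
  class(out) <- c("sweep_scan", "data.frame")
  out
}

#' Rank scan windows by absolute CEh difference
#'
#' Orders the usable (non-flagged) windows of a \code{\link{sweep_scan}} by
#' decreasing \eqn{|CEh_A - CEh_B|}, ties broken by genomic order, and
#' returns the top \code{top_k} with their window FST and FST rank.
#'
#' @param scan a \code{\link{sweep_scan}} result.
#' @param top_k number of windows to report (default 10).
#' @return data frame of the top windows, most extreme first.
#' @export
rank_outliers <- function(scan, top_k = 10) {
  tab <- as.data.frame(scan)
  flag <- if (is.null(tab$flag)) rep("", nrow(tab)) else tab$flag
  ok <- flag != "zero_het" & !is.na(tab$ceh_diff)
  tab <- tab[ok, , drop = FALSE]
  ord <- order(-abs(tab$ceh_diff), tab$window)
  out <- utils::head(tab[ord, , drop = FALSE], top_k)
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' @export
print.sweep_scan <- function(x, ...) {
  cat(sprintf("Sweep scan: %d windows (%d flagged)\n", nrow(x),
              sum(x$flag != "")))
  cat("Top windows by |CEh difference|:\n")
  print.data.frame(utils::head(rank_outliers(x, 5), 5), digits = 4)
  invisible(x)
}

#' @export
plot.sweep_scan <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$window, x$ceh_a, type = "l", col = "firebrick",
                 xlab = "window", ylab = "CEh",
                 main = "Population window CEh", ...)
  graphics::lines(x$window, x$ceh_b, col = "steelblue")
  graphics::legend("topright", legend = c("population A", "population B"),
                   col = c("firebrick", "steelblue"), lty = 1, bty = "n")
  graphics::plot(x$window, x$fst, type = "h", xlab = "window",
                 ylab = "window FST", main = "Window-average FST")
  invisible(x)
}
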