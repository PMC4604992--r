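#' Sample allele frequencies
#'
#' B-allele frequency per locus, computed from non-missing calls only:
#' \eqn{p_i = } (mean dosage at locus \eqn{i}) / 2. The per-locus
#' heterozygosity weights \eqn{p_i(1 - p_i)} and the VanRaden scaling
#' denominator \eqn{2\sum_i p_i(1 - p_i)} are attached.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @return named numeric vector \code{p} with attributes \code{weight}
#'   (\eqn{p(1-p)} per locus) and \code{denom} (\eqn{2\sum p(1-p)}).
#' @export
allele_frequencies <- function(g) {
  m <- unclass(g)
  if (!nrow(m)) stop("no animals")
  miss <- m == MISSING_CALL
  if (any(colSums(!miss) == 0L)) {
    bad <- colnames(m)[which(colSums(!miss) == 0L)[1L]]
    stop("all calls missing at locus ", bad)
  }
  mm <- m
  mm[miss] <- NA_integer_
  p <- colMeans(mm, na.rm = TRUE) / 2
  w <- p * (1 - p)
  structure(p, weight = w, denom = 2 * sum(w))
}

#' Genomic relationship matrix (VanRaden)
#'
#' \deqn{GRM = \frac{Z Z'}{2 \sum_i p_i (1 - p_i)}}
#' where \eqn{Z} is the genotype matrix column-centered by twice the B-allele
#' frequency (\eqn{Z = M - 2p}). The scaling makes the GRM analogous to the
#' pedigree numerator relationship matrix: diagonal near 1 for non-inbred
#' individuals, expectation 0.5 between full sibs and 0.25 between half
#' sibs. Missing calls contribute zero to the cross-products (they are
#' centered to zero); monomorphic loci contribute zero to both numerator and
#' denominator and are retained.
#'
#' @param g a \code{\link{genotype_matrix}} with at least 2 animals and at
#'   least one polymorphic locus.
#' @param p optional allele frequencies to center with (defaults to sample
#'   frequencies from \code{g}).
#' @return a \code{\link{relmat}} of kind \code{"GRM"} (symmetric, positive
#'   semi-definite).
#' @examples
#' toy <- toy_fixture()
#' round(grm(toy$genotypes)[1, 2], 2)   # 0.35
#' @export
grm <- function(g, p = NULL) {
  m <- unclass(g)
  if (nrow(m) < 2L) stop("GRM needs at least 2 animals")
  if (is.null(p)) p <- allele_frequencies(g)
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all loci are monomorphic; GRM undefined")
  z <- sweep(m, 2L, 2 * p)
  z[m == MISSING_CALL] <- 0   # missing calls carry no information
  val <- tcrossprod(z) / denom
  relmat((val + t(val)) / 2, kind = "GRM", animal_ids = rownames(m))
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Expected additive relatedness from the pedigree, computed recursively:
#' \eqn{a_{jj} = 1 + \frac{1}{2} a_{s(j), d(j)}} and
#' \eqn{a_{ij} = \frac{1}{2}(a_{i, s(j)} + a_{i, d(j)})} for \eqn{i} older
#' than \eqn{j}, with unknown parents contributing zero. Founders are
#' treated as non-inbred.
#'
#' @param ped pedigree data frame (columns animal, sire, dam; \code{"0"} =
#'   unknown). Must be acyclic.
#' @param max_generations optionally truncate ancestry: animals more than
#'   this many generations above the youngest generation have their parents
#'   treated as unknown. Default unlimited.
#' @return a \code{\link{relmat}} of kind \code{"NRM"} over all animals in
#'   the pedigree.
#' @export
nrm <- function(ped, max_generations = Inf) {
  ped <- validate_pedigree(ped)
  ids <- ped$animal
  n <- length(ids)
  sire <- match(ped$sire, ids)  # NA = unknown / not in pedigree
  dam <- match(ped$dam, ids)
  if (is.finite(max_generations)) {
    gen <- integer(n)
    for (j in seq_len(n)) {
      gp <- c(gen[sire[j]], gen[dam[j]])
      gen[j] <- if (all(is.na(c(sire[j], dam[j])))) 0L else 1L + max(gp, 0L, na.rm = TRUE)
    }
    cut <- max(gen) - max_generations
    sire[gen <= cut] <- NA_integer_
    dam[gen <= cut] <- NA_integer_
  }
  a <- matrix(0, n, n)
  for (j in seq_len(n)) {
    s <- sire[j]; d <- dam[j]
    a[j, j] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * a[s, d] else 0
    if (j > 1L) {
      for (i in seq_len(j - 1L)) {
        v <- 0
        if (!is.na(s)) v <- v + 0.5 * a[i, s]
        if (!is.na(d)) v <- v + 0.5 * a[i, d]
        a[i, j] <- a[j, i] <- v
      }
    }
  }
  relmat(a, kind = "NRM", animal_ids = ids)
}

#' CRM1: Shepard distance-to-similarity transform of the NCD matrix
#'
#' Element-wise \eqn{s_{ij} = a e^{-b d_{ij}}} (defaults \eqn{a = 2.5},
#' \eqn{b = 5}), mapping short compression distances to large similarities.
#' The diagonal is unscaled (self--self NCD is small but nonzero), so CRM1
#' diagonals sit above 1; CRM2 addresses that scaling issue.
#'
#' @param d an \code{\link{ncd_matrix}} (or any square symmetric distance
#'   matrix).
#' @param a,b positive transform constants.
#' @return a \code{\link{relmat}} of kind \code{"CRM1"}.
#' @export
crm1 <- function(d, a = 2.5, b = 5) {
  stopifnot(a > 0, b > 0)
  relmat(a * exp(-b * unclass(d)), kind = "CRM1", animal_ids = rownames(d))
}

#' CRM2: linear rescaling of the NCD matrix
#'
#' Grounds the compression distances in the expected relatedness of meiosis
#' (self--self near 1, full sibs near 0.5, half sibs near 0.25):
#' \deqn{s_{ii} = \overline{d}_{diag} / d_{ii}, \qquad
#'       s_{ij} = 1.75\left[1 - \frac{d_{ij} - \min(d)}{\max(d) - \min(d)}\right]
#'       \ (i \neq j)}
#' where \eqn{\overline{d}_{diag}} is the mean self--self distance (so the
#' diagonal averages exactly 1) and the off-diagonal min/max range is taken
#' over all pairs by default (under which off-diagonal values are bounded
#' between 0 and 0.75 on data whose self--self distances are the smallest),
#' or over off-diagonal pairs only via \code{range_scope}.
#'
#' @param d an \code{\link{ncd_matrix}}.
#' @param coef off-diagonal coefficient (default 1.75).
#' @param range_scope \code{"all"} (min/max over every cell, default) or
#'   \code{"offdiag"} (off-diagonal cells only).
#' @return a \code{\link{relmat}} of kind \code{"CRM2"}.
#' @export
crm2 <- function(d, coef = 1.75, range_scope = c("all", "offdiag")) {
  range_scope <- match.arg(range_scope)
  stopifnot(coef > 0)
  dm <- unclass(d)
  if (nrow(dm) < 2L) stop("CRM2 needs at least 2 animals")
  off <- dm[row(dm) != col(dm)]
  rng <- if (range_scope == "all") range(dm) else range(off)
  if (diff(rng) <= 0) stop("degenerate NCD range: max(d) equals min(d)")
  s <- coef * (1 - (dm - rng[1L]) / (rng[2L] - rng[1L]))
  diag(s) <- mean(diag(dm)) / diag(dm)
  relmat((s + t(s)) / 2, kind = "CRM2", animal_ids = rownames(d))
}

#' Per-window compression efficiency matrix
#'
#' Splits the loci into consecutive non-overlapping windows (the final
#' window keeps the remainder) and computes the CE of each animal's encoded
#' genotype string within each window. Window-level CE is measured net of
#' container overhead, since at window scale (tens of loci) the gzip
#' container would otherwise swamp the signal.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param window_size number of consecutive SNPs per window (default 50).
#' @param cfg a \code{\link{compressor_config}}; \code{net_overhead} is
#'   forced on for the window computation.
#' @return animals x windows numeric matrix, with the window partition
#'   attached as attribute \code{"windows"}.
#' @export
window_ce_matrix <- function(g, window_size = 50, cfg = compressor_config()) {
  win <- partition_windows(ncol(g), window_size)
  cfg$net_overhead <- TRUE
  m <- unclass(g)
  out <- matrix(NA_real_, nrow(m), nrow(win),
                dimnames = list(rownames(m), NULL))
  for (w in seq_len(nrow(win))) {
    idx <- win$start[w]:win$end[w]
    for (i in seq_len(nrow(m)))
      out[i, w] <- ce_of_bytes(encode_genotype_string(m[i, idx],
                                                      cfg$missing_char), cfg)
  }
  attr(out, "windows") <- win
  out
}

#' CRM3: correlation of window-CE profiles
#'
#' Each animal is summarized by its vector of per-window CE values
#' (\code{\link{window_ce_matrix}}); relatedness between two animals is the
#' correlation of their profiles across windows. The diagonal is exactly 1.
#' Animals whose profile is constant across windows have an undefined
#' correlation: their off-diagonal entries are \code{NA} and they are listed
#' in the \code{"flagged"} attribute.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param window_size consecutive SNPs per window (default 50).
#' @param cfg a \code{\link{compressor_config}}.
#' @param method correlation type: \code{"pearson"} (default) or
#'   \code{"spearman"}.
#' @return a \code{\link{relmat}} of kind \code{"CRM3"}.
#' @export
crm3 <- function(g, window_size = 50, cfg = compressor_config(),
                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ce <- window_ce_matrix(g, window_size, cfg)
  if (ncol(ce) < 2L) stop("CRM3 needs at least 2 windows")
  flagged <- rownames(ce)[apply(ce, 1L, function(v) stats::sd(v) == 0)]
  s <- suppressWarnings(stats::cor(t(ce), method = method))
  diag(s) <- 1
  out <- relmat((s + t(s)) / 2, kind = "CRM3", animal_ids = rownames(ce))
  attr(out, "flagged") <- flagged
  out
}

#' Summarize a relationship matrix by pedigree class
#'
#' Groups the cells of a relationship matrix \code{m} by the distinct values
#' of the corresponding pedigree NRM cells (e.g. 1 self--self, 0.5
#' parent--offspring / full sib, 0.25 half sib, ...), and reports the count,
#' mean, SD, min and max of the \code{m} entries in each class. Upper
#' triangle plus diagonal; classes with a single cell report SD 0.
#'
#' @param n the NRM \code{\link{relmat}}.
#' @param m any \code{\link{relmat}} over the same animals.
#' @param digits rounding applied to NRM values when forming classes.
#' @return data frame with columns \code{nrm_value}, \code{n}, \code{mean},
#'   \code{sd}, \code{min}, \code{max}, ordered by increasing
#'   \code{nrm_value}.
#' @export
summarize_by_pedigree_class <- function(n, m, digits = 6) {
  if (!identical(rownames(n), rownames(m))) {
    if (!setequal(rownames(n), rownames(m)))
      stop("animal ids of the two matrices do not match")
    m <- m[rownames(n), rownames(n)]
  }
  ut <- upper.tri(unclass(n), diag = TRUE)
  cls <- round(unclass(n)[ut], digits)
  val <- unclass(m)[ut]
  out <- do.call(rbind, lapply(split(val, cls), function(v) {
    data.frame(n = length(v), mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else 0,
               min = min(v), max = max(v))
  }))
  out <- cbind(nrm_value = as.numeric(rownames(out)), out)
  rownames(out) <- NULL
  out[order(out$nrm_value), ]
}
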