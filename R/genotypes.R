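#' @useDynLib comprel, .registration = TRUE
#' @importFrom stats cor rnorm rbinom runif rbeta sd var optim setNames
#' @importFrom utils read.table write.table
NULL

# Internal missing sentinel for genotype calls.  Kept as an explicit integer
# rather than NA so that encoded genotype strings stay fixed-length and
# arithmetic on calls fails loudly instead of silently propagating NA.
MISSING_CALL <- -9L

#' Construct a genotype matrix
#'
#' A genotype matrix holds allele-dosage codes (0, 1, 2 = copies of the B
#' allele) for a set of animals (rows) at a set of SNP loci (columns).
#' Missing calls are stored as the integer sentinel \code{-9}; \code{NA}s in
#' the input are converted to it.
#'
#' @param calls numeric/integer matrix of dosages, animals in rows. Values
#'   must be 0, 1, 2, \code{NA} or \code{-9}.
#' @param animal_ids,locus_ids optional identifier vectors; default to
#'   existing dimnames or generated labels. Must be unique.
#' @param locus_map optional data frame with one row per locus and columns
#'   \code{chrom} and \code{pos}; positions must be non-decreasing within a
#'   chromosome.
#' @return an integer matrix of class \code{"genotype_matrix"} with animal and
#'   locus ids as dimnames and the locus map (if any) attached as an
#'   attribute.
#' @examples
#' g <- genotype_matrix(rbind(c(0, 1, 2), c(2, 1, 0)))
#' g
#' @export
genotype_matrix <- function(calls, animal_ids = NULL, locus_ids = NULL,
                            locus_map = NULL) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  calls[is.na(calls)] <- MISSING_CALL
  if (is.null(animal_ids)) {
    animal_ids <- rownames(calls)
    if (is.null(animal_ids)) animal_ids <- paste0("A", seq_len(nrow(calls)))
  }
  if (is.null(locus_ids)) {
    locus_ids <- colnames(calls)
    if (is.null(locus_ids)) locus_ids <- paste0("L", seq_len(ncol(calls)))
  }
  animal_ids <- as.character(animal_ids)
  locus_ids <- as.character(locus_ids)
  if (length(animal_ids) != nrow(calls))
    stop("animal_ids length does not match row count")
  if (length(locus_ids) != ncol(calls))
    stop("locus_ids length does not match column count")
  if (anyDuplicated(animal_ids))
    stop("duplicate animal ids: ",
         paste(unique(animal_ids[duplicated(animal_ids)]), collapse = ", "))
  if (anyDuplicated(locus_ids))
    stop("duplicate locus ids")
  bad <- !(calls %in% c(0L, 1L, 2L, MISSING_CALL))
  if (any(bad)) {
    w <- which(bad)[1L]
    stop(sprintf("invalid genotype code %d at animal %s, locus %s",
                 calls[w],
                 animal_ids[(w - 1L) %% nrow(calls) + 1L],
                 locus_ids[(w - 1L) %/% nrow(calls) + 1L]))
  }
  dimnames(calls) <- list(animal_ids, locus_ids)
  if (!is.null(locus_map)) {
    locus_map <- as.data.frame(locus_map)
    if (nrow(locus_map) != ncol(calls))
      stop("locus_map must have exactly one row per locus")
    if (!all(c("chrom", "pos") %in% names(locus_map)))
      stop("locus_map needs 'chrom' and 'pos' columns")
    for (ch in unique(locus_map$chrom)) {
      ps <- locus_map$pos[locus_map$chrom == ch]
      if (is.unsorted(ps))
        stop("locus_map positions must be non-decreasing within chromosome ", ch)
    }
    attr(calls, "locus_map") <- locus_map
  }
  class(calls) <- c("genotype_matrix", class(calls))
  calls
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d animals x %d loci\n", nrow(x), ncol(x)))
  nmiss <- sum(x == MISSING_CALL)
  if (nmiss > 0) cat(sprintf("  missing calls: %d\n", nmiss))
  k <- min(nrow(x), 6L)
  m <- min(ncol(x), 10L)
  print(unclass(x)[seq_len(k), seq_len(m), drop = FALSE])
  if (nrow(x) > k || ncol(x) > m) cat("  ...\n")
  invisible(x)
}

#' @export
`[.genotype_matrix` <- function(x, i, j, ..., drop = FALSE) {
  lm <- attr(x, "locus_map")
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    if (!is.null(lm) && !missing(j)) lm <- lm[j, , drop = FALSE]
    attr(out, "locus_map") <- lm
    class(out) <- c("genotype_matrix", "matrix", "array")
  }
  out
}

#' Encode one genotype row as a byte string
#'
#' Each call becomes one byte: \code{'0'}, \code{'1'} or \code{'2'}; missing
#' calls become the configured sentinel character. No delimiters are inserted,
#' so the encoded length always equals the locus count.
#'
#' @param row integer vector of calls (a row of a genotype matrix).
#' @param missing_char single character standing in for missing calls.
#' @return a \code{raw} vector, one byte per locus.
#' @examples
#' rawToChar(encode_genotype_string(c(0, 1, 2)))
#' @export
encode_genotype_string <- function(row, missing_char = "3") {
  stopifnot(nchar(missing_char) == 1L)
  row <- as.integer(row)
  out <- raw(length(row))
  lut <- charToRaw("012")
  ok <- row %in% c(0L, 1L, 2L)
  out[ok] <- lut[row[ok] + 1L]
  out[!ok] <- charToRaw(missing_char)
  out
}

#' Worked five-animal toy example
#'
#' Expands the five 30-SNP run-length genotype descriptions used throughout
#' the documentation (animals 1 and 2 near-copies, 3 and 4 near-copies with a
#' periodic structure, 5 a pure 0,1,2 repeat) together with a small pedigree
#' in which animal 1 results from a parent--offspring mating (so it is the
#' only inbred animal), animal 2 is the offspring of the two ungenotyped
#' founders U1 and U2, and animal 4 is the offspring of animals 3 and 5.
#'
#' @param pedigree optional replacement pedigree (data frame with columns
#'   \code{animal}, \code{sire}, \code{dam}; \code{"0"} = unknown).
#' @return list with elements \code{genotypes} (a
#'   \code{\link{genotype_matrix}}, 5 x 30) and \code{pedigree}.
#' @examples
#' toy <- toy_fixture()
#' rawToChar(encode_genotype_string(toy$genotypes[1, ]))
#' @export
toy_fixture <- function(pedigree = NULL) {
  rows <- list(
    A1 = c(rep(0L, 10), rep(1L, 10), rep(2L, 10)),
    A2 = c(rep(2L, 3), rep(0L, 10), rep(1L, 10), rep(2L, 7)),
    A3 = c(rep(c(rep(0L, 3), rep(1L, 3), rep(2L, 3)), 3), 0L, 1L, 2L),
    A4 = c(rep(c(0L, 0L, 0L, 1L, 1L, 2L, 2L, 2L, 1L), 3), 0L, 1L, 2L),
    A5 = rep(c(0L, 1L, 2L), 10)
  )
  g <- genotype_matrix(do.call(rbind, rows),
                       animal_ids = names(rows),
                       locus_ids = paste0("snp", 1:30))
  if (is.null(pedigree)) {
    pedigree <- data.frame(
      animal = c("U1", "U2", "A2", "A1", "A3", "A5", "A4"),
      sire   = c("0",  "0",  "U1", "U1", "0",  "0",  "A3"),
      dam    = c("0",  "0",  "U2", "A2", "0",  "0",  "A5"),
      stringsAsFactors = FALSE
    )
  }
  list(genotypes = g, pedigree = validate_pedigree(pedigree))
}
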