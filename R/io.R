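#' Read a genotype matrix
#'
#' Reads genotypes from one of three dialects and returns a validated
#' \code{\link{genotype_matrix}}:
#' \describe{
#'   \item{\code{"tsv"}}{the package's canonical interchange format: one row
#'     per animal, first column the animal id, remaining whitespace/tab
#'     separated dosage codes; an optional header line of locus ids.}
#'   \item{\code{"raw"}}{PLINK \code{--recode A} output (header
#'     \code{FID IID PAT MAT SEX PHENOTYPE} then one dosage column per SNP).}
#'   \item{\code{"vcf"}}{a VCF file; diploid genotypes are converted to
#'     alternate-allele dosage 0/1/2 (requires the \pkg{vcfR} package).}
#' }
#'
#' @param path file path.
#' @param format one of \code{"tsv"}, \code{"raw"}, \code{"vcf"}.
#' @param missing_code value in the file denoting a missing call (additional
#'   to \code{NA}); defaults to \code{-9}.
#' @return a \code{\link{genotype_matrix}}.
#' @seealso \code{\link{write_genotypes}}
#' @export
read_genotypes <- function(path, format = c("tsv", "raw", "vcf"),
                           missing_code = -9) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
    tsv = read_genotypes_tsv(path, missing_code),
    raw = read_genotypes_plink_raw(path, missing_code),
    vcf = read_genotypes_vcf(path)
  )
}

read_genotypes_tsv <- function(path, missing_code) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty genotype file: ", path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  # header detection: a first line whose fields beyond the first are not all
  # parseable as genotype codes is taken as locus ids
  locus_ids <- NULL
  first <- toks[[1L]]
  codes1 <- suppressWarnings(as.numeric(first[-1L]))
  if (length(first) > 1L && anyNA(codes1)) {
    locus_ids <- first[-1L]
    toks <- toks[-1L]
  }
  if (!length(toks)) stop("no genotype rows in ", path)
  nfield <- length(toks[[1L]])
  lens <- lengths(toks)
  if (any(lens != nfield)) {
    bad <- which(lens != nfield)[1L]
    stop(sprintf("malformed genotype row at line %d of %s: %d fields, expected %d",
                 bad + (if (is.null(locus_ids)) 0L else 1L), path,
                 lens[bad], nfield))
  }
  ids <- vapply(toks, `[[`, "", 1L)
  vals <- vapply(toks, function(tk) suppressWarnings(as.numeric(tk[-1L])),
                 numeric(nfield - 1L))
  calls <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = nfield - 1L)
  if (anyNA(calls)) stop("non-numeric genotype code in ", path)
  calls[calls == missing_code] <- MISSING_CALL
  genotype_matrix(calls, animal_ids = ids, locus_ids = locus_ids)
}

read_genotypes_plink_raw <- function(path, missing_code) {
  d <- read.table(path, header = TRUE, check.names = FALSE,
                  stringsAsFactors = FALSE)
  need <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(need %in% names(d)))
    stop("not a PLINK .raw file (missing ", paste(setdiff(need, names(d)),
         collapse = ", "), "): ", path)
  snps <- setdiff(names(d), need)
  calls <- as.matrix(d[, snps, drop = FALSE])
  calls[calls == missing_code] <- NA
  genotype_matrix(calls, animal_ids = d$IID, locus_ids = snps)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF import requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1L]]
    if (any(al == ".")) return(NA_integer_)
    sum(as.integer(al) > 0L)
  })
  ids <- rownames(gt)
  if (is.null(ids)) ids <- paste0("L", seq_len(nrow(gt)))
  fix <- vcfR::getFIX(v)
  lm <- data.frame(chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]))
  genotype_matrix(t(dose), animal_ids = colnames(gt), locus_ids = ids,
                  locus_map = lm)
}

#' Write a genotype matrix as canonical TSV
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_genotypes <- function(g, path) {
  header <- paste(c("id", colnames(g)), collapse = "\t")
  body <- vapply(seq_len(nrow(g)), function(i)
    paste(c(rownames(g)[i], unclass(g)[i, ]), collapse = "\t"), "")
  writeLines(c(header, body), path)
  invisible(path)
}

validate_pedigree <- function(ped) {
  ped <- as.data.frame(ped, stringsAsFactors = FALSE)
  if (ncol(ped) < 3L) stop("pedigree needs 3 columns (animal, sire, dam)")
  names(ped)[1:3] <- c("animal", "sire", "dam")
  ped$animal <- as.character(ped$animal)
  ped$sire <- as.character(ped$sire)
  ped$dam <- as.character(ped$dam)
  ped$sire[is.na(ped$sire)] <- "0"
  ped$dam[is.na(ped$dam)] <- "0"
  if (anyDuplicated(ped$animal))
    stop("duplicate animals in pedigree: ",
         paste(unique(ped$animal[duplicated(ped$animal)]), collapse = ", "))
  sort_pedigree(ped)  # errors on cycles
}

# Topological sort so every parent precedes its offspring; detects cycles and
# reports one offending chain.
sort_pedigree <- function(ped) {
  ids <- ped$animal
  known <- character(0)
  rest <- ped
  out <- ped[0, ]
  while (nrow(rest)) {
    ready <- (!(rest$sire %in% ids) | rest$sire %in% known) &
             (!(rest$dam %in% ids) | rest$dam %in% known)
    if (!any(ready)) {
      chain <- rest$animal[1L]
      cur <- rest$sire[1L]
      seen <- chain
      while (cur %in% rest$animal && !(cur %in% seen)) {
        seen <- c(seen, cur)
        cur <- rest$sire[match(cur, rest$animal)]
      }
      stop("pedigree contains a cycle involving: ",
           paste(seen, collapse = " -> "))
    }
    out <- rbind(out, rest[ready, ])
    known <- c(known, rest$animal[ready])
    rest <- rest[!ready, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Read / write a pedigree table
#'
#' Three tab-separated columns: animal, sire, dam; \code{0} marks an unknown
#' parent. Rows are returned sorted so parents precede offspring; a cyclic
#' pedigree is an error.
#'
#' @param path file path.
#' @return data frame with columns \code{animal}, \code{sire}, \code{dam}.
#' @export
read_pedigree <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  colClasses = "character")
  validate_pedigree(d)
}

#' @rdname read_pedigree
#' @param ped pedigree data frame.
#' @export
write_pedigree <- function(ped, path) {
  ped <- validate_pedigree(ped)
  write.table(ped, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a phenotype table
#'
#' Tab-separated with a header; first column is the animal id, one column per
#' trait or covariate.
#'
#' @param path file path.
#' @return data frame; first column named \code{animal}.
#' @export
read_phenotypes <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  names(d)[1L] <- "animal"
  d$animal <- as.character(d$animal)
  if (anyDuplicated(d$animal)) stop("duplicate animal ids in ", path)
  d
}

#' @rdname read_phenotypes
#' @param phen phenotype data frame (first column the animal id).
#' @export
write_phenotypes <- function(phen, path) {
  write.table(phen, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Relationship matrices: construction and square-TSV round trip
#'
#' A relationship matrix is a square symmetric numeric matrix over a set of
#' animals, tagged with its construction (\code{NRM}, \code{GRM},
#' \code{CRM1}, \code{CRM2}, \code{CRM3}, or \code{other}).
#' \code{write_relmat} writes a square TSV (header row and column of animal
#' ids) at full precision so that \code{read_relmat} inverts it bit-exactly.
#'
#' @param values square symmetric numeric matrix.
#' @param kind provenance tag.
#' @param animal_ids identifiers; default taken from dimnames.
#' @param tol symmetry tolerance.
#' @return a matrix of class \code{"relmat"} with a \code{kind} attribute.
#' @export
relmat <- function(values, kind = c("other", "NRM", "GRM", "CRM1", "CRM2", "CRM3"),
                   animal_ids = NULL, tol = 1e-10) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("relationship matrix must be square")
  if (max(abs(values - t(values))) > tol)
    stop("relationship matrix is not symmetric within tolerance ", tol)
  if (is.null(animal_ids)) {
    animal_ids <- rownames(values)
    if (is.null(animal_ids)) animal_ids <- paste0("A", seq_len(nrow(values)))
  }
  if (length(animal_ids) != nrow(values))
    stop("animal_ids length mismatch")
  dimnames(values) <- list(animal_ids, animal_ids)
  structure(values, kind = kind, class = c("relmat", "matrix", "array"))
}

#' @export
print.relmat <- function(x, ...) {
  cat(sprintf("%s relationship matrix, %d animals\n", attr(x, "kind"), nrow(x)))
  k <- min(nrow(x), 8L)
  print(round(unclass(x)[seq_len(k), seq_len(k), drop = FALSE], 4))
  if (nrow(x) > k) cat("  ...\n")
  invisible(x)
}

#' @rdname relmat
#' @param m a \code{relmat}.
#' @param path file path.
#' @export
write_relmat <- function(m, path) {
  if (!inherits(m, "relmat")) m <- relmat(m)
  ids <- rownames(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("kind", attr(m, "kind")), collapse = "\t"), con)
  writeLines(paste(c("id", ids), collapse = "\t"), con)
  for (i in seq_along(ids))
    writeLines(paste(c(ids[i], sprintf("%.17g", unclass(m)[i, ])),
                     collapse = "\t"), con)
  invisible(path)
}

#' @rdname relmat
#' @export
read_relmat <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("malformed relationship matrix file: ", path)
  kind <- strsplit(lines[1L], "\t")[[1L]][2L]
  ids <- strsplit(lines[2L], "\t")[[1L]][-1L]
  vals <- t(vapply(lines[-(1:2)], function(ln) {
    as.numeric(strsplit(ln, "\t")[[1L]][-1L])
  }, numeric(length(ids)), USE.NAMES = FALSE))
  relmat(vals, kind = kind, animal_ids = ids)
}
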