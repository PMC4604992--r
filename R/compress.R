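#' Compressor configuration
#'
#' All compression statistics in this package are measured with the DEFLATE
#' algorithm (the algorithm behind gzip). The stream is produced with a
#' pinned gzip header (zero timestamp, no filename), so byte counts are fully
#' deterministic: the same input and configuration always yield the same
#' size.
#'
#' The default level is 9 (deepest match search), not the gzip tool's
#' default of 6. On genotype strings the alphabet has only three or four
#' symbols, so the hash chains that DEFLATE searches for back-references are
#' saturated by short nearby matches; at level 6 the bounded chain search
#' gives up long before reaching a matching segment thousands of bytes
#' back, and the normalized compression distance between near-identical
#' kilobase-scale strings collapses towards 1. Level 9 searches chains
#' deeply enough to recover long-range similarity throughout DEFLATE's
#' 32 KB window.
#'
#' @param level DEFLATE compression level, integer 1--9 (default 9; see
#'   Details -- level 6 mirrors the gzip tool's default).
#' @param container \code{"gzip"} (gzip header + CRC trailer, as written by
#'   the gzip tool) or \code{"raw"} (bare DEFLATE stream, no container
#'   bytes).
#' @param net_overhead if \code{TRUE}, sizes are additionally reported net of
#'   the container/stream overhead, measured as the compressed size of the
#'   empty input under the same configuration. Useful at toy scale where the
#'   ~20-byte gzip container would otherwise dominate.
#' @param missing_char sentinel character used when encoding missing calls.
#' @return a list of class \code{"compressor_config"}.
#' @export
compressor_config <- function(level = 9L, container = c("gzip", "raw"),
                              net_overhead = FALSE, missing_char = "3") {
  container <- match.arg(container)
  level <- as.integer(level)
  if (is.na(level) || level < 1L || level > 9L)
    stop("level must be an integer in 1..9")
  structure(list(level = level, container = container,
                 net_overhead = isTRUE(net_overhead),
                 missing_char = missing_char),
            class = "compressor_config")
}

#' @export
print.compressor_config <- function(x, ...) {
  cat(sprintf("DEFLATE level %d, %s container%s\n", x$level, x$container,
              if (x$net_overhead) ", net of overhead" else ""))
  invisible(x)
}

# Compressed byte count of a raw vector under cfg.
deflate_size <- function(data, cfg = compressor_config()) {
  if (is.character(data)) data <- charToRaw(paste(data, collapse = ""))
  stopifnot(is.raw(data))
  .Call(C_deflate_size, data, cfg$level, cfg$container == "gzip")
}

# Container overhead: size of compressing the empty input.
compressor_overhead <- function(cfg = compressor_config()) {
  deflate_size(raw(0), cfg)
}

#' Measure compressed size
#'
#' @param data a \code{raw} vector (or a character string, converted to
#'   bytes).
#' @param cfg a \code{\link{compressor_config}}.
#' @return list with \code{raw_size} (bytes before compression),
#'   \code{compressed_size} (bytes after), \code{overhead} (size of
#'   compressing the empty input) and \code{net_compressed_size}
#'   (\code{compressed_size - overhead}, floored at 0).
#' @examples
#' compressed_size(charToRaw(strrep("0", 100)))
#' @export
compressed_size <- function(data, cfg = compressor_config()) {
  if (is.character(data)) data <- charToRaw(paste(data, collapse = ""))
  sa <- deflate_size(data, cfg)
  ov <- compressor_overhead(cfg)
  list(raw_size = length(data),
       compressed_size = sa,
       overhead = ov,
       net_compressed_size = max(sa - ov, 0L))
}

#' Compression efficiency
#'
#' The fractional size reduction \eqn{CE = (S_B - S_A)/S_B} of a byte
#' sequence under lossless compression, where \eqn{S_B} and \eqn{S_A} are the
#' sizes before and after compression. Highly patterned (repetitive)
#' genotype sequences compress well and score a high CE; irregular sequences
#' score low (CE can be negative when container overhead exceeds the gain).
#'
#' @param s_b size before compression (must be > 0).
#' @param s_a size after compression.
#' @return \eqn{(S_B - S_A)/S_B}.
#' @examples
#' compression_efficiency(7, 2)   # 0.714...
#' @export
compression_efficiency <- function(s_b, s_a) {
  if (any(s_b <= 0)) stop("uncompressed size must be positive")
  (s_b - s_a) / s_b
}

# CE of an encoded genotype row under cfg (net sizes if configured).
ce_of_bytes <- function(bytes, cfg = compressor_config()) {
  cs <- compressed_size(bytes, cfg)
  sa <- if (cfg$net_overhead) cs$net_compressed_size else cs$compressed_size
  compression_efficiency(cs$raw_size, sa)
}

#' Genome-wide heterozygosity of a genotype row
#'
#' Proportion of non-missing calls that are heterozygous (dosage 1).
#'
#' @param row integer vector of calls.
#' @return value in \eqn{[0, 1]}.
#' @export
heterozygosity <- function(row) {
  row <- as.integer(row)
  ok <- row %in% c(0L, 1L, 2L)
  if (!any(ok)) stop("heterozygosity undefined: all calls missing")
  mean(row[ok] == 1L)
}

#' Heterozygosity-corrected compression efficiency (CEh)
#'
#' CE of the encoded genotype row divided by its genome-wide heterozygosity:
#' \eqn{CEh = CE / Het}. Dividing by heterozygosity separates compressibility
#' that reflects haplotype structure from the trivial compressibility of
#' near-homozygous sequences. When \eqn{Het = 0} the statistic is undefined
#' and \code{NA} is returned (flagged, never silently zero).
#'
#' @param row integer vector of calls.
#' @param cfg a \code{\link{compressor_config}}.
#' @return CEh value, or \code{NA} when heterozygosity is zero.
#' @export
ceh_individual <- function(row, cfg = compressor_config()) {
  het <- heterozygosity(row)
  if (het == 0) return(NA_real_)
  ce_of_bytes(encode_genotype_string(row, cfg$missing_char), cfg) / het
}

#' Normalized compression distance between two byte sequences
#'
#' \deqn{NCD(x, y) = \frac{Z(xy) - \min\{Z(x), Z(y)\}}{\max\{Z(x), Z(y)\}}}
#' where \eqn{Z(\cdot)} is the compressed size under the configured
#' compressor and \eqn{Z(xy)} compresses the concatenation of the two
#' sequences. An ideal compressor would give \eqn{NCD(x,x) = 0}; a real
#' DEFLATE compressor gives a small positive self-distance.
#'
#' @param x,y \code{raw} vectors (or character strings).
#' @param cfg a \code{\link{compressor_config}}. Raw (container-inclusive)
#'   compressed sizes are used, matching the defining formula.
#' @return the NCD value (non-negative for any real compressor).
#' @export
ncd <- function(x, y, cfg = compressor_config()) {
  if (is.character(x)) x <- charToRaw(paste(x, collapse = ""))
  if (is.character(y)) y <- charToRaw(paste(y, collapse = ""))
  if (!length(x) || !length(y)) stop("NCD needs non-empty sequences")
  zx <- deflate_size(x, cfg)
  zy <- deflate_size(y, cfg)
  zxy <- deflate_size(c(x, y), cfg)
  (zxy - min(zx, zy)) / max(zx, zy)
}

#' Pairwise NCD matrix for a genotyped population
#'
#' Computes the normalized compression distance between every pair of
#' animals, including the self--self diagonal (small but positive under a
#' real compressor; closely related pairs have short distances). The
#' concatenation \eqn{Z(xy)} is order-sensitive in practice though symmetric
#' in intent, so by default the matrix is symmetrized by averaging
#' \eqn{NCD(x,y)} and \eqn{NCD(y,x)}.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param cfg a \code{\link{compressor_config}}.
#' @param symmetrize average the two concatenation orders (default
#'   \code{TRUE}).
#' @return a square matrix of class \code{"ncd_matrix"} with animal ids as
#'   dimnames.
#' @export
ncd_matrix <- function(g, cfg = compressor_config(), symmetrize = TRUE) {
  n <- nrow(g)
  if (n < 2L) stop("NCD matrix needs at least 2 animals")
  enc <- lapply(seq_len(n), function(i)
    encode_genotype_string(unclass(g)[i, ], cfg$missing_char))
  z <- vapply(enc, deflate_size, 0L, cfg = cfg)
  d <- matrix(0, n, n, dimnames = list(rownames(g), rownames(g)))
  for (i in seq_len(n)) {
    for (j in i:n) {
      zij <- deflate_size(c(enc[[i]], enc[[j]]), cfg)
      dij <- (zij - min(z[i], z[j])) / max(z[i], z[j])
      if (symmetrize && j > i) {
        zji <- deflate_size(c(enc[[j]], enc[[i]]), cfg)
        dji <- (zji - min(z[i], z[j])) / max(z[i], z[j])
        dij <- (dij + dji) / 2
      }
      d[i, j] <- d[j, i] <- dij
    }
  }
  structure(d, class = c("ncd_matrix", "matrix", "array"))
}

#' @export
print.ncd_matrix <- function(x, ...) {
  cat(sprintf("NCD matrix, %d animals (diagonal = self-self distance)\n",
              nrow(x)))
  k <- min(nrow(x), 8L)
  print(round(unclass(x)[seq_len(k), seq_len(k), drop = FALSE], 4))
  if (nrow(x) > k) cat("  ...\n")
  invisible(x)
}
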