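#' Banded LD correlation matrices
#'
#' The LD matrix \eqn{\hat R} holds pairwise genotype correlations estimated
#' from an ancestry-matched reference panel. It is stored banded and
#' symmetric: entries beyond the declared bandwidth are exactly zero, and
#' cross-chromosome LD is exactly zero. Internally the matrix is a sparse
#' symmetric [Matrix::Matrix] aligned with a SNP table.
#'
#' @param R A symmetric matrix (dense or sparse) of SNP correlations with
#'   unit diagonal, aligned with `snp_id`.
#' @param snp_id Character vector of SNP identifiers.
#' @param chrom Character vector of chromosome labels per SNP.
#' @param bandwidth Number of off-diagonals stored.
#' @return An object of class `ld_matrix`.
#' @export
ld_matrix <- function(R, snp_id, chrom, bandwidth) {
  R <- methods::as(methods::as(Matrix::Matrix(R, sparse = TRUE), "generalMatrix"),
                   "CsparseMatrix")
  p <- length(snp_id)
  if (nrow(R) != p || ncol(R) != p) {
    abort("LD matrix dimension does not match the number of SNPs.",
          class = "rssnet_validation_error")
  }
  if (length(chrom) != p) {
    abort("`chrom` must have one entry per SNP.",
          class = "rssnet_validation_error")
  }
  d <- Matrix::diag(R)
  if (any(abs(d - 1) > 1e-6)) {
    abort("LD matrix diagonal must be 1 (tolerance 1e-6).",
          class = "rssnet_validation_error")
  }
  if (any(abs(R@x) > 1 + 1e-12)) {
    abort("LD entries must lie in [-1, 1].", class = "rssnet_validation_error")
  }
  structure(
    list(R = R, snp_id = as.character(snp_id), chrom = as.character(chrom),
         bandwidth = as.integer(bandwidth)),
    class = "ld_matrix"
  )
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("<ld_matrix> %d SNPs, bandwidth %d, %d stored entries\n",
              length(x$snp_id), x$bandwidth, length(x$R@x)))
  invisible(x)
}

#' @export
dim.ld_matrix <- function(x) c(length(x$snp_id), length(x$snp_id))

#' @export
as.matrix.ld_matrix <- function(x, ...) as.matrix(x$R)

#' Identity LD matrix
#'
#' Convenience constructor for unlinked SNPs (bandwidth 0).
#'
#' @param snp_id SNP identifiers.
#' @param chrom Chromosome labels (defaults to a single chromosome).
#' @return An `ld_matrix`.
#' @export
ld_identity <- function(snp_id, chrom = rep("1", length(snp_id))) {
  p <- length(snp_id)
  ld_matrix(Matrix::Diagonal(p), snp_id, chrom, bandwidth = 0L)
}

# Band storage used by the C++ coordinate-ascent sweep: a (bandwidth+1) x p
# matrix B with B[k+1, j] = R[j, j+k] (zero past the chromosome end).
ld_band_storage <- function(ld) {
  p <- length(ld$snp_id)
  bw <- ld$bandwidth
  B <- matrix(0, nrow = bw + 1L, ncol = p)
  B[1L, ] <- 1
  if (bw > 0L) {
    Rt <- methods::as(Matrix::triu(ld$R), "TsparseMatrix")
    i <- Rt@i + 1L
    j <- Rt@j + 1L
    k <- j - i
    keep <- k >= 1L & k <= bw
    B[cbind(k[keep] + 1L, i[keep])] <- Rt@x[keep]
  }
  B
}

#' Write a banded LD matrix as text
#'
#' Plain-text banded container: a header line `#rssnet_ld bandwidth=<b>`
#' followed by a TSV of within-band entries (`chrom`, `i`, `j`, `r`) with
#' `i < j` indexing SNP order within the file's SNP list, then implied unit
#' diagonal. The SNP list itself (id and chromosome) precedes the band as a
#' second header section. Round trips are lossless at double precision.
#'
#' @param ld An `ld_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld <- function(ld, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("#rssnet_ld bandwidth=%d nsnp=%d", ld$bandwidth,
                     length(ld$snp_id)), con)
  writeLines(paste(ld$snp_id, ld$chrom, sep = "\t"), con)
  Rt <- methods::as(Matrix::triu(ld$R, k = 1L), "TsparseMatrix")
  if (length(Rt@x) > 0) {
    lines <- sprintf("%d\t%d\t%s", Rt@i + 1L, Rt@j + 1L,
                     format(Rt@x, digits = 17, scientific = TRUE, trim = TRUE))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a banded LD matrix from text
#'
#' Inverse of [write_ld()]. Entries outside the declared band are treated as
#' exactly zero; a diagonal differing from 1 beyond 1e-6, or any entry
#' outside \[-1, 1\], is a validation error.
#'
#' @param path Path written by [write_ld()].
#' @return An `ld_matrix`.
#' @export
read_ld <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  if (!grepl("^#rssnet_ld ", hdr)) {
    abort("Not an rssnet LD file (missing header).",
          class = "rssnet_format_error")
  }
  bw <- as.integer(sub(".*bandwidth=(\\d+).*", "\\1", hdr))
  p <- as.integer(sub(".*nsnp=(\\d+).*", "\\1", hdr))
  snp_lines <- strsplit(lines[2:(1 + p)], "\t", fixed = TRUE)
  snp_id <- vapply(snp_lines, `[[`, character(1), 1L)
  chrom <- vapply(snp_lines, `[[`, character(1), 2L)
  body <- lines[-seq_len(1 + p)]
  if (length(body) > 0) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    i <- vapply(parts, function(z) as.integer(z[[1]]), integer(1))
    j <- vapply(parts, function(z) as.integer(z[[2]]), integer(1))
    r <- vapply(parts, function(z) as.numeric(z[[3]]), numeric(1))
    keep <- (j - i) <= bw & chrom[i] == chrom[j]
    i <- i[keep]; j <- j[keep]; r <- r[keep]
    R <- Matrix::sparseMatrix(i = c(i, j, seq_len(p)),
                              j = c(j, i, seq_len(p)),
                              x = c(r, r, rep(1, p)), dims = c(p, p))
  } else {
    R <- Matrix::Diagonal(p)
  }
  ld_matrix(R, snp_id, chrom, bandwidth = bw)
}

# Banded sample correlation of a genotype matrix, zero across chromosomes.
# Computed chunk-wise so only within-band crossproducts hit BLAS. `shrink`
# scales off-diagonal entries toward zero (the usual regularization of
# reference-panel LD estimates), keeping the banded matrix positive
# definite.
banded_cor <- function(X, chrom, bandwidth, shrink = 0) {
  n <- nrow(X)
  p <- ncol(X)
  Xs <- X - rep(colMeans(X), each = n)
  Xs <- Xs / rep(sqrt(colSums(Xs^2)), each = n)  # crossprod gives correlations
  ii <- integer(0); jj <- integer(0); rr <- numeric(0)
  if (bandwidth > 0L) {
    chunk <- max(200L, bandwidth)
    starts <- seq(1L, p, by = chunk)
    for (s in starts) {
      e <- min(s + chunk - 1L, p)
      e2 <- min(e + bandwidth, p)
      C <- crossprod(Xs[, s:e, drop = FALSE], Xs[, s:e2, drop = FALSE])
      a <- rep(s:e, times = e2 - s + 1L)
      b <- rep(s:e2, each = e - s + 1L)
      keep <- b > a & (b - a) <= bandwidth & chrom[a] == chrom[b]
      ii <- c(ii, a[keep]); jj <- c(jj, b[keep]); rr <- c(rr, C[keep])
    }
  }
  rr <- pmin(1, pmax(-1, rr)) * (1 - shrink)
  Matrix::sparseMatrix(i = c(ii, jj, seq_len(p)), j = c(jj, ii, seq_len(p)),
                       x = c(rr, rr, rep(1, p)), dims = c(p, p))
}
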