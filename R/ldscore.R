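## LD scores from adjusted r-squared, and local LD around an index SNP.

#' Small-sample adjusted r-squared
#'
#' \eqn{r^2_{adj} = r^2 - (1 - r^2) / (n - 2)}: unbiased at 0 for
#' independent markers, so LD scores do not inflate with window size.
#'
#' @param r2 squared Pearson correlation(s) in [0, 1].
#' @param n number of individuals (> 2).
#' @export
adjusted_r2 <- function(r2, n) {
  if (any(n <= 2)) stop("n must exceed 2")
  stopifnot(all(r2 >= 0 & r2 <= 1))
  r2 - (1 - r2) / (n - 2)
}

#' LD scores for the markers of one chromosome
#'
#' Per index marker, the sum of adjusted r-squared (squared Pearson
#' correlation of dosages, genotypic r^2) against all markers within
#' \code{window_bp} up- and downstream, the self-pair included (its
#' adjusted r^2 is 1). Monomorphic markers have undefined correlations and
#' are excluded with a log.
#'
#' @param geno a \code{geno_matrix}.
#' @param chrom chromosome to score.
#' @param window_bp window half-width in bp (default 1 Mb each side).
#' @param include_self include the self-pair (default TRUE).
#' @return data.frame: marker, chrom, bp, ld_score, n_pairs, n (clones).
#' @export
ld_scores <- function(geno, chrom, window_bp = 1e6, include_self = TRUE) {
  idx <- which(geno$map$chrom == chrom)
  if (length(idx) < 2) stop("need >= 2 markers on chromosome ", chrom)
  M <- geno$dosages[, idx, drop = FALSE]
  n <- nrow(M)
  sds <- apply(M, 2, stats::sd, na.rm = TRUE)
  poly <- !is.na(sds) & sds > 0
  if (!all(poly))
    message(sum(!poly), " monomorphic marker(s) excluded from LD scores")
  M <- M[, poly, drop = FALSE]
  pos <- geno$map$pos[idx][poly]
  C2 <- stats::cor(M, use = "pairwise.complete.obs")^2
  A <- adjusted_r2(pmin(pmax(C2, 0), 1), n)
  m <- ncol(M)
  score <- numeric(m); npairs <- integer(m)
  for (j in seq_len(m)) {
    inw <- which(abs(pos - pos[j]) <= window_bp)
    if (!include_self) inw <- setdiff(inw, j)
    score[j] <- sum(A[j, inw])
    npairs[j] <- length(inw)
  }
  data.frame(marker = geno$map$marker[idx][poly], chrom = chrom, bp = pos,
             ld_score = score, n_pairs = npairs, n = n, row.names = NULL)
}

#' Pairwise r-squared between an index SNP and its neighbourhood
#'
#' r^2 between the index SNP and every marker within \code{window_bp}
#' upstream and downstream (a 2 Mb span at the default), as used to colour
#' local-LD plots around a top GWAS hit.
#'
#' @param geno a \code{geno_matrix}.
#' @param index_snp marker id of the index SNP.
#' @param window_bp half-width in bp (default 1 Mb each side).
#' @return data.frame: marker, chrom, bp, r2, n.
#' @export
local_r2 <- function(geno, index_snp, window_bp = 1e6) {
  j <- match(index_snp, geno$map$marker)
  if (is.na(j)) stop("index SNP not in the marker map: ", index_snp)
  x <- geno$dosages[, j]
  if (is.na(stats::sd(x, na.rm = TRUE)) || stats::sd(x, na.rm = TRUE) == 0)
    stop("index SNP is monomorphic")
  ch <- geno$map$chrom[j]
  inw <- which(geno$map$chrom == ch &
                 abs(geno$map$pos - geno$map$pos[j]) <= window_bp)
  r2 <- vapply(inw, function(k) {
    v <- suppressWarnings(stats::cor(x, geno$dosages[, k],
                                     use = "pairwise.complete.obs"))
    v^2
  }, numeric(1))
  data.frame(marker = geno$map$marker[inw], chrom = ch,
             bp = geno$map$pos[inw], r2 = r2, n = nrow(geno$dosages),
             row.names = NULL)
}
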