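## Marker QC cascade, VanRaden GRM, SNP heritability, PCA, VCF I/O.

#' Read a VCF into a genotype matrix
#'
#' GT is converted to the ALT-allele dosage (0/1/2, NA for missing); the
#' AR2 imputation-quality field is read from INFO when present.
#'
#' @param path path to a (possibly gzipped) VCF.
#' @param panel optional named panel labels per clone.
#' @return a \code{\link{genotype_matrix}}.
#' @export
read_vcf_dosages <- function(path, panel = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_real_, nrow = ncol(gt), ncol = nrow(gt),
                dimnames = list(colnames(gt), rownames(gt)))
  alt_count <- function(g) {
    ifelse(is.na(g) | g %in% c(".", "./.", ".|."), NA_real_,
           vapply(strsplit(gsub("\\|", "/", g), "/"), function(a)
             sum(a == "1"), numeric(1)))
  }
  for (j in seq_len(nrow(gt))) dos[, j] <- alt_count(gt[j, ])
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ar2 <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AR2")))
  map <- data.frame(marker = ifelse(is.na(fix$ID) | fix$ID == ".",
                                    paste0("S", fix$CHROM, "_", fix$POS),
                                    fix$ID),
                    chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT, ar2 = ar2)
  colnames(dos) <- map$marker
  genotype_matrix(dos, map, panel)
}

#' Write a genotype matrix as VCF (GT field, dosage = ALT count)
#' @param geno a \code{geno_matrix} (integer dosages).
#' @param path output path.
#' @export
write_vcf <- function(geno, path) {
  map <- geno$map
  gt_code <- c("0/0", "0/1", "1/1")
  dos <- round(t(geno$dosages))           # markers x clones
  body <- matrix("./.", nrow(dos), ncol(dos))
  ok <- !is.na(dos)
  body[ok] <- gt_code[dos[ok] + 1L]
  info <- if (!is.null(map$ar2) && !all(is.na(map$ar2)))
    sprintf("AR2=%.4f", map$ar2) else rep(".", nrow(map))
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AR2,Number=1,Type=Float,Description=\"Estimated allelic r-squared\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno$dosages)), collapse = "\t"),
    paste(map$chrom, map$pos, map$marker, map$ref, map$alt, ".", "PASS",
          info, "GT",
          apply(body, 1, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

marker_freq <- function(dosages) colMeans(dosages, na.rm = TRUE) / 2

#' Marker QC cascade: missingness, imputation quality, MAF
#'
#' Filters are applied in order (configurable): markers with a missing-call
#' fraction above \code{max_missing} are removed, then markers with
#' AR2 not higher than \code{ar2_min} (markers without an AR2 value are
#' kept), then markers with MAF not higher than \code{maf_min}. The
#' comparisons are strict, so a marker exactly at a threshold is removed.
#' Counts surviving each step are attached as the \code{"filter_log"}
#' attribute.
#'
#' @param geno a \code{geno_matrix}.
#' @param max_missing maximum tolerated missing fraction (default 0.6).
#' @param ar2_min minimum imputation quality, exclusive (default 0.3).
#' @param maf_min minimum minor allele frequency, exclusive (default 0.01).
#' @param order filter order, a permutation of
#'   \code{c("missing", "ar2", "maf")}.
#' @return the filtered \code{geno_matrix}.
#' @export
filter_markers <- function(geno, max_missing = 0.6, ar2_min = 0.3,
                           maf_min = 0.01,
                           order = c("missing", "ar2", "maf")) {
  stopifnot(all(c(max_missing, ar2_min, maf_min) >= 0),
            all(c(max_missing, ar2_min, maf_min) <= 1),
            setequal(order, c("missing", "ar2", "maf")))
  keep <- rep(TRUE, ncol(geno$dosages))
  log <- c(input = sum(keep))
  for (step in order) {
    idx <- which(keep)
    if (step == "missing") {
      miss <- colMeans(is.na(geno$dosages[, idx, drop = FALSE]))
      keep[idx[miss > max_missing]] <- FALSE
    } else if (step == "ar2") {
      ar2 <- geno$map$ar2[idx]
      keep[idx[!is.na(ar2) & ar2 <= ar2_min]] <- FALSE
    } else {
      p <- marker_freq(geno$dosages[, idx, drop = FALSE])
      maf <- pmin(p, 1 - p)
      keep[idx[is.na(maf) | maf <= maf_min]] <- FALSE
    }
    log[step] <- sum(keep)
  }
  if (!any(keep)) stop("all markers removed by QC filters")
  out <- genotype_matrix(geno$dosages[, keep, drop = FALSE],
                         geno$map[keep, , drop = FALSE], geno$panel)
  attr(out, "filter_log") <- log
  out
}

#' VanRaden genomic relationship matrix
#'
#' \eqn{G = W W' / (2 \sum_k p_k (1 - p_k))} with \eqn{W} the dosage matrix
#' column-centered by \eqn{2 p_k} and \eqn{p_k} the observed allele
#' frequency (mean dosage / 2). Missing dosages are mean-imputed before
#' centering. Monomorphic markers contribute nothing.
#'
#' @param geno a \code{geno_matrix} or a plain dosage matrix.
#' @return clone x clone matrix with attributes \code{method} and
#'   \code{n_markers}.
#' @export
grm_vanraden <- function(geno) {
  M <- if (inherits(geno, "geno_matrix")) geno$dosages else geno
  stopifnot(nrow(M) >= 2)
  p <- colMeans(M, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic markers; cannot build a GRM")
  M <- M[, poly, drop = FALSE]
  p <- p[poly]
  W <- sweep(M, 2, 2 * p)
  W[is.na(W)] <- 0
  G <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  attr(G, "method") <- "vanraden"
  attr(G, "n_markers") <- sum(poly)
  G
}

#' SNP heritability from a kernel mixed model
#'
#' REML fit of \eqn{y = \mu + g + e}, \eqn{g \sim N(0, G\sigma^2_g)}, on the
#' clones shared between the phenotype vector and the GRM.
#'
#' @param dereg named numeric (typically de-regressed BLUPs).
#' @param G GRM with clone dimnames.
#' @param min_shared minimum number of shared clones (default 30).
#' @return list with \code{h2}, \code{varcomps}, \code{n}, \code{fit}.
#' @export
snp_heritability <- function(dereg, G, min_shared = 30) {
  shared <- intersect(names(dereg), rownames(G))
  if (length(shared) < min_shared)
    stop("only ", length(shared), " clones shared between phenotype and GRM")
  y <- dereg[shared]
  fit <- emma_reml(y, G[shared, shared])
  list(h2 = unname(fit$h2), varcomps = fit$varcomps, n = length(shared),
       fit = fit)
}

#' Principal components of the genotype matrix
#'
#' Eigen-decomposition of the covariance of centered (optionally
#' standardized) dosages, for population-stratification diagnostics.
#'
#' @param geno a \code{geno_matrix}.
#' @param k number of components to return.
#' @param standardize scale each marker to unit variance (default FALSE).
#' @return list with \code{scores} (clones x k), \code{varfrac} (fraction
#'   of total variance per returned component, non-increasing).
#' @export
pca_genotypes <- function(geno, k = 10, standardize = FALSE) {
  M <- geno$dosages
  if (k <= 0) stop("k must be positive")
  k <- min(k, nrow(M), ncol(M))
  M[is.na(M)] <- 0
  sds <- apply(M, 2, stats::sd)
  if (standardize) M <- M[, sds > 0, drop = FALSE]
  pc <- stats::prcomp(M, center = TRUE, scale. = standardize)
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       varfrac = varfrac[seq_len(k)])
}
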