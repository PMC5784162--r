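## Mixed-linear-model association with leave-one-chromosome-out kinship,
## significance thresholds, variance explained, candidate-gene annotation.

#' MLMA with leave-one-chromosome-out kinship
#'
#' For each chromosome, variance components are re-estimated under a GRM
#' built from all other chromosomes (so a candidate marker never
#' contributes to its own kinship), and every marker on the chromosome is
#' tested by generalized least squares under that fit. The per-marker test
#' re-estimates the residual scale from the marker model and refers the
#' statistic to a t distribution (df = n - p - 1), which reduces exactly to
#' ordinary least squares when the kinship is the identity.
#'
#' @param geno a \code{geno_matrix}.
#' @param dereg named numeric phenotype (de-regressed BLUPs).
#' @param maf_min markers with MAF not above this are skipped (default
#'   0.05, the association-stage filter).
#' @param min_shared minimum clones shared between phenotype and genotypes.
#' @param kinship \code{"loco"} (default), \code{"whole_genome"}, or
#'   \code{"identity"} (the no-polygenic-background limit, in which the
#'   test reduces to ordinary least squares); with a single chromosome the
#'   whole-genome kinship is used with a warning.
#' @return data.frame of class \code{gwas_table}: marker, chrom, bp, freq,
#'   effect, se, p, neg_log10_p; metadata in attributes.
#' @export
mlma_loco <- function(geno, dereg, maf_min = 0.05, min_shared = 50,
                      kinship = c("loco", "whole_genome", "identity")) {
  kinship <- match.arg(kinship)
  dereg <- dereg[!is.na(dereg)]
  shared <- intersect(rownames(geno$dosages), names(dereg))
  if (length(shared) < min_shared)
    stop("only ", length(shared), " clones shared; need >= ", min_shared)
  M <- geno$dosages[shared, , drop = FALSE]
  y <- dereg[shared]
  n <- length(y)
  p <- colMeans(M, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf > maf_min
  map <- geno$map
  chroms <- unique(map$chrom)
  if (length(chroms) < 2 && kinship == "loco") {
    warning("single chromosome: falling back to whole-genome kinship")
    kinship <- "whole_genome"
  }
  Mimp <- M
  if (anyNA(Mimp)) {
    for (j in which(colSums(is.na(Mimp)) > 0))
      Mimp[is.na(Mimp[, j]), j] <- mean(Mimp[, j], na.rm = TRUE)
  }
  G_all <- switch(kinship,
                  whole_genome = grm_vanraden(Mimp),
                  identity = diag(n),
                  NULL)
  if (kinship == "loco") {
    ## per-chromosome centered cross-products; the LOCO kinship for a
    ## chromosome is the whole-genome sum minus its own block
    pim <- colMeans(Mimp) / 2
    XP <- lapply(chroms, function(ch) {
      idx <- which(map$chrom == ch)
      W <- sweep(Mimp[, idx, drop = FALSE], 2, 2 * pim[idx])
      list(P = tcrossprod(W), d = 2 * sum(pim[idx] * (1 - pim[idx])))
    })
    P_tot <- Reduce(`+`, lapply(XP, `[[`, "P"))
    d_tot <- sum(vapply(XP, `[[`, numeric(1), "d"))
  }

  res <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    on_ch <- which(map$chrom == ch & keep)
    if (length(on_ch) == 0) next
    K <- if (kinship == "loco")
      (P_tot - XP[[ci]]$P) / (d_tot - XP[[ci]]$d) else G_all
    dimnames(K) <- NULL
    null <- emma_reml(y, K)
    U <- null$U
    w <- 1 / (null$eigenvalues + null$delta)
    ys <- as.numeric(crossprod(U, y))
    x0 <- as.numeric(crossprod(U, rep(1, n)))
    Gs <- crossprod(U, Mimp[, on_ch, drop = FALSE])
    ## weighted regression of ys on (x0, g) per marker, closed form
    a11 <- sum(w * x0^2)
    b1 <- sum(w * x0 * ys)
    syy <- sum(w * ys^2)
    a12 <- colSums(w * x0 * Gs)
    a22 <- colSums(w * Gs^2)
    b2 <- colSums(w * ys * Gs)
    det <- a11 * a22 - a12^2
    beta <- (a11 * b2 - a12 * b1) / det
    alpha <- (b1 - a12 * beta) / a11
    rss <- syy - alpha * b1 - beta * b2
    df <- n - 2
    sigma2 <- pmax(rss, 0) / df
    se <- sqrt(sigma2 * a11 / det)
    tval <- beta / se
    pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
    res[[ci]] <- data.frame(marker = map$marker[on_ch],
                            chrom = map$chrom[on_ch], bp = map$pos[on_ch],
                            freq = p[on_ch], effect = beta, se = se,
                            p = pval, neg_log10_p = -log10(pval),
                            row.names = NULL)
  }
  out <- do.call(rbind, res)
  out <- out[order(match(out$chrom, chroms), out$bp), ]
  rownames(out) <- NULL
  attr(out, "n_clones") <- n
  attr(out, "kinship") <- kinship
  attr(out, "maf_min") <- maf_min
  class(out) <- c("gwas_table", class(out))
  out
}

#' Bonferroni genome-wide significance threshold on the -log10 scale
#'
#' @param n_markers number of tested markers.
#' @param alpha family-wise error rate (default 0.05).
#' @return -log10(alpha / n_markers).
#' @export
bonferroni_threshold <- function(n_markers, alpha = 0.05) {
  stopifnot(n_markers >= 1)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)")
  -log10(alpha / n_markers)
}

#' Phenotypic variance explained by a marker
#'
#' The conventional single-marker estimator
#' \eqn{2 p (1 - p) \beta^2 / Var(y)}, clipped to [0, 1].
#'
#' @param effect estimated allele-substitution effect.
#' @param freq allele frequency in (0, 1).
#' @param pheno_var phenotypic variance (variance of the de-regressed
#'   BLUPs).
#' @export
pve <- function(effect, freq, pheno_var) {
  if (any(pheno_var <= 0)) stop("pheno_var must be > 0")
  if (any(freq <= 0 | freq >= 1)) stop("freq must lie in (0,1)")
  pmin(pmax(2 * freq * (1 - freq) * effect^2 / pheno_var, 0), 1)
}

#' Annotate significant GWAS hits with gene models
#'
#' Markers above the -log10(p) threshold are intersected with gene
#' intervals from a GFF3 file (1-based inclusive coordinates); markers
#' falling in no gene are reported as intergenic.
#'
#' @param table a \code{gwas_table}.
#' @param gff path to a GFF3 file, or a \code{GRanges} of gene models.
#' @param threshold -log10(p) significance threshold.
#' @param feature_type GFF3 feature type to intersect (default
#'   \code{"gene"}).
#' @return data.frame: marker, chrom, bp, neg_log10_p, gene_id (NA =
#'   intergenic), genic flag.
#' @export
annotate_hits <- function(table, gff, threshold, feature_type = "gene") {
  hits <- table[table$neg_log10_p > threshold, , drop = FALSE]
  if (nrow(hits) == 0)
    return(data.frame(marker = character(), chrom = character(),
                      bp = integer(), neg_log10_p = numeric(),
                      gene_id = character(), genic = logical()))
  genes <- if (methods::is(gff, "GRanges")) gff else
    rtracklayer::import(gff, format = "gff3")
  if ("type" %in% names(S4Vectors::mcols(genes)))
    genes <- genes[genes$type == feature_type]
  gchr <- as.character(GenomicRanges::seqnames(genes))
  missing_chr <- setdiff(unique(hits$chrom), unique(gchr))
  if (length(missing_chr) == length(unique(hits$chrom)))
    stop("chromosome names do not match the gene models: ",
         paste(missing_chr, collapse = ", "))
  snp_gr <- GenomicRanges::GRanges(hits$chrom,
                                   IRanges::IRanges(hits$bp, hits$bp))
  ov <- GenomicRanges::findOverlaps(snp_gr, genes)
  gene_id <- rep(NA_character_, nrow(hits))
  ids <- if (!is.null(genes$ID)) genes$ID else
    if (!is.null(genes$gene_id)) genes$gene_id else
      as.character(seq_along(genes))
  gene_id[S4Vectors::queryHits(ov)] <- ids[S4Vectors::subjectHits(ov)]
  data.frame(marker = hits$marker, chrom = hits$chrom, bp = hits$bp,
             neg_log10_p = hits$neg_log10_p, gene_id = gene_id,
             genic = !is.na(gene_id), row.names = NULL)
}
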