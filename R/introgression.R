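## M. glaziovii introgression-segment detection from ancestry-informative
## SNPs by windowed majority calling.

#' Match ancestry-informative SNPs to the genotype matrix
#'
#' Markers are matched to the catalog by (chrom, position) and the allele
#' orientation reconciled so that dosage counts the \emph{glaziovii}
#' allele: when the catalog's glaziovii allele is the VCF REF, the dosage
#' is flipped to 2 - d. Records whose allele pair matches neither
#' orientation are dropped with a log.
#'
#' @param geno a \code{geno_matrix}.
#' @param catalog data.frame with \code{chrom}, \code{pos},
#'   \code{esculenta_allele}, \code{glaziovii_allele}.
#' @return list: \code{dosages} (clones x matched AI SNPs, glaziovii
#'   orientation), \code{map} (matched markers), \code{n_dropped}.
#' @export
match_ai_snps <- function(geno, catalog) {
  stopifnot(all(c("chrom", "pos", "esculenta_allele",
                  "glaziovii_allele") %in% names(catalog)))
  if (any(catalog$esculenta_allele == catalog$glaziovii_allele))
    stop("catalog rows with identical alleles")
  key_g <- paste(geno$map$chrom, geno$map$pos)
  key_c <- paste(catalog$chrom, catalog$pos)
  hit <- match(key_c, key_g)
  ok <- !is.na(hit)
  if (!any(ok)) stop("no AI SNPs match the genotype map by position")
  cat_m <- catalog[ok, , drop = FALSE]
  idx <- hit[ok]
  same <- geno$map$alt[idx] == cat_m$glaziovii_allele &
    geno$map$ref[idx] == cat_m$esculenta_allele
  flip <- geno$map$ref[idx] == cat_m$glaziovii_allele &
    geno$map$alt[idx] == cat_m$esculenta_allele
  usable <- same | flip
  n_dropped <- sum(!ok) + sum(!usable)
  if (n_dropped > 0)
    message(n_dropped, " catalog SNP(s) dropped (unmatched position or ",
            "irreconcilable alleles)")
  idx <- idx[usable]; flip <- flip[usable]
  D <- geno$dosages[, idx, drop = FALSE]
  if (any(flip)) D[, flip] <- 2 - D[, flip]
  map <- geno$map[idx, c("marker", "chrom", "pos"), drop = FALSE]
  ord <- order(match(map$chrom, unique(map$chrom)), map$pos)
  list(dosages = D[, ord, drop = FALSE], map = map[ord, , drop = FALSE],
       n_dropped = n_dropped)
}

#' Call window ancestry from matched AI-SNP dosages
#'
#' Per chromosome, AI SNPs are tiled into non-overlapping windows of
#' \code{window} SNPs in bp order (a trailing remainder is dropped). In
#' each window each genotype is classified GG (dosage 2 on the glaziovii
#' orientation), GE (1) or EE (0); the window call is the most common
#' class iff its proportion is at least \code{ratio} times the
#' second-most-common (ties at exactly the ratio are calls), otherwise
#' NoCall. Missing genotypes are excluded from the proportions; windows
#' with fewer than \code{min_informative} non-missing AI SNPs are NoCall.
#'
#' @param matched result of \code{\link{match_ai_snps}}.
#' @param window AI SNPs per window (default 20).
#' @param ratio majority dominance ratio (default 2).
#' @param min_informative minimum non-missing AI SNPs per window
#'   (default 10).
#' @return data.frame: clone, chrom, window, start_bp, end_bp, call,
#'   prop_GG, prop_GE, prop_EE, n_informative.
#' @export
call_windows <- function(matched, window = 20, ratio = 2,
                         min_informative = 10) {
  D <- matched$dosages; map <- matched$map
  out <- list()
  for (ch in unique(map$chrom)) {
    cols <- which(map$chrom == ch)
    nwin <- length(cols) %/% window
    if (nwin == 0) next
    if (length(cols) %% window > 0)
      message("chromosome ", ch, ": dropping ", length(cols) %% window,
              " trailing AI SNP(s) not filling a window")
    for (w in seq_len(nwin)) {
      wc <- cols[((w - 1) * window + 1):(w * window)]
      Dw <- D[, wc, drop = FALSE]
      nGG <- rowSums(Dw == 2, na.rm = TRUE)
      nGE <- rowSums(Dw == 1, na.rm = TRUE)
      nEE <- rowSums(Dw == 0, na.rm = TRUE)
      ninf <- nGG + nGE + nEE
      P <- cbind(GG = nGG, GE = nGE, EE = nEE) / pmax(ninf, 1)
      top <- max.col(P, ties.method = "first")
      first <- P[cbind(seq_len(nrow(P)), top)]
      Pminus <- P; Pminus[cbind(seq_len(nrow(P)), top)] <- -1
      second <- apply(Pminus, 1, max)
      call <- colnames(P)[top]
      call[first < ratio * second] <- "NoCall"
      call[ninf < min_informative] <- "NoCall"
      out[[length(out) + 1]] <- data.frame(
        clone = rownames(D), chrom = ch, window = w,
        start_bp = min(map$pos[wc]), end_bp = max(map$pos[wc]),
        call = call, prop_GG = P[, "GG"], prop_GE = P[, "GE"],
        prop_EE = P[, "EE"], n_informative = ninf, row.names = NULL)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$clone, match(res$chrom, unique(map$chrom)), res$window), ]
}

#' Merge window calls into introgression segments
#'
#' Maximal runs of identical non-EE window calls per clone and chromosome
#' are merged into (clone, chrom, start, end, call) segments; a NoCall or
#' EE window breaks a run. Pure-esculenta panels therefore yield an empty
#' table.
#'
#' @param calls output of \code{\link{call_windows}}.
#' @return data.frame: clone, chrom, start_bp, end_bp, call, n_windows.
#' @export
segments_from_windows <- function(calls) {
  calls <- calls[order(calls$clone, calls$chrom, calls$window), ]
  segs <- list()
  for (key in split(seq_len(nrow(calls)),
                    paste(calls$clone, calls$chrom))) {
    cc <- calls[key, ]
    keep <- cc$call %in% c("GG", "GE")
    if (!any(keep)) next
    r <- rle(paste(cc$call, cumsum(!keep)))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in seq_along(r$lengths)) {
      i1 <- starts[k]; i2 <- ends[k]
      if (!keep[i1]) next
      segs[[length(segs) + 1]] <- data.frame(
        clone = cc$clone[i1], chrom = cc$chrom[i1],
        start_bp = cc$start_bp[i1], end_bp = cc$end_bp[i2],
        call = cc$call[i1], n_windows = i2 - i1 + 1)
    }
  }
  if (length(segs) == 0)
    return(data.frame(clone = character(), chrom = character(),
                      start_bp = integer(), end_bp = integer(),
                      call = character(), n_windows = integer()))
  res <- do.call(rbind, segs)
  rownames(res) <- NULL
  res
}

#' Write introgression segments as BED (0-based half-open)
#' @param segments output of \code{\link{segments_from_windows}}.
#' @param path output path.
#' @export
write_segments_bed <- function(segments, path) {
  bed <- data.frame(chrom = segments$chrom,
                    start = segments$start_bp - 1L,
                    end = segments$end_bp,
                    name = paste0(segments$clone, ":", segments$call))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
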