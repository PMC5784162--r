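# In-code fixtures shared across test files.

# Genotype matrix of iid markers (no LD), for calibration-style tests.
quick_geno <- function(n = 100, m = 50, n_chrom = 2, seed = 1,
                       freq = NULL) {
  set.seed(seed)
  if (is.null(freq)) freq <- runif(m, 0.1, 0.9)
  M <- matrix(rbinom(n * m, 2, rep(freq, each = n)), n, m)
  chrom <- as.character(rep(seq_len(n_chrom), each = ceiling(m / n_chrom),
                            length.out = m))
  pos <- as.integer(unlist(lapply(table(chrom)[unique(chrom)], function(k)
    sort(sample.int(3e7, k)))))
  map <- data.frame(marker = paste0("S", chrom, "_", pos), chrom = chrom,
                    pos = pos, ref = "A", alt = "C", ar2 = NA_real_)
  dimnames(M) <- list(sprintf("c%04d", seq_len(n)), map$marker)
  genotype_matrix(M, map)
}

# Small downscale of the default generator, for structural tests. The
# donor interval spans most of chromosome 4 so that 20-AI-SNP windows fit
# even at the reduced marker density.
small_cfg <- function(seed = 1, n_clones_panel1 = 60, n_clones_panel2 = 120,
                      markers_per_chrom = 200, n_background = 80,
                      introgression_spec = list(chrom = "4", start_bp = 1e6,
                                                end_bp = 2.9e7,
                                                carrier_freq = 0.25,
                                                effect = -0.4),
                      ...) {
  sim_config(n_clones_panel1 = n_clones_panel1,
             n_clones_panel2 = n_clones_panel2,
             markers_per_chrom = markers_per_chrom,
             n_background = n_background,
             introgression_spec = introgression_spec, seed = seed, ...)
}

# Matched-AI-SNP object built directly from a dosage matrix (glaziovii
# orientation), bypassing catalog matching, for window-rule tests.
fake_matched <- function(D, chrom = "4") {
  m <- ncol(D)
  list(dosages = D,
       map = data.frame(marker = paste0("ai", seq_len(m)), chrom = chrom,
                        pos = seq_len(m) * 1000L),
       n_dropped = 0L)
}
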