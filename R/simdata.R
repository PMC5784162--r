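## Synthetic two-panel breeding-population generator. Emulates the study
## conditions every downstream stage assumes: two panels (alpha-lattice and
## augmented designs) scored 1-5 at three locations each, a M. glaziovii
## introgression block on chromosome 4, a QTL cluster on chromosome 11,
## polygenic background, and location-varying entry-mean heritability.

#' Configuration for the synthetic breeding panel
#'
#' Defaults are a desk-scale downscale of the study population: two panels
#' (300 + 600 clones, the field panels' 1:2 ratio), five chromosomes labelled
#' 1, 2, 3, 4 and 11 with 1,000 markers each, a donor introgression block on
#' chromosome 4 and a QTL cluster on chromosome 11, and per-location
#' entry-mean heritabilities spanning the low-to-intermediate range seen in
#' multi-location CBSD trials.
#'
#' @param n_clones_panel1,n_clones_panel2 panel sizes.
#' @param n_chrom number of chromosomes; labelled by \code{chrom_names}.
#' @param markers_per_chrom markers per chromosome.
#' @param chrom_length_bp chromosome length in bp.
#' @param chrom_names chromosome labels (length \code{n_chrom}).
#' @param qtl_spec data.frame with columns \code{chrom}, \code{bp},
#'   \code{add}, \code{dom}: large-effect loci on the latent severity scale.
#' @param introgression_spec list with \code{chrom}, \code{start_bp},
#'   \code{end_bp}, \code{carrier_freq} (fraction of clones carrying at
#'   least one donor haplotype), \code{effect} (additive latent-scale effect
#'   per donor haplotype copy).
#' @param h2_per_location named numeric in [0,1]: target entry-mean
#'   heritability per location.
#' @param locations named list: character vector of locations per panel.
#' @param location_means named numeric, latent-scale location shifts.
#' @param design list with \code{alpha_lattice} (reps, block_size,
#'   blocks_per_range) for Panel 1 and \code{augmented} (n_checks,
#'   block_size) for Panel 2.
#' @param score_thresholds four strictly increasing cutpoints on the latent
#'   scale; ordinal score = 1 + number of cutpoints below the latent value.
#' @param traits severity trait columns to simulate.
#' @param trait_corr genetic correlation among severity traits (shared QTL,
#'   partially shared polygenic background).
#' @param loc_corr genetic correlation of a trait between locations
#'   (exposed as a single parameter; independent location deviations).
#' @param polygenic_var additive background variance on the latent scale.
#' @param n_background number of small-effect background loci per trait.
#' @param n_founders,block_len founder-haplotype pool size and copy-block
#'   length in markers; block copying induces local LD.
#' @param ai_fraction fraction of donor-chromosome markers designated
#'   ancestry-informative (fixed difference between species).
#' @param missing_rate fraction of genotype calls masked to NA (default 0;
#'   post-imputation data are complete).
#' @param include_cmds also simulate an independent CMD severity trait.
#' @param score_jitter extra latent noise added before thresholding.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_clones_panel1 = 300,
                       n_clones_panel2 = 600,
                       n_chrom = 5,
                       markers_per_chrom = 1000,
                       chrom_length_bp = 30e6,
                       chrom_names = c("1", "2", "3", "4", "11"),
                       qtl_spec = data.frame(
                         chrom = c("11", "11", "11"),
                         bp = c(13.0e6, 13.6e6, 14.2e6),
                         add = c(-0.45, -0.35, -0.30),
                         dom = c(0.15, 0, 0)),
                       introgression_spec = list(
                         chrom = "4", start_bp = 5e6, end_bp = 15e6,
                         carrier_freq = 0.25, effect = -0.4),
                       h2_per_location = c(Namulonge = 0.25, Ngetta = 0.50,
                                           Kasese = 0.30, Serere = 0.55,
                                           Kamuli = 0.60),
                       locations = list(
                         panel1 = c("Namulonge", "Ngetta", "Kasese"),
                         panel2 = c("Namulonge", "Serere", "Kamuli")),
                       location_means = c(Namulonge = 0.6, Ngetta = -0.4,
                                          Kasese = 0.4, Serere = 0,
                                          Kamuli = -0.2),
                       design = list(
                         alpha_lattice = list(reps = 2, block_size = 25,
                                              blocks_per_range = 4),
                         augmented = list(n_checks = 6, block_size = 25)),
                       score_thresholds = c(-2, -0.7, 0.7, 2),
                       traits = c("cbsd3s", "cbsd6s", "cbsdrs"),
                       trait_corr = 0.7,
                       loc_corr = 0.6,
                       polygenic_var = 1,
                       n_background = 200,
                       n_founders = 40,
                       block_len = 25,
                       ai_fraction = 0.5,
                       missing_rate = 0,
                       include_cmds = TRUE,
                       score_jitter = 0,
                       seed = 1L) {
  cfg <- list(n_clones_panel1 = n_clones_panel1,
              n_clones_panel2 = n_clones_panel2,
              n_chrom = n_chrom, markers_per_chrom = markers_per_chrom,
              chrom_length_bp = chrom_length_bp, chrom_names = chrom_names,
              qtl_spec = qtl_spec, introgression_spec = introgression_spec,
              h2_per_location = h2_per_location, locations = locations,
              location_means = location_means, design = design,
              score_thresholds = score_thresholds, traits = traits,
              trait_corr = trait_corr, loc_corr = loc_corr,
              polygenic_var = polygenic_var, n_background = n_background,
              n_founders = n_founders, block_len = block_len,
              ai_fraction = ai_fraction, missing_rate = missing_rate,
              include_cmds = include_cmds, score_jitter = score_jitter,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$chrom_names) == cfg$n_chrom)
  if (any(diff(cfg$score_thresholds) <= 0))
    stop("score_thresholds must be strictly increasing")
  if (length(cfg$score_thresholds) != 4)
    stop("exactly 4 score cutpoints are required for a 1-5 scale")
  if (any(cfg$h2_per_location < 0 | cfg$h2_per_location > 1))
    stop("h2_per_location values must lie in [0,1]")
  if (nrow(cfg$qtl_spec) > 0) {
    if (!all(cfg$qtl_spec$chrom %in% cfg$chrom_names))
      stop("qtl_spec names a chromosome not in chrom_names")
    if (any(cfg$qtl_spec$bp < 1 | cfg$qtl_spec$bp > cfg$chrom_length_bp))
      stop("qtl_spec position outside chromosome bounds")
  }
  isp <- cfg$introgression_spec
  if (!is.null(isp)) {
    stopifnot(isp$chrom %in% cfg$chrom_names,
              isp$start_bp < isp$end_bp,
              isp$carrier_freq >= 0, isp$carrier_freq <= 1)
  }
  locs <- unique(unlist(cfg$locations))
  if (!all(locs %in% names(cfg$h2_per_location)))
    stop("every location needs an h2_per_location entry")
  invisible(cfg)
}

#' Genotype container: dosages plus marker map and panel labels
#'
#' @param dosages clones x markers numeric matrix with values in [0,2]
#'   (fractional allowed for imputed data); row and column names required.
#' @param map data.frame with one row per marker: \code{marker},
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}, optional \code{ar2}.
#' @param panel named character/factor, panel label per clone (optional).
#' @export
genotype_matrix <- function(dosages, map, panel = NULL) {
  stopifnot(is.matrix(dosages), nrow(map) == ncol(dosages))
  if (is.null(rownames(dosages)) || is.null(colnames(dosages)))
    stop("dosages needs clone rownames and marker colnames")
  if (!all(map$marker == colnames(dosages)))
    stop("map order must match dosage columns")
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0,2]")
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("bp must be strictly increasing within chromosome ", ch)
  }
  structure(list(dosages = dosages, map = map, panel = panel),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("genotype matrix:", nrow(x$dosages), "clones x", ncol(x$dosages),
      "markers on", length(unique(x$map$chrom)), "chromosomes\n")
  invisible(x)
}

#' Simulate genotypes, genetic architecture and ancestry truth
#'
#' Founder haplotypes with U-shaped (Beta) allele frequencies are copied in
#' blocks to build gametes, inducing local LD. Clones carrying the donor
#' (\emph{M. glaziovii}) segment receive a diagnostic donor haplotype across
#' the introgressed interval; heterozygous carriers arise from pairing one
#' donor with one recipient gamete. The realized donor interval is snapped
#' to 20-AI-SNP window boundaries so that window-level ancestry truth is
#' exact. Returns the genotype matrix, a truth set (breeding values, total
#' genetic values, window ancestry, per-marker effects) and the
#' ancestry-informative SNP catalog.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list with elements \code{geno} (\code{geno_matrix}),
#'   \code{truth}, and \code{catalog} (AI-SNP table).
#' @export
simulate_genotypes <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  M <- cfg$n_chrom * cfg$markers_per_chrom
  n1 <- cfg$n_clones_panel1; n2 <- cfg$n_clones_panel2
  n <- n1 + n2

  map <- do.call(rbind, lapply(seq_len(cfg$n_chrom), function(i) {
    pos <- sort(sample.int(cfg$chrom_length_bp, cfg$markers_per_chrom))
    data.frame(chrom = cfg$chrom_names[i], pos = pos)
  }))
  map$marker <- paste0("S", map$chrom, "_", map$pos)
  alleles <- c("A", "C", "G", "T")
  map$ref <- sample(alleles, M, replace = TRUE)
  map$alt <- vapply(map$ref, function(r) sample(setdiff(alleles, r), 1), "")
  map$ar2 <- stats::rbeta(M, 9, 1)
  map <- map[, c("marker", "chrom", "pos", "ref", "alt", "ar2")]

  isp <- cfg$introgression_spec
  donor_chrom <- if (is.null(isp)) NA_character_ else isp$chrom
  is_donor_chr <- map$chrom == donor_chrom

  ## AI SNPs: a subset of donor-chromosome markers fixed for the esculenta
  ## allele in the recipient pool (low ALT frequency outside the segment)
  ai_idx <- integer(0)
  if (!is.na(donor_chrom)) {
    cand <- which(is_donor_chr)
    ai_idx <- sort(sample(cand, max(1, round(length(cand) * cfg$ai_fraction))))
  }
  p <- pmin(pmax(stats::rbeta(M, 0.3, 0.3), 0.01), 0.99)
  p[ai_idx] <- pmin(stats::rbeta(length(ai_idx), 0.5, 20), 0.2)

  founders <- matrix(stats::rbinom(cfg$n_founders * M, 1, rep(p, each = cfg$n_founders)),
                     nrow = cfg$n_founders, ncol = M)

  ## gametes by founder-block copying
  nb_per_chr <- ceiling(cfg$markers_per_chrom / cfg$block_len)
  nblocks <- cfg$n_chrom * nb_per_chr
  blk <- rep(seq_len(nblocks),
             each = cfg$block_len, length.out = M)
  n_gam <- 2L * n
  choice <- matrix(sample.int(cfg$n_founders, n_gam * nblocks, replace = TRUE),
                   nrow = n_gam)
  fid <- choice[, blk, drop = FALSE]                       # n_gam x M founder ids
  gam <- matrix(founders[cbind(as.vector(fid), rep(seq_len(M), each = n_gam))],
                nrow = n_gam, ncol = M)

  ## introgression: realized interval snapped to AI-window boundaries
  window_size <- 20L
  seg_idx <- integer(0)
  donor_gam <- rep(FALSE, n_gam)
  ai_window <- rep(NA_integer_, M)
  if (!is.na(donor_chrom)) {
    ai_window[ai_idx] <- rep(seq_len(length(ai_idx) %/% window_size + 1L),
                             each = window_size, length.out = length(ai_idx))
    complete <- table(ai_window[ai_idx]) == window_size
    keep_w <- as.integer(names(complete)[complete])
    ai_window[!(ai_window %in% keep_w)] <- NA  # trailing remainder dropped
    in_spec <- ai_idx[map$pos[ai_idx] >= isp$start_bp &
                        map$pos[ai_idx] <= isp$end_bp]
    if (length(in_spec) < window_size)
      stop("introgression interval contains fewer than ", window_size,
           " AI markers; cannot be window-called")
    w_in <- unique(stats::na.omit(ai_window[in_spec]))
    w_full <- w_in[vapply(w_in, function(w) {
      all(ai_idx[which(ai_window[ai_idx] == w)] %in% in_spec)
    }, logical(1))]
    if (length(w_full) == 0)
      stop("no complete 20-AI-SNP window inside the introgression interval")
    seg_snps <- ai_idx[ai_window[ai_idx] %in% w_full]
    seg_lo <- min(map$pos[seg_snps]); seg_hi <- max(map$pos[seg_snps])
    seg_idx <- which(is_donor_chr & map$pos >= seg_lo & map$pos <= seg_hi)
    donor_hap <- stats::rbinom(length(seg_idx), 1, p[seg_idx])
    donor_hap[seg_idx %in% ai_idx] <- 1L       # diagnostic ALT (glaziovii)
    if (isp$carrier_freq > 0) {
      a <- 1 - sqrt(1 - isp$carrier_freq)      # per-gamete donor probability
      donor_gam <- stats::rbinom(n_gam, 1, a) == 1
      if (any(donor_gam))
        gam[donor_gam, seg_idx] <- matrix(donor_hap, sum(donor_gam),
                                          length(seg_idx), byrow = TRUE)
    }
  }

  g1 <- seq_len(n) * 2L - 1L
  dos <- gam[g1, , drop = FALSE] + gam[g1 + 1L, , drop = FALSE]
  clones <- c(sprintf("P1_C%03d", seq_len(n1)), sprintf("P2_C%03d", seq_len(n2)))
  rownames(dos) <- clones
  colnames(dos) <- map$marker
  panel <- stats::setNames(rep(c("panel1", "panel2"), c(n1, n2)), clones)
  seg_dose <- as.integer(donor_gam[g1]) + as.integer(donor_gam[g1 + 1L])
  names(seg_dose) <- clones

  if (cfg$missing_rate > 0) {
    nmiss <- round(cfg$missing_rate * length(dos))
    dos[sample.int(length(dos), nmiss)] <- NA
  }

  ## genetic architecture on the latent severity scale
  qtl_marker <- integer(0)
  qtl_effects <- stats::setNames(numeric(0), character(0))
  add_bv <- rep(0, n); dom_dev <- rep(0, n)
  if (nrow(cfg$qtl_spec) > 0) {
    obs_p <- colMeans(dos, na.rm = TRUE) / 2
    for (q in seq_len(nrow(cfg$qtl_spec))) {
      ## anchor to the nearest segregating marker: a monomorphic QTL would
      ## contribute no variance and break the stated architecture
      on_chr <- which(map$chrom == cfg$qtl_spec$chrom[q] &
                        pmin(obs_p, 1 - obs_p) >= 0.05)
      if (length(on_chr) == 0)
        on_chr <- which(map$chrom == cfg$qtl_spec$chrom[q])
      j <- on_chr[which.min(abs(map$pos[on_chr] - cfg$qtl_spec$bp[q]))]
      qtl_marker <- c(qtl_marker, j)
      qtl_effects[map$marker[j]] <- cfg$qtl_spec$add[q]
      dj <- dos[, j]; dj[is.na(dj)] <- mean(dj, na.rm = TRUE)
      add_bv <- add_bv + cfg$qtl_spec$add[q] * (dj - mean(dj))
      dom_dev <- dom_dev + cfg$qtl_spec$dom[q] * (dj == 1)
    }
  }
  if (!is.na(donor_chrom) && !is.null(isp$effect) && isp$effect != 0) {
    add_bv <- add_bv + isp$effect * (seg_dose - mean(seg_dose))
  }

  ## partially shared polygenic background across severity traits
  bg_idx <- sample(setdiff(seq_len(M), qtl_marker), cfg$n_background)
  Wbg <- dos[, bg_idx, drop = FALSE]
  Wbg[is.na(Wbg)] <- 0
  Wbg <- scale(Wbg, center = TRUE, scale = FALSE)
  draw_bg <- function() {
    b <- stats::rnorm(cfg$n_background, 0, 1)
    g <- as.numeric(Wbg %*% b)
    g * sqrt(cfg$polygenic_var) / stats::sd(g)
  }
  bg_common <- draw_bg()
  traits <- cfg$traits
  bv <- sapply(traits, function(tr) {
    add_bv + sqrt(cfg$trait_corr) * bg_common +
      sqrt(1 - cfg$trait_corr) * draw_bg()
  })
  rownames(bv) <- clones
  tgv <- bv + dom_dev
  cmds_bv <- NULL
  if (cfg$include_cmds) cmds_bv <- stats::setNames(draw_bg(), clones)

  ## window ancestry truth on the donor chromosome
  truth_anc <- NULL
  catalog <- NULL
  if (!is.na(donor_chrom)) {
    w_ids <- sort(unique(stats::na.omit(ai_window[ai_idx])))
    truth_anc <- do.call(rbind, lapply(w_ids, function(w) {
      snps <- ai_idx[which(ai_window[ai_idx] == w)]
      inside <- all(snps %in% seg_idx)
      cls <- if (inside) c("EE", "GE", "GG")[seg_dose + 1L] else rep("EE", n)
      data.frame(clone = clones, chrom = donor_chrom, window = w,
                 start_bp = min(map$pos[snps]), end_bp = max(map$pos[snps]),
                 truth = cls)
    }))
    catalog <- data.frame(chrom = map$chrom[ai_idx], pos = map$pos[ai_idx],
                          esculenta_allele = map$ref[ai_idx],
                          glaziovii_allele = map$alt[ai_idx])
  }

  geno <- genotype_matrix(dos, map, panel)
  truth <- list(generating_freq = stats::setNames(p, map$marker),
                true_breeding_values = bv,
                true_total_genetic_values = tgv,
                dominance_deviations = stats::setNames(dom_dev, clones),
                cmds_breeding_values = cmds_bv,
                introgression_dose = seg_dose,
                segment_markers = map$marker[seg_idx],
                true_ancestry = truth_anc,
                qtl_effects = qtl_effects,
                qtl_markers = map$marker[qtl_marker])
  list(geno = geno, truth = truth, catalog = catalog)
}

## ---- field designs -------------------------------------------------------

layout_alpha_lattice <- function(clones, location, reps, block_size,
                                 blocks_per_range) {
  do.call(rbind, lapply(seq_len(reps), function(r) {
    ord <- sample(clones)
    blockn <- ceiling(seq_along(ord) / block_size)
    data.frame(clone = ord, location = location, rep = r,
               block = blockn,
               range = ceiling(blockn / blocks_per_range),
               is_check = FALSE)
  }))
}

layout_augmented <- function(entries, checks, location, block_size) {
  ord <- sample(entries)
  blockn <- ceiling(seq_along(ord) / block_size)
  ent <- data.frame(clone = ord, location = location, rep = 1,
                    block = blockn, range = NA_integer_, is_check = FALSE)
  chk <- do.call(rbind, lapply(unique(blockn), function(b) {
    data.frame(clone = checks, location = location, rep = 1, block = b,
               range = NA_integer_, is_check = TRUE)
  }))
  rbind(ent, chk)
}

#' Simulate plot-level ordinal phenotypes over the trial designs
#'
#' Latent plot value = location mean + per-location genetic value + block
#' (and range, alpha lattice) effects + residual, with the non-genetic
#' variance scaled so the per-location entry-mean heritability matches the
#' configuration. Ordinal scores are 1 + the number of cutpoints below the
#' latent value. Design columns (rep/block/range, check flags) are
#' populated per panel.
#'
#' @param geno \code{geno_matrix} from \code{\link{simulate_genotypes}}.
#' @param truth truth set from the same call.
#' @param cfg the \code{sim_config} used to generate them.
#' @param seed optional seed (default derived from \code{cfg$seed}).
#' @return data.frame with design columns, one ordinal column per trait and
#'   matching \code{<trait>_latent} columns.
#' @export
simulate_phenotypes <- function(geno, truth, cfg, seed = cfg$seed + 1000L) {
  validate_sim_config(cfg)
  set.seed(seed)
  clones <- rownames(geno$dosages)
  if (!all(clones %in% rownames(truth$true_breeding_values)))
    stop("every clone in the genotype matrix needs a truth entry")
  if (cfg$score_jitter > 0 && any(cfg$h2_per_location == 1))
    stop("h2 = 1 with nonzero score_jitter is inconsistent")

  traits <- cfg$traits
  panels <- split(clones, geno$panel[clones])
  out <- list()
  for (pn in names(panels)) {
    pcl <- panels[[pn]]
    locs <- cfg$locations[[pn]]
    des <- if (pn == "panel1") "alpha_lattice" else "augmented"
    for (loc in locs) {
      if (des == "alpha_lattice") {
        d <- cfg$design$alpha_lattice
        lay <- layout_alpha_lattice(pcl, loc, d$reps, d$block_size,
                                    d$blocks_per_range)
        rbar <- d$reps
        props <- c(block = 0.15, range = 0.15, resid = 0.70)
      } else {
        d <- cfg$design$augmented
        checks <- pcl[seq_len(d$n_checks)]
        entries <- setdiff(pcl, checks)
        lay <- layout_augmented(entries, checks, loc, d$block_size)
        rbar <- 1
        props <- c(block = 0.20, range = 0, resid = 0.80)
      }
      h2 <- cfg$h2_per_location[[loc]]
      mu <- if (loc %in% names(cfg$location_means))
        cfg$location_means[[loc]] else 0

      for (tr in c(traits, if (cfg$include_cmds) "cmds")) {
        bv <- if (tr == "cmds") truth$cmds_breeding_values[pcl]
          else truth$true_breeding_values[pcl, tr]
        gtot <- bv + if (tr == "cmds") 0 else truth$dominance_deviations[pcl]
        ## location-specific genetic deviation (single correlation parameter)
        gsd <- stats::sd(gtot)
        gloc <- sqrt(cfg$loc_corr) * gtot +
          sqrt(1 - cfg$loc_corr) * stats::rnorm(length(pcl), 0, gsd)
        names(gloc) <- pcl
        vg <- stats::var(gloc)
        vother <- if (h2 > 0) rbar * vg * (1 - h2) / h2 else 100 * vg
        nb <- max(lay$block) * max(lay$rep)
        beff <- stats::rnorm(nb, 0, sqrt(vother * props["block"]))
        bkey <- (lay$rep - 1) * max(lay$block) + lay$block
        reff <- 0
        if (props["range"] > 0) {
          nr <- max(lay$range) * max(lay$rep)
          rv <- stats::rnorm(nr, 0, sqrt(vother * props["range"]))
          reff <- rv[(lay$rep - 1) * max(lay$range) + lay$range]
        }
        eps <- stats::rnorm(nrow(lay), 0, sqrt(vother * props["resid"]))
        latent <- mu + gloc[lay$clone] + beff[bkey] + reff + eps
        if (cfg$score_jitter > 0)
          latent <- latent + stats::rnorm(length(latent), 0, cfg$score_jitter)
        score <- 1L + vapply(latent, function(v)
          sum(cfg$score_thresholds < v), integer(1))
        lay[[tr]] <- score
        lay[[paste0(tr, "_latent")]] <- latent
      }
      lay$panel <- pn
      out[[paste(pn, loc)]] <- lay
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full generator and optionally write its files
#'
#' @param cfg a \code{sim_config}.
#' @param dir if non-NULL, write genotypes (VCF + dosage CSV), phenotypes,
#'   truth and the AI-SNP catalog there.
#' @return list with \code{geno}, \code{truth}, \code{catalog},
#'   \code{pheno}.
#' @export
simulate_panel <- function(cfg, dir = NULL) {
  sim <- simulate_genotypes(cfg)
  pheno <- simulate_phenotypes(sim$geno, sim$truth, cfg)
  res <- c(sim, list(pheno = pheno))
  if (!is.null(dir)) write_sim_data(res, dir)
  res
}

#' @rdname simulate_panel
#' @param sim result of \code{simulate_panel}.
#' @export
write_sim_data <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_vcf(sim$geno, file.path(dir, "genotypes.vcf"))
  utils::write.csv(data.frame(clone = rownames(sim$geno$dosages),
                              sim$geno$dosages, check.names = FALSE),
                   file.path(dir, "dosages.csv"), row.names = FALSE)
  utils::write.csv(sim$geno$map, file.path(dir, "marker_map.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$pheno, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE)
  bv <- sim$truth$true_breeding_values
  utils::write.csv(data.frame(clone = rownames(bv), bv, check.names = FALSE),
                   file.path(dir, "truth_breeding_values.csv"),
                   row.names = FALSE)
  if (!is.null(sim$truth$true_ancestry))
    utils::write.csv(sim$truth$true_ancestry,
                     file.path(dir, "truth_ancestry.csv"), row.names = FALSE)
  if (!is.null(sim$catalog))
    utils::write.csv(sim$catalog, file.path(dir, "ai_catalog.csv"),
                     row.names = FALSE)
  invisible(dir)
}
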