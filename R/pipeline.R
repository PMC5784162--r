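## End-to-end orchestration: simulate (or ingest) -> stage-1 mixed models ->
## QC/GRM/PCA -> MLMA-LOCO GWAS -> genomic prediction -> introgression ->
## LD diagnostics, from one configuration, with a manifest for provenance.

#' Default pipeline configuration
#'
#' @param seed global seed; per-stage seeds are derived from it by fixed
#'   offsets so stages can be re-run in isolation.
#' @param stages character subset of c("simdata", "stage1", "genomics",
#'   "gwas", "prediction", "introgression", "ld").
#' @param traits severity traits to analyse.
#' @param models prediction models for the CV stage.
#' @param sim a \code{\link{sim_config}} (rebuilt with the derived seed if
#'   NULL).
#' @param maf_min,ar2_min,max_missing QC thresholds.
#' @param gwas_maf association-stage MAF filter.
#' @param alpha Bonferroni family-wise error rate.
#' @param cv_k,cv_reps cross-validation folds and repetitions.
#' @param gff optional GFF3 path for hit annotation.
#' @export
pipeline_config <- function(seed = 1L,
                            stages = c("simdata", "stage1", "genomics",
                                       "gwas", "prediction",
                                       "introgression", "ld"),
                            traits = c("cbsd3s", "cbsd6s", "cbsdrs"),
                            models = c("gblup", "mk_gblup"),
                            sim = NULL,
                            maf_min = 0.01, ar2_min = 0.3,
                            max_missing = 0.6, gwas_maf = 0.05,
                            alpha = 0.05, cv_k = 5, cv_reps = 2,
                            gff = NULL) {
  if (length(stages) == 0) stop("at least one stage must be enabled")
  if (is.null(sim)) sim <- sim_config(seed = seed + 101L)
  list(seed = as.integer(seed), stages = stages, traits = traits,
       models = models, sim = sim, maf_min = maf_min, ar2_min = ar2_min,
       max_missing = max_missing, gwas_maf = gwas_maf, alpha = alpha,
       cv_k = cv_k, cv_reps = cv_reps, gff = gff)
}

#' Run the two-stage pipeline
#'
#' Each enabled stage consumes the previous stages' outputs and writes its
#' tables under \code{out_dir}; a JSON manifest records the seed, the
#' parameters and per-stage row counts. The run is deterministic given the
#' configuration seed.
#'
#' @param config list from \code{\link{pipeline_config}} or the path to a
#'   YAML file with the same fields.
#' @param out_dir output directory.
#' @return (invisibly) a list of in-memory stage results plus the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run")) {
  if (is.character(config)) {
    raw <- yaml::read_yaml(config)
    config <- do.call(pipeline_config, raw)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "cassavaGS",
                   version = as.character(utils::packageVersion("cassavaGS")),
                   seed = config$seed, stages = config$stages, rows = list())
  res <- list()
  on_fail <- function(stage, e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)

  if ("simdata" %in% config$stages) {
    res$sim <- tryCatch(simulate_panel(config$sim, dir = out_dir),
                        error = function(e) on_fail("simdata", e))
    manifest$rows$simdata <- as.list(c(clones = nrow(res$sim$geno$dosages),
                               markers = ncol(res$sim$geno$dosages),
                               plots = nrow(res$sim$pheno)))
  }
  if ("stage1" %in% config$stages) {
    ph <- res$sim$pheno
    dereg <- list()
    fits <- list()
    for (pn in unique(ph$panel)) {
      des <- if (pn == "panel1") "alpha_lattice" else "augmented"
      for (tr in config$traits) {
        fit <- tryCatch(reml_fit(ph[ph$panel == pn, ], tr, design = des),
                        error = function(e) on_fail("stage1", e))
        fits[[paste(pn, tr)]] <- fit
        d <- fit$dereg
        dereg[[tr]] <- c(dereg[[tr]],
                         stats::setNames(d$dereg, d$clone))
      }
    }
    res$stage1 <- list(fits = fits, dereg = dereg)
    h2tab <- data.frame(fit = names(fits),
                        H2 = vapply(fits, function(f) f$H2, numeric(1)))
    utils::write.csv(h2tab, file.path(out_dir, "stage1_h2.csv"),
                     row.names = FALSE)
    dtab <- do.call(rbind, lapply(names(dereg), function(tr)
      data.frame(trait = tr, clone = names(dereg[[tr]]),
                 dereg = unname(dereg[[tr]]))))
    utils::write.csv(dtab, file.path(out_dir, "dereg_blups.csv"),
                     row.names = FALSE)
    manifest$rows$stage1 <- as.list(c(fits = length(fits), dereg = nrow(dtab)))
  }
  if ("genomics" %in% config$stages) {
    geno_f <- tryCatch(filter_markers(res$sim$geno, config$max_missing,
                                      config$ar2_min, config$maf_min),
                       error = function(e) on_fail("genomics", e))
    G <- grm_vanraden(geno_f)
    pcs <- pca_genotypes(geno_f, k = 10)
    h2snp <- lapply(config$traits, function(tr) {
      d <- res$stage1$dereg[[tr]]
      snp_heritability(d[!is.na(d)], G)$h2
    })
    names(h2snp) <- config$traits
    res$genomics <- list(geno = geno_f, G = G, pca = pcs,
                         snp_h2 = unlist(h2snp))
    utils::write.csv(data.frame(clone = rownames(pcs$scores), pcs$scores),
                     file.path(out_dir, "pca_scores.csv"), row.names = FALSE)
    manifest$rows$genomics <- as.list(c(markers_kept = ncol(geno_f$dosages),
                                attr(geno_f, "filter_log")))
  }
  if ("gwas" %in% config$stages) {
    geno_f <- res$genomics$geno
    gtabs <- list()
    for (tr in config$traits) {
      d <- res$stage1$dereg[[tr]]
      tab <- tryCatch(mlma_loco(geno_f, d[!is.na(d)],
                                maf_min = config$gwas_maf),
                      error = function(e) on_fail("gwas", e))
      thr <- bonferroni_threshold(nrow(tab), config$alpha)
      attr(tab, "threshold") <- thr
      gtabs[[tr]] <- tab
      utils::write.table(
        data.frame(SNP = tab$marker, CHR = tab$chrom, BP = tab$bp,
                   P = tab$p),
        file.path(out_dir, paste0("gwas_", tr, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(config$gff)) {
        hits <- annotate_hits(tab, config$gff, thr)
        utils::write.table(hits,
                           file.path(out_dir, paste0("hits_", tr, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    res$gwas <- gtabs
    manifest$rows$gwas <- as.list(vapply(gtabs, nrow, integer(1)))
  }
  if ("prediction" %in% config$stages) {
    tr <- config$traits[1]
    d <- res$stage1$dereg[[tr]]
    acc <- tryCatch(cross_validate(config$models, res$genomics$geno,
                                   d[!is.na(d)],
                                   scheme = list(type = "kfold",
                                                 k = config$cv_k,
                                                 reps = config$cv_reps),
                                   seed = config$seed + 202L),
                    error = function(e) on_fail("prediction", e))
    res$prediction <- acc
    utils::write.csv(acc, file.path(out_dir, "cv_accuracy.csv"),
                     row.names = FALSE)
    manifest$rows$prediction <- as.list(c(rows = nrow(acc)))
  }
  if ("introgression" %in% config$stages) {
    matched <- tryCatch(match_ai_snps(res$sim$geno, res$sim$catalog),
                        error = function(e) on_fail("introgression", e))
    calls <- call_windows(matched)
    segs <- segments_from_windows(calls)
    res$introgression <- list(calls = calls, segments = segs)
    utils::write.table(calls, file.path(out_dir, "ancestry_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_segments_bed(segs, file.path(out_dir, "segments.bed"))
    manifest$rows$introgression <- as.list(c(windows = nrow(calls),
                                     segments = nrow(segs)))
  }
  if ("ld" %in% config$stages) {
    ch <- config$sim$introgression_spec$chrom
    ld <- tryCatch(ld_scores(res$genomics$geno, ch),
                   error = function(e) on_fail("ld", e))
    res$ld <- ld
    utils::write.table(ld, file.path(out_dir, "ld_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$rows$ld <- as.list(c(markers = nrow(ld)))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  res$out_dir <- out_dir
  invisible(res)
}
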