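## Genomic prediction: single- and multi-kernel GBLUP, Gaussian-kernel
## RKHS, Bayesian whole-genome regressions, Random Forest, and a
## cross-validation harness.

#' Single-kernel GBLUP
#'
#' REML on the training clones; GEBVs flow to untrained clones through
#' their genomic relationships with the training set.
#'
#' @param train named numeric training phenotypes.
#' @param G GRM covering at least the union of training and prediction
#'   clones.
#' @param predict_for clones to predict (default: all clones in G).
#' @param allow_overlap permit train/test overlap (default FALSE).
#' @return list of class \code{prediction_result}: \code{pred} (named GEBV
#'   + intercept), \code{gebv} (genetic effects only), \code{varcomps},
#'   \code{h2}, \code{model}.
#' @export
gblup <- function(train, G, predict_for = rownames(G),
                  allow_overlap = FALSE) {
  train <- train[!is.na(train)]
  tr <- names(train)
  stopifnot(all(tr %in% rownames(G)), all(predict_for %in% rownames(G)))
  if (!allow_overlap && length(intersect(tr, predict_for)) &&
      !setequal(tr, predict_for))
    stop("train/test overlap; pass allow_overlap = TRUE if intended")
  fit <- emma_reml(train, G[tr, tr])
  gebv <- as.numeric(fit$varcomps["g"] * G[predict_for, tr, drop = FALSE] %*%
                       fit$Py)
  names(gebv) <- predict_for
  structure(list(pred = gebv + fit$beta[1], gebv = gebv,
                 varcomps = fit$varcomps, h2 = fit$h2, model = "gblup"),
            class = "prediction_result")
}

#' Multi-kernel GBLUP / RKHS kernel averaging
#'
#' One variance component per kernel, estimated by REML; total prediction
#' is the sum of per-kernel components plus the intercept, so the
#' contribution of each kernel (e.g. chromosome 4, chromosome 11, rest of
#' genome) can be read off directly.
#'
#' @param train named numeric training phenotypes.
#' @param kernels named list of kernels (\code{\link{build_chromosome_kernels}}
#'   or \code{\link{rkhs_kernels}}), all indexed by the same clone set.
#' @param predict_for clones to predict.
#' @param allow_overlap permit train/test overlap.
#' @return \code{prediction_result} with per-kernel \code{components}
#'   (matrix), \code{varcomps} and REML kernel \code{weights}.
#' @export
multikernel_gblup <- function(train, kernels, predict_for = NULL,
                              allow_overlap = FALSE) {
  stopifnot(length(kernels) >= 2)
  cl <- rownames(kernels[[1]])
  for (K in kernels)
    if (!identical(rownames(K), cl)) stop("kernels have mismatched clone sets")
  if (is.null(predict_for)) predict_for <- cl
  train <- train[!is.na(train)]
  tr <- names(train)
  stopifnot(all(tr %in% cl), all(predict_for %in% cl))
  if (!allow_overlap && length(intersect(tr, predict_for)) &&
      !setequal(tr, predict_for))
    stop("train/test overlap; pass allow_overlap = TRUE if intended")
  Ktr <- lapply(kernels, function(K) K[tr, tr])
  fit <- aireml_multi(train, Ktr)
  comp <- sapply(seq_along(kernels), function(k) {
    as.numeric(fit$varcomps[k] *
                 kernels[[k]][predict_for, tr, drop = FALSE] %*% fit$Py)
  })
  comp <- matrix(comp, nrow = length(predict_for),
                 dimnames = list(predict_for, names(kernels)))
  gebv <- rowSums(comp)
  structure(list(pred = gebv + fit$beta[1], gebv = gebv, components = comp,
                 varcomps = fit$varcomps, weights = fit$weights,
                 loglik = fit$loglik, model = "multikernel_gblup"),
            class = "prediction_result")
}

#' Chromosome-partitioned kernels for GWAS-guided prediction
#'
#' One VanRaden GRM per focal chromosome plus one built from all remaining
#' chromosomes (e.g. G_chr4, G_chr11, G_rest).
#'
#' @param geno a \code{geno_matrix}.
#' @param focal_chroms chromosomes given their own kernel; empty gives the
#'   single whole-genome GRM.
#' @return named list of kernels with per-kernel \code{n_markers} and
#'   \code{scale} (the VanRaden normalizer 2*sum(p(1-p))) attributes.
#' @export
build_chromosome_kernels <- function(geno, focal_chroms = character()) {
  map <- geno$map
  focal_chroms <- as.character(focal_chroms)
  if (!all(focal_chroms %in% map$chrom))
    stop("focal chromosome(s) absent from the map: ",
         paste(setdiff(focal_chroms, map$chrom), collapse = ", "))
  grm_part <- function(idx, name) {
    if (length(idx) == 0) stop("kernel ", name, " has 0 markers")
    G <- grm_vanraden(geno$dosages[, idx, drop = FALSE])
    p <- colMeans(geno$dosages[, idx, drop = FALSE], na.rm = TRUE) / 2
    attr(G, "scale") <- 2 * sum(p * (1 - p))
    G
  }
  if (length(focal_chroms) == 0)
    return(list(whole_genome = grm_part(seq_len(nrow(map)), "whole_genome")))
  ker <- lapply(focal_chroms, function(ch)
    grm_part(which(map$chrom == ch), ch))
  names(ker) <- paste0("chr", focal_chroms)
  rest <- which(!map$chrom %in% focal_chroms)
  ker$rest <- grm_part(rest, "rest")
  ker
}

#' Gaussian kernels over a bandwidth grid (RKHS)
#'
#' \eqn{K_{ij} = \exp(-d_{ij}\theta)} with \eqn{d_{ij}} the squared
#' Euclidean distance between dosage rows and \eqn{\theta} the bandwidth
#' controlling the decay of correlation; one kernel per bandwidth, fitted
#' jointly by REML in \code{\link{multikernel_gblup}} (kernel averaging).
#'
#' @param geno a \code{geno_matrix} or dosage matrix.
#' @param thetas bandwidth grid; the default is the six-bandwidth grid used
#'   for multi-kernel RKHS.
#' @param distance \code{"squared"} (default) or \code{"euclidean"}.
#' @return named list of kernels (\code{theta_<value>}).
#' @export
rkhs_kernels <- function(geno,
                         thetas = c(0.0000005, 0.00005, 0.0005, 0.005,
                                    0.01, 0.05),
                         distance = c("squared", "euclidean")) {
  distance <- match.arg(distance)
  stopifnot(all(thetas > 0))
  M <- if (inherits(geno, "geno_matrix")) geno$dosages else geno
  M[is.na(M)] <- 0
  sq <- rowSums(M^2)
  D <- outer(sq, sq, "+") - 2 * tcrossprod(M)
  D[D < 0] <- 0
  if (distance == "euclidean") D <- sqrt(D)
  ker <- lapply(thetas, function(th) {
    K <- exp(-D * th)
    dimnames(K) <- list(rownames(M), rownames(M))
    K
  })
  names(ker) <- paste0("theta_", format(thetas, scientific = FALSE,
                                        trim = TRUE))
  ker
}

#' Bayesian whole-genome regression (BayesA / BayesB / BayesC-pi / BL)
#'
#' Gibbs sampling of marker effects under the named prior: scaled-t
#' (BayesA), point mass + scaled-t with fixed mixing proportion (BayesB),
#' point mass + Gaussian with the mixing proportion sampled (BayesC-pi),
#' or double-exponential (Bayesian LASSO). Dosages are centered
#' internally; hyperpriors follow the usual defaults of the model family
#' (5 prior degrees of freedom, scales matched so the prior mode explains
#' half the phenotypic variance).
#'
#' @param geno_train training dosage matrix (clones x markers).
#' @param y named training phenotypes (aligned with rows of
#'   \code{geno_train}).
#' @param model one of \code{"BayesA"}, \code{"BayesB"}, \code{"BayesCpi"},
#'   \code{"BL"}.
#' @param iters,burnin chain length and burn-in (defaults 6000 / 1000).
#' @param pi_zero prior probability a marker has no effect (BayesB fixed;
#'   BayesC-pi starting value).
#' @param geno_test optional test dosage matrix for GEBV prediction.
#' @param seed optional seed for the sampler.
#' @return \code{prediction_result} with posterior-mean marker
#'   \code{effects}, \code{mu}, \code{pi_zero} (posterior mean), and
#'   \code{pred} for test clones (or training clones if no test set).
#' @export
bayes_regression <- function(geno_train, y, model = c("BayesA", "BayesB",
                                                      "BayesCpi", "BL"),
                             iters = 6000, burnin = 1000, pi_zero = 0.95,
                             geno_test = NULL, seed = NULL) {
  model <- match.arg(model)
  stopifnot(iters > burnin)
  W <- if (inherits(geno_train, "geno_matrix")) geno_train$dosages else
    as.matrix(geno_train)
  stopifnot(nrow(W) == length(y))
  W[is.na(W)] <- 0
  ctr <- colMeans(W)
  Wc <- sweep(W, 2, ctr)
  if (!is.null(seed)) set.seed(seed)
  code <- match(model, c("BayesA", "BayesB", "BayesCpi", "BL")) - 1L
  fit <- bayes_mcmc_cpp(Wc, as.numeric(y), code, as.integer(iters),
                        as.integer(burnin), pi_zero)
  if (any(!is.finite(fit$effects)))
    stop("divergent chain at iteration ", fit$bad_iter)
  effects <- stats::setNames(fit$effects, colnames(W))
  predict_mat <- function(Mt) {
    Mt[is.na(Mt)] <- 0
    as.numeric(sweep(Mt, 2, ctr) %*% effects) + fit$mu
  }
  pred <- if (is.null(geno_test)) {
    stats::setNames(predict_mat(W), rownames(W))
  } else {
    Mt <- if (inherits(geno_test, "geno_matrix")) geno_test$dosages else
      as.matrix(geno_test)
    stats::setNames(predict_mat(Mt), rownames(Mt))
  }
  structure(list(pred = pred, effects = effects, mu = fit$mu,
                 pi_zero = fit$pi_zero, varcomps = c(e = fit$sigma2e),
                 model = model),
            class = "prediction_result")
}

#' Random Forest genomic prediction
#'
#' Ensemble regression on dosage columns (a total-genetic-value predictor:
#' it can absorb non-additive signal). Defaults follow the standard
#' settings for this application: 500 trees and 300 candidate markers per
#' split.
#'
#' @param geno_train,geno_test training/test dosage matrices.
#' @param y training phenotypes.
#' @param ntree,mtry forest size and variables per split; \code{mtry} is
#'   clipped to the marker count with a warning.
#' @param seed optional seed.
#' @return \code{prediction_result} with test predictions.
#' @export
random_forest_gp <- function(geno_train, y, geno_test, ntree = 500,
                             mtry = 300, seed = NULL) {
  Wtr <- if (inherits(geno_train, "geno_matrix")) geno_train$dosages else
    as.matrix(geno_train)
  Wte <- if (inherits(geno_test, "geno_matrix")) geno_test$dosages else
    as.matrix(geno_test)
  if (!is.numeric(Wtr) || !is.numeric(Wte)) stop("dosages must be numeric")
  Wtr[is.na(Wtr)] <- 0; Wte[is.na(Wte)] <- 0
  if (mtry > ncol(Wtr)) {
    warning("mtry > number of markers; clipping to ", ncol(Wtr))
    mtry <- ncol(Wtr)
  }
  if (!is.null(seed)) set.seed(seed)
  rf <- randomForest::randomForest(x = Wtr, y = as.numeric(y),
                                   ntree = ntree, mtry = mtry)
  pred <- stats::predict(rf, Wte)
  names(pred) <- rownames(Wte)
  structure(list(pred = pred, model = "rf", fit_importance = NULL),
            class = "prediction_result")
}

#' Cross-validation harness over the prediction models
#'
#' Accuracy is the Pearson correlation between predictions and the
#' held-out clones' de-regressed BLUPs, per fold and repetition.
#' Schemes: repeated k-fold within the combined set, or cross-panel
#' (train on one panel, predict the other).
#'
#' @param models character subset of \code{c("gblup", "mk_gblup", "rkhs",
#'   "bayesA", "bayesB", "bayesCpi", "bl", "rf")}.
#' @param geno a \code{geno_matrix}.
#' @param dereg named numeric phenotype.
#' @param scheme list: \code{list(type = "kfold", k = 5, reps = 10)} or
#'   \code{list(type = "cross_panel", train = "panel1", test = "panel2")}.
#' @param seed RNG seed for fold assignment and stochastic models.
#' @param focal_chroms chromosomes for the multi-kernel model.
#' @param iters,burnin chain settings for the Bayesian models.
#' @param ntree,mtry Random Forest settings.
#' @param min_test minimum held-out clones per fold.
#' @return data.frame: model, rep, fold, n_test, accuracy.
#' @export
cross_validate <- function(models, geno, dereg,
                           scheme = list(type = "kfold", k = 5, reps = 10),
                           seed = 1, focal_chroms = c("4", "11"),
                           iters = 6000, burnin = 1000,
                           ntree = 500, mtry = 300, min_test = 10) {
  known <- c("gblup", "mk_gblup", "rkhs", "bayesA", "bayesB", "bayesCpi",
             "bl", "rf")
  stopifnot(all(models %in% known))
  dereg <- dereg[!is.na(dereg)]
  clones <- intersect(rownames(geno$dosages), names(dereg))
  y <- dereg[clones]
  M <- geno$dosages[clones, , drop = FALSE]
  gsub_ <- genotype_matrix(M, geno$map, geno$panel[clones])

  needs_G <- any(models %in% c("gblup"))
  G <- if (needs_G || "mk_gblup" %in% models) grm_vanraden(gsub_) else NULL
  CK <- if ("mk_gblup" %in% models)
    build_chromosome_kernels(gsub_, focal_chroms) else NULL
  RK <- if ("rkhs" %in% models) rkhs_kernels(gsub_) else NULL

  set.seed(seed)
  folds <- list()
  if (scheme$type == "kfold") {
    for (r in seq_len(scheme$reps)) {
      fid <- sample(rep(seq_len(scheme$k), length.out = length(clones)))
      for (f in seq_len(scheme$k))
        folds[[length(folds) + 1]] <- list(rep = r, fold = f,
                                           test = clones[fid == f])
    }
  } else if (scheme$type == "cross_panel") {
    if (is.null(geno$panel)) stop("cross_panel scheme needs panel labels")
    test <- clones[geno$panel[clones] == scheme$test]
    folds[[1]] <- list(rep = 1, fold = 1, test = test)
  } else stop("unknown scheme type: ", scheme$type)

  out <- list()
  for (fd in folds) {
    test <- fd$test
    if (length(test) < min_test)
      stop("fold with fewer than ", min_test, " test clones")
    train <- setdiff(clones, test)
    ytr <- y[train]
    for (mod in models) {
      pred <- switch(mod,
        gblup = gblup(ytr, G, predict_for = test)$pred,
        mk_gblup = multikernel_gblup(ytr, CK, predict_for = test)$pred,
        rkhs = multikernel_gblup(ytr, RK, predict_for = test)$pred,
        bayesA = bayes_regression(M[train, , drop = FALSE], ytr, "BayesA",
                                  iters, burnin,
                                  geno_test = M[test, , drop = FALSE])$pred,
        bayesB = bayes_regression(M[train, , drop = FALSE], ytr, "BayesB",
                                  iters, burnin,
                                  geno_test = M[test, , drop = FALSE])$pred,
        bayesCpi = bayes_regression(M[train, , drop = FALSE], ytr,
                                    "BayesCpi", iters, burnin,
                                    geno_test = M[test, , drop = FALSE])$pred,
        bl = bayes_regression(M[train, , drop = FALSE], ytr, "BL",
                              iters, burnin,
                              geno_test = M[test, , drop = FALSE])$pred,
        rf = random_forest_gp(M[train, , drop = FALSE], ytr,
                              M[test, , drop = FALSE], ntree, mtry)$pred)
      out[[length(out) + 1]] <- data.frame(
        model = mod, rep = fd$rep, fold = fd$fold, n_test = length(test),
        accuracy = stats::cor(pred[test], y[test]))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
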