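## First stage of the two-stage analysis: trial-design linear mixed models,
## clone BLUPs with prediction error variances, de-regressed BLUPs and
## entry-mean broad-sense heritability.

#' Fit the trial-design mixed model and extract clone BLUPs
#'
#' For an alpha-lattice trial the model has fixed effects for the
#' population mean and location (plus any covariates) and random effects
#' for clone, incomplete block and range, blocks and ranges nested within
#' location-rep. For an augmented trial the range term is dropped and a
#' fixed check effect is added. A one-way layout (clone only) is available
#' for balanced-design work. Fitting is REML via \code{lme4::lmer}, the
#' tool the two-stage analysis convention is built around; PEVs are the
#' conditional variances of the clone BLUPs.
#'
#' @param data plot-level phenotype table; must contain \code{clone} and,
#'   depending on the design, \code{location}, \code{rep}, \code{block},
#'   \code{range}, \code{is_check}.
#' @param response name of the (numeric) response column.
#' @param design one of \code{"alpha_lattice"}, \code{"augmented"},
#'   \code{"one_way"}.
#' @param covariates optional character vector of fixed-effect covariate
#'   columns (e.g. CMD severity for the covariate-corrected re-fit).
#' @return object of class \code{stage1_fit}: \code{varcomps}, \code{blups},
#'   \code{pevs}, \code{H2}, \code{loglik}, \code{n_plots_per_clone},
#'   \code{fit} (the underlying lmerMod).
#' @export
reml_fit <- function(data, response, design = c("alpha_lattice",
                                                "augmented", "one_way"),
                     covariates = NULL) {
  design <- match.arg(design)
  stopifnot(response %in% names(data), "clone" %in% names(data))
  y <- data[[response]]
  if (!is.numeric(y)) stop("response must be numeric")
  data <- data[!is.na(y), , drop = FALSE]
  if (length(unique(data$clone)) < 2) stop("need >= 2 clone levels")

  multi_loc <- "location" %in% names(data) &&
    length(unique(data$location)) > 1
  fixed <- "1"
  if (multi_loc) fixed <- c(fixed, "location")
  if (design == "augmented" && "is_check" %in% names(data) &&
      length(unique(data$is_check)) > 1)
    fixed <- c(fixed, "is_check")
  for (cv in covariates) {
    if (!cv %in% names(data)) stop("covariate column not found: ", cv)
    if (length(unique(data[[cv]])) > 1) fixed <- c(fixed, cv)
  }
  rand <- "(1 | clone)"
  if (design != "one_way") {
    data$.block <- interaction(if (multi_loc) data$location else "L",
                               data$rep, data$block, drop = TRUE)
    if (nlevels(data$.block) >= 2) rand <- c(rand, "(1 | .block)")
    if (design == "alpha_lattice" && "range" %in% names(data) &&
        !all(is.na(data$range))) {
      data$.range <- interaction(if (multi_loc) data$location else "L",
                                 data$rep, data$range, drop = TRUE)
      if (nlevels(data$.range) >= 2) rand <- c(rand, "(1 | .range)")
    }
  }
  fml <- stats::reformulate(c(fixed, rand), response = response)
  fit <- suppressMessages(lme4::lmer(fml, data = data, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE)))

  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomps <- stats::setNames(vc$vcov, ifelse(vc$grp == "Residual", "residual",
                                              sub("^\\.", "", vc$grp)))
  re <- lme4::ranef(fit, condVar = TRUE)$clone
  blups <- stats::setNames(re[, 1], rownames(re))
  pevs <- stats::setNames(as.numeric(attr(re, "postVar")), rownames(re))
  nplots <- table(data$clone)[names(blups)]

  out <- structure(list(varcomps = varcomps, blups = blups, pevs = pevs,
                        loglik = as.numeric(stats::logLik(fit)),
                        n_plots_per_clone = as.numeric(nplots),
                        design = design, response = response, fit = fit),
                   class = "stage1_fit")
  names(out$n_plots_per_clone) <- names(blups)
  out$H2 <- broad_sense_h2(out)
  out$dereg <- if (out$varcomps[["clone"]] > 0) deregress(out) else NULL
  out
}

#' @export
print.stage1_fit <- function(x, ...) {
  cat("stage-1 fit (", x$design, "): ", length(x$blups), " clones, H2 = ",
      round(x$H2, 3), "\n", sep = "")
  print(round(x$varcomps, 4))
  invisible(x)
}

#' De-regress clone BLUPs
#'
#' dereg = BLUP / (1 - PEV / sigma2_c). The denominator is the BLUP's
#' reliability; clones whose reliability falls at or below
#' \code{reliability_floor} (including any with PEV >= sigma2_c) are
#' flagged and their de-regressed value set to NA rather than returned as
#' an exploding ratio.
#'
#' @param fit a \code{stage1_fit} (or a list with \code{blups},
#'   \code{pevs}, \code{varcomps["clone"]}).
#' @param reliability_floor minimum reliability for a usable value.
#' @return data.frame: clone, blup, pev, reliability, dereg, excluded.
#' @export
deregress <- function(fit, reliability_floor = 0.05) {
  s2c <- fit$varcomps[["clone"]]
  if (is.na(s2c) || s2c <= 0) stop("clone variance component must be > 0")
  rel <- 1 - fit$pevs / s2c
  excluded <- rel <= reliability_floor
  dereg <- ifelse(excluded, NA_real_, fit$blups / rel)
  data.frame(clone = names(fit$blups), blup = unname(fit$blups),
             pev = unname(fit$pevs), reliability = unname(rel),
             dereg = unname(dereg), excluded = unname(excluded),
             row.names = NULL)
}

#' Entry-mean broad-sense heritability
#'
#' \eqn{H^2 = \sigma^2_c / (\sigma^2_c + \sigma^2_{other}/\bar r)} with
#' \eqn{\bar r} the harmonic mean of plots per clone and
#' \eqn{\sigma^2_{other}} the sum of the non-clone random variances
#' (block, range, residual), all apportioned per plot — the standard
#' plant-breeding entry-mean convention.
#'
#' @param fit a \code{stage1_fit}.
#' @return H2 in [0, 1].
#' @export
broad_sense_h2 <- function(fit) {
  s2c <- fit$varcomps[["clone"]]
  other <- sum(fit$varcomps[setdiff(names(fit$varcomps), "clone")])
  np <- fit$n_plots_per_clone
  np <- np[np > 0]
  rbar <- length(np) / sum(1 / np)
  if (s2c + other == 0) return(0)
  unname(s2c / (s2c + other / rbar))
}

#' Pairwise correlations of de-regressed BLUP sets
#'
#' Pearson correlations on the clone intersection of each pair of sets
#' (traits, locations, or trait-location combinations), with the shared-n
#' reported. Pairs with fewer than \code{min_shared} shared clones are
#' returned as NA.
#'
#' @param dereg_sets named list of named numeric vectors.
#' @param min_shared minimum clones in common (default 3).
#' @return data.frame: set1, set2, n, correlation.
#' @export
correlate_traits <- function(dereg_sets, min_shared = 3) {
  stopifnot(is.list(dereg_sets), length(dereg_sets) >= 2)
  nms <- names(dereg_sets)
  pairs <- utils::combn(length(nms), 2)
  res <- apply(pairs, 2, function(ij) {
    a <- dereg_sets[[ij[1]]]; b <- dereg_sets[[ij[2]]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    shared <- intersect(names(a), names(b))
    r <- if (length(shared) >= min_shared)
      stats::cor(a[shared], b[shared]) else NA_real_
    c(n = length(shared), correlation = r)
  })
  data.frame(set1 = nms[pairs[1, ]], set2 = nms[pairs[2, ]],
             n = res["n", ], correlation = res["correlation", ])
}
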