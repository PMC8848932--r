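#' Median-of-ratios size factors
#'
#' Per-sample normalisation factor: the median, over features with
#' non-zero counts in every sample, of the ratio of the sample's count to
#' the feature's geometric mean across samples.
#'
#' @param counts non-negative matrix, features x samples.
#' @return numeric vector of positive factors, one per sample.
#' @export
sizeFactorsMedianRatio <- function(counts) {
  counts <- as.matrix(counts)
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok))
    stop("no feature has non-zero counts in all samples; ",
         "consider a pseudocount")
  lg <- log(counts[ok, , drop = FALSE])
  gm <- rowMeans(lg)
  sf <- apply(exp(lg - gm), 2, median)
  setNames(sf, colnames(counts))
}

# Method-of-moments NB dispersion with a mean-dispersion trend used as a
# shrinkage target: per-feature estimates (few residual df) are pulled
# toward the trend alpha(mu) = a0 + a1/mu with prior weight priorDf.
estimateDispersions <- function(norm, group, priorDf = 8) {
  lev <- levels(group)
  n1 <- sum(group == lev[1]); n2 <- sum(group == lev[2])
  m1 <- rowMeans(norm[, group == lev[1], drop = FALSE])
  m2 <- rowMeans(norm[, group == lev[2], drop = FALSE])
  v1 <- apply(norm[, group == lev[1], drop = FALSE], 1, var)
  v2 <- apply(norm[, group == lev[2], drop = FALSE], 1, var)
  # pooled excess variance over the Poisson expectation
  pooledVar <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  mu <- (n1 * m1 + n2 * m2) / (n1 + n2)
  alphaMom <- (pooledVar - mu) / mu^2
  alphaMom[!is.finite(alphaMom)] <- 0
  alphaMom <- pmax(alphaMom, 0)
  use <- mu > 0
  fit <- tryCatch(
    lm(alphaMom[use] ~ I(1 / mu[use]), weights = mu[use]),
    error = function(e) NULL)
  trend <- if (!is.null(fit)) {
    cf <- pmax(coef(fit), 0)
    cf[is.na(cf)] <- 0
    cf[1] + cf[2] / pmax(mu, 1e-8)
  } else rep(mean(alphaMom[use]), length(mu))
  df <- n1 + n2 - 2
  alpha <- (df * alphaMom + priorDf * trend) / (df + priorDf)
  pmax(alpha, 1e-8)
}

#' Negative-binomial Wald test for a two-group contrast
#'
#' A documented NB Wald approximation of the usual count-based
#' differential expression test: counts are normalised by median-of-ratios
#' size factors, per-feature dispersions are estimated by method of
#' moments and shrunk toward a 1/mean trend, and the Wald statistic is the
#' pseudocount-stabilised log2 fold change of group means over its
#' delta-method standard error under the NB variance function
#' \eqn{\mu + \alpha \mu^2}. It is an approximation calibrated on
#' simulations, not a reimplementation of any specific package's
#' shrinkage estimators.
#'
#' @param counts non-negative matrix, features x samples.
#' @param group two-level factor over samples (first level = reference;
#'   log2FC is second vs first).
#' @param sizeFactors optional precomputed factors; default
#'   median-of-ratios.
#' @param alpha FDR threshold for the \code{significant} flag
#'   (default 0.01).
#' @param pseudocount added to normalised group means in the fold change
#'   (default 0.5).
#' @return data.frame with \code{feature}, \code{base_mean},
#'   \code{log2fc}, \code{dispersion}, \code{wald_stat}, \code{p_value},
#'   \code{q_value} (Benjamini-Hochberg) and \code{significant}. All-zero
#'   features are excluded and reported via the \code{nExcluded}
#'   attribute.
#' @export
nbWaldTest <- function(counts, group, sizeFactors = NULL, alpha = 0.01,
                       pseudocount = 0.5) {
  counts <- as.matrix(counts)
  group <- droplevels(as.factor(group))
  stopifnot(nlevels(group) == 2, ncol(counts) == length(group))
  if (min(table(group)) < 2) stop("need >= 2 replicates per group")
  if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMedianRatio(counts)
  keep <- rowSums(counts) > 0
  x <- counts[keep, , drop = FALSE]
  norm <- sweep(x, 2, sizeFactors, "/")
  lev <- levels(group)
  i1 <- group == lev[1]; i2 <- group == lev[2]
  n1 <- sum(i1); n2 <- sum(i2)
  mu1 <- rowMeans(norm[, i1, drop = FALSE])
  mu2 <- rowMeans(norm[, i2, drop = FALSE])
  disp <- estimateDispersions(norm, group)
  l2fc <- log2(mu2 + pseudocount) - log2(mu1 + pseudocount)
  c1 <- mean(1 / sizeFactors[i1]); c2 <- mean(1 / sizeFactors[i2])
  # Var(log mu_hat) by the delta method, NB variance mu/s + alpha*mu^2
  vlog1 <- (c1 / pmax(mu1, pseudocount) + disp) / n1
  vlog2 <- (c2 / pmax(mu2, pseudocount) + disp) / n2
  se <- sqrt(vlog1 + vlog2) / log(2)
  z <- l2fc / se
  p <- 2 * pnorm(-abs(z))
  q <- bhAdjust(p)
  out <- data.frame(feature = rownames(x), base_mean = (mu1 + mu2) / 2,
                    log2fc = l2fc, dispersion = disp, wald_stat = z,
                    p_value = p, q_value = q, significant = q < alpha,
                    stringsAsFactors = FALSE)
  attr(out, "nExcluded") <- sum(!keep)
  attr(out, "sizeFactors") <- sizeFactors
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with enforced monotonicity (wraps
#' \code{stats::p.adjust}).
#'
#' @param p p-values in [0, 1].
#' @return q-values, same length and order.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

kmeansPlusPlusCenters <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1, ] <- x[sample.int(n, 1, prob = prob), ]
    dn <- rowSums((x - matrix(centers[j + 1, ], n, ncol(x),
                              byrow = TRUE))^2)
    d2 <- pmin(d2, dn)
  }
  centers
}

#' k-means clustering of fold-change profiles
#'
#' Euclidean k-means with k-means++ initialisation, taking the best of
#' \code{nInit} restarts by total within-cluster inertia. Deterministic
#' under the seed. Rows named in \code{exclude} (e.g. let-7 family
#' members) are left out of the clustering.
#'
#' @param x numeric matrix, features x contrasts (e.g. per-contrast log2
#'   fold changes).
#' @param k number of clusters (default 15).
#' @param seed RNG seed (default 0).
#' @param nInit restarts (default 25).
#' @param exclude row names to drop before clustering.
#' @return data.frame with \code{feature}, \code{cluster} (0-based),
#'   \code{dist_to_centroid}; centers and total inertia in attributes
#'   \code{centers}, \code{inertia}.
#' @export
kmeansProfiles <- function(x, k = 15, seed = 0, nInit = 25,
                           exclude = NULL) {
  x <- as.matrix(x)
  if (!is.null(exclude)) x <- x[!rownames(x) %in% exclude, , drop = FALSE]
  if (k > nrow(x)) stop("k exceeds the number of rows")
  best <- NULL
  for (i in seq_len(nInit)) {
    set.seed(deriveSeed(seed, i))
    centers <- kmeansPlusPlusCenters(x, k)
    centers <- centers[!duplicated(centers), , drop = FALSE]
    fit <- suppressWarnings(
      kmeans(x, centers = centers, iter.max = 100, algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  d <- sqrt(rowSums((x - best$centers[best$cluster, , drop = FALSE])^2))
  out <- data.frame(feature = rownames(x), cluster = best$cluster - 1L,
                    dist_to_centroid = d, stringsAsFactors = FALSE)
  attr(out, "centers") <- best$centers
  attr(out, "inertia") <- best$tot.withinss
  out
}

#' PCA quality control of count samples
#'
#' Principal components of log2-transformed, size-factor-normalised
#' counts (features centred), used to check that replicates of a genotype
#' cluster together.
#'
#' @param counts non-negative matrix, features x samples.
#' @param sizeFactors optional normalisation factors; default
#'   median-of-ratios (falling back to depth ratios if no feature is
#'   always non-zero).
#' @param nComponents components to return (default up to 5).
#' @return list with \code{scores} (samples x components) and
#'   \code{varExplained} (fractions summing to 1 over all components).
#' @export
pcaQC <- function(counts, sizeFactors = NULL, nComponents = 5) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need >= 2 samples")
  if (is.null(sizeFactors))
    sizeFactors <- tryCatch(sizeFactorsMedianRatio(counts),
                            error = function(e) {
                              cs <- colSums(counts)
                              cs / exp(mean(log(cs)))
                            })
  lx <- log2(sweep(counts, 2, sizeFactors, "/") + 1)
  if (all(apply(lx, 1, var) == 0))
    warning("constant matrix: all components have zero variance")
  pc <- prcomp(t(lx), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2
  ve <- if (sum(ve) > 0) ve / sum(ve) else ve
  kk <- seq_len(min(nComponents, ncol(pc$x)))
  list(scores = pc$x[, kk, drop = FALSE], varExplained = ve)
}
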