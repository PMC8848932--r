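#' Hypergeometric set enrichment
#'
#' Upper-tail hypergeometric test per annotation set: with background size
#' N, set size K (after intersection with the background), query size n
#' and overlap k, the p-value is P(X >= k). Benjamini-Hochberg adjustment
#' across sets.
#'
#' @param query character vector of features (intersected with the
#'   background; by design the background is the set of detected features,
#'   not the annotation universe).
#' @param sets named list of character vectors.
#' @param background character vector of all eligible features.
#' @return data.frame with per-set k, K, n, N, p_value, q_value.
#' @export
hypergeomEnrich <- function(query, sets, background) {
  background <- unique(background)
  N <- length(background)
  if (!N) stop("empty background")
  query <- intersect(unique(query), background)
  n <- length(query)
  res <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), background)
    K <- length(s)
    k <- length(intersect(query, s))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- bhAdjust(out$p_value)
  out
}

#' Filter miRNA-mRNA edges by anticorrelated deregulation
#'
#' Keeps target edges whose endpoints are significantly deregulated in
#' opposite directions (up-miRNA/down-mRNA, down-miRNA/up-mRNA, or both
#' modes). Edges whose endpoints move in the same significant direction
#' are reported separately as positive-correlation edges; edges with a
#' non-significant endpoint or an unknown node are dropped with a report.
#'
#' @param edges data.frame with columns \code{mirna_id}, \code{mrna_id}
#'   (and optionally \code{source}).
#' @param mirnaDE,mrnaDE DE tables (as from \code{\link{nbWaldTest}}) with
#'   columns \code{feature}, \code{log2fc}, \code{q_value}.
#' @param alpha FDR threshold for calling a node deregulated
#'   (default 0.01).
#' @param mode "up_mirna_down_mrna", "down_mirna_up_mrna" or "both".
#' @return list with \code{negative}, \code{positive} and \code{dropped}
#'   edge tables; each negative/positive row carries both endpoint
#'   statuses and log2 fold changes.
#' @export
negativeCorrelationEdges <- function(edges, mirnaDE, mrnaDE, alpha = 0.01,
                                     mode = c("both", "up_mirna_down_mrna",
                                              "down_mirna_up_mrna")) {
  mode <- match.arg(mode)
  status <- function(de, ids) {
    i <- match(ids, de$feature)
    s <- ifelse(is.na(i), "unknown",
         ifelse(de$q_value[i] < alpha & de$log2fc[i] > 0, "up",
         ifelse(de$q_value[i] < alpha & de$log2fc[i] < 0, "down", "ns")))
    list(status = s, log2fc = de$log2fc[i])
  }
  mi <- status(mirnaDE, edges$mirna_id)
  mr <- status(mrnaDE, edges$mrna_id)
  e <- edges
  e$mirna_status <- mi$status; e$mirna_log2fc <- mi$log2fc
  e$mrna_status <- mr$status; e$mrna_log2fc <- mr$log2fc
  upDown <- e$mirna_status == "up" & e$mrna_status == "down"
  downUp <- e$mirna_status == "down" & e$mrna_status == "up"
  neg <- switch(mode, both = upDown | downUp,
                up_mirna_down_mrna = upDown, down_mirna_up_mrna = downUp)
  pos <- e$mirna_status %in% c("up", "down") &
    e$mirna_status == e$mrna_status
  list(negative = e[neg, , drop = FALSE],
       positive = e[pos, , drop = FALSE],
       dropped = e[!neg & !pos, , drop = FALSE])
}

#' Relative confluency
#'
#' Subtracts each well's confluency at the earliest time point from every
#' later measurement, so the baseline row becomes 0. Idempotent.
#'
#' @param series data.frame with columns \code{time_h}, \code{confluency}
#'   and optionally \code{well}.
#' @return the series with adjusted \code{confluency}.
#' @export
relativeConfluency <- function(series) {
  if (!nrow(series)) stop("empty series")
  if (is.null(series$well)) series$well <- "well1"
  for (w in unique(series$well)) {
    i <- series$well == w
    t0 <- which.min(series$time_h[i])
    series$confluency[i] <- series$confluency[i] -
      series$confluency[i][t0]
  }
  series
}

#' Logistic growth model
#'
#' \deqn{N(t) = K / (1 + e^{-rt} (K - N_0)/N_0)}
#'
#' @param t time (hours).
#' @param K carrying capacity.
#' @param r growth rate per hour.
#' @param N0 initial value; \code{N(0) = N0} identically.
#' @return N(t).
#' @export
logisticCurve <- function(t, K, r, N0) {
  K / (1 + exp(-r * t) * (K - N0) / N0)
}

#' Fit the logistic growth model to a confluency series
#'
#' Nonlinear least squares over (K, r, N0) with data-driven
#' initialisation: K starts at 1.1 x max(N), N0 at the first positive
#' value, r at the early-phase log-linear slope. The p-value of r is a
#' Wald t-test on the estimate with n - 3 degrees of freedom.
#' Near-constant series are returned as the degenerate r = 0 fit rather
#' than an error.
#'
#' @param series data.frame with columns \code{time_h} and
#'   \code{confluency} (>= 4 distinct time points, values > 0).
#' @return list of class \code{growthFit}: \code{K}, \code{r}, \code{N0},
#'   \code{rss}, \code{se_r}, \code{p_r}, \code{converged}, \code{n} and
#'   the fitted model (or NULL). No exception on non-convergence.
#' @export
fitLogistic <- function(series) {
  t <- series$time_h; y <- series$confluency
  if (length(unique(t)) < 4) stop("need >= 4 distinct time points")
  if (any(y <= 0)) stop("confluency values must be > 0")
  n <- length(y)
  out <- list(K = NA_real_, r = NA_real_, N0 = NA_real_, rss = NA_real_,
              se_r = NA_real_, p_r = NA_real_, converged = FALSE, n = n,
              fit = NULL)
  class(out) <- "growthFit"
  if (sd(y) < 1e-10 * max(mean(y), 1)) {    # flat series: degenerate limit
    out$K <- max(y); out$r <- 0; out$N0 <- mean(y)
    out$rss <- sum((y - mean(y))^2); out$se_r <- NA_real_; out$p_r <- 1
    out$converged <- TRUE
    return(out)
  }
  K0 <- 1.1 * max(y)
  N00 <- y[which.min(t)]
  early <- t <= quantile(t, 0.5)
  r0 <- tryCatch({
    sl <- coef(lm(log(y[early]) ~ t[early]))[2]
    max(as.numeric(sl), 1e-3)
  }, error = function(e) 0.05)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ K / (1 + exp(-r * t) * (K - N0) / N0),
      start = list(K = K0, r = r0, N0 = N00),
      lower = c(K = max(y) * 0.5, r = -1, N0 = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(out)
  cf <- coef(fit)
  sm <- summary(fit)
  seR <- sm$coefficients["r", "Std. Error"]
  out$K <- cf[["K"]]; out$r <- cf[["r"]]; out$N0 <- cf[["N0"]]
  out$rss <- sum(residuals(fit)^2)
  out$se_r <- seR
  out$p_r <- 2 * pt(-abs(cf[["r"]] / seR), df = n - 3)
  out$converged <- TRUE
  out$fit <- fit
  out
}

#' @export
print.growthFit <- function(x, ...) {
  cat(sprintf(
    "Logistic growth fit (n = %d): K = %.3f, r = %.4f /h, N0 = %.3f\n",
    x$n, x$K, x$r, x$N0))
  cat(sprintf("  RSS = %.4g, p(r) = %.3g, converged: %s\n",
              x$rss, x$p_r, x$converged))
  invisible(x)
}
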