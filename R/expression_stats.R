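# Biweight midcorrelation of expression with phenotypes, FDR control, and
# likelihood-ratio tests for dynamic expression over a differentiation
# time course.

#' Biweight midcorrelation
#'
#' Robust correlation built from median/MAD-standardized deviations:
#' \code{u_i = (x_i - med(x)) / (9 mad(x))} with the unscaled median
#' absolute deviation, Tukey biweights \code{w_i = (1 - u_i^2)^2} for
#' \code{|u_i| < 1} (0 otherwise), and the normalized cross-product of the
#' weighted deviations of x and y. Invariant to positive affine transforms
#' of either input; \code{bicor(x, x) = 1} for any non-degenerate x.
#'
#' @param x,y numeric vectors; pairs with missing values are removed.
#' @return correlation in \[-1, 1\].
#' @export
bicor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stopf("need at least 4 complete pairs")
  wx <- bicor_weights(x)
  wy <- bicor_weights(y)
  r <- sum(wx * wy) / sqrt(sum(wx^2) * sum(wy^2))
  min(1, max(-1, r))  # clamp rounding noise so |bicor| <= 1 holds exactly
}

bicor_weights <- function(x) {
  med <- stats::median(x)
  madx <- stats::mad(x, constant = 1)
  if (madx == 0) stopf("degenerate scale: mad(x) = 0")
  u <- (x - med) / (9 * madx)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  (x - med) * w
}

#' Correlation screen of expression against phenotypes
#'
#' Computes the biweight midcorrelation of every gene x phenotype pair over
#' pairwise-complete shared samples, with the Student-t p-value
#' \code{t = r sqrt((n-2)/(1-r^2))} on n-2 df, and FDR control across the
#' whole family.
#'
#' @param expr genes x samples matrix (rownames = genes, colnames = sample
#'   ids).
#' @param pheno phenotypes x samples matrix.
#' @param fdr significance threshold on the q-value (default 0.05).
#' @param method \code{"BH"} (default) or \code{"storey"} (BH scaled by the
#'   pi0 estimate \code{min(1, 2 mean(p > 0.5))}; unstable for small
#'   families).
#' @return data.frame with \code{gene, phenotype, bicor, n_used, pvalue,
#'   qvalue, significant}.
#' @export
bicor_screen <- function(expr, pheno, fdr = 0.05,
                         method = c("BH", "storey")) {
  method <- match.arg(method)
  shared <- intersect(colnames(expr), colnames(pheno))
  if (length(shared) == 0) stopf("no shared samples between matrices")
  expr <- expr[, shared, drop = FALSE]
  pheno <- pheno[, shared, drop = FALSE]
  grid <- expand.grid(gene = rownames(expr), phenotype = rownames(pheno),
                      stringsAsFactors = FALSE)
  res <- mapply(function(g, ph) {
    x <- expr[g, ]; y <- pheno[ph, ]
    ok <- stats::complete.cases(x, y)
    r <- bicor(x[ok], y[ok])
    n <- sum(ok)
    r2 <- min(r^2, 1 - 1e-15)
    t_stat <- r * sqrt((n - 2) / (1 - r2))
    c(r = r, n = n,
      p = 2 * stats::pt(abs(t_stat), df = n - 2, lower.tail = FALSE))
  }, grid$gene, grid$phenotype)
  out <- data.frame(gene = grid$gene, phenotype = grid$phenotype,
                    bicor = res["r", ], n_used = as.integer(res["n", ]),
                    pvalue = res["p", ], stringsAsFactors = FALSE)
  q <- stats::p.adjust(out$pvalue, method = "BH")
  if (method == "storey") {
    pi0 <- min(1, 2 * mean(out$pvalue > 0.5))
    q <- pmin(1, q * pi0)
  }
  out$qvalue <- q
  out$significant <- out$qvalue < fdr
  rownames(out) <- NULL
  out
}

gaussian_ll <- function(rss, n) {
  if (rss <= 0) return(Inf)
  -n / 2 * (log(2 * pi * rss / n) + 1)
}

#' Likelihood-ratio test for dynamic expression over time
#'
#' Fits Gaussian models of expression on time and compares the
#' time-dependent alternative to an intercept-only null with the LRT
#' (chi-square, df = extra parameters). The \code{"factor"} alternative
#' fits a free mean per timepoint (df = #timepoints - 1); \code{"linear"}
#' fits a slope on continuous time (df = 1).
#'
#' @param values expression values for one gene.
#' @param time numeric time per value; >= 3 distinct timepoints required.
#' @param time_model \code{"factor"} (default) or \code{"linear"}.
#' @param alpha dynamic-call threshold (default 0.05).
#' @return list of class \code{lrt_result}: \code{ll_alt, ll_null,
#'   statistic, df, pvalue, dynamic}.
#' @export
lrt_dynamic <- function(values, time, time_model = c("factor", "linear"),
                        alpha = 0.05) {
  time_model <- match.arg(time_model)
  ok <- stats::complete.cases(values, time)
  values <- values[ok]; time <- time[ok]
  n <- length(values)
  tp <- unique(time)
  if (length(tp) < 3) stopf("need at least 3 distinct timepoints")
  rss0 <- sum((values - mean(values))^2)
  if (time_model == "factor") {
    mu_t <- stats::ave(values, time)
    rss1 <- sum((values - mu_t)^2)
    df <- length(tp) - 1
  } else {
    fit <- stats::lm.fit(cbind(1, time), values)
    rss1 <- sum(fit$residuals^2)
    df <- 1
  }
  if (n - df - 1 < 1) stopf("no residual degrees of freedom")
  if (rss1 <= 0 || rss0 <= 0) stopf("degenerate fit: zero residual variance")
  ll0 <- gaussian_ll(rss0, n)
  ll1 <- gaussian_ll(rss1, n)
  stat <- max(0, 2 * (ll1 - ll0))
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  structure(list(ll_alt = ll1, ll_null = ll0, statistic = stat, df = df,
                 pvalue = p, dynamic = p < alpha),
            class = "lrt_result")
}

#' LRT screen over a time-course expression matrix
#'
#' @param expr genes x samples matrix.
#' @param time per-sample time.
#' @inheritParams lrt_dynamic
#' @return data.frame with \code{gene, statistic, df, pvalue, dynamic}.
#' @export
lrt_screen <- function(expr, time, time_model = "factor", alpha = 0.05) {
  rows <- lapply(rownames(expr), function(g) {
    r <- lrt_dynamic(expr[g, ], time, time_model = time_model, alpha = alpha)
    data.frame(gene = g, statistic = r$statistic, df = r$df,
               pvalue = r$pvalue, dynamic = r$dynamic,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
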