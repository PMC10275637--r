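# Sum-of-single-effects fine-mapping on summary statistics (z, R).
#
# Model: z | b ~ N(R b, R) with b = sum_l b_l, each b_l having a single
# non-zero coordinate (uniform over variants a priori, effect ~ N(0, s0l^2)).
# Fitting is iterative Bayesian stepwise selection: for each effect,
# residualize the other effects' contributions, compute per-variant
# single-effect Bayes factors, and set the effect's inclusion posterior to
# their softmax. The objective (variational lower bound with unit residual
# variance in the sufficient-statistic parameterization XtX = R, Xty = z)
# is non-decreasing over updates and drives convergence.

single_effect_regression <- function(rvec, s0sq, estimate_prior = FALSE) {
  # rvec: residualized Xty; per-variant bhat = rvec (diag XtX = 1), shat2 = 1
  if (estimate_prior) {
    lpn <- log(length(rvec))
    obj <- function(ls0) -(logsumexp(ser_lbf(rvec, exp(ls0))) - lpn)
    opt <- stats::optimize(obj, c(log(1e-4), log(1e4)))
    # keep the estimated prior only if the effect's model log-BF beats the
    # null (zero-variance) limit
    if (-opt$objective > 0) s0sq <- exp(opt$minimum) else s0sq <- 0
  }
  lbf <- ser_lbf(rvec, s0sq)
  alpha <- softmax_log(lbf)
  post_var <- s0sq / (1 + s0sq)
  mu <- post_var * rvec
  list(alpha = alpha, mu = mu, mu2 = mu^2 + post_var, s2 = post_var,
       lbf = lbf, s0sq = s0sq, lbf_model = logsumexp(lbf) - log(length(rvec)))
}

ser_lbf <- function(bhat, s0sq) {
  if (s0sq == 0) return(rep(0, length(bhat)))
  0.5 * (log(1 / (1 + s0sq)) + bhat^2 * s0sq / (1 + s0sq))
}

ser_kl <- function(fit, p) {
  if (fit$s0sq == 0) return(0)  # null effect: posterior equals prior at 0
  a <- fit$alpha
  nz <- a > 0
  sum(a[nz] * (log(a[nz] * p) +
                 0.5 * (log(fit$s0sq / fit$s2) - 1 +
                          (fit$s2 + fit$mu[nz]^2) / fit$s0sq)))
}

#' Sum-of-single-effects fine-mapping from z-scores and LD
#'
#' @param z per-variant z-scores.
#' @param R an \code{\link{ld_matrix}} (or plain matrix) over the same
#'   variants.
#' @param L maximum number of effects (default 5).
#' @param prior_var prior effect variance on the z scale (default 50, a
#'   weak prior appropriate for genome-wide-significant signals); ignored
#'   per effect when \code{estimate_prior_variance} finds a better value.
#' @param estimate_prior_variance per-effect empirical-Bayes estimation of
#'   the prior variance (default TRUE; an effect whose best prior variance
#'   is 0 carries no signal and its inclusion posterior flattens).
#' @param max_iter,tol convergence controls on the objective
#'   (change < tol, default 1e-3).
#' @return object of class \code{susie_fit}: \code{alpha} (L x p inclusion
#'   posteriors, rows sum to 1), \code{mu}, \code{pip}
#'   (\code{1 - prod_l(1 - alpha_l)}), \code{lbf_effect}, \code{elbo_trace},
#'   \code{converged}, \code{prior_var} (per effect).
#' @export
susie_rss <- function(z, R, L = 5, prior_var = 50,
                      estimate_prior_variance = TRUE,
                      max_iter = 100, tol = 1e-3) {
  if (inherits(R, "ld_matrix")) {
    ids <- R$ids; R <- R$r
  } else ids <- colnames(R) %||% as.character(seq_len(ncol(R)))
  p <- length(z)
  stopifnot(all(is.finite(z)), nrow(R) == p, L >= 1)
  if (inherits(tryCatch(chol(R + diag(1e-8, p)), error = identity), "error"))
    stopf("LD matrix is not positive semi-definite after repair")
  alpha <- matrix(1 / p, L, p)
  mu <- matrix(0, L, p); mu2 <- matrix(0, L, p)
  s0 <- rep(prior_var, L)
  b_bar <- rep(0, p)           # sum_l alpha_l * mu_l
  Rb <- rep(0, p)              # R %*% b_bar
  zz <- sum(z^2)
  fits <- vector("list", L)
  elbo <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    for (l in seq_len(L)) {
      bl <- alpha[l, ] * mu[l, ]
      r_l <- z - (Rb - R %*% bl)            # residualized Xty
      fit <- single_effect_regression(as.numeric(r_l), s0[l],
                                      estimate_prior = estimate_prior_variance)
      alpha[l, ] <- fit$alpha; mu[l, ] <- fit$mu
      mu2[l, ] <- fit$alpha * fit$mu2
      s0[l] <- fit$s0sq
      fits[[l]] <- fit
      bl_new <- fit$alpha * fit$mu
      Rb <- Rb + as.numeric(R %*% (bl_new - bl))
    }
    b_bar <- colSums(alpha * mu)
    # E||z - R b||-style objective in the sufficient-stat parameterization:
    # -0.5 [ z'z - 2 b'z + sum_{l!=k} bl' R bk + sum_l E(bl' R bl) ] - KL
    Bl <- alpha * mu
    RB <- Bl %*% R
    b_bar <- colSums(Bl)
    full <- as.numeric(t(b_bar) %*% R %*% b_bar)  # sum_{l,k} bl' R bk
    diag_l <- sum(RB * Bl)                   # sum_l bl' R bl
    e_quad <- full - diag_l + sum(rowSums(mu2))   # E[b' R b]
    kl <- sum(vapply(fits, ser_kl, numeric(1), p = p))
    elbo_it <- -0.5 * (zz - 2 * sum(b_bar * z) + e_quad) - kl
    elbo <- c(elbo, elbo_it)
    if (it > 1 && abs(elbo[it] - elbo[it - 1]) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warnf("susie_rss did not converge in %d iterations", max_iter)
  pip <- 1 - apply(1 - alpha, 2, prod)
  colnames(alpha) <- ids
  structure(list(L = L, alpha = alpha, mu = mu, pip = stats::setNames(pip, ids),
                 lbf_effect = vapply(fits, `[[`, numeric(1), "lbf_model"),
                 prior_var = s0, elbo_trace = elbo, converged = converged,
                 variant_ids = ids),
            class = "susie_fit")
}

#' @export
print.susie_fit <- function(x, ...) {
  cat(sprintf("<susie_fit> L = %d, %d variants, converged: %s (%d iterations)\n",
              x$L, length(x$pip), x$converged, length(x$elbo_trace)))
  invisible(x)
}

#' Coverage- and purity-filtered credible sets from a susie fit
#'
#' One candidate set per effect: the minimal variant set whose inclusion
#' mass reaches \code{coverage}. Sets whose minimum absolute pairwise LD
#' falls below \code{min_purity} are discarded (a diffuse, null effect has
#' near-uniform alpha and fails purity); duplicate member sets are merged.
#' Sets whose lead variant carries a marginal posterior inclusion
#' probability above \code{high_conf_pip} are flagged high-confidence;
#' raw alpha rows remain available on the fit for any other rule.
#'
#' @param fit a \code{susie_fit}.
#' @param R the \code{ld_matrix} (or matrix) used in fitting.
#' @param coverage per-set coverage (default 0.95).
#' @param min_purity minimum absolute pairwise correlation (default 0.5).
#' @param high_conf_pip PIP threshold for the high-confidence flag
#'   (default 0.70).
#' @return list of credible sets; each has \code{member_ids},
#'   \code{coverage_attained}, \code{purity}, \code{lead_id},
#'   \code{high_confidence}, \code{effect}.
#' @export
susie_credible_sets <- function(fit, R, coverage = 0.95, min_purity = 0.5,
                                high_conf_pip = 0.70) {
  if (inherits(R, "ld_matrix")) R <- R$r
  out <- list()
  seen <- character(0)
  for (l in seq_len(fit$L)) {
    a <- fit$alpha[l, ]
    ord <- order(-a, fit$variant_ids)
    k <- which(cumsum(a[ord]) >= coverage - 1e-12)[1]
    if (is.na(k)) k <- length(a)
    members <- ord[seq_len(k)]
    purity <- if (length(members) == 1) 1 else {
      sub <- abs(R[members, members, drop = FALSE])
      min(sub[upper.tri(sub)])
    }
    if (purity < min_purity) next
    key <- paste(sort(fit$variant_ids[members]), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    lead <- fit$variant_ids[members[1]]
    out[[length(out) + 1L]] <-
      list(effect = l, member_ids = fit$variant_ids[members],
           coverage_attained = unname(cumsum(a[ord])[k]), purity = purity,
           lead_id = lead,
           high_confidence = unname(fit$pip[lead] > high_conf_pip))
  }
  out
}

#' Prior-variance sensitivity scan
#'
#' Refits the model at each prior variance in \code{grid} and reports the
#' stability of credible-set discovery.
#'
#' @param z,R as in \code{\link{susie_rss}}.
#' @param prior_var_grid numeric grid of prior variances.
#' @param ... further arguments to \code{susie_rss} /
#'   \code{susie_credible_sets}.
#' @param coverage,min_purity set filters.
#' @return data.frame with one row per grid point: \code{prior_var},
#'   \code{n_credible_sets}, \code{lead_ids} (comma-joined).
#' @export
sensitivity_scan <- function(z, R, prior_var_grid, coverage = 0.95,
                             min_purity = 0.5, ...) {
  stopifnot(length(prior_var_grid) >= 1)
  rows <- lapply(prior_var_grid, function(v) {
    fit <- susie_rss(z, R, prior_var = v, estimate_prior_variance = FALSE, ...)
    cs <- susie_credible_sets(fit, R, coverage = coverage,
                              min_purity = min_purity)
    data.frame(prior_var = v, n_credible_sets = length(cs),
               lead_ids = paste(vapply(cs, `[[`, character(1), "lead_id"),
                                collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
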