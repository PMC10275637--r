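# Annotation-enrichment estimation over colocalization Bayes factors and
# tissue-of-action (TOA) scoring of signals.
#
# Enrichment model: each locus carries exactly one causal variant whose
# location prior is pi_i proportional to exp(sum_k gamma_k a_ik), where
# a_ik indicates variant i carrying annotation k. The per-locus marginal
# likelihood is sum_i pi_i(gamma) BF_i with BF_i the per-variant
# colocalization Bayes factor; gamma is fit by maximizing the summed log
# marginal likelihood. This one-causal-per-locus model is a simplification
# of segment-level hierarchical enrichment models, adequate for
# already-colocalized loci.

annot_matrix <- function(labels, vocabulary) {
  m <- matrix(0, length(labels), length(vocabulary),
              dimnames = list(names(labels), vocabulary))
  for (i in seq_along(labels)) {
    hit <- intersect(labels[[i]], vocabulary)
    m[i, hit] <- 1
  }
  m
}

#' Fit annotation enrichment over per-variant colocalization Bayes factors
#'
#' @param loci list of loci, each a list with \code{lnbf} (named per-variant
#'   natural-log Bayes factors) and \code{annots} (an
#'   \code{\link{annotation_map}} or a named list of label vectors covering
#'   the same variants).
#' @param vocabulary annotation vocabulary; defaults to the union of the
#'   maps' vocabularies.
#' @param bound box bound on |gamma| during optimization (default 10).
#' @return object of class \code{enrichment_model}: \code{gamma} (named
#'   log-enrichments, NA for annotations absent from every variant),
#'   \code{se_gamma} (from observed-information curvature),
#'   \code{fitted_loglik}, and \code{gamma_empirical} (closed-form
#'   posterior-weighted diagnostic estimator).
#' @export
fit_enrichment <- function(loci, vocabulary = NULL, bound = 10) {
  stopifnot(length(loci) >= 1)
  get_map <- function(l) if (inherits(l$annots, "annotation_map"))
    l$annots$labels else l$annots
  vocabulary <- vocabulary %||%
    sort(unique(unlist(lapply(loci, function(l) {
      if (inherits(l$annots, "annotation_map")) l$annots$vocabulary
      else unique(unlist(l$annots))
    }))))
  mats <- lapply(loci, function(l) {
    stopifnot(length(l$lnbf) >= 1)
    annot_matrix(get_map(l)[names(l$lnbf)], vocabulary)
  })
  lnbfs <- lapply(loci, `[[`, "lnbf")

  present <- Reduce(`+`, lapply(mats, colSums)) > 0
  if (!any(present)) stopf("no annotation present at any variant")
  k_fit <- which(present)

  negll <- function(gamma_fit) {
    g <- numeric(length(vocabulary)); g[k_fit] <- gamma_fit
    -sum(vapply(seq_along(loci), function(j) {
      eta <- as.numeric(mats[[j]] %*% g)
      lpi <- eta - logsumexp(eta)
      logsumexp(lpi + lnbfs[[j]])
    }, numeric(1)))
  }

  # empirical fallback: posterior-weighted annotation frequency over
  # background frequency, pooled across loci
  w_list <- lapply(lnbfs, softmax_log)
  num <- Reduce(`+`, lapply(seq_along(loci),
                            function(j) colSums(w_list[[j]] * mats[[j]])))
  n_var <- sum(vapply(mats, nrow, numeric(1)))
  bg <- Reduce(`+`, lapply(mats, colSums)) / n_var
  gamma_emp <- log((num / length(loci)) / bg)
  gamma_emp[!present] <- NA_real_

  start0 <- rep(0, length(k_fit))
  start1 <- pmin(pmax(gamma_emp[k_fit], -bound / 2), bound / 2)
  start1[!is.finite(start1)] <- 0
  fits <- lapply(list(start0, start1), function(s)
    tryCatch(stats::optim(s, negll, method = "L-BFGS-B",
                          lower = -bound, upper = bound,
                          control = list(maxit = 500)),
             error = function(e) NULL))
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) stopf("enrichment optimizer failed to run")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  if (best$convergence != 0)
    stopf("enrichment optimizer did not converge (code %d: %s)",
          best$convergence, best$message %||% "")

  hess <- stats::optimHess(best$par, negll)
  se_fit <- rep(NA_real_, length(k_fit))
  cov <- tryCatch(solve(hess), error = function(e) NULL)
  if (!is.null(cov)) {
    dg <- diag(cov)
    se_fit[dg > 0] <- sqrt(dg[dg > 0])
  }
  gamma <- stats::setNames(rep(NA_real_, length(vocabulary)), vocabulary)
  se_gamma <- gamma
  gamma[k_fit] <- best$par
  se_gamma[k_fit] <- se_fit
  structure(list(gamma = gamma, se_gamma = se_gamma,
                 fitted_loglik = -best$value,
                 gamma_empirical = stats::setNames(gamma_emp, vocabulary),
                 vocabulary = vocabulary),
            class = "enrichment_model")
}

label_tissue <- function(labels) sub("\\|.*$", "", labels)

#' Tissue-of-action scores for one signal
#'
#' Each credible-set variant's posterior mass p_i is split across tissues
#' proportionally to \code{w_it = sum_k exp(gamma_k) a_ik} over that
#' tissue's annotations. Genome-level annotations (tissue \code{"genome"},
#' e.g. coding) take precedence when \code{genome_precedence} is set: such
#' variants contribute their whole mass to the unclassified share before
#' tissue allocation. Variants with no tissue annotation also contribute to
#' unclassified. Residual credible-set mass (1 - sum p_i) is unclassified,
#' so the scores always sum to 1.
#'
#' @param posteriors named per-variant posterior masses (sum <= 1).
#' @param annots an \code{\link{annotation_map}} covering the variants.
#' @param model an \code{enrichment_model} (annotations with NA gamma get
#'   weight exp(0)).
#' @param tissues tissue vocabulary; defaults to the tissues seen in the
#'   model vocabulary, minus \code{"genome"}.
#' @param genome_precedence allocate genome-level-annotated variants to the
#'   unclassified share before tissue allocation (default TRUE).
#' @return object of class \code{toa_result}: \code{scores} (per tissue
#'   plus \code{"unclassified"}, summing to 1).
#' @export
toa_scores <- function(posteriors, annots, model, tissues = NULL,
                       genome_precedence = TRUE) {
  if (length(posteriors) == 0) stopf("empty credible set")
  if (sum(posteriors) > 1 + 1e-8) stopf("posterior mass exceeds 1")
  labels <- if (inherits(annots, "annotation_map")) annots$labels else annots
  tissues <- tissues %||%
    setdiff(unique(label_tissue(model$vocabulary)), "genome")
  gam <- model$gamma
  gam[is.na(gam)] <- 0
  scores <- stats::setNames(numeric(length(tissues)), tissues)
  unclassified <- 1 - sum(posteriors)
  for (i in seq_along(posteriors)) {
    vid <- names(posteriors)[i]
    lab <- labels[[vid]] %||% character(0)
    if (genome_precedence && any(label_tissue(lab) == "genome")) {
      unclassified <- unclassified + posteriors[i]
      next
    }
    lab <- lab[label_tissue(lab) %in% tissues]
    if (length(lab) == 0) {
      unclassified <- unclassified + posteriors[i]
      next
    }
    w <- vapply(tissues, function(tt) {
      kk <- lab[label_tissue(lab) == tt]
      sum(exp(gam[kk]))
    }, numeric(1))
    scores <- scores + posteriors[i] * w / sum(w)
  }
  structure(list(scores = c(scores, unclassified = unname(unclassified))),
            class = "toa_result")
}

#' Classify a signal's tissue of action from its TOA scores
#'
#' If the top tissue score is below \code{primary_thresh} the signal is
#' unclassified; if the top two tissues differ by less than
#' \code{share_margin} the assignment is shared between them; otherwise the
#' top tissue is assigned.
#'
#' @param scores named per-tissue scores (the \code{"unclassified"} entry,
#'   if present, is ignored for classification).
#' @param primary_thresh minimum score for a tissue assignment
#'   (default 0.20).
#' @param share_margin top-two gap below which the assignment is shared
#'   (default 0.10).
#' @return list with \code{classification} (\code{"unclassified"},
#'   \code{"shared"}, or the tissue name) and \code{tissues} (length 2 for
#'   shared assignments).
#' @export
classify_toa <- function(scores, primary_thresh = 0.20, share_margin = 0.10) {
  if (inherits(scores, "toa_result")) scores <- scores$scores
  scores <- scores[setdiff(names(scores), "unclassified")]
  ord <- order(-scores, names(scores))
  top <- scores[ord[1]]
  if (top < primary_thresh)
    return(list(classification = "unclassified", tissues = character(0)))
  if (length(scores) >= 2 && top - scores[ord[2]] < share_margin)
    return(list(classification = "shared",
                tissues = names(scores)[ord[1:2]]))
  list(classification = names(scores)[ord[1]],
       tissues = names(scores)[ord[1]])
}
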