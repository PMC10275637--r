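# Simulators for LD, paired GWAS summary statistics under explicit
# colocalization hypotheses, annotation maps with planted enrichment, and
# expression / time-course matrices. Every simulator is a pure function of
# (parameters, seed).
#
# Summary statistics follow the regression-with-summary-statistics (RSS)
# model: at a locus with LD matrix R and causal non-centrality vector
# lambda (z-scale), the observed z-scores are drawn MVN(R lambda, R).
# This is the statistical structure the ABF machinery assumes, so no
# individual-level genotypes are needed.

#' Scenario truth for one simulated locus
#'
#' @param hypothesis one of \code{"H0".."H4"}: no association, trait a only,
#'   trait b only, distinct causal variants, shared causal variant.
#' @param causal_a,causal_b causal variant id(s) per trait (empty when the
#'   trait is null under the hypothesis).
#' @param sign_concordant for H4: do the two traits share the effect sign?
#' @param lambda z-scale non-centrality at each causal variant.
#' @return object of class \code{scenario_truth}.
#' @export
scenario_truth <- function(hypothesis, causal_a = character(0),
                           causal_b = character(0),
                           sign_concordant = TRUE, lambda = 7) {
  stopifnot(hypothesis %in% paste0("H", 0:4))
  if (hypothesis == "H4" && !identical(causal_a, causal_b))
    stopf("H4 requires identical causal ids across traits")
  if (hypothesis == "H3" && length(intersect(causal_a, causal_b)) > 0)
    stopf("H3 requires distinct causal ids")
  structure(list(hypothesis = hypothesis, causal_a = causal_a,
                 causal_b = causal_b, sign_concordant = sign_concordant,
                 lambda = lambda),
            class = "scenario_truth")
}

#' Simulate an LD matrix and variant metadata
#'
#' Builds either an AR(1)-style correlation matrix (entry \code{decay^|i-j|})
#' or, when \code{n_hap} is given, the empirical correlation of simulated
#' binary haplotypes. The matrix is ridge-repaired (add eps to the diagonal,
#' renormalize to unit diagonal) so Cholesky-based MVN draws always work.
#'
#' @param p number of variants (>= 2).
#' @param decay AR(1) decay in \[0,1\]; 0 gives identity LD, 1 a degenerate
#'   all-ones matrix (accepted, but flagged with a warning).
#' @param n_hap optional haplotype count for empirical LD.
#' @param maf_range minor-allele-frequency interval for simulated variants.
#' @param seed RNG seed.
#' @param chrom,window_start,window_bp genomic frame for the variant
#'   positions (evenly spaced across the window).
#' @param prefix variant-id prefix.
#' @param eps ridge size for PSD repair.
#' @return list with \code{ld} (an \code{\link{ld_matrix}}) and \code{meta}
#'   (data.frame \code{variant_id, chrom, pos, maf, ea, nea}).
#' @export
simulate_ld <- function(p, decay = 0.9, n_hap = NULL,
                        maf_range = c(0.05, 0.5), seed = 1,
                        chrom = "1", window_start = 1e6, window_bp = 1e6,
                        prefix = "v", eps = 1e-6) {
  stopifnot(p >= 2, decay >= 0, decay <= 1)
  set.seed(seed)
  ids <- sprintf("%s%04d", prefix, seq_len(p))
  if (is.null(n_hap)) {
    r <- decay^abs(outer(seq_len(p), seq_len(p), "-"))
    if (decay == 1) warnf("decay = 1 gives a degenerate all-ones LD matrix")
  } else {
    # latent AR(1) Gaussian haplotypes thresholded at the MAF quantile
    mafs0 <- stats::runif(p, maf_range[1], maf_range[2])
    lat <- matrix(stats::rnorm(n_hap * p), n_hap, p)
    if (decay > 0)
      for (j in 2:p) lat[, j] <- decay * lat[, j - 1] +
        sqrt(1 - decay^2) * lat[, j]
    hap <- sweep(lat, 2, stats::qnorm(mafs0), "<") * 1
    sds <- apply(hap, 2, stats::sd)
    keep_var <- sds > 0
    hap[, !keep_var] <- matrix(stats::rbinom(sum(!keep_var) * n_hap, 1, 0.5),
                               n_hap)
    r <- stats::cor(hap)
  }
  # ridge repair + renormalize to unit diagonal
  r <- r + diag(eps, p)
  d <- sqrt(diag(r))
  r <- r / tcrossprod(d)
  ch <- tryCatch(chol(r), error = function(e) NULL)
  if (is.null(ch)) {
    r <- r + diag(1e-4, p)
    d <- sqrt(diag(r)); r <- r / tcrossprod(d)
    ch <- tryCatch(chol(r), error = function(e) NULL)
    if (is.null(ch)) stopf("LD matrix not positive definite after repair")
  }
  # non-ambiguous allele pairs so harmonization keeps every variant
  pairs <- rbind(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  pick <- sample.int(4, p, replace = TRUE)
  meta <- data.frame(variant_id = ids, chrom = chrom,
                     pos = as.integer(round(seq(window_start,
                                                window_start + window_bp,
                                                length.out = p))),
                     maf = stats::runif(p, maf_range[1], maf_range[2]),
                     ea = pairs[pick, 1], nea = pairs[pick, 2],
                     stringsAsFactors = FALSE)
  list(ld = ld_matrix(r, ids), meta = meta, chol = ch)
}

mvn_from_chol <- function(mu, ch) {
  as.numeric(mu + crossprod(ch, stats::rnorm(nrow(ch))))
}

stats_from_z <- function(z, meta, n, trait_name, trait_type = "quantitative") {
  se <- 1 / sqrt(2 * meta$maf * (1 - meta$maf) * n)
  summary_stats(data.frame(variant_id = meta$variant_id, chrom = meta$chrom,
                           pos = meta$pos, ea = meta$ea, nea = meta$nea,
                           eaf = meta$maf, beta = z * se, se = se,
                           n = n, stringsAsFactors = FALSE),
                trait_name = trait_name, trait_type = trait_type)
}

#' Simulate a harmonized pair of GWAS for one locus
#'
#' Draws per-trait z-scores from MVN(R lambda_vec, R) under the scenario's
#' causal configuration, then reconstructs beta/se from z, allele frequency
#' and sample size. For a sign-discordant H4 scenario the sign of lambda is
#' flipped for trait b.
#'
#' @param sim output of \code{\link{simulate_ld}}.
#' @param truth a \code{\link{scenario_truth}}.
#' @param n_a,n_b GWAS sample sizes.
#' @param seed RNG seed.
#' @param trait_types length-2 character; \code{"case_control"} traits are
#'   simulated on the log-odds scale so the same z machinery applies.
#' @return list \code{(a, b, truth)} with two \code{summary_stats} objects.
#' @export
simulate_gwas_pair <- function(sim, truth, n_a = 5e5, n_b = 5e5, seed = 1,
                               trait_types = c("quantitative",
                                               "quantitative")) {
  ld <- sim$ld; meta <- sim$meta
  stopifnot(all(c(truth$causal_a, truth$causal_b) %in% ld$ids))
  stopifnot(all(is.finite(truth$lambda)))
  set.seed(seed)
  p <- length(ld$ids)
  lam_a <- lam_b <- numeric(p)
  lam_a[match(truth$causal_a, ld$ids)] <- truth$lambda
  sgn_b <- if (truth$hypothesis == "H4" && !truth$sign_concordant) -1 else 1
  lam_b[match(truth$causal_b, ld$ids)] <- sgn_b * truth$lambda
  ch <- sim$chol %||% chol(ld$r)
  z_a <- mvn_from_chol(ld$r %*% lam_a, ch)
  z_b <- mvn_from_chol(ld$r %*% lam_b, ch)
  list(a = stats_from_z(z_a, meta, n_a, "trait_a", trait_types[1]),
       b = stats_from_z(z_b, meta, n_b, "trait_b", trait_types[2]),
       truth = truth)
}

pick_scenario_causals <- function(ld, hypothesis, max_r2 = 0.1) {
  p <- length(ld$ids)
  i <- sample.int(p, 1)
  switch(hypothesis,
    H0 = list(a = character(0), b = character(0)),
    H1 = list(a = ld$ids[i], b = character(0)),
    H2 = list(a = character(0), b = ld$ids[i]),
    H3 = {
      # distinct causals in low LD so the scenarios are distinguishable;
      # on a locus too small to offer r2 < max_r2, take the least-linked pair
      cand <- setdiff(which(ld$r[i, ]^2 < max_r2), i)
      j <- if (length(cand) == 0) {
        others <- setdiff(seq_len(p), i)
        others[which.min(ld$r[i, others]^2)]
      } else cand[sample.int(length(cand), 1)]
      list(a = ld$ids[i], b = ld$ids[j])
    },
    H4 = list(a = ld$ids[i], b = ld$ids[i]))
}

#' Simulate a set of loci with mixed colocalization scenarios
#'
#' @param n_loci number of loci.
#' @param mix named proportions over
#'   \code{c("H0","H1","H2","H3","H4","H4_discordant")}; must sum to 1.
#'   Counts are assigned deterministically by rounding, remainders by draw.
#' @param seed master seed; per-locus seeds are derived from it.
#' @param p,decay,lambda,n_a,n_b locus-level simulation parameters.
#' @param h3_max_r2 maximum r2 between the two causal variants of an H3
#'   locus.
#' @return list of loci; each has \code{ld, meta, a, b, truth} and a locus id.
#' @export
simulate_locus_set <- function(n_loci, mix = c(H4_discordant = 1),
                               seed = 1, p = 60, decay = 0.9, lambda = 7,
                               n_a = 5e5, n_b = 5e5, h3_max_r2 = 0.1) {
  if (n_loci == 0) return(list())
  stopifnot(abs(sum(mix) - 1) < 1e-8)
  valid <- c("H0", "H1", "H2", "H3", "H4", "H4_discordant")
  stopifnot(all(names(mix) %in% valid))
  set.seed(seed)
  counts <- floor(mix * n_loci)
  rem <- n_loci - sum(counts)
  if (rem > 0) {
    extra <- sample(names(mix), rem, replace = TRUE, prob = mix)
    for (e in extra) counts[e] <- counts[e] + 1
  }
  scenarios <- sample(rep(names(counts), counts))
  seeds <- derive_seeds(seed, 2L * n_loci)
  out <- vector("list", n_loci)
  for (k in seq_len(n_loci)) {
    sim <- simulate_ld(p = p, decay = decay, seed = seeds[k],
                       chrom = as.character((k - 1L) %% 22L + 1L),
                       window_start = 1e6 + 2e6 * ((k - 1L) %/% 22L),
                       prefix = sprintf("L%03dv", k))
    scen <- scenarios[k]
    hyp <- if (scen == "H4_discordant") "H4" else scen
    set.seed(seeds[n_loci + k])
    caus <- pick_scenario_causals(sim$ld, hyp, h3_max_r2)
    truth <- scenario_truth(hyp, caus$a, caus$b,
                            sign_concordant = scen != "H4_discordant",
                            lambda = lambda)
    pair <- simulate_gwas_pair(sim, truth, n_a = n_a, n_b = n_b,
                               seed = seeds[n_loci + k])
    out[[k]] <- list(locus_id = sprintf("locus%03d", k), ld = sim$ld,
                     meta = sim$meta, a = pair$a, b = pair$b,
                     truth = truth, scenario = scen)
  }
  out
}

#' Simulate an annotation map with planted enrichment at causal variants
#'
#' Each variant receives label k with probability
#' \code{plogis(qlogis(base_rate) + gamma_k * causal)}, independently per
#' label, so the log-odds enrichment of labels at causal variants is
#' exactly \code{gamma_k}.
#'
#' @param meta variant metadata (needs \code{variant_id}).
#' @param gamma named numeric: per-label log-enrichment
#'   (names \code{"tissue|state"}).
#' @param causal_ids variant ids treated as causal.
#' @param base_rate background label probability in (0,1).
#' @param seed RNG seed.
#' @return an \code{\link{annotation_map}} with vocabulary
#'   \code{names(gamma)}.
#' @export
simulate_annotations <- function(meta, gamma, causal_ids = character(0),
                                 base_rate = 0.1, seed = 1) {
  stopifnot(base_rate > 0, base_rate < 1, !is.null(names(gamma)))
  set.seed(seed)
  ids <- meta$variant_id
  causal <- ids %in% causal_ids
  labels <- stats::setNames(rep(list(character(0)), length(ids)), ids)
  for (k in names(gamma)) {
    pr <- stats::plogis(stats::qlogis(base_rate) + gamma[[k]] * causal)
    on <- stats::runif(length(ids)) < pr
    for (i in which(on)) labels[[i]] <- c(labels[[i]], k)
  }
  annotation_map(labels, vocabulary = names(gamma))
}

#' Simulate an expression study with target gene-phenotype correlations
#'
#' Gaussian construction: genes and phenotypes are drawn jointly MVN with
#' identity within-block correlation and the requested cross-correlation
#' block, so empirical correlations converge to the targets as n grows.
#' Optional independent noise attenuates the realized correlations by
#' \code{1/(1 + noise^2)} and is off by default.
#'
#' @param n_samples number of samples (>= 4).
#' @param true_bicor genes x phenotypes matrix of target correlations,
#'   entries strictly inside (-1, 1).
#' @param noise sd of additional independent expression noise.
#' @param seed RNG seed.
#' @return list with \code{expr} (genes x samples) and \code{pheno}
#'   (phenotypes x samples) matrices, row names \code{gene_i} /
#'   \code{pheno_j}, column names \code{sample_k}.
#' @export
simulate_expression_study <- function(n_samples, true_bicor, noise = 0,
                                      seed = 1) {
  true_bicor <- as.matrix(true_bicor)
  if (n_samples < 4) stopf("n_samples below minimum usable sample size (4)")
  if (any(abs(true_bicor) >= 1)) stopf("target correlations must be in (-1,1)")
  g <- nrow(true_bicor); q <- ncol(true_bicor)
  sigma <- rbind(cbind(diag(g), true_bicor),
                 cbind(t(true_bicor), diag(q)))
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) stopf("target correlation matrix is not realizable (non-PSD)")
  set.seed(seed)
  xx <- matrix(stats::rnorm(n_samples * (g + q)), n_samples) %*% ch
  expr <- t(xx[, seq_len(g), drop = FALSE])
  if (noise > 0) expr <- expr + matrix(stats::rnorm(length(expr), 0, noise),
                                       nrow(expr))
  pheno <- t(xx[, g + seq_len(q), drop = FALSE])
  dimnames(expr) <- list(paste0("gene_", seq_len(g)),
                         paste0("sample_", seq_len(n_samples)))
  dimnames(pheno) <- list(paste0("pheno_", seq_len(q)),
                          paste0("sample_", seq_len(n_samples)))
  list(expr = expr, pheno = pheno)
}

#' Simulate an adipogenesis-style expression time course
#'
#' Dynamic genes follow \code{mean + effect * time}; null genes are flat;
#' Gaussian noise with sd \code{noise} is added everywhere. Defaults mirror
#' a 16-day differentiation course sampled every two days with a handful of
#' replicate wells per timepoint.
#'
#' @param n_genes number of genes.
#' @param dynamic_fraction fraction of genes given a time trend.
#' @param timepoints numeric vector of >= 3 distinct times.
#' @param effect slope per unit time for dynamic genes.
#' @param noise residual sd.
#' @param reps replicates per timepoint.
#' @param seed RNG seed.
#' @return list with \code{expr} (genes x samples), \code{time} (per
#'   sample), and \code{truth} (logical per gene: dynamic).
#' @export
simulate_timecourse <- function(n_genes, dynamic_fraction = 0.2,
                                timepoints = seq(0, 16, by = 2),
                                effect = 0.5, noise = 1, reps = 5,
                                seed = 1) {
  stopifnot(length(unique(timepoints)) >= 3)
  set.seed(seed)
  time <- rep(timepoints, each = reps)
  n_dyn <- round(n_genes * dynamic_fraction)
  dynamic <- rep(c(TRUE, FALSE), c(n_dyn, n_genes - n_dyn))
  slope <- ifelse(dynamic, effect, 0)
  expr <- outer(slope, time) +
    matrix(stats::rnorm(n_genes * length(time), sd = noise), n_genes)
  rownames(expr) <- paste0("gene_", seq_len(n_genes))
  colnames(expr) <- sprintf("t%g_r%d", time,
                            stats::ave(seq_along(time), time, FUN = seq_along))
  list(expr = expr, time = time,
       truth = stats::setNames(dynamic, rownames(expr)))
}
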