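# Analysis-window construction around genome-wide-significant variants,
# per-variant discordance classification over credible sets, greedy LD
# clumping into signals, and the PheWAS-style harmonized lookup.

#' Build merged analysis windows around significant variants
#'
#' Every variant with p below \code{sig_p} in either trait seeds a window of
#' \code{flank} bp on each side; windows on the same chromosome are merged
#' when they overlap or their gap is below \code{merge_gap}. Rare variants
#' (eaf below \code{min_eaf} or above 1 - \code{min_eaf} in either study)
#' are excluded from window contents.
#'
#' @param pair a \code{\link{harmonize}}d pair.
#' @param sig_p genome-wide significance threshold (default 5e-8).
#' @param flank window half-width in bp (default 500 kb).
#' @param merge_gap merge windows closer than this (default 250 kb).
#' @param min_eaf rare-variant frequency cutoff (default 1%).
#' @return list of windows; each has \code{chrom, start, end} (1-based
#'   inclusive), \code{seed_variants}, \code{variant_ids}. Empty list when
#'   nothing is significant.
#' @export
build_windows <- function(pair, sig_p = 5e-8, flank = 5e5,
                          merge_gap = 2.5e5, min_eaf = 0.01) {
  common <- !(pair$eaf_a < min_eaf | pair$eaf_a > 1 - min_eaf |
                pair$eaf_b < min_eaf | pair$eaf_b > 1 - min_eaf)
  sig <- (pair$p_a < sig_p | pair$p_b < sig_p)
  seeds <- pair[sig, , drop = FALSE]
  if (nrow(seeds) == 0) return(list())
  out <- list()
  for (ch in sort(unique(seeds$chrom))) {
    s <- seeds[seeds$chrom == ch, , drop = FALSE]
    s <- s[order(s$pos, s$variant_id), , drop = FALSE]
    start <- pmax(1, s$pos - flank + 1); end <- s$pos + flank
    # merge overlapping or proximal windows
    grp <- cumsum(c(1, ifelse(start[-1] - cummax(end)[-nrow(s)] < merge_gap,
                              0, 1)))
    for (g in unique(grp)) {
      i <- grp == g
      w_start <- min(start[i]); w_end <- max(end[i])
      in_win <- pair$chrom == ch & pair$pos >= w_start & pair$pos <= w_end &
        common
      out[[length(out) + 1L]] <-
        structure(list(chrom = ch, start = w_start, end = w_end,
                       seed_variants = s$variant_id[i],
                       variant_ids = pair$variant_id[in_win]),
                  class = "analysis_window")
    }
  }
  out
}

#' Classify credible-set variants as concordant or discordant
#'
#' With z-scores harmonized to the same effect allele: a variant is
#' discordant when the two traits' z signs disagree and both associations
#' pass \code{p_thresh}; concordant when the signs agree and both pass;
#' otherwise unlabeled. A z of exactly 0 leaves the variant unlabeled.
#'
#' @param members harmonized-pair rows for the credible-set variants
#'   (needs \code{z_a, z_b, p_a, p_b}).
#' @param p_thresh per-trait association threshold (default 1e-5).
#' @return character vector (\code{"discordant"}, \code{"concordant"},
#'   \code{"unlabeled"}) named by variant id.
#' @export
classify_discordance <- function(members, p_thresh = 1e-5) {
  s <- sign(members$z_a) * sign(members$z_b)
  pass <- members$p_a < p_thresh & members$p_b < p_thresh
  lab <- ifelse(!pass | s == 0, "unlabeled",
                ifelse(s < 0, "discordant", "concordant"))
  stats::setNames(lab, members$variant_id)
}

#' Greedy LD clumping of labeled variants into signals
#'
#' Repeatedly seeds on the unassigned variant with the smallest
#' \code{min(p_a, p_b)} and assigns to it every unassigned variant with
#' r-squared above \code{r2_thresh} to that lead. This matches standard
#' clumping semantics; it is not a connected-components decomposition, so a
#' chain a-b-c with only a-b and b-c linked yields clumps {a,b} and {c}
#' when a is most significant.
#'
#' @param members harmonized-pair rows (needs \code{variant_id, p_a, p_b},
#'   and optionally \code{label} to carry through).
#' @param ld \code{ld_matrix} covering all members.
#' @param r2_thresh clumping threshold (default 0.50).
#' @param labels optional per-variant labels (e.g. from
#'   \code{\link{classify_discordance}}); each signal takes its lead's label.
#' @return list of signals: \code{lead_id, member_ids, label, z_a, z_b}.
#' @export
clump_signals <- function(members, ld, r2_thresh = 0.50, labels = NULL) {
  missing <- setdiff(members$variant_id, ld$ids)
  if (length(missing) > 0)
    stopf("members missing from LD matrix: %s", paste(missing, collapse = ", "))
  if (nrow(members) == 0) return(list())
  pm <- pmin(members$p_a, members$p_b)
  unassigned <- rep(TRUE, nrow(members))
  out <- list()
  while (any(unassigned)) {
    cand <- which(unassigned)
    lead <- cand[order(pm[cand], members$variant_id[cand])][1]
    lead_id <- members$variant_id[lead]
    r2 <- ld$r[lead_id, members$variant_id]^2
    take <- unassigned & (r2 > r2_thresh | members$variant_id == lead_id)
    unassigned[take] <- FALSE
    out[[length(out) + 1L]] <-
      structure(list(lead_id = lead_id,
                     member_ids = members$variant_id[take],
                     label = if (!is.null(labels)) unname(labels[lead_id])
                             else NA_character_,
                     z_a = members$z_a[lead], z_b = members$z_b[lead]),
                class = "signal")
  }
  out
}

#' PheWAS-style lookup of one variant across local summary-statistic sets
#'
#' Aligns each study to a common effect allele (that of the first study
#' carrying the variant) and reports the aligned effect, its standard error
#' and p-value per study; studies without the variant are reported as
#' missing rows, not errors.
#'
#' @param variant_id variant to query.
#' @param studies list of \code{summary_stats}.
#' @return data.frame with columns \code{trait, present, ea, beta, se, p}.
#' @export
phewas_lookup <- function(variant_id, studies) {
  if (length(studies) == 0)
    return(data.frame(trait = character(), present = logical(),
                      ea = character(), beta = numeric(), se = numeric(),
                      p = numeric(), stringsAsFactors = FALSE))
  ref_ea <- ref_nea <- NULL
  rows <- lapply(studies, function(ss) {
    d <- ss$data[ss$data$variant_id == variant_id, , drop = FALSE]
    if (nrow(d) == 0)
      return(data.frame(trait = ss$trait_name, present = FALSE,
                        ea = NA_character_, beta = NA_real_, se = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    d <- d[1, ]
    if (is.null(ref_ea)) { ref_ea <<- d$ea; ref_nea <<- d$nea }
    if (d$ea == ref_ea && d$nea == ref_nea) {
      beta <- d$beta
    } else if (d$ea == ref_nea && d$nea == ref_ea) {
      beta <- -d$beta
    } else {
      return(data.frame(trait = ss$trait_name, present = FALSE,
                        ea = NA_character_, beta = NA_real_, se = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    data.frame(trait = ss$trait_name, present = TRUE, ea = ref_ea,
               beta = beta, se = d$se, p = d$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!any(out$present)) warnf("variant %s absent from all studies", variant_id)
  out
}
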