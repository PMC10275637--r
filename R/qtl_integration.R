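# GWAS-QTL integration: colocalization by approximate Bayes factors
# (PPH4 > 0.50 rule), the SMR statistic with Benjamini-Hochberg FDR at 5%,
# and reconciliation of the two routes into pleiotropy categories.

#' Select genes within a margin of an analysis window
#'
#' @param window an \code{analysis_window}.
#' @param gene_table data.frame with \code{gene, chrom, start, end}.
#' @param margin bp margin on either side (default 1 Mb).
#' @return character vector of gene names overlapping
#'   \[window.start - margin, window.end + margin\].
#' @export
select_qtl_genes <- function(window, gene_table, margin = 1e6) {
  if (nrow(gene_table) == 0) return(character(0))
  hit <- gene_table$chrom == window$chrom &
    gene_table$end >= window$start - margin &
    gene_table$start <= window$end + margin
  gene_table$gene[hit]
}

#' SMR statistic for one instrument variant
#'
#' Approximate chi-square statistic for the mediated (gene -> trait) effect:
#' \deqn{T = z_g^2 z_q^2 / (z_g^2 + z_q^2)} with p from the upper tail of
#' chi-square with 1 df. T = 0 (p = 1) by continuity when both z are 0.
#'
#' @param z_gwas,z_qtl z-statistics at the instrument (vectorized).
#' @return data.frame with columns \code{T} and \code{p}.
#' @export
smr_test <- function(z_gwas, z_qtl) {
  if (any(!is.finite(z_gwas)) || any(!is.finite(z_qtl)))
    stopf("non-finite z in smr_test")
  num <- z_gwas^2 * z_qtl^2
  den <- z_gwas^2 + z_qtl^2
  t_stat <- ifelse(den == 0, 0, num / den)
  data.frame(T = t_stat,
             p = stats::pchisq(t_stat, df = 1, lower.tail = FALSE))
}

#' GWAS-QTL colocalization by approximate Bayes factors
#'
#' Delegates to \code{\link{coloc_pair}} with the QTL-specific pass rule:
#' colocalized iff PPH4 strictly exceeds \code{pph4_thresh} (0.50 by
#' default; PPH4 alone, unlike the PPH3+PPH4 rule used GWAS-to-GWAS).
#'
#' @param pair harmonized GWAS-QTL pair (QTL as trait b).
#' @param pph4_thresh pass threshold on PPH4.
#' @param ... further arguments to \code{\link{coloc_pair}}.
#' @return list with \code{abf_pph4}, \code{abf_pass}, \code{result}.
#' @export
qtl_coloc_abf <- function(pair, pph4_thresh = 0.50, ...) {
  res <- coloc_pair(pair, rule = "h4", threshold = pph4_thresh, ...)
  pph4 <- unname(res$pp["PPH4"])
  list(abf_pph4 = pph4, abf_pass = pph4 > pph4_thresh, result = res)
}

#' Benjamini-Hochberg q-values and pass flags for SMR tests
#'
#' Adjusts across the whole supplied family (all gene x tissue x kind tests
#' run for one GWAS trait) and flags q < \code{fdr}.
#'
#' @param records data.frame with at least \code{smr_p}; other columns are
#'   carried through.
#' @param fdr threshold (default 0.05).
#' @return the records with \code{smr_q} and \code{smr_pass} added.
#' @export
smr_fdr <- function(records, fdr = 0.05) {
  if (nrow(records) == 0) {
    records$smr_q <- numeric(0); records$smr_pass <- logical(0)
    return(records)
  }
  stopifnot(all(records$smr_p > 0 & records$smr_p <= 1))
  records$smr_q <- stats::p.adjust(records$smr_p, method = "BH")
  records$smr_pass <- records$smr_q < fdr
  records
}

#' Reconcile the two QTL-colocalization routes into a category
#'
#' Both routes positive: candidate causal effector transcript. ABF-only:
#' potential horizontal pleiotropy. SMR-only: potential locus-level
#' colocalization. Neither: none.
#'
#' @param abf_pass,smr_pass logical flags (vectorized).
#' @return character category.
#' @export
reconcile <- function(abf_pass, smr_pass) {
  ifelse(abf_pass & smr_pass, "candidate_causal",
         ifelse(abf_pass, "horizontal_pleiotropy",
                ifelse(smr_pass, "locus_level", "none")))
}

#' Assemble the eGene catalog from per-gene QTL colocalization records
#'
#' @param records data.frame with \code{locus, gene, tissue, qtl_kind,
#'   abf_pph4, abf_pass, smr_T, smr_p, smr_q, smr_pass, qtl_beta_aligned}
#'   (QTL beta aligned to the locus's trait-protective allele).
#' @return data.frame of genes with category != "none": one row per
#'   gene x tissue x kind with \code{category},
#'   \code{expression_direction} (sign of the aligned QTL beta) and
#'   \code{consensus} (passed both routes). Loci with no passing gene are
#'   listed in the \code{no_egene_loci} attribute.
#' @export
egene_catalog <- function(records) {
  records$category <- reconcile(records$abf_pass, records$smr_pass)
  keep <- records$category != "none"
  out <- records[keep, , drop = FALSE]
  out$expression_direction <- ifelse(out$qtl_beta_aligned > 0, "+",
                                     ifelse(out$qtl_beta_aligned < 0, "-", "0"))
  out$consensus <- out$abf_pass & out$smr_pass
  rownames(out) <- NULL
  attr(out, "no_egene_loci") <- setdiff(unique(records$locus),
                                        unique(out$locus))
  out
}
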