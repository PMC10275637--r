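# Readers, validators and harmonization for GWAS/QTL summary statistics,
# BED chromatin-state annotations and LD matrices.

CANONICAL_COLS <- c(SNP = "variant_id", CHR = "chrom", POS = "pos",
                    EA = "ea", NEA = "nea", EAF = "eaf", BETA = "beta",
                    SE = "se", P = "p", N = "n", Z = "z")

#' Construct a validated summary-statistics object
#'
#' Container for one trait's per-variant association records. Rows violating
#' the record invariants (non-positive or non-finite standard error,
#' allele frequency outside \[0,1\], identical or non-ACGT alleles,
#' p outside (0,1\]) are dropped, as are duplicated variant ids; the counts
#' are kept in the \code{load_report} attribute. Missing p-values are
#' backfilled from z via the two-sided normal tail; missing beta/se are
#' backfilled from (z, eaf, n) via
#' \code{se = 1/sqrt(2 eaf (1-eaf) (n + z^2))}, \code{beta = z se}.
#' P-values are additionally carried in natural-log space (\code{log_p})
#' so that lead variants whose p underflows double precision remain ordered.
#'
#' @param data data.frame with columns \code{variant_id, chrom, pos, ea,
#'   nea, eaf, beta, se} and optionally \code{p, n, z}.
#' @param trait_name label for the trait.
#' @param trait_type \code{"quantitative"} or \code{"case_control"};
#'   selects the default ABF prior standard deviation downstream.
#' @param case_fraction for case-control traits, the fraction of cases.
#' @return object of class \code{summary_stats}.
#' @export
summary_stats <- function(data, trait_name = "trait",
                          trait_type = c("quantitative", "case_control"),
                          case_fraction = NA_real_) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(data))
  need <- c("variant_id", "chrom", "pos", "ea", "nea", "eaf", "beta", "se")
  for (col in c("p", "n", "z")) if (is.null(data[[col]])) data[[col]] <- NA_real_
  missing_cols <- setdiff(c("variant_id", "chrom", "pos", "ea", "nea"),
                          names(data))
  if (length(missing_cols) > 0)
    stopf("missing mandatory columns: %s", paste(missing_cols, collapse = ", "))
  for (col in setdiff(need, names(data))) data[[col]] <- NA_real_

  n_in <- nrow(data)
  data$ea <- toupper(as.character(data$ea))
  data$nea <- toupper(as.character(data$nea))

  # backfill beta/se from z, eaf, n where absent
  fill <- is.na(data$beta) & is.na(data$se) & !is.na(data$z) &
    !is.na(data$eaf) & !is.na(data$n)
  if (any(fill)) {
    se_fill <- 1 / sqrt(2 * data$eaf[fill] * (1 - data$eaf[fill]) *
                          (data$n[fill] + data$z[fill]^2))
    data$se[fill] <- se_fill
    data$beta[fill] <- data$z[fill] * se_fill
  }
  data$z <- data$beta / data$se

  # backfill p from z (two-sided)
  data$log_p <- suppressWarnings(log(data$p))
  fill_p <- is.na(data$p) & !is.na(data$z)
  if (any(fill_p)) {
    data$log_p[fill_p] <- z_to_p(data$z[fill_p], log.p = TRUE)
    # clamp underflowing p at the smallest subnormal; log_p keeps the order
    data$p[fill_p] <- pmax(pmin(exp(data$log_p[fill_p]), 1),
                           .Machine$double.xmin)
  }

  ok_allele <- data$ea %in% c("A", "C", "G", "T") &
    data$nea %in% c("A", "C", "G", "T") & data$ea != data$nea
  ok <- !is.na(data$se) & is.finite(data$se) & data$se > 0 &
    !is.na(data$eaf) & data$eaf >= 0 & data$eaf <= 1 &
    ok_allele &
    !is.na(data$beta) & is.finite(data$beta) &
    !is.na(data$p) & data$p > 0 & data$p <= 1
  dropped_invalid <- sum(!ok)
  data <- data[ok, , drop = FALSE]
  dup <- duplicated(data$variant_id)
  dropped_dup <- sum(dup)
  data <- data[!dup, , drop = FALSE]
  if (nrow(data) == 0) stopf("no valid rows after validation")
  data$z <- data$beta / data$se
  rownames(data) <- NULL

  out <- list(trait_name = trait_name, trait_type = trait_type,
              case_fraction = case_fraction,
              data = data[, c("variant_id", "chrom", "pos", "ea", "nea",
                              "eaf", "beta", "se", "p", "log_p", "n", "z")])
  attr(out, "load_report") <- list(n_input = n_in,
                                   dropped = dropped_invalid,
                                   dropped_duplicate = dropped_dup,
                                   n_retained = nrow(data))
  class(out) <- "summary_stats"
  out
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("<summary_stats> trait '%s' (%s), %d variants\n",
              x$trait_name, x$trait_type, nrow(x$data)))
  invisible(x)
}

#' Read GWAS/QTL summary statistics from a delimited text file
#'
#' @param path tab- or whitespace-delimited file with a header row.
#' @param column_map named character vector mapping canonical names
#'   (\code{SNP, CHR, POS, EA, NEA, EAF, BETA, SE, P, N, Z}) to the file's
#'   column names; defaults to the canonical names themselves.
#' @param trait_type passed to \code{\link{summary_stats}}.
#' @param trait_name passed to \code{\link{summary_stats}}.
#' @param case_fraction passed to \code{\link{summary_stats}}.
#' @return a \code{summary_stats} object; the load report (rows dropped,
#'   duplicates) is in \code{attr(x, "load_report")}.
#' @export
read_gwas_sumstats <- function(path, column_map = NULL,
                               trait_type = "quantitative",
                               trait_name = basename(path),
                               case_fraction = NA_real_) {
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  cmap <- stats::setNames(names(CANONICAL_COLS), names(CANONICAL_COLS))
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  mandatory <- c("SNP", "CHR", "POS", "EA", "NEA", "EAF")
  absent <- mandatory[!cmap[mandatory] %in% names(raw)]
  if (length(absent) > 0)
    stopf("missing mandatory columns in %s: %s", path,
          paste(cmap[absent], collapse = ", "))
  df <- data.frame(variant_id = as.character(raw[[cmap["SNP"]]]),
                   chrom = as.character(raw[[cmap["CHR"]]]),
                   pos = as.integer(raw[[cmap["POS"]]]),
                   ea = raw[[cmap["EA"]]], nea = raw[[cmap["NEA"]]],
                   eaf = as.numeric(raw[[cmap["EAF"]]]),
                   stringsAsFactors = FALSE)
  for (cc in c("BETA", "SE", "P", "N", "Z")) {
    if (cmap[cc] %in% names(raw))
      df[[CANONICAL_COLS[cc]]] <- as.numeric(raw[[cmap[cc]]])
  }
  summary_stats(df, trait_name = trait_name, trait_type = trait_type,
                case_fraction = case_fraction)
}

is_strand_ambiguous <- function(ea, nea) {
  (ea == "A" & nea == "T") | (ea == "T" & nea == "A") |
    (ea == "C" & nea == "G") | (ea == "G" & nea == "C")
}

#' Harmonize two summary-statistics sets to a shared effect allele
#'
#' Intersects on variant id and aligns study b to study a's effect allele:
#' if b lists the alleles swapped, its beta (and z) sign is flipped and its
#' effect-allele frequency replaced by 1 - eaf. Variants whose allele sets
#' cannot be reconciled are dropped and counted; strand-ambiguous variants
#' (A/T, C/G) are dropped when \code{drop_ambiguous} is set (the default,
#' since frequency-based resolution is not attempted).
#'
#' @param a,b \code{summary_stats} objects.
#' @param drop_ambiguous drop A/T and C/G variants.
#' @return object of class \code{harmonized_pair}: a data.frame with one row
#'   per retained variant (columns suffixed \code{_a}/\code{_b}, alleles as
#'   in a) plus a \code{counts} attribute.
#' @export
harmonize <- function(a, b, drop_ambiguous = TRUE) {
  stopifnot(inherits(a, "summary_stats"), inherits(b, "summary_stats"))
  da <- a$data; db <- b$data
  ix <- match(da$variant_id, db$variant_id)
  keep <- !is.na(ix)
  if (!any(keep)) stopf("empty overlap between '%s' and '%s'",
                        a$trait_name, b$trait_name)
  da <- da[keep, , drop = FALSE]
  db <- db[ix[keep], , drop = FALSE]

  same <- da$ea == db$ea & da$nea == db$nea
  swapped <- da$ea == db$nea & da$nea == db$ea
  irreconcilable <- !(same | swapped)
  ambiguous <- is_strand_ambiguous(da$ea, da$nea)
  drop <- irreconcilable | (drop_ambiguous & ambiguous)

  # align b to a's effect allele
  db$beta[swapped] <- -db$beta[swapped]
  db$z[swapped] <- -db$z[swapped]
  db$eaf[swapped] <- 1 - db$eaf[swapped]
  db$ea <- da$ea; db$nea <- da$nea

  out <- data.frame(variant_id = da$variant_id, chrom = da$chrom,
                    pos = da$pos, ea = da$ea, nea = da$nea,
                    eaf_a = da$eaf, beta_a = da$beta, se_a = da$se,
                    p_a = da$p, log_p_a = da$log_p, n_a = da$n, z_a = da$z,
                    eaf_b = db$eaf, beta_b = db$beta, se_b = db$se,
                    p_b = db$p, log_p_b = db$log_p, n_b = db$n, z_b = db$z,
                    stringsAsFactors = FALSE)[!drop, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) stopf("empty overlap after allele reconciliation")
  attr(out, "counts") <- list(intersected = length(same),
                              flipped = sum(swapped & !drop),
                              dropped_irreconcilable = sum(irreconcilable),
                              dropped_ambiguous =
                                sum(drop_ambiguous & ambiguous & !irreconcilable),
                              retained = nrow(out))
  attr(out, "traits") <- c(a = a$trait_name, b = b$trait_name)
  attr(out, "trait_types") <- c(a = a$trait_type, b = b$trait_type)
  class(out) <- c("harmonized_pair", "data.frame")
  out
}

#' Extract one side of a harmonized pair as summary_stats
#'
#' @param pair a \code{harmonized_pair}.
#' @param which \code{"a"} or \code{"b"}.
#' @return a \code{summary_stats} object on the harmonized alleles.
#' @export
as_summary_stats <- function(pair, which = c("a", "b")) {
  which <- match.arg(which)
  s <- function(col) pair[[paste0(col, "_", which)]]
  df <- data.frame(variant_id = pair$variant_id, chrom = pair$chrom,
                   pos = pair$pos, ea = pair$ea, nea = pair$nea,
                   eaf = s("eaf"), beta = s("beta"), se = s("se"),
                   p = s("p"), n = s("n"), stringsAsFactors = FALSE)
  summary_stats(df, trait_name = attr(pair, "traits")[[which]],
                trait_type = attr(pair, "trait_types")[[which]])
}

#' Build a positional annotation index from BED files
#'
#' Each input BED file carries one (tissue, state) label; intervals are
#' 0-based half-open per the BED standard. The returned index answers
#' point queries at 1-based variant positions: position p overlaps
#' \[s, e) iff s <= p-1 < e.
#'
#' @param specs data.frame with columns \code{tissue}, \code{state},
#'   \code{path} (one BED file per row).
#' @return object of class \code{annotation_index}.
#' @export
read_bed_annotations <- function(specs) {
  stopifnot(is.data.frame(specs),
            all(c("tissue", "state", "path") %in% names(specs)))
  rows <- list()
  for (i in seq_len(nrow(specs))) {
    lines <- readLines(specs$path[i])
    lines <- lines[nzchar(trimws(lines))]
    for (j in seq_along(lines)) {
      f <- strsplit(trimws(lines[j]), "[ \t]+")[[1]]
      if (length(f) < 3 || is.na(suppressWarnings(as.numeric(f[2]))) ||
          is.na(suppressWarnings(as.numeric(f[3]))))
        stopf("malformed BED line %d in %s", j, specs$path[i])
      s <- as.numeric(f[2]); e <- as.numeric(f[3])
      if (s < 0 || e < s) stopf("malformed BED line %d in %s (start %g, end %g)",
                                j, specs$path[i], s, e)
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = f[1], start = s, end = e,
                   tissue = specs$tissue[i], state = specs$state[i],
                   stringsAsFactors = FALSE)
    }
  }
  intervals <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               tissue = character(), state = character())
  structure(list(intervals = intervals,
                 vocabulary = unique(paste(specs$tissue, specs$state,
                                           sep = "|"))),
            class = "annotation_index")
}

#' Map variants to their annotation label sets
#'
#' @param index an \code{annotation_index} from
#'   \code{\link{read_bed_annotations}}.
#' @param variants data.frame with \code{variant_id, chrom, pos}
#'   (1-based positions).
#' @return an \code{annotation_map}: named list variant_id -> character
#'   vector of \code{"tissue|state"} labels (empty when the variant falls in
#'   no interval), with the declared vocabulary attached.
#' @export
annotate_variants <- function(index, variants) {
  stopifnot(inherits(index, "annotation_index"))
  iv <- index$intervals
  labels <- stats::setNames(vector("list", nrow(variants)),
                            variants$variant_id)
  for (ch in unique(variants$chrom)) {
    vi <- which(variants$chrom == ch)
    ii <- which(iv$chrom == ch)
    if (length(ii) == 0) { labels[vi] <- list(character(0)); next }
    # convert BED to 1-based closed intervals for IRanges
    subj <- IRanges::IRanges(start = iv$start[ii] + 1L, end = iv$end[ii])
    qry <- IRanges::IRanges(start = variants$pos[vi], width = 1L)
    hits <- IRanges::findOverlaps(qry, subj)
    lab <- paste(iv$tissue[ii], iv$state[ii], sep = "|")
    for (k in seq_along(vi)) {
      hit_lab <- unique(lab[S4Vectors::subjectHits(hits)[
        S4Vectors::queryHits(hits) == k]])
      labels[[vi[k]]] <- hit_lab
    }
  }
  annotation_map(labels, vocabulary = index$vocabulary)
}

#' Construct an annotation map from explicit variant label sets
#'
#' @param labels named list: variant_id -> character vector of labels
#'   (format \code{"tissue|state"}; genome-level labels use tissue
#'   \code{"genome"}, e.g. \code{"genome|coding"}).
#' @param vocabulary declared label vocabulary; defaults to the labels seen.
#' @return object of class \code{annotation_map}.
#' @export
annotation_map <- function(labels, vocabulary = NULL) {
  stopifnot(is.list(labels), !is.null(names(labels)))
  vocabulary <- vocabulary %||% sort(unique(unlist(labels)))
  bad <- setdiff(unlist(labels), vocabulary)
  if (length(bad) > 0)
    stopf("labels outside declared vocabulary: %s", paste(bad, collapse = ", "))
  structure(list(labels = labels, vocabulary = vocabulary),
            class = "annotation_map")
}

#' Construct a validated LD matrix
#'
#' @param r square numeric matrix of signed correlations.
#' @param ids variant ids, in matrix order.
#' @param tol asymmetry/range tolerance before erroring.
#' @return object of class \code{ld_matrix} with elements \code{ids} and
#'   \code{r} (symmetrized, unit diagonal).
#' @export
ld_matrix <- function(r, ids, tol = 1e-8) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stopf("LD matrix is not square")
  if (length(ids) != nrow(r)) stopf("ids length does not match matrix")
  if (any(abs(r) > 1 + tol)) stopf("LD entries outside [-1, 1]")
  if (max(abs(r - t(r))) > tol) stopf("LD matrix asymmetric beyond tolerance")
  r <- (r + t(r)) / 2
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  dimnames(r) <- list(ids, ids)
  structure(list(ids = as.character(ids), r = r), class = "ld_matrix")
}

#' Read a whitespace-delimited LD matrix
#'
#' The first row is a header of variant ids; subsequent rows are the square
#' correlation matrix in the same order.
#'
#' @param path file path.
#' @param ids optional ordered subset of ids to slice out (order preserved);
#'   ids absent from the file raise a lookup error.
#' @inheritParams ld_matrix
#' @return an \code{ld_matrix}.
#' @export
read_ld_matrix <- function(path, ids = NULL, tol = 1e-8) {
  header <- strsplit(trimws(readLines(path, n = 1L)), "[ \t]+")[[1]]
  m <- as.matrix(utils::read.table(path, header = FALSE, skip = 1L))
  if (nrow(m) != length(header) || ncol(m) != length(header))
    stopf("LD matrix in %s is not square against its header", path)
  obj <- ld_matrix(m, header, tol = tol)
  if (!is.null(ids)) obj <- ld_slice(obj, ids)
  obj
}

#' Slice an LD matrix to an ordered id subset
#' @param ld an \code{ld_matrix}.
#' @param ids ids to keep, in the requested order.
#' @return an \code{ld_matrix} over \code{ids}.
#' @export
ld_slice <- function(ld, ids) {
  ix <- match(ids, ld$ids)
  if (anyNA(ix))
    stopf("ids missing from LD matrix: %s",
          paste(ids[is.na(ix)], collapse = ", "))
  ld_matrix(ld$r[ix, ix, drop = FALSE], ids)
}

#' Write an LD matrix in the package's text format
#' @param ld an \code{ld_matrix}.
#' @param path output path.
#' @export
write_ld_matrix <- function(ld, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(ld$ids, collapse = "\t"), con)
  utils::write.table(format(ld$r, digits = 17, trim = TRUE), con,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Write summary statistics as canonical TSV
#' @param ss a \code{summary_stats}.
#' @param path output path.
#' @export
write_gwas_sumstats <- function(ss, path) {
  d <- ss$data
  out <- data.frame(SNP = d$variant_id, CHR = d$chrom, POS = d$pos,
                    EA = d$ea, NEA = d$nea, EAF = d$eaf, BETA = d$beta,
                    SE = d$se, P = d$p, N = d$n)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
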