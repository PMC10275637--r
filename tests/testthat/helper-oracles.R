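# Independent oracles, written directly from definitions and kept separate
# from the package's optimized code paths.

# Wakefield log-ABF by numerical quadrature of the normal-normal marginal
# likelihood ratio: marginal density of betahat under prior N(0, W) over
# its density under the point null.
quad_labf <- function(z, se, prior_sd) {
  betahat <- z * se
  marginal <- stats::integrate(function(b)
    stats::dnorm(betahat, mean = b, sd = se) *
      stats::dnorm(b, mean = 0, sd = prior_sd),
    lower = -Inf, upper = Inf, rel.tol = 1e-12, abs.tol = 0)$value
  log(marginal) - stats::dnorm(betahat, mean = 0, sd = se, log = TRUE)
}

# Brute-force colocalization posteriors by enumeration of all causal
# configurations: each H1 config (variant i causal for a) has prior p1 and
# Bayes factor BFa_i; H2 likewise; H3 ordered pairs i != j with prior
# p1 * p2; H4 shared variant with prior p12. Direct arithmetic, no
# log-sum-exp; valid for small |labf| loci only.
brute_coloc <- function(labf_a, labf_b, p1 = 1e-4, p2 = 1e-4, p12 = 5e-6) {
  bfa <- exp(labf_a); bfb <- exp(labf_b)
  p <- length(bfa)
  s0 <- 1
  s1 <- p1 * sum(bfa)
  s2 <- p2 * sum(bfb)
  s3 <- 0
  for (i in seq_len(p)) for (j in seq_len(p)) if (i != j)
    s3 <- s3 + p1 * p2 * bfa[i] * bfb[j]
  s4 <- p12 * sum(bfa * bfb)
  tot <- s0 + s1 + s2 + s3 + s4
  c(PPH0 = s0, PPH1 = s1, PPH2 = s2, PPH3 = s3, PPH4 = s4) / tot
}

# Definitional Benjamini-Hochberg q-values: q_i = min over j with
# p_j >= p_i of m * p_j / rank(p_j), capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  r <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(pmin(r, 1))))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Literal biweight midcorrelation, written as a scalar loop from the
# definition: u = (x - med) / (9 mad), w = (1 - u^2)^2 I(|u| < 1),
# correlate the weighted deviations.
bicor_literal <- function(x, y) {
  med_x <- median(x); med_y <- median(y)
  mad_x <- median(abs(x - med_x)); mad_y <- median(abs(y - med_y))
  n <- length(x)
  ax <- numeric(n); ay <- numeric(n)
  for (i in seq_len(n)) {
    ux <- (x[i] - med_x) / (9 * mad_x)
    uy <- (y[i] - med_y) / (9 * mad_y)
    wx <- if (abs(ux) < 1) (1 - ux^2)^2 else 0
    wy <- if (abs(uy) < 1) (1 - uy^2)^2 else 0
    ax[i] <- (x[i] - med_x) * wx
    ay[i] <- (y[i] - med_y) * wy
  }
  s <- 0
  for (i in seq_len(n)) s <- s + ax[i] * ay[i]
  s / (sqrt(sum(ax^2)) * sqrt(sum(ay^2)))
}

# Brute-force per-base BED membership: is 1-based pos inside any 0-based
# half-open [start, end) interval row?
bed_overlap_brute <- function(pos, starts, ends) {
  hits <- logical(length(starts))
  for (k in seq_along(starts)) {
    covered <- seq.int(starts[k] + 1, ends[k])  # 1-based covered positions
    hits[k] <- pos %in% covered
  }
  hits
}

# small well-formed summary-stats data.frame
make_ss_df <- function(n = 5, chrom = "1", seed = 1) {
  set.seed(seed)
  data.frame(variant_id = sprintf("rs%d", seq_len(n)), chrom = chrom,
             pos = seq(1000, by = 1000, length.out = n),
             ea = "A", nea = "G", eaf = runif(n, 0.1, 0.9),
             beta = rnorm(n, 0, 0.05), se = runif(n, 0.01, 0.03),
             n = 10000, stringsAsFactors = FALSE)
}

write_ss_file <- function(df, path = tempfile(fileext = ".tsv")) {
  cols <- c(variant_id = "SNP", chrom = "CHR", pos = "POS", ea = "EA",
            nea = "NEA", eaf = "EAF", beta = "BETA", se = "SE", p = "P",
            n = "N", z = "Z")
  names(df) <- ifelse(names(df) %in% names(cols), cols[names(df)], names(df))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
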