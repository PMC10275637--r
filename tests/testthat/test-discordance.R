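make_pair <- function(df_a, df_b = NULL) {
  if (is.null(df_b)) { df_b <- df_a; df_b$beta <- df_a$beta_b %||% df_a$beta }
  harmonize(summary_stats(df_a), summary_stats(df_b))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

base_df <- function(pos, p = NULL, eaf = 0.3, beta = 0.01, se = 0.01,
                    chrom = "1") {
  n <- length(pos)
  df <- data.frame(variant_id = sprintf("rs%d", seq_len(n)), chrom = chrom,
                   pos = pos, ea = "A", nea = "G", eaf = eaf,
                   beta = beta, se = se, stringsAsFactors = FALSE)
  if (!is.null(p)) { df$beta <- -qnorm(p / 2) * se; df$p <- p }
  df
}

test_that("build_windows flanks, merges and filters rare variants", {
  df <- base_df(c(1e6, 3e6), p = c(1e-9, 0.5))
  pair <- make_pair(df)
  w <- build_windows(pair)
  expect_length(w, 1)
  expect_equal(w[[1]]$start, 500001)
  expect_equal(w[[1]]$end, 1500000)
  expect_equal(w[[1]]$seed_variants, "rs1")
  expect_equal(w[[1]]$variant_ids, "rs1")  # rs2 is 2 Mb away

  # two significant variants 200 kb apart: gap < 250 kb, one merged window
  df2 <- base_df(c(1e6, 1.2e6), p = c(1e-9, 1e-9))
  w2 <- build_windows(make_pair(df2))
  expect_length(w2, 1)
  expect_equal(w2[[1]]$end - w2[[1]]$start + 1, 1.2e6)

  # 1.3 Mb apart: gap 300 kb >= 250 kb, two windows
  df3 <- base_df(c(1e6, 2.3e6), p = c(1e-9, 1e-9))
  expect_length(build_windows(make_pair(df3)), 2)

  # rare variant excluded from window contents in either study
  df4 <- base_df(c(1e6, 1.01e6), p = c(1e-9, 1e-3))
  df4b <- df4; df4b$eaf <- c(0.3, 0.005)
  pair4 <- harmonize(summary_stats(df4), summary_stats(df4b))
  w4 <- build_windows(pair4)
  expect_equal(w4[[1]]$variant_ids, "rs1")

  # nothing significant: empty list
  expect_length(build_windows(make_pair(base_df(1e6, p = 0.01))), 0)
})

test_that("build_windows is invariant to input row order", {
  set.seed(5)
  df <- base_df(sort(sample(1:5e6, 40)), p = runif(40)^8)
  pair <- make_pair(df)
  perm <- pair[sample(nrow(pair)), ]
  class(perm) <- class(pair)
  attr(perm, "trait_types") <- attr(pair, "trait_types")
  w1 <- build_windows(pair); w2 <- build_windows(perm)
  expect_equal(lapply(w1, function(x) x[c("chrom", "start", "end")]),
               lapply(w2, function(x) x[c("chrom", "start", "end")]))
  expect_equal(lapply(w1, function(w) sort(w$variant_ids)),
               lapply(w2, function(w) sort(w$variant_ids)))
})

test_that("classify_discordance follows the sign-and-threshold rule", {
  members <- data.frame(variant_id = c("v1", "v2", "v3", "v4"),
                        z_a = c(5.5, 5.5, 5.5, 0),
                        z_b = c(-4.5, 5.5, -3.0, 5.5))
  members$p_a <- 2 * pnorm(-abs(members$z_a))
  members$p_b <- 2 * pnorm(-abs(members$z_b))
  lab <- classify_discordance(members)
  expect_equal(unname(lab), c("discordant", "concordant", "unlabeled",
                              "unlabeled"))
})

test_that("clump_signals clumps greedily by significance", {
  ids <- c("a", "b", "c")
  mk_ld <- function(rab, rbc, rac) {
    m <- diag(3)
    m[1, 2] <- m[2, 1] <- rab
    m[2, 3] <- m[3, 2] <- rbc
    m[1, 3] <- m[3, 1] <- rac
    ld_matrix(m, ids)
  }
  members <- data.frame(variant_id = ids, p_a = c(1e-10, 1e-8, 1e-6),
                        p_b = c(1e-9, 1e-8, 1e-6),
                        z_a = c(6, 5, 4), z_b = c(-6, -5, -4))
  # pair r2 = 0.6: one signal
  two <- members[1:2, ]
  s1 <- clump_signals(two, mk_ld(sqrt(0.6), 0, 0))
  expect_length(s1, 1)
  expect_equal(s1[[1]]$lead_id, "a")
  # pair r2 = 0.4: two signals
  s2 <- clump_signals(two, mk_ld(sqrt(0.4), 0, 0))
  expect_length(s2, 2)
  # chain a-b (0.6), b-c (0.6), a-c (0.3): greedy gives {a,b} and {c}
  s3 <- clump_signals(members, mk_ld(sqrt(0.6), sqrt(0.6), sqrt(0.3)))
  expect_length(s3, 2)
  expect_setequal(s3[[1]]$member_ids, c("a", "b"))
  expect_equal(s3[[2]]$member_ids, "c")

  expect_error(clump_signals(members, mk_ld(0, 0, 0)[c("ids", "r")] |>
                               (\(x) ld_matrix(x$r[1:2, 1:2], ids[1:2]))()),
               "missing")
})

test_that("clumps partition the members (property)", {
  set.seed(17)
  for (rep in 1:10) {
    p <- 25
    sim <- simulate_ld(p, decay = runif(1, 0.3, 0.95), seed = 300 + rep)
    members <- data.frame(variant_id = sim$ld$ids,
                          p_a = runif(p)^4, p_b = runif(p)^4,
                          z_a = rnorm(p), z_b = rnorm(p))
    sigs <- clump_signals(members, sim$ld)
    all_members <- unlist(lapply(sigs, `[[`, "member_ids"))
    expect_setequal(all_members, members$variant_id)
    expect_equal(length(all_members), p)  # each member in exactly one signal
    for (s in sigs) expect_true(s$lead_id %in% s$member_ids)
  }
})

test_that("signals carry their lead's label", {
  ids <- c("a", "b")
  m <- diag(2); m[1, 2] <- m[2, 1] <- 0.9
  members <- data.frame(variant_id = ids, p_a = c(1e-10, 1e-8),
                        p_b = c(1e-9, 1e-8), z_a = c(6, 5), z_b = c(-6, -5))
  labels <- c(a = "discordant", b = "discordant")
  s <- clump_signals(members, ld_matrix(m, ids), labels = labels)
  expect_equal(s[[1]]$label, "discordant")
})

test_that("phewas_lookup aligns effect alleles across studies", {
  mk <- function(name, present = TRUE, swap = FALSE, beta = 0.2) {
    df <- base_df(c(1e6, 2e6))
    df$beta <- beta
    if (!present) df <- df[2, , drop = FALSE]
    if (swap) {
      df$ea[1] <- "G"; df$nea[1] <- "A"; df$beta[1] <- -beta
    }
    summary_stats(df, trait_name = name)
  }
  studies <- list(mk("s1"), mk("s2", present = FALSE), mk("s3", swap = TRUE),
                  mk("s4"), mk("s5", present = FALSE))
  tab <- phewas_lookup("rs1", studies)
  expect_equal(nrow(tab), 5)
  expect_equal(sum(tab$present), 3)
  # s3 listed the complementary allele order: sign flipped back
  expect_equal(tab$beta[tab$trait == "s3"], 0.2)
  expect_equal(unique(tab$ea[tab$present]), "A")

  expect_warning(none <- phewas_lookup("rs_absent", studies), "absent")
  expect_true(all(!none$present))
  expect_equal(nrow(phewas_lookup("rs1", list())), 0)
})
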