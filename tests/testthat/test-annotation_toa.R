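mk_model <- function(gamma) {
  structure(list(gamma = gamma, se_gamma = gamma * 0,
                 vocabulary = names(gamma)),
            class = "enrichment_model")
}

test_that("toa_scores allocates posterior mass by enrichment weight", {
  model <- mk_model(c("adipose|Enhancer" = 1, "liver|Enhancer" = 1,
                      "genome|coding" = 0.5))
  # single fully-confident variant annotated only in adipose
  am <- annotation_map(list(v1 = "adipose|Enhancer"),
                       vocabulary = model$vocabulary)
  sc <- toa_scores(c(v1 = 1), am, model)
  expect_equal(unname(sc$scores["adipose"]), 1)
  expect_equal(sum(sc$scores), 1)

  # equal annotation, equal gamma: 50/50
  am2 <- annotation_map(list(v1 = c("adipose|Enhancer", "liver|Enhancer")),
                        vocabulary = model$vocabulary)
  sc2 <- toa_scores(c(v1 = 1), am2, model)
  expect_equal(unname(sc2$scores["adipose"]), 0.5)
  expect_equal(unname(sc2$scores["liver"]), 0.5)

  # unannotated variants fall to unclassified, as does residual mass
  am3 <- annotation_map(list(v1 = character(0), v2 = character(0)),
                        vocabulary = model$vocabulary)
  sc3 <- toa_scores(c(v1 = 0.6, v2 = 0.3), am3, model)
  expect_equal(unname(sc3$scores["unclassified"]), 1)

  # genome-level annotation takes precedence over tissue allocation
  am4 <- annotation_map(list(v1 = c("genome|coding", "adipose|Enhancer")),
                        vocabulary = model$vocabulary)
  sc4 <- toa_scores(c(v1 = 1), am4, model)
  expect_equal(unname(sc4$scores["unclassified"]), 1)
  sc4b <- toa_scores(c(v1 = 1), am4, model, genome_precedence = FALSE)
  expect_equal(unname(sc4b$scores["adipose"]), 1)

  expect_error(toa_scores(numeric(0), am, model), "empty")
})

test_that("toa scores sum to 1 and respect gamma monotonicity (property)", {
  set.seed(23)
  tissues <- c("adipose", "liver", "muscle")
  vocab <- paste0(tissues, "|Enh")
  for (rep in 1:15) {
    p <- sample(3:12, 1)
    ids <- paste0("v", seq_len(p))
    labels <- setNames(lapply(seq_len(p), function(i)
      vocab[runif(3) < 0.5]), ids)
    pp <- runif(p); pp <- pp / sum(pp) * runif(1, 0.7, 1)
    names(pp) <- ids
    am <- annotation_map(labels, vocabulary = vocab)
    g <- setNames(rnorm(3), vocab)
    sc <- toa_scores(pp, am, mk_model(g))
    expect_equal(sum(sc$scores), 1, tolerance = 1e-8)
    expect_true(all(sc$scores >= -1e-12))
    # raising adipose gamma never lowers the adipose score
    g2 <- g; g2["adipose|Enh"] <- g["adipose|Enh"] + 1.5
    sc2 <- toa_scores(pp, am, mk_model(g2))
    expect_gte(sc2$scores["adipose"], sc$scores["adipose"] - 1e-12)
  }
})

test_that("classify_toa applies the 0.20 / 0.10 rules", {
  shared <- classify_toa(c(adipose = 0.45, muscle = 0.40, liver = 0.15))
  expect_equal(shared$classification, "shared")
  expect_setequal(shared$tissues, c("adipose", "muscle"))

  top <- classify_toa(c(adipose = 0.60, muscle = 0.20))
  expect_equal(top$classification, "adipose")

  uncl <- classify_toa(c(adipose = 0.15, muscle = 0.15, liver = 0.12))
  expect_equal(uncl$classification, "unclassified")

  # the unclassified share never competes for the assignment
  withu <- classify_toa(c(adipose = 0.3, muscle = 0.1, unclassified = 0.6))
  expect_equal(withu$classification, "adipose")
})

test_that("fit_enrichment recovers the direction of planted enrichment", {
  set.seed(33)
  # annotation covering exactly the top-BF variant in every locus
  loci <- lapply(1:50, function(k) {
    lnbf <- rnorm(20, 0, 2)
    ids <- sprintf("L%dv%d", k, 1:20)
    names(lnbf) <- ids
    labels <- setNames(rep(list(character(0)), 20), ids)
    labels[[which.max(lnbf)]] <- "adipose|Enh"
    list(lnbf = lnbf, annots = annotation_map(labels,
                                              vocabulary = "adipose|Enh"))
  })
  em <- fit_enrichment(loci)
  expect_gt(em$gamma[["adipose|Enh"]], 0)
  expect_gt(em$gamma_empirical[["adipose|Enh"]], 0)
  expect_true(is.finite(em$se_gamma[["adipose|Enh"]]))

  # annotation absent from every variant: reported missing, not +-Inf
  loci2 <- lapply(loci, function(l) {
    l$annots <- annotation_map(l$annots$labels,
                               vocabulary = c("adipose|Enh", "liver|Enh"))
    l
  })
  em2 <- fit_enrichment(loci2)
  expect_true(is.na(em2$gamma[["liver|Enh"]]))
  expect_false(is.na(em2$gamma[["adipose|Enh"]]))
})

test_that("likelihood and empirical estimators agree in sign", {
  set.seed(43)
  agree <- 0; total <- 0
  for (rep in 1:6) {
    g_true <- sample(c(-1.5, 1.5), 1)
    loci <- lapply(1:120, function(k) {
      sim <- simulate_ld(15, decay = 0.3, seed = 5000 + rep * 200 + k,
                         prefix = sprintf("r%dL%dv", rep, k))
      cid <- sim$ld$ids[sample.int(15, 1)]
      pr <- simulate_gwas_pair(sim, scenario_truth("H4", cid, cid,
                                                   lambda = 6),
                               seed = 6000 + rep * 200 + k)
      h <- harmonize(pr$a, pr$b)
      cl <- coloc_pair(h)
      lnbf <- cl$labf_a + cl$labf_b
      names(lnbf) <- names(cl$snp_pp_h4)
      am <- simulate_annotations(sim$meta, c("adipose|Enh" = g_true),
                                 causal_ids = cid, base_rate = 0.2,
                                 seed = 7000 + rep * 200 + k)
      list(lnbf = lnbf, annots = am)
    })
    em <- fit_enrichment(loci)
    total <- total + 1
    agree <- agree + (sign(em$gamma[["adipose|Enh"]]) ==
                        sign(em$gamma_empirical[["adipose|Enh"]]) &&
                        sign(em$gamma[["adipose|Enh"]]) == sign(g_true))
  }
  expect_gte(agree / total, 0.95)
})
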