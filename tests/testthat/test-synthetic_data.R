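test_that("simulate_ld: determinism, boundary decays, PSD repair", {
  s1 <- simulate_ld(50, decay = 0.9, seed = 5)
  s2 <- simulate_ld(50, decay = 0.9, seed = 5)
  expect_identical(s1$ld$r, s2$ld$r)          # bitwise across runs
  expect_identical(s1$meta, s2$meta)

  id <- simulate_ld(10, decay = 0, seed = 1)
  off <- id$ld$r[upper.tri(id$ld$r)]
  expect_true(all(abs(off) < 1e-5))           # identity up to ridge repair

  expect_warning(deg <- simulate_ld(5, decay = 1, seed = 1), "degenerate")
  expect_true(all(deg$ld$r > 0.99))

  hap <- simulate_ld(20, decay = 0.8, n_hap = 500, seed = 2)
  expect_silent(chol(hap$ld$r))
  expect_equal(diag(hap$ld$r), setNames(rep(1, 20), hap$ld$ids))
})

test_that("H0 z-scores are standard normal marginally", {
  zs <- c()
  for (s in 1:10) {
    sim <- simulate_ld(100, decay = 0.9, seed = s)
    pr <- simulate_gwas_pair(sim, scenario_truth("H0"), seed = 100 + s)
    zs <- c(zs, pr$a$data$z)
  }
  expect_equal(mean(zs), 0, tolerance = 0.1)
  expect_equal(sd(zs), 1, tolerance = 0.1)
  expect_lt(mean(abs(zs) > qnorm(1 - 5e-6)), 1e-3)  # p < 1e-5 essentially never
})

test_that("H4 plants the requested non-centrality and discordant signs", {
  sim <- simulate_ld(50, decay = 0.9, seed = 9)
  v <- sim$ld$ids[25]
  tr <- scenario_truth("H4", v, v, lambda = 7)
  trd <- scenario_truth("H4", v, v, sign_concordant = FALSE, lambda = 7)
  z_at_v <- numeric(500); flipped <- logical(500)
  for (r in 1:500) {
    pr <- simulate_gwas_pair(sim, tr, seed = 1000 + r)
    z_at_v[r] <- pr$a$data$z[25]
    prd <- simulate_gwas_pair(sim, trd, seed = 5000 + r)
    flipped[r] <- sign(prd$a$data$z[25]) != sign(prd$b$data$z[25])
  }
  expect_equal(mean(z_at_v), 7, tolerance = 0.2)
  expect_gte(mean(flipped), 0.99)
})

test_that("scenario_truth enforces hypothesis structure", {
  expect_error(scenario_truth("H4", "v1", "v2"), "identical")
  expect_error(scenario_truth("H3", "v1", "v1"), "distinct")
  tr <- scenario_truth("H3", "v1", "v2")
  expect_equal(tr$hypothesis, "H3")
})

test_that("simulate_locus_set honors the mix and is reproducible", {
  set6 <- simulate_locus_set(6, mix = c(H4_discordant = 1), seed = 3,
                             p = 20, lambda = 7)
  expect_length(set6, 6)
  expect_true(all(vapply(set6, `[[`, "", "scenario") == "H4_discordant"))
  expect_true(all(vapply(set6, function(l) !l$truth$sign_concordant,
                         logical(1))))

  expect_length(simulate_locus_set(0), 0)

  mix <- c(H0 = 0.2, H1 = 0.2, H2 = 0.2, H3 = 0.2, H4 = 0.2)
  sA <- simulate_locus_set(20, mix = mix, seed = 1, p = 40)
  sB <- simulate_locus_set(20, mix = mix, seed = 2, p = 40)
  # different draws, identical deterministic scenario counts
  expect_false(identical(sA[[1]]$a$data$z, sB[[1]]$a$data$z))
  expect_equal(table(vapply(sA, `[[`, "", "scenario")),
               table(vapply(sB, `[[`, "", "scenario")))
  # H3 causal pairs are planted in low LD
  for (l in sA) {
    if (l$truth$hypothesis == "H3")
      expect_lt(l$ld$r[l$truth$causal_a, l$truth$causal_b]^2, 0.1)
  }
})

test_that("truth labels round-trip through serialization", {
  tr <- scenario_truth("H4", "v5", "v5", sign_concordant = FALSE, lambda = 7)
  back <- jsonlite::fromJSON(jsonlite::toJSON(unclass(tr), auto_unbox = TRUE))
  expect_equal(back$hypothesis, tr$hypothesis)
  expect_equal(back$causal_a, tr$causal_a)
  expect_equal(back$sign_concordant, tr$sign_concordant)
  expect_equal(back$lambda, tr$lambda)
})

test_that("simulate_annotations plants exact log-odds enrichment", {
  sim <- simulate_ld(200, decay = 0, seed = 4)
  # gamma = 0: label frequency near base rate everywhere
  am0 <- simulate_annotations(sim$meta, c("adipose|Enh" = 0),
                              causal_ids = sim$ld$ids[1], base_rate = 0.2,
                              seed = 6)
  expect_equal(mean(lengths(am0$labels) > 0), 0.2, tolerance = 0.08)
  # gamma -> +inf: causal variant always labeled
  am_inf <- simulate_annotations(sim$meta, c("adipose|Enh" = 50),
                                 causal_ids = sim$ld$ids[1:50],
                                 base_rate = 0.1, seed = 7)
  expect_true(all(lengths(am_inf$labels[sim$ld$ids[1:50]]) == 1))
  # fixed seed: identical map
  am_a <- simulate_annotations(sim$meta, c("x|y" = 1), base_rate = 0.3,
                               seed = 8)
  am_b <- simulate_annotations(sim$meta, c("x|y" = 1), base_rate = 0.3,
                               seed = 8)
  expect_identical(am_a$labels, am_b$labels)
})

test_that("simulate_expression_study hits target correlations", {
  tgt <- matrix(c(0, 0.9), 2, 1)
  es <- simulate_expression_study(2000, tgt, seed = 10)
  b0 <- bicor(es$expr[1, ], es$pheno[1, ])
  b9 <- bicor(es$expr[2, ], es$pheno[1, ])
  expect_lt(abs(b0), 0.05)
  expect_equal(b9, 0.9, tolerance = 0.03)
  expect_error(simulate_expression_study(3, tgt), "minimum")
  expect_error(simulate_expression_study(100, matrix(1, 1, 1)), "in \\(-1,1\\)")
  # non-realizable joint: two genes perfectly tied to one phenotype
  expect_error(simulate_expression_study(100, matrix(0.95, 2, 1)),
               "not realizable")
})

test_that("simulate_timecourse truth labels and determinism", {
  tc0 <- simulate_timecourse(20, dynamic_fraction = 0, seed = 2)
  expect_true(all(!tc0$truth))
  tc1 <- simulate_timecourse(20, dynamic_fraction = 0.5, effect = 1,
                             seed = 2)
  expect_equal(sum(tc1$truth), 10)
  tc2 <- simulate_timecourse(20, dynamic_fraction = 0.5, effect = 1,
                             seed = 2)
  expect_identical(tc1$expr, tc2$expr)
  expect_error(simulate_timecourse(5, timepoints = c(0, 1)), "3")
})
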