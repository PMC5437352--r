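test_that("metacommunity generation is normalized, reproducible, log-linear", {
  expect_equal(makeMetacommunity(1)$p, 1)
  m1 <- makeMetacommunity(500, seed = 4)
  m2 <- makeMetacommunity(500, seed = 4)
  expect_identical(m1, m2)
  expect_equal(sum(m1$p), 1, tolerance = 1e-12)
  expect_true(all(m1$p > 0))
  expect_true(all(m1$thermalBreadth > 0))
  expect_true(all(m1$thermalOptimum >= 5 & m1$thermalOptimum <= 65))
  # lognormal pool: rank-abundance roughly log-linear through mid ranks
  la <- log(sort(m1$p, decreasing = TRUE))
  mid <- 100:400
  fit <- lm(la[mid] ~ qnorm(1 - (mid - 0.5) / 500))
  expect_gt(summary(fit)$r.squared, 0.98)
})

test_that("neutral urn at m = 1 reproduces multinomial sampling", {
  meta <- makeMetacommunity(50, seed = 8)
  sim <- simulateNeutralCommunities(meta, N = 500, m = 1, nSamples = 200,
                                    seed = 8)
  cnt <- matrix(0, 50, 200, dimnames = list(meta$taxon_id, NULL))
  cnt[rownames(counts(sim)), ] <- counts(sim)
  meanCount <- rowMeans(cnt)
  se <- sqrt(500 * meta$p * (1 - meta$p) / 200)
  z <- abs(meanCount - 500 * meta$p) / pmax(se, 1e-9)
  expect_gte(mean(z <= 3), 0.95)
})

test_that("urn simulators are seed-deterministic and record provenance", {
  meta <- makeMetacommunity(60, seed = 2)
  a <- simulateNeutralCommunities(meta, N = 200, m = 0.2, nSamples = 5,
                                  seed = 11)
  b <- simulateNeutralCommunities(meta, N = 200, m = 0.2, nSamples = 5,
                                  seed = 11)
  expect_identical(counts(a), counts(b))
  expect_true(all(sampleDepths(a) == 200))
  prov <- S4Vectors::metadata(a)$provenance$simulation
  expect_equal(prov$m, 0.2)
  expect_gte(prov$burninEvents, 10 * 200)
  expect_error(simulateNeutralCommunities(meta, N = 5, m = 0.2,
                                          nSamples = 2), "N < 10")
  expect_error(simulateNeutralCommunities(meta, N = 100, m = 0,
                                          nSamples = 2), "m must be")
})

test_that("richness declines as immigration decreases (drift to dominance)", {
  meta <- makeMetacommunity(150, seed = 6)
  rich <- vapply(c(1, 0.1, 0.01), function(m) {
    sim <- simulateNicheCommunities(meta, N = 300, m = m,
                                    temperatures = rep(25, 15), sigma = 0,
                                    seed = 31)
    mean(colSums(counts(sim) > 0))
  }, numeric(1))
  expect_true(all(diff(rich) < 0))
})

test_that("sigma = 0 reduces the niche simulator exactly to the neutral one", {
  meta <- makeMetacommunity(80, seed = 3)
  a <- simulateNeutralCommunities(meta, N = 150, m = 0.3, nSamples = 4,
                                  seed = 12)
  b <- simulateNicheCommunities(meta, N = 150, m = 0.3,
                                temperatures = rep(40, 4), sigma = 0,
                                seed = 12)
  expect_identical(counts(a), counts(b))
})

test_that("a strong thermal filter concentrates and impoverishes communities", {
  meta <- makeMetacommunity(200, seed = 9)
  hot <- simulateNicheCommunities(meta, N = 500, m = 0.3,
                                  temperatures = rep(55, 10), sigma = 8,
                                  seed = 13)
  cnt <- counts(hot)
  tol <- meta$taxon_id[abs(meta$thermalOptimum - 55) < 10]
  share <- sum(cnt[rownames(cnt) %in% tol, ]) / sum(cnt)
  expect_gt(share, 0.9)

  # paired with the same seeds, filtering lowers richness
  neu <- simulateNicheCommunities(meta, N = 500, m = 0.3,
                                  temperatures = rep(55, 10), sigma = 0,
                                  seed = 13)
  expect_lt(mean(colSums(counts(hot) > 0)), mean(colSums(counts(neu) > 0)))
})

test_that("divergent dominants split hot samples into dissimilar groups", {
  meta <- makeMetacommunity(250, seed = 14)
  temps <- rep(c(35, 45, 55), 7)
  div <- simulateDivergentDominants(meta, N = 1000, temperatures = temps,
                                    priorityGroups = 3, seed = 15)
  grp <- sampleFrame(div)$priority_group
  d <- as.matrix(brayCurtis(div))
  same <- outer(grp, grp, "==") & upper.tri(d)
  diffg <- outer(grp, grp, "!=") & upper.tri(d)
  expect_gt(mean(d[diffg]), mean(d[same]))

  # boosted taxa are detected essentially everywhere in the hot class
  boosted <- unlist(S4Vectors::metadata(div)$provenance$simulation$boostedTaxa)
  occ <- rowMeans(counts(div)[boosted, , drop = FALSE] > 0)
  expect_true(all(occ >= 0.9))

  # determinism
  div2 <- simulateDivergentDominants(meta, N = 1000, temperatures = temps,
                                     priorityGroups = 3, seed = 15)
  expect_identical(counts(div), counts(div2))
})

test_that("simulated trees cover the taxa and can cluster thermophiles", {
  two <- simulateTree(c("a", "b"), seed = 1)
  expect_setequal(two$tip.label, c("a", "b"))
  expect_equal(nrow(two$edge), 2)

  meta <- makeMetacommunity(60, seed = 21)
  tr <- simulateTree(meta$taxon_id, seed = 2,
                     clusterBy = meta$thermalOptimum)
  expect_setequal(tr$tip.label, meta$taxon_id)
  expect_true(ape::is.rooted(tr))
  expect_true(all(tr$edge.length >= 0))
  cop <- stats::cophenetic(tr)[meta$taxon_id, meta$taxon_id]
  thermo <- meta$thermalOptimum > 45
  within <- mean(cop[thermo, thermo][upper.tri(cop[thermo, thermo])])
  between <- mean(cop[thermo, !thermo])
  expect_lt(within, between)
})

test_that("the chronosequence scenario is complete and reproducible", {
  ce1 <- simulateChronosequence(seed = 3, S = 120, N = 600)
  ce2 <- simulateChronosequence(seed = 3, S = 120, N = 600)
  expect_identical(counts(ce1), counts(ce2))
  expect_identical(sampleFrame(ce1), sampleFrame(ce2))
  expect_equal(ncol(counts(ce1)), 18)
  expect_equal(unname(table(fireClass(ce1))[c("fire_affected", "recovered",
                                              "reference")]),
               c(9L, 7L, 2L), ignore_attr = TRUE)
  sf <- sampleFrame(ce1)
  hot <- sf$fire_class == "fire_affected"
  expect_true(all(sf$temperature[hot] >= 21 & sf$temperature[hot] <= 58))
  expect_true(all(sf$temperature[!hot] >= 12 & sf$temperature[!hot] <= 15))
  expect_false(is.null(communityTree(ce1)))
  expect_true("phylum" %in% colnames(taxonomyTable(ce1)))
  expect_true(all(sampleDepths(ce1) == 600))
})
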