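test_that("null tables preserve per-sample richness and depth", {
  meta <- makeMetacommunity(120, seed = 2)
  ce <- simulateNeutralCommunities(meta, N = 400, m = 0.3, nSamples = 8,
                                   seed = 2)
  m <- counts(ce)
  for (s in 1:5) {
    nm <- counts(nullCommunity(ce, seed = s))
    full <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
    full[rownames(nm), ] <- nm
    expect_equal(colSums(full > 0), colSums(m > 0))
    expect_equal(colSums(full), colSums(m))
  }
})

test_that("one-sample tables make the occurrence step deterministic", {
  m <- matrix(c(5L, 0L, 3L, 2L, 0L), ncol = 1,
              dimnames = list(paste0("t", 1:5), "s1"))
  occupied <- rownames(m)[m[, 1] > 0]
  for (s in 1:5) {
    nm <- counts(nullCommunity(communityExperiment(m), seed = s))
    expect_setequal(rownames(nm)[nm[, 1] > 0], occupied)
  }
})

test_that("taxon selection rate increases with occupancy", {
  # 30 taxa with occupancy staircase across 10 samples
  set.seed(9)
  m <- matrix(0L, 30, 10, dimnames = list(sprintf("t%02d", 1:30),
                                          paste0("s", 1:10)))
  for (i in 1:30) {
    occ <- ceiling(i / 3)          # occupancy 1..10 by block
    m[i, sample(10, occ)] <- 5L
  }
  ce <- communityExperiment(m)
  sel <- matrix(0, 30, 0)
  selRate <- rowMeans(vapply(1:400, function(s) {
    nm <- counts(nullCommunity(ce, seed = s))
    out <- setNames(rep(FALSE, 30), rownames(m))
    out[rownames(nm)[rowSums(nm > 0) > 0]] <- TRUE
    # count presence anywhere in the null table
    out
  }, logical(30)))
  occupancy <- rowSums(m > 0)
  expect_gt(cor(occupancy, selRate, method = "spearman"), 0.8)
})

test_that("beta-null results are deterministic and internally consistent", {
  ce <- simulateChronosequence(seed = 21, S = 100, N = 500)
  r1 <- betaNullDeviation(ce, "bray_curtis", nIter = 99, seed = 5)
  r2 <- betaNullDeviation(ce, "bray_curtis", nIter = 99, seed = 5)
  expect_identical(pairDeviations(r1), pairDeviations(r2))
  p <- pairDeviations(r1)
  expect_equal(p$deviation, p$dObs - p$nullMean)
  expect_true(all(p$nullSd >= 0))
  # per-sample summary is the mean of that sample's pair deviations
  s <- sampleDeviations(r1)
  sid <- s$sample_id[3]
  sel <- p$sample1 == sid | p$sample2 == sid
  expect_equal(s$meanDeviation[s$sample_id == sid], mean(p$deviation[sel]))
  expect_warning(betaNullDeviation(ce, "bray_curtis", nIter = 50, seed = 1),
                 "fewer than 99")
})

test_that("weighted UniFrac beta-null requires and reuses the fixed tree", {
  meta <- makeMetacommunity(80, seed = 31)
  ce <- simulateNeutralCommunities(meta, N = 300, m = 0.3, nSamples = 6,
                                   seed = 31)
  expect_error(betaNullDeviation(ce, "weighted_unifrac", nIter = 99),
               "no phylogeny")
  communityTree(ce) <- simulateTree(rownames(counts(ce)), seed = 32)
  r <- betaNullDeviation(ce, "weighted_unifrac", nIter = 99, seed = 6)
  expect_s4_class(r, "BetaNullResult")
  expect_true(all(is.finite(pairDeviations(r)$deviation)))
})

test_that("deviations of self-null tables are centered near zero", {
  meta <- makeMetacommunity(150, seed = 5)
  base <- simulateNeutralCommunities(meta, N = 600, m = 0.3, nSamples = 12,
                                     seed = 5)
  tab <- nullCommunity(nullCommunity(base, seed = 6), seed = 7)
  r <- betaNullDeviation(tab, "bray_curtis", nIter = 299, seed = 8)
  expect_lt(abs(mean(sampleDeviations(r)$meanDeviation)), 0.05)
})

test_that("mean deviation rises with selection strength", {
  meta <- makeMetacommunity(150, seed = 41)
  temps <- seq(25, 55, length.out = 10)
  devs <- vapply(c(0, 1, 3, 5), function(sg) {
    mean(vapply(1:4, function(r) {
      sim <- simulateNicheCommunities(meta, N = 500, m = 0.3,
                                      temperatures = temps, sigma = sg,
                                      seed = 50 + r)
      rr <- betaNullDeviation(sim, "bray_curtis", nIter = 99,
                              seed = 60 + r)
      mean(sampleDeviations(rr)$meanDeviation)
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cor(c(0, 1, 3, 5), devs, method = "spearman"), 0.9)
  expect_gt(devs[4], devs[1])
})

test_that("deviation grows with temperature when selection scales with it", {
  meta <- makeMetacommunity(200, seed = 5)
  temps <- seq(21, 58, length.out = 16)
  sim <- simulateDivergentDominants(meta, N = 1000, temperatures = temps,
                                    priorityGroups = 1, seed = 2,
                                    sigma = 8 * (temps - 15) / 43,
                                    boost = 1, nBoost = 1)
  r <- betaNullDeviation(sim, "bray_curtis", nIter = 99, seed = 9)
  ct <- suppressWarnings(cor.test(temps,
                                  sampleDeviations(r)$meanDeviation,
                                  method = "spearman"))
  expect_gt(ct$estimate, 0)
})

test_that("group comparison tests classes and refuses degenerate input", {
  ce <- simulateChronosequence(seed = 31, S = 100, N = 500)
  r <- betaNullDeviation(ce, "bray_curtis", nIter = 99, seed = 10)
  sf <- sampleFrame(ce)
  cmp <- deviationByGroup(r, sf, alternative = "greater")
  expect_true(all(c("groupMeans", "tests", "trajectory") %in% names(cmp)))
  expect_gt(cmp$groupMeans[["fire_affected"]],
            cmp$groupMeans[["recovered"]])
  expect_true(all(diff(cmp$trajectory$temperature) >= 0))
  one <- sf
  one$fire_class <- "recovered"
  expect_error(deviationByGroup(r, one), "one class")
})

test_that("group test p-values are uniform under label permutation", {
  ce <- simulateChronosequence(seed = 41, S = 100, N = 500)
  r <- betaNullDeviation(ce, "bray_curtis", nIter = 99, seed = 11)
  sf <- sampleFrame(ce)
  set.seed(12)
  pv <- vapply(1:200, function(i) {
    perm <- sf
    perm$fire_class <- sample(perm$fire_class)
    cmp <- try(deviationByGroup(r, perm), silent = TRUE)
    if (inherits(cmp, "try-error")) return(NA_real_)
    cmp$tests$welch_p[cmp$tests$class1 == "fire_affected" &
                      cmp$tests$class2 == "recovered"]
  }, numeric(1))
  pv <- pv[is.finite(pv)]
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})
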