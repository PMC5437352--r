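test_that("TSV community tables parse, validate and round-trip", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\ts1\ts2", "t1\t5\t0", "t2\t3\t3", "t3\t0\t7"), tf)
  ce <- readCommunityTable(tf)
  expect_s4_class(ce, "CommunityExperiment")
  expect_equal(unname(sampleDepths(ce)), c(8, 10))
  expect_equal(counts(ce)["t1", "s1"], 5L)

  # round trip is the identity
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeCommunityTable(ce, tf2)
  expect_identical(counts(readCommunityTable(tf2)), counts(ce))

  # malformed inputs are rejected
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_error(readCommunityTable(empty))
  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\ts1\ts2", "t1\t5\t1", "t1\t3\t3"), dup)
  expect_error(readCommunityTable(dup), "duplicate")
  neg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\ts1\ts2", "t1\t-5\t1", "t2\t3\t3"), neg)
  expect_error(readCommunityTable(neg), "negative")
  frac <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\ts1\ts2", "t1\t5.5\t1", "t2\t3\t3"), frac)
  expect_error(readCommunityTable(frac), "integer")
})

test_that("dense-JSON BIOM tables are read", {
  m <- randomSmallCounts(4, 3, seed = 2)
  b <- biomformat::make_biom(m)
  tf <- withr::local_tempfile(fileext = ".biom")
  biomformat::write_biom(b, tf)
  ce <- readCommunityTable(tf, format = "biom_json")
  expect_equal(counts(ce)[rownames(m), colnames(m)], m)
})

test_that("newick trees validate, midpoint-root on request, round-trip", {
  tf <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", tf)
  tr <- readTree(tf)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_true(ape::is.rooted(tr))
  expect_equal(sum(tr$edge.length), 5)

  un <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1,C:2);", un)  # unrooted trifurcation
  expect_error(readTree(un), "unrooted")
  expect_true(ape::is.rooted(readTree(un, rootAtMidpoint = TRUE)))

  tf2 <- withr::local_tempfile(fileext = ".nwk")
  writeTree(tr, tf2)
  tr2 <- readTree(tf2)
  expect_equal(sort(tr2$tip.label), sort(tr$tip.label))
  expect_equal(sum(tr2$edge.length), sum(tr$edge.length))
})

test_that("sample metadata and taxonomy readers enforce their schemas", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tfire_class\ttemperature",
               "s1\tfire_affected\t45", "s2\treference\t13"), tf)
  sd <- readSampleData(tf)
  expect_equal(rownames(sd), c("s1", "s2"))
  tf3 <- withr::local_tempfile(fileext = ".tsv")
  writeSampleData(sd, tf3)
  expect_equal(readSampleData(tf3), sd)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\ttemperature", "s1\t45"), bad)
  expect_error(readSampleData(bad), "fire_class")
  badv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tfire_class", "s1\tburnt"), badv)
  expect_error(readSampleData(badv), "fire_class")

  tx <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\ttaxonomy",
               "t1\tBacteria;Chloroflexi;Ktedonobacteria",
               "t2\tBacteria"), tx)
  tt <- readTaxonomy(tx)
  expect_equal(tt["t1", "phylum"], "Chloroflexi")
  expect_equal(tt["t2", "phylum"], "unassigned")
  expect_equal(unname(phylumOf(tt)), c("Chloroflexi", "unidentified"))
  tx2 <- withr::local_tempfile(fileext = ".tsv")
  writeTaxonomy(tt, tx2)
  expect_equal(readTaxonomy(tx2), tt)
})

test_that("taxa absent from the tree abort unless pruning is requested", {
  m <- randomSmallCounts(4, 3, seed = 5)
  tr <- randomSmallTree(3, seed = 5)  # covers t1..t3 only
  expect_error(communityExperiment(m, tree = tr), "absent from the tree")
  ce <- communityExperiment(m, tree = tr, prune = TRUE)
  expect_setequal(rownames(counts(ce)), c("t1", "t2", "t3"))
  expect_equal(S4Vectors::metadata(ce)$provenance$prunedFromTree, "t4")
})

test_that("replicate collapsing sums counts and conserves totals", {
  m <- matrix(c(1, 2, 0, 4, 2, 0), nrow = 2,
              dimnames = list(c("tA", "tB"), c("r1", "r2", "r3")))
  ce <- communityExperiment(m)
  out <- collapseReplicates(ce, c(r1 = "soil1", r2 = "soil1", r3 = "soil1"))
  expect_equal(unname(counts(out)[, "soil1"]), c(3, 6))
  expect_equal(sum(counts(out)), sum(counts(ce)))
  # identity mapping leaves the table unchanged
  idm <- setNames(colnames(m), colnames(m))
  expect_identical(counts(collapseReplicates(ce, idm)), counts(ce))
  expect_error(collapseReplicates(ce, c(r1 = "soil1")), "no soil assignment")
})

test_that("rarefaction preserves depth, reproducibility, and moments", {
  m <- randomSmallCounts(6, 4, seed = 9, maxCount = 50)
  ce <- communityExperiment(m * 10L)
  depth <- min(sampleDepths(ce))
  r1 <- rarefyTable(ce, depth, seed = 3)
  expect_true(all(sampleDepths(r1) == depth))
  r2 <- rarefyTable(ce, depth, seed = 3)
  expect_identical(counts(r1), counts(r2))
  # a sample already at the target depth is untouched
  atDepth <- which(sampleDepths(ce) == depth)[1]
  expect_equal(counts(r1)[rownames(counts(r1)), atDepth],
               counts(ce)[rownames(counts(r1)), atDepth])
  expect_error(rarefyTable(ce, max(sampleDepths(ce)) + 1), "exceeds")

  # forced outcome: single-taxon sample
  one <- communityExperiment(matrix(c(100L, 100L), 1, 2,
                                    dimnames = list("tx", c("a", "b"))))
  expect_equal(unname(counts(rarefyTable(one, 10))[1, ]), c(10L, 10L))

  # hypergeometric moments: taxon at 50% relative abundance, depth 1000
  tab <- communityExperiment(matrix(c(1000L, 1000L), 2, 1,
                                    dimnames = list(c("u", "v"), "s")))
  props <- vapply(seq_len(400), function(s)
    counts(rarefyTable(tab, 1000, seed = s))["u", 1] / 1000, numeric(1))
  sdDraw <- sqrt(1000 * 0.5 * 0.5 * (2000 - 1000) / (2000 - 1)) / 1000
  expect_lt(abs(mean(props) - 0.5), 3 * sdDraw / sqrt(400))
})

test_that("singleton removal is dataset-wide and order-preserving", {
  m <- rbind(a = c(1L, 0L, 0L),   # dataset total 1 -> removed
             b = c(1L, 1L, 0L),   # once in each of two samples -> kept
             c = c(0L, 1L, 1L),
             d = c(5L, 5L, 5L))
  colnames(m) <- c("s1", "s2", "s3")
  ce <- communityExperiment(m)
  out <- removeSingletons(ce)
  # 'a' totals 1 -> removed; 'b' is 1+1=2 across two samples -> retained
  expect_setequal(rownames(counts(out)), c("b", "c", "d"))
  expect_equal(rownames(counts(out)), c("b", "c", "d"))
  # no singletons -> identity
  expect_identical(counts(removeSingletons(out)), counts(out))
})

test_that("the preprocessing chain runs collapse -> rarefy -> singletons", {
  m <- randomSmallCounts(8, 6, seed = 21) * 30L
  ce <- communityExperiment(m)
  mp <- setNames(rep(c("x", "y", "z"), each = 2), colnames(m))
  out <- preprocessCommunity(ce, replicateMap = mp, depth = 100, seed = 4)
  expect_equal(ncol(counts(out)), 3)
  expect_true(all(sampleDepths(out) <= 100))
  expect_true(!is.null(S4Vectors::metadata(out)$provenance$depths))
  expect_error(collapseReplicates(ce, mp[-1]), "no soil assignment")
})
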