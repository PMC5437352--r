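.nullOnce <- function(m, occWeight, regAbund) {
  # one randomized table preserving, per sample, observed richness S_j and
  # depth N_j: occurrence by occupancy-weighted sampling without
  # replacement, then "seed one individual per chosen taxon and allocate
  # the remainder multinomially" by regional relative abundance
  S <- nrow(m)
  out <- matrix(0L, S, ncol(m), dimnames = dimnames(m))
  for (j in seq_len(ncol(m))) {
    Sj <- sum(m[, j] > 0)
    Nj <- sum(m[, j])
    if (Sj > S) stop("sample richness exceeds taxon pool")
    chosen <- sample.int(S, Sj, prob = occWeight)
    alloc <- rep(1L, Sj)
    if (Nj > Sj)
      alloc <- alloc + as.integer(rmultinom(1, Nj - Sj, regAbund[chosen]))
    out[chosen, j] <- alloc
  }
  out
}

#' Draw one abundance-null community table
#'
#' Randomizes a table while preserving each sample's observed richness and
#' total abundance. Which taxa occur is sampled without replacement with
#' probability proportional to occupancy (number of samples occupied);
#' each chosen taxon is seeded with one individual and the remaining reads
#' are allocated by a multinomial draw proportional to the taxa's regional
#' relative abundances, so chosen taxa can never end at zero. Either
#' weighting can be switched to uniform.
#'
#' @param x a `CommunityExperiment` (or taxa-by-samples matrix).
#' @param seed integer seed.
#' @param occupancyWeighted weight occurrence sampling by occupancy.
#' @param abundanceWeighted weight read allocation by regional relative
#'   abundance.
#' @return an object of the same kind as `x` with identical per-sample
#'   richness and depth.
#' @export
nullCommunity <- function(x, seed = 1L, occupancyWeighted = TRUE,
                          abundanceWeighted = TRUE) {
  isCE <- methods::is(x, "CommunityExperiment")
  m <- if (isCE) counts(x) else x
  occ <- if (occupancyWeighted) rowSums(m > 0) else rep(1, nrow(m))
  reg <- if (abundanceWeighted) rowSums(m) / sum(m) else
    rep(1 / nrow(m), nrow(m))
  out <- withr::with_seed(seed, .nullOnce(m, occ, reg))
  if (!isCE) return(out)
  ce <- communityExperiment(out,
                            sampleData = if (ncol(sampleFrame(x)))
                              sampleFrame(x) else NULL)
  S4Vectors::metadata(ce)$provenance$null <- list(
    seed = seed, occupancyWeighted = occupancyWeighted,
    abundanceWeighted = abundanceWeighted)
  ce
}

.pairIndex <- function(n) {
  a <- rep(seq_len(n - 1), times = (n - 1):1)
  b <- unlist(lapply(2:n, function(k) k:n))
  cbind(a, b)
}

.distVec <- function(m, metric, dec, normalized) {
  # lower-triangle distance vector for one (possibly permuted) table
  if (metric == "bray_curtis") {
    as.vector(vegan::vegdist(t(m), method = "bray"))
  } else {
    P <- sweep(m, 2, colSums(m), "/")[dec$tipLabels, , drop = FALSE]
    as.vector(as.dist(.unifracFromProportions(P, dec, weighted = TRUE,
                                              normalized = normalized)))
  }
}

#' Beta-null deviation modeling
#'
#' Computes observed pairwise beta diversity (Bray-Curtis, or the
#' phylogenetic extension via weighted UniFrac), the expectation of the
#' same metric over `nIter` randomized tables from [nullCommunity()] (the
#' tree is held fixed; only the table is permuted), and reports per-pair
#' deviations `d_obs - null_mean` with their standardized form, plus
#' per-sample means over each sample's comparison set.
#'
#' @param x a `CommunityExperiment` (tree required for
#'   `metric = "weighted_unifrac"`).
#' @param metric `"bray_curtis"` or `"weighted_unifrac"`.
#' @param nIter number of null iterations (warning below 99; default 999).
#' @param scope `"all_pairs"` (per-sample means over every pair) or
#'   `"within_group"` (pairs within the same level of `groups` only).
#' @param groups grouping factor, required for `scope = "within_group"`.
#' @param seed integer seed; identical inputs and seed give identical
#'   results.
#' @param normalized normalization flag passed to the weighted UniFrac.
#' @param checkMargins assert richness/depth preservation at every
#'   iteration.
#' @return a [BetaNullResult-class] object.
#' @export
betaNullDeviation <- function(x, metric = c("bray_curtis",
                                            "weighted_unifrac"),
                              nIter = 999, scope = c("all_pairs",
                                                     "within_group"),
                              groups = NULL, seed = 1L, normalized = TRUE,
                              checkMargins = TRUE) {
  metric <- match.arg(metric)
  scope <- match.arg(scope)
  if (nIter < 99)
    warning("fewer than 99 null iterations; null moments will be noisy")
  m <- counts(x)
  n <- ncol(m)
  if (n < 2) stop("need at least two samples")
  dec <- if (metric == "weighted_unifrac") .decompositionFor(x) else NULL
  if (scope == "within_group" && is.null(groups))
    stop("scope = 'within_group' requires groups")

  dObs <- .distVec(m, metric, dec, normalized)
  occ <- rowSums(m > 0)
  reg <- rowSums(m) / sum(m)
  rich <- colSums(m > 0)
  dep <- colSums(m)

  acc <- withr::with_seed(seed, {
    s1 <- numeric(length(dObs))
    s2 <- numeric(length(dObs))
    for (k in seq_len(nIter)) {
      nm <- .nullOnce(m, occ, reg)
      if (checkMargins) {
        stopifnot(all(colSums(nm > 0) == rich), all(colSums(nm) == dep))
      }
      dk <- .distVec(nm, metric, dec, normalized)
      s1 <- s1 + dk
      s2 <- s2 + dk^2
    }
    list(s1 = s1, s2 = s2)
  })
  nullMean <- acc$s1 / nIter
  nullVar <- pmax(0, (acc$s2 - nIter * nullMean^2) / (nIter - 1))
  nullSd <- sqrt(nullVar)
  deviation <- dObs - nullMean
  degenerate <- nullSd < 1e-12
  if (any(degenerate))
    warning(sum(degenerate), " pair(s) with degenerate null SD; ",
            "standardized deviation reported as NA")
  ses <- ifelse(degenerate, NA_real_, deviation / nullSd)

  idx <- .pairIndex(n)
  ids <- colnames(m)
  pairs <- data.frame(sample1 = ids[idx[, 1]], sample2 = ids[idx[, 2]],
                      dObs = dObs, nullMean = nullMean, nullSd = nullSd,
                      deviation = deviation, ses = ses, row.names = NULL)
  inScope <- if (scope == "all_pairs") rep(TRUE, nrow(pairs)) else
    as.character(groups[idx[, 1]]) == as.character(groups[idx[, 2]])
  samples <- do.call(rbind, lapply(seq_len(n), function(j) {
    sel <- inScope & (idx[, 1] == j | idx[, 2] == j)
    data.frame(sample_id = ids[j],
               meanDeviation = if (any(sel)) mean(deviation[sel]) else NA,
               meanSes = if (any(sel)) mean(ses[sel], na.rm = TRUE) else NA,
               nPairs = sum(sel), row.names = NULL)
  }))
  methods::new("BetaNullResult", metric = metric, normalized = normalized,
               nIterations = as.integer(nIter), scope = scope,
               pairs = pairs, samples = samples, seed = as.integer(seed))
}

#' Compare beta-null deviations across fire classes
#'
#' Groups the per-sample deviation summaries by fire classification,
#' reports group means, pairwise two-sample tests between classes (Welch t
#' and Mann-Whitney, both one-sided variants available), and the
#' deviation-versus-temperature trajectory (samples ordered by
#' temperature) with a Spearman trend among fire-affected samples.
#'
#' @param result a [BetaNullResult-class] object.
#' @param sampleData `data.frame` with `fire_class` (and optionally
#'   `temperature`), rows named by sample.
#' @param alternative alternative hypothesis for tests comparing the first
#'   class of each pair against the second (classes ordered
#'   fire_affected, recovered, reference).
#' @return list with `groupMeans`, `tests` (`data.frame`), `trajectory`
#'   (`data.frame` ordered by temperature), and `hotTrend` (Spearman rho
#'   and p among fire-affected samples, if temperature is available).
#' @export
deviationByGroup <- function(result, sampleData,
                             alternative = c("two.sided", "greater",
                                             "less")) {
  alternative <- match.arg(alternative)
  stopifnot(methods::is(result, "BetaNullResult"))
  smp <- sampleDeviations(result)
  if (!"fire_class" %in% colnames(sampleData))
    stop("sampleData must contain fire_class")
  cls <- factor(sampleData[smp$sample_id, "fire_class"],
                levels = c("fire_affected", "recovered", "reference"))
  cls <- droplevels(cls)
  if (nlevels(cls) < 2)
    stop("all samples belong to one class; between-class test impossible")
  groupMeans <- tapply(smp$meanDeviation, cls, mean)

  combos <- utils::combn(levels(cls), 2)
  tests <- do.call(rbind, apply(combos, 2, function(pr) {
    a <- smp$meanDeviation[cls == pr[1]]
    b <- smp$meanDeviation[cls == pr[2]]
    if (length(a) < 2 || length(b) < 2) return(NULL)
    tt <- t.test(a, b, alternative = alternative)
    wt <- suppressWarnings(wilcox.test(a, b, alternative = alternative))
    data.frame(class1 = pr[1], class2 = pr[2],
               welch_t = unname(tt$statistic), welch_p = tt$p.value,
               mannwhitney_W = unname(wt$statistic),
               mannwhitney_p = wt$p.value, row.names = NULL)
  }))

  trajectory <- NULL
  hotTrend <- NULL
  if ("temperature" %in% colnames(sampleData)) {
    temp <- sampleData[smp$sample_id, "temperature"]
    ord <- order(temp)
    trajectory <- data.frame(sample_id = smp$sample_id[ord],
                             temperature = temp[ord],
                             fire_class = as.character(cls)[ord],
                             meanDeviation = smp$meanDeviation[ord],
                             row.names = NULL)
    hot <- cls == "fire_affected"
    if (sum(hot, na.rm = TRUE) >= 4) {
      ct <- suppressWarnings(cor.test(temp[hot], smp$meanDeviation[hot],
                                      method = "spearman"))
      hotTrend <- list(rho = unname(ct$estimate), p = ct$p.value)
    }
  }
  list(groupMeans = groupMeans, tests = tests, trajectory = trajectory,
       hotTrend = hotTrend)
}
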