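#' Generate a regional species pool
#'
#' Draws a lognormal metacommunity of `S` taxa: relative abundances from a
#' lognormal (then normalized to sum to one), thermal optima uniform on
#' [5, 65] degrees C, and positive thermal niche breadths (lognormal around
#' 8 degrees C). The pool is the source of immigrants for every simulator.
#'
#' @param S number of taxa.
#' @param seed integer seed.
#' @param sdlog lognormal shape of the rank-abundance distribution.
#' @param breadthMean,breadthSdlog location/shape of the thermal breadth
#'   distribution (degrees C).
#' @return `data.frame` with `taxon_id`, `p` (relative abundance),
#'   `thermalOptimum`, `thermalBreadth`.
#' @export
makeMetacommunity <- function(S, seed = 1L, sdlog = 1.5,
                              breadthMean = 8, breadthSdlog = 0.3) {
  stopifnot(S >= 1)
  withr::with_seed(seed, {
    ab <- rlnorm(S, meanlog = 0, sdlog = sdlog)
    data.frame(
      taxon_id = sprintf("OTU_%04d", seq_len(S)),
      p = ab / sum(ab),
      thermalOptimum = runif(S, 5, 65),
      thermalBreadth = rlnorm(S, meanlog = log(breadthMean),
                              sdlog = breadthSdlog),
      stringsAsFactors = FALSE)
  })
}

.gaussFitness <- function(temperature, opt, breadth, sigma) {
  # Gaussian thermal kernel raised to the selection-strength exponent;
  # sigma = 0 gives exactly 1 for every taxon (neutral reduction)
  if (sigma == 0) return(rep(1, length(opt)))
  exp(-sigma * (temperature - opt)^2 / (2 * breadth^2))
}

.urnSteps <- function(N, m) {
  # relaxation time of the migration-drift urn scales like N/m events;
  # ceiling(N * max(10, 5/m)) keeps >= 10N while covering small m
  ceiling(N * max(10, 5 / m))
}

.simulateUrn <- function(meta, N, m, temperatures, sigma, sampleIds) {
  S <- nrow(meta)
  out <- matrix(0L, S, length(temperatures),
                dimnames = list(meta$taxon_id, sampleIds))
  steps <- .urnSteps(N, m)
  for (j in seq_along(temperatures)) {
    w <- .gaussFitness(temperatures[j], meta$thermalOptimum,
                       meta$thermalBreadth, sigma)
    imm <- meta$p * w
    if (sum(imm) <= 0)
      stop("thermal filter removed all taxa at T = ", temperatures[j])
    init <- as.integer(rmultinom(1, N, imm))
    out[, j] <- .urnSample(init, imm, w, m, steps)
  }
  out
}

#' Simulate neutral local communities
#'
#' Forward-simulates the discrete urn: per event one uniformly chosen
#' individual dies and is replaced by an immigrant drawn from the
#' metacommunity with probability `m`, else by the offspring of a surviving
#' resident chosen proportionally to local abundance. Each sample is
#' initialized at the metacommunity expectation and burned in for
#' `N * max(10, 5/m)` events before being read out, so every sample is an
#' (approximately stationary) N-individual community.
#'
#' @param meta a metacommunity from [makeMetacommunity()].
#' @param N local community size (>= 10).
#' @param m per-event immigration probability in (0, 1].
#' @param nSamples number of local communities.
#' @param seed integer seed.
#' @return a `CommunityExperiment`; every column sums to `N`.
#' @export
simulateNeutralCommunities <- function(meta, N, m, nSamples, seed = 1L) {
  simulateNicheCommunities(meta, N = N, m = m,
                           temperatures = rep(25, nSamples),
                           sigma = 0, seed = seed)
}

#' Simulate thermally filtered local communities
#'
#' Identical urn process to [simulateNeutralCommunities()], but both
#' immigration and local birth probabilities are reweighted by a Gaussian
#' thermal fitness kernel `w_i(T) = exp(-(T - opt_i)^2 / (2 breadth_i^2))`
#' raised to the selection strength `sigma`. `sigma = 0` reduces exactly to
#' the neutral simulator (same seed, same draws).
#'
#' @inheritParams simulateNeutralCommunities
#' @param temperatures per-sample temperatures (degrees C); length sets the
#'   number of samples.
#' @param sigma selection strength (>= 0).
#' @export
simulateNicheCommunities <- function(meta, N, m, temperatures, sigma,
                                     seed = 1L) {
  stopifnot(is.data.frame(meta), nrow(meta) >= 1)
  if (N < 10) stop("N < 10: stationarity of the urn is unreliable")
  if (m <= 0 || m > 1) stop("m must be in (0, 1]")
  if (sigma < 0) stop("sigma must be >= 0")
  n <- length(temperatures)
  ids <- sprintf("S%02d", seq_len(n))
  cnt <- withr::with_seed(seed,
    .simulateUrn(meta, N, m, temperatures, sigma, ids))
  sd <- data.frame(temperature = temperatures, row.names = ids)
  ce <- communityExperiment(cnt, sampleData = sd)
  S4Vectors::metadata(ce)$provenance$simulation <- list(
    generator = if (sigma == 0) "neutral" else "niche",
    N = N, m = m, sigma = sigma, seed = seed, nTaxa = nrow(meta),
    burninEvents = .urnSteps(N, m))
  ce
}

#' Simulate communities with divergent dominants (priority effects)
#'
#' Emulates priority effects among hot soils: samples are assigned
#' round-robin to `priorityGroups`; each group elevates a distinct random
#' subset of thermotolerant taxa (those whose optima lie closest to the
#' mean sampled temperature) by a multiplicative dominance boost on top of
#' the thermal-filtered metacommunity weights, before one multinomial draw
#' of `N` individuals per sample. Dominant membership therefore diverges
#' across groups while every taxon stays available at low abundance
#' everywhere. `priorityGroups = 1` adds no divergence beyond the thermal
#' filter itself.
#'
#' @inheritParams simulateNicheCommunities
#' @param priorityGroups number of divergent dominance groups (>= 1).
#' @param sigma selection strength of the underlying thermal filter; a
#'   scalar, or one value per sample (e.g. increasing with temperature).
#' @param boost multiplicative weight applied to each boosted taxon.
#' @param nBoost number of boosted taxa per group.
#' @param backgroundShare fraction of each community drawn uniformly from
#'   the union of priority winners (the dormant "seed bank" awake at low
#'   abundance everywhere); `NULL` sizes it so each winner's expected
#'   background count is about 5 reads.
#' @param dominanceSd lognormal standard deviation of the per-soil jitter
#'   on winner dominance (relative abundances of shared dominants differ
#'   between soils; 0 disables).
#' @return a `CommunityExperiment`; the provenance records the boosted
#'   taxa and the group of every sample.
#' @export
simulateDivergentDominants <- function(meta, N, temperatures,
                                       priorityGroups = 3, seed = 1L,
                                       sigma = 5, boost = 100,
                                       nBoost = 10,
                                       backgroundShare = NULL,
                                       dominanceSd = 1.5) {
  stopifnot(is.data.frame(meta), priorityGroups >= 1, nBoost >= 1)
  n <- length(temperatures)
  sigma <- rep_len(sigma, n)
  ids <- sprintf("S%02d", seq_len(n))
  grp <- ((seq_len(n) - 1L) %% priorityGroups) + 1L
  res <- withr::with_seed(seed, {
    tBar <- mean(temperatures)
    need <- priorityGroups * nBoost
    pool <- which(abs(meta$thermalOptimum - tBar) < 10)
    if (length(pool) < need)
      pool <- order(abs(meta$thermalOptimum - tBar))[seq_len(need)]
    chosen <- sample(pool, need)
    boostSets <- split(chosen, rep(seq_len(priorityGroups), each = nBoost))
    cnt <- matrix(0L, nrow(meta), n,
                  dimnames = list(meta$taxon_id, ids))
    for (j in seq_len(n)) {
      w <- .gaussFitness(temperatures[j], meta$thermalOptimum,
                         meta$thermalBreadth, sigma[j])
      wt <- meta$p * w
      bs <- boostSets[[grp[j]]]
      # a priority winner is, by assumption, viable at its group's
      # temperatures (fitness floored at 0.1 before boosting, so a harsh
      # filter cannot hand every group the same filter-fittest taxa), and
      # its realized dominance varies from soil to soil (lognormal jitter:
      # relative abundances change between soils even when membership is
      # shared)
      # winner dominance does not inherit regional rarity: a dormant
      # thermophile that wins priority dominates regardless of how rare it
      # was in the pool (mean-abundance offset)
      wt[bs] <- boost * (meta$p[bs] + mean(meta$p)) * pmax(w[bs], 0.1) *
        rlnorm(length(bs), 0, dominanceSd)
      wt <- wt / sum(wt)
      # seed-bank background: a small share of every hot community is a
      # uniform draw over the union of priority winners, so each winner is
      # detectable (rare-biosphere) in essentially all hot samples while
      # dominating only where its group won priority
      beta <- if (is.null(backgroundShare))
        min(0.2, 5 * length(chosen) / N) else backgroundShare
      bg <- numeric(nrow(meta))
      bg[chosen] <- 1 / length(chosen)
      wt <- (1 - beta) * wt + beta * bg
      # every taxon keeps a nonzero detection probability everywhere
      wt <- wt + 1e-6 * meta$p
      cnt[, j] <- as.integer(rmultinom(1, N, wt))
    }
    list(cnt = cnt, boostSets = boostSets)
  })
  sd <- data.frame(temperature = temperatures, priority_group = grp,
                   row.names = ids)
  ce <- communityExperiment(res$cnt, sampleData = sd)
  S4Vectors::metadata(ce)$provenance$simulation <- list(
    generator = "divergent_dominants", N = N, sigma = sigma,
    priorityGroups = priorityGroups, boost = boost, nBoost = nBoost,
    seed = seed,
    boostedTaxa = lapply(res$boostSets, function(i) meta$taxon_id[i]))
  ce
}

#' Simulate a rooted phylogeny over a taxon set
#'
#' Random coalescent-style rooted topology with exponential branch lengths.
#' In clustered mode the topology is built by average-linkage clustering of
#' (jittered) thermal optima, so thermophiles are phylogenetically
#' aggregated — emulating the clade-level thermal conservatism seen in
#' fire-affected communities.
#'
#' @param taxonIds tip labels.
#' @param seed integer seed.
#' @param clusterBy optional numeric vector (e.g. thermal optima, one per
#'   taxon); when given, tips with similar values are placed in the same
#'   clades.
#' @param rate rate of the exponential branch-length distribution.
#' @return a rooted `phylo` whose tip set equals `taxonIds` exactly.
#' @export
simulateTree <- function(taxonIds, seed = 1L, clusterBy = NULL, rate = 10) {
  n <- length(taxonIds)
  stopifnot(n >= 2)
  withr::with_seed(seed, {
    if (is.null(clusterBy)) {
      tr <- ape::rcoal(n, tip.label = taxonIds)
    } else {
      stopifnot(length(clusterBy) == n)
      jit <- clusterBy + rnorm(n, sd = stats::sd(clusterBy) / 10)
      hc <- stats::hclust(dist(jit), method = "average")
      hc$labels <- taxonIds
      tr <- ape::as.phylo(hc)
    }
    tr$edge.length <- rexp(nrow(tr$edge), rate = rate)
    tr
  })
}

#' Simulate a full fire chronosequence study
#'
#' Builds the complete synthetic counterpart of a press-disturbance soil
#' chronosequence: reference and recovered soils at ambient temperatures
#' (12-15 degrees C) assembled neutrally from a shared regional pool;
#' fire-affected soils at 21-58 degrees C assembled under a thermal filter
#' whose strength increases with temperature, with divergent dominance
#' groups (priority effects); a clustered phylogeny; clade-derived
#' taxonomy; and sample metadata with soil chemistry in which ammonium and
#' nitrate increase with temperature, recovered soils are more acidic than
#' reference soils, and coordinates carry no spatial signal.
#'
#' @param seed integer seed governing every draw.
#' @param S regional pool size (taxa).
#' @param N per-sample community size (individuals = even depth).
#' @param nReference,nRecovered,nFireAffected class sample sizes.
#' @param m immigration probability for the neutral classes.
#' @param sigmaMax selection strength reached at the hottest temperature;
#'   per-sample strength scales linearly between ambient (15 C) and 58 C.
#' @param priorityGroups,boost,nBoost divergent-dominants settings (see
#'   [simulateDivergentDominants()]).
#' @return a `CommunityExperiment` with counts, tree, taxonomy and sample
#'   metadata, ready for [runChronosequenceAnalysis()].
#' @export
simulateChronosequence <- function(seed = 1L, S = 400, N = 2000,
                                   nReference = 2, nRecovered = 7,
                                   nFireAffected = 9, m = 0.3,
                                   sigmaMax = 6, priorityGroups = 3,
                                   boost = 100, nBoost = 10) {
  meta <- makeMetacommunity(S, seed = seed)
  n <- nReference + nRecovered + nFireAffected
  cls <- c(rep("reference", nReference), rep("recovered", nRecovered),
           rep("fire_affected", nFireAffected))
  prm <- withr::with_seed(seed + 1L, {
    temps <- c(runif(nReference + nRecovered, 12, 15),
               runif(nFireAffected, 21, 58))
    list(temps = temps,
         xy = cbind(x = runif(n, 0, 1000), y = runif(n, 0, 1000)))
  })
  temps <- prm$temps

  cool <- simulateNicheCommunities(meta, N = N, m = m,
                                   temperatures = temps[cls != "fire_affected"],
                                   sigma = 0, seed = seed + 2L)
  hotT <- temps[cls == "fire_affected"]
  # per-sample selection strength rises linearly with temperature
  sigmaHot <- sigmaMax * (hotT - 15) / (58 - 15)
  hot <- simulateDivergentDominants(meta, N = N, temperatures = hotT,
                                    priorityGroups = priorityGroups,
                                    seed = seed + 3L,
                                    sigma = sigmaHot, boost = boost,
                                    nBoost = nBoost)
  cnt <- matrix(0L, S, n, dimnames = list(
    meta$taxon_id, sprintf("C%02d", seq_len(n))))
  cnt[rownames(counts(cool)), cls != "fire_affected"] <- counts(cool)
  cnt[rownames(counts(hot)), cls == "fire_affected"] <- counts(hot)

  chem <- withr::with_seed(seed + 4L, {
    ph <- ifelse(cls == "reference", rnorm(n, 5.9, 0.2),
          ifelse(cls == "recovered", rnorm(n, 4.4, 0.3),
                 runif(n, 4.0, 7.0)))
    sdT <- stats::sd(temps)
    nh4 <- 2 + 0.10 * temps + rnorm(n, 0, 0.10 * sdT * sqrt(3))
    no3 <- 3 + 0.12 * temps + rnorm(n, 0, 0.12 * sdT * sqrt(2.4))
    data.frame(
      pH = round(ph, 2),
      NO3 = round(pmax(no3, 0.1), 2), NH4 = round(pmax(nh4, 0.1), 2),
      SO4 = round(rlnorm(n, log(20), 0.5), 2),
      K = round(rlnorm(n, log(80), 0.4), 1),
      Ca = round(rlnorm(n, log(600), 0.6), 1),
      Mg = round(rlnorm(n, log(120), 0.4), 1),
      P = round(rlnorm(n, log(25), 0.5), 1),
      As = round(rlnorm(n, log(4), 0.6), 2),
      Fe = round(rlnorm(n, log(300), 0.5), 1),
      moisture = round(runif(n, 10, 45), 1),
      organic_matter = round(runif(n, 2, 15), 1))
  })
  fh <- withr::with_seed(seed + 5L, ifelse(
    cls == "recovered", round(runif(n, 10, 35)),
    ifelse(cls == "fire_affected", round(runif(n, 0, 10)), NA)))
  sampleData <- data.frame(
    fire_class = cls, temperature = round(temps, 1), chem,
    x = round(prm$xy[, "x"], 1), y = round(prm$xy[, "y"], 1),
    fire_history_years = fh,
    row.names = colnames(cnt))

  tree <- simulateTree(meta$taxon_id, seed = seed + 6L,
                       clusterBy = meta$thermalOptimum)
  taxonomy <- .cladeTaxonomy(tree, seed = seed + 7L)

  ce <- communityExperiment(cnt, sampleData = sampleData,
                            taxonomy = taxonomy, tree = tree)
  S4Vectors::metadata(ce)$provenance$simulation <- list(
    generator = "chronosequence", seed = seed, S = S, N = N,
    classSizes = c(reference = nReference, recovered = nRecovered,
                   fire_affected = nFireAffected),
    m = m, sigmaMax = sigmaMax, priorityGroups = priorityGroups,
    boost = boost, nBoost = nBoost,
    boostedTaxa = S4Vectors::metadata(hot)$provenance$simulation$boostedTaxa)
  ce
}

.cladeTaxonomy <- function(tree, seed = 1L, nPhyla = 12,
                           fracUnassigned = 0.08, fracDeNovo = 0.15) {
  # synthetic taxonomy: phyla follow tree clades; a fraction of taxa keep
  # no phylum-level assignment (the "unidentified" bin of real surveys)
  ids <- tree$tip.label
  n <- length(ids)
  withr::with_seed(seed, {
    cl <- stats::cutree(stats::hclust(as.dist(stats::cophenetic(tree)),
                                      method = "average"),
                        k = min(nPhyla, n))
    ph <- sprintf("Phylum_%02d", cl[ids])
    unas <- sample(n, round(fracUnassigned * n))
    ph[unas] <- "unassigned"
    out <- data.frame(
      domain = "Bacteria", phylum = ph,
      class = ifelse(ph == "unassigned", "unassigned",
                     paste0(ph, "_class")),
      order = "unassigned", family = "unassigned", genus = "unassigned",
      species = "unassigned",
      is_de_novo = seq_len(n) %in%
        union(unas, sample(n, round(fracDeNovo * n))),
      row.names = ids, stringsAsFactors = FALSE)
    out
  })
}
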