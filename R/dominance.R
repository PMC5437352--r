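#' Top-k prevalent taxa per sample and their group-wide occurrence
#'
#' For each sample of the chosen fire class, ranks taxa by within-sample
#' count (ties broken lexicographically by taxon id, so rankings are
#' deterministic) and keeps the top `k`. Reports the union of top-k taxa
#' across the class; for every union member, its percent occurrence (share
#' of class samples where it is detected) and its percent share of the
#' class's total reads; and its phylum.
#'
#' @param x a `CommunityExperiment` with `fire_class` sample metadata.
#' @param group which fire class to analyse.
#' @param k list depth per sample (default 10).
#' @return list with `k`, `group`, `perSample` (named list of ranked
#'   top-k taxon vectors), `union` (character), `table` (`data.frame` with
#'   `taxon_id`, `occurrence_pct`, `cumulative_abundance_pct`, `phylum`,
#'   ordered by decreasing abundance share), and `possible` (`k` times the
#'   number of samples).
#' @export
topKAnalysis <- function(x, group = "fire_affected", k = 10) {
  cls <- fireClass(x)
  keep <- which(!is.na(cls) & cls == group)
  if (!length(keep)) stop("no samples in class '", group, "'")
  m <- counts(x)[, keep, drop = FALSE]
  perSample <- lapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]
    pos <- which(v > 0)
    if (length(pos) < k)
      warning("sample ", colnames(m)[j], " has richness ", length(pos),
              " < k = ", k, "; list truncated")
    ord <- pos[order(-v[pos], names(v)[pos])]
    names(v)[head(ord, k)]
  })
  names(perSample) <- colnames(m)
  un <- sort(unique(unlist(perSample)))
  occ <- 100 * rowMeans(m[un, , drop = FALSE] > 0)
  cum <- 100 * rowSums(m[un, , drop = FALSE]) / sum(m)
  tax <- taxonomyTable(x)
  ph <- if ("phylum" %in% colnames(tax))
    phylumOf(tax)[un] else rep(NA_character_, length(un))
  tab <- data.frame(taxon_id = un, occurrence_pct = as.numeric(occ),
                    cumulative_abundance_pct = as.numeric(cum),
                    phylum = unname(ph), row.names = NULL)
  tab <- tab[order(-tab$cumulative_abundance_pct, tab$taxon_id), ]
  rownames(tab) <- NULL
  list(k = k, group = group, perSample = perSample, union = un,
       table = tab, possible = k * ncol(m))
}

#' Phylum-level mean relative abundances per fire class
#'
#' Collapses taxa to phyla (taxa without a phylum assignment go to the
#' `"unidentified"` bin), averages per-sample relative abundances within
#' each fire class, and pools phyla whose grand-mean relative abundance is
#' below `poolBelow` into a `"Phyla Below 0.01"` bin. Per-class means sum
#' to one across bins.
#'
#' @param x a `CommunityExperiment` with taxonomy and `fire_class`.
#' @param poolBelow pooling threshold on the grand-mean relative abundance.
#' @return matrix of mean relative abundances, phyla (plus pooled bins) as
#'   rows, fire classes as columns.
#' @export
phylumSummary <- function(x, poolBelow = 0.01) {
  cls <- fireClass(x)
  P <- relAbundance(x)
  ph <- phylumOf(taxonomyTable(x))[rownames(P)]
  byPhylum <- rowsum(P, group = ph)
  grand <- rowMeans(byPhylum)
  pool <- grand < poolBelow & rownames(byPhylum) != "unidentified"
  if (any(pool)) {
    pooled <- colSums(byPhylum[pool, , drop = FALSE])
    byPhylum <- rbind(byPhylum[!pool, , drop = FALSE],
                      "Phyla Below 0.01" = pooled)
  }
  cols <- levels(droplevels(cls))
  out <- vapply(cols, function(cc)
    rowMeans(byPhylum[, which(cls == cc), drop = FALSE]),
    numeric(nrow(byPhylum)))
  out <- matrix(out, nrow = nrow(byPhylum),
                dimnames = list(rownames(byPhylum), cols))
  out[order(-rowMeans(out)), , drop = FALSE]
}

.stage <- function(name, expr, partial) {
  tryCatch(expr, error = function(e)
    stop("analysis stage '", name, "' failed: ", conditionMessage(e),
         " (completed stages: ",
         paste(names(partial), collapse = ", "), ")", call. = FALSE))
}

#' Run the full chronosequence analysis
#'
#' Orchestrates the complete community-assembly workflow on a processed
#' table: alpha diversity with pairwise class tests; Bray-Curtis and
#' UniFrac resemblances; PERMANOVA, dispersion, PCoA with environmental
#' vectors, and temperature-partialled ordination; spatial Mantel;
#' per-class Sloan neutral fits; beta-null deviations for Bray-Curtis and
#' weighted UniFrac with class comparisons, temperature trajectory and the
#' between-metric correlation; top-k dominance and phylum summaries. Any
#' stage failure aborts with the stage name while preserving completed
#' stages in the error message.
#'
#' @param x a `CommunityExperiment` with counts, tree, taxonomy and sample
#'   metadata (`fire_class`, `temperature`, chemistry, `x`/`y`).
#' @param k top-k depth for the dominance analysis.
#' @param nIter beta-null iterations.
#' @param nPermanova,nPerm permutation counts (PERMANOVA vs other tests).
#' @param seed integer seed routed to every stochastic stage.
#' @param welch use Welch's t for alpha class tests (`FALSE` for the
#'   classic equal-variance form).
#' @return a named list ("analysis bundle") with sections `alpha`,
#'   `alphaTests`, `distances`, `permanova`, `dispersion`, `ordination`,
#'   `envfit`, `partialOrdination`, `spatialMantel`, `neutral`,
#'   `betaNull`, `topK`, `phylumSummary`, `provenance`.
#' @export
runChronosequenceAnalysis <- function(x, k = 10, nIter = 199,
                                      nPermanova = 1000, nPerm = 999,
                                      seed = 1L, welch = TRUE) {
  out <- list()
  cls <- fireClass(x)
  sf <- sampleFrame(x)

  out$alpha <- .stage("alpha", alphaDiversity(x), out)
  out$alphaTests <- .stage("alphaTests", {
    combos <- utils::combn(levels(droplevels(cls)), 2)
    do.call(rbind, lapply(seq_len(ncol(combos)), function(i) {
      pr <- combos[, i]
      do.call(rbind, lapply(c("richness", "pielou", "faith_pd"),
                            function(v) {
        a <- out$alpha[[v]][cls == pr[1]]
        b <- out$alpha[[v]][cls == pr[2]]
        a <- a[is.finite(a)]; b <- b[is.finite(b)]
        if (length(a) < 2 || length(b) < 2) return(NULL)
        tt <- t.test(a, b, var.equal = !welch)
        data.frame(metric = v, class1 = pr[1], class2 = pr[2],
                   mean1 = mean(a), mean2 = mean(b),
                   t = unname(tt$statistic), p = tt$p.value,
                   row.names = NULL)
      }))
    }))
  }, out)

  out$distances <- .stage("distances", list(
    bray_curtis = brayCurtis(x),
    weighted_unifrac = uniFrac(x, weighted = TRUE, normalized = TRUE),
    weighted_unifrac_raw = uniFrac(x, weighted = TRUE, normalized = FALSE),
    unweighted_unifrac = uniFrac(x, weighted = FALSE)), out)
  dW <- out$distances$weighted_unifrac

  out$permanova <- .stage("permanova",
    permanova(dW, cls, nPerm = nPermanova, seed = seed), out)
  out$dispersion <- .stage("dispersion",
    dispersionTest(dW, cls, nPerm = nPerm, seed = seed), out)
  out$ordination <- .stage("ordination", pcoaOrdination(dW), out)
  out$envfit <- .stage("envfit", {
    num <- sf[, setdiff(colnames(sf)[vapply(sf, is.numeric, logical(1))],
                        c("x", "y", "fire_history_years")),
              drop = FALSE]
    envfitVectors(out$ordination, num, nPerm = nPerm, seed = seed)
  }, out)
  out$partialOrdination <- .stage("partialOrdination",
    partialOrdination(dW, sf$temperature), out)
  out$spatialMantel <- .stage("spatialMantel", {
    if (all(c("x", "y") %in% colnames(sf)))
      spatialMantel(dW, sf[, c("x", "y")], nPerm = nPerm, seed = seed)
    else NULL
  }, out)

  out$neutral <- .stage("neutral", {
    res <- list()
    for (cc in levels(droplevels(cls))) {
      idx <- which(cls == cc)
      res[[cc]] <- if (length(idx) >= 5) fitNeutral(x[, idx]) else
        paste0("skipped: ", length(idx), " samples (< 5)")
    }
    res
  }, out)

  out$betaNull <- .stage("betaNull", {
    bn <- list()
    for (met in c("bray_curtis", "weighted_unifrac")) {
      # whole-set deviations drive the temperature trajectory and the
      # between-metric correlation; the class contrast uses deviations
      # computed on each class's own table so one class's dominants cannot
      # distort another class's null allocation
      whole <- betaNullDeviation(x, met, nIter = nIter, seed = seed)
      perClass <- list()
      for (cc in levels(droplevels(cls))) {
        idx <- which(cls == cc)
        if (length(idx) >= 2)
          perClass[[cc]] <- betaNullDeviation(x[, idx], met,
                                              nIter = nIter, seed = seed)
      }
      classDev <- do.call(rbind, lapply(names(perClass), function(cc) {
        s <- sampleDeviations(perClass[[cc]])
        s$fire_class <- cc
        s
      }))
      groupMeans <- tapply(classDev$meanDeviation, classDev$fire_class,
                           mean)
      tests <- NULL
      if ("fire_affected" %in% classDev$fire_class) {
        tests <- do.call(rbind, lapply(
          setdiff(unique(classDev$fire_class), "fire_affected"),
          function(cc) {
            a <- classDev$meanDeviation[classDev$fire_class ==
                                          "fire_affected"]
            b <- classDev$meanDeviation[classDev$fire_class == cc]
            if (length(a) < 2 || length(b) < 2) return(NULL)
            tt <- t.test(a, b, alternative = "greater")
            wt <- suppressWarnings(wilcox.test(a, b,
                                               alternative = "greater"))
            data.frame(class1 = "fire_affected", class2 = cc,
                       welch_t = unname(tt$statistic),
                       welch_p = tt$p.value,
                       mannwhitney_p = wt$p.value, row.names = NULL)
          }))
      }
      bn[[met]] <- list(whole = whole, perClass = perClass,
                        classDeviations = classDev,
                        groupMeans = groupMeans, tests = tests,
                        trajectory = deviationByGroup(
                          whole, sf, alternative = "greater"))
    }
    dv1 <- sampleDeviations(bn$bray_curtis$whole)$meanDeviation
    dv2 <- sampleDeviations(bn$weighted_unifrac$whole)$meanDeviation
    ct <- cor.test(dv1, dv2, method = "pearson")
    bn$metricCorrelation <- list(r = unname(ct$estimate), p = ct$p.value)
    bn
  }, out)

  out$topK <- .stage("topK", {
    res <- list()
    for (cc in intersect(c("fire_affected", "recovered"),
                         levels(droplevels(cls))))
      res[[cc]] <- suppressWarnings(topKAnalysis(x, group = cc, k = k))
    res
  }, out)
  out$phylumSummary <- .stage("phylumSummary", {
    if (ncol(taxonomyTable(x))) phylumSummary(x) else NULL
  }, out)

  out$provenance <- list(
    seed = seed, k = k, nIter = nIter, nPermanova = nPermanova,
    nPerm = nPerm, nSamples = ncol(counts(x)), nTaxa = nrow(counts(x)),
    classSizes = table(cls),
    upstream = S4Vectors::metadata(x)$provenance)
  out
}
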