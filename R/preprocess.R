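#' Collapse technical replicates
#'
#' Sums the counts of replicate samples that belong to the same soil. Every
#' sample of `x` must be present in `mapping`; sample metadata for a soil
#' is taken from its first replicate.
#'
#' @param x a `CommunityExperiment`.
#' @param mapping named character vector, `names(mapping)` are replicate
#'   (sample) ids and values are soil ids.
#' @return a `CommunityExperiment` with one column per soil.
#' @export
collapseReplicates <- function(x, mapping) {
  m <- counts(x)
  unmapped <- setdiff(colnames(m), names(mapping))
  if (length(unmapped))
    stop("replicate(s) with no soil assignment: ",
         paste(unmapped, collapse = ", "))
  soil <- mapping[colnames(m)]
  collapsed <- t(rowsum(t(m), group = soil, reorder = FALSE))
  cd <- sampleFrame(x)
  keep <- !duplicated(soil)
  cdNew <- cd[keep, , drop = FALSE]
  rownames(cdNew) <- soil[keep]
  cdNew <- cdNew[colnames(collapsed), , drop = FALSE]
  out <- communityExperiment(collapsed,
                             sampleData = if (ncol(cdNew)) cdNew else NULL,
                             taxonomy = if (ncol(taxonomyTable(x)))
                               taxonomyTable(x) else NULL,
                             tree = communityTree(x))
  S4Vectors::metadata(out)$provenance$collapsedFrom <- ncol(m)
  out
}

.rarefyOne <- function(v, depth) {
  # sequential conditional hypergeometric draws = one multivariate
  # hypergeometric sample (subsampling reads without replacement)
  out <- integer(length(v))
  left <- depth
  rem <- sum(v)
  for (i in seq_along(v)) {
    if (left == 0L) break
    rem <- rem - v[i]
    k <- rhyper(1, v[i], rem, left)
    out[i] <- k
    left <- left - k
  }
  out
}

#' Rarefy to an even depth
#'
#' Subsamples each sample to `depth` reads without replacement (one
#' multivariate hypergeometric draw per sample). Taxa left with zero total
#' count are dropped by construction of the container.
#'
#' @param x a `CommunityExperiment`.
#' @param depth target per-sample depth; must not exceed any sample's
#'   total count.
#' @param seed integer seed; recorded in the provenance metadata.
#' @return a `CommunityExperiment` with every column summing to `depth`.
#' @export
rarefyTable <- function(x, depth, seed = 1L) {
  m <- counts(x)
  d <- colSums(m)
  short <- d < depth
  if (any(short))
    stop("depth ", depth, " exceeds the total count of sample(s): ",
         paste(colnames(m)[short], collapse = ", "))
  out <- withr::with_seed(seed, {
    res <- m
    for (j in seq_len(ncol(m)))
      if (d[j] > depth) res[, j] <- .rarefyOne(m[, j], depth)
    res
  })
  ce <- communityExperiment(out,
                            sampleData = if (ncol(sampleFrame(x)))
                              sampleFrame(x) else NULL,
                            taxonomy = if (ncol(taxonomyTable(x)))
                              taxonomyTable(x) else NULL,
                            tree = communityTree(x))
  S4Vectors::metadata(ce)$provenance$rarefaction <-
    list(depth = depth, seed = seed)
  ce
}

#' Remove dataset-wide singletons
#'
#' Drops taxa observed exactly once in the whole table (total count across
#' all samples equal to one); taxa seen once in each of two samples are
#' retained. Order of the remaining taxa is preserved.
#'
#' @param x a `CommunityExperiment`.
#' @export
removeSingletons <- function(x) {
  tot <- rowSums(counts(x))
  out <- x[tot > 1L, ]
  S4Vectors::metadata(out)$provenance$singletonsRemoved <- sum(tot == 1L)
  out
}

#' Standard preprocessing chain
#'
#' Collapse technical replicates (optional), rarefy to an even depth, then
#' remove dataset-wide singletons — in that fixed order. The provenance
#' record notes the requested depth and the post-singleton depths.
#'
#' @param x a `CommunityExperiment`.
#' @param replicateMap optional replicate-to-soil mapping for
#'   [collapseReplicates()].
#' @param depth rarefaction depth.
#' @param seed integer seed for the rarefaction draw.
#' @export
preprocessCommunity <- function(x, replicateMap = NULL, depth, seed = 1L) {
  if (!is.null(replicateMap)) x <- collapseReplicates(x, replicateMap)
  x <- rarefyTable(x, depth, seed = seed)
  x <- removeSingletons(x)
  S4Vectors::metadata(x)$provenance$depths <-
    list(requested = depth, afterSingletonRemoval = unname(sampleDepths(x)))
  x
}
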