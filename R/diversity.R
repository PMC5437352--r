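#' Branch decomposition of a rooted tree
#'
#' Internal workhorse for UniFrac and Faith's PD: a postorder pass over the
#' edges yields, for every branch, the set of tips descending from it
#' (tips-by-edges incidence matrix), the branch lengths, and the
#' root-to-tip distances. Computed once per tree and reused across the
#' hundreds of permuted tables of a beta-null run, where the tree is held
#' fixed.
#'
#' @noRd
.treeDecomposition <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  nt <- length(tree$tip.label)
  E <- nrow(tree$edge)
  M <- matrix(0, nt, E)
  nodeTips <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) nodeTips[[i]] <- i
  for (e in seq_len(E)) {
    child <- tree$edge[e, 2]
    parent <- tree$edge[e, 1]
    below <- nodeTips[[child]]
    M[below, e] <- 1
    nodeTips[[parent]] <- c(nodeTips[[parent]], below)
  }
  rownames(M) <- tree$tip.label
  list(tipLabels = tree$tip.label, lengths = tree$edge.length, M = M,
       tipDepth = stats::setNames(
         ape::node.depth.edgelength(tree)[seq_len(nt)], tree$tip.label))
}

.decompositionFor <- function(x) {
  tr <- communityTree(x)
  if (is.null(tr)) stop("no phylogeny attached; phylogenetic metrics abort")
  .treeDecomposition(tr)
}

#' Alpha diversity per sample
#'
#' Computes, per sample: richness (taxa with positive count), Shannon
#' entropy H' in nats, Pielou's evenness J = H'/ln(richness) (undefined at
#' richness 1, reported as `NA` with a warning), and — when a tree is
#' attached — Faith's phylogenetic diversity under the whole-tree
#' convention: the summed length of every branch with at least one observed
#' descendant, which connects the observed tips through the root.
#'
#' @param x a `CommunityExperiment` (no zero-depth samples).
#' @return `data.frame` with columns `sample_id`, `richness`, `shannon`,
#'   `pielou`, `faith_pd` (`NA` if no tree).
#' @export
alphaDiversity <- function(x) {
  m <- counts(x)
  d <- colSums(m)
  if (any(d == 0))
    stop("sample(s) with zero depth: ",
         paste(colnames(m)[d == 0], collapse = ", "))
  q <- sweep(m, 2, d, "/")
  rich <- colSums(m > 0)
  shan <- apply(q, 2, function(v) { v <- v[v > 0]; -sum(v * log(v)) })
  piel <- ifelse(rich > 1, shan / log(rich), NA_real_)
  if (any(rich == 1))
    warning("evenness undefined for sample(s) with richness 1: ",
            paste(colnames(m)[rich == 1], collapse = ", "))
  pd <- rep(NA_real_, ncol(m))
  tr <- communityTree(x)
  if (!is.null(tr)) {
    dec <- .treeDecomposition(tr)
    pres <- crossprod(dec$M, (m[dec$tipLabels, , drop = FALSE] > 0) * 1) > 0
    pd <- as.numeric(colSums(pres * dec$lengths))
  }
  data.frame(sample_id = colnames(m), richness = as.integer(rich),
             shannon = as.numeric(shan), pielou = as.numeric(piel),
             faith_pd = pd, row.names = NULL)
}

.asDistanceMatrix <- function(mat, ids, metric, normalized) {
  d <- as.dist(mat)
  attr(d, "Labels") <- ids
  attr(d, "metric") <- metric
  attr(d, "normalized") <- normalized
  d
}

#' Bray-Curtis dissimilarity
#'
#' `d(x, y) = sum|x_i - y_i| / sum(x_i + y_i)` on counts; samples are
#' assumed to share an even depth (ensured by preprocessing). Delegates to
#' [vegan::vegdist()].
#'
#' @param x a `CommunityExperiment` or taxa-by-samples matrix.
#' @return a `dist` with attributes `metric = "bray_curtis"` and
#'   `normalized = TRUE`.
#' @export
brayCurtis <- function(x) {
  m <- if (methods::is(x, "CommunityExperiment")) counts(x) else x
  d <- vegan::vegdist(t(m), method = "bray")
  attr(d, "metric") <- "bray_curtis"
  attr(d, "normalized") <- TRUE
  d
}

.unifracFromProportions <- function(P, dec, weighted, normalized) {
  # P: tips x samples relative abundances, rows ordered as dec$tipLabels
  n <- ncol(P)
  B <- crossprod(dec$M, P)            # branch proportions (edges x samples)
  l <- dec$lengths
  out <- matrix(0, n, n)
  if (weighted) {
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      num <- sum(l * abs(B[, a] - B[, b]))
      if (normalized) {
        den <- sum(dec$tipDepth * (P[, a] + P[, b]))
        num <- if (den > 0) num / den else 0
      }
      out[a, b] <- out[b, a] <- num
    }
  } else {
    pres <- B > 1e-12
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      un <- sum(l[pres[, a] | pres[, b]])
      sh <- sum(l[pres[, a] & pres[, b]])
      out[a, b] <- out[b, a] <- if (un > 0) (un - sh) / un else 0
    }
  }
  out
}

#' UniFrac distances
#'
#' Phylogenetic beta diversity from per-sample relative abundances via a
#' single branch traversal. Unweighted UniFrac is the unique-to-either
#' fraction of the branch length present in either sample (the `normalized`
#' flag has no effect and is only recorded). Weighted UniFrac in its raw
#' (non-normalized) form is `sum_b l_b |p_A(b) - p_B(b)|` over branches,
#' with `p_X(b)` the proportion of sample X's individuals descending from
#' branch b; raw values can exceed 1. The normalized form divides by
#' `sum_j d_j (p_A(j) + p_B(j))` over tips, `d_j` the root-to-tip distance,
#' bounding the result to [0, 1].
#'
#' @param x a `CommunityExperiment` with an attached tree.
#' @param weighted abundance-weighted (`TRUE`) or presence-based (`FALSE`).
#' @param normalized apply the weighted normalization.
#' @return a `dist` with attributes `metric` and `normalized`.
#' @export
uniFrac <- function(x, weighted = TRUE, normalized = TRUE) {
  dec <- .decompositionFor(x)
  P <- relAbundance(x)[dec$tipLabels, , drop = FALSE]
  mat <- .unifracFromProportions(P, dec, weighted, normalized)
  .asDistanceMatrix(mat, colnames(P),
                    metric = if (weighted) "weighted_unifrac"
                             else "unweighted_unifrac",
                    normalized = if (weighted) normalized else TRUE)
}

#' Compare two resemblance matrices
#'
#' Mantel correlation (with permutation p-value) plus the Procrustes
#' correlation between the two PCoA embeddings (permutation p-value via
#' [vegan::protest()]).
#'
#' @param d1,d2 `dist` objects over the same samples.
#' @param nPerm permutations.
#' @param seed integer seed.
#' @return list with `mantelR`, `mantelP`, `procrustesR`, `procrustesP`.
#' @export
compareResemblances <- function(d1, d2, nPerm = 999, seed = 1L) {
  stopifnot(attr(d1, "Size") == attr(d2, "Size"))
  withr::with_seed(seed, {
    mt <- vegan::mantel(d1, d2, permutations = nPerm)
    o1 <- pcoaOrdination(d1)$coordinates
    o2 <- pcoaOrdination(d2)$coordinates
    k <- min(ncol(o1), ncol(o2))
    pr <- vegan::protest(o1[, seq_len(k), drop = FALSE],
                         o2[, seq_len(k), drop = FALSE],
                         permutations = nPerm)
    list(mantelR = unname(mt$statistic), mantelP = mt$signif,
         procrustesR = unname(pr$t0), procrustesP = pr$signif,
         nPerm = nPerm)
  })
}
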