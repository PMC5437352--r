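.checkDist <- function(d) {
  if (!inherits(d, "dist")) d <- as.dist(d)
  v <- as.vector(d)
  if (any(!is.finite(v))) stop("non-finite distances")
  if (stats::sd(v) < 1e-12)
    stop("constant distance matrix; tests would be degenerate")
  d
}

#' PERMANOVA on a distance matrix
#'
#' One-way permutational multivariate analysis of variance: the total sum
#' of squared distances is partitioned into between- and within-group
#' parts, the pseudo-F ratio is referred to a permutation distribution of
#' the group labels. Delegates to [vegan::adonis2()].
#'
#' @param d `dist` over samples.
#' @param groups grouping factor (every group must have >= 2 samples).
#' @param nPerm number of permutations (1000 by convention here).
#' @param seed integer seed.
#' @return list with `pseudoF`, `r2`, `p`, `nPerm` and the underlying
#'   anova `table`.
#' @export
permanova <- function(d, groups, nPerm = 1000, seed = 1L) {
  d <- .checkDist(d)
  groups <- as.factor(groups)
  if (length(groups) != attr(d, "Size"))
    stop("groups length does not match the distance matrix")
  if (any(table(groups) < 2))
    stop("group(s) of size 1: ",
         paste(names(which(table(groups) < 2)), collapse = ", "))
  df <- data.frame(grp = groups)
  tab <- withr::with_seed(seed,
    vegan::adonis2(d ~ grp, data = df, permutations = nPerm, by = "terms"))
  list(pseudoF = tab$F[1], r2 = tab$R2[1], p = tab$`Pr(>F)`[1],
       nPerm = nPerm, table = tab)
}

#' Multivariate dispersion test
#'
#' Embeds the distance matrix by PCoA, measures each sample's distance to
#' its group's spatial median, and tests group differences in dispersion
#' by permutation ([vegan::betadisper()] with `type = "median"`, then
#' [vegan::permutest()]). Reports per-group median dispersions and their
#' pairwise differences.
#'
#' @inheritParams permanova
#' @return list with `medianDispersion` (per group), `differences`
#'   (pairwise differences of medians), `p`, `F`, and the `betadisper`
#'   object.
#' @export
dispersionTest <- function(d, groups, nPerm = 999, seed = 1L) {
  d <- .checkDist(d)
  groups <- as.factor(groups)
  bd <- vegan::betadisper(d, groups, type = "median")
  pt <- withr::with_seed(seed, vegan::permutest(bd, permutations = nPerm))
  med <- tapply(bd$distances, groups, stats::median)
  combos <- utils::combn(levels(groups), 2)
  diffs <- apply(combos, 2, function(pr) med[pr[1]] - med[pr[2]])
  names(diffs) <- apply(combos, 2, paste, collapse = " - ")
  list(medianDispersion = med, differences = diffs,
       F = pt$tab$F[1], p = pt$tab$`Pr(>F)`[1], nPerm = nPerm,
       model = bd)
}

#' Principal coordinates analysis
#'
#' Classical metric scaling ([stats::cmdscale()], the tool used for the
#' original ordinations). Axes with non-positive eigenvalues are not
#' retained as coordinates; their (absolute) eigenvalue mass is reported so
#' non-Euclidean matrices (Bray-Curtis, raw weighted UniFrac) are flagged
#' rather than silently truncated. No Cailliez correction is applied.
#'
#' @param d `dist` over samples.
#' @return list with `coordinates` (samples x axes), `eigenvalues`
#'   (positive ones), `proportionExplained`, `negativeEigenvalueMass`.
#' @export
pcoaOrdination <- function(d) {
  d <- as.dist(d)
  n <- attr(d, "Size")
  sc <- suppressWarnings(cmdscale(d, k = n - 1, eig = TRUE))
  eig <- sc$eig
  pos <- which(eig > 1e-10)
  coords <- sc$points[, seq_along(pos), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_along(pos))
  list(coordinates = coords, eigenvalues = eig[pos],
       proportionExplained = eig[pos] / sum(eig[pos]),
       negativeEigenvalueMass = sum(abs(eig[eig < 0])))
}

#' Fit environmental vectors to an ordination
#'
#' Per-variable direction in ordination space maximizing the correlation
#' with the sample scores, with squared correlation and permutation
#' p-value ([vegan::envfit()]). Constant variables are skipped with a
#' warning.
#'
#' @param ord result of [pcoaOrdination()] (or a samples-by-axes matrix).
#' @param vars `data.frame` of numeric per-sample variables.
#' @param axes how many leading axes to fit against.
#' @param nPerm permutations.
#' @param seed integer seed.
#' @return `data.frame` with `variable`, `r2`, `p` and arrow components.
#' @export
envfitVectors <- function(ord, vars, axes = 2, nPerm = 999, seed = 1L) {
  sc <- if (is.list(ord)) ord$coordinates else ord
  axes <- min(axes, ncol(sc))
  sc <- sc[, seq_len(axes), drop = FALSE]
  vars <- as.data.frame(vars)
  num <- vapply(vars, is.numeric, logical(1))
  vars <- vars[, num, drop = FALSE]
  const <- vapply(vars, function(v) stats::sd(v, na.rm = TRUE) < 1e-12,
                  logical(1))
  if (any(const)) {
    warning("skipping constant variable(s): ",
            paste(colnames(vars)[const], collapse = ", "))
    vars <- vars[, !const, drop = FALSE]
  }
  if (!ncol(vars)) stop("no usable variables")
  ef <- withr::with_seed(seed,
    vegan::envfit(sc, vars, permutations = nPerm, na.rm = TRUE))
  arrows <- ef$vectors$arrows
  data.frame(variable = rownames(arrows),
             r2 = unname(ef$vectors$r), p = unname(ef$vectors$pvals),
             arrows, row.names = NULL)
}

#' Ordination after removing one variable's influence
#'
#' Distance-based partial ordination: the conditioning variable is partialled
#' out of the distance matrix and the residual structure is re-ordinated
#' ([vegan::capscale()] with a `Condition()` term).
#'
#' @param d `dist` over samples.
#' @param condition numeric conditioning variable (e.g. temperature).
#' @return list with `coordinates`, `eigenvalues`, `proportionExplained`
#'   of the residual (conditioned) ordination and the `capscale` model.
#' @export
partialOrdination <- function(d, condition) {
  d <- .checkDist(d)
  if (length(condition) != attr(d, "Size"))
    stop("condition length does not match the distance matrix")
  df <- data.frame(cond = condition)
  mod <- vegan::capscale(d ~ 1 + Condition(cond), data = df)
  sc <- vegan::scores(mod, display = "sites",
                      choices = seq_along(mod$CA$eig))
  eig <- mod$CA$eig
  pos <- eig[eig > 0]
  list(coordinates = sc, eigenvalues = eig,
       proportionExplained = pos / sum(pos), model = mod)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal entries with a p-value from
#' joint row/column permutations of one matrix ([vegan::mantel()]).
#'
#' @param d1,d2 `dist` objects over the same samples.
#' @param nPerm permutations (999 by convention).
#' @param seed integer seed.
#' @return list with `r`, `p`, `nPerm`.
#' @export
mantelTest <- function(d1, d2, nPerm = 999, seed = 1L) {
  stopifnot(attr(as.dist(d1), "Size") == attr(as.dist(d2), "Size"))
  mt <- withr::with_seed(seed,
    vegan::mantel(as.dist(d1), as.dist(d2), permutations = nPerm))
  list(r = unname(mt$statistic), p = mt$signif, nPerm = nPerm)
}

#' @rdname mantelTest
#' @param d community distance matrix.
#' @param xy two-column matrix of planar coordinates (finite).
#' @export
spatialMantel <- function(d, xy, nPerm = 999, seed = 1L) {
  xy <- as.matrix(xy)
  if (any(!is.finite(xy))) stop("non-finite coordinates")
  mantelTest(d, dist(xy), nPerm = nPerm, seed = seed)
}
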