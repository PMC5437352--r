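#' Container for a community count table with phylogeny and sample metadata
#'
#' `CommunityExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment] and is the central data
#' object of the package. The `"counts"` assay holds non-negative integer
#' counts with taxa as rows and samples as columns; per-sample metadata
#' (fire classification, temperature, soil chemistry, coordinates) live in
#' `colData`, per-taxon taxonomy in `rowData`, and a rooted phylogeny whose
#' tip set equals the taxon set is stored in `metadata(x)$tree`.
#'
#' Validity requires: unique taxon and sample identifiers, integer-valued
#' non-negative finite counts, and (when a tree is present) exact agreement
#' between tree tips and taxon identifiers.
#'
#' @seealso [communityExperiment()] for the validating constructor.
#' @export
setClass("CommunityExperiment",
         contains = "SummarizedExperiment")

setValidity("CommunityExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  m <- SummarizedExperiment::assay(object, "counts")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "counts must have taxon (row) and sample (column) names")
  if (anyDuplicated(rownames(m)))
    msg <- c(msg, "duplicate taxon identifiers")
  if (anyDuplicated(colnames(m)))
    msg <- c(msg, "duplicate sample identifiers")
  if (any(!is.finite(m)))
    msg <- c(msg, "counts contain NA or non-finite values")
  else {
    if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
    if (max(abs(m - round(m))) > 1e-9)
      msg <- c(msg, "counts must be integer-valued")
  }
  tr <- S4Vectors::metadata(object)$tree
  if (!is.null(tr)) {
    if (!inherits(tr, "phylo")) msg <- c(msg, "tree must be a 'phylo' object")
    else if (!setequal(tr$tip.label, rownames(m)))
      msg <- c(msg, "tree tip labels must match taxon identifiers exactly")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CommunityExperiment
#'
#' Validates a taxa-by-samples count matrix, attaches optional sample
#' metadata, taxonomy and a rooted phylogeny, and reconciles the taxon set
#' with the tree tips. Taxa with zero total count are dropped (a table in
#' which every taxon has been observed at least once is an invariant of the
#' container). Taxa missing from the tree abort construction unless
#' `prune = TRUE`, in which case they are dropped and counted in the
#' provenance record: silent pruning would quietly change UniFrac
#' denominators, so it is opt-in.
#'
#' @param counts numeric matrix of non-negative integers, taxa as rows,
#'   samples as columns, both dimensions named.
#' @param sampleData `data.frame` (or `DataFrame`) of per-sample metadata,
#'   rows matching `colnames(counts)`.
#' @param taxonomy `data.frame` of per-taxon annotation, rows matching
#'   `rownames(counts)`.
#' @param tree rooted `phylo` object whose tips cover the taxa.
#' @param prune drop table taxa absent from the tree (and tree tips absent
#'   from the table) instead of aborting.
#' @return a validated [CommunityExperiment-class] object.
#' @examples
#' m <- matrix(c(5, 3, 0, 0, 3, 7), nrow = 3,
#'             dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
#' ce <- communityExperiment(m)
#' sampleDepths(ce)
#' @export
communityExperiment <- function(counts, sampleData = NULL, taxonomy = NULL,
                                tree = NULL, prune = FALSE) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have taxon (row) and sample (column) names")
  if (any(!is.finite(counts)))
    stop("counts contain NA or non-finite values")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (max(abs(counts - round(counts))) > 1e-9)
    stop("counts must be integer-valued")
  storage.mode(counts) <- "integer"

  dropped <- character()
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    dropped <- rownames(counts)[tot == 0]
    counts <- counts[tot > 0, , drop = FALSE]
  }

  prunedFromTree <- character()
  if (!is.null(tree)) {
    if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
    if (!ape::is.rooted(tree)) stop("tree must be rooted")
    missingTips <- setdiff(rownames(counts), tree$tip.label)
    if (length(missingTips)) {
      if (!prune)
        stop(length(missingTips), " taxa are absent from the tree ",
             "(e.g. '", missingTips[1], "'); pass prune = TRUE to drop them")
      prunedFromTree <- missingTips
      counts <- counts[setdiff(rownames(counts), missingTips), , drop = FALSE]
    }
    extraTips <- setdiff(tree$tip.label, rownames(counts))
    if (length(extraTips))
      tree <- ape::keep.tip(tree, rownames(counts))
    if (any(tree$edge.length < 0)) stop("negative branch lengths")
  }

  cd <- if (is.null(sampleData)) {
    S4Vectors::DataFrame(row.names = colnames(counts))
  } else {
    sampleData <- as.data.frame(sampleData)
    if (!all(colnames(counts) %in% rownames(sampleData)))
      stop("sampleData is missing rows for some samples")
    S4Vectors::DataFrame(sampleData[colnames(counts), , drop = FALSE])
  }
  rd <- if (is.null(taxonomy)) {
    S4Vectors::DataFrame(row.names = rownames(counts))
  } else {
    taxonomy <- as.data.frame(taxonomy)
    if (!all(rownames(counts) %in% rownames(taxonomy)))
      stop("taxonomy is missing rows for some taxa")
    S4Vectors::DataFrame(taxonomy[rownames(counts), , drop = FALSE])
  }

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd, rowData = rd)
  obj <- methods::new("CommunityExperiment", se)
  S4Vectors::metadata(obj)$tree <- tree
  S4Vectors::metadata(obj)$provenance <- list(
    droppedEmptyTaxa = dropped,
    prunedFromTree = prunedFromTree)
  methods::validObject(obj)
  obj
}

#' Fitted Sloan neutral community model
#'
#' Holds the immigration estimate on both the canonical beta-approximation
#' scale (`m`) and the equivalent per-event urn immigration probability
#' (`mMoran`), the goodness of fit, and the per-taxon occurrence records
#' with their 95% neutral envelope and partition.
#'
#' @slot m numeric, immigration estimate on the Sloan beta scale.
#' @slot mMoran numeric, equivalent per-event immigration probability of the
#'   discrete urn process (same stationary beta parameter).
#' @slot N integer, local community size (per-sample sequencing depth).
#' @slot nSamples integer, number of local communities fitted.
#' @slot rSquared numeric, 1 - SSR/SST about the mean observed frequency
#'   (may be negative; `NA` when SST degenerates).
#' @slot detectionLimit numeric, relative-abundance detection limit.
#' @slot boundary logical, whether the least-squares search hit a bound.
#' @slot taxa `data.frame` with columns `taxon_id`, `p`, `fObs`, `fPred`,
#'   `envelopeLo`, `envelopeHi`, `partition`.
#' @export
setClass("NeutralFit",
         representation(m = "numeric", mMoran = "numeric", N = "integer",
                        nSamples = "integer", rSquared = "numeric",
                        detectionLimit = "numeric", boundary = "logical",
                        taxa = "data.frame"))

setValidity("NeutralFit", function(object) {
  msg <- character()
  if (length(object@m) != 1 || object@m <= 0 || object@m > 1)
    msg <- c(msg, "m must be a single value in (0, 1]")
  if (!is.na(object@rSquared) && object@rSquared > 1)
    msg <- c(msg, "rSquared cannot exceed 1")
  need <- c("taxon_id", "p", "fObs", "fPred", "envelopeLo", "envelopeHi",
            "partition")
  if (!all(need %in% colnames(object@taxa)))
    msg <- c(msg, "taxa table is missing required columns")
  if (length(msg)) msg else TRUE
})

#' Beta-null deviation result
#'
#' Per-pair observed distances, their permuted-null expectation, and the
#' resulting deviations, together with per-sample summaries.
#'
#' @slot metric character, `"bray_curtis"` or `"weighted_unifrac"`.
#' @slot normalized logical, normalization flag of the underlying metric.
#' @slot nIterations integer, number of null iterations.
#' @slot scope character, `"all_pairs"` or `"within_group"`.
#' @slot pairs `data.frame` with `sample1`, `sample2`, `dObs`, `nullMean`,
#'   `nullSd`, `deviation` (= `dObs - nullMean`), `ses`
#'   (= `deviation / nullSd`, `NA` when `nullSd` is 0).
#' @slot samples `data.frame` with `sample_id`, `meanDeviation`, `meanSes`,
#'   `nPairs`.
#' @slot seed integer seed used for the null draws.
#' @export
setClass("BetaNullResult",
         representation(metric = "character", normalized = "logical",
                        nIterations = "integer", scope = "character",
                        pairs = "data.frame", samples = "data.frame",
                        seed = "integer"))

setValidity("BetaNullResult", function(object) {
  msg <- character()
  p <- object@pairs
  if (any(p$nullSd < -1e-12, na.rm = TRUE))
    msg <- c(msg, "null standard deviations must be non-negative")
  if (any(abs(p$deviation - (p$dObs - p$nullMean)) > 1e-10, na.rm = TRUE))
    msg <- c(msg, "deviation must equal dObs - nullMean")
  if (length(msg)) msg else TRUE
})

#' @describeIn CommunityExperiment-class retrieve the integer count matrix
#'   (taxa as rows, samples as columns).
#' @param x a `CommunityExperiment`.
#' @export
counts <- function(x) {
  stopifnot(methods::is(x, "CommunityExperiment"))
  SummarizedExperiment::assay(x, "counts")
}

#' @describeIn CommunityExperiment-class per-sample relative abundances
#'   (columns renormalized to sum to one).
#' @export
relAbundance <- function(x) {
  m <- counts(x)
  d <- colSums(m)
  if (any(d == 0)) stop("sample(s) with zero depth: ",
                        paste(colnames(m)[d == 0], collapse = ", "))
  sweep(m, 2, d, "/")
}

#' @describeIn CommunityExperiment-class per-sample total counts.
#' @export
sampleDepths <- function(x) colSums(counts(x))

#' @describeIn CommunityExperiment-class the attached rooted phylogeny (or
#'   `NULL`).
#' @export
communityTree <- function(x) S4Vectors::metadata(x)$tree

#' @describeIn CommunityExperiment-class replace the attached phylogeny
#'   (revalidates the object).
#' @param value a rooted `phylo` object covering the taxa.
#' @export
`communityTree<-` <- function(x, value) {
  S4Vectors::metadata(x)$tree <- value
  methods::validObject(x)
  x
}

#' @describeIn CommunityExperiment-class sample metadata as a `data.frame`.
#' @export
sampleFrame <- function(x)
  as.data.frame(SummarizedExperiment::colData(x))

#' @describeIn CommunityExperiment-class taxonomy as a `data.frame`.
#' @export
taxonomyTable <- function(x)
  as.data.frame(SummarizedExperiment::rowData(x))

#' @describeIn CommunityExperiment-class fire classification factor
#'   (levels `fire_affected`, `recovered`, `reference`).
#' @export
fireClass <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"fire_class" %in% colnames(cd))
    stop("no 'fire_class' column in the sample metadata")
  factor(cd$fire_class,
         levels = c("fire_affected", "recovered", "reference"))
}

#' Subset a CommunityExperiment
#'
#' Standard `[i, j]` subsetting; the attached tree is pruned to the retained
#' taxa so that the tip set always matches the table.
#'
#' @param x a `CommunityExperiment`.
#' @param i,j taxon and sample indices.
#' @param ... ignored.
#' @param drop ignored (always `FALSE`).
#' @export
setMethod("[", c("CommunityExperiment", "ANY", "ANY", "ANY"),
          function(x, i, j, ..., drop = FALSE) {
  out <- methods::callNextMethod()
  tr <- S4Vectors::metadata(out)$tree
  if (!is.null(tr) && !setequal(tr$tip.label, rownames(out)))
    S4Vectors::metadata(out)$tree <- ape::keep.tip(tr, rownames(out))
  out
})

setMethod("show", "CommunityExperiment", function(object) {
  m <- counts(object)
  cat("CommunityExperiment:", nrow(m), "taxa x", ncol(m), "samples\n")
  d <- colSums(m)
  cat("  depth:", if (length(unique(d)) == 1L) paste(d[1], "(even)")
      else paste0(min(d), "-", max(d)), "\n")
  cat("  tree:", if (is.null(communityTree(object))) "absent" else
      paste0("rooted, ", length(communityTree(object)$tip.label), " tips"),
      "\n")
  cd <- SummarizedExperiment::colData(object)
  if ("fire_class" %in% colnames(cd))
    print(table(fireClass(object)))
  invisible(NULL)
})

setMethod("show", "NeutralFit", function(object) {
  cat("Sloan neutral community model fit\n")
  cat(sprintf("  m = %.4g (Sloan scale); urn-equivalent m = %.4g\n",
              object@m, object@mMoran))
  cat(sprintf("  N = %d, samples = %d, R^2 = %.3f%s\n", object@N,
              object@nSamples, object@rSquared,
              if (object@boundary) " [boundary hit]" else ""))
  print(table(object@taxa$partition))
  invisible(NULL)
})

setMethod("show", "BetaNullResult", function(object) {
  cat("Beta-null deviation (", object@metric, ", ",
      object@nIterations, " iterations, scope = ", object@scope, ")\n",
      sep = "")
  cat(sprintf("  mean per-sample deviation: %.4f\n",
              mean(object@samples$meanDeviation)))
  invisible(NULL)
})

#' @describeIn NeutralFit-class per-taxon records of a fit.
#' @param fit a `NeutralFit`.
#' @export
neutralTaxa <- function(fit) {
  stopifnot(methods::is(fit, "NeutralFit"))
  fit@taxa
}

#' @describeIn BetaNullResult-class per-pair records.
#' @param x a `BetaNullResult`.
#' @export
pairDeviations <- function(x) {
  stopifnot(methods::is(x, "BetaNullResult"))
  x@pairs
}

#' @describeIn BetaNullResult-class per-sample mean deviations.
#' @export
sampleDeviations <- function(x) {
  stopifnot(methods::is(x, "BetaNullResult"))
  x@samples
}
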