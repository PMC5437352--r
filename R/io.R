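#' Read a community count table
#'
#' Reads a taxa-by-samples count table from tab-separated text (taxa as
#' rows, first column the taxon identifier) or from a dense-JSON BIOM file.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom_json"`.
#' @return a [CommunityExperiment-class] (counts only).
#' @export
readCommunityTable <- function(path, format = c("tsv", "biom_json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- tryCatch(
      read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
      error = function(e) stop("malformed community table: ",
                               conditionMessage(e)))
    if (nrow(df) == 0 || ncol(df) < 2)
      stop("malformed community table: no counts found")
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids)) stop("duplicate taxon identifiers")
    if (anyDuplicated(colnames(df)[-1])) stop("duplicate sample identifiers")
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric count cells")
    rownames(m) <- ids
  } else {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
  }
  if (any(is.na(m))) stop("NA count cells")
  if (any(m < 0)) stop("negative count cells")
  if (max(abs(m - round(m))) > 1e-9) stop("non-integer count cells")
  communityExperiment(m)
}

#' Write a community count table as TSV
#'
#' Inverse of [readCommunityTable()] for the TSV dialect; round-trips
#' counts exactly.
#'
#' @param x a `CommunityExperiment` or a taxa-by-samples matrix.
#' @param path output file path.
#' @export
writeCommunityTable <- function(x, path) {
  m <- if (methods::is(x, "CommunityExperiment")) counts(x) else x
  df <- data.frame(taxon_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny from newick
#'
#' @param path newick file.
#' @param rootAtMidpoint if the tree is unrooted, midpoint-root it instead
#'   of aborting.
#' @return a rooted `phylo` object with non-negative branch lengths.
#' @export
readTree <- function(path, rootAtMidpoint = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("malformed newick file")
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  if (any(tr$edge.length < 0)) stop("negative branch lengths")
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels")
  if (!ape::is.rooted(tr)) {
    if (!rootAtMidpoint)
      stop("tree is unrooted; pass rootAtMidpoint = TRUE to midpoint-root")
    tr <- phangorn::midpoint(tr)
  }
  tr
}

#' @rdname readTree
#' @param tree a `phylo` object.
#' @export
writeTree <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}

#' Read per-sample metadata
#'
#' Tab-separated, first column the sample identifier. A `fire_class`
#' column with values in `fire_affected`/`recovered`/`reference` is
#' required; `temperature` (degrees C) must be finite when present, and
#' planar coordinates `x`/`y` must be finite when present.
#'
#' @param path TSV file.
#' @return `data.frame` with sample identifiers as row names.
#' @export
readSampleData <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty metadata file")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate sample identifiers")
  df <- df[, -1, drop = FALSE]
  rownames(df) <- ids
  if (!"fire_class" %in% colnames(df))
    stop("metadata is missing the required 'fire_class' column")
  ok <- c("fire_affected", "recovered", "reference")
  bad <- setdiff(unique(df$fire_class), ok)
  if (length(bad))
    stop("unknown fire_class value(s): ", paste(bad, collapse = ", "))
  if ("temperature" %in% colnames(df) && any(!is.finite(df$temperature)))
    stop("non-finite temperature")
  for (cc in intersect(c("x", "y"), colnames(df)))
    if (any(!is.finite(df[[cc]]))) stop("non-finite coordinate: ", cc)
  df
}

#' @rdname readSampleData
#' @param df sample metadata `data.frame` (sample ids as row names).
#' @export
writeSampleData <- function(df, path) {
  out <- data.frame(sample_id = rownames(df), df, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
            "species")

#' Read a taxonomy table
#'
#' Tab-separated, first column the taxon identifier, followed either by a
#' single semicolon-delimited `taxonomy` column or by the seven rank
#' columns `domain` ... `species`. Missing ranks are filled with
#' `"unassigned"`. An optional logical `is_de_novo` column flags taxa with
#' no reference-database match; absent, it defaults to `FALSE`.
#'
#' @param path TSV file.
#' @return `data.frame` with the seven rank columns plus `is_de_novo`,
#'   taxon identifiers as row names.
#' @export
readTaxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty taxonomy file")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate taxon identifiers")
  df <- df[, -1, drop = FALSE]
  if ("taxonomy" %in% colnames(df)) {
    parts <- strsplit(as.character(df$taxonomy), ";")
    ranks <- t(vapply(parts, function(p) {
      p <- trimws(p)
      p <- p[nzchar(p)]
      length(p) <- length(.RANKS)
      p[is.na(p)] <- "unassigned"
      p
    }, character(length(.RANKS))))
    colnames(ranks) <- .RANKS
    out <- as.data.frame(ranks, stringsAsFactors = FALSE)
  } else {
    miss <- setdiff(.RANKS, colnames(df))
    out <- as.data.frame(df[, intersect(.RANKS, colnames(df)), drop = FALSE])
    for (r in miss) out[[r]] <- "unassigned"
    out <- out[, .RANKS]
  }
  out$is_de_novo <- if ("is_de_novo" %in% colnames(df))
    as.logical(df$is_de_novo) else FALSE
  rownames(out) <- ids
  out
}

#' @rdname readTaxonomy
#' @param df taxonomy `data.frame` (taxon ids as row names).
#' @export
writeTaxonomy <- function(df, path) {
  out <- data.frame(taxon_id = rownames(df), df, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Phylum labels with an explicit sentinel
#'
#' Extracts the phylum rank for each taxon; empty, `NA` or `"unassigned"`
#' phyla are mapped to the `"unidentified"` sentinel so extraction never
#' fails.
#'
#' @param taxonomy a taxonomy `data.frame` as returned by [readTaxonomy()].
#' @return character vector of phylum labels named by taxon.
#' @export
phylumOf <- function(taxonomy) {
  ph <- if ("phylum" %in% colnames(taxonomy))
    as.character(taxonomy$phylum) else rep(NA_character_, nrow(taxonomy))
  ph[is.na(ph) | !nzchar(ph) | tolower(ph) == "unassigned"] <- "unidentified"
  names(ph) <- rownames(taxonomy)
  ph
}
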