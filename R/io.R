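#' Read a taxa-by-samples or samples-by-taxa abundance table
#'
#' Reads a delimited community table (TSV or CSV; header row, first column =
#' id) and returns a validated [community_matrix()] in the package's canonical
#' samples x taxa orientation. The orientation of the file must be declared
#' explicitly -- it is never guessed from the dimensions, because silent
#' transposition is a classic microbiome-pipeline bug.
#'
#' @param path path to the table.
#' @param orientation `"taxa_rows"` if rows are taxa and columns are samples
#'   (the common OTU-table layout), `"samples_rows"` for the transpose.
#' @param sep field separator; defaults to `","` for `.csv` files and tab
#'   otherwise.
#' @return a `community_matrix`.
#' @seealso [write_community_table()], [validate_inputs()]
#' @export
read_community_table <- function(path,
                                 orientation = c("taxa_rows", "samples_rows"),
                                 sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "\"")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric abundances in ", path)
  rownames(m) <- ids
  if (orientation == "taxa_rows") m <- t(m)
  community_matrix(m)
}

#' Write a community matrix to a delimited file
#'
#' @param comm community matrix (samples x taxa).
#' @param path output path; `.csv` selects comma separation, otherwise tab.
#' @param orientation layout to write (see [read_community_table()]).
#' @param id_column header of the first (identifier) column.
#' @export
write_community_table <- function(comm, path,
                                  orientation = c("taxa_rows", "samples_rows"),
                                  id_column = "id") {
  orientation <- match.arg(orientation)
  m <- unclass(comm)
  attr(m, "group") <- NULL
  if (orientation == "taxa_rows") m <- t(m)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny with branch lengths from a newick file
#'
#' @param path newick file (or a length-1 newick string).
#' @return an [ape::phylo] tree, rooted, with nonnegative branch lengths.
#' @export
read_phylogeny <- function(path) {
  tree <- if (file.exists(path)) ape::read.tree(path) else ape::read.tree(text = path)
  if (is.null(tree)) stop("unparseable newick in ", path)
  check_phylogeny(tree)
  tree
}

#' @keywords internal
check_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylogeny")
  if (is.null(tree$edge.length))
    stop("phylogeny has no branch lengths; patristic distances are undefined")
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop("phylogeny has missing or negative branch lengths")
  if (!ape::is.rooted(tree)) stop("phylogeny must be rooted")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  invisible(tree)
}

#' Write a phylogeny to newick
#' @param tree an `ape::phylo` object.
#' @param path output path.
#' @export
write_phylogeny <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read sample metadata (coordinates + environmental features)
#'
#' The file must contain columns `sample_id`, `x`, `y`; any further numeric
#' columns are treated as environmental features.
#'
#' @param path TSV/CSV path.
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return data.frame with one row per sample.
#' @export
read_sample_metadata <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "x", "y")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("metadata lacks required column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (anyDuplicated(colnames(df)))
    stop("duplicate feature names in metadata")
  if (!is.numeric(df$x) || !is.numeric(df$y) || anyNA(df$x) || anyNA(df$y))
    stop("metadata coordinates x/y must be numeric and complete")
  df
}

#' Write sample metadata
#' @param meta data.frame with `sample_id`, `x`, `y`, and feature columns.
#' @param path output path; `.csv` selects comma separation, otherwise tab.
#' @export
write_sample_metadata <- function(meta, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(meta, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cross-validate a community table, phylogeny, and metadata
#'
#' Confirms that every taxon in the community table is a tip of the tree and
#' that every sample has a metadata row. Tips absent from the table are
#' reported as ignorable extras (they are pruned by downstream steps); taxa
#' absent from the tree block the phylogenetic stage; samples absent from the
#' metadata block only the spatial stage.
#'
#' @param comm community matrix.
#' @param tree phylogeny (optional).
#' @param meta metadata data.frame (optional).
#' @param strict raise an error on any blocking discrepancy.
#' @return an object of class `"assembly_validation"` listing discrepancies.
#' @export
validate_inputs <- function(comm, tree = NULL, meta = NULL, strict = FALSE) {
  taxa <- colnames(comm)
  samples <- rownames(comm)
  rep <- list(
    missing_from_tree = character(0), extra_tips = character(0),
    missing_from_metadata = character(0), extra_metadata = character(0)
  )
  if (!is.null(tree)) {
    check_phylogeny(tree)
    rep$missing_from_tree <- sort(setdiff(taxa, tree$tip.label))
    rep$extra_tips <- sort(setdiff(tree$tip.label, taxa))
  }
  if (!is.null(meta)) {
    rep$missing_from_metadata <- sort(setdiff(samples, meta$sample_id))
    rep$extra_metadata <- sort(setdiff(meta$sample_id, samples))
  }
  rep$phylo_ok <- length(rep$missing_from_tree) == 0L
  rep$spatial_ok <- length(rep$missing_from_metadata) == 0L
  class(rep) <- "assembly_validation"
  if (strict) {
    if (!rep$phylo_ok)
      stop("taxa absent from the phylogeny: ",
           paste(rep$missing_from_tree, collapse = ", "))
    if (!is.null(meta) && !rep$spatial_ok)
      stop("samples absent from the metadata: ",
           paste(rep$missing_from_metadata, collapse = ", "))
  }
  rep
}

#' @export
print.assembly_validation <- function(x, ...) {
  cat("input validation\n")
  cat("  taxa missing from tree (blocking): ",
      if (length(x$missing_from_tree)) paste(x$missing_from_tree, collapse = ", ") else "none", "\n", sep = "")
  cat("  extra tree tips (pruned): ",
      if (length(x$extra_tips)) paste(x$extra_tips, collapse = ", ") else "none", "\n", sep = "")
  cat("  samples missing from metadata (blocks spatial stage): ",
      if (length(x$missing_from_metadata)) paste(x$missing_from_metadata, collapse = ", ") else "none", "\n", sep = "")
  invisible(x)
}
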