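#' Construct a validated community matrix
#'
#' A community matrix holds nonnegative taxon abundances (counts or relative
#' abundances) with samples as rows and taxa as columns. This is the canonical
#' internal orientation used throughout the package; file readers accept either
#' orientation via an explicit flag (see [read_community_table()]).
#'
#' @param x numeric matrix, samples x taxa, with unique row (sample) and
#'   column (taxon) names.
#' @param group optional per-sample grouping label (e.g., a geologic formation
#'   or metacommunity id); recycled checks require one value per sample.
#'
#' @return a matrix of class `"community_matrix"` with a `"group"` attribute.
#'
#' @details Validation enforces the container's invariants: no negative or
#'   missing entries, no sample whose total abundance is zero, and unique
#'   sample/taxon identifiers. Violations produce errors naming the offending
#'   sample, taxon, or cell.
#'
#' @examples
#' m <- matrix(rpois(12, 5) + 1, 3, 4,
#'             dimnames = list(paste0("S", 1:3), paste0("t", 1:4)))
#' comm <- community_matrix(m)
#' relative_abundance(comm)
#' @export
community_matrix <- function(x, group = NULL) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("`x` must be a numeric matrix (samples x taxa)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("`x` must have sample (row) and taxon (column) names")
  if (anyDuplicated(rownames(x)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate taxon ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1L, ]
    stop("missing abundance at sample '", rownames(x)[bad[1L]],
         "', taxon '", colnames(x)[bad[2L]], "'")
  }
  if (any(x < 0)) {
    bad <- which(x < 0, arr.ind = TRUE)[1L, ]
    stop("negative abundance at sample '", rownames(x)[bad[1L]],
         "', taxon '", colnames(x)[bad[2L]], "'")
  }
  tot <- rowSums(x)
  if (any(tot == 0))
    stop("sample with total abundance 0: ",
         paste(rownames(x)[tot == 0], collapse = ", "))
  if (!is.null(group)) {
    if (length(group) != nrow(x))
      stop("`group` must supply one label per sample")
    group <- as.character(group)
    names(group) <- rownames(x)
  }
  structure(x, class = c("community_matrix", class(x)), group = group)
}

#' Row-normalized relative abundances
#'
#' @param comm a community matrix (or any samples x taxa numeric matrix).
#' @return matrix of the same shape whose rows sum to 1.
#' @export
relative_abundance <- function(comm) {
  m <- unclass(comm)
  attr(m, "group") <- NULL
  sweep(m, 1L, rowSums(m), "/")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat("community_matrix: ", nrow(x), " samples x ", ncol(x), " taxa\n", sep = "")
  g <- attr(x, "group")
  if (!is.null(g))
    cat("groups: ", paste(unique(g), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @keywords internal
sample_groups <- function(comm, groups = NULL) {
  if (is.null(groups)) groups <- attr(comm, "group")
  if (is.null(groups)) {
    groups <- rep("all", nrow(comm))
    names(groups) <- rownames(comm)
  }
  if (is.null(names(groups))) names(groups) <- rownames(comm)
  groups[rownames(comm)]
}
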