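#' Spatial eigenvector basis (PCNM / Moran's eigenvector maps)
#'
#' Builds spatial eigenfunctions from the pairwise Euclidean distances of
#' sampling locations: distances above a truncation threshold (by default the
#' longest edge of the minimum spanning tree) are replaced by four times the
#' threshold, the truncated matrix is double-centered (Gower transform) and
#' eigen-decomposed, and the axes with positive eigenvalues are retained,
#' scaled by the square root of their eigenvalues. The resulting axes are
#' mutually orthogonal, centered, and describe spatial structure from broad
#' (first axes) to fine scales.
#'
#' @param coords two-column matrix or data.frame of planar coordinates; row
#'   names (or a `sample_id` column) identify the locations.
#' @param truncation optional truncation distance; `NULL` uses the minimum
#'   spanning tree default.
#' @return object of class `"spatial_eigenbasis"`: `ids`, `threshold`,
#'   `values` (positive eigenvalues, descending), `vectors` (locations x
#'   axes, columns named `PCNM1`, `PCNM2`, ...).
#' @export
pcnm_axes <- function(coords, truncation = NULL) {
  if (is.data.frame(coords)) {
    ids <- if ("sample_id" %in% colnames(coords)) as.character(coords$sample_id)
           else rownames(coords)
    coords <- as.matrix(coords[, intersect(c("x", "y"), colnames(coords)),
                               drop = FALSE])
  } else {
    ids <- rownames(coords)
  }
  if (!is.numeric(coords) || ncol(coords) < 1L)
    stop("coords must be numeric planar coordinates")
  if (nrow(coords) < 3L) stop("need at least 3 locations")
  if (is.null(ids)) ids <- paste0("loc", seq_len(nrow(coords)))
  d <- stats::dist(coords)
  if (any(d == 0))
    warning("duplicate coordinates: distinct samples at distance 0")
  p <- if (is.null(truncation)) vegan::pcnm(d) else vegan::pcnm(d, threshold = truncation)
  if (is.null(p$vectors) || !length(p$values) || max(p$values) <= 0)
    stop("degenerate configuration: no positive spatial eigenvalues")
  pos <- p$values[p$values > 0]
  # vegan returns unit-norm eigenvectors; scale each axis by sqrt(eigenvalue)
  v <- sweep(p$vectors, 2L, sqrt(pos[seq_len(ncol(p$vectors))]), "*")
  rownames(v) <- ids
  colnames(v) <- paste0("PCNM", seq_len(ncol(v)))
  structure(list(ids = ids, threshold = p$threshold, values = pos,
                 vectors = v),
            class = "spatial_eigenbasis")
}

#' @export
print.spatial_eigenbasis <- function(x, ...) {
  cat("spatial_eigenbasis: ", length(x$ids), " locations, ",
      ncol(x$vectors), " positive axes (truncation ", format(x$threshold),
      ")\n", sep = "")
  invisible(x)
}

#' Priority-based collinearity filter for candidate explanatory variables
#'
#' Ranks candidates -- all environmental features ahead of all spatial axes,
#' and within each class by descending absolute Pearson correlation with the
#' response -- then scans in rank order, dropping any candidate significantly
#' correlated (two-sided test at `alpha`) with an already-retained one. This
#' removes strong covariation while favoring measured environmental features
#' over purely spatial descriptors.
#'
#' @param X data.frame of candidate variables.
#' @param y response vector (a process-influence fraction).
#' @param env_vars,spatial_vars names of the environmental and spatial
#'   candidates (must partition the columns of `X` that are considered).
#' @param alpha significance level of the pairwise correlation test.
#' @return character vector of retained variable names, in priority order.
#' @export
priority_filter <- function(X, y, env_vars, spatial_vars = character(0),
                            alpha = 0.05) {
  vars <- c(env_vars, spatial_vars)
  if (!length(vars)) stop("no candidate variables supplied")
  miss <- setdiff(vars, colnames(X))
  if (length(miss)) stop("candidates absent from X: ", paste(miss, collapse = ", "))
  const <- vars[vapply(vars, function(v) stats::sd(X[[v]]) == 0, logical(1))]
  if (length(const)) {
    warning("dropping zero-variance candidate(s): ", paste(const, collapse = ", "))
    env_vars <- setdiff(env_vars, const)
    spatial_vars <- setdiff(spatial_vars, const)
  }
  rank_by_cor <- function(v) {
    if (!length(v)) return(character(0))
    r <- vapply(v, function(nm) abs(stats::cor(X[[nm]], y)), numeric(1))
    v[order(-r)]
  }
  ordered <- c(rank_by_cor(env_vars), rank_by_cor(spatial_vars))
  retained <- character(0)
  for (v in ordered) {
    clash <- any(vapply(retained, function(r)
      stats::cor.test(X[[v]], X[[r]])$p.value < alpha, logical(1)))
    if (!clash) retained <- c(retained, v)
  }
  retained
}

#' @keywords internal
#' Small-sample-corrected AIC for an OLS fit.
#' k counts the fitted slopes plus the intercept plus the error variance.
aicc_ols <- function(n, rss, n_predictors) {
  k <- n_predictors + 2
  if (n - k - 1 <= 0) return(Inf)
  # floor RSS so noiseless fits stay finite and compare via the 2k penalty
  n * log(max(rss, 1e-300) / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Exhaustive all-subsets OLS regression selected by AICc
#'
#' Fits an ordinary-least-squares model for every non-empty subset of at most
#' `max_vars` candidate variables and returns the subset with the lowest
#' small-sample-corrected Akaike Information Criterion,
#' \deqn{AICc = n \ln(RSS/n) + 2k + 2k(k+1)/(n-k-1),}
#' with `k` = number of predictors + intercept + error variance. Exact ties
#' are broken toward fewer variables, then lexicographically. Variable
#' importance is ranked by absolute standardized coefficient
#' (`coef * sd(x) / sd(y)`).
#'
#' @param X data.frame of candidate variables (at most 20).
#' @param y response vector.
#' @param max_vars largest subset size considered (default 7).
#' @param response_name label stored with the model.
#' @return object of class `"selected_model"`: `variables`, `coefficients`
#'   (named, including `(Intercept)`), `r_squared`, `aicc`,
#'   `std_coefficients`, `n`.
#' @export
best_subsets_aicc <- function(X, y, max_vars = 7, response_name = "response") {
  X <- as.data.frame(X)
  n <- length(y)
  if (nrow(X) != n) stop("X and y disagree on the number of samples")
  if (ncol(X) > 20)
    stop("more than 20 candidate variables; exhaustive search refused -- ",
         "filter candidates first (see priority_filter)")
  if (n <= max_vars + 2) stop("need more samples than max_vars + 2")
  vars <- sort(colnames(X))
  best <- NULL
  for (k in seq_len(min(max_vars, length(vars)))) {
    for (subset in utils::combn(vars, k, simplify = FALSE)) {
      mm <- cbind(`(Intercept)` = 1, as.matrix(X[, subset, drop = FALSE]))
      fit <- stats::lm.fit(mm, y)
      if (fit$rank < ncol(mm)) {
        message("skipping singular subset: ", paste(subset, collapse = " + "))
        next
      }
      rss <- sum(fit$residuals^2)
      a <- aicc_ols(n, rss, k)
      better <- is.null(best) || a < best$aicc - 1e-12 ||
        (abs(a - best$aicc) <= 1e-12 &&
           (k < length(best$variables) ||
              (k == length(best$variables) &&
                 paste(subset, collapse = ",") <
                 paste(best$variables, collapse = ","))))
      if (better) {
        tss <- sum((y - mean(y))^2)
        sds <- vapply(subset, function(v) stats::sd(X[[v]]), numeric(1))
        best <- list(response = response_name, variables = subset,
                     coefficients = fit$coefficients,
                     r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                     aicc = a,
                     std_coefficients = fit$coefficients[subset] * sds /
                       stats::sd(y),
                     n = n)
      }
    }
  }
  if (is.null(best)) stop("no estimable subset found")
  structure(best, class = "selected_model")
}

#' @export
print.selected_model <- function(x, ...) {
  cat("selected_model for ", x$response, ": ",
      paste(x$variables, collapse = " + "), "\n  AICc = ", format(x$aicc),
      ", R^2 = ", format(x$r_squared), ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Predict process influences at arbitrary locations
#'
#' Evaluates a [best_subsets_aicc()] model on a design table that must
#' contain every selected variable (environmental features plus any spatial
#' axes, which should be computed once over the full location set so that
#' training rows are a subset of the design). Predictions of fraction
#' responses are clipped to `[0, 1]`; clipped locations are flagged.
#'
#' @param model a `selected_model`.
#' @param newdata data.frame with the model's variables at every location.
#' @param clip clip predictions into `[0, 1]` (default TRUE).
#' @return numeric vector of predictions with attribute `"clipped"` (logical
#'   vector marking locations where clipping occurred).
#' @export
predict_map <- function(model, newdata, clip = TRUE) {
  miss <- setdiff(model$variables, colnames(newdata))
  if (length(miss))
    stop("missing feature(s) at prediction locations: ",
         paste(miss, collapse = ", "))
  mm <- cbind(1, as.matrix(newdata[, model$variables, drop = FALSE]))
  pred <- drop(mm %*% model$coefficients)
  clipped <- rep(FALSE, length(pred))
  if (clip) {
    clipped <- pred < 0 | pred > 1
    pred <- pmin(1, pmax(0, pred))
  }
  attr(pred, "clipped") <- clipped
  pred
}

#' @export
predict.selected_model <- function(object, newdata, clip = TRUE, ...) {
  predict_map(object, newdata, clip = clip)
}

#' Piecewise-linear interpolation of point values onto a regular grid
#'
#' Triangulates the data locations and interpolates barycentrically within
#' each triangle; grid nodes outside the convex hull of the data are masked
#' (`in_hull = FALSE`, value `NA`). Values that are a globally linear
#' function of the coordinates are reproduced exactly at interior nodes.
#'
#' @param points two-column matrix/data.frame of locations (`x`, `y`).
#' @param values numeric vector of values at the locations.
#' @param resolution number of grid nodes per axis (default 100), or a
#'   length-2 vector `(nx, ny)`.
#' @return data.frame of class `"grid_prediction"` with columns `x`, `y`,
#'   `value`, `in_hull`.
#' @export
interpolate_grid <- function(points, values, resolution = 100) {
  points <- as.matrix(as.data.frame(points)[, 1:2])
  if (nrow(points) < 3L) stop("need at least 3 locations")
  if (length(values) != nrow(points)) stop("one value per location required")
  if (qr(sweep(points, 2L, colMeans(points)))$rank < 2L)
    stop("degenerate geometry: all locations are collinear")
  res <- rep_len(resolution, 2L)
  xo <- seq(min(points[, 1]), max(points[, 1]), length.out = res[1L])
  yo <- seq(min(points[, 2]), max(points[, 2]), length.out = res[2L])
  g <- interp::interp(x = points[, 1], y = points[, 2], z = values,
                      xo = xo, yo = yo, method = "linear",
                      duplicate = "error")
  out <- data.frame(x = rep(g$x, times = length(g$y)),
                    y = rep(g$y, each = length(g$x)),
                    value = as.vector(g$z))
  out$in_hull <- !is.na(out$value)
  class(out) <- c("grid_prediction", "data.frame")
  out
}

#' Model and map one process influence across a landscape
#'
#' Convenience driver for the spatial stage: builds PCNM axes over all
#' locations in `meta`, filters candidates with [priority_filter()] against
#' the process fractions of the sampled locations, selects the AICc-best
#' model with [best_subsets_aicc()], predicts at every location with
#' [predict_map()], and grids the predictions with [interpolate_grid()].
#'
#' @param fractions data.frame from [run_inference()] (`$fractions`).
#' @param meta metadata for all locations (`sample_id`, `x`, `y`, features);
#'   rows without community data are still used as prediction locations.
#' @param process one of [process_categories()].
#' @param env_vars names of the environmental feature columns in `meta`.
#' @param max_vars largest model size (default 7).
#' @param alpha collinearity-filter significance level.
#' @param resolution interpolation grid resolution.
#' @return list with `model`, `predictions` (data.frame `sample_id`, `x`,
#'   `y`, `value`), and `grid` (a [interpolate_grid()] result).
#' @export
map_process_influence <- function(fractions, meta, process, env_vars,
                                  max_vars = 7, alpha = 0.05,
                                  resolution = 100) {
  process <- match.arg(process, process_categories())
  basis <- pcnm_axes(meta)
  design <- cbind(meta, as.data.frame(basis$vectors))
  rownames(design) <- meta$sample_id
  train <- design[match(fractions$sample_id, meta$sample_id), , drop = FALSE]
  if (anyNA(train$x))
    stop("samples absent from the metadata: ",
         paste(fractions$sample_id[is.na(train$x)], collapse = ", "))
  y <- fractions[[process]]
  keep <- priority_filter(train, y, env_vars = env_vars,
                          spatial_vars = colnames(basis$vectors),
                          alpha = alpha)
  model <- best_subsets_aicc(train[, keep, drop = FALSE], y,
                             max_vars = max_vars, response_name = process)
  pred <- predict_map(model, design)
  grid <- interpolate_grid(design[, c("x", "y")], as.numeric(pred),
                           resolution = resolution)
  list(model = model,
       predictions = data.frame(sample_id = meta$sample_id,
                                x = meta$x, y = meta$y,
                                value = as.numeric(pred),
                                clipped = attr(pred, "clipped"),
                                stringsAsFactors = FALSE),
       grid = grid)
}
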