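#' Build a strain-profile feature matrix
#'
#' Joins a strain x variant cell-quota matrix (see [quota_matrix()]) with
#' per-strain mortality rates into the feature matrix used for ordination:
#' per-variant quotas, total amphidinol quota and brine-shrimp mortality
#' rate, one row per strain.
#'
#' @param quotas Numeric matrix with strain row names (variants and
#'   `total_AM` columns).
#' @param toxicity `data.frame` from [assay_reduce()].
#' @return Numeric matrix with an added `mortality_rate` column; strains
#'   missing a mortality rate get `NA`.
#' @export
build_strain_profile <- function(quotas, toxicity) {
  stopifnot(is.matrix(quotas), !is.null(rownames(quotas)))
  rate <- toxicity$mortality_rate_per_day[
    match(rownames(quotas), toxicity$strain_id)]
  cbind(quotas, mortality_rate = rate)
}

#' Scale and log-transform a feature matrix
#'
#' Per feature: min-max scaling to `[0, 1]` (constant features map to 0),
#' then the `ln(x + 1)` transform, so every entry lies in `[0, ln 2]`.
#' This puts cell quotas (spanning orders of magnitude) and mortality rates
#' on a common scale before computing distances.
#'
#' @param X Non-negative numeric matrix (strains x features).
#' @return Transformed matrix of the same shape.
#' @export
scale_transform <- function(X) {
  X <- as.matrix(X)
  if (!nrow(X) || !ncol(X)) stop("empty profile matrix")
  if (any(X < 0, na.rm = TRUE)) stop("profile matrix must be non-negative")
  out <- apply(X, 2, function(col) {
    rng <- range(col)
    if (rng[2] > rng[1]) (col - rng[1]) / (rng[2] - rng[1]) else col * 0
  })
  out <- matrix(out, nrow = nrow(X), dimnames = dimnames(X))
  log1p(out)
}

#' Principal coordinate analysis of strain profiles
#'
#' Classical metric scaling (`stats::cmdscale`) of the pairwise distance
#' matrix between strain profiles. Euclidean distance is the default (the
#' conventional input for classical scaling, under which PCoA scores equal
#' centered principal-component scores); Bray-Curtis is available through
#' the vegan package. Negative eigenvalues are truncated to zero for the
#' percent-variability computation and axes are ordered by eigenvalue.
#'
#' @param X Scaled profile matrix (>= 3 strains; no non-finite entries).
#' @param distance `"euclidean"` or `"bray"`.
#' @return An object of class `am_pcoa`: list with `scores` (strains x
#'   axes, positive-eigenvalue axes only), `eigenvalues` (all, descending)
#'   and `pct_variability` (per axis, summing to 100 over positive axes).
#' @export
pcoa_profiles <- function(X, distance = c("euclidean", "bray")) {
  distance <- match.arg(distance)
  X <- as.matrix(X)
  if (nrow(X) < 3) stop("PCoA needs at least 3 strains")
  bad <- which(!is.finite(X), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite value in profile matrix at strain '",
         rownames(X)[bad[1, 1]] %||% bad[1, 1], "', feature '",
         colnames(X)[bad[1, 2]] %||% bad[1, 2], "'")
  d <- if (distance == "euclidean") {
    dist(X)
  } else {
    if (!requireNamespace("vegan", quietly = TRUE))
      stop("Bray-Curtis distance requires the vegan package")
    vegan::vegdist(X, method = "bray")
  }
  n <- nrow(X)
  fit <- suppressWarnings(cmdscale(d, k = n - 1, eig = TRUE))
  eig <- sort(fit$eig, decreasing = TRUE)
  pos <- fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig), 1)
  scores <- fit$points[, seq_len(min(sum(pos), ncol(fit$points))),
                       drop = FALSE]
  rownames(scores) <- rownames(X)
  colnames(scores) <- paste0("PCo", seq_len(ncol(scores)))
  pct <- 100 * pmax(eig, 0) / sum(pmax(eig, 0))
  structure(list(scores = scores, eigenvalues = eig,
                 pct_variability = pct, distance = distance),
            class = "am_pcoa")
}

#' @export
print.am_pcoa <- function(x, ...) {
  cat(sprintf("<am_pcoa> %d strains, %d axes (%s distance)\n",
              nrow(x$scores), ncol(x$scores), x$distance))
  k <- min(3, length(x$pct_variability))
  cat("  variability: ",
      paste(sprintf("%.1f%%", x$pct_variability[seq_len(k)]),
            collapse = ", "), " ...\n", sep = "")
  invisible(x)
}

#' Hierarchical clustering of ordination scores
#'
#' Agglomerative clustering (default complete linkage) of the Euclidean
#' distances between PCoA score rows, cut at `k` clusters. Labels are
#' renumbered `1..k` by decreasing cluster size (ties broken by the first
#' strain index in each cluster), so labelling is deterministic.
#'
#' @param scores Numeric score matrix (e.g. `pcoa_profiles(X)$scores`) or
#'   an `am_pcoa` object.
#' @param k Number of clusters, `1 <= k <=` number of strains.
#' @param linkage Linkage method passed to [stats::hclust()].
#' @return Integer vector of cluster labels, named by strain.
#' @export
cluster_scores <- function(scores, k, linkage = "complete") {
  if (inherits(scores, "am_pcoa")) scores <- scores$scores
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k must be <= number of strains (", n, ")")
  hc <- hclust(dist(scores), method = linkage)
  raw <- cutree(hc, k = k)
  sizes <- tabulate(raw, nbins = k)
  first <- vapply(seq_len(k), function(g) min(which(raw == g)), integer(1))
  ord <- order(-sizes, first)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  out <- relabel[raw]
  names(out) <- rownames(scores)
  out
}

#' Ordinate and cluster a strain panel in one call
#'
#' Convenience wrapper: [scale_transform()] then [pcoa_profiles()] then
#' [cluster_scores()].
#'
#' @param profile Raw (unscaled) strain-profile matrix, e.g. from
#'   [build_strain_profile()].
#' @param k Number of clusters (default 3, the number of main chemotype
#'   groups typically resolved).
#' @param distance,linkage Passed through.
#' @return `am_pcoa` object with an added `cluster_labels` element.
#' @export
profile_strains <- function(profile, k = 3,
                            distance = c("euclidean", "bray"),
                            linkage = "complete") {
  ord <- pcoa_profiles(scale_transform(profile), distance)
  ord$cluster_labels <- cluster_scores(ord$scores, k, linkage)
  ord
}
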