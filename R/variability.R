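# Trial-to-trial dispersion: pairwise distances, single-linkage trees,
# cluster-content curves and the C_1/3 statistic.

#' Cosine distance between two feature vectors
#'
#' \code{1 - cos(alpha)} between the vectors; for non-negative features the
#' result lies in [0, 1]. Degenerate cases: two zero vectors are at distance
#' 0, a zero vector and a non-zero vector at distance 1.
#'
#' @param u,v numeric vectors of equal length.
#' @export
cosine_distance <- function(u, v) {
  if (length(u) != length(v))
    stop("feature vectors differ in length: ", length(u), " vs ", length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 && nv == 0) return(0)
  if (nu == 0 || nv == 0) return(1)
  max(0, 1 - sum(u * v) / (nu * nv))
}

#' Pairwise distance matrix of feature vectors
#'
#' @param x numeric matrix, one feature vector per row.
#' @param metric \code{"cosine"} (default, \code{1 - cos}),
#'   \code{"correlation"}, \code{"euclidean"} or \code{"levenshtein"} (edit
#'   distance on the digit strings; intended for binary words).
#' @return Symmetric matrix with zero diagonal and a \code{"metric"}
#'   attribute.
#' @export
pairwise_distances <- function(x, metric = c("cosine", "correlation",
                                             "euclidean", "levenshtein")) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 feature vectors")
  d <- switch(metric,
    cosine = {
      nrm <- sqrt(rowSums(x^2))
      zero <- nrm == 0
      xs <- x / ifelse(nrm == 0, 1, nrm)
      d <- 1 - tcrossprod(xs)
      d[zero, ] <- 1; d[, zero] <- 1
      d[zero, zero] <- 0
      d
    },
    correlation = 1 - stats::cor(t(x)),
    euclidean = as.matrix(stats::dist(x)),
    levenshtein = {
      s <- apply(x, 1L, paste0, collapse = "")
      matrix(as.numeric(utils::adist(s)), nrow(x), nrow(x))
    })
  d <- pmax(d, 0)
  d[d < 1e-12] <- 0   # zap numerical fuzz so identical rows are at 0
  d <- (d + t(d)) / 2
  diag(d) <- 0
  attr(d, "metric") <- metric
  d
}

#' Single-linkage dendrogram of a distance matrix
#'
#' Agglomerative clustering in which, at every iteration, the distance
#' between two clusters is the most proximal (minimum) pairwise distance
#' between their members; merge heights are non-decreasing.
#'
#' @param d symmetric distance matrix (e.g. from
#'   \code{\link{pairwise_distances}}).
#' @return A \code{\link[stats]{hclust}} object.
#' @export
single_linkage_tree <- function(d) {
  stats::hclust(stats::as.dist(d), method = "single")
}

#' Cluster-content curve of a dendrogram
#'
#' Counts the clusters obtained by cutting the tree at each distance cutoff
#' (merges at heights up to and including the cutoff are applied). The count
#' is non-increasing in the cutoff and reaches 1 at the maximum linkage
#' height.
#'
#' @param tree an \code{\link[stats]{hclust}} object.
#' @param cutoffs ascending cutoff values; default: \code{n_grid} evenly
#'   spaced values from 0 to the maximum merge height.
#' @param n_grid grid resolution for the default cutoffs (default 200).
#' @param at_merges logical; use the sorted set of merge heights as cutoffs
#'   instead of a grid.
#' @return Object of class \code{"cluster_content_curve"}: list with
#'   \code{cutoffs}, \code{n_clusters} and \code{n_leaves}.
#' @export
cluster_content_curve <- function(tree, cutoffs = NULL, n_grid = 200L,
                                  at_merges = FALSE) {
  h <- tree$height
  n_leaves <- length(h) + 1L
  if (is.null(cutoffs)) {
    cutoffs <- if (at_merges) sort(unique(h))
               else seq(0, max(h), length.out = n_grid)
  } else if (is.unsorted(cutoffs)) stop("cutoffs must be ascending")
  n_clusters <- vapply(cutoffs,
                       function(co) n_leaves - sum(h <= co), numeric(1))
  structure(list(cutoffs = cutoffs, n_clusters = n_clusters,
                 n_leaves = n_leaves),
            class = "cluster_content_curve")
}

#' The C 1/3 cluster-content statistic
#'
#' The smallest distance cutoff at which the number of clusters drops
#' strictly below one third of its maximum (the number of responses),
#' located on the curve's cutoff grid. Small values mean the responses
#' collapse into few clusters already at small distances, i.e. low
#' trial-to-trial variability.
#'
#' @param curve a \code{\link{cluster_content_curve}}.
#' @return List with \code{value} (the cutoff) and \code{dropped} (FALSE if
#'   the curve never falls below a third within the grid, in which case the
#'   maximum cutoff is returned).
#' @export
c_one_third <- function(curve) {
  stopifnot(inherits(curve, "cluster_content_curve"))
  thr <- curve$n_leaves / 3
  idx <- which(curve$n_clusters < thr)
  if (length(idx))
    list(value = curve$cutoffs[idx[1]], dropped = TRUE)
  else
    list(value = max(curve$cutoffs), dropped = FALSE)
}

#' Paired condition comparison of C 1/3 values
#'
#' Forms the per-network (or per-electrode) differences control - blocked
#' and tests them with the one-sided paired signed-rank test (right tail by
#' default: blocking inhibition shrinks C 1/3).
#'
#' @param control,blocked numeric vectors of paired C 1/3 values.
#' @param tail test tail, see \code{\link{paired_signed_rank}}.
#' @return List with \code{delta}, \code{n}, \code{n_positive} and
#'   \code{p_value}.
#' @export
compare_conditions <- function(control, blocked, tail = "right") {
  if (length(control) != length(blocked))
    stop("conditions are not paired: ", length(control), " vs ",
         length(blocked))
  if (length(control) < 2L) stop("need at least 2 pairs")
  delta <- control - blocked
  list(delta = delta, n = length(delta), n_positive = sum(delta > 0),
       p_value = paired_signed_rank(delta, tail = tail)$p_value)
}
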