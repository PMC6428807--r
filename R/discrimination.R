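# Stimulus separability: unsupervised contrast, supervised SVM
# classification and cross-condition transfer.

#' Contrast between responses to two stimulation sources
#'
#' \code{(D_out - D_in) / (D_out + D_in)}, where \code{D_in} is the sum of
#' pairwise distances between responses to the same source (pooled over both
#' sources of the pair by default) and \code{D_out} the sum over all
#' cross-source pairs. Ranges over [-1, 1]: 1 means identical responses
#' within a source and distinct ones across sources; 0 means no separation.
#' The index only needs the ground-truth stimulus labels, not a classifier.
#'
#' @param x numeric feature matrix, one response per row.
#' @param labels source label per row (exactly two distinct values).
#' @param metric distance metric, see \code{\link{pairwise_distances}}.
#' @param pool_intra pool the intra-source sums of both sources into one
#'   \code{D_in} (default); otherwise a per-source breakdown is returned too.
#' @param use_means normalize the sums by their pair counts (default FALSE:
#'   plain sums).
#' @return List with \code{contrast}, \code{d_in}, \code{d_out},
#'   \code{degenerate} (TRUE when both sums are zero and the contrast is set
#'   to 0), and \code{d_in_by_source} when \code{pool_intra = FALSE}.
#' @export
source_contrast <- function(x, labels, metric = "cosine",
                            pool_intra = TRUE, use_means = FALSE) {
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2L)
    stop("contrast is defined for exactly 2 sources, got ", length(lv))
  tab <- table(labels)
  if (any(tab < 2L))
    stop("each source needs >= 2 responses; counts: ",
         paste(tab, collapse = ", "))
  d <- pairwise_distances(x, metric = metric)
  same <- outer(labels, labels, "==")
  ut <- upper.tri(d)
  d_in <- sum(d[ut & same])
  d_out <- sum(d[ut & !same])
  if (use_means) {
    n1 <- tab[[1]]; n2 <- tab[[2]]
    d_in <- d_in / (choose(n1, 2) + choose(n2, 2))
    d_out <- d_out / (n1 * n2)
  }
  degenerate <- (d_in + d_out) == 0
  res <- list(
    contrast = if (degenerate) 0 else (d_out - d_in) / (d_out + d_in),
    d_in = d_in, d_out = d_out, degenerate = degenerate)
  if (!pool_intra)
    res$d_in_by_source <- vapply(lv, function(l) {
      m <- labels == l
      sum(d[ut & outer(m, m, "&")])
    }, numeric(1))
  res
}

# median-heuristic RBF bandwidth: gamma = 1 / (2 * median squared distance)
rbf_gamma <- function(x) {
  d2 <- stats::dist(x)^2
  m <- stats::median(d2[d2 > 0])
  if (!length(m) || !is.finite(m) || m == 0) 1 / ncol(x) else 1 / (2 * m)
}

svm_fit <- function(x, y, kernel) {
  if (kernel == "rbf")
    e1071::svm(x, y, kernel = "radial", gamma = rbf_gamma(x), cost = 1,
               scale = FALSE)
  else
    e1071::svm(x, y, kernel = "linear", cost = 1, scale = FALSE)
}

# restrict population-rate traces to the 10-70 ms segment (bins are 1 ms
# starting at 10 ms, so columns 1..61)
rate_segment <- function(x, from_ms = 10, to_ms = 70, start_ms = 10) {
  x[, (from_ms - start_ms + 1L):(to_ms - start_ms + 1L), drop = FALSE]
}

#' Supervised classification of stimulation sources
#'
#' Support-vector classification of single-trial response features by
#' stimulation source. Each repetition draws a stratified random 50/50
#' train/test split, fits the SVM (one-vs-one voting for more than two
#' sources) and records test accuracy; the mean and SD over repetitions are
#' returned. The radial-basis kernel uses a median-heuristic bandwidth and
#' regularization constant 1. For population-rate features with the
#' radial-basis kernel only the 10--70 ms segment of the trace is used.
#'
#' @param x feature matrix, one response per row.
#' @param labels source label per row (>= 2 classes, >= 2 members each).
#' @param kernel \code{"rbf"} (Gaussian radial basis, default) or
#'   \code{"linear"}.
#' @param n_reps number of random splits (default 50).
#' @param holdout validation fraction (default 0.5).
#' @param feature optional feature tag; \code{"rate"} triggers the 10--70 ms
#'   restriction under the RBF kernel.
#' @return List with \code{accuracy} (per repetition), \code{mean},
#'   \code{sd}, \code{chance} (1 / number of classes) and \code{kernel}.
#'   Uses the current RNG state for the splits.
#' @export
classify_sources <- function(x, labels, kernel = c("rbf", "linear"),
                             n_reps = 50L, holdout = 0.5, feature = NULL) {
  kernel <- match.arg(kernel)
  y <- factor(labels)
  if (nlevels(y) < 2L) stop("need >= 2 classes")
  if (any(table(y) < 2L)) stop("every class needs >= 2 members")
  if (identical(feature, "rate") && kernel == "rbf")
    x <- rate_segment(x)
  acc <- vapply(seq_len(n_reps), function(rep) {
    test_idx <- unlist(lapply(split(seq_along(y), y), function(ix)
      sample(ix, floor(length(ix) * holdout))), use.names = FALSE)
    fit <- svm_fit(x[-test_idx, , drop = FALSE], y[-test_idx], kernel)
    mean(stats::predict(fit, x[test_idx, , drop = FALSE]) == y[test_idx])
  }, numeric(1))
  list(accuracy = acc, mean = mean(acc), sd = stats::sd(acc),
       chance = 1 / nlevels(y), kernel = kernel)
}

#' Cross-condition transfer classification
#'
#' Fits the classifier entirely on one condition's responses and evaluates
#' it entirely on the other condition's, with no leakage in either
#' direction. Transfer accuracy above chance indicates that the two
#' conditions' response patterns carry shared stimulus information.
#'
#' @param train_x,train_labels training condition features and source labels.
#' @param test_x,test_labels held-out condition features and labels.
#' @param kernel \code{"rbf"} or \code{"linear"}.
#' @param feature optional feature tag (see \code{\link{classify_sources}}).
#' @return List with \code{accuracy}, \code{chance} and \code{n_test}.
#' @export
cross_condition_classify <- function(train_x, train_labels, test_x,
                                     test_labels,
                                     kernel = c("rbf", "linear"),
                                     feature = NULL) {
  kernel <- match.arg(kernel)
  if (ncol(train_x) != ncol(test_x))
    stop("feature dimensionality differs between conditions: ",
         ncol(train_x), " vs ", ncol(test_x))
  if (identical(feature, "rate") && kernel == "rbf") {
    train_x <- rate_segment(train_x)
    test_x <- rate_segment(test_x)
  }
  lev <- sort(unique(as.character(c(train_labels, test_labels))))
  y_tr <- factor(as.character(train_labels), levels = lev)
  y_te <- factor(as.character(test_labels), levels = lev)
  fit <- svm_fit(train_x, y_tr, kernel)
  list(accuracy = mean(stats::predict(fit, test_x) == y_te),
       chance = 1 / length(lev), n_test = length(y_te))
}

#' Paired condition comparison of discrimination values
#'
#' Signed-rank comparison of per-source-pair contrasts or accuracies across
#' the two conditions, on the differences control - blocked. The left tail
#' (default) asks whether blocking inhibition increases the value.
#'
#' @param control,blocked paired numeric vectors (one entry per source pair).
#' @param tail test tail (default \code{"left"}).
#' @return List with \code{delta}, \code{n}, \code{n_blocked_higher} and
#'   \code{p_value}.
#' @export
discrimination_summary <- function(control, blocked, tail = "left") {
  if (length(control) != length(blocked))
    stop("conditions are not paired")
  if (length(control) < 2L) stop("need at least 2 pairs")
  delta <- control - blocked
  list(delta = delta, n = length(delta),
       n_blocked_higher = sum(delta < 0),
       p_value = paired_signed_rank(delta, tail = tail)$p_value)
}
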