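# Isolation-forest anomaly scoring and threshold-based cleaning.
#
# The forest is implemented from scratch following the path-length
# formulation: each tree recursively splits a subsample at a uniform random
# cut on a uniform random feature; the anomaly score of a point is
# s(x) = 2^(-E[h(x)] / c(psi)), where h(x) is its isolation depth (plus the
# average-path correction at truncated nodes) and c(psi) is the average
# unsuccessful-search path length of a binary search tree of size psi.

# average unsuccessful-search path length c(n)
if_c <- function(n) {
  ifelse(n <= 1, 0,
         ifelse(n == 2, 1,
                2 * (log(n - 1) + 0.5772156649) - 2 * (n - 1) / n))
}

# Grow one isolation tree on X[idx, ]; nodes stored in a flat list.
grow_itree <- function(X, idx, depth_limit) {
  nodes <- list()
  new_node <- function(node) {
    nodes[[length(nodes) + 1L]] <<- node
    length(nodes)
  }
  build <- function(idx, depth) {
    n <- length(idx)
    if (n <= 1L || depth >= depth_limit) {
      return(new_node(list(leaf = TRUE, size = n)))
    }
    sub <- X[idx, , drop = FALSE]
    rng <- apply(sub, 2L, range)
    splittable <- which(rng[2L, ] > rng[1L, ])
    if (!length(splittable)) {
      return(new_node(list(leaf = TRUE, size = n)))
    }
    feat <- splittable[sample.int(length(splittable), 1L)]
    cut <- stats::runif(1L, rng[1L, feat], rng[2L, feat])
    left <- idx[sub[, feat] < cut]
    right <- idx[sub[, feat] >= cut]
    if (!length(left) || !length(right)) {
      return(new_node(list(leaf = TRUE, size = n)))
    }
    lid <- build(left, depth + 1L)
    rid <- build(right, depth + 1L)
    new_node(list(leaf = FALSE, feat = feat, cut = cut,
                  left = lid, right = rid))
  }
  root <- build(idx, 0L)
  list(nodes = nodes, root = root)
}

# Depths of all rows of X in one tree, by recursive descent on index sets.
itree_depths <- function(tree, X) {
  depths <- numeric(nrow(X))
  walk <- function(node_id, idx, depth) {
    node <- tree$nodes[[node_id]]
    if (node$leaf) {
      depths[idx] <<- depth + if_c(node$size)
      return(invisible())
    }
    go_left <- X[idx, node$feat] < node$cut
    if (any(go_left)) walk(node$left, idx[go_left], depth + 1L)
    if (any(!go_left)) walk(node$right, idx[!go_left], depth + 1L)
  }
  walk(tree$root, seq_len(nrow(X)), 0L)
  depths
}

#' Isolation-forest anomaly scores
#'
#' @param pc_scores n x k numeric matrix (n >= 10, k >= 2) of PC scores.
#' @param n_trees number of isolation trees.
#' @param subsample per-tree subsample size (clamped to n with a warning
#'   when larger).
#' @param seed integer seed; scores are deterministic under a fixed seed.
#' @return Numeric vector of anomaly scores in \[0, 1\], higher = more
#'   anomalous.
#' @export
isolation_scores <- function(pc_scores, n_trees = 100L, subsample = 256L,
                             seed = 1L) {
  X <- as.matrix(pc_scores)
  n <- nrow(X)
  if (n < 10L) stop("isolation forest needs n >= 10")
  if (ncol(X) < 2L) stop("isolation forest needs >= 2 dimensions")
  if (subsample > n) {
    warning("subsample (", subsample, ") larger than n (", n, "); clamping")
    subsample <- n
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  depth_limit <- ceiling(log2(subsample))
  total_depth <- numeric(n)
  for (t in seq_len(n_trees)) {
    idx <- sample.int(n, subsample)
    tree <- grow_itree(X, idx, depth_limit)
    total_depth <- total_depth + itree_depths(tree, X)
  }
  2^(-(total_depth / n_trees) / if_c(subsample))
}

#' Per-class isolation-forest scores
#'
#' Scores each class's rows against their own class only. Pooled scoring
#' lets large between-class differences (size, depth) mask within-class
#' anomalies -- and risks flagging unusually variable species wholesale --
#' so the cleaning stage scores per class by default.
#'
#' @param pc_scores n x k matrix of PC scores.
#' @param classes class label per row.
#' @inheritParams isolation_scores
#' @return Numeric score vector aligned with the input rows.
#' @export
isolation_scores_by_class <- function(pc_scores, classes, n_trees = 100L,
                                      subsample = 256L, seed = 1L) {
  X <- as.matrix(pc_scores)
  classes <- as.character(classes)
  if (length(classes) != nrow(X)) stop("one class label per row required")
  out <- numeric(nrow(X))
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    out[idx] <- suppressWarnings(
      isolation_scores(X[idx, , drop = FALSE], n_trees = n_trees,
                       subsample = min(subsample, length(idx)), seed = seed))
  }
  out
}

#' Filter anomalies from a dataset
#'
#' Removes every specimen whose anomaly score is at or above `threshold`.
#' Per-class removal counts are recorded, and a warning is raised when a
#' single class loses more than 20% of its members (the over-classification
#' concern: unusually variable species must not be wholesale removed).
#'
#' @param dataset a `pit_dataset` or data.frame of feature rows with a
#'   `taxon` column.
#' @param scores anomaly scores from [isolation_scores()], one per
#'   specimen.
#' @param threshold removal threshold in (0, 1); the reference band is
#'   0.625-0.700 and the package default is its midpoint, 0.65.
#' @return List with `dataset` (cleaned) and `report` (an
#'   `anomaly_report`: `scores`, `threshold`, `removed_ids`,
#'   `removed_fraction`, `per_class_removed`).
#' @export
filter_anomalies <- function(dataset, scores, threshold = 0.65) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  is_ds <- inherits(dataset, "pit_dataset")
  n <- if (is_ds) length(dataset$id) else nrow(dataset)
  if (length(scores) != n) stop("one score per specimen required")
  ids <- if (is_ds) dataset$id else as.character(dataset$specimen_id)
  taxa <- if (is_ds) dataset$taxon else as.character(dataset$taxon)
  removed <- scores >= threshold
  if (all(removed)) stop("threshold ", threshold, " removes every specimen")
  per_class <- table(factor(taxa)[removed])
  class_sizes <- table(factor(taxa))
  frac_class <- as.numeric(per_class) / as.numeric(class_sizes[names(per_class)])
  heavy <- names(per_class)[frac_class > 0.2]
  if (length(heavy)) {
    warning("classes losing > 20% of members to anomaly filtering: ",
            paste(heavy, collapse = ", "))
  }
  cleaned <- if (is_ds) subset_dataset(dataset, !removed)
             else dataset[!removed, , drop = FALSE]
  report <- structure(
    list(scores = scores, threshold = threshold,
         removed_ids = ids[removed], removed_fraction = mean(removed),
         per_class_removed = per_class),
    class = "anomaly_report")
  list(dataset = cleaned, report = report)
}

#' @export
print.anomaly_report <- function(x, ...) {
  cat(sprintf("<anomaly_report> threshold %.3f: removed %d/%d (%.1f%%)\n",
              x$threshold, length(x$removed_ids), length(x$scores),
              100 * x$removed_fraction))
  if (length(x$removed_ids)) print(x$per_class_removed)
  invisible(x)
}
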