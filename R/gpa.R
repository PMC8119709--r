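# Generalized Procrustes superimposition, allometry, PCA with permutation
# PC selection, mean shapes and phylogenetic signal.

# Best orthogonal rotation (reflection disallowed) aligning X onto Y.
# Tooth pits are physical impressions, so chirality is meaningful and
# improper rotations are never fitted.
procrustes_rotation <- function(X, Y) {
  s <- svd(crossprod(X, Y))
  d <- sign(det(s$u %*% t(s$v)))
  dd <- diag(c(rep(1, ncol(X) - 1L), d))
  s$u %*% dd %*% t(s$v)
}

#' Generalized Procrustes alignment
#'
#' Iterative superimposition: all configurations are centred, optionally
#' rescaled to unit centroid size (shape space), rotated to the running
#' consensus by orthogonal Procrustes (reflections disallowed), and the
#' consensus recomputed until its change drops below `tol`. In shape space
#' the aligned coordinates are then orthogonally projected into the tangent
#' space at the consensus. In form space (`scale = FALSE`) the scaling step
#' is skipped entirely, centroid sizes are preserved exactly, and log
#' centroid size is carried alongside for allometric regression.
#'
#' @param dataset a `pit_dataset` (>= 2 configurations).
#' @param scale `TRUE` for shape space (unit centroid size), `FALSE` for
#'   form space.
#' @param tol convergence tolerance on the consensus change.
#' @param max_iter maximum number of superimposition iterations.
#' @return An `aligned_shapes` object: `coords` (n x 30 x 3 array),
#'   `centroid_sizes`, `consensus` (30 x 3), `scaled`, `iterations`,
#'   `converged`, plus the dataset labels.
#' @export
gpa_align <- function(dataset, scale = TRUE, tol = 1e-10, max_iter = 100L) {
  stopifnot(inherits(dataset, "pit_dataset"))
  n <- length(dataset$id)
  if (n < 2L) stop("GPA needs at least 2 configurations")
  k <- nrow(dataset$configurations[[1L]])
  cs <- numeric(n)
  arr <- array(NA_real_, dim = c(n, k, N_DIMS))
  for (i in seq_len(n)) {
    x <- dataset$configurations[[i]]
    x <- sweep(x, 2L, colMeans(x))
    s <- sqrt(sum(x^2))
    if (s < 1e-12) stop("degenerate (all-coincident) configuration: ",
                        dataset$id[i])
    cs[i] <- s
    arr[i, , ] <- if (scale) x / s else x
  }
  consensus <- apply(arr, c(2L, 3L), mean)
  if (scale) consensus <- consensus / sqrt(sum(consensus^2))
  iterations <- 0L
  converged <- FALSE
  while (iterations < max_iter) {
    iterations <- iterations + 1L
    for (i in seq_len(n)) {
      arr[i, , ] <- arr[i, , ] %*% procrustes_rotation(arr[i, , ], consensus)
    }
    new_consensus <- apply(arr, c(2L, 3L), mean)
    if (scale) new_consensus <- new_consensus / sqrt(sum(new_consensus^2))
    delta <- sqrt(sum((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warning("GPA did not converge in ", max_iter, " iterations")
  unprojected <- NULL
  if (scale) {
    unprojected <- arr
    # orthogonal tangent projection at the consensus: remove the component
    # of each deviation along the (unit-norm) consensus direction
    cvec <- as.vector(consensus)
    flat <- matrix(arr, nrow = n)
    proj <- flat - (flat %*% cvec) %*% t(cvec) + matrix(cvec, n, length(cvec),
                                                       byrow = TRUE)
    arr <- array(proj, dim = dim(arr))
  }
  structure(list(coords = arr, coords_unprojected = unprojected,
                 centroid_sizes = cs, consensus = consensus,
                 scaled = scale, iterations = iterations,
                 converged = converged, id = dataset$id,
                 taxon = dataset$taxon, family = dataset$family,
                 provenance = dataset$provenance),
            class = "aligned_shapes")
}

#' Flatten aligned coordinates
#'
#' @param aligned an `aligned_shapes` object.
#' @return n x (landmarks * 3) matrix; columns ordered x1..xk, y1..yk,
#'   z1..zk.
#' @export
flatten_shapes <- function(aligned) {
  matrix(aligned$coords, nrow = dim(aligned$coords)[1L])
}

#' Allometric regression of shape on log centroid size
#'
#' Regresses shape on size: each form-space configuration is rescaled to
#' unit centroid size (leaving pure shape) and the flattened shape
#' coordinates are regressed on log centroid size. Regressing the raw
#' form-space coordinates would detect size itself, not allometry, since
#' form coordinates scale with centroid size by construction. The model
#' sum of squares is tested by permutation: log CS values are permuted
#' `n_perm` times, the F ratio recomputed, and
#' `p = (1 + #\{F_perm >= F_obs\}) / (n_perm + 1)` (add-one convention, so the
#' smallest attainable p at 999 permutations is 0.001). The effect size is
#' the observed F standardized against the permutation distribution.
#'
#' @param aligned a form-space `aligned_shapes` (`scaled = FALSE`).
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed for the permutations.
#' @return An `allometry_result`: `squared_residuals` (model sum of
#'   squares), `F`, `effect_size`, `p`, `bfb`.
#' @export
allometry_test <- function(aligned, n_perm = 999L, seed = 1L) {
  stopifnot(inherits(aligned, "aligned_shapes"))
  if (aligned$scaled) {
    stop("allometry_test needs a form-space alignment (scale = FALSE)")
  }
  if (n_perm < 1L) stop("n_perm must be >= 1")
  x <- log(aligned$centroid_sizes)
  if (stats::sd(x) < 1e-12) stop("constant centroid size")
  Y <- flatten_shapes(aligned) / aligned$centroid_sizes
  n <- nrow(Y)
  Yc <- sweep(Y, 2L, colMeans(Y))
  ss_total <- sum(Yc^2)
  model_ss <- function(xv) {
    xc <- xv - mean(xv)
    sxx <- sum(xc^2)
    sum((crossprod(Yc, xc))^2) / sxx
  }
  f_of <- function(ssm) (ssm / 1) / ((ss_total - ssm) / (n - 2))
  ss_obs <- model_ss(x)
  f_obs <- f_of(ss_obs)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  f_perm <- vapply(seq_len(n_perm),
                   function(i) f_of(model_ss(sample(x))), numeric(1))
  p <- (1 + sum(f_perm >= f_obs)) / (n_perm + 1)
  z <- (f_obs - mean(f_perm)) / stats::sd(f_perm)
  structure(list(squared_residuals = ss_obs, F = f_obs, effect_size = z,
                 p = p, bfb = bfb(p)),
            class = "allometry_result")
}

#' Principal component analysis of aligned shapes
#'
#' Centred covariance PCA of the flattened coordinates. Variance fractions
#' sum to one and scores times loadings reproduce the centred data.
#'
#' @param aligned an `aligned_shapes` object (n >= 3) or a numeric matrix.
#' @return A `pc_space`: `scores` (n x k), `loadings` (p x k),
#'   `variance_fraction`, `retained` (initialised to k), `center`, plus
#'   specimen labels when available.
#' @export
pca_reduce <- function(aligned) {
  if (inherits(aligned, "aligned_shapes")) {
    Y <- flatten_shapes(aligned)
    labels <- aligned[c("id", "taxon", "family", "provenance")]
    cs <- aligned$centroid_sizes
  } else {
    Y <- as.matrix(aligned)
    labels <- NULL
    cs <- NULL
  }
  if (nrow(Y) < 3L) stop("PCA needs at least 3 specimens")
  pc <- stats::prcomp(Y, center = TRUE, scale. = FALSE)
  keep <- pc$sdev > max(pc$sdev) * 1e-10
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(c(list(scores = pc$x[, keep, drop = FALSE],
                   loadings = pc$rotation[, keep, drop = FALSE],
                   variance_fraction = vf[keep],
                   retained = sum(keep), center = pc$center,
                   centroid_sizes = cs, source = Y),
              labels),
            class = "pc_space")
}

#' Permutation-based selection of principal components
#'
#' For each of `n_iter` iterations every original variable's column is
#' independently permuted, the PCA re-run, and the variance explained at
#' each rank recorded. A PC is supported when its observed variance fraction
#' exceeds the 95th percentile of the permuted fractions at the same rank;
#' the retained count is the contiguous leading block of supported PCs.
#'
#' @param pcspace a `pc_space` from [pca_reduce()].
#' @param n_iter number of randomization iterations (>= 1).
#' @param seed integer seed.
#' @return Integer count of retained PCs (possibly 0).
#' @export
optimal_pcs <- function(pcspace, n_iter = 50L, seed = 1L) {
  stopifnot(inherits(pcspace, "pc_space"))
  if (n_iter < 1L) stop("n_iter must be >= 1")
  Y <- pcspace$source
  n <- nrow(Y)
  k <- length(pcspace$variance_fraction)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  perm_vf <- matrix(NA_real_, n_iter, k)
  for (it in seq_len(n_iter)) {
    Yp <- apply(Y, 2L, sample)
    sv <- svd(scale(Yp, center = TRUE, scale = FALSE), nu = 0, nv = 0)
    vfp <- sv$d^2 / sum(sv$d^2)
    perm_vf[it, ] <- vfp[seq_len(k)]
  }
  crit <- apply(perm_vf, 2L, stats::quantile, probs = 0.95, na.rm = TRUE)
  supported <- pcspace$variance_fraction > crit
  if (!supported[1L]) return(0L)
  unsupported <- which(!supported)
  if (!length(unsupported)) return(length(supported))
  as.integer(unsupported[1L] - 1L)
}

#' Per-group mean shapes
#'
#' @param aligned an `aligned_shapes` object.
#' @param by character vector of group labels (default the taxon labels).
#' @return Named list of 30x3 mean configurations, one per group.
#' @export
mean_shape <- function(aligned, by = aligned$taxon) {
  stopifnot(inherits(aligned, "aligned_shapes"))
  by <- as.character(by)
  if (length(by) != dim(aligned$coords)[1L]) {
    stop("grouping length must match specimen count")
  }
  groups <- unique(by)
  out <- lapply(groups, function(g) {
    idx <- which(by == g)
    if (!length(idx)) stop("empty group: ", g)
    apply(aligned$coords[idx, , , drop = FALSE], c(2L, 3L), mean)
  })
  names(out) <- groups
  out
}

#' Multivariate phylogenetic signal (K statistic)
#'
#' Multivariate generalisation of Blomberg's K: the ratio of the observed
#' mean squared error under a star phylogeny to the phylogenetically
#' corrected mean squared error, scaled by its Brownian-motion expectation
#' on the tree. K near 1 matches Brownian evolution along the tree; K near 0
#' means no signal. Significance comes from permuting tip assignments.
#'
#' @param group_means named list of 30x3 mean configurations (or a matrix
#'   with row names) whose names match the tree tips; spaces in names are
#'   mapped to underscores before matching.
#' @param tree newick text, a path to a newick file, or an `ape::phylo`.
#' @param n_perm number of tip permutations.
#' @param seed integer seed.
#' @return A `phylo_signal_result`: `statistic` (K), `effect_size`, `p`,
#'   `bfb`.
#' @export
phylogenetic_signal <- function(group_means, tree, n_perm = 999L, seed = 1L) {
  if (inherits(tree, "phylo")) {
    phy <- tree
  } else if (is.character(tree) && length(tree) == 1L) {
    phy <- if (file.exists(tree)) ape::read.tree(tree)
           else ape::read.tree(text = tree)
  } else {
    stop("tree must be newick text, a newick path, or a phylo object")
  }
  if (is.matrix(group_means)) {
    Y <- group_means
  } else {
    Y <- t(vapply(group_means, as.vector,
                  numeric(length(as.vector(group_means[[1L]])))))
  }
  rownames(Y) <- gsub(" ", "_", rownames(Y))
  tips <- phy$tip.label
  if (!setequal(rownames(Y), tips)) {
    stop("tree tips and group labels differ: missing ",
         paste(setdiff(tips, rownames(Y)), collapse = ", "))
  }
  Y <- Y[tips, , drop = FALSE]
  C <- ape::vcv(phy)
  Cinv <- solve(C)
  N <- nrow(Y)
  one <- matrix(1, N, 1)
  denom_a <- as.numeric(t(one) %*% Cinv %*% one)
  expected <- (sum(diag(C)) - N / denom_a) / (N - 1)
  k_stat <- function(Ym) {
    a <- (t(one) %*% Cinv %*% Ym) / denom_a
    R <- Ym - one %*% a
    mse0 <- sum(R^2) / (N - 1)
    mse <- sum(diag(t(R) %*% Cinv %*% R)) / (N - 1)
    (mse0 / mse) / expected
  }
  k_obs <- k_stat(Y)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  k_perm <- vapply(seq_len(n_perm),
                   function(i) k_stat(Y[sample(N), , drop = FALSE]),
                   numeric(1))
  p <- (1 + sum(k_perm >= k_obs)) / (n_perm + 1)
  z <- (k_obs - mean(k_perm)) / stats::sd(k_perm)
  structure(list(statistic = k_obs, effect_size = z, p = p, bfb = bfb(p)),
            class = "phylo_signal_result")
}

#' Export PC scores as a tidy table
#'
#' @param pcspace a `pc_space` carrying specimen labels.
#' @param k number of leading PCs to export (default `pcspace$retained`).
#' @return data.frame with specimen_id, taxon, family, provenance,
#'   centroid_size and PC1..PCk columns.
#' @export
pc_score_table <- function(pcspace, k = pcspace$retained) {
  stopifnot(inherits(pcspace, "pc_space"))
  k <- min(k, ncol(pcspace$scores))
  sc <- pcspace$scores[, seq_len(k), drop = FALSE]
  colnames(sc) <- paste0("PC", seq_len(k))
  df <- data.frame(specimen_id = pcspace$id, taxon = pcspace$taxon,
                   family = pcspace$family, provenance = pcspace$provenance,
                   stringsAsFactors = FALSE)
  if (!is.null(pcspace$centroid_sizes)) {
    df$centroid_size <- pcspace$centroid_sizes
  }
  cbind(df, as.data.frame(sc))
}
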