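# Data augmentation of cleaned PC-score classes: robustly defined
# univariate targets sampled by random-walk Metropolis, with robust
# equivalency validation and class balancing.
#
# Targets are per-PC and independent: PCs are decorrelated by construction,
# and equivalency is validated per PC. A joint-Gaussian target is available
# through `build_target(..., joint = TRUE)` for users who want to preserve
# residual between-PC dependence.

#' Build a robust augmentation target for one class
#'
#' Per-PC robust location (median) and scale (square root of the biweight
#' midvariance). The skew-normal family additionally fits a shape parameter
#' by method of moments on 10%-trimmed data, capping the sample skewness at
#' the skew-normal's attainable range.
#'
#' @param class_rows numeric matrix (n >= 10) of a single class's PC scores.
#' @param family `"gaussian"` or `"skew-normal"`.
#' @param joint logical; when `TRUE` a joint-Gaussian target with the
#'   class's full covariance is built instead of independent per-PC targets.
#' @return A `target_spec`: `family`, `location`, `scale`, `alpha`
#'   (skew-normal shape, 0 for gaussian), `joint`, `sigma` (joint only).
#' @export
build_target <- function(class_rows, family = c("gaussian", "skew-normal"),
                         joint = FALSE) {
  family <- match.arg(family)
  X <- as.matrix(class_rows)
  if (nrow(X) < 10L) stop("target fitting needs class n >= 10")
  location <- apply(X, 2L, stats::median)
  scale <- sqrt(apply(X, 2L, function(col) {
    v <- suppressWarnings(biweight_midvariance(col))
    if (v == 0) stop("zero robust scale on a PC (constant column?)")
    v
  }))
  alpha <- rep(0, ncol(X))
  if (family == "skew-normal") {
    alpha <- apply(X, 2L, function(col) {
      tr <- sort(col)
      g <- floor(0.1 * length(tr))
      if (g > 0) tr <- tr[(g + 1L):(length(tr) - g)]
      m <- mean(tr)
      s <- stats::sd(tr)
      skew <- mean(((tr - m) / s)^3)
      skew <- max(min(skew, 0.99), -0.99)
      # method of moments: |delta| from |skewness|
      b <- (2 * abs(skew) / (4 - pi))^(1 / 3)
      delta <- sign(skew) * b / sqrt(2 / pi * (1 + b^2))
      delta <- max(min(delta, 0.995), -0.995)
      delta / sqrt(1 - delta^2)
    })
  }
  sigma <- NULL
  if (joint) sigma <- stats::cov(X)
  structure(list(family = family, location = location, scale = scale,
                 alpha = alpha, joint = joint, sigma = sigma,
                 k = ncol(X), colnames = colnames(X)),
            class = "target_spec")
}

# log target density, vectorized over x for one PC
target_logpdf <- function(x, location, scale, alpha, family) {
  z <- (x - location) / scale
  if (family == "gaussian" || alpha == 0) {
    stats::dnorm(z, log = TRUE) - log(scale)
  } else {
    stats::dnorm(z, log = TRUE) +
      stats::pnorm(alpha * z, log.p = TRUE) + log(2) - log(scale)
  }
}

#' MCMC augmentation from a robust target
#'
#' Independent per-PC random-walk Metropolis chains targeting the robustly
#' defined density. The proposal step is adapted toward 30-45% acceptance
#' during burn-in only (so the post-burn-in chain is a valid fixed-kernel
#' sampler), then `n_new` rows are taken after thinning. A warning names
#' the step size if the post-adaptation acceptance rate leaves the 5-95%
#' window.
#'
#' @param target a [build_target()] specification.
#' @param n_new number of synthetic rows to generate (>= 1).
#' @param seed integer seed; output is bit-reproducible.
#' @param burn_in number of discarded initial steps (adaptation window).
#' @param thin keep every `thin`-th post-burn-in state.
#' @param step initial proposal sd in units of the target scale.
#' @return Numeric matrix `n_new x k` with attributes `acceptance_rate`
#'   (per PC) and `step` (final per-PC proposal sd); column names follow
#'   the target.
#' @export
mcmc_augment <- function(target, n_new, seed = 1L, burn_in = 1000L,
                         thin = 10L, step = 2.4) {
  stopifnot(inherits(target, "target_spec"))
  if (n_new < 1L) stop("n_new must be >= 1")
  if (thin < 1L) stop("thin must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  k <- target$k
  steps <- target$scale * step
  x <- target$location
  lp <- vapply(seq_len(k), function(j)
    target_logpdf(x[j], target$location[j], target$scale[j],
                  target$alpha[j], target$family), numeric(1))
  n_keep <- 0L
  total <- burn_in + n_new * thin
  out <- matrix(NA_real_, n_new, k)
  acc <- numeric(k)
  acc_window <- numeric(k)
  window <- 0L
  post_acc <- numeric(k)
  post_n <- 0L
  for (t in seq_len(total)) {
    prop <- x + stats::rnorm(k) * steps
    lp_prop <- vapply(seq_len(k), function(j)
      target_logpdf(prop[j], target$location[j], target$scale[j],
                    target$alpha[j], target$family), numeric(1))
    accept <- log(stats::runif(k)) < (lp_prop - lp)
    x[accept] <- prop[accept]
    lp[accept] <- lp_prop[accept]
    if (t <= burn_in) {
      acc_window <- acc_window + accept
      window <- window + 1L
      if (window == 50L) { # adapt during burn-in only
        rate <- acc_window / window
        steps <- steps * ifelse(rate < 0.30, 0.8,
                                ifelse(rate > 0.45, 1.25, 1))
        acc_window[] <- 0
        window <- 0L
      }
    } else {
      post_acc <- post_acc + accept
      post_n <- post_n + 1L
      if ((t - burn_in) %% thin == 0L) {
        n_keep <- n_keep + 1L
        out[n_keep, ] <- x
      }
    }
  }
  rate <- post_acc / max(post_n, 1L)
  bad <- which(rate < 0.05 | rate > 0.95)
  if (length(bad)) {
    warning("MCMC acceptance rate outside [0.05, 0.95] for PC(s) ",
            paste(bad, collapse = ", "), "; step size(s) ",
            paste(signif(steps[bad], 3), collapse = ", "))
  }
  colnames(out) <- target$colnames
  attr(out, "acceptance_rate") <- rate
  attr(out, "step") <- steps
  out
}

#' Validate augmented data against the originals
#'
#' Robust equivalence ([robust_equivalence()]) per PC between the real and
#' synthetic rows; the augmentation is accepted when every PC declares
#' equivalence at p <= 0.005.
#'
#' @param real_rows,synthetic_rows numeric matrices with matching columns.
#' @param margin equivalence margin in pooled robust-sd units.
#' @return List with `per_pc` (list of `equivalence_result`), `table`
#'   (data.frame of d_abs / p / bfb per PC) and `accepted`.
#' @export
validate_augmentation <- function(real_rows, synthetic_rows, margin = 0.1) {
  R <- as.matrix(real_rows)
  S <- as.matrix(synthetic_rows)
  if (ncol(R) != ncol(S)) stop("dimension mismatch: real has ", ncol(R),
                               " PCs, synthetic has ", ncol(S))
  if (!nrow(R) || !nrow(S)) stop("both row sets must be non-empty")
  per_pc <- lapply(seq_len(ncol(R)), function(j)
    robust_equivalence(R[, j], S[, j], margin = margin))
  names(per_pc) <- colnames(R) %||% paste0("PC", seq_len(ncol(R)))
  tab <- data.frame(
    pc = names(per_pc),
    d_abs = vapply(per_pc, `[[`, numeric(1), "d_abs"),
    p = vapply(per_pc, `[[`, numeric(1), "p"),
    bfb = vapply(per_pc, `[[`, numeric(1), "bfb"),
    equivalent = vapply(per_pc, `[[`, logical(1), "equivalent"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(per_pc = per_pc, table = tab, accepted = all(tab$equivalent))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Balance a PC-score dataset by augmentation
#'
#' Tops every class up to `per_class_target` rows (or to the size of the
#' largest class when `mode = "match-largest"`) with synthetic rows from the
#' selected backend. Original rows pass through bit-identical and keep
#' provenance `"original"`; generated rows are flagged `"synthetic"` and are
#' only ever used for training/validation downstream.
#'
#' @param pc_table data.frame with `specimen_id`, `taxon`, `provenance` and
#'   PC columns (as from [pc_score_table()]).
#' @param per_class_target target class size; must be >= the largest
#'   original class unless `mode = "match-largest"`.
#' @param backend `"mcmc"` or `"wgan-gp"`.
#' @param mode `"target"` or `"match-largest"`.
#' @param family target family for the MCMC backend.
#' @param seed integer seed.
#' @param margin equivalence margin for per-class validation.
#' @param ... further arguments to [mcmc_augment()] or
#'   [wgan_gp_augment()].
#' @return List with `data` (balanced data.frame), `validation` (per-class
#'   [validate_augmentation()] results) and `backend`.
#' @export
balance_dataset <- function(pc_table, per_class_target = 100L,
                            backend = c("mcmc", "wgan-gp"),
                            mode = c("target", "match-largest"),
                            family = "gaussian", seed = 1L, margin = 0.1,
                            ...) {
  backend <- match.arg(backend)
  mode <- match.arg(mode)
  pc_cols <- grep("^PC[0-9]+$", names(pc_table), value = TRUE)
  if (!length(pc_cols)) stop("no PC columns found")
  counts <- table(pc_table$taxon)
  if (mode == "match-largest") per_class_target <- max(counts)
  if (per_class_target < max(counts)) {
    stop("per_class_target (", per_class_target,
         ") is below the largest class (", max(counts), ")")
  }
  validation <- list()
  synth <- list()
  classes <- names(counts)
  for (i in seq_along(classes)) {
    cls <- classes[i]
    rows <- pc_table[pc_table$taxon == cls, , drop = FALSE]
    need <- per_class_target - nrow(rows)
    if (need <= 0L) next
    X <- as.matrix(rows[, pc_cols, drop = FALSE])
    cls_seed <- (as.integer(seed) * 131L + i) %% .Machine$integer.max
    if (backend == "mcmc") {
      target <- build_target(X, family = family)
      new_rows <- mcmc_augment(target, n_new = need, seed = cls_seed, ...)
    } else {
      new_rows <- wgan_gp_augment(X, n_new = need, seed = cls_seed, ...)
    }
    if (need >= 10L) { # robust equivalence is undefined below n = 10
      validation[[cls]] <- validate_augmentation(X, new_rows,
                                                 margin = margin)
    }
    df <- as.data.frame(new_rows)
    names(df) <- pc_cols
    meta <- rows[rep(1L, need), setdiff(names(pc_table), pc_cols),
                 drop = FALSE]
    meta$specimen_id <- sprintf("%s_synth_%03d", gsub("[^A-Za-z]", "", cls),
                                seq_len(need))
    meta$provenance <- "synthetic"
    if ("centroid_size" %in% names(meta)) meta$centroid_size <- NA_real_
    synth[[cls]] <- cbind(meta, df)[, names(pc_table), drop = FALSE]
  }
  out <- rbind(pc_table, do.call(rbind, unname(synth)))
  rownames(out) <- NULL
  list(data = out, validation = validation, backend = backend,
       per_class_target = per_class_target)
}
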