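# Supervised classification of PC scores: soft-margin SVM with a radial
# kernel or Laplacian random Fourier features, and a neural SVM whose
# feature extractor is a small trained MLP feeding a linear maximum-margin
# head. Probabilities come from Platt scaling (pairwise-coupled for the
# one-vs-one SVM). Hyperparameters can be tuned with Gaussian-process
# Bayesian optimization.
#
# The SVM is solved in the primal with a squared hinge:
#   min_a,b  0.5 a' K a + C sum_i max(0, 1 - y_i (K a + b)_i)^2
# which is smooth, convex, deterministic, and comfortably fast at the few
# hundred rows per one-vs-one problem this pipeline produces.

#' Classifier specification
#'
#' @param kind `"svm-rbf"`, `"svm-rff"` (Laplacian random Fourier
#'   features + linear SVM) or `"nsvm"`.
#' @param C soft-margin penalty.
#' @param gamma kernel width (RBF: `exp(-gamma ||x-y||^2)`; RFF: scale of
#'   the Laplacian kernel `exp(-gamma ||x-y||_1)`); default `1/k` at fit
#'   time.
#' @param D number of random Fourier features (svm-rff).
#' @param hidden hidden-layer widths of the NSVM feature extractor.
#' @param epochs,lr NSVM training schedule.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(kind = c("svm-rbf", "svm-rff", "nsvm"), C = 1,
                            gamma = NULL, D = 300L, hidden = c(32L, 16L),
                            epochs = 300L, lr = 0.01) {
  kind <- match.arg(kind)
  structure(list(kind = kind, C = C, gamma = gamma, D = as.integer(D),
                 hidden = as.integer(hidden), epochs = as.integer(epochs),
                 lr = lr),
            class = "classifier_spec")
}

rbf_kernel <- function(X1, X2, gamma) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), `+`) - 2 * tcrossprod(X1, X2)
  exp(-gamma * pmax(d2, 0))
}

# primal squared-hinge solver; K symmetric PSD (kernel) or feature matrix
# (linear = TRUE, in which case weights live in feature space)
solve_squared_hinge <- function(M, y, C, linear = FALSE) {
  n <- nrow(M)
  p <- if (linear) ncol(M) else n
  obj <- function(par) {
    w <- par[seq_len(p)]
    b <- par[p + 1L]
    f <- as.vector(M %*% w) + b
    h <- pmax(0, 1 - y * f)
    reg <- if (linear) 0.5 * sum(w^2) else 0.5 * sum(w * (M %*% w))
    reg + C * sum(h^2)
  }
  grad <- function(par) {
    w <- par[seq_len(p)]
    b <- par[p + 1L]
    f <- as.vector(M %*% w) + b
    h <- pmax(0, 1 - y * f)
    gv <- -2 * C * (y * h)
    gw <- if (linear) w + as.vector(crossprod(M, gv))
          else as.vector(M %*% w) + as.vector(M %*% gv)
    c(gw, sum(gv))
  }
  fit <- stats::optim(rep(0, p + 1L), obj, grad, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-10))
  list(w = fit$par[seq_len(p)], b = fit$par[p + 1L])
}

# Platt scaling: sigmoid p = 1/(1+exp(A f + B)) fitted on decision values
platt_fit <- function(f, y01) {
  n1 <- sum(y01 == 1)
  n0 <- sum(y01 == 0)
  t <- ifelse(y01 == 1, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  nll <- function(par) {
    z <- par[1L] * f + par[2L]
    sum(log1p(exp(-abs(z))) + pmax(z, 0) - (1 - t) * z)
  }
  fit <- stats::optim(c(-1, 0), nll, method = "BFGS",
                      control = list(maxit = 100))
  fit$par
}

platt_prob <- function(par, f) 1 / (1 + exp(par[1L] * f + par[2L]))

#' Train a support vector machine
#'
#' Soft-margin SVM with either a Gaussian (radial) kernel or a Laplacian
#' random-Fourier-feature map (frequencies drawn from the Laplacian
#' kernel's Cauchy spectral measure, then a linear SVM). Multiclass by
#' one-vs-one with Platt-scaled pairwise probabilities coupled into
#' per-class estimates.
#'
#' @param train_rows numeric matrix of training rows.
#' @param labels class labels (>= 2 classes, each with >= 5 rows).
#' @param spec a [classifier_spec()] of kind `"svm-rbf"` or `"svm-rff"`.
#' @param seed integer seed (used by the random feature draw).
#' @return A `pit_model`.
#' @export
train_svm <- function(train_rows, labels, spec = classifier_spec(),
                      seed = 1L) {
  X <- as.matrix(train_rows)
  y <- factor(labels)
  classes <- levels(y)
  if (length(classes) < 2L) stop("need >= 2 classes")
  small <- table(y) < 5L
  if (any(small)) {
    stop("classes with < 5 rows (augment first): ",
         paste(names(small)[small], collapse = ", "))
  }
  gamma <- spec$gamma %||% (1 / ncol(X))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  rff <- NULL
  if (spec$kind == "svm-rff") {
    # Cauchy spectral measure of exp(-gamma ||x - y||_1)
    W <- matrix(stats::rcauchy(ncol(X) * spec$D, scale = gamma),
                ncol(X), spec$D)
    phase <- stats::runif(spec$D, 0, 2 * pi)
    rff <- list(W = W, phase = phase, D = spec$D)
  } else if (spec$kind != "svm-rbf") {
    stop("train_svm handles svm-rbf / svm-rff; use train_nsvm for nsvm")
  }
  featurize <- function(Xn) {
    if (is.null(rff)) return(Xn)
    sqrt(2 / rff$D) * cos(sweep(Xn %*% rff$W, 2L, rff$phase, `+`))
  }
  Xf <- featurize(X)
  pairs <- utils::combn(classes, 2L)
  models <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    sel <- y %in% pairs[, j]
    yy <- ifelse(y[sel] == pairs[1L, j], 1, -1)
    Xs <- Xf[sel, , drop = FALSE]
    if (is.null(rff)) {
      K <- rbf_kernel(Xs, Xs, gamma)
      fit <- solve_squared_hinge(K, yy, spec$C, linear = FALSE)
      f_train <- as.vector(K %*% fit$w) + fit$b
      fit$sv <- Xs
    } else {
      fit <- solve_squared_hinge(Xs, yy, spec$C, linear = TRUE)
      f_train <- as.vector(Xs %*% fit$w) + fit$b
    }
    fit$platt <- platt_fit(f_train, as.integer(yy == 1))
    fit$pair <- pairs[, j]
    models[[j]] <- fit
  }
  structure(list(kind = spec$kind, classes = classes, models = models,
                 gamma = gamma, rff = rff, spec = spec),
            class = "pit_model")
}

# pairwise coupling (Price et al.): p_i = 1 / (sum_j 1/r_ij - (k - 2))
couple_pairwise <- function(R, classes) {
  k <- length(classes)
  n <- nrow(R[[1L]]$r)
  P <- matrix(0, n, k, dimnames = list(NULL, classes))
  for (i in seq_len(k)) {
    inv_sum <- rep(0, n)
    for (m in R) {
      if (m$pair[1L] == classes[i]) inv_sum <- inv_sum + 1 / m$r[, 1L]
      if (m$pair[2L] == classes[i]) inv_sum <- inv_sum + 1 / (1 - m$r[, 1L])
    }
    P[, i] <- 1 / (inv_sum - (k - 2))
  }
  P <- pmin(pmax(P, 1e-12), 1)
  P / rowSums(P)
}

#' Predict from a trained model
#'
#' @param object a `pit_model`.
#' @param newdata numeric matrix of rows to classify.
#' @param ... unused.
#' @return List with `class` (factor over the training classes) and `prob`
#'   (n x k probability matrix).
#' @export
predict.pit_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (object$kind == "nsvm") return(predict_nsvm(object, X))
  featurize <- function(Xn) {
    if (is.null(object$rff)) return(Xn)
    sqrt(2 / object$rff$D) *
      cos(sweep(Xn %*% object$rff$W, 2L, object$rff$phase, `+`))
  }
  Xf <- featurize(X)
  R <- lapply(object$models, function(m) {
    f <- if (object$kind == "svm-rbf") {
      as.vector(rbf_kernel(Xf, m$sv, object$gamma) %*% m$w) + m$b
    } else {
      as.vector(Xf %*% m$w) + m$b
    }
    r <- platt_prob(m$platt, f)
    list(pair = m$pair, r = cbind(pmin(pmax(r, 1e-7), 1 - 1e-7)))
  })
  P <- couple_pairwise(R, object$classes)
  cls <- factor(object$classes[max.col(P, ties.method = "first")],
                levels = object$classes)
  list(class = cls, prob = P)
}

# ---- neural SVM ------------------------------------------------------------

nsvm_forward <- function(net, X) {
  L <- length(net$W)
  A <- vector("list", L)
  H <- vector("list", L + 1L)
  H[[1L]] <- X
  for (l in seq_len(L)) {
    A[[l]] <- sweep(H[[l]] %*% net$W[[l]], 2L, net$b[[l]], `+`)
    H[[l + 1L]] <- if (l < L) tanh(A[[l]]) else A[[l]]
  }
  list(A = A, H = H, out = H[[L + 1L]])
}

nsvm_backward <- function(net, fw, dOut) {
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- dOut
  for (l in rev(seq_len(L))) {
    if (l < L) delta <- delta * (1 - fw$H[[l + 1L]]^2)
    gW[[l]] <- crossprod(fw$H[[l]], delta)
    gb[[l]] <- colSums(delta)
    delta <- delta %*% t(net$W[[l]])
  }
  list(gW = gW, gb = gb, dX = delta)
}

#' Train a neural support vector machine
#'
#' A small feed-forward feature extractor (tanh hidden layers) trained
#' jointly with a linear squared-hinge (maximum-margin) output layer, one
#' margin per class (one-vs-rest targets +1/-1), with L2 weight decay,
#' full-batch Adam and a fixed seed for reproducibility.
#'
#' @inheritParams train_svm
#' @param spec a [classifier_spec()] of kind `"nsvm"`; `epochs = 0` leaves
#'   the network at its random initialisation (chance-level baseline).
#' @return A `pit_model`.
#' @export
train_nsvm <- function(train_rows, labels, spec = classifier_spec("nsvm"),
                       seed = 1L) {
  X <- as.matrix(train_rows)
  y <- factor(labels)
  classes <- levels(y)
  if (length(classes) < 2L) stop("need >= 2 classes")
  small <- table(y) < 5L
  if (any(small)) {
    stop("classes with < 5 rows (augment first): ",
         paste(names(small)[small], collapse = ", "))
  }
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2L, mu), 2L, sdv, `/`)
  Tmat <- 2 * one_hot(y, classes) - 1
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  net <- mlp_init(c(ncol(X), spec$hidden, length(classes)))
  opt <- adam_init(net)
  n <- nrow(Xs)
  decay <- 1e-4
  for (ep in seq_len(spec$epochs)) {
    fw <- nsvm_forward(net, Xs)
    h <- pmax(0, 1 - Tmat * fw$out)
    loss <- sum(h^2) / n
    if (!is.finite(loss)) stop("NSVM training produced non-finite loss")
    dOut <- -2 * Tmat * h / n
    g <- nsvm_backward(net, fw, dOut)
    g$gW <- Map(function(gw, w) gw + decay * w, g$gW, net$W)
    upd <- adam_step(net, g, opt, spec$lr, beta1 = 0.9, beta2 = 0.999)
    net <- upd$net
    opt <- upd$state
  }
  fw <- nsvm_forward(net, Xs)
  # probability calibration is part of training: an untrained (0-epoch)
  # network keeps the identity calibration and predicts at chance
  platt <- if (spec$epochs > 0) {
    lapply(seq_along(classes), function(i)
      platt_fit(fw$out[, i], as.integer(y == classes[i])))
  } else {
    rep(list(c(-1, 0)), length(classes))
  }
  structure(list(kind = "nsvm", classes = classes, net = net, mu = mu,
                 sdv = sdv, platt = platt, spec = spec),
            class = "pit_model")
}

predict_nsvm <- function(object, X) {
  Xs <- sweep(sweep(X, 2L, object$mu), 2L, object$sdv, `/`)
  margins <- nsvm_forward(object$net, Xs)$out
  P <- vapply(seq_along(object$classes), function(i)
    platt_prob(object$platt[[i]], margins[, i]),
    numeric(nrow(Xs)))
  P <- matrix(P, nrow = nrow(Xs),
              dimnames = list(NULL, object$classes))
  P <- pmin(pmax(P, 1e-12), 1)
  P <- P / rowSums(P)
  cls <- factor(object$classes[max.col(P, ties.method = "first")],
                levels = object$classes)
  list(class = cls, prob = P)
}

#' Feature extraction from a trained NSVM
#'
#' @param model an NSVM `pit_model`.
#' @param newdata numeric matrix.
#' @return Matrix of last-hidden-layer activations (columns = configured
#'   width of the final hidden layer).
#' @export
nsvm_features <- function(model, newdata) {
  stopifnot(model$kind == "nsvm")
  Xs <- sweep(sweep(as.matrix(newdata), 2L, model$mu), 2L, model$sdv, `/`)
  fw <- nsvm_forward(model$net, Xs)
  fw$H[[length(fw$H) - 1L]]
}

# ---- Bayesian hyperparameter optimization ----------------------------------

#' Gaussian-process Bayesian optimization
#'
#' Sequential model-based minimization: a squared-exponential GP surrogate
#' is fitted to the evaluations so far (inputs mapped to the unit cube,
#' log-scaling any parameter whose bounds are positive and span >= 2
#' decades), and the next point maximizes expected improvement over a
#' random candidate set. Objective evaluations returning non-finite values
#' are kept in the log as failures and excluded from the surrogate.
#'
#' @param objective function of a named list of parameters, returning a
#'   scalar to minimize.
#' @param bounds named list of `c(lower, upper)` pairs (finite).
#' @param budget total number of objective evaluations (>= 5).
#' @param seed integer seed.
#' @param n_init number of initial random evaluations.
#' @return List with `best` (named list), `value`, `log` (data.frame of
#'   all evaluations).
#' @export
bayesian_optimize <- function(objective, bounds, budget = 25L, seed = 1L,
                              n_init = NULL) {
  if (budget < 5L) stop("budget must be >= 5")
  d <- length(bounds)
  lo <- vapply(bounds, `[`, numeric(1), 1L)
  hi <- vapply(bounds, `[`, numeric(1), 2L)
  if (!all(is.finite(lo)) || !all(is.finite(hi)) || any(hi <= lo)) {
    stop("bounds must be finite with upper > lower")
  }
  logsc <- lo > 0 & hi / lo >= 100
  to_unit <- function(x) {
    u <- ifelse(logsc, (log(x) - log(lo)) / (log(hi) - log(lo)),
                (x - lo) / (hi - lo))
    unname(u)
  }
  from_unit <- function(u) {
    x <- ifelse(logsc, exp(log(lo) + u * (log(hi) - log(lo))),
                lo + u * (hi - lo))
    stats::setNames(as.list(x), names(bounds))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  n_init <- n_init %||% min(budget, max(4L, d + 2L))
  U <- matrix(stats::runif(n_init * d), n_init, d)
  evals <- data.frame()
  run_point <- function(u) {
    par <- from_unit(u)
    val <- tryCatch(objective(par), error = function(e) NaN)
    if (!is.numeric(val) || length(val) != 1L) val <- NaN
    row <- as.data.frame(par)
    row$value <- as.numeric(val)
    row$failed <- !is.finite(val)
    evals <<- rbind(evals, row)
    val
  }
  for (i in seq_len(n_init)) run_point(U[i, ])
  ell <- 0.2 * sqrt(d)
  while (nrow(evals) < budget) {
    ok <- !evals$failed
    if (sum(ok) < 2L) {
      u_next <- stats::runif(d)
    } else {
      Uok <- U[ok, , drop = FALSE]
      yok <- evals$value[ok]
      ymu <- mean(yok)
      ysd <- stats::sd(yok)
      if (ysd == 0) ysd <- 1
      ys <- (yok - ymu) / ysd
      Kd <- exp(-as.matrix(stats::dist(Uok))^2 / (2 * ell^2)) +
        diag(1e-6, nrow(Uok))
      Kinv_y <- solve(Kd, ys)
      Kinv <- solve(Kd)
      cand <- matrix(stats::runif(512L * d), ncol = d)
      d2 <- outer(rowSums(cand^2), rowSums(Uok^2), `+`) -
        2 * tcrossprod(cand, Uok)
      ks <- exp(-pmax(d2, 0) / (2 * ell^2))
      mu_c <- as.vector(ks %*% Kinv_y)
      var_c <- pmax(1 - rowSums((ks %*% Kinv) * ks), 1e-12)
      sd_c <- sqrt(var_c)
      best <- min(ys)
      z <- (best - mu_c) / sd_c
      ei <- sd_c * (z * stats::pnorm(z) + stats::dnorm(z))
      u_next <- cand[which.max(ei), ]
    }
    U <- rbind(U, u_next)
    run_point(u_next)
  }
  ok <- which(!evals$failed)
  if (!length(ok)) stop("all objective evaluations failed")
  best_i <- ok[which.min(evals$value[ok])]
  list(best = from_unit(U[best_i, ]), value = evals$value[best_i],
       log = evals)
}

# ---- evaluation protocols --------------------------------------------------

pc_columns <- function(df) grep("^PC[0-9]+$", names(df), value = TRUE)

#' Evaluate a model on original specimens only
#'
#' Final metrics are computed exclusively on rows with provenance
#' `"original"`; synthetic (augmented) rows are never scored.
#'
#' @param model a `pit_model`.
#' @param dataset data.frame with `taxon`, `provenance` and PC columns.
#' @param dataset_name report annotation.
#' @return An [evaluation_report()].
#' @export
evaluate_on_originals <- function(model, dataset,
                                  dataset_name = "dataset") {
  stopifnot(inherits(model, "pit_model"))
  if (!"provenance" %in% names(dataset)) {
    stop("dataset must carry a provenance column")
  }
  orig <- dataset[dataset$provenance == "original", , drop = FALSE]
  if (!nrow(orig)) stop("no original rows to evaluate on")
  stopifnot(all(orig$provenance == "original"))
  X <- as.matrix(orig[, pc_columns(orig), drop = FALSE])
  pred <- predict(model, X)
  evaluation_report(orig$taxon, as.character(pred$class), pred$prob,
                    dataset_name = dataset_name,
                    algorithm_name = model$kind)
}

#' Stratified 70/30 protocol on raw (non-augmented) data
#'
#' The no-augmentation baseline: original rows are split 70/30 per class,
#' the model trained on the 70% and evaluated on the held-out 30%.
#'
#' @param dataset data.frame with `taxon`, `provenance` and PC columns.
#' @param spec a [classifier_spec()].
#' @param train_frac training fraction.
#' @param seed integer seed (controls the split and the training).
#' @param dataset_name report annotation.
#' @return An [evaluation_report()] with attribute `split` (list of train
#'   and test row indices).
#' @export
raw_split_protocol <- function(dataset, spec = classifier_spec(),
                               train_frac = 0.70, seed = 1L,
                               dataset_name = "dataset") {
  orig <- dataset[dataset$provenance == "original", , drop = FALSE]
  sizes <- table(orig$taxon)
  if (any(sizes < 4L)) {
    stop("classes too small to stratify (need >= 4): ",
         paste(names(sizes)[sizes < 4], collapse = ", "))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  train_idx <- integer(0)
  for (cl in names(sizes)) {
    idx <- which(orig$taxon == cl)
    n_train <- round(train_frac * length(idx))
    train_idx <- c(train_idx, sample(idx, n_train))
  }
  test_idx <- setdiff(seq_len(nrow(orig)), train_idx)
  X <- as.matrix(orig[, pc_columns(orig), drop = FALSE])
  trainer <- if (spec$kind == "nsvm") train_nsvm else train_svm
  model <- trainer(X[train_idx, , drop = FALSE], orig$taxon[train_idx],
                   spec, seed = seed)
  pred <- predict(model, X[test_idx, , drop = FALSE])
  rep <- evaluation_report(orig$taxon[test_idx], as.character(pred$class),
                           pred$prob, dataset_name = dataset_name,
                           algorithm_name = paste0(spec$kind, "-raw70/30"))
  attr(rep, "split") <- list(train = train_idx, test = test_idx)
  rep
}
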