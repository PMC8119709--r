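# Confusion-matrix metric suite: accuracy, sensitivity, specificity,
# precision, recall (= sensitivity), F-measure, Cohen's kappa, multiclass
# ROC AUC and the mean-squared-error loss on probability vectors.

#' Confusion-matrix metrics
#'
#' Per-class one-vs-rest TP/TN/FP/FN with sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, precision `TP/(TP+FP)` (reported as 0 with a
#' flag when TP+FP = 0), recall identical to sensitivity, and
#' `F = 2PR/(P+R)`. Overall accuracy is micro accuracy (trace over total);
#' overall sensitivity/specificity/precision/F are macro (unweighted)
#' averages; Cohen's kappa is `(p_o - p_e)/(1 - p_e)`.
#'
#' @param y_true true labels.
#' @param y_pred predicted labels (a subset of the true label set).
#' @return List with `confusion` (matrix, rows = truth), `per_class`
#'   (data.frame), `accuracy`, `sensitivity`, `specificity`, `precision`,
#'   `recall`, `f_measure`, `kappa`, `undefined_precision` (class names).
#' @export
confusion_metrics <- function(y_true, y_pred) {
  if (!length(y_true)) stop("empty inputs")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  extra <- setdiff(unique(y_pred), unique(y_true))
  if (length(extra)) stop("predicted labels not in truth: ",
                          paste(extra, collapse = ", "))
  levs <- sort(unique(y_true))
  cm <- table(factor(y_true, levs), factor(y_pred, levs))
  n <- sum(cm)
  undefined <- character(0)
  per <- lapply(levs, function(cl) {
    tp <- cm[cl, cl]
    fn <- sum(cm[cl, ]) - tp
    fp <- sum(cm[, cl]) - tp
    tn <- n - tp - fn - fp
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else {
      undefined <<- c(undefined, cl)
      0
    }
    f <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
    data.frame(class = cl, accuracy = (tp + tn) / n, sensitivity = sens,
               specificity = spec, precision = prec, recall = sens,
               f_measure = f, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  p_o <- sum(diag(cm)) / n
  p_e <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else 0
  list(confusion = unclass(cm), per_class = per, accuracy = p_o,
       sensitivity = mean(per$sensitivity, na.rm = TRUE),
       specificity = mean(per$specificity, na.rm = TRUE),
       precision = mean(per$precision), recall = mean(per$recall,
                                                      na.rm = TRUE),
       f_measure = mean(per$f_measure), kappa = kappa,
       undefined_precision = undefined)
}

#' Multiclass one-vs-rest ROC AUC
#'
#' Rank (Mann-Whitney) formulation with tie correction per class; the macro
#' AUC is the unweighted mean over classes present in the truth. AUC is
#' invariant to strictly monotone transforms of the scores.
#'
#' @param y_true true labels.
#' @param class_scores n x k matrix of per-class scores; columns named by
#'   class; rows should sum to 1 (within 1e-6) for probabilistic scores.
#' @return List with `per_class` (named numeric) and `macro`.
#' @export
auc_multiclass <- function(y_true, class_scores) {
  scores <- as.matrix(class_scores)
  y_true <- as.character(y_true)
  if (nrow(scores) != length(y_true)) stop("row/label length mismatch")
  if (is.null(colnames(scores))) stop("class_scores needs column names")
  rs <- rowSums(scores)
  if (any(abs(rs - 1) > 1e-6)) {
    warning("score rows do not sum to 1; treating as raw scores")
  }
  absent <- setdiff(colnames(scores), unique(y_true))
  if (length(absent)) {
    warning("classes absent from y_true skipped: ",
            paste(absent, collapse = ", "))
  }
  classes <- intersect(colnames(scores), unique(y_true))
  per <- vapply(classes, function(cl) {
    pos <- y_true == cl
    n1 <- sum(pos)
    n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) return(NA_real_)
    r <- rank(scores[, cl]) # midranks handle ties
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  list(per_class = per, macro = mean(per, na.rm = TRUE))
}

#' Mean-squared-error loss on probability vectors
#'
#' `MSE = mean((y - yhat)^2)` over all n x k entries of the one-hot truth
#' and the predicted class-probability matrix.
#'
#' @param y_true_onehot n x k one-hot (0/1) matrix.
#' @param class_scores n x k probability matrix.
#' @return Non-negative scalar.
#' @export
mse_loss <- function(y_true_onehot, class_scores) {
  Y <- as.matrix(y_true_onehot)
  S <- as.matrix(class_scores)
  if (!all(dim(Y) == dim(S))) stop("shape mismatch between truth and scores")
  mean((Y - S)^2)
}

#' One-hot encode labels
#'
#' @param y labels.
#' @param levels class order (default sorted unique labels).
#' @return n x k 0/1 matrix with class column names.
#' @export
one_hot <- function(y, levels = sort(unique(as.character(y)))) {
  y <- as.character(y)
  out <- matrix(0, length(y), length(levels),
                dimnames = list(NULL, levels))
  out[cbind(seq_along(y), match(y, levels))] <- 1
  out
}

#' Full evaluation report for a dataset/algorithm pair
#'
#' One row per class plus an overall row, mirroring the standard reporting
#' layout: Accuracy, Sensitivity, Specificity, Precision, Recall, AUC,
#' F-Measure, Kappa and MSE Loss.
#'
#' @param y_true true labels.
#' @param y_pred predicted labels.
#' @param class_scores n x k probability matrix (columns named by class).
#' @param dataset_name,algorithm_name report annotations.
#' @return An `evaluation_report`: `table` (data.frame with classes + 1
#'   overall row), `confusion`, `dataset`, `algorithm`.
#' @export
evaluation_report <- function(y_true, y_pred, class_scores,
                              dataset_name = "dataset",
                              algorithm_name = "algorithm") {
  cmm <- confusion_metrics(y_true, y_pred)
  auc <- auc_multiclass(y_true, class_scores)
  levs <- cmm$per_class$class
  scores <- as.matrix(class_scores)[, levs, drop = FALSE]
  loss_overall <- mse_loss(one_hot(y_true, levs), scores)
  per_loss <- vapply(levs, function(cl) {
    idx <- y_true == cl
    mse_loss(one_hot(y_true[idx], levs), scores[idx, , drop = FALSE])
  }, numeric(1))
  tab <- cmm$per_class
  tab$auc <- auc$per_class[tab$class]
  tab$kappa <- NA_real_
  tab$loss <- per_loss
  overall <- data.frame(class = "overall", accuracy = cmm$accuracy,
                        sensitivity = cmm$sensitivity,
                        specificity = cmm$specificity,
                        precision = cmm$precision, recall = cmm$recall,
                        f_measure = cmm$f_measure, auc = auc$macro,
                        kappa = cmm$kappa, loss = loss_overall,
                        stringsAsFactors = FALSE)
  tab <- rbind(tab[, names(overall)], overall)
  rownames(tab) <- NULL
  structure(list(table = tab, confusion = cmm$confusion,
                 dataset = dataset_name, algorithm = algorithm_name,
                 accuracy = cmm$accuracy, kappa = cmm$kappa,
                 auc = auc$macro, loss = loss_overall),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s / %s\n", x$dataset, x$algorithm))
  print(x$table, digits = 3)
  invisible(x)
}
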