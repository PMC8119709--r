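# Robust statistical reporting layer: Bayes Factor Bounds, normality-gated
# test selection, robust scale estimation and equivalence testing.
#
# Significance convention throughout the package: p <= 0.005 ("3 sigma") is
# reported as significant, 0.005 < p <= 0.05 as suggestive only.

#' Bayes Factor Bound
#'
#' Upper bound on the Bayes factor in favour of the alternative implied by a
#' p-value: `BFB = 1 / (-e * p * ln p)` (natural log). For `p >= 1/e` the
#' bound is <= 1 and is flagged as favouring the null; callers report such
#' values as odds "against H_a".
#'
#' @param p p-value strictly inside (0, 1).
#' @return Numeric BFB with attribute `direction` (`"favors H_a"` or
#'   `"favors H_0"`).
#' @export
bfb <- function(p) {
  if (!is.numeric(p) || any(p <= 0) || any(p >= 1)) {
    stop("p must lie strictly in (0, 1)")
  }
  out <- 1 / (-exp(1) * p * log(p))
  attr(out, "direction") <- ifelse(p < exp(-1), "favors H_a", "favors H_0")
  out
}

#' Significance label under the 3-sigma convention
#'
#' @param p p-value.
#' @return `"significant"` (p <= 0.005), `"suggestive"` (p <= 0.05) or
#'   `"not significant"`.
#' @export
significance_label <- function(p) {
  ifelse(p <= 0.005, "significant",
         ifelse(p <= 0.05, "suggestive", "not significant"))
}

#' Biweight midvariance
#'
#' Robust variance estimator (Lax/Tukey) down-weighting observations far
#' from the median: with `u_i = (x_i - M) / (9 MAD)` and terms restricted to
#' `|u| < 1`,
#' `n * sum((x-M)^2 (1-u^2)^4) / (sum((1-u^2)(1-5u^2)))^2`.
#'
#' @param x numeric sample, n >= 2.
#' @return Non-negative variance estimate; 0 (with a warning) when the MAD
#'   is zero.
#' @export
biweight_midvariance <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop("biweight midvariance needs n >= 2")
  m <- stats::median(x)
  mad <- stats::median(abs(x - m))
  if (mad == 0) {
    warning("MAD is zero; biweight midvariance undefined, returning 0")
    return(0)
  }
  u <- (x - m) / (9 * mad)
  keep <- abs(u) < 1
  num <- n * sum(((x - m)^2 * (1 - u^2)^4)[keep])
  den <- sum(((1 - u^2) * (1 - 5 * u^2))[keep])^2
  num / den
}

#' Shapiro-Wilk normality gate
#'
#' Decides between the parametric and robust branches of downstream tests:
#' the parametric branch is taken iff Shapiro-Wilk p > 0.05.
#'
#' @param x numeric sample with 3 <= n <= 5000 and non-zero variance.
#' @return List with `parametric` (logical), `statistic` (W) and `p`.
#' @export
normality_gate <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L || n > 5000L) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(x) < .Machine$double.eps^0.5 * max(1, abs(mean(x)))) {
    stop("degenerate (constant) sample")
  }
  sw <- stats::shapiro.test(x)
  list(parametric = sw$p.value > 0.05,
       statistic = unname(sw$statistic), p = sw$p.value)
}

test_result <- function(statistic_name, statistic, p) {
  # degenerate tests can return p numerically equal to 0 or 1; clamp into
  # the open interval for the BFB evaluation only
  b <- bfb(min(max(p, 1e-300), 1 - 1e-12))
  structure(list(statistic_name = statistic_name,
                 statistic = unname(statistic), p = p,
                 bfb = as.numeric(b), direction = attr(b, "direction"),
                 significance = significance_label(p)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  against <- if (x$direction == "favors H_0") " against H_a" else ""
  cat(sprintf("%s = %.4g, p = %.4g, BFB = %.4g%s (%s)\n",
              x$statistic_name, x$statistic, x$p, x$bfb, against,
              x$significance))
  invisible(x)
}

#' Normality-gated univariate group comparison
#'
#' Classic one-way ANOVA when every group passes [normality_gate()];
#' otherwise the tie-corrected Kruskal-Wallis rank test. A Bayes Factor
#' Bound accompanies the p-value either way.
#'
#' @param values numeric response.
#' @param groups group labels (>= 2 groups, each n >= 2).
#' @return A `test_result` with `statistic_name` `"F"` or `"chi-squared"`.
#' @export
group_difference_test <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  sizes <- table(groups)
  if (any(sizes < 2L)) {
    stop("every group needs n >= 2 (offending: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), ")")
  }
  parametric <- all(vapply(split(values, groups),
                           function(g) normality_gate(g)$parametric,
                           logical(1)))
  if (parametric) {
    a <- stats::anova(stats::lm(values ~ groups))
    test_result("F", a$`F value`[1L], a$`Pr(>F)`[1L])
  } else {
    kw <- stats::kruskal.test(values, groups)
    test_result("chi-squared", kw$statistic, kw$p.value)
  }
}

# Wilks lambda and Hotelling-Lawley trace from the eigenvalues of E^-1 H,
# with Rao's and McKeon-style F approximations as used by stats::manova.
manova_from_eigen <- function(Y, groups) {
  groups <- factor(groups)
  n <- nrow(Y)
  g <- nlevels(groups)
  p <- ncol(Y)
  grand <- colMeans(Y)
  H <- matrix(0, p, p)
  E <- matrix(0, p, p)
  for (lev in levels(groups)) {
    idx <- which(groups == lev)
    gm <- colMeans(Y[idx, , drop = FALSE])
    H <- H + length(idx) * tcrossprod(gm - grand)
    R <- sweep(Y[idx, , drop = FALSE], 2L, gm)
    E <- E + crossprod(R)
  }
  ev <- tryCatch(Re(eigen(solve(E, H), only.values = TRUE)$values),
                 error = function(e) stop("singular within-group covariance; ",
                                          "retain fewer PCs"))
  ev <- pmax(ev, 0)
  list(eigenvalues = ev, H = H, E = E, n = n, g = g, p = p)
}

#' Normality-gated MANOVA on PC scores
#'
#' Multivariate analysis of variance with the Hotelling-Lawley trace when
#' every variable in every group passes the normality gate, Wilks' Lambda
#' otherwise, both with their standard F approximations (as in
#' `stats::manova`).
#'
#' @param scores n x k numeric matrix of retained PC scores.
#' @param groups group labels (>= 2 groups, per-group n > k).
#' @param statistic `"auto"` (normality-gated), `"Hotelling-Lawley"` or
#'   `"Wilks"`.
#' @return A `test_result`.
#' @export
multivariate_test <- function(scores, groups, statistic = "auto") {
  scores <- as.matrix(scores)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  sizes <- table(groups)
  if (any(sizes <= ncol(scores))) {
    stop("every group needs n > number of PCs (", ncol(scores), ")")
  }
  if (statistic == "auto") {
    parametric <- all(vapply(seq_len(ncol(scores)), function(j) {
      all(vapply(split(scores[, j], groups),
                 function(g) normality_gate(g)$parametric, logical(1)))
    }, logical(1)))
    statistic <- if (parametric) "Hotelling-Lawley" else "Wilks"
  }
  dec <- manova_from_eigen(scores, groups)
  p_dim <- dec$p
  q <- dec$g - 1L
  v <- dec$n - dec$g
  if (statistic == "Hotelling-Lawley") {
    hl <- sum(dec$eigenvalues)
    s <- min(p_dim, q)
    m <- (abs(p_dim - q) - 1) / 2
    nn <- (v - p_dim - 1) / 2
    df1 <- s * (2 * m + s + 1)
    df2 <- 2 * (s * nn + 1)
    fstat <- df2 * hl / (s^2 * (2 * m + s + 1))
    pval <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
    res <- test_result("Hotelling-Lawley", hl, pval)
  } else if (statistic == "Wilks") {
    lambda <- prod(1 / (1 + dec$eigenvalues))
    # Rao's F approximation
    r <- v - (p_dim - q + 1) / 2
    t <- if (p_dim^2 + q^2 - 5 > 0) {
      sqrt((p_dim^2 * q^2 - 4) / (p_dim^2 + q^2 - 5))
    } else 1
    u <- (p_dim * q - 2) / 4
    df1 <- p_dim * q
    df2 <- r * t - 2 * u
    lt <- lambda^(1 / t)
    fstat <- (1 - lt) / lt * df2 / df1
    pval <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
    res <- test_result("Wilks-Lambda", lambda, pval)
  } else {
    stop("unknown statistic: ", statistic)
  }
  res$F_approx <- fstat
  res
}

#' Pairwise multivariate comparisons
#'
#' Runs [multivariate_test()] over all group pairs. Raw p-values with BFBs
#' are reported by default (no multiplicity adjustment, matching the
#' reporting convention of the analysis); Benjamini-Hochberg adjustment is
#' available as an option.
#'
#' @param scores n x k matrix of PC scores.
#' @param groups group labels.
#' @param statistic passed to [multivariate_test()].
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame: group_a, group_b, statistic_name, statistic, p, bfb,
#'   direction.
#' @export
pairwise_multivariate_test <- function(scores, groups, statistic = "auto",
                                       adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  groups <- factor(groups)
  levs <- levels(groups)
  pairs <- utils::combn(levs, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    sel <- groups %in% pairs[, j]
    r <- multivariate_test(scores[sel, , drop = FALSE],
                           droplevels(groups[sel]), statistic)
    data.frame(group_a = pairs[1L, j], group_b = pairs[2L, j],
               statistic_name = r$statistic_name, statistic = r$statistic,
               p = r$p, bfb = r$bfb, direction = r$direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  }
  out
}

# Yuen-style moments of a trimmed mean: effective n, trimmed mean and the
# squared standard error based on the winsorized variance.
trimmed_moments <- function(x, trim = 0.2) {
  n <- length(x)
  g <- floor(trim * n)
  h <- n - 2L * g
  xs <- sort(x)
  tm <- mean(xs[(g + 1L):(n - g)])
  xw <- pmin(pmax(x, xs[g + 1L]), xs[n - g])
  swv <- stats::var(xw)
  list(mean = tm, se2 = (n - 1) * swv / (h * (h - 1)), h = h)
}

#' Robust equivalence test (TOST on 20% trimmed means)
#'
#' Tests whether two samples are statistically equivalent within a margin
#' expressed in pooled robust standard deviation units (square root of the
#' pooled biweight midvariance). `d_abs` is the absolute difference of
#' medians on the same standardized scale. The p-value is the larger of the
#' two one-sided Yuen trimmed-mean tests of the difference against the
#' margins (-margin, +margin); small p supports equivalence.
#'
#' @param sample_a,sample_b numeric samples, both n >= 10.
#' @param margin equivalence margin (> 0) in pooled robust-sd units.
#' @param trim trimming fraction for the Yuen tests.
#' @return An `equivalence_result`: `d_abs`, `p`, `bfb`, `equivalent`
#'   (p <= 0.005).
#' @export
robust_equivalence <- function(sample_a, sample_b, margin = 0.1,
                               trim = 0.2) {
  sample_a <- as.numeric(sample_a)
  sample_b <- as.numeric(sample_b)
  if (length(sample_a) < 10L || length(sample_b) < 10L) {
    stop("both samples need n >= 10")
  }
  if (margin <= 0) stop("margin must be > 0")
  na <- length(sample_a)
  nb <- length(sample_b)
  bw_a <- biweight_midvariance(sample_a)
  bw_b <- biweight_midvariance(sample_b)
  pooled_sd <- sqrt(((na - 1) * bw_a + (nb - 1) * bw_b) / (na + nb - 2))
  if (pooled_sd == 0) stop("pooled robust scale is zero")
  d_abs <- abs(stats::median(sample_a) - stats::median(sample_b)) / pooled_sd
  delta <- margin * pooled_sd
  ma <- trimmed_moments(sample_a, trim)
  mb <- trimmed_moments(sample_b, trim)
  diff <- ma$mean - mb$mean
  se <- sqrt(ma$se2 + mb$se2)
  df <- (ma$se2 + mb$se2)^2 /
    (ma$se2^2 / (ma$h - 1) + mb$se2^2 / (mb$h - 1))
  p_lower <- stats::pt((diff + delta) / se, df, lower.tail = FALSE)
  p_upper <- stats::pt((diff - delta) / se, df, lower.tail = TRUE)
  p <- max(p_lower, p_upper)
  p <- min(max(p, .Machine$double.xmin), 1)
  b <- if (p < 1) bfb(p) else structure(NA_real_, direction = "favors H_0")
  structure(list(d_abs = d_abs, p = p, bfb = as.numeric(b),
                 direction = attr(b, "direction"),
                 equivalent = p <= 0.005),
            class = "equivalence_result")
}

#' Tidy table of test results
#'
#' @param results named list of `test_result` / `equivalence_result`
#'   objects.
#' @return data.frame (comparison, statistic_name, statistic, p, bfb,
#'   direction) suitable for CSV export.
#' @export
results_table <- function(results) {
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(comparison = nm,
               statistic_name = if (!is.null(r$statistic_name))
                 r$statistic_name else "d_abs",
               statistic = if (!is.null(r$statistic)) r$statistic else r$d_abs,
               p = r$p, bfb = r$bfb, direction = r$direction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
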