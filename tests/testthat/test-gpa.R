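test_that("GPA recovers a shape duplicated under rigid motions", {
  base <- template_pit()
  ds <- pit_dataset(lapply(1:6, function(i) rigid_motion(base, seed = i)),
                    id = paste0("s", 1:6), taxon = "t", family = "Canidae")
  aligned <- gpa_align(ds, scale = TRUE)
  expect_true(aligned$converged)
  flat <- flatten_shapes(aligned)
  spread <- max(abs(sweep(flat, 2, colMeans(flat))))
  expect_lt(spread, 1e-8)

  # unit centroid size holds on the pre-projection coordinates
  cs <- apply(aligned$coords_unprojected, 1, function(m) sqrt(sum(m^2)))
  expect_lt(max(abs(cs - 1)), 1e-9)
  # centred at the origin
  ctr <- apply(aligned$coords, 1, function(m)
    max(abs(colMeans(matrix(m, ncol = 3)))))
  expect_lt(max(ctr), 1e-9)
})

test_that("two-configuration GPA matches the closed-form Procrustes fit", {
  set.seed(11)
  A <- template_pit()
  B <- template_pit() + matrix(rnorm(90, sd = 0.05), 30, 3)
  ds <- pit_dataset(list(A, rigid_motion(B, seed = 2)),
                    id = c("a", "b"), taxon = "t", family = "Canidae")
  aligned <- gpa_align(ds, scale = TRUE, tol = 1e-14)

  # closed-form oracle: centre+scale both, rotate b onto a (proper
  # rotation from the SVD of the cross-covariance), consensus = midpoint
  norm_cfg <- function(X) {
    X <- sweep(X, 2, colMeans(X))
    X / sqrt(sum(X^2))
  }
  a <- norm_cfg(A)
  b <- norm_cfg(rigid_motion(B, seed = 2))
  s <- svd(crossprod(b, a))
  R <- s$u %*% diag(c(1, 1, sign(det(s$u %*% t(s$v))))) %*% t(s$v)
  oracle <- (a + b %*% R) / 2
  oracle <- oracle / sqrt(sum(oracle^2))

  # consensus agrees up to a global rotation: compare Procrustes-aligned
  so <- svd(crossprod(oracle, aligned$consensus))
  Ro <- so$u %*% diag(c(1, 1, sign(det(so$u %*% t(so$v))))) %*% t(so$v)
  expect_lt(max(abs(oracle %*% Ro - aligned$consensus)), 1e-10)
})

test_that("GPA is order-invariant and preserves CS in form space", {
  ds <- generate_study(default_study_spec(seed = 2, n_scale = 0.08))
  aligned <- gpa_align(ds, scale = FALSE)
  expect_equal(aligned$centroid_sizes,
               vapply(ds$configurations, centroid_size, numeric(1)),
               tolerance = 1e-14)

  set.seed(5)
  perm <- sample(length(ds$id))
  aligned_p <- gpa_align(subset_dataset(ds, perm), scale = FALSE)
  expect_lt(max(abs(aligned_p$consensus - aligned$consensus)), 1e-8)

  degenerate <- pit_dataset(list(matrix(1, 30, 3), template_pit()),
                            id = c("a", "b"), taxon = "t",
                            family = "Canidae")
  expect_error(gpa_align(degenerate), "degenerate")
})

test_that("allometry test detects a planted slope and guards bad input", {
  spec <- taxon_spec("x", "Canidae", 50, log_cs_mean = 1.5,
                     allometric_slope = 0.2, within_sd = 0.1)
  ds <- generate_taxon_sample(spec, seed = 3)
  aligned <- gpa_align(ds, scale = FALSE)
  res <- allometry_test(aligned, n_perm = 499, seed = 1)
  expect_lt(res$p, 0.005)
  expect_gt(res$effect_size, 2)
  expect_gt(res$bfb, 1)

  expect_error(allometry_test(aligned, n_perm = 0), "n_perm")
  expect_error(allometry_test(gpa_align(ds, scale = TRUE)), "form-space")
})

test_that("PCA satisfies its algebraic contracts", {
  ds <- generate_study(default_study_spec(seed = 6, n_scale = 0.1))
  aligned <- gpa_align(ds, scale = FALSE)
  pcs <- pca_reduce(aligned)
  expect_lte(ncol(pcs$scores), min(length(ds$id) - 1, 90))
  expect_equal(sum(pcs$variance_fraction), 1, tolerance = 1e-9)

  # scores' covariance is diagonal
  cv <- cov(pcs$scores)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8 * max(diag(cv)))

  # reconstruction from all PCs reproduces the centred data
  rec <- pcs$scores %*% t(pcs$loadings)
  centred <- sweep(flatten_shapes(aligned), 2, pcs$center)
  expect_lt(max(abs(rec - centred)), 1e-8)

  expect_error(pca_reduce(matrix(1:4, 2, 2)), "at least 3")
})

test_that("permutation PC selection finds planted factors and rejects noise", {
  hits <- 0
  for (s in 1:3) {
    set.seed(s)
    n <- 80
    f1 <- rnorm(n)
    f2 <- rnorm(n)
    Y <- outer(f1, runif(20, -1, 1)) * 3 + outer(f2, runif(20, -1, 1)) * 2 +
      matrix(rnorm(n * 20, sd = 0.5), n, 20)
    hits <- hits + (optimal_pcs(pca_reduce(Y), seed = s) == 2)
  }
  expect_gte(hits, 2) # rank-2 recovered in most replicates

  set.seed(1)
  noise <- matrix(rnorm(80 * 20), 80, 20)
  expect_equal(optimal_pcs(pca_reduce(noise), seed = 1), 0L)

  pcs <- pca_reduce(noise)
  expect_identical(optimal_pcs(pcs, seed = 3), optimal_pcs(pcs, seed = 3))
  expect_error(optimal_pcs(pcs, n_iter = 0), "n_iter")
})

test_that("mean shapes equal the brute-force per-group average", {
  ds <- generate_study(default_study_spec(seed = 4, n_scale = 0.06))
  aligned <- gpa_align(ds, scale = TRUE)
  ms <- mean_shape(aligned)
  for (g in names(ms)) {
    idx <- which(aligned$taxon == g)
    acc <- matrix(0, 30, 3)
    for (i in idx) acc <- acc + aligned$coords[i, , ]
    expect_equal(ms[[g]], acc / length(idx), tolerance = 1e-12)
  }
  single <- mean_shape(aligned, by = ifelse(seq_along(aligned$id) == 1,
                                            "solo", "rest"))
  expect_equal(single$solo, aligned$coords[1, , ], tolerance = 1e-14)
  expect_error(mean_shape(aligned, by = rep("g", 3)), "length")
})

test_that("phylogenetic signal detects Brownian structure on the fixture tree", {
  phy <- ape::read.tree(text = fixture_phylogeny())
  hits <- 0
  for (s in 1:5) {
    set.seed(s)
    Y <- cbind(ape::rTraitCont(phy, sigma = 1), ape::rTraitCont(phy, sigma = 1))
    r <- phylogenetic_signal(Y, phy, n_perm = 499, seed = s)
    hits <- hits + (r$p < 0.05)
  }
  expect_gte(hits, 4)

  set.seed(7)
  Yn <- matrix(rnorm(16), 8, 2, dimnames = list(phy$tip.label, NULL))
  rn <- phylogenetic_signal(Yn, phy, n_perm = 199, seed = 1)
  expect_gt(rn$p, 0.01) # null data should not be strongly significant

  bad <- Yn
  rownames(bad)[1] <- "Not_a_tip"
  expect_error(phylogenetic_signal(bad, phy), "differ")
})
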