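test_that("robust targets estimate location and scale consistently", {
  set.seed(1)
  X <- matrix(rnorm(2e4), 1e4, 2, dimnames = list(NULL, c("PC1", "PC2")))
  tg <- build_target(X)
  expect_lt(max(abs(tg$location)), 0.05)
  expect_lt(max(abs(tg$scale - 1)), 0.05)

  # 5% contamination at +20 barely moves the robust estimates (the
  # population median of the mixture sits at 0.066, within the band)
  set.seed(2)
  xc <- c(rnorm(9500), rep(20, 500))
  tgc <- build_target(cbind(PC1 = xc, PC2 = rnorm(10000)))
  expect_lt(abs(tgc$location[1]), 0.1)
  expect_lt(abs(tgc$scale[1] - 1), 0.15)

  expect_error(build_target(cbind(PC1 = rep(1, 50), PC2 = rnorm(50))),
               "zero robust scale")
  expect_error(build_target(matrix(rnorm(10), 5, 2)), "n >= 10")

  # skew-normal fit recovers the sign of the skew
  set.seed(3)
  xs <- exp(rnorm(2000, sd = 0.5))
  tgs <- build_target(cbind(PC1 = xs, PC2 = rnorm(2000)),
                      family = "skew-normal")
  expect_gt(tgs$alpha[1], 0)
})

test_that("the Metropolis sampler reproduces its Gaussian target", {
  tg <- build_target(matrix(rnorm(4e3), 2e3, 2,
                            dimnames = list(NULL, c("PC1", "PC2"))))
  draws <- mcmc_augment(tg, n_new = 5000, seed = 4)
  expect_equal(dim(draws), c(5000, 2))
  expect_lt(max(abs(apply(draws, 2, median) - tg$location)), 0.06)
  rate <- attr(draws, "acceptance_rate")
  expect_true(all(rate > 0.2 & rate < 0.6))

  # equivalence against a fresh draw from the same distribution
  set.seed(5)
  fresh <- matrix(rnorm(1e4), 5000, 2)
  val <- validate_augmentation(fresh, draws, margin = 0.2)
  expect_true(val$accepted)

  # determinism at n_new = 3
  d1 <- mcmc_augment(tg, n_new = 3, seed = 9)
  d2 <- mcmc_augment(tg, n_new = 3, seed = 9)
  expect_identical(d1, d2)
  expect_error(mcmc_augment(tg, n_new = 0), "n_new")
})

test_that("MCMC quantiles converge to the target with sample size", {
  tg <- build_target(matrix(rnorm(4e3), 2e3, 2,
                            dimnames = list(NULL, c("PC1", "PC2"))))
  ks_dist <- vapply(c(500, 5000), function(n) {
    draws <- mcmc_augment(tg, n_new = n, seed = 11)
    suppressWarnings(ks.test(draws[, 1], pnorm, tg$location[1],
                             tg$scale[1])$statistic)
  }, numeric(1))
  expect_lt(ks_dist[2], ks_dist[1])
  expect_lt(ks_dist[2], 0.05)
})

test_that("skew-normal sampling exaggerates the fitted skew direction", {
  set.seed(6)
  xs <- exp(rnorm(2000, sd = 0.5))
  tgs <- build_target(cbind(PC1 = xs, PC2 = rnorm(2000)),
                      family = "skew-normal")
  draws <- mcmc_augment(tgs, n_new = 3000, seed = 7)
  z <- (draws[, 1] - mean(draws[, 1])) / sd(draws[, 1])
  expect_gt(mean(z^3), 0) # positive sample skewness
})

test_that("validation names failing PCs and counts match", {
  set.seed(8)
  real <- matrix(rnorm(2000 * 3), 2000, 3,
                 dimnames = list(NULL, paste0("PC", 1:3)))
  boot <- real[sample(2000, 2000, replace = TRUE), ]
  ok <- validate_augmentation(real, boot, margin = 0.2)
  expect_true(ok$accepted)
  expect_equal(nrow(ok$table), 3)

  shifted <- boot
  shifted[, 1] <- shifted[, 1] + 2
  bad <- validate_augmentation(real, shifted, margin = 0.2)
  expect_false(bad$accepted)
  expect_false(bad$table$equivalent[bad$table$pc == "PC1"])
  expect_true(all(bad$table$equivalent[bad$table$pc != "PC1"]))

  expect_error(validate_augmentation(real, boot[, 1:2]), "mismatch")
})

test_that("balancing reaches targets and never touches original rows", {
  ds <- generate_study(default_study_spec(seed = 12, n_scale = 0.5))
  tab <- pc_table_of(ds, k = 4)
  before <- tab[order(tab$specimen_id), ]
  bal <- balance_dataset(tab, per_class_target = 60, backend = "mcmc",
                         seed = 3)
  counts <- table(bal$data$taxon)
  expect_true(all(counts == 60))

  kept <- bal$data[bal$data$provenance == "original", ]
  kept <- kept[order(kept$specimen_id), ]
  rownames(kept) <- rownames(before) <- NULL
  expect_identical(kept, before) # bit-identical originals

  synth <- bal$data[bal$data$provenance == "synthetic", ]
  expect_true(all(grepl("synth", synth$specimen_id)))

  # match-largest mode balances to the maximum class size
  bal2 <- balance_dataset(tab, backend = "mcmc", mode = "match-largest",
                          seed = 3)
  expect_true(all(table(bal2$data$taxon) == max(table(tab$taxon))))

  # already balanced at target: unchanged
  sub <- tab[tab$taxon %in% names(which(table(tab$taxon) ==
                                          max(table(tab$taxon)))), ]
  bal3 <- balance_dataset(sub, per_class_target = max(table(sub$taxon)),
                          backend = "mcmc", seed = 3)
  expect_equal(nrow(bal3$data), nrow(sub))

  expect_error(balance_dataset(tab, per_class_target = 2), "below")
})
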