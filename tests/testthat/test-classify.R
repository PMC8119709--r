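make_separable <- function(seed, n = 100, gap = 6) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n * 5), n, 5),
             sweep(matrix(rnorm(n * 5), n, 5), 2,
                   rep(gap / sqrt(5), 5), `+`))
  list(X = X, y = rep(c("a", "b"), each = n))
}

test_that("all three classifiers solve the separable simulation", {
  sim <- make_separable(1)
  set.seed(2)
  idx <- sample(200, 150)
  accs <- vapply(c("svm-rbf", "svm-rff", "nsvm"), function(kind) {
    trainer <- if (kind == "nsvm") train_nsvm else train_svm
    m <- trainer(sim$X[idx, ], sim$y[idx], classifier_spec(kind), seed = 1)
    p <- predict(m, sim$X[-idx, ])
    expect_true(all(p$class %in% c("a", "b")))
    expect_equal(rowSums(p$prob), rep(1, 50), tolerance = 1e-9)
    mean(p$class == sim$y[-idx])
  }, numeric(1))
  expect_true(all(accs >= 0.95))
  # radial kernel and Laplacian RFF agree within 5 accuracy points
  expect_lt(abs(accs["svm-rbf"] - accs["svm-rff"]), 0.05 + 1e-9)
})

test_that("shuffled labels yield chance-level accuracy", {
  sim <- make_separable(3)
  set.seed(4)
  y_shuf <- sample(sim$y)
  idx <- sample(200, 140)
  m <- train_svm(sim$X[idx, ], y_shuf[idx], classifier_spec("svm-rbf"),
                 seed = 1)
  p <- predict(m, sim$X[-idx, ])
  acc <- mean(p$class == y_shuf[-idx])
  expect_lt(abs(acc - 0.5), 0.15)
})

test_that("training is deterministic and guards small classes", {
  sim <- make_separable(5, n = 40)
  m1 <- train_svm(sim$X, sim$y, classifier_spec("svm-rff", D = 200),
                  seed = 9)
  m2 <- train_svm(sim$X, sim$y, classifier_spec("svm-rff", D = 200),
                  seed = 9)
  p1 <- predict(m1, sim$X)
  p2 <- predict(m2, sim$X)
  expect_identical(p1$prob, p2$prob)

  expect_error(train_svm(sim$X[1:44, ], rep(c("a", "b"), c(40, 4)),
                         seed = 1), "augment")
  expect_error(train_nsvm(sim$X[1:44, ], rep(c("a", "b"), c(40, 4))),
               "augment")
  expect_error(train_svm(sim$X, rep("a", 80)), "2 classes")
})

test_that("zero-epoch NSVM predicts at chance; features have set width", {
  sim <- make_separable(6, n = 100)
  m0 <- train_nsvm(sim$X, sim$y, classifier_spec("nsvm", epochs = 0),
                   seed = 2)
  p0 <- predict(m0, sim$X)
  expect_lt(abs(mean(p0$class == sim$y) - 0.5), 0.2)

  m <- train_nsvm(sim$X, sim$y,
                  classifier_spec("nsvm", hidden = c(24, 12), epochs = 50),
                  seed = 2)
  feats <- nsvm_features(m, sim$X)
  expect_equal(ncol(feats), 12)
})

test_that("Bayesian optimization finds a known optimum within budget", {
  res <- bayesian_optimize(function(p) (p$x - 2)^2, list(x = c(-5, 5)),
                           budget = 25, seed = 3)
  expect_lt(abs(res$best$x - 2), 0.2)
  expect_equal(nrow(res$log), 25)
  expect_true(res$best$x >= -5 && res$best$x <= 5)

  res5 <- bayesian_optimize(function(p) p$x^2, list(x = c(-1, 1)),
                            budget = 5, seed = 1)
  expect_equal(nrow(res5$log), 5) # exactly budget evaluations

  # non-finite evaluations are logged as failures, search continues
  resf <- bayesian_optimize(function(p) if (p$x < 0) NaN else p$x,
                            list(x = c(-1, 1)), budget = 10, seed = 2)
  expect_true(any(resf$log$failed))
  expect_true(is.finite(resf$value))
  expect_gte(res$best$x, -5)

  expect_error(bayesian_optimize(function(p) 1, list(x = c(0, 1)),
                                 budget = 3), "budget")
  expect_error(bayesian_optimize(function(p) 1, list(x = c(0, Inf)),
                                 budget = 5), "finite")
})

test_that("evaluation protocols never score synthetic rows", {
  ds <- generate_study(separated_study_spec(seed = 3, n_per_class = 40))
  tab <- pc_table_of(ds, k = 5)
  bal <- balance_dataset(tab, per_class_target = 70, backend = "mcmc",
                         seed = 2)
  X <- as.matrix(bal$data[, paste0("PC", 1:5)])
  m <- train_svm(X, bal$data$taxon, classifier_spec("svm-rbf"), seed = 1)
  rep <- evaluate_on_originals(m, bal$data, dataset_name = "sep4")
  # report covers the original rows only
  expect_equal(sum(rep$confusion), sum(bal$data$provenance == "original"))
  expect_equal(nrow(rep$table), 5) # 4 classes + overall
  expect_gte(rep$accuracy, 0.9)

  no_prov <- bal$data[, setdiff(names(bal$data), "provenance")]
  expect_error(evaluate_on_originals(m, no_prov), "provenance")
  empty <- bal$data[bal$data$provenance == "synthetic", ]
  expect_error(evaluate_on_originals(m, empty), "no original")
})

test_that("raw 70/30 protocol splits exactly and reproducibly", {
  ds <- generate_study(separated_study_spec(seed = 7, n_per_class = 40))
  tab <- pc_table_of(ds, k = 5)
  r1 <- raw_split_protocol(tab, classifier_spec("svm-rbf"), seed = 5)
  r2 <- raw_split_protocol(tab, classifier_spec("svm-rbf"), seed = 5)
  expect_identical(r1$table, r2$table)
  split <- attr(r1, "split")
  expect_equal(length(split$train), 4 * round(0.7 * 40))
  expect_equal(length(split$test), 160 - length(split$train))

  small <- tab[c(1:3, 41:80, 81:120, 121:160), ]
  expect_error(raw_split_protocol(small), "stratify")
})
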