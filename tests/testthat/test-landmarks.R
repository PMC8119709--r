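test_that("centroid size matches closed forms and a brute-force oracle", {
  square <- rbind(c(0.5, 0.5, 0), c(0.5, -0.5, 0),
                  c(-0.5, 0.5, 0), c(-0.5, -0.5, 0))
  expect_equal(centroid_size(square), sqrt(2), tolerance = 1e-12)

  set.seed(42)
  config <- template_pit() + matrix(rnorm(90, sd = 0.05), 30, 3)
  # brute-force oracle: explicit double loop over landmarks and axes
  ctr <- unname(colMeans(config))
  acc <- 0
  for (i in seq_len(nrow(config))) {
    for (j in 1:3) acc <- acc + (config[i, j] - ctr[j])^2
  }
  expect_equal(centroid_size(config), unname(sqrt(acc)), tolerance = 1e-12)

  moved <- rigid_motion(config, seed = 7)
  expect_equal(centroid_size(moved), centroid_size(config),
               tolerance = 1e-12)
})

test_that("centroid size is exactly homogeneous and guards degenerate input", {
  set.seed(3)
  config <- template_pit() + matrix(rnorm(90, sd = 0.02), 30, 3)
  for (c_scale in c(0.1, 2, 17.5)) {
    expect_equal(centroid_size(c_scale * config),
                 c_scale * centroid_size(config), tolerance = 1e-12)
  }
  expect_error(centroid_size(matrix(1, 1, 3)), "at least 2")
})

test_that("validate_configuration flags each semantic violation", {
  expect_length(validate_configuration(template_pit()), 0)

  swapped <- template_pit()
  swapped[c(5, 18), ] <- swapped[c(18, 5), ] # LM5 <-> a patch landmark
  expect_true("LM5 not deepest" %in% validate_configuration(swapped))

  wide <- template_pit()
  wide[3, 2] <- -3
  wide[4, 2] <- 3 # width now exceeds length
  expect_true("axis order" %in% validate_configuration(wide))

  stray <- template_pit()
  stray[20, 1] <- 10 # patch point far outside the rim
  expect_true("patch outside rim" %in% validate_configuration(stray))

  expect_error(validate_configuration(matrix(0, 10, 3)), "30x3")
})

test_that("morphologika round trip preserves coordinates and labels", {
  path <- withr::local_tempfile(fileext = ".txt")
  ds <- write_fixture_morphologika(path)
  back <- read_morphologika(path)
  expect_length(back$id, 2)
  expect_identical(back$id, ds$id)
  expect_identical(back$taxon, ds$taxon)
  for (i in 1:2) {
    expect_equal(back$configurations[[i]], ds$configurations[[i]],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }

  # full-precision coordinates survive (randomized property)
  set.seed(9)
  noisy <- pit_dataset(
    lapply(1:3, function(i) template_pit() + matrix(rnorm(90), 30, 3) * 1e-7),
    id = paste0("s", 1:3), taxon = "t", family = "Canidae")
  p2 <- withr::local_tempfile(fileext = ".txt")
  write_morphologika(noisy, p2)
  back2 <- read_morphologika(p2)
  for (i in 1:3) {
    expect_equal(back2$configurations[[i]], noisy$configurations[[i]],
                 tolerance = 1e-13, ignore_attr = TRUE)
  }
})

test_that("morphologika parser rejects malformed files with line numbers", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_fixture_morphologika(path)
  lines <- readLines(path)

  bad <- lines
  bad[which(bad == "[landmarks]") + 1L] <- "29"
  p <- withr::local_tempfile()
  writeLines(bad, p)
  expect_error(read_morphologika(p), "29")

  # fuzz: mutate each header keyword in turn; every mutation must error
  for (key in c("[individuals]", "[landmarks]", "[dimensions]",
                "[rawpoints]")) {
    mut <- lines
    mut[mut == key] <- sub("\\[", "[zz", key)
    pm <- withr::local_tempfile()
    writeLines(mut, pm)
    expect_error(suppressWarnings(read_morphologika(pm)), "morphologika")
  }

  # non-numeric coordinate row names its line
  badc <- lines
  i <- grep("^'", badc)[1L] + 3L
  badc[i] <- "not a number"
  pc <- withr::local_tempfile()
  writeLines(badc, pc)
  expect_error(read_morphologika(pc), paste0("line ", i))

  expect_error(read_morphologika(withr::local_tempfile()), "not found")
})

test_that("dataset container enforces ids and provenance", {
  cfg <- template_pit()
  expect_error(pit_dataset(list(cfg, cfg), id = c("a", "a"), taxon = "t"),
               "unique")
  expect_error(pit_dataset(list(cfg), id = "a", taxon = "t",
                           provenance = "fabricated"), "provenance")
  ds <- pit_dataset(list(cfg, cfg), id = c("a", "b"), taxon = "t",
                    family = "Canidae")
  expect_s3_class(subset_dataset(ds, 1), "pit_dataset")
  man <- dataset_manifest(ds)
  expect_named(man, c("specimen_id", "taxon", "family", "provenance",
                      "centroid_size"))
  expect_error(write_morphologika(subset_dataset(ds, integer(0)),
                                  tempfile()), "at least one")
})
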