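# Shared fixtures, built in code at test time.

# random rigid motion (proper rotation + translation) of a configuration
rigid_motion <- function(config, seed) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3, 3)
  qr_d <- qr(A)
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  sweep(config %*% R, 2, rnorm(3, sd = 2), `+`)
}

# four-class study with class-mean separation >= 4 pooled robust sd in the
# first 5 PCs: large size spacing plus depth/elongation contrasts
separated_study_spec <- function(seed, n_per_class = 60) {
  study_spec(list(
    taxon_spec("Taxon A", "Canidae", n_per_class, 0.7, log_cs_sd = 0.15,
               depth_scale = 0.6, elongation = 1.0,
               allometric_slope = 0.05, within_sd = 0.065),
    taxon_spec("Taxon B", "Felidae", n_per_class, 1.6, log_cs_sd = 0.15,
               depth_scale = 1.0, elongation = 1.35,
               allometric_slope = 0.05, within_sd = 0.065),
    taxon_spec("Taxon C", "Hyaenidae", n_per_class, 2.5, log_cs_sd = 0.15,
               depth_scale = 1.5, elongation = 1.0,
               allometric_slope = 0.05, within_sd = 0.065),
    taxon_spec("Taxon D", "Ursidae", n_per_class, 3.4, log_cs_sd = 0.15,
               depth_scale = 1.0, elongation = 1.6,
               allometric_slope = 0.05, within_sd = 0.065)
  ), seed = seed)
}

# PC-score table for a dataset: form-space GPA + PCA, k leading PCs
pc_table_of <- function(dataset, k = 5) {
  aligned <- gpa_align(dataset, scale = FALSE)
  pc_score_table(pca_reduce(aligned), k = k)
}

# a two-specimen morphologika fixture written to a temp file
write_fixture_morphologika <- function(path) {
  ds <- pit_dataset(
    list(template_pit(), template_pit(2.4, 1.8, 0.8)),
    id = c("Ursus_001", "Crocuta_001"),
    taxon = c("Ursus arctos", "Crocuta crocuta"),
    family = c("Ursidae", "Hyaenidae")
  )
  write_morphologika(ds, path)
  ds
}
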