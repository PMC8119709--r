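# Synthetic tooth-pit generator.
#
# Stands in for scanned carnivore pits: every downstream stage (GPA, robust
# statistics, anomaly filtering, augmentation, classification) is testable
# against data whose generating process is known. The generator works at the
# landmark level only -- no meshes or point clouds are simulated.

#' Template tooth-pit shape
#'
#' A parabolic bowl sampled by the 30-landmark model: an elliptical rim in
#' the x-y plane (bone surface at z = 0), LM1/LM2 on the long axis, LM3/LM4
#' on the perpendicular width axis, LM5 at the apex of the bowl (minimum z)
#' and a 5x5 semilandmark patch over the pit interior in row-major order.
#' Passes [validate_configuration()] by construction.
#'
#' @param length_mm rim length along the LM1-LM2 axis (mm).
#' @param width_mm rim width along the LM3-LM4 axis (mm).
#' @param depth_mm depth of the deepest point LM5 below the surface (mm).
#' @return A 30x3 coordinate matrix.
#' @export
template_pit <- function(length_mm = 2.0, width_mm = 1.6, depth_mm = 0.6) {
  stopifnot(length_mm >= width_mm, depth_mm > 0)
  a <- length_mm / 2
  b <- width_mm / 2
  fixed <- rbind(
    c(1.00 * a, 0, 0),    # LM1: length extremity, farthest from width axis
    c(-0.90 * a, 0, 0),   # LM2: opposite length extremity
    c(0.05 * a, -b, 0),   # LM3: left width extremity
    c(0.05 * a, b, 0),    # LM4: right width extremity
    c(0.05 * a, 0, -depth_mm) # LM5: deepest point
  )
  u <- seq(-0.75, 0.75, length.out = PATCH_ROWS)
  g <- expand.grid(y = u, x = u)[, c("x", "y")] # row-major over x rows
  px <- 0.05 * a + g$x * a
  py <- g$y * b
  bowl <- 1 - (g$x^2 / 0.75^2 + g$y^2 / 0.75^2) / 2
  pz <- -0.9 * depth_mm * pmax(bowl, 0.05)
  as_config(rbind(fixed, cbind(px, py, pz)))
}

#' Specify one synthetic taxon
#'
#' Parameters of the per-class generating process. Centroid sizes are
#' log-normal; pit depth and elongation rescale the template; allometric
#' displacement couples shape to log centroid size; within-class noise is an
#' isotropic Gaussian whose scale is inflated by `tail_weight` with
#' probability 0.1 (a scale mixture producing heavy-tailed classes); a
#' `floor(anomaly_fraction * n)` subset is planted as anomalies by coherently
#' displacing the semilandmark patch.
#'
#' @param name taxon label.
#' @param family one of `"Canidae"`, `"Felidae"`, `"Hyaenidae"`, `"Ursidae"`.
#' @param n number of pits (>= 1).
#' @param log_cs_mean,log_cs_sd mean and sd of log centroid size (log mm).
#' @param depth_scale mean relative pit depth (multiplier on template z).
#' @param elongation mean length/width stretch (>= 1) along the LM1-LM2 axis.
#' @param allometric_slope per-coordinate shape displacement per unit log
#'   centroid size (0 = no allometry).
#' @param within_sd within-class isotropic coordinate noise (mm, > 0).
#' @param tail_weight >= 1; noise-scale multiplier applied with prob. 0.1.
#' @param anomaly_fraction fraction in \[0, 0.1\] of pits planted as anomalies.
#' @return A `taxon_spec` list.
#' @export
taxon_spec <- function(name, family, n, log_cs_mean, log_cs_sd = 0.25,
                       depth_scale = 1, elongation = 1,
                       allometric_slope = 0, within_sd = 0.1,
                       tail_weight = 1, anomaly_fraction = 0) {
  if (n < 1L) stop("taxon ", name, ": n must be >= 1")
  if (log_cs_sd <= 0) stop("taxon ", name, ": log_cs_sd must be > 0")
  if (within_sd <= 0) stop("taxon ", name, ": within_sd must be > 0")
  if (elongation < 1) stop("taxon ", name, ": elongation must be >= 1")
  if (tail_weight < 1) stop("taxon ", name, ": tail_weight must be >= 1")
  if (anomaly_fraction < 0 || anomaly_fraction > 0.1) {
    stop("taxon ", name, ": anomaly_fraction must be in [0, 0.1]")
  }
  if (!family %in% c("Canidae", "Felidae", "Hyaenidae", "Ursidae")) {
    stop("taxon ", name, ": unknown family ", family)
  }
  structure(list(name = name, family = family, n = as.integer(n),
                 log_cs_mean = log_cs_mean, log_cs_sd = log_cs_sd,
                 depth_scale = depth_scale, elongation = elongation,
                 allometric_slope = allometric_slope, within_sd = within_sd,
                 tail_weight = tail_weight,
                 anomaly_fraction = anomaly_fraction),
            class = "taxon_spec")
}

# Planted anomalies are displaced by this many within-class sd along one
# coordinate axis (coherently over the whole patch); must stay >= 6 so the
# planting invariant is directly assertable.
ANOMALY_SHIFT_SD <- 10

#' Default eight-taxon study specification
#'
#' Reproduces the design constants of the reference sample: eight carnivore
#' taxa with 69/86/80/89/53/77/84/82 pits (620 in total). Per-class size,
#' depth, elongation and tail-weight defaults are qualitative: lions leave
#' the largest and some of the deepest pits, foxes the smallest; wolves
#' leave superficial pits; foxes and African wild dogs leave deep pits
#' relative to their size; felids leave more elongated pits than canids;
#' lions and wolves are heavy-tailed classes. All defaults are overridable.
#'
#' @param seed integer seed stored in the spec.
#' @param anomaly_fraction planted-anomaly fraction applied to every class.
#' @param allometric_slope allometric coupling applied to every class.
#' @param n_scale optional multiplier on every class size (testing aid);
#'   counts are rounded and kept >= 4.
#' @return A `study_spec` list with fields `taxa`, `seed`, `template_shape`.
#' @export
default_study_spec <- function(seed = 1L, anomaly_fraction = 0,
                               allometric_slope = 0.05, n_scale = 1) {
  tx <- list(
    taxon_spec("Ursus arctos",    "Ursidae",   69, 1.85, depth_scale = 1.05,
               elongation = 1.10, allometric_slope = allometric_slope,
               anomaly_fraction = anomaly_fraction),
    taxon_spec("Crocuta crocuta", "Hyaenidae", 86, 1.70, depth_scale = 1.00,
               elongation = 1.15, allometric_slope = allometric_slope,
               anomaly_fraction = anomaly_fraction),
    taxon_spec("Canis lupus",     "Canidae",   80, 1.10, depth_scale = 0.60,
               elongation = 1.00, allometric_slope = allometric_slope,
               tail_weight = 2, anomaly_fraction = anomaly_fraction),
    taxon_spec("Lycaon pictus",   "Canidae",   89, 1.25, depth_scale = 1.30,
               elongation = 1.05, allometric_slope = allometric_slope,
               anomaly_fraction = anomaly_fraction),
    taxon_spec("Vulpes vulpes",   "Canidae",   53, 0.90, depth_scale = 1.30,
               elongation = 1.00, allometric_slope = allometric_slope,
               anomaly_fraction = anomaly_fraction),
    taxon_spec("Panthera onca",   "Felidae",   77, 1.40, depth_scale = 1.10,
               elongation = 1.30, allometric_slope = allometric_slope,
               anomaly_fraction = anomaly_fraction),
    taxon_spec("Panthera pardus", "Felidae",   84, 1.55, depth_scale = 1.10,
               elongation = 1.30, allometric_slope = allometric_slope,
               anomaly_fraction = anomaly_fraction),
    taxon_spec("Panthera leo",    "Felidae",   82, 2.00, depth_scale = 1.40,
               elongation = 1.25, allometric_slope = allometric_slope,
               tail_weight = 2, anomaly_fraction = anomaly_fraction)
  )
  if (n_scale != 1) {
    tx <- lapply(tx, function(t) {
      t$n <- max(4L, as.integer(round(t$n * n_scale)))
      t
    })
  }
  study_spec(tx, seed = seed)
}

#' Assemble a study specification
#'
#' @param taxa non-empty list of [taxon_spec()] objects with unique names.
#' @param seed integer seed.
#' @param template_shape 30x3 reference configuration
#'   (default [template_pit()]).
#' @return A `study_spec` list.
#' @export
study_spec <- function(taxa, seed = 1L, template_shape = template_pit()) {
  if (!length(taxa)) stop("taxa must be non-empty")
  nm <- vapply(taxa, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate taxon names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  structure(list(taxa = taxa, seed = as.integer(seed),
                 template_shape = as_config(template_shape)),
            class = "study_spec")
}

# Deterministic per-specimen build: template -> depth scale -> elongation ->
# normalise to unit centroid size -> allometric shape displacement ->
# shape-space noise -> scale to the drawn centroid size.
#
# Noise lives in shape space (scaled by specimen size), so shape is exactly
# independent of size when allometric_slope = 0; within_sd is the
# per-coordinate noise in mm at the class's geometric-mean centroid size.
build_taxon_configs <- function(spec, template) {
  n <- spec$n
  log_cs <- stats::rnorm(n, spec$log_cs_mean, spec$log_cs_sd)
  heavy <- stats::runif(n) < 0.1
  relsd <- spec$within_sd / exp(spec$log_cs_mean)
  noise_sd <- relsd * ifelse(heavy, spec$tail_weight, 1)
  # allometric displacement field: deepening of the bowl with size, unit
  # Frobenius norm so allometric_slope is a per-coordinate shape
  # displacement per unit log centroid size
  field <- matrix(0, N_LANDMARKS, N_DIMS)
  field[, 3L] <- -abs(template[, 3L] - max(template[, 3L]))
  field <- field / sqrt(sum(field^2))
  n_anom <- floor(spec$anomaly_fraction * n)
  anom_idx <- if (n_anom > 0) seq.int(n - n_anom + 1L, n) else integer(0)
  anom_sign <- sample(c(-1, 1), n, replace = TRUE)
  noise <- array(stats::rnorm(n * N_LANDMARKS * N_DIMS),
                 dim = c(N_LANDMARKS, N_DIMS, n))
  configs <- vector("list", n)
  for (i in seq_len(n)) {
    shape <- template
    shape[, 3L] <- shape[, 3L] * spec$depth_scale
    shape[, 1L] <- shape[, 1L] * spec$elongation
    shape <- shape / centroid_size(shape)
    shape <- shape + spec$allometric_slope *
      (log_cs[i] - spec$log_cs_mean) * field
    shape <- shape + noise_sd[i] * noise[, , i]
    if (i %in% anom_idx) {
      # coherent depth displacement of the whole patch: depth is where
      # natural pit variation concentrates, so planted anomalies stay
      # visible after dimensionality reduction
      shape[6:30, 3L] <- shape[6:30, 3L] +
        anom_sign[i] * ANOMALY_SHIFT_SD * relsd
    }
    configs[[i]] <- shape * exp(log_cs[i])
  }
  list(configs = configs, log_cs = log_cs, anomaly = seq_len(n) %in% anom_idx)
}

#' Generate one taxon's synthetic sample
#'
#' Draws `spec$n` configurations from the taxon's generating process (see
#' [taxon_spec()]). Planted anomalies, if any, are the last
#' `floor(anomaly_fraction * n)` specimens and are displaced by
#' `10 * within_sd` along the depth (z) axis coherently over the whole
#' semilandmark patch; the `is_anomaly` attribute records them.
#'
#' @param spec a [taxon_spec()].
#' @param template 30x3 reference configuration.
#' @param seed integer seed; the draw is bit-reproducible.
#' @return A `pit_dataset` with provenance `"original"` and attribute
#'   `is_anomaly` (logical vector).
#' @export
generate_taxon_sample <- function(spec, template = template_pit(), seed = 1L) {
  stopifnot(inherits(spec, "taxon_spec"))
  template <- as_config(template)
  if (length(validate_configuration(template))) {
    stop("template fails validate_configuration")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  built <- build_taxon_configs(spec, template)
  slug <- gsub("[^A-Za-z]", "", spec$name)
  ds <- pit_dataset(built$configs,
                    id = sprintf("%s_%03d", slug, seq_len(spec$n)),
                    taxon = spec$name, family = spec$family,
                    provenance = "original")
  attr(ds, "is_anomaly") <- built$anomaly
  ds
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a full synthetic study
#'
#' Concatenates per-taxon samples (each seeded deterministically from
#' `spec$seed`) with unique specimen ids.
#'
#' @param spec a [study_spec()].
#' @return A `pit_dataset`; attribute `is_anomaly` flags planted anomalies
#'   and attribute `class_counts` tabulates per-class sizes.
#' @export
generate_study <- function(spec) {
  stopifnot(inherits(spec, "study_spec"))
  parts <- vector("list", length(spec$taxa))
  anom <- logical(0)
  for (i in seq_along(spec$taxa)) {
    parts[[i]] <- generate_taxon_sample(spec$taxa[[i]], spec$template_shape,
                                        seed = spec$seed * 1000L + i)
    anom <- c(anom, attr(parts[[i]], "is_anomaly"))
  }
  ds <- do.call(bind_datasets, parts)
  attr(ds, "is_anomaly") <- anom
  attr(ds, "class_counts") <- table(ds$taxon)
  ds
}

#' Fixture phylogeny for the eight default taxa
#'
#' An ultrametric stand-in tree (newick text) with family-consistent clades:
#' the three canids form a clade, the three felids form a clade, and
#' Hyaenidae (feliform) attaches to the felid side before the
#' canid/caniform split. Branch lengths are arbitrary but positive and
#' root-to-tip path lengths are equal.
#'
#' @return A single newick string with 8 tips.
#' @export
fixture_phylogeny <- function() {
  paste0(
    "(((Canis_lupus:14,(Lycaon_pictus:10,Vulpes_vulpes:10):4):36,",
    "Ursus_arctos:50):10,",
    "((Panthera_leo:8,(Panthera_pardus:6,Panthera_onca:6):2):32,",
    "Crocuta_crocuta:40):20);"
  )
}
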