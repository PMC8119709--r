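# Landmark configurations and morphologika I/O.
#
# The landmark model is fixed at 30 points per pit: five fixed landmarks
# (LM1/LM2 span the maximal length, LM3/LM4 the perpendicular maximal width,
# LM5 the deepest point) followed by a 5 x 5 semilandmark patch sampling the
# pit interior, stored row-major as LM6..LM30. Coordinates are in mm with the
# bone surface near z = 0 and the pit interior at z < 0.

N_LANDMARKS <- 30L
N_DIMS <- 3L
PATCH_ROWS <- 5L
PATCH_COLS <- 5L

#' Number of landmarks in the tooth-pit model
#'
#' @return Integer, always 30 (5 fixed landmarks + a 5x5 semilandmark patch).
#' @export
n_landmarks <- function() N_LANDMARKS

as_config <- function(coords) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (!all(dim(coords) == c(N_LANDMARKS, N_DIMS))) {
    stop("a landmark configuration must be a ", N_LANDMARKS, "x", N_DIMS,
         " matrix, got ", nrow(coords), "x", ncol(coords))
  }
  if (!all(is.finite(coords))) stop("landmark coordinates must be finite")
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  coords
}

#' Validate a tooth-pit landmark configuration
#'
#' Checks the geometric semantics of the 30-landmark model and returns a
#' character vector of violations (empty when the configuration is valid):
#'
#' * `"LM5 not deepest"` — LM5 must have the minimum z coordinate;
#' * `"axis order"` — the LM1–LM2 length must be >= the LM3–LM4 width;
#' * `"LM1 orientation"` — LM1 must lie farther from the width axis than LM2;
#' * `"patch outside rim"` — every patch semilandmark must project inside the
#'   bounding box of LM1..LM4 in the x–y plane (within `tol`).
#'
#' Violations are reported, never auto-corrected: silent reorientation could
#' mask digitisation errors.
#'
#' @param config 30x3 numeric matrix of landmark coordinates (mm).
#' @param tol numeric tolerance for the geometric comparisons.
#' @return Character vector of violation labels; `character(0)` if valid.
#' @export
validate_configuration <- function(config, tol = 1e-9) {
  config <- as_config(config)
  violations <- character(0)
  if (config[5L, 3L] > min(config[, 3L]) + tol) {
    violations <- c(violations, "LM5 not deepest")
  }
  len <- sqrt(sum((config[1L, ] - config[2L, ])^2))
  wid <- sqrt(sum((config[3L, ] - config[4L, ])^2))
  if (len < wid - tol) violations <- c(violations, "axis order")
  # LM1 is defined as the length extremity farthest from the width axis
  # (the line through LM3-LM4); LM2 the closest.
  mid <- (config[3L, 1:2] + config[4L, 1:2]) / 2
  wdir <- config[4L, 1:2] - config[3L, 1:2]
  wnorm <- sqrt(sum(wdir^2))
  if (wnorm > tol) {
    wdir <- wdir / wnorm
    d1 <- abs(sum((config[1L, 1:2] - mid) * c(-wdir[2L], wdir[1L])))
    d2 <- abs(sum((config[2L, 1:2] - mid) * c(-wdir[2L], wdir[1L])))
    if (d1 < d2 - tol) violations <- c(violations, "LM1 orientation")
  }
  patch <- config[6:30, 1:2, drop = FALSE]
  rim <- config[1:4, 1:2, drop = FALSE]
  lo <- apply(rim, 2L, min) - tol
  hi <- apply(rim, 2L, max) + tol
  inside <- patch[, 1L] >= lo[1L] & patch[, 1L] <= hi[1L] &
    patch[, 2L] >= lo[2L] & patch[, 2L] <= hi[2L]
  if (!all(inside)) violations <- c(violations, "patch outside rim")
  violations
}

#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of all landmarks from
#' their centroid; the standard geometric-morphometric size measure.
#' Invariant to rotation and translation, and homogeneous of degree one
#' under scaling.
#'
#' @param config numeric matrix (landmarks x dimensions), at least 2 rows.
#' @return Positive numeric scalar (mm when coordinates are mm).
#' @export
centroid_size <- function(config) {
  config <- as.matrix(config)
  if (nrow(config) < 2L) stop("centroid size needs at least 2 landmarks")
  if (!all(is.finite(config))) stop("landmark coordinates must be finite")
  centred <- sweep(config, 2L, colMeans(config))
  sqrt(sum(centred^2))
}

#' Construct a labelled tooth-pit dataset
#'
#' A `pit_dataset` houses specimens (landmark configurations) together with
#' their specimen ids, taxon and family labels, and a provenance flag
#' distinguishing original from synthetic (augmented) specimens.
#'
#' @param configurations list of 30x3 coordinate matrices.
#' @param id character vector of unique specimen ids.
#' @param taxon character vector of taxon labels.
#' @param family character vector of family labels.
#' @param provenance character vector, each `"original"` or `"synthetic"`.
#' @return An object of class `pit_dataset`.
#' @export
pit_dataset <- function(configurations, id, taxon, family = NA_character_,
                        provenance = "original") {
  n <- length(configurations)
  id <- as.character(id)
  taxon <- rep_len(as.character(taxon), n)
  family <- rep_len(as.character(family), n)
  provenance <- rep_len(as.character(provenance), n)
  if (length(id) != n) stop("length(id) must match number of configurations")
  if (anyDuplicated(id)) stop("specimen ids must be unique")
  if (!all(provenance %in% c("original", "synthetic"))) {
    stop("provenance must be 'original' or 'synthetic'")
  }
  configurations <- lapply(configurations, as_config)
  structure(list(configurations = configurations, id = id, taxon = taxon,
                 family = family, provenance = provenance),
            class = "pit_dataset")
}

#' @export
print.pit_dataset <- function(x, ...) {
  cat("<pit_dataset> ", length(x$id), " specimens, ",
      length(unique(x$taxon)), " taxa\n", sep = "")
  print(table(taxon = x$taxon, provenance = x$provenance))
  invisible(x)
}

#' @export
length.pit_dataset <- function(x) length(x$id)

#' Subset a pit dataset by specimen index
#'
#' @param dataset a `pit_dataset`.
#' @param idx integer or logical index vector.
#' @return A `pit_dataset` containing the selected specimens.
#' @export
subset_dataset <- function(dataset, idx) {
  pit_dataset(dataset$configurations[idx], dataset$id[idx],
              dataset$taxon[idx], dataset$family[idx],
              dataset$provenance[idx])
}

#' Combine pit datasets
#'
#' @param ... `pit_dataset` objects with disjoint specimen ids.
#' @return A single concatenated `pit_dataset`.
#' @export
bind_datasets <- function(...) {
  parts <- list(...)
  pit_dataset(
    do.call(c, lapply(parts, `[[`, "configurations")),
    do.call(c, lapply(parts, `[[`, "id")),
    do.call(c, lapply(parts, `[[`, "taxon")),
    do.call(c, lapply(parts, `[[`, "family")),
    do.call(c, lapply(parts, `[[`, "provenance"))
  )
}

#' Dataset manifest
#'
#' One row per specimen: id, taxon, family, provenance and centroid size.
#'
#' @param dataset a `pit_dataset`.
#' @return A data.frame.
#' @export
dataset_manifest <- function(dataset) {
  data.frame(
    specimen_id = dataset$id,
    taxon = dataset$taxon,
    family = dataset$family,
    provenance = dataset$provenance,
    centroid_size = vapply(dataset$configurations, centroid_size, numeric(1)),
    stringsAsFactors = FALSE
  )
}

# ---- morphologika format ---------------------------------------------------
# Classic text dialect: [individuals], [landmarks], [dimensions], optional
# [names] and [labels*], then [rawpoints] with one "'<name>" line per
# individual followed by one whitespace-separated coordinate row per landmark.
# Unknown bracketed sections are skipped with a warning.

#' Read a morphologika landmark file
#'
#' Parses the classic bracketed morphologika text dialect (`[individuals]`,
#' `[landmarks]`, `[dimensions]`, optional `[names]`, `[rawpoints]`; a
#' `[wireframe]` section, if present, is ignored). Individual names of the
#' form `taxon_suffix` populate the taxon label; a parallel `[labels]`
#' section, when present, overrides them.
#'
#' @param path path to a morphologika file.
#' @return A `pit_dataset`.
#' @export
read_morphologika <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  trimmed <- trimws(lines)
  headers <- grep("^\\[.*\\]$", trimmed)
  if (!length(headers)) stop("morphologika parse error line 1: no [sections]")
  sections <- list()
  keys <- tolower(gsub("^\\[|\\]$", "", trimmed[headers]))
  bounds <- c(headers, length(lines) + 1L)
  for (i in seq_along(headers)) {
    body <- seq.int(headers[i] + 1L, bounds[i + 1L] - 1L)
    body <- body[body <= length(lines)]
    sections[[keys[i]]] <- list(start = headers[i], lines = trimmed[body],
                                idx = body)
  }
  known <- c("individuals", "landmarks", "dimensions", "names", "labels",
             "labelvalues", "rawpoints", "wireframe")
  unknown <- setdiff(keys, known)
  if (length(unknown)) {
    warning("ignoring unknown morphologika sections: ",
            paste(unknown, collapse = ", "))
  }
  get_int <- function(key) {
    sec <- sections[[key]]
    if (is.null(sec)) stop("morphologika parse error: missing [", key, "]")
    vals <- sec$lines[nzchar(sec$lines)]
    if (!length(vals)) {
      stop("morphologika parse error line ", sec$start, ": empty [", key, "]")
    }
    x <- suppressWarnings(as.integer(vals[1L]))
    if (is.na(x)) {
      stop("morphologika parse error line ", sec$idx[1L],
           ": non-integer [", key, "]")
    }
    x
  }
  n_ind <- get_int("individuals")
  n_lm <- get_int("landmarks")
  n_dim <- get_int("dimensions")
  if (n_ind < 1L) stop("morphologika parse error: [individuals] must be >= 1")
  if (n_lm != N_LANDMARKS || n_dim != N_DIMS) {
    stop("morphologika parse error line ", sections$landmarks$start,
         ": expected ", N_LANDMARKS, " landmarks x ", N_DIMS,
         " dimensions, file declares ", n_lm, " x ", n_dim)
  }
  raw <- sections$rawpoints
  if (is.null(raw)) stop("morphologika parse error: missing [rawpoints]")
  keep <- nzchar(raw$lines)
  rlines <- raw$lines[keep]
  ridx <- raw$idx[keep]
  name_rows <- grep("^'", rlines)
  if (length(name_rows) != n_ind) {
    stop("morphologika parse error line ", raw$start, ": found ",
         length(name_rows), " individuals in [rawpoints], header declares ",
         n_ind)
  }
  nb <- c(name_rows, length(rlines) + 1L)
  configs <- vector("list", n_ind)
  names_ind <- character(n_ind)
  for (i in seq_len(n_ind)) {
    names_ind[i] <- sub("^'", "", rlines[nb[i]])
    rows <- seq.int(nb[i] + 1L, nb[i + 1L] - 1L)
    if (length(rows) != n_lm) {
      stop("morphologika parse error line ", ridx[nb[i]], ": individual '",
           names_ind[i], "' has ", length(rows), " landmark rows, expected ",
           n_lm)
    }
    mat <- matrix(NA_real_, n_lm, n_dim)
    for (j in seq_along(rows)) {
      vals <- suppressWarnings(as.numeric(strsplit(rlines[rows[j]],
                                                   "[ \t]+")[[1]]))
      if (length(vals) != n_dim || anyNA(vals)) {
        stop("morphologika parse error line ", ridx[rows[j]],
             ": non-numeric or wrong-arity coordinate row")
      }
      mat[j, ] <- vals
    }
    configs[[i]] <- mat
  }
  taxon <- sub("_[^_]*$", "", names_ind)
  lab <- sections$labelvalues
  if (!is.null(lab)) {
    vals <- lab$lines[nzchar(lab$lines)]
    if (length(vals) >= n_ind) taxon <- vals[seq_len(n_ind)]
  }
  pit_dataset(configs, id = names_ind, taxon = taxon)
}

#' Write a morphologika landmark file
#'
#' Inverse of [read_morphologika()]: coordinates survive a round trip to
#' better than 1e-12 (17 significant digits are written) and specimen ids and
#' taxon labels are preserved exactly.
#'
#' @param dataset a `pit_dataset` of 30x3 configurations.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_morphologika <- function(dataset, path) {
  stopifnot(inherits(dataset, "pit_dataset"))
  n <- length(dataset$id)
  if (n < 1L) stop("morphologika requires at least one individual")
  con <- file(path, open = "wt")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("[individuals]", as.character(n),
     "[landmarks]", as.character(N_LANDMARKS),
     "[dimensions]", as.character(N_DIMS),
     "[labels]", "taxon", "[labelvalues]")
  wl(dataset$taxon)
  wl("[rawpoints]")
  for (i in seq_len(n)) {
    wl(paste0("'", dataset$id[i]))
    coords <- dataset$configurations[[i]]
    wl(apply(coords, 1L, function(r)
      paste(formatC(r, digits = 17, format = "g"), collapse = " ")))
  }
  invisible(path)
}
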