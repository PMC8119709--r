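# Orchestration of the full analysis: generate/ingest -> validate -> GPA ->
# PCA -> stats -> clean -> augment -> train -> evaluate, with one global
# seed deterministically deriving every stage seed so partial reruns match
# full runs. Stage artifacts are immutable CSV files; stages communicate
# only through them.

GROUPING_MEMBERS <- list(
  "Pleistocene European Taxa" = c("Ursus arctos", "Vulpes vulpes",
                                  "Crocuta crocuta", "Panthera pardus",
                                  "Panthera leo", "Canis lupus"),
  "African Taxa" = c("Crocuta crocuta", "Panthera pardus", "Lycaon pictus",
                     "Panthera leo"),
  "Taxonomic Family" = c("Ursus arctos", "Crocuta crocuta", "Canis lupus",
                         "Lycaon pictus", "Vulpes vulpes", "Panthera onca",
                         "Panthera pardus", "Panthera leo"),
  "Canidae" = c("Vulpes vulpes", "Lycaon pictus", "Canis lupus"),
  "Felidae" = c("Panthera pardus", "Panthera onca", "Panthera leo")
)

#' Pipeline configuration
#'
#' @param input a [study_spec()] (synthetic input) or a morphologika file
#'   path.
#' @param form_space align in form space (`TRUE`, default: size retained)
#'   or shape space.
#' @param retained_pcs `"auto"` (permutation selection) or a positive
#'   integer override.
#' @param anomaly_threshold isolation-forest removal threshold.
#' @param backend augmentation backend, `"mcmc"` or `"wgan-gp"`.
#' @param per_class_target augmentation target class size; the Taxonomic
#'   Family grouping instead balances to its largest class.
#' @param classifier a [classifier_spec()].
#' @param groupings character vector naming the sub-datasets to analyse
#'   (subset of the five standard groupings).
#' @param seed global integer seed.
#' @param run_raw_protocol also run the 70/30 no-augmentation baseline.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(input = default_study_spec(),
                            form_space = TRUE, retained_pcs = "auto",
                            anomaly_threshold = 0.65, backend = "mcmc",
                            per_class_target = 100L,
                            classifier = classifier_spec(),
                            groupings = names(GROUPING_MEMBERS),
                            seed = 1L, run_raw_protocol = TRUE) {
  if (!inherits(input, "study_spec") &&
      !(is.character(input) && length(input) == 1L)) {
    stop("config error: input must be a study_spec or a file path")
  }
  if (!identical(retained_pcs, "auto")) {
    retained_pcs <- as.integer(retained_pcs)
    if (is.na(retained_pcs) || retained_pcs < 1L) {
      stop("config error: retained_pcs must be 'auto' or a positive integer")
    }
  }
  if (anomaly_threshold <= 0 || anomaly_threshold >= 1) {
    stop("config error: anomaly_threshold must be in (0, 1)")
  }
  if (!backend %in% c("mcmc", "wgan-gp")) {
    stop("config error: unknown backend ", backend)
  }
  if (!inherits(classifier, "classifier_spec")) {
    stop("config error: classifier must be a classifier_spec")
  }
  bad <- setdiff(groupings, names(GROUPING_MEMBERS))
  if (length(bad)) stop("config error: unknown groupings ",
                        paste(bad, collapse = ", "))
  structure(list(input = input, form_space = form_space,
                 retained_pcs = retained_pcs,
                 anomaly_threshold = anomaly_threshold, backend = backend,
                 per_class_target = as.integer(per_class_target),
                 classifier = classifier, groupings = groupings,
                 seed = as.integer(seed),
                 run_raw_protocol = isTRUE(run_raw_protocol)),
            class = "pipeline_config")
}

# all stage seeds derive deterministically from the global seed
stage_seed <- function(seed, stage) {
  offsets <- c(generate = 1L, gpa = 2L, stats = 3L, clean = 4L,
               augment = 5L, train = 6L, evaluate = 7L, split = 8L)
  (seed * 101L + offsets[[stage]]) %% .Machine$integer.max
}

#' Build the named sub-datasets (groupings)
#'
#' Five standard groupings: Pleistocene European Taxa (6 species), African
#' Taxa (4 species), Taxonomic Family (all specimens relabelled to their
#' family), Canidae (3 species) and Felidae (3 species).
#'
#' @param pc_table data.frame with `taxon` and `family` columns.
#' @param groupings names of the groupings to build.
#' @return Named list of data.frames; the Taxonomic Family table's `taxon`
#'   column holds family labels.
#' @export
make_groupings <- function(pc_table, groupings = names(GROUPING_MEMBERS)) {
  out <- list()
  for (g in groupings) {
    members <- GROUPING_MEMBERS[[g]]
    if (is.null(members)) stop("unknown grouping: ", g)
    missing <- setdiff(members, unique(pc_table$taxon))
    if (length(missing)) {
      stop("grouping '", g, "' is missing taxa: ",
           paste(missing, collapse = ", "))
    }
    sub <- pc_table[pc_table$taxon %in% members, , drop = FALSE]
    if (g == "Taxonomic Family") sub$taxon <- sub$family
    rownames(sub) <- NULL
    out[[g]] <- sub
  }
  out
}

write_stage_csv <- function(df, outdir, name) {
  path <- file.path(outdir, paste0(name, ".csv"))
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full tooth-pit analysis pipeline
#'
#' Executes the stages in order (generate/ingest, validate, GPA, allometry,
#' PCA + PC selection, group statistics, anomaly cleaning, augmentation
#' with equivalency validation, classifier training, evaluation on original
#' specimens, optional 70/30 raw baseline) and writes every stage artifact
#' as CSV plus a JSON run manifest into `outdir`. Reruns with the same
#' config and seed are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the in-memory stage results (`pc_table`,
#'   `allometry`, `anomaly_report`, `groupings`, `reports`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile(),
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[pitmorph] ", ...)
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }

  say("stage: generate/ingest")
  dataset <- clock("generate", {
    if (inherits(config$input, "study_spec")) {
      spec <- config$input
      spec$seed <- stage_seed(config$seed, "generate")
      generate_study(spec)
    } else {
      read_morphologika(config$input)
    }
  })
  write_stage_csv(dataset_manifest(dataset), outdir, "manifest_specimens")

  say("stage: validate")
  clock("validate", {
    viol <- lapply(dataset$configurations, validate_configuration)
    n_bad <- sum(lengths(viol) > 0)
    if (n_bad) say(n_bad, " configurations carry geometric violations ",
                   "(anomalies are expected to)")
  })

  say("stage: GPA (", if (config$form_space) "form" else "shape", " space)")
  aligned <- clock("gpa", gpa_align(dataset, scale = !config$form_space))
  allom <- NULL
  if (config$form_space) {
    allom <- clock("stats", allometry_test(
      aligned, seed = stage_seed(config$seed, "stats")))
    write_stage_csv(
      data.frame(squared_residuals = allom$squared_residuals, F = allom$F,
                 effect_size = allom$effect_size, p = allom$p,
                 bfb = allom$bfb), outdir, "allometry")
  }

  say("stage: PCA")
  pcs <- pca_reduce(aligned)
  retained <- if (identical(config$retained_pcs, "auto")) {
    optimal_pcs(pcs, seed = stage_seed(config$seed, "stats"))
  } else {
    min(config$retained_pcs, ncol(pcs$scores))
  }
  retained <- max(retained, 2L) # downstream stages need >= 2 dimensions
  say("retained PCs: ", retained)
  pc_table <- pc_score_table(pcs, k = retained)
  write_stage_csv(pc_table, outdir, "pc_scores")

  say("stage: group statistics")
  stats_tab <- clock("group_stats", {
    cs_test <- group_difference_test(pc_table$centroid_size, pc_table$taxon)
    mv_test <- multivariate_test(
      as.matrix(pc_table[, pc_columns(pc_table), drop = FALSE]),
      pc_table$taxon)
    results_table(list(centroid_size = cs_test, pc_scores = mv_test))
  })
  write_stage_csv(stats_tab, outdir, "group_stats")

  say("stage: anomaly cleaning")
  cleaned <- clock("clean", {
    sc <- isolation_scores_by_class(
      as.matrix(pc_table[, pc_columns(pc_table), drop = FALSE]),
      pc_table$taxon, seed = stage_seed(config$seed, "clean"))
    filter_anomalies(pc_table, sc, threshold = config$anomaly_threshold)
  })
  pc_clean <- cleaned$dataset
  write_stage_csv(
    data.frame(specimen_id = pc_table$specimen_id,
               score = cleaned$report$scores,
               removed = pc_table$specimen_id %in%
                 cleaned$report$removed_ids),
    outdir, "anomaly_scores")

  say("stage: groupings")
  groups <- make_groupings(pc_clean, config$groupings)

  reports <- list()
  equiv_rows <- list()
  for (g in names(groups)) {
    say("grouping: ", g)
    gtab <- groups[[g]]
    mode <- if (g == "Taxonomic Family") "match-largest" else "target"
    bal <- clock(paste0("augment_", g), balance_dataset(
      gtab, per_class_target = config$per_class_target,
      backend = config$backend, mode = mode,
      seed = stage_seed(config$seed, "augment")))
    for (cls in names(bal$validation)) {
      tb <- bal$validation[[cls]]$table
      tb$grouping <- g
      tb$class <- cls
      tb$backend <- bal$backend
      equiv_rows[[paste(g, cls)]] <- tb
    }
    Xtr <- as.matrix(bal$data[, pc_columns(bal$data), drop = FALSE])
    trainer <- if (config$classifier$kind == "nsvm") train_nsvm
               else train_svm
    model <- clock(paste0("train_", g), trainer(
      Xtr, bal$data$taxon, config$classifier,
      seed = stage_seed(config$seed, "train")))
    rep_aug <- clock(paste0("evaluate_", g), evaluate_on_originals(
      model, bal$data, dataset_name = g))
    reports[[g]] <- list(augmented = rep_aug)
    write_stage_csv(rep_aug$table, outdir,
                    paste0("report_", gsub("[^A-Za-z]", "_", g),
                           "_augmented"))
    if (config$run_raw_protocol) {
      rep_raw <- clock(paste0("raw_", g), raw_split_protocol(
        gtab, config$classifier, seed = stage_seed(config$seed, "split"),
        dataset_name = g))
      reports[[g]]$raw <- rep_raw
      write_stage_csv(rep_raw$table, outdir,
                      paste0("report_", gsub("[^A-Za-z]", "_", g), "_raw"))
    }
  }
  if (length(equiv_rows)) {
    write_stage_csv(do.call(rbind, unname(equiv_rows)), outdir,
                    "augmentation_equivalency")
  }

  manifest <- list(
    seed = config$seed,
    stage_seeds = lapply(stats::setNames(nm = c("generate", "gpa", "stats",
                                                "clean", "augment", "train",
                                                "evaluate", "split")),
                         function(s) stage_seed(config$seed, s)),
    form_space = config$form_space, retained_pcs = retained,
    anomaly_threshold = config$anomaly_threshold,
    removed = length(cleaned$report$removed_ids),
    removed_fraction = cleaned$report$removed_fraction,
    backend = config$backend, classifier = config$classifier$kind,
    groupings = config$groupings,
    package_version = as.character(utils::packageVersion("pitmorph")),
    timings = timings
  )
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(dataset = dataset, aligned = aligned, allometry = allom,
                 pc_table = pc_table, anomaly_report = cleaned$report,
                 groupings = groups, reports = reports,
                 manifest = manifest, outdir = outdir))
}
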