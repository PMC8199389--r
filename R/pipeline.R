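#' Pipeline configuration
#'
#' Bundles the generator, classifier, SOM and evaluation settings with a
#' single master seed from which every stage's seed is derived
#' deterministically.
#'
#' @param generator An [emotion_sim_config()].
#' @param odcnn An [odcnn_config()].
#' @param som Named list with `rows`, `cols`, `iterations` (NULL =
#'   `1000 * n inputs`), `k`.
#' @param evaluation Named list with `folds` and `run_comparators`.
#' @param seed Master seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = emotion_sim_config(),
                            odcnn = odcnn_config(),
                            som = list(rows = 10L, cols = 10L,
                                       iterations = NULL, k = 4L),
                            evaluation = list(folds = 5L,
                                              run_comparators = FALSE),
                            seed = 1L) {
  stopifnot(inherits(generator, "emotion_sim_config"),
            inherits(odcnn, "odcnn_config"))
  generator$seed <- derive_seed(seed, 1L)
  odcnn$seed <- derive_seed(seed, 2L)
  structure(list(generator = generator, odcnn = odcnn, som = som,
                 evaluation = evaluation, seed = seed),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' `parse(serialize(config))` reproduces the configuration exactly.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  obj <- list(seed = config$seed,
              generator = unclass(config$generator),
              odcnn = unclass(config$odcnn),
              som = config$som,
              evaluation = config$evaluation)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  gen <- obj$generator
  cfg <- pipeline_config(
    generator = emotion_sim_config(
      n_base = gen$n_base, n_augmented = gen$n_augmented,
      male_fraction = gen$male_fraction,
      rank_counts = unlist(gen$rank_counts), seed = gen$seed,
      clip_ranges = lapply(gen$clip_ranges, unlist),
      augment_noise_scale = gen$augment_noise_scale),
    odcnn = do.call(odcnn_config, obj$odcnn[setdiff(names(obj$odcnn),
                                                    "seed")]),
    som = obj$som,
    evaluation = obj$evaluation,
    seed = obj$seed)
  cfg
}

write_manifest <- function(run_dir) {
  files <- setdiff(list.files(run_dir), "manifest.csv")
  hashes <- tools::md5sum(file.path(run_dir, files))
  man <- data.frame(artifact = files, md5 = unname(hashes))
  utils::write.csv(man, file.path(run_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  man
}

#' Run the full pipeline
#'
#' Generate -> augment -> cross-validate the convolutional classifier ->
#' fit a final model -> aggregate predicted emotions per organization ->
#' train the SOM -> partition its codebook -> categorize organizational
#' competitiveness.  Every stage writes its artifact into `run_dir` and a
#' manifest of MD5 content hashes is produced; a rerun with the same
#' configuration and seed reproduces identical hashes.
#'
#' @param config A [pipeline_config()].
#' @param run_dir Output directory (created if missing).
#' @param verbose Log stage progress.
#' @return Invisibly, a list with the in-memory artifacts and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         run_dir = tempfile("emocomp_run_"),
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      write_manifest(run_dir)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  say("[1/6] generating %d base records", config$generator$n_base)
  base <- stage("generate", simulate_employees(config$generator))
  data <- stage("augment",
                augment_records(base, config$generator$n_augmented,
                                config$generator$augment_noise_scale,
                                seed = derive_seed(config$seed, 3L),
                                clip_ranges = config$generator$clip_ranges))
  write_emotion_records(data, file.path(run_dir, "dataset.csv"))

  say("[2/6] encoding features and cross-validating the classifier")
  fm <- stage("features", emotion_feature_matrix(data))
  cv <- stage("cv", cv_odcnn(fm$x, fm$y, config$odcnn,
                             k = config$evaluation$folds,
                             seed = derive_seed(config$seed, 4L)))
  report <- list(accuracy = cv$accuracy, misclassified = cv$misclassified,
                 confusion = cv$confusion,
                 per_class_auc = as.list(cv$per_class_auc),
                 macro_auc = cv$macro_auc)
  jsonlite::write_json(report, file.path(run_dir, "training_report.json"),
                       digits = NA, auto_unbox = TRUE)

  say("[3/6] fitting the final model on all data")
  model <- stage("train", odcnn(fm$x, fm$y, config$odcnn))
  write_odcnn(model, file.path(run_dir, "model.rds"))

  say("[4/6] aggregating per-organization emotion profiles")
  pred <- predict(model, fm$x)
  profiles <- stage("profiles",
                    org_profiles(data$org_rank,
                                 emotion_levels()[pred + 1L]))
  utils::write.csv(profiles, file.path(run_dir, "org_profiles.csv"),
                   row.names = FALSE, quote = FALSE)

  say("[5/6] training the self-organizing map")
  iters <- config$som$iterations
  if (is.null(iters)) iters <- 1000L * nrow(profiles)
  som <- stage("som", som_fit(as.matrix(profiles[, emotion_levels()]),
                              rows = config$som$rows,
                              cols = config$som$cols,
                              iterations = iters,
                              seed = derive_seed(config$seed, 5L)))
  write_som(som, file.path(run_dir, "som.json"))

  say("[6/6] categorizing organizational competitiveness")
  part <- stage("partition",
                kmeans_partition(som, k = config$som$k,
                                 seed = derive_seed(config$seed, 6L)))
  comp <- stage("categorize",
                categorize_competitiveness(profiles, som, part))
  utils::write.csv(comp, file.path(run_dir, "competitiveness.csv"),
                   row.names = FALSE, quote = FALSE)
  write_pipeline_config(config, file.path(run_dir, "config.yaml"))
  man <- write_manifest(run_dir)
  say("done: %s", run_dir)
  invisible(list(run_dir = run_dir, data = data, cv = cv, model = model,
                 profiles = profiles, som = som, partition = part,
                 competitiveness = comp, manifest = man))
}
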