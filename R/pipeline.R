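# End-to-end pipeline: curate -> featurize -> train -> screen ->
# (optional cross-evaluation) -> consensus, with a run manifest tying
# the stages, seeds and record counts together.

default_config <- function() {
  list(
    seed = 1L,
    out = "selectscreen-run",
    n_bits = 2048L,
    # data: either a synthetic preset or paths to curated tables
    synthetic = TRUE,
    n_scaffolds = 20L,
    substituents_per_scaffold = 100L,
    inactive_fraction = 0.25,
    noise_sd = 0.4,
    training_table = NULL,     # path, read with `dialect`
    dialect = "chembl",
    receptor = NULL,
    library_path = NULL,       # screening library (.smi or CSV)
    dock_path = NULL,          # PDBQT dir/file or score table
    # model
    hidden = c(512L, 128L),
    learning_rate = 1e-3,
    epochs = 100L,
    batch_size = 32L,
    split_fraction = 0.8,
    # selection
    min_class = 7L,
    energy_cutoff = -10.5,
    crosseval = FALSE,
    crosseval_runs = 1L)
}

#' Assemble a validated pipeline configuration
#'
#' Starts from the package defaults and overrides them with the named
#' values supplied (from code, a YAML file via [read_config()], or CLI
#' flags). Unknown keys are rejected.
#'
#' @param ... named overrides of the default configuration.
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- default_config()
  over <- list(...)
  if (length(over) && is.list(over[[1]]) && is.null(names(over)[1])) {
    over <- utils::modifyList(over[[1]], over[-1])
  }
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("Unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(cfg, over)
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file of configuration keys.
#' @return a `run_config` list.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("The 'yaml' package is required to read configuration files",
         call. = FALSE)
  }
  run_config(yaml::read_yaml(path))
}

#' Run the screening pipeline end to end
#'
#' Executes curate -> featurize -> train -> screen -> (optional
#' cross-evaluation) -> consensus and writes every stage product plus
#' a JSON manifest (configuration, seeds, per-stage record counts,
#' stage status) to the output directory. With the synthetic preset
#' (default) all inputs are generated from the configured seed, so a
#' rerun with the same configuration reproduces the run byte for byte
#' in single-threaded mode.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly; artifacts are written under
#'   `config$out`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config), stages = list())
  fail <- function(stage, err) {
    manifest$stages[[stage]] <- list(status = "FAILED",
                                     error = conditionMessage(err))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    writeLines(stage, file.path(out, "FAILED"))
    stop("Pipeline stage '", stage, "' failed: ", conditionMessage(err),
         call. = FALSE)
  }

  # -- curate ---------------------------------------------------------
  stage <- "curate"
  ds <- tryCatch({
    if (isTRUE(config$synthetic)) {
      gspec <- generator_spec(
        n_scaffolds = config$n_scaffolds,
        substituents_per_scaffold = config$substituents_per_scaffold,
        inactive_fraction = config$inactive_fraction,
        noise_sd = config$noise_sd, seed = config$seed)
      generate_receptor_library(gspec, receptor = config$receptor %||% "SYN1")
    } else {
      if (is.null(config$training_table)) {
        stop("training_table path is required when synthetic = FALSE")
      }
      read_activity_table(config$training_table, dialect = config$dialect,
                          receptor = config$receptor)
    }
  }, error = function(e) fail(stage, e))
  ds <- clean_dataset(ds)
  write_activity_table(ds, file.path(out, "curated.csv"))
  manifest$stages[[stage]] <- list(status = "ok", records = nrow(ds$records))

  # -- featurize ------------------------------------------------------
  stage <- "featurize"
  feat <- tryCatch({
    X <- fingerprint_matrix(ds$records$smiles, ids = ds$records$compound_id,
                            n_bits = config$n_bits)
    keep <- !is.na(X[, 1])
    list(X = X[keep, , drop = FALSE], classes = ds$records$activity_class[keep])
  }, error = function(e) fail(stage, e))
  manifest$stages[[stage]] <- list(status = "ok", records = nrow(feat$X),
                                   n_bits = config$n_bits)

  # -- train ----------------------------------------------------------
  stage <- "train"
  trained <- tryCatch({
    sp <- nn_spec(input_width = config$n_bits, hidden = config$hidden,
                  learning_rate = config$learning_rate,
                  epochs = config$epochs, batch_size = config$batch_size,
                  seed = config$seed)
    split <- split_dataset(nrow(feat$X), fraction = config$split_fraction,
                           seed = config$seed)
    model <- build_model(sp)
    model <- train_model(model, feat$X[split$train_indices, , drop = FALSE],
                         feat$classes[split$train_indices])
    ev <- evaluate_model(model, feat$X[split$validation_indices, , drop = FALSE],
                         feat$classes[split$validation_indices])
    list(model = model, split = split, eval = ev)
  }, error = function(e) fail(stage, e))
  save_model(trained$model, file.path(out, "model"))
  manifest$stages[[stage]] <- list(
    status = "ok", n_train = length(trained$split$train_indices),
    n_validation = length(trained$split$validation_indices),
    validation_loss = trained$eval$loss,
    validation_accuracy = trained$eval$accuracy, seed = config$seed)

  # -- screen ---------------------------------------------------------
  stage <- "screen"
  screen <- tryCatch({
    lib <- if (!is.null(config$library_path)) {
      read_smiles_library(config$library_path)
    } else {
      gspec <- generator_spec(
        n_scaffolds = config$n_scaffolds,
        substituents_per_scaffold = config$substituents_per_scaffold,
        inactive_fraction = config$inactive_fraction,
        noise_sd = config$noise_sd, seed = config$seed + 1000L)
      g <- generate_receptor_library(gspec, receptor = "LIB")
      g$records[, c("compound_id", "smiles")]
    }
    screen_library(trained$model, lib)
  }, error = function(e) fail(stage, e))
  utils::write.csv(screen, file.path(out, "screen.csv"), row.names = FALSE)
  manifest$stages[[stage]] <- list(status = "ok", records = nrow(screen))

  # -- crosseval (optional) ------------------------------------------
  if (isTRUE(config$crosseval)) {
    stage <- "crosseval"
    cem <- tryCatch({
      gspec <- generator_spec(
        n_scaffolds = config$n_scaffolds,
        substituents_per_scaffold = config$substituents_per_scaffold,
        inactive_fraction = config$inactive_fraction,
        noise_sd = config$noise_sd, seed = config$seed)
      pair <- generate_subtype_pair(gspec)
      sets <- prepare_receptor_sets(list(A = clean_dataset(pair$A),
                                         B = clean_dataset(pair$B)),
                                    fraction = config$split_fraction,
                                    seed = config$seed,
                                    n_bits = config$n_bits)
      sp <- nn_spec(input_width = config$n_bits, hidden = config$hidden,
                    learning_rate = config$learning_rate,
                    epochs = config$epochs, batch_size = config$batch_size)
      cross_evaluate(sets, sp, n_runs = config$crosseval_runs,
                     base_seed = config$seed)
    }, error = function(e) fail(stage, e))
    utils::write.csv(as.data.frame(cem), file.path(out, "crosseval.csv"),
                     row.names = FALSE)
    manifest$stages[[stage]] <- list(status = "ok", cells = nrow(cem))
  }

  # -- consensus ------------------------------------------------------
  stage <- "consensus"
  cons <- tryCatch({
    dock <- if (!is.null(config$dock_path)) {
      read_vina_scores(config$dock_path)
    } else {
      generate_dock_scores(screen$compound_id, seed = config$seed + 2000L,
                           mean = -9, sd = 1.2)
    }
    consensus_select(screen, dock, min_class = config$min_class,
                     cutoff = config$energy_cutoff)
  }, error = function(e) fail(stage, e))
  utils::write.csv(cons, file.path(out, "consensus.csv"), row.names = FALSE)
  manifest$stages[[stage]] <- list(status = "ok", hits = nrow(cons))

  manifest$complete <- TRUE
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
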