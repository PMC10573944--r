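# Receptor-subtype selectivity protocol: train one classifier per
# receptor, evaluate it against every receptor's validation set, pair
# each cell with Tanimoto diagnostics between the training and
# validation fingerprint sets, and average over repeated seeded runs.

#' Split and featurize a set of receptor datasets
#'
#' Convenience front end for [cross_evaluate()]: takes labeled
#' [activity_dataset()]s, splits each into training/validation
#' (default 80/20) and computes ECFP4 fingerprint matrices.
#'
#' @param datasets named list of labeled `activity_dataset`s, one per
#'   receptor.
#' @param fraction training fraction.
#' @param seed split seed (one per receptor is derived as
#'   `seed + position`).
#' @param n_bits fingerprint width.
#' @return named list, per receptor: `train`/`validation`, each with
#'   `X` (fingerprints) and `classes`.
#' @export
prepare_receptor_sets <- function(datasets, fraction = 0.8, seed = 1L,
                                  n_bits = 2048L) {
  stopifnot(length(names(datasets)) == length(datasets))
  out <- list()
  for (i in seq_along(datasets)) {
    ds <- datasets[[i]]
    stopifnot(inherits(ds, "activity_dataset"))
    X <- fingerprint_matrix(ds$records$smiles, ids = ds$records$compound_id,
                            n_bits = n_bits)
    keep <- !is.na(X[, 1])
    sp <- split_dataset(sum(keep), fraction = fraction, seed = seed + i)
    Xk <- X[keep, , drop = FALSE]
    cls <- ds$records$activity_class[keep]
    out[[names(datasets)[i]]] <- list(
      train = list(X = Xk[sp$train_indices, , drop = FALSE],
                   classes = cls[sp$train_indices]),
      validation = list(X = Xk[sp$validation_indices, , drop = FALSE],
                        classes = cls[sp$validation_indices]))
  }
  out
}

#' Cross-receptor selectivity evaluation
#'
#' For each training receptor, trains `n_runs` classifiers (seeds
#' `base_seed + run - 1`) on that receptor's training set and
#' evaluates each on every receptor's validation set. Reported loss
#' and accuracy are arithmetic means over runs; `accuracy_change` is
#' the cell accuracy minus the matched-subtype accuracy of the same
#' ensemble (zero on the diagonal by construction). Each cell also
#' carries the average and mode Tanimoto coefficient between the
#' training and validation fingerprint sets.
#'
#' @param sets output of [prepare_receptor_sets()] (receptor ->
#'   train/validation feature sets).
#' @param spec an [nn_spec()]; its `epochs` (conventionally 100 for
#'   this protocol) and architecture apply to every run.
#' @param n_runs independent training repetitions per receptor.
#' @param base_seed first seed of the run ensemble.
#' @return a `cross_eval_matrix`: data.frame of cells with attributes
#'   `n_runs` and `base_seed`.
#' @export
cross_evaluate <- function(sets, spec, n_runs = 1L, base_seed = 1L) {
  stopifnot(inherits(spec, "nn_spec"), n_runs >= 1)
  receptors <- names(sets)
  if (length(receptors) < 2) stop("Need at least 2 receptors", call. = FALSE)
  for (r in receptors) {
    if (is.null(sets[[r]]$validation)) {
      stop("Missing validation set for receptor '", r, "'", call. = FALSE)
    }
  }
  cells <- list()
  for (tr in receptors) {
    acc <- matrix(0, n_runs, length(receptors),
                  dimnames = list(NULL, receptors))
    los <- acc
    for (run in seq_len(n_runs)) {
      run_seed <- base_seed + run - 1L
      sp <- spec; sp$seed <- as.integer(run_seed)
      model <- build_model(sp)
      model <- train_model(model, sets[[tr]]$train$X, sets[[tr]]$train$classes)
      for (va in receptors) {
        ev <- evaluate_model(model, sets[[va]]$validation$X,
                             sets[[va]]$validation$classes)
        acc[run, va] <- ev$accuracy
        los[run, va] <- ev$loss
      }
    }
    for (va in receptors) {
      sim <- cross_set_similarity(sets[[tr]]$train$X, sets[[va]]$validation$X)
      cells[[length(cells) + 1L]] <- data.frame(
        train_receptor = tr, val_receptor = va,
        n_train = nrow(sets[[tr]]$train$X),
        n_val = nrow(sets[[va]]$validation$X),
        loss = mean(los[, va]), accuracy = mean(acc[, va]),
        accuracy_change = mean(acc[, va]) - mean(acc[, tr]),
        accuracy_sd = stats::sd(acc[, va]),
        avg_tanimoto = sim$average, mode_tanimoto = sim$mode,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  structure(out, n_runs = as.integer(n_runs),
            base_seed = as.integer(base_seed),
            class = c("cross_eval_matrix", "data.frame"))
}

#' Averaged metrics over repeated training runs
#'
#' Trains `n_runs` independent models (seeds `base_seed + run - 1`) on
#' one training set and summarizes validation loss and accuracy as
#' mean and standard deviation over runs.
#'
#' @param train,validation lists with `X` (fingerprints) and `classes`.
#' @param spec an [nn_spec()].
#' @param n_runs number of runs (>= 1).
#' @param epochs override of `spec$epochs` (the protocol convention is
#'   100 epochs when averaging 100 runs).
#' @param base_seed first seed.
#' @return list with `loss_mean`, `loss_sd`, `accuracy_mean`,
#'   `accuracy_sd`, and the per-run metric data.frame `runs`.
#' @export
repeated_training_summary <- function(train, validation, spec,
                                      n_runs = 100L, epochs = 100L,
                                      base_seed = 1L) {
  if (n_runs < 1) stop("n_runs must be >= 1", call. = FALSE)
  runs <- data.frame(run = seq_len(n_runs), loss = NA_real_,
                     accuracy = NA_real_)
  for (run in seq_len(n_runs)) {
    sp <- spec; sp$seed <- as.integer(base_seed + run - 1L)
    model <- build_model(sp)
    model <- train_model(model, train$X, train$classes, epochs = epochs)
    ev <- evaluate_model(model, validation$X, validation$classes)
    runs$loss[run] <- ev$loss
    runs$accuracy[run] <- ev$accuracy
  }
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  list(loss_mean = mean(runs$loss), loss_sd = sd0(runs$loss),
       accuracy_mean = mean(runs$accuracy),
       accuracy_sd = sd0(runs$accuracy), runs = runs)
}

#' Rank correlation between cell accuracy and training/validation
#' similarity
#'
#' Spearman rank correlation between accuracy and the average
#' cross-set Tanimoto coefficient over the cells of one or more
#' cross-evaluation matrices — the diagnostic behind the observation
#' that a classifier transfers to another receptor's ligands in
#' proportion to how similar those ligands are to its training set.
#'
#' @param cells a `cross_eval_matrix` or any data.frame with
#'   `accuracy` and `avg_tanimoto` columns (>= 3 rows).
#' @return list with `rho` (Spearman) and the audited `pairs` table.
#' @export
accuracy_similarity_correlation <- function(cells) {
  cells <- as.data.frame(cells)
  stopifnot(all(c("accuracy", "avg_tanimoto") %in% names(cells)))
  if (nrow(cells) < 3) stop("Need at least 3 cells", call. = FALSE)
  rho <- stats::cor(cells$accuracy, cells$avg_tanimoto, method = "spearman")
  pairs <- cells[, intersect(c("train_receptor", "val_receptor", "accuracy",
                               "avg_tanimoto"), names(cells))]
  pairs$accuracy_rank <- rank(cells$accuracy)
  pairs$tanimoto_rank <- rank(cells$avg_tanimoto)
  list(rho = rho, pairs = pairs)
}
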