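# The seven-class activity classifier: a sequential feed-forward
# network mapping ECFP4 bit vectors to a probability distribution over
# the seven pChEMBL activity categories.

N_CLASSES <- 7L

#' Specification of the activity classifier
#'
#' Architecture and training hyperparameters of the sequential
#' feed-forward classifier: ReLU hidden layers, a 7-unit softmax
#' output, categorical cross-entropy loss and the Adam optimizer.
#' Defaults: two hidden layers of 512 and 128 units over 2048
#' fingerprint bits, learning rate 1e-3, batch size 32, 1000 epochs
#' (loss and accuracy typically stabilize well before that; the
#' repeated-run selectivity protocol uses 100).
#'
#' @param input_width fingerprint width the model consumes.
#' @param hidden integer vector of hidden-layer widths.
#' @param learning_rate Adam step size.
#' @param epochs training epochs (>= 1).
#' @param batch_size minibatch size.
#' @param seed integer seed controlling initialization and shuffling.
#' @return an `nn_spec` object.
#' @export
nn_spec <- function(input_width = 2048L, hidden = c(512L, 128L),
                    learning_rate = 1e-3, epochs = 1000L,
                    batch_size = 32L, seed = 1L) {
  stopifnot(input_width >= 1, all(hidden >= 1), epochs >= 1,
            batch_size >= 1, learning_rate > 0)
  structure(list(input_width = as.integer(input_width),
                 hidden = as.integer(hidden),
                 output_classes = N_CLASSES,
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "nn_spec")
}

#' @export
print.nn_spec <- function(x, ...) {
  cat(sprintf("<nn_spec> [%s] relu/softmax, lr %g, batch %d, %d epochs, seed %d\n",
              paste(c(x$input_width, x$hidden, x$output_classes),
                    collapse = " -> "),
              x$learning_rate, x$batch_size, x$epochs, x$seed))
  invisible(x)
}

#' Build an (untrained) classifier from a spec
#'
#' Parameters are He-initialized from the spec's seed; the model is
#' immediately usable for prediction.
#'
#' @param spec an [nn_spec()].
#' @return an `nn_model` with empty training history.
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "nn_spec"))
  widths <- c(spec$input_width, spec$hidden, spec$output_classes)
  params <- cpp_mlp_init(widths, spec$seed)
  structure(list(spec = spec, params = params,
                 history = data.frame(epoch = integer(0), loss = numeric(0),
                                      accuracy = numeric(0))),
            class = "nn_model")
}

#' @export
print.nn_model <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  trained epochs: %d\n", nrow(x$history)))
  invisible(x)
}

check_features <- function(model, X) {
  X <- as_bit_matrix(X)
  if (ncol(X) != model$spec$input_width) {
    stop("Fingerprint width ", ncol(X), " does not match model input width ",
         model$spec$input_width, call. = FALSE)
  }
  storage.mode(X) <- "double"
  X
}

#' Train the activity classifier
#'
#' Minibatch Adam on categorical cross-entropy. The per-epoch history
#' (running mean of batch loss and accuracy) is appended to the model.
#' Reproducible for a fixed seed in single-threaded mode.
#'
#' @param model an `nn_model` from [build_model()].
#' @param X fingerprint matrix (compounds by bits).
#' @param classes integer activity classes in 1..7, one per row of `X`.
#' @param epochs,seed optional overrides of the spec values.
#' @return the trained `nn_model`.
#' @export
train_model <- function(model, X, classes, epochs = NULL, seed = NULL) {
  stopifnot(inherits(model, "nn_model"))
  X <- check_features(model, X)
  if (nrow(X) == 0) stop("Empty training set", call. = FALSE)
  classes <- as.integer(classes)
  if (length(classes) != nrow(X)) {
    stop("One class label per compound is required", call. = FALSE)
  }
  if (any(is.na(classes) | classes < 1 | classes > N_CLASSES)) {
    stop("Activity classes must lie in 1..7", call. = FALSE)
  }
  epochs <- if (is.null(epochs)) model$spec$epochs else as.integer(epochs)
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  seed <- if (is.null(seed)) model$spec$seed else as.integer(seed)
  fit <- cpp_mlp_train(model$params, X, classes - 1L, N_CLASSES,
                       model$spec$learning_rate, epochs,
                       model$spec$batch_size, seed)
  model$params <- list(W = fit$W, b = fit$b)
  model$history <- rbind(model$history,
                         data.frame(epoch = nrow(model$history) + seq_len(epochs),
                                    loss = fit$loss, accuracy = fit$accuracy))
  model
}

#' Predict class probabilities
#'
#' @param model an `nn_model`.
#' @param X fingerprint matrix.
#' @return matrix of softmax probabilities, one row per compound,
#'   columns = activity classes 1..7; each row sums to 1.
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "nn_model"))
  X <- check_features(model, X)
  if (nrow(X) == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = N_CLASSES))
  }
  P <- cpp_mlp_predict(model$params, X)
  colnames(P) <- as.character(1:N_CLASSES)
  rownames(P) <- rownames(X)
  P
}

# argmax with ties broken toward the lower class index (conservative
# activity call)
argmax_class <- function(P) apply(P, 1, which.max)

#' Evaluate the classifier on a labeled set
#'
#' Loss is the mean per-sample categorical cross-entropy of the
#' predicted distributions against one-hot labels; accuracy is the
#' fraction of top-1 matches, argmax ties broken toward the lower
#' class.
#'
#' @param model an `nn_model`.
#' @param X fingerprint matrix.
#' @param classes integer labels in 1..7.
#' @return an `eval_result`: list with `loss`, `accuracy` and the 7x7
#'   `confusion` count table (rows = truth, columns = prediction).
#' @export
evaluate_model <- function(model, X, classes) {
  X <- as_bit_matrix(X)
  if (nrow(X) == 0) stop("Empty validation set", call. = FALSE)
  P <- predict_proba(model, X)
  eval_predictions(P, classes)
}

#' Evaluate a probability matrix against labels
#'
#' The arithmetic core of [evaluate_model()], exposed so that
#' hand-built distributions can be scored in tests and audits.
#'
#' @param P probability matrix (rows sum to 1, 7 columns).
#' @param classes integer labels in 1..7.
#' @return an `eval_result` (see [evaluate_model()]).
#' @export
eval_predictions <- function(P, classes) {
  classes <- as.integer(classes)
  stopifnot(nrow(P) == length(classes), ncol(P) == N_CLASSES,
            all(classes >= 1 & classes <= N_CLASSES))
  p_true <- P[cbind(seq_len(nrow(P)), classes)]
  loss <- mean(-log(pmax(p_true, 1e-12)))
  pred <- argmax_class(P)
  confusion <- table(factor(classes, levels = 1:N_CLASSES),
                     factor(pred, levels = 1:N_CLASSES))
  structure(list(loss = loss,
                 accuracy = mean(pred == classes),
                 confusion = unclass(confusion)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> loss %.4f, accuracy %.3f (n = %d)\n",
              x$loss, x$accuracy, sum(x$confusion)))
  invisible(x)
}

#' Save / load a trained model
#'
#' The model is serialized as plain text: the spec and training
#' history as JSON, the weights as one CSV per layer.
#'
#' @param model an `nn_model`.
#' @param dir output directory (created if needed).
#' @return `dir` (save) or the restored `nn_model` (load).
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "nn_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(model$spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(model$history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  for (l in seq_along(model$params$W)) {
    utils::write.csv(as.data.frame(model$params$W[[l]]),
                     file.path(dir, sprintf("W%d.csv", l)), row.names = FALSE)
    utils::write.csv(data.frame(b = as.numeric(model$params$b[[l]])),
                     file.path(dir, sprintf("b%d.csv", l)), row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  spec_l <- jsonlite::read_json(file.path(dir, "spec.json"),
                                simplifyVector = TRUE)
  spec <- nn_spec(input_width = spec_l$input_width, hidden = spec_l$hidden,
                  learning_rate = spec_l$learning_rate,
                  epochs = spec_l$epochs, batch_size = spec_l$batch_size,
                  seed = spec_l$seed)
  L <- length(spec$hidden) + 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- as.matrix(utils::read.csv(file.path(dir, sprintf("W%d.csv", l))))
    dimnames(W[[l]]) <- NULL
    b[[l]] <- matrix(utils::read.csv(file.path(dir, sprintf("b%d.csv", l)))$b,
                     nrow = 1)
  }
  hist <- utils::read.csv(file.path(dir, "history.csv"))
  structure(list(spec = spec, params = list(W = W, b = b), history = hist),
            class = "nn_model")
}
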