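# Library screening: per-compound class distributions, predicted
# activity ranges, and percent-rank statistics.
#
# Compounds are ranked by the expected class ordinal of their
# predicted distribution (sum over k of p_k * k, so a pure class-k
# prediction scores exactly k); ties are broken by the probability of
# the top class and then by library order. A compound's overall
# percent rank is 100 * rank / N with rank 1 the best prediction, and
# its within-range percent rank is the same statistic computed among
# the compounds sharing its predicted class.

#' Screen a compound library with a trained classifier
#'
#' @param model a trained `nn_model`.
#' @param library a data.frame with `compound_id` and `smiles`, a bare
#'   character vector of SMILES, or a precomputed `ecfp_matrix` with
#'   compound ids as rownames.
#' @return a `screen_result` data.frame, one row per parseable
#'   compound in library order: probability columns `p1..p7`,
#'   `predicted_class`, `range_label`, `ranking_score`,
#'   `overall_percent_rank`, `within_range_percent_rank`. Unparseable
#'   compounds are counted in a message and skipped.
#' @export
screen_library <- function(model, library) {
  stopifnot(inherits(model, "nn_model"))
  if (is.character(library)) {
    library <- data.frame(compound_id = as.character(seq_along(library)),
                          smiles = library, stringsAsFactors = FALSE)
  }
  if (is.matrix(library)) {
    X <- library
    ids <- rownames(X)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  } else {
    stopifnot(all(c("compound_id", "smiles") %in% names(library)))
    if (nrow(library) == 0) stop("Empty screening library", call. = FALSE)
    X <- fingerprint_matrix(library$smiles, ids = library$compound_id,
                            n_bits = model$spec$input_width)
    ids <- library$compound_id
  }
  ok <- !is.na(X[, 1])
  if (any(!ok)) {
    ss_log("screen_library: skipped %d unparseable compound(s)", sum(!ok))
  }
  if (!any(ok)) stop("No parseable compounds in library", call. = FALSE)
  X <- X[ok, , drop = FALSE]
  ids <- ids[ok]
  P <- predict_proba(model, X)
  score_screen(P, ids)
}

#' Rank a probability matrix into a screening result
#'
#' The ranking core of [screen_library()], exposed so that hand-built
#' class distributions can be ranked and audited directly.
#'
#' @param P probability matrix, 7 columns, one row per compound.
#' @param ids compound identifiers, one per row.
#' @return a `screen_result` (see [screen_library()]).
#' @export
score_screen <- function(P, ids) {
  n <- nrow(P)
  stopifnot(length(ids) == n, ncol(P) == 7)
  pred <- argmax_class(P)
  score <- as.vector(P %*% (1:7))
  ord <- order(-score, -P[, 7], seq_len(n))   # rank 1 = best
  rank_overall <- integer(n)
  rank_overall[ord] <- seq_len(n)
  res <- data.frame(compound_id = as.character(ids),
                    stringsAsFactors = FALSE)
  colnames(P) <- paste0("p", 1:7)
  res <- cbind(res, as.data.frame(P, row.names = seq_len(n)))
  res$predicted_class <- pred
  res$range_label <- activity_range_labels()[pred]
  res$ranking_score <- score
  res$overall_percent_rank <- 100 * rank_overall / n
  res$within_range_percent_rank <- NA_real_
  for (k in unique(pred)) {
    idx <- which(pred == k)
    sub_ord <- order(-score[idx], -P[idx, 7], idx)
    r <- integer(length(idx)); r[sub_ord] <- seq_along(idx)
    res$within_range_percent_rank[idx] <- 100 * r / length(idx)
  }
  class(res) <- c("screen_result", class(res))
  res
}

#' Select top-range screening hits
#'
#' Keeps the compounds whose predicted class reaches `min_class` (by
#' default 7, the "9-above" pChEMBL range), ordered by ranking score
#' descending.
#'
#' @param results a `screen_result`.
#' @param min_class minimum predicted class, 1..7.
#' @return the selected subset, best first.
#' @export
select_top_by_range <- function(results, min_class = 7L) {
  if (min_class < 1 || min_class > 7) {
    stop("min_class must be in 1..7", call. = FALSE)
  }
  if (nrow(results) == 0) stop("Empty screening results", call. = FALSE)
  sel <- results[results$predicted_class >= min_class, , drop = FALSE]
  sel[order(-sel$ranking_score, sel$overall_percent_rank), , drop = FALSE]
}

#' Percent-rank report for named target compounds
#'
#' Reports, for each target id, how high the classifier placed it in
#' the screened library: the overall percent rank ("in x% of top
#' predictions"), the percent rank among compounds of the same
#' predicted activity range, and the range label. Percentages are
#' rounded to one decimal.
#'
#' @param results a `screen_result`.
#' @param targets character vector of compound ids present in
#'   `results`.
#' @return data.frame in target order: `compound_id`,
#'   `overall_percent`, `within_range_percent`, `range_label`.
#' @export
percent_rank_report <- function(results, targets) {
  idx <- match(targets, results$compound_id)
  if (any(is.na(idx))) {
    stop("Unknown target id(s): ",
         paste(targets[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  data.frame(compound_id = targets,
             overall_percent = round(results$overall_percent_rank[idx], 1),
             within_range_percent = round(results$within_range_percent_rank[idx], 1),
             range_label = results$range_label[idx],
             stringsAsFactors = FALSE)
}
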