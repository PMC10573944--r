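# Docking-score ingestion and NN+docking consensus selection.

new_dock_scores <- function(df) {
  df$compound_id <- trimws(as.character(df$compound_id))
  class(df) <- unique(c("dock_scores", class(df)))
  df
}

#' Read AutoDock Vina docking scores
#'
#' Accepts a multi-model PDBQT file (one `REMARK VINA RESULT` line per
#' pose; the compound id is the file name without extension), a
#' directory of such files, or a delimited table with `compound_id`
#' and `affinity` columns (`pose_index` optional, defaulting to pose
#' order).
#'
#' @param path PDBQT file, directory of PDBQT files, or CSV/TSV table.
#' @return a `dock_scores` data.frame: `compound_id`, `pose_index`,
#'   `affinity` (kcal/mol, more negative = stronger), `source`.
#' @export
read_vina_scores <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.pdbqt$", full.names = TRUE)
    if (!length(files)) stop("No .pdbqt files in ", path, call. = FALSE)
    return(new_dock_scores(do.call(rbind, lapply(files, read_vina_scores))))
  }
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  if (tolower(tools::file_ext(path)) == "pdbqt") {
    lines <- grep("REMARK VINA RESULT", readLines(path), value = TRUE)
    if (!length(lines)) {
      stop("No 'REMARK VINA RESULT' lines in ", path, call. = FALSE)
    }
    aff <- as.numeric(vapply(strsplit(sub(".*REMARK VINA RESULT:", "", lines),
                                      "[ \t]+"),
                             function(p) p[p != ""][1], character(1)))
    new_dock_scores(data.frame(
      compound_id = tools::file_path_sans_ext(basename(path)),
      pose_index = seq_along(aff), affinity = aff,
      source = path, stringsAsFactors = FALSE))
  } else {
    sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
    if (!all(c("compound_id", "affinity") %in% names(df))) {
      stop("Docking table ", path,
           " must have 'compound_id' and 'affinity' columns", call. = FALSE)
    }
    if (!"pose_index" %in% names(df)) {
      df$pose_index <- stats::ave(seq_len(nrow(df)), df$compound_id,
                                  FUN = seq_along)
    }
    df$source <- path
    new_dock_scores(df[, c("compound_id", "pose_index", "affinity", "source")])
  }
}

#' Filter docking poses by an affinity cutoff
#'
#' Keeps poses at least as strong as the cutoff (affinity <= cutoff;
#' the boundary itself passes). Order-preserving and idempotent; a
#' cutoff of `Inf` disables the filter.
#'
#' @param scores a `dock_scores` data.frame.
#' @param cutoff affinity cutoff in kcal/mol, default -10.5.
#' @return the surviving poses.
#' @export
apply_energy_cutoff <- function(scores, cutoff = -10.5) {
  scores[scores$affinity <= cutoff, , drop = FALSE]
}

#' Best pose per compound
#'
#' @param scores a `dock_scores` data.frame.
#' @return data.frame with `compound_id` and `best_affinity` (minimum
#'   over poses).
#' @export
best_pose_scores <- function(scores) {
  if (nrow(scores) == 0) {
    return(data.frame(compound_id = character(0), best_affinity = numeric(0)))
  }
  agg <- stats::aggregate(affinity ~ compound_id, data = scores, FUN = min)
  names(agg)[2] <- "best_affinity"
  agg
}

#' Consensus of classifier selection and docking scores
#'
#' Intersects the compounds the classifier placed in the top activity
#' range with the compounds whose docking affinity survives the energy
#' cutoff (or, alternatively, the `top_n` best-docked compounds).
#' Matching is on whitespace-normalized compound ids.
#'
#' @param screen a `screen_result` from [screen_library()].
#' @param dock a `dock_scores` data.frame.
#' @param min_class minimum predicted class for the classifier arm
#'   (default 7, the "9-above" range).
#' @param cutoff docking affinity cutoff (default -10.5 kcal/mol,
#'   inclusive); ignored when `top_n` is given.
#' @param top_n alternatively, keep the `top_n` compounds with the
#'   best (lowest) best-pose affinity.
#' @return a `consensus_hits` data.frame ordered by ranking score
#'   descending then affinity ascending: `compound_id`,
#'   `predicted_class`, `ranking_score`, `best_affinity`, `passed_nn`,
#'   `passed_dock` (both `TRUE` for every listed hit by construction).
#' @export
consensus_select <- function(screen, dock, min_class = 7L, cutoff = -10.5,
                             top_n = NULL) {
  nn_sel <- select_top_by_range(screen, min_class)
  nn_ids <- trimws(nn_sel$compound_id)
  best <- best_pose_scores(dock)
  best$compound_id <- trimws(best$compound_id)
  if (is.null(top_n)) {
    dock_ids <- best$compound_id[best$best_affinity <= cutoff]
  } else {
    dock_ids <- best$compound_id[order(best$best_affinity)][seq_len(min(top_n, nrow(best)))]
  }
  if (!length(intersect(trimws(unique(dock$compound_id)), nn_ids))) {
    warning("Classifier and docking id spaces do not overlap; ",
            "consensus is empty", call. = FALSE)
  }
  hits <- nn_sel[nn_ids %in% dock_ids, , drop = FALSE]
  out <- data.frame(compound_id = trimws(hits$compound_id),
                    predicted_class = hits$predicted_class,
                    ranking_score = hits$ranking_score,
                    best_affinity = best$best_affinity[match(trimws(hits$compound_id),
                                                             best$compound_id)],
                    passed_nn = rep(TRUE, nrow(hits)),
                    passed_dock = rep(TRUE, nrow(hits)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$ranking_score, out$best_affinity), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("consensus_hits", class(out))
  out
}
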