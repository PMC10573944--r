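# Reading, cleaning, labeling and splitting of activity datasets in a
# ChEMBL-export-compatible dialect.

#' Construct an activity dataset
#'
#' An activity dataset holds the curated compound records for one
#' receptor: compound id, SMILES, pChEMBL value (-log10 molar
#' activity; 0 is the inactive sentinel) and, once labeled, the
#' seven-level activity class.
#'
#' @param records data.frame with columns `compound_id`, `smiles`,
#'   `pchembl` and optionally `activity_class`.
#' @param receptor receptor label, e.g. `"CCR2"`.
#' @param provenance free-text source note.
#' @return an `activity_dataset` object.
#' @export
activity_dataset <- function(records, receptor = "unknown",
                             provenance = "") {
  stopifnot(is.data.frame(records),
            all(c("compound_id", "smiles", "pchembl") %in% names(records)))
  if (!"activity_class" %in% names(records)) {
    records[["activity_class"]] <- rep(NA_integer_, nrow(records))
  }
  records$compound_id <- as.character(records$compound_id)
  records$smiles <- as.character(records$smiles)
  records$pchembl <- as.numeric(records$pchembl)
  if (any(!is.na(records$pchembl) & records$pchembl < 0)) {
    stop("pChEMBL values must be non-negative", call. = FALSE)
  }
  rownames(records) <- NULL
  structure(list(receptor = receptor,
                 records = records[, c("compound_id", "smiles", "pchembl",
                                       "activity_class")],
                 provenance = provenance),
            class = "activity_dataset")
}

#' @export
print.activity_dataset <- function(x, ...) {
  cat(sprintf("<activity_dataset> %s: %d compounds\n",
              x$receptor, nrow(x$records)))
  if (nrow(x$records)) print(head(x$records, 4))
  invisible(x)
}

#' @export
length.activity_dataset <- function(x) nrow(x$records)

#' Column-name dialects for activity tables
#'
#' `"chembl"` matches ChEMBL web-export headers; `"plain"` matches the
#' lowercase names this package writes. A custom dialect is a named
#' character vector with entries `id`, `smiles`, `pchembl` and
#' optionally `receptor`.
#'
#' @param dialect dialect name or named character vector.
#' @return named character vector of column names.
#' @export
table_dialect <- function(dialect = "chembl") {
  if (is.character(dialect) && length(dialect) == 1) {
    dialect <- switch(dialect,
      chembl = c(id = "Molecule ChEMBL ID", smiles = "Smiles",
                 pchembl = "pChEMBL Value", receptor = "Receptor"),
      plain = c(id = "compound_id", smiles = "smiles",
                pchembl = "pchembl", receptor = "receptor"),
      stop("Unknown dialect '", dialect, "'", call. = FALSE))
  }
  if (!all(c("id", "smiles", "pchembl") %in% names(dialect))) {
    stop("A dialect must map 'id', 'smiles' and 'pchembl'", call. = FALSE)
  }
  dialect
}

#' Read an activity table
#'
#' Reads a delimited (CSV/TSV, by extension) activity table into an
#' [activity_dataset()]. Rows without a usable pChEMBL value are
#' excluded and counted in a message; the literal strings
#' `"inactive"`/`"Inactive"` in the pChEMBL column are mapped to the
#' inactive sentinel 0 rather than excluded.
#'
#' @param path file path.
#' @param dialect see [table_dialect()].
#' @param receptor receptor label to stamp on the dataset; defaults to
#'   the dialect's receptor column when present, else `"unknown"`.
#' @param sep field separator; default inferred from the extension
#'   (`.tsv`/`.smi` = tab, otherwise comma).
#' @return an `activity_dataset`, records in file order.
#' @export
read_activity_table <- function(path, dialect = "chembl", receptor = NULL,
                                sep = NULL) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  dialect <- table_dialect(dialect)
  if (is.null(sep)) {
    sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "smi")) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  for (col in c("id", "smiles", "pchembl")) {
    if (!dialect[[col]] %in% names(df)) {
      stop("Missing mandatory column '", dialect[[col]], "' in ", path,
           call. = FALSE)
    }
  }
  p_raw <- df[[dialect[["pchembl"]]]]
  p <- suppressWarnings(as.numeric(p_raw))
  p[!is.na(p_raw) & tolower(trimws(as.character(p_raw))) == "inactive"] <- 0
  keep <- !is.na(p)
  if (sum(!keep) > 0) {
    ss_log("read_activity_table: removed %d row(s) with no usable pChEMBL value",
           sum(!keep))
  }
  if (is.null(receptor)) {
    rc <- dialect["receptor"]
    receptor <- if (!is.na(rc) && rc %in% names(df) && any(keep)) {
      as.character(df[[rc]][keep][1])
    } else "unknown"
  }
  rec <- data.frame(compound_id = as.character(df[[dialect[["id"]]]][keep]),
                    smiles = as.character(df[[dialect[["smiles"]]]][keep]),
                    pchembl = p[keep], stringsAsFactors = FALSE)
  if (nrow(rec) == 0) warning("Empty dataset read from ", path, call. = FALSE)
  activity_dataset(rec, receptor = receptor,
                   provenance = paste0("read from ", path))
}

#' Write an activity table
#'
#' Writes the dataset in the `"plain"` dialect (lowercase column names,
#' plus the receptor label per row) so that
#' `read_activity_table(..., dialect = "plain")` round-trips every
#' retained field.
#'
#' @param ds an `activity_dataset`.
#' @param path output file path (`.tsv` for tab-separated).
#' @return `path`, invisibly.
#' @export
write_activity_table <- function(ds, path) {
  stopifnot(inherits(ds, "activity_dataset"))
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "smi")) "\t" else ","
  out <- ds$records
  out$receptor <- ds$receptor
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a SMILES screening library
#'
#' Accepts `.smi` files (SMILES followed by an optional id per line,
#' whitespace-separated, no header) or delimited tables with `smiles`
#' and `compound_id` columns.
#'
#' @param path file path.
#' @return data.frame with `compound_id` and `smiles`.
#' @export
read_smiles_library <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  if (tolower(tools::file_ext(path)) == "smi") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "[ \t]+")
    data.frame(
      compound_id = vapply(seq_along(parts), function(i) {
        if (length(parts[[i]]) >= 2) parts[[i]][2] else sprintf("lib%d", i)
      }, character(1)),
      smiles = vapply(parts, `[`, character(1), 1),
      stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    stopifnot(all(c("compound_id", "smiles") %in% names(df)))
    df[, c("compound_id", "smiles")]
  }
}

#' Curate an activity dataset
#'
#' Canonicalizes SMILES, drops records whose SMILES cannot be parsed,
#' collapses duplicate compound ids (first occurrence kept, an
#' order-stable and reproducible policy), and (re)labels activity
#' classes from the pChEMBL values. Idempotent: cleaning a clean
#' dataset is a no-op. All removals are counted in messages.
#'
#' @param ds an `activity_dataset`.
#' @return the curated `activity_dataset`.
#' @export
clean_dataset <- function(ds) {
  stopifnot(inherits(ds, "activity_dataset"))
  rec <- ds$records
  if (nrow(rec) == 0) return(ds)
  dup <- duplicated(rec$compound_id)
  if (any(dup)) {
    ss_log("clean_dataset: collapsed %d duplicate compound id(s), first kept",
           sum(dup))
    rec <- rec[!dup, , drop = FALSE]
  }
  can <- canonical_smiles(rec$smiles)
  bad <- is.na(can)
  if (any(bad)) {
    ss_log("clean_dataset: dropped %d record(s) with unparseable SMILES",
           sum(bad))
    rec <- rec[!bad, , drop = FALSE]
    can <- can[!bad]
  }
  rec$smiles <- can
  rec$pchembl[is.na(rec$pchembl)] <- 0
  rec$activity_class <- assign_activity_class(rec$pchembl)
  activity_dataset(rec, receptor = ds$receptor, provenance = ds$provenance)
}

#' Assign seven-level activity classes to pChEMBL values
#'
#' Bins the pChEMBL scale into the seven activity categories
#' 1 (below 4), 2 (4-5), 3 (5-6), 4 (6-7), 5 (7-8), 6 (8-9) and
#' 7 (9 and above). Interval boundaries are left-closed/right-open,
#' so 5.0 falls in class 3 and 9.0 in class 7; the map is total and
#' monotone on the non-negative reals, and pChEMBL 0 (the inactive
#' sentinel) lands in class 1.
#'
#' @param pchembl numeric vector of non-negative pChEMBL values.
#' @return integer vector of classes in 1..7.
#' @examples
#' assign_activity_class(c(0, 3.5, 5.0, 9.2))  # 1 1 3 7
#' @export
assign_activity_class <- function(pchembl) {
  if (any(is.na(pchembl))) stop("pChEMBL value is NA", call. = FALSE)
  if (any(pchembl < 0)) stop("pChEMBL values must be >= 0", call. = FALSE)
  findInterval(pchembl, 4:9) + 1L
}

#' Labels of the seven activity ranges
#'
#' @return character vector of length 7, indexed by activity class.
#' @export
activity_range_labels <- function() {
  c("below 4", "4\u20135", "5\u20136", "6\u20137", "7\u20138",
    "8\u20139", "9\u2013above")
}

#' Random training/validation split
#'
#' Uniform random partition of a dataset's records, 80% to training by
#' default. Reproducible for a fixed seed; an optional stratified
#' variant samples the fraction within each activity class.
#'
#' @param ds an `activity_dataset` (or anything with a length/row
#'   count via `n`).
#' @param fraction training fraction in (0, 1); default 0.8.
#' @param seed integer seed, recorded in the result.
#' @param stratify stratify by `activity_class` (requires labels).
#' @return a `data_split`: list with integer `train_indices`,
#'   `validation_indices`, `fraction`, `seed`.
#' @export
split_dataset <- function(ds, fraction = 0.8, seed = 1L, stratify = FALSE) {
  n <- if (inherits(ds, "activity_dataset")) nrow(ds$records) else as.integer(ds)
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must be strictly between 0 and 1", call. = FALSE)
  }
  if (n < 2) stop("Need at least 2 records to split", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  if (stratify && inherits(ds, "activity_dataset")) {
    cls <- ds$records$activity_class
    if (any(is.na(cls))) stop("Stratified split needs labeled records",
                              call. = FALSE)
    train <- integer(0)
    for (k in sort(unique(cls))) {
      idx <- which(cls == k)
      train <- c(train, sort(sample(idx, round(fraction * length(idx)))))
    }
    train <- sort(train)
  } else {
    train <- sort(sample.int(n, round(fraction * n)))
  }
  structure(list(train_indices = train,
                 validation_indices = setdiff(seq_len(n), train),
                 fraction = fraction, seed = as.integer(seed)),
            class = "data_split")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Histogram of activity classes
#'
#' @param ds a labeled `activity_dataset`.
#' @return named integer vector of counts for classes 1..7.
#' @export
class_histogram <- function(ds) {
  stopifnot(inherits(ds, "activity_dataset"))
  cls <- ds$records$activity_class
  if (any(is.na(cls))) {
    stop("Unlabeled record(s): ",
         paste(head(ds$records$compound_id[is.na(cls)], 5), collapse = ", "),
         call. = FALSE)
  }
  counts <- tabulate(cls, nbins = 7L)
  names(counts) <- as.character(1:7)
  counts
}
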