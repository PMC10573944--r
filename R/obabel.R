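# Thin wrappers around the OpenBabel command-line tool. All SMILES
# parsing, canonicalization and ECFP4 hashing go through obabel in a
# single batch call per dataset; per-molecule subprocesses would
# dominate run time for realistic library sizes.

ss_log <- function(...) message("[selectscreen] ", sprintf(...))

obabel_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) {
    stop("The 'obabel' executable was not found on PATH; OpenBabel is ",
         "required for SMILES handling and ECFP4 fingerprints.",
         call. = FALSE)
  }
  p
}

# Write SMILES with positional names mol<i> so results can be matched
# back to inputs even when obabel drops unparseable entries.
write_smi_input <- function(smiles) {
  f <- tempfile(fileext = ".smi")
  writeLines(paste(smiles, sprintf("mol%d", seq_along(smiles))), f)
  f
}

parse_mol_index <- function(names) as.integer(sub("^mol", "", names))

#' Syntactic SMILES validity screen
#'
#' OpenBabel is lenient and silently repairs some malformed SMILES
#' (for example an unbalanced `"C(("` parses as methane). Dataset
#' curation must reject such strings rather than quietly mutate them,
#' so this check flags clearly broken syntax before any parser sees
#' it: unbalanced parentheses or brackets, unmatched ring-closure
#' digits, illegal characters, or an empty string. It is deliberately
#' conservative; chemistry-level validity is still decided by the
#' parser.
#'
#' @param smiles character vector of SMILES strings.
#' @return logical vector, `TRUE` where the string passes the screen.
#' @export
smiles_syntax_ok <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    if (grepl("[^A-Za-z0-9@+\\-\\[\\]()=#$:/\\\\%.*]", s)) return(FALSE)
    chars <- strsplit(s, "")[[1]]
    if (sum(chars == "(") != sum(chars == ")")) return(FALSE)
    if (sum(chars == "[") != sum(chars == "]")) return(FALSE)
    # ring-closure digits outside brackets must pair up (%nn two-digit
    # closures counted as units)
    bare <- gsub("\\[[^]]*\\]", "", s)
    bare <- gsub("%[0-9]{2}", "", bare)   # treat %nn closures as paired-checked below
    ring <- gsub("[^0-9]", "", bare)
    if (nzchar(ring)) {
      tab <- table(strsplit(ring, "")[[1]])
      if (any(tab %% 2 != 0)) return(FALSE)
    }
    m <- gregexpr("%[0-9]{2}", gsub("\\[[^]]*\\]", "", s))[[1]]
    if (m[1] != -1) {
      cl <- regmatches(gsub("\\[[^]]*\\]", "", s),
                       gregexpr("%[0-9]{2}", gsub("\\[[^]]*\\]", "", s)))[[1]]
      if (any(table(cl) %% 2 != 0)) return(FALSE)
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical form in one batch call.
#' Strings that fail the syntactic screen or that the parser rejects
#' come back as `NA`.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` for failures.
#' @export
canonical_smiles <- function(smiles) {
  out <- rep(NA_character_, length(smiles))
  if (length(smiles) == 0) return(out)
  ok <- smiles_syntax_ok(smiles)
  if (!any(ok)) return(out)
  idx <- which(ok)
  fin <- write_smi_input(smiles[idx])
  on.exit(unlink(fin), add = TRUE)
  res <- suppressWarnings(system2(obabel_path(), c(fin, "-ocan"),
                                  stdout = TRUE, stderr = FALSE))
  if (length(res)) {
    parts <- strsplit(res, "[ \t]+")
    for (p in parts) {
      if (length(p) >= 2) {
        i <- parse_mol_index(p[2])
        if (!is.na(i)) out[idx[i]] <- p[1]
      }
    }
  }
  out
}

# Parse the hex dump emitted by `obabel -ofpt -xh`. Records start with
# ">name ..."; the fingerprint is printed as one big hex number,
# most-significant 32-bit word first. For a fingerprint of W words,
# printed word w (0-based) holding bit j contributes bit position
# (W-1-w)*32 + j (0-based). Verified against ChemmineOB's binding.
parse_fpt_hex <- function(lines, n_unfolded) {
  n_words <- n_unfolded / 32L
  rec_starts <- grep("^>", lines)
  out <- list()
  for (k in seq_along(rec_starts)) {
    a <- rec_starts[k]
    b <- if (k < length(rec_starts)) rec_starts[k + 1] - 1L else length(lines)
    name <- sub("^>([^ \t]+).*", "\\1", lines[a])
    hex <- unlist(strsplit(paste(lines[seq(a + 1L, b)], collapse = " "), "[ \t]+"))
    # drop commentary lines such as "Possible superstructure of molN"
    hex <- hex[grepl("^[0-9a-fA-F]{8}$", hex)]
    if (length(hex) != n_words) {
      stop("Unexpected fingerprint dump width for '", name, "': got ",
           length(hex), " words, expected ", n_words, call. = FALSE)
    }
    hi <- strtoi(substr(hex, 1, 4), 16L)  # bits 16..31 of each word
    lo <- strtoi(substr(hex, 5, 8), 16L)  # bits 0..15
    bits <- integer(0)
    masks <- bitwShiftL(1L, 0:15)
    for (w in which(hi + lo != 0)) {
      j <- c(which(bitwAnd(rep(lo[w], 16), masks) != 0) - 1L,
             which(bitwAnd(rep(hi[w], 16), masks) != 0) + 15L)
      bits <- c(bits, (n_words - w) * 32L + j)  # w is 1-based here
    }
    out[[name]] <- sort(bits)
  }
  out
}

# Batch ECFP4 bit positions (0-based, unfolded 4096-bit space) for a
# SMILES vector. Returns a list parallel to `smiles`; NULL where the
# molecule could not be parsed.
obabel_ecfp4_bits <- function(smiles) {
  res <- vector("list", length(smiles))
  if (length(smiles) == 0) return(res)
  ok <- smiles_syntax_ok(smiles)
  idx <- which(ok)
  if (!length(idx)) return(res)
  fin <- write_smi_input(smiles[idx])
  on.exit(unlink(fin), add = TRUE)
  lines <- suppressWarnings(system2(obabel_path(),
                                    c(fin, "-ofpt", "-xfECFP4", "-xh"),
                                    stdout = TRUE, stderr = FALSE))
  recs <- parse_fpt_hex(lines, 4096L)
  for (nm in names(recs)) {
    i <- parse_mol_index(nm)
    if (!is.na(i)) res[[idx[i]]] <- recs[[nm]]
  }
  res
}
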