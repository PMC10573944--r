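# ECFP4 featurization and Tanimoto similarity.
#
# Fingerprints are extended-connectivity fingerprints of bond diameter
# 4 (Morgan radius 2), hashed by OpenBabel into a 4096-bit space and
# folded here (bitwise OR of congruent positions) to the requested
# width, 2048 bits by default. A single fingerprint is an integer 0/1
# vector of class "ecfp"; a collection is a compounds-by-bits 0/1
# matrix of class "ecfp_matrix" with rownames as compound ids. Both
# carry `n_bits` and `radius` attributes.

OB_ECFP_SPACE <- 4096L

new_ecfp <- function(bits01, n_bits) {
  structure(as.integer(bits01), n_bits = as.integer(n_bits),
            radius = 2L, class = "ecfp")
}

fold_bits <- function(bits0, n_bits) sort(unique(bits0 %% n_bits))

#' ECFP4 fingerprint of a single molecule
#'
#' @param smiles one SMILES string.
#' @param n_bits folded fingerprint width (default 2048; at most 4096,
#'   the width of the underlying hash space).
#' @return an `ecfp` object: integer 0/1 vector of length `n_bits`.
#' @examples
#' \dontrun{
#' identical(ecfp4("CCO"), ecfp4("OCC"))  # TRUE: same molecule
#' }
#' @export
ecfp4 <- function(smiles, n_bits = 2048L) {
  stopifnot(length(smiles) == 1L)
  check_n_bits(n_bits)
  bits <- obabel_ecfp4_bits(smiles)[[1]]
  if (is.null(bits)) {
    stop("Unparseable SMILES: '", smiles, "'", call. = FALSE)
  }
  v <- integer(n_bits)
  v[fold_bits(bits, n_bits) + 1L] <- 1L
  new_ecfp(v, n_bits)
}

check_n_bits <- function(n_bits) {
  if (n_bits < 1 || n_bits > OB_ECFP_SPACE) {
    stop("n_bits must be in 1..", OB_ECFP_SPACE, call. = FALSE)
  }
}

#' ECFP4 fingerprint matrix for a compound collection
#'
#' Featurizes a SMILES vector in one OpenBabel batch call. Unparseable
#' SMILES yield all-`NA` rows (callers curating data should have
#' dropped them already); use [clean_dataset()] upstream.
#'
#' @param smiles character vector of SMILES.
#' @param ids compound identifiers used as rownames (default
#'   positional).
#' @param n_bits folded width, default 2048.
#' @return an `ecfp_matrix`: integer 0/1 matrix, one row per compound.
#' @export
fingerprint_matrix <- function(smiles, ids = NULL, n_bits = 2048L) {
  check_n_bits(n_bits)
  if (is.null(ids)) ids <- as.character(seq_along(smiles))
  stopifnot(length(ids) == length(smiles))
  bits <- obabel_ecfp4_bits(smiles)
  m <- matrix(0L, nrow = length(smiles), ncol = n_bits,
              dimnames = list(ids, NULL))
  for (i in seq_along(bits)) {
    if (is.null(bits[[i]])) m[i, ] <- NA_integer_
    else m[i, fold_bits(bits[[i]], n_bits) + 1L] <- 1L
  }
  structure(m, n_bits = as.integer(n_bits), radius = 2L,
            class = c("ecfp_matrix", class(m)))
}

as_bit_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  matrix(as.integer(x), nrow = 1)
}

#' Tanimoto similarity of two fingerprints
#'
#' Jaccard similarity of the set bits, `|a & b| / |a | b|`. Defined as
#' 0 when both fingerprints are empty (no 0/0).
#'
#' @param a,b `ecfp` fingerprints (or plain 0/1 vectors) of equal
#'   length.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) != length(b)) {
    stop("Fingerprint lengths differ (", length(a), " vs ", length(b), ")",
         call. = FALSE)
  }
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) 0 else inter / uni
}

# All-pairs Tanimoto between the rows of two 0/1 matrices via one
# cross-product: |A_i & B_j| = A %*% t(B), |A_i | B_j| = pa + pb - int.
tanimoto_cross <- function(A, B) {
  A <- as_bit_matrix(A); B <- as_bit_matrix(B)
  stopifnot(ncol(A) == ncol(B))
  inter <- A %*% t(B)
  uni <- outer(rowSums(A), rowSums(B), "+") - inter
  s <- inter / uni
  s[uni == 0] <- 0
  s
}

#' Cross-set Tanimoto similarity summary
#'
#' Average and mode of the Tanimoto coefficient between two fingerprint
#' collections, the diagnostic reported alongside selectivity
#' cross-evaluation cells. By default the statistic is taken over all
#' `|A| x |B|` cross pairs; `per_compound_max = TRUE` instead summarizes
#' each A compound's best match in B (an alternative reading of
#' "similarity between two datasets" found in the literature).
#'
#' @param A,B `ecfp_matrix` collections (or 0/1 matrices).
#' @param bin_width resolution of the mode estimate; similarities are
#'   rounded down onto this grid and the most frequent bin is reported
#'   (ties toward the lower bin). Default 0.01, matching the two-decimal
#'   modes conventionally reported.
#' @param per_compound_max summarize per-A-compound maxima instead of
#'   all pairs.
#' @return a `similarity_summary`: list with `average`, `mode`,
#'   `n_pairs`.
#' @export
cross_set_similarity <- function(A, B, bin_width = 0.01,
                                 per_compound_max = FALSE) {
  A <- as_bit_matrix(A); B <- as_bit_matrix(B)
  if (nrow(A) == 0 || nrow(B) == 0) {
    stop("cross_set_similarity() needs non-empty collections", call. = FALSE)
  }
  s <- tanimoto_cross(A, B)
  vals <- if (per_compound_max) apply(s, 1, max) else as.vector(s)
  bin <- floor(vals / bin_width + 1e-9)
  tab <- tabulate(bin + 1L, nbins = max(bin) + 1L)
  mode <- (which.max(tab) - 1L) * bin_width     # which.max: first = lowest bin
  structure(list(average = mean(vals), mode = mode, n_pairs = length(vals)),
            class = "similarity_summary")
}

#' @export
print.similarity_summary <- function(x, ...) {
  cat(sprintf("Cross-set Tanimoto: average %.3f (mode: %.2f) over %d pairs\n",
              x$average, x$mode, x$n_pairs))
  invisible(x)
}

#' Rank a fingerprint library by similarity to a query
#'
#' @param query an `ecfp` fingerprint.
#' @param library an `ecfp_matrix` with compound ids as rownames.
#' @param k number of hits to return (capped at the library size).
#' @return data.frame with `compound_id` and `similarity`, descending;
#'   ties keep library order.
#' @export
top_k_similar <- function(query, library, k = 10L) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  library <- as_bit_matrix(library)
  if (nrow(library) == 0) stop("library is empty", call. = FALSE)
  sims <- as.vector(tanimoto_cross(matrix(as.integer(query), nrow = 1), library))
  ord <- order(-sims, seq_along(sims))  # stable: library order breaks ties
  ord <- ord[seq_len(min(k, length(ord)))]
  ids <- rownames(library)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(library)))
  data.frame(compound_id = ids[ord], similarity = sims[ord],
             stringsAsFactors = FALSE)
}
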