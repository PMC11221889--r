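# Sequence featurization: one-hot block, PSSM block, and their
# concatenation into the (n, 40) matrix the network consumes.

#' One-hot encode an amino-acid sequence
#'
#' Each residue becomes an indicator row over the fixed 20-letter
#' alphabet `ACDEFGHIKLMNPQRSTVWY`.  The unknown residue `'X'` encodes as
#' an all-zero row.
#'
#' @param seq Amino-acid string over the canonical alphabet plus `'X'`.
#' @return Numeric matrix of shape `(nchar(seq), 20)`.
#' @examples
#' one_hot_encode("ACD")
#' @export
one_hot_encode <- function(seq) {
  chars <- assert_sequence(seq, "seq")
  n <- length(chars)
  m <- matrix(0, n, 20L, dimnames = list(NULL, AA_ALPHABET))
  idx <- aa_index(chars)
  hit <- !is.na(idx)
  m[cbind(which(hit), idx[hit])] <- 1
  m
}

# BLOSUM62 log-odds block reordered to the model alphabet; memoised.
blosum62_block <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      cache <<- env$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
    }
    cache
  }
})

#' Deterministic substitution-profile stand-in for a PSSM
#'
#' When no PSI-BLAST profile is available (synthetic sequences, offline
#' runs), each residue's profile row is its BLOSUM62 substitution-score
#' row, reordered to the model alphabet.  `'X'` rows are all zeros.
#'
#' @inheritParams one_hot_encode
#' @return Numeric matrix of shape `(nchar(seq), 20)`.
#' @export
pseudo_pssm <- function(seq) {
  chars <- assert_sequence(seq, "seq")
  n <- length(chars)
  bl <- blosum62_block()
  m <- matrix(0, n, 20L, dimnames = list(NULL, AA_ALPHABET))
  idx <- aa_index(chars)
  hit <- !is.na(idx)
  if (any(hit)) m[hit, ] <- bl[idx[hit], , drop = FALSE]
  m
}

#' Parse a PSI-BLAST ASCII PSSM
#'
#' Reads the 20-column log-odds block of a file produced with
#' `psiblast -out_ascii_pssm`, reordering the columns from PSI-BLAST's
#' native residue order (`ARNDCQEGHILKMFPSTWYV`) to the model alphabet.
#'
#' @param path Path to the ASCII PSSM file.
#' @param expected_seq Optional amino-acid string; when supplied the
#'   residue column of the file must match it exactly.
#' @return Numeric matrix of shape `(n, 20)` in model-alphabet column
#'   order, with the residue letters as row names.
#' @export
parse_pssm <- function(path, expected_seq = NULL) {
  lines <- readLines(path, warn = FALSE)
  # data rows look like: "  12 K   -1  2 ... " with >= 22 fields; the
  # first two are the 1-based position and the residue letter.
  is_data <- grepl("^\\s*\\d+\\s+[A-Z]\\s+-?\\d", lines)
  rows <- lines[is_data]
  if (length(rows) == 0L)
    stop("no PSSM data rows found in '", path, "' (truncated file?)",
         call. = FALSE)
  fields <- strsplit(trimws(rows), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 22L))
    stop("truncated PSSM data row (", min(nf), " fields, expected >= 22)",
         call. = FALSE)
  pos <- as.integer(vapply(fields, `[[`, "", 1L))
  res <- vapply(fields, `[[`, "", 2L)
  if (!identical(pos, seq_along(pos)))
    stop("PSSM rows are not consecutively numbered from 1", call. = FALSE)
  raw <- t(vapply(fields, function(f) {
    v <- suppressWarnings(as.numeric(f[3:22]))
    if (anyNA(v)) stop("non-numeric cell in PSSM row starting '",
                       paste(f[1:2], collapse = " "), "'", call. = FALSE)
    v
  }, numeric(20L)))
  if (!is.null(expected_seq)) {
    chars <- assert_sequence(expected_seq, "expected_seq")
    if (length(chars) != length(res) || !all(chars == res))
      stop("PSSM residue column does not match the expected sequence",
           call. = FALSE)
  }
  out <- raw[, match(AA_ALPHABET, PSIBLAST_ORDER), drop = FALSE]
  dimnames(out) <- list(res, AA_ALPHABET)
  out
}

#' Write a profile matrix in PSI-BLAST ASCII PSSM layout
#'
#' Emits the header, the 20-column log-odds block (in PSI-BLAST native
#' column order) and a trailing statistics stub, so that the output is
#' re-readable by [parse_pssm()].  Used to persist computed profiles and
#' to build test fixtures.
#'
#' @param mat `(n, 20)` profile matrix in model-alphabet column order.
#' @param seq Amino-acid string of length `n`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(mat, seq, path) {
  chars <- assert_sequence(seq, "seq")
  stopifnot(is.matrix(mat), nrow(mat) == length(chars), ncol(mat) == 20L)
  native <- mat[, match(PSIBLAST_ORDER, AA_ALPHABET), drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("           ", paste(sprintf("%3s", PSIBLAST_ORDER), collapse = ""))
  ), con)
  for (i in seq_along(chars)) {
    writeLines(paste0(sprintf("%5d %s ", i, chars[i]),
                      paste(sprintf("%3d", round(native[i, ])), collapse = "")),
               con)
  }
  writeLines(c("", "                      K         Lambda"), con)
  invisible(path)
}

#' Build the (n, 40) feature matrix for one protein sequence
#'
#' Concatenates the one-hot block (columns 1-20) with a PSSM block
#' (columns 21-40).  When no PSSM is supplied, the deterministic
#' [pseudo_pssm()] profile is used.
#'
#' @inheritParams one_hot_encode
#' @param pssm Optional `(nchar(seq), 20)` profile matrix in
#'   model-alphabet column order.
#' @param zscale Logical; z-scale the PSSM block over the whole matrix
#'   (default `FALSE`: raw log-odds are used).
#' @return Numeric matrix of shape `(nchar(seq), 40)`.
#' @export
featurize <- function(seq, pssm = NULL, zscale = FALSE) {
  oh <- one_hot_encode(seq)
  if (is.null(pssm)) {
    pssm <- pseudo_pssm(seq)
  } else {
    if (!is.matrix(pssm) || ncol(pssm) != 20L)
      stop("pssm must be a (n, 20) matrix", call. = FALSE)
    if (nrow(pssm) != nrow(oh))
      stop(sprintf("pssm has %d rows but sequence has %d residues",
                   nrow(pssm), nrow(oh)), call. = FALSE)
    if (!all(is.finite(pssm)))
      stop("pssm contains non-finite values", call. = FALSE)
  }
  if (zscale) {
    s <- stats::sd(pssm)
    if (s > 0) pssm <- (pssm - mean(pssm)) / s
  }
  out <- cbind(oh, pssm)
  dimnames(out) <- NULL
  out
}

#' Featurize all four sequences of one mutation record
#'
#' Produces the wild-type and mutant antibody/antigen feature matrices
#' consumed by [predict_ddg()].  Multi-chain proteins are concatenated in
#' table order.  PSSMs, when given, apply to the concatenated wild-type
#' protein; the mutant profile reuses the wild-type rows with mutated
#' positions replaced by their [pseudo_pssm()] rows (profiles for mutant
#' sequences are rarely available).
#'
#' @param record A record as returned by [dataset_record()].
#' @param pssm_ab,pssm_ag Optional wild-type profile matrices for the
#'   concatenated antibody and antigen sequences.
#' @return List with elements `ab_wt`, `ag_wt`, `ab_mt`, `ag_mt`, each an
#'   `(n, 40)` matrix.
#' @export
featurize_record <- function(record, pssm_ab = NULL, pssm_ag = NULL) {
  ab_wt_seq <- paste(record$ab_chains, collapse = "")
  ag_wt_seq <- paste(record$ag_chains, collapse = "")
  mt <- apply_mutations(c(record$ab_chains, record$ag_chains),
                        record$mutations)
  ab_ids <- names(record$ab_chains)
  ab_mt_seq <- paste(mt[ab_ids], collapse = "")
  ag_mt_seq <- paste(mt[setdiff(names(mt), ab_ids)], collapse = "")

  mutant_profile <- function(wt_profile, wt_seq, mt_seq) {
    if (is.null(wt_profile)) return(NULL)
    changed <- which(strsplit(wt_seq, "")[[1]] != strsplit(mt_seq, "")[[1]])
    if (length(changed)) {
      sub <- pseudo_pssm(mt_seq)
      wt_profile[changed, ] <- sub[changed, , drop = FALSE]
    }
    wt_profile
  }
  list(
    ab_wt = featurize(ab_wt_seq, pssm_ab),
    ag_wt = featurize(ag_wt_seq, pssm_ag),
    ab_mt = featurize(ab_mt_seq, mutant_profile(pssm_ab, ab_wt_seq, ab_mt_seq)),
    ag_mt = featurize(ag_mt_seq, mutant_profile(pssm_ag, ag_wt_seq, ag_mt_seq))
  )
}
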