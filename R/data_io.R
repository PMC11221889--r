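# Mutation tables, FASTA input, mutation-string parsing, and the
# canonical dataset representation.
#
# A dataset is a data.frame with one row per labeled mutation record and
# columns: complex_id, ab_chains, ag_chains, ab_seq, ag_seq, mutations,
# ddg.  Multi-chain proteins keep one ';'-separated field per role;
# positions in mutation strings are 1-based indices into the named chain.

DATASET_COLUMNS <- c("complex_id", "ab_chains", "ag_chains",
                     "ab_seq", "ag_seq", "mutations", "ddg")

new_mutation_dataset <- function(df, name = "", provenance = "synthetic") {
  stopifnot(all(DATASET_COLUMNS %in% names(df)))
  provenance <- match.arg(provenance, c("abbind", "skempi", "synthetic"))
  df <- df[, DATASET_COLUMNS]
  rownames(df) <- NULL
  structure(df, name = name, provenance = provenance,
            class = c("mutation_dataset", "data.frame"))
}

#' @export
print.mutation_dataset <- function(x, ...) {
  n_cx <- length(unique(x$complex_id))
  cat(sprintf("<mutation_dataset '%s' (%s): %d records, %d complexes>\n",
              attr(x, "name"), attr(x, "provenance"), nrow(x), n_cx))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Parse a mutation specification string
#'
#' The compact form is a comma-separated list of `CHAIN:WT<POS>MT`
#' tokens, e.g. `"A:Y32W"` or `"A:S56M,A:L97W,A:T99V"`.  SKEMPI-style
#' tokens `WT CHAIN POS MT` (e.g. `"YA32W"`) are supported via
#' `style = "skempi"`.
#'
#' @param s Mutation string.
#' @param style Token grammar, `"colon"` (default) or `"skempi"`.
#' @return A data.frame with columns `chain`, `wt`, `pos`, `mt`, one row
#'   per mutation, in input order.
#' @examples
#' parse_mutation_string("A:Y32W")
#' parse_mutation_string("A:S56M,A:L97W,A:T99V")
#' @export
parse_mutation_string <- function(s, style = c("colon", "skempi")) {
  style <- match.arg(style)
  stopifnot(is.character(s), length(s) == 1L)
  tokens <- trimws(strsplit(s, ",")[[1]])
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L)
    stop("empty mutation string", call. = FALSE)
  pat <- if (style == "colon") "^([A-Za-z0-9]):([A-Z])([0-9]+)([A-Z])$"
         else "^([A-Z])([A-Za-z0-9])([0-9]+)([A-Z])$"
  m <- regmatches(tokens, regexec(pat, tokens))
  bad <- which(lengths(m) != 5L)
  if (length(bad))
    stop("malformed mutation token '", tokens[bad[1L]], "'", call. = FALSE)
  parts <- do.call(rbind, m)
  out <- data.frame(
    chain = if (style == "colon") parts[, 2L] else parts[, 3L],
    wt    = if (style == "colon") parts[, 3L] else parts[, 2L],
    pos   = as.integer(parts[, 4L]),
    mt    = parts[, 5L],
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(out))) {
    if (!is_canonical(out$wt[i]) || !is_canonical(out$mt[i]))
      stop("invalid residue letter in token '", tokens[i], "'", call. = FALSE)
    if (out$wt[i] == out$mt[i])
      stop("wild-type and mutant residue are identical in token '",
           tokens[i], "'", call. = FALSE)
  }
  out
}

#' Format a mutation table back to its compact string form
#' @param mutations A data.frame as returned by [parse_mutation_string()].
#' @return A single `"CHAIN:WTposMT,..."` string.
#' @export
format_mutations <- function(mutations) {
  paste(sprintf("%s:%s%d%s", mutations$chain, mutations$wt,
                mutations$pos, mutations$mt), collapse = ",")
}

#' Apply point mutations to a set of chains
#'
#' @param chains Named character vector of chain sequences; names are
#'   chain ids.
#' @param mutations Mutation data.frame (columns `chain`, `wt`, `pos`,
#'   `mt`); positions are 1-based indices into the named chain.
#' @return Named character vector of mutated sequences; the input is not
#'   modified.
#' @examples
#' apply_mutations(c(A = "AYC"), parse_mutation_string("A:Y2W"))
#' @export
apply_mutations <- function(chains, mutations) {
  stopifnot(is.character(chains), !is.null(names(chains)))
  if (is.null(mutations) || nrow(mutations) == 0L) return(chains)
  for (i in seq_len(nrow(mutations))) {
    ch <- mutations$chain[i]
    if (!ch %in% names(chains))
      stop("mutation references unknown chain '", ch, "'", call. = FALSE)
    seq <- chains[[ch]]
    pos <- mutations$pos[i]
    if (pos < 1L || pos > nchar(seq))
      stop(sprintf("position %d out of range for chain '%s' (length %d)",
                   pos, ch, nchar(seq)), call. = FALSE)
    found <- substr(seq, pos, pos)
    if (found != mutations$wt[i])
      stop(sprintf(
        "wild-type mismatch on chain '%s' position %d: expected '%s', found '%s'",
        ch, pos, mutations$wt[i], found), call. = FALSE)
    substr(seq, pos, pos) <- mutations$mt[i]
    chains[[ch]] <- seq
  }
  chains
}

#' Read a FASTA file of amino-acid sequences
#'
#' Sequences are uppercased; duplicate ids, empty records and gap/stop
#' characters are rejected.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences in file order.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id '", ids[duplicated(ids)][1L], "'", call. = FALSE)
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[i])) stop("empty sequence for id '", ids[i], "'",
                               call. = FALSE)
    assert_sequence(seqs[i], paste0("sequence '", ids[i], "'"))
  }
  stats::setNames(seqs, ids)
}

# ---- dialects -------------------------------------------------------------

#' Load a mutation-table dialect configuration
#'
#' Dialects map source-specific CSV column names onto the canonical
#' record fields.  `"abbind"`, `"skempi"` and `"synthetic"` ship with the
#' package; a path to a custom YAML file is also accepted.
#'
#' @param dialect Built-in dialect name or path to a YAML config.
#' @return Named list of dialect settings.
#' @export
dialect_config <- function(dialect) {
  path <- if (file.exists(dialect)) dialect else
    system.file("extdata", "dialects", paste0(dialect, ".yaml"),
                package = "seqddg")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown dialect '", dialect, "'", call. = FALSE)
  yaml::read_yaml(path)
}

split_field <- function(x, sep) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, sep, fixed = TRUE)[[1]]
}

# per-chain offsets field like "H:-2;L:0"; sequence position = table
# position - offset
parse_offsets <- function(x, sep = ";") {
  toks <- split_field(x, sep)
  if (length(toks) == 0L) return(NULL)
  parts <- strsplit(toks, ":", fixed = TRUE)
  stats::setNames(as.integer(vapply(parts, `[[`, "", 2L)),
                  vapply(parts, `[[`, "", 1L))
}

validate_record_row <- function(rec) {
  chains <- c(rec$ab_chains, rec$ag_chains)
  if (any(!nzchar(chains))) return("empty chain sequence")
  for (nm in names(chains)) {
    ok <- tryCatch({assert_sequence(chains[[nm]], nm); TRUE},
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) return(ok)
  }
  if (anyDuplicated(names(chains))) return("duplicate chain id")
  ok <- tryCatch({apply_mutations(chains, rec$mutations); TRUE},
                 error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) return(ok)
  if (!is.finite(rec$ddg)) return("non-finite ddG label")
  TRUE
}

#' Load a mutation dataset from a CSV/TSV table
#'
#' One record is built per row; rows violating record invariants (chain
#' membership, wild-type residue identity at the mutated position, legal
#' alphabet) are reported with their row numbers.  An optional per-chain
#' offsets column lets tables using author/PDB numbering be shifted onto
#' 1-based sequence positions; without it, sequential numbering is
#' assumed and mismatches fail loudly.
#'
#' @param path Path to the table.
#' @param dialect Dialect name or YAML path, see [dialect_config()].
#' @param strict If `TRUE` (default) any invalid row is an error;
#'   otherwise invalid rows are dropped with a warning.
#' @param quiet Suppress the summary message.
#' @return A `mutation_dataset` data.frame.
#' @export
load_dataset <- function(path, dialect = "synthetic", strict = TRUE,
                         quiet = FALSE) {
  cfg <- dialect_config(dialect)
  raw <- utils::read.csv(path, sep = cfg$sep %||% ",", check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("empty table: ", path, call. = FALSE)
  need <- unlist(cfg[c("col_complex", "col_ab_chains", "col_ag_chains",
                       "col_ab_seq", "col_ag_seq", "col_mutations",
                       "col_ddg")])
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  chain_sep <- cfg$chain_sep %||% ";"
  style <- cfg$mutation_style %||% "colon"

  rows <- vector("list", nrow(raw))
  problems <- character(0)
  for (i in seq_len(nrow(raw))) {
    res <- tryCatch({
      ab_ids <- split_field(raw[i, cfg$col_ab_chains], chain_sep)
      ag_ids <- split_field(raw[i, cfg$col_ag_chains], chain_sep)
      ab_seqs <- toupper(split_field(raw[i, cfg$col_ab_seq], chain_sep))
      ag_seqs <- toupper(split_field(raw[i, cfg$col_ag_seq], chain_sep))
      if (length(ab_ids) != length(ab_seqs) ||
          length(ag_ids) != length(ag_seqs))
        stop("chain id / sequence count mismatch", call. = FALSE)
      muts <- parse_mutation_string(as.character(raw[i, cfg$col_mutations]),
                                    style = style)
      if (!is.null(cfg$col_offsets) && cfg$col_offsets %in% names(raw)) {
        off <- parse_offsets(as.character(raw[i, cfg$col_offsets]), chain_sep)
        if (!is.null(off)) {
          shift <- off[muts$chain]
          shift[is.na(shift)] <- 0L
          muts$pos <- muts$pos - as.integer(shift)
        }
      }
      rec <- list(complex_id = as.character(raw[i, cfg$col_complex]),
                  ab_chains = stats::setNames(ab_seqs, ab_ids),
                  ag_chains = stats::setNames(ag_seqs, ag_ids),
                  mutations = muts,
                  ddg = as.numeric(raw[i, cfg$col_ddg]))
      v <- validate_record_row(rec)
      if (!isTRUE(v)) stop(v, call. = FALSE)
      data.frame(complex_id = rec$complex_id,
                 ab_chains = paste(ab_ids, collapse = ";"),
                 ag_chains = paste(ag_ids, collapse = ";"),
                 ab_seq = paste(ab_seqs, collapse = ";"),
                 ag_seq = paste(ag_seqs, collapse = ";"),
                 mutations = format_mutations(muts),
                 ddg = rec$ddg, stringsAsFactors = FALSE)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      problems <- c(problems, sprintf("row %d: %s", i, res))
      rows[[i]] <- NULL
    } else rows[[i]] <- res
  }
  if (length(problems)) {
    msg <- paste(problems, collapse = "\n  ")
    if (strict) stop("invalid record(s):\n  ", msg, call. = FALSE)
    warning("dropped ", length(problems), " invalid record(s):\n  ", msg,
            call. = FALSE)
  }
  df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(df) || nrow(df) == 0L)
    stop("no valid records in ", path, call. = FALSE)
  ds <- new_mutation_dataset(df, name = basename(path),
                             provenance = cfg$provenance %||% "synthetic")
  if (!quiet) {
    npts <- vapply(strsplit(ds$mutations, ","), length, integer(1))
    message(sprintf(
      "loaded %d records / %d complexes (%d single-point, %d multi-point)",
      nrow(ds), length(unique(ds$complex_id)), sum(npts == 1L),
      sum(npts > 1L)))
  }
  ds
}

#' Write a dataset in the canonical CSV dialect
#' @param dataset A `mutation_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset)[, DATASET_COLUMNS], path,
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Extract one parsed record from a dataset
#'
#' @param dataset A `mutation_dataset`.
#' @param i Row index.
#' @return List with `complex_id`, named chain vectors `ab_chains` and
#'   `ag_chains`, a `mutations` data.frame, and the `ddg` label.
#' @export
dataset_record <- function(dataset, i) {
  row <- dataset[i, ]
  list(
    complex_id = row$complex_id,
    ab_chains = stats::setNames(split_field(row$ab_seq, ";"),
                                split_field(row$ab_chains, ";")),
    ag_chains = stats::setNames(split_field(row$ag_seq, ";"),
                                split_field(row$ag_chains, ";")),
    mutations = parse_mutation_string(row$mutations),
    ddg = row$ddg
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
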