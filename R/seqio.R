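#' Read protein sequences from a FASTA file
#'
#' Reads a FASTA file into a tibble of identifier/residue pairs, sanitizing
#' each record so that downstream encoders only ever see the 20 standard
#' amino-acid letters. Record IDs are the first whitespace-delimited token of
#' each header line.
#'
#' Two sanitization policies are available. `"drop"` (the default) uppercases
#' the sequence and removes every character outside the standard alphabet
#' (ambiguity codes such as B/J/X/Z, the rare U/O, gap characters and stop
#' marks), warning with a count of affected records; records left empty are
#' skipped (also with a warning) and reported in the `skipped` attribute.
#' `"reject"` errors on the first record containing any non-standard
#' character after uppercasing.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped sequence lines).
#' @param policy Sanitization policy, `"drop"` or `"reject"`.
#' @return A tibble with columns `id` and `residues`, in file order.
#'   Attribute `skipped` holds the IDs of records dropped because nothing
#'   remained after sanitization.
#' @seealso [write_fasta()], [load_labeled()]
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 some description", "ACDEF", ">p2", "MKVL"), fa)
#' read_fasta(fa)
read_fasta <- function(path, policy = c("drop", "reject")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) {
    abort(sprintf("cannot read FASTA file '%s': no such file", path))
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    abort(sprintf("duplicate sequence ID '%s' in '%s'", dup, path))
  }
  raw <- as.character(set)
  clean <- vapply(raw, sanitize_residues, character(1),
                  policy = policy, USE.NAMES = FALSE)

  n_modified <- sum(clean != toupper(raw))
  if (policy == "drop" && n_modified > 0) {
    warn(sprintf("%d record(s) in '%s' contained non-standard residues; dropped",
                 n_modified, path))
  }
  keep <- nzchar(clean)
  if (any(!keep)) {
    warn(sprintf("skipped %d record(s) with no standard residues: %s",
                 sum(!keep), paste(ids[!keep], collapse = ", ")))
  }
  out <- tibble(id = ids[keep], residues = clean[keep])
  attr(out, "skipped") <- ids[!keep]
  out
}

#' Sanitize a residue string
#'
#' Uppercases the string, then either removes (`"drop"`) or rejects
#' (`"reject"`) characters outside the 20-letter standard amino-acid
#' alphabet. Idempotent under both policies.
#'
#' @param residues A single residue string.
#' @param policy `"drop"` or `"reject"`.
#' @return The sanitized string (possibly empty under `"drop"`).
#' @export
sanitize_residues <- function(residues, policy = c("drop", "reject")) {
  policy <- match.arg(policy)
  up <- toupper(residues)
  chars <- strsplit(up, "", fixed = TRUE)[[1]]
  ok <- chars %in% AA20
  if (policy == "reject" && !all(ok)) {
    abort(sprintf("non-standard residue '%s' (policy = \"reject\")",
                  chars[!ok][1]))
  }
  paste(chars[ok], collapse = "")
}

#' Write sequences to a FASTA file
#'
#' @param data A tibble/data frame with columns `id` and `residues`.
#' @param path Output file path.
#' @param width Line-wrap width for sequence lines (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path, width = 60) {
  stopifnot(all(c("id", "residues") %in% names(data)))
  set <- Biostrings::BStringSet(stats::setNames(data$residues, data$id))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Load a labeled two-class dataset from a positive and a negative FASTA
#'
#' Positives (MHC) are labeled 1, negatives (non-MHC) 0; the result keeps
#' positives first, then negatives, each in file order.
#'
#' @param pos_path FASTA file of positive (MHC) sequences.
#' @param neg_path FASTA file of negative (non-MHC) sequences.
#' @inheritParams read_fasta
#' @return A tibble with columns `id`, `residues`, `label` (integer 0/1).
#' @export
load_labeled <- function(pos_path, neg_path, policy = c("drop", "reject")) {
  policy <- match.arg(policy)
  pos <- read_fasta(pos_path, policy)
  neg <- read_fasta(neg_path, policy)
  clash <- intersect(pos$id, neg$id)
  if (length(clash) > 0) {
    abort(sprintf("ID(s) present in both classes: %s",
                  paste(head(clash, 5), collapse = ", ")))
  }
  dplyr::bind_rows(
    dplyr::mutate(pos, label = 1L),
    dplyr::mutate(neg, label = 0L)
  )
}

#' Read a two-column id/label table
#'
#' Plain TSV with columns `id` and `label` (0/1); a header line is detected
#' and skipped automatically.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `id` (character) and `label` (integer).
#' @export
read_label_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0) {
    abort(sprintf("label table line %d does not have two tab-separated fields", bad[1]))
  }
  first_lab <- if (length(parts) > 0) parts[[1]][2] else NA_character_
  if (length(parts) > 0 && !first_lab %in% c("0", "1") &&
      is.na(suppressWarnings(as.numeric(first_lab)))) {
    parts <- parts[-1]  # header
  }
  lab <- vapply(parts, `[`, character(1), 2)
  if (!all(lab %in% c("0", "1"))) {
    abort("labels must be 0 or 1")
  }
  tibble(
    id = vapply(parts, `[`, character(1), 1),
    label = as.integer(lab)
  )
}

#' Assign stratified cross-validation folds
#'
#' Splits a labeled dataset into `n_folds` folds, stratified by class so
#' that within each class the fold sizes differ by at most one. The
#' assignment is deterministic for a fixed seed.
#'
#' @param data A tibble with a `label` column (0/1), one row per sequence.
#' @param n_folds Number of folds (>= 2).
#' @param seed Integer seed controlling the shuffle.
#' @return `data` with an integer `fold` column (values in 1..`n_folds`)
#'   appended.
#' @export
#' @examples
#' d <- tibble::tibble(id = paste0("s", 1:20), label = rep(0:1, each = 10))
#' table(stratified_kfold(d, 5, seed = 1)$fold, d$label)
stratified_kfold <- function(data, n_folds, seed) {
  stopifnot("label" %in% names(data))
  if (n_folds < 2) {
    abort("n_folds must be at least 2")
  }
  counts <- table(factor(data$label, levels = c(0L, 1L)))
  if (any(counts < n_folds)) {
    small <- names(counts)[counts < n_folds][1]
    abort(sprintf("class %s has %d members, fewer than n_folds = %d",
                  small, counts[[small]], n_folds))
  }
  fold <- integer(nrow(data))
  withr::with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- which(data$label == cls)
      fold[sample(idx)] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  dplyr::mutate(data, fold = fold)
}
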