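#' Read protein sequences from a FASTA file
#'
#' Parses a multi-entry FASTA file into a record table. Sequences are
#' uppercased, whitespace is stripped, and multi-line entries are
#' concatenated. The record id is the first whitespace-delimited token of
#' the header; the remainder of the header is kept as a description.
#'
#' @param path Path to a FASTA file.
#' @param label Optional binary class label (1 = positive/AFP,
#'   0 = negative/non-AFP) applied to every record in the file.
#' @return A data frame of class `afp_records` with columns `id`,
#'   `sequence`, `label` (integer or `NA`), `length` and `description`,
#'   one row per FASTA entry in file order.
#' @seealso [validate_sequences()], [load_dataset()], [write_fasta()]
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 toy", "MKAL", ">p2", "MK", "AL"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, label = NULL) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("no FASTA entries in ", path)
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("empty sequence for record(s): ",
         paste(ids[empty], collapse = ", "))
  }
  dup <- duplicated(ids)
  if (any(dup)) {
    stop("duplicate record id(s): ",
         paste(unique(ids[dup]), collapse = ", "))
  }
  if (!is.null(label)) {
    label <- as.integer(label)
    stopifnot(length(label) == 1L, label %in% c(0L, 1L))
  }
  records <- data.frame(
    id = ids,
    sequence = seqs,
    label = if (is.null(label)) NA_integer_ else label,
    length = nchar(seqs),
    description = desc,
    stringsAsFactors = FALSE
  )
  class(records) <- c("afp_records", "data.frame")
  records
}

#' Write records back to FASTA
#'
#' Inverse of [read_fasta()]: ids (plus descriptions, when present) become
#' headers and sequences are written as single lines, so a write/read
#' round trip reproduces ids and sequences exactly.
#'
#' @param records An `afp_records` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  headers <- records$id
  if (!is.null(records$description)) {
    has_desc <- nzchar(records$description)
    headers[has_desc] <- paste(records$id[has_desc], records$description[has_desc])
  }
  writeLines(paste0(">", headers, "\n", records$sequence), path, sep = "\n")
  invisible(path)
}

#' Validate sequences against the 20-letter amino-acid alphabet
#'
#' The composition encoders are defined only over the 20 standard residues,
#' so non-standard letters (B, J, O, U, X, Z — ambiguity and rare codes)
#' must be handled before encoding. Under `"drop_nonstandard"` (the
#' default) they are removed and lengths recomputed; under `"reject"` any
#' such letter is an error naming the record, character and position.
#' Letters outside the amino-acid code entirely (digits, `*`, ...) are
#' always an error.
#'
#' @param records An `afp_records` data frame (or anything with `id` and
#'   `sequence` columns).
#' @param policy `"drop_nonstandard"` or `"reject"`.
#' @return The validated records with `sequence` and `length` updated.
#' @export
validate_sequences <- function(records,
                               policy = c("drop_nonstandard", "reject")) {
  policy <- match.arg(policy)
  seqs <- toupper(records$sequence)
  standard <- paste(aa_alphabet, collapse = "")
  for (i in seq_along(seqs)) {
    bad <- regmatches(seqs[i], gregexpr(sprintf("[^%s]", standard), seqs[i]))[[1]]
    if (length(bad) == 0L) next
    unknown <- setdiff(unique(bad), nonstandard_letters)
    if (length(unknown) > 0L) {
      stop("record ", records$id[i], ": unrecognized character(s) ",
           paste(unknown, collapse = ", "))
    }
    if (policy == "reject") {
      pos <- regexpr(sprintf("[^%s]", standard), seqs[i])
      stop("record ", records$id[i], ": non-standard residue '",
           substr(seqs[i], pos, pos), "' at position ", pos)
    }
    seqs[i] <- gsub(sprintf("[^%s]", standard), "", seqs[i])
    if (!nzchar(seqs[i])) {
      stop("record ", records$id[i],
           ": sequence empty after removing non-standard residues")
    }
  }
  records$sequence <- seqs
  records$length <- nchar(seqs)
  records
}

#' Load a labeled positive/negative benchmark dataset
#'
#' Reads a positive (label 1) and a negative (label 0) FASTA file,
#' validates both, and returns a single labeled record table. The class
#' counts are available via `table(dataset$label)` and are attached as the
#' `class_counts` attribute.
#'
#' @param pos_path FASTA of positive (AFP) sequences.
#' @param neg_path FASTA of negative (non-AFP) sequences.
#' @param policy Validation policy, see [validate_sequences()].
#' @return An `afp_records` data frame with every record labeled.
#' @examples
#' pos <- tempfile(fileext = ".fasta"); neg <- tempfile(fileext = ".fasta")
#' writeLines(c(">a1", "MKALCW"), pos)
#' writeLines(c(">n1", "GGGS", ">n2", "PQRST"), neg)
#' ds <- load_dataset(pos, neg)
#' attr(ds, "class_counts")
#' @export
load_dataset <- function(pos_path, neg_path,
                         policy = c("drop_nonstandard", "reject")) {
  policy <- match.arg(policy)
  pos <- validate_sequences(read_fasta(pos_path, label = 1L), policy)
  neg <- validate_sequences(read_fasta(neg_path, label = 0L), policy)
  clash <- intersect(pos$id, neg$id)
  if (length(clash) > 0L) {
    stop("record id(s) present in both files: ",
         paste(clash, collapse = ", "))
  }
  dataset <- rbind(pos, neg)
  rownames(dataset) <- NULL
  class(dataset) <- c("afp_records", "data.frame")
  attr(dataset, "class_counts") <- c(`1` = nrow(pos), `0` = nrow(neg))
  dataset
}

#' @export
print.afp_records <- function(x, ...) {
  n <- nrow(x)
  cat("afp_records: ", n, " sequence(s)\n", sep = "")
  if (!all(is.na(x$label))) {
    tab <- table(factor(x$label, levels = c(1, 0)))
    cat("  labels: ", tab[["1"]], " positive / ", tab[["0"]],
        " negative\n", sep = "")
  }
  cat("  length: ", min(x$length), "-", max(x$length),
      " (median ", stats::median(x$length), ")\n", sep = "")
  invisible(x)
}
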