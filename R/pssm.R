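#' Construct a PSSM object
#'
#' An L x 20 position-specific scoring matrix with its query residues.
#' Columns follow the fixed PSI-BLAST order [pssm_column_order]
#' (A R N D C Q E G H I L K M F P S T W Y V).
#'
#' @param scores Numeric L x 20 matrix of log-odds scores.
#' @param residues Character vector of length L, the query residue per row.
#' @param record_id Identifier linking the profile to its sequence record.
#' @param normalized Logical; `TRUE` once scores have been squashed to
#'   (0, 1) by [normalize_pssm()].
#' @return An object of class `pssm`.
#' @export
pssm <- function(scores, residues, record_id = "", normalized = FALSE) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (ncol(scores) != 20L) {
    stop("a PSSM must have exactly 20 columns, got ", ncol(scores))
  }
  if (nrow(scores) == 0L) stop("empty PSSM")
  if (nrow(scores) != length(residues)) {
    stop("row count (", nrow(scores), ") does not match residue column (",
         length(residues), ")")
  }
  colnames(scores) <- pssm_column_order
  rownames(scores) <- NULL
  structure(
    list(record_id = record_id, scores = scores,
         residues = as.character(residues), normalized = isTRUE(normalized)),
    class = "pssm"
  )
}

#' @export
print.pssm <- function(x, ...) {
  cat("pssm '", x$record_id, "': ", nrow(x$scores), " x 20, ",
      if (x$normalized) "normalized (0,1)" else "raw log-odds", "\n", sep = "")
  invisible(x)
}

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the `-out_ascii_pssm` dialect: three header lines, then one row
#' per residue holding the position index, the query residue, twenty
#' log-odds integers, twenty weighted-percentage columns and two trailing
#' floats. Only the first (log-odds) block is retained: the sigmoid
#' normalization applied downstream is the chosen squashing for log-odds,
#' while the percentage block is already bounded. Footer lines after the
#' matrix are ignored.
#'
#' @param path Path to the PSSM file.
#' @param record_id Id to attach; defaults to the file name without the
#'   `.pssm` extension.
#' @param residues Optional expected query sequence; a mismatch with the
#'   file's residue column raises a warning (PSI-BLAST masks
#'   low-complexity residues to X in its echo column), never an error.
#' @return A `pssm` object with `normalized = FALSE`.
#' @export
read_pssm_ascii <- function(path, record_id = NULL, residues = NULL) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  if (is.null(record_id)) {
    record_id <- sub("\\.pssm$", "", basename(path))
  }
  lines <- readLines(path)
  if (length(lines) < 4L) stop("PSSM file too short: ", path)
  body <- lines[-(1:3)]
  is_row <- grepl("^\\s*[0-9]+\\s+[A-Z]\\b", body)
  # matrix rows are contiguous from the top of the body; anything after the
  # first non-row line is footer
  end <- if (all(is_row)) length(body) else which(!is_row)[1] - 1L
  if (end < 1L) stop("no matrix rows found in ", path)
  rows <- body[seq_len(end)]
  fields <- strsplit(trimws(rows), "\\s+")
  nf <- lengths(fields)
  bad <- which(nf != 44L)
  if (length(bad) > 0L) {
    stop("malformed PSSM row at line ", bad[1] + 3L, " of ", path,
         ": expected 44 fields, got ", nf[bad[1]])
  }
  res <- vapply(fields, `[`, character(1), 2L)
  scores <- t(vapply(fields, function(f) as.numeric(f[3:22]), numeric(20)))
  if (anyNA(scores)) stop("non-numeric score in PSSM ", path)
  out <- pssm(scores, res, record_id = record_id, normalized = FALSE)
  if (!is.null(residues)) {
    expected <- strsplit(toupper(residues), "")[[1]]
    if (length(expected) != length(res) || any(expected != res)) {
      warning("PSSM residue column for '", record_id,
              "' disagrees with the paired sequence; PSSM retained")
    }
  }
  out
}

#' Write a PSSM in PSI-BLAST ASCII dialect
#'
#' Renders a raw (unnormalized) PSSM so that [read_pssm_ascii()] recovers
#' the scores bit-exactly. The percentage block is filled with zeros and
#' the two trailing floats with `0.00` placeholders; both are ignored on
#' read.
#'
#' @param x A `pssm` object with integer-valued raw scores.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm_ascii <- function(x, path) {
  stopifnot(inherits(x, "pssm"))
  if (x$normalized) stop("refusing to write a normalized PSSM as log-odds")
  hdr <- c(
    "",
    paste("Last position-specific scoring matrix computed, weighted",
          "observed percentages rounded down, information per position,",
          "and relative weight of gapless real matches to pseudocounts"),
    paste0("           ",
           paste(sprintf("%3s", c(pssm_column_order, pssm_column_order)),
                 collapse = ""))
  )
  body <- vapply(seq_len(nrow(x$scores)), function(m) {
    paste0(sprintf("%5d %s ", m, x$residues[m]),
           paste(sprintf("%3d", as.integer(round(x$scores[m, ]))),
                 collapse = ""),
           paste(sprintf("%4d", integer(20)), collapse = ""),
           sprintf("  %4.2f %8.2f", 0, 0))
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Sigmoid-normalize a PSSM
#'
#' Squashes every log-odds entry t to 1 / (1 + exp(-t)), mapping the
#' matrix into the open interval (0, 1) while preserving the ordering of
#' entries. Applying it twice is an error, guarding against silently
#' squashing already-normalized scores.
#'
#' @param x A `pssm` object with `normalized = FALSE`.
#' @return The `pssm` with squashed scores and `normalized = TRUE`.
#' @export
normalize_pssm <- function(x) {
  stopifnot(inherits(x, "pssm"))
  if (x$normalized) stop("PSSM '", x$record_id, "' is already normalized")
  x$scores <- 1 / (1 + exp(-x$scores))
  x$normalized <- TRUE
  x
}

#' Plan a three-way row partition of a PSSM
#'
#' Both PSSM descriptors cut the profile into three contiguous row blocks
#' of near-equal size: the first two take floor(L/3) rows and the third
#' takes the remainder, L - 2*floor(L/3). `mode` records which descriptor
#' the plan serves ("slice" for the tri-sliced pseudo descriptor,
#' "segment" for segmented autocorrelation); the geometry is identical.
#'
#' @param L Number of profile rows (sequence length); must be at least 3.
#' @param mode `"slice"` or `"segment"`.
#' @return A `partition_plan`: list with `mode`, `sizes` (length 3) and
#'   `rows`, a list of three integer row-index vectors covering `1:L`.
#' @examples
#' plan_partition(10, "slice")$sizes  # 3 3 4
#' @export
plan_partition <- function(L, mode = c("slice", "segment")) {
  mode <- match.arg(mode)
  L <- as.integer(L)
  if (is.na(L) || L < 3L) {
    stop("sequence too short to partition (L = ", L, ", need >= 3)")
  }
  s <- L %/% 3L
  sizes <- c(s, s, L - 2L * s)
  starts <- c(1L, s + 1L, 2L * s + 1L)
  rows <- Map(function(a, n) seq.int(a, length.out = n), starts, sizes)
  structure(list(mode = mode, sizes = sizes, rows = rows), class = "partition_plan")
}

#' @export
print.partition_plan <- function(x, ...) {
  cat("partition_plan (", x$mode, "): sizes ",
      paste(x$sizes, collapse = " + "), " = ", sum(x$sizes), " rows\n", sep = "")
  invisible(x)
}
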