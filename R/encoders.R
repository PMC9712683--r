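#' Encoder configuration
#'
#' Tunable settings shared by the profile-based encoders. `act_lags`
#' controls the autocorrelation lags of the segmented descriptor (default
#' lag 1, giving the canonical 60 dimensions; lags `c(1, 2)` give 120).
#' `pse_mode` selects what each slice of the tri-sliced pseudo descriptor
#' contributes: per-column means (default, 60 dimensions),
#' rank-correlation factors, or both; `pse_ranks` lists the ranks used by
#' the correlation factors.
#'
#' @param act_lags Positive integers, autocorrelation lags.
#' @param pse_ranks Positive integers, pseudo correlation ranks (may be
#'   empty when `pse_mode = "means"`).
#' @param pse_mode One of `"means"`, `"corr"`, `"means+corr"`.
#' @return A list of class `encoder_config`.
#' @export
encoder_config <- function(act_lags = 1L, pse_ranks = integer(0),
                           pse_mode = c("means", "corr", "means+corr")) {
  pse_mode <- match.arg(pse_mode)
  act_lags <- sort(unique(as.integer(act_lags)))
  pse_ranks <- sort(unique(as.integer(pse_ranks)))
  if (length(act_lags) == 0L || any(act_lags < 1L)) {
    stop("act_lags must be positive integers")
  }
  if (any(pse_ranks < 1L)) stop("pse_ranks must be positive integers")
  if (pse_mode != "means" && length(pse_ranks) == 0L) {
    stop("pse_mode '", pse_mode, "' requires at least one rank in pse_ranks")
  }
  structure(list(act_lags = act_lags, pse_ranks = pse_ranks,
                 pse_mode = pse_mode, gaac_groups = gaac_groups),
            class = "encoder_config")
}

#' Grouped amino-acid composition (GAAC)
#'
#' Frequency of each of the five physicochemical residue groups
#' (aliphatic AGLIMV, negatively charged DE, aromatic FWY, positively
#' charged HRK, uncharged CNPQST): count of residues in the group divided
#' by the sequence length. Always 5 features summing to 1.
#'
#' @param sequence A validated amino-acid sequence (single string).
#' @return Named numeric vector `GAAC.G1` .. `GAAC.G5`.
#' @examples
#' encode_gaac("ADFHC")  # one residue per group: 0.2 each
#' @export
encode_gaac <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  if (n < 1L) stop("empty sequence")
  chars <- strsplit(sequence, "")[[1]]
  counts <- vapply(gaac_groups, function(g) sum(chars %in% g), numeric(1))
  stats::setNames(counts / n, paste0("GAAC.", names(gaac_groups)))
}

# 400 dipeptides in fixed lexicographic order: AA, AC, ..., YY
dpc_names <- local({
  grid <- expand.grid(second = aa_alphabet, first = aa_alphabet,
                      stringsAsFactors = FALSE)
  paste0(grid$first, grid$second)
})

#' Dipeptide composition (DPC)
#'
#' Frequencies of the 400 ordered adjacent residue pairs: count of each
#' dipeptide divided by the number of dipeptides in the sequence (L - 1),
#' so the 400 values sum to 1.
#'
#' @param sequence A validated amino-acid sequence of length >= 2.
#' @return Named numeric vector `DPC.AA` .. `DPC.YY` (lexicographic).
#' @examples
#' v <- encode_dpc("ACAC")
#' v[v > 0]  # AC: 2/3, CA: 1/3
#' @export
encode_dpc <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  L <- nchar(sequence)
  if (L < 2L) stop("sequence too short for DPC (need length >= 2)")
  chars <- strsplit(sequence, "")[[1]]
  pairs <- paste0(chars[-L], chars[-1])
  counts <- table(factor(pairs, levels = dpc_names))
  stats::setNames(as.numeric(counts) / (L - 1L), paste0("DPC.", dpc_names))
}

check_pssm_part <- function(x, plan, index) {
  stopifnot(inherits(x, "pssm"), inherits(plan, "partition_plan"))
  if (!x$normalized) stop("PSSM must be normalized before encoding")
  if (sum(plan$sizes) != nrow(x$scores)) {
    stop("partition plan covers ", sum(plan$sizes),
         " rows but PSSM has ", nrow(x$scores))
  }
  if (!(index %in% 1:3)) stop("part index must be 1, 2 or 3")
  x$scores[plan$rows[[index]], , drop = FALSE]
}

#' Per-column mean of one PSSM slice
#'
#' The composition of a slice: the arithmetic mean of each of the 20
#' profile columns over the slice's rows.
#'
#' @param x A normalized `pssm`.
#' @param plan A `partition_plan` (mode `"slice"`).
#' @param slice_index 1, 2 or 3.
#' @return Named numeric vector of 20 column means.
#' @export
slice_composition <- function(x, plan, slice_index) {
  part <- check_pssm_part(x, plan, slice_index)
  if (nrow(part) == 0L) stop("empty slice")
  colMeans(part)
}

#' Pseudo rank-correlation factors of a PSSM part
#'
#' For each profile column, the mean squared difference between entries
#' `rank` rows apart within the part: sequence-order information beyond
#' composition.
#'
#' @param part Numeric matrix, the rows of a normalized PSSM part.
#' @param rank Positive integer, strictly smaller than `nrow(part)`.
#' @return Numeric vector of 20 correlation factors.
#' @export
pse_correlation <- function(part, rank) {
  part <- as.matrix(part)
  n <- nrow(part)
  rank <- as.integer(rank)
  if (rank < 1L) stop("rank must be positive")
  if (n <= rank) {
    stop("rank exceeds slice length (", n, " rows, rank ", rank, ")")
  }
  d <- part[seq_len(n - rank), , drop = FALSE] -
    part[seq.int(rank + 1L, n), , drop = FALSE]
  colMeans(d^2)
}

#' Pseudo tri-sliced PSSM descriptor (PseTS-PSSM)
#'
#' Splits the normalized profile into three row slices and encodes each.
#' With the default configuration each slice contributes its 20 column
#' means, giving 60 features. With `pse_mode` `"corr"` or `"means+corr"`
#' each slice additionally (or instead) contributes 20 rank-correlation
#' factors per configured rank (see [pse_correlation()]), appended
#' slice by slice.
#'
#' @param x A normalized `pssm`.
#' @param config An [encoder_config()].
#' @return Named numeric vector; 60 values under the defaults. Names
#'   follow `PSETS.slice<i>.<mean|rank<r>>.<column letter>`.
#' @export
encode_psets_pssm <- function(x, config = encoder_config()) {
  stopifnot(inherits(x, "pssm"))
  L <- nrow(x$scores)
  ranks <- if (config$pse_mode == "means") integer(0) else config$pse_ranks
  if (length(ranks) > 0L) {
    need <- 3L * (max(ranks) + 1L)
    if (L < need) {
      stop("sequence too short for rank ", max(ranks),
           " correlation factors (L = ", L, ", need >= ", need, ")")
    }
  }
  plan <- plan_partition(L, "slice")
  out <- numeric(0)
  for (i in 1:3) {
    part <- check_pssm_part(x, plan, i)
    if (config$pse_mode %in% c("means", "means+corr")) {
      block <- colMeans(part)
      names(block) <- paste0("PSETS.slice", i, ".mean.", pssm_column_order)
      out <- c(out, block)
    }
    for (r in ranks) {
      block <- pse_correlation(part, r)
      names(block) <- paste0("PSETS.slice", i, ".rank", r, ".",
                             pssm_column_order)
      out <- c(out, block)
    }
  }
  out
}

#' Lagged autocovariance of one PSSM segment
#'
#' For each profile column, the lag-`lag` autocovariance of that column
#' within the segment: mean over positions m of
#' (A\[m\] - mu)(A\[m + lag\] - mu), where mu is the segment's own column
#' mean and the mean is over the segment-length-minus-lag admissible
#' pairs. Pairs never straddle segment boundaries.
#'
#' @param x A normalized `pssm`.
#' @param plan A `partition_plan` (mode `"segment"`).
#' @param segment_index 1, 2 or 3.
#' @param lag Positive integer smaller than the segment length.
#' @return Numeric vector of 20 autocovariances.
#' @export
segment_act <- function(x, plan, segment_index, lag = 1L) {
  part <- check_pssm_part(x, plan, segment_index)
  n <- nrow(part)
  lag <- as.integer(lag)
  if (lag < 1L) stop("lag must be positive")
  if (n <= lag) {
    stop("segment length (", n, ") must exceed lag (", lag, ")")
  }
  dev <- sweep(part, 2L, colMeans(part))
  colSums(dev[seq_len(n - lag), , drop = FALSE] *
            dev[seq.int(lag + 1L, n), , drop = FALSE]) / (n - lag)
}

#' Segmented PSSM autocorrelation descriptor (Sg-PSSM-ACT)
#'
#' Splits the normalized profile into three row segments and, for each
#' segment and each configured lag, computes the 20 per-column lagged
#' autocovariances (see [segment_act()]). The default lag set \{1\}
#' yields 3 x 20 = 60 features.
#'
#' @param x A normalized `pssm`.
#' @param config An [encoder_config()].
#' @return Named numeric vector; 60 values under the defaults. Names
#'   follow `SGACT.seg<i>.lag<l>.<column letter>`.
#' @export
encode_sg_pssm_act <- function(x, config = encoder_config()) {
  stopifnot(inherits(x, "pssm"))
  L <- nrow(x$scores)
  need <- 3L * (max(config$act_lags) + 1L)
  if (L < need) {
    stop("sequence too short for lag ", max(config$act_lags),
         " autocorrelation (L = ", L, ", need >= ", need, ")")
  }
  plan <- plan_partition(L, "segment")
  out <- numeric(0)
  for (i in 1:3) {
    for (l in config$act_lags) {
      block <- segment_act(x, plan, i, l)
      names(block) <- paste0("SGACT.seg", i, ".lag", l, ".",
                             pssm_column_order)
      out <- c(out, block)
    }
  }
  out
}

#' Fuse per-encoder feature matrices
#'
#' Column-binds feature matrices from different encoders in the order
#' given, checking that every matrix covers the same records in the same
#' order. Feature names already carry their encoder prefix
#' (`GAAC.`, `DPC.`, `PSETS.`, `SGACT.`), so fused names stay unique and
#' auditable.
#'
#' @param blocks Named list of numeric matrices with identical rownames
#'   (record ids).
#' @param which Optional character vector selecting and ordering a subset
#'   of `names(blocks)`.
#' @return A single numeric matrix.
#' @export
fuse_features <- function(blocks, which = names(blocks)) {
  stopifnot(is.list(blocks), length(blocks) > 0L)
  missing_blocks <- setdiff(which, names(blocks))
  if (length(missing_blocks) > 0L) {
    stop("requested encoder block(s) not present: ",
         paste(missing_blocks, collapse = ", "))
  }
  blocks <- blocks[which]
  ids <- rownames(blocks[[1]])
  for (tag in names(blocks)) {
    b <- blocks[[tag]]
    if (is.null(rownames(b)) || !identical(rownames(b), ids)) {
      bad <- if (is.null(rownames(b))) ids else setdiff(ids, rownames(b))
      stop("encoder '", tag, "' missing or misordered for record(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  out <- do.call(cbind, unname(blocks))
  if (anyDuplicated(colnames(out))) stop("duplicate feature names after fusion")
  out
}

#' Encode a dataset into a feature matrix
#'
#' Convenience wrapper running the selected encoders over every record
#' (and its PSSM, for the profile-based encoders) and fusing the blocks.
#' Raw PSSMs are sigmoid-normalized on the fly.
#'
#' @param records An `afp_records` data frame.
#' @param pssms Named list of `pssm` objects keyed by record id; required
#'   when `"PSETS"` or `"SGACT"` is requested.
#' @param encoders Ordered subset of `c("GAAC", "DPC", "PSETS", "SGACT")`.
#' @param config An [encoder_config()].
#' @return Numeric matrix, one row per record (rownames = ids), with the
#'   record labels attached as attribute `"labels"` when present.
#' @export
encode_features <- function(records, pssms = NULL,
                            encoders = c("GAAC", "DPC", "PSETS", "SGACT"),
                            config = encoder_config()) {
  encoders <- match.arg(encoders, several.ok = TRUE)
  need_pssm <- any(encoders %in% c("PSETS", "SGACT"))
  if (need_pssm) {
    if (is.null(pssms)) stop("profile-based encoders need pssms")
    absent <- setdiff(records$id, names(pssms))
    if (length(absent) > 0L) {
      stop("no PSSM for record(s): ",
           paste(utils::head(absent, 5), collapse = ", "))
    }
    pssms <- lapply(pssms[records$id], function(p) {
      if (p$normalized) p else normalize_pssm(p)
    })
  }
  blocks <- list()
  for (tag in encoders) {
    rows <- switch(
      tag,
      GAAC = lapply(records$sequence, encode_gaac),
      DPC = lapply(records$sequence, encode_dpc),
      PSETS = lapply(pssms, encode_psets_pssm, config = config),
      SGACT = lapply(pssms, encode_sg_pssm_act, config = config)
    )
    blocks[[tag]] <- do.call(rbind, rows)
    rownames(blocks[[tag]]) <- records$id
  }
  out <- fuse_features(blocks, encoders)
  if (!all(is.na(records$label))) {
    attr(out, "labels") <- records$label
  }
  out
}
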