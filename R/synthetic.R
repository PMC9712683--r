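#' Synthetic benchmark configuration
#'
#' Conditions for the synthetic sequence/profile generator. Class signal
#' enters at two independent levels: `group_bias` sets per-class sampling
#' weights over the five physicochemical residue groups (driving the
#' composition encoders), and `pssm_signal` mixes residue identity into
#' the synthetic profile columns (driving the PSSM encoders), so each
#' encoder family can be exercised in isolation.
#'
#' Presets: `"strong"` (the default conditions — a clearly separable
#' benchmark: aliphatic-enriched positives, group-1 weight 0.45 vs 0.25,
#' and profile signal 0.8) and `"null"` (identical uniform composition
#' for both classes and pure-noise profiles; no class signal anywhere).
#'
#' @param preset `"strong"` or `"null"`; sets `group_bias` and
#'   `pssm_signal` unless given explicitly.
#' @param n_pos,n_neg Class sizes (default 300 each, the balanced draw of
#'   the evaluation protocol).
#' @param length_range Inclusive sequence-length range; minimum must be
#'   at least 9 so every three-way profile partition is valid at the
#'   default lags.
#' @param group_bias List with numeric weight vectors `pos` and `neg`
#'   over groups G1..G5, each summing to 1.
#' @param pssm_signal Real in \[0, 1\]: weight of the residue-identity
#'   one-hot component in synthetic profile rows.
#' @param pssm_noise_sd Standard deviation of the additive profile noise.
#' @param seed Integer seed; fixes generated sequences and profiles.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(preset = c("strong", "null"),
                         n_pos = 300, n_neg = 300,
                         length_range = c(30, 90),
                         group_bias = NULL,
                         pssm_signal = NULL,
                         pssm_noise_sd = 1,
                         seed = 1) {
  preset <- match.arg(preset)
  uniform <- vapply(gaac_groups, length, numeric(1)) / 20
  if (is.null(group_bias)) {
    group_bias <- switch(
      preset,
      strong = list(pos = c(0.45, 0.10, 0.10, 0.10, 0.25),
                    neg = c(0.25, 0.15, 0.15, 0.20, 0.25)),
      null = list(pos = uniform, neg = uniform)
    )
  }
  if (is.null(pssm_signal)) {
    pssm_signal <- switch(preset, strong = 0.8, null = 0)
  }
  stopifnot(length(length_range) == 2L, length_range[1] >= 9,
            length_range[1] <= length_range[2],
            pssm_signal >= 0, pssm_signal <= 1, pssm_noise_sd >= 0,
            n_pos >= 1, n_neg >= 1)
  for (cls in c("pos", "neg")) {
    w <- group_bias[[cls]]
    if (length(w) != 5L || any(w < 0) || sum(w) == 0) {
      stop("group_bias$", cls, " must be 5 non-negative weights with support")
    }
    group_bias[[cls]] <- w / sum(w)
  }
  structure(list(preset = preset, n_pos = as.integer(n_pos),
                 n_neg = as.integer(n_neg),
                 length_range = as.integer(length_range),
                 group_bias = group_bias, pssm_signal = pssm_signal,
                 pssm_noise_sd = pssm_noise_sd, seed = as.integer(seed)),
            class = "synth_config")
}

# residue-level sampling probabilities implied by group weights
# (uniform within each group)
residue_probs <- function(weights) {
  p <- stats::setNames(numeric(20), aa_alphabet)
  for (g in seq_along(gaac_groups)) {
    members <- gaac_groups[[g]]
    p[members] <- weights[g] / length(members)
  }
  p
}

#' Generate a labeled synthetic sequence dataset
#'
#' Draws each sequence residue-by-residue from its class's group-biased
#' residue distribution (uniform within a group), with lengths uniform
#' over `length_range`. Ids encode class and index (`pos_0001`, ...).
#' Fully reproducible from the config seed.
#'
#' @param config A [synth_config()].
#' @return A labeled `afp_records` data frame.
#' @examples
#' ds <- generate_dataset(synth_config("strong", n_pos = 5, n_neg = 5))
#' ds
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  gen_class <- function(n, weights, prefix) {
    p <- residue_probs(weights)
    len_pool <- seq.int(config$length_range[1], config$length_range[2])
    lens <- len_pool[sample.int(length(len_pool), n, replace = TRUE)]
    seqs <- vapply(lens, function(L) {
      paste(sample(aa_alphabet, L, replace = TRUE, prob = p), collapse = "")
    }, character(1))
    data.frame(id = sprintf("%s_%04d", prefix, seq_len(n)),
               sequence = seqs,
               label = if (prefix == "pos") 1L else 0L,
               length = lens, description = "synthetic",
               stringsAsFactors = FALSE)
  }
  out <- rbind(gen_class(config$n_pos, config$group_bias$pos, "pos"),
               gen_class(config$n_neg, config$group_bias$neg, "neg"))
  class(out) <- c("afp_records", "data.frame")
  attr(out, "class_counts") <- c(`1` = config$n_pos, `0` = config$n_neg)
  out
}

#' Generate one synthetic PSSM
#'
#' Row m of the raw profile is `pssm_signal` times a one-hot template
#' (+6 in the column of the row's own residue, -2 elsewhere — log-odds
#' magnitudes typical of a conserved position) plus Gaussian noise of sd
#' `pssm_noise_sd`, rounded to integers to match the ASCII dialect's
#' integer log-odds block. At `pssm_signal = 0` the profile is pure
#' noise and carries no information about the sequence.
#'
#' @param sequence Amino-acid sequence string.
#' @param config A [synth_config()].
#' @param record_id Id stored in the profile.
#' @param seed Optional seed; when `NULL` the current RNG stream is used
#'   (so [generate_pssms()] stays reproducible as a whole).
#' @return A raw `pssm` (use [write_pssm_ascii()] for the file form).
#' @export
synth_pssm <- function(sequence, config = synth_config(), record_id = "",
                       seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  template <- matrix(-2, nrow = L, ncol = 20,
                     dimnames = list(NULL, pssm_column_order))
  template[cbind(seq_len(L), match(chars, pssm_column_order))] <- 6
  noise <- matrix(stats::rnorm(L * 20, sd = config$pssm_noise_sd), nrow = L)
  scores <- round(config$pssm_signal * template + noise)
  pssm(scores, chars, record_id = record_id, normalized = FALSE)
}

#' Generate PSSMs for every record of a dataset
#'
#' @param records A labeled `afp_records` data frame.
#' @param config A [synth_config()]; profiles are seeded from
#'   `config$seed` (offset so they are independent of the sequence draw).
#' @return Named list of raw `pssm` objects keyed by record id.
#' @export
generate_pssms <- function(records, config = synth_config()) {
  set.seed(config$seed + 1L)
  out <- lapply(seq_len(nrow(records)), function(i) {
    synth_pssm(records$sequence[i], config, record_id = records$id[i])
  })
  names(out) <- records$id
  out
}

#' Write a synthetic benchmark bundle to disk
#'
#' Writes the FASTA, one PSI-BLAST-dialect PSSM file per record
#' (`<id>.pssm`), and a tab-separated labels manifest
#' (id, label, length, source) — the on-disk layout the encoders consume.
#'
#' @param records Labeled `afp_records`.
#' @param pssms Named list of raw `pssm` objects.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_bundle <- function(records, pssms, dir) {
  dir.create(file.path(dir, "pssm"), recursive = TRUE, showWarnings = FALSE)
  write_fasta(records, file.path(dir, "sequences.fasta"))
  for (id in names(pssms)) {
    write_pssm_ascii(pssms[[id]], file.path(dir, "pssm", paste0(id, ".pssm")))
  }
  manifest <- data.frame(id = records$id, label = records$label,
                         length = records$length, source = "synthetic")
  utils::write.table(manifest, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
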