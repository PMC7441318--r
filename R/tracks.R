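#' Fixed-bin intensity tracks
#'
#' An `intensity_track` holds one non-negative score per fixed-width bin per
#' chromosome (default 25 bp, the resolution ENCODE-style signal files use).
#' Bins not covered by any record score 0.
#'
#' @param scores named list (per chromosome) of numeric score vectors.
#' @param bin_bp bin width in bp.
#' @param genome a `genome_layout`; score vector lengths must equal
#'   `ceiling(chrom_length / bin_bp)`.
#' @return an `intensity_track`.
#' @export
intensity_track <- function(scores, bin_bp, genome) {
  stopifnot(bin_bp > 0)
  for (ch in names(scores)) {
    want <- ceiling(chrom_length(genome, ch) / bin_bp)
    if (length(scores[[ch]]) != want) {
      abort(sprintf("chrom %s: expected %d bins, got %d", ch, want,
                    length(scores[[ch]])))
    }
    if (any(scores[[ch]] < 0)) abort("negative intensity score")
  }
  structure(list(scores = scores, bin_bp = bin_bp, genome = genome),
            class = "intensity_track")
}

#' @export
print.intensity_track <- function(x, ...) {
  cat(sprintf("<intensity_track> %d chromosome(s), %d bp bins\n",
              length(x$scores), x$bin_bp))
  invisible(x)
}

#' Read a bedGraph-like score file into an intensity track
#'
#' Records are (chrom, start, end, score), 0-based half-open. Records need
#' not align to the bin grid: each bin takes the maximum score over all
#' records covering any part of it (conservative for downstream peak
#' calling). Uncovered bins score 0.
#'
#' @param path file path.
#' @param genome a `genome_layout`.
#' @param bin_bp bin width (default 25).
#' @return an `intensity_track`.
#' @export
read_bedgraph <- function(path, genome, bin_bp = 25) {
  df <- read_bed(path, genome = genome, extra_names = "score",
                 normalize = FALSE)
  if (nrow(df) > 0 && (!is.numeric(df$score) || any(df$score < 0))) {
    abort(paste0("negative or non-numeric score in ", path))
  }
  scores <- lapply(setNames(nm = genome$chrom$chrom), function(ch) {
    numeric(ceiling(chrom_length(genome, ch) / bin_bp))
  })
  for (i in seq_len(nrow(df))) {
    ch <- df$chrom[i]
    b0 <- floor(df$start[i] / bin_bp) + 1L
    b1 <- ceiling(df$end[i] / bin_bp)
    b1 <- min(b1, length(scores[[ch]]))
    idx <- b0:b1
    scores[[ch]][idx] <- pmax(scores[[ch]][idx], df$score[i])
  }
  intensity_track(scores, bin_bp, genome)
}

#' @rdname read_bedgraph
#' @param track an `intensity_track` to write; runs of equal non-zero bins
#'   are emitted as single records, so reading the file back reproduces the
#'   bin scores exactly.
#' @export
write_bedgraph <- function(track, path) {
  rows <- purrr::imap(track$scores, function(v, ch) {
    if (length(v) == 0L) return(NULL)
    r <- rle(v)
    end_bin <- cumsum(r$lengths)
    start_bin <- end_bin - r$lengths
    keep <- r$values != 0
    if (!any(keep)) return(NULL)
    tibble(chrom = ch,
           start = start_bin[keep] * track$bin_bp,
           end = pmin(end_bin[keep] * track$bin_bp,
                      chrom_length(track$genome, ch)),
           score = r$values[keep])
  })
  df <- bind_rows(rows)
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Categorical state tracks (ChromHMM-style segmentations)
#'
#' A `state_track` assigns exactly one label from a closed alphabet to each
#' fixed-width bin (default 200 bp, the resolution ChromHMM reports). Bins
#' not covered by any input record carry `fill`, conventionally the
#' quiescent state.
#'
#' @param labels named list (per chromosome) of integer vectors indexing
#'   `alphabet`.
#' @param bin_bp bin width in bp.
#' @param alphabet character vector of state names.
#' @param genome a `genome_layout`.
#' @return a `state_track`.
#' @export
state_track <- function(labels, bin_bp, alphabet, genome) {
  stopifnot(bin_bp > 0, length(alphabet) >= 1)
  for (ch in names(labels)) {
    want <- ceiling(chrom_length(genome, ch) / bin_bp)
    if (length(labels[[ch]]) != want) {
      abort(sprintf("chrom %s: expected %d bins, got %d", ch, want,
                    length(labels[[ch]])))
    }
    if (anyNA(labels[[ch]]) ||
        any(labels[[ch]] < 1L | labels[[ch]] > length(alphabet))) {
      abort("state label outside alphabet")
    }
  }
  structure(list(labels = labels, bin_bp = bin_bp, alphabet = alphabet,
                 genome = genome),
            class = "state_track")
}

#' The 15-state ChromHMM core alphabet
#'
#' State mnemonics of the Roadmap 15-state chromatin model (active TSS
#' through quiescent). The enhancer subset used by default downstream is
#' `c("EnhG", "Enh")`.
#'
#' @return character vector of 15 state names.
#' @export
chromhmm15_states <- function() {
  c("TssA", "TssAFlnk", "TxFlnk", "Tx", "TxWk", "EnhG", "Enh", "ZNF.Rpts",
    "Het", "TssBiv", "BivFlnk", "EnhBiv", "ReprPC", "ReprPCWk", "Quies")
}

#' Read a BED state segmentation into a state track
#'
#' Column 4 carries the state label. Segment boundaries are snapped to the
#' bin grid (a bin takes the label of the record covering its start); bins
#' uncovered by any record take `fill`.
#'
#' @param path file path.
#' @param genome a `genome_layout`.
#' @param bin_bp bin width (default 200).
#' @param alphabet closed state alphabet (default the 15-state ChromHMM
#'   mnemonics).
#' @param fill label for uncovered bins (default the last alphabet entry).
#' @return a `state_track`.
#' @export
read_states <- function(path, genome, bin_bp = 200,
                        alphabet = chromhmm15_states(),
                        fill = alphabet[length(alphabet)]) {
  df <- read_bed(path, genome = genome, extra_names = "state",
                 normalize = FALSE)
  unknown <- setdiff(unique(df$state), alphabet)
  if (length(unknown) > 0L) {
    abort(paste0("state label outside alphabet: ", unknown[1]))
  }
  fill_idx <- match(fill, alphabet)
  labels <- lapply(setNames(nm = genome$chrom$chrom), function(ch) {
    rep(fill_idx, ceiling(chrom_length(genome, ch) / bin_bp))
  })
  for (i in seq_len(nrow(df))) {
    ch <- df$chrom[i]
    b0 <- floor(df$start[i] / bin_bp) + 1L
    b1 <- ceiling(df$end[i] / bin_bp)
    b1 <- min(b1, length(labels[[ch]]))
    labels[[ch]][b0:b1] <- match(df$state[i], alphabet)
  }
  state_track(labels, bin_bp, alphabet, genome)
}

#' Bins in a chosen state subset, as intervals
#'
#' @param track a `state_track`.
#' @param states character vector of state names (subset of the alphabet).
#' @return normalized interval tibble of the bp spans of matching bins.
#' @export
states_to_intervals <- function(track, states) {
  bad <- setdiff(states, track$alphabet)
  if (length(bad) > 0L) abort(paste0("state not in alphabet: ", bad[1]))
  want <- match(states, track$alphabet)
  rows <- purrr::imap(track$labels, function(v, ch) {
    hit <- v %in% want
    if (!any(hit)) return(NULL)
    r <- rle(hit)
    end_bin <- cumsum(r$lengths)
    start_bin <- end_bin - r$lengths
    keep <- r$values
    tibble(chrom = ch,
           start = start_bin[keep] * track$bin_bp,
           end = pmin(end_bin[keep] * track$bin_bp,
                      chrom_length(track$genome, ch)))
  })
  res <- bind_rows(rows)
  if (nrow(res) == 0L) return(empty_intervals())
  interval_merge(res)
}
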