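#' Default emulated-caller specification
#'
#' Four independent callers with configurable sensitivity, Gaussian
#' boundary jitter and a Poisson false-call rate per sample, emulating the
#' behaviour of a multi-algorithm CNV calling setup without running any
#' real caller.
#'
#' @param n_callers number of callers (default 4).
#' @param sensitivity per-caller probability of detecting a true CNV.
#' @param jitter_sd boundary jitter standard deviation (bp).
#' @param fp_rate expected false calls per sample per caller.
#' @param fp_mean_bp mean length of false calls.
#' @param fp_cn_probs named probabilities of the copy-number class of
#'   false calls.
#' @return caller-spec tibble.
#' @export
default_caller_spec <- function(n_callers = 4, sensitivity = 0.95,
                                jitter_sd = 2000, fp_rate = 0.5,
                                fp_mean_bp = 20000,
                                fp_cn_probs = c("0" = 0.05, "1" = 0.55,
                                                "3" = 0.3, "4" = 0.1)) {
  tibble(caller = paste0("caller", seq_len(n_callers)),
         sensitivity = rep_len(sensitivity, n_callers),
         jitter_sd = rep_len(jitter_sd, n_callers),
         fp_rate = rep_len(fp_rate, n_callers),
         fp_mean_bp = rep_len(fp_mean_bp, n_callers)) %>%
    structure(fp_cn_probs = fp_cn_probs)
}

#' Emulate multi-caller CNV call sets from true CNVs
#'
#' Each caller independently detects each true CNV with its sensitivity,
#' jitters both boundaries with Gaussian bp noise (clipped so length stays
#' positive), preserves the copy-number class of true detections, and
#' emits Poisson false calls placed uniformly on the mappable genome with
#' exponential lengths.
#'
#' @param truth tibble of true CNVs: `sample`, `chrom`, `start`, `end`,
#'   `cn`, `probes`.
#' @param callers caller spec (see [default_caller_spec()]).
#' @param mappable a `mappable_genome` (for false-call placement; can be
#'   omitted when all `fp_rate` are 0).
#' @param probe_spacing_bp probe density used to assign probe counts to
#'   false calls.
#' @param seed optional integer seed.
#' @return caller-call tibble: `sample`, `caller`, `chrom`, `start`,
#'   `end`, `cn`, `probes`, `true_call` (logical).
#' @export
sim_caller_calls <- function(truth, callers = default_caller_spec(),
                             mappable = NULL, probe_spacing_bp = 5000,
                             seed = NULL) {
  truth <- as_tibble(truth)
  callers <- as_tibble(callers)
  stopifnot(all(callers$sensitivity >= 0 & callers$sensitivity <= 1),
            all(callers$fp_rate >= 0), all(callers$jitter_sd >= 0))
  if (!is.null(seed)) withr::local_seed(seed)
  fp_cn <- attr(callers, "fp_cn_probs", exact = TRUE)
  if (is.null(fp_cn)) fp_cn <- c("0" = 0.05, "1" = 0.55, "3" = 0.3, "4" = 0.1)
  out <- list()
  samples <- unique(truth$sample)
  for (ci in seq_len(nrow(callers))) {
    cl <- callers[ci, ]
    det <- truth[runif(nrow(truth)) < cl$sensitivity, , drop = FALSE]
    if (nrow(det) > 0L) {
      if (cl$jitter_sd > 0) {
        det$start <- round(det$start + rnorm(nrow(det), 0, cl$jitter_sd))
        det$end <- round(det$end + rnorm(nrow(det), 0, cl$jitter_sd))
        det$start <- pmax(det$start, 0)
        flip <- det$end <= det$start
        det$end[flip] <- det$start[flip] + 1
      }
      out[[length(out) + 1L]] <- tibble(
        sample = det$sample, caller = cl$caller, chrom = det$chrom,
        start = det$start, end = det$end, cn = det$cn,
        probes = det$probes, true_call = TRUE)
    }
    if (cl$fp_rate > 0) {
      if (is.null(mappable)) abort("false-call emission needs a mappable genome")
      n_fp <- rpois(length(samples), cl$fp_rate)
      tot <- sum(n_fp)
      if (tot > 0L) {
        lens <- pmax(1000, round(stats::rexp(tot, 1 / cl$fp_mean_bp)))
        pl <- place_random(lens, mappable, n = 1)
        out[[length(out) + 1L]] <- tibble(
          sample = rep(samples, n_fp), caller = cl$caller,
          chrom = as.character(pl$chrom[, 1]),
          start = as.numeric(pl$start[, 1]),
          end = as.numeric(pl$start[, 1]) + lens,
          cn = as.integer(sample(names(fp_cn), tot, replace = TRUE,
                                 prob = fp_cn)),
          probes = pmax(1, round(lens / probe_spacing_bp)),
          true_call = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble(sample = character(), caller = character(),
                  chrom = character(), start = numeric(), end = numeric(),
                  cn = integer(), probes = numeric(), true_call = logical()))
  }
  bind_rows(out) %>% arrange(.data$sample, .data$caller, .data$chrom,
                             .data$start)
}

#' Simulate annotation tracks with controlled genome coverage
#'
#' Places non-overlapping peaks with exponential lengths (mean
#' `mean_peak_bp`, snapped to the bin grid) uniformly over the genome
#' until the target coverage fraction is reached. Returns the peak
#' intervals plus matched intensity and chromatin-state tracks: peak bins
#' carry `peak_score` / the `peak_state`, all other bins
#' `background_score` / `background_state`.
#'
#' @param genome a `genome_layout`.
#' @param coverage_fraction target fraction of the genome covered by
#'   peaks, in (0, 1).
#' @param mean_peak_bp mean peak length.
#' @param peak_score,background_score intensity values (defaults 30 and
#'   0).
#' @param bin_bp intensity bin width (default 25); the state track uses
#'   `state_bin_bp` (default 200).
#' @param peak_state,background_state state labels (defaults "Enh",
#'   "Quies").
#' @param state_bin_bp state-track bin width (default 200).
#' @param make_tracks build the dense intensity and state tracks (default
#'   TRUE; set FALSE to generate only the peak intervals, e.g. in large
#'   placement studies).
#' @param seed optional integer seed.
#' @return list: `peaks` (interval tibble), `track` (`intensity_track`),
#'   `states` (`state_track`), `coverage` (realized fraction).
#' @export
sim_tracks <- function(genome, coverage_fraction, mean_peak_bp = 5000,
                       peak_score = 30, background_score = 0, bin_bp = 25,
                       state_bin_bp = 200, peak_state = "Enh",
                       background_state = "Quies", make_tracks = TRUE,
                       seed = NULL) {
  stopifnot(coverage_fraction > 0, coverage_fraction < 1,
            mean_peak_bp > 0, peak_score >= 0, background_score >= 0)
  if (!is.null(seed)) withr::local_seed(seed)
  total_bp <- sum(genome$chrom$length_bp)
  if (mean_peak_bp >= total_bp) abort("mean peak length exceeds the genome")
  target <- coverage_fraction * total_bp
  chroms <- genome$chrom$chrom
  lens <- genome$chrom$length_bp
  p_start <- lapply(setNames(nm = chroms), function(ch) numeric(0))
  p_end <- p_start
  covered <- 0
  rejects <- 0L
  while (covered < target) {
    L <- max(bin_bp, round(stats::rexp(1, 1 / mean_peak_bp) / bin_bp) * bin_bp)
    ci <- sample.int(length(chroms), 1L, prob = lens)
    if (L >= lens[ci]) { rejects <- rejects + 1L; next }
    s <- floor(runif(1, 0, lens[ci] - L) / bin_bp) * bin_bp
    ch <- chroms[ci]
    if (any(p_start[[ch]] < s + L & p_end[[ch]] > s)) {
      rejects <- rejects + 1L
      if (rejects > 1e5) abort("cannot reach target coverage; too many rejections")
      next
    }
    p_start[[ch]] <- c(p_start[[ch]], s)
    p_end[[ch]] <- c(p_end[[ch]], s + L)
    covered <- covered + L
  }
  peaks <- purrr::imap(p_start, function(st, ch) {
    if (length(st) == 0L) return(NULL)
    tibble(chrom = ch, start = st, end = p_end[[ch]])
  }) %>% bind_rows() %>% interval_merge()

  if (!make_tracks) {
    return(list(peaks = peaks, track = NULL, states = NULL,
                coverage = interval_total(peaks) / total_bp))
  }
  fill_track <- function(bw, peak_val, bg_val) {
    vals <- lapply(setNames(nm = chroms), function(ch) {
      nb <- ceiling(chrom_length(genome, ch) / bw)
      v <- rep(bg_val, nb)
      pk <- peaks[peaks$chrom == ch, ]
      for (i in seq_len(nrow(pk))) {
        b0 <- floor(pk$start[i] / bw) + 1L
        b1 <- min(ceiling(pk$end[i] / bw), nb)
        v[b0:b1] <- peak_val
      }
      v
    })
    vals
  }
  track <- intensity_track(fill_track(bin_bp, peak_score, background_score),
                           bin_bp, genome)
  alphabet <- chromhmm15_states()
  states <- state_track(fill_track(state_bin_bp, match(peak_state, alphabet),
                                   match(background_state, alphabet)),
                        state_bin_bp, alphabet, genome)
  list(peaks = peaks, track = track, states = states,
       coverage = interval_total(peaks) / total_bp)
}

#' Simulate case/control CNV sets with a controllable peak-overlap bias
#'
#' Unbiased CNVs follow exactly the null placement contract of
#' [place_random()]; a fraction `overlap_bias` of the affected set is
#' instead placed uniformly among peak-overlapping placements (by
#' rejection from the same null sampler), planting a true enrichment
#' signal of known strength for power and calibration studies.
#'
#' @param n_affected,n_unaffected set sizes.
#' @param lengths CNV lengths: a numeric vector (recycled/sampled to size)
#'   or a function `n -> lengths`.
#' @param overlap_bias fraction of affected CNVs forced to intersect a
#'   peak, in \[0, 1\].
#' @param peaks peak interval tibble.
#' @param mappable a `mappable_genome`.
#' @param seed optional integer seed.
#' @return list of two interval tibbles, `affected` and `unaffected`.
#' @export
sim_case_control_cnvs <- function(n_affected, n_unaffected, lengths,
                                  overlap_bias, peaks, mappable,
                                  seed = NULL) {
  stopifnot(overlap_bias >= 0, overlap_bias <= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  draw_lengths <- function(n) {
    if (is.function(lengths)) return(lengths(n))
    if (length(lengths) == n) return(lengths)
    sample(lengths, n, replace = TRUE)
  }
  pk <- interval_merge(peaks)
  off <- chrom_offsets(unique(c(pk$chrom, mappable$intervals$chrom)))
  pl <- linearize(pk, off)
  o <- order(pl$start)
  ps <- pl$start[o]; pe <- pl$end[o]

  place_set <- function(n, biased) {
    if (n == 0L) return(empty_intervals())
    lens <- draw_lengths(n)
    res <- tibble(chrom = character(n), start = numeric(n))
    todo <- seq_len(n)
    tries <- 0L
    while (length(todo) > 0L) {
      p <- place_random(lens[todo], mappable, n = 1)
      ch <- as.character(p$chrom[, 1]); st <- as.numeric(p$start[, 1])
      ok <- if (biased) {
        hits_any(off[ch] + st, lens[todo], ps, pe)
      } else rep(TRUE, length(todo))
      res$chrom[todo[ok]] <- ch[ok]
      res$start[todo[ok]] <- st[ok]
      todo <- todo[!ok]
      tries <- tries + 1L
      if (tries > 1e4) abort("no feasible peak-overlapping placement found")
    }
    tibble(chrom = res$chrom, start = res$start, end = res$start + lens)
  }
  n_biased <- round(overlap_bias * n_affected)
  affected <- bind_rows(place_set(n_biased, biased = TRUE),
                        place_set(n_affected - n_biased, biased = FALSE))
  unaffected <- place_set(n_unaffected, biased = FALSE)
  list(affected = affected, unaffected = unaffected)
}
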