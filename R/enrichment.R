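#' Build the mappable genome from marker density
#'
#' The mappable genome is where the array can see CNVs: per chromosome,
#' the span from the first to the last marker, minus inter-marker gaps
#' larger than `max_gap_bp` (low probe density) and minus any exclusion
#' regions (centromeres etc.). Only autosomes are used. Chromosomes with
#' fewer than two markers are dropped with a warning.
#'
#' @param markers tibble with `chrom`, `bp`.
#' @param genome a `genome_layout` (supplies the autosome set and
#'   exclusions).
#' @param max_gap_bp largest tolerated inter-marker distance (default
#'   100 kb).
#' @return object of class `mappable_genome`: `intervals` (normalized
#'   interval tibble), `total_bp`, and provenance fields.
#' @export
build_mappable <- function(markers, genome, max_gap_bp = 1e5) {
  markers <- as_tibble(markers)
  stopifnot(all(c("chrom", "bp") %in% names(markers)))
  markers <- filter(markers, .data$chrom %in% autosome_names(genome))
  out <- list()
  for (ch in unique(markers$chrom)) {
    bp <- sort(markers$bp[markers$chrom == ch])
    if (length(bp) < 2L) {
      warn(sprintf("chromosome %s has < 2 markers; excluded from mappable genome", ch))
      next
    }
    gap_after <- diff(bp) > max_gap_bp
    run_id <- cumsum(c(0L, gap_after))
    seg <- tibble(bp = bp, run = run_id) %>%
      group_by(.data$run) %>%
      summarise(start = min(.data$bp), end = max(.data$bp), .groups = "drop") %>%
      filter(.data$start < .data$end)
    if (nrow(seg) > 0L) {
      out[[length(out) + 1L]] <- tibble(chrom = ch, start = seg$start,
                                        end = seg$end)
    }
  }
  iv <- if (length(out) == 0L) empty_intervals() else
    interval_merge(bind_rows(out))
  iv <- interval_subtract(iv, genome$exclusions)
  structure(list(intervals = iv, total_bp = interval_total(iv),
                 max_gap_bp = max_gap_bp,
                 n_markers = nrow(markers)),
            class = "mappable_genome")
}

#' @export
print.mappable_genome <- function(x, ...) {
  cat(sprintf("<mappable_genome> %.3g bp in %d interval(s) (max gap %g bp)\n",
              x$total_bp, nrow(x$intervals), x$max_gap_bp))
  invisible(x)
}

#' Call peaks from an intensity track with a fixed threshold
#'
#' Maximal runs of bins scoring at or above `threshold` become peak
#' intervals; adjacent qualifying bins merge.
#'
#' @param track an `intensity_track`.
#' @param threshold minimum score, inclusive (default 20).
#' @return normalized interval tibble of peaks.
#' @export
call_peaks <- function(track, threshold = 20) {
  stopifnot(threshold >= 0)
  rows <- purrr::imap(track$scores, function(v, ch) {
    hit <- v >= threshold
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

# Linearize a genome: per-chromosome offsets so interval work is plain
# numeric, plus peak boundary arrays for O(log n) hit tests.
linearize <- function(intervals, offsets) {
  tibble(start = unname(offsets[intervals$chrom]) + intervals$start,
         end = unname(offsets[intervals$chrom]) + intervals$end)
}

chrom_offsets <- function(chroms) {
  # generous, collision-free spacing: each chromosome gets its own 1e10 slab
  setNames((seq_along(chroms) - 1) * 1e10, chroms)
}

# do half-open intervals [s, s+len) hit any merged peak? vectorized
hits_any <- function(s, len, pk_start, pk_end) {
  if (length(pk_start) == 0L) return(rep(FALSE, length(s)))
  i <- findInterval(s, pk_start)
  hit <- i >= 1L & pk_end[pmax(i, 1L)] > s
  j <- i + 1L
  unname(hit |
           (j <= length(pk_start) & pk_start[pmin(j, length(pk_start))] < s + len))
}

#' Which CNVs coincide with annotation peaks
#'
#' A CNV coincides with a track collection when it intersects at least one
#' peak by one or more bp (half-open coordinates: book-ended intervals do
#' not touch). A collection is the union of the peak sets of its profiles.
#'
#' @param cnvs interval tibble of CNVs.
#' @param peaks a peak interval tibble, or a named list of them (one per
#'   collection).
#' @return tibble with one row per CNV: the CNV columns plus one logical
#'   column per collection (named after the list, or `coincides`).
#' @export
count_coincidences <- function(cnvs, peaks) {
  cnvs <- as_interval_tbl(cnvs)
  if (is.data.frame(peaks)) peaks <- list(coincides = peaks)
  chroms <- unique(c(cnvs$chrom, unlist(lapply(peaks, function(p) p$chrom))))
  off <- chrom_offsets(chroms)
  q <- linearize(cnvs, off)
  for (nm in names(peaks)) {
    pk <- interval_merge(peaks[[nm]])
    pl <- linearize(pk, off)
    o <- order(pl$start)
    cnvs[[nm]] <- hits_any(q$start, q$end - q$start,
                           pl$start[o], pl$end[o])
  }
  cnvs
}

#' Random placement of CNV-length intervals on the mappable genome
#'
#' The null placement of the randomization test: each interval keeps its
#' length and is placed uniformly over all positions at which it fits
#' wholly inside one mappable interval (a mappable interval is chosen with
#' probability proportional to its number of valid starts for that length,
#' then a valid start uniformly).
#'
#' @param lengths interval lengths (bp).
#' @param mappable a `mappable_genome`.
#' @param n number of replicate placements per length.
#' @param seed optional integer seed.
#' @return list: `chrom`, `start` (length(lengths) x n matrices of placed
#'   positions).
#' @export
place_random <- function(lengths, mappable, n = 1, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  iv <- mappable$intervals
  if (nrow(iv) == 0L) abort("mappable genome is empty")
  ilen <- iv$end - iv$start
  chrom <- matrix(NA_character_, length(lengths), n)
  start <- matrix(NA_real_, length(lengths), n)
  for (li in seq_along(lengths)) {
    L <- lengths[li]
    w <- pmax(ilen - L + 1, 0)
    if (sum(w) == 0) {
      abort(sprintf("CNV of length %g fits in no mappable interval", L))
    }
    idx <- sample.int(nrow(iv), n, replace = TRUE, prob = w)
    u <- floor(runif(n) * w[idx])
    chrom[li, ] <- iv$chrom[idx]
    start[li, ] <- iv$start[idx] + u
  }
  list(chrom = chrom, start = start)
}

#' Monte-Carlo joint enrichment/depletion test of CNV-peak coincidence
#'
#' Randomizes the locations of the affected and unaffected CNV sets
#' (lengths preserved, placements uniform on the mappable genome,
#' independent between groups and replicates) and counts per-replicate
#' coincidences with the peak set. Marginal p-values use the add-one
#' estimator: enrichment p = (1 + #\{A_i >= A_obs\})/(n+1) for affected,
#' depletion p = (1 + #\{U_i <= U_obs\})/(n+1) for unaffected, and the
#' joint p counts replicates at least as extreme in both directions
#' simultaneously.
#'
#' @param affected,unaffected interval tibbles of observed CNVs (the
#'   unaffected set may be empty).
#' @param peaks peak interval tibble (union over profiles).
#' @param mappable a `mappable_genome`.
#' @param n_replicates number of Monte-Carlo replicates (default 10,000).
#' @param seed optional integer seed (recorded in the result).
#' @return object of class `mc_overlap`: observed and expected counts,
#'   marginal and joint p-values, replicate counts, seed.
#' @export
mc_overlap_test <- function(affected, unaffected, peaks, mappable,
                            n_replicates = 10000, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  affected <- as_interval_tbl(affected)
  unaffected <- if (is.null(unaffected) || nrow(as_tibble(unaffected)) == 0L)
    empty_intervals() else as_interval_tbl(unaffected)
  pk <- interval_merge(peaks)
  chroms <- unique(c(affected$chrom, unaffected$chrom, pk$chrom,
                     mappable$intervals$chrom))
  off <- chrom_offsets(chroms)
  pl <- linearize(pk, off)
  o <- order(pl$start)
  ps <- pl$start[o]; pe <- pl$end[o]

  obs_group <- function(cnvs) {
    if (nrow(cnvs) == 0L) return(0L)
    q <- linearize(cnvs, off)
    sum(hits_any(q$start, q$end - q$start, ps, pe))
  }
  count_replicates <- function(cnvs) {
    if (nrow(cnvs) == 0L) return(rep(0L, n_replicates))
    lens <- cnvs$end - cnvs$start
    pl <- place_random(lens, mappable, n = n_replicates)
    gs <- off[pl$chrom] + pl$start
    hit <- hits_any(as.numeric(gs), rep(lens, times = n_replicates), ps, pe)
    colSums(matrix(hit, nrow = length(lens)))
  }

  a_obs <- obs_group(affected)
  u_obs <- obs_group(unaffected)
  a_rep <- count_replicates(affected)
  u_rep <- count_replicates(unaffected)
  n <- n_replicates
  structure(list(
    n_replicates = n,
    affected_observed = a_obs, unaffected_observed = u_obs,
    affected_expected = mean(a_rep), unaffected_expected = mean(u_rep),
    p_enrichment = (1 + sum(a_rep >= a_obs)) / (n + 1),
    p_depletion = (1 + sum(u_rep <= u_obs)) / (n + 1),
    p_joint = (1 + sum(a_rep >= a_obs & u_rep <= u_obs)) / (n + 1),
    n_affected = nrow(affected), n_unaffected = nrow(unaffected),
    replicate_counts = tibble(affected = a_rep, unaffected = u_rep),
    seed = seed),
    class = "mc_overlap")
}

#' @export
print.mc_overlap <- function(x, ...) {
  cat(sprintf("Monte-Carlo coincidence test (%d replicates)\n", x$n_replicates))
  cat(sprintf("  affected:   %d/%d observed, %.2f expected (enrichment p = %.4g)\n",
              x$affected_observed, x$n_affected, x$affected_expected,
              x$p_enrichment))
  cat(sprintf("  unaffected: %d/%d observed, %.2f expected (depletion p = %.4g)\n",
              x$unaffected_observed, x$n_unaffected, x$unaffected_expected,
              x$p_depletion))
  cat(sprintf("  joint p = %.4g\n", x$p_joint))
  invisible(x)
}

#' @export
tidy.mc_overlap <- function(x, ...) {
  tibble(group = c("affected", "unaffected"),
         n_cnvs = c(x$n_affected, x$n_unaffected),
         observed = c(x$affected_observed, x$unaffected_observed),
         expected = c(x$affected_expected, x$unaffected_expected),
         p_value = c(x$p_enrichment, x$p_depletion),
         side = c("enrichment", "depletion"))
}

#' @export
glance.mc_overlap <- function(x, ...) {
  tibble(p_joint = x$p_joint, p_enrichment = x$p_enrichment,
         p_depletion = x$p_depletion, n_replicates = x$n_replicates)
}

#' ChromHMM-state coincidence testing per epigenome, with tissue unions
#'
#' Runs the Monte-Carlo coincidence test against the bins of a chosen
#' chromatin-state subset, independently for each epigenome's state track,
#' and optionally for unions of the selected-state bins across all
#' epigenomes of a tissue. CNVs intersecting a coding exon can be excluded
#' first (noncoding-only analysis). No multiple-testing correction is
#' applied: tissues overlap and are highly correlated, so all marginal and
#' joint p-values are reported as-is.
#'
#' @param affected,unaffected observed CNV interval tibbles.
#' @param tracks named list of `state_track` objects (one per epigenome).
#' @param mappable a `mappable_genome`.
#' @param states state subset tested (default the enhancer states
#'   `c("EnhG", "Enh")`).
#' @param genes gene-model tibble (see [read_refflat()]); required when
#'   `noncoding_only = TRUE`.
#' @param noncoding_only drop CNVs that intersect any coding exon of a
#'   coding gene before testing.
#' @param tissues optional named list mapping tissue name -> character
#'   vector of epigenome names; adds one union test per tissue.
#' @param n_replicates,seed Monte-Carlo control.
#' @return tibble with one row per epigenome (and per tissue union):
#'   `profile`, `kind`, observed/expected counts and the three p-values.
#' @export
chromhmm_overlap <- function(affected, unaffected, tracks, mappable,
                             states = c("EnhG", "Enh"), genes = NULL,
                             noncoding_only = FALSE, tissues = NULL,
                             n_replicates = 10000, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  bins <- unique(vapply(tracks, function(t) t$bin_bp, numeric(1)))
  if (length(bins) > 1L) abort("state tracks use different bin widths")
  if (noncoding_only) {
    if (is.null(genes)) abort("noncoding_only requires gene models")
    keep_nc <- function(cnvs) {
      if (nrow(as_tibble(cnvs)) == 0L) return(empty_intervals())
      ann <- annotate_exonic(cnvs, genes)
      ann[!ann$exonic, c("chrom", "start", "end"), drop = FALSE]
    }
    affected <- keep_nc(affected)
    unaffected <- keep_nc(unaffected)
  }
  sets <- lapply(tracks, states_to_intervals, states = states)
  if (!is.null(tissues)) {
    for (tn in names(tissues)) {
      sets[[paste0("tissue:", tn)]] <-
        interval_merge(bind_rows(sets[tissues[[tn]]]))
    }
  }
  res <- purrr::imap(sets, function(pk, nm) {
    fit <- mc_overlap_test(affected, unaffected, pk, mappable,
                           n_replicates = n_replicates)
    tibble(profile = sub("^tissue:", "", nm),
           kind = ifelse(grepl("^tissue:", nm), "tissue_union", "epigenome"),
           affected_observed = fit$affected_observed,
           affected_expected = fit$affected_expected,
           unaffected_observed = fit$unaffected_observed,
           unaffected_expected = fit$unaffected_expected,
           p_enrichment = fit$p_enrichment,
           p_depletion = fit$p_depletion,
           p_joint = fit$p_joint)
  })
  bind_rows(res)
}
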