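#' Call runs of homozygosity with a sliding SNP window
#'
#' Slides a window of `window_snps` markers (step 1) along each sample and
#' chromosome. A window qualifies when the homozygous fraction among its
#' non-missing calls is at least `min_hom_frac` (windows with no
#' non-missing call never qualify). A marker supports a run when at least
#' one qualifying window covers it; maximal stretches of run-supporting
#' markers become runs, whose boundaries are the outermost supporting
#' markers. Runs whose genetic length (cM of last minus first marker)
#' reaches `min_cM` are retained. Chromosomes with fewer markers than the
#' window are skipped with a warning.
#'
#' @param panel a `genotype_panel` whose markers carry `cM`.
#' @param window_snps window size in markers (default 100).
#' @param min_hom_frac minimum homozygous fraction per window, inclusive
#'   (default 0.98).
#' @param min_cM minimum run genetic length in cM, inclusive (default 5).
#' @param autosomes optional chromosome subset to scan.
#' @return tibble of runs: `id`, `chrom`, `start_bp`, `end_bp`, `first`,
#'   `last` (marker indices within chromosome), `n_markers`, `n_het`,
#'   `n_missing`, `length_cM`.
#' @export
call_roh <- function(panel, window_snps = 100, min_hom_frac = 0.98,
                     min_cM = 5, autosomes = NULL) {
  stopifnot(inherits(panel, "genotype_panel"), window_snps >= 1)
  mk <- panel$markers
  if (!"cM" %in% names(mk)) abort("panel markers need a cM column")
  chroms <- unique(mk$chrom)
  if (!is.null(autosomes)) chroms <- intersect(chroms, autosomes)
  out <- list()
  for (ch in chroms) {
    midx <- which(mk$chrom == ch)
    midx <- midx[order(mk$bp[midx])]
    if (length(midx) < window_snps) {
      warn(sprintf("chromosome %s has %d markers (< window of %d); skipped",
                   ch, length(midx), window_snps))
      next
    }
    cM <- mk$cM[midx]
    bp <- mk$bp[midx]
    for (si in seq_len(nrow(panel$samples))) {
      g <- panel$genotypes[si, midx]
      runs <- roh_runs_one(g, window_snps, min_hom_frac)
      if (nrow(runs) == 0L) next
      runs$length_cM <- cM[runs$last] - cM[runs$first]
      runs <- runs[runs$length_cM >= min_cM, , drop = FALSE]
      if (nrow(runs) == 0L) next
      out[[length(out) + 1L]] <- tibble(
        id = panel$samples$id[si], chrom = ch,
        start_bp = bp[runs$first], end_bp = bp[runs$last] + 1,
        first = runs$first, last = runs$last,
        n_markers = runs$last - runs$first + 1L,
        n_het = runs$n_het, n_missing = runs$n_missing,
        length_cM = runs$length_cM)
    }
  }
  if (length(out) == 0L) {
    return(tibble(id = character(), chrom = character(),
                  start_bp = numeric(), end_bp = numeric(),
                  first = integer(), last = integer(),
                  n_markers = integer(), n_het = integer(),
                  n_missing = integer(), length_cM = numeric()))
  }
  bind_rows(out)
}

# Run detection for one sample on one chromosome; cumulative-sum window
# qualification, then marker-level support as a window-length dilation of
# qualifying window starts.
roh_runs_one <- function(g, W, min_hom_frac) {
  n <- length(g)
  nonmiss <- !is.na(g)
  hom <- nonmiss & g != 1L
  het <- nonmiss & g == 1L
  cs_hom <- cumsum(c(0L, hom))
  cs_nm <- cumsum(c(0L, nonmiss))
  nS <- n - W + 1L
  s <- seq_len(nS)
  w_hom <- cs_hom[s + W] - cs_hom[s]
  w_nm <- cs_nm[s + W] - cs_nm[s]
  qual <- w_nm > 0L & w_hom >= min_hom_frac * w_nm
  if (!any(qual)) {
    return(tibble(first = integer(), last = integer(),
                  n_het = integer(), n_missing = integer()))
  }
  cq <- cumsum(c(0L, qual))
  i <- seq_len(n)
  lo <- pmax(i - W + 1L, 1L)
  hi <- pmin(i, nS)
  supported <- hi >= lo & (cq[hi + 1L] - cq[lo]) > 0L
  r <- rle(supported)
  cum <- cumsum(r$lengths)
  first <- c(1L, cum[-length(cum)] + 1L)[r$values]
  last <- cum[r$values]
  cs_het <- cumsum(c(0L, het))
  tibble(first = first, last = last,
         n_het = as.integer(cs_het[last + 1L] - cs_het[first]),
         n_missing = as.integer((last - first + 1L) -
                                  (cs_nm[last + 1L] - cs_nm[first])))
}

#' Per-sample autozygosity as a percentage of the genetic map
#'
#' Sums retained run lengths (already minimum-length-filtered by
#' [call_roh()]) and divides by the total autosomal genetic map length.
#'
#' @param runs run tibble from [call_roh()].
#' @param map a `genetic_map`.
#' @param genome optional `genome_layout` restricting the denominator to
#'   autosomes.
#' @param ids sample ids to report (default: the ids present in `runs`);
#'   ids without runs report 0.
#' @return tibble: `id`, `autozygosity_pct`.
#' @export
total_autozygosity <- function(runs, map, genome = NULL, ids = NULL) {
  denom <- total_map_cM(map, genome)
  if (is.null(ids)) ids <- unique(runs$id)
  runs %>%
    group_by(.data$id) %>%
    summarise(cM = sum(.data$length_cM), .groups = "drop") %>%
    tidyr::complete(id = ids, fill = list(cM = 0)) %>%
    filter(.data$id %in% ids) %>%
    mutate(autozygosity_pct = 100 * .data$cM / denom) %>%
    select("id", "autozygosity_pct")
}

#' Classify families by child homozygosity
#'
#' A family is highly homozygous when at least one child reaches the
#' threshold percentage of the autosomal genetic map in retained runs
#' (inclusive: exactly 2.5% classifies high).
#'
#' @param child_fractions tibble with columns `family`, `id`,
#'   `autozygosity_pct` (children only).
#' @param threshold percent threshold (default 2.5).
#' @return tibble: `family`, `max_child_pct`, `class` ("high"/"low").
#' @export
classify_families <- function(child_fractions, threshold = 2.5) {
  df <- as_tibble(child_fractions)
  stopifnot(all(c("family", "autozygosity_pct") %in% names(df)))
  if (nrow(df) == 0L) abort("no children to classify")
  df %>%
    group_by(.data$family) %>%
    summarise(max_child_pct = max(.data$autozygosity_pct),
              .groups = "drop") %>%
    mutate(class = ifelse(.data$max_child_pct >= threshold, "high", "low"))
}
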