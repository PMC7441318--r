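#' Genotype panels
#'
#' A `genotype_panel` binds a sample table, a marker table carrying the
#' genetic map (per-marker cM), and a samples-by-markers genotype matrix
#' coded 0/1/2 (alternate-allele count; `NA` = missing call).
#'
#' @param genotypes integer matrix, samples in rows (rownames = sample ids),
#'   markers in columns.
#' @param markers tibble with columns `marker`, `chrom`, `bp` and optionally
#'   `cM`, `freq`.
#' @param samples tibble with column `id` and optional `sex`, `family`,
#'   `affected`, `declared_sex`.
#' @return a `genotype_panel`.
#' @export
genotype_panel <- function(genotypes, markers, samples) {
  markers <- as_tibble(markers)
  samples <- as_tibble(samples)
  stopifnot(all(c("marker", "chrom", "bp") %in% names(markers)),
            "id" %in% names(samples),
            nrow(genotypes) == nrow(samples),
            ncol(genotypes) == nrow(markers))
  if (is.null(rownames(genotypes))) rownames(genotypes) <- samples$id
  structure(list(genotypes = genotypes, markers = markers,
                 samples = samples),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d samples x %d markers (%d chromosome(s))\n",
              nrow(x$samples), nrow(x$markers),
              length(unique(x$markers$chrom))))
  invisible(x)
}

#' Evenly spaced marker grid for a genome
#'
#' @param genome a `genome_layout`.
#' @param map a `genetic_map` (adds the per-marker `cM` column).
#' @param spacing_bp distance between adjacent markers.
#' @param maf minor-allele frequency model: a single value, a vector
#'   recycled over markers, or a function `n -> frequencies`. Default draws
#'   uniform on (0.05, 0.5).
#' @param seed optional integer seed (used for frequency draws).
#' @return marker tibble (`marker`, `chrom`, `bp`, `cM`, `freq`).
#' @export
marker_grid <- function(genome, map, spacing_bp = 1e5, maf = NULL,
                        seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  chroms <- genome$chrom$chrom
  mk <- purrr::map(chroms, function(ch) {
    len <- chrom_length(genome, ch)
    bp <- seq(0, len - 1, by = spacing_bp)
    tibble(chrom = ch, bp = bp)
  }) %>% bind_rows()
  n <- nrow(mk)
  freq <- if (is.null(maf)) {
    runif(n, 0.05, 0.5)
  } else if (is.function(maf)) {
    maf(n)
  } else {
    rep_len(maf, n)
  }
  if (any(freq <= 0 | freq >= 1)) abort("allele frequencies must be in (0,1)")
  mk %>%
    mutate(marker = paste0("m", row_number()),
           cM = interpolate_cM(map, .data$chrom, .data$bp),
           freq = freq) %>%
    select("marker", "chrom", "bp", "cM", "freq")
}

#' Simulate genotypes from a founder-ancestry mosaic
#'
#' Founder haplotypes draw an allele per marker from the marker's allele
#' frequency; each individual's genotype is read off its two-haplotype
#' founder mosaic, so true autozygous regions are exactly homozygous before
#' noise. Missingness and genotype-class error are then applied: with
#' probability `error_rate` a homozygous call is observed heterozygous and
#' a heterozygous call is observed as a random homozygote (the dominant
#' hom/het confusion mode of array calling, and the reason heterozygote
#' calls appear inside true autozygous runs at approximately `error_rate`).
#'
#' @param ancestry founder mosaic tibble from [drop_ancestry()] for a single
#'   replicate: columns `id`, `hap`, `chrom`, `start_cM`, `end_cM`,
#'   `founder_hap`.
#' @param markers marker tibble (see [marker_grid()]); every marker must lie
#'   within the mosaic's cM span.
#' @param samples optional sample tibble (default: the ids in `ancestry`).
#' @param missing_rate per-genotype missing probability.
#' @param error_rate per-genotype class-error probability.
#' @param seed optional integer seed.
#' @return a `genotype_panel`; the true (pre-noise) genotypes are kept in
#'   the `truth` attribute for evaluation.
#' @export
sim_genotypes <- function(ancestry, markers, samples = NULL,
                          missing_rate = 0, error_rate = 0, seed = NULL) {
  stopifnot(missing_rate >= 0, missing_rate <= 1,
            error_rate >= 0, error_rate <= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  markers <- as_tibble(markers)
  if (!"cM" %in% names(markers)) abort("markers need a cM column")
  if (!"freq" %in% names(markers)) abort("markers need a freq column")
  ids <- unique(ancestry$id)
  if (is.null(samples)) samples <- tibble(id = ids)

  founders <- sort(unique(ancestry$founder_hap))
  # founder haplotype alleles: founders x markers, 0/1
  alleles <- matrix(rbinom(length(founders) * nrow(markers), 1L,
                           rep(markers$freq, each = length(founders))),
                    nrow = length(founders))

  span <- ancestry %>%
    group_by(.data$chrom) %>%
    summarise(lo = min(.data$start_cM), hi = max(.data$end_cM),
              .groups = "drop")
  for (ch in unique(markers$chrom)) {
    sp <- span[span$chrom == ch, ]
    if (nrow(sp) == 0L) abort(paste0("marker chromosome not in ancestry: ", ch))
    mk <- markers[markers$chrom == ch, ]
    if (any(mk$cM < sp$lo - 1e-9 | mk$cM > sp$hi + 1e-9)) {
      abort("marker outside the simulated map span")
    }
  }

  geno <- matrix(NA_integer_, nrow = length(ids), ncol = nrow(markers),
                 dimnames = list(ids, markers$marker))
  truth <- geno
  for (i in seq_along(ids)) {
    g <- integer(nrow(markers))
    for (h in 1:2) {
      seg <- ancestry[ancestry$id == ids[i] & ancestry$hap == h, ]
      for (ch in unique(seg$chrom)) {
        sch <- seg[seg$chrom == ch, ]
        ord <- order(sch$start_cM)
        midx <- which(markers$chrom == ch)
        j <- findInterval(markers$cM[midx], sch$start_cM[ord],
                          rightmost.closed = FALSE)
        j[j == 0L] <- 1L
        lab <- sch$founder_hap[ord][j]
        g[midx] <- g[midx] + alleles[cbind(match(lab, founders), midx)]
      }
    }
    truth[i, ] <- g
  }
  geno <- truth
  n <- length(geno)
  err <- runif(n) < error_rate
  if (any(err)) {
    hom <- geno %in% c(0L, 2L) & err
    het <- geno == 1L & err
    geno[hom] <- 1L
    geno[het] <- sample(c(0L, 2L), sum(het), replace = TRUE)
  }
  geno[runif(n) < missing_rate] <- NA_integer_
  genotype_panel(geno, markers, samples) %>%
    structure(truth = truth)
}
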