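#' Genome layout
#'
#' A `genome_layout` bundles chromosome names, physical lengths and excluded
#' regions (centromeres, assembly gaps, ...). All coordinates in the package
#' are 0-based half-open; human-readable report writers convert to 1-based
#' starts.
#'
#' @param chrom_lengths data frame with columns `chrom` and `length_bp`, or a
#'   named numeric vector of chromosome lengths.
#' @param exclusions optional interval data frame (`chrom`, `start`, `end`)
#'   of regions excluded from placement and mappable-genome construction.
#' @param autosomes character vector naming the autosomes; defaults to every
#'   chromosome whose name is not X/Y (with or without a "chr" prefix).
#'
#' @return an object of class `genome_layout` with elements `chrom`
#'   (tibble: `chrom`, `length_bp`, `is_autosome`) and `exclusions`
#'   (normalized interval tibble).
#' @export
genome_layout <- function(chrom_lengths, exclusions = NULL, autosomes = NULL) {
  if (is.numeric(chrom_lengths) && !is.null(names(chrom_lengths))) {
    chrom_lengths <- tibble(chrom = names(chrom_lengths),
                            length_bp = unname(chrom_lengths))
  }
  chrom_lengths <- as_tibble(chrom_lengths)
  stopifnot(all(c("chrom", "length_bp") %in% names(chrom_lengths)))
  if (anyDuplicated(chrom_lengths$chrom) > 0L) {
    abort("chromosome names must be unique")
  }
  if (any(chrom_lengths$length_bp <= 0)) {
    abort("chromosome lengths must be positive")
  }
  if (is.null(autosomes)) {
    sex_chr <- c("X", "Y", "chrX", "chrY")
    autosomes <- setdiff(chrom_lengths$chrom, sex_chr)
  }
  chrom <- chrom_lengths %>%
    mutate(is_autosome = .data$chrom %in% autosomes)
  if (is.null(exclusions)) {
    exclusions <- empty_intervals()
  } else {
    exclusions <- interval_merge(as_interval_tbl(exclusions))
    bad <- !exclusions$chrom %in% chrom$chrom
    if (any(bad)) abort("exclusion on unknown chromosome")
    len <- setNames(chrom$length_bp, chrom$chrom)
    if (any(exclusions$end > len[exclusions$chrom])) {
      abort("exclusion interval outside its chromosome")
    }
  }
  structure(list(chrom = chrom, exclusions = exclusions),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  n_aut <- sum(x$chrom$is_autosome)
  cat(sprintf("<genome_layout> %d chromosomes (%d autosomes), %.1f Mb, %d exclusion(s)\n",
              nrow(x$chrom), n_aut, sum(x$chrom$length_bp) / 1e6,
              nrow(x$exclusions)))
  invisible(x)
}

chrom_length <- function(genome, chrom) {
  len <- setNames(genome$chrom$length_bp, genome$chrom$chrom)
  unname(len[chrom])
}

autosome_names <- function(genome) {
  genome$chrom$chrom[genome$chrom$is_autosome]
}

#' Genetic map with linear interpolation
#'
#' A genetic map is a table of (bp, cM) anchor points per chromosome. Queries
#' between anchors interpolate linearly; queries outside the anchored range
#' clamp to the terminal cM values rather than extrapolate, so sparse maps
#' can never produce negative genetic lengths.
#'
#' @param anchors data frame with columns `chrom`, `bp`, `cM`. Within each
#'   chromosome `bp` must be strictly increasing and `cM` non-decreasing.
#' @return a `genetic_map` tibble.
#' @export
genetic_map <- function(anchors) {
  anchors <- as_tibble(anchors)
  stopifnot(all(c("chrom", "bp", "cM") %in% names(anchors)))
  anchors <- arrange(anchors, .data$chrom, .data$bp)
  ok <- anchors %>%
    group_by(.data$chrom) %>%
    summarise(bp_inc = all(diff(.data$bp) > 0),
              cM_inc = all(diff(.data$cM) >= 0), .groups = "drop")
  if (!all(ok$bp_inc)) abort("bp positions must be strictly increasing per chromosome")
  if (!all(ok$cM_inc)) abort("cM positions must be non-decreasing per chromosome")
  class(anchors) <- c("genetic_map", class(anchors))
  anchors
}

#' Read a PLINK-style .map file as a genetic map
#'
#' Expects the four whitespace-separated PLINK columns: chromosome, marker
#' id, genetic position (cM), physical position (bp).
#'
#' @param path file path.
#' @return a `genetic_map`.
#' @export
read_genetic_map <- function(path) {
  df <- readr::read_table(path,
                          col_names = c("chrom", "id", "cM", "bp"),
                          col_types = "ccdd", progress = FALSE)
  genetic_map(tibble(chrom = df$chrom, bp = df$bp, cM = df$cM))
}

#' Interpolate genetic position
#'
#' Converts physical (bp) to genetic (cM) coordinates by linear
#' interpolation between map anchors; positions beyond the anchored range
#' clamp to the terminal cM values. `interpolate_bp()` is the inverse
#' (cM to bp); over intervals where the map is flat it returns the first
#' bp attaining that cM.
#'
#' @param map a `genetic_map`.
#' @param chrom chromosome name (scalar, or vector recycled against `bp`).
#' @param bp,cM query positions.
#' @return numeric vector of interpolated positions.
#' @export
interpolate_cM <- function(map, chrom, bp) {
  interp_map(map, chrom, bp, from = "bp", to = "cM")
}

#' @rdname interpolate_cM
#' @export
interpolate_bp <- function(map, chrom, cM) {
  interp_map(map, chrom, cM, from = "cM", to = "bp")
}

interp_map <- function(map, chrom, x, from, to) {
  n <- max(length(chrom), length(x))
  chrom <- rep_len(chrom, n)
  x <- rep_len(x, n)
  out <- numeric(n)
  for (ch in unique(chrom)) {
    anchors <- map[map$chrom == ch, , drop = FALSE]
    if (nrow(anchors) == 0L) abort(paste0("chromosome not in genetic map: ", ch))
    idx <- chrom == ch
    if (nrow(anchors) == 1L) {
      out[idx] <- anchors[[to]][1L]
    } else {
      out[idx] <- approx(anchors[[from]], anchors[[to]], xout = x[idx],
                         rule = 2, ties = "ordered")$y
    }
  }
  out
}

#' Genetic length of each chromosome, and the autosomal total
#'
#' @param map a `genetic_map`.
#' @param genome optional `genome_layout`; when given, only autosomes are
#'   totalled.
#' @return `map_lengths_cM()` returns a tibble (`chrom`, `cM`);
#'   `total_map_cM()` the summed autosomal genetic length.
#' @export
map_lengths_cM <- function(map) {
  map %>%
    group_by(.data$chrom) %>%
    summarise(cM = max(.data$cM) - min(.data$cM), .groups = "drop")
}

#' @rdname map_lengths_cM
#' @export
total_map_cM <- function(map, genome = NULL) {
  len <- map_lengths_cM(map)
  if (!is.null(genome)) len <- filter(len, .data$chrom %in% autosome_names(genome))
  sum(len$cM)
}

# Genetic lengths of the 22 human autosomes (cM, sex-averaged scale),
# used as relative weights for the synthetic genome.
human_autosome_cM <- c(284, 269, 223, 214, 204, 192, 187, 168, 166, 181,
                       158, 175, 126, 119, 141, 134, 128, 117, 107, 108,
                       62, 74)

#' Synthetic genome and genetic map
#'
#' Builds a genome of `n_chrom` autosomes whose genetic lengths are scaled
#' from the human autosomal map to a configurable total (default ~3,500 cM)
#' with a uniform recombination rate, so physical length follows directly
#' from genetic length. This is the coordinate system every simulator in the
#' package works on; a 2-chromosome toy (`n_chrom = 2`) keeps unit tests
#' fast.
#'
#' @param n_chrom number of autosomes (1-22).
#' @param total_cM total autosomal genetic length in cM.
#' @param cM_per_Mb uniform recombination rate.
#' @return list with elements `genome` (a `genome_layout`) and `map`
#'   (a `genetic_map` with anchors at both chromosome ends).
#' @export
synthetic_genome <- function(n_chrom = 22, total_cM = 3500, cM_per_Mb = 1) {
  stopifnot(n_chrom >= 1, n_chrom <= length(human_autosome_cM),
            total_cM > 0, cM_per_Mb > 0)
  w <- human_autosome_cM[seq_len(n_chrom)]
  cM <- w / sum(w) * total_cM
  bp <- round(cM / cM_per_Mb * 1e6)
  chroms <- paste0("chr", seq_len(n_chrom))
  genome <- genome_layout(tibble(chrom = chroms, length_bp = bp))
  map <- genetic_map(tibble(chrom = rep(chroms, each = 2L),
                            bp = as.numeric(rbind(0, bp)),
                            cM = as.numeric(rbind(0, cM))))
  list(genome = genome, map = map)
}
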