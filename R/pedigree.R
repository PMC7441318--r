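#' Pedigree specification
#'
#' A pedigree is a tibble with columns `id`, `father`, `mother` (both `NA`
#' for founders), `sex` ("M"/"F") and `affected` (logical). Every
#' non-founder has exactly two parents and parent links must be acyclic.
#'
#' @param df data frame with the columns above (`sex`/`affected` optional).
#' @return validated pedigree tibble, ordered so parents precede children.
#' @export
pedigree <- function(df) {
  df <- as_tibble(df)
  stopifnot(all(c("id", "father", "mother") %in% names(df)))
  if (!"sex" %in% names(df)) df$sex <- NA_character_
  if (!"affected" %in% names(df)) df$affected <- FALSE
  if (anyDuplicated(df$id) > 0L) abort("duplicate individual id")
  has_f <- !is.na(df$father)
  has_m <- !is.na(df$mother)
  if (any(has_f != has_m)) {
    abort("individuals must have two parents or none")
  }
  for (p in c(df$father[has_f], df$mother[has_m])) {
    if (!p %in% df$id) abort(paste0("unknown parent id: ", p))
  }
  df[topo_order(df), , drop = FALSE]
}

# Topological order (founders first); errors on parent-link cycles.
topo_order <- function(ped) {
  n <- nrow(ped)
  placed <- rep(FALSE, n)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  order <- integer(0)
  repeat {
    ready <- !placed & (is.na(fa) | placed[fa]) & (is.na(mo) | placed[mo])
    if (!any(ready)) break
    order <- c(order, which(ready))
    placed[ready] <- TRUE
  }
  if (length(order) < n) abort("pedigree contains a cycle")
  order
}

is_founder <- function(ped) is.na(ped$father)

#' Canonical pedigree templates
#'
#' Templates for the family structures the simulators emulate: an offspring
#' of a first-cousin mating (autozygosity loop of 6 meioses, inbreeding
#' coefficient 1/16), of a second-cousin mating (8 meioses, 1/64), and an
#' outbred trio.
#'
#' @param type one of "first_cousin", "second_cousin", "outbred".
#' @param n_offspring number of children of the focal mating (all marked
#'   affected).
#' @return a pedigree tibble; offspring ids are `"O1"`, `"O2"`, ...
#' @export
pedigree_template <- function(type = c("first_cousin", "second_cousin",
                                       "outbred"),
                              n_offspring = 1) {
  type <- match.arg(type)
  off <- tibble(id = paste0("O", seq_len(n_offspring)),
                father = "C1", mother = "C2",
                sex = rep_len(c("M", "F"), n_offspring), affected = TRUE)
  base <- switch(type,
    first_cousin = tibble(
      id     = c("F1", "F2", "S1", "S2", "P1", "P2", "C1", "C2"),
      father = c(NA,   NA,   NA,   NA,   "F1", "F1", "P1", "P2"),
      mother = c(NA,   NA,   NA,   NA,   "F2", "F2", "S1", "S2"),
      sex    = c("M", "F", "F", "F", "M", "M", "M", "F"),
      affected = FALSE),
    second_cousin = tibble(
      id     = c("F1", "F2", "S1", "S2", "S3", "S4", "A1", "A2", "B1", "B2"),
      father = c(NA,   NA,   NA,   NA,   NA,   NA,   "F1", "F1", "A1", "A2"),
      mother = c(NA,   NA,   NA,   NA,   NA,   NA,   "F2", "F2", "S1", "S2"),
      sex    = c("M", "F", "F", "F", "F", "F", "M", "M", "M", "M"),
      affected = FALSE) %>%
      bind_rows(tibble(id = c("C1", "C2"), father = c("B1", "B2"),
                       mother = c("S3", "S4"), sex = c("M", "F"),
                       affected = FALSE)),
    outbred = tibble(
      id = c("C1", "C2"), father = c(NA, NA), mother = c(NA, NA),
      sex = c("M", "F"), affected = FALSE))
  pedigree(bind_rows(base, off))
}

# Sort helpers tuned for the very short vectors gene dropping produces
# (typically 0-5 crossovers per meiosis): branch before falling back to
# sort.int, whose argument matching dominates runtime otherwise.
fsort <- function(x) {
  n <- length(x)
  if (n < 2L) return(x)
  if (n == 2L) {
    if (x[1L] > x[2L]) return(x[2:1]) else return(x)
  }
  sort.int(x, method = "quick")
}

# sorted union; exact duplicates (inherited shared breakpoints) dropped
fsortu <- function(x) {
  x <- fsort(x)
  if (length(x) < 2L) return(x)
  x[c(TRUE, diff(x) > 0)]
}

# One meiosis on a chromosome of genetic length L (cM). Haplotypes are
# lists (b = interior breakpoints in cM, v = founder-haplotype labels,
# length(b) + 1). Crossovers are Poisson with rate 1 per Morgan, no
# interference; the starting chromatid is random.
meiosis <- function(h1, h2, L) {
  nx <- rpois(1L, L / 100)
  if (nx == 0L) {
    if (runif(1L) < 0.5) return(h1) else return(h2)
  }
  x <- fsort(runif(nx, 0, L))
  phase <- if (runif(1L) < 0.5) 0L else 1L
  b <- fsortu(c(x, h1$b, h2$b))
  mids <- (c(0, b) + c(b, L)) / 2
  from1 <- (findInterval(mids, x) + phase) %% 2L == 0L
  lab <- integer(length(mids))
  if (any(from1)) lab[from1] <- h1$v[findInterval(mids[from1], h1$b) + 1L]
  if (!all(from1)) lab[!from1] <- h2$v[findInterval(mids[!from1], h2$b) + 1L]
  chg <- lab[-1L] != lab[-length(lab)]
  list(b = b[chg], v = lab[c(TRUE, chg)])
}

# Segments where the two haplotypes carry the same founder label.
azyg_segments <- function(h1, h2, L) {
  b <- fsortu(c(h1$b, h2$b))
  mids <- (c(0, b) + c(b, L)) / 2
  eq <- h1$v[findInterval(mids, h1$b) + 1L] ==
    h2$v[findInterval(mids, h2$b) + 1L]
  starts <- c(0, b)
  ends <- c(b, L)
  r <- rle(eq)
  cum <- cumsum(r$lengths)
  g0 <- starts[c(1L, cum[-length(cum)] + 1L)]
  g1 <- ends[cum]
  keep <- r$values
  list(start = g0[keep], end = g1[keep])
}

# Drop one chromosome through the whole pedigree; returns haplotype pairs
# indexed by pedigree row. fa/mo are row indices (NA for founders).
drop_chrom <- function(fa, mo, L) {
  n <- length(fa)
  haps <- vector("list", n)
  for (i in seq_len(n)) {
    if (is.na(fa[i])) {
      haps[[i]] <- list(h1 = list(b = numeric(0), v = 2L * i - 1L),
                        h2 = list(b = numeric(0), v = 2L * i))
    } else {
      f <- haps[[fa[i]]]
      m <- haps[[mo[i]]]
      haps[[i]] <- list(h1 = meiosis(f$h1, f$h2, L),
                        h2 = meiosis(m$h1, m$h2, L))
    }
  }
  haps
}

map_chrom_spans <- function(map) {
  map %>%
    group_by(.data$chrom) %>%
    summarise(cM0 = min(.data$cM), cM1 = max(.data$cM), .groups = "drop") %>%
    mutate(L = .data$cM1 - .data$cM0)
}

#' Gene-dropping simulation of autozygosity
#'
#' Drops founder haplotypes through a pedigree with Poisson recombination
#' (rate 1 per Morgan, no interference, no sex-specific maps), independently
#' per chromosome and replicate, and reports the autozygous segments of the
#' chosen offspring: maximal regions where both haplotypes descend from the
#' same founder haplotype. Segment genetic lengths come from the map; bp
#' coordinates by inverse interpolation.
#'
#' @param ped a pedigree (see [pedigree()]).
#' @param map a `genetic_map` covering every chromosome to simulate.
#' @param n_replicates number of independent replicates of the pedigree.
#' @param seed optional integer seed (restores the caller's RNG state).
#' @param offspring ids to report; default: individuals that are nobody's
#'   parent.
#' @param chroms chromosomes to simulate; default: all in `map`.
#' @return tibble with one row per autozygous segment: `replicate`, `id`,
#'   `chrom`, `start_cM`, `end_cM`, `length_cM`, `start_bp`, `end_bp`.
#'   Attributes `n_replicates`, `offspring` and `total_cM` record the run
#'   so offspring with zero autozygosity are not lost in summaries.
#' @seealso [autozygosity_summary()], [simulate_founder_ibd()]
#' @export
gene_drop <- function(ped, map, n_replicates = 1, seed = NULL,
                      offspring = NULL, chroms = NULL) {
  ped <- pedigree(ped)
  if (!is.null(seed)) withr::local_seed(seed)
  if (is.null(offspring)) {
    offspring <- setdiff(ped$id, c(ped$father, ped$mother))
  }
  off_rows <- match(offspring, ped$id)
  if (anyNA(off_rows)) abort("offspring id not in pedigree")
  spans <- map_chrom_spans(map)
  if (!is.null(chroms)) {
    missing <- setdiff(chroms, spans$chrom)
    if (length(missing) > 0L) {
      abort(paste0("chromosome not in genetic map: ", missing[1]))
    }
    spans <- spans[spans$chrom %in% chroms, , drop = FALSE]
  }
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)

  acc <- vector("list", n_replicates * nrow(spans))
  k <- 0L
  for (rep_i in seq_len(n_replicates)) {
    for (ci in seq_len(nrow(spans))) {
      L <- spans$L[ci]
      haps <- drop_chrom(fa, mo, L)
      for (oi in seq_along(off_rows)) {
        h <- haps[[off_rows[oi]]]
        seg <- azyg_segments(h$h1, h$h2, L)
        if (length(seg$start) == 0L) next
        k <- k + 1L
        acc[[k]] <- list(rep = rep_i, off = oi, ci = ci,
                         s = seg$start, e = seg$end)
      }
    }
  }
  acc <- acc[seq_len(k)]
  nseg <- vapply(acc, function(a) length(a$s), integer(1))
  out <- tibble(
    replicate = rep(vapply(acc, `[[`, numeric(1), "rep"), nseg),
    id = offspring[rep(vapply(acc, `[[`, numeric(1), "off"), nseg)],
    chrom = spans$chrom[rep(vapply(acc, `[[`, numeric(1), "ci"), nseg)],
    start_cM = unlist(lapply(acc, `[[`, "s"), use.names = FALSE),
    end_cM = unlist(lapply(acc, `[[`, "e"), use.names = FALSE))
  if (nrow(out) == 0L) {
    out <- tibble(replicate = numeric(0), id = character(0),
                  chrom = character(0), start_cM = numeric(0),
                  end_cM = numeric(0))
  }
  cM0 <- setNames(spans$cM0, spans$chrom)
  out <- out %>%
    mutate(length_cM = .data$end_cM - .data$start_cM,
           start_bp = interpolate_bp(map, .data$chrom,
                                     .data$start_cM + cM0[.data$chrom]),
           end_bp = interpolate_bp(map, .data$chrom,
                                   .data$end_cM + cM0[.data$chrom]))
  attr(out, "n_replicates") <- n_replicates
  attr(out, "offspring") <- offspring
  attr(out, "total_cM") <- sum(spans$L)
  class(out) <- c("gene_drop", class(out))
  out
}

#' Per-offspring autozygosity fractions from a gene-drop run
#'
#' Sums autozygous segments at or above `min_cM` per replicate and
#' offspring and expresses them as a percentage of the simulated genetic
#' map, the quantity the 2.5% family-classification threshold is applied
#' to. Offspring with no qualifying segment appear with 0.
#'
#' @param drops result of [gene_drop()].
#' @param min_cM minimum segment genetic length retained (default 5).
#' @return tibble: `replicate`, `id`, `autozygosity_pct`.
#' @export
autozygosity_summary <- function(drops, min_cM = 5) {
  total_cM <- attr(drops, "total_cM")
  offspring <- attr(drops, "offspring")
  n_rep <- attr(drops, "n_replicates")
  drops %>%
    as_tibble() %>%
    filter(.data$length_cM >= min_cM) %>%
    group_by(.data$replicate, .data$id) %>%
    summarise(cM = sum(.data$length_cM), .groups = "drop") %>%
    tidyr::complete(replicate = seq_len(n_rep), id = offspring,
                    fill = list(cM = 0)) %>%
    mutate(autozygosity_pct = 100 * .data$cM / total_cM) %>%
    select("replicate", "id", "autozygosity_pct")
}

#' IBD segments through an autozygosity loop from a single founder
#'
#' Simulates autozygosity between two descent lines of `meioses_per_side`
#' meioses each from one founder haplotype (total loop of
#' `2 * meioses_per_side` meioses). Crossovers of all loop meioses are
#' pooled as a Poisson process at rate 1 per Morgan per meiosis; a position
#' is autozygous when every meiosis in the loop is in the transmitting
#' phase. Because unconditioned descent through a deep loop almost never
#' carries founder material, each chromosome is simulated conditional on
#' founder descent to both alleles at its start; by memorylessness of the
#' crossover process the recorded segment lengths are unbiased draws of the
#' segment-length distribution (approximately exponential with mean
#' `100 / (2 * meioses_per_side)` cM in chromosome interiors).
#'
#' @param meioses_per_side meioses in each descent line (>= 1).
#' @param map a `genetic_map`.
#' @param n number of replicates (> 0).
#' @param seed optional integer seed.
#' @param chroms chromosomes to simulate; default all in `map`.
#' @return tibble: `replicate`, `chrom`, `start_cM`, `end_cM`, `length_cM`.
#' @export
simulate_founder_ibd <- function(meioses_per_side, map, n, seed = NULL,
                                 chroms = NULL) {
  stopifnot(meioses_per_side >= 1)
  if (n <= 0) abort("n must be positive")
  if (!is.null(seed)) withr::local_seed(seed)
  spans <- map_chrom_spans(map)
  if (!is.null(chroms)) spans <- spans[spans$chrom %in% chroms, , drop = FALSE]
  m_loop <- 2L * meioses_per_side

  acc <- vector("list", n * nrow(spans))
  k <- 0L
  for (rep_i in seq_len(n)) {
    for (ci in seq_len(nrow(spans))) {
      L <- spans$L[ci]
      nx <- rpois(1L, m_loop * L / 100)
      if (nx == 0L) {
        k <- k + 1L
        acc[[k]] <- list(rep = rep_i, ci = ci, s = 0, e = L)
        next
      }
      x <- fsort(runif(nx, 0, L))
      who <- sample.int(m_loop, nx, replace = TRUE)
      # each crossover toggles its meiosis between transmitting and not;
      # odd occurrences leave the transmitting set, even ones rejoin it
      occ <- stats::ave(seq_len(nx), who, FUN = seq_along)
      wrong <- cumsum(ifelse(occ %% 2L == 1L, 1L, -1L))
      ibd <- c(TRUE, wrong == 0L)   # state on [x_i, x_{i+1})
      bounds <- c(0, x, L)
      r <- rle(ibd)
      cum <- cumsum(r$lengths)
      g0 <- bounds[c(1L, cum[-length(cum)] + 1L)][r$values]
      g1 <- bounds[cum + 1L][r$values]
      k <- k + 1L
      acc[[k]] <- list(rep = rep_i, ci = ci, s = g0, e = g1)
    }
  }
  acc <- acc[seq_len(k)]
  nseg <- vapply(acc, function(a) length(a$s), integer(1))
  out <- tibble(
    replicate = rep(vapply(acc, function(a) a$rep, numeric(1)), nseg),
    chrom = spans$chrom[rep(vapply(acc, function(a) a$ci, numeric(1)), nseg)],
    start_cM = unlist(lapply(acc, `[[`, "s"), use.names = FALSE),
    end_cM = unlist(lapply(acc, `[[`, "e"), use.names = FALSE),
    length_cM = numeric(sum(nseg)))
  out$length_cM <- out$end_cM - out$start_cM
  out
}

#' Length-weighted fraction of IBD segment length passing a minimum-length
#' filter
#'
#' @param segments tibble with a `length_cM` column (e.g. from
#'   [simulate_founder_ibd()] or [gene_drop()]).
#' @param min_cM the filter threshold (default 5).
#' @return fraction in \[0, 1\] of total segment length in segments at or
#'   above `min_cM`.
#' @export
length_retained_fraction <- function(segments, min_cM = 5) {
  tot <- sum(segments$length_cM)
  if (tot == 0) return(NA_real_)
  sum(segments$length_cM[segments$length_cM >= min_cM]) / tot
}

#' Full founder-haplotype ancestry mosaic for chosen individuals
#'
#' Like [gene_drop()] but reports the complete two-haplotype founder
#' mosaic, which the genotype simulator reads genotypes off.
#'
#' @inheritParams gene_drop
#' @param ids individuals to report (default all).
#' @return tibble: `replicate`, `id`, `hap` (1/2), `chrom`, `start_cM`,
#'   `end_cM`, `founder_hap` (integer label unique per founder haplotype).
#' @export
drop_ancestry <- function(ped, map, n_replicates = 1, seed = NULL,
                          ids = NULL, chroms = NULL) {
  ped <- pedigree(ped)
  if (!is.null(seed)) withr::local_seed(seed)
  if (is.null(ids)) ids <- ped$id
  rows <- match(ids, ped$id)
  if (anyNA(rows)) abort("id not in pedigree")
  spans <- map_chrom_spans(map)
  if (!is.null(chroms)) spans <- spans[spans$chrom %in% chroms, , drop = FALSE]
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  out <- list()
  for (rep_i in seq_len(n_replicates)) {
    for (ci in seq_len(nrow(spans))) {
      L <- spans$L[ci]
      haps <- drop_chrom(fa, mo, L)
      for (ri in seq_along(rows)) {
        for (hi in 1:2) {
          h <- haps[[rows[ri]]][[hi]]
          out[[length(out) + 1L]] <- tibble(
            replicate = rep_i, id = ids[ri], hap = hi,
            chrom = spans$chrom[ci],
            start_cM = c(0, h$b), end_cM = c(h$b, L),
            founder_hap = h$v)
        }
      }
    }
  }
  bind_rows(out)
}
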