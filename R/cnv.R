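#' Multi-caller CNV consensus by per-base support depth
#'
#' Caller calls are grouped by sample and copy-number class (classes are
#' never pooled) and each caller's calls are merged; consensus events are
#' the maximal intervals where at least `min_algorithms` distinct callers
#' agree, base by base. The consensus probe support is the minimum probe
#' count among the supporting calls, and events below `min_probes` are
#' dropped.
#'
#' @param calls caller-call tibble: `sample`, `caller`, `chrom`, `start`,
#'   `end`, `cn` (0/1/3/4), `probes`.
#' @param min_algorithms minimum number of distinct supporting callers.
#' @param min_probes minimum probe support (applied to the consensus
#'   minimum; default 1). Use 5 for biallelic-deletion discovery and 25 for
#'   de novo burden scans.
#' @param callers the caller universe; defaults to the distinct callers in
#'   `calls`. Supplying it lets a run where some configured caller emitted
#'   nothing return an empty consensus instead of erroring.
#' @return consensus tibble: `sample`, `chrom`, `start`, `end`, `cn`,
#'   `n_callers`, `callers` (comma-joined), `min_probes`.
#' @export
build_consensus <- function(calls, min_algorithms = 3, min_probes = 1,
                            callers = NULL) {
  calls <- as_tibble(calls)
  need <- c("sample", "caller", "chrom", "start", "end", "cn", "probes")
  stopifnot(all(need %in% names(calls)))
  if (nrow(calls) > 0 && any(calls$probes < 1)) abort("probe count must be >= 1")
  if (is.null(callers)) callers <- unique(calls$caller)
  n_avail <- length(unique(c(callers, calls$caller)))
  if (min_algorithms > max(n_avail, 1L)) {
    abort(sprintf("min_algorithms (%d) exceeds the %d distinct caller(s) present",
                  min_algorithms, n_avail))
  }
  empty <- tibble(sample = character(), chrom = character(),
                  start = numeric(), end = numeric(), cn = integer(),
                  n_callers = integer(), callers = character(),
                  min_probes = numeric())
  if (nrow(calls) == 0L) return(empty)

  out <- calls %>%
    group_by(.data$sample, .data$cn, .data$chrom) %>%
    dplyr::group_map(function(df, key) {
      cons <- depth_consensus(df, min_algorithms)
      if (nrow(cons) == 0L) return(NULL)
      cons %>%
        mutate(sample = key$sample, cn = key$cn, chrom = key$chrom)
    }) %>%
    bind_rows()
  if (nrow(out) == 0L) return(empty)
  out %>%
    filter(.data$min_probes >= .env$min_probes) %>%
    select("sample", "chrom", "start", "end", "cn", "n_callers",
           "callers", "min_probes") %>%
    arrange(.data$sample, .data$chrom, .data$start)
}

# depth sweep over one sample/class/chromosome group
depth_consensus <- function(df, k) {
  per_caller <- df %>%
    mutate(chrom = "x") %>%
    group_by(.data$caller) %>%
    dplyr::group_map(function(d, key) {
      m <- interval_merge(d)
      m$caller <- key$caller
      m
    }) %>%
    bind_rows()
  bp <- sort(unique(c(per_caller$start, per_caller$end)))
  if (length(bp) < 2L) return(tibble())
  seg_s <- bp[-length(bp)]
  seg_e <- bp[-1L]
  depth <- vapply(seq_along(seg_s), function(i) {
    sum(per_caller$start <= seg_s[i] & per_caller$end >= seg_e[i])
  }, integer(1))
  hit <- depth >= k
  if (!any(hit)) return(tibble())
  # elementary segments partition the covered span, so runs of qualifying
  # segments merge into maximal depth>=k intervals
  r <- rle(hit)
  cum <- cumsum(r$lengths)
  first <- c(1L, cum[-length(cum)] + 1L)[r$values]
  last <- cum[r$values]
  starts <- seg_s[first]
  ends <- seg_e[last]
  res <- purrr::map2(starts, ends, function(s, e) {
    sup_calls <- df[df$start < e & df$end > s, ]
    sup <- sort(unique(sup_calls$caller))
    tibble(start = s, end = e, n_callers = length(sup),
           callers = paste(sup, collapse = ","),
           min_probes = min(sup_calls$probes))
  })
  bind_rows(res)
}

#' Classify consensus CNVs as rare or common against a control catalog
#'
#' An event is common when more than half of its length (strictly > 50%)
#' is covered by a single catalog entry of the same copy-number class;
#' an event seen only in a different class (e.g. CNV1 but never CNV0)
#' stays rare. The query length is the denominator.
#'
#' @param cnvs consensus tibble (needs `chrom`, `start`, `end`, `cn`).
#' @param catalog control catalog tibble: `chrom`, `start`, `end`, `cn`,
#'   optionally `count` (>= 1 observations).
#' @param max_overlap query-fraction above which an event is common
#'   (default 0.5, strict).
#' @return `cnvs` with added `overlap_frac` and `rarity` ("rare"/"common").
#' @export
classify_rarity <- function(cnvs, catalog, max_overlap = 0.5) {
  cnvs <- as_tibble(cnvs)
  catalog <- as_tibble(catalog)
  if ("count" %in% names(catalog) && any(catalog$count < 1)) {
    abort("catalog observation counts must be >= 1")
  }
  frac <- vapply(seq_len(nrow(cnvs)), function(i) {
    q <- cnvs[i, ]
    ent <- catalog[catalog$chrom == q$chrom & catalog$cn == q$cn &
                     catalog$start < q$end & catalog$end > q$start, ]
    if (nrow(ent) == 0L) return(0)
    ov <- pmin(ent$end, q$end) - pmax(ent$start, q$start)
    max(ov) / (q$end - q$start)
  }, numeric(1))
  cnvs %>%
    mutate(overlap_frac = frac,
           rarity = ifelse(frac > max_overlap, "common", "rare"))
}

#' Flag consensus CNVs as de novo or inherited
#'
#' Parental evidence is deliberately lenient where child discovery is
#' stringent: a child event is inherited if either parent has any
#' single-caller call of the same dosage direction (loss: CN 0/1; gain:
#' CN 3/4) overlapping it by at least 1 bp; de novo only when both
#' genotyped parents are call-free at the locus; unknown when a parent is
#' not genotyped.
#'
#' @param cnvs consensus tibble with a `sample` column.
#' @param parent_calls raw caller-call tibble (any caller, any probe
#'   count).
#' @param ped pedigree declaring parents.
#' @param genotyped ids with genotype data; default: every id occurring in
#'   `parent_calls` plus every child in `cnvs` (a parent absent from this
#'   set makes the call "unknown").
#' @return `cnvs` with an `inheritance` column
#'   ("de novo"/"inherited"/"unknown").
#' @export
flag_de_novo <- function(cnvs, parent_calls, ped, genotyped = NULL) {
  cnvs <- as_tibble(cnvs)
  ped <- pedigree(ped)
  if (is.null(genotyped)) {
    genotyped <- union(unique(parent_calls$sample), unique(cnvs$sample))
  }
  direction <- function(cn) ifelse(cn < 2, "loss", "gain")
  res <- vapply(seq_len(nrow(cnvs)), function(i) {
    q <- cnvs[i, ]
    ri <- match(q$sample, ped$id)
    if (is.na(ri)) return("unknown")
    fa <- ped$father[ri]; mo <- ped$mother[ri]
    if (is.na(fa) || !all(c(fa, mo) %in% genotyped)) return("unknown")
    pc <- parent_calls[parent_calls$sample %in% c(fa, mo) &
                         parent_calls$chrom == q$chrom &
                         direction(parent_calls$cn) == direction(q$cn) &
                         parent_calls$start < q$end &
                         parent_calls$end > q$start, ]
    if (nrow(pc) > 0L) "inherited" else "de novo"
  }, character(1))
  mutate(cnvs, inheritance = res)
}

#' Exact one-sided burden test for carrier excess in affected individuals
#'
#' The one-sided Fisher test: with both margins fixed, the p-value is the
#' exact upper hypergeometric tail probability of observing at least the
#' given number of affected carriers. Computed by direct summation of the
#' hypergeometric mass, no approximation.
#'
#' @param affected_carriers,affected_n carriers and group size among
#'   affected individuals.
#' @param unaffected_carriers,unaffected_n same for unaffected siblings.
#' @return object of class `burden_test`: counts, carrier rates (%), and
#'   the one-sided `p_value`.
#' @export
burden_test <- function(affected_carriers, affected_n,
                        unaffected_carriers, unaffected_n) {
  if (affected_n <= 0 || unaffected_n <= 0) abort("group sizes must be positive")
  stopifnot(affected_carriers >= 0, unaffected_carriers >= 0,
            affected_carriers <= affected_n,
            unaffected_carriers <= unaffected_n)
  K <- affected_carriers + unaffected_carriers
  N <- affected_n + unaffected_n
  hi <- min(K, affected_n)
  p <- sum(dhyper(affected_carriers:hi, K, N - K, affected_n))
  p <- min(max(p, .Machine$double.xmin), 1)
  structure(list(affected_carriers = affected_carriers,
                 affected_n = affected_n,
                 unaffected_carriers = unaffected_carriers,
                 unaffected_n = unaffected_n,
                 affected_rate_pct = 100 * affected_carriers / affected_n,
                 unaffected_rate_pct = 100 * unaffected_carriers / unaffected_n,
                 p_value = p),
            class = "burden_test")
}

#' @export
print.burden_test <- function(x, ...) {
  cat(sprintf("Carrier burden: %d/%d affected (%.1f%%) vs %d/%d unaffected (%.1f%%)\n",
              x$affected_carriers, x$affected_n, x$affected_rate_pct,
              x$unaffected_carriers, x$unaffected_n, x$unaffected_rate_pct))
  cat(sprintf("One-sided exact p = %.4g\n", x$p_value))
  invisible(x)
}

#' @export
tidy.burden_test <- function(x, ...) {
  tibble(group = c("affected", "unaffected"),
         carriers = c(x$affected_carriers, x$unaffected_carriers),
         n = c(x$affected_n, x$unaffected_n),
         rate_pct = c(x$affected_rate_pct, x$unaffected_rate_pct))
}

#' @export
glance.burden_test <- function(x, ...) {
  tibble(p_value = x$p_value,
         odds_direction = "affected-enriched",
         n_total = x$affected_n + x$unaffected_n)
}

carrier_counts <- function(events, samples) {
  carriers <- unique(events$sample)
  samples %>%
    mutate(group = ifelse(.data$affected, "affected", "unaffected")) %>%
    group_by(.data$group) %>%
    summarise(n = dplyr::n(),
              carriers = sum(.data$id %in% carriers), .groups = "drop")
}

#' Biallelic-deletion selection cascade
#'
#' Applies the increasingly stringent selection used to compare
#' homozygous-deletion (CNV0) rates between affected individuals and
#' unaffected siblings: drop families with a known cause, keep
#' copy-number-0 events, require caller and probe support, and keep events
#' rare against the control catalog. Event and carrier counts for both
#' phenotype groups plus the one-sided exact burden p are reported at
#' every stage.
#'
#' @param consensus consensus tibble (from [build_consensus()], any
#'   `min_algorithms` at build time; support is re-checked here).
#' @param catalog control catalog for [classify_rarity()].
#' @param samples sample tibble: `id`, `family`, `affected` (logical).
#' @param excluded_families families with previously identified causes.
#' @param min_algorithms,min_probes support thresholds for the stringent
#'   stage (defaults 3 and 5).
#' @return object of class `cnv0_selection`: `events` (the surviving
#'   events, with rarity columns) and `cascade` (per-stage counts and p).
#' @export
select_cnv0 <- function(consensus, catalog, samples,
                        excluded_families = character(),
                        min_algorithms = 3, min_probes = 5) {
  samples <- as_tibble(samples)
  stopifnot(all(c("id", "family", "affected") %in% names(samples)))
  kept_samples <- samples %>%
    filter(!.data$family %in% excluded_families)
  stages <- list()
  note_stage <- function(label, ev) {
    cc <- carrier_counts(ev, kept_samples)
    get <- function(grp, col) {
      v <- cc[[col]][cc$group == grp]
      if (length(v) == 0L) 0L else v
    }
    an <- sum(kept_samples$affected)
    un <- sum(!kept_samples$affected)
    bt <- burden_test(get("affected", "carriers"), an,
                      get("unaffected", "carriers"), un)
    tibble(stage = label, n_events = nrow(ev),
           affected_carriers = bt$affected_carriers, affected_n = an,
           unaffected_carriers = bt$unaffected_carriers, unaffected_n = un,
           affected_rate_pct = bt$affected_rate_pct,
           unaffected_rate_pct = bt$unaffected_rate_pct,
           p_one_sided = bt$p_value)
  }

  ev <- consensus %>% filter(.data$sample %in% kept_samples$id)
  stages[[1]] <- note_stage("families without known cause", ev)
  ev <- ev %>% filter(.data$cn == 0)
  stages[[2]] <- note_stage("CNV0", ev)
  ev <- ev %>%
    filter(.data$n_callers >= min_algorithms,
           .data$min_probes >= .env$min_probes)
  stages[[3]] <- note_stage(sprintf(">=%d algorithms & >=%d probes",
                                    min_algorithms, min_probes), ev)
  ev <- classify_rarity(ev, catalog) %>% filter(.data$rarity == "rare")
  stages[[4]] <- note_stage("rare vs control catalog", ev)

  structure(list(events = ev, cascade = bind_rows(stages),
                 samples = kept_samples),
            class = "cnv0_selection")
}

#' @export
print.cnv0_selection <- function(x, ...) {
  cat("<cnv0_selection>\n")
  print(as.data.frame(x$cascade), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.cnv0_selection <- function(x, ...) x$cascade

#' @export
glance.cnv0_selection <- function(x, ...) {
  final <- x$cascade[nrow(x$cascade), ]
  tibble(n_events = final$n_events,
         affected_rate_pct = final$affected_rate_pct,
         unaffected_rate_pct = final$unaffected_rate_pct,
         p_one_sided = final$p_one_sided)
}
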