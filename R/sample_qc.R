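#' Platform QC thresholds
#'
#' Default per-platform chip-QC thresholds: a sample fails when its call
#' rate is below the platform minimum or its CNV-call count is at or above
#' the platform cap. The defaults mirror common practice for the two array
#' families the pipeline targets: call rate >= 97% and < 200 CNV calls for
#' high-density arrays, call rate >= 95% and < 125 calls for the older
#' 5.0/500K designs.
#'
#' @return tibble: `platform`, `min_call_rate` (fraction), `max_cnvs`
#'   (exclusive cap).
#' @export
default_qc_thresholds <- function() {
  tibble(platform = c("affy6", "affy5", "affy500k"),
         min_call_rate = c(0.97, 0.95, 0.95),
         max_cnvs = c(200, 125, 125))
}

#' Sample-level chip QC filter
#'
#' @param metrics tibble with columns `id`, `platform`, `call_rate`
#'   (fraction in \[0,1\] or percent in \[0,100\]; percents are detected and
#'   rescaled), `n_cnvs`.
#' @param thresholds per-platform thresholds (see
#'   [default_qc_thresholds()]).
#' @return the metrics tibble with logical `pass` and a `reasons` character
#'   column listing every failed check (empty string when passing).
#' @export
qc_filter <- function(metrics, thresholds = default_qc_thresholds()) {
  metrics <- as_tibble(metrics)
  stopifnot(all(c("id", "platform", "call_rate", "n_cnvs") %in%
                  names(metrics)))
  unknown <- setdiff(unique(metrics$platform), thresholds$platform)
  if (length(unknown) > 0L) {
    abort(paste0("no QC thresholds configured for platform: ", unknown[1]))
  }
  cr <- metrics$call_rate
  if (any(cr > 1)) cr <- cr / 100   # percent input
  df <- metrics %>%
    mutate(call_rate_frac = cr) %>%
    left_join(thresholds, by = "platform")
  fail_cr <- df$call_rate_frac < df$min_call_rate
  fail_cnv <- df$n_cnvs >= df$max_cnvs
  reasons <- character(nrow(df))
  reasons[fail_cr] <- sprintf("call rate %.1f%% < %.0f%%",
                              100 * df$call_rate_frac[fail_cr],
                              100 * df$min_call_rate[fail_cr])
  reasons[fail_cnv] <- trimws(paste(
    reasons[fail_cnv],
    sprintf("CNV count %d >= %d", df$n_cnvs[fail_cnv],
            df$max_cnvs[fail_cnv]), sep = "; "))
  reasons <- sub("^; ", "", reasons)
  metrics %>%
    mutate(pass = !(fail_cr | fail_cnv), reasons = reasons)
}

#' Genotype-based sex inference
#'
#' Counts heterozygous and homozygous calls on the X chromosome and call
#' presence on Y. A sample is called male when its X heterozygosity rate is
#' below `max_male_x_het` and its Y call rate above `min_y_call_rate`;
#' female otherwise; "undetermined" when no sex-chromosome markers exist.
#' When the sample table declares a sex, mismatches are flagged.
#'
#' @param panel a `genotype_panel`; X/Y markers are recognized by
#'   chromosome name ("X"/"chrX", "Y"/"chrY").
#' @param max_male_x_het X heterozygosity rate below which a sample is
#'   male-consistent (default 0.05).
#' @param min_y_call_rate Y call rate above which Y material is considered
#'   present (default 0.5).
#' @return tibble: `id`, `x_het_rate`, `y_call_rate`, `inferred_sex`,
#'   `declared_sex`, `mismatch`.
#' @export
infer_sex <- function(panel, max_male_x_het = 0.05, min_y_call_rate = 0.5) {
  stopifnot(inherits(panel, "genotype_panel"))
  mk <- panel$markers
  xi <- which(mk$chrom %in% c("X", "chrX"))
  yi <- which(mk$chrom %in% c("Y", "chrY"))
  gx <- panel$genotypes[, xi, drop = FALSE]
  gy <- panel$genotypes[, yi, drop = FALSE]
  n_x <- rowSums(!is.na(gx))
  x_het <- ifelse(n_x > 0, rowSums(gx == 1L, na.rm = TRUE) / n_x, NA_real_)
  y_call <- if (length(yi) > 0) rowSums(!is.na(gy)) / length(yi) else
    rep(NA_real_, nrow(panel$samples))
  inferred <- dplyr::case_when(
    length(xi) == 0L ~ "undetermined",
    is.na(x_het) ~ "undetermined",
    x_het < max_male_x_het &
      (is.na(y_call) | y_call > min_y_call_rate) ~ "M",
    TRUE ~ "F")
  declared <- if ("declared_sex" %in% names(panel$samples)) {
    panel$samples$declared_sex
  } else if ("sex" %in% names(panel$samples)) {
    panel$samples$sex
  } else {
    rep(NA_character_, nrow(panel$samples))
  }
  tibble(id = panel$samples$id,
         x_het_rate = x_het, y_call_rate = y_call,
         inferred_sex = inferred, declared_sex = declared,
         mismatch = !is.na(declared) & inferred != "undetermined" &
           inferred != declared)
}

#' Verify declared pedigree relationships from genotype sharing
#'
#' For each declared parent-child pair, counts opposite homozygotes (one
#' parent 0/0 while the child is 2/2 or vice versa), which true pairs show
#' only through genotype error; for each declared full-sib pair, the
#' fraction of identical genotypes. Pairs outside the configured windows
#' are flagged `drop`; near-identical declared sibs are flagged
#' `duplicate`; pairs with too few overlapping markers report
#' `insufficient`.
#'
#' @param panel a `genotype_panel`.
#' @param ped a pedigree (see [pedigree()]) declaring the relationships.
#' @param max_parent_opp_hom maximum opposite-homozygote fraction for a
#'   kept parent-child pair (default 0.02, accommodating ~1% genotype
#'   error).
#' @param sib_ident_window inclusive \[low, high\] window of
#'   identical-genotype fraction for a kept full-sib pair (default
#'   c(0.45, 0.9); above the window flags duplicate/MZ).
#' @param min_markers minimum jointly non-missing markers per pair.
#' @return tibble: `id1`, `id2`, `declared`, `n_markers`,
#'   `frac_identical`, `frac_share_allele`, `opp_hom_frac`, `action`
#'   (`keep`, `drop`, `duplicate`, `insufficient`).
#' @export
verify_relationships <- function(panel, ped,
                                 max_parent_opp_hom = 0.02,
                                 sib_ident_window = c(0.45, 0.9),
                                 min_markers = 100) {
  stopifnot(inherits(panel, "genotype_panel"))
  ped <- pedigree(ped)
  ids <- panel$samples$id
  g <- panel$genotypes

  pairs <- list()
  for (i in seq_len(nrow(ped))) {
    for (p in c(ped$father[i], ped$mother[i])) {
      if (!is.na(p) && ped$id[i] %in% ids && p %in% ids) {
        pairs[[length(pairs) + 1L]] <-
          tibble(id1 = p, id2 = ped$id[i], declared = "parent-child")
      }
    }
  }
  key <- paste(ped$father, ped$mother)
  for (k in unique(key[!is.na(ped$father)])) {
    sibs <- ped$id[key == k & !is.na(ped$father)]
    sibs <- sibs[sibs %in% ids]
    if (length(sibs) >= 2L) {
      cmb <- utils::combn(sibs, 2L)
      for (j in seq_len(ncol(cmb))) {
        pairs[[length(pairs) + 1L]] <-
          tibble(id1 = cmb[1L, j], id2 = cmb[2L, j], declared = "sib")
      }
    }
  }
  if (length(pairs) == 0L) {
    return(tibble(id1 = character(), id2 = character(),
                  declared = character(), n_markers = integer(),
                  frac_identical = numeric(), frac_share_allele = numeric(),
                  opp_hom_frac = numeric(), action = character()))
  }
  pairs <- bind_rows(pairs)

  stats_one <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    n <- sum(ok)
    if (n == 0L) {
      return(c(n = 0, ident = NA, share = NA, opp = NA))
    }
    a <- a[ok]; b <- b[ok]
    ident <- mean(a == b)
    opp <- mean((a == 0L & b == 2L) | (a == 2L & b == 0L))
    share <- mean(!((a == 0L & b == 2L) | (a == 2L & b == 0L)))
    c(n = n, ident = ident, share = share, opp = opp)
  }
  st <- t(vapply(seq_len(nrow(pairs)), function(j) {
    stats_one(g[match(pairs$id1[j], ids), ], g[match(pairs$id2[j], ids), ])
  }, numeric(4)))
  pairs <- pairs %>%
    mutate(n_markers = as.integer(st[, 1]),
           frac_identical = st[, 2],
           frac_share_allele = st[, 3],
           opp_hom_frac = st[, 4])
  pairs %>%
    mutate(action = dplyr::case_when(
      n_markers < min_markers ~ "insufficient",
      declared == "parent-child" &
        opp_hom_frac <= max_parent_opp_hom ~ "keep",
      declared == "parent-child" ~ "drop",
      declared == "sib" & frac_identical > sib_ident_window[2] ~ "duplicate",
      declared == "sib" & frac_identical >= sib_ident_window[1] ~ "keep",
      TRUE ~ "drop"))
}
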