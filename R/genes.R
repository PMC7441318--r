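#' Gene models
#'
#' Gene annotations are held as a `gene_models` object: a `genes` tibble
#' (`gene`, `chrom`, `strand`, `tx_start`, `tx_end`, `cds_start`,
#' `cds_end`, `coding`) plus a flat `coding_exons` interval tibble. A
#' noncoding gene has an empty coding span (`cds_start == cds_end`) and no
#' coding exons.
#'
#' @param genes gene tibble as above.
#' @param coding_exons tibble `gene`, `chrom`, `start`, `end`.
#' @return a `gene_models` object.
#' @export
gene_models <- function(genes, coding_exons) {
  genes <- as_tibble(genes)
  coding_exons <- as_tibble(coding_exons)
  stopifnot(all(c("gene", "chrom", "tx_start", "tx_end", "cds_start",
                  "cds_end", "coding") %in% names(genes)))
  if (any(genes$cds_start > genes$cds_end)) abort("cds_start > cds_end")
  if (any(genes$cds_start < genes$tx_start | genes$cds_end > genes$tx_end)) {
    abort("coding span outside transcript span")
  }
  if (nrow(coding_exons) > 0L) {
    j <- left_join(coding_exons, genes, by = c("gene", "chrom"))
    if (any(is.na(j$cds_start)) ||
        any(j$start < j$cds_start | j$end > j$cds_end)) {
      abort("coding exon outside its gene's coding span")
    }
  }
  structure(list(genes = genes, coding_exons = coding_exons),
            class = "gene_models")
}

#' Read a refFlat-like gene annotation table
#'
#' Expects the standard 11 refFlat columns (geneName, name, chrom, strand,
#' txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds) in a
#' headerless TSV; exon block lists are comma-separated. Transcripts of the
#' same gene are kept as separate rows; coding exons are the exon blocks
#' clipped to the coding span.
#'
#' @param path file path.
#' @return a `gene_models` object.
#' @export
read_refflat <- function(path) {
  df <- readr::read_tsv(path, col_names = c(
    "gene", "name", "chrom", "strand", "txStart", "txEnd",
    "cdsStart", "cdsEnd", "exonCount", "exonStarts", "exonEnds"),
    col_types = "ccccddddicc", progress = FALSE)
  genes <- tibble(gene = df$gene, chrom = df$chrom, strand = df$strand,
                  tx_start = df$txStart, tx_end = df$txEnd,
                  cds_start = df$cdsStart, cds_end = df$cdsEnd,
                  coding = df$cdsEnd > df$cdsStart)
  ex <- purrr::map(seq_len(nrow(df)), function(i) {
    if (!genes$coding[i]) return(NULL)
    s <- as.numeric(strsplit(df$exonStarts[i], ",")[[1]])
    e <- as.numeric(strsplit(df$exonEnds[i], ",")[[1]])
    cs <- pmax(s, df$cdsStart[i])
    ce <- pmin(e, df$cdsEnd[i])
    keep <- cs < ce
    if (!any(keep)) return(NULL)
    tibble(gene = df$gene[i], chrom = df$chrom[i],
           start = cs[keep], end = ce[keep])
  })
  gene_models(genes, bind_rows(ex))
}

#' Flag CNVs that disrupt coding exons
#'
#' A CNV is exonic when it intersects any coding exon of a coding gene
#' (by >= 1 bp); exon overlap with noncoding genes does not count, and
#' purely intronic or intergenic CNVs are noncoding.
#'
#' @param cnvs interval tibble.
#' @param genes a `gene_models` object.
#' @return `cnvs` with logical `exonic` and comma-joined `exonic_genes`.
#' @export
annotate_exonic <- function(cnvs, genes) {
  cnvs <- as_tibble(cnvs)
  ex <- genes$coding_exons
  res <- purrr::map(seq_len(nrow(cnvs)), function(i) {
    q <- cnvs[i, ]
    hit <- ex[ex$chrom == q$chrom & ex$start < q$end & ex$end > q$start, ]
    g <- sort(unique(hit$gene))
    list(exonic = length(g) > 0L, genes = paste(g, collapse = ","))
  })
  cnvs %>%
    mutate(exonic = vapply(res, `[[`, logical(1), "exonic"),
           exonic_genes = vapply(res, `[[`, character(1), "genes"))
}

gap_bp <- function(a_start, a_end, b_start, b_end) {
  pmax(0, pmax(b_start - a_end, a_start - b_end))
}

#' Coding genes neighboring a CNV
#'
#' For each CNV, reports the nearest coding gene by genomic distance to its
#' coding span (0 when overlapping; ties all reported), plus any coding
#' gene whose coding span lies within `window_kb` of the nearest gene's
#' coding span. No reported gene may be farther than `cap_kb` from the CNV
#' itself. Distances anchor on coding spans because regulatory
#' neighborhoods are defined around the coding region.
#'
#' @param cnvs interval tibble; an `id` column is used when present,
#'   otherwise row numbers.
#' @param genes a `gene_models` object (only coding genes are considered).
#' @param window_kb window around the nearest gene's coding span
#'   (default 150).
#' @param cap_kb maximum CNV-to-gene distance (default 1150, i.e.
#'   1 Mb + the 150 kb window).
#' @return tibble: `cnv_id`, `gene`, `distance_bp` (CNV to coding span),
#'   `role` ("nearest"/"neighbor"), `side` ("overlap"/"left"/"right",
#'   the gene's position relative to the CNV).
#' @export
neighbor_genes <- function(cnvs, genes, window_kb = 150, cap_kb = 1150) {
  cnvs <- as_tibble(cnvs)
  ids <- if ("id" %in% names(cnvs)) cnvs$id else as.character(seq_len(nrow(cnvs)))
  g <- genes$genes %>% filter(.data$coding)
  out <- purrr::map(seq_len(nrow(cnvs)), function(i) {
    q <- cnvs[i, ]
    cand <- g %>% filter(.data$chrom == q$chrom)
    if (nrow(cand) == 0L) return(NULL)
    d <- gap_bp(q$start, q$end, cand$cds_start, cand$cds_end)
    cand <- cand %>% mutate(distance_bp = d) %>%
      filter(.data$distance_bp <= cap_kb * 1000)
    if (nrow(cand) == 0L) return(NULL)
    dmin <- min(cand$distance_bp)
    nearest <- cand %>% filter(.data$distance_bp == dmin)
    # genes within the window of any tied nearest gene's coding span
    near_window <- vapply(seq_len(nrow(cand)), function(j) {
      any(gap_bp(nearest$cds_start, nearest$cds_end,
                 cand$cds_start[j], cand$cds_end[j]) <= window_kb * 1000)
    }, logical(1))
    keep <- cand[near_window | cand$distance_bp == dmin, ]
    keep %>%
      mutate(cnv_id = ids[i],
             role = ifelse(.data$distance_bp == dmin, "nearest", "neighbor"),
             side = dplyr::case_when(
               .data$cds_end <= q$start ~ "left",
               .data$cds_start >= q$end ~ "right",
               TRUE ~ "overlap")) %>%
      select("cnv_id", "gene", "distance_bp", "role", "side")
  })
  res <- bind_rows(out)
  if (nrow(res) == 0L) {
    return(tibble(cnv_id = character(), gene = character(),
                  distance_bp = numeric(), role = character(),
                  side = character()))
  }
  res
}

#' TAD-boundary disruption by deletions
#'
#' Boundary regions are the gaps between consecutive TADs of a profile
#' (abutting TADs yield a 1-bp point boundary). A deletion disrupts a
#' boundary strictly when it contains an entire boundary region, and
#' permissively when a TAD start or end coordinate falls strictly inside
#' it (full-boundary removal counts as permissive too, so strict always
#' implies permissive).
#'
#' @param cnvs interval tibble; `id` column used when present.
#' @param tads a TAD interval tibble, or a named list of them (one per
#'   profile). TADs must be non-overlapping within a profile.
#' @return tibble: `cnv_id`, `profile`, `strict`, `permissive`.
#' @export
tad_disruption <- function(cnvs, tads) {
  cnvs <- as_tibble(cnvs)
  ids <- if ("id" %in% names(cnvs)) cnvs$id else as.character(seq_len(nrow(cnvs)))
  if (is.data.frame(tads)) tads <- list(profile1 = tads)
  out <- list()
  for (pn in names(tads)) {
    td <- as_interval_tbl(tads[[pn]]) %>%
      arrange(.data$chrom, .data$start)
    ovl <- td %>%
      group_by(.data$chrom) %>%
      summarise(bad = any(lag(.data$end, default = -Inf) > .data$start),
                .groups = "drop")
    if (any(ovl$bad)) abort(sprintf("overlapping TADs in profile %s", pn))
    bounds <- td %>%
      group_by(.data$chrom) %>%
      mutate(nxt = dplyr::lead(.data$start)) %>%
      ungroup() %>%
      filter(!is.na(.data$nxt)) %>%
      mutate(bstart = .data$end,
             bend = pmax(.data$nxt, .data$end + 1)) %>%   # 1-bp point if abutting
      select(chrom = "chrom", start = "bstart", end = "bend")
    coords <- td %>%
      tidyr::pivot_longer(c("start", "end"), values_to = "pos") %>%
      select("chrom", "pos")
    for (i in seq_len(nrow(cnvs))) {
      q <- cnvs[i, ]
      b <- bounds[bounds$chrom == q$chrom, ]
      strict <- any(b$start >= q$start & b$end <= q$end)
      x <- coords$pos[coords$chrom == q$chrom]
      permissive <- strict || any(x > q$start & x < q$end)
      out[[length(out) + 1L]] <- tibble(cnv_id = ids[i], profile = pn,
                                        strict = strict,
                                        permissive = permissive)
    }
  }
  bind_rows(out)
}
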