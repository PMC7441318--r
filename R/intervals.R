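#' Interval tables
#'
#' Genomic intervals are plain tibbles with columns `chrom`, `start`, `end`
#' in 0-based half-open coordinates. `interval_merge()` normalizes a table
#' by sorting and merging overlapping or book-ended intervals (idempotent);
#' `interval_total()` returns the summed length of a normalized table.
#'
#' @param x interval data frame (`chrom`, `start`, `end`; extra columns are
#'   dropped by `interval_merge()`).
#' @return `interval_merge()`: a normalized interval tibble;
#'   `interval_total()`: total bp covered.
#' @export
interval_merge <- function(x) {
  x <- as_interval_tbl(x)
  if (nrow(x) == 0L) return(empty_intervals())
  x <- arrange(x, .data$chrom, .data$start, .data$end)
  x %>%
    group_by(.data$chrom) %>%
    mutate(grp = cumsum(.data$start > cummax_lag(.data$end))) %>%
    group_by(.data$chrom, .data$grp) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop") %>%
    select("chrom", "start", "end")
}

# running max of previous ends; -Inf for the first row so it opens a group
cummax_lag <- function(end) {
  c(-Inf, cummax(end)[-length(end)])
}

#' @rdname interval_merge
#' @export
interval_total <- function(x) {
  x <- interval_merge(x)
  sum(x$end - x$start)
}

empty_intervals <- function() {
  tibble(chrom = character(), start = numeric(), end = numeric())
}

as_interval_tbl <- function(x, extra = character()) {
  x <- as_tibble(x)
  need <- c("chrom", "start", "end", extra)
  if (!all(need %in% names(x))) {
    abort(paste0("interval table needs columns: ", paste(need, collapse = ", ")))
  }
  if (any(x$start >= x$end)) abort("interval start must be < end")
  x[, union(need, names(x))]
}

#' Intersect two interval tables
#'
#' Returns the normalized intersection of the regions covered by `x` and
#' `y`.
#'
#' @param x,y interval data frames.
#' @return normalized interval tibble.
#' @export
interval_intersect <- function(x, y) {
  x <- interval_merge(x)
  y <- interval_merge(y)
  out <- vector("list", 0L)
  for (ch in intersect(unique(x$chrom), unique(y$chrom))) {
    xi <- x[x$chrom == ch, ]
    yi <- y[y$chrom == ch, ]
    pieces <- purrr::map2(xi$start, xi$end, function(s, e) {
      os <- pmax(s, yi$start)
      oe <- pmin(e, yi$end)
      keep <- os < oe
      tibble(chrom = ch, start = os[keep], end = oe[keep])
    })
    out <- c(out, pieces)
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L) return(empty_intervals())
  interval_merge(res)
}

#' Subtract one interval table from another
#'
#' @param x,y interval data frames; regions of `y` are removed from `x`.
#' @return normalized interval tibble covering `x` minus `y`.
#' @export
interval_subtract <- function(x, y) {
  x <- interval_merge(x)
  y <- interval_merge(y)
  if (nrow(y) == 0L || nrow(x) == 0L) return(x)
  out <- vector("list", nrow(x))
  for (i in seq_len(nrow(x))) {
    ch <- x$chrom[i]; s <- x$start[i]; e <- x$end[i]
    yi <- y[y$chrom == ch & y$start < e & y$end > s, ]
    if (nrow(yi) == 0L) {
      out[[i]] <- tibble(chrom = ch, start = s, end = e)
      next
    }
    starts <- c(s, pmin(pmax(yi$end, s), e))
    ends <- c(pmin(pmax(yi$start, s), e), e)
    keep <- starts < ends
    out[[i]] <- tibble(chrom = ch, start = starts[keep], end = ends[keep])
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L) return(empty_intervals())
  interval_merge(res)
}

#' Read and write BED interval files
#'
#' `read_bed()` parses a 3+ column tab-separated BED file (0-based
#' half-open). Records on chromosomes absent from `genome` are rejected or
#' skipped according to `on_unknown`. `write_bed()` writes the three BED
#' columns plus any extra columns present.
#'
#' @param path file path.
#' @param genome optional `genome_layout` used to validate chromosome names.
#' @param on_unknown what to do with records on unknown chromosomes:
#'   `"error"` (default) or `"skip"`.
#' @param extra_names optional names for columns beyond the third (e.g. a
#'   state label in column 4).
#' @param normalize merge overlapping/adjacent intervals after reading
#'   (default TRUE; set FALSE to keep per-record rows, e.g. labelled
#'   segmentations).
#' @return `read_bed()`: interval tibble.
#' @export
read_bed <- function(path, genome = NULL, on_unknown = c("error", "skip"),
                     extra_names = NULL, normalize = is.null(extra_names)) {
  on_unknown <- match.arg(on_unknown)
  df <- tryCatch(
    readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                    show_col_types = FALSE, comment = "#"),
    error = function(e) abort(paste0("failed to parse BED file ", path, ": ",
                                     conditionMessage(e))))
  if (nrow(df) == 0L) return(empty_intervals())
  if (ncol(df) < 3L) abort(paste0("BED file needs >= 3 columns: ", path))
  names(df)[1:3] <- c("chrom", "start", "end")
  if (!is.null(extra_names)) {
    if (ncol(df) < 3L + length(extra_names)) {
      abort(paste0("BED file has no column ", 4L, ": ", path))
    }
    names(df)[3L + seq_along(extra_names)] <- extra_names
  }
  df <- df[, c("chrom", "start", "end", extra_names)]
  df$chrom <- as.character(df$chrom)
  if (!is.numeric(df$start) || !is.numeric(df$end)) {
    abort(paste0("non-numeric coordinates in ", path))
  }
  bad <- which(df$start >= df$end | df$start < 0)
  if (length(bad) > 0L) {
    abort(sprintf("invalid interval at line %d of %s (start >= end or negative)",
                  bad[1], path))
  }
  if (!is.null(genome)) {
    unknown <- !df$chrom %in% genome$chrom$chrom
    if (any(unknown)) {
      if (on_unknown == "error") {
        abort(sprintf("unknown chromosome at line %d of %s: %s",
                      which(unknown)[1], path, df$chrom[which(unknown)[1]]))
      }
      df <- df[!unknown, , drop = FALSE]
    }
  }
  if (normalize) interval_merge(df) else as_tibble(df)
}

#' @rdname read_bed
#' @param x interval data frame to write.
#' @export
write_bed <- function(x, path) {
  x <- as_interval_tbl(x)
  readr::write_tsv(x, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

# "chr" prefix normalization: force presence/absence of the prefix so
# datasets from different sources can be compared by exact string match.
#' Normalize chromosome-name style
#'
#' @param chrom character vector of chromosome names.
#' @param style `"chr"` to force a chr prefix, `"plain"` to strip it.
#' @return character vector.
#' @export
normalize_chrom <- function(chrom, style = c("chr", "plain")) {
  style <- match.arg(style)
  bare <- sub("^chr", "", chrom)
  if (style == "chr") paste0("chr", bare) else bare
}
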