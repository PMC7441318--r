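# Independent brute-force oracles used across the suite. These stay
# deliberately naive: enumerate everything, no shared code with the
# implementation under test.

# ROH oracle: enumerate every window, mark supported markers, merge runs.
roh_oracle <- function(g, cM, W = 100, min_hom_frac = 0.98, min_cM = 5) {
  n <- length(g)
  if (n < W) return(data.frame(first = integer(), last = integer()))
  supported <- rep(FALSE, n)
  for (s in 1:(n - W + 1)) {
    win <- g[s:(s + W - 1)]
    nm <- !is.na(win)
    if (sum(nm) == 0) next
    if (sum(win[nm] != 1) / sum(nm) >= min_hom_frac) {
      supported[s:(s + W - 1)] <- TRUE
    }
  }
  runs <- data.frame(first = integer(), last = integer())
  i <- 1
  while (i <= n) {
    if (supported[i]) {
      j <- i
      while (j < n && supported[j + 1]) j <- j + 1
      if (cM[j] - cM[i] >= min_cM) {
        runs <- rbind(runs, data.frame(first = i, last = j))
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  runs
}

# Consensus oracle: per-base caller-support depth on an integer grid.
consensus_oracle <- function(calls, min_algorithms) {
  out <- list()
  for (smp in unique(calls$sample)) {
    for (cls in unique(calls$cn[calls$sample == smp])) {
      sub <- calls[calls$sample == smp & calls$cn == cls, ]
      for (ch in unique(sub$chrom)) {
        cc <- sub[sub$chrom == ch, ]
        hi <- max(cc$end)
        depth <- integer(hi)          # depth[b] covers base b-1 (0-based)
        for (cl in unique(cc$caller)) {
          cov <- rep(FALSE, hi)
          rows <- cc[cc$caller == cl, ]
          for (r in seq_len(nrow(rows))) {
            cov[(rows$start[r] + 1):rows$end[r]] <- TRUE
          }
          depth <- depth + cov
        }
        ok <- depth >= min_algorithms
        b <- 1
        while (b <= hi) {
          if (ok[b]) {
            e <- b
            while (e < hi && ok[e + 1]) e <- e + 1
            out[[length(out) + 1]] <- data.frame(
              sample = smp, chrom = ch, start = b - 1, end = e, cn = cls)
            b <- e + 1
          } else {
            b <- b + 1
          }
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(sample = character(), chrom = character(),
                      start = numeric(), end = numeric(), cn = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$sample, res$cn, res$chrom, res$start), , drop = FALSE]
}

# All-pairs interval intersection oracle (>= 1 bp).
overlaps_oracle <- function(q, set) {
  any(set$chrom == q$chrom & set$start < q$end & set$end > q$start)
}
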