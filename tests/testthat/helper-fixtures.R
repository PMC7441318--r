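# Shared small fixtures, built in code.

toy_genome_1mb <- function() genome_layout(c(chr1 = 1e6, chr2 = 5e5))

# a one-chromosome mappable genome spanning [0, len)
flat_mappable <- function(len = 1000, chrom = "chr1") {
  g <- genome_layout(stats::setNames(len, chrom))
  build_mappable(tibble::tibble(chrom = chrom, bp = c(0, len)), g,
                 max_gap_bp = len + 1)
}

# genotype panel from a plain vector on an even cM grid
panel_from_genotypes <- function(g, cM_span = 20, chrom = "chr1",
                                 id = "s1") {
  n <- length(g)
  mk <- tibble::tibble(marker = paste0("m", seq_len(n)), chrom = chrom,
                       bp = seq(0, by = 1e5, length.out = n),
                       cM = seq(0, cM_span, length.out = n))
  genotype_panel(matrix(as.integer(g), nrow = 1,
                        dimnames = list(id, NULL)),
                 mk, tibble::tibble(id = id))
}

# random genotype vector with sprinkled hets/missing for oracle comparisons
random_panel_genotypes <- function(n, p_het = 0.02, p_miss = 0.02,
                                   p_block_het = 0.3) {
  g <- rep(0L, n)
  # alternate homozygous blocks with heterozygous-rich blocks
  pos <- 1
  while (pos <= n) {
    blk <- min(n - pos + 1, sample(50:400, 1))
    if (runif(1) < p_block_het) {
      g[pos:(pos + blk - 1)] <- sample(c(0L, 1L, 2L), blk, replace = TRUE,
                                       prob = c(0.4, 0.35, 0.25))
    } else {
      g[pos:(pos + blk - 1)] <- sample(c(0L, 2L), blk, replace = TRUE)
    }
    pos <- pos + blk
  }
  het <- runif(n) < p_het
  g[het] <- 1L
  g[runif(n) < p_miss] <- NA_integer_
  g
}

expect_same_intervals <- function(a, b) {
  a <- as.data.frame(a[order(a$chrom, a$start), c("chrom", "start", "end")])
  b <- as.data.frame(b[order(b$chrom, b$start), c("chrom", "start", "end")])
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
}
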