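test_that("the mappable genome applies the marker-gap rule", {
  g <- genome_layout(c(chr1 = 3e5))
  mp <- build_mappable(tibble::tibble(chrom = "chr1",
                                      bp = c(0, 5e4, 2e5, 2.5e5)), g,
                       max_gap_bp = 1e5)
  expect_same_intervals(mp$intervals,
                        tibble::tibble(chrom = "chr1", start = c(0, 2e5),
                                       end = c(5e4, 2.5e5)))
  expect_equal(mp$total_bp, 1e5)

  # uniform dense spacing: the full marker span
  mp2 <- build_mappable(tibble::tibble(chrom = "chr1",
                                       bp = seq(0, 3e5, by = 1e4)), g)
  expect_same_intervals(mp2$intervals,
                        tibble::tibble(chrom = "chr1", start = 0, end = 3e5))

  # all gaps too large: empty, and placement errors out downstream
  mp3 <- build_mappable(tibble::tibble(chrom = "chr1",
                                       bp = c(0, 1.5e5, 3e5)), g)
  expect_equal(mp3$total_bp, 0)
  expect_error(place_random(100, mp3, 1), "empty")

  # exclusions carved out; sex chromosomes never enter
  gx <- genome_layout(c(chr1 = 3e5, chrX = 1e5),
                      exclusions = tibble::tibble(chrom = "chr1",
                                                  start = 1e4, end = 2e4))
  mpx <- build_mappable(tibble::tibble(chrom = c("chr1", "chr1", "chrX", "chrX"),
                                       bp = c(0, 3e5, 0, 1e5)), gx,
                        max_gap_bp = 5e5)
  expect_false("chrX" %in% mpx$intervals$chrom)
  expect_equal(mpx$total_bp, 3e5 - 1e4)
})

test_that("peak calling thresholds and merges intensity bins", {
  g <- genome_layout(c(chr1 = 100))
  tr <- intensity_track(list(chr1 = c(10, 25, 30, 15)), 25, g)
  expect_same_intervals(call_peaks(tr, 20),
                        tibble::tibble(chrom = "chr1", start = 25, end = 75))
  expect_equal(nrow(call_peaks(tr, 50)), 0)
  # threshold 0: whole covered chromosome is one peak
  expect_same_intervals(call_peaks(tr, 0),
                        tibble::tibble(chrom = "chr1", start = 0, end = 100))
})

test_that("coincidence uses half-open >= 1 bp intersection", {
  pk <- tibble::tibble(chrom = "chr1", start = 200, end = 300)
  cnvs <- tibble::tibble(chrom = "chr1", start = c(100, 150, 300),
                         end = c(200, 250, 400))
  cc <- count_coincidences(cnvs, pk)
  expect_equal(cc$coincides, c(FALSE, TRUE, FALSE))  # book-ended misses
  # genome-wide peak set: everything coincides
  all_pk <- tibble::tibble(chrom = "chr1", start = 0, end = 1e6)
  expect_true(all(count_coincidences(cnvs, all_pk)$coincides))
  # matches the all-pairs oracle on random sets
  withr::local_seed(47)
  for (case in 1:5) {
    q <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 30, TRUE),
                        start = sample(0:900, 30, TRUE))
    q$end <- q$start + sample(10:120, 30, TRUE)
    p <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 10, TRUE),
                        start = sample(0:900, 10, TRUE))
    p$end <- p$start + sample(10:120, 10, TRUE)
    got <- count_coincidences(q, p)$coincides
    exp <- vapply(seq_len(nrow(q)), function(i) overlaps_oracle(q[i, ], p),
                  logical(1))
    expect_equal(got, exp, info = paste("case", case))
  }
})

test_that("random placement is uniform over feasible starts", {
  # two mappable intervals of different sizes; length-10 interval has
  # 92 + 41 = 133 feasible starts
  g <- genome_layout(c(chr1 = 500))
  mp <- structure(list(
    intervals = tibble::tibble(chrom = "chr1", start = c(0, 300),
                               end = c(101, 350)),
    total_bp = 151, max_gap_bp = NA, n_markers = NA),
    class = "mappable_genome")
  pl <- place_random(10, mp, n = 50000, seed = 53)
  starts <- as.numeric(pl$start)
  feasible <- c(0:91, 300:340)
  expect_true(all(starts %in% feasible))
  tab <- table(factor(starts, levels = feasible))
  chi <- stats::chisq.test(tab)
  expect_gt(chi$p.value, 0.001)
})

test_that("replicate mean matches the single-peak brute-force probability", {
  mp <- flat_mappable(1000)
  pk <- tibble::tibble(chrom = "chr1", start = 400, end = 500)
  cnv <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
  fit <- mc_overlap_test(cnv, NULL, pk, mp, n_replicates = 5000, seed = 59)
  p0 <- 199 / 901   # all 901 placements enumerated: starts 301..499 hit
  se <- stats::sd(fit$replicate_counts$affected) / sqrt(5000)
  expect_lt(abs(fit$affected_expected - p0), 3 * se)
})

test_that("joint p-value respects its bounds and saturates when peaks cover everything", {
  mp <- flat_mappable(10000)
  pk <- tibble::tibble(chrom = "chr1", start = 0, end = 10000)
  aff <- tibble::tibble(chrom = "chr1", start = c(0, 5000), end = c(100, 5100))
  una <- tibble::tibble(chrom = "chr1", start = 2000, end = 2100)
  fit <- mc_overlap_test(aff, una, pk, mp, n_replicates = 500, seed = 61)
  expect_equal(fit$p_joint, 1)
  expect_equal(fit$affected_expected, 2)
  expect_equal(fit$unaffected_observed, 1)

  pk2 <- tibble::tibble(chrom = "chr1", start = 4000, end = 4500)
  fit2 <- mc_overlap_test(aff, una, pk2, mp, n_replicates = 400, seed = 62)
  expect_gte(fit2$p_joint, 1 / 401)
  expect_lte(fit2$p_joint, 1)
  # joint replicate count can never exceed either marginal count
  expect_lte(fit2$p_joint, fit2$p_enrichment + 1 / 401)
  expect_lte(fit2$p_joint, fit2$p_depletion + 1 / 401)
  # a CNV longer than every mappable interval errors by name
  too_long <- tibble::tibble(chrom = "chr1", start = 0, end = 20000)
  expect_error(mc_overlap_test(too_long, NULL, pk2, mp, 10),
               "fits in no mappable interval")
})

test_that("tidy/glance/autoplot expose the Monte-Carlo result", {
  mp <- flat_mappable(5000)
  pk <- tibble::tibble(chrom = "chr1", start = 1000, end = 1500)
  aff <- tibble::tibble(chrom = "chr1", start = c(1100, 3000),
                        end = c(1200, 3100))
  fit <- mc_overlap_test(aff, NULL, pk, mp, n_replicates = 200, seed = 63)
  td <- tidy(fit)
  expect_equal(td$group, c("affected", "unaffected"))
  expect_equal(td$observed[1], fit$affected_observed)
  gl <- glance(fit)
  expect_equal(gl$p_joint, fit$p_joint)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("chromatin-state testing filters exonic CNVs and honors the state subset", {
  g <- genome_layout(c(chr1 = 2e5))
  mp <- build_mappable(tibble::tibble(chrom = "chr1", bp = c(0, 2e5)), g,
                       max_gap_bp = 3e5)
  alphabet <- chromhmm15_states()
  labs <- rep(match("Quies", alphabet), 1000)   # 200 bp bins over 200 kb
  labs[101:200] <- match("Enh", alphabet)       # enhancer block [20k, 40k)
  st <- state_track(list(chr1 = labs), 200, alphabet, g)
  genes <- gene_models(
    tibble::tibble(gene = "G1", chrom = "chr1", strand = "+",
                   tx_start = 1.5e5, tx_end = 1.6e5, cds_start = 1.5e5,
                   cds_end = 1.6e5, coding = TRUE),
    tibble::tibble(gene = "G1", chrom = "chr1", start = 1.5e5, end = 1.52e5))
  aff <- tibble::tibble(chrom = "chr1",
                        start = c(2.5e4, 1.49e5), end = c(3e4, 1.55e5))
  res <- chromhmm_overlap(aff, NULL, list(E1 = st), mp,
                          states = "Enh", genes = genes,
                          noncoding_only = TRUE, n_replicates = 300,
                          seed = 67)
  # the exonic CNV is excluded, leaving one enhancer-overlapping CNV
  expect_equal(res$affected_observed, 1)
  # full alphabet: every bin carries a state, every CNV coincides, joint p = 1
  res_all <- chromhmm_overlap(aff, NULL, list(E1 = st), mp,
                              states = alphabet, n_replicates = 100,
                              seed = 68)
  expect_equal(res_all$affected_observed, 2)
  expect_equal(res_all$p_joint, 1)
  # mismatched bin grids error
  st2 <- state_track(list(chr1 = rep(1L, 500)), 400, alphabet, g)
  expect_error(chromhmm_overlap(aff, NULL, list(a = st, b = st2), mp),
               "bin widths")
})

test_that("a planted enhancer bias drives the joint p to its attainable bound", {
  g <- genome_layout(c(chr1 = 5e6, chr2 = 5e6))
  mp <- build_mappable(tibble::tibble(chrom = c("chr1", "chr1", "chr2", "chr2"),
                                      bp = c(0, 5e6, 0, 5e6)), g,
                       max_gap_bp = 6e6)
  tk <- sim_tracks(g, 0.05, seed = 71, make_tracks = FALSE)
  sets <- sim_case_control_cnvs(15, 5, lengths = rep(1e4, 15),
                                overlap_bias = 1, peaks = tk$peaks,
                                mappable = mp, seed = 72)
  n_rep <- 400
  fit <- mc_overlap_test(sets$affected, sets$unaffected, tk$peaks, mp,
                         n_replicates = n_rep, seed = 73)
  expect_equal(fit$affected_observed, 15)
  expect_lt(fit$p_enrichment, 0.05)
  expect_gte(fit$p_joint, 1 / (n_rep + 1))
})

test_that("tissue unions pool selected-state bins across epigenomes", {
  g <- genome_layout(c(chr1 = 1e5))
  mp <- build_mappable(tibble::tibble(chrom = "chr1", bp = c(0, 1e5)), g,
                       max_gap_bp = 2e5)
  alphabet <- chromhmm15_states()
  mk_track <- function(from, to) {
    labs <- rep(match("Quies", alphabet), 500)
    labs[from:to] <- match("Enh", alphabet)
    state_track(list(chr1 = labs), 200, alphabet, g)
  }
  tr <- list(e1 = mk_track(1, 50), e2 = mk_track(200, 260))
  aff <- tibble::tibble(chrom = "chr1", start = 4.5e4, end = 4.7e4)
  res <- chromhmm_overlap(aff, NULL, tr, mp, states = "Enh",
                          tissues = list(brain = c("e1", "e2")),
                          n_replicates = 100, seed = 74)
  expect_equal(nrow(res), 3)
  un <- res[res$kind == "tissue_union", ]
  # the CNV hits e2's enhancer block only; the union inherits it
  expect_equal(res$affected_observed[res$profile == "e1"], 0)
  expect_equal(res$affected_observed[res$profile == "e2"], 1)
  expect_equal(un$affected_observed, 1)
})
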