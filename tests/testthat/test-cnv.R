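ccall <- function(caller, start, end, sample = "s1", chrom = "chr1",
                  cn = 0L, probes = 10) {
  tibble::tibble(sample = sample, caller = caller, chrom = chrom,
                 start = start, end = end, cn = cn, probes = probes)
}

test_that("identical calls from all callers yield one full-support consensus", {
  calls <- dplyr::bind_rows(lapply(c("A", "B", "C", "D"),
                                   ccall, start = 100, end = 200))
  cons <- build_consensus(calls, min_algorithms = 3)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$start, 100)
  expect_equal(cons$end, 200)
  expect_equal(cons$n_callers, 4)
})

test_that("consensus is the depth->=k region of staggered calls", {
  calls <- dplyr::bind_rows(ccall("A", 100, 200), ccall("B", 105, 195),
                            ccall("C", 110, 210))
  cons <- build_consensus(calls, min_algorithms = 3)
  expect_equal(cons$start, 110)
  expect_equal(cons$end, 195)
  expect_equal(cons$min_probes, 10)
})

test_that("copy-number classes are never pooled in consensus", {
  calls <- dplyr::bind_rows(ccall("A", 100, 200, cn = 0L),
                            ccall("B", 100, 200, cn = 0L),
                            ccall("C", 100, 200, cn = 1L),
                            ccall("D", 100, 200, cn = 1L))
  expect_equal(nrow(build_consensus(calls, min_algorithms = 3)), 0)
  expect_equal(nrow(build_consensus(calls, min_algorithms = 2)), 2)
})

test_that("consensus equals the per-base depth oracle on random call sets", {
  withr::local_seed(29)
  for (case in 1:20) {
    n <- sample(3:12, 1)
    calls <- tibble::tibble(
      sample = sample(c("s1", "s2"), n, replace = TRUE),
      caller = sample(c("A", "B", "C", "D"), n, replace = TRUE),
      chrom = "chr1",
      start = sample(0:150, n, replace = TRUE),
      cn = sample(c(0L, 1L), n, replace = TRUE),
      probes = sample(5:20, n, replace = TRUE))
    calls$end <- calls$start + sample(10:80, n, replace = TRUE)
    k <- sample(2:3, 1)
    if (length(unique(calls$caller)) < k) {
      expect_error(build_consensus(calls, min_algorithms = k),
                   "distinct caller")
      next
    }
    got <- build_consensus(calls, min_algorithms = k)
    exp <- consensus_oracle(calls, k)
    expect_equal(nrow(got), nrow(exp), info = paste("case", case))
    if (nrow(got) > 0) {
      expect_equal(got$start, exp$start, info = paste("case", case))
      expect_equal(got$end, exp$end, info = paste("case", case))
      expect_equal(got$cn, exp$cn, info = paste("case", case))
    }
  }
})

test_that("raising min_algorithms never enlarges the consensus set", {
  withr::local_seed(31)
  for (case in 1:5) {
    n <- 10
    calls <- tibble::tibble(
      sample = "s1", caller = sample(c("A", "B", "C", "D"), n, replace = TRUE),
      chrom = "chr1", start = sample(0:100, n, replace = TRUE),
      cn = 0L, probes = 10)
    calls$end <- calls$start + sample(20:60, n, replace = TRUE)
    c2 <- build_consensus(calls, min_algorithms = 2)
    c3 <- build_consensus(calls, min_algorithms = 3)
    # every depth>=3 base is a depth>=2 base
    expect_lte(interval_total(c3[, c("chrom", "start", "end")]),
               interval_total(c2[, c("chrom", "start", "end")]))
    if (nrow(c3) > 0) {
      expect_equal(interval_total(interval_intersect(
        c3[, c("chrom", "start", "end")], c2[, c("chrom", "start", "end")])),
        interval_total(c3[, c("chrom", "start", "end")]))
    }
  }
  expect_error(build_consensus(ccall("A", 1, 2), min_algorithms = 3),
               "distinct caller")
})

test_that("rarity requires >50% same-class catalog overlap", {
  q <- tibble::tibble(sample = "s1", chrom = "chr1", start = 110, end = 190,
                      cn = 0L)
  # empty catalog: rare
  r0 <- classify_rarity(q, tibble::tibble(chrom = character(),
                                          start = numeric(), end = numeric(),
                                          cn = integer()))
  expect_equal(r0$rarity, "rare")
  # same locus, wrong class (CNV1 never CNV0): still rare
  cat1 <- tibble::tibble(chrom = "chr1", start = 100, end = 200, cn = 1L)
  expect_equal(classify_rarity(q, cat1)$rarity, "rare")
  # same class fully covering: common
  cat0 <- dplyr::mutate(cat1, cn = 0L)
  expect_equal(classify_rarity(q, cat0)$rarity, "common")
  # exactly 50% overlap is NOT common (strict inequality)
  q2 <- tibble::tibble(chrom = "chr1", start = 0, end = 100e3, cn = 0L)
  cat50 <- tibble::tibble(chrom = "chr1", start = 50e3, end = 500e3, cn = 0L)
  expect_equal(classify_rarity(q2, cat50)$rarity, "rare")
  cat51 <- tibble::tibble(chrom = "chr1", start = 49999, end = 500e3, cn = 0L)
  expect_equal(classify_rarity(q2, cat51)$rarity, "common")
})

test_that("adding catalog entries never converts common to rare", {
  withr::local_seed(37)
  q <- tibble::tibble(chrom = "chr1", start = sample(0:1000, 20),
                      cn = 0L)
  q$end <- q$start + sample(50:300, 20, replace = TRUE)
  cat_small <- tibble::tibble(chrom = "chr1", start = sample(0:1000, 10),
                              cn = 0L)
  cat_small$end <- cat_small$start + sample(50:300, 10, replace = TRUE)
  extra <- tibble::tibble(chrom = "chr1", start = sample(0:1000, 10), cn = 0L)
  extra$end <- extra$start + sample(50:300, 10, replace = TRUE)
  r1 <- classify_rarity(q, cat_small)
  r2 <- classify_rarity(q, dplyr::bind_rows(cat_small, extra))
  expect_true(all(r2$rarity[r1$rarity == "common"] == "common"))
})

test_that("de novo flags follow the lenient-parent rule", {
  ped <- pedigree(tibble::tibble(id = c("fa", "mo", "kid"),
                                 father = c(NA, NA, "fa"),
                                 mother = c(NA, NA, "mo")))
  child <- tibble::tibble(sample = "kid", chrom = "chr1", start = 1000,
                          end = 2000, cn = 1L)
  none <- tibble::tibble(sample = character(), caller = character(),
                         chrom = character(), start = numeric(),
                         end = numeric(), cn = integer(), probes = numeric())
  r <- flag_de_novo(child, none, ped, genotyped = c("fa", "mo", "kid"))
  expect_equal(r$inheritance, "de novo")
  # a 10%-overlap single-caller parent call of the same direction inherits
  father_call <- ccall("A", 1900, 3000, sample = "fa", cn = 1L)
  r2 <- flag_de_novo(child, father_call, ped, genotyped = c("fa", "mo", "kid"))
  expect_equal(r2$inheritance, "inherited")
  # opposite direction does not count as parental evidence
  father_gain <- ccall("A", 1900, 3000, sample = "fa", cn = 3L)
  r3 <- flag_de_novo(child, father_gain, ped, genotyped = c("fa", "mo", "kid"))
  expect_equal(r3$inheritance, "de novo")
  # ungenotyped parent: unknown
  r4 <- flag_de_novo(child, none, ped, genotyped = c("mo", "kid"))
  expect_equal(r4$inheritance, "unknown")
})

test_that("de novo labels match planted truth in jitter-free trios", {
  withr::local_seed(41)
  ped_rows <- list()
  truth <- list()
  parent_truth <- list()
  for (f in 1:10) {
    fa <- paste0("fa", f); mo <- paste0("mo", f); kid <- paste0("kid", f)
    ped_rows[[f]] <- tibble::tibble(id = c(fa, mo, kid),
                                    father = c(NA, NA, fa),
                                    mother = c(NA, NA, mo))
    s <- f * 1e5
    transmitted <- f <= 5   # first five families inherit, rest are de novo
    truth[[f]] <- tibble::tibble(sample = kid, chrom = "chr1",
                                 start = s, end = s + 2e4, cn = 1L,
                                 probes = 10, de_novo = !transmitted)
    if (transmitted) {
      parent_truth[[f]] <- tibble::tibble(sample = fa, chrom = "chr1",
                                          start = s, end = s + 2e4, cn = 1L,
                                          probes = 10)
    }
  }
  ped <- pedigree(dplyr::bind_rows(ped_rows))
  spec <- default_caller_spec(sensitivity = 1, jitter_sd = 0, fp_rate = 0)
  parent_calls <- sim_caller_calls(dplyr::bind_rows(parent_truth), spec,
                                   seed = 42)
  kid_cnvs <- dplyr::bind_rows(truth)
  r <- flag_de_novo(kid_cnvs, parent_calls, ped,
                    genotyped = ped$id)
  expect_equal(r$inheritance == "de novo", kid_cnvs$de_novo)
})

test_that("the exact one-sided burden test matches fisher.test on random tables", {
  expect_equal(burden_test(0, 10, 0, 10)$p_value, 1.0)
  withr::local_seed(43)
  for (i in 1:200) {
    n1 <- sample(5:200, 1); n2 <- sample(5:200, 1)
    a <- sample(0:n1, 1); b <- sample(0:n2, 1)
    p_pkg <- burden_test(a, n1, b, n2)$p_value
    tab <- matrix(c(a, n1 - a, b, n2 - b), 2)
    p_ref <- stats::fisher.test(tab, alternative = "greater")$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-9)
  }
  expect_error(burden_test(0, 0, 0, 10), "positive")
})

test_that("the extreme 5/5 vs 0/1000 table matches its closed form", {
  p <- burden_test(5, 5, 0, 1000)$p_value
  expect_equal(p, 1 / choose(1005, 5), tolerance = 1e-12)
  expect_lt(p, 1e-10)
})

test_that("selection cascade attributes losses to the correct stage", {
  samples <- tibble::tibble(
    id = c(paste0("a", 1:6), paste0("u", 1:4)),
    family = c(paste0("f", 1:6), paste0("f", 1:4)),
    affected = rep(c(TRUE, FALSE), c(6, 4)))
  mk_ev <- function(sample, cn, n_callers = 4, min_probes = 10,
                    start = 1e4, end = 5e4) {
    tibble::tibble(sample = sample, chrom = "chr1", start = start, end = end,
                   cn = cn, n_callers = n_callers,
                   callers = "A,B,C,D", min_probes = min_probes)
  }
  consensus <- dplyr::bind_rows(
    mk_ev("a1", 0L),                              # survives everything
    mk_ev("a2", 0L, start = 2e5, end = 3e5),      # common: removed by catalog
    mk_ev("a3", 1L),                              # not CNV0
    mk_ev("a4", 0L, n_callers = 2),               # insufficient callers
    mk_ev("a5", 0L, min_probes = 3),              # insufficient probes
    mk_ev("a6", 0L),                              # excluded family
    mk_ev("u1", 0L, start = 7e5, end = 8e5))
  catalog <- tibble::tibble(chrom = "chr1", start = 2e5, end = 3e5, cn = 0L)
  sel <- select_cnv0(consensus, catalog, samples,
                     excluded_families = "f6")
  cascade <- sel$cascade
  expect_equal(cascade$n_events, c(6, 5, 3, 2))
  expect_equal(sel$events$sample, c("a1", "u1"))
  # the common event is removed exactly at the rarity stage
  expect_true("a2" %in% consensus$sample)
  expect_equal(cascade$n_events[3] - cascade$n_events[4], 1)
  # a cohort with no CNV0 calls: empty from stage 2 on
  no0 <- dplyr::filter(consensus, cn != 0)
  sel2 <- select_cnv0(no0, catalog, samples)
  expect_equal(sel2$cascade$n_events[-1], c(0, 0, 0))
})

test_that("carrier percentages and burden p reproduce on a planted cohort", {
  samples <- tibble::tibble(id = paste0("s", 1:330),
                            family = paste0("f", 1:330),
                            affected = rep(c(TRUE, FALSE), c(199, 131)))
  carriers <- c(paste0("s", 1:25), paste0("s", 200:204))
  events <- tibble::tibble(sample = carriers, chrom = "chr1",
                           start = 1e4, end = 2e4, cn = 0L,
                           n_callers = 4, callers = "A,B,C,D",
                           min_probes = 10)
  sel <- select_cnv0(events, tibble::tibble(chrom = character(),
                                            start = numeric(),
                                            end = numeric(), cn = integer()),
                     samples)
  final <- sel$cascade[nrow(sel$cascade), ]
  expect_equal(final$affected_rate_pct, 100 * 25 / 199)   # 12.56%, "12.5%"
  expect_equal(final$unaffected_rate_pct, 100 * 5 / 131)  # 3.82%, "3.8%"
  expect_equal(final$p_one_sided,
               stats::fisher.test(matrix(c(25, 174, 5, 126), 2),
                                  alternative = "greater")$p.value,
               tolerance = 1e-9)
  expect_lt(final$p_one_sided, 0.01)
})
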