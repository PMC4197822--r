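sorted_ev_table <- function(evidence) {
  tab <- evidence_table(evidence)
  data.table::setorderv(tab[, k := svprob:::chrom_rank_key(l_chrom)],
                        c("k", "l_start"))
  tab[, k := NULL]
  tab
}

test_that("sweep clustering groups intersecting same-variety evidence", {
  four <- lapply(1:4, function(i)
    uniform_evidence(100 + i, 300 + i, 1000 + i, 1200 + i))
  cl <- sweep_cluster(sorted_ev_table(four))
  expect_length(cl, 1)
  expect_length(cl[[1]]$idx, 4)

  apart <- c(four, list(uniform_evidence(1e6, 1e6 + 200, 2e6, 2e6 + 200)))
  expect_length(sweep_cluster(sorted_ev_table(apart)), 2)

  mixed <- list(uniform_evidence(100, 300, 1000, 1200, "DELETION"),
                uniform_evidence(100, 300, 1000, 1200, "INVERSION"))
  expect_length(sweep_cluster(sorted_ev_table(mixed)), 2)

  ## both sides must intersect: shared left, disjoint right
  lr <- list(uniform_evidence(100, 300, 1000, 1200),
             uniform_evidence(100, 300, 5000, 5200))
  expect_length(sweep_cluster(sorted_ev_table(lr)), 2)
})

test_that("unsorted evidence streams are rejected", {
  tab <- evidence_table(list(uniform_evidence(5000, 5200, 9000, 9200),
                             uniform_evidence(100, 300, 1000, 1200)))
  expect_error(sweep_cluster(tab), "not sorted")
})

test_that("sweep equals the batch transitive-closure oracle (property)", {
  set.seed(47)
  for (trial in 1:40) {
    n <- sample(10:50, 1)
    evidence <- lapply(seq_len(n), function(i) {
      ls <- sample.int(20000, 1)
      rs <- ls + 3000 + sample.int(2000, 1)
      uniform_evidence(ls, ls + sample.int(400, 1),
                       rs, rs + sample.int(400, 1),
                       variety = sample(c("DELETION", "INVERSION"), 1))
    })
    tab <- sorted_ev_table(evidence)
    got <- lapply(sweep_cluster(tab), function(cl) sort(cl$idx))
    want <- lapply(oracle_clusters(tab), sort)
    expect_setequal(lapply(got, paste, collapse = ","),
                    lapply(want, paste, collapse = ","))
  }
})

test_that("clustering is independent of stream order (property)", {
  set.seed(53)
  evidence <- lapply(1:30, function(i) {
    ls <- sample.int(5000, 1)
    uniform_evidence(ls, ls + 300, ls + 2000, ls + 2300)
  })
  base <- lapply(sweep_cluster(sorted_ev_table(evidence)),
                 function(cl) sort(cl$l_start))
  for (perm in 1:5) {
    tab <- sorted_ev_table(sample(evidence))
    got <- lapply(sweep_cluster(tab), function(cl) sort(cl$l_start))
    expect_setequal(got, base)
  }
})

test_that("thresholds: total weight, per-sample minima, required samples", {
  mk <- function(weights, samples) list(weights = weights, samples = samples)
  t4 <- calling_thresholds(min_total_weight = 4)
  expect_true(apply_thresholds(mk(rep(1, 4), rep("S1", 4)), t4))
  expect_false(apply_thresholds(mk(rep(1, 3), rep("S1", 3)), t4))
  ## two reads plus a weight-2 prior reach the threshold
  expect_true(apply_thresholds(mk(c(1, 1, 2), c("S1", "S1", "PRIOR")), t4))
  ## trio rule: >= 4 from one individual, >= 1 from the child
  trio <- calling_thresholds(4,
                             per_sample_min = c(child = 4, mom = 4, dad = 4),
                             required_samples = "child")
  expect_false(apply_thresholds(mk(rep(1, 5), rep("dad", 5)), trio))
  expect_true(apply_thresholds(mk(c(rep(1, 5), 1),
                                  c(rep("dad", 5), "child")), trio))
  expect_false(apply_thresholds(mk(c(2, 2, 1), c("dad", "mom", "child")),
                                trio))
})

test_that("excluded-region filtering uses half-open alignment overlap", {
  ev <- list(uniform_evidence(100, 800, 2000, 2700),
             uniform_evidence(5100, 5800, 7000, 7700))
  tab <- sorted_ev_table(ev)
  regions <- data.table::data.table(chrom = "chr1", start = 0, end = 1000)
  expect_equal(nrow(filter_excluded(tab, regions)), 1)
  expect_equal(nrow(filter_excluded(tab, NULL)), 2)
  ## abutting (half-open adjacent) alignment is kept
  reg2 <- data.table::data.table(chrom = "chr1", start = 0, end = 5100)
  expect_equal(nrow(filter_excluded(tab, reg2)), 1)
})

test_that("depth-based exclusion: 2*mode + 3*sd rule and chrM", {
  depth <- data.table::data.table(
    chrom = c(rep("chr1", 3), "chrM"),
    start = c(0, 1000, 1100, 0),
    end = c(1000, 1100, 2000, 16000),
    depth = c(50, 200, 50, 30))
  ## mode 50; weighted population sd from the same numbers
  d <- rep(depth$depth[1:3], depth$end[1:3] - depth$start[1:3])
  thr <- 2 * 50 + 3 * sqrt(mean((d - mean(d))^2))
  expect_true(200 > thr)
  ex <- compute_excluded_regions(depth)
  expect_true(any(ex$chrom == "chr1" & ex$start == 1000 & ex$end == 1100))
  expect_true(any(ex$chrom == "chrM" & ex$start == 0 & ex$end == 16000))

  flat <- data.table::data.table(chrom = "chr1", start = 0, end = 1e6,
                                 depth = 50)
  expect_equal(nrow(compute_excluded_regions(flat)), 0)   # 50 < 100
  expect_error(compute_excluded_regions(flat[0]), "empty")
})

test_that("end-to-end: one deletion, idealized 20X alignments, mw = 4", {
  x <- small_deletion_sim(n_del = 1, coverage = 20, seed = 11)
  spec <- sample_spec("S1", pe = list(alignments = x$aln),
                      sr = list(alignments = x$aln))
  calls <- call_structural_variants(spec, calling_thresholds(4),
                                    chrom_lengths = c(chr1 = 1e6),
                                    verbose = FALSE)
  expect_length(calls, 1)
  expect_equal(calls[[1]]$variety, "DELETION")
  tr <- x$sim$truth
  expect_true(calls[[1]]$ci95_left[1] <= tr$pos1 &&
                tr$pos1 <= calls[[1]]$ci95_left[2])
  expect_true(calls[[1]]$ci95_right[1] <= tr$pos2 &&
                tr$pos2 <= calls[[1]]$ci95_right[2])

  ## a variant-free genome yields no calls
  x0 <- small_deletion_sim(n_del = 0, coverage = 10, seed = 12)
  calls0 <- call_structural_variants(
    sample_spec("S1", pe = list(alignments = x0$aln),
                sr = list(alignments = x0$aln)),
    calling_thresholds(4), chrom_lengths = c(chr1 = 1e6), verbose = FALSE)
  expect_length(calls0, 0)
})

test_that("support pools across samples without per-sample rules", {
  ## the same variant seen with 2 pieces of evidence in each of 2 samples
  mk <- function(sid) list(
    uniform_evidence(100, 400, 1000, 1300, sample_id = sid),
    uniform_evidence(150, 450, 1050, 1350, sample_id = sid))
  sA <- sample_spec("A", bedpe = list(evidence = mk("A")))
  sB <- sample_spec("B", bedpe = list(evidence = mk("B")))
  calls <- call_structural_variants(list(sA, sB), calling_thresholds(4),
                                    verbose = FALSE)
  expect_length(calls, 1)
  expect_equal(calls[[1]]$total_weight, 4)
  expect_equal(sort(names(calls[[1]]$per_sample_support)), c("A", "B"))
  ## either sample alone stays below threshold
  expect_length(call_structural_variants(sA, calling_thresholds(4),
                                         verbose = FALSE), 0)
})

test_that("calls are monotone in the evidence threshold (property)", {
  x <- small_deletion_sim(n_del = 8, coverage = 6, seed = 21)
  spec <- sample_spec("S1", pe = list(alignments = x$aln),
                      sr = list(alignments = x$aln))
  key <- function(calls) vapply(calls, function(c)
    sprintf("%s:%d", c$variety, c$max_left), "")
  prev <- NULL
  for (mw in c(3, 4, 5, 6, 8)) {
    calls <- call_structural_variants(spec, calling_thresholds(mw),
                                      chrom_lengths = c(chr1 = 1e6),
                                      verbose = FALSE)
    if (!is.null(prev)) expect_true(all(key(calls) %in% prev))
    prev <- key(calls)
  }
})

test_that("generic priors corroborate but never remove calls", {
  x <- small_deletion_sim(n_del = 4, coverage = 4, seed = 31)
  base_spec <- sample_spec("S1", pe = list(alignments = x$aln),
                           sr = list(alignments = x$aln))
  base <- call_structural_variants(base_spec, calling_thresholds(4),
                                   chrom_lengths = c(chr1 = 1e6),
                                   verbose = FALSE)
  prior_ev <- lapply(seq_len(nrow(x$sim$truth)), function(i) {
    tr <- x$sim$truth[i]
    bp_evidence(uniform_interval("chr1", tr$pos1 - 100, tr$pos1 + 100),
                uniform_interval("chr1", tr$pos2 - 100, tr$pos2 + 100),
                "DELETION", weight = 2, sample_id = "S1",
                source = "GENERIC")
  })
  with_spec <- sample_spec("S1", pe = list(alignments = x$aln),
                           sr = list(alignments = x$aln),
                           bedpe = list(evidence = prior_ev))
  with_prior <- call_structural_variants(with_spec, calling_thresholds(4),
                                         chrom_lengths = c(chr1 = 1e6),
                                         verbose = FALSE)
  expect_gte(length(with_prior), length(base))
  ## every base call persists with at least its original weight
  for (b in base) {
    m <- Filter(function(c) c$variety == b$variety &&
                  abs(c$max_left - b$max_left) < 500, with_prior)
    expect_gte(length(m), 1)
    expect_gte(m[[1]]$total_weight, b$total_weight)
  }
})
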