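test_that("interval intersection uses half-open semantics", {
  a <- list(chrom = "chr1", start = 100, end = 200)
  expect_true(intervals_intersect(a, list(chrom = "chr1", start = 150,
                                          end = 250)))
  expect_false(intervals_intersect(a, list(chrom = "chr1", start = 200,
                                           end = 300)))
  expect_false(intervals_intersect(a, list(chrom = "chr2", start = 100,
                                           end = 200)))
})

test_that("liberal merge tracks floored means of member bounds", {
  e1 <- uniform_evidence(100, 200, 1000, 1100)
  cl <- new_cluster(e1)
  b <- cluster_bounds(cl)
  expect_equal(b$left, c(100, 200))    # singleton: identity
  expect_equal(b$right, c(1000, 1100))

  cl <- merge_into_cluster(cl, uniform_evidence(110, 210, 1010, 1110))
  expect_equal(cluster_bounds(cl)$left[1], 105)   # mean of {100, 110}

  cl <- merge_into_cluster(cl, uniform_evidence(130, 230, 1030, 1130))
  expect_equal(cluster_bounds(cl)$left[1], 113)   # floor(340 / 3)
})

test_that("merge contract violations are rejected", {
  cl <- new_cluster(uniform_evidence(100, 200, 1000, 1100))
  expect_error(
    merge_into_cluster(cl, uniform_evidence(100, 200, 1000, 1100,
                                            variety = "INVERSION")),
    "variety")
  expect_error(
    merge_into_cluster(cl, uniform_evidence(5000, 5100, 9000, 9100)),
    "intersect")
})

test_that("merged bounds stay within member min/max (property)", {
  set.seed(101)
  for (trial in 1:50) {
    members <- random_overlapping_cluster(sample(2:8, 1))
    cl <- new_cluster(members[[1]])
    for (e in members[-1]) cl <- merge_into_cluster(cl, e)
    b <- cluster_bounds(cl)
    ls <- vapply(members, function(e) e$left$start, 0)
    le <- vapply(members, function(e) e$left$end, 0)
    expect_gte(b$left[1], min(ls)); expect_lte(b$left[1], max(ls))
    expect_gte(b$left[2], min(le)); expect_lte(b$left[2], max(le))
  }
})

test_that("trim_distribution removes low ends greedily", {
  u <- bp_interval("chr1", 0, 10, rep(0.1, 10))
  t1 <- trim_distribution(u, keep = 1.0)
  expect_equal(c(t1$start, t1$end), c(0, 10))     # nothing removable

  p <- c(.001, .009, .49, .49, .009, .001)
  t2 <- trim_distribution(bp_interval("chr1", 0, 6, p), keep = 0.998)
  expect_equal(c(t2$start, t2$end), c(1, 5))      # both .001 ends removed
  expect_equal(sum(t2$p), 1)

  t3 <- trim_distribution(bp_interval("chr1", 0, 3, c(.2, .4, .4)),
                          keep = 0)
  expect_equal(c(t3$start, t3$end), c(1, 2))      # leftmost argmax
  t4 <- trim_distribution(u, keep = 0)
  expect_equal(c(t4$start, t4$end), c(0, 1))      # uniform tie -> leftmost
})

test_that("trimmed support is non-increasing in removed mass (property)", {
  set.seed(7)
  for (trial in 1:20) {
    n <- sample(5:40, 1)
    p <- runif(n); p <- p / sum(p)
    iv <- bp_interval("chr1", 0, n, p)
    widths <- vapply(c(1, 0.999, 0.99, 0.9, 0.5, 0), function(k) {
      t <- trim_distribution(iv, k); t$end - t$start
    }, 0)
    expect_true(all(diff(widths) <= 0))
  }
})

test_that("confidence_interval matches the cumulative-tail oracle", {
  pm <- bp_interval("chr1", 42, 43, 1)
  expect_equal(confidence_interval(pm), c(42, 43))          # point mass

  u <- bp_interval("chr1", 0, 100, rep(0.01, 100))
  expect_equal(confidence_interval(u), c(2, 98))            # central 96

  tri <- c(1:10, 9:1); tri <- tri / sum(tri)
  ci <- confidence_interval(bp_interval("chr1", 0, 19, tri))
  expect_equal(ci[1] - 0, 19 - ci[2])                        # symmetric

  set.seed(13)
  for (trial in 1:25) {
    n <- sample(3:60, 1)
    p <- runif(n); p <- p / sum(p)
    iv <- bp_interval("chr1", 10, 10 + n, p)
    expect_equal(confidence_interval(iv), oracle_ci(p, 10))
  }
})

test_that("max_position returns the leftmost argmax", {
  expect_equal(max_position(bp_interval("chr1", 5, 8, c(.1, .8, .1))), 6)
  expect_equal(max_position(uniform_interval("chr1", 30, 40)), 30)
  expect_equal(max_position(bp_interval("chr1", 0, 3, c(.2, .4, .4))), 1)
})

test_that("finalize_product handles identity, overlap and fallback", {
  single <- new_cluster(uniform_evidence(0, 10, 100, 110))
  s <- finalize_product(single, trim_keep = 1)
  expect_equal(c(s$left$start, s$left$end), c(0, 10))
  expect_equal(s$left$p, rep(0.1, 10))

  two <- list(uniform_evidence(0, 10, 100, 110),
              uniform_evidence(5, 15, 100, 110))
  s2 <- finalize_product(two, trim_keep = 1)
  expect_equal(c(s2$left$start, s2$left$end), c(5, 10))
  expect_equal(s2$left$p, rep(0.2, 5))

  ## disjoint left intervals: fallback keeps the leftmost peak's members
  disjoint <- list(uniform_evidence(0, 10, 100, 110),
                   uniform_evidence(20, 30, 100, 110))
  s3 <- finalize_product(disjoint, trim_keep = 1)
  expect_equal(c(s3$left$start, s3$left$end), c(0, 10))
  expect_equal(s3$left$p, rep(0.1, 10))
  expect_equal(s3$n_evidence, 1)
})

test_that("finalize_sum mixes member distributions positionwise", {
  single <- finalize_sum(list(uniform_evidence(0, 10, 100, 110)),
                         trim_keep = 1)
  expect_equal(single$left$p, rep(0.1, 10))

  two <- finalize_sum(list(uniform_evidence(0, 10, 100, 110),
                           uniform_evidence(5, 15, 100, 110)),
                      trim_keep = 1)
  expect_equal(c(two$left$start, two$left$end), c(0, 15))
  expect_equal(two$left$p,
               c(rep(.05, 5), rep(.1, 5), rep(.05, 5)))   # central plateau

  disj <- finalize_sum(list(uniform_evidence(0, 10, 100, 110),
                            uniform_evidence(20, 30, 100, 110)),
                       trim_keep = 1)
  expect_equal(c(disj$left$start, disj$left$end), c(0, 30))  # no fallback
})

test_that("product equals the brute-force oracle on random clusters", {
  set.seed(23)
  for (trial in 1:60) {
    members <- random_overlapping_cluster(sample(2:10, 1))
    call <- finalize_product(members, trim_keep = 1)
    orc <- oracle_product(members)
    expect_equal(call$left$start, orc$left$start)
    expect_lt(max(abs(call$left$p - orc$left$p)), 1e-9)
    expect_lt(max(abs(call$right$p - orc$right$p)), 1e-9)
    ## normalization and annotation invariants
    expect_equal(sum(call$left$p), 1, tolerance = 1e-9)
    expect_true(call$ci95_left[1] >= call$left$start &&
                  call$ci95_left[2] <= call$left$end)
    expect_true(call$max_left >= call$ci95_left[1] &&
                  call$max_left < call$ci95_left[2])
    ## product support contained in every member interval
    for (e in members) {
      expect_gte(call$left$start, e$left$start)
      expect_lte(call$left$end, e$left$end)
    }
  }
})

test_that("sum and product agree on singleton clusters (property)", {
  set.seed(31)
  for (trial in 1:10) {
    m <- random_overlapping_cluster(1)
    a <- finalize_product(m, trim_keep = 0.999)
    b <- finalize_sum(m, trim_keep = 0.999)
    expect_equal(a$left$p, b$left$p)
    expect_equal(c(a$left$start, a$left$end, a$max_left, a$ci95_left),
                 c(b$left$start, b$left$end, b$max_left, b$ci95_left))
  }
})

test_that("finalizing an empty cluster is a contract violation", {
  expect_error(finalize_product(list()), "empty")
})
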