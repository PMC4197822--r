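lib_norm <- fragment_library_normal(500, 50)

test_that("fragment library: mean, stdev and empirical survival", {
  lib <- fragment_library(c(400, 500, 600))
  expect_equal(lib$mean, 500)
  expect_equal(lib$stdev, 100)
  expect_equal(lib$D(450), 2 / 3)
  expect_equal(lib$D(0), 1)
  expect_equal(lib$D(601), 0)

  lib2 <- fragment_library(c(500, 500))
  expect_equal(c(lib2$mean, lib2$stdev), c(500, 0))

  h <- tempfile()
  writeLines(c("# fragment histogram", "500\t3", "700\t1"), h)
  lib3 <- fragment_library(h)
  expect_equal(lib3$D(600), 0.25)
  expect_equal(lib3$mean, 550)

  expect_error(fragment_library(numeric(0)), ">= 2")
})

test_that("discordance test: orientation, chromosome and length band", {
  cfg <- readpair_config(discordant_z = 4)
  pr <- function(o1, o2, s1, e1, s2, e2, c2 = "chr1") {
    read_pair(read_alignment("chr1", o1, s1, e1),
              read_alignment(c2, o2, s2, e2))
  }
  expect_false(is_discordant(pr("+", "-", 1000, 1150, 1350, 1500),
                             lib_norm, cfg))              # length 500
  expect_true(is_discordant(pr("+", "+", 1000, 1150, 1350, 1500),
                            lib_norm, cfg))               # same orientation
  expect_true(is_discordant(pr("+", "-", 1000, 1150, 1650, 1800),
                            lib_norm, cfg))               # length 800 > 700
  expect_true(is_discordant(pr("+", "-", 1000, 1150, 1350, 1500, "chr2"),
                            lib_norm, cfg))               # chromosomes
})

test_that("pair variety follows evidence orientation", {
  pr <- function(o1, o2, c2 = "chr1") {
    read_pair(read_alignment("chr1", o1, 1000, 1150),
              read_alignment(c2, o2, 2000, 2150))
  }
  expect_equal(classify_pair_variety(pr("+", "-")), "DELETION")
  expect_equal(classify_pair_variety(pr("-", "+")), "DUPLICATION")
  expect_equal(classify_pair_variety(pr("+", "+")), "INVERSION")
  expect_equal(classify_pair_variety(pr("-", "-")), "INVERSION")
  expect_equal(classify_pair_variety(pr("+", "-", "chr5")), "INTERCHROM")
})

test_that("pair evidence geometry and survival-based profile", {
  cfg <- readpair_config(discordant_z = 4, back_distance = 20)
  pair <- read_pair(read_alignment("chr1", "+", 1000, 1150),
                    read_alignment("chr1", "-", 2000, 2150))
  ev <- pair_to_breakpoint_evidence(pair, lib_norm, cfg)
  expect_equal(ev$variety, "DELETION")
  expect_equal(c(ev$left$start, ev$left$end), c(1130, 1850))  # 1150 + 700
  ## at i = 1450 the profile is D(1450 - 1000) = D(450)
  expect_equal(ev$left$p[1450 - 1130 + 1], lib_norm$D(450))
  ## mirror: reverse read 2000-2150 spans [1300, 2020), p[i] = D(2150 - i)
  expect_equal(c(ev$right$start, ev$right$end), c(1300, 2020))
  expect_equal(ev$right$p[1700 - 1300 + 1], lib_norm$D(450))
})

test_that("zero spread collapses the interval to ceiling(mean)", {
  lib0 <- fragment_library_normal(500, 0)
  cfg <- readpair_config(back_distance = 0)
  pair <- read_pair(read_alignment("chr1", "+", 1000, 1150),
                    read_alignment("chr1", "-", 2400, 2550))
  ev <- pair_to_breakpoint_evidence(pair, lib0, cfg)
  expect_equal(ev$left$end - ev$left$start, 500)
})

test_that("profile is non-increasing beyond the read (property)", {
  cfg <- readpair_config()
  pair <- read_pair(read_alignment("chr1", "+", 1000, 1150),
                    read_alignment("chr1", "-", 2650, 2800))
  ev <- pair_to_breakpoint_evidence(pair, lib_norm, cfg)
  expect_true(all(diff(ev$left$p) <= 1e-12))
  expect_true(all(diff(ev$right$p) >= -1e-12))
})

test_that("orientation symmetry: strand-flipped mirror geometry", {
  cfg <- readpair_config()
  G <- 100000
  ## an inversion pair and its reflection through the genome midpoint
  p1 <- read_pair(read_alignment("chr1", "+", 10000, 10150),
                  read_alignment("chr1", "+", 20000, 20150))
  p2 <- read_pair(read_alignment("chr1", "-", G - 20150, G - 20000),
                  read_alignment("chr1", "-", G - 10150, G - 10000))
  e1 <- pair_to_breakpoint_evidence(p1, lib_norm, cfg)
  e2 <- pair_to_breakpoint_evidence(p2, lib_norm, cfg)
  expect_equal(e2$left$start, G - e1$right$end)
  expect_equal(e2$left$end, G - e1$right$start)
  ## survival offsets are mirrored up to the half-open one-base shift
  expect_equal(e2$left$p, rev(e1$right$p), tolerance = 0.02)
  expect_equal(e2$left$p[-1],
               rev(e1$right$p)[-length(e1$right$p)], tolerance = 1e-12)
})

test_that("vectorized channel drops concordant pairs and honors mapq", {
  pairs <- data.table::data.table(
    x_chrom = "chr1", x_orient = c("+", "+", "+"),
    x_start = c(1000, 1000, 1000), x_end = c(1150, 1150, 1150),
    x_mapq = c(60, 60, 0),
    y_chrom = "chr1", y_orient = c("-", "-", "-"),
    y_start = c(1350, 1650, 1650), y_end = c(1500, 1800, 1800),
    y_mapq = 60)
  tab <- svprob:::readpair_evidence_table(pairs, lib_norm,
                                          readpair_config())
  expect_equal(nrow(tab), 1)       # concordant + low-mapq removed
  expect_equal(tab$variety, "DELETION")
  ## matches the scalar path
  ev <- pair_to_breakpoint_evidence(
    read_pair(read_alignment("chr1", "+", 1000, 1150),
              read_alignment("chr1", "-", 1650, 1800)),
    lib_norm, readpair_config())
  expect_equal(tab$l_start, ev$left$start)
  expect_equal(tab$p_l[[1]], ev$left$p)
  expect_equal(tab$p_r[[1]], ev$right$p)
})

test_that("intervals are clipped at chromosome edges", {
  cfg <- readpair_config()
  pair <- read_pair(read_alignment("chr1", "-", 100, 250),
                    read_alignment("chr1", "-", 600, 750))
  ev <- pair_to_breakpoint_evidence(pair, lib_norm, cfg,
                                    chrom_lengths = c(chr1 = 1000))
  expect_equal(ev$left$start, 0)   # 100 - 700 clipped to 0
  expect_equal(length(ev$left$p), ev$left$end - ev$left$start)
})
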