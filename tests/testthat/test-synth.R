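test_that("variant embedding: length bookkeeping and truth adjacencies", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 10000), n_del = 1,
                    size_range = c(100, 100), min_gap = 500, seed = 5)
  sim <- simulate_variants(cfg)
  expect_equal(unname(sim$alt_lengths["chr1"]), 9900)
  expect_equal(nrow(sim$truth), 1)
  v <- sim$variants
  expect_equal(sim$truth$pos1, v$start)
  expect_equal(sim$truth$pos2, v$end)

  cfg2 <- sim_config(chrom_lengths = c(chr1 = 20000), n_dup = 1,
                     size_range = c(500, 500), min_gap = 500, seed = 6)
  sim2 <- simulate_variants(cfg2)
  expect_equal(unname(sim2$alt_lengths["chr1"]), 20500)
  ## the duplication adjacency joins the unit end back to its start
  expect_equal(sim2$truth$pos1, sim2$variants$start)
  expect_equal(sim2$truth$pos2, sim2$variants$end)
  expect_equal(sim2$truth$variety, "DUPLICATION")

  cfg3 <- sim_config(chrom_lengths = c(chr1 = 30000, chr2 = 30000),
                     n_ins = 1, min_gap = 500, seed = 7)
  sim3 <- simulate_variants(cfg3)
  expect_equal(nrow(sim3$truth), 2)
  expect_true(all(sim3$truth$variety == "INTERCHROM"))
})

test_that("truth record count follows the adjacency formula (property)", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 2e5, chr2 = 2e5),
                    n_del = 3, n_dup = 2, n_inv = 2, n_ins = 2,
                    size_range = c(200, 2000), min_gap = 1000, seed = 9)
  sim <- simulate_variants(cfg)
  expect_equal(nrow(sim$truth), 3 + 2 + 2 * 2 + 2 * 2)
  expect_equal(length(unique(sim$truth$variant_id)), 9)
})

test_that("a variant-free genome yields only proper concordant pairs", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 2e5), coverage = 10, seed = 8)
  aln <- simulate_alignments(identity_map(cfg$chrom_lengths),
                             cfg$chrom_lengths, cfg)
  expect_true(all(aln$proper))
  expect_true(all(!aln$supplementary))
  expect_true(all(aln$query_start == 0 & aln$query_end == 150))
})

test_that("reads crossing a deletion junction split at block boundaries", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 5e5), n_del = 1,
                    size_range = c(1000, 1000), coverage = 30, seed = 10)
  sim <- simulate_variants(cfg)
  aln <- simulate_alignments(sim$blocks, sim$alt_lengths, cfg)
  v <- sim$variants
  segs <- splits_from_alignments(aln)
  expect_gt(nrow(segs), 0)
  byread <- split(segs, segs$read_name)
  for (rd in byread) {
    expect_equal(nrow(rd), 2)
    rd <- rd[order(rd$ref_start), ]
    expect_equal(rd$ref_end[1], v$start)    # left piece ends at the junction
    expect_equal(rd$ref_start[2], v$end)    # right piece resumes after it
    expect_true(all(rd$ref_end - rd$ref_start >= cfg$min_flank))
    expect_equal(sum(rd$query_end - rd$query_start), 150)
  }
  ## fragments spanning the deletion produce (+,-) pairs with apparent
  ## length stretched by the deletion size
  prs <- pairs_from_alignments(aln)
  disc <- prs[prs$x_end <= v$start & prs$y_start >= v$end &
                prs$x_orient == "+" & prs$y_orient == "-", ]
  expect_gt(nrow(disc), 0)
  app <- disc$y_end - disc$x_start
  expect_true(all(app > 1000))
  expect_true(all(abs(app - 1000 - 500) < 4 * 50 + 150))
})

test_that("mapping fidelity: records push back through the block map", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 1e5), n_del = 1, n_inv = 1,
                    size_range = c(500, 1500), coverage = 5,
                    min_gap = 2000, seed = 12)
  sim <- simulate_variants(cfg)
  aln <- simulate_alignments(sim$blocks, sim$alt_lengths, cfg)
  bl <- sim$blocks
  ## every aligned segment must lie inside exactly one block with
  ## consistent strand composition
  for (i in seq_len(nrow(aln))) {
    rec <- aln[i]
    hit <- bl[bl$ref_chrom == rec$chrom & bl$ref_start <= rec$start &
                bl$ref_end >= rec$end]
    expect_gte(nrow(hit), 1)
  }
})

test_that("simulation is deterministic under its seed", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 1e5), n_del = 2,
                    coverage = 5, seed = 77)
  s1 <- simulate_variants(cfg); s2 <- simulate_variants(cfg)
  expect_identical(s1$truth, s2$truth)
  a1 <- simulate_alignments(s1$blocks, s1$alt_lengths, cfg)
  a2 <- simulate_alignments(s2$blocks, s2$alt_lengths, cfg)
  expect_identical(as.data.frame(a1), as.data.frame(a2))
})

test_that("mixture bookkeeping is exact: 5% of 10X is 0.5X + 9.5X", {
  L <- 2e5
  cfg <- sim_config(chrom_lengths = c(chr1 = L), n_del = 1,
                    size_range = c(500, 500), coverage = 1, seed = 14)
  sim <- simulate_variants(cfg)
  aln <- mix_samples(sim, c(chr1 = L), cfg, allele_frequency = 0.05,
                     total_coverage = 10)
  n_t <- length(unique(aln$qname[startsWith(aln$qname, "t")]))
  n_n <- length(unique(aln$qname[startsWith(aln$qname, "n")]))
  expect_equal(n_t, round(0.5 * sum(sim$alt_lengths) / 300))
  expect_equal(n_n, round(9.5 * L / 300))
  ## allele-frequency bounds are enforced
  expect_error(mix_samples(sim, c(chr1 = L), cfg, 0, 10), "allele_frequency")
})

test_that("altered genome sequence matches the coordinate map", {
  lens <- c(chr1 = 20000)
  ref <- simulate_reference(lens, seed = 2)
  cfg <- sim_config(chrom_lengths = lens, n_dup = 1, n_inv = 1,
                    size_range = c(300, 600), min_gap = 1500, seed = 2)
  sim <- simulate_variants(cfg)
  alt <- altered_genome_sequence(ref, sim$blocks)
  expect_equal(Biostrings::width(alt)[1],
               unname(sim$alt_lengths["chr1"]))
  dup <- sim$variants[sim$variants$variety == "DUPLICATION", ]
  unit <- as.character(Biostrings::subseq(ref[["chr1"]], dup$start + 1,
                                          dup$end))
  expect_equal(
    length(gregexpr(unit, as.character(alt[[1]]), fixed = TRUE)[[1]]), 2)
  inv <- sim$variants[sim$variants$variety == "INVERSION", ]
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::subseq(ref[["chr1"]], inv$start + 1, inv$end)))
  expect_true(grepl(rc, as.character(alt[[1]]), fixed = TRUE))
})

test_that("key=value config files mirror sim_config", {
  f <- tempfile()
  writeLines(c("# comment", "chrom_lengths=chr1:50000,chr2:30000",
               "n_del=3", "coverage=7.5", "size_range=200,800",
               "size_dist=loguniform", "seed=99"), f)
  cfg <- read_sim_config(f)
  expect_equal(cfg$chrom_lengths, c(chr1 = 50000, chr2 = 30000))
  expect_equal(cfg$n_del, 3)
  expect_equal(cfg$coverage, 7.5)
  expect_equal(cfg$size_dist, "loguniform")
  expect_equal(cfg$seed, 99L)
  expect_error(sim_config(chrom_lengths = c(chr1 = 1e4)), "seed")
})
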