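## Scaled-down reproductions of the published simulation studies, shared
## by the acceptance tests and scripts/acceptance.R.  Both studies run the
## caller with the published settings: minimum evidence 4, discordant_z 4,
## back_distance 20, min_non_overlap 150, weight 1, mapping threshold 1,
## and score calls with 50 bp truth slop under the both-interval,
## type-matched rule.

published_thresholds <- function() calling_thresholds(min_total_weight = 4)

study_channels <- function(aln) {
  sample_spec("S1",
              pe = list(alignments = aln, discordant_z = 4,
                        back_distance = 20, weight = 1,
                        min_mapping_threshold = 1),
              sr = list(alignments = aln, v_s = 20, min_non_overlap = 150,
                        weight = 1, min_mapping_threshold = 1))
}

#' Scaled-down homozygous-deletion simulation study
#'
#' Embeds random non-overlapping deletions (100 bp-10 kb, uniform sizes)
#' in a random reference, renders idealized paired-end/split alignments at
#' the requested coverage, calls with the published parameters and scores
#' against the truth with 50 bp slop.  One replicate per seed.
#'
#' @param coverage Haploid coverage.
#' @param seeds Integer vector of replicate seeds.
#' @param n_del Number of deletions (default 200).
#' @param genome_length Reference length in bases (default 1e7).
#' @param size_range,size_dist Deletion size model (defaults 100-10000,
#'   uniform).
#' @param verbose Log progress (default FALSE).
#' @return List with `sensitivity` and `fdr` (percent, averaged over
#'   seeds) plus a `per_seed` table.
#' @export
run_homozygous_study <- function(coverage, seeds, n_del = 200,
                                 genome_length = 1e7,
                                 size_range = c(100, 10000),
                                 size_dist = "uniform", verbose = FALSE) {
  per_seed <- rbindlist(lapply(seeds, function(sd) {
    lens <- c(chr1 = genome_length)
    cfg <- sim_config(chrom_lengths = lens, n_del = n_del,
                      size_range = size_range, size_dist = size_dist,
                      coverage = coverage, seed = sd)
    sim <- simulate_variants(cfg)
    aln <- simulate_alignments(sim$blocks, sim$alt_lengths, cfg)
    calls <- call_structural_variants(study_channels(aln),
                                      published_thresholds(),
                                      chrom_lengths = lens,
                                      verbose = verbose)
    res <- match_calls(calls, pad_truth(sim$truth, 50))
    data.table(seed = sd, coverage = coverage,
               sensitivity = 100 * res$sensitivity,
               fdr = 100 * if (is.na(res$fdr)) 0 else res$fdr,
               n_calls = res$n_calls)
  }))
  list(sensitivity = mean(per_seed$sensitivity),
       fdr = mean(per_seed$fdr), per_seed = per_seed)
}

#' Scaled-down heterogeneous-tumor simulation study
#'
#' Embeds deletions with the small-size skew of population callsets
#' (log-uniform 50 bp-10 kb), mixes variant-genome reads at
#' `af * total_coverage` with reference-genome reads at the complementary
#' coverage, and calls/scores as in [run_homozygous_study()].
#'
#' @param total_coverage Pooled sample coverage.
#' @param af SV allele frequency (fraction of reads from the variant
#'   genome).
#' @param seeds Integer vector of replicate seeds.
#' @param n_del Number of deletions (default 300).
#' @param genome_length Reference length (default 1e7).
#' @param verbose Log progress (default FALSE).
#' @return As [run_homozygous_study()].
#' @export
run_mixture_study <- function(total_coverage, af, seeds, n_del = 300,
                              genome_length = 1e7, verbose = FALSE) {
  per_seed <- rbindlist(lapply(seeds, function(sd) {
    lens <- c(chr1 = genome_length)
    cfg <- sim_config(chrom_lengths = lens, n_del = n_del,
                      size_range = c(50, 10000), size_dist = "loguniform",
                      coverage = 1, seed = sd)
    sim <- simulate_variants(cfg)
    aln <- mix_samples(sim, lens, cfg, allele_frequency = af,
                       total_coverage = total_coverage)
    calls <- call_structural_variants(study_channels(aln),
                                      published_thresholds(),
                                      chrom_lengths = lens,
                                      verbose = verbose)
    res <- match_calls(calls, pad_truth(sim$truth, 50))
    data.table(seed = sd, coverage = total_coverage, af = af,
               sensitivity = 100 * res$sensitivity,
               fdr = 100 * if (is.na(res$fdr)) 0 else res$fdr,
               n_calls = res$n_calls)
  }))
  list(sensitivity = mean(per_seed$sensitivity),
       fdr = mean(per_seed$fdr), per_seed = per_seed)
}
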