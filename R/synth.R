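## Desk-scale simulator: builds a variant-bearing genome from a (random or
## supplied) reference, simulates paired-end fragments and renders
## idealized alignment records (concordant, discordant, split,
## soft-clipped) plus a truth BEDPE.  Reads are coordinate-level: every
## read maps uniquely and exactly (no repeats, no base errors), which
## isolates the clustering math from aligner behavior and biases
## scaled-down sensitivities upward relative to real genomes.

#' Simulation configuration
#'
#' @param chrom_lengths Named vector of reference chromosome lengths
#'   (default one 1 Mb chromosome `chr1`).
#' @param n_del,n_dup,n_inv,n_ins Variant counts per variety
#'   (`n_ins` = translocation-style insertions, needs >= 2 chromosomes).
#' @param size_range Variant size range in bases (default 100-10000).
#' @param size_dist `"uniform"` (default) or `"loguniform"`; log-uniform
#'   mimics the small-size skew of population deletion callsets.
#' @param ins_size Inserted-segment size for translocations (default 1000).
#' @param read_length Read length (default 150).
#' @param frag_mean,frag_sd Fragment-length mean and standard deviation
#'   (defaults 500 and 50).
#' @param coverage Haploid sequence coverage (default 10).
#' @param min_flank Minimum aligned bases on both sides of a junction for a
#'   crossing read to be rendered as a split alignment (default 20);
#'   shorter overhangs are soft-clipped.
#' @param min_gap Minimum distance between placed variants and from
#'   chromosome edges (default 1000, two fragment lengths, so evidence
#'   clusters of neighboring variants stay distinct).
#' @param seed Mandatory RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 1e6), n_del = 0, n_dup = 0,
                       n_inv = 0, n_ins = 0, size_range = c(100, 10000),
                       size_dist = c("uniform", "loguniform"),
                       ins_size = 1000, read_length = 150, frag_mean = 500,
                       frag_sd = 50, coverage = 10, min_flank = 20,
                       min_gap = 1000, seed) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  stopifnot(coverage > 0, !is.null(names(chrom_lengths)))
  structure(list(chrom_lengths = chrom_lengths, n_del = n_del,
                 n_dup = n_dup, n_inv = n_inv, n_ins = n_ins,
                 size_range = size_range, size_dist = match.arg(size_dist),
                 ins_size = ins_size, read_length = read_length,
                 frag_mean = frag_mean, frag_sd = frag_sd,
                 coverage = coverage, min_flank = min_flank,
                 min_gap = min_gap, seed = as.integer(seed)),
            class = "sim_config")
}

## evaluate expr with a private RNG stream; restores the caller's RNG state
with_sim_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a random reference genome
#'
#' Uniform base composition; mainly for FASTA round trips and
#' sequence-level checks - the alignment simulator itself is
#' coordinate-level and does not need bases.
#'
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param seed RNG seed.
#' @return A [Biostrings::DNAStringSet].
#' @export
simulate_reference <- function(chrom_lengths, seed) {
  with_sim_seed(seed, {
    seqs <- vapply(chrom_lengths, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, "")
    Biostrings::DNAStringSet(setNames(seqs, names(chrom_lengths)))
  })
}

draw_sizes <- function(n, cfg) {
  lo <- cfg$size_range[1]; hi <- cfg$size_range[2]
  if (cfg$size_dist == "loguniform") {
    round(exp(runif(n, log(lo), log(hi))))
  } else {
    round(runif(n, lo, hi))
  }
}

#' Embed variants in a reference and derive the coordinate map
#'
#' Randomly places the requested non-overlapping variants (deletions
#' remove their segment, tandem duplications repeat it in place,
#' inversions reverse it, translocation-style insertions copy a donor
#' segment from another chromosome).  Returns a piecewise block map
#' between altered and reference coordinates and a truth table with one
#' record per novel adjacency: one for deletions and duplications, two
#' for inversions and insertions.
#'
#' @param cfg A [sim_config].
#' @return List with `variants`, `blocks` (the coordinate map),
#'   `alt_lengths` and `truth` (`data.table`: chrom1, pos1, chrom2, pos2,
#'   variety, variant_id, adjacency).
#' @export
simulate_variants <- function(cfg) {
  with_sim_seed(cfg$seed, simulate_variants_impl(cfg))
}

simulate_variants_impl <- function(cfg) {
  lens <- cfg$chrom_lengths
  chroms <- names(lens)
  total <- cfg$n_del + cfg$n_dup + cfg$n_inv + cfg$n_ins
  if (cfg$n_ins > 0 && length(lens) < 2)
    stop("simulate_variants: translocation insertions need >= 2 chromosomes")
  variety <- rep(c("DELETION", "DUPLICATION", "INVERSION", "INS"),
                 c(cfg$n_del, cfg$n_dup, cfg$n_inv, cfg$n_ins))
  sizes <- draw_sizes(total, cfg)
  sizes[variety == "INS"] <- cfg$ins_size
  ## rejection placement with min_gap spacing (donor sites included)
  placed <- data.table(chrom = character(), start = numeric(),
                       end = numeric())
  gap <- cfg$min_gap
  reserve <- function(chrom, start, end) {
    ok <- !any(placed$chrom == chrom & placed$start - gap < end &
                 placed$end + gap > start)
    if (ok) placed <<- rbind(placed, data.table(chrom, start, end))
    ok
  }
  draw_span <- function(size) {
    for (try in 1:200) {
      cn <- sample(chroms, 1, prob = lens)
      if (lens[cn] < size + 2 * gap) next
      s <- floor(runif(1, gap, lens[cn] - size - gap))
      if (reserve(cn, s, s + size)) return(list(chrom = cn, start = s))
    }
    stop("simulate_variants: could not place variant (genome too full)")
  }
  empty_variants <- data.table(
    variant_id = character(), variety = character(), chrom = character(),
    start = numeric(), end = numeric(), donor_chrom = character(),
    donor_start = numeric(), donor_end = numeric())
  vars <- vector("list", total)
  for (i in seq_len(total)) {
    sp <- draw_span(sizes[i])
    v <- list(variant_id = sprintf("v%04d", i), variety = variety[i],
              chrom = sp$chrom, start = sp$start, end = sp$start + sizes[i],
              donor_chrom = NA_character_, donor_start = NA_real_,
              donor_end = NA_real_)
    if (variety[i] == "INS") {
      ## insertion point is v$start (zero reference width at the site);
      ## donor segment comes from a different chromosome
      v$end <- v$start
      repeat {
        d <- draw_span(cfg$ins_size)
        if (d$chrom != sp$chrom) break
      }
      v$donor_chrom <- d$chrom
      v$donor_start <- d$start
      v$donor_end <- d$start + cfg$ins_size
    }
    vars[[i]] <- v
  }
  variants <- if (total > 0) rbindlist(vars) else empty_variants
  blocks <- build_block_map(lens, variants)
  truth <- build_truth(variants)
  alt_lengths <- blocks[, .(len = max(alt_end)), by = alt_chrom]
  list(variants = variants,
       blocks = blocks,
       alt_lengths = setNames(alt_lengths$len, alt_lengths$alt_chrom),
       truth = truth)
}

## Piecewise map altered genome -> reference: one row per contiguous
## reference block in the altered genome.
build_block_map <- function(chrom_lengths, variants) {
  out <- list()
  for (cn in names(chrom_lengths)) {
    L <- chrom_lengths[[cn]]
    vv <- variants[chrom == cn][order(start)]
    cur <- 0
    blocks <- list()
    add <- function(ref_chrom, ref_start, ref_end, strand = "+") {
      if (ref_end > ref_start)
        blocks[[length(blocks) + 1L]] <<-
          data.table(ref_chrom, ref_start, ref_end, strand)
    }
    for (i in seq_len(nrow(vv))) {
      v <- vv[i]
      add(cn, cur, v$start)
      if (v$variety == "DELETION") {
        cur <- v$end
      } else if (v$variety == "DUPLICATION") {
        add(cn, v$start, v$end)
        add(cn, v$start, v$end)
        cur <- v$end
      } else if (v$variety == "INVERSION") {
        add(cn, v$start, v$end, "-")
        cur <- v$end
      } else {  # INS: copy donor segment at the insertion point
        add(v$donor_chrom, v$donor_start, v$donor_end)
        cur <- v$start
      }
    }
    add(cn, cur, L)
    b <- rbindlist(blocks)
    ## merge reference-contiguous forward blocks (no junction between them)
    keep <- c(TRUE, !(b$ref_chrom[-1] == b$ref_chrom[-nrow(b)] &
                        b$strand[-1] == "+" & b$strand[-nrow(b)] == "+" &
                        b$ref_start[-1] == b$ref_end[-nrow(b)]))
    grp <- cumsum(keep)
    b <- b[, .(ref_chrom = ref_chrom[1], ref_start = min(ref_start),
               ref_end = max(ref_end), strand = strand[1]), by = grp]
    b[, grp := NULL]
    b[, alt_chrom := cn]
    w <- b$ref_end - b$ref_start
    b[, alt_end := cumsum(w)]
    b[, alt_start := alt_end - w]
    out[[cn]] <- b
  }
  rbindlist(out)[, .(alt_chrom, alt_start, alt_end, ref_chrom, ref_start,
                     ref_end, strand)]
}

build_truth <- function(variants) {
  recs <- list(data.table(chrom1 = character(), pos1 = numeric(),
                          chrom2 = character(), pos2 = numeric(),
                          variety = character(), variant_id = character(),
                          adjacency = character()))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i]
    recs[[length(recs) + 1L]] <- switch(v$variety,
      DELETION = data.table(chrom1 = v$chrom, pos1 = v$start,
                            chrom2 = v$chrom, pos2 = v$end,
                            variety = "DELETION",
                            variant_id = v$variant_id, adjacency = "A"),
      DUPLICATION = data.table(chrom1 = v$chrom, pos1 = v$start,
                               chrom2 = v$chrom, pos2 = v$end,
                               variety = "DUPLICATION",
                               variant_id = v$variant_id, adjacency = "A"),
      INVERSION = data.table(chrom1 = v$chrom, pos1 = c(v$start, v$start),
                             chrom2 = v$chrom, pos2 = c(v$end, v$end),
                             variety = "INVERSION",
                             variant_id = v$variant_id,
                             adjacency = c("A", "B")),
      INS = data.table(chrom1 = c(v$chrom, v$chrom),
                       pos1 = c(v$start, v$start),
                       chrom2 = c(v$donor_chrom, v$donor_chrom),
                       pos2 = c(v$donor_start, v$donor_end),
                       variety = "INTERCHROM",
                       variant_id = v$variant_id, adjacency = c("A", "B")))
  }
  rbindlist(recs)
}

#' Identity coordinate map for an unmodified genome
#'
#' @param chrom_lengths Named chromosome lengths.
#' @return A block table mapping each chromosome onto itself.
#' @export
identity_map <- function(chrom_lengths) {
  data.table(alt_chrom = names(chrom_lengths), alt_start = 0,
             alt_end = as.numeric(chrom_lengths),
             ref_chrom = names(chrom_lengths), ref_start = 0,
             ref_end = as.numeric(chrom_lengths), strand = "+")
}

#' Simulate idealized paired-end alignments
#'
#' Fragments are drawn uniformly along the altered genome with
#' normal(frag_mean, frag_sd) lengths truncated at `2 * read_length`; both
#' reads are pushed through the coordinate map.  Reads inside one
#' reference-contiguous block become contiguous records; reads crossing a
#' junction with at least `min_flank` aligned bases on each side become
#' split records (primary + supplementary); shorter overhangs are
#' soft-clipped.  Mate fields reflect the reference-space geometry, and
#' pairs whose whole fragment lies inside one block are flagged proper.
#'
#' @param blocks A block map from [simulate_variants()] or
#'   [identity_map()].
#' @param alt_lengths Named altered-genome chromosome lengths.
#' @param cfg A [sim_config]; `coverage`, `read_length`, `frag_mean`,
#'   `frag_sd`, `min_flank` and `seed` are used.
#' @param prefix Read-name prefix (default `"frag"`).
#' @param sample_id Sample identifier on the records.
#' @return An alignment record table (see [read_alignments()]).
#' @export
simulate_alignments <- function(blocks, alt_lengths, cfg, prefix = "frag",
                                sample_id = "S1") {
  with_sim_seed(cfg$seed + 1L,
                simulate_alignments_impl(blocks, alt_lengths, cfg, prefix,
                                         sample_id))
}

simulate_alignments_impl <- function(blocks, alt_lengths, cfg, prefix,
                                     sample_id) {
  rl <- cfg$read_length
  total_len <- sum(alt_lengths)
  n_frag <- round(cfg$coverage * total_len / (2 * rl))
  if (n_frag == 0) return(empty_alignment_table())
  chrom_i <- sample.int(length(alt_lengths), n_frag, replace = TRUE,
                        prob = alt_lengths)
  flen <- pmax(round(rnorm(n_frag, cfg$frag_mean, cfg$frag_sd)), 2 * rl)
  clen <- as.numeric(alt_lengths[chrom_i])
  flen <- pmin(flen, clen)
  fstart <- floor(runif(n_frag) * (clen - flen + 1))

  ## global (concatenated) altered coordinates for one findInterval pass
  offs_v <- cumsum(c(0, head(as.numeric(alt_lengths), -1)))
  bl <- copy(blocks)
  bl[, g_start := alt_start + offs_v[match(alt_chrom, names(alt_lengths))]]
  bl[, g_end := g_start + (alt_end - alt_start)]
  setorder(bl, g_start)
  bl_gs <- bl$g_start; bl_ge <- bl$g_end
  bl_rs <- bl$ref_start; bl_fwd <- bl$strand == "+"
  bl_chrom <- bl$ref_chrom

  ## per-read vectors (mate 1 then mate 2)
  g_s <- c(fstart, fstart + flen - rl) + offs_v[rep(chrom_i, 2L)]
  g_e <- g_s + rl
  r_strand_fwd <- rep(c(TRUE, FALSE), each = n_frag)
  qname <- rep(paste0(prefix, seq_len(n_frag)), 2L)
  mate <- rep(c(1L, 2L), each = n_frag)
  bi_s <- findInterval(g_s, bl_gs)
  bi_e <- findInterval(g_e - 1, bl_gs)
  ## whole-fragment block membership (for the proper flag); a fragment
  ## inside one forward block implies both its reads are contiguous
  fb_s <- findInterval(fstart + offs_v[chrom_i], bl_gs)
  fb_e <- findInterval(fstart + flen - 1 + offs_v[chrom_i], bl_gs)
  proper <- rep(fb_s == fb_e & bl_fwd[fb_s], 2L)

  simple <- bi_s == bi_e
  si <- which(simple)
  sb <- bi_s[si]
  fwd <- bl_fwd[sb]
  ref_start <- fifelse(fwd, bl_rs[sb] + (g_s[si] - bl_gs[sb]),
                       bl_rs[sb] + (bl_ge[sb] - g_e[si]))
  out_simple <- data.table(
    qname = qname[si], mate = mate[si], chrom = bl_chrom[sb],
    start = ref_start, end = ref_start + rl,
    strand = fifelse(r_strand_fwd[si] == fwd, "+", "-"),
    mapq = 60, supplementary = FALSE, proper = proper[si],
    query_start = 0, query_end = rl, read_len = rl,
    sample_id = sample_id)

  ## junction-crossing reads (minority), fully vectorized: one row per
  ## (read, overlapped block)
  ci <- which(!simple)
  out <- out_simple
  if (length(ci)) {
    nseg <- bi_e[ci] - bi_s[ci] + 1L
    rid <- rep(ci, nseg)                       # read index per segment
    bj <- sequence(nseg, from = bi_s[ci])      # block index per segment
    a1 <- pmax(bl_gs[bj], g_s[rid]); a2 <- pmin(bl_ge[bj], g_e[rid])
    rfwd <- r_strand_fwd[rid]
    qs <- fifelse(rfwd, a1 - g_s[rid], g_e[rid] - a2)
    qe <- fifelse(rfwd, a2 - g_s[rid], g_e[rid] - a1)
    bfwd <- bl_fwd[bj]
    rs <- fifelse(bfwd, bl_rs[bj] + (a1 - bl_gs[bj]),
                  bl_rs[bj] + (bl_ge[bj] - a2))
    keep <- (qe - qs) >= cfg$min_flank
    rid <- rid[keep]; bj <- bj[keep]; qs <- qs[keep]; qe <- qe[keep]
    rs <- rs[keep]; a1 <- a1[keep]; a2 <- a2[keep]
    bfwd <- bfwd[keep]; rfwd <- rfwd[keep]
    ## primary = widest surviving segment per read (first on ties)
    o <- order(rid, -(qe - qs), qs)
    primary_pos <- o[!duplicated(rid[o])]
    suppl <- rep(TRUE, length(rid)); suppl[primary_pos] <- FALSE
    out_cross <- data.table(
      qname = qname[rid], mate = mate[rid], chrom = bl_chrom[bj],
      start = rs, end = rs + (a2 - a1),
      strand = fifelse(rfwd == bfwd, "+", "-"),
      mapq = 60, supplementary = suppl, proper = FALSE,
      query_start = qs, query_end = qe, read_len = rl,
      sample_id = sample_id)
    out <- rbindlist(list(out_simple, out_cross))
  }
  setorder(out, chrom, start, qname, mate)
  out[]
}

#' Simulate a heterogeneous (tumor/normal) read mixture
#'
#' Draws reads from the variant-bearing genome at
#' `allele_frequency * total_coverage` and from the unmodified reference
#' at the complementary coverage, pools and coordinate-sorts them: a
#' single mixed sample whose SV allele frequency is the fraction of reads
#' from the variant genome.
#'
#' @param sim Result of [simulate_variants()].
#' @param ref_lengths Named reference chromosome lengths.
#' @param cfg A [sim_config] (geometry parameters and seed).
#' @param allele_frequency Fraction of reads from the variant genome
#'   (0 < AF < 1).
#' @param total_coverage Total coverage of the pooled sample.
#' @param sample_id Sample identifier.
#' @return An alignment record table.
#' @export
mix_samples <- function(sim, ref_lengths, cfg, allele_frequency,
                        total_coverage, sample_id = "S1") {
  stopifnot(allele_frequency > 0, allele_frequency < 1)
  cfg_t <- cfg; cfg_t$coverage <- allele_frequency * total_coverage
  cfg_n <- cfg; cfg_n$coverage <- (1 - allele_frequency) * total_coverage
  cfg_n$seed <- cfg$seed + 104729L   # independent stream for the normal
  tum <- simulate_alignments(sim$blocks, sim$alt_lengths, cfg_t,
                             prefix = "t", sample_id = sample_id)
  nor <- simulate_alignments(identity_map(ref_lengths), ref_lengths, cfg_n,
                             prefix = "n", sample_id = sample_id)
  out <- rbind(tum, nor)
  setorder(out, chrom, start, qname, mate)
  out[]
}

#' Extract the altered genome sequence through the coordinate map
#'
#' @param ref A [Biostrings::DNAStringSet] reference.
#' @param blocks A block map.
#' @return A `DNAStringSet` of altered chromosomes.
#' @export
altered_genome_sequence <- function(ref, blocks) {
  chroms <- unique(blocks$alt_chrom)
  seqs <- vapply(chroms, function(cn) {
    bb <- blocks[alt_chrom == cn][order(alt_start)]
    pieces <- vapply(seq_len(nrow(bb)), function(i) {
      s <- Biostrings::subseq(ref[[bb$ref_chrom[i]]], bb$ref_start[i] + 1,
                              bb$ref_end[i])
      if (bb$strand[i] == "-") s <- Biostrings::reverseComplement(s)
      as.character(s)
    }, "")
    paste(pieces, collapse = "")
  }, "")
  Biostrings::DNAStringSet(setNames(seqs, chroms))
}

#' Write a truth table as BEDPE
#'
#' Breakpoints are written as 1-base intervals with a `TYPE:` token in the
#' name column, readable by [read_generic_evidence()].
#'
#' @param truth A truth `data.table` from [simulate_variants()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_bedpe <- function(truth, path) {
  type <- fifelse(truth$variety == "INTERCHROM", "TRANSLOCATION",
                  truth$variety)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s\t%d\t%s\t%s\t%s",
                   truth$chrom1, as.integer(truth$pos1),
                   as.integer(truth$pos1) + 1L, truth$chrom2,
                   as.integer(truth$pos2), as.integer(truth$pos2) + 1L,
                   sprintf("%s_%s;TYPE:%s", truth$variant_id,
                           truth$adjacency, type),
                   0L, "+", "-", truth$variety)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a key=value simulation config file
#'
#' Recognized keys mirror the [sim_config()] arguments; `chrom_lengths`
#' is given as `name:length` pairs separated by commas.
#'
#' @param path Config file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  args <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    if (k == "chrom_lengths") {
      parts <- strsplit(strsplit(v, ",")[[1]], ":")
      args$chrom_lengths <- setNames(
        as.numeric(vapply(parts, `[`, "", 2)),
        vapply(parts, `[`, "", 1))
    } else if (k == "size_dist") {
      args[[k]] <- v
    } else if (k == "size_range") {
      args[[k]] <- as.numeric(strsplit(v, ",")[[1]])
    } else {
      args[[k]] <- as.numeric(v)
    }
  }
  do.call(sim_config, args)
}
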