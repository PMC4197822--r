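## Readers/writers for SAM/BAM, BEDPE and bedgraph, plus the conversion
## between SAM's 1-based inclusive coordinates and the internal 0-based
## half-open convention.  The internal currency is the "alignment record
## table": one row per aligned segment with columns
##   qname, mate (1/2), chrom, start, end, strand, mapq, supplementary,
##   proper, query_start, query_end, read_len
## where query coordinates are half-open in original-read orientation.

cigar_ref_width <- function(cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)
  vapply(regmatches(cigar, ops), function(x) {
    op <- substring(x, nchar(x))
    n <- as.numeric(substring(x, 1, nchar(x) - 1))
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, 0)
}

cigar_query_clips <- function(cigar) {
  ## returns matrix: leading clip, aligned query bases, trailing clip
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)
  t(vapply(regmatches(cigar, ops), function(x) {
    op <- substring(x, nchar(x))
    n <- as.numeric(substring(x, 1, nchar(x) - 1))
    k <- length(op)
    lead <- if (op[1] %in% c("S", "H")) n[1] else 0
    trail <- if (k > 1 && op[k] %in% c("S", "H")) n[k] else 0
    c(lead, sum(n[op %in% c("M", "I", "=", "X")]), trail)
  }, c(0, 0, 0)))
}

#' Read alignments from a SAM or BAM file
#'
#' Loads primary and supplementary records (secondary and duplicate-flagged
#' records are dropped), converts SAM's 1-based inclusive coordinates to
#' the internal 0-based half-open convention, and derives per-record query
#' coordinates in original-read orientation from the CIGAR string.  `.sam`
#' input is converted with [Rsamtools::asBam()] on the fly.
#'
#' @param path SAM or BAM file.
#' @param min_mapq Drop records below this mapping quality (default 0).
#' @param sample_id Sample identifier attached to the records.
#' @return A `data.table` alignment record table (see source for schema).
#' @export
read_alignments <- function(path, min_mapq = 0, sample_id = "S1") {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "cigar", "mapq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  if (length(b$qname) == 0) return(empty_alignment_table())
  clips <- cigar_query_clips(b$cigar)
  read_len <- rowSums(clips)
  strand <- as.character(b$strand)
  qs <- ifelse(strand == "+", clips[, 1], clips[, 3])
  tab <- data.table(
    qname = b$qname,
    mate = fifelse(bitwAnd(b$flag, 128L) > 0L, 2L, 1L),
    chrom = as.character(b$rname),
    start = b$pos - 1,                     # SAM 1-based -> 0-based
    end = b$pos - 1 + cigar_ref_width(b$cigar),
    strand = strand,
    mapq = as.numeric(b$mapq),
    supplementary = bitwAnd(b$flag, 2048L) > 0L,
    proper = bitwAnd(b$flag, 2L) > 0L,
    query_start = qs,
    query_end = qs + clips[, 2],
    read_len = read_len,
    sample_id = sample_id)
  tab[mapq >= min_mapq]
}

empty_alignment_table <- function() {
  data.table(qname = character(), mate = integer(), chrom = character(),
             start = numeric(), end = numeric(), strand = character(),
             mapq = numeric(), supplementary = logical(), proper = logical(),
             query_start = numeric(), query_end = numeric(),
             read_len = numeric(), sample_id = character())
}

#' Assemble read pairs from an alignment record table
#'
#' Pairs the two primary records of each read name.  Fragments in which
#' either mate aligned in split fashion (has supplementary segments) are
#' excluded: their breakpoint signal is carried by the split-read channel,
#' and counting the same fragment in both channels would double-count it.
#' Pairs are canonicalized by `(chromosome, start)`.
#'
#' @param tab An alignment record table.
#' @return A `data.table` with columns `name`, `x_chrom`, `x_orient`,
#'   `x_start`, `x_end`, `x_mapq`, `y_*`.
#' @export
pairs_from_alignments <- function(tab) {
  if (nrow(tab) == 0) {
    return(data.table(name = character(), x_chrom = character(),
                      x_orient = character(), x_start = numeric(),
                      x_end = numeric(), x_mapq = numeric(),
                      y_chrom = character(), y_orient = character(),
                      y_start = numeric(), y_end = numeric(),
                      y_mapq = numeric(), proper = logical()))
  }
  split_names <- unique(tab$qname[tab$supplementary])
  prim <- tab[supplementary == FALSE & !(qname %in% split_names)]
  m1 <- prim[mate == 1L]; m2 <- prim[mate == 2L]
  j <- m2[m1, on = "qname", nomatch = NULL]
  ## canonical order by (chrom, start), natural chromosome ranking
  fwd <- chrom_lte(j$i.chrom, j$i.start, j$chrom, j$start)
  data.table(
    name = j$qname,
    x_chrom = fifelse(fwd, j$i.chrom, j$chrom),
    x_orient = fifelse(fwd, j$i.strand, j$strand),
    x_start = fifelse(fwd, j$i.start, j$start),
    x_end = fifelse(fwd, j$i.end, j$end),
    x_mapq = fifelse(fwd, j$i.mapq, j$mapq),
    y_chrom = fifelse(fwd, j$chrom, j$i.chrom),
    y_orient = fifelse(fwd, j$strand, j$i.strand),
    y_start = fifelse(fwd, j$start, j$i.start),
    y_end = fifelse(fwd, j$end, j$i.end),
    y_mapq = fifelse(fwd, j$mapq, j$i.mapq),
    proper = j$proper & j$i.proper)
}

#' Extract split-read segments from an alignment record table
#'
#' Reads (per mate) with two or more aligned segments - a primary plus
#' supplementary records - become split-segment tables keyed by
#' `read_name = qname "/" mate`.
#'
#' @param tab An alignment record table.
#' @return A `data.table` with columns `read_name`, `chrom`, `orient`,
#'   `ref_start`, `ref_end`, `query_start`, `query_end`, `mapq`.
#' @export
splits_from_alignments <- function(tab) {
  if (nrow(tab) == 0) {
    return(data.table(read_name = character(), chrom = character(),
                      orient = character(), ref_start = numeric(),
                      ref_end = numeric(), query_start = numeric(),
                      query_end = numeric(), mapq = numeric()))
  }
  ## candidate reads: any supplementary record, or more than the two
  ## primary records expected of a fragment
  cnt <- tab[, .N, by = qname]
  cand <- union(cnt[N > 2L, qname], unique(tab$qname[tab$supplementary]))
  tab <- tab[qname %in% cand]
  if (nrow(tab) == 0) {
    return(data.table(read_name = character(), chrom = character(),
                      orient = character(), ref_start = numeric(),
                      ref_end = numeric(), query_start = numeric(),
                      query_end = numeric(), mapq = numeric()))
  }
  tab <- copy(tab)[, read_name := paste0(qname, "/", mate)]
  nseg <- tab[, .N, by = read_name]
  splitr <- nseg[N >= 2L, read_name]
  seg <- tab[read_name %in% splitr]
  data.table(read_name = seg$read_name, chrom = seg$chrom,
             orient = seg$strand, ref_start = seg$start, ref_end = seg$end,
             query_start = seg$query_start, query_end = seg$query_end,
             mapq = seg$mapq)
}

## ---------------------------------------------------------------------------
## SAM writing (alignment record table -> SAM text)

sam_flag <- function(tab, mate_strand) {
  flag <- 1L +                                   # paired
    fifelse(tab$proper, 2L, 0L) +
    fifelse(tab$strand == "-", 16L, 0L) +
    fifelse(mate_strand == "-", 32L, 0L) +
    fifelse(tab$mate == 1L, 64L, 128L) +
    fifelse(tab$supplementary, 2048L, 0L)
  flag
}

build_cigar <- function(strand, query_start, query_end, read_len) {
  ## idealized gapless records: one M run plus soft clips; for reverse
  ## strand records SAM stores the clip lengths in reversed query order
  lead <- ifelse(strand == "+", query_start, read_len - query_end)
  m <- query_end - query_start
  trail <- read_len - m - lead
  paste0(ifelse(lead > 0, paste0(lead, "S"), ""), m, "M",
         ifelse(trail > 0, paste0(trail, "S"), ""))
}

#' Write an alignment record table as SAM
#'
#' Emits a coordinate-sorted SAM file with proper `@SQ`/`@HD` headers, mate
#' fields, TLEN and SA tags for split reads.  Sequences and qualities are
#' written as `*` (the records are coordinate-level).
#'
#' @param tab An alignment record table.
#' @param path Output path.
#' @param chrom_lengths Named vector of chromosome lengths for the header.
#' @return `path`, invisibly.
#' @export
write_sam <- function(tab, path, chrom_lengths) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  tab <- copy(tab)
  setorder(tab, chrom, start, qname, mate, -supplementary)
  ## mate (primary) coordinates per qname
  prim <- tab[supplementary == FALSE]
  mates <- prim[, .(qname, mate, chrom, start, end, strand)]
  other <- copy(mates)[, mate := fifelse(mate == 1L, 2L, 1L)]
  setnames(other, c("chrom", "start", "end", "strand"),
           c("mchrom", "mstart", "mend", "mstrand"))
  tab <- other[tab, on = c("qname", "mate")]
  tab[is.na(mchrom), `:=`(mchrom = "*", mstart = -1, mstrand = "+")]
  tlen <- fifelse(tab$mchrom == tab$chrom & tab$mchrom != "*",
                  fifelse(tab$start <= tab$mstart,
                          tab$mend - tab$start, -(tab$end - tab$mstart)),
                  0)
  cigar <- build_cigar(tab$strand, tab$query_start, tab$query_end,
                       tab$read_len)
  ## SA tags on records of split reads
  tab[, segid := paste0(qname, "/", mate)]
  nseg <- tab[, .N, by = segid]
  sa_needed <- nseg[N >= 2L, segid]
  sa <- rep("", nrow(tab))
  if (length(sa_needed)) {
    tab[, row := .I]
    sadt <- tab[segid %in% sa_needed,
                .(row, segid, part = sprintf("%s,%d,%s,%s,%d,0;", chrom,
                                             as.integer(start) + 1L, strand,
                                             cigar[row], as.integer(mapq)))]
    satag <- sadt[, .(tag = paste0("SA:Z:", paste(part, collapse = ""))),
                  by = segid]
    ## each record's SA lists the *other* segments; for simplicity list all
    sa[sadt$row] <- satag$tag[match(sadt$segid, satag$segid)]
  }
  rnext <- fifelse(tab$mchrom == tab$chrom & tab$mchrom != "*", "=",
                   tab$mchrom)
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t*\t*%s",
                   tab$qname, sam_flag(tab, tab$mstrand), tab$chrom,
                   as.integer(tab$start) + 1L, as.integer(tab$mapq), cigar,
                   rnext, as.integer(tab$mstart) + 1L, as.integer(tlen),
                   ifelse(sa == "", "", paste0("\t", sa)))
  con <- file(path, "wb")            # binary mode: LF endings, stable bytes
  on.exit(close(con))
  writeLines(c(hdr, lines), con, sep = "\n")
  invisible(path)
}

## ---------------------------------------------------------------------------
## BEDPE call output

strand_by_variety <- function(variety) {
  switch(variety, DELETION = c("+", "-"), DUPLICATION = c("-", "+"),
         c(".", "."))
}

#' Write SV calls as BEDPE
#'
#' One record per call: the (trimmed) breakpoint intervals as the two
#' coordinate blocks, total evidence weight as the score, the variety in
#' the `type` column, then auxiliary columns with per-sample support,
#' per-source evidence counts, 95% credible intervals and maximum
#' positions.  With `emit_distributions = TRUE` two final columns carry the
#' comma-serialized probability vectors.
#'
#' @param calls List of `sv_call` objects.
#' @param path Output path.
#' @param emit_distributions Serialize the probability vectors (default
#'   FALSE).
#' @return `path`, invisibly.
#' @export
write_bedpe_calls <- function(calls, path, emit_distributions = FALSE) {
  fmt <- function(x, i) {
    strands <- strand_by_variety(x$variety)
    base <- sprintf(
      "%s\t%d\t%d\t%s\t%d\t%d\t%s\t%g\t%s\t%s\t%s\t%s\t%s\t%d,%d;%d,%d\t%d,%d",
      x$left$chrom, as.integer(x$left$start), as.integer(x$left$end),
      x$right$chrom, as.integer(x$right$start), as.integer(x$right$end),
      sprintf("call_%d;TYPE:%s", i, x$variety), x$total_weight,
      strands[1], strands[2], x$variety,
      paste(sprintf("%s:%g", names(x$per_sample_support),
                    x$per_sample_support), collapse = ";"),
      paste(sprintf("%s:%d", names(x$evidence_counts),
                    as.integer(x$evidence_counts)), collapse = ";"),
      as.integer(x$ci95_left[1]), as.integer(x$ci95_left[2]),
      as.integer(x$ci95_right[1]), as.integer(x$ci95_right[2]),
      as.integer(x$max_left), as.integer(x$max_right))
    if (emit_distributions) {
      base <- paste0(base, "\t", paste(signif(x$left$p, 6), collapse = ","),
                     "\t", paste(signif(x$right$p, 6), collapse = ","))
    }
    base
  }
  lines <- if (length(calls)) {
    vapply(seq_along(calls), function(i) fmt(calls[[i]], i), "")
  } else character()
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a bedgraph depth track
#'
#' @param path bedgraph path (chrom, start, end, depth; no header).
#' @return A `data.table` with those four columns.
#' @export
read_bedgraph <- function(path) {
  tab <- data.table::fread(path, header = FALSE, sep = "\t",
                           col.names = c("chrom", "start", "end", "depth"))
  if (nrow(tab) == 0) stop("read_bedgraph: empty depth track")
  tab
}
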