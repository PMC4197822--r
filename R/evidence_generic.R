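## Generic evidence: externally supplied breakpoint intervals (known
## variants, third-party CNV segmentations) injected via BEDPE/BED files.
## Priors carry a uniform probability over each interval (the files encode
## intervals only, no shape) and corroborate read-derived clusters; with
## weight below the calling threshold they cannot create a call alone.

parse_variety_token <- function(type_col, name_col) {
  v <- toupper(trimws(type_col))
  v[v == "TRANSLOCATION"] <- "INTERCHROM"
  bad <- !(v %in% VARIETIES)
  if (any(bad)) {
    ## fall back to a "TYPE:" token in the name column
    hit <- regexpr("TYPE:[A-Za-z]+", name_col)
    tok <- rep(NA_character_, length(v))
    tok[hit > 0] <- toupper(sub("TYPE:", "", regmatches(name_col, hit)))
    tok[!is.na(tok) & tok == "TRANSLOCATION"] <- "INTERCHROM"
    v[bad] <- tok[bad]
    v[!(v %in% VARIETIES)] <- NA
  }
  v
}

#' Read BEDPE prior evidence
#'
#' Each record of a 10+-column BEDPE file (chrom1, start1, end1, chrom2,
#' start2, end2, name, score, strand1, strand2, \[type\]) becomes one piece
#' of breakpoint evidence with uniform probability over each (optionally
#' padded) interval.  The variety is read from the 11th column when
#' present, else from a `TYPE:` token in the name column; `TRANSLOCATION`
#' maps to `INTERCHROM`.
#'
#' @param path BEDPE file path.
#' @param weight Evidence weight for every record (default 1).
#' @param sample_id Sample identifier.
#' @param pad Bases added on both sides of each interval (default 0).
#' @return A list of [bp_evidence] with `source = "GENERIC"`.
#' @export
read_generic_evidence <- function(path, weight = 1, sample_id = "PRIOR",
                                  pad = 0) {
  if (!file.exists(path)) stop("read_generic_evidence: no such file: ", path)
  tab <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (ncol(tab) < 10)
    stop("read_generic_evidence: BEDPE needs >= 10 columns, got ", ncol(tab))
  variety <- parse_variety_token(
    if (ncol(tab) >= 11) as.character(tab[[11]]) else rep("", nrow(tab)),
    as.character(tab[[7]]))
  if (anyNA(variety)) {
    stop("read_generic_evidence: unparseable variety at line(s) ",
         paste(which(is.na(variety)), collapse = ", "))
  }
  bad <- !(tab[[2]] < tab[[3]]) | !(tab[[5]] < tab[[6]])
  if (any(bad)) {
    stop("read_generic_evidence: malformed coordinates at line(s) ",
         paste(which(bad), collapse = ", "))
  }
  lapply(seq_len(nrow(tab)), function(i) {
    s1 <- max(0, tab[[2]][i] - pad); e1 <- tab[[3]][i] + pad
    s2 <- max(0, tab[[5]][i] - pad); e2 <- tab[[6]][i] + pad
    bp_evidence(
      bp_interval(as.character(tab[[1]][i]), s1, e1, rep(1, e1 - s1)),
      bp_interval(as.character(tab[[4]][i]), s2, e2, rep(1, e2 - s2)),
      variety = variety[i], weight = weight, sample_id = sample_id,
      source = "GENERIC")
  })
}

#' Convert CNV segmentation calls to breakpoint evidence
#'
#' Read-depth segmentations locate copy-number change at segment edges.  A
#' copy-loss segment becomes DELETION evidence (a copy-gain segment
#' DUPLICATION evidence) whose left interval brackets the segment start
#' and whose right interval brackets the segment end, each extended by
#' half the segmentation window on both sides, with uniform probability.
#'
#' @param segment_bed Path to a BED file with columns chrom, start, end,
#'   label, where label contains `loss`/`deletion`/`del` or
#'   `gain`/`duplication`/`dup` (case-insensitive).
#' @param window Segmentation window size in bases; each breakpoint
#'   interval is `[edge - window/2, edge + window/2)`.  Must be >= 2 so the
#'   intervals are non-degenerate.
#' @param weight Evidence weight (default 1).
#' @param sample_id Sample identifier.
#' @return A list of [bp_evidence] with `source = "GENERIC"`.
#' @export
cnv_calls_to_evidence <- function(segment_bed, window, weight = 1,
                                  sample_id = "CNV") {
  if (window < 2)
    stop("cnv_calls_to_evidence: window must be >= 2 (degenerate intervals)")
  tab <- data.table::fread(segment_bed, header = FALSE, sep = "\t",
                           fill = TRUE)
  if (ncol(tab) < 4)
    stop("cnv_calls_to_evidence: need chrom/start/end/label columns")
  lab <- tolower(as.character(tab[[4]]))
  variety <- rep(NA_character_, nrow(tab))
  variety[grepl("loss|deletion|^del", lab)] <- "DELETION"
  variety[grepl("gain|duplication|^dup", lab)] <- "DUPLICATION"
  if (anyNA(variety)) {
    stop("cnv_calls_to_evidence: unlabeled row(s) ",
         paste(which(is.na(variety)), collapse = ", "))
  }
  half <- window / 2
  lapply(seq_len(nrow(tab)), function(i) {
    s <- tab[[2]][i]; e <- tab[[3]][i]
    l1 <- max(0, floor(s - half)); l2 <- floor(s + half)
    r1 <- max(0, floor(e - half)); r2 <- floor(e + half)
    bp_evidence(
      bp_interval(as.character(tab[[1]][i]), l1, l2, rep(1, l2 - l1)),
      bp_interval(as.character(tab[[1]][i]), r1, r2, rep(1, r2 - r1)),
      variety = variety[i], weight = weight, sample_id = sample_id,
      source = "GENERIC")
  })
}
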