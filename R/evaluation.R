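## Benchmarking: match calls against simulated truth and compute
## sensitivity and false discovery rate under the both-interval,
## type-matched overlap rule.

#' Pad truth breakpoints with bidirectional slop
#'
#' Each simulated breakpoint coordinate is expanded by `slop` bases on
#' both sides, so a point breakpoint becomes a ~100 bp interval at the
#' default slop of 50 - accounting for the varied spatial resolution of
#' SV callers.
#'
#' @param truth A truth `data.table` with `pos1`/`pos2` point columns (as
#'   from [simulate_variants()]) or `start1`/`end1`/`start2`/`end2`
#'   interval columns.
#' @param slop Padding in bases (default 50).
#' @return A `data.table` with `chrom1`, `start1`, `end1`, `chrom2`,
#'   `start2`, `end2`, `variety`, `variant_id`.
#' @export
pad_truth <- function(truth, slop = 50) {
  tr <- as.data.table(truth)
  if ("pos1" %in% names(tr)) {
    out <- tr[, .(chrom1, start1 = pos1 - slop, end1 = pos1 + slop,
                  chrom2, start2 = pos2 - slop, end2 = pos2 + slop,
                  variety,
                  variant_id = if ("variant_id" %in% names(tr)) variant_id
                    else sprintf("t%d", .I))]
  } else {
    out <- tr[, .(chrom1, start1 = start1 - slop, end1 = end1 + slop,
                  chrom2, start2 = start2 - slop, end2 = end2 + slop,
                  variety,
                  variant_id = if ("variant_id" %in% names(tr)) variant_id
                    else sprintf("t%d", .I))]
  }
  out[, `:=`(start1 = pmax(start1, 0), start2 = pmax(start2, 0))]
  ## canonical side order, matching how calls are reported
  swap <- !chrom_lte(out$chrom1, out$start1, out$chrom2, out$start2)
  if (any(swap)) {
    tmp <- out[swap, .(chrom1, start1, end1)]
    out[swap, `:=`(chrom1 = chrom2, start1 = start2, end1 = end2)]
    out[swap, `:=`(chrom2 = tmp$chrom1, start2 = tmp$start1,
                   end2 = tmp$end1)]
  }
  out[]
}

#' Convert finalized calls to a benchmarking table
#'
#' @param calls List of `sv_call` objects.
#' @return `data.table` with the two (trimmed) call intervals, variety and
#'   a `has_split`/`has_pair` flag per call.
#' @export
calls_to_table <- function(calls) {
  if (length(calls) == 0) {
    return(data.table(chrom1 = character(), start1 = numeric(),
                      end1 = numeric(), chrom2 = character(),
                      start2 = numeric(), end2 = numeric(),
                      variety = character(), total_weight = numeric(),
                      has_split = logical(), has_pair = logical()))
  }
  data.table(
    chrom1 = vapply(calls, function(x) x$left$chrom, ""),
    start1 = vapply(calls, function(x) x$left$start, 0),
    end1 = vapply(calls, function(x) x$left$end, 0),
    chrom2 = vapply(calls, function(x) x$right$chrom, ""),
    start2 = vapply(calls, function(x) x$right$start, 0),
    end2 = vapply(calls, function(x) x$right$end, 0),
    variety = vapply(calls, function(x) x$variety, ""),
    total_weight = vapply(calls, function(x) x$total_weight, 0),
    has_split = vapply(calls, function(x)
      "SPLITREAD" %in% names(x$evidence_counts), TRUE),
    has_pair = vapply(calls, function(x)
      "READPAIR" %in% names(x$evidence_counts), TRUE))
}

#' Pad single-base calls from point-resolution callers
#'
#' External callers reporting single-base breakpoints are widened to the
#' mean interval size of comparable probabilistic calls before matching:
#' split-read-supported calls to `sr_pad` bases, pair-only calls to
#' `pe_pad` bases, centered on the point.  Calls that are already wider
#' than one base are left unchanged.
#'
#' @param calls A call `data.table` (see [calls_to_table()]).
#' @param sr_pad,pe_pad Target interval sizes (defaults 28 and 282).
#' @return The padded call table.
#' @export
pad_point_calls <- function(calls, sr_pad = 28, pe_pad = 282) {
  calls <- copy(as.data.table(calls))
  pad <- fifelse(calls$has_split, sr_pad, pe_pad)
  for (side in c(1, 2)) {
    s <- calls[[paste0("start", side)]]
    e <- calls[[paste0("end", side)]]
    point <- (e - s) <= 1
    ctr <- s
    ns <- fifelse(point, pmax(ctr - floor(pad / 2), 0), s)
    ne <- fifelse(point, ns + pad, e)
    set(calls, j = paste0("start", side), value = ns)
    set(calls, j = paste0("end", side), value = ne)
  }
  calls[]
}

#' Match calls against padded truth
#'
#' A call is a true positive iff both of its breakpoint intervals
#' intersect the two intervals of one truth record and the SV types
#' match.  Each call is assigned to at most one truth record (greedy by
#' total overlap); each truth *variant* counts once toward sensitivity no
#' matter how many calls or adjacencies hit it (a variant with several
#' truth adjacencies, e.g. an inversion, is detected when any of them is
#' matched).  Unmatched calls are false positives; by default extra calls
#' on an already-hit truth record are collapsed (neither TP nor FP), with
#' `strict = TRUE` they count as FP.
#'
#' @param calls A call `data.table` (or list of `sv_call`).
#' @param padded_truth Output of [pad_truth()].
#' @param strict Count duplicate hits as false positives (default FALSE).
#' @return A `benchmark_result`: `n_truth` (variants), `n_calls`,
#'   `true_positives` (variants detected), `false_positives`,
#'   `sensitivity`, `fdr` (NA when no calls).
#' @export
match_calls <- function(calls, padded_truth, strict = FALSE) {
  if (is.list(calls) && !is.data.frame(calls)) calls <- calls_to_table(calls)
  calls <- as.data.table(calls)
  tr <- as.data.table(padded_truth)
  n_variants <- length(unique(tr$variant_id))
  hit_variant <- character(0)
  matched_record <- rep(FALSE, nrow(tr))
  fp <- 0L
  dup <- 0L
  for (i in seq_len(nrow(calls))) {
    cand <- which(tr$variety == calls$variety[i] &
                  tr$chrom1 == calls$chrom1[i] &
                  tr$chrom2 == calls$chrom2[i] &
                  tr$start1 < calls$end1[i] & calls$start1[i] < tr$end1 &
                  tr$start2 < calls$end2[i] & calls$start2[i] < tr$end2)
    if (length(cand) == 0) { fp <- fp + 1L; next }
    if (length(cand) > 1) {
      ov <- pmin(tr$end1[cand], calls$end1[i]) -
        pmax(tr$start1[cand], calls$start1[i]) +
        pmin(tr$end2[cand], calls$end2[i]) -
        pmax(tr$start2[cand], calls$start2[i])
      cand <- cand[which.max(ov)]
    }
    if (matched_record[cand]) dup <- dup + 1L
    matched_record[cand] <- TRUE
    hit_variant <- c(hit_variant, tr$variant_id[cand])
  }
  tp <- length(unique(hit_variant))
  if (strict) fp <- fp + dup
  sens <- if (n_variants > 0) tp / n_variants else NA_real_
  fdr <- if (nrow(calls) == 0) NA_real_
    else if (tp + fp == 0) 1 else fp / (tp + fp)
  structure(list(n_truth = n_variants, n_calls = nrow(calls),
                 true_positives = tp, false_positives = fp,
                 sensitivity = sens, fdr = fdr),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf(paste0("<benchmark_result> truth=%d calls=%d TP=%d FP=%d ",
                     "sensitivity=%.3f FDR=%s\n"),
              x$n_truth, x$n_calls, x$true_positives, x$false_positives,
              x$sensitivity,
              if (is.na(x$fdr)) "NA" else sprintf("%.3f", x$fdr)))
  invisible(x)
}
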