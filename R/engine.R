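## Orchestration: streaming evidence collection, transitive cluster
## merging, thresholding (single-sample, weighted, multi-sample/trio),
## excluded-region filtering and call emission.

#' Calling thresholds
#'
#' @param min_total_weight Minimum total evidence weight for a call
#'   (default 4).
#' @param per_sample_min Optional named numeric: a cluster passes when at
#'   least one named sample contributes at least its stated weight (the
#'   trio rule: "support of four from at least one individual").
#' @param required_samples Optional character vector of samples that must
#'   each contribute positive weight.
#' @param mode `"product"` (default) or `"sum"` finalization.
#' @param trim_keep Mass retained by distribution trimming (default 0.999).
#' @return A `calling_thresholds` list.
#' @export
calling_thresholds <- function(min_total_weight = 4, per_sample_min = NULL,
                               required_samples = NULL,
                               mode = c("product", "sum"),
                               trim_keep = 0.999) {
  stopifnot(min_total_weight > 0)
  structure(list(min_total_weight = min_total_weight,
                 per_sample_min = per_sample_min,
                 required_samples = required_samples,
                 mode = match.arg(mode), trim_keep = trim_keep),
            class = "calling_thresholds")
}

#' Does a cluster meet the calling thresholds?
#'
#' @param cluster A `bp_cluster`, or any list with `weights` and `samples`
#'   vectors (one entry per evidence item).
#' @param t A [calling_thresholds].
#' @return `TRUE` iff total weight, per-sample minima and required-sample
#'   rules are all satisfied.
#' @export
apply_thresholds <- function(cluster, t) {
  if (inherits(cluster, "bp_cluster")) {
    weights <- vapply(cluster$evidence, `[[`, 0, "weight")
    samples <- vapply(cluster$evidence, `[[`, "", "sample_id")
  } else {
    weights <- cluster$weights; samples <- cluster$samples
  }
  if (sum(weights) < t$min_total_weight) return(FALSE)
  per_sample <- vapply(split(weights, samples), sum, 0)
  if (!is.null(t$per_sample_min)) {
    got <- per_sample[names(t$per_sample_min)]
    got[is.na(got)] <- 0
    if (!any(got >= t$per_sample_min)) return(FALSE)
  }
  if (!is.null(t$required_samples)) {
    if (!all(t$required_samples %in% names(per_sample))) return(FALSE)
    if (!all(per_sample[t$required_samples] > 0)) return(FALSE)
  }
  TRUE
}

## ---------------------------------------------------------------------------
## Sweep clustering

#' Cluster an evidence stream by transitive intersection
#'
#' Evidence items cluster when they agree in variety and chromosome pair
#' and their breakpoint intervals intersect on *both* sides; membership is
#' the transitive closure of this pairwise relation, so the result is
#' independent of arrival order.  The stream must be sorted by
#' `(left chromosome, left start)`: the sweep retires a member once the
#' sweep position passes its left end, and closes a cluster when all its
#' members are retired, which makes the streaming output identical to the
#' batch fixed point.
#'
#' @param tab An evidence table sorted by `(l_chrom, l_start)` under the
#'   natural chromosome order.
#' @return A list of clusters; each has `idx` (row indices into `tab`),
#'   floored per-side mean bounds `l_start`, `l_end`, `r_start`, `r_end`,
#'   plus `variety`, `l_chrom`, `r_chrom`, `weights`, `samples`.
#' @export
sweep_cluster <- function(tab) {
  n <- nrow(tab)
  if (n == 0) return(list())
  key <- chrom_rank_key(tab$l_chrom)
  if (n > 1) {
    ok <- key[-1] > key[-n] |
      (key[-1] == key[-n] & tab$l_start[-1] >= tab$l_start[-n])
    if (!all(ok))
      stop("sweep_cluster: evidence not sorted by (l_chrom, l_start)")
  }
  out <- list()
  groups <- split(seq_len(n), paste(tab$variety, tab$l_chrom, tab$r_chrom,
                                    sep = "\r"))
  for (g in groups) {
    if (is.unsorted(tab$l_start[g]))
      stop("sweep_cluster: evidence not sorted by (l_chrom, l_start)")
    out <- c(out, sweep_group(tab, g))
  }
  ## deterministic output order by merged left bound
  if (length(out) > 1) {
    k <- order(chrom_rank_key(vapply(out, `[[`, "", "l_chrom")),
               vapply(out, `[[`, 0, "l_start"))
    out <- out[k]
  }
  out
}

sweep_group <- function(tab, rows) {
  ls <- tab$l_start[rows]; le <- tab$l_end[rows]
  rs <- tab$r_start[rows]; re <- tab$r_end[rows]
  m <- length(rows)
  comp <- integer(m)            # component id per item
  ncomp <- 0L
  active <- integer(0)          # positions (1..m) still able to intersect
  members <- list()             # per component: item positions
  open <- logical(0)            # component still open?
  for (i in seq_len(m)) {
    ## retire members the sweep has passed; close exhausted components
    if (length(active)) {
      dead <- le[active] <= ls[i]
      if (any(dead)) active <- active[!dead]
    }
    hit <- if (length(active)) {
      active[ls[i] < le[active] & ls[active] < le[i] &
             rs[i] < re[active] & rs[active] < re[i]]
    } else integer(0)
    cids <- unique(comp[hit])
    if (length(cids) == 0) {
      ncomp <- ncomp + 1L
      comp[i] <- ncomp
      members[[ncomp]] <- i
      open[ncomp] <- TRUE
    } else {
      target <- min(cids)
      comp[i] <- target
      members[[target]] <- c(members[[target]], i)
      for (cid in setdiff(cids, target)) {
        comp[members[[cid]]] <- target
        members[[target]] <- c(members[[target]], members[[cid]])
        members[[cid]] <- integer(0)
        open[cid] <- FALSE
      }
    }
    active <- c(active, i)
  }
  keep <- which(vapply(members, length, 0L) > 0)
  lapply(keep, function(cid) {
    pos <- sort(members[[cid]])
    idx <- rows[pos]
    list(idx = idx,
         l_chrom = tab$l_chrom[idx[1]], r_chrom = tab$r_chrom[idx[1]],
         variety = tab$variety[idx[1]],
         l_start = floor(mean(ls[pos])), l_end = floor(mean(le[pos])),
         r_start = floor(mean(rs[pos])), r_end = floor(mean(re[pos])),
         weights = tab$weight[idx], samples = tab$sample_id[idx])
  })
}

## ---------------------------------------------------------------------------
## Excluded regions

#' Filter evidence overlapping excluded regions
#'
#' Drops evidence whose originating alignment (either side) overlaps an
#' excluded range under half-open semantics; abutting alignments are kept.
#'
#' @param tab An evidence table.
#' @param regions A `data.table` of `chrom`, `start`, `end` (merged,
#'   non-overlapping per chromosome) or `NULL` for no filtering.
#' @return The filtered evidence table.
#' @export
filter_excluded <- function(tab, regions = NULL) {
  if (is.null(regions) || nrow(regions) == 0 || nrow(tab) == 0) return(tab)
  regions <- regions[order(chrom_rank_key(regions$chrom), regions$start)]
  hit_side <- function(chrom, s, e) {
    out <- logical(length(chrom))
    for (cn in unique(regions$chrom)) {
      rr <- regions[chrom == cn]
      sel <- which(chrom == cn)
      if (!length(sel)) next
      ## merged sorted ranges: overlap iff the last range starting at or
      ## before s extends past s, or the next range starts before e
      j <- findInterval(s[sel], rr$start)
      ov <- (j >= 1 & rr$end[pmax(j, 1)] > s[sel]) |
        (j < nrow(rr) & rr$start[pmin(j + 1, nrow(rr))] < e[sel])
      out[sel] <- ov
    }
    out
  }
  drop <- hit_side(tab$l_chrom, tab$al_start, tab$al_end) |
    hit_side(tab$r_chrom, tab$ar_start, tab$ar_end)
  tab[!drop]
}

#' Derive excluded regions from a depth track
#'
#' Regions of consistently extreme sequencing depth indicate reference
#' artifacts.  The depth mode and standard deviation are computed
#' separately for autosomes and sex chromosomes (each weighted by span
#' length); positions with depth exceeding `2 * mode + 3 * stdev` are
#' collected into merged ranges.  Doubling the mode keeps duplicated CNV
#' regions includable.  The mitochondrial chromosome is excluded entirely.
#'
#' @param depth A bedgraph `data.table` (see [read_bedgraph()]) or a path.
#' @param sex_chroms Chromosome names treated as sex chromosomes.
#' @param mito_chroms Names recognized as mitochondrial (default
#'   `c("chrM", "MT", "M")`).
#' @param chrom_lengths Optional named lengths used to emit the full
#'   mitochondrial range; otherwise the observed span is used.
#' @return A `data.table` of `chrom`, `start`, `end` exclusion ranges.
#' @export
compute_excluded_regions <- function(depth, sex_chroms = c("chrX", "chrY"),
                                     mito_chroms = c("chrM", "MT", "M"),
                                     chrom_lengths = NULL) {
  if (is.character(depth)) depth <- read_bedgraph(depth)
  if (nrow(depth) == 0) stop("compute_excluded_regions: empty depth track")
  is_mito <- depth$chrom %in% mito_chroms
  core <- depth[!is_mito]
  grp <- fifelse(core$chrom %in% sex_chroms, "sex", "auto")
  excl <- list()
  for (gname in unique(grp)) {
    d <- core[grp == gname]
    w <- d$end - d$start
    ## weighted mode: depth value covering the most bases
    tab <- d[, .(bases = sum(end - start)), by = depth]
    mode_d <- tab$depth[which.max(tab$bases)]
    mu <- sum(d$depth * w) / sum(w)
    sd_d <- sqrt(sum(w * (d$depth - mu)^2) / sum(w))
    thr <- 2 * mode_d + 3 * sd_d
    excl[[gname]] <- d[depth > thr, .(chrom, start, end)]
  }
  out <- rbindlist(excl)
  ## mitochondrial chromosome: excluded entirely
  for (mc in unique(depth$chrom[is_mito])) {
    mlen <- if (!is.null(chrom_lengths) && mc %in% names(chrom_lengths))
      chrom_lengths[[mc]] else max(depth[chrom == mc, end])
    out <- rbind(out, data.table(chrom = mc, start = 0, end = mlen))
  }
  if (nrow(out) == 0) return(out)
  merge_ranges(out)
}

## merge overlapping ranges per chromosome (sorted input not required)
merge_ranges <- function(tab) {
  tab <- tab[order(chrom_rank_key(chrom), start)]
  out <- tab[, {
    brk <- c(TRUE, start[-1] > head(cummax(end), -1))
    g <- cumsum(brk)
    dt <- data.table(s = start, e = end, g = g)
    dt[, .(start = min(s), end = max(e)), by = g][, .(start, end)]
  }, by = chrom]
  out[]
}

## ---------------------------------------------------------------------------
## Sample specifications and end-to-end calling

#' Specify one sample's evidence channels
#'
#' Each channel configuration is a list; any subset may be present.
#' * `pe`: read-pair channel.  `alignments` is an alignment record table
#'   or SAM/BAM path; the fragment library comes from `histogram` (path),
#'   `mean`+`stdev`, or is estimated from properly-paired records.
#'   Optional: `read_length`, `discordant_z` (or `v_l`/`v_f`),
#'   `back_distance`, `weight`, `min_mapping_threshold`.
#' * `sr`: split-read channel.  `alignments` as above; optional `v_s`,
#'   `decay_scale`, `min_non_overlap`, `weight`, `min_mapping_threshold`.
#' * `bedpe`: generic channel. `path` (BEDPE) or `evidence` (list of
#'   [bp_evidence]); optional `weight`, `pad`.
#'
#' @param sample_id Identifier shared across this sample's channels.
#' @param pe,sr,bedpe Channel configuration lists (or `NULL`).
#' @return A `sample_spec`.
#' @export
sample_spec <- function(sample_id, pe = NULL, sr = NULL, bedpe = NULL) {
  if (is.null(pe) && is.null(sr) && is.null(bedpe))
    stop("sample_spec: at least one evidence channel is required")
  structure(list(sample_id = sample_id, pe = pe, sr = sr, bedpe = bedpe),
            class = "sample_spec")
}

load_alignment_input <- function(x, min_mapq, sample_id) {
  if (is.character(x)) read_alignments(x, min_mapq = 0,
                                       sample_id = sample_id)
  else x
}

collect_sample_evidence <- function(spec, chrom_lengths = NULL,
                                    verbose = TRUE) {
  sid <- spec$sample_id
  ev <- list()
  note <- function(...) if (verbose) message(sprintf(...))
  if (!is.null(spec$pe)) {
    pe <- spec$pe
    aln <- load_alignment_input(pe$alignments, 0, sid)
    pairs <- pairs_from_alignments(aln)
    lib <- if (!is.null(pe$histogram)) {
      fragment_library(pe$histogram,
                       read_length = pe$read_length %||% 150)
    } else if (!is.null(pe$mean) && !is.null(pe$stdev)) {
      fragment_library_normal(pe$mean, pe$stdev,
                              read_length = pe$read_length %||% 150)
    } else {
      lens <- pairs[proper == TRUE, y_end - x_start]
      if (length(lens) < 2)
        stop("sample ", sid, ": cannot estimate fragment library ",
             "(no properly paired reads; supply histogram or mean/stdev)")
      fragment_library(lens, read_length = pe$read_length %||% 150)
    }
    cfg <- readpair_config(
      discordant_z = pe$discordant_z %||% 4,
      v_l = pe$v_l %||% pe$discordant_z %||% 4,
      v_f = pe$v_f %||% pe$discordant_z %||% 4,
      back_distance = pe$back_distance %||% 20,
      weight = pe$weight %||% 1,
      min_mapping_threshold = pe$min_mapping_threshold %||% 1,
      sample_id = sid)
    tab <- readpair_evidence_table(pairs, lib, cfg, chrom_lengths)
    note("[%s/pe] %d pairs -> %d discordant evidence", sid, nrow(pairs),
         nrow(tab))
    ev <- c(ev, list(tab))
  }
  if (!is.null(spec$sr)) {
    sr <- spec$sr
    aln <- load_alignment_input(sr$alignments, 0, sid)
    segs <- splits_from_alignments(aln)
    cfg <- splitread_config(
      v_s = sr$v_s %||% sr$back_distance %||% 20,
      decay_scale = sr$decay_scale %||% (sr$v_s %||% sr$back_distance %||% 20) / 4,
      min_non_overlap = sr$min_non_overlap %||% 150,
      weight = sr$weight %||% 1,
      min_mapping_threshold = sr$min_mapping_threshold %||% 1,
      sample_id = sid)
    tab <- splitread_evidence_table(segs, cfg, chrom_lengths)
    note("[%s/sr] %d segments -> %d split evidence", sid, nrow(segs),
         nrow(tab))
    ev <- c(ev, list(tab))
  }
  if (!is.null(spec$bedpe)) {
    bp <- spec$bedpe
    items <- if (!is.null(bp$evidence)) bp$evidence
      else read_generic_evidence(bp$path, weight = bp$weight %||% 1,
                                 sample_id = sid, pad = bp$pad %||% 0)
    tab <- evidence_table(items)
    note("[%s/bedpe] %d prior evidence", sid, nrow(tab))
    ev <- c(ev, list(tab))
  }
  rbindlist(ev)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Call structural variants end to end
#'
#' Runs the full pipeline: evidence extraction from every channel of every
#' sample, excluded-region filtering, coordinate sorting, transitive sweep
#' clustering, thresholding and finalization (trimmed product by default).
#'
#' @param samples A [sample_spec] or list of them.
#' @param thresholds A [calling_thresholds] (default: minimum weight 4,
#'   product mode).
#' @param exclusions Optional exclusion ranges (`data.table` of
#'   chrom/start/end, or a BED path).
#' @param chrom_lengths Optional named chromosome lengths for interval
#'   clipping.
#' @param verbose Log per-channel counts to standard error (default TRUE).
#' @return A list of `sv_call` objects sorted by coordinate.
#' @export
call_structural_variants <- function(samples,
                                     thresholds = calling_thresholds(),
                                     exclusions = NULL,
                                     chrom_lengths = NULL, verbose = TRUE) {
  if (inherits(samples, "sample_spec")) samples <- list(samples)
  if (is.character(exclusions)) {
    exclusions <- data.table::fread(exclusions, header = FALSE,
                                    col.names = c("chrom", "start", "end"))
  }
  note <- function(...) if (verbose) message(sprintf(...))
  ev <- rbindlist(lapply(samples, collect_sample_evidence,
                         chrom_lengths = chrom_lengths, verbose = verbose))
  n0 <- nrow(ev)
  ev <- filter_excluded(ev, exclusions)
  note("[engine] %d evidence (%d removed by exclusions)", nrow(ev),
       n0 - nrow(ev))
  if (nrow(ev) == 0) return(list())
  setorderv(ev[, rank_key := chrom_rank_key(l_chrom)],
            c("rank_key", "l_start"))
  ev[, rank_key := NULL]
  clusters <- sweep_cluster(ev)
  pass <- Filter(function(cl) apply_thresholds(cl, thresholds), clusters)
  note("[engine] %d clusters, %d above threshold", length(clusters),
       length(pass))
  calls <- lapply(pass, function(cl) {
    members <- evidence_list(ev[cl$idx])
    if (thresholds$mode == "product") {
      res <- finalize_members(members, "product", thresholds$trim_keep)
      if (is.null(res)) res <- product_fallback(members, thresholds$trim_keep)
      res
    } else {
      finalize_members(members, "sum", thresholds$trim_keep)
    }
  })
  if (length(calls) > 1) {
    k <- order(chrom_rank_key(vapply(calls, function(x) x$left$chrom, "")),
               vapply(calls, function(x) x$left$start, 0))
    calls <- calls[k]
  }
  note("[engine] %d calls", length(calls))
  calls
}
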