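#' Copy-number calling thresholds
#'
#' Log2-ratio cutoffs for per-clone state calls. A clone is called a
#' high-level amplification when its ratio exceeds `amp_min`; the
#' default of 1 log2 unit corresponds to a tumor/reference ratio above
#' 2, and 1.5 is the conventional alternate preset for whole-genome
#' platforms. Single-copy loss/gain bounds of +/-0.25 log2 are the
#' usual aCGH convention; they are configurable because different
#' platforms place them differently.
#'
#' @param loss_max Call loss at or below this ratio (default -0.25).
#' @param gain_min Call gain above this ratio (default +0.25).
#' @param amp_min Call amplification above this ratio (default +1.0).
#' @return An object of class `call_thresholds`.
#' @export
call_thresholds <- function(loss_max = -0.25, gain_min = 0.25, amp_min = 1.0) {
  if (!is_number(loss_max) || !is_number(gain_min) || !is_number(amp_min)) {
    stopf("thresholds must be finite numbers")
  }
  if (!(loss_max < 0 && 0 < gain_min && gain_min < amp_min)) {
    stopf("require loss_max < 0 < gain_min < amp_min")
  }
  structure(list(loss_max = loss_max, gain_min = gain_min, amp_min = amp_min),
            class = "call_thresholds")
}

#' Per-clone copy-number state calls
#'
#' Pure per-clone thresholding of log2 ratios (no segmentation or
#' smoothing): `amp` if value > `amp_min`, `gain` if
#' `gain_min` < value <= `amp_min`, `loss` if value <= `loss_max`,
#' otherwise `neutral`; `NA` values give `missing`.
#'
#' @param values Numeric vector or matrix of log2 ratios (a profile, or
#'   a clones-by-tumors matrix), or a [cgh_cohort()].
#' @param thresholds A [call_thresholds()] object.
#' @return Character vector/matrix of states, same shape as the input.
#' @export
call_clone_states <- function(values, thresholds = call_thresholds()) {
  if (inherits(values, "cgh_cohort")) values <- values$log2
  st <- ifelse(is.na(values), "missing",
        ifelse(values > thresholds$amp_min, "amp",
        ifelse(values > thresholds$gain_min, "gain",
        ifelse(values <= thresholds$loss_max, "loss", "neutral"))))
  if (is.matrix(values)) dimnames(st) <- dimnames(values) else names(st) <- names(values)
  st
}

#' Binned loss/gain frequency map
#'
#' Divides each chromosome into `bin_size` windows and, per bin,
#' reports the fraction of tumors with at least one clone called loss
#' (resp. gain-or-amplified: an amplified clone is also a copy-number
#' increase). The denominator is the number of tumors with at least
#' one informative (non-missing) clone in the bin; bins never covered
#' by an informative clone are reported with `NA` frequencies rather
#' than zero. A tumor counts at most once per bin per state, which
#' makes the map robust to uneven clone density.
#'
#' @param cohort A [cgh_cohort()].
#' @param bin_size Bin width in bp (default 2e6).
#' @param thresholds A [call_thresholds()].
#' @return data.frame with columns chrom, start, end (bp, half-open
#'   bin bounds), n_informative, n_loss, n_gain, loss_freq, gain_freq.
#' @export
aberration_frequency <- function(cohort, bin_size = 2e6,
                                 thresholds = call_thresholds()) {
  if (!is_number(bin_size) || bin_size <= 0) stopf("bin_size must be > 0")
  clones <- cohort$clones
  states <- call_clone_states(cohort$log2, thresholds)
  chroms <- unique(as.character(GenomicRanges::seqnames(clones)))
  out <- list()
  for (ch in chroms) {
    on_ch <- as.character(GenomicRanges::seqnames(clones)) == ch
    span_end <- max(GenomicRanges::end(clones[on_ch]))
    starts <- seq(0, span_end - 1, by = bin_size)
    ends <- pmin(starts + bin_size, span_end)
    bins <- GRanges(ch, IRanges(starts + 1, ends))
    hits <- findOverlaps(bins, clones[on_ch])
    idx_all <- which(on_ch)
    n_t <- ncol(states)
    n_inf <- n_loss <- n_gain <- integer(length(bins))
    for (b in seq_along(bins)) {
      cl <- idx_all[subjectHits(hits)[queryHits(hits) == b]]
      if (!length(cl)) next
      st <- states[cl, , drop = FALSE]
      inf <- colSums(st != "missing") > 0
      n_inf[b] <- sum(inf)
      n_loss[b] <- sum(inf & colSums(st == "loss") > 0)
      n_gain[b] <- sum(inf & colSums(st == "gain" | st == "amp") > 0)
    }
    out[[ch]] <- data.frame(
      chrom = ch, start = starts, end = ends,
      n_informative = n_inf, n_loss = n_loss, n_gain = n_gain,
      loss_freq = ifelse(n_inf > 0, n_loss / n_inf, NA_real_),
      gain_freq = ifelse(n_inf > 0, n_gain / n_inf, NA_real_),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-clone high-level amplification frequency
#'
#' For every clone: the number of tumors whose log2 ratio exceeds
#' `amp_min`, over the number of tumors informative at that clone.
#'
#' @inheritParams aberration_frequency
#' @return data.frame with clone_id, chrom, start, end, n_amp,
#'   n_informative and freq columns, in clone-map order.
#' @export
amplification_frequency <- function(cohort, thresholds = call_thresholds()) {
  states <- call_clone_states(cohort$log2, thresholds)
  n_amp <- rowSums(states == "amp")
  n_inf <- rowSums(states != "missing")
  cl <- cohort$clones
  data.frame(
    clone_id = names(cl),
    chrom = as.character(GenomicRanges::seqnames(cl)),
    start = GenomicRanges::start(cl) - 1,
    end = GenomicRanges::end(cl),
    n_amp = n_amp, n_informative = n_inf,
    freq = ifelse(n_inf > 0, n_amp / n_inf, NA_real_),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Extract amplified segments from one profile
#'
#' Finds maximal runs of consecutive amplification-state clones along
#' each chromosome (clone-map order). Runs separated by at most
#' `max_gap_clones` non-amplified clones are merged -- useful on tiling
#' arrays where a single noisy clone may interrupt an amplicon. The
#' segment spans from the start of its first clone to the end of its
#' last.
#'
#' @param cohort A [cgh_cohort()].
#' @param tumor_id Column of the cohort to segment (default: all).
#' @param thresholds A [call_thresholds()].
#' @param max_gap_clones Merge runs separated by at most this many
#'   non-amp clones (default 0).
#' @return A `GRanges` of segments with mcols `tumor_id`, `n_clones`
#'   and `peak_log2`; empty when no clone is amplified.
#' @export
extract_amplicons <- function(cohort, tumor_id = colnames(cohort$log2),
                              thresholds = call_thresholds(),
                              max_gap_clones = 0L) {
  stopifnot(is_count(max_gap_clones))
  clones <- cohort$clones
  chrom <- as.character(GenomicRanges::seqnames(clones))
  segs <- list()
  for (tid in tumor_id) {
    vals <- cohort$log2[, tid]
    amp <- !is.na(vals) & vals > thresholds$amp_min
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      runs <- amp_runs(amp[idx], max_gap_clones)
      for (r in runs) {
        first <- idx[r[1L]]; last <- idx[r[2L]]
        run_idx <- idx[r[1L]:r[2L]]
        segs[[length(segs) + 1L]] <- GRanges(
          ch,
          IRanges(GenomicRanges::start(clones)[first],
                  GenomicRanges::end(clones)[last]),
          tumor_id = tid,
          n_clones = sum(amp[run_idx]),
          peak_log2 = max(vals[run_idx], na.rm = TRUE)
        )
      }
    }
  }
  if (!length(segs)) {
    empty <- GRanges()
    mcols(empty) <- S4Vectors::DataFrame(tumor_id = character(0),
                                         n_clones = integer(0),
                                         peak_log2 = numeric(0))
    return(empty)
  }
  do.call(c, segs)
}

# maximal runs of TRUE, merging runs separated by <= max_gap FALSEs;
# returns list of c(first, last) indices
amp_runs <- function(flag, max_gap) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values)
  if (!length(hit)) return(list())
  runs <- list(c(starts[hit[1L]], ends[hit[1L]]))
  for (h in hit[-1L]) {
    gap <- starts[h] - runs[[length(runs)]][2L] - 1L
    if (gap <= max_gap) {
      runs[[length(runs)]][2L] <- ends[h]
    } else {
      runs[[length(runs) + 1L]] <- c(starts[h], ends[h])
    }
  }
  runs
}

#' Minimal common region of per-tumor amplicons
#'
#' Computes the consensus (minimal common) region: the interval shared
#' by every amplicon-bearing tumor, i.e. the intersection over tumors
#' of the union of each tumor's segments. If the strict intersection
#' is empty, the maximal-support region is returned instead (the
#' widest interval covered by the largest number of tumors), with
#' `support` reporting how many tumors actually contain it.
#'
#' @param segments A `GRanges` with a `tumor_id` mcol (as returned by
#'   [extract_amplicons()]), or a named list of per-tumor `GRanges`.
#' @param min_support `"all"` (default) for the strict intersection,
#'   or an integer number of tumors.
#' @return A list of class `consensus_region`: chrom, start, end (bp,
#'   1-based closed), width_bp, width_mb, support,
#'   supporting_tumor_ids.
#' @export
consensus_region <- function(segments, min_support = "all") {
  per_tumor <- split_by_tumor(segments)
  if (!length(per_tumor) || all(vapply(per_tumor, length, 1L) == 0L)) {
    stopf("no amplicons to intersect")
  }
  per_tumor <- per_tumor[vapply(per_tumor, length, 1L) > 0L]
  n <- length(per_tumor)
  want <- if (identical(min_support, "all")) n else as.integer(min_support)
  if (want > n) stopf("min_support exceeds the %d contributing tumors", n)
  reduced <- lapply(per_tumor, function(gr) reduce(unname(gr)))
  cov <- coverage(do.call(c, unname(reduced)))
  # strict intersection first; if empty under min_support = "all", fall
  # back to the maximal-support region and report its actual support
  floor_support <- if (identical(min_support, "all")) 1L else want
  best <- NULL
  for (support in seq(n, floor_support, by = -1L)) {
    sl <- IRanges::slice(cov, lower = support, rangesOnly = TRUE)
    hits <- unlist(sl)
    if (length(hits) == 0L) next
    chroms <- rep(names(sl), lengths(sl))
    widest <- which.max(IRanges::width(hits))
    best <- list(chrom = chroms[widest],
                 start = IRanges::start(hits)[widest],
                 end = IRanges::end(hits)[widest],
                 support = support)
    break
  }
  if (is.null(best)) stopf("no region reaches min_support = %d", want)
  region <- GRanges(best$chrom, IRanges(best$start, best$end))
  supp_ids <- names(per_tumor)[vapply(per_tumor, function(gr) {
    length(subsetByOverlaps(region, reduce(gr), type = "within")) > 0L
  }, TRUE)]
  structure(list(
    chrom = best$chrom, start = best$start, end = best$end,
    width_bp = best$end - best$start + 1L,
    width_mb = (best$end - best$start + 1L) / 1e6,
    support = best$support,
    supporting_tumor_ids = supp_ids
  ), class = "consensus_region")
}

split_by_tumor <- function(segments) {
  if (is.list(segments) && !inherits(segments, "GRanges")) {
    return(segments)
  }
  if (!"tumor_id" %in% names(mcols(segments))) {
    stopf("segments must carry a tumor_id column or be a per-tumor list")
  }
  split(segments, mcols(segments)$tumor_id)
}

#' @export
print.consensus_region <- function(x, ...) {
  cat(sprintf("consensus region %s:%.1f-%.1f Mb (%.2f Mb), support %d/%d tumor(s)\n",
              x$chrom, x$start / 1e6, x$end / 1e6, x$width_mb,
              x$support, length(x$supporting_tumor_ids)))
  invisible(x)
}

#' As a GRanges
#' @param x A `consensus_region`.
#' @return A length-1 `GRanges`.
#' @export
as_granges <- function(x) {
  stopifnot(inherits(x, "consensus_region"))
  GRanges(x$chrom, IRanges(x$start, x$end))
}

#' Genes overlapping a genomic region
#'
#' Returns annotation records whose span overlaps the (optionally
#' flanked) query region; any overlap counts, but a gene exactly
#' abutting the region boundary (half-open BED semantics) is excluded.
#' Output order is stable by gene start.
#'
#' @param region A `GRanges` of length 1, a [consensus_region], or a
#'   `c(start, end)` pair in bp (half-open, with `chrom`).
#' @param annotation A `GRanges` named by gene symbol
#'   (see [read_gene_annotation()]).
#' @param flank Extend the query by this many bp on each side.
#' @param chrom Chromosome, used when `region` is a numeric pair.
#' @return data.frame with gene, chrom, start, end (bp, BED-style
#'   half-open) in positional order.
#' @export
genes_in_region <- function(region, annotation, flank = 0, chrom = "chr3") {
  if (inherits(region, "consensus_region")) region <- as_granges(region)
  if (is.numeric(region) && length(region) == 2L) {
    region <- GRanges(chrom, IRanges(region[1L] + 1, region[2L]))
  }
  stopifnot(inherits(region, "GRanges"), length(region) == 1L)
  if (length(annotation) == 0L) {
    return(data.frame(gene = character(), chrom = character(),
                      start = numeric(), end = numeric()))
  }
  q <- GRanges(GenomicRanges::seqnames(region),
               IRanges(max(1, GenomicRanges::start(region) - flank),
                       GenomicRanges::end(region) + flank))
  hits <- subsetByOverlaps(annotation, q)
  hits <- hits[order(GenomicRanges::start(hits))]
  data.frame(
    gene = names(hits),
    chrom = as.character(GenomicRanges::seqnames(hits)),
    start = GenomicRanges::start(hits) - 1,
    end = GenomicRanges::end(hits),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
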