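# Binned depth, GC normalization, per-scaffold summaries and copy-ratio
# classification: the coverage analysis that identifies the hemizygous (X)
# scaffold in a male assembly.

#' Aggregate depth intervals into fixed-width bins
#'
#' Bin mean depth is the overlap-weighted average of interval depths over the
#' bin window; positions covered by no interval contribute 0. The trailing
#' partial bin of each scaffold is emitted but flagged `short`, and excluded
#' from normalization and summaries downstream.
#'
#' @param intervals data frame of 0-based half-open depth intervals
#'   (`scaffold`, `start`, `end`, `depth`), non-overlapping per scaffold.
#' @param scaffold_lengths named numeric vector covering every scaffold
#'   appearing in `intervals`.
#' @param bin_size bin width in bases (default 10 kb).
#' @return A data frame of bins: `scaffold`, `start`, `end`, `span`,
#'   `mean_depth`, `short`.
#' @export
bin_depth <- function(intervals, scaffold_lengths, bin_size = 10000) {
  check_positive_scalar(bin_size, "bin_size")
  stopifnot(!is.null(names(scaffold_lengths)))
  missing_sc <- setdiff(unique(intervals$scaffold), names(scaffold_lengths))
  if (length(missing_sc) > 0L) {
    stopf("scaffold '%s' absent from scaffold_lengths", missing_sc[1])
  }
  out <- vector("list", length(scaffold_lengths))
  for (k in seq_along(scaffold_lengths)) {
    sc <- names(scaffold_lengths)[k]
    L <- scaffold_lengths[[k]]
    nb <- ceiling(L / bin_size)
    acc <- numeric(nb)
    iv <- intervals[intervals$scaffold == sc, , drop = FALSE]
    if (nrow(iv) > 0L) {
      iv <- iv[order(iv$start), , drop = FALSE]
      if (any(iv$start[-1] < iv$end[-nrow(iv)])) {
        stopf("overlapping depth intervals on scaffold '%s'", sc)
      }
      if (max(iv$end) > L) {
        stopf("interval beyond scaffold length on '%s' (%g > %g)",
              sc, max(iv$end), L)
      }
      i0 <- iv$start %/% bin_size
      i1 <- (iv$end - 1) %/% bin_size
      same <- i0 == i1
      if (any(same)) {
        add <- tapply((iv$end - iv$start)[same] * iv$depth[same],
                      i0[same], sum)
        idx <- as.integer(names(add)) + 1L
        acc[idx] <- acc[idx] + as.numeric(add)
      }
      for (r in which(!same)) {
        for (b in i0[r]:i1[r]) {
          ov <- min(iv$end[r], (b + 1) * bin_size) - max(iv$start[r], b * bin_size)
          acc[b + 1L] <- acc[b + 1L] + ov * iv$depth[r]
        }
      }
    }
    starts <- (seq_len(nb) - 1L) * bin_size
    ends <- pmin(starts + bin_size, L)
    span <- ends - starts
    out[[k]] <- data.frame(scaffold = sc, start = starts, end = ends,
                           span = span, mean_depth = acc / span,
                           short = span < bin_size,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "bin_size") <- bin_size
  res
}

#' Annotate bins with GC fraction
#'
#' GC of a bin is (G+C) / (non-N bases in the window); it is left undefined
#' (`NA`) when fewer than half of the window's positions are non-N, and such
#' bins are excluded from normalization downstream.
#'
#' @param bins bins from [bin_depth()].
#' @param seqs named character vector of scaffold sequences (A/C/G/T/N).
#' @return `bins` with a `gc` column added.
#' @export
annotate_gc <- function(bins, seqs) {
  missing_sc <- setdiff(unique(bins$scaffold), names(seqs))
  if (length(missing_sc) > 0L) {
    stopf("scaffold '%s' has no sequence", missing_sc[1])
  }
  gc <- rep(NA_real_, nrow(bins))
  for (sc in unique(bins$scaffold)) {
    idx <- which(bins$scaffold == sc)
    s <- Biostrings::BString(seqs[[sc]])
    if (length(s) < max(bins$end[idx])) {
      stopf("bins extend beyond sequence of scaffold '%s'", sc)
    }
    v <- Biostrings::Views(s, start = bins$start[idx] + 1L, end = bins$end[idx])
    cnt <- Biostrings::letterFrequency(v, letters = c("A", "C", "G", "T"))
    nonN <- rowSums(cnt)
    g <- rowSums(cnt[, c("G", "C"), drop = FALSE]) / nonN
    g[nonN < bins$span[idx] / 2] <- NA_real_
    gc[idx] <- g
  }
  bins$gc <- gc
  bins
}

#' GC-normalize binned depth by stratified median ratio
#'
#' Bins are stratified by GC in windows of `stratum_width`; each bin's depth
#' is scaled by (global median) / (its stratum's median raw depth), a
#' CNV-style median-ratio correction. Strata holding fewer than `min_bins`
#' bins are merged with the nearest populated stratum; if no stratum reaches
#' `min_bins`, all bins form one stratum. Bins with undefined GC or a short
#' span receive no normalized depth.
#'
#' @param bins bins from [annotate_gc()].
#' @param stratum_width GC width of one stratum (default 0.01).
#' @param min_bins minimum bins for a stratum to stand alone (default 30).
#' @return A list: `bins` (with `norm_depth` column) and `model`
#'   (`stratum_width`, `stratum_medians`, `global_median`, `min_bins`).
#' @export
gc_normalize <- function(bins, stratum_width = 0.01, min_bins = 30) {
  check_positive_scalar(stratum_width, "stratum_width")
  if (!"gc" %in% names(bins)) stopf("bins lack a gc column; run annotate_gc()")
  eligible <- !bins$short & !is.na(bins$gc)
  if (!any(eligible)) stopf("no bins with defined GC to normalize")
  if (!any(bins$mean_depth[eligible] > 0)) stopf("all eligible bins have zero depth")
  stratum <- floor(bins$gc / stratum_width)
  se <- stratum[eligible]
  counts <- table(se)
  populated <- as.numeric(names(counts))[counts >= min_bins]
  if (length(populated) == 0L) populated <- as.numeric(names(counts))[which.max(counts)]
  # assign every eligible bin to its nearest populated stratum
  assign_to <- populated[vapply(se, function(s) which.min(abs(populated - s)),
                                integer(1))]
  med <- tapply(bins$mean_depth[eligible], assign_to, stats::median)
  if (any(med <= 0)) stopf("a GC stratum has zero median depth; cannot normalize")
  global_median <- stats::median(bins$mean_depth[eligible])
  norm <- rep(NA_real_, nrow(bins))
  norm[eligible] <- bins$mean_depth[eligible] *
    global_median / as.numeric(med[as.character(assign_to)])
  bins$norm_depth <- norm
  model <- list(stratum_width = stratum_width,
                stratum_medians = stats::setNames(as.numeric(med),
                                                  as.character(as.numeric(names(med)) * stratum_width)),
                global_median = global_median,
                min_bins = min_bins)
  class(model) <- "gc_norm_model"
  list(bins = bins, model = model)
}

#' @export
print.gc_norm_model <- function(x, ...) {
  cat(sprintf("<gc_norm_model> %d strata (width %.3g), global median %.4g\n",
              length(x$stratum_medians), x$stratum_width, x$global_median))
  invisible(x)
}

#' Per-scaffold summaries of normalized depth
#'
#' Median and central 95% interval (2.5th and 97.5th percentiles, linear
#' interpolation) of bin normalized depth, per scaffold. Scaffolds with
#' fewer usable bins than `min_bins_per_scaffold` are dropped with a
#' warning.
#'
#' @param bins bins carrying `norm_depth` (from [gc_normalize()]).
#' @param min_bins_per_scaffold minimum usable bins (default 50).
#' @return A data frame: `scaffold`, `n_bins`, `median_norm`, `lo95`, `hi95`.
#' @export
summarize_scaffolds <- function(bins, min_bins_per_scaffold = 50) {
  if (!"norm_depth" %in% names(bins)) {
    stopf("bins lack norm_depth; run gc_normalize()")
  }
  use <- bins[!is.na(bins$norm_depth), , drop = FALSE]
  scs <- unique(bins$scaffold)
  rows <- lapply(scs, function(sc) {
    v <- use$norm_depth[use$scaffold == sc]
    if (length(v) < min_bins_per_scaffold) return(NULL)
    q <- stats::quantile(v, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
    data.frame(scaffold = sc, n_bins = length(v), median_norm = q[2],
               lo95 = q[1], hi95 = q[3], stringsAsFactors = FALSE)
  })
  dropped <- scs[vapply(rows, is.null, logical(1))]
  if (length(dropped) > 0L) {
    warnf("dropping %d scaffold(s) with fewer than %d usable bins: %s",
          length(dropped), min_bins_per_scaffold,
          paste(dropped, collapse = ", "))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stopf("no scaffold has enough usable bins")
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Classify scaffold copy ratio (diploid / hemizygous / ambiguous)
#'
#' The reference depth is the length-weighted median of all scaffolds'
#' median normalized depth (weights are bin counts); each scaffold's ratio
#' is its median over that reference. A ratio inside `hemi_band` is called
#' hemizygous, inside `diploid_band` diploid, otherwise ambiguous.
#'
#' @param summaries data frame from [summarize_scaffolds()].
#' @param hemi_band copy-ratio band for hemizygous calls (default 0.35-0.65).
#' @param diploid_band band for diploid calls (default 0.80-1.20).
#' @return A data frame: `scaffold`, `ratio`, `label`, `reference_depth`.
#' @export
classify_ploidy <- function(summaries, hemi_band = c(0.35, 0.65),
                            diploid_band = c(0.80, 1.20)) {
  if (nrow(summaries) < 2L) stopf("need summaries for at least 2 scaffolds")
  ref <- weighted_median(summaries$median_norm, summaries$n_bins)
  if (ref == 0) stopf("reference depth is zero")
  ratio <- summaries$median_norm / ref
  label <- ifelse(ratio >= hemi_band[1] & ratio <= hemi_band[2], "hemizygous",
                  ifelse(ratio >= diploid_band[1] & ratio <= diploid_band[2],
                         "diploid", "ambiguous"))
  data.frame(scaffold = summaries$scaffold, ratio = ratio, label = label,
             reference_depth = ref, stringsAsFactors = FALSE)
}

#' Full depth scan: bin, GC-normalize, summarize, classify
#'
#' Convenience chain over [bin_depth()], [annotate_gc()], [gc_normalize()],
#' [summarize_scaffolds()] and [classify_ploidy()], restricted to scaffolds
#' of at least `min_scaffold_len` (the chromosome-scale scaffolds a
#' karyotype-level analysis classifies).
#'
#' @param seqs named character vector of scaffold sequences.
#' @param intervals depth intervals (see [read_depth_bed()]).
#' @param bin_size bin width (default 10 kb).
#' @param min_scaffold_len minimum scaffold length to classify (default 1 Mb).
#' @param stratum_width,min_bins GC normalization controls.
#' @param min_bins_per_scaffold summary inclusion threshold.
#' @param hemi_band,diploid_band classification bands.
#' @return A list: `bins`, `model`, `summaries`, `calls`.
#' @export
xscan <- function(seqs, intervals, bin_size = 10000, min_scaffold_len = 1e6,
                  stratum_width = 0.01, min_bins = 30,
                  min_bins_per_scaffold = 50, hemi_band = c(0.35, 0.65),
                  diploid_band = c(0.80, 1.20)) {
  lens <- nchar(seqs)
  keep <- names(seqs)[lens >= min_scaffold_len]
  if (length(keep) < 2L) stopf("fewer than 2 scaffolds pass min_scaffold_len")
  seqs <- seqs[keep]
  intervals <- intervals[intervals$scaffold %in% keep, , drop = FALSE]
  bins <- bin_depth(intervals, stats::setNames(nchar(seqs), names(seqs)),
                    bin_size = bin_size)
  bins <- annotate_gc(bins, seqs)
  norm <- gc_normalize(bins, stratum_width = stratum_width,
                       min_bins = min_bins)
  summaries <- summarize_scaffolds(norm$bins,
                                   min_bins_per_scaffold = min_bins_per_scaffold)
  calls <- classify_ploidy(summaries, hemi_band = hemi_band,
                           diploid_band = diploid_band)
  list(bins = norm$bins, model = norm$model, summaries = summaries,
       calls = calls)
}
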