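# Segment filtering, median centering, window binning, gene-level copy
# number and aberration summaries.

#' Filter copy-number segments by size and probe support
#'
#' Segments shorter than 1 kb are removed on every platform. SNP-array
#' segments are additionally kept only if they are supported by more than
#' ten probes AND reach an average probe density of at least one probe per
#' 5 kb.
#'
#' @param profile a [cna_profile].
#' @param platform platform of the profile; probe rules apply to `"SNP"`.
#' @param min_size minimum segment size in bp (default 1000).
#' @return filtered [cna_profile].
#' @export
filter_segments <- function(profile, platform = "WGS", min_size = 1000) {
  len <- profile$end - profile$start
  keep <- len >= min_size
  if (toupper(platform) == "SNP") {
    if (all(is.na(profile$n_probes)))
      stop("SNP profile '", attr(profile, "sample_id"),
           "' lacks n_probes; probe filters cannot be applied")
    density_ok <- profile$n_probes / len >= 1 / 5000
    keep <- keep & profile$n_probes > 10 & density_ok
  }
  out <- profile[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(profile),
            sample_id = attr(profile, "sample_id"),
            genome_build = attr(profile, "genome_build"))
}

# largest-overlap window assignment shared by bin_profile and the 10-kb
# centering median; ties broken toward the leftmost segment
.bin_chrom <- function(start, end, value, width) {
  first_w <- floor(start / width)
  last_w <- floor((end - 1) / width)
  n_w <- last_w - first_w + 1L
  seg_idx <- rep.int(seq_along(start), n_w)
  win <- unlist(lapply(seq_along(start),
                       function(i) seq.int(first_w[i], last_w[i])),
                use.names = FALSE)
  ov <- pmin(end[seg_idx], (win + 1) * width) - pmax(start[seg_idx], win * width)
  # pick per window the segment with the largest overlap; ties -> leftmost
  # segment, i.e. smallest index. order by window, then -overlap, then index
  o <- order(win, -ov, seg_idx)
  win_o <- win[o]
  keep <- !duplicated(win_o)
  list(window = win_o[keep], value = value[seg_idx[o][keep]])
}

#' Bin a segment profile into fixed-width windows
#'
#' Each genomic window of `width` bp overlapped by at least one segment
#' receives the log2 ratio of the segment with the largest overlap (ties go
#' to the leftmost segment); windows with no segment coverage are absent.
#'
#' @param profile a [cna_profile].
#' @param width window width in bp (default 100 kb).
#' @return data frame of class `binned_profile` with columns `chrom`,
#'   `start`, `end`, `log2_ratio`; attribute `width`.
#' @export
bin_profile <- function(profile, width = 1e5) {
  if (!is.numeric(width) || width <= 0) stop("width must be positive")
  chroms <- unique(profile$chrom)
  out <- lapply(chroms, function(ch) {
    s <- profile[profile$chrom == ch, , drop = FALSE]
    b <- .bin_chrom(s$start, s$end, s$log2_ratio, width)
    data.frame(chrom = ch, start = b$window * width,
               end = (b$window + 1) * width, log2_ratio = b$value,
               stringsAsFactors = FALSE)
  })
  out <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               log2_ratio = numeric())
  rownames(out) <- NULL
  structure(out, class = c("binned_profile", "data.frame"), width = width,
            sample_id = attr(profile, "sample_id"))
}

#' Median-center a segment profile
#'
#' Bins the profile into 10-kb windows, takes the median window log2 ratio
#' over the covered genome, and subtracts it from every segment, so the
#' centered profile's own 10-kb window median is zero. Centering
#' approximates normalization by sample ploidy and is idempotent.
#'
#' @param profile a [cna_profile].
#' @param width window width used to compute the median (default 10 kb).
#' @return centered [cna_profile].
#' @export
median_center <- function(profile, width = 1e4) {
  if (nrow(profile) == 0L)
    stop("cannot center an empty profile ('",
         attr(profile, "sample_id"), "')")
  b <- bin_profile(profile, width)
  m <- median(b$log2_ratio)
  out <- profile
  out$log2_ratio <- out$log2_ratio - m
  structure(out, class = class(profile),
            sample_id = attr(profile, "sample_id"),
            genome_build = attr(profile, "genome_build"))
}

#' Gene-level copy number by conservative segment intersection
#'
#' Intersects segments with gene coordinates; where a gene spans several
#' segments, the most conservative (lowest) log2 ratio represents the whole
#' gene. Genes overlapping no segment are absent from the result.
#'
#' @param profile a filtered, centered [cna_profile].
#' @param genes gene-model data frame (see [read_gene_models()]).
#' @return named numeric vector of log2 ratios, names are `gene_id`s, in
#'   gene-table order.
#' @export
gene_copy_number <- function(profile, genes) {
  if (is.null(genes) || nrow(genes) == 0L) stop("empty gene table")
  vals <- rep(NA_real_, nrow(genes))
  for (ch in intersect(unique(genes$chrom), unique(profile$chrom))) {
    gi <- which(genes$chrom == ch)
    s <- profile[profile$chrom == ch, , drop = FALSE]
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(genes$start[gi] + 1L, genes$end[gi]),
      IRanges::IRanges(s$start + 1L, s$end))
    if (!length(ov)) next
    mins <- tapply(s$log2_ratio[S4Vectors::subjectHits(ov)],
                   S4Vectors::queryHits(ov), min)
    vals[gi[as.integer(names(mins))]] <- as.numeric(mins)
  }
  out <- setNames(vals, genes$gene_id)
  out[!is.na(out)]
}

#' Aberration summary of a binned profile
#'
#' Computes the variance and the 5-95% inter-percentile range (IPR) of the
#' binned log2 ratios. The IPR is the preferred degree-of-aberration metric:
#' a narrow range means at least 90% of the covered genome shows only
#' low-level gains and losses. Callers classify a profile as non-aberrant
#' when IPR < 0.3.
#'
#' @param binned a `binned_profile` (see [bin_profile()]).
#' @param min_windows minimum number of covered windows required (default 20).
#' @return list with `variance`, `ipr_5_95`, `n_windows`.
#' @export
aberration_summary <- function(binned, min_windows = 20) {
  v <- binned$log2_ratio
  if (length(v) < min_windows)
    stop("too few covered windows (", length(v), " < ", min_windows, ")")
  q <- quantile(v, c(0.05, 0.95), names = FALSE)
  list(variance = var(v), ipr_5_95 = q[2L] - q[1L], n_windows = length(v))
}

#' Label segments as gain, loss or neutral
#'
#' Gains are segments with log2 ratio strictly above `thr`, losses strictly
#' below `-thr`; values at the threshold are neutral.
#'
#' @param profile a centered [cna_profile].
#' @param thr threshold on the log2 ratio (default 0.1).
#' @return the profile with an added `call` column
#'   (`"gain"`/`"loss"`/`"neutral"`).
#' @export
classify_gain_loss <- function(profile, thr = 0.1) {
  out <- as.data.frame(profile)
  out$call <- ifelse(out$log2_ratio > thr, "gain",
                     ifelse(out$log2_ratio < -thr, "loss", "neutral"))
  structure(out, class = c("cna_profile", "data.frame"),
            sample_id = attr(profile, "sample_id"),
            genome_build = attr(profile, "genome_build"))
}

#' Segment-size and dynamic-range statistics over aberrant segments
#'
#' Aberrant segments here are those with |log2 ratio| >= `thr` (inclusive,
#' the convention used for resolution comparisons, unlike the strict
#' gain/loss labels of [classify_gain_loss()]). Reports the median and mean
#' aberrant-segment length and the min/max log2 ratio over the profile set.
#'
#' @param profiles a list of [cna_profile] objects.
#' @param thr absolute log2-ratio threshold (default 0.1, inclusive).
#' @return list with `median_size`, `mean_size`, `value_range` (length-2),
#'   `n_segments`.
#' @export
segment_size_stats <- function(profiles, thr = 0.1) {
  if (inherits(profiles, "cna_profile")) profiles <- list(profiles)
  if (!length(profiles)) stop("no profiles supplied")
  seg <- do.call(rbind, lapply(profiles, as.data.frame))
  ab <- abs(seg$log2_ratio) >= thr
  if (!any(ab)) stop("no aberrant segments at |log2| >= ", thr)
  len <- (seg$end - seg$start)[ab]
  list(median_size = median(len), mean_size = mean(len),
       value_range = range(seg$log2_ratio), n_segments = sum(ab))
}
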