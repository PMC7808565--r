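# Expression-based CNA inference: e-karyotyping preprocessing of
# RNA-seq / array matrices into positional relative-expression profiles,
# and an exact penalized piecewise-constant-fit (PCF) segmenter.

#' e-karyotyping configuration
#'
#' @param floor expression floor: values below it are candidates for removal
#'   or are raised to it. Defaults to 1 (TPM, linear) for RNA-seq and 6
#'   (log2 intensity) for arrays; pass `NULL` to pick by the matrix unit.
#' @param max_below_floor_fraction remove a gene when it is below the floor
#'   in more than this fraction of the dataset (default 0.20).
#' @param top_variable_fraction fraction of most-variable genes removed
#'   (default 0.10; variability is the sum of squared deviations from the
#'   gene's cross-sample median).
#' @param calibration `"NORM"`: subtract the per-gene median of normal
#'   samples; `"TUM"`: subtract the per-gene median of the tumor samples
#'   themselves (tumor-only datasets).
#' @param drop_sex_chromosomes drop X/Y genes first (default TRUE).
#' @return list of class `ekaryo_config`.
#' @export
ekaryo_config <- function(floor = NULL, max_below_floor_fraction = 0.20,
                          top_variable_fraction = 0.10,
                          calibration = c("NORM", "TUM"),
                          drop_sex_chromosomes = TRUE) {
  calibration <- match.arg(calibration)
  stopifnot(max_below_floor_fraction > 0, max_below_floor_fraction < 1,
            top_variable_fraction > 0, top_variable_fraction < 1)
  structure(list(floor = floor,
                 max_below_floor_fraction = max_below_floor_fraction,
                 top_variable_fraction = top_variable_fraction,
                 calibration = calibration,
                 drop_sex_chromosomes = drop_sex_chromosomes),
            class = "ekaryo_config")
}

#' e-karyotyping preprocessing of an expression matrix
#'
#' Turns a genes-by-samples expression matrix into per-tumor-sample
#' positional relative-expression profiles ready for [pcf_segment()]:
#' (1) sex-chromosome genes are dropped; (2) genes below the floor (1 TPM
#' for RNA-seq, log2 value 6 for arrays) in more than 20% of the dataset
#' are removed; (3) remaining sub-floor values are raised to the floor;
#' (4) of multiple transcripts/probesets per gene, the one with the highest
#' median across the whole dataset is kept; (5) the 10% most variable genes
#' (sum of squares around the gene's own cross-sample median) are removed;
#' (6) per tumor sample, the per-gene median log2 expression of the normal
#' samples (NORM) or of the tumor samples themselves (TUM) is subtracted.
#'
#' @param expr an `expr_matrix` (see [read_expression()]).
#' @param cfg an [ekaryo_config].
#' @return list of class `ekaryo_profiles`: one data frame per tumor sample
#'   (`gene_id`, `chrom`, `start`, `end`, `value`), genes ordered by
#'   chromosome then start; attribute `qc` records counts removed at each
#'   step.
#' @export
preprocess_expression <- function(expr, cfg = ekaryo_config()) {
  stopifnot(inherits(expr, "expr_matrix"))
  m <- expr$values
  feats <- expr$features
  feats <- feats[match(rownames(m), feats$feature_id), , drop = FALSE]
  qc <- list(n_input = nrow(m))
  if (cfg$drop_sex_chromosomes) {
    keep <- !(.normalize_chrom(feats$chrom) %in% c("X", "Y"))
    qc$n_sex_dropped <- sum(!keep)
    m <- m[keep, , drop = FALSE]; feats <- feats[keep, , drop = FALSE]
  }
  floor_val <- cfg$floor
  if (is.null(floor_val)) floor_val <- if (expr$unit == "TPM") 1 else 6
  below <- rowMeans(m < floor_val)
  keep <- below <= cfg$max_below_floor_fraction
  qc$n_floor_dropped <- sum(!keep)
  m <- m[keep, , drop = FALSE]; feats <- feats[keep, , drop = FALSE]
  if (!nrow(m)) stop("no genes survive the expression floor filter")
  m[m < floor_val] <- floor_val
  if (expr$unit == "TPM") m <- log2(m)
  # collapse transcripts/probesets: keep the feature with the highest
  # median across the entire dataset
  med <- apply(m, 1L, median)
  ord <- order(feats$gene_id, -med)
  first <- !duplicated(feats$gene_id[ord])
  sel <- sort(ord[first])
  qc$n_collapsed <- nrow(m) - length(sel)
  m <- m[sel, , drop = FALSE]; feats <- feats[sel, , drop = FALSE]
  # drop the most variable genes
  ss <- apply(m, 1L, function(v) sum((v - median(v))^2))
  n_drop <- floor(cfg$top_variable_fraction * length(ss))
  if (n_drop > 0L) {
    keep <- rank(-ss, ties.method = "first") > n_drop
    qc$n_variable_dropped <- sum(!keep)
    m <- m[keep, , drop = FALSE]; feats <- feats[keep, , drop = FALSE]
  } else qc$n_variable_dropped <- 0L
  tum <- names(expr$sample_class)[expr$sample_class == "tumor"]
  nrm <- names(expr$sample_class)[expr$sample_class == "normal"]
  if (!length(tum)) stop("no tumor samples in the matrix")
  if (cfg$calibration == "NORM" && !length(nrm))
    stop("NORM calibration requested but the matrix has no normal samples")
  ref <- if (cfg$calibration == "NORM")
    apply(m[, nrm, drop = FALSE], 1L, median)
  else apply(m[, tum, drop = FALSE], 1L, median)
  chrom <- .normalize_chrom(feats$chrom)
  lev <- .chrom_order(chrom)
  o <- order(match(chrom, lev), feats$start)
  out <- lapply(tum, function(s) {
    data.frame(gene_id = feats$gene_id[o], chrom = chrom[o],
               start = feats$start[o], end = feats$end[o],
               value = (m[, s] - ref)[o], stringsAsFactors = FALSE)
  })
  names(out) <- tum
  qc$n_retained <- nrow(m)
  structure(out, class = "ekaryo_profiles", qc = qc,
            calibration = cfg$calibration)
}

#' PCF segmentation parameters
#'
#' @param penalty per-breakpoint penalty applied to the least-squares
#'   objective on robustly standardized values (default 12).
#' @param winsorize_q winsorization quantile (default 0.001): values outside
#'   the (q, 1-q) empirical quantiles are clamped before segmentation.
#' @param min_aberration_size minimum genes per called aberration
#'   (default 30).
#' @param min_deviation minimum |segment mean| for an aberration call
#'   (default 0.25 log2 units).
#' @param call_threshold two-sided significance level on the segment mean
#'   (t test against zero) additionally required for a call (default 0.01).
#' @return list of class `pcf_params`.
#' @export
pcf_params <- function(penalty = 12, winsorize_q = 0.001,
                       min_aberration_size = 30, min_deviation = 0.25,
                       call_threshold = 0.01) {
  stopifnot(penalty >= 0, winsorize_q > 0, winsorize_q < 0.5)
  structure(list(penalty = penalty, winsorize_q = winsorize_q,
                 min_aberration_size = min_aberration_size,
                 min_deviation = min_deviation,
                 call_threshold = call_threshold), class = "pcf_params")
}

# exact O(n^2) dynamic program: minimize sum of within-segment squared
# deviations + penalty * (number of breakpoints). returns segment start
# indices.
.pcf_dp <- function(z, penalty) {
  n <- length(z)
  if (n == 1L) return(1L)
  cs <- c(0, cumsum(z)); cs2 <- c(0, cumsum(z^2))
  # cost of segment i..j (1-based, inclusive)
  best <- numeric(n + 1L)       # best[j+1] = optimal cost of z[1..j]
  prev <- integer(n)            # prev[j] = start index of last segment
  best[1L] <- -penalty          # first segment's penalty cancels
  for (j in seq_len(n)) {
    i <- seq_len(j)
    len <- j - i + 1
    s <- cs[j + 1L] - cs[i]
    cost <- (cs2[j + 1L] - cs2[i]) - s^2 / len
    tot <- best[i] + cost + penalty
    k <- which.min(tot)
    best[j + 1L] <- tot[k]
    prev[j] <- k
  }
  starts <- integer(0)
  j <- n
  while (j > 0L) {
    starts <- c(prev[j], starts)
    j <- prev[j] - 1L
  }
  starts
}

#' Penalized piecewise-constant-fit segmentation of a positional profile
#'
#' Segments each chromosome's ordered relative-expression values into
#' constant-mean pieces by exact dynamic programming, minimizing the sum of
#' squared residuals plus `penalty` per breakpoint. Values are winsorized at
#' the (`winsorize_q`, 1-`winsorize_q`) quantiles of the whole profile, and
#' the penalty is applied on values standardized by the profile's median
#' absolute deviation so that it is comparable across samples. A segment is
#' called gain/loss (by the sign of its mean) only when it spans at least
#' `min_aberration_size` genes, its |mean| reaches `min_deviation`, and its
#' mean differs from zero at the `call_threshold` significance level;
#' otherwise it is neutral.
#'
#' @param profile one sample's profile from [preprocess_expression()]: a
#'   data frame with `gene_id`, `chrom`, `start`, `end`, `value` ordered by
#'   position.
#' @param params a [pcf_params] object.
#' @return data frame of class `pcf_result`: one row per segment with
#'   `chrom`, `idx_start`, `idx_end` (gene indices within the chromosome),
#'   `n_genes`, `mean`, `call`, plus genomic anchors `gene_start`,
#'   `gene_end`.
#' @export
pcf_segment <- function(profile, params = pcf_params()) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "value") %in%
                  names(profile)))
  v <- profile$value
  q <- quantile(v, c(params$winsorize_q, 1 - params$winsorize_q),
                names = FALSE)
  w <- pmin(pmax(v, q[1L]), q[2L])
  s <- stats::mad(w)
  if (!is.finite(s) || s == 0) s <- 1
  rows <- list()
  for (ch in unique(profile$chrom)) {
    ix <- which(profile$chrom == ch)
    wc <- w[ix]
    starts <- if (length(ix) < 2L) 1L else .pcf_dp(wc / s, params$penalty)
    ends <- c(starts[-1L] - 1L, length(ix))
    for (k in seq_along(starts)) {
      seg_ix <- seq.int(starts[k], ends[k])
      mu <- mean(wc[seg_ix])
      n <- length(seg_ix)
      p <- if (n < 2L || sd(wc[seg_ix]) == 0) {
        if (abs(mu) > 0) 0 else 1
      } else t.test(wc[seg_ix])$p.value
      call <- if (n >= params$min_aberration_size &&
                  abs(mu) >= params$min_deviation &&
                  p < params$call_threshold) {
        if (mu > 0) "gain" else "loss"
      } else "neutral"
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, idx_start = starts[k], idx_end = ends[k], n_genes = n,
        mean = mu, call = call,
        gene_start = profile$start[ix[starts[k]]],
        gene_end = max(profile$end[ix[seg_ix]]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  structure(res, class = c("pcf_result", "data.frame"),
            sample_id = attr(profile, "sample_id"))
}

#' Convert PCF segments into a genomic segment profile
#'
#' Bridges expression-inferred copy-number calls into the DNA-side
#' machinery: each PCF segment becomes a genomic segment spanning its first
#' to last gene, with the segment mean as log2 ratio. Overlapping gene
#' bodies at segment boundaries are resolved by clamping each segment's
#' start to the previous segment's end, so adjacent segments never overlap.
#'
#' @param pcf a `pcf_result` (see [pcf_segment()]).
#' @param sample_id sample identifier for the resulting profile.
#' @return a [cna_profile].
#' @export
expression_cna_to_segments <- function(pcf, sample_id = "ekaryo") {
  seg <- data.frame(chrom = pcf$chrom, start = pcf$gene_start,
                    end = pcf$gene_end, log2_ratio = pcf$mean,
                    stringsAsFactors = FALSE)
  out <- list()
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1L)
      for (i in 2:nrow(s)) s$start[i] <- max(s$start[i], s$end[i - 1L])
    s <- s[s$start < s$end, , drop = FALSE]
    out[[ch]] <- s
  }
  cna_profile(do.call(rbind, out), sample_id = sample_id,
              genome_build = "expression-inferred")
}
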