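# Pair enumeration, pairwise concordance (correlation + improved
# regression), altered-gene calling, cross-platform comparison and the
# group-comparison tests.

# externally studentized residuals with degenerate-fit protection: an
# essentially perfect fit has no outliers (the studentized values are
# numerical noise), and a point whose removal makes the fit perfect is an
# infinite outlier (its leave-one-out sigma is zero)
.safe_rstudent <- function(fit) {
  y <- fitted(fit) + resid(fit)
  tol <- max(1e-12, 1e-8 * sd(y))
  sigma <- suppressWarnings(summary(fit)$sigma)
  if (sigma < tol) return(rep(0, length(resid(fit))))
  rs <- rstudent(fit)
  bad <- !is.finite(rs)
  rs[bad] <- ifelse(resid(fit)[bad] == 0, 0, Inf * sign(resid(fit)[bad]))
  rs
}

# a lineage id is a dot-separated path ("L1", "L1.2", "L1.2.1"); two PDX
# samples are in the same lineage iff one path is a prefix of the other,
# i.e. they differ only by consecutive serial passages
.same_lineage <- function(a, b) {
  if (is.na(a) || is.na(b)) return(NA)
  a == b || startsWith(a, paste0(b, ".")) || startsWith(b, paste0(a, "."))
}

#' Enumerate and classify sample pairs
#'
#' Builds all comparable pairs from validated metadata: within each model,
#' all same-platform pairs of usable samples (PDX samples without passage
#' information are omitted); optionally, cross-model background pairs
#' restricted to samples of different models sharing tumor type, center and
#' platform. Pair types are `PT_PDX`, `PDX_PDX`, `PT_PT_INTRAPATIENT`
#' (patient-tumor pairs of a common patient, within or across models) and
#' `CROSS_MODEL`. For `PDX_PDX` pairs the lineage relation is `SAME_LINEAGE`
#' when one sample's lineage path is an ancestor of the other's (consecutive
#' serial passages only) and `DIFFERENT_LINEAGE` after a lineage split.
#'
#' The first-listed sample of a pair is the reference (regression predictor):
#' the PT in `PT_PDX` pairs, the lower-passage sample in `PDX_PDX` pairs.
#'
#' @param metadata a `cna_metadata` data frame (see [read_metadata()]).
#' @param cross_model also emit cross-model background pairs (default FALSE).
#' @return data frame with columns `sample_a`, `sample_b`, `pair_type`,
#'   `lineage_relation`, `model_id`, `platform`, `passage_a`, `passage_b`.
#' @export
enumerate_pairs <- function(metadata, cross_model = FALSE) {
  md <- as.data.frame(metadata)
  md <- md[md$sample_class %in% c("PT", "PDX") & !md$excluded_from_pairing, ,
           drop = FALSE]
  mk <- function(i, j, type, model) {
    # orientation: PT (reference) first; else lower passage first
    swap <- FALSE
    if (type == "PT_PDX") {
      swap <- md$sample_class[i] != "PT"
    } else if (type == "PDX_PDX") {
      pi_ <- md$passage[i]; pj <- md$passage[j]
      swap <- !is.na(pi_) && !is.na(pj) && pj < pi_
    }
    if (swap) { k <- i; i <- j; j <- k }
    lr <- NA_character_
    if (type == "PDX_PDX") {
      sl <- .same_lineage(md$lineage_id[i], md$lineage_id[j])
      lr <- if (is.na(sl)) NA_character_ else
        if (sl) "SAME_LINEAGE" else "DIFFERENT_LINEAGE"
    }
    data.frame(sample_a = md$sample_id[i], sample_b = md$sample_id[j],
               pair_type = type, lineage_relation = lr, model_id = model,
               platform = md$platform[i], passage_a = md$passage[i],
               passage_b = md$passage[j], stringsAsFactors = FALSE)
  }
  out <- list()
  for (m in unique(md$model_id)) {
    ix <- which(md$model_id == m)
    if (length(ix) < 2L) next
    for (a in seq_along(ix)[-length(ix)]) for (b in seq.int(a + 1L, length(ix))) {
      i <- ix[a]; j <- ix[b]
      if (md$platform[i] != md$platform[j]) next
      cls <- sort(c(md$sample_class[i], md$sample_class[j]))
      type <- if (all(cls == c("PDX", "PT"))) "PT_PDX"
              else if (all(cls == "PDX")) "PDX_PDX"
              else "PT_PT_INTRAPATIENT"
      out[[length(out) + 1L]] <- mk(i, j, type, m)
    }
  }
  # intra-patient PT pairs across models (e.g. primary vs relapse)
  pts <- which(md$sample_class == "PT")
  if (length(pts) > 1L) {
    for (a in seq_along(pts)[-length(pts)])
      for (b in seq.int(a + 1L, length(pts))) {
        i <- pts[a]; j <- pts[b]
        if (md$model_id[i] == md$model_id[j]) next
        if (md$patient_id[i] != md$patient_id[j]) next
        if (md$platform[i] != md$platform[j]) next
        out[[length(out) + 1L]] <- mk(i, j, "PT_PT_INTRAPATIENT",
                                      NA_character_)
      }
  }
  if (cross_model) {
    n <- nrow(md)
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      if (md$model_id[i] == md$model_id[j]) next
      if (md$patient_id[i] == md$patient_id[j]) next
      if (md$tumor_type[i] != md$tumor_type[j] ||
          md$center[i] != md$center[j] ||
          md$platform[i] != md$platform[j]) next
      out[[length(out) + 1L]] <- mk(i, j, "CROSS_MODEL", NA_character_)
    }
  }
  if (!length(out))
    return(data.frame(sample_a = character(), sample_b = character(),
                      pair_type = character(), lineage_relation = character(),
                      model_id = character(), platform = character(),
                      passage_a = integer(), passage_b = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pearson correlation of two profiles on shared features
#'
#' Profiles are named numeric vectors (gene-level log2 ratios or 100-kb
#' window values); features missing in either sample are excluded. With
#' zero variance in either vector the correlation is undefined and `NA` is
#' returned with a warning (callers flag the pair invalid).
#'
#' @param a,b named numeric vectors.
#' @param min_features minimum number of shared features (default 30).
#' @return Pearson correlation coefficient (or `NA`).
#' @export
correlate_profiles <- function(a, b, min_features = 30) {
  sh <- intersect(names(a), names(b))
  if (length(sh) < min_features)
    stop("only ", length(sh), " shared features (need >= ", min_features, ")")
  x <- a[sh]; y <- b[sh]
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance in a profile; correlation undefined")
    return(NA_real_)
  }
  cor(x, y)
}

#' Convert a binned profile to a named feature vector
#'
#' Feature names are `chrom:start`, the shared feature space for
#' window-based correlations and cross-platform regression.
#'
#' @param binned a `binned_profile`.
#' @return named numeric vector of window log2 ratios.
#' @export
binned_to_vector <- function(binned) {
  setNames(binned$log2_ratio, paste(binned$chrom, binned$start, sep = ":"))
}

#' Improved linear regression between two gene-level profiles
#'
#' Fits the concordance model between two samples of one PDX model: gene
#' log2 ratios below the deletion floor are rescaled to the floor (-3) to
#' avoid leverage from extreme negative log values, sample `b` is regressed
#' on the reference sample `a` by ordinary least squares, extreme outliers
#' with |externally studentized residual| > 3 are removed, and the model is
#' refit on the remaining genes (the "improved" fit). Residuals from the
#' improved fit, in log2 units, are computed for every shared gene
#' (including the removed outliers) and drive altered-gene calling via
#' [altered_genes()].
#'
#' The fit is deliberately asymmetric: `a` is the predictor (PT in PT-PDX
#' pairs, the lower-passage sample in PDX-PDX pairs).
#'
#' @param a,b named numeric vectors of gene-level log2 ratios; `a` is the
#'   reference.
#' @param floor deletion floor (default -3); use `-Inf` to disable.
#' @param outlier_thr studentized-residual cutoff for the refit (default 3).
#' @param min_genes minimum shared genes (default 200).
#' @return object of class `cna_pair_fit` with elements `genes`, `x`, `y`
#'   (floored values), `initial` and `improved` coefficient vectors,
#'   `studentized` (initial-fit studentized residuals), `outliers`,
#'   `residuals` (improved-fit raw residuals for all shared genes),
#'   `pearson_r`, `both_deleted`, `n_genes`.
#' @export
cna_pair_fit <- function(a, b, floor = -3, outlier_thr = 3, min_genes = 200) {
  sh <- intersect(names(a), names(b))
  if (length(sh) < min_genes)
    stop("only ", length(sh), " shared genes (need >= ", min_genes, ")")
  x <- pmax(a[sh], floor)
  y <- pmax(b[sh], floor)
  floored <- a[sh] < floor | b[sh] < floor
  if (sd(x) == 0)
    stop("reference profile has zero variance over shared genes")
  fit0 <- lm(y ~ x)
  rs <- .safe_rstudent(fit0)
  out_ix <- which(abs(rs) > outlier_thr)
  keep <- setdiff(seq_along(sh), out_ix)
  fit1 <- lm(y[keep] ~ x[keep])
  cf1 <- c(intercept = unname(coef(fit1)[1L]), slope = unname(coef(fit1)[2L]))
  resid_all <- y - (cf1["intercept"] + cf1["slope"] * x)
  obj <- list(genes = sh, x = x, y = y,
              initial = c(intercept = unname(coef(fit0)[1L]),
                          slope = unname(coef(fit0)[2L])),
              improved = cf1,
              studentized = setNames(as.numeric(rs), sh),
              outliers = sh[out_ix],
              residuals = setNames(unname(resid_all), sh),
              pearson_r = cor(x, y),
              both_deleted = sh[a[sh] <= floor & b[sh] <= floor],
              floored = sh[floored],
              floor = floor, n_genes = length(sh))
  class(obj) <- "cna_pair_fit"
  obj
}

#' @export
print.cna_pair_fit <- function(x, ...) {
  cat("Pairwise CNA concordance fit (improved linear regression)\n")
  cat(sprintf("  %d shared genes; Pearson r = %.4f\n", x$n_genes, x$pearson_r))
  cat(sprintf("  initial fit:  y = %.4f + %.4f x\n",
              x$initial["intercept"], x$initial["slope"]))
  cat(sprintf("  improved fit: y = %.4f + %.4f x (%d outlier gene(s) removed)\n",
              x$improved["intercept"], x$improved["slope"], length(x$outliers)))
  invisible(x)
}

#' @export
coef.cna_pair_fit <- function(object, improved = TRUE, ...) {
  if (improved) object$improved else object$initial
}

#' @export
residuals.cna_pair_fit <- function(object, ...) object$residuals

#' @export
fitted.cna_pair_fit <- function(object, ...) {
  setNames(object$improved["intercept"] + object$improved["slope"] * object$x,
           object$genes)
}

#' @export
predict.cna_pair_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else newdata
  object$improved["intercept"] + object$improved["slope"] * x
}

#' @export
summary.cna_pair_fit <- function(object, thr = 0.5, ...) {
  alt <- altered_genes(object, thr = thr)
  structure(list(n_genes = object$n_genes, pearson_r = object$pearson_r,
                 improved = object$improved, n_outliers = length(object$outliers),
                 thr = thr, n_altered = length(alt),
                 prop_altered = length(alt) / object$n_genes),
            class = "summary.cna_pair_fit")
}

#' @export
print.summary.cna_pair_fit <- function(x, ...) {
  cat(sprintf(paste0("CNA pair: %d genes, r = %.4f, %d regression outliers\n",
                     "  altered genes at |residual| > %.2f: %d (%.2f%%)\n"),
              x$n_genes, x$pearson_r, x$n_outliers, x$thr, x$n_altered,
              100 * x$prop_altered))
  invisible(x)
}

#' @export
plot.cna_pair_fit <- function(x, thr = 0.5, ...) {
  alt <- altered_genes(x, thr = thr)
  col <- ifelse(x$genes %in% alt, "firebrick",
                ifelse(x$genes %in% x$outliers, "orange", "grey40"))
  graphics::plot(x$x, x$y, col = col, pch = 16, cex = 0.5,
                 xlab = "reference sample log2 ratio",
                 ylab = "comparison sample log2 ratio", ...)
  graphics::abline(x$improved["intercept"], x$improved["slope"], col = "blue")
  graphics::abline(x$improved["intercept"] + thr, x$improved["slope"],
                   col = "blue", lty = 2)
  graphics::abline(x$improved["intercept"] - thr, x$improved["slope"],
                   col = "blue", lty = 2)
  invisible(x)
}

#' Altered genes from a pair fit
#'
#' Genes whose raw residual from the improved regression exceeds `thr` in
#' absolute value (log2 units). The default 0.5 is the subclonal-inclusive
#' threshold; 1.0 selects changes with possible functional impact. At the
#' stringent threshold, genes deleted to the floor in both samples are
#' omitted (a difference between two floored deletions is not
#' interpretable).
#'
#' @param fit a [cna_pair_fit] object.
#' @param thr residual threshold (default 0.5).
#' @param omit_both_deleted drop genes at the deletion floor in both
#'   samples; defaults to `TRUE` when `thr >= 1`.
#' @return character vector of gene ids.
#' @export
altered_genes <- function(fit, thr = 0.5, omit_both_deleted = thr >= 1) {
  stopifnot(inherits(fit, "cna_pair_fit"))
  alt <- fit$genes[abs(fit$residuals) > thr]
  if (omit_both_deleted) alt <- setdiff(alt, fit$both_deleted)
  alt
}

#' Cross-platform comparison of two segment profiles
#'
#' Bins both profiles into shared fixed-width windows, regresses the second
#' on the first, flags windows with |externally studentized residual| > 3 as
#' having discrepant copy number, maps flagged windows back to their source
#' segments in each profile (to size the discordant CNA events), and reports
#' the discordant genome fraction (summed flagged-window length over summed
#' shared-window length).
#'
#' @param a,b [cna_profile] objects (reference first).
#' @param width window width in bp (default 100 kb).
#' @param outlier_thr studentized-residual cutoff (default 3).
#' @param min_windows minimum shared windows (default 100).
#' @return list of class `cross_platform_result`: `fit` (intercept/slope),
#'   `pearson_r`, `outlier_windows` (data frame), `discordant_fraction`,
#'   `outlier_segments_a`, `outlier_segments_b`, `n_windows`.
#' @export
cross_platform_compare <- function(a, b, width = 1e5, outlier_thr = 3,
                                   min_windows = 100) {
  va <- binned_to_vector(bin_profile(a, width))
  vb <- binned_to_vector(bin_profile(b, width))
  sh <- intersect(names(va), names(vb))
  if (length(sh) < min_windows)
    stop("only ", length(sh), " shared windows (need >= ", min_windows, ")")
  x <- va[sh]; y <- vb[sh]
  fit0 <- lm(y ~ x)
  rs <- .safe_rstudent(fit0)
  out_ix <- which(abs(rs) > outlier_thr)
  parts <- strsplit(sh, ":", fixed = TRUE)
  w <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                  start = as.numeric(vapply(parts, `[`, "", 2L)),
                  stringsAsFactors = FALSE)
  w$end <- w$start + width
  ow <- w[out_ix, , drop = FALSE]
  ow$studentized <- as.numeric(rs[out_ix])
  rownames(ow) <- NULL
  map_back <- function(profile) {
    if (!nrow(ow)) return(profile[0, , drop = FALSE])
    hits <- integer(0)
    for (ch in unique(ow$chrom)) {
      s <- which(profile$chrom == ch)
      if (!length(s)) next
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(ow$start[ow$chrom == ch] + 1L, ow$end[ow$chrom == ch]),
        IRanges::IRanges(profile$start[s] + 1L, profile$end[s]))
      hits <- c(hits, s[unique(S4Vectors::subjectHits(ov))])
    }
    seg <- as.data.frame(profile[sort(unique(hits)), , drop = FALSE])
    seg$size <- seg$end - seg$start
    rownames(seg) <- NULL
    seg
  }
  structure(list(
    fit = c(intercept = unname(coef(fit0)[1L]), slope = unname(coef(fit0)[2L])),
    pearson_r = if (sd(x) > 0 && sd(y) > 0) cor(x, y) else NA_real_,
    outlier_windows = ow,
    discordant_fraction = nrow(ow) * width / (length(sh) * width),
    outlier_segments_a = map_back(a), outlier_segments_b = map_back(b),
    n_windows = length(sh)), class = "cross_platform_result")
}

#' Validity filter for sample pairs
#'
#' A pair is dropped (invalid) when its correlation is low (< `r_min`) AND
#' either sample has a non-aberrant profile (5-95% IPR < `ipr_min`): low
#' correlation driven by genomic stability rather than true discordance.
#'
#' @param pair_table data frame with at least `pearson_r`, `ipr_a`, `ipr_b`.
#' @param r_min correlation cutoff (default 0.6).
#' @param ipr_min aberration cutoff (default 0.3).
#' @return `pair_table` with a logical `valid` column added.
#' @export
filter_valid_pairs <- function(pair_table, r_min = 0.6, ipr_min = 0.3) {
  nonab <- pmin(pair_table$ipr_a, pair_table$ipr_b) < ipr_min
  low_r <- is.na(pair_table$pearson_r) | pair_table$pearson_r < r_min
  pair_table$valid <- !(nonab & low_r) & !is.na(pair_table$pearson_r)
  pair_table
}

#' Flag highly discordant pairs
#'
#' A pair is highly discordant when BOTH samples are clearly aberrant
#' (5-95% IPR > 0.5) yet the correlation is below 0.6.
#'
#' @param r Pearson correlation of the pair.
#' @param ipr_a,ipr_b per-sample 5-95% inter-percentile ranges.
#' @param r_max correlation cutoff (default 0.6, strict).
#' @param ipr_min aberration requirement (default 0.5, strict).
#' @return logical.
#' @export
flag_discordant <- function(r, ipr_a, ipr_b, r_max = 0.6, ipr_min = 0.5) {
  !is.na(r) & ipr_a > ipr_min & ipr_b > ipr_min & r < r_max
}

#' CNA range ratio of a pair
#'
#' Ratio of the first sample's aberration range (5-95% IPR) to the second
#' sample's. With PT listed first in PT-PDX pairs, stromal dilution of the
#' patient tumor shows up as a ratio below 1.
#'
#' @param ipr_a,ipr_b per-sample IPR values (first sample the PT/reference).
#' @return ratio, or `NA` with a warning when the denominator is zero.
#' @export
range_ratio <- function(ipr_a, ipr_b) {
  out <- ipr_a / ipr_b
  if (any(bad <- !is.na(ipr_b) & ipr_b == 0)) {
    warning("zero denominator IPR; ratio undefined")
    out[bad] <- NA_real_
  }
  out
}

#' Two-group distribution comparison
#'
#' Wilcoxon rank-sum or Kolmogorov-Smirnov test between two groups of pair
#' statistics (correlations, proportions, range ratios...), one- or
#' two-sided. Used for pair-type, lineage, passage-bin and mutation-status
#' comparisons.
#'
#' @param values_by_group list of exactly two numeric vectors (each >= 3
#'   values); names are group labels.
#' @param test `"wilcoxon"` (default) or `"ks"`.
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (first group
#'   relative to second).
#' @return list with `p_value`, `test`, `alternative`, `n` (group sizes).
#' @export
compare_groups <- function(values_by_group, test = c("wilcoxon", "ks"),
                           alternative = "two.sided") {
  test <- match.arg(test)
  if (length(values_by_group) != 2L)
    stop("exactly two groups required")
  if (any(lengths(values_by_group) < 3L))
    stop("each group needs at least 3 values")
  a <- values_by_group[[1L]]; b <- values_by_group[[2L]]
  if (length(unique(c(a, b))) == 1L) {
    warning("all values tied; returning p = 1")
    return(list(p_value = 1, test = test, alternative = alternative,
                n = lengths(values_by_group)))
  }
  p <- if (test == "wilcoxon")
    suppressWarnings(wilcox.test(a, b, alternative = alternative))$p.value
  else
    suppressWarnings(ks.test(a, b, alternative = switch(alternative,
      two.sided = "two.sided", less = "greater", greater = "less")))$p.value
  list(p_value = p, test = test, alternative = alternative,
       n = lengths(values_by_group))
}

#' Detect potentially mislabeled samples
#'
#' A sample in a low-correlation intra-model pair (r < `r_low`) that shows
#' high correlation (r > `r_high`) to a sample of a *different* model is
#' reported for manual review (it is never dropped automatically).
#'
#' @param pair_table pair results including cross-model pairs, with columns
#'   `sample_a`, `sample_b`, `pair_type`, `pearson_r`.
#' @param r_low,r_high cutoffs (defaults 0.6 and 0.9).
#' @return character vector of suspect sample ids (possibly empty).
#' @export
flag_mislabeled <- function(pair_table, r_low = 0.6, r_high = 0.9) {
  intra <- pair_table$pair_type %in% c("PT_PDX", "PDX_PDX")
  low <- pair_table[intra & !is.na(pair_table$pearson_r) &
                      pair_table$pearson_r < r_low, , drop = FALSE]
  cross <- pair_table[pair_table$pair_type == "CROSS_MODEL" &
                        !is.na(pair_table$pearson_r) &
                        pair_table$pearson_r > r_high, , drop = FALSE]
  suspects <- intersect(unique(c(low$sample_a, low$sample_b)),
                        unique(c(cross$sample_a, cross$sample_b)))
  sort(suspects)
}
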