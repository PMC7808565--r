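# Cohort-level recurrent-CNA analysis: simplified G scores with
# cyclic-permutation significance, PT-anchored rescaling, delta-G shift
# analysis, and preranked GSEA with the leading-edge significant-gene rule.

#' Simplified cohort G scores
#'
#' For every fixed-width genomic bin, the amplification G score is the mean
#' over samples of `max(log2 - t, 0)` and the deletion G score the mean of
#' `max(-log2 - t, 0)` with event threshold `t` — one expression combining
#' event frequency and average amplitude across the cohort. Samples without
#' coverage of a bin contribute zero. Gene-level scores take the value of
#' the bin with the largest overlap (ties toward the leftmost bin).
#' Significance comes from cyclic within-genome permutation of each
#' sample's bin values (which preserves each sample's amplitude spectrum
#' and segment-length structure): permuted scores are pooled across bins to
#' form the null, per-bin p values are Benjamini-Hochberg adjusted, and
#' genes are flagged significant at q < `sig_q`.
#'
#' @param profiles list of centered [cna_profile] objects (>= 5 samples).
#' @param genes gene-model data frame.
#' @param width bin width in bp (default 100 kb).
#' @param t event threshold on |log2 ratio| (default 0.1).
#' @param n_perm number of cyclic permutations (default 20; the null pools
#'   all bins of all permutations).
#' @param seed RNG seed for the permutations.
#' @param sig_q q-value cutoff for the significance mask (default 0.25).
#' @return list of class `cohort_gscores`: `genes` (data frame with `gene`,
#'   `g_amp`, `g_del`, `q_amp`, `q_del`, `sig_amp`, `sig_del`), `bins`
#'   (per-bin scores), `n_samples`, `t`, `width`.
#' @export
compute_gscores <- function(profiles, genes, width = 1e5, t = 0.1,
                            n_perm = 20, seed = 1, sig_q = 0.25) {
  if (length(profiles) < 5L)
    stop("cohort G scores need at least 5 samples (got ",
         length(profiles), ")")
  binned <- lapply(profiles, function(p) binned_to_vector(bin_profile(p, width)))
  all_bins <- sort(unique(unlist(lapply(binned, names), use.names = FALSE)))
  M <- matrix(0, nrow = length(all_bins), ncol = length(binned),
              dimnames = list(all_bins, NULL))
  for (j in seq_along(binned)) M[names(binned[[j]]), j] <- binned[[j]]
  # order bins genomically for the cyclic shift
  parts <- strsplit(all_bins, ":", fixed = TRUE)
  bchrom <- vapply(parts, `[`, "", 1L)
  bstart <- as.numeric(vapply(parts, `[`, "", 2L))
  o <- order(match(bchrom, .chrom_order(bchrom)), bstart)
  M <- M[o, , drop = FALSE]
  bchrom <- bchrom[o]; bstart <- bstart[o]
  g_amp <- rowMeans(pmax(M - t, 0))
  g_del <- rowMeans(pmax(-M - t, 0))
  nb <- nrow(M)
  set.seed(seed)
  null_amp <- numeric(0); null_del <- numeric(0)
  for (p in seq_len(n_perm)) {
    shifts <- sample.int(nb, ncol(M), replace = TRUE)
    P <- vapply(seq_len(ncol(M)), function(j) {
      s <- shifts[j]
      M[c(seq.int(s, nb), seq_len(s - 1L)), j]
    }, numeric(nb))
    null_amp <- c(null_amp, rowMeans(pmax(P - t, 0)))
    null_del <- c(null_del, rowMeans(pmax(-P - t, 0)))
  }
  p_of <- function(obs, null) {
    sn <- sort(null)
    n_ge <- length(sn) - findInterval(obs, sn, left.open = TRUE)
    (1 + n_ge) / (1 + length(sn))
  }
  p_amp <- p_of(g_amp, null_amp)
  p_del <- p_of(g_del, null_del)
  q_amp <- p.adjust(p_amp, "BH")
  q_del <- p.adjust(p_del, "BH")
  bins <- data.frame(chrom = bchrom, start = bstart, end = bstart + width,
                     g_amp = g_amp, g_del = g_del,
                     q_amp = q_amp, q_del = q_del, stringsAsFactors = FALSE)
  # gene-level: bin with the largest overlap, ties to the leftmost bin
  gi <- rep(NA_integer_, nrow(genes))
  for (ch in intersect(unique(genes$chrom), unique(bchrom))) {
    gix <- which(genes$chrom == ch)
    bix <- which(bchrom == ch)
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(genes$start[gix] + 1L, genes$end[gix]),
      IRanges::IRanges(bstart[bix] + 1L, bstart[bix] + width))
    if (!length(ov)) next
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    ovw <- pmin(genes$end[gix][qh], bstart[bix][sh] + width) -
      pmax(genes$start[gix][qh], bstart[bix][sh])
    oo <- order(qh, -ovw, sh)
    keep <- !duplicated(qh[oo])
    gi[gix[qh[oo][keep]]] <- bix[sh[oo][keep]]
  }
  ok <- !is.na(gi)
  gdf <- data.frame(gene = genes$gene_id[ok],
                    g_amp = g_amp[gi[ok]], g_del = g_del[gi[ok]],
                    q_amp = q_amp[gi[ok]], q_del = q_del[gi[ok]],
                    stringsAsFactors = FALSE)
  gdf$sig_amp <- gdf$q_amp < sig_q
  gdf$sig_del <- gdf$q_del < sig_q
  rownames(gdf) <- NULL
  structure(list(genes = gdf, bins = bins, n_samples = length(profiles),
                 t = t, width = width), class = "cohort_gscores")
}

#' @export
print.cohort_gscores <- function(x, ...) {
  cat("Cohort G scores:", x$n_samples, "samples,", nrow(x$bins), "bins,",
      nrow(x$genes), "genes\n")
  cat(sprintf("  max g_amp = %.3f, max g_del = %.3f; %d / %d genes significant (amp/del)\n",
              max(x$genes$g_amp), max(x$genes$g_del),
              sum(x$genes$sig_amp), sum(x$genes$sig_del)))
  invisible(x)
}

#' Rescale a PDX cohort's G scores onto the PT scale
#'
#' G-score ranges are systematically lower in PT cohorts (stromal DNA
#' dilutes the CNA signal), so PDX gene-level G scores are mapped onto the
#' PT scale via a global linear regression of PDX on PT scores over shared
#' genes, separately for the amplification and deletion tracks: scaled
#' G = (G - intercept) / slope.
#'
#' @param pdx,pt `cohort_gscores` objects (see [compute_gscores()]).
#' @param min_slope smallest usable |slope| (default 0.05).
#' @return `pdx` with rescaled gene-level scores and an added `scaling`
#'   element (`amp`/`del` intercept-slope vectors).
#' @export
scale_gscores <- function(pdx, pt, min_slope = 0.05) {
  sh <- intersect(pdx$genes$gene, pt$genes$gene)
  if (length(sh) < 10L) stop("too few shared genes to fit a scaling")
  ia <- match(sh, pdx$genes$gene); ib <- match(sh, pt$genes$gene)
  fit_track <- function(y, x) {
    f <- lm(y ~ x)
    cf <- c(intercept = unname(coef(f)[1L]), slope = unname(coef(f)[2L]))
    if (!is.finite(cf["slope"]) || abs(cf["slope"]) < min_slope)
      stop("near-zero scaling slope; cohorts not comparable")
    cf
  }
  sc_amp <- fit_track(pdx$genes$g_amp[ia], pt$genes$g_amp[ib])
  sc_del <- fit_track(pdx$genes$g_del[ia], pt$genes$g_del[ib])
  out <- pdx
  out$genes$g_amp <- (pdx$genes$g_amp - sc_amp["intercept"]) / sc_amp["slope"]
  out$genes$g_del <- (pdx$genes$g_del - sc_del["intercept"]) / sc_del["slope"]
  out$scaling <- list(amp = sc_amp, del = sc_del)
  out
}

#' Per-gene G-score shift between two cohorts
#'
#' Computes delta-G = G(cohort 2) - G(cohort 1) per gene over the shared
#' gene universe, for the amplification and deletion tracks. Cohorts should
#' be on a common scale first (see [scale_gscores()]).
#'
#' @param g1,g2 `cohort_gscores` objects.
#' @return data frame with `gene`, `dg_amp`, `dg_del`.
#' @export
delta_g <- function(g1, g2) {
  sh <- intersect(g1$genes$gene, g2$genes$gene)
  i1 <- match(sh, g1$genes$gene); i2 <- match(sh, g2$genes$gene)
  data.frame(gene = sh,
             dg_amp = g2$genes$g_amp[i2] - g1$genes$g_amp[i1],
             dg_del = g2$genes$g_del[i2] - g1$genes$g_del[i1],
             stringsAsFactors = FALSE)
}

#' Correlation of two G-score shift vectors
#'
#' Pearson correlation of two delta-G tables (e.g. PT to PDX-early vs
#' PDX-early to PDX-late) over shared genes; a positive correlation would
#' indicate directional selection acting at both steps.
#'
#' @param d1,d2 data frames from [delta_g()].
#' @return named numeric: `amp` and `del` correlations.
#' @export
delta_g_correlation <- function(d1, d2) {
  sh <- intersect(d1$gene, d2$gene)
  i1 <- match(sh, d1$gene); i2 <- match(sh, d2$gene)
  safe_cor <- function(x, y)
    if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
  c(amp = safe_cor(d1$dg_amp[i1], d2$dg_amp[i2]),
    del = safe_cor(d1$dg_del[i1], d2$dg_del[i2]))
}

# weighted KS running enrichment score (weight exponent 1); returns the
# signed extreme of the running statistic and the index where it occurs
.gsea_es <- function(ord_scores, hit) {
  nr <- sum(abs(ord_scores[hit]))
  n_miss <- length(ord_scores) - sum(hit)
  if (nr == 0 || n_miss == 0) return(list(es = 0, at = 1L))
  step <- ifelse(hit, abs(ord_scores) / nr, -1 / n_miss)
  running <- cumsum(step)
  at <- which.max(abs(running))
  list(es = running[at], at = at)
}

#' Preranked gene-set enrichment with a leading-edge significance filter
#'
#' Classic preranked GSEA on a gene-level score vector (e.g. G scores):
#' genes are ranked by decreasing score, the weighted Kolmogorov-Smirnov
#' enrichment score (weight exponent 1) is computed per set, NES and
#' nominal p come from gene-label permutations, and FDR q values from the
#' pooled permutation null. Because genomic gene sets can contain many
#' positionally adjacent genes inside one amplicon, spurious enrichments
#' are filtered by requiring that leading-edge genes that individually pass
#' the cohort's G-score significance mask make up at least `le_frac_min` of
#' the set; a set is significant when NES > `nes_min`, q < `q_max` and the
#' leading-edge rule holds.
#'
#' @param gene_scores named numeric vector of gene-level scores (>= 0 for
#'   G-score tracks).
#' @param gene_sets a `gene_set_collection` or named list of character
#'   vectors; sets with fewer than `min_set` members in the ranked universe
#'   are skipped.
#' @param significant_genes character vector of genes passing the
#'   cohort-level significance mask (GISTIC-style q < 0.25).
#' @param n_perm number of gene-label permutations (default 1000).
#' @param seed RNG seed.
#' @param nes_min,q_max,le_frac_min significance rules (defaults 1.5, 0.05,
#'   0.20).
#' @param min_set minimum set size within the universe (default 5).
#' @return data frame of class `gsea_result`: `set`, `size`, `es`, `nes`,
#'   `p`, `q`, `leading_edge` (comma-separated), `le_sig_fraction`,
#'   `significant`.
#' @export
gsea_preranked <- function(gene_scores, gene_sets,
                           significant_genes = character(),
                           n_perm = 1000, seed = 1, nes_min = 1.5,
                           q_max = 0.05, le_frac_min = 0.20, min_set = 5) {
  sets <- if (inherits(gene_sets, "gene_set_collection")) gene_sets$sets
          else gene_sets
  o <- order(-gene_scores)
  scores <- gene_scores[o]
  universe <- names(scores)
  n <- length(universe)
  sets_u <- lapply(sets, intersect, y = universe)
  sets_u <- sets_u[lengths(sets_u) >= min_set]
  if (!length(sets_u)) stop("no gene set has >= ", min_set,
                            " members in the ranked universe")
  es <- numeric(length(sets_u)); le <- vector("list", length(sets_u))
  for (k in seq_along(sets_u)) {
    hit <- universe %in% sets_u[[k]]
    r <- .gsea_es(scores, hit)
    es[k] <- r$es
    le[[k]] <- if (r$es >= 0) universe[seq_len(r$at)][hit[seq_len(r$at)]]
               else universe[seq.int(r$at, n)][hit[seq.int(r$at, n)]]
  }
  set.seed(seed)
  sizes <- lengths(sets_u)
  usize <- sort(unique(sizes))
  perm_es <- matrix(NA_real_, nrow = length(sets_u), ncol = n_perm)
  for (p in seq_len(n_perm)) {
    # one label permutation serves every set size
    perm <- sample.int(n)
    for (k in seq_along(sets_u)) {
      hit <- logical(n)
      hit[perm[seq_len(sizes[k])]] <- TRUE
      perm_es[k, p] <- .gsea_es(scores, hit)$es
    }
  }
  nes <- numeric(length(sets_u)); pval <- numeric(length(sets_u))
  perm_nes <- perm_es
  for (k in seq_along(sets_u)) {
    pos <- perm_es[k, perm_es[k, ] >= 0]
    neg <- perm_es[k, perm_es[k, ] < 0]
    mpos <- if (length(pos)) mean(pos) else NA_real_
    mneg <- if (length(neg)) mean(abs(neg)) else NA_real_
    nes[k] <- if (es[k] >= 0) {
      if (is.na(mpos) || mpos == 0) 0 else es[k] / mpos
    } else {
      if (is.na(mneg) || mneg == 0) 0 else es[k] / mneg
    }
    pval[k] <- if (es[k] >= 0) {
      if (!length(pos)) 1 else (1 + sum(pos >= es[k])) / (1 + length(pos))
    } else {
      if (!length(neg)) 1 else (1 + sum(neg <= es[k])) / (1 + length(neg))
    }
    perm_nes[k, ] <- ifelse(perm_es[k, ] >= 0,
                            if (is.na(mpos) || mpos == 0) 0
                            else perm_es[k, ] / mpos,
                            if (is.na(mneg) || mneg == 0) 0
                            else perm_es[k, ] / mneg)
  }
  # permutation-based FDR (positive and negative sides separately)
  all_perm <- as.numeric(perm_nes)
  q <- vapply(seq_along(nes), function(k) {
    if (nes[k] >= 0) {
      num <- mean(all_perm >= nes[k])
      den <- mean(nes >= nes[k])
    } else {
      num <- mean(all_perm <= nes[k])
      den <- mean(nes <= nes[k])
    }
    if (den == 0) 1 else min(1, num / den)
  }, 0)
  le_frac <- vapply(seq_along(sets_u), function(k)
    length(intersect(le[[k]], significant_genes)) / length(sets_u[[k]]), 0)
  res <- data.frame(set = names(sets_u), size = sizes, es = es, nes = nes,
                    p = pval, q = q,
                    leading_edge = vapply(le, paste, "", collapse = ","),
                    le_sig_fraction = le_frac,
                    significant = nes > nes_min & q < q_max &
                      le_frac >= le_frac_min,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, class = c("gsea_result", "data.frame"))
}

#' Gene-set enrichment shift between two cohorts
#'
#' Delta-NES = NES(cohort 2) - NES(cohort 1) restricted to sets significant
#' in at least one cohort.
#'
#' @param res1,res2 `gsea_result` data frames on a shared set universe.
#' @return data frame with `set`, `nes_1`, `nes_2`, `delta_nes` (possibly
#'   zero rows, with a warning).
#' @export
delta_nes <- function(res1, res2) {
  sh <- intersect(res1$set, res2$set)
  i1 <- match(sh, res1$set); i2 <- match(sh, res2$set)
  keep <- res1$significant[i1] | res2$significant[i2]
  if (!any(keep))
    warning("no set significant in either cohort; empty delta-NES")
  out <- data.frame(set = sh[keep], nes_1 = res1$nes[i1][keep],
                    nes_2 = res2$nes[i2][keep],
                    delta_nes = res2$nes[i2][keep] - res1$nes[i1][keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
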