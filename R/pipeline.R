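# End-to-end convenience driver: raw profiles + metadata + genes ->
# per-pair concordance table with altered-gene sets.

#' Prepare profiles for concordance analysis
#'
#' Applies the standard preprocessing to each profile: size/probe
#' filtering (platform-aware), 10-kb median centering, gene-level copy
#' number and the binned aberration summary.
#'
#' @param profiles named list of [cna_profile] objects.
#' @param metadata a `cna_metadata` covering the profiles.
#' @param genes gene-model data frame.
#' @param width window width for the aberration summary (default 100 kb).
#' @return list of class `prepared_profiles`: `gene_cn` (named list of
#'   gene-level vectors), `ipr` (named numeric), `centered` (profiles).
#' @export
prepare_profiles <- function(profiles, metadata, genes, width = 1e5) {
  md <- as.data.frame(metadata)
  platform <- setNames(md$platform, md$sample_id)
  out_cn <- list(); out_ipr <- numeric(0); centered <- list()
  for (sid in names(profiles)) {
    p <- filter_segments(profiles[[sid]],
                         platform = if (sid %in% names(platform))
                           platform[[sid]] else "WGS")
    p <- median_center(p)
    centered[[sid]] <- p
    out_cn[[sid]] <- gene_copy_number(p, genes)
    out_ipr[sid] <- aberration_summary(bin_profile(p, width))$ipr_5_95
  }
  structure(list(gene_cn = out_cn, ipr = out_ipr, centered = centered),
            class = "prepared_profiles")
}

#' Pairwise concordance over an enumerated pair table
#'
#' Runs the full per-pair analysis: gene-based Pearson correlation,
#' improved-regression fit, altered genes at the subclonal (0.5) and
#' stringent (1.0) thresholds, range ratio, validity and discordance flags.
#'
#' @param pairs pair table from [enumerate_pairs()].
#' @param prepared output of [prepare_profiles()].
#' @param min_genes minimum shared genes per pair (default 200).
#' @return list of class `pair_results`: `table` (one row per pair with
#'   `pearson_r`, `n_genes`, `ipr_a`, `ipr_b`, `range_ratio`, `valid`,
#'   `discordant`, `n_altered_05`, `n_altered_10`), `fits`, `altered_05`,
#'   `altered_10` (lists indexed like the table rows).
#' @export
pair_concordance <- function(pairs, prepared, min_genes = 200) {
  n <- nrow(pairs)
  fits <- vector("list", n)
  alt05 <- vector("list", n); alt10 <- vector("list", n)
  r <- numeric(n); ng <- integer(n)
  for (i in seq_len(n)) {
    a <- prepared$gene_cn[[pairs$sample_a[i]]]
    b <- prepared$gene_cn[[pairs$sample_b[i]]]
    fit <- tryCatch(cna_pair_fit(a, b, min_genes = min_genes),
                    error = function(e) NULL)
    fits[[i]] <- fit
    if (is.null(fit)) {
      r[i] <- NA_real_; ng[i] <- length(intersect(names(a), names(b)))
      alt05[[i]] <- character(); alt10[[i]] <- character()
    } else {
      r[i] <- fit$pearson_r; ng[i] <- fit$n_genes
      alt05[[i]] <- altered_genes(fit, 0.5)
      alt10[[i]] <- altered_genes(fit, 1.0)
    }
  }
  tab <- pairs
  tab$pearson_r <- r
  tab$n_genes <- ng
  tab$ipr_a <- unname(prepared$ipr[pairs$sample_a])
  tab$ipr_b <- unname(prepared$ipr[pairs$sample_b])
  tab$range_ratio <- suppressWarnings(range_ratio(tab$ipr_a, tab$ipr_b))
  tab <- filter_valid_pairs(tab)
  tab$discordant <- flag_discordant(tab$pearson_r, tab$ipr_a, tab$ipr_b)
  tab$n_altered_05 <- lengths(alt05)
  tab$n_altered_10 <- lengths(alt10)
  structure(list(table = tab, fits = fits, altered_05 = alt05,
                 altered_10 = alt10), class = "pair_results")
}

#' @export
print.pair_results <- function(x, ...) {
  t <- x$table
  cat("Pairwise CNA concordance:", nrow(t), "pairs (",
      sum(t$valid), "valid )\n")
  for (ty in unique(t$pair_type)) {
    sel <- t$pair_type == ty & t$valid
    if (any(sel))
      cat(sprintf("  %-20s n = %3d  median r = %.3f  median range ratio = %.3f\n",
                  ty, sum(sel), median(t$pearson_r[sel]),
                  median(t$range_ratio[sel], na.rm = TRUE)))
  }
  invisible(x)
}
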