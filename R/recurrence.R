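# Model-based recurrence of altered genes, gene-set proportion tests and
# the copy-number / drug-response association screen.

#' Model-based recurrence frequency of altered genes
#'
#' Aggregates per-pair altered-gene sets (called at the stringent threshold,
#' |residual| > 1.0, with both-deleted omission) into per-gene recurrence
#' frequencies. Counting is per model: a gene altered in several pairs of
#' one model contributes once, which avoids bias toward models with many
#' similar samples. The denominator is the number of models contributing at
#' least one valid pair of the requested comparison type.
#'
#' @param altered_sets named list of character vectors (one per pair).
#' @param pair_table data frame with one row per element of `altered_sets`
#'   (matched by name or position), with columns `model_id` and `pair_type`.
#' @param comparison_type `"PT_PDX"` or `"PDX_PDX"`.
#' @return data frame with `gene`, `n_models_altered`, `n_models_total`,
#'   `frequency`, sorted by decreasing frequency.
#' @export
recurrence_frequency <- function(altered_sets, pair_table,
                                 comparison_type = c("PT_PDX", "PDX_PDX")) {
  comparison_type <- match.arg(comparison_type)
  if (!length(altered_sets)) stop("no altered-gene sets supplied")
  stopifnot(length(altered_sets) == nrow(pair_table))
  sel <- which(pair_table$pair_type == comparison_type)
  if (!length(sel)) stop("no pairs of type ", comparison_type)
  models <- unique(pair_table$model_id[sel])
  per_model <- lapply(models, function(m) {
    unique(unlist(altered_sets[sel[pair_table$model_id[sel] == m]],
                  use.names = FALSE))
  })
  genes <- sort(unique(unlist(per_model, use.names = FALSE)))
  n_alt <- vapply(genes, function(g)
    sum(vapply(per_model, function(s) g %in% s, TRUE)), 0L)
  out <- data.frame(gene = genes, n_models_altered = as.integer(n_alt),
                    n_models_total = length(models),
                    frequency = n_alt / length(models),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Proportion of altered genes per gene set, tested against background
#'
#' For each pair and gene set, the proportion of the set's genes (within the
#' evaluated gene universe) called altered at the subclonal-inclusive
#' threshold. Each set's per-pair proportions are compared with the
#' protein-coding background proportions by a one-sided Wilcoxon rank-sum
#' test (alternative: set proportions greater).
#'
#' @param altered_sets named list of per-pair altered-gene vectors (at
#'   thr 0.5).
#' @param gene_sets a `gene_set_collection` (see [read_gene_sets()]) or a
#'   named list of character vectors.
#' @param universe character vector: the evaluated (protein-coding) gene
#'   universe shared by the pairs.
#' @return list with `proportions` (pairs x sets matrix), `background`
#'   (per-pair background proportion), `p_values` (named, one-sided
#'   rank-sum vs background).
#' @export
geneset_proportions <- function(altered_sets, gene_sets, universe) {
  sets <- if (inherits(gene_sets, "gene_set_collection")) gene_sets$sets
          else gene_sets
  sets_u <- lapply(sets, intersect, y = universe)
  empty <- lengths(sets_u) == 0L
  if (any(empty)) {
    warning("gene set(s) with no genes in the universe skipped: ",
            paste(names(sets_u)[empty], collapse = ", "))
    sets_u <- sets_u[!empty]
  }
  if (!length(sets_u)) stop("no usable gene sets")
  alt_u <- lapply(altered_sets, intersect, y = universe)
  prop <- vapply(sets_u, function(s)
    vapply(alt_u, function(a) length(intersect(a, s)) / length(s), 0),
    numeric(length(alt_u)))
  if (is.null(dim(prop)))
    prop <- matrix(prop, nrow = length(alt_u),
                   dimnames = list(names(altered_sets), names(sets_u)))
  bg <- vapply(alt_u, function(a) length(a) / length(universe), 0)
  p <- vapply(seq_len(ncol(prop)), function(j)
    suppressWarnings(wilcox.test(prop[, j], bg,
                                 alternative = "greater"))$p.value, 0)
  names(p) <- colnames(prop)
  list(proportions = prop, background = bg, p_values = p)
}

#' Copy-number / drug-response association screen
#'
#' Screens every gene-drug combination by the Pearson correlation between
#' the gene's log2 copy-number ratio and the drug's AUC sensitivity score
#' across cell lines (pairwise-complete). P values are Bonferroni-adjusted
#' over the whole tested family (q values); associations with q < `q_max`
#' are retained and called significant only when the gene's expression is
#' also correlated with the drug's AUC at nominal p < `expr_p` with the
#' same sign.
#'
#' @param gene_cn genes x cell-lines matrix of log2 CN ratios.
#' @param drug_auc drugs x cell-lines matrix of AUC scores.
#' @param expression genes x cell-lines expression matrix (same gene ids).
#' @param min_lines minimum shared cell lines per test (default 20).
#' @param q_max Bonferroni q cutoff (default 0.1).
#' @param expr_p expression-confirmation p cutoff (default 0.05).
#' @return data frame with one row per tested gene-drug combination:
#'   `gene`, `drug`, `n`, `r_cn`, `p_cn`, `q_cn`, `r_expr`, `p_expr`,
#'   `same_direction`, `significant`.
#' @export
drug_association <- function(gene_cn, drug_auc, expression,
                             min_lines = 20, q_max = 0.1, expr_p = 0.05) {
  shared <- intersect(colnames(gene_cn), colnames(drug_auc))
  rows <- list()
  for (g in rownames(gene_cn)) for (d in rownames(drug_auc)) {
    x <- gene_cn[g, shared]; y <- drug_auc[d, shared]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < min_lines) next
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) next  # constant vector: skip
    ct <- cor.test(x[ok], y[ok])
    rows[[length(rows) + 1L]] <-
      data.frame(gene = g, drug = d, n = sum(ok),
                 r_cn = unname(ct$estimate), p_cn = ct$p.value,
                 stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no testable gene-drug combinations")
  res <- do.call(rbind, rows)
  res$q_cn <- pmin(res$p_cn * nrow(res), 1)  # Bonferroni over the family
  res$r_expr <- NA_real_; res$p_expr <- NA_real_
  res$same_direction <- NA
  for (i in which(res$q_cn < q_max)) {
    g <- res$gene[i]; d <- res$drug[i]
    if (!g %in% rownames(expression)) next
    sh2 <- intersect(colnames(expression), colnames(drug_auc))
    x <- expression[g, sh2]; y <- drug_auc[d, sh2]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < min_lines || sd(x[ok]) == 0 || sd(y[ok]) == 0) next
    ct <- cor.test(x[ok], y[ok])
    res$r_expr[i] <- unname(ct$estimate)
    res$p_expr[i] <- ct$p.value
    res$same_direction[i] <- sign(ct$estimate) == sign(res$r_cn[i])
  }
  res$significant <- !is.na(res$same_direction) & res$q_cn < q_max &
    res$p_expr < expr_p & res$same_direction
  res$significant[is.na(res$significant)] <- FALSE
  rownames(res) <- NULL
  res
}
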