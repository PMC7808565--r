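# small gene table on a two-chromosome toy genome
toy_genes <- function(n = 40, chrom_len = 4e6) {
  data.frame(gene_id = sprintf("g%02d", 1:n), symbol = sprintf("g%02d", 1:n),
             chrom = rep(c("1", "2"), each = n / 2),
             start = rep(seq(0, chrom_len - 1e5, length.out = n / 2), 2),
             end = rep(seq(0, chrom_len - 1e5, length.out = n / 2), 2) + 5e4,
             biotype = "protein_coding", stringsAsFactors = FALSE)
}

flat_cohort <- function(values_list, chrom_len = 4e6) {
  profs <- lapply(seq_along(values_list), function(i) {
    v <- values_list[[i]]
    cna_profile(data.frame(
      chrom = rep(c("1", "2"), each = length(v) / 2),
      start = rep(seq(0, chrom_len - chrom_len / (length(v) / 2),
                      length.out = length(v) / 2), 2),
      end = rep(seq(chrom_len / (length(v) / 2), chrom_len,
                    length.out = length(v) / 2), 2),
      log2_ratio = v), sprintf("S%d", i))
  })
  names(profs) <- sprintf("S%d", seq_along(profs))
  profs
}

test_that("G scores combine frequency and amplitude above the event threshold", {
  genes <- toy_genes()
  # all samples flat zero -> all G scores zero
  cz <- flat_cohort(replicate(5, rep(0, 20), simplify = FALSE))
  g0 <- compute_gscores(cz, genes, n_perm = 2)
  expect_true(all(g0$genes$g_amp == 0) && all(g0$genes$g_del == 0))
  # all 5 samples share one +1 segment -> g_amp = 1 - 0.1 = 0.9 there
  vals <- rep(0, 20); vals[3] <- 1
  ca <- flat_cohort(replicate(5, vals, simplify = FALSE))
  ga <- compute_gscores(ca, genes, n_perm = 2)
  expect_equal(max(ga$bins$g_amp), 0.9, tolerance = 1e-9)
  expect_equal(sum(ga$bins$g_amp > 0), sum(ga$bins$chrom == "1") / 10)
  # one of five samples -> frequency scaling: 0.9 / 5
  cb <- flat_cohort(c(list(vals), replicate(4, rep(0, 20), simplify = FALSE)))
  gb <- compute_gscores(cb, genes, n_perm = 2)
  expect_equal(max(gb$bins$g_amp), 0.9 / 5, tolerance = 1e-9)
  # deletions score on the negative side
  vd <- rep(0, 20); vd[12] <- -1
  gd <- compute_gscores(flat_cohort(replicate(5, vd, simplify = FALSE)),
                        genes, n_perm = 2)
  expect_equal(max(gd$bins$g_del), 0.9, tolerance = 1e-9)
  expect_true(all(gd$bins$g_amp == 0))
  expect_error(compute_gscores(ca[1:4], genes), "at least 5")
})

test_that("G scores are additive when cohorts are mixed", {
  genes <- toy_genes()
  set.seed(31)
  mk <- function(n) replicate(n, round(rnorm(20, 0, 0.6), 2), simplify = FALSE)
  va <- mk(5); vb <- mk(7)
  ga <- compute_gscores(flat_cohort(va), genes, n_perm = 2)
  gb <- compute_gscores(flat_cohort(vb), genes, n_perm = 2)
  gab <- compute_gscores(flat_cohort(c(va, vb)), genes, n_perm = 2)
  expect_equal(gab$bins$g_amp,
               (5 * ga$bins$g_amp + 7 * gb$bins$g_amp) / 12, tolerance = 1e-9)
  expect_equal(gab$bins$g_del,
               (5 * ga$bins$g_del + 7 * gb$bins$g_del) / 12, tolerance = 1e-9)
})

test_that("PT-anchored rescaling recovers exact linear relations and is idempotent", {
  genes <- toy_genes()
  set.seed(32)
  vals <- replicate(6, abs(round(rnorm(20, 0, 0.6), 2)) *
                      sample(c(1, -1), 20, TRUE), simplify = FALSE)
  pt <- compute_gscores(flat_cohort(vals), genes, n_perm = 2)
  # pdx = 2 * pt exactly -> scaled pdx equals pt
  pdx <- pt
  pdx$genes$g_amp <- 2 * pt$genes$g_amp
  pdx$genes$g_del <- 2 * pt$genes$g_del
  sc <- scale_gscores(pdx, pt)
  expect_equal(sc$genes$g_amp, pt$genes$g_amp, tolerance = 1e-9)
  expect_equal(unname(sc$scaling$amp["slope"]), 2, tolerance = 1e-9)
  # identity case
  sc_id <- scale_gscores(pt, pt)
  expect_equal(unname(sc_id$scaling$amp["slope"]), 1, tolerance = 1e-9)
  expect_equal(unname(sc_id$scaling$amp["intercept"]), 0, tolerance = 1e-9)
  # idempotence: rescaling an already-scaled cohort gives slope 1
  sc2 <- scale_gscores(sc, pt)
  expect_equal(unname(sc2$scaling$amp["slope"]), 1, tolerance = 1e-6)
  # degenerate: flat PDX scores cannot be anchored
  flat <- pt
  flat$genes$g_amp <- rep(0.01, nrow(flat$genes))
  expect_error(scale_gscores(flat, pt), "slope")
})

test_that("stromal dilution lowers the PT G-score range and rescaling repairs it", {
  cfg <- sim_config(n_models = 8)
  sim <- simulate_cohort(cfg, seed = 21)
  pts <- grep("_PT$", names(sim$samples), value = TRUE)
  pdx <- grep("_P0_L1$", names(sim$samples), value = TRUE)
  prof_pt <- lapply(pts, function(s)
    median_center(render_platform(sim, s, "WGS", seed = 21)))
  prof_px <- lapply(pdx, function(s)
    median_center(render_platform(sim, s, "WGS", seed = 21)))
  g_pt <- compute_gscores(prof_pt, sim$genes, n_perm = 3)
  g_px <- compute_gscores(prof_px, sim$genes, n_perm = 3)
  sc <- scale_gscores(g_px, g_pt)
  # dilution-compressed PT scores -> PDX-on-PT slope above 1
  expect_gt(unname(sc$scaling$amp["slope"]), 1)
  # rescaling preserves correlation and matches the range
  sh <- intersect(g_px$genes$gene, g_pt$genes$gene)
  r_before <- cor(g_px$genes$g_amp[match(sh, g_px$genes$gene)],
                  g_pt$genes$g_amp[match(sh, g_pt$genes$gene)])
  r_after <- cor(sc$genes$g_amp[match(sh, sc$genes$gene)],
                 g_pt$genes$g_amp[match(sh, g_pt$genes$gene)])
  expect_equal(r_before, r_after, tolerance = 1e-9)
})

test_that("delta-G is zero for identical cohorts and tracks injected shifts", {
  genes <- toy_genes()
  set.seed(33)
  vals <- replicate(6, abs(round(rnorm(20, 0, 0.5), 2)), simplify = FALSE)
  g1 <- compute_gscores(flat_cohort(vals), genes, n_perm = 2)
  d0 <- delta_g(g1, g1)
  expect_true(all(d0$dg_amp == 0) && all(d0$dg_del == 0))
  # independent random perturbations at two steps decorrelate
  set.seed(34)
  g2 <- g1; g2$genes$g_amp <- g1$genes$g_amp + runif(40, 0, 0.2)
  g3 <- g2; g3$genes$g_amp <- g2$genes$g_amp + runif(40, 0, 0.2)
  dc <- delta_g_correlation(delta_g(g1, g2), delta_g(g2, g3))
  expect_lt(abs(dc[["amp"]]), 0.5)
  # a shared systematic shift at both steps correlates positively
  shift <- c(rep(0.5, 10), rep(0, 30))
  g2s <- g1; g2s$genes$g_amp <- g1$genes$g_amp + shift + runif(40, 0, 0.02)
  g3s <- g2s; g3s$genes$g_amp <- g2s$genes$g_amp + shift + runif(40, 0, 0.02)
  dcs <- delta_g_correlation(delta_g(g1, g2s), delta_g(g2s, g3s))
  expect_gt(dcs[["amp"]], 0.5)
})

test_that("enrichment scores match the naive running-sum recomputation and fgsea", {
  set.seed(41)
  scores <- setNames(sort(abs(rnorm(400, 0, 0.5)), decreasing = TRUE),
                     sprintf("g%03d", 1:400))
  scores <- sample(scores)  # shuffle gene order, keep names attached
  sets <- list(top = names(sort(scores, decreasing = TRUE))[1:25],
               random = sample(names(scores), 40),
               spread = names(scores)[seq(1, 400, by = 8)])
  res <- gsea_preranked(scores, sets, n_perm = 50, seed = 7)
  sorted <- sort(scores, decreasing = TRUE)
  for (s in names(sets)) {
    expect_equal(res$es[res$set == s], naive_es(sorted, sets[[s]]),
                 tolerance = 1e-9)
  }
  expect_gt(res$es[res$set == "top"], 0.9)  # maximal enrichment at the top
  # independent cross-check of the ES statistic against fgsea
  skip_if_not_installed("fgsea")
  fg <- suppressWarnings(fgsea::fgsea(sets, scores, nperm = 16,
                                      gseaParam = 1))
  expect_equal(res$es[match(fg$pathway, res$set)], fg$ES, tolerance = 1e-6)
})

test_that("random gene sets are not called enriched; adjacency needs the leading-edge rule", {
  set.seed(43)
  n <- 600
  scores <- setNames(c(abs(rnorm(n - 40, 0, 0.1)), rep(0.9, 40)),
                     sprintf("g%03d", 1:n))
  # an "amplicon": 40 adjacent genes with identical high scores, none of
  # which passes the per-gene significance mask
  amplicon <- names(scores)[(n - 39):n]
  random_sets <- lapply(1:10, function(i) sample(names(scores), 30))
  names(random_sets) <- paste0("R", 1:10)
  res <- gsea_preranked(scores, c(list(AMP = amplicon), random_sets),
                        significant_genes = character(), n_perm = 200,
                        seed = 11)
  amp_row <- res[res$set == "AMP", ]
  expect_gt(amp_row$nes, 1.5)              # spuriously enriched by NES
  expect_equal(amp_row$le_sig_fraction, 0) # but no significant leading edge
  expect_false(amp_row$significant)        # filtered by the 20% rule
  # with the amplicon genes individually significant the set passes
  res2 <- gsea_preranked(scores, list(AMP = amplicon),
                         significant_genes = amplicon, n_perm = 200,
                         seed = 11)
  expect_true(res2$significant[1])
  expect_gte(res2$le_sig_fraction[1], 0.2)
  # random sets: no enrichment calls
  expect_false(any(res$significant[res$set != "AMP"]))
})

test_that("delta-NES restricts to significant sets and is zero for identical cohorts", {
  res <- data.frame(set = c("A", "B", "C"), size = 10, es = c(0.5, 0.2, 0.7),
                    nes = c(1.8, 0.9, 2.2), p = 0.01, q = c(0.01, 0.5, 0.01),
                    leading_edge = "", le_sig_fraction = c(0.3, 0, 0.4),
                    significant = c(TRUE, FALSE, TRUE))
  d0 <- delta_nes(res, res)
  expect_equal(d0$delta_nes, c(0, 0))
  expect_setequal(d0$set, c("A", "C"))
  res2 <- res; res2$nes <- c(1.2, 1.0, 2.6); res2$significant <- c(FALSE, FALSE, TRUE)
  d <- delta_nes(res, res2)
  expect_setequal(d$set, c("A", "C"))  # significant in >= 1 cohort
  expect_equal(d$delta_nes[d$set == "A"], -0.6)
  res3 <- res; res3$significant <- FALSE
  expect_warning(dd <- delta_nes(res3, res3), "no set significant")
  expect_equal(nrow(dd), 0L)
})
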