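test_that("pair enumeration covers intra-model combinatorics and lineage relations", {
  md <- make_metadata(md_row("PT1", class = "PT", passage = NA),
                      md_row("X1", passage = 0),
                      md_row("X2", passage = 1))
  pr <- enumerate_pairs(md)
  expect_equal(sum(pr$pair_type == "PT_PDX"), 2L)
  expect_equal(sum(pr$pair_type == "PDX_PDX"), 1L)
  # PT is always listed first (reference); lower passage first in PDX pairs
  expect_true(all(pr$sample_a[pr$pair_type == "PT_PDX"] == "PT1"))
  expect_equal(pr$sample_a[pr$pair_type == "PDX_PDX"], "X1")

  # P1 -> split into two mice at P2: the branch samples are different
  # lineages of each other but the same lineage as their trunk ancestor
  md2 <- make_metadata(md_row("A", passage = 1, lineage = "L1"),
                      md_row("B", passage = 2, lineage = "L1.1"),
                      md_row("C", passage = 2, lineage = "L1.2"))
  pr2 <- enumerate_pairs(md2)
  rel <- function(a, b) pr2$lineage_relation[pr2$sample_a == a &
                                               pr2$sample_b == b]
  expect_equal(rel("A", "B"), "SAME_LINEAGE")
  expect_equal(rel("A", "C"), "SAME_LINEAGE")
  expect_equal(rel("B", "C"), "DIFFERENT_LINEAGE")

  # PDX without passage info is omitted from pairing
  md3 <- make_metadata(md_row("A", passage = 1),
                       md_row("B", passage = NA))
  expect_equal(nrow(enumerate_pairs(md3)), 0L)

  # platform must match within a pair
  md4 <- make_metadata(md_row("A", passage = 1, platform = "SNP"),
                       md_row("B", passage = 2, platform = "WES"))
  expect_equal(nrow(enumerate_pairs(md4)), 0L)
})

test_that("intra-patient PT pairs and cross-model background pairs are classified", {
  md <- make_metadata(
    md_row("PT_A", model_id = "M1", class = "PT", passage = NA, patient = "P1"),
    md_row("PT_B", model_id = "M2", class = "PT", passage = NA, patient = "P1"),
    md_row("X_A", model_id = "M1", passage = 1, patient = "P1"),
    md_row("X_C", model_id = "M3", passage = 1, patient = "P3"))
  pr <- enumerate_pairs(md, cross_model = TRUE)
  expect_equal(sum(pr$pair_type == "PT_PT_INTRAPATIENT"), 1L)
  cm <- pr[pr$pair_type == "CROSS_MODEL", ]
  # cross-model pairs exclude same-patient combinations
  expect_false(any(cm$sample_a == "PT_A" & cm$sample_b == "PT_B"))
  expect_true(nrow(cm) > 0)
})

test_that("profile correlation matches the closed-form Pearson computation", {
  set.seed(11)
  a <- setNames(rnorm(50), paste0("w", 1:50))
  expect_equal(correlate_profiles(a, a), 1.0)
  expect_equal(correlate_profiles(a, -a), -1.0)
  b <- setNames(rnorm(50), paste0("w", 1:50))
  manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(correlate_profiles(a, b), manual)
  expect_equal(correlate_profiles(a, b), correlate_profiles(b, a))
  expect_warning(r <- correlate_profiles(a, setNames(rep(1, 50), names(a))),
                 "zero variance")
  expect_true(is.na(r))
  expect_error(correlate_profiles(a[1:10], a[1:10]), "shared features")
})

test_that("studentized residuals equal the brute-force leave-one-out computation", {
  for (seed in c(2, 5, 9)) {
    set.seed(seed)
    n <- 20
    x <- rnorm(n); y <- 0.9 * x + rnorm(n, 0, 0.3)
    names(x) <- names(y) <- paste0("g", 1:n)
    fit <- cna_pair_fit(x, y, min_genes = n)
    expect_equal(unname(fit$studentized), loo_studentized(x, y),
                 tolerance = 1e-9)
  }
})

test_that("improved fit excludes exactly the |studentized| > 3 outliers and refits", {
  gp <- make_gene_pair(n = 300, seed = 4, noise = 0.05)
  y <- gp$b
  y[c(5, 50)] <- y[c(5, 50)] + 4  # gross outliers
  fit <- cna_pair_fit(gp$a, y, min_genes = 200)
  expect_setequal(fit$outliers, names(y)[abs(fit$studentized) > 3])
  expect_true(all(c("g005", "g050") %in% fit$outliers))
  keep <- setdiff(fit$genes, fit$outliers)
  ref <- lm(y[keep] ~ gp$a[keep])
  expect_equal(unname(fit$improved["intercept"]), unname(coef(ref)[1]))
  expect_equal(unname(fit$improved["slope"]), unname(coef(ref)[2]))
  # residuals of the improved fit are reported for ALL shared genes
  expect_length(fit$residuals, 300)
})

test_that("altered-gene calling responds to thresholds and nests", {
  gp <- make_gene_pair(n = 300, seed = 8, noise = 0)
  fit0 <- cna_pair_fit(gp$a, gp$b, min_genes = 200)
  expect_length(altered_genes(fit0, 0.1), 0L)  # identical relation
  y <- gp$b
  y["g010"] <- y["g010"] + 0.6
  fit <- cna_pair_fit(gp$a, y, min_genes = 200)
  expect_true("g010" %in% altered_genes(fit, 0.5))
  expect_false("g010" %in% altered_genes(fit, 1.0))
  # nesting holds on noisy synthetic pairs
  gp2 <- make_gene_pair(n = 400, seed = 13, noise = 0.4)
  fit2 <- cna_pair_fit(gp2$a, gp2$b, min_genes = 200)
  expect_true(all(altered_genes(fit2, 1.0) %in% altered_genes(fit2, 0.5)))
})

test_that("deletion flooring rescales below -3 and both-deleted genes are omitted at thr 1", {
  # under a fitted slope well below 1, a gene floored at (-3, -3) sits far
  # off the regression line: without the omission it would be called
  # altered even though both samples simply carry the same deep deletion
  gp <- make_gene_pair(n = 300, seed = 21, noise = 0.05, slope = 0.6)
  a <- gp$a; b <- gp$b
  a["g001"] <- -7; b["g001"] <- -3.5   # deleted in both samples
  a["g002"] <- -6; b["g002"] <- 0.2    # deleted in a only
  fit <- cna_pair_fit(a, b, min_genes = 200)
  expect_equal(unname(fit$x["g001"]), -3)  # floored
  expect_true("g001" %in% fit$both_deleted)
  expect_gt(abs(fit$residuals["g001"]), 1)
  expect_false("g001" %in% altered_genes(fit, 1.0))
  expect_true("g001" %in% altered_genes(fit, 1.0, omit_both_deleted = FALSE))
  expect_true("g002" %in% altered_genes(fit, 1.0))  # one-sided deletion kept
})

test_that("the pair fit is asymmetric while correlation is symmetric", {
  gp <- make_gene_pair(n = 250, seed = 31, noise = 0.2, slope = 1.4)
  f_ab <- cna_pair_fit(gp$a, gp$b, min_genes = 200)
  f_ba <- cna_pair_fit(gp$b, gp$a, min_genes = 200)
  expect_equal(f_ab$pearson_r, f_ba$pearson_r)
  expect_false(isTRUE(all.equal(f_ab$improved["slope"],
                                f_ba$improved["slope"])))
})

test_that("cross-platform comparison flags exactly the discrepant windows", {
  # 60 Mb of shared genome at 100-kb windows
  set.seed(17)
  vals <- rep(rnorm(60, 0, 0.5), each = 10)  # 600 windows in 1-Mb blocks
  a <- make_flat_profile(vals, seg_len = 1e5)
  b <- make_flat_profile(0.8 * vals, seg_len = 1e5, sample_id = "S2")
  cp <- cross_platform_compare(a, b)
  expect_equal(nrow(cp$outlier_windows), 0L)
  expect_equal(cp$discordant_fraction, 0)
  expect_equal(unname(cp$fit["slope"]), 0.8, tolerance = 1e-9)
  # one window perturbed by +5 is the only outlier
  vals2 <- 0.8 * vals
  vals2[300] <- vals2[300] + 5
  b2 <- make_flat_profile(vals2, seg_len = 1e5, sample_id = "S2")
  cp2 <- cross_platform_compare(a, b2)
  expect_equal(nrow(cp2$outlier_windows), 1L)
  expect_equal(cp2$outlier_windows$start, (300 - 1) * 1e5)
  expect_equal(cp2$discordant_fraction, 1 / 600)
  # a 1.5-Mb focal deletion absent in b: flagged windows cover the event
  vals3 <- vals
  vals3[101:115] <- vals3[101:115] - 2.5
  a3 <- make_flat_profile(vals3, seg_len = 1e5, sample_id = "S3")
  cp3 <- cross_platform_compare(a3, b)
  expect_true(all(((101:115 - 1) * 1e5) %in% cp3$outlier_windows$start))
  expect_gte(cp3$discordant_fraction, 15 / 600)
  # flagged windows map back to their source segments
  expect_true(any(cp3$outlier_segments_a$start >= 100 * 1e5 - 1 &
                    cp3$outlier_segments_a$start <= 115 * 1e5))
  expect_error(cross_platform_compare(make_flat_profile(rnorm(5)),
                                      make_flat_profile(rnorm(5))),
               "shared windows")
})

test_that("pair validity and discordance rules combine correlation and aberration", {
  tab <- data.frame(pearson_r = c(0.2, 0.95, 0.3, 0.5),
                    ipr_a = c(0.1, 0.1, 0.6, 0.6),
                    ipr_b = c(0.4, 0.4, 0.7, 0.4))
  out <- filter_valid_pairs(tab)
  expect_equal(out$valid, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(flag_discordant(c(0.5, 0.5, 0.6), c(0.6, 0.6, 0.7),
                               c(0.7, 0.4, 0.7)),
               c(TRUE, FALSE, FALSE))  # both-sample rule; strict r < 0.6
})

test_that("range ratios invert with argument order and handle zero denominators", {
  expect_equal(range_ratio(0.5, 0.5), 1.0)
  expect_equal(range_ratio(0.3, 0.6) * range_ratio(0.6, 0.3), 1.0)
  expect_warning(rr <- range_ratio(0.3, 0), "denominator")
  expect_true(is.na(rr))
})

test_that("group comparison agrees with an exhaustive rank-sum permutation null", {
  # exact two-sided rank-sum p via full enumeration at small n
  x <- c(1.1, 2.3, 3.7, 5.2)
  y <- c(2.0, 4.1, 6.5)
  w_obs <- sum(rank(c(x, y))[seq_along(x)])
  combs <- combn(7, 4)
  all_w <- apply(combs, 2, function(ix) sum(rank(c(x, y))[ix]))
  mu <- mean(all_w)
  p_exact <- mean(abs(all_w - mu) >= abs(w_obs - mu))
  expect_equal(compare_groups(list(x, y))$p_value, p_exact)
  # strong shift is detected; wrong-sided test is not
  set.seed(5)
  g1 <- rnorm(30); g2 <- rnorm(30) + 5
  expect_lt(compare_groups(list(g1, g2), alternative = "less")$p_value, 1e-6)
  expect_gt(compare_groups(list(g1, g2), alternative = "greater")$p_value, 0.5)
  expect_gt(compare_groups(list(g1, g1))$p_value, 0.9)
  expect_warning(p <- compare_groups(list(rep(1, 5), rep(1, 5)))$p_value,
                 "tied")
  expect_equal(p, 1)
  expect_error(compare_groups(list(g1, g2[1:2])), "at least 3")
  # KS branch
  expect_lt(compare_groups(list(g1, g2), test = "ks")$p_value, 1e-6)
})

test_that("mislabeled-sample detection reports but the pair table is untouched", {
  tab <- data.frame(
    sample_a = c("M1_PT", "M1_PT", "M2_X"),
    sample_b = c("M1_X", "M2_X", "M3_X"),
    pair_type = c("PT_PDX", "CROSS_MODEL", "CROSS_MODEL"),
    pearson_r = c(0.3, 0.95, 0.2), stringsAsFactors = FALSE)
  expect_equal(flag_mislabeled(tab), "M1_PT")
})
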