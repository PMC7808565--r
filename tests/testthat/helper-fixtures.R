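# Small in-code fixtures shared across test files.

# one-sample profile from parallel vectors (internal 0-based coords)
make_profile <- function(chrom, start, end, value, n_probes = NA,
                         sample_id = "S1") {
  cna_profile(data.frame(chrom = as.character(chrom), start = start,
                         end = end, log2_ratio = value,
                         n_probes = rep(n_probes, length.out = length(start))),
              sample_id = sample_id)
}

# a single-chromosome profile with given segment values, each `seg_len` bp
make_flat_profile <- function(values, seg_len = 1e6, chrom = "1",
                              sample_id = "S1") {
  n <- length(values)
  make_profile(rep(chrom, n), seg_len * (seq_len(n) - 1), seg_len * seq_len(n),
               values, sample_id = sample_id)
}

# tiny metadata table builder
make_metadata <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, as.data.frame))
  read_metadata(df)
}

md_row <- function(sample_id, model_id = "M1", class = "PDX", passage = 1,
                   lineage = "L1", platform = "WGS", patient = "P1",
                   tumor_type = "CRC", center = "C1") {
  list(sample_id = sample_id, model_id = model_id, patient_id = patient,
       tumor_type = tumor_type, center = center, sample_class = class,
       passage = passage, lineage_id = lineage, platform = platform)
}

# deterministic correlated gene vectors for regression tests
make_gene_pair <- function(n = 300, seed = 1, noise = 0.05, shift = 0,
                           slope = 1) {
  set.seed(seed)
  a <- rnorm(n, 0, 0.6)
  b <- slope * a + shift + rnorm(n, 0, noise)
  names(a) <- names(b) <- sprintf("g%03d", seq_len(n))
  list(a = a, b = b)
}

# brute-force externally studentized residuals (leave-one-out refit)
loo_studentized <- function(x, y) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    f <- lm(y[-i] ~ x[-i])
    pred <- coef(f)[1] + coef(f)[2] * x[i]
    s2 <- sum(resid(f)^2) / (n - 1 - 2)
    xb <- mean(x[-i])
    h <- 1 + 1 / (n - 1) + (x[i] - xb)^2 / sum((x[-i] - xb)^2)
    (y[i] - pred) / sqrt(s2 * h)
  }, 0)
}

# exhaustive optimal segmentation: minimize SSE + penalty * breakpoints
brute_force_pcf <- function(z, penalty) {
  n <- length(z)
  sse <- function(v) sum((v - mean(v))^2)
  best_cost <- Inf; best_starts <- 1L
  # enumerate all 2^(n-1) breakpoint patterns
  for (mask in 0:(2^(n - 1) - 1)) {
    bp <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    starts <- c(1L, bp + 1L)
    ends <- c(bp, n)
    cost <- sum(vapply(seq_along(starts), function(k)
      sse(z[starts[k]:ends[k]]), 0)) + penalty * length(bp)
    if (cost < best_cost - 1e-12) { best_cost <- cost; best_starts <- starts }
  }
  list(cost = best_cost, starts = best_starts)
}

# naive O(N * |set|) GSEA running-score recomputation
naive_es <- function(scores_sorted, set_members) {
  n <- length(scores_sorted)
  hit <- names(scores_sorted) %in% set_members
  nr <- sum(abs(scores_sorted[hit]))
  running <- numeric(n); acc <- 0
  for (i in seq_len(n)) {
    acc <- acc + if (hit[i]) abs(scores_sorted[i]) / nr else -1 / (n - sum(hit))
    running[i] <- acc
  }
  running[which.max(abs(running))]
}
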