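# Ground-truthed simulator of PDX-model cohorts: clonal/subclonal segment
# profiles, stromal dilution, lineage-tree passaging with drift, platform
# rendering and CN-coupled expression.

#' Chromosome lengths for simulation
#'
#' Approximate human autosome + X lengths, optionally scaled down for fast
#' test runs (scale 0.1 gives a ~310-Mb genome with realistic relative
#' chromosome sizes).
#'
#' @param scale multiplicative length scale (default 1).
#' @return named numeric vector of chromosome lengths in bp.
#' @export
sim_genome <- function(scale = 1) {
  mb <- c(`1` = 249, `2` = 242, `3` = 198, `4` = 190, `5` = 182, `6` = 171,
          `7` = 159, `8` = 145, `9` = 138, `10` = 134, `11` = 135,
          `12` = 133, `13` = 114, `14` = 107, `15` = 102, `16` = 90,
          `17` = 83, `18` = 80, `19` = 59, `20` = 64, `21` = 47, `22` = 51,
          X = 156)
  round(mb * 1e6 * scale)
}

#' Simulation configuration
#'
#' Defaults describe a plausible solid-tumor PDX cohort: ~25 clonal copy
#' number events per genome with lengths log-uniform between 100 kb and
#' 50 Mb (scaled with the genome) and log2 amplitudes concentrated at
#' single-copy-like gains/losses with rare deep deletions; a minor subclone
#' in the patient tumor; stromal contamination of the PT drawn from a
#' Beta(2, 3) (mean 0.4) against nearly pure PDXs (0.05); subclonal drift
#' events accumulating along the PDX lineage tree with a split into two
#' mice; and platform rendering with resolution floors and noise ordered
#' SNP (finest) < WGS < WES.
#'
#' @param genome named chromosome-length vector (default [sim_genome()]
#'   scaled to ~310 Mb for tractable runs).
#' @param n_models number of PDX models (default 20).
#' @param events_per_genome Poisson mean of clonal events (default 25).
#' @param subclone_events Poisson mean of extra events private to the PT
#'   minor subclone (default 5).
#' @param subclone_fraction cellular fraction of the PT minor subclone
#'   (default 0.3).
#' @param event_length_range log-uniform event length range in bp
#'   (default 100 kb to 50 Mb; events are capped at 90% of the chromosome).
#' @param amplitudes,amplitude_weights discrete log2 amplitude distribution.
#' @param drift_rate Poisson mean of new subclonal events per passage
#'   (default 2).
#' @param drift_cf_range cellular-fraction range of drift events.
#' @param passages PDX passages sampled along each branch (default
#'   P0, P1 pre-split; P2 and P4 on each of two branches).
#' @param split_at passage after which the lineage splits in two
#'   (default 1).
#' @param stroma_pt_beta Beta shape parameters of the PT stromal fraction.
#' @param stroma_pdx PDX stromal fraction (default 0.05).
#' @param n_genes number of synthetic genes (default 2000).
#' @param platform_res,platform_noise,platform_clip per-platform segment
#'   resolution floors (bp), additive log2 noise SD and lower dynamic-range
#'   clip.
#' @param expr_baseline_mean,expr_baseline_sd,expr_noise_sd,expr_decoupled
#'   expression model: per-gene baseline log2 TPM distribution, additive
#'   noise SD, and the fraction of genes whose expression is decoupled from
#'   copy number.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(genome = sim_genome(0.1), n_models = 20,
                       events_per_genome = 25, subclone_events = 5,
                       subclone_fraction = 0.3,
                       event_length_range = c(1e5, 5e7),
                       amplitudes = c(0.3, -0.3, 0.58, -0.58, 1, -1, -3),
                       amplitude_weights = c(0.24, 0.24, 0.16, 0.16,
                                             0.08, 0.08, 0.04),
                       drift_rate = 2, drift_cf_range = c(0.3, 1),
                       passages = list(trunk = c(0, 1), branch = c(2, 4)),
                       split_at = 1,
                       stroma_pt_beta = c(2, 3), stroma_pdx = 0.05,
                       n_genes = 2000,
                       platform_res = c(SNP = 5e4, WGS = 2e5, WES = 1e6),
                       platform_noise = c(SNP = 0.05, WGS = 0.10, WES = 0.15),
                       platform_clip = c(SNP = -8.6, WGS = -3.0, WES = -3.0),
                       expr_baseline_mean = 5, expr_baseline_sd = 1.5,
                       expr_noise_sd = 0.3, expr_decoupled = 0.2) {
  structure(list(genome = genome, n_models = n_models,
                 events_per_genome = events_per_genome,
                 subclone_events = subclone_events,
                 subclone_fraction = subclone_fraction,
                 event_length_range = event_length_range,
                 amplitudes = amplitudes,
                 amplitude_weights = amplitude_weights / sum(amplitude_weights),
                 drift_rate = drift_rate, drift_cf_range = drift_cf_range,
                 passages = passages, split_at = split_at,
                 stroma_pt_beta = stroma_pt_beta, stroma_pdx = stroma_pdx,
                 n_genes = n_genes, platform_res = platform_res,
                 platform_noise = platform_noise,
                 platform_clip = platform_clip,
                 expr_baseline_mean = expr_baseline_mean,
                 expr_baseline_sd = expr_baseline_sd,
                 expr_noise_sd = expr_noise_sd,
                 expr_decoupled = expr_decoupled),
            class = "sim_config")
}

# random CNA events: chromosome sampled by length, start uniform, length
# log-uniform (truncated at the chromosome end), amplitude from the
# discrete distribution; cf = cellular fraction of the event
.sim_events <- function(n, cfg, cf = 1) {
  if (n == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), amp = numeric(), cf = numeric()))
  g <- cfg$genome
  chrom <- sample(names(g), n, replace = TRUE, prob = g / sum(g))
  len <- exp(runif(n, log(cfg$event_length_range[1L]),
                   log(cfg$event_length_range[2L])))
  len <- pmin(len, g[chrom] * 0.9)
  start <- floor(runif(n, 0, g[chrom] - len))
  amp <- sample(cfg$amplitudes, n, replace = TRUE,
                prob = cfg$amplitude_weights)
  data.frame(chrom = chrom, start = start, end = floor(start + len),
             amp = amp, cf = cf, stringsAsFactors = FALSE)
}

# events -> pure-tumor segment profile: linear CN at any point is
# 2 * prod over covering events of ((1-cf) + cf * 2^amp); segments are the
# intervals between event breakpoints, log2 ratio is log2(CN / 2)
.events_to_profile <- function(events, cfg, sample_id) {
  rows <- list()
  for (ch in names(cfg$genome)) {
    ev <- events[events$chrom == ch, , drop = FALSE]
    bp <- sort(unique(c(0, cfg$genome[[ch]], ev$start, ev$end)))
    st <- bp[-length(bp)]; en <- bp[-1L]
    mid <- (st + en) / 2
    l2 <- vapply(mid, function(m) {
      cov <- ev$start <= m & ev$end > m
      log2(prod((1 - ev$cf[cov]) + ev$cf[cov] * 2^ev$amp[cov]))
    }, 0)
    # merge runs of equal value
    grp <- cumsum(c(1, diff(l2) != 0))
    rows[[ch]] <- data.frame(
      chrom = ch, start = tapply(st, grp, min), end = tapply(en, grp, max),
      log2_ratio = tapply(l2, grp, `[`, 1L), stringsAsFactors = FALSE)
  }
  cna_profile(do.call(rbind, rows), sample_id = sample_id)
}

# synthetic gene models: genes placed on a regular grid per chromosome
.sim_genes <- function(cfg) {
  g <- cfg$genome
  n_per <- round(cfg$n_genes * g / sum(g))
  n_per[n_per < 1] <- 1
  rows <- lapply(names(g), function(ch) {
    n <- n_per[[ch]]
    spacing <- g[[ch]] / n
    start <- floor((seq_len(n) - 1) * spacing + spacing * 0.25)
    end <- floor(start + pmin(spacing * 0.5, 2e4))
    data.frame(gene_id = sprintf("G%s_%04d", ch, seq_len(n)),
               symbol = sprintf("G%s_%04d", ch, seq_len(n)),
               chrom = ch, start = start, end = end,
               biotype = "protein_coding", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a cohort of PDX models with ground truth
#'
#' Each model gets a patient tumor (clonal events plus a minor subclone)
#' and a PDX lineage: trunk passages, a split into two mouse lineages at
#' `split_at`, and branch passages, with new subclonal drift events added
#' at every passage. Truth is platform-independent: per sample, the pure
#' tumor segment profile and per-gene true log2 ratio (stromal dilution and
#' platform noise are applied only at rendering time).
#'
#' @param cfg a [sim_config].
#' @param seed RNG seed; fixed seed gives a bit-identical truth set.
#' @return list of class `cna_simulation`: `metadata` (a `cna_metadata`),
#'   `genes`, `samples` (per sample: `events`, `segments` ([cna_profile]),
#'   `gene_log2` (named vector), `stromal_fraction`), `config`.
#' @export
simulate_cohort <- function(cfg = sim_config(), seed = 1) {
  set.seed(seed)
  genes <- .sim_genes(cfg)
  meta_rows <- list(); samples <- list()
  add_sample <- function(sid, model, patient, class, passage, lineage,
                         events, stroma) {
    meta_rows[[length(meta_rows) + 1L]] <<- data.frame(
      sample_id = sid, model_id = model, patient_id = patient,
      tumor_type = "SYNTH", center = "SIM", sample_class = class,
      passage = if (is.na(passage)) NA_integer_ else as.integer(passage),
      lineage_id = lineage, platform = "WGS", stringsAsFactors = FALSE)
    prof <- .events_to_profile(events, cfg, sid)
    samples[[sid]] <<- list(events = events, segments = prof,
                            gene_log2 = gene_copy_number(prof, genes),
                            stromal_fraction = stroma)
  }
  for (m in seq_len(cfg$n_models)) {
    model <- sprintf("M%03d", m)
    patient <- sprintf("PAT%03d", m)
    clonal <- .sim_events(rpois(1L, cfg$events_per_genome), cfg, cf = 1)
    sub <- .sim_events(rpois(1L, cfg$subclone_events), cfg,
                       cf = cfg$subclone_fraction)
    pt_events <- rbind(clonal, sub)
    f_pt <- rbeta(1L, cfg$stroma_pt_beta[1L], cfg$stroma_pt_beta[2L])
    add_sample(paste0(model, "_PT"), model, patient, "PT", NA, NA_character_,
               pt_events, f_pt)
    drift <- function() .sim_events(rpois(1L, cfg$drift_rate), cfg,
                                    cf = runif(1L, cfg$drift_cf_range[1L],
                                               cfg$drift_cf_range[2L]))
    # trunk
    trunk_events <- pt_events
    last_trunk_p <- -1L
    for (p in cfg$passages$trunk) {
      for (i in seq_len(p - last_trunk_p)) trunk_events <- rbind(trunk_events, drift())
      last_trunk_p <- p
      add_sample(sprintf("%s_P%d_L1", model, p), model, patient, "PDX", p,
                 "L1", trunk_events, cfg$stroma_pdx)
    }
    # split at cfg$split_at into two branches that drift independently
    for (br in 1:2) {
      br_events <- trunk_events
      last_p <- max(last_trunk_p, cfg$split_at)
      lin <- paste0("L1.", br)
      for (p in cfg$passages$branch) {
        for (i in seq_len(p - last_p)) br_events <- rbind(br_events, drift())
        last_p <- p
        add_sample(sprintf("%s_P%d_%s", model, p, lin), model, patient,
                   "PDX", p, lin, br_events, cfg$stroma_pdx)
      }
    }
  }
  metadata <- read_metadata(do.call(rbind, meta_rows))
  structure(list(metadata = metadata, genes = genes, samples = samples,
                 config = cfg), class = "cna_simulation")
}

#' @export
print.cna_simulation <- function(x, ...) {
  cat("Synthetic PDX cohort:", length(unique(x$metadata$model_id)),
      "models,", length(x$samples), "samples,", nrow(x$genes), "genes\n")
  invisible(x)
}

#' True altered genes between two simulated samples
#'
#' @param sim a `cna_simulation`.
#' @param sample_a,sample_b sample ids.
#' @param thr threshold on |difference of true gene log2 ratios|.
#' @return character vector of gene ids.
#' @export
true_altered_genes <- function(sim, sample_a, sample_b, thr = 0.5) {
  a <- sim$samples[[sample_a]]$gene_log2
  b <- sim$samples[[sample_b]]$gene_log2
  sh <- intersect(names(a), names(b))
  sh[abs(b[sh] - a[sh]) > thr]
}

#' Render a simulated sample as an observed segment profile
#'
#' Applies the measurement model of a platform to the sample's truth:
#' stromal dilution on the linear copy scale (observed CN =
#' (1-f) x tumor CN + f x 2, then log2), loss of segments below the
#' platform's resolution floor (absorbed into the longer neighbor),
#' additive Gaussian noise on segment means, and clipping of deep
#' deletions at the platform's dynamic-range floor. SNP profiles carry
#' probe counts at one probe per 2 kb.
#'
#' @param sim a `cna_simulation`.
#' @param sample_id which sample to render.
#' @param platform `"SNP"`, `"WGS"` or `"WES"`.
#' @param seed RNG seed for the noise.
#' @param stroma override stromal fraction (default: the sample's truth).
#' @return a [cna_profile].
#' @export
render_platform <- function(sim, sample_id, platform = "WGS", seed = 1,
                            stroma = NULL) {
  smp <- sim$samples[[sample_id]]
  if (is.null(smp)) stop("unknown sample ", sample_id)
  cfg <- sim$config
  f <- if (is.null(stroma)) smp$stromal_fraction else stroma
  seg <- as.data.frame(smp$segments)
  cn <- 2 * 2^seg$log2_ratio
  seg$log2_ratio <- log2(((1 - f) * cn + f * 2) / 2)
  res_floor <- cfg$platform_res[[platform]]
  rows <- list()
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, , drop = FALSE]
    # absorb sub-resolution segments into the longer flanking segment
    repeat {
      len <- s$end - s$start
      small <- which(len < res_floor)
      if (!length(small) || nrow(s) == 1L) break
      i <- small[which.min(len[small])]
      left_len <- if (i > 1L) len[i - 1L] else -1
      right_len <- if (i < nrow(s)) len[i + 1L] else -1
      if (left_len >= right_len) {
        s$end[i - 1L] <- s$end[i]
      } else {
        s$start[i + 1L] <- s$start[i]
      }
      s <- s[-i, , drop = FALSE]
    }
    # merge adjacent equal-value runs
    grp <- cumsum(c(1, diff(s$log2_ratio) != 0))
    s <- data.frame(chrom = ch, start = tapply(s$start, grp, min),
                    end = tapply(s$end, grp, max),
                    log2_ratio = tapply(s$log2_ratio, grp, `[`, 1L),
                    stringsAsFactors = FALSE)
    rows[[ch]] <- s
  }
  out <- do.call(rbind, rows)
  set.seed(seed + match(sample_id, names(sim$samples)))
  out$log2_ratio <- out$log2_ratio +
    rnorm(nrow(out), 0, cfg$platform_noise[[platform]])
  out$log2_ratio <- pmax(out$log2_ratio, cfg$platform_clip[[platform]])
  if (platform == "SNP") out$n_probes <- round((out$end - out$start) / 2000)
  cna_profile(out, sample_id = sample_id)
}

#' Render a whole cohort on one platform
#'
#' @param sim a `cna_simulation`.
#' @param platform platform to render (default `"WGS"`).
#' @param seed RNG seed.
#' @param sample_ids subset of samples (default: all).
#' @return named `cna_profile_list`.
#' @export
render_cohort <- function(sim, platform = "WGS", seed = 1,
                          sample_ids = names(sim$samples)) {
  out <- lapply(sample_ids, function(s)
    render_platform(sim, s, platform, seed = seed))
  names(out) <- sample_ids
  structure(out, class = "cna_profile_list")
}

#' Render CN-coupled expression for simulated samples
#'
#' Tumor expression is a per-gene baseline (log2 TPM, Normal) plus the true
#' gene log2 copy-number ratio plus noise; matched normals are baseline
#' plus noise. A configurable fraction of genes is decoupled from copy
#' number (expression ignores the CNA), emulating the limited fidelity of
#' expression-based CNA inference.
#'
#' @param sim a `cna_simulation`.
#' @param sample_ids tumor samples to render.
#' @param n_normals number of matched normal samples (default 10).
#' @param seed RNG seed.
#' @return an `expr_matrix` (TPM unit) covering tumors plus normals.
#' @export
render_expression <- function(sim, sample_ids, n_normals = 10, seed = 1) {
  cfg <- sim$config
  genes <- sim$genes
  set.seed(seed)
  baseline <- rnorm(nrow(genes), cfg$expr_baseline_mean, cfg$expr_baseline_sd)
  decoupled <- runif(nrow(genes)) < cfg$expr_decoupled
  cols <- c(sample_ids, sprintf("NORMAL%02d", seq_len(n_normals)))
  m <- matrix(NA_real_, nrow = nrow(genes), ncol = length(cols),
              dimnames = list(genes$gene_id, cols))
  for (j in seq_along(cols)) {
    noise <- rnorm(nrow(genes), 0, cfg$expr_noise_sd)
    if (j <= length(sample_ids)) {
      cn <- sim$samples[[cols[j]]]$gene_log2[genes$gene_id]
      cn[is.na(cn)] <- 0
      cn[decoupled] <- 0
      m[, j] <- baseline + cn + noise
    } else {
      m[, j] <- baseline + noise
    }
  }
  feats <- data.frame(feature_id = genes$gene_id, gene_id = genes$gene_id,
                      chrom = genes$chrom, start = genes$start,
                      end = genes$end, stringsAsFactors = FALSE)
  cls <- setNames(c(rep("tumor", length(sample_ids)),
                    rep("normal", n_normals)), cols)
  read_expression(2^m, feats, cls, unit = "TPM")
}
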