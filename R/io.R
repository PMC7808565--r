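#' @importFrom stats median quantile var lm predict rstudent coef resid sd
#'   wilcox.test ks.test cor cor.test p.adjust rnorm rpois runif rbeta pt
#'   setNames t.test fitted
#' @importFrom utils read.delim write.table head tail
NULL

# Internal coordinate convention: 0-based, half-open [start, end).
# SEG input defaults to 1-based inclusive (the common dialect).

.normalize_chrom <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  x[x == "M"] <- "MT"
  x
}

# chromosomes dropped everywhere (mitochondrial + Y); X retained for DNA
.DROP_CHROMS <- c("MT", "Y")

.chrom_order <- function(chroms) {
  u <- unique(chroms)
  num <- suppressWarnings(as.integer(u))
  ord <- order(is.na(num), num, u)
  u[ord]
}

#' Construct a single-sample copy-number segment profile
#'
#' A `cna_profile` is a data frame of genomic segments (`chrom`, `start`,
#' `end`, `log2_ratio`, optional `n_probes`) carrying one sample's genome-wide
#' copy-number calls as log2 ratios relative to the sample baseline.
#' Coordinates are 0-based half-open. Segments must be non-overlapping within
#' a chromosome and are stored sorted by chromosome then start.
#'
#' @param segments data frame with columns `chrom`, `start`, `end`,
#'   `log2_ratio` and optionally `n_probes`.
#' @param sample_id sample identifier.
#' @param genome_build free-text genome build tag (e.g. `"GRCh38"`).
#' @return an object of class `cna_profile`.
#' @export
cna_profile <- function(segments, sample_id, genome_build = "synthetic") {
  stopifnot(is.data.frame(segments))
  req <- c("chrom", "start", "end", "log2_ratio")
  miss <- setdiff(req, names(segments))
  if (length(miss))
    stop("segment table for sample '", sample_id, "' is missing column(s): ",
         paste(miss, collapse = ", "))
  seg <- segments
  seg$chrom <- .normalize_chrom(seg$chrom)
  seg <- seg[!(seg$chrom %in% .DROP_CHROMS), , drop = FALSE]
  seg$start <- as.numeric(seg$start)
  seg$end <- as.numeric(seg$end)
  seg$log2_ratio <- as.numeric(seg$log2_ratio)
  if (!"n_probes" %in% names(seg)) seg$n_probes <- NA_real_
  seg <- seg[, c("chrom", "start", "end", "log2_ratio", "n_probes")]
  if (any(!is.finite(seg$log2_ratio)))
    stop("non-finite log2_ratio in sample '", sample_id, "'")
  if (any(seg$start >= seg$end))
    stop("segment with start >= end in sample '", sample_id, "'")
  lev <- .chrom_order(seg$chrom)
  seg <- seg[order(match(seg$chrom, lev), seg$start), , drop = FALSE]
  rownames(seg) <- NULL
  for (ch in lev) {
    s <- seg[seg$chrom == ch, , drop = FALSE]
    if (nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)]))
      stop("overlapping segments on chromosome ", ch,
           " in sample '", sample_id, "'")
  }
  structure(seg, class = c("cna_profile", "data.frame"),
            sample_id = sample_id, genome_build = genome_build)
}

#' @export
print.cna_profile <- function(x, ...) {
  cat("CNA segment profile: sample '", attr(x, "sample_id"), "' (",
      attr(x, "genome_build"), ")\n", sep = "")
  cat("  ", nrow(x), " segments on ", length(unique(x$chrom)),
      " chromosomes; log2 ratio range [",
      sprintf("%.3f", min(x$log2_ratio)), ", ",
      sprintf("%.3f", max(x$log2_ratio)), "]\n", sep = "")
  invisible(x)
}

#' Read a SEG-like segment table into a list of profiles
#'
#' Expects a tab-delimited file with header columns `sample`, `chrom`,
#' `start`, `end`, optionally `n_probes`, and `log2_ratio` (column names
#' `ID/chrom/loc.start/loc.end/num.mark/seg.mean` from DNAcopy-style SEG
#' files are also recognized). Rows on unrecognized chromosomes are skipped
#' with a warning; malformed rows are an error naming the line.
#'
#' @param path file path.
#' @param dialect coordinate convention of the input: `"seg-1based"`
#'   (1-based inclusive; the common SEG dialect; default) or `"internal"`
#'   (0-based half-open, as written by [write_segments()]).
#' @param genome_build genome build tag attached to each profile.
#' @return named list of [cna_profile] objects (class `cna_profile_list`),
#'   in file order of first appearance.
#' @export
read_segments <- function(path, dialect = c("seg-1based", "internal"),
                          genome_build = "unknown") {
  dialect <- match.arg(dialect)
  raw <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  cn <- tolower(names(raw))
  pick <- function(cands) {
    i <- match(cands, cn)
    i <- i[!is.na(i)]
    if (!length(i)) NA_integer_ else i[1L]
  }
  idx <- c(sample = pick(c("sample", "id", "sample_id")),
           chrom = pick(c("chrom", "chromosome", "chr")),
           start = pick(c("start", "loc.start")),
           end = pick(c("end", "loc.end")),
           log2_ratio = pick(c("log2_ratio", "seg.mean", "seg_mean")),
           n_probes = pick(c("n_probes", "num.mark", "num_probes")))
  if (any(is.na(idx[c("sample", "chrom", "start", "end", "log2_ratio")])))
    stop("SEG header must provide sample, chrom, start, end and log2_ratio ",
         "(seg.mean) columns; got: ", paste(names(raw), collapse = ", "))
  df <- data.frame(sample = as.character(raw[[idx["sample"]]]),
                   chrom = .normalize_chrom(raw[[idx["chrom"]]]),
                   start = suppressWarnings(as.numeric(raw[[idx["start"]]])),
                   end = suppressWarnings(as.numeric(raw[[idx["end"]]])),
                   log2_ratio = suppressWarnings(
                     as.numeric(raw[[idx["log2_ratio"]]])),
                   stringsAsFactors = FALSE)
  df$n_probes <- if (!is.na(idx["n_probes"]))
    suppressWarnings(as.numeric(raw[[idx["n_probes"]]])) else NA_real_
  bad <- which(!is.finite(df$start) | !is.finite(df$end) |
                 !is.finite(df$log2_ratio) | df$sample == "")
  if (length(bad))
    stop("malformed SEG row at line ", bad[1L] + 1L, " of ", path)
  skip <- df$chrom %in% .DROP_CHROMS | !grepl("^([0-9]+|X)$", df$chrom)
  if (any(skip)) {
    warning(sum(skip), " row(s) on unrecognized or excluded chromosome(s) ",
            "skipped (", paste(unique(df$chrom[skip]), collapse = ", "), ")")
    df <- df[!skip, , drop = FALSE]
  }
  if (dialect == "seg-1based") df$start <- df$start - 1
  samples <- unique(df$sample)
  out <- lapply(samples, function(s) {
    cna_profile(df[df$sample == s, -1L, drop = FALSE], sample_id = s,
                genome_build = genome_build)
  })
  names(out) <- samples
  structure(out, class = "cna_profile_list")
}

#' Write profiles to a SEG-like table
#'
#' Inverse of [read_segments()]: `read_segments(write_segments(x))`
#' round-trips exactly for the canonical dialect.
#'
#' @param profiles a `cna_profile_list` or list of [cna_profile] objects.
#' @param path output path.
#' @param dialect coordinate convention to emit (see [read_segments()]).
#' @export
write_segments <- function(profiles, path,
                           dialect = c("seg-1based", "internal")) {
  dialect <- match.arg(dialect)
  rows <- lapply(profiles, function(p) {
    d <- as.data.frame(p)
    d$sample <- attr(p, "sample_id")
    d[, c("sample", "chrom", "start", "end", "n_probes", "log2_ratio")]
  })
  df <- do.call(rbind, rows)
  if (dialect == "seg-1based") df$start <- df$start + 1
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Required columns: `sample_id`, `model_id`, `patient_id`, `tumor_type`,
#' `center`, `sample_class` (PT/PDX/NORMAL), `passage`, `lineage_id`,
#' `platform` (SNP/WES/WGS/RNASEQ/EXPARR). PDX samples lacking a passage are
#' retained but flagged `excluded_from_pairing` (they are omitted from pair
#' enumeration downstream); a passage on a PT row is ignored with a warning.
#'
#' @param path TSV path, or a data frame already holding the columns.
#' @return data frame of class `cna_metadata` with a logical
#'   `excluded_from_pairing` column.
#' @export
read_metadata <- function(path) {
  df <- if (is.data.frame(path)) path else
    read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  req <- c("sample_id", "model_id", "patient_id", "tumor_type", "center",
           "sample_class", "platform")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (!"passage" %in% names(df)) df$passage <- NA
  if (!"lineage_id" %in% names(df)) df$lineage_id <- NA_character_
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  df$sample_class <- toupper(as.character(df$sample_class))
  bad <- setdiff(unique(df$sample_class), c("PT", "PDX", "NORMAL"))
  if (length(bad)) stop("unknown sample_class: ", paste(bad, collapse = ", "))
  df$platform <- toupper(as.character(df$platform))
  bad <- setdiff(unique(df$platform), c("SNP", "WES", "WGS", "RNASEQ", "EXPARR"))
  if (length(bad)) stop("unknown platform: ", paste(bad, collapse = ", "))
  df$passage <- suppressWarnings(as.integer(df$passage))
  if (any(!is.na(df$passage) & df$passage < 0)) stop("negative passage number")
  pt_with_passage <- df$sample_class == "PT" & !is.na(df$passage)
  if (any(pt_with_passage)) {
    warning(sum(pt_with_passage), " PT sample(s) carried a passage number; ",
            "ignored")
    df$passage[pt_with_passage] <- NA_integer_
  }
  df$lineage_id <- as.character(df$lineage_id)
  df$excluded_from_pairing <- df$sample_class == "PDX" & is.na(df$passage)
  class(df) <- c("cna_metadata", "data.frame")
  df
}

#' Write sample metadata
#' @param metadata a `cna_metadata` data frame.
#' @param path output TSV path.
#' @export
write_metadata <- function(metadata, path) {
  cols <- c("sample_id", "model_id", "patient_id", "tumor_type", "center",
            "sample_class", "passage", "lineage_id", "platform")
  write.table(as.data.frame(metadata)[, cols], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models from BED6 or a minimal GTF subset
#'
#' BED6: chrom, start (0-based), end, name (`gene_id|symbol` or plain id),
#' score, strand. GTF: only records with feature type `gene` are used;
#' `gene_id`, and when present `gene_name` and `gene_biotype`, are parsed
#' from the attributes column.
#'
#' @param path file path.
#' @param format `"bed"` or `"gtf"`; guessed from the extension by default.
#' @return data frame with columns `gene_id`, `symbol`, `chrom`, `start`,
#'   `end`, `biotype` (0-based half-open coordinates).
#' @export
read_gene_models <- function(path, format = c("auto", "bed", "gtf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gtf(\\.gz)?$", path)) "gtf" else "bed"
  if (format == "bed") {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 4L) stop("BED gene file needs at least 4 columns")
    name <- as.character(df[[4L]])
    parts <- strsplit(name, "|", fixed = TRUE)
    gene_id <- vapply(parts, `[`, "", 1L)
    symbol <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else p[1L], "")
    out <- data.frame(gene_id = gene_id, symbol = symbol,
                      chrom = .normalize_chrom(df[[1L]]),
                      start = as.numeric(df[[2L]]), end = as.numeric(df[[3L]]),
                      biotype = if (ncol(df) >= 7L) as.character(df[[7L]])
                                else "protein_coding",
                      stringsAsFactors = FALSE)
  } else {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "#")]
    f <- strsplit(ln, "\t", fixed = TRUE)
    keep <- vapply(f, function(x) length(x) >= 9L && x[3L] == "gene", TRUE)
    f <- f[keep]
    if (!length(f)) stop("no gene records in GTF ", path)
    attr_get <- function(a, key) {
      m <- regmatches(a, regexpr(paste0(key, ' "[^"]+"'), a))
      if (!length(m)) NA_character_ else sub(paste0(key, ' "([^"]+)"'), "\\1", m)
    }
    out <- do.call(rbind, lapply(f, function(x) {
      data.frame(gene_id = attr_get(x[9L], "gene_id"),
                 symbol = {
                   s <- attr_get(x[9L], "gene_name")
                   if (is.na(s)) attr_get(x[9L], "gene_id") else s
                 },
                 chrom = .normalize_chrom(x[1L]),
                 start = as.numeric(x[4L]) - 1, end = as.numeric(x[5L]),
                 biotype = {
                   b <- attr_get(x[9L], "gene_biotype")
                   if (is.na(b)) "protein_coding" else b
                 },
                 stringsAsFactors = FALSE)
    }))
  }
  out <- out[!(out$chrom %in% .DROP_CHROMS), , drop = FALSE]
  if (any(out$start >= out$end)) stop("gene with start >= end in ", path)
  if (anyDuplicated(out$gene_id))
    stop("duplicate gene_id in ", path)
  rownames(out) <- NULL
  out
}

#' Write gene models as BED6
#' @param genes gene model data frame (see [read_gene_models()]).
#' @param path output path.
#' @export
write_gene_models <- function(genes, path) {
  bed <- data.frame(genes$chrom, genes$start, genes$end,
                    paste(genes$gene_id, genes$symbol, sep = "|"),
                    0L, "+", genes$biotype)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>member...`.
#' Optionally attaches a category per set from a two-column companion TSV
#' (`set`, `category`), and reports (but keeps) identifiers that do not
#' resolve against a gene-model table.
#'
#' @param path GMT path.
#' @param categories optional path to a two-column TSV or a named character
#'   vector mapping set name to category.
#' @param genes optional gene-model data frame used to report unresolved
#'   member identifiers.
#' @return list of class `gene_set_collection` with elements `sets` (named
#'   list of character vectors), `category` (named character vector) and
#'   `unresolved` (named list, possibly empty).
#' @export
read_gene_sets <- function(path, categories = NULL, genes = NULL) {
  ln <- readLines(path)
  ln <- ln[nzchar(ln)]
  f <- strsplit(ln, "\t", fixed = TRUE)
  nm <- vapply(f, `[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene set name: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(f, function(x) unique(x[-(1:2)][nzchar(x[-(1:2)])]))
  names(sets) <- nm
  if (any(lengths(sets) == 0L))
    stop("empty gene set: ",
         paste(nm[lengths(sets) == 0L], collapse = ", "))
  cat_vec <- setNames(rep(NA_character_, length(nm)), nm)
  if (!is.null(categories)) {
    if (is.character(categories) && length(categories) == 1L &&
        file.exists(categories)) {
      cdf <- read.delim(categories, header = TRUE, stringsAsFactors = FALSE)
      categories <- setNames(as.character(cdf[[2L]]), cdf[[1L]])
    }
    hit <- intersect(names(categories), nm)
    cat_vec[hit] <- categories[hit]
  }
  unresolved <- list()
  if (!is.null(genes)) {
    known <- unique(c(genes$gene_id, genes$symbol))
    unresolved <- lapply(sets, function(s) setdiff(s, known))
    unresolved <- unresolved[lengths(unresolved) > 0L]
    if (length(unresolved))
      message(sum(lengths(unresolved)), " gene-set member id(s) in ",
              length(unresolved), " set(s) did not resolve against the ",
              "gene models (kept; see $unresolved)")
  }
  structure(list(sets = sets, category = cat_vec, unresolved = unresolved),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("Gene set collection:", length(x$sets), "sets; sizes",
      min(lengths(x$sets)), "-", max(lengths(x$sets)), "\n")
  invisible(x)
}

#' Read a genes-by-samples expression matrix
#'
#' Plain TSV with a feature-id first column and one column per sample.
#' Feature positions and the feature-to-gene map come from `features`;
#' sample tumor/normal labels from `sample_class`.
#'
#' @param path TSV path (first column: feature id) or a numeric matrix with
#'   feature rownames.
#' @param features data frame with columns `feature_id`, `gene_id`, `chrom`,
#'   `start`, `end` (a gene may carry several features: transcripts or
#'   probesets).
#' @param sample_class named character vector (`"tumor"`/`"normal"`) per
#'   sample column.
#' @param unit `"TPM"` (linear; RNA-seq) or `"log2"` (array intensities).
#' @return list of class `expr_matrix`: `values` (features x samples),
#'   `features`, `sample_class`, `unit`.
#' @export
read_expression <- function(path, features, sample_class,
                            unit = c("TPM", "log2")) {
  unit <- match.arg(unit)
  if (is.matrix(path)) {
    m <- path
  } else {
    df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                     check.names = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- as.character(df[[1L]])
  }
  if (unit == "TPM" && any(m < 0)) stop("negative TPM values")
  stopifnot(all(c("feature_id", "gene_id", "chrom", "start", "end") %in%
                  names(features)))
  features <- features[features$feature_id %in% rownames(m), , drop = FALSE]
  if (!all(rownames(m) %in% features$feature_id))
    stop("expression features without positions: ",
         paste(head(setdiff(rownames(m), features$feature_id), 5L),
               collapse = ", "))
  sample_class <- sample_class[colnames(m)]
  if (any(is.na(sample_class)))
    stop("missing tumor/normal class for some samples")
  structure(list(values = m, features = features,
                 sample_class = sample_class, unit = unit),
            class = "expr_matrix")
}
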