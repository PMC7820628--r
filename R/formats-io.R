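# Readers and writers for the tabular/interval formats the pipeline touches.
#
# Conventions, fixed across the package:
#   * credible-set SNP positions are 1-based (the fine-mapping convention);
#   * chromatin states and CDS intervals are 0-based half-open (BED);
#   * all tables are tab-separated with a header; lines starting with '#'
#     are provenance comments and are skipped on read.

#' Column dialect for credible-set tables
#'
#' Credible-set exports from different consortia name their columns
#' differently; a dialect maps the canonical names used by this package onto
#' the file's actual headers.
#'
#' @param signal_id,locus,snp_id,chrom,pos,ppa required column names.
#' @param beta,se,is_index optional column names (`NA` to omit).
#' @return named list of class `cs_dialect`.
#' @export
cs_dialect <- function(signal_id = "signal_id", locus = "locus",
                       snp_id = "snp_id", chrom = "chrom", pos = "pos",
                       ppa = "ppa", beta = "beta", se = "se",
                       is_index = "is_index") {
  structure(
    list(signal_id = signal_id, locus = locus, snp_id = snp_id,
         chrom = chrom, pos = pos, ppa = ppa, beta = beta, se = se,
         is_index = is_index),
    class = "cs_dialect"
  )
}

read_tsv_checked <- function(path) {
  if (!file.exists(path)) {
    ts_error(sprintf("file not found: %s", path), "toascore_io_error")
  }
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read 99% genetic credible sets
#'
#' Reads a TSV of fine-mapped credible-set SNPs (one row per SNP) and returns
#' a validated table with one group of rows per conditionally independent
#' signal, variants sorted by descending PPA, with the running cumulative PPA
#' recorded per signal.
#'
#' @param path TSV file path.
#' @param dialect a [cs_dialect()] mapping canonical column names onto the
#'   file's headers.
#' @param chrom_style chromosome naming style to normalize to.
#' @return a `data.frame` of class `credible_sets` with columns `signal_id`,
#'   `locus`, `snp_id`, `chrom`, `pos`, `ppa`, `cum_ppa`, and, when present
#'   in the file, `beta`, `se`, `is_index`.
#' @export
read_credible_sets <- function(path, dialect = cs_dialect(),
                               chrom_style = c("plain", "chr")) {
  chrom_style <- match.arg(chrom_style)
  raw <- read_tsv_checked(path)
  required <- c("signal_id", "locus", "snp_id", "chrom", "pos", "ppa")
  for (col in required) {
    file_col <- dialect[[col]]
    if (is.na(file_col) || !file_col %in% names(raw)) {
      ts_error(sprintf("credible-set file %s is missing required column '%s' (canonical '%s')",
                       path, file_col, col),
               "toascore_format_error")
    }
  }
  df <- data.frame(
    signal_id = as.character(raw[[dialect$signal_id]]),
    locus = as.character(raw[[dialect$locus]]),
    snp_id = as.character(raw[[dialect$snp_id]]),
    chrom = normalize_chrom(raw[[dialect$chrom]], chrom_style),
    pos = as.integer(raw[[dialect$pos]]),
    ppa = as.numeric(raw[[dialect$ppa]]),
    stringsAsFactors = FALSE
  )
  for (opt in c("beta", "se", "is_index")) {
    fc <- dialect[[opt]]
    if (!is.na(fc) && fc %in% names(raw)) df[[opt]] <- raw[[fc]]
  }
  if (nrow(df) == 0) {
    df$cum_ppa <- numeric(0)
    class(df) <- c("credible_sets", "data.frame")
    return(df)
  }
  validate_credible_sets(df)
}

#' Validate and finalize a credible-set table
#'
#' Applies the type invariants (PPA in \[0, 1\], positive positions, per-signal
#' PPA sum in (0, 1 + 1e-6\], no duplicate SNP within a signal), sorts
#' variants by descending PPA within signal and records cumulative PPA.
#'
#' @param df data.frame with canonical credible-set columns.
#' @return validated `credible_sets` data.frame.
#' @export
validate_credible_sets <- function(df) {
  bad_ppa <- which(is.na(df$ppa) | df$ppa < 0 | df$ppa > 1)
  if (length(bad_ppa)) {
    ts_error(sprintf("PPA outside [0, 1] at row(s): %s",
                     paste(utils::head(bad_ppa, 10), collapse = ", ")),
             "toascore_validation_error")
  }
  bad_pos <- which(is.na(df$pos) | df$pos < 1)
  if (length(bad_pos)) {
    ts_error(sprintf("position < 1 at row(s): %s",
                     paste(utils::head(bad_pos, 10), collapse = ", ")),
             "toascore_validation_error")
  }
  if (any(!nzchar(df$snp_id))) {
    ts_error("empty snp_id encountered", "toascore_validation_error")
  }
  key <- paste(df$signal_id, df$snp_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][[1]]
    ts_error(sprintf("duplicated (signal_id, snp_id) pair: %s",
                     sub("\r", " / ", dup)),
             "toascore_validation_error")
  }
  sums <- tapply(df$ppa, df$signal_id, sum)
  over <- names(sums)[sums > 1 + 1e-6]
  if (length(over)) {
    ts_error(sprintf("PPA sums exceed 1 for signal(s): %s (sum %.4f)",
                     paste(over, collapse = ", "), max(sums)),
             "toascore_validation_error")
  }
  zero <- names(sums)[sums <= 0]
  if (length(zero)) {
    ts_error(sprintf("PPA sums are zero for signal(s): %s",
                     paste(zero, collapse = ", ")),
             "toascore_validation_error")
  }
  ord <- order(df$signal_id, -df$ppa, df$snp_id)
  df <- df[ord, , drop = FALSE]
  df$cum_ppa <- stats::ave(df$ppa, df$signal_id, FUN = cumsum)
  rownames(df) <- NULL
  class(df) <- c("credible_sets", "data.frame")
  df
}

#' Read per-tissue chromatin-state segmentations
#'
#' Reads one BED4 file per tissue (`chrom`, `start`, `end`, `state`; 0-based
#' half-open) and validates that each tissue's intervals form a segmentation
#' (no intra-tissue overlap on a chromosome).
#'
#' @param paths named character vector, `tissue = path`. Files may have a
#'   header line (`chrom` in the first field) or none.
#' @param chrom_style chromosome naming style to normalize to.
#' @return data.frame of class `state_maps` with columns `chrom`, `start`,
#'   `end`, `state`, `tissue`.
#' @export
read_state_maps <- function(paths, chrom_style = c("plain", "chr")) {
  chrom_style <- match.arg(chrom_style)
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    ts_error("'paths' must be a named vector: tissue = path", "toascore_format_error")
  }
  per_tissue <- lapply(names(paths), function(tissue) {
    path <- paths[[tissue]]
    if (!file.exists(path)) {
      ts_error(sprintf("state map for tissue '%s' not found: %s", tissue, path),
               "toascore_io_error")
    }
    first <- readLines(path, n = 1L)
    has_header <- grepl("^chrom\t", first) || grepl("^#", first)
    bed <- utils::read.delim(path, header = has_header && !grepl("^#", first),
                             sep = "\t", comment.char = "#",
                             stringsAsFactors = FALSE)
    if (ncol(bed) < 4) {
      ts_error(sprintf("state map %s: expected >= 4 columns (BED4)", path),
               "toascore_format_error")
    }
    data.frame(
      chrom = normalize_chrom(bed[[1]], chrom_style),
      start = as.integer(bed[[2]]),
      end = as.integer(bed[[3]]),
      state = as.character(bed[[4]]),
      tissue = tissue,
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, per_tissue)
  validate_state_maps(df)
}

#' Validate a chromatin-state interval table
#'
#' @param df data.frame with columns `chrom`, `start`, `end`, `state`,
#'   `tissue` (0-based half-open coordinates).
#' @return validated `state_maps` data.frame.
#' @export
validate_state_maps <- function(df) {
  bad <- which(df$start >= df$end | df$start < 0)
  if (length(bad)) {
    ts_error(sprintf("invalid interval (start >= end or start < 0) at row(s): %s",
                     paste(utils::head(bad, 10), collapse = ", ")),
             "toascore_validation_error")
  }
  for (tissue in unique(df$tissue)) {
    sub <- df[df$tissue == tissue, , drop = FALSE]
    gr <- granges_from_bed(sub$chrom, sub$start, sub$end)
    hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
    if (length(hits)) {
      i <- S4Vectors::queryHits(hits)[[1]]
      j <- S4Vectors::subjectHits(hits)[[1]]
      ts_error(sprintf(
        "tissue '%s' is not a segmentation: intervals %s:[%d,%d) and %s:[%d,%d) overlap",
        tissue, sub$chrom[i], sub$start[i], sub$end[i],
        sub$chrom[j], sub$start[j], sub$end[j]),
        "toascore_validation_error")
    }
  }
  rownames(df) <- NULL
  class(df) <- c("state_maps", "data.frame")
  df
}

#' Read coding-sequence intervals
#'
#' BED4 with a gene identifier in column 4; 0-based half-open. Overlapping
#' records are permitted (isoforms).
#'
#' @param path file path.
#' @param chrom_style chromosome naming style to normalize to.
#' @return data.frame of class `cds_records` with columns `chrom`, `start`,
#'   `end`, `gene_id`.
#' @export
read_cds <- function(path, chrom_style = c("plain", "chr")) {
  chrom_style <- match.arg(chrom_style)
  if (!file.exists(path)) {
    ts_error(sprintf("CDS file not found: %s", path), "toascore_io_error")
  }
  first <- readLines(path, n = 1L)
  has_header <- grepl("^chrom\t", first)
  bed <- utils::read.delim(path, header = has_header, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(bed) < 4) {
    ts_error(sprintf("CDS file %s: expected >= 4 columns", path),
             "toascore_format_error")
  }
  df <- data.frame(
    chrom = normalize_chrom(bed[[1]], chrom_style),
    start = as.integer(bed[[2]]),
    end = as.integer(bed[[3]]),
    gene_id = as.character(bed[[4]]),
    stringsAsFactors = FALSE
  )
  if (any(df$start >= df$end)) {
    ts_error("CDS record with start >= end", "toascore_validation_error")
  }
  if (any(!nzchar(df$gene_id))) {
    ts_error("CDS record with empty gene_id", "toascore_validation_error")
  }
  class(df) <- c("cds_records", "data.frame")
  df
}

#' Read an expression count matrix with sample and gene metadata
#'
#' @param counts_path TSV: first column `gene_id`, remaining columns one per
#'   sample (nonnegative counts, or TPMs if `already_tpm` downstream).
#' @param sample_map_path two-column TSV `sample_id`, `tissue`.
#' @param gene_length_path two-column TSV `gene_id`, `length` (bp); optional
#'   (`NULL`) when the matrix is already TPM-normalized.
#' @return list of class `expression_data`: `counts` (gene x sample matrix),
#'   `gene_length` (named vector or NULL), `sample_tissue` (named character).
#' @export
read_expression <- function(counts_path, sample_map_path, gene_length_path = NULL) {
  cnt <- read_tsv_checked(counts_path)
  genes <- as.character(cnt[[1]])
  mat <- as.matrix(cnt[, -1, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- genes
  if (any(mat < 0, na.rm = TRUE)) {
    ts_error("expression matrix contains negative values", "toascore_validation_error")
  }
  smap <- read_tsv_checked(sample_map_path)
  sample_tissue <- stats::setNames(as.character(smap[[2]]), as.character(smap[[1]]))
  missing <- setdiff(colnames(mat), names(sample_tissue))
  if (length(missing)) {
    ts_error(sprintf("samples missing from tissue map: %s",
                     paste(utils::head(missing, 5), collapse = ", ")),
             "toascore_validation_error")
  }
  gene_length <- NULL
  if (!is.null(gene_length_path)) {
    gl <- read_tsv_checked(gene_length_path)
    gene_length <- stats::setNames(as.numeric(gl[[2]]), as.character(gl[[1]]))
    if (any(gene_length <= 0, na.rm = TRUE)) {
      ts_error("gene lengths must be positive", "toascore_validation_error")
    }
  }
  structure(
    list(counts = mat, gene_length = gene_length,
         sample_tissue = sample_tissue[colnames(mat)]),
    class = "expression_data"
  )
}

#' Write a TOA profile table
#'
#' Emits a TSV with columns `signal_id`, one per tissue, `unclassified`, and
#' the bookkeeping columns (`cumulative_ppa`, `max_ppa`, `n_snps`,
#' `coding_score`, `ssd`) when present. Values round-trip through
#' [read_toa_table()] to 1e-9.
#'
#' @param profiles a `toa_profiles` data.frame (see [compute_toa()]).
#' @param path output path.
#' @param provenance optional character scalar written as a leading `#`
#'   comment line.
#' @export
write_toa_table <- function(profiles, path, provenance = NULL) {
  if (!is.data.frame(profiles) || nrow(profiles) == 0) {
    ts_error("'profiles' must be a non-empty data.frame", "toascore_validation_error")
  }
  if (anyDuplicated(profiles$signal_id)) {
    ts_error("duplicate signal_id in profiles", "toascore_validation_error")
  }
  out <- profiles
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], tsv_num)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TOA profile table written by [write_toa_table()]
#'
#' @param path file path.
#' @param tissues optional character vector naming the tissue columns; by
#'   default every column that is not a known bookkeeping column is treated
#'   as a tissue.
#' @return `toa_profiles` data.frame.
#' @export
read_toa_table <- function(path, tissues = NULL) {
  df <- read_tsv_checked(path)
  if (anyDuplicated(df$signal_id)) {
    ts_error("duplicate signal_id in TOA table", "toascore_validation_error")
  }
  reserved <- c("signal_id", "unclassified", "cumulative_ppa", "max_ppa",
                "n_snps", "coding_score", "ssd")
  if (is.null(tissues)) tissues <- setdiff(names(df), reserved)
  class(df) <- c("toa_profiles", "data.frame")
  attr(df, "tissues") <- tissues
  df
}
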