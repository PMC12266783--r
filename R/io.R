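# Recognised probe feature classes (array annotation vocabulary).
FEATURE_CLASSES <- c("promoter", "exon", "intron", "five_prime_utr",
                     "three_prime_utr", "intergenic_downstream", "intergenic")

#' Feature classes recognised by the probe manifest
#'
#' @return Character vector of valid `feature_class` values.
#' @export
feature_classes <- function() FEATURE_CLASSES

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a beta-value matrix
#'
#' Reads a probes x samples table of methylation fractions. The first column
#' must hold probe ids and the header row sample ids. Values must lie in
#' \[0, 1\]; empty cells / NA are recorded as missing.
#'
#' @param path TSV or CSV file.
#' @return Numeric matrix (probes x samples) with probe ids as rownames and
#'   sample ids as colnames; missing values are `NA`.
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  probe_ids <- as.character(df[[1L]])
  if (anyDuplicated(probe_ids)) {
    stop("duplicate probe_id in beta matrix: ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- probe_ids
  validate_beta_matrix(m)
  m
}

#' Validate a beta-value matrix
#'
#' @param beta numeric matrix with probe rownames and sample colnames.
#' @return `beta`, invisibly, if valid; otherwise an error naming the
#'   offending probe/sample.
#' @export
validate_beta_matrix <- function(beta) {
  if (!is.matrix(beta) || !is.numeric(beta))
    stop("beta matrix must be a numeric matrix")
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop("beta matrix needs probe rownames and sample colnames")
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "beta value out of [0,1]: probe '%s', sample '%s' (value %g)",
      rownames(beta)[bad[1L, 1L]], colnames(beta)[bad[1L, 2L]],
      beta[bad[1L, , drop = FALSE]]))
  }
  invisible(beta)
}

#' Write a beta-value matrix
#'
#' @param beta validated beta matrix.
#' @param path output TSV/CSV path.
#' @export
write_beta_matrix <- function(beta, path) {
  validate_beta_matrix(beta)
  df <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / validate a sample sheet
#'
#' Columns: sample_id, animal_id, age_group (young/old), treatment
#' (vehicle/senolytic), limb (PBS/BaCl2), batch (sentrix id). Each animal may
#' contribute at most one PBS and one BaCl2 limb.
#'
#' @param path TSV/CSV file.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param sheet data.frame to validate.
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "animal_id", "age_group", "treatment", "limb", "batch")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("sample sheet missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet")
  if (!all(sheet$age_group %in% c("young", "old")))
    stop("age_group must be young/old")
  if (!all(sheet$treatment %in% c("vehicle", "senolytic")))
    stop("treatment must be vehicle/senolytic")
  if (!all(sheet$limb %in% c("PBS", "BaCl2")))
    stop("limb must be PBS/BaCl2")
  tab <- table(sheet$animal_id, sheet$limb)
  if (any(tab > 1L))
    stop("an animal has more than one sample for the same limb condition")
  sheet
}

#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  validate_sample_sheet(sheet)
  utils::write.table(sheet, path, sep = delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / validate a probe manifest
#'
#' Columns: probe_id, chrom, pos (1-based bp), gene_id (may be NA),
#' feature_class, tss_distance (signed bp, negative upstream of the assigned
#' gene's TSS; NA for intergenic probes).
#'
#' @param path TSV/CSV file.
#' @param promoter_window maximum |tss_distance| allowed for probes classed
#'   as promoter.
#' @return data.frame.
#' @export
read_manifest <- function(path, promoter_window = 1000L) {
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          stringsAsFactors = FALSE)
  validate_manifest(df, promoter_window = promoter_window)
}

#' @rdname read_manifest
#' @param manifest data.frame to validate.
#' @export
validate_manifest <- function(manifest, promoter_window = 1000L) {
  need <- c("probe_id", "chrom", "pos", "gene_id", "feature_class",
            "tss_distance")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) stop("manifest missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(manifest$probe_id))
    stop("duplicate probe_id in manifest: ",
         paste(unique(manifest$probe_id[duplicated(manifest$probe_id)]),
               collapse = ", "))
  if (any(manifest$pos < 1L)) stop("manifest positions must be >= 1 (1-based)")
  bad <- setdiff(unique(manifest$feature_class), FEATURE_CLASSES)
  if (length(bad)) stop("unknown feature_class: ", paste(bad, collapse = ", "))
  prom <- manifest$feature_class == "promoter"
  if (any(prom & (is.na(manifest$gene_id) | manifest$gene_id == "")))
    stop("promoter probes must carry a gene_id")
  if (any(prom & (is.na(manifest$tss_distance) |
                  abs(manifest$tss_distance) > promoter_window)))
    stop("promoter probes must have |tss_distance| <= ", promoter_window)
  manifest
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a differential-expression table
#'
#' Columns: gene_id, log2_fold_change, p, adj_p. External tables are
#' accepted as-is (no adj_p >= p requirement) but gene ids must be unique and
#' p-values in \[0, 1\].
#'
#' @param path TSV/CSV file.
#' @return data.frame.
#' @export
read_de_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          stringsAsFactors = FALSE)
  validate_de_table(df)
}

#' @rdname read_de_table
#' @param de data.frame to validate.
#' @export
validate_de_table <- function(de) {
  need <- c("gene_id", "log2_fold_change", "p", "adj_p")
  miss <- setdiff(need, names(de))
  if (length(miss)) stop("DE table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(de$gene_id)) stop("duplicate gene_id in DE table")
  for (cc in c("p", "adj_p")) {
    v <- de[[cc]]
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop("DE table column '", cc, "' outside [0,1]")
  }
  de
}

#' @rdname read_de_table
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene models from BED or GTF
#'
#' BED input is 0-based half-open and converted at the boundary; GTF is
#' 1-based closed. All returned coordinates are 1-based closed. The TSS is
#' the start of the span on the + strand and the end on the - strand; a
#' missing strand is an error because the TSS is then undefined.
#'
#' @param path BED or GTF/GFF file.
#' @param format "auto" (by extension), "bed" or "gtf".
#' @return data.frame with gene_id, symbol, chrom, strand, start, end, tss.
#' @export
read_gene_models <- function(path, format = c("auto", "bed", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed"
              else if (grepl("\\.(gtf|gff3?)$", path, ignore.case = TRUE)) "gtf"
              else stop("cannot infer gene-model format from extension: ", path)
  }
  gr <- rtracklayer::import(path, format = toupper(format))
  if (format == "gtf") {
    type <- as.character(gr$type)
    if (any(type == "gene")) gr <- gr[type == "gene"]
    gene_id <- as.character(gr$gene_id)
    symbol <- if (!is.null(gr$gene_name)) as.character(gr$gene_name) else gene_id
  } else {
    if (is.null(gr$name)) stop("BED gene models need a name (column 4)")
    gene_id <- as.character(gr$name)
    symbol <- gene_id
  }
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*"))
    stop("gene model without strand: TSS undefined for ",
         paste(gene_id[strand == "*"], collapse = ", "))
  if (anyDuplicated(gene_id)) stop("duplicate gene_id in gene models")
  start <- BiocGenerics::start(gr)  # rtracklayer already yields 1-based
  end <- BiocGenerics::end(gr)
  data.frame(
    gene_id = gene_id, symbol = symbol,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand, start = start, end = end,
    tss = ifelse(strand == "+", start, end),
    stringsAsFactors = FALSE)
}

#' Write gene models as BED
#'
#' Converts the internal 1-based closed span to BED 0-based half-open.
#'
#' @param genes gene-model data.frame (see [read_gene_models()]).
#' @param path output BED path.
#' @export
write_gene_models_bed <- function(genes, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   genes$chrom, genes$start - 1L, genes$end, genes$gene_id,
                   0L, genes$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Write methylation peaks as BED
#'
#' Single-bp intervals, 0-based half-open; the name column carries the probe
#' id and the score column the direction sign (+1 hypermethylated, -1
#' hypomethylated), documented in a header comment.
#'
#' @param peaks data.frame with chrom, pos (1-based), probe_id, direction.
#' @param path output BED path.
#' @export
write_peaks_bed <- function(peaks, path) {
  header <- "# methylation peaks; score column: +1 = hyper, -1 = hypomethylated"
  if (nrow(peaks) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  score <- ifelse(peaks$direction == "hyper", 1L, -1L)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   peaks$chrom, peaks$pos - 1L, peaks$pos, peaks$probe_id,
                   score, ".")
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read methylation peaks from BED
#'
#' Inverse of [write_peaks_bed()]; restores 1-based positions and the
#' direction from the score sign.
#'
#' @param path BED file written by [write_peaks_bed()].
#' @return data.frame with chrom, pos, probe_id, direction.
#' @export
read_peaks_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      probe_id = character(), direction = character(),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    chrom = vapply(f, `[[`, "", 1L),
    pos = as.integer(vapply(f, `[[`, "", 3L)),  # end == 1-based position
    probe_id = vapply(f, `[[`, "", 4L),
    direction = ifelse(as.integer(vapply(f, `[[`, "", 5L)) > 0L,
                       "hyper", "hypo"),
    stringsAsFactors = FALSE)
}
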