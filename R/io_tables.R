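## TSV result tables and gene annotations (BED / GFF3).

#' Write a per-SNP scan result table
#'
#' Fixed column order `chrom, pos, snp_id, p0, stat, pvalue, qvalue`;
#' missing values written as `NA`. Calibration metadata (test name, group,
#' degrees of freedom or robust mean/SD) is written to a sidecar
#' `<path>.meta` file as `key<TAB>value` lines.
#'
#' @param result a `scan_result` data frame (see [flk_scan()]).
#' @param path output TSV path.
#' @return Invisibly, `result`.
#' @export
write_scan_results <- function(result, path) {
  cols <- c("chrom", "pos", "snp_id", "p0", "stat", "pvalue", "qvalue")
  tab <- as.data.frame(result)[, intersect(cols, names(result)), drop = FALSE]
  write.table(tab, path, quote = FALSE, sep = "\t", row.names = FALSE,
              col.names = TRUE, na = "NA")
  cal <- attr(result, "calibration")
  if (!is.null(cal)) {
    meta <- data.frame(key = names(cal),
                       value = vapply(cal, function(v)
                         paste(format(v, digits = 17), collapse = ","), ""))
    write.table(meta, paste0(path, ".meta"), quote = FALSE, sep = "\t",
                row.names = FALSE, col.names = FALSE)
  }
  invisible(result)
}

#' Read a scan result table written by [write_scan_results()]
#' @param path TSV path.
#' @return A data frame; calibration metadata (if a `.meta` sidecar exists)
#'   is attached as the `"calibration"` attribute (character values).
#' @export
read_scan_results <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"), na.strings = "NA")
  meta_path <- paste0(path, ".meta")
  if (file.exists(meta_path)) {
    meta <- read.table(meta_path, header = FALSE, sep = "\t",
                       stringsAsFactors = FALSE)
    attr(tab, "calibration") <- setNames(as.list(meta[[2]]), meta[[1]])
  }
  class(tab) <- c("scan_result", class(tab))
  tab
}

#' Read a gene annotation in BED or GFF3 format
#'
#' Coordinates are unified to 1-based inclusive (BED input is 0-based
#' half-open and converted at the boundary).
#'
#' @param path file path.
#' @param format `"BED"` or `"GFF3"`.
#' @param biotype for GFF3, keep only features whose attributes contain
#'   `biotype=<value>`; `NULL` keeps all `gene` features. Ignored for BED.
#' @return A data frame with columns `chrom`, `start`, `end`, `gene`,
#'   `biotype` (1-based inclusive).
#' @export
read_gene_annotation <- function(path, format = c("BED", "GFF3"),
                                 biotype = NULL) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (format == "BED") {
    parts <- strsplit(lines, "[ \t]+")
    nf <- lengths(parts)
    if (any(nf < 3L)) stop("malformed BED line ", which(nf < 3L)[1])
    if (any(nf == 9L)) stop("line ", which(nf == 9L)[1],
                            " looks like GFF, not BED")
    chrom <- vapply(parts, `[[`, "", 1L)
    start0 <- as.numeric(vapply(parts, `[[`, "", 2L))
    end0 <- as.numeric(vapply(parts, `[[`, "", 3L))
    gene <- vapply(parts, function(p) if (length(p) >= 4L) p[[4L]] else NA_character_, "")
    start <- start0 + 1   # 0-based half-open -> 1-based inclusive
    end <- end0
    bt <- rep(NA_character_, length(chrom))
  } else {
    parts <- strsplit(lines, "\t")
    nf <- lengths(parts)
    if (any(nf != 9L)) stop("malformed GFF3 line ", which(nf != 9L)[1])
    type <- vapply(parts, `[[`, "", 3L)
    keep <- type == "gene"
    parts <- parts[keep]
    chrom <- vapply(parts, `[[`, "", 1L)
    start <- as.numeric(vapply(parts, `[[`, "", 4L))
    end <- as.numeric(vapply(parts, `[[`, "", 5L))
    attrs <- vapply(parts, `[[`, "", 9L)
    gene <- sub(".*(?:Name|ID)=([^;]+).*", "\\1", attrs)
    bt <- ifelse(grepl("biotype=", attrs),
                 sub(".*biotype=([^;]+).*", "\\1", attrs), NA_character_)
    if (!is.null(biotype)) {
      keep2 <- !is.na(bt) & bt == biotype
      chrom <- chrom[keep2]; start <- start[keep2]; end <- end[keep2]
      gene <- gene[keep2]; bt <- bt[keep2]
    }
  }
  bad <- start > end
  if (any(bad)) stop("start >= end after conversion at line ", which(bad)[1])
  data.frame(chrom = chrom, start = start, end = end, gene = gene,
             biotype = bt, stringsAsFactors = FALSE)
}

#' Write a gene table as BED (0-based half-open)
#' @param genes gene table from [read_gene_annotation()].
#' @param path output path.
#' @return Invisibly, `genes`.
#' @export
write_gene_annotation_bed <- function(genes, path) {
  tab <- data.frame(genes$chrom, genes$start - 1, genes$end, genes$gene)
  write.table(tab, path, quote = FALSE, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(genes)
}

#' Write a region table
#'
#' Columns mirror the within-group signature tables: group, test, chromosome,
#' begin/end (bp), peak position, minimum p- and q-value, most differentiated
#' populations, SNP count.
#'
#' @param regions region data frame from [call_flk_regions()] or
#'   [call_hapflk_regions()].
#' @param path output TSV path.
#' @param style `"bp"` writes positions as base pairs; `"mbp"` writes
#'   begin/end in megabases with 2 decimals (the usual summary-table style).
#' @return Invisibly, `regions`.
#' @export
write_regions <- function(regions, path, style = c("bp", "mbp")) {
  style <- match.arg(style)
  tab <- as.data.frame(regions)
  if (style == "mbp" && nrow(tab)) {
    for (col in c("begin", "end", "peak", "cand_begin", "cand_end"))
      if (col %in% names(tab))
        tab[[col]] <- sprintf("%.2f", tab[[col]] / 1e6)
  }
  write.table(tab, path, quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(regions)
}
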