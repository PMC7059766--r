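#' Hotspot panels
#'
#' A hotspot panel is an ordered table of single-nucleotide cancer hotspots
#' (e.g. EGFR-T790M) against which cfDNA fragments are typed. Panels are plain
#' `data.frame`s with class `hotspot_panel` and columns `name`, `gene`,
#' `chrom`, `pos` (1-based reference position of the variant base), `ref`
#' and `alt` (single bases, forward reference strand).
#'
#' Only single-base substitutions are supported: the variant classes this
#' package profiles are SNV hotspots, and allele typing is a single-base
#' lookup. Indels, MNVs and fusions are rejected at panel construction.
#'
#' @param name character vector of unique hotspot names.
#' @param gene character vector of gene symbols.
#' @param chrom character vector of reference sequence names.
#' @param pos integer vector of 1-based variant positions (>= 1).
#' @param ref,alt single reference/alternate bases (A/C/G/T), `ref != alt`.
#' @return A `hotspot_panel` data.frame.
#' @examples
#' hotspot_panel(name = "EGFR-T790M", gene = "EGFR", chrom = "chr7",
#'               pos = 55249071, ref = "C", alt = "T")
#' @export
hotspot_panel <- function(name, gene, chrom, pos, ref, alt) {
  df <- data.frame(
    name = as.character(name), gene = as.character(gene),
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = toupper(as.character(ref)), alt = toupper(as.character(alt)),
    stringsAsFactors = FALSE
  )
  validate_panel(df)
}

#' @rdname hotspot_panel
#' @param x a data.frame with panel columns, checked and upgraded.
#' @export
validate_panel <- function(x) {
  required <- c("name", "gene", "chrom", "pos", "ref", "alt")
  if (!all(required %in% names(x)))
    stop("panel must have columns: ", paste(required, collapse = ", "))
  if (nrow(x) == 0L) stop("empty panel")
  if (anyNA(x$pos) || any(x$pos < 1L))
    stop("hotspot positions must be integers >= 1")
  bases <- c("A", "C", "G", "T")
  bad <- !(x$ref %in% bases) | !(x$alt %in% bases)
  if (any(bad))
    stop("ref/alt must be single bases A/C/G/T (SNVs only): ",
         paste(x$name[bad], collapse = ", "))
  same <- x$ref == x$alt
  if (any(same))
    stop("ref and alt base identical for: ", paste(x$name[same], collapse = ", "))
  if (anyDuplicated(x$name))
    stop("duplicate hotspot names: ",
         paste(unique(x$name[duplicated(x$name)]), collapse = ", "))
  key <- paste(x$chrom, x$pos, x$alt, sep = ":")
  if (anyDuplicated(key))
    stop("duplicate (chrom, pos, alt) hotspots: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  class(x) <- c("hotspot_panel", "data.frame")
  x
}

#' Read a hotspot panel from TSV
#'
#' The panel file has six tab-separated columns (name, gene, chrom, pos, ref,
#' alt). A header line is optional and is detected by a non-numeric `pos`
#' field; lines starting with `#` and blank lines are ignored. Rows are kept
#' in file order.
#'
#' @param path path to the TSV file.
#' @return A `hotspot_panel`.
#' @seealso [write_panel()] for the inverse; `read_panel(write_panel(p))`
#'   restores `p` exactly.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) stop("empty panel")
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 6L))
    stop("malformed panel line ", idx[which(nf != 6L)[1L]],
         ": expected 6 tab-separated fields, got ", nf[nf != 6L][1L])
  mat <- do.call(rbind, fields)
  # optional header: detected by a non-numeric pos field on the first row
  if (is.na(suppressWarnings(as.numeric(mat[1L, 4L])))) {
    mat <- mat[-1L, , drop = FALSE]
    idx <- idx[-1L]
    if (nrow(mat) == 0L) stop("empty panel")
  }
  pos_num <- suppressWarnings(as.numeric(mat[, 4L]))
  if (anyNA(pos_num))
    stop("malformed panel line ", idx[which(is.na(pos_num))[1L]],
         ": position is not numeric")
  hotspot_panel(name = mat[, 1L], gene = mat[, 2L], chrom = mat[, 3L],
                pos = pos_num, ref = mat[, 5L], alt = mat[, 6L])
}

#' Write a hotspot panel to TSV
#'
#' Writes the six panel columns tab-separated, one hotspot per line, in panel
#' order, with a commented header line. Round-trips with [read_panel()].
#'
#' @param panel a `hotspot_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  panel <- validate_panel(panel)
  lines <- c("#name\tgene\tchrom\tpos\tref\talt",
             paste(panel$name, panel$gene, panel$chrom, panel$pos,
                   panel$ref, panel$alt, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
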