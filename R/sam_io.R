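#' Fabricate a reference sequence for a simulated hotspot
#'
#' Builds a seeded random chromosome long enough to hold every fragment that
#' can span the hotspot (maximum fragment length 500 bp plus padding), with
#' the hotspot's reference base planted at its position. Intended for
#' simulated loci with small coordinates; for real genomic coordinates supply
#' a FASTA instead (a random multi-megabase chromosome would be useless).
#'
#' @param hotspot a 1-row `hotspot_panel`.
#' @param seed integer seed.
#' @return A named [Biostrings::DNAStringSet] of length 1.
#' @export
make_reference <- function(hotspot, seed = 1L) {
  hotspot <- as_single_hotspot(hotspot)
  if (hotspot$pos > 2e6)
    stop("refusing to fabricate a reference for position ", hotspot$pos,
         "; supply a reference FASTA covering the locus")
  len <- hotspot$pos + FRAG_LEN_MAX + 100L
  seqchar <- withr::with_seed(as.integer(seed), {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  })
  substr(seqchar, hotspot$pos, hotspot$pos) <- hotspot$ref
  ref <- Biostrings::DNAStringSet(seqchar)
  names(ref) <- hotspot$chrom
  ref
}

#' Write simulated fragments as aligned paired-end SAM
#'
#' Emits two primary alignment records per fragment (a proper pair, mates
#' pointing at each other) such that the template-length field (TLEN, SAM
#' column 9) carries the fragment length exactly: the leftmost mate has
#' `TLEN = +L`, its mate `TLEN = -L`. Read sequences are copied from the
#' reference (CIGAR all-match); mutant fragments carry the alternate base at
#' the hotspot position in every mate base that covers it, wild fragments the
#' reference base. MD and NM tags are written consistently with the
#' mismatches. Reads are `read_length` bp, truncated to the fragment length
#' when the fragment is shorter (the mates then fully overlap).
#'
#' @param fragments a fragment table from [simulate_fragments()], or any
#'   data.frame with columns `allele`, `length`, `start` (0-based).
#' @param hotspot a 1-row `hotspot_panel`; defaults to the one recorded on
#'   `fragments`.
#' @param reference a named [Biostrings::DNAStringSet] or path to a FASTA
#'   covering every fragment; `NULL` fabricates one via [make_reference()].
#' @param sam_path output SAM path.
#' @param fasta_path if non-`NULL`, the reference is (also) written here.
#' @param read_length read length in bp; defaults to the value recorded on
#'   `fragments`, else 151.
#' @param base_error_rate optional per-base substitution error rate applied
#'   independently to every read base (default 0: reads match the template).
#' @param seed seed for reference fabrication and error injection.
#' @return `sam_path`, invisibly.
#' @export
fragments_to_sam <- function(fragments, hotspot = attr(fragments, "hotspot"),
                             reference = NULL, sam_path,
                             fasta_path = NULL,
                             read_length = attr(fragments, "read_length"),
                             base_error_rate = 0, seed = 1L) {
  hotspot <- as_single_hotspot(hotspot)
  stopifnot(all(c("allele", "length", "start") %in% names(fragments)))
  if (is.null(read_length)) read_length <- 151L
  read_length <- as.integer(read_length)

  if (is.null(reference)) {
    reference <- make_reference(hotspot, seed = seed)
  } else if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  if (!hotspot$chrom %in% names(reference))
    stop("reference has no sequence named ", hotspot$chrom)
  refseq <- as.character(reference[[hotspot$chrom]])
  ref_len <- nchar(refseq)
  if (substr(refseq, hotspot$pos, hotspot$pos) != hotspot$ref)
    stop("reference base at ", hotspot$chrom, ":", hotspot$pos,
         " is not the panel ref base ", hotspot$ref)
  if (!is.null(fasta_path)) Biostrings::writeXStringSet(reference, fasta_path)

  n <- nrow(fragments)
  L <- as.integer(fragments$length)
  s0 <- as.integer(fragments$start)
  if (any(s0 < 0L) || any(s0 + L > ref_len))
    stop("fragment outside reference (reference length ", ref_len, ")")

  templates <- substring(refseq, s0 + 1L, s0 + L)
  is_mut <- fragments$allele == "mutant"
  off <- hotspot$pos - s0  # 1-based offset of the hotspot within the template
  covers <- off >= 1L & off <= L
  plant <- is_mut & covers
  if (any(plant))
    substr(templates[plant], off[plant], off[plant]) <- hotspot$alt

  r <- pmin(read_length, L)
  seq1 <- substring(templates, 1L, r)
  seq2 <- substring(templates, L - r + 1L, L)
  if (base_error_rate > 0) {
    err <- withr::with_seed(as.integer(seed) + 1L, list(
      seq1 = inject_errors(seq1, base_error_rate),
      seq2 = inject_errors(seq2, base_error_rate)))
    seq1 <- err$seq1
    seq2 <- err$seq2
  }

  pos1 <- s0 + 1L          # SAM 1-based leftmost
  pos2 <- s0 + L - r + 1L
  qname <- sprintf("frag%06d", seq_len(n))
  ref1 <- substring(refseq, pos1, pos1 + r - 1L)
  ref2 <- substring(refseq, pos2, pos2 + r - 1L)
  tags1 <- md_nm_tags(seq1, ref1)
  tags2 <- md_nm_tags(seq2, ref2)
  cigar <- paste0(r, "M")
  qual <- strrep("I", r)

  rec <- function(flag, pos, cig, pnext, tlen, sq, ql, tags) {
    paste(qname, flag, hotspot$chrom, pos, 60L, cig, "=", pnext, tlen,
          sq, ql, tags, sep = "\t")
  }
  header <- c("@HD\tVN:1.6\tSO:unknown",
              paste0("@SQ\tSN:", hotspot$chrom, "\tLN:", ref_len),
              "@PG\tID:ctfrag\tPN:ctfrag")
  # FLAG 99: paired, proper, mate reverse, first; 147: paired, proper,
  # reverse, second
  body <- c(rec(99L, pos1, cigar, pos2, L, seq1, qual, tags1),
            rec(147L, pos2, cigar, pos1, -L, seq2, qual, tags2))
  body <- body[order(rep(seq_len(n), 2L))]  # keep mate records adjacent
  writeLines(c(header, body), sam_path)
  invisible(sam_path)
}

inject_errors <- function(seqs, rate) {
  vapply(seqs, function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1L]]
    hit <- which(stats::runif(length(b)) < rate)
    for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1L)
    paste(b, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# MD/NM tag pair for an all-match (CIGAR nM) alignment: runs of matches
# interleaved with the reference base at each mismatch
md_nm_tags <- function(read, ref) {
  mapply(function(rd, rf) {
    a <- strsplit(rd, "", fixed = TRUE)[[1L]]
    b <- strsplit(rf, "", fixed = TRUE)[[1L]]
    mm <- which(a != b)
    if (length(mm) == 0L)
      return(paste0("NM:i:0\tMD:Z:", length(a)))
    parts <- character(0)
    prev <- 0L
    for (i in mm) {
      parts <- c(parts, as.character(i - prev - 1L), b[i])
      prev <- i
    }
    parts <- c(parts, as.character(length(a) - prev))
    paste0("NM:i:", length(mm), "\tMD:Z:", paste(parts, collapse = ""))
  }, read, ref, USE.NAMES = FALSE)
}

#' Export simulated fragments as FASTQ
#'
#' Convenience export of the same read pairs [fragments_to_sam()] aligns,
#' as unaligned FASTQ (mate 2 reverse-complemented, as a sequencer would
#' emit it). Provided for workflows that want to run an external aligner;
#' the package's own pipeline consumes the aligned SAM directly.
#'
#' @inheritParams fragments_to_sam
#' @param fq1_path,fq2_path output paths for mate 1 / mate 2.
#' @return `c(fq1_path, fq2_path)`, invisibly.
#' @export
fragments_to_fastq <- function(fragments, hotspot = attr(fragments, "hotspot"),
                               reference = NULL, fq1_path, fq2_path,
                               read_length = attr(fragments, "read_length"),
                               seed = 1L) {
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam))
  fragments_to_sam(fragments, hotspot, reference, sam,
                   read_length = read_length, seed = seed)
  recs <- readLines(sam)
  recs <- recs[!startsWith(recs, "@")]
  f <- strsplit(recs, "\t", fixed = TRUE)
  qname <- vapply(f, `[[`, character(1), 1L)
  flag <- as.integer(vapply(f, `[[`, character(1), 2L))
  sq <- vapply(f, `[[`, character(1), 10L)
  ql <- vapply(f, `[[`, character(1), 11L)
  first <- bitwAnd(flag, 64L) > 0L
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  writeLines(paste0("@", qname[first], "/1\n", sq[first], "\n+\n", ql[first]),
             fq1_path)
  writeLines(paste0("@", qname[!first], "/2\n", rc(sq[!first]), "\n+\n",
                    ql[!first]), fq2_path)
  invisible(c(fq1_path, fq2_path))
}

#' Write a fragment truth table as TSV
#'
#' @param fragments fragment table from [simulate_fragments()].
#' @param path output path.
#' @param header_lines optional `#`-prefixed provenance lines.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path, header_lines = character(0)) {
  lines <- c(header_lines, "#allele\tlength\tstart",
             paste(fragments$allele, fragments$length, fragments$start,
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
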