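#' Extract read-pair observations at a hotspot
#'
#' Collects, from an aligned paired-end SAM/BAM, one observation per DNA
#' template (fragment) whose aligned span covers the hotspot position, and
#' recovers the fragment length from the template-length field
#' (`tlen_abs = |TLEN|`, SAM column 9). Records are filtered before
#' deduplication: secondary and supplementary alignments, unmapped reads or
#' mates, records with `TLEN = 0` (unpaired/singleton), mapping quality below
#' `min_mapq`, and — when `require_proper_pair` — pairs not flagged proper.
#'
#' A fragment is counted once even though two records may carry it: records
#' are deduplicated by template name, and the record with positive TLEN is
#' the canonical one when both mates cover the hotspot. The observed base at
#' the hotspot is looked up on every covering mate by a CIGAR-aware
#' coordinate walk (M/=/X consume query and reference, I/S query only, D/N
#' reference only); a deletion spanning the hotspot records the sentinel
#' `"-"`. Template names seen on more than two primary records are ambiguous
#' and flagged so that typing resolves them to `unresolved`.
#'
#' @param path SAM or BAM file. SAM is converted in place (to a temporary
#'   BAM) via [Rsamtools::asBam()].
#' @param hotspot a 1-row `hotspot_panel`.
#' @param min_mapq minimum mapping quality per record (default 20).
#' @param require_proper_pair drop pairs without the proper-pair flag
#'   (default `TRUE`).
#' @param min_base_quality minimum Phred base quality at the hotspot for a
#'   mate's base call to be used (default 0: ignored, no quality filtering).
#' @return A list with `observations` — a data.frame with one row per
#'   surviving template: `template`, `chrom`, `leftmost_start` (0-based),
#'   `tlen_abs`, `base1`, `base2` (observed hotspot bases per covering mate,
#'   `NA` when only one mate covers), `ambiguous` — and `tallies`, a named
#'   integer vector of per-filter exclusion counts.
#' @export
extract_pairs_at_hotspot <- function(path, hotspot, min_mapq = 20L,
                                     require_proper_pair = TRUE,
                                     min_base_quality = 0L) {
  hotspot <- as_single_hotspot(hotspot)
  bam <- as_bam(path)
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  if (is.null(hdr) || length(hdr) == 0L) stop("alignment file has no header")
  if (!hotspot$chrom %in% names(hdr))
    stop("chromosome ", hotspot$chrom, " not present in alignment header")

  which <- GenomicRanges::GRanges(hotspot$chrom,
                                  IRanges::IRanges(hotspot$pos, hotspot$pos))
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "pos", "mapq", "cigar", "seq", "qual", "isize"),
    which = which)
  res <- Rsamtools::scanBam(bam, param = param)[[1L]]

  flag <- res$flag
  n0 <- length(flag)
  keep <- rep(TRUE, n0)
  tallies <- integer(0)
  drop_filter <- function(drop, label) {
    tallies[label] <<- sum(drop & keep)
    keep <<- keep & !drop
  }
  drop_filter(bitwAnd(flag, 256L) > 0L, "secondary")
  drop_filter(bitwAnd(flag, 2048L) > 0L, "supplementary")
  drop_filter(bitwAnd(flag, 4L) > 0L, "unmapped")
  drop_filter(bitwAnd(flag, 8L) > 0L, "mate_unmapped")
  if (require_proper_pair)
    drop_filter(bitwAnd(flag, 2L) == 0L, "not_proper_pair")
  drop_filter(is.na(res$isize) | res$isize == 0L, "tlen_zero")
  drop_filter(is.na(res$mapq) | res$mapq < min_mapq, "low_mapq")

  idx <- which(keep)
  if (length(idx) == 0L) {
    obs <- data.frame(template = character(0), chrom = character(0),
                      leftmost_start = integer(0), tlen_abs = integer(0),
                      base1 = character(0), base2 = character(0),
                      ambiguous = logical(0), stringsAsFactors = FALSE)
    return(list(observations = obs, tallies = tallies))
  }

  qname <- res$qname[idx]
  pos <- res$pos[idx]
  cigar <- res$cigar[idx]
  seqs <- as.character(res$seq)[idx]
  quals <- as.character(res$qual)[idx]
  isize <- res$isize[idx]

  base <- character(length(idx))
  for (i in seq_along(idx)) {
    base[i] <- read_base_at(pos[i], cigar[i], seqs[i], quals[i],
                            hotspot$pos, min_base_quality)
  }
  # the index query returns records whose reference span overlaps the
  # hotspot, so every record here has a covering mate (base or "-")
  grp <- split(seq_along(idx), qname)
  obs <- lapply(names(grp), function(nm) {
    g <- grp[[nm]]
    ambiguous <- length(g) > 2L
    canon <- g[which.max(isize[g] > 0L)]  # positive-TLEN record if present
    b <- base[g][!is.na(base[g])]
    data.frame(template = nm, chrom = hotspot$chrom,
               leftmost_start = min(pos[g]) - 1L,
               tlen_abs = abs(isize[canon]),
               base1 = if (length(b) >= 1L) b[1L] else NA_character_,
               base2 = if (length(b) >= 2L) b[2L] else NA_character_,
               ambiguous = ambiguous, stringsAsFactors = FALSE)
  })
  obs <- do.call(rbind, obs)
  obs <- obs[order(obs$template), , drop = FALSE]
  rownames(obs) <- NULL
  list(observations = obs, tallies = tallies)
}

as_bam <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile()
    return(Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = TRUE))
  }
  if (!file.exists(paste0(path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", path)))
    Rsamtools::indexBam(path)
  path
}

#' Observed base of one read at a reference position
#'
#' Walks the CIGAR string from the record's leftmost aligned position to
#' locate the query base aligned to `at_pos`: M/=/X consume query and
#' reference, I and S consume query only, D and N consume reference only,
#' H and P consume neither. Returns the base character, `"-"` when `at_pos`
#' falls in a deletion or reference skip, and `NA` when the alignment does
#' not cover `at_pos` or the base quality is below `min_base_quality`.
#'
#' @param pos 1-based leftmost aligned reference position of the record.
#' @param cigar CIGAR string.
#' @param seq query sequence (SAM SEQ).
#' @param qual Phred+33 quality string, or `NA`/`"*"` to skip the check.
#' @param at_pos 1-based reference position to look up.
#' @param min_base_quality minimum Phred quality for the call (default 0).
#' @return A single character: a base, `"-"`, or `NA_character_`.
#' @export
read_base_at <- function(pos, cigar, seq, qual = NA_character_, at_pos,
                         min_base_quality = 0L) {
  if (is.na(cigar) || cigar == "*") return(NA_character_)
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  lens <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  kinds <- substr(ops, nchar(ops), nchar(ops))
  rpos <- pos  # next reference position to account for
  qpos <- 1L   # next query position
  for (k in seq_along(kinds)) {
    len <- lens[k]
    kind <- kinds[k]
    if (kind %in% c("M", "=", "X")) {
      if (at_pos >= rpos && at_pos <= rpos + len - 1L) {
        qi <- qpos + (at_pos - rpos)
        if (min_base_quality > 0L && !is.na(qual) && qual != "*") {
          q <- utf8ToInt(substr(qual, qi, qi)) - 33L
          if (q < min_base_quality) return(NA_character_)
        }
        return(toupper(substr(seq, qi, qi)))
      }
      rpos <- rpos + len
      qpos <- qpos + len
    } else if (kind %in% c("I", "S")) {
      qpos <- qpos + len
    } else if (kind %in% c("D", "N")) {
      if (at_pos >= rpos && at_pos <= rpos + len - 1L) return("-")
      rpos <- rpos + len
    }
    # H and P consume neither
  }
  NA_character_
}

#' Type the allele of each observed fragment
#'
#' Applies the agreement rule to the hotspot base calls of each observation:
#' if all covering mates report the alternate base the fragment is `mutant`;
#' if all report the reference base, `wild`; disagreement between mates, a
#' third base, a deletion spanning the hotspot, ambiguous pairing, or no
#' usable base call all yield `unresolved`. Unresolvable fragments are
#' labelled, never dropped, so the typed table partitions the observations.
#'
#' @param observations the `observations` data.frame from
#'   [extract_pairs_at_hotspot()].
#' @param hotspot a 1-row `hotspot_panel`.
#' @return A data.frame of typed fragments: `hotspot_name`, `allele`
#'   (`"mutant"`, `"wild"` or `"unresolved"`), `length` (bp).
#' @export
type_fragments <- function(observations, hotspot) {
  hotspot <- as_single_hotspot(hotspot)
  n <- nrow(observations)
  allele <- character(n)
  for (i in seq_len(n)) {
    allele[i] <- type_one(observations$base1[i], observations$base2[i],
                          observations$ambiguous[i], hotspot$ref, hotspot$alt)
  }
  data.frame(hotspot_name = rep(hotspot$name, n), allele = allele,
             length = observations$tlen_abs, stringsAsFactors = FALSE)
}

type_one <- function(base1, base2, ambiguous, ref, alt) {
  if (isTRUE(ambiguous)) return("unresolved")
  b <- c(base1, base2)
  b <- b[!is.na(b)]
  if (length(b) == 0L || any(b == "-")) return("unresolved")
  u <- unique(b)
  if (length(u) != 1L) return("unresolved")
  if (u == alt) return("mutant")
  if (u == ref) return("wild")
  "unresolved"
}
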