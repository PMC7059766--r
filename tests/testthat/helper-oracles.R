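# independent brute-force oracles, deliberately naive

# reconstruct a read's reference-aligned bases position by position:
# returns a named character vector, names = 1-based reference positions,
# values = query base or "-" inside deletions/skips
oracle_aligned_bases <- function(pos, cigar, seq) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  lens <- as.integer(sub("[A-Z=]$", "", ops))
  kinds <- substr(ops, nchar(ops), nchar(ops))
  out <- character(0)
  rpos <- pos
  qpos <- 1L
  for (k in seq_along(kinds)) {
    for (j in seq_len(lens[k])) {   # one unit at a time, on purpose
      kind <- kinds[k]
      if (kind %in% c("M", "=", "X")) {
        out[as.character(rpos)] <- substr(seq, qpos, qpos)
        rpos <- rpos + 1L
        qpos <- qpos + 1L
      } else if (kind %in% c("I", "S")) {
        qpos <- qpos + 1L
      } else if (kind %in% c("D", "N")) {
        out[as.character(rpos)] <- "-"
        rpos <- rpos + 1L
      }
    }
  }
  out
}

oracle_base_at <- function(pos, cigar, seq, at_pos) {
  bases <- oracle_aligned_bases(pos, cigar, seq)
  b <- bases[as.character(at_pos)]
  if (is.na(b)) NA_character_ else unname(b)
}

# sort-based median
oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2L == 1L) s[(n + 1L) %/% 2L] else (s[n %/% 2L] + s[n %/% 2L + 1L]) / 2
}

# brute-force modes: scan every observed length, compare against neighbours
oracle_modes <- function(x, frac = 0.8) {
  counts <- table(x)
  lens <- as.integer(names(counts))
  cmax <- max(counts)
  count_at <- function(l) if (l %in% lens) as.integer(counts[as.character(l)]) else 0L
  keep <- vapply(lens, function(l) {
    c0 <- count_at(l)
    c0 >= count_at(l - 1L) && c0 >= count_at(l + 1L) && c0 >= frac * cmax
  }, logical(1))
  sort(lens[keep])
}

# random CIGAR + read for the typing oracle; always has >= 1 aligned block
random_alignment <- function(ref_len = 400L) {
  n_ops <- sample(1:4, 1L)
  kinds <- c("M", sample(c("M", "I", "D"), n_ops, replace = TRUE))
  lens <- c(sample(10:60, 1L), sample(1:12, n_ops, replace = TRUE))
  if (sample(c(TRUE, FALSE), 1L)) {   # optional leading soft clip
    kinds <- c("S", kinds)
    lens <- c(sample(1:10, 1L), lens)
  }
  # no two consecutive identical ops needed for validity; samtools accepts
  qlen <- sum(lens[kinds %in% c("M", "I", "S")])
  seq <- paste(sample(c("A", "C", "G", "T"), qlen, replace = TRUE),
               collapse = "")
  pos <- sample(seq_len(ref_len %/% 2L), 1L)
  list(pos = pos, cigar = paste0(lens, kinds, collapse = ""), seq = seq)
}
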