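# fixture hotspot: sim1:180 C>T
fx_hotspot <- function() test_hotspot(pos = 180L, ref = "C", alt = "T")

# 20 bp read sequence with `base` planted at query offset `at`
seq_with <- function(base, at, len = 20L) {
  s <- strrep("A", len)
  substr(s, at, at) <- base
  s
}

test_that("proper pair is deduplicated to one observation with |TLEN|", {
  hs <- fx_hotspot()
  sam <- withr::local_tempfile(fileext = ".sam")
  s1 <- seq_with("T", 81L, 151L)   # POS 100, hotspot 180 -> offset 81
  s2 <- seq_with("T", 65L, 151L)   # POS 116 -> offset 65
  write_sam_fixture(c(
    sam_record("tA", 99L, 100L, "151M", 167L, s1, pnext = 116L),
    sam_record("tA", 147L, 116L, "151M", -167L, s2, pnext = 100L)), sam)
  ext <- extract_pairs_at_hotspot(sam, hs)
  expect_equal(nrow(ext$observations), 1L)
  o <- ext$observations
  expect_equal(o$tlen_abs, 167L)
  expect_equal(o$leftmost_start, 99L)   # 0-based
  expect_equal(sort(c(o$base1, o$base2)), c("T", "T"))
  expect_false(o$ambiguous)
  typed <- type_fragments(ext$observations, hs)
  expect_equal(typed$allele, "mutant")
  expect_equal(typed$length, 167L)
})

test_that("secondary and TLEN=0 records are filtered; one template survives", {
  hs <- fx_hotspot()
  sam <- withr::local_tempfile(fileext = ".sam")
  cov <- seq_with("C", 11L)  # POS 170 -> hotspot at offset 11
  write_sam_fixture(c(
    sam_record("tA", 99L, 170L, "20M", 167L, cov),
    sam_record("tA", 147L, 175L, "20M", -167L, seq_with("C", 6L)),
    sam_record("tB", 355L, 170L, "20M", 167L, cov),          # secondary
    sam_record("tC", 99L, 170L, "20M", 0L, cov)), sam)       # TLEN = 0
  ext <- extract_pairs_at_hotspot(sam, hs)
  expect_equal(nrow(ext$observations), 1L)
  expect_equal(ext$observations$template, "tA")
  expect_equal(unname(ext$tallies["secondary"]), 1L)
  expect_equal(unname(ext$tallies["tlen_zero"]), 1L)
})

test_that("pairs not covering the hotspot are excluded", {
  hs <- fx_hotspot()
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam_fixture(c(
    sam_record("tA", 99L, 100L, "20M", 60L, strrep("A", 20L), pnext = 140L),
    sam_record("tA", 147L, 140L, "20M", -60L, strrep("A", 20L), pnext = 100L)),
    sam)
  ext <- extract_pairs_at_hotspot(sam, hs)
  expect_equal(nrow(ext$observations), 0L)
})

test_that("mapq and proper-pair filters apply per record", {
  hs <- fx_hotspot()
  sam <- withr::local_tempfile(fileext = ".sam")
  cov <- seq_with("T", 11L)
  write_sam_fixture(c(
    sam_record("tLow", 99L, 170L, "20M", 167L, cov, mapq = 5L),
    sam_record("tImp", 97L, 170L, "20M", 167L, cov)), sam)  # not proper (0x2 unset)
  ext <- extract_pairs_at_hotspot(sam, hs, min_mapq = 20L)
  expect_equal(nrow(ext$observations), 0L)
  expect_equal(unname(ext$tallies["low_mapq"]), 1L)
  expect_equal(unname(ext$tallies["not_proper_pair"]), 1L)
  # relaxing the filters admits both templates
  ext2 <- extract_pairs_at_hotspot(sam, hs, min_mapq = 0L,
                                   require_proper_pair = FALSE)
  expect_equal(nrow(ext2$observations), 2L)
})

test_that("a missing chromosome is an error", {
  hs <- test_hotspot(pos = 180L, chrom = "chrX")
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam_fixture(sam_record("tA", 99L, 170L, "20M", 167L,
                               strrep("A", 20L)), sam)
  expect_error(extract_pairs_at_hotspot(sam, hs), "chrX")
})

test_that("allele typing applies the agreement rules", {
  hs <- fx_hotspot()
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam_fixture(c(
    # mates agree on alt -> mutant
    sam_record("mut", 99L, 170L, "20M", 167L, seq_with("T", 11L)),
    sam_record("mut", 147L, 175L, "20M", -167L, seq_with("T", 6L)),
    # mates agree on ref -> wild
    sam_record("wld", 99L, 170L, "20M", 167L, seq_with("C", 11L)),
    sam_record("wld", 147L, 175L, "20M", -167L, seq_with("C", 6L)),
    # mates disagree (C vs T) -> unresolved
    sam_record("dis", 99L, 170L, "20M", 167L, seq_with("C", 11L)),
    sam_record("dis", 147L, 175L, "20M", -167L, seq_with("T", 6L)),
    # third base -> unresolved
    sam_record("thr", 99L, 170L, "20M", 167L, seq_with("G", 11L)),
    # deletion spanning the hotspot -> unresolved
    sam_record("del", 99L, 100L, "75M10D76M", 167L,
               strrep("A", 151L)),
    # ambiguous pairing: three primary records -> unresolved
    sam_record("amb", 99L, 170L, "20M", 167L, seq_with("T", 11L)),
    sam_record("amb", 147L, 175L, "20M", -167L, seq_with("T", 6L)),
    sam_record("amb", 99L, 172L, "20M", 167L, seq_with("T", 9L))), sam)
  ext <- extract_pairs_at_hotspot(sam, hs)
  typed <- type_fragments(ext$observations, hs)
  got <- setNames(typed$allele, ext$observations$template)
  expect_equal(got[["mut"]], "mutant")
  expect_equal(got[["wld"]], "wild")
  expect_equal(got[["dis"]], "unresolved")
  expect_equal(got[["thr"]], "unresolved")
  expect_equal(got[["del"]], "unresolved")
  expect_equal(got[["amb"]], "unresolved")
  # partition: every observation yields exactly one typed fragment
  expect_equal(nrow(typed), nrow(ext$observations))
})

test_that("base quality below the threshold voids the call", {
  hs <- fx_hotspot()
  sam <- withr::local_tempfile(fileext = ".sam")
  qual <- strrep("I", 20L)
  substr(qual, 11L, 11L) <- "#"  # Q2 at the hotspot offset
  write_sam_fixture(
    sam_record("tQ", 99L, 170L, "20M", 167L, seq_with("T", 11L), qual = qual),
    sam)
  ext <- extract_pairs_at_hotspot(sam, hs, min_base_quality = 20L)
  typed <- type_fragments(ext$observations, hs)
  expect_equal(typed$allele, "unresolved")
  ext0 <- extract_pairs_at_hotspot(sam, hs)  # quality ignored by default
  expect_equal(type_fragments(ext0$observations, hs)$allele, "mutant")
})

test_that("CIGAR walk handles clips, insertions, deletions and skips", {
  #            1234567890...
  expect_equal(read_base_at(100L, "151M", seq_with("T", 81L, 151L),
                            at_pos = 180L), "T")
  # leading soft clip consumes query only
  expect_equal(read_base_at(100L, "10S141M", seq_with("G", 25L, 151L),
                            at_pos = 114L), "G")
  # insertion shifts query offsets
  expect_equal(read_base_at(100L, "50M5I96M", seq_with("G", 61L, 151L),
                            at_pos = 155L), "G")
  # deletion spanning the position reports the sentinel
  expect_equal(read_base_at(100L, "75M10D76M", strrep("A", 151L),
                            at_pos = 180L), "-")
  # reference skip behaves like a deletion for coverage
  expect_equal(read_base_at(100L, "50M100N50M", strrep("A", 100L),
                            at_pos = 180L), "-")
  # past the end: not covered
  expect_true(is.na(read_base_at(100L, "20M", strrep("A", 20L),
                                 at_pos = 180L)))
})

test_that("CIGAR walk agrees with a position-by-position oracle", {
  withr::with_seed(99L, {
    for (i in 1:300) {
      a <- random_alignment()
      span <- sum(as.integer(
        regmatches(a$cigar,
                   gregexpr("\\d+(?=[MDN=X])", a$cigar, perl = TRUE))[[1]]))
      for (at in seq(a$pos - 2L, a$pos + span + 2L, by = 3L)) {
        expect_identical(read_base_at(a$pos, a$cigar, a$seq, at_pos = at),
                         oracle_base_at(a$pos, a$cigar, a$seq, at),
                         label = sprintf("cigar=%s pos=%d at=%d",
                                         a$cigar, a$pos, at))
      }
    }
  })
})

test_that("typed counts partition the observations under sequencing errors", {
  hs <- test_hotspot()
  run <- run_pipeline(hs, 0.3, 400, wild_model = frag_normal(168, 10),
                      mutant_model = frag_normal(150, 12), seed = 13,
                      base_error_rate = 0.02)
  tab <- table(factor(run$typed$allele,
                      levels = c("mutant", "wild", "unresolved")))
  expect_equal(sum(tab), nrow(run$ext$observations))
  expect_equal(nrow(run$ext$observations), 400L)
})
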