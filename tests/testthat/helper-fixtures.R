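# shared fixtures: small-coordinate hotspots so references can be fabricated

test_hotspot <- function(pos = 600L, ref = "C", alt = "T", chrom = "sim1",
                         name = "EGFR-T790M", gene = "EGFR") {
  hotspot_panel(name = name, gene = gene, chrom = chrom, pos = pos,
                ref = ref, alt = alt)
}

# synthetic n-entry panel (fixture coordinates, not real loci)
make_synthetic_panel <- function(n = 38L) {
  pairs <- rbind(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"))
  k <- ((seq_len(n) - 1L) %% 4L) + 1L
  hotspot_panel(
    name = sprintf("HS-%03d", seq_len(n)),
    gene = paste0("GENE", ((seq_len(n) - 1L) %% 7L) + 1L),
    chrom = paste0("sim", ((seq_len(n) - 1L) %% 5L) + 1L),
    pos = 300L + 13L * seq_len(n),
    ref = pairs[k, 1L], alt = pairs[k, 2L])
}

# write a complete SAM file from hand-built alignment lines
write_sam_fixture <- function(records, path, chrom = "sim1", ln = 2000L) {
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               paste0("@SQ\tSN:", chrom, "\tLN:", ln),
               records), path)
  path
}

# one hand-built alignment record; seq defaults to all ref-like 'A's
sam_record <- function(qname, flag, pos, cigar, tlen, seq,
                       chrom = "sim1", mapq = 60L, pnext = pos,
                       qual = strrep("I", nchar(seq))) {
  paste(qname, flag, chrom, pos, mapq, cigar, "=", pnext, tlen,
        seq, qual, sep = "\t")
}

# simulate -> SAM -> extract -> type, returning everything
run_pipeline <- function(hotspot, true_maf, n_templates, wild_model,
                         mutant_model = NULL, seed = 1L,
                         allele_assignment = "deterministic",
                         read_length = 151L, base_error_rate = 0) {
  frags <- simulate_fragments(hotspot, true_maf, n_templates,
                              wild_model = wild_model,
                              mutant_model = mutant_model,
                              read_length = read_length,
                              allele_assignment = allele_assignment,
                              seed = seed)
  sam <- tempfile(fileext = ".sam")
  fragments_to_sam(frags, hotspot, sam_path = sam, seed = seed,
                   base_error_rate = base_error_rate)
  ext <- extract_pairs_at_hotspot(sam, hotspot)
  typed <- type_fragments(ext$observations, hotspot)
  list(frags = frags, sam = sam, ext = ext, typed = typed)
}
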