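# Hand-constructed transcript fixtures used across test files.

# Build a transcript table from explicit region sequences.
make_tx <- function(utr5, cds, utr3, id = "tx1", chrom = "chrI",
                    gene_start = 1L, strand = "+") {
  seqs <- paste0(utr5, cds, utr3)
  n <- length(seqs)
  if (length(id) == 1 && n > 1) id <- paste0(id, seq_len(n))
  tab <- data.table::data.table(
    transcript_id = id, gene_id = paste0("g_", id), chrom = chrom,
    gene_start = gene_start, gene_end = gene_start + nchar(seqs) - 1L,
    strand = strand,
    utr5_len = nchar(utr5), cds_len = nchar(cds), utr3_len = nchar(utr3),
    sequence = seqs)
  build_transcripts(tab)
}

# A well-behaved single transcript: 10 nt 5'-UTR, 10-codon CDS,
# extension of 4 codons (stop + 3 sense), then TAA, then distal UTR.
# rt_extension = [40, 52), next stop at 52.
example_tx <- function() {
  make_tx(utr5 = "CCCCCCCCCC",
          cds = paste0("ATG", strrep("GCT", 9)),
          utr3 = paste0("TAA", "GCAGGCGGA", "TAA", "CCCCCCCCCCCC"))
}

# P-site table builder: positions given per transcript, frame derived.
make_psites <- function(tx, pos, library_id = "lib1", strain = "s1",
                        transcript_id = tx$transcript_id[1]) {
  part <- partition_regions(tx)
  ps <- data.table::data.table(
    transcript_id = transcript_id, psite_pos = as.integer(pos),
    read_length = 28L, library_id = library_id, strain = strain)
  ps <- merge(ps, data.table::as.data.table(tx)[, .(transcript_id, cds_start)],
              by = "transcript_id", sort = FALSE)
  ps[, frame := (psite_pos - cds_start) %% 3L]
  ps[, cds_start := NULL]
  ps[, region := riboRT:::region_label(psite_pos, part[J(ps$transcript_id)])]
  ps[]
}

# tiny config for fast simulations; caller arguments override the defaults
quick_config <- function(...) {
  args <- list(n_transcripts = 40L, replicates = 2L,
               cds_codon_range = c(60L, 150L))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

one_strain <- data.frame(strain = "WT", rt_multiplier = 1, te_frac = 0,
                         te_log2 = 0, rna_frac = 0, rna_log2 = 0)
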