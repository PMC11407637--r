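test_that("loading transcripts from a written fixture round-trips all fields", {
  sim <- simulate_transcriptome(quick_config(n_transcripts = 20L), seed = 3)
  dir <- withr::local_tempdir()
  write_fixture(list(transcripts = sim$transcripts, truth = sim$truth,
                     footprints = data.table::data.table(
                       transcript_id = sim$transcripts$transcript_id[1],
                       five_prime_pos = 1L, read_length = 28L,
                       library_id = "l", strain = "s"),
                     rna = matrix(1L, 2, 1, dimnames = list(
                       sim$transcripts$transcript_id[1:2], "l")),
                     offsets = c(`28` = 12L), config = quick_config(),
                     seed = 3), dir)
  re <- load_transcripts(file.path(dir, "transcripts.fa"),
                         file.path(dir, "transcripts.tsv"))
  orig <- data.table::as.data.table(sim$transcripts)
  for (col in c("transcript_id", "sequence", "cds_start", "cds_end",
                "utr5_len", "cds_len", "utr3_len", "tx_len"))
    expect_equal(re[[col]], orig[[col]], info = col)
})

test_that("id mismatches are fatal and bad CDS lengths are skipped with a warning", {
  tx <- example_tx()
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "t.fa"); tsv <- file.path(dir, "t.tsv")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(tx$sequence, tx$transcript_id)), fa)
  tab <- data.table::as.data.table(tx)[, .(transcript_id = "other_id", gene_id,
    chrom, gene_start, gene_end, strand, utr5_len, cds_len, utr3_len)]
  data.table::fwrite(tab, tsv, sep = "\t")
  expect_error(load_transcripts(fa, tsv), "absent from FASTA")

  bad <- data.table::copy(data.table::as.data.table(tx))
  bad[, cds_len := 31L]  # not a codon multiple
  expect_warning(res <- build_transcripts(bad), "multiple of 3")
  expect_equal(nrow(res), 0L)
})

test_that("next in-frame stop finder matches hand cases and a brute-force oracle", {
  # 3'-UTR after the stop = GCTTAAAC: first in-frame codon GCT, second TAA
  seq1 <- paste0(strrep("C", 10), "ATG", strrep("GCA", 9), "TAA", "GCTTAAAC")
  expect_equal(find_next_inframe_stop(seq1, 40L), 46L)
  # all-A 3'-UTR: no stop
  seq2 <- paste0(strrep("C", 10), "ATG", strrep("GCA", 9), "TAA", strrep("A", 30))
  expect_true(is.na(find_next_inframe_stop(seq2, 40L)))
  # first downstream in-frame codon is a stop
  seq3 <- paste0(strrep("C", 10), "ATG", strrep("GCA", 9), "TAA", "TGA", "CCC")
  expect_equal(find_next_inframe_stop(seq3, 40L), 43L)

  oracle <- function(s, ce) {
    for (j in seq(ce + 3L, nchar(s) - 3L, by = 3L))
      if (substr(s, j + 1L, j + 3L) %in% c("TAA", "TAG", "TGA"))
        return(as.integer(j))
    NA_integer_
  }
  set.seed(42)
  for (i in 1:200) {
    n <- sample(60:200, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    ce <- sample(seq(3, n - 12, by = 3), 1)
    expect_identical(find_next_inframe_stop(s, ce), oracle(s, ce))
  }
})

test_that("region partition matches the hand-constructed example", {
  tx <- example_tx()
  p <- partition_regions(tx)
  expect_equal(p$rt_ext_lo, 40L)
  expect_equal(p$rt_ext_hi, 52L)
  expect_equal(p$rt_ext_len, 12L)
  expect_equal(p$figext_lo, 46L)   # stop window ends at cds_end + 3 + 3
  expect_equal(p$figext_hi, 52L)
  expect_equal(p$distal_lo, 52L)
  expect_equal(p$stopw_lo, 37L)
  expect_equal(p$startw_lo, 7L)
  expect_equal(p$startw_hi, 16L)
  expect_false(p$open_extension)
})

test_that("degenerate geometries truncate windows instead of going negative", {
  # no 5'-UTR: start window truncated at 0
  tx <- make_tx("", paste0("ATG", strrep("GCT", 9)), "TAATTTGAACCC")
  p <- partition_regions(tx)
  expect_equal(p$startw_lo, 0L)
  expect_equal(p$startw_hi, 6L)
  # next stop immediately after the canonical stop: extension length 3,
  # post-stop-window extension empty
  tx2 <- make_tx("CCCCC", paste0("ATG", strrep("GCT", 9)), "TAATAACCCCCC")
  p2 <- partition_regions(tx2)
  expect_equal(p2$rt_ext_len, 3L)
  expect_equal(p2$figext_hi, p2$figext_lo)  # empty post-stop-window extension
})

test_that("partitions tile every synthetic transcript exactly once", {
  sim <- simulate_transcriptome(quick_config(n_transcripts = 30L), seed = 9)
  part <- partition_regions(sim$transcripts)
  tx <- data.table::as.data.table(sim$transcripts)
  for (i in seq_len(nrow(part))) {
    p <- part[i]
    len <- tx[transcript_id == p$transcript_id, tx_len]
    cover <- integer(len)
    for (r in list(c(p$utr5_lo, p$utr5_hi), c(p$startw_lo, p$startw_hi),
                   c(p$cdsbody_lo, p$cdsbody_hi), c(p$stopw_lo, p$stopw_hi),
                   c(p$figext_lo, p$figext_hi), c(p$distal_lo, p$distal_hi)))
      if (r[2] > r[1]) cover[(r[1] + 1):r[2]] <- cover[(r[1] + 1):r[2]] + 1L
    expect_true(all(cover == 1L), info = p$transcript_id)
    expect_equal(p$rt_ext_len %% 3L, 0L)
  }
})

test_that("overlap filter applies the strict same-strand threshold symmetrically", {
  base <- data.table::data.table(
    transcript_id = c("a", "b"), gene_id = c("ga", "gb"), chrom = "chrI",
    strand = "+", gene_start = c(1L, 81L), gene_end = c(100L, 200L))
  # overlap = 100 - 81 + 1 = 20 >= 18: both excluded
  expect_length(overlap_filter(base), 0L)
  # overlap 17 (< 18): both retained
  b17 <- data.table::copy(base)[2, gene_start := 84L]
  expect_setequal(overlap_filter(b17), c("a", "b"))
  # 20 bp overlap on opposite strands: both retained
  bop <- data.table::copy(base)[2, strand := "-"]
  expect_setequal(overlap_filter(bop), c("a", "b"))
  # symmetry on random layouts: exclusion always affects both partners
  set.seed(7)
  for (i in 1:20) {
    n <- 8
    st <- sample(1:500, n)
    d <- data.table::data.table(
      transcript_id = paste0("t", 1:n), gene_id = paste0("g", 1:n),
      chrom = "chrI", strand = sample(c("+", "-"), n, TRUE),
      gene_start = st, gene_end = st + sample(50:150, n, TRUE))
    kept <- overlap_filter(d)
    excluded <- setdiff(d$transcript_id, kept)
    for (e in excluded) {
      row <- d[transcript_id == e]
      partners <- d[strand == row$strand & transcript_id != e &
                    pmin(gene_end, row$gene_end) -
                    pmax(gene_start, row$gene_start) + 1L >= 18L]
      expect_true(nrow(partners) > 0)
      expect_true(all(!partners$transcript_id %in% kept))
    }
  }
})

test_that("transcripts without a gene span are excluded with a warning", {
  d <- data.table::data.table(
    transcript_id = c("a", "b"), gene_id = c("ga", "gb"), chrom = c("chrI", NA),
    strand = "+", gene_start = c(1L, NA), gene_end = c(100L, NA))
  expect_warning(kept <- overlap_filter(d), "lack a gene span")
  expect_equal(kept, "a")
})
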