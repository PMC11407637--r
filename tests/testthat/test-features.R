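test_that("uORF finder classifies hand-built cases", {
  # 5'-UTR "AA ATG GCT TAA ..." : one upstream uORF
  s1 <- paste0("AAATGGCTTAACC", "ATG", strrep("GCT", 5), "TAACCC")
  u1 <- find_uorfs(s1, cds_start = 13L)
  expect_equal(nrow(u1), 1L)
  expect_equal(u1$class, "upstream")
  expect_equal(u1$start, 2L)
  expect_equal(u1$end, 11L)
  # AUG 4 nt before the main start with no stop in between: overlapping
  s2 <- paste0(strrep("C", 8), "ATGC", "ATG", strrep("GCT", 5), "TAACCC")
  u2 <- find_uorfs(s2, cds_start = 12L)
  expect_equal(u2$class, "overlapping")
  # no AUG in the 5'-UTR: no uORFs
  s3 <- paste0(strrep("C", 12), "ATG", strrep("GCT", 5), "TAA")
  expect_equal(nrow(find_uorfs(s3, 12L)), 0L)
})

test_that("uORF finder agrees with a brute-force ORF oracle on random UTRs", {
  oracle <- function(s, cds_start) {
    stops <- c("TAA", "TAG", "TGA")
    res <- list()
    for (st in seq_len(cds_start)) {   # 1-based start of candidate AUG
      if (substr(s, st, st + 2) != "ATG") next
      j <- st + 3; end <- NA
      while (j + 2 <= nchar(s)) {
        if (substr(s, j, j + 2) %in% stops) { end <- j + 2; break }
        j <- j + 3
      }
      cls <- if (!is.na(end) && end <= cds_start) "upstream" else "overlapping"
      res[[length(res) + 1]] <- data.frame(start = st - 1, class = cls)
    }
    if (!length(res)) data.frame(start = integer(0), class = character(0))
    else do.call(rbind, res)
  }
  set.seed(21)
  for (i in 1:200) {
    utr5 <- paste(sample(c("A", "C", "G", "T"), sample(10:60, 1), TRUE),
                  collapse = "")
    s <- paste0(utr5, "ATG", strrep("GCT", 10), "TAA", strrep("C", 9))
    got <- find_uorfs(s, nchar(utr5))
    ref <- oracle(s, nchar(utr5))
    expect_equal(nrow(got), nrow(ref))
    if (nrow(got)) {
      expect_equal(got$start, ref$start)
      expect_equal(got$class, ref$class)
    }
  }
})

test_that("poly(A) and oligo(U) scanners implement the window rules", {
  expect_true(scan_polya("AAAAAAAAAA"))
  expect_true(scan_polya("AAAAGAAAAA"))        # 9 A in a 10-window
  expect_true(scan_polya("AAAAGGAAAA"))        # exactly 8 A
  expect_false(scan_polya("AAAAGGGAAA"))       # 7 A only
  expect_false(scan_polya("AAAAAAAAA"))        # too short for the window
  expect_true(scan_oligou("UUUUUUU"))
  expect_true(scan_oligou("TTTTTTT"))
  expect_false(scan_oligou("UUUUUU"))
  expect_false(scan_oligou("UUUAUUUU"))        # interrupted run
  # oracle agreement on random sequences
  polya_oracle <- function(s) {
    n <- nchar(s); if (n < 10) return(FALSE)
    ch <- strsplit(s, "")[[1]] == "A"
    any(vapply(1:(n - 9), function(i) sum(ch[i:(i + 9)]) >= 8, logical(1)))
  }
  set.seed(22)
  for (i in 1:300) {
    s <- paste(sample(c("A", "A", "C", "G", "T"), sample(5:40, 1), TRUE),
               collapse = "")
    expect_identical(scan_polya(s), polya_oracle(s))
    expect_identical(scan_oligou(s), grepl("T{7}", s))
  }
})

test_that("tAI weights satisfy their structural invariants", {
  gcn_path <- system.file("extdata", "trna_gcn_synthetic.tsv", package = "riboRT")
  gcn <- read.delim(gcn_path)
  w <- compute_tai(gcn)
  expect_length(w, 61L)
  expect_equal(max(w), 1)
  expect_true(all(w > 0))
  expect_false(any(c("TAA", "TAG", "TGA") %in% names(w)))
  # doubling copy numbers leaves weights unchanged
  gcn2 <- gcn; gcn2$copy_number <- gcn2$copy_number * 2
  expect_equal(compute_tai(gcn2), w)
  # one dedicated Watson-Crick decoder per codon, equal copies, no wobble
  # decoding: every codon equally optimal
  all_ac <- unique(riboRT:::revcomp(riboRT:::tai_codon_order()))
  flat <- data.frame(anticodon = all_ac, copy_number = 1)
  s0 <- data.frame(pairing_class = c("WC:T", "WC:C", "WC:A", "WC:G",
                                     "G:U", "I:C", "I:A", "U:G"),
                   s = c(0, 0, 0, 0, 1, 1, 1, 1))
  expect_true(all(compute_tai(flat, s0) == 1))
  # codons with W = 0 get the geometric mean of nonzero weights
  tiny <- data.frame(anticodon = c("AGC", "GGC"), copy_number = c(5, 0))
  wt <- compute_tai(tiny)
  nz <- wt[wt != wt[["TTT"]]]  # weights actually backed by a decoder
  expect_gt(wt[["TTT"]], 0)
})

test_that("codon optimality is the geometric mean of codon weights", {
  w <- c(GCT = 0.5, GCA = 0.25, GCC = 1.0)
  expect_equal(codon_optimality_score("GCTGCTGCT", w), 0.5)
  expect_equal(codon_optimality_score("GCAGCC", w), 0.5)
  expect_error(codon_optimality_score("GCTG", w), "multiple of 3")
  expect_error(codon_optimality_score("TTTTTT", w), "without a weight")
  # permutation invariance and bounds
  set.seed(23)
  gcn <- read.delim(system.file("extdata", "trna_gcn_synthetic.tsv",
                                package = "riboRT"))
  wt <- compute_tai(gcn)
  cods <- sample(names(wt), 50, TRUE)
  sc1 <- codon_optimality_score(paste(cods, collapse = ""), wt)
  sc2 <- codon_optimality_score(paste(sample(cods), collapse = ""), wt)
  expect_equal(sc1, sc2, tolerance = 1e-12)
  expect_gte(sc1, min(wt[cods])); expect_lte(sc1, max(wt[cods]))
  expect_equal(sc1, exp(mean(log(wt[cods]))), tolerance = 1e-12)
})

test_that("stop-codon context reads off the expected positions", {
  # ... GCT | TAA | GACGTC ... : P-site codon GCT, +4 = G
  tx <- make_tx(strrep("C", 12), paste0("ATG", strrep("GCT", 9)),
                paste0("TAA", "GACGTC", "TAA", strrep("C", 12)))
  ctx <- stop_context_features(tx, partition_regions(tx))
  expect_equal(ctx$stop_codon, "TAA")
  expect_equal(ctx$p_site_codon, "GCT")
  expect_equal(ctx$nt_plus4, "G")
  expect_equal(ctx$nt_plus5, "A")
  expect_equal(ctx$nt_plus9, "C")
  expect_false(ctx$context_truncated)
  # short 3'-UTR: +6 and beyond absent, flagged
  tx2 <- make_tx(strrep("C", 12), paste0("ATG", strrep("GCT", 9)), "TAAGA")
  ctx2 <- stop_context_features(tx2, partition_regions(tx2))
  expect_equal(ctx2$nt_plus5, "A")
  expect_true(is.na(ctx2$nt_plus6))
  expect_true(ctx2$context_truncated)
})

test_that("nucleotide-usage log-ratios vanish for identical groups and flag planted skews", {
  sim <- simulate_transcriptome(quick_config(n_transcripts = 40L), seed = 31)
  tx <- sim$transcripts
  ids <- tx$transcript_id
  out <- context_usage_logratio(tx, list(Reference = ids, Up = ids),
                                anchor = "aug", positions = c(-3:-1, 1:3))
  expect_true(all(abs(out$proportions[group == "Up", log2_ratio]) < 1e-12,
                  na.rm = TRUE))
  # proportions sum to 1 per group and position
  sums <- out$proportions[, .(s = sum(proportion)), by = .(group, position)]
  expect_equal(sums$s, rep(1, nrow(sums)))
  # a group constructed to carry A at -3 shows a positive log-ratio there
  tx2 <- data.table::copy(data.table::as.data.table(tx))
  forced <- tx2$transcript_id[1:20]
  for (id in forced) {
    i <- which(tx2$transcript_id == id)
    p <- tx2$cds_start[i] - 3L
    substr(tx2$sequence[i], p + 1L, p + 1L) <- "A"
  }
  out2 <- context_usage_logratio(tx2, list(Reference = ids, Up = forced),
                                 anchor = "aug", positions = c(-3:-1))
  lr <- out2$proportions[group == "Up" & position == -3 & nt == "A", log2_ratio]
  expect_gt(lr, 0)
})

test_that("out-of-frame QC flags planted +1-frame stops and degenerate fractions", {
  # CDS with a TAA planted in frame +1
  cds <- paste0("ATG", "CTA", "AGG", strrep("GCT", 7))
  expect_equal(substr(paste0(cds, ""), 5, 7), "TAA")  # +1 frame triplet
  tx <- make_tx(strrep("C", 12), cds, paste0("TAA", "GCAGCA", "TAA",
                                             strrep("C", 12)))
  cs <- tx$cds_start[1]; ce <- tx$cds_end[1]
  ps <- make_psites(tx, pos = c(rep(ce - 30L + 3L * (0:9), 4)))
  qc <- out_of_frame_qc(ps, tx)
  expect_true(qc$per_gene$has_oof_stop_in_cds)
  expect_equal(qc$per_gene$oof_fraction, 0)  # all window reads frame 0
  # no OOF stop in a clean CDS
  tx3 <- make_tx(strrep("C", 12), paste0("ATG", strrep("GGG", 9)),
                 paste0("TAA", "GGGGGG", "TAA", strrep("C", 12)))
  ps3 <- make_psites(tx3, pos = tx3$cds_start[1] + 3L * (0:5))
  expect_false(out_of_frame_qc(ps3, tx3)$per_gene$has_oof_stop_in_cds)
})

test_that("the feature table matches planted ground truth on a simulated fixture", {
  cfg <- quick_config(n_transcripts = 60L, uorf_frac = 0.4, polya_frac = 0.25,
                      oligou_frac = 0.25)
  sim <- simulate_transcriptome(cfg, seed = 33)
  part <- partition_regions(sim$transcripts)
  ft <- feature_table(sim$transcripts, part)
  m <- merge(ft, sim$truth, by = "transcript_id")
  expect_equal(m$has_upstream_uorf.x, m$has_upstream_uorf.y)
  expect_equal(m$has_overlapping_uorf.x, m$has_overlapping_uorf.y)
  expect_equal(m$polya_5utr.x, m$polya_5utr.y)
  expect_equal(m$polya_3utr.x, m$polya_3utr.y)
  expect_equal(m$oligou_5utr.x, m$oligou_5utr.y)
  expect_equal(m$oligou_3utr.x, m$oligou_3utr.y)
  expect_equal(m$stop_codon.x, m$stop_codon.y)
  expect_equal(m$rt_ext_len.x, m$rt_ext_len.y)
})
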