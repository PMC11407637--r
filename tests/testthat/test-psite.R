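test_that("read-length filter keeps the two footprint size classes", {
  fp <- data.table::data.table(read_length = c(19L, 20L, 23L, 24L, 27L, 32L, 33L))
  expect_equal(sort(filter_read_lengths(fp)$read_length), c(20L, 23L, 27L, 32L))
  expect_warning(empty <- filter_read_lengths(fp, keep = 28L), "no footprints")
  expect_equal(empty$read_length, integer(0))
  fp28 <- data.table::data.table(read_length = c(28L, 29L))
  expect_equal(filter_read_lengths(fp28, keep = 28L)$read_length, 28L)
  # retained count equals histogram mass on the keep-set
  set.seed(1)
  lens <- sample(18:34, 1000, TRUE)
  fp2 <- data.table::data.table(read_length = lens)
  expect_equal(nrow(filter_read_lengths(fp2)),
               sum(lens %in% c(20:23, 27:32)))
})

test_that("P-site assignment adds offsets and derives frames and regions", {
  tx <- make_tx(strrep("C", 10), paste0("ATG", strrep("GCT", 49)),
                paste0("TAA", strrep("GCA", 3), "TAA", strrep("C", 130)))
  offs <- c(`28` = 12L, `30` = 13L)
  fp <- data.table::data.table(
    transcript_id = tx$transcript_id[1],
    five_prime_pos = c(100L, 35L, 0L),
    read_length = c(28L, 30L, 28L))
  ps <- assign_psites(fp, offs, tx)
  expect_equal(ps$psite_pos, c(112L, 48L, 12L))
  expect_equal(ps$frame, (ps$psite_pos - 10L) %% 3L)
  expect_equal(ps$frame[2], (48L - 10L) %% 3L)
  expect_true(all(ps$region %in% c("five_utr", "start", "cds", "stop",
                                   "extension", "distal_3utr")))
  # missing offset for a present length is fatal
  expect_error(assign_psites(fp, c(`28` = 12L), tx), "read length")
})

test_that("simulated footprints round-trip through offset inversion", {
  cfg <- quick_config(strains = one_strain, replicates = 1L)
  sim <- simulate_experiment(cfg, seed = 21)
  ps <- assign_psites(sim$footprints, sim$offsets, sim$transcripts)
  # the generator draws psites then subtracts the offset, so adding it back
  # must land every read on a within-transcript position
  expect_equal(nrow(ps), nrow(sim$footprints))
  tx <- data.table::as.data.table(sim$transcripts)
  m <- merge(ps, tx[, .(transcript_id, tx_len)], by = "transcript_id")
  expect_true(all(m$psite_pos >= 0 & m$psite_pos < m$tx_len))
})

test_that("offsets are recoverable from start-codon pileups", {
  cfg <- quick_config(strains = one_strain, replicates = 1L,
                      n_transcripts = 80L, ribo_depth = 2)
  sim <- simulate_experiment(cfg, seed = 8)
  est <- suppressWarnings(
    estimate_offsets(sim$footprints, sim$transcripts, min_support = 20L))
  common <- intersect(names(est), names(sim$offsets))
  # the modal 5'-to-start distance equals the generator offset for
  # well-supported lengths
  support <- table(sim$footprints$read_length)
  strong <- common[support[common] > 500]
  expect_true(length(strong) >= 3)
  expect_equal(est[strong], sim$offsets[strong])
})

test_that("offset estimation falls back to the nearest supported length", {
  cfg <- quick_config(strains = one_strain, replicates = 1L, ribo_depth = 1.5,
                      read_lengths = c(20L, 28L),
                      read_length_probs = c(0.01, 0.99),
                      offsets = c(`20` = 8L, `28` = 12L))
  sim <- simulate_experiment(cfg, seed = 4)
  expect_warning(est <- estimate_offsets(sim$footprints, sim$transcripts,
                                         min_support = 200L),
                 "inherited")
  expect_equal(unname(est["20"]), unname(est["28"]))
})

test_that("metagene profiles are normalized and localize point masses", {
  tx <- example_tx()
  ps <- make_psites(tx, pos = rep(10L, 25L))  # all P-sites on the start codon
  prof <- metagene_profile(ps, tx)
  expect_equal(sum(prof$fraction), 1, tolerance = 1e-9)
  expect_equal(prof[anchor == "start" & distance == 0, fraction], 1)
  # stop-anchor convention: last sense nucleotide = 0
  ps2 <- make_psites(tx, pos = rep(39L, 10L))
  prof2 <- metagene_profile(ps2, tx)
  expect_equal(prof2[anchor == "stop" & distance == 0, fraction], 0.5)
  expect_equal(prof2[anchor == "start" & distance == 29, fraction], 0.5)
})

test_that("pooled metagene equals the count-weighted mix of per-library profiles", {
  tx <- example_tx()
  ps <- rbind(make_psites(tx, pos = c(10L, 13L, 16L, 40L), library_id = "a"),
              make_psites(tx, pos = rep(22L, 6L), library_id = "b"))
  pooled <- metagene_profile(ps, tx, pool_replicates = TRUE)
  per <- metagene_profile(ps, tx, pool_replicates = FALSE)
  w <- per[, .(w = sum(count)), by = library_id]
  per <- merge(per, w, by = "library_id")
  mix <- per[, .(fraction = sum(fraction * w) / sum(w)),
             by = .(anchor, distance)]
  m <- merge(pooled, mix, by = c("anchor", "distance"))
  expect_equal(m$fraction.x, m$fraction.y, tolerance = 1e-12)
})

test_that("region and frame percentages behave as ratios and sum to 100", {
  tx <- make_tx(strrep("C", 12), paste0("ATG", strrep("GCT", 49)),
                paste0("TAA", strrep("GCA", 5), "TAA", strrep("C", 40)))
  cs <- tx$cds_start[1]
  # 90 frame-0 + 10 frame-1 P-sites in the CDS body
  pos <- c(rep(cs + 3L * (10:39), 3), cs + 1L + 3L * (10:19))
  ps <- make_psites(tx, pos = pos)
  rfc <- region_frame_counts(ps)
  expect_equal(rfc$frame0_share[region == "cds", frame0_pct], 90)
  expect_equal(sum(rfc$region_share$share), 100, tolerance = 1e-9)
})

test_that("frame computation is translation invariant", {
  tx <- example_tx()
  ps <- make_psites(tx, pos = c(10L, 14L, 27L, 41L))
  shifted <- make_tx(strrep("G", 22), paste0("ATG", strrep("GCT", 9)),
                     paste0("TAA", "GCAGGCGGA", "TAA", strrep("C", 12)))
  ps2 <- make_psites(shifted, pos = c(10L, 14L, 27L, 41L) + 12L)
  expect_equal(ps$frame, ps2$frame)
})

test_that("perfect frame fidelity yields a pure frame-0 CDS body", {
  cfg <- quick_config(strains = one_strain, replicates = 1L,
                      frame_fidelity = 1, noise_rate = 0)
  sim <- simulate_experiment(cfg, seed = 13)
  part <- partition_regions(sim$transcripts)
  ps <- assign_psites(sim$footprints, sim$offsets, sim$transcripts, part)
  rfc <- region_frame_counts(ps)
  expect_equal(rfc$frame0_share[region == "cds", frame0_pct], 100)
})
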