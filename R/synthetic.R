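#' Configuration for the synthetic ribosome-profiling experiment
#'
#' The defaults emulate the study design the package targets: three strains
#' (a wild type, a single deletion with near-wild-type termination, and a
#' double deletion with a strong termination defect), three replicates each,
#' footprints concentrated in the CDS with high frame-0 fidelity, strain
#' scaled extension occupancy (readthrough), and negative-binomial RNA
#' counts. Extension occupancy is density-proportional: a transcript with
#' per-ribosome readthrough rate rho has extension frame-0 density =
#' rho x CDS frame-0 density, and the distal 3'-UTR receives rho^2 (double
#' readthrough) plus low uniform noise.
#'
#' @param n_transcripts number of transcripts (default 300).
#' @param utr5_range,cds_codon_range,ext_codon_range,distal_range sampling
#'   ranges for 5'-UTR nt, CDS sense codons, extension codons (canonical stop
#'   included), and distal 3'-UTR nt (after the terminating stop).
#' @param strains data.frame: `strain`, `rt_multiplier` (readthrough scale),
#'   `te_frac`/`te_log2` (fraction and magnitude of TE effects vs the first
#'   strain), `rna_frac`/`rna_log2` (likewise for RNA abundance).
#' @param replicates libraries per strain (default 3).
#' @param frame_fidelity probability a P-site stays in frame 0 (default 0.9).
#' @param rho_range per-ribosome readthrough-rate range, sampled log-uniform
#'   (default 0.005-0.1 before strain scaling).
#' @param read_lengths,read_length_probs footprint length distribution over
#'   the admitted lengths (default peak at 28 nt).
#' @param offsets named P-site offset vector (read length -> offset).
#' @param ribo_depth expected CDS footprints per codon at unit abundance and
#'   unit TE (default 0.5).
#' @param abundance_sdlog log-normal spread of transcript abundance
#'   (default 0.8).
#' @param rna_mean expected RNA count at unit abundance (default 200).
#' @param nb_dispersion RNA negative-binomial dispersion (default 0.02,
#'   typical of yeast replicate libraries).
#' @param noise_rate uniform background footprint density relative to the
#'   per-nt CDS footprint density (default 0.001).
#' @param start_peak initiation-pause strength: extra footprint mass on the
#'   start codon, in multiples of the per-codon CDS density (default 5,
#'   emulating ribosome accumulation over the start codon).
#' @param uorf_frac,polya_frac,oligou_frac fractions of transcripts carrying
#'   each planted 5'/3' feature.
#' @return config list (class `sim_config`).
#' @export
sim_config <- function(n_transcripts = 300L,
                       utr5_range = c(24L, 80L),
                       cds_codon_range = c(100L, 400L),
                       ext_codon_range = c(1L, 20L),
                       distal_range = c(45L, 150L),
                       strains = data.frame(
                         strain = c("WT", "pbp1d", "pab1dpbp1d"),
                         rt_multiplier = c(1, 1.5, 3),
                         te_frac = c(0, 0, 0.1), te_log2 = c(0, 0, 1),
                         rna_frac = c(0, 0.1, 0.1), rna_log2 = c(0, 1, 1)),
                       replicates = 3L,
                       frame_fidelity = 0.9,
                       rho_range = c(0.005, 0.1),
                       read_lengths = c(20:23, 27:32),
                       read_length_probs = c(2, 3, 4, 3, 5, 30, 20, 10, 5, 3),
                       offsets = c(`20` = 8L, `21` = 9L, `22` = 9L, `23` = 10L,
                                   `27` = 11L, `28` = 12L, `29` = 12L,
                                   `30` = 13L, `31` = 13L, `32` = 14L),
                       ribo_depth = 0.5,
                       abundance_sdlog = 0.8,
                       rna_mean = 200,
                       nb_dispersion = 0.02,
                       noise_rate = 0.001,
                       start_peak = 5,
                       uorf_frac = 0.2, polya_frac = 0.1, oligou_frac = 0.1) {
  cfg <- as.list(environment())
  cfg$read_length_probs <- cfg$read_length_probs / sum(cfg$read_length_probs)
  stopifnot(length(cfg$read_lengths) == length(cfg$read_length_probs),
            all(as.character(cfg$read_lengths) %in% names(cfg$offsets)),
            cfg$frame_fidelity > 1 / 3, cfg$frame_fidelity <= 1)
  class(cfg) <- c("sim_config", "list")
  cfg
}

rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

SENSE_CODONS <- setdiff(tai_codon_order(), c("TAA", "TAG", "TGA"))

rand_sense_codons <- function(n) paste(sample(SENSE_CODONS, n, replace = TRUE),
                                       collapse = "")

# sample a 5'-UTR matching the requested feature flags exactly (as judged by
# the package's own scanners); rejection-sampled
sample_utr5 <- function(len, want_up_uorf, want_over_uorf, want_polya,
                        want_oligou, max_tries = 400L) {
  for (i in seq_len(max_tries)) {
    s <- rand_nt(len)
    if (want_oligou) {
      pos <- sample(len - 7L, 1L)
      substr(s, pos, pos + 6L) <- "TTTTTTT"
    }
    if (want_polya) {
      pos <- sample(len - 10L, 1L)
      substr(s, pos, pos + 9L) <- "AAAAAAAAAA"
    }
    if (want_up_uorf) {
      # AUG ... UAA fully inside the UTR
      pos <- sample(max(1L, len - 17L), 1L)
      substr(s, pos, pos + 8L) <- "ATGGCCTAA"
    }
    if (want_over_uorf) {
      # AUG 4 nt before the main start, out of frame, reads into the CDS
      if (len < 4L) next
      substr(s, len - 3L, len - 1L) <- "ATG"
    }
    u <- find_uorfs(paste0(s, "ATG"), len)  # main AUG appended for framing
    ok_uorf <- (any(u$class == "upstream") == want_up_uorf) &&
               (any(u$class == "overlapping") == want_over_uorf)
    ok_polya <- scan_polya(paste0(s, "A")) == want_polya  # A of main AUG
    ok_ou <- scan_oligou(s) == want_oligou
    if (ok_uorf && ok_polya && ok_ou) return(s)
  }
  stop("could not sample a 5'-UTR satisfying the requested feature flags")
}

sample_utr3 <- function(ext_codons, distal_len, want_polya, want_oligou,
                        stop_codon, max_tries = 400L) {
  for (i in seq_len(max_tries)) {
    ext <- if (ext_codons > 1L) rand_sense_codons(ext_codons - 1L) else ""
    next_stop <- sample(c("TAA", "TAG", "TGA"), 1L)
    distal <- rand_nt(distal_len)
    if (want_oligou) {
      pos <- sample(distal_len - 7L, 1L)
      substr(distal, pos, pos + 6L) <- "TTTTTTT"
    }
    if (want_polya) {
      pos <- sample(distal_len - 10L, 1L)
      substr(distal, pos, pos + 9L) <- "AAAAAAAAAA"
    }
    s <- paste0(stop_codon, ext, next_stop, distal)
    if (scan_polya(s) != want_polya) next
    if (scan_oligou(s) != want_oligou) next
    # planted next in-frame stop must be the first one
    if (ext_codons > 1L) {
      ext_cods <- substring(ext, seq(1, nchar(ext), 3), seq(3, nchar(ext), 3))
      if (any(ext_cods %in% STOP_CODONS)) next
    }
    return(s)
  }
  stop("could not sample a 3'-UTR satisfying the requested feature flags")
}

#' Simulate a transcriptome with planted ground-truth features
#'
#' Generates transcript sequences with an AUG at `cds_start`, a stop codon at
#' `cds_end`, a planted next in-frame stop at the configured extension
#' distance (with no earlier in-frame 3'-UTR stop), and 5'/3' features
#' (uORFs, poly(A), oligo(U)) exactly where flagged -- every planted flag is
#' re-detectable by the package's own scanners.
#'
#' @param config [sim_config()] output.
#' @param seed RNG seed.
#' @return list: `transcripts` (transcript table) and `truth` (`data.table`
#'   of per-transcript ground truth: abundance, base readthrough rate, flags,
#'   stop codon, extension length, planted TE/RNA effect indicators per
#'   strain).
#' @export
simulate_transcriptome <- function(config = sim_config(), seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- config$n_transcripts
  utr5_len <- sample(config$utr5_range[1]:config$utr5_range[2], n, TRUE)
  cds_codons <- sample(config$cds_codon_range[1]:config$cds_codon_range[2], n, TRUE)
  ext_codons <- sample(config$ext_codon_range[1]:config$ext_codon_range[2], n, TRUE)
  distal_len <- sample(config$distal_range[1]:config$distal_range[2], n, TRUE)
  stop_codon <- sample(c("TAA", "TAG", "TGA"), n, TRUE, prob = c(0.47, 0.23, 0.30))
  up_uorf <- stats::runif(n) < config$uorf_frac / 2
  over_uorf <- !up_uorf & stats::runif(n) < config$uorf_frac / 2
  polya5 <- stats::runif(n) < config$polya_frac
  polya3 <- stats::runif(n) < config$polya_frac
  oligou5 <- stats::runif(n) < config$oligou_frac
  oligou3 <- stats::runif(n) < config$oligou_frac
  abundance <- exp(stats::rnorm(n, 0, config$abundance_sdlog))
  abundance <- abundance / mean(abundance)
  lr <- log(config$rho_range)
  rho <- exp(stats::runif(n, lr[1], lr[2]))
  seqs <- character(n)
  for (i in seq_len(n)) {
    utr5 <- sample_utr5(utr5_len[i], up_uorf[i], over_uorf[i], polya5[i], oligou5[i])
    cds <- paste0("ATG", rand_sense_codons(cds_codons[i] - 1L))
    utr3 <- sample_utr3(ext_codons[i], distal_len[i], polya3[i], oligou3[i],
                        stop_codon[i])
    seqs[i] <- paste0(utr5, cds, utr3)
  }
  ids <- sprintf("TX%04d", seq_len(n))
  # synthetic gene spans: genes tiled along one chromosome, non-overlapping
  lens <- nchar(seqs)
  starts <- cumsum(c(1L, utils::head(lens + 100L, -1L)))
  tab <- data.table::data.table(
    transcript_id = ids, gene_id = sub("TX", "G", ids),
    chrom = "chrI", gene_start = starts, gene_end = starts + lens - 1L,
    strand = rep(c("+", "-"), length.out = n),
    utr5_len = utr5_len, cds_len = 3L * cds_codons,
    utr3_len = lens - utr5_len - 3L * cds_codons,
    sequence = seqs)
  transcripts <- build_transcripts(tab)
  strains <- config$strains
  te_mat <- rna_mat <- matrix(0, n, nrow(strains),
                              dimnames = list(ids, strains$strain))
  for (j in seq_len(nrow(strains))) {
    sel <- stats::runif(n) < strains$te_frac[j]
    te_mat[sel, j] <- sample(c(-1, 1), sum(sel), TRUE) * strains$te_log2[j]
    sel2 <- stats::runif(n) < strains$rna_frac[j]
    rna_mat[sel2, j] <- sample(c(-1, 1), sum(sel2), TRUE) * strains$rna_log2[j]
  }
  truth <- data.table::data.table(
    transcript_id = ids, abundance = abundance, rho = rho,
    stop_codon = stop_codon, ext_codons = ext_codons,
    rt_ext_len = 3L * ext_codons,
    has_upstream_uorf = up_uorf, has_overlapping_uorf = over_uorf,
    polya_5utr = polya5, polya_3utr = polya3,
    oligou_5utr = oligou5, oligou_3utr = oligou3)
  for (s in strains$strain) {
    truth[[paste0("te_log2_", s)]] <- te_mat[, s]
    truth[[paste0("rna_log2_", s)]] <- rna_mat[, s]
    truth[[paste0("rho_", s)]] <-
      pmin(rho * strains$rt_multiplier[strains$strain == s], 0.8)
  }
  list(transcripts = transcripts, truth = truth)
}

# draw footprint records at given psite positions
fp_records <- function(tx_id, psites, config, tx_len) {
  if (!length(psites)) return(NULL)
  lens <- sample(config$read_lengths, length(psites), TRUE,
                 prob = config$read_length_probs)
  fp5 <- psites - config$offsets[as.character(lens)]
  keep <- fp5 >= 0L & fp5 + lens <= tx_len
  if (!any(keep)) return(NULL)
  data.table::data.table(transcript_id = tx_id,
                         five_prime_pos = as.integer(fp5[keep]),
                         read_length = as.integer(lens[keep]))
}

#' Simulate ribosome footprints for all libraries
#'
#' Per transcript and library: CDS P-site count is Poisson with mean
#' `ribo_depth x abundance x TE x codons`, P-sites uniform over CDS codons
#' with frame-0 probability `frame_fidelity` (+-1 nt jitter otherwise);
#' extension density is the CDS density times the strain-scaled readthrough
#' rate rho; the distal 3'-UTR receives rho^2 plus uniform background noise,
#' as do the UTRs. Raw records carry 5' positions (= P-site - offset) and
#' sampled read lengths.
#'
#' @param transcripts,truth output of [simulate_transcriptome()].
#' @param config [sim_config()].
#' @param seed RNG seed.
#' @return `data.table`: `transcript_id`, `five_prime_pos`, `read_length`,
#'   `library_id`, `strain`.
#' @export
simulate_footprints <- function(transcripts, truth, config = sim_config(),
                                seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed + 1L)
  tx <- data.table::as.data.table(transcripts)
  tr <- data.table::as.data.table(truth)
  d <- merge(tx, tr, by = "transcript_id", sort = FALSE)
  strains <- config$strains
  out <- vector("list", 0)
  jitter_frames <- function(pos, f, lo, hi) {
    n <- length(pos)
    off <- ifelse(stats::runif(n) < f, 0L, sample(c(-1L, 1L), n, TRUE))
    pmin(pmax(pos + off, lo), hi - 1L)
  }
  for (j in seq_len(nrow(strains))) {
    s <- strains$strain[j]
    rho_s <- d[[paste0("rho_", s)]]
    te_s <- 2^d[[paste0("te_log2_", s)]]
    rna_s <- 2^d[[paste0("rna_log2_", s)]]
    for (r in seq_len(config$replicates)) {
      lib <- sprintf("%s_rep%d", s, r)
      recs <- vector("list", nrow(d))
      for (i in seq_len(nrow(d))) {
        n_cod <- d$cds_len[i] %/% 3L
        dens <- config$ribo_depth * d$abundance[i] * rna_s[i] * te_s[i]
        cs <- d$cds_start[i]; ce <- d$cds_end[i]; tl <- d$tx_len[i]
        ext_cod <- d$ext_codons[i]
        ext_hi <- ce + 3L * ext_cod
        # CDS, plus an initiation pause on the start codon
        n1 <- stats::rpois(1, dens * n_cod)
        p1 <- cs + 3L * sample.int(n_cod, n1, TRUE) - 3L
        n1b <- stats::rpois(1, dens * config$start_peak)
        p1 <- c(p1, rep(cs, n1b))
        # extension (readthrough, in-frame before jitter)
        n2 <- stats::rpois(1, dens * rho_s[i] * ext_cod)
        p2 <- ce + 3L * sample.int(ext_cod, n2, TRUE) - 3L
        # distal (double readthrough): in-frame beyond the next stop
        dist_cod <- max(0L, (tl - ext_hi) %/% 3L)
        n3 <- if (dist_cod > 0) stats::rpois(1, dens * rho_s[i]^2 * dist_cod) else 0L
        p3 <- if (n3 > 0) ext_hi + 3L * sample.int(dist_cod, n3, TRUE) - 3L else integer(0)
        ps <- jitter_frames(c(p1, p2, p3), config$frame_fidelity, cs, tl)
        # uniform background over the whole transcript (any frame);
        # noise_rate is relative to the per-nt CDS footprint density
        n4 <- stats::rpois(1, config$noise_rate * (dens / 3) * tl)
        ps <- c(ps, sample.int(tl, n4, TRUE) - 1L)
        recs[[i]] <- fp_records(d$transcript_id[i], ps, config, tl)
      }
      lib_dt <- data.table::rbindlist(recs)
      lib_dt[, library_id := lib][, strain := s]
      out[[length(out) + 1L]] <- lib_dt
    }
  }
  data.table::rbindlist(out)
}

#' Simulate RNA-Seq counts
#'
#' Negative-binomial counts with mean `rna_mean x abundance x strain effect`
#' and the configured dispersion, independent across replicates.
#'
#' @inheritParams simulate_footprints
#' @return integer matrix, transcripts x libraries (named `strain_repN`).
#' @export
simulate_rna_counts <- function(transcripts, truth, config = sim_config(),
                                seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed + 2L)
  tr <- data.table::as.data.table(truth)
  strains <- config$strains
  libs <- as.vector(t(outer(strains$strain, seq_len(config$replicates),
                            function(s, r) sprintf("%s_rep%d", s, r))))
  mat <- matrix(0L, nrow(tr), length(libs),
                dimnames = list(tr$transcript_id, libs))
  size <- 1 / config$nb_dispersion
  for (j in seq_len(nrow(strains))) {
    s <- strains$strain[j]
    mu <- config$rna_mean * tr$abundance * 2^tr[[paste0("rna_log2_", s)]]
    for (r in seq_len(config$replicates)) {
      lib <- sprintf("%s_rep%d", s, r)
      mat[, lib] <- stats::rnbinom(nrow(tr), mu = mu, size = size)
    }
  }
  mat
}

#' Simulate a complete experiment
#'
#' @inheritParams simulate_transcriptome
#' @return list: `transcripts`, `truth`, `footprints`, `rna`, `offsets`,
#'   `config`, `seed`.
#' @export
simulate_experiment <- function(config = sim_config(), seed = 1L) {
  sim <- simulate_transcriptome(config, seed)
  fp <- simulate_footprints(sim$transcripts, sim$truth, config, seed)
  rna <- simulate_rna_counts(sim$transcripts, sim$truth, config, seed)
  list(transcripts = sim$transcripts, truth = sim$truth, footprints = fp,
       rna = rna, offsets = config$offsets, config = config, seed = seed)
}

#' Write a simulated experiment to disk
#'
#' Emits the file dialects the loaders consume -- FASTA, transcript table TSV,
#' offset TSV, footprint TSV, RNA count TSV, ground-truth TSV -- plus a
#' manifest JSON recording the seed and an md5 hash of the canonical config
#' serialization.
#'
#' @param sim [simulate_experiment()] output.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
write_fixture <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  tx <- sim$transcripts
  seqs <- Biostrings::DNAStringSet(setNames(tx$sequence, tx$transcript_id))
  Biostrings::writeXStringSet(seqs, file.path(out_dir, "transcripts.fa"))
  tab_cols <- c("transcript_id", "gene_id", "chrom", "gene_start", "gene_end",
                "strand", "utr5_len", "cds_len", "utr3_len")
  data.table::fwrite(data.table::as.data.table(tx)[, tab_cols, with = FALSE],
                     file.path(out_dir, "transcripts.tsv"), sep = "\t")
  data.table::fwrite(data.table::data.table(
    read_length = as.integer(names(sim$offsets)),
    offset = as.integer(sim$offsets)),
    file.path(out_dir, "psite_offsets.tsv"), sep = "\t")
  data.table::fwrite(sim$footprints, file.path(out_dir, "footprints.tsv"),
                     sep = "\t")
  rna <- data.table::as.data.table(sim$rna, keep.rownames = "transcript_id")
  data.table::fwrite(rna, file.path(out_dir, "rna_counts.tsv"), sep = "\t")
  data.table::fwrite(sim$truth, file.path(out_dir, "truth.tsv"), sep = "\t")
  cfg_json <- jsonlite::toJSON(sim$config[setdiff(names(sim$config), "strains")],
                               auto_unbox = TRUE, digits = NA)
  cfg_file <- tempfile(fileext = ".json")
  writeLines(c(as.character(cfg_json),
               as.character(jsonlite::toJSON(sim$config$strains, digits = NA))),
             cfg_file)
  manifest <- list(seed = sim$seed,
                   n_transcripts = nrow(tx),
                   config_hash = unname(tools::md5sum(cfg_file)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}
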