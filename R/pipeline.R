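#' Read a footprint table
#'
#' @param path TSV with columns `transcript_id`, `five_prime_pos`,
#'   `read_length` and optionally `library_id`, `strain`.
#' @return `data.table`.
#' @export
read_footprints <- function(path) data.table::fread(path, sep = "\t")

#' Read an RNA count table
#'
#' @param path TSV: first column `transcript_id`, remaining columns library
#'   counts.
#' @return integer matrix, transcripts x libraries.
#' @export
read_rna_counts <- function(path) {
  d <- data.table::fread(path, sep = "\t")
  m <- as.matrix(d[, -1])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Run the readthrough analysis pipeline on a fixture directory
#'
#' Loads annotation, footprints, offsets and RNA counts (the dialect written
#' by [write_fixture()]), then computes the P-site table, region/frame
#' accounting, per-strain readthrough efficiencies with pairwise strain
#' comparisons, TE differential results for the last strain vs the first,
#' and the mRNA feature table. Results are written as TSV/JSON under
#' `out_dir` when given.
#'
#' @param fixture_dir directory holding `transcripts.fa`, `transcripts.tsv`,
#'   `psite_offsets.tsv`, `footprints.tsv`, `rna_counts.tsv`.
#' @param out_dir optional output directory.
#' @param keep_lengths admitted read lengths.
#' @return list with `transcripts`, `partitions`, `psites`, `region_counts`,
#'   `readthrough` (per strain), `strain_tests`, `te`, `features`.
#' @export
run_pipeline <- function(fixture_dir, out_dir = NULL,
                         keep_lengths = c(20:23, 27:32)) {
  tx <- load_transcripts(file.path(fixture_dir, "transcripts.fa"),
                         file.path(fixture_dir, "transcripts.tsv"))
  offs <- read_offset_table(file.path(fixture_dir, "psite_offsets.tsv"))
  fp <- read_footprints(file.path(fixture_dir, "footprints.tsv"))
  rna <- read_rna_counts(file.path(fixture_dir, "rna_counts.tsv"))
  part <- partition_regions(tx)
  fp <- filter_read_lengths(fp, keep = keep_lengths)
  ps <- assign_psites(fp, offs, tx, partitions = part)
  rfc <- region_frame_counts(ps)
  rt <- readthrough_efficiency(ps, part, by = "strain")
  strain_tests <- if (length(unique(rt$strain)) >= 2)
    compare_strain_distributions(rt) else NULL
  ribo <- cds_counts_for_te(ps, tx)
  strain_of <- function(libs) sub("_rep[0-9]+$", "", libs)
  cond_r <- strain_of(colnames(ribo)); cond_m <- strain_of(colnames(rna))
  strains <- unique(cond_r)
  te <- if (length(strains) >= 2) {
    contrast <- c(strains[length(strains)], strains[1])
    sel_r <- cond_r %in% contrast; sel_m <- cond_m %in% contrast
    te_differential(ribo[, sel_r, drop = FALSE], rna[, sel_m, drop = FALSE],
                    cond_r[sel_r], cond_m[sel_m], contrast = contrast)
  } else NULL
  gcn <- read.delim(system.file("extdata", "trna_gcn_synthetic.tsv",
                                package = "riboRT"))
  feats <- feature_table(tx, part, weights = compute_tai(gcn))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(rt, file.path(out_dir, "readthrough.tsv"), sep = "\t")
    data.table::fwrite(feats, file.path(out_dir, "features.tsv"), sep = "\t")
    if (!is.null(te))
      data.table::fwrite(te, file.path(out_dir, "te_differential.tsv"), sep = "\t")
    rep <- list(
      region_share = as.data.frame(rfc$region_share),
      frame0_share = as.data.frame(rfc$frame0_share),
      strain_tests = if (!is.null(strain_tests)) as.data.frame(strain_tests))
    jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(transcripts = tx, partitions = part, psites = ps, region_counts = rfc,
       readthrough = rt, strain_tests = strain_tests, te = te,
       features = feats)
}
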