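#' Reads per kilobase of region per million library reads
#'
#' @param count reads in the region.
#' @param length region length in nt (> 0).
#' @param library_size total reads in the library (> 0).
#' @return RPKM (vectorized).
#' @export
rpkm <- function(count, length, library_size) {
  if (any(length <= 0)) stop("rpkm: region length must be > 0")
  if (any(library_size <= 0)) stop("rpkm: library size must be > 0")
  count / (length / 1e3) / (library_size / 1e6)
}

#' Per-mRNA stop-codon readthrough efficiency
#'
#' For each transcript and grouping unit (library or strain), computes
#'
#'   RT = (frame-0 count in extension / extension length) /
#'        (frame-0 count in CDS / effective CDS length)
#'
#' where the extension runs from the canonical stop codon (inclusive) to the
#' next in-frame stop codon (exclusive), and the first `cds_trim` nt of the
#' CDS are excluded from the frame-0 CDS count (and from the effective CDS
#' length) to avoid start-codon pile-up bias. Efficiency is reported only for
#' mRNAs passing the density filters: CDS RPKM > `min_cds_rpkm` and extension
#' RPKM > `min_ext_rpkm` (all-frame region counts; library size = total
#' assigned P-sites in the grouping unit). Transcripts with an open extension
#' (no downstream in-frame stop) are excluded by default.
#'
#' @param psites P-site table from [assign_psites()].
#' @param partitions [partition_regions()] output.
#' @param by grouping column(s) in `psites` defining a library/strain unit
#'   (default `"library_id"` if present, else none -- all reads pooled).
#' @param cds_trim nt removed from the CDS 5' end (default 15).
#' @param min_cds_rpkm,min_ext_rpkm detectability filters (strict `>`).
#' @param include_open_extension include transcripts whose extension has no
#'   terminating stop (default `FALSE`).
#' @return `data.table`: one row per transcript x group with counts, lengths,
#'   `cds_rpkm`, `ext_rpkm`, `detectable` and `readthrough_efficiency` (`NA`
#'   when not detectable).
#' @export
readthrough_efficiency <- function(psites, partitions,
                                   by = intersect("library_id", names(psites)),
                                   cds_trim = 15L,
                                   min_cds_rpkm = 0.2, min_ext_rpkm = 0.1,
                                   include_open_extension = FALSE) {
  ps <- data.table::as.data.table(psites)
  part <- data.table::as.data.table(partitions)
  if (!include_open_extension) part <- part[open_extension == FALSE]
  part <- part[rt_ext_len > 0L & cds_end - cds_start > cds_trim]
  ps <- data.table::copy(ps)
  if (length(by) == 0L) { ps[, group__ := "all"]; by <- "group__" }
  lib_size <- ps[, .(library_size = .N), by = by]
  ps <- merge(ps, part[, .(transcript_id, p_cds_start = cds_start,
                           p_cds_end = cds_end, rt_ext_lo, rt_ext_hi)],
              by = "transcript_id", sort = FALSE)
  ps[, in_cds := psite_pos >= p_cds_start & psite_pos < p_cds_end]
  ps[, in_cds_trim := psite_pos >= p_cds_start + cds_trim & psite_pos < p_cds_end]
  ps[, in_ext := psite_pos >= rt_ext_lo & psite_pos < rt_ext_hi]
  agg <- ps[, .(cds_count = sum(in_cds),
                cds_frame0 = sum(in_cds_trim & frame == 0L),
                ext_count = sum(in_ext),
                ext_frame0 = sum(in_ext & frame == 0L)),
            by = c("transcript_id", by)]
  # grid over all transcripts x groups so zero-count mRNAs are represented
  groups <- unique(lib_size[, by, with = FALSE])
  info <- part[, .(transcript_id, cds_start, cds_end, rt_ext_len)]
  grid <- cbind(info[rep(seq_len(nrow(info)), times = nrow(groups))],
                groups[rep(seq_len(nrow(groups)), each = nrow(info))])
  out <- merge(grid, agg, by = c("transcript_id", by), all.x = TRUE)
  for (col in c("cds_count", "cds_frame0", "ext_count", "ext_frame0"))
    out[is.na(get(col)), (col) := 0L]
  out <- merge(out, lib_size, by = by)
  out[, cds_len := cds_end - cds_start]
  out[, cds_effective_length := cds_len - cds_trim]
  out[, ext_length := rt_ext_len]
  out[, cds_rpkm := rpkm(cds_count, cds_len, library_size)]
  out[, ext_rpkm := rpkm(ext_count, ext_length, library_size)]
  out[, detectable := cds_rpkm > min_cds_rpkm & ext_rpkm > min_ext_rpkm]
  out[, readthrough_efficiency := ifelse(detectable & cds_frame0 > 0,
    (ext_frame0 / ext_length) / (cds_frame0 / cds_effective_length),
    NA_real_)]
  if (identical(by, "group__")) out[, group__ := NULL]
  data.table::setcolorder(out, c("transcript_id", setdiff(names(out), "transcript_id")))
  out[]
}

#' Detectability flag from density filters
#'
#' @param cds_rpkm,ext_rpkm region densities.
#' @param min_cds_rpkm,min_ext_rpkm strict thresholds (defaults 0.2 / 0.1).
#' @return logical vector.
#' @export
detectability <- function(cds_rpkm, ext_rpkm,
                          min_cds_rpkm = 0.2, min_ext_rpkm = 0.1) {
  cds_rpkm > min_cds_rpkm & ext_rpkm > min_ext_rpkm
}

#' Pairwise comparison of readthrough-efficiency distributions across strains
#'
#' Two-sided Wilcoxon rank-sum tests on detectable mRNAs between every pair of
#' strains, Benjamini-Hochberg adjusted. Replicates should be pooled before
#' calling (compute efficiencies with `by = "strain"`).
#'
#' @param rt readthrough table from [readthrough_efficiency()] with a
#'   `strain` column.
#' @param min_n skip a strain with fewer detectable mRNAs than this.
#' @return `data.table` of pairwise results with medians, n, p and padj.
#' @export
compare_strain_distributions <- function(rt, min_n = 3L) {
  rt <- data.table::as.data.table(rt)
  vals <- rt[detectable == TRUE & !is.na(readthrough_efficiency),
             .(eff = readthrough_efficiency), by = strain]
  ns <- vals[, .N, by = strain]
  drop <- ns[N < min_n, strain]
  if (length(drop)) {
    warning("strain(s) with < ", min_n, " detectable mRNAs skipped: ",
            paste(drop, collapse = ", "))
    vals <- vals[!strain %in% drop]
  }
  strains <- unique(vals$strain)
  if (length(strains) < 2) stop("need at least two strains with detectable mRNAs")
  pairs <- utils::combn(strains, 2, simplify = FALSE)
  res <- data.table::rbindlist(lapply(pairs, function(p) {
    x <- vals[strain == p[1], eff]; y <- vals[strain == p[2], eff]
    tst <- rank_sum_test(x, y)
    data.table::data.table(strain_a = p[1], strain_b = p[2],
                           n_a = length(x), n_b = length(y),
                           median_a = stats::median(x), median_b = stats::median(y),
                           statistic = tst$statistic, pvalue = tst$pvalue)
  }))
  res[, padj := bh_adjust(pvalue)]
  res[]
}

#' Spearman correlation of readthrough efficiency with 3'-UTR length
#'
#' Reports the rank correlation for all detectable mRNAs ("all") and,
#' optionally, within strata defined by the identity of the stop codon.
#'
#' @param rt readthrough table (one strain / pooled) from
#'   [readthrough_efficiency()].
#' @param transcripts transcript table (supplies `utr3_len` and sequence for
#'   stop-codon identity).
#' @param stratify_by_stop also report per-stop-codon strata (default `TRUE`).
#' @param low_n strata smaller than this are flagged (default 10).
#' @return `data.table`: `stratum`, `n`, `rho`, `pvalue`, `low_n`.
#' @export
rt_length_correlation <- function(rt, transcripts, stratify_by_stop = TRUE,
                                  low_n = 10L) {
  rt <- data.table::as.data.table(rt)
  tx <- data.table::as.data.table(transcripts)
  tx[, stop_codon := substr(sequence, cds_end + 1L, cds_end + 3L)]
  d <- merge(rt[detectable == TRUE & !is.na(readthrough_efficiency)],
             tx[, .(transcript_id, utr3_len, stop_codon)],
             by = "transcript_id")
  one <- function(dd, label) {
    if (nrow(dd) < 3)
      return(data.table::data.table(stratum = label, n = nrow(dd),
                                    rho = NA_real_, pvalue = NA_real_,
                                    low_n = TRUE))
    sp <- spearman(dd$readthrough_efficiency, dd$utr3_len)
    data.table::data.table(stratum = label, n = nrow(dd), rho = sp$rho,
                           pvalue = sp$pvalue, low_n = nrow(dd) < low_n)
  }
  out <- one(d, "all")
  if (stratify_by_stop)
    out <- rbind(out, data.table::rbindlist(
      lapply(intersect(STOP_CODONS, unique(d$stop_codon)),
             function(s) one(d[stop_codon == s], s))))
  out[]
}
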