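#' Filter ribosome footprints by read length
#'
#' Keeps footprints whose lengths fall in the admitted set. The default set,
#' 20-23 nt plus 27-32 nt, captures the two footprint size classes produced by
#' RNase digestion of 80S ribosomes.
#'
#' @param footprints `data.table` with at least `read_length`; typically also
#'   `transcript_id`, `five_prime_pos`, `library_id`.
#' @param keep integer vector of admitted read lengths.
#' @param verbose log per-length retention counts (message).
#' @return filtered `data.table` (copy).
#' @export
filter_read_lengths <- function(footprints,
                                keep = c(20:23, 27:32),
                                verbose = FALSE) {
  fp <- data.table::as.data.table(footprints)
  if (verbose) {
    tab <- fp[, .N, by = read_length][order(read_length)]
    tab[, kept := read_length %in% keep]
    message(paste(sprintf("len %d: %d reads %s", tab$read_length, tab$N,
                          ifelse(tab$kept, "kept", "dropped")), collapse = "; "))
  }
  out <- fp[read_length %in% keep]
  if (nrow(out) == 0L) warning("no footprints pass the read-length filter")
  out
}

#' Read a P-site offset table
#'
#' @param path TSV with columns `read_length`, `offset` (nt from the read 5'
#'   end to the first nucleotide of the P-site codon).
#' @return named integer vector (names = read lengths).
#' @export
read_offset_table <- function(path) {
  tab <- data.table::fread(path, sep = "\t")
  offs <- as.integer(tab$offset)
  names(offs) <- as.character(tab$read_length)
  validate_offsets(offs)
  offs
}

validate_offsets <- function(offsets) {
  len <- as.integer(names(offsets))
  if (any(is.na(offsets)) || any(offsets < 0L) || any(offsets >= len))
    stop("offsets must satisfy 0 <= offset < read_length for every length")
  invisible(offsets)
}

#' Assign P-site positions, reading frames and region labels
#'
#' P-site position = read 5' end + offset(read length). The reading frame is
#' `(psite - cds_start) mod 3` (frame 0 = annotated CDS frame). Footprints
#' whose P-site falls outside the transcript are dropped (count reported via
#' message when `verbose`).
#'
#' @param footprints `data.table` with `transcript_id`, `five_prime_pos`,
#'   `read_length` and optionally `library_id`, `strain`.
#' @param offsets named integer vector (read length -> offset), e.g. from
#'   [read_offset_table()] or [estimate_offsets()].
#' @param transcripts transcript table.
#' @param partitions optional precomputed [partition_regions()] output; when
#'   supplied (or computable) a `region` column is added.
#' @param verbose log dropped-read counts.
#' @return P-site table: `transcript_id`, `read_length`, `psite_pos`, `frame`,
#'   `region` (if partitions available) plus any library metadata columns.
#' @export
assign_psites <- function(footprints, offsets, transcripts,
                          partitions = NULL, verbose = FALSE) {
  fp <- data.table::as.data.table(footprints)
  validate_offsets(offsets)
  lens <- sort(unique(fp$read_length))
  miss <- setdiff(as.character(lens), names(offsets))
  if (length(miss))
    stop("no P-site offset for read length(s): ", paste(miss, collapse = ", "))
  fp[, psite_pos := five_prime_pos + offsets[as.character(read_length)]]
  tx <- data.table::as.data.table(transcripts)[, .(transcript_id, cds_start, tx_len)]
  fp <- merge(fp, tx, by = "transcript_id", sort = FALSE)
  out_of_tx <- fp$psite_pos < 0L | fp$psite_pos >= fp$tx_len
  if (any(out_of_tx) && verbose)
    message(sum(out_of_tx), " footprint(s) dropped: P-site outside transcript")
  fp <- fp[!out_of_tx]
  fp[, frame := (psite_pos - cds_start) %% 3L]
  fp[, c("cds_start", "tx_len") := NULL]
  if (is.null(partitions) && "has_utr_annotation" %in% names(transcripts))
    partitions <- partition_regions(transcripts)
  if (!is.null(partitions)) {
    part <- partitions[J(fp$transcript_id)]
    fp[, region := region_label(psite_pos, part)]
  }
  fp[]
}

#' Estimate P-site offsets from start-codon metagene signal
#'
#' Fallback when no curated offset table is available: for each read length,
#' the offset is the modal distance from the read 5' end to the annotated
#' start codon, among reads whose span covers `cds_start`. Lengths with fewer
#' than `min_support` qualifying reads inherit the offset of the nearest
#' estimated length.
#'
#' @param footprints raw footprint table (`transcript_id`, `five_prime_pos`,
#'   `read_length`).
#' @param transcripts transcript table.
#' @param min_support minimum qualifying reads per length (default 200).
#' @return named integer vector of offsets.
#' @export
estimate_offsets <- function(footprints, transcripts, min_support = 200L) {
  fp <- data.table::as.data.table(footprints)
  tx <- data.table::as.data.table(transcripts)[, .(transcript_id, cds_start)]
  fp <- merge(fp, tx, by = "transcript_id", sort = FALSE)
  fp <- fp[five_prime_pos <= cds_start & five_prime_pos + read_length > cds_start]
  fp[, dist := cds_start - five_prime_pos]
  lens <- sort(unique(fp$read_length))
  est <- sapply(lens, function(L) {
    d <- fp$dist[fp$read_length == L]
    if (length(d) < min_support) return(NA_integer_)
    tab <- table(d)
    as.integer(names(tab)[which.max(tab)])
  })
  names(est) <- as.character(lens)
  if (all(is.na(est)))
    stop("no read length has ", min_support,
         " reads over start codons; supply an offset table")
  if (any(is.na(est))) {
    known <- lens[!is.na(est)]
    for (L in lens[is.na(est)]) {
      nearest <- known[which.min(abs(known - L))]
      est[as.character(L)] <- est[as.character(nearest)]
      warning("offset for length ", L, " inherited from length ", nearest,
              " (insufficient support)")
    }
  }
  validate_offsets(est)
  est
}

#' Metagene profile of P-site density around start and stop codons
#'
#' Counts P-sites by distance from the start codon (first nt of AUG = 0) and
#' by distance from the stop (last sense nucleotide = 0, so the stop codon
#' occupies distances 1..3 and the 3'-UTR is strictly distance > 0), then
#' normalizes by the total count over both windows jointly, so the two-window
#' profile sums to 1.
#'
#' @param psites P-site table from [assign_psites()].
#' @param transcripts transcript table.
#' @param window_start integer pair `c(lo, hi)` of distances from start
#'   (default `c(-25, 80)`).
#' @param window_stop integer pair of distances from stop (default
#'   `c(-25, 80)`, covering the CDS tail and the 3'-UTR).
#' @param pool_replicates pool all libraries (default `TRUE`); otherwise a
#'   profile per `library_id` normalized within library.
#' @return `data.table` with `anchor` ("start"/"stop"), `distance`, `count`,
#'   `fraction` (and `library_id` when not pooling).
#' @export
metagene_profile <- function(psites, transcripts,
                             window_start = c(-25L, 80L),
                             window_stop = c(-25L, 80L),
                             pool_replicates = TRUE) {
  ps <- data.table::as.data.table(psites)
  tx <- data.table::as.data.table(transcripts)[, .(transcript_id, cds_start, cds_end)]
  ps <- merge(ps, tx, by = "transcript_id", sort = FALSE)
  ps[, d_start := psite_pos - cds_start]
  ps[, d_stop := psite_pos - (cds_end - 1L)]
  by_lib <- if (pool_replicates || !"library_id" %in% names(ps)) character(0) else "library_id"
  grid <- function(anchor, w) data.table::data.table(anchor = anchor,
                                                     distance = seq(w[1], w[2]))
  tally <- function(d, w, anchor, dt) {
    sel <- dt[[d]] >= w[1] & dt[[d]] <= w[2]
    cnt <- dt[sel, .(count = .N), by = c(by_lib, d)]
    data.table::setnames(cnt, d, "distance")
    cnt[, anchor := anchor]
    cnt
  }
  counts <- rbind(tally("d_start", window_start, "start", ps),
                  tally("d_stop", window_stop, "stop", ps))
  libs <- if (length(by_lib)) unique(ps$library_id) else NULL
  full <- rbind(grid("start", window_start), grid("stop", window_stop))
  if (!is.null(libs))
    full <- data.table::rbindlist(lapply(libs, function(l) {
      g <- data.table::copy(full); g[, library_id := l]; g
    }))
  out <- merge(full, counts, by = c(by_lib, "anchor", "distance"), all.x = TRUE)
  out[is.na(count), count := 0L]
  out[, fraction := count / sum(count), by = by_lib]
  data.table::setorderv(out, c(by_lib, "anchor", "distance"))
  out[]
}

#' Frame-resolved region counts and percentages
#'
#' Contingency counts of P-sites by library, region and reading frame, with
#' two derived percentages: each region's share of the library's footprints,
#' and the frame-0 share within each region.
#'
#' @param psites P-site table with `region` and `frame` (and `library_id`).
#' @return list with `counts` (library x region x frame long table),
#'   `region_share` (percent of library footprints per region) and
#'   `frame0_share` (percent frame-0 within region).
#' @export
region_frame_counts <- function(psites) {
  ps <- data.table::as.data.table(psites)
  if (!"library_id" %in% names(ps)) ps[, library_id := "all"]
  ps <- ps[!is.na(region)]
  counts <- ps[, .(count = .N), by = .(library_id, region, frame)]
  region_tot <- counts[, .(count = sum(count)), by = .(library_id, region)]
  region_tot[, share := 100 * count / sum(count), by = library_id]
  f0 <- merge(counts[frame == 0L, .(library_id, region, f0 = count)],
              region_tot[, .(library_id, region, total = count)],
              by = c("library_id", "region"), all.y = TRUE)
  f0[is.na(f0), f0 := 0L]
  f0[, frame0_pct := 100 * f0 / total]
  list(counts = counts[],
       region_share = region_tot[],
       frame0_share = f0[])
}
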