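#' Load transcript models from FASTA plus a transcript table
#'
#' Builds the transcript annotation used by all downstream analyses. Sequences
#' are spliced transcript sequences; the table supplies per-transcript UTR and
#' CDS lengths and the genomic span of the gene (used only by
#' [overlap_filter()]).
#'
#' @param fasta_path path to a FASTA file of spliced transcript sequences.
#' @param table_path path to a tab-separated table with columns
#'   `transcript_id`, `gene_id`, `chrom`, `gene_start`, `gene_end`, `strand`,
#'   `utr5_len`, `cds_len`, `utr3_len`.
#' @return A `data.table` with one row per transcript: the table columns plus
#'   `sequence` (DNA alphabet, uppercase), `tx_len`, `cds_start`, `cds_end`
#'   (0-based, half-open; CDS excludes the stop codon) and
#'   `has_utr_annotation`. Rows whose CDS length is not a positive multiple of
#'   3 are dropped with a warning.
#' @export
load_transcripts <- function(fasta_path, table_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  tab <- data.table::fread(table_path, sep = "\t")
  req <- c("transcript_id", "gene_id", "chrom", "gene_start", "gene_end",
           "strand", "utr5_len", "cds_len", "utr3_len")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    stop("transcript table lacks columns: ", paste(missing_cols, collapse = ", "))
  missing_ids <- setdiff(tab$transcript_id, names(seqs))
  if (length(missing_ids))
    stop("ids in table absent from FASTA: ", paste(missing_ids, collapse = ", "))
  tab <- data.table::as.data.table(tab)
  tab[, sequence := norm_seq(as.character(seqs[transcript_id]))]
  build_transcripts(tab)
}

#' Assemble a transcript table from in-memory fields
#'
#' Shared constructor behind [load_transcripts()] and the synthetic generator:
#' derives CDS coordinates, validates the codon-multiple invariant and flags
#' UTR annotation status.
#'
#' @param tab data.table with at least `transcript_id`, `utr5_len`, `cds_len`,
#'   `utr3_len` and `sequence` columns.
#' @return transcript `data.table` (see [load_transcripts()]).
#' @export
build_transcripts <- function(tab) {
  tab <- data.table::as.data.table(tab)
  tab[, sequence := norm_seq(sequence)]
  tab[, tx_len := nchar(sequence)]
  bad <- tab$cds_len <= 0L | tab$cds_len %% 3L != 0L
  if (any(bad)) {
    warning(sum(bad), " transcript(s) skipped: CDS length not a positive multiple of 3 (",
            paste(utils::head(tab$transcript_id[bad], 5), collapse = ", "), ")")
    tab <- tab[!bad]
  }
  tab[, cds_start := as.integer(utr5_len)]
  tab[, cds_end := as.integer(utr5_len + cds_len)]
  tab[, has_utr_annotation := utr3_len > 0L]
  exp_len <- tab$utr5_len + tab$cds_len + tab$utr3_len
  if (any(exp_len != tab$tx_len))
    stop("sequence length disagrees with utr5_len + cds_len + utr3_len for: ",
         paste(utils::head(tab$transcript_id[exp_len != tab$tx_len], 5), collapse = ", "))
  # annotated stop codon should be a stop; real annotations may violate
  has3 <- tab$has_utr_annotation & tab$utr3_len >= 3L
  stopc <- substr(tab$sequence, tab$cds_end + 1L, tab$cds_end + 3L)
  odd <- has3 & !(stopc %in% STOP_CODONS)
  if (any(odd))
    warning(sum(odd), " transcript(s) lack a stop codon at the annotated CDS end")
  tab[]
}

#' Find the next in-frame stop codon downstream of the canonical stop
#'
#' Scans codons `cds_end + 3k` (k >= 1) and returns the 0-based offset of the
#' first downstream in-frame stop codon, or `NA` if none fits within the
#' transcript.
#'
#' @param sequence transcript sequence (character scalar or vector).
#' @param cds_end 0-based exclusive end of the last sense codon (vectorized).
#' @return integer vector of offsets (`NA` where no downstream in-frame stop
#'   exists).
#' @export
find_next_inframe_stop <- function(sequence, cds_end) {
  sequence <- norm_seq(sequence)
  mapply(function(s, ce) {
    n <- nchar(s)
    j <- ce + 3L
    while (j + 3L <= n) {
      if (substr(s, j + 1L, j + 3L) %in% STOP_CODONS) return(j)
      j <- j + 3L
    }
    NA_integer_
  }, sequence, as.integer(cds_end), USE.NAMES = FALSE)
}

#' Partition transcripts into analysis regions
#'
#' Computes, per transcript, the disjoint region partition (5'-UTR, start
#' window, CDS body, stop window, post-stop-window extension, distal 3'-UTR)
#' plus the readthrough extension. Two extension conventions coexist:
#' `rt_ext_*` starts at the canonical stop codon (inclusive) and ends at the
#' next in-frame stop codon (exclusive) and backs the readthrough-efficiency
#' statistic; `fig_ext_*` starts where the stop window ends and is used for
#' region-percentage accounting so that regions tile the transcript exactly.
#'
#' The start window spans the AUG plus 3 flanking nt on each side; the stop
#' window spans the stop codon plus 3 flanking nt each side; windows truncate
#' at transcript ends, never going negative.
#'
#' @param transcripts transcript table from [load_transcripts()].
#' @param flank window flank size in nt (default 3).
#' @return `data.table` keyed by `transcript_id` with interval bounds
#'   (`*_lo`/`*_hi`, 0-based half-open): `utr5`, `startw`, `cdsbody`, `stopw`,
#'   `figext`, `distal`, plus `rt_ext_lo`, `rt_ext_hi`, `rt_ext_len`,
#'   `next_stop` and `open_extension` (no downstream in-frame stop found; the
#'   extension then runs to the last complete in-frame codon).
#' @export
partition_regions <- function(transcripts, flank = 3L) {
  tx <- data.table::as.data.table(transcripts)
  tx <- tx[has_utr_annotation == TRUE]
  n <- nrow(tx)
  next_stop <- find_next_inframe_stop(tx$sequence, tx$cds_end)
  open_ext <- is.na(next_stop)
  # open extension: run to last complete in-frame codon
  last_codon_end <- tx$cds_end + ((tx$tx_len - tx$cds_end) %/% 3L) * 3L
  rt_ext_hi <- ifelse(open_ext, last_codon_end, next_stop)
  out <- data.table::data.table(
    transcript_id = tx$transcript_id,
    tx_len = tx$tx_len,
    cds_start = tx$cds_start,
    cds_end = tx$cds_end,
    startw_lo = pmax(0L, tx$cds_start - flank),
    startw_hi = pmin(tx$tx_len, tx$cds_start + 3L + flank),
    stopw_lo = pmax(0L, tx$cds_end - flank),
    stopw_hi = pmin(tx$tx_len, tx$cds_end + 3L + flank),
    rt_ext_lo = tx$cds_end,
    rt_ext_hi = as.integer(rt_ext_hi),
    next_stop = as.integer(next_stop),
    open_extension = open_ext
  )
  out[, rt_ext_len := rt_ext_hi - rt_ext_lo]
  out[, utr5_lo := 0L][, utr5_hi := startw_lo]
  out[, cdsbody_lo := startw_hi][, cdsbody_hi := pmax(startw_hi, stopw_lo)]
  out[, figext_lo := stopw_hi][, figext_hi := pmax(stopw_hi, rt_ext_hi)]
  out[, distal_lo := figext_hi][, distal_hi := tx_len]
  data.table::setkey(out, transcript_id)
  out[]
}

#' Region label for a transcript position
#'
#' Vectorized lookup of the disjoint region containing each P-site position,
#' given the matching partition rows (same length as `pos`).
#'
#' @param pos integer positions (0-based).
#' @param part partition rows aligned with `pos` (one row per element).
#' @return character vector with levels `five_utr`, `start`, `cds`, `stop`,
#'   `extension`, `distal_3utr`, or `NA` outside the transcript.
#' @keywords internal
region_label <- function(pos, part) {
  lab <- rep(NA_character_, length(pos))
  lab[pos >= part$utr5_lo & pos < part$utr5_hi] <- "five_utr"
  lab[pos >= part$startw_lo & pos < part$startw_hi] <- "start"
  lab[pos >= part$cdsbody_lo & pos < part$cdsbody_hi] <- "cds"
  lab[pos >= part$stopw_lo & pos < part$stopw_hi] <- "stop"
  lab[pos >= part$figext_lo & pos < part$figext_hi] <- "extension"
  lab[pos >= part$distal_lo & pos < part$distal_hi] <- "distal_3utr"
  lab
}

#' Filter genes by same-strand genomic overlap
#'
#' Retains transcripts whose gene span overlaps every other gene on the same
#' strand by strictly less than `max_overlap` nt; opposite-strand overlap is
#' ignored. Used to exclude ambiguous footprint assignment in readthrough
#' analyses.
#'
#' @param transcripts transcript table with `chrom`, `gene_start`, `gene_end`,
#'   `strand` (1-based closed genomic spans, or any consistent convention:
#'   overlap is computed as `min(end) - max(start) + 1`).
#' @param max_overlap maximum tolerated overlap in nt (default 18; the
#'   retention rule is overlap `< max_overlap`).
#' @return character vector of retained `transcript_id`s.
#' @export
overlap_filter <- function(transcripts, max_overlap = 18L) {
  tx <- data.table::as.data.table(transcripts)
  no_span <- is.na(tx$gene_start) | is.na(tx$gene_end) | is.na(tx$chrom) | is.na(tx$strand)
  if (any(no_span)) {
    warning(sum(no_span), " transcript(s) lack a gene span and were excluded")
    tx <- tx[!no_span]
  }
  keep <- rep(TRUE, nrow(tx))
  groups <- split(seq_len(nrow(tx)), paste(tx$chrom, tx$strand))
  for (idx in groups) {
    if (length(idx) < 2) next
    s <- tx$gene_start[idx]; e <- tx$gene_end[idx]; g <- tx$gene_id[idx]
    for (a in seq_along(idx)) {
      others <- which(g != g[a])
      if (!length(others)) next
      ov <- pmin(e[a], e[others]) - pmax(s[a], s[others]) + 1L
      if (any(ov >= max_overlap)) keep[idx[a]] <- FALSE
    }
  }
  tx$transcript_id[keep]
}
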