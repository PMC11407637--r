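#' Find AUG-initiated upstream open reading frames
#'
#' Every AUG starting within the 5'-UTR opens a candidate uORF, with no
#' minimum length. Translating in that frame, a uORF whose first in-frame
#' stop codon ends at or before the main start codon is classed `upstream`;
#' one whose reading continues past the main start (or never meets a stop
#' before the transcript end) is classed `overlapping`.
#'
#' @param sequence transcript sequence.
#' @param cds_start 0-based offset of the main AUG.
#' @return `data.table`: `start` (0-based), `end` (exclusive end of the stop
#'   codon, `NA` if none), `class`.
#' @export
find_uorfs <- function(sequence, cds_start) {
  s <- norm_seq(sequence)
  n <- nchar(s)
  starts <- gregexpr("ATG", s, fixed = TRUE)[[1]]
  starts <- starts[starts > 0 & starts <= cds_start]  # 1-based; uORF AUG in 5'-UTR
  if (!length(starts) || starts[1] == -1)
    return(data.table::data.table(start = integer(0), end = integer(0),
                                  class = character(0)))
  res <- lapply(starts, function(st1) {
    j <- st1 + 2L  # last nt of AUG, 1-based
    end <- NA_integer_
    while (j + 3L <= n) {
      codon <- substr(s, j + 1L, j + 3L)
      j <- j + 3L
      if (codon %in% STOP_CODONS) { end <- j; break }
    }
    cls <- if (!is.na(end) && end <= cds_start) "upstream" else "overlapping"
    data.table::data.table(start = st1 - 1L, end = end, class = cls)
  })
  data.table::rbindlist(res)
}

#' Scan for poly(A) tracts
#'
#' A poly(A) tract is a 10-nt window containing at least `min_a` adenines
#' (operationalizing "at least 10 consecutive A allowing at most 2 other
#' nucleotides in the window"). For 5'-UTR scanning, append the A of the main
#' AUG to the region before calling so windows may extend to it.
#'
#' @param region_seq region sequence.
#' @param window window width in nt (default 10).
#' @param min_a minimum adenines per window (default 8).
#' @return `TRUE` if any qualifying window exists.
#' @export
scan_polya <- function(region_seq, window = 10L, min_a = 8L) {
  s <- norm_seq(region_seq)
  n <- nchar(s)
  if (n < window) return(FALSE)
  isa <- as.integer(strsplit(s, "", fixed = TRUE)[[1]] == "A")
  run <- cumsum(isa)
  counts <- run[window:n] - c(0L, run[seq_len(n - window)])
  any(counts >= min_a)
}

#' Scan for oligo(U) tracts
#'
#' @param region_seq region sequence.
#' @param min_len minimum exact run length of U (default 7); no interruptions
#'   allowed.
#' @return `TRUE` if a run of at least `min_len` uracils exists.
#' @export
scan_oligou <- function(region_seq, min_len = 7L) {
  grepl(paste0("T{", min_len, "}"), norm_seq(region_seq))
}

# codon table in tAI block order: 16 families (first two nt), third base
# T, C, A, G within each family
tai_codon_order <- function() {
  b <- c("T", "C", "A", "G")
  fam <- unlist(lapply(b, function(x) paste0(x, b)))  # TT, TC, TA, TG, CT, ...
  as.vector(sapply(fam, function(f) paste0(f, b)))
}

revcomp <- function(x) {
  sapply(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE),
         function(v) paste(rev(v), collapse = ""))
}

#' tRNA adaptation index codon weights
#'
#' Computes per-codon tAI weights from tRNA gene copy numbers per anticodon
#' and wobble pairing penalties: each codon's absolute adaptiveness is
#' `W = sum_j (1 - s_j) * tGCN_j` over its Watson-Crick decoder and the
#' wobble decoder allowed for its third base (G34:U, I34:C, I34:A, U34:G),
#' normalized to the best codon; codons with `W = 0` receive the geometric
#' mean of the nonzero weights.
#'
#' @param gcn named numeric vector of tRNA gene copy numbers per anticodon
#'   (5'->3', DNA alphabet), or a data.frame with columns `anticodon`,
#'   `copy_number`.
#' @param s named numeric vector of pairing penalties in `[0, 1]` with names
#'   `WC:T`, `WC:C`, `WC:A`, `WC:G`, `G:U`, `I:C`, `I:A`, `U:G`, or a
#'   data.frame with columns `pairing_class`, `s`. Defaults to the standard
#'   published penalty set (shipped in `inst/extdata`).
#' @return named numeric vector of weights in (0, 1] over the 61 sense
#'   codons.
#' @export
compute_tai <- function(gcn, s = NULL) {
  if (is.data.frame(gcn))
    gcn <- setNames(as.numeric(gcn$copy_number), norm_seq(gcn$anticodon))
  if (is.null(s)) {
    path <- system.file("extdata", "tai_wobble_penalties.tsv", package = "riboRT")
    s <- read.delim(path)
  }
  if (is.data.frame(s)) s <- setNames(as.numeric(s$s), s$pairing_class)
  if (any(gcn < 0)) stop("tRNA gene copy numbers must be nonnegative")
  if (all(gcn == 0)) stop("all tRNA gene copy numbers are zero")
  if (any(s < 0 | s > 1)) stop("pairing penalties must lie in [0, 1]")
  codons <- tai_codon_order()
  trna <- gcn[revcomp(codons)]
  trna[is.na(trna)] <- 0
  p <- 1 - s
  W <- numeric(64)
  for (i in seq(1, 61, by = 4)) {
    W[i]     <- p[["WC:T"]] * trna[i]     + p[["G:U"]] * trna[i + 1]
    W[i + 1] <- p[["WC:C"]] * trna[i + 1] + p[["I:C"]] * trna[i]
    W[i + 2] <- p[["WC:A"]] * trna[i + 2] + p[["I:A"]] * trna[i]
    W[i + 3] <- p[["WC:G"]] * trna[i + 3] + p[["U:G"]] * trna[i + 2]
  }
  names(W) <- codons
  # ATG is decoded only by its own Watson-Crick tRNA (no I:A contribution
  # from the ATA decoder, which is a distinct isoacceptor)
  W[["ATG"]] <- p[["WC:G"]] * trna[[which(codons == "ATG")]]
  W <- W[!codons %in% STOP_CODONS]
  w <- W / max(W)
  if (any(w == 0)) {
    gm <- exp(mean(log(w[w > 0])))
    w[w == 0] <- gm
  }
  w
}

#' Codon optimality score of a CDS
#'
#' Geometric mean of tAI weights over all codons of the CDS (stop codon
#' excluded).
#'
#' @param cds_seq CDS sequence (length a multiple of 3, stop excluded).
#' @param weights codon weights from [compute_tai()].
#' @return scalar score in (0, 1].
#' @export
codon_optimality_score <- function(cds_seq, weights) {
  s <- norm_seq(cds_seq)
  if (nchar(s) %% 3L != 0L) stop("CDS length must be a multiple of 3")
  codons <- substring(s, seq(1, nchar(s), by = 3), seq(3, nchar(s), by = 3))
  w <- weights[codons]
  if (any(is.na(w))) stop("codon(s) without a weight: ",
                          paste(unique(codons[is.na(w)]), collapse = ", "))
  exp(mean(log(w)))
}

#' Stop-codon context of a transcript
#'
#' Reads off the stop codon, the nucleotides at positions +4..+9 (first
#' nucleotide after the stop codon = +4; the stop itself occupies +1..+3),
#' the last sense (P-site) codon, the 3'-UTR length and the readthrough
#' extension length. Positions beyond the transcript end are `NA` and
#' flagged.
#'
#' @param transcripts transcript table.
#' @param partitions [partition_regions()] output (for extension lengths).
#' @return `data.table`: `transcript_id`, `stop_codon`, `p_site_codon`,
#'   `nt_plus4` .. `nt_plus9`, `utr3_len`, `rt_ext_len`, `context_truncated`.
#' @export
stop_context_features <- function(transcripts, partitions) {
  tx <- data.table::as.data.table(transcripts)[has_utr_annotation == TRUE]
  part <- data.table::as.data.table(partitions)
  out <- data.table::data.table(
    transcript_id = tx$transcript_id,
    stop_codon = substr(tx$sequence, tx$cds_end + 1L, tx$cds_end + 3L),
    p_site_codon = substr(tx$sequence, tx$cds_end - 2L, tx$cds_end),
    utr3_len = tx$utr3_len)
  for (k in 4:9) {
    pos <- tx$cds_end + (k - 1L)  # 0-based position of +k
    nt <- substr(tx$sequence, pos + 1L, pos + 1L)
    data.table::set(out, j = paste0("nt_plus", k),
                    value = ifelse(pos < tx$tx_len & nzchar(nt), nt,
                                   NA_character_))
  }
  out[, context_truncated := is.na(nt_plus9)]
  out <- merge(out, part[, .(transcript_id, rt_ext_len)],
               by = "transcript_id", all.x = TRUE, sort = FALSE)
  out[]
}

#' Nucleotide-usage log-ratios between gene groups
#'
#' For positions anchored at the main AUG (negative = upstream of the A,
#' `+1 +2 +3` = the AUG itself, positive beyond +3 = CDS) or at the 5' cap
#' (position 1 = first transcript nucleotide), computes each group's
#' per-position nucleotide proportions, the log2 ratio of each non-reference
#' group's proportion to the reference group's, and chi-squared tests of the
#' position's nucleotide frequency between each group pair
#' (Benjamini-Hochberg adjusted across positions and pairs).
#'
#' @param transcripts transcript table.
#' @param groups named list of transcript-id vectors; must include
#'   `Reference`.
#' @param anchor `"aug"` or `"cap"`.
#' @param positions integer positions (anchor-relative; for `"aug"`, -18..-1
#'   and 1..9 are typical; for `"cap"`, 1..18). Defaults to -18..9 (aug) /
#'   1..18 (cap), 0 skipped.
#' @param min_obs positions with fewer observations in any group are masked
#'   (default 20).
#' @return list: `proportions` (group x position x nt long table with
#'   `log2_ratio` vs Reference) and `tests` (`data.table` of pairwise
#'   chi-squared results).
#' @export
context_usage_logratio <- function(transcripts, groups,
                                   anchor = c("aug", "cap"),
                                   positions = NULL, min_obs = 20L) {
  anchor <- match.arg(anchor)
  if (is.null(positions))
    positions <- if (anchor == "aug") setdiff(-18:9, 0) else 1:18
  if (!"Reference" %in% names(groups))
    stop("groups must include a 'Reference' element")
  tx <- data.table::as.data.table(transcripts)
  nt_at <- function(ids, pos) {
    t2 <- tx[transcript_id %in% ids]
    idx0 <- if (anchor == "aug") {
      t2$cds_start + ifelse(pos > 0, pos - 1L, pos)  # +1 = A of AUG
    } else pos - 1L
    nt <- substr(t2$sequence, idx0 + 1L, idx0 + 1L)
    nt[idx0 < 0 | idx0 >= t2$tx_len | !nzchar(nt)] <- NA_character_
    nt
  }
  counts <- data.table::rbindlist(lapply(names(groups), function(g) {
    data.table::rbindlist(lapply(positions, function(p) {
      nt <- nt_at(groups[[g]], p)
      nt <- nt[!is.na(nt)]
      data.table::data.table(group = g, position = p,
                             nt = c("A", "C", "G", "T"),
                             count = as.integer(table(factor(nt, c("A", "C", "G", "T")))))
    }))
  }))
  counts[, total := sum(count), by = .(group, position)]
  counts[, proportion := ifelse(total > 0, count / total, NA_real_)]
  counts[, masked := total < min_obs]
  ref <- counts[group == "Reference", .(position, nt, ref_prop = proportion)]
  counts <- merge(counts, ref, by = c("position", "nt"), sort = FALSE)
  counts[, log2_ratio := log2(proportion / ref_prop)]
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  tests <- data.table::rbindlist(lapply(pairs, function(pr) {
    data.table::rbindlist(lapply(positions, function(p) {
      tab <- data.table::dcast(counts[group %in% pr & position == p],
                               group ~ nt, value.var = "count")
      m <- as.matrix(tab[, -1])
      m <- m[, colSums(m) > 0, drop = FALSE]
      pv <- if (any(rowSums(m) < min_obs) || ncol(m) < 2) NA_real_ else
        suppressWarnings(stats::chisq.test(m)$p.value)
      data.table::data.table(group_a = pr[1], group_b = pr[2],
                             position = p, pvalue = pv)
    }))
  }))
  tests[, padj := bh_adjust(pvalue)]
  list(proportions = counts[], tests = tests[])
}

#' Out-of-frame footprint QC near the CDS 3' end
#'
#' Computes, per transcript, the fraction of non-frame-0 P-sites within the
#' last `window` nt of the CDS, flags CDS sequences containing an
#' out-of-frame (+1/+2) stop triplet, and relates both to 3'-UTR footprint
#' density: Spearman correlation of the out-of-frame fraction with 3'-UTR
#' RPKM (transcripts passing `min_cds_rpkm`, `min_utr3_rpkm` and
#' `min_window_fp`), and a rank-sum comparison of 3'-UTR RPKM between flagged
#' and unflagged transcripts.
#'
#' @param psites P-site table (pool libraries beforehand if desired).
#' @param transcripts transcript table.
#' @param window nt at the CDS 3' end (default 30).
#' @param min_window_fp minimum footprints in the window for the correlation
#'   (default 30).
#' @param min_cds_rpkm,min_utr3_rpkm density filters (defaults 0.2 / 0.1).
#' @return list: `per_gene` table, `correlation` (Spearman list) and
#'   `flag_test` (rank-sum list), the latter two `NULL` when too few genes
#'   qualify.
#' @export
out_of_frame_qc <- function(psites, transcripts, window = 30L,
                            min_window_fp = 30L, min_cds_rpkm = 0.2,
                            min_utr3_rpkm = 0.1) {
  ps <- data.table::as.data.table(psites)
  tx <- data.table::as.data.table(transcripts)[has_utr_annotation == TRUE]
  lib_size <- nrow(ps)
  ps <- merge(ps, tx[, .(transcript_id, cds_start, cds_end, tx_len)],
              by = "transcript_id", sort = FALSE)
  ps[, in_window := psite_pos >= cds_end - window & psite_pos < cds_end]
  ps[, in_cds := psite_pos >= cds_start & psite_pos < cds_end]
  ps[, in_utr3 := psite_pos >= cds_end & psite_pos < tx_len]
  agg <- ps[, .(window_fp = sum(in_window),
                window_oof = sum(in_window & frame != 0L),
                cds_count = sum(in_cds),
                utr3_count = sum(in_utr3)), by = transcript_id]
  per <- merge(tx[, .(transcript_id, sequence, cds_start, cds_end, tx_len)],
               agg, by = "transcript_id", all.x = TRUE)
  for (col in c("window_fp", "window_oof", "cds_count", "utr3_count"))
    per[is.na(get(col)), (col) := 0L]
  per[, oof_fraction := ifelse(window_fp > 0, window_oof / window_fp, NA_real_)]
  cds_seq <- substr(per$sequence, per$cds_start + 1L, per$cds_end)
  per[, has_oof_stop_in_cds := vapply(cds_seq, function(s) {
    any(vapply(1:2, function(off) {
      sub <- substr(s, off + 1L, nchar(s))
      sub <- substr(sub, 1L, (nchar(sub) %/% 3L) * 3L)
      if (nchar(sub) < 3) return(FALSE)
      any(substring(sub, seq(1, nchar(sub), 3), seq(3, nchar(sub), 3)) %in% STOP_CODONS)
    }, logical(1)))
  }, logical(1))]
  per[, cds_rpkm := rpkm(cds_count, cds_end - cds_start, lib_size)]
  per[, utr3_rpkm := ifelse(tx_len > cds_end,
                            rpkm(utr3_count, tx_len - cds_end, lib_size), NA_real_)]
  per[, sequence := NULL]
  qual <- per[cds_rpkm > min_cds_rpkm & utr3_rpkm > min_utr3_rpkm & !is.na(utr3_rpkm)]
  corr <- NULL
  sub <- qual[window_fp >= min_window_fp]
  if (nrow(sub) >= 3) corr <- spearman(sub$oof_fraction, sub$utr3_rpkm)
  flag_test <- NULL
  if (length(unique(qual$has_oof_stop_in_cds)) == 2) {
    x <- qual[has_oof_stop_in_cds == TRUE, utr3_rpkm]
    y <- qual[has_oof_stop_in_cds == FALSE, utr3_rpkm]
    if (length(x) >= 3 && length(y) >= 3) flag_test <- rank_sum_test(x, y)
  }
  list(per_gene = per[], correlation = corr, flag_test = flag_test)
}

#' Assemble the per-mRNA feature table
#'
#' One row per UTR-annotated transcript with the features used in
#' readthrough-efficiency modeling: lengths, uORF flags and counts, poly(A)
#' and oligo(U) tract flags per UTR, codon optimality (geometric-mean tAI),
#' stop codon, downstream nucleotide context (+4..+9), P-site codon,
#' extension length, and the out-of-frame-stop flag. Negative-control
#' columns are added separately by [augment_negative_controls()].
#'
#' @param transcripts transcript table.
#' @param partitions [partition_regions()] output.
#' @param weights codon weights from [compute_tai()]; `NULL` skips the
#'   optimality column.
#' @return `data.table`, one row per transcript.
#' @export
feature_table <- function(transcripts, partitions, weights = NULL) {
  tx <- data.table::as.data.table(transcripts)[has_utr_annotation == TRUE]
  ctx <- stop_context_features(tx, partitions)
  uorfs <- lapply(seq_len(nrow(tx)), function(i)
    find_uorfs(tx$sequence[i], tx$cds_start[i]))
  utr5 <- substr(tx$sequence, 1L, tx$cds_start)
  utr5_plusA <- substr(tx$sequence, 1L, tx$cds_start + 1L)  # include A of AUG
  utr3 <- substr(tx$sequence, tx$cds_end + 1L, tx$tx_len)   # stop included
  cds <- substr(tx$sequence, tx$cds_start + 1L, tx$cds_end)
  out <- data.table::data.table(
    transcript_id = tx$transcript_id,
    utr5_len = tx$utr5_len, cds_len = tx$cds_len, utr3_len = tx$utr3_len,
    transcript_len = tx$tx_len,
    n_uorfs = vapply(uorfs, nrow, integer(1)),
    has_upstream_uorf = vapply(uorfs, function(u) any(u$class == "upstream"), logical(1)),
    has_overlapping_uorf = vapply(uorfs, function(u) any(u$class == "overlapping"), logical(1)),
    polya_5utr = vapply(utr5_plusA, scan_polya, logical(1), USE.NAMES = FALSE),
    polya_3utr = vapply(utr3, scan_polya, logical(1), USE.NAMES = FALSE),
    oligou_5utr = vapply(utr5, scan_oligou, logical(1), USE.NAMES = FALSE),
    oligou_3utr = vapply(utr3, scan_oligou, logical(1), USE.NAMES = FALSE))
  out[, has_uorf := n_uorfs > 0L]
  if (!is.null(weights))
    out[, codon_optimality := vapply(cds, codon_optimality_score, numeric(1),
                                     weights = weights, USE.NAMES = FALSE)]
  out[, has_oof_stop_in_cds := vapply(cds, function(s) {
    any(vapply(1:2, function(off) {
      sub <- substr(s, off + 1L, nchar(s))
      sub <- substr(sub, 1L, (nchar(sub) %/% 3L) * 3L)
      if (nchar(sub) < 3) return(FALSE)
      any(substring(sub, seq(1, nchar(sub), 3), seq(3, nchar(sub), 3)) %in% STOP_CODONS)
    }, logical(1)))
  }, logical(1), USE.NAMES = FALSE)]
  merge(out, ctx[, .(transcript_id, stop_codon, p_site_codon, nt_plus4,
                     nt_plus5, nt_plus6, rt_ext_len)],
        by = "transcript_id", sort = FALSE)
}
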