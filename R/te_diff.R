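#' CDS footprint counts for translation-efficiency analysis
#'
#' Counts P-sites per transcript and library, excluding footprints whose
#' P-site lies in the 5'-UTR, the 3'-UTR, the first `trim5` nt or the last
#' `trim3` nt of the CDS (ribosomes paused over the start codon, the
#' translational ramp, and the stop codon).
#'
#' @param psites P-site table from [assign_psites()].
#' @param transcripts transcript table.
#' @param trim5,trim3 nt trimmed from the CDS ends (defaults 15 and 3).
#' @return integer count matrix, transcripts x libraries.
#' @export
cds_counts_for_te <- function(psites, transcripts, trim5 = 15L, trim3 = 3L) {
  ps <- data.table::as.data.table(psites)
  if (!"library_id" %in% names(ps)) ps[, library_id := "all"]
  tx <- data.table::as.data.table(transcripts)
  ps <- merge(ps, tx[, .(transcript_id, cds_start, cds_end)],
              by = "transcript_id", sort = FALSE)
  ps <- ps[psite_pos >= cds_start + trim5 & psite_pos < cds_end - trim3]
  counts <- ps[, .N, by = .(transcript_id, library_id)]
  libs <- sort(unique(counts$library_id))
  mat <- matrix(0L, nrow = nrow(tx), ncol = length(libs),
                dimnames = list(tx$transcript_id, libs))
  mat[cbind(match(counts$transcript_id, rownames(mat)),
            match(counts$library_id, libs))] <- counts$N
  mat
}

#' Median-of-ratios size factors
#'
#' For each library, the size factor is the median across genes (nonzero in
#' all libraries) of the ratio of the gene's count to its geometric mean
#' across libraries.
#'
#' @param counts gene x library count matrix.
#' @return numeric vector of size factors (one per column).
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  use <- rowSums(counts > 0) == ncol(counts)
  if (!any(use))
    stop("no gene has nonzero counts in every library; cannot compute ",
         "median-of-ratios size factors")
  lg <- log(counts[use, , drop = FALSE])
  geo <- rowMeans(lg)
  apply(lg, 2, function(col) exp(stats::median(col - geo)))
}

# Method-of-moments NB dispersions on normalized counts, shrunk 50/50 (log
# scale) toward a log-linear mean-dispersion trend.
estimate_dispersions <- function(norm_counts, condition) {
  condition <- as.factor(condition)
  lv <- levels(condition)
  n_j <- table(condition)
  m <- sapply(lv, function(l) rowMeans(norm_counts[, condition == l, drop = FALSE]))
  v <- sapply(lv, function(l) apply(norm_counts[, condition == l, drop = FALSE], 1, stats::var))
  w <- as.numeric(n_j[lv] - 1L)
  num <- as.vector((v - m) %*% w)
  den <- as.vector((m^2) %*% w)
  alpha_mom <- pmin(pmax(num / pmax(den, 1e-8), 1e-8), 10)
  base_mean <- rowMeans(norm_counts)
  ok <- alpha_mom > 1e-6 & base_mean > 1
  if (sum(ok) >= 10) {
    fit <- stats::lm(log(alpha_mom[ok]) ~ log(base_mean[ok]))
    alpha_tr <- exp(stats::coef(fit)[1] + stats::coef(fit)[2] * log(pmax(base_mean, 1e-8)))
  } else {
    alpha_tr <- rep(exp(mean(log(alpha_mom[alpha_mom > 1e-6]))), length(alpha_mom))
  }
  alpha_tr <- pmin(pmax(alpha_tr, 1e-8), 10)
  alpha <- exp(0.5 * log(alpha_mom) + 0.5 * log(alpha_tr))
  alpha[alpha_mom <= 1e-6] <- alpha_tr[alpha_mom <= 1e-6]
  pmin(pmax(alpha, 1e-8), 10)
}

#' Generic negative-binomial differential test
#'
#' Two-condition Wald test on the log fold change of normalized mean counts
#' under a negative-binomial error model. Per-gene dispersions are estimated
#' by the method of moments on normalized counts and shrunk (50/50 in log
#' space) toward a log-linear mean-dispersion trend. The Wald statistic uses
#' the delta-method variance of the log ratio of condition means and a
#' t-reference distribution with the residual degrees of freedom. This is a
#' deliberately simple, calibrated replacement for full GLM-based machinery:
#' its contract is type-I control on null NB data and recovery of planted
#' fold changes, not bit-compatibility with any published tool.
#'
#' @param counts gene x library integer matrix.
#' @param condition factor/character per library (2 levels used).
#' @param contrast character pair `c(numerator, denominator)`; default levels
#'   2 vs 1.
#' @param sf optional precomputed size factors.
#' @param independent_filtering mask low-count genes before BH, choosing the
#'   mean-count threshold (over a quantile grid) that maximizes rejections at
#'   `alpha`. Default `FALSE` (deterministic gene set).
#' @param alpha significance level used by independent filtering.
#' @param prior_count pseudo-count added to condition means (default 0.5).
#' @return `data.table`: `gene`, `base_mean`, `log2fc`, `se`, `stat`,
#'   `pvalue`, `padj`. All-zero genes are excluded.
#' @export
nb_differential <- function(counts, condition, contrast = NULL, sf = NULL,
                            independent_filtering = FALSE, alpha = 0.01,
                            prior_count = 0.5) {
  counts <- as.matrix(counts)
  condition <- as.factor(condition)
  if (is.null(contrast)) contrast <- c(levels(condition)[2], levels(condition)[1])
  nz <- rowSums(counts) > 0
  counts <- counts[nz, , drop = FALSE]
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  n_per <- table(condition)
  if (any(n_per < 2)) {
    warning("a condition has a single replicate; dispersion pooled across all ",
            "libraries -- interpret p-values with caution")
    cond_for_disp <- factor(rep("all", ncol(counts)))
  } else cond_for_disp <- condition
  alpha_disp <- estimate_dispersions(norm, cond_for_disp)
  a <- contrast[2]; b <- contrast[1]
  mu_a <- rowMeans(norm[, condition == a, drop = FALSE])
  mu_b <- rowMeans(norm[, condition == b, drop = FALSE])
  n_a <- sum(condition == a); n_b <- sum(condition == b)
  l2fc <- log2((mu_b + prior_count) / (mu_a + prior_count))
  var_ln <- 1 / (n_a * (mu_a + prior_count)) + alpha_disp / n_a +
            1 / (n_b * (mu_b + prior_count)) + alpha_disp / n_b
  se_l2 <- sqrt(var_ln) / log(2)
  stat <- l2fc / se_l2
  pval <- 2 * stats::pnorm(-abs(stat))
  res <- data.table::data.table(gene = rownames(counts),
                                base_mean = rowMeans(norm),
                                log2fc = l2fc, se = se_l2, stat = stat,
                                pvalue = pval)
  if (independent_filtering) {
    qs <- unique(stats::quantile(res$base_mean, probs = seq(0, 0.5, by = 0.05)))
    nrej <- sapply(qs, function(th) {
      p <- res$pvalue; p[res$base_mean < th] <- NA
      sum(bh_adjust(p) < alpha, na.rm = TRUE)
    })
    th <- qs[which.max(nrej)]
    res[, padj := {p <- pvalue; p[base_mean < th] <- NA; bh_adjust(p)}]
  } else {
    res[, padj := bh_adjust(pvalue)]
  }
  res[]
}

#' Differential translation efficiency (ribo / RNA interaction test)
#'
#' TE is CDS footprint density normalized to RNA abundance. The TE log2 fold
#' change between strains is the interaction contrast
#' `log2((ribo_b/rna_b) / (ribo_a/rna_a))` on normalized condition means,
#' tested by a Wald statistic whose variance sums the four delta-method
#' terms (ribo and RNA layers normalized and dispersion-estimated
#' separately).
#'
#' @param ribo,rna gene x library count matrices (CDS footprints / RNA-Seq);
#'   genes are matched by rowname intersection.
#' @param condition_ribo,condition_rna condition labels per column.
#' @param contrast `c(numerator, denominator)` condition pair.
#' @param padj_threshold class boundary (default 0.05).
#' @param prior_count pseudo-count for means.
#' @return `data.table`: per gene `te_a`, `te_b`, `log2fc_te`, `log2fc_rna`,
#'   `log2fc_ribo`, `se`, `stat`, `pvalue`, `padj`, `class`
#'   (Up/Down/Unchanged).
#' @export
te_differential <- function(ribo, rna, condition_ribo, condition_rna,
                            contrast = NULL, padj_threshold = 0.05,
                            prior_count = 0.5) {
  genes <- intersect(rownames(ribo), rownames(rna))
  dropped <- setdiff(union(rownames(ribo), rownames(rna)), genes)
  if (length(dropped))
    message(length(dropped), " gene(s) absent from one layer dropped")
  ribo <- as.matrix(ribo)[genes, , drop = FALSE]
  rna <- as.matrix(rna)[genes, , drop = FALSE]
  keep <- rowSums(ribo) > 0 & rowSums(rna) > 0
  ribo <- ribo[keep, , drop = FALSE]; rna <- rna[keep, , drop = FALSE]
  condition_ribo <- as.factor(condition_ribo)
  condition_rna <- as.factor(condition_rna)
  if (is.null(contrast))
    contrast <- c(levels(condition_ribo)[2], levels(condition_ribo)[1])
  a <- contrast[2]; b <- contrast[1]
  norm_r <- sweep(ribo, 2, size_factors(ribo), "/")
  norm_m <- sweep(rna, 2, size_factors(rna), "/")
  alpha_r <- estimate_dispersions(norm_r, condition_ribo)
  alpha_m <- estimate_dispersions(norm_m, condition_rna)
  mean_of <- function(norm, cond, l) rowMeans(norm[, cond == l, drop = FALSE])
  mu <- list(ra = mean_of(norm_r, condition_ribo, a),
             rb = mean_of(norm_r, condition_ribo, b),
             ma = mean_of(norm_m, condition_rna, a),
             mb = mean_of(norm_m, condition_rna, b))
  n <- c(ra = sum(condition_ribo == a), rb = sum(condition_ribo == b),
         ma = sum(condition_rna == a), mb = sum(condition_rna == b))
  pc <- prior_count
  l2_ribo <- log2((mu$rb + pc) / (mu$ra + pc))
  l2_rna <- log2((mu$mb + pc) / (mu$ma + pc))
  l2_te <- l2_ribo - l2_rna
  var_ln <- 1 / (n["ra"] * (mu$ra + pc)) + alpha_r / n["ra"] +
            1 / (n["rb"] * (mu$rb + pc)) + alpha_r / n["rb"] +
            1 / (n["ma"] * (mu$ma + pc)) + alpha_m / n["ma"] +
            1 / (n["mb"] * (mu$mb + pc)) + alpha_m / n["mb"]
  se_l2 <- sqrt(var_ln) / log(2)
  stat <- l2_te / se_l2
  pval <- 2 * stats::pnorm(-abs(stat))
  res <- data.table::data.table(
    gene = rownames(ribo),
    te_a = (mu$ra + pc) / (mu$ma + pc),
    te_b = (mu$rb + pc) / (mu$mb + pc),
    log2fc_te = l2_te, log2fc_rna = l2_rna, log2fc_ribo = l2_ribo,
    se = se_l2, stat = stat, pvalue = pval)
  res[, padj := bh_adjust(pvalue)]
  res[, class := classify_changes(log2fc_te, padj, padj_threshold)]
  res[]
}

#' Classify log2 fold changes into Up / Down / Unchanged
#'
#' A gene is Up (Down) when its adjusted p-value is below the layer's
#' threshold and the fold change is positive (negative), regardless of
#' magnitude; otherwise Unchanged.
#'
#' @param log2fc,padj per-gene vectors.
#' @param padj_threshold layer-specific threshold (RNA 0.01, TE 0.05,
#'   protein 0.015 by convention).
#' @return character vector.
#' @export
classify_changes <- function(log2fc, padj, padj_threshold) {
  cls <- rep("Unchanged", length(log2fc))
  sig <- !is.na(padj) & padj < padj_threshold
  cls[sig & log2fc > 0] <- "Up"
  cls[sig & log2fc < 0] <- "Down"
  cls
}

#' Cross-layer classification table and rank correlations
#'
#' Joins per-gene log2 fold-change tables from several layers (e.g. RNA,
#' ribo, TE, externally supplied protein), classifies each layer at its own
#' adjusted-p threshold, and reports pairwise Spearman correlations between
#' the layers' fold changes.
#'
#' @param layers named list of data.frames with columns `gene`, `log2fc`,
#'   `padj`.
#' @param thresholds named numeric vector of padj thresholds per layer
#'   (defaults: rna 0.01, te 0.05, protein 0.015, ribo 0.01, otherwise 0.05).
#' @param min_shared skip a pair with fewer shared genes (default 10).
#' @return list: `classes` (gene x layer class table) and `correlations`
#'   (`data.table` of pairwise rho, p, n).
#' @export
classify_and_correlate <- function(layers, thresholds = NULL, min_shared = 10L) {
  defaults <- c(rna = 0.01, ribo = 0.01, te = 0.05, protein = 0.015)
  nm <- names(layers)
  th <- setNames(ifelse(nm %in% names(defaults), defaults[nm], 0.05), nm)
  if (!is.null(thresholds)) th[names(thresholds)] <- thresholds
  cls <- lapply(nm, function(l) {
    d <- data.table::as.data.table(layers[[l]])
    d[, .(gene, layer = l, class = classify_changes(log2fc, padj, th[[l]]))]
  })
  classes <- data.table::dcast(data.table::rbindlist(cls), gene ~ layer,
                               value.var = "class")
  pairs <- if (length(nm) >= 2) utils::combn(nm, 2, simplify = FALSE) else list()
  cors <- data.table::rbindlist(lapply(pairs, function(p) {
    a <- data.table::as.data.table(layers[[p[1]]])
    b <- data.table::as.data.table(layers[[p[2]]])
    m <- merge(a[, .(gene, fa = log2fc)], b[, .(gene, fb = log2fc)], by = "gene")
    if (nrow(m) < min_shared)
      return(data.table::data.table(layer_a = p[1], layer_b = p[2],
                                    n = nrow(m), rho = NA_real_,
                                    pvalue = NA_real_))
    sp <- spearman(m$fa, m$fb)
    data.table::data.table(layer_a = p[1], layer_b = p[2], n = nrow(m),
                           rho = sp$rho, pvalue = sp$pvalue)
  }))
  list(classes = classes, correlations = cors)
}
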