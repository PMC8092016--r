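# Annotation cross-referencing of association signals: Hi-C contact
# significance with CTCF orientation verification, lncRNA tissue
# enrichment, conservation-score enrichment and leading-SNP block tests.
# All operations are pure functions of their inputs.

#' Read a BED-like interval file
#'
#' @param path tab-separated file without header; first three columns are
#'   chrom, start, end (0-based half-open).
#' @param col_names names for any further columns.
#' @return data frame with `chrom`, `start`, `end` and the extra columns.
#' @export
read_bed <- function(path, col_names = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (!is.null(col_names) && ncol(df) >= 3 + length(col_names))
    names(df)[3 + seq_along(col_names)] <- col_names
  df
}

#' Read a square Hi-C contact matrix with its bin sidecar
#'
#' @param path whitespace-delimited square matrix of contact support.
#' @param bins_path BED file of the bin intervals, in matrix order.
#' @return list with `support` (matrix) and `bins` (data frame).
#' @export
read_contacts <- function(path, bins_path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m)) stop("contact matrix is not square")
  bins <- read_bed(bins_path)
  if (nrow(bins) != nrow(m))
    stop("bin sidecar has ", nrow(bins), " rows for a ", nrow(m),
         "-bin matrix")
  list(support = m, bins = bins)
}

#' Call significant Hi-C contacts for CNV regions
#'
#' For every bin overlapping a CNV region, the support of each off-diagonal
#' contact is divided by the bin's self-support (main contact). The 95th
#' quantile of the pooled ratio distribution over all CNV bins sets the
#' significance threshold; pairs strictly above it are called. A single
#' pooled ratio can never exceed its own quantile, so degenerate inputs
#' return no calls.
#'
#' @param cnv_regions data frame `chrom`, `start`, `end` of CNV spans.
#' @param contacts list with `support` and `bins` ([read_contacts()]).
#' @param quantile significance quantile (default 0.95).
#' @return data frame of called pairs `bin_i`, `bin_j`, `ratio`, with the
#'   threshold in `attr(, "threshold")`.
#' @export
hic_significant_contacts <- function(cnv_regions, contacts,
                                     quantile = 0.95) {
  m <- contacts$support
  bins <- contacts$bins
  if (any(m < 0)) stop("negative contact support")
  cnv_bins <- which(IRanges::overlapsAny(gr_of(bins), gr_of(cnv_regions)))
  if (!length(cnv_bins)) stop("no bin overlaps a CNV region")
  rows <- list()
  for (i in cnv_bins) {
    if (m[i, i] == 0) {
      warning("bin ", i, " has zero self-support; skipped")
      next
    }
    j <- setdiff(seq_len(ncol(m)), i)
    rows[[length(rows) + 1]] <-
      data.frame(bin_i = i, bin_j = j, ratio = m[i, j] / m[i, i])
  }
  if (!length(rows)) stop("no usable CNV bin")
  all_pairs <- do.call(rbind, rows)
  thr <- stats::quantile(all_pairs$ratio, quantile, names = FALSE)
  out <- all_pairs[all_pairs$ratio > thr, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}

#' Verify convergent CTCF orientation at a contact's anchors
#'
#' A chromatin loop is supported when each anchor carries at least one
#' CTCF motif and the motifs face each other: a plus-strand motif on the
#' left (lower-coordinate) anchor and a minus-strand motif on the right.
#'
#' @param left,right data frames (or one-row lists) with `chrom`, `start`,
#'   `end` for the two anchors, ordered by coordinate.
#' @param motifs data frame `chrom`, `start`, `end`, `strand` (`"+"` or
#'   `"-"`).
#' @return `TRUE` if the contact passes the convergence check.
#' @export
ctcf_convergence_check <- function(left, right, motifs) {
  if (!all(motifs$strand %in% c("+", "-")))
    stop("invalid strand value in motif track")
  left <- as.data.frame(left); right <- as.data.frame(right)
  if (left$start > right$start) stop("anchors must be coordinate-ordered")
  mg <- gr_of(motifs)
  in_left <- IRanges::overlapsAny(mg, gr_of(left))
  in_right <- IRanges::overlapsAny(mg, gr_of(right))
  any(in_left & motifs$strand == "+") &&
    any(in_right & motifs$strand == "-")
}

#' lncRNA tissue enrichment of association signals
#'
#' Pairs every association signal with the lncRNAs within `range_bp` and
#' tabulates trait against the lncRNA's top expression tissue. Under the
#' null the table is multinomial with independent margins
#' (`p_trait x q_tissue`); excessive cells are reported as z-scores
#' `(obs - exp) / sqrt(n p q (1 - p q))`.
#'
#' @param signals data frame `chrom`, `start`, `end`, `trait`.
#' @param lncrnas data frame `chrom`, `start`, `end`, `name`, `tissue`.
#' @param range_bp pairing distance (default 10000).
#' @return list with `observed`, `expected` and `z` matrices
#'   (trait x tissue) and `n_pairs`.
#' @export
lncrna_tissue_enrichment <- function(signals, lncrnas, range_bp = 10000) {
  sg <- signals
  sg$start <- pmax(sg$start - range_bp, 0)
  sg$end <- sg$end + range_bp
  hits <- GenomicRanges::findOverlaps(gr_of(sg), gr_of(lncrnas))
  if (!length(hits)) stop("no signal lies within range of any lncRNA")
  tab <- table(trait = signals$trait[S4Vectors::queryHits(hits)],
               tissue = lncrnas$tissue[S4Vectors::subjectHits(hits)])
  obs <- unclass(tab)
  n <- sum(obs)
  p <- rowSums(obs) / n
  q <- colSums(obs) / n
  pq <- outer(p, q)
  expected <- n * pq
  z <- (obs - expected) / sqrt(n * pq * (1 - pq))
  list(observed = obs, expected = expected, z = z, n_pairs = n)
}

#' Conservation enrichment of associated variants (Fisher's test)
#'
#' Conserved elements are score-track entries above the 95th quantile of
#' the score distribution. The 2x2 table of background structural variants
#' (associated yes/no x overlapping a conserved element yes/no) is tested
#' for independence with a two-sided Fisher exact test.
#'
#' @param associated data frame `chrom`, `start`, `end` of associated
#'   (non-exonic) variants; must be a subset of `background`.
#' @param background data frame of all (non-exonic) variants.
#' @param scores data frame `chrom`, `start`, `end`, `score`.
#' @param quantile conservation quantile (default 0.95).
#' @return list with `odds_ratio`, `p_value`, `table` and the score
#'   `threshold`.
#' @export
gerp_fisher_enrichment <- function(associated, background, scores,
                                   quantile = 0.95) {
  thr <- stats::quantile(scores$score, quantile, names = FALSE)
  cons <- scores[scores$score > thr, , drop = FALSE]
  hit <- IRanges::overlapsAny(gr_of(background), gr_of(cons))
  key <- function(df) paste(df$chrom, df$start, df$end)
  is_assoc <- key(background) %in% key(associated)
  tab <- table(factor(is_assoc, c(TRUE, FALSE)),
               factor(hit, c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0) || all(colSums(tab) == 0))
    stop("empty margin in the association x conservation table")
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value,
       table = tab, threshold = thr)
}

#' Leading-SNP block test
#'
#' Collects structural-variant GWAS p-values within 1 Mb of a leading SNP,
#' bins the 2-Mb span into equally sized blocks, and asks whether the
#' block containing the SNP holds more sub-threshold p-values than the
#' others.
#'
#' @param snp_pos SNP position (bp, same chromosome as `sv_pos`).
#' @param sv_pos structural-variant window positions (bp).
#' @param sv_p their association p-values.
#' @param threshold_p p-value cutoff counted as significant (the secondary
#'   threshold on the p scale).
#' @param n_blocks number of equal blocks (default 10, i.e. 200-kb blocks).
#' @param flank_bp half-span around the SNP (default 1 Mb).
#' @return list with `counts` per block, `snp_block`, `rank` of the SNP
#'   block (1 = most significant counts; ties share the minimum rank) and
#'   `quantile` (fraction of blocks with counts <= the SNP block's).
#' @export
leading_snp_block_test <- function(snp_pos, sv_pos, sv_p, threshold_p,
                                   n_blocks = 10, flank_bp = 1e6) {
  lo <- snp_pos - flank_bp
  hi <- snp_pos + flank_bp
  inside <- sv_pos >= lo & sv_pos < hi
  if (!any(inside)) stop("no structural-variant p-value within range")
  breaks <- seq(lo, hi, length.out = n_blocks + 1)
  blk <- findInterval(sv_pos[inside], breaks, rightmost.closed = TRUE)
  sig <- sv_p[inside] < threshold_p
  counts <- vapply(seq_len(n_blocks), function(b) sum(sig[blk == b]),
                   integer(1))
  snp_block <- findInterval(snp_pos, breaks, rightmost.closed = TRUE)
  rk <- rank(-counts, ties.method = "min")[snp_block]
  list(counts = counts, snp_block = snp_block, rank = rk,
       quantile = mean(counts <= counts[snp_block]))
}
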