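# From per-window credible CN calls to merged CNV events: dup/del window
# definitions, event merging, duplication genotype-interval classification,
# GMM deletion re-genotyping, gene overlap and gain-clustering statistics.

gr_of <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L,
                                          end = df$end))
}

#' Classify windows as duplication / deletion / diploid
#'
#' A window is a duplication if at least one sample's credible CN interval
#' lies entirely above 2, a deletion if at least one lies entirely below 2;
#' a window can be both. Intervals overlapping 2 are treated as diploid.
#'
#' @param calls a `cn_calls` object from [genotype_cohort()].
#' @return data frame, one row per grid window: `chrom`, `start`, `end`,
#'   `dup`, `del`, `status` in `{dup, del, both, diploid}`.
#' @export
call_dup_del_windows <- function(calls) {
  dup <- apply(calls$cred_low > 2, 2, any)
  del <- apply(calls$cred_high < 2, 2, any)
  status <- ifelse(dup & del, "both",
                   ifelse(dup, "dup", ifelse(del, "del", "diploid")))
  data.frame(chrom = calls$grid$chrom, start = calls$grid$start,
             end = calls$grid$end, dup = dup, del = del, status = status,
             stringsAsFactors = FALSE)
}

#' Merge same-type windows into CNV events
#'
#' Maximal runs of duplication (or deletion) windows adjacent in grid order
#' are merged into events; adjacency is grid order within a chromosome, so
#' masked gaps between consecutive windows do not break a run. Windows
#' flagged both dup and del enter both event sets, yielding overlapping
#' events of different types. Events smaller than `min_size_bp` are
#' dropped (the event-size floor of 1 kb keeps single full windows).
#'
#' @param statuses output of [call_dup_del_windows()].
#' @param grid the [window_grid()].
#' @param min_size_bp minimum event span in bp.
#' @param calls optional `cn_calls`; when given, a per-sample genotype
#'   matrix (median MAP CN over the event span) and carrier frequency are
#'   attached.
#' @return data frame of events: `event_id`, `chrom`, `start`, `end`,
#'   `type`, `n_windows`, `windows` (list column of grid row indices) and,
#'   with `calls`, `carrier_freq`; genotypes in `attr(, "genotypes")`.
#' @export
merge_events <- function(statuses, grid, min_size_bp = 1000, calls = NULL) {
  stopifnot(nrow(statuses) == nrow(grid))
  one_type <- function(flag, type) {
    runs <- rle(paste0(grid$chrom, "|", flag))
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- grepl("\\|TRUE$", runs$values)
    out <- lapply(which(keep), function(k) {
      idx <- starts[k]:ends[k]
      data.frame(chrom = grid$chrom[idx[1]], start = grid$start[idx[1]],
                 end = grid$end[idx[length(idx)]], type = type,
                 n_windows = length(idx), stringsAsFactors = FALSE)
    })
    wins <- lapply(which(keep), function(k) starts[k]:ends[k])
    list(df = do.call(rbind, out), windows = wins)
  }
  gains <- one_type(statuses$dup, "gain")
  losses <- one_type(statuses$del, "loss")
  ev <- rbind(gains$df, losses$df)
  wins <- c(gains$windows, losses$windows)
  if (is.null(ev) || !nrow(ev))
    return(data.frame(event_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      type = character(0), n_windows = integer(0)))
  keep <- ev$end - ev$start >= min_size_bp
  ev <- ev[keep, , drop = FALSE]
  wins <- wins[keep]
  ord <- order(ev$chrom, ev$start, ev$type)
  ev <- ev[ord, , drop = FALSE]
  wins <- wins[ord]
  ev$event_id <- paste0("cnv_", seq_len(nrow(ev)))
  ev$windows <- wins
  rownames(ev) <- NULL
  if (!is.null(calls)) {
    geno <- vapply(wins, function(idx) {
      as.integer(round(apply(calls$map_cn[, idx, drop = FALSE], 1,
                             stats::median)))
    }, integer(length(calls$sample_ids)))
    rownames(geno) <- calls$sample_ids
    colnames(geno) <- ev$event_id
    ev$carrier_freq <- colMeans(geno != 2L)
    attr(ev, "genotypes") <- geno
  }
  ev[, c("event_id", setdiff(names(ev), "event_id"))]
}

# inclusive integer-interval helpers for CN credible ranges
iv_len <- function(iv) iv[2] - iv[1] + 1
iv_jaccard <- function(a, b) {
  inter <- min(a[2], b[2]) - max(a[1], b[1]) + 1
  if (inter <= 0) return(0)
  inter / (iv_len(a) + iv_len(b) - inter)
}

#' Classify credible CN intervals at a duplicated window into categories
#'
#' Ranged genotypes resist clustering, so each duplicated window's credible
#' intervals are reduced to a small set of disjoint CN categories: the
#' modal interval and the interval(s) most distant from it seed the
#' categories, remaining ranges are assigned to the category they overlap
#' most (Jaccard), and ranges overlapping no category spawn intermediate
#' categories. Iteration runs to a fixed point (the procedure is idempotent
#' on its own output).
#'
#' @param intervals integer matrix n x 2 of credible `(low, high)` bounds,
#'   one row per sample.
#' @param max_iter iteration cap (convergence reported).
#' @return list with `categories` (data frame `low`, `high`), `assignment`
#'   (category index per sample) and `converged`.
#' @export
classify_duplication_intervals <- function(intervals, max_iter = 50) {
  intervals <- as.matrix(intervals)
  if (!nrow(intervals)) stop("no intervals to classify")
  if (!any(intervals[, 1] > 2))
    stop("no duplication carrier at this window")
  keyf <- paste(intervals[, 1], intervals[, 2])
  tab <- sort(table(keyf), decreasing = TRUE)
  top <- names(tab[tab == tab[1]])
  cand <- do.call(rbind, lapply(strsplit(top, " "), as.integer))
  mid <- rowMeans(cand)
  modal <- cand[order(abs(mid - 2), cand[, 1])[1], ]    # tie: nearest CN 2
  mmid <- mean(modal)

  cats <- list(modal)
  # seed: most distant interval(s) not overlapping the modal one
  dist_mid <- abs(rowMeans(intervals) - mmid)
  nonov <- apply(intervals, 1, function(r) iv_jaccard(r, modal) == 0)
  if (any(nonov)) {
    far <- which(nonov & dist_mid == max(dist_mid[nonov]))
    for (f in far) {
      new <- intervals[f, ]
      if (all(vapply(cats, function(c) iv_jaccard(new, c) == 0, logical(1))))
        cats[[length(cats) + 1]] <- new
    }
  }
  assignment <- rep(NA_integer_, nrow(intervals))
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    prev <- assignment
    for (i in seq_len(nrow(intervals))) {
      j <- vapply(cats, function(c) iv_jaccard(intervals[i, ], c),
                  numeric(1))
      if (max(j) > 0) {
        assignment[i] <- which.max(j)
      } else {   # spawns an intermediate, disjoint category
        cats[[length(cats) + 1]] <- intervals[i, ]
        assignment[i] <- length(cats)
      }
    }
    if (identical(assignment, prev)) { converged <- TRUE; break }
  }
  ord <- order(vapply(cats, `[`, numeric(1), 1))
  cats <- cats[ord]
  assignment <- match(assignment, ord)
  list(categories = data.frame(low = vapply(cats, `[`, numeric(1), 1),
                               high = vapply(cats, `[`, numeric(1), 2)),
       assignment = assignment, converged = converged)
}

#' Re-genotype a deletion window with a fixed-means Gaussian mixture
#'
#' Fits, by EM over the mixture weights only, a three-component Gaussian
#' mixture with fixed means 0, 1, 2 and fixed per-sample spreads
#' `sd(CN=2)/2`, `sd(CN=2)/2`, `sd(CN=2)` (the stated component scales are
#' read as standard deviations, matching the emission-model scale). The
#' cohort-averaged component probabilities act as the prior that updates
#' each sample through Bayes' rule; the most likely genotype is emitted.
#'
#' @param cr copy ratios of all samples at one deletion window.
#' @param sigma_cr per-sample diploid dispersion (recycled if scalar).
#' @param max_iter,tol EM controls; non-convergence after `max_iter` is
#'   flagged and the last iterate returned.
#' @return list with `genotype` (integer 0/1/2 per sample), `weights`
#'   (mixture weights, sum 1), `responsibilities`, `converged`, `n_iter`.
#' @export
recall_deletions_gmm <- function(cr, sigma_cr, max_iter = 500, tol = 1e-8) {
  n <- length(cr)
  if (n < 10) stop("need at least 10 samples, got ", n)
  sigma_cr <- rep_len(sigma_cr, n)
  sds <- cbind(sigma_cr / 2, sigma_cr / 2, sigma_cr)
  dens <- vapply(1:3, function(j)
    stats::dnorm(cr, mean = j - 1, sd = sds[, j]), numeric(n))
  dens <- pmax(dens, 1e-300)
  w <- rep(1 / 3, 3)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    num <- sweep(dens, 2, w, `*`)
    resp <- num / rowSums(num)
    w_new <- colMeans(resp)
    if (max(abs(w_new - w)) < tol) { w <- w_new; converged <- TRUE; break }
    w <- w_new
  }
  num <- sweep(dens, 2, w, `*`)
  resp <- num / rowSums(num)
  list(genotype = max.col(resp) - 1L, weights = w,
       responsibilities = resp, converged = converged, n_iter = iter)
}

#' Gene overlap report for CNV events
#'
#' @param events event data frame ([merge_events()]).
#' @param genes data frame `chrom`, `start`, `end`, `name` (0-based
#'   half-open, sorted).
#' @return data frame of event x gene overlaps with `overlap_bp`,
#'   `gene_frac` (fraction of the gene covered), `partial` (>= 5% of the
#'   gene) and `full` (entire gene contained).
#' @export
gene_overlap <- function(events, genes) {
  if (!nrow(events) || !nrow(genes))
    return(data.frame(event_id = character(0), gene = character(0),
                      overlap_bp = integer(0), gene_frac = numeric(0),
                      partial = logical(0), full = logical(0)))
  ge <- gr_of(genes); eve <- gr_of(events)
  hits <- GenomicRanges::findOverlaps(eve, ge)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::pintersect(eve[qi], ge[si])
  obp <- BiocGenerics::width(ov)
  gl <- genes$end[si] - genes$start[si]
  frac <- obp / gl
  data.frame(event_id = events$event_id[qi], gene = genes$name[si],
             overlap_bp = obp, gene_frac = frac,
             partial = frac >= 0.05, full = obp == gl,
             stringsAsFactors = FALSE)
}

#' Test whether events of one type cluster along chromosomes
#'
#' Per chromosome with at least two events, the observed mean
#' nearest-neighbour distance between event midpoints (in window units) is
#' compared against uniform random placement of equally sized events on the
#' chromosome's window space (one-sided permutation p, small distances =
#' clustering). Per-chromosome p-values are aggregated by Fisher's method,
#' `chi2 = -2 sum log p` on `2k` degrees of freedom.
#'
#' @param events events of a single type.
#' @param grid the [window_grid()].
#' @param n_permutations permutation count per chromosome.
#' @param seed RNG seed.
#' @return list with `per_chromosome` (data frame `chrom`, `n_events`, `p`)
#'   and `fisher_p`.
#' @export
event_clustering_test <- function(events, grid, n_permutations = 999,
                                  seed = 1) {
  set.seed(seed)
  mean_nn <- function(mid) {
    d <- as.matrix(stats::dist(mid))
    diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  rows <- list()
  for (ch in unique(events$chrom)) {
    sub <- events[events$chrom == ch, , drop = FALSE]
    if (nrow(sub) < 2) next
    W <- sum(grid$chrom == ch)
    wsize <- grid_window_size(grid)
    sizes <- sub$n_windows
    mids <- (sub$start + sub$end) / 2 / wsize
    obs <- mean_nn(mids)
    perm <- replicate(n_permutations, {
      st <- stats::runif(length(sizes), 0, W - sizes)
      mean_nn(st + sizes / 2)
    })
    p <- (1 + sum(perm <= obs)) / (n_permutations + 1)
    rows[[length(rows) + 1]] <-
      data.frame(chrom = ch, n_events = nrow(sub), p = p,
                 stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("fewer than 2 events on every chromosome")
  per <- do.call(rbind, rows)
  chi2 <- -2 * sum(log(per$p))
  list(per_chromosome = per,
       fisher_p = stats::pchisq(chi2, df = 2 * nrow(per),
                                lower.tail = FALSE))
}
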