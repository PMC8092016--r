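# Population structure over copy-number genotypes: V_ST differentiation
# scans with subsampling, balanced-basis PCA with projection, Euclidean
# CN phylogenies, indicator-matrix topology collapse and comparison, and
# shared-haplotype-corrected distances.

#' Pairwise V_ST between two groups of copy numbers
#'
#' Variance-partitioning differentiation statistic (an F_ST analogue for
#' copy number):
#' `V_ST = 1 - (n1*Var(x1) + n2*Var(x2)) / ((n1+n2)*Var(c(x1,x2)))`,
#' with sample variances (n-1 denominator). Values are at most 1 and equal
#' 1 exactly when both within-group variances vanish but the groups
#' differ; negative values are retained so medians over subsamples stay
#' unbiased.
#'
#' @param x1,x2 numeric copy-number vectors (each of length >= 2).
#' @return the V_ST value; 0 when the pooled variance is 0.
#' @export
vst_pair <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 2 || n2 < 2)
    stop("each group needs at least 2 samples, got ", n1, " and ", n2)
  vp <- stats::var(c(x1, x2))
  if (vp == 0) return(0)
  1 - (n1 * stats::var(x1) + n2 * stats::var(x2)) / ((n1 + n2) * vp)
}

# per-column sample variance of a matrix (n-1 denominator)
col_vars <- function(m) {
  n <- nrow(m)
  (colSums(m^2) - n * colMeans(m)^2) / (n - 1)
}

vst_columns <- function(m1, m2) {
  n1 <- nrow(m1); n2 <- nrow(m2)
  vp <- col_vars(rbind(m1, m2))
  num <- n1 * col_vars(m1) + n2 * col_vars(m2)
  out <- 1 - num / ((n1 + n2) * vp)
  out[vp == 0] <- 0
  out
}

#' Subsampled V_ST scan over windows and clade pairs
#'
#' Small groups bias the genomic V_ST distribution, so every clade is
#' subsampled to `k` individuals `reps` times and the median V_ST is kept
#' per window and clade pair. Only clades with at least `k` samples are
#' eligible; a pair where both clades have exactly `k` samples admits no
#' subsampling freedom and is evaluated once, deterministically.
#'
#' @param cn numeric matrix samples x windows (integer MAP copy numbers).
#' @param panel a [breed_panel()] covering the rows of `cn`.
#' @param windows integer indices of windows to scan (default: all).
#' @param k subsample size (default 6).
#' @param reps number of subsampling replicates (default 1000).
#' @param seed RNG seed.
#' @return data frame: `window`, `clade1`, `clade2`, `vst`, `n1`, `n2`,
#'   `subsampled`, `n_replicates`.
#' @export
vst_subsampled_scan <- function(cn, panel, windows = NULL, k = 6,
                                reps = 1000, seed = 1) {
  set.seed(seed)
  if (is.null(windows)) windows <- seq_len(ncol(cn))
  clade_of <- stats::setNames(panel$clade, panel$sample_id)
  members <- split(rownames(cn), clade_of[rownames(cn)])
  members <- members[vapply(members, length, integer(1)) >= k]
  if (length(members) < 2)
    stop("need at least two clades with >= ", k, " samples")
  pairs <- utils::combn(names(members), 2)
  out <- list()
  for (pp in seq_len(ncol(pairs))) {
    c1 <- pairs[1, pp]; c2 <- pairs[2, pp]
    m1 <- cn[members[[c1]], windows, drop = FALSE]
    m2 <- cn[members[[c2]], windows, drop = FALSE]
    fixed <- nrow(m1) == k && nrow(m2) == k
    if (fixed) {
      v <- vst_columns(m1, m2)
      nrep <- 1L
    } else {
      draws <- vapply(seq_len(reps), function(r) {
        vst_columns(m1[sample(nrow(m1), k), , drop = FALSE],
                    m2[sample(nrow(m2), k), , drop = FALSE])
      }, numeric(length(windows)))
      v <- apply(matrix(draws, nrow = length(windows)), 1, stats::median)
      nrep <- reps
    }
    out[[pp]] <- data.frame(window = windows, clade1 = c1, clade2 = c2,
                            vst = v, n1 = nrow(m1), n2 = nrow(m2),
                            subsampled = !fixed, n_replicates = nrep,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Balanced-basis PCA of the copy-number matrix
#'
#' A common PCA basis is built from a random clade-balanced subset
#' (`per_clade_k` samples per clade) so that over-represented clades do not
#' dominate the axes; all other samples are projected into the basis with
#' the stored centering, scaling and rotation. Zero-variance windows
#' within the basis subset are dropped (recorded in the result).
#'
#' @param cn numeric matrix samples x windows.
#' @param panel a [breed_panel()].
#' @param per_clade_k samples drawn per clade (must not exceed the
#'   smallest clade).
#' @param seed RNG seed for the balanced draw.
#' @return a `pca_basis`: list with `center`, `scale`, `rotation`,
#'   `keep_windows`, `basis_samples`, `sdev` and `scores` (basis-sample
#'   scores).
#' @export
pca_balanced <- function(cn, panel, per_clade_k = 4, seed = 1) {
  set.seed(seed)
  clade_of <- stats::setNames(panel$clade, panel$sample_id)
  members <- split(rownames(cn), clade_of[rownames(cn)])
  small <- vapply(members, length, integer(1)) < per_clade_k
  if (any(small))
    stop("per_clade_k exceeds clade size: ", names(members)[small][1])
  basis_samples <- unlist(lapply(members, sample, size = per_clade_k),
                          use.names = FALSE)
  if (length(basis_samples) < 2) stop("fewer than 2 basis samples")
  sub <- cn[basis_samples, , drop = FALSE]
  keep <- which(col_vars(sub) > 0)
  if (!length(keep)) stop("no window varies within the basis subset")
  pc <- stats::prcomp(sub[, keep, drop = FALSE], center = TRUE,
                      scale. = TRUE)
  structure(list(center = pc$center, scale = pc$scale,
                 rotation = pc$rotation, keep_windows = keep,
                 basis_samples = basis_samples, sdev = pc$sdev,
                 scores = pc$x),
            class = "pca_basis")
}

#' Project samples into a common PCA basis
#'
#' Applies the basis's centering, scaling and rotation; projecting the
#' basis samples themselves reproduces their basis scores.
#'
#' @param cn numeric matrix samples x windows (full grid; the basis
#'   selects its retained windows).
#' @param basis a `pca_basis` from [pca_balanced()].
#' @return score matrix samples x components.
#' @export
pca_project <- function(cn, basis) {
  x <- cn[, basis$keep_windows, drop = FALSE]
  x <- sweep(x, 2, basis$center, `-`)
  x <- sweep(x, 2, basis$scale, `/`)
  x %*% basis$rotation
}

#' Euclidean distance matrix over copy numbers
#'
#' @param cn numeric matrix samples x windows; no missing values.
#' @param windows optional window subset.
#' @return symmetric distance matrix with sample labels and zero diagonal.
#' @export
distance_matrix <- function(cn, windows = NULL) {
  if (anyNA(cn)) stop("missing CN entries; impute before distances")
  if (!is.null(windows)) cn <- cn[, windows, drop = FALSE]
  as.matrix(stats::dist(cn))
}

#' Build a tree from a distance matrix
#'
#' Neighbour-joining by default (unrooted, additive-consistent); UPGMA as
#' an alternative.
#'
#' @param D symmetric distance matrix with labels.
#' @param method `"nj"` or `"upgma"`.
#' @return an [ape::nj()] `phylo` object.
#' @export
build_tree <- function(D, method = c("nj", "upgma")) {
  method <- match.arg(method)
  if (nrow(D) < 3) stop("need at least 3 samples for a tree")
  if (method == "nj") ape::nj(stats::as.dist(D))
  else ape::as.phylo(stats::hclust(stats::as.dist(D), method = "average"))
}

#' Breed indicator matrix
#'
#' @param samples ordered sample labels (rows of the distance matrix).
#' @param panel a [breed_panel()].
#' @return binary matrix samples x breeds, exactly one 1 per row.
#' @export
breed_indicator <- function(samples, panel) {
  breed_of <- stats::setNames(panel$breed, panel$sample_id)
  b <- breed_of[samples]
  breeds <- unique(b)
  B <- outer(b, breeds, `==`) * 1
  dimnames(B) <- list(samples, breeds)
  B
}

#' Collapse a sample distance matrix to breed level
#'
#' Projects the distance matrix onto the column space of the breed
#' indicator matrix, `B (B'B)^-1 B' D` (replacing each row by its breed
#' mean), then averages columns within breeds, symmetrizes by
#' `(A + A')/2` and zeroes the diagonal. The result is a synthetic
#' breed-level distance matrix that retains the topology of the original
#' and is comparable across cohorts under common scaling. The operation is
#' idempotent on breed-constant matrices and invariant to sample order.
#'
#' @param D sample distance matrix.
#' @param B breed indicator matrix ([breed_indicator()]) with rows matching
#'   `D`'s labels.
#' @return breed x breed symmetric matrix, zero diagonal.
#' @export
breed_collapse_projection <- function(D, B) {
  if (!identical(rownames(D), rownames(B)))
    stop("indicator rows must match distance labels")
  sizes <- colSums(B)
  if (any(sizes == 0)) stop("empty breed column: ",
                            colnames(B)[sizes == 0][1])
  BtB_inv <- diag(1 / sizes, ncol(B))
  A <- BtB_inv %*% t(B) %*% D %*% B %*% BtB_inv   # breed-block means
  A <- (A + t(A)) / 2
  diag(A) <- 0
  dimnames(A) <- list(colnames(B), colnames(B))
  A
}

#' Compare two breed-level distance matrices
#'
#' Pearson correlation over the upper off-diagonal entries, and the
#' Frobenius norm of the difference after each matrix is scaled to unit
#' Frobenius norm (so the comparison is scale-free: `compare(M, 3M)` gives
#' r = 1, norm = 0).
#'
#' @param M1,M2 breed distance matrices over the same label set.
#' @return list with `pearson_r` and `two_norm`.
#' @export
compare_topologies <- function(M1, M2) {
  if (!setequal(rownames(M1), rownames(M2)))
    stop("breed label sets differ")
  M2 <- M2[rownames(M1), rownames(M1)]
  up <- upper.tri(M1)
  fnorm <- function(m) sqrt(sum(m^2))
  list(pearson_r = stats::cor(M1[up], M2[up]),
       two_norm = fnorm(M1 / fnorm(M1) - M2 / fnorm(M2)))
}

#' Distances over the deletion space excluding shared haplotypes
#'
#' Windows overlapping pairwise-shared haplotype intervals are removed from
#' the deletion space and distances are recomputed over the remaining
#' windows; squared distances are rescaled by the fraction of windows
#' retained (`W_total / W_retained`) to correct for the subtracted
#' positions.
#'
#' @param cn numeric matrix samples x windows.
#' @param del_windows indices of deletion windows (the working space).
#' @param shared data frame `chrom`, `start`, `end` of shared-haplotype
#'   intervals (0-based half-open, grid coordinates).
#' @param grid the [window_grid()].
#' @return corrected sample distance matrix.
#' @export
exclude_shared_haplotypes <- function(cn, del_windows, shared, grid) {
  if (!length(del_windows)) stop("empty deletion space")
  if (nrow(shared)) {
    gw <- gr_of(grid[del_windows, , drop = FALSE])
    hit <- IRanges::overlapsAny(gw, gr_of(shared))
    retained <- del_windows[!hit]
  } else retained <- del_windows
  if (!length(retained)) stop("all deletion windows removed")
  d2 <- as.matrix(stats::dist(cn[, retained, drop = FALSE]))^2
  d2 <- d2 * (length(del_windows) / length(retained))
  sqrt(d2)
}
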