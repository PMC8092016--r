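# Sample-level quality control on control-region copy ratios.
#
# Three per-sample criteria, each computed on the presumed-diploid control
# windows only: departure of the copy-ratio distribution from a Gaussian
# (Kolmogorov distance against a moment-fitted normal), a hard cap on the
# copy-ratio standard deviation, and lag-1 autocorrelation between
# neighbouring control windows. QC is per-sample, so permuting sample rows
# permutes the report identically.

#' Kolmogorov distance from a fitted Gaussian
#'
#' Sup distance between the empirical CDF of the control-region copy ratios
#' and a normal distribution fitted by moments (sample mean and standard
#' deviation). Large distances signal a non-Gaussian shape, e.g. bimodality
#' from faulty normalization.
#'
#' @param cr_control numeric vector of control-window copy ratios (>= 50).
#' @return the Kolmogorov distance in `[0, 1]`.
#' @export
ks_gaussian_distance <- function(cr_control) {
  if (length(cr_control) < 50)
    stop("need at least 50 control values, got ", length(cr_control))
  m <- mean(cr_control)
  s <- stats::sd(cr_control)
  if (s == 0) stop("degenerate control distribution: sd = 0")
  x <- sort(cr_control)
  n <- length(x)
  theo <- stats::pnorm(x, m, s)
  # sup over both one-sided gaps of the step-function ECDF
  max(pmax(seq_len(n) / n - theo, theo - (seq_len(n) - 1) / n))
}

#' Hard threshold on control-region copy-ratio standard deviation
#'
#' @param cr_control numeric vector of control-window copy ratios.
#' @param threshold maximum admissible standard deviation (default 0.45).
#' @return `TRUE` if the sample passes (sd <= threshold).
#' @export
cr_sd_filter <- function(cr_control, threshold = 0.45) {
  if (!length(cr_control)) stop("empty control vector")
  stats::sd(cr_control) <= threshold
}

#' Lag-1 neighbour autocorrelation of control copy ratios
#'
#' Pearson coefficient between copy ratios at adjacent control windows.
#' Pairs are restricted to windows adjacent in grid order on the same
#' chromosome with no non-control window between them; an excess of
#' correlation indicates non-independent windows.
#'
#' @param cr_control copy ratios in grid order (control windows only).
#' @param chrom optional chromosome label per value; pairs never straddle a
#'   label change.
#' @param index optional grid window index per value; pairs are kept only
#'   where indices are consecutive (control-mask gaps break pairs).
#' @return Pearson lag-1 coefficient, or `NA` if variance is zero.
#' @export
neighbor_autocorrelation <- function(cr_control, chrom = NULL, index = NULL) {
  n <- length(cr_control)
  if (n < 3) stop("need at least 3 consecutive control windows")
  keep <- rep(TRUE, n - 1)
  if (!is.null(chrom)) keep <- keep & chrom[-n] == chrom[-1]
  if (!is.null(index)) keep <- keep & diff(index) == 1
  x <- cr_control[-n][keep]
  y <- cr_control[-1][keep]
  if (length(x) < 2) stop("fewer than 2 adjacent control pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Apply sample quality control
#'
#' Runs all three criteria on every sample's control-region copy ratios and
#' removes samples failing any of them.
#'
#' @param mat a [cr_matrix()] with a control mask on its grid.
#' @param max_sd cap on control copy-ratio standard deviation.
#' @param max_ks cap on the Kolmogorov distance.
#' @param max_autocor cap on `|lag-1 autocorrelation|`.
#' @return A list with `report` (data frame: sample_id, ks_distance, cr_sd,
#'   neighbor_r, pass, reasons) and `matrix` (the filtered [cr_matrix()]).
#' @export
apply_qc <- function(mat, max_sd = 0.45, max_ks = 0.1, max_autocor = 0.3) {
  grid <- mat$grid
  ctrl <- which(grid$control)
  if (length(ctrl) < 50)
    stop("need at least 50 control windows, got ", length(ctrl))
  rep_rows <- lapply(mat$sample_ids, function(id) {
    v <- mat$values[id, ctrl]
    ks <- ks_gaussian_distance(v)
    sdv <- stats::sd(v)
    r <- neighbor_autocorrelation(v, chrom = grid$chrom[ctrl],
                                  index = grid$window_index[ctrl])
    reasons <- c(
      if (ks > max_ks) sprintf("ks_distance %.3f > %.3f", ks, max_ks),
      if (sdv > max_sd) sprintf("cr_sd %.3f > %.3f", sdv, max_sd),
      if (!is.na(r) && abs(r) > max_autocor)
        sprintf("neighbor_r %.3f beyond %.3f", r, max_autocor))
    data.frame(sample_id = id, ks_distance = ks, cr_sd = sdv,
               neighbor_r = r, pass = length(reasons) == 0,
               reasons = paste(reasons, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rep_rows)
  keep <- report$sample_id[report$pass]
  if (!length(keep)) stop("all samples fail quality control")
  filtered <- cr_matrix(mat$values[keep, , drop = FALSE], grid,
                        sample_ids = keep)
  list(report = report, matrix = filtered)
}
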