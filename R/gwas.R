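# Window-wise CNV association against breed-standard phenotypes.
#
# Categorical (or split continuous) traits use a generalized
# Cochran-Mantel-Haenszel correlation statistic with integer scores, which
# honours the ordinal nature of both copy number and grouped phenotype and
# admits stratification into subpopulations. Continuous traits use linear
# regression with the first principal components of the scaled copy-number
# matrix as stratification covariates. Two Bonferroni-style thresholds are
# reported: the primary divides alpha = 0.05 by the number of CNV windows
# tested; the secondary sits one order of magnitude below it, acknowledging
# that successive windows of one event are not independent tests.

#' Split breed trait values into top-70 / bottom-30 groups
#'
#' @param values named numeric vector of per-breed trait values (>= 10
#'   breeds).
#' @return list with `bottom` and `top` breed name vectors; breeds at or
#'   below the 30th percentile go to the bottom group (boundary ties fall
#'   to the bottom).
#' @export
split_percentiles <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 10)
    stop("need at least 10 breeds with values, got ", length(values))
  if (stats::sd(values) == 0) stop("constant trait cannot be split")
  cut <- stats::quantile(values, 0.3, names = FALSE)
  list(bottom = names(values)[values <= cut],
       top = names(values)[values > cut])
}

#' Generalized Cochran-Mantel-Haenszel correlation test
#'
#' The Landis correlation-type statistic with integer scores (ordinal CN
#' category and binary group code), summed over strata:
#' `M^2 = (sum_h T_h)^2 / sum_h Var_h` with
#' `T_h = sum u v - (sum u)(sum v)/n_h` and
#' `Var_h = SS_u SS_v / (n_h - 1)`, on 1 degree of freedom. With a single
#' stratum this reduces exactly to `(n - 1) r^2`. Strata without variation
#' in either score contribute nothing and are dropped.
#'
#' @param cn ordinal copy-number scores per sample.
#' @param group binary group membership per sample (two levels).
#' @param strata optional stratum label per sample (default: one stratum).
#' @return list with `statistic`, `p_value`, `df` (= 1) and `strata_used`.
#' @export
gen_cmh_test <- function(cn, group, strata = NULL) {
  if (is.null(strata)) strata <- rep(1L, length(cn))
  g <- as.integer(factor(group)) - 1L
  if (length(unique(g)) < 2) stop("all samples in one group")
  if (length(unique(cn)) < 2) stop("fewer than 2 CN categories")
  u <- as.numeric(cn)
  Tsum <- 0; Vsum <- 0; used <- 0L
  for (h in unique(strata)) {
    i <- strata == h
    nh <- sum(i)
    if (nh < 2) next
    uh <- u[i]; vh <- g[i]
    ssu <- sum(uh^2) - sum(uh)^2 / nh
    ssv <- sum(vh^2) - sum(vh)^2 / nh
    if (ssu == 0 || ssv == 0) next
    Tsum <- Tsum + sum(uh * vh) - sum(uh) * sum(vh) / nh
    Vsum <- Vsum + ssu * ssv / (nh - 1)
    used <- used + 1L
  }
  if (used == 0) stop("no informative stratum")
  stat <- Tsum^2 / Vsum
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L, strata_used = used)
}

#' Linear-regression association with PC covariates
#'
#' Two-sided t-test on the copy-number coefficient of
#' `trait ~ intercept + CN + PC1..PCk`.
#'
#' @param trait continuous trait per sample.
#' @param cn copy number per sample.
#' @param pcs optional covariate matrix (columns = principal components).
#' @return list with `beta`, `se`, `p_value`, `df`. A p-value that
#'   underflows is reported at the smallest positive double.
#' @export
linreg_assoc <- function(trait, cn, pcs = NULL) {
  X <- cbind(1, cn, pcs)
  n <- length(trait)
  if (n <= ncol(X) + 1)
    stop("need n > covariates + 2, got n = ", n)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X))
    stop("collinear CN/covariates: rank ", qr_x$rank, " < ", ncol(X))
  fit <- qr.coef(qr_x, trait)
  res <- trait - X %*% fit
  df <- n - ncol(X)
  s2 <- sum(res^2) / df
  XtX_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(s2 * XtX_inv[2, 2])
  tval <- fit[2] / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  list(beta = unname(fit[2]), se = se,
       p_value = max(p, .Machine$double.xmin), df = df)
}

#' Dual significance thresholds
#'
#' Primary: Bonferroni over the number of CNV windows tested,
#' `-log10(0.05 / n)`. Secondary: one order of magnitude more permissive,
#' `primary - 1`, acknowledging the non-independence of successive windows
#' within one event.
#'
#' @param n_windows_tested number of windows tested (>= 1).
#' @return list with `primary` and `secondary`, both on the -log10 scale.
#' @export
compute_thresholds <- function(n_windows_tested) {
  if (n_windows_tested < 1) stop("n_windows_tested must be >= 1")
  primary <- -log10(0.05 / n_windows_tested)
  list(primary = primary, secondary = primary - 1)
}

#' Genomic inflation factor
#'
#' `lambda = median(qchisq(p, df = 1, lower = FALSE)) / 0.45494...`; values
#' well above 1 signal population stratification and trigger the
#' stratified or covariate-adjusted re-test.
#'
#' @param p_values vector of p-values (>= 100).
#' @return lambda.
#' @export
inflation_factor <- function(p_values) {
  if (length(p_values) < 100)
    stop("need at least 100 tests, got ", length(p_values))
  if (any(!is.finite(p_values))) stop("non-finite p-values")
  chis <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chis) / stats::qchisq(0.5, df = 1)
}

#' Select case and control breeds for a disease cohort
#'
#' Breeds below a minimum prevalence (one affected in 2000 by default) are
#' excluded from case eligibility; the highest-risk eligible breeds become
#' cases and the lowest-risk breeds controls.
#'
#' @param prevalence named per-breed disease prevalence in `[0, 1]`.
#' @param min_prev case-eligibility floor (default 0.0005).
#' @param case_q top quantile of eligible breeds taken as cases.
#' @param control_q bottom quantile taken as controls.
#' @param min_cases warn when fewer case breeds than this are selected
#'   (default 21).
#' @return list with `cases` and `controls` (disjoint breed name vectors).
#' @export
select_disease_cohorts <- function(prevalence, min_prev = 0.0005,
                                   case_q = 0.25, control_q = 0.25,
                                   min_cases = 21) {
  if (any(prevalence < 0 | prevalence > 1))
    stop("prevalences must lie in [0, 1]")
  eligible <- prevalence[prevalence >= min_prev]
  if (!length(eligible)) stop("no breed reaches the prevalence floor")
  case_cut <- stats::quantile(eligible, 1 - case_q, names = FALSE)
  cases <- names(eligible)[eligible >= case_cut]
  ctrl_cut <- stats::quantile(prevalence, control_q, names = FALSE)
  controls <- setdiff(names(prevalence)[prevalence <= ctrl_cut], cases)
  if (!length(controls)) stop("empty control set")
  if (length(cases) < min_cases)
    warning("only ", length(cases), " case breeds selected; ",
            min_cases, " is the recommended floor")
  list(cases = cases, controls = controls)
}

# two similarly sized substrata from the CNV tree: pick the bipartition of
# the NJ tree whose tip split is closest to half/half
tree_substrata <- function(cn, panel) {
  samples <- rownames(cn)
  D <- distance_matrix(cn)
  B <- breed_indicator(samples, panel)
  Db <- breed_collapse_projection(D, B)
  breeds <- rownames(Db)
  if (length(breeds) < 4) {   # too few breeds for a meaningful tree cut
    half <- breeds[seq_len(length(breeds) %/% 2)]
  } else {
    tr <- build_tree(Db)
    n <- length(tr$tip.label)
    internal <- setdiff(unique(tr$edge[, 2]), seq_len(n))
    best <- NULL; best_gap <- Inf
    for (node in internal) {
      tips <- ape::extract.clade(tr, node)$tip.label
      gap <- abs(length(tips) - n / 2)
      if (gap < best_gap) { best_gap <- gap; best <- tips }
    }
    half <- best
  }
  breed_of <- stats::setNames(panel$breed, panel$sample_id)
  ifelse(breed_of[samples] %in% half, "stratum1", "stratum2")
}

#' Run a copy-number GWAS for one trait
#'
#' Restricted to the duplication/deletion window space. Continuous traits
#' are tested by [linreg_assoc()] with the first `n_pcs` principal
#' components of the scaled copy-number matrix as covariates. Categorical
#' traits (and continuous traits under `test = "cmh"`, after a 70/30
#' split) are tested by [gen_cmh_test()]; stratification into two
#' similarly sized breed-tree substrata is applied only when the genomic
#' inflation factor of the unstratified scan exceeds `lambda_trigger`.
#'
#' @param cn integer copy-number matrix samples x windows (MAP calls).
#' @param panel a [breed_panel()] covering the samples.
#' @param phenotypes a [phenotype_table()].
#' @param trait trait name in the phenotype table.
#' @param variant_windows indices of dup/del windows to test.
#' @param test `"auto"` (by trait type), `"cmh"` or `"linreg"`.
#' @param n_pcs PC covariates for the regression test (default 4).
#' @param lambda_trigger inflation threshold for stratifying the CMH scan.
#' @param strata optional per-sample stratum assignment overriding the
#'   breed-tree substrata.
#' @param grid optional [window_grid()]; when supplied, `chrom` and
#'   `start` columns are added for Manhattan-plot-ready output.
#' @return data frame per tested window: `window`, `chrom`, `start`,
#'   `statistic`, `p_value`, `neg_log10_p`, `test`, `strata_used`,
#'   `passes_primary`, `passes_secondary`; thresholds and lambda in
#'   attributes `thresholds` and `lambda`.
#' @export
run_gwas <- function(cn, panel, phenotypes, trait, variant_windows,
                     test = c("auto", "cmh", "linreg"), n_pcs = 4,
                     lambda_trigger = 1.1, strata = NULL, grid = NULL) {
  test <- match.arg(test)
  if (!length(variant_windows)) stop("no variant windows to test")
  if (!trait %in% names(phenotypes$types)) stop("unknown trait: ", trait)
  type <- phenotypes$types[[trait]]
  if (test == "auto") test <- if (type == "continuous") "linreg" else "cmh"
  samples <- rownames(cn)
  breed_of <- stats::setNames(panel$breed, panel$sample_id)
  ph <- phenotypes$values
  trait_of_breed <- stats::setNames(ph[[trait]], ph$breed)
  y <- trait_of_breed[breed_of[samples]]
  keep <- !is.na(y)
  cnv <- cn[keep, variant_windows, drop = FALSE]
  y <- y[keep]
  samples <- samples[keep]

  if (test == "linreg") {
    y <- as.numeric(y)
    pcs <- NULL
    if (n_pcs > 0) {
      sc <- scale(cn[keep, , drop = FALSE])
      sc <- sc[, apply(is.finite(sc), 2, all), drop = FALSE]
      pc <- stats::prcomp(sc, center = FALSE, scale. = FALSE)
      informative <- sum(pc$sdev > 1e-8 * pc$sdev[1])  # effective rank
      k_pcs <- min(n_pcs, informative - 1L)
      if (k_pcs > 0)
        pcs <- pc$x[, seq_len(k_pcs), drop = FALSE]
    }
    res <- apply(cnv, 2, function(x) {
      if (stats::sd(x) == 0) return(c(NA_real_, 1))
      r <- tryCatch(linreg_assoc(y, x, pcs), error = function(e) NULL)
      if (is.null(r)) c(NA_real_, 1) else c(r$beta, r$p_value)
    })
    stat <- res[1, ]; p <- res[2, ]
    strata_used <- rep(1L, length(p))
    lambda <- NA_real_
  } else {
    if (type == "continuous") {
      grp_split <- split_percentiles(trait_of_breed)
      gb <- ifelse(breed_of[samples] %in% grp_split$top, 1L, 0L)
    } else {
      lev <- sort(unique(as.character(y)))
      if (length(lev) != 2)
        stop("CMH needs a two-level grouping; trait has ", length(lev))
      gb <- as.integer(as.character(y) == lev[2])
    }
    cmh_scan <- function(str) {
      apply(cnv, 2, function(x) {
        if (length(unique(x)) < 2) return(c(NA_real_, 1, 0))
        r <- tryCatch(gen_cmh_test(x, gb, strata = str),
                      error = function(e) NULL)
        if (is.null(r)) c(NA_real_, 1, 0)
        else c(r$statistic, r$p_value, r$strata_used)
      })
    }
    res <- cmh_scan(NULL)
    lambda <- if (length(variant_windows) >= 100)
      inflation_factor(res[2, ]) else NA_real_
    if (!is.na(lambda) && lambda > lambda_trigger) {
      if (is.null(strata)) strata <- tree_substrata(cn[keep, , drop = FALSE],
                                                    panel)
      res <- cmh_scan(strata)
    }
    stat <- res[1, ]; p <- res[2, ]; strata_used <- as.integer(res[3, ])
  }
  thr <- compute_thresholds(length(variant_windows))
  nlp <- -log10(p)
  out <- data.frame(window = variant_windows,
                    chrom = if (is.null(grid)) NA_character_
                            else grid$chrom[variant_windows],
                    start = if (is.null(grid)) NA_integer_
                            else grid$start[variant_windows],
                    statistic = stat, p_value = p, neg_log10_p = nlp,
                    test = test, strata_used = strata_used,
                    passes_primary = nlp >= thr$primary,
                    passes_secondary = nlp >= thr$secondary,
                    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- thr
  attr(out, "lambda") <- lambda
  out
}
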