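# Integer copy-number genotyping.
#
# A hidden Markov model links the observed copy ratio (emission) to an
# integer copy-number state via a Gaussian whose spread grows with both the
# hidden CN and the sample's diploid dispersion:
#
#   sd(N) = max(0.5 * N * sigma_CR, 0.5 * sigma_CR)
#
# States are the integers 0..20 plus one aggregate ">20" state emitting an
# equal-weight Gaussian mixture with means 21..50. The transition matrix is
# trained by Baum-Welch on designated training samples; per-window state
# posteriors come from the scaled forward-backward recursion, and are then
# sharpened across the cohort: the mean posterior over all samples in a
# 5-window sliding range centred on each window acts as a local prior, and
# every sample's copy ratio is re-scored through Bayes' rule
#
#   p(CN = N | cr) = PDF(cr; N, sd(N)) p(N) / sum_M PDF(cr; M, sd(M)) p(M).
#
# The smallest set of states accumulating 0.95 posterior mass is reported
# as the credible CN interval.

N_INT_STATES <- 21L   # CN 0..20
AGG_MEANS <- 21:50    # aggregate ">20" state mixture means

#' Per-sample diploid dispersion
#'
#' Standard deviation of the copy ratio over control (presumed diploid)
#' windows; this is `sd(CN = 2)`, the scale unit of the emission model and
#' of the deletion mixture.
#'
#' @param mat a [cr_matrix()] whose grid carries a control mask.
#' @return named numeric vector of per-sample dispersions.
#' @export
estimate_sigma_cr <- function(mat) {
  ctrl <- which(mat$grid$control)
  if (length(ctrl) < 50)
    stop("need at least 50 control windows, got ", length(ctrl))
  out <- apply(mat$values[, ctrl, drop = FALSE], 1, stats::sd)
  stats::setNames(out, mat$sample_ids)
}

#' Gaussian emission model for one sample
#'
#' @param sigma_cr the sample's diploid copy-ratio dispersion (> 0).
#' @return an `emission_model` (list with `sigma_cr`, `n_states`, `states`).
#'   State labels are the integers 0..20; the 22nd state aggregates CN > 20.
#' @export
emission_model <- function(sigma_cr) {
  if (!is.finite(sigma_cr) || sigma_cr <= 0)
    stop("sigma_cr must be positive, got ", sigma_cr)
  structure(list(sigma_cr = sigma_cr, n_states = N_INT_STATES + 1L,
                 states = c(0:20, NA)),
            class = "emission_model")
}

emission_sd <- function(n, sigma_cr) pmax(0.5 * n * sigma_cr, 0.5 * sigma_cr)

#' Emission log-likelihood matrix
#'
#' @param x numeric vector of copy ratios.
#' @param model an [emission_model()].
#' @return matrix `length(x)` x 22 of log emission densities.
#' @export
emission_loglik <- function(x, model) {
  if (any(!is.finite(x)))
    stop("non-finite copy ratio at window ", which(!is.finite(x))[1])
  s <- model$sigma_cr
  ll <- matrix(vapply(0:20, function(n)
    stats::dnorm(x, n, emission_sd(n, s), log = TRUE),
    numeric(length(x))), nrow = length(x))
  # aggregate state: equal-weight mixture over means 21..50
  dens <- vapply(AGG_MEANS, function(n)
    stats::dnorm(x, n, emission_sd(n, s)), numeric(length(x)))
  agg <- log(rowMeans(matrix(dens, nrow = length(x))) + 1e-300)
  cbind(ll, agg, deparse.level = 0)
}

#' Default transition model
#'
#' Row-stochastic 22-state matrix: self-transition mass `self`, remainder
#' uniform; start distribution puts `start2` on the diploid state.
#'
#' @param self self-transition probability used for initialization.
#' @param start2 start mass on CN 2.
#' @return a `transition_model` (list with matrix `A` and vector `pi`).
#' @export
init_transitions <- function(self = 0.9, start2 = 0.9) {
  k <- N_INT_STATES + 1L
  A <- matrix((1 - self) / (k - 1), k, k)
  diag(A) <- self
  p <- rep((1 - start2) / (k - 1), k)
  p[3] <- start2
  structure(list(A = A, pi = p), class = "transition_model")
}

# Scaled forward-backward on a precomputed log emission matrix.
# Returns normalized posteriors (gamma), scaled alpha/beta, per-step scale
# factors and the sequence log-likelihood. Row-max shifting of the emission
# matrix keeps the scaled recursion finite for sequences of 1e5+ windows.
forward_backward_core <- function(logB, A, p0) {
  T_ <- nrow(logB); k <- ncol(logB)
  m <- apply(logB, 1, max)
  B <- exp(logB - m)
  alpha <- matrix(0, T_, k)
  cvec <- numeric(T_)
  a <- p0 * B[1, ]
  cvec[1] <- sum(a)
  alpha[1, ] <- a / cvec[1]
  for (t in 2:T_) {
    a <- (alpha[t - 1, ] %*% A)[1, ] * B[t, ]
    cvec[t] <- sum(a)
    alpha[t, ] <- a / cvec[t]
  }
  beta <- matrix(0, T_, k)
  beta[T_, ] <- 1
  for (t in (T_ - 1):1) {
    beta[t, ] <- (A %*% (B[t + 1, ] * beta[t + 1, ]))[, 1] / cvec[t + 1]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  list(gamma = gamma, alpha = alpha, beta = beta, B = B, c = cvec,
       loglik = sum(log(cvec)) + sum(m))
}

#' Forward-backward posterior decoding
#'
#' Computes the per-window posterior over the 22 copy-number states for one
#' sample's copy-ratio sequence (one chromosome: transitions never span
#' chromosome boundaries).
#'
#' @param x copy ratios in grid order along one chromosome.
#' @param model the sample's [emission_model()].
#' @param trans a `transition_model` ([init_transitions()] or trained).
#' @return list with `posterior` (matrix `length(x)` x 22, rows sum to 1)
#'   and `loglik`.
#' @export
posterior_decode <- function(x, model, trans) {
  logB <- emission_loglik(x, model)
  fb <- forward_backward_core(logB, trans$A, trans$pi)
  list(posterior = fb$gamma, loglik = fb$loglik)
}

#' Train the transition matrix by Baum-Welch
#'
#' Expectation-maximization over the transition matrix and start
#' distribution only; the Gaussian emissions stay fixed at their
#' dispersion-law values. Each chromosome of each training sample is one
#' independent chain. The log-likelihood is non-decreasing across
#' iterations (an EM guarantee asserted in the tests).
#'
#' @param sequences list of numeric copy-ratio vectors (one per chain).
#' @param models list of [emission_model()]s, one per chain (recycled if
#'   length 1).
#' @param max_iter maximum EM iterations.
#' @param tol stop when the mean per-window log-likelihood improves by less
#'   than this.
#' @param init initial `transition_model`.
#' @param pseudocount Dirichlet pseudocount added to the expected
#'   transition counts in the M-step. Training cohorts are small and need
#'   not visit every state, and a transition never seen in training would
#'   otherwise collapse to a probability so small that no emission
#'   evidence in a test sample could overcome it; the pseudocount keeps
#'   unseen transitions rare but payable.
#' @return a `transition_model` with `A`, `pi`, `loglik_trace` and
#'   `converged`.
#' @export
train_transitions <- function(sequences, models, max_iter = 100, tol = 1e-4,
                              init = init_transitions(),
                              pseudocount = 0.05) {
  if (!length(sequences)) stop("need at least one training sequence")
  if (length(models) == 1) models <- rep(models, length(sequences))
  logBs <- mapply(function(x, mod) emission_loglik(x, mod),
                  sequences, models, SIMPLIFY = FALSE)
  A <- init$A; p0 <- init$pi
  k <- ncol(A)
  n_tot <- sum(vapply(sequences, length, numeric(1)))
  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    xi_sum <- matrix(0, k, k)
    g1_sum <- numeric(k)
    ll <- 0
    for (s in seq_along(logBs)) {
      fb <- forward_backward_core(logBs[[s]], A, p0)
      T_ <- nrow(fb$gamma)
      # sum_t xi_t = (alpha[1:T-1]' %*% (B*beta/c)[2:T]) * A elementwise
      V <- fb$B[-1, , drop = FALSE] * fb$beta[-1, , drop = FALSE] /
        fb$c[-1]
      xi_sum <- xi_sum +
        (t(fb$alpha[-T_, , drop = FALSE]) %*% V) * A
      g1_sum <- g1_sum + fb$gamma[1, ]
      ll <- ll + fb$loglik
    }
    trace <- c(trace, ll)
    if (iter > 1 && (ll - trace[iter - 1]) / n_tot < tol) {
      converged <- TRUE
      break
    }
    xi_sum <- xi_sum + pseudocount
    A <- xi_sum / rowSums(xi_sum)
    p0 <- (g1_sum + pseudocount) / sum(g1_sum + pseudocount)
  }
  structure(list(A = A, pi = p0, loglik_trace = trace,
                 converged = converged),
            class = "transition_model")
}

# Credible set: states in descending posterior order until >= `mass` is
# accumulated; ties broken toward the state nearer CN 2, then the lower CN.
# Returns c(low, high) as indices into 1..22 (state CN = index - 1).
credible_bounds <- function(p, mass = 0.95) {
  states <- seq_along(p) - 1L
  ord <- order(-p, abs(states - 2L), states)
  cum <- cumsum(p[ord])
  take <- ord[seq_len(which(cum >= mass)[1])]
  c(min(take), max(take))
}

#' Cohort-level Bayes smoothing and credible sets
#'
#' For each window, the mean of the forward-backward posteriors over all
#' samples and over a five-window sliding range centred on the window
#' (truncated at chromosome ends) forms a local state prior. Each sample's
#' copy ratio at the window is then re-scored through Bayes' rule against
#' its own emission densities, and the smallest posterior-ordered state set
#' reaching 0.95 becomes the credible CN interval.
#'
#' @param posteriors list over samples of per-window posterior matrices
#'   (rows = all grid windows, 22 columns), as stacked from
#'   [posterior_decode()] per chromosome.
#' @param mat the [cr_matrix()] the posteriors were computed from.
#' @param sigma_cr named per-sample dispersion vector.
#' @param mass credible mass (default 0.95).
#' @return A `cn_calls` object: matrices `map_cn`, `cred_low`, `cred_high`,
#'   `post_max` (samples x windows), logical `above20` flag matrix, plus
#'   `grid` and `sample_ids`. The aggregate state is reported as CN 21 with
#'   `above20 = TRUE`.
#' @export
cohort_smooth <- function(posteriors, mat, sigma_cr, mass = 0.95) {
  grid <- mat$grid
  n_win <- nrow(grid)
  ids <- mat$sample_ids
  if (!setequal(names(posteriors), ids))
    stop("posterior list does not match matrix samples")
  if (any(vapply(posteriors, nrow, integer(1)) != n_win))
    stop("posterior grids mismatch the copy-ratio grid")
  k <- N_INT_STATES + 1L

  # local prior: mean posterior over samples, then over the 5-window range
  pmean <- Reduce(`+`, posteriors[ids]) / length(ids)
  prior <- matrix(0, n_win, k)
  for (ch in unique(grid$chrom)) {
    idx <- which(grid$chrom == ch)
    cs <- rbind(0, apply(pmean[idx, , drop = FALSE], 2, cumsum))
    n <- length(idx)
    lo <- pmax(seq_len(n) - 2L, 1L)
    hi <- pmin(seq_len(n) + 2L, n)
    prior[idx, ] <- (cs[hi + 1L, , drop = FALSE] -
                       cs[lo, , drop = FALSE]) / (hi - lo + 1L)
  }

  map_cn <- cred_low <- cred_high <- matrix(0L, length(ids), n_win,
                                            dimnames = list(ids, NULL))
  post_max <- matrix(0, length(ids), n_win, dimnames = list(ids, NULL))
  above20 <- matrix(FALSE, length(ids), n_win, dimnames = list(ids, NULL))
  for (id in ids) {
    logB <- emission_loglik(mat$values[id, ], emission_model(sigma_cr[id]))
    logpost <- logB + log(prior + 1e-300)
    logpost <- logpost - apply(logpost, 1, max)
    post <- exp(logpost)
    post <- post / rowSums(post)
    bounds <- apply(post, 1, credible_bounds, mass = mass)
    map_idx <- max.col(post, ties.method = "first")
    map_cn[id, ] <- ifelse(map_idx == k, 21L, map_idx - 1L)
    cred_low[id, ] <- ifelse(bounds[1, ] == k, 21L, bounds[1, ] - 1L)
    cred_high[id, ] <- ifelse(bounds[2, ] == k, 21L, bounds[2, ] - 1L)
    post_max[id, ] <- post[cbind(seq_len(n_win), map_idx)]
    above20[id, ] <- bounds[2, ] == k
  }
  structure(list(map_cn = map_cn, cred_low = cred_low,
                 cred_high = cred_high, post_max = post_max,
                 above20 = above20, grid = grid, sample_ids = ids),
            class = "cn_calls")
}

#' @export
print.cn_calls <- function(x, ...) {
  cat("CN calls:", length(x$sample_ids), "samples x", nrow(x$grid),
      "windows\n")
  invisible(x)
}

#' Genotype a whole cohort
#'
#' End-to-end genotyping: per-sample dispersion estimation, optional
#' Baum-Welch transition training on designated training samples,
#' forward-backward decoding per sample and chromosome, and cohort-level
#' Bayes smoothing. Training samples are excluded from the output cohort,
#' mirroring the practice of training on held-out samples.
#'
#' @param mat a [cr_matrix()] (after QC).
#' @param train_samples character vector of sample ids used to train the
#'   transition matrix; they are dropped from the calls.
#' @param trans optional pre-trained `transition_model`; when supplied no
#'   training is run.
#' @param max_iter,tol Baum-Welch controls.
#' @return a `cn_calls` object (see [cohort_smooth()]) with the trained
#'   `transition_model` attached as `$transitions`.
#' @export
genotype_cohort <- function(mat, train_samples = character(0), trans = NULL,
                            max_iter = 100, tol = 1e-4) {
  sigma <- estimate_sigma_cr(mat)
  if (any(sigma == 0))
    stop("constant copy ratios (sigma_cr = 0) for sample ",
         names(sigma)[sigma == 0][1])
  grid <- mat$grid
  chrom_idx <- split(seq_len(nrow(grid)), grid$chrom)
  if (is.null(trans)) {
    if (!length(train_samples))
      stop("supply train_samples or a pre-trained transition model")
    seqs <- list(); mods <- list()
    for (id in train_samples) {
      for (idx in chrom_idx) {
        seqs[[length(seqs) + 1]] <- mat$values[id, idx]
        mods[[length(mods) + 1]] <- emission_model(sigma[id])
      }
    }
    trans <- train_transitions(seqs, mods, max_iter = max_iter, tol = tol)
  }
  keep <- setdiff(mat$sample_ids, train_samples)
  sub <- cr_matrix(mat$values[keep, , drop = FALSE], grid, sample_ids = keep)
  posteriors <- lapply(keep, function(id) {
    mod <- emission_model(sigma[id])
    out <- matrix(0, nrow(grid), N_INT_STATES + 1L)
    for (idx in chrom_idx)
      out[idx, ] <- posterior_decode(mat$values[id, idx], mod,
                                     trans)$posterior
    out
  })
  names(posteriors) <- keep
  calls <- cohort_smooth(posteriors, sub, sigma[keep])
  calls$transitions <- trans
  calls$sigma_cr <- sigma[keep]
  calls
}
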