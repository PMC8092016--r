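# Shared fixtures: small cohorts built in code.

small_cohort <- function(seed = 11, n_bad = 0, windows = 300) {
  cfg <- cohort_config(
    n_chromosomes = 2, windows_per_chromosome = windows,
    clades = list(list(name = "A", n_breeds = 3, samples_per_breed = 4),
                  list(name = "B", n_breeds = 3, samples_per_breed = 4)),
    sigma_cr_range = c(0.1, 0.15),
    event_spec = list(
      list(id = "del1", scope_type = "clade", scope = "A", chrom = "chr1",
           start_window = 10, n_windows = 5, cn = 1, freq = 0.8),
      list(id = "dup1", scope_type = "clade", scope = "B", chrom = "chr2",
           start_window = 30, n_windows = 4, cn = 4, freq = 0.6),
      list(id = "del0", scope_type = "clade", scope = "B", chrom = "chr1",
           start_window = 45, n_windows = 3, cn = 0, freq = 1)),
    phenotype_spec = list(
      list(trait = "height", type = "continuous", causal_event = "del1",
           effect_per_copy = 1.5, noise_sd = 0.3),
      list(trait = "herding", type = "binary", causal_event = "dup1",
           effect_per_copy = 1, noise_sd = 0.5)),
    n_bad_samples = n_bad, seed = seed)
  generate_cohort(cfg)
}

# toy 3-window grid on one chromosome
toy_grid <- function() {
  window_grid(rep("chr1", 3), c(0, 1000, 2000), c(1000, 2000, 3000))
}

# GWAS power design: 30 breeds x 4 samples, 1000 variant windows.
# Six 50-window breed-fixed blocks (one per clade) carry the clade-level
# structure the PC covariates are meant to absorb; 34 smaller sample-level
# events are undifferentiated background; the causal deletion is
# breed-fixed at frequency 0.5 with a per-copy effect of 1.5 trait SDs
# (residual SD 0.661 makes the total across-breed trait SD 1).
gwas_power_config <- function(seed) {
  set.seed(seed)
  clades <- lapply(1:6, function(i)
    list(name = paste0("cl", i), n_breeds = 5, samples_per_breed = 4))
  structure_ev <- lapply(1:6, function(i)
    list(id = paste0("str", i), scope_type = "clade",
         scope = paste0("cl", i), chrom = "chr1",
         start_window = (i - 1) * 50, n_windows = 50,
         cn = sample(c(1, 3), 1), freq = 0.8, unit = "breed"))
  bg <- lapply(1:34, function(i)
    list(id = paste0("bg", i), scope_type = "clade",
         scope = paste0("cl", 1 + (i - 1) %% 6), chrom = "chr1",
         start_window = 300 + (i - 1) * 20, n_windows = 20,
         cn = sample(c(0, 1, 3, 4), 1), freq = runif(1, 0.3, 0.7)))
  causal <- list(id = "causal", scope_type = "all", scope = NA,
                 chrom = "chr1", start_window = 980, n_windows = 20,
                 cn = 1, freq = 0.5, unit = "breed")
  cohort_config(n_chromosomes = 1, windows_per_chromosome = 1000,
                clades = clades, sigma_cr_range = c(0.1, 0.15),
                event_spec = c(structure_ev, bg, list(causal)),
                phenotype_spec = list(
                  list(trait = "height", type = "continuous",
                       causal_event = "causal", effect_per_copy = 1.5,
                       noise_sd = 0.661)),
                seed = seed)
}

# brute-force forward-backward posterior by exhaustive path enumeration
enumerate_posterior <- function(logB, A, p0) {
  T_ <- nrow(logB); k <- ncol(logB)
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), T_)))
  w <- apply(paths, 1, function(s) {
    lp <- log(p0[s[1]]) + logB[1, s[1]]
    for (t in 2:T_) lp <- lp + log(A[s[t - 1], s[t]]) + logB[t, s[t]]
    exp(lp)
  })
  post <- matrix(0, T_, k)
  for (t in seq_len(T_))
    for (j in seq_len(k))
      post[t, j] <- sum(w[paths[, t] == j])
  post / rowSums(post)
}
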