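# V_ST, balanced PCA, trees, indicator-matrix collapse, haplotype exclusion.

test_that("V_ST matches hand evaluation and its boundary behaviour", {
  # hand evaluation with sample variances:
  # var(2,2,3) = var(4,4,5) = 1/3, var(all six) = 22/15
  # 1 - (3/3 + 3/3) / (6 * 22/15) = 1 - 30/132
  expect_equal(vst_pair(c(2, 2, 3), c(4, 4, 5)), 1 - 30 / 132,
               tolerance = 1e-9)
  expect_equal(vst_pair(c(2, 2, 3), c(4, 4, 5)), 0.7727, tolerance = 1e-4)

  expect_equal(vst_pair(rep(2, 6), rep(4, 6)), 1)   # full differentiation
  set.seed(10)
  x <- rnorm(50, 2, 0.5)
  expect_lt(abs(vst_pair(x, x)), 0.2)               # identical groups
  expect_equal(vst_pair(rep(2, 5), rep(2, 5)), 0)   # pooled variance 0
  expect_lte(vst_pair(c(1, 5, 2), c(2, 4, 3)), 1)
  expect_error(vst_pair(2, c(2, 2)), "at least 2")
})

test_that("subsampled scan is deterministic at k and recovers planted differentiation", {
  set.seed(11)
  cn <- rbind(matrix(2, 6, 10), matrix(2, 6, 10), matrix(2, 8, 10))
  rownames(cn) <- paste0("s", 1:20)
  cn[1:6, 3] <- 4                       # clade A fixed CN-4 duplication
  cn[, 7] <- rpois(20, 2)               # undifferentiated noise
  panel <- breed_panel(rownames(cn),
                       breed = rep(c("b1", "b2", "b3"), c(6, 6, 8)),
                       clade = rep(c("A", "B", "C"), c(6, 6, 8)))
  res <- vst_subsampled_scan(cn, panel, k = 6, reps = 50, seed = 1)
  ab <- res[res$clade1 == "A" & res$clade2 == "B", ]
  expect_false(any(ab$subsampled))      # both exactly k: deterministic
  expect_equal(ab$vst[ab$window == 3], 1)
  expect_equal(ab$vst[ab$window == 3],
               vst_pair(cn[1:6, 3], cn[7:12, 3]))
  ac <- res[res$clade1 == "A" & res$clade2 == "C", ]
  expect_true(all(ac$subsampled))
  expect_equal(ac$vst[ac$window == 3], 1)  # fixed difference survives subsampling

  # same seed reproduces; different seed stays within tolerance
  res2 <- vst_subsampled_scan(cn, panel, k = 6, reps = 50, seed = 1)
  expect_identical(res, res2)
  res3 <- vst_subsampled_scan(cn, panel, k = 6, reps = 50, seed = 2)
  expect_lt(max(abs(res3$vst - res$vst)), 0.05)
})

test_that("balanced PCA projection is exact on the basis and separates clades", {
  set.seed(12)
  n_win <- 80
  cn <- matrix(rnorm(40 * n_win, 2, 0.1), 40, n_win,
               dimnames = list(paste0("s", 1:40), NULL))
  cn[1:20, 1:10] <- cn[1:20, 1:10] + 2      # clade A planted CNV block
  cn[21:40, 11:20] <- cn[21:40, 11:20] + 2  # clade B disjoint block
  panel <- breed_panel(rownames(cn),
                       breed = rep(c("b1", "b2", "b3", "b4"), each = 10),
                       clade = rep(c("A", "B"), each = 20))
  basis <- pca_balanced(cn, panel, per_clade_k = 8, seed = 3)
  proj <- pca_project(cn, basis)
  expect_equal(proj[basis$basis_samples, ], basis$scores,
               tolerance = 1e-9)
  expect_true(all(diff(basis$sdev) <= 1e-12))   # non-increasing variance

  # silhouette of the two clades on PC1
  pc1 <- proj[, 1]
  clade <- panel$clade
  sil <- vapply(seq_along(pc1), function(i) {
    same <- setdiff(which(clade == clade[i]), i)
    a <- mean(abs(pc1[i] - pc1[same]))
    b <- mean(abs(pc1[i] - pc1[clade != clade[i]]))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
})

test_that("distances, NJ trees and monophyly behave on planted structure", {
  cn <- rbind(c(2, 2), c(2, 2), c(2, 4))
  rownames(cn) <- paste0("s", 1:3)
  D <- distance_matrix(cn)
  expect_equal(D["s1", "s2"], 0)
  expect_equal(D["s1", "s3"], 2)
  expect_equal(D["s2", "s3"], 2)
  expect_error(distance_matrix(rbind(c(1, NA), c(1, 2))), "missing")

  # additive 4-taxon metric: NJ recovers the generating topology ((a,b),(c,d))
  tdist <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  # tree: a-1-x, b-2-x, x-3-y, c-4-y, d-5-y
  tdist["a", "b"] <- tdist["b", "a"] <- 3
  tdist["a", "c"] <- tdist["c", "a"] <- 8
  tdist["a", "d"] <- tdist["d", "a"] <- 9
  tdist["b", "c"] <- tdist["c", "b"] <- 9
  tdist["b", "d"] <- tdist["d", "b"] <- 10
  tdist["c", "d"] <- tdist["d", "c"] <- 9
  tr <- build_tree(tdist)
  expect_true(ape::is.monophyletic(ape::unroot(tr), c("a", "b")))
  # Newick round trip preserves the leaf set
  nwk <- ape::write.tree(tr)
  tr2 <- ape::read.tree(text = nwk)
  expect_setequal(tr2$tip.label, letters[1:4])

  # clade-structured synthetic CN: each clade monophyletic
  set.seed(13)
  cn2 <- matrix(rnorm(30 * 50, 2, 0.05), 30, 50,
                dimnames = list(paste0("s", 1:30), NULL))
  cn2[1:10, 1:5] <- 4; cn2[11:20, 6:10] <- 0; cn2[21:30, 11:15] <- 3
  tr3 <- build_tree(distance_matrix(cn2))
  expect_true(ape::is.monophyletic(tr3, paste0("s", 1:10)))
  expect_true(ape::is.monophyletic(tr3, paste0("s", 11:20)))
  expect_true(ape::is.monophyletic(tr3, paste0("s", 21:30)))
})

test_that("breed collapse equals hand-computed block means and is idempotent", {
  samples <- paste0("s", 1:4)
  panel <- breed_panel(samples, breed = c("x", "x", "y", "y"),
                       clade = "c1")
  B <- breed_indicator(samples, panel)
  expect_equal(colSums(B), c(x = 2, y = 2))
  D <- matrix(c(0, 1, 2, 3,
                1, 0, 2, 3,
                2, 2, 0, 1,
                3, 3, 1, 0), 4, 4, byrow = TRUE,
              dimnames = list(samples, samples))
  M <- breed_collapse_projection(D, B)
  # hand: cross-block mean = mean(2,3,2,3) = 2.5; diagonal zeroed
  expect_equal(M["x", "y"], 2.5)
  expect_equal(M["y", "x"], 2.5)
  expect_equal(diag(M), c(x = 0, y = 0))

  # breed-constant matrix: projection is the identity on block values
  D2 <- matrix(2.5, 4, 4, dimnames = list(samples, samples))
  D2[1:2, 1:2] <- 0; D2[3:4, 3:4] <- 0
  M2 <- breed_collapse_projection(D2, B)
  expect_equal(M2["x", "y"], 2.5)

  # permutation invariance
  perm <- c(3, 1, 4, 2)
  Mp <- breed_collapse_projection(D[perm, perm],
                                  breed_indicator(samples[perm], panel))
  expect_equal(Mp[rownames(M), colnames(M)], M)
})

test_that("topology comparison is scale-free and detects identity", {
  M <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  cmp <- compare_topologies(M, M)
  expect_equal(cmp$pearson_r, 1)
  expect_equal(cmp$two_norm, 0)
  cmp3 <- compare_topologies(M, 3 * M)
  expect_equal(cmp3$pearson_r, 1)
  expect_equal(cmp3$two_norm, 0, tolerance = 1e-12)

  set.seed(14)
  r_abs <- replicate(30, {
    A <- matrix(runif(36), 6, 6); A <- (A + t(A)); diag(A) <- 0
    Bm <- matrix(runif(36), 6, 6); Bm <- (Bm + t(Bm)); diag(Bm) <- 0
    dimnames(A) <- dimnames(Bm) <- list(letters[1:6], letters[1:6])
    cmp <- compare_topologies(A, Bm)
    # direct correlation oracle on the upper off-diagonal
    expect_equal(cmp$pearson_r, cor(A[upper.tri(A)], Bm[upper.tri(Bm)]))
    cmp$pearson_r
  })
  expect_lt(abs(mean(r_abs)), 0.2)
  expect_error(compare_topologies(M, M[c(1, 2), c(1, 2)]), "differ")
})

test_that("haplotype exclusion rescales distances and removes differentiation", {
  g <- window_grid(rep("chr1", 2000), (0:1999) * 1000, (1:2000) * 1000)
  set.seed(15)
  cn <- matrix(rpois(20 * 2000, 2), 20, 2000,
               dimnames = list(paste0("s", 1:20), NULL))
  del_windows <- seq_len(2000)
  # empty exclusion: unchanged
  D0 <- exclude_shared_haplotypes(cn, del_windows,
                                  data.frame(chrom = character(0),
                                             start = integer(0),
                                             end = integer(0)), g)
  expect_equal(D0, distance_matrix(cn))

  # removing half the windows of an i.i.d. matrix: rescaled within 10%
  shared <- data.frame(chrom = "chr1", start = 0, end = 1000 * 1000)
  D1 <- exclude_shared_haplotypes(cn, del_windows, shared, g)
  off <- upper.tri(D1)
  expect_lt(max(abs(D1[off] / D0[off] - 1)), 0.10)

  # removing the only differentiating block collapses two clades
  cn2 <- cn
  cn2[1:10, 1:50] <- 6
  full <- distance_matrix(cn2)
  D2 <- exclude_shared_haplotypes(cn2, del_windows,
                                  data.frame(chrom = "chr1", start = 0,
                                             end = 50 * 1000), g)
  between_full <- mean(full[1:10, 11:20])
  between_corr <- mean(D2[1:10, 11:20])
  within <- mean(full[11:20, 11:20][upper.tri(matrix(0, 10, 10))])
  expect_lt(between_corr, between_full)
  expect_lt(abs(between_corr - within * sqrt(2000 / 1950)) / within, 0.1)
  expect_error(exclude_shared_haplotypes(cn, 1:10,
    data.frame(chrom = "chr1", start = 0, end = 2e6), g), "all deletion")
})
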