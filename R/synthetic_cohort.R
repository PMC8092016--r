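# Synthetic cohort generator.
#
# Emits clade-structured cohorts with planted copy-number events, Gaussian
# read-depth noise around the true copy number, breed-standard phenotypes
# linked additively to causal events, and annotation tracks (genes, lncRNA,
# Hi-C contacts with convergent CTCF motifs, conservation scores, shared
# haplotype intervals). Everything downstream can be validated against the
# returned truth set.

#' Cohort configuration
#'
#' @param n_chromosomes number of chromosomes in the synthetic genome.
#' @param windows_per_chromosome analysis windows per chromosome.
#' @param window_size_bp window width in bp (default 1000).
#' @param clades list of clades, each `list(name=, n_breeds=,
#'   samples_per_breed=)`.
#' @param sigma_cr_range length-2 numeric: per-sample diploid copy-ratio
#'   dispersion is drawn uniformly from this range. Real cohorts mix
#'   coverages, so dispersion is heterogeneous by design.
#' @param event_spec list of planted events, each `list(id=, scope_type=
#'   "clade"|"breed"|"all", scope=, chrom=, start_window=, n_windows=,
#'   cn=, freq=, unit=)`; `start_window` is the 0-based window ordinal
#'   within `chrom`, `cn` the carrier copy number and `freq` the carrier
#'   frequency within scope. `unit = "sample"` (default) draws carriers
#'   per sample; `unit = "breed"` draws whole breeds as carriers,
#'   emulating breed-fixed variants.
#' @param phenotype_spec list of traits, each `list(trait=, type=
#'   "continuous"|"binary", causal_event= id or NULL, effect_per_copy=,
#'   noise_sd=, intercept=)`.
#' @param n_bad_samples number of extra samples planted to violate quality
#'   control (cycling through inflated dispersion, a bimodal mean shift and
#'   strong neighbour autocorrelation).
#' @param seed integer seed; the whole cohort is a deterministic function
#'   of the configuration.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_chromosomes = 2,
                          windows_per_chromosome = 1000,
                          window_size_bp = 1000,
                          clades = list(
                            list(name = "cladeA", n_breeds = 3,
                                 samples_per_breed = 4),
                            list(name = "cladeB", n_breeds = 3,
                                 samples_per_breed = 4)),
                          sigma_cr_range = c(0.1, 0.2),
                          event_spec = list(),
                          phenotype_spec = list(),
                          n_bad_samples = 0,
                          seed = 1L) {
  stopifnot(window_size_bp > 0, n_chromosomes >= 1,
            windows_per_chromosome >= 1,
            length(sigma_cr_range) == 2,
            sigma_cr_range[1] > 0,
            sigma_cr_range[1] <= sigma_cr_range[2])
  for (ev in event_spec) {
    if (is.null(ev$id)) stop("every event needs an id")
    if (!is.null(ev$freq) && (ev$freq < 0 || ev$freq > 1))
      stop("carrier frequency must lie in [0,1] for event ", ev$id)
    if (ev$cn < 0) stop("copy number must be >= 0 for event ", ev$id)
    if (ev$start_window < 0 ||
        ev$start_window + ev$n_windows > windows_per_chromosome)
      stop("event ", ev$id, " span lies outside the window grid")
    if (!ev$chrom %in% paste0("chr", seq_len(n_chromosomes)))
      stop("event ", ev$id, " names unknown chromosome ", ev$chrom)
  }
  ev_ids <- vapply(event_spec, `[[`, character(1), "id")
  for (ph in phenotype_spec) {
    if (!is.null(ph$causal_event) && !ph$causal_event %in% ev_ids)
      stop("trait ", ph$trait, " references unknown event ",
           ph$causal_event)
  }
  structure(list(n_chromosomes = n_chromosomes,
                 windows_per_chromosome = windows_per_chromosome,
                 window_size_bp = window_size_bp,
                 clades = clades,
                 sigma_cr_range = sigma_cr_range,
                 event_spec = event_spec,
                 phenotype_spec = phenotype_spec,
                 n_bad_samples = n_bad_samples,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic cohort
#'
#' Copy ratios are drawn as `CR ~ Normal(true_cn, max(0.5 * true_cn * sigma_s,
#' 0.5 * sigma_s))`, the same dispersion law the genotyper's emission model
#' assumes: noise scales with the hidden copy number and with the sample's
#' diploid dispersion `sigma_s`, floored at half the diploid value so
#' homozygous deletions still have spread. Breed-standard phenotypes are
#' breed-level: `intercept + effect_per_copy * (breed mean true CN over the
#' causal span) + Normal(0, noise_sd)`, identical for every sample of the
#' breed. Binary traits threshold the latent continuous value at its 70th
#' percentile.
#'
#' @param config a [cohort_config()].
#' @return A list with components `grid` ([window_grid()]), `cr`
#'   ([cr_matrix()]), `panel` ([breed_panel()]), `phenotypes`
#'   ([phenotype_table()]), `truth` (true CN matrix, per-sample sigma,
#'   carrier sets, causal windows, planted bad samples) and `annotations`
#'   (genes, lncRNA, CTCF motifs, Hi-C contacts, conservation scores,
#'   shared-haplotype intervals, plus the planted annotation truth).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  W <- config$windows_per_chromosome
  n_chr <- config$n_chromosomes
  wsize <- config$window_size_bp
  chroms <- paste0("chr", seq_len(n_chr))
  n_win <- W * n_chr

  # panel -------------------------------------------------------------
  rows <- list()
  for (cl in config$clades) {
    for (b in seq_len(cl$n_breeds)) {
      breed <- paste0(cl$name, "_breed", b)
      for (s in seq_len(cl$samples_per_breed)) {
        rows[[length(rows) + 1]] <-
          data.frame(sample_id = paste0(breed, "_s", s), breed = breed,
                     clade = cl$name, class = "breed-dog",
                     stringsAsFactors = FALSE)
      }
    }
  }
  pan <- do.call(rbind, rows)
  bad_ids <- character(0)
  bad_type <- character(0)
  if (config$n_bad_samples > 0) {
    bad_ids <- paste0("qcfail_s", seq_len(config$n_bad_samples))
    bad_type <- rep(c("inflated_sd", "mean_shift", "autocorrelated"),
                    length.out = config$n_bad_samples)
    pan <- rbind(pan, data.frame(sample_id = bad_ids, breed = "qcfail",
                                 clade = config$clades[[1]]$name,
                                 class = "breed-dog",
                                 stringsAsFactors = FALSE))
  }
  panel <- breed_panel(pan$sample_id, pan$breed, pan$clade, pan$class)
  n_samp <- nrow(panel)
  good <- !panel$sample_id %in% bad_ids

  # true CN ------------------------------------------------------------
  true_cn <- matrix(2L, n_samp, n_win,
                    dimnames = list(panel$sample_id, NULL))
  carriers <- list()
  event_windows <- integer(0)
  for (ev in config$event_spec) {
    chrom_i <- match(ev$chrom, chroms)
    span <- (chrom_i - 1L) * W + ev$start_window + seq_len(ev$n_windows)
    scope <- switch(ev$scope_type %||% "clade",
      breed = panel$sample_id[panel$breed == ev$scope & good],
      all = panel$sample_id[good],
      panel$sample_id[panel$clade == ev$scope & good])
    if (!length(scope))
      stop("event ", ev$id, " scope matches no samples: ", ev$scope)
    freq <- if (is.null(ev$freq)) 1 else ev$freq
    if (identical(ev$unit, "breed")) {
      sb <- unique(panel$breed[panel$sample_id %in% scope])
      carr_b <- sb[stats::runif(length(sb)) < freq]
      carr <- scope[panel$breed[match(scope, panel$sample_id)] %in% carr_b]
    } else {
      carr <- scope[stats::runif(length(scope)) < freq]
    }
    true_cn[carr, span] <- as.integer(ev$cn)
    carriers[[ev$id]] <- carr
    event_windows <- union(event_windows, span)
  }
  control <- !(seq_len(n_win) %in% event_windows)

  # grid ----------------------------------------------------------------
  starts <- rep(seq_len(W) - 1L, n_chr) * wsize
  grid <- window_grid(rep(chroms, each = W), starts, starts + wsize,
                      control = control)

  # copy ratios ----------------------------------------------------------
  sigma <- stats::runif(n_samp, config$sigma_cr_range[1],
                        config$sigma_cr_range[2])
  names(sigma) <- panel$sample_id
  cr <- matrix(0, n_samp, n_win, dimnames = list(panel$sample_id, NULL))
  for (i in seq_len(n_samp)) {
    sdv <- pmax(0.5 * true_cn[i, ] * sigma[i], 0.5 * sigma[i])
    cr[i, ] <- stats::rnorm(n_win, mean = true_cn[i, ], sd = sdv)
  }
  # planted QC violations overwrite the drawn values
  for (k in seq_along(bad_ids)) {
    id <- bad_ids[k]
    cr[id, ] <- switch(bad_type[k],
      inflated_sd = stats::rnorm(n_win, 2, 0.8),
      mean_shift = {  # bimodal around a shifted centre: faulty normalization
        half <- n_win %/% 2
        c(stats::rnorm(half, 1.5, 0.1), stats::rnorm(n_win - half, 2.7, 0.1))
      },
      autocorrelated = 2 + as.numeric(
        stats::arima.sim(list(ar = 0.9), n_win, sd = 0.15)))
  }
  crmat <- cr_matrix(cr, grid)

  # phenotypes ----------------------------------------------------------
  breeds <- unique(panel$breed[good])
  phen <- data.frame(breed = breeds, stringsAsFactors = FALSE)
  types <- character(0)
  causal_windows <- list()
  for (ph in config$phenotype_spec) {
    intercept <- if (is.null(ph$intercept)) 0 else ph$intercept
    if (!is.null(ph$causal_event)) {
      ev <- config$event_spec[[match(ph$causal_event,
        vapply(config$event_spec, `[[`, character(1), "id"))]]
      chrom_i <- match(ev$chrom, chroms)
      span <- (chrom_i - 1L) * W + ev$start_window + seq_len(ev$n_windows)
      breed_cn <- vapply(breeds, function(b) {
        mean(true_cn[panel$sample_id[panel$breed == b & good], span])
      }, numeric(1))
      causal_windows[[ph$trait]] <- span
    } else {
      breed_cn <- rep(0, length(breeds))
    }
    effect <- if (is.null(ph$effect_per_copy)) 0 else ph$effect_per_copy
    latent <- intercept + effect * breed_cn +
      stats::rnorm(length(breeds), 0, ph$noise_sd)
    if (identical(ph$type, "binary")) {
      cut <- stats::quantile(latent, 0.7, names = FALSE)
      phen[[ph$trait]] <- ifelse(latent > cut, "high", "low")
      types[ph$trait] <- "categorical"
    } else {
      phen[[ph$trait]] <- latent
      types[ph$trait] <- "continuous"
    }
  }
  phenotypes <- if (length(types)) phenotype_table(phen, types) else NULL

  annotations <- synth_annotations(grid, config, event_windows)

  truth <- list(true_cn = true_cn, sigma_cr = sigma,
                breed_of_sample = stats::setNames(panel$breed,
                                                  panel$sample_id),
                clade_of_breed = stats::setNames(panel$clade, panel$breed),
                carriers = carriers, causal_windows = causal_windows,
                bad_samples = stats::setNames(bad_type, bad_ids),
                annotation_truth = annotations$truth,
                seed = config$seed)

  list(grid = grid, cr = crmat, panel = panel, phenotypes = phenotypes,
       truth = truth, annotations = annotations)
}

# Annotation tracks: random gene/lncRNA/conservation background plus one
# planted long-range Hi-C contact flanked by convergent CTCF motifs.
synth_annotations <- function(grid, config, event_windows) {
  n_win <- nrow(grid)
  wsize <- grid_window_size(grid)
  chroms <- unique(grid$chrom)
  W <- config$windows_per_chromosome

  rand_intervals <- function(n, min_w, max_w, prefix) {
    chrom <- sample(chroms, n, replace = TRUE)
    w0 <- sample.int(max(W - max_w, 1), n, replace = TRUE) - 1L
    len <- sample(min_w:max_w, n, replace = TRUE)
    data.frame(chrom = chrom, start = w0 * wsize,
               end = pmin(w0 + len, W) * wsize,
               name = paste0(prefix, seq_len(n)),
               stringsAsFactors = FALSE)
  }
  genes <- rand_intervals(max(20, n_win %/% 50), 2, 8, "gene")
  genes <- genes[order(genes$chrom, genes$start), ]

  tissues <- c("brain", "testis", "skin", "liver", "blood")
  lnc <- rand_intervals(20, 1, 3, "lnc")
  lnc$tissue <- sample(tissues, nrow(lnc), replace = TRUE)

  gerp <- stats::rnorm(n_win, 0, 1.5)
  conserved <- sample.int(n_win, max(5, n_win %/% 100))
  gerp[conserved] <- stats::runif(length(conserved), 4, 6)

  # Hi-C over coarse bins (10 windows per bin) on the first chromosome
  bin_w <- 10L
  n_bins <- W %/% bin_w
  bins <- data.frame(chrom = chroms[1],
                     start = (seq_len(n_bins) - 1L) * bin_w * wsize,
                     end = seq_len(n_bins) * bin_w * wsize,
                     stringsAsFactors = FALSE)
  support <- matrix(stats::rpois(n_bins * n_bins, 5), n_bins, n_bins)
  support <- support + t(support)          # symmetric background
  diag(support) <- stats::rpois(n_bins, 200) + 100
  i <- max(1L, n_bins %/% 4L); j <- min(n_bins, 3L * n_bins %/% 4L)
  support[i, j] <- support[j, i] <- 10L * as.integer(mean(support[upper.tri(support)]))

  # convergent CTCF motifs at the planted anchors, random strands elsewhere
  ctcf <- data.frame(
    chrom = chroms[1],
    start = c(bins$start[i] + wsize, bins$start[j] + wsize,
              sample.int(W - 1L, 10) * wsize),
    stringsAsFactors = FALSE)
  ctcf$end <- ctcf$start + 20L
  ctcf$name <- paste0("ctcf", seq_len(nrow(ctcf)))
  ctcf$score <- round(stats::runif(nrow(ctcf), 5, 15), 2)
  ctcf$strand <- c("+", "-", sample(c("+", "-"), 10, replace = TRUE))

  hap_n <- 5
  hap <- rand_intervals(hap_n, 2, 6, "hap")[, c("chrom", "start", "end")]
  hap <- hap[order(hap$chrom, hap$start), ]

  list(genes = genes, lncrna = lnc,
       conservation = data.frame(chrom = grid$chrom, start = grid$start,
                                 end = grid$end, score = round(gerp, 4)),
       contacts = support, contact_bins = bins, ctcf = ctcf,
       haplotypes = hap,
       truth = list(planted_contact = c(i, j),
                    conserved_windows = sort(conserved)))
}

#' Write a cohort bundle to disk
#'
#' Serializes every cohort component to plain-text files (BED for interval
#' tracks, TSV for matrices and tables, a whitespace-delimited square
#' contact matrix with a BED sidecar) and a JSON manifest listing the files
#' and the generating seed.
#'
#' @param cohort output of [generate_cohort()].
#' @param directory output directory, created if absent.
#' @return the manifest as a named list, invisibly.
#' @export
write_bundle <- function(cohort, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(directory, f)
  write_window_grid(cohort$grid, p("grid.bed"))
  write_cr_matrix(cohort$cr, p("cr_matrix.tsv"))
  write_panel(cohort$panel, p("panel.tsv"))
  files <- c("grid.bed", "cr_matrix.tsv", "panel.tsv")
  if (!is.null(cohort$phenotypes)) {
    write_phenotypes(cohort$phenotypes, p("phenotypes.tsv"))
    files <- c(files, "phenotypes.tsv")
  }
  an <- cohort$annotations
  write_bed <- function(df, f) {
    utils::write.table(df, p(f), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    f
  }
  files <- c(files,
             write_bed(an$genes, "genes.bed"),
             write_bed(an$ctcf, "ctcf.bed"),
             write_bed(an$haplotypes, "haplotypes.bed"),
             write_bed(an$contact_bins, "contact_bins.bed"))
  utils::write.table(an$lncrna, p("lncrna.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(an$conservation, p("conservation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(an$contacts, p("contacts.txt"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  files <- c(files, "lncrna.tsv", "conservation.tsv", "contacts.txt")
  manifest <- list(files = files,
                   seed = cohort$truth$seed %||% NA,
                   n_samples = length(cohort$cr$sample_ids),
                   n_windows = nrow(cohort$grid))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
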