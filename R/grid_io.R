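# Shared coordinate frame and readers/writers.
#
# All internal coordinates are 0-based half-open (BED convention); the VCF
# export is the only 1-based surface. Window adjacency is defined by grid
# order within a chromosome, not genomic distance, so masked gaps between
# consecutive windows do not break runs.

#' Construct a window grid
#'
#' The grid of fixed-width analysis windows is the coordinate frame shared by
#' every stage: copy-ratio matrices, calls, events and annotation tracks all
#' refer to its windows by position.
#'
#' @param chrom character vector of chromosome labels, one per window.
#' @param start,end integer vectors of window bounds, 0-based half-open.
#' @param control optional logical vector flagging presumed-diploid
#'   ("control") windows used to calibrate per-sample dispersion.
#' @return A `window_grid`: a data frame with columns `chrom`, `start`,
#'   `end`, `window_index` (0-based ordinal within chromosome) and `control`.
#' @export
window_grid <- function(chrom, start, end, control = NULL) {
  if (length(chrom) != length(start) || length(start) != length(end))
    stop("chrom, start and end must have equal length")
  if (is.null(control)) control <- rep(TRUE, length(chrom))
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   control = as.logical(control),
                   stringsAsFactors = FALSE)
  validate_grid(df)
  df$window_index <- stats::ave(df$start, df$chrom,
                                FUN = function(x) seq_along(x) - 1L)
  df <- df[, c("chrom", "start", "end", "window_index", "control")]
  class(df) <- c("window_grid", "data.frame")
  df
}

validate_grid <- function(df) {
  if (any(df$end <= df$start))
    stop("window with end <= start at record ",
         which(df$end <= df$start)[1])
  widths <- df$end - df$start
  if (length(unique(widths)) > 1)
    stop("windows must share a single width; first deviant record ",
         which(widths != widths[1])[1])
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    if (is.unsorted(sub$start, strictly = TRUE))
      stop("unsorted windows on ", ch, ": first offending record ",
           which(diff(sub$start) <= 0)[1] + 1L)
    if (any(sub$start[-1] < sub$end[-nrow(sub)]))
      stop("overlapping windows on ", ch, ": first offending record ",
           which(sub$start[-1] < sub$end[-nrow(sub)])[1] + 1L)
  }
  invisible(df)
}

#' @return window size in bp of a grid
#' @noRd
grid_window_size <- function(grid) as.integer(grid$end[1] - grid$start[1])

window_ids <- function(grid) {
  paste0(grid$chrom, ":", grid$start, "-", grid$end)
}

#' Read a window grid from BED
#'
#' Expects 3 or 5 columns (chrom, start, end\[, name, control\]); the fifth
#' column, when present, is a 0/1 control-region flag. Windows must be
#' sorted and non-overlapping within each chromosome.
#'
#' @param path path to a BED file (no header).
#' @return A [window_grid()].
#' @export
read_window_grid <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED needs at least 3 columns: ", path)
  control <- if (ncol(df) >= 5) df[[5]] != 0 else NULL
  window_grid(df[[1]], df[[2]], df[[3]], control = control)
}

#' Write a window grid to BED
#'
#' @param grid a [window_grid()].
#' @param path output path; columns are chrom, start, end, window id,
#'   control flag (1 = control region).
#' @export
write_window_grid <- function(grid, path) {
  out <- data.frame(grid$chrom, grid$start, grid$end, window_ids(grid),
                    as.integer(grid$control))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a copy-ratio matrix
#'
#' @param values numeric matrix, samples in rows, grid windows in columns.
#'   Values are continuous copy-number estimates calibrated so diploid
#'   regions average 2.
#' @param sample_ids row labels; defaults to rownames of `values`.
#' @param grid the [window_grid()] the columns refer to.
#' @return A `cr_matrix` object (list with `values`, `sample_ids`, `grid`).
#' @export
cr_matrix <- function(values, grid, sample_ids = rownames(values)) {
  values <- as.matrix(values)
  if (ncol(values) != nrow(grid))
    stop("copy-ratio matrix has ", ncol(values),
         " columns but grid has ", nrow(grid), " windows")
  if (is.null(sample_ids)) stop("sample ids required")
  if (!all(is.finite(values)))
    stop("non-finite copy ratio at sample ",
         sample_ids[which(!is.finite(values), arr.ind = TRUE)[1, 1]])
  rownames(values) <- sample_ids
  colnames(values) <- window_ids(grid)
  structure(list(values = values, sample_ids = sample_ids, grid = grid),
            class = "cr_matrix")
}

#' @export
print.cr_matrix <- function(x, ...) {
  cat("Copy-ratio matrix:", length(x$sample_ids), "samples x",
      nrow(x$grid), "windows (",
      sum(x$grid$control), "control )\n")
  invisible(x)
}

#' Read a copy-ratio matrix from TSV
#'
#' The file has a header row of window identifiers and a leading `sample`
#' column; each further row is one sample's copy ratios in grid order.
#'
#' @param path TSV path.
#' @param grid the grid the columns must match (count check enforced).
#' @return A [cr_matrix()].
#' @export
read_cr_matrix <- function(path, grid) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (ncol(vals) != nrow(grid))
    stop("matrix has ", ncol(vals), " windows but grid has ", nrow(grid))
  cr_matrix(vals, grid, sample_ids = ids)
}

#' Write a copy-ratio matrix to TSV
#' @param mat a [cr_matrix()].
#' @param path output path.
#' @export
write_cr_matrix <- function(mat, path) {
  df <- data.frame(sample = mat$sample_ids, mat$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a breed panel
#'
#' Maps each sample to a breed, each breed to a clade, and tags the sample
#' class (purebred, village dog or wolf). Every sample row of a copy-ratio
#' matrix must have a panel entry.
#'
#' @param sample_id,breed,clade,class character vectors of equal length;
#'   `class` must be one of `"breed-dog"`, `"village"`, `"wolf"`.
#' @return A `breed_panel` data frame.
#' @export
breed_panel <- function(sample_id, breed, clade,
                        class = rep("breed-dog", length(sample_id))) {
  ok <- class %in% c("breed-dog", "village", "wolf")
  if (!all(ok)) stop("unknown sample class: ", class[!ok][1])
  if (anyDuplicated(sample_id))
    stop("duplicated sample id: ", sample_id[duplicated(sample_id)][1])
  df <- data.frame(sample_id = sample_id, breed = breed, clade = clade,
                   class = class, stringsAsFactors = FALSE)
  class(df) <- c("breed_panel", "data.frame")
  df
}

#' Read a sample panel table
#' @param path TSV with header columns sample_id, breed, clade, class.
#' @return A [breed_panel()].
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "breed", "clade", "class")
  if (!all(need %in% names(df)))
    stop("panel must have columns: ", paste(need, collapse = ", "))
  breed_panel(df$sample_id, df$breed, df$clade, df$class)
}

#' Write a sample panel table
#' @param panel a [breed_panel()].
#' @param path output path.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_panel_covers <- function(mat, panel) {
  missing <- setdiff(mat$sample_ids, panel$sample_id)
  if (length(missing))
    stop("sample missing from panel: ", missing[1])
  invisible(TRUE)
}

#' Construct a breed-level phenotype table
#'
#' Breed standards serve as proxy phenotypes: every sample of a breed
#' carries the breed's published trait value.
#'
#' @param values data frame, one row per breed, one column per trait, with a
#'   `breed` column.
#' @param types named character vector mapping trait name to `"continuous"`
#'   or `"categorical"`.
#' @return A `phenotype_table` (list with `values` and `types`).
#' @export
phenotype_table <- function(values, types) {
  if (!"breed" %in% names(values)) stop("values needs a breed column")
  traits <- setdiff(names(values), "breed")
  if (!all(traits %in% names(types)))
    stop("missing type for trait: ",
         setdiff(traits, names(types))[1])
  bad <- !types[traits] %in% c("continuous", "categorical")
  if (any(bad)) stop("unknown trait type: ", types[traits][bad][1])
  for (tr in traits[types[traits] == "categorical"]) {
    if (length(unique(stats::na.omit(values[[tr]]))) < 2)
      stop("categorical trait ", tr, " has fewer than 2 levels")
  }
  structure(list(values = values, types = types[traits]),
            class = "phenotype_table")
}

#' Read a breed phenotype table
#'
#' @param path TSV with header; a `breed` column plus one column per trait.
#'   Trait types are read from a companion row or guessed: numeric columns
#'   are continuous, others categorical.
#' @return A [phenotype_table()].
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!"breed" %in% names(df)) stop("phenotype table needs a breed column")
  traits <- setdiff(names(df), "breed")
  types <- vapply(df[traits], function(x)
    if (is.numeric(x)) "continuous" else "categorical", character(1))
  phenotype_table(df, types)
}

#' Write a breed phenotype table
#' @param pheno a [phenotype_table()].
#' @param path output path.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export CNV events to VCF
#'
#' Writes symbolic-allele records (`<DUP>`/`<DEL>`) with an `END` info key
#' and a per-sample integer copy-number (`CN`) format field. Internal
#' 0-based half-open spans are converted to 1-based VCF coordinates here and
#' nowhere else.
#'
#' @param events a data frame of merged events as returned by
#'   [merge_events()]: columns `chrom`, `start`, `end`, `type`.
#' @param genotypes integer matrix, samples x events, of per-sample copy
#'   numbers (MAP calls over each event).
#' @param path output VCF path.
#' @param reference_name value for the `##reference` header line.
#' @return the path, invisibly.
#' @export
export_vcf <- function(events, genotypes, path, reference_name = "unknown") {
  if (nrow(events) != ncol(genotypes))
    stop("genotypes must have one column per event")
  samples <- rownames(genotypes)
  if (is.null(samples)) stop("genotypes needs sample rownames")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##reference=", reference_name),
    "##ALT=<ID=DUP,Description=\"Copy number gain\">",
    "##ALT=<ID=DEL,Description=\"Copy number loss\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=CN,Number=1,Type=Integer,Description=\"Integer copy number\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  ), con)
  for (i in seq_len(nrow(events))) {
    alt <- if (events$type[i] == "gain") "<DUP>" else "<DEL>"
    svtype <- if (events$type[i] == "gain") "DUP" else "DEL"
    gt <- paste0("./.:", genotypes[, i])
    line <- paste(c(events$chrom[i],
                    events$start[i] + 1L,          # 0-based -> 1-based
                    paste0("cnv_", i), "N", alt, ".", "PASS",
                    paste0("END=", events$end[i], ";SVTYPE=", svtype),
                    "GT:CN", gt), collapse = "\t")
    writeLines(line, con)
  }
  invisible(path)
}
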