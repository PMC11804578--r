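#' plastiscan: past-cue expression plasticity and its fate during adaptation
#'
#' Tools to ask whether plastic gene-expression responses to an ancestral
#' environmental cue (salinity, for coastal populations) are lost, transferred
#' to a novel cue (zinc, at metal-contaminated mine sites), or genetically
#' adopted as constitutive expression changes during rapid parallel
#' adaptation. The package covers the whole analysis path: reading paired
#' count matrices for the salt and zinc experiments, a compact
#' negative-binomial differential-expression engine, the contrast catalog
#' (within-population plasticity, mine-vs-coast divergence, cross-experiment
#' control comparability), gene classification, randomization and proportion
#' tests, and PST-FST screening, plus a synthetic generator that plants gene
#' classes with known directions for end-to-end validation.
#'
#' @importFrom stats median pnorm pchisq p.adjust quantile rnbinom rlnorm
#'   rbeta rbinom runif var sd setNames prop.test
#' @importFrom utils read.delim write.table head modifyList packageVersion
#' @keywords internal
"_PACKAGE"

POPULATIONS <- c("Coast-W", "Mine-W", "Coast-E", "Mine-E")
ECOTYPES <- c("coast", "mine")
PAIRS <- c("W", "E")
TREATMENTS <- c("control", "salt", "zinc")
EXPERIMENTS <- c("salt_expt", "zinc_expt")

#' Construct and validate a count matrix
#'
#' Wraps a genes-by-samples matrix of non-negative integer read counts.
#' Gene and sample identifiers are carried as dimnames and must be unique.
#'
#' @param counts numeric matrix of non-negative integers, genes in rows.
#' @param gene_ids,sample_ids optional identifier vectors; defaults to the
#'   matrix dimnames.
#' @return A validated integer matrix of class `count_matrix`.
#' @export
count_matrix <- function(counts, gene_ids = rownames(counts),
                         sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("count matrix needs gene and sample identifiers", call. = FALSE)
  rownames(counts) <- as.character(gene_ids)
  colnames(counts) <- as.character(sample_ids)
  validate_count_matrix(counts)
  storage.mode(counts) <- "integer"
  class(counts) <- c("count_matrix", class(counts))
  counts
}

validate_count_matrix <- function(counts) {
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("count matrix must have at least 2 genes and 2 samples",
         call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene identifiers in count matrix", call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers in count matrix", call. = FALSE)
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric and non-missing", call. = FALSE)
  if (any(counts < 0))
    stop("negative values in count matrix", call. = FALSE)
  if (any(counts != round(counts)))
    stop("non-integer values in count matrix", call. = FALSE)
  invisible(counts)
}

#' Validate a sample sheet against a count matrix
#'
#' The sheet must describe every sample column exactly once, use the
#' fixed population/ecotype/pair vocabulary, keep treatments inside their
#' experiment (salt only in the salt experiment, zinc only in the zinc
#' experiment) and provide both treatments for every population within
#' each experiment present.
#'
#' @param sheet data.frame with columns `sample_id`, `population`,
#'   `ecotype`, `pair`, `individual`, `treatment`, `experiment`.
#' @param cm optional `count_matrix` to cross-check sample ids against.
#' @return The sheet, invisibly, with character columns.
#' @export
validate_sample_sheet <- function(sheet, cm = NULL) {
  needed <- c("sample_id", "population", "ecotype", "pair", "individual",
              "treatment", "experiment")
  missing_cols <- setdiff(needed, names(sheet))
  if (length(missing_cols))
    stop("sample sheet is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in needed) sheet[[col]] <- as.character(sheet[[col]])
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet", call. = FALSE)
  bad <- function(col, allowed) {
    v <- setdiff(unique(sheet[[col]]), allowed)
    if (length(v))
      stop("invalid ", col, " value(s): ", paste(v, collapse = ", "),
           call. = FALSE)
  }
  bad("population", POPULATIONS)
  bad("ecotype", ECOTYPES)
  bad("pair", PAIRS)
  bad("treatment", TREATMENTS)
  bad("experiment", EXPERIMENTS)
  if (any(sheet$treatment == "salt" & sheet$experiment != "salt_expt") ||
      any(sheet$treatment == "zinc" & sheet$experiment != "zinc_expt"))
    stop("treatment 'salt' belongs to salt_expt and 'zinc' to zinc_expt",
         call. = FALSE)
  for (ex in unique(sheet$experiment)) {
    sub <- sheet[sheet$experiment == ex, ]
    cue <- if (ex == "salt_expt") "salt" else "zinc"
    for (pop in unique(sub$population)) {
      trt <- unique(sub$treatment[sub$population == pop])
      if (!all(c("control", cue) %in% trt))
        stop("population ", pop, " lacks both treatments in ", ex,
             call. = FALSE)
    }
  }
  if (!is.null(cm)) {
    absent <- setdiff(colnames(cm), sheet$sample_id)
    if (length(absent))
      stop("sample(s) in count matrix absent from sheet: ",
           paste(absent, collapse = ", "), call. = FALSE)
  }
  invisible(sheet)
}

#' Read a count matrix and sample sheet for one experiment
#'
#' The counts file is TSV or CSV (sniffed from the extension; `.csv` means
#' comma) with a `gene_id` first column and one column per sample. The
#' sheet is TSV with the standard columns. The two are cross-checked: every
#' matrix column must appear in the sheet.
#'
#' @param counts_path path to the counts table.
#' @param sheet_path path to the sample sheet.
#' @return list with elements `counts` (a `count_matrix`) and `sheet`.
#' @export
read_experiment <- function(counts_path, sheet_path) {
  cm <- read_counts(counts_path)
  sheet <- read_sample_sheet(sheet_path)
  validate_sample_sheet(sheet, cm)
  list(counts = cm, sheet = sheet)
}

#' @rdname read_experiment
#' @export
read_counts <- function(counts_path) {
  if (!file.exists(counts_path))
    stop("counts file not found: ", counts_path, call. = FALSE)
  sep <- if (grepl("\\.csv$", counts_path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(counts_path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "gene_id")
    stop("first column of counts file must be 'gene_id'", call. = FALSE)
  if (anyDuplicated(tab$gene_id))
    stop("duplicate gene id in counts file", call. = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene_id
  count_matrix(m)
}

#' @rdname read_experiment
#' @export
read_sample_sheet <- function(sheet_path) {
  if (!file.exists(sheet_path))
    stop("sample sheet not found: ", sheet_path, call. = FALSE)
  sheet <- utils::read.delim(sheet_path, stringsAsFactors = FALSE,
                             colClasses = "character")
  validate_sample_sheet(sheet)
  sheet
}

#' Read a genome-wide FST distribution for one population pair
#'
#' Single-column TSV (header `fst`, or headerless) of differentiation
#' values in \[0, 1\].
#'
#' @param path file path.
#' @param pair population pair label ("W" or "E").
#' @return object of class `fst_distribution`: list with `pair`, `values`.
#' @export
read_fst <- function(path, pair) {
  if (!file.exists(path)) stop("FST file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  header <- is.na(suppressWarnings(as.numeric(first)))
  v <- utils::read.delim(path, header = header,
                         stringsAsFactors = FALSE)[[1]]
  fst_distribution(pair, as.numeric(v))
}

#' @rdname read_fst
#' @param values numeric vector of FST values.
#' @export
fst_distribution <- function(pair, values) {
  if (!length(values)) stop("empty FST distribution", call. = FALSE)
  if (anyNA(values) || any(values < 0 | values > 1))
    stop("FST values must lie in [0, 1]", call. = FALSE)
  structure(list(pair = as.character(pair), values = as.numeric(values)),
            class = "fst_distribution")
}

#' Remove genes with insufficient counts
#'
#' Default mode (`mode = "any"`) drops a gene when any sample count falls
#' below `min_count`, the stricter reading that keeps the matrix
#' rectangular. `mode = "total"` instead drops genes whose summed count
#' across samples is below `min_count`.
#'
#' @param cm a `count_matrix`.
#' @param min_count non-negative count floor (default 10).
#' @param mode `"any"` (per-sample floor) or `"total"` (sum floor).
#' @return The filtered `count_matrix`.
#' @export
low_count_filter <- function(cm, min_count = 10L, mode = c("any", "total")) {
  mode <- match.arg(mode)
  stopifnot(min_count >= 0)
  keep <- if (mode == "any") {
    apply(cm >= min_count, 1L, all)
  } else {
    rowSums(cm) >= min_count
  }
  if (!any(keep))
    stop("low_count_filter removed every gene", call. = FALSE)
  out <- cm[keep, , drop = FALSE]
  class(out) <- c("count_matrix", "matrix", "array")
  out
}

#' Analysis configuration
#'
#' @param alpha significance level for direction calls (default 0.05).
#' @param min_count per-sample count floor for [low_count_filter()].
#' @param n_permutations permutations for randomization tests.
#' @param bootstrap_reps bootstrap replicates for PST intervals.
#' @param c_over_h2 PST scalar c/h^2 (default 1, the conservative
#'   convention when heritability is unknown).
#' @param seed integer seed controlling all randomness.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(alpha = 0.05, min_count = 10L,
                            n_permutations = 1000L, bootstrap_reps = 200L,
                            c_over_h2 = 1, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, n_permutations >= 1, c_over_h2 > 0,
            min_count >= 0, bootstrap_reps >= 0)
  structure(list(alpha = alpha, min_count = as.integer(min_count),
                 n_permutations = as.integer(n_permutations),
                 bootstrap_reps = as.integer(bootstrap_reps),
                 c_over_h2 = c_over_h2, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Write result tables and run metadata to a directory
#'
#' Each table becomes `<name>.tsv` (tab-separated, header row, `NA` for
#' missing). A `run_metadata.yaml` snapshot of the configuration and seed
#' is written alongside.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if needed).
#' @param config optional `analysis_config` recorded in the metadata file.
#' @return Invisibly, a character vector of written file paths (the
#'   manifest), named by table.
#' @export
write_results <- function(tables, out_dir, config = NULL) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, mode = 2L) != 0L)
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(tables[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    paths[nm] <- p
  }
  meta <- list(written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
               package_version = as.character(utils::packageVersion("plastiscan")),
               tables = names(tables))
  if (!is.null(config)) meta$config <- unclass(config)
  meta_path <- file.path(out_dir, "run_metadata.yaml")
  yaml::write_yaml(meta, meta_path)
  paths["run_metadata"] <- meta_path
  invisible(paths)
}

#' Read back a TSV result table written by [write_results()]
#' @param path file path.
#' @return data.frame.
#' @export
read_result_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

# round half away from zero at `digits` decimals (R's round() is half-even)
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
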