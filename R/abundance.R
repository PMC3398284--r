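#' Strain-by-sample abundance dataset
#'
#' Container for an abundance matrix (strains x samples, arbitrary units,
#' nonnegative) plus its sample sheet. The sample sheet must have one row per
#' matrix column with columns `sample_id`, `experiment`, `bio_rep`,
#' `tech_rep` and `time_h` (hours; continuous-culture start = 0).
#'
#' @param matrix Numeric matrix, strains x samples; rownames are strain ids.
#' @param samples Data frame of sample metadata, rows aligned to columns.
#' @return An object of class `abundance_dataset` with elements `matrix`,
#'   `strains` and `samples`.
#' @export
abundance_dataset <- function(matrix, samples) {
  required <- c("sample_id", "experiment", "bio_rep", "tech_rep", "time_h")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols))
    stop("sample sheet lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (ncol(matrix) != nrow(samples))
    stop("matrix has ", ncol(matrix), " columns but sample sheet has ",
         nrow(samples), " rows", call. = FALSE)
  if (is.null(rownames(matrix)))
    stop("matrix must have strain ids as rownames", call. = FALSE)
  if (anyDuplicated(rownames(matrix)))
    stop("duplicate strain ids", call. = FALSE)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample ids", call. = FALSE)
  if (!is.null(colnames(matrix))) {
    bad <- colnames(matrix) != samples$sample_id
    if (any(bad))
      stop("matrix columns do not match sample sheet: ",
           paste(colnames(matrix)[bad], collapse = ", "), call. = FALSE)
  } else colnames(matrix) <- samples$sample_id
  if (any(!is.finite(matrix)) || any(matrix < 0))
    stop("abundance values must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(samples$time_h)))
    stop("every sample needs a finite time_h", call. = FALSE)
  rownames(samples) <- NULL
  structure(list(matrix = matrix, strains = rownames(matrix),
                 samples = samples),
            class = "abundance_dataset")
}

#' @export
print.abundance_dataset <- function(x, ...) {
  cat("abundance_dataset:", nrow(x$matrix), "strains x", ncol(x$matrix),
      "samples\n")
  cat("experiments:", paste(unique(x$samples$experiment), collapse = ", "),
      "\n")
  cat("times (h):", paste(sort(unique(x$samples$time_h)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Read an abundance dataset from TSV files
#'
#' The matrix file is tab-delimited with a header row: first column strain
#' ids, remaining columns one per sample. The sample sheet is tab-delimited
#' with columns `sample_id`, `experiment`, `bio_rep`, `tech_rep`, `time_h`.
#' Matrix columns must match sample-sheet rows one-to-one; mismatches are
#' reported by name.
#'
#' @param matrix_path,samplesheet_path Paths to the two TSV files.
#' @return An [abundance_dataset()].
#' @export
read_dataset <- function(matrix_path, samplesheet_path) {
  for (p in c(matrix_path, samplesheet_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  tab <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  samples <- utils::read.delim(samplesheet_path, check.names = FALSE,
                               stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab[[1]]
  storage.mode(mat) <- "double"
  only_mat <- setdiff(colnames(mat), samples$sample_id)
  only_sheet <- setdiff(samples$sample_id, colnames(mat))
  if (length(only_mat) || length(only_sheet))
    stop("sample mismatch; matrix-only: [",
         paste(only_mat, collapse = ", "), "] sheet-only: [",
         paste(only_sheet, collapse = ", "), "]", call. = FALSE)
  mat <- mat[, samples$sample_id, drop = FALSE]
  abundance_dataset(mat, samples)
}

#' Write an abundance dataset to TSV files
#'
#' @param dataset An [abundance_dataset()].
#' @param matrix_path,samplesheet_path Output paths.
#' @return `dataset`, invisibly.
#' @export
write_dataset <- function(dataset, matrix_path, samplesheet_path) {
  stopifnot(inherits(dataset, "abundance_dataset"))
  tab <- data.frame(strain_id = dataset$strains,
                    dataset$matrix, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dataset$samples, samplesheet_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dataset)
}

#' Normalise abundances to within-sample relative abundance
#'
#' Adds `pseudocount` to every cell, then divides each sample column by its
#' total, so columns sum to 1. The pseudocount (default 0 here; the fitting
#' step uses 0.5) keeps zero counts finite after log transformation.
#'
#' @param dataset An [abundance_dataset()].
#' @param pseudocount Nonnegative value added to every cell before scaling.
#' @return A new [abundance_dataset()] of relative abundances.
#' @export
normalize_relative <- function(dataset, pseudocount = 0) {
  stopifnot(inherits(dataset, "abundance_dataset"))
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  m <- dataset$matrix + pseudocount
  tot <- colSums(m)
  if (any(tot == 0)) {
    bad <- colnames(m)[tot == 0]
    stop("all-zero sample column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  abundance_dataset(sweep(m, 2, tot, "/"), dataset$samples)
}

#' Remove listed strains from a dataset
#'
#' Drops strains on an exclusion list (e.g. mutants known to carry secondary
#' aberrations) before fitting. Ids absent from the dataset are ignored with
#' a warning; the number of strains removed is reported.
#'
#' @param dataset An [abundance_dataset()].
#' @param exclusion_list Character vector of strain ids to remove.
#' @return The dataset without the excluded strains.
#' @export
apply_exclusions <- function(dataset, exclusion_list) {
  stopifnot(inherits(dataset, "abundance_dataset"))
  exclusion_list <- unique(as.character(exclusion_list))
  unknown <- setdiff(exclusion_list, dataset$strains)
  if (length(unknown))
    warning(length(unknown), " excluded id(s) not present in dataset: ",
            paste(utils::head(unknown, 5), collapse = ", "),
            if (length(unknown) > 5) ", ...")
  keep <- !(dataset$strains %in% exclusion_list)
  message("apply_exclusions: removed ", sum(!keep), " of ",
          length(keep), " strains")
  abundance_dataset(dataset$matrix[keep, , drop = FALSE], dataset$samples)
}

#' Read an exclusion list (one strain id per line)
#'
#' @param path Text file path.
#' @return Character vector of strain ids.
#' @export
read_exclusion_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ids <- readLines(path)
  ids[nzchar(trimws(ids))]
}
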