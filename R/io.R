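#' Construct an omics block
#'
#' A single omics layer: a numeric matrix of `N` samples by `D` features.
#' Missing values are rejected at construction; upstream loaders must drop
#' or impute before building a block.
#'
#' @param name short label, e.g. `"mrna"`.
#' @param values numeric matrix, samples in rows.
#' @param feature_ids optional feature identifiers (default: column names).
#' @return An object of class `omics_block`.
#' @export
omics_block <- function(name, values, feature_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop_data("block '", name, "': values must be numeric")
  if (anyNA(values) || any(!is.finite(values))) {
    stop_data("block '", name, "' contains missing or non-finite entries")
  }
  if (nrow(values) < 2) stop_data("block '", name, "' needs at least 2 samples")
  if (ncol(values) < 1) stop_data("block '", name, "' needs at least 1 feature")
  feature_ids <- feature_ids %||% paste0(name, "_f", seq_len(ncol(values)))
  if (length(feature_ids) != ncol(values)) {
    stop_data("block '", name, "': feature_ids length does not match feature count")
  }
  colnames(values) <- feature_ids
  structure(list(name = name, values = values, feature_ids = feature_ids),
            class = "omics_block")
}

#' Construct a multi-omics dataset
#'
#' Bundles one or more [omics_block()]s that share the same samples in the
#' same row order.
#'
#' @param blocks list of `omics_block` objects.
#' @param sample_ids character vector of unique sample identifiers, one per row.
#' @return An object of class `omics_dataset`.
#' @export
omics_dataset <- function(blocks, sample_ids) {
  if (length(blocks) < 1) stop_data("need at least one omics block")
  n <- nrow(blocks[[1]]$values)
  for (b in blocks) {
    if (!inherits(b, "omics_block")) stop_data("blocks must be omics_block objects")
    if (nrow(b$values) != n) {
      stop_data("block '", b$name, "' has ", nrow(b$values), " rows; expected ", n)
    }
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n) stop_data("sample_ids length does not match row count")
  if (anyDuplicated(sample_ids)) stop_data("sample_ids must be unique")
  for (i in seq_along(blocks)) rownames(blocks[[i]]$values) <- sample_ids
  names(blocks) <- vapply(blocks, function(b) b$name, character(1))
  structure(list(blocks = blocks, sample_ids = sample_ids),
            class = "omics_dataset")
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat("omics_dataset:", length(x$sample_ids), "samples,",
      length(x$blocks), "blocks\n")
  for (b in x$blocks) cat("  ", b$name, ": ", ncol(b$values), " features\n", sep = "")
  invisible(x)
}

#' @export
dim.omics_dataset <- function(x) {
  c(length(x$sample_ids), sum(vapply(x$blocks, function(b) ncol(b$values), 1L)))
}

block_matrices <- function(data) lapply(data$blocks, function(b) b$values)

block_widths <- function(data) {
  vapply(data$blocks, function(b) ncol(b$values), integer(1))
}

#' Read aligned multi-omics matrices from delimited text
#'
#' Each file holds one omics block: a header row of feature IDs and a first
#' column of sample IDs. Blocks are row-aligned on the intersection of
#' sample IDs across files, preserving the sample order of the first file;
#' dropped samples are reported via `message()`.
#'
#' @param paths character vector of file paths, one per block.
#' @param delimiter field separator (default tab).
#' @param block_names labels for the blocks; defaults to file base names.
#' @return An [omics_dataset()].
#' @export
read_omics <- function(paths, delimiter = "\t", block_names = NULL) {
  if (length(paths) < 1) stop_data("no input files given")
  block_names <- block_names %||%
    sub("\\.[^.]*$", "", basename(paths))
  raw <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    df <- utils::read.table(paths[i], sep = delimiter, header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            row.names = NULL)
    ids <- as.character(df[[1]])
    m <- df[, -1, drop = FALSE]
    for (j in seq_len(ncol(m))) {
      col <- m[[j]]
      if (!is.numeric(col)) {
        bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1]
        stop_data("non-numeric value in file '", paths[i], "', row ",
                  if (is.na(bad)) "?" else bad, ", column '", colnames(m)[j], "'")
      }
    }
    mm <- as.matrix(m)
    if (anyNA(mm)) {
      idx <- which(is.na(mm), arr.ind = TRUE)[1, ]
      stop_data("missing value in file '", paths[i], "', row ", idx[1],
                ", column '", colnames(mm)[idx[2]], "'")
    }
    rownames(mm) <- ids
    raw[[i]] <- mm
  }
  common <- rownames(raw[[1]])
  for (i in seq_along(raw)[-1]) common <- common[common %in% rownames(raw[[i]])]
  if (length(common) == 0) {
    stop(errorCondition("no samples shared across all input files",
                        class = c("sadln_alignment_error", "sadln_data_error", "error")))
  }
  dropped <- setdiff(unique(unlist(lapply(raw, rownames))), common)
  if (length(dropped) > 0) {
    message("read_omics: dropped ", length(dropped),
            " samples absent from some blocks: ",
            paste(utils::head(dropped, 10), collapse = ", "),
            if (length(dropped) > 10) ", ..." else "")
  }
  blocks <- lapply(seq_along(raw), function(i) {
    omics_block(block_names[i], raw[[i]][common, , drop = FALSE])
  })
  omics_dataset(blocks, common)
}

#' Write an omics dataset as delimited text, one file per block
#'
#' @param data an [omics_dataset()].
#' @param dir output directory (created if absent).
#' @param delimiter field separator.
#' @return Invisibly, the written file paths.
#' @export
write_omics <- function(data, dir, delimiter = "\t") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(data$blocks))
  for (i in seq_along(data$blocks)) {
    b <- data$blocks[[i]]
    paths[i] <- file.path(dir, paste0(b$name, ".tsv"))
    df <- data.frame(sample_id = data$sample_ids, b$values, check.names = FALSE)
    utils::write.table(df, paths[i], sep = delimiter, quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}

#' Construct a clinical table
#'
#' Survival and clinical covariates per sample. `time` is a nonnegative
#' follow-up duration, `event` is 1 for an observed death and 0 for
#' censoring. Additional columns are clinical labels (numeric or
#' categorical); missing entries are allowed there and are dropped per-label
#' at test time.
#'
#' @param sample_ids character vector of sample identifiers.
#' @param time nonnegative survival/follow-up times.
#' @param event 0/1 event indicators.
#' @param labels optional data.frame of clinical label columns.
#' @return A data.frame of class `clinical_table`.
#' @export
clinical_table <- function(sample_ids, time, event, labels = NULL) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop_data("clinical sample_ids must be unique")
  if (any(is.na(time)) || any(time < 0)) stop_data("survival times must be >= 0")
  if (!all(event %in% c(0, 1))) stop_data("event must be 0 or 1")
  df <- data.frame(sample_id = sample_ids, time = as.numeric(time),
                   event = as.integer(event), stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    if (nrow(labels) != length(sample_ids)) stop_data("labels row count mismatch")
    df <- cbind(df, labels)
  }
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Read a clinical table from TSV
#'
#' Requires columns `sample_id`, `time`, `event`; any further columns become
#' clinical labels.
#' @param path file path.
#' @param delimiter field separator.
#' @return A `clinical_table`.
#' @export
read_clinical <- function(path, delimiter = "\t") {
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% colnames(df))) {
    stop_data("clinical table must have columns: ", paste(need, collapse = ", "))
  }
  extra <- df[, setdiff(colnames(df), need), drop = FALSE]
  clinical_table(df$sample_id, df$time, df$event,
                 labels = if (ncol(extra) > 0) extra else NULL)
}

#' Write a clinical table to TSV
#' @param clinical a `clinical_table`.
#' @param path output file path.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align a clinical table to a dataset's samples by identifier
#'
#' Matching is by `sample_id`, never by position.
#' @param clinical a `clinical_table`.
#' @param sample_ids identifiers, typically `data$sample_ids`.
#' @return The clinical rows reordered to `sample_ids`.
#' @export
align_clinical <- function(clinical, sample_ids) {
  idx <- match(sample_ids, clinical$sample_id)
  if (anyNA(idx)) {
    stop_data(sum(is.na(idx)), " samples have no clinical record")
  }
  out <- clinical[idx, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("clinical_table", "data.frame")
  out
}
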