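# Tabular I/O: connectivity matrices in CSV/TSV (matrix or long layout),
# result bundles as a JSON manifest plus per-table CSVs.

delim_for <- function(path) if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","

read_table_checked <- function(path, header, sep) {
  raw <- utils::read.table(path, header = header, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           row.names = NULL, quote = "\"")
  raw
}

matrix_from_table <- function(tab, header) {
  first_col_labels <- !is.numeric(tab[[1]])
  if (first_col_labels) {
    labels_r <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- labels_r
  } else {
    m <- as.matrix(tab)
  }
  suppressWarnings(storage.mode(m) <- "double")
  if (anyNA(m)) stopf("non-numeric or missing cells in matrix file")
  m
}

#' Read a connectivity matrix from CSV/TSV
#'
#' Reads a square labelled weight matrix and returns a [connectome] in the
#' canonical source-rows x target-columns orientation. TSV is auto-detected
#' from the file extension. Files written target x source can be normalised
#' via `orientation = "target_source"`. Missing labels are replaced by
#' `"R01"`, `"R02"`, ...; duplicate labels are an error.
#'
#' @param path file path.
#' @param orientation `"source_target"` (default) or `"target_source"`
#'   (the matrix is transposed on read).
#' @param header does the file carry a header row of labels?
#' @param k_in_ext optional external in-degree vector passed through to
#'   [connectome].
#' @return A [connectome].
#' @examples
#' path <- system.file("extdata", "toy7_weights.csv", package = "strengthnet")
#' read_connectome_csv(path)
#' @export
read_connectome_csv <- function(path, orientation = c("source_target", "target_source"),
                                header = TRUE, k_in_ext = NULL) {
  orientation <- match.arg(orientation)
  tab <- read_table_checked(path, header, delim_for(path))
  m <- matrix_from_table(tab, header)
  if (nrow(m) != ncol(m)) stopf("expected a square matrix, got %d x %d", nrow(m), ncol(m))
  if (is.null(rownames(m)) && !is.null(colnames(m))) rownames(m) <- colnames(m)
  if (orientation == "target_source") m <- t(m)
  labels <- rownames(m) %||% colnames(m)
  if (!is.null(labels) && anyDuplicated(labels)) stopf("duplicate region labels in %s", path)
  connectome(m, labels = labels, k_in_ext = k_in_ext,
             meta = list(source = path, orientation = orientation))
}

#' Read a raw tracing table from CSV/TSV
#'
#' Supports both layouts distributed for tract-tracing data: a sources x
#' targets count matrix (`layout = "matrix"`), or a long table with columns
#' `source`, `target`, `count` (`layout = "long"`). Returns a [raw_tracing]
#' in the canonical orientation.
#'
#' @param path file path.
#' @param layout `"matrix"` or `"long"`.
#' @param orientation for the matrix layout, whether rows are sources
#'   (default) or targets.
#' @param neurons_ext optional per-target extrinsic-neuron totals.
#' @return A [raw_tracing].
#' @export
read_tracing_csv <- function(path, layout = c("matrix", "long"),
                             orientation = c("source_target", "target_source"),
                             neurons_ext = NULL) {
  layout <- match.arg(layout)
  orientation <- match.arg(orientation)
  if (layout == "matrix") {
    tab <- read_table_checked(path, TRUE, delim_for(path))
    m <- matrix_from_table(tab, TRUE)
    if (orientation == "target_source") m <- t(m)
    return(raw_tracing(m, neurons_ext = neurons_ext))
  }
  tab <- read_table_checked(path, TRUE, delim_for(path))
  need <- c("source", "target", "count")
  if (!all(need %in% names(tab)))
    stopf("long layout needs columns %s", paste(need, collapse = ", "))
  if (!is.numeric(tab$count)) stopf("non-numeric counts in %s", path)
  sources <- sort(unique(tab$source))
  targets <- sort(unique(tab$target))
  m <- matrix(0, length(sources), length(targets),
              dimnames = list(sources, targets))
  dup <- duplicated(tab[, c("source", "target")])
  if (any(dup)) stopf("duplicate source/target rows in %s", path)
  m[cbind(match(tab$source, sources), match(tab$target, targets))] <- tab$count
  raw_tracing(m, neurons_ext = neurons_ext)
}

#' Write a result bundle to disk
#'
#' Serialises a pipeline result bundle as a JSON manifest (`manifest.json`:
#' scalar metrics, null summaries, partitions, config and seeds, with 17
#' significant digits so floats round-trip) plus one CSV per table (rich-club
#' curves, morphospace points, coupling-sweep tables) in `dir`.
#'
#' @param bundle a `result_bundle` from [run_all] (or a compatible list).
#' @param dir output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  manifest <- bundle[setdiff(names(bundle), "tables")]
  mpath <- file.path(dir, "manifest.json")
  # 17 significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null")
  paths <- c(paths, mpath)
  for (tname in names(bundle$tables %||% list())) {
    tpath <- file.path(dir, paste0(tname, ".csv"))
    utils::write.csv(bundle$tables[[tname]], tpath, row.names = FALSE)
    paths <- c(paths, tpath)
  }
  invisible(paths)
}

#' Read a result bundle written by [write_report]
#'
#' @param dir directory containing `manifest.json` and table CSVs.
#' @return A list with the manifest fields and a `tables` list of data frames.
#' @export
read_report <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stopf("no manifest.json under %s", dir)
  bundle <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  csvs <- setdiff(list.files(dir, pattern = "\\.csv$"), "manifest.json")
  tables <- lapply(csvs, function(f)
    utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE))
  names(tables) <- sub("\\.csv$", "", csvs)
  bundle$tables <- tables
  bundle
}
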