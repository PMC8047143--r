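#' @include AllClasses.R
NULL

#' Read one subject's ROI time series from delimited text
#'
#' Expects rows = time points and columns = regions, with an optional
#' header of region names. The delimiter is sniffed from the extension
#' (".tsv"/".txt" = tab, otherwise comma).
#'
#' @param path file path.
#' @param subjectId subject identifier (default: file name without
#'   extension).
#' @param label binary label (default NA).
#' @return A [RoiTimeSeries-class].
#' @export
readTimeSeries <- function(path,
                           subjectId = sub("\\.[^.]*$", "", basename(path)),
                           label = NA_integer_) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  first <- readLines(path, n = 1L)
  hasHeader <- anyNA(suppressWarnings(
    as.numeric(strsplit(first, sep, fixed = TRUE)[[1L]])))
  d <- utils::read.table(path, header = hasHeader, sep = sep)
  RoiTimeSeries(as.matrix(d), subjectId, label)
}

#' Read a cohort from a manifest
#'
#' The manifest is a CSV with columns `subject_id`, `path` and `label`
#' (paths relative to the manifest's directory, or absolute).
#'
#' @param manifestPath path to the manifest CSV.
#' @return List of [RoiTimeSeries-class] objects.
#' @export
readCohort <- function(manifestPath) {
  m <- utils::read.csv(manifestPath, stringsAsFactors = FALSE)
  need <- c("subject_id", "path", "label")
  if (!all(need %in% names(m)))
    stop(sprintf("manifest must have columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  base <- dirname(manifestPath)
  lapply(seq_len(nrow(m)), function(i) {
    p <- m$path[i]
    if (!file.exists(p)) p <- file.path(base, p)
    readTimeSeries(p, m$subject_id[i], as.integer(m$label[i]))
  })
}

#' Write a cohort as per-subject CSV files plus a manifest
#'
#' @param cohort a list as returned by [sampleCohort()], or a plain list of
#'   [RoiTimeSeries-class] objects.
#' @param dir output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  subjects <- if (is.list(cohort) && !is.null(cohort$subjects))
    cohort$subjects else cohort
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(subjects, function(s) {
    f <- paste0(subjectId(s), ".csv")
    utils::write.csv(tsMatrix(s), file.path(dir, f), row.names = FALSE)
    data.frame(subject_id = subjectId(s), path = f,
               label = subjectLabel(s), stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}

#' Write the window matrices of a dynamic network as delimited text
#'
#' One CSV per window, named `<subjectId>_win<k>.csv`.
#'
#' @param net a [DynamicNetwork-class].
#' @param dir output directory (created if absent).
#' @return Character vector of file paths, invisibly.
#' @export
writeDynamicNetwork <- function(net, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_along(net@matrices), function(k) {
    f <- file.path(dir, sprintf("%s_win%03d.csv", net@subjectId, k))
    utils::write.csv(net@matrices[[k]], f, row.names = FALSE)
    f
  }, character(1))
  invisible(paths)
}
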