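#' Read a single-channel amplitude file
#'
#' Reads one channel in the plain-text convention of the benchmark EEG
#' corpus: one amplitude value per line (integer or decimal, microvolts),
#' surrounding whitespace and CRLF line endings tolerated, blank lines
#' ignored.
#'
#' @param path path to the channel file; the channel id is the file stem.
#' @return named list with `channelId` (character) and `samples` (numeric
#'   vector in file order).
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("12", "-7", "3"), f)
#' readChannelFile(f)$samples
#' @export
readChannelFile <- function(path) {
    if (!file.exists(path))
        stop("cannot read channel file: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("\r$", "", lines)
    keep <- nzchar(trimws(lines))
    if (!any(keep))
        stop("channel file is empty: ", path)
    idx <- which(keep)
    vals <- suppressWarnings(as.numeric(trimws(lines[idx])))
    if (anyNA(vals))
        stop(sprintf("non-numeric value in '%s' at line %d: '%s'",
                     path, idx[which(is.na(vals))[1L]],
                     lines[idx[which(is.na(vals))[1L]]]))
    list(channelId = sub("\\.[^.]*$", "", basename(path)), samples = vals)
}

#' Load a directory of channel files as one recording
#'
#' Every regular file in `directory` is read with [readChannelFile()];
#' channels are ordered lexicographically by filename so the assembled
#' recording is deterministic for a given directory content.
#'
#' @param directory directory containing one file per channel.
#' @param setId set identifier (for "A".."E" the class label is implied).
#' @param classLabel diagnostic class, defaulting from `setId`.
#' @param durationSeconds recording duration (default 23.6 s).
#' @return An [EEGRecording-class].
#' @export
loadSignalSet <- function(directory, setId, classLabel = NULL,
                          durationSeconds = 23.6) {
    if (!dir.exists(directory))
        stop("no such directory: ", directory)
    files <- list.files(directory, full.names = TRUE)
    files <- files[!dir.exists(files)]
    if (!length(files))
        stop("no channel files found in ", directory)
    files <- files[order(basename(files), method = "radix")]
    chans <- lapply(files, readChannelFile)
    len <- vapply(chans, function(ch) length(ch$samples), integer(1))
    if (length(unique(len)) > 1L) {
        bad <- basename(files)[len != stats::median(len)]
        stop("channel files differ in length (",
             paste(unique(len), collapse = ", "), "); offending: ",
             paste(bad, collapse = ", "))
    }
    m <- vapply(chans, function(ch) ch$samples, numeric(len[1L]))
    if (is.null(dim(m))) m <- matrix(m, nrow = len[1L])
    colnames(m) <- vapply(chans, function(ch) ch$channelId, character(1))
    EEGRecording(m, setId = setId, classLabel = classLabel,
                 durationSeconds = durationSeconds)
}

#' Persist a recording in the one-file-per-channel layout
#'
#' Writes each channel of `rec` as a plain-text file (one value per line)
#' under `directory`, readable back with [loadSignalSet()].
#'
#' @param rec an [EEGRecording-class].
#' @param directory output directory (created if needed).
#' @param digits significant digits kept for real-valued amplitudes.
#' @return invisibly, the vector of file paths written.
#' @export
writeSignalSet <- function(rec, directory, digits = 6L) {
    dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    m <- signalMatrix(rec)
    paths <- file.path(directory, paste0(colnames(m), ".txt"))
    for (j in seq_len(ncol(m)))
        writeLines(format(m[, j], digits = digits, trim = TRUE,
                          scientific = FALSE), paths[j])
    invisible(paths)
}

#' Write / read a feature matrix as CSV
#'
#' The CSV carries the eleven feature columns (named as [featureNames()]),
#' a `class` column and a `set` column; reading back reproduces values,
#' labels and order exactly (full stored precision).
#'
#' @param fm a [FeatureMatrix-class].
#' @param path CSV file path.
#' @return `writeFeatureMatrix` invisibly returns `path`;
#'   `readFeatureMatrix` returns a [FeatureMatrix-class].
#' @export
writeFeatureMatrix <- function(fm, path) {
    df <- as.data.frame(featureValues(fm))
    df$class <- as.character(classLabels(fm))
    df$set <- setIds(fm)
    utils::write.csv(format(df, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path) {
    if (!file.exists(path))
        stop("cannot read feature matrix: ", path)
    df <- utils::read.csv(path, check.names = FALSE)
    need <- c(.FEATURE_NAMES, "class", "set")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("feature CSV is missing required column(s): ",
             paste(miss, collapse = ", "))
    vals <- as.matrix(df[, .FEATURE_NAMES, drop = FALSE])
    FeatureMatrix(vals, classLabels = df$class, setIds = df$set)
}
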