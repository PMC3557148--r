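## Constructors and delimited-text I/O. All tables are TSV with a
## header row; probes/clusters are rows, arrays are columns; floats are
## written with full (17 significant digit) precision so round-trips
## are lossless well past 12 significant digits.

#' Construct a ProbeMatrix
#'
#' @param values numeric matrix, probes x arrays, with dimnames.
#' @param scale "linear" (raw) or "log2" (preprocessed).
#' @return a validated [ProbeMatrix-class].
#' @export
ProbeMatrix <- function(values, scale = c("linear", "log2")) {
    scale <- match.arg(scale)
    new("ProbeMatrix", values = values, scale = scale)
}

#' Construct a ProbeAnnotation
#'
#' @param ann data.frame with columns probe_id, cluster_id, probe_type,
#'   position_index, transcript_length_bp.
#' @return a validated [ProbeAnnotation-class].
#' @export
ProbeAnnotation <- function(ann) {
    ann$probe_id <- as.character(ann$probe_id)
    ann$cluster_id <- as.character(ann$cluster_id)
    ann$probe_type <- as.character(ann$probe_type)
    ann$position_index <- as.integer(ann$position_index)
    ann$transcript_length_bp <- as.numeric(ann$transcript_length_bp)
    new("ProbeAnnotation", ann = ann)
}

#' Construct a SampleMetadata
#'
#' @param info data.frame with columns array_id, patient_id, condition,
#'   batch, rin, a260_230.
#' @return a validated [SampleMetadata-class].
#' @export
SampleMetadata <- function(info) {
    info$array_id <- as.character(info$array_id)
    info$patient_id <- as.character(info$patient_id)
    info$condition <- as.character(info$condition)
    info$batch <- as.character(info$batch)
    new("SampleMetadata", info = info)
}

#' Read a probe intensity matrix from TSV
#'
#' First column is the probe id, remaining columns one array each.
#'
#' @param path TSV file path.
#' @param scale "linear" or "log2".
#' @return a validated [ProbeMatrix-class]; row and column order of the
#'   file is preserved.
#' @export
readProbeMatrix <- function(path, scale = c("linear", "log2")) {
    scale <- match.arg(scale)
    tab <- utils::read.delim(path, check.names = FALSE,
        colClasses = "character")
    if (ncol(tab) < 2L)
        stop("probe matrix file needs a probe_id column and >=1 array column")
    ids <- tab[[1L]]
    if (anyDuplicated(ids))
        stop("duplicated probe id in ", path, ": ",
            ids[duplicated(ids)][1L])
    m <- matrix(NA_real_, nrow(tab), ncol(tab) - 1L,
        dimnames = list(ids, names(tab)[-1L]))
    for (j in seq_len(ncol(m))) {
        x <- suppressWarnings(as.numeric(tab[[j + 1L]]))
        bad <- which(is.na(x))
        if (length(bad))
            stop(sprintf("non-numeric value at probe %s, array %s",
                ids[bad[1L]], colnames(m)[j]))
        m[, j] <- x
    }
    if (scale == "linear" && any(m <= 0)) {
        bad <- which(m <= 0, arr.ind = TRUE)[1L, ]
        stop(sprintf(
            "non-positive linear intensity at probe %s, array %s",
            rownames(m)[bad[1L]], colnames(m)[bad[2L]]))
    }
    ProbeMatrix(m, scale)
}

#' Write a ProbeMatrix (or any named numeric matrix) to TSV
#'
#' @param x a [ProbeMatrix-class] or a matrix with dimnames.
#' @param path output path.
#' @param id_column header for the identifier column.
#' @return `path`, invisibly.
#' @export
writeProbeMatrix <- function(x, path, id_column = "probe_id") {
    m <- if (is(x, "ProbeMatrix")) intensities(x) else x
    tab <- data.frame(rownames(m), format(m, digits = 17, trim = TRUE,
        scientific = FALSE), check.names = FALSE,
        stringsAsFactors = FALSE)
    names(tab) <- c(id_column, colnames(m))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(path)
}

#' Read a probe annotation table from TSV
#'
#' @param path TSV with columns probe_id, cluster_id, probe_type,
#'   position_index, transcript_length_bp; background probes may leave
#'   position and length empty.
#' @return a validated [ProbeAnnotation-class].
#' @export
readAnnotation <- function(path) {
    tab <- utils::read.delim(path, check.names = FALSE,
        na.strings = c("NA", ""))
    ProbeAnnotation(tab)
}

#' Write a probe annotation table
#' @param ann a [ProbeAnnotation-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAnnotation <- function(ann, path) {
    utils::write.table(annotation(ann), path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(path)
}

#' Read sample metadata from TSV
#'
#' @param path TSV with columns array_id, patient_id, condition, batch,
#'   rin, a260_230.
#' @return a validated [SampleMetadata-class]; the pairing invariant
#'   (one array per patient and condition, pairs not split across
#'   batches) is enforced.
#' @export
readMetadata <- function(path) {
    tab <- utils::read.delim(path, check.names = FALSE)
    SampleMetadata(tab)
}

#' Write sample metadata
#' @param meta a [SampleMetadata-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMetadata <- function(meta, path) {
    utils::write.table(sampleInfo(meta), path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(path)
}

#' Write a generic results table to TSV with full float precision
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTable <- function(df, path) {
    num <- vapply(df, is.numeric, logical(1L))
    df[num] <- lapply(df[num], function(x)
        ifelse(is.na(x), NA, format(x, digits = 17, trim = TRUE,
            scientific = TRUE)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(path)
}
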