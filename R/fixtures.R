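## Packaged fixtures: the published 34-array quality-assessment
## summary table and the qPCR primer table (documentation only; no
## computation uses the sequences).

#' The published 34-array quality-assessment summary table
#'
#' Per-array RIN, A260/230 ratio, pass/fail status (with printed
#' precision ranks for the failing arrays) on the three quality
#' metrics (median GNUSE, probe-level CV, PM-BG), and the estimated
#' array weight with its rank. Statuses and ranks are stored exactly
#' as printed; the printed CV fail ranks run (1)-(10) with rank (6)
#' attached to no row, and that gap is preserved rather than
#' repaired.
#'
#' @return data.frame with one row per array.
#' @examples
#' t1 <- qualityAssessmentTable()
#' sum(applyFlagRule(cbind(t1$cv_status, t1$pm_bg_status,
#'     t1$gnuse_status) == "pass"))  # 7 flagged
#' @export
qualityAssessmentTable <- function() {
    path <- system.file("extdata", "table1_quality.tsv",
        package = "degradeQC", mustWork = TRUE)
    utils::read.delim(path, check.names = FALSE)
}

#' QCReport built from the published quality table
#'
#' Applies the two-of-three rule to the printed pass/fail columns via
#' [qcReportFromStatus()].
#'
#' @param config configuration list.
#' @return a [QCReport-class].
#' @export
qualityAssessmentReport <- function(config = defaultConfig()) {
    t1 <- qualityAssessmentTable()
    qcReportFromStatus(t1$sample_id,
        cv_pass = t1$cv_status == "pass",
        pm_bg_pass = t1$pm_bg_status == "pass",
        gnuse_pass = t1$gnuse_status == "pass",
        gnuse_rank = t1$gnuse_rank,
        array_weight = t1$array_weight,
        config = config)
}

#' Sample metadata for the published cohort
#'
#' Array, patient and condition identifiers plus RIN and A260/230
#' from the published quality table. The study processed the arrays
#' in two batches of 10 and 24 without splitting patient pairs, but
#' the batch membership of individual arrays is not published; the
#' batch column here is a synthetic assignment (the first 5 patient
#' pairs by sorted patient id form batch 1) satisfying the published
#' batch sizes and pairing constraint.
#'
#' @return a [SampleMetadata-class].
#' @export
cohortMetadata <- function() {
    t1 <- qualityAssessmentTable()
    patient <- sub("[TN]$", "", t1$sample_id)
    condition <- ifelse(grepl("T$", t1$sample_id), "tumour", "normal")
    batch1 <- sort(unique(patient))[1:5]
    SampleMetadata(data.frame(array_id = t1$sample_id,
        patient_id = patient, condition = condition,
        batch = ifelse(patient %in% batch1, "batch1", "batch2"),
        rin = t1$rin, a260_230 = t1$a260_230,
        stringsAsFactors = FALSE))
}

#' qPCR primer table
#'
#' Primer sequences and product sizes for the two validated test
#' genes (DPEP1, CLDN1) and the three reference genes (UBC, B2M,
#' ATP5E). Shipped for documentation; no computation uses the
#' sequences.
#'
#' @return data.frame.
#' @export
qpcrPrimerTable <- function() {
    path <- system.file("extdata", "qpcr_primers.tsv",
        package = "degradeQC", mustWork = TRUE)
    utils::read.delim(path, check.names = FALSE)
}
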