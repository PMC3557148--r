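## Efficiency-corrected relative quantification. Classical ddCt
## assumes perfect doubling per cycle (efficiency 2); with measured
## primer efficiencies e in (1, 2], the fold change for a test gene t
## against reference genes i = 1..n is
##
##   FC = e_t^dCt_t / ( prod_i e_i^dCt_i )^(1/n)
##
## i.e. the test gene's efficiency-powered dCt normalized by the
## geometric mean of the references' efficiency-powered dCts, with
## dCt = Ct_normal - Ct_tumour so FC > 1 means higher expression in
## tumour. With all efficiencies equal to 2 this reduces exactly to
## 2^(dCt_t - mean(dCt_refs)), the classical ddCt form.

#' Efficiency-corrected fold change
#'
#' @param dct_test numeric, per-patient delta Ct of the test gene
#'   (Ct_normal - Ct_tumour, replicate-averaged).
#' @param eff_test scalar primer efficiency of the test gene, in
#'   (1, 2].
#' @param dct_refs matrix patients x reference genes of reference
#'   delta Cts (a vector is treated as a single reference).
#' @param eff_refs numeric efficiencies of the reference genes.
#' @return per-patient linear fold change (tumour vs normal).
#' @examples
#' efficiencyFoldChange(3, 2, matrix(1, 1, 1), 2)  # classical: 2^3/2 = 4
#' @export
efficiencyFoldChange <- function(dct_test, eff_test, dct_refs,
        eff_refs) {
    if (is.vector(dct_refs))
        dct_refs <- matrix(dct_refs, ncol = 1L)
    if (any(c(eff_test, eff_refs) <= 1) ||
            any(c(eff_test, eff_refs) > 2))
        stop("efficiencies must lie in (1, 2]")
    if (ncol(dct_refs) != length(eff_refs))
        stop("one efficiency per reference gene required")
    if (anyNA(dct_test) || anyNA(dct_refs))
        stop("missing reference or test measurement")
    if (length(dct_test) != nrow(dct_refs))
        stop("test and reference delta Cts must cover the same patients")
    num <- eff_test^dct_test
    logden <- dct_refs %*% log(eff_refs) / length(eff_refs)
    as.vector(num / exp(logden))
}

#' Per-patient fold changes from a long Ct table
#'
#' Averages replicate Cts per gene/array (arithmetic mean), forms
#' delta Ct = Ct_normal - Ct_tumour per patient and gene, and applies
#' [efficiencyFoldChange()] for each test gene against all reference
#' genes.
#'
#' @param ct_table long-format data.frame with columns `gene`, `role`
#'   ("test"/"reference"), `efficiency`, `patient_id`, `condition`,
#'   `replicate`, `ct` (as written by [simulateQpcr()]).
#' @return data.frame: `gene`, `patient_id`, `fold_change`,
#'   `log2_fold_change`.
#' @export
qpcrFoldChanges <- function(ct_table) {
    need <- c("gene", "role", "efficiency", "patient_id", "condition",
        "ct")
    if (!all(need %in% names(ct_table)))
        stop("missing columns: ",
            paste(setdiff(need, names(ct_table)), collapse = ", "))
    agg <- stats::aggregate(ct ~ gene + patient_id + condition +
        role + efficiency, ct_table, mean)
    wide <- merge(
        agg[agg$condition == "normal",
            c("gene", "patient_id", "role", "efficiency", "ct")],
        agg[agg$condition == "tumour",
            c("gene", "patient_id", "ct")],
        by = c("gene", "patient_id"), suffixes = c("_normal",
            "_tumour"))
    wide$dct <- wide$ct_normal - wide$ct_tumour
    refs <- unique(wide$gene[wide$role == "reference"])
    tests <- unique(wide$gene[wide$role == "test"])
    if (!length(refs)) stop("no reference genes in table")
    patients <- sort(unique(wide$patient_id))
    ref_mat <- sapply(refs, function(g) {
        d <- wide[wide$gene == g, ]
        d$dct[match(patients, d$patient_id)]
    })
    ref_mat <- matrix(ref_mat, nrow = length(patients),
        dimnames = list(patients, refs))
    eff_refs <- vapply(refs, function(g)
        wide$efficiency[wide$gene == g][1L], numeric(1L))
    out <- lapply(tests, function(g) {
        d <- wide[wide$gene == g, ]
        dct <- d$dct[match(patients, d$patient_id)]
        fc <- efficiencyFoldChange(dct, d$efficiency[1L], ref_mat,
            eff_refs)
        data.frame(gene = g, patient_id = patients, fold_change = fc,
            log2_fold_change = log2(fc), stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Correlate qPCR and array fold changes
#'
#' Ordinary least squares of log2(qPCR fold change) on the array log2
#' fold change across patients, reporting slope, intercept and
#' adjusted R^2 = 1 - (1 - R^2)(n - 1)/(n - 2).
#'
#' @param qpcr_fc positive per-patient qPCR fold changes.
#' @param array_log2fc per-patient array log2 fold changes (same
#'   patients, same order).
#' @return list with `slope`, `intercept`, `r_squared`,
#'   `adj_r_squared`, `n`.
#' @export
correlateFoldChanges <- function(qpcr_fc, array_log2fc) {
    stopifnot(length(qpcr_fc) == length(array_log2fc))
    if (length(qpcr_fc) < 3) stop("need >= 3 patients")
    if (any(qpcr_fc <= 0)) stop("fold changes must be positive")
    y <- log2(qpcr_fc)
    fit <- stats::lm(y ~ array_log2fc)
    sm <- summary(fit)
    list(slope = unname(stats::coef(fit)[2L]),
        intercept = unname(stats::coef(fit)[1L]),
        r_squared = sm$r.squared,
        adj_r_squared = sm$adj.r.squared,
        n = length(y))
}

#' Per-patient array log2 fold changes for selected clusters
#'
#' tumour minus normal expression per patient, from a summarized
#' expression matrix.
#'
#' @param expr clusters x arrays log2 expression matrix.
#' @param metadata a [SampleMetadata-class].
#' @param genes cluster ids.
#' @return data.frame `gene`, `patient_id`, `array_log2fc`.
#' @export
arrayFoldChanges <- function(expr, metadata, genes) {
    info <- sampleInfo(metadata)
    patients <- sort(unique(info$patient_id))
    out <- lapply(genes, function(g) {
        if (!g %in% rownames(expr)) stop("unknown cluster: ", g)
        fc <- vapply(patients, function(p) {
            tid <- info$array_id[info$patient_id == p &
                info$condition == "tumour"]
            nid <- info$array_id[info$patient_id == p &
                info$condition == "normal"]
            if (!length(tid) || !length(nid)) return(NA_real_)
            expr[g, tid] - expr[g, nid]
        }, numeric(1L))
        data.frame(gene = g, patient_id = patients,
            array_log2fc = unname(fc), stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}
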