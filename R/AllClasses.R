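#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' ProbeMatrix: probe-level intensity container
#'
#' Holds a probes-by-arrays intensity matrix together with its scale.
#' Raw data are on the linear scale (strictly positive); preprocessed
#' data are on the log2 scale. Probes are rows, arrays are columns
#' everywhere in this package.
#'
#' @slot values numeric matrix with probe ids as rownames and array ids
#'   as colnames; no missing entries.
#' @slot scale either \code{"linear"} or \code{"log2"}.
#'
#' @seealso [readProbeMatrix()], [simulateCohort()]
#' @export
setClass("ProbeMatrix",
    representation(values = "matrix", scale = "character"))

setValidity("ProbeMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (!is.numeric(v))
        msg <- c(msg, "'values' must be a numeric matrix")
    if (is.null(rownames(v)) || is.null(colnames(v)))
        msg <- c(msg, "'values' must carry probe ids (rownames) and array ids (colnames)")
    if (anyDuplicated(rownames(v)))
        msg <- c(msg, sprintf("duplicated probe id: %s",
            rownames(v)[duplicated(rownames(v))][1L]))
    if (anyDuplicated(colnames(v)))
        msg <- c(msg, sprintf("duplicated array id: %s",
            colnames(v)[duplicated(colnames(v))][1L]))
    if (anyNA(v))
        msg <- c(msg, "missing intensities are not allowed")
    if (length(object@scale) != 1L || !object@scale %in% c("linear", "log2"))
        msg <- c(msg, "'scale' must be \"linear\" or \"log2\"")
    if (identical(object@scale, "linear") && !anyNA(v) && any(v <= 0)) {
        bad <- which(v <= 0, arr.ind = TRUE)[1L, ]
        msg <- c(msg, sprintf(
            "linear-scale intensities must be strictly positive (probe %s, array %s)",
            rownames(v)[bad[1L]], colnames(v)[bad[2L]]))
    }
    if (length(msg)) msg else TRUE
})

#' ProbeAnnotation: probe-to-cluster map
#'
#' Maps each probe to a transcript cluster, its role (perfect match or
#' background), its 5'-to-3' position within the cluster, and the
#' cluster's transcript length. Background probes carry no position and
#' no cluster length.
#'
#' @slot ann data.frame with columns \code{probe_id}, \code{cluster_id},
#'   \code{probe_type} ("pm"/"background"), \code{position_index}
#'   (integer, NA for background probes) and \code{transcript_length_bp}
#'   (positive, NA for background probes).
#'
#' @export
setClass("ProbeAnnotation", representation(ann = "data.frame"))

setValidity("ProbeAnnotation", function(object) {
    a <- object@ann
    msg <- character()
    need <- c("probe_id", "cluster_id", "probe_type", "position_index",
        "transcript_length_bp")
    if (!all(need %in% names(a)))
        return(paste("missing annotation columns:",
            paste(setdiff(need, names(a)), collapse = ", ")))
    if (anyDuplicated(a$probe_id))
        msg <- c(msg, "duplicated probe_id in annotation")
    if (!all(a$probe_type %in% c("pm", "background")))
        msg <- c(msg, "probe_type must be 'pm' or 'background'")
    pm <- a[a$probe_type == "pm", , drop = FALSE]
    if (nrow(pm)) {
        if (anyNA(pm$position_index))
            msg <- c(msg, sprintf("pm probe without position_index: %s",
                pm$probe_id[which(is.na(pm$position_index))[1L]]))
        else {
            if (any(pm$position_index < 1))
                msg <- c(msg, "position_index must be >= 1")
            dup <- tapply(pm$position_index, pm$cluster_id,
                anyDuplicated)
            if (any(dup > 0))
                msg <- c(msg, sprintf(
                    "duplicated position_index within cluster %s",
                    names(dup)[dup > 0][1L]))
        }
        if (anyNA(pm$transcript_length_bp) ||
                any(pm$transcript_length_bp <= 0, na.rm = TRUE))
            msg <- c(msg, "pm probes need a positive transcript_length_bp")
        nlen <- tapply(pm$transcript_length_bp, pm$cluster_id,
            function(x) length(unique(x)))
        if (any(nlen > 1))
            msg <- c(msg, sprintf(
                "inconsistent transcript_length_bp within cluster %s",
                names(nlen)[nlen > 1][1L]))
    }
    if (length(msg)) msg else TRUE
})

#' SampleMetadata: per-array phenotype and provenance
#'
#' @slot info data.frame with columns \code{array_id}, \code{patient_id},
#'   \code{condition} ("tumour"/"normal"), \code{batch}, \code{rin}
#'   (in \[1, 10\]) and \code{a260_230} (positive).
#'
#' @details Each patient contributes at most one array per condition and
#' patient pairs are never split across batches; both constraints are
#' enforced by the validity method.
#'
#' @export
setClass("SampleMetadata", representation(info = "data.frame"))

setValidity("SampleMetadata", function(object) {
    m <- object@info
    msg <- character()
    need <- c("array_id", "patient_id", "condition", "batch", "rin",
        "a260_230")
    if (!all(need %in% names(m)))
        return(paste("missing metadata columns:",
            paste(setdiff(need, names(m)), collapse = ", ")))
    if (anyDuplicated(m$array_id))
        msg <- c(msg, "duplicated array_id")
    if (!all(m$condition %in% c("tumour", "normal")))
        msg <- c(msg, "condition must be 'tumour' or 'normal'")
    if (any(m$rin < 1 | m$rin > 10))
        msg <- c(msg, sprintf("rin out of [1, 10] for array %s",
            m$array_id[which(m$rin < 1 | m$rin > 10)[1L]]))
    if (any(m$a260_230 <= 0))
        msg <- c(msg, "a260_230 must be positive")
    key <- paste(m$patient_id, m$condition)
    if (anyDuplicated(key))
        msg <- c(msg, sprintf("patient %s has multiple %s arrays",
            m$patient_id[duplicated(key)][1L],
            m$condition[duplicated(key)][1L]))
    nb <- tapply(m$batch, m$patient_id, function(b) length(unique(b)))
    if (any(nb > 1))
        msg <- c(msg, sprintf("patient pair split across batches: %s",
            names(nb)[nb > 1][1L]))
    if (length(msg)) msg else TRUE
})

#' QCThresholds: pass/fail boundaries for the three quality metrics
#'
#' @slot cv_max upper bound on the probe-level coefficient of variation.
#' @slot pm_bg_min lower bound on the PM-minus-background difference.
#' @slot gnuse_max upper bound on the median GNUSE (default 1.25).
#'
#' @export
setClass("QCThresholds",
    representation(cv_max = "numeric", pm_bg_min = "numeric",
        gnuse_max = "numeric"))

setValidity("QCThresholds", function(object) {
    if (length(object@cv_max) != 1L || length(object@pm_bg_min) != 1L ||
            length(object@gnuse_max) != 1L)
        "all thresholds must be scalar" else TRUE
})

#' QCReport: per-array metrics, pass/fail calls, flags and ranking
#'
#' @slot report data.frame with one row per array: metric values
#'   (\code{cv}, \code{pm_bg}, \code{gnuse_median}), per-metric logical
#'   passes, \code{n_fail}, \code{flagged}, \code{quality_rank}
#'   (1 = worst precision, i.e. highest GNUSE median) and optional
#'   \code{array_weight}.
#' @slot flag_min_failures number of failed metrics that triggers the
#'   flag (default 2, the two-of-three rule).
#'
#' @export
setClass("QCReport",
    representation(report = "data.frame", flag_min_failures = "numeric"))

setValidity("QCReport", function(object) {
    r <- object@report
    msg <- character()
    need <- c("array_id", "cv", "pm_bg", "gnuse_median", "cv_pass",
        "pm_bg_pass", "gnuse_pass", "n_fail", "flagged", "quality_rank")
    if (!all(need %in% names(r)))
        return(paste("missing QC report columns:",
            paste(setdiff(need, names(r)), collapse = ", ")))
    k <- object@flag_min_failures
    nf <- (!r$cv_pass) + (!r$pm_bg_pass) + (!r$gnuse_pass)
    if (!identical(as.integer(nf), as.integer(r$n_fail)))
        msg <- c(msg, "n_fail inconsistent with pass columns")
    if (!identical(r$flagged, nf >= k))
        msg <- c(msg, "flagged inconsistent with the n-of-3 rule")
    if (!setequal(r$quality_rank, seq_len(nrow(r))))
        msg <- c(msg, "quality_rank must be a permutation of 1..n")
    if (length(msg)) msg else TRUE
})

#' FrozenReference: frozen preprocessing parameters
#'
#' Parameters learned once from a reference collection of high-quality
#' arrays and then held fixed: per-probe affinity effects, target
#' quantiles for normalization, and per-cluster reference standard-error
#' medians used to scale GNUSE.
#'
#' @slot probe_effects named numeric, log2 affinity per pm probe;
#'   sums to zero within each cluster.
#' @slot reference_quantiles non-decreasing numeric vector of length
#'   equal to the number of pm probes.
#' @slot cluster_se_median named non-negative numeric, one per cluster.
#' @slot cluster_ids character, cluster of each pm probe (parallel to
#'   \code{probe_effects}).
#'
#' @export
setClass("FrozenReference",
    representation(probe_effects = "numeric",
        reference_quantiles = "numeric",
        cluster_se_median = "numeric",
        cluster_ids = "character"))

setValidity("FrozenReference", function(object) {
    msg <- character()
    if (length(object@probe_effects) != length(object@reference_quantiles))
        msg <- c(msg, "reference_quantiles length must equal the pm probe count")
    if (is.unsorted(object@reference_quantiles))
        msg <- c(msg, "reference_quantiles must be non-decreasing")
    if (length(object@probe_effects) != length(object@cluster_ids))
        msg <- c(msg, "cluster_ids must parallel probe_effects")
    if (any(object@cluster_se_median < 0))
        msg <- c(msg, "cluster_se_median must be non-negative")
    if (length(msg)) msg else TRUE
})

#' SurrogateVariables: latent factors estimated from residual structure
#'
#' @slot sv matrix, arrays by n_sv, orthonormal columns (empty matrix
#'   when no surrogate variable is supported by the data).
#'
#' @export
setClass("SurrogateVariables", representation(sv = "matrix"))

setValidity("SurrogateVariables", function(object) {
    s <- object@sv
    if (ncol(s) >= 2L) {
        g <- crossprod(s)
        if (max(abs(g - diag(diag(g)))) > 1e-6)
            return("surrogate variable columns must be orthogonal")
    }
    if (ncol(s) >= 1L && max(abs(colSums(s^2) - 1)) > 1e-6)
        return("surrogate variable columns must have unit norm")
    TRUE
})

#' SimulationTruth: generative parameters of a synthetic cohort
#'
#' @slot clusters data.frame per cluster: \code{cluster_id},
#'   \code{true_log2fc}, \code{de_flag}, \code{gamma} (signed
#'   length-dependent degradation coefficient), \code{mu} (baseline
#'   log2), \code{transcript_length_bp}, \code{short_noncoding},
#'   \code{reference_gene}.
#' @slot arrays data.frame per array: \code{array_id}, \code{rin},
#'   \code{q} (degradation level in \[0, 1\]), \code{sigma} (probe noise
#'   SD in log2 units).
#' @slot batch_effects matrix clusters x batches of additive log2
#'   batch offsets (first batch fixed at zero).
#' @slot patient_log2fc matrix clusters x patients of patient-level
#'   deviations from \code{true_log2fc} (zero for reference genes).
#' @slot probe_effects named numeric, the simulated per-probe log2
#'   affinities (sum to zero within each cluster).
#'
#' @export
setClass("SimulationTruth",
    representation(clusters = "data.frame", arrays = "data.frame",
        batch_effects = "matrix", patient_log2fc = "matrix",
        probe_effects = "numeric"))

## ---- show methods -------------------------------------------------------

setMethod("show", "ProbeMatrix", function(object) {
    cat(sprintf("ProbeMatrix: %d probes x %d arrays (%s scale)\n",
        nrow(object@values), ncol(object@values), object@scale))
})

setMethod("show", "ProbeAnnotation", function(object) {
    a <- object@ann
    cat(sprintf(
        "ProbeAnnotation: %d probes (%d pm, %d background), %d clusters\n",
        nrow(a), sum(a$probe_type == "pm"),
        sum(a$probe_type == "background"),
        length(unique(a$cluster_id[a$probe_type == "pm"]))))
})

setMethod("show", "SampleMetadata", function(object) {
    m <- object@info
    cat(sprintf(
        "SampleMetadata: %d arrays, %d patients, batches: %s, RIN range [%.1f, %.1f]\n",
        nrow(m), length(unique(m$patient_id)),
        paste(names(table(m$batch)), table(m$batch), sep = ":",
            collapse = ", "), min(m$rin), max(m$rin)))
})

setMethod("show", "QCReport", function(object) {
    r <- object@report
    cat(sprintf("QCReport: %d arrays, %d flagged (>=%d of 3 metrics failed)\n",
        nrow(r), sum(r$flagged), object@flag_min_failures))
})

setMethod("show", "QCThresholds", function(object) {
    cat(sprintf("QCThresholds: CV <= %.4g, PM-BG >= %.4g, GNUSE median <= %.4g\n",
        object@cv_max, object@pm_bg_min, object@gnuse_max))
})

setMethod("show", "FrozenReference", function(object) {
    cat(sprintf("FrozenReference: %d pm probes, %d clusters\n",
        length(object@probe_effects),
        length(object@cluster_se_median)))
})

setMethod("show", "SurrogateVariables", function(object) {
    cat(sprintf("SurrogateVariables: %d arrays x %d surrogate variable(s)\n",
        nrow(object@sv), ncol(object@sv)))
})

setMethod("show", "SimulationTruth", function(object) {
    cat(sprintf(
        "SimulationTruth: %d clusters (%d DE), %d arrays (%d degraded)\n",
        nrow(object@clusters), sum(object@clusters$de_flag),
        nrow(object@arrays), sum(object@arrays$q > 0)))
})
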