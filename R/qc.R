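## Within-array quality metrics, threshold construction, GNUSE-based
## flagging and the composite two-of-three quality decision.

#' Probe-level coefficient of variation per array
#'
#' CV_j = sample SD (divisor n - 1) over all probes of array j divided
#' by the mean over all probes. Computed on the raw linear scale.
#'
#' @param raw a linear-scale [ProbeMatrix-class].
#' @return named numeric, one CV per array.
#' @examples
#' m <- ProbeMatrix(matrix(c(1, 2, 3), 3, 1,
#'     dimnames = list(c("p1", "p2", "p3"), "a1")), "linear")
#' probeCV(m)  # 0.5
#' @export
probeCV <- function(raw) {
    if (intensityScale(raw) != "linear")
        stop("probeCV expects raw linear-scale intensities")
    v <- intensities(raw)
    mu <- colMeans(v)
    if (any(mu == 0)) stop("zero-mean array column")
    apply(v, 2L, stats::sd) / mu
}

#' Perfect-match minus background mean difference per array
#'
#' mean(pm probes) - mean(background probes) on the raw linear scale.
#' Falls with RNA degradation as overall specific signal is attenuated.
#'
#' @param raw a linear-scale [ProbeMatrix-class].
#' @param ann a [ProbeAnnotation-class] covering the probes of `raw`.
#' @return named numeric, one difference per array.
#' @export
pmBgDifference <- function(raw, ann) {
    if (intensityScale(raw) != "linear")
        stop("pmBgDifference expects raw linear-scale intensities")
    a <- annotation(ann)
    pm <- intersect(a$probe_id[a$probe_type == "pm"], probeIds(raw))
    bg <- intersect(a$probe_id[a$probe_type == "background"],
        probeIds(raw))
    if (!length(pm)) stop("no pm probes in annotation")
    if (!length(bg)) stop("no background probes in annotation")
    v <- intensities(raw)
    colMeans(v[pm, , drop = FALSE]) - colMeans(v[bg, , drop = FALSE])
}

#' Derive data-driven QC thresholds from high-RIN arrays
#'
#' The CV threshold is the mean plus `cv_sd_multiplier` sample
#' standard deviations of the CVs of arrays whose RIN exceeds
#' `cv_rin_cutoff` (one-sided upper: degraded arrays show elevated
#' CV). The PM-BG threshold mirrors the construction on the lower
#' side: mean minus the same multiple of SDs (degraded arrays show
#' depressed PM-BG). The GNUSE bound comes straight from the
#' configuration (default 1.25).
#'
#' @param cvs named per-array CVs from [probeCV()].
#' @param pm_bgs named per-array differences from [pmBgDifference()].
#' @param metadata a [SampleMetadata-class] carrying RINs.
#' @param config configuration list.
#' @return a [QCThresholds-class].
#' @export
deriveThresholds <- function(cvs, pm_bgs, metadata,
        config = defaultConfig()) {
    info <- sampleInfo(metadata)
    hi <- info$array_id[info$rin > config$cv_rin_cutoff]
    hi <- intersect(hi, names(cvs))
    if (length(hi) < 2)
        stop("need >=2 arrays with RIN > ", config$cv_rin_cutoff,
            " to derive thresholds")
    k <- config$cv_sd_multiplier
    cv_hi <- cvs[hi]
    pb_hi <- pm_bgs[hi]
    new("QCThresholds",
        cv_max = mean(cv_hi) + k * stats::sd(cv_hi),
        pm_bg_min = mean(pb_hi) - k * stats::sd(pb_hi),
        gnuse_max = config$gnuse_flag_threshold)
}

#' Per-array median GNUSE
#'
#' GNUSE scales each cluster's standard error by the frozen reference
#' median for that cluster, so that a typical high-quality array
#' scores 1; the per-array median over clusters summarises precision
#' relative to the reference collection.
#'
#' @param se_matrix clusters x arrays standard-error matrix from
#'   [summarizeFrozen()].
#' @param frozen a [FrozenReference-class].
#' @return named numeric, median GNUSE per array.
#' @export
gnuseMedian <- function(se_matrix, frozen) {
    med <- frozen@cluster_se_median
    common <- intersect(rownames(se_matrix), names(med))
    if (!length(common)) stop("no shared clusters with frozen reference")
    med <- med[common]
    if (any(med == 0))
        stop("frozen SE median is zero for cluster ",
            names(med)[med == 0][1L])
    apply(se_matrix[common, , drop = FALSE] / med, 2L, stats::median)
}

#' Apply the n-of-3 flag rule to pass/fail calls
#'
#' @param pass logical matrix, arrays x metrics (TRUE = pass).
#' @param min_failures number of failures that triggers the flag
#'   (default 2: the two-of-three rule).
#' @return logical flag per array.
#' @export
applyFlagRule <- function(pass, min_failures = 2) {
    stopifnot(is.logical(pass))
    rowSums(!pass) >= min_failures
}

#' Score arrays against the thresholds and flag them
#'
#' Each array passes or fails each of the three metrics; an array
#' failing at least `flag_min_failures` (default two) of the three is
#' flagged. Arrays are ranked by median GNUSE, descending, so rank 1
#' is the least precise array; ties are broken by array id.
#'
#' @param cv,pm_bg,gnuse_median named per-array metric vectors sharing
#'   the same array ids.
#' @param thresholds a [QCThresholds-class].
#' @param config configuration list (supplies `flag_min_failures`).
#' @return a [QCReport-class].
#' @export
flagArrays <- function(cv, pm_bg, gnuse_median, thresholds,
        config = defaultConfig()) {
    ids <- names(cv)
    stopifnot(!is.null(ids), setequal(ids, names(pm_bg)),
        setequal(ids, names(gnuse_median)))
    pm_bg <- pm_bg[ids]
    gnuse_median <- gnuse_median[ids]
    cv_pass <- cv <= thresholds@cv_max
    pm_bg_pass <- pm_bg >= thresholds@pm_bg_min
    gnuse_pass <- gnuse_median <= thresholds@gnuse_max
    pass <- cbind(cv = cv_pass, pm_bg = pm_bg_pass, gnuse = gnuse_pass)
    flagged <- applyFlagRule(pass, config$flag_min_failures)
    rank <- order(order(-gnuse_median, ids))
    rep <- data.frame(array_id = ids, cv = unname(cv),
        pm_bg = unname(pm_bg), gnuse_median = unname(gnuse_median),
        cv_pass = unname(cv_pass), pm_bg_pass = unname(pm_bg_pass),
        gnuse_pass = unname(gnuse_pass),
        n_fail = unname(rowSums(!pass)), flagged = unname(flagged),
        quality_rank = rank, array_weight = NA_real_,
        stringsAsFactors = FALSE)
    new("QCReport", report = rep,
        flag_min_failures = config$flag_min_failures)
}

#' Build a QCReport from externally printed pass/fail calls
#'
#' For published QC tables that record pass/fail outcomes (but not the
#' underlying thresholds), applies the n-of-3 rule directly to the
#' printed calls. Metric values unavailable from such tables are NA.
#'
#' @param array_id character array ids.
#' @param cv_pass,pm_bg_pass,gnuse_pass logical pass calls per array.
#' @param gnuse_rank optional printed precision ranks (1 = worst) used
#'   as the quality ranking; when absent arrays are ranked by id.
#' @param array_weight optional printed per-array weights.
#' @param config configuration list.
#' @return a [QCReport-class].
#' @export
qcReportFromStatus <- function(array_id, cv_pass, pm_bg_pass,
        gnuse_pass, gnuse_rank = NULL, array_weight = NULL,
        config = defaultConfig()) {
    pass <- cbind(cv = cv_pass, pm_bg = pm_bg_pass, gnuse = gnuse_pass)
    flagged <- applyFlagRule(pass, config$flag_min_failures)
    n <- length(array_id)
    rank <- if (is.null(gnuse_rank)) order(order(array_id))
        else {
            ## printed tables rank only failing arrays; passing arrays
            ## fill the remaining ranks in table order
            r <- gnuse_rank
            r[is.na(r)] <- setdiff(seq_len(n), r[!is.na(r)])
            r
        }
    rep <- data.frame(array_id = array_id, cv = NA_real_,
        pm_bg = NA_real_, gnuse_median = NA_real_,
        cv_pass = cv_pass, pm_bg_pass = pm_bg_pass,
        gnuse_pass = gnuse_pass, n_fail = unname(rowSums(!pass)),
        flagged = unname(flagged), quality_rank = as.integer(rank),
        array_weight = if (is.null(array_weight)) NA_real_
            else array_weight,
        stringsAsFactors = FALSE)
    new("QCReport", report = rep,
        flag_min_failures = config$flag_min_failures)
}

#' Cohort-level QC summary
#'
#' Summarises a [QCReport-class] against sample metadata: number of
#' flagged arrays; mean and population SD (divisor n) of the flagged
#' arrays' RINs; cohort mean and sample SD (divisor n - 1) of all
#' RINs; the number of arrays below RIN 7 that nevertheless passed QC;
#' and the proportion flagged among arrays at or below the low-RIN
#' cutoff (default 3.3). The two SD conventions are deliberate: the
#' flagged-group spread is reported as a population SD, the cohort
#' spread as a sample SD.
#'
#' @param report a [QCReport-class].
#' @param metadata a [SampleMetadata-class] sharing array ids.
#' @param config configuration list (supplies `low_rin_cutoff` and the
#'   RIN 7 convention via `cv_rin_cutoff` + 1 is \emph{not} used; the
#'   RIN < 7 count follows the conventional intact-RNA cutoff).
#' @return named list of summary statistics.
#' @export
qcSummary <- function(report, metadata, config = defaultConfig()) {
    r <- qcTable(report)
    info <- sampleInfo(metadata)
    if (!setequal(r$array_id, info$array_id))
        stop("QC report and metadata array ids differ")
    rin <- info$rin[match(r$array_id, info$array_id)]
    fl <- r$flagged
    pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
    low <- rin <= config$low_rin_cutoff
    list(
        n_arrays = nrow(r),
        n_flagged = sum(fl),
        flagged_rin_mean = if (any(fl)) mean(rin[fl]) else NA_real_,
        flagged_rin_sd = if (any(fl)) pop_sd(rin[fl]) else NA_real_,
        cohort_rin_mean = mean(rin),
        cohort_rin_sd = stats::sd(rin),
        n_pass_rin_below_7 = sum(!fl & rin < 7),
        n_pass_all_rin_below_3 = sum(r$n_fail == 0 & rin < 3),
        prop_flagged_low_rin = if (any(low)) mean(fl[low]) else NA_real_)
}

#' Association between chemical purity and the quality flag
#'
#' Two-sample t-test comparing A260/230 ratios between quality-flagged
#' and quality-passed arrays. The default is the equal-variance
#' Student's t-test; Welch's correction is available.
#'
#' @param report a [QCReport-class].
#' @param metadata a [SampleMetadata-class].
#' @param var.equal assume equal group variances (default TRUE).
#' @return list with `t`, `df` and `p`.
#' @export
purityAssociation <- function(report, metadata, var.equal = TRUE) {
    r <- qcTable(report)
    info <- sampleInfo(metadata)
    a <- info$a260_230[match(r$array_id, info$array_id)]
    x <- a[r$flagged]
    y <- a[!r$flagged]
    if (length(x) < 2 || length(y) < 2)
        stop("both flag groups need >=2 arrays")
    tt <- stats::t.test(x, y, var.equal = var.equal)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value)
}
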