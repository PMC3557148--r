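## Frozen-reference preprocessing: learn probe effects, target
## quantiles and reference SE medians once from a high-quality
## reference collection, then process new arrays one at a time against
## those frozen parameters. Summarization is robust median/MAD rather
## than iterative weighted least squares: deterministic, single-array
## compatible, and sufficient for precision (GNUSE) scoring.

log2Floor <- function(m, floor = 0.5) {
    if (any(m < floor)) m[m < floor] <- floor
    log2(m)
}

pmOnly <- function(x, ann) {
    a <- annotation(ann)
    pm <- a$probe_id[a$probe_type == "pm"]
    keep <- intersect(probeIds(x), pm)
    intensities(x)[keep, , drop = FALSE]
}

clusterIndex <- function(probe_ids, ann) {
    a <- annotation(ann)
    cl <- a$cluster_id[match(probe_ids, a$probe_id)]
    if (anyNA(cl))
        stop("probe missing from annotation: ",
            probe_ids[is.na(cl)][1L])
    cl
}

#' Build frozen preprocessing parameters from a reference set
#'
#' From a collection of high-quality reference arrays: (1) log2
#' transform (0.5 floor); (2) frozen quantiles = mean of the sorted pm
#' columns; (3) frozen probe effects = per-probe median across arrays
#' of the deviation from the array's cluster median, centred to sum to
#' zero within each cluster; (4) frozen cluster SE medians = median
#' across the reference arrays of the per-array summarization SE,
#' obtained by processing the reference set back through its own
#' frozen quantiles and probe effects. These SE medians are the GNUSE
#' denominators, so a typical reference-quality array has median
#' GNUSE near 1.
#'
#' @param reference_raw linear-scale [ProbeMatrix-class] of reference
#'   arrays (>= 3).
#' @param ann a [ProbeAnnotation-class].
#' @return a [FrozenReference-class].
#' @export
buildFrozenReference <- function(reference_raw, ann) {
    v <- pmOnly(reference_raw, ann)
    if (ncol(v) < 3) stop("need >= 3 reference arrays")
    y <- log2Floor(v)
    cl <- clusterIndex(rownames(y), ann)
    sizes <- table(cl)
    if (any(sizes < 2))
        stop("cluster with < 2 pm probes: ",
            names(sizes)[sizes < 2][1L])
    ref_q <- rowMeans(apply(y, 2L, sort))
    ## probe effects: deviation from the array-wise cluster median
    cl_f <- factor(cl, levels = unique(cl))
    arr_cl_med <- apply(y, 2L, function(col)
        stats::ave(col, cl_f, FUN = stats::median))
    dev <- y - arr_cl_med
    phi <- apply(dev, 1L, stats::median)
    phi <- stats::ave(phi, cl_f, FUN = function(x) x - mean(x))
    names(phi) <- rownames(y)
    frozen <- new("FrozenReference", probe_effects = phi,
        reference_quantiles = ref_q,
        cluster_se_median = stats::setNames(rep(1, nlevels(cl_f)),
            levels(cl_f)),
        cluster_ids = cl)
    ## per-cluster reference SE medians from the reference set itself
    norm <- quantileNormalizeToReference(reference_raw, frozen)
    sm <- summarizeFrozen(norm, ann, frozen)
    se_med <- apply(sm$se, 1L, stats::median)
    frozen@cluster_se_median <- se_med
    frozen
}

#' Quantile-normalize arrays to frozen reference quantiles
#'
#' Each array's sorted log2 pm values are replaced by the frozen
#' reference quantiles; tied input values receive the mean of the
#' reference quantiles they span. Arrays are processed independently,
#' so the result for one array never depends on which other arrays are
#' present.
#'
#' @param raw [ProbeMatrix-class] (linear or log2) over the same pm
#'   probe universe as `frozen`.
#' @param frozen a [FrozenReference-class].
#' @return a log2-scale [ProbeMatrix-class] restricted to pm probes.
#' @export
quantileNormalizeToReference <- function(raw, frozen) {
    ids <- names(frozen@probe_effects)
    v <- intensities(raw)
    if (!all(ids %in% rownames(v)))
        stop("probe universe mismatch: ", sum(!ids %in% rownames(v)),
            " frozen pm probes absent from input")
    v <- v[ids, , drop = FALSE]
    if (nrow(v) != length(frozen@reference_quantiles))
        stop("probe count mismatch with reference quantiles")
    y <- if (intensityScale(raw) == "linear") log2Floor(v) else v
    q <- frozen@reference_quantiles
    out <- apply(y, 2L, function(col) {
        res <- numeric(length(col))
        o <- order(col)
        res[o] <- q
        ## ties share the mean of the quantile values they span
        stats::ave(res, match(col, col), FUN = mean)
    })
    dimnames(out) <- dimnames(v)
    ProbeMatrix(out, "log2")
}

#' Summarize probes into cluster expression with frozen probe effects
#'
#' Subtracts the frozen probe effect from each normalized probe value
#' and summarises each cluster per array by the median of the
#' residuals; the standard error is 1.4826 * MAD of the residuals
#' divided by sqrt(number of probes).
#'
#' @param norm log2-scale [ProbeMatrix-class] from
#'   [quantileNormalizeToReference()].
#' @param ann a [ProbeAnnotation-class].
#' @param frozen a [FrozenReference-class].
#' @return list with `expression` and `se`, both clusters x arrays
#'   matrices.
#' @export
summarizeFrozen <- function(norm, ann, frozen) {
    if (intensityScale(norm) != "log2")
        stop("summarizeFrozen expects log2-scale input")
    ids <- names(frozen@probe_effects)
    v <- intensities(norm)
    if (!all(ids %in% rownames(v)))
        stop("normalized matrix missing frozen pm probes")
    v <- v[ids, , drop = FALSE]
    r <- v - frozen@probe_effects
    cl <- factor(frozen@cluster_ids, levels = unique(frozen@cluster_ids))
    idx <- split(seq_along(ids), cl)
    n_cl <- length(idx)
    expr <- matrix(NA_real_, n_cl, ncol(v),
        dimnames = list(names(idx), colnames(v)))
    se <- expr
    for (g in seq_len(n_cl)) {
        rows <- idx[[g]]
        block <- r[rows, , drop = FALSE]
        expr[g, ] <- apply(block, 2L, stats::median)
        se[g, ] <- apply(block, 2L, stats::mad) / sqrt(length(rows))
    }
    list(expression = expr, se = se)
}

#' One-call frozen preprocessing
#'
#' Convenience wrapper: normalize to the frozen quantiles, summarize
#' with the frozen probe effects, and compute median GNUSE per array.
#'
#' @param raw linear-scale [ProbeMatrix-class].
#' @param ann a [ProbeAnnotation-class].
#' @param frozen a [FrozenReference-class].
#' @return list with `expression`, `se` and `gnuse_median`.
#' @export
preprocessFrozen <- function(raw, ann, frozen) {
    norm <- quantileNormalizeToReference(raw, frozen)
    sm <- summarizeFrozen(norm, ann, frozen)
    c(sm, list(gnuse_median = gnuseMedian(sm$se, frozen)))
}
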