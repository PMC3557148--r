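## Degradation-bias analysis: which clusters differ between the
## quality categories, how the affected classes relate to transcript
## length, and the 5'-to-3' positional intensity profile.

#' Clusters affected by array quality
#'
#' Runs the same fit -> moderation -> BH chain as differential
#' expression, but with the quality flag as the grouping factor
#' instead of disease status. Clusters with adjusted p at or below
#' `p_threshold` and |linear fold change| at or above `fc_threshold`
#' are classed "up" or "down" (intensity in flagged arrays relative
#' to passed arrays) by the sign of the log2 fold change; all others
#' are "unaffected".
#'
#' @param expr clusters x arrays log2 expression matrix.
#' @param report a [QCReport-class]; both flag groups need >= 2
#'   arrays.
#' @param p_threshold adjusted-p cutoff (default 0.05).
#' @param fc_threshold linear fold-change cutoff (default 2; the
#'   published figure legends use the stricter p <= 0.01 variant,
#'   available by argument).
#' @return data.frame per cluster: `cluster_id`, `log2fc`
#'   (flagged - passed), `p`, `adj_p`, `class`.
#' @export
qualityAffected <- function(expr, report, p_threshold = 0.05,
        fc_threshold = 2) {
    r <- qcTable(report)
    flag <- r$flagged[match(colnames(expr), r$array_id)]
    if (anyNA(flag)) stop("expression columns missing from QC report")
    if (sum(flag) < 2 || sum(!flag) < 2)
        stop("both quality groups need >= 2 arrays")
    design <- cbind(intercept = 1, flagged = as.numeric(flag))
    fit <- fitGeneLM(expr, design)
    mod <- ebayesModerate(fit, "flagged")
    adj <- bhAdjust(mod$p)
    cls <- rep("unaffected", nrow(expr))
    hit <- adj <= p_threshold & abs(mod$log2fc) >= log2(fc_threshold)
    cls[hit & mod$log2fc > 0] <- "up"
    cls[hit & mod$log2fc < 0] <- "down"
    data.frame(cluster_id = rownames(expr), log2fc = mod$log2fc,
        p = mod$p, adj_p = adj, class = cls,
        stringsAsFactors = FALSE, row.names = NULL)
}

#' Transcript-length bias tests between affected classes
#'
#' One-sided Mann-Whitney (Wilcoxon rank-sum) tests of transcript
#' length: the "up" class is tested for being shorter than the
#' unaffected class, the "down" class for being longer (directions
#' fixed a priori by the degradation phenomenology: degraded RNA
#' under-represents long transcripts and over-represents short ones).
#' Tests are exact when both groups have at most 8 members and no
#' ties; otherwise the normal approximation with tie correction is
#' used. An empty class skips its test with a notice rather than
#' failing.
#'
#' @param classes character vector of classes ("up", "down",
#'   "unaffected") per cluster.
#' @param lengths transcript lengths (bp), parallel to `classes`.
#' @param alternative "one.sided" (default, directions as above) or
#'   "two.sided".
#' @return data.frame with `comparison`, `n1`, `n2`, `W`, `p`, and
#'   per-class medians as attribute `class_medians`.
#' @export
lengthBiasTest <- function(classes, lengths,
        alternative = c("one.sided", "two.sided")) {
    alternative <- match.arg(alternative)
    stopifnot(length(classes) == length(lengths))
    med <- tapply(lengths, factor(classes,
        c("up", "unaffected", "down")), stats::median)
    one <- function(cls, alt) {
        x <- lengths[classes == cls]
        y <- lengths[classes == "unaffected"]
        if (!length(x) || !length(y)) {
            message("class '", cls, "' empty; test skipped")
            return(data.frame(comparison = paste0(cls,
                "_vs_unaffected"), n1 = length(x), n2 = length(y),
                W = NA_real_, p = NA_real_))
        }
        exact <- max(length(x), length(y)) <= 8 &&
            !anyDuplicated(c(x, y))
        alt2 <- if (alternative == "two.sided") "two.sided" else alt
        wt <- suppressWarnings(stats::wilcox.test(x, y,
            alternative = alt2, exact = exact, correct = !exact))
        data.frame(comparison = paste0(cls, "_vs_unaffected"),
            n1 = length(x), n2 = length(y),
            W = unname(wt$statistic), p = wt$p.value)
    }
    out <- rbind(one("up", "less"), one("down", "greater"))
    attr(out, "class_medians") <- med
    out
}

#' 5'-to-3' positional mean-intensity profile
#'
#' Restricts to transcript clusters with exactly `k` pm probes and
#' averages, per array and probe position, the intensity over those
#' clusters. On random-primed ST-style data the profile is flat;
#' 3'-biased (oligo-dT) chemistry shows a rising profile.
#'
#' @param x a [ProbeMatrix-class] (raw linear or normalized log2).
#' @param ann a [ProbeAnnotation-class].
#' @param k number of pm probes per cluster to select (default 25,
#'   the largest probe-count group on the ST platform).
#' @return matrix k x arrays of positional means; attribute
#'   `n_clusters` records how many clusters were used.
#' @export
positionalProfile <- function(x, ann, k = 25L) {
    a <- annotation(ann)
    pm <- a[a$probe_type == "pm", , drop = FALSE]
    sizes <- table(pm$cluster_id)
    use <- names(sizes)[sizes == k]
    if (!length(use))
        stop("no cluster with exactly ", k, " pm probes; available ",
            "sizes: ", paste(sort(unique(as.vector(sizes))),
                collapse = ", "))
    sel <- pm[pm$cluster_id %in% use, , drop = FALSE]
    v <- intensities(x)[sel$probe_id, , drop = FALSE]
    prof <- rowsum(v, group = sel$position_index) /
        as.vector(table(sel$position_index))
    prof <- prof[order(as.integer(rownames(prof))), , drop = FALSE]
    rownames(prof) <- paste0("pos", rownames(prof))
    attr(prof, "n_clusters") <- length(use)
    prof
}
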