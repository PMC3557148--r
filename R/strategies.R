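## The five compensation strategies for differential expression with
## variable-quality arrays, plus list-overlap counting and
## hierarchical clustering used to evaluate them.

#' Differential expression under one compensation strategy
#'
#' All strategies share the fit -> empirical-Bayes moderation -> BH
#' chain on the tumour - normal contrast; they differ in how array
#' quality enters:
#' \describe{
#'   \item{weights}{per-array quality weights from
#'     [estimateArrayWeights()] enter the weighted fit; all arrays are
#'     retained.}
#'   \item{exclude}{quality-flagged arrays are dropped before an
#'     unweighted fit.}
#'   \item{combat}{the expression matrix is first directly adjusted
#'     for batch and then for the binary quality category
#'     ([adjustBatchThenQuality()]); the fit then uses condition
#'     only.}
#'   \item{covariate}{quality (the binary flag) and batch join
#'     condition as factors in the design.}
#'   \item{sva}{surrogate variables estimated from the residual
#'     structure ([runSVA()], or supplied) join the design.}
#' }
#' No fold-change cutoff is applied to the result; callers filter as
#' needed.
#'
#' @param strategy one of "weights", "exclude", "combat", "covariate",
#'   "sva".
#' @param expr clusters x arrays log2 expression matrix.
#' @param report a [QCReport-class].
#' @param metadata a [SampleMetadata-class].
#' @param sv optional [SurrogateVariables-class] for the sva strategy
#'   (estimated from `expr` when missing).
#' @param config configuration list.
#' @return data.frame (one row per cluster): `cluster_id`, `log2fc`
#'   (tumour - normal), `t`, `p`, `adj_p`, `mean_expr`; the arrays
#'   actually used are recorded in attribute `arrays_used`.
#' @export
runStrategy <- function(strategy, expr, report, metadata, sv = NULL,
        config = defaultConfig()) {
    strategy <- match.arg(strategy,
        c("weights", "exclude", "combat", "covariate", "sva"))
    info <- sampleInfo(metadata)
    ord <- match(colnames(expr), info$array_id)
    if (anyNA(ord)) stop("expression columns missing from metadata")
    info <- info[ord, , drop = FALSE]
    r <- qcTable(report)
    flag <- r$flagged[match(colnames(expr), r$array_id)]
    tum <- as.numeric(info$condition == "tumour")
    two_batches <- length(unique(info$batch)) > 1L

    weights <- NULL
    if (strategy == "exclude") {
        keep <- !flag
        grp <- table(info$condition[keep])
        if (length(grp) < 2L || any(grp < 3L))
            stop("excluding flagged arrays leaves < 3 arrays in a group")
        expr <- expr[, keep, drop = FALSE]
        info <- info[keep, , drop = FALSE]
        tum <- tum[keep]
        flag <- flag[keep]
        two_batches <- length(unique(info$batch)) > 1L
    } else if (strategy == "combat") {
        expr <- adjustBatchThenQuality(expr, metadata, report,
            tol = config$combat_tol, max_iter = config$combat_max_iter)
    }

    design <- cbind(intercept = 1, tumour = tum)
    if (strategy == "covariate") {
        ## factors with a single observed level carry no information
        ## and would make the design singular
        if (length(unique(flag)) > 1L)
            design <- cbind(design, quality = as.numeric(flag))
        if (two_batches)
            design <- cbind(design,
                batch = as.numeric(factor(info$batch)) - 1)
    } else if (strategy == "sva") {
        if (is.null(sv))
            sv <- runSVA(expr, design, config)
        if (numSV(sv) > 0L)
            design <- cbind(design, svMatrix(sv))
    } else if (strategy == "weights") {
        weights <- estimateArrayWeights(expr, design,
            tol = config$aw_tol, max_iter = config$aw_max_iter)
    }

    fit <- fitGeneLM(expr, design, weights = weights)
    mod <- ebayesModerate(fit, "tumour")
    out <- data.frame(cluster_id = rownames(expr),
        log2fc = mod$log2fc, t = mod$t, p = mod$p,
        adj_p = bhAdjust(mod$p), mean_expr = rowMeans(expr),
        stringsAsFactors = FALSE, row.names = NULL)
    attr(out, "strategy") <- strategy
    attr(out, "arrays_used") <- colnames(expr)
    out
}

#' Run several strategies and collect the results
#'
#' @param expr,report,metadata,sv,config as in [runStrategy()].
#' @param strategies character vector of strategy ids.
#' @return named list of [runStrategy()] results.
#' @export
runAllStrategies <- function(expr, report, metadata, sv = NULL,
        strategies = c("weights", "exclude", "combat", "covariate",
            "sva"), config = defaultConfig()) {
    stats::setNames(lapply(strategies, runStrategy, expr = expr,
        report = report, metadata = metadata, sv = sv,
        config = config), strategies)
}

#' Venn region counts for a collection of gene lists
#'
#' Counts every intersection region of the k lists (2^k - 1 regions);
#' the region counts sum to the size of the union.
#'
#' @param lists named list of character vectors.
#' @return data.frame with one row per region: a membership pattern
#'   column per list and `count`.
#' @export
overlapCounts <- function(lists) {
    if (length(lists) < 2L) stop("need >= 2 lists")
    if (is.null(names(lists)))
        names(lists) <- paste0("list", seq_along(lists))
    u <- unique(unlist(lists))
    member <- vapply(lists, function(l) u %in% l,
        logical(length(u)))
    if (length(u) == 1L) member <- matrix(member, nrow = 1L,
        dimnames = list(NULL, names(lists)))
    pat <- expand.grid(rep(list(c(TRUE, FALSE)), length(lists)))
    names(pat) <- names(lists)
    pat <- pat[rowSums(pat) > 0, , drop = FALSE]
    pat$count <- apply(pat, 1L, function(row)
        sum(apply(member, 1L, function(m) all(m == row))))
    rownames(pat) <- NULL
    pat
}

#' Average-linkage hierarchical clustering of arrays
#'
#' Clusters arrays (columns) with average linkage under either
#' Euclidean distance or 1 - Pearson correlation. The published
#' methods text and figure legend disagree on the distance (Euclidean
#' vs 1 - Pearson); both are available and the correlation form is
#' the default.
#'
#' @param expr clusters x arrays log2 expression matrix.
#' @param distance "one_minus_pearson" or "euclidean".
#' @return an [stats::hclust] object over the arrays.
#' @export
hclusterArrays <- function(expr,
        distance = c("one_minus_pearson", "euclidean")) {
    distance <- match.arg(distance)
    if (ncol(expr) < 2L) stop("need >= 2 arrays")
    d <- if (distance == "euclidean") {
        stats::dist(t(expr))
    } else {
        sds <- apply(expr, 2L, stats::sd)
        if (any(sds == 0))
            stop("constant array under correlation distance: ",
                colnames(expr)[sds == 0][1L])
        stats::as.dist(1 - stats::cor(expr))
    }
    stats::hclust(d, method = "average")
}

#' Mean silhouette of a binary partition under a distance
#'
#' Used to quantify whether quality-flagged arrays still form their
#' own cluster after adjustment (values near 0 or below: they do
#' not).
#'
#' @param expr clusters x arrays matrix.
#' @param groups logical or factor partition of the arrays.
#' @param distance as in [hclusterArrays()].
#' @return mean silhouette width.
#' @export
partitionSilhouette <- function(expr, groups,
        distance = c("one_minus_pearson", "euclidean")) {
    distance <- match.arg(distance)
    d <- if (distance == "euclidean") as.matrix(stats::dist(t(expr)))
        else 1 - stats::cor(expr)
    g <- as.factor(groups)
    if (nlevels(g) < 2L) stop("need >= 2 groups")
    n <- ncol(expr)
    s <- numeric(n)
    for (i in seq_len(n)) {
        own <- which(g == g[i]); own <- setdiff(own, i)
        oth <- which(g != g[i])
        if (!length(own)) { s[i] <- 0; next }
        a <- mean(d[i, own]); b <- mean(d[i, oth])
        s[i] <- (b - a) / max(a, b)
    }
    mean(s)
}
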