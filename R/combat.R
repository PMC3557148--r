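## Parametric empirical-Bayes location/scale batch adjustment
## (Johnson-style). Only the parametric variant is implemented; the
## quality adjustment is the same operation with the QC flag
## categories as "batches", applied after the batch adjustment.

#' Empirical-Bayes adjustment for a known batch (or quality) factor
#'
#' Gene-wise standardization removes the grand mean, protected
#' covariate effects and the pooled variance; per-batch location and
#' scale parameters estimated on the standardized data are shrunk via
#' a normal prior on locations and an inverse-gamma prior on scales
#' (hyperparameters by method of moments across genes, posteriors by
#' the standard iterative fixed point); the adjusted values restore
#' the protected fit. With a single batch level the input is returned
#' unchanged.
#'
#' @param expr genes x arrays log2 expression matrix.
#' @param batch factor-like batch (or quality-category) label per
#'   array; every level needs >= 2 arrays.
#' @param covariates optional arrays x p design matrix of biological
#'   terms to protect (e.g. a condition indicator); an intercept is
#'   always included internally and must not be supplied.
#' @param tol convergence tolerance of the posterior fixed point.
#' @param max_iter maximum fixed-point iterations per batch.
#' @return adjusted matrix with the dimensions of `expr`.
#' @export
combatAdjust <- function(expr, batch, covariates = NULL, tol = 1e-4,
        max_iter = 100L) {
    batch <- factor(batch)
    n <- ncol(expr)
    stopifnot(length(batch) == n)
    if (nlevels(batch) < 2L) return(expr)
    nb <- table(batch)
    if (any(nb < 2))
        stop("batch level with a single array: ",
            names(nb)[nb < 2][1L])
    B <- stats::model.matrix(~ 0 + batch)          # n x K indicators
    X <- B
    if (!is.null(covariates)) {
        covariates <- as.matrix(covariates)
        X <- cbind(B, covariates)
        if (qr(X)$rank < ncol(X))
            stop("covariates confounded with batch (design not full rank)")
    }
    K <- nlevels(batch)
    ## gene-wise OLS on the full design
    beta <- t(solve(crossprod(X), crossprod(X, t(expr))))  # genes x p
    gamma_hat0 <- beta[, seq_len(K), drop = FALSE]
    grand <- as.vector(gamma_hat0 %*% (as.vector(nb) / n))
    stand_mean <- matrix(grand, nrow(expr), n)
    if (!is.null(covariates))
        stand_mean <- stand_mean +
            beta[, -seq_len(K), drop = FALSE] %*% t(covariates)
    resid <- expr - t(X %*% t(beta))
    var_pooled <- rowSums(resid^2) / n  # divisor n, population convention
    if (any(var_pooled == 0))
        stop("gene with zero pooled variance; cannot standardize")
    s_data <- (expr - stand_mean) / sqrt(var_pooled)

    adj <- s_data
    for (k in seq_len(K)) {
        cols <- which(batch == levels(batch)[k])
        nk <- length(cols)
        zk <- s_data[, cols, drop = FALSE]
        g_hat <- rowMeans(zk)
        d_hat <- apply(zk, 1L, stats::var)
        g_bar <- mean(g_hat); t2 <- stats::var(g_hat)
        m <- mean(d_hat); s2 <- stats::var(d_hat)
        a_prior <- (2 * s2 + m^2) / s2
        b_prior <- (m * s2 + m^3) / s2
        g_new <- g_hat; d_new <- d_hat
        for (it in seq_len(max_iter)) {
            g_old <- g_new; d_old <- d_new
            g_new <- (t2 * nk * g_hat + d_new * g_bar) /
                (t2 * nk + d_new)
            ss <- rowSums((zk - g_new)^2)
            d_new <- (b_prior + 0.5 * ss) / (nk / 2 + a_prior - 1)
            change <- max(abs(g_new - g_old) /
                    pmax(abs(g_old), 1e-12),
                abs(d_new - d_old) / pmax(abs(d_old), 1e-12))
            if (change < tol) break
            if (it == max_iter)
                stop("EB fixed point did not converge for batch ",
                    levels(batch)[k])
        }
        adj[, cols] <- (zk - g_new) / sqrt(d_new)
    }
    adj * sqrt(var_pooled) + stand_mean
}

#' Sequential batch-then-quality adjustment
#'
#' The direct-adjustment compensation strategy: adjust for processing
#' batch first, then for the binary quality category derived from the
#' QC flag, protecting the disease-status covariate in both passes
#' (protection can be disabled).
#'
#' @param expr genes x arrays log2 expression matrix.
#' @param metadata a [SampleMetadata-class].
#' @param report a [QCReport-class] whose flags define the quality
#'   categories.
#' @param protect_condition protect tumour/normal status during
#'   adjustment (default TRUE).
#' @param ... passed on to [combatAdjust()].
#' @return adjusted matrix.
#' @export
adjustBatchThenQuality <- function(expr, metadata, report,
        protect_condition = TRUE, ...) {
    info <- sampleInfo(metadata)
    ord <- match(colnames(expr), info$array_id)
    if (anyNA(ord)) stop("expression columns missing from metadata")
    cov <- if (protect_condition)
        cbind(tumour = as.numeric(info$condition[ord] == "tumour"))
        else NULL
    out <- combatAdjust(expr, info$batch[ord], cov, ...)
    r <- qcTable(report)
    flag <- r$flagged[match(colnames(expr), r$array_id)]
    if (anyNA(flag)) stop("expression columns missing from QC report")
    if (length(unique(flag)) > 1L && min(table(flag)) >= 2L)
        out <- combatAdjust(out, ifelse(flag, "flagged", "passed"),
            cov, ...)
    out
}
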