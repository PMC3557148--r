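## Gene-wise (weighted) least squares, heteroscedastic array-quality
## weights, empirical-Bayes variance moderation and BH adjustment.

#' Gene-wise weighted least-squares fit
#'
#' Fits the same design to every gene, optionally with per-array
#' precision weights (var(e_gj) = sigma_g^2 / w_j). Residual variances
#' are unbiased with df = n - rank(design).
#'
#' @param expr genes x arrays log2 expression matrix.
#' @param design arrays x p full-rank design matrix (with intercept).
#' @param weights optional positive per-array weights.
#' @return list with `coefficients` (genes x p), `sigma2`, `df_residual`
#'   (scalar), `cov_unscaled` (p x p: (X'WX)^-1) and `design`.
#' @export
fitGeneLM <- function(expr, design, weights = NULL) {
    design <- as.matrix(design)
    n <- ncol(expr); p <- ncol(design)
    stopifnot(nrow(design) == n)
    if (n <= p) stop("more design terms than arrays")
    if (qr(design)$rank < p) {
        stop("design is rank deficient; check terms: ",
            paste(colnames(design), collapse = ", "))
    }
    if (is.null(weights)) weights <- rep(1, n)
    stopifnot(length(weights) == n, all(weights > 0))
    sw <- sqrt(weights)
    Xw <- design * sw
    Yw <- expr * rep(sw, each = nrow(expr))
    XtX <- crossprod(Xw)
    cov_unscaled <- solve(XtX)
    beta <- t(cov_unscaled %*% crossprod(Xw, t(Yw)))
    resid <- Yw - beta %*% t(Xw)
    df <- n - p
    sigma2 <- rowSums(resid^2) / df
    colnames(beta) <- colnames(design)
    list(coefficients = beta, sigma2 = sigma2, df_residual = df,
        cov_unscaled = cov_unscaled, design = design,
        weights = weights)
}

#' Estimate per-array quality weights
#'
#' Heteroscedastic model var(e_gj) = sigma_g^2 / w_j, fitted by
#' iterative moment updates: given current weights, each gene is fit
#' by weighted least squares; the leverage-corrected standardized
#' squared residuals are averaged over genes to update each array's
#' variance factor. Weights are normalized so their product is 1.
#' Degraded arrays receive small weights.
#'
#' @param expr genes x arrays log2 expression matrix (>= 100 genes
#'   recommended).
#' @param design arrays x p design matrix.
#' @param tol relative-change convergence tolerance.
#' @param max_iter iteration cap; non-convergence yields a warning and
#'   the last iterate.
#' @return named positive weights with product 1.
#' @export
estimateArrayWeights <- function(expr, design, tol = 1e-4,
        max_iter = 50L) {
    design <- as.matrix(design)
    n <- ncol(expr)
    if (n < 3) stop("need >= 3 arrays")
    w <- rep(1, n)
    for (it in seq_len(max_iter)) {
        fit <- fitGeneLM(expr, design, weights = w)
        sw <- sqrt(w)
        Xw <- design * sw
        h <- diag(Xw %*% fit$cov_unscaled %*% t(Xw))
        resid_w <- (expr - fit$coefficients %*% t(design)) *
            rep(sw, each = nrow(expr))
        z <- resid_w^2 / fit$sigma2  # genes x arrays, standardized
        ## residuals carry the current weights, so the column means
        ## estimate the multiplicative correction to each weight
        v_corr <- colMeans(z) / pmax(1 - h, 1e-8)
        w_new <- w / v_corr
        w_new <- w_new / exp(mean(log(w_new)))
        change <- max(abs(w_new - w) / w)
        w <- w_new
        if (change < tol) break
        if (it == max_iter)
            warning("array weight estimation did not converge; ",
                "returning last iterate")
    }
    stats::setNames(w, colnames(expr))
}

## Newton inversion of the trigamma function (for prior df matching).
trigammaInverse <- function(x) {
    if (x > 1e7) return(1 / sqrt(x))
    if (x < 1e-6) return(1 / x)
    y <- 0.5 + 1 / x
    for (i in 1:50) {
        tri <- trigamma(y)
        dif <- tri * (1 - tri / x) / psigamma(y, 2L)
        y <- y + dif
        if (abs(dif) / y < 1e-8) break
    }
    y
}

#' Empirical-Bayes moderation of gene-wise variances
#'
#' Estimates a prior df d0 and prior variance s0^2 by matching the
#' moments of log sigma_g^2 (digamma/trigamma matching of a scaled-F
#' model), shrinks each gene's variance to the posterior
#' (d0 s0^2 + d sigma_g^2) / (d0 + d), and returns moderated t and
#' two-sided p for the requested coefficient with d0 + d degrees of
#' freedom. When the observed log-variances are underdispersed
#' relative to chi-square sampling noise, d0 is infinite and all
#' variances shrink to s0^2.
#'
#' @param fit result of [fitGeneLM()].
#' @param coef name or index of the tested coefficient.
#' @param prior_df optional override of the estimated prior df d0
#'   (0 disables moderation entirely, recovering the ordinary
#'   gene-wise t-test).
#' @return data.frame with `log2fc` (the coefficient), `t`, `p`,
#'   `s2_post`, plus attributes `d0` and `s0_2`.
#' @export
ebayesModerate <- function(fit, coef, prior_df = NULL) {
    s2 <- fit$sigma2
    d <- fit$df_residual
    if (length(s2) < 10)
        stop("need >= 10 genes for hyperparameter estimation")
    if (all(s2 == 0)) stop("all residual variances are zero")
    ok <- s2 > 0
    z <- log(s2[ok])
    e <- z - digamma(d / 2) + log(d / 2)
    emean <- mean(e)
    evar <- stats::var(e) - trigamma(d / 2)
    if (is.finite(evar) && evar > 0) {
        d0 <- 2 * trigammaInverse(evar)
        s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
        d0 <- Inf
        s0_2 <- exp(emean)
    }
    if (!is.null(prior_df)) d0 <- prior_df
    if (d0 == 0) s0_2 <- 0
    s2_post <- if (is.finite(d0))
        (d0 * s0_2 + d * s2) / (d0 + d) else rep(s0_2, length(s2))
    j <- if (is.character(coef))
        match(coef, colnames(fit$coefficients)) else coef
    if (is.na(j)) stop("unknown coefficient: ", coef)
    beta <- fit$coefficients[, j]
    v <- fit$cov_unscaled[j, j]
    tstat <- beta / sqrt(s2_post * v)
    df_total <- d0 + d
    p <- 2 * stats::pt(-abs(tstat),
        df = if (is.finite(df_total)) df_total else Inf)
    if (!is.finite(df_total)) p <- 2 * stats::pnorm(-abs(tstat))
    out <- data.frame(log2fc = beta, t = tstat, p = p,
        s2_post = s2_post)
    attr(out, "d0") <- d0
    attr(out, "s0_2") <- s0_2
    out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (delegates to [stats::p.adjust()] after
#' validating the inputs); output order matches input order.
#'
#' @param p numeric p-values in \[0, 1\].
#' @return adjusted p-values.
#' @export
bhAdjust <- function(p) {
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}
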