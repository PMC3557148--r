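## Surrogate variable analysis: estimate how many latent factors the
## residual matrix supports (permutation test on singular-value
## variance proportions) and construct the surrogate variables from
## the genes most associated with each residual singular vector.

residualMatrix <- function(expr, design) {
    design <- as.matrix(design)
    H <- design %*% solve(crossprod(design), t(design))
    expr - expr %*% t(H)
}

#' Estimate the number of surrogate variables
#'
#' Permutation (Buja-Eyuboglu style) criterion: the proportion of
#' residual variance carried by each right singular vector is compared
#' with its null distribution obtained by permuting every gene's
#' residuals independently; leading components whose observed
#' proportion exceeds the permutation null at the configured
#' significance level are counted. Empirical p-values are made
#' monotone along the component index before thresholding.
#'
#' @param expr genes x arrays log2 expression matrix.
#' @param design arrays x p full-rank design of known (protected)
#'   terms, including the intercept.
#' @param n_permutations number of permutation draws (>= 20).
#' @param seed RNG seed for the permutations.
#' @param sig_level significance level of the permutation test
#'   (default 0.10).
#' @return integer number of surrogate variables.
#' @export
estimateNumSV <- function(expr, design, n_permutations = 100L,
        seed = 1L, sig_level = 0.10) {
    if (n_permutations < 20L) stop("need >= 20 permutations")
    design <- as.matrix(design)
    if (ncol(expr) - qr(design)$rank < 2L)
        stop("residual degrees of freedom < 2")
    set.seed(seed)
    E <- residualMatrix(expr, design)
    prop <- function(M) {
        d <- svd(M, nu = 0, nv = 0)$d^2
        d / sum(d)
    }
    obs <- prop(E)
    m <- length(obs)
    null <- matrix(NA_real_, n_permutations, m)
    for (b in seq_len(n_permutations)) {
        P <- t(apply(E, 1L, sample))
        null[b, ] <- prop(residualMatrix(P, design))
    }
    p <- vapply(seq_len(m), function(i) mean(null[, i] >= obs[i]),
        numeric(1L))
    p <- cummax(p)  # once a component fails, later ones cannot count
    sum(p <= sig_level)
}

#' Estimate surrogate variables
#'
#' For each of the leading `n_sv` right singular vectors of the
#' residual matrix: every gene is scored by the correlation of its
#' residual profile with the vector; genes with association p below
#'   the threshold (at least `min_genes`, topped up by smallest p)
#' form a subset whose residual expression (protected design
#' projected out) is decomposed by SVD; the singular vector of that
#' subset most correlated with the original residual vector becomes
#' the surrogate variable. Working on residuals rather than raw
#' expression keeps the surrogate variables from absorbing the
#' protected biological contrast. Columns are orthonormalized
#' (Gram-Schmidt) before return.
#'
#' @param expr genes x arrays log2 expression matrix.
#' @param design arrays x p design of protected terms (with
#'   intercept).
#' @param n_sv number of surrogate variables (0 gives an empty set).
#' @param seed RNG seed (kept for interface symmetry; the construction
#'   is deterministic given the inputs).
#' @param gene_p association p-value threshold for the gene subset.
#' @param min_genes minimum subset size.
#' @return a [SurrogateVariables-class] with arrays x n_sv matrix.
#' @export
estimateSV <- function(expr, design, n_sv, seed = 1L, gene_p = 0.05,
        min_genes = 50L) {
    design <- as.matrix(design)
    n <- ncol(expr)
    if (n_sv == 0L)
        return(new("SurrogateVariables",
            sv = matrix(numeric(0), n, 0)))
    set.seed(seed)
    E <- residualMatrix(expr, design)
    sv_res <- svd(E)$v[, seq_len(n_sv), drop = FALSE]
    df <- n - ncol(design) - 1L
    out <- matrix(NA_real_, n, n_sv)
    for (k in seq_len(n_sv)) {
        v <- sv_res[, k]
        r <- as.vector(E %*% v) /
            (sqrt(rowSums(E^2)) * sqrt(sum(v^2)))
        r[is.na(r)] <- 0
        tstat <- r * sqrt(df / pmax(1 - r^2, 1e-12))
        p <- 2 * stats::pt(-abs(tstat), df)
        sel <- which(p < gene_p)
        if (length(sel) < min_genes)
            sel <- order(p)[seq_len(min(min_genes, nrow(expr)))]
        ## decompose the subset with the protected design projected
        ## out, so surrogate variables cannot absorb the biological
        ## contrast they are meant to protect
        sub <- svd(E[sel, , drop = FALSE])
        cors <- abs(stats::cor(sub$v, v))
        out[, k] <- sub$v[, which.max(cors)]
    }
    ## Gram-Schmidt orthonormalization
    for (k in seq_len(n_sv)) {
        if (k > 1L)
            out[, k] <- out[, k] -
                out[, seq_len(k - 1L), drop = FALSE] %*%
                crossprod(out[, seq_len(k - 1L), drop = FALSE],
                    out[, k])
        nk <- sqrt(sum(out[, k]^2))
        if (nk < 1e-10) stop("degenerate surrogate variable ", k)
        out[, k] <- out[, k] / nk
    }
    rownames(out) <- colnames(expr)
    colnames(out) <- paste0("sv", seq_len(n_sv))
    new("SurrogateVariables", sv = out)
}

#' Full SVA step: estimate count, then construct
#'
#' @param expr genes x arrays log2 expression matrix.
#' @param design arrays x p protected design (with intercept).
#' @param config configuration list (permutations, significance and
#'   gene-subset settings).
#' @param seed RNG seed.
#' @return a [SurrogateVariables-class].
#' @export
runSVA <- function(expr, design, config = defaultConfig(),
        seed = config$rng_seed) {
    n_sv <- estimateNumSV(expr, design,
        n_permutations = config$sva_n_permutations, seed = seed,
        sig_level = config$sva_sig_level)
    estimateSV(expr, design, n_sv, seed = seed,
        gene_p = config$sva_gene_p, min_genes = config$sva_min_genes)
}
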