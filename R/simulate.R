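## Synthetic probe-level cohorts with known truth.
##
## Generative model (log2 scale, pm probe p of cluster g on array j):
##   y_pgj = mu_g + (delta_g + eta_g,pat(j)) * I[tumour_j]
##         + b_batch(j),g + q_j * gamma_g - c * q_j + phi_p + eps_pj
## with eps_pj ~ N(0, sigma_j^2), sigma_j = sigma0 * (1 + lambda * q_j),
## q_j = clip((7 - rin_j) / 5, 0, 1) and
## gamma_g = -kappa * log2(length_g / median length).
## Linear intensities are 2^y. Background probes are drawn from a fixed
## low-mean log-normal and do not depend on condition or degradation;
## the global attenuation -c * q_j of pm signal makes the PM-BG metric
## fall with degradation.

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x < lo | x > hi))
        x[bad] <- stats::rnorm(sum(bad), mean, sd)
    x
}

#' RIN to degradation level
#'
#' Deterministic map from RIN to the latent degradation level q used by
#' the generative model: q = clip((7 - rin) / 5, 0, 1), so arrays with
#' RIN >= 7 are undegraded and RIN 2 is fully degraded.
#'
#' @param rin numeric RIN values.
#' @return numeric in \[0, 1\].
#' @export
rinToDegradation <- function(rin) pmin(pmax((7 - rin) / 5, 0), 1)

## Chip-level parameters (annotation, baselines, probe affinities) are
## drawn from their own RNG stream keyed off the seed so that cohort
## and reference arrays share the same chip, as physical arrays do.
simulateChip <- function(n_clusters, probes_per_cluster, cfg) {
    if (probes_per_cluster < 2)
        stop("probes_per_cluster must be >= 2 (summarization undefined)")
    set.seed(cfg$rng_seed + 777L)
    k <- probes_per_cluster
    cl_ids <- sprintf("CL%05d", seq_len(n_clusters))
    len <- stats::rlnorm(n_clusters, cfg$length_meanlog, cfg$length_sdlog)
    n_short <- round(cfg$short_noncoding_fraction * n_clusters)
    short <- rep(FALSE, n_clusters)
    if (n_short > 0) {
        idx <- seq_len(n_short)
        short[idx] <- TRUE
        len[idx] <- stats::runif(n_short, 60, cfg$short_noncoding_max_bp)
    }
    len <- round(len)
    gamma <- -cfg$kappa * log2(len / stats::median(len))
    mu <- stats::rnorm(n_clusters, cfg$mu_mean, cfg$mu_sd)
    phi <- stats::rnorm(n_clusters * k, 0, cfg$probe_effect_sd)
    phi <- as.vector(apply(matrix(phi, k, n_clusters), 2,
        function(x) x - mean(x)))
    pm_ids <- sprintf("%s_P%02d", rep(cl_ids, each = k), rep(seq_len(k),
        n_clusters))
    names(phi) <- pm_ids
    bg_ids <- sprintf("BG%05d", seq_len(cfg$n_background_probes))
    ann <- data.frame(
        probe_id = c(pm_ids, bg_ids),
        cluster_id = c(rep(cl_ids, each = k),
            rep("background", length(bg_ids))),
        probe_type = c(rep("pm", length(pm_ids)),
            rep("background", length(bg_ids))),
        position_index = c(rep(seq_len(k), n_clusters),
            rep(NA_integer_, length(bg_ids))),
        transcript_length_bp = c(rep(len, each = k),
            rep(NA_real_, length(bg_ids))),
        stringsAsFactors = FALSE)
    list(cluster_id = cl_ids, length = len, gamma = gamma, mu = mu,
        phi = phi, short = short, ann = ProbeAnnotation(ann),
        pm_ids = pm_ids, bg_ids = bg_ids, k = k)
}

## pm log2 signal matrix for a set of arrays, given chip + array-level
## states. tumour, batch_col, q, sigma, patient_idx are per-array.
pmSignal <- function(chip, cfg, truthcl, batch_effects, patient_log2fc,
        tumour, batch_col, q, sigma, patient_idx) {
    n_arrays <- length(tumour)
    k <- chip$k
    n_probes <- length(chip$pm_ids)
    pos <- rep(seq_len(k), length(chip$cluster_id))
    y <- matrix(0, n_probes, n_arrays)
    base <- rep(chip$mu, each = k) + chip$phi
    slope <- cfg$positional_bias_slope
    if (slope != 0)
        base <- base + slope * (pos - (k + 1) / 2) / k
    for (j in seq_len(n_arrays)) {
        fc <- truthcl$true_log2fc
        if (!is.null(patient_log2fc) && !is.na(patient_idx[j]))
            fc <- fc + patient_log2fc[, patient_idx[j]]
        cl_term <- (if (tumour[j]) fc else 0) +
            (if (!is.null(batch_effects)) batch_effects[, batch_col[j]]
             else 0) + q[j] * truthcl$gamma
        y[, j] <- base + rep(cl_term, each = k) -
            cfg$pm_attenuation * q[j] +
            stats::rnorm(n_probes, 0, sigma[j])
    }
    dimnames(y) <- list(chip$pm_ids, NULL)
    y
}

bgSignal <- function(chip, cfg, n_arrays) {
    matrix(stats::rnorm(length(chip$bg_ids) * n_arrays, cfg$bg_mean_log2,
        cfg$bg_sd_log2), length(chip$bg_ids), n_arrays,
        dimnames = list(chip$bg_ids, NULL))
}

#' Simulate a paired tumour/normal probe-level cohort
#'
#' Generates a cohort with the structure the quality-assessment
#' pipeline assumes: paired tumour/normal arrays, two processing
#' batches with pairs never split across batches, RIN-linked
#' degradation that inflates probe-level noise, attenuates overall pm
#' signal and redistributes signal by transcript length (long
#' transcripts down, short ones up), additive per-gene batch effects,
#' fixed probe affinities, and background probes.
#'
#' @param n_patients number of patient pairs (default from config: 17,
#'   i.e. 34 arrays).
#' @param n_clusters number of transcript clusters.
#' @param probes_per_cluster pm probes per cluster (>= 2).
#' @param config configuration list from [defaultConfig()].
#' @return list with elements \code{raw} ([ProbeMatrix-class], linear),
#'   \code{annotation} ([ProbeAnnotation-class]), \code{metadata}
#'   ([SampleMetadata-class]) and \code{truth}
#'   ([SimulationTruth-class]).
#' @examples
#' sim <- simulateCohort(4, 50, 4, defaultConfig(rng_seed = 7))
#' sim$raw
#' @export
simulateCohort <- function(n_patients = config$n_patients,
        n_clusters = config$n_clusters,
        probes_per_cluster = config$probes_per_cluster,
        config = defaultConfig()) {
    cfg <- config
    if (n_patients < 2) stop("n_patients must be >= 2")
    chip <- simulateChip(n_clusters, probes_per_cluster, cfg)
    set.seed(cfg$rng_seed)

    ## cluster-level truth
    n_de <- round(cfg$de_fraction * n_clusters)
    de <- rep(FALSE, n_clusters)
    de[sample.int(n_clusters, n_de)] <- TRUE
    fc <- numeric(n_clusters)
    fc[de] <- sample(c(-1, 1), n_de, replace = TRUE) *
        stats::runif(n_de, cfg$de_log2fc_min, cfg$de_log2fc_max)
    ref <- rep(FALSE, n_clusters)
    ref[sample(which(!de), 3L)] <- TRUE
    clusters <- data.frame(cluster_id = chip$cluster_id,
        true_log2fc = fc, de_flag = de, gamma = chip$gamma,
        mu = chip$mu, transcript_length_bp = chip$length,
        short_noncoding = chip$short, reference_gene = ref,
        stringsAsFactors = FALSE)

    ## patients / arrays / batches
    patients <- sprintf("P%02d", seq_len(n_patients))
    b1 <- min(max(cfg$batch1_pairs, 1L), n_patients - 1L)
    batch <- rep(c("batch1", "batch2"), c(b1, n_patients - b1))
    array_id <- as.vector(rbind(paste0(patients, "T"),
        paste0(patients, "N")))
    tumour <- rep(c(TRUE, FALSE), n_patients)
    patient_of <- rep(patients, each = 2L)
    batch_of <- rep(batch, each = 2L)
    w <- cfg$rin_low_weight
    lowq <- stats::runif(2L * n_patients) < w
    rin <- ifelse(lowq,
        rtruncnorm1(2L * n_patients, cfg$rin_low_mean, cfg$rin_low_sd,
            cfg$rin_min, cfg$rin_max),
        rtruncnorm1(2L * n_patients, cfg$rin_high_mean, cfg$rin_high_sd,
            cfg$rin_min, cfg$rin_max))
    rin <- round(rin, 1)
    a260 <- round(stats::runif(2L * n_patients, 1.6, 2.4), 2)
    q <- rinToDegradation(rin)
    sigma <- cfg$sigma0 * (1 + cfg$noise_inflation * q)

    meta <- SampleMetadata(data.frame(array_id = array_id,
        patient_id = patient_of, condition = ifelse(tumour, "tumour",
            "normal"), batch = batch_of, rin = rin, a260_230 = a260,
        stringsAsFactors = FALSE))

    ## per-gene batch effects (batch1 is the baseline) and
    ## patient-level biological deviations from the cohort log2FC
    batch_effects <- cbind(batch1 = 0,
        batch2 = stats::rnorm(n_clusters, 0, cfg$batch_effect_sd))
    rownames(batch_effects) <- chip$cluster_id
    ## patient-level biological heterogeneity of the tumour effect is
    ## confined to the dysregulated (DE) clusters; housekeeping-like
    ## clusters (including the reference genes) are stable
    patient_log2fc <- matrix(0, n_clusters, n_patients,
        dimnames = list(chip$cluster_id, patients))
    patient_log2fc[de, ] <- stats::rnorm(n_de * n_patients, 0,
        cfg$patient_fc_sd)

    y_pm <- pmSignal(chip, cfg, clusters, batch_effects, patient_log2fc,
        tumour, match(batch_of, colnames(batch_effects)), q, sigma,
        match(patient_of, patients))
    y_bg <- bgSignal(chip, cfg, length(array_id))
    y <- rbind(y_pm, y_bg)
    colnames(y) <- array_id
    raw <- ProbeMatrix(2^y, "linear")

    truth <- new("SimulationTruth", clusters = clusters,
        arrays = data.frame(array_id = array_id, rin = rin, q = q,
            sigma = sigma, stringsAsFactors = FALSE),
        batch_effects = batch_effects,
        patient_log2fc = patient_log2fc,
        probe_effects = chip$phi)
    list(raw = raw, annotation = chip$ann, metadata = meta,
        truth = truth)
}

#' Simulate a high-quality reference array set
#'
#' Generates undegraded (q = 0), single-batch, condition-free arrays
#' from the same chip (same annotation, baselines and probe
#' affinities) as [simulateCohort()] under the same configuration.
#' These arrays stand in for a large public collection of high-quality
#' arrays and are used only to build a [FrozenReference-class].
#'
#' @param n_arrays number of reference arrays (>= 3; >= 10
#'   recommended).
#' @param n_clusters,probes_per_cluster chip layout; must match the
#'   cohort the frozen reference will be applied to.
#' @param config configuration list from [defaultConfig()].
#' @return a linear-scale [ProbeMatrix-class].
#' @export
simulateReferenceSet <- function(n_arrays, n_clusters = config$n_clusters,
        probes_per_cluster = config$probes_per_cluster,
        config = defaultConfig()) {
    cfg <- config
    if (n_arrays < 3) stop("n_arrays must be >= 3 (median SE undefined robustly)")
    chip <- simulateChip(n_clusters, probes_per_cluster, cfg)
    set.seed(cfg$rng_seed + 1337L)
    clusters <- data.frame(true_log2fc = numeric(n_clusters),
        gamma = chip$gamma)
    y_pm <- pmSignal(chip, cfg, clusters, NULL, NULL,
        tumour = rep(FALSE, n_arrays), batch_col = rep(1L, n_arrays),
        q = rep(0, n_arrays), sigma = rep(cfg$sigma0, n_arrays),
        patient_idx = rep(NA_integer_, n_arrays))
    y_bg <- bgSignal(chip, cfg, n_arrays)
    y <- rbind(y_pm, y_bg)
    colnames(y) <- sprintf("REF%03d", seq_len(n_arrays))
    ProbeMatrix(2^y, "linear")
}

#' Simulate qPCR Ct measurements consistent with a simulated cohort
#'
#' For each selected gene and array, replicate Ct values are drawn as
#' Ct = A - theta * ln(2) / ln(e) + N(0, sigma_ct^2), where theta is
#' the biological log2 abundance of the gene in that sample (baseline
#' plus the patient-specific tumour effect) and e is the primer
#' efficiency. With this parameterisation e^(Ct_normal - Ct_tumour)
#' equals the true linear fold change exactly when sigma_ct = 0. The
#' three clusters marked \code{reference_gene} in the truth are always
#' included with true fold change 1.
#'
#' @param truth a [SimulationTruth-class] from [simulateCohort()].
#' @param metadata the matching [SampleMetadata-class].
#' @param genes character, test-gene cluster ids (subset of simulated
#'   clusters).
#' @param efficiencies named numeric in (1, 2], one per test and
#'   reference gene; unnamed scalar recycles to all.
#' @param config configuration list.
#' @return data.frame in long format: gene, role (test/reference),
#'   efficiency, array_id, patient_id, condition, replicate, ct.
#' @export
simulateQpcr <- function(truth, metadata, genes,
        efficiencies = 2, config = defaultConfig()) {
    cfg <- config
    cl <- truthClusters(truth)
    refs <- cl$cluster_id[cl$reference_gene]
    all_genes <- unique(c(genes, refs))
    if (!all(all_genes %in% cl$cluster_id))
        stop("genes must be simulated cluster ids")
    if (length(efficiencies) == 1L && is.null(names(efficiencies)))
        efficiencies <- stats::setNames(rep(efficiencies,
            length(all_genes)), all_genes)
    if (!all(all_genes %in% names(efficiencies)))
        stop("missing efficiency for: ", paste(setdiff(all_genes,
            names(efficiencies)), collapse = ", "))
    if (any(efficiencies <= 1 | efficiencies > 2))
        stop("efficiencies must lie in (1, 2]")
    set.seed(cfg$rng_seed + 4242L)
    info <- sampleInfo(metadata)
    gi <- match(all_genes, cl$cluster_id)
    out <- vector("list", length(all_genes))
    for (g in seq_along(all_genes)) {
        e <- efficiencies[[all_genes[g]]]
        theta <- cl$mu[gi[g]] + ifelse(info$condition == "tumour",
            cl$true_log2fc[gi[g]] +
                truth@patient_log2fc[gi[g], info$patient_id], 0)
        ct_mean <- cfg$qpcr_ct_offset - theta * log(2) / log(e)
        reps <- cfg$qpcr_replicates
        out[[g]] <- data.frame(
            gene = all_genes[g],
            role = if (all_genes[g] %in% refs) "reference" else "test",
            efficiency = e,
            array_id = rep(info$array_id, each = reps),
            patient_id = rep(info$patient_id, each = reps),
            condition = rep(info$condition, each = reps),
            replicate = rep(seq_len(reps), nrow(info)),
            ct = rep(ct_mean, each = reps) +
                stats::rnorm(reps * nrow(info), 0, cfg$qpcr_sigma_ct),
            stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
}
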