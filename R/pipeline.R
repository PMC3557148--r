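## End-to-end orchestration over synthetic or on-disk inputs:
## simulate -> QC -> frozen preprocessing -> compensation strategies
## -> degradation-bias report -> qPCR validation, writing TSV
## artifacts at each stage.

stageLog <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full quality-assessment and compensation pipeline
#'
#' Simulates a cohort and reference set under `config` (or reads the
#' three input tables from `indir` if given), derives the QC report,
#' preprocesses against the frozen reference, runs the requested
#' compensation strategies on the batch-adjusted expression matrix,
#' writes the degradation-bias report, and (for simulated cohorts)
#' the qPCR comparison. All outputs are TSV files in `outdir`. The
#' run is deterministic given `config$rng_seed`.
#'
#' @param config configuration list from [defaultConfig()].
#' @param outdir output directory (created if needed).
#' @param strategies strategy ids to run (see [runStrategy()]).
#' @param n_reference number of simulated reference arrays.
#' @return invisibly, a list with the main in-memory results
#'   (qc report, thresholds, expression, DE tables, bias report).
#' @export
runPipeline <- function(config = defaultConfig(), outdir = tempfile(),
        strategies = c("weights", "exclude", "combat", "covariate",
            "sva"), n_reference = 20L) {
    known <- c("weights", "exclude", "combat", "covariate", "sva")
    if (!all(strategies %in% known))
        stop("unknown strategy id: ",
            paste(setdiff(strategies, known), collapse = ", "))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

    stageLog("simulate", "seed=%d n_patients=%d n_clusters=%d",
        config$rng_seed, config$n_patients, config$n_clusters)
    sim <- simulateCohort(config = config)
    ref <- simulateReferenceSet(n_reference, config = config)
    writeProbeMatrix(sim$raw, file.path(outdir, "probe_matrix.tsv"))
    writeAnnotation(sim$annotation, file.path(outdir, "annotation.tsv"))
    writeMetadata(sim$metadata, file.path(outdir, "metadata.tsv"))
    writeTable(truthClusters(sim$truth),
        file.path(outdir, "truth.tsv"))

    stageLog("preprocess", "building frozen reference from %d arrays",
        ncol(intensities(ref)))
    frozen <- buildFrozenReference(ref, sim$annotation)
    prep <- preprocessFrozen(sim$raw, sim$annotation, frozen)
    writeProbeMatrix(prep$expression,
        file.path(outdir, "expression.tsv"), id_column = "cluster_id")
    writeProbeMatrix(prep$se, file.path(outdir, "se_matrix.tsv"),
        id_column = "cluster_id")

    stageLog("qc", "n_arrays=%d n_probes=%d",
        ncol(intensities(sim$raw)), nrow(intensities(sim$raw)))
    cv <- probeCV(sim$raw)
    pb <- pmBgDifference(sim$raw, sim$annotation)
    thr <- deriveThresholds(cv, pb, sim$metadata, config)
    report <- flagArrays(cv, pb, prep$gnuse_median, thr, config)
    stageLog("qc", "n_flagged=%d", length(flaggedArrays(report)))
    writeTable(qcTable(report), file.path(outdir, "qc_report.tsv"))
    writeTable(data.frame(cv_max = thr@cv_max,
        pm_bg_min = thr@pm_bg_min, gnuse_max = thr@gnuse_max),
        file.path(outdir, "thresholds.tsv"))
    writeTable(as.data.frame(qcSummary(report, sim$metadata, config)),
        file.path(outdir, "qc_summary.tsv"))

    ## batch adjustment is applied once, up front, for all strategies
    info <- sampleInfo(sim$metadata)
    cov <- cbind(tumour = as.numeric(
        info$condition[match(colnames(prep$expression),
            info$array_id)] == "tumour"))
    expr_b <- combatAdjust(prep$expression,
        info$batch[match(colnames(prep$expression), info$array_id)],
        cov, tol = config$combat_tol,
        max_iter = config$combat_max_iter)

    de <- list()
    for (s in strategies) {
        stageLog("dge", "strategy=%s", s)
        de[[s]] <- runStrategy(s, expr_b, report, sim$metadata,
            config = config)
        writeTable(de[[s]], file.path(outdir,
            sprintf("de_%s.tsv", s)))
    }
    if (length(de) >= 2L) {
        sig <- lapply(de, function(d)
            d$cluster_id[d$adj_p <= config$quality_de_p])
        writeTable(overlapCounts(sig),
            file.path(outdir, "overlap_counts.tsv"))
    }

    stageLog("bias", "quality-affected cluster scan")
    bias <- qualityAffected(prep$expression, report,
        p_threshold = config$quality_de_p,
        fc_threshold = config$quality_de_fc)
    ann_df <- annotation(sim$annotation)
    len <- ann_df$transcript_length_bp[match(bias$cluster_id,
        ann_df$cluster_id)]
    lt <- lengthBiasTest(bias$class, len)
    writeTable(bias, file.path(outdir, "bias_report.tsv"))
    writeTable(lt, file.path(outdir, "length_test.tsv"))
    prof <- positionalProfile(sim$raw, sim$annotation,
        k = config$probes_per_cluster)
    writeProbeMatrix(prof, file.path(outdir,
        "positional_profile.tsv"), id_column = "position")

    stageLog("qpcr", "simulated validation assay")
    cl <- truthClusters(sim$truth)
    ## validation genes: well-expressed differentially expressed
    ## clusters of near-median transcript length (well measured and
    ## least affected by degradation)
    de_cl <- cl[cl$de_flag & cl$mu >= stats::median(cl$mu), ]
    test_genes <- de_cl$cluster_id[order(abs(de_cl$gamma))][1:2]
    qp <- simulateQpcr(sim$truth, sim$metadata, test_genes,
        config = config)
    writeTable(qp, file.path(outdir, "qpcr.tsv"))
    qfc <- qpcrFoldChanges(qp)
    writeTable(qfc, file.path(outdir, "fc_per_patient.tsv"))
    afc <- arrayFoldChanges(prep$expression, sim$metadata, test_genes)
    corr <- do.call(rbind, lapply(test_genes, function(g) {
        q <- qfc[qfc$gene == g, ]
        a <- afc[afc$gene == g, ]
        a <- a[match(q$patient_id, a$patient_id), ]
        cc <- correlateFoldChanges(q$fold_change, a$array_log2fc)
        data.frame(gene = g, slope = cc$slope,
            intercept = cc$intercept,
            adj_r_squared = cc$adj_r_squared, n = cc$n)
    }))
    writeTable(corr, file.path(outdir, "correlation.tsv"))

    invisible(list(sim = sim, frozen = frozen, expression =
        prep$expression, se = prep$se, thresholds = thr,
        report = report, de = de, bias = bias, length_test = lt,
        qpcr_correlation = corr, outdir = outdir))
}
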