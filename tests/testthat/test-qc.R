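toy_matrix <- function(v, ids = paste0("p", seq_along(v)),
        arrays = "a1") {
    ProbeMatrix(matrix(v, length(v), length(arrays),
        dimnames = list(ids, arrays)), "linear")
}

test_that("probe CV matches hand computations and is scale invariant", {
    expect_equal(unname(probeCV(toy_matrix(c(1, 2, 3)))), 0.5)
    expect_equal(unname(probeCV(toy_matrix(c(5, 5, 5)))), 0)
    m <- matrix(rlnorm(60), 30, 2, dimnames = list(paste0("p", 1:30),
        c("a1", "a2")))
    m[, 2] <- m[, 1] * 10
    cvs <- probeCV(ProbeMatrix(m, "linear"))
    expect_equal(cvs[["a1"]], cvs[["a2"]])
    lg <- ProbeMatrix(log2(m), "log2")
    expect_error(probeCV(lg), "linear")
})

test_that("PM-BG difference matches hand computation and is shift invariant", {
    ann <- ProbeAnnotation(data.frame(
        probe_id = c("p1", "p2", "b1"),
        cluster_id = c("c1", "c1", "background"),
        probe_type = c("pm", "pm", "background"),
        position_index = c(1, 2, NA),
        transcript_length_bp = c(100, 100, NA)))
    expect_equal(unname(pmBgDifference(toy_matrix(c(10, 20, 5),
        c("p1", "p2", "b1")), ann)), 10)
    shifted <- toy_matrix(c(10, 20, 5) + 7, c("p1", "p2", "b1"))
    expect_equal(unname(pmBgDifference(shifted, ann)), 10)
    no_bg <- ProbeAnnotation(data.frame(probe_id = c("p1", "p2"),
        cluster_id = "c1", probe_type = "pm", position_index = 1:2,
        transcript_length_bp = 100))
    expect_error(pmBgDifference(toy_matrix(c(10, 20, 5),
        c("p1", "p2", "b1")), no_bg), "background")
})

test_that("thresholds derive from high-RIN arrays only", {
    meta <- SampleMetadata(data.frame(
        array_id = c("a1", "a2", "a3", "a4"),
        patient_id = c("p1", "p2", "p3", "p4"),
        condition = "tumour", batch = "b1",
        rin = c(8, 7.5, 3, 2.5), a260_230 = 2))
    cvs <- c(a1 = 0.1, a2 = 0.2, a3 = 0.9, a4 = 1.5)
    pbs <- c(a1 = 50, a2 = 60, a3 = 5, a4 = 2)
    thr <- deriveThresholds(cvs, pbs, meta)
    expect_equal(thr@cv_max, 0.15 + 2 * sd(c(0.1, 0.2)))
    expect_equal(thr@cv_max, 0.2914214, tolerance = 1e-6)
    expect_equal(thr@pm_bg_min, 55 - 2 * sd(c(50, 60)))
    expect_equal(thr@gnuse_max, 1.25)
    ## zero-SD degenerate case and stratification invariance
    thr0 <- deriveThresholds(c(a1 = 0.1, a2 = 0.1, a3 = 2, a4 = 3),
        pbs, meta)
    expect_equal(thr0@cv_max, 0.1)
    ## adding more low-RIN arrays never moves the thresholds
    meta2 <- SampleMetadata(data.frame(
        array_id = c("a1", "a2", "a3", "a4", "a5"),
        patient_id = c("p1", "p2", "p3", "p4", "p5"),
        condition = "tumour", batch = "b1",
        rin = c(8, 7.5, 3, 2.5, 4), a260_230 = 2))
    thr2 <- deriveThresholds(c(cvs, a5 = 5), c(pbs, a5 = 1), meta2)
    expect_equal(thr2@cv_max, thr@cv_max)
    ## too few qualifying arrays
    meta_low <- SampleMetadata(data.frame(array_id = c("a1", "a2"),
        patient_id = c("p1", "p2"), condition = "tumour",
        batch = "b1", rin = c(8, 3), a260_230 = 2))
    expect_error(deriveThresholds(cvs[1:2], pbs[1:2], meta_low),
        ">=2 arrays")
})

test_that("GNUSE is 1 at the reference medians and scales homogeneously", {
    med <- c(c1 = 0.2, c2 = 0.4, c3 = 0.1)
    frozen <- new("FrozenReference",
        probe_effects = setNames(numeric(6), paste0("p", 1:6)),
        reference_quantiles = sort(rnorm(6)),
        cluster_se_median = med,
        cluster_ids = rep(names(med), each = 2))
    se <- cbind(a1 = med, a2 = 2 * med)
    g <- gnuseMedian(se, frozen)
    expect_equal(g, c(a1 = 1, a2 = 2))
    frozen@cluster_se_median["c2"] <- 0
    expect_error(gnuseMedian(se, frozen), "zero")
})

test_that("two-of-three flagging follows the published row patterns", {
    thr <- new("QCThresholds", cv_max = 1, pm_bg_min = 10,
        gnuse_max = 1.25)
    ## rows mirror printed outcomes: fail{gnuse,cv} -> flagged;
    ## fail{cv} only -> not flagged; pass all -> not flagged
    cv <- c(r63T = 1.5, r13N = 1.5, r4N = 0.5)
    pb <- c(r63T = 20, r13N = 30, r4N = 30)
    gn <- c(r63T = 1.5, r13N = 1.0, r4N = 1.1)
    rep <- flagArrays(cv, pb, gn, thr)
    tab <- qcTable(rep)
    expect_identical(tab$flagged[tab$array_id == "r63T"], TRUE)
    expect_identical(tab$flagged[tab$array_id == "r13N"], FALSE)
    expect_identical(tab$flagged[tab$array_id == "r4N"], FALSE)
    expect_identical(flaggedArrays(rep), "r63T")
    ## ranking by gnuse descending
    expect_identical(tab$quality_rank[order(-tab$gnuse_median)], 1:3)
    ## flag decision invariant to array ordering
    perm <- c(2, 3, 1)
    rep2 <- flagArrays(cv[perm], pb[perm], gn[perm], thr)
    t2 <- qcTable(rep2)
    expect_identical(t2$flagged[match(tab$array_id, t2$array_id)],
        tab$flagged)
})

test_that("published quality table reproduces every printed summary", {
    rep <- qualityAssessmentReport()
    meta <- cohortMetadata()
    s <- qcSummary(rep, meta)
    expect_identical(s$n_flagged, 7L)
    expect_equal(s$flagged_rin_mean, 3.2, tolerance = 0.05 / 3.2)
    expect_equal(s$flagged_rin_sd, 0.42, tolerance = 0.005 / 0.42)
    expect_equal(s$cohort_rin_mean, 6.3, tolerance = 0.05 / 6.3)
    expect_equal(s$cohort_rin_sd, 2.0, tolerance = 0.05 / 2)
    expect_identical(s$n_pass_rin_below_7, 10L)
    expect_identical(s$n_pass_all_rin_below_3, 1L)
    expect_equal(s$prop_flagged_low_rin, 6 / 7)
    ## the one RIN < 3 array passing everything is 4N
    tab <- qcTable(rep)
    info <- sampleInfo(meta)
    pass_all <- tab$array_id[tab$n_fail == 0]
    expect_identical(intersect(pass_all,
        info$array_id[info$rin < 3]), "4N")
})

test_that("empty flag group leaves summaries empty", {
    rep <- qcReportFromStatus(c("a1", "a2", "a3", "a4"),
        cv_pass = rep(TRUE, 4), pm_bg_pass = rep(TRUE, 4),
        gnuse_pass = rep(TRUE, 4))
    meta <- SampleMetadata(data.frame(array_id = paste0("a", 1:4),
        patient_id = paste0("p", 1:4), condition = "tumour",
        batch = "b1", rin = c(8, 7, 6, 5), a260_230 = 2))
    s <- qcSummary(rep, meta)
    expect_identical(s$n_flagged, 0L)
    expect_true(is.na(s$flagged_rin_mean))
    expect_true(is.na(s$flagged_rin_sd))
})

test_that("purity association reproduces the published equal-variance p", {
    p <- purityAssociation(qualityAssessmentReport(), cohortMetadata())
    expect_equal(p$p, 0.14, tolerance = 0.005 / 0.14)
    expect_equal(p$df, 32)
    ## same-mean groups give t = 0, p = 1
    rep <- qcReportFromStatus(paste0("a", 1:6),
        cv_pass = c(F, F, F, T, T, T),
        pm_bg_pass = c(F, F, F, T, T, T),
        gnuse_pass = rep(TRUE, 6))
    meta <- SampleMetadata(data.frame(array_id = paste0("a", 1:6),
        patient_id = paste0("p", 1:6), condition = "tumour",
        batch = "b1", rin = 5, a260_230 = rep(c(1.8, 2.0, 2.2), 2)))
    same <- purityAssociation(rep, meta)
    expect_equal(same$t, 0)
    expect_equal(same$p, 1)
    ## separated groups are detected
    meta2 <- SampleMetadata(data.frame(array_id = paste0("a", 1:6),
        patient_id = paste0("p", 1:6), condition = "tumour",
        batch = "b1", rin = 5,
        a260_230 = c(11.8, 12.0, 12.2, 1.8, 2.0, 2.2)))
    expect_lt(purityAssociation(rep, meta2)$p, 1e-6)
})

test_that("flagged proportion grows with the low-RIN mixture weight", {
    prop_flagged <- function(w, s) {
        cfg <- defaultConfig(n_clusters = 200L,
            probes_per_cluster = 8L, n_background_probes = 80L,
            rng_seed = s, rin_low_weight = w)
        sim <- simulateCohort(config = cfg)
        ref <- simulateReferenceSet(10L, config = cfg)
        fro <- buildFrozenReference(ref, sim$annotation)
        prep <- preprocessFrozen(sim$raw, sim$annotation, fro)
        cv <- probeCV(sim$raw)
        pb <- pmBgDifference(sim$raw, sim$annotation)
        thr <- deriveThresholds(cv, pb, sim$metadata, cfg)
        mean(qcTable(flagArrays(cv, pb, prep$gnuse_median, thr,
            cfg))$flagged)
    }
    for (s in 1:2) {
        props <- vapply(c(0.1, 0.3, 0.55), prop_flagged, numeric(1),
            s = s)
        expect_true(all(diff(props) >= 0))
    }
})
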