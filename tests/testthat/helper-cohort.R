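## Shared simulated cohort, built once per test run. Slightly reduced
## cluster count relative to the package defaults keeps the suite
## fast; tests that exercise the full default conditions build their
## own cohorts.

.cohort_cache <- new.env(parent = emptyenv())

sharedCohort <- function() {
    if (!is.null(.cohort_cache$res)) return(.cohort_cache$res)
    cfg <- defaultConfig(n_clusters = 600L, probes_per_cluster = 25L,
        n_background_probes = 200L, rng_seed = 11L)
    sim <- simulateCohort(config = cfg)
    ref <- simulateReferenceSet(20L, config = cfg)
    frozen <- buildFrozenReference(ref, sim$annotation)
    prep <- preprocessFrozen(sim$raw, sim$annotation, frozen)
    cv <- probeCV(sim$raw)
    pb <- pmBgDifference(sim$raw, sim$annotation)
    thr <- deriveThresholds(cv, pb, sim$metadata, cfg)
    report <- flagArrays(cv, pb, prep$gnuse_median, thr, cfg)
    .cohort_cache$res <- list(cfg = cfg, sim = sim, ref = ref,
        frozen = frozen, prep = prep, cv = cv, pm_bg = pb,
        thresholds = thr, report = report)
    .cohort_cache$res
}

## small cohort for cheap structural tests
smallCohort <- function(seed = 5L, ...) {
    cfg <- defaultConfig(n_clusters = 80L, probes_per_cluster = 4L,
        n_background_probes = 40L, rng_seed = seed, ...)
    c(simulateCohort(config = cfg), list(cfg = cfg))
}

## a clean cohort: no degradation, no batch effects, no patient
## heterogeneity -- i.i.d. Normal probe noise around the signal
cleanConfig <- function(seed = 1L, ...) {
    defaultConfig(rng_seed = seed, rin_low_weight = 0,
        rin_high_mean = 9, rin_high_sd = 0.3, batch_effect_sd = 0,
        patient_fc_sd = 0, ...)
}

expect_matrix_equal <- function(a, b, tol = 1e-8) {
    expect_lt(max(abs(a - b)), tol)
}
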