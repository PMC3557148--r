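#' Default pipeline configuration
#'
#' Returns the flat list of tunable constants used throughout the
#' pipeline. QC constants default to the published rules: a median
#' GNUSE above 1.25 fails the precision metric; the CV and PM-BG
#' thresholds are constructed as mean +/- 2 SD of the arrays whose
#' RIN exceeds 6; an array failing at least two of the three metrics
#' is flagged. Simulation constants define the default synthetic
#' cohort: 17 patient pairs (34 arrays) split 10/24 across two
#' batches, a 75/25 mixture of intact (RIN ~ N(7.5, 0.8^2)) and
#' degraded (RIN ~ N(3.0, 0.5^2)) samples truncated to [2, 10],
#' log-normal transcript lengths with median 2,400 bp, and a signed
#' length-dependent degradation coefficient gamma = -kappa *
#' log2(length / median length).
#'
#' @param ... named overrides of any default.
#' @return named list of configuration values.
#' @examples
#' cfg <- defaultConfig(n_clusters = 200)
#' cfg$gnuse_flag_threshold
#' @export
defaultConfig <- function(...) {
    cfg <- list(
        ## QC rules
        gnuse_flag_threshold = 1.25,
        cv_rin_cutoff = 6,
        cv_sd_multiplier = 2,
        flag_min_failures = 2,
        quality_de_p = 0.05,
        quality_de_fc = 2,
        low_rin_cutoff = 3.3,
        ## reproducibility
        rng_seed = 1L,
        ## cohort layout
        n_patients = 17L,
        n_clusters = 1000L,
        probes_per_cluster = 25L,
        n_background_probes = 400L,
        batch1_pairs = 5L,
        ## RIN mixture
        rin_high_mean = 7.5, rin_high_sd = 0.8,
        rin_low_mean = 3.0, rin_low_sd = 0.5,
        rin_low_weight = 0.25,
        rin_min = 2, rin_max = 10,
        ## expression model
        mu_mean = 6, mu_sd = 1.5,
        probe_effect_sd = 0.7,
        de_fraction = 0.1,
        de_log2fc_min = 0.5, de_log2fc_max = 2,
        patient_fc_sd = 0.6,
        batch_effect_sd = 0.3,
        sigma0 = 0.25,
        noise_inflation = 2,
        pm_attenuation = 1.0,
        ## transcript lengths / degradation bias
        length_meanlog = log(2400), length_sdlog = 1.2,
        short_noncoding_fraction = 0.1,
        short_noncoding_max_bp = 400,
        kappa = 0.4,
        positional_bias_slope = 0,
        ## background probes (linear-scale log-normal, log2 parameters)
        bg_mean_log2 = 3, bg_sd_log2 = 0.5,
        ## qPCR
        qpcr_sigma_ct = 0.2,
        qpcr_replicates = 3L,
        qpcr_ct_offset = 30,
        ## ComBat / SVA numerics
        combat_tol = 1e-4, combat_max_iter = 100L,
        sva_n_permutations = 100L,
        sva_sig_level = 0.10,
        sva_gene_p = 0.05,
        sva_min_genes = 50L,
        ## array weights
        aw_tol = 1e-4, aw_max_iter = 50L)
    override <- list(...)
    if (length(override)) {
        unknown <- setdiff(names(override), names(cfg))
        if (length(unknown))
            stop("unknown configuration key(s): ",
                paste(unknown, collapse = ", "))
        cfg[names(override)] <- override
    }
    validateConfig(cfg)
}

#' Read a configuration file
#'
#' Reads a flat key-value (YAML-syntax) configuration file; keys not
#' present keep their defaults, unknown keys are an error.
#'
#' @param path path to the YAML file.
#' @return named list of configuration values.
#' @export
readConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    if (!is.list(vals)) stop("configuration file must be a key-value map")
    do.call(defaultConfig, vals)
}

validateConfig <- function(cfg) {
    stopifnot(cfg$gnuse_flag_threshold > 0, cfg$cv_sd_multiplier >= 0,
        cfg$flag_min_failures >= 1, cfg$n_patients >= 2,
        cfg$probes_per_cluster >= 2, cfg$rin_min >= 1,
        cfg$rin_max <= 10, cfg$sigma0 >= 0,
        cfg$batch1_pairs >= 1, cfg$batch1_pairs < cfg$n_patients)
    cfg
}

#' Write a configuration file
#'
#' @param cfg configuration list from [defaultConfig()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeConfig <- function(cfg, path) {
    yaml::write_yaml(cfg, path)
    invisible(path)
}
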