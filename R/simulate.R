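# Synthetic family-structured methylation studies with planted region
# effects, for calibration (type-I error) and power experiments.
#
# Generative model: a quantitative phenotype with covariate effects, a
# polygenic family random effect (covariance h2 * 2 phi) and residual noise;
# per-region probe M-values drawn multivariate normal with exchangeable or
# AR(1) correlation, plus effect * phenotype added to causal probes. M-values
# are generated directly and converted to betas, keeping the generative
# correlation on the scale the region statistic uses.

#' Build and validate a simulation configuration
#'
#' Defaults describe the reference calibration regime: 200 unrelated samples,
#' regions of 5 probes with exchangeable correlation rho = 0.6, age/sex/
#' center/smoking covariates, no family variance, no causal regions.
#'
#' @param n_families Number of families (for `"unrelated"`, the number of
#'   singleton samples).
#' @param family_structure `"unrelated"`, `"trio"` (father/mother/child) or
#'   `"sibs"` (`family_size` full siblings, parents unobserved).
#' @param family_size Siblings per family for `"sibs"` (default 3).
#' @param n_regions Number of annotated probe regions.
#' @param probes_per_region Probes in each region.
#' @param correlation_model `"exchangeable"` or `"ar1"`.
#' @param rho Inter-probe correlation parameter, in (-1, 1).
#' @param n_null_singletons Unannotated null probes appended to the array.
#' @param causal_regions List of `list(region = <index>, effect = <per-probe
#'   M change per unit phenotype>)`; empty for a null study.
#' @param h2 Phenotype heritability attributable to the kinship random
#'   effect, in \[0, 1).
#' @param noise_sd Scale of the probe-level M noise (default 1).
#' @param baseline_sd SD of per-probe baseline M levels (default 1.5, i.e.
#'   baseline betas mostly within ~0.1-0.9).
#' @param covariate_effects Named numeric vector of phenotype effects for
#'   `age` (per year, age centered at 50), `sexM`, `centerC2`,
#'   `smoking_former`, `smoking_current`.
#' @param seed Mandatory integer seed.
#' @return A validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_families = 200L,
                              family_structure = c("unrelated", "trio", "sibs"),
                              family_size = 3L,
                              n_regions = 10L,
                              probes_per_region = 5L,
                              correlation_model = c("exchangeable", "ar1"),
                              rho = 0.6,
                              n_null_singletons = 20L,
                              causal_regions = list(),
                              h2 = 0,
                              noise_sd = 1,
                              baseline_sd = 1.5,
                              covariate_effects = c(age = 0.01, sexM = 0.3,
                                                    centerC2 = 0.2,
                                                    smoking_former = 0.1,
                                                    smoking_current = 0.25),
                              seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  family_structure <- match.arg(family_structure)
  correlation_model <- match.arg(correlation_model)
  stopifnot(n_families >= 2, n_regions >= 1, probes_per_region >= 1,
            family_size >= 1, n_null_singletons >= 0,
            rho > -1, rho < 1, h2 >= 0, h2 < 1,
            noise_sd > 0, baseline_sd >= 0)
  for (cr in causal_regions) {
    if (!is.list(cr) || is.null(cr$region) || is.null(cr$effect))
      stop("each causal_regions entry needs $region and $effect")
    if (cr$region < 1 || cr$region > n_regions)
      stop("causal region index out of range")
    if (!is.finite(cr$effect)) stop("causal effect must be finite")
  }
  structure(list(n_families = as.integer(n_families),
                 family_structure = family_structure,
                 family_size = as.integer(family_size),
                 n_regions = as.integer(n_regions),
                 probes_per_region = as.integer(probes_per_region),
                 correlation_model = correlation_model, rho = rho,
                 n_null_singletons = as.integer(n_null_singletons),
                 causal_regions = causal_regions, h2 = h2,
                 noise_sd = noise_sd, baseline_sd = baseline_sd,
                 covariate_effects = covariate_effects,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

family_kinship_block <- function(structure, family_size) {
  switch(structure,
    unrelated = matrix(0.5, 1, 1),
    trio = matrix(c(0.5, 0, 0.25,
                    0, 0.5, 0.25,
                    0.25, 0.25, 0.5), 3, 3, byrow = TRUE),
    sibs = {
      b <- matrix(0.25, family_size, family_size)
      diag(b) <- 0.5
      b
    })
}

region_correlation <- function(model, rho, m) {
  if (m == 1L) return(matrix(1, 1, 1))
  if (model == "exchangeable") {
    s <- matrix(rho, m, m); diag(s) <- 1; s
  } else {
    rho ^ abs(outer(seq_len(m), seq_len(m), "-"))
  }
}

#' Simulate a family-structured methylation study
#'
#' See [simulation_config()] for the generative model. Fully reproducible
#' from the config seed.
#'
#' @param config A `simulation_config`.
#' @return A list of class `"simulated_study"`: `meth` (probe x sample beta
#'   matrix), `samples` (with covariates attribute), `kinship`, `manifest`
#'   (each region annotated as the Body of a synthetic gene), `truth`
#'   (region_id, causal, effect) and `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  set.seed(cfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  fam_size <- switch(cfg$family_structure, unrelated = 1L, trio = 3L,
                     sibs = cfg$family_size)
  n <- cfg$n_families * fam_size
  sample_id <- sprintf("S%05d", seq_len(n))
  family_id <- sprintf("F%04d", rep(seq_len(cfg$n_families), each = fam_size))

  block <- family_kinship_block(cfg$family_structure, cfg$family_size)
  phi <- matrix(0, n, n, dimnames = list(sample_id, sample_id))
  for (f in seq_len(cfg$n_families)) {
    i <- ((f - 1L) * fam_size + 1L):(f * fam_size)
    phi[i, i] <- block
  }

  samples <- data.frame(
    sample_id = sample_id,
    phenotype = NA_real_,
    age = round(stats::runif(n, 30, 70)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    center = sample(c("C1", "C2"), n, replace = TRUE),
    smoking = sample(c("never", "former", "current"), n, replace = TRUE,
                     prob = c(0.5, 0.3, 0.2)),
    family_id = family_id,
    stringsAsFactors = FALSE)

  ce <- cfg$covariate_effects
  fixed <- ce[["age"]] * (samples$age - 50) +
    ce[["sexM"]] * (samples$sex == "M") +
    ce[["centerC2"]] * (samples$center == "C2") +
    ce[["smoking_former"]] * (samples$smoking == "former") +
    ce[["smoking_current"]] * (samples$smoking == "current")
  g <- if (cfg$h2 > 0) {
    # family random effect: block-diagonal chol of h2 * 2 phi
    L <- chol(2 * block)
    as.vector(t(L) %*% matrix(stats::rnorm(n), fam_size, cfg$n_families)) *
      sqrt(cfg$h2)
  } else numeric(n)
  samples$phenotype <- fixed + g + stats::rnorm(n, sd = sqrt(1 - cfg$h2))
  attr(samples, "covariates") <- c("age", "sex", "center", "smoking")

  m <- cfg$probes_per_region
  effects <- numeric(cfg$n_regions)
  for (cr in cfg$causal_regions) effects[cr$region] <- cr$effect

  Lr <- chol(region_correlation(cfg$correlation_model, cfg$rho, m))
  M <- matrix(NA_real_, cfg$n_regions * m + cfg$n_null_singletons, n)
  probe_names <- character(nrow(M))
  man <- vector("list", cfg$n_regions)
  for (r in seq_len(cfg$n_regions)) {
    mu <- stats::rnorm(m, 0, cfg$baseline_sd)
    E <- matrix(stats::rnorm(n * m), n, m) %*% Lr        # n x m, corr rho
    Mr <- t(E) * cfg$noise_sd + mu                        # m x n
    if (effects[r] != 0)
      Mr <- Mr + matrix(effects[r] * samples$phenotype, m, n, byrow = TRUE)
    rows <- ((r - 1L) * m + 1L):(r * m)
    M[rows, ] <- Mr
    probe_names[rows] <- sprintf("cg%02d_%02d", r, seq_len(m))
    man[[r]] <- data.frame(
      probe_id = probe_names[rows], chrom = "chr1",
      pos = as.integer(r * 100000L + 200L * (seq_len(m) - 1L)),
      gene_names = sprintf("GENE%02d", r), gene_groups = "Body",
      island_name = NA_character_, island_relation = "none",
      stringsAsFactors = FALSE)
  }
  if (cfg$n_null_singletons > 0) {
    rows <- (cfg$n_regions * m + 1L):nrow(M)
    mu <- stats::rnorm(cfg$n_null_singletons, 0, cfg$baseline_sd)
    M[rows, ] <- matrix(stats::rnorm(cfg$n_null_singletons * n),
                        ncol = n) * cfg$noise_sd + mu
    probe_names[rows] <- sprintf("cg_null_%03d", seq_len(cfg$n_null_singletons))
    man[[cfg$n_regions + 1L]] <- data.frame(
      probe_id = probe_names[rows], chrom = "chr1",
      pos = as.integer((cfg$n_regions + 1L) * 100000L +
                         200L * (seq_len(cfg$n_null_singletons) - 1L)),
      gene_names = NA_character_, gene_groups = NA_character_,
      island_name = NA_character_, island_relation = "none",
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, man)
  dimnames(M) <- list(probe_names, sample_id)

  truth <- data.frame(region_id = sprintf("GENE%02d:Body", seq_len(cfg$n_regions)),
                      causal = effects != 0, effect = effects,
                      stringsAsFactors = FALSE)

  structure(list(meth = m_to_beta(M), samples = samples, kinship = phi,
                 manifest = manifest, truth = truth, config = cfg),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("simulated study: %d samples (%s), %d regions x %d probes + %d singletons, %d causal\n",
              ncol(x$meth), cfg$family_structure, cfg$n_regions,
              cfg$probes_per_region, cfg$n_null_singletons,
              sum(x$truth$causal)))
  invisible(x)
}

#' Write / read a simulated study directory
#'
#' Persists a study as the plain-text files every pipeline stage consumes
#' (methylation TSV, samples TSV, manifest TSV, kinship CSV, truth TSV and a
#' YAML echo of the configuration).
#'
#' @param study A `simulated_study`.
#' @param dir Directory (created if needed).
#' @return `dir` (write) / a `simulated_study`-shaped list (read).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_methylation(study$meth, file.path(dir, "methylation.tsv"))
  utils::write.table(study$samples, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_kinship(study$kinship, file.path(dir, "kinship.csv"))
  utils::write.table(study$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- unclass(study$config)
  cfg$covariate_effects <- as.list(cfg$covariate_effects)
  cfg$covariates <- attr(study$samples, "covariates")
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  cfg_path <- file.path(dir, "config.yaml")
  cfg <- if (file.exists(cfg_path)) yaml::read_yaml(cfg_path) else list()
  header <- names(utils::read.table(file.path(dir, "samples.tsv"),
                                    header = TRUE, sep = "\t", nrows = 1L,
                                    check.names = FALSE, quote = ""))
  covs <- unlist(cfg$covariates)
  if (is.null(covs))
    covs <- setdiff(header, c("sample_id", "phenotype", "family_id"))
  samples <- read_samples(file.path(dir, "samples.tsv"), covariates = covs,
                          family_col = if ("family_id" %in% header) "family_id")
  kin_path <- file.path(dir, "kinship.csv")
  truth_path <- file.path(dir, "truth.tsv")
  list(meth = read_methylation(file.path(dir, "methylation.tsv")),
       samples = samples,
       kinship = if (file.exists(kin_path)) read_kinship(kin_path),
       manifest = read_manifest(file.path(dir, "manifest.tsv"),
                                col_map = c(probe_id = "probe_id", chrom = "chrom",
                                            pos = "pos", gene_names = "gene_names",
                                            gene_groups = "gene_groups",
                                            island_relation = "island_relation",
                                            island_name = "island_name")),
       truth = if (file.exists(truth_path))
         utils::read.table(truth_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = ""),
       config = cfg)
}

spawn_seeds <- function(master, n) {
  set.seed(master, kind = "Mersenne-Twister")
  sample.int(.Machine$integer.max - 1L, n)
}

# run simulate -> ewas -> region scan for one study; returns the fit plus
# the probe-level EWAS table
run_simulated_pipeline <- function(study, alpha = 0.05, min_probes = 2L,
                                   kinship_cache = NULL) {
  mvals <- beta_to_m(study$meth)
  if (study$config$family_structure == "unrelated") {
    ew <- run_ewas(mvals, study$samples, model = "ols",
                   manifest = study$manifest)
  } else {
    kin <- kinship_cache %||% study$kinship
    ew <- run_ewas(mvals, study$samples, kinship = kin, model = "lmm",
                   manifest = study$manifest)
  }
  rs <- attach_regions(build_gene_regions(study$manifest), NULL,
                       min_probes = min_probes)
  fit <- globalp(ew, rs, study$meth, study$samples, alpha = alpha,
                 min_probes = min_probes)
  list(fit = fit, ewas = ew)
}

binom_ci <- function(k, n) {
  if (n == 0) return(c(NA_real_, NA_real_))
  ci <- stats::binom.test(k, n)$conf.int
  c(ci[1L], ci[2L])
}

#' Null-calibration (type-I error) experiment
#'
#' Simulates `n_reps` studies from a null configuration (no causal regions),
#' runs the full pipeline (simulate, EWAS, region scan) on each, and reports
#' the fraction of region tests — and of per-probe EWAS tests — with
#' p < alpha, with exact binomial Monte-Carlo confidence intervals.
#'
#' @param config Null `simulation_config` (an error if any causal region is
#'   present).
#' @param n_reps Number of replicate studies (>= 2).
#' @param alpha Nominal significance level (default 0.05).
#' @param seed Master seed; replicate seeds are spawned from it
#'   deterministically.
#' @return A list of class `"calibration_report"`: `region_rate`,
#'   `region_ci`, `n_region_tests`, `probe_rate`, `probe_ci`,
#'   `n_probe_tests`, `alpha`, `n_reps`.
#' @export
type_one_error_experiment <- function(config, n_reps, alpha = 0.05, seed) {
  stopifnot(inherits(config, "simulation_config"))
  if (length(config$causal_regions)) stop("config must be null (no causal regions)")
  if (n_reps < 2) stop("n_reps must be at least 2")
  if (missing(seed)) stop("seed is mandatory")
  seeds <- spawn_seeds(seed, n_reps)
  kin_cache <- NULL
  region_hits <- region_tot <- probe_hits <- probe_tot <- 0L
  for (i in seq_len(n_reps)) {
    cfg <- config; cfg$seed <- seeds[i]
    study <- simulate_study(cfg)
    if (is.null(kin_cache) && cfg$family_structure != "unrelated")
      kin_cache <- kinship_eigen(study$kinship)
    out <- run_simulated_pipeline(study, alpha = alpha,
                                  kinship_cache = kin_cache)
    p <- out$fit$results$p_value
    region_hits <- region_hits + sum(p < alpha)
    region_tot <- region_tot + length(p)
    pe <- out$ewas$p_value[out$ewas$converged]
    probe_hits <- probe_hits + sum(pe < alpha)
    probe_tot <- probe_tot + length(pe)
  }
  structure(list(region_rate = region_hits / region_tot,
                 region_ci = binom_ci(region_hits, region_tot),
                 n_region_tests = region_tot,
                 probe_rate = probe_hits / probe_tot,
                 probe_ci = binom_ci(probe_hits, probe_tot),
                 n_probe_tests = probe_tot,
                 alpha = alpha, n_reps = n_reps),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("null calibration over %d replicates at alpha = %.3g\n",
              x$n_reps, x$alpha))
  cat(sprintf("  region-level type-I: %.4f (95%% CI %.4f-%.4f, %d tests)\n",
              x$region_rate, x$region_ci[1], x$region_ci[2], x$n_region_tests))
  cat(sprintf("  probe-level type-I:  %.4f (95%% CI %.4f-%.4f, %d tests)\n",
              x$probe_rate, x$probe_ci[1], x$probe_ci[2], x$n_probe_tests))
  invisible(x)
}

#' Power experiment over an effect-size grid
#'
#' For each effect size, plants that per-probe effect in the configured
#' causal region(s) (defaulting to region 1) and reports the fraction of
#' replicates in which every causal region attains FDR q < alpha. Effect 0
#' reduces to a (q-based) type-I measurement.
#'
#' @param config Base `simulation_config`.
#' @param effect_sizes Numeric grid of per-probe M effects per unit phenotype.
#' @param n_reps Replicates per grid point (default 500).
#' @param alpha FDR threshold for declaring detection (default 0.05).
#' @param seed Master seed.
#' @return A data.frame of class `"power_report"`: `effect`, `power`,
#'   `ci_lo`, `ci_hi`, `n_reps`.
#' @export
power_experiment <- function(config, effect_sizes, n_reps = 500L,
                             alpha = 0.05, seed) {
  stopifnot(inherits(config, "simulation_config"))
  if (missing(seed)) stop("seed is mandatory")
  regions <- if (length(config$causal_regions))
    vapply(config$causal_regions, function(cr) cr$region, numeric(1)) else 1
  out <- vector("list", length(effect_sizes))
  kin_cache <- NULL
  for (k in seq_along(effect_sizes)) {
    eff <- effect_sizes[k]
    cfg <- config
    cfg$causal_regions <- if (eff != 0)
      lapply(regions, function(r) list(region = r, effect = eff)) else list()
    seeds <- spawn_seeds(seed + k, n_reps)
    hits <- 0L
    for (i in seq_len(n_reps)) {
      cfg$seed <- seeds[i]
      study <- simulate_study(cfg)
      if (is.null(kin_cache) && cfg$family_structure != "unrelated")
        kin_cache <- kinship_eigen(study$kinship)
      fit <- run_simulated_pipeline(study, alpha = alpha,
                                    kinship_cache = kin_cache)$fit
      res <- fit$results
      target <- study$truth$region_id[regions]
      q <- res$q_value[match(target, res$region_id)]
      if (all(!is.na(q)) && all(q < alpha)) hits <- hits + 1L
    }
    ci <- binom_ci(hits, n_reps)
    out[[k]] <- data.frame(effect = eff, power = hits / n_reps,
                           ci_lo = ci[1L], ci_hi = ci[2L], n_reps = n_reps)
  }
  res <- do.call(rbind, out)
  class(res) <- c("power_report", "data.frame")
  res
}
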