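# End-to-end pipeline over a study directory; the thin command-line interface
# at inst/cli/globalp-cli.R dispatches to these functions.

#' Run the full DMR pipeline on a study directory
#'
#' Reads a study directory (the layout written by [write_study()], or any
#' directory holding `methylation.tsv`, `samples.tsv`, `manifest.tsv` and
#' optionally `kinship.csv`), aligns samples, applies exclusion lists, runs
#' the per-probe EWAS and the region scan, and writes `ewas.tsv`,
#' `results.tsv`, `results.bed` and a small run log (seed, package version,
#' input checksums) to `out_dir`. The computation is deterministic given the
#' inputs, so repeated runs produce byte-identical outputs.
#'
#' @param study_dir Input study directory.
#' @param out_dir Output directory (created if needed).
#' @param model `"auto"` (LMM when a kinship file is present, else OLS),
#'   `"lmm"` or `"ols"`.
#' @param alpha FDR threshold (default 0.05).
#' @param min_probes Minimum probes per region (default 2).
#' @param eig_tol Eigenvalue truncation threshold for Sigma.
#' @param exclusion_lists Optional character vector of exclusion-list paths.
#' @param seed Integer recorded in the run log (the pipeline itself is
#'   deterministic; the seed matters only when the study is simulated).
#' @return The fitted [globalp()] object, invisibly.
#' @export
run_pipeline <- function(study_dir, out_dir, model = c("auto", "lmm", "ols"),
                         alpha = 0.05, min_probes = 2L, eig_tol = 1e-8,
                         exclusion_lists = character(), seed = NULL) {
  model <- match.arg(model)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(meth = file.path(study_dir, "methylation.tsv"),
             samples = file.path(study_dir, "samples.tsv"),
             manifest = file.path(study_dir, "manifest.tsv"),
             kinship = file.path(study_dir, "kinship.csv"))
  study <- read_study(study_dir)
  kin <- if (file.exists(paths[["kinship"]])) study$kinship else NULL
  if (model == "auto") model <- if (is.null(kin)) "ols" else "lmm"
  if (model == "ols") kin <- NULL

  excl <- lapply(exclusion_lists, read_exclusion_list)
  filt <- filter_probes(study$manifest, excl)
  meth <- study$meth[rownames(study$meth) %in% filt$retained, , drop = FALSE]

  al <- align_samples(meth, study$samples, kin)
  mvals <- beta_to_m(al$meth)
  ew <- run_ewas(mvals, al$samples, kinship = al$kinship,
                 model = if (is.null(al$kinship)) "ols" else "lmm",
                 manifest = study$manifest)
  rs <- attach_regions(build_gene_regions(study$manifest, filt$retained),
                       build_island_regions(study$manifest, filt$retained),
                       min_probes = min_probes)
  fit <- globalp(ew, rs, al$meth, al$samples, alpha = alpha,
                 min_probes = min_probes, eig_tol = eig_tol)

  write_ewas(ew, file.path(out_dir, "ewas.tsv"))
  write_results(fit$results, file.path(out_dir, "results.tsv"),
                bed = file.path(out_dir, "results.bed"))
  log <- c(sprintf("package_version: %s",
                   as.character(utils::packageVersion("globalp"))),
           sprintf("seed: %s", if (is.null(seed)) "NA" else seed),
           sprintf("model: %s", model),
           sprintf("alpha: %g", alpha),
           sprintf("min_probes: %d", as.integer(min_probes)),
           sprintf("probes_retained: %d", length(filt$retained)),
           vapply(names(paths), function(k) {
             p <- paths[[k]]
             sprintf("md5_%s: %s", k,
                     if (file.exists(p)) unname(tools::md5sum(p)) else "absent")
           }, character(1)))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(fit)
}
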