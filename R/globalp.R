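# Core region statistic. Under the null the vector of per-probe z-scores in a
# region of m probes is multivariate normal with mean 0 and covariance Sigma,
# the (partial) correlation matrix between the probes' methylation values in
# the study sample; hence z' Sigma^{-1} z is chi-square with m degrees of
# freedom. Ill-conditioned Sigma is handled by eigenvalue truncation with the
# retained rank as degrees of freedom.

#' Inter-probe partial correlation for one region
#'
#' Residualizes each probe's M-values on an intercept plus the covariates by
#' least squares and returns the Pearson correlation matrix of the residual
#' vectors — the partial correlation between probes given the covariates.
#' With no covariates, residualization only centers, so the result is the
#' plain correlation of the M-values. Samples with a missing value at any
#' region probe (or covariate) are dropped (complete-case per region).
#'
#' Eigenvalues below `tol * lambda_max` are clipped to zero and the retained
#' count recorded as the numerical rank; the downstream statistic inverts
#' Sigma on the retained eigenspace only.
#'
#' @param m_values Probe x sample matrix of M-values for the region's probes.
#' @param samples Aligned sample data.frame (for the covariates).
#' @param covariates Covariate names; defaults to the table's attribute. Use
#'   `character()` for the no-covariate (plain correlation) case.
#' @param tol Relative eigenvalue truncation threshold (default 1e-8).
#' @return An object of class `"partial_corr"`: `probe_ids`, `sigma`
#'   (symmetric, unit diagonal), `n_eff` (samples used), `rank`, and the
#'   truncated eigendecomposition (`values`, `vectors`).
#' @export
partial_correlation <- function(m_values, samples,
                                covariates = attr(samples, "covariates"),
                                tol = 1e-8) {
  stopifnot(is.matrix(m_values))
  m <- nrow(m_values)
  covm <- covariate_matrix(samples, covariates)
  X <- cbind(1, covm)
  keep <- stats::complete.cases(cbind(t(m_values), X))
  n <- sum(keep)
  if (n < m + ncol(covm) + 2L)
    warning(sprintf("only %d complete samples for %d probes + %d covariate column(s); Sigma estimate may be rank-deficient",
                    n, m, ncol(covm)))
  if (n < 3L) stop("fewer than 3 complete samples in region")
  Y <- t(m_values[, keep, drop = FALSE])       # n x m
  Xk <- X[keep, , drop = FALSE]
  res <- qr.resid(qr(Xk), Y)
  sds <- sqrt(colSums(res^2))
  zero <- sds <= 1e-12 * sqrt(n)
  if (any(zero))
    stop("zero residual variance for probe(s): ",
         paste(rownames(m_values)[zero], collapse = ", "))
  sigma <- crossprod(res / rep(sds, each = n))
  sigma <- (sigma + t(sigma)) / 2
  diag(sigma) <- 1
  e <- eigen(sigma, symmetric = TRUE)
  keep_ev <- e$values > tol * max(e$values)
  structure(list(probe_ids = rownames(m_values), sigma = sigma,
                 n_eff = n, rank = sum(keep_ev),
                 values = ifelse(keep_ev, e$values, 0),
                 vectors = e$vectors, tol = tol),
            class = "partial_corr")
}

#' @export
print.partial_corr <- function(x, ...) {
  cat(sprintf("partial correlation: %d probes, n_eff = %d, rank = %d\n",
              length(x$probe_ids), x$n_eff, x$rank))
  invisible(x)
}

as_partial_corr <- function(sigma, tol = 1e-8) {
  if (inherits(sigma, "partial_corr")) return(sigma)
  stopifnot(is.matrix(sigma), nrow(sigma) == ncol(sigma))
  sigma <- (sigma + t(sigma)) / 2
  e <- eigen(sigma, symmetric = TRUE)
  keep_ev <- e$values > tol * max(e$values)
  structure(list(probe_ids = rownames(sigma) %||% paste0("p", seq_len(nrow(sigma))),
                 sigma = sigma, n_eff = NA_integer_, rank = sum(keep_ev),
                 values = ifelse(keep_ev, e$values, 0),
                 vectors = e$vectors, tol = tol),
            class = "partial_corr")
}

#' Quadratic-form chi-square region statistic
#'
#' Computes `statistic = z' Sigma^+ z`, where `Sigma^+` is the pseudo-inverse
#' defined by the truncated eigendecomposition of the inter-probe correlation
#' matrix, with degrees of freedom equal to the retained rank and an
#' upper-tail chi-square p-value. With full-rank Sigma this is exactly
#' `z' Sigma^{-1} z` on m degrees of freedom; for m = 1 it reduces to the
#' squared z-score, i.e. the probe's own two-sided normal test.
#'
#' @param z Numeric z-score vector of length m (finite).
#' @param sigma A `partial_corr` object or a plain correlation matrix of
#'   matching dimension.
#' @param tol Eigenvalue truncation threshold when `sigma` is a plain matrix.
#' @return A list: `statistic`, `df`, `p_value`.
#' @export
region_chi2 <- function(z, sigma, tol = 1e-8) {
  pc <- as_partial_corr(sigma, tol)
  m <- length(z)
  if (m != nrow(pc$sigma)) stop("z length does not match Sigma dimension")
  if (any(!is.finite(z))) stop("non-finite z-scores")
  pos <- pc$values > 0
  if (!any(pos)) stop("Sigma has rank 0 after truncation")
  u <- crossprod(pc$vectors[, pos, drop = FALSE], z)
  statistic <- sum(u^2 / pc$values[pos])
  df <- sum(pos)
  list(statistic = statistic, df = df,
       p_value = stats::pchisq(statistic, df = df, lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Step-up FDR adjustment: with K p-values sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) * K / j`, capped at 1 and mapped back to the
#' input order (ties stable). Used across all tested regions because
#' overlapping annotations make a Bonferroni correction too conservative.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed, returned NA).
#' @return q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) stop("p-values outside [0,1]")
  K <- length(pv)
  if (K == 0L) return(out)
  o <- order(pv, method = "radix")            # stable ties
  q <- (pv[o] * K) / seq_len(K)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  tmp <- numeric(K)
  tmp[o] <- q
  out[ok] <- tmp
  out
}

#' Fit the annotation-based DMR model
#'
#' The central fitting function: for every annotation region it assembles the
#' per-probe EWAS z-scores in genomic position order, estimates the
#' inter-probe partial correlation Sigma from covariate-residualized
#' M-values, forms the quadratic-form chi-square statistic
#' `z' Sigma^+ z` with df = rank(Sigma), and controls FDR across all tested
#' regions by Benjamini-Hochberg.
#'
#' Probes without a usable EWAS record (unconverged or missing) are dropped
#' from their regions; regions falling below `min_probes` after drops are
#' skipped and audited. The full result table is returned regardless of
#' significance.
#'
#' @param ewas EWAS record table from [run_ewas()] (or [read_ewas()]).
#' @param regions A `region_set` (see [attach_regions()]).
#' @param meth Probe x sample methylation matrix covering the region probes,
#'   aligned with `samples`.
#' @param samples Aligned sample data.frame.
#' @param covariates Covariate names used for partial correlation; defaults
#'   to the table's `"covariates"` attribute.
#' @param assay `"beta"` (default; converted with [beta_to_m()]) or
#'   `"mvalue"`.
#' @param alpha FDR threshold marking rows significant (default 0.05).
#' @param min_probes Minimum analyzable probes per region (default 2).
#' @param eig_tol Eigenvalue truncation threshold for Sigma (default 1e-8).
#' @return An object of class `"globalp"`: `results` (one row per tested
#'   region: `region_id`, `category`, `chrom`, `start`, `stop`, `n_probes`,
#'   `statistic`, `df`, `p_value`, `q_value`, `significant`), `alpha`,
#'   `audit`, `call`.
#' @examples
#' study <- simulate_study(simulation_config(
#'   n_families = 60, n_regions = 6, probes_per_region = 4,
#'   causal_regions = list(list(region = 1, effect = 0.6)), seed = 7))
#' ew <- run_ewas(beta_to_m(study$meth), study$samples, model = "ols",
#'                manifest = study$manifest)
#' rs <- attach_regions(build_gene_regions(study$manifest), NULL)
#' fit <- globalp(ew, rs, study$meth, study$samples)
#' summary(fit)
#' @export
globalp <- function(ewas, regions, meth, samples,
                    covariates = attr(samples, "covariates"),
                    assay = c("beta", "mvalue"),
                    alpha = 0.05, min_probes = 2L, eig_tol = 1e-8) {
  assay <- match.arg(assay)
  stopifnot(inherits(regions, "region_set"))
  if (!identical(colnames(meth), samples$sample_id))
    stop("meth columns and sample table are not aligned; run align_samples() first")
  mvals <- if (assay == "beta") beta_to_m(meth) else meth

  usable <- ewas$converged & is.finite(ewas$z)
  zmap <- stats::setNames(ewas$z, ewas$probe_id)
  usable_ids <- ewas$probe_id[usable]

  meta <- regions$meta
  skipped <- character()
  rows <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    pid <- regions$probes[[i]]
    pid <- pid[pid %in% usable_ids & pid %in% rownames(mvals)]
    if (length(pid) < min_probes) {
      skipped <- c(skipped, meta$region_id[i])
      next
    }
    z <- unname(zmap[pid])
    stat <- tryCatch({
      pc <- partial_correlation(mvals[pid, , drop = FALSE], samples,
                                covariates = covariates, tol = eig_tol)
      region_chi2(z, pc)
    }, error = function(e) NULL)
    if (is.null(stat)) { skipped <- c(skipped, meta$region_id[i]); next }
    rows[[i]] <- data.frame(
      region_id = meta$region_id[i], category = meta$category[i],
      chrom = meta$chrom[i], start = meta$start[i], stop = meta$stop[i],
      n_probes = length(pid), statistic = stat$statistic, df = stat$df,
      p_value = stat$p_value, stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(results)) {
    results <- data.frame(region_id = character(), category = character(),
                          chrom = character(), start = integer(),
                          stop = integer(), n_probes = integer(),
                          statistic = numeric(), df = numeric(),
                          p_value = numeric(), stringsAsFactors = FALSE)
  }
  results$q_value <- bh_fdr(results$p_value)
  results$significant <- !is.na(results$q_value) & results$q_value < alpha
  rownames(results) <- NULL
  structure(list(results = results, alpha = alpha,
                 audit = list(n_regions_in = nrow(meta),
                              n_tested = nrow(results),
                              skipped = skipped,
                              min_probes = min_probes, eig_tol = eig_tol),
                 call = match.call()),
            class = "globalp")
}

#' @export
print.globalp <- function(x, ...) {
  cat("Annotation-based DMR scan (quadratic-form chi-square on EWAS z-scores)\n")
  cat(sprintf("  regions tested: %d (of %d; %d skipped)\n",
              x$audit$n_tested, x$audit$n_regions_in, length(x$audit$skipped)))
  cat(sprintf("  significant at FDR < %.3g: %d\n", x$alpha,
              sum(x$results$significant)))
  invisible(x)
}

#' @export
summary.globalp <- function(object, n = 10L, ...) {
  res <- object$results
  res <- res[order(res$p_value), , drop = FALSE]
  out <- list(top = utils::head(res, n),
              n_tested = object$audit$n_tested,
              n_significant = sum(res$significant),
              alpha = object$alpha)
  class(out) <- "summary.globalp"
  out
}

#' @export
print.summary.globalp <- function(x, ...) {
  cat(sprintf("%d regions tested; %d significant at FDR < %.3g\n",
              x$n_tested, x$n_significant, x$alpha))
  if (nrow(x$top)) {
    cat("Top regions:\n")
    print(format(x$top, digits = 4), row.names = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.globalp <- function(x, ...) x$results

#' @export
coef.globalp <- function(object, ...) {
  stats::setNames(object$results$statistic, object$results$region_id)
}

#' Plot region significance along the genome
#'
#' Simple per-chromosome scatter of -log10 region p-values at the region
#' midpoint, with the FDR-significant regions highlighted.
#'
#' @param x A `globalp` fit.
#' @param ... Passed to [plot()].
#' @export
plot.globalp <- function(x, ...) {
  res <- x$results
  if (!nrow(res)) { plot.new(); return(invisible(x)) }
  chroms <- unique(res$chrom)
  offs <- stats::setNames(cumsum(c(0, vapply(chroms, function(ch)
    max(res$stop[res$chrom == ch]) + 1e5, numeric(1))))[seq_along(chroms)], chroms)
  xpos <- offs[res$chrom] + (res$start + res$stop) / 2
  y <- -log10(pmax(res$p_value, 1e-300))
  plot(xpos, y, pch = 16, col = ifelse(res$significant, "firebrick", "grey40"),
       xlab = "genomic position (concatenated chromosomes)",
       ylab = expression(-log[10]~p), ...)
  graphics::abline(h = -log10(x$alpha), lty = 2, col = "grey60")
  invisible(x)
}
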