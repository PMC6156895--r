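# Per-probe EWAS: regression of methylation M-values on the phenotype plus
# covariates, either by OLS (unrelated designs) or by a linear mixed model
# with a single kinship random effect fitted by profiled REML.

build_design <- function(samples, covariates = attr(samples, "covariates")) {
  covm <- covariate_matrix(samples, covariates)
  X <- cbind("(Intercept)" = 1, phenotype = samples$phenotype, covm)
  X
}

new_ewas_record <- function(probe_id, beta_hat = NA_real_, se = NA_real_,
                            n_used = NA_integer_, converged = FALSE,
                            boundary = FALSE, note = "") {
  z <- if (is.finite(se) && se > 0) beta_hat / se else NA_real_
  data.frame(probe_id = probe_id, beta_hat = beta_hat, se = se, z = z,
             p_value = if (is.finite(z)) 2 * stats::pnorm(-abs(z)) else NA_real_,
             n_used = n_used, converged = converged, boundary = boundary,
             note = note, stringsAsFactors = FALSE)
}

#' Ordinary least squares fit for one probe
#'
#' Fits `M ~ intercept + phenotype + covariates` by OLS with classical
#' standard errors; the association p-value uses the normal (Wald) reference,
#' matching the z-score contract consumed by the region test.
#'
#' @param m Numeric vector of per-sample M-values (aligned with `samples`).
#' @param samples Sample data.frame with `phenotype` and covariate columns.
#' @param covariates Covariate names; defaults to the table's attribute.
#' @return A one-row data.frame: `probe_id`, `beta_hat`, `se`, `z`, `p_value`,
#'   `n_used`, `converged`, `boundary`, `note`.
#' @export
fit_probe_ols <- function(m, samples, covariates = attr(samples, "covariates")) {
  X <- build_design(samples, covariates)
  keep <- stats::complete.cases(cbind(m, X))
  y <- m[keep]; X <- X[keep, , drop = FALSE]
  n <- length(y); k <- ncol(X)
  if (n <= k) stop("too few complete cases for the OLS design")
  if (stats::var(y) == 0) stop("zero-variance M vector")
  qx <- qr(X)
  if (qx$rank < k) {
    drop_cols <- colnames(X)[qx$pivot[(qx$rank + 1L):k]]
    stop("rank-deficient design; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  b <- qr.coef(qx, y)
  r <- qr.resid(qx, y)
  rss <- sum(r^2)
  if (rss <= 1e-12 * sum(y^2)) stop("perfect fit: residual variance is zero")
  sigma2 <- rss / (n - k)
  xtx_inv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  se <- sqrt(sigma2 * diag(xtx_inv))
  new_ewas_record("probe", beta_hat = unname(b["phenotype"]),
                  se = unname(se[which(colnames(X) == "phenotype")]),
                  n_used = n, converged = TRUE)
}

# -2 * profiled REML criterion for the variance ratio delta = sg2/se2,
# in the rotated basis where Var(y) = se2 * diag(delta * d + 1).
reml_criterion <- function(log_delta, ytil, Xtil, d, n, k) {
  delta <- exp(log_delta)
  v <- delta * d + 1
  w <- 1 / v
  Xw <- Xtil * w
  XtWX <- crossprod(Xtil, Xw)
  XtWy <- crossprod(Xw, ytil)
  R <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(R)) return(Inf)
  b <- backsolve(R, forwardsolve(t(R), XtWy))
  r <- ytil - Xtil %*% b
  rss <- sum(w * r^2)
  if (!is.finite(rss) || rss <= 0) return(Inf)
  (n - k) * log(rss) + sum(log(v)) + 2 * sum(log(diag(R)))
}

lmm_reml_fit <- function(y, X, eig_values, log_delta_bounds = c(-10, 10)) {
  n <- length(y); k <- ncol(X)
  ytil <- y                          # y, X already rotated by caller
  Xtil <- X
  d <- eig_values
  obj <- function(ld) reml_criterion(ld, ytil, Xtil, d, n, k)
  opt <- stats::optimize(obj, interval = log_delta_bounds, tol = 1e-8)
  ld <- opt$minimum
  boundary <- min(abs(ld - log_delta_bounds)) < 1e-3
  delta <- exp(ld)
  v <- delta * d + 1
  w <- 1 / v
  XtWX <- crossprod(Xtil, Xtil * w)
  XtWy <- crossprod(Xtil * w, ytil)
  XtWX_inv <- chol2inv(chol(XtWX))
  b <- drop(XtWX_inv %*% XtWy)
  names(b) <- colnames(X)
  r <- ytil - Xtil %*% b
  rss <- sum(w * r^2)
  sigma2e <- rss / (n - k)
  se <- sqrt(sigma2e * diag(XtWX_inv))
  names(se) <- colnames(X)
  list(coefficients = b, se = se, delta = delta, log_delta = ld,
       sigma2e = sigma2e, sigma2g = delta * sigma2e,
       objective = opt$objective, boundary = boundary, n = n, k = k)
}

resolve_kinship_eigen <- function(kinship, sample_ids) {
  if (inherits(kinship, "kinship_eigen")) {
    if (!identical(kinship$sample_ids, sample_ids))
      stop("kinship eigendecomposition sample ids do not match the data")
    return(kinship)
  }
  if (!all(sample_ids %in% rownames(kinship)))
    stop("kinship matrix does not cover all samples")
  kinship_eigen(kinship[sample_ids, sample_ids, drop = FALSE])
}

#' Linear mixed model fit for one probe with a kinship random effect
#'
#' Fits `M ~ intercept + phenotype + covariates` with random-effect covariance
#' `sg2 * (2 phi) + se2 * I` by restricted maximum likelihood. The additive
#' relationship matrix 2 phi is eigendecomposed once; REML then reduces to a
#' bounded 1-D search over the variance ratio delta = sg2/se2 on
#' log(delta) in \[-10, 10\], with the error variance and fixed effects
#' profiled out by generalized least squares in the rotated basis. Inference
#' on the phenotype coefficient uses the normal (Wald) reference.
#'
#' @param m Numeric per-sample M-value vector (aligned with `samples`).
#' @param samples Sample data.frame with `sample_id`, `phenotype`, covariates.
#' @param kinship Kinship matrix phi with id dimnames, or a precomputed
#'   [kinship_eigen()] object over exactly the analysis samples.
#' @param covariates Covariate names; defaults to the table's attribute.
#' @return A one-row record as in [fit_probe_ols()], with attributes
#'   `delta`, `sigma2g`, `sigma2e` carrying the variance components.
#' @export
fit_probe_lmm <- function(m, samples, kinship,
                          covariates = attr(samples, "covariates")) {
  X <- build_design(samples, covariates)
  keep <- stats::complete.cases(cbind(m, X))
  ids <- samples$sample_id
  if (!all(keep)) {
    if (inherits(kinship, "kinship_eigen"))
      stop("precomputed kinship_eigen cannot be subset; pass the phi matrix when data have missing values")
    m <- m[keep]; X <- X[keep, , drop = FALSE]; ids <- ids[keep]
    samples <- samples[keep, , drop = FALSE]
  } else {
    m <- m[keep]; X <- X[keep, , drop = FALSE]
  }
  n <- length(m); k <- ncol(X)
  if (n < k + 2L) stop("too few complete cases for the mixed-model design")
  if (stats::var(m) == 0) stop("zero-variance M vector")
  ke <- resolve_kinship_eigen(kinship, ids)
  U <- ke$vectors
  ytil <- drop(crossprod(U, m))
  Xtil <- crossprod(U, X)
  fit <- tryCatch(lmm_reml_fit(ytil, Xtil, ke$values),
                  error = function(e) NULL)
  if (is.null(fit)) {
    return(new_ewas_record("probe", n_used = n, converged = FALSE,
                           note = "REML fit failed"))
  }
  rec <- new_ewas_record("probe",
                         beta_hat = unname(fit$coefficients["phenotype"]),
                         se = unname(fit$se["phenotype"]),
                         n_used = n, converged = TRUE,
                         boundary = fit$boundary)
  attr(rec, "delta") <- fit$delta
  attr(rec, "sigma2g") <- fit$sigma2g
  attr(rec, "sigma2e") <- fit$sigma2e
  rec
}

#' Run the per-probe EWAS over a methylation matrix
#'
#' Produces one association record per probe (effect, SE, z = effect/SE,
#' two-sided normal p). Complete cases are selected per probe; per-probe
#' failures (zero variance, too few samples) are returned as flagged records
#' rather than aborting the run. Output is deterministic given the inputs.
#'
#' With `model = "lmm"` and no missing data, the kinship eigendecomposition is
#' computed once and the rotation applied to all probes in a single matrix
#' product.
#'
#' @param meth Probe x sample matrix of M-values (use [beta_to_m()] upstream;
#'   set `assay = "beta"` to convert in place).
#' @param samples Aligned sample data.frame.
#' @param kinship Kinship matrix or [kinship_eigen()] object (`model = "lmm"`
#'   only; ignored with a warning under OLS).
#' @param model `"lmm"` (kinship random effect) or `"ols"`.
#' @param covariates Covariate names; defaults to the table's attribute.
#' @param assay `"mvalue"` (default) or `"beta"`.
#' @param manifest Optional manifest to annotate records with `chrom`, `pos`.
#' @return A data.frame with one row per probe: `probe_id`, `chrom`, `pos`,
#'   `beta_hat`, `se`, `z`, `p_value`, `n_used`, `converged`, `boundary`,
#'   `note`.
#' @export
run_ewas <- function(meth, samples, kinship = NULL,
                     model = c("lmm", "ols"),
                     covariates = attr(samples, "covariates"),
                     assay = c("mvalue", "beta"), manifest = NULL) {
  model <- match.arg(model)
  assay <- match.arg(assay)
  stopifnot(is.matrix(meth))
  if (!identical(colnames(meth), samples$sample_id))
    stop("meth columns and sample table are not aligned; run align_samples() first")
  if (assay == "beta") meth <- beta_to_m(meth)
  if (model == "ols" && !is.null(kinship)) {
    warning("kinship supplied with model = 'ols'; ignored")
    kinship <- NULL
  }
  if (model == "lmm") {
    if (is.null(kinship)) stop("model = 'lmm' requires a kinship matrix")
    ke <- resolve_kinship_eigen(kinship, samples$sample_id)
  }

  X <- build_design(samples, covariates)
  design_complete <- stats::complete.cases(X)
  probes <- rownames(meth)
  p <- length(probes)

  fit_one <- function(m) {
    tryCatch({
      if (model == "ols") return(fit_probe_ols(m, samples, covariates))
      complete <- !is.na(m) & design_complete
      if (all(complete)) fit_probe_lmm(m, samples, ke, covariates)
      else fit_probe_lmm(m, samples, kinship, covariates)
    }, error = function(e) {
      new_ewas_record("probe", n_used = sum(!is.na(m) & design_complete),
                      converged = FALSE, note = conditionMessage(e))
    })
  }

  no_missing <- !anyNA(meth) && all(design_complete)
  if (no_missing && model == "ols") {
    recs <- ols_all_probes(meth, X)
  } else if (no_missing && model == "lmm") {
    Xtil <- crossprod(ke$vectors, X)
    Ytil <- crossprod(ke$vectors, t(meth))   # n x p rotated outcomes
    recs <- do.call(rbind, lapply(seq_len(p), function(j) {
      m <- meth[j, ]
      if (stats::var(m) == 0)
        return(new_ewas_record("probe", n_used = ncol(meth), converged = FALSE,
                               note = "zero-variance M vector"))
      fit <- tryCatch(lmm_reml_fit(Ytil[, j], Xtil, ke$values),
                      error = function(e) NULL)
      if (is.null(fit))
        return(new_ewas_record("probe", n_used = ncol(meth), converged = FALSE,
                               note = "REML fit failed"))
      new_ewas_record("probe", beta_hat = unname(fit$coefficients["phenotype"]),
                      se = unname(fit$se["phenotype"]), n_used = ncol(meth),
                      converged = TRUE, boundary = fit$boundary)
    }))
  } else {
    recs <- do.call(rbind, lapply(seq_len(p), function(j) fit_one(meth[j, ])))
  }
  recs$probe_id <- probes
  recs <- annotate_records(recs, manifest)
  rownames(recs) <- NULL
  recs
}

# vectorized OLS across probes sharing one complete design
ols_all_probes <- function(meth, X) {
  n <- ncol(meth); k <- ncol(X)
  qx <- qr(X)
  if (qx$rank < k) stop("rank-deficient design; collinear column(s): ",
                        paste(colnames(X)[qx$pivot[(qx$rank + 1L):k]], collapse = ", "))
  Y <- t(meth)
  B <- qr.coef(qx, Y)                       # k x p
  Rm <- qr.resid(qx, Y)                     # n x p
  rss <- colSums(Rm^2)
  sigma2 <- rss / (n - k)
  xtx_inv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  jph <- which(colnames(X) == "phenotype")
  se <- sqrt(sigma2 * xtx_inv[jph, jph])
  beta_hat <- B[jph, ]
  zerovar <- apply(meth, 1L, stats::var) == 0
  perfect <- rss <= 1e-12 * colSums(Y^2)
  z <- ifelse(se > 0, beta_hat / se, NA_real_)
  out <- data.frame(probe_id = rownames(meth), beta_hat = beta_hat, se = se,
                    z = z, p_value = 2 * stats::pnorm(-abs(z)),
                    n_used = n, converged = TRUE, boundary = FALSE,
                    note = "", stringsAsFactors = FALSE)
  bad <- zerovar | perfect | !is.finite(se)
  if (any(bad)) {
    out$beta_hat[bad] <- NA_real_; out$se[bad] <- NA_real_
    out$z[bad] <- NA_real_; out$p_value[bad] <- NA_real_
    out$converged[bad] <- FALSE
    out$note[bad] <- ifelse(zerovar[bad], "zero-variance M vector",
                            "perfect fit: residual variance is zero")
  }
  out
}

annotate_records <- function(recs, manifest) {
  if (is.null(manifest)) {
    recs$chrom <- NA_character_; recs$pos <- NA_integer_
  } else {
    i <- match(recs$probe_id, manifest$probe_id)
    recs$chrom <- manifest$chrom[i]
    recs$pos <- manifest$pos[i]
  }
  recs[, c("probe_id", "chrom", "pos", "beta_hat", "se", "z", "p_value",
           "n_used", "converged", "boundary", "note")]
}

#' Write / read the EWAS summary-statistics table
#'
#' The TSV contract (`probe_id`, `chrom`, `pos`, `beta_hat`, `se`, `z`,
#' `p_value`, `n_used`, `converged`) is the summary-statistics input consumed
#' by the region stage.
#'
#' @param ewas EWAS record data.frame from [run_ewas()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ewas <- function(ewas, path) {
  utils::write.table(ewas, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ewas
#' @export
read_ewas <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE, quote = "")
}
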