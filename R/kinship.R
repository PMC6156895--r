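#' Kinship matrix from pedigree relationships
#'
#' Computes the recursive kinship coefficients phi(i, j) — the probability
#' that one allele sampled at random from i and one from j are identical by
#' descent — from a pedigree. Founders (unknown parents) are taken as
#' unrelated and non-inbred:
#' \itemize{
#'   \item phi(i, i) = 0.5 * (1 + phi(father_i, mother_i))
#'   \item phi(i, j) = 0.5 * (phi(father_i, j) + phi(mother_i, j)) for j not a
#'     descendant of i (guaranteed by processing parents before children)
#' }
#' The additive relationship matrix used as random-effect covariance in the
#' mixed model is 2 * phi.
#'
#' @param pedigree Data.frame with columns `id`, `father`, `mother`
#'   (NA/missing for founders), e.g. from [read_pedigree()].
#' @return Symmetric kinship matrix phi with ids as dimnames.
#' @export
kinship_from_pedigree <- function(pedigree) {
  ped <- pedigree
  stopifnot(all(c("id", "father", "mother") %in% names(ped)))
  ids <- as.character(ped$id)
  if (anyDuplicated(ids)) stop("duplicate individual ids in pedigree")
  fa <- as.character(ped$father)
  mo <- as.character(ped$mother)
  fa[!fa %in% ids] <- NA_character_   # parents outside the table act as founders
  mo[!mo %in% ids] <- NA_character_
  if (any(!is.na(fa) & fa == ids) || any(!is.na(mo) & mo == ids))
    stop("individual listed as its own parent")

  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  placed <- logical(n)
  remaining <- seq_len(n)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(i) {
      (is.na(fa[i]) || placed[idx[[fa[i]]]]) &&
        (is.na(mo[i]) || placed[idx[[mo[i]]]])
    }, logical(1))]
    if (!length(ready))
      stop("pedigree contains a cycle (an individual is its own ancestor)")
    for (i in ready) {
      f <- if (is.na(fa[i])) NA_integer_ else idx[[fa[i]]]
      m <- if (is.na(mo[i])) NA_integer_ else idx[[mo[i]]]
      phi_fm <- if (is.na(f) || is.na(m)) 0 else phi[f, m]
      done <- which(placed)
      if (length(done)) {
        pf <- if (is.na(f)) numeric(length(done)) else phi[f, done]
        pm <- if (is.na(m)) numeric(length(done)) else phi[m, done]
        phi[i, done] <- phi[done, i] <- 0.5 * (pf + pm)
      }
      phi[i, i] <- 0.5 * (1 + phi_fm)
      placed[i] <- TRUE
    }
    remaining <- setdiff(remaining, ready)
  }
  validate_kinship(phi)
  phi
}

#' Validate a kinship matrix
#'
#' Checks symmetry, self-kinship at least 0.5 (non-inbred lower bound), and
#' positive semidefiniteness of the additive relationship matrix 2 * phi
#' (smallest eigenvalue above a small negative floor). Off-diagonal values
#' above 0.5 are possible only under inbreeding and trigger a warning.
#'
#' @param phi Square numeric kinship matrix with id dimnames.
#' @param tol Eigenvalue floor relative to the largest eigenvalue.
#' @return `phi`, invisibly, if valid.
#' @export
validate_kinship <- function(phi, tol = 1e-8) {
  stopifnot(is.matrix(phi), nrow(phi) == ncol(phi))
  if (is.null(rownames(phi))) stop("kinship matrix must carry sample-id dimnames")
  if (!isTRUE(all.equal(phi, t(phi), tolerance = 1e-10)))
    stop("kinship matrix is not symmetric")
  if (any(diag(phi) < 0.5 - 1e-10))
    stop("self-kinship below 0.5; not a valid kinship matrix")
  off <- phi[upper.tri(phi)]
  if (any(off < -1e-10)) stop("negative kinship coefficients")
  if (any(off > 0.5 + 1e-10))
    warning("off-diagonal kinship above 0.5 (inbreeding present?)")
  ev <- eigen(2 * phi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(ev))
    stop("2*phi is not positive semidefinite")
  invisible(phi)
}

#' Precompute the eigendecomposition of the relationship matrix
#'
#' The mixed-model fit rotates the data by the eigenvectors of 2 * phi; when
#' many probes (or many simulation replicates) share one kinship matrix, the
#' decomposition should be computed once and reused. [run_ewas()] and
#' [fit_probe_lmm()] accept this object wherever a kinship matrix is accepted.
#'
#' @param phi Kinship matrix with sample-id dimnames.
#' @return An object of class `"kinship_eigen"` with elements `sample_ids`,
#'   `values` (eigenvalues of 2 * phi) and `vectors`.
#' @export
kinship_eigen <- function(phi) {
  validate_kinship(phi)
  e <- eigen(2 * phi, symmetric = TRUE)
  structure(list(sample_ids = rownames(phi),
                 values = pmax(e$values, 0),
                 vectors = e$vectors),
            class = "kinship_eigen")
}

#' @export
print.kinship_eigen <- function(x, ...) {
  cat(sprintf("kinship eigendecomposition: %d samples, eigenvalue range [%.4g, %.4g]\n",
              length(x$sample_ids), min(x$values), max(x$values)))
  invisible(x)
}

#' Write a kinship matrix as CSV
#'
#' @param phi Kinship matrix with id dimnames.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_kinship <- function(phi, path) {
  txt <- apply(phi, 2L, function(col) sprintf("%.17g", col))
  df <- data.frame(sample_id = rownames(phi), txt, check.names = FALSE)
  colnames(df) <- c("sample_id", colnames(phi))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
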