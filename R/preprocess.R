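#' Convert methylation beta values to M-values
#'
#' The M-value is the variance-stabilized methylation scale
#' \eqn{M = \log_2(\beta / (1 - \beta))}. Beta values of exactly 0 or 1 give
#' infinite M; by default they are clamped into \[eps, 1 - eps\] first, since
#' array betas occasionally hit the boundary. Missing values propagate.
#'
#' @param beta Numeric vector or matrix of beta values in \[0, 1\].
#' @param clamp If `TRUE` (default) clamp betas to \[eps, 1 - eps\]; if
#'   `FALSE`, boundary betas are an error.
#' @param eps Clamp width (default 1e-6).
#' @return M-values with the same shape and dimnames as `beta`.
#' @seealso [m_to_beta()] for the inverse.
#' @export
beta_to_m <- function(beta, clamp = TRUE, eps = 1e-6) {
  x <- beta
  bad <- !is.na(x) & (x < 0 | x > 1)
  if (any(bad)) stop("beta values outside [0,1]")
  boundary <- !is.na(x) & (x <= 0 | x >= 1)
  if (any(boundary)) {
    if (!clamp) stop("beta value of exactly 0 or 1 encountered with clamp = FALSE")
    x[!is.na(x)] <- pmin(pmax(x[!is.na(x)], eps), 1 - eps)
  }
  log2(x / (1 - x))
}

#' Convert M-values back to beta values
#'
#' Inverse of [beta_to_m()]: \eqn{\beta = 2^M / (1 + 2^M)}.
#'
#' @param m Numeric vector or matrix of M-values.
#' @return Beta values in (0, 1), same shape as `m`.
#' @export
m_to_beta <- function(m) {
  # logistic in base 2; written via plogis for overflow safety at large |M|
  stats::plogis(m * log(2))
}

#' Read a probe exclusion list
#'
#' One probe id per line, plain text. The reason tag records why probes are
#' excluded (for the audit trail), e.g. probes overlapping common polymorphisms
#' or probes whose 50-bp sequence cross-hybridizes elsewhere in the genome.
#'
#' @param path Path to the list file.
#' @param reason One of `"polymorphic"`, `"cross_reactive"`, `"user"`; when
#'   `NULL` it is inferred from the filename, falling back to `"user"`.
#' @return A data.frame with columns `probe_id`, `reason`.
#' @export
read_exclusion_list <- function(path, reason = NULL) {
  stopifnot(file.exists(path))
  if (is.null(reason)) {
    fn <- tolower(basename(path))
    reason <- if (grepl("polymorph|snp", fn)) "polymorphic"
              else if (grepl("cross", fn)) "cross_reactive"
              else "user"
  }
  reason <- match.arg(reason, c("polymorphic", "cross_reactive", "user"))
  ids <- readLines(path, warn = FALSE)
  ids <- trimws(ids)
  ids <- unique(ids[nzchar(ids)])
  data.frame(probe_id = ids, reason = reason, stringsAsFactors = FALSE)
}

#' Apply probe-exclusion filters
#'
#' Removes manifest probes named in any exclusion list (set semantics: the
#' result is independent of list order) and reports an audit of counts removed
#' per reason. Ids absent from the manifest are counted as unmatched no-ops.
#'
#' @param manifest Probe manifest data.frame (see [read_manifest()]).
#' @param exclusions A single exclusion data.frame or a list of them
#'   (see [read_exclusion_list()]); may be empty.
#' @return A list with `retained` (character vector of probe ids, manifest
#'   order) and `audit` (named counts: per-reason removals, `unmatched`,
#'   `retained`, `input`).
#' @export
filter_probes <- function(manifest, exclusions = list()) {
  if (is.data.frame(exclusions)) exclusions <- list(exclusions)
  excl <- if (length(exclusions)) do.call(rbind, exclusions)
          else data.frame(probe_id = character(), reason = character())
  excl <- unique(excl)
  present <- excl$probe_id %in% manifest$probe_id
  drop_ids <- unique(excl$probe_id[present])
  retained <- manifest$probe_id[!manifest$probe_id %in% drop_ids]
  by_reason <- if (nrow(excl)) {
    tab <- table(excl$reason[present])
    stats::setNames(as.integer(tab), names(tab))
  } else integer()
  audit <- c(by_reason,
             unmatched = sum(!present),
             removed = length(drop_ids),
             retained = length(retained),
             input = nrow(manifest))
  list(retained = retained, audit = audit)
}
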