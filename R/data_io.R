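#' Read a probe-by-sample methylation beta-value matrix
#'
#' Reads a delimited table of methylation beta values (fraction of methylated
#' DNA strands per CpG probe, in \[0, 1\]). By default probes are rows and
#' samples are columns, with probe identifiers in the first column; set
#' `samples_in_rows = TRUE` for the transposed layout.
#'
#' @param path Path to a TSV/CSV file.
#' @param sep Field separator; `NULL` (default) infers it from the file
#'   extension (`.csv` gives `","`, anything else tab).
#' @param samples_in_rows Logical; if `TRUE` the file stores samples as rows.
#' @param allow_missing Logical; if `TRUE` (default) empty cells and `NA`
#'   become missing values, otherwise they are an error.
#' @return A numeric matrix with probe ids as rownames and sample ids as
#'   colnames; all non-missing values lie in \[0, 1\].
#' @export
read_methylation <- function(path, sep = NULL, samples_in_rows = FALSE,
                             allow_missing = TRUE) {
  stopifnot(file.exists(path))
  sep <- sep %||% infer_sep(path)
  # read.table de-duplicates header names, so check the raw header ourselves
  hdr <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]][-1L]
  if (anyDuplicated(hdr)) stop("duplicate sample ids in methylation matrix")
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""), quote = "", comment.char = "")
  ids <- as.character(raw[[1L]])
  body <- raw[, -1L, drop = FALSE]
  # locate non-numeric cells before coercion so the error can name them
  num <- vapply(body, function(col) {
    if (is.numeric(col)) return(col)
    suppressWarnings(as.numeric(col))
  }, numeric(nrow(body)))
  if (nrow(body) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, colnames(body)))
  bad <- which(is.na(num) & !is.na(as.matrix(body)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric methylation value at row '%s', column '%s'",
                 ids[bad[1L, 1L]], colnames(body)[bad[1L, 2L]]))
  }
  mat <- num
  rownames(mat) <- ids
  if (samples_in_rows) mat <- t(mat)
  if (!allow_missing && anyNA(mat)) {
    stop("missing beta values present but allow_missing = FALSE")
  }
  validate_beta_matrix(mat)
  mat
}

`%||%` <- function(a, b) if (is.null(a)) b else a

infer_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Validate a methylation beta matrix
#'
#' Checks the invariants of the beta-value container: unique probe and sample
#' identifiers and all non-missing values in \[0, 1\].
#'
#' @param beta Numeric matrix, probes x samples, with dimnames.
#' @return The matrix, invisibly, if valid; otherwise an error.
#' @export
validate_beta_matrix <- function(beta) {
  stopifnot(is.matrix(beta), is.numeric(beta))
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop("beta matrix must carry probe rownames and sample colnames")
  if (anyDuplicated(rownames(beta))) stop("duplicate probe ids in methylation matrix")
  if (anyDuplicated(colnames(beta))) stop("duplicate sample ids in methylation matrix")
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("beta value %.4g outside [0,1] at probe '%s', sample '%s'",
                 beta[bad[1L, 1L], bad[1L, 2L]],
                 rownames(beta)[bad[1L, 1L]], colnames(beta)[bad[1L, 2L]]))
  }
  invisible(beta)
}

#' Write a methylation matrix to a delimited file
#'
#' @param beta Numeric probe x sample matrix.
#' @param path Output path; separator inferred from extension.
#' @param sep Optional explicit separator.
#' @return `path`, invisibly.
#' @export
write_methylation <- function(beta, path, sep = NULL) {
  sep <- sep %||% infer_sep(path)
  # %.17g keeps the round-trip exact to the last bit
  txt <- apply(beta, 2L, function(col) ifelse(is.na(col), "NA", sprintf("%.17g", col)))
  if (nrow(beta) == 1L) txt <- matrix(txt, nrow = 1L)
  df <- data.frame(probe_id = rownames(beta), txt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("probe_id", colnames(beta))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample phenotype/covariate table
#'
#' @param path Path to a TSV/CSV with one row per sample.
#' @param id_col Name of the sample-identifier column.
#' @param phenotype Name of the quantitative phenotype column.
#' @param covariates Character vector of covariate column names (may be empty).
#' @param family_col Optional name of a family-identifier column.
#' @param log_phenotype If `TRUE`, analyze the natural log of the phenotype
#'   (the convention for right-skewed traits such as triglycerides).
#' @param sep Optional separator (inferred from extension when `NULL`).
#' @return A data.frame with columns `sample_id`, `phenotype`, the covariates,
#'   and optionally `family_id`; attribute `"covariates"` records the
#'   covariate names.
#' @export
read_samples <- function(path, id_col = "sample_id", phenotype = "phenotype",
                         covariates = character(), family_col = NULL,
                         log_phenotype = FALSE, sep = NULL) {
  stopifnot(file.exists(path))
  sep <- sep %||% infer_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""), quote = "")
  need <- c(id_col, phenotype, covariates, family_col)
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("sample table lacks column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(sample_id = as.character(raw[[id_col]]),
                    phenotype = as.numeric(raw[[phenotype]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$sample_id)) stop("duplicate sample ids in sample table")
  if (log_phenotype) {
    if (any(out$phenotype <= 0, na.rm = TRUE))
      stop("log_phenotype requires strictly positive phenotype values")
    out$phenotype <- log(out$phenotype)
  }
  for (cv in covariates) out[[cv]] <- raw[[cv]]
  if (!is.null(family_col)) out$family_id <- as.character(raw[[family_col]])
  attr(out, "covariates") <- covariates
  out
}

#' Expand covariates into a numeric design block
#'
#' Categorical covariates are expanded to indicator columns deterministically:
#' levels sorted alphabetically, first level dropped as reference. Numeric
#' covariates pass through unchanged. This fixed encoding keeps fitted results
#' reproducible across runs and platforms.
#'
#' @param samples Sample data.frame (see [read_samples()]).
#' @param covariates Covariate column names; defaults to the table's
#'   `"covariates"` attribute.
#' @return Numeric matrix with one row per sample (zero columns when there are
#'   no covariates).
#' @export
covariate_matrix <- function(samples, covariates = attr(samples, "covariates")) {
  covariates <- covariates %||% character()
  n <- nrow(samples)
  blocks <- lapply(covariates, function(cv) {
    x <- samples[[cv]]
    if (is.null(x)) stop("unknown covariate column: ", cv)
    if (is.numeric(x)) {
      m <- matrix(as.numeric(x), ncol = 1L, dimnames = list(NULL, cv))
      return(m)
    }
    x <- as.character(x)
    lev <- sort(unique(x[!is.na(x)]))
    if (length(lev) < 2L) return(matrix(numeric(n), ncol = 0L))
    keep <- lev[-1L]
    m <- vapply(keep, function(l) as.numeric(x == l), numeric(n))
    if (n == 1L) m <- matrix(m, nrow = 1L)
    colnames(m) <- paste(cv, keep, sep = ".")
    m[is.na(x), ] <- NA_real_
    m
  })
  if (!length(blocks)) return(matrix(numeric(0), nrow = n, ncol = 0L))
  do.call(cbind, blocks)
}

# canonical island-relation spellings (Illumina manifest uses e.g. "N_Shore")
.island_levels <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf")

#' Read an Illumina-manifest-style probe annotation table
#'
#' Parses a probe manifest with genomic coordinates and UCSC-style gene and
#' CpG-island annotations. `gene_names` and `gene_groups` are parallel
#' semicolon-delimited lists (one gene symbol paired positionally with one
#' functional category per token); their token counts must agree per probe.
#'
#' @param path Path to a TSV/CSV manifest.
#' @param col_map Named character vector mapping internal names
#'   (`probe_id`, `chrom`, `pos`, `gene_names`, `gene_groups`,
#'   `island_relation`, `island_name`) to file column names; defaults to the
#'   Illumina 450K header names.
#' @param sep Optional separator.
#' @return A data.frame with the internal columns above; `island_relation` is
#'   normalized to one of Island, N_Shore, S_Shore, N_Shelf, S_Shelf or
#'   `"none"`. Probes with no annotations are retained (they simply belong to
#'   no region).
#' @export
read_manifest <- function(path, col_map = NULL, sep = NULL) {
  stopifnot(file.exists(path))
  defaults <- c(probe_id = "IlmnID", chrom = "CHR", pos = "MAPINFO",
                gene_names = "UCSC_RefGene_Name",
                gene_groups = "UCSC_RefGene_Group",
                island_relation = "Relation_to_UCSC_CpG_Island",
                island_name = "UCSC_CpG_Islands_Name")
  map <- defaults
  if (!is.null(col_map)) map[names(col_map)] <- col_map
  sep <- sep %||% infer_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""), quote = "",
                           comment.char = "")
  need <- map[c("probe_id", "chrom", "pos")]
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("manifest lacks column(s): ", paste(miss, collapse = ", "))
  getcol <- function(key, default = NA_character_) {
    cn <- map[[key]]
    if (cn %in% names(raw)) raw[[cn]] else rep(default, nrow(raw))
  }
  man <- data.frame(
    probe_id = as.character(raw[[map[["probe_id"]]]]),
    chrom = as.character(raw[[map[["chrom"]]]]),
    pos = as.integer(raw[[map[["pos"]]]]),
    gene_names = trimna(getcol("gene_names")),
    gene_groups = trimna(getcol("gene_groups")),
    island_name = trimna(getcol("island_name")),
    island_relation = normalize_island_relation(getcol("island_relation")),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(man$probe_id)) stop("duplicate probe ids in manifest")
  if (any(!is.na(man$pos) & man$pos <= 0L)) stop("manifest positions must be positive 1-based integers")
  # token-count parity between the two parallel gene lists
  nn <- token_count(man$gene_names)
  ng <- token_count(man$gene_groups)
  bad <- which(nn != ng)
  if (length(bad)) {
    stop(sprintf("probe '%s': gene_names has %d token(s) but gene_groups has %d",
                 man$probe_id[bad[1L]], nn[bad[1L]], ng[bad[1L]]))
  }
  man
}

trimna <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & trimws(x) == ""] <- NA_character_
  x
}

token_count <- function(x) {
  ifelse(is.na(x), 0L, lengths(strsplit(x, ";", fixed = TRUE)))
}

normalize_island_relation <- function(x) {
  x <- trimna(x)
  key <- toupper(gsub("[ _-]", "", x))
  lut <- c(ISLAND = "Island", NSHORE = "N_Shore", SSHORE = "S_Shore",
           NSHELF = "N_Shelf", SSHELF = "S_Shelf",
           NORTHSHORE = "N_Shore", SOUTHSHORE = "S_Shore",
           NORTHSHELF = "N_Shelf", SOUTHSHELF = "S_Shelf",
           NONE = "none")
  out <- unname(lut[key])
  out[is.na(x)] <- "none"
  unknown <- !is.na(x) & is.na(out)
  if (any(unknown)) {
    warning("unrecognized island relation value(s): ",
            paste(unique(x[unknown]), collapse = ", "), "; treated as 'none'")
    out[unknown] <- "none"
  }
  out
}

#' Align methylation, sample table and kinship on their common samples
#'
#' Restricts every component to the intersection of sample ids and reorders
#' all of them to the same deterministic (sorted) order, so the aligned object
#' does not depend on input ordering.
#'
#' @param meth Probe x sample beta (or M-value) matrix.
#' @param samples Sample data.frame with a `sample_id` column.
#' @param kinship Optional square kinship matrix with sample-id dimnames.
#' @return A list with elements `meth`, `samples`, `kinship` (NULL if absent),
#'   `sample_ids`, and `dropped` (counts removed from each input).
#' @export
align_samples <- function(meth, samples, kinship = NULL) {
  ids_m <- colnames(meth)
  ids_s <- samples$sample_id
  common <- intersect(ids_m, ids_s)
  if (!is.null(kinship)) common <- intersect(common, rownames(kinship))
  if (length(common) == 0L) stop("no samples shared across inputs")
  common <- sort(common)
  out <- list(
    meth = meth[, common, drop = FALSE],
    samples = {
      s <- samples[match(common, samples$sample_id), , drop = FALSE]
      rownames(s) <- NULL
      attr(s, "covariates") <- attr(samples, "covariates")
      s
    },
    kinship = if (!is.null(kinship)) kinship[common, common, drop = FALSE],
    sample_ids = common,
    dropped = c(meth = length(ids_m) - length(common),
                samples = length(ids_s) - length(common),
                kinship = if (is.null(kinship)) 0L else nrow(kinship) - length(common))
  )
  out
}

#' Write a DMR result table to TSV (and optionally BED6)
#'
#' The TSV mirrors the conventional DMR report layout (chromosome, start,
#' stop, probe count, statistic, p value) plus region identifier, annotation
#' category and FDR q-value. Coordinates are 1-based inclusive internally; the
#' BED export converts to 0-based half-open (`bed_start = start - 1`).
#'
#' @param results A data.frame of region results (see [globalp()]).
#' @param path Output TSV path.
#' @param bed Optional path for a BED6 export.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, bed = NULL) {
  cols <- c("chromosome", "start", "stop", "n_probes", "statistic", "df",
            "p_value", "q_value", "region_id", "category")
  df <- as.data.frame(results)
  if ("chrom" %in% names(df) && !"chromosome" %in% names(df))
    names(df)[names(df) == "chrom"] <- "chromosome"
  if ("m" %in% names(df) && !"n_probes" %in% names(df))
    names(df)[names(df) == "m"] <- "n_probes"
  miss <- setdiff(cols, names(df))
  if (length(miss)) stop("result table lacks column(s): ", paste(miss, collapse = ", "))
  utils::write.table(df[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(bed)) {
    score <- ifelse(is.na(df$p_value) | df$p_value <= 0, 1000,
                    pmin(1000, round(-10 * log10(df$p_value))))
    bed6 <- data.frame(df$chromosome, df$start - 1L, df$stop, df$region_id,
                       score, ".")
    utils::write.table(bed6, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a pedigree table
#'
#' @param path TSV/CSV with columns family (optional), id, father, mother.
#'   Unknown parents are coded 0, "0", or NA.
#' @param sep Optional separator.
#' @return A data.frame with columns `family_id` (may be NA), `id`, `father`,
#'   `mother` (NA for founders).
#' @export
read_pedigree <- function(path, sep = NULL) {
  stopifnot(file.exists(path))
  sep <- sep %||% infer_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""), quote = "")
  nm <- tolower(names(raw))
  pick <- function(keys) {
    i <- which(nm %in% keys)[1L]
    if (is.na(i)) NULL else as.character(raw[[i]])
  }
  id <- pick(c("id", "individual", "iid"))
  if (is.null(id)) stop("pedigree lacks an individual id column")
  fa <- pick(c("father", "fid", "sire", "pat")) %||% rep(NA_character_, length(id))
  mo <- pick(c("mother", "mid", "dam", "mat")) %||% rep(NA_character_, length(id))
  fam <- pick(c("family", "family_id", "famid")) %||% rep(NA_character_, length(id))
  clean <- function(x) { x[x %in% c("0", "")] <- NA_character_; x }
  data.frame(family_id = fam, id = id, father = clean(fa), mother = clean(mo),
             stringsAsFactors = FALSE)
}

#' Read a precomputed square kinship matrix
#'
#' @param path CSV/TSV with a sample-id header row and ids in the first column.
#' @param sep Optional separator.
#' @return Symmetric numeric matrix with sample-id dimnames.
#' @export
read_kinship <- function(path, sep = NULL) {
  stopifnot(file.exists(path))
  sep <- sep %||% if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "")
  ids <- as.character(raw[[1L]])
  phi <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(phi) <- ids
  storage.mode(phi) <- "double"
  validate_kinship(phi)
  phi
}
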