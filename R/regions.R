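# Annotation-defined probe regions: six gene functional categories
# (TSS1500, TSS200, 5'UTR, 1stExon, Body, 3'UTR) and five CpG-island relation
# categories (Island, N_Shore, S_Shore, N_Shelf, S_Shelf).

gene_categories <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body", "3'UTR")
island_categories <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf")

new_region_set <- function(meta, probes, audit = list()) {
  stopifnot(nrow(meta) == length(probes))
  names(probes) <- meta$region_id
  structure(list(meta = meta, probes = probes, audit = audit),
            class = "region_set")
}

empty_region_meta <- function() {
  data.frame(region_id = character(), name = character(),
             category = character(), chrom = character(),
             start = integer(), stop = integer(), m = integer(),
             stringsAsFactors = FALSE)
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region set: %d regions over %d distinct probes\n",
              nrow(x$meta), length(unique(unlist(x$probes, use.names = FALSE)))))
  if (nrow(x$meta)) {
    tab <- table(x$meta$category)
    cat("  by category:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.region_set <- function(x) nrow(x$meta)

#' @export
as.data.frame.region_set <- function(x, ...) {
  df <- x$meta
  df$probe_ids <- vapply(x$probes, paste, "", collapse = ";")
  df
}

# shared assembly step: membership table (probe_id, name, category) -> regions
assemble_regions <- function(members, manifest) {
  if (nrow(members) == 0L) return(new_region_set(empty_region_meta(), list()))
  members <- unique(members)                     # duplicate pairs -> one membership
  i <- match(members$probe_id, manifest$probe_id)
  members$chrom <- manifest$chrom[i]
  members$pos <- manifest$pos[i]
  key <- paste(members$name, members$category, sep = ":")
  ord <- order(key, members$pos, members$probe_id, method = "radix")
  members <- members[ord, , drop = FALSE]
  key <- key[ord]
  idx <- split(seq_len(nrow(members)), factor(key, levels = unique(key)))
  meta <- do.call(rbind, lapply(names(idx), function(k) {
    rows <- idx[[k]]
    chrom <- unique(members$chrom[rows])
    if (length(chrom) > 1L)
      stop(sprintf("region '%s' spans chromosomes %s", k, paste(chrom, collapse = ",")))
    data.frame(region_id = k,
               name = members$name[rows[1L]],
               category = members$category[rows[1L]],
               chrom = chrom,
               start = min(members$pos[rows]),
               stop = max(members$pos[rows]),
               m = length(rows), stringsAsFactors = FALSE)
  }))
  probes <- lapply(idx, function(rows) members$probe_id[rows])
  # deterministic region order: genomic, then id
  o <- order(meta$chrom, meta$start, meta$region_id, method = "radix")
  new_region_set(meta[o, , drop = FALSE], probes[o])
}

#' Build gene-functional-category regions from the manifest
#'
#' Pairs each probe's `gene_names` and `gene_groups` tokens positionally and
#' creates one region per distinct (gene, category) pair. Duplicate pairs
#' within a probe contribute a single membership. Unknown category tokens are
#' skipped with a warning and counted in the audit.
#'
#' @param manifest Probe manifest (see [read_manifest()]).
#' @param retained Optional character vector of analyzable probe ids (from
#'   [filter_probes()]); defaults to all manifest probes.
#' @return A `region_set`: regions with probes ordered by genomic position,
#'   `start`/`stop` the min/max probe position.
#' @export
build_gene_regions <- function(manifest, retained = NULL) {
  man <- manifest
  if (!is.null(retained)) man <- man[man$probe_id %in% retained, , drop = FALSE]
  has <- !is.na(man$gene_names)
  names_l <- strsplit(man$gene_names[has], ";", fixed = TRUE)
  groups_l <- strsplit(man$gene_groups[has], ";", fixed = TRUE)
  members <- data.frame(
    probe_id = rep(man$probe_id[has], lengths(names_l)),
    name = unlist(names_l, use.names = FALSE),
    category = unlist(groups_l, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  unknown <- !members$category %in% gene_categories
  n_unknown <- sum(unknown)
  if (n_unknown) {
    warning("skipping ", n_unknown, " gene annotation token(s) with unknown category: ",
            paste(unique(members$category[unknown]), collapse = ", "))
    members <- members[!unknown, , drop = FALSE]
  }
  rs <- assemble_regions(members, man)
  rs$audit <- list(unknown_category_tokens = n_unknown)
  rs
}

#' Build CpG-island relation regions from the manifest
#'
#' Creates one region per distinct (island name, relation) pair, so the north
#' and south shores of one island are distinct regions. Probes with relation
#' `"none"` belong to no island region; a probe with a relation but no island
#' name is skipped with a warning.
#'
#' @inheritParams build_gene_regions
#' @return A `region_set`.
#' @export
build_island_regions <- function(manifest, retained = NULL) {
  man <- manifest
  if (!is.null(retained)) man <- man[man$probe_id %in% retained, , drop = FALSE]
  rel <- man$island_relation
  has <- !is.na(rel) & rel != "none"
  orphan <- has & is.na(man$island_name)
  n_orphan <- sum(orphan)
  if (n_orphan) {
    warning("skipping ", n_orphan, " probe(s) with an island relation but no island name")
    has <- has & !orphan
  }
  members <- data.frame(probe_id = man$probe_id[has],
                        name = man$island_name[has],
                        category = rel[has], stringsAsFactors = FALSE)
  rs <- assemble_regions(members, man)
  rs$audit <- list(orphan_relation_probes = n_orphan)
  rs
}

#' Combine gene and island region sets and apply probe-count bounds
#'
#' Takes the union of the two sets and keeps regions with
#' `min_probes <= m <= max_probes`. Overlap between the sets is preserved:
#' the same probes may drive both a gene region and an island region, which is
#' the intended behavior of annotation-based testing (overlapping annotations
#' are handled by FDR, not deduplicated).
#'
#' @param gene_set,island_set `region_set`s built from the same retained
#'   probes (either may be empty or NULL).
#' @param min_probes Minimum region size (default 2; single-probe regions
#'   duplicate the per-probe EWAS test).
#' @param max_probes Maximum region size (default Inf).
#' @return A combined, filtered `region_set`; the audit records counts before
#'   and after the size filter.
#' @export
attach_regions <- function(gene_set, island_set, min_probes = 2L,
                           max_probes = Inf) {
  if (min_probes > max_probes) stop("min_probes exceeds max_probes")
  if (min_probes < 1L) stop("min_probes must be at least 1")
  sets <- Filter(Negate(is.null), list(gene_set, island_set))
  meta <- do.call(rbind, lapply(sets, function(s) s$meta))
  probes <- do.call(c, lapply(sets, function(s) s$probes))
  if (is.null(meta)) meta <- empty_region_meta()
  if (anyDuplicated(meta$region_id))
    stop("duplicate region ids across the gene and island sets")
  keep <- meta$m >= min_probes & meta$m <= max_probes
  out <- new_region_set(meta[keep, , drop = FALSE], probes[keep])
  out$audit <- list(n_before_size_filter = nrow(meta),
                    n_after_size_filter = sum(keep),
                    min_probes = min_probes, max_probes = max_probes)
  out
}

#' Write / read a region set as TSV
#'
#' Columns: `region_id`, `name`, `category`, `chrom`, `start`, `stop`, `m`,
#' `probe_ids` (semicolon-joined, position order). The file is consumable as
#' a user-supplied custom region definition.
#'
#' @param regions A `region_set`.
#' @param path TSV path.
#' @return `path` (write) or a `region_set` (read).
#' @export
write_regions <- function(regions, path) {
  utils::write.table(as.data.frame(regions), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_regions
#' @export
read_regions <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  probes <- strsplit(df$probe_ids, ";", fixed = TRUE)
  meta <- df[, c("region_id", "name", "category", "chrom", "start", "stop", "m")]
  new_region_set(meta, probes)
}
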