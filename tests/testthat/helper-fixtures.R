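# shared fixture builders (everything generated in code, no stored data)

tiny_manifest <- function() {
  data.frame(
    probe_id = c("cg1", "cg2", "cg3", "cg4", "cg5", "cg6"),
    chrom = c("chr11", "chr11", "chr11", "chr11", "chr12", "chr12"),
    pos = c(68607622L, 68607700L, 68607900L, 68608200L, 11803199L, 11803500L),
    gene_names = c("CPT1A", "CPT1A", "CPT1A", NA, "ETV6;ETV6", "ETV6"),
    gene_groups = c("5'UTR", "5'UTR", "5'UTR", NA, "Body;Body", "Body"),
    island_name = c("chr11:68607737-68608125", "chr11:68607737-68608125",
                    "chr11:68607737-68608125", NA, NA, NA),
    island_relation = c("N_Shore", "N_Shore", "Island", "none", "none", "none"),
    stringsAsFactors = FALSE
  )
}

tiny_samples <- function(n = 8, seed = 42, covariates = c("age", "sex")) {
  set.seed(seed)
  s <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    phenotype = rnorm(n),
    age = round(runif(n, 30, 70)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  attr(s, "covariates") <- covariates
  s
}

random_beta_matrix <- function(n_probes = 4, n_samples = 6, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n_probes * n_samples, 0.05, 0.95), n_probes, n_samples,
              dimnames = list(sprintf("cg%d", seq_len(n_probes)),
                              sprintf("S%03d", seq_len(n_samples))))
  m
}

# random full-rank correlation matrix (empirical correlation of a tall
# gaussian sample, so it is a genuine correlation matrix)
random_corr <- function(m, n = m + 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stats::cor(matrix(rnorm(n * m), n, m))
}

# sibling-family kinship matrix (k sibs per family)
sib_kinship <- function(n_families, k = 3) {
  blk <- matrix(0.25, k, k); diag(blk) <- 0.5
  ids <- sprintf("S%05d", seq_len(n_families * k))
  phi <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (f in seq_len(n_families)) {
    i <- ((f - 1) * k + 1):(f * k)
    phi[i, i] <- blk
  }
  phi
}
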