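test_that("methylation matrix survives a write/read round trip at full precision", {
  beta <- random_beta_matrix(3, 2, seed = 5)
  beta[1, 1] <- 0.1 + 1e-16  # exercise last-bit fidelity
  f <- withr::local_tempfile(fileext = ".tsv")
  write_methylation(beta, f)
  back <- read_methylation(f)
  expect_identical(dim(back), dim(beta))
  expect_identical(back, beta)
})

test_that("out-of-range and non-numeric beta cells are rejected with location", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\tA\tB", "cg1\t0.1\t0.2", "cg2\t1.2\t0.3"), f)
  expect_error(read_methylation(f), "cg2.*A|\\[0,1\\]")
  writeLines(c("probe_id\tA\tB", "cg1\t0.1\toops"), f)
  expect_error(read_methylation(f), "non-numeric.*cg1.*B")
})

test_that("missing beta cells are preserved or rejected per the flag", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\tA\tB", "cg1\t\t0.2", "cg2\t0.5\t0.3"), f)
  got <- read_methylation(f)
  expect_true(is.na(got["cg1", "A"]))
  expect_equal(got["cg2", "B"], 0.3)
  expect_error(read_methylation(f, allow_missing = FALSE), "missing")
})

test_that("duplicate probe or sample ids are a hard error", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\tA\tA", "cg1\t0.1\t0.2"), f)
  expect_error(read_methylation(f), "duplicate sample")
  writeLines(c("probe_id\tA\tB", "cg1\t0.1\t0.2", "cg1\t0.3\t0.4"), f)
  expect_error(read_methylation(f), "duplicate probe")
})

test_that("manifest parsing pairs gene tokens positionally and checks parity", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("IlmnID,CHR,MAPINFO,UCSC_RefGene_Name,UCSC_RefGene_Group,Relation_to_UCSC_CpG_Island,UCSC_CpG_Islands_Name",
               "cg1,chr11,68607622,CPT1A,5'UTR,N_Shore,chr11:68607737-68608125",
               "cg2,chr12,100,ETV6;ETV6,Body;Body,,",
               "cg3,chr12,200,,,,"), f)
  man <- read_manifest(f)
  expect_equal(man$probe_id, c("cg1", "cg2", "cg3"))
  expect_equal(man$gene_names[2], "ETV6;ETV6")
  expect_equal(man$island_relation, c("N_Shore", "none", "none"))
  expect_true(is.na(man$gene_names[3]))  # unannotated probes retained

  writeLines(c("IlmnID,CHR,MAPINFO,UCSC_RefGene_Name,UCSC_RefGene_Group",
               "cg1,chr1,10,A;B,Body"), f)
  expect_error(read_manifest(f), "cg1.*2 token.*1")
})

test_that("island relation strings are normalized to the canonical five", {
  expect_equal(globalp:::normalize_island_relation(
    c("Island", "N_Shore", "south shore", "NORTH-SHELF", NA, "none")),
    c("Island", "N_Shore", "S_Shore", "N_Shelf", "none", "none"))
})

test_that("align_samples restricts to the sorted common set, invariant to order", {
  beta <- random_beta_matrix(3, 3, seed = 2)
  colnames(beta) <- c("A", "B", "C")
  s <- tiny_samples(3)
  s$sample_id <- c("B", "C", "D")
  al <- align_samples(beta, s)
  expect_equal(al$sample_ids, c("B", "C"))
  expect_equal(al$dropped[["meth"]], 1L)
  expect_equal(al$dropped[["samples"]], 1L)

  perm <- align_samples(beta[, c(3, 1, 2)], s[c(2, 1, 3), ])
  expect_identical(perm$meth, al$meth)
  expect_identical(perm$samples$sample_id, al$samples$sample_id)

  again <- align_samples(al$meth, al$samples)
  expect_identical(again$meth, al$meth)  # idempotent

  s$sample_id <- c("X", "Y", "Z")
  expect_error(align_samples(beta, s), "no samples shared")
})

test_that("result table export matches the report layout and BED convention", {
  res <- data.frame(region_id = "CPT1A:5'UTR", category = "5'UTR",
                    chrom = "chr11", start = 68583422L, stop = 68609203L,
                    n_probes = 15L, statistic = 75.2, df = 15,
                    p_value = 3.25e-14, q_value = 1e-9, significant = TRUE)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_results(res, tsv, bed = bed)
  back <- read.table(tsv, header = TRUE, sep = "\t", quote = "")
  expect_equal(back$chromosome, "chr11")
  expect_equal(back$start, 68583422L)
  expect_equal(back$stop, 68609203L)
  expect_equal(back$n_probes, 15L)
  bedrow <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(bedrow[1:3], c("chr11", "68583421", "68609203"))

  empty <- res[0, ]
  write_results(empty, tsv)
  expect_length(readLines(tsv), 1L)  # header only
})

test_that("BED start is TSV start - 1 for every row", {
  set.seed(9)
  n <- 12
  res <- data.frame(region_id = paste0("r", 1:n), category = "Body",
                    chrom = "chr2", start = sample.int(1e6, n),
                    n_probes = 2L, statistic = rchisq(n, 2), df = 2,
                    p_value = runif(n), q_value = runif(n))
  res$stop <- res$start + sample.int(1e4, n)
  tsv <- withr::local_tempfile(); bed <- withr::local_tempfile()
  write_results(res, tsv, bed = bed)
  tt <- read.table(tsv, header = TRUE, sep = "\t")
  bb <- read.table(bed, sep = "\t")
  expect_equal(bb$V2, tt$start - 1L)
})

test_that("categorical covariates expand deterministically (sorted levels, first dropped)", {
  s <- data.frame(sample_id = c("a", "b", "c"), phenotype = 1:3,
                  smoking = c("never", "current", "former"))
  cm <- covariate_matrix(s, "smoking")
  expect_equal(colnames(cm), c("smoking.former", "smoking.never"))
  expect_equal(cm[, "smoking.never"], c(1, 0, 0))
  # permuting rows permutes values, never the encoding
  cm2 <- covariate_matrix(s[c(3, 1, 2), ], "smoking")
  expect_equal(colnames(cm2), colnames(cm))
})

test_that("sample table reader applies the log transform and validates columns", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\ttg\tage", "A\t100\t50", "B\t200\t60"), f)
  s <- read_samples(f, phenotype = "tg", covariates = "age", log_phenotype = TRUE)
  expect_equal(s$phenotype, log(c(100, 200)))
  expect_error(read_samples(f, phenotype = "nope"), "lacks column")
})

test_that("pedigree and kinship files round-trip", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("family\tid\tfather\tmother", "F1\tP1\t0\t0", "F1\tP2\t0\t0",
               "F1\tC1\tP1\tP2"), f)
  ped <- read_pedigree(f)
  expect_true(is.na(ped$father[1]))
  expect_equal(ped$father[3], "P1")
  phi <- kinship_from_pedigree(ped)
  k <- withr::local_tempfile(fileext = ".csv")
  write_kinship(phi, k)
  expect_identical(read_kinship(k), phi)
})
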