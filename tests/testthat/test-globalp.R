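test_that("partial correlation without covariates is the plain correlation", {
  set.seed(14)
  M <- matrix(rnorm(4 * 30), 4, 30,
              dimnames = list(paste0("cg", 1:4), sprintf("S%03d", 1:30)))
  s <- data.frame(sample_id = colnames(M), phenotype = rnorm(30))
  attr(s, "covariates") <- character()
  pc <- partial_correlation(M, s)
  expect_equal(pc$sigma, unname(cor(t(M))), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(diag(pc$sigma)), rep(1, 4))
  expect_equal(pc$rank, 4L)
  expect_equal(pc$n_eff, 30L)
})

test_that("partial correlation matches a per-probe regression-residual oracle", {
  # n = 6 toy dataset, one numeric covariate, m = 2 probes
  s <- data.frame(sample_id = letters[1:6], phenotype = rnorm(6),
                  x = c(1, 2, 3, 4, 5, 6))
  attr(s, "covariates") <- "x"
  M <- rbind(cg1 = c(0.2, 0.5, 0.1, 0.9, 0.4, 0.7),
             cg2 = c(1.1, 0.3, 0.8, 0.2, 0.6, 0.5))
  colnames(M) <- s$sample_id
  pc <- partial_correlation(M, s)
  r1 <- resid(lm(M[1, ] ~ s$x))
  r2 <- resid(lm(M[2, ] ~ s$x))
  expect_equal(pc$sigma[1, 2], cor(r1, r2), tolerance = 1e-12)
})

test_that("a duplicated probe yields unit off-diagonal and rank m - 1", {
  set.seed(6)
  M <- matrix(rnorm(3 * 20), 3, 20,
              dimnames = list(paste0("cg", 1:3), sprintf("S%03d", 1:20)))
  M <- rbind(M, cg4 = M[1, ])
  s <- data.frame(sample_id = colnames(M), phenotype = rnorm(20))
  attr(s, "covariates") <- character()
  pc <- partial_correlation(M, s)
  expect_equal(pc$sigma[1, 4], 1, tolerance = 1e-12)
  expect_equal(pc$rank, 3L)
  # clipping one eigenvalue reduces df by exactly one
  out <- region_chi2(c(1, -0.5, 0.3, 1), pc)
  expect_equal(out$df, 3)
})

test_that("zero residual variance is an error naming the probe", {
  M <- rbind(cg1 = rnorm(10), flatprobe = rep(2, 10))
  colnames(M) <- sprintf("S%03d", 1:10)
  s <- data.frame(sample_id = colnames(M), phenotype = rnorm(10))
  attr(s, "covariates") <- character()
  expect_error(partial_correlation(M, s), "flatprobe")
})

test_that("region statistic reduces correctly in analytic cases", {
  out0 <- region_chi2(c(0, 0, 0), diag(3))
  expect_equal(out0$statistic, 0)
  expect_equal(out0$df, 3)
  expect_equal(out0$p_value, 1)

  out1 <- region_chi2(1.96, matrix(1))
  expect_equal(out1$statistic, 1.96^2, tolerance = 1e-12)
  expect_equal(out1$p_value, 2 * pnorm(-1.96), tolerance = 1e-12)

  # Sigma = I: statistic is the sum of squared z-scores exactly
  set.seed(8)
  z <- rnorm(6)
  expect_equal(region_chi2(z, diag(6))$statistic, sum(z^2))
})

test_that("the worked 2x2 case matches the closed-form oracle", {
  sig <- matrix(c(1, 0.5, 0.5, 1), 2)
  out <- region_chi2(c(1, 1), sig)
  expect_equal(out$statistic, 4 / 3, tolerance = 1e-12)
  expect_equal(out$df, 2)
  expect_equal(out$p_value, exp(-2 / 3), tolerance = 1e-12)
})

test_that("the statistic is invariant under joint permutation of z and Sigma", {
  set.seed(19)
  for (i in 1:20) {
    m <- sample(2:8, 1)
    sig <- random_corr(m)
    z <- rnorm(m)
    perm <- sample(m)
    a <- region_chi2(z, sig)
    b <- region_chi2(z[perm], sig[perm, perm])
    expect_equal(b$statistic, a$statistic, tolerance = 1e-9)
    expect_equal(b$df, a$df)
  }
})

test_that("region statistic errors on malformed input", {
  expect_error(region_chi2(c(1, 2), diag(3)), "dimension")
  expect_error(region_chi2(c(1, NA), diag(2)), "finite")
  expect_error(region_chi2(c(1, 1), matrix(0, 2, 2)), "rank 0")
})

test_that("null p-values are uniform when z is drawn from the model", {
  set.seed(33)
  m <- 5
  sig <- random_corr(m, n = 50)
  L <- chol(sig)
  Z <- matrix(rnorm(1e4 * m), 1e4, m) %*% L
  p <- apply(Z, 1, function(z) region_chi2(z, sig)$p_value)
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("BH step-up adjustment matches its hand-worked cases", {
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(0.005, 0.5)), c(0.01, 0.5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_fdr(c(0.5, 1.2)), "outside")
  expect_equal(bh_fdr(c(0.5, NA, 0.1)), c(0.5, NA, 0.2))
})

test_that("BH agrees with stats::p.adjust on random vectors", {
  set.seed(44)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    if (i %% 3 == 0) p <- round(p, 2)  # force ties
    expect_equal(bh_fdr(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("single-probe regions reproduce the probe's own two-sided p-value", {
  set.seed(50)
  st <- simulate_study(simulation_config(n_families = 80, n_regions = 3,
                                         probes_per_region = 1,
                                         n_null_singletons = 0, seed = 50))
  ew <- run_ewas(beta_to_m(st$meth), st$samples, model = "ols",
                 manifest = st$manifest)
  rs <- attach_regions(build_gene_regions(st$manifest), NULL, min_probes = 1)
  fit <- globalp(ew, rs, st$meth, st$samples, min_probes = 1)
  # region p for m = 1 equals the probe's two-sided EWAS p to numerical precision
  expect_equal(sort(fit$results$p_value), sort(ew$p_value), tolerance = 1e-12)
})

test_that("a planted region effect attains the smallest q-value", {
  st <- simulate_study(simulation_config(
    n_families = 150, n_regions = 8, probes_per_region = 5,
    causal_regions = list(list(region = 3, effect = 0.4)), seed = 99))
  ew <- run_ewas(beta_to_m(st$meth), st$samples, model = "ols",
                 manifest = st$manifest)
  rs <- attach_regions(build_gene_regions(st$manifest), NULL)
  fit <- globalp(ew, rs, st$meth, st$samples)
  res <- fit$results
  expect_equal(res$region_id[which.min(res$q_value)], "GENE03:Body")
  expect_true(res$significant[res$region_id == "GENE03:Body"])
})

test_that("overlapping gene and island regions sharing signal probes both fire", {
  st <- simulate_study(simulation_config(
    n_families = 200, n_regions = 6, probes_per_region = 2,
    causal_regions = list(list(region = 1, effect = 0.5)), seed = 13))
  man <- st$manifest
  # annotate the two causal probes as the north shore of an island too, so a
  # gene region and an island region share exactly their signal probes
  shared <- st$manifest$probe_id[1:2]
  man$island_name[man$probe_id %in% shared] <- "chr1:100000-100500"
  man$island_relation[man$probe_id %in% shared] <- "N_Shore"
  ew <- run_ewas(beta_to_m(st$meth), st$samples, model = "ols", manifest = man)
  rs <- attach_regions(build_gene_regions(man), build_island_regions(man))
  fit <- globalp(ew, rs, st$meth, st$samples)
  res <- fit$results
  gene_q <- res$q_value[res$region_id == "GENE01:Body"]
  isl_q <- res$q_value[res$region_id == "chr1:100000-100500:N_Shore"]
  expect_true(res$significant[res$region_id == "GENE01:Body"])
  expect_true(res$significant[res$region_id == "chr1:100000-100500:N_Shore"])
  expect_equal(gene_q, isl_q)  # identical probe sets give identical tests
})

test_that("regions dropping below min_probes after failed probes are audited", {
  st <- simulate_study(simulation_config(n_families = 40, n_regions = 3,
                                         probes_per_region = 2,
                                         n_null_singletons = 0, seed = 21))
  mvals <- beta_to_m(st$meth)
  mvals[1, ] <- 0  # kill one probe of region 1
  ew <- run_ewas(mvals, st$samples, model = "ols", manifest = st$manifest)
  rs <- attach_regions(build_gene_regions(st$manifest), NULL)
  fit <- globalp(ew, rs, mvals, st$samples, assay = "mvalue")
  expect_equal(fit$audit$skipped, "GENE01:Body")
  expect_equal(nrow(fit$results), 2L)
})

test_that("the fit object exposes the standard methods", {
  st <- simulate_study(simulation_config(n_families = 50, n_regions = 4,
                                         probes_per_region = 3, seed = 61))
  ew <- run_ewas(beta_to_m(st$meth), st$samples, model = "ols",
                 manifest = st$manifest)
  rs <- attach_regions(build_gene_regions(st$manifest), NULL)
  fit <- globalp(ew, rs, st$meth, st$samples)
  expect_s3_class(fit, "globalp")
  expect_output(print(fit), "regions tested")
  expect_output(print(summary(fit)), "Top regions")
  expect_equal(nrow(as.data.frame(fit)), 4L)
  expect_named(coef(fit), fit$results$region_id)
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
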