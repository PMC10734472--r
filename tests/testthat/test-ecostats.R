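test_that("signed-rank anchors: single minimal discordant pair among 8", {
  # differences with |d| ranks 1..8, only the smallest negative
  w <- wilcoxon_signed_rank(c(-1, 2, 3, 4, 5, 6, 7, 8))
  expect_equal(w$statistic, 1)
  expect_equal(w$p_value, 0.015625)        # exactly 1/64
  expect_equal(format(round(w$p_value, 3)), "0.016")

  w0 <- wilcoxon_signed_rank(1:8)
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p_value, 0.0078125)      # 2/256, by enumeration

  wz <- wilcoxon_signed_rank(c(1, 2), c(1, 2))
  expect_true(is.na(wz$statistic))
  expect_equal(wz$status, "all differences zero")
})

test_that("exact signed-rank p equals literal 2^n enumeration", {
  set.seed(17)
  for (i in 1:60) {
    n <- sample(2:10, 1)
    d <- round(stats::rnorm(n), 2)
    d[d == 0] <- 0.01
    # induce ties in |d| half the time
    if (i %% 2 == 0) d[1:2] <- c(0.5, -0.5)
    w <- wilcoxon_signed_rank(d)
    expect_equal(w$p_value, brute_wilcoxon(d), info = paste(d, collapse = ","))
  }
})

test_that("exact signed-rank p agrees with the reference implementation", {
  set.seed(18)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    d <- stats::rnorm(n)
    ours <- wilcoxon_signed_rank(d)
    ref <- stats::wilcox.test(d, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Spearman anchors, exact enumeration, and degenerate inputs", {
  expect_equal(spearman_correlation(1:6, (1:6) * 3)$rho, 1)
  expect_equal(spearman_correlation(1:6, rev(1:6))$rho, -1)
  set.seed(19)
  for (i in 1:15) {
    x <- stats::rnorm(5); y <- stats::rnorm(5)
    ours <- spearman_correlation(x, y)
    expect_equal(ours$p_value, brute_spearman_p(x, y))
  }
  # reference implementation (no ties, exact AS89 path)
  for (i in 1:10) {
    x <- sample(100, 8); y <- sample(100, 8)
    ours <- spearman_correlation(x, y)
    ref <- stats::cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(ours$rho, unname(ref$estimate))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  }
  z <- spearman_correlation(rep(1, 5), 1:5)
  expect_true(is.na(z$rho))
  expect_equal(z$status, "zero variance")
  expect_error(spearman_correlation(1:2, 1:2), "at least 3")
  # large-n t-approximation stays close to the reference
  set.seed(20)
  x <- stats::rnorm(40); y <- x + stats::rnorm(40)
  ours <- spearman_correlation(x, y)
  ref <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(ours$rho, unname(ref$estimate))
  expect_equal(ours$p_value, ref$p.value, tolerance = 0.05)
})

test_that("Kruskal-Wallis matches hand computation and the reference", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$statistic, 27 / 7, tolerance = 1e-12)  # rank-sum arithmetic
  # identical groups of identical values: degenerate
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2)))$status, "degenerate")
  # copies of the same values across k groups: H = 0
  kw0 <- kruskal_wallis(list(c(1, 5, 9), c(1, 5, 9), c(1, 5, 9)))
  expect_equal(kw0$statistic, 0)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
  expect_error(kruskal_wallis(list(numeric(0), 1:3)), "observation")
  set.seed(21)
  for (i in 1:10) {
    g <- list(stats::rnorm(6), stats::rnorm(5), round(stats::rnorm(7), 1))
    ours <- kruskal_wallis(g)
    ref <- stats::kruskal.test(g)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("p-values and statistics stay in range", {
  set.seed(22)
  for (i in 1:30) {
    d <- stats::rnorm(sample(3:30, 1))
    w <- wilcoxon_signed_rank(d)
    expect_true(w$p_value >= 0 && w$p_value <= 1)
    x <- stats::rnorm(sample(4:30, 1)); y <- stats::rnorm(length(x))
    s <- spearman_correlation(x, y)
    expect_true(s$rho >= -1 && s$rho <= 1)
    expect_true(s$p_value >= 0 && s$p_value <= 1)
    k <- kruskal_wallis(list(stats::rnorm(4), stats::rnorm(4)))
    expect_gte(k$statistic, 0)
  }
})

test_that("island prevalence arithmetic", {
  expect_identical(island_prevalence(24, 150), 16)
  expect_equal(island_prevalence(0, 10), 0)
  expect_error(island_prevalence(11, 10), "exceeds")
})

test_that("version abundance concentrates mass on the source version", {
  sp <- small_population()
  pop <- sp$pop; sim <- sp$sim
  cass <- pop$truth$cassettes[["fGIp-1"]]
  vs <- c(A = cass$A, E = cass$E)
  phos <- setNames(pop$truth$samples$phosphate_uM,
                   pop$truth$samples$sample_id)
  ab <- version_abundance(sim$reads, vs,
                          metagenome_size = sim$metagenome_size,
                          phosphate_uM = phos)
  # high-phosphate sample is dominated by the gene-poor version A
  expect_gt(ab["A", "S1"], 10 * ab["E", "S1"])
  expect_gt(ab["E", "S3"], 10 * ab["A", "S3"])
  rel <- version_abundance(sim$reads, vs,
                           metagenome_size = sim$metagenome_size,
                           relative = TRUE)
  expect_equal(unname(colSums(rel)), rep(1, 3))
  # relative shares track the truth strain abundances within sampling error
  truth_share <- pop$truth$abundances["sp1_s1", ]
  expect_lt(max(abs(rel["A", ] - truth_share)), 0.05)
  # a read-free sample gives a zero column
  ab0 <- version_abundance(list(S0 = character(0)), vs,
                           metagenome_size = c(S0 = 1e6))
  expect_true(all(ab0 == 0))
  expect_error(version_abundance(sim$reads, c(A = "")), "non-empty")
})

test_that("environment correlation recovers the simulated gradient", {
  sp <- small_population()
  pop <- sp$pop; sim <- sp$sim
  cass <- pop$truth$cassettes[["fGIp-1"]]
  phos <- setNames(pop$truth$samples$phosphate_uM,
                   pop$truth$samples$sample_id)
  ab <- version_abundance(sim$reads, c(A = cass$A, E = cass$E),
                          metagenome_size = sim$metagenome_size,
                          phosphate_uM = phos)
  corr <- correlate_versions_with_environment(ab)
  rho <- setNames(corr$per_version$rho, corr$per_version$version)
  expect_gt(rho[["A"]], 0)   # gene-poor version rises with phosphate
  expect_lt(rho[["E"]], 0)   # gene-rich version falls
  # constant phosphate: zero variance, NA for every version
  const <- correlate_versions_with_environment(
    ab, setNames(rep(0.1, 3), colnames(ab)))
  expect_true(all(is.na(const$per_version$rho)))
  # single-sample detection: rho NA but version still in the KW groups
  M <- rbind(A = c(5, 4, 3), B = c(0, 0, 2))
  colnames(M) <- colnames(ab)
  one <- correlate_versions_with_environment(M, phos)
  expect_true(is.na(one$per_version$rho[one$per_version$version == "B"]))
  expect_false(is.null(one$kruskal))
  Mz <- M * 0
  expect_error(correlate_versions_with_environment(Mz, phos), "no version")
})
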