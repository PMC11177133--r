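test_that("double-genotype tabulation matches a per-sample loop and handles missingness", {
  # identity pairing puts one sample in each diagonal cell
  t1 <- tabulate_double_genotypes(c(0L, 1L, 2L), c(0L, 1L, 2L))
  expect_equal(as.vector(t(unclass(t1))), c(1, 0, 0, 0, 1, 0, 0, 0, 1))

  # samples missing at either site are excluded pairwise
  t2 <- tabulate_double_genotypes(c(0L, NA), c(0L, 0L))
  expect_equal(sum(t2), 1)
  expect_equal(unclass(t2)[1, 1], 1)

  expect_error(tabulate_double_genotypes(c(0L, 1L), 0L),
               class = "svld_alignment_error")
  expect_error(tabulate_double_genotypes(NA_integer_, 0L),
               class = "svld_no_data_error")

  # vectorized build equals a naive per-sample loop on random vectors
  set.seed(41)
  for (rep in 1:5) {
    sv <- sample(c(0:2, NA), 200, replace = TRUE)
    snp <- sample(c(0:2, NA), 200, replace = TRUE)
    loop <- matrix(0, 3, 3)
    for (s in seq_along(sv)) {
      if (!is.na(sv[s]) && !is.na(snp[s])) {
        loop[sv[s] + 1, snp[s] + 1] <- loop[sv[s] + 1, snp[s] + 1] + 1
      }
    }
    expect_equal(unclass(tabulate_double_genotypes(sv, snp)),
                 unclass(geno_table(loop)))
  }
})

test_that("dosage moments equal the expanded-pair averages", {
  # single-cell tables pin the coding
  m1 <- dosage_moments(geno_table(c(5, 0, 0, 0, 0, 0, 0, 0, 0)))
  expect_equal(unlist(m1[, 1:5]), c(mu_xy = 1, mu_x = 1, mu_y = 1,
                                    mu_x2 = 1, mu_y2 = 1))
  m5 <- dosage_moments(geno_table(c(0, 0, 0, 0, 7, 0, 0, 0, 0)))
  expect_equal(unlist(m5[, 1:5]), c(mu_xy = 4, mu_x = 2, mu_y = 2,
                                    mu_x2 = 4, mu_y2 = 4))

  # reference table: moments frozen from the dosage-expansion oracle
  m <- dosage_moments(geno_table(c(10, 5, 1, 4, 20, 4, 1, 5, 10)))
  expect_equal(m$mu_xy, 4.3)
  expect_equal(m$mu_x, 2)
  expect_equal(m$mu_y, 2)
  expect_equal(m$mu_x2, 272 / 60)
  expect_equal(m$mu_y2, 4.5)
  expect_equal(m$n, 60)
})

test_that("g2 reproduces exact limits and the frozen oracle value", {
  # perfectly coupled dosages
  expect_identical(g_squared(geno_table(c(2, 0, 0, 0, 0, 0, 0, 0, 2)))$g_squared, 1)
  # independence factorization (outer product of marginals)
  expect_lt(g_squared(geno_table(c(1, 2, 1, 2, 4, 2, 1, 2, 1)))$g_squared, 1e-12)
  # frozen regression value from the expansion oracle
  res <- g_squared(geno_table(c(10, 5, 1, 4, 20, 4, 1, 5, 10)))
  expect_equal(res$g_squared, 0.3375, tolerance = 1e-12)
  expect_equal(res$g_squared, dosage_pearson_oracle(c(10, 5, 1, 4, 20, 4, 1, 5, 10)),
               tolerance = 1e-12)
  expect_false(res$degenerate)
  expect_equal(res$n_samples, 60)
})

test_that("monomorphic sites are flagged degenerate, not errors", {
  res <- g_squared(geno_table(c(3, 2, 1, 0, 0, 0, 0, 0, 0))) # SV fixed hom-ref
  expect_true(res$degenerate)
  expect_true(is.na(res$g_squared))
  expect_true(is.na(res$p_value))
  expect_equal(res$n_samples, 6)
  expect_error(dosage_pearson_oracle(c(3, 2, 1, 0, 0, 0, 0, 0, 0)),
               class = "svld_degenerate_error")
})

test_that("real-valued (expected) tables are accepted by the moment formulas", {
  x <- c(2.5, 1.25, 0.5, 1, 3.75, 1, 0.5, 1.25, 2.5)
  res <- g_squared(geno_table(x))
  expect_false(res$degenerate)
  expect_gte(res$g_squared, 0)
  expect_lte(res$g_squared, 1)
  # scaling all cells leaves g2 unchanged (moments are ratios)
  expect_equal(g_squared(geno_table(10 * x))$g_squared, res$g_squared,
               tolerance = 1e-12)
})

test_that("the 1/2/3 coding and the 0/1/2 dosage convention give identical g2", {
  set.seed(11)
  for (rep in 1:20) {
    x <- rand_table()
    X <- rep(rep(1:3, each = 3), times = x)
    Y <- rep(rep(1:3, times = 3), times = x)
    expect_equal(g_squared(geno_table(x))$g_squared,
                 cor(X - 1, Y - 1)^2, tolerance = 1e-10)
  }
})

test_that("LD p-value follows the chi-square(1) tail and is monotone", {
  expect_equal(ld_pvalue(0, 32), 1)
  # frozen value, cross-checked against the erfc identity for 1 df
  expect_equal(ld_pvalue(1, 32), 1.5417257900280023e-08, tolerance = 1e-10)
  expect_equal(ld_pvalue(1, 32), 2 * pnorm(sqrt(32), lower.tail = FALSE),
               tolerance = 1e-12)
  # decreasing in N at fixed g2, decreasing in g2 at fixed N
  expect_lt(ld_pvalue(0.5, 64), ld_pvalue(0.5, 32))
  g <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(ld_pvalue(g, 32)) < 0))
  expect_true(is.na(ld_pvalue(NA_real_, 32)))
  expect_error(ld_pvalue(1.5, 32), class = "svld_internal_error")
})

test_that("g2 is invariant under transposition and allele relabeling", {
  set.seed(12)
  for (rep in 1:50) {
    x <- rand_table()
    g <- g_squared(geno_table(x))$g_squared
    m <- matrix(x, 3, byrow = TRUE)
    expect_equal(g_squared(geno_table(t(m)))$g_squared, g, tolerance = 1e-12)
    expect_equal(g_squared(geno_table(m[3:1, ]))$g_squared, g, tolerance = 1e-12)
    expect_equal(g_squared(geno_table(m[, 3:1]))$g_squared, g, tolerance = 1e-12)
  }
})
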