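test_that("generating parameters are validated", {
  expect_error(generating_params(a = 0.5, e = 0.4), "equal 1")
  expect_error(generating_params(a = 1, c = 0, e = 0), "e must be > 0")
  expect_silent(generating_params(a = 1, c = 0, e = 0,
                                  allow_degenerate = TRUE))
  badR <- matrix(c(1, 1.5, 1.5, 1), 2)
  expect_error(generating_params(a = c(.5, .5), e = c(.5, .5), rA = badR),
               "rA")
})

test_that("same seed reproduces the table; different seeds differ", {
  t1 <- simulate_twins(study_params(seed = 5))
  t2 <- simulate_twins(study_params(seed = 5))
  t3 <- simulate_twins(study_params(seed = 6))
  expect_identical(t1, t2)
  expect_false(isTRUE(all.equal(t1$trait1_1, t3$trait1_1)))
})

test_that("perfect heritability makes MZ co-twins identical, rDZ near 1/2", {
  pp <- generating_params(a = 1, c = 0, e = 0, nMZ = 20000, nDZ = 20000,
                          seed = 21, allow_degenerate = TRUE)
  tab <- simulate_twins(pp, traits = "y")
  mz <- tab$zygosity == "MZ"
  expect_equal(tab$y_1[mz], tab$y_2[mz], tolerance = 1e-12)
  se <- (1 - 0.5^2) / sqrt(20000)
  expect_lt(abs(stats::cor(tab$y_1[!mz], tab$y_2[!mz]) - 0.5), 3 * se)
})

test_that("empirical twin correlations match the a/c/e closed forms", {
  pp <- generating_params(a = 0.4, c = 0.2, e = 0.4,
                          nMZ = 50000, nDZ = 50000, seed = 22)
  tab <- simulate_twins(pp, traits = "y")
  mz <- tab$zygosity == "MZ"
  expect_lt(abs(stats::cor(tab$y_1[mz], tab$y_2[mz]) - 0.6), 0.01)
  expect_lt(abs(stats::cor(tab$y_1[!mz], tab$y_2[!mz]) - 0.4), 0.01)
})

test_that("analytic correlations obey the closed forms and identities", {
  # pure noise: everything uncorrelated
  pp0 <- generating_params(a = c(0, 0), c = c(0, 0), e = c(1, 1))
  ec0 <- expected_correlations(pp0)
  expect_equal(ec0$rMZ, c(0, 0))
  expect_equal(ec0$rDZ, c(0, 0))
  expect_equal(ec0$ctct_MZ[1, 2], 0)

  # two-trait arithmetic example
  rA <- matrix(c(1, .22, .22, 1), 2); rE <- matrix(c(1, .15, .15, 1), 2)
  pp <- generating_params(a = c(.34, .42), e = c(.66, .58),
                          rA = rA, rE = rE)
  ec <- expected_correlations(pp)
  expect_equal(ec$rph[1, 2],
               .22 * sqrt(.34 * .42) + .15 * sqrt(.66 * .58),
               tolerance = 1e-12)
  expect_equal(round(ec$rph[1, 2], 2), 0.18)

  # CTCT MZ - CTCT DZ = rA_jk sqrt(a_j a_k) / 2 for random valid params
  set.seed(31)
  for (i in 1:20) {
    a <- stats::runif(2, 0, 0.6); c <- stats::runif(2, 0, 0.3)
    r <- stats::runif(3, -0.8, 0.8)
    pp <- generating_params(a = a, c = c, e = 1 - a - c,
                            rA = matrix(c(1, r[1], r[1], 1), 2),
                            rC = matrix(c(1, r[2], r[2], 1), 2),
                            rE = matrix(c(1, r[3], r[3], 1), 2))
    ec <- expected_correlations(pp)
    expect_equal(ec$ctct_MZ[1, 2] - ec$ctct_DZ[1, 2],
                 0.5 * r[1] * sqrt(prod(a)), tolerance = 1e-12)
  }
})

test_that("study-scale simulation reproduces the implied trivariate rph", {
  tab <- simulate_twins(study_params(seed = 23, nMZ = 4290, nDZ = 7070))
  r13 <- stats::cor(c(tab$trait1_1, tab$trait1_2),
                    c(tab$trait3_1, tab$trait3_2))
  ec <- expected_correlations(study_params())
  expect_lt(abs(ec$rph[1, 3] - 0.233), 0.005)
  expect_lt(abs(r13 - ec$rph[1, 3]), 0.03)
})

test_that("simulated covariance converges to the model-implied covariance", {
  # sample size chosen so 0.01 is >3 Monte-Carlo SEs for variance entries
  pp <- generating_params(a = c(.34, .42, .57), e = c(.66, .58, .43),
                          rA = truth_rA, rE = truth_rE,
                          nMZ = 400000, nDZ = 400000, seed = 24)
  tab <- simulate_twins(pp)
  comp <- component_matrices(
    A = truth_rA * sqrt(outer(truth_a, truth_a)),
    E = truth_rE * sqrt(outer(truth_e, truth_e)))
  cols <- c(paste0("trait", 1:3, "_1"), paste0("trait", 1:3, "_2"))
  for (z in c("MZ", "DZ")) {
    emp <- stats::cov(as.matrix(tab[tab$zygosity == z, cols]))
    expect_lt(max(abs(emp - expected_covariance(comp, z))), 0.01)
  }
})

test_that("masking hits the requested missing rate", {
  pp <- generating_params(a = 0.4, e = 0.6, missing_rate = 0.07,
                          nMZ = 5000, nDZ = 5000, seed = 25)
  tab <- suppressWarnings(simulate_twins(pp, traits = "y"))
  # count masked values against the original 2 x 10000 draws, including
  # the all-missing pairs dropped at construction
  n <- 2 * 10000
  n_obs <- sum(!is.na(c(tab$y_1, tab$y_2)))
  frac <- (n - n_obs) / n
  se <- sqrt(0.07 * 0.93 / n)
  expect_lt(abs(frac - 0.07), 3 * se)
})
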