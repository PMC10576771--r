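test_that("expected covariance has the MZ/DZ block structure", {
  # pure E: both zygosities are white noise
  comp <- component_matrices(E = diag(2))
  expect_equal(expected_covariance(comp, "MZ"), diag(4))
  expect_equal(expected_covariance(comp, "DZ"), diag(4))

  # one standardized trait with a = 0.34
  comp <- component_matrices(A = matrix(0.34), E = matrix(0.66))
  expect_equal(expected_covariance(comp, "MZ"),
               matrix(c(1, .34, .34, 1), 2), tolerance = 1e-12)
  expect_equal(expected_covariance(comp, "DZ"),
               matrix(c(1, .17, .17, 1), 2), tolerance = 1e-12)

  # cross-block identity MZ - DZ = A/2 for random components
  set.seed(41)
  for (i in 1:10) {
    p <- sample(2:4, 1)
    comp <- component_matrices(A = random_psd(p), C = random_psd(p),
                               E = random_psd(p))
    d <- expected_covariance(comp, "MZ") - expected_covariance(comp, "DZ")
    expect_equal(d[seq_len(p), p + seq_len(p)], 0.5 * comp$A,
                 tolerance = 1e-12)
    expect_equal(d[seq_len(p), seq_len(p)], matrix(0, p, p),
                 tolerance = 1e-12)
  }
})

test_that("FIML -2LL matches closed forms and the per-pair oracle", {
  # single complete standard-normal MZ pair at the origin: 2 log(2 pi)
  tab1 <- twin_pair_table(data.frame(
    family_id = "f", zygosity = "MZ", sex1 = "female", sex2 = "female",
    y_1 = 0, y_2 = 0), "y")
  comp1 <- component_matrices(E = matrix(1))
  expect_equal(fiml_minus2ll(comp1, tab1), 2 * log(2 * pi),
               tolerance = 1e-12)

  # complete data: equals the two-group moment-based closed form
  tab <- simulate_twins(study_params(seed = 42, nMZ = 80, nDZ = 120))
  comp <- component_matrices(
    A = truth_rA * sqrt(outer(truth_a, truth_a)),
    E = truth_rE * sqrt(outer(truth_e, truth_e)))
  expect_equal(fiml_minus2ll(comp, tab), moment_m2ll(comp, tab),
               tolerance = 1e-8)
  expect_equal(fiml_minus2ll(comp, tab), naive_m2ll(comp, tab),
               tolerance = 1e-8)
})

test_that("masking a value marginalizes the likelihood exactly", {
  tab <- toy_table()
  comp <- component_matrices(A = matrix(0.5), E = matrix(0.7),
                             means = 0.1)
  masked <- tab
  masked$y_2[2] <- NA
  expect_equal(fiml_minus2ll(comp, masked), naive_m2ll(comp, masked),
               tolerance = 1e-10)
  # the change from masking equals the difference of closed-form terms
  expect_equal(fiml_minus2ll(comp, tab) - fiml_minus2ll(comp, masked),
               naive_m2ll(comp, tab) - naive_m2ll(comp, masked),
               tolerance = 1e-10)
  # all-missing rows contribute nothing
  gone <- tab
  gone$y_1[3] <- NA; gone$y_2[3] <- NA
  expect_warning(kept <- twin_pair_table(as.data.frame(gone), "y"),
                 "all trait values missing")
  expect_equal(fiml_minus2ll(comp, suppressWarnings(
    twin_pair_table(as.data.frame(gone), "y", drop_empty = FALSE))),
    fiml_minus2ll(comp, kept), tolerance = 1e-12)
})

test_that("likelihood is invariant to pair order and twin order", {
  tab <- simulate_twins(study_params(seed = 43, nMZ = 60, nDZ = 90))
  comp <- component_matrices(
    A = truth_rA * sqrt(outer(truth_a, truth_a)),
    E = truth_rE * sqrt(outer(truth_e, truth_e)))
  base <- fiml_minus2ll(comp, tab)

  perm <- twin_pair_table(as.data.frame(tab)[sample(nrow(tab)), ],
                          attr(tab, "traits"))
  expect_equal(fiml_minus2ll(comp, perm), base, tolerance = 1e-8)

  sw <- as.data.frame(tab)
  for (tr in attr(tab, "traits")) {
    tmp <- sw[[paste0(tr, "_1")]]
    sw[[paste0(tr, "_1")]] <- sw[[paste0(tr, "_2")]]
    sw[[paste0(tr, "_2")]] <- tmp
  }
  expect_equal(fiml_minus2ll(comp, twin_pair_table(sw, attr(tab, "traits"))),
               base, tolerance = 1e-8)
})

test_that("degrees of freedom equal observed values minus free parameters", {
  tab <- simulate_twins(study_params(seed = 44, nMZ = 30, nDZ = 40))
  masked <- as.data.frame(tab)
  masked$trait1_1[1:5] <- NA
  tab2 <- twin_pair_table(masked, attr(tab, "traits"))
  n_obs <- sum(!is.na(as.matrix(
    tab2[, c(paste0("trait", 1:3, "_1"), paste0("trait", 1:3, "_2"))])))
  fit <- fit_ace(tab2, "AE", starts = 1)
  expect_identical(fit$df, n_obs - (3L + 6L + 6L))
  expect_identical(fit$n_free_params, 15L)
  fit_e <- fit_ace(tab2, "E", starts = 1)
  expect_identical(fit_e$df, n_obs - (3L + 6L))
})

test_that("null heritability is recovered near zero", {
  pp <- generating_params(a = 0, c = 0, e = 1, nMZ = 5000, nDZ = 5000,
                          seed = 45)
  tab <- simulate_twins(pp, traits = "y")
  fit <- fit_ace(tab, "AE", starts = 2)
  std <- standardize_components(fit$estimates)
  expect_lt(abs(std$std_a), 0.05)
})

test_that("nested models obey likelihood dominance", {
  tab <- simulate_twins(study_params(seed = 46, nMZ = 200, nDZ = 300))
  sat <- fit_constrained_saturated(tab)
  fits <- lapply(c("ACE", "AE", "CE", "E"), function(m)
    fit_ace(tab, m, starts = 3, seed = 2))
  names(fits) <- c("ACE", "AE", "CE", "E")
  m2 <- vapply(fits, `[[`, numeric(1), "minus2ll")
  tol <- 1e-6
  expect_lte(sat$minus2ll, m2[["ACE"]] + tol)
  expect_lte(m2[["ACE"]], m2[["AE"]] + tol)
  expect_lte(m2[["AE"]], m2[["E"]] + tol)
  expect_lte(m2[["ACE"]], m2[["CE"]] + tol)
  expect_lte(m2[["CE"]], m2[["E"]] + tol)
  # Falconer direction sanity band for the single-trait projection
  mz <- tab$zygosity == "MZ"
  rmz <- stats::cor(tab$trait1_1[mz], tab$trait1_2[mz])
  rdz <- stats::cor(tab$trait1_1[!mz], tab$trait1_2[!mz])
  std <- standardize_components(fits[["AE"]]$estimates)
  expect_gt(std$std_a[1], 0)
  expect_lt(std$std_a[1], 2 * (rmz - rdz) + 0.1 + 0.25)
})

test_that("models needing the MZ/DZ contrast refuse single-group data", {
  tab <- simulate_twins(study_params(seed = 47, nMZ = 50, nDZ = 50))
  mzonly <- twin_pair_table(as.data.frame(tab)[tab$zygosity == "MZ", ],
                            attr(tab, "traits"))
  expect_error(fit_ace(mzonly, "AE"), "MZ/DZ contrast")
})

test_that("profile bounds solve the quadratic toy exactly", {
  b <- twinace:::profile_bounds(function(t) (t - 2)^2, est = 2,
                                min_val = 0, crit = stats::qchisq(.95, 1))
  expect_equal(unname(b), 2 + c(-1, 1) * sqrt(stats::qchisq(.95, 1)),
               tolerance = 1e-4)
})

test_that("profile CI endpoints agree with a dense grid search", {
  pp <- generating_params(a = 0.5, e = 0.5, nMZ = 150, nDZ = 250, seed = 48)
  tab <- simulate_twins(pp, traits = "y")
  fit <- fit_ace(tab, "AE", starts = 1)
  ci <- profile_ci(fit, list(type = "std", comp = "A", trait = 1))

  # independent grid evaluation of the profiled likelihood
  spec <- model_spec("AE")
  obj <- function(th) fiml_minus2ll(
    component_matrices(A = matrix(th[2]), E = matrix(th[3]),
                       means = th[1]), fit$fd)
  prof <- function(t) {
    # std_a fixed at t: A = t/(1-t) * E
    stats::nlminb(c(0, 0.5), function(r)
      obj(c(r[1], t / (1 - t) * r[2], r[2])))$objective
  }
  target <- fit$minus2ll + stats::qchisq(0.95, 1)
  for (side in 1:2) {
    g <- seq(ci[side] - 0.004, ci[side] + 0.004, by = 5e-4)
    vals <- vapply(g, prof, numeric(1))
    crossing <- g[which.min(abs(vals - target))]
    expect_lt(abs(crossing - ci[side]), 1e-3)
  }
})
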