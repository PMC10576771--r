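test_that("empty input yields an empty table with the right traits", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("family_id,zygosity,sex1,sex2,y_1,y_2", f)
  tab <- read_twin_csv(f, "y")
  expect_s3_class(tab, "twin_pair_table")
  expect_identical(nrow(tab), 0L)
  expect_identical(n_traits(tab), 1L)
})

test_that("read/write round trip is lossless, including missingness", {
  pp <- generating_params(a = c(0.4, 0.3), e = c(0.6, 0.7),
                          rA = matrix(c(1, .5, .5, 1), 2),
                          rE = matrix(c(1, .2, .2, 1), 2),
                          missing_rate = 0.1, nMZ = 25, nDZ = 25, seed = 7)
  tab <- simulate_twins(pp, traits = c("u", "v"))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_twin_csv(tab, f1)
  back <- read_twin_csv(f1, c("u", "v"))
  for (col in c("u_1", "u_2", "v_1", "v_2"))
    expect_identical(back[[col]], tab[[col]])
  expect_identical(back$zygosity, tab$zygosity)
  # and the file itself reproduces byte for byte
  write_twin_csv(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a study-sized fixture loads with all pairs and writes n+1 lines", {
  tab <- simulate_twins(study_params(seed = 3))
  expect_identical(nrow(tab), 1136L)
  expect_identical(sum(tab$zygosity == "MZ"), 429L)
  expect_identical(sum(tab$zygosity == "DZ"), 707L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_twin_csv(tab, f)
  expect_identical(length(readLines(f)), 1137L)
})

test_that("loader rejects malformed input with informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("family_id,zygosity,sex1,sex2,y_1",
               "f1,MZ,female,female,1.0"), f)
  expect_error(read_twin_csv(f, "y"), "y_2")

  writeLines(c("family_id,zygosity,sex1,sex2,y_1,y_2",
               "f1,XX,female,female,1.0,2.0",
               "f2,MZ,female,female,1.0,2.0"), f)
  expect_warning(tab <- read_twin_csv(f, "y"), "zygosity")
  expect_identical(nrow(tab), 1L)

  writeLines(c("family_id,zygosity,sex1,sex2,y_1,y_2",
               "f1,MZ,female,female,,",
               "f2,MZ,female,female,1.0,2.0"), f)
  expect_warning(tab <- read_twin_csv(f, "y"), "all trait values missing")
  expect_identical(nrow(tab), 1L)
})

test_that("residualization removes the sex effect and shrinks variance", {
  pp <- generating_params(a = 0.4, e = 0.6, sex_effect = 0.5,
                          nMZ = 400, nDZ = 600, seed = 11)
  tab <- simulate_twins(pp, traits = "y")
  res <- residualize(tab)
  # post-residualization regression of the trait on sex has slope ~ 0
  y <- c(res$y_1, res$y_2)
  s <- c(as.integer(tab$sex1), as.integer(tab$sex2)) - 1L
  expect_lt(abs(stats::coef(stats::lm(y ~ s))[2]), 1e-10)
  expect_lte(stats::var(c(res$y_1, res$y_2)),
             stats::var(c(tab$y_1, tab$y_2)))
})

test_that("with no sex effect residualization is near-centering", {
  pp <- generating_params(a = 0.4, e = 0.6, means = 5,
                          nMZ = 8000, nDZ = 8000, seed = 12)
  tab <- simulate_twins(pp, traits = "y")
  res <- residualize(tab)
  centered <- c(tab$y_1, tab$y_2) - mean(c(tab$y_1, tab$y_2))
  expect_lt(max(abs(c(res$y_1, res$y_2) - centered)), 0.05)
})

test_that("residualization is idempotent and commutes with row order", {
  pp <- generating_params(a = c(0.3, 0.5), e = c(0.7, 0.5),
                          sex_effect = c(0.4, -0.2),
                          nMZ = 150, nDZ = 150, seed = 13)
  tab <- simulate_twins(pp, traits = c("u", "v"))
  r1 <- residualize(tab)
  r2 <- residualize(r1)
  for (col in c("u_1", "u_2", "v_1", "v_2"))
    expect_equal(r2[[col]], r1[[col]], tolerance = 1e-10)

  perm <- sample(nrow(tab))
  rp <- residualize(twin_pair_table(as.data.frame(tab)[perm, ],
                                    c("u", "v")))
  for (col in c("u_1", "u_2", "v_1", "v_2"))
    expect_equal(rp[[col]], r1[[col]][perm], tolerance = 1e-12)
})

test_that("missing sex masks the trait; constant sex is an error", {
  df <- data.frame(family_id = c("f1", "f2", "f3", "f4"),
                   zygosity = c("MZ", "MZ", "DZ", "DZ"),
                   sex1 = c(NA, "male", "female", "male"),
                   sex2 = c("female", "male", "female", "female"),
                   y_1 = c(1, 2, 3, 4), y_2 = c(2, 1, 4, 3))
  tab <- twin_pair_table(df, "y")
  expect_warning(res <- residualize(tab), "covariate missing")
  expect_true(is.na(res$y_1[1]))
  expect_false(anyNA(res$y_2))

  df$sex1 <- "female"; df$sex2 <- "female"
  expect_error(residualize(twin_pair_table(df, "y")), "constant")
})
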