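test_that("species calls follow the dDDH-first, ANI-fallback criteria", {
  expect_equal(classify_species(dDDH = 46), "different")
  expect_equal(classify_species(dDDH = 25), "different")
  expect_equal(classify_species(dDDH = 70), "same")       # boundary inclusive
  expect_equal(classify_species(ANI = 92.3), "different")
  expect_equal(classify_species(ANI = 95), "same")
  expect_equal(classify_species(), "undetermined")
  # dDDH takes precedence over ANI when both are present
  expect_equal(classify_species(dDDH = 30, ANI = 99), "different")
})

test_that("species calls are monotone in dDDH", {
  calls <- vapply(seq(0, 100, by = 5), function(d) classify_species(dDDH = d),
                  character(1))
  expect_false(is.unsorted(calls == "same"))
})

test_that("regression handles collinear and zero-correlation inputs", {
  df <- data.frame(pair_id = letters[1:5], x = 0:4, y = 2 * (0:4) + 1)
  r <- regress_pairs(df, "x", "y")
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)
  df0 <- data.frame(x = c(0, 1, 2), y = c(0, 1, 0))
  expect_equal(regress_pairs(df0, "x", "y")$r_squared, 0)
  expect_error(regress_pairs(df0[1:2, ], "x", "y"),
               class = "bgcrep_insufficient_data")
})

test_that("regression agrees with the closed-form least-squares solution", {
  set.seed(33)
  ddh <- runif(8, 20, 90)
  rc <- 0.9 * ddh + rnorm(8, sd = 5)
  df <- data.frame(dDDH = ddh, RC = rc)
  r <- regress_pairs(df, "dDDH", "RC")
  # independent closed-form OLS
  sxy <- sum((ddh - mean(ddh)) * (rc - mean(rc)))
  sxx <- sum((ddh - mean(ddh))^2)
  expect_equal(r$slope, sxy / sxx)
  expect_equal(r$intercept, mean(rc) - r$slope * mean(ddh))
  expect_equal(r$r_squared, sxy^2 / (sxx * sum((rc - mean(rc))^2)))
  expect_gte(r$r_squared, 0.6)
  expect_lte(r$r_squared, 1.0)
})

test_that("r-squared is invariant to record order and affine x-rescaling", {
  set.seed(34)
  df <- data.frame(x = runif(10), y = runif(10))
  base <- regress_pairs(df, "x", "y")$r_squared
  perm <- df[sample(nrow(df)), ]
  expect_equal(regress_pairs(perm, "x", "y")$r_squared, base)
  df$x2 <- 3.7 * df$x - 12
  expect_equal(regress_pairs(df, "x2", "y")$r_squared, base)
})

test_that("pair tables load, validate and get species calls; NA is complete-case dropped", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pair_id\tsim16S\tdDDH\tANI\tRC",
               "p1\t99.93\t46\t92.3\t45",
               "p2\t99.79\t\t96\t80",
               "p3\t98.5\t22\t\t10",
               "p4\t99.0\t\t\t30",
               "p5\t98.2\t75\t\t85"), f)
  tab <- read_pair_table(f)
  expect_equal(tab$species_call, c("different", "same", "different",
                                   "undetermined", "same"))
  r <- regress_pairs(tab, "dDDH", "RC")
  expect_equal(r$n, 3)  # only p1, p3, p5 carry both dDDH and RC
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pair_id\tsim16S\tdDDH\tANI\tRC", "p1\t120\t\t\t10"), bad)
  expect_error(read_pair_table(bad), class = "bgcrep_format_error")
})

test_that("mean RC is higher within species than between, on synthetic truth", {
  # generator scenarios: same-species pairs share most clusters, different-
  # species pairs share few
  set.seed(35)
  rc_same <- vapply(1:5, function(k) {
    gp <- generate_pair(generator_config(nA = 8, nB = 8, nShared = 7,
                                         divergence = 0.05, seed = 600 + k))
    compute_rc(gp$invA, gp$invB)$RC_exact
  }, numeric(1))
  rc_diff <- vapply(1:5, function(k) {
    gp <- generate_pair(generator_config(nA = 8, nB = 8, nShared = 2,
                                         divergence = 0.05, seed = 700 + k))
    compute_rc(gp$invA, gp$invB)$RC_exact
  }, numeric(1))
  expect_gt(mean(rc_same), mean(rc_diff))
})
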