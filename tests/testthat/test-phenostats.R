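test_that("flocculation score identities hold", {
  expect_equal(as.numeric(flocculation_score(1.0, 1.0)), 0)
  expect_equal(as.numeric(flocculation_score(0, 0.8)), 1)
  expect_equal(as.numeric(flocculation_score(0.25, 1.0)), 0.75)
  expect_error(flocculation_score(0.2, 0), "od_t")
  expect_warning(s <- flocculation_score(1.2, 1.0), "clipped")
  expect_equal(as.numeric(s), 0)
  expect_true(attr(s, "flagged"))
  # monotone decreasing in od_p at fixed od_t
  sc <- as.numeric(flocculation_score(seq(0, 1, 0.1), 1.0))
  expect_true(all(diff(sc) < 0))
})

test_that("Welch t matches the closed-form oracle and is antisymmetric", {
  r <- welch_t(c(10, 11, 12), c(13, 14, 15))
  # frozen closed-form evaluation: t = -3/sqrt(2/3), df = 4
  expect_equal(r$t, -3.6742346142, tolerance = 1e-8)
  expect_equal(r$df, 4, tolerance = 1e-8)
  expect_equal(r$p, 0.0213116411, tolerance = 1e-8)
  # independent cross-check against the stock implementation
  tt <- stats::t.test(c(10, 11, 12), c(13, 14, 15))
  expect_equal(r$t, unname(tt$statistic))
  expect_equal(r$p, tt$p.value)

  swapped <- welch_t(c(13, 14, 15), c(10, 11, 12))
  expect_equal(swapped$t, -r$t)
  expect_equal(swapped$p, r$p)

  same <- welch_t(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(welch_t(1, c(1, 2)), "n >= 2")
})

test_that("Welch reduces to Student when variances and sizes match", {
  set.seed(3)
  a <- rnorm(8); b <- rnorm(8)
  r <- welch_t(a, b)
  st <- stats::t.test(a, b, var.equal = TRUE)
  # equal n: the statistics coincide; df differ unless variances equal
  expect_equal(r$t, unname(st$statistic), tolerance = 1e-12)
  b2 <- a + 1            # identical variance, shifted
  expect_equal(welch_t(a, b2)$df, 2 * length(a) - 2, tolerance = 1e-9)
})

test_that("relative expression follows 2^-ddCt with the control at 1", {
  ct <- data.frame(
    strain = rep(c("anc", "up", "down"), each = 2),
    ct_target = c(20, 20, 18, 18, 21, 21),
    ct_reference = c(15, 15, 15, 15, 15, 15))
  fold <- relative_expression(ct, control = "anc")
  expect_equal(fold$fold[fold$strain == "anc"], 1)
  expect_equal(fold$fold[fold$strain == "up"], 4)      # ddCt = -2
  expect_equal(fold$fold[fold$strain == "down"], 0.5)  # ddCt = +1
  # invariant to a constant shift of all Ct values
  ct2 <- ct; ct2$ct_target <- ct2$ct_target + 3
  ct2$ct_reference <- ct2$ct_reference + 3
  expect_equal(relative_expression(ct2, "anc")$fold, fold$fold)
  # replicates lacking the reference Ct are dropped with a warning
  ct3 <- ct; ct3$ct_reference[3] <- NA
  expect_warning(f3 <- relative_expression(ct3, "anc"), "dropped")
  expect_equal(f3$n[f3$strain == "up"], 1)
  expect_error(relative_expression(ct, "absent"), "control")
})

test_that("replicate summaries use the sample SD convention", {
  s <- score_summary(c(0.5, 0.5, 0.5))
  expect_equal(s$mean, 0.5)
  expect_equal(s$sd, 0)
  s1 <- score_summary(0.7)
  expect_true(is.na(s1$sd))
  expect_equal(s1$n, 1)
  s3 <- score_summary(c(0.2, 0.4, 0.6))
  expect_equal(s3$mean, 0.4)
  expect_equal(s3$sd, 0.2)
})

test_that("significance stars follow the figure-legend convention", {
  expect_equal(p_stars(c(0.0005, 0.005, 0.04, 0.2)),
               c("***", "**", "*", ""))
})
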