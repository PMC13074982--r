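# The six published equations and the reproduction pipelines.

test_that("frozen coefficients match the published equations verbatim", {
  m <- mp_qsar_models()
  expect_length(m, 6)
  expect_true(all(vapply(m, function(x) x$k == 4L, logical(1))))

  pe5 <- m$PE_full54
  expect_equal(pe5$intercept, 11.520)
  expect_equal(unname(pe5$coefficients),
               c(-0.090, 6.934, -4.129, 28.365))
  expect_equal(pe5$descriptors, c("AATS1m", "AATS7p", "ATSC0p", "AATSC1p"))

  pe2 <- m$PE_split43
  expect_equal(pe2$intercept, 9.879)
  expect_equal(unname(pe2$coefficients),
               c(-0.039, -0.212, -21.91, -0.638))
  expect_equal(pe2$descriptors, c("ATSC1m", "AATSC0v", "MATS1m", "BCUTw-1h"))

  expect_equal(m$POM_full54$intercept, 9.285)
  expect_equal(unname(m$POM_full54$coefficients),
               c(-0.068, 6.050, -3.229, 31.582))
  expect_equal(m$PVA_full54$intercept, 14.772)
  expect_equal(unname(m$PVA_full54$coefficients),
               c(-0.097, 6.944, -3.987, 36.499))
  expect_equal(unname(m$POM_split43$coefficients),
               c(-0.04, -0.217, -3.728, -0.482))
  expect_equal(unname(m$PVA_split43$coefficients),
               c(-0.047, -0.157, -6.006, -0.661))
})

test_that("prediction is the linear form over the descriptor vector", {
  m <- mp_qsar_models()$PE_full54
  zero <- as.data.frame(as.list(stats::setNames(rep(0, 4), m$descriptors)),
                        check.names = FALSE)
  expect_equal(predict_ead(m, zero, ad = FALSE)$ead, 11.520)

  v <- as.data.frame(as.list(stats::setNames(c(10, 0.5, -2, 0.1),
                                             m$descriptors)),
                     check.names = FALSE)
  expect_equal(predict_ead(m, v, ad = FALSE)$ead,
               11.520 + sum(c(10, 0.5, -2, 0.1) * m$coefficients))

  # linearity
  d1 <- as.data.frame(as.list(stats::setNames(rnorm(4), m$descriptors)),
                      check.names = FALSE)
  d2 <- as.data.frame(as.list(stats::setNames(rnorm(4), m$descriptors)),
                      check.names = FALSE)
  alpha <- 0.3
  mix <- alpha * d1 + (1 - alpha) * d2
  expect_equal(predict_ead(m, mix, ad = FALSE)$ead,
               alpha * predict_ead(m, d1, ad = FALSE)$ead +
                 (1 - alpha) * predict_ead(m, d2, ad = FALSE)$ead)
})

test_that("predicting from SMILES attaches applicability-domain columns", {
  m <- mp_qsar_models()$PE_full54
  p <- predict_ead(m, "c1ccccc1")
  # engine descriptors through the published PE equation land within one
  # model RMSE of the dataset's DFT value for benzene
  expect_lt(abs(p$ead - (-7.68)), 3.91)
  expect_false(p$extrapolation)
  expect_equal(p$h_star, warning_leverage(4, 54))

  empty <- predict_ead(m, character(0))
  expect_equal(nrow(empty), 0)
  expect_true(all(c("id", "ead", "h", "extrapolation") %in% names(empty)))

  bad <- data.frame(AATS1m = 1, AATS7p = 1, ATSC0p = 1)
  expect_error(predict_ead(m, bad), "AATSC1p")
})

test_that("the descriptor engine passes its published calibration anchors", {
  v <- verify_descriptor_anchors()
  expect_true(all(v$pass))
  expect_true(attr(v, "pass"))
})

test_that("full-dataset refits recover the published models closely", {
  rep <- reproduce_full_models()
  expect_named(rep$fits, c("PE", "POM", "PVA"))
  cmp <- rep$comparison
  r2 <- cmp[cmp$statistic == "r_squared", ]
  expect_true(all(abs(r2$published - r2$refit) < 0.01))
  # refit coefficients keep the published signs and magnitudes
  for (p in names(rep$fits)) {
    pub <- mp_qsar_models()[[paste0(p, "_full54")]]$coefficients
    est <- rep$fits[[p]]$coefficients[-1]
    expect_equal(sign(unname(est)), sign(unname(pub)))
    expect_true(all(abs(est - pub) < pmax(0.5 * abs(pub), 0.05)))
  }
  # every AD report covers the full dataset
  expect_true(all(vapply(rep$ad, nrow, integer(1)) == 54))
})

test_that("split refits enforce 43/11 and report per-seed statistics", {
  rep <- reproduce_split_models(seeds = c(2, 5))
  expect_equal(nrow(rep$stats), 6)   # 2 seeds x 3 polymers
  expect_true(all(rep$stats$r_squared > 0.8))
  expect_true(all(c("q2_loo", "q2_ext", "rmse_v") %in% names(rep$stats)))
  # same seed twice gives identical statistics
  again <- reproduce_split_models(seeds = c(2, 5))
  expect_equal(rep$stats, again$stats)
})
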