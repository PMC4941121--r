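mixing_series <- c(8, 4, 2, 1, 0.5, 0.25, 0.125)

test_that("the canonical mixing series gives symmetric log2 design points", {
  expect_equal(log2(mixing_series), c(3, 2, 1, 0, -1, -2, -3))
})

test_that("calibration fitting recovers noiseless parameters exactly", {
  pts <- data.frame(mix_ratio = mixing_series,
                    log2_intensity_ratio = log2(mixing_series))
  ident <- fit_calibration(pts)
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0)
  expect_equal(ident$r_squared, 1)

  pts2 <- data.frame(mix_ratio = mixing_series,
                     log2_intensity_ratio = 0.9 * log2(mixing_series) + 0.2)
  fit2 <- fit_calibration(pts2)
  expect_equal(fit2$slope, 0.9)
  expect_equal(fit2$intercept, 0.2)

  expect_error(fit_calibration(pts[1:2, ]), "at least 3")
  flat <- data.frame(mix_ratio = rep(2, 4), log2_intensity_ratio = 1:4)
  expect_error(fit_calibration(flat), "variance")
})

test_that("allelic ratios invert the curve and normalize by gDNA", {
  ident <- fit_calibration(data.frame(
    mix_ratio = mixing_series, log2_intensity_ratio = log2(mixing_series)))
  expect_equal(quantify_allelic_ratio(1.0, 0.0, ident), 2.0)
  expect_equal(quantify_allelic_ratio(0.7, 0.7, ident), 1.0)

  # forward-encode a true ratio of 1.5 through slope 0.9 / intercept 0.2
  curve <- list(slope = 0.9, intercept = 0.2)
  class(curve) <- "CalibrationCurve"
  cdna <- 0.9 * log2(1.5) + 0.2
  gdna <- 0.9 * log2(1.0) + 0.2
  expect_equal(quantify_allelic_ratio(cdna, gdna, curve), 1.5)

  degenerate <- list(slope = 0, intercept = 0)
  class(degenerate) <- "CalibrationCurve"
  expect_error(quantify_allelic_ratio(1, 0, degenerate), "invertible")
})

test_that("calibration round trips and label swaps invert the ratio exactly", {
  withr::with_seed(61L, {
    for (i in 1:20) {
      slope <- runif(1, 0.5, 1.5)
      icpt <- runif(1, -0.5, 0.5)
      true_ratio <- runif(1, 0.25, 4)
      curve <- structure(list(slope = slope, intercept = icpt),
                         class = "CalibrationCurve")
      cdna <- slope * log2(true_ratio) + icpt
      gdna <- icpt
      got <- quantify_allelic_ratio(cdna, gdna, curve)
      expect_equal(got, true_ratio, tolerance = 1e-10)
      # swapping allele labels negates both log2 ratios
      swapped <- quantify_allelic_ratio(2 * icpt - cdna, 2 * icpt - gdna,
                                        curve)
      expect_equal(swapped, 1 / true_ratio, tolerance = 1e-10)
    }
  })
})

test_that("the imbalance t-test matches the closed-form one-sample formula", {
  sym <- aei_test(c(0.8, 1.2, 0.9, 1.1))
  expect_equal(sym$t, 0)
  expect_equal(sym$p_value, 1)

  r <- c(1.2, 1.3, 1.25)
  got <- aei_test(r)
  t_hand <- (mean(r) - 1) / (sd(r) / sqrt(3))
  expect_equal(got$t, t_hand)
  expect_equal(got$p_value, 2 * pt(-abs(t_hand), df = 2))

  expect_error(aei_test(1.2), "at least 2")
  expect_equal(aei_test(rep(1, 5))$p_value, 1)
  expect_error(aei_test(rep(1.2, 5)), "zero variance")
})

test_that("an imbalanced locus at the study design size is reliably detected", {
  hits <- vapply(1:60, function(s) {
    cfg <- sim_config(seed = s)  # true ratio 1.3, sd 0.1, n = 23
    d <- generate_allelic_dataset(cfg)
    curve <- fit_calibration(d$calibration)
    r <- quantify_allelic_ratio(d$measurements$cdna_log2_ratio,
                                d$measurements$gdna_log2_ratio, curve)
    aei_test(r)$p_value < 1e-4
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("haploChIP compares antibody groups against the control by Welch t", {
  curve <- structure(list(slope = 1, intercept = 0),
                     class = "CalibrationCurve")
  base <- expand.grid(sample_id = paste0("h", 1:4),
                      replicate = 1:3, stringsAsFactors = FALSE)
  withr::with_seed(62L, {
    input <- data.frame(antibody = "input", base,
                        cdna_log2_ratio = rnorm(12, 0, 0.05),
                        gdna_log2_ratio = rnorm(12, 0, 0.05))
    same <- data.frame(antibody = "H3K27ac", base,
                       cdna_log2_ratio = rnorm(12, 0, 0.05),
                       gdna_log2_ratio = rnorm(12, 0, 0.05))
    # 2-fold allele-1 enrichment, 5% measurement noise
    enr <- data.frame(antibody = "JUN", base,
                      cdna_log2_ratio = rnorm(12, 1, 0.05),
                      gdna_log2_ratio = rnorm(12, 0, 0.05))
  })
  out <- haplochip_allele_enrichment(rbind(input, same, enr), curve)
  expect_gt(out$p_value[out$antibody == "H3K27ac"], 0.2)
  expect_lt(out$p_value[out$antibody == "JUN"], 0.01)
  expect_equal(out$mean_ratio[out$antibody == "JUN"], 2, tolerance = 0.1)
})

test_that("low-signal control groups are flagged and excluded", {
  curve <- structure(list(slope = 1, intercept = 0),
                     class = "CalibrationCurve")
  df <- data.frame(
    antibody = rep(c("input", "IgG", "JUN"), each = 3),
    sample_id = rep(paste0("h", 1:3), 3),
    cdna_log2_ratio = c(0.01, -0.02, 0.02, 2, -3, 1, 0.5, 0.55, 0.6),
    gdna_log2_ratio = 0,
    signal = c(1, 1, 1, 0.001, 0.002, 0.001, 1, 1, 1)
  )
  out <- haplochip_allele_enrichment(df, curve)
  expect_equal(attr(out, "low_signal"), "IgG")
  expect_false("IgG" %in% out$antibody)
  expect_error(
    haplochip_allele_enrichment(df[df$antibody != "input", ], curve),
    "control"
  )
})
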