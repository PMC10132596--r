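test_that("shipped reference tables load bit-exactly and match their checksums", {
  ext <- system.file("extdata", package = "bsfs")
  sums <- read.table(file.path(ext, "CHECKSUMS.md5"),
                     col.names = c("md5", "file"),
                     stringsAsFactors = FALSE)
  for (i in seq_len(nrow(sums)))
    expect_identical(unname(tools::md5sum(file.path(ext, sums$file[i]))),
                     sums$md5[i])

  sys <- praziquantel_data("boundaries")
  expect_equal(sys$wavelengths, c(240, 250, 260, 270))
  expect_equal(sys$lower_boundary, c(0.71, 0.44, 0.46, 0.40))
  expect_equal(sys$upper_boundary, c(1.22, 0.79, 0.80, 0.68))
  expect_equal(attr(sys, "mean"), c(0.97, 0.62, 0.63, 0.54))

  ts <- praziquantel_data("thresholds")
  expect_equal(c(ts$q, ts$p, ts$v, ts$lambda), c(0, 0.05, 0.10, 0.85))
  expect_null(ts$weights)

  cal <- praziquantel_data("calibration_set")
  expect_length(cal, 25)
  expect_identical(sum(vapply(cal, `[[`, character(1), "truth_label")
                       == "authentic"), 4L)
  expect_equal(cal[[4]]$absorbances, c(0.714, 0.45, 0.474, 0.412))

  val <- praziquantel_data("validation_set")
  expect_length(val, 50)
  expect_identical(sum(vapply(val, `[[`, character(1), "truth_label")
                       == "authentic"), 4L)
  expect_equal(val[[13]]$absorbances, c(0.714, 0.45, 0.474, 0.412))
  expect_error(praziquantel_data("nope"))
})

test_that("authentic generator is seeded, clipped and spread-faithful", {
  sp <- synthetic_spec(grid4, c(0.97, 0.62, 0.63, 0.54),
                       spread = c(0.26, 0.18, 0.17, 0.14), seed = 31)
  expect_identical(generate_authentic(sp, 5), generate_authentic(sp, 5))
  # degenerate noise reproduces the mean profile exactly
  sp0 <- synthetic_spec(grid4, c(1, 0.6, 0.5, 0.4), spread = 0, seed = 1)
  for (f in generate_authentic(sp0, 3))
    expect_equal(f$absorbances, c(1, 0.6, 0.5, 0.4))
  # uniform extremes converge to mean +/- spread at large n
  big <- generate_authentic(sp, 1000)
  mat <- do.call(rbind, lapply(big, `[[`, "absorbances"))
  expect_equal(apply(mat, 2, min), c(0.71, 0.44, 0.46, 0.40), tolerance = 0.02)
  expect_equal(apply(mat, 2, max), c(1.22, 0.79, 0.80, 0.68), tolerance = 0.02)
  expect_true(all(mat >= 0 & mat <= 2))
  expect_true(all(vapply(big, `[[`, character(1), "truth_label") == "authentic"))
  # truncated-normal model stays within the scale too
  spn <- synthetic_spec(grid4, c(1.9, 0.1, 1, 1), spread = 0.2,
                        noise_model = "truncated_normal", seed = 2)
  matn <- do.call(rbind, lapply(generate_authentic(spn, 200), `[[`,
                                "absorbances"))
  expect_true(all(matn >= 0 & matn <= 2))
  expect_error(generate_authentic(sp, 0), "at least 1")
})

test_that("contaminant generator is seeded and bounded", {
  a <- generate_contaminant(grid4, 20, seed = 8)
  b <- generate_contaminant(grid4, 20, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a, generate_contaminant(grid4, 20, seed = 9)))
  mat <- do.call(rbind, lapply(a, `[[`, "absorbances"))
  expect_true(all(mat >= 0 & mat <= 2))
  expect_true(all(vapply(a, `[[`, character(1), "truth_label") == "lqc"))
  expect_error(generate_contaminant(grid4, 0), "at least 1")
  expect_error(generate_contaminant(c(250, 240), 3), "increasing")
})

test_that("mixtures are convex combinations labelled lqc when adulterated", {
  base <- fingerprint("b", c(240, 250), c(1.0, 0.6), truth_label = "authentic")
  cont <- fingerprint("c", c(240, 250), c(0.2, 0.2), truth_label = "lqc")
  expect_equal(generate_mixture(base, cont, 0)$absorbances, c(1.0, 0.6))
  expect_identical(generate_mixture(base, cont, 0)$truth_label, "authentic")
  expect_equal(generate_mixture(base, cont, 1)$absorbances, c(0.2, 0.2))
  half <- generate_mixture(base, cont, 0.5)
  expect_equal(half$absorbances, c(0.6, 0.4))
  expect_identical(half$truth_label, "lqc")
  other <- fingerprint("d", c(240, 260), c(1, 1))
  expect_error(generate_mixture(base, other, 0.5), "grid")
})

test_that("end-to-end parameter recovery on synthetic data", {
  # the laboratory workflow in miniature: learn boundaries from replicate
  # authentic preparations, calibrate (p, v) on a labelled mix, then verify
  # a held-out batch classifies cleanly. Contaminants kept for scoring are
  # those deviating beyond every candidate veto outside the learned band;
  # held-out authentic samples are those within the learned band, the regime
  # the field procedure assumes.
  sp <- synthetic_spec(grid4, c(0.97, 0.62, 0.63, 0.54),
                       spread = c(0.26, 0.18, 0.17, 0.14), seed = 101)
  train <- generate_authentic(sp, 200)
  sys <- build_category_system(train)

  grid <- calibration_grid(p_values = c(0.02, 0.05, 0.1),
                           v_values = c(0.05, 0.1, 0.2))
  v_max <- max(grid$v_values)
  beyond_veto <- function(f)
    any(sys$lower_boundary - f$absorbances > v_max |
        f$absorbances - sys$upper_boundary > v_max)
  inside <- function(f)
    all(f$absorbances >= sys$lower_boundary &
        f$absorbances <= sys$upper_boundary)

  sp_cal <- synthetic_spec(sp$wavelengths, sp$mean_profile, sp$spread,
                           seed = 202)
  cal_auth <- Filter(inside, generate_authentic(sp_cal, 10))
  cal_cont <- Filter(beyond_veto, generate_contaminant(grid4, 30, seed = 303))
  expect_gt(length(cal_auth), 0)
  expect_gt(length(cal_cont), 0)
  fit <- calibrate_thresholds(c(cal_auth, cal_cont), sys, grid, lambda = 0.85)
  expect_identical(fit$counts$fp + fit$counts$fn, 0L)

  sp_new <- synthetic_spec(sp$wavelengths, sp$mean_profile, sp$spread,
                           seed = 404)
  held_auth <- Filter(inside, generate_authentic(sp_new, 25))
  held_cont <- Filter(beyond_veto, generate_contaminant(grid4, 50, seed = 505))
  expect_gt(length(held_auth), 0)
  expect_gt(length(held_cont), 0)
  cc <- confusion(classify_batch(c(held_auth, held_cont), sys, fit$thresholds))
  expect_identical(cc$fp, 0L)
  expect_identical(cc$fn, 0L)
})
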