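test_that("per-channel SDs match a two-pass recomputation", {
  fm <- study_features_coarse()
  sds <- channel_sd(fm)
  expect_named(sds, channel_codes())
  for (ch in channel_codes()) {
    v <- as.vector(fm$values[, fm$meta$kind == "organic" &
                               !is.na(fm$meta$channel) &
                               fm$meta$channel == ch])
    m <- sum(v) / length(v)
    expect_equal(unname(sds[ch]),
                 sqrt(sum((v - m)^2) / (length(v) - 1)), tolerance = 1e-12)
  }
  # closed forms
  x <- matrix(c(0, 1, 0, 1), 1)
  colnames(x) <- organic_column_name("R254", c(0.1, 0.2, 0.3, 0.4))
  expect_equal(unname(channel_sd(as_feature_matrix(x))),
               sd(c(0, 1, 0, 1)))
  const <- as_feature_matrix(matrix(0.3, 2, 2, dimnames = list(
    NULL, organic_column_name("R254", c(0.1, 0.2)))))
  expect_equal(unname(channel_sd(const)), 0)
})

test_that("row-count arithmetic holds for arbitrary repeat settings", {
  fm <- study_features_coarse()
  for (cfg in list(c(2L, 3L, 1L), c(1L, 5L, 0L), c(0L, 21L, 1L))) {
    out <- augment(fm, augmentation_config(outer_repeats = cfg[1],
                                           inner_repeats = cfg[2],
                                           keep_originals = cfg[3] == 1L))
    expect_equal(nrow(out$values),
                 cfg[1] * cfg[2] * 68L + cfg[3] * 68L)
    # label marginals: every class has identical multiplicity
    expect_true(all(table(out$labels) == cfg[1] * cfg[2] + cfg[3]))
  }
})

test_that("augmentation is deterministic, non-negative, and identity at zero noise", {
  fm <- study_features_coarse()
  cfg <- augmentation_config(outer_repeats = 2L, inner_repeats = 3L, seed = 5L)
  a1 <- augment(fm, cfg); a2 <- augment(fm, cfg)
  expect_identical(a1$values, a2$values)
  expect_gte(min(a1$values), 0)

  zero <- augmentation_config(rf_drift_bound = 0, au_noise_multiplier = 0,
                              sugar_noise_fraction = 0,
                              outer_repeats = 2L, inner_repeats = 2L,
                              keep_originals = FALSE)
  az <- augment(fm, zero)
  for (i in c(1L, 40L, 68L))
    expect_equal(unname(az$values[az$labels == fm$labels[i], ][1, ]),
                 unname(fm$values[i, ]))
})

test_that("intensity noise moments match the configured channel multiplier", {
  # one sample, one channel, values large enough that truncation at zero
  # never bites; drift disabled so cells stay in place
  vals <- matrix(c(1000, 1200, 1400, 800, 1100), 1)
  colnames(vals) <- organic_column_name("R254", seq(0.1, 0.5, 0.1))
  fm <- as_feature_matrix(vals)
  target_sd <- 1.25 * sd(as.vector(vals))
  out <- augment(fm, augmentation_config(rf_drift_bound = 0,
                                         sugar_noise_fraction = 0,
                                         outer_repeats = 20000L,
                                         inner_repeats = 1L,
                                         keep_originals = FALSE, seed = 9L))
  noise <- sweep(out$values, 2L, as.vector(vals))
  expect_equal(sd(as.vector(noise)), target_sd, tolerance = 0.02)
  expect_lt(abs(mean(noise)), 0.02 * target_sd)
})

test_that("sugar noise is proportional with the configured fraction", {
  vals <- matrix(c(1000, 500, 200, 50, 100, 120), 1)
  colnames(vals) <- c(c("fructose", "glucose", "maltose", "sucrose"),
                      organic_column_name("R254", c(0.3, 0.4)))
  fm <- as_feature_matrix(vals)
  out <- augment(fm, augmentation_config(rf_drift_bound = 0,
                                         au_noise_multiplier = 0,
                                         outer_repeats = 20000L,
                                         inner_repeats = 1L,
                                         keep_originals = FALSE, seed = 10L))
  for (j in 1:4)
    expect_equal(sd(out$values[, j]), 0.05 * vals[j], tolerance = 0.03)
})

test_that("Rf drift is bounded and distributed as rounded uniform shifts", {
  # single band mid-grid; noise off, so the band's landing column is the
  # realised shift; compare against the exact rounding probabilities of
  # Uniform(-0.0173, 0.0173) on a 0.005 grid
  g <- seq(0.05, 0.60, 0.005)
  vals <- matrix(0, 1, length(g)); vals[1, 51] <- 1
  colnames(vals) <- organic_column_name("R254", g)
  fm <- as_feature_matrix(vals)
  out <- augment(fm, augmentation_config(au_noise_multiplier = 0,
                                         sugar_noise_fraction = 0,
                                         outer_repeats = 50000L,
                                         inner_repeats = 1L,
                                         keep_originals = FALSE, seed = 4L))
  land <- apply(out$values, 1L, which.max)
  offs <- land - 51L
  expect_true(all(abs(offs) * 0.005 <= 0.0173 + 0.0025))
  b <- 0.0173; s <- 0.005
  p_exact <- vapply(-3:3, function(k)
    (min(b, (k + 0.5) * s) - max(-b, (k - 0.5) * s)) / (2 * b), numeric(1))
  p_emp <- tabulate(offs + 4L, 7L) / length(offs)
  expect_equal(p_emp, p_exact, tolerance = 0.05)
})

test_that("invalid augmentation inputs are rejected", {
  expect_error(augmentation_config(rf_drift_bound = -1), "non-negative")
  expect_error(augmentation_config(outer_repeats = -1), "non-negative")
  x <- matrix(1, 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(augment(as_feature_matrix(x)), "channel")
})
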