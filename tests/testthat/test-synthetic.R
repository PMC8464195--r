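test_that("default templates have the documented compositional contrasts", {
  tpl <- default_templates()
  expect_length(tpl, 8L)
  # honeys: fructose/glucose dominant, no quantifiable sucrose, rich band sets
  for (h in honey_codes()) {
    expect_gt(tpl[[h]]$sugar_means["fructose"], tpl[[h]]$sugar_means["maltose"])
    expect_equal(unname(tpl[[h]]$sugar_means["sucrose"]), 0)
    expect_gte(nrow(tpl[[h]]$bands), 5L)
  }
  expect_false(identical(tpl$MAN$bands[, c("channel", "rf")],
                         tpl$JAR$bands[, c("channel", "rf")]))
  # maltose-rich vs sucrose-rich syrups
  for (s in c("RIC", "COR", "GLU"))
    expect_gt(tpl[[s]]$sugar_means["maltose"], tpl[[s]]$sugar_means["sucrose"])
  for (s in c("GOL", "TRE", "MAP"))
    expect_gt(tpl[[s]]$sugar_means["sucrose"], tpl[[s]]$sugar_means["maltose"])
  # maple marker band at Rf 0.41
  expect_true(any(abs(tpl$MAP$bands$rf - 0.41) < 1e-9))
  # syrups carry no major organic bands (honeys do)
  syr_max <- max(vapply(syrup_codes(), function(s) max(tpl[[s]]$bands$au), 1))
  expect_lt(max(vapply(c("RIC", "COR", "GLU", "GOL", "TRE"),
                       function(s) max(default_templates()[[s]]$bands$au), 1)),
            min(vapply(honey_codes(), function(h) max(tpl[[h]]$bands$au), 1)))
})

test_that("blending is the exact linear mixing rule with identity endpoints", {
  tpl <- default_templates()
  man <- hptlcauth:::template_record(tpl$MAN)
  ric <- hptlcauth:::template_record(tpl$RIC)
  expect_equal(blend(man, ric, 0)$sugars, man$sugars)
  expect_equal(blend(man, ric, 1)$sugars, ric$sugars)
  b3 <- blend(man, ric, 0.3)
  expect_equal(b3$sugars, 0.7 * man$sugars + 0.3 * ric$sugars)
  expect_equal(b3$label, "MAN-RIC 30%")

  # honey bands dilute strictly monotonically; maltose rises strictly
  fr <- seq(0.1, 0.5, by = 0.1)
  blends <- lapply(fr, function(f) blend(man, ric, f))
  key <- paste(man$bands$channel, man$bands$rf)
  band_au <- sapply(blends, function(b)
    b$bands$au[match(key, paste(b$bands$channel, b$bands$rf))])
  expect_true(all(apply(band_au, 1L, function(v) all(diff(v) < 0))))
  maltose <- vapply(blends, function(b) b$sugars[["maltose"]], numeric(1))
  expect_true(all(diff(maltose) > 0))
})

test_that("blend rejects invalid parents and fractions", {
  tpl <- default_templates()
  man <- hptlcauth:::template_record(tpl$MAN)
  ric <- hptlcauth:::template_record(tpl$RIC)
  expect_error(blend(man, ric, 1.2), "fraction")
  expect_error(blend(ric, man, 0.2), "honey")
  expect_error(blend(man, blend(man, ric, 0.2), 0.2), "syrup")
})

test_that("the default design yields 68 samples (60 blends) deterministically", {
  tab <- generate_study(study_design_config(seed = 11L))
  expect_length(tab$labels, 68L)
  p <- parse_sample_label(tab$labels)
  expect_equal(sum(!is.na(p$adulterant)), 60L)
  tab2 <- generate_study(study_design_config(seed = 11L))
  expect_identical(tab$sugars, tab2$sugars)
  expect_identical(tab$organics, tab2$organics)
  tab3 <- generate_study(study_design_config(seed = 12L))
  expect_false(identical(tab$sugars, tab3$sugars))
})

test_that("noise scale zero reproduces the noiseless mixing rule and mass balance", {
  cfg <- study_design_config(noise_scale = 0)
  tab <- generate_study(cfg)
  tpl <- cfg$templates
  man <- hptlcauth:::template_record(tpl$MAN)
  gol <- hptlcauth:::template_record(tpl$GOL)
  b <- blend(man, gol, 0.4)
  i <- match("MAN-GOL 40%", tab$labels)
  expect_equal(unname(tab$sugars[i, ]), unname(b$sugars))
  # mass balance of total sugars
  tot <- rowSums(tab$sugars)
  expect_equal(tot[[i]],
               0.6 * tot[[match("MAN", tab$labels)]] +
               0.4 * tot[[match("GOL", tab$labels)]])
  # monotone dilution of every honey-only band
  jar_rows <- match(sprintf("JAR-MAP %d%%", seq(10, 50, 10)), tab$labels)
  jar_bands <- tab$organic_meta$channel == "R254"  # JAR has R254 bands, MAP none
  au <- tab$organics[jar_rows, jar_bands, drop = FALSE]
  expect_true(all(apply(au, 2L, function(v) all(diff(v) <= 0))))
})

test_that("duplicate product codes in a design are rejected", {
  expect_error(study_design_config(honeys = c("MAN", "MAN")), "duplicate")
})
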