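test_that("lipid names parse across prefix, suffix and Unicode spellings", {
  p <- parse_lipid_name(c("16:0", "i15:0", "15:0anteiso", "cy17:0",
                          "16:1w5c", "19:1w8t", "18:02OH", "15∶1ω8c"))
  expect_equal(p$canonical,
               c("16:0", "i15:0", "a15:0", "cy17:0", "16:1w5c", "19:1w8t",
                 "18:02OH", "15:1w8c"))
  expect_equal(p$chain, c(16L, 15L, 15L, 17L, 16L, 19L, 18L, 15L))
  expect_error(parse_lipid_name("not-a-lipid"), "not-a-lipid")
})

test_that("core filtering removes 16:0-absent cores and >=20-chain lipids only", {
  tab <- make_lipid_fixture(n = 81, n_missing_16_0 = 9)
  flt <- filter_cores(tab)
  expect_equal(nrow(flt$table), 72L)
  expect_equal(sort(flt$removed$core_id), 1:9)
  expect_equal(flt$dropped_lipids, "20:4w6c")
  # retained values are bit-identical pass-through
  kept <- tab$core_id %in% flt$table$core_id
  for (cc in c("16:0", "i15:0", "a15:0", "18:1w9c")) {
    expect_identical(flt$table[[cc]], tab[[cc]][kept])
  }
  # unparseable column is named in the error
  bad <- tab
  names(bad)[2] <- "mystery_peak"
  expect_error(filter_cores(bad), "mystery_peak")
})

test_that("mole percents sum to 100, preserve proportions, and are scale invariant", {
  tab <- data.frame(core_id = 1:2,
                    "16:0" = c(1, 10), "i15:0" = c(1, 10),
                    "a15:0" = c(2, 20), check.names = FALSE)
  mp <- mole_percent(tab)
  expect_equal(unname(unlist(mp[1, -1])), c(25, 25, 50))
  expect_equal(unname(unlist(mp[2, -1])), c(25, 25, 50))

  one <- data.frame(core_id = 1, "16:0" = 7, check.names = FALSE)
  expect_equal(mole_percent(one)[["16:0"]], 100)

  zero <- data.frame(core_id = 1, "16:0" = 0, check.names = FALSE)
  expect_error(mole_percent(zero), "zero total")

  # property: row sums 100 and invariance under positive rescaling
  set.seed(42)
  for (i in 1:20) {
    k <- sample(3:8, 1)
    amt <- stats::runif(k, 0.01, 50)
    nm <- paste0(sample(12:19, k), ":0")
    t1 <- as.data.frame(as.list(stats::setNames(amt, nm)),
                        check.names = FALSE)
    t1 <- cbind(core_id = 1, t1)
    c_ <- stats::runif(1, 0.1, 10)
    t2 <- t1; t2[-1] <- t2[-1] * c_
    expect_equal(sum(mole_percent(t1)[-1]), 100)
    expect_equal(mole_percent(t1), mole_percent(t2))
  }
})

test_that("fungi-to-bacteria ratio follows the marker formula", {
  expect_equal(fb_ratio(c("18:1w9c" = 1, "16:1w5" = 1, "i15:0" = 4)), 0.5)
  expect_equal(fb_ratio(c("i15:0" = 2, "15:0" = 1)), 0)    # no fungal markers
  expect_true(is.na(fb_ratio(c("18:1w9c" = 3, "12:0" = 1)))) # no bacterial
  # suffix-tolerant matching: 16:1w5c satisfies the 16:1w5 marker
  expect_equal(fb_ratio(c("16:1w5c" = 2, "15:0" = 4)), 0.5)
  # ratio-of-means on the bundled plot profile (hand arithmetic:
  # (16.10+1.35)/(3.02+3.13+1.21+1.61+5.43+2.55+1.65+3.41) = 0.7928)
  prof <- plot_lipid_profiles()$mean[, "glade_crown"]
  expect_equal(fb_ratio(prof[!is.na(prof)]), 17.45 / 22.01, tolerance = 1e-12)
})

test_that("community metrics are invariant to rescaling raw amounts", {
  tab <- make_lipid_fixture(n = 10, n_missing_16_0 = 0)
  m1 <- community_metrics(filter_cores(tab)$table)
  tab2 <- tab
  tab2[, -1] <- tab2[, -1] * 3.7
  m2 <- community_metrics(filter_cores(tab2)$table)
  for (cc in c("fb_ratio", "gm_pos", "gm_neg", "stress_ratio")) {
    expect_equal(m1[[cc]], m2[[cc]], tolerance = 1e-12)
  }
  expect_equal(m2$abundance_nmol, 3.7 * m1$abundance_nmol)
})

test_that("Gram marker sums use exactly the stated sets", {
  expect_equal(marker_sums(c("i15:0" = 0.02, "16:0" = 0.5)),
               c(gm_pos = 0.02, gm_neg = 0))
  gm_neg_names <- c("15:1w8", "16:1w7", "17:1w7", "19:1w8t", "15:1w9")
  v <- stats::setNames(rep(0.01, 5), gm_neg_names)
  expect_equal(marker_sums(v)[["gm_neg"]], 0.05)
  # a plot whose Gm+ markers hold 1.6% of moles reads back 0.016
  d <- generate_design()
  prof <- c("i15:0" = 0.5, "a15:0" = 0.5, "i16:0" = 0.3, "a17:0" = 0.2,
            "i17:0" = 0.1, "16:0" = 30, "18:1w9c" = 30, "15:0" = 38.4)
  tab <- simulate_lipid_table(d, prof, total_mean = 374, total_sd = 100,
                              profile_conc = 400, seed = 21)
  met <- community_metrics(filter_cores(tab)$table)
  s <- plot_summary(met$gm_pos)
  expect_lt(abs(s[["mean"]] - 0.016), 3 * max(s[["se"]], 1e-4))
})

test_that("stress ratio is flagged undefined without a15:0", {
  expect_equal(stress_ratio(c("i15:0" = 3.13, "a15:0" = 3.02)),
               3.13 / 3.02)
  expect_true(is.na(stress_ratio(c("i15:0" = 1, "16:0" = 5))))
})

test_that("plot summaries report mean, sd/sqrt(n), and n", {
  expect_equal(plot_summary(c(1, 2, 3)),
               c(mean = 2, se = 1 / sqrt(3), n = 3))
  expect_equal(plot_summary(rep(4, 10))[["se"]], 0)
  expect_true(is.na(plot_summary(5)[["se"]]))
  expect_equal(plot_summary(c(1, NA, 3))[["n"]], 2)
  # resampling oracle at the scale of a plot abundance summary
  set.seed(77)
  v <- stats::rnorm(81, mean = 374, sd = 225)
  s <- plot_summary(v)
  expect_equal(s[["se"]], stats::sd(v) / 9)
  expect_lt(abs(s[["se"]] - 25), 10)
})

test_that("marker coverage reports matches and misses", {
  cov <- marker_coverage(make_lipid_fixture(n = 3, n_missing_16_0 = 0))
  expect_true(all(c("fungal", "bacterial", "gm_pos", "gm_neg") %in% cov$set))
  expect_equal(cov$matched[cov$marker == "i15:0" & cov$set == "gm_pos"],
               "i15:0")
  expect_equal(cov$matched[cov$marker == "16:1w5"], "")
})
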