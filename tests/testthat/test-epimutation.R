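test_that("variance F-test identities, symmetry and degenerate handling", {
  set.seed(1)
  x <- rnorm(14)
  res <- variance_ftest(x, x)
  expect_equal(res$F, 1)
  expect_equal(res$p, 1)
  expect_equal(c(res$df1, res$df2), c(13, 13))

  # two-sidedness: p is symmetric under swapping the groups
  for (i in 1:20) {
    a <- rnorm(14, sd = runif(1, 0.5, 2))
    b <- rnorm(25, sd = runif(1, 0.5, 2))
    expect_equal(variance_ftest(a, b)$p, variance_ftest(b, a)$p)
  }

  both0 <- variance_ftest(rep(0.3, 5), rep(0.7, 6))
  expect_true(both0$degenerate)
  expect_true(is.na(both0$F))
  expect_equal(both0$p, 1)
  one0 <- variance_ftest(rnorm(5), rep(0.7, 6))
  expect_true(one0$degenerate)
  expect_equal(one0$p, 0)
  expect_error(variance_ftest(1, rnorm(5)), ">= 2 observations")
})

test_that("variance scan flags the obvious extreme probe and matches scalar F-tests", {
  sheet <- paired_sheet(6, 8)
  betas <- paired_betas(50, sheet, seed = 14)
  conv_m0 <- paste0(sprintf("C%02d", 1:6), "_M0")
  nonc_m0 <- paste0(sprintf("N%02d", 1:8), "_M0")
  betas["cg000001", conv_m0] <- rep(c(0.01, 0.99), 3)     # huge variance
  betas["cg000001", nonc_m0] <- 0.5 + (1:8) * 1e-6        # almost constant

  scan <- scan_variances(betas, sheet, "M0")
  row1 <- scan[scan$probe_id == "cg000001", ]
  expect_equal(row1$higher_variance_group, "converter")
  expect_equal(row1$p, min(scan$p))
  expect_lt(row1$p, 1e-8)

  # scan rows agree with the scalar two-sample F-test, probe by probe
  for (p in sample(rownames(betas), 10)) {
    ref <- variance_ftest(betas[p, conv_m0], betas[p, nonc_m0])
    row <- scan[scan$probe_id == p, ]
    expect_equal(row$F, ref$F)
    expect_equal(row$p, ref$p)
  }
  expect_error(scan_variances(betas, sheet, "M9"), "timepoint")
})

test_that("scan FDR equals an independent Benjamini-Hochberg step-up oracle", {
  sheet <- paired_sheet(14, 25)
  betas <- paired_betas(1000, sheet, seed = 15)
  scan <- scan_variances(betas, sheet, "MF")
  expect_false(any(scan$degenerate))
  expect_equal(scan$q, bh_oracle(scan$p))
  expect_true(all(scan$q >= scan$p))

  # degenerate probes stay out of the FDR family
  betas2 <- betas
  betas2[1, paste0(sprintf("C%02d", 1:14), "_MF")] <- 0.4
  scan2 <- scan_variances(betas2, sheet, "MF")
  expect_true(scan2$degenerate[scan2$probe_id == "cg000001"])
  expect_true(is.na(scan2$q[scan2$probe_id == "cg000001"]))
  ok <- !scan2$degenerate
  expect_equal(scan2$q[ok], bh_oracle(scan2$p[ok]))
})

test_that("candidate selection applies the three filters, increase strictly", {
  mk_scan <- function(tp, q, hi, var_c) {
    data.frame(probe_id = sprintf("cg%d", seq_along(q)), timepoint = tp,
               var_converter = var_c, var_nonconverter = 1e-4,
               F = 1, df1 = 13, df2 = 24, p = q, q = q,
               higher_variance_group = hi, degenerate = FALSE,
               degenerate_reason = "", stringsAsFactors = FALSE)
  }
  # cg1: textbook candidate; cg2: no MF variance increase (equal variances);
  # cg3: significant at MF but in non-converters; cg4: also significant for
  # non-converters at M0 -> fails specificity; cg5: not significant
  scan_mf <- mk_scan("MF",
                     q = c(0.001, 0.001, 0.001, 0.01, 0.5),
                     hi = c("converter", "converter", "nonconverter",
                            "converter", "converter"),
                     var_c = c(2e-3, 1e-3, 1e-3, 2e-3, 2e-3))
  scan_m0 <- mk_scan("M0",
                     q = c(0.9, 0.9, 0.9, 0.001, 0.9),
                     hi = c("tie", "tie", "tie", "nonconverter", "tie"),
                     var_c = c(1e-3, 1e-3, 1e-3, 1e-3, 1e-3))
  cand <- select_candidates(scan_m0, scan_mf, alpha = 0.05)
  got <- setNames(cand$is_candidate, cand$probe_id)
  expect_true(got[["cg1"]])
  expect_false(got[["cg2"]])   # strict increase required
  expect_false(got[["cg3"]])
  expect_false(got[["cg4"]])
  expect_false(got[["cg5"]])
  expect_equal(cand$probe_id[1], cand$probe_id[order(cand$q_mf)][1])

  # explicit exclusion list overrides the derived non-converter set
  cand2 <- select_candidates(scan_m0, scan_mf, alpha = 0.05,
                             nonconverter_exclude = "cg1")
  expect_false(cand2$is_candidate[cand2$probe_id == "cg1"])
})

test_that("planted converter-specific variance inflations are selected cleanly", {
  cfg <- sim_config(n_probes = 2000, n_epimutation = 5, seed = 42)
  sim <- simulate_cohort(cfg)
  scan_m0 <- scan_variances(sim$betas_m0, sim$sheet, "M0")
  scan_mf <- scan_variances(sim$betas_mf, sim$sheet, "MF")
  cand <- select_candidates(scan_m0, scan_mf, alpha = 0.05)
  planted <- unique(sim$truth$epimutation$probe_id)
  expect_setequal(cand$probe_id[cand$is_candidate], planted)
})

test_that("deviations are beta minus group median and match a loop oracle", {
  sheet <- data.frame(sample_id = c("a", "b", "c"),
                      subject_id = c("A", "B", "C"),
                      group = "converter", timepoint = "MF",
                      stringsAsFactors = FALSE)
  betas <- matrix(c(0.2, 0.3, 0.4), 1, 3,
                  dimnames = list("cg1", c("a", "b", "c")))
  dev <- compute_deviations(betas, sheet, "converter", "MF")
  expect_equal(unname(dev["cg1", ]), c(-0.1, 0, 0.1))
  expect_equal(colnames(dev), c("A", "B", "C"))

  sheet2 <- paired_sheet(9, 4)
  betas2 <- paired_betas(300, sheet2, seed = 16)
  dev2 <- compute_deviations(betas2, sheet2, "converter", "M0")
  conv_m0 <- paste0(sprintf("C%02d", 1:9), "_M0")
  for (p in sample(rownames(betas2), 20)) {
    med <- median_oracle(betas2[p, conv_m0])
    expect_equal(unname(dev2[p, ]), unname(betas2[p, conv_m0] - med))
  }
  # per-probe median of deviations is 0 by construction
  expect_lt(max(abs(apply(dev2, 1, median))), 1e-12)

  expect_error(compute_deviations(betas2, sheet2, "converter", "M0",
                                  probes = "cgNOPE"), "cgNOPE")
  few <- sheet2[sheet2$subject_id %in% c("C01", "C02", "N01", "N02"), ]
  expect_error(compute_deviations(betas2, few, "converter", "M0"), ">= 3")
})

test_that("reconstructed betas reproduce the printed deviation fixture", {
  fx <- load_table3_fixture()
  # put each probe at an arbitrary feasible methylation level; deviations
  # must be invariant to the chosen center
  center <- 0.5 - (apply(fx$after, 1, max) + apply(fx$after, 1, min)) / 2
  betas <- fx$after + center
  sheet <- data.frame(sample_id = colnames(fx$after),
                      subject_id = colnames(fx$after),
                      group = "converter", timepoint = "MF",
                      stringsAsFactors = FALSE)
  dev <- compute_deviations(betas, sheet, "converter", "MF")
  expect_equal(unclass(dev)[, ], fx$after[, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("strict outlier calling reproduces the published example calls", {
  fx <- load_table3_fixture()
  calls <- call_epimutations(fx$after, threshold = 0.10, strict = TRUE)

  # printed 0.10 deviations are NOT calls (the threshold is strict)
  expect_false(any(calls$probe_id == "cg17364044" &
                     calls$subject_id == "IC01.105"))
  expect_false(any(calls$probe_id == "cg26447413" &
                     calls$subject_id == "IC01.151"))
  # ... but become calls under the inclusive rule
  incl <- call_epimutations(fx$after, threshold = 0.10, strict = FALSE)
  expect_true(any(incl$probe_id == "cg17364044" &
                    incl$subject_id == "IC01.105"))

  rac1 <- calls[calls$probe_id == "cg18404925", ]
  expect_equal(rac1$subject_id, "IC01.055")
  expect_equal(rac1$direction, "hyper")
  astn2 <- calls[calls$probe_id == "cg13978347", ]
  expect_equal(astn2$subject_id, "IC01.178")
  expect_equal(astn2$direction, "hypo")

  # quiet before-transition block yields no call at all
  expect_equal(nrow(call_epimutations(fx$before, 0.10)), 0)
})

test_that("call summaries count subjects, probes and shared directions", {
  fx <- load_table3_fixture()
  calls <- call_epimutations(fx$after, 0.10)
  s <- summarize_calls(calls, colnames(fx$after))
  expect_equal(s$n_calls, 16)
  expect_equal(s$n_probes, 12)
  expect_equal(s$histogram, c("0" = 4L, "1" = 5L, "2" = 4L, "3" = 1L))
  expect_equal(nrow(s$multi_carrier), 4)
  expect_true(all(s$multi_carrier$n_carriers == 2))
  expect_true(all(s$multi_carrier$shared_direction))
  expect_setequal(
    s$multi_carrier$probe_id[s$multi_carrier$direction == "hyper"],
    c("cg19041132", "cg01558909", "cg14993491"))
  expect_equal(s$multi_carrier$probe_id[s$multi_carrier$direction == "hypo"],
               "cg12053442")

  empty <- summarize_calls(calls[0, ], paste0("S", 1:5))
  expect_equal(empty$histogram, c("0" = 5L))
  expect_equal(empty$n_calls, 0)
  expect_error(summarize_calls(calls, "nobody"), "not in the subject list")
})

test_that("shift invariance and scale covariance of the variance machinery", {
  sheet <- paired_sheet(7, 9)
  betas <- 0.2 + 0.5 * paired_betas(100, sheet, seed = 17)
  scan <- scan_variances(betas, sheet, "MF")
  shifted <- betas
  shifted[,] <- betas + 0.2   # same constant to every group member
  scan_s <- scan_variances(shifted, sheet, "MF")
  expect_equal(scan_s$F, scan$F)
  expect_equal(scan_s$p, scan$p)

  dev <- compute_deviations(betas, sheet, "converter", "MF")
  dev_s <- compute_deviations(shifted, sheet, "converter", "MF")
  expect_equal(unclass(dev_s), unclass(dev))
  expect_equal(call_epimutations(dev_s, 0.1), call_epimutations(dev, 0.1))

  # scaling a probe's values by c multiplies variances by c^2 and keeps
  # the between-group ratio consistent
  x <- betas[1, paste0(sprintf("C%02d", 1:7), "_MF")]
  y <- betas[1, paste0(sprintf("N%02d", 1:9), "_MF")]
  base <- variance_ftest(x, y)
  scaled <- variance_ftest(0.5 * x, y)
  expect_equal(scaled$F, base$F * 0.25)
  both <- variance_ftest(0.5 * x, 0.5 * y)
  expect_equal(both$F, base$F)
  expect_equal(both$p, base$p)
})
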