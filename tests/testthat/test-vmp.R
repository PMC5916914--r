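test_that("compute_delta subtracts baseline from follow-up per subject", {
  sheet <- paired_sheet(1, 1)
  betas <- matrix(c(0.20, 0.50, 0.32, 0.50), 1, 4,
                  dimnames = list("cg1", sheet$sample_id))
  d <- compute_delta(betas, sheet)
  expect_equal(d$values["cg1", "C01"], 0.12)  # 0.32 - 0.20
  expect_equal(d$values["cg1", "N01"], 0)
  expect_equal(unname(d$subject_group), c("converter", "nonconverter"))
})

test_that("compute_delta equals an elementwise loop oracle on random cohorts", {
  sheet <- paired_sheet(5, 7)
  betas <- paired_betas(100, sheet, seed = 2)
  betas[4, 1] <- NA
  d <- compute_delta(betas, sheet)
  subjects <- unique(sheet$subject_id)
  for (s in subjects) {
    for (p in rownames(betas)) {
      expected <- betas[p, paste0(s, "_MF")] - betas[p, paste0(s, "_M0")]
      expect_identical(d$values[p, s], expected)
    }
  }
  expect_true(all(abs(d$values) <= 1, na.rm = TRUE))
})

test_that("compute_delta handles unpaired subjects and ambiguous pairings", {
  sheet <- paired_sheet(2, 1)
  sheet <- sheet[sheet$sample_id != "C02_MF", ]       # C02 unpaired
  betas <- paired_betas(10, sheet, seed = 4)
  expect_warning(d <- compute_delta(betas, sheet), "unpaired subject.*C02")
  expect_false("C02" %in% colnames(d$values))

  dup <- paired_sheet(1, 1)
  dup <- rbind(dup, data.frame(sample_id = "C01_extra", subject_id = "C01",
                               group = "converter", timepoint = "MF"))
  betas2 <- paired_betas(10, dup, seed = 4)
  # ambiguous pairing is rejected (already at sheet validation)
  expect_error(compute_delta(betas2, dup), "duplicate")

  zero <- paired_sheet(2, 2)
  b <- paired_betas(10, zero, seed = 5)
  b[, grep("_MF$", colnames(b))] <- b[, grep("_M0$", colnames(b))]
  expect_true(all(compute_delta(b, zero)$values == 0))
})

test_that("the two group-median summaries differ exactly as designed", {
  sheet <- paired_sheet(3, 2)
  betas <- paired_betas(2, sheet, seed = 6)
  # converter deltas at probe 1: {-0.2, 0, +0.2}; probe 2: {0.10, 0.11, 0.12}
  for (i in 1:3) {
    s <- sprintf("C%02d", i)
    betas[1, paste0(s, "_M0")] <- 0.5
    betas[1, paste0(s, "_MF")] <- 0.5 + c(-0.2, 0, 0.2)[i]
    betas[2, paste0(s, "_M0")] <- 0.5
    betas[2, paste0(s, "_MF")] <- 0.5 + c(0.10, 0.11, 0.12)[i]
  }
  d <- compute_delta(betas, sheet)
  s_abs_med <- group_median_statistic(d, "converter", mode = "abs_of_median")
  s_med_abs <- group_median_statistic(d, "converter", mode = "median_of_abs")
  expect_equal(unname(s_abs_med[1]), 0)    # median of symmetric set is 0
  expect_equal(unname(s_med_abs[1]), 0.2)  # but absolute changes are large
  expect_equal(unname(s_abs_med[2]), 0.11) # odd-n middle value
  expect_error(group_median_statistic(d, "martian"), "unknown")
})

test_that("group-median statistics match a sort-based oracle on 1000 probes", {
  sheet <- paired_sheet(6, 8)   # even-sized groups
  sheet2 <- paired_sheet(5, 8)  # odd converter group
  for (sh in list(sheet, sheet2)) {
    betas <- paired_betas(1000, sh, seed = 8)
    d <- compute_delta(betas, sh)
    for (grp in c("converter", "nonconverter")) {
      v <- d$values[, d$subject_group == grp, drop = FALSE]
      exp_abs_med <- abs(apply(v, 1, median_oracle))
      exp_med_abs <- apply(abs(v), 1, median_oracle)
      expect_equal(as.vector(group_median_statistic(d, grp, "abs_of_median")),
                   unname(exp_abs_med))
      expect_equal(as.vector(group_median_statistic(d, grp, "median_of_abs")),
                   unname(exp_med_abs))
    }
  }
})

test_that("VMP thresholding is inclusive at 0.1 and sorts by statistic", {
  stat <- structure(c(cgB = 0.11, cgA = 0.10, cgC = 0.099, cgD = 0.25),
                    mode = "abs_of_median", group = "converter",
                    signed_median = c(cgB = 0.11, cgA = -0.10,
                                      cgC = 0.099, cgD = 0.25))
  res <- detect_vmps(stat, threshold = 0.1)
  expect_equal(res$probe_id, c("cgD", "cgB", "cgA", "cgC"))
  expect_equal(res$is_vmp, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(res$signed_median[res$probe_id == "cgA"], -0.10)

  # ties break lexicographically by probe id
  tied <- structure(c(z = 0.2, a = 0.2), mode = "abs_of_median",
                    group = "converter", signed_median = c(z = 0.2, a = 0.2))
  expect_equal(detect_vmps(tied)$probe_id, c("a", "z"))
})

test_that("violin summary agrees with detect_vmps and a percentile oracle", {
  set.seed(9)
  stat <- structure(setNames(abs(rnorm(500, 0, 0.05)),
                             sprintf("cg%03d", 1:500)),
                    mode = "abs_of_median", group = "converter")
  vs <- violin_summary(stat, threshold = 0.1)
  expect_equal(vs$count_above, sum(detect_vmps(stat, 0.1)$is_vmp))
  expect_equal(unname(vs$quantiles["50%"]), unname(quantile(stat, 0.5)))
  empty <- violin_summary(setNames(numeric(0), character(0)))
  expect_equal(empty$n, 0L)
  expect_equal(empty$count_above, 0L)
})

test_that("VMP results are invariant to translation and to sign flips", {
  sheet <- paired_sheet(7, 9)
  betas <- 0.25 + 0.5 * paired_betas(200, sheet, seed = 10)  # room to shift
  d <- compute_delta(betas, sheet)
  res <- detect_vmps(group_median_statistic(d, "converter"))

  # adding a constant to both timepoints of every sample leaves results alone
  shifted <- betas + 0.2
  ds <- compute_delta(shifted, sheet)
  res_shifted <- detect_vmps(group_median_statistic(ds, "converter"))
  expect_equal(res_shifted, res)

  # negating all deltas leaves the absolute-median statistic unchanged
  dneg <- d
  dneg$values <- -d$values
  expect_equal(as.vector(group_median_statistic(dneg, "converter")),
               as.vector(group_median_statistic(d, "converter")))
})

test_that("heavily missing probes get a missing statistic, not a biased one", {
  sheet <- paired_sheet(10, 2)
  betas <- paired_betas(3, sheet, seed = 12)
  betas[1, paste0(sprintf("C%02d", 1:3), "_MF")] <- NA  # 30% missing
  betas[2, "C01_MF"] <- NA                              # 10% missing: fine
  d <- compute_delta(betas, sheet)
  stat <- group_median_statistic(d, "converter")
  expect_true(is.na(stat[1]))
  expect_false(is.na(stat[2]))
  expect_false(is.na(stat[3]))
})
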