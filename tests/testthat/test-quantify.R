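test_that("incidence matrix has mass-conserving columns and full rank for the trio", {
  fx <- trio_fixture()
  M <- fx$M
  expect_equal(dim(M), c(5, 3))
  expect_equal(unname(colSums(M)), c(1968, 1959, 1959))
  expect_equal(qr(M)$rank, 3)  # the linear system is solvable
  expect_true(all(M >= 0))
  # single uncut variant -> 1x1 matrix with entry = length
  pat <- digest(c(solo = strrep("ACGT", 25)), clai())
  M1 <- build_incidence(classify_bands(pat), pat)
  expect_equal(unname(M1[1, 1]), 100)
  # mismatched variant set is rejected
  expect_error(build_incidence(fx$bands, c(other = "ACGTACGT")),
               "disagree")
})

test_that("noise-free lanes invert exactly in both modes", {
  fx <- trio_fixture()
  ab <- c(variant_a = 1, variant_b = 2, variant_c = 3)
  lane <- simulate_lane(ab, fx$M, reference_intensity = 1, noise_sd = 0,
                        seed = 5)
  ls <- quantify(lane, fx$M, "least_squares")
  dg <- quantify(lane, fx$M, "diagnostic")
  expect_equal(ls$raw, unname(ab), tolerance = 1e-9)
  expect_equal(dg$raw, unname(ab), tolerance = 1e-9)
  # the two estimators agree on noise-free data
  expect_equal(ls$raw, dg$raw, tolerance = 1e-6)
  # intensity only in the 1968 band -> b = c = 0
  lone <- lane_densitometry("L", "c", band_length = 1968, intensity = 500,
                            reference_intensity = 1)
  q <- quantify(lone, fx$M, "least_squares")
  expect_equal(q$raw[q$variant %in% c("variant_b", "variant_c")], c(0, 0))
})

test_that("diagnostic mode errors usefully and handles degenerate lanes", {
  fx <- trio_fixture()
  # a band table where one variant has no diagnostic band
  s <- "AAATCGATAAGG"
  pats <- digest(c(x = s, y = s), clai())
  M2 <- build_incidence(classify_bands(pats, 0), pats)
  lane2 <- simulate_lane(c(1, 1), M2, noise_sd = 0, seed = 1)
  expect_error(quantify(lane2, M2, "diagnostic"), "no diagnostic band")
  # all-zero intensities: zero abundances with a warning
  dark <- lane_densitometry("L0", "c", band_length = fx$bands$length,
                            intensity = rep(0, 5), reference_intensity = 10)
  expect_warning(q0 <- quantify(dark, fx$M, "least_squares"), "zero")
  expect_equal(q0$normalized, rep(0, 3))
  expect_error(
    lane_densitometry("L", "c", 100, 10, reference_intensity = 0), "> 0")
})

test_that("quantification is scale-equivariant and never negative", {
  fx <- trio_fixture()
  set.seed(19)
  for (i in 1:25) {
    ab <- stats::runif(3, 0, 5)
    lane <- simulate_lane(ab, fx$M, reference_intensity = 800,
                          noise_sd = 0.1, seed = 1000 + i)
    q <- quantify(lane, fx$M, "least_squares")
    expect_true(all(q$normalized >= 0))
    # multiply every intensity and the reference by one constant
    cst <- 7.3
    scaled <- lane_densitometry(
      lane$lane, lane$condition, lane$bands$band_length,
      lane$bands$intensity * cst, lane$reference_intensity * cst)
    qs <- quantify(scaled, fx$M, "least_squares")
    expect_equal(qs$normalized, q$normalized, tolerance = 1e-9)
  }
})

test_that("least-squares recovery under 5% noise: median relative error <= 10%", {
  fx <- trio_fixture()
  ab <- c(1, 2, 3)
  errs <- vapply(1:200, function(s) {
    lane <- simulate_lane(ab, fx$M, reference_intensity = 1, noise_sd = 0.05,
                          seed = s)
    q <- quantify(lane, fx$M, "least_squares")
    # per simulated lane: median relative error across variants
    stats::median(abs(q$raw - ab) / ab)
  }, numeric(1))
  expect_lte(stats::median(errs), 0.10)
})

test_that("percent change follows 100 * (treated/control - 1)", {
  expect_equal(percent_change(2, 1), 100)
  expect_equal(percent_change(1, 1), 0)
  # a 3.17-fold increase is reported as +217%
  expect_equal(percent_change(3.17, 1), 217)
  expect_error(percent_change(1, 0), "control")
})

test_that("group comparison: Bonferroni count, thresholds, letters", {
  # identical groups: non-significant, one shared letter
  same <- list(a = c(1, 1.1, 0.9), b = c(1, 1.1, 0.9), c = c(1, 1.1, 0.9))
  cg <- compare_groups(same)
  expect_equal(cg$m, 3)  # 3 groups -> g(g-1)/2 = 3 comparisons
  expect_false(any(cg$comparisons$significant))
  expect_true(all(cg$letters == cg$letters[1]))
  expect_equal(unique(cg$comparisons$threshold), 0.05 / 3)
  # zero-variance identical groups: not significant, no error
  flat <- list(a = c(2, 2, 2), b = c(2, 2, 2))
  expect_false(any(compare_groups(flat)$comparisons$significant))
  # clearly separated groups significant at P <= 0.001 (seeded)
  set.seed(42)
  cg2 <- compare_groups(list(ctrl = rnorm(9, 0, 1), trt = rnorm(9, 5, 1)),
                        alpha = 0.001)
  expect_true(all(cg2$comparisons$significant))
  expect_true(length(unique(cg2$letters)) == 2)
  expect_error(compare_groups(list(a = 1:3)), ">= 2 groups")
  expect_error(compare_groups(list(a = 1, b = 2)), "replicates")
})

test_that("lane-set summary averages technical within biological replicates", {
  fx <- trio_fixture()
  ab_ctrl <- c(1, 1, 1); ab_trt <- c(1, 6.85, 4.01)  # b +585%, c +301%
  lanes <- list()
  s <- 0
  for (cond in c("control", "treated")) {
    ab <- if (cond == "control") ab_ctrl else ab_trt
    for (bio in 1:3) for (tech in 1:3) {
      s <- s + 1
      lanes[[s]] <- simulate_lane(
        ab, fx$M, reference_intensity = 1000, noise_sd = 0.03,
        seed = 400 + s, lane = sprintf("%s_b%d_t%d", cond, bio, tech),
        condition = cond, bio = paste0(cond, bio))
    }
  }
  q <- quantify_lanes(lanes, fx$M, mode = "diagnostic", control = "control")
  # technical triplicates collapse onto biological replicates: n = 3
  expect_true(all(q$summary$n == 3))
  trt <- q$summary[q$summary$condition == "treated", ]
  pc <- setNames(trt$percent_change, trt$variant)
  expect_equal(unname(pc["variant_b"]), 585, tolerance = 0.1)
  expect_equal(unname(pc["variant_c"]), 301, tolerance = 0.12)
  expect_equal(unname(pc["variant_a"]), 0, tolerance = 10)
})
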