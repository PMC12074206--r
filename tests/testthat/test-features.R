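test_that("hand-computed feature values on the alternating segment", {
  f <- extractFeatures(c(1, -1, 1, -1), zeroThresholds())
  expect_equal(f[["mav"]], 1)
  expect_equal(f[["iemg"]], 4)
  expect_equal(f[["rms"]], 1)
  expect_equal(f[["ssi"]], 4)
  expect_equal(f[["wl"]], 6)
  expect_equal(f[["dasdv"]], 2)
  expect_equal(f[["zc"]], 3)
  expect_equal(f[["ssc"]], 2)
  expect_equal(f[["aac"]], 1.5)
  # zero-mean moments: m2 = 1, m3 = 0, m4 = 1
  expect_equal(f[["kurt"]], 1)
  expect_equal(f[["skew"]], 0)
})

test_that("constant segments degenerate as documented", {
  expect_warning(f <- extractFeatures(rep(3, 10), zeroThresholds()),
                 "zero-variance")
  expect_equal(f[["mav"]], 3)
  expect_equal(f[["rms"]], 3)
  expect_equal(f[["wl"]], 0)
  expect_equal(f[["dasdv"]], 0)
  expect_equal(f[["zc"]], 0)
  expect_equal(f[["ssc"]], 0)
  expect_equal(f[["std"]], 0)
  expect_true(is.nan(f[["kurt"]]) && is.nan(f[["skew"]]))
  expect_error(extractFeatures(c(1, 2, 3)), "at least 4")
})

test_that("exact algebraic identities hold on random segments", {
  set.seed(11)
  for (k in 1:1000) {
    n <- sample(4:60, 1)
    x <- rnorm(n, sd = runif(1, 0.1, 50))
    f <- extractFeatures(x, zeroThresholds())
    expect_equal(f[["iemg"]], n * f[["mav"]], tolerance = 1e-15)
    expect_equal(f[["ssi"]], (n - 1) * f[["var"]], tolerance = 1e-15)
    expect_equal(f[["rms"]], sqrt(f[["ssi"]] / n), tolerance = 1e-14)
    expect_true(f[["zc"]] %% 1 == 0 && f[["ssc"]] %% 1 == 0 &&
                  f[["wamp"]] %% 1 == 0)
    expect_true(f[["myop"]] >= 0 && f[["myop"]] <= 1)
    expect_true(all(f[featureNames("amplitude")] >= 0))
  }
})

test_that("features scale as documented under amplitude scaling", {
  set.seed(21)
  x <- rnorm(200, sd = 10)
  a <- 3.7
  th0 <- zeroThresholds()
  f1 <- extractFeatures(x, th0)
  f2 <- extractFeatures(a * x, th0)
  lin <- c("iemg", "mav", "mmav1", "mmav2", "rms", "std", "wl", "dasdv",
           "aac", "iav", "vorder", "log_det")
  for (nm in lin) expect_equal(f2[[nm]], a * f1[[nm]], tolerance = 1e-9,
                               label = nm)
  expect_equal(f2[["ssi"]], a^2 * f1[["ssi"]])
  expect_equal(f2[["var"]], a^2 * f1[["var"]])
  expect_equal(f2[["kurt"]], f1[["kurt"]])
  expect_equal(f2[["skew"]], f1[["skew"]])
  # counts invariant only when thresholds are co-scaled
  th <- ThresholdSpec(2, 2, 2, 2, 3)
  thA <- ThresholdSpec(2 * a, 2 * a^2, 2 * a, 2 * a, 3)
  g1 <- extractFeatures(x, th); g2 <- extractFeatures(a * x, thA)
  for (nm in c("zc", "ssc", "wamp", "myop"))
    expect_equal(g2[[nm]], g1[[nm]], label = nm)
})

test_that("sinusoid limits: RMS -> A/sqrt(2), MAV -> 2A/pi, ZC -> 2/period", {
  A <- 10; periods <- 20; spp <- 200
  x <- A * sin(2 * pi * (0:(periods * spp - 1)) / spp)
  f <- extractFeatures(x, zeroThresholds())
  expect_equal(f[["rms"]], A / sqrt(2), tolerance = 0.01)
  expect_equal(f[["mav"]], 2 * A / pi, tolerance = 0.01)
  expect_equal(f[["zc"]], 2 * periods - 1)
})

test_that("vectorised features match the loop oracle on random segments", {
  set.seed(33)
  for (k in 1:100) {
    n <- sample(4:80, 1)
    x <- rnorm(n, mean = runif(1, -2, 2), sd = runif(1, 0.5, 30))
    zt <- runif(1, 0, 5); st <- runif(1, 0, 10)
    wt <- runif(1, 0, 10); mt <- runif(1, 0, 20)
    got <- extractFeatures(x, ThresholdSpec(zt, st, wt, mt, 3))
    want <- naiveFeatures(x, zt, st, wt, mt, 3)
    for (nm in c("zc", "ssc", "wamp"))
      expect_identical(unname(got[nm]), unname(want[nm]))
    for (nm in setdiff(featureNames(), c("zc", "ssc", "wamp")))
      expect_equal(unname(got[nm]), unname(want[nm]), tolerance = 1e-10,
                   label = nm)
  }
})

test_that("trial aggregation equals brute-force column means", {
  pr <- smallProtocol(n_trials = 4L)
  prof <- SubjectProfile("S1", hb_grade = 2, lesioned_side = "right",
                         seed = 61)
  rec <- applyConditioning(generateRecording(prof, pr))
  ft <- extractFeatureTable(rec, pr)
  agg <- aggregateTrials(ft)
  sub <- ft[ft$side == "left" & ft$condition == "MOVE", ]
  for (nm in c("mav", "rms", "ssc")) {
    row <- agg[agg$side == "left" & agg$condition == "MOVE" &
                 agg$feature == nm, ]
    expect_equal(row$mean, sum(sub[[nm]]) / nrow(sub))
    expect_equal(row$sd, sd(sub[[nm]]))
  }
  # identical vectors aggregate to themselves with zero sd
  two <- ft[c(1, 1), ]
  agg2 <- aggregateTrials(two)
  expect_equal(agg2$mean[agg2$feature == "mav"], ft$mav[1])
  expect_equal(agg2$sd[agg2$feature == "mav"], 0)
  expect_error(aggregateTrials(ft[0, ]), "empty")
})

test_that("feature tables carry the expected structure", {
  pr <- smallProtocol(n_trials = 2L, movement = "eyes")
  prof <- SubjectProfile("S1", hb_grade = 1, lesioned_side = "none",
                         seed = 71)
  rec <- applyConditioning(generateRecording(prof, pr))
  ft <- extractFeatureTable(rec, pr)
  # relevant region only: 2 sides x 2 conditions x 2 trials
  expect_equal(nrow(ft), 8)
  expect_setequal(unique(ft$region), "eye")
  expect_true(all(featureNames() %in% names(ft)))
  long <- featureTableLong(ft)
  expect_equal(nrow(long), 8 * 20)
  expect_setequal(unique(long$feature), featureNames())
})
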