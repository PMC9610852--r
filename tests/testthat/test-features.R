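test_that("epoch enumeration follows the sliding-window arithmetic", {
  ep <- make_epochs(290, epoch_spec(90, 10, 10))
  expect_identical(nrow(ep), 20L)
  expect_equal(ep$start[1], 10)
  expect_equal(ep$end[20], 290)
  expect_identical(nrow(make_epochs(90, epoch_spec(90, 10, 0))), 1L)
  expect_warning(out <- make_epochs(89, epoch_spec(90, 10, 0)),
                 "shorter than one epoch")
  expect_identical(nrow(out), 0L)
  expect_error(epoch_spec(90, 90), "twin > tslide")
})

test_that("IBI cleaning rejects range and median-deviation outliers", {
  mk <- function(ibi) {
    tt <- cumsum(c(1, ibi))[seq_along(ibi)]
    structure(data.frame(time = tt, ibi = ibi, flag = "ok"),
              class = c("beat_series", "data.frame"))
  }
  clean <- clean_ibi(mk(rep(1, 50)))
  expect_identical(nrow(clean), 50L)
  expect_identical(attr(clean, "n_rejected"), 0L)
  # 150 beats/min is outside the 45-115 range
  out <- clean_ibi(mk(c(rep(1, 20), 0.4, rep(1, 20))))
  expect_identical(attr(out, "n_rejected"), 1L)
  expect_false(any(abs(out$ibi - 0.4) < 1e-9))
  # a 3 s dropout interval deviates > 30% from the running median
  out2 <- clean_ibi(mk(c(rep(1, 20), 3, rep(1, 20))))
  expect_identical(attr(out2, "n_rejected"), 1L)
})

test_that("HRV features match their definitions on constructed tachograms", {
  mk <- function(ibi, t0 = 0) {
    tt <- t0 + cumsum(c(0, ibi[-length(ibi)]))
    structure(data.frame(time = tt, ibi = ibi, flag = "ok"),
              class = c("beat_series", "data.frame"))
  }
  const <- hrv_features(mk(rep(1, 80)), c(0, 90))
  expect_equal(unname(const["hr_mean"]), 60)
  expect_equal(unname(const["ibi_sd"]), 0)
  expect_equal(unname(const["pibi50"]), 0)
  expect_lt(unname(const["hf"]), 1e-10)
  alt <- hrv_features(mk(rep(c(0.8, 0.9), 45)), c(0, 90))
  expect_equal(unname(alt["pibi50"]), 1)
  expect_error(hrv_features(mk(rep(1, 5)), c(0, 90)), "too few")
})

test_that("a pure LF-modulated tachogram gives a large LF/HF ratio", {
  tt <- cumsum(c(0, rep(1, 119)))
  ibi <- 1 + 0.05 * sin(2 * pi * 0.1 * tt)
  b <- structure(data.frame(time = tt, ibi = ibi, flag = "ok"),
                 class = c("beat_series", "data.frame"))
  f <- hrv_features(b, c(0, 120))
  expect_gt(unname(f["lf_hf"]), 10)
})

test_that("RWV features zero out for metronomic breathing", {
  te <- seq(4, 88, by = 4)
  bs <- structure(data.frame(tb = te - 1.6, te = te, r_tb = 0, r_te = 1,
                             iri = 4, ii = 1.6, ei = 2.4, iv = 1),
                  class = c("breath_series", "data.frame"))
  f <- rwv_features(bs, c(0, 90))
  expect_length(f, 36L)
  expect_identical(names(f), vigilwave:::rwv_feature_names())
  expect_equal(unname(f["iri_mean"]), 4)
  expect_equal(unname(f["eii_mean"]), 1.5)
  expect_equal(unname(f["rr_mean"]), 15)
  sd_cols <- grepl("_sd$", names(f)) | grepl("^sd[12].*(_mean|_sd|_eta)$",
                                             names(f))
  expect_true(all(abs(f[sd_cols]) < 1e-12))
})

test_that("successive-difference features track a linear IRI drift", {
  iri <- 4 + 0.1 * (0:19)
  te <- 4 + cumsum(iri)
  bs <- structure(data.frame(tb = te - 1.6, te = te, r_tb = 0, r_te = 1,
                             iri = iri, ii = 1.6, ei = iri - 1.6, iv = 1),
                  class = c("breath_series", "data.frame"))
  f <- rwv_features(bs, c(0, te[20] + 1))
  expect_equal(unname(f["sd1_iri_mean"]), 0.1)
  expect_equal(unname(f["sd1_iri_sd"]), 0)
  expect_equal(unname(f["sd2_iri_mean"]), 0)
})

test_that("the SD identity links feature moments to raw moments", {
  set.seed(8)
  iri <- 4 + rnorm(30, sd = 0.3)
  te <- 4 + cumsum(iri)
  bs <- structure(data.frame(tb = te - 1.6, te = te, r_tb = 0, r_te = 1,
                             iri = iri, ii = 1.6, ei = iri - 1.6, iv = 1),
                  class = c("breath_series", "data.frame"))
  f <- rwv_features(bs, c(0, te[30] + 1))
  d <- diff(iri)
  n <- length(d)
  lhs <- f[["sd1_iri_sd"]]^2 * (n - 1) / n + f[["sd1_iri_mean"]]^2
  expect_equal(unname(lhs), mean(d^2), tolerance = 1e-12)
})

test_that("the feature table has 43 labelled columns per epoch", {
  bt <- generate_breath_truth(resp_params(), 300, seed = 41)
  beat <- generate_beat_truth(cardiac_params(), breath_phase(bt), 300,
                              seed = 42)
  tab <- feature_matrix(truth_beat_series(beat), truth_breath_series(bt),
                        290, epoch_spec(), label = "R", subject_id = "s7")
  expect_identical(nrow(tab), 20L)
  expect_identical(sum(colnames(tab) %in% feature_names()), 43L)
  expect_true(all(tab$label == "R"))
  expect_false(any(is.na(as.matrix(tab[, feature_names()]))))
  # event order must not matter (sorting contract)
  beats <- truth_beat_series(beat); breaths <- truth_breath_series(bt)
  set.seed(9)
  tab2 <- feature_matrix(beats[sample(nrow(beats)), ],
                         breaths[sample(nrow(breaths)), ], 290, epoch_spec(),
                         label = "R", subject_id = "s7")
  expect_equal(tab, tab2, ignore_attr = TRUE)
})

test_that("features are invariant to a common time shift", {
  bt <- generate_breath_truth(resp_params(), 200, seed = 43)
  beat <- generate_beat_truth(cardiac_params(), breath_phase(bt), 200,
                              seed = 44)
  beats <- truth_beat_series(beat); breaths <- truth_breath_series(bt)
  ep <- c(20, 110)
  f1 <- c(hrv_features(beats, ep), rwv_features(breaths, ep))
  shift <- 137.5
  beats2 <- beats; beats2$time <- beats2$time + shift
  breaths2 <- breaths
  breaths2$te <- breaths2$te + shift; breaths2$tb <- breaths2$tb + shift
  f2 <- c(hrv_features(beats2, ep + shift), rwv_features(breaths2,
                                                         ep + shift))
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("feature ranges respect their definitions over random epochs", {
  for (seed in c(51, 52)) {
    bt <- generate_breath_truth(resp_params(), 200, seed = seed)
    beat <- generate_beat_truth(cardiac_params(), breath_phase(bt), 200,
                                seed = seed + 1)
    f <- c(hrv_features(truth_beat_series(beat), c(10, 100)),
           rwv_features(truth_breath_series(bt), c(10, 100)))
    expect_gte(f[["pibi50"]], 0); expect_lte(f[["pibi50"]], 1)
    expect_gte(f[["lf"]], 0); expect_gte(f[["hf"]], 0)
    if (f[["hf"]] > 0)
      expect_equal(f[["lf_hf"]], f[["lf"]] / f[["hf"]], tolerance = 1e-12)
    expect_true(all(f[grepl("_sd$", names(f))] >= 0))
  }
})
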