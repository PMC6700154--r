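fake_profile <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(dG_sd_TM = rnorm(n), dG_sds_TM = rnorm(n),
             dG_sd_EM = rnorm(n), dG_sds_EM = rnorm(n),
             log_N = log(n), chain = "A", stringsAsFactors = FALSE)
}

model_with <- function(alpha, a0 = 0) {
  structure(list(alpha = alpha, a0 = a0, meta = list()),
            class = "localization_model")
}

test_that("the localization index is the stated linear combination", {
  prof <- fake_profile(10)
  expect_equal(localization_index(prof, model_with(rep(0, 6))), rep(0, 10))
  expect_equal(localization_index(prof, model_with(c(0, 0, 0, 0, 0, 1))),
               rep(1, 10))
  m <- model_with(c(1, 0, 0, 0, 0, 0))
  expect_equal(localization_index(prof, m), prof$dG_sd_TM)
  m2 <- model_with(c(0.5, -1, 2, 0.25, 3, -7))
  want <- 0.5 * prof$dG_sd_TM - prof$dG_sds_TM + 2 * prof$dG_sd_EM +
    0.25 * prof$dG_sds_EM + 3 * log(10) - 7
  expect_equal(localization_index(prof, m2, N = 10), want)
  expect_error(localization_index(prof, m2, N = 0), "at least 1")
})

test_that("chain smoothing uses the half-prefactor window with terminus rescale", {
  # constant index: interior value is (5/2) c
  expect_equal(smooth_index(rep(2, 9))[3:7], rep(5, 5))
  # unit impulse: center picks up 1/2
  expect_equal(smooth_index(c(0, 0, 1, 0, 0))[3], 0.5)
  # terminus of a 5-residue chain: m = 3 available, rescaled by 5/3
  v <- c(1, 2, 3, 4, 5)
  expect_equal(smooth_index(v)[1], 0.5 * (5 / 3) * (1 + 2 + 3))
  expect_equal(smooth_index(v)[2], 0.5 * (5 / 4) * (1 + 2 + 3 + 4))
  expect_equal(smooth_index(v)[3], 0.5 * (1 + 2 + 3 + 4 + 5))
  # windows never cross chain boundaries
  ch <- rep(c("A", "B"), each = 5)
  two <- smooth_index(rep(1, 10), ch)
  expect_equal(two, rep(smooth_index(rep(1, 5)), 2))
  expect_error(smooth_index(numeric(0)), "empty")
})

test_that("balanced accuracy and rank AUC behave on canonical cases", {
  truth <- rep(c("TM", "EM"), each = 50)
  # identical scores: no discrimination
  expect_equal(auc_low_positive(rep(1, 100), truth), 0.5)
  # perfect ordering, TM all lower
  sc <- c(seq_len(50), 100 + seq_len(50))
  expect_equal(auc_low_positive(sc, truth), 1.0)
  expect_equal(balanced_accuracy(truth, ifelse(sc <= 75, "TM", "EM")), 1.0)
  # random scores concentrate at 1/2
  set.seed(99)
  expect_equal(auc_low_positive(runif(1e4), rep(c("TM", "EM"), 5e3)), 0.5,
               tolerance = 0.02)
})

test_that("rank AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  sc <- rnorm(500)
  truth <- runif(500) < 0.4
  ours <- auc_low_positive(sc, truth)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = sc, levels = c(FALSE, TRUE),
    direction = ">", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("the threshold sweep attains the exhaustive BACC maximum", {
  set.seed(13)
  for (rep in 1:5) {
    n <- 400
    sc <- round(rnorm(n), 1)              # ties on purpose
    truth <- runif(n) < plogis(-sc)       # low score more likely TM
    truth[1] <- TRUE; truth[2] <- FALSE   # both classes guaranteed
    sw <- sweep_threshold(sc, truth)
    # oracle: BACC of "score <= t" over every candidate threshold
    cand <- sort(unique(c(sc - 0.05, sc, sc + 0.05)))
    best <- max(vapply(cand, function(t)
      balanced_accuracy(truth, sc <= t), numeric(1)))
    expect_equal(sw$bacc, best, tolerance = 1e-12)
    expect_equal(balanced_accuracy(truth, sc <= sw$a0), sw$bacc,
                 tolerance = 1e-12)
  }
  expect_error(sweep_threshold(1:5, rep(TRUE, 5)), "both classes")
})

test_that("separable features are fit to training BACC 1", {
  n <- 200
  feats <- fake_profile(n, seed = 4)
  truth <- feats$dG_sd_TM < 0
  feats$dG_sd_TM <- feats$dG_sd_TM + ifelse(truth, -5, 5)
  # one residue per chain: separability must survive the smoothing
  feats$chain <- as.character(seq_len(n))
  m <- fit_localization_model(feats, truth)
  expect_equal(m$training$bacc, 1.0)
  sc <- mempot:::model_scores(m, feats)
  expect_equal(unname(classify_and_evaluate(sc$I_sm, truth, m$a0)
                      $metrics["auc"]), 1.0)
})

test_that("permuted labels fit to chance-level BACC", {
  set.seed(31)
  n <- 1e4
  feats <- fake_profile(n, seed = 31)
  truth <- sample(rep(c(TRUE, FALSE), n / 2))
  m <- fit_localization_model(feats, truth)
  # training BACC exceeds 1/2 by construction (sweep optimizes), but
  # on independent permuted labels the model carries no signal
  truth2 <- sample(truth)
  sc <- mempot:::model_scores(m, feats)
  bacc2 <- balanced_accuracy(truth2, sc$I_sm <= m$a0)
  expect_equal(bacc2, 0.5, tolerance = 0.03)
  expect_equal(unname(classify_and_evaluate(sc$I_sm, truth2, m$a0)
                      $metrics["auc"]), 0.5, tolerance = 0.03)
})

test_that("duplicating every training row leaves the fit unchanged", {
  feats <- fake_profile(300, seed = 6)
  truth <- feats$dG_sds_EM + 0.3 * rnorm(300) > 0
  m1 <- fit_localization_model(feats, truth)
  m2 <- fit_localization_model(rbind(feats, feats), c(truth, truth))
  expect_equal(m2$alpha, m1$alpha, tolerance = 1e-6)
  expect_equal(m2$a0, m1$a0, tolerance = 1e-6)
})

test_that("rescaling the energy features does not change predictions", {
  feats <- fake_profile(400, seed = 16)
  truth <- feats$dG_sd_TM + feats$dG_sds_TM < 0
  m1 <- fit_localization_model(feats, truth)
  feats2 <- feats
  for (cc in c("dG_sd_TM", "dG_sds_TM", "dG_sd_EM", "dG_sds_EM"))
    feats2[[cc]] <- 10 * feats2[[cc]]
  m2 <- fit_localization_model(feats2, truth)
  p1 <- mempot:::model_scores(m1, feats)$I_sm <= m1$a0
  p2 <- mempot:::model_scores(m2, feats2)$I_sm <= m2$a0
  expect_equal(p1, p2)
})

test_that("decision rule is monotone: lower smoothed index never flips TM to EM", {
  m <- model_with(rep(0, 6), a0 = 0.7)
  I_sm <- seq(-2, 2, length.out = 41)
  calls <- I_sm <= m$a0
  expect_true(all(diff(as.integer(calls)) <= 0))
})

test_that("classification errors on missing labels and single class", {
  expect_error(classify_and_evaluate(1:4, c("TM", NA, "EM", "EM"), 0),
               "missing")
  expect_error(fit_localization_model(fake_profile(10), rep(TRUE, 10)),
               "both classes")
})

test_that("models persist to JSON and back", {
  feats <- fake_profile(100, seed = 3)
  truth <- feats$dG_sd_EM > 0
  m <- fit_localization_model(feats, truth, seed = 42L)
  path <- withr::local_tempfile(fileext = ".json")
  write_localization_model(m, path)
  back <- read_localization_model(path)
  expect_equal(back$alpha, m$alpha)
  expect_equal(back$a0, m$a0)
  expect_equal(coef(back), coef(m))
  expect_named(coef(m), paste0("alpha", 0:6))
})

test_that("the strict LOO benchmark enforces its preconditions", {
  gen <- generate_structures(fixture_config(n_proteins = 2), seed = 2)
  expect_error(run_loo_benchmark(lapply(gen, `[[`, "structure")),
               "at least 3")
})
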