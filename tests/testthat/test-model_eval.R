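# a separable toy set: exact one-hot class markers plus pure-noise columns
toy_feature_matrix <- function(n_per_class = 15, classes = all_labels(),
                               seed = 1) {
  set.seed(seed)
  n <- n_per_class * length(classes)
  labels <- rep(classes, each = n_per_class)
  markers <- outer(labels, classes, "==") * 1
  x <- cbind(markers, matrix(rnorm(n * 3, sd = 0.05), n))
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  structure(list(x = x, labels = labels, mode = "toy"),
            class = "feature_matrix")
}

test_that("the registry holds exactly the twelve named classifiers", {
  reg <- model_registry()
  expect_named(reg, c("LR", "NB", "DT", "SVM", "MLP", "Ridge", "RF", "QDA",
                      "Ada", "GBC", "LDA", "LGBM"))
  for (m in reg) {
    expect_true(is.function(m$fit))
    expect_true(is.function(m$predict))
  }
  expect_error(model_registry("nope"), "unknown")
})

test_that("every model separates the toy problem perfectly", {
  fm <- toy_feature_matrix()
  res <- run_cv(fm, model_registry(), k = 5, seed = 3)
  s <- summary(res)
  expect_equal(nrow(s), 12)
  for (i in seq_len(nrow(s))) {
    expect_equal(s$mean_accuracy[i], 1.0,
                 info = paste("model", s$model[i]))
  }
})

test_that("stratified folds split every class evenly", {
  fm <- toy_feature_matrix(n_per_class = 10)
  fold <- cv_folds(fm$labels, k = 5, seed = 2)
  tab <- table(fm$labels, fold)
  expect_true(all(tab == 2))  # 10 per class over 5 folds
  res <- run_cv(fm, model_registry("Ridge"), k = 5, seed = 2)
  expect_equal(unique(res$n_train), 56)
  expect_equal(unique(res$n_test), 14)
  expect_equal(sort(unique(res$fold)), 1:5)
  expect_error(run_cv(toy_feature_matrix(n_per_class = 3),
                      model_registry("Ridge"), k = 5),
               "fewer than k")
})

test_that("amplitude-coded classes push the waveform-shape features down", {
  # two classes that differ only in amplitude: MC/ZC/ARC carry no class
  # signal, so they must occupy the lowest ranks
  set.seed(8)
  mk <- function(label, amp, n) {
    lapply(seq_len(n), function(i) {
      list(samples = matrix(rnorm(200 * 6, sd = amp), ncol = 6),
           label = label)
    })
  }
  windows <- c(mk("LEb", 1, 20), mk("Bk", 3, 20))
  rk <- rank_single_features(windows, model_registry("LDA"), k = 5, seed = 4)
  expect_equal(nrow(rk), 8)
  expect_setequal(rk$family, feature_families())
  expect_setequal(rk$family[1:3], c("MC", "ZC", "ARC"))
  expect_true(all(rk$mean_accuracy[4:8] > max(rk$mean_accuracy[1:3])))
})

test_that("full ties fall back to the declared feature order", {
  # all-zero windows: every family yields an identical constant design
  # matrix, so all eight accuracies tie exactly
  windows <- lapply(1:20, function(i) {
    list(samples = matrix(0, 200, 6),
         label = if (i <= 10) "LEb" else "Bk")
  })
  rk <- rank_single_features(windows, model_registry("NB"), k = 5, seed = 1)
  expect_equal(rk$family, feature_families())
  expect_equal(length(unique(rk$mean_accuracy)), 1)
})

test_that("the reduction schedule ends at VAR, RMS and MAC", {
  steps <- reduction_steps()
  expect_length(steps, 8)
  expect_equal(lengths(steps), 8:1)
  expect_setequal(steps[[6]], c("VAR", "RMS", "MAC"))
  expect_equal(steps[[8]], "MAC")
  expect_error(reduction_steps(c("MC", "ZC")), "permutation")
  expect_error(reduction_steps(rep("MC", 8)), "permutation")
})

test_that("the reduction curve tracks accuracy and monotone cost", {
  w <- small_windows()[seq(1, 288, by = 2)]
  curve <- feature_reduction_curve(w, model = "LDA", k = 3, seed = 2)
  expect_equal(curve$n_features, 8:1)
  expect_setequal(strsplit(curve$families[curve$n_features == 3], ",")[[1]],
                  c("VAR", "RMS", "MAC"))
  expect_true(all(diff(curve$feature_time_s) <= 1e-12))
  expect_true(all(curve$mean_accuracy >= 0 & curve$mean_accuracy <= 1))
})

test_that("mode comparison runs paired t-tests per model", {
  set.seed(21)
  grid <- expand.grid(subject = paste0("S", 1:7),
                      model = names(model_registry()),
                      stringsAsFactors = FALSE)
  sf <- transform(grid, accuracy = 0.90 + rnorm(nrow(grid), sd = 0.002))
  af <- transform(grid, accuracy = sf$accuracy + 0.05 +
                    rnorm(nrow(grid), sd = 1e-4))
  ef <- sf; ef$accuracy <- af$accuracy  # identical to AF
  rep <- compare_modes(sf, af, ef)
  expect_equal(nrow(rep), 12)
  expect_true(all(rep$p_sf_vs_af < 0.01))
  expect_true(all(rep$p_ef_vs_af == 1))  # identical vectors
  bad <- af[-1, ]
  expect_error(compare_modes(sf, bad, ef), "pairing")
  shifted <- sf; shifted$accuracy <- sf$accuracy + 0.05  # exact constant
  expect_error(compare_modes(sf, shifted, shifted), "zero variance")
})

test_that("permutation test matches exhaustive enumeration", {
  expect_equal(permutation_test(c(3, 3, 3), c(3, 3, 3)), 1.0)
  expect_equal(permutation_test(rep(1, 5), rep(9, 5)), 2 / 252)
  set.seed(14)
  for (i in 1:5) {
    a <- round(runif(sample(3:6, 1), 0, 10), 1)
    b <- round(runif(sample(3:6, 1), 0, 10), 1)
    expect_equal(permutation_test(a, b), perm_oracle(a, b))
  }
  # Monte-Carlo branch obeys the add-one floor
  p <- permutation_test(1:5, 6:10 + 90, n_perm = 200, seed = 2,
                        exhaustive_limit = 1)
  expect_gte(p, 1 / 201)
  expect_lte(p, 1)
  expect_error(permutation_test(numeric(0), 1:3), "non-empty")
  expect_error(permutation_test(1:3, 1:3, n_perm = 0), "n_perm")
})
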