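test_that("constant and tiny hand-computed windows give the known values", {
  f <- compute_feature_set(rep(2.5, 50))
  expect_equal(unname(f[c("mav", "rms", "max")]), c(2.5, 2.5, 2.5))
  expect_equal(unname(f[c("mc", "mac", "zc", "var")]), c(0, 0, 0, 0))
  # the 3-point vector (AR(3) undefined there)
  f3 <- compute_feature_set(c(1, -1, 2), include_arc = FALSE)
  expect_equal(unname(f3["mav"]), 4 / 3)
  expect_equal(unname(f3["rms"]), sqrt(2))
  expect_equal(unname(f3["mc"]), 1 / 3)
  expect_equal(unname(f3["mac"]), 5 / 3)
  expect_equal(unname(f3["max"]), 2)
  expect_equal(unname(f3["zc"]), 2)
  expect_equal(unname(f3["var"]), 7 / 3)
  expect_error(compute_feature_set(c(1, -1, 2)), "4 samples")
  expect_error(compute_feature_set(c(1, NA, 2, 3)), "finite")
})

test_that("sign flip fixes even features and negates the odd ones", {
  set.seed(31)
  x <- rnorm(100)
  f <- compute_feature_set(x)
  g <- compute_feature_set(-x)
  for (k in c("mav", "rms", "mac", "zc", "var")) {
    expect_equal(unname(g[k]), unname(f[k]))
  }
  expect_equal(unname(g["mc"]), -unname(f["mc"]))
  expect_equal(unname(g["max"]), -min(x))
})

test_that("exact zeros never count as zero crossings", {
  expect_equal(unname(compute_feature_set(c(1, 0, -1, 1))["zc"]), 1)
  expect_equal(unname(compute_feature_set(c(0, 0, 0, 0))["zc"]), 0)
})

test_that("every feature matches the naive loop oracle on random windows", {
  set.seed(202)
  worst <- 0
  for (i in 1:1000) {
    x <- rnorm(sample(20:200, 1), sd = runif(1, 0.1, 5))
    mine <- compute_feature_set(x)
    ref <- c(naive_feature_oracle(x),
             stats::setNames(arc_oracle(x), c("arc1", "arc2", "arc3")))
    worst <- max(worst, max(abs(mine - ref[names(mine)]) /
                              pmax(abs(ref[names(mine)]), 1e-12)))
  }
  expect_lt(worst, 1e-10)
})

test_that("MC telescopes and amplitude scaling acts as expected", {
  set.seed(77)
  for (i in 1:50) {
    x <- rnorm(120)
    f <- compute_feature_set(x)
    expect_equal(unname(f["mc"]), (x[120] - x[1]) / 120)
    lam <- runif(1, 0.1, 10)
    g <- compute_feature_set(lam * x)
    expect_equal(unname(g[c("mav", "rms", "mac", "max")]),
                 unname(lam * f[c("mav", "rms", "mac", "max")]))
    expect_equal(unname(g["var"]), unname(lam^2 * f["var"]))
    expect_equal(unname(g["zc"]), unname(f["zc"]))
  }
})

test_that("AR(3) estimation recovers known coefficients", {
  a_true <- c(0.6, -0.3, 0.1)  # stable AR(3)
  set.seed(5)
  x <- as.numeric(stats::arima.sim(list(ar = a_true), n = 20000, sd = 1))
  yw <- compute_feature_set(x)[c("arc1", "arc2", "arc3")]
  expect_equal(unname(yw), a_true, tolerance = 0.05)
  ls <- compute_feature_set(x, arc_method = "least_squares")[
    c("arc1", "arc2", "arc3")]
  expect_equal(unname(ls), a_true, tolerance = 0.05)
})

test_that("VAR as-printed reproduces the truncated sum", {
  set.seed(13)
  x <- rnorm(60)
  v <- compute_feature_set(x, var_as_printed = TRUE)["var"]
  expect_equal(unname(v), sum((x[1:59] - mean(x))^2) / 59)
  expect_equal(unname(compute_feature_set(x)["var"]), var(x))
})

test_that("assembled design matrices have the documented shapes", {
  w <- small_windows()[1:40]
  af <- assemble_features(w, "AF")
  expect_equal(dim(af$x), c(40, 60))
  expect_equal(colnames(af$x)[1:3], c("ch1_mav", "ch1_rms", "ch1_mc"))
  expect_equal(colnames(af$x)[11], "ch2_mav")  # channel-major layout
  ef <- assemble_features(w, "EF")
  expect_equal(ncol(ef$x), 18)
  expect_setequal(unique(sub("^ch._", "", colnames(ef$x))),
                  c("rms", "mac", "var"))
  expect_equal(ncol(assemble_features(w, "SF:RMS")$x), 6)
  expect_equal(ncol(assemble_features(w, "SF:ARC")$x), 18)
  expect_error(assemble_features(w, "SF:WAV"), "unknown")
  expect_error(assemble_features(list(), "AF"), "no windows")
  expect_equal(af$labels, vapply(w, `[[`, character(1), "label"))
})

test_that("vectorised assembly agrees with the scalar path", {
  w <- small_windows()[seq(1, 280, by = 24)]
  af <- assemble_features(w, "AF")
  for (i in seq_along(w)) {
    for (ch in c(1, 4)) {
      f <- compute_feature_set(w[[i]]$samples[, ch])
      cols <- paste0("ch", ch, "_", names(f))
      expect_equal(unname(af$x[i, cols]), unname(f), tolerance = 1e-12)
    }
  }
})
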