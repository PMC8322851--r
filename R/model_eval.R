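# Offline evaluation harness: 12-classifier registry, stratified k-fold CV,
# single-feature ranking, sequential feature reduction and the statistical
# comparisons (paired t-test, permutation test).

as_label_factor <- function(labels) factor(labels, levels = all_labels())

# closed-form ridge classifier: L2 least squares on +/-1 one-hot targets
fit_ridge_classifier <- function(x, y, lambda = 1) {
  lev <- levels(y)
  Y <- 2 * (outer(as.integer(y), seq_along(lev), function(i, j) i == j)) - 1
  xm <- colMeans(x); ym <- colMeans(Y)
  Xc <- sweep(x, 2, xm); Yc <- sweep(Y, 2, ym)
  W <- solve(crossprod(Xc) + lambda * diag(ncol(x)), crossprod(Xc, Yc))
  list(W = W, xm = xm, ym = ym, lev = lev)
}

predict_ridge_classifier <- function(m, x) {
  S <- sweep(as.matrix(x), 2, m$xm) %*% m$W
  S <- sweep(S, 2, m$ym, "+")
  m$lev[max.col(S, ties.method = "first")]
}

# SAMME AdaBoost over depth-1 rpart stumps
fit_adaboost <- function(x, y, n_estimators = 50L, seed = 1L) {
  df <- data.frame(y = y, x, check.names = FALSE)
  n <- nrow(df); K <- nlevels(y)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = 1, cp = 0, minsplit = 2,
                               xval = 0, maxcompete = 0, maxsurrogate = 0)
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w, method = "class",
                        control = ctrl)
    pred <- predict(fit, df, type = "class")
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 1 - 1 / K) break
    if (err <= 0) {
      stumps[[length(stumps) + 1L]] <- fit
      alphas <- c(alphas, 10)  # perfect stump dominates
      break
    }
    alpha <- log((1 - err) / err) + log(K - 1)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
  }
  list(stumps = stumps, alphas = alphas, lev = levels(y))
}

predict_adaboost <- function(m, x) {
  df <- data.frame(as.data.frame(x), check.names = FALSE)
  S <- matrix(0, nrow(df), length(m$lev))
  for (i in seq_along(m$stumps)) {
    pred <- predict(m$stumps[[i]], df, type = "class")
    S <- S + m$alphas[i] * outer(as.integer(pred), seq_along(m$lev), "==")
  }
  m$lev[max.col(S, ties.method = "first")]
}

fit_xgb <- function(x, y, seed, extra = list()) {
  params <- utils::modifyList(list(objective = "multi:softmax",
                                   num_class = nlevels(y),
                                   max_depth = 3, eta = 0.1,
                                   nthread = 1, seed = seed), extra)
  dtrain <- xgboost::xgb.DMatrix(as.matrix(x),
                                 label = as.integer(y) - 1L)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = 100, verbose = 0)
  list(booster = booster, lev = levels(y))
}

predict_xgb <- function(m, x) {
  p <- predict(m$booster, xgboost::xgb.DMatrix(as.matrix(x)))
  m$lev[as.integer(p) + 1L]
}

# QDA/LDA can hit exact within-class collinearity on degenerate synthetic
# input; retry once with a small deterministic jitter scaled to the data.
fit_da <- function(fun, x, y, seed) {
  tryCatch(fun(x, grouping = y),
           error = function(e) {
             sd_j <- 1e-3 * max(stats::sd(as.numeric(x)), 1)
             with_seed(seed, fun(x + matrix(stats::rnorm(length(x), sd = sd_j),
                                            nrow(x)), grouping = y))
           })
}

#' The twelve-classifier registry
#'
#' Named list of classifier specifications, each with `fit(x, y, seed)` and
#' `predict(model, x)` closures: LR (multinomial logistic), NB (Gaussian
#' naive Bayes), DT (CART decision tree), SVM (linear kernel), MLP
#' (single-hidden-layer perceptron), Ridge (closed-form L2 least-squares
#' classifier), RF (random forest), QDA, Ada (SAMME AdaBoost over stumps),
#' GBC (gradient-boosted trees), LDA, and LGBM (leaf-wise histogram
#' gradient boosting). Hyperparameters are fixed library defaults; all
#' stochastic fits take the supplied seed.
#'
#' @param models optional character subset of the 12 names.
#' @return named list of model specs.
#' @export
model_registry <- function(models = NULL) {
  reg <- list(
    LR = list(
      fit = function(x, y, seed) {
        df <- data.frame(y = y, x, check.names = FALSE)
        m <- nnet::multinom(y ~ ., data = df, trace = FALSE, maxit = 200,
                            MaxNWts = 10000)
        list(m = m)
      },
      predict = function(model, x) {
        as.character(predict(model$m,
                             data.frame(as.data.frame(x), check.names = FALSE)))
      }),
    NB = list(
      fit = function(x, y, seed) list(m = e1071::naiveBayes(x, y)),
      predict = function(model, x) as.character(predict(model$m, x))),
    DT = list(
      fit = function(x, y, seed) {
        df <- data.frame(y = y, x, check.names = FALSE)
        list(m = rpart::rpart(y ~ ., data = df, method = "class"))
      },
      predict = function(model, x) {
        as.character(predict(model$m,
                             data.frame(as.data.frame(x), check.names = FALSE),
                             type = "class"))
      }),
    SVM = list(
      fit = function(x, y, seed) {
        list(m = suppressWarnings(e1071::svm(x, y, kernel = "linear")))
      },
      predict = function(model, x) as.character(predict(model$m, x))),
    MLP = list(
      fit = function(x, y, seed) {
        with_seed(seed, {
          m <- nnet::nnet(x, nnet::class.ind(y), size = 16, softmax = TRUE,
                          decay = 1e-3, maxit = 200, trace = FALSE,
                          MaxNWts = 20000)
          list(m = m, lev = levels(y))
        })
      },
      predict = function(model, x) {
        p <- predict(model$m, x)
        model$lev[max.col(p, ties.method = "first")]
      }),
    Ridge = list(
      fit = function(x, y, seed) fit_ridge_classifier(x, y),
      predict = predict_ridge_classifier),
    RF = list(
      fit = function(x, y, seed) {
        list(m = ranger::ranger(x = x, y = y, num.trees = 300, seed = seed,
                                num.threads = 1))
      },
      predict = function(model, x) {
        as.character(predict(model$m, data = x,
                             num.threads = 1)$predictions)
      }),
    QDA = list(
      fit = function(x, y, seed) list(m = fit_da(MASS::qda, x, y, seed)),
      predict = function(model, x) as.character(predict(model$m, x)$class)),
    Ada = list(
      fit = function(x, y, seed) fit_adaboost(x, y, seed = seed),
      predict = predict_adaboost),
    GBC = list(
      # exact greedy splits, depth-wise: the classical gradient-boosting
      # classifier (leaf-wise histogram variant is the LGBM entry)
      fit = function(x, y, seed) {
        fit_xgb(x, y, seed, extra = list(tree_method = "exact"))
      },
      predict = predict_xgb),
    LDA = list(
      fit = function(x, y, seed) list(m = fit_da(MASS::lda, x, y, seed)),
      predict = function(model, x) as.character(predict(model$m, x)$class)),
    LGBM = list(
      fit = function(x, y, seed) {
        fit_xgb(x, y, seed, extra = list(tree_method = "hist",
                                         grow_policy = "lossguide",
                                         max_leaves = 31, max_depth = 0))
      },
      predict = predict_xgb)
  )
  if (!is.null(models)) {
    bad <- setdiff(models, names(reg))
    if (length(bad)) stop("unknown models: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    reg <- reg[models]
  }
  reg
}

#' Stratified fold assignment
#'
#' Per class: seeded shuffle, then round-robin assignment to k folds, so a
#' class with a multiple of k members splits exactly (e.g. 400 windows per
#' action at k = 5 give 320 train / 80 test in every fold).
#'
#' @param labels character or factor labels, one per row.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer fold index (1..k) per row.
#' @export
cv_folds <- function(labels, k = 5L, seed = 1L) {
  stratified_folds(droplevels(as_label_factor(labels)), k, seed)
}

# stratified fold assignment: per class, seeded shuffle then round-robin
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      if (length(idx) > 0 && length(idx) < k) {
        stop("class ", cl, " has fewer than k = ", k, " samples",
             call. = FALSE)
      }
      fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Stratified k-fold cross-validation over a model registry
#'
#' Splits the rows of a feature matrix into k stratified folds (exact
#' per-class 80/20 splits at k = 5 when class counts are divisible by 5),
#' trains each registry model on k-1 folds and scores accuracy on the held
#' out fold.
#'
#' @param fm a [assemble_features()] feature matrix.
#' @param registry a [model_registry()] (or subset).
#' @param k number of folds (default 5).
#' @param seed integer seed controlling the shuffle and all model fits.
#' @return object of class `cv_result`: data.frame with columns `model`,
#'   `fold`, `accuracy`, `n_train`, `n_test`, plus a `summary()` method.
#' @export
run_cv <- function(fm, registry = model_registry(), k = 5L, seed = 1L) {
  y <- droplevels(as_label_factor(fm$labels))
  fold <- stratified_folds(y, k, seed)
  rows <- list()
  for (mn in names(registry)) {
    spec <- registry[[mn]]
    for (f in seq_len(k)) {
      tr <- fold != f; te <- !tr
      model <- spec$fit(fm$x[tr, , drop = FALSE], droplevels(y[tr]),
                        seed = seed + f)
      pred <- spec$predict(model, fm$x[te, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        model = mn, fold = f,
        accuracy = mean(pred == as.character(y[te])),
        n_train = sum(tr), n_test = sum(te),
        stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows), class = c("cv_result", "data.frame"))
}

#' Summarise a CV result
#' @param object a [run_cv()] result.
#' @param ... unused.
#' @return data.frame with per-model mean and sd accuracy.
#' @export
summary.cv_result <- function(object, ...) {
  agg <- stats::aggregate(accuracy ~ model, data = object,
                          FUN = function(a) c(mean = mean(a), sd = stats::sd(a)))
  data.frame(model = agg$model,
             mean_accuracy = agg$accuracy[, "mean"],
             sd_accuracy = agg$accuracy[, "sd"],
             stringsAsFactors = FALSE)
}

#' Rank the eight features by single-feature accuracy
#'
#' Runs CV for each `SF:<family>` design matrix and orders the families by
#' the model-averaged mean accuracy, ascending (worst first). Ties break by
#' the canonical declared feature order.
#'
#' @param windows labelled windows ([segment_dataset()]).
#' @param registry a [model_registry()] (or subset).
#' @param k folds (default 5).
#' @param seed integer seed.
#' @return data.frame with columns `family` (ordered ascending) and
#'   `mean_accuracy`.
#' @export
rank_single_features <- function(windows, registry = model_registry(),
                                 k = 5L, seed = 1L) {
  fams <- feature_families()
  acc <- vapply(fams, function(f) {
    fm <- assemble_features(windows, paste0("SF:", f))
    mean(run_cv(fm, registry, k, seed)$accuracy)
  }, numeric(1))
  ord <- order(acc, match(fams, fams))
  data.frame(family = fams[ord], mean_accuracy = acc[ord],
             stringsAsFactors = FALSE)
}

#' Family sets along a sequential removal order
#'
#' Structural companion to [feature_reduction_curve()]: starting from all 8
#' families, drop one per step following `removal_order`; step j keeps
#' 8 - j + 1 families. With the default order the last three surviving
#' families are VAR, RMS and MAC.
#'
#' @param removal_order permutation of [feature_families()] (default is the
#'   ascending single-feature ranking MC, ZC, ARC, MAV, MAX, VAR, RMS, MAC).
#' @return list of character vectors, lengths 8 down to 1.
#' @export
reduction_steps <- function(removal_order = c("MC", "ZC", "ARC", "MAV",
                                              "MAX", "VAR", "RMS", "MAC")) {
  if (!setequal(removal_order, feature_families()) ||
      length(removal_order) != 8L) {
    stop("removal_order must be a permutation of the 8 feature families",
         call. = FALSE)
  }
  lapply(0:7, function(j) {
    keep <- setdiff(removal_order, removal_order[seq_len(j)])
    feature_families()[feature_families() %in% keep]
  })
}

#' Sequential feature-reduction curve
#'
#' Removes one feature family per step in `removal_order`, recording the CV
#' accuracy of `model` and the feature-computation cost of the surviving
#' set. Cost is measured once per family (wall-clock of computing that
#' family's columns over all windows) and summed over survivors, so the
#' curve is monotone in the set size by construction.
#'
#' @inheritParams rank_single_features
#' @param removal_order permutation of the 8 families.
#' @param model registry name to evaluate (default `"GBC"`).
#' @return data.frame with columns `n_features`, `families`
#'   (comma-collapsed), `mean_accuracy`, `feature_time_s`.
#' @export
feature_reduction_curve <- function(windows,
                                    removal_order = c("MC", "ZC", "ARC",
                                                      "MAV", "MAX", "VAR",
                                                      "RMS", "MAC"),
                                    model = "GBC", k = 5L, seed = 1L) {
  steps <- reduction_steps(removal_order)
  reg <- model_registry(model)
  fam_time <- vapply(feature_families(), function(f) {
    system.time(assemble_features(windows, paste0("SF:", f)))[["elapsed"]]
  }, numeric(1))
  rows <- lapply(steps, function(fams) {
    fm <- assemble_features(windows, fams)
    data.frame(n_features = length(fams),
               families = paste(fams, collapse = ","),
               mean_accuracy = mean(run_cv(fm, reg, k, seed)$accuracy),
               feature_time_s = sum(fam_time[fams]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

paired_t_p <- function(a, b) {
  if (length(a) != length(b)) stop("mismatched pairing", call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(1)
    stop("zero variance of non-zero paired differences", call. = FALSE)
  }
  stats::t.test(a, b, paired = TRUE)$p.value
}

#' Compare feature-assembly modes across subjects
#'
#' Per model: mean and sd accuracy in each mode and paired t-tests (across
#' subjects) of best-single-feature vs all-features and elected vs
#' all-features. Inputs are per-subject per-model accuracies; the SF input
#' should already be the per-subject maximum over families.
#'
#' @param results_sf,results_af,results_ef data.frames with columns
#'   `subject`, `model`, `accuracy`, identically paired.
#' @return data.frame with one row per model: means, sds, `p_sf_vs_af`,
#'   `p_ef_vs_af`.
#' @export
compare_modes <- function(results_sf, results_af, results_ef) {
  key <- function(d) paste(d$subject, d$model)
  a <- results_sf[order(key(results_sf)), ]
  b <- results_af[order(key(results_af)), ]
  c_ <- results_ef[order(key(results_ef)), ]
  if (!identical(key(a), key(b)) || !identical(key(a), key(c_))) {
    stop("mismatched subject/model pairing across modes", call. = FALSE)
  }
  rows <- lapply(unique(a$model), function(mn) {
    ia <- a$model == mn
    data.frame(model = mn,
               sf_mean = mean(a$accuracy[ia]), sf_sd = stats::sd(a$accuracy[ia]),
               af_mean = mean(b$accuracy[ia]), af_sd = stats::sd(b$accuracy[ia]),
               ef_mean = mean(c_$accuracy[ia]), ef_sd = stats::sd(c_$accuracy[ia]),
               p_sf_vs_af = paired_t_p(a$accuracy[ia], b$accuracy[ia]),
               p_ef_vs_af = paired_t_p(c_$accuracy[ia], b$accuracy[ia]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-sided permutation test for a difference in means
#'
#' Exchanges group labels and compares |mean(a) - mean(b)|. When the number
#' of distinct regroupings is at most `exhaustive_limit`, all are
#' enumerated and the p-value is exact; otherwise `n_perm` seeded random
#' permutations are drawn and the add-one estimate (b + 1) / (m + 1) is
#' returned.
#'
#' @param times_a,times_b numeric vectors (non-empty).
#' @param n_perm Monte-Carlo permutations (default 10000).
#' @param seed integer seed.
#' @param exhaustive_limit switch to exact enumeration when
#'   `choose(n, n_a)` does not exceed this (default 1e6).
#' @return p-value in (0, 1].
#' @export
permutation_test <- function(times_a, times_b, n_perm = 10000L, seed = 1L,
                             exhaustive_limit = 1e6) {
  if (length(times_a) == 0 || length(times_b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  pooled <- c(times_a, times_b)
  na <- length(times_a); n <- length(pooled)
  obs <- abs(mean(times_a) - mean(times_b))
  tol <- 1e-12 * max(1, obs)
  stat_for <- function(idx_a) {
    abs(mean(pooled[idx_a]) - mean(pooled[-idx_a]))
  }
  if (choose(n, na) <= exhaustive_limit) {
    combos <- utils::combn(n, na)
    hits <- sum(apply(combos, 2, stat_for) >= obs - tol)
    hits / ncol(combos)
  } else {
    with_seed(seed, {
      hits <- sum(vapply(seq_len(n_perm), function(i) {
        stat_for(sample(n, na)) >= obs - tol
      }, logical(1)))
      (hits + 1) / (n_perm + 1)
    })
  }
}
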