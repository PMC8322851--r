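# Eight time-domain window features per channel: MAV, RMS, MC, MAC, MAX, ZC,
# VAR and the three coefficients of an order-3 autoregressive model (ARC).

#' Feature families
#'
#' The eight time-domain features, in the canonical declared order used for
#' column layout and tie-breaking. `ARC` expands to three columns
#' (coefficients a1..a3); every other family is one column per channel.
#'
#' @return character vector of the 8 family names.
#' @export
feature_families <- function() {
  c("MAV", "RMS", "MC", "MAC", "MAX", "ZC", "VAR", "ARC")
}

#' Elected feature subset
#'
#' The three features kept for online use after single-feature ranking and
#' sequential reduction: VAR, RMS and MAC.
#' @return character vector of length 3.
#' @export
elected_features <- function() c("VAR", "RMS", "MAC")

feature_columns <- function(families = feature_families()) {
  unlist(lapply(families, function(f) {
    if (f == "ARC") c("arc1", "arc2", "arc3") else tolower(f)
  }))
}

# order-3 Yule-Walker on the biased, non-demeaned autocovariance
arc_yule_walker <- function(x, p = 3L) {
  n <- length(x)
  r <- vapply(0:p, function(k) sum(x[seq_len(n - k)] * x[(k + 1):n]) / n,
              numeric(1))
  if (r[1] <= 0) return(rep(0, p))
  a <- tryCatch(solve(stats::toeplitz(r[1:p]), r[2:(p + 1)]),
                error = function(e) rep(0, p))
  as.numeric(a)
}

# least-squares (covariance method) alternative
arc_least_squares <- function(x, p = 3L) {
  n <- length(x)
  X <- sapply(1:p, function(k) x[(p + 1 - k):(n - k)])
  y <- x[(p + 1):n]
  a <- tryCatch(qr.solve(X, y), error = function(e) rep(0, p))
  as.numeric(a)
}

#' Compute the time-domain feature set of one window channel
#'
#' For a window `x` of `N` samples:
#' MAV = mean(|x|); RMS = sqrt(mean(x^2)); MC = sum(diff(x))/N (which
#' telescopes to (x_N - x_1)/N); MAC = sum(|diff(x)|)/N; MAX = max(x);
#' ZC counts strict sign changes (x_i * x_{i+1} < 0; exact zeros never
#' count); VAR is the sample variance (denominator N-1); ARC are the three
#' coefficients of the AR(3) model x_i = a1 x_{i-1} + a2 x_{i-2} +
#' a3 x_{i-3} + e_i.
#'
#' @param x numeric vector of N >= 4 finite samples (N >= 2 when
#'   `include_arc = FALSE`).
#' @param var_as_printed if `TRUE`, VAR uses the truncated sum over
#'   i = 1..N-1 around the full-window mean (still divided by N-1) instead
#'   of the standard sample variance.
#' @param arc_method `"yule_walker"` (default, biased autocovariance, no
#'   demeaning) or `"least_squares"` (covariance method).
#' @param include_arc if `FALSE`, only the seven scalar features are
#'   returned (the AR(3) fit is undefined below 4 samples).
#' @return named numeric vector: mav, rms, mc, mac, max, zc, var, and
#'   arc1..arc3 unless `include_arc = FALSE`.
#' @export
compute_feature_set <- function(x, var_as_printed = FALSE,
                                arc_method = c("yule_walker", "least_squares"),
                                include_arc = TRUE) {
  arc_method <- match.arg(arc_method)
  n <- length(x)
  if (include_arc && n < 4L) {
    stop("need at least 4 samples for the AR(3) coefficients", call. = FALSE)
  }
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  if (!all(is.finite(x))) stop("non-finite samples", call. = FALSE)
  d <- diff(x)
  v <- if (var_as_printed) {
    sum((x[seq_len(n - 1)] - mean(x))^2) / (n - 1)
  } else stats::var(x)
  out <- c(mav = mean(abs(x)),
           rms = sqrt(mean(x^2)),
           mc = sum(d) / n,
           mac = sum(abs(d)) / n,
           max = max(x),
           zc = sum(x[-n] * x[-1] < 0),
           var = v)
  if (include_arc) {
    arc <- if (arc_method == "yule_walker") arc_yule_walker(x) else
      arc_least_squares(x)
    out <- c(out, arc1 = arc[1], arc2 = arc[2], arc3 = arc[3])
  }
  out
}

# vectorised feature computation for one channel across many windows;
# M is wlen x nwin, returns nwin x 10
features_channel_block <- function(M, var_as_printed = FALSE) {
  n <- nrow(M)
  D <- M[-1, , drop = FALSE] - M[-n, , drop = FALSE]
  mu <- colMeans(M)
  v <- if (var_as_printed) {
    colSums((M[-n, , drop = FALSE] - rep(mu, each = n - 1))^2) / (n - 1)
  } else {
    (colSums(M^2) - n * mu^2) / (n - 1)
  }
  r <- sapply(0:3, function(k) {
    colSums(M[seq_len(n - k), , drop = FALSE] *
              M[(k + 1):n, , drop = FALSE]) / n
  })
  arc <- t(apply(r, 1, function(rr) {
    if (rr[1] <= 0) return(c(0, 0, 0))
    tryCatch(as.numeric(solve(stats::toeplitz(rr[1:3]), rr[2:4])),
             error = function(e) c(0, 0, 0))
  }))
  cbind(mav = colMeans(abs(M)),
        rms = sqrt(colMeans(M^2)),
        mc = (M[n, ] - M[1, ]) / n,
        mac = colSums(abs(D)) / n,
        max = apply(M, 2, max),
        zc = colSums(M[-n, , drop = FALSE] * M[-1, , drop = FALSE] < 0),
        var = pmax(v, 0),
        arc1 = arc[, 1], arc2 = arc[, 2], arc3 = arc[, 3])
}

#' Assemble a per-window design matrix
#'
#' Builds the feature matrix for a list of labelled windows in one of three
#' modes: `"SF:<FAMILY>"` (one feature family on all 6 channels; 6 columns,
#' 18 for `SF:ARC`), `"AF"` (all families, 60 columns) or `"EF"` (the
#' elected subset VAR/RMS/MAC, 18 columns). Columns are channel-major
#' (all of channel 1's features first), feature order canonical, named
#' `ch<k>_<feature>`.
#'
#' @param windows list of labelled windows from [segment_recording()].
#' @param mode `"AF"`, `"EF"` or `"SF:<FAMILY>"`.
#' @param var_as_printed passed to the VAR computation.
#' @return object of class `feature_matrix`: list with `x` (numeric
#'   matrix), `labels` (character), `mode`.
#' @export
assemble_features <- function(windows, mode = "AF", var_as_printed = FALSE) {
  if (length(windows) == 0L) stop("no windows", call. = FALSE)
  families <- if (identical(mode, "AF")) {
    feature_families()
  } else if (identical(mode, "EF")) {
    # canonical order within the elected subset
    feature_families()[feature_families() %in% elected_features()]
  } else if (length(mode) > 1L || all(mode %in% feature_families())) {
    # explicit family subset (used by the feature-reduction curve)
    if (!all(mode %in% feature_families())) {
      stop("unknown feature families: ",
           paste(setdiff(mode, feature_families()), collapse = ", "),
           call. = FALSE)
    }
    feature_families()[feature_families() %in% mode]
  } else if (grepl("^SF:", mode)) {
    fam <- sub("^SF:", "", mode)
    if (!fam %in% feature_families()) stop("unknown feature family: ", fam,
                                           call. = FALSE)
    fam
  } else stop("unknown mode: ", mode, call. = FALSE)
  cols <- feature_columns(families)
  nwin <- length(windows)
  blocks <- vector("list", 6L)
  for (ch in 1:6) {
    M <- vapply(windows, function(w) w$samples[, ch], numeric(nrow(windows[[1]]$samples)))
    B <- features_channel_block(M, var_as_printed)[, cols, drop = FALSE]
    colnames(B) <- paste0("ch", ch, "_", cols)
    blocks[[ch]] <- B
  }
  x <- do.call(cbind, blocks)
  rownames(x) <- NULL
  structure(list(x = x,
                 labels = vapply(windows, `[[`, character(1), "label"),
                 mode = paste(mode, collapse = ",")),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d windows x %d columns, mode %s\n",
              nrow(x$x), ncol(x$x), x$mode))
  invisible(x)
}
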