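## k-fold cross-validation, the median-alpha refit protocol, window-size
## scanning, MS-vs-SS comparison, and the Pearson correlation helper.

#' Randomly partition records into k folds
#'
#' Records are permuted under `seed` and dealt round-robin, so fold sizes
#' differ by at most one; n = 1000, k = 10 gives ten folds of exactly 100.
#'
#' @param n Number of records.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed for the permutation.
#' @return An object of class `"fold_assignment"`: a list with `k`, `n`,
#'   `seed`, and `fold` (integer fold index per record).
#' @export
make_folds <- function(n, k = 10L, seed = 1L) {
  if (k < 2L) stop("'k' must be at least 2")
  if (n < k) stop("need at least as many records as folds")
  perm <- with_seed(seed, sample.int(n))
  fold <- integer(n)
  fold[perm] <- rep_len(seq_len(k), n)
  structure(list(k = as.integer(k), n = as.integer(n),
                 seed = as.integer(seed), fold = fold),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("fold assignment: n = %d records in k = %d folds (seed %d); sizes %s\n",
              x$n, x$k, x$seed, paste(tabulate(x$fold, x$k), collapse = "/")))
  invisible(x)
}

#' Standard-deviation-normalized RMSE
#'
#' Root-mean-square prediction error divided by the sample standard deviation
#' (n-1 denominator) of the observed values.  A value below 1 means the
#' prediction beats the trivial mean predictor (whose normalized RMSE is
#' sqrt((n-1)/n)); the normalization removes the dependence of the raw RMS
#' error on the spread of a small test set.
#'
#' @param predicted,observed Equal-length numeric vectors.
#' @return A single dimensionless score >= 0.
#' @export
#' @examples
#' normalized_rmse(c(1, 1), c(0, 2))  # 1/sqrt(2)
normalized_rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(observed) == 0L)
    stop("'predicted' and 'observed' must have equal, non-zero length")
  s <- sd(observed)
  if (!is.finite(s) || s == 0)
    stop("normalized RMSE is undefined for a constant observed vector")
  sqrt(mean((predicted - observed)^2)) / s
}

#' Pearson correlation with validation
#'
#' Thin, validating wrapper around the product-moment correlation, used e.g.
#' to correlate model predictions with independently measured dissociation
#' constants.
#'
#' @param x,y Equal-length numeric vectors (length >= 3, both non-constant).
#' @return The Pearson coefficient in \[-1, 1\].
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("'x' and 'y' must have equal length >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation is undefined for a constant input")
  cor(x, y)
}

#' Cross-validate an MS or SS model at one window size
#'
#' Implements the evaluation protocol: records are split into k folds; each
#' fold in turn is the test set and the rest the training set.
#'
#' For the MS model the protocol has two passes.  Pass 1 fits each training
#' set with a free offset \eqn{\alpha}, yielding k \eqn{\alpha} values whose
#' **median** is taken (robust to an occasional diverged fold).  Pass 2
#' refits each training set with \eqn{\alpha} fixed at that median, and each
#' test fold is scored by the std-normalized RMSE.
#'
#' For the SS model, every candidate site offset r in 0..(Nmin - S) is
#' cross-validated (Nmin = shortest peptide, so the site exists in every
#' record) and the site with the smallest mean normalized RMSE is reported
#' (ties broken by smaller r).
#'
#' @inheritParams ms_fit
#' @param model `"ms"` or `"ss"`.
#' @param k Number of folds (default 10).
#' @param folds Optional [make_folds()] assignment; created from
#'   `k`/`fold_seed` when absent.  Supply the same assignment to both models
#'   when the results will go to [compare_models()].
#' @param fold_seed Seed for the fold permutation.
#' @param ... Passed to [ms_fit()] (e.g. `n_restarts`, `seed`) — ignored for
#'   `model = "ss"`.
#' @return An object of class `"spot_cv"`: per-fold normalized RMSEs and
#'   (MS) per-fold free \eqn{\alpha} values plus the selected median, or
#'   (SS) the selected site and the per-site mean RMSE table.
#' @export
crossval <- function(data, model = c("ms", "ss"), window_size,
                     k = 10L, folds = NULL, fold_seed = 1L,
                     profile = "most_frequent", ...) {
  model <- match.arg(model)
  S <- check_window_size(window_size)
  n <- nrow(data)
  if (is.null(folds)) folds <- make_folds(n, k = k, seed = fold_seed)
  if (folds$n != n) stop("fold assignment does not match the data size")
  if (model == "ms") crossval_ms(data, S, folds, profile = profile, ...)
  else crossval_ss(data, S, folds, profile = profile)
}

crossval_ms <- function(data, S, folds, profile, ...) {
  k <- folds$k
  pass1 <- lapply(seq_len(k), function(j) {
    train <- data[folds$fold != j, , drop = FALSE]
    tryCatch(ms_fit(train, window_size = S, profile = profile, ...),
             error = function(e) e)
  })
  failed <- vapply(pass1, inherits, logical(1), what = "error")
  alphas <- rep(NA_real_, k)
  alphas[!failed] <- vapply(pass1[!failed], function(f) f$alpha, numeric(1))
  alpha_med <- median(alphas, na.rm = TRUE)
  fold_rmse <- rep(NA_real_, k)
  for (j in seq_len(k)) {
    train <- data[folds$fold != j, , drop = FALSE]
    test <- data[folds$fold == j, , drop = FALSE]
    fit <- tryCatch(ms_fit(train, window_size = S, profile = profile,
                           fixed_alpha = alpha_med, ...),
                    error = function(e) e)
    if (inherits(fit, "error")) { failed[j] <- TRUE; next }
    pred <- predict(fit, test)
    fold_rmse[j] <- normalized_rmse(pred, prepare_spot_data(test, S)$y)
  }
  structure(list(model = "ms", window_size = S, k = k, folds = folds,
                 fold_rmse = fold_rmse, fold_alpha = alphas,
                 alpha = alpha_med,
                 mean_rmse = mean(fold_rmse, na.rm = TRUE),
                 sd_rmse = sd(fold_rmse[!is.na(fold_rmse)]),
                 incomplete = any(failed)),
            class = "spot_cv")
}

crossval_ss <- function(data, S, folds, profile) {
  k <- folds$k
  seqs <- as.character(data$sequence)
  n_min <- min(nchar(seqs))
  if (S > n_min) stop("window size exceeds the shortest peptide (", n_min, ")")
  sites <- 0:(n_min - S)
  site_rmse <- matrix(NA_real_, nrow = length(sites), ncol = k)
  for (si in seq_along(sites)) {
    for (j in seq_len(k)) {
      train <- data[folds$fold != j, , drop = FALSE]
      test <- data[folds$fold == j, , drop = FALSE]
      fit <- tryCatch(
        suppressWarnings(ss_fit(train, window_size = S, site = sites[si],
                                profile = profile)),
        error = function(e) e)
      if (inherits(fit, "error")) next
      pred <- tryCatch(predict(fit, test), error = function(e) NULL)
      if (is.null(pred)) next
      site_rmse[si, j] <- normalized_rmse(pred, prepare_spot_data(test, S)$y)
    }
  }
  site_mean <- rowMeans(site_rmse, na.rm = TRUE)
  best <- which.min(site_mean)   # ties: which.min takes the first = smaller r
  structure(list(model = "ss", window_size = S, k = k, folds = folds,
                 site = sites[best],
                 fold_rmse = site_rmse[best, ],
                 site_table = data.frame(site = sites, mean_rmse = site_mean),
                 mean_rmse = site_mean[best],
                 sd_rmse = sd(site_rmse[best, !is.na(site_rmse[best, ])]),
                 incomplete = anyNA(site_rmse[best, ])),
            class = "spot_cv")
}

#' @export
print.spot_cv <- function(x, ...) {
  cat(sprintf("%s-model %d-fold cross-validation, S = %d\n",
              toupper(x$model), x$k, x$window_size))
  if (x$model == "ms")
    cat(sprintf("  median alpha = %.4f RT (fold alphas: %s)\n", x$alpha,
                paste(sprintf("%.2f", x$fold_alpha), collapse = ", ")))
  else
    cat(sprintf("  selected site offset r = %d (0-based) of %d candidates\n",
                x$site, nrow(x$site_table)))
  cat(sprintf("  normalized RMSE: mean %.4f, sd %.4f%s\n", x$mean_rmse, x$sd_rmse,
              if (isTRUE(x$incomplete)) "  [INCOMPLETE: some folds failed]" else ""))
  invisible(x)
}

#' Scan window sizes for one model kind
#'
#' Runs [crossval()] at each window size and marks the best (minimum mean
#' normalized RMSE; ties broken by the smaller S).  For the MS model a
#' full-length window (S equal to the shortest peptide, a single site for
#' some records) is excluded from the best-S selection — with one window the
#' ensemble degenerates to the SS model — unless it is the only size
#' scanned.
#'
#' @inheritParams crossval
#' @param window_sizes Integer vector of window sizes S to scan.
#' @return An object of class `"window_scan"`: the per-S [crossval()]
#'   results, a summary `table` (S, mean/sd RMSE), and `best_S`.
#' @export
scan_windows <- function(data, model = c("ms", "ss"), window_sizes,
                         k = 10L, folds = NULL, fold_seed = 1L,
                         profile = "most_frequent", ...) {
  model <- match.arg(model)
  if (length(window_sizes) == 0L) stop("'window_sizes' must be non-empty")
  window_sizes <- sort(unique(vapply(window_sizes, check_window_size, integer(1))))
  n_min <- min(nchar(as.character(data$sequence)))
  if (any(window_sizes > n_min))
    stop("window sizes must not exceed the shortest peptide length (", n_min, ")")
  if (is.null(folds)) folds <- make_folds(nrow(data), k = k, seed = fold_seed)
  results <- lapply(window_sizes, function(S)
    crossval(data, model = model, window_size = S, folds = folds,
             profile = profile, ...))
  means <- vapply(results, function(r) r$mean_rmse, numeric(1))
  eligible <- if (model == "ms" && any(window_sizes < n_min))
    window_sizes < n_min else rep(TRUE, length(window_sizes))
  best <- which(eligible)[which.min(means[eligible])]
  structure(list(model = model, window_sizes = window_sizes, folds = folds,
                 results = results,
                 table = data.frame(window_size = window_sizes,
                                    mean_rmse = means,
                                    sd_rmse = vapply(results, function(r) r$sd_rmse, numeric(1))),
                 best_S = window_sizes[best], best = results[[best]]),
            class = "window_scan")
}

#' @export
print.window_scan <- function(x, ...) {
  cat(sprintf("%s-model window scan (k = %d folds)\n", toupper(x$model), x$folds$k))
  print(transform(x$table, best = ifelse(window_size == x$best_S, "*", "")),
        row.names = FALSE)
  invisible(x)
}

#' RMSE-vs-window-size curves for one or two scans
#'
#' @param x A `"window_scan"`.
#' @param other Optional second scan (e.g. the other model kind) overlaid.
#' @param ... Passed to [plot()].
#' @export
plot.window_scan <- function(x, other = NULL, ...) {
  tabs <- list(x$table)
  labs <- toupper(x$model)
  if (!is.null(other)) { tabs <- c(tabs, list(other$table)); labs <- c(labs, toupper(other$model)) }
  ylim <- range(unlist(lapply(tabs, function(t) t$mean_rmse)))
  plot(tabs[[1]]$window_size, tabs[[1]]$mean_rmse, type = "b", pch = 19,
       xlab = "window size S", ylab = "normalized RMSE", ylim = ylim, ...)
  if (length(tabs) > 1) {
    points(tabs[[2]]$window_size, tabs[[2]]$mean_rmse, type = "b", pch = 2)
    legend("topright", legend = labs, pch = c(19, 2), bty = "n")
  }
  invisible(x)
}

#' Compare the best MS and best SS models fold by fold
#'
#' Takes two [scan_windows()] results computed on the **same** fold
#' assignment, selects each scan's best window size, and evaluates the
#' percent decrease in prediction error of MS relative to SS per fold:
#' \deqn{100 (RMSE_{SS} - RMSE_{MS}) / RMSE_{SS},}
#' then averages over folds and reports the fold standard deviation.  A
#' positive mean means the MS model predicts better.
#'
#' @param ms_scan,ss_scan `"window_scan"` objects for the MS and SS models
#'   on identical folds.
#' @return An object of class `"model_comparison"` with per-fold decreases,
#'   their mean and sd, and the two best entries.
#' @export
compare_models <- function(ms_scan, ss_scan) {
  stopifnot(inherits(ms_scan, "window_scan"), inherits(ss_scan, "window_scan"))
  if (!identical(ms_scan$folds$fold, ss_scan$folds$fold))
    stop("the two scans were not run on identical fold assignments")
  ms <- ms_scan$best$fold_rmse
  ss <- ss_scan$best$fold_rmse
  dec <- 100 * (ss - ms) / ss
  structure(list(ms_S = ms_scan$best_S, ss_S = ss_scan$best_S,
                 ss_site = ss_scan$best$site,
                 fold_ms_rmse = ms, fold_ss_rmse = ss,
                 fold_decrease = dec,
                 mean_decrease = mean(dec, na.rm = TRUE),
                 sd_decrease = sd(dec[!is.na(dec)]),
                 ms_mean_rmse = ms_scan$best$mean_rmse,
                 ss_mean_rmse = ss_scan$best$mean_rmse),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("MS vs SS model comparison (best window size of each scan)\n")
  cat(sprintf("  best MS: S = %d, mean normalized RMSE %.4f\n", x$ms_S, x$ms_mean_rmse))
  cat(sprintf("  best SS: S = %d at site r = %d, mean normalized RMSE %.4f\n",
              x$ss_S, x$ss_site, x$ss_mean_rmse))
  cat(sprintf("  percent error decrease of MS vs SS: %.2f%% (fold sd %.2f)\n",
              x$mean_decrease, x$sd_decrease))
  cat("  (positive = MS predicts better)\n")
  invisible(x)
}

#' Paired-difference summary plot for a model comparison
#'
#' @param x A `"model_comparison"`.
#' @param ... Passed to [plot()].
#' @export
plot.model_comparison <- function(x, ...) {
  d <- -x$fold_decrease   # negative = MS better, matching the error-difference view
  m <- mean(d, na.rm = TRUE); s <- sd(d[!is.na(d)])
  plot(1, m, ylim = range(c(m - s, m + s, 0)), pch = 15, xaxt = "n",
       xlab = "", ylab = "percent error difference (MS - SS)", ...)
  segments(1, m - s, 1, m + s)
  abline(h = 0, lty = 2, col = "grey50")
  invisible(x)
}
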