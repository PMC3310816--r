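## Ordinary least-squares estimation of the SS model at a fixed site.

#' Fit the Single-Site model at a fixed representative window
#'
#' Ordinary linear least squares of the observed pseudo-binding energy on the
#' indicator encoding of the window at offset `site`:
#' \eqn{G^{SPOT} = J_0 + \sum_s J_{s,a_s} + \epsilon}.  The solution is
#' closed-form via a rank-revealing QR.  Design columns that are never
#' observed in the data (a residue never seen at a position), or that the QR
#' drops as collinear, get J = 0 — predictions for unseen residues then fall
#' back to the reference energy — with a warning listing the columns.
#'
#' @inheritParams ms_fit
#' @param site 0-based start offset r of the representative window; records
#'   with peptides shorter than `site + window_size` are skipped with a
#'   warning.
#' @return An object of class `c("ss_fit", "ss_model")` with components
#'   `J`, `J0`, `site`, `profile`, `sse`, `residuals`, `fitted`, `n`,
#'   `n_skipped`, `zeroed_columns`, `config`, `call`.
#' @seealso [ms_fit()], [crossval()]
#' @export
#' @examples
#' sim <- simulate_spot_array(n_peptides = 80, lengths = 8, window_size = 3,
#'                            truth = "ss", site = 2, noise_sd = 0, seed = 2)
#' fit <- ss_fit(sim$records, window_size = 3, site = 2, profile = "fixed_alanine")
#' fit$sse   # essentially zero: exact linear recovery
ss_fit <- function(data, window_size, site = 0L, profile = "most_frequent") {
  cl <- match.call()
  S <- check_window_size(window_size)
  if (site < 0 || site != round(site)) stop("'site' must be a non-negative integer offset")
  site <- as.integer(site)
  dat <- prepare_spot_data(data, S + site)   # need the full window at `site`
  if (length(dat$y) < 2L) stop("need at least 2 usable records")
  windows <- substring(dat$sequences, site + 1L, site + S)
  prof <- resolve_profile(list(windows = windows), S, profile)
  X <- encode_windows(windows, prof, intercept = TRUE)
  fit <- stats::lm.fit(X, dat$y)
  beta <- fit$coefficients
  zeroed <- names(beta)[is.na(beta)]
  never <- colnames(X)[colSums(X) == 0]
  zeroed <- union(zeroed, never)
  if (length(zeroed)) {
    beta[is.na(beta)] <- 0
    beta[never] <- 0
    warning("coefficients set to 0 for unobserved/collinear design columns: ",
            paste(head(zeroed, 8L), collapse = ", "),
            if (length(zeroed) > 8L) ", ..." else "")
  }
  fitted <- drop(X %*% beta)
  res <- dat$y - fitted
  names(res) <- names(fitted) <- dat$ids

  out <- ss_model(theta_to_J(beta[-1L], prof), J0 = beta[[1L]],
                  site = site, profile = prof)
  out$sse <- sum(res^2)
  out$residuals <- res
  out$fitted <- fitted
  out$n <- length(dat$y)
  out$n_skipped <- dat$n_skipped
  out$zeroed_columns <- zeroed
  out$data <- data.frame(peptide_id = dat$ids, sequence = dat$sequences,
                         pseudo_energy = dat$y, stringsAsFactors = FALSE)
  out$config <- list(window_size = S, site = site,
                     profile_policy = attr(prof, "policy"))
  out$call <- cl
  class(out) <- c("ss_fit", "ss_model")
  out
}

#' @export
print.ss_fit <- function(x, ...) {
  cat("Single-Site (SS) model fit\n")
  cat(sprintf("  n = %d peptides (%d skipped), S = %d, site offset r = %d (0-based)\n",
              x$n, x$n_skipped, x$window_size, x$site))
  cat(sprintf("  J0 = %.4f RT, SSE = %.6g RT^2\n", x$J0, x$sse))
  if (length(x$zeroed_columns))
    cat(sprintf("  %d design column(s) zeroed (unobserved/collinear)\n",
                length(x$zeroed_columns)))
  invisible(x)
}

#' @export
summary.ss_fit <- function(object, n_top = 10L, ...) {
  J <- coef(object)[-1L]
  top <- head(J[order(-abs(J))], n_top)
  structure(list(fit = object, top_J = top,
                 rmse = sqrt(object$sse / object$n),
                 nrmse = normalized_rmse(object$fitted, object$data$pseudo_energy)),
            class = "summary.ss_fit")
}

#' @export
print.summary.ss_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  RMS error = %.4f RT; std-normalized RMSE (training) = %.4f\n",
              x$rmse, x$nrmse))
  cat("  Largest |J| terms (RT):\n")
  print(round(x$top_J, 4))
  invisible(x)
}

#' @export
residuals.ss_fit <- function(object, ...) object$residuals

#' @export
fitted.ss_fit <- function(object, ...) object$fitted

#' @export
plot.ss_fit <- function(x, ...) {
  obs <- x$data$pseudo_energy
  plot(x$fitted, obs, xlab = "fitted pseudo-energy (RT)",
       ylab = "observed pseudo-energy (RT)",
       main = sprintf("SS model, S = %d, r = %d", x$window_size, x$site), ...)
  abline(0, 1, col = "grey50", lty = 2)
  invisible(x)
}
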