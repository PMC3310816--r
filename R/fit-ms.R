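## Nonlinear least-squares estimation of the MS model.

## Seed-scoped evaluation that restores the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  expr
}

## Normalise user data into (ids, sequence, pseudo_energy); drops and reports
## peptides shorter than the window size.
prepare_spot_data <- function(data, window_size) {
  if (!is.data.frame(data))
    stop("'data' must be a data frame (see read_spot_table / simulate_spot_array)")
  if (!"sequence" %in% names(data)) stop("'data' must have a 'sequence' column")
  y <- if ("pseudo_energy" %in% names(data)) {
    as.numeric(data$pseudo_energy)
  } else if ("intensity" %in% names(data)) {
    intensity_to_energy(data$intensity)
  } else stop("'data' must have a 'pseudo_energy' or 'intensity' column")
  bad <- which(!is.finite(y))
  if (length(bad))
    stop("non-finite pseudo-energy for record(s): ",
         paste(head(bad, 5L), collapse = ", "))
  sequences <- as.character(data$sequence)
  validate_peptides(sequences)
  ids <- if ("peptide_id" %in% names(data)) as.character(data$peptide_id)
         else default_ids(sequences)
  short <- which(nchar(sequences) < window_size)
  if (length(short)) {
    warning(length(short), " peptide(s) shorter than the window size (",
            window_size, ") skipped")
    sequences <- sequences[-short]; y <- y[-short]; ids <- ids[-short]
  }
  if (length(sequences) < 2L)
    stop("need at least 2 usable records to fit a model")
  list(ids = ids, sequences = sequences, y = y, n_skipped = length(short))
}

resolve_profile <- function(d, S, profile) {
  if (inherits(profile, "reference_profile") ||
      (is.character(profile) && length(profile) == S && all(nchar(profile) == 1L))) {
    prof <- structure(as.character(profile), class = "reference_profile",
                      policy = attr(profile, "policy") %||% "custom")
    if (length(prof) != S) stop("profile length must equal the window size")
    return(prof)
  }
  policy <- match.arg(profile, c("most_frequent", "fixed_alanine"))
  reference_profile(d$windows, policy = policy, window_size = S)
}

#' Fit the Multiple-Site model to SPOT pseudo-binding energies
#'
#' Estimates the offset \eqn{\alpha} and the 19 x S single-residue energies J
#' by nonlinear least squares on
#' \deqn{G^{SPOT}_j = \alpha - \ln \sum_i e^{-G_P(\sigma_{ji})} + \epsilon_j,}
#' using Levenberg-Marquardt with an analytic Jacobian and several random
#' restarts (the objective is non-convex; the best-SSE solution over all
#' starts is returned).  Peptides shorter than S are skipped with a warning —
#' real arrays mix 13- and 14-mers.  J values are box-bounded to
#' `c(-J_bound, J_bound)` to keep rare features from diverging; J entries for
#' (position, residue) pairs never observed in the training windows are fixed
#' at 0 (predictions for unseen residues fall back to the reference energy).
#'
#' @param data Data frame with a `sequence` column and `pseudo_energy` (RT
#'   units) or `intensity` (BLU) column; optional `peptide_id`.
#' @param window_size Binding-site size S (residues).
#' @param profile Reference-residue policy, `"most_frequent"` (default) or
#'   `"fixed_alanine"`, or an explicit [reference_profile()] / character
#'   vector of length S.
#' @param n_restarts Number of random starts (>= 1).  Initial J values for
#'   restart r are the r-th draw of `runif(19*S, -init_spread, init_spread)`
#'   under `seed`, so the best-of-k SSE is non-increasing in `n_restarts`.
#' @param seed Integer seed controlling the restart initializations.
#' @param init_spread Half-width of the uniform initial-J distribution (RT).
#' @param alpha_init `"mean_energy"` (start \eqn{\alpha} at the mean observed
#'   energy) or `"zero"`.
#' @param fixed_alpha If supplied, \eqn{\alpha} is held at this value and only
#'   J is optimized (used by the cross-validation median-\eqn{\alpha} refit).
#' @param J_bound Box bound on each J (RT units).
#' @param max_iter,ftol,ptol Levenberg-Marquardt control (iteration cap and
#'   relative convergence tolerances on SSE and parameters).
#' @return An object of class `c("ms_fit", "ms_model")` with components
#'   `J`, `alpha`, `profile`, `sse`, `residuals`, `fitted`, `converged`,
#'   `restart_sse`, `restart_index`, `n`, `n_skipped`, `config`, `call`.
#' @seealso [ss_fit()], [crossval()], [predict.ms_model()]
#' @export
#' @examples
#' sim <- simulate_spot_array(n_peptides = 60, lengths = 8, window_size = 3,
#'                            noise_sd = 0.05, seed = 1)
#' fit <- ms_fit(sim$records, window_size = 3, profile = "fixed_alanine",
#'               n_restarts = 2, seed = 1)
#' fit
ms_fit <- function(data, window_size, profile = "most_frequent",
                   n_restarts = 10L, seed = 1L, init_spread = 1,
                   alpha_init = c("mean_energy", "zero"),
                   fixed_alpha = NULL, J_bound = 20,
                   max_iter = 500L, ftol = 1e-14, ptol = 1e-14) {
  cl <- match.call()
  S <- check_window_size(window_size)
  alpha_init <- match.arg(alpha_init)
  if (n_restarts < 1L) stop("'n_restarts' must be >= 1")
  dat <- prepare_spot_data(data, S)
  d <- window_split(dat$sequences, S)
  prof <- resolve_profile(d, S, profile)
  F <- encode_windows(d$windows, prof, intercept = FALSE)
  pep <- d$pep
  y <- dat$y
  n <- length(y)
  # features never observed in the data have zero gradient; pin them to 0 so
  # the returned J is deterministic (prediction falls back to the reference)
  obs_cols <- colSums(F) > 0
  Fo <- F[, obs_cols, drop = FALSE]
  p <- ncol(Fo)
  free_alpha <- is.null(fixed_alpha)
  a0 <- if (alpha_init == "mean_energy") mean(y) else 0

  predict_theta <- function(alpha, theta) {
    G <- drop(Fo %*% theta)
    lse_total(G, pep, alpha)
  }
  resid_fn <- function(par) {
    if (free_alpha) y - predict_theta(par[1L], par[-1L])
    else y - predict_theta(fixed_alpha, par)
  }
  jac_fn <- function(par) {
    theta <- if (free_alpha) par[-1L] else par
    G <- drop(Fo %*% theta)
    w <- lse_weights(G, pep)
    A <- rowsum(Fo * w, pep, reorder = TRUE)   # d pred / d theta
    if (free_alpha) cbind(-1, -A) else -A
  }

  if (n < p + free_alpha)
    stop("need at least as many records (", n, ") as free parameters (",
         p + free_alpha, "); use a smaller window size or more data")
  inits <- with_seed(seed, lapply(seq_len(n_restarts), function(r)
    runif(p, -init_spread, init_spread)))
  lower <- rep(-J_bound, p); upper <- rep(J_bound, p)
  if (free_alpha) { lower <- c(-1e6, lower); upper <- c(1e6, upper) }
  ctrl <- minpack.lm::nls.lm.control(maxiter = max_iter, ftol = ftol,
                                     ptol = ptol, gtol = 0)
  runs <- lapply(inits, function(th0) {
    par0 <- if (free_alpha) c(a0, th0) else th0
    minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                       fn = resid_fn, jac = jac_fn, control = ctrl)
  })
  sses <- vapply(runs, function(f) sum(f$fvec^2), numeric(1))
  best <- which.min(sses)
  fit <- runs[[best]]
  par <- fit$par
  alpha <- if (free_alpha) par[1L] else fixed_alpha
  theta_obs <- if (free_alpha) par[-1L] else par
  fitted <- predict_theta(alpha, theta_obs)
  theta <- numeric(ncol(F))
  theta[obs_cols] <- theta_obs
  res <- y - fitted
  names(res) <- names(fitted) <- dat$ids

  out <- ms_model(theta_to_J(theta, prof), alpha = alpha, profile = prof)
  out$sse <- sum(res^2)
  out$residuals <- res
  out$fitted <- fitted
  out$converged <- fit$info %in% 1:4
  out$restart_sse <- sses
  out$restart_index <- best
  out$n <- n
  out$n_skipped <- dat$n_skipped
  out$data <- data.frame(peptide_id = dat$ids, sequence = dat$sequences,
                         pseudo_energy = y, stringsAsFactors = FALSE)
  out$config <- list(window_size = S, profile_policy = attr(prof, "policy"),
                     n_restarts = n_restarts, seed = seed,
                     init_spread = init_spread, alpha_init = alpha_init,
                     fixed_alpha = fixed_alpha, J_bound = J_bound,
                     max_iter = max_iter, ftol = ftol, ptol = ptol)
  out$call <- cl
  class(out) <- c("ms_fit", "ms_model")
  out
}

#' @export
print.ms_fit <- function(x, ...) {
  cat("Multiple-Site (MS) model fit\n")
  cat(sprintf("  n = %d peptides (%d skipped), S = %d, profile '%s'\n",
              x$n, x$n_skipped, x$window_size, attr(x$profile, "policy")))
  cat(sprintf("  alpha = %.4f RT%s\n", x$alpha,
              if (is.null(x$config$fixed_alpha)) "" else " (fixed)"))
  cat(sprintf("  SSE = %.6g RT^2  (best of %d restarts, #%d%s)\n",
              x$sse, length(x$restart_sse), x$restart_index,
              if (x$converged) ", converged" else ", NOT converged"))
  invisible(x)
}

#' @export
summary.ms_fit <- function(object, n_top = 10L, ...) {
  J <- coef(object)[-1L]
  top <- head(J[order(-abs(J))], n_top)
  structure(list(fit = object, top_J = top,
                 rmse = sqrt(object$sse / object$n),
                 nrmse = normalized_rmse(object$fitted, object$data$pseudo_energy)),
            class = "summary.ms_fit")
}

#' @export
print.summary.ms_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  RMS error = %.4f RT; std-normalized RMSE (training) = %.4f\n",
              x$rmse, x$nrmse))
  cat("  Largest |J| terms (RT):\n")
  print(round(x$top_J, 4))
  invisible(x)
}

#' @export
residuals.ms_fit <- function(object, ...) object$residuals

#' @export
fitted.ms_fit <- function(object, ...) object$fitted

#' Observed vs fitted pseudo-binding energies
#'
#' @param x A fitted `"ms_fit"` or `"ss_fit"` object.
#' @param ... Passed to [plot()].
#' @export
plot.ms_fit <- function(x, ...) {
  obs <- x$data$pseudo_energy
  plot(x$fitted, obs, xlab = "fitted pseudo-energy (RT)",
       ylab = "observed pseudo-energy (RT)",
       main = sprintf("MS model, S = %d", x$window_size), ...)
  abline(0, 1, col = "grey50", lty = 2)
  invisible(x)
}

#' Simulate noisy pseudo-energies from a fitted or constructed model
#'
#' Draws Gaussian energy-scale noise around the model's predictions — the
#' generative counterpart of the fitting error term.
#'
#' @param object An `"ms_model"` / `"ss_model"` (possibly fitted).
#' @param nsim Number of replicate draws.
#' @param seed Optional integer seed.
#' @param newdata Sequences to predict for (defaults to training data for a
#'   fitted model).
#' @param noise_sd Energy-scale noise standard deviation (RT); defaults to
#'   the residual RMS for a fitted model.
#' @param ... Unused.
#' @return A data frame with one column per replicate (`sim_1`, ...).
#' @export
simulate.ms_model <- function(object, nsim = 1, seed = NULL,
                              newdata = NULL, noise_sd = NULL, ...) {
  mu <- predict(object, newdata)
  if (is.null(noise_sd))
    noise_sd <- if (!is.null(object$sse)) sqrt(object$sse / object$n) else 0
  draw <- function() mu + rnorm(length(mu), 0, noise_sd)
  sims <- if (is.null(seed)) replicate(nsim, draw())
          else with_seed(seed, replicate(nsim, draw()))
  sims <- matrix(sims, ncol = nsim,
                 dimnames = list(names(mu), paste0("sim_", seq_len(nsim))))
  as.data.frame(sims)
}

#' @export
simulate.ss_model <- simulate.ms_model
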