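## MS and SS energy functions: per-window additive energies, the
## log-sum-exp ensemble total, and the single-site special case.

#' Construct a Multiple-Site (MS) energy model
#'
#' An MS model scores a peptide as
#' \deqn{G = \alpha - \ln \sum_{i=1}^{N-S+1} e^{-G_P(\sigma_i)},}
#' the Boltzmann ensemble over all S-residue windows \eqn{\sigma_i}, where
#' each window energy \eqn{G_P} is additive over positions (a J-term per
#' position and residue, reference residues carrying 0).  All energies are
#' dimensionless (RT units).  The per-window intercept J0 is fixed at 0:
#' in the ensemble it is confounded with \eqn{\alpha}, which absorbs the
#' offset (unique parameterization).
#'
#' @param J Numeric 20 x S matrix of single-residue energies, rows named by
#'   [amino_acids()]; entries on the reference residue of each column must be
#'   0 (they are forced to 0 with a warning otherwise).
#' @param alpha Additive offset \eqn{\alpha} (RT units), correcting the
#'   imperfect mapping from SPOT intensity to free energy.
#' @param profile A [reference_profile()] of length S.
#' @return An object of class `"ms_model"`.
#' @seealso [ms_fit()] to estimate a model from data, [predict.ms_model()],
#'   [mlp()].
#' @export
ms_model <- function(J, alpha = 0, profile) {
  J <- check_J(J, profile)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  structure(list(window_size = ncol(J), profile = profile, J = J,
                 alpha = alpha, J0 = 0),
            class = "ms_model")
}

#' Construct a Single-Site (SS) energy model
#'
#' The SS baseline scores a peptide by the additive energy of one fixed
#' representative window at offset `site`:
#' \eqn{G = J_0 + \sum_s J_{s,a_s}} over that window only.  It is the
#' special case of the MS model in which a single site carries all binding.
#'
#' @param J Numeric 20 x S matrix as in [ms_model()].
#' @param J0 Intercept (RT units).
#' @param site 0-based start offset of the representative window.
#' @param profile A [reference_profile()] of length S.
#' @return An object of class `"ss_model"`.
#' @export
ss_model <- function(J, J0 = 0, site = 0L, profile) {
  J <- check_J(J, profile)
  stopifnot(is.numeric(J0), length(J0) == 1L, is.finite(J0))
  if (site < 0 || site != round(site)) stop("'site' must be a non-negative integer offset")
  structure(list(window_size = ncol(J), profile = profile, J = J,
                 J0 = J0, site = as.integer(site)),
            class = "ss_model")
}

check_J <- function(J, profile) {
  aa <- amino_acids()
  S <- length(profile)
  if (!is.matrix(J) || nrow(J) != 20L || ncol(J) != S)
    stop("'J' must be a 20 x S numeric matrix (S = ", S, ")")
  if (is.null(rownames(J))) rownames(J) <- aa
  if (!identical(rownames(J), aa))
    J <- J[aa, , drop = FALSE]
  if (any(!is.finite(J))) stop("all J energies must be finite")
  refval <- J[cbind(match(as.character(profile), aa), seq_len(S))]
  if (any(refval != 0)) {
    warning("J entries on reference residues forced to 0")
    J[cbind(match(as.character(profile), aa), seq_len(S))] <- 0
  }
  colnames(J) <- paste0("p", seq_len(S))
  J
}

## Flatten the non-reference entries of a 20 x S J matrix into the 19*S
## coefficient vector matching encode_windows() column order, and back.
J_to_theta <- function(J, profile) {
  aa <- amino_acids()
  unlist(lapply(seq_along(profile), function(s)
    J[setdiff(aa, profile[[s]]), s]), use.names = FALSE)
}

theta_to_J <- function(theta, profile) {
  aa <- amino_acids()
  S <- length(profile)
  J <- matrix(0, 20L, S, dimnames = list(aa, paste0("p", seq_len(S))))
  for (s in seq_len(S))
    J[setdiff(aa, profile[[s]]), s] <- theta[(s - 1L) * 19L + seq_len(19L)]
  J
}

#' Per-window additive energies
#'
#' Evaluates \eqn{G_P(\sigma) = J_0 + \sum_s J_{s,a_s}} for each window
#' sequence (reference residues contribute 0), i.e. the dot product of the
#' indicator feature vector with the flattened parameter vector.
#'
#' @param model An `"ms_model"` or `"ss_model"`.
#' @param windows Character vector of window sequences of length S.
#' @return Numeric vector of energies (RT units).
#' @export
#' @examples
#' prof <- reference_profile(window_size = 2, policy = "fixed_alanine")
#' J <- matrix(0, 20, 2, dimnames = list(amino_acids(), NULL)); J["C", 1] <- -1.5
#' window_energy(ms_model(J, alpha = 0, profile = prof), "CA")  # -1.5
window_energy <- function(model, windows) {
  stopifnot(inherits(model, c("ms_model", "ss_model")))
  F <- encode_windows(windows, model$profile, intercept = FALSE)
  drop(F %*% J_to_theta(model$J, model$profile)) + model$J0
}

## Grouped log-sum-exp machinery -------------------------------------------

## total_i = alpha - ln sum_{w in group i} exp(-G_w), max-shift stabilized.
## G: window energies; pep: group index (1..n, contiguous blocks).
lse_total <- function(G, pep, alpha = 0) {
  gmin <- as.vector(tapply(G, pep, min))
  scaled <- exp(-(G - gmin[pep]))
  sumexp <- as.vector(rowsum(scaled, pep, reorder = TRUE))
  alpha + gmin - log(sumexp)
}

## Boltzmann occupancy weights within each group (softmax of -G).
lse_weights <- function(G, pep) {
  gmin <- as.vector(tapply(G, pep, min))
  scaled <- exp(-(G - gmin[pep]))
  sumexp <- as.vector(rowsum(scaled, pep, reorder = TRUE))
  scaled / sumexp[pep]
}

#' Window-resolved energy profile of peptides under a model
#'
#' For each peptide, the individual window energies \eqn{G_P(\sigma_i)}
#' (ordered by window start) and the model's total predicted energy.  For an
#' MS model the total is the log-sum-exp ensemble
#' \eqn{\alpha - \ln\sum_i e^{-G_P(\sigma_i)}}, so it never exceeds
#' \eqn{\alpha + \min_i G_P(\sigma_i)}; for an SS model it is the energy of
#' the representative window alone.
#'
#' @param model An `"ms_model"` or `"ss_model"`.
#' @param sequences Character vector of peptide sequences (length >= S; for
#'   SS, length >= site + S).
#' @param ids Optional peptide labels.
#' @return A list with `total` (named numeric vector) and `windows` (a data
#'   frame with columns `peptide_id`, `start`, `subsequence`, `energy`).
#' @export
energy_profile <- function(model, sequences, ids = NULL) {
  stopifnot(inherits(model, c("ms_model", "ss_model")))
  if (is.null(ids)) ids <- default_ids(sequences)
  S <- model$window_size
  if (any(nchar(sequences) < S))
    stop("all peptides must be at least as long as the window size (", S, ")")
  d <- window_design(sequences, S, model$profile)
  G <- drop(d$F %*% J_to_theta(model$J, model$profile)) + model$J0
  if (inherits(model, "ms_model")) {
    total <- lse_total(G, d$pep, model$alpha)
  } else {
    r <- model$site
    if (any(nchar(sequences) < r + S))
      stop("site offset ", r, " out of range for some peptides")
    total <- G[d$start == r][order(d$pep[d$start == r])]
    total <- as.vector(total)
  }
  names(total) <- ids
  list(total = total,
       windows = data.frame(peptide_id = ids[d$pep], start = d$start,
                            subsequence = d$windows, energy = G,
                            stringsAsFactors = FALSE))
}

default_ids <- function(sequences) {
  sprintf("pep%0*d", max(4L, nchar(length(sequences))), seq_along(sequences))
}

extract_sequences <- function(newdata) {
  if (is.character(newdata)) return(newdata)
  if (is.data.frame(newdata)) {
    if (!"sequence" %in% names(newdata))
      stop("'newdata' data frame must have a 'sequence' column")
    return(as.character(newdata$sequence))
  }
  stop("'newdata' must be a character vector of sequences or a data frame with a 'sequence' column")
}

#' Predict peptide energies from an MS model
#'
#' @param object An `"ms_model"` (or fitted `"ms_fit"`).
#' @param newdata Character vector of peptide sequences, or a data frame with
#'   a `sequence` column.  For a fitted model, defaults to the training data.
#' @param ... Unused.
#' @return Numeric vector of predicted pseudo-binding energies (RT units).
#' @export
predict.ms_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    if (!is.null(object$fitted)) return(object$fitted)
    stop("'newdata' is required for an unfitted model")
  }
  sequences <- extract_sequences(newdata)
  energy_profile(object, sequences)$total
}

#' Predict peptide energies from an SS model
#'
#' @inheritParams predict.ms_model
#' @param object An `"ss_model"` (or fitted `"ss_fit"`).
#' @return Numeric vector of predicted pseudo-binding energies (RT units).
#' @export
predict.ss_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    if (!is.null(object$fitted)) return(object$fitted)
    stop("'newdata' is required for an unfitted model")
  }
  sequences <- extract_sequences(newdata)
  energy_profile(object, sequences)$total
}

#' @export
coef.ms_model <- function(object, ...) {
  c(alpha = object$alpha,
    setNames(J_to_theta(object$J, object$profile),
             colnames(encode_windows(paste(rep("A", object$window_size), collapse = ""),
                                     object$profile, intercept = FALSE))))
}

#' @export
coef.ss_model <- function(object, ...) {
  c(`(Intercept)` = object$J0,
    setNames(J_to_theta(object$J, object$profile),
             colnames(encode_windows(paste(rep("A", object$window_size), collapse = ""),
                                     object$profile, intercept = FALSE))))
}

#' @export
print.ms_model <- function(x, ...) {
  cat("Multiple-Site (MS) energy model\n")
  cat(sprintf("  window size S = %d, reference policy '%s'\n",
              x$window_size, attr(x$profile, "policy") %||% "custom"))
  cat(sprintf("  reference profile: %s\n", paste(as.character(x$profile), collapse = "")))
  cat(sprintf("  alpha = %.4f RT (J0 fixed at 0)\n", x$alpha))
  invisible(x)
}

#' @export
print.ss_model <- function(x, ...) {
  cat("Single-Site (SS) energy model\n")
  cat(sprintf("  window size S = %d, representative site offset r = %d (0-based)\n",
              x$window_size, x$site))
  cat(sprintf("  reference profile: %s\n", paste(as.character(x$profile), collapse = "")))
  cat(sprintf("  J0 = %.4f RT\n", x$J0))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
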