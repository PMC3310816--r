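## Synthetic SPOT-array generator with known ground truth.

#' Embed a literal/wildcard motif into a peptide sequence
#'
#' Literal residues of `pattern` overwrite the draft sequence at the chosen
#' start; `"x"` (or `"X"` used as wildcard here is not allowed — the canonical
#' alphabet reserves X) wildcards leave the underlying residues untouched.
#' Used to plant proline-rich cores such as `"PxxP"` into random peptides.
#'
#' @param sequence A single peptide sequence.
#' @param pattern Motif of canonical residues and `"x"` wildcards.
#' @param at 1-based start position; when `NULL`, sampled uniformly among
#'   valid placements (under `seed` if given).
#' @param seed Optional integer seed for the placement draw.
#' @return The modified sequence.
#' @export
#' @examples
#' embed_motif("AAAAAAAAAA", "PxxP", at = 5)  # residues 5 and 8 become P
embed_motif <- function(sequence, pattern, at = NULL, seed = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            is.character(pattern), length(pattern) == 1L)
  validate_peptides(sequence)
  pat <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  ok <- pat == "x" | pat %in% amino_acids()
  if (!all(ok))
    stop("invalid pattern character '", pat[which(!ok)[1L]],
         "': use canonical residues and 'x' wildcards")
  N <- nchar(sequence); L <- length(pat)
  if (L > N) stop("motif longer than the peptide")
  if (is.null(at)) {
    draw <- function() sample.int(N - L + 1L, 1L)
    at <- if (is.null(seed)) draw() else with_seed(seed, draw())
  }
  if (at < 1L || at + L - 1L > N) stop("motif placement out of range")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  lit <- pat != "x"
  chars[at - 1L + which(lit)] <- pat[lit]
  paste(chars, collapse = "")
}

#' Simulate a SPOT peptide array with known ground truth
#'
#' Generates a per-domain dataset shaped like a real SPOT selection: ~1000
#' peptides of 13--14 residues, each carrying a proline-rich core motif at a
#' random position, with intensities produced by a known multi-site (or
#' single-site) energy model plus Gaussian energy-scale noise.  The observed
#' pseudo-energy is the clean model energy plus `Normal(0, noise_sd)`, and
#' the intensity is its exact inverse `exp(-pseudo_energy)` (noise is
#' log-normal on the intensity scale, additive on the energy scale — the
#' scale on which the fitting error lives).
#'
#' The defaults mirror the study conditions the models are meant for:
#' 1000 peptides, a 50/50 mix of 13- and 14-mers, a `PxxP` core, a true
#' window size of 6, true J values drawn once from `Normal(0, 1)` RT, an
#' offset of 5 RT (placing pseudo-energies in a plausible small/negative
#' range after the log-sum-exp), and 0.1 RT observation noise.
#'
#' @param n_peptides Number of array spots.
#' @param lengths Integer vector of peptide lengths on offer.
#' @param length_props Sampling proportions for `lengths` (summing to 1).
#' @param aa_freqs Optional named residue-frequency vector over
#'   [amino_acids()]; uniform when `NULL`.
#' @param motif Motif pattern planted in every peptide (literals + `"x"`
#'   wildcards), or `NULL` for none.
#' @param truth `"ms"` or `"ss"` — which model generates the clean energies.
#' @param window_size True window size S of the generating model.
#' @param J_mean,J_sd Normal distribution of the true non-reference J values
#'   (RT units).
#' @param alpha True offset \eqn{\alpha} (MS) (RT units); for SS truth it is
#'   used as the intercept J0.
#' @param site 0-based representative site of an SS truth.
#' @param noise_sd Observation noise sd on the energy scale (RT units).
#' @param seed Integer seed; the full dataset is reproducible from it.
#' @param domain Domain label stamped on the records.
#' @return A list of class `"spot_sim"`: `records` (data frame with
#'   `domain`, `peptide_id`, `sequence`, `intensity`, `pseudo_energy`),
#'   `truth` (the generating `ms_model`/`ss_model`), `clean` (noise-free
#'   energies), and `config`.
#' @export
simulate_spot_array <- function(n_peptides = 1000L,
                                lengths = c(13L, 14L),
                                length_props = NULL,
                                aa_freqs = NULL,
                                motif = "PxxP",
                                truth = c("ms", "ss"),
                                window_size = 6L,
                                J_mean = 0, J_sd = 1,
                                alpha = 5,
                                site = 3L,
                                noise_sd = 0.1,
                                seed = 1L,
                                domain = "synthetic") {
  truth <- match.arg(truth)
  S <- check_window_size(window_size)
  if (n_peptides < 1L) stop("'n_peptides' must be >= 1")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  lengths <- as.integer(lengths)
  if (any(lengths < S)) stop("peptide lengths must be >= the window size")
  if (is.null(length_props)) length_props <- rep(1 / length(lengths), length(lengths))
  if (length(length_props) != length(lengths) ||
      abs(sum(length_props) - 1) > 1e-8)
    stop("'length_props' must match 'lengths' and sum to 1")
  aa <- amino_acids()
  if (is.null(aa_freqs)) {
    aa_freqs <- setNames(rep(1 / 20, 20), aa)
  } else {
    if (!all(aa %in% names(aa_freqs))) stop("'aa_freqs' must be named by all 20 amino acids")
    aa_freqs <- aa_freqs[aa] / sum(aa_freqs[aa])
  }
  if (!is.null(motif) && nchar(motif) > min(lengths))
    stop("motif longer than the shortest peptide length")
  if (truth == "ss" && site + S > min(lengths))
    stop("SS truth site out of range for the shortest peptide length")

  prof <- reference_profile(window_size = S, policy = "fixed_alanine")
  out <- with_seed(seed, {
    J <- matrix(0, 20L, S, dimnames = list(aa, NULL))
    nonref <- aa != "A"
    J[nonref, ] <- rnorm(19L * S, J_mean, J_sd)
    model <- if (truth == "ms") ms_model(J, alpha = alpha, profile = prof)
             else ss_model(J, J0 = alpha, site = site, profile = prof)
    len <- lengths[sample.int(length(lengths), n_peptides, replace = TRUE,
                              prob = length_props)]
    sequences <- vapply(len, function(N)
      paste(sample(aa, N, replace = TRUE, prob = aa_freqs), collapse = ""),
      character(1))
    if (!is.null(motif))
      sequences <- vapply(sequences, embed_motif, character(1),
                          pattern = motif, USE.NAMES = FALSE)
    clean <- unname(energy_profile(model, sequences)$total)
    observed <- clean + rnorm(n_peptides, 0, noise_sd)
    list(model = model, sequences = sequences, clean = clean,
         observed = observed)
  })
  ids <- default_ids(out$sequences)
  records <- data.frame(domain = domain, peptide_id = ids,
                        sequence = out$sequences,
                        intensity = exp(-out$observed),
                        pseudo_energy = out$observed,
                        stringsAsFactors = FALSE)
  structure(list(records = records, truth = out$model,
                 clean = setNames(out$clean, ids),
                 config = list(n_peptides = n_peptides, lengths = lengths,
                               length_props = length_props, aa_freqs = aa_freqs,
                               motif = motif, truth = truth, window_size = S,
                               J_mean = J_mean, J_sd = J_sd, alpha = alpha,
                               site = if (truth == "ss") site else NA_integer_,
                               noise_sd = noise_sd, seed = seed,
                               domain = domain)),
            class = "spot_sim")
}

#' @export
print.spot_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("synthetic SPOT array: %d peptides (lengths %s), %s truth, S = %d\n",
              cfg$n_peptides, paste(cfg$lengths, collapse = "/"),
              toupper(cfg$truth), cfg$window_size))
  cat(sprintf("  motif %s, noise sd %.3g RT, seed %d\n",
              cfg$motif %||% "none", cfg$noise_sd, cfg$seed))
  cat(sprintf("  pseudo-energy range: [%.2f, %.2f] RT\n",
              min(x$records$pseudo_energy), max(x$records$pseudo_energy)))
  invisible(x)
}
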