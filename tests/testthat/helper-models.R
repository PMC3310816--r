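# Shared fixtures: tiny hand-built models and a deterministic random-peptide
# generator, all constructed in code.

aa20 <- amino_acids()

# A 20 x S matrix of J energies with alanine-reference zeros.
make_J <- function(S, fill = 0) {
  J <- matrix(fill, 20L, S, dimnames = list(aa20, NULL))
  J["A", ] <- 0
  J
}

ala_profile <- function(S) reference_profile(window_size = S, policy = "fixed_alanine")

# MS model with explicit per-(position, residue) energies:
# entries is a list of c(position, residue, value).
tiny_ms <- function(S, entries = list(), alpha = 0) {
  J <- make_J(S)
  for (e in entries) J[e[[2]], as.integer(e[[1]])] <- as.numeric(e[[3]])
  ms_model(J, alpha = alpha, profile = ala_profile(S))
}

random_peptides <- function(n, len, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(aa20, len, replace = TRUE), collapse = ""), character(1))
}

# Direct-summation oracle for the MS total: alpha - ln sum exp(-g), no
# stabilization, independent of the package's grouped log-sum-exp path.
lse_oracle <- function(g, alpha = 0) alpha - log(sum(exp(-g)))

`%||%` <- function(a, b) if (is.null(a)) b else a
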