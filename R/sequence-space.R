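## Peptide representation, sliding windows, and the indicator-basis encoding.

#' The canonical amino-acid alphabet
#'
#' The 20 canonical one-letter codes in alphabetical order.  This ordering is
#' load-bearing: within each window position the 19 non-reference indicator
#' slots are laid out alphabetically with the reference residue removed, so a
#' serialized model is portable across sessions.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' amino_acids()
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Validate peptide sequences
#'
#' Checks that every residue is one of the 20 canonical uppercase one-letter
#' codes.  Non-canonical codes (B, J, O, U, X, Z, lowercase, gaps) are rejected
#' with an error naming the offending character and its position; SPOT
#' peptides are synthesized from canonical residues only.
#'
#' @param sequences Character vector of peptide sequences.
#' @return Invisibly, `sequences`.
#' @export
validate_peptides <- function(sequences) {
  if (!is.character(sequences) || length(sequences) == 0L)
    stop("'sequences' must be a non-empty character vector")
  if (anyNA(sequences) || any(nchar(sequences) < 1L))
    stop("peptide sequences must be non-missing and non-empty")
  aa <- amino_acids()
  for (i in seq_along(sequences)) {
    chars <- strsplit(sequences[[i]], "", fixed = TRUE)[[1L]]
    bad <- which(!chars %in% aa)
    if (length(bad)) {
      stop(sprintf(
        "invalid residue '%s' at position %d of sequence %d ('%s'); only the 20 canonical uppercase amino-acid codes are allowed",
        chars[bad[1L]], bad[1L], i, sequences[[i]]))
    }
  }
  invisible(sequences)
}

#' Enumerate the sliding windows of a peptide
#'
#' A length-N peptide has N-S+1 contiguous windows of size S, each a candidate
#' binding site.  Windows are enumerated left to right; starts are 0-based and
#' half-open internally (the window at start r covers residues r+1..r+S in
#' 1-based sequence coordinates).
#'
#' @param sequence A single peptide sequence.
#' @param window_size Window size S (integer >= 1).
#' @return A data frame with columns `start` (0-based offset) and
#'   `subsequence`; zero rows when S exceeds the peptide length.
#' @export
#' @examples
#' peptide_windows("ACDEF", 2)  # "AC","CD","DE","EF"
peptide_windows <- function(sequence, window_size) {
  S <- check_window_size(window_size)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  validate_peptides(sequence)
  N <- nchar(sequence)
  if (S > N)
    return(data.frame(start = integer(0), subsequence = character(0),
                      stringsAsFactors = FALSE))
  starts <- 0:(N - S)
  data.frame(start = starts,
             subsequence = substring(sequence, starts + 1L, starts + S),
             stringsAsFactors = FALSE)
}

check_window_size <- function(window_size) {
  if (!is.numeric(window_size) || length(window_size) != 1L ||
      is.na(window_size) || window_size < 1 || window_size != round(window_size))
    stop("'window_size' must be a single integer >= 1")
  as.integer(window_size)
}

#' Build a per-position reference profile
#'
#' The additive energy expansion is anchored on one reference residue per
#' window position (that residue carries energy 0 by convention).  Two
#' policies are available: `"most_frequent"` takes the modal residue per
#' position over the supplied training windows (ties broken alphabetically),
#' which centers the expansion on the data; `"fixed_alanine"` uses alanine
#' everywhere and is handy for reproducibility experiments and simulations.
#'
#' @param windows Character vector of equal-length window subsequences
#'   (ignored for `"fixed_alanine"` except to determine S when `window_size`
#'   is missing).
#' @param policy `"most_frequent"` or `"fixed_alanine"`.
#' @param window_size Window size S; inferred from `windows` when missing.
#' @return A character vector of length S (class `"reference_profile"`), with
#'   the policy recorded in `attr(, "policy")`.
#' @export
reference_profile <- function(windows = NULL,
                              policy = c("most_frequent", "fixed_alanine"),
                              window_size = NULL) {
  policy <- match.arg(policy)
  if (is.null(window_size)) {
    if (is.null(windows) || length(windows) == 0L)
      stop("need non-empty 'windows' (or an explicit 'window_size')")
    window_size <- nchar(windows[[1L]])
  }
  S <- check_window_size(window_size)
  if (policy == "fixed_alanine") {
    ref <- rep("A", S)
  } else {
    if (is.null(windows) || length(windows) == 0L)
      stop("policy 'most_frequent' requires a non-empty window list")
    if (any(nchar(windows) != S))
      stop("all windows must have length ", S)
    validate_peptides(windows)
    ref <- vapply(seq_len(S), function(s) {
      res <- substr(windows, s, s)
      tab <- table(res)
      # ties broken alphabetically: table() is already sorted by name
      names(tab)[which.max(tab)]
    }, character(1))
  }
  structure(ref, class = "reference_profile", policy = policy)
}

#' Encode windows in the indicator basis
#'
#' Each window sequence maps to a binary feature vector: a leading intercept
#' indicator (always 1) followed by S blocks of 19 indicators, one block per
#' window position, over the 19 non-reference residues in alphabetical order.
#' A block is all-zero exactly when its position carries the reference
#' residue.  The per-window additive energy is linear in this vector.
#'
#' @param windows Character vector of window subsequences, all of length
#'   `length(profile)`.
#' @param profile A [reference_profile()] (or plain character vector of
#'   reference residues).
#' @param intercept Include the leading intercept column (default `TRUE`).
#' @return A binary matrix with one row per window and `1 + 19*S` columns
#'   (or `19*S` without the intercept), with informative column names.
#' @export
#' @examples
#' encode_windows("CA", reference_profile(window_size = 2, policy = "fixed_alanine"))
encode_windows <- function(windows, profile, intercept = TRUE) {
  S <- length(profile)
  if (S < 1L) stop("empty reference profile")
  if (length(windows) == 0L) stop("no windows to encode")
  if (any(nchar(windows) != S))
    stop("window size must equal profile size (", S, ")")
  validate_peptides(windows)
  validate_peptides(as.character(profile))
  aa <- amino_acids()
  F <- matrix(0, nrow = length(windows), ncol = 19L * S)
  cn <- character(19L * S)
  for (s in seq_len(S)) {
    nonref <- setdiff(aa, profile[[s]])
    cols <- (s - 1L) * 19L + seq_len(19L)
    cn[cols] <- paste0("p", s, ".", nonref)
    slot <- match(substr(windows, s, s), nonref)   # NA for the reference residue
    hit <- which(!is.na(slot))
    if (length(hit))
      F[cbind(hit, (s - 1L) * 19L + slot[hit])] <- 1
  }
  colnames(F) <- cn
  if (intercept) {
    F <- cbind(`(Intercept)` = 1, F)
  }
  F
}

## Internal workhorse: decompose a set of peptides (all of length >= S) into
## their windows, flat across peptides with a group index.
window_split <- function(sequences, S) {
  validate_peptides(sequences)
  N <- nchar(sequences)
  if (any(N < S)) stop("all peptides must be at least as long as the window size")
  nwin <- N - S + 1L
  pep <- rep.int(seq_along(sequences), nwin)
  start <- unlist(lapply(nwin, function(k) 0:(k - 1L)), use.names = FALSE)
  windows <- substring(rep.int(sequences, nwin), start + 1L, start + S)
  list(pep = pep, start = start, windows = windows, n_windows = nwin)
}

## window_split plus the indicator encoding (no intercept; the MS model
## fixes J0 = 0 and keeps the offset in alpha).
window_design <- function(sequences, S, profile) {
  d <- window_split(sequences, S)
  d$F <- encode_windows(d$windows, profile, intercept = FALSE)
  d
}
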