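## Plain-text IO: SPOT tables (TSV), model JSON, FASTA proteome scans.

#' Convert SPOT intensities to pseudo-binding energies
#'
#' The pseudo-binding free energy of a spot is the negative natural
#' logarithm of its light intensity, `-ln(BLU)`, a dimensionless (RT-unit)
#' stand-in for the true binding free energy; larger intensity means
#' stronger binding, i.e. lower energy.
#'
#' @param blu Numeric vector of intensities (arbitrary light units, > 0).
#' @return Pseudo-energies in RT units.
#' @export
#' @examples
#' intensity_to_energy(1)        # 0
#' intensity_to_energy(exp(1))   # -1
intensity_to_energy <- function(blu) {
  if (!is.numeric(blu)) stop("'blu' must be numeric")
  bad <- which(!is.finite(blu) | blu <= 0)
  if (length(bad))
    stop("intensity must be a positive finite number; offending record(s): ",
         paste(head(bad, 5L), collapse = ", "))
  -log(blu)
}

#' @rdname intensity_to_energy
#' @param energy Pseudo-energies (RT units).
#' @export
energy_to_intensity <- function(energy) {
  if (!is.numeric(energy) || any(!is.finite(energy)))
    stop("'energy' must be finite numeric")
  exp(-energy)
}

#' Read a SPOT peptide-array table
#'
#' Reads a TSV (or CSV) with a header and optional `#` comment lines.
#' Required: a `sequence` column plus either `intensity` (BLU) or
#' `pseudo_energy` (RT); optional `domain` and `peptide_id` (auto-generated
#' from the row index when absent).  The missing one of
#' intensity/pseudo_energy is back-filled via the exact maps
#' `E = -ln(BLU)` / `BLU = exp(-E)`.  Rows with non-positive or non-finite
#' intensity, non-finite energy, or non-canonical residues are rejected with
#' a warning listing their line numbers.
#'
#' @param path Input file.
#' @param sep Field separator; `"\t"` (default) or `","`.
#' @return A data frame with columns `domain`, `peptide_id`, `sequence`,
#'   `intensity`, `pseudo_energy`; attributes `n_accepted` / `n_rejected`.
#' @export
read_spot_table <- function(path, sep = "\t") {
  tab <- read.delim(path, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = TRUE)
  if (!"sequence" %in% names(tab))
    stop("SPOT table must have a 'sequence' column: ", path)
  if (!any(c("intensity", "pseudo_energy") %in% names(tab)))
    stop("SPOT table must have an 'intensity' or 'pseudo_energy' column: ", path)
  n <- nrow(tab)
  keep <- rep(TRUE, n)
  why <- character(n)
  seqs <- toupper(trimws(as.character(tab$sequence)))
  aa_ok <- vapply(seqs, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    length(chars) > 0L && all(chars %in% amino_acids())
  }, logical(1), USE.NAMES = FALSE)
  keep[!aa_ok] <- FALSE; why[!aa_ok] <- "non-canonical residue"
  if ("intensity" %in% names(tab)) {
    blu <- suppressWarnings(as.numeric(tab$intensity))
    bad <- !is.finite(blu) | blu <= 0
    keep[bad] <- FALSE; why[bad & why == ""] <- "non-positive intensity"
  }
  if ("pseudo_energy" %in% names(tab)) {
    en <- suppressWarnings(as.numeric(tab$pseudo_energy))
    bad <- !is.finite(en)
    keep[bad] <- FALSE; why[bad & why == ""] <- "non-finite pseudo-energy"
  }
  if (any(!keep)) {
    lines <- which(!keep)
    warning(sum(!keep), " row(s) rejected (", path, "): ",
            paste(sprintf("row %d: %s", head(lines, 5L), head(why[lines], 5L)),
                  collapse = "; "),
            if (length(lines) > 5L) "; ..." else "")
  }
  idx <- which(keep)
  intensity <- if ("intensity" %in% names(tab))
    as.numeric(tab$intensity)[idx] else exp(-as.numeric(tab$pseudo_energy)[idx])
  pseudo <- if ("pseudo_energy" %in% names(tab))
    as.numeric(tab$pseudo_energy)[idx] else -log(intensity)
  out <- data.frame(
    domain = if ("domain" %in% names(tab)) as.character(tab$domain)[idx] else "unknown",
    peptide_id = if ("peptide_id" %in% names(tab)) as.character(tab$peptide_id)[idx]
                 else as.character(idx),
    sequence = seqs[idx],
    intensity = intensity,
    pseudo_energy = pseudo,
    stringsAsFactors = FALSE)
  if (anyDuplicated(paste(out$domain, out$peptide_id)))
    stop("duplicate (domain, peptide_id) keys in ", path)
  attr(out, "n_accepted") <- nrow(out)
  attr(out, "n_rejected") <- sum(!keep)
  attr(out, "source") <- path
  out
}

#' Write a SPOT table as TSV
#'
#' Numeric fields are written with `%.17g`, so a read/write/read round trip
#' is lossless at double precision.
#'
#' @param x Data frame with at least `sequence` and one of
#'   `intensity` / `pseudo_energy`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_spot_table <- function(x, path) {
  if (!"sequence" %in% names(x)) stop("'x' must have a 'sequence' column")
  out <- data.frame(
    domain = if ("domain" %in% names(x)) x$domain else "unknown",
    peptide_id = if ("peptide_id" %in% names(x)) x$peptide_id
                 else as.character(seq_len(nrow(x))),
    sequence = x$sequence, stringsAsFactors = FALSE)
  if ("intensity" %in% names(x)) out$intensity <- sprintf("%.17g", x$intensity)
  if ("pseudo_energy" %in% names(x)) out$pseudo_energy <- sprintf("%.17g", x$pseudo_energy)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a fitted or constructed model to JSON
#'
#' The document records everything needed to reproduce predictions: model
#' kind, window size, reference profile, the amino-acid ordering behind the
#' indicator encoding, the full J table (position -> residue -> energy,
#' including the zero reference entries), J0 / alpha / site, and an optional
#' provenance block (seed, config echo, per-restart SSEs for a fit).
#' Round trips are lossless at full float precision.
#'
#' @param model An `"ms_model"` or `"ss_model"` (fitted or not).
#' @param path Output JSON file.
#' @param provenance Optional named list merged into the provenance block.
#' @return Invisibly, `path`.
#' @export
write_model_json <- function(model, path, provenance = list()) {
  stopifnot(inherits(model, c("ms_model", "ss_model")))
  aa <- amino_acids()
  S <- model$window_size
  J_table <- lapply(seq_len(S), function(s) as.list(setNames(model$J[, s], aa)))
  names(J_table) <- paste0("p", seq_len(S))
  prov <- c(list(package = "spotms",
                 version = as.character(utils::packageVersion("spotms"))),
            provenance)
  if (!is.null(model$config)) prov$fit_config <- model$config
  if (!is.null(model$restart_sse)) prov$restart_sse <- model$restart_sse
  doc <- list(model_kind = if (inherits(model, "ms_model")) "ms" else "ss",
              window_size = S,
              reference_profile = as.character(model$profile),
              profile_policy = attr(model$profile, "policy") %||% "custom",
              amino_acid_order = aa,
              J_table = J_table,
              J0 = model$J0,
              alpha = if (inherits(model, "ms_model")) model$alpha else NULL,
              site_offset = if (inherits(model, "ss_model")) model$site else NULL,
              provenance = prov)
  # digits = I(17): 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a model back from JSON
#'
#' @param path JSON file written by [write_model_json()].
#' @return An `"ms_model"` or `"ss_model"`.
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  aa <- amino_acids()
  if (!identical(as.character(doc$amino_acid_order), aa))
    stop("unsupported amino-acid ordering in ", path)
  S <- as.integer(doc$window_size)
  prof <- structure(as.character(doc$reference_profile),
                    class = "reference_profile",
                    policy = doc$profile_policy %||% "custom")
  J <- vapply(seq_len(S), function(s)
    unlist(doc$J_table[[paste0("p", s)]])[aa], numeric(20))
  rownames(J) <- aa
  if (identical(doc$model_kind, "ms"))
    ms_model(J, alpha = doc$alpha, profile = prof)
  else
    ss_model(J, J0 = doc$J0, site = doc$site_offset, profile = prof)
}

#' Scan proteins from a FASTA file with an MS model
#'
#' Tiles each protein into `peptide_length`-mers at the given step, scores
#' every tile with the MS ensemble energy and MLP, and returns one
#' localization report over all tiles, sorted by predicted energy.  Tile ids
#' are `"<protein>|<start>"` with a 0-based start.  Proteins shorter than
#' `peptide_length`, and tiles containing non-canonical residues, are
#' skipped with a warning count.
#'
#' @param model An `"ms_model"`.
#' @param path FASTA file of protein sequences (requires the Biostrings
#'   package).
#' @param peptide_length Tile length L (>= the model's window size).
#' @param step Tiling step (default 1).
#' @return A [localization_report()] over all scored tiles.
#' @export
scan_fasta <- function(model, path, peptide_length, step = 1L) {
  stopifnot(inherits(model, "ms_model"))
  L <- check_window_size(peptide_length)
  if (L < model$window_size)
    stop("'peptide_length' must be >= the model window size (", model$window_size, ")")
  if (step < 1L || step != round(step)) stop("'step' must be a positive integer")
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("scan_fasta() requires the Biostrings package")
  seqs <- Biostrings::readAAStringSet(path)
  proteins <- toupper(as.character(seqs))
  names(proteins) <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1L)
  n_short <- sum(nchar(proteins) < L)
  if (n_short)
    warning(n_short, " protein(s) shorter than the tile length skipped")
  tiles <- character(0); ids <- character(0)
  for (nm in names(proteins)[nchar(proteins) >= L]) {
    p <- proteins[[nm]]
    starts <- seq.int(1L, nchar(p) - L + 1L, by = step)
    tiles <- c(tiles, substring(p, starts, starts + L - 1L))
    ids <- c(ids, paste0(nm, "|", starts - 1L))
  }
  ok <- vapply(tiles, function(s)
    all(strsplit(s, "", fixed = TRUE)[[1L]] %in% amino_acids()),
    logical(1), USE.NAMES = FALSE)
  if (any(!ok))
    warning(sum(!ok), " tile(s) with non-canonical residues skipped")
  if (!any(ok)) stop("no scannable tiles in ", path)
  localization_report(model, tiles[ok], ids = ids[ok])
}
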