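# Sequence-level glycosylation accounting: N-glycosylation sequon
# scanning (the canonical N-X(!=P)-[S/T] rule), average-mass chain
# computation with optional signal-peptide / GPI trimming, and glycoform
# mass-shift bookkeeping.

# Average (not monoisotopic) residue masses in Da, ExPASy-style; a residue
# mass is the free amino acid minus one water. Pinned here so chain masses
# are stable across releases.
AA_RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

WATER_MASS <- 18.0153

#' Average residue mass table
#'
#' @return Named numeric vector of the 20 canonical average residue
#'   masses (Da) used by [average_mass()].
#' @export
aa_residue_masses <- function() AA_RESIDUE_MASS

.validate_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 ||
      nchar(sequence) == 0) {
    stop("sequence must be a non-empty character scalar")
  }
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% names(AA_RESIDUE_MASS))
  if (length(bad) > 0) {
    stop(sprintf("non-canonical residue '%s' at position %d",
                 chars[bad[1]], bad[1]))
  }
  chars
}

#' Construct a protein record
#'
#' @param id record identifier.
#' @param sequence uppercase amino-acid string over the 20 canonical
#'   letters; positions are 1-based on this (untrimmed) chain.
#' @param signal_end last residue of the signal peptide (so the mature
#'   chain starts at `signal_end + 1`), or `NA`.
#' @param gpi_omega GPI-anchor omega-site position (last residue retained
#'   in the mature, anchored chain), or `NA`.
#' @return Class `"protein_record"`.
#' @export
protein_record <- function(id, sequence, signal_end = NA_integer_,
                           gpi_omega = NA_integer_) {
  .validate_sequence(sequence)
  n <- nchar(sequence)
  if (!is.na(signal_end) &&
      (signal_end < 1 || signal_end >= n)) {
    stop("signal_end must satisfy 1 <= signal_end < length(sequence)")
  }
  if (!is.na(gpi_omega) && (gpi_omega < 1 || gpi_omega > n)) {
    stop("gpi_omega must lie within the sequence")
  }
  if (!is.na(signal_end) && !is.na(gpi_omega) &&
      signal_end >= gpi_omega) {
    stop("signal_end must be < gpi_omega")
  }
  structure(list(id = as.character(id), sequence = sequence,
                 signal_end = as.integer(signal_end),
                 gpi_omega = as.integer(gpi_omega)),
            class = "protein_record")
}

#' Read protein records from a FASTA file
#'
#' @param path FASTA file (single or multi-record).
#' @return A list of [protein_record()] objects (boundaries unset; signal
#'   and GPI boundaries are external inputs).
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  lapply(seq_along(seqs), function(i) {
    protein_record(attr(seqs[[i]], "name"),
                   toupper(as.character(seqs[[i]])))
  })
}

.as_sequence <- function(x) {
  if (inherits(x, "protein_record")) x$sequence else x
}

#' Scan for N-glycosylation sequons
#'
#' Reports all (overlapping) occurrences of the canonical sequon
#' N-X-[S/T] with X != P: positions `i` such that residue `i` is N,
#' residue `i+1` is not P, and residue `i+2` is S or T. No veto is
#' applied at position `i+2`. Positions are 1-based on the untrimmed
#' chain, so they are directly comparable to "N141"-style annotations.
#'
#' @param x a [protein_record()] or an amino-acid string.
#' @return data.frame with `position` (strictly increasing) and `motif`
#'   (the 3-residue window).
#' @export
scan_nglyc_sequons <- function(x) {
  seq <- .as_sequence(x)
  chars <- .validate_sequence(seq)
  n <- length(chars)
  if (n < 3) {
    return(data.frame(position = integer(0), motif = character(0)))
  }
  i <- seq_len(n - 2)
  hit <- chars[i] == "N" & chars[i + 1] != "P" & chars[i + 2] %in% c("S", "T")
  pos <- i[hit]
  data.frame(position = pos,
             motif = vapply(pos, function(p)
               paste(chars[p:(p + 2)], collapse = ""), character(1)),
             stringsAsFactors = FALSE)
}

#' Average mass of a (optionally trimmed) protein chain
#'
#' Sum of average residue masses plus one water for the terminal groups:
#' `sum(residues) + 18.0153 Da`, equivalently free amino-acid masses
#' minus `(n - 1)` waters. Trimming `remove_signal` retains residues
#' `signal_end + 1 .. end`; `remove_signal_and_gpi` retains
#' `signal_end + 1 .. gpi_omega` (the mature, anchor-trimmed chain whose
#' mass matches coding-sequence MW predictions without saccharides).
#'
#' @param x a [protein_record()] (required for trimming) or an
#'   amino-acid string.
#' @param trim `"none"`, `"remove_signal"`, or
#'   `"remove_signal_and_gpi"`.
#' @return Mass in kDa.
#' @export
average_mass <- function(x, trim = c("none", "remove_signal",
                                     "remove_signal_and_gpi")) {
  trim <- match.arg(trim)
  seq <- .as_sequence(x)
  chars <- .validate_sequence(seq)
  from <- 1L
  to <- length(chars)
  if (trim != "none") {
    if (!inherits(x, "protein_record")) {
      stop("trimming requires a protein_record with boundaries")
    }
    if (is.na(x$signal_end)) stop("trim requested but signal_end is unset")
    from <- x$signal_end + 1L
    if (trim == "remove_signal_and_gpi") {
      if (is.na(x$gpi_omega)) stop("trim requested but gpi_omega is unset")
      to <- x$gpi_omega
    }
  }
  kept <- chars[from:to]
  (sum(AA_RESIDUE_MASS[kept]) + WATER_MASS) / 1000
}

#' Mass shift between glycoform chains
#'
#' Difference between a mature (glycosylated) and pre-mature
#' (non-glycosylated) chain mass; the glycan contribution. Sign is
#' preserved.
#'
#' @param mature_kDa,premature_kDa chain masses in kDa, both > 0.
#' @return `mature_kDa - premature_kDa` in kDa.
#' @export
glycoform_mass_shift <- function(mature_kDa, premature_kDa) {
  if (mature_kDa <= 0 || premature_kDa <= 0) {
    stop("chain masses must be > 0")
  }
  mature_kDa - premature_kDa
}

#' Sequon report for a protein record
#'
#' Convenience wrapper bundling [scan_nglyc_sequons()] positions with the
#' chain mass at the requested trim.
#'
#' @inheritParams average_mass
#' @return list with `id`, `positions`, `motifs`, `chain_mass_kDa`,
#'   `trim`.
#' @export
sequon_report <- function(x, trim = "none") {
  hits <- scan_nglyc_sequons(x)
  list(id = if (inherits(x, "protein_record")) x$id else NA_character_,
       positions = hits$position, motifs = hits$motif,
       chain_mass_kDa = average_mass(x, trim = trim), trim = trim)
}
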