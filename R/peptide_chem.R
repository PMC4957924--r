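## Mass arithmetic for synthesised phosphopeptides: N-terminal acetylation,
## C-terminal amidation, phosphotyrosine, and [M+H]+/[M+Na]+ adduct ions.

## Monoisotopic amino-acid residue masses (Da), IUPAC/CODATA standard
## atomic masses (residue = amino acid - H2O).
MONO_RESIDUE <- c(
  A = 71.037114, C = 103.009185, D = 115.026943, E = 129.042593,
  F = 147.068414, G = 57.021464, H = 137.058912, I = 113.084064,
  K = 128.094963, L = 113.084064, M = 131.040485, N = 114.042927,
  P = 97.052764, Q = 128.058578, R = 156.101111, S = 87.032028,
  T = 101.047679, V = 99.068414, W = 186.079313, Y = 163.063329
)

## Average residue masses (Da), standard atomic weights.
AVG_RESIDUE <- c(
  A = 71.0788, C = 103.1388, D = 115.0886, E = 129.1155,
  F = 147.1766, G = 57.0519, H = 137.1411, I = 113.1594,
  K = 128.1741, L = 113.1594, M = 131.1926, N = 114.1038,
  P = 97.1167, Q = 128.1307, R = 156.1875, S = 87.0782,
  T = 101.1051, V = 99.1326, W = 186.2132, Y = 163.1760
)

MONO_WATER <- 18.010565     # H2O
MONO_ACETYL <- 42.010565    # +C2H2O
MONO_AMIDE <- -0.984016     # -OH +NH2
MONO_PHOSPHO <- 79.966331   # +HPO3
AVG_WATER <- 18.01528
AVG_ACETYL <- 42.0367
AVG_AMIDE <- -0.98476
AVG_PHOSPHO <- 79.9799
MASS_PROTON <- 1.007276
MASS_SODIUM_ION <- 22.989218

#' Parse a phosphopeptide written in pY notation
#'
#' \code{"DPSDNpYAEPID"} denotes the 11-mer DPSDNYAEPID phosphorylated on
#' the tyrosine after the \code{p} flag; multiple \code{pY} occurrences are
#' allowed (e.g. doubly phosphorylated peptides).
#'
#' @param text Peptide string with zero or more \code{pY} tokens.
#' @param n_terminal \code{"free"} or \code{"acetyl"}.
#' @param c_terminal \code{"free"} or \code{"amide"}.
#' @return An object of class \code{modified_peptide}: list with
#'   \code{sequence} (plain one-letter), \code{phospho_positions} (1-based,
#'   tyrosines only) and the terminal states.
#' @export
parse_modified_peptide <- function(text, n_terminal = c("free", "acetyl"),
                                   c_terminal = c("free", "amide")) {
  n_terminal <- match.arg(n_terminal)
  c_terminal <- match.arg(c_terminal)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  seq_chars <- character()
  phospho <- integer()
  i <- 1L
  while (i <= length(chars)) {
    if (chars[i] == "p") {
      if (i == length(chars) || chars[i + 1L] != "Y") {
        stop("'p' modification flag must be followed by Y in: ", text)
      }
      phospho <- c(phospho, length(seq_chars) + 1L)
      seq_chars <- c(seq_chars, "Y")
      i <- i + 2L
    } else {
      seq_chars <- c(seq_chars, chars[i])
      i <- i + 1L
    }
  }
  modified_peptide(paste(seq_chars, collapse = ""), phospho,
                   n_terminal, c_terminal)
}

#' Construct a modified peptide from explicit fields
#'
#' @param sequence Plain one-letter peptide sequence (20 standard AA).
#' @param phospho_positions Integer positions carrying a phosphate; each
#'   must point at a tyrosine.
#' @inheritParams parse_modified_peptide
#' @return A \code{modified_peptide}.
#' @export
modified_peptide <- function(sequence, phospho_positions = integer(),
                             n_terminal = c("free", "acetyl"),
                             c_terminal = c("free", "amide")) {
  n_terminal <- match.arg(n_terminal)
  c_terminal <- match.arg(c_terminal)
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  unknown <- setdiff(chars, names(MONO_RESIDUE))
  if (length(unknown) > 0L) {
    stop("unknown residue(s): ", paste(unknown, collapse = ", "))
  }
  phospho_positions <- as.integer(phospho_positions)
  if (any(phospho_positions < 1L | phospho_positions > length(chars))) {
    stop("phospho position outside the peptide")
  }
  if (any(chars[phospho_positions] != "Y")) {
    stop("phospho positions must point at tyrosine (Y)")
  }
  structure(list(sequence = sequence,
                 phospho_positions = sort(unique(phospho_positions)),
                 n_terminal = n_terminal, c_terminal = c_terminal),
            class = "modified_peptide")
}

peptide_mass <- function(p, residue, water, acetyl, amide, phospho) {
  stopifnot(inherits(p, "modified_peptide"))
  chars <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
  m <- sum(residue[chars]) + water
  if (p$n_terminal == "acetyl") m <- m + acetyl
  if (p$c_terminal == "amide") m <- m + amide
  m + phospho * length(p$phospho_positions)
}

#' Monoisotopic mass of a modified peptide
#'
#' Sum of monoisotopic residue masses plus water (18.010565 Da), plus
#' 42.010565 Da for an N-terminal acetyl, minus 0.984016 Da for a
#' C-terminal amide, plus 79.966331 Da per phosphate.
#'
#' @param p A \code{modified_peptide}.
#' @return Mass in Da.
#' @export
monoisotopic_mass <- function(p) {
  peptide_mass(p, MONO_RESIDUE, MONO_WATER, MONO_ACETYL, MONO_AMIDE,
               MONO_PHOSPHO)
}

#' Average (isotope-abundance-weighted) mass of a modified peptide
#'
#' @inheritParams monoisotopic_mass
#' @return Mass in Da.
#' @export
average_mass <- function(p) {
  peptide_mass(p, AVG_RESIDUE, AVG_WATER, AVG_ACETYL, AVG_AMIDE,
               AVG_PHOSPHO)
}

#' Theoretical singly charged adduct ion m/z
#'
#' @param mass Neutral monoisotopic (or average) mass in Da.
#' @param adduct \code{"H"} for [M+H]+ or \code{"Na"} for [M+Na]+.
#' @return m/z at charge 1.
#' @export
adduct_mz <- function(mass, adduct = c("H", "Na")) {
  adduct <- match.arg(adduct)
  if (!is.numeric(mass) || any(mass <= 0)) stop("mass must be positive")
  mass + switch(adduct, H = MASS_PROTON, Na = MASS_SODIUM_ION)
}

#' Mass report for a set of pY-notation peptides
#'
#' Computes monoisotopic and average masses of each peptide (by default
#' N-acetylated and C-amidated, the usual state of synthetic phosphopeptide
#' substrates), the integer part of the monoisotopic mass as the
#' conventional "calculated MW", and the theoretical [M+H]+ and [M+Na]+
#' m/z values.
#'
#' @param peptides Character vector in pY notation, or a TSV path with a
#'   \code{peptide} column.
#' @inheritParams parse_modified_peptide
#' @return Data frame with one row per peptide.
#' @export
mass_report <- function(peptides, n_terminal = "acetyl",
                        c_terminal = "amide") {
  if (length(peptides) == 1L && file.exists(peptides)) {
    peptides <- utils::read.delim(peptides, stringsAsFactors = FALSE)$peptide
  }
  rows <- lapply(peptides, function(txt) {
    p <- parse_modified_peptide(txt, n_terminal, c_terminal)
    mono <- monoisotopic_mass(p)
    data.frame(peptide = txt, sequence = p$sequence,
               n_phospho = length(p$phospho_positions),
               monoisotopic = mono, average = average_mass(p),
               calc_mw = floor(mono),
               mz_H = adduct_mz(mono, "H"), mz_Na = adduct_mz(mono, "Na"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
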