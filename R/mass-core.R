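#' Monoisotopic residue masses
#'
#' Monoisotopic masses of the 20 standard amino-acid residues (the mass each
#' residue contributes inside a peptide chain, i.e. the free amino acid minus
#' one water), in Daltons.
#'
#' @return Named numeric vector, names are one-letter residue codes.
#' @export
#' @examples
#' residue_masses()[["G"]]
residue_masses <- function() {
  c(
    A = 71.03711378, R = 156.10111102, N = 114.04292744, D = 115.02694302,
    C = 103.00918478, E = 129.04259309, Q = 128.05857751, G = 57.02146372,
    H = 137.05891186, I = 113.08406398, L = 113.08406398, K = 128.09496301,
    M = 131.04048491, F = 147.06841391, P = 97.05276385, S = 87.03202840,
    T = 101.04767847, W = 186.07931295, Y = 163.06332853, V = 99.06841391
  )
}

#' Mass constants for peptide and modification arithmetic
#'
#' Monoisotopic constants used throughout: the water added on hydrolysis, the
#' proton for the singly protonated MH+ ion, the citrullination mass shift
#' (arginine -> citrulline deimination, +0.984 Da), and the phenylglyoxal
#' (PGM) condensation adduct added per citrulline (+116.026 Da; phenylglyoxal
#' C8H6O2 condensing with loss of one water).
#'
#' @param water,proton,delta_cit,delta_pgm Override individual constants (Da).
#' @return Named list with elements `water`, `proton`, `delta_cit`, `delta_pgm`.
#' @export
mass_constants <- function(water = 18.010565, proton = 1.007276,
                           delta_cit = 0.984016, delta_pgm = 116.026215) {
  stopifnot(water > 0, proton > 0, delta_cit > 0, delta_pgm > 0)
  list(water = water, proton = proton, delta_cit = delta_cit, delta_pgm = delta_pgm)
}

split_residues <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  if (!nzchar(sequence)) stop("sequence must be non-empty", call. = FALSE)
  strsplit(sequence, "", fixed = TRUE)[[1L]]
}

#' Singly protonated monoisotopic peptide mass (MH+)
#'
#' Sum of monoisotopic residue masses plus water and a proton, plus the mass
#' shifts of any citrullinated arginines and, optionally, their PGM adducts.
#' PGM derivatizes every citrulline in the peptide when `pgm = TRUE`.
#'
#' @param sequence Amino-acid string (one-letter codes, 20 standard residues).
#' @param cit Integer positions (1-based within `sequence`) of citrullinated
#'   arginines. Each must be an `R` in the sequence.
#' @param pgm Logical; if `TRUE` each citrulline also carries the PGM adduct.
#' @param constants Mass constants, see [mass_constants()].
#' @param residues Residue mass table, see [residue_masses()].
#' @return MH+ in Daltons.
#' @export
#' @examples
#' peptide_mh("LRDSLFNYQK")                      # 1283.67 (2 dp)
#' peptide_mh("LRDSLFNYQK", cit = 2, pgm = TRUE) # shifted by ~117.01
peptide_mh <- function(sequence, cit = integer(), pgm = FALSE,
                       constants = mass_constants(), residues = residue_masses()) {
  aa <- split_residues(sequence)
  unknown <- setdiff(unique(aa), names(residues))
  if (length(unknown)) {
    stop("unknown residue symbol(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cit <- as.integer(cit)
  if (length(cit)) {
    if (anyDuplicated(cit)) stop("duplicated citrullination positions", call. = FALSE)
    if (any(cit < 1L | cit > length(aa))) {
      stop("citrullination position outside the peptide span", call. = FALSE)
    }
    not_r <- cit[aa[cit] != "R"]
    if (length(not_r)) {
      stop("citrullinated position(s) not an arginine: ",
           paste(not_r, collapse = ", "), call. = FALSE)
    }
  }
  sum(residues[aa]) + constants$water + constants$proton +
    mod_delta(length(cit), pgm, constants)
}

#' Mass shift of citrullination and PGM derivatization
#'
#' @param n_cit Number of citrullinated arginines (non-negative integer).
#' @param pgm Logical; if `TRUE` each citrulline also carries the PGM adduct.
#' @param constants Mass constants, see [mass_constants()].
#' @return Total mass shift in Daltons, `n_cit * delta_cit` plus
#'   `n_cit * delta_pgm` when `pgm` is `TRUE`; exactly linear in `n_cit`.
#' @export
#' @examples
#' mod_delta(1, pgm = TRUE) # ~117.01, the diagnostic PGM-derivatized shift
mod_delta <- function(n_cit, pgm = FALSE, constants = mass_constants()) {
  n_cit <- as.integer(n_cit)
  stopifnot(length(n_cit) == 1L, !is.na(n_cit))
  if (n_cit < 0L) stop("n_cit must be non-negative", call. = FALSE)
  n_cit * (constants$delta_cit + if (isTRUE(pgm)) constants$delta_pgm else 0)
}

#' Side-chain and terminal pKa values
#'
#' The EMBOSS pKa table used for isoelectric-point calculation: free alpha-amino
#' terminus 8.6, alpha-carboxyl terminus 3.6; basic side chains K 10.8, R 12.5,
#' H 6.5; acidic/ionizable side chains D 3.9, E 4.1, C 8.5, Y 10.1. Only the
#' ordering of pI shifts is scientifically asserted by this package, never an
#' absolute pI, so any self-consistent published table gives the same
#' qualitative behaviour.
#'
#' @return Named numeric vector with entries `Nterm`, `Cterm`, `K`, `R`, `H`,
#'   `D`, `E`, `C`, `Y`.
#' @export
pka_table <- function() {
  c(Nterm = 8.6, Cterm = 3.6, K = 10.8, R = 12.5, H = 6.5,
    D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
}

#' Theoretical isoelectric point of a peptide, with citrullination
#'
#' Solves net charge = 0 by bisection under a Henderson-Hasselbalch model.
#' Citrullination removes the arginine side-chain positive charge (citrulline
#' is neutral), so the pI is monotonically non-increasing in `n_cit`; which of
#' the arginines is citrullinated does not affect the net charge.
#'
#' @param sequence Amino-acid string.
#' @param n_cit Number of arginines converted to citrulline; must not exceed
#'   the number of `R` residues in `sequence`.
#' @param pka pKa table, see [pka_table()].
#' @param tol Bisection tolerance in pH units.
#' @return pI in pH units, inside (0, 14).
#' @export
#' @examples
#' isoelectric_point("SRIEILRR", 0) > isoelectric_point("SRIEILRR", 2)
isoelectric_point <- function(sequence, n_cit = 0L, pka = pka_table(),
                              tol = 1e-6) {
  aa <- split_residues(sequence)
  n_cit <- as.integer(n_cit)
  n_r <- sum(aa == "R")
  if (n_cit < 0L) stop("n_cit must be non-negative", call. = FALSE)
  if (n_cit > n_r) {
    stop("n_cit (", n_cit, ") exceeds the number of arginines (", n_r, ")",
         call. = FALSE)
  }
  counts_pos <- c(Nterm = 1, K = sum(aa == "K"), R = n_r - n_cit, H = sum(aa == "H"))
  counts_neg <- c(Cterm = 1, D = sum(aa == "D"), E = sum(aa == "E"),
                  C = sum(aa == "C"), Y = sum(aa == "Y"))
  net_charge <- function(ph) {
    pos <- sum(counts_pos / (1 + 10^(ph - pka[names(counts_pos)])))
    neg <- sum(counts_neg / (1 + 10^(pka[names(counts_neg)] - ph)))
    pos - neg
  }
  lo <- 1e-4
  hi <- 14 - 1e-4
  # net charge is strictly decreasing in pH, so the root is unique
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Load mass constants and pKa overrides from a YAML config
#'
#' The file may contain any of the top-level keys `constants` (sub-keys
#' `water`, `proton`, `delta_cit`, `delta_pgm`), `pka` (sub-keys as in
#' [pka_table()]), and `residues` (one-letter code to monoisotopic mass, e.g.
#' a fixed cysteine carbamidomethylation can be expressed as `C: 160.03065`).
#' Missing keys keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return List with elements `constants`, `pka`, `residues`, each directly
#'   usable as the corresponding argument of [peptide_mh()], [mod_delta()] and
#'   [isoelectric_point()].
#' @export
load_mass_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  constants <- mass_constants()
  for (k in intersect(names(cfg$constants), names(constants))) {
    constants[[k]] <- as.numeric(cfg$constants[[k]])
  }
  pka <- pka_table()
  for (k in intersect(names(cfg$pka), names(pka))) {
    pka[[k]] <- as.numeric(cfg$pka[[k]])
  }
  residues <- residue_masses()
  for (k in names(cfg$residues)) {
    residues[[k]] <- as.numeric(cfg$residues[[k]])
  }
  if (any(residues <= 0)) stop("residue masses must be strictly positive", call. = FALSE)
  list(constants = constants, pka = pka, residues = residues)
}
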