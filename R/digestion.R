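#' A protein chain with 1-based residue coordinates
#'
#' @param chain_id Chain label, e.g. `"alpha"`, `"beta"`, `"gamma"`.
#' @param sequence Amino-acid string; all residues must be standard.
#' @return Object of class `protein_chain`: a list with `chain_id` and
#'   `sequence`.
#' @export
protein_chain <- function(chain_id, sequence) {
  stopifnot(is.character(chain_id), length(chain_id) == 1L, nzchar(chain_id))
  aa <- split_residues(sequence)
  unknown <- setdiff(unique(aa), names(residue_masses()))
  if (length(unknown)) {
    stop("non-standard residue(s) in chain '", chain_id, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(chain_id = chain_id, sequence = sequence),
            class = "protein_chain")
}

#' @export
print.protein_chain <- function(x, ...) {
  cat("<protein_chain> ", x$chain_id, " (", nchar(x$sequence), " aa)\n", sep = "")
  invisible(x)
}

# Positions after which trypsin can cleave (Keil rule): C-terminal to K/R,
# never before proline. The chain C-terminus is a boundary regardless.
cleavage_positions <- function(aa) {
  n <- length(aa)
  if (n < 2L) return(integer())
  which(aa[-n] %in% c("K", "R") & aa[-1L] != "P")
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to lysine and arginine, never before proline (Keil
#' rule), retaining up to `max_missed` internal missed cleavage sites. The
#' zero-missed-cleavage peptides tile the chain exactly.
#'
#' @param chain A [protein_chain()].
#' @param max_missed Maximum internal missed cleavages (non-negative).
#' @return data.frame with columns `chain_id`, `start`, `end` (1-based,
#'   inclusive), `sequence`, `missed_cleavages`.
#' @export
#' @examples
#' digest(protein_chain("demo", "AKRPGR"), max_missed = 0)
digest <- function(chain, max_missed = 2L) {
  stopifnot(inherits(chain, "protein_chain"))
  max_missed <- as.integer(max_missed)
  if (max_missed < 0L) stop("max_missed must be non-negative", call. = FALSE)
  aa <- split_residues(chain$sequence)
  n <- length(aa)
  bounds <- c(0L, cleavage_positions(aa), n)
  bounds <- sort(unique(bounds))
  out <- list()
  nb <- length(bounds)
  for (i in seq_len(nb - 1L)) {
    for (j in (i + 1L):min(nb, i + 1L + max_missed)) {
      start <- bounds[i] + 1L
      end <- bounds[j]
      out[[length(out) + 1L]] <- data.frame(
        chain_id = chain$chain_id,
        start = start,
        end = end,
        sequence = paste(aa[start:end], collapse = ""),
        missed_cleavages = j - i - 1L,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Enumerate modification-aware candidate peptides
#'
#' Generates every tryptic peptide together with every admissible assignment
#' of citrullination to its arginines, honouring the fact that trypsin cannot
#' cleave after citrulline:
#' * a citrullinated internal arginine is a *blocked* site, not a missed
#'   cleavage; only uncitrullinated internal K/R cleavage sites consume the
#'   `max_missed` budget;
#' * a C-terminal arginine at an internal cleavage boundary cannot be
#'   citrullinated (trypsin could not have cleaved there otherwise);
#' * arginines before proline (non-cleavable) and a chain-terminal arginine
#'   may be citrullinated freely.
#'
#' When `pgm = TRUE`, every citrullinated candidate is emitted twice: once at
#' its native citrullinated mass and once PGM-derivatized (each citrulline
#' +116.026 Da), mirroring the paired spectra used to distinguish
#' citrullination from miscleavage.
#'
#' @param chain A [protein_chain()].
#' @param max_missed Maximum uncitrullinated internal cleavage sites.
#' @param max_cit Maximum citrullines per peptide.
#' @param pgm Logical; also emit PGM-derivatized forms of citrullinated
#'   candidates.
#' @param constants,residues See [peptide_mh()].
#' @return data.frame with columns `chain_id`, `start`, `end`, `sequence`,
#'   `cit` (list column of 1-based chain coordinates), `n_cit`, `pgm`,
#'   `missed_cleavages`, `theoretical_mh`.
#' @export
enumerate_candidates <- function(chain, max_missed = 2L, max_cit = 3L,
                                 pgm = TRUE, constants = mass_constants(),
                                 residues = residue_masses()) {
  stopifnot(inherits(chain, "protein_chain"))
  max_missed <- as.integer(max_missed)
  max_cit <- as.integer(max_cit)
  if (max_cit < 0L) stop("max_cit must be non-negative", call. = FALSE)
  if (max_missed < 0L) stop("max_missed must be non-negative", call. = FALSE)
  aa <- split_residues(chain$sequence)
  n <- length(aa)
  cleave <- cleavage_positions(aa)
  bounds <- sort(unique(c(0L, cleave, n)))
  nb <- length(bounds)

  rows <- list()
  emit <- function(start, end, cit, missed, with_pgm) {
    pep <- paste(aa[start:end], collapse = "")
    mh <- peptide_mh(pep, cit - start + 1L, pgm = with_pgm,
                     constants = constants, residues = residues)
    rows[[length(rows) + 1L]] <<- data.frame(
      chain_id = chain$chain_id, start = start, end = end, sequence = pep,
      cit = I(list(as.integer(cit))), n_cit = length(cit), pgm = with_pgm,
      missed_cleavages = missed, theoretical_mh = mh, stringsAsFactors = FALSE
    )
  }

  # spans between boundaries with at most max_missed + max_cit internal
  # cleavage sites (citrullination can block at most max_cit of them)
  for (i in seq_len(nb - 1L)) {
    for (j in (i + 1L):nb) {
      internal <- j - i - 1L
      if (internal > max_missed + max_cit) break
      start <- bounds[i] + 1L
      end <- bounds[j]
      internal_cleave <- cleave[cleave >= start & cleave < end]
      # citrullinatable arginines: any R in the span except a C-terminal R at
      # an internal cleavage boundary
      r_pos <- start - 1L + which(aa[start:end] == "R")
      if (end < n && aa[end] == "R") r_pos <- setdiff(r_pos, end)
      for (k in 0:min(max_cit, length(r_pos))) {
        subsets <- if (k == 0L) list(integer()) else
          utils::combn(seq_along(r_pos), k, function(idx) r_pos[idx],
                       simplify = FALSE)
        for (S in subsets) {
          missed <- sum(!(internal_cleave %in% S))
          if (missed > max_missed) next
          emit(start, end, S, missed, FALSE)
          if (isTRUE(pgm) && k > 0L) emit(start, end, S, missed, TRUE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
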