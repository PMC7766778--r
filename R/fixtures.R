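build_scaffold <- function(chain_id, length, placements) {
  aa <- rep("G", length)
  for (p in placements) {
    span <- p$start:(p$start + nchar(p$sequence) - 1L)
    aa[span] <- split_residues(p$sequence)
    if (p$start > 1L) aa[p$start - 1L] <- "K"  # tryptic boundary before span
  }
  protein_chain(chain_id, paste(aa, collapse = ""))
}

#' Reference PAD2/PAD4 citrullination fingerprint of bovine fibrinogen
#'
#' The published MALDI-TOF peptide-mass-fingerprint evidence for in-vitro
#' citrullination of bovine fibrinogen: seven observed positive-mode m/z
#' values, the tryptic peptides they map to (with printed unmodified MH+ and
#' chain coordinates), the citrullinated arginine positions annotated for
#' PAD2, and the PAD4 site annotation (which shares six sites with PAD2, adds
#' one, and lacks two).
#'
#' The full bovine fibrinogen chain sequences are not part of the reference
#' data, so the `chains` element holds **synthetic** scaffolds: each chain
#' places the reference peptides at their printed residue coordinates and
#' fills the remaining positions with glycine (plus a lysine immediately
#' before each peptide so that it is a valid tryptic product). Scaffold
#' placements were checked exhaustively so that no two candidate peptides
#' with different citrullination-site sets fall within the 0.2 Da matching
#' tolerance of each other (equal-mass positional isomers excepted; those
#' are reported as ambiguity groups). The PAD4-only peptide
#' `KEEAPSLRPVPPPISGGGYR` has no printed coordinates and is placed at
#' synthetic alpha-chain positions 251-270 (citrullination site R258).
#'
#' @return List with elements:
#'   * `chains`: named list of synthetic [protein_chain()] scaffolds
#'     (`alpha`, `beta`, `gamma`);
#'   * `peptides`: data.frame of the seven reference peaks - `peak`,
#'     `mz_observed`, `chain_id`, `start`, `end`, `sequence`, `sites` (list
#'     column, annotated citrullinated positions), `mh_printed`, `in_pad4`;
#'   * `peaks`: data.frame (`mz`, `intensity`) of the PAD2+PGM observed peaks;
#'   * `pad2_sites`, `pad4_sites`: data.frames (`chain_id`, `position`) of
#'     the annotated citrullination sites per enzyme.
#' @export
fibrinogen_reference <- function() {
  peptides <- data.frame(
    peak = 1:7,
    mz_observed = c(1276.77, 1400.87, 1509.69, 1579.67, 1542.76, 1659.69,
                    1787.71),
    chain_id = c("alpha", "alpha", "alpha", "alpha", "beta", "beta", "gamma"),
    start = c(139L, 91L, 111L, 229L, 16L, 16L, 169L),
    end = c(146L, 100L, 122L, 241L, 28L, 28L, 183L),
    sequence = c("SRIEILRR", "LRDSLFNYQK", "NIVELMRGDFAK", "MSTITGPVPREFK",
                 "VGLGARGHRPYDK", "VGLGARGHRPYDK", "IHDVTGRDCQDVANK"),
    mh_printed = c(1042.65, 1283.67, 1392.73, 1462.77, 1425.77, 1425.77,
                   1670.79),
    in_pad4 = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  peptides$sites <- I(list(c(140L, 145L), 92L, 117L, 238L, c(21L, 24L),
                           c(21L, 24L), 175L))

  pad4_extra <- list(chain_id = "alpha", start = 251L,
                     sequence = "KEEAPSLRPVPPPISGGGYR", site = 258L)

  chains <- list(
    alpha = build_scaffold("alpha", 270L, c(
      lapply(which(peptides$chain_id == "alpha"), function(i)
        list(start = peptides$start[i], sequence = peptides$sequence[i])),
      list(list(start = pad4_extra$start, sequence = pad4_extra$sequence))
    )),
    beta = build_scaffold("beta", 38L, list(
      list(start = 16L, sequence = "VGLGARGHRPYDK")
    )),
    gamma = build_scaffold("gamma", 190L, list(
      list(start = 169L, sequence = "IHDVTGRDCQDVANK")
    ))
  )

  pad2_sites <- data.frame(
    chain_id = c("alpha", "alpha", "alpha", "alpha", "alpha",
                 "beta", "beta", "gamma"),
    position = c(92L, 117L, 140L, 145L, 238L, 21L, 24L, 175L),
    stringsAsFactors = FALSE
  )
  pad4_sites <- data.frame(
    chain_id = c("alpha", "alpha", "alpha", "alpha", "alpha", "beta", "beta"),
    position = c(92L, 140L, 145L, 238L, pad4_extra$site, 21L, 24L),
    stringsAsFactors = FALSE
  )

  list(chains = chains, peptides = peptides,
       peaks = data.frame(mz = peptides$mz_observed, intensity = NA_real_),
       pad2_sites = pad2_sites, pad4_sites = pad4_sites)
}
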