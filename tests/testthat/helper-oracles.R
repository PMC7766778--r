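# Brute-force oracles, independent of the implementation paths they check.

AA20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_peptide <- function(len) paste(sample(AA20, len, replace = TRUE),
                                      collapse = "")

# exhaustive tryptic digestion: every (start, end) whose boundaries are valid
# cleavage points (cleave after K/R, never before P) with <= max_missed
# retained internal sites
oracle_digest <- function(sequence, max_missed) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  is_boundary_after <- function(i) {
    i == 0L || i == n || (aa[i] %in% c("K", "R") && aa[i + 1L] != "P")
  }
  out <- character()
  for (start in 1:n) {
    for (end in start:n) {
      if (!is_boundary_after(start - 1L) || !is_boundary_after(end)) next
      internal <- if (end - start >= 1L)
        sum(vapply((start):(end - 1L), is_boundary_after, logical(1))) else 0L
      if (internal > max_missed) next
      out <- c(out, paste(start, end, internal, sep = "|"))
    }
  }
  sort(out)
}

# exhaustive enumeration of (start, end, citrullination subset) triples
# checked directly against the candidate-peptide invariants
oracle_candidates <- function(sequence, max_missed, max_cit) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  is_boundary_after <- function(i) {
    i == 0L || i == n || (aa[i] %in% c("K", "R") && aa[i + 1L] != "P")
  }
  out <- character()
  for (start in 1:n) {
    for (end in start:n) {
      if (!is_boundary_after(start - 1L) || !is_boundary_after(end)) next
      r_pos <- (start:end)[aa[start:end] == "R"]
      if (end < n && aa[end] == "R") r_pos <- setdiff(r_pos, end)
      cleavable <- if (end - start >= 1L)
        (start:(end - 1L))[vapply(start:(end - 1L), is_boundary_after,
                                  logical(1))] else integer()
      subsets <- list(integer())
      for (k in seq_len(min(max_cit, length(r_pos)))) {
        subsets <- c(subsets, utils::combn(seq_along(r_pos), k,
                                           function(ix) r_pos[ix],
                                           simplify = FALSE))
      }
      for (S in subsets) {
        missed <- sum(!(cleavable %in% S))
        if (missed > max_missed) next
        out <- c(out, paste(start, end,
                            paste(sort(S), collapse = ";"), missed,
                            sep = "|"))
      }
    }
  }
  sort(out)
}

candidate_keys <- function(cand) {
  sort(paste(cand$start, cand$end,
             vapply(cand$cit, function(s) paste(sort(s), collapse = ";"),
                    character(1)),
             cand$missed_cleavages, sep = "|"))
}

# classical two-sample KS statistic between hit and miss rank distributions,
# computed from empirical CDFs (closed form, not a running sum)
oracle_ks_es <- function(stats, gene_set) {
  ord <- names(sort(stats, decreasing = TRUE))
  hit <- ord %in% gene_set
  n_hit <- sum(hit)
  n_miss <- sum(!hit)
  d <- cumsum(hit) / n_hit - cumsum(!hit) / n_miss
  d[which.max(abs(d))]
}
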