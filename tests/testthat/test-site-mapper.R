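alpha_chain <- fibrinogen_reference()$chains$alpha

test_that("peaks match candidates only within the mass tolerance", {
  cand <- enumerate_candidates(alpha_chain, 2, 3)
  peak <- data.frame(mz = 1400.87)
  m <- match_peaks(cand, peak, tolerance_da = 0.2)
  expect_equal(nrow(m), 1L)
  expect_equal(m$sequence, "LRDSLFNYQK")
  expect_equal(m$cit[[1]], 92L)
  expect_true(m$pgm)
  # theoretical ~1400.68, observed 1400.87: gap 0.19 exceeds a 0.05 window
  expect_equal(nrow(match_peaks(cand, peak, tolerance_da = 0.05)), 0L)
  expect_equal(nrow(match_peaks(cand, data.frame(mz = numeric()), 0.2)), 0L)
  expect_equal(nrow(match_peaks(cand[0, ], peak, 0.2)), 0L)
  expect_error(match_peaks(cand, peak, tolerance_da = 0), "positive")
})

test_that("ppm tolerance mode is equivalent to the matched Da window", {
  cand <- enumerate_candidates(alpha_chain, 2, 3)
  peak <- data.frame(mz = 1400.87)
  # 0.19 Da at m/z 1400.87 is ~136 ppm
  expect_equal(nrow(match_peaks(cand, peak, tolerance_ppm = 150)), 1L)
  expect_equal(nrow(match_peaks(cand, peak, tolerance_ppm = 50)), 0L)
})

test_that("tie-breaking prefers fewer modifications and is deterministic", {
  # two candidates at identical mass, different citrullination sets
  cand <- enumerate_candidates(protein_chain("c", "GAKARARAK"), 2, 2)
  one_cit <- cand[cand$n_cit == 1 & cand$pgm & cand$start == 4 &
                    cand$end == 9, ]
  expect_gte(nrow(one_cit), 2)  # positional isomers R5 / R7
  m <- match_peaks(cand, data.frame(mz = one_cit$theoretical_mh[1]), 0.2)
  expect_equal(nrow(m), 1L)
  expect_true(m$ambiguous)       # co-optimal isomer reported, not hidden
  expect_equal(m$cit[[1]], 5L)   # lexicographically smallest site set wins
  m2 <- match_peaks(cand[rev(seq_len(nrow(cand))), ],
                    data.frame(mz = one_cit$theoretical_mh[1]), 0.2)
  expect_equal(m2$cit[[1]], m$cit[[1]])
})

test_that("site assignment requires PGM evidence and ignores match order", {
  ref <- fibrinogen_reference()
  res <- map_sites(ref$chains, ref$peaks, tolerance_da = 0.2)
  expect_true(all(res$sites$n_evidence >= 1))
  # every assigned position is covered by a matched PGM candidate citing it
  for (i in seq_len(nrow(res$sites))) {
    cover <- vapply(seq_len(nrow(res$matches)), function(j) {
      res$matches$pgm[j] &&
        res$matches$chain_id[j] == res$sites$chain_id[i] &&
        res$sites$position[i] %in% res$matches$cit[[j]]
    }, logical(1))
    expect_true(any(cover))
  }
  shuffled <- assign_sites(res$matches[sample(nrow(res$matches)), ])
  expect_equal(shuffled, res$sites)
  expect_equal(nrow(assign_sites(res$matches[0, ])), 0L)
  # matches without any PGM evidence assign nothing
  native_only <- res$matches[!res$matches$pgm, ]
  expect_equal(nrow(assign_sites(native_only)), 0L)
})

test_that("paired-native mode demands the matching non-PGM peak", {
  chain <- protein_chain("c", "GAKLRDSLFNYQKGAK")
  cand <- enumerate_candidates(chain, 2, 3)
  cit_pgm <- cand[cand$n_cit == 1 & cand$pgm & cand$sequence == "LRDSLFNYQK", ]
  cit_nat <- cand[cand$n_cit == 1 & !cand$pgm & cand$sequence == "LRDSLFNYQK", ]
  both <- data.frame(mz = c(cit_pgm$theoretical_mh, cit_nat$theoretical_mh))
  pgm_only <- data.frame(mz = cit_pgm$theoretical_mh)
  m_both <- match_peaks(cand, both, 0.05)
  m_pgm <- match_peaks(cand, pgm_only, 0.05)
  expect_equal(assign_sites(m_both, require_paired_native = TRUE)$position, 5L)
  expect_equal(nrow(assign_sites(m_pgm, require_paired_native = TRUE)), 0L)
  expect_equal(assign_sites(m_pgm, require_paired_native = FALSE)$position, 5L)
})

test_that("run comparison counts shared and exclusive sites consistently", {
  a <- data.frame(chain_id = c("alpha", "alpha", "beta"),
                  position = c(10L, 20L, 5L))
  b <- data.frame(chain_id = c("alpha", "beta", "beta"),
                  position = c(10L, 5L, 9L))
  cmp <- compare_runs(a, b)
  expect_equal(cmp$shared, 2L)
  expect_equal(cmp$n_a, cmp$a_only + cmp$shared)
  expect_equal(cmp$n_b, cmp$b_only + cmp$shared)
  ident <- compare_runs(a, a)
  expect_equal(ident$shared, nrow(a))
  expect_equal(ident$a_only + ident$b_only, 0L)
  disjoint <- compare_runs(a, data.frame(chain_id = "gamma", position = 1L))
  expect_equal(disjoint$shared, 0L)
  expect_error(compare_runs(a, b, chains = c("alpha")), "unknown chain")
})
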