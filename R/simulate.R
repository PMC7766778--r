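#' Simulate a MALDI-TOF peak list with planted citrullination sites
#'
#' Emits, for every candidate peptide whose citrullination set is a subset of
#' the planted `true_sites` (including the unmodified digest), its theoretical
#' MH+ plus Gaussian m/z jitter, then adds a Poisson-distributed number of
#' decoy peaks drawn uniformly over the observed m/z range. When `pgm = TRUE`
#' citrullinated candidates appear in their PGM-derivatized form (the
#' spectrum of a PGM-treated digest); when `FALSE`, at their native
#' citrullinated mass. Deterministic for a fixed seed.
#'
#' @param chain A [protein_chain()].
#' @param true_sites Integer vector of 1-based arginine positions planted as
#'   citrullinated (may be empty).
#' @param pgm Logical; simulate the PGM-derivatized spectrum.
#' @param mz_jitter_sd Gaussian m/z error, Daltons (>= 0).
#' @param decoy_rate Expected decoy peaks per true peak (>= 0).
#' @param seed Integer seed.
#' @param max_missed,max_cit,constants Passed to [enumerate_candidates()].
#' @return List with `peaks` (data.frame `mz`, `intensity`, sorted) and
#'   `truth` (list with `chain_id`, `sites`, `n_true_peaks`, `n_decoys`).
#' @export
simulate_spectrum <- function(chain, true_sites = integer(), pgm = TRUE,
                              mz_jitter_sd = 0.05, decoy_rate = 0,
                              seed = 1L, max_missed = 2L, max_cit = 3L,
                              constants = mass_constants()) {
  stopifnot(inherits(chain, "protein_chain"),
            mz_jitter_sd >= 0, decoy_rate >= 0)
  true_sites <- sort(unique(as.integer(true_sites)))
  aa <- split_residues(chain$sequence)
  if (length(true_sites) &&
      (any(true_sites < 1L | true_sites > length(aa)) ||
       any(aa[true_sites] != "R"))) {
    stop("true_sites must all be arginine positions in the chain",
         call. = FALSE)
  }
  cand <- enumerate_candidates(chain, max_missed = max_missed,
                               max_cit = max(max_cit, length(true_sites)),
                               pgm = pgm, constants = constants)
  consistent <- vapply(cand$cit, function(s) all(s %in% true_sites),
                       logical(1))
  form <- (cand$n_cit == 0L & !cand$pgm) |
    (cand$n_cit > 0L & cand$pgm == isTRUE(pgm))
  mh <- sort(unique(round(cand$theoretical_mh[consistent & form], 9)))

  set.seed(as.integer(seed))
  mz <- mh + stats::rnorm(length(mh), 0, mz_jitter_sd)
  n_decoys <- stats::rpois(1L, decoy_rate * length(mh))
  if (n_decoys > 0L && length(mh) >= 2L) {
    mz <- c(mz, stats::runif(n_decoys, min(mh), max(mh)))
  } else {
    n_decoys <- 0L
  }
  peaks <- as_peak_list(data.frame(mz = mz, intensity = 1))
  list(peaks = peaks,
       truth = list(chain_id = chain$chain_id, sites = true_sites,
                    n_true_peaks = length(mh), n_decoys = n_decoys))
}

#' Simulate a log2 expression matrix with planted module structure
#'
#' Emulates the three-condition (vehicle / fibrinogen / citrullinated
#' fibrinogen), multi-donor design: background genes sit at baseline in every
#' condition; module-1 (module-3) genes gain `+effect_log2` (`-effect_log2`)
#' under both fibrinogen conditions; module-2 genes gain a random-signed
#' `effect_log2` under fibrinogen that is opposed by `reversal_log2` under
#' citrullinated fibrinogen. Independent Gaussian donor noise is added to
#' every measurement. Deterministic for a fixed seed. The default module
#' fractions place roughly 3.3% / 0.65% / 4.7% of genes in modules 1/2/3,
#' matching the relative module sizes reported for genome-scale monocyte
#' arrays.
#'
#' @param n_genes Number of genes.
#' @param module_fractions Named proportions for `module1`, `module2`,
#'   `module3`, `background`; must sum to 1.
#' @param effect_log2 Planted fibrinogen effect (log2 units).
#' @param reversal_log2 Planted citrullination reversal (log2 units).
#' @param donor_noise_sd Per-measurement Gaussian noise sd (>= 0).
#' @param n_donors Number of donors (>= 2).
#' @param baseline_log2 Baseline expression level.
#' @param seed Integer seed.
#' @return List with `expr` (matrix genes x samples), `design` (data.frame
#'   `sample`, `condition`, `donor`) and `truth` (data.frame `gene`,
#'   `module`).
#' @export
simulate_expression <- function(n_genes = 20000L,
                                module_fractions = c(module1 = 0.033,
                                                     module2 = 0.0065,
                                                     module3 = 0.047,
                                                     background = 0.9135),
                                effect_log2 = 2, reversal_log2 = 2,
                                donor_noise_sd = 0.3, n_donors = 2L,
                                baseline_log2 = 8, seed = 1L) {
  stopifnot(n_genes >= 1L, donor_noise_sd >= 0, n_donors >= 2L,
            all(c("module1", "module2", "module3", "background") %in%
                  names(module_fractions)),
            abs(sum(module_fractions) - 1) < 1e-8,
            all(module_fractions >= 0))
  set.seed(as.integer(seed))
  n1 <- round(n_genes * module_fractions[["module1"]])
  n2 <- round(n_genes * module_fractions[["module2"]])
  n3 <- round(n_genes * module_fractions[["module3"]])
  n0 <- n_genes - n1 - n2 - n3
  if (n0 < 0) stop("module fractions leave no room for background genes",
                   call. = FALSE)
  module <- sample(rep(c("module1", "module2", "module3", "none"),
                       c(n1, n2, n3, n0)))
  genes <- sprintf("gene%05d", seq_len(n_genes))

  donors <- paste0("donor", seq_len(n_donors))
  design <- expand.grid(condition = CONDITIONS, donor = donors,
                        stringsAsFactors = FALSE)
  design$sample <- paste(design$donor, design$condition, sep = "_")
  design <- design[, c("sample", "condition", "donor")]

  m2_sign <- ifelse(stats::runif(n_genes) < 0.5, 1, -1)
  fib_effect <- ifelse(module == "module1", effect_log2,
                ifelse(module == "module3", -effect_log2,
                ifelse(module == "module2", m2_sign * effect_log2, 0)))
  cit_effect <- ifelse(module == "module2",
                       fib_effect - m2_sign * reversal_log2, fib_effect)

  expr <- matrix(baseline_log2, nrow = n_genes, ncol = nrow(design),
                 dimnames = list(genes, design$sample))
  expr[, design$condition == "fibrinogen"] <-
    expr[, design$condition == "fibrinogen"] + fib_effect
  expr[, design$condition == "cit_fibrinogen"] <-
    expr[, design$condition == "cit_fibrinogen"] + cit_effect
  expr <- expr + matrix(stats::rnorm(length(expr), 0, donor_noise_sd),
                        nrow = n_genes)

  list(expr = expr, design = design,
       truth = data.frame(gene = genes, module = module,
                          stringsAsFactors = FALSE))
}
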