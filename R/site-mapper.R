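cit_key <- function(cit) paste(sort(as.integer(cit)), collapse = ";")

candidate_key <- function(df) {
  paste(df$chain_id, df$start, df$end,
        vapply(df$cit, cit_key, character(1)), sep = "|")
}

#' Match observed peaks against candidate peptides
#'
#' Each peak is assigned to at most one candidate: the one with the smallest
#' absolute mass error, ties broken by fewest modifications (citrullines, then
#' the PGM flag), fewest missed cleavages, lowest start coordinate, and
#' finally the lexicographically smallest citrullination set, so the result is
#' deterministic. `n_candidates` counts all candidates within tolerance and
#' `ambiguous` flags peaks where a co-optimal candidate (equal mass, equal
#' modification load) evidences a different citrullination set; such site
#' ambiguity is reported, never silently resolved.
#'
#' @param candidates data.frame from [enumerate_candidates()].
#' @param peaks data.frame with columns `mz` and optionally `intensity`
#'   (see [read_peak_list()]); m/z values must be positive.
#' @param tolerance_da Absolute match tolerance in Daltons (default 0.2,
#'   consistent with MALDI-TOF calibration error on singly protonated ions).
#' @param tolerance_ppm If non-`NULL`, overrides `tolerance_da` with a
#'   relative tolerance in parts per million.
#' @return data.frame with one row per matched peak: `mz`, `intensity`,
#'   candidate columns, `error_da`, `error_ppm`, `n_candidates`, `ambiguous`.
#' @export
match_peaks <- function(candidates, peaks, tolerance_da = 0.2,
                        tolerance_ppm = NULL) {
  if (is.null(tolerance_ppm) && tolerance_da <= 0) {
    stop("tolerance_da must be positive", call. = FALSE)
  }
  peaks <- as_peak_list(peaks)
  empty <- data.frame(
    mz = numeric(), intensity = numeric(), chain_id = character(),
    start = integer(), end = integer(), sequence = character(),
    cit = I(list()), n_cit = integer(), pgm = logical(),
    missed_cleavages = integer(), theoretical_mh = numeric(),
    error_da = numeric(), error_ppm = numeric(), n_candidates = integer(),
    ambiguous = logical(), stringsAsFactors = FALSE
  )
  if (is.null(candidates) || nrow(candidates) == 0L || nrow(peaks) == 0L) {
    return(empty)
  }
  out <- list()
  for (p in seq_len(nrow(peaks))) {
    mz <- peaks$mz[p]
    tol <- if (is.null(tolerance_ppm)) tolerance_da else mz * tolerance_ppm * 1e-6
    err <- mz - candidates$theoretical_mh
    hit <- which(abs(err) <= tol)
    if (!length(hit)) next
    ord <- hit[order(abs(err[hit]),
                     candidates$n_cit[hit] + as.integer(candidates$pgm[hit]),
                     candidates$missed_cleavages[hit],
                     candidates$start[hit],
                     vapply(candidates$cit[hit], cit_key, character(1)))]
    best <- ord[1L]
    co_optimal <- ord[abs(err[ord] - err[best]) < 1e-9 &
                        candidates$n_cit[ord] == candidates$n_cit[best] &
                        candidates$pgm[ord] == candidates$pgm[best]]
    amb <- length(unique(vapply(candidates$cit[co_optimal], cit_key,
                                character(1)))) > 1L
    row <- candidates[best, , drop = FALSE]
    out[[length(out) + 1L]] <- cbind(
      data.frame(mz = mz, intensity = peaks$intensity[p]),
      row,
      data.frame(error_da = err[best], error_ppm = err[best] / mz * 1e6,
                 n_candidates = length(hit), ambiguous = amb)
    )
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign citrullination sites from matched peaks
#'
#' A chain position is declared citrullinated when at least one matched
#' PGM-derivatized candidate carries a citrulline at that position. With
#' `require_paired_native = TRUE` an assignment additionally requires that the
#' same candidate (same span and citrullination set) was also matched in its
#' native, non-PGM form, i.e. that the observed pair of peaks differs by
#' exactly `n_cit` PGM adducts.
#'
#' @param matches data.frame from [match_peaks()], from a single experiment.
#' @param require_paired_native Logical; demand a paired non-PGM match.
#' @return data.frame with one row per distinct site: `chain_id`, `position`,
#'   `n_evidence` (number of evidencing PGM matches), `peaks` (list column of
#'   evidencing m/z values), `min_abs_error_da`, `ambiguous` (any evidencing
#'   match was ambiguous), sorted by chain then position. The output is
#'   invariant to the order of the input matches.
#' @export
assign_sites <- function(matches, require_paired_native = FALSE) {
  empty <- data.frame(chain_id = character(), position = integer(),
                      n_evidence = integer(), peaks = I(list()),
                      min_abs_error_da = numeric(), ambiguous = logical(),
                      stringsAsFactors = FALSE)
  if (is.null(matches) || nrow(matches) == 0L) return(empty)
  ev <- matches[matches$pgm & matches$n_cit > 0L, , drop = FALSE]
  if (isTRUE(require_paired_native)) {
    native <- matches[!matches$pgm & matches$n_cit > 0L, , drop = FALSE]
    ev <- ev[candidate_key(ev) %in% candidate_key(native), , drop = FALSE]
  }
  if (nrow(ev) == 0L) return(empty)
  recs <- list()
  for (i in seq_len(nrow(ev))) {
    for (pos in ev$cit[[i]]) {
      key <- paste(ev$chain_id[i], pos, sep = "|")
      recs[[key]] <- rbind(recs[[key]], data.frame(
        chain_id = ev$chain_id[i], position = as.integer(pos),
        mz = ev$mz[i], abs_err = abs(ev$error_da[i]),
        ambiguous = ev$ambiguous[i], stringsAsFactors = FALSE
      ))
    }
  }
  out <- do.call(rbind, lapply(recs, function(r) {
    data.frame(chain_id = r$chain_id[1L], position = r$position[1L],
               n_evidence = nrow(r), peaks = I(list(sort(r$mz))),
               min_abs_error_da = min(r$abs_err),
               ambiguous = any(r$ambiguous), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chain_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare citrullination-site assignments between two runs
#'
#' Intersects two site tables (e.g. PAD2- versus PAD4-treated fibrinogen) on
#' (chain, position).
#'
#' @param run_a,run_b data.frames with columns `chain_id` and `position`
#'   (e.g. from [assign_sites()]).
#' @param chains Optional character vector of valid chain ids; an assignment
#'   on any other chain is an error (both runs must reference the same
#'   chains).
#' @return List of class `site_comparison`: `n_a`, `n_b`, `shared`, `a_only`,
#'   `b_only` (counts, with `n_a = a_only + shared` and
#'   `n_b = b_only + shared`) and data.frames `shared_sites`, `a_only_sites`,
#'   `b_only_sites`.
#' @export
compare_runs <- function(run_a, run_b, chains = NULL) {
  site_tab <- function(run, label) {
    stopifnot(all(c("chain_id", "position") %in% names(run)))
    if (!is.null(chains) && !all(run$chain_id %in% chains)) {
      bad <- setdiff(unique(run$chain_id), chains)
      stop("run ", label, " references unknown chain(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    unique(data.frame(chain_id = as.character(run$chain_id),
                      position = as.integer(run$position),
                      stringsAsFactors = FALSE))
  }
  a <- site_tab(run_a, "A")
  b <- site_tab(run_b, "B")
  ka <- paste(a$chain_id, a$position)
  kb <- paste(b$chain_id, b$position)
  shared <- a[ka %in% kb, , drop = FALSE]
  a_only <- a[!(ka %in% kb), , drop = FALSE]
  b_only <- b[!(kb %in% ka), , drop = FALSE]
  structure(list(
    n_a = nrow(a), n_b = nrow(b), shared = nrow(shared),
    a_only = nrow(a_only), b_only = nrow(b_only),
    shared_sites = shared, a_only_sites = a_only, b_only_sites = b_only
  ), class = "site_comparison")
}

#' @export
print.site_comparison <- function(x, ...) {
  cat("<site_comparison> A:", x$n_a, " B:", x$n_b,
      " shared:", x$shared,
      " A-only:", x$a_only, " B-only:", x$b_only, "\n")
  invisible(x)
}

#' Map citrullination sites from chains and a peak list
#'
#' Convenience wrapper running [enumerate_candidates()], [match_peaks()] and
#' [assign_sites()] over one or more chains.
#'
#' @param chains A [protein_chain()] or list of them.
#' @param peaks Peak list (see [read_peak_list()]).
#' @param tolerance_da,tolerance_ppm See [match_peaks()].
#' @param max_missed,max_cit See [enumerate_candidates()].
#' @param require_paired_native See [assign_sites()].
#' @param constants See [mass_constants()].
#' @return List with elements `candidates`, `matches`, `sites`.
#' @export
map_sites <- function(chains, peaks, tolerance_da = 0.2, tolerance_ppm = NULL,
                      max_missed = 2L, max_cit = 3L,
                      require_paired_native = FALSE,
                      constants = mass_constants()) {
  if (inherits(chains, "protein_chain")) chains <- list(chains)
  candidates <- do.call(rbind, lapply(chains, enumerate_candidates,
                                      max_missed = max_missed,
                                      max_cit = max_cit, pgm = TRUE,
                                      constants = constants))
  matches <- match_peaks(candidates, peaks, tolerance_da = tolerance_da,
                         tolerance_ppm = tolerance_ppm)
  sites <- assign_sites(matches, require_paired_native = require_paired_native)
  list(candidates = candidates, matches = matches, sites = sites)
}
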