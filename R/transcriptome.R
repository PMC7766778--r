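CONDITIONS <- c("vehicle", "fibrinogen", "cit_fibrinogen")

check_design <- function(expr, design) {
  stopifnot(is.matrix(expr), is.data.frame(design),
            all(c("sample", "condition", "donor") %in% names(design)))
  if (!all(design$sample %in% colnames(expr))) {
    stop("design samples absent from expression matrix", call. = FALSE)
  }
  donors <- unique(design$donor)
  for (d in donors) {
    have <- design$condition[design$donor == d]
    miss <- setdiff(CONDITIONS, have)
    if (length(miss)) {
      stop("donor '", d, "' is missing condition(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  donors
}

# genes x donors matrix of log2 deltas between two conditions
donor_deltas <- function(expr, design, cond, ref) {
  donors <- unique(design$donor)
  out <- matrix(NA_real_, nrow = nrow(expr), ncol = length(donors),
                dimnames = list(rownames(expr), donors))
  for (d in donors) {
    s1 <- design$sample[design$donor == d & design$condition == cond][1L]
    s0 <- design$sample[design$donor == d & design$condition == ref][1L]
    out[, d] <- expr[, s1] - expr[, s0]
  }
  out
}

#' Call fibrinogen-responsive genes per donor with cross-donor concordance
#'
#' Per donor, a gene is `UP` if its fibrinogen-minus-vehicle log2 difference
#' is at least `fc_threshold`, `DN` if at most `-fc_threshold`, otherwise
#' `NC`. The concordant call is `UP` (`DN`, `NC`) only when every donor
#' agrees; otherwise `discordant`.
#'
#' @param expr Numeric matrix, genes x samples, log2 scale.
#' @param design data.frame with columns `sample`, `condition`
#'   (`vehicle`/`fibrinogen`/`cit_fibrinogen`), `donor`; every donor must
#'   have all three conditions.
#' @param fc_threshold Positive log2 fold-change threshold (default 1).
#' @return data.frame with `gene`, one direction column per donor (named
#'   `dir_<donor>`), and `concordant`.
#' @export
call_degs <- function(expr, design, fc_threshold = 1) {
  stopifnot(fc_threshold > 0)
  donors <- check_design(expr, design)
  deltas <- donor_deltas(expr, design, "fibrinogen", "vehicle")
  dirs <- matrix("NC", nrow = nrow(expr), ncol = length(donors),
                 dimnames = list(rownames(expr), donors))
  dirs[deltas >= fc_threshold] <- "UP"
  dirs[deltas <= -fc_threshold] <- "DN"
  concordant <- apply(dirs, 1L, function(d) {
    if (all(d == "UP")) "UP" else if (all(d == "DN")) "DN"
    else if (all(d == "NC")) "NC" else "discordant"
  })
  out <- data.frame(gene = rownames(expr), dirs, concordant,
                    stringsAsFactors = FALSE, row.names = NULL,
                    check.names = FALSE)
  names(out) <- c("gene", paste0("dir_", donors), "concordant")
  out
}

#' Classify fibrinogen-regulated genes by citrullination responsiveness
#'
#' Concordantly fibrinogen-regulated genes are split into three modules:
#' * **module1** - upregulated by fibrinogen, not reversed by citrullination;
#' * **module2** - up- or downregulated by fibrinogen but reversed
#'   significantly by citrullinated fibrinogen (the
#'   citrullinated-minus-fibrinogen log2 difference opposes the fibrinogen
#'   direction by at least `reversal_threshold`);
#' * **module3** - downregulated by fibrinogen, not reversed.
#'
#' With `donor_rule = "all"` (default) reversal must hold in every donor;
#' `"majority"` relaxes this to more than half the donors. A gene whose
#' citrullination response is concordantly in the *same* direction as its
#' fibrinogen response is labelled `none`, as is any gene that is not
#' concordantly fibrinogen-regulated. The three module labels are mutually
#' exclusive, and the classification does not depend on gene or donor order.
#'
#' @param degs data.frame from [call_degs()].
#' @param expr,design As in [call_degs()]; every DEG gene must be present.
#' @param reversal_threshold Positive log2 threshold for the citrullination
#'   reversal (default 1).
#' @param donor_rule `"all"` or `"majority"`.
#' @return data.frame with columns `gene` and `module`
#'   (`module1`/`module2`/`module3`/`none`).
#' @export
classify_modules <- function(degs, expr, design, reversal_threshold = 1,
                             donor_rule = c("all", "majority")) {
  stopifnot(reversal_threshold > 0)
  donor_rule <- match.arg(donor_rule)
  check_design(expr, design)
  absent <- setdiff(degs$gene, rownames(expr))
  if (length(absent)) {
    stop("DEG gene(s) absent from expression matrix: ",
         paste(utils::head(absent, 5L), collapse = ", "), call. = FALSE)
  }
  cit_delta <- donor_deltas(expr, design, "cit_fibrinogen", "fibrinogen")
  n_donors <- ncol(cit_delta)
  need <- if (donor_rule == "all") n_donors else floor(n_donors / 2) + 1L

  module <- rep("none", nrow(degs))
  for (i in seq_len(nrow(degs))) {
    dir <- degs$concordant[i]
    if (!dir %in% c("UP", "DN")) next
    cd <- cit_delta[degs$gene[i], ]
    sign_fib <- if (dir == "UP") 1 else -1
    reversed_per_donor <- sign_fib * cd <= -reversal_threshold
    same_per_donor <- sign_fib * cd >= reversal_threshold
    if (sum(same_per_donor) >= need) next        # concordant same-direction -> none
    if (sum(reversed_per_donor) >= need) {
      module[i] <- "module2"
    } else {
      module[i] <- if (dir == "UP") "module1" else "module3"
    }
  }
  data.frame(gene = degs$gene, module = module, stringsAsFactors = FALSE)
}

#' Rank genes by mean fibrinogen response
#'
#' Helper producing the ranked, named score vector consumed by
#' [enrichment_score()]: the per-gene mean over donors of the log2 difference
#' between `contrast` and `baseline`, sorted decreasing.
#'
#' @param expr,design As in [call_degs()].
#' @param contrast,baseline Condition names.
#' @return Named numeric vector sorted in decreasing order.
#' @export
gene_ranking <- function(expr, design, contrast = "fibrinogen",
                         baseline = "vehicle") {
  check_design(expr, design)
  deltas <- donor_deltas(expr, design, contrast, baseline)
  sort(rowMeans(deltas), decreasing = TRUE)
}

#' Weighted running-sum enrichment score
#'
#' The standard weighted Kolmogorov-Smirnov-like statistic: walking down the
#' ranked list, hits increment the running sum by `|score|^weight`
#' (normalized over hits) and misses decrement by a constant (normalized over
#' misses); the enrichment score is the extremum of largest magnitude.
#' Positive ES indicates concentration at the top of the ranking, negative at
#' the bottom. At `weight = 0` this is the classical Kolmogorov-Smirnov
#' statistic between hit and miss rank distributions (up to sign).
#'
#' @param stats Named numeric vector of gene-level scores; sorted internally
#'   in decreasing order.
#' @param gene_set Character vector of gene identifiers; must intersect the
#'   names of `stats`.
#' @param weight Non-negative exponent (default 1).
#' @return ES, a number in `[-1, 1]`.
#' @export
enrichment_score <- function(stats, gene_set, weight = 1) {
  stopifnot(!is.null(names(stats)), weight >= 0)
  stats <- sort(stats, decreasing = TRUE)
  hit <- names(stats) %in% gene_set
  n_hit <- sum(hit)
  if (n_hit == 0L) {
    stop("gene_set has empty intersection with the ranked list", call. = FALSE)
  }
  n <- length(stats)
  if (n_hit == n) stop("gene_set covers the whole ranked list", call. = FALSE)
  w <- abs(stats)^weight
  norm_hit <- sum(w[hit])
  incr <- ifelse(hit, if (norm_hit > 0) w / norm_hit else 1 / n_hit,
                 -1 / (n - n_hit))
  # degenerate all-zero scores at weight > 0: fall back to uniform hit steps
  if (norm_hit == 0) incr[hit] <- 1 / n_hit
  running <- cumsum(incr)
  running[which.max(abs(running))]
}

#' Permutation-normalized enrichment with FDR q-values
#'
#' For each gene set, a null ES distribution is built from `n_perm` random
#' gene sets of the same size drawn from the ranked list (gene-label
#' permutation; phenotype permutation is not meaningful with two donors).
#' NES is the ES divided by the mean |null ES| of matching sign, and FDR
#' q-values follow the standard positive/negative-tail procedure comparing
#' the pooled null NES distribution against the observed NES values, within
#' the tail matching each set's sign.
#'
#' @param stats Named numeric score vector (see [enrichment_score()]).
#' @param gene_sets Named list of character vectors (e.g. [read_gmt()]), or a
#'   single character vector.
#' @param n_perm Number of permutations, at least 100.
#' @param weight See [enrichment_score()].
#' @param seed Integer seed for reproducibility.
#' @return data.frame with one row per gene set: `gene_set`, `size` (after
#'   intersection), `es`, `nes`, `fdr_q`, `n_perm`, `tail_warning` (`TRUE`
#'   when fewer than 10 null ES shared the observed sign, so the tail
#'   estimate is unstable).
#' @export
permutation_nes <- function(stats, gene_sets, n_perm = 1000L, weight = 1,
                            seed = NULL) {
  n_perm <- as.integer(n_perm)
  if (n_perm < 100L) stop("n_perm must be at least 100", call. = FALSE)
  if (!is.list(gene_sets)) gene_sets <- list(gene_set = gene_sets)
  if (is.null(names(gene_sets))) {
    names(gene_sets) <- paste0("set", seq_along(gene_sets))
  }
  if (!is.null(seed)) set.seed(seed)
  stats <- sort(stats, decreasing = TRUE)
  universe <- names(stats)

  sizes <- vapply(gene_sets, function(s) sum(universe %in% s), integer(1))
  if (any(sizes == 0L)) {
    stop("gene set(s) with empty intersection: ",
         paste(names(gene_sets)[sizes == 0L], collapse = ", "), call. = FALSE)
  }
  es_obs <- vapply(gene_sets, function(s) enrichment_score(stats, s, weight),
                   numeric(1))

  null_es <- matrix(NA_real_, nrow = n_perm, ncol = length(gene_sets))
  for (j in seq_along(gene_sets)) {
    for (p in seq_len(n_perm)) {
      null_es[p, j] <- enrichment_score(
        stats, sample(universe, sizes[j]), weight)
    }
  }

  norm_by_sign <- function(es, null) {
    same <- null[sign(null) == sign(es) & null != 0]
    if (!length(same)) return(list(nes = NA_real_, warn = TRUE))
    list(nes = es / mean(abs(same)), warn = length(same) < 10L)
  }
  nes_obs <- numeric(length(gene_sets))
  warn <- logical(length(gene_sets))
  null_nes <- matrix(NA_real_, nrow = n_perm, ncol = length(gene_sets))
  for (j in seq_along(gene_sets)) {
    nn <- norm_by_sign(es_obs[j], null_es[, j])
    nes_obs[j] <- nn$nes
    warn[j] <- nn$warn
    pos <- null_es[, j] > 0
    neg <- null_es[, j] < 0
    mp <- mean(null_es[pos, j])
    mn <- mean(abs(null_es[neg, j]))
    null_nes[pos, j] <- null_es[pos, j] / mp
    null_nes[neg, j] <- null_es[neg, j] / mn
  }

  pool <- null_nes[!is.na(null_nes)]
  fdr_q <- vapply(seq_along(gene_sets), function(j) {
    nes <- nes_obs[j]
    if (is.na(nes)) return(NA_real_)
    if (nes >= 0) {
      n_pos <- sum(pool >= 0)
      num <- if (n_pos > 0) sum(pool >= nes) / n_pos else 0
      den <- sum(nes_obs >= nes, na.rm = TRUE) /
        max(1L, sum(nes_obs >= 0, na.rm = TRUE))
    } else {
      n_neg <- sum(pool < 0)
      num <- if (n_neg > 0) sum(pool <= nes) / n_neg else 0
      den <- sum(nes_obs <= nes, na.rm = TRUE) /
        max(1L, sum(nes_obs < 0, na.rm = TRUE))
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))

  data.frame(gene_set = names(gene_sets), size = sizes, es = es_obs,
             nes = nes_obs, fdr_q = fdr_q, n_perm = n_perm,
             tail_warning = warn, stringsAsFactors = FALSE, row.names = NULL)
}
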