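# tiny two-donor design and a matrix builder: values are per-condition log2
# levels (vehicle, fibrinogen, cit_fibrinogen) per donor
make_design <- function(donors = c("d1", "d2")) {
  data.frame(
    sample = as.vector(outer(c("vehicle", "fibrinogen", "cit_fibrinogen"),
                             donors, function(c, d) paste(d, c, sep = "_"))),
    condition = rep(c("vehicle", "fibrinogen", "cit_fibrinogen"),
                    length(donors)),
    donor = rep(donors, each = 3),
    stringsAsFactors = FALSE
  )
}

make_expr <- function(genes, values, design) {
  m <- rbind(values)
  dimnames(m) <- list(genes, design$sample)
  m
}

test_that("per-donor direction calls and concordance follow the thresholds", {
  design <- make_design()
  expr <- make_expr(
    c("up", "disc", "flat"),
    rbind(c(0, 2.0, 2, 0, 1.5, 1.5),   # +2.0 / +1.5 -> concordant UP
          c(0, 2.0, 2, 0, -2.0, -2),   # +2.0 / -2.0 -> discordant
          c(0, 0, 0, 0, 0, 0)),        # all zero -> NC
    design)
  degs <- call_degs(expr, design, fc_threshold = 1)
  expect_equal(degs$concordant, c("UP", "discordant", "NC"))
  expect_equal(degs$dir_d1, c("UP", "UP", "NC"))
  expect_equal(degs$dir_d2, c("UP", "DN", "NC"))
  expect_error(call_degs(expr, design, 0), "fc_threshold")
  expect_error(call_degs(expr[, -2], design[-2, ], 1), "missing condition")
})

test_that("module classification implements the reversal rules", {
  design <- make_design()
  # columns: d1 veh/fib/cit, d2 veh/fib/cit
  expr <- make_expr(
    c("m2", "m1", "m3", "same", "m2dn"),
    rbind(c(0, 2, 0.5, 0, 2, 0.8),    # UP, cit deltas -1.5/-1.2 -> module2
          c(0, 2, 1.9, 0, 2, 2.2),    # UP, cit deltas -0.1/+0.2 -> module1
          c(0, -2, -2, 0, -2, -2),    # DN, no reversal      -> module3
          c(0, 2, 4, 0, 2, 4),        # UP, cit further up   -> none
          c(0, -2, 0, 0, -2, -0.5)),  # DN, reversed up      -> module2
    design)
  degs <- call_degs(expr, design, 1)
  mods <- classify_modules(degs, expr, design, reversal_threshold = 1)
  expect_equal(mods$module,
               c("module2", "module1", "module3", "none", "module2"))
  expect_error(classify_modules(data.frame(gene = "ghost", concordant = "UP"),
                                expr, design, 1), "absent")
})

test_that("classification is invariant to gene and donor order", {
  sim <- simulate_expression(n_genes = 300, donor_noise_sd = 0.3, seed = 5)
  degs <- call_degs(sim$expr, sim$design, 1)
  mods <- classify_modules(degs, sim$expr, sim$design, 1)
  perm <- sample(nrow(sim$expr))
  design_rev <- sim$design[rev(seq_len(nrow(sim$design))), ]
  degs2 <- call_degs(sim$expr[perm, ], design_rev, 1)
  mods2 <- classify_modules(degs2, sim$expr[perm, ], design_rev, 1)
  expect_equal(mods2$module[match(mods$gene, mods2$gene)], mods$module)
  # module labels are mutually exclusive by construction: one label per gene
  expect_equal(anyDuplicated(mods$gene), 0L)
})

test_that("majority donor rule relaxes the strict-concordance reversal", {
  design <- make_design(c("d1", "d2", "d3"))
  expr <- make_expr("g",
                    rbind(c(0, 2, 0.5, 0, 2, 0.5, 0, 2, 1.8)), design)
  degs <- call_degs(expr, design, 1)
  strict <- classify_modules(degs, expr, design, 1, donor_rule = "all")
  major <- classify_modules(degs, expr, design, 1, donor_rule = "majority")
  expect_equal(strict$module, "module1")  # reversal fails in donor 3
  expect_equal(major$module, "module2")   # 2 of 3 donors reversed
})

test_that("enrichment score is the weighted running-sum statistic", {
  set.seed(41)
  stats <- sort(rnorm(100), decreasing = TRUE)
  names(stats) <- paste0("g", seq_along(stats))
  # top-loaded set reaches its extremum before any miss: ES = +1 at weight 0
  expect_equal(enrichment_score(stats, paste0("g", 1:10), weight = 0), 1)
  # uniformly interleaved set: |ES| is small at large n
  inter <- paste0("g", seq(1, 100, by = 4))
  expect_lt(abs(enrichment_score(stats, inter, weight = 0)), 0.1)
  # reversing the ranking flips the sign of the weight-0 statistic
  rev_stats <- sort(-stats, decreasing = TRUE)
  names(rev_stats) <- rev(names(stats))
  expect_equal(enrichment_score(rev_stats, paste0("g", 1:10), weight = 0),
               -1)
  expect_error(enrichment_score(stats, "absent"), "empty intersection")
})

test_that("weight-0 enrichment equals the closed-form KS oracle", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    stats <- sort(rnorm(n), decreasing = TRUE)
    names(stats) <- paste0("g", seq_len(n))
    set <- sample(names(stats), sample(1:(n - 1), 1))
    expect_equal(enrichment_score(stats, set, weight = 0),
                 oracle_ks_es(stats, set), tolerance = 1e-12)
  }
})

test_that("weighted enrichment agrees with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(43)
  for (i in 1:10) {
    n <- sample(20:80, 1)
    stats <- sort(rnorm(n), decreasing = TRUE)
    names(stats) <- paste0("g", seq_len(n))
    set <- sample(names(stats), sample(3:10, 1))
    es_fgsea <- fgsea::calcGseaStat(stats, which(names(stats) %in% set),
                                    gseaParam = 1)
    expect_equal(enrichment_score(stats, set, weight = 1), es_fgsea,
                 tolerance = 1e-8)
  }
})

test_that("permutation NES flags planted enrichment and is reproducible", {
  set.seed(44)
  stats <- sort(rnorm(500), decreasing = TRUE)
  names(stats) <- paste0("g", seq_along(stats))
  res <- permutation_nes(stats, list(planted = paste0("g", 1:25)),
                         n_perm = 1000, seed = 7)
  expect_gt(res$nes, 1)
  expect_lt(res$fdr_q, 0.25)
  res2 <- permutation_nes(stats, list(planted = paste0("g", 1:25)),
                          n_perm = 1000, seed = 7)
  expect_equal(res, res2)
  expect_true(all(abs(res$es) <= 1))
  expect_true(res$fdr_q >= 0 && res$fdr_q <= 1)
  expect_error(permutation_nes(stats, list(s = "g1"), n_perm = 50, seed = 1),
               "at least 100")
})
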