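test_that("enrichment score matches hand computations on the 4-gene list", {
  r <- ranked_list(c(g1 = 4, g2 = 3, g3 = 2, g4 = 1))
  expect_equal(enrichment_score(r, "g1"), 1.0, tolerance = 1e-12)
  expect_equal(enrichment_score(r, "g4"), -1.0, tolerance = 1e-12)
  run <- enrichment_score(r, "g4", running = TRUE)$running_sum
  expect_equal(run, c(-1 / 3, -2 / 3, -1, 0), tolerance = 1e-12)
  expect_error(enrichment_score(r, c("g1", "g2", "g3", "g4")), "whole")
  expect_error(enrichment_score(r, "absent"), "intersect")
})

test_that("enrichment score equals the brute-force running-sum oracle", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    ranked <- random_ranked(n)
    k <- sample(seq_len(n - 1), 1)
    gs <- sample(names(ranked), k)
    p <- sample(c(0, 1, 1.5), 1)
    expect_equal(enrichment_score(ranked, gs, p = p),
                 es_oracle(ranked, gs, p = p), tolerance = 1e-12)
  }
})

test_that("hit-position fast path agrees with the full running sum", {
  set.seed(202)
  for (i in 1:100) {
    n <- sample(5:400, 1)
    ranked <- random_ranked(n)
    k <- sample(seq_len(n - 1), 1)
    pos <- sort(sample.int(n, k))
    gs <- names(ranked)[pos]
    expect_equal(autolnc:::es_at_positions(abs(ranked), n, pos),
                 es_oracle(ranked, gs), tolerance = 1e-12)
  }
})

test_that("enrichment score agrees with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(303)
  for (i in 1:20) {
    n <- sample(20:100, 1)
    ranked <- random_ranked(n)
    gs <- sample(names(ranked), sample(3:10, 1))
    expect_equal(enrichment_score(ranked, gs),
                 fgsea::calcGseaStat(ranked, which(names(ranked) %in% gs),
                                     gseaParam = 1),
                 tolerance = 1e-10)
  }
})

test_that("nominal p estimator matches exhaustive enumeration on 4-gene lists", {
  # list g1..g4 scores 4,3,2,1; single-member sets have null ES
  # {1, 2/3, -2/3, -1} over the four placements; observed set {g1}: ES = 1,
  # same-sign nulls {1, 2/3}, add-one estimator (1 + 1) / (1 + 2) = 2/3
  r <- ranked_list(c(g1 = 4, g2 = 3, g3 = 2, g4 = 1))
  null_es <- vapply(names(r), function(g) enrichment_score(r, g), numeric(1))
  expect_equal(sort(unname(null_es)), c(-1, -2 / 3, 2 / 3, 1),
               tolerance = 1e-12)
  est <- autolnc:::gsea_from_null(enrichment_score(r, "g1"), unname(null_es))
  expect_equal(est$nominal_p, 2 / 3, tolerance = 1e-12)
  # bottom placement mirrors it on the negative side
  est2 <- autolnc:::gsea_from_null(enrichment_score(r, "g4"), unname(null_es))
  expect_equal(est2$nominal_p, 2 / 3, tolerance = 1e-12)
  # a sub-maximal placement is less extreme than only itself
  est3 <- autolnc:::gsea_from_null(enrichment_score(r, "g2"), unname(null_es))
  expect_equal(est3$nominal_p, 1, tolerance = 1e-12)
  # NES normalizes by the mean same-sign null magnitude
  expect_equal(est$nes, 1 / mean(c(1, 2 / 3)), tolerance = 1e-12)
})

test_that("permutation GSEA is reproducible and respects the p floor", {
  set.seed(9)
  ranked <- random_ranked(60)
  gs <- sample(names(ranked), 8)
  a <- gsea_significance(ranked, gs, n_perm = 200, seed = 5)
  b <- gsea_significance(ranked, gs, n_perm = 200, seed = 5)
  expect_identical(a$null_es, b$null_es)
  expect_identical(a$nominal_p, b$nominal_p)
  expect_gte(a$nominal_p, 1 / 201)
  expect_equal(sign(a$nes), sign(a$es))
  expect_error(gsea_significance(ranked, gs, n_perm = 10, seed = 1), "100")
  expect_error(gsea_significance(ranked, gs, n_perm = 200), "seed")
})

test_that("null permutation p-values are approximately uniform", {
  set.seed(77)
  p <- replicate(60, {
    ranked <- random_ranked(80)
    gs <- sample(names(ranked), 10)
    gsea_significance(ranked, gs, n_perm = 200,
                      seed = sample.int(1e6, 1))$nominal_p
  })
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("RS ranking adjusts for purity and recovers planted targets", {
  set.seed(55)
  n <- 60
  purity <- runif(n, 0.5, 0.95)
  f <- as.vector(scale(purity))
  lnc <- rnorm(n)
  gene_expr <- matrix(rnorm(200 * n), nrow = 200,
                      dimnames = list(sprintf("G%03d", 1:200), NULL))
  # planted co-expressed target
  gene_expr["G001", ] <- 0.75 * scale(lnc) + rnorm(n)
  # pure purity proxy: high marginal, near-zero partial correlation
  lnc_conf <- f + rnorm(n, sd = 0.3)
  gene_expr["G002", ] <- f + rnorm(n, sd = 0.3)
  rs <- rs_rank_genes(lnc, gene_expr, purity)
  expect_lte(which(names(rs) == "G001"), 10)  # top 5% of 200
  rs_conf <- rs_rank_genes(lnc_conf, gene_expr, purity)
  marg <- cor(lnc_conf, gene_expr["G002", ], method = "spearman")
  expect_gt(marg, 0.5)
  expect_lt(abs(rs_conf[["G002"]]), 0.25)
  # constant purity falls back to the plain Spearman ordering
  rs_plain <- rs_rank_genes(lnc, gene_expr, rep(0.7, n))
  marg_all <- apply(gene_expr, 1, function(g) cor(lnc, g, method = "spearman"))
  expect_identical(names(rs_plain), names(ranked_list(marg_all)))
  expect_error(rs_rank_genes(rep(1, n), gene_expr, purity), "constant")
})

test_that("lncAut conversion and the strict selection boundary", {
  mk <- function(p, q) structure(list(es = 0.5, nes = 1.5, nominal_p = p,
                                      fdr_q = q, n_perm = 1000, seed = 1,
                                      set_size = 10, nes_defined = TRUE,
                                      null_es = numeric(0)),
                                 class = "gsea_result")
  res <- list(L1 = mk(0.05, 0.01), L2 = mk(0.10, 0.01), L3 = mk(1, 0.5),
              L4 = mk(0.05, 0.20))
  out <- lncaut_select(res)
  expect_equal(out$lncaut, c(0.95, 0.90, 0, 0.95))
  expect_identical(out$selected, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("BH fallback FDR for GSEA batches matches bh_adjust", {
  set.seed(13)
  ranked <- random_ranked(50)
  res <- lapply(1:4, function(i) {
    gsea_significance(ranked, sample(names(ranked), 6), n_perm = 100,
                      seed = i)
  })
  names(res) <- paste0("L", 1:4)
  res <- gsea_fdr(res, method = "bh")
  p <- vapply(res, `[[`, numeric(1), "nominal_p")
  expect_equal(unname(vapply(res, `[[`, numeric(1), "fdr_q")),
               unname(bh_adjust(p)))
})
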