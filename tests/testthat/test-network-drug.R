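test_that("network recovers planted signed edges and respects thresholds", {
  co <- generate_cohort(small_config(seed = 23))
  tum <- co$labels$sample[co$labels$group == "tumor"]
  lt <- co$lnc_expr[, tum]
  gt <- co$gene_expr[, tum]
  l <- co$truth$autophagy_lnc_ids[1]
  net <- build_regulatory_network(l, lt, co$autophagy$gene_id, gt,
                                  co$purity[tum])
  ts <- co$truth$target_sets[[l]]
  hit <- merge(net$edges, ts, by = "gene_id")
  expect_gte(nrow(hit), 0.8 * nrow(ts))
  expect_true(all(hit$sign.x == ifelse(hit$sign.y > 0, "positive",
                                       "negative")))
  # an impossible threshold removes every edge
  net2 <- build_regulatory_network(l, lt, co$autophagy$gene_id, gt,
                                   co$purity[tum], rho_threshold = 1.0)
  expect_equal(nrow(net2$edges), 0)
  expect_warning(build_regulatory_network(character(0), lt,
                                          co$autophagy$gene_id, gt,
                                          co$purity[tum]), "empty")
})

test_that("permuted samples drive the edge count to the null level", {
  co <- generate_cohort(small_config(seed = 29))
  tum <- co$labels$sample[co$labels$group == "tumor"]
  lt <- co$lnc_expr[, tum]
  gt <- co$gene_expr[, tum]
  set.seed(1)
  perm <- sample(ncol(gt))  # break lncRNA-gene pairing, keep purity-gene
  net <- build_regulatory_network(co$truth$autophagy_lnc_ids,
                                  lt[, perm, drop = FALSE],
                                  co$autophagy$gene_id, gt, co$purity[tum])
  expect_lte(nrow(net$edges), ceiling(0.01 * nrow(net$rho_table)))
})

test_that("activator/inhibitor classification separates the clear cases", {
  ann <- data.frame(gene_id = sprintf("G%03d", 1:20),
                    group = rep(c("AT+", "AT-"), each = 10),
                    stringsAsFactors = FALSE)
  tab <- data.frame(lncrna_id = "L1", gene_id = ann$gene_id,
                    rho = rep(c(0.5, -0.5), each = 10),
                    stringsAsFactors = FALSE)
  r <- activator_inhibitor_test("L1", tab, ann)
  expect_identical(r$inferred_role, "promoting")
  tab$rho <- -tab$rho
  expect_identical(activator_inhibitor_test("L1", tab, ann)$inferred_role,
                   "inhibiting")
  # symmetric-around-zero correlations stay unclassified
  set.seed(2)
  tab$rho <- rnorm(20, sd = 0.05)
  expect_identical(activator_inhibitor_test("L1", tab, ann)$inferred_role,
                   "unclassified")
  # too few annotated genes
  expect_identical(
    activator_inhibitor_test("L1", tab[1:3, ],
                             ann[c(1, 2, 11), ])$inferred_role,
    "unclassified")
})

test_that("a planted activator-style lncRNA is classified as promoting", {
  # dense AT- targeting so both one-sample tests have power
  cfg <- small_config(seed = 37,
                      n_targets_per_lnc = c(at_plus = 10, at_minus = 8))
  co <- generate_cohort(cfg)
  tum <- co$labels$sample[co$labels$group == "tumor"]
  l <- co$truth$autophagy_lnc_ids[1]
  net <- build_regulatory_network(l, co$lnc_expr[, tum],
                                  co$autophagy$gene_id,
                                  co$gene_expr[, tum], co$purity[tum])
  r <- activator_inhibitor_test(l, net$rho_table, co$autophagy)
  expect_identical(r$inferred_role, "promoting")
  expect_lt(r$p_plus, 0.05)
  expect_lt(r$p_minus, 0.05)
})

test_that("target set extraction filters the edge list exactly", {
  edges <- data.frame(lncrna_id = c("L1", "L1", "L2"),
                      gene_id = c("G2", "G1", "G3"),
                      stringsAsFactors = FALSE)
  expect_identical(target_gene_set("L1", edges), c("G1", "G2"))
  expect_identical(target_gene_set("L2", edges), "G3")
  expect_warning(ts <- target_gene_set("L9", edges), "no edges")
  expect_length(ts, 0)
})

test_that("drug screen recovers planted pairs with correct NES signs", {
  cfg <- small_config(seed = 41)
  co <- generate_cohort(cfg)
  sigs <- generate_drug_signatures(cfg, co$truth,
                                   gene_ids = rownames(co$gene_expr))
  tsets <- lapply(co$truth$target_sets, function(d) d$gene_id)
  out <- suppressWarnings(drug_lncrna_screen(tsets, sigs, n_perm = 500,
                                             seed = 43))
  truth_pairs <- co$truth$drug_pairs
  hit <- merge(out[out$reported, ], truth_pairs,
               by = c("drug_id", "lncrna_id"))
  expect_gte(nrow(hit), 0.8 * nrow(truth_pairs))
  expect_true(all(sign(hit$nes) == hit$sign))
  expect_true(all(hit$direction == ifelse(hit$sign > 0, "induces",
                                          "represses")))
  # reversing a planted drug's ranked list flips the ES sign
  d1 <- truth_pairs$drug_id[1]
  l1 <- truth_pairs$lncrna_id[1]
  flipped <- ranked_list(-sigs[[d1]])
  es_fwd <- enrichment_score(sigs[[d1]], tsets[[l1]])
  es_rev <- enrichment_score(flipped, tsets[[l1]])
  expect_equal(es_fwd, -es_rev, tolerance = 1e-12)
})

test_that("drug and lncAut stages share one enrichment kernel", {
  set.seed(47)
  ranked <- random_ranked(100)
  gs <- sample(names(ranked), 12)
  a <- gsea_significance(ranked, gs, n_perm = 100, seed = 3)
  out <- suppressWarnings(drug_lncrna_screen(list(L = gs), list(D = ranked),
                                             n_perm = 100, seed = 2))
  expect_equal(out$es, a$es, tolerance = 1e-12)
})

test_that("over-representation analysis composes the hypergeometric + BH", {
  universe <- sprintf("G%03d", 1:10)
  sets <- list(hit = universe[1:5], miss = universe[6:10])
  out <- ora_enrichment(universe[1:4], sets, universe)
  expect_equal(out$p[out$set == "hit"], 5 / 210, tolerance = 1e-12)
  expect_equal(out$fdr, bh_adjust(out$p), ignore_attr = TRUE)
  # empty query: all p = 1
  out0 <- ora_enrichment(character(0), sets, universe)
  expect_true(all(out0$p == 1))
  # disjoint set skipped with a warning
  expect_warning(ora_enrichment(universe[1:2],
                                c(sets, list(alien = c("X1", "X2"))),
                                universe),
                 "disjoint")
  expect_error(ora_enrichment("Z9", sets, universe), "universe")
})
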