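test_that("site-to-region mapping honors half-open interval semantics", {
  regions <- data.frame(chrom = "chr1", start = 100L, end = 200L,
                        name = "LNC1", score = 0, strand = "+",
                        role = "promoter", stringsAsFactors = FALSE)
  sites <- data.frame(site_id = c("s_left", "s_mid", "s_right", "s_out"),
                      chrom = "chr1", position = c(100L, 150L, 200L, 99L),
                      stringsAsFactors = FALSE)
  m <- map_sites_to_regions(sites, regions)
  expect_setequal(m$site_id, c("s_left", "s_mid"))  # 100 in, 200 and 99 out
  # different chromosome never maps
  sites$chrom <- "chr2"
  expect_equal(nrow(map_sites_to_regions(sites, regions)), 0)
})

test_that("mapping equals the all-pairs quadratic oracle on random fixtures", {
  set.seed(12)
  for (i in 1:10) {
    n_s <- sample(5:15, 1); n_r <- sample(3:8, 1)
    sites <- data.frame(site_id = sprintf("s%02d", seq_len(n_s)),
                        chrom = sample(c("chr1", "chr2"), n_s, TRUE),
                        position = sample(0:500, n_s),
                        stringsAsFactors = FALSE)
    start <- sample(0:400, n_r)
    regions <- data.frame(chrom = sample(c("chr1", "chr2"), n_r, TRUE),
                          start = start,
                          end = start + sample(20:150, n_r, TRUE),
                          name = sprintf("L%02d", seq_len(n_r)), score = 0,
                          strand = "+",
                          role = sample(c("promoter", "enhancer"), n_r, TRUE),
                          stringsAsFactors = FALSE)
    got <- map_sites_to_regions(sites, regions)
    want <- overlap_oracle(sites, regions)
    rownames(got) <- NULL
    expect_equal(got, want)
  }
})

make_dysreg_fixture <- function(meth_dir = "hyper", expr_dir = "down",
                                rho_sign = -1, seed = 1) {
  set.seed(seed)
  n_t <- 30; n_n <- 15
  samples <- c(sprintf("T%02d", 1:n_t), sprintf("N%02d", 1:n_n))
  v <- rnorm(n_t)
  shift <- if (expr_dir == "down") -3 else 3
  lnc <- matrix(rnorm(n_t + n_n, 6), nrow = 1,
                dimnames = list("LNC1", samples))
  lnc[1, 1:n_t] <- lnc[1, 1:n_t] + shift + 0.8 * v
  dmu <- if (meth_dir == "hyper") c(0.65, 0.35) else c(0.35, 0.65)
  b <- plogis(qlogis(rep(dmu, c(n_t, n_n))) +
                rho_sign * 0.8 * c(v, rep(0, n_n)) +
                rnorm(n_t + n_n, sd = 0.3))
  beta <- matrix(runif(4 * (n_t + n_n), 0.3, 0.7), nrow = 4,
                 dimnames = list(sprintf("cg%02d", 1:4), samples))
  beta["cg01", ] <- b
  de <- data.frame(id = "LNC1", log2fc = shift, p = 1e-6, fdr = 1e-6,
                   direction = expr_dir, stringsAsFactors = FALSE)
  dm <- data.frame(id = rownames(beta), delta_beta = c(0.3, 0, 0, 0),
                   p = c(1e-8, 0.5, 0.6, 0.7), fdr = c(1e-7, 0.8, 0.8, 0.8),
                   direction = c(meth_dir, "ns", "ns", "ns"),
                   stringsAsFactors = FALSE)
  mapping <- data.frame(site_id = "cg01", lncrna_id = "LNC1",
                        role = "promoter", stringsAsFactors = FALSE)
  list(de = de, dm = dm, mapping = mapping, beta = beta, lnc = lnc,
       tumor = samples[1:n_t])
}

test_that("the four-clause dysregulation rule is enforced jointly", {
  # hypo + up with negative correlation: called
  fx <- make_dysreg_fixture("hypo", "up")
  calls <- call_dysregulated_lncrnas(fx$de, fx$dm, fx$mapping, fx$beta,
                                     fx$lnc, fx$tumor)
  expect_true(calls$dysregulated[1])
  expect_identical(calls$meth_direction[1], "hypo")
  expect_identical(calls$expr_direction[1], "up")
  expect_lt(calls$rho[1], 0)
  # hyper + down: called
  fx2 <- make_dysreg_fixture("hyper", "down")
  calls2 <- call_dysregulated_lncrnas(fx2$de, fx2$dm, fx2$mapping, fx2$beta,
                                      fx2$lnc, fx2$tumor)
  expect_true(calls2$dysregulated[1])
  # same-direction (hyper + up) is excluded regardless of correlation
  fx3 <- make_dysreg_fixture("hyper", "up")
  calls3 <- call_dysregulated_lncrnas(fx3$de, fx3$dm, fx3$mapping, fx3$beta,
                                      fx3$lnc, fx3$tumor)
  expect_equal(sum(calls3$dysregulated), 0)
  # positive methylation-expression correlation fails clause (iv)
  fx4 <- make_dysreg_fixture("hyper", "down", rho_sign = +1)
  calls4 <- call_dysregulated_lncrnas(fx4$de, fx4$dm, fx4$mapping, fx4$beta,
                                      fx4$lnc, fx4$tumor)
  expect_true(nrow(calls4) == 0 || !any(calls4$dysregulated))
})

test_that("every positive call satisfies all four clauses on a real cohort", {
  co <- generate_cohort(small_config(seed = 17))
  de_lnc <- differential_expression(co$lnc_expr, co$labels)
  dm <- differential_methylation(co$beta, co$labels)
  mapping <- map_sites_to_regions(co$sites, co$regions)
  tum <- co$labels$sample[co$labels$group == "tumor"]
  calls <- call_dysregulated_lncrnas(de_lnc, dm, mapping, co$beta,
                                     co$lnc_expr, tum)
  pos <- calls[calls$dysregulated, ]
  for (i in seq_len(nrow(pos))) {
    expect_true(pos$expr_direction[i] %in% c("up", "down"))
    opposite <- (pos$meth_direction[i] == "hyper" &
                   pos$expr_direction[i] == "down") |
      (pos$meth_direction[i] == "hypo" & pos$expr_direction[i] == "up")
    expect_true(opposite)
    expect_lt(pos$rho[i], 0)
    expect_lt(pos$corr_fdr[i], 0.05)
    expect_gte(pos$n_dm_sites[i], 1)
  }
  # planted lncRNAs are recovered on this fixture
  expect_true(all(co$truth$dysregulated_lnc_ids %in%
                    pos$lncrna_id))
})

test_that("null cohorts yield essentially no dysregulation calls", {
  n_calls <- 0
  for (s in 1:5) {
    co <- generate_cohort(small_null_config(seed = 50 + s))
    de_lnc <- differential_expression(co$lnc_expr, co$labels)
    dm <- differential_methylation(co$beta, co$labels)
    mapping <- map_sites_to_regions(co$sites, co$regions)
    tum <- co$labels$sample[co$labels$group == "tumor"]
    calls <- call_dysregulated_lncrnas(de_lnc, dm, mapping, co$beta,
                                       co$lnc_expr, tum)
    n_calls <- n_calls + sum(calls$dysregulated)
  }
  expect_lte(n_calls, 1)
})
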