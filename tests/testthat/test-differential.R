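test_that("fold_change uses pseudocounted arithmetic means", {
  fc <- fold_change(c(2, 2), c(1, 1), pseudocount = 0)
  expect_equal(fc$log2fc, 1)
  expect_equal(fold_change(c(3, 5), c(3, 5))$log2fc, 0)
  expect_equal(fold_change(c(0, 0), c(0, 0), pseudocount = 0.5)$log2fc, 0)
  expect_error(fold_change(numeric(0), 1), "non-empty")
})

test_that("the exact Wilcoxon p matches brute-force enumeration", {
  # the worked case: most extreme separation of 3 vs 3
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(enum_wilcox_p(c(1, 2, 3), c(4, 5, 6)), 0.1)
  # random tie-free inputs across the exact regime
  withr::local_seed(41)
  for (m in 2:5) {
    for (n in m:min(6, 11 - m)) {
      x <- rnorm(m)
      y <- rnorm(n)
      expect_equal(
        wilcoxon_rank_sum(x, y), enum_wilcox_p(x, y),
        tolerance = 1e-12,
        label = sprintf("m=%d n=%d", m, n)
      )
    }
  }
})

test_that("wilcoxon_rank_sum edge behavior", {
  # identical multisets: zero-shift null
  expect_equal(wilcoxon_rank_sum(c(2, 2, 2), c(2, 2)), 1)
  # symmetry in the two-sided p
  x <- c(0.3, 1.7, 2.2, 5.0)
  y <- c(0.9, 1.1, 4.2)
  expect_equal(wilcoxon_rank_sum(x, y), wilcoxon_rank_sum(y, x))
  # p is in (0, 1] even for large separated groups (normal approximation)
  p <- wilcoxon_rank_sum(1:20, 21:40)
  expect_gt(p, 0)
  expect_lte(p, 1)
})

test_that("benjamini_hochberg matches the step-up definition", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.123), 0.123)
  expect_equal(benjamini_hochberg(c(1, 1)), c(1, 1))
  expect_equal(benjamini_hochberg(numeric(0)), numeric(0))
  withr::local_seed(42)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))
    adj <- benjamini_hochberg(p)
    expect_equal(adj, manual_bh(p), tolerance = 1e-12)
    # monotone in p and never below the raw p
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
  }
})

make_rpkm <- function(values_case, values_control, gene_ids = NULL) {
  # fabricate a tss_rpkm long tibble from per-gene value matrices
  n_gene <- nrow(values_case)
  gene_ids <- gene_ids %||% sprintf("g%04d", seq_len(n_gene))
  case_ids <- sprintf("case%02d", seq_len(ncol(values_case)))
  ctrl_ids <- sprintf("control%02d", seq_len(ncol(values_control)))
  long <- dplyr::bind_rows(
    tidyr::expand_grid(gene_id = gene_ids, sample_id = case_ids),
    tidyr::expand_grid(gene_id = gene_ids, sample_id = ctrl_ids)
  )
  long$rpkm <- c(as.vector(t(values_case)), as.vector(t(values_control)))
  long$count <- long$rpkm
  structure(long, class = c("tss_rpkm", class(long)))
}

make_sheet <- function(rpkm) {
  ids <- unique(rpkm$sample_id)
  tibble::tibble(
    sample_id = ids,
    cohort = ifelse(grepl("^control", ids), "control", "case")
  )
}

test_that("identical cohorts produce no tested TSSs and no calls", {
  withr::local_seed(43)
  vals <- matrix(runif(40, 1, 10), nrow = 10)
  rp <- make_rpkm(vals, vals)
  d <- differential_tss(rp, make_sheet(rp))
  expect_equal(sum(d$tested), 0)
  expect_true(all(d$call == "ns"))
  expect_true(all(is.na(d$p_value)))
  expect_equal(d$log2fc, rep(0, 10))
})

test_that("differential_tss applies the three-criterion call with BH on the tested set", {
  withr::local_seed(44)
  n_gene <- 60
  case <- matrix(rpois(n_gene * 8, 50), nrow = n_gene)
  ctrl <- matrix(rpois(n_gene * 8, 50), nrow = n_gene)
  case[1:5, ] <- case[1:5, ] * 3 # strong planted up-coverage genes
  rp <- make_rpkm(case + runif(length(case), 0, 0.01), # break ties
    ctrl + runif(length(ctrl), 0, 0.01))
  d <- differential_tss(rp, make_sheet(rp))
  expect_s3_class(d, "tss_diff")
  # planted genes are tested, significant and signed up
  expect_true(all(d$tested[1:5]))
  expect_true(all(d$call[1:5] == "up"))
  # fdr only on tested TSSs, and consistent with BH of their p-values
  idx <- which(d$tested)
  expect_equal(d$fdr[idx], benjamini_hochberg(d$p_value[idx]))
  expect_true(all(is.na(d$fdr[-idx])))
  # every call satisfies all three criteria
  called <- d[d$call != "ns", ]
  expect_true(all(called$p_value < 0.05))
  expect_true(all(abs(called$log2fc) >= log2(1.5)))
  expect_true(all(called$fdr < 0.2))
  # glance summarises counts
  g <- glance(d)
  expect_equal(g$n_up, sum(d$call == "up"))
  expect_equal(g$n_tss, n_gene)
})

test_that("fdr_scope = 'all' corrects across every TSS", {
  withr::local_seed(45)
  case <- matrix(rpois(30 * 6, 40) + runif(180, 0, 0.01), nrow = 30)
  ctrl <- matrix(rpois(30 * 6, 40) + runif(180, 0, 0.01), nrow = 30)
  case[1:3, ] <- case[1:3, ] * 3
  rp <- make_rpkm(case, ctrl)
  d_tested <- differential_tss(rp, make_sheet(rp), fdr_scope = "tested")
  d_all <- differential_tss(rp, make_sheet(rp), fdr_scope = "all")
  idx <- which(d_all$tested)
  # correcting over more hypotheses can only raise the planted genes' FDR
  expect_true(all(d_all$fdr[idx] >= d_tested$fdr[idx] - 1e-12))
})

test_that("label permutation destroys planted calls", {
  withr::local_seed(46)
  n_gene <- 200
  case <- matrix(rpois(n_gene * 10, 40), nrow = n_gene)
  ctrl <- matrix(rpois(n_gene * 10, 40), nrow = n_gene)
  case[1:20, ] <- case[1:20, ] * 2
  jitter <- function(m) m + runif(length(m), 0, 0.01)
  rp <- make_rpkm(jitter(case), jitter(ctrl))
  sheet <- make_sheet(rp)
  d <- differential_tss(rp, sheet)
  expect_gte(sum(d$call != "ns"), 15)
  sheet$cohort <- sample(sheet$cohort) # break the case/control structure
  d_perm <- differential_tss(rp, sheet)
  expect_lte(sum(d_perm$call != "ns"), 5)
})

test_that("cohorts with fewer than two samples are rejected", {
  rp <- make_rpkm(matrix(1:10, nrow = 5), matrix(1:5, nrow = 5))
  expect_error(differential_tss(rp, make_sheet(rp)), "at least 2")
})

test_that("volcano_table contains exactly the tested TSSs", {
  withr::local_seed(47)
  case <- matrix(rpois(50 * 5, 30) + runif(250, 0, 0.01), nrow = 50)
  ctrl <- matrix(rpois(50 * 5, 30) + runif(250, 0, 0.01), nrow = 50)
  case[1:4, ] <- case[1:4, ] * 4
  rp <- make_rpkm(case, ctrl)
  d <- differential_tss(rp, make_sheet(rp))
  v <- volcano_table(d)
  expect_equal(nrow(v), sum(d$tested))
  expect_true(all(c("ns", "up") %in% unique(c(v$call, "ns"))))
  p01 <- v$neg_log10_p[match(d$gene_id[d$tested], v$gene_id)]
  expect_equal(p01, -log10(d$p_value[d$tested]))
  # heatmap matrix is z-scored per called TSS
  hm <- heatmap_matrix(rp, d)
  expect_equal(ncol(hm), sum(d$call != "ns"))
  expect_true(all(abs(colMeans(hm)) < 1e-12))
})
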