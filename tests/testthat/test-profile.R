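test_that("window_count sums weights of overlapping fragments", {
  tss <- tss_row(5000)
  expect_equal(window_count(frags(integer(0), integer(0)), tss, 1000)$count, 0)
  # one unit-weight fragment inside the window
  expect_equal(window_count(frags(4990, 5140), tss, 1000)$count, 1)
  # 7 fragments placed by hand, 3 overlap [4000, 6001) by >= 1 bp
  fr <- frags(
    start = c(100, 3850, 3900, 5995, 6001, 8000, 4500),
    end = c(250, 4000, 4050, 6150, 6151, 8150, 4650)
  )
  brute <- sum(fr$start < 6001 & fr$end > 4000)
  expect_equal(brute, 3)
  expect_equal(window_count(fr, tss, 1000)$count, brute)
  # weighted: weights sum, not counts
  fr$weight <- c(1, 1, 0.5, 0.25, 1, 1, 2)
  expect_equal(
    window_count(fr, tss, 1000)$count,
    sum(fr$weight[fr$start < 6001 & fr$end > 4000])
  )
})

test_that("per_base_profile is strand-oriented per-base coverage", {
  W <- 1000
  fr <- frags(1000, 1150)
  plus <- per_base_profile(fr, tss_row(1000, "+"), W)
  expect_equal(nrow(plus), 2 * W + 1)
  expect_equal(plus$depth[plus$offset >= 0 & plus$offset <= 149], rep(1, 150))
  expect_equal(sum(plus$depth), 150)
  minus <- per_base_profile(fr, tss_row(1000, "-"), W)
  expect_equal(minus$depth[minus$offset >= -149 & minus$offset <= 0], rep(1, 150))
  expect_equal(sum(minus$depth), 150)
  # linear in the weight
  fr$weight <- 0.5
  half <- per_base_profile(fr, tss_row(1000, "+"), W)
  expect_equal(half$depth, plus$depth * 0.5)
})

test_that("profile depth matches a brute-force per-position counter", {
  withr::local_seed(31)
  fr <- frags(
    start = sample(0:9000, 60, replace = TRUE),
    end = 0, weight = runif(60, 0.5, 2)
  )
  fr$end <- fr$start + sample(150:160, 60, replace = TRUE)
  tss <- tss_row(5000, "+")
  prof <- per_base_profile(fr, tss, 500)
  expect_equal(prof$depth, brute_depth(fr, 5000 + prof$offset))
  # conservation: sum of depths equals total overlap length x weight
  ov <- pmin(fr$end, 5000 + 501) - pmax(fr$start, 5000 - 500)
  expect_equal(sum(prof$depth), sum(fr$weight * pmax(ov, 0)))
})

test_that("profiles are invariant under coordinate mirroring", {
  withr::local_seed(32)
  L <- 20000
  fr <- frags(start = sample(0:(L - 200), 50), end = 0)
  fr$end <- fr$start + 155
  tss <- tss_row(9000, "+")
  prof <- per_base_profile(fr, tss, 800)
  # mirror everything about L and flip the strand (positions map to L-1-pos)
  fr_m <- frags(start = L - fr$end, end = L - fr$start)
  tss_m <- tss_row(L - 1 - 9000, "-")
  prof_m <- per_base_profile(fr_m, tss_m, 800)
  expect_equal(prof_m$depth, prof$depth)
})

test_that("RPKM follows the formula and its invariances", {
  # count 10, region 2000, total 1e6 -> RPKM 5
  samples <- tibble::tibble(
    sample_id = "s1", cohort = "case", gestational_age = 20,
    total_mapped_fragments = 1e6,
    fragments = list(frags(seq(4000, 4900, 100), seq(4150, 5050, 100)))
  )
  tss <- tss_row(5000)
  rp <- rpkm_matrix(samples, tss, 1000)
  expect_equal(rp$count, 10)
  expect_equal(rp$rpkm, 10 * 1e9 / (2000 * 1e6))
  # zero-count TSS
  rp0 <- rpkm_matrix(samples, tss_row(50000, gene_id = "gB"), 1000)
  expect_equal(rp0$rpkm, 0)
  # doubling fragments and the total leaves RPKM unchanged
  samples2 <- samples
  samples2$fragments[[1]] <- dplyr::bind_rows(
    samples$fragments[[1]], samples$fragments[[1]]
  )
  samples2$total_mapped_fragments <- 2e6
  expect_equal(rpkm_matrix(samples2, tss, 1000)$rpkm, rp$rpkm)
  # zero totals are rejected
  samples$total_mapped_fragments <- 0
  expect_error(rpkm_matrix(samples, tss, 1000), "total_mapped_fragments")
})

test_that("pool_controls partitions, discards leftovers, and conserves counts", {
  withr::local_seed(33)
  n <- 13
  samples <- tibble::tibble(
    sample_id = sprintf("c%02d", 1:n), cohort = "control",
    gestational_age = runif(n, 12, 28),
    total_mapped_fragments = rpois(n, 500),
    fragments = purrr::map(1:n, ~ frags(0:9 * 1000, 0:9 * 1000 + 155))
  )
  expect_warning(pools <- pool_controls(samples, 4, seed = 1), "leftover")
  expect_equal(nrow(pools), 3) # floor(13 / 4)
  expect_true(all(lengths(pools$members) == 4))
  used <- unlist(pools$members)
  expect_equal(length(used), length(unique(used)))
  # pooled totals and fragment counts are member sums
  for (i in seq_len(nrow(pools))) {
    idx <- match(pools$members[[i]], samples$sample_id)
    expect_equal(
      pools$total_mapped_fragments[i],
      sum(samples$total_mapped_fragments[idx])
    )
    expect_equal(nrow(pools$fragments[[i]]), sum(purrr::map_int(samples$fragments[idx], nrow)))
  }
  # determinism: same seed, same membership
  expect_warning(pools2 <- pool_controls(samples, 4, seed = 1))
  expect_identical(pools$members, pools2$members)
  # 5 controls with pool_size 4: 1 pool, 1 discarded
  expect_warning(p5 <- pool_controls(samples[1:5, ], 4, seed = 2), "1 leftover")
  expect_equal(nrow(p5), 1)
  expect_error(
    suppressWarnings(pool_controls(samples[1:3, ], 4)),
    "pool_size"
  )
})

test_that("stratified pooling pools within strata only", {
  samples <- tibble::tibble(
    sample_id = sprintf("c%02d", 1:8), cohort = "control",
    gestational_age = c(rep(15, 4), rep(22, 4)),
    week = c(rep(15, 4), rep(22, 4)),
    total_mapped_fragments = 100,
    fragments = purrr::map(1:8, ~ frags(0, 155))
  )
  pools <- pool_controls(samples, 4, seed = 3, stratify_by = "week")
  expect_equal(nrow(pools), 2)
  ages <- sort(pools$gestational_age)
  expect_equal(ages, c(15, 22)) # members never cross strata
})

test_that("relative normalization sets the flank mean to 1", {
  withr::local_seed(34)
  prof <- tibble::tibble(
    gene_id = "gA", offset = -1000:1000,
    depth = runif(2001, 0.5, 2)
  )
  rel <- relative_profile(prof)
  flank <- abs(rel$offset) >= 750
  expect_equal(mean(rel$depth[flank]), 1, tolerance = 1e-12)
  # all-zero flank gives NA
  prof$depth <- c(rep(0, 500), rep(1, 1001), rep(0, 500))
  expect_true(all(is.na(relative_profile(prof)$depth)))
})

test_that("geneset_mean_profile identities hold in both modes", {
  withr::local_seed(35)
  one <- tibble::tibble(
    sample_id = "s1", gene_id = "gA", offset = -200:200,
    depth = runif(401, 0.5, 2)
  )
  for (mode in c("aggregate", "per_gene")) {
    out <- geneset_mean_profile(one, "gA", normalize = mode)
    manual <- one$depth / mean(one$depth[abs(one$offset) >= 150])
    expect_equal(out$mean_depth, manual, tolerance = 1e-12)
  }
  # flat profiles give a mean relative profile of exactly 1
  flat <- tidyr::expand_grid(
    sample_id = c("s1", "s2"), gene_id = c("gA", "gB"), offset = -200:200
  )
  flat$depth <- 3
  out <- geneset_mean_profile(flat, c("gA", "gB"))
  expect_true(all(abs(out$mean_depth - 1) < 1e-12))
  expect_true(all(out$sd_depth == 0))
  expect_error(geneset_mean_profile(flat, character(0)), "empty")
  expect_error(geneset_mean_profile(flat, "gZ"), "not profiled")
})

test_that("active promoters show lower central relative depth than inactive", {
  spec <- synthetic_spec(genome_length = 6e5, n_genes = 120, mean_depth = 1)
  sim <- simulate_cohorts(spec, n_case = 0, n_control = 3, seed = 36)
  prof <- sample_profiles(sim$samples, sim$tss, 1000)
  act <- sim$truth$gene_id[sim$truth$active_control]
  inact <- sim$truth$gene_id[!sim$truth$active_control]
  a <- geneset_mean_profile(prof, act)
  i <- geneset_mean_profile(prof, inact)
  centre <- abs(a$offset) <= 50
  expect_lt(mean(a$mean_depth[centre]), mean(i$mean_depth[centre]))
})

test_that("select_top_bottom returns disjoint deterministic sets", {
  expr <- tibble::tibble(
    gene_id = sprintf("g%04d", 1:1000),
    expression = c(seq_len(999), 500) # a tie at 500
  )
  sets <- select_top_bottom(expr, 500)
  top <- sets$gene_id[sets$set == "top"]
  bottom <- sets$gene_id[sets$set == "bottom"]
  expect_equal(length(top), 500)
  expect_equal(length(bottom), 500)
  expect_equal(length(intersect(top, bottom)), 0)
  # all-equal expression: split is by gene id, still disjoint
  expr$expression <- 1
  sets2 <- select_top_bottom(expr, 500)
  expect_equal(
    length(intersect(
      sets2$gene_id[sets2$set == "top"],
      sets2$gene_id[sets2$set == "bottom"]
    )), 0
  )
  expect_error(select_top_bottom(expr[1:999, ], 500), "at least")
  # truth-table proxy: top_n = #active recovers the active set exactly
  expr3 <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:40),
    expression = rep(c(1, 0), each = 20)
  )
  sets3 <- select_top_bottom(expr3, 20)
  expect_setequal(sets3$gene_id[sets3$set == "top"], sprintf("g%02d", 1:20))
})
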