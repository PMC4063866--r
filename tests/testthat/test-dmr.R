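# full-enumeration two-sided permutation p for the rank-sum statistic,
# independent of the implementation (midranks for ties)
enum_mw_p <- function(xs, ys) {
  n1 <- length(xs); n2 <- length(ys)
  v <- c(xs, ys)
  r <- rank(v)
  u_of <- function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, u_of)
  mu <- n1 * n2 / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

test_that("Mann-Whitney exact p matches full enumeration", {
  # complete separation of 5 vs 5: the classic 2/252
  r <- mann_whitney_u(rep(0, 5), rep(100, 5))
  expect_equal(r$p, 2 / 252)
  expect_equal(r$u, 0)

  # interleaved values: compare against the enumeration oracle
  xs <- c(10, 20, 30); ys <- c(15, 25, 35)
  expect_equal(mann_whitney_u(xs, ys)$p, enum_mw_p(xs, ys))

  xs2 <- c(1, 4, 6, 9); ys2 <- c(2, 3, 7, 12)
  expect_equal(mann_whitney_u(xs2, ys2)$p, enum_mw_p(xs2, ys2))

  # identical constant vectors: p = 1
  expect_equal(mann_whitney_u(rep(5, 4), rep(5, 4))$p, 1)

  # cross-check against the standard implementation, exact branch
  w <- stats::wilcox.test(xs2, ys2, exact = TRUE, correct = FALSE)
  expect_equal(mann_whitney_u(xs2, ys2)$p, w$p.value)
})

test_that("Mann-Whitney enumeration handles tied values exactly", {
  # tied case at small n: full enumeration, not the continuous distribution
  xs <- c(0, 0, 50, 100); ys <- c(50, 50, 100, 100)
  expect_equal(mann_whitney_u(xs, ys)$p, enum_mw_p(xs, ys))
  xs2 <- c(10, 10, 20); ys2 <- c(10, 20, 20, 30)
  expect_equal(mann_whitney_u(xs2, ys2)$p, enum_mw_p(xs2, ys2))
})

test_that("Mann-Whitney approximate branch matches wilcox.test beyond n = 20", {
  set.seed(4)
  for (i in 1:5) {
    xs <- sample(seq(0, 100, by = 10), 12, replace = TRUE)
    ys <- sample(seq(0, 100, by = 10), 12, replace = TRUE)
    got <- mann_whitney_u(xs, ys)
    w <- suppressWarnings(
      stats::wilcox.test(xs, ys, exact = FALSE, correct = TRUE)
    )
    expect_equal(got$p, w$p.value, tolerance = 1e-8)
  }
})

test_that("chi-square region test uses the closed 2x2 form without Yates", {
  r <- chi_square_region(90, 10, 10, 90)
  expect_equal(r$chi2, 128)
  ct <- stats::chisq.test(matrix(c(90, 10, 10, 90), 2, byrow = TRUE),
                          correct = FALSE)
  expect_equal(r$chi2, unname(ct$statistic))
  expect_equal(r$p, ct$p.value)

  expect_equal(chi_square_region(50, 50, 50, 50), list(chi2 = 0, p = 1))
  expect_equal(chi_square_region(0, 0, 5, 5)$p, 1)
  expect_equal(chi_square_region(5, 0, 5, 0)$p, 1) # zero T marginal

  # genome-scale pooled counts must not overflow integer arithmetic
  big <- chi_square_region(60000L, 20000L, 20000L, 60000L)
  ctb <- stats::chisq.test(matrix(c(60000, 20000, 20000, 60000), 2,
                                  byrow = TRUE), correct = FALSE)
  expect_equal(big$chi2, unname(ctb$statistic))
  expect_false(is.na(big$p))
})

test_that("valid CpG sites require depth n in both samples at the same site", {
  a <- calls_from_levels(c(100L, 200L, 300L), c(50, 50, 50), 5L, seed = 1)
  b <- calls_from_levels(c(100L, 200L, 400L), c(50, 50, 50), 100L, seed = 2)
  a$t_count[2] <- 0L; a$c_count[2] <- 4L # depth 4 in A at pos 200
  v <- valid_cpgs(a, b, "chr1", 1L, 1000L, dmr_params())
  expect_equal(v$pos, 100L) # 200 fails depth in A; 300/400 not shared
  expect_equal(nrow(valid_cpgs(a, b, "chr1", 900L, 950L, dmr_params())), 0)
})

test_that("seed search slides on the grid until enough valid CpGs", {
  # 4 valid CpGs in [1,500], 5 in [101,600]
  pos <- c(150L, 250L, 350L, 450L, 550L)
  a <- calls_from_levels(pos, rep(80, 5), 10L, seed = 3)
  b <- calls_from_levels(pos, rep(20, 5), 10L, seed = 4)
  s <- find_next_seed(a, b, "chr1", 1L, dmr_params())
  expect_equal(s$start, 101L)
  expect_equal(s$end, 600L)
  expect_equal(nrow(s$sites), 5)

  # no CpGs at all
  expect_null(find_next_seed(a[0, ], b[0, ], "chr1", 1L, dmr_params()))

  # first window already valid: returned unmoved
  pos2 <- seq(50L, 450L, by = 80L)
  a2 <- calls_from_levels(pos2, rep(80, length(pos2)), 10L, seed = 5)
  b2 <- calls_from_levels(pos2, rep(20, length(pos2)), 10L, seed = 6)
  s2 <- find_next_seed(a2, b2, "chr1", 1L, dmr_params())
  expect_equal(s2$start, 1L)
})

test_that("extension merges qualifying windows until the region exceeds k", {
  # CpGs every 50 bp with a strong difference across 2500 bp: every window
  # qualifies, so extension must stop at length k + w = 1500
  pos <- seq(25L, 2500L, by = 50L)
  a <- calls_from_levels(pos, rep(90, length(pos)), 20L, seed = 7)
  b <- calls_from_levels(pos, rep(10, length(pos)), 20L, seed = 8)
  p <- dmr_params()
  seed <- find_next_seed(a, b, "chr1", 1L, p)
  expect_true(seed$mw_p < p$p_seed)
  reg <- extend_seed(seed, a, b, p)
  expect_equal(reg$end - reg$start + 1L, 1500L)

  # next window not differentially methylated: region stays one window
  b2 <- b
  b2[b2$pos > 500L, c("c_count", "t_count")] <-
    a[a$pos > 500L, c("c_count", "t_count")]
  seed2 <- find_next_seed(a, b2, "chr1", 1L, p)
  reg2 <- extend_seed(seed2, a, b2, p)
  expect_equal(c(reg2$start, reg2$end), c(1L, 500L))

  # opposite-direction window stops extension too
  b3 <- b
  flip <- b3$pos > 500L & b3$pos <= 1000L
  b3[flip, c("c_count", "t_count")] <-
    tibble::tibble(c_count = 20L - b$c_count[flip],
                   t_count = 20L - b$t_count[flip])
  b3$c_count[flip] <- 20L # fully methylated: hyper, opposite of the seed
  b3$t_count[flip] <- 0L
  seed3 <- find_next_seed(a, b3, "chr1", 1L, p)
  reg3 <- extend_seed(seed3, a, b3, p)
  expect_equal(c(reg3$start, reg3$end), c(1L, 500L))
})

test_that("adjacent regions merge under gap, direction and MD-similarity rules", {
  pos <- seq(25L, 4000L, by = 50L)
  a <- calls_from_levels(pos, rep(90, length(pos)), 50L, seed = 9)
  b <- calls_from_levels(pos, rep(10, length(pos)), 50L, seed = 10)
  p <- dmr_params()
  regions <- tibble::tibble(
    chrom = "chr1", start = c(1L, 1301L), end = c(500L, 1800L),
    dir = c(-1L, -1L), mw_p = c(0.001, 0.002)
  )
  # gap 800 <= 1000, same direction, pooled MDs within 10 points
  m <- merge_adjacent(regions, a, b, p)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(1L, 1800L))
  expect_equal(m$mw_p, 0.002) # worst constituent p survives

  # gap 1200 exceeds merge_dist
  regions2 <- dplyr::mutate(regions, start = c(1L, 1701L),
                            end = c(500L, 2200L))
  expect_equal(nrow(merge_adjacent(regions2, a, b, p)), 2)

  # MD difference of ~15 points in sample A blocks the merge
  a3 <- a
  right <- a3$pos >= 1301L & a3$pos <= 1800L
  a3$c_count[right] <- stats::rbinom(sum(right), 50L, 0.75)
  a3$t_count[right] <- 50L - a3$c_count[right]
  m3 <- merge_adjacent(regions, a3, b, p)
  expect_equal(nrow(m3), 2)

  # opposite directions never merge
  regions4 <- dplyr::mutate(regions, dir = c(-1L, 1L))
  expect_equal(nrow(merge_adjacent(regions4, a, b, p)), 2)
})

test_that("call_dmrs finds exactly the planted block and nothing else", {
  set.seed(11)
  # 1-kb block at [1501,2500] with ~100% vs ~0%: depth 10, 1 CpG / 50 bp
  pos <- seq(25L, 4000L, by = 50L)
  in_block <- pos >= 1501L & pos <= 2500L
  a <- calls_from_levels(pos, rep(100, length(pos)), 10L, seed = 12)
  b <- calls_from_levels(pos, ifelse(in_block, 0, 100), 10L, seed = 13)
  res <- call_dmrs(a, b, dmr_params())
  d <- tidy(res)
  expect_equal(nrow(d), 1)
  expect_equal(d$direction, "hypo") # sample B lower than A
  # the call covers most of the block and stays within one window of it
  overlap <- min(d$end, 2500L) - max(d$start, 1501L) + 1L
  expect_gte(overlap, 700L)
  expect_gte(d$start, 1501L - 500L)
  expect_lte(d$end, 2500L + 500L)
  expect_true(d$chi2_p <= 0.01)
  expect_gte(d$md1 - d$md2, 50)

  # identical samples: nothing called
  res0 <- call_dmrs(a, a, dmr_params())
  expect_equal(nrow(tidy(res0)), 0)

  # only 4 CpGs per 500-bp window: the m = 5 rule blocks every seed
  sparse <- pos[seq_along(pos) %% 3 != 0] # ~7 per kb
  sparse <- sparse[seq(1, length(sparse), by = 2)]
  a4 <- calls_from_levels(sparse, rep(100, length(sparse)), 10L, seed = 14)
  b4 <- calls_from_levels(sparse, rep(0, length(sparse)), 10L, seed = 15)
  res4 <- call_dmrs(a4, b4, dmr_params(m = 6L))
  expect_equal(nrow(tidy(res4)), 0)
})

test_that("emitted DMRs satisfy their structural invariants", {
  rep_ <- planted_dmr_replicate(seed = 99)
  p <- dmr_params()
  d <- tidy(call_dmrs(rep_$callsA, rep_$callsB, p))
  expect_true(all(d$end - d$start + 1L >= p$w))
  expect_true(all(d$chi2_p <= p$p_region))
  expect_true(all(ifelse(d$direction == "hyper", d$md2 > d$md1,
                         d$md2 < d$md1)))
  expect_true(all(d$n_cpgs >= p$m))
})

test_that("swapping the samples mirrors every DMR exactly", {
  rep_ <- planted_dmr_replicate(seed = 42)
  d_ab <- tidy(call_dmrs(rep_$callsA, rep_$callsB, dmr_params()))
  d_ba <- tidy(call_dmrs(rep_$callsB, rep_$callsA, dmr_params()))
  expect_equal(nrow(d_ab), nrow(d_ba))
  expect_equal(d_ab$start, d_ba$start)
  expect_equal(d_ab$end, d_ba$end)
  expect_equal(d_ab$chi2_p, d_ba$chi2_p)
  expect_equal(d_ab$direction,
               ifelse(d_ba$direction == "hyper", "hypo", "hyper"))
})

test_that("validity and seed counts move monotonically with n and p_seed", {
  rep_ <- planted_dmr_replicate(seed = 7)
  a <- rep_$callsA; b <- rep_$callsB
  n_valid <- vapply(c(1L, 5L, 8L, 10L), function(n) {
    nrow(valid_cpgs(a, b, "chr1", 1L, 4000L, dmr_params(n = n)))
  }, integer(1))
  expect_true(all(diff(n_valid) <= 0))

  count_sig_windows <- function(p_seed) {
    p <- dmr_params(p_seed = p_seed)
    starts <- seq(1L, 3501L, by = p$s)
    sum(vapply(starts, function(x) {
      s <- valid_cpgs(a, b, "chr1", x, x + p$w - 1L, p)
      nrow(s) >= p$m && mann_whitney_u(s$md_a, s$md_b)$p < p$p_seed
    }, logical(1)))
  }
  counts <- vapply(c(0.001, 0.01, 0.05, 0.25), count_sig_windows, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("classify_unchanged follows the p > 0.25 rule", {
  pos <- seq(50L, 450L, by = 80L)
  a <- calls_from_levels(pos, rep(50, length(pos)), 30L, seed = 20)
  expect_true(classify_unchanged(a, a, "chr1", 1L, 500L, dmr_params()))

  b <- calls_from_levels(pos, rep(95, length(pos)), 30L, seed = 21)
  a2 <- calls_from_levels(pos, rep(5, length(pos)), 30L, seed = 22)
  expect_false(classify_unchanged(a2, b, "chr1", 1L, 500L, dmr_params()))

  # untestable region: fewer than m valid CpGs
  expect_true(is.na(classify_unchanged(a, a, "chr1", 1L, 100L, dmr_params())))
})
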