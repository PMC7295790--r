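test_that("rank_by_richness sorts by richness with ascending-id ties", {
  m <- make_im(matrix(c(1, 1, 0,
                        1, 0, 0,
                        0, 1, 1), 3, 3, byrow = TRUE,
                      dimnames = list(NULL, c("b", "a", "c"))))
  r <- rank_by_richness(m)
  expect_equal(r$condition, c("a", "b", "c"))  # 2, 2, 1 with a < b tie
  expect_equal(r$richness, c(2L, 2L, 1L))
  expect_equal(nrow(rank_by_richness(m, top_k = 2)), 2L)
  expect_error(rank_by_richness(m, top_k = 0), "positive")

  set.seed(21)
  big <- random_im(20, 6)
  hand <- sort(colSums(unclass(big)), decreasing = TRUE)
  expect_equal(rank_by_richness(big)$richness, unname(hand))
})

test_that("marginal_gain counts species no selected condition grew", {
  m <- make_im(matrix(c(1, 1, 0, 0,
                        1, 0, 1, 0,
                        0, 0, 1, 1,
                        0, 0, 0, 1), 4, 4, byrow = TRUE))
  expect_equal(marginal_gain(m, character(0), "c01"), richness(m, "c01")[[1]])
  expect_equal(marginal_gain(m, "c01", "c03"), 1L)   # only sp3 is new
  expect_equal(marginal_gain(m, c("c03", "c04"), "c02"), 1L)
  # candidate subset of the selected union gains nothing
  expect_equal(marginal_gain(m, c("c01", "c04"), "c03"), 0L)
  expect_error(marginal_gain(m, "c01", "c01"), "already selected")
})

test_that("greedy_cover replays the greedy rule and flags exhaustion", {
  # crafted 8 species x 5 conditions with a known greedy sequence
  m <- make_im(matrix(c(
    1, 0, 0, 0, 0,
    1, 0, 0, 0, 0,
    1, 1, 0, 0, 0,
    0, 1, 0, 1, 0,
    0, 1, 0, 0, 0,
    0, 0, 1, 1, 0,
    0, 0, 1, 0, 0,
    0, 0, 0, 1, 1), 8, 5, byrow = TRUE))
  cov <- greedy_cover(m)
  oracle <- greedy_oracle(m)
  expect_equal(cov$steps$condition, oracle$picks)
  expect_equal(cov$steps$marginal_gain, oracle$gains)
  expect_equal(max(cov$steps$cumulative_covered), 8L)
  expect_false(cov$exhausted)

  # one condition covering everything -> a single step at fraction 1
  all1 <- make_im(cbind(rep(1, 4), c(1, 0, 0, 0)))
  cov1 <- greedy_cover(all1)
  expect_equal(nrow(cov1$steps), 1L)
  expect_equal(cov1$steps$cumulative_fraction, 1)

  # a valid matrix (every species isolated somewhere) can always reach
  # full coverage, so the exhausted flag stays off even at target 1
  ex <- greedy_cover(make_im(matrix(c(1, 1, 1, 1), 2, 2)), target_fraction = 1)
  expect_false(ex$exhausted)

  # seeding the argmax-richness condition equals the unseeded run
  set.seed(31)
  r <- random_im(25, 8)
  un <- greedy_cover(r)
  seeded <- greedy_cover(r, seed_condition = rank_by_richness(r)$condition[1])
  expect_equal(seeded$steps, un$steps)

  # forcing a seed that is not the richest still covers everything
  other <- greedy_cover(r, seed_condition = rank_by_richness(r)$condition[8])
  expect_equal(max(other$steps$cumulative_covered), 25L)
})

test_that("greedy marginal gains are non-increasing on random matrices", {
  set.seed(41)
  for (i in 1:50) {
    r <- random_im(sample(5:25, 1), sample(3:8, 1), runif(1, 0.1, 0.5))
    cov <- greedy_cover(r)
    expect_true(all(diff(cov$steps$marginal_gain) <= 0))
    expect_true(all(diff(cov$steps$cumulative_covered) > 0))
    expect_equal(max(cov$steps$cumulative_covered), nrow(r))
  }
})

test_that("exact_min_cover is exact, deterministic and bounds greedy", {
  # one condition covers all
  m1 <- make_im(cbind(rep(1, 5), rbinom(5, 1, 0.5) * c(1, 1, 1, 1, 0)))
  expect_equal(exact_min_cover(m1)$size, 1L)

  # three disjoint conditions partition the species: forced size 3
  m3 <- make_im(rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  mc <- exact_min_cover(m3)
  expect_equal(mc$size, 3L)
  expect_equal(mc$conditions, c("c01", "c02", "c03"))

  # capacity cap
  wide <- make_im(matrix(1, 2, 21))
  expect_error(exact_min_cover(wide), "20 conditions")

  set.seed(51)
  for (i in 1:20) {
    r <- random_im(12, 8, runif(1, 0.15, 0.4))
    opt <- exact_min_cover(r)
    cov <- greedy_cover(r)
    expect_lte(opt$size, nrow(cov$steps))
    u <- unclass(r)
    expect_true(all(rowSums(u[, opt$conditions, drop = FALSE]) > 0))
  }
})

test_that("greedy k-step coverage respects the (1 - 1/e) guarantee", {
  set.seed(61)
  for (i in 1:10) {
    r <- random_im(15, 7, runif(1, 0.15, 0.4))
    cov <- greedy_cover(r)
    for (k in 1:3) {
      if (nrow(cov$steps) < k) break
      expect_gte(cov$steps$cumulative_covered[k],
                 (1 - 1 / exp(1)) * best_k_coverage(r, k))
    }
  }
})

test_that("panel_report mirrors the published table arithmetic", {
  set.seed(71)
  r <- random_im(30, 6)
  cov <- greedy_cover(r)
  rep <- panel_report(cov, r)
  expect_equal(rep$cumulative_species, cumsum(rep$species_added))
  expect_true(all(diff(rep$cumulative_percent) >= 0))
  expect_equal(rep$cumulative_percent[nrow(rep)],
               floor(100 * max(rep$cumulative_species) / 30 + 0.5))

  # single-step cover: cumulative = marginal = richness
  one <- make_im(cbind(rep(1, 4), c(1, 0, 0, 0)))
  r1 <- panel_report(greedy_cover(one), one)
  expect_equal(r1$species_added[1], r1$species_total[1])
  expect_equal(r1$cumulative_species[1], r1$species_total[1])

  # numeric method: bare gain column plus a total
  num <- panel_report(c(3, 2, 1), total_species = 10)
  expect_equal(num$cumulative_species, c(3L, 5L, 6L))
  expect_equal(num$cumulative_percent, c(30, 50, 60))
  expect_error(panel_report(c(5, 6), total_species = 10), "exceed")

  expect_error(panel_report(cov, random_im(29, 6)), "match")
})

test_that("force_include appends manual picks with their gain at append time", {
  m <- make_im(rbind(c(1, 1, 0), c(1, 0, 0), c(0, 0, 1), c(1, 1, 0)))
  cov <- greedy_cover(m, target_fraction = 0.75, force_include = "c02")
  expect_true("c02" %in% cov$steps$condition)
  forced <- cov$steps[cov$steps$forced, ]
  expect_equal(forced$condition, "c02")
  expect_equal(forced$marginal_gain, 0L)  # c02 adds nothing after c01
})

test_that("accumulation curve: greedy dominates random orders under a fixed seed", {
  set.seed(81)
  r <- random_im(30, 10, 0.25)
  a1 <- accumulation_curve(r, n_permutations = 50, seed = 9)
  a2 <- accumulation_curve(r, n_permutations = 50, seed = 9)
  expect_identical(a1, a2)
  expect_true(all(a1$greedy >= a1$random_mean - 1e-9))
  expect_equal(a1$greedy[nrow(a1)], 30)
  expect_true(all(a1$random_max <= a1$greedy[nrow(a1)]))

  # identical columns -> flat after rank 1
  flat <- make_im(matrix(1, 4, 3))
  af <- accumulation_curve(flat, n_permutations = 5, seed = 1)
  expect_equal(af$greedy, rep(4, 3))
  expect_error(accumulation_curve(r, n_permutations = 0), ">= 1")
})
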