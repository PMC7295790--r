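three_group_im <- function(m) {
  n <- ncol(m)
  tags <- rep(c("gA", "gB", "gC"), length.out = n)[order(seq_len(n))]
  cm <- data.frame(id = sprintf("c%02d", seq_len(n)),
                   label = sprintf("c%02d", seq_len(n)),
                   atmosphere = "anaerobic", temperature_c = 37,
                   supplements = "none", pretreatment = "none",
                   group = sort(tags), stringsAsFactors = FALSE)
  make_im(m, condition_meta = cm)
}

test_that("group_species unions conditions sharing a tag", {
  m <- three_group_im(rbind(c(1, 0, 1, 0, 0, 0),
                            c(1, 1, 0, 0, 0, 0),
                            c(0, 0, 1, 1, 0, 0),
                            c(0, 0, 0, 0, 1, 1)))
  # groups: c01-c02 = gA, c03-c04 = gB, c05-c06 = gC
  expect_setequal(group_species(m, "gA"), c("sp01", "sp02"))
  expect_setequal(group_species(m, "gB"), c("sp01", "sp03"))
  expect_setequal(group_species(m, "gC"), c("sp04"))
  expect_error(group_species(m, "gZ"), "group tag")
})

test_that("partition regions follow inclusion-exclusion and sum to the union", {
  m <- three_group_im(rbind(c(1, 0, 1, 0, 1, 0),   # in all three
                            c(1, 1, 0, 0, 0, 0),   # gA only
                            c(0, 0, 1, 1, 0, 0),   # gB only
                            c(0, 0, 0, 1, 1, 0),   # gB & gC
                            c(0, 0, 0, 0, 1, 1)))  # gC only
  p <- species_partition(m, c("gA", "gB", "gC"))
  expect_equal(sum(p$region_counts), p$union_size)
  expect_equal(p$union_size, 5L)
  expect_equal(p$region_counts[["111"]], 1L)
  expect_equal(p$region_counts[["011"]], 1L)
  expect_equal(p$percent_common, 20)
  # per-group size recoverable by summing regions containing the group
  sigs <- names(p$region_counts)
  expect_equal(sum(p$region_counts[substr(sigs, 1, 1) == "1"]),
               unname(p$group_sizes["gA"]))

  # permutation invariance up to signature relabeling
  q <- species_partition(m, c("gC", "gA", "gB"))
  expect_equal(q$union_size, p$union_size)
  expect_equal(q$region_counts[["111"]], p$region_counts[["111"]])
  expect_equal(q$region_counts[["010"]],  # gA only under the new order
               p$region_counts[["100"]])

  expect_error(species_partition(m, c("gA", "gA", "gB")), "distinct")
  expect_error(species_partition(m, "gA"), "2 or 3")
})

test_that("disjoint and identical groups produce the degenerate partitions", {
  dis <- three_group_im(rbind(c(1, 0, 0, 0, 0, 0),
                              c(0, 0, 1, 0, 0, 0),
                              c(0, 0, 0, 0, 1, 0)))
  p <- species_partition(dis, c("gA", "gB", "gC"))
  expect_equal(unname(p$region_counts[c("100", "010", "001")]),
               c(1L, 1L, 1L))
  expect_equal(sum(p$region_counts), 3L)
  expect_equal(p$region_counts[["111"]], 0L)

  # identical species sets in two groups -> single shared region
  same <- make_im(rbind(c(1, 0, 1, 0),
                        c(1, 0, 1, 0)),
                  condition_meta = data.frame(
                    id = c("c01", "c02", "c03", "c04"),
                    label = "x", atmosphere = "anaerobic",
                    temperature_c = 37, supplements = "none",
                    pretreatment = "none", group = c("gA", "gA", "gB", "gB"),
                    stringsAsFactors = FALSE))
  p2 <- species_partition(same, c("gA", "gB"))
  expect_equal(p2$region_counts[["11"]], 2L)
  expect_equal(sum(p2$region_counts), 2L)
})

test_that("partition regions sum to the union on random group assignments", {
  set.seed(91)
  for (i in 1:30) {
    n_cond <- sample(4:9, 1)
    m <- random_im(sample(8:30, 1), n_cond, runif(1, 0.15, 0.5))
    tags <- sample(c("gA", "gB", "gC"), n_cond, replace = TRUE)
    while (length(unique(tags)) < 3) {
      tags <- sample(c("gA", "gB", "gC"), n_cond, replace = TRUE)
    }
    cm <- condition_meta(m); cm$group <- tags
    m2 <- make_im(unclass(m), condition_meta = cm)
    p <- species_partition(m2, c("gA", "gB", "gC"))
    expect_equal(sum(p$region_counts), p$union_size)
    union_hand <- length(Reduce(union, lapply(c("gA", "gB", "gC"),
                                              function(g) group_species(m2, g))))
    expect_equal(p$union_size, union_hand)
  }
})

test_that("added_and_specific matches brute-force set differences", {
  m <- three_group_im(rbind(c(1, 0, 1, 0, 0, 0),   # A and B
                            c(1, 1, 0, 0, 0, 0),   # A only
                            c(0, 0, 1, 1, 0, 0),   # B only
                            c(0, 0, 1, 0, 1, 0),   # B and C
                            c(0, 0, 0, 0, 1, 1)))  # C only
  res <- added_and_specific(m, baseline = "gA", other = "gB")
  # B \ A = {sp03, sp04}; of those, sp04 is also in C
  expect_equal(res, c(added = 2L, specific = 1L))

  expect_error(added_and_specific(m, "gA", "gA"), "overlap")

  # other subset of baseline -> (0, 0)
  m2 <- make_im(rbind(c(1, 1, 0), c(1, 0, 0)),
                condition_meta = data.frame(
                  id = c("c01", "c02", "c03"), label = "x",
                  atmosphere = "anaerobic", temperature_c = 37,
                  supplements = "none", pretreatment = "none",
                  group = c("base", "sub", "other"), stringsAsFactors = FALSE))
  expect_equal(added_and_specific(m2, "base", "sub"),
               c(added = 0L, specific = 0L))

  # invariant: specific <= added <= |other|
  set.seed(101)
  for (i in 1:20) {
    m3 <- random_im(15, 6, 0.3)
    cm <- condition_meta(m3)
    cm$group <- rep(c("gA", "gB", "gC"), each = 2)
    m3 <- make_im(unclass(m3), condition_meta = cm)
    r <- added_and_specific(m3, "gA", "gB")
    expect_lte(r[["specific"]], r[["added"]])
    expect_lte(r[["added"]], length(group_species(m3, "gB")))
  }
})

test_that("catalogue comparison counts normalized absent names", {
  sp <- c("Bacteroides  fragilis", "akkermansia muciniphila", "New species X")
  cat1 <- c("Bacteroides fragilis", "Akkermansia muciniphila")
  res <- compare_to_catalogue(sp, cat1)
  expect_equal(res$novel_count, 1L)
  expect_equal(res$novel_names, "New species X")

  expect_equal(compare_to_catalogue(sp, normalize_species(sp))$novel_count, 0L)
  expect_equal(compare_to_catalogue(c("a b", "c d"), "e f")$novel_count, 2L)
  expect_error(compare_to_catalogue(sp, character(0)), "non-empty")
})
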