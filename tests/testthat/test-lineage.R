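test_that("V/J/length grouping partitions clonotypes exhaustively", {
  tab <- clone_table(c(rand_nt(1, 36), rand_nt(1, 39)), v = "V1", j = "J1")
  g <- group_by_vjl(tab)
  expect_equal(length(unique(g$vjl)), 2)
  # identical CDR3 under different J genes stays in different groups
  s <- rand_nt(1, 24)
  g2 <- group_by_vjl(clone_table(c(s, s), v = "V1", j = c("J1", "J2")))
  expect_equal(nrow(g2), 2)
  expect_equal(length(unique(g2$vjl)), 2)
  # 5 clonotypes, 2 keys, all covered; counts aggregate duplicates
  tab3 <- clone_table(c(rand_nt(3, 24), rand_nt(2, 27)))
  g3 <- group_by_vjl(dplyr::bind_rows(tab3, tab3))
  expect_equal(nrow(g3), 5)
  expect_equal(sort(unique(table(g3$vjl))), c(2, 3))
  expect_equal(sum(g3$count), 10)
})

test_that("percent identity is exact at boundary fractions", {
  a <- rand_nt(1, 20)
  expect_equal(identity_pct(a, a), 100)
  expect_equal(identity_pct(a, mutate_positions(a, 1)), 95)  # 19/20 exactly
  b <- rand_nt(1, 36)
  expect_equal(identity_pct(b, mutate_positions(b, 1:18)), 50)
  expect_equal(identity_pct(a, mutate_positions(a, 3)),
               identity_pct(mutate_positions(a, 3), a))
  expect_error(identity_pct("ACGT", "ACGTA"), "equal length")
})

test_that("nearest neighbors take the maximum over same-group companions", {
  base <- rand_nt(1, 100)
  s1 <- mutate_positions(base, 1:3)    # 97% to base
  nn <- nearest_neighbor(c(base, s1))
  expect_equal(unname(nn), c(97, 97))
  s_far <- mutate_positions(base, 1:20)  # 80%
  s_near <- mutate_positions(base, 1:5)  # 95%
  nn3 <- nearest_neighbor(c(base, s_near, s_far))
  expect_equal(unname(nn3[base]), 95)
  expect_length(nearest_neighbor(base), 0)
})

test_that("nearest-neighbor distribution separates mutants from background", {
  base <- rand_nt(1, 39)
  mutants <- vapply(1:6, function(i) mutate_positions(base, i), character(1))
  tab <- clone_table(c(base, mutants))
  d <- nn_distribution(tab)
  expect_true(all(d$identity_bin >= 95))
  expect_equal(sum(d$n), 7)
  # unrelated random sequences sit well below 95%
  set.seed(13)
  bg <- unique(rand_nt(40, 36))
  d_bg <- nn_distribution(clone_table(bg))
  expect_true(all(d_bg$identity_bin < 90))
  empty <- nn_distribution(clone_table(character(0)))
  expect_equal(nrow(empty), 0)
})

test_that("lineages are single-linkage components at an inclusive 95% cut-off", {
  a <- rand_nt(1, 20)
  b <- mutate_positions(a, 7)          # exactly 95%
  net <- build_lineages(clone_table(c(a, b)))
  expect_equal(net$n_lineages, 1)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$identity_pct, 95)

  # chain u-v, v-w within threshold, u-w outside: one lineage, two edges
  u <- rand_nt(1, 25)
  v <- mutate_positions(u, 1)          # 96%
  w <- mutate_positions(v, 2)          # 96% to v, 92% to u
  net3 <- build_lineages(clone_table(c(u, v, w)))
  expect_equal(net3$n_lineages, 1)
  expect_equal(sum(!is.na(net3$nodes$lineage_id)), 3)
  expect_equal(nrow(net3$edges), 2)
  has_uw <- any((net3$nodes$cdr3_nt[net3$edges$from] == u &
                 net3$nodes$cdr3_nt[net3$edges$to] == w) |
                (net3$nodes$cdr3_nt[net3$edges$from] == w &
                 net3$nodes$cdr3_nt[net3$edges$to] == u))
  expect_false(has_uw)

  # isolated clonotype forms no lineage
  iso <- build_lineages(clone_table(rand_nt(2, c(24, 27))))
  expect_equal(iso$n_lineages, 0)
  expect_true(all(is.na(iso$nodes$lineage_id)))
})

test_that("mutated ratio and degree statistics follow their definitions", {
  base <- rand_nt(1, 40)
  pair <- c(base, mutate_positions(base, 1))
  bg <- rand_nt(8, 33)
  net <- build_lineages(clone_table(c(pair, bg)))
  expect_equal(mutated_ratio(net), 100 * 2 / 10)
  ds <- net |> degree_stats()
  expect_equal(ds$degree_dist$ratio[ds$degree_dist$degree == "1"], 1)
  expect_equal(ds$max_degree, 1)

  # complete triangle: all members at degree 2
  tri <- c(base, mutate_positions(base, 1), mutate_positions(base, 2))
  ds3 <- degree_stats(build_lineages(clone_table(tri)))
  expect_equal(ds3$degree_dist$ratio[ds3$degree_dist$degree == "2"], 1)
  expect_equal(ds3$max_degree, 2)

  # star with 5 leaves
  hub <- rand_nt(1, 100)
  leaves <- vapply(1:5, function(i) {
    mutate_positions(hub, (10 * i):(10 * i + 4))   # 95% to hub, <95% pairwise
  }, character(1))
  ds5 <- degree_stats(build_lineages(clone_table(c(hub, leaves))))
  expect_equal(ds5$max_degree, 5)

  empty <- degree_stats(build_lineages(clone_table(rand_nt(3, 21))))
  expect_equal(empty$max_degree, 0)
  expect_equal(nrow(empty$degree_dist), 0)
  expect_equal(mutated_ratio(build_lineages(clone_table(rand_nt(3, 21)))), 0)
})

test_that("network components equal the brute-force reference and respect threshold monotonicity", {
  for (seed in 1:8) {
    tab <- rand_lineage_subset(60, seed)
    net <- build_lineages(tab, min_nodes = 1)
    got <- split(net$nodes$cdr3_nt, net$nodes$component)
    ref <- lineage_components_bruteforce(tab)
    expect_true(same_partition(got, ref))

    prev_edges <- Inf; prev_nodes <- Inf; prev_deg <- Inf
    for (th in c(90, 95, 99)) {
      nt <- build_lineages(tab, threshold_pct = th)
      expect_lte(nrow(nt$edges), prev_edges)
      expect_lte(sum(!is.na(nt$nodes$lineage_id)), prev_nodes)
      expect_lte(max(nt$nodes$degree), prev_deg)
      prev_edges <- nrow(nt$edges)
      prev_nodes <- sum(!is.na(nt$nodes$lineage_id))
      prev_deg <- max(nt$nodes$degree)
    }
  }
})

test_that("edges never cross V/J/length group boundaries", {
  s <- rand_nt(1, 24)
  tab <- clone_table(c(s, mutate_positions(s, 1), s, mutate_positions(s, 1)),
                     v = c("V1", "V1", "V2", "V2"))
  net <- build_lineages(tab)
  vjl_from <- net$nodes$vjl[net$edges$from]
  vjl_to <- net$nodes$vjl[net$edges$to]
  expect_true(all(vjl_from == vjl_to))
  expect_equal(net$n_lineages, 2)
})
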