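test_that("sharing ratios enumerate occupancy over the clonotype union", {
  # {a: 2 mice, b: 1, c: 1, d: 3} over 3 mice
  subs <- list(m1 = c("a", "d"), m2 = c("a", "b", "d"), m3 = c("c", "d"))
  sr <- sharing_ratios(subs)
  expect_equal(sr$pct, c(50, 25, 25))
  expect_equal(sum(sr$pct), 100)
  # fully disjoint repertoires are 100% private
  dis <- sharing_ratios(list(m1 = "x", m2 = "y", m3 = "z"))
  expect_equal(dis$pct[dis$k == 1], 100)
  # a clonotype in every individual lands in the top bin
  all5 <- sharing_ratios(stats::setNames(rep(list("core"), 5),
                                         paste0("m", 1:5)))
  expect_equal(all5$pct[all5$k == 5], 100)
  # adding a private clonotype only grows the k = 1 bin count
  before <- sharing_ratios(subs)
  subs$m1 <- c(subs$m1, "private_new")
  after <- sharing_ratios(subs)
  expect_equal(after$n_clonotypes[after$k == 1],
               before$n_clonotypes[before$k == 1] + 1)
  expect_equal(after$n_clonotypes[-1], before$n_clonotypes[-1])
  expect_error(sharing_ratios(list(m1 = "x")), "two individuals")
})

make_cross_toy <- function() {
  anc <- "ACGTACGTACGTACGTACGTACGTACGTACGTACGT"  # 36 nt
  m1 <- mutate_positions(anc, 1)
  m2 <- mutate_positions(anc, 2)
  lone <- rand_nt(1, 36)
  pairA <- rand_nt(1, 30)
  pairB <- mutate_positions(pairA, 1)
  dplyr::bind_rows(
    clone_table(c(anc, lone), sample_id = "m1_blood", count = c(4L, 1L)),
    clone_table(m1, sample_id = "m2_blood", count = 2L),
    clone_table(c(m2, pairA), sample_id = "m3_spleen", count = c(1L, 1L)),
    clone_table(pairB, sample_id = "m2_spleen", count = 3L)
  ) |>
    dplyr::mutate(
      mouse_id = sub("_.*", "", .data$sample_id),
      tissue = sub(".*_", "", .data$sample_id),
      strain = "BAL", isotype = "IgM"
    )
}

test_that("cross-individual lineages pool, cluster and trace back exactly", {
  set.seed(500)
  toy <- make_cross_toy()
  cl <- build_cross_lineages(toy, min_nodes = 3)
  # only the 3-node lineage (anc + two mutants, three different mice) survives
  expect_equal(nrow(cl$lineages), 1)
  expect_equal(cl$lineages$n_nodes, 3)
  expect_equal(cl$lineages$n_samples, 3)
  expect_equal(cl$lineages$n_blood, 2)
  expect_equal(cl$lineages$n_spleen, 1)
  # the 2-node component is discarded at min_nodes = 3, retained at 2,
  # dropped again at the large-lineage setting of 5
  cl2 <- build_cross_lineages(toy, min_nodes = 2)
  expect_equal(nrow(cl2$lineages), 2)
  cl5 <- build_cross_lineages(toy, min_nodes = 5)
  expect_equal(nrow(cl5$lineages), 0)

  # trace-back is exact: presence iff the (V, J, CDR3 nt) triple occurs
  for (i in seq_len(nrow(cl$presence))) {
    p <- cl$presence[i, ]
    nd <- cl$nodes[cl$nodes$lineage_id == p$lineage_id, ]
    hit <- toy$sample_id == p$sample_id &
      paste(toy$v_gene, toy$j_gene, toy$cdr3_nt) %in%
        paste(nd$v_gene, nd$j_gene, nd$cdr3_nt)
    expect_equal(sum(hit), p$n_nodes)
  }
  # abundance is the summed node frequency within the sample
  p1 <- cl$presence[cl$presence$sample_id == "m1_blood", ]
  expect_equal(p1$abundance, 4 / 5)
})

test_that("lineage occupancy matrices sum to 100 with one cell per lineage", {
  set.seed(501)
  toy <- make_cross_toy()
  cl <- build_cross_lineages(toy, min_nodes = 2)
  occ <- lineage_occupancy(cl)
  expect_equal(sum(occ), 100)
  # anc lineage in (2 blood, 1 spleen); pair lineage in (0 blood, 2 spleen)
  expect_equal(occ["2", "1"], 50)
  expect_equal(occ["0", "2"], 50)
  # raising min_nodes never increases the lineage count
  expect_gte(nrow(build_cross_lineages(toy, min_nodes = 2)$lineages),
             nrow(build_cross_lineages(toy, min_nodes = 3)$lineages))
})

test_that("lineage-abundance MHSI agrees with the hand-evaluated formula", {
  set.seed(502)
  toy <- make_cross_toy()
  cl <- build_cross_lineages(toy, min_nodes = 2)
  # m3_spleen holds lineage 1 (freq 1/2) and lineage 2 (freq 1/2);
  # m2_spleen holds lineage 2 only (freq 1): MHSI = 2*(0.5*0 + 0.5*1) /
  # ((0.25 + 0.25) + 1) = 1 / 1.5
  expect_equal(lineage_abundance_mhsi(cl, "m3_spleen", "m2_spleen"), 2 / 3,
               tolerance = 1e-12)
  # identical profile with itself
  expect_equal(lineage_abundance_mhsi(cl, "m1_blood", "m1_blood"), 1)
  # samples sharing no lineage: m1_blood (lineage 1) vs m2_spleen (lineage 2)
  expect_equal(lineage_abundance_mhsi(cl, "m1_blood", "m2_spleen"), 0)
})

test_that("lineage size distributions count node numbers", {
  set.seed(503)
  base <- rand_nt(3, 60)
  seqs <- c(base[1], mutate_positions(base[1], 1),
            base[2], mutate_positions(base[2], 1),
            base[3], mutate_positions(base[3], 1))
  net <- build_lineages(clone_table(seqs))
  nsd <- node_size_distribution(net)
  expect_equal(nsd$pct[nsd$size == 2], 100)
  # sizes {2, 2, 2, 3}
  tri <- rand_nt(1, 90)
  seqs2 <- c(seqs, tri, mutate_positions(tri, 1), mutate_positions(tri, 2))
  nsd2 <- node_size_distribution(build_lineages(clone_table(seqs2)))
  expect_equal(nsd2$pct[nsd2$size == 2], 75)
  expect_equal(nsd2$pct[nsd2$size == 3], 25)
  empty <- node_size_distribution(build_lineages(clone_table(rand_nt(2, c(21, 24)))))
  expect_equal(nrow(empty), 0)
})

test_that("group comparisons reproduce exact Wilcoxon p-values", {
  # fully separated 5 vs 5, unpaired: 2 / choose(10, 5)
  res <- compare_groups(1:5, 11:15)
  expect_equal(res$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_true(res$significant)
  # paired shift, n = 8, all-positive differences: 2 / 2^8
  a <- c(1.2, 2.1, 0.7, 3.3, 2.8, 1.9, 0.4, 2.2)
  res_p <- compare_groups(a + 10 + seq(0.01, 0.08, by = 0.01), a,
                          paired = TRUE)  # distinct all-positive differences
  expect_equal(res_p$p_value, 2 / 2^8, tolerance = 1e-12)
  # identical paired samples carry no signal
  expect_warning(res0 <- compare_groups(a, a, paired = TRUE), "zero")
  expect_equal(res0$p_value, 1)
  expect_false(res0$significant)
  expect_error(compare_groups(numeric(0), 1:3), "at least one")
})
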