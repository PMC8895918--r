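small_cfg <- function(...) {
  sim_config(n_individuals = 3, n_clonotypes = 300, seed = 21, ...)
}

test_that("simulation is deterministic under a fixed seed", {
  s1 <- simulate_repertoires(small_cfg())
  s2 <- simulate_repertoires(small_cfg())
  expect_identical(s1$clones, s2$clones)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_repertoires(sim_config(n_individuals = 3,
                                        n_clonotypes = 300, seed = 22))
  expect_false(identical(s1$clones, s3$clones))
})

test_that("emitted clones satisfy the qualified-clone invariants", {
  sim <- simulate_repertoires(small_cfg())
  expect_true(all(nchar(sim$clones$cdr3_aa) >= 4))
  expect_false(any(grepl("[*_]", sim$clones$cdr3_aa)))
  expect_true(all(nchar(sim$clones$cdr3_nt) ==
                    3 * nchar(sim$clones$cdr3_aa)))
  expect_true(all(sim$clones$count >= 1))
  filtered <- suppressMessages(filter_qualified(sim$clones))
  expect_equal(nrow(filtered), nrow(sim$clones))
})

test_that("zero sharing and zero lineage fractions plant nothing", {
  sim0 <- simulate_repertoires(small_cfg(public_fraction = 0))
  by_mouse <- split(sim0$clones, sim0$clones$mouse_id)
  occ <- sharing_ratios(lapply(by_mouse, clonotype_profile,
                               level = "nt_vj") |> lapply(names))
  expect_equal(occ$pct[occ$k == 1], 100)

  sim_l0 <- simulate_repertoires(small_cfg(lineage_fraction = 0))
  for (sid in unique(sim_l0$clones$sample_id)[1:2]) {
    for (iso in c("IgA", "IgM")) {
      sub <- sim_l0$clones[sim_l0$clones$sample_id == sid &
                             sim_l0$clones$isotype == iso, ]
      expect_equal(build_lineages(sub)$n_lineages, 0)
    }
  }
})

test_that("planted lineages are recovered exactly within each subset", {
  sim <- simulate_repertoires(small_cfg())
  sub <- sim$clones[sim$clones$sample_id == "BAL_m01_blood" &
                      sim$clones$isotype == "IgM", ]
  net <- build_lineages(sub)
  nodes <- dplyr::left_join(net$nodes, sim$truth,
                            by = c("v_gene", "j_gene", "cdr3_nt"))
  recovered <- ifelse(is.na(nodes$lineage_id),
                      paste0("solo_r", seq_len(nrow(nodes))),
                      paste0("rec", nodes$lineage_id))
  planted <- ifelse(is.na(nodes$lineage_uid),
                    paste0("solo_p", seq_len(nrow(nodes))),
                    nodes$lineage_uid)
  expect_equal(adjusted_rand(recovered, planted), 1)
  expect_equal(mutated_ratio(net), 100 * mean(!is.na(nodes$lineage_uid)))
})

test_that("an infeasible lineage mutation budget is rejected", {
  expect_error(sim_config(cdr3_aa_len = c(4L, 6L), lineage_fraction = 0.2),
               "infeasible")
  # but allowed when no lineages are requested
  cfg <- sim_config(cdr3_aa_len = c(4L, 6L), cdr3_len_mode = 5L,
                    lineage_fraction = 0)
  expect_s3_class(cfg, "sim_config")
})

test_that("repertoire evenness decreases with abundance skew", {
  vals <- vapply(c(0.3, 1.2, 2.5), function(sdlog) {
    sim <- simulate_repertoires(
      sim_config(n_individuals = 1, tissues = "blood",
                 isotype_mix = c(IgM = 1), n_clonotypes = 500,
                 abundance = list(law = "lognormal", meanlog = 1,
                                  sdlog = sdlog),
                 seed = 77))
    nsde(clonotype_profile(sim$clones))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("AIRR round trip reproduces the clone tables byte for byte", {
  sim <- simulate_repertoires(small_cfg())
  d <- withr::local_tempdir()
  paths <- emit_airr(sim, d)
  expect_length(paths, length(unique(sim$clones$sample_id)))
  back <- dplyr::bind_rows(lapply(sort(unname(paths)), read_airr))
  orig <- dplyr::arrange(sim$clones, .data$sample_id, .data$v_gene,
                         .data$cdr3_nt)
  back <- dplyr::arrange(back[, names(orig)], .data$sample_id, .data$v_gene,
                         .data$cdr3_nt)
  expect_equal(as.data.frame(back), as.data.frame(orig))
  # fixed seed gives byte-identical files
  d2 <- withr::local_tempdir()
  emit_airr(simulate_repertoires(small_cfg()), d2)
  for (p in paths) {
    expect_identical(unname(tools::md5sum(p)),
                     unname(tools::md5sum(file.path(d2, basename(p)))))
  }
  # empty table still writes a header-only file
  p0 <- file.path(d, "empty.tsv")
  write_airr(sim$clones[0, ], p0)
  expect_equal(nrow(read_airr(p0)), 0)
  # custom column mapping round-trips
  mp <- airr_default_mapping()
  mp[["cdr3_nt"]] <- "cdr3_sequence"
  p1 <- file.path(d, "mapped.tsv")
  write_airr(sim$clones[1:5, ], p1, mapping = mp)
  expect_true("cdr3_sequence" %in% names(readr::read_tsv(p1, col_types = readr::cols())))
  expect_equal(read_airr(p1, mapping = mp)$cdr3_nt, sim$clones$cdr3_nt[1:5])
})

test_that("emitted reads demultiplex according to the recorded ground truth", {
  cfg <- sim_config(n_individuals = 2, n_clonotypes = 120, seed = 31,
                    read_error_rate = 0)
  sim <- simulate_repertoires(cfg)
  d <- withr::local_tempdir()
  rd <- emit_reads(sim, d)
  expect_true(all(file.exists(rd$files$r1)))
  # error-free reads recover the true isotype perfectly
  for (i in seq_len(nrow(rd$files))) {
    lab <- classify_isotype(read_fastq(rd$files$r1[i]), cfg$primers)
    truth <- rd$reads[rd$reads$sample_id == rd$files$sample_id[i], ]
    expect_equal(unname(lab), truth$true_isotype)
  }
  # with heavy errors, classification still matches the per-read expectation
  cfg_e <- sim_config(n_individuals = 2, n_clonotypes = 120, seed = 31,
                      read_error_rate = 0.15)
  rd_e <- emit_reads(simulate_repertoires(cfg_e), withr::local_tempdir())
  f1 <- rd_e$files$r1[1]
  lab_e <- suppressWarnings(classify_isotype(read_fastq(f1), cfg_e$primers))
  truth_e <- rd_e$reads[rd_e$reads$sample_id == rd_e$files$sample_id[1], ]
  expect_equal(unname(lab_e), truth_e$expected)
  expect_true(any(truth_e$expected == "unassigned"))
})
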