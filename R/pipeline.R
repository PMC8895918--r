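#' Configuration of a full repertoire-similarity run
#'
#' Bundles the inputs, thresholds and toggles of [run_pipeline()]. Inputs
#' are either a directory of AIRR rearrangement TSVs (one per sample), a
#' character vector of file paths, or an in-memory clone table.
#'
#' @param input Directory, file paths, or clone table (data frame).
#' @param out_dir Output directory for the report bundle.
#' @param mapping AIRR column mapping, see [airr_default_mapping()].
#' @param analyses Which stages to run; any subset of `"diversity"`,
#'   `"rarefaction"`, `"lineage"`, `"sharing"`, `"cross_lineage"`.
#' @param threshold_pct Lineage identity threshold (default 95).
#' @param min_nodes Minimum lineage size within a sample (default 2).
#' @param min_nodes_cross Minimum cross-individual lineage size (default 3;
#'   5 reproduces the large-lineage variant).
#' @param degree_cap Degrees pooled from this value up (default 8).
#' @param increment_pct,reps,extrap_factor Rarefaction parameters, see
#'   [rarefaction_curve()].
#' @param rarefaction_method `"bootstrap"` or `"analytic"`.
#' @param collapse_replicates Keep only the larger technical replicate when
#'   several samples share one `(mouse_id, tissue)` (default TRUE).
#' @param seed Integer seed for all stochastic stages.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input, out_dir,
                       mapping = airr_default_mapping(),
                       analyses = c("diversity", "rarefaction", "lineage",
                                    "sharing", "cross_lineage"),
                       threshold_pct = 95, min_nodes = 2L,
                       min_nodes_cross = 3L, degree_cap = 8L,
                       increment_pct = 1, reps = 100, extrap_factor = 5,
                       rarefaction_method = c("bootstrap", "analytic"),
                       collapse_replicates = TRUE, seed = 1L) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  rarefaction_method <- match.arg(rarefaction_method)
  if (threshold_pct <= 0 || threshold_pct > 100) {
    abort("`threshold_pct` must be in (0, 100]")
  }
  if (min_nodes < 2 || min_nodes_cross < 2) {
    abort("minimum lineage sizes must be >= 2")
  }
  structure(
    list(input = input, out_dir = out_dir, mapping = mapping,
         analyses = analyses, threshold_pct = threshold_pct,
         min_nodes = as.integer(min_nodes),
         min_nodes_cross = as.integer(min_nodes_cross),
         degree_cap = as.integer(degree_cap),
         increment_pct = increment_pct, reps = reps,
         extrap_factor = extrap_factor,
         rarefaction_method = rarefaction_method,
         collapse_replicates = collapse_replicates,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

load_pipeline_input <- function(cfg) {
  inp <- cfg$input
  if (is.data.frame(inp)) return(tibble::as_tibble(inp))
  if (is.character(inp) && length(inp) == 1 && dir.exists(inp)) {
    inp <- list.files(inp, pattern = "\\.tsv$", full.names = TRUE)
  }
  if (!is.character(inp) || length(inp) == 0) {
    abort("no input: supply a clone table, a directory of AIRR TSVs, or file paths")
  }
  dplyr::bind_rows(lapply(sort(inp), read_airr, mapping = cfg$mapping))
}

# Keep one technical replicate per (mouse_id, tissue): the one with more
# clones.
collapse_replicates <- function(clones) {
  if (!all(c("mouse_id", "tissue") %in% names(clones))) return(clones)
  keys <- paste(clones$mouse_id, clones$tissue)
  keep <- unlist(lapply(split(clones$sample_id, keys), function(sids) {
    u <- unique(sids)
    if (length(u) == 1) return(u)
    tabs <- lapply(u, function(s) clones[clones$sample_id == s, ])
    names(tabs) <- u
    attr(select_technical_duplicate(tabs, "clones"), "selected")
  }))
  clones[clones$sample_id %in% keep, ]
}

#' Run the full repertoire similarity pipeline
#'
#' Executes qualified-clone filtering, technical-replicate selection, and
#' the enabled analysis stages over every sample x isotype subset, writing
#' the report bundle to the configured output directory:
#'
#' * `subset_summary.tsv` — clones, clonotypes, Chao1 richness, coverage,
#'   evenness, mutated-clonotype ratio and maximal network degree per
#'   subset;
#' * `gene_usage.tsv`, `pearson_<isotype>.tsv` — pooled V/D/J usage and
#'   pairwise Pearson matrices;
#' * `mhsi_<isotype>.tsv` — pairwise Morisita-Horn matrices of CDR3 aa
#'   profiles;
#' * `rarefaction.tsv` — long-format accumulation curves;
#' * `nn_distribution.tsv`, `degree_distribution.tsv` — nearest-neighbor
#'   similarity histogram and lineage-network degree distributions;
#' * `sharing.tsv` — shared-clonotype occupancy per strain x tissue x
#'   isotype;
#' * `cross_lineage_occupancy_<strain>_<isotype>.tsv`,
#'   `lineage_mhsi_<strain>_<isotype>.tsv`, `lineage_sizes.tsv` —
#'   cross-individual lineage results;
#' * `manifest.json` — version, seed and parameter echo; identical inputs
#'   and seed reproduce identical outputs.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the computed tables (`summary`,
#'   `gene_usage`, `pearson`, `mhsi`, `rarefaction`, `nn`, `degree`,
#'   `sharing`, `cross`, `manifest`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  clones <- load_pipeline_input(cfg)
  clones <- filter_qualified(clones)
  if (!"isotype" %in% names(clones)) clones$isotype <- "all"
  if (!"sample_id" %in% names(clones)) {
    abort("input has no sample_id column (check the column mapping)")
  }
  if (cfg$collapse_replicates) clones <- collapse_replicates(clones)
  drop_counts <- attr(clones, "drop_counts")

  subset_key <- paste(clones$sample_id, clones$isotype, sep = "::")
  subsets <- split(clones, subset_key)
  subsets <- subsets[order(names(subsets))]
  out <- list()
  written <- character()
  emit <- function(tab, name) {
    p <- file.path(cfg$out_dir, name)
    readr::write_tsv(tab, p, progress = FALSE)
    written <<- c(written, name)
  }
  emit_matrix <- function(m, name) {
    tab <- tibble::as_tibble(m, rownames = "sample")
    emit(tab, name)
  }

  # --- per-subset summary, lineage stats -----------------------------------
  nets <- list()
  summary_rows <- lapply(names(subsets), function(k) {
    tab <- subsets[[k]]
    prof <- clonotype_profile(tab, level = "aa")
    row <- tibble::tibble(
      sample_id = tab$sample_id[1], isotype = tab$isotype[1],
      n_clones = sum(tab$count), n_clonotypes_aa = length(prof),
      s_chao = chao1(prof), coverage_pct = coverage_pct(prof),
      nsde = if (length(prof) > 1) nsde(prof) else 0
    )
    if ("lineage" %in% cfg$analyses) {
      net <- build_lineages(tab, threshold_pct = cfg$threshold_pct,
                            min_nodes = cfg$min_nodes)
      nets[[k]] <<- net
      ds <- degree_stats(net, cap = cfg$degree_cap)
      row$mutated_ratio_pct <- mutated_ratio(net)
      row$max_degree <- ds$max_degree
    }
    row
  })
  summary_tab <- dplyr::bind_rows(summary_rows)
  out$summary <- summary_tab
  emit(summary_tab, "subset_summary.tsv")

  # --- diversity: gene usage, pearson, MHSI --------------------------------
  if ("diversity" %in% cfg$analyses) {
    gu <- lapply(subsets, gene_usage)
    gu_tab <- dplyr::bind_rows(lapply(names(gu), function(k) {
      dplyr::mutate(gu[[k]], sample_id = subsets[[k]]$sample_id[1],
                    isotype = subsets[[k]]$isotype[1])
    }))
    out$gene_usage <- gu_tab
    emit(gu_tab, "gene_usage.tsv")

    out$pearson <- list()
    out$mhsi <- list()
    for (iso in unique(clones$isotype)) {
      ks <- names(subsets)[vapply(subsets, function(s) s$isotype[1] == iso,
                                  logical(1))]
      if (length(ks) < 2) next
      sids <- vapply(ks, function(k) subsets[[k]]$sample_id[1], character(1))
      profs <- lapply(ks, function(k) clonotype_profile(subsets[[k]], "aa"))
      n <- length(ks)
      pm <- matrix(1, n, n, dimnames = list(sids, sids))
      mm <- matrix(1, n, n, dimnames = list(sids, sids))
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          pm[i, j] <- pm[j, i] <- gene_usage_correlation(gu[[ks[i]]],
                                                         gu[[ks[j]]])
          mm[i, j] <- mm[j, i] <- mhsi(profs[[i]], profs[[j]])
        }
      }
      out$pearson[[iso]] <- pm
      out$mhsi[[iso]] <- mm
      emit_matrix(pm, sprintf("pearson_%s.tsv", iso))
      emit_matrix(mm, sprintf("mhsi_%s.tsv", iso))
    }
  }

  # --- rarefaction ---------------------------------------------------------
  if ("rarefaction" %in% cfg$analyses) {
    rc_tab <- dplyr::bind_rows(lapply(seq_along(subsets), function(i) {
      tab <- subsets[[i]]
      prof <- clonotype_profile(tab, level = "aa")
      if (sum(prof) < 100 / cfg$increment_pct) return(NULL)
      rc <- rarefaction_curve(prof, increment_pct = cfg$increment_pct,
                              reps = cfg$reps,
                              extrap_factor = cfg$extrap_factor,
                              seed = cfg$seed + i,
                              method = cfg$rarefaction_method)
      dplyr::mutate(rc$curve, sample_id = tab$sample_id[1],
                    isotype = tab$isotype[1])
    }))
    out$rarefaction <- rc_tab
    emit(rc_tab, "rarefaction.tsv")
  }

  # --- lineage: NN distribution, degree distributions ----------------------
  if ("lineage" %in% cfg$analyses) {
    nn_tab <- dplyr::bind_rows(lapply(names(subsets), function(k) {
      dplyr::mutate(nn_distribution(subsets[[k]]),
                    sample_id = subsets[[k]]$sample_id[1],
                    isotype = subsets[[k]]$isotype[1])
    }))
    out$nn <- nn_tab
    emit(nn_tab, "nn_distribution.tsv")

    deg_tab <- dplyr::bind_rows(lapply(names(subsets), function(k) {
      ds <- degree_stats(nets[[k]], cap = cfg$degree_cap)
      if (nrow(ds$degree_dist) == 0) return(NULL)
      dplyr::mutate(ds$degree_dist, sample_id = subsets[[k]]$sample_id[1],
                    isotype = subsets[[k]]$isotype[1])
    }))
    out$degree <- deg_tab
    emit(deg_tab, "degree_distribution.tsv")
  }

  # --- sharing across individuals ------------------------------------------
  if ("sharing" %in% cfg$analyses &&
      all(c("strain", "tissue", "mouse_id") %in% names(clones))) {
    grp_key <- paste(clones$strain, clones$tissue, clones$isotype, sep = "::")
    share_tab <- dplyr::bind_rows(lapply(split(clones, grp_key), function(g) {
      by_mouse <- split(g, g$mouse_id)
      if (length(by_mouse) < 2) return(NULL)
      dplyr::mutate(sharing_ratios(by_mouse, level = "aa"),
                    strain = g$strain[1], tissue = g$tissue[1],
                    isotype = g$isotype[1])
    }))
    out$sharing <- share_tab
    emit(share_tab, "sharing.tsv")
  }

  # --- cross-individual lineages -------------------------------------------
  if ("cross_lineage" %in% cfg$analyses &&
      all(c("strain", "tissue", "mouse_id") %in% names(clones))) {
    out$cross <- list()
    size_tabs <- list()
    for (key in sort(unique(paste(clones$strain, clones$isotype, sep = "::")))) {
      parts <- strsplit(key, "::", fixed = TRUE)[[1]]
      g <- clones[clones$strain == parts[1] & clones$isotype == parts[2], ]
      if (length(unique(g$sample_id)) < 2) next
      cl <- build_cross_lineages(g, threshold_pct = cfg$threshold_pct,
                                 min_nodes = cfg$min_nodes_cross)
      out$cross[[key]] <- cl
      if (nrow(cl$lineages) == 0) next
      occ <- lineage_occupancy(cl)
      occ_tab <- tibble::as_tibble(occ, rownames = "n_blood") |>
        tidyr::pivot_longer(-"n_blood", names_to = "n_spleen",
                            values_to = "pct")
      emit(occ_tab, sprintf("cross_lineage_occupancy_%s_%s.tsv",
                            parts[1], parts[2]))
      sids <- cl$presence$sample_id |> unique() |> sort()
      if (length(sids) >= 2) {
        lm <- matrix(1, length(sids), length(sids),
                     dimnames = list(sids, sids))
        for (i in seq_len(length(sids) - 1)) {
          for (j in (i + 1):length(sids)) {
            lm[i, j] <- lm[j, i] <-
              lineage_abundance_mhsi(cl, sids[i], sids[j])
          }
        }
        emit_matrix(lm, sprintf("lineage_mhsi_%s_%s.tsv",
                                parts[1], parts[2]))
      }
      cl2 <- build_cross_lineages(g, threshold_pct = cfg$threshold_pct,
                                  min_nodes = 2L)
      size_tabs[[key]] <- dplyr::mutate(node_size_distribution(cl2),
                                        strain = parts[1],
                                        isotype = parts[2])
    }
    if (length(size_tabs) > 0) {
      emit(dplyr::bind_rows(size_tabs), "lineage_sizes.tsv")
    }
  }

  # --- manifest ------------------------------------------------------------
  manifest <- list(
    package = "ighrep",
    version = as.character(utils::packageVersion("ighrep")),
    seed = cfg$seed,
    parameters = cfg[c("analyses", "threshold_pct", "min_nodes",
                       "min_nodes_cross", "degree_cap", "increment_pct",
                       "reps", "extrap_factor", "rarefaction_method",
                       "collapse_replicates")],
    input = list(n_clones = sum(clones$count), n_records = nrow(clones),
                 n_subsets = length(subsets),
                 dropped = as.list(drop_counts)),
    outputs = sort(unique(written))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out$manifest <- manifest
  invisible(out)
}
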