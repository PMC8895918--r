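#' Configuration for the synthetic repertoire generator
#'
#' Describes the statistical structure of a simulated IgH repertoire study:
#' several individuals of one inbred strain, blood and spleen samples,
#' IgA/IgG/IgM subsets, skewed clonal abundance, planted somatic-mutation
#' lineages whose members stay within 5% CDR3 nucleotide divergence of their
#' ancestor against a background kept below 95% pairwise identity within each
#' V/J/length group, a configurable fraction of public clonotypes shared
#' across individuals, and blood/spleen overlap within an individual.
#'
#' @param n_individuals Number of mice (default 5).
#' @param strain Strain label (`"BAL"` or `"C57"`).
#' @param tissues Tissues sampled per individual.
#' @param isotype_mix Named proportions of clonotypes per isotype
#'   (normalized internally). The default puts most mass on IgM, little on
#'   IgG, as observed in baseline mouse libraries.
#' @param n_clonotypes Clonotypes per individual per tissue (split across
#'   isotypes by `isotype_mix`).
#' @param v_genes,d_genes,j_genes Germline gene-name pools.
#' @param gene_concentration Dirichlet concentration for gene-usage
#'   probabilities (smaller = more skewed usage); usage is drawn once per
#'   simulation and shared by all individuals, as inbred mice share germline
#'   usage.
#' @param d_empty_weight Relative weight of clones whose CDR3 shows no D
#'   segment.
#' @param cdr3_aa_len Integer range `c(min, max)` of CDR3 amino-acid
#'   lengths.
#' @param cdr3_len_mode Modal CDR3 amino-acid length (triangular length
#'   distribution).
#' @param abundance Clonal abundance law: `list(law = "lognormal", meanlog,
#'   sdlog)` or `list(law = "powerlaw", exponent)`.
#' @param lineage_fraction Fraction of each individual's clonotypes planted
#'   inside somatic-mutation lineages.
#' @param lineage_size_p Geometric parameter of lineage sizes:
#'   `P(size = 2) = lineage_size_p`, larger lineages decaying geometrically
#'   (capped at `max_lineage_size`). The default 0.7 makes ~70% of lineages
#'   two-node.
#' @param max_lineage_size Cap on planted lineage size.
#' @param public_fraction Fraction of each individual's clonotypes drawn
#'   from a pool shared across individuals.
#' @param public_pool_factor Shared-pool size as a multiple of each
#'   individual's public draw; values above 1 make pool membership partial,
#'   so occupancy across `m` individuals is approximately binomial with
#'   success probability `1 / public_pool_factor`.
#' @param tissue_overlap Fraction of an individual's per-tissue clonotypes
#'   present in both blood and spleen.
#' @param primers [primer_set] whose primers tag the emitted reads.
#' @param read_error_rate Per-base substitution rate injected into emitted
#'   reads (applied in the primer window and payload alike).
#' @param overhang_len Length of random synthesis overhang prepended before
#'   the primer on read 1 (0 = primer starts the read).
#' @param read_len Emitted read length.
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 5L,
                       strain = c("BAL", "C57"),
                       tissues = c("blood", "spleen"),
                       isotype_mix = c(IgA = 0.35, IgG = 0.05, IgM = 0.60),
                       n_clonotypes = 1000L,
                       v_genes = sprintf("IGHV1-%d", 1:20),
                       d_genes = sprintf("IGHD%d-%d", rep(1:2, each = 5), 1:5),
                       j_genes = sprintf("IGHJ%d", 1:4),
                       gene_concentration = 0.5,
                       d_empty_weight = 1,
                       cdr3_aa_len = c(8L, 19L),
                       cdr3_len_mode = 12L,
                       abundance = list(law = "lognormal", meanlog = 1,
                                        sdlog = 1.5),
                       lineage_fraction = 0.2,
                       lineage_size_p = 0.7,
                       max_lineage_size = 8L,
                       public_fraction = 0.1,
                       public_pool_factor = 2,
                       tissue_overlap = 0.3,
                       primers = primers_inhouse(),
                       read_error_rate = 0,
                       overhang_len = 0L,
                       read_len = 150L,
                       seed = 1L) {
  strain <- match.arg(strain)
  fracs <- c(lineage_fraction = lineage_fraction,
             public_fraction = public_fraction,
             tissue_overlap = tissue_overlap,
             read_error_rate = read_error_rate)
  if (any(fracs < 0 | fracs > 1)) {
    abort("lineage/public/overlap fractions and error rate must lie in [0, 1]")
  }
  if (any(isotype_mix < 0) || sum(isotype_mix) <= 0) {
    abort("`isotype_mix` must be nonnegative with positive total")
  }
  isotype_mix <- isotype_mix / sum(isotype_mix)
  cdr3_aa_len <- as.integer(cdr3_aa_len)
  if (length(cdr3_aa_len) != 2 || cdr3_aa_len[1] < 4 ||
      cdr3_aa_len[2] < cdr3_aa_len[1]) {
    abort("`cdr3_aa_len` must be c(min, max) with min >= 4")
  }
  if (lineage_fraction > 0 && floor(0.05 * 3 * cdr3_aa_len[1]) < 1) {
    abort(paste0(
      "infeasible config: lineage members must fit >= 1 mutation within ",
      "5% of the CDR3 nt length; raise cdr3_aa_len[1] to at least 7"))
  }
  if (!abundance$law %in% c("lognormal", "powerlaw")) {
    abort("`abundance$law` must be 'lognormal' or 'powerlaw'")
  }
  if (lineage_size_p <= 0 || lineage_size_p > 1) {
    abort("`lineage_size_p` must be in (0, 1]")
  }
  if (public_pool_factor < 1) abort("`public_pool_factor` must be >= 1")
  stopifnot(inherits(primers, "primer_set"))
  structure(
    list(n_individuals = as.integer(n_individuals), strain = strain,
         tissues = tissues, isotype_mix = isotype_mix,
         n_clonotypes = as.integer(n_clonotypes),
         v_genes = v_genes, d_genes = d_genes, j_genes = j_genes,
         gene_concentration = gene_concentration,
         d_empty_weight = d_empty_weight,
         cdr3_aa_len = cdr3_aa_len, cdr3_len_mode = as.integer(cdr3_len_mode),
         abundance = abundance,
         lineage_fraction = lineage_fraction,
         lineage_size_p = lineage_size_p,
         max_lineage_size = as.integer(max_lineage_size),
         public_fraction = public_fraction,
         public_pool_factor = public_pool_factor,
         tissue_overlap = tissue_overlap,
         primers = primers, read_error_rate = read_error_rate,
         overhang_len = as.integer(overhang_len),
         read_len = as.integer(read_len), seed = as.integer(seed)),
    class = "sim_config"
  )
}

# --- internal generator machinery ------------------------------------------

# Triangular-ish discrete length distribution over [min, max] peaking at mode.
length_weights <- function(lo, hi, mode) {
  lens <- lo:hi
  w <- pmin(lens - lo + 1, hi - lens + 1)
  w <- w * ifelse(lens <= mode,
                  (lens - lo + 1) / (mode - lo + 1),
                  (hi - lens + 1) / (hi - mode + 1))
  w / sum(w)
}

random_cdr3_nt <- function(n_aa) {
  paste(sample(CODONS_NO_STOP, n_aa, replace = TRUE), collapse = "")
}

draw_abundance <- function(n, law) {
  if (law$law == "lognormal") {
    pmax(1L, as.integer(round(stats::rlnorm(n, law$meanlog, law$sdlog))))
  } else {
    u <- stats::runif(n)
    pmax(1L, pmin(100000L, as.integer(floor(u^(-1 / (law$exponent - 1))))))
  }
}

# Registry of every generated CDR3 nt sequence per (V, J, length) group, used
# to rejection-check the planted separability: members of one lineage stay
# >= 95% identical to their ancestor while every other same-group pair stays
# strictly below 95%.
registry_new <- function() new.env(parent = emptyenv())

registry_can_add <- function(reg, key, seq, owner) {
  grp <- reg[[key]]
  if (is.null(grp)) return(TRUE)
  ids <- identity_pct(rep(seq, length(grp$seqs)), grp$seqs)
  if (any(ids >= 100 - IDENTITY_TOL)) return(FALSE)   # duplicate clonotype
  other <- is.na(owner) | is.na(grp$owner) | grp$owner != owner
  all(ids[other] < 95 - 1e-6)
}

registry_add <- function(reg, key, seq, owner) {
  grp <- reg[[key]]
  if (is.null(grp)) grp <- list(seqs = character(), owner = character())
  grp$seqs <- c(grp$seqs, seq)
  grp$owner <- c(grp$owner, owner)
  reg[[key]] <- grp
  invisible(NULL)
}

# Draw one background clonotype (gene calls + CDR3), rejection-checked
# against the registry. Redraws genes and length if a group gets too crowded
# to place a sufficiently dissimilar sequence.
gen_background <- function(cfg, reg, gene_probs, len_probs, owner = NA_character_) {
  lens <- cfg$cdr3_aa_len[1]:cfg$cdr3_aa_len[2]
  for (outer in 1:50) {
    v <- sample(cfg$v_genes, 1, prob = gene_probs$v)
    d <- sample(c(cfg$d_genes, ""), 1, prob = gene_probs$d)
    j <- sample(cfg$j_genes, 1, prob = gene_probs$j)
    L <- sample(lens, 1, prob = len_probs)
    key <- paste(v, j, 3L * L, sep = "|")
    for (try in 1:30) {
      nt <- random_cdr3_nt(L)
      if (registry_can_add(reg, key, nt, owner)) {
        registry_add(reg, key, nt, owner)
        return(list(v_gene = v, d_gene = d, j_gene = j, cdr3_nt = nt,
                    cdr3_aa = translate_nt(nt), key = key))
      }
    }
  }
  abort("could not place a background clonotype; gene pools too small for n_clonotypes")
}

mutate_nt <- function(nt, k) {
  chars <- strsplit(nt, "")[[1]]
  pos <- sample(length(chars), k)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# Plant one lineage: an ancestor plus (size - 1) mutants, each within
# floor(0.05 * nt length) substitutions of the ancestor, all stop-free.
gen_lineage <- function(cfg, reg, gene_probs, len_probs, size, uid) {
  lens <- max(7L, cfg$cdr3_aa_len[1]):cfg$cdr3_aa_len[2]
  lp <- length_weights(lens[1], lens[length(lens)],
                       max(lens[1], min(cfg$cdr3_len_mode, lens[length(lens)])))
  for (attempt in 1:20) {
    anc <- gen_background(cfg, reg, gene_probs, lp, owner = uid)
    L_nt <- nchar(anc$cdr3_nt)
    max_mut <- floor(0.05 * L_nt)
    members <- list(anc)
    ok <- TRUE
    for (m in seq_len(size - 1)) {
      placed <- FALSE
      for (try in 1:50) {
        k <- sample.int(max_mut, 1)
        nt <- mutate_nt(anc$cdr3_nt, k)
        aa <- translate_nt(nt)
        if (grepl("\\*", aa)) next
        if (registry_can_add(reg, anc$key, nt, uid)) {
          registry_add(reg, anc$key, nt, uid)
          members[[length(members) + 1]] <- list(
            v_gene = anc$v_gene, d_gene = anc$d_gene, j_gene = anc$j_gene,
            cdr3_nt = nt, cdr3_aa = aa, key = anc$key)
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(members)
    # abandon this ancestor's partial lineage and retry in a fresh group;
    # orphaned registry entries only make later checks stricter
  }
  abort("could not plant a lineage; check lineage parameters")
}

#' Simulate a multi-individual IgH repertoire study
#'
#' Generates clone tables for every individual x tissue x isotype subset of
#' the configured study, together with the ground truth needed to verify
#' recovery: which clonotypes are public (shared across individuals), which
#' belong to which planted somatic-mutation lineage, and the gene-usage
#' probabilities used. The generator guarantees the separability the lineage
#' criteria assume: within each V/J/length group, members of one planted
#' lineage are within 5% divergence of their ancestor while all other pairs
#' are kept strictly below 95% identity by rejection sampling.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `ighrep_sim`: list with `clones` (one tibble
#'   of clone records across all samples, columns `sample_id`, `mouse_id`,
#'   `strain`, `tissue`, `batch`, `isotype`, `v_gene`, `d_gene`, `j_gene`,
#'   `cdr3_nt`, `cdr3_aa`, `count`), `truth` (tibble keyed by
#'   `(isotype, v_gene, j_gene, cdr3_nt)` with `public` flag and
#'   `lineage_uid`), and `config`.
#' @examples
#' sim <- simulate_repertoires(sim_config(n_individuals = 2,
#'                                        n_clonotypes = 60, seed = 7))
#' dplyr::count(sim$clones, sample_id, isotype)
#' @export
simulate_repertoires <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed(cfg$seed)

  gene_probs <- list(
    v = rdirichlet1(length(cfg$v_genes), cfg$gene_concentration),
    d = {
      w <- rdirichlet1(length(cfg$d_genes) + 1L, cfg$gene_concentration)
      w[length(w)] <- w[length(w)] * cfg$d_empty_weight
      w / sum(w)
    },
    j = rdirichlet1(length(cfg$j_genes), cfg$gene_concentration)
  )
  len_probs <- length_weights(cfg$cdr3_aa_len[1], cfg$cdr3_aa_len[2],
                              cfg$cdr3_len_mode)

  both_tissues <- length(cfg$tissues) > 1
  clone_rows <- list()
  truth_rows <- list()

  for (iso in names(cfg$isotype_mix)) {
    n_sub <- max(2L, round(cfg$n_clonotypes * cfg$isotype_mix[[iso]]))
    n_overlap <- if (both_tissues) round(cfg$tissue_overlap * n_sub) else 0L
    pool_n <- if (both_tissues) 2L * n_sub - n_overlap else n_sub
    reg <- registry_new()

    # shared (public) clonotype pool for this isotype
    s_pub <- round(cfg$public_fraction * pool_n)
    pool_size <- max(s_pub, round(cfg$public_pool_factor * s_pub))
    pool <- if (pool_size > 0) {
      lapply(seq_len(pool_size), function(i) {
        gen_background(cfg, reg, gene_probs, len_probs)
      })
    } else {
      list()
    }

    for (ind in seq_len(cfg$n_individuals)) {
      mouse <- sprintf("m%02d", ind)
      # planted lineages
      n_lin_target <- round(cfg$lineage_fraction * pool_n)
      units <- list()
      clonos <- list()
      lin_count <- 0L
      lin_idx <- 0L
      while (lin_count < n_lin_target) {
        size <- min(cfg$max_lineage_size,
                    2L + stats::rgeom(1, cfg$lineage_size_p))
        if (lin_count + size > n_lin_target) {
          size <- max(2L, n_lin_target - lin_count)
        }
        lin_idx <- lin_idx + 1L
        uid <- sprintf("%s_%s_L%04d", iso, mouse, lin_idx)
        members <- gen_lineage(cfg, reg, gene_probs, len_probs, size, uid)
        ids <- length(clonos) + seq_along(members)
        for (k in seq_along(members)) {
          clonos[[ids[k]]] <- c(members[[k]][c("v_gene", "d_gene", "j_gene",
                                               "cdr3_nt", "cdr3_aa")],
                                list(public = FALSE, lineage_uid = uid))
        }
        units[[length(units) + 1]] <- ids
        lin_count <- lin_count + length(members)
      }
      # public singletons
      pub_idx <- if (s_pub > 0) sample(pool_size, s_pub) else integer(0)
      for (pi in pub_idx) {
        id <- length(clonos) + 1L
        clonos[[id]] <- c(pool[[pi]][c("v_gene", "d_gene", "j_gene",
                                       "cdr3_nt", "cdr3_aa")],
                          list(public = TRUE, lineage_uid = NA_character_))
        units[[length(units) + 1]] <- id
      }
      # private singletons
      n_priv <- max(0L, pool_n - s_pub - lin_count)
      for (k in seq_len(n_priv)) {
        id <- length(clonos) + 1L
        bg <- gen_background(cfg, reg, gene_probs, len_probs)
        clonos[[id]] <- c(bg[c("v_gene", "d_gene", "j_gene",
                               "cdr3_nt", "cdr3_aa")],
                          list(public = FALSE, lineage_uid = NA_character_))
        units[[length(units) + 1]] <- id
      }

      ctab <- dplyr::bind_rows(lapply(clonos, tibble::as_tibble))
      truth_rows[[paste(iso, mouse)]] <- dplyr::mutate(
        ctab[, c("v_gene", "j_gene", "cdr3_nt", "public", "lineage_uid")],
        isotype = iso, mouse_id = mouse
      )

      # allocate whole units to blood-only / both / spleen-only bins so that
      # lineages never straddle a tissue boundary partially
      if (both_tissues) {
        budgets <- c(both = n_overlap, t1 = n_sub - n_overlap,
                     t2 = n_sub - n_overlap)
        assign_bin <- character(length(units))
        for (u in sample(seq_along(units))) {
          usz <- length(units[[u]])
          bin <- names(budgets)[which.max(budgets)]
          assign_bin[u] <- bin
          budgets[bin] <- budgets[bin] - usz
        }
        tissue_members <- list()
        tissue_members[[cfg$tissues[1]]] <-
          unlist(units[assign_bin %in% c("both", "t1")])
        tissue_members[[cfg$tissues[2]]] <-
          unlist(units[assign_bin %in% c("both", "t2")])
      } else {
        tissue_members <- stats::setNames(list(unlist(units)), cfg$tissues[1])
      }

      for (tis in cfg$tissues) {
        rows <- ctab[sort(tissue_members[[tis]]), ]
        rows$count <- draw_abundance(nrow(rows), cfg$abundance)
        rows$sample_id <- paste(cfg$strain, mouse, tis, sep = "_")
        rows$mouse_id <- mouse
        rows$strain <- cfg$strain
        rows$tissue <- tis
        rows$batch <- "sim_b1"
        rows$isotype <- iso
        clone_rows[[paste(iso, mouse, tis)]] <-
          rows[, c("sample_id", "mouse_id", "strain", "tissue", "batch",
                   "isotype", "v_gene", "d_gene", "j_gene", "cdr3_nt",
                   "cdr3_aa", "count")]
      }
    }
  }

  truth <- dplyr::bind_rows(truth_rows) |>
    dplyr::distinct(.data$isotype, .data$v_gene, .data$j_gene, .data$cdr3_nt,
                    .keep_all = TRUE)
  structure(
    list(clones = dplyr::bind_rows(clone_rows), truth = truth, config = cfg),
    class = "ighrep_sim"
  )
}

#' @export
print.ighrep_sim <- function(x, ...) {
  cat(sprintf(
    "Simulated repertoire: %d clone records, %d samples, %d individuals (%s)\n",
    nrow(x$clones), length(unique(x$clones$sample_id)),
    x$config$n_individuals, x$config$strain))
  invisible(x)
}

#' Emit primer-tagged reads for a simulated repertoire
#'
#' Writes one FASTQ pair per sample. Read 1 carries (optionally after a
#' random synthesis overhang) the clone's isotype-specific primer — with
#' degenerate positions resolved to a concrete base — followed by the CDR3
#' and random filler up to the configured read length; read 2 is the
#' reverse-complement payload. Per-base substitution errors at the
#' configured rate are injected; within the primer comparison window each
#' injected error is guaranteed to mismatch the primer, so the ground truth
#' records the exact mismatch count and whether the read is expected to
#' demultiplex (`expected` = isotype when the count is below the primer
#' set's threshold, `"unassigned"` otherwise).
#'
#' @param sim A [simulate_repertoires()] result.
#' @param dir Output directory for FASTQ files.
#' @param seed Seed for error injection (defaults to the simulation seed
#'   plus 1).
#' @return List with `files` (tibble: `sample_id`, `r1`, `r2`) and `reads`
#'   (tibble: `read_id`, `sample_id`, `true_isotype`,
#'   `injected_mismatches`, `expected`).
#' @export
emit_reads <- function(sim, dir, seed = sim$config$seed + 1L) {
  stopifnot(inherits(sim, "ighrep_sim"))
  cfg <- sim$config
  primers <- cfg$primers
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  allowed_by_primer <- lapply(primers$entries, function(p) {
    IUPAC_BASES[strsplit(p, "")[[1]]]
  })
  files <- list()
  read_truth <- list()
  for (sid in unique(sim$clones$sample_id)) {
    tab <- sim$clones[sim$clones$sample_id == sid, ]
    n <- nrow(tab)
    r1 <- character(n)
    r2 <- character(n)
    mm_inj <- integer(n)
    for (i in seq_len(n)) {
      iso <- tab$isotype[i]
      allowed <- allowed_by_primer[[iso]]
      primer <- vapply(allowed, function(b) {
        if (length(b) == 1) b else sample(b, 1)
      }, character(1))
      window <- min(primers$window_len, length(primer))
      k <- stats::rbinom(1, window, cfg$read_error_rate)
      if (k > 0) {
        pos <- sample(window, k)
        for (p in pos) {
          primer[p] <- sample(setdiff(c("A", "C", "G", "T"), allowed[[p]]), 1)
        }
      }
      mm_inj[i] <- k
      payload <- tab$cdr3_nt[i]
      over <- if (cfg$overhang_len > 0) {
        paste(sample(c("A", "C", "G", "T"), cfg$overhang_len, replace = TRUE),
              collapse = "")
      } else ""
      body <- paste0(over, paste(primer, collapse = ""), payload)
      fill <- cfg$read_len - nchar(body)
      if (fill > 0) {
        body <- paste0(body, paste(sample(c("A", "C", "G", "T"), fill,
                                          replace = TRUE), collapse = ""))
      }
      r1[i] <- substr(body, 1, cfg$read_len)
      r2[i] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(substr(body, nchar(over) + 1, nchar(body)))))
    }
    ids <- sprintf("%s_read%06d", sid, seq_len(n))
    f1 <- file.path(dir, paste0(sid, "_R1.fastq"))
    f2 <- file.path(dir, paste0(sid, "_R2.fastq"))
    write_fastq(stats::setNames(r1, ids), f1)
    write_fastq(stats::setNames(r2, ids), f2)
    files[[sid]] <- tibble::tibble(sample_id = sid, r1 = f1, r2 = f2)
    read_truth[[sid]] <- tibble::tibble(
      read_id = ids, sample_id = sid, true_isotype = tab$isotype,
      injected_mismatches = mm_inj,
      expected = ifelse(mm_inj < primers$max_mismatch, tab$isotype,
                        "unassigned")
    )
  }
  list(files = dplyr::bind_rows(files), reads = dplyr::bind_rows(read_truth))
}

#' Write a simulated study as AIRR rearrangement files
#'
#' Writes one AIRR TSV per sample (all isotypes of one individual x tissue
#' together). Reading the files back with [read_airr()] under the same
#' column mapping reproduces the clone tables exactly.
#'
#' @param sim A [simulate_repertoires()] result (or a clone table with a
#'   `sample_id` column).
#' @param dir Output directory.
#' @param mapping Column mapping, see [airr_default_mapping()].
#' @return Character vector of written paths (named by sample), invisibly.
#' @export
emit_airr <- function(sim, dir, mapping = airr_default_mapping()) {
  clones <- if (inherits(sim, "ighrep_sim")) sim$clones else sim
  stopifnot(is.data.frame(clones), "sample_id" %in% names(clones))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(split(clones, clones$sample_id), function(tab) {
    p <- file.path(dir, paste0(tab$sample_id[1], ".tsv"))
    write_airr(tab, p, mapping)
    p
  }, character(1))
  invisible(paths)
}
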