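# Shared fixture builders and independent reference implementations used as
# oracles. Everything here is deliberately naive and separate from the
# package's own code paths.

rand_nt <- function(n, len) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE), collapse = "")
  }, character(1))
}

mutate_positions <- function(seq, pos) {
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
  paste(chars, collapse = "")
}

# Minimal clone table around given CDR3 nt sequences (single V/J context).
clone_table <- function(cdr3_nt, v = "V1", j = "J1", count = 1L,
                        sample_id = "s1") {
  aa_len <- nchar(cdr3_nt) %/% 3L
  tibble::tibble(
    sample_id = sample_id, v_gene = v, d_gene = "D1", j_gene = j,
    cdr3_nt = cdr3_nt,
    cdr3_aa = vapply(aa_len, function(n) paste(rep("A", n), collapse = ""),
                     character(1)),
    count = count
  )
}

# Naive one-line Morisita-Horn on two named count vectors.
mhsi_naive <- function(a, b) {
  keys <- union(names(a), names(b))
  pa <- sapply(keys, function(k) if (k %in% names(a)) a[[k]] else 0)
  pb <- sapply(keys, function(k) if (k %in% names(b)) b[[k]] else 0)
  pa <- pa / sum(pa); pb <- pb / sum(pb)
  2 * sum(pa * pb) / (sum(pa^2) + sum(pb^2))
}

nsde_naive <- function(x) {
  p <- x / sum(x)
  -sum(p * log(p)) / log(length(x))
}

# All-pairs O(n^2) reference for lineage components: edges between
# same-(v, j, length) clonotypes at >= threshold identity, components via
# repeated label propagation (no igraph).
lineage_components_bruteforce <- function(tab, threshold = 95) {
  tab <- unique(tab[, c("v_gene", "j_gene", "cdr3_nt")])
  n <- nrow(tab)
  comp <- seq_len(n)
  for (pass in seq_len(n)) {
    changed <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (tab$v_gene[i] != tab$v_gene[j]) next
        if (tab$j_gene[i] != tab$j_gene[j]) next
        if (nchar(tab$cdr3_nt[i]) != nchar(tab$cdr3_nt[j])) next
        a <- utf8ToInt(tab$cdr3_nt[i]); b <- utf8ToInt(tab$cdr3_nt[j])
        idp <- 100 * mean(a == b)
        if (idp >= threshold - 1e-9 && comp[i] != comp[j]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  split(tab$cdr3_nt, comp)
}

# Partition comparison: same set of node groups (order-free).
same_partition <- function(groups_a, groups_b) {
  norm <- function(gs) sort(unname(vapply(gs, function(g) {
    paste(sort(g), collapse = ";")
  }, character(1))))
  identical(norm(groups_a), norm(groups_b))
}

# Adjusted Rand index between two label vectors.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  sx <- sum(choose(tab, 2))
  e <- sa * sb / choose(n, 2)
  (sx - e) / ((sa + sb) / 2 - e)
}

# Random clone subset with a mix of background sequences and planted
# near-duplicate pairs, concentrated in few V/J/length groups so the
# network has edges.
rand_lineage_subset <- function(n, seed) {
  set.seed(seed)
  vs <- c("V1", "V2"); js <- c("J1", "J2"); lens <- c(24L, 30L)
  rows <- list()
  while (length(rows) < n) {
    v <- sample(vs, 1); j <- sample(js, 1); len <- sample(lens, 1)
    base <- rand_nt(1, len)
    rows[[length(rows) + 1]] <- c(v, j, base)
    if (stats::runif(1) < 0.4 && length(rows) < n) {
      k <- sample.int(max(1L, floor(0.05 * len)), 1)
      rows[[length(rows) + 1]] <-
        c(v, j, mutate_positions(base, sample(len, k)))
    }
  }
  tab <- do.call(rbind, rows)
  clone_table(tab[, 3], v = tab[, 1], j = tab[, 2])
}
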