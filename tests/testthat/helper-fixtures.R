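# Fixture builders and independent oracles shared across test files.

# canonical record frame with sensible defaults
make_records <- function(cdr3, v = "IGHV1-2*02", j = "IGHJ4*02",
                         sample = "S1", seq_id = NULL, copy = 2L,
                         productive = TRUE, mut_count = 0L, v_len = 240L,
                         muts = NULL) {
  n <- length(cdr3)
  if (is.null(seq_id)) seq_id <- sprintf("seq%03d", seq_len(n))
  if (is.null(muts)) muts <- replicate(n, NULL)
  df <- data.frame(
    sequence_id = seq_id, sample_id = rep_len(sample, n),
    v_call = rep_len(v, n), j_call = rep_len(j, n),
    cdr3_aa = cdr3, stringsAsFactors = FALSE)
  df$v_gene <- sub("\\*.*$", "", df$v_call)
  df$j_gene <- sub("\\*.*$", "", df$j_call)
  df$cdr3_length <- nchar(df$cdr3_aa)
  df$productive <- rep_len(productive, n)
  df$copy_number <- as.integer(rep_len(copy, n))
  df$v_mutation_count <- as.integer(rep_len(mut_count, n))
  df$v_sequenced_length <- as.integer(rep_len(v_len, n))
  df$v_mutation_set <- muts
  df
}

make_meta <- function(sample_id, patient = "P1", tissue = "blood", pod = 30L,
                      rejection = "none", gate = 150L, chimerism = NA_real_) {
  n <- length(sample_id)
  data.frame(sample_id = sample_id, patient_id = rep_len(patient, n),
             tissue = rep_len(tissue, n), pod = as.integer(rep_len(pod, n)),
             rejection_status = rep_len(rejection, n),
             allograft = rep_len(tissue, n) %in% c("ileum", "colon", "duodenum"),
             parent_gate_count = as.integer(rep_len(gate, n)),
             chimerism_pct = rep_len(chimerism, n), stringsAsFactors = FALSE)
}

random_cdr3 <- function(len, n = 1L, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, len, replace = TRUE), collapse = ""), character(1))
}

# mutate `k` positions of a CDR3
mutate_cdr3 <- function(cdr3, k) {
  ch <- strsplit(cdr3, "")[[1]]
  pos <- sample(seq_along(ch), k)
  ab <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (p in pos) ch[p] <- sample(setdiff(ab, ch[p]), 1)
  paste(ch, collapse = "")
}

# independent single-linkage oracle: all-pairs identity + BFS components
oracle_partition <- function(cdr3s, threshold = 0.85) {
  n <- length(cdr3s)
  len <- nchar(cdr3s[1])
  chars <- strsplit(cdr3s, "")
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ident <- sum(chars[[i]] == chars[[j]]) / len
      adj[i, j] <- ident >= threshold - 1e-9
    }
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[u])) next
      comp[u] <- cid
      queue <- c(queue, which(adj[u, ] & is.na(comp)))
    }
  }
  comp
}

# normalize a partition (vector of labels) to canonical form for comparison
canon_partition <- function(x) match(x, unique(x))

# build a lineage members frame from genotype sets + tissue labels:
# one row per (sequence, tissue instance)
lineage_members <- function(sets, tissues_per_seq) {
  rows <- list()
  for (i in seq_along(sets)) {
    for (k in seq_along(tissues_per_seq[[i]])) {
      rows[[length(rows) + 1L]] <- data.frame(
        sequence_id = sprintf("s%02d", i),
        sample_id = sprintf("smp_%s_%d", tissues_per_seq[[i]][k], k),
        tissue = tissues_per_seq[[i]][k], stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df$v_mutation_set <- sets[match(as.integer(sub("s", "", df$sequence_id)),
                                  seq_along(sets))]
  df$v_mutation_count <- lengths(df$v_mutation_set)
  df$v_sequenced_length <- 240L
  df
}

# clumpiness over all clones of a simulated dataset for a tissue pair
sim_clumpiness_values <- function(config) {
  sim <- simulate_repertoire(config)
  a <- annotate_samples(group_clones(sim$rearrangements), sim$metadata)
  vapply(split(seq_len(nrow(a)), a$clone_id), function(i) {
    m <- a[i, , drop = FALSE]
    clumpiness(build_lineage(m), "blood", "ileum")
  }, numeric(1))
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
mwu_enumerate <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  ustat <- function(idx) {
    a <- pooled[idx]
    sum(rank(pooled)[idx]) - nx * (nx + 1) / 2
  }
  obs <- ustat(seq_len(nx))
  combos <- utils::combn(n, nx)
  us <- apply(combos, 2, ustat)
  m <- nx * (n - nx)
  dev_obs <- abs(obs - m / 2)
  mean(abs(us - m / 2) >= dev_obs - 1e-9)
}
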