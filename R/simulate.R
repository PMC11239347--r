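# Deterministic synthetic repertoire generator.
#
# Emulates the post-alignment, clonally-annotatable input the analysis
# consumes: clonal lineages grown as a branching process over nested
# V-mutation sets, per-tissue sampling with a tunable mixing parameter,
# geometric copy numbers, power-law clone sizes, time-bracketed samples
# and logistic chimerism trajectories. Everything is a function of the
# seed.

.sim_v_pool <- c("IGHV1-2*02", "IGHV1-69*01", "IGHV3-23*01", "IGHV3-30*03",
                 "IGHV4-34*02", "IGHV4-59*01", "IGHV5-51*01", "IGHV6-1*01")
.sim_j_pool <- c("IGHJ1*01", "IGHJ2*01", "IGHJ3*02", "IGHJ4*02", "IGHJ5*02",
                 "IGHJ6*02")
.sim_aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.sim_bases <- c("A", "C", "G", "T")
.sim_v_len <- 240L  # post-trim V length (nt), from the start of CDR1

#' Default post-operative sampling schedule
#'
#' One pre-transplant blood draw (POD 0) and three blood + ileum sampling
#' days per time bracket (early 1-90, mid 91-365, late > 365), all
#' quiescent, each with a parent-gate count of 150 events.
#'
#' @return data.frame with `pod`, `tissue`, `rejection_status`,
#'   `parent_gate_count`.
#' @export
default_pod_schedule <- function() {
  pods <- c(30L, 60L, 80L, 120L, 200L, 320L, 420L, 600L, 850L)
  rbind(
    data.frame(pod = 0L, tissue = "blood", rejection_status = "none",
               parent_gate_count = 150L, stringsAsFactors = FALSE),
    data.frame(pod = rep(pods, each = 2L),
               tissue = rep(c("blood", "ileum"), length(pods)),
               rejection_status = "none", parent_gate_count = 150L,
               stringsAsFactors = FALSE))
}

#' Simulation configuration
#'
#' Validated parameter bundle for [simulate_repertoire()] and
#' [simulate_chimerism()].
#'
#' @param seed integer RNG seed; fully determines the output.
#' @param n_patients number of patients, default 5.
#' @param n_clones clones per patient, default 200.
#' @param clone_size_exponent skew of the clone-size distribution
#'   (Pareto-tail dial; 0 gives near-equal sizes, larger values a heavier
#'   tail and hence lower evenness), default 0.7.
#' @param shm_rate expected new V mutations per branching step (Poisson,
#'   plus one guaranteed), default 2.
#' @param branching_depth maximum genotype depth below germline, default 4.
#' @param tissue_mix mixing fraction `pi` in `[0, 1]`: the probability a
#'   unique sequence is sampled in both tissues. At 0 every clone splits
#'   into tissue-pure founder clades (clumpiness 0); at 1 every unique
#'   sequence carries both labels (clumpiness 1).
#' @param copy_number_mean mean of the (shifted-geometric) per-instance
#'   copy number, default 2 — so about half of instances reach the
#'   copy-number-2 detectability bar.
#' @param pod_schedule sampling schedule, see [default_pod_schedule()].
#' @param growth_bias probability a clone grows between consecutive
#'   brackets, default 0.5 (no drift).
#' @param chimerism_curve list with `midpoint` (day), `steepness` (1/day),
#'   `asymptote` (percent) and `noise` (bounded additive, percent).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_patients = 5L, n_clones = 200L,
                       clone_size_exponent = 0.7, shm_rate = 2,
                       branching_depth = 4L, tissue_mix = 0.5,
                       copy_number_mean = 2, pod_schedule = default_pod_schedule(),
                       growth_bias = 0.5,
                       chimerism_curve = list(midpoint = 60, steepness = 0.05,
                                              asymptote = 95, noise = 3)) {
  stopifnot(length(seed) == 1L, is.finite(seed),
            n_patients >= 1L, n_clones >= 1L,
            clone_size_exponent >= 0, shm_rate >= 0, branching_depth >= 1L,
            tissue_mix >= 0, tissue_mix <= 1,
            copy_number_mean >= 1,
            growth_bias >= 0, growth_bias <= 1,
            all(c("pod", "tissue", "rejection_status", "parent_gate_count")
                %in% names(pod_schedule)),
            all(pod_schedule$pod >= 0),
            chimerism_curve$asymptote >= 0, chimerism_curve$asymptote <= 100,
            chimerism_curve$noise >= 0)
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 n_clones = as.integer(n_clones),
                 clone_size_exponent = clone_size_exponent,
                 shm_rate = shm_rate, branching_depth = as.integer(branching_depth),
                 tissue_mix = tissue_mix, copy_number_mean = copy_number_mean,
                 pod_schedule = pod_schedule, growth_bias = growth_bias,
                 chimerism_curve = chimerism_curve),
            class = "sim_config")
}

.logistic_pct <- function(pod, curve, falling = FALSE) {
  s <- curve$steepness * (pod - curve$midpoint)
  if (falling) s <- -s
  curve$asymptote / (1 + exp(-s))
}

# one clone's genotype forest: nested mutation sets, clade of origin
.grow_genotypes <- function(n_gen, shm_rate, depth_cap) {
  pool <- sample(80:319)  # V positions, unique per clone
  ptr <- 0L
  sets <- vector("list", n_gen)
  parent <- integer(n_gen)
  depth <- integer(n_gen)
  clade <- integer(n_gen)
  n_clades <- 0L
  for (i in seq_len(n_gen)) {
    parent[i] <- if (i <= 2L) 0L else {
      cand <- which(depth[seq_len(i - 1L)] < depth_cap)
      if (length(cand)) cand[sample.int(length(cand), 1L)] else 0L
    }
    n_new <- min(1L + rpois(1L, shm_rate), length(pool) - ptr)
    pos <- pool[ptr + seq_len(n_new)]
    ptr <- ptr + n_new
    fromto <- vapply(pos, function(p) {
      bt <- sample(.sim_bases, 2L)
      sprintf("%d%s>%s", p, bt[1], bt[2])
    }, character(1))
    if (parent[i] == 0L) {
      sets[[i]] <- sort(fromto)
      depth[i] <- 1L
      n_clades <- n_clades + 1L
      clade[i] <- n_clades
    } else {
      sets[[i]] <- sort(c(sets[[parent[i]]], fromto))
      depth[i] <- depth[parent[i]] + 1L
      clade[i] <- clade[parent[i]]
    }
  }
  list(sets = sets, clade = clade)
}

#' Simulate an annotated rearrangement table with metadata
#'
#' Generates, per patient, `n_clones` clonal lineages: a germline founder
#' with toy V/J genes and a random CDR3 (14-20 aa), evolved by a branching
#' process that accumulates distinct V mutations (one guaranteed plus
#' Poisson(`shm_rate`) per step) into nested mutation sets. Founder clades
#' alternate between blood and ileum; each unique sequence is sampled in
#' both tissues with probability `tissue_mix` and otherwise only in its
#' clade's tissue. Per tissue, clone sizes start from a Pareto-skewed base
#' in the early bracket (where every eligible genotype is sampled at least
#' once) and then grow or shrink between brackets with probability
#' `growth_bias`; instances are distinct (sequence, sample) pairs with
#' shifted-geometric copy numbers. Sample metadata carries logistic
#' chimerism percentages (declining donor fraction in blood, rising
#' recipient fraction in the graft).
#'
#' @param config a [sim_config()].
#' @return list with `rearrangements` (canonical record frame, as returned
#'   by [read_rearrangements()]) and `metadata` (frame accepted by
#'   [read_metadata()]).
#' @export
simulate_repertoire <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sched <- config$pod_schedule
  sched$bracket <- assign_bracket(sched$pod)
  meta_list <- list()
  rec_list <- list()

  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%02d", p)
    smp <- sched
    smp$sample_id <- sprintf("%s_%s_d%04d", pid, smp$tissue, smp$pod)
    smp$patient_id <- pid
    smp$allograft <- smp$tissue %in% c("ileum", "colon", "duodenum")
    noise <- runif(nrow(smp), -config$chimerism_curve$noise,
                   config$chimerism_curve$noise)
    base <- ifelse(smp$tissue == "blood",
                   .logistic_pct(smp$pod, config$chimerism_curve, falling = TRUE),
                   .logistic_pct(smp$pod, config$chimerism_curve))
    smp$chimerism_pct <- pmin(100, pmax(0, base + noise))
    meta_list[[pid]] <- smp

    samples_of <- split(smp$sample_id, paste(smp$tissue, smp$bracket))

    for (cl in seq_len(config$n_clones)) {
      v <- sample(.sim_v_pool, 1L)
      j <- sample(.sim_j_pool, 1L)
      len <- sample(14:20, 1L)
      founder <- sample(.sim_aa, len, replace = TRUE)
      n_gen <- sample(2:6, 1L)
      g <- .grow_genotypes(n_gen, config$shm_rate, config$branching_depth)
      clade_tissue <- rep(c("blood", "ileum"), length.out = max(g$clade))
      both <- runif(n_gen) < config$tissue_mix
      tissue_of <- lapply(seq_len(n_gen), function(i)
        if (both[i]) c("blood", "ileum") else clade_tissue[g$clade[i]])

      cdr3_of <- vapply(seq_len(n_gen), function(i) {
        cd <- founder
        if (runif(1) < 0.3) {
          pos <- sample.int(len, 1L)
          cd[pos] <- sample(setdiff(.sim_aa, cd[pos]), 1L)
        }
        paste(cd, collapse = "")
      }, character(1))

      inst_geno <- integer(0)
      inst_sample <- character(0)
      for (t in c("blood", "ileum")) {
        gt <- which(vapply(tissue_of, function(x) t %in% x, logical(1)))
        if (!length(gt)) next
        base_size <- length(gt) +
          min(floor(runif(1)^(-config$clone_size_exponent)) - 1,
              2L * length(gt))
        s <- base_size
        for (br in c("early", "mid", "late")) {
          ss <- samples_of[[paste(t, br)]]
          if (is.null(ss)) next
          cap <- length(gt) * length(ss)
          size <- max(1L, min(s, cap))
          if (br == "early") {
            # coverage: every eligible genotype sampled at least once
            pick_g <- c(gt, gt[sample.int(length(gt), max(0L, size - length(gt)),
                                          replace = TRUE)])[seq_len(max(size, length(gt)))]
            pick_s <- ss[sample.int(length(ss), length(pick_g), replace = TRUE)]
            pair <- paste(pick_g, pick_s)
            dup <- duplicated(pair)
            # replace duplicate pairs deterministically from unused pairs
            if (any(dup)) {
              all_pairs <- expand.grid(g = gt, s = ss, stringsAsFactors = FALSE)
              unused <- which(!paste(all_pairs$g, all_pairs$s) %in% pair[!dup])
              need <- sum(dup)
              take <- unused[seq_len(min(need, length(unused)))]
              pick_g <- c(pick_g[!dup], all_pairs$g[take])
              pick_s <- c(pick_s[!dup], all_pairs$s[take])
            }
          } else {
            all_g <- rep(gt, times = length(ss))
            all_s <- rep(ss, each = length(gt))
            take <- sample.int(length(all_g), size)
            pick_g <- all_g[take]
            pick_s <- all_s[take]
          }
          inst_geno <- c(inst_geno, pick_g)
          inst_sample <- c(inst_sample, pick_s)
          delta <- (1L + rpois(1L, 0.5)) *
            (if (runif(1) < config$growth_bias) 1L else -1L)
          s <- max(1L, size + delta)
        }
        # pre-transplant blood draw
        if (t == "blood" && !is.null(samples_of[["blood pre"]])) {
          npre <- min(length(gt), max(1L, base_size %/% 2L))
          pre_g <- gt[seq_len(npre)]
          inst_geno <- c(inst_geno, pre_g)
          inst_sample <- c(inst_sample, rep(samples_of[["blood pre"]][1], npre))
        }
      }
      if (!length(inst_geno)) next
      n_i <- length(inst_geno)
      rec_list[[length(rec_list) + 1L]] <- data.frame(
        sequence_id = sprintf("%s_c%04d_g%02d", pid, cl, inst_geno),
        sample_id = inst_sample,
        v_call = v, j_call = j,
        cdr3_aa = cdr3_of[inst_geno],
        productive = runif(n_i) < 0.97,
        copy_number = 1L + rgeom(n_i, 1 / config$copy_number_mean),
        v_mutation_count = lengths(g$sets)[inst_geno],
        v_sequenced_length = .sim_v_len,
        v_mutation_set = I(unname(g$sets[inst_geno])),
        stringsAsFactors = FALSE)
    }
  }

  rec <- as.data.frame(data.table::rbindlist(rec_list))
  rec$v_gene <- strip_allele(rec$v_call)
  rec$j_gene <- strip_allele(rec$j_call)
  rec$cdr3_length <- nchar(rec$cdr3_aa)
  rec <- rec[, c("sequence_id", "sample_id", "v_call", "j_call", "v_gene",
                 "j_gene", "cdr3_aa", "cdr3_length", "productive",
                 "copy_number", "v_mutation_count", "v_sequenced_length",
                 "v_mutation_set")]
  meta <- do.call(rbind, meta_list)
  meta <- meta[, c("sample_id", "patient_id", "tissue", "pod",
                   "rejection_status", "allograft", "parent_gate_count",
                   "chimerism_pct")]
  rownames(meta) <- rownames(rec) <- NULL
  list(rearrangements = rec, metadata = meta)
}

#' Simulate chimerism time series
#'
#' Logistic replacement trajectories sampled at the configured schedule:
#' donor B-cell chimerism in blood falls from its asymptote as recipient
#' cells return, recipient chimerism in the graft rises towards it.
#' Bounded uniform noise is added and values are clipped to `[0, 100]`.
#'
#' @param config a [sim_config()].
#' @return data.frame with `patient_id`, `compartment` (`pbmc_donor` or
#'   `graft_recipient`), `pod`, `percent`, `parent_gate_count`.
#' @export
simulate_chimerism <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sched <- config$pod_schedule
  out <- list()
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%02d", p)
    s <- sched
    s$compartment <- ifelse(s$tissue == "blood", "pbmc_donor", "graft_recipient")
    base <- ifelse(s$compartment == "pbmc_donor",
                   .logistic_pct(s$pod, config$chimerism_curve, falling = TRUE),
                   .logistic_pct(s$pod, config$chimerism_curve))
    pct <- pmin(100, pmax(0, base + runif(nrow(s), -config$chimerism_curve$noise,
                                          config$chimerism_curve$noise)))
    out[[pid]] <- data.frame(patient_id = pid, compartment = s$compartment,
                             pod = s$pod, percent = pct,
                             parent_gate_count = s$parent_gate_count,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$patient_id, res$compartment, res$pod), ]
}

#' Write a simulated dataset to disk
#'
#' Emits the rearrangement table (AIRR dialect by default) and the
#' metadata table for a configuration; the files round-trip through
#' [read_rearrangements()] and [read_metadata()].
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @param dialect rearrangement dialect to write.
#' @return named character vector of the two file paths, invisibly.
#' @export
write_simulation <- function(config, dir, dialect = "airr") {
  sim <- simulate_repertoire(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rpath <- file.path(dir, "rearrangements.tsv")
  mpath <- file.path(dir, "metadata.tsv")
  write_rearrangements(sim$rearrangements, rpath, dialect)
  m <- sim$metadata
  m$chimerism_pct <- sprintf("%.6f", m$chimerism_pct)
  data.table::fwrite(m, mpath, sep = "\t", quote = FALSE)
  invisible(c(rearrangements = rpath, metadata = mpath))
}
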