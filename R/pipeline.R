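# End-to-end report: compose clonal inference, lineages, clumpiness,
# diversity/cosine metrics and longitudinal statistics into plain TSV
# report tables, mirroring the per-figure computations of the analysis.

#' Default analysis thresholds
#'
#' The printed definitional thresholds used throughout: CDR3 identity for
#' clonal grouping (0.85), copy number for detectability (2), average
#' mutation fraction defining a mutated clone (0.02, strict), trunk rule
#' (5 mutations in 85% of unique sequences), minimum clones per slice
#' (strictly more than 5), minimum unique sequences for lineage-mixing
#' eligibility (3), minimum clones behind a clumpiness median (6, i.e.
#' strictly more than 5), and minimum parent-gate events (40).
#'
#' @return named list of thresholds.
#' @export
default_thresholds <- function() {
  list(identity = 0.85, min_copies = 2L, mutated_cutoff = 0.02,
       trunk_mutations = 5L, trunk_prop = 0.85, min_clones = 5L,
       min_unique_seqs = 3L, median_min_clones = 6L, gate_events = 40L)
}

.write_tsv <- function(d, dir, name) {
  path <- file.path(dir, name)
  data.table::fwrite(d, path, sep = "\t", quote = FALSE, na = "NA")
  path
}

# per-(patient,tissue,bracket) mutated-clone fractions; a clone's average
# mutation fraction is taken over its instances within the cell
.mutated_fraction_table <- function(assigned, cutoff, min_clones) {
  inst <- .unique_instances(assigned)
  dt <- data.table::as.data.table(inst)
  frac <- dt[, list(mut = mean(v_mutation_count / v_sequenced_length)),
             by = c("patient_id", "tissue", "bracket", "clone_id")]
  cell <- frac[, list(n_clones = .N, frac_mutated = mean(mut > cutoff)),
               by = c("patient_id", "tissue", "bracket")]
  cell <- cell[cell$n_clones > min_clones, ]
  data.table::setorder(cell, patient_id, tissue, bracket)
  as.data.frame(cell)
}

.evenness_table <- function(bracket_sizes, min_clones) {
  slices <- min_clone_filter(repertoire_slices(bracket_sizes), min_clones)
  if (!length(slices)) return(data.frame())
  keys <- do.call(rbind, strsplit(names(slices), "|", fixed = TRUE))
  out <- data.frame(patient_id = keys[, 1], tissue = keys[, 2],
                    bracket = keys[, 3],
                    richness = vapply(slices, length, integer(1)),
                    d0 = vapply(slices, hill_diversity, numeric(1), q = 0),
                    d1 = vapply(slices, hill_diversity, numeric(1), q = 1),
                    stringsAsFactors = FALSE)
  out$evenness <- out$d1 / out$richness
  rownames(out) <- NULL
  out[order(out$patient_id, out$tissue, match(out$bracket, .brackets)), ]
}

.sign_test_table <- function(bracket_sizes) {
  slices <- repertoire_slices(bracket_sizes)
  rows <- list()
  keys <- unique(sub("\\|[^|]+$", "", names(slices)))
  for (k in keys) {
    for (i in seq_len(length(.brackets) - 1L)) {
      a <- slices[[paste(k, .brackets[i], sep = "|")]]
      b <- slices[[paste(k, .brackets[i + 1L], sep = "|")]]
      if (is.null(a) || is.null(b)) next
      st <- withCallingHandlers(
        sign_test_clone_sizes(a, b),
        warning = function(w) {
          if (inherits(w, "bcrflow_no_informative_clones"))
            invokeRestart("muffleWarning")
        })
      pt <- strsplit(k, "|", fixed = TRUE)[[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pt[1], tissue = pt[2],
        bracket_from = .brackets[i], bracket_to = .brackets[i + 1L],
        n_plus = st$n_plus, n_minus = st$n_minus, p_value = st$p_value,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}

.clumpiness_tables <- function(assigned, label_pairs, th) {
  per_clone <- list()
  for (lp in label_pairs) {
    eligible <- tryCatch(
      min_unique_sequences_filter(assigned, th$min_unique_seqs, lp),
      error = function(e) assigned[0, , drop = FALSE])
    if (!nrow(eligible)) next
    for (i in split(seq_len(nrow(eligible)), eligible$clone_id)) {
      m <- eligible[i, , drop = FALSE]
      tree <- build_lineage(m, clone_id = m$clone_id[1])
      per_clone[[length(per_clone) + 1L]] <- data.frame(
        clone_id = m$clone_id[1], patient_id = m$patient_id[1],
        label_pair = tissue_pair(lp[1], lp[2]),
        n_unique_seqs = length(unique(m$sequence_id)),
        value = clumpiness(tree, lp[1], lp[2]), stringsAsFactors = FALSE)
    }
  }
  if (!length(per_clone))
    return(list(per_clone = data.frame(), medians = data.frame()))
  pc <- do.call(rbind, per_clone)
  list(per_clone = pc,
       medians = median_clumpiness(pc, th$median_min_clones))
}

.cosine_table <- function(bracket_sizes) {
  slices <- repertoire_slices(bracket_sizes)
  info <- do.call(rbind, strsplit(names(slices), "|", fixed = TRUE))
  rows <- list()
  for (pt in unique(info[, 1])) {
    for (br in unique(info[info[, 1] == pt, 3])) {
      ts <- sort(info[info[, 1] == pt & info[, 3] == br, 2])
      if (length(ts) < 2L) next
      cmb <- utils::combn(ts, 2L)
      for (cc in seq_len(ncol(cmb))) {
        a <- slices[[paste(pt, cmb[1, cc], br, sep = "|")]]
        b <- slices[[paste(pt, cmb[2, cc], br, sep = "|")]]
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = pt, bracket = br,
          tissue_a = cmb[1, cc], tissue_b = cmb[2, cc],
          cosine = cosine_similarity(a, b), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}

.chimerism_table <- function(meta, gate_events) {
  rows <- list()
  for (key in split(seq_len(nrow(meta)),
                    paste(meta$patient_id, meta$tissue, sep = "|"))) {
    s <- meta[key, , drop = FALSE]
    s <- s[!is.na(s$chimerism_pct), , drop = FALSE]
    if (nrow(s) < 2L) next
    s <- data.frame(pod = s$pod, percent = s$chimerism_pct,
                    parent_gate_count = s$parent_gate_count)
    s <- suppressWarnings(parent_gate_filter(s, gate_events))
    for (br in c("early", "mid", "late")) {
      val <- withCallingHandlers(
        chimerism_auc_normalized(s, br),
        warning = function(w) {
          if (inherits(w, "bcrflow_auc_undefined"))
            invokeRestart("muffleWarning")
        })
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = meta$patient_id[key[1]], tissue = meta$tissue[key[1]],
        bracket = br, auc_normalized = val, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, rows)
  out[order(out$patient_id, out$tissue, match(out$bracket, .brackets)), ]
}

#' Run the full repertoire report
#'
#' Reads a rearrangement table and sample metadata, restricts to quiescent
#' samples (by default), groups clones per patient, and writes one TSV per
#' analysis: mutated-clone fractions by tissue and bracket, evenness and
#' Hill diversities per repertoire slice, consecutive-bracket sign tests,
#' per-clone and per-individual-median clumpiness for each tissue pair,
#' cross-tissue cosine similarities, and normalized chimerism AUC per
#' bracket. A `manifest.json` records every threshold and the MD5 digest
#' of both inputs; reruns on identical inputs are byte-identical.
#'
#' @param rearrangements path to a rearrangement TSV.
#' @param metadata path to a metadata TSV.
#' @param out_dir output directory (created if needed).
#' @param dialect rearrangement dialect, `"airr"` or `"immunedb"`.
#' @param thresholds list from [default_thresholds()]; any element may be
#'   overridden.
#' @param quiescent_only drop samples with mild-or-greater rejection or
#'   AMR before analysis (default TRUE).
#' @param label_pairs list of length-2 tissue vectors for clumpiness.
#' @return invisibly, a named list of the written file paths.
#' @export
run_report <- function(rearrangements, metadata, out_dir, dialect = "airr",
                       thresholds = default_thresholds(),
                       quiescent_only = TRUE,
                       label_pairs = list(c("blood", "ileum"))) {
  th <- utils::modifyList(default_thresholds(), thresholds)
  stage <- "read inputs"
  result <- tryCatch({
    rec <- suppressMessages(read_rearrangements(rearrangements, dialect))
    meta <- suppressMessages(read_metadata(metadata))
    if (quiescent_only) meta <- filter_quiescent(meta)
    rec <- rec[rec$sample_id %in% meta$sample_id, , drop = FALSE]
    if (!nrow(rec)) stop("no records left after sample filtering")

    stage <- "clonal grouping"
    parts <- list()
    offset <- 0L
    idx <- match(rec$sample_id, meta$sample_id)
    for (pt in sort(unique(meta$patient_id[idx]))) {
      sub <- rec[meta$patient_id[idx] == pt, , drop = FALSE]
      g <- group_clones(sub, th$identity)
      g$clone_id <- g$clone_id + offset
      offset <- max(g$clone_id)
      parts[[pt]] <- g
    }
    assigned <- as.data.frame(data.table::rbindlist(parts))
    assigned <- annotate_samples(assigned, meta)

    stage <- "clone summaries"
    sizes <- clone_bracket_sizes(assigned, meta)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- list()
    summ <- clone_summary(assigned, th$mutated_cutoff)
    files$clones <- .write_tsv(summ, out_dir, "clones.tsv")

    stage <- "mutation profile"
    files$mutated_fraction <- .write_tsv(
      .mutated_fraction_table(assigned, th$mutated_cutoff, th$min_clones),
      out_dir, "mutated_fraction.tsv")

    stage <- "diversity"
    files$evenness <- .write_tsv(.evenness_table(sizes, th$min_clones),
                                 out_dir, "evenness.tsv")

    stage <- "sign tests"
    files$sign_test <- .write_tsv(.sign_test_table(sizes), out_dir,
                                  "sign_test.tsv")

    stage <- "clumpiness"
    cl <- .clumpiness_tables(assigned, label_pairs, th)
    files$clumpiness <- .write_tsv(cl$per_clone, out_dir, "clumpiness.tsv")
    files$clumpiness_medians <- .write_tsv(cl$medians, out_dir,
                                           "clumpiness_medians.tsv")

    stage <- "cosine similarity"
    files$cosine <- .write_tsv(.cosine_table(sizes), out_dir, "cosine.tsv")

    stage <- "chimerism AUC"
    files$chimerism_auc <- .write_tsv(
      .chimerism_table(meta, th$gate_events), out_dir, "chimerism_auc.tsv")

    stage <- "manifest"
    manifest <- list(
      thresholds = th,
      quiescent_only = quiescent_only,
      label_pairs = vapply(label_pairs, paste, character(1), collapse = "|"),
      inputs = list(
        rearrangements = unname(tools::md5sum(rearrangements)),
        metadata = unname(tools::md5sum(metadata))),
      n_records = nrow(assigned), n_samples = nrow(meta),
      n_clones = nrow(summ))
    mpath <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    files$manifest <- mpath
    files
  }, error = function(e) {
    stop("report failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

.cli_parse <- function(args) {
  opts <- list()
  pos <- character(0)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (grepl("=", key)) {
        kv <- strsplit(key, "=", fixed = TRUE)[[1]]
        opts[[kv[1]]] <- paste(kv[-1], collapse = "=")
      } else {
        opts[[key]] <- args[i + 1L]
        i <- i + 1L
      }
    } else pos <- c(pos, a)
    i <- i + 1L
  }
  list(opts = opts, pos = pos)
}

.cli_config <- function(opts) {
  num <- function(k, d) if (is.null(opts[[k]])) d else as.numeric(opts[[k]])
  sim_config(seed = num("seed", 1), n_patients = num("patients", 5),
             n_clones = num("clones", 200),
             clone_size_exponent = num("size-exponent", 0.7),
             shm_rate = num("shm-rate", 2),
             tissue_mix = num("pi", 0.5),
             growth_bias = num("growth-bias", 0.5))
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic dataset), `clones` (clone
#' summary TSV), `lineages` (Newick per eligible clone), `clumpiness`,
#' `metrics` (evenness/diversity and cosine tables), `stats` (sign tests
#' and chimerism AUC) and `report` (everything). Options are `--key value`
#' or `--key=value`; common ones are `--rearrangements`, `--metadata`,
#' `--out`, `--seed`, `--dialect`, `--threshold` (CDR3 identity) and the
#' simulation dials (`--patients`, `--clones`, `--pi`, `--growth-bias`,
#' `--size-exponent`, `--shm-rate`). Returns 0 on success; errors carry
#' the failing stage in their message.
#'
#' @param args character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return exit status 0, invisibly.
#' @export
bcr_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: bcrflow <simulate|clones|lineages|clumpiness|metrics|stats|report> [--options]")
  cmd <- args[1]
  parsed <- .cli_parse(args[-1])
  o <- parsed$opts
  out <- if (is.null(o$out)) "." else o$out
  need_inputs <- function() {
    if (is.null(o$rearrangements) || is.null(o$metadata))
      stop(cmd, ": --rearrangements and --metadata are required")
  }
  load_assigned <- function() {
    rec <- read_rearrangements(o$rearrangements,
                               if (is.null(o$dialect)) "airr" else o$dialect)
    meta <- read_metadata(o$metadata)
    meta <- filter_quiescent(meta)
    rec <- rec[rec$sample_id %in% meta$sample_id, , drop = FALSE]
    th <- if (is.null(o$threshold)) 0.85 else as.numeric(o$threshold)
    list(assigned = annotate_samples(group_clones(rec, th), meta), meta = meta)
  }
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  switch(cmd,
    simulate = {
      write_simulation(.cli_config(o), out)
    },
    clones = {
      need_inputs()
      d <- load_assigned()
      .write_tsv(clone_summary(d$assigned), out, "clones.tsv")
    },
    lineages = {
      need_inputs()
      d <- load_assigned()
      el <- min_unique_sequences_filter(d$assigned)
      nwk <- vapply(split(seq_len(nrow(el)), el$clone_id), function(i)
        lineage_newick(build_lineage(el[i, , drop = FALSE])), character(1))
      writeLines(paste0(names(nwk), "\t", nwk), file.path(out, "lineages.nwk"))
    },
    clumpiness = {
      need_inputs()
      d <- load_assigned()
      cl <- .clumpiness_tables(d$assigned, list(c("blood", "ileum")),
                               default_thresholds())
      .write_tsv(cl$per_clone, out, "clumpiness.tsv")
      .write_tsv(cl$medians, out, "clumpiness_medians.tsv")
    },
    metrics = {
      need_inputs()
      d <- load_assigned()
      sizes <- clone_bracket_sizes(d$assigned, d$meta)
      .write_tsv(.evenness_table(sizes, 5L), out, "evenness.tsv")
      .write_tsv(.cosine_table(sizes), out, "cosine.tsv")
    },
    stats = {
      need_inputs()
      d <- load_assigned()
      sizes <- clone_bracket_sizes(d$assigned, d$meta)
      .write_tsv(.sign_test_table(sizes), out, "sign_test.tsv")
      .write_tsv(.chimerism_table(d$meta, 40L), out, "chimerism_auc.tsv")
    },
    report = {
      need_inputs()
      run_report(o$rearrangements, o$metadata, out,
                 dialect = if (is.null(o$dialect)) "airr" else o$dialect)
    },
    stop("unknown subcommand: ", cmd))
  invisible(0L)
}
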