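#' Read a numeric analyte matrix from TSV
#'
#' UTF-8 tab-delimited text, first column the analyte identifier, one header
#' row. Empty fields and "NA" become absent entries; leading comment lines
#' starting with `#` are skipped. Ragged rows, duplicate identifiers and
#' non-numeric cells raise errors naming the offending line.
#'
#' @param path File path.
#' @return Numeric matrix with analyte rownames.
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  body_at <- which(!startsWith(lines, "#"))
  if (!length(body_at)) stop("no content in ", path)
  offset <- body_at[1] - 1L
  lines <- lines[body_at[1]:length(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- length(fields[[1]])
  widths <- lengths(fields)
  if (any(widths != n_col)) {
    bad <- which(widths != n_col)[1]
    stop(sprintf("ragged row at line %d of %s (%d fields, expected %d)",
                 bad + offset, path, widths[bad], n_col))
  }
  header <- fields[[1]][-1]
  ids <- vapply(fields[-1], `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop("duplicate analyte identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  cells <- do.call(rbind, lapply(fields[-1], function(f) f[-1]))
  cells[cells == "" | cells == "NA"] <- NA
  m <- suppressWarnings(matrix(as.numeric(cells), nrow(cells), ncol(cells)))
  bad <- which(is.na(m) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric cell '%s' at line %d, column '%s' of %s",
                 cells[bad[1, 1], bad[1, 2]], bad[1, 1] + 1L + offset,
                 header[bad[1, 2]], path))
  }
  dimnames(m) <- list(ids, header)
  m
}

#' Write a numeric matrix as TSV
#'
#' Full-precision, decimal-point formatting independent of the locale. An
#' optional header comment records the tool version and configuration hash.
#'
#' @param m Matrix with rownames.
#' @param path Output file.
#' @param id_name Name of the identifier column.
#' @param comment Optional character vector of comment lines (written as
#'   `# ...`).
#' @return The path, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_name = "analyte", comment = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(c(id_name, colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1, function(r) {
    paste(vapply(r, function(v) {
      if (is.na(v)) "NA" else format(v, digits = 17, scientific = FALSE,
                                     decimal.mark = ".", trim = TRUE)
    }, character(1)), collapse = "\t")
  })
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Write a replicate table as TSV with two header rows
#'
#' Row 1: treatment per column; row 2: replicate index; then one row per
#' analyte. Cell counts, if present, are written as an extra `#cell_counts`
#' comment line.
#'
#' @param table A [replicate_table()].
#' @param path Output file.
#' @param comment Optional comment lines.
#' @return The path, invisibly.
#' @export
write_replicate_table <- function(table, path, comment = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste0("#layer\t", table$layer_name, "\t",
                    "control\t", table$control_label, "\t",
                    "log2\t", as.integer(table$log2_scale)), con)
  if (!is.null(table$cell_counts)) {
    writeLines(paste(c("#cell_counts",
                       format(table$cell_counts, digits = 17, trim = TRUE)),
                     collapse = "\t"), con)
  }
  writeLines(paste(c("treatment", table$treatment), collapse = "\t"), con)
  writeLines(paste(c("replicate", table$replicate), collapse = "\t"), con)
  body <- apply(table$values, 1, function(r) {
    paste(ifelse(is.na(r), "NA",
                 format(r, digits = 17, scientific = FALSE, trim = TRUE)),
          collapse = "\t")
  })
  writeLines(paste(rownames(table$values), body, sep = "\t"), con)
  invisible(path)
}

#' Read a replicate table written by [write_replicate_table()]
#'
#' @param path File path.
#' @return A [replicate_table()].
#' @export
read_replicate_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- list(layer = "layer", control = NA, log2 = 0)
  cell_counts <- NULL
  while (startsWith(lines[1], "#")) {
    f <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (f[1] == "#layer") {
      meta <- as.list(stats::setNames(f[seq(2, length(f), 2)],
                                      sub("^#", "", f[seq(1, length(f) - 1, 2)])))
    } else if (f[1] == "#cell_counts") {
      cell_counts <- as.numeric(f[-1])
    }
    lines <- lines[-1]
  }
  trt <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
  rep_idx <- as.integer(strsplit(lines[2], "\t", fixed = TRUE)[[1]][-1])
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  writeLines(c(paste(c("analyte", paste(trt, rep_idx, sep = ".")),
                     collapse = "\t"), lines[-(1:2)]), tmp)
  m <- read_matrix_tsv(tmp)
  replicate_table(m, treatment = trt, replicate = rep_idx,
                  control_label = meta$control, layer_name = meta$layer,
                  cell_counts = cell_counts,
                  log2_scale = meta$log2 == "1")
}

#' Write a fold-change object as three aligned TSVs
#'
#' `<prefix>_log2fc.tsv`, `<prefix>_p_raw.tsv`, `<prefix>_p_adj.tsv` (plus
#' `<prefix>_n_quantified.tsv`), all with identical row/column layout.
#'
#' @param fc A `fold_change` object.
#' @param prefix Path prefix.
#' @param comment Optional comment lines.
#' @return Character vector of written paths, invisibly.
#' @export
write_fold_change <- function(fc, prefix, comment = NULL) {
  paths <- c(log2fc = paste0(prefix, "_log2fc.tsv"),
             p_raw = paste0(prefix, "_p_raw.tsv"),
             p_adj = paste0(prefix, "_p_adj.tsv"),
             n_quantified = paste0(prefix, "_n_quantified.tsv"))
  for (slot in names(paths)) {
    write_matrix_tsv(fc[[slot]], paths[[slot]], comment = comment)
  }
  invisible(paths)
}

#' Pipeline configuration
#'
#' All tunables of the end-to-end pipeline with their defaults. Unknown
#' arguments are rejected; every run writes the resolved configuration next
#' to its outputs.
#'
#' @param min_present Replicate-filter threshold.
#' @param alpha Significance level for counting/calls.
#' @param beta Soft power threshold.
#' @param min_module_size Minimum module size.
#' @param merge_cut_height Eigengene merge cut height.
#' @param gs_threshold,mm_threshold Key-driver thresholds.
#' @param network_type `"unsigned"` or `"signed"`.
#' @param cut_interpretation `"merge"` or `"static"`.
#' @param adjust_family BH family (`"layer"` or `"treatment"`).
#' @param use_adjusted Use adjusted p-values for the per-layer significance
#'   counts (the heatmap-style counts stay on raw p by default).
#' @param min_significant,overall_min_layers Activity-call rule parameters.
#' @param call_use_adjusted Use BH-adjusted p-values for the activity call
#'   (default `TRUE`: at omics scale a raw-p call is dominated by chance
#'   significances).
#' @param call_min_fraction Per-layer active threshold as a fraction of the
#'   layer's analytes (default 0.05); `NULL` falls back to `min_significant`.
#' @param network_layers Layers entering the network (`NULL` = all).
#' @param seed Integer seed.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_present = 3, alpha = 0.05, beta = 18,
                            min_module_size = 25, merge_cut_height = 0.1,
                            gs_threshold = 0.75, mm_threshold = 0.75,
                            network_type = "unsigned",
                            cut_interpretation = "merge",
                            adjust_family = "layer", use_adjusted = FALSE,
                            min_significant = 1, overall_min_layers = 2,
                            call_use_adjusted = TRUE, call_min_fraction = 0.05,
                            network_layers = NULL, seed = 1L) {
  cfg <- list(min_present = min_present, alpha = alpha, beta = beta,
              min_module_size = min_module_size,
              merge_cut_height = merge_cut_height,
              gs_threshold = gs_threshold, mm_threshold = mm_threshold,
              network_type = match.arg(network_type, c("unsigned", "signed")),
              cut_interpretation = match.arg(cut_interpretation,
                                             c("merge", "static")),
              adjust_family = match.arg(adjust_family, c("layer", "treatment")),
              use_adjusted = isTRUE(use_adjusted),
              min_significant = min_significant,
              overall_min_layers = overall_min_layers,
              call_use_adjusted = isTRUE(call_use_adjusted),
              call_min_fraction = call_min_fraction,
              network_layers = network_layers, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected with an error listing them.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

#' Run the integrative multi-omics pipeline
#'
#' Executes, in order: per-layer normalization (cell-count normalization when
#' cell counts are present, then log2 median normalization), the replicate
#' filter, fold-change statistics with BH adjustment, per-layer significance
#' counts, cross-omics symmetric scaling and treatment clustering, activity
#' calls, 0-100 integer scaling, network construction (adjacency + TOM),
#' module detection, eigengenes, module-trait correlation, gene significance
#' and module membership, key-driver selection, and driver-list export.
#' Identical inputs, config and seed give identical outputs.
#'
#' @param layers Named list of [replicate_table()] objects (raw intensities;
#'   tables already flagged `log2_scale` are used as-is).
#' @param traits Optional trait matrix (samples x traits; sample labels must
#'   match the network sample axis, i.e. the treatment names). If `NULL`,
#'   trait-dependent stages are skipped.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when given, every stage's TSV
#'   products, Newick dendrograms, the resolved configuration and a run log
#'   are written there.
#' @param verbose Log progress to standard error.
#' @return A list bundle: `fold_changes`, `counts`, `integrated`,
#'   `treatment_clustering`, `activity`, `scaled`, `network`, `partition`,
#'   `eigengenes`, `module_count`, `trait_correlation`, `gs`, `mm`,
#'   `key_drivers`, `driver_lists`, `config`.
#' @export
run_pipeline <- function(layers, traits = NULL, config = pipeline_config(),
                         out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  t0 <- proc.time()[["elapsed"]]
  run_log <- character(0)
  note <- function(stage, ...) {
    line <- sprintf("%-12s %6.1fs  %s", stage,
                    proc.time()[["elapsed"]] - t0, paste0(...))
    run_log <<- c(run_log, line)
    log_msg(line, verbose = verbose)
  }
  cfg_hash <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg_path <- file.path(out_dir, "config.yaml")
    yaml::write_yaml(unclass(config), cfg_path)
    cfg_hash <- unname(tools::md5sum(cfg_path))
  }
  hdr <- paste0("nmomics ", as.character(utils::packageVersion("nmomics")),
                if (!is.null(cfg_hash)) paste0("; config_hash=", cfg_hash))

  # --- preprocess -----------------------------------------------------------
  fcs <- list()
  counts <- list()
  for (l in names(layers)) {
    tab <- layers[[l]]
    if (!isTRUE(tab$log2_scale)) {
      if (!is.null(tab$cell_counts)) tab <- normalize_cell_count(tab)
      tab <- normalize_log2_median(tab)
    }
    keep <- replicate_filter(tab, min_present = config$min_present)
    note("preprocess", sprintf("layer %s: %d/%d analytes pass the %d-replicate filter",
                               l, length(keep), nrow(tab$values), config$min_present))
    tab <- subset_analytes(tab, keep)
    fcs[[l]] <- fold_change_test(tab, adjust_family = config$adjust_family)
    counts[[l]] <- count_significant(fcs[[l]], alpha = config$alpha,
                                     use_adjusted = config$use_adjusted)
  }

  # --- integration clustering + activity calls ------------------------------
  integrated <- scale_to_symmetric_range(fcs)
  trt_clust <- hierarchical_cluster(integrated, axis = "columns")
  activity <- call_activity(fcs, alpha = config$alpha,
                            min_significant = config$min_significant,
                            min_fraction = config$call_min_fraction,
                            use_adjusted = config$call_use_adjusted,
                            overall_min_layers = config$overall_min_layers)
  note("cluster", sprintf("treatment order: %s",
                          paste(trt_clust$order, collapse = " ")))
  note("activity", sprintf("%d active / %d equivocal / %d passive",
                           sum(activity$overall == "active"),
                           sum(activity$overall == "equivocal"),
                           sum(activity$overall == "passive")))

  # --- network --------------------------------------------------------------
  net_layers <- config$network_layers %||% names(fcs)
  scaled <- scale_to_int_range(fcs[net_layers])
  network <- adjacency_network(scaled, beta = config$beta,
                               network_type = config$network_type)
  network <- tom_similarity(network)
  partition <- detect_modules(network, scaled,
                              min_module_size = config$min_module_size,
                              merge_cut_height = config$merge_cut_height,
                              cut_interpretation = config$cut_interpretation)
  n_mod <- length(setdiff(unique(partition$module_of), GREY_LABEL))
  note("network", sprintf("%d analytes, %d modules (%d incl. grey)",
                          nrow(scaled$values), n_mod,
                          n_mod + any(partition$module_of == GREY_LABEL)))
  eigengenes <- NULL
  if (n_mod > 0) eigengenes <- module_eigengenes(scaled, partition)

  # --- traits ---------------------------------------------------------------
  trait_cor <- gs <- mm <- key_drivers <- driver_lists <- NULL
  if (!is.null(traits) && !is.null(eigengenes)) {
    trait_cor <- module_trait_correlation(eigengenes, traits)
    gs <- gene_significance(scaled, traits)
    mm <- module_membership(scaled, eigengenes)
    key_drivers <- select_key_drivers(
      gs, mm, partition, trait_cor,
      gs_threshold = config$gs_threshold,
      mm_threshold = config$mm_threshold)
    driver_lists <- export_driver_lists(key_drivers,
                                        traits = colnames(as.matrix(traits)))
    note("drivers", sprintf("%d key-driver rows over %d traits",
                            nrow(key_drivers), ncol(as.matrix(traits))))
  }

  bundle <- list(fold_changes = fcs, counts = counts, integrated = integrated,
                 treatment_clustering = trt_clust, activity = activity,
                 scaled = scaled, network = network, partition = partition,
                 eigengenes = eigengenes,
                 module_count = c(modules = n_mod,
                                  incl_grey = n_mod + as.integer(
                                    any(partition$module_of == GREY_LABEL))),
                 trait_correlation = trait_cor, gs = gs, mm = mm,
                 key_drivers = key_drivers, driver_lists = driver_lists,
                 config = config)
  if (!is.null(out_dir)) {
    write_bundle(bundle, out_dir, hdr)
    writeLines(run_log, file.path(out_dir, "run_log.txt"))
  }
  bundle
}

write_bundle <- function(bundle, out_dir, hdr) {
  for (l in names(bundle$fold_changes)) {
    write_fold_change(bundle$fold_changes[[l]],
                      file.path(out_dir, paste0("fc_", l)), comment = hdr)
    utils::write.table(bundle$counts[[l]],
                       file.path(out_dir, paste0("counts_", l, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_matrix_tsv(bundle$integrated$values,
                   file.path(out_dir, "integrated_scaled.tsv"), comment = hdr)
  write_dendrogram_newick(bundle$treatment_clustering,
                          file.path(out_dir, "treatment_dendrogram.nwk"))
  act <- data.frame(treatment = names(bundle$activity$overall),
                    bundle$activity$per_layer,
                    overall = bundle$activity$overall, row.names = NULL,
                    check.names = FALSE)
  utils::write.table(act, file.path(out_dir, "activity_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(bundle$scaled$values,
                   file.path(out_dir, "wgcna_input_scaled.tsv"), comment = hdr)
  part <- cbind(analyte = names(bundle$partition$module_of),
                module = unname(bundle$partition$module_of))
  utils::write.table(part, file.path(out_dir, "module_partition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_dendrogram_newick(bundle$partition$dendrogram,
                          file.path(out_dir, "analyte_dendrogram.nwk"))
  if (!is.null(bundle$eigengenes)) {
    write_matrix_tsv(bundle$eigengenes$values,
                     file.path(out_dir, "module_eigengenes.tsv"),
                     id_name = "module", comment = hdr)
  }
  if (!is.null(bundle$trait_correlation)) {
    for (slot in c("r", "p", "stars")) {
      m <- bundle$trait_correlation[[slot]]
      if (slot == "stars") {
        utils::write.table(cbind(module = rownames(m), m),
                           file.path(out_dir, "module_trait_stars.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
      } else {
        write_matrix_tsv(m, file.path(out_dir, paste0("module_trait_", slot, ".tsv")),
                         id_name = "module", comment = hdr)
      }
    }
    write_matrix_tsv(bundle$gs, file.path(out_dir, "gene_significance.tsv"),
                     comment = hdr)
    write_matrix_tsv(bundle$mm, file.path(out_dir, "module_membership.tsv"),
                     comment = hdr)
    utils::write.table(bundle$key_drivers,
                       file.path(out_dir, "key_drivers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    export_driver_lists(bundle$key_drivers,
                        dir = file.path(out_dir, "driver_lists"),
                        traits = names(bundle$driver_lists))
  }
}

#' Score recovery of a planted module partition
#'
#' Compares a detected partition (and optionally its eigengenes) to the
#' generator's ground truth: adjusted Rand index over all network analytes
#' (grey/background as its own class) and, for each planted module, the best
#' absolute correlation between its latent eigengene profile and a detected
#' eigengene (greedy one-to-one matching, largest correlations first).
#'
#' @param truth Ground-truth list from [generate_dataset()].
#' @param partition A `module_partition`.
#' @param eigengenes Optional `eigengene_matrix` (treatment-level samples).
#' @return List with `ari`, `matched_cor` (per planted module), and
#'   `mean_matched_cor`.
#' @export
evaluate_recovery <- function(truth, partition, eigengenes = NULL) {
  ids <- names(truth$module_of)
  det <- partition$module_of[ids]
  det[is.na(det)] <- GREY_LABEL
  ari <- mclust::adjustedRandIndex(truth$module_of, det)
  matched <- NULL
  if (!is.null(eigengenes) && nrow(truth$eigengene_profiles) > 0) {
    E <- truth$eigengene_profiles
    M <- eigengenes$values[, colnames(E), drop = FALSE]
    r <- abs(stats::cor(t(E), t(M)))
    matched <- stats::setNames(rep(NA_real_, nrow(E)), rownames(E))
    r_work <- r
    for (step in seq_len(min(nrow(r), ncol(r)))) {
      idx <- which(r_work == max(r_work), arr.ind = TRUE)[1, ]
      matched[rownames(r)[idx[1]]] <- r_work[idx[1], idx[2]]
      r_work[idx[1], ] <- -Inf
      r_work[, idx[2]] <- -Inf
    }
  }
  list(ari = ari, matched_cor = matched,
       mean_matched_cor = if (is.null(matched)) NA_real_ else
         mean(matched, na.rm = TRUE))
}

#' Score key-driver recovery against planted drivers
#'
#' @param truth Ground truth from [generate_dataset()] (with `driver_flags`).
#' @param key_drivers A `key_driver_table`.
#' @param traits Traits to score (default: all columns of `driver_flags`).
#' @return List with `recall`, `precision`, `n_true`, `n_selected`.
#' @export
evaluate_drivers <- function(truth, key_drivers, traits = NULL) {
  flags <- truth$driver_flags
  if (is.null(flags)) stop("ground truth has no driver flags")
  if (is.null(traits)) traits <- colnames(flags)
  true_set <- unlist(lapply(traits, function(tr) {
    paste(rownames(flags)[flags[, tr]], tr)
  }))
  sel <- key_drivers[key_drivers$trait %in% traits, , drop = FALSE]
  sel_set <- paste(sel$analyte, sel$trait)
  tp <- length(intersect(sel_set, true_set))
  list(recall = if (length(true_set)) tp / length(true_set) else NA_real_,
       precision = if (length(sel_set)) tp / length(sel_set) else NA_real_,
       n_true = length(true_set), n_selected = length(sel_set))
}

#' Write a generated dataset to a directory
#'
#' Writes each layer as a two-header-row replicate TSV, the trait matrix
#' (with a trait-kind header row), and the ground truth as separate TSVs.
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (l in names(dataset$layers)) {
    write_replicate_table(dataset$layers[[l]],
                          file.path(dir, paste0("intensities_", l, ".tsv")))
  }
  if (!is.null(dataset$traits)) {
    tm <- dataset$traits
    con <- file(file.path(dir, "traits.tsv"), "w", encoding = "UTF-8")
    kind <- attr(tm, "kind")
    if (!is.null(kind)) {
      writeLines(paste(c("#kind", unname(kind[colnames(tm)])), collapse = "\t"), con)
    }
    writeLines(paste(c("sample", colnames(tm)), collapse = "\t"), con)
    writeLines(paste(rownames(tm),
                     apply(tm, 1, function(r) paste(format(r, digits = 17, trim = TRUE),
                                                    collapse = "\t")),
                     sep = "\t"), con)
    close(con)
  }
  truth <- dataset$truth
  utils::write.table(
    data.frame(analyte = names(truth$module_of),
               module = unname(truth$module_of),
               loading = unname(truth$loadings[names(truth$module_of)])),
    file.path(dir, "truth_modules.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(truth$eigengene_profiles,
                   file.path(dir, "truth_eigengenes.tsv"), id_name = "module")
  if (!is.null(truth$driver_flags)) {
    write_matrix_tsv(truth$driver_flags * 1,
                     file.path(dir, "truth_driver_flags.tsv"))
  }
  invisible(dir)
}

#' Read a trait matrix written by [write_dataset()]
#'
#' @param path File path.
#' @return A [trait_matrix()].
#' @export
read_trait_matrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  kind <- NULL
  if (startsWith(lines[1], "#kind")) {
    kind <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
    lines <- lines[-1]
  }
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  m <- read_matrix_tsv(tmp)
  if (!is.null(kind)) names(kind) <- colnames(m)
  trait_matrix(m, kind = kind)
}
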