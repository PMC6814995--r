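#' Top-3 peptide protein quantification
#'
#' Summarizes a peptide x sample intensity matrix to protein level: the
#' protein intensity in a sample is the mean of its three highest-intensity
#' peptides in that sample (all peptides if fewer than three are present).
#' A protein with no quantified peptide in a sample gets an absent entry.
#'
#' @param peptides Numeric matrix, peptides x samples, NA allowed.
#' @param protein_of Character vector mapping each peptide row to a protein.
#' @param treatment,replicate,control_label Sample annotation passed to
#'   [replicate_table()].
#' @param layer_name Layer name of the result.
#' @param min_peptides Minimum identified peptides per protein (proteins with
#'   fewer are dropped, mirroring a two-peptide identification rule).
#' @return A [replicate_table()] of protein intensities.
#' @export
protein_quant_top3 <- function(peptides, protein_of, treatment, replicate,
                               control_label, layer_name = "proteomics",
                               min_peptides = 2L) {
  peptides <- as.matrix(peptides)
  stopifnot(length(protein_of) == nrow(peptides))
  keep <- names(which(table(protein_of) >= min_peptides))
  prot <- sort(keep)
  out <- matrix(NA_real_, length(prot), ncol(peptides),
                dimnames = list(prot, colnames(peptides)))
  for (p in prot) {
    sub <- peptides[protein_of == p, , drop = FALSE]
    out[p, ] <- apply(sub, 2, function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) return(NA_real_)
      mean(sort(v, decreasing = TRUE)[seq_len(min(3, length(v)))])
    })
  }
  replicate_table(out, treatment, replicate, control_label,
                  layer_name = layer_name)
}

#' Log2 transform and median-normalize a replicate table
#'
#' Each present value becomes `log2(value) - median(log2 values of its
#' column)`, so every sample column has median zero afterwards.
#'
#' @param table A [replicate_table()] of positive raw intensities.
#' @return The table on the log2 scale, median-normalized per column.
#' @export
normalize_log2_median <- function(table) {
  stopifnot(inherits(table, "replicate_table"))
  v <- table$values
  bad <- which(!is.na(v) & v <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-positive intensity at analyte '%s', sample '%s'",
                 rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]]))
  }
  lv <- log2(v)
  med <- apply(lv, 2, stats::median, na.rm = TRUE)
  table$values <- sweep(lv, 2, med, `-`)
  table$log2_scale <- TRUE
  table
}

#' Normalize metabolite concentrations to cell numbers
#'
#' Divides each value by its sample's cell count expressed in units of
#' `reference` cells; values below the analyte's limit of detection are set
#' absent beforehand (below-LOD measurements are not taken into account).
#'
#' @param table A [replicate_table()] with `cell_counts` set.
#' @param reference Reference cell number (values are reported per this many
#'   cells).
#' @return The normalized table (cell counts cleared).
#' @export
normalize_cell_count <- function(table, reference = 1e6) {
  stopifnot(inherits(table, "replicate_table"))
  if (is.null(table$cell_counts)) {
    stop("cell counts are required for cell-number normalization")
  }
  v <- table$values
  if (!is.null(table$lod)) {
    below <- !is.na(v) & v < table$lod
    v[below] <- NA
  }
  table$values <- sweep(v, 2, table$cell_counts / reference, `/`)
  table$cell_counts <- NULL
  table
}

#' Replicate-presence filter
#'
#' Retains an analyte only if it was quantified in at least `min_present`
#' replicates in every treatment (including the control) of every table.
#'
#' @param tables A [replicate_table()] or list of tables sharing analytes.
#' @param min_present Minimum present replicate values per treatment.
#' @return Character vector of retained analyte identifiers.
#' @export
replicate_filter <- function(tables, min_present = 3L) {
  if (inherits(tables, "replicate_table")) tables <- list(tables)
  keep <- NULL
  for (tab in tables) {
    ok <- rep(TRUE, nrow(tab$values))
    for (tr in treatments_of(tab)) {
      cnt <- rowSums(!is.na(tab$values[, treatment_cols(tab, tr), drop = FALSE]))
      ok <- ok & cnt >= min_present
    }
    ids <- rownames(tab$values)[ok]
    keep <- if (is.null(keep)) ids else intersect(keep, ids)
  }
  keep
}

#' Fold changes and Student's t-tests against the control
#'
#' For each analyte and treatment: log2 fold change = mean of the treatment's
#' log2 replicate values minus the mean of the control's; the p-value is a
#' two-sided two-sample Student's t-test (equal variance by default) of
#' treatment vs control replicates. P-values are Benjamini-Hochberg adjusted
#' over the chosen family.
#'
#' @param table A [replicate_table()] on the log2 scale (apply
#'   [normalize_log2_median()] or set `log2_scale` first).
#' @param var_equal Equal-variance (pooled) t-test; set `FALSE` for Welch.
#' @param adjust_family `"layer"` adjusts over all analyte x treatment tests
#'   of the table jointly (default); `"treatment"` adjusts within treatment.
#' @return An object of class `fold_change` with matrices `log2fc`, `p_raw`,
#'   `p_adj`, `n_quantified` (analytes x treatments) and `layer_name`.
#' @export
fold_change_test <- function(table, var_equal = TRUE,
                             adjust_family = c("layer", "treatment")) {
  stopifnot(inherits(table, "replicate_table"))
  adjust_family <- match.arg(adjust_family)
  if (!isTRUE(table$log2_scale)) {
    stop("fold_change_test expects log2-scale values; normalize first")
  }
  trts <- setdiff(treatments_of(table), table$control_label)
  ids <- rownames(table$values)
  ctl <- table$values[, treatment_cols(table, table$control_label), drop = FALSE]
  dims <- list(ids, trts)
  log2fc <- p_raw <- matrix(NA_real_, length(ids), length(trts), dimnames = dims)
  n_quant <- matrix(0L, length(ids), length(trts), dimnames = dims)
  for (tr in trts) {
    x <- table$values[, treatment_cols(table, tr), drop = FALSE]
    n_x <- rowSums(!is.na(x))
    n_c <- rowSums(!is.na(ctl))
    n_quant[, tr] <- n_x
    fc <- rowMeans(x, na.rm = TRUE) - rowMeans(ctl, na.rm = TRUE)
    fc[n_x < 1 | n_c < 1] <- NA
    log2fc[, tr] <- fc
    testable <- which(n_x >= 2 & n_c >= 2)
    p_raw[testable, tr] <- vapply(testable, function(i) {
      xi <- x[i, !is.na(x[i, ])]
      ci <- ctl[i, !is.na(ctl[i, ])]
      if (stats::sd(xi) == 0 && stats::sd(ci) == 0) {
        return(if (mean(xi) == mean(ci)) 1 else 0)
      }
      tryCatch(stats::t.test(xi, ci, var.equal = var_equal)$p.value,
               error = function(e) NA_real_)
    }, numeric(1))
  }
  p_adj <- matrix(NA_real_, length(ids), length(trts), dimnames = dims)
  if (adjust_family == "layer") {
    p_adj[] <- bh_adjust(as.vector(p_raw))
  } else {
    for (tr in trts) p_adj[, tr] <- bh_adjust(p_raw[, tr])
  }
  structure(list(log2fc = log2fc, p_raw = p_raw, p_adj = p_adj,
                 n_quantified = n_quant, layer_name = table$layer_name),
            class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  cat(sprintf("fold_change '%s': %d analytes x %d treatments\n",
              x$layer_name, nrow(x$log2fc), ncol(x$log2fc)))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment: p-values are multiplied
#' by m/rank, made monotone from the largest rank down, and capped at 1.
#' NA entries are passed through (and do not count toward m).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Count significantly altered analytes per treatment
#'
#' @param fc A `fold_change` object.
#' @param alpha Significance level.
#' @param use_adjusted Count on BH-adjusted p-values instead of raw.
#' @return A data.frame with one row per treatment: `treatment`, `up`,
#'   `down`, `total`.
#' @export
count_significant <- function(fc, alpha = 0.05, use_adjusted = FALSE) {
  stopifnot(inherits(fc, "fold_change"))
  p <- if (use_adjusted) fc$p_adj else fc$p_raw
  sig <- !is.na(p) & p <= alpha
  up <- colSums(sig & fc$log2fc > 0, na.rm = TRUE)
  down <- colSums(sig & fc$log2fc < 0, na.rm = TRUE)
  data.frame(treatment = colnames(p), up = as.integer(up),
             down = as.integer(down), total = as.integer(up + down),
             row.names = NULL)
}

# Subset a replicate table to a set of analytes (order preserved).
subset_analytes <- function(table, ids) {
  table$values <- table$values[intersect(rownames(table$values), ids), ,
                               drop = FALSE]
  table
}
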