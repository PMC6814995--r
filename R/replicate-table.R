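#' Construct a per-replicate intensity table
#'
#' The basic container for one omics layer: an analyte x sample matrix of
#' non-negative intensities (or concentrations), where samples are organized
#' as treatment x replicate. Entries may be `NA` (not quantified). Metabolite
#' layers may carry per-sample cell counts (for cell-number normalization)
#' and per-analyte limits of detection.
#'
#' @param values Numeric matrix, analytes in rows (rownames required), samples
#'   in columns.
#' @param treatment Character/factor of length `ncol(values)`: treatment label
#'   of each column.
#' @param replicate Integer vector of length `ncol(values)`: replicate index
#'   within treatment.
#' @param control_label Treatment label of the untreated control.
#' @param layer_name Name of the omics layer (e.g. `"proteomics"`).
#' @param cell_counts Optional numeric vector of per-column cell counts.
#' @param lod Optional numeric vector of per-analyte limits of detection
#'   (named by analyte or in row order).
#' @param log2_scale Logical; `TRUE` once values are on the log2 scale.
#' @return An object of class `replicate_table`.
#' @export
replicate_table <- function(values, treatment, replicate, control_label,
                            layer_name = "layer", cell_counts = NULL,
                            lod = NULL, log2_scale = FALSE) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    stop("`values` must have analyte rownames")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate analyte identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  }
  treatment <- as.character(treatment)
  replicate <- as.integer(replicate)
  if (length(treatment) != ncol(values) || length(replicate) != ncol(values)) {
    stop("`treatment` and `replicate` must have one entry per column")
  }
  if (!control_label %in% treatment) {
    stop("control label '", control_label, "' not among treatments")
  }
  # unbalanced designs are allowed (e.g. three to five replicates per
  # treatment), but replicate indices must be unique within a treatment
  if (anyDuplicated(paste(treatment, replicate))) {
    stop("duplicate (treatment, replicate) column")
  }
  if (!is.null(cell_counts)) {
    if (length(cell_counts) != ncol(values)) {
      stop("`cell_counts` must have one entry per column")
    }
    if (any(is.na(cell_counts) | cell_counts <= 0)) {
      stop("cell counts must be positive and non-missing")
    }
  }
  if (!is.null(lod)) {
    if (is.null(names(lod))) names(lod) <- rownames(values)
    lod <- lod[rownames(values)]
  }
  colnames(values) <- paste(treatment, replicate, sep = ".")
  structure(
    list(values = values, treatment = treatment, replicate = replicate,
         control_label = control_label, layer_name = layer_name,
         cell_counts = cell_counts, lod = lod,
         log2_scale = isTRUE(log2_scale)),
    class = "replicate_table"
  )
}

#' @export
print.replicate_table <- function(x, ...) {
  cat(sprintf(
    "replicate_table '%s': %d analytes x %d samples (%d treatments x %d replicates)\n",
    x$layer_name, nrow(x$values), ncol(x$values),
    length(unique(x$treatment)), max(x$replicate)))
  cat(sprintf("  control: %s | log2 scale: %s | missing: %.1f%%\n",
              x$control_label, x$log2_scale,
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.replicate_table <- function(x) dim(x$values)

treatments_of <- function(x) unique(x$treatment)

# columns belonging to one treatment
treatment_cols <- function(x, treatment) which(x$treatment == treatment)
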