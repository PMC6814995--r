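#' Scale fold-change layers to a shared symmetric range
#'
#' Per layer, linearly maps the layer's global minimum to `lo` and maximum to
#' `hi` (no rounding) and stacks the layers over the shared treatment axis —
#' the pre-scaling used before joint cross-omics clustering so that no layer
#' dominates the distance. A constant layer maps to 0.
#'
#' @param fc_list A `fold_change` object, named list of them, or matrices.
#' @param lo,hi Target endpoints (defaults -2 and 2).
#' @return Object of class `integrated_matrix`: `values` (stacked analytes x
#'   treatments) and `layer_of`.
#' @export
scale_to_symmetric_range <- function(fc_list, lo = -2, hi = 2) {
  mats <- fc_as_matrix_list(fc_list)
  if (!length(mats)) stop("at least one layer is required")
  cols <- lapply(mats, colnames)
  for (i in seq_along(cols)) {
    if (!identical(cols[[i]], cols[[1]])) {
      stop("treatments differ across layers: '", names(mats)[i],
           "' has {", paste(cols[[i]], collapse = ", "), "} vs {",
           paste(cols[[1]], collapse = ", "), "}")
    }
  }
  out <- list()
  layer_of <- character(0)
  for (l in names(mats)) {
    m <- mats[[l]]
    rng <- range(m, na.rm = TRUE)
    s <- if (rng[1] == rng[2]) m * 0 else
      lo + (m - rng[1]) / (rng[2] - rng[1]) * (hi - lo)
    out[[l]] <- s
    layer_of <- c(layer_of, stats::setNames(rep(l, nrow(m)), rownames(m)))
  }
  structure(list(values = do.call(rbind, out), layer_of = layer_of),
            class = "integrated_matrix")
}

#' Hierarchical clustering of treatments or analytes
#'
#' Agglomerative clustering with Euclidean distance and complete linkage (the
#' defaults). Absent values enter the distance pairwise-complete with
#' rescaling by the shared-coordinate fraction (the behavior of
#' [stats::dist()]).
#'
#' @param m An `integrated_matrix`, `scaled_matrix` or plain matrix.
#' @param axis `"columns"` (treatments; default) or `"rows"` (analytes).
#' @param metric Distance measure passed to [stats::dist()].
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return List with `tree` (an `hclust`), `order` (leaf labels in dendrogram
#'   order), `axis`.
#' @export
hierarchical_cluster <- function(m, axis = c("columns", "rows"),
                                 metric = "euclidean", linkage = "complete") {
  axis <- match.arg(axis)
  v <- if (is.list(m) && !is.null(m$values)) m$values else as.matrix(m)
  if (axis == "columns") v <- t(v)
  if (nrow(v) < 2) stop("need at least 2 items on the clustered axis")
  if (anyNA(v)) {
    log_msg("distance computed pairwise-complete with shared-coordinate rescaling")
  }
  d <- stats::dist(v, method = metric)
  tree <- stats::hclust(d, method = linkage)
  list(tree = tree, order = tree$labels[tree$order], axis = axis)
}

#' Write a dendrogram in Newick form
#'
#' @param cl Result of [hierarchical_cluster()] (or an `hclust`).
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_dendrogram_newick <- function(cl, path) {
  tree <- if (inherits(cl, "hclust")) cl else cl$tree
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Rule-based active/passive/equivocal categorization
#'
#' Per layer, a treatment is called `active` iff at least `min_significant`
#' analytes are significantly altered (p <= `alpha`), else `passive`. The
#' overall call is `active` if the treatment is active in >= 2 layers,
#' `equivocal` if active in exactly 1, and `passive` otherwise. This
#' configurable rule formalizes what is usually a narrative judgement; the
#' rule actually applied is recorded in the result.
#'
#' @param fc_list Named list of `fold_change` objects (one per layer).
#' @param alpha Per-analyte significance level.
#' @param min_significant Minimum significant analytes for a per-layer
#'   `active` call.
#' @param min_fraction If non-`NULL`, overrides `min_significant` per layer
#'   with `max(1, ceiling(min_fraction * analytes in the layer))` — the
#'   threshold that keeps the call meaningful when thousands of analytes are
#'   tested.
#' @param use_adjusted Use BH-adjusted instead of raw p-values.
#' @param overall_min_layers Layers required for an overall `active` call.
#' @return Object of class `activity_call`: `per_layer` (treatment x layer
#'   character matrix), `overall` (named vector), `evidence` (treatment x
#'   layer significant counts), `rule`.
#' @export
call_activity <- function(fc_list, alpha = 0.05, min_significant = 1,
                          min_fraction = NULL, use_adjusted = FALSE,
                          overall_min_layers = 2) {
  if (inherits(fc_list, "fold_change")) {
    fc_list <- stats::setNames(list(fc_list), fc_list$layer_name)
  }
  trts <- colnames(fc_list[[1]]$log2fc)
  evidence <- matrix(0L, length(trts), length(fc_list),
                     dimnames = list(trts, names(fc_list)))
  thresh <- stats::setNames(rep(min_significant, length(fc_list)), names(fc_list))
  for (l in names(fc_list)) {
    cnt <- count_significant(fc_list[[l]], alpha = alpha,
                             use_adjusted = use_adjusted)
    evidence[cnt$treatment, l] <- cnt$total
    if (!is.null(min_fraction)) {
      thresh[l] <- max(1, ceiling(min_fraction * nrow(fc_list[[l]]$log2fc)))
    }
  }
  per_layer <- ifelse(sweep(evidence, 2, thresh, `>=`), "active", "passive")
  n_active <- rowSums(per_layer == "active")
  overall <- ifelse(n_active >= overall_min_layers, "active",
                    ifelse(n_active == 1, "equivocal", "passive"))
  names(overall) <- trts
  structure(list(per_layer = per_layer, overall = overall,
                 evidence = evidence,
                 rule = list(alpha = alpha, min_significant = thresh,
                             min_fraction = min_fraction,
                             use_adjusted = use_adjusted,
                             overall_min_layers = overall_min_layers,
                             note = paste("overall rule is a formalized",
                                          "interpretation of narrative calls"))),
            class = "activity_call")
}

#' @export
print.activity_call <- function(x, ...) {
  cat("activity_call (alpha =", x$rule$alpha, "):\n")
  print(data.frame(x$per_layer, overall = x$overall))
  invisible(x)
}
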