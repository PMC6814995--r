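#' Scale fold changes to integers between 0 and 100
#'
#' Per layer, linearly maps the layer's global minimum to `lo` and maximum to
#' `hi` and rounds half-away-from-zero to integers — the conventional
#' pre-scaling of pooled fold-change matrices before network construction.
#' A constant layer maps to the midpoint.
#'
#' @param fc A `fold_change` object, a named list of them, or a plain numeric
#'   matrix (single layer).
#' @param lo,hi Target range endpoints.
#' @return An object of class `scaled_matrix`: integer matrix `values`
#'   (analytes x samples) and `layer_of` (analyte -> layer).
#' @export
scale_to_int_range <- function(fc, lo = 0, hi = 100) {
  mats <- fc_as_matrix_list(fc)
  out <- list()
  layer_of <- character(0)
  for (l in names(mats)) {
    m <- mats[[l]]
    if (length(m) == 0) stop("layer '", l, "' is empty")
    rng <- range(m, na.rm = TRUE)
    if (!all(is.finite(rng))) stop("layer '", l, "' has no finite values")
    s <- if (rng[1] == rng[2]) {
      m * 0 + (lo + hi) / 2
    } else {
      lo + (m - rng[1]) / (rng[2] - rng[1]) * (hi - lo)
    }
    out[[l]] <- round_half_away(s)
    layer_of <- c(layer_of, stats::setNames(rep(l, nrow(m)), rownames(m)))
  }
  values <- do.call(rbind, out)
  structure(list(values = values, layer_of = layer_of),
            class = "scaled_matrix")
}

# Coerce fold_change / list / matrix inputs to a named list of log2fc matrices.
fc_as_matrix_list <- function(fc) {
  if (inherits(fc, "fold_change")) fc <- stats::setNames(list(fc), fc$layer_name)
  if (is.matrix(fc)) fc <- list(layer = fc)
  lapply(fc, function(x) if (inherits(x, "fold_change")) x$log2fc else as.matrix(x))
}

#' Soft-threshold adjacency of a co-expression network
#'
#' Computes the analyte x analyte adjacency `|cor|^beta` (unsigned, the
#' default) or `((1 + cor)/2)^beta` (signed) from Pearson correlations over
#' pairwise-complete samples. Pairs with fewer than 3 shared samples get
#' correlation 0; the diagonal is 1.
#'
#' @param x A `scaled_matrix` (or numeric matrix, analytes x samples).
#' @param beta Soft power threshold (default 18).
#' @param network_type `"unsigned"` or `"signed"`.
#' @return An object of class `coexpression_network` with `adjacency`,
#'   `beta`, `network_type` (the TOM slot is filled by [tom_similarity()]).
#' @export
adjacency_network <- function(x, beta = 18, network_type = c("unsigned", "signed")) {
  network_type <- match.arg(network_type)
  v <- if (inherits(x, "scaled_matrix")) x$values else as.matrix(x)
  if (ncol(v) < 3) stop("at least 3 samples are required")
  if (beta <= 0) stop("beta must be positive")
  r <- row_cor(v, min_overlap = 3L, fallback = 0)
  n_zv <- sum(is.na(r[upper.tri(r)]))
  if (n_zv > 0) {
    log_msg(sprintf("adjacency: %d analyte pairs with undefined correlation set to 0", n_zv))
    r[is.na(r)] <- 0
  }
  a <- if (network_type == "unsigned") abs(r)^beta else ((1 + r) / 2)^beta
  diag(a) <- 1
  dimnames(a) <- list(rownames(v), rownames(v))
  structure(list(adjacency = a, tom = NULL, beta = beta,
                 network_type = network_type),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression_network: %d analytes, %s, beta = %g, TOM %s\n",
              nrow(x$adjacency), x$network_type, x$beta,
              if (is.null(x$tom)) "not computed" else "computed"))
  invisible(x)
}

#' Scale-free topology fit
#'
#' Diagnostic for the soft-power choice: the connectivity
#' `k_i = sum_{j != i} a_ij` is binned, and `log10(frequency)` is regressed on
#' `log10(mean k per bin)`. Returns the fit R-squared and the slope.
#'
#' @param network A `coexpression_network`, or a numeric vector of
#'   connectivities `k` (for direct diagnostics).
#' @param n_bins Number of equal-width connectivity bins.
#' @return List with `r_squared`, `slope`, `k` (NA R-squared if all
#'   connectivities are equal).
#' @export
scale_free_fit <- function(network, n_bins = 10) {
  k <- if (inherits(network, "coexpression_network")) {
    if (nrow(network$adjacency) < 2) stop("need at least 2 analytes")
    rowSums(network$adjacency) - diag(network$adjacency)
  } else {
    as.numeric(network)
  }
  if (length(k) < 2) stop("need at least 2 connectivity values")
  if (diff(range(k)) == 0) {
    return(list(r_squared = NA_real_, slope = NA_real_, k = k))
  }
  bins <- cut(k, breaks = n_bins, include.lowest = TRUE)
  freq <- tapply(k, bins, length)
  kmean <- tapply(k, bins, mean)
  ok <- !is.na(freq) & freq > 0 & kmean > 0
  lf <- log10(freq[ok]); lk <- log10(kmean[ok])
  if (sum(ok) < 2 || stats::sd(lf) == 0) {
    return(list(r_squared = if (sum(ok) >= 2) 1 else NA_real_,
                slope = 0, k = k))
  }
  fit <- stats::lm(lf ~ lk)
  list(r_squared = suppressWarnings(summary(fit)$r.squared),
       slope = unname(stats::coef(fit)[2]), k = k)
}

#' Topological overlap matrix
#'
#' Fills the TOM similarity of a network: for `i != j`,
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{u != i} a_iu`;
#' the diagonal is 1.
#'
#' @param network A `coexpression_network` with adjacency computed.
#' @return The network with its `tom` slot filled.
#' @export
tom_similarity <- function(network) {
  stopifnot(inherits(network, "coexpression_network"))
  a <- network$adjacency
  diag(a) <- 0
  k <- rowSums(a)
  l <- a %*% a                       # sum_u a_iu a_uj, u != i,j since diag 0
  kmin <- outer(k, k, pmin)
  denom <- kmin + 1 - a
  tom <- (l + a) / denom
  tom[denom <= 0] <- 1               # a_ij = 1 with zero side connectivity
  diag(tom) <- 1
  dimnames(tom) <- dimnames(network$adjacency)
  network$tom <- tom
  network
}

#' Module eigengenes (first principal components)
#'
#' For each non-grey module: analyte profiles are standardized to mean 0 /
#' sd 1 across samples, the eigengene is the standardized first principal
#' component score vector across samples, with its sign fixed so that it
#' correlates non-negatively with the module's mean standardized profile.
#' `variance_explained` is the leading eigenvalue fraction. Zero-variance
#' analytes are dropped from the computation.
#'
#' @param x A `scaled_matrix` or numeric matrix (analytes x samples).
#' @param partition A `module_partition` or named character vector
#'   (analyte -> module label).
#' @return An object of class `eigengene_matrix`: `values` (modules x
#'   samples) and `variance_explained`.
#' @export
module_eigengenes <- function(x, partition) {
  v <- if (inherits(x, "scaled_matrix")) x$values else as.matrix(x)
  module_of <- if (inherits(partition, "module_partition")) partition$module_of else partition
  mods <- setdiff(unique(module_of), GREY_LABEL)
  if (!length(mods)) stop("no non-grey modules in the partition")
  me <- matrix(NA_real_, length(mods), ncol(v),
               dimnames = list(mods, colnames(v)))
  ve <- stats::setNames(rep(NA_real_, length(mods)), mods)
  for (m in mods) {
    ids <- names(module_of)[module_of == m]
    sub <- v[intersect(rownames(v), ids), , drop = FALSE]
    sds <- apply(sub, 1, stats::sd)
    if (any(sds == 0 | is.na(sds))) {
      log_msg(sprintf("module '%s': dropping %d zero-variance analytes from PCA",
                      m, sum(sds == 0 | is.na(sds))))
      sub <- sub[!is.na(sds) & sds > 0, , drop = FALSE]
    }
    if (nrow(sub) < 2) stop("module '", m, "' has fewer than 2 usable analytes")
    z <- t(scale(t(sub)))
    z[is.na(z)] <- 0                 # missing entries contribute nothing
    sv <- svd(z)
    scores <- sv$v[, 1]
    scores <- (scores - mean(scores)) / stats::sd(scores)
    if (stats::cor(scores, colMeans(z)) < 0) scores <- -scores
    me[m, ] <- scores
    ve[m] <- sv$d[1]^2 / sum(sv$d^2)
  }
  structure(list(values = me, variance_explained = ve),
            class = "eigengene_matrix")
}

#' @export
print.eigengene_matrix <- function(x, ...) {
  cat(sprintf("eigengene_matrix: %d modules x %d samples\n",
              nrow(x$values), ncol(x$values)))
  print(round(x$variance_explained, 3))
  invisible(x)
}

#' Detect co-expression modules from the TOM
#'
#' Average-linkage hierarchical clustering of the dissimilarity `1 - TOM`,
#' followed by a simplified dynamic-hybrid cut: the tree is cut at a main
#' height (by default the midpoint of the largest gap among the sorted merge
#' heights above their median — deterministic and adaptive), clusters smaller
#' than `min_module_size` are dissolved and their members reassigned to the
#' module whose eigengene they correlate with best (if `|cor| >=
#' reassign_min_cor`, else grey), and module pairs whose eigengene
#' dissimilarity `1 - cor` falls below `merge_cut_height` are merged
#' iteratively (closest pair first). Modules are labeled by the conventional
#' color sequence in order of decreasing size; `grey` is reserved for
#' unassigned analytes. `cut_interpretation = "static"` instead cuts the
#' `1 - TOM` dendrogram directly at `merge_cut_height`.
#'
#' @param network A `coexpression_network` with TOM computed.
#' @param x The expression matrix used for eigengenes (a `scaled_matrix` or
#'   matrix, analytes x samples).
#' @param min_module_size Minimum analytes per module (default 25).
#' @param merge_cut_height Eigengene merge cut height (default 0.1).
#' @param cut_interpretation `"merge"` (default; merge_cut_height applies to
#'   eigengene merging after the dynamic cut) or `"static"` (cut the 1 - TOM
#'   tree at merge_cut_height).
#' @param cut_height Optional fixed main cut height overriding the
#'   largest-gap heuristic.
#' @param reassign_min_cor Minimum absolute eigengene correlation for
#'   reassigning members of dissolved small clusters (default 0.8; strict
#'   enough that chance correlations at a dozen samples rarely pass).
#' @return An object of class `module_partition`: `module_of` (analyte ->
#'   color label), `dendrogram` (the hclust tree), `min_module_size`,
#'   `merge_cut_height`, `cut_height_used`.
#' @export
detect_modules <- function(network, x, min_module_size = 25,
                           merge_cut_height = 0.1,
                           cut_interpretation = c("merge", "static"),
                           cut_height = NULL, reassign_min_cor = 0.8) {
  stopifnot(inherits(network, "coexpression_network"))
  if (is.null(network$tom)) stop("TOM not computed; run tom_similarity() first")
  cut_interpretation <- match.arg(cut_interpretation)
  v <- if (inherits(x, "scaled_matrix")) x$values else as.matrix(x)
  d <- stats::as.dist(1 - network$tom)
  tree <- stats::hclust(d, method = "average")
  h <- sort(tree$height)
  if (cut_interpretation == "static") {
    cut_h <- merge_cut_height
  } else if (!is.null(cut_height)) {
    cut_h <- cut_height
  } else {
    # largest gap between consecutive merge heights above the median height
    upper <- h[h >= stats::median(h)]
    if (length(upper) < 2) {
      cut_h <- max(h) * 0.99
    } else {
      gaps <- diff(upper)
      i <- which.max(gaps)
      cut_h <- (upper[i] + upper[i + 1]) / 2
    }
  }
  cl <- stats::cutree(tree, h = cut_h)
  module_of <- stats::setNames(rep(GREY_LABEL, length(cl)), names(cl))
  sizes <- table(cl)
  # candidate clusters: at least half the minimum size (dissolved members can
  # be rescued by eigengene reassignment before the full size rule applies),
  # and cohesive (mean internal dissimilarity below the cut height), which
  # rejects the loose clump that unclustered background analytes form near
  # the top of the tree
  cand_min <- if (cut_interpretation == "merge") {
    max(3L, min_module_size %/% 2L)
  } else {
    min_module_size
  }
  keep <- names(sizes)[sizes >= cand_min]
  if (cut_interpretation == "merge" && length(keep)) {
    dtom <- 1 - network$tom
    cohesive <- vapply(keep, function(g) {
      idx <- which(cl == as.integer(g))
      mean(dtom[idx, idx][upper.tri(diag(length(idx)))]) < cut_h
    }, logical(1))
    keep <- keep[cohesive]
  }
  if (!length(keep)) {
    log_msg("no cohesive cluster reaches the candidate size; all analytes grey")
    return(new_partition(module_of, tree, min_module_size, merge_cut_height, cut_h))
  }
  for (g in keep) module_of[cl == as.integer(g)] <- paste0("m", g)
  # PAM-like reassignment of dissolved small-cluster members
  small <- names(module_of)[module_of == GREY_LABEL]
  if (length(small) && cut_interpretation == "merge") {
    me <- module_eigengenes(v, module_of)
    r <- row_cor(v[small, , drop = FALSE], me$values, fallback = NA_real_)
    for (i in seq_along(small)) {
      ri <- r[i, ]
      if (all(is.na(ri))) next
      j <- which.max(abs(ri))
      if (!is.na(ri[j]) && abs(ri[j]) >= reassign_min_cor) {
        module_of[small[i]] <- rownames(me$values)[j]
      }
    }
  }
  # enforce the full minimum module size on the rescued partition
  for (m in setdiff(unique(module_of), GREY_LABEL)) {
    if (sum(module_of == m) < min_module_size) {
      module_of[module_of == m] <- GREY_LABEL
    }
  }
  # iterative eigengene merging, closest pair first
  if (cut_interpretation == "merge") {
    repeat {
      mods <- setdiff(unique(module_of), GREY_LABEL)
      if (length(mods) < 2) break
      me <- module_eigengenes(v, module_of)
      rc <- stats::cor(t(me$values))
      diag(rc) <- -Inf
      dmin <- 1 - max(rc)
      if (dmin >= merge_cut_height) break
      idx <- which(rc == max(rc), arr.ind = TRUE)[1, ]
      a <- rownames(rc)[idx[1]]; b <- rownames(rc)[idx[2]]
      module_of[module_of == b] <- a
    }
  }
  module_of <- relabel_by_size(module_of)
  new_partition(module_of, tree, min_module_size, merge_cut_height, cut_h)
}

new_partition <- function(module_of, tree, min_module_size, merge_cut_height,
                          cut_height_used) {
  structure(list(module_of = module_of, dendrogram = tree,
                 min_module_size = min_module_size,
                 merge_cut_height = merge_cut_height,
                 cut_height_used = cut_height_used),
            class = "module_partition")
}

# Rename modules by decreasing size with the conventional color sequence.
relabel_by_size <- function(module_of) {
  mods <- setdiff(unique(module_of), GREY_LABEL)
  if (!length(mods)) return(module_of)
  sizes <- vapply(mods, function(m) sum(module_of == m), integer(1))
  ord <- mods[order(-sizes, mods)]
  colors <- module_color_labels(length(ord))
  out <- module_of
  for (i in seq_along(ord)) out[module_of == ord[i]] <- colors[i]
  out
}

#' @export
print.module_partition <- function(x, ...) {
  tab <- sort(table(x$module_of), decreasing = TRUE)
  cat(sprintf("module_partition: %d analytes, %d modules (+ grey)\n",
              length(x$module_of),
              length(setdiff(names(tab), GREY_LABEL))))
  print(tab)
  invisible(x)
}
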