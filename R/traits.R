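#' Construct a trait matrix
#'
#' @param values Numeric matrix, samples x traits; binary traits coded 0/1,
#'   continuous traits in native units. Sample rownames must match the
#'   expression sample labels.
#' @param kind Optional character vector (per trait) classifying each trait,
#'   e.g. `treatment`, `core_material`, `morphology`, `physchem`, `toxicity`,
#'   `activity_class`.
#' @return The matrix with a `kind` attribute, class `trait_matrix`.
#' @export
trait_matrix <- function(values, kind = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("trait matrix needs sample rownames and trait colnames")
  }
  for (j in seq_len(ncol(values))) {
    v <- values[, j]
    u <- unique(v[!is.na(v)])
    if (length(u) <= 2 && !all(u %in% c(0, 1)) && all(u %in% c(TRUE, FALSE))) {
      values[, j] <- as.numeric(v)
    }
  }
  if (!is.null(kind)) {
    if (is.null(names(kind))) names(kind) <- colnames(values)
    attr(values, "kind") <- kind
  }
  class(values) <- c("trait_matrix", class(values))
  values
}

check_shared_samples <- function(expr_samples, trait_samples) {
  if (!all(trait_samples %in% expr_samples) ||
      !all(expr_samples %in% trait_samples)) {
    stop("trait sample labels do not match expression sample labels; ",
         "mismatch: ",
         paste(union(setdiff(expr_samples, trait_samples),
                     setdiff(trait_samples, expr_samples)), collapse = ", "))
  }
}

#' Module-trait correlation with significance stars
#'
#' Pearson correlation of each module eigengene with each trait over shared
#' non-absent samples; two-sided p-values via the Student-t transform
#' `t = r sqrt(n-2) / sqrt(1-r^2)` with `n - 2` degrees of freedom; stars
#' `*`/`**`/`***` at p <= 0.1 / 0.05 / 0.01.
#'
#' @param me An `eigengene_matrix`.
#' @param traits A matrix or [trait_matrix()], samples x traits.
#' @return Object of class `trait_correlation` with matrices `r`, `p`,
#'   `stars`, `n` (modules x traits).
#' @export
module_trait_correlation <- function(me, traits) {
  stopifnot(inherits(me, "eigengene_matrix"))
  traits <- as.matrix(traits)
  check_shared_samples(colnames(me$values), rownames(traits))
  traits <- traits[colnames(me$values), , drop = FALSE]
  mods <- rownames(me$values)
  dims <- list(mods, colnames(traits))
  r <- p <- matrix(NA_real_, length(mods), ncol(traits), dimnames = dims)
  n <- matrix(0L, length(mods), ncol(traits), dimnames = dims)
  for (j in seq_len(ncol(traits))) {
    tv <- traits[, j]
    for (m in mods) {
      ok <- !is.na(tv) & !is.na(me$values[m, ])
      n[m, j] <- sum(ok)
      if (sum(ok) < 3) next
      if (stats::sd(tv[ok]) == 0 || stats::sd(me$values[m, ok]) == 0) {
        log_msg(sprintf("zero-variance trait '%s' vs module '%s': correlation undefined",
                        colnames(traits)[j], m))
        next
      }
      r[m, j] <- stats::cor(me$values[m, ok], tv[ok])
    }
  }
  p[] <- cor_p_value(as.vector(r), as.vector(n))
  stars <- matrix(p_stars(as.vector(p)), nrow(p), ncol(p), dimnames = dims)
  structure(list(r = r, p = p, stars = stars, n = n),
            class = "trait_correlation")
}

#' @export
print.trait_correlation <- function(x, ...) {
  out <- matrix(sprintf("%.2f%s", x$r, ifelse(is.na(x$stars), "", x$stars)),
                nrow(x$r), dimnames = dimnames(x$r))
  print(out, quote = FALSE)
  invisible(x)
}

#' Gene significance
#'
#' Correlation of each analyte's expression profile with each trait across
#' samples. Zero-variance analytes give absent values.
#'
#' @param x A `scaled_matrix` or matrix (analytes x samples).
#' @param traits Samples x traits matrix.
#' @return Numeric matrix, analytes x traits.
#' @export
gene_significance <- function(x, traits) {
  v <- if (inherits(x, "scaled_matrix")) x$values else as.matrix(x)
  traits <- as.matrix(traits)
  check_shared_samples(colnames(v), rownames(traits))
  traits <- traits[colnames(v), , drop = FALSE]
  row_cor(v, t(traits), fallback = NA_real_)
}

#' Module membership
#'
#' Correlation of each analyte's expression profile with every module
#' eigengene (not only the analyte's own module).
#'
#' @param x A `scaled_matrix` or matrix (analytes x samples).
#' @param me An `eigengene_matrix`.
#' @return Numeric matrix, analytes x modules.
#' @export
module_membership <- function(x, me) {
  stopifnot(inherits(me, "eigengene_matrix"))
  v <- if (inherits(x, "scaled_matrix")) x$values else as.matrix(x)
  row_cor(v, me$values, fallback = NA_real_)
}

#' Select key drivers
#'
#' For each trait, candidate analytes are those in modules whose module-trait
#' correlation is significant (p <= `module_p`) when
#' `require_significant_module`, otherwise all non-grey analytes. An analyte
#' is a key driver iff `|GS| >= gs_threshold` and `|MM|` to its own module
#' `>= mm_threshold` (boundary values included).
#'
#' @param gs Gene-significance matrix (analytes x traits).
#' @param mm Module-membership matrix (analytes x modules).
#' @param partition A `module_partition` (or analyte -> module vector).
#' @param trait_correlation A `trait_correlation` (needed when
#'   `require_significant_module`).
#' @param gs_threshold,mm_threshold Absolute thresholds (defaults 0.75).
#' @param require_significant_module Restrict candidates to significantly
#'   trait-correlated modules (grey excluded either way).
#' @param module_p Significance level for module-trait candidacy.
#' @return A data.frame (class `key_driver_table`): `analyte`, `module`,
#'   `trait`, `gene_significance`, `module_membership`.
#' @export
select_key_drivers <- function(gs, mm, partition, trait_correlation = NULL,
                               gs_threshold = 0.75, mm_threshold = 0.75,
                               require_significant_module = TRUE,
                               module_p = 0.05) {
  module_of <- if (inherits(partition, "module_partition")) partition$module_of else partition
  if (require_significant_module && is.null(trait_correlation)) {
    stop("trait_correlation is required when require_significant_module = TRUE")
  }
  rows <- list()
  for (tr in colnames(gs)) {
    cand_mods <- setdiff(unique(module_of), GREY_LABEL)
    if (require_significant_module) {
      pcol <- trait_correlation$p[, tr]
      cand_mods <- intersect(cand_mods,
                             rownames(trait_correlation$p)[!is.na(pcol) & pcol <= module_p])
    }
    if (!length(cand_mods)) next
    for (a in rownames(gs)) {
      m <- module_of[[a]]
      if (is.null(m) || is.na(m) || !(m %in% cand_mods)) next
      g <- gs[a, tr]
      w <- if (m %in% colnames(mm)) mm[a, m] else NA_real_
      if (!is.na(g) && !is.na(w) &&
          abs(g) >= gs_threshold && abs(w) >= mm_threshold) {
        rows[[length(rows) + 1L]] <- data.frame(
          analyte = a, module = m, trait = tr,
          gene_significance = g, module_membership = w,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(analyte = character(0), module = character(0),
               trait = character(0), gene_significance = numeric(0),
               module_membership = numeric(0))
  rownames(out) <- NULL
  class(out) <- c("key_driver_table", class(out))
  out
}

#' Export per-trait key-driver identifier lists
#'
#' One plain-text identifier list per trait (for external GO / pathway
#' enrichment services), ordered by decreasing |GS| with ties broken
#' lexicographically by identifier.
#'
#' @param table A `key_driver_table`.
#' @param dir Output directory (created if needed); `NULL` returns the lists
#'   without writing.
#' @param traits Traits to export (default: all traits present in `table`;
#'   traits without drivers give empty lists).
#' @return Named list of character vectors (invisibly if written).
#' @export
export_driver_lists <- function(table, dir = NULL, traits = NULL) {
  if (is.null(traits)) traits <- unique(table$trait)
  lists <- lapply(stats::setNames(traits, traits), function(tr) {
    sub <- table[table$trait == tr, , drop = FALSE]
    sub <- sub[order(-abs(sub$gene_significance), sub$analyte), , drop = FALSE]
    sub$analyte
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (tr in names(lists)) {
      path <- file.path(dir, paste0("key_drivers_", gsub("[^A-Za-z0-9_.-]", "_", tr), ".txt"))
      writeLines(c("analyte", lists[[tr]]), path)
    }
    return(invisible(lists))
  }
  lists
}
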