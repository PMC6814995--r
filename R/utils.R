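#' @keywords internal
"_PACKAGE"

# Reserved label for analytes not assigned to any module.
GREY_LABEL <- "grey"

# WGCNA-convention color sequence used to label modules by decreasing size.
MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue",
  "lightcyan", "grey60", "lightgreen", "lightyellow", "royalblue", "darkred",
  "darkgreen", "darkturquoise", "darkgrey", "orange", "darkorange", "white",
  "skyblue", "saddlebrown", "steelblue", "paleturquoise", "violet",
  "darkolivegreen", "darkmagenta"
)

module_color_labels <- function(n) {
  if (n <= length(MODULE_COLORS)) {
    MODULE_COLORS[seq_len(n)]
  } else {
    c(MODULE_COLORS, sprintf("module%03d", seq_len(n - length(MODULE_COLORS))))
  }
}

# Round half away from zero (deterministic across platforms, unlike round()).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Significance stars for correlation p-values
#'
#' Maps p-values to the star annotation used in module-trait heatmaps:
#' `***` for p <= 0.01, `**` for p <= 0.05, `*` for p <= 0.1, otherwise "".
#'
#' @param p Numeric vector of p-values (NA allowed).
#' @return Character vector of the same length.
#' @export
p_stars <- function(p) {
  out <- character(length(p))
  out[!is.na(p) & p <= 0.1] <- "*"
  out[!is.na(p) & p <= 0.05] <- "**"
  out[!is.na(p) & p <= 0.01] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

# Pearson correlation between rows of x (and rows of y if given), pairwise
# complete, with pairs sharing fewer than min_overlap samples set to `fallback`
# (NA or 0). Zero-variance rows give NA unless fallback overrides.
row_cor <- function(x, y = NULL, min_overlap = 3L, fallback = NA_real_) {
  tx <- t(x)
  ty <- if (is.null(y)) NULL else t(y)
  r <- suppressWarnings(stats::cor(tx, ty, use = "pairwise.complete.obs"))
  nx <- !is.na(tx)
  ov <- if (is.null(ty)) crossprod(nx) else crossprod(nx, !is.na(ty))
  r[ov < min_overlap] <- fallback
  r
}

# Two-sided p-value for a Pearson correlation r at sample size n via the
# Student-t transform with n - 2 degrees of freedom.
cor_p_value <- function(r, n) {
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r) & n > 2
  rr <- pmin(pmax(r[ok], -1), 1)
  t_stat <- rr * sqrt(n[ok] - 2) / sqrt(pmax(1 - rr^2, .Machine$double.eps))
  p[ok] <- 2 * stats::pt(abs(t_stat), df = n[ok] - 2, lower.tail = FALSE)
  p[ok][abs(rr) == 1] <- 0
  pmin(p, 1)
}

log_msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message("[nmomics] ", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
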