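#' Default trait specifications for the synthetic generator
#'
#' Four continuous physico-chemical/toxicological traits and two binary
#' activity classifications, each driven by one planted module. Target
#' correlations are the sample correlations the generator realizes between
#' the trait column and the driving module's eigengene profile.
#'
#' @return A data.frame with columns `name`, `module` (index of the driving
#'   planted module), `rho` (target correlation), `binary`, `kind`.
#' @export
default_trait_specs <- function() {
  data.frame(
    name = c("agglomerate_size", "zeta_potential", "surface_area",
             "viability", "active_invitro", "active_invivo"),
    module = c(1L, 2L, 3L, 4L, 1L, 2L),
    rho = c(0.95, -0.9, 0.9, -0.95, 0.95, -0.9),
    binary = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    kind = c("physchem", "physchem", "physchem", "toxicity",
             "activity_class", "activity_class"),
    stringsAsFactors = FALSE
  )
}

#' Default per-layer activity pattern
#'
#' Which treatments receive planted differential shifts in which layer.
#' Four treatments are perturbed in at least two layers (overall "active"),
#' one in exactly one layer (overall "equivocal"), the rest in none
#' ("passive") — the 4/1/7 pattern of a 12-treatment screen.
#'
#' @param treatment_names Character vector of treatment names.
#' @return Named list, one character vector of active treatments per layer.
#' @export
default_active_pattern <- function(treatment_names = sprintf("NM%02d", 1:12)) {
  stopifnot(length(treatment_names) >= 5)
  t <- treatment_names
  list(
    proteomics   = t[c(1, 2, 3, 5)],
    metabolomics = t[c(1, 2, 4)],
    sh2          = t[c(1, 3, 4)]
  )
}

#' Configuration for the synthetic multi-omics generator
#'
#' Defines the study geometry (treatments, replicates, layer sizes), the
#' planted co-expression structure (modules, loadings, noise), trait
#' construction, planted differential effects, and missingness.
#'
#' @param n_treatments Number of treatments, excluding the control.
#' @param n_replicates Biological replicates per treatment (and control).
#' @param layers Named integer vector: analytes per omics layer.
#' @param network_layers Layers whose analytes enter the co-expression
#'   network (and carry the planted module structure).
#' @param n_modules Number of planted modules K (0 = no co-expression
#'   structure; all network analytes are background).
#' @param module_sizes Integer vector of length `n_modules`; `NULL` splits the
#'   non-background network analytes near-equally.
#' @param background_fraction Fraction of network analytes with no module
#'   (the "grey" truth).
#' @param loading_range Interval for analyte loadings on the module eigengene.
#' @param noise_sd Residual standard deviation (log2 scale), used for both the
#'   treatment-level residual and the replicate noise.
#' @param missing_rate Probability that an individual replicate measurement is
#'   absent.
#' @param traits Trait specification data.frame (see [default_trait_specs()]),
#'   or `NULL` for no traits.
#' @param active_pattern Named list of planted-active treatments per layer
#'   (see [default_active_pattern()]), or `NULL` for none.
#' @param differential_fraction Fraction of a layer's analytes that respond in
#'   that layer's active treatments.
#' @param effect_size Mean absolute planted log2 fold change of responding
#'   analytes.
#' @param baseline_log2 Mean baseline abundance on the log2 scale.
#' @param signed_loadings If `TRUE` (default), loadings get random signs —
#'   module members split between induced and repressed, which keeps sample
#'   medians stable under median normalization and is exactly what the
#'   unsigned `|cor|^beta` network detects. `FALSE` gives all-positive
#'   loadings (the signed-network scenario).
#' @param network_samples `"treatment"` (fold-change columns, one per
#'   treatment — the default) or `"replicate"` (treatment x replicate
#'   columns) for the downstream network/trait sample axis.
#' @param log2_output If `TRUE`, emit tables directly on the log2 scale
#'   (flagged as such, so the pipeline skips normalization). Default `FALSE`:
#'   raw positive intensities that exercise the normalization stages. Note
#'   that median normalization of a panel in which nearly every analyte is
#'   modulated subtracts a shared per-sample median of the effects; the log2
#'   mode isolates downstream stages from that (realistic) contamination.
#' @param treatment_names Treatment labels.
#' @param control_label Label for the control condition.
#' @param seed Integer seed; the generator is deterministic given the config.
#' @return A validated object of class `generator_config`.
#' @export
generator_config <- function(n_treatments = 12L,
                             n_replicates = 5L,
                             layers = c(proteomics = 1174L,
                                        metabolomics = 88L,
                                        sh2 = 54L),
                             network_layers = c("proteomics", "metabolomics"),
                             n_modules = 9L,
                             module_sizes = NULL,
                             background_fraction = 0.1,
                             loading_range = c(0.6, 0.95),
                             noise_sd = 0.1,
                             missing_rate = 0.02,
                             traits = default_trait_specs(),
                             active_pattern = default_active_pattern(treatment_names),
                             differential_fraction = 0.2,
                             effect_size = 2,
                             baseline_log2 = 20,
                             signed_loadings = TRUE,
                             network_samples = c("treatment", "replicate"),
                             log2_output = FALSE,
                             treatment_names = sprintf("NM%02d", seq_len(n_treatments)),
                             control_label = "control",
                             seed = 1L) {
  network_samples <- match.arg(network_samples)
  if (is.null(names(layers)) || any(names(layers) == "")) {
    stop("`layers` must be a named vector of analyte counts")
  }
  if (!all(network_layers %in% names(layers))) {
    stop("network_layers must be a subset of names(layers)")
  }
  n_net <- sum(layers[network_layers])
  n_modules <- as.integer(n_modules)
  if (n_modules > 0) {
    if (is.null(module_sizes)) {
      n_bg <- round(background_fraction * n_net)
      base <- (n_net - n_bg) %/% n_modules
      module_sizes <- rep(base, n_modules)
      extra <- (n_net - n_bg) - base * n_modules
      if (extra > 0) module_sizes[seq_len(extra)] <- base + 1L
    }
    module_sizes <- as.integer(module_sizes)
    if (length(module_sizes) != n_modules || any(module_sizes < 1)) {
      stop("`module_sizes` must give a positive size for each of the ",
           n_modules, " modules")
    }
    if (sum(module_sizes) > n_net) {
      stop("sum(module_sizes) exceeds the number of network-layer analytes")
    }
  } else {
    module_sizes <- integer(0)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  if (length(loading_range) != 2 || diff(loading_range) < 0) {
    stop("loading_range must be an interval (lo, hi)")
  }
  traits_defaulted <- missing(traits)
  if (!is.null(traits) && nrow(traits) > 0) {
    if (any(abs(traits$rho) > 1)) stop("target correlations must be in [-1, 1]")
    if (n_modules == 0) {
      traits <- traits[0, ]
    } else if (any(traits$module < 1 | traits$module > n_modules)) {
      if (traits_defaulted) {
        traits <- traits[traits$module <= n_modules, , drop = FALSE]
      } else {
        stop("trait driving-module indices must be in 1..n_modules")
      }
    }
  }
  if (!is.null(active_pattern)) {
    active_pattern <- active_pattern[intersect(names(active_pattern), names(layers))]
    bad <- setdiff(unlist(active_pattern), treatment_names)
    if (length(bad)) stop("active_pattern names unknown treatments: ",
                          paste(bad, collapse = ", "))
  }
  structure(
    list(n_treatments = as.integer(n_treatments),
         n_replicates = as.integer(n_replicates),
         layers = layers, network_layers = network_layers,
         n_modules = n_modules, module_sizes = module_sizes,
         background_fraction = background_fraction,
         loading_range = loading_range, noise_sd = noise_sd,
         missing_rate = missing_rate, traits = traits,
         active_pattern = active_pattern,
         differential_fraction = differential_fraction,
         effect_size = effect_size, baseline_log2 = baseline_log2,
         signed_loadings = isTRUE(signed_loadings),
         network_samples = network_samples,
         log2_output = isTRUE(log2_output),
         treatment_names = treatment_names,
         control_label = control_label, seed = as.integer(seed)),
    class = "generator_config"
  )
}

# Construct a vector with exact sample correlation rho to e (rho in [-1, 1]).
# Errors if e is constant (target correlation unreachable).
correlated_vector <- function(e, rho) {
  if (stats::sd(e) == 0) {
    stop("target correlation unreachable: driving eigengene profile is constant")
  }
  e_s <- as.numeric(scale(e))
  if (abs(rho) >= 1) return(sign(rho) * e_s)
  z <- stats::rnorm(length(e))
  z_r <- stats::residuals(stats::lm(z ~ e_s))
  if (stats::sd(z_r) == 0) {
    stop("target correlation unreachable: degenerate residual noise")
  }
  z_s <- as.numeric(scale(z_r))
  rho * e_s + sqrt(1 - rho^2) * z_s
}

#' Generate a synthetic multi-omics dataset with known ground truth
#'
#' Builds per-replicate intensity tables for each layer, a trait matrix, and
#' the planted ground truth. Network-layer analytes are partitioned into
#' `n_modules` planted modules plus a background ("grey") fraction; each
#' module is driven by a latent eigengene profile (i.i.d. standard normal per
#' treatment, zero at the control), and each member analyte follows
#' `loading * eigengene` plus a treatment-level residual (imperfect
#' co-expression) and replicate noise on the log2 scale; background analytes
#' carry replicate noise only, so they are true nulls against the control.
#' Traits are noisy (or, for the continuous construction,
#' exact-correlation) linear functions of their driving eigengene; binary
#' traits threshold the driving eigengene at its median. Planted differential
#' shifts of mean magnitude `effect_size` are added for the treatments listed
#' in `active_pattern`.
#'
#' @param config A [generator_config()].
#' @return A list with elements `layers` (named list of [replicate_table()]),
#'   `traits` (a trait matrix, samples x traits, with a `kind` attribute),
#'   and `truth` (list: `module_of`, `eigengene_profiles`, `loadings`,
#'   `driver_flags`, `differential_flags`, `active_pattern`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  trt <- config$treatment_names
  ctl <- config$control_label
  all_cond <- c(trt, ctl)
  K <- config$n_modules
  nrep <- config$n_replicates

  # latent eigengene profiles over treatments; zero at control so planted
  # fold changes equal loading * eigengene
  E <- matrix(stats::rnorm(K * length(trt)), nrow = max(K, 0),
              dimnames = if (K > 0) list(paste0("planted_", seq_len(K)), trt))
  E_full <- cbind(E, matrix(0, nrow = max(K, 0), ncol = 1,
                            dimnames = list(NULL, ctl)))

  # pooled module assignment over network-layer analytes
  analyte_ids <- lapply(names(config$layers), function(l) {
    sprintf("%s_%04d", l, seq_len(config$layers[[l]]))
  })
  names(analyte_ids) <- names(config$layers)
  net_ids <- unlist(analyte_ids[config$network_layers], use.names = FALSE)
  n_net <- length(net_ids)
  labels <- rep(GREY_LABEL, n_net)
  if (K > 0) {
    lab_pool <- rep(rownames(E), times = config$module_sizes)
    pos <- sample.int(n_net, length(lab_pool))
    labels[pos] <- lab_pool
  }
  names(labels) <- net_ids
  lo <- config$loading_range[1]; hi <- config$loading_range[2]
  loadings <- stats::runif(n_net, lo, hi)
  if (config$signed_loadings) loadings <- loadings * sample(c(-1, 1), n_net, TRUE)
  loadings[labels == GREY_LABEL] <- 0
  names(loadings) <- net_ids

  sample_trt <- rep(all_cond, each = nrep)
  sample_rep <- rep(seq_len(nrep), times = length(all_cond))

  layers_out <- list()
  differential_flags <- list()
  for (l in names(config$layers)) {
    ids <- analyte_ids[[l]]
    n_a <- length(ids)
    mu <- stats::rnorm(n_a, config$baseline_log2, 1.5)
    # treatment-level module effect
    eff <- matrix(0, n_a, length(all_cond), dimnames = list(ids, all_cond))
    if (l %in% config$network_layers && K > 0) {
      mod <- labels[ids]
      in_mod <- mod != GREY_LABEL
      if (any(in_mod)) {
        eff[in_mod, ] <- loadings[ids][in_mod] * E_full[mod[in_mod], , drop = FALSE]
      }
    }
    # planted differential shifts for this layer's active treatments
    shifts <- matrix(0, n_a, length(trt), dimnames = list(ids, trt))
    act <- config$active_pattern[[l]]
    if (length(act) > 0 && config$differential_fraction > 0) {
      idx <- sample.int(n_a, max(1L, round(config$differential_fraction * n_a)))
      sgn <- sample(c(-1, 1), length(idx), TRUE)
      mag <- config$effect_size * stats::runif(length(idx), 0.5, 1.5)
      for (a in act) shifts[idx, a] <- sgn * mag
    }
    eff[, trt] <- eff[, trt] + shifts
    # treatment-level residual (imperfect co-expression) for module members
    # only: background analytes are true nulls against the control
    resid <- matrix(0, n_a, length(all_cond))
    if (l %in% config$network_layers && K > 0) {
      in_mod <- labels[ids] != GREY_LABEL
      resid[in_mod, ] <- stats::rnorm(sum(in_mod) * length(all_cond), 0,
                                      config$noise_sd)
    }
    latent <- mu + eff + resid
    vals <- latent[, sample_trt, drop = FALSE] +
      matrix(stats::rnorm(n_a * length(sample_trt), 0, config$noise_sd),
             n_a, length(sample_trt))
    cell_counts <- NULL
    if (config$log2_output) {
      raw <- vals
    } else {
      raw <- 2^vals
      if (l == "metabolomics") {
        cell_counts <- stats::runif(length(sample_trt), 2e6, 6e6)
        raw <- sweep(raw, 2, cell_counts / 1e6, `*`)
      }
    }
    if (config$missing_rate > 0) {
      raw[stats::runif(length(raw)) < config$missing_rate] <- NA
    }
    rownames(raw) <- ids
    layers_out[[l]] <- replicate_table(
      raw, treatment = sample_trt, replicate = sample_rep,
      control_label = ctl, layer_name = l, cell_counts = cell_counts,
      log2_scale = config$log2_output
    )
    differential_flags[[l]] <- shifts != 0
  }

  # trait matrix over the downstream sample axis
  sample_labels <- if (config$network_samples == "treatment") trt else
    paste(rep(trt, each = nrep), seq_len(nrep), sep = ".")
  traits_m <- NULL
  spec <- config$traits
  if (!is.null(spec) && nrow(spec) > 0) {
    traits_m <- matrix(NA_real_, length(sample_labels), nrow(spec),
                       dimnames = list(sample_labels, spec$name))
    for (j in seq_len(nrow(spec))) {
      e <- E[spec$module[j], trt]
      e_smp <- if (config$network_samples == "treatment") e else rep(e, each = nrep)
      if (spec$binary[j]) {
        v <- as.numeric(e_smp >= stats::median(e_smp))
        if (spec$rho[j] < 0) v <- 1 - v
      } else {
        v <- correlated_vector(e_smp, spec$rho[j])
      }
      traits_m[, j] <- v
    }
    attr(traits_m, "kind") <- stats::setNames(spec$kind, spec$name)
  }

  # planted drivers: members of the trait's driving module, provided the
  # module's noise-free profile (loading * E_m, planted |MM| = 1) reaches
  # |cor| >= 0.75 with the realized trait. Modules that correlate with a
  # trait by chance are not planted truth. Binary traits carry no
  # planted-driver truth: median-thresholding cannot pin the realized
  # correlation, so their drivers would sit on the 0.75 boundary by
  # construction and are not a recoverable ground truth.
  driver_flags <- NULL
  if (!is.null(traits_m) && any(!spec$binary)) {
    cont <- which(!spec$binary)
    driver_flags <- matrix(FALSE, n_net, length(cont),
                           dimnames = list(net_ids, spec$name[cont]))
    for (j in cont) {
      k <- spec$module[j]
      ek <- if (config$network_samples == "treatment") E[k, trt] else
        rep(E[k, trt], each = nrep)
      r_k <- abs(stats::cor(ek, traits_m[, spec$name[j]]))
      if (!is.na(r_k) && r_k >= 0.75) {
        driver_flags[labels == rownames(E)[k], spec$name[j]] <- TRUE
      }
    }
  }

  truth <- list(
    module_of = labels,
    eigengene_profiles = E,
    loadings = loadings,
    driver_flags = driver_flags,
    differential_flags = differential_flags,
    active_pattern = config$active_pattern
  )
  list(layers = layers_out, traits = traits_m, truth = truth,
       config = config)
}
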