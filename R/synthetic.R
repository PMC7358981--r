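#' Configuration for a synthetic two-group cohort
#'
#' Describes a cohort of carrier / noncarrier subjects with hemisphere-block
#' correlation structure, mirroring the study conditions the pipeline is
#' designed for: 27 + 31 subjects, 26 ROI (13 per hemisphere, interleaved)
#' and K = 130 timepoints per series.
#'
#' The group-level correlation matrix has three tiers, reflecting the
#' canonical structure of resting-state functional connectivity:
#' `within_block_rho` inside a hemisphere, `homotopic_rho` between mirror
#' regions of the two hemispheres (homotopic connections are among the
#' strongest in the brain), and `between_block_rho` for the remaining,
#' diffuse cross-hemisphere pairs. The carrier group's correlations are
#' raised by `coupling_boost` at the pairs selected by `boost_on` - by
#' default the homotopic bridges, planting a "faster aggregation" effect:
#' the bridging minimum-spanning-tree weights fall, components merge at
#' lower filtration values, and the Betti and IPF curves steepen, while the
#' bulk of pairwise weights (which dominate path-length-type measures) moves
#' little. Subject-level biological variability enters through three
#' channels drawn per subject: a cortical-coupling shift applied to within
#' and homotopic correlations (sd `within_sd`), a diffuse interhemispheric
#' shift applied to the non-homotopic cross pairs (sd `between_sd`), and a
#' global coherence factor `c = exp(N(0, scale_sd^2))` that compresses every
#' correlation toward 1 via `r -> 1 - c (1 - r)` (emulating subject
#' differences in overall functional-connectivity level). `noise_sd` scales
#' the marginal amplitude of the series and does not affect correlations.
#'
#' @param n_carrier,n_noncarrier Group sizes (defaults 27 and 31).
#' @param n_roi Number of ROI (default 26; must be even so hemispheres
#'   alternate).
#' @param n_timepoints Timepoints per series (default 130).
#' @param within_block_rho Within-hemisphere correlation (default 0.45).
#' @param homotopic_rho Correlation between mirror-region pairs (default
#'   0.50).
#' @param between_block_rho Non-homotopic cross-hemisphere correlation
#'   (default 0.15).
#' @param coupling_boost Added to the carrier group's correlations at the
#'   pairs selected by `boost_on` (default 0.15; 0 gives an exchangeable
#'   null cohort).
#' @param boost_on Which correlations the carrier boost acts on:
#'   `"homotopic"` (default: the mirror-region bridges whose strengthening
#'   makes components aggregate faster), `"between"` (all cross-hemisphere
#'   pairs), `"within"`, or `"uniform"` (all pairs).
#' @param within_sd,between_sd,scale_sd Subject-level variability (defaults
#'   0.08, 0.08, 0.15; see Details).
#' @param noise_sd Marginal standard deviation of each series (default 1).
#' @param ar1 Optional AR(1) coefficient for temporal autocorrelation
#'   (default 0, i.e. white signals).
#' @param seed RNG seed for the cohort (default 1).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_carrier = 27L, n_noncarrier = 31L, n_roi = 26L,
                          n_timepoints = 130L,
                          within_block_rho = 0.45, homotopic_rho = 0.50,
                          between_block_rho = 0.15,
                          coupling_boost = 0.15,
                          boost_on = c("homotopic", "between", "within",
                                       "uniform"),
                          within_sd = 0.08, between_sd = 0.08,
                          scale_sd = 0.15,
                          noise_sd = 1, ar1 = 0, seed = 1L) {
  boost_on <- match.arg(boost_on)
  cfg <- list(
    n_carrier = as.integer(n_carrier),
    n_noncarrier = as.integer(n_noncarrier),
    n_roi = as.integer(n_roi),
    n_timepoints = as.integer(n_timepoints),
    within_block_rho = within_block_rho,
    homotopic_rho = homotopic_rho,
    between_block_rho = between_block_rho,
    coupling_boost = coupling_boost,
    boost_on = boost_on,
    within_sd = within_sd, between_sd = between_sd, scale_sd = scale_sd,
    noise_sd = noise_sd, ar1 = ar1, seed = as.integer(seed)
  )
  if (cfg$n_carrier < 2L || cfg$n_noncarrier < 2L) {
    stop("each group needs at least 2 subjects", call. = FALSE)
  }
  if (cfg$n_roi < 2L) stop("need at least 2 ROI", call. = FALSE)
  if (cfg$n_timepoints < 3L) stop("need at least 3 timepoints", call. = FALSE)
  if (cfg$within_block_rho < 0 || cfg$within_block_rho >= 1) {
    stop("within_block_rho must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$coupling_boost < 0) stop("coupling_boost must be >= 0",
                                   call. = FALSE)
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (abs(cfg$ar1) >= 1) stop("ar1 must lie in (-1, 1)", call. = FALSE)
  class(cfg) <- "cohort_config"
  cfg
}

# Hemisphere membership pattern for n ROI: left/right alternating, matching
# the atlas convention (left node first in each homologous pair).
block_pattern <- function(n_roi) {
  rep(c("left", "right"), length.out = n_roi)
}

# Node labels: atlas abbreviations for the standard 26-ROI layout, otherwise
# synthetic ".L"/".R"-suffixed names so hemispheric scoping still works.
cohort_labels <- function(n_roi) {
  if (n_roi == 26L) {
    atlas <- dmn_atlas()
    return(atlas$abbreviation)
  }
  suffix <- ifelse(block_pattern(n_roi) == "left", "L", "R")
  sprintf("ROI%02d.%s", seq_len(n_roi), suffix)
}

#' Group-level correlation matrix
#'
#' Builds the tiered correlation matrix for one group: unit diagonal,
#' `within_block_rho` inside each hemisphere block, `homotopic_rho` at
#' mirror-region pairs and `between_block_rho` at the remaining cross-block
#' pairs, with `coupling_boost` added to the carrier group's entries at the
#' pairs named by the config's `boost_on` (homotopic pairs by default).
#' Optional subject-level shifts and the global coherence scale apply the
#' per-subject variability channels. All off-diagonal correlations are
#' clipped to \[-0.99, 0.99\] and, should the result fail positive
#' semi-definiteness, projected by eigenvalue flooring and renormalised to
#' unit diagonal.
#'
#' @param config A `cohort_config`.
#' @param group `"carrier"` or `"noncarrier"`.
#' @param within_shift,between_shift Subject-level additive correlation
#'   shifts (default 0: the group template). `within_shift` moves the
#'   within-hemisphere and homotopic tiers together; `between_shift` moves
#'   the non-homotopic cross-hemisphere tier.
#' @param scale Subject-level global coherence factor (default 1).
#' @return Correlation matrix of dimension `config$n_roi`.
#' @export
make_group_covariance <- function(config, group = c("noncarrier", "carrier"),
                                  within_shift = 0, between_shift = 0,
                                  scale = 1) {
  stopifnot(inherits(config, "cohort_config"))
  group <- match.arg(group)
  boost <- if (group == "carrier") config$coupling_boost else 0
  b_on <- config$boost_on
  rw <- config$within_block_rho + within_shift +
    if (b_on %in% c("within", "uniform")) boost else 0
  rh <- config$homotopic_rho + within_shift +
    if (b_on %in% c("homotopic", "between", "uniform")) boost else 0
  rb <- config$between_block_rho + between_shift +
    if (b_on %in% c("between", "uniform")) boost else 0
  # global coherence compression toward r = 1
  comp <- function(r) min(0.99, max(-0.99, 1 - scale * (1 - r)))
  rw <- comp(rw)
  rh <- comp(rh)
  rb <- comp(rb)

  n <- config$n_roi
  blocks <- block_pattern(n)
  same <- outer(blocks, blocks, `==`)
  R <- ifelse(same, rw, rb)
  # mirror-region pairs: consecutive (left, right) positions
  for (k in seq_len(n %/% 2L)) {
    R[2L * k - 1L, 2L * k] <- rh
    R[2L * k, 2L * k - 1L] <- rh
  }
  diag(R) <- 1

  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    eg <- eigen(R, symmetric = TRUE)
    vals <- pmax(eg$values, 1e-8)
    R <- eg$vectors %*% (vals * t(eg$vectors))
    d <- sqrt(diag(R))
    R <- R / outer(d, d)
    diag(R) <- 1
    ev2 <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev2) < -1e-10) {
      stop("correlation matrix not positive semi-definite after projection ",
           "(eigenvalue floor ", format(min(ev2)), ")", call. = FALSE)
    }
  }
  R
}

#' Simulate one subject's ROI time series
#'
#' Draws `n_timepoints` multivariate normal vectors with the given
#' correlation matrix (eigen factorisation, so positive semi-definite inputs
#' are accepted), optionally with AR(1) temporal autocorrelation, and scales
#' the marginal amplitude by `noise_sd`. Sample pairwise correlations
#' converge to the target as `n_timepoints` grows.
#'
#' @param correlation Correlation matrix (rows define the ROI).
#' @param n_timepoints Number of timepoints (columns).
#' @param noise_sd Marginal standard deviation of each series.
#' @param seed Optional local seed (caller's RNG state restored).
#' @param ar1 AR(1) coefficient in (-1, 1); 0 gives white signals.
#' @param labels Optional ROI row labels.
#' @return Numeric matrix, rows = ROI, columns = timepoints.
#' @export
simulate_subject <- function(correlation, n_timepoints = 130L, noise_sd = 1,
                             seed = NULL, ar1 = 0, labels = NULL) {
  correlation <- as.matrix(correlation)
  m <- nrow(correlation)
  if (m != ncol(correlation)) stop("correlation matrix must be square",
                                   call. = FALSE)
  n_timepoints <- as.integer(n_timepoints)
  if (n_timepoints < 3L) stop("need at least 3 timepoints", call. = FALSE)
  with_local_seed(seed, {
    E <- MASS::mvrnorm(n_timepoints, mu = rep(0, m), Sigma = correlation)
    if (ar1 != 0) {
      Z <- E
      s <- sqrt(1 - ar1^2)
      for (t in 2:n_timepoints) Z[t, ] <- ar1 * Z[t - 1L, ] + s * E[t, ]
      E <- Z
    }
    ts <- noise_sd * t(E)
    rownames(ts) <- labels
    ts
  })
}

#' Simulate a two-group cohort
#'
#' Composes [make_group_covariance()] and [simulate_subject()] per subject
#' under a single master seed: per-subject seeds and variability shifts are
#' drawn first, so every subject is individually reproducible and the whole
#' cohort is byte-identical across reruns with the same configuration.
#'
#' @param config A `cohort_config`.
#' @return An object of class `dmn_cohort`: list with `subjects` (each a
#'   list `subject_id`, `group`, `values`) and `config`.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_carrier = 2, n_noncarrier = 2,
#'                                      n_roi = 6, n_timepoints = 30))
#' length(coh$subjects)   # 4
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_carrier + config$n_noncarrier
  groups <- rep(c("carrier", "noncarrier"),
                c(config$n_carrier, config$n_noncarrier))
  labels <- cohort_labels(config$n_roi)
  with_local_seed(config$seed, {
    subject_seeds <- sample.int(2147483646L, n)
    w_shift <- stats::rnorm(n, 0, config$within_sd)
    b_shift <- stats::rnorm(n, 0, config$between_sd)
    scales <- exp(stats::rnorm(n, 0, config$scale_sd))
    subjects <- vector("list", n)
    idx_in_group <- c(seq_len(config$n_carrier),
                      seq_len(config$n_noncarrier))
    for (i in seq_len(n)) {
      Sigma <- make_group_covariance(config, groups[i],
                                     within_shift = w_shift[i],
                                     between_shift = b_shift[i],
                                     scale = scales[i])
      values <- simulate_subject(Sigma, config$n_timepoints,
                                 noise_sd = config$noise_sd,
                                 seed = subject_seeds[i],
                                 ar1 = config$ar1, labels = labels)
      subjects[[i]] <- list(
        subject_id = sprintf("%s_%02d", groups[i], idx_in_group[i]),
        group = groups[i],
        values = values
      )
    }
    structure(list(subjects = subjects, config = config),
              class = "dmn_cohort")
  })
}

#' @export
print.dmn_cohort <- function(x, ...) {
  groups <- vapply(x$subjects, `[[`, character(1), "group")
  dims <- dim(x$subjects[[1L]]$values)
  cat("Synthetic cohort:", sum(groups == "carrier"), "carrier +",
      sum(groups == "noncarrier"), "noncarrier subjects,",
      dims[1L], "ROI x", dims[2L], "timepoints\n")
  invisible(x)
}

#' Write a cohort to per-subject files plus a manifest
#'
#' Each subject's series goes to `<subject_id>.tsv` (see
#' [write_timeseries()]) and `manifest.tsv` maps `subject_id`, `group` and
#' the relative file path.
#'
#' @param cohort A `dmn_cohort`.
#' @param dir Output directory (created if absent).
#' @return Path to the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dmn_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(cohort$subjects, function(s) {
    path <- paste0(s$subject_id, ".tsv")
    write_timeseries(s$values, file.path(dir, path))
    data.frame(subject_id = s$subject_id, group = s$group, path = path,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest_path)
}

#' Read a cohort from a manifest of time-series files
#'
#' @param manifest_path Path to a delimited manifest with columns
#'   `subject_id`, `group`, `path` (paths relative to the manifest).
#' @param atlas Optional atlas used to validate ROI ordering of each file.
#' @return A `dmn_cohort` (without a simulation config).
#' @export
read_cohort <- function(manifest_path, atlas = NULL) {
  manifest <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  required <- c("subject_id", "group", "path")
  if (!all(required %in% names(manifest))) {
    stop("manifest needs columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(manifest$subject_id)) {
    stop("subject ids must be unique", call. = FALSE)
  }
  base <- dirname(manifest_path)
  subjects <- lapply(seq_len(nrow(manifest)), function(i) {
    list(
      subject_id = manifest$subject_id[i],
      group = manifest$group[i],
      values = read_timeseries(file.path(base, manifest$path[i]),
                               atlas = atlas)
    )
  })
  structure(list(subjects = subjects, config = NULL), class = "dmn_cohort")
}
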