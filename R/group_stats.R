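# Permutation p-values for several features sharing the same group labels.
# values: n x f matrix; is_a: logical group indicator. The same label
# shuffles are applied to every column, which keeps the per-feature p-values
# comparable across features. Add-one correction keeps p > 0.
perm_pvalues <- function(values, is_a, n_perm, statistic = c("mean", "t")) {
  statistic <- match.arg(statistic)
  values <- as.matrix(values)
  n <- nrow(values)
  na <- sum(is_a)
  nb <- n - na
  if (na < 1L || nb < 1L) stop("both groups must be non-empty", call. = FALSE)
  stat_fun <- if (statistic == "mean") {
    function(A, B) abs(colMeans(A) - colMeans(B))
  } else {
    function(A, B) {
      va <- apply(A, 2L, stats::var)
      vb <- apply(B, 2L, stats::var)
      abs(colMeans(A) - colMeans(B)) / sqrt(va / nrow(A) + vb / nrow(B))
    }
  }
  obs <- stat_fun(values[is_a, , drop = FALSE], values[!is_a, , drop = FALSE])
  count <- numeric(ncol(values))
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n, na)
    s <- stat_fun(values[idx, , drop = FALSE], values[-idx, , drop = FALSE])
    count <- count + (s >= obs)
  }
  list(p = (1 + count) / (1 + n_perm), observed = obs)
}

#' Two-group permutation test
#'
#' Tests for a difference between two groups of subject-level values by
#' permuting the group labels. The default statistic is the absolute
#' difference of group means (two-sided; the direction of a group effect is
#' not pre-specified); a Welch t statistic is available as an option. The
#' p-value uses the add-one convention `p = (1 + #{perm >= obs}) /
#' (1 + n_perm)`, so p is never zero and has resolution `1/(n_perm + 1)`.
#'
#' @param values_a,values_b Numeric vectors, one entry per subject.
#' @param n_perm Number of label permutations (default 10000, the standard
#'   choice for this analysis).
#' @param seed Optional local seed (caller's RNG state restored).
#' @param statistic `"mean"` (absolute mean difference) or `"t"` (absolute
#'   Welch t).
#' @return List with `p_value`, `observed` (the observed statistic),
#'   `n_perm`, `statistic` and `seed`.
#' @examples
#' permutation_test(rnorm(10), rnorm(10) + 3, n_perm = 200, seed = 1)$p_value
#' @export
permutation_test <- function(values_a, values_b, n_perm = 10000L,
                             seed = NULL, statistic = c("mean", "t")) {
  statistic <- match.arg(statistic)
  if (length(values_a) < 1L || length(values_b) < 1L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (anyNA(values_a) || anyNA(values_b)) {
    stop("values contain missing entries", call. = FALSE)
  }
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  values <- matrix(c(values_a, values_b), ncol = 1L)
  is_a <- rep(c(TRUE, FALSE), c(length(values_a), length(values_b)))
  res <- with_local_seed(seed, perm_pvalues(values, is_a, n_perm, statistic))
  list(p_value = res$p[1L], observed = res$observed[1L], n_perm = n_perm,
       statistic = statistic, seed = seed)
}

#' Per-subject feature table for a cohort
#'
#' Builds each subject's weighted network at every requested scope and
#' computes the seven network features, returning one row per subject and
#' scope. Subjects may carry raw time series (`values`) or a precomputed
#' whole-brain weight matrix (`network`); in the latter case hemispheric
#' scopes are taken as submatrices, which is exact because the pairwise
#' weights are computed independently per pair.
#'
#' @param cohort A `dmn_cohort` (or list with a `subjects` element).
#' @param scopes Character vector of scopes (default all three).
#' @param atlas Atlas used for scope selection of atlas-sized matrices.
#' @param n_restarts Louvain restarts for the modularity feature.
#' @param n_discard Leading volumes to drop from each subject's raw series
#'   before network construction (default 0: series are assumed already
#'   trimmed, as produced by [simulate_cohort()]).
#' @return Data frame with columns `subject_id`, `group`, `scope`, `sip`,
#'   `bnp`, `cpl`, `nr`, `ec`, `mod`, `gc`.
#' @export
feature_table <- function(cohort, scopes = c("both", "left", "right"),
                          atlas = dmn_atlas(), n_restarts = 10L,
                          n_discard = 0L) {
  subjects <- cohort$subjects
  if (is.null(subjects)) stop("cohort has no subjects", call. = FALSE)
  scopes <- match.arg(scopes, several.ok = TRUE)
  rows <- list()
  for (s in subjects) {
    for (scope in scopes) {
      W <- tryCatch(
        subject_network(s, scope, atlas, n_discard),
        error = function(e) stop("subject ", s$subject_id, ": ",
                                 conditionMessage(e), call. = FALSE)
      )
      f <- subject_features(W, n_restarts = n_restarts)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s$subject_id, group = s$group, scope = scope,
        as.list(f), stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# One subject's network at a scope, from raw series or a precomputed matrix.
subject_network <- function(subject, scope, atlas, n_discard = 0L) {
  if (!is.null(subject$network)) {
    W <- validate_network(subject$network)
    if (scope == "both") return(W)
    if (nrow(W) == nrow(atlas)) {
      idx <- scope_indices(atlas, scope)
    } else {
      labels <- rownames(W)
      suffix <- if (scope == "left") "\\.L$" else "\\.R$"
      idx <- grep(suffix, labels)
      if (length(idx) < 2L) {
        stop("cannot resolve scope '", scope, "' from node labels",
             call. = FALSE)
      }
    }
    return(W[idx, idx, drop = FALSE])
  }
  ts <- subject$values
  if (is.null(ts)) stop("subject carries neither time series nor network",
                        call. = FALSE)
  if (n_discard > 0L) ts <- discard_initial_volumes(ts, n_discard)
  build_network(ts, scope = scope, atlas = atlas)
}

#' Two-group permutation comparison of all features
#'
#' Computes the feature table for the cohort (7 features x requested scopes
#' per subject) and, for each feature-scope cell, the permutation p-value of
#' the two-sided group difference. With the default three scopes this yields
#' the 21-cell grid of the standard report (rows = scope, columns =
#' features).
#'
#' @param cohort A `dmn_cohort` whose subjects carry exactly two group
#'   labels, at least 2 subjects each.
#' @param scopes Character vector of scopes (default all three).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Seed for the permutation draws (and Louvain restarts), applied
#'   locally.
#' @param statistic `"mean"` or `"t"` (see [permutation_test()]).
#' @param atlas Atlas used for scope selection.
#' @param n_restarts Louvain restarts for the modularity feature.
#' @param features Optional precomputed [feature_table()] output (skips
#'   network construction).
#' @return An object of class `dmn_comparison`: list with `table` (long
#'   results: scope, feature, group means, observed difference, p_value),
#'   `features`, `groups`, `n_perm`, `statistic`, `seed`.
#' @export
compare_groups <- function(cohort, scopes = c("both", "left", "right"),
                           n_perm = 10000L, seed = NULL,
                           statistic = c("mean", "t"), atlas = dmn_atlas(),
                           n_restarts = 10L, features = NULL) {
  statistic <- match.arg(statistic)
  scopes <- match.arg(scopes, several.ok = TRUE)
  with_local_seed(seed, {
    if (is.null(features)) {
      features <- feature_table(cohort, scopes = scopes, atlas = atlas,
                                n_restarts = n_restarts)
    }
    groups <- unique(features$group)
    if (length(groups) != 2L) {
      stop("exactly two groups are required, found: ",
           paste(groups, collapse = ", "), call. = FALSE)
    }
    if ("carrier" %in% groups) {
      groups <- c("carrier", setdiff(groups, "carrier"))
    }
    if (any(table(features$group, features$scope) < 2L)) {
      stop("each group needs at least 2 subjects", call. = FALSE)
    }
    rows <- list()
    for (scope in scopes) {
      sub <- features[features$scope == scope, , drop = FALSE]
      V <- as.matrix(sub[, FEATURE_NAMES, drop = FALSE])
      is_a <- sub$group == groups[1L]
      res <- perm_pvalues(V, is_a, n_perm, statistic)
      mean_a <- colMeans(V[is_a, , drop = FALSE])
      mean_b <- colMeans(V[!is_a, , drop = FALSE])
      rows[[scope]] <- data.frame(
        scope = scope, feature = FEATURE_NAMES,
        mean_a = unname(mean_a), mean_b = unname(mean_b),
        diff = unname(mean_a - mean_b),
        observed = unname(res$observed), p_value = unname(res$p),
        stringsAsFactors = FALSE
      )
    }
    table <- do.call(rbind, rows)
    rownames(table) <- NULL
    structure(
      list(table = table, features = features, groups = groups,
           n_perm = n_perm, statistic = statistic, seed = seed),
      class = "dmn_comparison"
    )
  })
}

#' P-value grid of a group comparison
#'
#' Reshapes the long comparison table into the scope-by-feature p-value grid
#' of the standard report layout.
#'
#' @param comparison A `dmn_comparison`.
#' @return Numeric matrix, rows = scopes, columns = features.
#' @export
comparison_grid <- function(comparison) {
  stopifnot(inherits(comparison, "dmn_comparison"))
  tab <- comparison$table
  scopes <- unique(tab$scope)
  grid <- matrix(NA_real_, length(scopes), length(FEATURE_NAMES),
                 dimnames = list(scopes, toupper(FEATURE_NAMES)))
  for (i in seq_len(nrow(tab))) {
    grid[tab$scope[i], toupper(tab$feature[i])] <- tab$p_value[i]
  }
  grid
}

#' @export
print.dmn_comparison <- function(x, digits = 4, ...) {
  cat("Two-group permutation comparison (", x$groups[1L], " vs ",
      x$groups[2L], ", ", x$n_perm, " permutations, statistic = ",
      x$statistic, ")\n\n", sep = "")
  print(round(comparison_grid(x), digits))
  invisible(x)
}

#' Write a feature table as delimited text
#'
#' @param features A [feature_table()] data frame.
#' @param file Output path.
#' @param sep Field separator (default tab).
#' @return `file`, invisibly.
#' @export
write_feature_table <- function(features, file, sep = "\t") {
  utils::write.table(features, file, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Write a comparison result (grid plus long table)
#'
#' Writes `<stem>_grid.tsv` (scope x feature p-values) and `<stem>_long.tsv`
#' (observed statistics and p-values per cell).
#'
#' @param comparison A `dmn_comparison`.
#' @param stem Output path stem.
#' @return Character vector of the two paths, invisibly.
#' @export
write_comparison <- function(comparison, stem) {
  grid <- comparison_grid(comparison)
  grid_path <- paste0(stem, "_grid.tsv")
  long_path <- paste0(stem, "_long.tsv")
  utils::write.table(data.frame(scope = rownames(grid), grid,
                                check.names = FALSE),
                     grid_path, sep = "\t", quote = FALSE, row.names = FALSE)
  long <- comparison$table
  long$n_perm <- comparison$n_perm
  long$seed <- if (is.null(comparison$seed)) NA else comparison$seed
  utils::write.table(long, long_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(grid_path, long_path))
}
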