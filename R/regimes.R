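#' Normalize environmental features across samples
#'
#' Per-feature z-scores (mean 0, SD 1 with the n-1 denominator) across
#' samples, the standard pre-treatment before Euclidean resemblance on
#' mixed-unit environmental variables.
#'
#' @param features numeric matrix or data frame, samples in rows, features in
#'   columns; row names label the samples.
#' @return Numeric matrix of z-scores.
#' @export
normalize_features <- function(features) {
  m <- as.matrix(features)
  if (nrow(m) < 2) stop("need at least 2 samples")
  sds <- apply(m, 2, sd)
  if (any(sds == 0))
    stop("constant feature(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  scale(m)[, , drop = FALSE]
}

#' Euclidean resemblance matrix
#'
#' @param normalized matrix of normalized features (samples x features).
#' @return A `dist` object of pairwise Euclidean distances.
#' @export
euclidean_resemblance <- function(normalized) {
  dist(normalized, method = "euclidean")
}

#' Similarity-profile (SIMPROF) permutation test for one sample set
#'
#' Tests whether the multivariate structure among a set of samples exceeds
#' what independent (exchangeable) features would produce. The observed
#' profile is the ordered vector of pairwise Euclidean distances; null
#' profiles are built by permuting each feature's values independently across
#' the samples. The statistic is pi = sum of absolute departures of the
#' observed ordered profile from the mean null profile, and the p-value is the
#' add-one permutation fraction of null pi at least as large.
#'
#' @param features normalized feature matrix (samples x features).
#' @param n_perm number of permutations, default 999.
#' @return A list: `pi`, `p_value`, `n`, `null_pi` (numeric vector).
#' @export
simprof_test <- function(features, n_perm = 999) {
  m <- as.matrix(features)
  n <- nrow(m)
  if (n < 3) return(list(pi = NA_real_, p_value = NA_real_, n = n,
                         null_pi = numeric(0)))
  obs <- sort(as.numeric(dist(m)))
  perm_profiles <- matrix(0, n_perm, length(obs))
  for (b in seq_len(n_perm)) {
    pm <- apply(m, 2, function(col) col[sample.int(n)])
    perm_profiles[b, ] <- sort(as.numeric(dist(pm)))
  }
  mean_null <- colMeans(perm_profiles)
  pi_obs <- sum(abs(obs - mean_null))
  pi_null <- rowSums(abs(sweep(perm_profiles, 2, mean_null)))
  p <- (sum(pi_null >= pi_obs) + 1) / (n_perm + 1)
  list(pi = pi_obs, p_value = p, n = n, null_pi = pi_null)
}

#' Hierarchical clustering with SIMPROF stopping
#'
#' Group-average (UPGMA) clustering of the Euclidean resemblance among
#' samples, with the SIMPROF permutation test applied top-down at each
#' dendrogram node: a node is split only while the profile within it is
#' significantly structured (p < `alpha`); descent stops at non-significant
#' nodes, whose members form one homogeneous group. Nodes with fewer than 3
#' samples are untestable and never split further.
#'
#' @param features normalized feature matrix (samples x features), row names
#'   labelling samples.
#' @param n_perm permutations per node test, default 999.
#' @param alpha significance level, default 0.05.
#' @param seed RNG seed making the permutation tests reproducible.
#' @return A list of class `"simprof_clust"`: `hclust` (the tree), `nodes`
#'   (data frame: node label, members, n, pi, p_value, significant, tested),
#'   `groups` (named integer vector of final group memberships).
#' @export
hcluster_simprof <- function(features, n_perm = 999, alpha = 0.05,
                             seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                       .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  m <- as.matrix(features)
  labs <- rownames(m)
  if (is.null(labs)) labs <- as.character(seq_len(nrow(m)))
  rownames(m) <- labs
  hc <- hclust(dist(m), method = "average")

  # members of each merge node
  node_members <- function(i) {
    get_m <- function(j)
      if (j < 0) -j else unlist(lapply(hc$merge[j, ], get_m))
    sort(unlist(lapply(hc$merge[i, ], get_m)))
  }

  nodes <- list()
  groups <- rep(NA_integer_, nrow(m)); names(groups) <- labs
  next_group <- 0L

  recurse <- function(idx) {
    # idx: row of hc$merge (node), or negative leaf index
    if (idx < 0) {
      next_group <<- next_group + 1L
      groups[-idx] <<- next_group
      return(invisible())
    }
    mem <- node_members(idx)
    res <- simprof_test(m[mem, , drop = FALSE], n_perm)
    sig <- !is.na(res$p_value) && res$p_value < alpha
    nodes[[length(nodes) + 1L]] <<- data.frame(
      node = idx, members = paste(labs[mem], collapse = ","),
      n = length(mem), pi = res$pi, p_value = res$p_value,
      significant = sig, tested = !is.na(res$p_value))
    if (sig) {
      recurse(hc$merge[idx, 1])
      recurse(hc$merge[idx, 2])
    } else {
      next_group <<- next_group + 1L
      groups[mem] <<- next_group
    }
    invisible()
  }
  recurse(nrow(hc$merge))
  structure(list(hclust = hc, nodes = do.call(rbind, nodes),
                 groups = groups),
            class = "simprof_clust")
}

#' Nonmetric multidimensional scaling of a resemblance matrix
#'
#' Kruskal stress-1 nMDS (via `vegan::monoMDS`, global model) minimized over
#' random restarts; the configuration with the lowest stress is returned,
#' centered on the origin.
#'
#' @param resemblance a `dist` object.
#' @param dims embedding dimension, default 2.
#' @param restarts random restarts, default 50.
#' @param seed RNG seed.
#' @return A list: `points` (samples x dims matrix), `stress` (Kruskal
#'   stress-1, 0-1 scale).
#' @export
nmds <- function(resemblance, dims = 2, restarts = 50, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                       .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  n <- attr(resemblance, "Size")
  if (n < 3) stop("need at least 3 samples")
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- matrix(rnorm(n * dims), n, dims)
    fit <- tryCatch(
      vegan::monoMDS(resemblance, y = init, k = dims, model = "global"),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  if (is.null(best)) stop("all nMDS restarts failed")
  pts <- scale(best$points, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  rownames(pts) <- attr(resemblance, "Labels")
  list(points = pts, stress = best$stress)
}

#' Printed spring-summer environmental summary for the M2 mooring, 2009-2012
#'
#' The eight-feature environmental summary (mean and maximum ice extent, ice
#' thickness, shallow temperature, and shallow salinity over March-August) for
#' the four study years, as published for the M2 mooring site. These are the
#' inputs of the between-year resemblance, clustering/SIMPROF, and nMDS
#' analyses.
#'
#' @param features_only drop the phenology-date rows (ice retreat, thin ice,
#'   stratification onset) and return only the eight resemblance features?
#'   Default `TRUE`.
#' @return A `data.frame` with years as rows. With `features_only = FALSE`,
#'   the phenology days are appended as extra columns (`NA` where not
#'   computed).
#' @export
m2_environment_table <- function(features_only = TRUE) {
  tab <- data.frame(
    year = c(2009L, 2010L, 2011L, 2012L),
    max_ice_pct = c(85, 85, 80, 85),
    max_ice_cm = c(100, 80, 61, 120),
    mean_ice_pct = c(13.9, 24.0, 17.6, 35.3),
    mean_ice_cm = c(11.3, 18.3, 9.12, 23.7),
    max_shtemp = c(10.1, 8.36, 10.4, 8.94),
    mean_shtemp = c(3.38, 3.40, 3.51, 2.73),
    max_shsal = c(31.9, 31.8, 31.9, 31.8),
    mean_shsal = c(31.6, 31.7, 31.5, 31.5))
  if (!features_only) {
    tab$ice_retreat_day <- c(140L, 158L, 138L, 184L)
    tab$thin_ice_day <- c(119L, 128L, 126L, 144L)
    tab$stratification_day <- c(169L, NA, 187L, 122L)
  }
  rownames(tab) <- tab$year
  tab
}
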