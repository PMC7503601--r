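#' Shadow-feature all-relevant selection
#'
#' Recursive feature exclusion against randomized shadow copies, in the
#' style popularised for random forests: each iteration appends a permuted
#' copy of every still-undecided feature, fits a random-forest regressor
#' (permutation importance z-scored by its standard error, 500 trees,
#' mtry = p/3 as for regression forests), and scores a "hit" for every real
#' feature whose importance exceeds the best shadow's. Hit counts are tested
#' against a Binomial(iterations, 1/2) null, two-sided, Bonferroni-corrected
#' over the starting features: features significantly above chance are
#' confirmed, significantly below are rejected and removed from subsequent
#' iterations. Features still undecided at `max_iter` are tentative;
#' `resolve_tentative = TRUE` settles them by comparing their median
#' importance across iterations to the median of the shadow maxima.
#'
#' With pilot-scale inputs (n < 20) single runs are unstable; a warning
#' suggests [shadow_selection_stability()], which reports status frequencies
#' across seeds instead of one run.
#'
#' @param x Data frame or matrix of numeric features (>= 2 columns,
#'   >= 5 rows).
#' @param y Numeric outcome (the adherence measure being profiled).
#' @param seed Integer seed (forest and permutations).
#' @param max_iter Maximum iterations (default 100).
#' @param alpha Significance level for the binomial decisions (default
#'   0.01).
#' @param num_trees Trees per forest (default 500).
#' @param resolve_tentative Settle leftover tentative features by the
#'   median-importance rule (default TRUE).
#' @return Object of class `selection_report`: `status` (named factor
#'   confirmed/tentative/rejected), `hits`, `n_iter`, `importance_history`
#'   (iterations x features, NA once removed), `shadow_max_history`, `seed`.
#' @export
shadow_feature_selection <- function(x, y, seed = 1, max_iter = 100,
                                     alpha = 0.01, num_trees = 500,
                                     resolve_tentative = TRUE) {
  x <- as.data.frame(x)
  if (ncol(x) < 2) stop("need at least 2 features", call. = FALSE)
  if (nrow(x) < 5) stop("need at least 5 rows", call. = FALSE)
  if (length(y) != nrow(x)) stop("y length must match rows of x", call. = FALSE)
  if (stats::sd(y) == 0) stop("degenerate target: outcome is constant", call. = FALSE)
  if (nrow(x) < 20)
    warning("n < 20: single-run selection is unstable; consider shadow_selection_stability()")
  p <- ncol(x)
  feat <- colnames(x)
  set.seed(seed)
  status <- stats::setNames(rep("undecided", p), feat)
  hits <- stats::setNames(integer(p), feat)
  imp_hist <- matrix(NA_real_, nrow = max_iter, ncol = p,
                     dimnames = list(NULL, feat))
  shadow_hist <- rep(NA_real_, max_iter)
  # decisions begin once the binomial null can reach significance at all
  min_iter <- 5L
  it <- 0L
  while (it < max_iter && any(status == "undecided")) {
    it <- it + 1L
    active <- names(status)[status != "rejected"]
    # keep at least 5 shadows so the best-shadow bar stays competitive even
    # when few real features remain
    shadow_src <- active
    while (length(shadow_src) < 5) shadow_src <- c(shadow_src, active)
    shadows <- as.data.frame(lapply(x[shadow_src], sample))
    names(shadows) <- paste0(".shadow_", seq_along(shadow_src))
    d <- cbind(x[active], shadows, .y = y)
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = d, num.trees = num_trees,
      importance = "permutation", scale.permutation.importance = TRUE,
      num.threads = 1,
      mtry = max(floor((ncol(d) - 1L) / 3), 1L),  # regression-forest default
      seed = seed * 1000L + it)
    imp <- fit$variable.importance
    # a feature never used by any tree has 0/0 z-score; count it as zero
    imp[!is.finite(imp)] <- 0
    shadow_max <- max(imp[names(shadows)])
    shadow_hist[it] <- shadow_max
    imp_hist[it, active] <- imp[active]
    und <- names(status)[status == "undecided"]
    hits[und] <- hits[und] + as.integer(imp[und] > shadow_max)
    if (it >= min_iter) {
      # two-sided binomial decisions, Bonferroni over the starting features
      thr <- alpha / p
      p_hi <- stats::pbinom(hits[und] - 1L, it, 0.5, lower.tail = FALSE)
      p_lo <- stats::pbinom(hits[und], it, 0.5)
      status[und[p_hi < thr / 2]] <- "confirmed"
      status[und[p_lo < thr / 2]] <- "rejected"
    }
  }
  status[status == "undecided"] <- "tentative"
  if (resolve_tentative && any(status == "tentative")) {
    med_shadow <- stats::median(shadow_hist[seq_len(it)], na.rm = TRUE)
    for (f in names(status)[status == "tentative"]) {
      med_f <- stats::median(imp_hist[seq_len(it), f], na.rm = TRUE)
      status[f] <- if (isTRUE(med_f > med_shadow)) "confirmed" else "rejected"
    }
  }
  structure(list(status = factor(status,
                                 levels = c("confirmed", "tentative", "rejected")),
                 hits = hits, n_iter = it,
                 importance_history = imp_hist[seq_len(it), , drop = FALSE],
                 shadow_max_history = shadow_hist[seq_len(it)],
                 alpha = alpha, seed = seed),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("shadow-feature selection (%d iterations, alpha = %g)\n",
              x$n_iter, x$alpha))
  for (lev in levels(x$status)) {
    f <- names(x$status)[x$status == lev]
    if (length(f)) cat(sprintf("  %-9s %s\n", paste0(lev, ":"),
                               paste(f, collapse = ", ")))
  }
  invisible(x)
}

#' Selection status frequencies across seeds
#'
#' Runs [shadow_feature_selection()] under several seeds and tabulates how
#' often each feature is confirmed/tentative/rejected — the honest summary
#' at pilot sample sizes, where any single run is seed-sensitive.
#'
#' @inheritParams shadow_feature_selection
#' @param seeds Integer vector of seeds.
#' @return Data frame: `feature`, `confirmed`, `tentative`, `rejected`
#'   (frequencies in [0, 1]).
#' @export
shadow_selection_stability <- function(x, y, seeds = 1:20, ...) {
  runs <- lapply(seeds, function(s)
    suppressWarnings(shadow_feature_selection(x, y, seed = s, ...))$status)
  tab <- sapply(levels(runs[[1]]), function(lev)
    rowMeans(sapply(runs, function(r) r == lev)))
  data.frame(feature = names(runs[[1]]), tab, row.names = NULL)
}

kmeanspp_centers <- function(xm, k = 2L) {
  n <- nrow(xm)
  centers <- xm[sample.int(n, 1L), , drop = FALSE]
  while (nrow(centers) < k) {
    d2 <- apply(xm, 1L, function(r)
      min(colSums((t(centers) - r)^2)))
    if (all(d2 == 0)) stop("degeneracy: fewer distinct points than clusters",
                           call. = FALSE)
    centers <- rbind(centers, xm[sample.int(n, 1L, prob = d2), , drop = FALSE])
  }
  centers
}

#' Two-cluster k-means on standardized features
#'
#' Lloyd's algorithm with k = 2 on z-scored features (the selected
#' predictors are on incommensurate scales — questionnaire points vs beats
#' per minute — so clustering is standardized by default). Ten k-means++
#' restarts; the run with the lowest within-cluster sum of squares wins and
#' its iteration count is reported.
#'
#' @param x Data frame/matrix of the selected features (>= 3 rows).
#' @param seed Integer seed.
#' @param n_init Number of restarts (default 10).
#' @param standardize Z-score features first (default TRUE).
#' @param max_iter,tol Lloyd iteration cap and centroid-movement tolerance.
#' @return Object of class `cluster_result`: `assignments` (1/2),
#'   `centroids` (standardized space), `iterations`, `inertia`, `seed`.
#' @export
kmeans_two <- function(x, seed = 1, n_init = 10, standardize = TRUE,
                       max_iter = 100, tol = 1e-6) {
  xm <- as.matrix(as.data.frame(x))
  if (!is.numeric(xm)) stop("features must be numeric", call. = FALSE)
  if (nrow(xm) < 3) stop("need at least 3 rows", call. = FALSE)
  if (nrow(unique(xm)) < 2)
    stop("degeneracy: fewer distinct points than clusters", call. = FALSE)
  if (standardize) {
    sds <- apply(xm, 2, stats::sd)
    if (any(sds == 0)) stop("constant feature cannot be standardized", call. = FALSE)
    xm <- scale(xm)
  }
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_init)) {
    centers <- kmeanspp_centers(xm, 2L)
    km <- suppressWarnings(
      stats::kmeans(xm, centers = centers, iter.max = max_iter,
                    algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss - tol) best <- km
  }
  structure(list(assignments = stats::setNames(best$cluster, rownames(xm)),
                 centroids = best$centers, iterations = best$iter,
                 inertia = best$tot.withinss, seed = seed),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("k-means (k = 2): sizes %s, inertia %.3f, converged in %d iteration(s)\n",
              paste(table(x$assignments), collapse = "/"), x$inertia,
              x$iterations))
  invisible(x)
}

#' Mean-split grouping
#'
#' Group 1 = strictly above the mean, group 2 = at or below. The simplest
#' two-group partition of a baseline outcome (e.g. walk-test distance into
#' faster/slower).
#'
#' @param values Numeric vector (>= 2 finite values).
#' @return List: `groups` (1/2 per value), `mean`, `empty_group` flag (all
#'   values equal leaves group 1 empty).
#' @export
mean_split <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 2) stop("need at least 2 finite values", call. = FALSE)
  m <- mean(values, na.rm = TRUE)
  g <- ifelse(values > m, 1L, 2L)
  empty <- length(unique(g[is.finite(values)])) < 2
  if (empty) warning("all values equal: one mean-split group is empty")
  list(groups = g, mean = m, empty_group = empty)
}

#' Clustering accuracy against known labels
#'
#' Cluster ids are arbitrary; accuracy is the best agreement over the two
#' labelings.
#'
#' @param assignments Cluster ids (1/2).
#' @param truth True binary labels (any two values).
#' @return Accuracy in [0.5, 1].
#' @export
cluster_accuracy <- function(assignments, truth) {
  t2 <- as.integer(factor(truth))
  max(mean(assignments == t2), mean(assignments == 3L - t2))
}

#' Full baseline-profiling chain
#'
#' The data-driven profiling pipeline: shadow-feature selection of baseline
#' predictors of an adherence outcome, then k = 2 clustering of the cohort
#' on the confirmed features. The adherence target is a parameter (walking
#' program adherence, exercise program adherence, or exercise volume
#' adherence), since different outcomes select different predictors.
#'
#' @param profiles Baseline feature table (data frame; non-feature columns
#'   dropped via `feature_cols`).
#' @param target Numeric outcome vector aligned with `profiles` rows.
#' @param feature_cols Character vector of feature column names (default:
#'   all numeric columns).
#' @param seed Integer seed shared by selection and clustering.
#' @param include_target Cluster in the joint space of the selected
#'   features and the (standardized) adherence outcome (default TRUE):
#'   the clusters are adherence clusters, characterised by the baseline
#'   predictors. Set FALSE to cluster on baseline features alone.
#' @param ... Passed to [shadow_feature_selection()].
#' @return Object of class `profiling_result`: `selection`, `cluster`
#'   (NULL when nothing was confirmed), `features_used`, `target`.
#' @export
profile_adherence <- function(profiles, target, feature_cols = NULL,
                              seed = 1, include_target = TRUE, ...) {
  if (is.null(feature_cols))
    feature_cols <- names(profiles)[vapply(profiles, is.numeric, logical(1))]
  x <- profiles[feature_cols]
  sel <- shadow_feature_selection(x, target, seed = seed, ...)
  used <- names(sel$status)[sel$status == "confirmed"]
  cl <- if (length(used) >= 1) {
    space <- x[used]
    if (include_target) space$.target <- target
    kmeans_two(space, seed = seed)
  } else NULL
  structure(list(selection = sel, cluster = cl, features_used = used,
                 target = target),
            class = "profiling_result")
}

#' @export
print.profiling_result <- function(x, ...) {
  print(x$selection)
  if (is.null(x$cluster)) cat("no features confirmed; clustering skipped\n")
  else print(x$cluster)
  invisible(x)
}
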