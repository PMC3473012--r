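# Cell-size / cycle-length phenotype clustering of boxels.

#' Cluster boxels on standardized features
#'
#' K-means (squared Euclidean distance) on z-scored features, by default
#' average cell size and cycle length per boxel. Censored cycle lengths
#' enter at the censoring cap (dropping them would delete exactly the
#' slow-cycling population of interest); they are counted in the summary.
#' Cluster labels are canonicalized by increasing mean cycle length so that
#' repeated runs and reports are comparable.
#'
#' @param grid A `boxel_grid` with the feature columns.
#' @param k Number of clusters.
#' @param features Character vector of feature columns.
#' @param standardize Z-score features before clustering (default `TRUE`).
#' @param n_restarts Random restarts; the best (lowest total
#'   within-cluster sum of squares) solution is kept.
#' @param seed Integer seed for reproducible initialisation.
#' @param censored_policy `"cap"` (default) keeps censored boxels at the cap
#'   value; `"drop"` excludes them.
#' @return A `boxel_clusters` object: list with `grid` (the input grid with a
#'   `cluster` column on valid rows), `summary` (per-cluster feature means
#'   and sizes), `totss`, `tot_withinss`, and the call parameters.
#' @export
cluster_boxels <- function(grid, k = 3, features = c("cell_size_um3", "t_c_h"),
                           standardize = TRUE, n_restarts = 20, seed = NULL,
                           censored_policy = c("cap", "drop")) {
  censored_policy <- match.arg(censored_policy)
  assert_that(all(features %in% names(grid)),
              paste("missing feature columns:",
                    paste(setdiff(features, names(grid)), collapse = ", ")))
  assert_that(is_number(k) && k >= 1, "`k` must be >= 1")
  use <- grid$valid
  for (f in features) use <- use & is.finite(grid[[f]])
  if (censored_policy == "drop" && "censored" %in% names(grid))
    use <- use & !isTRUE_vec(grid$censored)
  x <- as.matrix(grid[use, features, drop = FALSE])
  if (nrow(x) < k)
    abort(sprintf("clustering infeasible: %d valid boxels for k = %d", nrow(x), k))
  centre <- colMeans(x); scale_ <- apply(x, 2, sd)
  if (standardize) {
    scale_[scale_ == 0] <- 1
    xs <- sweep(sweep(x, 2, centre), 2, scale_, "/")
  } else xs <- x
  seed <- seed %||% next_seed()
  km <- with_seed(seed, kmeans(xs, centers = k, nstart = n_restarts,
                               iter.max = 100))
  # canonical order: increasing mean cycle length (fall back to first feature)
  ord_feat <- if ("t_c_h" %in% features) "t_c_h" else features[1]
  means <- tapply(x[, ord_feat], km$cluster, mean)
  relabel <- match(seq_len(k), order(means))
  cl <- relabel[km$cluster]
  grid$cluster <- NA_integer_
  grid$cluster[use] <- cl
  summary <- dplyr::as_tibble(cbind(
    cluster = seq_len(k),
    n = as.integer(table(factor(cl, levels = seq_len(k)))),
    do.call(rbind, lapply(seq_len(k), function(ci)
      colMeans(x[cl == ci, , drop = FALSE])))))
  if ("censored" %in% names(grid))
    summary$n_censored <- as.integer(tapply(
      grid$censored[use], factor(cl, levels = seq_len(k)),
      function(v) sum(v, na.rm = TRUE)))
  structure(list(grid = grid, summary = summary, k = k, features = features,
                 standardize = standardize, seed = seed,
                 totss = km$totss, tot_withinss = km$tot.withinss,
                 censored_policy = censored_policy),
            class = "boxel_clusters")
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.boxel_clusters <- function(x, ...) {
  cat(sprintf("boxel_clusters: k = %d on (%s), %d boxels clustered\n",
              x$k, paste(x$features, collapse = ", "),
              sum(!is.na(x$grid$cluster))))
  print(x$summary)
  invisible(x)
}

#' @rdname cluster_boxels
#' @param x A `boxel_clusters` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.boxel_clusters <- function(x, ...) x$summary

#' @rdname cluster_boxels
#' @exportS3Method generics::glance
glance.boxel_clusters <- function(x, ...) {
  tibble(k = x$k, n = sum(!is.na(x$grid$cluster)),
         totss = x$totss, tot_withinss = x$tot_withinss,
         prop_within = x$tot_withinss / x$totss)
}

#' Spatial contiguity of cluster labels
#'
#' For each cluster, the fraction of its boxels whose 6-neighbourhood
#' (face-adjacent boxels with a cluster label) has a majority of the same
#' label. Clusters formed without any spatial information but spatially
#' organised score near 1; randomly permuted labels score near the cluster's
#' size fraction. Reported, not thresholded.
#'
#' @param grid A `boxel_grid` with a `cluster` column (from
#'   [cluster_boxels()]`$grid`).
#' @return Tibble: `cluster`, `n`, `contiguity`.
#' @export
spatial_contiguity <- function(grid) {
  assert_that("cluster" %in% names(grid), "`grid` must carry a cluster column")
  lab <- grid[!is.na(grid$cluster), c("bx", "by", "bz", "cluster")]
  key <- function(b) paste(b$bx, b$by, b$bz, sep = "/")
  lut <- setNames(lab$cluster, key(lab))
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  agree <- vapply(seq_len(nrow(lab)), function(i) {
    nb <- lut[paste(lab$bx[i] + offs[, 1], lab$by[i] + offs[, 2],
                    lab$bz[i] + offs[, 3], sep = "/")]
    nb <- nb[!is.na(nb)]
    if (!length(nb)) return(NA)
    mean(nb == lab$cluster[i]) >= 0.5
  }, NA)
  lab$agree <- agree
  lab |>
    dplyr::group_by(cluster = .data$cluster) |>
    dplyr::summarise(n = dplyr::n(),
                     contiguity = mean(.data$agree, na.rm = TRUE),
                     .groups = "drop")
}
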