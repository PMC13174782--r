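#' Two-dimensional manifold embedding of LI profiles
#'
#' Projects the participants x features LI matrix to two dimensions
#' with UMAP (uniform manifold approximation and projection), using the
#' conventional defaults for this analysis: `n_neighbors = 15`,
#' `min_dist = 0.1`, Euclidean distance. LI features share the bounded
#' \[-1, 1\] scale, so they are passed unstandardised by default; set
#' `scale = TRUE` to z-score them first. The seed and all parameters
#' are recorded in the result for reproducibility.
#'
#' @param li_mat A complete (no missing cells) [li_matrix()]-shaped
#'   tibble: `participant_id` plus numeric feature columns.
#' @param n_neighbors,min_dist,metric UMAP parameters.
#' @param scale Standardise features before embedding (default FALSE).
#' @param seed RNG seed for the embedding.
#' @return Object of class `li_embedding`: tibble `participant_id`,
#'   `umap1`, `umap2` with the parameters as attributes. Plot with
#'   [autoplot()].
#' @export
embed_li <- function(li_mat, n_neighbors = 15L, min_dist = 0.1,
                     metric = "euclidean", scale = FALSE, seed = 42L) {
  x <- as.matrix(li_mat[setdiff(names(li_mat), "participant_id")])
  if (anyNA(x)) abort("LI matrix has missing cells; use listwise exclusion")
  if (nrow(x) <= n_neighbors) {
    abort("need more participants than n_neighbors")
  }
  if (scale) x <- base::scale(x)
  coords <- withr::with_seed(seed, {
    uwot::umap(x, n_neighbors = n_neighbors, min_dist = min_dist,
               metric = metric, n_threads = 1, n_sgd_threads = 1)
  })
  out <- tibble::tibble(participant_id = li_mat$participant_id,
                        umap1 = coords[, 1], umap2 = coords[, 2])
  structure(out, class = c("li_embedding", class(out)),
            embed_params = list(n_neighbors = n_neighbors,
                                min_dist = min_dist, metric = metric,
                                scale = scale, seed = seed,
                                backend = paste0("uwot ",
                                  utils::packageVersion("uwot"))))
}

#' Clustering tendency of LI profiles
#'
#' Quantifies whether lateralisation profiles form discrete clusters or
#' a continuum, computed on the original feature space (not the 2-D
#' embedding, to avoid projection artefacts). Two complementary
#' diagnostics:
#' \itemize{
#'   \item Hopkins statistic against a uniform reference on the feature
#'     bounding box (~0.5 for unstructured data, toward 1 for clustered
#'     data);
#'   \item the best average silhouette width over k-means partitions
#'     across `k_grid` (at most ~0.3 for a single Gaussian cloud, above
#'     0.5 for well-separated archetypes).
#' }
#'
#' @inheritParams embed_li
#' @param k_grid Candidate cluster counts for k-means (default 2:8).
#' @param n_ref Number of sampled origins for the Hopkins statistic.
#' @param seed RNG seed (reference draws and k-means restarts).
#' @return Object of class `li_clusterability`: `hopkins`,
#'   `silhouette` (tibble by k), `silhouette_best`, `best_k`, `n`.
#' @export
clusterability <- function(li_mat, k_grid = 2:8, n_ref = 200L, seed = 1L) {
  x <- as.matrix(li_mat[setdiff(names(li_mat), "participant_id")])
  if (anyNA(x)) abort("LI matrix has missing cells")
  if (nrow(x) < 10) abort("need at least 10 participants")
  # canonical row order so the diagnostics are exactly invariant to
  # participant order
  x <- x[do.call(order, as.data.frame(x)), , drop = FALSE]

  withr::with_seed(seed, {
    hop <- hopkins_statistic(x, m = min(nrow(x) - 1L, n_ref))
    d <- dist(x)
    sil <- purrr::map_dfr(k_grid, function(k) {
      km <- kmeans(x, centers = k, nstart = 10, iter.max = 50)
      sw <- cluster::silhouette(km$cluster, d)
      tibble::tibble(k = k, silhouette = mean(sw[, "sil_width"]))
    })
  })

  best <- which.max(sil$silhouette)
  structure(
    list(hopkins = hop, silhouette = sil,
         silhouette_best = sil$silhouette[best], best_k = sil$k[best],
         n = nrow(x), k_grid = k_grid, n_ref = n_ref, seed = seed),
    class = "li_clusterability"
  )
}

# Hopkins statistic, power-1 distance variant: m uniform points on the
# data bounding box and m sampled data points; H = sum(u) / (sum(u) +
# sum(w)) where u are reference-to-data and w are data-to-data (self
# excluded) nearest-neighbour distances. ~0.5 under spatial randomness.
hopkins_statistic <- function(x, m) {
  n <- nrow(x)
  p <- ncol(x)
  rng <- apply(x, 2, range)
  ref <- matrix(runif(m * p, rng[1, ], rng[2, ]), m, p, byrow = TRUE)
  idx <- sample(n, m, replace = m > n)

  nn_dist <- function(a, b, exclude_self = FALSE) {
    # nearest neighbour in b for each row of a
    vapply(seq_len(nrow(a)), function(i) {
      d2 <- colSums((t(b) - a[i, ])^2)
      if (exclude_self) d2[d2 < .Machine$double.eps] <- Inf
      sqrt(min(d2))
    }, numeric(1))
  }

  u <- nn_dist(ref, x)
  w <- nn_dist(x[idx, , drop = FALSE], x, exclude_self = TRUE)
  sum(u) / (sum(u) + sum(w))
}

#' @exportS3Method base::print
print.li_clusterability <- function(x, ...) {
  cat("Clustering tendency of LI profiles (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  Hopkins statistic: %.3f (0.5 = unstructured)\n", x$hopkins))
  cat(sprintf("  best silhouette: %.3f at k = %d\n",
              x$silhouette_best, x$best_k))
  invisible(x)
}
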