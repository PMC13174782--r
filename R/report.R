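#' End-to-end analysis report
#'
#' Chains every stage of the pipeline on a cohort — per-participant LI,
#' Bayesian lateralisation table, the 24-test variability family, the
#' manifold embedding with clusterability diagnostics — and writes the
#' results as plain-text files plus a run manifest sufficient to
#' regenerate every number: `li.tsv`, `bayes.tsv`, `vi_results.tsv`,
#' `embedding.tsv`, `clusterability.json`, `manifest.json`.
#'
#' @param cohort A cohort table, or `NULL` to simulate from `config`.
#' @param config A [cohort_config()] used when `cohort` is `NULL` (its
#'   seed drives the simulation).
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed for the analysis stages (permutation
#'   substreams, embedding, clusterability).
#' @param n_perm Permutations per variability test.
#' @param embed Run the embedding/clusterability stage (needs more
#'   participants than the UMAP neighbourhood size).
#' @param ... Passed to [bf_li()].
#' @return Invisibly, a named list of output paths.
#' @export
run_report <- function(cohort = NULL, config = NULL, out_dir,
                       seed = 1L, n_perm = 10000L, embed = TRUE, ...) {
  if (is.null(cohort)) {
    if (is.null(config)) abort("provide a cohort or a config")
    message("simulating cohort (n = ", config$n_participants, ")")
    cohort <- simulate_cohort(config)
  }
  cohort <- validate_cohort(cohort)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  li <- li_table(cohort)
  paths$li <- file.path(out_dir, "li.tsv")
  readr::write_tsv(li, paths$li, na = "NA")

  dropped <- attr(li_matrix(cohort), "dropped_participants")
  if (length(dropped)) {
    message("listwise exclusion drops ", length(dropped),
            " participant(s): ", paste(dropped, collapse = ", "))
  }

  excluded_tracts <- li |>
    dplyr::group_by(.data$tract) |>
    dplyr::summarise(all_missing = all(is.na(.data$li)), .groups = "drop") |>
    dplyr::filter(.data$all_missing)
  if (nrow(excluded_tracts)) {
    message("tract(s) with no complete pairs excluded from inference: ",
            paste(excluded_tracts$tract, collapse = ", "))
  }

  message("Bayesian lateralisation tests (21 features)")
  bayes <- bayes_li(li, ...)
  paths$bayes <- file.path(out_dir, "bayes.tsv")
  readr::write_tsv(bayes, paths$bayes, na = "NA")

  message("variability-index permutation family (24 tests, n_perm = ",
          n_perm, ")")
  vi <- vi_family_analysis(cohort, n_perm = n_perm, seed = seed)
  paths$vi <- file.path(out_dir, "vi_results.tsv")
  readr::write_tsv(vi, paths$vi, na = "NA")

  if (embed) {
    message("manifold embedding and clusterability")
    mat <- li_matrix(cohort)
    emb <- embed_li(mat, seed = derive_seed(seed, "embed"))
    paths$embedding <- file.path(out_dir, "embedding.tsv")
    readr::write_tsv(tibble::as_tibble(emb), paths$embedding)
    clus <- clusterability(mat, seed = derive_seed(seed, "clusterability"))
    paths$clusterability <- file.path(out_dir, "clusterability.json")
    jsonlite::write_json(
      list(hopkins = clus$hopkins,
           silhouette_best = clus$silhouette_best,
           best_k = clus$best_k,
           silhouette_by_k = as.data.frame(clus$silhouette)),
      paths$clusterability, auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    package = "hemilat",
    version = as.character(utils::packageVersion("hemilat")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    master_seed = seed,
    n_perm = n_perm,
    cohort_digest = rlang::hash(cohort),
    config = if (!is.null(config)) {
      list(seed = config$seed, n_participants = config$n_participants,
           digest = rlang::hash(config))
    },
    substreams = list(
      vi_family = "derive_seed(seed, c(tract, metric)) per test",
      embedding = derive_seed(seed, "embed"),
      clusterability = derive_seed(seed, "clusterability")),
    outputs = lapply(paths, function(p) {
      list(file = basename(p),
           digest = rlang::hash(readLines(p, warn = FALSE)))
    }))
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}
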