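#' Pipeline configuration
#'
#' Collects every tunable of the analysis with its default: cohort rules
#' (multimorbidity count, age window, rare-disease threshold), embedding
#' parameters, fuzzy k-means parameters, the cluster-count selection range,
#' the membership threshold, sub-clustering controls and the master seed.
#' All stage seeds are derived deterministically from the master seed via
#' [stage_seed()].
#'
#' @param min_diseases Multimorbidity filter: minimum diseases per patient.
#' @param age_min,age_max Inclusive study age window in years.
#' @param rare_threshold Prevalence below which a disease is excluded.
#' @param perplexity t-SNE perplexity (`"auto"` = `min(10, floor((K-1)/3))`).
#' @param tsne_iter t-SNE gradient iterations.
#' @param m Fuzzifier of the fuzzy k-means objective.
#' @param tol Fuzzy k-means convergence tolerance (Frobenius norm of the
#'   membership change).
#' @param max_iter Fuzzy k-means iteration cap per restart.
#' @param n_init Fuzzy k-means random restarts.
#' @param g_min,g_max Cluster-count selection range (`g_max` is clipped to
#'   K - 1 per population).
#' @param n_restarts Hard k-means restarts during selection.
#' @param threshold Membership threshold for hard assignment, `[0.5, 1)`.
#' @param n_clusters Optional fixed G, bypassing selection.
#' @param subcluster Whether to sub-cluster each macro cluster (depth 1).
#' @param subcluster_min Minimum assigned diseases for a cluster to be
#'   sub-clustered; smaller clusters are skipped and logged.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(min_diseases = 2L, age_min = 25L, age_max = 100L,
                            rare_threshold = 5e-4,
                            perplexity = "auto", tsne_iter = 1000L,
                            m = 2, tol = 1e-6, max_iter = 500L, n_init = 10L,
                            g_min = 2L, g_max = 6L, n_restarts = 10L,
                            threshold = 0.5, n_clusters = NULL,
                            subcluster = TRUE, subcluster_min = 4L,
                            seed = 1L) {
  cfg <- list(min_diseases = as.integer(min_diseases),
              age_min = as.integer(age_min), age_max = as.integer(age_max),
              rare_threshold = rare_threshold, perplexity = perplexity,
              tsne_iter = as.integer(tsne_iter), m = m, tol = tol,
              max_iter = as.integer(max_iter), n_init = as.integer(n_init),
              g_min = as.integer(g_min), g_max = as.integer(g_max),
              n_restarts = as.integer(n_restarts), threshold = threshold,
              n_clusters = if (!is.null(n_clusters)) as.integer(n_clusters),
              subcluster = isTRUE(subcluster),
              subcluster_min = as.integer(subcluster_min),
              seed = as.integer(seed))
  stopifnot(cfg$min_diseases >= 1, cfg$age_min <= cfg$age_max,
            cfg$rare_threshold >= 0, cfg$m > 1, cfg$tol > 0,
            cfg$threshold >= 0.5, cfg$threshold < 1,
            cfg$g_min >= 2, cfg$g_min <= cfg$g_max)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Keys not present fall back to the [pipeline_config()] defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, vals)
}

#' Run the full clustering analysis on one population
#'
#' Executes, on an already multimorbidity-filtered population: rare-disease
#' exclusion, the Jaccard co-occurrence distance, the 2-D t-SNE embedding,
#' elbow/silhouette cluster-count selection, the fuzzy k-means fit, the 0.5
#' membership thresholding, sub-clustering of each macro cluster (depth 1),
#' and the prevalence report. All stage seeds derive from the master seed
#' and the population label, and a manifest records every parameter plus
#' fingerprints of the intermediate artifacts, so identical inputs give
#' byte-identical outputs.
#'
#' @param x An `occurrence_matrix`, already passed through
#'   [filter_multimorbid()].
#' @param config A [pipeline_config()].
#' @param label Population label used in logs, seeds and reports.
#' @param .stratum Optional [stratum()] recorded in the solution.
#' @return A `cluster_solution`: `label`, `stratum`, `excluded_rare`,
#'   `exclusion_report`, `distance`, `embedding`, `selection`, `fkm`,
#'   `clusters` (cluster id -> disease codes), `not_assigned` (codes plus
#'   their membership rows), `subclusters`, `skipped_subclusters`,
#'   `prevalence` and `manifest`.
#' @export
run_population <- function(x, config = pipeline_config(),
                           label = "population", .stratum = NULL) {
  stopifnot(inherits(x, "occurrence_matrix"),
            inherits(config, "pipeline_config"))
  step <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", label, "/", stage, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  er <- step("exclude_rare", exclude_rare(x, config$rare_threshold))
  mat <- er$matrix
  k <- ncol(mat$values)
  if (k < 4) {
    stop("[", label, "] only ", k, " diseases remain after rare-disease ",
         "exclusion; at least 4 are needed for the embedding", call. = FALSE)
  }
  d <- step("distance", jaccard_distance_matrix(mat))
  emb <- step("embedding",
              embed_2d(d, perplexity = config$perplexity,
                       seed = stage_seed(config$seed, "embedding", label),
                       n_iter = config$tsne_iter))
  g_max <- min(config$g_max, k - 1L)
  if (g_max < config$g_max) {
    message("[", label, "] selection range clipped to [", config$g_min,
            ", ", g_max, "] (K = ", k, ")")
  }
  if (is.null(config$n_clusters)) {
    sel <- step("selection",
                select_num_clusters(emb, g_min = min(config$g_min, g_max),
                                    g_max = g_max,
                                    n_restarts = config$n_restarts,
                                    seed = stage_seed(config$seed,
                                                      "selection", label)))
    g <- sel$G_best
  } else {
    sel <- NULL
    g <- min(config$n_clusters, k)
  }
  fit <- step("fkm",
              fkm_fit(emb, G = g, m = config$m, tol = config$tol,
                      max_iter = config$max_iter,
                      seed = stage_seed(config$seed, "fkm", label),
                      n_init = config$n_init, threshold = config$threshold))

  codes <- colnames(mat$values)
  labels <- fit$hard_labels
  clusters <- lapply(seq_len(g), function(gg) codes[!is.na(labels) &
                                                      labels == gg])
  names(clusters) <- as.character(seq_len(g))
  na_codes <- fit$not_assigned
  not_assigned <- list(codes = na_codes,
                       memberships = fit$memberships[na_codes, ,
                                                     drop = FALSE])

  solution <- structure(
    list(label = label, stratum = .stratum, excluded_rare = er$excluded,
         exclusion_report = er$report, matrix_dim = dim(mat$values),
         distance = d, embedding = emb, selection = sel, fkm = fit,
         clusters = clusters, not_assigned = not_assigned,
         subclusters = list(), skipped_subclusters = character(0),
         config = config),
    class = "cluster_solution")

  if (config$subcluster) {
    for (gg in names(clusters)) {
      sub <- subcluster(solution, gg, mat, config)
      if (is.null(sub)) {
        solution$skipped_subclusters <- c(solution$skipped_subclusters, gg)
      } else {
        solution$subclusters[[gg]] <- sub
      }
    }
  }

  solution$prevalence <- step("prevalence", compute_prevalence(mat, solution))
  solution$manifest <- list(
    package = as.character(utils::packageVersion("morbclust")),
    label = label,
    stratum = if (!is.null(.stratum)) format(.stratum),
    config = unclass(config),
    seeds = list(embedding = stage_seed(config$seed, "embedding", label),
                 selection = stage_seed(config$seed, "selection", label),
                 fkm = stage_seed(config$seed, "fkm", label)),
    n_patients = nrow(mat$values), n_diseases = k, G = g,
    excluded_rare = er$excluded,
    fingerprints = list(occurrence = fingerprint(mat$values),
                        distance = fingerprint(d),
                        embedding = fingerprint(emb),
                        memberships = fingerprint(fit$memberships)))
  solution
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("<cluster_solution> ", x$label, ": ", x$matrix_dim[1], " patients, ",
      x$matrix_dim[2], " diseases in ", length(x$clusters), " clusters (",
      length(x$not_assigned$codes), " not assigned, ",
      length(x$excluded_rare), " rare excluded)\n", sep = "")
  for (g in names(x$clusters)) {
    cat("  cluster ", g, " [",
        sprintf("%.2f%%", 100 * x$prevalence$cluster_prevalence[[g]]),
        "]: ", paste(x$clusters[[g]], collapse = ", "), "\n", sep = "")
  }
  if (length(x$not_assigned$codes)) {
    cat("  not assigned: ", paste(x$not_assigned$codes, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Sub-cluster one macro cluster
#'
#' Repeats the full procedure on the column-submatrix of the occurrence
#' matrix restricted to the cluster's assigned diseases, keeping all
#' patients of the population (so prevalence denominators are unchanged).
#' Clusters with fewer than `config$subcluster_min` assigned diseases are
#' skipped with a log message (`NULL` returned). Recursion stops at depth 1:
#' the sub-analysis does not sub-cluster again.
#'
#' @param solution A `cluster_solution`.
#' @param cluster_id Cluster id (name in `solution$clusters`).
#' @param matrix The population's analysed `occurrence_matrix` (post
#'   rare-exclusion).
#' @param config The [pipeline_config()].
#' @return A `cluster_solution` for the sub-analysis, or `NULL` if skipped.
#' @export
subcluster <- function(solution, cluster_id, matrix, config) {
  codes <- solution$clusters[[as.character(cluster_id)]]
  if (is.null(codes)) stop("no cluster ", cluster_id, " in solution")
  if (length(codes) < config$subcluster_min) {
    message("[", solution$label, "] cluster ", cluster_id, " has ",
            length(codes), " diseases (< ", config$subcluster_min,
            "); sub-clustering skipped")
    return(NULL)
  }
  sub_mat <- om_subset(matrix, cols = match(codes, colnames(matrix$values)))
  sub_cfg <- config
  sub_cfg$subcluster <- FALSE
  sub_cfg$n_clusters <- NULL
  run_population(sub_mat, sub_cfg,
                 label = paste0(solution$label, "/sub", cluster_id),
                 .stratum = solution$stratum)
}

#' Prevalence report for a cluster solution
#'
#' Cluster prevalence is the share of the multimorbid population counted as
#' belonging to that disease cluster. Since a patient typically carries
#' diseases from several clusters, each patient is counted in exactly one:
#' the cluster containing the plurality of the patient's assigned-cluster
#' diseases, ties broken by the larger sum of those diseases' membership
#' degrees, then by the lowest cluster index. Patients carrying no assigned
#' disease are counted in none, so cluster prevalences sum to at most 1.
#' Not-assigned diseases take no part in patient counting. Disease-specific
#' prevalence is the column sum over the population size. Sub-cluster
#' prevalences are computed identically inside each sub-solution, whose
#' patient set is the whole population.
#'
#' @param matrix The analysed `occurrence_matrix` (post rare-exclusion).
#' @param solution A `cluster_solution` (or a list with `clusters`, `fkm`
#'   and optionally `subclusters`).
#' @return A `prevalence_report`: `cluster_prevalence`,
#'   `subcluster_prevalence`, `disease_prevalence`, `population_size` and
#'   the per-patient assignment `patient_cluster` (`NA` = counted in none).
#' @export
compute_prevalence <- function(matrix, solution) {
  v <- matrix$values
  codes <- colnames(v)
  clusters <- solution$clusters
  u <- solution$fkm$memberships
  stopifnot(setequal(rownames(u), codes))
  u <- u[codes, , drop = FALSE]
  n <- nrow(v)
  g <- length(clusters)
  ind <- vapply(clusters, function(cc) codes %in% cc, logical(length(codes)))
  ind <- matrix(ind, nrow = length(codes))
  counts <- v %*% ind                       # assigned diseases per cluster
  wsum <- v %*% (u[, seq_len(g), drop = FALSE] * ind)
  best <- do.call(pmax, c(lapply(seq_len(g), function(j) counts[, j]),
                          list(0)))
  assigned <- best > 0
  key <- ifelse(counts == best, wsum, -Inf)
  pick <- max.col(key, ties.method = "first")
  patient_cluster <- ifelse(assigned, pick, NA_integer_)
  cl_prev <- vapply(seq_len(g),
                    function(gg) sum(patient_cluster == gg, na.rm = TRUE) / n,
                    0)
  names(cl_prev) <- names(clusters)
  sub_prev <- lapply(solution$subclusters,
                     function(s) s$prevalence$cluster_prevalence)
  structure(list(cluster_prevalence = cl_prev,
                 subcluster_prevalence = sub_prev,
                 disease_prevalence = colSums(v) / n,
                 population_size = n,
                 patient_cluster = patient_cluster),
            class = "prevalence_report")
}

#' @export
print.prevalence_report <- function(x, ...) {
  cat("<prevalence_report> N = ", x$population_size, "; cluster prevalence: ",
      paste(sprintf("%s = %.2f%%", names(x$cluster_prevalence),
                    100 * x$cluster_prevalence), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Run the analysis on the whole population and all canonical strata
#'
#' Builds and multimorbidity-filters the cohort, then runs
#' [run_population()] on the whole population and on each of the eight
#' sex-by-age strata. Empty or degenerate strata (too few patients or
#' diseases for the procedure) are skipped with a log message.
#'
#' @param records Long records data frame (see [build_matrix()]) or an
#'   `occurrence_matrix`.
#' @param config A [pipeline_config()].
#' @return Named list of `cluster_solution`s, `"all/all"` first, then the
#'   strata; skipped strata are absent, with reasons in the
#'   `skipped` attribute.
#' @export
run_strata <- function(records, config = pipeline_config()) {
  x <- if (inherits(records, "occurrence_matrix")) records else
    build_matrix(records)
  x <- filter_multimorbid(x, config$min_diseases, config$age_min,
                          config$age_max)
  pops <- c(list(`all/all` = stratum("all", "all")), canonical_strata())
  out <- list()
  skipped <- character(0)
  for (nm in names(pops)) {
    sx <- stratify(x, pops[[nm]])
    if (nrow(sx$values) == 0) {
      message("[", nm, "] empty stratum; skipped")
      skipped[nm] <- "empty stratum"
      next
    }
    sol <- tryCatch(run_population(sx, config, label = nm,
                                   .stratum = pops[[nm]]),
                    error = function(e) {
                      message("[", nm, "] skipped: ", conditionMessage(e))
                      skipped[nm] <<- conditionMessage(e)
                      NULL
                    })
    if (!is.null(sol)) out[[nm]] <- sol
  }
  attr(out, "skipped") <- skipped
  out
}
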