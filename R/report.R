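#' Write a cluster solution's artifacts to a directory
#'
#' Emits, per population: the distance matrix CSV, the embedded coordinates
#' CSV (`disease_code,x,y`), the membership CSV (one column per cluster plus
#' `assigned_cluster`, `NA` where not assigned), the rare-exclusion report
#' CSV, a cluster report JSON (clusters, sub-clusters, not-assigned,
#' prevalences) and the run manifest JSON. Sub-solutions recurse into
#' `sub_<id>/` subdirectories. All content is deterministic: rerunning with
#' the same config and master seed reproduces every file byte for byte.
#'
#' @param solution A `cluster_solution`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_solution <- function(solution, dir) {
  stopifnot(inherits(solution, "cluster_solution"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)

  write_distance_csv(solution$distance, fp("distance.csv"))

  emb <- solution$embedding
  write.csv(data.frame(disease_code = rownames(emb),
                       x = .fmt_full(emb[, 1]), y = .fmt_full(emb[, 2]),
                       stringsAsFactors = FALSE),
            fp("coords.csv"), row.names = FALSE, quote = FALSE)

  u <- solution$fkm$memberships
  mdf <- data.frame(disease_code = rownames(u),
                    apply(u, 2, .fmt_full),
                    assigned_cluster = solution$fkm$hard_labels,
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(mdf)[2:(ncol(u) + 1)] <- paste0("cluster_", seq_len(ncol(u)))
  write.csv(mdf, fp("membership.csv"), row.names = FALSE, quote = FALSE)

  write.csv(solution$exclusion_report, fp("exclusions.csv"),
            row.names = FALSE, quote = FALSE)

  report <- list(
    label = solution$label,
    population_size = solution$prevalence$population_size,
    clusters = solution$clusters,
    not_assigned = solution$not_assigned$codes,
    excluded_rare = solution$excluded_rare,
    cluster_prevalence = as.list(solution$prevalence$cluster_prevalence),
    subcluster_prevalence = lapply(solution$prevalence$subcluster_prevalence,
                                   as.list),
    disease_prevalence = as.list(solution$prevalence$disease_prevalence),
    skipped_subclusters = solution$skipped_subclusters)
  jsonlite::write_json(report, fp("clusters.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  jsonlite::write_json(solution$manifest, fp("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")

  for (g in names(solution$subclusters)) {
    write_solution(solution$subclusters[[g]], file.path(dir, paste0("sub_", g)))
  }
  invisible(dir)
}
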