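#' Configuration of an end-to-end pipeline run
#'
#' @param features_csv,survival_csv Input paths (the `features.csv` /
#'   `survival.csv` dialect); ignored when `cohort` is supplied directly to
#'   [run_pipeline()].
#' @param output_dir Directory for artifacts (created if needed).
#' @param missing_threshold Feature-screen cutoff, default 0.40.
#' @param mapper A [mapper_config()].
#' @param k_phenogroups Target phenogroup count, default 5.
#' @param endpoint `"all_cause_death"` or `"composite"`.
#' @param adjustment Covariate set for the multivariable device models,
#'   `"af"` (age, sex, atrial fibrillation, ventricular arrhythmia) or
#'   `"etiology"` (etiology in place of atrial fibrillation).
#' @param arr_horizons Yearly horizons for the absolute-risk-reduction
#'   table.
#' @param seed Integer seed governing the Louvain node order.
#' @return An object of class `run_config`.
#' @export
run_config <- function(features_csv = NULL, survival_csv = NULL,
                       output_dir = tempfile("crtpheno_run_"),
                       missing_threshold = 0.40,
                       mapper = mapper_config(),
                       k_phenogroups = 5,
                       endpoint = "all_cause_death",
                       adjustment = "af",
                       arr_horizons = 1:10,
                       seed = 1L) {
  structure(
    list(features_csv = features_csv, survival_csv = survival_csv,
         output_dir = output_dir, missing_threshold = missing_threshold,
         mapper = mapper, k_phenogroups = as.integer(k_phenogroups),
         endpoint = endpoint, adjustment = adjustment,
         arr_horizons = arr_horizons, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Check the arithmetic consistency of a run report's counts
#'
#' Two invariants tie the stage counts of a network run together: the
#' patients in the network equal the cohort minus the outliers, and the sum
#' of phenogroup sizes minus the doubly-assigned patients equals the network
#' size again (valid when no patient carries three or more labels).
#'
#' @param total_patients Cohort size.
#' @param outlier_patients Patients only in disconnected nodes.
#' @param network_patients Patients in the main network.
#' @param phenogroup_sizes Integer vector of per-group patient counts.
#' @param doubly_assigned Patients belonging to exactly two phenogroups.
#' @return A list with logical `network_count_ok`, `phenogroup_count_ok`
#'   and `ok` (both).
#' @export
check_report_counts <- function(total_patients, outlier_patients,
                                network_patients, phenogroup_sizes,
                                doubly_assigned) {
  c1 <- (total_patients - outlier_patients) == network_patients
  c2 <- (sum(phenogroup_sizes) - doubly_assigned) == network_patients
  list(network_count_ok = c1, phenogroup_count_ok = c2, ok = c1 && c2)
}

#' Percentage as printed in a clinical table
#'
#' @param num,den Counts.
#' @param digits Decimal places, default 0.
#' @return `round(100 * num / den, digits)`.
#' @export
count_percent <- function(num, den, digits = 0) {
  round(100 * num / den, digits)
}

#' Run the phenogrouping pipeline end to end
#'
#' Feature screen, mean imputation and z-scoring; normalized-correlation
#' distances and the two MDS lenses; the Mapper network; outlier removal,
#' Louvain autogrouping and the merge to `k` phenogroups; then the survival
#' layer (per-arm Kaplan-Meier summaries, the yearly absolute-risk-reduction
#' table, and device-effect Cox models overall and per phenogroup). Writes
#' GraphML, the assignment CSV, KM/ARR/Cox CSV tables and a JSON run
#' report; identical inputs and seed give identical reports.
#'
#' @param cfg A [run_config()].
#' @param cohort Optional in-memory cohort (list with `features` and
#'   `survival`) overriding the CSV paths in `cfg`.
#' @return The run report, invisibly a list: stage counts
#'   (`n_patients`, `features_discarded`, `n_outliers`,
#'   `n_network_patients`, `n_nodes`, `n_edges`, `n_autogroups`,
#'   `n_phenogroups`, `n_multi_label`, `phenogroup_sizes`), the count
#'   consistency checks, follow-up quantiles, and the fitted result objects
#'   (`arr`, `cox`, `cox_by_group`, `groups`, `assignment`).
#' @export
run_pipeline <- function(cfg, cohort = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cohort)) {
    cohort <- list(features = read_features(cfg$features_csv),
                   survival = utils::read.csv(cfg$survival_csv,
                                              stringsAsFactors = FALSE,
                                              na.strings = ""))
    cohort$survival$patient_id <- as.character(cohort$survival$patient_id)
    cohort$survival$event <- as.logical(cohort$survival$event)
  }
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "preprocess"
  report <- tryCatch({
    prep <- preprocess(cohort$features, cfg$missing_threshold)

    stage <- "distance_lens"
    d <- normalized_correlation_distance(prep$matrix)
    lens <- mds_lenses(d)
    write_lenses(lens, file.path(cfg$output_dir, "lenses.csv"))

    stage <- "mapper"
    mg <- build_mapper(lens, d, cfg$mapper)

    stage <- "phenogroup"
    ro <- remove_outliers(mg)
    main <- ro$graph
    part <- louvain_autogroup(main, seed = cfg$seed)
    n_auto <- length(unique(part))
    k <- min(cfg$k_phenogroups, n_auto)
    groups <- merge_to_k(main, part, k)
    assignment <- assign_patients(groups)
    n_labels <- lengths(assignment)
    write_assignments(assignment, file.path(cfg$output_dir, "phenogroups.csv"))
    mort <- node_means(main, {
      ev <- cohort$survival$event[match(main$patient_ids,
                                        cohort$survival$patient_id)]
      as.numeric(ev)
    })
    glab <- integer(igraph::vcount(main$graph))
    for (g in groups) glab[g$node_set] <- g$label
    write_graphml(main, file.path(cfg$output_dir, "network.graphml"),
                  node_attrs = list(mortality = mort, phenogroup = glab))
    write_edge_list(main, file.path(cfg$output_dir, "edges.csv"))

    stage <- "survival"
    spec <- endpoint_spec(cfg$endpoint)
    net_ids <- names(assignment)
    recs <- cohort$survival[cohort$survival$patient_id %in% net_ids, ]
    surv_out <- survival_tables(recs, spec, cfg$adjustment, cfg$arr_horizons,
                                assignment, cfg$output_dir,
                                k_groups = length(groups))

    rep <- c(
      list(
        n_patients = nrow(cohort$features$values),
        features_discarded = prep$discarded,
        n_features_used = ncol(prep$matrix$values),
        n_nodes = igraph::vcount(main$graph),
        n_edges = igraph::ecount(main$graph),
        n_outliers = length(ro$outlier_patients),
        n_network_patients = length(assignment),
        n_autogroups = n_auto,
        n_phenogroups = length(groups),
        n_multi_label = sum(n_labels >= 2),
        phenogroup_sizes = vapply(groups, function(g) length(g$patient_set),
                                  integer(1)),
        phenogroups_connected = all(phenogroups_connected(main, groups)),
        seed = cfg$seed
      ),
      surv_out$report
    )
    rep$counts <- check_report_counts(
      rep$n_patients, rep$n_outliers, rep$n_network_patients,
      rep$phenogroup_sizes, sum(n_labels == 2)
    )
    rep$groups <- groups
    rep$assignment <- assignment
    rep$arr <- surv_out$arr
    rep$cox <- surv_out$cox
    rep$cox_by_group <- surv_out$cox_by_group
    rep
  }, error = function(e) {
    # remove partial artifacts so a failed run leaves no half-written state
    unlink(cfg$output_dir, recursive = TRUE)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  json_report <- report[!(names(report) %in%
                            c("groups", "assignment", "arr", "cox",
                              "cox_by_group"))]
  jsonlite::write_json(json_report,
                       file.path(cfg$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

# survival layer of the pipeline: KM summaries per arm, ARR table,
# device Cox overall and per phenogroup
survival_tables <- function(recs, spec, adjustment, horizons, assignment,
                            output_dir, k_groups) {
  te <- apply_endpoint(recs, spec)
  fu <- reverse_km(te$time, te$event)

  is_d <- recs$device == "CRT-D"
  arr <- NULL
  cox <- NULL
  if (length(unique(recs$device)) == 2) {
    km_p <- km_estimate(te$time[!is_d], te$event[!is_d])
    km_d <- km_estimate(te$time[is_d], te$event[is_d])
    arr <- arr_table(km_p, km_d, horizons)
    utils::write.csv(arr, file.path(output_dir, "arr_by_year.csv"),
                     row.names = FALSE)
    cox <- tryCatch(device_cox(recs, spec, adjustment),
                    error = function(e) NULL)
    km_summary <- do.call(rbind, lapply(
      list(`CRT-P` = km_p, `CRT-D` = km_d), function(cv) {
        data.frame(
          mortality_5y = 100 * (1 - km_at(cv, 5)),
          mortality_10y = 100 * (1 - km_at(cv, 10))
        )
      }
    ))
    km_summary$arm <- c("CRT-P", "CRT-D")
    utils::write.csv(km_summary, file.path(output_dir, "km_summary.csv"),
                     row.names = FALSE)
    if (!is.null(cox)) {
      utils::write.csv(cox$multivariable$coefficients,
                       file.path(output_dir, "cox_multivariable.csv"),
                       row.names = FALSE)
    }
  }

  cox_by_group <- NULL
  skip_reason <- NULL
  if (k_groups >= 2) {
    labels1 <- primary_labels(assignment)
    cox_by_group <- lapply(seq_len(k_groups), function(lab) {
      ids <- names(labels1)[labels1 == lab]
      sub <- recs[recs$patient_id %in% ids, ]
      if (length(unique(sub$device)) < 2) return(NULL)
      tryCatch(device_cox(sub, spec, adjustment), error = function(e) NULL)
    })
  } else {
    skip_reason <- "fewer than 2 phenogroups: between-group survival comparison skipped"
  }

  list(
    report = list(
      followup_median = fu$median, followup_q25 = fu$q25,
      followup_q75 = fu$q75,
      n_events = sum(te$event),
      survival_comparison_skipped = skip_reason
    ),
    arr = arr, cox = cox, cox_by_group = cox_by_group
  )
}
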