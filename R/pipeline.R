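#' Analysis configuration for the cohort pipeline
#'
#' @param preprocess An `fc_preproc_config`.
#' @param taus Threshold sweep grid.
#' @param threshold_scale `"r"` or `"z"` (see [threshold_graph()]).
#' @param null_M Nulls per threshold for small-worldness (0 disables).
#' @param lp_convention Disconnected-graph Lp convention for the sweep
#'   (see [metric_curves()]).
#' @param seed Seed for null ensembles.
#' @param t_variant `"student"` or `"welch"`.
#' @param fdr_method `"BH"` or `"BY"`.
#' @param alpha_edge FDR level of the edgewise comparison.
#' @param alpha_metric Significance level for metric comparisons.
#' @param gate_correlations Correlate only metrics whose group comparison
#'   is significant (mirrors the confirmatory design); disable for
#'   exploratory runs.
#' @param auc_rule Quadrature rule for AUC summaries.
#' @return A list of class `fc_run_config`.
#' @export
run_config <- function(preprocess = preprocess_config(),
                       taus = seq(0.40, 0.90, by = 0.05),
                       threshold_scale = "r",
                       null_M = 100, lp_convention = "harmonic", seed = 1,
                       t_variant = "student", fdr_method = "BH",
                       alpha_edge = 0.01, alpha_metric = 0.05,
                       gate_correlations = TRUE,
                       auc_rule = "trapezoid") {
  structure(as.list(environment()), class = "fc_run_config")
}

#' Run the full group analysis on a cohort
#'
#' Per subject: preprocessing (with motion-based exclusion), the 50-node
#' connectivity matrix, the edge-count profile and the metric curves and
#' AUCs over the threshold sweep. Then, at the group level: group-mean z
#' matrices, edgewise comparison with FDR correction, two-sample t-tests on
#' the global metric AUCs, FDR-corrected t-tests on the region-averaged
#' nodal AUCs, and Pearson correlations between the (significant, unless
#' ungated) region-averaged nodal metrics and the six CRS-R subscales and
#' total within the patient group.
#'
#' @param cohort An `fc_cohort` from [generate_cohort()], or a list with
#'   components `raw` (named list of `fc_raw`) and `clinical` (tibble in
#'   the clinical-table schema with `id` and `group`).
#' @param atlas An `fc_atlas`.
#' @param config An `fc_run_config`.
#' @return A list of class `fc_results`; see Details.
#' @details The result carries: `subjects` (per-subject status tibble),
#'   `connectivity` (named list of `fc_conn`), `edge_profiles` (tidy tibble),
#'   `edge_summary` (per-subject mean edge count), `global_auc` and
#'   `nodal_roi_auc` (tidy AUC tibbles), `group_mean_z` (list of matrices),
#'   `demographics`, `edgewise`, `global_comparison`, `nodal_comparison`,
#'   `correlations`, and a stage `log`.
#' @examples
#' \donttest{
#' cfg <- synth_config(n_hc = 3, n_mcs = 3, duration_s = 150, seed = 2)
#' cohort <- generate_cohort(cfg)
#' res <- run_cohort_pipeline(cohort, config = run_config(null_M = 0))
#' res$global_comparison
#' }
#' @export
run_cohort_pipeline <- function(cohort, atlas = default_atlas(),
                                config = run_config()) {
  stopifnot(inherits(config, "fc_run_config"))
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))
  clinical <- as_tibble(cohort$clinical)
  ids <- names(cohort$raw)
  groups <- clinical$group[match(ids, clinical$id)]
  if (anyNA(groups)) abort("clinical table does not cover every recording")

  note("pipeline: %d subjects (%s)", length(ids),
       paste(sprintf("%s=%d", names(table(groups)), table(groups)),
             collapse = ", "))

  pp <- map(cohort$raw, run_preprocess, config = config$preprocess)
  excluded <- vapply(pp, `[[`, logical(1), "excluded")
  for (i in which(excluded)) {
    note("excluded %s: %s", ids[i], pp[[i]]$exclusion_reason)
  }
  keep <- !excluded
  if (sum(keep & groups == "HC") < 2 || sum(keep & groups == "MCS") < 2) {
    abort("fewer than 2 usable subjects in a group after exclusion")
  }

  conn <- map(pp[keep], function(p) build_connectivity(p$hemo, atlas))
  kids <- ids[keep]; kgroups <- groups[keep]
  note("connectivity: %d matrices of %d nodes", length(conn),
       length(conn[[1]]$nodes))

  profiles <- imap(conn, function(cn, id) {
    ep <- edge_profile(cn, config$taus, scale = config$threshold_scale)
    mutate(ep, id = id, .before = 1)
  })
  edge_profiles <- bind_rows(profiles) %>%
    left_join(tibble(id = kids, group = kgroups), by = "id")
  edge_summary <- edge_profiles %>%
    group_by(.data$id, .data$group) %>%
    summarise(mean_edges = mean(.data$n_edges), .groups = "drop")

  curves <- imap(conn, function(cn, id) {
    metric_curves(cn, config$taus, null_M = config$null_M,
                  seed = config$seed + match(id, kids),
                  scale = config$threshold_scale,
                  lp_convention = config$lp_convention,
                  auc_rule = config$auc_rule)
  })
  global_auc <- bind_rows(imap(curves, function(cv, id) {
    mutate(cv$global_auc, id = id, .before = 1)
  })) %>% left_join(tibble(id = kids, group = kgroups), by = "id")
  nodal_roi_auc <- bind_rows(imap(curves, function(cv, id) {
    mutate(roi_average(cv$nodal_auc, atlas), id = id, .before = 1)
  })) %>% left_join(tibble(id = kids, group = kgroups), by = "id")
  note("metrics: AUC over %d thresholds (%g..%g), %d nulls per threshold",
       length(config$taus), min(config$taus), max(config$taus),
       config$null_M)

  group_mean_z <- lapply(split(conn, kgroups), group_mean_matrix)

  demographics <- tryCatch(demographics_summary(clinical),
                           error = function(e) NULL)

  edgewise <- edgewise_comparison(
    conn[kgroups == "HC"], conn[kgroups == "MCS"],
    alpha = config$alpha_edge, variant = config$t_variant)
  note("edgewise: %d significant connection(s) at FDR %g",
       sum(edgewise$significant), config$alpha_edge)

  global_comparison <- global_auc %>%
    tidyr::pivot_wider(names_from = "group", values_from = "auc") %>%
    group_by(.data$metric) %>%
    summarise(comp = list(two_sample_t(
      .data$HC[!is.na(.data$HC)], .data$MCS[!is.na(.data$MCS)],
      variant = config$t_variant)), .groups = "drop")
  global_comparison <- bind_rows(
    map2(global_comparison$comp, global_comparison$metric,
         function(cmp, m) mutate(cmp, variable = m))) %>%
    mutate(significant = .data$p_value < config$alpha_metric)

  nodal_comparison <- nodal_roi_auc %>%
    group_by(.data$metric, .data$region) %>%
    summarise(comp = list(two_sample_t(
      .data$value[.data$group == "HC"], .data$value[.data$group == "MCS"],
      variant = config$t_variant)), .groups = "drop")
  nodal_comparison <- bind_rows(pmap(
    nodal_comparison,
    function(metric, region, comp) {
      mutate(comp, variable = paste(metric, region, sep = ":"),
             metric = metric, region = region)
    }))
  nodal_comparison <- nodal_comparison %>%
    group_by(.data$metric) %>%
    mutate(p_adj = p.adjust(.data$p_value, method = config$fdr_method)) %>%
    ungroup() %>%
    mutate(significant = .data$p_adj < config$alpha_metric)
  note("nodal: %d significant region comparison(s) after %s",
       sum(nodal_comparison$significant), config$fdr_method)

  mcs_scores <- clinical %>%
    filter(.data$group == "MCS", .data$id %in% kids)
  corr_targets <- if (config$gate_correlations) {
    nodal_comparison %>% filter(.data$significant)
  } else {
    nodal_comparison
  }
  correlations <- NULL
  if (nrow(corr_targets) > 0 && nrow(mcs_scores) >= 3) {
    scales <- c(crsr_subscales, "crsr_total")
    correlations <- bind_rows(lapply(seq_len(nrow(corr_targets)), function(k) {
      vals <- nodal_roi_auc %>%
        filter(.data$metric == corr_targets$metric[k],
               .data$region == corr_targets$region[k],
               .data$group == "MCS")
      vals <- vals[match(mcs_scores$id, vals$id), ]
      bind_rows(lapply(scales, function(sc) {
        tryCatch(
          crsr_correlation(vals$value, mcs_scores[[sc]],
                           metric = paste(corr_targets$metric[k],
                                          corr_targets$region[k],
                                          sep = ":"),
                           scale = sc),
          error = function(e) NULL)
      }))
    }))
    note("correlations: %d metric x scale pairs", nrow(correlations))
  } else {
    note("correlations: skipped (no significant nodal metric or too few patients)")
  }

  structure(
    list(
      subjects = tibble(id = ids, group = unname(groups),
                        excluded = unname(excluded),
                        reason = unname(vapply(pp, `[[`, character(1),
                                               "exclusion_reason"))),
      connectivity = conn,
      edge_profiles = edge_profiles,
      edge_summary = edge_summary,
      global_auc = global_auc,
      nodal_roi_auc = nodal_roi_auc,
      group_mean_z = group_mean_z,
      demographics = demographics,
      edgewise = edgewise,
      global_comparison = global_comparison,
      nodal_comparison = nodal_comparison,
      correlations = correlations,
      config = config,
      log = log),
    class = "fc_results")
}

#' @export
print.fc_results <- function(x, ...) {
  cat(sprintf(
    "<fc_results> %d subjects (%d excluded); %d significant edges; %d significant nodal comparisons\n",
    nrow(x$subjects), sum(x$subjects$excluded),
    sum(x$edgewise$significant), sum(x$nodal_comparison$significant)))
  invisible(x)
}

#' Tidy the group-level comparison tables of a pipeline run
#'
#' @param x An `fc_results` object.
#' @param which One of `"global"`, `"nodal"`, `"edgewise"`,
#'   `"correlations"`.
#' @param ... Unused.
#' @return The requested tidy tibble.
#' @method tidy fc_results
#' @export
tidy.fc_results <- function(x, which = c("global", "nodal", "edgewise",
                                         "correlations"), ...) {
  which <- match.arg(which)
  switch(which,
         global = x$global_comparison,
         nodal = x$nodal_comparison,
         edgewise = x$edgewise,
         correlations = x$correlations %||% tibble())
}

#' One-row summary of a pipeline run
#'
#' @param x An `fc_results` object.
#' @param ... Unused.
#' @return A one-row tibble: subject counts, exclusions, significant edge
#'   and nodal counts, mean edge counts per group.
#' @method glance fc_results
#' @export
glance.fc_results <- function(x, ...) {
  es <- x$edge_summary %>%
    group_by(.data$group) %>%
    summarise(m = mean(.data$mean_edges), .groups = "drop")
  tibble(
    n_subjects = nrow(x$subjects),
    n_excluded = sum(x$subjects$excluded),
    n_significant_edges = sum(x$edgewise$significant),
    n_significant_nodal = sum(x$nodal_comparison$significant),
    mean_edges_hc = es$m[es$group == "HC"],
    mean_edges_mcs = es$m[es$group == "MCS"])
}

#' Write pipeline results as plain-text tables
#'
#' Emits the tidy result tables as TSV files (edge profiles, AUC tables,
#' comparisons, significant edges, correlations, subject status, group-mean
#' matrices) into a directory, together with the stage log.
#'
#' @param results An `fc_results` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, name) {
    if (!is.null(x)) {
      readr::write_tsv(as_tibble(x), file.path(dir, name), progress = FALSE)
    }
  }
  wt(results$subjects, "subjects.tsv")
  wt(results$edge_profiles, "edge_profiles.tsv")
  wt(results$edge_summary, "edge_summary.tsv")
  wt(results$global_auc, "global_auc.tsv")
  wt(results$nodal_roi_auc, "nodal_roi_auc.tsv")
  wt(results$demographics, "demographics.tsv")
  wt(results$global_comparison, "global_comparison.tsv")
  wt(results$nodal_comparison, "nodal_comparison.tsv")
  wt(results$edgewise[results$edgewise$significant, ],
     "significant_edges.tsv")
  wt(results$correlations, "correlations.tsv")
  for (g in names(results$group_mean_z)) {
    m <- results$group_mean_z[[g]]
    df <- as_tibble(as.data.frame(m))
    names(df) <- paste0("ch", attr(m, "nodes"))
    wt(df, sprintf("group_mean_z_%s.tsv", g))
  }
  writeLines(results$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
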