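# End-to-end orchestration: simulate -> preprocess -> epoch ->
# congruency -> metrics -> report, with per-condition outputs written as
# CSV + JSON and a manifest recording configuration and seeds.

#' Pipeline configuration
#'
#' @param cohort A [cohort_config()] describing the (synthetic) cohort.
#' @param K Components per congruency feature vector.
#' @param K_hat Leading components summed by the cumulative metric.
#' @param gamma Within-covariance shrinkage.
#' @param n_perm Permutations for AUC significance; the default of
#'   1,000 keeps runs fast, publication-grade inference would
#'   typically use 10,000.
#' @param pad Segment padding in seconds.
#' @param seed Seed for the stochastic stages (permutation draws).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort, K = 10, K_hat = 3, gamma = 0.05,
                            n_perm = 1000, pad = 2.0, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_config"))
  if (K_hat > K) stop("K_hat cannot exceed K")
  structure(list(cohort = cohort, K = as.integer(K),
                 K_hat = as.integer(K_hat), gamma = gamma,
                 n_perm = as.integer(n_perm), pad = pad,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Preprocess and epoch a cohort
#'
#' Runs the preprocessing chain on every recording, aligns each
#' fixation log to the condition windows, and epochs every condition
#' segment, returning FRP sets grouped by condition.
#'
#' @param cohort List with `recordings`, `fixations`, `manifest` (an
#'   `rrnc_cohort` or the result of [read_cohort()]).
#' @param pad Segment padding in seconds.
#' @return List by condition of lists by participant of `frp_set`
#'   objects.
#' @export
cohort_frp_sets <- function(cohort, pad = 2.0) {
  manifest <- cohort$manifest
  out <- list()
  for (p in manifest$participant) {
    rec <- preprocess_recording(cohort$recordings[[p]])
    segs <- extract_condition_segments(rec, pad = pad, participant = p)
    fx <- align_fixations(cohort$fixations[[p]], condition_windows(rec))
    for (seg in segs) {
      frp <- epoch_at_fixations(seg, fx)
      cnd <- as.character(seg$condition)
      out[[cnd]][[p]] <- frp
    }
  }
  out
}

#' Concatenated matrices for one condition, truncated to a common count
#'
#' @param frp_list List by participant of `frp_set` objects for one
#'   condition.
#' @return List by participant of `D x (T * F_common)` matrices;
#'   attribute `f_common` carries the truncation count.
#' @export
condition_matrices <- function(frp_list) {
  f_common <- common_fixation_count(frp_list)
  X <- lapply(frp_list, concatenate_epochs, f_common = f_common)
  attr(X, "f_common") <- f_common
  X
}

#' Full congruency analysis of one condition
#'
#' Leave-one-out congruency features, cumulative and LASSO-weighted
#' metrics, AUC and its permutation test.
#'
#' @param X_list List by participant of concatenated matrices.
#' @param manifest Data frame with `participant`, `group`, `grade`
#'   matching `X_list` order.
#' @param condition Condition id carried into the metric table.
#' @param K,K_hat,gamma,n_perm,seed See [pipeline_config()].
#' @return List with `metrics` (metric table rows), `classifier`
#'   (`classifier_result`), `perm` (permutation test), `features`,
#'   `reference_basis` (components from the full reference group),
#'   `pairs`.
#' @export
analyze_condition <- function(X_list, manifest, condition, K = 10,
                              K_hat = 3, gamma = 0.05, n_perm = 1000,
                              seed = 1L) {
  is_ref <- manifest$group == "CAC"
  pairs <- pair_covariances(X_list)
  cf <- congruency_features(pairs = pairs, is_ref = is_ref, K = K,
                            gamma = gamma)
  feats <- cf$features
  clf <- congruency_classifier(pairs, manifest$group, K = K, gamma = gamma)
  perm <- permutation_test_auc(pairs, manifest$group, clf$auc,
                               n_perm = n_perm, seed = seed, K = K,
                               gamma = gamma)
  metrics <- data.frame(
    participant = manifest$participant,
    group = manifest$group,
    grade = manifest$grade,
    condition = condition,
    c_rrnc = apply(feats, 1, cumulative_metric, K_hat = K_hat),
    lasso_score = clf$cv_scores,
    stringsAsFactors = FALSE
  )
  metrics <- cbind(metrics,
                   stats::setNames(as.data.frame(feats),
                                   paste0("rrnc_", seq_len(K))))
  ref_pc <- pooled_covariances_from_pairs(pairs, which(is_ref), gamma)
  list(metrics = metrics, classifier = clf, perm = perm,
       features = feats,
       reference_basis = solve_congruency_components(ref_pc, K),
       pairs = pairs)
}

roc_points <- function(scores, labels, positive = "CAC") {
  ord <- order(scores, decreasing = TRUE)
  lab <- as.character(labels)[ord] == positive
  data.frame(fpr = c(0, cumsum(!lab) / sum(!lab)),
             tpr = c(0, cumsum(lab) / sum(lab)))
}

#' Run the full pipeline
#'
#' Generates the configured synthetic cohort, preprocesses and epochs
#' it, runs the per-condition congruency analysis, the group-by-grade
#' ANOVA per condition, the repeated-measures modality-by-confusability
#' ANOVA (when all four conditions are present), and writes all outputs
#' under `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created; one subdirectory per
#'   condition).
#' @param write_raw Also write the raw cohort containers under
#'   `out_dir/raw`.
#' @return Invisibly, a list with `metrics` (all-condition metric
#'   table), `conditions` (per-condition analysis objects), `anova`
#'   (per-condition group-by-grade tables), `rm_anova`, `run_dir`.
#' @export
run_pipeline <- function(config, out_dir, write_raw = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config$cohort)
  if (write_raw) write_cohort(cohort, file.path(out_dir, "raw"))
  frp_by_cond <- cohort_frp_sets(cohort, pad = config$pad)
  manifest <- cohort$manifest
  cond_ids <- sort(as.integer(names(frp_by_cond)))

  all_metrics <- NULL
  cond_results <- list()
  anovas <- list()
  for (cnd in cond_ids) {
    frps <- frp_by_cond[[as.character(cnd)]]
    X <- condition_matrices(frps)
    res <- analyze_condition(X, manifest, cnd, K = config$K,
                             K_hat = config$K_hat, gamma = config$gamma,
                             n_perm = config$n_perm,
                             seed = config$seed + cnd)
    res$f_common <- attr(X, "f_common")
    res$profiles <- temporal_profiles(
      res$reference_basis$W,
      split(frps, manifest$group))
    cond_results[[as.character(cnd)]] <- res
    anovas[[as.character(cnd)]] <- anova_group_grade(res$metrics)
    all_metrics <- rbind(all_metrics, res$metrics)

    cdir <- file.path(out_dir, sprintf("condition_%d", cnd))
    dir.create(cdir, showWarnings = FALSE)
    utils::write.csv(res$metrics, file.path(cdir, "metrics.csv"),
                     row.names = FALSE)
    b <- res$reference_basis
    utils::write.csv(as.data.frame(b$W), file.path(cdir, "components.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(b$A),
                     file.path(cdir, "forward_models.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(k = seq_along(b$lambdas),
                                lambda = b$lambdas, rho = b$rhos),
                     file.path(cdir, "lambdas.csv"), row.names = FALSE)
    for (g in names(res$profiles))
      utils::write.csv(as.data.frame(t(res$profiles[[g]])),
                       file.path(cdir, sprintf("profiles_%s.csv", g)),
                       row.names = FALSE)
    utils::write.csv(roc_points(res$classifier$cv_scores, manifest$group),
                     file.path(cdir, "roc.csv"), row.names = FALSE)
    utils::write.csv(anovas[[as.character(cnd)]],
                     file.path(cdir, "anova_group_grade.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(condition = cnd, auc = res$classifier$auc,
           perm_p = res$perm$p, n_perm = res$perm$n_perm,
           f_common = res$f_common, K = config$K, K_hat = config$K_hat,
           gamma = config$gamma),
      file.path(cdir, "classifier.json"), auto_unbox = TRUE, digits = NA)
  }

  rm_tab <- NULL
  if (length(cond_ids) == 4 && all(cond_ids == 1:4)) {
    rm_tab <- rm_anova_modality_confusability(all_metrics)
    utils::write.csv(rm_tab,
                     file.path(out_dir, "rm_anova_modality_confusability.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(all_metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("rrnc")),
         r_version = as.character(getRversion()),
         seed = config$seed, cohort_seed = config$cohort$seed,
         K = config$K, K_hat = config$K_hat, gamma = config$gamma,
         n_perm = config$n_perm, pad = config$pad,
         n_participants = nrow(manifest),
         conditions = cond_ids),
    file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(metrics = all_metrics, conditions = cond_results,
                 anova = anovas, rm_anova = rm_tab, run_dir = out_dir))
}

#' Summarize a completed run directory
#'
#' Writes `report.txt`: per-condition AUC and permutation p, eigenvalue
#' spectra (knee diagnostics), and the ANOVA tables. Regeneration is
#' idempotent.
#'
#' @param run_dir Directory produced by [run_pipeline()].
#' @return Path of the report, invisibly.
#' @export
write_report <- function(run_dir) {
  man_path <- file.path(run_dir, "run_manifest.json")
  if (!file.exists(man_path))
    stop(sprintf("incomplete run: missing %s", man_path))
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  lines <- c("Neural-congruency pipeline report",
             sprintf("participants: %d; K = %d; K_hat = %d; gamma = %g; n_perm = %d",
                     man$n_participants, man$K, man$K_hat, man$gamma,
                     man$n_perm), "")
  for (cnd in man$conditions) {
    cdir <- file.path(run_dir, sprintf("condition_%d", cnd))
    cls_path <- file.path(cdir, "classifier.json")
    if (!file.exists(cls_path))
      stop(sprintf("incomplete run: missing %s", cls_path))
    cls <- jsonlite::read_json(cls_path, simplifyVector = TRUE)
    lam <- utils::read.csv(file.path(cdir, "lambdas.csv"))
    an <- utils::read.csv(file.path(cdir, "anova_group_grade.csv"))
    lines <- c(lines,
               sprintf("condition %d: AUC = %.3f, permutation p = %.4g (n_perm = %d, F_common = %d)",
                       cnd, cls$auc, cls$perm_p, cls$n_perm, cls$f_common),
               sprintf("  lambda spectrum: %s",
                       paste(sprintf("%.3f", lam$lambda), collapse = " ")),
               sprintf("  ANOVA %s: F(%g) = %.3f, p = %.4g",
                       an$effect, an$df, an$F, an$p),
               "")
  }
  rm_path <- file.path(run_dir, "rm_anova_modality_confusability.csv")
  if (file.exists(rm_path)) {
    rm_tab <- utils::read.csv(rm_path)
    lines <- c(lines, "repeated-measures modality x confusability:",
               sprintf("  %s: F(%g) = %.3f, p = %.4g",
                       rm_tab$effect, rm_tab$df, rm_tab$F, rm_tab$p))
  }
  path <- file.path(run_dir, "report.txt")
  writeLines(lines, path)
  invisible(path)
}
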