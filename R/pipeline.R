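# End-to-end pipeline orchestration --------------------------------------

#' Pipeline run configuration
#'
#' Bundles all stage configurations with one master seed from which every
#' stage seed is derived deterministically, so a whole run is reproducible
#' from `(config, master_seed)` alone.
#'
#' @param out_dir output directory for run artifacts.
#' @param seed master seed.
#' @param stages character subset of
#'   `c("cohort", "imaging", "train", "evaluate", "explain")`.
#' @param cohort_config a [default_cohort_config()].
#' @param cohort_csv optional path to an existing cohort CSV; when given the
#'   cohort stage is skipped and this table is used downstream.
#' @param models named list; each element is
#'   `list(spec = model_spec(...), variable_set = ...)`. Defaults to the
#'   baseline regression, the all-automated regression, and the recurrent
#'   model.
#' @param comparisons list of 2-vectors of model names compared by paired
#'   bootstrap on AUPRC.
#' @param n_phantom_pairs phantom pairs generated in the imaging validation
#'   stage.
#' @param bootstrap_B bootstrap replicates for model comparison.
#' @param n_explain number of subjects explained in the attribution stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("edemarun"), seed = 1L,
                       stages = c("cohort", "train", "evaluate", "explain"),
                       cohort_config = default_cohort_config(),
                       cohort_csv = NULL,
                       models = NULL,
                       comparisons = list(c("lstm_automated",
                                            "regression_automated")),
                       n_phantom_pairs = 3L,
                       bootstrap_B = 1000L,
                       n_explain = 8L) {
  stages <- match.arg(stages, c("cohort", "imaging", "train", "evaluate",
                                "explain"), several.ok = TRUE)
  vs <- variable_sets()
  if (is.null(models)) {
    models <- list(
      regression_baseline = list(spec = model_spec("logistic"),
                                 variable_set = vs$baseline),
      regression_automated = list(spec = model_spec("logistic"),
                                  variable_set = vs$automated),
      lstm_automated = list(spec = model_spec("lstm", restarts = 3L),
                            variable_set = vs$lstm_automated)
    )
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 cohort_config = cohort_config, cohort_csv = cohort_csv,
                 models = models, comparisons = comparisons,
                 n_phantom_pairs = as.integer(n_phantom_pairs),
                 bootstrap_B = as.integer(bootstrap_B),
                 n_explain = as.integer(n_explain)),
            class = "run_config")
}

#' Run the full simulation-to-explanation workflow
#'
#' Executes the selected stages in order — cohort simulation (or CSV
#' ingest), phantom-based imaging validation, nested cross-validated model
#' training, precision-recall evaluation with bootstrap model comparison,
#' and Shapley explanation — writing every artifact plus a manifest
#' (derived seeds, file checksums, timings, warnings) under
#' `config$out_dir`. Re-running the same config reproduces byte-identical
#' CSV/JSON artifacts.
#'
#' @param config a [run_config()].
#' @return The manifest, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list(), files = list(),
                   warnings = list())
  note <- function(stage, ...) {
    manifest$warnings[[stage]] <<- c(manifest$warnings[[stage]],
                                     sprintf(...))
  }
  t_start <- Sys.time()
  stage_wrap <- function(name, body) {
    t0 <- Sys.time()
    res <- tryCatch(body(), error = function(e) {
      stop_config("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e))
    })
    manifest$stages[[name]] <<- list(
      status = "complete",
      seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2))
    res
  }

  # ---- cohort ----
  table <- NULL
  if (!is.null(config$cohort_csv)) {
    table <- read_cohort_csv(config$cohort_csv)
    manifest$stages$cohort <- list(status = "loaded-from-csv")
  } else if ("cohort" %in% config$stages) {
    table <- stage_wrap("cohort", function() {
      tab <- generate_cohort(config$cohort_config,
                             seed = derive_seed(config$seed, "cohort"))
      write_cohort_csv(tab, file.path(config$out_dir, "cohort.csv"))
      tab
    })
  }

  # ---- imaging validation on phantom pairs ----
  if ("imaging" %in% config$stages) {
    stage_wrap("imaging", function() {
      rows <- lapply(seq_len(config$n_phantom_pairs), function(i) {
        eff <- (i - 1) / max(1, config$n_phantom_pairs - 1) * 0.8
        side <- if (i %% 2 == 0) "right" else "left"
        ph <- generate_head_phantom(
          phantom_spec(seed = derive_seed(config$seed, paste0("ph", i))))
        fu <- apply_edema(ph$ct, ph$truth,
                          edema_spec(side, effacement = eff,
                                     compression = 0.4 * eff,
                                     shift_mm = 8 * eff,
                                     lesion_ml = 30 * eff))
        fe <- extract_volumetrics(ph$ct, fu$ct,
                                  lesion_side = if (eff > 0) side else NULL)
        truth_ratio <- if (side == "left")
          fu$truth$csf_left_ml / fu$truth$csf_right_ml
        else fu$truth$csf_right_ml / fu$truth$csf_left_ml
        cbind(fe, truth_csf_ratio_24h = truth_ratio,
              truth_delta_csf = 100 * (fu$truth$csf_total_ml /
                                         ph$truth$csf_total_ml - 1))
      })
      utils::write.csv(do.call(rbind, rows),
                       file.path(config$out_dir, "phantom_validation.csv"),
                       row.names = FALSE)
    })
  }

  # ---- training ----
  cv_results <- list()
  if ("train" %in% config$stages) {
    if (is.null(table)) stop_config("training requires a cohort")
    cv_results <- stage_wrap("train", function() {
      res <- lapply(names(config$models), function(nm) {
        m <- config$models[[nm]]
        sp <- m$spec
        sp$seed <- derive_seed(config$seed, paste0("model-", nm))
        cv <- nested_cv(table, sp, m$variable_set,
                        seed = derive_seed(config$seed, "cvplan"))
        utils::write.csv(as.data.frame(cv),
                         file.path(config$out_dir,
                                   paste0("cv_", nm, ".csv")),
                         row.names = FALSE)
        cv
      })
      names(res) <- names(config$models)
      res
    })
  }

  # ---- evaluation ----
  if ("evaluate" %in% config$stages && length(cv_results)) {
    stage_wrap("evaluate", function() {
      metrics <- lapply(cv_results, evaluate_predictions)
      comps <- lapply(config$comparisons, function(pair) {
        a <- cv_results[[pair[1]]] ; b <- cv_results[[pair[2]]]
        cmp <- bootstrap_auprc_pvalue(a$label, a$prob, b$prob,
                                      B = config$bootstrap_B,
                                      seed = derive_seed(config$seed,
                                                         "bootstrap"))
        list(a = pair[1], b = pair[2], auprc_a = cmp$auprc_a,
             auprc_b = cmp$auprc_b, p_value = cmp$p_value)
      })
      jsonlite::write_json(
        list(metrics = metrics, comparisons = comps),
        file.path(config$out_dir, "metrics.json"),
        auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE)
    })
  }

  # ---- explanation ----
  if ("explain" %in% config$stages && length(cv_results)) {
    stage_wrap("explain", function() {
      nm <- names(config$models)[length(config$models)]
      m <- config$models[[nm]]
      sp <- m$spec
      sp$seed <- derive_seed(config$seed, paste0("model-", nm))
      expl <- explain_out_of_fold(table, sp, m$variable_set,
                                  cv_seed = derive_seed(config$seed,
                                                        "cvplan"),
                                  n_explain = config$n_explain,
                                  seed = derive_seed(config$seed, "explain"))
      utils::write.csv(expl$per_subject,
                       file.path(config$out_dir, "attributions.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        lapply(expl$reports, unclass),
        file.path(config$out_dir, "force_reports.json"),
        auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE)
      utils::write.csv(
        data.frame(player = names(expl$summary$importance),
                   mean_abs_contribution =
                     as.numeric(expl$summary$importance)),
        file.path(config$out_dir, "global_importance.csv"),
        row.names = FALSE)
    })
  }

  manifest$elapsed_seconds <- round(as.numeric(Sys.time() - t_start,
                                               units = "secs"), 2)
  files <- list.files(config$out_dir, full.names = TRUE)
  files <- files[!grepl("manifest[.]json$", files)]
  manifest$files <- lapply(stats::setNames(files, basename(files)),
                           function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(manifest)
}

#' Out-of-fold Shapley explanations
#'
#' Explains each selected subject with the model from the outer fold in
#' which that subject was a test subject (so explanations accompany honest
#' predictions): per outer fold the preprocessor and model are refitted on
#' the outer-training rows with the same derived seeds as in
#' [nested_cv()]'s final fits, and exact Shapley values are computed over
#' the named clinical/imaging variables against a background of training
#' rows.
#'
#' @param table a `cohort_table`.
#' @param spec a [model_spec()].
#' @param variable_set feature set or [sequence_layout()].
#' @param cv_seed the fold-plan seed (must match the training run).
#' @param n_explain number of subjects (all cases first, then controls).
#' @param n_background background rows sampled from the training fold.
#' @param seed selection/background seed.
#' @return List with `attributions`, `per_subject` (long data.frame),
#'   `reports` (force reports) and `summary` (a [global_summary()]).
#' @export
explain_out_of_fold <- function(table, spec, variable_set, cv_seed = 1L,
                                n_explain = 8L, n_background = 50L,
                                seed = 1L) {
  fold <- make_cv_plan(table$outcome, 10L, seed = cv_seed)
  feats <- if (is_sequence_set(variable_set)) variable_set$features
           else variable_set
  pick <- withr::with_seed(seed, {
    cases <- sample(which(table$outcome == 1))
    ctrls <- sample(which(table$outcome == 0))
    utils::head(c(cases, ctrls), n_explain)
  })
  atts <- list() ; reports <- list() ; rows_out <- list()
  for (f in sort(unique(fold[pick]))) {
    tr <- table[fold != f, , drop = FALSE]
    fitted <- fit_one(tr, spec, variable_set)
    mf <- shapley_model_fn(fitted, variable_set)
    bg_idx <- withr::with_seed(derive_seed(seed, paste0("bg", f)),
                               sample(nrow(tr), min(n_background, nrow(tr))))
    bg <- impute_with(fitted$pp, tr[bg_idx, , drop = FALSE], feats)
    for (s in pick[fold[pick] == f]) {
      inst_row <- impute_with(fitted$pp, table[s, , drop = FALSE], feats)
      inst <- stats::setNames(as.numeric(inst_row[1, ]), feats)
      at <- exact_shapley(mf, inst, bg)
      atts[[table$id[s]]] <- at
      reports[[table$id[s]]] <- force_report(at, inst)
      rows_out[[table$id[s]]] <- data.frame(
        id = table$id[s], fold = f, player = names(at$contributions),
        value = as.numeric(inst[names(at$contributions)]),
        contribution = as.numeric(at$contributions),
        base_value = at$base_value, prediction = at$prediction)
    }
  }
  vals <- do.call(rbind, lapply(names(atts), function(id) {
    r <- rows_out[[id]]
    stats::setNames(as.data.frame(t(r$value)), r$player)
  }))
  list(attributions = atts,
       per_subject = do.call(rbind, rows_out),
       reports = reports,
       summary = global_summary(atts, vals))
}

# raw-feature matrix with training-median imputation (for shapley inputs)
impute_with <- function(pp, rows, feats) {
  out <- vapply(feats, function(nm) {
    x <- rows[[nm]]
    ifelse(is.na(x), pp$pars[[nm]]$median, x)
  }, numeric(nrow(rows)))
  matrix(out, nrow = nrow(rows), dimnames = list(NULL, feats))
}

#' Fit one model on a whole cohort
#'
#' Convenience wrapper fitting the preprocessor and model on all rows (no
#' cross-validation); used by [predict_single()] for the clinician-facing
#' single-subject path.
#'
#' @inheritParams explain_out_of_fold
#' @return A fitted pipeline: list with `pp`, `model`, `variable_set`.
#' @export
fit_cohort_model <- function(table, spec, variable_set) {
  fitted <- fit_one(table, spec, variable_set)
  fitted$variable_set <- variable_set
  fitted
}

#' Predict malignant-edema risk for one subject from a scan pair
#'
#' The clinician-facing path: extracts CSF volumetrics from the paired
#' baseline/follow-up volumes, merges them with the supplied clinical
#' variables (missing clinical fields are imputed with training medians,
#' with a warning), and returns the predicted probability together with a
#' Shapley force report.
#'
#' @param baseline_ct,followup_ct `ct_volume`s.
#' @param clinical named list/vector of clinical variables (age,
#'   nihss_baseline, nihss_24h, glucose, sbp, tpa, aspects).
#' @param fitted a [fit_cohort_model()] result.
#' @param lesion_side optional visible-lesion side.
#' @param n_background background rows for the explanation (taken from the
#'   training table via the preprocessor medians when no table is given).
#' @param background optional matrix of raw background rows.
#' @return List with `probability`, `features`, `report`.
#' @export
predict_single <- function(baseline_ct, followup_ct, clinical, fitted,
                           lesion_side = NULL, background = NULL) {
  vols <- extract_volumetrics(baseline_ct, followup_ct, lesion_side)
  feats <- if (is_sequence_set(fitted$variable_set))
    fitted$variable_set$features else fitted$variable_set
  row <- as.list(clinical)
  row$intracranial_reserve <- vols$intracranial_reserve
  row$csf_ratio_baseline <- vols$csf_ratio_baseline
  row$csf_ratio_24h <- vols$csf_ratio_24h
  row$delta_csf <- vols$delta_csf
  missing <- setdiff(feats, names(row))
  if (length(missing)) {
    warning("missing clinical fields imputed with training medians: ",
            paste(missing, collapse = ", "))
    for (nm in missing) row[[nm]] <- NA_real_
  }
  df <- as.data.frame(row[intersect(names(row), c(feats))],
                      stringsAsFactors = FALSE)
  for (nm in feats) if (is.null(df[[nm]])) df[[nm]] <- NA_real_
  prob <- predict_one(fitted, df, fitted$variable_set)
  inst_row <- impute_with(fitted$pp, df, feats)
  inst <- stats::setNames(as.numeric(inst_row[1, ]), feats)
  bg <- background %||% matrix(
    vapply(feats, function(nm) fitted$pp$pars[[nm]]$median, numeric(1)),
    nrow = 1, dimnames = list(NULL, feats))
  at <- exact_shapley(shapley_model_fn(fitted, fitted$variable_set),
                      inst, bg)
  list(probability = unname(prob), features = df,
       report = force_report(at, inst))
}
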