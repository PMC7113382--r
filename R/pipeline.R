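#' Pipeline configuration
#'
#' Assembles and validates the parameters for a full [run_pipeline()] run.
#' Defaults mirror the analysis the package targets: TR = 0.72 s, six MODWT
#' levels with level 4 as the band of interest, 5% connection density with
#' signed ranking, induced-subgraph subnetwork efficiency, BH-FDR at 0.05,
#' and 1000 bootstrap replicates for indirect effects.
#'
#' Exactly one of `simulate` (a [cohort_config()]) or `input_dir` (a
#' directory holding `manifest.tsv`, `parcels.tsv`, and
#' `timeseries/<subject_id>.tsv`, optionally
#' `confounds/<subject_id>.tsv`) must be given.
#'
#' @param output_dir Run directory to create/populate.
#' @param simulate Optional [cohort_config()] for a synthetic cohort.
#' @param input_dir Optional directory of on-disk inputs.
#' @param tr_seconds,wavelet_levels,level_of_interest MODWT settings.
#' @param drop_boundary Drop circular-boundary-affected wavelet
#'   coefficients before correlating.
#' @param density,threshold_mode Binarization settings.
#' @param efficiency_mode `"induced"` or `"restricted"` E_s.
#' @param fdr_alpha FDR significance threshold used in the mediation
#'   trimming step and reported comparisons.
#' @param n_boot Bootstrap replicates for indirect effects.
#' @param mediate Run the mediation stage (requires score columns and a
#'   two-level group in the manifest).
#' @param write_correlations Also write each subject's full correlation
#'   matrix (large; edge lists are always written).
#' @param seed Seed for simulation and bootstrap.
#' @return A validated list of class `waveconn_pipeline_config`.
#' @export
pipeline_config <- function(output_dir,
                            simulate = NULL,
                            input_dir = NULL,
                            tr_seconds = 0.72,
                            wavelet_levels = 6L,
                            level_of_interest = 4L,
                            drop_boundary = FALSE,
                            density = 0.05,
                            threshold_mode = "signed",
                            efficiency_mode = "induced",
                            fdr_alpha = 0.05,
                            n_boot = 1000L,
                            mediate = TRUE,
                            write_correlations = FALSE,
                            seed = 1L) {
  if (is.null(simulate) == is.null(input_dir)) {
    stop("give exactly one of `simulate` or `input_dir`")
  }
  if (!is.null(simulate)) {
    stopifnot(inherits(simulate, "waveconn_cohort_config"))
    tr_seconds <- simulate$tr_seconds
  }
  stopifnot(tr_seconds > 0, wavelet_levels >= 1,
            level_of_interest >= 1, level_of_interest <= wavelet_levels,
            density > 0, density <= 1,
            threshold_mode %in% c("signed", "absolute"),
            efficiency_mode %in% c("induced", "restricted"),
            fdr_alpha > 0, fdr_alpha < 1, n_boot >= 1)
  structure(
    list(output_dir = output_dir, simulate = simulate, input_dir = input_dir,
         tr_seconds = tr_seconds, wavelet_levels = as.integer(wavelet_levels),
         level_of_interest = as.integer(level_of_interest),
         drop_boundary = drop_boundary, density = density,
         threshold_mode = threshold_mode, efficiency_mode = efficiency_mode,
         fdr_alpha = fdr_alpha, n_boot = as.integer(n_boot),
         mediate = mediate, write_correlations = write_correlations,
         seed = as.integer(seed)),
    class = "waveconn_pipeline_config"
  )
}

.config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$simulate <- if (!is.null(cfg$simulate)) unclass(cfg$simulate)
  fnv1a_hash(as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)))
}

.stage <- function(name, subject = NULL, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s'%s failed: %s", name,
                 if (is.null(subject)) "" else paste0(" (subject ", subject, ")"),
                 conditionMessage(e)), call. = FALSE)
  })
}

.read_cohort_inputs <- function(input_dir) {
  manifest <- read_tsv(file.path(input_dir, "manifest.tsv"))
  parcels <- read_parcel_table(file.path(input_dir, "parcels.tsv"))
  tsdir <- file.path(input_dir, "timeseries")
  ts <- lapply(manifest$subject_id, function(id) {
    f <- file.path(tsdir, paste0(id, ".tsv"))
    if (!file.exists(f)) stop("missing time-series file for subject ", id)
    as.matrix(read_tsv(f))
  })
  names(ts) <- manifest$subject_id
  confdir <- file.path(input_dir, "confounds")
  confounds <- NULL
  if (dir.exists(confdir)) {
    confounds <- lapply(manifest$subject_id, function(id) {
      f <- file.path(confdir, paste0(id, ".tsv"))
      if (file.exists(f)) as.matrix(read_tsv(f)) else NULL
    })
    names(confounds) <- manifest$subject_id
  }
  list(manifest = manifest, parcels = parcels, timeseries = ts,
       confounds = confounds)
}

#' Run the full connectivity-efficiency-mediation pipeline
#'
#' Executes, in order: cohort simulation (or input loading), optional
#' confound regression, MODWT decomposition, level-of-interest correlation
#' matrices, fixed-density binarization, global/subnetwork efficiency,
#' group comparisons with FDR control, and (optionally) the
#' covariate-residualized mediation analysis with bootstrap confidence
#' intervals. All artifacts are written under `config$output_dir` as
#' plain-text TSV/JSON, together with a run manifest holding the full
#' configuration and its hash; identical configurations produce
#' byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return The output directory path, invisibly; the in-memory results are
#'   returned as the attribute `"results"` (efficiency table, comparisons,
#'   mediation).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "waveconn_pipeline_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$simulate)) {
    cohort <- .stage("simulate", expr = generate_cohort(config$simulate))
    manifest <- cohort$manifest
    parcels <- cohort$parcels
    ts <- cohort$timeseries
    confounds <- NULL
    .stage("simulate", expr = {
      write_tsv(manifest, file.path(out, "manifest.tsv"))
      write_parcel_table(parcels, file.path(out, "parcels.tsv"))
      gt <- cohort$ground_truth
      gt$config <- unclass(gt$config)
      jsonlite::write_json(gt, file.path(out, "ground_truth.json"),
                           auto_unbox = TRUE, digits = NA)
    })
  } else {
    inputs <- .stage("load", expr = .read_cohort_inputs(config$input_dir))
    manifest <- inputs$manifest
    parcels <- inputs$parcels
    ts <- inputs$timeseries
    confounds <- inputs$confounds
    write_tsv(manifest, file.path(out, "manifest.tsv"))
    write_parcel_table(parcels, file.path(out, "parcels.tsv"))
  }

  edge_dir <- file.path(out, "edges")
  dir.create(edge_dir, showWarnings = FALSE)
  if (config$write_correlations) {
    corr_dir <- file.path(out, "correlations")
    dir.create(corr_dir, showWarnings = FALSE)
  }

  adjacencies <- vector("list", nrow(manifest))
  names(adjacencies) <- manifest$subject_id
  thresholds <- numeric(nrow(manifest))
  for (i in seq_along(adjacencies)) {
    id <- manifest$subject_id[i]
    x <- ts[[id]]
    if (!is.null(confounds) && !is.null(confounds[[id]])) {
      x <- .stage("confound_regression", id, regress_confounds(x, confounds[[id]]))
    }
    w <- .stage("modwt", id,
                modwt(x, levels = config$wavelet_levels,
                      tr_seconds = config$tr_seconds))
    coeffs <- .stage("modwt", id,
                     wavelet_band_series(w, config$level_of_interest,
                                         drop_boundary = config$drop_boundary))
    corr <- .stage("correlation", id, correlation_matrix(coeffs))
    adj <- .stage("threshold", id,
                  threshold_to_density(corr, config$density,
                                       config$threshold_mode))
    adjacencies[[i]] <- adj
    thresholds[i] <- adj$threshold
    write_edge_list(adj, file.path(edge_dir, paste0(id, ".tsv")), corr = corr)
    if (config$write_correlations) {
      write_tsv(as.data.frame(corr), file.path(corr_dir, paste0(id, ".tsv")))
    }
  }

  efficiency <- .stage("efficiency", expr =
    cohort_efficiency(adjacencies, parcels, mode = config$efficiency_mode))
  write_tsv(efficiency, file.path(out, "efficiency.tsv"))

  comparisons <- .stage("compare", expr =
    compare_cohort(efficiency, manifest))
  write_tsv(comparisons, file.path(out, "comparisons.tsv"))

  mediation <- NULL
  if (config$mediate) {
    mediation <- .stage("mediate", expr =
      run_mediation_stage(efficiency, manifest, parcels,
                          alpha = config$fdr_alpha,
                          n_boot = config$n_boot, seed = config$seed))
    jsonlite::write_json(.mediation_json(mediation),
                         file.path(out, "mediation.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  summary <- list(
    n_subjects = nrow(manifest),
    n_regions = nrow(parcels),
    edge_count = adjacencies[[1L]]$edge_count,
    density = adjacencies[[1L]]$density,
    thresholds = stats::setNames(as.list(thresholds), manifest$subject_id)
  )
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA)

  run_manifest <- list(
    package = "waveconn",
    version = as.character(utils::packageVersion("waveconn")),
    config_hash = .config_hash(config),
    config = {
      cfg <- unclass(config)
      cfg$simulate <- if (!is.null(cfg$simulate)) unclass(cfg$simulate)
      cfg
    }
  )
  jsonlite::write_json(run_manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  results <- list(efficiency = efficiency, comparisons = comparisons,
                  mediation = mediation)
  invisible(structure(out, results = results))
}

#' Mediation stage of the pipeline
#'
#' Builds the hypothesis model — group acting on every named network's
#' efficiency, every efficiency acting on every cognitive score, plus
#' direct group-to-score paths — residualizes scores and efficiencies
#' against the nuisance covariates (sex, age, other substance use when
#' present), fits it by ML, trims nonsignificant paths, and reports
#' bootstrap confidence intervals for the surviving two-step indirect
#' effects.
#'
#' @param efficiency Data frame from [cohort_efficiency()].
#' @param manifest Cohort manifest (needs `group`, score columns, and any
#'   of `sex`, `age`, `other_substance_months` as nuisance covariates).
#' @param parcels Parcel table (names the networks).
#' @param alpha Trimming threshold.
#' @param n_boot,seed Bootstrap settings.
#' @return List with `initial_fit`, `trimmed` (spec/fit/removed), and
#'   `indirect` (list of [indirect_effect()] results).
#' @export
run_mediation_stage <- function(efficiency, manifest, parcels,
                                alpha = 0.05, n_boot = 1000L, seed = 1L) {
  score_cols <- attr(manifest, "score_cols") %||% default_score_cols(manifest)
  nets <- paste0("E_", named_networks(parcels))
  dat <- merge(efficiency, manifest, by = "subject_id")
  dat$group01 <- as.integer(dat$group == sort(unique(dat$group))[2L])
  # code the consumer group as 1 when the labels are the study's IC/HC
  if (all(c("IC", "HC") %in% dat$group)) {
    dat$group01 <- as.integer(dat$group == "IC")
  }
  covars <- intersect(c("sex", "age", "other_substance_months"), names(dat))
  if (length(covars)) {
    keep <- covars[vapply(covars, function(v) length(unique(dat[[v]])) > 1,
                          logical(1))]
    if (length(keep)) {
      dat <- residualize(dat, target_columns = c(nets, score_cols),
                         covariate_columns = keep)
    }
  }
  edges <- c(
    paste("group01 ->", nets),
    as.vector(outer(nets, score_cols, function(m, y) paste(m, "->", y))),
    paste("group01 ->", score_cols)
  )
  spec <- path_model_spec(edges)
  initial_fit <- fit_path_model(spec, dat)
  trimmed <- trim_model(spec, dat, alpha = alpha)

  indirect <- list()
  for (m in nets) {
    for (y in score_cols) {
      has_a <- any(trimmed$spec$edges$from == "group01" &
                     trimmed$spec$edges$to == m)
      has_b <- any(trimmed$spec$edges$from == m & trimmed$spec$edges$to == y)
      if (has_a && has_b) {
        indirect[[paste(m, y, sep = "->")]] <-
          indirect_effect(trimmed$spec, dat, c("group01", m, y),
                          n_boot = n_boot, seed = seed)
      }
    }
  }
  list(initial_fit = initial_fit, trimmed = trimmed, indirect = indirect)
}

.mediation_json <- function(med) {
  fit_to_list <- function(f) {
    list(estimates = f$estimates, chi_square = f$chi_square, df = f$df,
         p_fit = f$p_fit, cfi = f$cfi, rmsea = f$rmsea,
         r_squared = as.list(f$r_squared), n = f$n)
  }
  list(
    initial = fit_to_list(med$initial_fit),
    trimmed = fit_to_list(med$trimmed$fit),
    removed = med$trimmed$removed,
    indirect = lapply(med$indirect, function(ie) {
      list(path = ie$path, point_estimate = ie$point_estimate,
           ci_low = ie$ci_low, ci_high = ie$ci_high,
           n_boot = ie$n_boot, n_failed = ie$n_failed)
    })
  )
}
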