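#' Configuration for a synthetic resting-state cohort
#'
#' Collects every parameter of the synthetic cohort generator. Defaults
#' emulate the study design the pipeline targets: two groups of
#' inhalant-consuming (IC, n = 30) and control (HC, n = 27) adolescents,
#' a 264-region parcellation with DMN/SN/FPN blocks, 500 volumes at
#' TR = 0.72 s, within-network correlation weaker in the consumer group,
#' signal content concentrated in the level-4 wavelet band
#' (0.043-0.087 Hz), and cognitive scores produced by a linear structural
#' model with a direct group path and a path mediated by DMN efficiency.
#'
#' @param n_per_group Named vector `c(IC = ..., HC = ...)` of group sizes.
#' @param n_regions Number of parcellation regions.
#' @param network_sizes Named region counts for DMN/SN/FPN (see
#'   [make_parcel_table()]).
#' @param n_timepoints Number of volumes T.
#' @param tr_seconds Repetition time in seconds.
#' @param rho_within Named vector of within-network target correlations per
#'   group, in (-1, 1); the consumer group's value is lower.
#' @param rho_between Between-network (and OTHER) target correlation.
#' @param band_level Wavelet level whose dyadic band carries the planted
#'   band-limited power.
#' @param band_power Fraction of signal power placed inside the band
#'   (0.5 = the band holds as much power as the whole remaining spectrum).
#' @param a Planted path coefficient group -> latent DMN-efficiency
#'   construct (group coded IC = 1, HC = 0).
#' @param efficiency_noise_sd Residual SD of the efficiency construct.
#' @param path_coeffs Named list, one entry per cognitive score, each
#'   `c(b = efficiency -> score, c = group -> score)`.
#' @param score_noise_sd Residual SD of every cognitive score.
#' @param seed Master seed; fully determines the cohort.
#' @return A validated list of class `waveconn_cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(IC = 30, HC = 27),
                          n_regions = 264,
                          network_sizes = c(DMN = 58, SN = 18, FPN = 25),
                          n_timepoints = 500,
                          tr_seconds = 0.72,
                          rho_within = c(IC = 0.35, HC = 0.60),
                          rho_between = 0.10,
                          band_level = 4,
                          band_power = 0.5,
                          a = -0.55,
                          efficiency_noise_sd = 0.85,
                          path_coeffs = list(
                            working_memory = c(b = 0.0, c = -0.53),
                            wcst           = c(b = 0.0, c = -0.58),
                            stroop         = c(b = 0.4, c =  0.0),
                            toh            = c(b = 0.4, c =  0.0)
                          ),
                          score_noise_sd = 1,
                          seed = 1L) {
  cfg <- list(
    n_per_group = n_per_group, n_regions = n_regions,
    network_sizes = network_sizes, n_timepoints = n_timepoints,
    tr_seconds = tr_seconds, rho_within = rho_within,
    rho_between = rho_between, band_level = band_level,
    band_power = band_power, a = a,
    efficiency_noise_sd = efficiency_noise_sd,
    path_coeffs = path_coeffs, score_noise_sd = score_noise_sd,
    seed = as.integer(seed)
  )
  stopifnot(
    length(n_per_group) == 2L, all(c("IC", "HC") %in% names(n_per_group)),
    all(n_per_group >= 1), tr_seconds > 0, n_timepoints >= 8,
    all(c("IC", "HC") %in% names(rho_within)),
    all(abs(rho_within) < 1), abs(rho_between) < 1,
    band_power > 0, band_power <= 1,
    efficiency_noise_sd >= 0, score_noise_sd >= 0
  )
  if (n_timepoints < 2^band_level) {
    stop("n_timepoints must be at least 2^band_level")
  }
  for (nm in names(path_coeffs)) {
    if (!all(c("b", "c") %in% names(path_coeffs[[nm]]))) {
      stop(sprintf("path_coeffs[['%s']] must have entries 'b' and 'c'", nm))
    }
  }
  class(cfg) <- "waveconn_cohort_config"
  cfg
}

# Block covariance: rho_within for pairs inside the same named network,
# rho_between for every other off-diagonal pair, 1 on the diagonal.
.block_covariance <- function(parcels, rho_within, rho_between) {
  n <- nrow(parcels)
  sigma <- matrix(rho_between, n, n)
  for (nm in unique(parcels$network)) {
    if (nm == "OTHER") next
    idx <- which(parcels$network == nm)
    sigma[idx, idx] <- rho_within
  }
  diag(sigma) <- 1
  sigma
}

# Zero-phase spectral shaping: unit gain inside [f_low, f_high], constant
# floor gain elsewhere, chosen so the band carries `band_power` of the
# expected output power. Applied identically to every column, so the
# cross-regional correlation structure is preserved exactly in expectation.
.band_shape <- function(x, tr_seconds, f_low, f_high, band_power) {
  n <- nrow(x)
  freq <- (0:(n - 1)) / (n * tr_seconds)
  freq <- pmin(freq, 1 / tr_seconds - freq) # two-sided spectrum, Hz
  in_band <- freq >= f_low & freq <= f_high
  n_in <- sum(in_band)
  if (n_in == 0L) stop("no Fourier bin falls inside the requested band")
  n_out <- n - n_in
  g0 <- if (band_power >= 1 || n_out == 0L) 0 else {
    sqrt(n_in * (1 - band_power) / (n_out * band_power))
  }
  gain <- ifelse(in_band, 1, g0)
  xf <- stats::mvfft(x) * gain
  out <- Re(stats::mvfft(xf, inverse = TRUE)) / n
  out / sqrt(mean(gain^2)) # keep unit-ish marginal variance
}

#' Simulate one subject's ROI time-series matrix
#'
#' Draws T samples from a multivariate normal with the group's block
#' covariance (within-network pairs at `rho_within[group]`, all other pairs
#' at `rho_between`), then applies a zero-phase spectral filter that places
#' `band_power` of the power inside the dyadic band of `band_level`,
#' emulating band-limited resting-state BOLD content over a broadband
#' floor. The filter acts identically on all regions, so correlations are
#' unchanged in expectation.
#'
#' @param config A [cohort_config()].
#' @param parcels Parcel table defining the network blocks.
#' @param group `"IC"` or `"HC"`.
#' @param subject_seed Integer seed; same seed gives a bit-identical matrix.
#' @return `T x R` matrix; columns named by `region_id`; attribute
#'   `tr_seconds` carries the sampling interval.
#' @export
simulate_subject_timeseries <- function(config, parcels, group, subject_seed) {
  stopifnot(inherits(config, "waveconn_cohort_config"))
  validate_parcel_table(parcels)
  group <- match.arg(group, c("IC", "HC"))
  sigma <- .block_covariance(parcels, config$rho_within[[group]],
                             config$rho_between)
  ch <- tryCatch(chol(sigma), error = function(e) {
    stop("block covariance is not positive definite for group ", group,
         " (rho_within = ", config$rho_within[[group]],
         ", rho_between = ", config$rho_between, ")")
  })
  band <- band_for_level(config$tr_seconds, config$band_level)
  n <- config$n_timepoints
  r <- nrow(parcels)
  x <- with_seed(subject_seed, {
    z <- matrix(stats::rnorm(n * r), n, r) %*% ch
    .band_shape(z, config$tr_seconds, band$f_low, band$f_high,
                config$band_power)
  })
  colnames(x) <- as.character(parcels$region_id)
  attr(x, "tr_seconds") <- config$tr_seconds
  x
}

#' Generate cognitive scores from the planted structural model
#'
#' Each score is `c * group + b * efficiency + noise`, where `group` is the
#' 0/1 consumer indicator and `efficiency` is the (standardized) DMN
#' efficiency construct. Coefficients come from `config$path_coeffs` and
#' are recorded as ground truth by [generate_cohort()].
#'
#' @param config A [cohort_config()].
#' @param group_indicator 0/1 vector (1 = consumer group).
#' @param dmn_efficiency Numeric vector, same length.
#' @param seed Optional seed for the score noise.
#' @return Data frame with one column per configured score.
#' @export
simulate_cognition <- function(config, group_indicator, dmn_efficiency,
                               seed = NULL) {
  stopifnot(inherits(config, "waveconn_cohort_config"),
            length(group_indicator) == length(dmn_efficiency),
            all(group_indicator %in% c(0, 1)))
  n <- length(group_indicator)
  with_seed(seed, {
    out <- lapply(config$path_coeffs, function(pc) {
      pc[["c"]] * group_indicator + pc[["b"]] * dmn_efficiency +
        stats::rnorm(n, sd = config$score_noise_sd)
    })
    as.data.frame(out)
  })
}

#' Generate a full synthetic cohort
#'
#' Produces subject records (group, sex, age, other-substance covariate,
#' cognitive scores), per-subject band-limited time series with the
#' planted block-correlation structure, and a ground-truth record holding
#' every planted parameter. Cognitive scores are driven by the planted
#' group-level efficiency construct (`a * group + noise`), so the planted
#' indirect effect for a mediated score is exactly `a * b`.
#'
#' Demographics loosely follow the target study: ages 12-17 (mean ~15),
#' sex ratio ~80% male in IC vs ~59% in HC, and months of other-substance
#' use only in the consumer group. They are nuisance-only: no planted
#' effect on series or scores.
#'
#' @param config A [cohort_config()].
#' @param timeseries If `FALSE`, skip the (relatively expensive) time-series
#'   simulation and return covariates/scores only.
#' @return A list of class `waveconn_cohort`: `manifest` (data frame),
#'   `timeseries` (named list of matrices or `NULL`), `parcels`,
#'   `ground_truth`.
#' @export
generate_cohort <- function(config, timeseries = TRUE) {
  stopifnot(inherits(config, "waveconn_cohort_config"))
  parcels <- make_parcel_table(config$n_regions, config$network_sizes)
  n_ic <- config$n_per_group[["IC"]]
  n_hc <- config$n_per_group[["HC"]]
  n <- n_ic + n_hc
  group <- c(rep("IC", n_ic), rep("HC", n_hc))
  g01 <- as.integer(group == "IC")
  subject_id <- sprintf("S%03d", seq_len(n))

  seeds <- derive_seeds(config$seed, n + 1L)
  subj_seeds <- seeds[seq_len(n)]

  demo <- with_seed(seeds[n + 1L], {
    p_male <- ifelse(group == "IC", 0.80, 0.59)
    sex <- ifelse(stats::runif(n) < p_male, "M", "F")
    age <- round(pmin(pmax(stats::rnorm(n, 15, 1.35), 12), 17), 1)
    other_substance_months <- ifelse(
      group == "IC", round(pmin(stats::rlnorm(n, log(16), 0.7), 72)), 0)
    eff <- config$a * g01 +
      stats::rnorm(n, sd = config$efficiency_noise_sd)
    scores <- simulate_cognition(config, g01, eff)
    list(sex = sex, age = age,
         other_substance_months = other_substance_months,
         efficiency_construct = eff, scores = scores)
  })

  manifest <- data.frame(
    subject_id = subject_id, group = group, sex = demo$sex, age = demo$age,
    other_substance_months = demo$other_substance_months,
    stringsAsFactors = FALSE
  )
  manifest <- cbind(manifest, demo$scores)
  attr(manifest, "score_cols") <- names(config$path_coeffs)

  ts <- NULL
  if (timeseries) {
    ts <- vector("list", n)
    names(ts) <- subject_id
    for (i in seq_len(n)) {
      ts[[i]] <- simulate_subject_timeseries(config, parcels, group[i],
                                             subj_seeds[i])
    }
  }

  ground_truth <- list(
    config = config,
    a = config$a,
    path_coeffs = config$path_coeffs,
    indirect_effects = vapply(config$path_coeffs,
                              function(pc) config$a * pc[["b"]], numeric(1)),
    efficiency_construct = demo$efficiency_construct,
    subject_seeds = subj_seeds
  )

  structure(
    list(manifest = manifest, timeseries = ts, parcels = parcels,
         ground_truth = ground_truth),
    class = "waveconn_cohort"
  )
}

#' @export
print.waveconn_cohort <- function(x, ...) {
  tab <- table(x$manifest$group)
  cat(sprintf(
    "Synthetic cohort: %d subjects (%s), %d regions, T = %s\n",
    nrow(x$manifest),
    paste(sprintf("%s = %d", names(tab), tab), collapse = ", "),
    nrow(x$parcels),
    if (is.null(x$timeseries)) "none" else nrow(x$timeseries[[1]])))
  invisible(x)
}

#' Write a cohort to disk as plain-text artifacts
#'
#' Writes `manifest.tsv`, `parcels.tsv`, `ground_truth.json`, and one
#' `timeseries/<subject_id>.tsv` per subject (T rows, one column per
#' region, header = region id).
#'
#' @param cohort A `waveconn_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "waveconn_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(cohort$manifest, file.path(dir, "manifest.tsv"))
  write_parcel_table(cohort$parcels, file.path(dir, "parcels.tsv"))
  gt <- cohort$ground_truth
  gt$config <- unclass(gt$config)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(cohort$timeseries)) {
    tsdir <- file.path(dir, "timeseries")
    dir.create(tsdir, showWarnings = FALSE)
    for (id in names(cohort$timeseries)) {
      write_tsv(as.data.frame(cohort$timeseries[[id]]),
                file.path(tsdir, paste0(id, ".tsv")))
    }
  }
  invisible(dir)
}

#' Simulate a single-mediator dataset
#'
#' Minimal generator for validating the mediation machinery in isolation:
#' `m = a * group + noise`, `y = c_prime * group + b * m + noise`, with a
#' balanced 0/1 group indicator. The planted indirect effect is `a * b`.
#'
#' @param n Total sample size (split evenly between groups).
#' @param a,b,c_prime Planted path coefficients.
#' @param noise_sd Residual SD for both `m` and `y`.
#' @param seed Seed.
#' @return Data frame with columns `group`, `m`, `y`.
#' @export
simulate_single_mediator <- function(n, a, b, c_prime, noise_sd = 1,
                                     seed = 1L) {
  group <- rep(c(0, 1), length.out = n)
  with_seed(seed, {
    m <- a * group + stats::rnorm(n, sd = noise_sd)
    y <- c_prime * group + b * m + stats::rnorm(n, sd = noise_sd)
    data.frame(group = group, m = m, y = y)
  })
}
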