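# Seeded generators for synthetic patient cohorts, model weights with
# controlled pre-activation ranges, and Weibull survival outcomes. The real
# clinical registry behind the reference model is not public; these generators
# emulate its statistical shape (per-patient visit sequences inside a 24-month
# window, one-hot categorical blocks, z-scored continuous features, a
# 10%-binned proportion feature, LOCF missingness, Weibull event times driven
# by a linear risk score, right censoring) so the protocol can be exercised
# end to end.

#' Cohort generator configuration
#'
#' The default feature schema encodes to exactly 70 columns: 12 one-hot
#' blocks totalling 40 columns, 29 continuous (z-scored) columns and one
#' 10%-binned proportion column. Visit counts follow `1 + Poisson(visit_rate
#' - 1)` (every patient has at least one visit) with visit months uniform in
#' the 24-month window; the default rate mirrors a typical follow-up schedule
#' of about five visits.
#'
#' @param n_patients Number of patients.
#' @param visit_window_months Length of the observation window (months).
#' @param visit_rate Expected visits per patient.
#' @param onehot_blocks Integer vector of one-hot block sizes.
#' @param n_continuous Number of continuous features.
#' @param missing_rate Probability that a continuous measurement is missing
#'   at a visit (filled by last observation carried forward; cohort mean at
#'   the first visit).
#' @param seed Integer generator seed.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_patients = 100L, visit_window_months = 24L,
                          visit_rate = 5.13,
                          onehot_blocks = c(2L, 2L, 2L, 3L, 3L, 3L, 3L, 4L,
                                            4L, 4L, 5L, 5L),
                          n_continuous = 29L, missing_rate = 0.1,
                          seed = 1L) {
  total <- sum(onehot_blocks) + n_continuous + 1L
  if (total != 70L) {
    he_error("hegru_config_error",
             sprintf("feature schema encodes to %d columns, expected 70", total))
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    he_error("hegru_config_error", "missing_rate must be in [0, 1)")
  }
  if (visit_rate <= 1) {
    he_error("hegru_config_error", "visit_rate must exceed 1")
  }
  structure(list(n_patients = as.integer(n_patients),
                 visit_window_months = as.integer(visit_window_months),
                 visit_rate = visit_rate,
                 onehot_blocks = as.integer(onehot_blocks),
                 n_continuous = as.integer(n_continuous),
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic patient cohort
#'
#' Deterministic per seed. Each patient receives a chronologically ordered
#' visit sequence inside the observation window; one-hot blocks sum to one
#' per visit (categories can change between visits), continuous features are
#' driven by a per-patient latent level plus visit noise, thinned by the
#' missingness process, imputed by last-observation-carried-forward (cohort
#' column mean at a missing first visit) and finally z-scored cohort-wide;
#' the binned proportion feature takes mid-bin values in
#' `{0.05, 0.15, ..., 0.95}`.
#'
#' @param cfg A [cohort_config()].
#' @return A list of `patient_record` objects.
#' @export
gen_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  n <- cfg$n_patients
  n_vis <- 1L + stats::rpois(n, cfg$visit_rate - 1)
  total_cols <- sum(cfg$onehot_blocks) + cfg$n_continuous + 1L
  cont_cols <- sum(cfg$onehot_blocks) + seq_len(cfg$n_continuous)
  bin_col <- total_cols
  raw <- vector("list", n)
  months <- vector("list", n)
  for (i in seq_len(n)) {
    nv <- n_vis[i]
    m <- sort(stats::runif(nv, 0, cfg$visit_window_months))
    x <- matrix(0, nv, total_cols)
    # one-hot categorical blocks (patient-level category, occasional switch)
    off <- 0L
    for (bs in cfg$onehot_blocks) {
      cat0 <- sample.int(bs, 1L)
      for (t in seq_len(nv)) {
        if (t > 1L && stats::runif(1) < 0.1) cat0 <- sample.int(bs, 1L)
        x[t, off + cat0] <- 1
      }
      off <- off + bs
    }
    # continuous: latent patient level + visit noise, with missingness
    latent <- stats::rnorm(cfg$n_continuous, 0, 1)
    vals <- matrix(stats::rnorm(nv * cfg$n_continuous, 0, 0.5), nv) +
      matrix(latent, nv, cfg$n_continuous, byrow = TRUE)
    miss <- matrix(stats::runif(nv * cfg$n_continuous) < cfg$missing_rate, nv)
    vals[miss] <- NA_real_
    x[, cont_cols] <- vals
    # binned proportion feature in 10% units (mid-bin values)
    prop <- pmin(pmax(stats::rbeta(1, 2, 5) +
                        cumsum(stats::rnorm(nv, 0, 0.05)), 0), 0.999)
    x[, bin_col] <- seq(0.05, 0.95, by = 0.1)[floor(prop * 10) + 1L]
    raw[[i]] <- x
    months[[i]] <- m
  }
  # LOCF imputation; a missing first observation takes the cohort column mean
  all_cont <- do.call(rbind, lapply(raw, function(x) x[, cont_cols, drop = FALSE]))
  col_means <- colMeans(all_cont, na.rm = TRUE)
  for (i in seq_len(n)) {
    v <- raw[[i]][, cont_cols, drop = FALSE]
    for (j in seq_len(ncol(v))) {
      if (is.na(v[1L, j])) v[1L, j] <- col_means[j]
      if (nrow(v) > 1L) {
        for (t in 2L:nrow(v)) if (is.na(v[t, j])) v[t, j] <- v[t - 1L, j]
      }
    }
    raw[[i]][, cont_cols] <- v
  }
  # cohort-wide z-scoring of the continuous block
  all_cont <- do.call(rbind, lapply(raw, function(x) x[, cont_cols, drop = FALSE]))
  mu <- colMeans(all_cont)
  sdv <- apply(all_cont, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  lapply(seq_len(n), function(i) {
    x <- raw[[i]]
    x[, cont_cols] <- sweep(sweep(x[, cont_cols, drop = FALSE], 2L, mu), 2L,
                            sdv, "/")
    structure(list(patient_id = sprintf("P%04d", i),
                   months = months[[i]], features = x, survival = NULL),
              class = "patient_record")
  })
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record %s visits=%d features=%d%s>\n",
              x$patient_id, nrow(x$features), ncol(x$features),
              if (is.null(x$survival)) "" else {
                sprintf(" time=%.2f event=%d", x$survival$time,
                        x$survival$event)
              }))
  invisible(x)
}

#' Generate GRU model weights with controlled pre-activation ranges
#'
#' Draws Gaussian weights (variance scaled by fan-in) and then calibrates a
#' global multiplier by bisection against a reference cohort so that
#' approximately `1 - outlier_frac` of all gate pre-activation components fall
#' inside the pass-through region `[-(R-1), R-1]` of their gate's clamp
#' threshold — guaranteeing the clamp path is actually exercised at the
#' requested rate. Deterministic per seed.
#'
#' @param dims Architecture dimensions `c(n_in, n_h1, n_h2, n_out)`.
#' @param preact_scale Base spread multiplier before calibration; 0 yields an
#'   all-zero model (every pre-activation equals its bias).
#' @param outlier_frac Target fraction of pre-activations outside the
#'   pass-through region (0 disables calibration).
#' @param seed Integer seed.
#' @param cfg [adjust_config()] supplying the clamp thresholds.
#' @param ref_cohort Optional cohort used for calibration; defaults to an
#'   internally generated 500-patient reference cohort.
#' @return A `gru_model_weights` object.
#' @export
gen_weights <- function(dims = c(70L, 32L, 20L, 2L), preact_scale = 1,
                        outlier_frac = 0, seed = 1L, cfg = adjust_config(),
                        ref_cohort = NULL) {
  if (outlier_frac < 0 || outlier_frac > 0.2) {
    he_error("hegru_config_error", "outlier_frac must be in [0, 0.2]")
  }
  set.seed(seed)
  rand_layer <- function(n_i, n_h, s) {
    gm <- function(r, c, sc) matrix(stats::rnorm(r * c, 0, sc), r, c)
    gru_cell_weights(
      W_z = gm(n_h, n_i, s / sqrt(n_i)), U_z = gm(n_h, n_h, s / sqrt(n_h)),
      b_z = stats::rnorm(n_h, 0, 0.2 * min(s, 1)),
      W_r = gm(n_h, n_i, s / sqrt(n_i)), U_r = gm(n_h, n_h, s / sqrt(n_h)),
      b_r = stats::rnorm(n_h, 0, 0.2 * min(s, 1)),
      W_g = gm(n_h, n_i, s / sqrt(n_i)), U_g = gm(n_h, n_h, s / sqrt(n_h)),
      b_g_vec = stats::rnorm(n_h, 0, 0.2 * min(s, 1)))
  }
  build <- function(s) {
    l1 <- rand_layer(dims[1L], dims[2L], s)
    l2 <- rand_layer(dims[2L], dims[3L], s)
    dw <- matrix(stats::rnorm(dims[4L] * dims[3L], 0, 1 / sqrt(dims[3L])),
                 dims[4L], dims[3L])
    db <- stats::rnorm(dims[4L], 0, 0.2)
    gru_model_weights(l1, l2, dw, db)
  }
  # one draw of unit-scale weights; scaling multiplies W, U (and biases via
  # the builder) coherently so bisection just rescales this draw
  base_state <- get(".Random.seed", envir = globalenv())
  model_at <- function(s) {
    assign(".Random.seed", base_state, envir = globalenv())
    build(s)
  }
  if (preact_scale == 0) {
    m <- model_at(0)
    return(m)
  }
  if (outlier_frac == 0) return(model_at(preact_scale))
  if (is.null(ref_cohort)) {
    ref_cohort <- gen_cohort(cohort_config(n_patients = 500L, seed = seed + 1L))
  }
  in_range_frac <- function(model) {
    fr <- vapply(ref_cohort, function(p) {
      pa <- model_forward(p$features, model, mode = "exact")$preacts
      v <- unlist(lapply(pa, function(g) {
        c(abs(g$z) <= cfg$R - 1, abs(g$r) <= cfg$R - 1,
          abs(g$g) <= cfg$R_tanh - 1)
      }))
      c(sum(v), length(v))
    }, numeric(2L))
    sum(fr[1L, ]) / sum(fr[2L, ])
  }
  target <- 1 - outlier_frac
  lo <- 0.01; hi <- 60
  for (it in seq_len(24L)) {
    mid <- sqrt(lo * hi)
    f <- in_range_frac(model_at(mid))
    if (f > target) lo <- mid else hi <- mid
    if (abs(f - target) < 0.002) break
  }
  model_at(sqrt(lo * hi))
}

#' Attach Weibull survival outcomes to a cohort
#'
#' Each patient's linear risk score is a fixed random projection of the mean
#' feature vector (standardized across the cohort); event times follow a
#' Weibull distribution with scale `exp(-effect_size * score)` (shape 1.5),
#' and independent uniform censoring is calibrated so the realized censored
#' fraction approximates `censor_frac`.
#'
#' @param cohort A cohort from [gen_cohort()].
#' @param effect_size Risk-score coefficient; 0 makes times independent of
#'   the features.
#' @param censor_frac Target censored fraction in `[0, 0.9]`.
#' @param seed Integer seed.
#' @return The cohort with `survival = list(time, event)` filled in; the true
#'   risk scores are attached as attribute `"risk_score"`.
#' @export
gen_outcomes <- function(cohort, effect_size = 1, censor_frac = 0.2,
                         seed = 1L) {
  if (censor_frac < 0 || censor_frac > 0.9) {
    he_error("hegru_config_error", "censor_frac must be in [0, 0.9]")
  }
  set.seed(seed + 7L)
  p <- ncol(cohort[[1L]]$features)
  proj <- stats::rnorm(p) / sqrt(p)
  s <- vapply(cohort, function(pt) sum(colMeans(pt$features) * proj),
              numeric(1L))
  s <- as.numeric(scale(s))
  n <- length(cohort)
  times <- stats::rweibull(n, shape = 1.5, scale = exp(-effect_size * s))
  if (censor_frac > 0) {
    u <- stats::runif(n)
    frac_at <- function(cmax) mean(u * cmax < times)
    # frac_at is decreasing in cmax: frac(lo) > censor_frac > frac(hi)
    lo <- 1e-6; hi <- max(times) * 2
    for (it in seq_len(40L)) {
      mid <- (lo + hi) / 2
      if (frac_at(mid) > censor_frac) lo <- mid else hi <- mid
    }
    ctime <- u * (lo + hi) / 2
    event <- as.integer(times <= ctime)
    obs <- pmin(times, ctime)
  } else {
    event <- rep(1L, n)
    obs <- times
  }
  out <- lapply(seq_len(n), function(i) {
    pt <- cohort[[i]]
    pt$survival <- list(time = obs[i], event = event[i])
    pt
  })
  attr(out, "risk_score") <- s
  out
}

#' Write survival outcomes to CSV
#'
#' @param cohort A cohort with survival fields.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survival_csv <- function(cohort, path) {
  df <- data.frame(
    patient_id = vapply(cohort, function(p) p$patient_id, character(1L)),
    time = vapply(cohort, function(p) p$survival$time, numeric(1L)),
    event = vapply(cohort, function(p) p$survival$event, integer(1L)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}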