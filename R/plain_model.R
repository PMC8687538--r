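# Plaintext reference implementations: the exact GRU cell/model, the
# clamp-then-approximate reference model (the oracle the secure pipeline must
# match), the Weibull output head, and Harrell's concordance index.

#' GRU cell weights
#'
#' Container for one GRU layer's parameters: input matrices `W`, recurrent
#' matrices `U` (each `n_h x n_i` / `n_h x n_h`) and bias vectors for the
#' update gate `z`, reset gate `r` and candidate gate `g`.
#'
#' @param W_z,W_r,W_g Input weight matrices, `n_h x n_i`.
#' @param U_z,U_r,U_g Recurrent weight matrices, `n_h x n_h`.
#' @param b_z,b_r,b_g_vec Bias vectors of length `n_h`.
#' @return A `gru_cell_weights` object.
#' @export
gru_cell_weights <- function(W_z, U_z, b_z, W_r, U_r, b_r, W_g, U_g, b_g_vec) {
  n_h <- nrow(W_z); n_i <- ncol(W_z)
  for (m in list(W_r, W_g)) {
    if (!all(dim(m) == c(n_h, n_i))) {
      he_error("hegru_shape_error", "input weight matrix dimensions differ")
    }
  }
  for (m in list(U_z, U_r, U_g)) {
    if (!all(dim(m) == c(n_h, n_h))) {
      he_error("hegru_shape_error", "recurrent weight matrices must be n_h x n_h")
    }
  }
  for (b in list(b_z, b_r, b_g_vec)) {
    if (length(b) != n_h) {
      he_error("hegru_shape_error", "bias length must equal the hidden size")
    }
  }
  structure(list(W_z = W_z, U_z = U_z, b_z = b_z,
                 W_r = W_r, U_r = U_r, b_r = b_r,
                 W_g = W_g, U_g = U_g, b_g_vec = b_g_vec,
                 n_h = n_h, n_i = n_i),
            class = "gru_cell_weights")
}

#' Full GRU model weights
#'
#' Two GRU layers plus the dense output head. The reference architecture maps
#' 70-length visit vectors through hidden sizes 32 and 20 to the two dense
#' outputs feeding the Weibull head; the second layer contributes only its
#' last state.
#'
#' @param layer1,layer2 `gru_cell_weights` objects with matching chain
#'   dimensions.
#' @param dense_W Dense weight matrix, `2 x n_h2`.
#' @param dense_b Dense bias of length 2.
#' @return A `gru_model_weights` object.
#' @export
gru_model_weights <- function(layer1, layer2, dense_W, dense_b) {
  stopifnot(inherits(layer1, "gru_cell_weights"),
            inherits(layer2, "gru_cell_weights"))
  if (layer2$n_i != layer1$n_h) {
    he_error("hegru_shape_error", "layer2 input size must match layer1 hidden size")
  }
  if (ncol(dense_W) != layer2$n_h || nrow(dense_W) != 2L ||
      length(dense_b) != 2L) {
    he_error("hegru_shape_error", "dense head must be 2 x n_h2 with bias length 2")
  }
  structure(list(layer1 = layer1, layer2 = layer2,
                 dense = list(W = dense_W, b = dense_b),
                 layer2_returns_last_state_only = TRUE),
            class = "gru_model_weights")
}

#' @export
print.gru_model_weights <- function(x, ...) {
  cat(sprintf("<gru_model_weights %d -> %d -> %d -> 2>\n",
              x$layer1$n_i, x$layer1$n_h, x$layer2$n_h))
  invisible(x)
}

# The rounding-aware reference clamp mirroring the secure protocol exactly:
# shares are integer-rounded, so the comparison acts on round(m); values are
# clamped iff |round(m)| > R. Outside the band this equals the ideal clamp.
clamp_round <- function(m, R) {
  rm <- round(m)
  ifelse(rm > R, R, ifelse(rm < -R, -R, m))
}

# ideal (textbook) clamp, used as the sweep oracle outside the rounding band
clamp_ideal <- function(m, R) pmin(pmax(m, -R), R)

#' Plaintext GRU cell
#'
#' Reference forward pass for one cell. `mode = "exact"` uses the true sigmoid
#' and tanh. `mode = "clamped"` is the clamp-then-approximate reference the
#' secure pipeline must match: each pre-activation is passed through the
#' rounding-aware clamp (threshold `R` for the sigmoid gates, `R_tanh` for the
#' candidate gate) and the activations are evaluated with the Chebyshev
#' sigmoid interpolant (tanh via `2 sigma(2x) - 1`).
#'
#' The state update uses the rewritten one-multiplication form
#' `h_t = g + z (.) (h - g)`, algebraically identical to
#' `z (.) h + (1 - z) (.) g`.
#'
#' @param x Input vector of length `n_i`.
#' @param h Previous state of length `n_h`.
#' @param w A `gru_cell_weights` object.
#' @param mode `"exact"` or `"clamped"`.
#' @param cheb Sigmoid interpolant for clamped mode.
#' @param cfg [adjust_config()] supplying the clamp thresholds.
#' @return The new state vector `h_t`.
#' @export
gru_cell_plain <- function(x, h, w, mode = c("exact", "clamped"),
                           cheb = NULL, cfg = adjust_config()) {
  mode <- match.arg(mode)
  stopifnot(inherits(w, "gru_cell_weights"))
  if (length(x) != w$n_i || length(h) != w$n_h) {
    he_error("hegru_shape_error", "input/state lengths do not match the weights")
  }
  z_in <- as.numeric(w$W_z %*% x + w$U_z %*% h + w$b_z)
  r_in <- as.numeric(w$W_r %*% x + w$U_r %*% h + w$b_r)
  if (mode == "exact") {
    z <- sigmoid(z_in)
    r <- sigmoid(r_in)
    g_in <- as.numeric(w$W_g %*% x + w$U_g %*% (h * r) + w$b_g_vec)
    g <- tanh(g_in)
  } else {
    if (is.null(cheb)) cheb <- cheb_sigmoid(24L, c(-10, 10))
    z <- cheb_eval(cheb, clamp_round(z_in, cfg$R))
    r <- cheb_eval(cheb, clamp_round(r_in, cfg$R))
    g_in <- as.numeric(w$W_g %*% x + w$U_g %*% (h * r) + w$b_g_vec)
    g <- cheb_tanh(cheb, clamp_round(g_in, cfg$R_tanh))
  }
  g + z * (h - g)
}

#' Plaintext GRU model forward pass
#'
#' Layer 1 runs over all visit steps and emits the state sequence; layer 2
#' consumes it and keeps only its last state; the dense head returns the two
#' Weibull pre-activations `(a, b)`.
#'
#' @param records Visit matrix (`N` x `n_i`) or `patient_record`.
#' @param model A `gru_model_weights`.
#' @inheritParams gru_cell_plain
#' @return List with `a`, `b` and the hidden pre-activations collected for
#'   diagnostics (`preacts`, a list of per-gate pre-activation vectors).
#' @export
model_forward <- function(records, model, mode = c("exact", "clamped"),
                          cheb = NULL, cfg = adjust_config()) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "gru_model_weights"))
  x <- validate_records(records, model$layer1$n_i)
  if (mode == "clamped" && is.null(cheb)) cheb <- cheb_sigmoid(24L, c(-10, 10))
  n <- nrow(x)
  preacts <- list()
  run_layer <- function(w, inputs) {
    h <- numeric(w$n_h)
    out <- matrix(0, nrow(inputs), w$n_h)
    for (t in seq_len(nrow(inputs))) {
      xt <- inputs[t, ]
      z_in <- as.numeric(w$W_z %*% xt + w$U_z %*% h + w$b_z)
      r_in <- as.numeric(w$W_r %*% xt + w$U_r %*% h + w$b_r)
      if (mode == "exact") {
        z <- sigmoid(z_in); r <- sigmoid(r_in)
      } else {
        z <- cheb_eval(cheb, clamp_round(z_in, cfg$R))
        r <- cheb_eval(cheb, clamp_round(r_in, cfg$R))
      }
      g_in <- as.numeric(w$W_g %*% xt + w$U_g %*% (h * r) + w$b_g_vec)
      g <- if (mode == "exact") tanh(g_in) else {
        cheb_tanh(cheb, clamp_round(g_in, cfg$R_tanh))
      }
      preacts[[length(preacts) + 1L]] <<- list(z = z_in, r = r_in, g = g_in)
      h <- g + z * (h - g)
      out[t, ] <- h
    }
    out
  }
  h1 <- run_layer(model$layer1, x)
  h2 <- run_layer(model$layer2, h1)
  last <- h2[n, ]
  ab <- as.numeric(model$dense$W %*% last + model$dense$b)
  list(a = ab[1L], b = ab[2L], preacts = preacts)
}

#' Weibull output activation
#'
#' Maps the dense outputs to strictly positive Weibull parameters:
#' `alpha = exp(a)` (scale) and `beta = softplus(b) = log(1 + exp(b))`
#' (shape). Both maps are strictly monotone, so the dense outputs and the
#' Weibull parameters are one-to-one.
#'
#' @param a,b Dense head outputs.
#' @return List with `alpha` and `beta`.
#' @export
weibull_activate <- function(a, b) {
  alpha <- exp(pmin(a, 700))
  # overflow-guarded softplus
  beta <- ifelse(b > 30, b, log1p(exp(pmin(b, 30))))
  list(alpha = alpha, beta = beta)
}

#' Predicted median event time of a Weibull distribution
#'
#' `median = alpha * log(2)^(1/beta)`; the negated median is the package's
#' default risk score (higher risk = shorter predicted time to event).
#'
#' @param alpha,beta Weibull scale and shape.
#' @return Median event time.
#' @export
weibull_median <- function(alpha, beta) alpha * log(2)^(1 / beta)

#' Harrell's concordance index
#'
#' Fraction of admissible pairs whose risk ordering agrees with the observed
#' event ordering: a pair is admissible when the earlier observed time is an
#' event (Harrell's original censoring rule); concordance means the earlier
#' event carries the higher risk; tied risks count 1/2.
#'
#' @param time Observed or censored times (positive).
#' @param event 0/1 event indicators (1 = event observed).
#' @param risk Model risk scores (higher = expected earlier event).
#' @return Concordance index in `[0, 1]`.
#' @export
concordance_index <- function(time, event, risk) {
  n <- length(time)
  stopifnot(length(event) == n, length(risk) == n)
  if (n < 2L || sum(event) < 1L) {
    he_error("hegru_input_error",
             "concordance needs at least two records and one event")
  }
  conc <- 0; ties <- 0; adm <- 0
  for (i in which(event == 1L)) {
    later <- (time > time[i]) | (time == time[i] & event == 0L)
    later[i] <- FALSE
    adm <- adm + sum(later)
    conc <- conc + sum(risk[i] > risk[later])
    ties <- ties + sum(risk[i] == risk[later])
  }
  if (adm == 0) {
    he_error("hegru_input_error", "no admissible pairs for the concordance index")
  }
  (conc + 0.5 * ties) / adm
}

# ---- model weight and record files ------------------------------------------

#' Write model weights to JSON
#'
#' Named arrays per gate per layer; full double precision.
#'
#' @param model A `gru_model_weights`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weights_json <- function(model, path) {
  stopifnot(inherits(model, "gru_model_weights"))
  ser_layer <- function(l) {
    list(W_z = l$W_z, U_z = l$U_z, b_z = l$b_z,
         W_r = l$W_r, U_r = l$U_r, b_r = l$b_r,
         W_g = l$W_g, U_g = l$U_g, b_g = l$b_g_vec)
  }
  jsonlite::write_json(
    list(format = "hegru-weights-1",
         layer1 = ser_layer(model$layer1),
         layer2 = ser_layer(model$layer2),
         dense = list(W = model$dense$W, b = model$dense$b)),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read model weights written by [write_weights_json()]
#'
#' Dimensions are validated on load.
#'
#' @param path JSON file path.
#' @return A `gru_model_weights`.
#' @export
read_weights_json <- function(path) {
  if (!file.exists(path)) {
    he_error("hegru_io_error", sprintf("weights file not found: %s", path))
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "hegru-weights-1")) {
    he_error("hegru_io_error", "unrecognized weights file format")
  }
  de_layer <- function(l) {
    gru_cell_weights(as.matrix(l$W_z), as.matrix(l$U_z), as.numeric(l$b_z),
                     as.matrix(l$W_r), as.matrix(l$U_r), as.numeric(l$b_r),
                     as.matrix(l$W_g), as.matrix(l$U_g), as.numeric(l$b_g))
  }
  gru_model_weights(de_layer(obj$layer1), de_layer(obj$layer2),
                    as.matrix(obj$dense$W), as.numeric(obj$dense$b))
}

#' Write patient visit records to CSV
#'
#' One row per visit: `patient_id`, `visit_index`, `month`, then the feature
#' columns `f1..f<n>`.
#'
#' @param cohort List of `patient_record` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(cohort, path) {
  rows <- lapply(cohort, function(p) {
    data.frame(patient_id = p$patient_id,
               visit_index = seq_len(nrow(p$features)),
               month = p$months,
               p$features)
  })
  df <- do.call(rbind, rows)
  names(df)[-(1:3)] <- paste0("f", seq_len(ncol(df) - 3L))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read patient visit records written by [write_records_csv()]
#'
#' @param path CSV file path.
#' @return A list of `patient_record` objects (without survival fields).
#' @export
read_records_csv <- function(path) {
  if (!file.exists(path)) {
    he_error("hegru_io_error", sprintf("records file not found: %s", path))
  }
  df <- utils::read.csv(path)
  fcols <- grep("^f[0-9]+$", names(df))
  lapply(split(df, df$patient_id), function(d) {
    d <- d[order(d$visit_index), ]
    structure(list(patient_id = d$patient_id[1L],
                   months = d$month,
                   features = as.matrix(d[, fcols, drop = FALSE]),
                   survival = NULL),
              class = "patient_record")
  })
}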