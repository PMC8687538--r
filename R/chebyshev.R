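# Chebyshev interpolants for the sigmoid (and tanh via the identity
# tanh(x) = 2*sigma(2x) - 1), evaluated in plain arithmetic (Clenshaw) and on
# ciphertexts (depth-balanced Chebyshev-basis product scheme).

#' Logistic sigmoid
#'
#' @param x Numeric vector.
#' @return `1 / (1 + exp(-x))`.
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Build a Chebyshev interpolant of the sigmoid
#'
#' Interpolates `sigma(x) = 1/(1+exp(-x))` at the `degree + 1` Chebyshev
#' points of the first kind mapped to `[a, b]`. The protocol default is degree
#' 24 on `[-10, 10]`; combined with the clamp threshold `R = 9` this keeps
#' every adjusted pre-activation (including the rounding band, which can reach
#' `R + 1` in magnitude) inside the interpolation range. The maximum absolute
#' error on a dense 10,001-point grid over the range is computed at build time
#' and stored in the returned metadata.
#'
#' @param degree Polynomial degree `d >= 1` (use `degree = 0` for the constant
#'   node-mean, mainly of diagnostic interest).
#' @param range Numeric `c(a, b)` interpolation interval, `a < b`.
#' @return An object of class `cheb_poly`: Chebyshev-basis `coef` (length
#'   `degree + 1`), `range`, `degree`, `target = "sigmoid"` and `max_err`.
#' @export
cheb_sigmoid <- function(degree = 24L, range = c(-10, 10)) {
  cheb_interpolant(sigmoid, degree, range, target = "sigmoid")
}

cheb_interpolant <- function(f, degree, range, target) {
  degree <- as.integer(degree)
  if (degree < 0L) he_error("hegru_param_error", "degree must be non-negative")
  a <- range[1L]; b <- range[2L]
  if (!is.finite(a) || !is.finite(b) || a >= b) {
    he_error("hegru_param_error", "range must be a finite interval with a < b")
  }
  n <- degree + 1L
  theta <- pi * (seq_len(n) - 0.5) / n
  t_nodes <- cos(theta)
  x_nodes <- (a + b) / 2 + (b - a) / 2 * t_nodes
  fx <- f(x_nodes)
  # first-kind node DCT: c_k = (2/n) sum_j f(x_j) cos(k theta_j), c_0 halved
  coef <- vapply(0:degree, function(k) {
    (2 / n) * sum(fx * cos(k * theta))
  }, numeric(1L))
  coef[1L] <- coef[1L] / 2
  p <- structure(
    list(coef = coef, range = c(a, b), degree = degree, target = target,
         max_err = NA_real_, nodes = x_nodes),
    class = "cheb_poly"
  )
  grid <- seq(a, b, length.out = 10001L)
  p$max_err <- max(abs(cheb_eval(p, grid) - f(grid)))
  p
}

#' @export
print.cheb_poly <- function(x, ...) {
  cat(sprintf("<cheb_poly %s degree=%d range=[%g, %g] max_err=%.3g>\n",
              x$target, x$degree, x$range[1L], x$range[2L], x$max_err))
  invisible(x)
}

#' Evaluate a Chebyshev interpolant (plain)
#'
#' Clenshaw recurrence; numerically stable inside the interpolation range.
#' Arguments outside the range are evaluated as-is — polynomial interpolants
#' diverge rapidly there, which is exactly the failure mode the secure clamp
#' protocol exists to prevent.
#'
#' @param p A `cheb_poly`.
#' @param x Numeric vector.
#' @return Numeric vector of interpolant values.
#' @export
cheb_eval <- function(p, x) {
  stopifnot(inherits(p, "cheb_poly"))
  t <- (2 * x - sum(p$range)) / diff(p$range)
  d <- p$degree
  if (d == 0L) return(rep(p$coef[1L], length(x)))
  b1 <- numeric(length(x))
  b2 <- numeric(length(x))
  for (k in seq(d + 1L, 2L)) {
    tmp <- 2 * t * b1 - b2 + p$coef[k]
    b2 <- b1
    b1 <- tmp
  }
  t * b1 - b2 + p$coef[1L]
}

#' Chebyshev coefficients in the power basis
#'
#' Converts the Chebyshev-basis coefficients to monomial coefficients in the
#' normalized variable `t = (2x - (a+b)) / (b-a)`. Used as an independent
#' cross-check of the Clenshaw evaluator; the conversion itself is
#' ill-conditioned at high degree and is not used for protocol evaluation.
#'
#' @param p A `cheb_poly`.
#' @return Numeric vector of monomial coefficients in `t`, constant first.
#' @export
cheb_to_power <- function(p) {
  d <- p$degree
  # rows: T_0 .. T_d in the monomial basis
  tmat <- matrix(0, d + 1L, d + 1L)
  tmat[1L, 1L] <- 1
  if (d >= 1L) tmat[2L, 2L] <- 1
  if (d >= 2L) {
    for (k in 3L:(d + 1L)) {
      tmat[k, ] <- 2 * c(0, tmat[k - 1L, -(d + 1L)]) - tmat[k - 2L, ]
    }
  }
  as.numeric(p$coef %*% tmat)
}

# depth (levels) consumed by cheb_eval_he: 1 for the affine slot map onto
# [-1, 1], ceil(log2 d) for the Chebyshev product chain, 1 for the plaintext
# coefficient products
cheb_he_depth <- function(degree) {
  if (degree <= 1L) return(2L)
  1L + as.integer(ceiling(log2(degree))) + 1L
}

#' Evaluate a Chebyshev interpolant on a ciphertext
#'
#' Homomorphic evaluation using a depth-balanced scheme: the Chebyshev basis
#' polynomials `T_k` are formed by the product recurrences
#' `T_{2m} = 2 T_m^2 - 1` and `T_{2m+1} = 2 T_m T_{m+1} - T_1` (doublings are
#' additions, which are free), so a degree-`d` interpolant consumes
#' `ceil(log2 d) + 2` levels instead of the `d` a naive Horner/Clenshaw walk
#' would. Slots are assumed pre-clamped into the interpolation range by the
#' secure input-adjustment protocol.
#'
#' @param p A `cheb_poly`.
#' @param ct An `he_ct` ciphertext with level at least `ceil(log2 d) + 2`.
#' @return An `he_ct` of per-slot interpolant values.
#' @export
cheb_eval_he <- function(p, ct) {
  stopifnot(inherits(p, "cheb_poly"), inherits(ct, "he_ct"))
  need <- cheb_he_depth(p$degree)
  if (ct$level < need) {
    he_error("hegru_depth_error",
             sprintf("degree-%d interpolant needs level %d, ciphertext is at %d",
                     p$degree, need, ct$level))
  }
  d <- p$degree
  if (d == 0L) {
    return(he_add(he_mul(ct, 0), p$coef[1L]))
  }
  # affine map onto [-1, 1]: t = (2x - (a+b)) / (b - a)
  t1 <- he_add(he_mul(ct, 2 / diff(p$range)), -sum(p$range) / diff(p$range))
  tk <- vector("list", d)        # tk[[k]] holds T_k(t) as a ciphertext
  tk[[1L]] <- t1
  get_t <- function(k) {
    if (!is.null(tk[[k]])) return(tk[[k]])
    m <- k %/% 2L
    res <- if (k %% 2L == 0L) {
      sq <- he_mul(get_t(m), get_t(m))
      he_add(he_add(sq, sq), -1)             # 2 T_m^2 - 1
    } else {
      pr <- he_mul(get_t(m), get_t(m + 1L))
      he_sub(he_add(pr, pr), t1)             # 2 T_m T_{m+1} - T_1
    }
    tk[[k]] <<- res
    res
  }
  acc <- NULL
  for (k in seq_len(d)) {
    if (p$coef[k + 1L] == 0) next
    term <- he_mul(get_t(k), p$coef[k + 1L])
    acc <- if (is.null(acc)) term else he_add(acc, term)
  }
  if (is.null(acc)) acc <- he_mul(ct, 0)
  he_add(acc, p$coef[1L])
}

#' Hyperbolic tangent via the sigmoid interpolant (plain)
#'
#' Uses `tanh(x) = 2 * sigma(2x) - 1` with the shared sigmoid interpolant, so
#' no separate tanh approximation is needed. Accuracy is at most twice the
#' sigmoid interpolant's error wherever `2x` stays inside the interpolation
#' range.
#'
#' @param p The sigmoid `cheb_poly`.
#' @param x Numeric vector with `2x` inside (or near) `p$range`.
#' @return Numeric vector of tanh approximations.
#' @export
cheb_tanh <- function(p, x) 2 * cheb_eval(p, 2 * x) - 1

#' Hyperbolic tangent via the sigmoid interpolant (ciphertext)
#'
#' Homomorphic counterpart of [cheb_tanh()]. The argument doubling and the
#' final affine step are additions, so the depth cost equals that of
#' [cheb_eval_he()]. Slots must be pre-clamped so `2x` lies in the sigmoid
#' interpolant's range (clamp threshold `R_tanh = 4` with the default
#' `[-10, 10]` range).
#'
#' @param p The sigmoid `cheb_poly`.
#' @param ct An `he_ct` ciphertext.
#' @return An `he_ct` of per-slot tanh approximations.
#' @export
cheb_tanh_he <- function(p, ct) {
  s <- cheb_eval_he(p, he_add(ct, ct))
  he_add(he_add(s, s), -1)
}

#' Serialize a Chebyshev interpolant to JSON
#'
#' @param p A `cheb_poly`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
cheb_save <- function(p, path) {
  stopifnot(inherits(p, "cheb_poly"))
  jsonlite::write_json(
    list(target = p$target, degree = p$degree, range = p$range,
         coef = p$coef, max_err = p$max_err),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a Chebyshev interpolant saved by [cheb_save()]
#'
#' @param path JSON file path.
#' @return A `cheb_poly`.
#' @export
cheb_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(coef = as.numeric(obj$coef), range = as.numeric(obj$range),
         degree = as.integer(obj$degree), target = obj$target,
         max_err = as.numeric(obj$max_err)),
    class = "cheb_poly"
  )
}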