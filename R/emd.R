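#' Sifting configuration for empirical mode decomposition
#'
#' Controls the inner sifting loop and the outer extraction loop of [emd()].
#'
#' The sifting stop is the classical Cauchy-type standard-deviation criterion
#' \eqn{SD = \sum_t (h_{prev}(t) - h(t))^2 / \sum_t h_{prev}(t)^2}: sifting a
#' candidate component ends once `SD < sd_threshold` *and* the candidate
#' passes the two intrinsic-mode-function conditions (see [is_imf()]), or
#' after `max_sift_iterations`.
#'
#' @param sd_threshold Positive Cauchy-type stopping threshold (default 0.2,
#'   the conventional value in the EMD literature).
#' @param max_sift_iterations Cap on sifting passes per component (default 100).
#' @param max_imfs Cap on the number of extracted components (default 16).
#' @param boundary_policy How envelopes are anchored at the series ends:
#'   `"mirror"` reflects the two extrema nearest each end across it before
#'   spline fitting (default), `"clamp"` pins the envelope to the end samples.
#' @param sym_tol Local-zero-mean tolerance used by [is_imf()], as a fraction
#'   of the candidate's amplitude half-range (default 0.05).
#' @param residue_range_tol Extraction stops when the running residue's range
#'   falls below this fraction of the source range (default 1e-3); a residue
#'   this small carries no further mode worth extracting.
#' @return A list of class `sift_config`.
#' @export
sift_config <- function(sd_threshold = 0.2, max_sift_iterations = 100L,
                        max_imfs = 16L, boundary_policy = c("mirror", "clamp"),
                        sym_tol = 0.05, residue_range_tol = 1e-3) {
  boundary_policy <- match.arg(boundary_policy)
  if (!is.numeric(sd_threshold) || sd_threshold <= 0) {
    abort("`sd_threshold` must be > 0.", class = "emdcast_invalid_input")
  }
  if (max_sift_iterations < 1) {
    abort("`max_sift_iterations` must be >= 1.", class = "emdcast_invalid_input")
  }
  structure(list(sd_threshold = sd_threshold,
                 max_sift_iterations = as.integer(max_sift_iterations),
                 max_imfs = as.integer(max_imfs),
                 boundary_policy = boundary_policy,
                 sym_tol = sym_tol,
                 residue_range_tol = residue_range_tol),
            class = "sift_config")
}

#' Locate local extrema of a sequence
#'
#' Strictly interior indices where the value exceeds (falls below) both
#' neighbours. A plateau of equal values bounded by smaller (larger) values
#' yields one representative index at the plateau midpoint, rounded down —
#' a deterministic convention that keeps extrema counts well defined.
#'
#' @param x Numeric vector, length >= 3.
#' @return A list with integer vectors `maxima` and `minima` (1-based indices).
#' @examples
#' find_extrema(c(0, 1, 0, -1, 0, 1, 0))
#' @export
find_extrema <- function(x) {
  if (length(x) < 3) {
    abort("`x` must have length >= 3 to hold interior extrema.",
          class = "emdcast_invalid_input")
  }
  r <- rle(as.numeric(x))
  K <- length(r$values)
  maxima <- integer(0)
  minima <- integer(0)
  if (K >= 3) {
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in 2:(K - 1L)) {
      mid <- (starts[k] + ends[k]) %/% 2L
      if (r$values[k] > r$values[k - 1L] && r$values[k] > r$values[k + 1L]) {
        maxima <- c(maxima, mid)
      } else if (r$values[k] < r$values[k - 1L] && r$values[k] < r$values[k + 1L]) {
        minima <- c(minima, mid)
      }
    }
  }
  list(maxima = maxima, minima = minima)
}

# Natural cubic spline through one family of extrema, evaluated at 1..n.
# mirror: reflect up to two extrema across each end so the spline is supported
# on the whole index range; clamp: anchor the end samples themselves.
envelope_spline <- function(idx, val, n, boundary_policy, end_values = NULL) {
  if (boundary_policy == "mirror") {
    k <- min(2L, length(idx))
    left_i <- 2L - idx[seq_len(k)]
    left_v <- val[seq_len(k)]
    right_i <- 2L * n - idx[length(idx) - seq_len(k) + 1L]
    right_v <- val[length(val) - seq_len(k) + 1L]
    xs <- c(left_i, idx, right_i)
    ys <- c(left_v, val, right_v)
  } else {
    xs <- idx
    ys <- val
    if (xs[1] != 1L) { xs <- c(1L, xs); ys <- c(end_values[1], ys) }
    if (xs[length(xs)] != n) { xs <- c(xs, n); ys <- c(ys, end_values[2]) }
  }
  ord <- order(xs)
  xs <- xs[ord]; ys <- ys[ord]
  keep <- !duplicated(xs)
  spline(xs[keep], ys[keep], xout = seq_len(n), method = "natural")$y
}

#' Upper and lower cubic-spline envelopes of a sequence
#'
#' Natural cubic splines through the local maxima (upper) and minima (lower),
#' evaluated at every sample. Requires at least two extrema of each kind;
#' signals with fewer are not siftable and the caller should terminate
#' decomposition.
#'
#' @param x Numeric vector.
#' @param boundary_policy `"mirror"` (default) or `"clamp"`; see [sift_config()].
#' @return A list with numeric vectors `upper` and `lower`, each `length(x)`.
#' @export
compute_envelopes <- function(x, boundary_policy = "mirror") {
  e <- find_extrema(x)
  if (length(e$maxima) < 2 || length(e$minima) < 2) {
    abort("Fewer than 2 maxima or minima: signal is not siftable; terminate decomposition.",
          class = "emdcast_not_siftable")
  }
  n <- length(x)
  list(upper = envelope_spline(e$maxima, x[e$maxima], n, boundary_policy,
                               end_values = c(x[1], x[n])),
       lower = envelope_spline(e$minima, x[e$minima], n, boundary_policy,
                               end_values = c(x[1], x[n])))
}

#' Mean of the upper and lower envelopes
#'
#' @param upper,lower Numeric vectors of equal length.
#' @return Elementwise `(upper + lower) / 2`.
#' @export
mean_envelope <- function(upper, lower) {
  if (length(upper) != length(lower)) {
    abort("`upper` and `lower` must have equal length.", class = "emdcast_invalid_input")
  }
  (upper + lower) / 2
}

# sign changes, zeros ignored
zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0L)
}

#' Test the two intrinsic-mode-function conditions
#'
#' A component qualifies as an intrinsic mode function (IMF) when (i) its
#' numbers of extrema and zero-crossings are equal or differ by at most one,
#' and (ii) it is locally symmetric about zero, checked here as the mean
#' envelope staying within `sym_tol` times the amplitude half-range.
#'
#' @param x Numeric vector, length >= 3.
#' @param sym_tol Symmetry tolerance as a fraction of the half-range
#'   (default 0.05).
#' @param boundary_policy Envelope boundary handling, as in [sift_config()].
#' @return `TRUE` or `FALSE`.
#' @export
is_imf <- function(x, sym_tol = 0.05, boundary_policy = "mirror") {
  e <- find_extrema(x)
  if (length(e$maxima) < 2 || length(e$minima) < 2) return(FALSE)
  n_ext <- length(e$maxima) + length(e$minima)
  if (abs(n_ext - zero_crossings(x)) > 1L) return(FALSE)
  env <- compute_envelopes(x, boundary_policy)
  m <- mean_envelope(env$upper, env$lower)
  half_range <- (max(x) - min(x)) / 2
  max(abs(m)) < sym_tol * half_range
}

#' Sift one intrinsic mode function out of a sequence
#'
#' Repeatedly subtracts the mean envelope, `h <- h - m(h)`, until the
#' Cauchy-type SD criterion drops below `cfg$sd_threshold` *and* [is_imf()]
#' holds, or `cfg$max_sift_iterations` passes are exhausted.
#'
#' @param x Numeric vector with at least two maxima and two minima.
#' @param cfg A [sift_config()].
#' @return A list with `imf` (numeric vector) and `n_iterations` (integer).
#' @export
sift_one_imf <- function(x, cfg = sift_config()) {
  e <- find_extrema(x)
  if (length(e$maxima) < 2 || length(e$minima) < 2) {
    abort("Input is not siftable (needs >= 2 maxima and >= 2 minima); terminate decomposition.",
          class = "emdcast_not_siftable")
  }
  h <- as.numeric(x)
  it <- 0L
  for (i in seq_len(cfg$max_sift_iterations)) {
    it <- i
    env <- tryCatch(compute_envelopes(h, cfg$boundary_policy),
                    emdcast_not_siftable = function(e) NULL)
    if (is.null(env)) break
    m <- mean_envelope(env$upper, env$lower)
    h_new <- h - m
    SD <- sum((h - h_new)^2) / sum(h^2)
    h <- h_new
    if (SD < cfg$sd_threshold && is_imf(h, cfg$sym_tol, cfg$boundary_policy)) break
  }
  list(imf = h, n_iterations = it)
}

is_monotone <- function(x) all(diff(x) >= 0) || all(diff(x) <= 0)

#' Empirical mode decomposition of a monthly series
#'
#' Decomposes `data$value` into intrinsic mode functions (IMFs), ordered from
#' highest to lowest characteristic frequency, plus a slowly varying residue.
#' Extraction stops when the running residue is monotone, has fewer than two
#' maxima or minima, shrinks below `residue_range_tol` of the source range, or
#' `max_imfs` is reached. By construction the components sum back to the
#' source series exactly (to floating-point roundoff).
#'
#' @param data Monthly series tibble (see [monthly_series()]), length >= 8.
#' @param cfg A [sift_config()].
#' @return An object of class `emd_decomposition`: a tibble with columns
#'   `date`, `imf1` ... `imfk`, `residue`, carrying the source values as
#'   attribute `source`. Use [tidy()] for a long view and [autoplot()] to plot.
#' @examples
#' x <- simulate_outpatient_series(seed = 1)
#' dec <- emd(x)
#' glance(dec)
#' @export
emd <- function(data, cfg = sift_config()) {
  data <- validate_monthly_series(data)
  x <- data$value
  if (length(x) < 8) {
    abort("Series too short to decompose (needs >= 8 samples for envelope fitting).",
          class = "emdcast_invalid_input")
  }
  source_range <- max(x) - min(x)
  residue <- x
  imfs <- list()
  repeat {
    if (length(imfs) >= cfg$max_imfs) break
    e <- find_extrema(residue)
    if (length(e$maxima) < 2 || length(e$minima) < 2) break
    if (is_monotone(residue)) break
    if ((max(residue) - min(residue)) < cfg$residue_range_tol * source_range) break
    s <- sift_one_imf(residue, cfg)
    imfs[[length(imfs) + 1L]] <- s$imf
    residue <- residue - s$imf
  }
  out <- tibble::tibble(date = data$date)
  for (i in seq_along(imfs)) out[[paste0("imf", i)]] <- imfs[[i]]
  out$residue <- residue
  structure(out, source = x, cfg = cfg,
            class = c("emd_decomposition", class(out)))
}

#' Number of intrinsic mode functions in a decomposition
#' @param x An `emd_decomposition`.
#' @return Integer count of IMF columns (excludes the residue).
#' @export
n_imfs <- function(x) {
  stopifnot(inherits(x, "emd_decomposition"))
  sum(grepl("^imf[0-9]+$", names(x)))
}

# component columns in extraction order, residue last
component_names <- function(x) {
  c(paste0("imf", seq_len(n_imfs(x))), "residue")
}

#' @export
print.emd_decomposition <- function(x, ...) {
  cat(sprintf("Empirical mode decomposition: %d IMFs + residue over %d months (%s to %s)\n",
              n_imfs(x), nrow(x), format(x$date[1], "%Y-%m"),
              format(x$date[nrow(x)], "%Y-%m")))
  NextMethod()
}
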