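#' Fit a PEG-turbidity curve to the Boltzmann sigmoid
#'
#' Fits `y = A2 + (A1 - A2) / (1 + exp((x - x0)/dx))` by nonlinear least
#' squares, the standard four-parameter description of crowding-induced
#' turbidity: `A1` is the soluble (low-PEG) plateau, `A2` the turbid
#' plateau, `x0` the midpoint in PEG weight percent and `dx` the
#' transition width.  The half-solubility point of a condition is `x0`,
#' i.e. the PEG% at which optical density reaches half of its maximal
#' plateau.
#'
#' A fitted midpoint is only trusted when the upper plateau is actually
#' reached inside the measured range; the reliability rule is
#' `x0 + plateau_k * dx <= max(x)` and `A2 <= 1.2 * max(y)`.  Curves that
#' fail it (e.g. a nearly flat gamma-crystallin curve) get
#' `plateau_reached = FALSE` and an `NA` half-solubility, mirroring how
#' unreliable solubility limits are reported as dashes.
#'
#' Re-entrant declines at extreme crowding (turbidity dropping again
#' above ~15% PEG) are not part of the sigmoid model: the data are
#' truncated at the curve maximum before fitting.
#'
#' @param peg_percent strictly increasing PEG weight/volume percentages.
#' @param od optical densities at those percentages.
#' @param plateau_k reliability multiplier on `dx` (default 2).
#' @param n_restarts extra randomized restarts if the first fit fails.
#' @return an object of class `sigmoid_fit`: list with `a1`, `a2`, `x0`,
#'   `dx`, `adj_r2`, `plateau_reached`, `half_solubility`, `converged`,
#'   and the fitted values.
#' @examples
#' x <- 0:20
#' y <- 1.6 + (0.2 - 1.6) / (1 + exp((x - 6.9) / 0.8))
#' fit_boltzmann(x, y)$x0
#' @export
fit_boltzmann <- function(peg_percent, od, plateau_k = 2, n_restarts = 5) {
  x <- as.numeric(peg_percent)
  y <- as.numeric(od)
  if (length(x) != length(y)) stop("peg_percent and od lengths differ")
  if (length(x) < 5) stop("need at least 5 points")
  if (is.unsorted(x, strictly = TRUE)) stop("peg_percent must be strictly increasing")
  if (diff(range(y)) <= 0) stop("od range is zero; nothing to fit")

  ## truncate any re-entrant decline past the maximum
  imax <- which.max(y)
  if (imax < length(y) && y[length(y)] < y[imax] - 0.15 * diff(range(y))) {
    x <- x[seq_len(imax)]
    y <- y[seq_len(imax)]
    if (length(x) < 5) stop("fewer than 5 points left of the turbidity maximum")
  }

  a1_0 <- min(y)
  a2_0 <- max(y)
  half <- (a1_0 + a2_0) / 2
  cross <- which(y >= half)[1]
  x0_0 <- if (is.na(cross)) stats::median(x) else x[cross]
  dx_0 <- diff(range(x)) / 10

  dat <- data.frame(x = x, y = y)
  fit <- NULL
  starts <- list(c(a1_0, a2_0, x0_0, dx_0))
  for (k in seq_len(n_restarts)) {
    jit <- 1 + 0.3 * sin(k * c(1.3, 2.1, 3.7, 0.9))  # deterministic jitter
    starts[[k + 1]] <- c(a1_0 * jit[1], a2_0 * jit[2],
                         x0_0 + (k - n_restarts / 2) * dx_0, dx_0 * jit[4])
  }
  for (s in starts) {
    fit <- tryCatch(
      stats::nls(y ~ a2 + (a1 - a2) / (1 + exp((x - x0) / dx)), data = dat,
                 start = list(a1 = s[1], a2 = s[2], x0 = s[3],
                              dx = max(s[4], 1e-3)),
                 control = stats::nls.control(maxiter = 200, warnOnly = FALSE),
                 algorithm = "port",
                 # plateaus are optical densities: non-negative; keeping
                 # A1 >= 0 also regularizes curves whose lower plateau
                 # lies outside the measured PEG range
                 lower = c(a1 = 0, a2 = 0, x0 = -Inf, dx = 1e-6)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    out <- list(a1 = NA_real_, a2 = NA_real_, x0 = NA_real_, dx = NA_real_,
                adj_r2 = NA_real_, plateau_reached = FALSE,
                half_solubility = NA_real_, converged = FALSE,
                fitted = rep(NA_real_, length(x)), x = x, y = y)
    class(out) <- "sigmoid_fit"
    return(out)
  }
  cf <- stats::coef(fit)
  yhat <- stats::fitted(fit)
  n <- length(y)
  p <- 4
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  plateau <- (cf[["x0"]] + plateau_k * cf[["dx"]] <= max(x)) &&
    (cf[["a2"]] <= 1.2 * max(y))
  out <- list(a1 = cf[["a1"]], a2 = cf[["a2"]], x0 = cf[["x0"]],
              dx = cf[["dx"]], adj_r2 = adj_r2, plateau_reached = plateau,
              half_solubility = if (plateau) cf[["x0"]] else NA_real_,
              converged = TRUE, fitted = yhat, x = x, y = y)
  class(out) <- "sigmoid_fit"
  out
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Boltzmann fit: did not converge\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Boltzmann fit: A1 = %.3f, A2 = %.3f, x0 = %.2f, dx = %.2f (adj R2 = %.3f)\n",
    x$a1, x$a2, x$x0, x$dx, x$adj_r2))
  if (x$plateau_reached) {
    cat(sprintf("  1/2-solubility: %.2f %% PEG\n", x$half_solubility))
  } else {
    cat("  plateau not reached within data range; 1/2-solubility unreliable (-)\n")
  }
  invisible(x)
}

#' Turbidity-kinetics summary metrics
#'
#' From a time/OD trace, computes the initial OD (mean over a leading
#' baseline window), the plateau OD (mean over the trailing fraction of
#' the trace), the percent turbidity increase
#' `100 * (plateau - initial) / initial`, the half-max
#' `OD_1/2 = (initial + plateau) / 2`, and the time `t_half` at which the
#' trace first crosses `OD_1/2` (linear interpolation between samples).
#'
#' @param time strictly increasing sample times (minutes by convention).
#' @param od optical densities.
#' @param baseline_n number of leading samples averaged for the initial
#'   OD (default 3).
#' @param plateau_fraction trailing fraction of samples averaged for the
#'   plateau (default 0.1).
#' @return a list of class `kinetics_metrics` with fields `initial_od`,
#'   `plateau_od`, `percent_increase`, `od_half`, `t_half` (NA with
#'   `crossed = FALSE` when the trace never reaches `OD_1/2`).
#' @export
kinetics_metrics <- function(time, od, baseline_n = 3, plateau_fraction = 0.1) {
  t <- as.numeric(time)
  y <- as.numeric(od)
  if (length(t) != length(y)) stop("time and od lengths differ")
  if (length(t) < 10) stop("need at least 10 samples")
  if (is.unsorted(t, strictly = TRUE)) stop("time must be strictly increasing")
  n <- length(t)
  initial <- mean(y[seq_len(min(baseline_n, n))])
  n_tail <- max(1L, ceiling(plateau_fraction * n))
  plateau <- mean(y[(n - n_tail + 1L):n])
  od_half <- (initial + plateau) / 2
  t_half <- first_crossing(t, y, od_half)
  out <- list(initial_od = initial, plateau_od = plateau,
              percent_increase = 100 * (plateau - initial) / initial,
              od_half = od_half, t_half = t_half,
              crossed = is.finite(t_half))
  class(out) <- "kinetics_metrics"
  out
}

## first time at which y rises through `level` from below, linearly
## interpolated; NA when no upward crossing exists (flat traces included)
first_crossing <- function(t, y, level) {
  n <- length(y)
  idx <- which(y[-n] < level & y[-1] >= level)
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  frac <- (level - y[i]) / (y[i + 1] - y[i])
  t[i] + frac * (t[i + 1] - t[i])
}

#' Min-max fluorescence normalization
#'
#' Maps every point of a trace through `(t - MIN) / (MAX - MIN)`.  By
#' default MIN and MAX are the minimum and maximum of the trace itself.
#' For near-flat control traces (e.g. alginate-only wells with minimal
#' signal), supply `reference` — the paired crystallin-containing trace —
#' and its maximum is used as MAX instead, so a flat control maps near 0
#' rather than being stretched over [0, 1].
#'
#' @param values fluorescence (or OD) trace.
#' @param reference optional reference trace supplying MAX.
#' @return normalized numeric vector.
#' @export
normalize_fluorescence <- function(values, reference = NULL) {
  v <- as.numeric(values)
  lo <- min(v)
  hi <- if (is.null(reference)) max(v) else max(as.numeric(reference))
  if (hi <= lo) stop("zero dynamic range: MAX must exceed MIN")
  (v - lo) / (hi - lo)
}

#' Time for a treated trace to reach the control's half-max OD
#'
#' Given kinetics metrics of a control trace (which define `OD_1/2`) and
#' a treated time/OD trace, returns the first time the treated trace
#' crosses the control's `OD_1/2`.  Used to quantify the turbidity delay
#' produced by candidate anti-cataract compounds.
#'
#' @param control a `kinetics_metrics` object for the control condition.
#' @param time,od the treated trace.
#' @return list with `t_cross` (NA if never crossed), `od_half` used, and
#'   `delay` relative to the control's own `t_half`.
#' @export
delay_report <- function(control, time, od) {
  stopifnot(inherits(control, "kinetics_metrics"))
  if (!control$crossed) stop("control trace never crossed its own OD_1/2")
  t_cross <- first_crossing(as.numeric(time), as.numeric(od), control$od_half)
  list(t_cross = t_cross, od_half = control$od_half,
       delay = t_cross - control$t_half, crossed = is.finite(t_cross))
}

#' Fit a table of turbidity curves
#'
#' Convenience wrapper applying [fit_boltzmann()] per condition of a long
#' table with columns `condition`, `peg_percent`, `od` (replicates are
#' averaged per PEG percentage first).
#'
#' @param df data frame in long format.
#' @return data frame with one row per condition: Boltzmann parameters,
#'   adjusted R-squared, plateau flag and half-solubility.
#' @export
fit_solubility_table <- function(df) {
  need <- c("condition", "peg_percent", "od")
  if (!all(need %in% names(df))) {
    stop("input must have columns: ", paste(need, collapse = ", "))
  }
  conds <- unique(df$condition)
  rows <- lapply(conds, function(cc) {
    sub <- df[df$condition == cc, , drop = FALSE]
    agg <- stats::aggregate(od ~ peg_percent, data = sub, FUN = mean)
    agg <- agg[order(agg$peg_percent), ]
    f <- fit_boltzmann(agg$peg_percent, agg$od)
    data.frame(condition = cc, a1 = f$a1, a2 = f$a2, x0 = f$x0, dx = f$dx,
               adj_r2 = f$adj_r2, plateau_reached = f$plateau_reached,
               half_solubility = f$half_solubility,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
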