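#' Surface pressure from a surface-tension trace
#'
#' Pendant-drop tensiometry reports surface tension gamma(t); the
#' surface pressure is the drop relative to the first sample,
#' `Pi(t) = gamma(t0) - gamma(t)`, so `Pi(t0) = 0` and protein adsorption
#' at the interface drives Pi upward.
#'
#' @param time_s strictly increasing sample times in seconds.
#' @param gamma surface tension in mN/m.
#' @return data frame with columns `time_s` and `pi` (mN/m).
#' @export
to_surface_pressure <- function(time_s, gamma) {
  t <- as.numeric(time_s)
  g <- as.numeric(gamma)
  if (length(t) != length(g)) stop("time_s and gamma lengths differ")
  if (length(t) < 2) stop("need at least 2 samples")
  if (is.unsorted(t, strictly = TRUE)) stop("time_s must be strictly increasing")
  data.frame(time_s = t, pi = g[1] - g)
}

#' Initial surface-pressure rate over the first 100 seconds
#'
#' The adsorption rate is estimated pointwise: a central finite
#' difference at every interior sample with `t <= window_s` (one-sided
#' differences at the two ends of the window), converted to
#' mN m^-1 min^-1.  The summary is the mean of these pointwise slopes
#' with its standard error, matching a "slope at each point, then
#' average" protocol.
#'
#' @param pressure data frame from [to_surface_pressure()] (columns
#'   `time_s`, `pi`), or any data frame with those columns.
#' @param window_s initial window in seconds (default 100).
#' @return list with `rate` (mN/m/min), `se`, `n`, and the per-point
#'   `slopes`.
#' @export
initial_rate <- function(pressure, window_s = 100) {
  t <- pressure$time_s
  p <- pressure$pi
  in_win <- which(t <= window_s + 1e-9 * max(1, window_s))  # fp-safe edge
  if (length(in_win) < 3) stop("need at least 3 samples within the window")
  idx <- in_win
  n <- length(idx)
  slopes <- numeric(n)
  for (k in seq_len(n)) {
    i <- idx[k]
    if (k == 1) {
      slopes[k] <- (p[idx[2]] - p[i]) / (t[idx[2]] - t[i])
    } else if (k == n) {
      slopes[k] <- (p[i] - p[idx[n - 1]]) / (t[i] - t[idx[n - 1]])
    } else {
      slopes[k] <- (p[idx[k + 1]] - p[idx[k - 1]]) / (t[idx[k + 1]] - t[idx[k - 1]])
    }
  }
  slopes <- slopes * 60  # per second -> per minute
  list(rate = mean(slopes), se = stats::sd(slopes) / sqrt(n), n = n,
       slopes = slopes)
}

#' Final surface pressure over the trailing 240 seconds
#'
#' Averages all samples in the last `tail_s` seconds of the trace (240 s,
#' i.e. the last 10% of a standard 40-minute acquisition).
#'
#' @param pressure data frame with `time_s`, `pi`.
#' @param tail_s trailing window in seconds (default 240).
#' @param total_duration total trial duration; defaults to the last
#'   sample time.
#' @return list with `final` (mN/m), `se`, `n`, and the window `values`.
#' @export
final_pressure <- function(pressure, tail_s = 240, total_duration = NULL) {
  t <- pressure$time_s
  p <- pressure$pi
  dur <- if (is.null(total_duration)) max(t) else total_duration
  if (dur < tail_s) stop("trace shorter than the trailing window (", tail_s, " s)")
  vals <- p[t >= dur - tail_s]
  list(final = mean(vals), se = stats::sd(vals) / sqrt(length(vals)),
       n = length(vals), values = vals)
}

#' Per-condition surface-pressure statistics from a tension table
#'
#' Takes a long table (columns `condition`, `drop_id`, `time_s`,
#' `gamma`), converts each drop to surface pressure, and pools the
#' per-point initial-rate slopes and trailing-window pressures across
#' drops of the same condition (point-level pooling; per-drop summaries
#' are also returned).
#'
#' @param df long-format tension table.
#' @param window_s initial-rate window (default 100 s).
#' @param tail_s final-pressure window (default 240 s).
#' @return object of class `pressure_stats`: per-condition list with
#'   pooled `rate_points` and `final_points` plus summary mean/SE.
#' @export
pressure_stats <- function(df, window_s = 100, tail_s = 240) {
  need <- c("condition", "drop_id", "time_s", "gamma")
  if (!all(need %in% names(df))) {
    stop("input must have columns: ", paste(need, collapse = ", "))
  }
  conds <- unique(df$condition)
  out <- lapply(conds, function(cc) {
    sub <- df[df$condition == cc, , drop = FALSE]
    drops <- unique(sub$drop_id)
    rate_pts <- list()
    fin_pts <- list()
    per_drop <- data.frame(drop_id = drops, rate = NA_real_, final = NA_real_)
    for (k in seq_along(drops)) {
      dd <- sub[sub$drop_id == drops[k], , drop = FALSE]
      dd <- dd[order(dd$time_s), ]
      pres <- to_surface_pressure(dd$time_s, dd$gamma)
      ir <- initial_rate(pres, window_s = window_s)
      fp <- final_pressure(pres, tail_s = tail_s)
      rate_pts[[k]] <- ir$slopes
      fin_pts[[k]] <- fp$values
      per_drop$rate[k] <- ir$rate
      per_drop$final[k] <- fp$final
    }
    rate_pts <- unlist(rate_pts)
    fin_pts <- unlist(fin_pts)
    list(condition = cc,
         initial_rate = mean(rate_pts),
         rate_se = stats::sd(rate_pts) / sqrt(length(rate_pts)),
         n_rate_points = length(rate_pts),
         final_pressure = mean(fin_pts),
         final_se = stats::sd(fin_pts) / sqrt(length(fin_pts)),
         n_final_points = length(fin_pts),
         rate_points = rate_pts, final_points = fin_pts,
         per_drop = per_drop)
  })
  names(out) <- conds
  class(out) <- "pressure_stats"
  out
}

#' @export
print.pressure_stats <- function(x, ...) {
  cat("Surface-pressure statistics (point-level pooling)\n")
  for (s in x) {
    cat(sprintf(
      "  %-12s rate %6.2f +/- %.2f mN/m/min (n=%d)   final Pi %6.2f +/- %.2f mN/m (n=%d)\n",
      s$condition, s$initial_rate, s$rate_se, s$n_rate_points,
      s$final_pressure, s$final_se, s$n_final_points))
  }
  invisible(x)
}

#' One-way ANOVA with Bonferroni-corrected pairwise t tests
#'
#' Classic fixed-effects one-way ANOVA across labeled groups followed by
#' all-pairs two-tailed homoscedastic (pooled-variance, two-sample)
#' t tests with Bonferroni correction `p_adj = min(1, p * n_comparisons)`.
#'
#' @param values numeric measurements.
#' @param groups group label per measurement.
#' @param alpha significance threshold (default 0.05).
#' @param pairs optional 2-column character matrix restricting which
#'   pairwise comparisons are made (and hence the Bonferroni count);
#'   default all pairs.
#' @return list with `f`, `p` (overall ANOVA), `table` (data frame:
#'   group_a, group_b, t, df, p, p_adj, significant), `alpha`.
#' @export
anova_posthoc <- function(values, groups, alpha = 0.05, pairs = NULL) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  sizes <- table(g)
  if (any(sizes < 2)) stop("every group needs at least 2 points")
  fit <- stats::lm(values ~ g)
  an <- stats::anova(fit)
  f <- an[["F value"]][1]
  p <- an[["Pr(>F)"]][1]
  if (!is.finite(f)) {
    warning("within-group variance is zero in all groups; F undefined")
  }
  levs <- levels(g)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(levs, 2))
  } else {
    pairs <- matrix(as.character(pairs), ncol = 2)
  }
  ncomp <- nrow(pairs)
  rows <- lapply(seq_len(ncomp), function(i) {
    a <- values[g == pairs[i, 1]]
    b <- values[g == pairs[i, 2]]
    tt <- stats::t.test(a, b, var.equal = TRUE)
    data.frame(group_a = pairs[i, 1], group_b = pairs[i, 2],
               mean_a = mean(a), mean_b = mean(b),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- pmin(1, tab$p * ncomp)
  tab$significant <- tab$p_adj < alpha
  list(f = f, p = p, table = tab, alpha = alpha, n_comparisons = ncomp)
}

#' Classify a crystallin mixture's interaction against a control
#'
#' Encodes the asymmetric call used for the interaction network:
#' a mixture is *repulsive* toward the control subtype if EITHER its
#' final surface pressure OR its initial rate is significantly greater
#' than the control's; it is *attractive* only if BOTH are significantly
#' lower; otherwise no interaction is called.
#'
#' @param mix_stats,ctrl_stats single-condition entries of a
#'   [pressure_stats()] object.
#' @param rate_p,final_p Bonferroni-corrected p-values for the
#'   mixture-vs-control rate and final-pressure comparisons.
#' @param alpha significance threshold (default 0.05).
#' @return list of class `interaction_call` with `mixture`, `control`,
#'   per-metric significance/direction, and `label` in
#'   `c("repulsive", "attractive", "none")`.
#' @export
classify_interaction <- function(mix_stats, ctrl_stats, rate_p, final_p,
                                 alpha = 0.05) {
  rate_sig <- is.finite(rate_p) && rate_p < alpha
  final_sig <- is.finite(final_p) && final_p < alpha
  rate_dir <- sign(mix_stats$initial_rate - ctrl_stats$initial_rate)
  final_dir <- sign(mix_stats$final_pressure - ctrl_stats$final_pressure)
  rate_higher <- rate_sig && rate_dir > 0
  rate_lower <- rate_sig && rate_dir < 0
  final_higher <- final_sig && final_dir > 0
  final_lower <- final_sig && final_dir < 0
  label <- if (final_higher || rate_higher) {
    "repulsive"
  } else if (final_lower && rate_lower) {
    "attractive"
  } else {
    "none"
  }
  out <- list(mixture = mix_stats$condition, control = ctrl_stats$condition,
              rate_significant = rate_sig, rate_direction = rate_dir,
              final_significant = final_sig, final_direction = final_dir,
              label = label)
  class(out) <- "interaction_call"
  out
}

#' Build the pairwise interaction network from tension data
#'
#' Runs [pressure_stats()], tests each mixture against its component
#' controls (control-wise comparisons, Bonferroni-corrected within each
#' metric across all comparisons made), classifies each comparison with
#' [classify_interaction()], and aggregates per component pair: an edge
#' is `repulsive` if any control comparison is repulsive, otherwise
#' `attractive` if any is attractive, otherwise `none`.
#'
#' Mixture conditions must be named `"a:b"` where `a` and `b` are control
#' condition names present in the table.
#'
#' @param df long-format tension table (`condition`, `drop_id`, `time_s`,
#'   `gamma`).
#' @param alpha significance threshold.
#' @return list with `stats`, `calls` (one per mixture/control
#'   comparison), and `edges` (data frame: mixture, comp_a, comp_b,
#'   label).
#' @export
interaction_network <- function(df, alpha = 0.05) {
  st <- pressure_stats(df)
  conds <- names(st)
  mixes <- conds[grepl(":", conds, fixed = TRUE)]
  comparisons <- list()
  for (mx in mixes) {
    comps <- strsplit(mx, ":", fixed = TRUE)[[1]]
    for (cc in comps) {
      if (cc %in% conds) comparisons[[length(comparisons) + 1]] <- c(mx, cc)
    }
  }
  if (!length(comparisons)) stop("no mixture-vs-control comparisons found")
  ncomp <- length(comparisons)
  calls <- list()
  for (cmp in comparisons) {
    mx <- st[[cmp[1]]]
    ct <- st[[cmp[2]]]
    rate_p <- min(1, stats::t.test(mx$rate_points, ct$rate_points,
                                   var.equal = TRUE)$p.value * ncomp)
    final_p <- min(1, stats::t.test(mx$final_points, ct$final_points,
                                    var.equal = TRUE)$p.value * ncomp)
    calls[[paste(cmp, collapse = " vs ")]] <-
      classify_interaction(mx, ct, rate_p, final_p, alpha = alpha)
  }
  edges <- lapply(mixes, function(mx) {
    comps <- strsplit(mx, ":", fixed = TRUE)[[1]]
    labs <- vapply(calls[startsWith(names(calls), paste0(mx, " vs "))],
                   function(x) x$label, character(1))
    lab <- if (any(labs == "repulsive")) "repulsive"
           else if (any(labs == "attractive")) "attractive" else "none"
    data.frame(mixture = mx, comp_a = comps[1], comp_b = comps[2],
               label = lab, stringsAsFactors = FALSE)
  })
  list(stats = st, calls = calls, edges = do.call(rbind, edges))
}
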