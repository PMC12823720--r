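# Novice/Expert segmentation of the surgeon's timeline. The temporal
# transformation of the OPI map between consecutive monthly bins is
# summarised by two dispersion traces of the weighted per-OPI displacement
# vectors (the same movement that drives the learning-curve distances):
# the leading eigenvalue of their 2x2 second-moment matrix, and the area
# of their convex hull anchored at the zero-movement origin. Each trace is
# fitted with an exponential decay f(x) = a * exp(-b x) + c; bins with
# fitted value above the expected value E[f] are Novice, the rest Expert,
# and the transition is the first Expert bin.

new_phase_trace <- function(kind, t, value, year_month, last_day) {
  structure(list(kind = kind, t = t, value = value,
                 year_month = year_month, last_day = as.Date(last_day),
                 fitted = NULL, params = NULL, expected_value = NULL,
                 labels = NULL, transition_t = NULL),
            class = "phase_trace")
}

#' Per-OPI displacement sets between consecutive embedded bins
#'
#' For each pair of consecutive bins, the per-OPI displacement vectors
#' `sqrt(w / c) * (p_{t+1} - p_t)` — the 2-D movements whose norms are the
#' weighted Euclidean distances of the learning curve. Each set is
#' indexed by the later bin.
#'
#' @param embedded Output of [embed_bins()].
#' @return List of sets, each with `t` (later bin index), `year_month`,
#'   `last_day`, and `points` (an `n_opi x 2` matrix).
#' @export
displacement_sets <- function(embedded) {
  B <- length(embedded)
  stopifnot(B >= 2)
  lapply(seq_len(B - 1), function(t) {
    w <- as.numeric(embedded[[t + 1]]$last_day - embedded[[t]]$last_day)
    cc <- embedded[[t + 1]]$c_t
    a <- embedded[[t]]$points
    b <- embedded[[t + 1]]$points[rownames(a), , drop = FALSE]
    list(t = embedded[[t + 1]]$t,
         year_month = embedded[[t + 1]]$year_month,
         last_day = embedded[[t + 1]]$last_day,
         points = sqrt(w / cc) * (b - a))
  })
}

#' Convex-hull area of a 2-D point set
#'
#' Shoelace area over the hull vertices found by [grDevices::chull()];
#' fewer than three points, or collinear points, give area 0.
#'
#' @param points Two-column numeric matrix.
#' @return Non-negative scalar.
#' @export
hull_area <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) return(0)
  h <- chull(points[, 1], points[, 2])
  shoelace_area(points[h, , drop = FALSE])
}

# Shoelace area of a polygon given vertices in order.
shoelace_area <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(0)
  i2 <- c(2:n, 1)
  abs(sum(xy[, 1] * xy[i2, 2] - xy[i2, 1] * xy[, 2])) / 2
}

#' Eigenvalue dispersion trace over point sets
#'
#' Per set, the leading eigenvalue of the 2x2 second-moment matrix of the
#' points. With `center = FALSE` (the default, intended for displacement
#' sets) the moment is taken about the origin — the zero-movement
#' reference — so that coherent movement of all OPIs registers as
#' dispersion; with `center = TRUE` it is the ordinary covariance of the
#' cloud. Sets with fewer than 2 points get value 0 with a warning.
#'
#' @param sets List of point sets ([displacement_sets()] output, or any
#'   list of elements with `t`, `year_month`, `last_day`, `points`).
#' @param center Use the centred covariance instead of the second moment
#'   about the origin.
#' @return An unfitted `phase_trace` of kind `"eigen"`.
#' @export
eigen_trace <- function(sets, center = FALSE) {
  value <- vapply(sets, function(b) {
    pts <- as.matrix(b$points)
    if (nrow(pts) < 2) {
      warning(sprintf("set %d has < 2 points; eigenvalue set to 0", b$t),
              call. = FALSE)
      return(0)
    }
    M <- if (center) stats::cov(pts) else crossprod(pts) / nrow(pts)
    max(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  }, numeric(1))
  new_phase_trace("eigen",
                  as.integer(vapply(sets, function(b) b$t, numeric(1))),
                  value,
                  vapply(sets, function(b) b$year_month, ""),
                  as.Date(vapply(sets, function(b)
                    as.character(b$last_day), "")))
}

#' Convex-hull-area dispersion trace over point sets
#'
#' Per set, the convex-hull area of the points; with `anchor = TRUE` (the
#' default, intended for displacement sets) the zero-movement origin is
#' included in the hull so that coherent movement away from zero
#' registers. Sets with fewer than 3 points (after anchoring) get area 0
#' with a warning; collinear sets give area 0.
#'
#' @param sets As in [eigen_trace()].
#' @param anchor Include the origin in each hull.
#' @return An unfitted `phase_trace` of kind `"hull"`.
#' @export
hull_trace <- function(sets, anchor = TRUE) {
  value <- vapply(sets, function(b) {
    pts <- as.matrix(b$points)
    if (anchor) pts <- rbind(pts, c(0, 0))
    if (nrow(pts) < 3) {
      warning(sprintf("set %d has < 3 points; hull area set to 0", b$t),
              call. = FALSE)
      return(0)
    }
    hull_area(pts)
  }, numeric(1))
  new_phase_trace("hull",
                  as.integer(vapply(sets, function(b) b$t, numeric(1))),
                  value,
                  vapply(sets, function(b) b$year_month, ""),
                  as.Date(vapply(sets, function(b)
                    as.character(b$last_day), "")))
}

#' Fit an exponential decay to a dispersion trace
#'
#' Nonlinear least squares for `f(x) = a * exp(-b * x) + c` with bounds
#' `a >= 0`, `b >= 0`. Several deterministic starts are tried
#' (`a0 = max - min`, `c0 = min`, `b0` spanning fast to slow decays) and
#' the converged fit with the lowest residual sum of squares is kept; if
#' none converges a log-linear fit of `log(value - min + eps)` against
#' `x` is used instead (noted by a message). The expected value `E[f]` is
#' the discrete mean of the fitted values over the observed bins; bins
#' with `f(t) > E[f]` are labelled Novice, the rest Expert, and the
#' transition is the first Expert bin.
#'
#' @param trace An unfitted `phase_trace` with at least 4 points.
#' @return The fitted `phase_trace` (fields `params`, `fitted`,
#'   `expected_value`, `labels`, `transition_t`).
#' @export
fit_decay <- function(trace) {
  stopifnot(inherits(trace, "phase_trace"))
  x <- as.numeric(trace$t)
  v <- trace$value
  if (length(v) < 4) stop("need at least 4 trace points", call. = FALSE)
  if (any(!is.finite(v))) stop("non-finite trace values", call. = FALSE)
  a0 <- max(v) - min(v)
  c0 <- min(v)
  best <- NULL
  for (b0 in c(2, 0.5, 0.125, 8) / diff(range(x))) {
    fit <- tryCatch({
      m <- minpack.lm::nlsLM(
        v ~ a * exp(-b * x) + c,
        start = list(a = a0, b = b0, c = c0),
        lower = c(a = 0, b = 0, c = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200))
      list(params = as.list(coef(m)), rss = sum(residuals(m)^2))
    }, error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$rss < best$rss))
      best <- fit
  }
  if (is.null(best)) {
    message("decay fit did not converge; falling back to log-linear fit")
    eps <- max(1e-8, 1e-6 * max(abs(v)))
    ll <- lm(log(v - min(v) + eps) ~ x)
    best <- list(params = list(a = exp(unname(coef(ll)[1])),
                               b = max(0, -unname(coef(ll)[2])),
                               c = min(v)))
  }
  p <- best$params
  trace$params <- p
  trace$fitted <- p$a * exp(-p$b * x) + p$c
  label_phases(trace)
}

# Apply the Novice/Expert inequality rule to a trace's fitted values.
# A relative tolerance keeps degenerate flat fits (a ~ 0) from labelling
# bins Novice on rounding noise.
label_phases <- function(trace) {
  stopifnot(!is.null(trace$fitted))
  ev <- mean(trace$fitted)
  eps <- 1e-9 * max(1, abs(ev))
  trace$expected_value <- ev
  trace$labels <- ifelse(trace$fitted > ev + eps, "Novice", "Expert")
  expert <- which(trace$labels == "Expert")
  trace$transition_t <- if (length(expert)) trace$t[expert[1]]
                        else NA_integer_
  trace
}

#' Segment the timeline into Novice and Expert phases
#'
#' Combines the fitted eigenvalue and convex-hull traces. Each trace
#' labels bins by the inequality rule (`f(t) > E[f]` means Novice). If the
#' two transitions agree the consensus bin is used; otherwise the later of
#' the two is taken (conservative Expert onset) and a disagreement flag is
#' set. The transition timestamp is the last case day of the transition
#' bin.
#'
#' @param trace_eigen,trace_hull Fitted `phase_trace`s over the same bin
#'   sequence.
#' @return List of class `segmentation_result`: per-trace labels and
#'   transitions, combined `transition_t`, `transition_date`, and
#'   `disagreement` flag.
#' @export
segment_phases <- function(trace_eigen, trace_hull) {
  for (tr in list(trace_eigen, trace_hull)) {
    if (is.null(tr$fitted))
      stop("traces must be fitted before segmentation", call. = FALSE)
    if (is.na(tr$transition_t))
      stop(sprintf("no convergence detected in %s trace (no Expert bins)",
                   tr$kind), call. = FALSE)
  }
  if (!identical(trace_eigen$t, trace_hull$t))
    stop("traces cover different bin sequences", call. = FALSE)
  te <- trace_eigen$transition_t
  th <- trace_hull$transition_t
  agree <- te == th
  tt <- max(te, th)
  idx <- match(tt, trace_eigen$t)
  structure(list(
    eigen = trace_eigen, hull = trace_hull,
    transition_eigen = te, transition_hull = th,
    transition_t = tt,
    transition_date = trace_eigen$last_day[idx],
    disagreement = !agree), class = "segmentation_result")
}

#' Re-run the OPI-only model competition after skill segmentation
#'
#' Cases dated before the transition bin's last day form the Novice
#' subset, the rest the Expert subset; an independent OPI-only model
#' competition is run on each.
#'
#' @param cases Filtered cohort data frame.
#' @param seg A `segmentation_result`.
#' @param grid A [model_grid()].
#' @return Named list of two `model_report`s (`novice`, `expert`).
#' @export
rerun_after_segmentation <- function(cases, seg, grid) {
  stopifnot(inherits(seg, "segmentation_result"))
  run_subset_comparison(
    cases, function(cs) subset_by_date(cs, seg$transition_date), grid,
    feature_set = "opi_only")
}

#' One-call skill segmentation from a case list
#'
#' Convenience wrapper for the full chain: monthly binning, joint t-SNE
#' embedding (one representation group), displacement sets, dispersion
#' traces (smoothed with the same Savitzky-Golay filter as the learning
#' curves), decay fits, and segmentation.
#'
#' @param cases Filtered cohort data frame (typically attending-only).
#' @param representation OPI representation used for the embedding.
#' @param perplexity,seed,n_iter,exaggeration t-SNE parameters.
#' @param smooth_window Savitzky-Golay window applied to the trace values
#'   before fitting (0 disables).
#' @return A `segmentation_result`.
#' @export
segment_cases <- function(cases, representation = "count",
                          perplexity = 30, seed = 0L, n_iter = 500,
                          exaggeration = 4, smooth_window = 5) {
  bins <- bin_by_month(cases)
  eb <- embed_bins(cases, bins, representation, perplexity = perplexity,
                   seed = seed, n_iter = n_iter,
                   exaggeration = exaggeration)
  sets <- displacement_sets(eb)
  tr_e <- eigen_trace(sets)
  tr_h <- hull_trace(sets)
  if (smooth_window >= 3) {
    tr_e$value <- pmax(0, smooth_series(tr_e$value, smooth_window, 2))
    tr_h$value <- pmax(0, smooth_series(tr_h$value, smooth_window, 2))
  }
  segment_phases(fit_decay(tr_e), fit_decay(tr_h))
}
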