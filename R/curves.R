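# OPI learning curves: monthly case bins, a joint t-SNE embedding of
# (case, OPI) rows, per-(bin, OPI) component averaging, weighted Euclidean
# distances between consecutive bins
#   d_{t,t+1} = sqrt( (w_{t+1,t} / c_{t+1}) * sum_{n in (i,j)}
#                     (p_{n|t+1} - p_{n|t})^2 ),
# with w the day gap between the bins' last case days and c the next bin's
# case volume, followed by Savitzky-Golay smoothing.

opi_representations <- c("count", "rate", "normalized_duration")

#' Bin cases by calendar month of operation
#'
#' @param cases Filtered, dated cohort data frame.
#' @return List of bins in chronological order, each a list with `t` (bin
#'   index over non-empty months), `year_month`, `last_day`, `c_t` and
#'   `case_idx` (row indices into `cases`). Empty months are omitted; the
#'   calendar gap they leave is absorbed by the day weighting downstream.
#' @export
bin_by_month <- function(cases) {
  stopifnot(is.data.frame(cases))
  if (anyNA(cases$date)) stop("undated case(s) present", call. = FALSE)
  ym <- format(as.Date(cases$date), "%Y-%m")
  uym <- sort(unique(ym))
  bins <- lapply(seq_along(uym), function(i) {
    idx <- which(ym == uym[i])
    list(t = i, year_month = uym[i],
         last_day = max(as.Date(cases$date[idx])),
         c_t = length(idx), case_idx = idx)
  })
  bins
}

# Row matrix for the joint embedding: one row per (case, OPI) carrying the
# OPI's metric value in the chosen representation, the complexity ordinal
# (0/1/2) and the bin's case volume. All columns are standardised; the two
# context columns (complexity, volume) are then down-weighted so that the
# embedding organises operator behaviour rather than calendar structure
# (with equal weights the bin-constant context features make the map
# encode the volume ramp and complexity drift directly).
embedding_rows <- function(cases, bins, representation,
                           context_weight = 0.25) {
  opi_cols <- grep(paste0("^opi_.*_", representation, "$"),
                   names(cases), value = TRUE)
  opi_names <- sub(paste0("_", representation, "$"), "",
                   sub("^opi_", "", opi_cols))
  ordinal <- as.numeric(factor(as.character(cases$complexity),
                               levels = complexity_levels)) - 1
  bin_of_case <- integer(nrow(cases))
  c_of_case <- numeric(nrow(cases))
  for (b in bins) {
    bin_of_case[b$case_idx] <- b$t
    c_of_case[b$case_idx] <- b$c_t
  }
  n_opi <- length(opi_cols)
  rows <- do.call(rbind, lapply(seq_len(n_opi), function(k) {
    cbind(value = cases[[opi_cols[k]]], complexity = ordinal,
          volume = c_of_case)
  }))
  zscale <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  rows_std <- apply(rows, 2, zscale)
  rows_std[, "complexity"] <- rows_std[, "complexity"] * context_weight
  rows_std[, "volume"] <- rows_std[, "volume"] * context_weight
  list(rows = rows_std,
       opi = rep(opi_names, each = nrow(cases)),
       bin = rep(bin_of_case, times = n_opi))
}

#' Embed monthly bins by joint t-SNE and average per (bin, OPI)
#'
#' All (case, OPI) rows across all bins are embedded jointly into 2-D so
#' that bins share one coordinate system; the components of rows belonging
#' to the same bin and OPI are then averaged into a single point.
#'
#' @param cases Filtered cohort data frame.
#' @param bins Output of [bin_by_month()].
#' @param representation One of `"count"`, `"rate"`,
#'   `"normalized_duration"`.
#' @param perplexity,seed,n_iter Passed to [tsne_embed()].
#' @param exaggeration Early-exaggeration factor; the pipeline default is
#'   milder than classic t-SNE so moderate row counts are not shattered
#'   into artificial fragments.
#' @param context_weight Weight of the standardised complexity and volume
#'   context columns relative to the metric value column.
#' @return List of embedded bins, each with `t`, `year_month`, `last_day`,
#'   `c_t` and `points` (an `n_opi x 2` matrix with OPI row names).
#' @export
embed_bins <- function(cases, bins, representation = "count",
                       perplexity = 30, seed = 0L, n_iter = 500,
                       exaggeration = 4, context_weight = 0.25) {
  representation <- match.arg(representation, opi_representations)
  er <- embedding_rows(cases, bins, representation, context_weight)
  Y <- tsne_embed(er$rows, perplexity = perplexity, seed = seed,
                  n_iter = n_iter, exaggeration = exaggeration)
  lapply(bins, function(b) {
    sel <- er$bin == b$t
    pts <- aggregate(Y[sel, , drop = FALSE], by = list(opi = er$opi[sel]),
                     FUN = mean)
    m <- as.matrix(pts[, -1, drop = FALSE])
    rownames(m) <- pts$opi
    colnames(m) <- c("i", "j")
    list(t = b$t, year_month = b$year_month, last_day = b$last_day,
         c_t = b$c_t, points = m[order(rownames(m)), , drop = FALSE])
  })
}

#' Weighted Euclidean distance between consecutive embedded bins
#'
#' Per OPI, the 2-D Euclidean distance between the bin's averaged points,
#' scaled by `sqrt(w / c)` where `w` is the day gap between the bins' last
#' case days and `c` the later bin's case count.
#'
#' @param p_t,p_t1 Embedded bins (elements of [embed_bins()] output).
#' @param w Day gap (> 0).
#' @param c Case count of the later bin (>= 1).
#' @return Named numeric vector of per-OPI distances.
#' @export
weighted_distance <- function(p_t, p_t1, w, c) {
  stopifnot(w > 0, c >= 1)
  a <- p_t$points; b <- p_t1$points
  if (!identical(sort(rownames(a)), sort(rownames(b)))) {
    d1 <- setdiff(rownames(a), rownames(b))
    d2 <- setdiff(rownames(b), rownames(a))
    stop("mismatched OPI sets between bins: ",
         paste(c(d1, d2), collapse = ", "), call. = FALSE)
  }
  b <- b[rownames(a), , drop = FALSE]
  sq <- rowSums((b - a)^2)
  sqrt((w / c) * sq)
}

#' Savitzky-Golay smoothing of a distance series
#'
#' Local least-squares polynomial smoothing with an odd moving window;
#' series shorter than the window are returned unsmoothed with a warning.
#'
#' @param d Numeric series.
#' @param window Odd window length (default 5).
#' @param polyorder Polynomial order (< window; default 2).
#' @return Smoothed series of the same length.
#' @export
smooth_series <- function(d, window = 5, polyorder = 2) {
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  if (polyorder >= window)
    stop("polyorder must be below window", call. = FALSE)
  if (length(d) < window) {
    warning(sprintf("series of length %d shorter than window %d; %s",
                    length(d), window, "returned unsmoothed"),
            call. = FALSE)
    return(d)
  }
  as.numeric(signal::sgolayfilt(d, p = polyorder, n = window))
}

#' Build the OPI learning curves
#'
#' Full chain per OPI representation group (count / rate / normalized
#' duration): monthly binning, joint t-SNE embedding, per-(bin, OPI)
#' averaging, weighted Euclidean distances between consecutive bins, and
#' Savitzky-Golay smoothing. Per-OPI distances are aggregated into one
#' grouped curve by mean (or median).
#'
#' @param cases Filtered cohort data frame (>= 3 non-empty months).
#' @param representations Character vector of groups to build.
#' @param perplexity,seed,n_iter,exaggeration t-SNE parameters.
#' @param window,polyorder Savitzky-Golay parameters.
#' @param aggregate `"mean"` or `"median"` across OPIs.
#' @return Object of class `learning_curves`: named list of per-group data
#'   frames `(t, year_month, w, c, raw_d, smoothed_d)` plus smoothing
#'   metadata.
#' @export
build_curves <- function(cases, representations = opi_representations,
                         perplexity = 30, seed = 0L, n_iter = 500,
                         exaggeration = 4, window = 5, polyorder = 2,
                         aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  bins <- bin_by_month(cases)
  if (length(bins) < 3)
    stop("need at least 3 non-empty monthly bins, got ", length(bins),
         call. = FALSE)
  agg_fun <- if (aggregate == "mean") mean else median
  curves <- lapply(representations, function(rep_g) {
    eb <- embed_bins(cases, bins, rep_g, perplexity = perplexity,
                     seed = seed, n_iter = n_iter,
                     exaggeration = exaggeration)
    B <- length(eb)
    raw <- numeric(B - 1)
    w_v <- c_v <- numeric(B - 1)
    for (t in seq_len(B - 1)) {
      w_v[t] <- as.numeric(eb[[t + 1]]$last_day - eb[[t]]$last_day)
      c_v[t] <- eb[[t + 1]]$c_t
      raw[t] <- agg_fun(weighted_distance(eb[[t]], eb[[t + 1]],
                                          w_v[t], c_v[t]))
    }
    data.frame(t = seq_len(B - 1),
               year_month = vapply(eb[-1], `[[`, "", "year_month"),
               w = w_v, c = c_v, raw_d = raw,
               smoothed_d = smooth_series(raw, window, polyorder),
               stringsAsFactors = FALSE)
  })
  names(curves) <- representations
  structure(list(groups = curves,
                 smoothing = list(window = window, polyorder = polyorder),
                 aggregate = aggregate),
            class = "learning_curves")
}

#' Early-versus-late contrast of the learning curves
#'
#' Ratio of the mean smoothed distance over the first `k` bins to that
#' over the last `k` bins, per representation group and pooled (each
#' group's series is scaled by its own mean before pooling so that no
#' group dominates).
#'
#' @param curves A `learning_curves` object.
#' @param k Number of bins on each end.
#' @return List with `per_group` (named ratios) and `pooled`.
#' @export
early_late_contrast <- function(curves, k = 10) {
  stopifnot(inherits(curves, "learning_curves"))
  per_group <- vapply(curves$groups, early_late_ratio, numeric(1), k = k)
  pooled <- NULL
  for (g in curves$groups) {
    s <- g$smoothed_d / mean(g$smoothed_d)
    pooled <- if (is.null(pooled)) s else pooled + s
  }
  n <- length(pooled)
  kk <- min(k, floor(n / 2))
  list(per_group = per_group,
       pooled = mean(pooled[seq_len(kk)]) /
         mean(pooled[seq(n - kk + 1, n)]))
}

#' Permutation test for a temporal trend in embedded movement
#'
#' Tests whether early bins moved systematically more than late bins.
#' The deterministic `sqrt(w / c)` weight of the distance formula trends
#' with the cohort's volume ramp by construction, so the test is run on
#' the movement with that known weight divided out; under a cohort with
#' no skill dynamic the statistic has no trend.
#'
#' @param curve_df One group's curve data frame (from a
#'   `learning_curves` object or [curves_to_df()]).
#' @param k Bins on each end entering the difference of means.
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @return List with `statistic` (early minus late mean movement) and
#'   `p_value` (two-sided).
#' @export
movement_trend_test <- function(curve_df, k = 10, n_perm = 500,
                                seed = 0L) {
  mv <- curve_df$raw_d / sqrt(curve_df$w / curve_df$c)
  n <- length(mv)
  k <- min(k, floor(n / 2))
  obs <- mean(mv[seq_len(k)]) - mean(mv[seq(n - k + 1, n)])
  set.seed(seed)
  null <- replicate(n_perm, {
    s <- sample(mv)
    mean(s[seq_len(k)]) - mean(s[seq(n - k + 1, n)])
  })
  list(statistic = obs, p_value = mean(abs(null) >= abs(obs)))
}

#' Export learning curves as a tidy data frame
#'
#' @param curves A `learning_curves` object.
#' @return Data frame `(group, t, year_month, w, c, raw_d, smoothed_d)`.
#' @export
curves_to_df <- function(curves) {
  stopifnot(inherits(curves, "learning_curves"))
  do.call(rbind, lapply(names(curves$groups), function(g) {
    cbind(data.frame(group = g, stringsAsFactors = FALSE),
          curves$groups[[g]])
  }))
}
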