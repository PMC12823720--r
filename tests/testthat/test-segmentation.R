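mk_set <- function(t, pts, last_day = as.Date("2013-02-28") + 30 * t) {
  list(t = t, year_month = format(last_day, "%Y-%m"), last_day = last_day,
       points = pts)
}

mk_trace <- function(values, kind = "eigen") {
  sets <- lapply(seq_along(values), function(i)
    mk_set(i, rbind(c(0, 0), c(1, 0), c(0, 1))))
  tr <- eigen_trace(sets)
  tr$kind <- kind
  tr$value <- values
  tr
}

# Brute-force hull: a directed edge (i, j) is on the hull iff every other
# point lies on its left; vertices ordered by angle, then shoelace.
oracle_hull_area <- function(pts) {
  n <- nrow(pts)
  if (n < 3) return(0)
  on_hull <- rep(FALSE, n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    cr <- (pts[j, 1] - pts[i, 1]) * (pts[, 2] - pts[i, 2]) -
      (pts[j, 2] - pts[i, 2]) * (pts[, 1] - pts[i, 1])
    if (all(cr >= -1e-12)) { on_hull[i] <- TRUE; on_hull[j] <- TRUE }
  }
  hp <- pts[on_hull, , drop = FALSE]
  if (nrow(hp) < 3) return(0)
  ctr <- colMeans(hp)
  hp <- hp[order(atan2(hp[, 2] - ctr[2], hp[, 1] - ctr[1])), ]
  i2 <- c(2:nrow(hp), 1)
  abs(sum(hp[, 1] * hp[i2, 2] - hp[i2, 1] * hp[, 2])) / 2
}

test_that("hull areas match closed forms and the brute-force oracle", {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(hull_area(square), 1.0)
  collinear <- cbind(seq(0, 1, length.out = 5), seq(0, 2, length.out = 5))
  expect_equal(hull_area(collinear), 0.0)
  expect_equal(hull_area(square[1:2, ]), 0.0)
  set.seed(61)
  for (i in 1:50) {
    pts <- matrix(rnorm(2 * sample(3:12, 1)), ncol = 2)
    expect_equal(hull_area(pts), oracle_hull_area(pts),
                 tolerance = 1e-10)
  }
})

test_that("eigen trace matches quadratic-formula roots of the 2x2 moment", {
  # all points identical at the origin -> zero dispersion
  same <- mk_set(1, rbind(c(0, 0), c(0, 0), c(0, 0)))
  expect_warning(tr0 <- eigen_trace(list(mk_set(1, rbind(c(1, 2))))),
                 "< 2 points")
  expect_equal(tr0$value, 0)
  expect_equal(eigen_trace(list(same))$value, 0)
  # centred segment along one axis: leading eigenvalue = variance v
  seg <- mk_set(1, cbind(c(-2, -1, 0, 1, 2), rep(0, 5)))
  expect_equal(eigen_trace(list(seg), center = TRUE)$value,
               var(c(-2, -1, 0, 1, 2)))
  # and the second-moment convention matches Sum(x^2)/n about the origin
  expect_equal(eigen_trace(list(seg))$value, mean(c(4, 1, 0, 1, 4)))
  # random clouds vs the characteristic-polynomial roots
  set.seed(62)
  for (i in 1:50) {
    pts <- matrix(rnorm(2 * sample(3:15, 1), sd = runif(1, 0.5, 4)),
                  ncol = 2)
    for (center in c(TRUE, FALSE)) {
      M <- if (center) cov(pts) else crossprod(pts) / nrow(pts)
      tr <- (M[1, 1] + M[2, 2]) / 2
      det_ <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
      lam <- tr + sqrt(max(0, tr^2 - det_))
      got <- eigen_trace(list(mk_set(1, pts)), center = center)$value
      expect_equal(got, lam, tolerance = 1e-10)
    }
  }
})

test_that("displacement sets reproduce the weighted distance geometry", {
  p0 <- mk_set(1, rbind(opi_a = c(0, 0), opi_b = c(1, 1)))
  p0$c_t <- 2
  p1 <- mk_set(2, rbind(opi_a = c(3, 4), opi_b = c(1, 1)))
  p1$c_t <- 4
  p1$last_day <- p0$last_day + 36
  ds <- displacement_sets(list(p0, p1))
  expect_length(ds, 1L)
  expect_equal(sqrt(rowSums(ds[[1]]$points^2)),
               weighted_distance(p0, p1, w = 36, c = 4))
})

test_that("exact decay data recover their parameters", {
  x <- 1:40
  v <- 5 * exp(-0.3 * x) + 1
  tr <- mk_trace(v)
  fit <- fit_decay(tr)
  expect_equal(fit$params$a, 5, tolerance = 1e-6)
  expect_equal(fit$params$b, 0.3, tolerance = 1e-6)
  expect_equal(fit$params$c, 1, tolerance = 1e-6)
  expect_gte(fit$params$b, 0)
})

test_that("a constant series degenerates to an all-Expert flat fit", {
  tr <- mk_trace(rep(4, 12))
  fit <- fit_decay(tr)
  expect_equal(fit$expected_value, 4, tolerance = 1e-6)
  expect_equal(unname(fit$fitted), rep(4, 12), tolerance = 1e-6)
  expect_true(all(fit$labels == "Expert"))
  expect_identical(fit$transition_t, 1L)
})

test_that("noisy decay recovers the rate within 25% in most runs", {
  ok <- 0L
  x <- 1:96
  for (sd in 1:20) {
    set.seed(sd)
    v <- 5 * exp(-0.08 * x) + 1 + rnorm(96, 0, 0.5)
    fit <- fit_decay(mk_trace(pmax(v, 0)))
    if (abs(fit$params$b - 0.08) / 0.08 < 0.25) ok <- ok + 1L
  }
  expect_gte(ok, 16L)
})

test_that("the labelling rule follows the inequality exactly", {
  tr <- mk_trace(c(10, 6, 3, 2, 1))
  tr$fitted <- c(10, 6, 3, 2, 1)
  tr <- opilearn:::label_phases(tr)
  expect_equal(tr$expected_value, 4.4)
  expect_identical(tr$labels, c("Novice", "Novice", "Expert", "Expert",
                                "Expert"))
  expect_identical(tr$transition_t, 3L)
  # no bin labelled Expert may sit above E[f]
  expect_true(all(tr$fitted[tr$labels == "Expert"] <= tr$expected_value))
})

test_that("a strictly decreasing fit yields a single Novice/Expert crossing", {
  set.seed(63)
  for (i in 1:10) {
    v <- sort(runif(30, 0, 10), decreasing = TRUE) +
      seq(5, 0, length.out = 30)
    fit <- fit_decay(mk_trace(v))
    lab <- fit$labels
    if (fit$params$b > 0) {
      runs <- rle(lab)$values
      expect_lte(length(runs), 2L)
      if (length(runs) == 2L)
        expect_identical(runs, c("Novice", "Expert"))
    }
  }
})

test_that("segmentation combines traces with the conservative rule", {
  t1 <- fit_decay(mk_trace(10 * exp(-0.4 * (1:20)) + 1))
  t2 <- fit_decay(mk_trace(12 * exp(-0.38 * (1:20)) + 1.2, kind = "hull"))
  seg <- segment_phases(t1, t2)
  expect_identical(seg$transition_t,
                   max(seg$transition_eigen, seg$transition_hull))
  expect_identical(seg$disagreement,
                   seg$transition_eigen != seg$transition_hull)
  expect_s3_class(seg, "segmentation_result")
  expect_identical(seg$transition_date,
                   t1$last_day[match(seg$transition_t, t1$t)])
  # increasing trace: never crosses below its mean from above -> no Experts
  up <- mk_trace(seq(1, 30))
  up$fitted <- seq(30, 1) * 0 + 31  # constant above mean impossible; force
  up$fitted <- seq_len(30) + 100
  up$expected_value <- 50
  up$labels <- rep("Novice", 30)
  up$transition_t <- NA_integer_
  expect_error(segment_phases(up, t2), "no convergence")
})

test_that("post-segmentation competitions run on both phases", {
  cs <- tiny_cases(seed = 67)
  g <- model_grid(families = "decision_tree", seed = 1)
  mid <- sort(cs$date)[floor(nrow(cs) / 2)]
  seg <- structure(list(transition_date = mid),
                   class = "segmentation_result")
  out <- rerun_after_segmentation(cs, seg, g)
  expect_setequal(names(out), c("novice", "expert"))
  expect_identical(out$novice$feature_set, "opi_only")
  # identical case lists fed as both segments give identical reports
  both <- run_subset_comparison(cs, subset_all_pass, g, "opi_only")
  expect_identical(both[[1]]$per_family, both[[2]]$per_family)
})
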