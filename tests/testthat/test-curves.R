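# Minimal hand-built embedded bins for distance tests.
mk_bin <- function(t, pts, last_day, c_t = 1, ym = "2013-02") {
  rownames(pts) <- paste0("opi_", seq_len(nrow(pts)))
  list(t = t, year_month = ym, last_day = as.Date(last_day), c_t = c_t,
       points = pts)
}

test_that("monthly binning is chronological, conservative and gap-aware", {
  cs <- tiny_cases(seed = 51)
  bins <- bin_by_month(cs)
  expect_identical(sum(vapply(bins, `[[`, 0L, "c_t")), nrow(cs))
  yms <- vapply(bins, `[[`, "", "year_month")
  expect_identical(yms, sort(unique(format(cs$date, "%Y-%m"))))
  expect_true(all(diff(vapply(bins, `[[`, 0L, "t")) == 1))
  for (b in bins[1:3]) {
    expect_identical(format(b$last_day, "%Y-%m"), b$year_month)
    expect_identical(b$last_day, max(cs$date[b$case_idx]))
  }
  # three cases in one month collapse into a single bin
  one <- cs[1:3, ]
  one$date <- as.Date(c("2013-02-05", "2013-02-14", "2013-02-28"))
  b1 <- bin_by_month(one)
  expect_length(b1, 1L)
  expect_identical(b1[[1]]$c_t, 3L)
  expect_identical(b1[[1]]$last_day, as.Date("2013-02-28"))
  # Jan and Mar only: two bins, the gap is carried by the day weighting
  two <- cs[1:2, ]
  two$date <- as.Date(c("2013-01-10", "2013-03-20"))
  b2 <- bin_by_month(two)
  expect_length(b2, 2L)
  expect_identical(as.numeric(b2[[2]]$last_day - b2[[1]]$last_day), 69)
  und <- cs; und$date[2] <- NA
  expect_error(bin_by_month(und), "undated")
})

test_that("weighted distance matches closed forms", {
  p0 <- mk_bin(1, rbind(c(0, 0)), "2013-02-28")
  p1 <- mk_bin(2, rbind(c(3, 4)), "2013-03-31")
  expect_equal(unname(weighted_distance(p0, p1, w = 1, c = 1)), 5.0)
  expect_equal(unname(weighted_distance(p0, p0, w = 7, c = 3)), 0.0)
  # sqrt(9/4 * 4) = 3
  p2 <- mk_bin(2, rbind(c(2, 0)), "2013-03-31")
  expect_equal(unname(weighted_distance(p0, p2, w = 9, c = 4)), 3.0)
  bad <- mk_bin(2, rbind(c(1, 1), c(2, 2)), "2013-03-31")
  rownames(bad$points) <- c("opi_1", "opi_x")
  expect_error(weighted_distance(mk_bin(1, rbind(c(0, 0), c(1, 0)),
                                        "2013-02-28"), bad, w = 1, c = 1),
               "mismatched OPI sets.*opi_x")
})

test_that("weighted distance equals an independent implementation", {
  set.seed(53)
  for (i in 1:100) {
    k <- sample(2:8, 1)
    a <- matrix(rnorm(2 * k), k, 2)
    b <- matrix(rnorm(2 * k), k, 2)
    w <- runif(1, 1, 90)
    cc <- sample(1:9, 1)
    p0 <- mk_bin(1, a, "2013-02-28", c_t = 1)
    p1 <- mk_bin(2, b, "2013-03-31", c_t = cc)
    got <- weighted_distance(p0, p1, w, cc)
    # from-scratch: d_n = sqrt(w/c * sum over components of (p' - p)^2)
    want <- vapply(seq_len(k), function(j)
      sqrt(w / cc * ((b[j, 1] - a[j, 1])^2 + (b[j, 2] - a[j, 2])^2)),
      numeric(1))
    expect_equal(unname(got), want, tolerance = 1e-12)
  }
})

test_that("distances scale as sqrt(w) and 1/sqrt(c)", {
  set.seed(54)
  a <- matrix(rnorm(10), 5, 2)
  b <- matrix(rnorm(10), 5, 2)
  p0 <- mk_bin(1, a, "2013-02-28")
  p1 <- mk_bin(2, b, "2013-03-31")
  d <- weighted_distance(p0, p1, w = 10, c = 2)
  expect_equal(weighted_distance(p0, p1, w = 40, c = 2), 2 * d,
               tolerance = 1e-12)
  expect_equal(weighted_distance(p0, p1, w = 10, c = 8), d / 2,
               tolerance = 1e-12)
  expect_error(weighted_distance(p0, p1, w = 0, c = 1))
})

test_that("Savitzky-Golay smoothing has the polynomial and variance properties", {
  expect_equal(smooth_series(rep(3, 20)), rep(3, 20), tolerance = 1e-10)
  x <- 1:40
  quad <- 2 + 0.5 * x - 0.03 * x^2
  sm <- smooth_series(quad, window = 5, polyorder = 2)
  expect_lt(max(abs(sm[3:38] - quad[3:38])), 1e-10)
  set.seed(55)
  noise <- rnorm(200)
  expect_lt(var(smooth_series(noise)), var(noise))
  expect_warning(out <- smooth_series(c(1, 2, 3)), "unsmoothed")
  expect_identical(out, c(1, 2, 3))
  expect_error(smooth_series(1:10, window = 4), "odd")
  expect_error(smooth_series(1:10, window = 5, polyorder = 5), "below")
})

test_that("curves run the full chain and keep their invariants", {
  cs <- tiny_cases(seed = 57)
  cv <- build_curves(cs, n_iter = 250, seed = 0)
  bins <- bin_by_month(cs)
  for (g in names(cv$groups)) {
    d <- cv$groups[[g]]
    expect_identical(nrow(d), length(bins) - 1L)
    expect_true(all(d$raw_d >= 0))
    expect_identical(length(d$smoothed_d), length(d$raw_d))
    expect_true(all(d$w > 0))
  }
  expect_setequal(names(cv$groups),
                  c("count", "rate", "normalized_duration"))
  # determinism of the whole chain
  cv2 <- build_curves(cs, n_iter = 250, seed = 0)
  expect_equal(curves_to_df(cv), curves_to_df(cv2))
  expect_error(build_curves(cs[cs$month_index == 1, ]), "at least 3")
})

test_that("a single OPI over two bins reduces to one weighted distance", {
  cs <- tiny_cases(seed = 57)
  keep <- grep("^opi_", names(cs), value = TRUE)
  drop <- keep[!grepl("head_in_console", keep)]
  cs1 <- cs[, setdiff(names(cs), drop)]
  bins <- bin_by_month(cs1)[1:2]
  sel <- c(bins[[1]]$case_idx, bins[[2]]$case_idx)
  cs2 <- cs1[sel, ]
  bins2 <- bin_by_month(cs2)
  # few rows: the perplexity clamp is expected here
  eb <- suppressWarnings(embed_bins(cs2, bins2, "count", perplexity = 3,
                                    seed = 1, n_iter = 200))
  w <- as.numeric(eb[[2]]$last_day - eb[[1]]$last_day)
  d <- weighted_distance(eb[[1]], eb[[2]], w, eb[[2]]$c_t)
  expect_length(d, 1L)
  expect_gte(d, 0)
})

test_that("averaging collapses duplicate rows onto their shared point", {
  cs <- tiny_cases(seed = 57)[1:20, ]
  cs$date <- rep(as.Date(c("2013-02-10", "2013-03-10")), each = 10)
  bins <- bin_by_month(cs)
  eb <- embed_bins(cs, bins, "count", perplexity = 8, seed = 0,
                   n_iter = 200)
  for (b in eb) {
    expect_identical(nrow(b$points),
                     length(grep("^opi_.*_count$", names(cs))))
    expect_true(all(is.finite(b$points)))
  }
})
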