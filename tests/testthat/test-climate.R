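test_that("daily-weather PCA has the standard spectral properties", {
  wx <- sim_station_weather(12, n_days = 365, seed = 1, noise_sd = 1)
  pc <- pca_daily(wx$weather)
  expect_equal(sum(pc$var_explained), 1, tolerance = 1e-10)
  # reconstruction from all axes reproduces the scaled monthly matrix
  monthly <- wx$weather |>
    dplyr::mutate(month = format(date, "%m")) |>
    dplyr::group_by(station, month) |>
    dplyr::summarise(tmin = mean(tmin), tmax = mean(tmax),
                     prcp = mean(prcp), .groups = "drop") |>
    tidyr::pivot_wider(names_from = month,
                       values_from = c(tmin, tmax, prcp))
  Xs <- scale(as.matrix(monthly[match(pc$scores$station, monthly$station),
                                -1]))
  recon <- as.matrix(pc$scores[, -1]) %*% t(pc$loadings)
  expect_lt(max(abs(recon - Xs)), 1e-8)

  # stations differing only along one gradient: PC1 explains ~ everything
  wx0 <- sim_station_weather(8, n_days = 365, seed = 2, noise_sd = 0,
                             phenology_sd = 0)
  pc0 <- pca_daily(wx0$weather)
  expect_gt(pc0$var_explained[1], 0.99)
})

test_that("best-subsets phenology model finds the generating axes", {
  set.seed(3)
  wx <- sim_station_weather(15, n_days = 365, seed = 4, noise_sd = 1.5)
  pc <- pca_daily(wx$weather)
  X <- as.matrix(pc$scores[, -1])
  # noiseless function of PC2: that subset wins with r2 = 1
  y <- 5 + 2 * X[, "PC2"]
  m <- suppressWarnings(
    fit_phenology_model(y, pc$scores[, c("PC1", "PC2", "PC3", "PC4")])
  )
  expect_equal(m$subset, "PC2")
  expect_equal(m$r2, 1, tolerance = 1e-9)
  # the chosen model's BIC beats every enumerated competitor
  y2 <- 3 + X[, "PC1"] + 0.5 * X[, "PC3"] + rnorm(15, 0, 0.3)
  cand <- pc$scores[, c("PC1", "PC2", "PC3", "PC4")]
  m2 <- fit_phenology_model(y2, cand)
  all_bics <- c()
  for (size in 1:4) {
    for (ss in utils::combn(colnames(cand), size, simplify = FALSE)) {
      fit <- lm(y2 ~ ., data = data.frame(y2 = y2,
                                          as.matrix(cand)[, ss, drop = FALSE]))
      all_bics <- c(all_bics, BIC(fit))
    }
  }
  expect_lte(m2$bic, min(all_bics) + 1e-9)
  expect_true(all(c("PC1", "PC3") %in% m2$subset))
})

test_that("growing-season prediction interpolates the training sites", {
  wx <- sim_station_weather(12, n_days = 365, seed = 5, noise_sd = 0,
                            phenology_sd = 0)
  pc <- pca_daily(wx$weather)
  train <- dplyr::inner_join(wx$phenology, pc$scores, by = "station")
  gm <- suppressWarnings(fit_phenology_model(train$greenup_doy,
                                             dplyr::select(train, PC1:PC4)))
  fm <- suppressWarnings(fit_phenology_model(train$flowering_doy,
                                             dplyr::select(train, PC1:PC4)))
  seas <- predict_growing_season(gm, fm, pc$scores)
  # noiseless: predictions reproduce the observed dates
  expect_equal(seas$greenup_doy, train$greenup_doy, tolerance = 0.1)
  # the padded window contains the observed phenological interval
  expect_true(all(seas$season_start < seas$greenup_doy))
  expect_true(all(seas$season_end > seas$flowering_doy))
  # higher-latitude stations green up later
  lat <- wx$stations$latitude[match(seas$station, wx$stations$station)]
  expect_gt(cor(lat, seas$season_start, method = "spearman"), 0.99)
})

test_that("interval statistics match the brute-force oracle", {
  # constant series
  dates <- seq(as.Date("2016-03-01"), by = "day", length.out = 200)
  wconst <- tibble::tibble(date = dates, tmin = 10, tmax = 30, prcp = 0)
  s <- interval_stats(wconst, as.Date("2016-04-01"), as.Date("2016-06-30"))
  expect_equal(unname(s[c("tmax_q95_i1", "tmax_q95_i2", "tmax_q95_i3")]),
               rep(30, 3))
  expect_equal(unname(s[c("hottest14_i1", "hottest14_i2", "hottest14_i3")]),
               rep(30, 3))
  expect_equal(unname(s[grep("prcp|driest|wettest", names(s))]), rep(0, 9))

  # a hot fortnight inside the middle third only
  whot <- wconst
  mid <- dates >= as.Date("2016-05-10") & dates <= as.Date("2016-05-23")
  whot$tmax[mid] <- 40
  s2 <- interval_stats(whot, as.Date("2016-04-01"), as.Date("2016-06-30"))
  expect_equal(unname(s2["hottest14_i2"]), 40)
  expect_equal(unname(s2["hottest14_i1"]), 30)

  # random series equal the loop oracle exactly
  set.seed(6)
  wrand <- tibble::tibble(
    date = dates,
    tmin = rnorm(200, 5, 3), tmax = rnorm(200, 20, 3) + 10,
    prcp = rexp(200, 1 / 2)
  )
  got <- interval_stats(wrand, as.Date("2016-04-01"), as.Date("2016-07-15"))
  want <- interval_stats_oracle(wrand, as.Date("2016-04-01"),
                                as.Date("2016-07-15"))
  expect_equal(unname(got), want, tolerance = 1e-12)

  # too-short seasons are rejected
  expect_error(interval_stats(wconst, as.Date("2016-04-01"),
                              as.Date("2016-04-20")), "42")
})

test_that("kNN imputation recovers maskable structure", {
  set.seed(7)
  X <- matrix(rnorm(40 * 8), 40, 8)
  colnames(X) <- paste0("v", 1:8)
  expect_identical(impute_knn(X), X)
  # a missing cell whose neighbours share a value gets that value
  X2 <- rbind(matrix(5, 6, 8), matrix(rnorm(40 * 8, 50), 40, 8))
  X2m <- X2; X2m[1, 3] <- NA
  expect_equal(impute_knn(X2m, k = 5)[1, 3], 5)
  # MCAR masking: imputation error is below the column SD
  Xs <- X %*% diag(8) + matrix(rep(rnorm(40), 8), 40)  # correlated columns
  mask <- matrix(runif(320) < 0.05, 40, 8)
  Xm <- Xs; Xm[mask] <- NA
  Xi <- impute_knn(Xm, k = 5)
  rmse <- sqrt(mean((Xi[mask] - Xs[mask])^2))
  expect_lt(rmse, mean(apply(Xs, 2, sd)))
  # entirely missing row errors
  Xbad <- Xs; Xbad[1, ] <- NA
  expect_error(impute_knn(Xbad), "entirely missing")
})

test_that("climate-envelope PCA retains leading informative axes", {
  set.seed(8)
  n <- 60
  # five independent planted gradients spread over 21 columns
  basis <- matrix(rnorm(n * 5), n, 5)
  load <- matrix(0, 5, 21)
  for (k in 1:5) load[k, ((k - 1) * 4 + 1):(k * 4)] <- 1
  X <- basis %*% load + matrix(rnorm(n * 21, 0, 0.05), n, 21)
  colnames(X) <- paste0("v", 1:21)
  env <- climate_pca(X)
  expect_equal(length(env$var_explained), 5)
  expect_true(all(env$var_explained > 0.05))
  expect_gt(env$combined, 0.75)
  # orthonormal loadings
  expect_equal(crossprod(env$loadings), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("IDW interpolation is exact, convex and hull-masked", {
  pts <- tibble::tibble(latitude = c(30, 34), longitude = c(-97, -97),
                        value = c(0, 10))
  # cell at a station: that value exactly
  at_station <- idw_interpolate(pts, pts[1, c("latitude", "longitude")])
  expect_equal(at_station$value, 0)
  # equidistant midpoint: arithmetic mean
  mid <- idw_interpolate(pts, tibble::tibble(latitude = 32,
                                             longitude = -97))
  expect_equal(mid$value, 5, tolerance = 1e-6)
  # equal values everywhere: constant raster
  ptsc <- dplyr::mutate(pts, value = 7)
  grid <- tidyr::crossing(latitude = seq(29, 35, 1),
                          longitude = seq(-99, -95, 1))
  rc <- idw_interpolate(ptsc, grid)
  expect_true(all(abs(rc$value - 7) < 1e-9))
  # bounded by the data range
  set.seed(9)
  ptsr <- tibble::tibble(latitude = runif(6, 28, 36),
                         longitude = runif(6, -100, -94),
                         value = rnorm(6))
  rr <- idw_interpolate(ptsr, grid)
  expect_true(all(rr$value >= min(ptsr$value) - 1e-9))
  expect_true(all(rr$value <= max(ptsr$value) + 1e-9))
  # hull masking: far-away cells are masked, site cells are not
  sites <- tibble::tibble(latitude = c(30, 30, 34, 34),
                          longitude = c(-98, -96, -98, -96))
  far_grid <- tibble::tibble(latitude = c(32, 60), longitude = c(-97, -97))
  rm <- idw_interpolate(ptsr, far_grid, sites = sites)
  expect_false(rm$masked[1])
  expect_true(rm$masked[2])
})
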