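#' Principal components of station weather
#'
#' Aggregates daily minimum/maximum temperature and precipitation to monthly
#' station means (36 columns per year of record) and runs a centered, scaled
#' PCA. These axes feed the phenology (growing season) prediction models.
#'
#' @param weather Tibble: station, date, tmin, tmax, prcp.
#' @return List: `scores` (tibble, station + PC columns), `loadings`,
#'   `var_explained` (fractions summing to 1), `center`, `scale`.
#' @export
pca_daily <- function(weather) {
  monthly <- weather |>
    dplyr::mutate(month = format(.data$date, "%m")) |>
    dplyr::group_by(.data$station, .data$month) |>
    dplyr::summarise(tmin = mean(.data$tmin), tmax = mean(.data$tmax),
                     prcp = mean(.data$prcp), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "month",
                       values_from = c("tmin", "tmax", "prcp"))
  X <- as.matrix(monthly[, -1])
  rownames(X) <- monthly$station
  assert_that(nrow(X) >= 2, "need at least 2 stations")
  keep <- apply(X, 2, function(x) stats::sd(x) > 0)
  if (!all(keep)) {
    warning(sum(!keep), " constant column(s) dropped before PCA")
    X <- X[, keep, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- tibble::as_tibble(pc$x, rownames = "station")
  list(scores = scores, loadings = pc$rotation, var_explained = var_frac,
       center = pc$center, scale = pc$scale)
}

#' Best-subsets phenology model over climate axes
#'
#' Exhaustive best-subsets regression of a phenological date on the station
#' weather principal components: all subsets of size 1..`max_terms` are fit
#' and the lowest-BIC subset wins (ties go to the smaller subset).
#'
#' @param dates Julian-day response at the training stations.
#' @param scores Data frame/matrix of PC scores aligned with `dates`
#'   (numeric columns only; a `station` column is carried along if present).
#' @param max_terms Largest subset size (default 4).
#' @return A `phenology_model`: `$subset`, `$coef`, `$bic`, `$r2`.
#' @export
fit_phenology_model <- function(dates, scores, max_terms = 4) {
  scores <- tibble::as_tibble(scores)
  X <- as.matrix(dplyr::select(scores, dplyr::where(is.numeric)))
  n <- length(dates)
  assert_that(nrow(X) == n, "dates and scores must align")
  assert_that(n > max_terms + 1, "need more sites than model terms")
  axes <- colnames(X)
  best <- NULL
  for (size in seq_len(max_terms)) {
    for (ss in utils::combn(axes, size, simplify = FALSE)) {
      fit <- stats::lm(dates ~ ., data = data.frame(dates = dates,
                                                    X[, ss, drop = FALSE]))
      b <- stats::BIC(fit)
      if (is.null(best) || b < best$bic - 1e-9) {
        best <- list(subset = ss, coef = stats::coef(fit), bic = b,
                     r2 = summary(fit)$r.squared)
      }
    }
  }
  structure(best, class = "phenology_model")
}

#' @export
predict.phenology_model <- function(object, newdata, ...) {
  newdata <- tibble::as_tibble(newdata)
  X <- as.matrix(newdata[, object$subset, drop = FALSE])
  drop(object$coef[1] + X %*% object$coef[-1])
}

#' Predict per-station growing seasons
#'
#' The growing season runs from 14 days before predicted green-up to 14 days
#' after predicted flowering. Stations whose predicted window is inverted
#' are flagged and excluded.
#'
#' @param greenup_model,flowering_model Fitted [fit_phenology_model()]s.
#' @param scores Tibble of station PC scores with a `station` column.
#' @param pad Days of padding around the phenological window (default 14).
#' @return Tibble: station, greenup_doy, flowering_doy, season_start,
#'   season_end, valid.
#' @export
predict_growing_season <- function(greenup_model, flowering_model, scores,
                                   pad = 14) {
  g <- predict(greenup_model, scores)
  f <- predict(flowering_model, scores)
  out <- tibble::tibble(
    station = scores$station,
    greenup_doy = g, flowering_doy = f,
    season_start = g - pad, season_end = f + pad,
    valid = g - pad < f + pad
  )
  if (any(!out$valid)) {
    warning(sum(!out$valid), " station(s) with inverted seasons excluded")
  }
  out
}

roll_mean <- function(x, w) {
  cs <- cumsum(c(0, x))
  (cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]) / w
}
roll_sum <- function(x, w) {
  cs <- cumsum(c(0, x))
  cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]
}

#' Growing-season interval statistics (21 variables)
#'
#' Splits the growing season into three equal thirds, extends each by 5 days
#' on both ends (the overlap), and computes per interval: 95th-quantile
#' tmax, 5th-quantile tmin, mean daily precipitation, and the hottest,
#' coldest (14-day rolling mean temperature), driest and wettest (14-day
#' rolling precipitation sum) fortnights. Rolling statistics use complete
#' windows only.
#'
#' @param weather One station's daily records (date, tmin, tmax, prcp).
#' @param season_start,season_end Season window as day-of-year (numeric) of
#'   `year`, or as Dates.
#' @param year Calendar year when day-of-year bounds are given (defaults to
#'   the first year of record).
#' @param pad Interval overlap in days (default 5).
#' @return Named numeric vector of 21 statistics in fixed order
#'   (interval-major: `tmax_q95_i1` ... `wettest14_i3`).
#' @export
interval_stats <- function(weather, season_start, season_end,
                           year = NULL, pad = 5) {
  weather <- weather[order(weather$date), ]
  assert_that(!anyNA(weather$date) && !any(duplicated(weather$date)),
              "weather dates must be unique")
  if (!inherits(season_start, "Date")) {
    year <- year %||% as.integer(format(min(weather$date), "%Y"))
    origin <- as.Date(sprintf("%d-01-01", year)) - 1
    season_start <- origin + round(season_start)
    season_end <- origin + round(season_end)
  }
  assert_that(season_end > season_start, "season must have positive length")
  assert_that(season_start >= min(weather$date) &&
                season_end <= max(weather$date),
              "season must lie within the weather record")
  len <- as.numeric(season_end - season_start) + 1
  assert_that(len >= 42, "season must be at least 42 days")
  b <- season_start + round(len * (0:3) / 3)
  out <- c()
  for (i in 1:3) {
    lo <- max(b[i] - pad, min(weather$date))
    hi <- min(b[i + 1] - 1 + pad, max(weather$date))
    d <- weather[weather$date >= lo & weather$date <= hi, ]
    if (nrow(d) < 14) {
      stop("interval ", i, " shorter than 14 days; rolling statistics ",
           "undefined")
    }
    stats_i <- c(
      tmax_q95 = unname(stats::quantile(d$tmax, 0.95)),
      tmin_q05 = unname(stats::quantile(d$tmin, 0.05)),
      prcp_mean = mean(d$prcp),
      hottest14 = max(roll_mean(d$tmax, 14)),
      coldest14 = min(roll_mean(d$tmin, 14)),
      driest14 = min(roll_sum(d$prcp, 14)),
      wettest14 = max(roll_sum(d$prcp, 14))
    )
    names(stats_i) <- paste0(names(stats_i), "_i", i)
    out <- c(out, stats_i)
  }
  out
}

#' k-nearest-neighbour imputation of a station matrix
#'
#' A missing cell is replaced by the mean of its column over the `k` nearest
#' rows, with distances computed as root-mean-square differences over the
#' standardized columns observed in both rows.
#'
#' @param X Numeric matrix (stations x variables).
#' @param k Number of neighbours (default 5).
#' @return Completed matrix.
#' @export
impute_knn <- function(X, k = 5) {
  X <- as.matrix(X)
  assert_that(all(colSums(!is.na(X)) >= k),
              "every column needs at least k non-missing entries")
  if (!anyNA(X)) return(X)
  assert_that(all(rowSums(!is.na(X)) > 0), "a row is entirely missing")
  Z <- scale(X)
  out <- X
  for (i in which(rowSums(is.na(X)) > 0)) {
    shared <- !is.na(Z) & matrix(!is.na(Z[i, ]), nrow(Z), ncol(Z), byrow = TRUE)
    d2 <- rowSums((Z - matrix(Z[i, ], nrow(Z), ncol(Z), byrow = TRUE))^2 *
                    shared, na.rm = TRUE) / pmax(rowSums(shared), 1)
    d2[i] <- Inf
    d2[rowSums(shared) == 0] <- Inf
    for (j in which(is.na(X[i, ]))) {
      cand <- which(!is.na(X[, j]))
      nb <- cand[order(d2[cand])][seq_len(min(k, length(cand)))]
      out[i, j] <- mean(X[nb, j])
    }
  }
  out
}

#' Climate-envelope PCA over the 21 interval statistics
#'
#' Centered, scaled PCA of the stations x 21 matrix; retains the leading
#' axes that each explain more than `min_var` of the variance, capped at
#' `max_axes` (the default mirrors keeping five eigenvectors each explaining
#' over 5%).
#'
#' @param X Complete stations x variables matrix.
#' @param max_axes Cap on retained axes (default 5).
#' @param min_var Minimum per-axis variance fraction (default 0.05).
#' @return A `climate_envelope`: `$scores` (tibble: station + retained PCs),
#'   `$loadings`, `$var_explained`, `$combined` (summed retained fraction).
#' @export
climate_pca <- function(X, max_axes = 5, min_var = 0.05) {
  X <- as.matrix(X)
  assert_that(!anyNA(X), "matrix must be complete (impute first)")
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  lead <- which(cumsum(frac > min_var) == seq_along(frac))
  n_keep <- min(length(lead), max_axes)
  assert_that(n_keep >= 1, "no axis explains the minimum variance fraction")
  keep <- seq_len(n_keep)
  structure(
    list(scores = tibble::as_tibble(pc$x[, keep, drop = FALSE],
                                    rownames = "station"),
         loadings = pc$rotation[, keep, drop = FALSE],
         var_explained = frac[keep],
         combined = sum(frac[keep])),
    class = "climate_envelope"
  )
}

#' @export
print.climate_envelope <- function(x, ...) {
  cat("<climate_envelope> ", nrow(x$scores), " stations; ",
      length(x$var_explained), " axes explaining ",
      sprintf("%.1f%%", 100 * x$combined), " of variance\n", sep = "")
  invisible(x)
}

#' Buffered convex hull membership
#'
#' @param grid Tibble with latitude/longitude.
#' @param sites Tibble with latitude/longitude of the anchor sites.
#' @param buffer_km Buffer distance (default 200 km).
#' @return Logical vector: TRUE when a grid point lies inside the convex
#'   hull of the sites or within `buffer_km` of its boundary.
#' @export
in_buffered_hull <- function(grid, sites, buffer_km = 200) {
  pts <- cbind(sites$longitude, sites$latitude)
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  gp <- cbind(grid$longitude, grid$latitude)
  if (nrow(hull) < 3) {
    inside <- rep(FALSE, nrow(gp))
  } else {
    inside <- mgcv::in.out(rbind(hull, hull[1, ]), gp)
  }
  ring <- rbind(hull, hull[1, ])
  # dist2Line emits a spurious min() warning for some point/ring geometries
  dist_m <- suppressWarnings(geosphere::dist2Line(gp, ring)[, "distance"])
  near <- dist_m <= buffer_km * 1000
  inside | near
}

#' Inverse-distance-weighted interpolation on a lat/lon grid
#'
#' Great-circle (haversine) distances with weights `d^-power`; a cell within
#' 1 m of a station takes that station's value exactly. When `sites` is
#' given, cells outside the convex hull of the sites buffered by
#' `buffer_km` are masked.
#'
#' @param points Tibble: latitude, longitude, value.
#' @param grid Tibble: latitude, longitude.
#' @param power IDW power (default 2).
#' @param sites Optional site tibble defining the buffered hull mask.
#' @param buffer_km Hull buffer (default 200 km).
#' @return Tibble: latitude, longitude, value, masked.
#' @export
idw_interpolate <- function(points, grid, power = 2, sites = NULL,
                            buffer_km = 200) {
  assert_that(nrow(points) >= 1, "need at least one observed point")
  assert_that(nrow(grid) >= 1, "empty grid")
  D <- geosphere::distm(cbind(points$longitude, points$latitude),
                        cbind(grid$longitude, grid$latitude),
                        fun = geosphere::distHaversine)
  v <- points$value
  w <- (pmax(D, 1))^(-power)
  val <- drop(crossprod(w, v)) / colSums(w)
  hit <- apply(D < 1, 2, function(z) if (any(z)) which(z)[1] else NA_integer_)
  val[!is.na(hit)] <- v[hit[!is.na(hit)]]
  masked <- if (!is.null(sites)) {
    !in_buffered_hull(grid, sites, buffer_km)
  } else rep(FALSE, nrow(grid))
  tibble::tibble(latitude = grid$latitude, longitude = grid$longitude,
                 value = val, masked = masked)
}

#' Regular lat/lon grid covering a set of sites
#'
#' @param sites Tibble with latitude/longitude.
#' @param n Grid points per axis (default 25).
#' @param expand_deg Margin beyond the site bounding box (default 2.5
#'   degrees, roughly a 200 km buffer in latitude).
#' @return Tibble: latitude, longitude.
#' @export
make_grid <- function(sites, n = 25, expand_deg = 2.5) {
  tidyr::crossing(
    latitude = seq(min(sites$latitude) - expand_deg,
                   max(sites$latitude) + expand_deg, length.out = n),
    longitude = seq(min(sites$longitude) - expand_deg,
                    max(sites$longitude) + expand_deg, length.out = n)
  )
}

#' Build the full station climate envelope
#'
#' Chains the growing-season prediction, interval statistics, k-NN
#' imputation and envelope PCA for a set of stations.
#'
#' @param weather Daily weather for all stations.
#' @param seasons Output of [predict_growing_season()].
#' @param k Imputation neighbours.
#' @param max_axes,min_var Passed to [climate_pca()].
#' @return A `climate_envelope` with the 21-variable matrix in `$stats`.
#' @export
build_climate_envelope <- function(weather, seasons, k = 5, max_axes = 5,
                                   min_var = 0.05) {
  seasons <- seasons[seasons$valid, ]
  rows <- purrr::pmap(
    list(seasons$station, seasons$season_start, seasons$season_end),
    function(st, s0, s1) {
      w <- weather[weather$station == st, ]
      tryCatch(interval_stats(w, s0, s1), error = function(e) {
        rep(NA_real_, 21)
      })
    }
  )
  X <- do.call(rbind, rows)
  rownames(X) <- seasons$station
  ok <- rowSums(is.na(X)) < ncol(X)
  X <- X[ok, , drop = FALSE]
  X <- impute_knn(X, k)
  env <- climate_pca(X, max_axes, min_var)
  env$stats <- X
  env
}
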