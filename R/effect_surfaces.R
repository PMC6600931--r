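#' SE-weighted meta-regression of QTL effects on climate axes
#'
#' For each candidate climate axis, fits the fixed-effect meta-regression
#' `effect_s = beta0 + beta1 PC_s` with weights `1/SE_s^2` (each site's QTL
#' estimate weighted by its sampling precision); the slope P value comes
#' from the Wald z statistic. The axis with the smallest slope P is
#' retained. With equal SEs the fit reduces to ordinary least squares.
#'
#' @param effects Tibble: one row per site with `estimate` and `se` (> 0).
#' @param site_scores Tibble/matrix of climate PC scores aligned with
#'   `effects` rows (numeric columns are the candidate axes).
#' @return A `metareg_fit`: `$axis`, `$beta0`, `$beta1`, `$se0`, `$se1`,
#'   `$p`, `$all_axes` (per-axis tibble), `$data`.
#' @export
metaregress_effect <- function(effects, site_scores) {
  effects <- tibble::as_tibble(effects)
  scores <- tibble::as_tibble(site_scores)
  X <- as.matrix(dplyr::select(scores, dplyr::where(is.numeric)))
  assert_that(nrow(effects) >= 4, "need at least 4 sites")
  assert_that(all(is.finite(effects$se) & effects$se > 0),
              "all standard errors must be finite and positive")
  assert_that(nrow(X) == nrow(effects), "effects and scores must align")
  w <- 1 / effects$se^2
  y <- effects$estimate
  per_axis <- purrr::map(colnames(X), function(ax) {
    x <- X[, ax]
    if (stats::sd(x) == 0) {
      return(tibble::tibble(axis = ax, beta0 = NA_real_, beta1 = NA_real_,
                            se0 = NA_real_, se1 = NA_real_, p = NA_real_,
                            flagged = TRUE))
    }
    Xd <- cbind(1, x)
    XtWX <- crossprod(Xd, w * Xd)
    V <- chol2inv(chol(XtWX))
    b <- drop(V %*% crossprod(Xd, w * y))
    se <- sqrt(diag(V))
    z <- b[2] / se[2]
    tibble::tibble(axis = ax, beta0 = b[1], beta1 = b[2],
                   se0 = se[1], se1 = se[2],
                   p = 2 * stats::pnorm(-abs(z)), flagged = FALSE)
  }) |> dplyr::bind_rows()
  ok <- per_axis[!per_axis$flagged, ]
  assert_that(nrow(ok) >= 1, "no usable axis (all constant)")
  best <- ok[which.min(ok$p), ]
  structure(
    list(axis = best$axis, beta0 = best$beta0, beta1 = best$beta1,
         se0 = best$se0, se1 = best$se1, p = best$p,
         all_axes = per_axis, data = effects),
    class = "metareg_fit"
  )
}

#' @export
print.metareg_fit <- function(x, ...) {
  cat("<metareg_fit> axis ", x$axis, ": slope ", signif(x$beta1, 4),
      " (SE ", signif(x$se1, 3), "), P = ", signif(x$p, 3), "\n", sep = "")
  invisible(x)
}

#' Gate meta-regression fits by FDR-adjusted significance
#'
#' Benjamini-Hochberg adjustment over the family of chosen-axis P values;
#' fits with adjusted P below `threshold` (default 0.05/5, the nominal level
#' divided by the number of candidate axes) are flagged significant.
#'
#' @param fits Tibble with a `p` column (one row per QTL x contrast).
#' @param threshold Significance gate (default `0.05 / 5`).
#' @return `fits` with `p_adj` and `significant` columns.
#' @export
adjust_and_gate <- function(fits, threshold = 0.05 / 5) {
  assert_that(nrow(fits) >= 1, "no fits to adjust")
  fits$p_adj <- stats::p.adjust(fits$p, method = "BH")
  fits$significant <- fits$p_adj < threshold
  fits
}

#' Predict and mask a QTL effect surface
#'
#' Applies a significant meta-regression fit to every station's climate
#' score, rasterizes the predictions by inverse-distance weighting over the
#' buffered convex hull of the field sites, and masks cells whose predicted
#' effect falls outside the envelope of observed effects (observed min/max
#' padded by twice the largest observed SE) or outside the hull.
#'
#' @param fit A `metareg_fit`.
#' @param station_scores Tibble: station, latitude, longitude and the PC
#'   columns.
#' @param sites Tibble of field-site coordinates (latitude, longitude).
#' @param grid Optional raster grid; defaults to [make_grid()] over sites.
#' @param power,buffer_km IDW parameters.
#' @param envelope One of "max_se" (default; observed range padded by 2
#'   max SE), "per_site_se", "sd" (2 SD of observed effects).
#' @return An `effect_surface` tibble: latitude, longitude, value, masked,
#'   with the fit and envelope recorded as attributes.
#' @export
predict_surface <- function(fit, station_scores, sites, grid = NULL,
                            power = 2, buffer_km = 200,
                            envelope = c("max_se", "per_site_se", "sd")) {
  stopifnot(inherits(fit, "metareg_fit"))
  envelope <- match.arg(envelope)
  grid <- grid %||% make_grid(sites)
  obs <- fit$data
  pad <- switch(envelope,
                max_se = 2 * max(obs$se),
                per_site_se = 2 * obs$se[which.max(abs(obs$estimate))],
                sd = 2 * stats::sd(obs$estimate))
  env_lo <- min(obs$estimate) - pad
  env_hi <- max(obs$estimate) + pad
  pred <- fit$beta0 + fit$beta1 * station_scores[[fit$axis]]
  pts <- tibble::tibble(latitude = station_scores$latitude,
                        longitude = station_scores$longitude,
                        value = pred)
  surf <- idw_interpolate(pts, grid, power = power, sites = sites,
                          buffer_km = buffer_km)
  surf$masked <- surf$masked | surf$value < env_lo | surf$value > env_hi
  if (all(surf$masked)) warning("surface is fully masked")
  structure(surf, class = c("effect_surface", class(surf)),
            fit = list(axis = fit$axis, beta0 = fit$beta0, beta1 = fit$beta1),
            envelope = c(lo = env_lo, hi = env_hi))
}

#' Assemble the optimal-genotype summary for one site
#'
#' Keeps QTL effects further than two standard errors from zero and credits
#' each `|estimate|` to the lowland pool when the trait-increasing allele is
#' lowland (positive estimates under the +/-0.5 coding: the A or C
#' grandparent allele) or to the upland pool otherwise (B or D allele).
#'
#' @param effects Tibble for one site: qtl, contrast, estimate, se.
#' @param se_factor Significance gate (default 2).
#' @return One-row tibble: n_qtl, lowland_sum, upland_sum, pct_lowland.
#' @export
assemble_optimal_genotype <- function(effects, se_factor = 2) {
  keep <- !is.na(effects$se) & abs(effects$estimate) > se_factor * effects$se
  sig <- effects[keep, ]
  lowland <- sum(abs(sig$estimate[sig$estimate > 0]))
  upland <- sum(abs(sig$estimate[sig$estimate < 0]))
  tot <- lowland + upland
  tibble::tibble(
    n_qtl = nrow(sig),
    lowland_sum = lowland,
    upland_sum = upland,
    pct_lowland = if (tot > 0) 100 * lowland / tot else NA_real_
  )
}
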