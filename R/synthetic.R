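#' Describe a four-way outbred cross
#'
#' A four-way cross crosses two F1 hybrids, (A x B) x (C x D), so every
#' progeny carries one recombinant A/B haplotype and one recombinant C/D
#' haplotype; each locus is one of AC, AD, BC, BD. The design object records
#' the population size and the simulated genome.
#'
#' @param n_progeny Number of recombinant progeny.
#' @param chromosomes A data frame with columns `chrom`, `length_cM`,
#'   `n_markers` (markers are placed evenly along each chromosome).
#' @param labels Grandparent labels, first cross then second cross.
#' @return An object of class `cross_design`.
#' @examples
#' cross_design(100, tibble::tibble(chrom = "1A", length_cM = 50, n_markers = 20))
#' @export
cross_design <- function(n_progeny,
                         chromosomes,
                         labels = c("A", "B", "C", "D")) {
  chromosomes <- tibble::as_tibble(chromosomes)
  assert_that(n_progeny >= 1, "n_progeny must be >= 1")
  assert_that(all(c("chrom", "length_cM", "n_markers") %in% names(chromosomes)),
              "chromosomes needs columns chrom, length_cM, n_markers")
  assert_that(all(chromosomes$length_cM > 0),
              "invalid design: chromosome lengths must be positive")
  assert_that(all(chromosomes$n_markers >= 2),
              "invalid design: need >= 2 markers per chromosome")
  assert_that(length(unique(labels)) == 4, "grandparent labels must be distinct")
  structure(
    list(n_progeny = as.integer(n_progeny), chromosomes = chromosomes,
         labels = labels),
    class = "cross_design"
  )
}

#' Preset cross design matching a 425-progeny, 2-chromosome study population
#'
#' @param n_progeny Population size; defaults to 425 recombinant progeny.
#' @param n_chrom,length_cM,n_markers Genome shape for desk-scale work.
#' @return A [cross_design()].
#' @export
demo_cross_design <- function(n_progeny = 425, n_chrom = 2,
                              length_cM = 21, n_markers = 100) {
  cross_design(
    n_progeny,
    tibble::tibble(
      chrom = paste0("chr", seq_len(n_chrom)),
      length_cM = length_cM,
      n_markers = n_markers
    )
  )
}

# One meiosis under no interference (Haldane): crossovers are a Poisson
# process along the chromosome; returns +1/-1 grandparent origin at `pos`.
sim_meiosis <- function(pos, length_cM) {
  n_xo <- stats::rpois(1, length_cM / 100)
  start <- sample(c(1L, -1L), 1)
  if (n_xo == 0) return(rep(start, length(pos)))
  xo <- sort(stats::runif(n_xo, 0, length_cM))
  start * (-1L)^findInterval(pos, xo)
}

#' Simulate phase-known four-way genotypes
#'
#' Each progeny receives one meiotic product of the (A x B) F1 and one of the
#' (C x D) F1, simulated independently with no crossover interference
#' (Haldane model). Calls are phase-known grandparent pairs (AC/AD/BC/BD),
#' emulating k-mer based genotyping that distinguishes all four grandparents.
#'
#' @param design A [cross_design()].
#' @param seed Integer seed.
#' @return A `fourway_geno` object: integer call matrix (`$geno`; progeny x
#'   marker, codes 1:4 = AC, AD, BC, BD) plus the true map (`$map`, a tibble
#'   with marker, chrom, cM and 0-based physical window start `bp`).
#' @examples
#' g <- sim_fourway_genotypes(demo_cross_design(50, 1, 50, 10), seed = 1)
#' table(geno_calls(g)[, 1])
#' @export
sim_fourway_genotypes <- function(design, seed = 1) {
  stopifnot(inherits(design, "cross_design"))
  set.seed(seed)
  n <- design$n_progeny
  maps <- purrr::pmap(design$chromosomes, function(chrom, length_cM, n_markers) {
    tibble::tibble(
      chrom = chrom,
      idx = seq_len(n_markers),
      cM = seq(0, length_cM, length.out = n_markers),
      length_cM = length_cM
    )
  })
  map <- dplyr::bind_rows(maps)
  map$marker <- sprintf("%s_m%04d", map$chrom, map$idx)
  # 64 bp windows binned in 50-marker blocks upstream: 3200 bp per marker
  map$bp <- (map$idx - 1L) * 3200L

  geno <- matrix(NA_integer_, n, nrow(map),
                 dimnames = list(sprintf("g%03d", seq_len(n)), map$marker))
  for (ch in unique(map$chrom)) {
    sel <- which(map$chrom == ch)
    pos <- map$cM[sel]
    L <- map$length_cM[sel][1]
    for (i in seq_len(n)) {
      ab <- sim_meiosis(pos, L)
      cd <- sim_meiosis(pos, L)
      geno[i, sel] <- code_from_ab_cd(ab, cd)
    }
  }
  structure(
    list(geno = geno,
         map = dplyr::select(map, "marker", "chrom", "cM", "bp")),
    class = "fourway_geno"
  )
}

#' @export
print.fourway_geno <- function(x, ...) {
  cat("<fourway_geno> ", nrow(x$geno), " progeny x ", ncol(x$geno),
      " markers on ", length(unique(x$map$chrom)), " chromosome(s); ",
      sprintf("%.1f%%", 100 * mean(is.na(x$geno))), " missing\n", sep = "")
  invisible(x)
}

#' Extract genotype calls as grandparent-pair tokens
#'
#' @param g A `fourway_geno`.
#' @return Character matrix with entries AC/AD/BC/BD or NA.
#' @export
geno_calls <- function(g) {
  out <- matrix(geno_levels()[g$geno], nrow(g$geno), ncol(g$geno),
                dimnames = dimnames(g$geno))
  out
}

#' Add missingness and genotyping error to four-way calls
#'
#' Cells are independently set missing with probability `missing_rate`;
#' surviving cells are swapped to a uniformly chosen other class with
#' probability `error_rate`. This emulates raw-call noise upstream of
#' missingness filtering and window binning.
#'
#' @param g A `fourway_geno`.
#' @param missing_rate,error_rate Per-cell probabilities in `[0, 1)`
#'   (`missing_rate = 1` is allowed as an explicit boundary).
#' @param seed Integer seed.
#' @return A `fourway_geno` with corrupted calls; the map is untouched.
#' @export
corrupt_genotypes <- function(g, missing_rate = 0.1, error_rate = 0.01,
                              seed = 1) {
  stopifnot(inherits(g, "fourway_geno"))
  assert_that(missing_rate >= 0 && missing_rate <= 1,
              "invalid parameter: missing_rate must be in [0, 1]")
  assert_that(error_rate >= 0 && error_rate < 1,
              "invalid parameter: error_rate must be in [0, 1)")
  set.seed(seed)
  geno <- g$geno
  ncell <- length(geno)
  if (error_rate > 0) {
    err <- which(stats::runif(ncell) < error_rate & !is.na(geno))
    if (length(err)) {
      # uniform over the three other classes
      shift <- sample(1:3, length(err), replace = TRUE)
      geno[err] <- (geno[err] - 1L + shift) %% 4L + 1L
    }
  }
  if (missing_rate > 0) {
    geno[stats::runif(ncell) < missing_rate] <- NA_integer_
  }
  g$geno <- geno
  g
}

#' Describe the multi-environment trial layout
#'
#' Environments are site-by-year combinations. The residual covariance
#' `sigma` (environments x environments) lets simulated residuals be
#' correlated across environments, as expected when sites share weather.
#'
#' @param sites A data frame with columns `site`, `latitude`, `longitude`.
#' @param years Vector of years (each site is phenotyped every year).
#' @param mu Environment means (length 1 or n_env, in trait units).
#' @param sigma Residual covariance across environments; a scalar is expanded
#'   to `scalar * I`. Must be symmetric positive-definite.
#' @return An `env_design` object with `$envs` (tibble: env, site, year,
#'   latitude, longitude, mu) and `$sigma`.
#' @export
env_design <- function(sites, years = 2016:2017, mu = 0, sigma = 1) {
  sites <- tibble::as_tibble(sites)
  assert_that(all(c("site", "latitude", "longitude") %in% names(sites)),
              "sites needs columns site, latitude, longitude")
  assert_that(all(abs(sites$latitude) <= 90), "latitude out of range")
  envs <- tidyr::crossing(sites, year = years)
  envs$env <- paste(envs$site, envs$year, sep = ":")
  E <- nrow(envs)
  if (is.matrix(sigma)) {
    assert_that(nrow(sigma) == E && ncol(sigma) == E,
                "sigma must be n_env x n_env")
    assert_that(max(abs(sigma - t(sigma))) < 1e-8, "sigma must be symmetric")
    ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    assert_that(min(ev) > 0, "covariance error: sigma not positive-definite")
  } else {
    assert_that(sigma > 0, "covariance error: sigma must be positive")
    sigma <- diag(sigma, E)
  }
  envs$mu <- rep_len(mu, E)
  structure(
    list(envs = dplyr::select(envs, "env", "site", "year",
                              "latitude", "longitude", "mu"),
         sigma = sigma),
    class = "env_design"
  )
}

#' Preset trial layout: 10 sites spanning a latitudinal transect, 2 years
#'
#' Ten sites from south Texas to eastern South Dakota phenotyped in two
#' consecutive years (20 environments), with compound-symmetric residual
#' correlation across environments.
#'
#' @param n_sites,years Trial shape.
#' @param sigma2 Residual variance per environment.
#' @param rho Cross-environment residual correlation.
#' @return An [env_design()].
#' @export
demo_env_design <- function(n_sites = 10, years = 2016:2017,
                            sigma2 = 1, rho = 0.2) {
  sites <- tibble::tibble(
    site = sprintf("S%02d", seq_len(n_sites)),
    latitude = seq(27.2, 44.3, length.out = n_sites),
    longitude = seq(-97.4, -96.8, length.out = n_sites)
  )
  E <- n_sites * length(years)
  sig <- sigma2 * ((1 - rho) * diag(E) + rho)
  env_design(sites, years, mu = 0, sigma = sig)
}

#' Tabulate true QTL with per-environment effects
#'
#' @param qtl,chrom,pos_cM QTL name, chromosome, genetic position.
#' @param env Environment ids (must match an `env_design`).
#' @param a,a2,d Per-environment additive (first cross A-B, second cross C-D)
#'   and dominance effects in trait units; scalars recycle over environments.
#' @return A long tibble, one row per QTL x environment.
#' @export
true_qtl <- function(qtl, chrom, pos_cM, env, a = 0, a2 = 0, d = 0) {
  tidyr::crossing(
    tibble::tibble(qtl = qtl, chrom = chrom, pos_cM = pos_cM),
    tibble::tibble(env = env)
  ) |>
    dplyr::group_by(.data$qtl) |>
    dplyr::mutate(a = rep_len(a, dplyr::n()), a2 = rep_len(a2, dplyr::n()),
                  d = rep_len(d, dplyr::n())) |>
    dplyr::ungroup()
}

#' Simulate multi-environment phenotypes from true QTL
#'
#' Generates `value(i, e) = mu_e + sum_q [x_a a_e + x_a2 a2_e + x_d d_e] +
#' eps(i, .)` with residual rows drawn with covariance `env$sigma` across
#' environments. Predictors use the +/-0.5 contrast coding (see
#' [encode_predictors()]); each QTL is placed at the nearest marker so its
#' genotype is known exactly.
#'
#' @param g A `fourway_geno` (uncorrupted truth).
#' @param qtls Tibble from [true_qtl()] (may be empty for a pure-noise trait).
#' @param env An [env_design()].
#' @param seed Integer seed.
#' @param trait Trait label.
#' @return Long tibble: genotype, site, year, env, trait, value.
#' @export
sim_phenotypes <- function(g, qtls, env, seed = 1, trait = "biomass") {
  stopifnot(inherits(g, "fourway_geno"), inherits(env, "env_design"))
  set.seed(seed)
  envs <- env$envs
  E <- nrow(envs)
  n <- nrow(g$geno)
  Y <- matrix(rep(envs$mu, each = n), n, E)
  if (nrow(qtls %||% tibble::tibble())) {
    assert_that(all(qtls$env %in% envs$env),
                "QTL effect environments must match the env design")
    per_qtl <- dplyr::group_split(qtls, .data$qtl)
    for (q in per_qtl) {
      m <- g$map[g$map$chrom == q$chrom[1], ]
      assert_that(nrow(m) > 0, "QTL chromosome not on map")
      marker <- m$marker[which.min(abs(m$cM - q$pos_cM[1]))]
      code <- g$geno[, marker]
      xa <- code_ab(code) / 2
      xa2 <- code_cd(code) / 2
      xd <- 2 * xa * xa2
      xa[is.na(xa)] <- 0; xa2[is.na(xa2)] <- 0; xd[is.na(xd)] <- 0
      eidx <- match(envs$env, q$env)
      Y <- Y + outer(xa, q$a[eidx]) + outer(xa2, q$a2[eidx]) +
        outer(xd, q$d[eidx])
    }
  }
  Y <- Y + MASS::mvrnorm(n, rep(0, E), env$sigma)
  dimnames(Y) <- list(rownames(g$geno), envs$env)
  tibble::as_tibble(Y, rownames = "genotype") |>
    tidyr::pivot_longer(-"genotype", names_to = "env", values_to = "value") |>
    dplyr::left_join(dplyr::select(envs, "env", "site", "year"), by = "env") |>
    dplyr::mutate(trait = trait) |>
    dplyr::select("genotype", "site", "year", "env", "trait", "value")
}

#' Simulate daily station weather along a latitudinal gradient
#'
#' Daily temperature follows a sinusoidal seasonal curve whose annual mean
#' decreases with latitude at 0.97 degrees C per degree latitude (mean annual
#' temperature = 47.2 - 0.97 x latitude), with additive noise; `tmax >= tmin`
#' holds by construction. Green-up and flowering dates are linear in
#' latitude: `greenup_doy = 30 + 3.5 (lat - 27)`,
#' `flowering_doy = 180 + 2.5 (lat - 27)`, plus noise.
#'
#' @param n_stations Number of stations (>= 2).
#' @param lat_range,lon_range Bounding box (degrees).
#' @param n_days Days of record, starting at `start`.
#' @param seed Integer seed.
#' @param noise_sd Weather noise SD in degrees C (0 gives deterministic
#'   series that depend on latitude only).
#' @param phenology_sd Noise SD (days) on green-up/flowering dates.
#' @param start First date of record.
#' @return List with `stations` (station, latitude, longitude), `weather`
#'   (station, date, tmin, tmax, prcp) and `phenology` (station, greenup_doy,
#'   flowering_doy).
#' @export
sim_station_weather <- function(n_stations, lat_range = c(27, 45),
                                lon_range = c(-103, -88), n_days = 730,
                                seed = 1, noise_sd = 2, phenology_sd = 3,
                                start = as.Date("2016-01-01")) {
  assert_that(n_stations >= 2, "need at least 2 stations")
  assert_that(diff(range(lat_range)) >= 0 && diff(range(lon_range)) >= 0,
              "invalid lat/lon box")
  set.seed(seed)
  stations <- tibble::tibble(
    station = sprintf("st%03d", seq_len(n_stations)),
    latitude = seq(lat_range[1], lat_range[2], length.out = n_stations),
    longitude = stats::runif(n_stations, lon_range[1], lon_range[2])
  )
  dates <- start + seq_len(n_days) - 1
  doy <- as.integer(format(dates, "%j"))
  weather <- purrr::pmap(stations, function(station, latitude, longitude) {
    tmean <- (47.2 - 0.97 * latitude) -
      15 * cos(2 * pi * (doy - 15) / 365.25)
    e1 <- stats::rnorm(n_days, 0, noise_sd)
    e2 <- stats::rnorm(n_days, 0, noise_sd)
    tmin <- tmean - 4 + e1
    tmax <- tmin + 8 + abs(e2)
    base <- 2.5 + 1.2 * sin(2 * pi * (doy - 120) / 365.25) +
      0.05 * (latitude - mean(lat_range))
    prcp <- pmax(0, base * (1 + noise_sd / 2 * stats::rnorm(n_days)))
    tibble::tibble(station = station, date = dates,
                   tmin = tmin, tmax = tmax, prcp = prcp)
  }) |> dplyr::bind_rows()
  phenology <- stations |>
    dplyr::mutate(
      greenup_doy = 30 + 3.5 * (.data$latitude - 27) +
        stats::rnorm(n_stations, 0, phenology_sd),
      flowering_doy = 180 + 2.5 * (.data$latitude - 27) +
        stats::rnorm(n_stations, 0, phenology_sd)
    ) |>
    dplyr::select("station", "greenup_doy", "flowering_doy")
  list(stations = stations, weather = weather, phenology = phenology)
}
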