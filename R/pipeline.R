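#' Pipeline configuration
#'
#' Collects every stage toggle and threshold with the defaults used
#' throughout the package: missingness filter 0.60, 50-marker bins,
#' linkage-group threshold r < 0.25, QTL separation 30 cM, cofactor
#' proximity 50 cM, genome-wide alpha 0.05, k = 5 imputation neighbours,
#' IDW power 2, 200 km hull buffer, FDR gate 0.05/5 and a 2-SE significance
#' rule. The `sim` block sets the synthetic study: its defaults are a
#' desk-scale version of a 425-progeny, 10-site, 2-year trial.
#'
#' @param seed Root seed; per-stage seeds are derived deterministically.
#' @param ... Overrides for any config entry (nested lists are merged).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    max_missing = 0.60, window_size = 50, r_threshold = 0.25,
    ripple_window = 4, min_sep_cM = 30, cofactor_prox_cM = 50,
    alpha = 0.05, rounds = 3, covariance_structure = "auto",
    knn_k = 5, idw_power = 2, buffer_km = 200,
    fdr_threshold = 0.05 / 5, se_factor = 2,
    sim = list(
      n_progeny = 200, n_chrom = 2, length_cM = 21, n_bins = 30,
      bin_size = 20, missing_rate = 0.10, error_rate = 0.01,
      n_sites = 8, years = 2016:2017, sigma2 = 1, rho = 0.2,
      n_extra_stations = 15, n_days = 730, weather_noise_sd = 1.5
    ),
    stages = c("simulate", "map", "scan", "quantgen", "climate",
               "surfaces", "tradeoffs"),
    max_rg_pairs = 3
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = "pipeline_config")
}

# default true QTL set for the simulated study: one constant-effect locus,
# one latitudinal sign-changer, one conditionally neutral southern locus
default_true_qtl <- function(cfg, env) {
  envs <- env$envs
  lat_z <- scale(envs$latitude)[, 1]
  south <- envs$latitude <= stats::median(envs$latitude)
  L <- cfg$sim$length_cM
  dplyr::bind_rows(
    true_qtl("Q1", "chr1", 0.25 * L, envs$env, a = 0.5, a2 = 0.25),
    true_qtl("Q2", "chr1", 0.80 * L, envs$env, a = -0.5 * lat_z),
    true_qtl("Q3", "chr2", 0.50 * L, envs$env,
             a = ifelse(south, 0.5, 0), a2 = ifelse(south, 0.4, 0))
  )
}

write_stage <- function(x, outdir, name) {
  path <- file.path(outdir, name)
  readr::write_csv(x, path)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — simulate (or ingest), map,
#' multi-environment QTL scan, quantitative genetics, climate envelope,
#' effect surfaces, trade-offs — writing each stage's tables as CSV under
#' `outdir` together with a manifest recording the config, per-stage seeds
#' and md5 checksums of every output. The same config and seed give
#' byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("run")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  res <- list()
  sm <- config$sim
  seeds <- stats::setNames(
    vapply(seq_along(config$stages), function(i) stage_seed(config$seed, i),
           integer(1)),
    config$stages
  )

  # --- simulate ---------------------------------------------------------
  design <- cross_design(
    sm$n_progeny,
    tibble::tibble(chrom = paste0("chr", seq_len(sm$n_chrom)),
                   length_cM = sm$length_cM,
                   n_markers = sm$n_bins * sm$bin_size)
  )
  truth <- sim_fourway_genotypes(design, seed = seeds[["simulate"]])
  env <- demo_env_design(n_sites = sm$n_sites, years = sm$years,
                         sigma2 = sm$sigma2, rho = sm$rho)
  qtls <- default_true_qtl(config, env)
  raw <- corrupt_genotypes(truth, sm$missing_rate, sm$error_rate,
                           seed = seeds[["simulate"]] + 1L)
  pheno <- sim_phenotypes(truth, qtls, env, seed = seeds[["simulate"]] + 2L)
  wx <- sim_station_weather(
    n_stations = sm$n_sites + sm$n_extra_stations,
    n_days = sm$n_days, seed = seeds[["simulate"]] + 3L,
    noise_sd = sm$weather_noise_sd
  )
  # anchor the first stations at the field sites
  sites <- dplyr::distinct(env$envs, .data$site, .data$latitude,
                           .data$longitude)
  site_station <- stats::setNames(wx$stations$station[seq_len(nrow(sites))],
                                  sites$site)
  wx$stations$latitude[seq_len(nrow(sites))] <- sites$latitude
  wx$stations$longitude[seq_len(nrow(sites))] <- sites$longitude
  res$truth <- list(geno = truth, qtls = qtls, env = env)
  files <- c(files, write_genotypes(raw, file.path(outdir, "genotypes")),
             write_stage(pheno, outdir, "phenotypes.csv"),
             write_stage(wx$weather, outdir, "weather.csv"),
             write_stage(wx$stations, outdir, "stations.csv"),
             write_stage(wx$phenology, outdir, "phenology.csv"),
             write_stage(qtls, outdir, "true_qtl.csv"))

  # --- map --------------------------------------------------------------
  lmap <- build_linkage_map(raw, max_missing = config$max_missing,
                            window_size = config$window_size,
                            r_threshold = config$r_threshold,
                            ripple_window = config$ripple_window)
  res$map <- lmap
  files <- c(files, write_stage(lmap$map, outdir, "linkage_map.csv"))

  # --- scan -------------------------------------------------------------
  pheno1 <- average_replicates(pheno)
  pheno1 <- cull_outliers(pheno1, alpha = config$alpha)
  geno_binned <- lmap$geno
  preds <- encode_predictors(geno_binned, map = lmap$map)
  structures <- if (config$covariance_structure == "auto") {
    c("id", "diag", "cs", "un")
  } else config$covariance_structure
  baseline <- select_covariance(pheno1, structures = structures)
  thr <- effective_tests(preds, alpha = config$alpha)
  cim <- cim_scan(pheno1, preds, baseline, threshold = thr$threshold,
                  min_sep_cM = config$min_sep_cM,
                  cofactor_prox_cM = config$cofactor_prox_cM,
                  rounds = config$rounds)
  res$scan <- list(threshold = thr, cim = cim, baseline = baseline)
  files <- c(files, write_stage(tibble::as_tibble(cim$profile),
                                outdir, "scan_profile.csv"))
  effects <- NULL
  if (nrow(cim$qtl) > 0) {
    fit <- fit_final_model(pheno1, preds, cim$qtl$pos, baseline,
                           alpha = config$alpha)
    effects <- fit$effects |>
      dplyr::left_join(
        dplyr::select(cim$qtl, qtl = "pos", "chrom", "cM"), by = "qtl"
      ) |>
      dplyr::mutate(qtl_name = sprintf("%s@%.0f", .data$chrom, .data$cM))
    res$fit <- fit
    files <- c(files, write_stage(effects, outdir, "qtl_effects.csv"))
  }

  # --- quantgen ---------------------------------------------------------
  K <- kinship_additive(geno_binned)
  h2 <- estimate_h2(pheno1, K, mode = "per_env")
  rg <- genetic_correlations(pheno1, K, max_pairs = config$max_rg_pairs)
  res$quantgen <- list(K = K, h2 = h2, rg = rg)
  files <- c(files, write_stage(h2, outdir, "heritability.csv"),
             write_stage(rg, outdir, "genetic_correlations.csv"))

  # --- climate ----------------------------------------------------------
  daily_pc <- pca_daily(wx$weather)
  train <- dplyr::inner_join(wx$phenology, daily_pc$scores, by = "station")
  gm <- fit_phenology_model(train$greenup_doy,
                            dplyr::select(train, dplyr::starts_with("PC")))
  fm <- fit_phenology_model(train$flowering_doy,
                            dplyr::select(train, dplyr::starts_with("PC")))
  seasons <- predict_growing_season(gm, fm, daily_pc$scores)
  envl <- build_climate_envelope(wx$weather, seasons, k = config$knn_k)
  station_scores <- envl$scores |>
    dplyr::inner_join(wx$stations, by = "station")
  res$climate <- list(envelope = envl, seasons = seasons,
                      station_scores = station_scores)
  envelope_tbl <- tibble::as_tibble(envl$stats, rownames = "station") |>
    dplyr::inner_join(station_scores, by = "station")
  files <- c(files, write_stage(seasons, outdir, "growing_seasons.csv"),
             write_stage(envelope_tbl, outdir, "climate_envelope.csv"))

  # --- surfaces ---------------------------------------------------------
  if (!is.null(effects)) {
    last_year <- max(pheno1$year)
    eff_year <- effects |>
      dplyr::filter(.data$term %in% c("a", "a2"), .data$retained,
                    endsWith(.data$env, as.character(last_year)))
    site_of_env <- function(e) sub(":.*$", "", e)
    fits <- eff_year |>
      dplyr::group_split(.data$qtl_name, .data$term) |>
      purrr::map(function(d) {
        d$site <- site_of_env(d$env)
        sc <- station_scores[match(site_station[d$site],
                                   station_scores$station), ]
        if (anyNA(sc$station) || nrow(d) < 4) return(NULL)
        mr <- metaregress_effect(
          dplyr::select(d, "estimate", "se"),
          dplyr::select(sc, dplyr::starts_with("PC"))
        )
        tibble::tibble(qtl = d$qtl_name[1], term = d$term[1],
                       axis = mr$axis, beta0 = mr$beta0, beta1 = mr$beta1,
                       se1 = mr$se1, p = mr$p, fit = list(mr))
      }) |>
      purrr::compact() |>
      dplyr::bind_rows()
    if (nrow(fits)) {
      fits <- adjust_and_gate(fits, threshold = config$fdr_threshold)
      surfaces <- fits |>
        dplyr::filter(.data$significant) |>
        purrr::pmap(function(qtl, term, fit, ...) {
          s <- predict_surface(fit, station_scores, sites,
                               power = config$idw_power,
                               buffer_km = config$buffer_km)
          dplyr::mutate(tibble::as_tibble(s), qtl = qtl, term = term)
        }) |>
        dplyr::bind_rows()
      res$surfaces <- list(fits = dplyr::select(fits, -"fit"),
                           raster = surfaces)
      files <- c(files,
                 write_stage(dplyr::select(fits, -"fit"), outdir,
                             "metaregression.csv"))
      if (nrow(surfaces)) {
        files <- c(files, write_stage(surfaces, outdir,
                                      "effect_surfaces.csv"))
      }
    }

    # --- tradeoffs ------------------------------------------------------
    trade <- tradeoff_table(
      dplyr::filter(effects, .data$term %in% c("a", "a2")),
      se_factor = config$se_factor
    )
    paired <- effects |>
      dplyr::filter(.data$term %in% c("a", "a2")) |>
      dplyr::select("qtl", "env", "term", "estimate") |>
      tidyr::pivot_wider(names_from = "term", values_from = "estimate")
    conc <- if (all(c("a", "a2") %in% names(paired))) {
      cross_concordance(paired$a, paired$a2)
    } else NULL
    opt <- effects |>
      dplyr::filter(.data$term %in% c("a", "a2")) |>
      dplyr::group_split(.data$env) |>
      purrr::map(function(d) {
        dplyr::mutate(assemble_optimal_genotype(d, config$se_factor),
                      env = d$env[1], .before = 1)
      }) |>
      dplyr::bind_rows()
    res$tradeoffs <- list(table = trade, concordance = conc, optimal = opt)
    files <- c(files, write_stage(trade, outdir, "tradeoffs.csv"),
               write_stage(opt, outdir, "optimal_genotypes.csv"))
    if (!is.null(conc)) {
      files <- c(files, write_stage(conc, outdir, "concordance.csv"))
    }
  }

  # --- manifest ---------------------------------------------------------
  cfg_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    stage_seeds = as.list(seeds),
    outputs = lapply(sort(unique(files)), function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  res$outdir <- outdir
  invisible(res)
}
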