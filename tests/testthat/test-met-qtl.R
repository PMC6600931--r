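make_pheno <- function(Y, years = 2016) {
  tibble::as_tibble(Y, rownames = "genotype") |>
    tidyr::pivot_longer(-genotype, names_to = "env", values_to = "value") |>
    dplyr::mutate(site = sub(":.*", "", env),
                  year = as.integer(sub(".*:", "", env)),
                  trait = "biomass") |>
    dplyr::select(genotype, site, year, env, trait, value)
}

test_that("replicate averaging yields one value per genotype x env", {
  p <- tibble::tibble(
    genotype = c("g1", "g1", "g2", "g1", "g1", "g1"),
    site = c("S1", "S1", "S1", "S2", "S2", "S2"),
    year = 2016, trait = "biomass",
    value = c(5, 7, 3, 1, 2, 9)
  )
  a <- average_replicates(p)
  expect_equal(a$value[a$genotype == "g1" & a$site == "S1"], 6)
  expect_equal(a$value[a$genotype == "g2" & a$site == "S1"], 3)
  expect_equal(a$value[a$genotype == "g1" & a$site == "S2"], 4)
})

test_that("outlier culling drops gross outliers and nothing else", {
  set.seed(2)
  d <- tidyr::crossing(genotype = sprintf("g%02d", 1:40),
                       site = c("S1", "S2", "S3"), year = 2016:2017) |>
    dplyr::mutate(trait = "biomass", value = rnorm(dplyr::n(), 10, 1),
                  env = paste(site, year, sep = ":"))
  # displace one observation by ~10 residual SD
  d$value[5] <- d$value[5] + 10
  culled <- cull_outliers(d)
  # the displaced point goes; with 2 replicates its cell partner carries the
  # mirror-image residual and may go with it, but nothing else does
  expect_false(d$value[5] %in% culled$value)
  expect_lte(nrow(d) - nrow(culled), 2)
  # noise-free data loses nothing
  clean <- dplyr::mutate(d[-5, ], value = 10)
  expect_equal(nrow(cull_outliers(clean)), nrow(clean))
  # saturated single-year design warns and skips
  sat <- dplyr::filter(d, year == 2016)
  expect_warning(cull_outliers(sat), "saturated")
})

test_that("predictor coding follows the +/-0.5 contrast convention", {
  tok <- rbind(c("AC", "AC"), c("AD", "AD"), c("BC", "BC"), c("BD", "BD"))
  g <- make_geno(tok, cM = c(0, 10))
  pr <- encode_predictors(g)
  expect_equal(pr$xa[, 1], c(0.5, 0.5, -0.5, -0.5), ignore_attr = TRUE)
  expect_equal(pr$xa2[, 1], c(0.5, -0.5, 0.5, -0.5), ignore_attr = TRUE)
  expect_equal(pr$xd[, 1], c(0.5, -0.5, -0.5, 0.5), ignore_attr = TRUE)
})

test_that("missing and pseudo positions get flanking-conditional predictors", {
  # progeny AC at both flanks, missing in the middle, tight linkage
  tok <- rbind(c("AC", NA, "AC"), c("BD", NA, "BD"), c("AC", "AC", "AC"))
  g <- make_geno(tok, cM = c(0, 1, 2))
  pr <- encode_predictors(g)
  expect_gt(pr$xa[1, 2], 0.49)   # nearly certain A
  expect_lt(pr$xa[2, 2], -0.49)  # nearly certain B
  expect_true(all(abs(pr$xa) <= 0.5 & abs(pr$xa2) <= 0.5))

  # pseudomarker midway between two AC markers
  g2 <- make_geno(rbind(c("AC", "AC"), c("AD", "AD")), cM = c(0, 2))
  pr2 <- encode_predictors(g2, step_cM = 1)
  mid <- which(pr2$positions$cM == 1)
  expect_gt(pr2$xa[1, mid], 0.49)
  expect_gt(pr2$xa2[1, mid], 0.49)
  expect_lt(pr2$xa2[2, mid], -0.49)
  # no flanking information at all gives the neutral expectation 0
  g3 <- make_geno(rbind(c(NA, NA), c("AC", "AC")), cM = c(0, 5))
  pr3 <- encode_predictors(g3)
  expect_equal(pr3$xa[1, ], c(0, 0), ignore_attr = TRUE)
})

test_that("covariance-structure selection identifies the generating model", {
  set.seed(31)
  n <- 300; E <- 6
  envs <- paste0("S", 1:E, ":2016")
  # heteroscedastic diagonal truth is never called identity
  hits <- replicate(20, {
    Y <- sapply(seq_len(E), function(e) rnorm(n, 0, sqrt(e)))
    colnames(Y) <- envs; rownames(Y) <- sprintf("g%03d", 1:n)
    select_covariance(make_pheno(Y))$structure
  })
  expect_gte(mean(hits %in% c("diag", "un")), 0.95)

  # isotropic truth keeps identity within 2 BIC of the winner
  Y <- matrix(rnorm(n * E), n, E, dimnames = list(sprintf("g%03d", 1:n), envs))
  cv <- select_covariance(make_pheno(Y))
  bic <- cv$bic
  expect_lt(bic$bic[bic$structure == "id"] - min(bic$bic), 2)

  # the fitted unstructured matrix is symmetric positive-definite
  cvu <- select_covariance(make_pheno(Y), structures = "un")
  expect_equal(cvu$sigma, t(cvu$sigma))
  expect_gt(min(eigen(cvu$sigma, symmetric = TRUE)$values), 0)
})

test_that("effective test count follows the eigenvalue formula", {
  # hand eigen-decomposition: correlation 0.5 -> eigenvalues 1.5, 0.5
  expect_equal(meff_li_ji(matrix(c(1, .5, .5, 1), 2)), 2)
  expect_equal(meff_li_ji(diag(6)), 6)
  expect_equal(meff_li_ji(matrix(1, 5, 5)), 1)
  # eigenvalue 1.5 contributes 1 + 0.5; eigenvalue 0.5 contributes 0.5
  lam <- eigen(matrix(c(1, .5, .5, 1), 2))$values
  expect_equal(sum((lam >= 1) + (lam - floor(lam))), 2)
})

test_that("GLS scan equals per-environment OLS under identity covariance", {
  set.seed(41)
  d <- demo_cross_design(150, 1, 30, 8)
  g <- sim_fourway_genotypes(d, seed = 51)
  env <- demo_env_design(2, 2016, sigma2 = 1, rho = 0)
  ph <- sim_phenotypes(g, true_qtl("Q", "chr1", 10, env$envs$env, a = 0.8),
                       env, seed = 52)
  preds <- encode_predictors(g)
  bl <- select_covariance(ph, structures = "id")
  sc <- sim_scan(ph, preds, bl)
  # manual: per-env OLS joint chi-square summed across environments
  Y <- tidyr::pivot_wider(ph[, c("genotype", "env", "value")],
                          names_from = "env", values_from = "value")
  Ym <- as.matrix(Y[, -1]); rownames(Ym) <- Y$genotype
  Ym <- Ym[rownames(g$geno), bl$envs]
  s2 <- bl$sigma[1, 1]
  j <- 3
  Z <- cbind(1, preds$xa[, j], preds$xa2[, j], preds$xd[, j])
  W_manual <- sum(vapply(1:2, function(e) {
    b <- solve(crossprod(Z), crossprod(Z, Ym[, e]))
    V <- solve(crossprod(Z)) * s2
    drop(t(b[-1]) %*% solve(V[-1, -1], b[-1]))
  }, numeric(1)))
  # the scan deflates the Wald statistic for covariance estimation
  n_g <- nrow(Ym); E <- 2
  expect_equal(sc$wald[j], W_manual * (n_g - E - 2) / (n_g - 1),
               tolerance = 1e-8)

  # profile invariant to environment relabeling
  ph2 <- dplyr::mutate(ph, env = ifelse(env == env[1], "zzz", env))
  bl2 <- select_covariance(ph2, structures = "id")
  sc2 <- sim_scan(ph2, preds, bl2)
  expect_equal(sc$wald, sc2$wald, tolerance = 1e-10)
})

test_that("stronger QTL never weaken their own peak (same noise seed)", {
  d <- demo_cross_design(200, 1, 21, 20)
  g <- sim_fourway_genotypes(d, seed = 61)
  env <- demo_env_design(4, 2016)
  preds <- encode_predictors(g)
  peaks <- vapply(c(0.3, 0.6, 1.2), function(a) {
    ph <- sim_phenotypes(g, true_qtl("Q", "chr1", 10, env$envs$env, a = a),
                         env, seed = 62)
    bl <- select_covariance(ph, structures = "un")
    max(sim_scan(ph, preds, bl)$neglog10p)
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("peak selection honours the 30-cM separation rule", {
  prof <- tibble::tibble(
    pos = c("p1", "p2", "p3"), chrom = "c1", cM = c(10, 30, 80),
    wald = c(60, 50, 40), df = 3,
    p = c(1e-10, 1e-8, 1e-6), skipped = FALSE,
    neglog10p = c(10, 8, 6)
  )
  sel <- qtlscape:::select_peaks(prof, threshold = 1e-4, min_sep_cM = 30)
  # p2 is 20 cM from the stronger p1: suppressed; p3 is kept
  expect_setequal(sel$pos, c("p1", "p3"))
})

test_that("CIM separates linked QTL and stabilises", {
  d <- cross_design(425, tibble::tibble(chrom = "chr1", length_cM = 100,
                                        n_markers = 50))
  g <- sim_fourway_genotypes(d, seed = 71)
  env <- demo_env_design(5, 2016)
  qtls <- dplyr::bind_rows(
    true_qtl("Q1", "chr1", 10, env$envs$env, a = 0.7),
    true_qtl("Q2", "chr1", 90, env$envs$env, a = -0.7)
  )
  ph <- sim_phenotypes(g, qtls, env, seed = 72)
  preds <- encode_predictors(g)
  bl <- select_covariance(ph, structures = "un")
  thr <- effective_tests(preds)
  cim <- cim_scan(ph, preds, bl, thr$threshold)
  expect_gte(nrow(cim$qtl), 2)
  expect_true(any(abs(cim$qtl$cM - 10) < 15))
  expect_true(any(abs(cim$qtl$cM - 90) < 15))
  expect_true(cim$stable)
})

test_that("backward selection separates stable from crossing QTL effects", {
  d <- demo_cross_design(300, 1, 21, 20)
  g <- sim_fourway_genotypes(d, seed = 81)
  env <- demo_env_design(5, 2016)
  envs <- env$envs$env
  preds <- encode_predictors(g)
  qpos <- preds$positions$pos[10]

  # constant effect: interaction dropped, main retained, estimate near truth
  ph_c <- sim_phenotypes(g, true_qtl("Q", "chr1", g$map$cM[10], envs, a = 0.6),
                         env, seed = 82)
  bl <- select_covariance(ph_c, structures = "un")
  fit_c <- fit_final_model(ph_c, preds, qpos, bl)
  eff_a <- dplyr::filter(fit_c$effects, term == "a")
  expect_false(any(eff_a$gxe))
  expect_true(all(eff_a$retained))
  expect_lt(abs(eff_a$estimate[1] - 0.6), 2 * eff_a$se[1] + 0.05)

  # sign-flipping effect: interaction retained
  a_flip <- c(0.8, 0.8, 0, -0.8, -0.8)
  ph_f <- sim_phenotypes(g, true_qtl("Q", "chr1", g$map$cM[10], envs,
                                     a = a_flip), env, seed = 83)
  bl_f <- select_covariance(ph_f, structures = "un")
  fit_f <- fit_final_model(ph_f, preds, qpos, bl_f)
  eff_fa <- dplyr::filter(fit_f$effects, term == "a")
  expect_true(all(eff_fa$gxe))
  expect_equal(cor(eff_fa$estimate, a_flip), 1, tolerance = 0.1)
})

test_that("effect-table standard errors shrink with sample size", {
  d <- demo_cross_design(400, 1, 21, 15)
  g <- sim_fourway_genotypes(d, seed = 91)
  env <- demo_env_design(4, 2016)
  ph <- sim_phenotypes(g, true_qtl("Q", "chr1", 10, env$envs$env, a = 0.5),
                       env, seed = 92)
  preds <- encode_predictors(g)
  qpos <- preds$positions$pos[8]
  get_se <- function(ids) {
    sub <- ph[ph$genotype %in% ids, ]
    bl <- select_covariance(sub, structures = "un")
    f <- fit_final_model(sub, preds, qpos, bl)
    mean(dplyr::filter(f$effects, term == "a")$se)
  }
  ids <- rownames(g$geno)
  se_full <- get_se(ids)
  se_half <- get_se(ids[1:200])
  expect_gt(se_half / se_full, 1.15)  # ~ sqrt(2) expected
})

test_that("tidiers expose scan and fit results as tibbles", {
  d <- demo_cross_design(120, 1, 21, 10)
  g <- sim_fourway_genotypes(d, seed = 95)
  env <- demo_env_design(3, 2016)
  ph <- sim_phenotypes(g, true_qtl("Q", "chr1", 10, env$envs$env, a = 1),
                       env, seed = 96)
  preds <- encode_predictors(g)
  bl <- select_covariance(ph, structures = "un")
  sc <- sim_scan(ph, preds, bl)
  expect_s3_class(tidy(sc), "tbl_df")
  expect_named(tidy(bl), c("structure", "logLik", "k", "bic", "selected"))
  fit <- fit_final_model(ph, preds, preds$positions$pos[5], bl)
  expect_s3_class(tidy(fit), "tbl_df")
  g1 <- glance(fit)
  expect_equal(g1$n_qtl, 1)
  expect_s3_class(autoplot(sc), "ggplot")
  expect_s3_class(autoplot(fit), "ggplot")
})
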