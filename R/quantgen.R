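#' Marker-based additive relationship matrix
#'
#' Builds the column-centered score matrix from the per-marker first-cross
#' (+/-0.5 for A vs B) and second-cross (C vs D) additive codes and returns
#' `K = W W'` scaled so the mean diagonal equals 1. Missing calls are set to
#' the marker mean (zero after centering); constant markers are dropped.
#'
#' @param g A `fourway_geno`.
#' @return A `kinship` matrix (progeny x progeny).
#' @export
kinship_additive <- function(g) {
  stopifnot(inherits(g, "fourway_geno"))
  assert_that(ncol(g$geno) >= 2, "need at least 2 markers")
  xa <- code_ab(g$geno) / 2
  xa2 <- code_cd(g$geno) / 2
  W <- cbind(xa, xa2)
  W <- scale(W, center = TRUE, scale = FALSE)
  W[is.na(W)] <- 0
  keep <- apply(W, 2, function(x) any(x != 0))
  W <- W[, keep, drop = FALSE]
  K <- tcrossprod(W)
  K <- K / mean(diag(K))
  rownames(K) <- colnames(K) <- rownames(g$geno)
  K
}

# REML profile log-likelihood machinery for y = mu + u + e, u ~ N(0, K sA2),
# on the eigenbasis of K (EMMA-style single-parameter optimization).
reml_kinship <- function(y, eigK) {
  n <- length(y)
  yt <- drop(crossprod(eigK$vectors, y))
  xt <- drop(crossprod(eigK$vectors, rep(1, n)))
  D <- pmax(eigK$values, 0)
  ll <- function(loglam) {
    lam <- exp(loglam)
    v <- lam * D + 1
    xx <- sum(xt^2 / v)
    beta <- sum(xt * yt / v) / xx
    r <- yt - xt * beta
    q <- sum(r^2 / v)
    s2 <- q / (n - 1)
    -0.5 * (sum(log(v)) + log(xx) + (n - 1) * (log(s2) + 1))
  }
  op <- stats::optimize(function(z) -ll(z), c(-14, 14))
  lam <- exp(op$minimum)
  v <- lam * D + 1
  xx <- sum(xt^2 / v)
  beta <- sum(xt * yt / v) / xx
  s2e <- sum((yt - xt * beta)^2 / v) / (n - 1)
  boundary <- op$minimum < -13.5 || op$minimum > 13.5
  # curvature-based SE of h2 = lam / (1 + lam)
  h <- 1e-3
  d2 <- (-ll(op$minimum + h) + 2 * ll(op$minimum) - ll(op$minimum - h)) / h^2
  se_loglam <- if (is.finite(d2) && d2 > 0) sqrt(1 / d2) else NA_real_
  h2 <- lam / (1 + lam)
  se_h2 <- if (!is.na(se_loglam)) se_loglam * lam / (1 + lam)^2 else NA_real_
  list(h2 = h2, sigma_a2 = lam * s2e, sigma_e2 = s2e,
       boundary = boundary, se = se_h2)
}

#' Narrow-sense heritability from a kinship matrix
#'
#' REML fit of `y = X beta + Z u + e` with `u ~ N(0, K sigma_A^2)`;
#' `h^2 = sigma_A^2 / (sigma_A^2 + sigma_e^2)`, i.e. additive variance over
#' total phenotypic variance on the genotype-mean scale.
#'
#' @param pheno Long phenotype tibble (one value per genotype x env).
#' @param K Kinship from [kinship_additive()] (a small ridge is applied when
#'   needed for positive semidefiniteness).
#' @param mode `"per_env"` (default) fits each environment separately;
#'   `"pooled"` uses each genotype's mean across environments.
#' @return Tibble: trait, env, h2, se, sigma_a2, sigma_e2, boundary.
#' @export
estimate_h2 <- function(pheno, K, mode = c("per_env", "pooled")) {
  mode <- match.arg(mode)
  eigK <- eigen(K, symmetric = TRUE)
  groups <- if (mode == "per_env") {
    pheno |> dplyr::group_split(.data$trait, .data$env)
  } else {
    pheno |>
      dplyr::group_by(.data$genotype, .data$trait) |>
      dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                       .groups = "drop") |>
      dplyr::mutate(env = "pooled") |>
      dplyr::group_split(.data$trait)
  }
  purrr::map(groups, function(d) {
    ids <- intersect(rownames(K), d$genotype[!is.na(d$value)])
    y <- d$value[match(ids, d$genotype)]
    sub <- match(ids, rownames(K))
    eig <- if (length(ids) == nrow(K)) eigK else
      eigen(K[sub, sub], symmetric = TRUE)
    fit <- reml_kinship(y, eig)
    tibble::tibble(trait = d$trait[1], env = d$env[1], h2 = fit$h2,
                   se = fit$se, sigma_a2 = fit$sigma_a2,
                   sigma_e2 = fit$sigma_e2, boundary = fit$boundary)
  }) |> dplyr::bind_rows()
}

#' Genetic correlation between two environments
#'
#' Bivariate REML with an additive genetic (co)variance structured by the
#' kinship matrix and environment-specific residual variances, fitted by
#' direct likelihood optimization on the kinship eigenbasis over
#' `(sigma_A1^2, sigma_A2^2, r_G, sigma_e1^2, sigma_e2^2)` with a
#' positive-definite reparameterization. The genetic correlation
#' `r_G = sigma_A12 / sqrt(sigma_A1^2 sigma_A2^2)` is clamped to `[-1, 1]`.
#'
#' @param pheno Long phenotype tibble.
#' @param K Kinship matrix.
#' @param env_pair Character vector of two environment ids.
#' @param trait Trait when several are present.
#' @return One-row tibble: env1, env2, r_g, sigma_a1, sigma_a2, sigma_a12,
#'   convergence, flagged (TRUE when either genetic variance is near zero).
#' @export
genetic_correlation <- function(pheno, K, env_pair, trait = NULL) {
  assert_that(length(env_pair) == 2, "env_pair must name two environments")
  if (!is.null(trait)) pheno <- pheno[pheno$trait == trait, ]
  Y <- pheno_wide(pheno)
  assert_that(all(env_pair %in% colnames(Y)),
              "both environments must be phenotyped")
  Y <- Y[, env_pair]
  cc <- stats::complete.cases(Y)
  ids <- intersect(rownames(Y)[cc], rownames(K))
  Y <- Y[ids, ]
  sub <- match(ids, rownames(K))
  eig <- eigen(K[sub, sub, drop = FALSE], symmetric = TRUE)
  n <- length(ids)
  D <- pmax(eig$values, 0)
  Yt <- crossprod(eig$vectors, Y)
  xt <- drop(crossprod(eig$vectors, rep(1, n)))

  nll <- function(th) {
    a1 <- exp(th[1]); a2 <- exp(th[2]); rg <- tanh(th[3])
    e1 <- exp(th[4]); e2 <- exp(th[5])
    c11 <- D * a1 + e1
    c22 <- D * a2 + e2
    c12 <- D * rg * sqrt(a1 * a2)
    det <- c11 * c22 - c12^2
    if (any(det <= 0)) return(1e10)
    i11 <- c22 / det; i22 <- c11 / det; i12 <- -c12 / det
    # GLS intercepts per trait
    A11 <- sum(xt^2 * i11); A22 <- sum(xt^2 * i22); A12 <- sum(xt^2 * i12)
    b1 <- sum(xt * (i11 * Yt[, 1] + i12 * Yt[, 2]))
    b2 <- sum(xt * (i12 * Yt[, 1] + i22 * Yt[, 2]))
    detA <- A11 * A22 - A12^2
    if (detA <= 0) return(1e10)
    mu1 <- (A22 * b1 - A12 * b2) / detA
    mu2 <- (A11 * b2 - A12 * b1) / detA
    r1 <- Yt[, 1] - xt * mu1
    r2 <- Yt[, 2] - xt * mu2
    quad <- sum(i11 * r1^2 + 2 * i12 * r1 * r2 + i22 * r2^2)
    0.5 * (sum(log(det)) + quad + log(detA))
  }

  v1 <- stats::var(Y[, 1]); v2 <- stats::var(Y[, 2])
  r0 <- stats::cor(Y[, 1], Y[, 2])
  th0 <- c(log(v1 / 2), log(v2 / 2), atanh(min(max(r0, -0.9), 0.9)),
           log(v1 / 2), log(v2 / 2))
  op <- stats::optim(th0, nll, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-10))
  a1 <- exp(op$par[1]); a2 <- exp(op$par[2]); rg <- tanh(op$par[3])
  flagged <- a1 < 1e-4 * v1 || a2 < 1e-4 * v2
  if (flagged) rg <- NA_real_
  tibble::tibble(
    env1 = env_pair[1], env2 = env_pair[2],
    r_g = pmin(pmax(rg, -1), 1),
    sigma_a1 = a1, sigma_a2 = a2, sigma_a12 = rg * sqrt(a1 * a2),
    convergence = op$convergence == 0, flagged = flagged
  )
}

#' All pairwise genetic correlations
#'
#' @param pheno,K,trait As in [genetic_correlation()].
#' @param max_pairs Optional cap on the number of environment pairs.
#' @return Tibble of pairwise fits.
#' @export
genetic_correlations <- function(pheno, K, trait = NULL, max_pairs = Inf) {
  envs <- sort(unique(pheno$env))
  pairs <- utils::combn(envs, 2, simplify = FALSE)
  if (length(pairs) > max_pairs) pairs <- pairs[seq_len(max_pairs)]
  purrr::map(pairs, function(ep) {
    genetic_correlation(pheno, K, ep, trait)
  }) |> dplyr::bind_rows()
}
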