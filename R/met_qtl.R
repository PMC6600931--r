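#' Average replicate phenotype observations
#'
#' Collapses a long phenotype table to one value per genotype x site x year
#' (x trait): the mean of replicates.
#'
#' @param pheno Long tibble with genotype, site, year, trait, value (an `env`
#'   column is rebuilt as `site:year`).
#' @return Tibble with one row per genotype x environment x trait.
#' @export
average_replicates <- function(pheno) {
  pheno |>
    dplyr::group_by(.data$genotype, .data$site, .data$year, .data$trait) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop") |>
    dplyr::mutate(env = paste(.data$site, .data$year, sep = ":")) |>
    dplyr::select("genotype", "site", "year", "env", "trait", "value")
}

#' Cull outlier phenotype observations
#'
#' Fits `value ~ line + site + line:site` (lines = genotypes) across years,
#' so the year replication provides residual degrees of freedom, and drops
#' observations whose externally studentized residual has a Bonferroni
#' corrected two-sided t-tail probability below `alpha`. With full
#' interaction the fit reduces to genotype x site cell means, which is used
#' directly. Cells with a single observation are saturated and skipped.
#'
#' @param pheno Long tibble (one value per genotype x site x year x trait).
#' @param alpha Family-wise error rate (default 0.05).
#' @return The table with outliers removed; attribute `"n_culled"` reports
#'   the per-trait cull counts.
#' @export
cull_outliers <- function(pheno, alpha = 0.05) {
  culled <- integer()
  out <- pheno |>
    dplyr::group_split(.data$trait) |>
    purrr::map(function(d) {
      tr <- d$trait[1]
      cell <- paste(d$genotype, d$site, sep = "\r")
      ncell <- stats::ave(d$value, cell, FUN = length)
      if (all(ncell == 1)) {
        warning("trait ", tr,
                ": one observation per genotype x site cell; outlier model ",
                "is saturated, skipping")
        culled[tr] <<- 0L
        return(d)
      }
      fitted <- stats::ave(d$value, cell)
      e <- d$value - fitted
      testable <- ncell > 1
      nu <- sum(testable) - length(unique(cell[testable]))
      if (nu < 3) {
        warning("trait ", tr, ": too few residual df for outlier culling")
        culled[tr] <<- 0L
        return(d)
      }
      s2 <- sum(e[testable]^2) / nu
      r <- e / sqrt(s2 * (1 - 1 / ncell))
      r[!testable] <- 0
      # externally studentized
      tval <- r * sqrt((nu - 1) / pmax(nu - r^2, 1e-12))
      ntest <- sum(testable)
      p <- 2 * stats::pt(-abs(tval), nu - 1)
      drop <- testable & (p * ntest < alpha)
      culled[tr] <<- sum(drop)
      d[!drop, ]
    }) |>
    dplyr::bind_rows()
  attr(out, "n_culled") <- culled
  out
}

# long phenotype tibble (single trait) -> genotype x environment matrix
pheno_wide <- function(pheno, trait = NULL) {
  if (!is.null(trait)) pheno <- pheno[pheno$trait == trait, ]
  if (length(unique(pheno$trait)) > 1) {
    stop("phenotype table contains several traits; pick one via `trait`")
  }
  wide <- tidyr::pivot_wider(
    pheno[, c("genotype", "env", "value")],
    names_from = "env", values_from = "value"
  )
  Y <- as.matrix(wide[, -1])
  rownames(Y) <- wide$genotype
  Y
}

#' Encode per-parent additive and dominance predictors
#'
#' At a marker, `x_a = +0.5` if the first-cross allele is A (else -0.5),
#' `x_a2 = +0.5` if the second-cross allele is C (else -0.5), and
#' `x_d = 2 x_a x_a2`, so each additive estimate equals the full allele
#' substitution effect. Missing calls (and grid pseudopositions when
#' `step_cM > 0`) are replaced by their conditional expectations given the
#' nearest non-missing flanking markers under Haldane transition
#' probabilities; with no information the expectation is 0.
#'
#' @param g A `fourway_geno`.
#' @param map Optional map tibble (marker, chrom-or-linkage_group, cM);
#'   defaults to `g$map`.
#' @param step_cM Pseudomarker grid step; 0 (default) scans at markers only.
#' @return A `qtl_predictors` object: matrices `$xa`, `$xa2`, `$xd`
#'   (progeny x position) and `$positions` (tibble: pos, chrom, cM, marker).
#' @export
encode_predictors <- function(g, map = NULL, step_cM = 0) {
  stopifnot(inherits(g, "fourway_geno"))
  map <- map %||% g$map
  if ("linkage_group" %in% names(map) && !"chrom" %in% names(map)) {
    map$chrom <- paste0("LG", map$linkage_group)
  }
  map <- map[map$marker %in% colnames(g$geno), ]
  n <- nrow(g$geno)
  blocks <- map |> dplyr::group_split(.data$chrom)
  xa_l <- list(); xa2_l <- list(); pos_l <- list()
  for (blk in blocks) {
    blk <- blk[order(blk$cM), ]
    mk <- blk$marker
    mcM <- blk$cM
    if (step_cM > 0) {
      pos <- sort(unique(c(mcM, seq(min(mcM), max(mcM), by = step_cM))))
    } else {
      pos <- mcM
    }
    sab <- code_ab(g$geno[, mk, drop = FALSE])
    scd <- code_cd(g$geno[, mk, drop = FALSE])
    xa_l[[length(xa_l) + 1L]] <- expected_allele(sab, mcM, pos)
    xa2_l[[length(xa2_l) + 1L]] <- expected_allele(scd, mcM, pos)
    pos_l[[length(pos_l) + 1L]] <- tibble::tibble(
      chrom = blk$chrom[1], cM = pos,
      marker = mk[match(pos, mcM)]
    )
  }
  xa <- do.call(cbind, xa_l)
  xa2 <- do.call(cbind, xa2_l)
  positions <- dplyr::bind_rows(pos_l)
  positions$pos <- ifelse(is.na(positions$marker),
                          sprintf("%s@%.1f", positions$chrom, positions$cM),
                          positions$marker)
  colnames(xa) <- colnames(xa2) <- positions$pos
  rownames(xa) <- rownames(xa2) <- rownames(g$geno)
  structure(
    list(xa = xa, xa2 = xa2, xd = 2 * xa * xa2,
         positions = dplyr::select(positions, "pos", "chrom", "cM", "marker")),
    class = "qtl_predictors"
  )
}

# E[x | flanking states] for one haplotype: s is n x m matrix of +1/-1/NA
# states at marker positions mcM; returns n x length(pos) expected +/-0.5
expected_allele <- function(s, mcM, pos) {
  n <- nrow(s); m <- ncol(s); P <- length(pos)
  # nearest non-missing marker index at or left of each position, per progeny
  Lidx <- matrix(0L, n, P); Ridx <- matrix(0L, n, P)
  last <- integer(n)  # 0 = none yet
  mi <- 1L
  for (j in seq_len(P)) {
    while (mi <= m && mcM[mi] <= pos[j] + 1e-9) {
      obs <- !is.na(s[, mi])
      last[obs] <- mi
      mi <- mi + 1L
    }
    Lidx[, j] <- last
  }
  nxt <- integer(n)
  mi <- m
  for (j in rev(seq_len(P))) {
    while (mi >= 1L && mcM[mi] >= pos[j] - 1e-9) {
      obs <- !is.na(s[, mi])
      nxt[obs] <- mi
      mi <- mi - 1L
    }
    Ridx[, j] <- nxt
  }
  out <- matrix(0, n, P)
  for (j in seq_len(P)) {
    li <- Lidx[, j]; ri <- Ridx[, j]
    sl <- ifelse(li > 0, s[cbind(seq_len(n), pmax(li, 1L))], NA)
    sr <- ifelse(ri > 0, s[cbind(seq_len(n), pmax(ri, 1L))], NA)
    rl <- ifelse(li > 0, haldane_r(pos[j] - mcM[pmax(li, 1L)]), NA)
    rr <- ifelse(ri > 0, haldane_r(mcM[pmax(ri, 1L)] - pos[j]), NA)
    # P(allele = +1 | flanks), proportional to transition probabilities
    wp <- ifelse(is.na(sl), 1, ifelse(sl > 0, 1 - rl, rl)) *
      ifelse(is.na(sr), 1, ifelse(sr > 0, 1 - rr, rr))
    wm <- ifelse(is.na(sl), 1, ifelse(sl > 0, rl, 1 - rl)) *
      ifelse(is.na(sr), 1, ifelse(sr > 0, rr, 1 - rr))
    p <- wp / (wp + wm)
    p[is.na(sl) & is.na(sr)] <- 0.5
    out[, j] <- p - 0.5
  }
  out
}

# deflation factor undoing the mean bias of the inverted sample covariance
wishart_correction <- function(n, E) {
  if (n > E + 2) (n - E - 2) / (n - 1) else 1
}

reml_ll_mvn <- function(S, sigma, n) {
  # REML log-likelihood (up to a shared constant) for column-mean model
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdet <- 2 * sum(log(diag(ch)))
  -0.5 * (n - 1) * (logdet + sum(diag(chol2inv(ch) %*% S)))
}

#' Select the cross-environment residual covariance structure
#'
#' Fits the multi-environment baseline model (fixed environment means; the
#' genotype and genotype-by-environment random terms absorbed into a single
#' environments x environments covariance of each genotype's record vector)
#' by REML under candidate structures identity, diagonal, compound symmetry
#' and unstructured, and keeps the lowest-BIC structure.
#'
#' @param pheno Long tibble (one trait) with one value per genotype x env.
#' @param trait Trait to use when several are present.
#' @param structures Candidate structures to compare.
#' @return A `met_covariance` object: `$structure`, `$sigma`, `$bic`
#'   (tibble), `$envs`, `$n`.
#' @export
select_covariance <- function(pheno, trait = NULL,
                              structures = c("id", "diag", "cs", "un")) {
  Y <- pheno_wide(pheno, trait)
  cc <- stats::complete.cases(Y)
  if (!all(cc)) {
    warning(sum(!cc), " genotypes with incomplete environment records dropped")
    Y <- Y[cc, , drop = FALSE]
  }
  n <- nrow(Y); E <- ncol(Y)
  assert_that(E >= 2, "need at least 2 environments")
  S <- stats::cov(Y)
  fits <- list()
  if ("id" %in% structures) {
    s2 <- mean(diag(S))
    fits$id <- list(sigma = diag(s2, E), k = 1)
  }
  if ("diag" %in% structures) {
    fits$diag <- list(sigma = diag(diag(S), E), k = E)
  }
  if ("cs" %in% structures) {
    prof <- function(rho) {
      A <- (1 - rho) * diag(E) + rho
      Ainv <- chol2inv(chol(A))
      s2 <- sum(diag(Ainv %*% S)) / E
      ll <- reml_ll_mvn(S, s2 * A, n)
      list(ll = ll, sigma = s2 * A)
    }
    op <- stats::optimize(function(rho) -prof(rho)$ll,
                          c(-1 / (E - 1) + 1e-4, 1 - 1e-4))
    fits$cs <- list(sigma = prof(op$minimum)$sigma, k = 2)
  }
  if ("un" %in% structures) {
    sig <- S
    ev <- eigen(sig, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-8 * max(ev)) {
      warning("unstructured covariance update not positive-definite; ",
              "ridge-stabilized")
      sig <- sig + diag(1e-6 * mean(diag(sig)), E)
    }
    fits$un <- list(sigma = sig, k = E * (E + 1) / 2)
  }
  bic <- purrr::imap(fits, function(f, nm) {
    ll <- reml_ll_mvn(S, f$sigma, n)
    tibble::tibble(structure = nm, logLik = ll, k = f$k,
                   bic = -2 * ll + f$k * log(n))
  }) |> dplyr::bind_rows()
  best <- bic$structure[which.min(bic$bic)]
  structure(
    list(structure = best, sigma = fits[[best]]$sigma,
         bic = bic, envs = colnames(Y), n = n),
    class = "met_covariance"
  )
}

#' @export
print.met_covariance <- function(x, ...) {
  cat("<met_covariance> selected: ", x$structure, " over ",
      length(x$envs), " environments (n = ", x$n, ")\n", sep = "")
  print(x$bic)
  invisible(x)
}

# align phenotype matrix with predictor rows; complete cases only
align_scan_data <- function(pheno, preds, trait, baseline) {
  Y <- pheno_wide(pheno, trait)
  if (!is.null(baseline)) Y <- Y[, baseline$envs, drop = FALSE]
  ids <- intersect(rownames(Y), rownames(preds$xa))
  Y <- Y[ids, , drop = FALSE]
  cc <- stats::complete.cases(Y)
  if (!all(cc)) {
    warning(sum(!cc), " genotypes with incomplete records dropped from scan")
    Y <- Y[cc, , drop = FALSE]
    ids <- ids[cc]
  }
  list(Y = Y, ids = ids)
}

#' Genome scan by simple interval mapping under the baseline covariance
#'
#' At each position the per-parent additive and dominance predictors and
#' their environment interactions enter the multi-environment model as fixed
#' effects; the profile value is the -log10 P of the joint Wald test of all
#' QTL terms, computed by generalized least squares with the baseline
#' covariance held fixed. Because the QTL design is shared by all
#' environments, the GLS coefficient estimates coincide with per-environment
#' least squares, and the covariance enters through the Wald statistic.
#'
#' @param pheno Long tibble (one value per genotype x env).
#' @param preds A `qtl_predictors`.
#' @param baseline A `met_covariance` from [select_covariance()].
#' @param trait Trait to scan when several are present.
#' @param include_dominance Include the dominance term (default TRUE).
#' @param cofactors Optional position ids used as background cofactors; at
#'   each tested position only cofactors at least `cofactor_prox_cM` away (or
#'   on another chromosome) are included.
#' @param cofactor_prox_cM Minimum cofactor proximity (default 50 cM).
#' @return A `qtl_scan` tibble: pos, chrom, cM, wald, df, p, neglog10p.
#' @export
sim_scan <- function(pheno, preds, baseline, trait = NULL,
                     include_dominance = TRUE, cofactors = NULL,
                     cofactor_prox_cM = 50) {
  stopifnot(inherits(preds, "qtl_predictors"),
            inherits(baseline, "met_covariance"))
  dat <- align_scan_data(pheno, preds, trait, baseline)
  Y <- dat$Y
  n <- nrow(Y)
  siginv <- chol2inv(chol(baseline$sigma))
  P <- nrow(preds$positions)
  idx <- match(dat$ids, rownames(preds$xa))
  cof_info <- NULL
  if (length(cofactors)) {
    cof_info <- preds$positions[match(cofactors, preds$positions$pos), ]
  }
  res <- purrr::map(seq_len(P), function(j) {
    Z <- cbind(1, preds$xa[idx, j], preds$xa2[idx, j])
    if (include_dominance) Z <- cbind(Z, preds$xd[idx, j])
    nq <- ncol(Z) - 1L
    if (length(cofactors)) {
      here <- preds$positions[j, ]
      far <- cof_info$chrom != here$chrom |
        abs(cof_info$cM - here$cM) >= cofactor_prox_cM
      for (cp in cof_info$pos[far]) {
        cj <- match(cp, preds$positions$pos)
        if (cj == j) next
        Z <- cbind(Z, preds$xa[idx, cj], preds$xa2[idx, cj],
                   preds$xd[idx, cj])
      }
    }
    ZtZ <- crossprod(Z)
    qr_z <- qr(ZtZ)
    if (qr_z$rank < ncol(Z)) {
      return(tibble::tibble(wald = NA_real_, df = NA_integer_,
                            p = NA_real_, skipped = TRUE))
    }
    C <- chol2inv(chol(ZtZ))
    B <- C %*% crossprod(Z, Y)
    qrows <- 2:(nq + 1L)
    Bq <- B[qrows, , drop = FALSE]
    Cqq <- C[qrows, qrows, drop = FALSE]
    W <- sum(solve(Cqq, Bq) * (Bq %*% siginv))
    # the covariance is estimated, not known: correct the Wald statistic for
    # the mean bias of the inverse sample covariance (E[S^-1] scales as
    # (n-1)/(n-E-2) for a Wishart S)
    W <- W * wishart_correction(n, ncol(Y))
    df <- nq * ncol(Y)
    tibble::tibble(wald = W, df = df,
                   p = stats::pchisq(W, df, lower.tail = FALSE),
                   skipped = FALSE)
  }) |> dplyr::bind_rows()
  if (any(res$skipped)) {
    warning(sum(res$skipped), " positions with collinear predictors skipped")
  }
  out <- dplyr::bind_cols(preds$positions[, c("pos", "chrom", "cM")], res)
  out$neglog10p <- -log10(pmax(out$p, 1e-300))
  class(out) <- c("qtl_scan", class(out))
  attr(out, "n") <- n
  out
}

#' Effective number of independent tests and genome-wide threshold
#'
#' The effective test count follows the eigenvalue decomposition of the
#' position-by-position predictor correlation matrix:
#' `M_eff = sum(I(lambda >= 1) + (lambda - floor(lambda)))`. The correlation
#' between positions averages the first-cross and second-cross additive
#' predictor correlations, which share the same linkage-driven decay. The
#' genome-wide threshold is `alpha / M_eff` (Bonferroni on effective tests).
#'
#' @param preds A `qtl_predictors`.
#' @param alpha Genome-wide significance level (default 0.05).
#' @return List: `m_eff`, `alpha`, `threshold`, `neglog10`.
#' @export
effective_tests <- function(preds, alpha = 0.05) {
  stopifnot(inherits(preds, "qtl_predictors"))
  assert_that(ncol(preds$xa) >= 2, "need at least 2 positions")
  C <- (stats::cor(preds$xa) + stats::cor(preds$xa2)) / 2
  C[is.na(C)] <- 0; diag(C) <- 1
  m_eff <- meff_li_ji(C)
  list(m_eff = m_eff, alpha = alpha, threshold = alpha / m_eff,
       neglog10 = -log10(alpha / m_eff))
}

#' Effective test count from a correlation matrix (Li-Ji estimator)
#'
#' @param C Correlation matrix.
#' @return Effective number of independent tests.
#' @export
meff_li_ji <- function(C) {
  lambda <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  lambda <- pmax(lambda, 0)
  sum((lambda >= 1) + (lambda - floor(lambda)))
}

# greedy peak selection: descending significance, ties by lower cM,
# minimum pairwise separation within a chromosome
select_peaks <- function(profile, threshold, min_sep_cM = 30) {
  cand <- profile[!is.na(profile$p) & profile$p <= threshold, ]
  cand <- cand[order(cand$p, cand$cM), ]
  sel <- cand[0, ]
  for (i in seq_len(nrow(cand))) {
    row <- cand[i, ]
    ok <- !any(sel$chrom == row$chrom & abs(sel$cM - row$cM) < min_sep_cM)
    if (ok) sel <- rbind(sel, row)
  }
  sel[order(sel$chrom, sel$cM), ]
}

#' Composite interval mapping with cofactor re-scanning
#'
#' Peaks above the genome-wide threshold, greedily selected in descending
#' significance subject to a minimum pairwise separation, become cofactors;
#' every position is then retested with all cofactors farther than
#' `cofactor_prox_cM` included as fixed background terms. Selection and
#' re-scanning repeat `rounds` times; the result records whether the
#' selected set was identical between the last two rounds ("stable").
#'
#' @param pheno,preds,baseline,trait,include_dominance As in [sim_scan()].
#' @param threshold Genome-wide P threshold (e.g. from [effective_tests()]).
#' @param min_sep_cM Minimum separation of selected QTL (default 30 cM).
#' @param cofactor_prox_cM Minimum cofactor proximity (default 50 cM).
#' @param rounds Consecutive CIM rounds (default 3).
#' @return List: `profile` (final `qtl_scan`), `qtl` (selected peaks),
#'   `stable`, `rounds` (per-round selections).
#' @export
cim_scan <- function(pheno, preds, baseline, threshold, trait = NULL,
                     include_dominance = TRUE, min_sep_cM = 30,
                     cofactor_prox_cM = 50, rounds = 3) {
  profile <- sim_scan(pheno, preds, baseline, trait, include_dominance)
  sel <- select_peaks(profile, threshold, min_sep_cM)
  history <- list(sel$pos)
  for (r in seq_len(rounds)) {
    if (nrow(sel) == 0) break
    profile <- sim_scan(pheno, preds, baseline, trait, include_dominance,
                        cofactors = sel$pos,
                        cofactor_prox_cM = cofactor_prox_cM)
    sel <- select_peaks(profile, threshold, min_sep_cM)
    history[[length(history) + 1L]] <- sel$pos
  }
  nh <- length(history)
  stable <- nh >= 2 && identical(history[[nh]], history[[nh - 1]])
  list(profile = profile, qtl = sel, stable = stable, rounds = history)
}

# build the whitened fixed-effect design for the final multi-QTL model.
# Terms: environment means; per QTL x contrast a main effect and (E-1)
# interaction contrasts. Returns design pieces for group-wise Wald tests.
build_final_design <- function(Y, preds, qtl_pos, idx, include_dominance) {
  n <- nrow(Y); E <- ncol(Y)
  terms <- c("a", "a2", if (include_dominance) "d")
  xmat <- list(a = preds$xa, a2 = preds$xa2, d = preds$xd)
  cols <- list(); groups <- list()
  # environment means
  for (e in seq_len(E)) {
    v <- matrix(0, E, n); v[e, ] <- 1
    cols[[length(cols) + 1L]] <- v
  }
  groups[["env"]] <- seq_len(E)
  for (q in qtl_pos) {
    j <- match(q, preds$positions$pos)
    for (tm in terms) {
      x <- xmat[[tm]][idx, j]
      main <- matrix(rep(x, each = E), E, n)
      cols[[length(cols) + 1L]] <- main
      groups[[paste(q, tm, "main", sep = "|")]] <- length(cols)
      start <- length(cols)
      for (e in 2:E) {
        v <- matrix(0, E, n); v[e, ] <- x
        cols[[length(cols) + 1L]] <- v
      }
      groups[[paste(q, tm, "gxe", sep = "|")]] <- start + seq_len(E - 1)
    }
  }
  list(cols = cols, groups = groups, terms = terms)
}

# GLS fit with fixed covariance via whitening; returns beta, V, logLik parts
gls_fit <- function(cols, keep_cols, Y, sigma) {
  E <- ncol(Y); n <- nrow(Y)
  Wh <- solve(t(chol(sigma)))  # whitener: Wh %*% sigma %*% t(Wh) = I
  Xw <- vapply(cols[keep_cols], function(v) as.vector(Wh %*% v),
               numeric(E * n))
  yw <- as.vector(Wh %*% t(Y))
  XtX <- crossprod(Xw)
  V <- chol2inv(chol(XtX))
  beta <- drop(V %*% crossprod(Xw, yw))
  resid_w <- yw - drop(Xw %*% beta)
  list(beta = beta, V = V, resid_w = resid_w)
}

#' Fit the final multi-QTL model with backward selection
#'
#' Fits the full model with all selected QTL (per-parent additive and
#' dominance main effects plus QTL x environment interactions) under the
#' selected covariance structure, then iteratively removes the least
#' significant term group with Wald P >= `alpha`, never removing a main
#' effect while its interaction remains. The covariance is re-estimated once
#' from full-model residuals before selection. Per-environment effects and
#' their standard errors are reported for every retained QTL.
#'
#' @param pheno Long tibble (one value per genotype x env).
#' @param preds A `qtl_predictors`.
#' @param qtl_pos Character vector of selected QTL position ids.
#' @param baseline A `met_covariance`.
#' @param trait Trait when several are present.
#' @param alpha Retention threshold for fixed terms (default 0.05).
#' @param include_dominance Include dominance terms (default TRUE).
#' @param reestimate Re-estimate the covariance from full-model residuals
#'   (default TRUE).
#' @return A `qtl_fit` object: `$effects` (tibble: qtl, env, term, estimate,
#'   se, p_gxe, gxe), `$dropped`, `$kept`, `$sigma`, `$wald`.
#' @export
fit_final_model <- function(pheno, preds, qtl_pos, baseline, trait = NULL,
                            alpha = 0.05, include_dominance = TRUE,
                            reestimate = TRUE) {
  assert_that(length(qtl_pos) >= 1, "QTL list is empty")
  dat <- align_scan_data(pheno, preds, trait, baseline)
  Y <- dat$Y
  idx <- match(dat$ids, rownames(preds$xa))
  n <- nrow(Y); E <- ncol(Y)
  des <- build_final_design(Y, preds, qtl_pos, idx, include_dominance)
  sigma <- baseline$sigma

  fit_with <- function(group_names, sigma) {
    keep <- sort(unique(unlist(des$groups[group_names])))
    f <- gls_fit(des$cols, keep, Y, sigma)
    # map kept column indices to positions in beta
    colpos <- stats::setNames(seq_along(keep), keep)
    group_idx <- lapply(des$groups[group_names], function(gi) {
      unname(colpos[as.character(gi)])
    })
    list(fit = f, keep = keep, group_idx = group_idx)
  }

  all_groups <- names(des$groups)
  active <- all_groups
  full <- fit_with(active, sigma)
  if (reestimate) {
    Rw <- matrix(full$fit$resid_w, E, n)
    # un-whiten to get residuals on the data scale, then re-estimate
    R <- t(t(chol(sigma)) %*% Rw)
    p_per_env <- length(full$keep) / E
    sigma2 <- crossprod(R) / max(n - p_per_env, E + 1)
    ev <- eigen(sigma2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 1e-10 * max(ev)) sigma <- sigma2
    full <- fit_with(active, sigma)
  }

  wald_group <- function(f, gname, group_idx) {
    gi <- group_idx[[gname]]
    b <- f$beta[gi]
    Vg <- f$fit$V[gi, gi, drop = FALSE]
    W <- drop(crossprod(b, solve(Vg, b))) * wishart_correction(n, E)
    stats::pchisq(W, length(gi), lower.tail = FALSE)
  }

  dropped <- character()
  cur <- full
  repeat {
    cand <- setdiff(active, "env")
    # a main effect is only removable once its interaction is gone
    removable <- purrr::keep(cand, function(gn) {
      if (!endsWith(gn, "|main")) return(TRUE)
      !sub("\\|main$", "|gxe", gn) %in% active
    })
    if (!length(removable)) break
    f <- list(beta = cur$fit$beta, fit = cur$fit)
    pvals <- vapply(removable, function(gn) wald_group(f, gn, cur$group_idx),
                    numeric(1))
    worst <- which.max(pvals)
    if (pvals[worst] < alpha) break
    dropped <- c(dropped, removable[worst])
    active <- setdiff(active, removable[worst])
    cur <- fit_with(active, sigma)
  }

  f <- list(beta = cur$fit$beta, fit = cur$fit)
  wald_tbl <- tibble::tibble(
    group = setdiff(active, "env"),
    p = vapply(setdiff(active, "env"),
               function(gn) wald_group(f, gn, cur$group_idx), numeric(1))
  )

  # per-environment effects: alpha_e = main + interaction_e (interaction
  # contrast of env 1 is 0 under treatment coding)
  effects <- purrr::map(qtl_pos, function(q) {
    purrr::map(des$terms, function(tm) {
      gmain <- paste(q, tm, "main", sep = "|")
      ggxe <- paste(q, tm, "gxe", sep = "|")
      est <- rep(0, E); se <- rep(NA_real_, E)
      p_gxe <- NA_real_
      has_main <- gmain %in% active
      has_gxe <- ggxe %in% active
      if (has_gxe) p_gxe <- wald_tbl$p[wald_tbl$group == ggxe]
      if (has_main || has_gxe) {
        nb <- length(cur$fit$beta)
        Cmat <- matrix(0, E, nb)
        if (has_main) Cmat[, cur$group_idx[[gmain]]] <- 1
        if (has_gxe) {
          gi <- cur$group_idx[[ggxe]]
          for (e in 2:E) Cmat[e, gi[e - 1]] <- 1
        }
        est <- drop(Cmat %*% cur$fit$beta)
        se <- sqrt(pmax(diag(Cmat %*% cur$fit$V %*% t(Cmat)), 0))
      }
      tibble::tibble(qtl = q, env = colnames(Y), term = tm,
                     estimate = est, se = se,
                     p_gxe = p_gxe, gxe = has_gxe,
                     retained = has_main || has_gxe)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  structure(
    list(effects = effects, dropped = dropped, kept = active,
         sigma = sigma, wald = wald_tbl, n = n, envs = colnames(Y)),
    class = "qtl_fit"
  )
}

#' @export
print.qtl_fit <- function(x, ...) {
  nq <- length(unique(x$effects$qtl))
  ngxe <- x$effects |>
    dplyr::distinct(.data$qtl, .data$term, .data$gxe) |>
    dplyr::summarise(any = sum(.data$gxe)) |> dplyr::pull()
  cat("<qtl_fit> ", nq, " QTL across ", length(x$envs),
      " environments; ", ngxe, " term(s) with retained QTLxE\n", sep = "")
  invisible(x)
}
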