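#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a genome scan
#'
#' @param x A `qtl_scan`.
#' @param ... Unused.
#' @return Tibble: pos, chrom, cM, wald, df, p, neglog10p.
#' @export
tidy.qtl_scan <- function(x, ...) {
  tibble::as_tibble(unclass(x))[, c("pos", "chrom", "cM", "wald", "df",
                                    "p", "neglog10p")]
}

#' Tidy a fitted multi-QTL model (per-environment effect table)
#'
#' @param x A `qtl_fit`.
#' @param ... Unused.
#' @return Tibble: qtl, env, term, estimate, se, p_gxe, gxe.
#' @export
tidy.qtl_fit <- function(x, ...) x$effects

#' One-row summary of a fitted multi-QTL model
#'
#' @param x A `qtl_fit`.
#' @param ... Unused.
#' @return Tibble: n_qtl, n_env, n_genotypes, n_gxe_terms, n_dropped.
#' @export
glance.qtl_fit <- function(x, ...) {
  gxe <- x$effects |>
    dplyr::distinct(.data$qtl, .data$term, .data$gxe)
  tibble::tibble(
    n_qtl = length(unique(x$effects$qtl)),
    n_env = length(x$envs),
    n_genotypes = x$n,
    n_gxe_terms = sum(gxe$gxe),
    n_dropped = length(x$dropped)
  )
}

#' Tidy the covariance-structure comparison
#'
#' @param x A `met_covariance`.
#' @param ... Unused.
#' @return The BIC tibble, flagged with the selected structure.
#' @export
tidy.met_covariance <- function(x, ...) {
  dplyr::mutate(x$bic, selected = .data$structure == x$structure)
}

#' One-row summary of the selected covariance structure
#'
#' @param x A `met_covariance`.
#' @param ... Unused.
#' @export
glance.met_covariance <- function(x, ...) {
  tibble::tibble(structure = x$structure, n_env = length(x$envs),
                 n_genotypes = x$n,
                 bic = x$bic$bic[x$bic$structure == x$structure])
}

#' Tidy a meta-regression fit (all candidate axes)
#'
#' @param x A `metareg_fit`.
#' @param ... Unused.
#' @return Per-axis tibble with the chosen axis flagged.
#' @export
tidy.metareg_fit <- function(x, ...) {
  dplyr::mutate(x$all_axes, chosen = .data$axis == x$axis)
}

#' One-row summary of a meta-regression fit
#'
#' @param x A `metareg_fit`.
#' @param ... Unused.
#' @export
glance.metareg_fit <- function(x, ...) {
  tibble::tibble(axis = x$axis, beta0 = x$beta0, beta1 = x$beta1,
                 se1 = x$se1, p = x$p, n_sites = nrow(x$data))
}
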