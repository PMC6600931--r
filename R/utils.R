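#' Haldane map function
#'
#' Convert a recombination fraction to a genetic distance in centimorgans
#' under the assumption of no crossover interference, and back.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @param d Genetic distance(s) in centimorgans.
#' @return `haldane_cm()` returns centimorgans; `haldane_r()` returns
#'   recombination fractions.
#' @examples
#' haldane_cm(0.25)  # 34.657
#' haldane_r(34.657) # 0.25
#' @export
haldane_cm <- function(r) {
  r <- pmin(r, 0.49)
  -50 * log(1 - 2 * r)
}

#' @rdname haldane_cm
#' @export
haldane_r <- function(d) (1 - exp(-2 * d / 100)) / 2

#' Kosambi map function (interference-aware alternative)
#'
#' @inheritParams haldane_cm
#' @return Centimorgans or recombination fractions.
#' @export
kosambi_cm <- function(r) {
  r <- pmin(r, 0.49)
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_cm
#' @export
kosambi_r <- function(d) tanh(2 * d / 100) / 2

# Genotype codes used internally: 1 = AC, 2 = AD, 3 = BC, 4 = BD, NA = missing.
geno_levels <- function() c("AC", "AD", "BC", "BD")

# first-meiosis allele indicator: +1 for A, -1 for B
code_ab <- function(code) ifelse(code <= 2L, 1L, -1L)
# second-meiosis allele indicator: +1 for C, -1 for D
code_cd <- function(code) ifelse(code %% 2L == 1L, 1L, -1L)

code_from_ab_cd <- function(ab, cd) {
  # ab, cd in {1, -1}
  2L * (ab < 0L) + (cd < 0L) + 1L
}

#' Derive a stage seed from a root seed
#'
#' All randomness in the pipeline flows from one root seed; each stage uses a
#' distinct deterministic offset so stages can be re-run in isolation.
#'
#' @param seed Root integer seed.
#' @param stage Integer stage offset.
#' @return An integer seed below 2^31.
#' @keywords internal
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 97L + stage * 1009L) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
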