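# Independent oracles used across the suite. These deliberately use naive
# loop/enumeration implementations, never the package's own code paths.

# a fourway_geno built directly from a token matrix and explicit map
make_geno <- function(tokens, chrom = NULL, cM = NULL, bp = NULL) {
  tokens <- as.matrix(tokens)
  if (is.null(rownames(tokens))) {
    rownames(tokens) <- sprintf("g%03d", seq_len(nrow(tokens)))
  }
  if (is.null(colnames(tokens))) {
    colnames(tokens) <- sprintf("m%03d", seq_len(ncol(tokens)))
  }
  m <- ncol(tokens)
  structure(
    list(
      geno = matrix(match(tokens, c("AC", "AD", "BC", "BD")), nrow(tokens),
                    m, dimnames = dimnames(tokens)),
      map = tibble::tibble(
        marker = colnames(tokens),
        chrom = chrom %||% rep("chr1", m),
        cM = cM %||% seq(0, by = 1, length.out = m),
        bp = bp %||% as.integer(seq(0, by = 3200, length.out = m))
      )
    ),
    class = "fourway_geno"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force recombination fraction between two call vectors
recfrac_loop <- function(x, y) {
  rec <- 0; inf <- 0
  ab <- function(tok) ifelse(substr(tok, 1, 1) == "A", 1, -1)
  cd <- function(tok) ifelse(substr(tok, 2, 2) == "C", 1, -1)
  for (i in seq_along(x)) {
    if (is.na(x[i]) || is.na(y[i])) next
    inf <- inf + 2
    if (ab(x[i]) != ab(y[i])) rec <- rec + 1
    if (cd(x[i]) != cd(y[i])) rec <- rec + 1
  }
  if (inf == 0) return(NA_real_)
  min(rec / inf, 0.5)
}

# naive rolling statistics by explicit looping
roll_oracle <- function(x, w, fn) {
  n <- length(x) - w + 1
  vapply(seq_len(n), function(i) fn(x[i:(i + w - 1)]), numeric(1))
}

# 21 interval statistics by explicit loops over padded thirds
interval_stats_oracle <- function(weather, start_date, end_date, pad = 5) {
  len <- as.numeric(end_date - start_date) + 1
  b <- start_date + round(len * (0:3) / 3)
  out <- c()
  for (i in 1:3) {
    lo <- max(b[i] - pad, min(weather$date))
    hi <- min(b[i + 1] - 1 + pad, max(weather$date))
    d <- weather[weather$date >= lo & weather$date <= hi, ]
    out <- c(out,
             unname(quantile(d$tmax, 0.95)),
             unname(quantile(d$tmin, 0.05)),
             mean(d$prcp),
             max(roll_oracle(d$tmax, 14, mean)),
             min(roll_oracle(d$tmin, 14, mean)),
             min(roll_oracle(d$prcp, 14, sum)),
             max(roll_oracle(d$prcp, 14, sum)))
  }
  out
}

# exact two-sided binomial P against 0.5 by tail-probability summation
binom_p_oracle <- function(k, n) {
  probs <- dbinom(0:n, n, 0.5)
  sum(probs[probs <= dbinom(k, n, 0.5) + 1e-12])
}

# two-sided Fisher exact P by full hypergeometric table enumeration
fisher_p_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(r1 + r2, c1)
  }, numeric(1))
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-9)])
}

# random recombination-fraction matrix from simulated marker geometry
random_rf <- function(n_markers, seed, n_progeny = 120, length_cM = 60) {
  d <- qtlscape::cross_design(
    n_progeny,
    tibble::tibble(chrom = "c1", length_cM = length_cM,
                   n_markers = n_markers)
  )
  g <- qtlscape::sim_fourway_genotypes(d, seed = seed)
  # shuffle marker order so the true path is hidden
  perm <- sample(n_markers)
  g$geno <- g$geno[, perm]
  g$map <- g$map[perm, ]
  list(rf = qtlscape::estimate_recfrac(g),
       true_order = g$map$marker[order(g$map$cM)])
}
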