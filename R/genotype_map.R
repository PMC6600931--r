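#' Drop markers with excessive missing data
#'
#' @param g A `fourway_geno`.
#' @param max_missing Markers whose missing fraction exceeds this are removed
#'   (default 0.60, i.e. markers with >60% missing data go).
#' @return A filtered `fourway_geno`; marker order is preserved.
#' @export
filter_markers <- function(g, max_missing = 0.60) {
  stopifnot(inherits(g, "fourway_geno"))
  assert_that(max_missing > 0 && max_missing <= 1,
              "max_missing must be in (0, 1]")
  frac <- colMeans(is.na(g$geno))
  keep <- frac <= max_missing
  if (!any(keep)) warning("all markers exceeded the missingness threshold")
  g$geno <- g$geno[, keep, drop = FALSE]
  g$map <- g$map[keep, , drop = FALSE]
  g
}

#' Collapse marker windows to binned consensus calls
#'
#' Markers are grouped into consecutive non-overlapping blocks of
#' `window_size` along the physical order within each chromosome; each
#' progeny's binned call is the modal non-missing call in the block. A tie
#' for the mode, or an all-missing block, yields a missing binned call.
#' The binned marker sits at the block's physical and genetic midpoint.
#'
#' @param g A `fourway_geno` (markers physically sorted within chromosome).
#' @param window_size Raw markers per bin (default 50).
#' @param step Block step; defaults to `window_size` (non-overlapping).
#' @return A binned `fourway_geno`.
#' @export
bin_windows <- function(g, window_size = 50, step = window_size) {
  stopifnot(inherits(g, "fourway_geno"))
  assert_that(window_size >= 1, "invalid parameter: window_size must be >= 1")
  assert_that(step >= 1, "invalid parameter: step must be >= 1")
  out_geno <- list(); out_map <- list()
  for (ch in unique(g$map$chrom)) {
    sel <- which(g$map$chrom == ch)
    stopifnot(!is.unsorted(g$map$bp[sel]))
    starts <- seq(1, length(sel), by = step)
    for (bi in seq_along(starts)) {
      idx <- sel[starts[bi]:min(starts[bi] + window_size - 1, length(sel))]
      block <- g$geno[, idx, drop = FALSE]
      counts <- vapply(1:4, function(k) rowSums(block == k, na.rm = TRUE),
                       numeric(nrow(block)))
      top <- max.col(counts, ties.method = "first")
      topn <- counts[cbind(seq_len(nrow(counts)), top)]
      tie <- rowSums(counts == topn) > 1
      call <- ifelse(topn == 0 | tie, NA_integer_, top)
      out_geno[[length(out_geno) + 1L]] <- call
      out_map[[length(out_map) + 1L]] <- tibble::tibble(
        marker = sprintf("%s_bin%03d", ch, bi),
        chrom = ch,
        cM = mean(range(g$map$cM[idx])),
        bp = as.integer(round(mean(range(g$map$bp[idx]))))
      )
    }
  }
  map <- dplyr::bind_rows(out_map)
  geno <- matrix(unlist(out_geno), nrow = nrow(g$geno),
                 dimnames = list(rownames(g$geno), map$marker))
  structure(list(geno = geno, map = map), class = "fourway_geno")
}

#' Estimate pairwise recombination fractions
#'
#' Calls are phase-known, so each progeny with both markers observed
#' contributes two scored meioses: a possible A/B switch on the first-cross
#' haplotype and a possible C/D switch on the second. The estimate is
#' recombinant meioses over informative meioses, truncated at 0.5.
#'
#' @param g A `fourway_geno`.
#' @return A `recfrac` object: `$r` (symmetric matrix, diagonal 0, NA where
#'   no informative meioses), `$n` (informative meioses), `$map`.
#' @export
estimate_recfrac <- function(g) {
  stopifnot(inherits(g, "fourway_geno"))
  obs <- !is.na(g$geno)
  Xa <- code_ab(g$geno); Xa[!obs] <- 0L
  Xc <- code_cd(g$geno); Xc[!obs] <- 0L
  Nboth <- crossprod(obs * 1L)
  Sa <- crossprod(Xa)
  Sc <- crossprod(Xc)
  n_meiosis <- 2 * Nboth
  rec <- Nboth - (Sa + Sc) / 2
  r <- ifelse(n_meiosis > 0, rec / n_meiosis, NA_real_)
  r <- pmin(r, 0.5)
  diag(r) <- 0
  structure(list(r = r, n = n_meiosis, map = g$map), class = "recfrac")
}

#' @export
print.recfrac <- function(x, ...) {
  cat("<recfrac> ", nrow(x$r), " markers; median adjacent-pair r = ",
      signif(stats::median(x$r[row(x$r) == col(x$r) + 1]), 3), "\n", sep = "")
  invisible(x)
}

#' Partition markers into linkage groups
#'
#' Groups are maximal marker sets in which every pairwise recombination
#' fraction is strictly below `threshold`, obtained by complete-linkage
#' agglomeration on the recombination-fraction matrix cut at the threshold.
#'
#' @param rf A `recfrac`.
#' @param threshold Within-group bound on every pairwise estimate
#'   (default 0.25).
#' @return Tibble: marker, linkage_group (groups numbered by size, largest
#'   first; singletons allowed).
#' @export
form_linkage_groups <- function(rf, threshold = 0.25) {
  stopifnot(inherits(rf, "recfrac"))
  d <- rf$r
  d[is.na(d)] <- 1  # undefined pairs can never co-group
  m <- nrow(d)
  if (m == 1) {
    return(tibble::tibble(marker = rownames(d) %||% "m1", linkage_group = 1L))
  }
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  grp <- stats::cutree(hc, h = threshold - 1e-12)
  sizes <- sort(table(grp), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes), names(sizes))
  tibble::tibble(marker = colnames(rf$r), linkage_group =
                   unname(relab[as.character(grp)]))
}

path_cost <- function(ord, r) sum(r[cbind(ord[-length(ord)], ord[-1])])

# 2-opt refinement of an open path; O(1) delta per candidate reversal.
two_opt <- function(ord, r, max_sweeps = 50) {
  m <- length(ord)
  if (m < 4) return(ord)
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (i in 1:(m - 1)) {
      for (j in (i + 1):m) {
        delta <- 0
        if (i > 1) delta <- delta + r[ord[i - 1], ord[j]] - r[ord[i - 1], ord[i]]
        if (j < m) delta <- delta + r[ord[i], ord[j + 1]] - r[ord[j], ord[j + 1]]
        if (delta < -1e-12) {
          ord[i:j] <- ord[j:i]
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  ord
}

# order runs of mutually indistinguishable markers (all pairwise r = 0) by
# physical position; cost is unchanged because their call vectors coincide
sort_zero_ties <- function(ord, r, map) {
  m <- length(ord)
  if (m < 2) return(ord)
  adj_zero <- r[cbind(ord[-m], ord[-1])] == 0
  runs <- split(seq_len(m), cumsum(c(TRUE, !adj_zero)))
  for (run in runs) {
    if (length(run) < 2) next
    ids <- ord[run]
    if (max(r[ids, ids]) > 0) next
    pos <- match(colnames(r)[ids], map$marker)
    o <- order(map$chrom[pos], map$bp[pos])
    # align the run's physical direction with its neighbours
    if (run[1] > 1) {
      left <- ord[run[1] - 1]
      lp <- match(colnames(r)[left], map$marker)
      if (map$chrom[lp] == map$chrom[pos[o[1]]] &&
          map$bp[lp] > map$bp[pos[o[length(o)]]]) o <- rev(o)
    }
    ord[run] <- ids[o]
  }
  ord
}

#' Order markers within a linkage group
#'
#' Finds an open Hamiltonian path minimising the sum of adjacent
#' recombination fractions: greedy double-ended construction followed by
#' 2-opt refinement. For groups of up to 8 markers the result matches the
#' brute-force optimum (tested property). Orientation is canonicalised so
#' the first marker id sorts lexicographically before the last; runs of
#' markers with identical call vectors (pairwise r = 0) are anchored to
#' physical position.
#'
#' @param markers Marker ids (length >= 2).
#' @param rf A `recfrac`.
#' @return Ordered character vector of marker ids.
#' @export
order_markers <- function(markers, rf) {
  stopifnot(inherits(rf, "recfrac"))
  assert_that(length(markers) >= 2, "need at least 2 markers to order")
  r <- rf$r[markers, markers, drop = FALSE]
  if (anyNA(r)) {
    warning("undefined recombination fractions within group imputed as 0.5")
    r[is.na(r)] <- 0.5
  }
  m <- length(markers)
  # greedy: start at the tightest pair, extend the cheaper endpoint
  roff <- r + diag(Inf, m)
  start <- which(roff == min(roff), arr.ind = TRUE)[1, ]
  path <- c(start[1], start[2])
  left <- setdiff(seq_len(m), path)
  while (length(left)) {
    head_r <- r[path[1], left]
    tail_r <- r[path[length(path)], left]
    if (min(head_r) <= min(tail_r)) {
      path <- c(left[which.min(head_r)], path)
    } else {
      path <- c(path, left[which.min(tail_r)])
    }
    left <- setdiff(left, path)
  }
  path <- two_opt(path, r)
  path <- sort_zero_ties(path, r, rf$map)
  if (markers[path[1]] > markers[path[m]]) path <- rev(path)
  markers[path]
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Exhaustive minimum-cost marker order (oracle for small groups)
#'
#' @param markers Marker ids (<= 9).
#' @param rf A `recfrac`.
#' @return List with `order` and `cost`.
#' @export
order_markers_bruteforce <- function(markers, rf) {
  m <- length(markers)
  assert_that(m >= 2 && m <= 9, "brute force is for 2..9 markers")
  r <- rf$r[markers, markers, drop = FALSE]
  r[is.na(r)] <- 0.5
  perms <- all_perms(m)
  costs <- 0
  for (j in seq_len(m - 1)) {
    costs <- costs + r[perms[, j] + (perms[, j + 1] - 1L) * m]
  }
  best <- perms[which.min(costs), ]
  list(order = markers[best], cost = min(costs))
}

#' Polish a marker order with the ripple algorithm
#'
#' Slides a window of `window` markers along the order; within each window
#' all permutations are tried and any that lowers the total adjacent
#' recombination-fraction sum is kept. Sweeps repeat until no improvement,
#' so the output cost never exceeds the input cost.
#'
#' @param ord Ordered marker ids.
#' @param rf A `recfrac`.
#' @param window Ripple window size (default 4; truncated to the group size).
#' @return Polished order (character vector).
#' @export
ripple_polish <- function(ord, rf, window = 4) {
  stopifnot(inherits(rf, "recfrac"))
  m <- length(ord)
  window <- min(window, m)
  if (window < 2 || m < 3) return(ord)
  r <- rf$r[ord, ord, drop = FALSE]
  r[is.na(r)] <- 0.5
  cur <- seq_len(m)
  perms <- all_perms(window)
  repeat {
    improved <- FALSE
    for (s in 1:(m - window + 1)) {
      win <- cur[s:(s + window - 1)]
      base_cost <- local_cost(cur, s, window, r, m)
      for (pi in seq_len(nrow(perms))) {
        cand <- cur
        cand[s:(s + window - 1)] <- win[perms[pi, ]]
        cc <- local_cost(cand, s, window, r, m)
        if (cc < base_cost - 1e-12) {
          cur <- cand
          base_cost <- cc
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  ord[cur]
}

# cost of the edges touching window [s, s+w-1] in order `cur`
local_cost <- function(cur, s, w, r, m) {
  lo <- max(1, s - 1); hi <- min(m, s + w)
  seg <- cur[lo:hi]
  sum(r[cbind(seg[-length(seg)], seg[-1])])
}

#' Assign centimorgan positions along an ordered group
#'
#' Cumulative map distances from adjacent recombination fractions via the
#' Haldane map function (Kosambi available). Estimates at or above 0.5 are
#' clamped to 0.49 with a warning.
#'
#' @param ord Ordered marker ids.
#' @param rf A `recfrac`.
#' @param map_fun `"haldane"` (default) or `"kosambi"`.
#' @return Tibble: marker, order_index, cM (3 decimals).
#' @export
assign_cm_positions <- function(ord, rf, map_fun = c("haldane", "kosambi")) {
  map_fun <- match.arg(map_fun)
  fn <- if (map_fun == "haldane") haldane_cm else kosambi_cm
  radj <- if (length(ord) > 1) rf$r[cbind(ord[-length(ord)], ord[-1])] else numeric()
  radj[is.na(radj)] <- 0.49
  if (any(radj >= 0.5)) {
    warning("adjacent recombination fraction >= 0.5 clamped to 0.49")
    radj <- pmin(radj, 0.49)
  }
  tibble::tibble(
    marker = ord,
    order_index = seq_along(ord),
    cM = round(cumsum(c(0, fn(radj))), 3)
  )
}

#' Reconstruct a linkage map from noisy four-way calls
#'
#' End-to-end map construction: missingness filter, window binning, pairwise
#' recombination fractions, complete-linkage grouping, greedy + 2-opt
#' ordering, ripple polishing, and Haldane position assignment.
#'
#' @param g A `fourway_geno` of raw calls.
#' @param max_missing,window_size,r_threshold,ripple_window,map_fun
#'   Stage parameters (defaults 0.60, 50, 0.25, 4, haldane).
#' @param bin Set `FALSE` if `g` is already binned.
#' @return A `linkage_map` object: `$map` (tibble: marker, linkage_group,
#'   order_index, cM), `$rf`, `$geno` (the binned matrix used).
#' @export
build_linkage_map <- function(g, max_missing = 0.60, window_size = 50,
                              r_threshold = 0.25, ripple_window = 4,
                              map_fun = "haldane", bin = TRUE) {
  g <- filter_markers(g, max_missing)
  if (bin) g <- bin_windows(g, window_size)
  rf <- estimate_recfrac(g)
  groups <- form_linkage_groups(rf, r_threshold)
  maps <- groups |>
    dplyr::group_split(.data$linkage_group) |>
    purrr::map(function(grp) {
      lg <- grp$linkage_group[1]
      if (nrow(grp) == 1) {
        return(tibble::tibble(marker = grp$marker, linkage_group = lg,
                              order_index = 1L, cM = 0))
      }
      ord <- order_markers(grp$marker, rf)
      ord <- ripple_polish(ord, rf, ripple_window)
      dplyr::mutate(assign_cm_positions(ord, rf, map_fun),
                    linkage_group = lg, .after = "marker")
    })
  structure(
    list(map = dplyr::bind_rows(maps), rf = rf, geno = g),
    class = "linkage_map"
  )
}

#' @export
print.linkage_map <- function(x, ...) {
  s <- x$map |>
    dplyr::group_by(.data$linkage_group) |>
    dplyr::summarise(n_markers = dplyr::n(), length_cM = max(.data$cM))
  cat("<linkage_map> ", nrow(s), " linkage group(s)\n", sep = "")
  print(s, n = 10)
  invisible(x)
}
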