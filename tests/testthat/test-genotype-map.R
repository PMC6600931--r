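test_that("missingness filter removes markers above the threshold", {
  tokens <- matrix("AC", 100, 10)
  # marker j missing in 10*(j-1)% of progeny
  for (j in 1:10) if (j > 1) tokens[seq_len(10 * (j - 1)), j] <- NA
  g <- make_geno(tokens)
  f <- filter_markers(g, 0.60)
  expect_equal(ncol(f$geno), 7)  # 0.0 .. 0.6 retained, > 0.6 dropped
  # 61% missing at threshold 0.60 is removed
  t2 <- matrix("AC", 100, 2)
  t2[1:61, 2] <- NA
  expect_equal(ncol(filter_markers(make_geno(t2), 0.60)$geno), 1)
  # no missing data: identity
  g3 <- make_geno(matrix("AD", 5, 4))
  expect_identical(filter_markers(g3)$geno, g3$geno)
})

test_that("window binning takes the majority call with conservative ties", {
  # one block: 30 AC, 15 AD, 5 missing -> AC; 25/25 tie -> NA
  row_major <- c(rep("AC", 30), rep("AD", 15), rep(NA, 5))
  row_tie <- c(rep("AC", 25), rep("AD", 25))
  tokens <- rbind(row_major, row_tie)
  g <- make_geno(tokens)
  b <- bin_windows(g, 50)
  expect_equal(ncol(b$geno), 1)
  expect_equal(geno_calls(b)[1, 1], "AC")
  expect_true(is.na(b$geno[2, 1]))

  # 120 markers with window 50 -> 3 bins (50, 50, 20)
  g2 <- make_geno(matrix("BD", 4, 120))
  b2 <- bin_windows(g2, 50)
  expect_equal(ncol(b2$geno), 3)
  expect_true(all(geno_calls(b2) == "BD"))

  # binning never increases missingness beyond block-level all-missing
  tokens3 <- matrix(sample(c("AC", "AD", NA), 50 * 100, TRUE,
                           prob = c(.45, .45, .1)), 50, 100)
  g3 <- make_geno(tokens3)
  b3 <- bin_windows(g3, 50)
  all_missing_blocks <- vapply(1:2, function(k) {
    idx <- ((k - 1) * 50 + 1):(k * 50)
    rowSums(!is.na(g3$geno[, idx])) == 0
  }, logical(50))
  expect_true(all(is.na(b3$geno[all_missing_blocks]) |
                    !all_missing_blocks[is.na(b3$geno)]))
  expect_error(bin_windows(g3, 0), "window_size")
})

test_that("recombination fractions count scored meioses correctly", {
  # identical vectors -> r = 0
  tok <- matrix(sample(c("AC", "AD", "BC", "BD"), 50, TRUE), 50, 2)
  tok[, 2] <- tok[, 1]
  rf <- estimate_recfrac(make_geno(tok))
  expect_equal(rf$r[1, 2], 0)
  expect_equal(rf$n[1, 2], 100)

  # constructed: 100 progeny, 20 recombinant meioses of 200 -> 0.10
  t2 <- matrix("AC", 100, 2)
  t2[1:10, 2] <- "BC"  # A/B switch: 1 recombinant meiosis each
  t2[11:20, 2] <- "AD" # C/D switch
  rf2 <- estimate_recfrac(make_geno(t2))
  expect_equal(rf2$r[1, 2], 0.10)

  # matches the loop oracle on noisy simulated data
  d <- demo_cross_design(60, 1, 80, 6)
  g <- corrupt_genotypes(sim_fourway_genotypes(d, seed = 2), 0.2, 0.05,
                         seed = 3)
  rf3 <- estimate_recfrac(g)
  tokens <- geno_calls(g)
  for (pair in list(c(1, 2), c(2, 5), c(1, 6))) {
    expect_equal(rf3$r[pair[1], pair[2]],
                 recfrac_loop(tokens[, pair[1]], tokens[, pair[2]]))
  }

  # independent loci converge to 0.5 (truncated)
  d2 <- cross_design(2000, tibble::tibble(chrom = c("a", "b"),
                                          length_cM = 10, n_markers = 2))
  g2 <- sim_fourway_genotypes(d2, seed = 4)
  rf4 <- estimate_recfrac(g2)
  expect_gt(rf4$r[1, 3], 0.5 - 3 * sqrt(0.25 / 4000))
})

test_that("linkage grouping enforces the all-pairs threshold", {
  mk_rf <- function(r) {
    dimnames(r) <- list(paste0("m", 1:nrow(r)), paste0("m", 1:nrow(r)))
    structure(list(r = r, n = matrix(100, nrow(r), nrow(r)),
                   map = tibble::tibble(marker = rownames(r), chrom = "c",
                                        cM = seq_len(nrow(r)),
                                        bp = seq_len(nrow(r)))),
              class = "recfrac")
  }
  # 3 tight markers + 1 unlinked
  r <- matrix(0.1, 4, 4); diag(r) <- 0
  r[4, 1:3] <- r[1:3, 4] <- 0.5
  gr <- form_linkage_groups(mk_rf(r))
  expect_equal(dplyr::n_distinct(gr$linkage_group), 2)
  expect_equal(length(unique(gr$linkage_group[1:3])), 1)

  # all pairwise 0.24: strictly below the threshold, one group
  r2 <- matrix(0.24, 5, 5); diag(r2) <- 0
  expect_equal(dplyr::n_distinct(form_linkage_groups(mk_rf(r2))$linkage_group), 1)

  # chain 0.1-0.1 with far ends at 0.3: complete linkage splits marker 3 off
  r3 <- matrix(0, 3, 3)
  r3[1, 2] <- r3[2, 1] <- 0.1
  r3[2, 3] <- r3[3, 2] <- 0.1
  r3[1, 3] <- r3[3, 1] <- 0.3
  gr3 <- form_linkage_groups(mk_rf(r3))
  expect_equal(gr3$linkage_group[1], gr3$linkage_group[2])
  expect_false(gr3$linkage_group[3] == gr3$linkage_group[1])
})

test_that("marker ordering matches the brute-force optimum on small groups", {
  set.seed(99)
  for (i in 1:25) {
    m <- sample(7:8, 1)
    inst <- random_rf(m, seed = 1000 + i)
    heur <- order_markers(inst$rf$map$marker, inst$rf)
    hcost <- sum(inst$rf$r[cbind(heur[-m], heur[-1])])
    bf <- order_markers_bruteforce(inst$rf$map$marker, inst$rf)
    expect_equal(hcost, bf$cost, tolerance = 1e-12)
  }
  # two markers: the only path
  inst2 <- random_rf(2, seed = 7)
  ord2 <- order_markers(inst2$rf$map$marker, inst2$rf)
  expect_setequal(ord2, inst2$rf$map$marker)
})

test_that("simulated marker order is recovered up to reversal", {
  d <- cross_design(400, tibble::tibble(chrom = "c1", length_cM = 100,
                                        n_markers = 15))
  g <- sim_fourway_genotypes(d, seed = 31)
  perm <- sample(15)
  g$geno <- g$geno[, perm]; g$map <- g$map[perm, ]
  rf <- estimate_recfrac(g)
  ord <- ripple_polish(order_markers(g$map$marker, rf), rf)
  true_ord <- g$map$marker[order(g$map$cM)]
  expect_true(identical(ord, true_ord) || identical(ord, rev(true_ord)))
})

test_that("ripple polishing repairs local swaps and never increases cost", {
  d <- cross_design(400, tibble::tibble(chrom = "c1", length_cM = 80,
                                        n_markers = 12))
  g <- sim_fourway_genotypes(d, seed = 13)
  rf <- estimate_recfrac(g)
  true_ord <- g$map$marker
  # already-optimal order is a fixed point
  expect_identical(ripple_polish(true_ord, rf), true_ord)
  # an adjacent swap is repaired
  swapped <- true_ord; swapped[5:6] <- swapped[6:5]
  expect_identical(ripple_polish(swapped, rf), true_ord)
  # monotone non-increase on random instances
  set.seed(5)
  for (i in 1:20) {
    inst <- random_rf(9, seed = 2000 + i)
    ord0 <- sample(inst$rf$map$marker)
    ord1 <- ripple_polish(ord0, inst$rf)
    c0 <- sum(inst$rf$r[cbind(ord0[-9], ord0[-1])])
    c1 <- sum(inst$rf$r[cbind(ord1[-9], ord1[-1])])
    expect_lte(c1, c0 + 1e-12)
  }
})

test_that("centimorgan positions follow the Haldane map function", {
  tok <- matrix("AC", 10, 3)
  rf <- estimate_recfrac(make_geno(tok))
  rf$r[1, 2] <- rf$r[2, 1] <- 0
  rf$r[2, 3] <- rf$r[3, 2] <- 0.25
  pos <- assign_cm_positions(c("m001", "m002", "m003"), rf)
  expect_equal(pos$cM, c(0, 0, 34.657), tolerance = 1e-3)
  rf$r[2, 3] <- rf$r[3, 2] <- 0.10
  pos2 <- assign_cm_positions(c("m001", "m002", "m003"), rf)
  expect_equal(pos2$cM[3], 11.157, tolerance = 1e-3)
  rf$r[2, 3] <- rf$r[3, 2] <- 0.5
  expect_warning(assign_cm_positions(c("m001", "m002", "m003"), rf),
                 "clamped")
})

test_that("end-to-end map reconstruction recovers the simulated genome", {
  # desk-scale version: 2 chromosomes x 40 bins x 25 raw markers
  d <- cross_design(425, tibble::tibble(chrom = c("chr1", "chr2"),
                                        length_cM = 21, n_markers = 1000))
  g <- sim_fourway_genotypes(d, seed = 8)
  raw <- corrupt_genotypes(g, 0.10, 0.01, seed = 9)
  lm <- build_linkage_map(raw, window_size = 25)
  truth <- bin_windows(g, 25)$map
  joined <- dplyr::inner_join(lm$map, truth, by = "marker",
                              suffix = c("", ".true"))
  # exact chromosome partition
  purity <- joined |>
    dplyr::group_by(linkage_group) |>
    dplyr::summarise(n_chrom = dplyr::n_distinct(chrom),
                     tau = abs(cor(order_index, cM.true,
                                   method = "kendall")))
  expect_equal(nrow(purity), 2)
  expect_true(all(purity$n_chrom == 1))
  expect_true(all(purity$tau == 1))
})
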