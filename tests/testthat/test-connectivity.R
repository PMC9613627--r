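make_events <- function(slice, layer, cls, amp, area = "V1") {
  tibble::tibble(cell_id = sprintf("c%02d", seq_along(amp)), slice_id = slice,
                 area = area, layer = layer, cell_class = cls, amplitude = amp)
}

test_that("log2 normalization divides by the slice's mean L2/3 pyramidal amplitude", {
  ev <- dplyr::bind_rows(
    make_events("s1", c("L2/3", "L5"), c("Pyr", "SOM"), c(100, 200)),
    make_events("s2", c("L2/3", "L2/3", "L4"), c("Pyr", "Pyr", "PV"),
                c(100, 300, 100))
  )
  norm <- normalize_to_reference(ev)
  expect_equal(norm$log2_ratio[norm$slice_id == "s1" & norm$cell_class == "SOM"], 1)
  expect_equal(norm$log2_ratio[norm$cell_class == "PV"], -1)
  # a slice with a single reference cell gives that cell log2 ratio 0
  expect_equal(norm$log2_ratio[norm$slice_id == "s1" & norm$cell_class == "Pyr"], 0)

  ev2 <- dplyr::bind_rows(ev, make_events("s3", "L5", "Pyr", 50))
  expect_warning(norm2 <- normalize_to_reference(ev2), "without an L2/3")
  expect_false("s3" %in% norm2$slice_id)

  ev3 <- make_events("s1", c("L2/3", "L5"), c("Pyr", "SOM"), c(0, 10))
  expect_error(normalize_to_reference(ev3), "0")
})

test_that("multiplying a slice's amplitudes by a constant leaves log2 ratios unchanged", {
  cfg <- test_config(seed = 3)
  ds <- gen_slice_dataset(cfg, n_per_group = 4, render_sweeps = FALSE)
  ev <- ds$ground_truth
  ev$amplitude <- ev$true_amplitude
  norm1 <- normalize_to_reference(ev)
  ev2 <- ev
  boost <- ev2$slice_id == ev2$slice_id[1]
  ev2$amplitude[boost] <- ev2$amplitude[boost] * 7.5
  norm2 <- normalize_to_reference(ev2)
  expect_equal(norm1$log2_ratio, norm2$log2_ratio)
})

test_that("responsive fractions report exact counts, percentages and a pooled row", {
  ev <- tibble::tibble(
    area = rep("V1", 10), layer = rep("L4", 10), cell_class = rep("Pyr", 10),
    responsive = rep(FALSE, 10)
  )
  tab <- responsive_fraction_table(ev)
  expect_equal(tab$percent[tab$area == "V1"], 0)
  expect_equal(tab$responsive_count[tab$area == "all"], 0)
  expect_equal(tab$total[tab$area == "all"], 10)
})

test_that("the Kruskal-Wallis H statistic matches the hand-ranked example", {
  res <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(res$statistic, 7.2)
  ident <- kruskal_wallis(list(rep(2, 5), rep(2, 5)))
  expect_equal(ident$p_raw, 1)
})

test_that("small-sample Kruskal-Wallis p agrees with a permutation enumeration oracle", {
  # permutation oracle: permute group labels exhaustively over all
  # assignments of 6 values to two groups of 3 and compare H
  x <- c(1.3, 2.1, 0.4, 3.9, 4.4, 5.1)
  H_of <- function(idx) {
    g <- rep(2L, 6); g[idx] <- 1L
    unname(stats::kruskal.test(x, factor(g))$statistic)
  }
  obs <- H_of(1:3)
  combos <- utils::combn(6, 3, simplify = FALSE)
  p_exact <- mean(vapply(combos, function(ix) H_of(ix) >= obs - 1e-12, logical(1)))
  res <- kruskal_wallis(list(x[1:3], x[4:6]))
  # the chi-square approximation at n = 3 + 3 is crude; demand agreement
  # in rejection region only loosely
  expect_lt(abs(res$p_raw - p_exact), 0.07)
})

test_that("Conover-Iman statistics match the published formula applied by hand", {
  res <- conover_posthoc(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
  expect_equal(nrow(res), 3)
  # frozen values from a hand application of the formula:
  # S2 = 7.5, H = 7.2, se = sqrt(7.5 * (8 - 7.2)/6 * 2/3) = 0.8164966
  expect_equal(res$statistic[res$group_labels == "a vs b"], -3.6742346,
               tolerance = 1e-6)
  expect_equal(res$p_raw[res$group_labels == "a vs b"], 0.01040172,
               tolerance = 1e-6)
  expect_equal(res$statistic[res$group_labels == "a vs c"], -7.3484692,
               tolerance = 1e-6)
  expect_equal(res$p_raw[res$group_labels == "a vs c"], 0.00032497,
               tolerance = 1e-4)

  near1 <- conover_posthoc(list(a = c(1, 3, 5, 7), b = c(2, 4, 6, 8)))
  expect_gt(near1$p_raw, 0.5)

  groups11 <- split(stats::rnorm(33), rep(1:11, each = 3))
  expect_equal(nrow(conover_posthoc(groups11)), 55)

  expect_warning(res2 <- conover_posthoc(list(a = 1:3, b = 4:6),
                                         pairs = list(c("a", "zzz"))),
                 "skipping")
  expect_equal(nrow(res2), 0)
})

test_that("the sign-flip permutation test enumerates exactly for small n", {
  res <- permutation_signed_test(c(0.5, 1.0, 0.2, 0.7, 0.3))
  expect_equal(res$p_raw, 2 / 32)
  expect_equal(res$statistic, mean(c(0.5, 1.0, 0.2, 0.7, 0.3)))

  expect_equal(permutation_signed_test(rep(0, 4))$p_raw, 1)

  # Monte-Carlo branch is seeded and reproducible
  set.seed(99)
  x22 <- stats::rnorm(22, 0.3)
  p1 <- permutation_signed_test(x22, seed = 5)$p_raw
  p2 <- permutation_signed_test(x22, seed = 5)$p_raw
  expect_identical(p1, p2)
})

test_that("exhaustive and Monte-Carlo sign-flip p-values agree at n = 10", {
  set.seed(4)
  x <- stats::rnorm(10, 0.4)
  p_exact <- permutation_signed_test(x)$p_raw
  p_mc <- permutation_signed_test(x, max_exact = 5, n_mc = 2e4, seed = 11)$p_raw
  expect_lt(abs(p_exact - p_mc),
            3 * sqrt(p_exact * (1 - p_exact) / 2e4) + 1e-3)
})

test_that("Benjamini-Hochberg step-up reproduces the hand-computed adjusted set", {
  fam <- list(a = list(1:10, 1:10 + 3), b = list(1:10, 1:10 + 2),
              c = list(1:10, 1:10 + 1.5), d = list(1:10, 1:10 + 1.2))
  res <- cross_pathway_comparison(fam)
  expect_equal(res$p_adjusted, stats::p.adjust(res$p_raw, "BH"))
  expect_true(all(diff(res$p_adjusted[order(res$p_raw)]) >= -1e-12))
  expect_true(all(res$p_adjusted >= res$p_raw))

  single <- cross_pathway_comparison(list(x = list(1:8, 3:10)))
  expect_equal(single$p_adjusted, single$p_raw)

  # shifted vs identical distributions at n = 20
  set.seed(8)
  a <- stats::rnorm(20)
  res2 <- cross_pathway_comparison(list(shift = list(a, a + 2),
                                        same = list(a, a)))
  expect_lt(res2$p_raw[res2$group_labels == "shift"], 0.05)
  expect_gt(res2$p_raw[res2$group_labels == "same"], 0.05)

  expect_equal(nrow(cross_pathway_comparison(list())), 0)
})

test_that("slice inclusion uses an inclusive 50 pA mean reference threshold", {
  ev <- dplyr::bind_rows(
    make_events("low", "L2/3", "Pyr", 49),
    make_events("edge", "L2/3", "Pyr", 50),
    make_events("high", c("L2/3", "L2/3"), "Pyr", c(40, 80)),
    make_events("noref", "L5", "Pyr", 500)
  )
  inc <- spiking_inclusion_filter(ev)
  expect_setequal(inc, c("edge", "high"))
})

test_that("spiking fractions count current-clamp cells per group", {
  cells <- tibble::tibble(
    slice_id = "s1", area = "vS1", layer = "L2/3",
    cell_class = rep(c("SOM", "PV"), c(4, 3)),
    mode = "current_clamp",
    spiked_to_feedback = c(rep(FALSE, 4), rep(TRUE, 3))
  )
  tab <- spiking_fraction_table(cells)
  expect_equal(tab$fraction[tab$cell_class == "SOM"], 0)
  expect_equal(tab$fraction[tab$cell_class == "PV"], 1)
  # voltage-clamp cells never enter the table
  vc <- dplyr::mutate(cells, mode = "voltage_clamp")
  expect_equal(nrow(spiking_fraction_table(vc)), 0)
})

test_that("rank-sum type-I error under the null sits near the nominal level", {
  set.seed(12)
  rejections <- vapply(seq_len(1000), function(i) {
    x <- stats::rnorm(20); y <- stats::rnorm(20)
    suppressWarnings(stats::wilcox.test(x, y)$p.value) < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.02)
})
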