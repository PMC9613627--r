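#' Normalize amplitudes within slices to the L2/3 pyramidal reference
#'
#' Whole-cell amplitudes are not comparable across slices and animals
#' because of virus-titer variability, so each cell's amplitude is divided
#' by the mean amplitude of the L2/3 pyramidal cell(s) recorded on the same
#' slice and reported on a log2 scale. Slices without a reference cell are
#' excluded with a warning.
#'
#' @param events Tidy events table (see [events_table()]) with columns
#'   `cell_id`, `slice_id`, `layer`, `cell_class`, `amplitude` (and
#'   grouping columns which are carried through).
#' @return Tibble of the input rows from slices with a reference, plus
#'   `reference_amplitude` and `log2_ratio`.
#' @export
normalize_to_reference <- function(events) {
  refs <- events |>
    dplyr::filter(.data$layer == "L2/3", .data$cell_class == "Pyr") |>
    dplyr::group_by(.data$slice_id) |>
    dplyr::summarise(reference_amplitude = mean(.data$amplitude), .groups = "drop")
  if (any(refs$reference_amplitude == 0)) {
    stop("slice reference mean amplitude is 0; cannot normalize", call. = FALSE)
  }
  dropped <- setdiff(unique(events$slice_id), refs$slice_id)
  if (length(dropped) > 0) {
    warning("excluding ", length(dropped),
            " slice(s) without an L2/3 pyramidal reference: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  events |>
    dplyr::inner_join(refs, by = "slice_id") |>
    dplyr::mutate(log2_ratio = log2(.data$amplitude / .data$reference_amplitude))
}

#' Responsive-fraction table
#'
#' Integer counts of responsive cells over recorded cells per (area, layer,
#' class), with percentages and a pooled overall row. Groups with no cells
#' report a missing percentage.
#'
#' @param events Events table with logical `responsive` and grouping columns
#'   `area`, `layer`, `cell_class`.
#' @return Tibble with `area`, `layer`, `cell_class`, `responsive_count`,
#'   `total`, `percent`; the pooled row has `"all"` in the grouping columns.
#' @export
responsive_fraction_table <- function(events) {
  per_group <- events |>
    dplyr::group_by(.data$area, .data$layer, .data$cell_class) |>
    dplyr::summarise(responsive_count = sum(.data$responsive),
                     total = dplyr::n(), .groups = "drop")
  pooled <- tibble::tibble(area = "all", layer = "all", cell_class = "all",
                           responsive_count = sum(per_group$responsive_count),
                           total = sum(per_group$total))
  dplyr::bind_rows(per_group, pooled) |>
    dplyr::mutate(percent = ifelse(.data$total > 0,
                                   100 * .data$responsive_count / .data$total,
                                   NA_real_))
}

#' Pool a table of per-group counts
#'
#' Aggregates per-group (responsive, total) counts into the overall
#' fraction, as printed in connectivity summary tables.
#'
#' @param counts Tibble with integer columns `responsive_count`, `total`.
#' @return List with `responsive_count`, `total`, `percent`.
#' @export
pooled_fraction <- function(counts) {
  r <- sum(counts$responsive_count)
  n <- sum(counts$total)
  list(responsive_count = r, total = n,
       percent = if (n > 0) 100 * r / n else NA_real_)
}

comparison_result <- function(test_name, group_labels, statistic, p_raw,
                              p_adjusted = p_raw, adjustment = "none") {
  tibble::tibble(test_name = test_name,
                 group_labels = paste(group_labels, collapse = " vs "),
                 statistic = statistic, p_raw = p_raw,
                 p_adjusted = p_adjusted, adjustment = adjustment)
}

#' Kruskal-Wallis test across groups
#'
#' Rank-based H statistic with tie correction and chi-square p-value,
#' wrapping [stats::kruskal.test()]. Degenerate all-identical input returns
#' H = 0, p = 1.
#'
#' @param groups Named list of numeric vectors (one per group, >= 2
#'   non-empty).
#' @return One-row comparison tibble (`test_name`, `group_labels`,
#'   `statistic`, `p_raw`, `p_adjusted`, `adjustment`).
#' @export
kruskal_wallis <- function(groups) {
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) stop("need >= 2 non-empty groups", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  labels <- if (!is.null(names(groups))) names(groups) else levels(g)
  if (length(unique(x)) == 1L) {
    return(comparison_result("kruskal_wallis", labels, 0, 1))
  }
  kt <- stats::kruskal.test(x, g)
  comparison_result("kruskal_wallis", labels,
                    unname(kt$statistic), unname(kt$p.value))
}

#' Conover-Iman post hoc pairwise comparisons
#'
#' Two-sided pairwise t-type comparisons on the pooled ranks following a
#' Kruskal-Wallis test, using the Conover-Iman statistic
#' \deqn{t = \frac{\bar R_i - \bar R_j}{\sqrt{S^2 \frac{N-1-H}{N-k}
#'   \left(\frac{1}{n_i}+\frac{1}{n_j}\right)}}}
#' with the tie-corrected pooled-rank variance
#' \eqn{S^2 = (\sum R^2 - N(N+1)^2/4)/(N-1)} and `N - k` degrees of
#' freedom. p-values are reported raw (no within-family adjustment).
#'
#' @param groups Named list of numeric vectors.
#' @param pairs Optional list of length-2 character vectors naming the
#'   group pairs to compare; defaults to all unordered pairs. Pairs that
#'   reference an empty/unknown group are skipped with a warning.
#' @return Comparison tibble, one row per pair.
#' @export
conover_posthoc <- function(groups, pairs = NULL) {
  groups <- groups[lengths(groups) > 0]
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  k <- length(groups)
  if (is.null(pairs)) {
    cmb <- utils::combn(names(groups), 2, simplify = FALSE)
  } else {
    cmb <- pairs
  }
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  H <- unname(kruskal_wallis(groups)$statistic)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  df <- N - k
  out <- purrr::map(cmb, function(p) {
    if (!all(p %in% names(groups))) {
      warning("skipping pair referencing empty or unknown group: ",
              paste(p, collapse = " vs "), call. = FALSE)
      return(NULL)
    }
    denom <- sqrt(S2 * (N - 1 - H) / df * (1 / n[[p[1]]] + 1 / n[[p[2]]]))
    tval <- (rbar[[p[1]]] - rbar[[p[2]]]) / denom
    pval <- if (!is.finite(tval)) 1 else 2 * stats::pt(-abs(tval), df)
    comparison_result("conover", p, tval, min(pval, 1))
  })
  dplyr::bind_rows(out)
}

#' Permutation sign-flip test against the reference
#'
#' Tests whether log2 normalized responses are symmetric about 0 (i.e.
#' whether a cell class differs from the within-slice L2/3 pyramidal
#' reference). The statistic is the sample mean; the two-sided p-value is
#' the fraction of sign assignments whose absolute mean is at least the
#' observed one — exhaustive over all \eqn{2^n} assignments for
#' `n <= max_exact`, otherwise a seeded Monte-Carlo sample of sign flips.
#'
#' @param values Numeric vector of log2 ratios (finite, `n >= 1`).
#' @param max_exact Largest `n` for exhaustive enumeration (default 20).
#' @param n_mc Monte-Carlo draws above `max_exact` (default 1e5).
#' @param seed Seed for the Monte-Carlo branch.
#' @return One-row comparison tibble.
#' @export
permutation_signed_test <- function(values, max_exact = 20, n_mc = 1e5,
                                    seed = 1L) {
  stopifnot(length(values) >= 1, all(is.finite(values)))
  n <- length(values)
  obs <- sum(values)
  if (all(values == 0)) {
    return(comparison_result("permutation_signed", "vs reference", 0, 1))
  }
  tol <- 1e-9 * max(1, abs(obs))
  if (n <= max_exact) {
    sums <- 0
    for (v in values) sums <- c(sums + v, sums - v)
    p <- mean(abs(sums) >= abs(obs) - tol)
  } else {
    p <- with_local_seed(seed, {
      signs <- matrix(sample(c(-1, 1), n_mc * n, replace = TRUE), nrow = n_mc)
      sums <- as.numeric(signs %*% values)
      mean(abs(sums) >= abs(obs) - tol)
    })
  }
  comparison_result("permutation_signed", "vs reference", obs / n, p)
}

#' Cross-pathway rank-sum comparisons with Benjamini-Hochberg adjustment
#'
#' Two-sided Wilcoxon rank-sum test for each matched cell type across the
#' two pathways, with the family of raw p-values adjusted by the
#' Benjamini-Hochberg step-up procedure.
#'
#' @param family Named list, one element per comparison, each a list of two
#'   numeric vectors (e.g. `list(v1 = ..., vs1 = ...)`).
#' @return Comparison tibble, one row per family member, with `p_adjusted`
#'   from [stats::p.adjust()] (`"BH"`).
#' @export
cross_pathway_comparison <- function(family) {
  if (length(family) == 0) {
    return(comparison_result("rank_sum", character(), numeric(), numeric())[0, ])
  }
  if (is.null(names(family))) names(family) <- paste0("pair", seq_along(family))
  rows <- purrr::imap(family, function(pair, nm) {
    stopifnot(length(pair) == 2, length(pair[[1]]) > 0, length(pair[[2]]) > 0)
    rank_sum_result(pair[[1]], pair[[2]], nm)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = "BH")
  out$adjustment <- "benjamini_hochberg"
  out
}

#' Slice inclusion filter for the spiking analysis
#'
#' Spiking probabilities are only meaningful on slices with a minimal level
#' of ChR2-expressing feedback innervation, defined by a minimum mean
#' L2/3 pyramidal (reference) EPSC of 50 pA. The boundary is inclusive.
#' Slices with no reference cell are excluded.
#'
#' @param events Events table (EPSC measure) with `slice_id`, `layer`,
#'   `cell_class`, `amplitude`.
#' @param min_mean_epsc_pA Inclusion threshold (default 50).
#' @return Character vector of included slice ids.
#' @export
spiking_inclusion_filter <- function(events, min_mean_epsc_pA = 50) {
  events |>
    dplyr::filter(.data$layer == "L2/3", .data$cell_class == "Pyr") |>
    dplyr::group_by(.data$slice_id) |>
    dplyr::summarise(mean_ref = mean(.data$amplitude), .groups = "drop") |>
    dplyr::filter(.data$mean_ref >= min_mean_epsc_pA) |>
    dplyr::pull(.data$slice_id)
}

#' Spiking-fraction table
#'
#' Counts of cells that spiked in response to feedback activation over all
#' cells recorded in current-clamp mode, per (area, layer, class), after
#' slice inclusion filtering.
#'
#' @param cells Tibble with `slice_id`, `area`, `layer`, `cell_class`,
#'   `mode` and logical `spiked_to_feedback`.
#' @param included_slices Slice ids passing [spiking_inclusion_filter()];
#'   `NULL` keeps all slices.
#' @return Tibble with `area`, `layer`, `cell_class`, `spiking_count`,
#'   `total`, `fraction`.
#' @export
spiking_fraction_table <- function(cells, included_slices = NULL) {
  cc <- dplyr::filter(cells, .data$mode == "current_clamp")
  if (!is.null(included_slices)) {
    cc <- dplyr::filter(cc, .data$slice_id %in% included_slices)
  }
  cc |>
    dplyr::group_by(.data$area, .data$layer, .data$cell_class) |>
    dplyr::summarise(spiking_count = sum(.data$spiked_to_feedback),
                     total = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(fraction = ifelse(.data$total > 0,
                                    .data$spiking_count / .data$total,
                                    NA_real_))
}
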