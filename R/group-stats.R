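#' Cluster frequencies per sample
#'
#' Fraction of each cluster among a parent lineage within each sample
#' (patient x tissue by default). Fractions sum to 1 within each sample.
#' Samples with zero parent cells are dropped with a warning.
#'
#' @param cells Cell table with cluster labels.
#' @param parent_selector Optional logical vector (or expression evaluated in
#'   `cells`) selecting the parent population, e.g. all CD8 cells. Default:
#'   all cells.
#' @param group_cols Columns defining a sample.
#' @param cluster_col Label column name.
#' @return Tibble with the grouping columns plus `cluster`, `n`,
#'   `n_parent` and `fraction`.
#' @export
cluster_frequencies <- function(cells, parent_selector = NULL,
                                group_cols = c("patient_id", "tissue_type"),
                                cluster_col = "cluster") {
  sel <- rlang::enquo(parent_selector)
  keep <- if (rlang::quo_is_null(sel)) rep(TRUE, nrow(cells)) else
    rlang::eval_tidy(sel, data = cells)
  dropped <- cells[!keep, , drop = FALSE] |>
    dplyr::distinct(dplyr::across(dplyr::all_of(group_cols)))
  dat <- cells[keep, , drop = FALSE]
  if (nrow(dat) == 0L) abort("no parent cells selected")
  present <- dat |>
    dplyr::distinct(dplyr::across(dplyr::all_of(group_cols)))
  lost <- dplyr::anti_join(dropped, present, by = group_cols)
  if (nrow(lost) > 0L)
    warn(sprintf("%d sample(s) with zero parent cells dropped", nrow(lost)))
  dat |>
    dplyr::count(dplyr::across(dplyr::all_of(group_cols)),
                 cluster = .data[[cluster_col]], name = "n") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::mutate(n_parent = sum(.data$n),
                  fraction = .data$n / .data$n_parent) |>
    dplyr::ungroup()
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control; adjusted values are monotone,
#' order-preserving and never smaller than the raw p-values.
#'
#' @param pvalues Numeric vector in `[0, 1]` (`NA` allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    abort("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Run one of the pipeline's hypothesis tests
#'
#' A uniform front end to the tests used throughout the analysis. Wilcoxon
#' tests use exact enumeration of the permutation null when samples are small
#' (< 50) and tie-free, and the tie-corrected normal approximation with
#' continuity correction otherwise; zero differences in the signed-rank test
#' are dropped (Wilcoxon's convention). The test is always an explicit
#' choice, never auto-selected from normality checks.
#'
#' @param x Numeric vector, or a blocks x groups matrix for `friedman`.
#' @param y Second sample (ignored for `friedman`; required otherwise —
#'   for paired tests, paired with `x` element-wise).
#' @param test One of `"wilcoxon_signed_rank"`, `"wilcoxon_rank_sum"`,
#'   `"t_paired"`, `"t_two_sample"`, `"friedman"`.
#' @param alternative `"two_sided"`, `"less"` or `"greater"`.
#' @return An object of class `imc_test` with `statistic`, `p_value`,
#'   `method`, `alternative`, `n`, and the underlying `htest`.
#' @export
run_test <- function(x, y = NULL,
                     test = c("wilcoxon_signed_rank", "wilcoxon_rank_sum",
                              "t_paired", "t_two_sample", "friedman"),
                     alternative = c("two_sided", "less", "greater")) {
  test <- match.arg(test)
  alternative <- match.arg(alternative)
  alt <- sub("two_sided", "two.sided", alternative, fixed = TRUE)
  ht <- switch(test,
    wilcoxon_signed_rank = {
      if (is.null(y)) abort("signed-rank test needs paired samples x and y")
      if (all(x == y)) {
        # all differences zero: no evidence against the null
        return(new_imc_test(NA_real_, 1, test, alternative, length(x), NULL))
      }
      suppressWarnings(wilcox.test(x, y, paired = TRUE, alternative = alt))
    },
    wilcoxon_rank_sum =
      suppressWarnings(wilcox.test(x, y, alternative = alt)),
    t_paired = t.test(x, y, paired = TRUE, alternative = alt),
    t_two_sample = t.test(x, y, alternative = alt, var.equal = FALSE),
    friedman = {
      if (!is.matrix(x)) abort("friedman test needs a blocks x groups matrix")
      friedman.test(x)
    }
  )
  n <- if (test == "friedman") nrow(x) else length(x)
  p <- ht$p.value
  if (is.nan(p)) p <- 1  # fully tied samples: no evidence either way
  new_imc_test(unname(ht$statistic), p, test, alternative, n, ht)
}

new_imc_test <- function(statistic, p_value, method, alternative, n, htest) {
  structure(list(statistic = statistic, p_value = p_value, method = method,
                 alternative = alternative, n = n, htest = htest),
            class = "imc_test")
}

#' @export
print.imc_test <- function(x, ...) {
  cat(sprintf("<imc_test> %s (%s): statistic = %s, p = %.4g, n = %d\n",
              x$method, x$alternative,
              format(x$statistic, digits = 4), x$p_value, x$n))
  invisible(x)
}

#' Tidy an `imc_test`
#' @param x An [run_test()] result.
#' @param ... Unused.
#' @return One-row tibble with `method`, `alternative`, `statistic`,
#'   `p_value`, `n`.
#' @export
tidy.imc_test <- function(x, ...) {
  tibble(method = x$method, alternative = x$alternative,
         statistic = x$statistic, p_value = x$p_value, n = x$n)
}

#' @rdname tidy.imc_test
#' @export
glance.imc_test <- function(x, ...) tidy(x)

#' Test one cluster's frequency between two conditions
#'
#' Convenience wrapper: pivots a [cluster_frequencies()] table to paired
#' per-patient fractions for one cluster and runs the requested test on
#' tissue-type contrast (e.g. tumor vs adjacent).
#'
#' @param freqs A [cluster_frequencies()] result with `patient_id` and
#'   `tissue_type` columns.
#' @param cluster Cluster label to test.
#' @param tissues Length-2 character: the two tissue levels, compared as
#'   `tissues[1]` vs `tissues[2]`.
#' @inheritParams run_test
#' @return An `imc_test`.
#' @export
test_cluster_frequency <- function(freqs, cluster,
                                   tissues = c("tumor", "adjacent"),
                                   test = "wilcoxon_signed_rank",
                                   alternative = "two_sided") {
  wide <- freqs |>
    dplyr::filter(.data$cluster == !!cluster,
                  .data$tissue_type %in% tissues) |>
    dplyr::select("patient_id", "tissue_type", "fraction") |>
    tidyr::pivot_wider(names_from = "tissue_type",
                       values_from = "fraction", values_fill = 0)
  for (tt in tissues) if (!tt %in% names(wide)) wide[[tt]] <- 0
  run_test(wide[[tissues[1]]], wide[[tissues[2]]],
           test = test, alternative = alternative)
}
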