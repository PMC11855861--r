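# Group comparisons of demand parameters. The default is the classic
# pooled-variance Student t test (df = n_a + n_b - 2), which is what a
# 12-subject, 6-per-group design with df = 10 implies; Welch is available
# behind a flag. P-values are two-sided. No multiple-testing correction is
# applied across the four parameter tests.

#' Two-sample t comparison of a demand parameter
#'
#' @param values_a,values_b Parameter values for the two groups (>= 2 finite
#'   values each).
#' @param parameter Optional label (e.g. `"ev"`) carried into the result.
#' @param pooled If `TRUE` (default) the pooled-variance Student test;
#'   otherwise Welch.
#' @return List of class `param_comparison`: `parameter`, `t_stat`, `df`,
#'   `p_value`, `mean_a`, `mean_b`, `sd_a`, `sd_b`, `n_a`, `n_b`.
#' @export
#' @examples
#' pooled_t_test(c(0.82, 0.79, 2.64, 1.81, 1.01, 4.22),
#'               c(0.09, 0.00, 0.13, 0.15, 0.19, 0.07), parameter = "ev")
pooled_t_test <- function(values_a, values_b, parameter = NA_character_,
                          pooled = TRUE) {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) < 2L || length(b) < 2L || any(!is.finite(c(a, b))))
    stop("each group needs >= 2 finite values", call. = FALSE)
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) != mean(b))
      stop("degenerate variance: zero within-group variance with unequal means",
           call. = FALSE)
    res <- list(statistic = c(t = 0),
                parameter = c(df = length(a) + length(b) - 2L), p.value = 1)
  } else {
    res <- t.test(a, b, var.equal = pooled)
  }
  df <- unname(res$parameter)
  if (pooled) df <- as.integer(round(df)) # exact n_a + n_b - 2 for Student
  structure(list(parameter = parameter,
                 t_stat = unname(res$statistic), df = df,
                 p_value = res$p.value,
                 mean_a = mean(a), mean_b = mean(b),
                 sd_a = sd(a), sd_b = sd(b),
                 n_a = length(a), n_b = length(b)),
            class = "param_comparison")
}

#' @export
print.param_comparison <- function(x, ...) {
  cat(sprintf("%s: t = %.3f, df = %.4g, p = %.4g (means %.3f vs %.3f)\n",
              if (is.na(x$parameter)) "comparison" else x$parameter,
              x$t_stat, x$df, x$p_value, x$mean_a, x$mean_b))
  invisible(x)
}

#' Group-wise t comparisons of all demand parameters
#'
#' Runs [pooled_t_test()] for EV, Q0, Pmax and Omax between the two groups of
#' a fitted cohort.
#'
#' @param fits Data frame of fits (see [demand_fits_table()]) with columns
#'   `group`, `ev`, `q0`, `pmax` and an Omax column.
#' @param group_order Optional length-2 vector giving which group is "a"
#'   (first) and "b"; defaults to the order of appearance.
#' @param omax Which Omax to compare: `"analytic"` (default; internally
#'   consistent with EV under a shared k) or `"observed"`.
#' @return Data frame with one row per parameter mirroring the
#'   `param_comparisons.tsv` output.
#' @export
compare_groups <- function(fits, group_order = NULL, omax = "analytic") {
  fits <- as.data.frame(fits)
  glev <- group_order %||% unique(as.character(fits$group))
  if (length(glev) != 2L) stop("exactly 2 groups required", call. = FALSE)
  omax_col <- match.arg(omax, c("analytic", "observed"))
  cols <- c(ev = "ev", q0 = "q0", pmax = "pmax",
            omax = paste0("omax_", omax_col))
  out <- lapply(names(cols), function(p) {
    r <- pooled_t_test(fits[fits$group == glev[1L], cols[[p]]],
                       fits[fits$group == glev[2L], cols[[p]]], parameter = p)
    data.frame(parameter = p, t_stat = r$t_stat, df = r$df,
               p_value = r$p_value, mean_a = r$mean_a, mean_b = r$mean_b,
               sd_a = r$sd_a, sd_b = r$sd_b, group_a = glev[1L],
               group_b = glev[2L], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-group means and SDs of demand parameters
#'
#' @param fits Data frame of fits with a `group` column.
#' @param params Which parameter columns to summarize.
#' @return Data frame with one row per group x parameter (`mean`, `sd`, `n`);
#'   `sd` is `NA` for single-subject groups.
#' @export
summarize_cohort <- function(fits, params = c("q0", "alpha", "ev", "pmax",
                                              "omax_analytic")) {
  fits <- as.data.frame(fits)
  params <- intersect(params, names(fits))
  out <- list()
  for (g in unique(as.character(fits$group))) {
    sub <- fits[fits$group == g, , drop = FALSE]
    for (p in params) {
      v <- sub[[p]]
      out[[length(out) + 1L]] <- data.frame(
        group = g, parameter = p, mean = mean(v),
        sd = if (length(v) > 1L) sd(v) else NA_real_, n = length(v),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
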