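# broom-style tidiers for fitted objects.

#' Tidy a permutation-ANCOVA result
#'
#' @param x A `perm_ancova` object from [permutation_pvalue()].
#' @param ... Unused.
#' @return One-row tibble: `statistic` (the partial F), `df1`, `df2`,
#'   `p_perm`, `p_param`.
#' @method tidy perm_ancova
#' @export
tidy.perm_ancova <- function(x, ...) {
  tibble(statistic = x$f_obs, df1 = x$df1, df2 = x$df2,
         p_perm = x$p_perm, p_param = x$p_param)
}

#' Glance at a permutation-ANCOVA result
#'
#' @inheritParams tidy.perm_ancova
#' @return One-row tibble of run metadata: `n`, `n_perm`, `scheme`,
#'   `seed`.
#' @method glance perm_ancova
#' @export
glance.perm_ancova <- function(x, ...) {
  tibble(n = x$n, n_perm = x$n_perm, scheme = x$scheme,
         seed = x$seed %||% NA_integer_)
}

#' Tidy covariate-adjusted group means
#'
#' @param x An `adjusted_means` object from [adjusted_group_means()].
#' @param ... Unused.
#' @return Tibble with `group`, `estimate`, `conf_low`, `conf_high` and
#'   `conf_level`.
#' @method tidy adjusted_means
#' @export
tidy.adjusted_means <- function(x, ...) {
  out <- as_tibble(x)
  out$conf_level <- attr(x, "conf_level")
  out
}
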