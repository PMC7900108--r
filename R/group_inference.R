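# Permutation-based ANCOVA with Freedman-Lane residual permutation,
# two-level Benjamini-Hochberg FDR, post-hoc pairwise contrasts, and
# covariate-adjusted group means.

with_preserved_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Validate a cohort design table
#'
#' A design is a data frame with one row per subject: a `subject_id`
#' column, a `group` column (factor or character) and numeric covariate
#' columns (by default `age`, `sex`, `education`; sex is a 0/1 code).
#'
#' @param design Data frame of subjects.
#' @param covariates Character vector of covariate column names (may be
#'   empty for an unadjusted analysis).
#' @param min_per_group Minimum group size enforced (analysis functions
#'   require 2; loading tolerates singleton groups).
#' @return The design as a tibble with `group` as a factor, invisibly
#'   usable downstream.
#' @export
validate_design <- function(design, covariates = c("age", "sex", "education"),
                            min_per_group = 2) {
  design <- as_tibble(design)
  needed <- c("subject_id", "group", covariates)
  missing_cols <- setdiff(needed, names(design))
  if (length(missing_cols) > 0) {
    abort(paste0("design is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  design$group <- factor(design$group)
  if (any(table(design$group) < min_per_group)) {
    abort(sprintf("every group must have at least %d subject(s).",
                  min_per_group))
  }
  for (cv in covariates) {
    if (!is.numeric(design[[cv]]) || any(!is.finite(design[[cv]]))) {
      abort(sprintf("covariate '%s' must be finite numeric.", cv))
    }
  }
  design
}

# Full / reduced design matrices and their thin-Q factors for the
# partial F of the group factor given the covariates.
ancova_design <- function(design, levels = NULL,
                          covariates = c("age", "sex", "education")) {
  design <- validate_design(design, covariates)
  if (!is.null(levels)) {
    keep <- design$group %in% levels
    design <- design[keep, , drop = FALSE]
    design$group <- droplevels(design$group)
  }
  g <- nlevels(design$group)
  if (g < 2) abort("need at least two groups to compare.")
  n <- nrow(design)
  rhs_red <- if (length(covariates) > 0) {
    stats::reformulate(covariates)
  } else {
    ~1
  }
  xr <- stats::model.matrix(rhs_red, data = design)
  xf <- cbind(xr, stats::model.matrix(~group, data = design)[, -1, drop = FALSE])
  qrf <- qr(xf)
  qrr <- qr(xr)
  if (qrf$rank < ncol(xf)) {
    abort("rank-deficient design: group indicators and covariates are collinear.")
  }
  df1 <- qrf$rank - qrr$rank
  df2 <- n - qrf$rank
  if (df2 <= 0) {
    abort(sprintf("too few subjects (n = %d) for %d model parameters.",
                  n, ncol(xf)))
  }
  list(design = design, keep = design$subject_id,
       qf = qr.Q(qrf), qr_ = qr.Q(qrr), df1 = df1, df2 = df2, n = n)
}

# Mathematically tied F values (e.g. an assignment and its complement)
# can differ by ~1e-16 across code paths; ties are counted with a
# relative tolerance so permutation p-values match exact enumeration.
f_tol <- function(f) 1e-12 * max(abs(f), 1)

# Partial F for each column of Y given precomputed Q factors.
partial_f_cols <- function(y, qr_, qf, df1, df2) {
  y <- as.matrix(y)
  tot <- colSums(y^2)
  rss_red <- tot - colSums(crossprod(qr_, y)^2)
  rss_full <- tot - colSums(crossprod(qf, y)^2)
  num <- pmax(rss_red - rss_full, 0) / df1
  den <- rss_full / df2
  ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
}

#' Partial F statistic of the group factor (ANCOVA)
#'
#' Least-squares F comparing the full linear model
#' (intercept + group indicators + covariates) with the reduced model
#' (intercept + covariates):
#' \deqn{F = \frac{(RSS_{red} - RSS_{full}) / (g - 1)}
#'            {RSS_{full} / (n - g - q)}.}
#' With no covariates this is exactly the one-way ANOVA F.
#'
#' @param y Numeric outcome vector aligned with `design` rows.
#' @param design Subject table, see [validate_design()].
#' @param levels Optional subset of group levels to compare (default all).
#' @param covariates Covariate column names.
#' @return Scalar F (>= 0).
#' @export
ancova_f <- function(y, design, levels = NULL,
                     covariates = c("age", "sex", "education")) {
  ad <- subset_outcome(y, design, levels, covariates)
  partial_f_cols(ad$y, ad$d$qr_, ad$d$qf, ad$d$df1, ad$d$df2)[[1]]
}

subset_outcome <- function(y, design, levels, covariates) {
  design <- validate_design(design, covariates)
  if (length(y) != nrow(design)) {
    abort("`y` must have one value per design row.")
  }
  if (!is.null(levels)) y <- y[design$group %in% levels]
  if (any(!is.finite(y))) abort("`y` must be finite.")
  list(y = y, d = ancova_design(design, levels, covariates))
}

#' Permutation p-value for the group factor
#'
#' Permutation-based ANCOVA.  The default scheme is Freedman-Lane:
#' `y` is regressed on the covariates alone, the residual vector is
#' permuted, the covariate fit is added back, and the partial F of the
#' group factor is recomputed on each reconstructed outcome.  This keeps
#' the test calibrated when covariates differ between groups, where a
#' naive label shuffle does not.  A `"label_shuffle"` mode (permute group
#' labels, covariates fixed) is provided for comparison.  The p-value is
#' \eqn{(b + 1) / (m + 1)} with `b` the number of permuted F values at or
#' above the observed one, so it is never exactly zero.
#'
#' With `exhaustive = TRUE` (two groups, no covariates) all
#' `choose(n, n1)` group assignments are enumerated and the p-value is
#' the exact proportion of assignments whose F reaches the observed F.
#'
#' @inheritParams ancova_f
#' @param n_perm Number of random permutations (default 10000).
#' @param seed Integer seed making the result reproducible; the caller's
#'   RNG state is left untouched.
#' @param scheme `"freedman_lane"` (default) or `"label_shuffle"`.
#' @param exhaustive Enumerate all assignments instead of sampling.
#' @return A `perm_ancova` object; see [tidy.perm_ancova()].
#' @export
permutation_pvalue <- function(y, design, levels = NULL,
                               covariates = c("age", "sex", "education"),
                               n_perm = 10000, seed = NULL,
                               scheme = c("freedman_lane", "label_shuffle"),
                               exhaustive = FALSE) {
  scheme <- arg_match(scheme)
  ad <- subset_outcome(y, design, levels, covariates)
  d <- ad$d
  y <- ad$y
  f_obs <- partial_f_cols(y, d$qr_, d$qf, d$df1, d$df2)[[1]]

  if (exhaustive) {
    grp <- d$design$group
    if (nlevels(grp) != 2 || length(covariates) > 0) {
      abort("exhaustive enumeration requires two groups and no covariates.")
    }
    n1 <- sum(grp == levels(grp)[1])
    assignments <- utils::combn(d$n, n1)
    f_perm <- apply(assignments, 2, function(ix) {
      g2 <- factor(ifelse(seq_len(d$n) %in% ix, "a", "b"))
      x <- stats::model.matrix(~g2)
      q <- qr.Q(qr(x))
      q0 <- matrix(1 / sqrt(d$n), d$n, 1)
      partial_f_cols(y, q0, q, d$df1, d$df2)[[1]]
    })
    p <- mean(f_perm >= f_obs - f_tol(f_obs))
    n_perm <- ncol(assignments)
  } else {
    if (n_perm < 1) abort("`n_perm` must be >= 1.")
    f_perm <- with_preserved_seed(seed, {
      if (scheme == "freedman_lane") {
        fit_red <- d$qr_ %*% crossprod(d$qr_, y)
        res_red <- y - fit_red
        idx <- replicate(n_perm, sample.int(d$n))
        yp <- as.vector(fit_red) + matrix(res_red[idx], d$n, n_perm)
        partial_f_cols(yp, d$qr_, d$qf, d$df1, d$df2)
      } else {
        gdum <- stats::model.matrix(~group, data = d$design)[, -1, drop = FALSE]
        vapply(seq_len(n_perm), function(i) {
          perm <- sample.int(d$n)
          qf_p <- qr.Q(qr(cbind(d$qr_, gdum[perm, , drop = FALSE])))
          partial_f_cols(y, d$qr_, qf_p, d$df1, d$df2)[[1]]
        }, numeric(1))
      }
    })
    p <- (1 + sum(f_perm >= f_obs - f_tol(f_obs))) / (1 + n_perm)
  }

  structure(
    list(f_obs = f_obs, p_perm = p, n_perm = n_perm, seed = seed,
         scheme = if (exhaustive) "exhaustive" else scheme,
         df1 = d$df1, df2 = d$df2, n = d$n,
         p_param = pf(f_obs, d$df1, d$df2, lower.tail = FALSE)),
    class = "perm_ancova"
  )
}

#' @export
print.perm_ancova <- function(x, ...) {
  cat(sprintf(
    "<perm_ancova> F(%d, %d) = %.4f, p_perm = %.4g (%s, %d permutations)\n",
    x$df1, x$df2, x$f_obs, x$p_perm, x$scheme, x$n_perm
  ))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: with order statistics
#' p_(1) <= ... <= p_(m), the adjusted value for p_(i) is
#' min over j >= i of p_(j) m / j, capped at 1.  Input p-values must lie
#' in (0, 1].
#'
#' @param pvals Numeric vector of p-values.
#' @return Adjusted p-values in the original order.
#' @export
fdr_bh <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  p.adjust(pvals, method = "BH")
}

#' Post-hoc pairwise permutation ANCOVAs
#'
#' Runs [permutation_pvalue()] on every pair of group levels (subsetting
#' subjects to the pair) and adjusts the pairwise p-values with
#' Benjamini-Hochberg across the contrasts.
#'
#' @inheritParams permutation_pvalue
#' @return Tibble with one row per contrast: `contrast`, `f`, `p_perm`,
#'   `p_fdr`.
#' @export
posthoc_pairwise <- function(y, design,
                             covariates = c("age", "sex", "education"),
                             n_perm = 10000, seed = NULL,
                             scheme = "freedman_lane") {
  design <- validate_design(design, covariates)
  levs <- levels(design$group)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  res <- purrr::imap(pairs, function(pr, k) {
    pa <- permutation_pvalue(
      y, design, levels = pr, covariates = covariates, n_perm = n_perm,
      seed = if (is.null(seed)) NULL else seed + k, scheme = scheme
    )
    tibble(contrast = paste(pr, collapse = " vs "),
           f = pa$f_obs, p_perm = pa$p_perm)
  }) %>% bind_rows()
  res$p_fdr <- fdr_bh(res$p_perm)
  res
}

#' Covariate-adjusted group means with confidence intervals
#'
#' Least-squares (marginal) means: the fitted value for each group at
#' the grand mean of every covariate, from the full linear model, with a
#' t-based confidence interval (default 95%).  When the covariate
#' distribution is identical across groups these equal the raw group
#' means.
#'
#' @inheritParams ancova_f
#' @param conf_level Confidence level for the intervals.
#' @return An `adjusted_means` tibble: `group`, `estimate`, `conf_low`,
#'   `conf_high`, plus the confidence level as an attribute.
#' @export
adjusted_group_means <- function(y, design,
                                 covariates = c("age", "sex", "education"),
                                 conf_level = 0.95) {
  design <- validate_design(design, covariates)
  if (length(y) != nrow(design)) abort("`y` must have one value per design row.")
  dat <- design
  dat$.y <- y
  fml <- stats::reformulate(c("group", covariates), response = ".y")
  fit <- lm(fml, data = dat)
  # every covariate (including 0/1 sex) is held at its grand mean
  emm <- emmeans::emmeans(fit, "group", level = conf_level,
                          cov.reduce = mean, cov.keep = character(0))
  s <- as.data.frame(emm)
  out <- tibble(
    group = as.character(s$group),
    estimate = s$emmean,
    conf_low = s$lower.CL,
    conf_high = s$upper.CL
  )
  attr(out, "conf_level") <- conf_level
  class(out) <- c("adjusted_means", class(out))
  out
}

#' Group comparison of every network measure
#'
#' The full group-comparison stage: for each nodal measure, an omnibus
#' permutation ANCOVA at every node followed by Benjamini-Hochberg FDR
#' across the nodes; post-hoc pairwise permutation ANCOVAs (each with
#' its own FDR across the three contrasts) at every node, or only at
#' nodes surviving the omnibus FDR.  Global measures are analyzed
#' identically but receive no across-feature FDR (their `p_fdr` is
#' `NA`), matching the convention of reporting global tests uncorrected.
#' Zero-variance features are skipped with a warning and returned with
#' `NA` statistics.
#'
#' @param metrics Long metric table from [connectome_metrics()].
#' @param design Subject table, see [validate_design()]; every design
#'   subject must appear in `metrics`.
#' @inheritParams permutation_pvalue
#' @param posthoc `"all"` (default) to test every feature pairwise, or
#'   `"survivors"` to restrict post-hoc tests to nodes with omnibus
#'   `p_fdr` below `alpha`.
#' @param alpha Omnibus FDR threshold used when `posthoc = "survivors"`.
#' @return Tibble with one row per feature: `scope`, `measure`, `node`,
#'   `f`, `df1`, `df2`, `p_perm`, `p_param` (parametric diagnostic),
#'   `p_fdr`, and a `posthoc` list-column of contrast tibbles.
#' @export
run_nodal_group_analysis <- function(metrics, design,
                                     covariates = c("age", "sex", "education"),
                                     n_perm = 10000, seed = 1,
                                     scheme = "freedman_lane",
                                     posthoc = c("all", "survivors"),
                                     alpha = 0.05) {
  posthoc <- arg_match(posthoc)
  design <- validate_design(design, covariates)
  wide <- align_metrics(metrics, design)

  features <- wide %>%
    dplyr::distinct(.data$scope, .data$measure, .data$node)

  stats_one <- function(scope, measure, node, k) {
    y <- feature_values(wide, scope, measure, node, design$subject_id)
    if (sd(y) == 0) {
      warn(sprintf("feature %s/%s%s has zero variance; skipped.",
                   scope, measure,
                   if (is.na(node)) "" else paste0("/", node)))
      return(tibble(scope = scope, measure = measure, node = node,
                    f = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
                    p_perm = NA_real_, p_param = NA_real_,
                    posthoc = list(NULL)))
    }
    pa <- permutation_pvalue(y, design, covariates = covariates,
                             n_perm = n_perm, seed = seed + 7 * k,
                             scheme = scheme)
    tibble(scope = scope, measure = measure, node = node,
           f = pa$f_obs, df1 = pa$df1, df2 = pa$df2,
           p_perm = pa$p_perm, p_param = pa$p_param,
           posthoc = list(NULL))
  }

  res <- purrr::pmap(
    list(features$scope, features$measure, features$node,
         seq_len(nrow(features))),
    stats_one
  ) %>% bind_rows()

  # across-node FDR, separately per nodal measure; global left unadjusted
  res <- res %>%
    group_by(.data$scope, .data$measure) %>%
    mutate(p_fdr = if (dplyr::first(.data$scope) == "nodal") {
      adj <- rep(NA_real_, dplyr::n())
      ok <- !is.na(.data$p_perm)
      adj[ok] <- fdr_bh(.data$p_perm[ok])
      adj
    } else {
      NA_real_
    }) %>%
    ungroup()

  do_ph <- !is.na(res$p_perm) &
    (posthoc == "all" | (!is.na(res$p_fdr) & res$p_fdr < alpha))
  res$posthoc[do_ph] <- purrr::map(which(do_ph), function(i) {
    y <- feature_values(wide, res$scope[i], res$measure[i], res$node[i],
                        design$subject_id)
    posthoc_pairwise(y, design, covariates = covariates, n_perm = n_perm,
                     seed = seed + 7 * i + 3, scheme = scheme)
  })

  dplyr::relocate(res, "p_fdr", .after = "p_param")
}

align_metrics <- function(metrics, design) {
  metrics <- as_tibble(metrics)
  needed <- c("subject_id", "scope", "measure", "node", "value")
  if (!all(needed %in% names(metrics))) {
    abort("`metrics` must have columns subject_id, scope, measure, node, value.")
  }
  missing_subj <- setdiff(design$subject_id, metrics$subject_id)
  if (length(missing_subj) > 0) {
    abort(paste0("metrics are missing subject(s): ",
                 paste(head(missing_subj, 5), collapse = ", ")))
  }
  metrics %>% filter(.data$subject_id %in% design$subject_id)
}

feature_values <- function(metrics, scope, measure, node, subject_order) {
  rows <- metrics[metrics$scope == scope & metrics$measure == measure &
                    (if (is.na(node)) is.na(metrics$node)
                     else !is.na(metrics$node) & metrics$node == node), ]
  idx <- match(subject_order, rows$subject_id)
  if (anyNA(idx) || anyDuplicated(rows$subject_id) > 0) {
    abort(sprintf("feature %s/%s is not aligned with the design.",
                  measure, if (is.na(node)) scope else node))
  }
  rows$value[idx]
}
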