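# Partial Pearson correlations between network measures and cognitive
# scores, controlling for covariates, with FDR across nodes.

#' Partial Pearson correlation
#'
#' Correlation between `x` and `y` after removing the linear effect of
#' the covariates from both: each variable is regressed on
#' (intercept + covariates) by least squares and the Pearson correlation
#' of the two residual vectors is returned.  With no covariates this is
#' the plain Pearson correlation.
#'
#' @param x,y Numeric vectors of equal length.
#' @param covariates Optional numeric matrix or data frame of covariate
#'   columns (NULL or zero columns for an unconditioned correlation).
#' @return Scalar correlation in \[-1, 1\].
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` must have equal length.")
  z <- covariate_matrix(covariates, n)
  if (n <= ncol(z) + 2) {
    abort(sprintf("need n > q + 2 observations (n = %d, q = %d).",
                  n, ncol(z)))
  }
  xm <- cbind(1, z)
  rx <- stats::lm.fit(xm, x)$residuals
  ry <- stats::lm.fit(xm, y)$residuals
  # scale-relative: least-squares residuals of a constant are ~1e-17
  degen <- function(res, v) sd(res) <= 1e-10 * max(abs(v), 1)
  if (degen(rx, x) || degen(ry, y)) {
    abort("degenerate input: a residual vector is constant.",
          class = "strucnet_degenerate")
  }
  cor(rx, ry)
}

covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(numeric(0), n, 0))
  z <- as.matrix(as.data.frame(covariates))
  if (nrow(z) != n) abort("covariates must have one row per observation.")
  storage.mode(z) <- "double"
  if (any(!is.finite(z))) abort("covariates must be finite numeric.")
  z
}

#' Two-sided p-value for a partial correlation
#'
#' The usual t transform: with n observations and q covariates,
#' \eqn{t = r \sqrt{(n - 2 - q) / (1 - r^2)}} on n - 2 - q degrees of
#' freedom.  `|r| = 1` is returned as the smallest representable
#' positive p-value with a warning.
#'
#' @param r Partial correlation coefficient.
#' @param n Number of observations.
#' @param q Number of covariates conditioned on.
#' @return Two-sided p-value in (0, 1].
#' @export
partial_corr_pvalue <- function(r, n, q = 0) {
  if (abs(r) > 1) abort("`r` must lie in [-1, 1].")
  df <- n - 2 - q
  if (df <= 0) abort(sprintf("need n > q + 2 (n = %d, q = %d).", n, q))
  if (abs(r) == 1) {
    warn("|r| = 1: p-value is a zero limit; returning .Machine$double.xmin.")
    return(.Machine$double.xmin)
  }
  tval <- r * sqrt(df / (1 - r^2))
  2 * pt(-abs(tval), df = df)
}

#' Contrast two independent partial correlations (Fisher z)
#'
#' Descriptive comparison of the same correlation estimated in two
#' independent groups: Fisher z-transform each r, divide the difference
#' by its standard error \eqn{\sqrt{1/(n_1 - 3 - q) + 1/(n_2 - 3 - q)}},
#' and refer to the standard normal.
#'
#' @param r1,r2 Partial correlations in the two groups.
#' @param n1,n2 Effective sample sizes.
#' @param q Number of covariates conditioned on.
#' @return Tibble with `z` and two-sided `p`.
#' @export
fisher_z_contrast <- function(r1, n1, r2, n2, q = 0) {
  if (min(n1, n2) <= q + 3) abort("need n > q + 3 in both groups.")
  z1 <- atanh(r1)
  z2 <- atanh(r2)
  se <- sqrt(1 / (n1 - 3 - q) + 1 / (n2 - 3 - q))
  z <- (z1 - z2) / se
  tibble(z = z, p = 2 * pnorm(-abs(z)))
}

#' Cognitive-domain map for the standard test battery
#'
#' Assigns each analyzed cognitive score to a domain: attention,
#' executive, learning, recall-recognition, visuospatial or language.
#'
#' @return Tibble with columns `score` and `domain`.
#' @export
cognitive_domains <- function() {
  tibble(
    score = c(
      "digit_span_forward", "digit_span_backward", "trail_making_a",
      "trail_making_a_z", "trail_making_a_seconds",
      "cowat_animal", "cowat_animal_z", "cowat_market", "cowat_market_z",
      "cowat_k", "cowat_o", "cowat_s",
      "word_list_learning", "word_list_learning_z",
      "word_list_recall", "word_list_recall_z",
      "word_list_recognition", "word_list_recognition_z",
      "constructional_praxis", "constructional_praxis_z",
      "constructional_praxis_recall", "constructional_praxis_recall_z",
      "boston_naming", "boston_naming_z", "mmse", "gds"
    ),
    domain = c(
      rep("attention", 5),
      rep("executive", 7),
      rep("learning", 2),
      rep("recall-recognition", 4),
      rep("visuospatial", 4),
      rep("language", 2),
      "global", "mood"
    )
  )
}

#' Partial correlations between network measures and cognitive scores
#'
#' For each analyzed group, cognitive score and network measure, the
#' partial Pearson correlation controlling for the covariates, with the
#' t-transform p-value.  For nodal measures the p-values are
#' Benjamini-Hochberg adjusted across the nodes within each
#' (group, score, measure) family; global measures are reported with raw
#' p-values only.  Missing scores are handled by per-pair complete-case
#' reduction and the effective n is recorded; a (group, score) cell with
#' too few complete cases is skipped with a warning.
#'
#' @param metrics Long metric table from [connectome_metrics()].
#' @param scores Data frame with `subject_id` and one numeric column per
#'   cognitive score (`NA` for missing).
#' @param design Subject table, see [validate_design()].
#' @param groups Group levels to analyze (default: the two patient
#'   groups if the design uses the standard labels, otherwise all).
#' @param covariates Covariate column names controlled for.
#' @return Tibble with columns `group`, `score`, `scope`, `measure`,
#'   `node`, `r`, `p`, `p_fdr` (`NA` for global rows) and `n_effective`.
#' @export
run_correlation_analysis <- function(metrics, scores, design,
                                     groups = NULL,
                                     covariates = c("age", "sex", "education")) {
  design <- validate_design(design, covariates)
  scores <- as_tibble(scores)
  if (!"subject_id" %in% names(scores)) {
    abort("`scores` must have a subject_id column.")
  }
  score_names <- setdiff(names(scores), "subject_id")
  if (is.null(groups)) {
    patient <- grep("MCI", levels(design$group), value = TRUE)
    groups <- if (length(patient) > 0) patient else levels(design$group)
  }
  wide <- align_metrics(metrics, design)
  features <- wide %>% dplyr::distinct(.data$scope, .data$measure, .data$node)
  q <- length(covariates)

  out <- list()
  for (grp in groups) {
    dsub <- design[design$group == grp, , drop = FALSE]
    zfull <- as.matrix(dsub[, covariates, drop = FALSE])
    for (sc in score_names) {
      svals <- scores[[sc]][match(dsub$subject_id, scores$subject_id)]
      ok <- is.finite(svals)
      if (sum(ok) <= q + 2) {
        warn(sprintf("group '%s', score '%s': only %d complete cases; skipped.",
                     grp, sc, sum(ok)))
        next
      }
      cell <- purrr::pmap(
        list(features$scope, features$measure, features$node),
        function(scope, measure, node) {
          y <- feature_values(wide, scope, measure, node, dsub$subject_id)
          use <- ok & is.finite(y)
          n_eff <- sum(use)
          if (n_eff <= q + 2) {
            return(tibble(group = grp, score = sc, scope = scope,
                          measure = measure, node = node, r = NA_real_,
                          p = NA_real_, n_effective = n_eff))
          }
          r <- tryCatch(
            partial_correlation(y[use], svals[use],
                                zfull[use, , drop = FALSE]),
            strucnet_degenerate = function(e) NA_real_
          )
          p <- if (is.na(r)) NA_real_ else partial_corr_pvalue(r, n_eff, q)
          tibble(group = grp, score = sc, scope = scope, measure = measure,
                 node = node, r = r, p = p, n_effective = n_eff)
        }
      ) %>% bind_rows()
      out[[length(out) + 1]] <- cell
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) return(res)

  # FDR family = the nodes within one (group, score, nodal measure)
  res %>%
    group_by(.data$group, .data$score, .data$scope, .data$measure) %>%
    mutate(p_fdr = if (dplyr::first(.data$scope) == "nodal") {
      adj <- rep(NA_real_, dplyr::n())
      ok <- !is.na(.data$p)
      adj[ok] <- fdr_bh(.data$p[ok])
      adj
    } else {
      NA_real_
    }) %>%
    ungroup() %>%
    dplyr::relocate("p_fdr", .after = "p") %>%
    arrange(.data$group, .data$score, dplyr::desc(.data$scope), .data$measure)
}
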