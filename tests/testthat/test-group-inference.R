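# Partial-F machinery, Freedman-Lane permutation test, BH adjustment,
# post-hoc contrasts and adjusted means, each against an independent
# oracle.

two_group_design <- function(y1, y2, covars = NULL) {
  n <- length(y1) + length(y2)
  d <- tibble::tibble(
    subject_id = sprintf("s%02d", seq_len(n)),
    group = rep(c("a", "b"), c(length(y1), length(y2)))
  )
  if (!is.null(covars)) d <- dplyr::bind_cols(d, covars)
  d
}

test_that("partial F matches the normal-equations oracle and nests one-way ANOVA", {
  # equal group means, no covariates -> F exactly 0
  d <- two_group_design(1:3, 1:3)
  expect_equal(ancova_f(c(1, 2, 3, 1, 2, 3), d, covariates = character(0)), 0)

  withr::with_seed(5, {
    # no covariates: identical to the classical one-way ANOVA F
    g1 <- rnorm(6); g2 <- rnorm(7, 0.5); g3 <- rnorm(5, 1)
    y <- c(g1, g2, g3)
    d3 <- tibble::tibble(subject_id = sprintf("s%02d", 1:18),
                         group = rep(c("a", "b", "c"), c(6, 7, 5)))
    expect_equal(ancova_f(y, d3, covariates = character(0)),
                 oneway_anova_f(list(g1, g2, g3)), tolerance = 1e-12)

    # 12-subject fixture with one covariate vs explicit least squares
    cov1 <- rnorm(12)
    y12 <- rnorm(12) + 0.8 * cov1
    d12 <- tibble::tibble(subject_id = sprintf("s%02d", 1:12),
                          group = rep(c("a", "b", "c"), each = 4),
                          age = cov1)
    expect_equal(ancova_f(y12, d12, covariates = "age"),
                 partial_f_oracle(y12, d12$group, cov1), tolerance = 1e-10)

    # full covariate set on a realistic design
    dd <- make_design()
    yy <- rnorm(nrow(dd)) + 0.05 * dd$age
    expect_equal(
      ancova_f(yy, dd),
      partial_f_oracle(yy, dd$group, as.matrix(dd[, c("age", "sex", "education")])),
      tolerance = 1e-10
    )
    # and against R's own model comparison
    full <- lm(yy ~ group + age + sex + education, data = dd)
    red <- lm(yy ~ age + sex + education, data = dd)
    expect_equal(ancova_f(yy, dd), anova(red, full)$F[2], tolerance = 1e-10)
  })
})

test_that("degenerate designs error informatively", {
  d <- two_group_design(1:3, 1:3, tibble::tibble(age = rep(1, 6)))
  expect_error(ancova_f(rnorm(6), d, covariates = "age"), "rank-deficient")
  d2 <- two_group_design(1:2, 1:2, tibble::tibble(age = rnorm(4),
                                                  x2 = rnorm(4)))
  expect_error(ancova_f(rnorm(4), d2, covariates = c("age", "x2")),
               "too few subjects")
})

test_that("permutation p equals exhaustive enumeration for 3 vs 3", {
  withr::with_seed(9, {
    y <- c(2.1, 3.4, 1.7, 4.0, 5.2, 4.4)
    d <- two_group_design(y[1:3], y[4:6])
    pa <- permutation_pvalue(y, d, covariates = character(0),
                             exhaustive = TRUE)
    expect_equal(pa$n_perm, 20)
    # oracle: enumerate all 20 assignments of 3 labels, classical F
    fs <- apply(utils::combn(6, 3), 2, function(ix) {
      oneway_anova_f(list(y[ix], y[-ix]))
    })
    f_obs <- oneway_anova_f(list(y[1:3], y[4:6]))
    expect_equal(pa$f_obs, f_obs, tolerance = 1e-12)
    expect_equal(pa$p_perm, mean(fs >= f_obs - 1e-12 * max(f_obs, 1)))
  })
})

test_that("permutation p is bounded, reproducible and rank-based", {
  d <- make_design()
  withr::with_seed(13, y <- rnorm(nrow(d)))
  pa1 <- permutation_pvalue(y, d, n_perm = 200, seed = 4)
  pa2 <- permutation_pvalue(y, d, n_perm = 200, seed = 4)
  expect_identical(pa1, pa2)
  expect_gte(pa1$p_perm, 1 / 201)
  expect_lte(pa1$p_perm, 1)

  # p depends on F only through ranks: a monotone transform of y that
  # preserves the linear model (affine) leaves p unchanged
  pa3 <- permutation_pvalue(2.5 * y + 7, d, n_perm = 200, seed = 4)
  expect_equal(pa1$p_perm, pa3$p_perm)

  # sex coding choice does not affect the F statistic
  d2 <- d
  d2$sex <- 1 - d2$sex
  expect_equal(ancova_f(y, d), ancova_f(y, d2))

  # label-shuffle mode runs and is reproducible
  pl <- permutation_pvalue(y, d, n_perm = 100, seed = 5,
                           scheme = "label_shuffle")
  expect_identical(pl,
                   permutation_pvalue(y, d, n_perm = 100, seed = 5,
                                      scheme = "label_shuffle"))
})

test_that("tidy and glance expose the permutation-ANCOVA result", {
  d <- make_design()
  withr::with_seed(1, y <- rnorm(nrow(d)))
  pa <- permutation_pvalue(y, d, n_perm = 50, seed = 2)
  td <- tidy(pa)
  expect_named(td, c("statistic", "df1", "df2", "p_perm", "p_param"))
  expect_equal(td$df2, nrow(d) - 3 - 3)
  gl <- glance(pa)
  expect_equal(gl$scheme, "freedman_lane")
  expect_equal(gl$n_perm, 50)
})

test_that("BH adjustment matches hand computations and its invariants", {
  expect_equal(fdr_bh(0.37), 0.37)
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(c(0.002, 0.9, 0.95)), c(0.006, 0.95, 0.95))
  expect_equal(fdr_bh(rep(0.2, 5)), rep(0.2, 5))
  expect_error(fdr_bh(c(0.1, 0)), "0, 1")
  expect_error(fdr_bh(c(0.1, 1.2)), "0, 1")

  withr::with_seed(17, {
    for (rep in 1:10) {
      p <- runif(sample(2:30, 1))
      adj <- fdr_bh(p)
      expect_true(all(adj >= p))            # never decreases
      expect_true(all(diff(adj[order(p)]) >= -1e-15))  # order preserved
      expect_true(all(adj <= 1))
    }
  })
})

test_that("post-hoc contrasts separate the affected pairs under a planted effect", {
  d <- make_design()
  withr::with_seed(23, {
    y <- rnorm(nrow(d))
    y[d$group == "LLD-MCI-A+"] <- y[d$group == "LLD-MCI-A+"] + 2.5
  })
  ph <- posthoc_pairwise(y, d, n_perm = 199, seed = 3)
  expect_equal(nrow(ph), 3)
  expect_equal(ph$p_fdr, fdr_bh(ph$p_perm))
  involving <- grepl("LLD-MCI-A\\+", ph$contrast)
  expect_true(max(ph$p_perm[involving]) < min(ph$p_perm[!involving]))
})

test_that("adjusted means equal the explicit least-squares-means oracle", {
  d <- make_design()
  withr::with_seed(29, y <- 50 + 0.4 * d$age - 1.1 * d$education +
                     rnorm(nrow(d), sd = 3))
  am <- adjusted_group_means(y, d)
  expect_s3_class(am, "adjusted_means")
  expect_true(all(am$conf_low <= am$estimate & am$estimate <= am$conf_high))

  # oracle: prediction at the grand covariate mean, explicit algebra
  x <- stats::model.matrix(~ group + age + sex + education,
                           data = dplyr::mutate(d, group = factor(group)))
  beta <- solve(crossprod(x), crossprod(x, y))
  sigma2 <- sum((y - x %*% beta)^2) / (nrow(x) - ncol(x))
  xtx_inv <- solve(crossprod(x))
  for (k in 1:3) {
    l <- c(1, as.numeric(k == 2), as.numeric(k == 3),
           mean(d$age), mean(d$sex), mean(d$education))
    est <- sum(l * beta)
    se <- sqrt(drop(t(l) %*% xtx_inv %*% l) * sigma2)
    tcrit <- qt(0.975, nrow(x) - ncol(x))
    expect_equal(am$estimate[k], est, tolerance = 1e-10)
    expect_equal(am$conf_low[k], est - tcrit * se, tolerance = 1e-8)
    expect_equal(am$conf_high[k], est + tcrit * se, tolerance = 1e-8)
  }

  # identical covariate distributions across groups -> raw group means
  d0 <- tibble::tibble(subject_id = sprintf("s%02d", 1:12),
                       group = rep(c("a", "b", "c"), each = 4),
                       age = rep(c(60, 65, 70, 75), 3),
                       sex = rep(c(0, 1, 0, 1), 3),
                       education = rep(c(8, 10, 12, 16), 3))
  withr::with_seed(31, y0 <- rnorm(12))
  am0 <- adjusted_group_means(y0, d0)
  expect_equal(am0$estimate, as.numeric(tapply(y0, d0$group, mean)),
               tolerance = 1e-10)

  # outcome exactly linear in age, no group effect -> equal adjusted means
  y1 <- 2 + 0.5 * d$age
  am1 <- suppressWarnings(adjusted_group_means(y1, d))  # perfect fit
  expect_equal(diff(range(am1$estimate)), 0, tolerance = 1e-10)
})

test_that("the full group analysis adjusts nodal measures across nodes only", {
  d <- make_design(n = c(7, 8, 8), seed = 3)
  withr::with_seed(37, {
    conns <- purrr::map(seq_len(nrow(d)), function(i) {
      conn <- random_connectome(8, density = 0.8)
      connectome(conn$weights, subject_id = d$subject_id[i])
    })
  })
  m <- connectome_metrics(conns)
  res <- suppressWarnings(
    run_nodal_group_analysis(m, d, n_perm = 49, seed = 1)
  )
  nodal <- dplyr::filter(res, scope == "nodal", measure == "strength",
                         !is.na(p_perm))
  expect_equal(nodal$p_fdr, fdr_bh(nodal$p_perm))
  expect_true(all(is.na(res$p_fdr[res$scope == "global"])))
  expect_true(all(res$p_fdr >= res$p_perm, na.rm = TRUE))
  # post-hoc present with its own 3-contrast FDR
  ph <- res$posthoc[[which(!is.na(res$p_perm))[1]]]
  expect_equal(nrow(ph), 3)
  expect_equal(ph$p_fdr, fdr_bh(ph$p_perm))
  # reproducible end to end
  res2 <- suppressWarnings(
    run_nodal_group_analysis(m, d, n_perm = 49, seed = 1)
  )
  expect_identical(res, res2)

  # constant feature: flagged and skipped, not crashed
  m_const <- m
  m_const$value[m_const$measure == "strength" &
                  m_const$node == "node_1"] <- 5
  expect_warning(
    res3 <- run_nodal_group_analysis(
      dplyr::filter(m_const, measure == "strength"), d,
      n_perm = 19, seed = 1
    ),
    "zero variance"
  )
  row1 <- dplyr::filter(res3, node == "node_1")
  expect_true(is.na(row1$f))

  # misaligned tables error
  expect_error(
    run_nodal_group_analysis(dplyr::filter(m, subject_id != "s01"), d,
                             n_perm = 9, seed = 1),
    "missing subject"
  )
})

test_that("Freedman-Lane stays calibrated under covariate confounding", {
  # null outcome that depends on the (group-confounded) covariates but
  # not on group; modest replicate count keeps this a quick check —
  # the stringent version lives with the acceptance suite
  d <- make_design()
  n_rep <- 60
  rej <- withr::with_seed(41, {
    sum(vapply(seq_len(n_rep), function(i) {
      y <- 0.08 * d$age - 0.1 * d$education + rnorm(nrow(d))
      permutation_pvalue(y, d, n_perm = 199, seed = 1000 + i)$p_perm < 0.05
    }, logical(1)))
  })
  expect_lte(rej, qbinom(0.999, n_rep, 0.05))
})

test_that("power rises with the planted effect size", {
  d <- make_design()
  mean_p <- vapply(c(0.5, 1.5, 3), function(eff) {
    ps <- withr::with_seed(43, {
      vapply(1:8, function(i) {
        y <- rnorm(nrow(d))
        y[d$group == "HOA"] <- y[d$group == "HOA"] + eff
        permutation_pvalue(y, d, n_perm = 99, seed = 500 + i)$p_perm
      }, numeric(1))
    })
    mean(ps)
  }, numeric(1))
  expect_true(mean_p[1] > mean_p[3])
  expect_true(all(diff(mean_p) <= 0.05))  # monotone up to small noise
})
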