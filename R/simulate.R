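# Synthetic cohorts with the statistical structure the analysis assumes:
# three groups with realistic covariate confounding, streamline-count-like
# connectomes with planted group effects at chosen nodes, and cognitive
# scores linked to chosen network measures at a target partial
# correlation given the covariates.

#' Simulation configuration
#'
#' Defaults emulate the study design: groups HOA / LLD-MCI-A+ /
#' LLD-MCI-A- of sizes 21/26/27; per-group age and education moments and
#' sex proportions as published; 90-node networks at density 0.30 with
#' log-normal streamline-count-like weights (so nodal strengths land in
#' the published ~600-2700 range); age mildly depressing all weights
#' (covariate confounding, since the patient groups are older); a
#' planted additive nodal-strength effect of 11 weight units per
#' incident edge at the left calcarine in the amyloid-positive group
#' (sized from the published ~290-unit strength gap over ~27 incident
#' edges); and one cognitive score linked to the right mid-cingulum's
#' regional efficiency at partial r = 0.5 in the amyloid-positive group
#' only.
#'
#' @param group_labels,group_sizes Group names and sizes.
#' @param age_moments,education_moments Data frames with `mean`, `sd`
#'   per group (rows in `group_labels` order).
#' @param sex_male_prop Probability of male (coded 1) per group.
#' @param n_nodes,density Network size and target edge density.
#' @param node_labels Node names (default: 90-region parcellation).
#' @param weight_meanlog,weight_sdlog Log-normal edge-weight parameters.
#' @param noise_cv Per-edge subject noise SD as a fraction of the
#'   template weight.
#' @param age_leak Relative weight change per year of age (negative:
#'   older subjects have globally weaker connections).
#' @param effects Data frame of planted group effects: `node`, `group`,
#'   `size` (additive weight units on each existing incident edge).
#' @param score_links Data frame of planted brain-behaviour links:
#'   `score`, `measure` (a nodal measure name or a global one), `node`
#'   (`NA` for global), `group`, `r` (target partial correlation given
#'   the covariates).
#' @param score_scale Conditional SD of each score given the covariates.
#' @param score_noise_floor Minimum residual noise SD for scores; a
#'   target `r` requiring less noise than this is rejected as
#'   infeasible.
#' @param score_cov_coefs Named coefficients through which covariates
#'   leak into every score.
#' @return A `sim_config` list.
#' @export
sim_config <- function(
    group_labels = c("HOA", "LLD-MCI-A+", "LLD-MCI-A-"),
    group_sizes = c(21L, 26L, 27L),
    age_moments = data.frame(mean = c(68.86, 76.85, 76.07),
                             sd = c(4.60, 7.30, 5.41)),
    education_moments = data.frame(mean = c(13.33, 6.92, 6.37),
                                   sd = c(4.23, 4.42, 4.36)),
    sex_male_prop = c(12 / 21, 4 / 26, 2 / 27),
    n_nodes = 90L,
    node_labels = NULL,
    density = 0.30,
    weight_meanlog = log(40),
    weight_sdlog = 0.8,
    noise_cv = 0.2,
    age_leak = -0.008,
    effects = data.frame(node = "Calcarine_L", group = "LLD-MCI-A+",
                         size = 11),
    score_links = data.frame(score = "word_list_recall_z",
                             measure = "efficiency",
                             node = "Cingulum_Mid_R",
                             group = "LLD-MCI-A+", r = 0.5),
    score_scale = 1,
    score_noise_floor = 0.2,
    score_cov_coefs = c(age = -0.03, sex = 0, education = 0.03)) {
  if (any(group_sizes < 2)) abort("every group needs at least 2 subjects.")
  if (density <= 0 || density > 1) abort("`density` must lie in (0, 1].")
  if (!is.null(score_links) && nrow(score_links) > 0 &&
      any(abs(score_links$r) >= 1)) {
    abort("target partial correlations must satisfy |r| < 1.")
  }
  if (is.null(node_labels)) {
    node_labels <- if (n_nodes == 90L) aal90_labels()
    else paste0("node_", seq_len(n_nodes))
  }
  if (length(node_labels) != n_nodes) {
    abort("`node_labels` must have length `n_nodes`.")
  }
  structure(
    list(group_labels = group_labels, group_sizes = as.integer(group_sizes),
         age_moments = age_moments, education_moments = education_moments,
         sex_male_prop = sex_male_prop, n_nodes = as.integer(n_nodes),
         node_labels = node_labels, density = density,
         weight_meanlog = weight_meanlog, weight_sdlog = weight_sdlog,
         noise_cv = noise_cv, age_leak = age_leak,
         effects = effects, score_links = score_links,
         score_scale = score_scale, score_noise_floor = score_noise_floor,
         score_cov_coefs = score_cov_coefs),
    class = "sim_config"
  )
}

#' Simulate cohort covariates
#'
#' Draws per-group age and education from normal distributions with the
#' configured moments and sex from per-group Bernoulli proportions.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A `synthetic_cohort`: list with a `subjects` tibble
#'   (`subject_id`, `group`, `age`, `sex`, `education`), empty
#'   `connectomes`, the `config`, and a `ground_truth` ledger.
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1) {
  if (any(config$age_moments$sd < 0) || any(config$education_moments$sd < 0)) {
    abort("covariate SDs must be >= 0.")
  }
  subjects <- with_preserved_seed(seed, {
    purrr::imap(config$group_labels, function(gl, k) {
      n <- config$group_sizes[k]
      tibble(
        group = gl,
        age = rnorm(n, config$age_moments$mean[k], config$age_moments$sd[k]),
        sex = rbinom(n, 1, config$sex_male_prop[k]),
        education = rnorm(n, config$education_moments$mean[k],
                          config$education_moments$sd[k])
      )
    }) %>% bind_rows()
  })
  subjects <- subjects %>%
    mutate(subject_id = sprintf("sub%03d", dplyr::row_number()),
           group = factor(.data$group, levels = config$group_labels)) %>%
    select("subject_id", "group", "age", "sex", "education")
  structure(
    list(subjects = subjects, connectomes = NULL, config = config,
         ground_truth = list(seed_cohort = seed)),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d subjects in %d groups; connectomes: %s; scores: %s\n",
    nrow(x$subjects), nlevels(x$subjects$group),
    if (is.null(x$connectomes)) "none" else length(x$connectomes),
    if (any(!names(x$subjects) %in%
            c("subject_id", "group", "age", "sex", "education")))
      "yes" else "none"
  ))
  invisible(x)
}

# Shared group-independent template: a seeded geometric layout (nodes
# uniform in the unit cube, the closest pairs connected up to the target
# density) with log-normal edge weights.
simulate_template <- function(config, seed) {
  with_preserved_seed(seed, {
    n <- config$n_nodes
    pos <- matrix(runif(3 * n), n, 3)
    d <- as.matrix(stats::dist(pos))
    m <- round(config$density * choose(n, 2))
    dv <- d[upper.tri(d)]
    thr <- sort(dv)[m]
    adj <- (d <= thr) & upper.tri(d)
    w <- matrix(0, n, n)
    w[adj] <- rlnorm(sum(adj), config$weight_meanlog, config$weight_sdlog)
    w + t(w)
  })
}

#' Simulate connectomes for a cohort
#'
#' Each subject's matrix is the shared template scaled by an age leak
#' term (`1 + age_leak * (age - reference age)`), plus independent
#' Gaussian edge noise with SD `noise_cv` times the template weight,
#' plus the planted additive effects on the configured nodes' existing
#' incident edges for the configured groups.  Negative weights are
#' clipped to zero and the clip rate is recorded in the ground-truth
#' ledger.
#'
#' @param cohort A `synthetic_cohort` from [simulate_cohort()].
#' @param seed Integer seed (template and noise both derive from it).
#' @return The cohort with `connectomes` filled and `ground_truth`
#'   extended (`template`, `clip_rate`, `effects`).
#' @export
simulate_connectomes <- function(cohort, seed = 2) {
  config <- cohort$config
  labels <- config$node_labels
  eff <- config$effects
  if (!is.null(eff) && nrow(eff) > 0 && !all(eff$node %in% labels)) {
    abort(paste0("effect spec names unknown node(s): ",
                 paste(setdiff(eff$node, labels), collapse = ", ")))
  }
  template <- simulate_template(config, seed)
  ut <- upper.tri(template)
  edge_idx <- which(ut & template > 0)
  age_ref <- sum(config$age_moments$mean * config$group_sizes) /
    sum(config$group_sizes)

  n_clipped <- 0L
  n_total <- 0L
  conns <- with_preserved_seed(seed + 1, {
    purrr::pmap(cohort$subjects, function(subject_id, group, age, sex,
                                          education, ...) {
      mult <- 1 + config$age_leak * (age - age_ref)
      w <- template * mult
      if (config$noise_cv > 0) {
        noise <- rnorm(length(edge_idx),
                       sd = config$noise_cv * template[edge_idx])
        w[edge_idx] <- w[edge_idx] + noise
      }
      w[lower.tri(w)] <- 0
      if (!is.null(eff) && nrow(eff) > 0) {
        for (i in seq_len(nrow(eff))) {
          if (eff$group[i] != as.character(group)) next
          v <- match(eff$node[i], labels)
          touch <- template[v, ] > 0
          # additive bump on every existing incident edge, upper triangle
          w[v, touch & seq_along(touch) > v] <-
            w[v, touch & seq_along(touch) > v] + eff$size[i]
          w[touch & seq_along(touch) < v, v] <-
            w[touch & seq_along(touch) < v, v] + eff$size[i]
        }
      }
      n_total <<- n_total + length(edge_idx)
      n_clipped <<- n_clipped + sum(w[edge_idx] < 0)
      w[w < 0] <- 0
      w <- w + t(w)
      connectome(w, node_labels = labels, subject_id = subject_id)
    })
  })
  cohort$connectomes <- conns
  cohort$ground_truth$template <- template
  cohort$ground_truth$effects <- eff
  cohort$ground_truth$clip_rate <- if (n_total > 0) n_clipped / n_total else 0
  cohort$ground_truth$seed_connectomes <- seed
  cohort
}

link_measure_values <- function(cohort, measure, node) {
  vapply(cohort$connectomes, function(conn) {
    switch(measure,
      degree = as.numeric(nodal_degree(conn)[[node]]),
      strength = nodal_strength(conn)[[node]],
      clustering = nodal_clustering(conn)[[node]],
      efficiency = regional_efficiency(conn)[[node]],
      edge_density = edge_density(conn),
      total_strength = total_strength(conn),
      clustering_coefficient = global_clustering(conn),
      characteristic_path_length = characteristic_path_length(conn),
      small_worldness = small_worldness(conn),
      abort(sprintf("unknown linked measure '%s'.", measure))
    )
  }, numeric(1))
}

#' Simulate cognitive scores for a cohort
#'
#' Each configured score is a linear function of covariates plus noise;
#' in its linked group it additionally loads on the linked network
#' measure with a slope solved so the partial correlation given the
#' covariates equals the target `r`: with conditional score SD `v`, the
#' measure contributes `r * v` of SD and the residual noise
#' `v * sqrt(1 - r^2)`.  A target whose implied noise falls below the
#' configured noise floor is rejected with the feasible bound.
#'
#' @param cohort A `synthetic_cohort` with connectomes.
#' @param seed Integer seed.
#' @return The cohort with score columns appended to `subjects` and the
#'   solved slopes recorded in `ground_truth$score_links`.
#' @export
simulate_scores <- function(cohort, seed = 3) {
  if (is.null(cohort$connectomes)) {
    abort("simulate connectomes before scores (linked measures are computed).")
  }
  config <- cohort$config
  links <- config$score_links
  if (is.null(links) || nrow(links) == 0) return(cohort)
  v <- config$score_scale
  r_max <- sqrt(max(0, 1 - (config$score_noise_floor / v)^2))
  if (any(abs(links$r) > r_max)) {
    abort(sprintf(
      "target |r| exceeds the feasible bound %.4f at noise floor %.3g.",
      r_max, config$score_noise_floor
    ))
  }
  subj <- cohort$subjects
  cov_ref <- c(age = sum(config$age_moments$mean * config$group_sizes) /
                 sum(config$group_sizes),
               sex = mean(subj$sex),
               education = sum(config$education_moments$mean *
                                 config$group_sizes) /
                 sum(config$group_sizes))
  cc <- config$score_cov_coefs
  cov_term <- cc[["age"]] * (subj$age - cov_ref[["age"]]) +
    cc[["sex"]] * (subj$sex - cov_ref[["sex"]]) +
    cc[["education"]] * (subj$education - cov_ref[["education"]])

  solved <- list()
  scores <- with_preserved_seed(seed, {
    purrr::pmap(links, function(score, measure, node, group, r, ...) {
      y <- cov_term + rnorm(nrow(subj), sd = v)
      beta <- 0
      if (r != 0) {
        in_grp <- subj$group == group
        m <- link_measure_values(cohort, measure, node)
        z <- as.matrix(subj[in_grp, c("age", "sex", "education")])
        m_res <- stats::lm.fit(cbind(1, z), m[in_grp])$residuals
        sd_m <- sd(m_res)
        if (sd_m == 0) abort("linked measure has no residual variance.")
        beta <- r * v / sd_m
        sigma <- v * sqrt(1 - r^2)
        y[in_grp] <- cov_term[in_grp] +
          beta * (m[in_grp] - mean(m[in_grp])) +
          rnorm(sum(in_grp), sd = sigma)
      }
      solved[[score]] <<- list(beta = beta, r = r, measure = measure,
                               node = node, group = group)
      setNames(list(y), score)
    })
  })
  for (s in scores) cohort$subjects[[names(s)]] <- s[[1]]
  cohort$ground_truth$score_links <- solved
  cohort$ground_truth$seed_scores <- seed
  cohort
}

#' Simulate a full synthetic study
#'
#' Chains [simulate_cohort()], [simulate_connectomes()] and
#' [simulate_scores()] with sub-seeds derived from one master seed, so
#' the entire study (covariates, matrices, scores, ground-truth ledger)
#' is reproducible from `(config, seed)`.
#'
#' @inheritParams simulate_cohort
#' @return A complete `synthetic_cohort`.
#' @export
simulate_study <- function(config = sim_config(), seed = 1) {
  simulate_cohort(config, seed = seed) %>%
    simulate_connectomes(seed = seed * 1000L + 1L) %>%
    simulate_scores(seed = seed * 1000L + 2L)
}
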