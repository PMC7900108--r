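# Independent oracles and graph fixtures used across tests.  These are
# deliberately naive (Floyd-Warshall, exhaustive triple enumeration,
# explicit normal equations) so they share no code with the package.

# Build a connectome from an edge list: edges = matrix/data.frame with
# columns i, j, w (1-based indices).
edge_connectome <- function(n, edges = NULL, subject_id = "test") {
  w <- matrix(0, n, n)
  if (!is.null(edges) && nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      w[edges[k, 1], edges[k, 2]] <- edges[k, 3]
      w[edges[k, 2], edges[k, 1]] <- edges[k, 3]
    }
  }
  connectome(w, subject_id = subject_id)
}

complete_connectome <- function(n, weight = 1) {
  w <- matrix(weight, n, n)
  diag(w) <- 0
  connectome(w)
}

# weighted triangle with w01 = 1, w02 = 0.5, w12 = 0.5 (a recurring
# worked example)
uneven_triangle <- function() {
  edge_connectome(3, rbind(c(1, 2, 1), c(1, 3, 0.5), c(2, 3, 0.5)))
}

random_connectome <- function(n, density = 0.5, max_weight = 1) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < density) {
        w[i, j] <- w[j, i] <- runif(1, 0.05, max_weight)
      }
    }
  }
  connectome(w)
}

# Floyd-Warshall all-pairs shortest paths on lengths 1/w.
floyd_warshall_oracle <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  d[w > 0] <- 1 / w[w > 0]
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Onnela clustering by exhaustive enumeration of ordered neighbour
# pairs.
clustering_oracle <- function(w, normalize = FALSE) {
  if (normalize && max(w) > 0) w <- w / max(w)
  n <- nrow(w)
  vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    tot <- 0
    for (j in nb) {
      for (h in nb) {
        if (j != h) tot <- tot + (w[i, j] * w[i, h] * w[j, h])^(1 / 3)
      }
    }
    tot / (k * (k - 1))
  }, numeric(1))
}

# Partial F of the group factor by explicit normal equations.
partial_f_oracle <- function(y, group, covars = NULL) {
  g <- factor(group)
  xf <- cbind(1, stats::model.matrix(~g)[, -1, drop = FALSE])
  xr <- matrix(1, length(y), 1)
  if (!is.null(covars)) {
    covars <- as.matrix(covars)
    xf <- cbind(xf, covars)
    xr <- cbind(xr, covars)
  }
  rss <- function(x) {
    beta <- solve(t(x) %*% x, t(x) %*% y)
    sum((y - x %*% beta)^2)
  }
  df1 <- nlevels(g) - 1
  df2 <- length(y) - ncol(xf)
  ((rss(xr) - rss(xf)) / df1) / (rss(xf) / df2)
}

# Standard three-group design with study-like covariate confounding
# (patient groups older and less educated than controls).
make_design <- function(n = c(21, 26, 27), seed = 42) {
  withr::with_seed(seed, {
    tibble::tibble(
      subject_id = sprintf("s%02d", seq_len(sum(n))),
      group = rep(c("HOA", "LLD-MCI-A+", "LLD-MCI-A-"), n),
      age = c(rnorm(n[1], 68.9, 4.6), rnorm(n[2], 76.9, 7.3),
              rnorm(n[3], 76.1, 5.4)),
      sex = c(rbinom(n[1], 1, 12 / 21), rbinom(n[2], 1, 4 / 26),
              rbinom(n[3], 1, 2 / 27)),
      education = c(rnorm(n[1], 13.3, 4.2), rnorm(n[2], 6.9, 4.4),
                    rnorm(n[3], 6.4, 4.4))
    )
  })
}
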