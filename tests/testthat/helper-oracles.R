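# Brute-force Calinski-Harabasz oracle via the pairwise-distance identity:
# within-group dispersion W_g = (1/(2 n_g)) * sum_{i,j in g} ||x_i - x_j||^2
# and total dispersion likewise, so B = T - W. No centroids are formed,
# making this an independent route to the same quantity.
ch_oracle <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  d2 <- as.matrix(dist(X))^2
  total <- sum(d2) / (2 * n)
  ids <- unique(labels)
  within <- 0
  for (g in ids) {
    idx <- which(labels == g)
    within <- within + sum(d2[idx, idx]) / (2 * length(idx))
  }
  between <- total - within
  k <- length(ids)
  (between / (k - 1)) / (within / (n - k))
}

# Exhaustive minimum-inertia 2-partition of a small point set.
best_two_partition_inertia <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    grp <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    if (!any(grp) || all(grp)) next
    inertia <- 0
    for (g in list(which(grp), which(!grp))) {
      Xi <- X[g, , drop = FALSE]
      inertia <- inertia + sum(sweep(Xi, 2, colMeans(Xi))^2)
    }
    best <- min(best, inertia)
  }
  best
}

# A small, fast scenario for pipeline-level tests.
small_scenario <- function(seed = 1, n_regions = 6, n_categories = 3,
                           samples = 12, n_tiers = 3) {
  scenario_config(n_regions = n_regions, n_categories = n_categories,
                  samples_per_combination = samples, n_tiers = n_tiers,
                  seed = seed)
}

# The published 20-region x 9-category risk-level grid used as a fixture for
# the proportion and ranking operations (regions in presentation order;
# columns: leafy, root and potato, melon, brassica, solanaceous, legume,
# bean sprouts, fresh edible fungus, bulb).
published_level_grid <- function() {
  regions <- c("Shanghai", "Inner Mongolia", "Beijing", "Jilin", "Sichuan",
               "Ningxia", "Guangdong", "Guangxi", "Jiangsu", "Jiangxi",
               "Hebei", "Henan", "Zhejiang", "Hubei", "Hunan", "Fujian",
               "Liaoning", "Shanxi", "Qinghai", "Heilongjiang")
  lv <- rbind(
    c(1, 1, 2, 1, 1, 1, 2, 5, 2),
    c(1, 2, 2, 1, 2, 1, 1, 2, 2),
    c(2, 1, 1, 1, 1, 1, 1, 2, 2),
    c(1, 2, 1, 1, 1, 1, 1, 1, 1),
    c(2, 3, 2, 1, 2, 2, 2, 5, 2),
    c(1, 1, 1, 1, 2, 2, 2, 1, 2),
    c(1, 1, 1, 1, 1, 1, 4, 1, 2),
    c(2, 1, 1, 1, 1, 1, 1, 1, 2),
    c(1, 1, 2, 1, 1, 1, 1, 3, 1),
    c(1, 1, 1, 1, 2, 1, 1, 1, 2),
    c(1, 1, 1, 1, 2, 1, 1, 1, 2),
    c(1, 1, 1, 1, 2, 1, 1, 3, 2),
    c(1, 2, 2, 1, 2, 1, 2, 3, 2),
    c(1, 1, 2, 1, 1, 1, 1, 3, 1),
    c(1, 1, 3, 1, 2, 1, 2, 1, 2),
    c(1, 3, 1, 1, 3, 1, 1, 1, 2),
    c(2, 1, 1, 1, 2, 1, 1, 3, 1),
    c(2, 2, 1, 1, 2, 1, 1, 5, 2),
    c(1, 1, 2, 1, 1, 1, 2, 1, 1),
    c(1, 1, 2, 1, 2, 1, 1, 2, 2)
  )
  cats <- c("leafy", "root and potato", "melon", "brassica", "solanaceous",
            "legume", "bean sprouts", "fresh edible fungus", "bulb")
  tibble::tibble(
    region = rep(regions, each = length(cats)),
    category = rep(cats, times = length(regions)),
    risk_level = as.integer(t(lv))
  )
}

# Classic non-convex geometry: a ring of points around a central blob.
ring_and_blob <- function(n_ring = 24, n_blob = 12, radius = 5, seed = 11) {
  withr::with_seed(seed, {
    theta <- seq(0, 2 * pi, length.out = n_ring + 1)[-1]
    ring <- cbind(radius * cos(theta), radius * sin(theta)) +
      matrix(rnorm(2 * n_ring, sd = 0.05), ncol = 2)
    blob <- matrix(rnorm(2 * n_blob, sd = 0.3), ncol = 2)
  })
  list(X = rbind(ring, blob),
       membership = rep(1:2, c(n_ring, n_blob)))
}
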