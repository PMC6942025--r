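# Shared fixture builders: everything is generated in code at test time.

# A small synthetic world, cheap enough for per-test simulation.
small_world <- function(seed = 1, rows = 20, cols = 20, years = 2011:2012,
                        variables = c("T13", "P06"), noise_scale = 0.3) {
  world_config(rows = rows, cols = cols, years = years,
               variables = variables, noise_scale = noise_scale, seed = seed)
}

# A labelled feature table of two Gaussian point clouds in covariate space.
# `sep` is the between-class mean shift in units of the within-class sd.
two_cloud_table <- function(n_per_class = 20, sep = 10, sd = 1, seed = 1,
                            vars = c("v1", "v2")) {
  withr::with_seed(seed, {
    mk <- function(role, mu, species) {
      cols <- lapply(seq_along(vars), function(i) rnorm(n_per_class, mu, sd))
      names(cols) <- vars
      tibble::tibble(species = species, role = role,
                     year = 2011L, x = runif(n_per_class),
                     y = runif(n_per_class), !!!cols)
    }
    dplyr::bind_rows(mk("invasive", 0, "inv"), mk("native", sep * sd, "nat"))
  })
}

# Both classes drawn from one distribution: no separable signal.
null_table <- function(n_per_class = 200, seed = 1, vars = c("v1", "v2")) {
  two_cloud_table(n_per_class, sep = 0, seed = seed, vars = vars)
}

# A feature table with one informative variable among pure-noise candidates.
informative_table <- function(n_per_class = 60, n_noise = 7, sep = 3, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    tab <- tibble::tibble(
      species = rep(c("inv", "nat"), each = n_per_class),
      role = rep(c("invasive", "native"), each = n_per_class),
      year = 2011L, x = runif(n), y = runif(n),
      signal = c(rnorm(n_per_class, 0), rnorm(n_per_class, sep))
    )
    for (i in seq_len(n_noise)) tab[[paste0("noise", i)]] <- rnorm(n)
    tab
  })
}

# A tiny climate stack built from explicit matrices.
tiny_stack <- function(layers, year = 2011, cell_size = 1) {
  climate_stack(layers, year = year, cell_size = cell_size)
}

# Exact two-sided Mann-Whitney p-value from the exact U distribution built
# by dynamic programming (counts of subsets of {1..n1+n2} of size n1 by rank
# sum) — independent of R's pwilcox. Tie-free samples only.
dp_mw_pvalue <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  u_obs <- sum(outer(x, y, ">"))
  N <- n1 + n2
  # ways[[j + 1]][s + 1] = number of j-subsets of ranks seen so far with sum s
  max_sum <- sum((N - n1 + 1):N)
  ways <- lapply(0:n1, function(j) numeric(max_sum + 1))
  ways[[1]][1] <- 1
  for (r in 1:N) {
    for (j in min(r, n1):1) {
      prev <- ways[[j]]
      shifted <- c(numeric(r), prev[1:(max_sum + 1 - r)])
      ways[[j + 1]] <- ways[[j + 1]] + shifted
    }
  }
  counts <- ways[[n1 + 1]]
  sums <- which(counts > 0) - 1
  u_vals <- sums - n1 * (n1 + 1) / 2
  probs <- counts[counts > 0] / sum(counts)
  p <- 2 * min(sum(probs[u_vals <= u_obs]), sum(probs[u_vals >= u_obs]))
  min(p, 1)
}

# Exact two-sided Mann-Whitney p-value by complete enumeration of all
# assignments of ranks to the first sample (independent oracle; tie-free
# samples only).
exact_mw_pvalue <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  u_obs <- sum(outer(x, y, ">"))
  combos <- utils::combn(n1 + n2, n1)
  ranks <- rank(c(x, y))
  us <- apply(combos, 2, function(idx) sum(ranks[idx]) - n1 * (n1 + 1) / 2)
  # two-sided: double the smaller tail (U distribution is symmetric)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(p, 1)
}
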