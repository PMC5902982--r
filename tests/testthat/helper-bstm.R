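# Shared fixtures, all built in code.

# small complete panel: R regions x T years of plausible counts
toy_panel <- function(R = 2, T = 3, seed = 1) {
  set.seed(seed)
  regions <- paste0("R", seq_len(R))
  years <- seq(2000L, length.out = T)
  tibble::tibble(
    region = rep(regions, each = T),
    year = rep(years, times = R),
    pop_total = rep(10000L, R * T),
    pop_65plus = stats::rpois(R * T, 800))
}

# ring graph over the given regions (every node has exactly 2 neighbours)
ring_graph <- function(regions) {
  k <- length(regions)
  adjacency_from_edges(
    data.frame(from = regions, to = regions[c(2:k, 1)]), regions)
}

# random connected graph on n nodes: a spanning tree plus extra edges
random_graph <- function(n, seed) {
  set.seed(seed)
  regions <- paste0("N", seq_len(n))
  from <- to <- character(0)
  for (i in 2:n) {            # spanning tree
    j <- sample(i - 1, 1)
    from <- c(from, regions[i]); to <- c(to, regions[j])
  }
  extra <- sample(n, 2)
  if (extra[1] != extra[2]) {
    from <- c(from, regions[extra[1]]); to <- c(to, regions[extra[2]])
  }
  adjacency_from_edges(data.frame(from = from, to = to), regions)
}

# random full parameter state on a given layout (for invariance checks)
random_state <- function(R, T, seed) {
  set.seed(seed)
  bstm:::new_state(
    R, T,
    alpha = stats::rnorm(1), b0 = stats::rnorm(1, 0, 0.05),
    c2 = stats::rnorm(1, 0, 0.01),
    s_struct = stats::rnorm(R, 0, 0.2), s_unstruct = stats::rnorm(R, 0, 0.1),
    v = stats::rnorm(T, 0, 0.05),
    b1_struct = stats::rnorm(R, 0, 0.01),
    b1_unstruct = stats::rnorm(R, 0, 0.01),
    b2_struct = stats::rnorm(R, 0, 0.002),
    b2_unstruct = stats::rnorm(R, 0, 0.002),
    eps = matrix(stats::rnorm(R * T, 0, 0.02), R, T),
    u = matrix(stats::rgamma(R * T, 50, 50), R, T),
    r = stats::runif(1, 5, 50),
    sigma = c(s_struct = 0.2, s_unstruct = 0.1, v = 0.05,
              b1_struct = 0.01, b1_unstruct = 0.01,
              b2_struct = 0.002, b2_unstruct = 0.002, eps = 0.02))
}

# brute-force Moran's I: explicit double sum with row-standardised weights
morans_i_bruteforce <- function(values, graph) {
  nodes <- graph$nodes
  N <- length(nodes)
  z <- values - mean(values)
  num <- 0; s0 <- 0
  for (i in seq_len(N)) {
    nb <- match(graph$neighbours[[nodes[i]]], nodes)
    w <- 1 / length(nb)
    for (j in nb) {
      num <- num + w * z[i] * z[j]
      s0 <- s0 + w
    }
  }
  (N / s0) * num / sum(z^2)
}

# the recovery-scale fit is expensive; build it once per test run
recovery_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      truth <- default_truth("provincial")
      panel <- simulate_panel(truth, seed = 7)
      fit <- fit_bstm(panel, truth$graph, bstm_spec(),
                      bstm_control(profile = "test", seed = 2))
      cache <<- list(truth = truth, panel = panel, fit = fit)
    }
    cache
  }
})
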