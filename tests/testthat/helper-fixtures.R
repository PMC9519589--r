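# Hand-built trees, independent oracles and scaled-down simulator configs
# shared across the test files.

# three-cell tree: root A (bipotent evidence via one Mk and one E leaf)
toy_mixed_tree <- function() {
  traj <- function(t0, t1, x0 = 0) {
    data.frame(frame = 0:1 + round(t0), time = c(t0, t1), x = c(x0, x0 + 1),
               y = 0)
  }
  lineage_tree(list(
    A = cell_record("A", NA, 0, 30, "divided", character(),
                    traj(0, 30), c("B", "C")),
    B = cell_record("B", "A", 30, 45, "movie_end", "CD41", traj(30, 45)),
    C = cell_record("C", "A", 30, 45, "movie_end", "CD71bright",
                    traj(30, 45))))
}

# chain of maintenance_E divisions ending in exhaustion:
# A -(maint E)-> {B bipotent, E1} ; B -(exhaustion)-> {E2, M1}
toy_chain_tree <- function() {
  traj <- function(t0, t1) data.frame(frame = c(round(t0 * 10),
                                                round(t1 * 10)),
                                      time = c(t0, t1), x = 0, y = 0)
  lineage_tree(list(
    A = cell_record("A", NA, 0, 20, "divided", character(), traj(0, 20),
                    c("B", "E1")),
    B = cell_record("B", "A", 20, 40, "divided", character(), traj(20, 40),
                    c("E2", "M1")),
    E1 = cell_record("E1", "A", 20, 60, "movie_end", "CD71bright",
                     traj(20, 60)),
    E2 = cell_record("E2", "B", 40, 60, "movie_end", "CD235a", traj(40, 60)),
    M1 = cell_record("M1", "B", 40, 55, "endomitosis", character(),
                     traj(40, 55))))
}

# brute-force motility oracles, deliberately loop-based and separate from
# the package's vectorized implementations
oracle_total_distance <- function(tr) {
  s <- 0
  for (i in seq_len(nrow(tr) - 1L))
    s <- s + sqrt((tr$x[i + 1L] - tr$x[i])^2 + (tr$y[i + 1L] - tr$y[i])^2)
  s
}
oracle_diffusion_distance <- function(tr) {
  n <- nrow(tr)
  sqrt((tr$x[n] - tr$x[1L])^2 + (tr$y[n] - tr$y[1L])^2)
}
oracle_peak_velocity <- function(tr) {
  best <- 0
  for (i in seq_len(nrow(tr) - 1L)) {
    v <- sqrt((tr$x[i + 1L] - tr$x[i])^2 + (tr$y[i + 1L] - tr$y[i])^2) /
      (tr$time[i + 1L] - tr$time[i])
    if (v > best) best <- v
  }
  best
}

random_trajectory <- function(n = NULL) {
  if (is.null(n)) n <- sample(2:60, 1L)
  # mixed 2 h and 10 min intervals, like the acquisition schedule
  dt <- sample(c(2, 1 / 6), n - 1L, replace = TRUE)
  data.frame(frame = seq_len(n) - 1L, time = cumsum(c(0, dt)),
             x = cumsum(stats::rnorm(n, sd = 3)),
             y = cumsum(stats::rnorm(n, sd = 3)))
}

# adjusted Rand index (independent reference implementation)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  exp_idx <- sum_a * sum_b / ch2(n)
  max_idx <- (sum_a + sum_b) / 2
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

no_death <- c(root_predivision = 0, bipotent = 0, E_destined = 0,
              Mk_destined = 0, ErP = 0, MkP = 0)

# scaled-down simulator configuration: coarser late frames, shorter movies
# and shallow committed lineages keep colonies small while preserving the
# generative structure
small_config <- function(seed, n_roots = 20L, ...) {
  args <- list(seed = seed, n_roots = n_roots, movie_hours = 200,
               late_interval = 2, e_commit_max_gen = 2L)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synthetic_config, args)
}
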