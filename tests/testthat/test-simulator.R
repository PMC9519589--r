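test_that("forced outcomes shape colonies as configured", {
  always_exhaust <- mep_markov_params(alpha = c(maintenance_E = -30,
                                                maintenance_Mk = -30,
                                                exhaustion = 30))
  cfg <- small_config(seed = 1, n_roots = 8, death = no_death,
                      outcome_model = always_exhaust,
                      exhaustion_mode = "mixed_pair",
                      e_commit_max_gen = 1L,
                      mk_mature_probs = 1)
  sim <- generate_colonies(cfg)
  for (tree in sim$trees) {
    root <- tree$cells[[tree$root_id]]
    expect_length(root$children, 2L)
    kid_states <- sim$truth$true_state[sim$truth$colony == tree$root_id &
                                       sim$truth$cell_id %in% root$children]
    expect_setequal(kid_states, c("E_destined", "Mk_destined"))
  }
  # all roots dying: only no_colony calls
  cfg2 <- small_config(seed = 2, n_roots = 10,
                       death = c(root_predivision = 1, bipotent = 0,
                                 E_destined = 0, Mk_destined = 0,
                                 ErP = 0, MkP = 0))
  sim2 <- generate_colonies(cfg2)
  eff <- colony_efficiency(sim2$trees)
  expect_equal(eff$forming_efficiency, 0)
  expect_equal(eff$death_frequency, 1)
})

test_that("generation and truth bookkeeping are mutually consistent", {
  cfg <- small_config(seed = 3, n_roots = 10)
  sim <- generate_colonies(cfg)
  # every emitted cell has truth and vice versa
  ids_trees <- unlist(lapply(sim$trees, function(t) names(t$cells)))
  expect_setequal(ids_trees, sim$truth$cell_id)
  for (tree in sim$trees) {
    gi <- generation_index(tree)
    tt <- sim$truth[sim$truth$colony == tree$root_id, ]
    expect_equal(unname(gi[tt$cell_id]), tt$generation)
    divd <- tt$generation[tt$true_state == "bipotent" &
                          tt$end_event == "divided"]
    if (length(divd)) expect_lte(max(divd), cfg$G_max)
  }
})

test_that("datasets are byte-reproducible and round-trip through read_tracks", {
  cfg <- small_config(seed = 4, n_roots = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- generate_dataset(cfg, d1)
  f2 <- generate_dataset(cfg, d2)
  for (k in names(f1)) {
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]]),
                     info = paste("file", k))
  }
  expect_error(generate_dataset(cfg, d1), "overwrite")

  trees <- read_tracks(f1[["tracks"]], f1[["lineage"]])
  expect_length(trees, 5L)
  orig <- generate_colonies(cfg)$trees
  names(trees) <- vapply(trees, function(t) t$root_id, character(1))
  for (ot in orig) {
    rt <- trees[[ot$root_id]]
    expect_setequal(names(rt$cells), names(ot$cells))
    for (id in names(ot$cells)) {
      expect_identical(rt$cells[[id]]$children, ot$cells[[id]]$children)
      expect_identical(rt$cells[[id]]$markers, ot$cells[[id]]$markers)
      expect_equal(rt$cells[[id]]$trajectory$time,
                   ot$cells[[id]]$trajectory$time, tolerance = 1e-9)
    }
  }
  # empty cohort still writes valid headered files
  f0 <- generate_dataset(small_config(seed = 5, n_roots = 0),
                         withr::local_tempdir())
  expect_equal(length(readLines(f0[["tracks"]])), 1L)
})

test_that("exhaustion mode controls whether single-lineage colonies can occur", {
  low_expansion <- mep_markov_params(alpha = c(maintenance_E = -2,
                                               maintenance_Mk = -2,
                                               exhaustion = 2))
  base <- list(seed = 6, n_roots = 40, death = no_death,
               outcome_model = low_expansion)
  mixed <- do.call(small_config, c(base, exhaustion_mode = "mixed_pair"))
  indep <- do.call(small_config, c(base, exhaustion_mode = "independent_draws"))
  sim_m <- generate_colonies(mixed)
  sim_i <- generate_colonies(indep)
  # realized lineage content: a mixed-pair exhaustion always deposits both
  # lineages, so every exhausted root stays truth-bipotent; independent
  # draws produce single-lineage colonies from genuinely bipotent roots
  root_label <- function(sim) {
    vapply(sim$trees, function(t)
      sim$truth$true_fate_label[sim$truth$colony == t$root_id &
                                sim$truth$cell_id == t$root_id],
      character(1))
  }
  exhausted <- function(sim) {
    vapply(sim$trees, function(t)
      any(sim$events$colony == t$root_id &
          sim$events$outcome == "exhaustion"), logical(1))
  }
  expect_true(all(root_label(sim_m)[exhausted(sim_m)] == "bipotent"))
  expect_true(any(root_label(sim_i) %in% c("E_destined", "Mk_destined")))
  # and at the marker level, single-lineage colony calls do occur
  calls_indep <- colony_efficiency(sim_i$trees)$calls
  expect_true(any(calls_indep %in% c("E_only", "Mk_only")))
})

test_that("condition variants shift death, cycling and exhaustion as configured", {
  base <- small_config(seed = 7)
  for (cond in c("noTPO", "noEPO")) {
    v <- condition_variant(base, cond)
    expect_equal(v$condition, cond)
    expect_true(all(v$death >= base$death))
    expect_true(all(v$cycle_mean >= base$cycle_mean))
    expect_equal(v$pi_E, base$pi_E)
    expect_gt(first_division_exhaustion(v$outcome_model),
              first_division_exhaustion(base$outcome_model))
  }
  expect_true(condition_variant(base, "noEPO")$cd235a_suppressed)
  expect_error(condition_variant(base, "noIL3"), "unknown condition")
  expect_error(condition_variant(condition_variant(base, "noTPO"), "noEPO"),
               "control")
})

test_that("acquisition schedule is sparse early and dense late", {
  cfg <- synthetic_config(seed = 1, movie_hours = 168)
  t <- acquisition_times(cfg)
  expect_true(all(diff(t) > 0))
  expect_equal(t[1], 0)
  expect_equal(t[2], 24)
  expect_true(all(abs(diff(t[t >= 24 & t <= 60]) - 2) < 1e-9))
  expect_true(all(abs(diff(t[t > 60]) - 1 / 6) < 1e-9))
  expect_lte(max(t), 168)
})
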