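test_that("death rates divide deaths by resolved same-state cells", {
  # 10 E-destined cells at generation 2, one death
  traj <- function(t0, t1) data.frame(frame = round(c(t0, t1) * 10),
                                      time = c(t0, t1), x = 0, y = 0)
  cells <- list(A = cell_record("A", NA, 0, 20, "divided",
                                trajectory = traj(0, 20),
                                children = c("B", "C")))
  cells$B <- cell_record("B", "A", 20, 40, "died", "CD71bright", traj(20, 40))
  cells$C <- cell_record("C", "A", 20, 40, "movie_end", "CD71bright",
                         traj(20, 40))
  tree <- lineage_tree(cells)
  d <- death_rate_by_state(tree, "E_destined")
  # censored C excluded by default: denominator 1
  expect_equal(d$rate[d$generation == 2], 1)
  d2 <- death_rate_by_state(tree, "E_destined", include_censored = TRUE)
  expect_equal(d2$rate[d2$generation == 2], 0.5)
  # no deaths -> all zeros
  expect_true(all(death_rate_by_state(toy_chain_tree(), "E_destined")$rate == 0))
})

test_that("expansion table doubles under pure expansion and is flat under maintenance", {
  # maintenance chain: bipotent count 1 at each generation
  chain <- toy_chain_tree()
  tab <- expansion_by_generation(chain)$summary
  bip <- tab[tab$state == "bipotent", ]
  # one bipotent cell at every generation until the terminal exhaustion
  expect_equal(bip$mean[order(bip$generation)], c(1, 1, 0))

  # two-generation full expansion: 1, 2 bipotent cells
  cells <- list(r = cell_record("r", NA, 0, 20, "divided",
                                children = c("a", "b")))
  for (k in c("a", "b")) {
    kk <- paste0(k, 1:2)
    cells[[k]] <- cell_record(k, "r", 20, 40, "divided", children = kk)
    for (k2 in kk)
      cells[[k2]] <- cell_record(k2, k, 40, 60, "movie_end",
                                 if (k2 %in% c("a1", "b1")) "CD41"
                                 else "CD235a")
  }
  tab <- expansion_by_generation(lineage_tree(cells))$summary
  bip <- tab[tab$state == "bipotent", ]
  expect_equal(bip$mean[order(bip$generation)][1:2], c(1, 2))
})

test_that("division outcome table aggregates classified events with totals", {
  trees <- list(toy_mixed_tree(), toy_chain_tree())
  tab <- division_outcome_table(trees)
  expect_equal(sum(tab$exhaustion), 2)
  expect_equal(sum(tab$maintenance_E), 1)
  expect_equal(sum(tab$total), 3)
  expect_equal(attr(tab, "excluded"), 0L)
  # conservation: totals equal classified bipotent divisions
  n_div <- sum(vapply(trees, function(t) {
    ev <- classify_divisions(t)
    sum(ev$outcome != "non_MEP")
  }, numeric(1)))
  expect_equal(sum(tab$total), n_div)
})

test_that("commitment frequency counts committed daughters", {
  # chain tree: daughters E1 (maintenance), E2 + M1 (exhaustion) -> 2 E, 1 Mk
  cf <- commitment_frequency(toy_chain_tree())
  expect_equal(cf$n_E, 2L)
  expect_equal(cf$n_Mk, 1L)
  expect_equal(cf$frac_E, 2 / 3)
  expect_true(cf$defined)
  # no committed daughters -> undefined, flagged
  single <- lineage_tree(list(A = cell_record("A", NA, 0, 10, "lost")))
  cf <- commitment_frequency(single)
  expect_false(cf$defined)
  expect_true(is.nan(cf$frac_E))
})

test_that("colony calls partition trees and efficiency counts roots", {
  mixed <- toy_mixed_tree()
  expect_equal(classify_colony(mixed), "MkE_mixed")
  mk <- mixed; mk$cells$C$markers <- "CD41"
  expect_equal(classify_colony(mk), "Mk_only")
  e <- mixed; e$cells$B$markers <- "CD235a"
  expect_equal(classify_colony(e), "E_only")
  dead <- lineage_tree(list(A = cell_record("A", NA, 0, 5, "died")))
  expect_equal(classify_colony(dead), "no_colony")

  trees <- list(mixed, mk, e, dead, dead)
  eff <- colony_efficiency(trees)
  expect_equal(eff$forming_efficiency, 3 / 5)
  expect_equal(eff$death_frequency, 2 / 5)
  # partition: every tree gets exactly one call
  expect_length(eff$calls, 5L)
  expect_true(all(eff$calls %in% c("MkE_mixed", "E_only", "Mk_only",
                                   "no_colony")))
})

test_that("condition comparison runs t-tests and ANOVA with sane nulls", {
  set.seed(5)
  base <- data.frame(condition = rep(c("a", "b"), each = 50),
                     m = stats::rnorm(100))
  # identical groups: p near 1 is not guaranteed, but mean difference ~ 0
  same <- base; same$m <- rep(stats::rnorm(50), 2)
  res <- compare_conditions(same, "m")
  expect_equal(res$mean_a, res$mean_b)
  expect_equal(res$p, 1)
  # 10 SD shift: decisive
  shift <- base
  shift$m[base$condition == "b"] <- shift$m[base$condition == "b"] + 10
  res <- compare_conditions(shift, "m")
  expect_lt(res$p, 1e-6)
  # three groups -> ANOVA
  three <- data.frame(condition = rep(c("a", "b", "c"), each = 30),
                      m = stats::rnorm(90) + rep(c(0, 0, 5), each = 30))
  res <- compare_conditions(three, "m")
  expect_equal(res$method, "anova")
  expect_lt(res$p, 1e-6)
  # tiny group skipped with warning
  tiny <- data.frame(condition = c("a", rep("b", 10)),
                     m = stats::rnorm(11))
  expect_warning(res <- compare_conditions(tiny, "m"), "skipped")
  expect_null(res)
})
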