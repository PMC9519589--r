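test_that("read_tracks reconstructs trees and infers end events", {
  f <- withr::local_tempfile(fileext = ".tsv")
  # single cell, 5 frames, no children -> one tree, movie_end
  writeLines(c(
    "frame\ttime_h\tcell_id\tparent_id\tx_um\ty_um\tend_event\tmarkers",
    paste(0:4, c(0, 24, 26, 28, 30), "A", "", 0:4, 0, "", "", sep = "\t")),
    f)
  trees <- read_tracks(f)
  expect_length(trees, 1L)
  expect_length(trees[[1]]$cells, 1L)
  expect_equal(trees[[1]]$cells$A$end_event, "movie_end")

  # root with two daughters appearing at the next frame
  rows <- c(
    "frame\ttime_h\tcell_id\tparent_id\tx_um\ty_um\tend_event\tmarkers",
    paste(0:10, seq(0, 30, 3), "A", "", 0, 0, "", "", sep = "\t"),
    paste(11:12, c(33, 36), "B", "A", 1, 0, "", "", sep = "\t"),
    paste(11:12, c(33, 36), "C", "A", -1, 0, c("", "died"), "", sep = "\t"))
  writeLines(rows, f)
  trees <- read_tracks(f)
  expect_length(trees, 1L)
  tree <- trees[[1]]
  expect_equal(tree$cells$A$end_event, "divided")
  expect_setequal(tree$cells$A$children, c("B", "C"))
  expect_equal(tree$cells$B$end_event, "movie_end")
  expect_equal(tree$cells$C$end_event, "died")
  expect_length(tree_leaves(tree), 2L)

  # unresolvable parent errors, naming the offender
  writeLines(c(
    "frame\ttime_h\tcell_id\tparent_id\tx_um\ty_um\tend_event\tmarkers",
    paste(0:1, c(0, 24), "D", "Z", 0, 0, "", "", sep = "\t")), f)
  expect_error(read_tracks(f), "Z")
})

test_that("tree validation rejects malformed structures", {
  good <- toy_mixed_tree()
  expect_silent(validate <- generation_index(good))
  # child born before parent's end
  bad <- good
  bad$cells$B$birth_time <- 10
  bad$cells$B$trajectory$time[1] <- 10
  expect_error(lineage_tree(bad$cells), "born before parent")
  # three children
  bad <- good
  bad$cells$A$children <- c("B", "C", "B")
  expect_error(lineage_tree(bad$cells), "> 2")
})

test_that("fate labels back-propagate terminal identity", {
  tree <- toy_mixed_tree()
  lab <- assign_fate_labels(tree)
  expect_equal(unname(lab["A"]), "bipotent")
  expect_equal(unname(lab["B"]), "Mk_destined")
  expect_equal(unname(lab["C"]), "E_destined")

  # all-E progeny: every internal cell E-destined, even from a sorted MEP
  tree$cells$B$markers <- "CD235a"
  lab <- assign_fate_labels(tree)
  expect_true(all(lab == "E_destined"))

  # no evidence anywhere -> indeterminate
  single <- lineage_tree(list(A = cell_record("A", NA, 0, 10, "lost")))
  expect_equal(unname(assign_fate_labels(single)["A"]), "indeterminate")

  # double-positive leaf is ambiguous: indeterminate, logged, no error
  amb <- toy_mixed_tree()
  amb$cells$B$markers <- c("CD41", "CD71bright")
  expect_message(lab <- assign_fate_labels(amb), "ambiguous")
  expect_equal(unname(lab["B"]), "indeterminate")
  expect_equal(attr(lab, "ambiguous"), "B")

  # sorted committed roots map to committed labels
  erp <- toy_mixed_tree()
  erp$cells$B$markers <- "CD71bright"
  erp$root_type <- "ErP"
  lab <- assign_fate_labels(erp)
  expect_true(all(lab == "committed_ErP"))

  # idempotence: relabeling changes nothing
  expect_identical(assign_fate_labels(tree), assign_fate_labels(tree))
})

test_that("division outcomes classify per the daughter-label rule", {
  # exhaustion: one E-destined + one Mk-destined daughter
  tree <- toy_mixed_tree()
  ev <- classify_divisions(tree)
  expect_equal(ev$outcome, "exhaustion")
  expect_equal(ev$generation, 1L)
  expect_equal(attr(ev, "excluded"), 0L)

  # maintenance then exhaustion along a chain
  chain <- toy_chain_tree()
  ev <- classify_divisions(chain)
  expect_equal(ev$outcome[order(ev$generation)],
               c("maintenance_E", "exhaustion"))

  # indeterminate daughter -> excluded, tallied, no error
  part <- toy_mixed_tree()
  part$cells$C$markers <- character()
  ev <- classify_divisions(part)
  expect_equal(nrow(ev), 0L)
  expect_equal(attr(ev, "excluded"), 1L)
})

test_that("generation index counts from 1 down a binary tree", {
  tree <- toy_chain_tree()
  gi <- generation_index(tree)
  expect_equal(unname(gi[c("A", "B", "E2")]), c(1L, 2L, 3L))
  # full binary depth-3 tree: generations 1..3 with counts 1,2,4
  cells <- list(r = cell_record("r", NA, 0, 10, "divided",
                                children = c("a", "b")))
  for (k in c("a", "b")) {
    kk <- paste0(k, c("1", "2"))
    cells[[k]] <- cell_record(k, "r", 10, 20, "divided", children = kk)
    for (k2 in kk)
      cells[[k2]] <- cell_record(k2, k, 20, 30, "movie_end")
  }
  gi <- generation_index(lineage_tree(cells))
  expect_equal(as.vector(table(gi)), c(1L, 2L, 4L))
})

test_that("division sequences follow bipotent paths and flag censoring", {
  chain <- toy_chain_tree()
  seqs <- extract_division_sequences(chain)
  expect_length(seqs, 1L)
  expect_equal(seqs[[1]]$outcome, c("maintenance_E", "exhaustion"))
  expect_false(attr(seqs[[1]], "censored"))
  expect_equal(attr(seqs[[1]], "end_reason"), "exhaustion")

  # expansion then both daughters exhaust: two sequences sharing a prefix
  traj <- function(t0, t1) data.frame(frame = round(c(t0, t1)),
                                      time = c(t0, t1), x = 0, y = 0)
  mk <- function(id, p, t0, t1, ev, m = character(), kids = character())
    cell_record(id, p, t0, t1, ev, m, traj(t0, t1), kids)
  cells <- list(
    A = mk("A", NA, 0, 20, "divided", kids = c("B", "C")),
    B = mk("B", "A", 20, 40, "divided", kids = c("B1", "B2")),
    C = mk("C", "A", 20, 40, "divided", kids = c("C1", "C2")),
    B1 = mk("B1", "B", 40, 60, "movie_end", "CD71bright"),
    B2 = mk("B2", "B", 40, 60, "endomitosis"),
    C1 = mk("C1", "C", 40, 60, "movie_end", "CD235a"),
    C2 = mk("C2", "C", 40, 60, "endomitosis"))
  seqs <- extract_division_sequences(lineage_tree(cells))
  expect_length(seqs, 2L)
  for (s in seqs) {
    expect_equal(s$outcome, c("expansion", "exhaustion"))
    expect_false(attr(s, "censored"))
  }

  # root dying before dividing: one empty censored sequence
  dead <- lineage_tree(list(A = cell_record("A", NA, 0, 8, "died")))
  seqs <- extract_division_sequences(dead)
  expect_length(seqs, 1L)
  expect_equal(nrow(seqs[[1]]), 0L)
  expect_true(attr(seqs[[1]], "censored"))
})

test_that("division_events derives from-states along the tree", {
  chain <- toy_chain_tree()
  ev <- division_events(chain)
  expect_equal(ev$from_state, c("start", "maintenance_E"))
  expect_equal(ev$outcome, c("maintenance_E", "exhaustion"))
  expect_equal(ev$generation, 1:2)
  expect_equal(attr(ev, "dropped"), 0L)
})

test_that("newick export round-trips topology, lengths and labels", {
  tree <- toy_chain_tree()
  lab <- assign_fate_labels(tree)
  nwk <- export_newick(tree, lab)
  parsed <- parse_newick(nwk)
  expect_setequal(parsed$id, names(tree$cells))
  for (i in seq_len(nrow(parsed))) {
    c <- tree$cells[[parsed$id[i]]]
    expect_equal(parsed$length[i], c$end_time - c$birth_time)
    expect_equal(parsed$parent[i],
                 if (is.na(c$parent_id)) NA_character_ else c$parent_id)
    expect_equal(parsed$label[i], unname(lab[parsed$id[i]]))
  }
  # single cell, lifespan 10 h
  single <- lineage_tree(list(R = cell_record("R", NA, 0, 10, "lost")))
  expect_equal(export_newick(single), "R:10;")
  # independent reader agrees on topology and branch lengths
  skip_if_not_installed("ape")
  ph <- ape::read.tree(text = gsub("\\[[^]]*\\]", "", nwk))
  expect_equal(sort(ph$tip.label), sort(tree_leaves(tree)))
  expect_equal(sort(ph$edge.length),
               sort(unname(vapply(setdiff(names(tree$cells), "A"),
                                  function(id) {
                                    c <- tree$cells[[id]]
                                    c$end_time - c$birth_time
                                  }, numeric(1)))))
})
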