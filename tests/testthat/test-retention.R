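mk_event <- function(branch, clade_a, clade_b, map) {
  sp <- function(g) sort(unique(unname(unclass(map)[g])))
  data.frame(orthogroup = "OG1", node = 1L,
             branch = paste(sort(strsplit(branch, ",")[[1]]),
                            collapse = ","),
             branch_size = length(strsplit(branch, ",")[[1]]),
             terminal = length(strsplit(branch, ",")[[1]]) == 1L,
             is_root_branch = FALSE,
             clade_a = paste(clade_a, collapse = ";"),
             clade_b = paste(clade_b, collapse = ";"),
             size_a = length(clade_a), size_b = length(clade_b),
             species_a = paste(sp(clade_a), collapse = ";"),
             species_b = paste(sp(clade_b), collapse = ";"),
             evidence_species = paste(intersect(sp(clade_a), sp(clade_b)),
                                      collapse = ";"),
             n_evidence = length(intersect(sp(clade_a), sp(clade_b))),
             stringsAsFactors = FALSE)
}

fixture_map <- function() {
  st <- species_tree("((A,B),C);")
  map <- load_gene_species_map(
    data.frame(g = c("a1", "a2", "b1", "b2", "c1"),
               s = c("A", "A", "B", "B", "C")), st)
  list(st = st, map = map)
}

test_that("evidence species requires a gene in both paralog clades", {
  fx <- fixture_map()
  e <- mk_event("A,B", c("a1", "b1"), c("a2", "b2"), fx$map)
  expect_equal(evidence_species(e, fx$map), c("A", "B"))
  e2 <- mk_event("A", "a1", "a2", fx$map)
  expect_equal(evidence_species(e2, fx$map), "A")
  e3 <- mk_event("A,B", c("a1", "b1"), "a2", fx$map)
  expect_equal(evidence_species(e3, fx$map), "A")
})

test_that("criterion 1 thresholds on the evidence-species count", {
  fx <- fixture_map()
  e <- mk_event("A,B", c("a1", "b1"), c("a2", "b2"), fx$map)
  expect_true(passes_criterion1(e, retention_criteria()))
  e2 <- mk_event("A", "a1", "a2", fx$map)
  expect_false(passes_criterion1(e2, retention_criteria()))
  expect_true(passes_criterion1(e2, retention_criteria(1L)))
  expect_error(retention_criteria(0L), ">= 1")
})

test_that("criterion 2 demands both copies in every descendant species", {
  fx <- fixture_map()
  expect_true(passes_criterion2(
    mk_event("A,B", c("a1", "b1"), c("a2", "b2"), fx$map), fx$st))
  expect_false(passes_criterion2(
    mk_event("A,B", c("a1", "b1"), "a2", fx$map), fx$st))
  # terminal event: vacuously retained over its single species
  expect_true(passes_criterion2(
    mk_event("A", "a1", "a2", fx$map), fx$st))
})

test_that("filter_events materializes the monotone chain", {
  fx <- fixture_map()
  catal <- rbind(
    mk_event("A,B", c("a1", "b1"), c("a2", "b2"), fx$map),  # retained
    mk_event("A", "a1", "a2", fx$map),                      # terminal
    mk_event("A,B", c("a1", "b1"), "a2", fx$map))           # copy lost in B
  catal$orthogroup <- c("OG1", "OG2", "OG3")
  fc <- filter_events(structure(catal,
                                class = c("event_catalog", "data.frame")),
                      stree = fx$st)
  expect_equal(attr(fc, "counts"),
               list(total = 3L, after_criterion1 = 1L, retained = 1L))
  expect_equal(fc$retained, c(TRUE, FALSE, FALSE))

  empty <- filter_events(
    structure(genedup:::.empty_events(),
              class = c("event_catalog", "data.frame")), stree = fx$st)
  expect_equal(attr(empty, "counts"),
               list(total = 0L, after_criterion1 = 0L, retained = 0L))
})

test_that("criterion 2 implies criterion 1 on internal branches (property)", {
  # on random simulated catalogs every internal-branch event passing
  # criterion 2 must pass criterion 1, and the filter chain is monotone
  for (seed in 1:5) {
    fst <- simulate_forest(sim_config(n_orthogroups = 15, seed = seed,
                                      lambda = 0.15, mu = 0.08))
    fc <- filter_events(reconcile_forest(fst))
    cnt <- attr(fc, "counts")
    expect_lte(cnt$retained, cnt$after_criterion1)
    expect_lte(cnt$after_criterion1, cnt$total)
    internal <- !fc$terminal
    expect_true(all(!internal | !fc$criterion2 | fc$criterion1))
    # terminal events never pass criterion 1 at the default threshold
    expect_true(all(!fc$criterion1[fc$terminal]))
  }
})

test_that("branch_summary counts events and distinct orthogroups", {
  fx <- fixture_map()
  catal <- rbind(
    mk_event("A,B", c("a1", "b1"), c("a2", "b2"), fx$map),
    mk_event("A,B", c("a1", "b1"), c("a2", "b2"), fx$map),
    mk_event("A,B", c("a1", "b1"), c("a2", "b2"), fx$map))
  catal$orthogroup <- c("OG1", "OG1", "OG2")   # 3 events, 2 orthogroups
  fc <- filter_events(structure(catal,
                                class = c("event_catalog", "data.frame")),
                      stree = fx$st)
  bs <- branch_summary(fc, fx$st)
  row <- bs[bs$branch == "A,B", ]
  expect_equal(row$n_events, 3L)
  expect_equal(row$n_orthogroups, 2L)
  expect_equal(sum(bs$n_events), sum(fc$retained))
  # no retained events -> all-zero table over nonterminal branches
  fc0 <- filter_events(
    structure(genedup:::.empty_events(),
              class = c("event_catalog", "data.frame")), stree = fx$st)
  bs0 <- branch_summary(fc0, fx$st)
  expect_true(all(bs0$n_events == 0L))
  expect_setequal(bs0$branch, c("A,B", "A,B,C"))
})

test_that("filter-chain bookkeeping subtracts terminal events", {
  ch <- filter_chain_counts(100, 30)
  expect_equal(ch$criterion1_survivors, 70)
  expect_error(filter_chain_counts(10, 20))
})
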