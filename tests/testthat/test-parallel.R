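test_that("hypergeometric tail matches enumeration and handles edges", {
  # N=10, K=3, n=4, k=2: 70 of the C(10,4)=210 draws have >= 2 marked
  expect_equal(hypergeometric_tail(10, 3, 4, 2), 70 / 210)
  expect_equal(hypergeometric_tail(10, 3, 4, 2),
               oracle_hyper_tail(10, 3, 4, 2))
  expect_equal(hypergeometric_tail(10, 3, 4, 0), 1)
  expect_equal(hypergeometric_tail(10, 3, 4, 4), 0)
  expect_error(hypergeometric_tail(5, 9, 2, 1), "inconsistent")
  # point probabilities over the support sum to one
  expect_equal(sum(stats::dhyper(0:120, 120, 500 - 120, 200)), 1,
               tolerance = 1e-12)
})

test_that("log-space tail is finite and exact at extreme scales", {
  lp <- hypergeometric_tail(13773, 381, 225, 41, log10p = TRUE)
  expect_true(is.finite(lp))
  expect_lt(lp, -15)
  expect_equal(10^hypergeometric_tail(2000, 200, 200, 100, log10p = TRUE),
               hypergeometric_tail(2000, 200, 200, 100))
})

test_that("focal branch pairs are validated", {
  st <- example_species_tree()
  p <- focal_branch_pair(st, c("Zmays", "Sbicolor"),
                         c("Sitalica", "Pvirgatum"))
  expect_equal(p$branch1, "Sbicolor,Zmays")
  expect_error(focal_branch_pair(st, "Zmays", c("Sitalica", "Pvirgatum")),
               "terminal")
  expect_error(focal_branch_pair(st, c("Zmays", "Osativa"),
                                 c("Sitalica", "Pvirgatum")),
               "no species-tree branch")
  expect_error(
    focal_branch_pair(st, c("Zmays", "Sbicolor"),
                      c("Zmays", "Sbicolor", "Sitalica", "Pvirgatum")),
    "nested")
})

test_that("overlap enrichment counts orthogroups and fills expectation", {
  cfg <- sim_config(n_orthogroups = 40, seed = 9,
                    planted_parallel = list(branch1 = "Sbicolor,Zmays",
                                            branch2 = "Pvirgatum,Sitalica",
                                            n_gene = 6, n_orthogroup = 0),
                    lambda = 0, mu = 0)
  fc <- filter_events(reconcile_forest(simulate_forest(cfg)))
  pair <- example_focal_pair()
  ov <- overlap_enrichment(fc, pair)
  expect_equal(ov$K, 6L)
  expect_equal(ov$n, 6L)
  expect_equal(ov$k_obs, 6L)
  expect_equal(ov$N, 40L)
  expect_equal(ov$expected, 6 * 6 / 40)
  expect_equal(ov$p_value, oracle_hyper_tail(40, 6, 6, 6), tolerance = 1e-9)
  # saturated case: K = n = N gives certain overlap, p = 1
  ov2 <- overlap_enrichment(fc, pair, universe = ov$overlap_orthogroups)
  expect_equal(ov2$k_obs, ov2$N)
  expect_equal(ov2$expected, ov2$N)
  expect_equal(ov2$p_value, 1)
})

test_that("same-gene parallelism requires a speciation-only path", {
  st <- example_species_tree()
  genes <- c("z1", "z2", "s1", "s2", "i1", "i2", "p1", "p2")
  sp <- c("Zmays", "Zmays", "Sbicolor", "Sbicolor",
          "Sitalica", "Sitalica", "Pvirgatum", "Pvirgatum")
  map <- load_gene_species_map(data.frame(g = genes, s = sp), st)

  # one ancestral gene speciates into the two focal lineages and
  # duplicates independently in each: the connecting path is speciation-only
  g <- parse_newick("(((z1,s1),(z2,s2)),((i1,p1),(i2,p2)));")
  r <- label_events(g, st, map)
  dups <- which(r$label == "duplication")
  expect_length(dups, 2L)
  expect_true(same_gene_parallel(r, dups[1], dups[2]))
  expect_true(same_gene_parallel(r, dups[2], dups[1]))  # symmetric

  # an older duplication separates the two events: same orthogroup,
  # different ancestral genes
  g2 <- parse_newick(paste0(
    "((((z1,s1),(z2,s2)),(i1,p1)),((z1b,s1b),((i1b,p1b),(i2b,p2b))));"))
  genes2 <- c(g2$tip.label)
  map2 <- load_gene_species_map(data.frame(
    g = genes2,
    s = c("Zmays", "Sbicolor", "Zmays", "Sbicolor", "Sitalica",
          "Pvirgatum", "Zmays", "Sbicolor", "Sitalica", "Pvirgatum",
          "Sitalica", "Pvirgatum")), st)
  r2 <- label_events(g2, st, map2)
  d_andro <- r2$events$node[r2$events$branch == "Sbicolor,Zmays"]
  d_pani <- r2$events$node[r2$events$branch == "Pvirgatum,Sitalica"]
  expect_length(d_andro, 1L)
  expect_length(d_pani, 1L)
  # these two sit in different paralog subtrees below the root duplication
  expect_false(same_gene_parallel(r2, d_andro, d_pani))

  # ancestor/descendant duplication pairs are FALSE by convention
  g3 <- parse_newick("(((z1,z2),s1),c1);")
  map3 <- load_gene_species_map(data.frame(
    g = c("z1", "z2", "s1", "c1"),
    s = c("Zmays", "Zmays", "Sbicolor", "Osativa")), st)
  r3 <- label_events(g3, st, map3)
  dd <- which(r3$label == "duplication")
  if (length(dd) >= 2)
    expect_false(same_gene_parallel(r3, dd[1], dd[2]))
  expect_error(same_gene_parallel(r, dups[1], r$index$root),
               "duplication nodes")
})

test_that("find_parallel_events separates gene- and orthogroup-level", {
  cfg <- sim_config(n_orthogroups = 100, seed = 21, lambda = 0, mu = 0,
                    planted_parallel = list(branch1 = "Sbicolor,Zmays",
                                            branch2 = "Pvirgatum,Sitalica",
                                            n_gene = 5, n_orthogroup = 3))
  fst <- simulate_forest(cfg)
  fc <- filter_events(reconcile_forest(fst))
  par <- find_parallel_events(fc, example_focal_pair())
  expect_equal(sum(par$level == "orthogroup"), 8L)
  expect_equal(sum(par$level == "gene"), 5L)
  expect_setequal(par$orthogroup[par$level == "gene"],
                  sprintf("OG%04d", 1:5))
  # no events on one branch -> nothing to report
  cfg0 <- sim_config(n_orthogroups = 10, seed = 22, lambda = 0, mu = 0)
  fc0 <- filter_events(reconcile_forest(simulate_forest(cfg0)))
  expect_equal(nrow(find_parallel_events(fc0, example_focal_pair())), 0L)
})

test_that("overlap test is calibrated on null draws and powered on signal", {
  # null: orthogroup sets drawn independently at fixed per-branch rates
  set.seed(33)
  reps <- 300
  N <- 500; K <- 40; n <- 30
  pvals <- replicate(reps, {
    s1 <- sample.int(N, K)
    s2 <- sample.int(N, n)
    hypergeometric_tail(N, K, n, length(intersect(s1, s2)))
  })
  mc_se <- sqrt(0.05 * 0.95 / reps)
  expect_lte(mean(pvals <= 0.05), 0.05 + 3 * mc_se)
  # power: overlap planted at 5x expectation is detected decisively
  p_sig <- replicate(50, {
    Np <- 2000; Kp <- 200; np <- 200   # expected overlap 20, planted 100
    shared <- sample.int(Np, 100)
    s1 <- c(shared, sample(setdiff(seq_len(Np), shared), Kp - 100))
    s2 <- c(shared, sample(setdiff(seq_len(Np), s1), np - 100))
    hypergeometric_tail(Np, Kp, np, length(intersect(s1, s2)))
  })
  expect_lt(stats::median(p_sig), 1e-3)
})
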