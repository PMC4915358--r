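mk_expr <- function(tpm_bs, tpm_m, gene = "g1", species = "Zmays") {
  k <- length(tpm_bs)
  mat <- matrix(c(tpm_bs, tpm_m), nrow = 1,
                dimnames = list(gene, c(sprintf("BS_%d", seq_len(k)),
                                        sprintf("M_%d", seq_len(k)))))
  expression_table(mat, data.frame(
    sample = colnames(mat), species = species,
    condition = rep(c("BS", "M"), each = k),
    replicate = rep(seq_len(k), 2)))
}

test_that("cell-preference classification calls clear-cut cases", {
  x <- mk_expr(c(100, 110, 90), c(10, 12, 8))
  calls <- classify_cell_preference(x, "Zmays")
  expect_equal(calls$call, "BS")
  expect_equal(calls$fold_change, 10)
  expect_lt(calls$padj, 0.05)

  # identical BS and M values: no preference
  x2 <- mk_expr(c(50, 60, 55), c(50, 60, 55))
  expect_equal(classify_cell_preference(x2, "Zmays")$call, "none")

  # all-zero gene is floored out of testing
  x3 <- mk_expr(c(0, 0, 0), c(0, 0, 0))
  c3 <- classify_cell_preference(x3, "Zmays")
  expect_equal(c3$call, "none")
  expect_true(is.na(c3$p))

  expect_error(classify_cell_preference(x, "Osativa"), "replicates")
})

test_that("classification is antisymmetric under swapping BS and M", {
  set.seed(55)
  n <- 40
  mat <- matrix(rlnorm(n * 6, log(20), 1), nrow = n,
                dimnames = list(sprintf("g%02d", 1:n), NULL))
  mat[1:10, 1:3] <- mat[1:10, 1:3] * 16
  samp <- data.frame(sample = sprintf("s%d", 1:6), species = "Zmays",
                     condition = rep(c("BS", "M"), each = 3),
                     replicate = rep(1:3, 2))
  colnames(mat) <- samp$sample
  a <- classify_cell_preference(expression_table(mat, samp), "Zmays")
  samp_sw <- samp
  samp_sw$condition <- rep(c("M", "BS"), each = 3)
  b <- classify_cell_preference(expression_table(mat, samp_sw), "Zmays")
  swap <- c(BS = "M", M = "BS", none = "none")
  expect_equal(unname(swap[a$call]), b$call)
})

test_that("preference enrichment uses the clipped two-sided binomial", {
  calls <- data.frame(gene = sprintf("g%02d", 1:20),
                      call = c(rep("BS", 15), rep("none", 5)),
                      stringsAsFactors = FALSE)
  bg <- data.frame(gene = sprintf("b%03d", 1:200),
                   call = c(rep("BS", 50), rep("none", 150)),
                   stringsAsFactors = FALSE)   # background proportion 0.25
  res <- preference_enrichment(calls$gene, calls, bg)
  bs <- res[res$cell_type == "BS", ]
  expect_equal(bs$p,
               min(1, 2 * sum(stats::dbinom(15:20, 20, 0.25))))
  expect_equal(bs$stars, "***")
  # set proportion equal to background: far from significant
  calls2 <- data.frame(gene = sprintf("g%02d", 1:20),
                       call = c(rep("BS", 5), rep("none", 15)))
  res2 <- preference_enrichment(calls2$gene, calls2, bg)
  expect_gte(res2$p[res2$cell_type == "BS"], 0.05)
  expect_equal(res2$stars[res2$cell_type == "BS"], "")
  # degenerate zero-probability background
  bg0 <- data.frame(gene = "b1", call = "none")
  res3 <- preference_enrichment(calls$gene, calls, bg0)
  expect_equal(res3$p[res3$cell_type == "BS"], 0)
  expect_error(preference_enrichment(character(0), calls), "empty")
  expect_error(preference_enrichment("zz", calls), "absent")
})

test_that("preference enrichment holds its type-I error on random cohorts", {
  set.seed(77)
  bg <- data.frame(gene = sprintf("b%04d", 1:2000),
                   call = sample(c("BS", "M", "none"), 2000, TRUE,
                                 prob = c(0.2, 0.15, 0.65)))
  reps <- 200
  hits <- replicate(reps, {
    res <- preference_enrichment(sample(bg$gene, 50), bg, bg)
    any(res$p <= 0.05)
  })
  # two tests per cohort; doubling-clipped exact binomial is conservative
  mc_se <- sqrt(0.1 * 0.9 / reps)
  expect_lte(mean(hits), 0.1 + 3 * mc_se)
})

test_that("BH adjustment matches the hand step-up on worked cases", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(c(0.001, 1.0)), c(0.002, 1.0))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  # adjusted values are monotone in the ranks of p and capped at 1
  p <- c(0.003, 0.2, 0.04, 0.9, 1)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= 0))
  expect_true(all(q <= 1))
})

test_that("dominance concordance applies the >10 TPM rule and ties", {
  st <- species_tree("(O,Z);")
  map <- load_gene_species_map(
    data.frame(g = c("o1", "o2", "z1", "z2", "o3", "o4", "z3", "z4",
                     "o5", "o6", "z5", "z6", "o7", "o8", "z7", "z8"),
               s = rep(c("O", "O", "Z", "Z"), 4)), st)
  mk <- function(og, ga, gb) data.frame(
    orthogroup = og, node = 3L, branch = "O,Z", branch_size = 2L,
    terminal = FALSE, is_root_branch = TRUE,
    clade_a = paste(ga, collapse = ";"), clade_b = paste(gb, collapse = ";"),
    size_a = length(ga), size_b = length(gb),
    species_a = "O;Z", species_b = "O;Z",
    evidence_species = "O;Z", n_evidence = 2L,
    criterion1 = TRUE, criterion2 = TRUE, retained = TRUE,
    stringsAsFactors = FALSE)
  fc <- rbind(mk("OG1", c("o1", "z1"), c("o2", "z2")),   # A dominant both
              mk("OG2", c("o3", "z3"), c("o4", "z4")),   # A dominant both
              mk("OG3", c("o5", "z5"), c("o6", "z6")),   # below threshold
              mk("OG4", c("o7", "z7"), c("o8", "z8")))   # tie in O
  fc <- structure(fc, class = c("filtered_catalog", "data.frame"),
                  forest = list(map = map, species_tree = st))
  leaf_tab <- function(genes, tpm, sp) {
    mat <- matrix(tpm, ncol = 1, dimnames = list(genes, "L1"))
    expression_table(mat, data.frame(sample = "L1", species = sp,
                                     condition = "leaf", replicate = 1))
  }
  xo <- leaf_tab(c("o1", "o2", "o3", "o4", "o5", "o6", "o7", "o8"),
                 c(100, 30, 80, 20, 5, 3, 50, 50), "O")
  xz <- leaf_tab(c("z1", "z2", "z3", "z4", "z5", "z6", "z7", "z8"),
                 c(200, 40, 90, 15, 8, 2, 60, 20), "Z")
  conc <- dominance_concordance(fc, "O,Z", xo, xz)
  expect_equal(conc$n_assessed, 2L)     # OG3 floored, OG4 tied
  expect_equal(conc$n_concordant, 2L)
  expect_equal(conc$percentage, 100)
  # relabelling clades A<->B consistently leaves the percentage unchanged
  fc2 <- fc
  tmp <- fc2$clade_a; fc2$clade_a <- fc2$clade_b; fc2$clade_b <- tmp
  conc2 <- dominance_concordance(fc2, "O,Z", xo, xz)
  expect_equal(conc2$percentage, conc$percentage)
  expect_error(dominance_concordance(fc, "O,Z", xo, xz, species2 = "X"),
               "descend")
})

test_that("concordance constructor computes the percentage", {
  cr <- concordance_result(1210, 893)
  expect_equal(cr$percentage, 100 * 893 / 1210)
  expect_error(concordance_result(10, 11))
})

test_that("term enrichment matches closed-form counts and validates input", {
  universe <- sprintf("OG%03d", 1:20)
  annot <- data.frame(orthogroup = universe[1:5], term = "GO:1",
                      stringsAsFactors = FALSE)
  # set of 5 capturing all 5 annotated orthogroups: p = 1/C(20,5)
  res <- term_enrichment(universe[1:5], universe, annot)
  expect_equal(res$p, 1 / choose(20, 5))
  expect_equal(res$k, 5L)
  expect_equal(res$K, 5L)
  # set = universe: every term has p = 1
  res2 <- term_enrichment(universe, universe, annot)
  expect_equal(res2$p, 1)
  expect_error(term_enrichment(c("OG999"), universe, annot), "subset")
  # padj >= p and BH applied across terms
  annot3 <- rbind(annot,
                  data.frame(orthogroup = universe[1:2], term = "GO:2"))
  res3 <- term_enrichment(universe[1:5], universe, annot3)
  expect_true(all(res3$padj >= res3$p))
  expect_equal(res3$padj, bh_adjust(res3$p))
})
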