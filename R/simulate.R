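#' The packaged example species tree (seven monocots)
#'
#' Topology of the monocot study clade: Andropogoneae (Zea mays, Sorghum
#' bicolor) and Paniceae (Setaria italica, Panicum virgatum) forming the
#' Panicoideae, the BEP grasses (Oryza sativa, Brachypodium distachyon) as
#' sister, and Musa acuminata as outgroup.  Only six monocots are named in
#' the study text; Musa is included here as a documented placeholder
#' seventh taxon.  Branch lengths are unit placeholders used by the
#' simulator as time units.
#'
#' @return a [species_tree()].
#' @export
example_species_tree <- function() {
  species_tree(paste0(
    "((((Zmays:1,Sbicolor:1):1,(Sitalica:1,Pvirgatum:1):1):1,",
    "(Osativa:1,Bdistachyon:1):2):1,Macuminata:4);"))
}

#' Focal C4-origin branches of the example tree
#'
#' @return a [focal_branch_pair()]: ancestor of the Andropogoneae
#'   (`Sbicolor,Zmays`) versus ancestor of the Paniceae
#'   (`Pvirgatum,Sitalica`).
#' @export
example_focal_pair <- function() {
  focal_branch_pair(example_species_tree(),
                    c("Zmays", "Sbicolor"), c("Sitalica", "Pvirgatum"))
}

#' Simulation configuration
#'
#' Defines the study conditions the simulator emulates.  Defaults: the
#' seven-taxon example tree; duplication rate `lambda = 1/16` per unit
#' branch length (about one surviving event per orthogroup over the tree's
#' total length of 16); loss rate `mu = 0.02` (modest fractionation);
#' expression block with bundle-sheath-preference fraction `f = 0.3`,
#' 16-fold planted preference, log-normal replicate noise `sigma = 0.25`
#' (the noncentral-t power of the 3-vs-3 Welch classifier at this noise
#' and effect size exceeds 99.9 percent, so preference calls are near
#' complete), and dominance-concordance rate `c = 0.74` on the
#' pre-Poaceae branch (the study's 893/1210 scale).
#'
#' @param stree species tree (default [example_species_tree()]).
#' @param n_orthogroups number of gene families to simulate.
#' @param lambda,mu duplication and loss rates per unit branch length.
#' @param seed integer seed; every simulation is a deterministic function
#'   of it.
#' @param planted_parallel list `(branch1, branch2, n_gene, n_orthogroup)`:
#'   numbers of orthogroups that receive forced same-gene (resp.
#'   same-orthogroup-only) parallel duplications on the two branches.
#' @param planted_ancestral list `(branch, n)`: orthogroups that receive
#'   one forced duplication on `branch` (used to plant the
#'   dominance-concordance cohort).
#' @param expression list of expression parameters; see Details in the
#'   vignette (`f`, `fold_change`, `sigma`, `concordance`,
#'   `dominance_branch`, `dominance_species`, `tpm_meanlog`, `tpm_sdlog`,
#'   `dominant_tpm`, `recessive_tpm`, `n_reps`, `n_leaf_reps`).
#' @param resample_extinct drop and redraw fully extinct orthogroups so
#'   that `n_orthogroups` is exact (default); `FALSE` keeps them as empty.
#' @return a `sim_config` list.
#' @export
sim_config <- function(stree = example_species_tree(),
                       n_orthogroups = 100L,
                       lambda = 1 / 16, mu = 0.02,
                       seed = 1L,
                       planted_parallel = list(branch1 = NULL,
                                               branch2 = NULL,
                                               n_gene = 0L,
                                               n_orthogroup = 0L),
                       planted_ancestral = list(branch = NULL, n = 0L),
                       expression = list(),
                       resample_extinct = TRUE) {
  stopifnot(lambda >= 0, mu >= 0, n_orthogroups >= 1)
  expr_defaults <- list(
    f = 0.3, fold_change = 16, sigma = 0.25, concordance = 0.74,
    dominance_branch = NULL, dominance_species = c("Osativa", "Zmays"),
    tpm_meanlog = log(20), tpm_sdlog = 1,
    dominant_tpm = 200, recessive_tpm = 20,
    n_reps = 3L, n_leaf_reps = 2L)
  expression <- utils::modifyList(expr_defaults, expression)
  np <- (planted_parallel$n_gene %||% 0L) +
    (planted_parallel$n_orthogroup %||% 0L) +
    (planted_ancestral$n %||% 0L)
  if (np > n_orthogroups)
    stop("planted orthogroup count exceeds n_orthogroups")
  structure(list(stree = stree, n_orthogroups = as.integer(n_orthogroups),
                 lambda = lambda, mu = mu, seed = as.integer(seed),
                 planted_parallel = planted_parallel,
                 planted_ancestral = planted_ancestral,
                 expression = expression,
                 resample_extinct = isTRUE(resample_extinct)),
            class = "sim_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- single gene-family simulation ------------------------------------------

# Recursive top-down birth-death along the species tree.  Returns a nested
# node list (or NULL if the lineage went extinct):
#   leaf: list(kind="leaf", gene=<id>, species=<sp>)
#   dup:  list(kind="dup", event=<id>, children=list(a, b))
#   spec: list(kind="spec", children=list(a, b))
# Events are recorded in env$events at creation (branch of occurrence);
# survival is decided afterwards by pruning.
.sim_lineage <- function(snode, t0, env) {
  sidx <- env$sidx
  L <- env$blen[snode]
  t <- t0
  # forced duplication consumed by the first lineage entering this branch
  if (t == 0 && env$forced[snode] > 0L) {
    env$forced[snode] <- env$forced[snode] - 1L
    ev <- .new_event(env, snode)
    a <- .sim_lineage_after(snode, 0, env)
    b <- .sim_lineage_after(snode, 0, env)
    return(.dup_or_collapse(ev, a, b, env))
  }
  .sim_lineage_after(snode, t, env)
}

.sim_lineage_after <- function(snode, t, env) {
  rate <- env$lambda + env$mu
  L <- env$blen[snode]
  repeat {
    wait <- if (rate > 0) stats::rexp(1L, rate) else Inf
    if (t + wait >= L) break
    t <- t + wait
    if (stats::runif(1L) < env$mu / rate) return(NULL)  # loss
    ev <- .new_event(env, snode)
    a <- .sim_lineage_after(snode, t, env)
    b <- .sim_lineage_after(snode, t, env)
    return(.dup_or_collapse(ev, a, b, env))
  }
  # reached the node at the bottom of the branch
  sidx <- env$sidx
  if (snode <= sidx$ntip) {
    sp <- sidx$phy$tip.label[snode]
    env$counter[sp] <- env$counter[sp] + 1L
    gene <- sprintf("%s_%s_%d", env$og, sp, env$counter[sp])
    env$map[[gene]] <- sp
    return(list(kind = "leaf", gene = gene, species = sp))
  }
  ch <- sidx$children[[snode]]
  a <- .sim_lineage(ch[1L], 0, env)
  b <- .sim_lineage(ch[2L], 0, env)
  if (is.null(a) && is.null(b)) return(NULL)
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  list(kind = "spec", children = list(a, b))
}

.new_event <- function(env, snode) {
  env$n_events <- env$n_events + 1L
  env$event_branch[[env$n_events]] <- snode
  env$n_events
}

# prune: a duplication survives only if both children survive
.dup_or_collapse <- function(ev, a, b, env) {
  if (is.null(a) && is.null(b)) return(NULL)
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  list(kind = "dup", event = ev, children = list(a, b))
}

.collect_leaves <- function(node) {
  if (node$kind == "leaf") return(node$gene)
  c(.collect_leaves(node$children[[1L]]),
    .collect_leaves(node$children[[2L]]))
}

.collect_events <- function(node, env, og) {
  if (node$kind == "leaf") return(NULL)
  sub <- rbind(.collect_events(node$children[[1L]], env, og),
               .collect_events(node$children[[2L]], env, og))
  if (node$kind == "dup") {
    snode <- env$event_branch[[node$event]]
    ca <- sort(.collect_leaves(node$children[[1L]]))
    cb <- sort(.collect_leaves(node$children[[2L]]))
    row <- data.frame(
      orthogroup = og,
      branch = branch_id_of(env$sidx, snode),
      clade_a = paste(ca, collapse = ";"),
      clade_b = paste(cb, collapse = ";"),
      size_a = length(ca), size_b = length(cb),
      stringsAsFactors = FALSE)
    sub <- rbind(row, sub)
  }
  sub
}

.nested_to_newick <- function(node) {
  build <- function(nd) {
    if (nd$kind == "leaf") return(nd$gene)
    paste0("(", build(nd$children[[1L]]), ",",
           build(nd$children[[2L]]), ")")
  }
  paste0(build(node), ";")
}

#' Simulate one gene family along the species tree
#'
#' One ancestral gene enters at the root; along each species branch every
#' extant copy duplicates at rate `lambda` and is lost at rate `mu`
#' (exponential waiting times), and copies bifurcate at speciations.  The
#' emitted gene tree contains only surviving lineages; the truth table
#' lists every duplication with surviving descendants on both sides, with
#' the species branch on which it occurred.
#'
#' @param stree a [species_tree()]; unit branch lengths are substituted
#'   when absent.
#' @param lambda,mu rates per unit branch length.
#' @param orthogroup identifier used in gene names and truth rows.
#' @param forced_branches character vector of branch ids that each receive
#'   one forced duplication at the top of the branch (first lineage to
#'   enter); `"root"` forces an ancestral duplication at the root node.
#' @param forced_root_split list of two character vectors of branch ids:
#'   forces a root duplication and gives each of the two root copies its
#'   own forced-branch set, so the forced events land in *different*
#'   (paralogous) ancestral lineages.
#' @return list with `tree` (`phylo`, or `NULL` if all lineages died or a
#'   single gene survived), `genes`, `map` (named species vector), `truth`
#'   (data frame of surviving true events).  Draws from the current RNG
#'   stream; seed management belongs to the caller ([simulate_forest()]).
#' @export
simulate_gene_tree <- function(stree, lambda, mu, orthogroup = "OG",
                               forced_branches = character(0),
                               forced_root_split = NULL) {
  sidx <- stree$index
  blen <- rep(1, sidx$nnode)
  if (!is.null(stree$phy$edge.length)) {
    for (i in seq_len(nrow(stree$phy$edge)))
      blen[stree$phy$edge[i, 2L]] <- stree$phy$edge.length[i]
  }
  env <- new.env(parent = emptyenv())
  env$sidx <- sidx
  env$blen <- blen
  env$lambda <- lambda
  env$mu <- mu
  env$og <- orthogroup
  env$counter <- stats::setNames(integer(sidx$ntip), stree$phy$tip.label)
  env$map <- list()
  env$n_events <- 0L
  env$event_branch <- list()
  branch_ids <- vapply(seq_len(sidx$nnode),
                       function(v) branch_id_of(sidx, v), character(1))
  forced_mask <- function(branches) {
    m <- integer(sidx$nnode)
    for (b in branches[branches != "root"]) {
      v <- match(.canon_branch(b), branch_ids)
      if (is.na(v)) stop("no species-tree branch {", b, "}")
      m[v] <- m[v] + 1L
    }
    m
  }
  force_root <- any(forced_branches == "root") ||
    !is.null(forced_root_split)
  env$forced <- forced_mask(forced_branches)

  start <- function() {
    ch <- sidx$children[[sidx$root]]
    a <- .sim_lineage(ch[1L], 0, env)
    b <- .sim_lineage(ch[2L], 0, env)
    if (is.null(a) && is.null(b)) return(NULL)
    if (is.null(a)) return(b)
    if (is.null(b)) return(a)
    list(kind = "spec", children = list(a, b))
  }
  root <- if (force_root) {
    ev <- .new_event(env, sidx$root)
    if (!is.null(forced_root_split))
      env$forced <- forced_mask(forced_root_split[[1L]])
    a <- start()
    if (!is.null(forced_root_split))
      env$forced <- forced_mask(forced_root_split[[2L]])
    b <- start()
    .dup_or_collapse(ev, a, b, env)
  } else {
    start()
  }
  if (is.null(root)) {
    return(list(tree = NULL, genes = character(0),
                map = character(0), truth = .empty_truth()))
  }
  genes <- sort(.collect_leaves(root))
  truth <- .collect_events(root, env, orthogroup)
  if (is.null(truth)) truth <- .empty_truth()
  tree <- if (length(genes) >= 2L)
    parse_newick(.nested_to_newick(root)) else NULL
  list(tree = tree, genes = genes,
       map = unlist(env$map) %||% character(0), truth = truth)
}

.empty_truth <- function() {
  data.frame(orthogroup = character(0), branch = character(0),
             clade_a = character(0), clade_b = character(0),
             size_a = integer(0), size_b = integer(0),
             stringsAsFactors = FALSE)
}

#' Simulate a gene forest with planted ground truth
#'
#' Generates `n_orthogroups` independent gene families from one seeded RNG
#' stream.  The first orthogroups carry the planted structure: same-gene
#' parallel duplications (one forced event at the top of each focal
#' branch, same ancestral lineage), orthogroup-level-only parallels (a
#' forced ancestral duplication at the root, then one focal-branch event
#' in each of the two root copies, so the two events are paralogous), and
#' forced ancestral duplications on a chosen branch.  Planted orthogroups
#' run with the background process switched off (`lambda = mu = 0` inside
#' them), so planted truth counts are exact by construction.  Fully
#' extinct background orthogroups are redrawn by default.
#'
#' @param config a [sim_config()].
#' @return a `sim_forest`: a [validate_forest()]-compatible `gene_forest`
#'   plus `truth` (true event table with `planted` flags) and `config`.
#' @export
simulate_forest <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  stree <- config$stree
  pp <- config$planted_parallel
  pa <- config$planted_ancestral
  n_gene <- pp$n_gene %||% 0L
  n_ogl <- pp$n_orthogroup %||% 0L
  n_anc <- pa$n %||% 0L
  n <- config$n_orthogroups
  ogids <- sprintf("OG%04d", seq_len(n))
  trees <- vector("list", n)
  names(trees) <- ogids
  ogs <- vector("list", n)
  names(ogs) <- ogids
  maps <- list()
  truths <- list()
  for (i in seq_len(n)) {
    og <- ogids[i]
    planted <- NULL
    forced <- character(0)
    split <- NULL
    lam <- config$lambda
    mu <- config$mu
    if (i <= n_gene) {
      planted <- "gene"
      forced <- c(pp$branch1, pp$branch2)
      lam <- 0; mu <- 0
    } else if (i <= n_gene + n_ogl) {
      planted <- "orthogroup"
      split <- list(pp$branch1, pp$branch2)
      lam <- 0; mu <- 0
    } else if (i <= n_gene + n_ogl + n_anc) {
      planted <- "ancestral"
      forced <- pa$branch
      lam <- 0; mu <- 0
    }
    repeat {
      sim <- simulate_gene_tree(stree, lam, mu, orthogroup = og,
                                forced_branches = forced,
                                forced_root_split = split)
      if (length(sim$genes) > 0L || !config$resample_extinct) break
    }
    ogs[[og]] <- sim$genes
    trees[[og]] <- sim$tree
    maps[[og]] <- sim$map
    if (nrow(sim$truth)) {
      sim$truth$planted <- planted %||% NA_character_
      truths[[og]] <- sim$truth
    }
  }
  keep <- lengths(ogs) > 0L
  ogs <- ogs[keep]
  trees <- trees[keep]
  map <- load_gene_species_map(
    data.frame(gene = unlist(lapply(maps, names), use.names = FALSE),
               species = unlist(maps, use.names = FALSE),
               stringsAsFactors = FALSE), stree)
  truth <- if (length(truths)) do.call(rbind, truths) else {
    tt <- .empty_truth(); tt$planted <- character(0); tt
  }
  rownames(truth) <- NULL
  forest <- validate_forest(load_orthogroups(ogs), trees, map, stree)
  structure(c(forest, list(truth = truth, config = config)),
            class = c("sim_forest", "gene_forest"))
}

#' @export
print.sim_forest <- function(x, ...) {
  cat("Simulated gene forest:", length(x$orthogroups), "orthogroups,",
      length(x$map), "genes;", nrow(x$truth), "true duplication events\n")
  invisible(x)
}

#' Write a simulated forest to disk in the package's input formats
#'
#' Emits `species_tree.nwk`, per-orthogroup `trees/<og>.nwk`,
#' `orthogroups.tsv`, `gene_species_map.tsv` and `truth_events.tsv`.
#'
#' @param forest a [simulate_forest()] result (any `gene_forest` works;
#'   the truth table is written only when present).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_forest <- function(forest, dir) {
  dir.create(file.path(dir, "trees"), recursive = TRUE, showWarnings = FALSE)
  writeLines(serialize_newick(forest$species_tree$phy),
             file.path(dir, "species_tree.nwk"))
  for (og in names(forest$trees)) {
    if (is.null(forest$trees[[og]])) next
    writeLines(serialize_newick(forest$trees[[og]]),
               file.path(dir, "trees", paste0(og, ".nwk")))
  }
  og_df <- data.frame(
    orthogroup_id = rep(names(forest$orthogroups),
                        lengths(forest$orthogroups)),
    gene_id = unlist(forest$orthogroups, use.names = FALSE))
  write_catalog_tsv(og_df, file.path(dir, "orthogroups.tsv"))
  write_catalog_tsv(
    data.frame(gene_id = names(forest$map),
               species_id = unclass(forest$map)),
    file.path(dir, "gene_species_map.tsv"))
  if (!is.null(forest$truth))
    write_catalog_tsv(forest$truth, file.path(dir, "truth_events.tsv"))
  invisible(dir)
}

#' Read a forest previously written by [write_forest()]
#'
#' @param dir directory produced by [write_forest()].
#' @return a [validate_forest()] `gene_forest`.
#' @export
read_forest <- function(dir) {
  stree <- species_tree(file.path(dir, "species_tree.nwk"))
  ogs <- load_orthogroups(file.path(dir, "orthogroups.tsv"))
  map <- load_gene_species_map(file.path(dir, "gene_species_map.tsv"), stree)
  trees <- list()
  for (og in names(ogs)) {
    f <- file.path(dir, "trees", paste0(og, ".nwk"))
    if (file.exists(f))
      trees[[og]] <- parse_newick(paste(readLines(f, warn = FALSE),
                                        collapse = ""))
  }
  validate_forest(ogs, trees, map, stree)
}

#' Simulate BS/M and whole-leaf expression with planted structure
#'
#' Per gene: a log-normal baseline TPM; a fixed fraction `f` of genes
#' (exactly `round(f * n)`, sampled) is bundle-sheath-preferential, with
#' the BS mean multiplied by `fold_change`.  For every true duplication on
#' the dominance branch, clade dominance in the two dominance species is
#' planted concordantly with probability `concordance`: all of the
#' dominant clade's genes in that species get whole-leaf mean
#' `dominant_tpm`, the other clade's `recessive_tpm`.  Replicates carry
#' multiplicative log-normal noise `sigma` (with `sigma = 0` the table
#' reproduces the planted means exactly).
#'
#' @param forest a [simulate_forest()] result.
#' @param config the [sim_config()] whose `expression` block to use;
#'   defaults to the forest's own.
#' @return list with `expression` (an [expression_table()] over all
#'   species), `truth_pref` (data frame `gene`, `bs_pref`), and
#'   `truth_dominance` (per planted event: dominant clade per species and
#'   concordance flag).
#' @export
simulate_expression <- function(forest, config = forest$config) {
  ex <- config$expression
  set.seed(config$seed + 1L)
  stree <- forest$species_tree
  species <- stree$phy$tip.label
  genes <- names(forest$map)
  ng <- length(genes)
  baseline <- stats::setNames(
    stats::rlnorm(ng, ex$tpm_meanlog, ex$tpm_sdlog), genes)
  n_bs <- round(ex$f * ng)
  bs_genes <- if (n_bs > 0) sample(genes, n_bs) else character(0)
  is_bs <- genes %in% bs_genes

  dom_branch <- .canon_branch(ex$dominance_branch %||%
    paste(setdiff(species, "Macuminata"), collapse = ","))
  sp_pair <- ex$dominance_species
  truth <- forest$truth
  dev <- truth[truth$branch == dom_branch, , drop = FALSE]
  leaf_mean <- baseline  # per-gene whole-leaf mean, overwritten for planted
  dom_rows <- list()
  if (nrow(dev)) {
    for (i in seq_len(nrow(dev))) {
      dom1 <- if (stats::runif(1L) < 0.5) "A" else "B"
      conc <- stats::runif(1L) < ex$concordance
      dom2 <- if (conc) dom1 else c(A = "B", B = "A")[[dom1]]
      doms <- c(dom1, dom2)
      for (j in 1:2) {
        sp <- sp_pair[j]
        ca <- .split_semi(dev$clade_a[i])
        cb <- .split_semi(dev$clade_b[i])
        ga <- ca[unclass(forest$map)[ca] == sp]
        gb <- cb[unclass(forest$map)[cb] == sp]
        hi <- if (doms[j] == "A") ga else gb
        lo <- if (doms[j] == "A") gb else ga
        leaf_mean[hi] <- ex$dominant_tpm
        leaf_mean[lo] <- ex$recessive_tpm
      }
      dom_rows[[i]] <- data.frame(
        orthogroup = dev$orthogroup[i], clade_a = dev$clade_a[i],
        clade_b = dev$clade_b[i], dominant_1 = dom1, dominant_2 = dom2,
        concordant = conc, stringsAsFactors = FALSE)
    }
  }
  truth_dominance <- if (length(dom_rows)) do.call(rbind, dom_rows) else
    data.frame(orthogroup = character(0), clade_a = character(0),
               clade_b = character(0), dominant_1 = character(0),
               dominant_2 = character(0), concordant = logical(0),
               stringsAsFactors = FALSE)

  samples <- list()
  for (sp in species) {
    for (r in seq_len(ex$n_reps)) {
      samples[[length(samples) + 1L]] <-
        data.frame(sample = sprintf("%s_BS_%d", sp, r), species = sp,
                   condition = "BS", replicate = r)
      samples[[length(samples) + 1L]] <-
        data.frame(sample = sprintf("%s_M_%d", sp, r), species = sp,
                   condition = "M", replicate = r)
    }
    for (r in seq_len(ex$n_leaf_reps)) {
      samples[[length(samples) + 1L]] <-
        data.frame(sample = sprintf("%s_leaf_%d", sp, r), species = sp,
                   condition = "leaf", replicate = r)
    }
  }
  samples <- do.call(rbind, samples)
  mat <- matrix(0, nrow = ng, ncol = nrow(samples),
                dimnames = list(genes, samples$sample))
  gene_sp <- unclass(forest$map)[genes]
  for (s in seq_len(nrow(samples))) {
    cond <- samples$condition[s]
    mean_s <- switch(cond,
                     BS = baseline * ifelse(is_bs, ex$fold_change, 1),
                     M = baseline,
                     leaf = leaf_mean)
    noise <- if (ex$sigma > 0) exp(stats::rnorm(ng, 0, ex$sigma)) else 1
    col <- mean_s * noise
    col[gene_sp != samples$species[s]] <- 0  # gene absent from other genomes
    mat[, s] <- col
  }
  list(expression = expression_table(mat, samples),
       truth_pref = data.frame(gene = genes, bs_pref = is_bs,
                               stringsAsFactors = FALSE),
       truth_dominance = truth_dominance)
}
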