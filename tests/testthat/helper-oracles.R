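# Independent oracles used across the suite.  These deliberately avoid the
# package's internal tree index: species LCAs come from ape::getMRCA and
# node depths from phangorn::Ancestors.

# depth (edge count from the root) of a node in a rooted phylo
oracle_depth <- function(phy, node) {
  length(phangorn::Ancestors(phy, node, type = "all"))
}

# species-tree node that a set of species maps to
oracle_species_mrca <- function(sphy, species) {
  species <- unique(species)
  if (length(species) == 1L) return(match(species, sphy$tip.label))
  ape::getMRCA(sphy, species)
}

# Brute-force LCA mapping: M(v) = species MRCA over all species below v.
oracle_lca_map <- function(gphy, sphy, map) {
  ntip <- length(gphy$tip.label)
  nnode <- ntip + gphy$Nnode
  M <- integer(nnode)
  for (v in seq_len(nnode)) {
    tips <- if (v <= ntip) gphy$tip.label[v] else
      ape::extract.clade(gphy, v)$tip.label
    M[v] <- oracle_species_mrca(sphy, unname(map[tips]))
  }
  M
}

# Duplication/loss score of a rooted gene tree, computed declaratively from
# the oracle mapping and the loss formula.
oracle_dl_score <- function(gphy, sphy, map) {
  M <- oracle_lca_map(gphy, sphy, map)
  ntip <- length(gphy$tip.label)
  D <- 0L
  L <- 0L
  for (v in (ntip + 1L):(ntip + gphy$Nnode)) {
    ch <- gphy$edge[gphy$edge[, 1L] == v, 2L]
    dup <- any(M[ch] == M[v])
    D <- D + as.integer(dup)
    for (cc in ch) {
      d <- oracle_depth(sphy, M[cc]) - oracle_depth(sphy, M[v])
      L <- L + d - (if (dup) 0L else 1L)
    }
  }
  list(D = D, L = L)
}

# All rootings of an unrooted binary tree, materialized with phytools.
oracle_all_rootings <- function(uphy) {
  out <- list()
  root_now <- length(uphy$tip.label) + 1L
  for (v in seq_len(length(uphy$tip.label) + uphy$Nnode)) {
    if (v == root_now) next
    out[[length(out) + 1L]] <- phytools::reroot(uphy, v)
  }
  out
}

# Exhaustive hypergeometric upper tail by enumeration of draws.
oracle_hyper_tail <- function(N, K, n, k) {
  if (k <= 0) return(1)
  if (k > min(K, n)) return(0)
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- apply(draws, 2L, function(d) sum(d %in% marked))
  mean(hits >= k)
}

# Benjamini-Hochberg step-up from its closed-form definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- pmin(1, m * ranked / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# random species tree + gene tree + map for property tests
random_recon_case <- function(n_species, n_genes) {
  sphy <- ape::rtree(n_species, br = NULL)
  sphy$tip.label <- sprintf("S%02d", seq_len(n_species))
  st <- species_tree(sphy)
  gphy <- ape::rtree(n_genes)  # keeps branch lengths (reroot needs them)
  gphy$tip.label <- sprintf("g%03d", seq_len(n_genes))
  sp <- sample(sphy$tip.label, n_genes, replace = TRUE)
  map <- load_gene_species_map(
    data.frame(gene = gphy$tip.label, species = sp), st)
  list(stree = st, gtree = gphy, map = map)
}

# canonical event keys for truth-vs-reconstruction comparison
event_keys <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  sort(paste(df$orthogroup, df$branch,
             pmin(df$clade_a, df$clade_b), pmax(df$clade_a, df$clade_b),
             sep = "|"))
}

grass_branch <- function() {
  paste(sort(c("Zmays", "Sbicolor", "Sitalica", "Pvirgatum",
               "Osativa", "Bdistachyon")), collapse = ",")
}
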