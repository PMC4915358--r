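# Internal flat index over an ape "phylo" object: parent/children arrays,
# edge-count depths from the root, a postorder, and per-node descendant
# leaf-label sets.  Node numbering follows ape (tips 1..ntip, root ntip+1).

build_index <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  parent <- integer(nnode)
  children <- vector("list", nnode)
  ne <- nrow(phy$edge)
  for (i in seq_len(ne)) {
    p <- phy$edge[i, 1L]
    ch <- phy$edge[i, 2L]
    parent[ch] <- p
    children[[p]] <- c(children[[p]], ch)
  }
  root <- ntip + 1L
  depth <- integer(nnode)
  # breadth-first from the root; children are always deeper than parents so
  # decreasing depth is a valid postorder
  queue <- root
  head <- 1L
  while (head <= length(queue)) {
    v <- queue[head]
    head <- head + 1L
    for (ch in children[[v]]) {
      depth[ch] <- depth[v] + 1L
      queue <- c(queue, ch)
    }
  }
  post <- order(depth, seq_len(nnode), decreasing = TRUE)
  clades <- vector("list", nnode)
  for (v in post) {
    clades[[v]] <- if (v <= ntip) phy$tip.label[v] else
      sort(unique(unlist(clades[children[[v]]], use.names = FALSE)))
  }
  list(phy = phy, ntip = ntip, nnode = nnode, parent = parent,
       children = children, root = root, depth = depth,
       postorder = post, clades = clades)
}

# LCA of two nodes by parent-pointer walk (O(height); trees here are small).
node_lca <- function(idx, a, b) {
  while (a != b) {
    da <- idx$depth[a]
    db <- idx$depth[b]
    if (da > db) a <- idx$parent[a]
    else if (db > da) b <- idx$parent[b]
    else { a <- idx$parent[a]; b <- idx$parent[b] }
  }
  a
}

# Is node a an ancestor of (or equal to) node b?
node_is_ancestor <- function(idx, a, b) {
  while (idx$depth[b] > idx$depth[a]) b <- idx$parent[b]
  a == b
}

# Canonical branch identifier: comma-joined sorted descendant species set.
branch_id_of <- function(idx, node) paste(idx$clades[[node]], collapse = ",")

# Nodes on the path from `from` up to (and including) `to`; `to` must be an
# ancestor of `from`.
path_to_ancestor <- function(idx, from, to) {
  out <- integer(0)
  v <- from
  while (v != to) {
    v <- idx$parent[v]
    out <- c(out, v)
  }
  out
}
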