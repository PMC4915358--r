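#' LCA (duplication-loss parsimony) mapping of a gene tree onto a species tree
#'
#' Maps every gene-tree node `v` to a species-tree node `M(v)`: for a leaf,
#' the species of the gene; for an internal node, the species-tree lowest
#' common ancestor of the children's mappings.  Computed in one post-order
#' traversal.
#'
#' @param gtree rooted binary `phylo` gene tree.
#' @param stree a [species_tree()].
#' @param map a [load_gene_species_map()] covering all leaves of `gtree`.
#' @return integer vector over gene-tree nodes (ape numbering) giving the
#'   mapped species-tree node for each.
#' @export
lca_map <- function(gtree, stree, map) {
  gidx <- build_index(gtree)
  sidx <- stree$index
  M <- integer(gidx$nnode)
  sp_node <- match(unclass(map)[gtree$tip.label], stree$phy$tip.label)
  if (anyNA(sp_node)) {
    bad <- gtree$tip.label[is.na(sp_node)]
    stop("unmapped gene(s) or unknown species: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  for (v in gidx$postorder) {
    if (v <= gidx$ntip) {
      M[v] <- sp_node[v]
    } else {
      ch <- gidx$children[[v]]
      m <- M[ch[1L]]
      for (k in ch[-1L]) m <- node_lca(sidx, m, M[k])
      M[v] <- m
    }
  }
  M
}

#' Label duplication and speciation nodes and extract duplication events
#'
#' An internal gene-tree node `v` is a duplication iff `M(v)` equals the
#' mapping of at least one of its children; otherwise it is a speciation.
#' Each duplication node yields one event record: its species branch (the
#' descendant-species set of `M(v)`), the gene sets of its two paralog
#' clades, and the species represented in each clade.  The evidence species
#' of an event are the species with a gene in *both* clades (a species
#' witnesses a duplication only if it retains both copies).
#'
#' @param gtree rooted binary `phylo` gene tree.
#' @param stree a [species_tree()].
#' @param map a [load_gene_species_map()].
#' @param orthogroup orthogroup identifier carried into the event records.
#' @return a `reconciled_gene_tree`: list with `phy`, `index`, `M` (node
#'   mapping), `label` (`"leaf"`, `"speciation"` or `"duplication"` per
#'   node) and `events` (data frame, one row per duplication node).
#' @export
label_events <- function(gtree, stree, map, orthogroup = "OG") {
  gidx <- build_index(gtree)
  sidx <- stree$index
  M <- lca_map(gtree, stree, map)
  lab <- character(gidx$nnode)
  rows <- vector("list", 0L)
  for (v in seq_len(gidx$nnode)) {
    if (v <= gidx$ntip) {
      lab[v] <- "leaf"
      next
    }
    ch <- gidx$children[[v]]
    is_dup <- any(M[ch] == M[v])
    lab[v] <- if (is_dup) "duplication" else "speciation"
    if (is_dup) {
      clade_a <- sort(gidx$clades[[ch[1L]]])
      clade_b <- sort(gidx$clades[[ch[2L]]])
      sp_a <- sort(unique(unclass(map)[clade_a]))
      sp_b <- sort(unique(unclass(map)[clade_b]))
      rows[[length(rows) + 1L]] <- data.frame(
        orthogroup = orthogroup,
        node = v,
        branch = branch_id_of(sidx, M[v]),
        branch_size = length(sidx$clades[[M[v]]]),
        terminal = M[v] <= sidx$ntip,
        is_root_branch = M[v] == sidx$root,
        clade_a = paste(clade_a, collapse = ";"),
        clade_b = paste(clade_b, collapse = ";"),
        size_a = length(clade_a),
        size_b = length(clade_b),
        species_a = paste(sp_a, collapse = ";"),
        species_b = paste(sp_b, collapse = ";"),
        evidence_species = paste(intersect(sp_a, sp_b), collapse = ";"),
        n_evidence = length(intersect(sp_a, sp_b)),
        stringsAsFactors = FALSE
      )
    }
  }
  events <- if (length(rows)) do.call(rbind, rows) else .empty_events()
  structure(list(phy = gtree, index = gidx, M = M, label = lab,
                 orthogroup = orthogroup, events = events),
            class = "reconciled_gene_tree")
}

.empty_events <- function() {
  data.frame(orthogroup = character(0), node = integer(0),
             branch = character(0), branch_size = integer(0),
             terminal = logical(0), is_root_branch = logical(0),
             clade_a = character(0), clade_b = character(0),
             size_a = integer(0), size_b = integer(0),
             species_a = character(0), species_b = character(0),
             evidence_species = character(0), n_evidence = integer(0),
             stringsAsFactors = FALSE)
}

#' @export
print.reconciled_gene_tree <- function(x, ...) {
  cat("Reconciled gene tree (", x$orthogroup, "): ",
      x$index$ntip, " genes, ", sum(x$label == "duplication"),
      " duplication node(s)\n", sep = "")
  invisible(x)
}

#' Count gene losses implied by a reconciliation
#'
#' For a gene-tree edge from node `v` down to child `c`, with `d` the number
#' of species-tree edges on the path from `M(v)` down to `M(c)`, the implied
#' loss count is `d - 1` if `v` is a speciation and `d` if `v` is a
#' duplication.
#'
#' @param recon a [label_events()] result.
#' @param stree the [species_tree()] used for the reconciliation.
#' @return list with `edges` (data frame `parent`, `child`, `losses`) and
#'   `total`.
#' @export
count_losses <- function(recon, stree) {
  gidx <- recon$index
  sidx <- stree$index
  M <- recon$M
  parent <- integer(0); child <- integer(0); losses <- integer(0)
  for (v in seq_len(gidx$nnode)) {
    if (v <= gidx$ntip) next
    for (cc in gidx$children[[v]]) {
      d <- sidx$depth[M[cc]] - sidx$depth[M[v]]
      l <- if (recon$label[v] == "duplication") d else d - 1L
      parent <- c(parent, v); child <- c(child, cc); losses <- c(losses, l)
    }
  }
  list(edges = data.frame(parent = parent, child = child, losses = losses),
       total = sum(losses))
}

# Score one rooting of an unrooted gene tree without materializing it.
# adj: adjacency list; lens: named edge lengths keyed "min-max";
# leaf_sp: species-tree node per tip (NA for internals).
.score_orientation <- function(u, from, adj, leaf_sp, sidx) {
  nb <- setdiff(adj[[u]], from)
  if (!length(nb))
    return(list(M = leaf_sp[u], D = 0L, L = 0L))
  if (length(nb) != 2L)
    stop("unrooted gene tree is not binary (internal degree != 3)")
  r1 <- .score_orientation(nb[1L], u, adj, leaf_sp, sidx)
  r2 <- .score_orientation(nb[2L], u, adj, leaf_sp, sidx)
  M <- node_lca(sidx, r1$M, r2$M)
  dup <- (M == r1$M) || (M == r2$M)
  d1 <- sidx$depth[r1$M] - sidx$depth[M]
  d2 <- sidx$depth[r2$M] - sidx$depth[M]
  pen <- if (dup) 0L else 1L
  list(M = M, D = r1$D + r2$D + as.integer(dup),
       L = r1$L + r2$L + (d1 - pen) + (d2 - pen))
}

# leaves of the subtree of u looking away from `from`
.side_leaves <- function(u, from, adj, tips) {
  nb <- setdiff(adj[[u]], from)
  if (!length(nb)) return(tips[u])
  sort(unlist(lapply(nb, .side_leaves, from = u, adj = adj, tips = tips)))
}

#' Root an unrooted gene tree by duplication-loss parsimony
#'
#' Scores every possible root position (one per edge) by the reconciliation
#' cost `w_dup * duplications + w_loss * losses` against the species tree
#' and returns the minimum-cost rooting.  Ties are broken deterministically:
#' minimal cost, then minimal duplication count, then the rooting whose root
#' clade *not* containing the globally smallest leaf label has the
#' lexicographically smallest minimum leaf label, then input edge order.
#' When branch lengths are present the rooted edge's length is split equally
#' across the two root edges.
#'
#' @param gtree unrooted binary `phylo` with >= 3 leaves (a rooted input is
#'   unrooted first).
#' @param stree a [species_tree()].
#' @param map a [load_gene_species_map()].
#' @param weights numeric `(w_dup, w_loss)`, default `c(1, 1)`.
#' @return rooted `phylo`, with attributes `cost`, `duplications`, `losses`.
#' @export
root_by_cost <- function(gtree, stree, map, weights = c(1, 1)) {
  if (length(gtree$tip.label) < 3L)
    stop("rooting requires >= 3 leaves")
  if (ape::is.rooted(gtree)) gtree <- ape::unroot(gtree)
  sidx <- stree$index
  ntip <- length(gtree$tip.label)
  nnode <- ntip + gtree$Nnode
  adj <- vector("list", nnode)
  has_len <- !is.null(gtree$edge.length)
  elen <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(gtree$edge))) {
    a <- gtree$edge[i, 1L]; b <- gtree$edge[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
    if (has_len) assign(paste(min(a, b), max(a, b)), gtree$edge.length[i],
                        envir = elen)
  }
  leaf_sp <- rep(NA_integer_, nnode)
  leaf_sp[seq_len(ntip)] <- match(unclass(map)[gtree$tip.label],
                                  stree$phy$tip.label)
  if (anyNA(leaf_sp[seq_len(ntip)]))
    stop("unmapped gene(s) in gene tree")
  gmin <- min(gtree$tip.label)
  best <- NULL
  for (i in seq_len(nrow(gtree$edge))) {
    u <- gtree$edge[i, 1L]; v <- gtree$edge[i, 2L]
    ru <- .score_orientation(u, v, adj, leaf_sp, sidx)
    rv <- .score_orientation(v, u, adj, leaf_sp, sidx)
    M <- node_lca(sidx, ru$M, rv$M)
    dup <- (M == ru$M) || (M == rv$M)
    pen <- if (dup) 0L else 1L
    D <- ru$D + rv$D + as.integer(dup)
    L <- ru$L + rv$L +
      (sidx$depth[ru$M] - sidx$depth[M] - pen) +
      (sidx$depth[rv$M] - sidx$depth[M] - pen)
    cost <- weights[1L] * D + weights[2L] * L
    lu <- .side_leaves(u, v, adj, gtree$tip.label)
    lv <- .side_leaves(v, u, adj, gtree$tip.label)
    key_clade <- if (gmin %in% lu) lv else lu
    key <- min(key_clade)
    cand <- list(edge = i, u = u, v = v, D = D, L = L, cost = cost,
                 key = key)
    if (is.null(best) ||
        cost < best$cost ||
        (cost == best$cost && D < best$D) ||
        (cost == best$cost && D == best$D && key < best$key)) {
      best <- cand
    }
  }
  # materialize the best rooting as a newick string
  half <- if (has_len)
    get(paste(min(best$u, best$v), max(best$u, best$v)), envir = elen) / 2
  else NA_real_
  fmt_label <- function(lab) {
    if (.needs_quoting(lab))
      paste0("'", gsub("'", "''", lab, fixed = TRUE), "'") else lab
  }
  to_nwk <- function(u, from) {
    nb <- setdiff(adj[[u]], from)
    if (!length(nb)) return(fmt_label(gtree$tip.label[u]))
    parts <- vapply(nb, function(b) {
      s <- to_nwk(b, u)
      if (has_len)
        s <- paste0(s, ":", format(get(paste(min(u, b), max(u, b)),
                                       envir = elen), digits = 12))
      s
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  s1 <- to_nwk(best$u, best$v)
  s2 <- to_nwk(best$v, best$u)
  if (has_len) {
    s1 <- paste0(s1, ":", format(half, digits = 12))
    s2 <- paste0(s2, ":", format(half, digits = 12))
  }
  # orient the clade containing the globally smallest leaf first
  lu <- .side_leaves(best$u, best$v, adj, gtree$tip.label)
  nwk <- if (gmin %in% lu) paste0("(", s1, ",", s2, ");")
         else paste0("(", s2, ",", s1, ");")
  rooted <- parse_newick(nwk)
  attr(rooted, "cost") <- best$cost
  attr(rooted, "duplications") <- best$D
  attr(rooted, "losses") <- best$L
  rooted
}

#' Reconcile every gene tree of a forest and collect the event catalog
#'
#' @param forest a [validate_forest()] result (orthogroups with a single
#'   gene contribute no events but remain part of the orthogroup universe).
#' @return an `event_catalog`: data frame of duplication events (one row per
#'   duplication node across all orthogroups) with the forest and the
#'   per-orthogroup reconciliations attached as attributes.
#' @export
reconcile_forest <- function(forest) {
  stopifnot(inherits(forest, "gene_forest"))
  stree <- forest$species_tree
  recons <- list()
  rows <- list()
  for (og in names(forest$orthogroups)) {
    tr <- forest$trees[[og]]
    if (is.null(tr)) next
    r <- label_events(tr, stree, forest$map, orthogroup = og)
    recons[[og]] <- r
    if (nrow(r$events)) rows[[og]] <- r$events
  }
  catalog <- if (length(rows)) do.call(rbind, rows) else .empty_events()
  rownames(catalog) <- NULL
  structure(catalog, class = c("event_catalog", "data.frame"),
            forest = forest, reconciliations = recons)
}

#' @export
print.event_catalog <- function(x, ...) {
  cat("Event catalog:", nrow(x), "duplication events in",
      length(unique(x$orthogroup)), "orthogroups\n")
  if (nrow(x)) {
    cat("  terminal-branch events:", sum(x$terminal), "\n")
    tab <- sort(table(x$branch[!x$terminal]), decreasing = TRUE)
    if (length(tab)) {
      cat("  top internal branches:\n")
      print(utils::head(tab, 5L))
    }
  }
  invisible(x)
}

#' Write an event catalog (or any data frame) as TSV
#'
#' @param x data frame.
#' @param path output path.
#' @export
write_catalog_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
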