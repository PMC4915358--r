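#' Parse a newick string into a rooted tree
#'
#' Thin, strict wrapper around [ape::read.tree()].  Before handing the string
#' to ape it checks that the statement is non-empty, terminated by `";"` and
#' has balanced parentheses, reporting the character offset of the first
#' violation.  Labels quoted with single quotes (the standard newick escape
#' for labels containing metacharacters such as spaces, parentheses or
#' colons) are unquoted on read, so `'sp one'` becomes the label `sp one`.
#'
#' @param text a single newick statement, e.g. `"((A:1,B:1):1,C:2);"`.
#' @return an [ape::read.tree()] `phylo` object.
#' @seealso [serialize_newick()]
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("newick parse error: input must be a single character string")
  s <- trimws(text)
  if (!nzchar(s))
    stop("newick parse error: empty string (offset 0)")

  # protect quoted labels ('' is the escaped quote inside a label)
  quoted <- character(0)
  repeat {
    m <- regexpr("'(?:[^']|'')*'", s, perl = TRUE)
    if (m == -1L) break
    lab <- substr(s, m, m + attr(m, "match.length") - 1L)
    quoted <- c(quoted, lab)
    ph <- sprintf("GENEDUPQLBL%dX", length(quoted))
    s <- paste0(substr(s, 1L, m - 1L), ph,
                substr(s, m + attr(m, "match.length"), nchar(s)))
  }

  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("newick parse error: unmatched ')' at offset %d", i))
    } else if (ch == ";" && depth > 0L) {
      stop(sprintf(
        "newick parse error: unbalanced parentheses at offset %d", i))
    }
  }
  if (depth != 0L)
    stop(sprintf(
      "newick parse error: unbalanced parentheses at end of input (offset %d)",
      nchar(s)))
  if (!endsWith(s, ";"))
    stop(sprintf("newick parse error: missing ';' terminator (offset %d)",
                 nchar(s)))
  if (sum(chars == ";") > 1L)
    stop("newick parse error: more than one statement")

  phy <- tryCatch(ape::read.tree(text = s),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy))
    stop("newick parse error: ape could not parse the statement")

  unquote <- function(labs) {
    if (is.null(labs)) return(labs)
    for (j in seq_along(quoted)) {
      inner <- gsub("''", "'", substr(quoted[j], 2L, nchar(quoted[j]) - 1L),
                    fixed = TRUE)
      labs[labs == sprintf("GENEDUPQLBL%dX", j)] <- inner
    }
    labs
  }
  phy$tip.label <- unquote(phy$tip.label)
  phy$node.label <- unquote(phy$node.label)
  if (anyDuplicated(phy$tip.label))
    stop("newick parse error: duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "))
  phy
}

# labels that must be quoted in newick output
.needs_quoting <- function(labs) grepl("[][ ():;,']", labs)

#' Serialize a tree to a newick string
#'
#' Inverse of [parse_newick()]: `parse_newick(serialize_newick(t))` is
#' isomorphic to `t` with labels and branch lengths preserved.  Labels
#' containing newick metacharacters are written single-quoted (internal
#' quotes doubled).
#'
#' @param phy a `phylo` object.
#' @return a single newick string terminated by `";"`.
#' @export
serialize_newick <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  orig_tip <- phy$tip.label
  orig_node <- phy$node.label
  ph_tip <- sprintf("GENEDUPTLBL%dX", seq_along(orig_tip))
  phy$tip.label <- ph_tip
  ph_node <- NULL
  if (!is.null(orig_node)) {
    ph_node <- sprintf("GENEDUPNLBL%dX", seq_along(orig_node))
    ph_node[is.na(orig_node) | orig_node == ""] <- ""
    phy$node.label <- ph_node
  }
  s <- ape::write.tree(phy)
  restore <- function(s, ph, orig) {
    for (j in seq_along(ph)) {
      if (!nzchar(ph[j])) next
      out <- orig[j]
      if (.needs_quoting(out))
        out <- paste0("'", gsub("'", "''", out, fixed = TRUE), "'")
      s <- sub(ph[j], out, s, fixed = TRUE)
    }
    s
  }
  s <- restore(s, ph_tip, orig_tip)
  if (!is.null(ph_node)) s <- restore(s, ph_node, orig_node)
  s
}

#' Read and validate a species tree
#'
#' The species tree must be rooted, strictly binary at internal nodes, with
#' unique leaf labels (species identifiers).  Every branch is addressable by
#' the comma-joined sorted set of species descending from its lower node
#' (e.g. `"Sbicolor,Zmays"`).
#'
#' @param x a newick string, a path to a newick file, or a `phylo` object.
#' @return a `species_tree` object (list with elements `phy` and `index`).
#' @export
species_tree <- function(x) {
  phy <- if (inherits(x, "phylo")) {
    x
  } else if (is.character(x) && length(x) == 1L && file.exists(x) &&
             !grepl(";", x)) {
    parse_newick(paste(readLines(x, warn = FALSE), collapse = ""))
  } else {
    parse_newick(x)
  }
  idx <- build_index(phy)
  internal <- which(seq_len(idx$nnode) > idx$ntip)
  nch <- lengths(idx$children[internal])
  if (idx$ntip > 1L && any(nch != 2L))
    stop("species tree must be strictly binary; node(s) with != 2 children: ",
         paste(internal[nch != 2L], collapse = ", "))
  if (anyDuplicated(phy$tip.label))
    stop("species tree has duplicate leaf labels")
  structure(list(phy = phy, index = idx), class = "species_tree")
}

#' @export
print.species_tree <- function(x, ...) {
  cat("Species tree:", x$index$ntip, "species,",
      x$index$nnode - x$index$ntip, "internal nodes\n")
  cat("  species:", paste(sort(x$phy$tip.label), collapse = ", "), "\n")
  invisible(x)
}

#' All branches of a species tree
#'
#' @param stree a [species_tree()].
#' @param nonterminal keep only branches with >= 2 descendant species.
#' @return data frame with columns `branch` (descendant-set identifier),
#'   `branch_size` and `is_root` (the root is listed so that events mapped to
#'   the root node have a reporting row; it is flagged because it is not a
#'   branch proper).
#' @export
species_branches <- function(stree, nonterminal = FALSE) {
  idx <- stree$index
  nodes <- seq_len(idx$nnode)
  if (nonterminal) nodes <- nodes[nodes > idx$ntip]
  df <- data.frame(
    branch = vapply(nodes, function(v) branch_id_of(idx, v), character(1)),
    branch_size = lengths(idx$clades[nodes]),
    is_root = nodes == idx$root,
    stringsAsFactors = FALSE
  )
  df[order(-df$branch_size, df$branch), , drop = FALSE]
}

# read a TSV allowing "#" comments; header optional, detected by name match
.read_tsv <- function(path, expected_names) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = "character", blank.lines.skip = TRUE)
  if (ncol(df) < length(expected_names))
    stop("expected at least ", length(expected_names), " columns in ", path)
  if (nrow(df) > 0L &&
      all(tolower(unlist(df[1L, seq_along(expected_names)])) ==
          tolower(expected_names)))
    df <- df[-1L, , drop = FALSE]
  names(df)[seq_along(expected_names)] <- expected_names
  rownames(df) <- NULL
  df
}

#' Load a gene-to-species map
#'
#' Two-column TSV (`gene_id`, `species_id`); header optional, `#` comments
#' allowed.  Species extraction from gene identifiers is deliberately not
#' guessed from prefixes: the map is the only source.
#'
#' @param x path to the TSV, or a data frame / 2-column matrix.
#' @param stree optional [species_tree()]; if given, all species must be
#'   leaves of it.
#' @return named character vector (names = gene ids, values = species ids)
#'   of class `gene_species_map`.
#' @export
load_gene_species_map <- function(x, stree = NULL) {
  df <- if (is.character(x) && length(x) == 1L) {
    .read_tsv(x, c("gene_id", "species_id"))
  } else {
    as.data.frame(x, stringsAsFactors = FALSE)
  }
  gene <- as.character(df[[1L]])
  sp <- as.character(df[[2L]])
  dup <- duplicated(gene)
  if (any(dup)) {
    for (g in unique(gene[dup])) {
      if (length(unique(sp[gene == g])) > 1L)
        stop("conflicting species for gene ", g)
    }
    keep <- !dup
    gene <- gene[keep]
    sp <- sp[keep]
  }
  if (!is.null(stree)) {
    bad <- setdiff(unique(sp), stree$phy$tip.label)
    if (length(bad))
      stop("species not in the species tree: ", paste(bad, collapse = ", "))
  }
  structure(stats::setNames(sp, gene), class = "gene_species_map")
}

#' @export
print.gene_species_map <- function(x, ...) {
  tab <- table(unclass(x))
  cat("Gene-species map:", length(x), "genes,", length(tab), "species\n")
  print(tab)
  invisible(x)
}

#' Load an orthogroup table
#'
#' Long-format two-column TSV (`orthogroup_id`, `gene_id`).  Gene sets must
#' be pairwise disjoint and non-empty.
#'
#' @param x path to the TSV, a data frame, or a named list of character
#'   vectors.
#' @return named list of gene-id character vectors, class `orthogroup_table`.
#' @export
load_orthogroups <- function(x) {
  ogs <- if (is.list(x) && !is.data.frame(x)) {
    x
  } else {
    df <- if (is.character(x) && length(x) == 1L)
      .read_tsv(x, c("orthogroup_id", "gene_id")) else x
    split(as.character(df[[2L]]), as.character(df[[1L]]))
  }
  if (length(ogs) == 0L || any(lengths(ogs) == 0L))
    stop("orthogroup table has empty orthogroups")
  all_genes <- unlist(ogs, use.names = FALSE)
  if (anyDuplicated(all_genes))
    stop("orthogroup gene sets are not disjoint: ",
         paste(utils::head(unique(all_genes[duplicated(all_genes)]), 5L),
               collapse = ", "))
  structure(ogs[order(names(ogs))], class = "orthogroup_table")
}

#' Validate a gene forest against a species tree
#'
#' Checks that every orthogroup with two or more genes has a gene tree whose
#' leaf set equals its gene set, that all gene trees are rooted and binary
#' (the `polytomy` policy decides what happens to multifurcations), and that
#' every leaf maps to a species of the species tree.  Idempotent: validating
#' a validated forest returns an equivalent object.
#'
#' @param orthogroups an [load_orthogroups()] table (or coercible input).
#' @param trees named list of `phylo` gene trees keyed by orthogroup id;
#'   orthogroups with a single gene may omit theirs.
#' @param map a [load_gene_species_map()].
#' @param stree a [species_tree()].
#' @param polytomy `"reject"` (default: multifurcating gene trees are an
#'   error, because silently resolving them changes duplication counts) or
#'   `"resolve"` (deterministic left-to-right resolution via
#'   [ape::multi2di()] with `random = FALSE`; affected orthogroups are
#'   recorded in the `resolved` element).
#' @return a `gene_forest` object.
#' @export
validate_forest <- function(orthogroups, trees, map, stree,
                            polytomy = c("reject", "resolve")) {
  polytomy <- match.arg(polytomy)
  if (inherits(orthogroups, "gene_forest")) {
    fst <- orthogroups
    orthogroups <- fst$orthogroups
    trees <- fst$trees
    map <- fst$map
    stree <- fst$species_tree
  }
  if (!inherits(orthogroups, "orthogroup_table"))
    orthogroups <- load_orthogroups(orthogroups)
  if (!inherits(map, "gene_species_map"))
    map <- load_gene_species_map(map, stree)
  bad_sp <- setdiff(unique(unclass(map)), stree$phy$tip.label)
  if (length(bad_sp))
    stop("species not in the species tree: ", paste(bad_sp, collapse = ", "))
  resolved <- character(0)
  out_trees <- vector("list", length(orthogroups))
  names(out_trees) <- names(orthogroups)
  for (og in names(orthogroups)) {
    genes <- orthogroups[[og]]
    unmapped <- genes[!genes %in% names(map)]
    if (length(unmapped))
      stop("orthogroup ", og, ": gene(s) missing from the species map: ",
           paste(utils::head(unmapped, 5L), collapse = ", "))
    if (length(genes) < 2L) next
    tr <- trees[[og]]
    if (is.null(tr))
      stop("orthogroup ", og, " has ", length(genes),
           " genes but no gene tree")
    if (!setequal(tr$tip.label, genes)) {
      delta <- c(setdiff(tr$tip.label, genes), setdiff(genes, tr$tip.label))
      stop("orthogroup ", og, ": tree leaves and gene set differ: ",
           paste(utils::head(delta, 5L), collapse = ", "))
    }
    if (!ape::is.binary(tr)) {
      if (polytomy == "reject")
        stop("orthogroup ", og, ": gene tree is multifurcating ",
             "(polytomy policy 'reject')")
      tr <- ape::multi2di(tr, random = FALSE)
      resolved <- c(resolved, og)
    }
    if (!ape::is.rooted(tr))
      stop("orthogroup ", og, ": gene tree is unrooted; ",
           "root it (see root_by_cost) before validation")
    out_trees[[og]] <- tr
  }
  structure(list(species_tree = stree, orthogroups = orthogroups,
                 trees = out_trees, map = map, resolved = resolved),
            class = "gene_forest")
}

#' @export
print.gene_forest <- function(x, ...) {
  cat("Gene forest:", length(x$orthogroups), "orthogroups,",
      length(x$map), "genes,", x$species_tree$index$ntip, "species\n")
  if (length(x$resolved))
    cat("  polytomies resolved in:", paste(x$resolved, collapse = ", "), "\n")
  invisible(x)
}
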