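#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` (an urn with `N` items of
#' which `K` are marked, `n` drawn without replacement).  Computed in log
#' space via [stats::phyper()], so tails at the scale of 1e-21 are exact and
#' do not underflow.
#'
#' @param N,K,n,k non-negative integers with `K <= N`, `n <= N`.
#' @param log10p return `log10` of the tail instead of the linear value.
#' @return the tail probability (or its log10; `k <= 0` gives 1,
#'   `k > min(K, n)` gives 0).
#' @export
hypergeometric_tail <- function(N, K, n, k, log10p = FALSE) {
  if (anyNA(c(N, K, n, k)) || N < 0 || K < 0 || n < 0 ||
      K > N || n > N || any(c(N, K, n, k) != round(c(N, K, n, k))))
    stop("inconsistent hypergeometric counts")
  if (k <= 0) return(if (log10p) 0 else 1)
  if (k > min(K, n)) return(if (log10p) -Inf else 0)
  lp <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  if (log10p) lp / log(10) else exp(lp)
}

#' A pair of focal species-tree branches
#'
#' The two nonterminal branches to be compared for parallel duplication
#' (in the C4 study: the ancestor of the Andropogoneae and the ancestor of
#' the Paniceae).  Neither branch may be ancestral to the other.
#'
#' @param stree a [species_tree()].
#' @param branch1,branch2 branch identifiers: a comma-joined species set or
#'   a character vector of species.
#' @return a `focal_branch_pair` object.
#' @export
focal_branch_pair <- function(stree, branch1, branch2) {
  b1 <- .canon_branch(branch1)
  b2 <- .canon_branch(branch2)
  br <- species_branches(stree)
  for (b in c(b1, b2)) {
    row <- br[br$branch == b, ]
    if (nrow(row) == 0L)
      stop("no species-tree branch has descendant set {", b, "}")
    if (row$branch_size < 2L)
      stop("focal branch {", b, "} is terminal")
  }
  s1 <- .split_comma(b1)
  s2 <- .split_comma(b2)
  if (all(s1 %in% s2) || all(s2 %in% s1))
    stop("focal branches must not be nested")
  structure(list(branch1 = b1, branch2 = b2), class = "focal_branch_pair")
}

#' Orthogroup-level overlap of retained duplications on two branches
#'
#' Counts the orthogroups with at least one retained duplication on each
#' focal branch and tests whether the overlap exceeds the hypergeometric
#' expectation `n * K / N` given the orthogroup universe.
#'
#' The default universe is every orthogroup of the forest containing at
#' least one gene from at least one species of each focal clade (the
#' orthogroups in which a duplication on both branches is observable);
#' pass `universe = "all"` for all orthogroups, or a character vector for
#' an explicit universe.
#'
#' @param fc a [filter_events()] result.
#' @param pair a [focal_branch_pair()].
#' @param universe `"observable"` (default), `"all"`, or explicit ids.
#' @return an `overlap_result`: list with `N`, `K`, `n`, `k_obs`,
#'   `expected`, `p_value`, `log10_p` and the overlapping orthogroup ids.
#' @export
overlap_enrichment <- function(fc, pair, universe = "observable") {
  forest <- attr(fc, "forest")
  og1 <- orthogroups_on_branch(fc, pair$branch1)
  og2 <- orthogroups_on_branch(fc, pair$branch2)
  if (is.character(universe) && length(universe) == 1L &&
      universe %in% c("observable", "all")) {
    if (is.null(forest))
      stop("catalog carries no forest; pass an explicit universe")
    ogs <- forest$orthogroups
    if (universe == "observable") {
      s1 <- .split_comma(pair$branch1)
      s2 <- .split_comma(pair$branch2)
      keep <- vapply(ogs, function(g) {
        sp <- unique(unclass(forest$map)[g])
        any(sp %in% s1) && any(sp %in% s2)
      }, logical(1))
      # orthogroups that carry a focal-branch event always belong to the
      # universe, even when post-duplication losses emptied the other clade
      uni <- union(names(ogs)[keep], union(og1, og2))
    } else {
      uni <- names(ogs)
    }
  } else {
    uni <- as.character(universe)
  }
  if (!length(uni)) stop("empty orthogroup universe")
  if (!all(og1 %in% uni) || !all(og2 %in% uni))
    stop("universe does not cover all orthogroups with focal-branch events")
  N <- length(uni)
  K <- length(og1)
  n <- length(og2)
  ov <- intersect(og1, og2)
  k <- length(ov)
  structure(list(
    branch1 = pair$branch1, branch2 = pair$branch2,
    N = N, K = K, n = n, k_obs = k,
    expected = n * K / N,
    p_value = hypergeometric_tail(N, K, n, k),
    log10_p = hypergeometric_tail(N, K, n, k, log10p = TRUE),
    overlap_orthogroups = sort(ov)
  ), class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("Orthogroup overlap between focal branches\n")
  cat("  branch 1 {", x$branch1, "}: ", x$K, " orthogroups\n", sep = "")
  cat("  branch 2 {", x$branch2, "}: ", x$n, " orthogroups\n", sep = "")
  cat(sprintf("  universe N = %d, observed overlap = %d, expected = %.4g\n",
              x$N, x$k_obs, x$expected))
  cat(sprintf("  hypergeometric P(X >= k) = %.4g (log10 = %.3f)\n",
              x$p_value, x$log10_p))
  invisible(x)
}

#' Are two duplication nodes parallel duplications of the same ortholog?
#'
#' Two duplication nodes of one reconciled gene tree are "same-gene"
#' parallel duplications iff every internal node strictly between them on
#' the gene-tree path (their LCA included, the two nodes themselves
#' excluded) is a speciation: the pre-duplication copies are then orthologs
#' rather than older paralogs.  If one node is an ancestor of the other the
#' result is `FALSE` by convention.  Symmetric in its two node arguments.
#'
#' @param recon a [label_events()] reconciled gene tree.
#' @param d1,d2 gene-tree node numbers of the two duplication nodes.
#' @return logical.
#' @export
same_gene_parallel <- function(recon, d1, d2) {
  idx <- recon$index
  if (recon$label[d1] != "duplication" || recon$label[d2] != "duplication")
    stop("d1 and d2 must be duplication nodes")
  if (d1 == d2) return(FALSE)
  lca <- node_lca(idx, d1, d2)
  if (lca == d1 || lca == d2) return(FALSE)
  path <- c(path_to_ancestor(idx, d1, lca),
            setdiff(path_to_ancestor(idx, d2, lca), lca))
  all(recon$label[path] == "speciation")
}

#' Enumerate parallel duplication events on a focal branch pair
#'
#' Every orthogroup with retained duplications on both focal branches
#' yields one orthogroup-level record.  Each cross pair of duplication
#' nodes is then tested with [same_gene_parallel()]; qualifying pairs are
#' deduplicated per ancestral gene lineage (the gene-tree LCA of the pair),
#' so multiple duplications on one branch within the same orthologous
#' lineage count once at gene level.
#'
#' @param fc a [filter_events()] result.
#' @param pair a [focal_branch_pair()].
#' @return data frame with columns `orthogroup`, `level` (`"orthogroup"` or
#'   `"gene"`), `node1`, `node2`, `lineage` (LCA node; `NA` for
#'   orthogroup-level rows).
#' @export
find_parallel_events <- function(fc, pair) {
  recons <- attr(fc, "reconciliations")
  if (is.null(recons))
    stop("catalog carries no reconciliations; rebuild with reconcile_forest")
  df <- as.data.frame(fc)
  ret <- df[df$retained, , drop = FALSE]
  ogs <- intersect(unique(ret$orthogroup[ret$branch == pair$branch1]),
                   unique(ret$orthogroup[ret$branch == pair$branch2]))
  out <- list()
  for (og in sort(ogs)) {
    out[[length(out) + 1L]] <- data.frame(
      orthogroup = og, level = "orthogroup",
      node1 = NA_integer_, node2 = NA_integer_, lineage = NA_integer_,
      stringsAsFactors = FALSE)
    recon <- recons[[og]]
    n1 <- ret$node[ret$orthogroup == og & ret$branch == pair$branch1]
    n2 <- ret$node[ret$orthogroup == og & ret$branch == pair$branch2]
    seen <- integer(0)
    for (a in n1) for (b in n2) {
      if (same_gene_parallel(recon, a, b)) {
        lca <- node_lca(recon$index, a, b)
        if (!(lca %in% seen)) {
          seen <- c(seen, lca)
          out[[length(out) + 1L]] <- data.frame(
            orthogroup = og, level = "gene",
            node1 = a, node2 = b, lineage = lca,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(orthogroup = character(0), level = character(0),
               node1 = integer(0), node2 = integer(0),
               lineage = integer(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
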