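#' Retention criteria for duplication events
#'
#' Two filters decide whether a duplication event is "retained":
#' criterion 1, the event must be witnessed by at least
#' `min_evidence_species` species, where a species witnesses an event only
#' if it has a gene in *both* paralog clades (under the default of 2 every
#' terminal-branch event fails); criterion 2, every species descending from
#' the event's species-tree node must retain at least one gene in each
#' paralog clade (full retention in all descendant genomes).
#'
#' @param min_evidence_species integer >= 1, default 2.
#' @param require_full_retention if `FALSE`, `retained` ignores criterion 2.
#' @return a `retention_criteria` object.
#' @export
retention_criteria <- function(min_evidence_species = 2L,
                               require_full_retention = TRUE) {
  min_evidence_species <- as.integer(min_evidence_species)
  if (is.na(min_evidence_species) || min_evidence_species < 1L)
    stop("min_evidence_species must be an integer >= 1")
  structure(list(min_evidence_species = min_evidence_species,
                 require_full_retention = isTRUE(require_full_retention)),
            class = "retention_criteria")
}

.split_semi <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else
    strsplit(x, ";", fixed = TRUE)[[1L]]
}

#' Evidence species of a duplication event
#'
#' Species with at least one gene in clade A *and* at least one in clade B.
#'
#' @param event one row of an event catalog (data frame row or list with
#'   `clade_a`, `clade_b`).
#' @param map a [load_gene_species_map()].
#' @return sorted character vector of species identifiers.
#' @export
evidence_species <- function(event, map) {
  sp_a <- unique(unclass(map)[.split_semi(event$clade_a)])
  sp_b <- unique(unclass(map)[.split_semi(event$clade_b)])
  sort(intersect(sp_a, sp_b))
}

#' @rdname filter_events
#' @param event one catalog row.
#' @export
passes_criterion1 <- function(event, criteria = retention_criteria()) {
  n <- if (!is.null(event$n_evidence)) event$n_evidence else
    length(.split_semi(event$evidence_species))
  n >= criteria$min_evidence_species
}

#' @rdname filter_events
#' @export
passes_criterion2 <- function(event, stree) {
  branch_sp <- .split_comma(event$branch)
  # clades were recorded with their species sets at reconciliation time
  sp_a <- .split_semi(event$species_a)
  sp_b <- .split_semi(event$species_b)
  all(branch_sp %in% sp_a) && all(branch_sp %in% sp_b)
}

#' Apply the retention filters to an event catalog
#'
#' Flags every event with `criterion1` (evidence from at least
#' `min_evidence_species` species), `criterion2` (both paralog copies
#' retained in every species that diverged after the duplication) and
#' `retained` (both).  Events mapped to the species-tree root are kept and
#' flagged `is_root_branch`; for them criterion 2 ranges over all species.
#'
#' @param catalog an [reconcile_forest()] event catalog.
#' @param criteria a [retention_criteria()].
#' @param stree the [species_tree()]; taken from the catalog's forest
#'   attribute when omitted.
#' @return a `filtered_catalog` (the catalog plus flag columns) whose
#'   `counts` attribute records the monotone filter chain
#'   (total, after criterion 1, retained).
#' @export
filter_events <- function(catalog, criteria = retention_criteria(),
                          stree = NULL) {
  if (is.null(stree)) stree <- attr(catalog, "forest")$species_tree
  df <- as.data.frame(catalog)
  n <- nrow(df)
  c1 <- df$n_evidence >= criteria$min_evidence_species
  c2 <- mapply(function(br, sa, sb) {
    bs <- .split_comma(br)
    all(bs %in% .split_semi(sa)) && all(bs %in% .split_semi(sb))
  }, df$branch, df$species_a, df$species_b, USE.NAMES = FALSE)
  if (n == 0L) { c1 <- logical(0); c2 <- logical(0) }
  df$criterion1 <- c1
  df$criterion2 <- c2
  df$retained <- if (criteria$require_full_retention) c1 & c2 else c1
  counts <- list(total = n, after_criterion1 = sum(c1),
                 retained = sum(df$retained))
  structure(df, class = c("filtered_catalog", "data.frame"),
            forest = attr(catalog, "forest"),
            reconciliations = attr(catalog, "reconciliations"),
            criteria = criteria, counts = counts)
}

#' @export
print.filtered_catalog <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat("Filtered event catalog\n")
  cat("  total events:        ", cnt$total, "\n")
  cat("  after criterion 1:   ", cnt$after_criterion1, "\n")
  cat("  fully retained:      ", cnt$retained, "\n")
  invisible(x)
}

#' @export
summary.filtered_catalog <- function(object, ...) {
  attr(object, "counts")
}

#' Filter-chain bookkeeping
#'
#' Given the total number of duplication events and the number on terminal
#' branches (which under the default criteria fail criterion 1 uniformly),
#' returns the count surviving criterion 1.
#'
#' @param n_total total duplication events.
#' @param n_terminal events on terminal species-tree branches.
#' @return list with `total`, `terminal` and `criterion1_survivors`.
#' @export
filter_chain_counts <- function(n_total, n_terminal) {
  stopifnot(n_total >= 0, n_terminal >= 0, n_terminal <= n_total)
  list(total = n_total, terminal = n_terminal,
       criterion1_survivors = n_total - n_terminal)
}

#' Per-branch summary of retained duplications
#'
#' One row per internal species-tree node (nonterminal branches, plus the
#' flagged root row so that totals add up): retained-event count and the
#' number of distinct orthogroups with at least one retained event there.
#'
#' @param fc a [filter_events()] result.
#' @param stree the [species_tree()]; defaults to the catalog's.
#' @return data frame `branch`, `branch_size`, `is_root`, `n_events`,
#'   `n_orthogroups`.
#' @export
branch_summary <- function(fc, stree = NULL) {
  if (is.null(stree)) stree <- attr(fc, "forest")$species_tree
  br <- species_branches(stree, nonterminal = TRUE)
  ret <- as.data.frame(fc)[fc$retained, , drop = FALSE]
  br$n_events <- vapply(br$branch, function(b) sum(ret$branch == b),
                        integer(1))
  br$n_orthogroups <- vapply(br$branch, function(b)
    length(unique(ret$orthogroup[ret$branch == b])), integer(1))
  rownames(br) <- NULL
  br
}

#' Orthogroups with a retained event on a given branch
#'
#' @param fc a [filter_events()] result.
#' @param branch branch identifier (comma-joined sorted species set) or a
#'   character vector of species to be joined.
#' @return character vector of orthogroup ids.
#' @export
orthogroups_on_branch <- function(fc, branch) {
  branch <- .canon_branch(branch)
  sort(unique(fc$orthogroup[fc$retained & fc$branch == branch]))
}

.canon_branch <- function(branch) {
  if (length(branch) > 1L) return(paste(sort(branch), collapse = ","))
  paste(sort(.split_comma(branch)), collapse = ",")
}

.split_comma <- function(x) strsplit(x, ",", fixed = TRUE)[[1L]]
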