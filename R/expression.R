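#' Expression table (TPM matrix plus sample sheet)
#'
#' @param mat numeric matrix, genes x samples, non-negative TPM values.
#' @param samples data frame with columns `sample`, `species`, `condition`
#'   (`"BS"`, `"M"` or a leaf-stage label such as `"leaf"`), `replicate`.
#' @return an `expression_table` object.
#' @export
expression_table <- function(mat, samples) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "double"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample", "species", "condition", "replicate")
  if (!all(req %in% names(samples)))
    stop("sample sheet needs columns: ", paste(req, collapse = ", "))
  if (ncol(mat) != nrow(samples))
    stop("matrix has ", ncol(mat), " columns but sample sheet has ",
         nrow(samples), " rows")
  if (is.null(colnames(mat))) colnames(mat) <- samples$sample
  if (!identical(colnames(mat), as.character(samples$sample)))
    mat <- mat[, match(samples$sample, colnames(mat)), drop = FALSE]
  if (any(mat < 0, na.rm = TRUE)) stop("TPM values must be non-negative")
  structure(list(mat = mat, samples = samples), class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat("Expression table:", nrow(x$mat), "genes x", ncol(x$mat), "samples\n")
  print(table(x$samples$species, x$samples$condition))
  invisible(x)
}

#' Read an expression table from TSV files
#'
#' @param matrix_path genes-by-samples TSV (first column = gene id, header
#'   = sample names).
#' @param samples_path sample sheet TSV with columns `sample`, `species`,
#'   `condition`, `replicate`.
#' @return an [expression_table()].
#' @export
load_expression <- function(matrix_path, samples_path) {
  m <- utils::read.delim(matrix_path, check.names = FALSE,
                         comment.char = "#", stringsAsFactors = FALSE)
  mat <- as.matrix(m[, -1L, drop = FALSE])
  rownames(mat) <- as.character(m[[1L]])
  s <- utils::read.delim(samples_path, comment.char = "#",
                         stringsAsFactors = FALSE)
  expression_table(mat, s)
}

#' Subset an expression table to one species
#'
#' @param x an [expression_table()].
#' @param species species identifier.
#' @return an [expression_table()] with that species' samples only.
#' @export
subset_species <- function(x, species) {
  keep <- x$samples$species == species
  if (!any(keep)) stop("no samples for species ", species)
  expression_table(x$mat[, keep, drop = FALSE],
                   x$samples[keep, , drop = FALSE])
}

# Welch t on log2(TPM+1) per gene; zero-variance-in-both-groups rows get
# p = 0 when the means differ and p = 1 when they are equal (the noiseless
# limit of the test).
.welch_rows <- function(a, b) {
  n <- nrow(a)
  p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    xa <- a[i, ]; xb <- b[i, ]
    if (stats::var(xa) == 0 && stats::var(xb) == 0) {
      p[i] <- if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else 0
    } else {
      p[i] <- tryCatch(stats::t.test(xa, xb)$p.value,
                       error = function(e) NA_real_)
    }
  }
  p
}

#' Classify genes as bundle-sheath- or mesophyll-preferential
#'
#' Per-gene Welch two-sample test of `log2(TPM + 1)` between BS and M
#' replicates of one species, Benjamini-Hochberg adjusted across all tested
#' genes.  A gene is called `BS` (resp. `M`) when the adjusted p-value is
#' at most `alpha` and the fold change (ratio of mean TPM) is at least
#' `min_fc` in that direction; genes whose mean TPM is below `floor_tpm`
#' in both conditions are not tested and called `none`.
#'
#' @param x an [expression_table()].
#' @param species species to classify.
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param min_fc minimum fold change (default 2).
#' @param floor_tpm expression floor below which a gene is untested
#'   (default 1 TPM).
#' @return a `preference_calls` data frame: `gene`, `mean_bs`, `mean_m`,
#'   `fold_change` (BS/M ratio of means), `p`, `padj`, `call`.
#' @export
classify_cell_preference <- function(x, species, alpha = 0.05, min_fc = 2,
                                     floor_tpm = 1) {
  keep_bs <- x$samples$species == species & x$samples$condition == "BS"
  keep_m <- x$samples$species == species & x$samples$condition == "M"
  if (sum(keep_bs) < 2L || sum(keep_m) < 2L)
    stop("need >= 2 BS and >= 2 M replicates for species ", species)
  bs <- x$mat[, keep_bs, drop = FALSE]
  m <- x$mat[, keep_m, drop = FALSE]
  mean_bs <- rowMeans(bs)
  mean_m <- rowMeans(m)
  tested <- pmax(mean_bs, mean_m) >= floor_tpm
  p <- rep(NA_real_, nrow(x$mat))
  p[tested] <- .welch_rows(log2(bs[tested, , drop = FALSE] + 1),
                           log2(m[tested, , drop = FALSE] + 1))
  padj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  padj[ok] <- bh_adjust(p[ok])
  fc <- mean_bs / mean_m
  call <- rep("none", length(p))
  sig <- !is.na(padj) & padj <= alpha
  call[sig & fc >= min_fc] <- "BS"
  call[sig & fc <= 1 / min_fc] <- "M"
  res <- data.frame(gene = rownames(x$mat), mean_bs = mean_bs,
                    mean_m = mean_m, fold_change = fc, p = p, padj = padj,
                    call = call, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, class = c("preference_calls", "data.frame"),
            species = species, alpha = alpha, min_fc = min_fc)
}

# two-sided exact binomial p by clipped doubling of the smaller tail
.binom_two_sided <- function(x, n, p0) {
  if (p0 <= 0) return(if (x > 0) 0 else 1)
  if (p0 >= 1) return(if (x < n) 0 else 1)
  lower <- stats::pbinom(x, n, p0)
  upper <- stats::pbinom(x - 1, n, p0, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

.stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.05, "*", "")))
}

#' Cell-type preference enrichment of a gene cohort
#'
#' For each cell type (BS and M) compares the proportion of preferential
#' genes within a cohort against the background proportion among all
#' classified genes, with a two-sided exact binomial test (clipped doubling
#' of the smaller tail).  A background proportion of exactly 0 (or 1) makes
#' any discordant observation impossible under the null, and the p-value
#' degenerates to 0/1 accordingly.
#'
#' @param genes character vector, the cohort (must be classified in
#'   `background`).
#' @param calls [classify_cell_preference()] calls for the cohort's
#'   species; used to look up the cohort's calls.
#' @param background calls defining the background universe (defaults to
#'   `calls`, i.e. all classified genes of the species).
#' @return data frame, one row per cell type: `cell_type`, `set_n`,
#'   `set_hits`, `set_prop`, `bg_prop`, `p`, `stars`.
#' @export
preference_enrichment <- function(genes, calls, background = calls) {
  if (!length(genes)) stop("empty gene set")
  idx <- match(genes, calls$gene)
  if (anyNA(idx))
    stop("cohort gene(s) absent from the calls: ",
         paste(utils::head(genes[is.na(idx)], 5L), collapse = ", "))
  set_calls <- calls$call[idx]
  rows <- lapply(c("BS", "M"), function(ct) {
    x <- sum(set_calls == ct)
    n <- length(set_calls)
    p0 <- mean(background$call == ct)
    p <- .binom_two_sided(x, n, p0)
    data.frame(cell_type = ct, set_n = n, set_hits = x, set_prop = x / n,
               bg_prop = p0, p = p, stars = .stars(p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Construct a concordance result from its counts
#'
#' @param n_assessed number of duplicate pairs assessed.
#' @param n_concordant number with the same dominant copy in both species.
#' @param events optional per-event data frame.
#' @return a `concordance_result` with `percentage = 100 * n_concordant /
#'   n_assessed`.
#' @export
concordance_result <- function(n_assessed, n_concordant, events = NULL) {
  stopifnot(n_assessed >= 0, n_concordant >= 0, n_concordant <= n_assessed)
  structure(list(n_assessed = n_assessed, n_concordant = n_concordant,
                 percentage = if (n_assessed > 0)
                   100 * n_concordant / n_assessed else NA_real_,
                 events = events),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "Expression-dominance concordance: %d/%d duplicate pairs (%.1f%%)\n",
    x$n_concordant, x$n_assessed, x$percentage))
  invisible(x)
}

#' Expression-dominance concordance of duplicate pairs across two species
#'
#' For every retained duplication on an ancestral branch, each paralog
#' clade is represented in each species by that species' most highly
#' expressed descendant gene (mean TPM over the samples with the given
#' condition).  An event is assessed only if, in *each* species, the higher
#' of its two clade representatives exceeds `threshold_tpm` (the >10 TPM
#' inclusion rule).  The dominant clade per species is the clade of the
#' higher representative; the event is concordant when both species agree.
#' Events with an exact representative tie in either species, or with a
#' clade unrepresented in a species, are excluded from `n_assessed`.
#'
#' @param fc a [filter_events()] result.
#' @param branch ancestral branch identifier (species set); both `species1`
#'   and `species2` must descend from it.
#' @param x1,x2 [expression_table()]s holding the two species' samples.
#' @param species1,species2 the two species compared; inferred when each
#'   table holds a single species.
#' @param threshold_tpm inclusion threshold (default 10 TPM).
#' @param condition sample condition used for dominance (default `"leaf"`).
#' @return a [concordance_result()] with a per-event data frame.
#' @export
dominance_concordance <- function(fc, branch, x1, x2,
                                  species1 = NULL, species2 = NULL,
                                  threshold_tpm = 10, condition = "leaf") {
  branch <- .canon_branch(branch)
  infer <- function(x, given) {
    if (!is.null(given)) return(given)
    sp <- unique(x$samples$species)
    if (length(sp) != 1L)
      stop("expression table holds several species; pass species1/species2")
    sp
  }
  species1 <- infer(x1, species1)
  species2 <- infer(x2, species2)
  branch_sp <- .split_comma(branch)
  if (!all(c(species1, species2) %in% branch_sp))
    stop("both species must descend from branch {", branch, "}")
  map <- attr(fc, "forest")$map
  cond_mean <- function(x, sp) {
    keep <- x$samples$species == sp & x$samples$condition == condition
    if (!any(keep)) stop("no '", condition, "' samples for species ", sp)
    rowMeans(x$mat[, keep, drop = FALSE])
  }
  e1 <- cond_mean(x1, species1)
  e2 <- cond_mean(x2, species2)
  df <- as.data.frame(fc)
  ev <- df[df$retained & df$branch == branch, , drop = FALSE]
  rep_tpm <- function(clade, sp, expr) {
    genes <- .split_semi(clade)
    genes <- genes[unclass(map)[genes] == sp]
    genes <- genes[genes %in% names(expr)]
    if (!length(genes)) return(NA_real_)
    max(expr[genes])
  }
  rows <- lapply(seq_len(nrow(ev)), function(i) {
    a1 <- rep_tpm(ev$clade_a[i], species1, e1)
    b1 <- rep_tpm(ev$clade_b[i], species1, e1)
    a2 <- rep_tpm(ev$clade_a[i], species2, e2)
    b2 <- rep_tpm(ev$clade_b[i], species2, e2)
    ok <- !anyNA(c(a1, b1, a2, b2)) &&
      max(a1, b1) > threshold_tpm && max(a2, b2) > threshold_tpm &&
      a1 != b1 && a2 != b2
    dom1 <- if (isTRUE(a1 > b1)) "A" else if (isTRUE(b1 > a1)) "B"
            else NA_character_
    dom2 <- if (isTRUE(a2 > b2)) "A" else if (isTRUE(b2 > a2)) "B"
            else NA_character_
    data.frame(orthogroup = ev$orthogroup[i], node = ev$node[i],
               dominant_1 = dom1, dominant_2 = dom2,
               included = ok,
               concordant = ok && identical(dom1, dom2),
               stringsAsFactors = FALSE)
  })
  events <- if (length(rows)) do.call(rbind, rows) else
    data.frame(orthogroup = character(0), node = integer(0),
               dominant_1 = character(0), dominant_2 = character(0),
               included = logical(0), concordant = logical(0),
               stringsAsFactors = FALSE)
  concordance_result(sum(events$included),
                     sum(events$concordant & events$included),
                     events = events)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values (FDR), capped at 1.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must be numbers in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Ontology-term enrichment of an orthogroup set
#'
#' Hypergeometric over-representation of each annotation term within a set
#' of orthogroups given a universe, Benjamini-Hochberg corrected across all
#' tested terms; `significant` marks adjusted p <= `fdr`.
#'
#' @param set character vector of orthogroup ids (subset of `universe`).
#' @param universe character vector of orthogroup ids.
#' @param annot data frame with columns `orthogroup`, `term` (optionally
#'   `description`); annotations of orthogroups outside the universe are
#'   ignored.
#' @param fdr significance cutoff on the adjusted p (default 0.05).
#' @return data frame, one row per term occurring in the set: `term`, `k`
#'   (set hits), `K` (universe hits), `n` (set size), `N` (universe size),
#'   `p`, `padj`, `significant`; sorted by `p`.
#' @export
term_enrichment <- function(set, universe, annot, fdr = 0.05) {
  set <- unique(as.character(set))
  universe <- unique(as.character(universe))
  if (!all(set %in% universe))
    stop("set is not a subset of the universe")
  annot <- annot[annot$orthogroup %in% universe, , drop = FALSE]
  terms_set <- unique(annot$term[annot$orthogroup %in% set])
  if (!length(terms_set))
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      padj = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE))
  N <- length(universe)
  n <- length(set)
  rows <- lapply(sort(terms_set), function(tm) {
    with_term <- unique(annot$orthogroup[annot$term == tm])
    K <- length(with_term)
    k <- length(intersect(with_term, set))
    if (K == 0L) {                       # unreachable when annot covers set
      warning("term ", tm, " unannotated in the universe; skipped")
      return(NULL)
    }
    data.frame(term = tm, k = k, K = K, n = n, N = N,
               p = hypergeometric_tail(N, K, n, k),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$padj <- bh_adjust(res$p)
  res$significant <- res$padj <= fdr
  res <- res[order(res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}
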