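#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement to a common depth so
#' richness-sensitive indices are comparable across samples. Samples with
#' fewer reads than `depth` are dropped with a warning.
#'
#' @param counts integer matrix, taxa x samples.
#' @param depth target reads per sample (>= 1). The full-scale convention is
#'   19000; synthetic tables use proportionally smaller depths.
#' @param seed integer RNG seed.
#' @return rarefied integer matrix (taxa x samples); every retained column
#'   sums to `depth`.
#' @export
rarefy <- function(counts, depth = 19000L, seed = 1L) {
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  totals <- colSums(counts)
  shallow <- totals < depth
  if (any(shallow)) {
    warning("sample(s) below rarefaction depth dropped: ",
            paste(colnames(counts)[shallow], collapse = ", "), call. = FALSE)
    counts <- counts[, !shallow, drop = FALSE]
  }
  if (ncol(counts) == 0) stop("no samples at rarefaction depth", call. = FALSE)
  set.seed(seed)
  out <- withCallingHandlers(
    t(vegan::rrarefy(t(counts), depth)),
    warning = function(w) {
      # vegan advises about "observed counts" whenever the smallest positive
      # count exceeds 1; that is expected for aggregated family-level tables
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  storage.mode(out) <- "integer"
  attr(out, "kind") <- "counts"
  out
}

#' Midpoint-root a phylogeny
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path, so the
#' two deepest leaves are equidistant from the root.
#'
#' @param tree an [ape] phylo object.
#' @return a rooted phylo object.
#' @export
midpoint_root <- function(tree) {
  if (length(tree$tip.label) < 2) return(tree)
  phangorn::midpoint(tree)
}

chao1 <- function(x) {
  x <- x[x > 0]
  s_obs <- length(x)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
}

strong_index <- function(x) {
  x <- x[x > 0]
  s <- length(x)
  n <- sum(x)
  b <- cumsum(sort(x, decreasing = TRUE))
  max(b / n - seq_len(s) / s)
}

#' Alpha-diversity indices for one sample
#'
#' Computes the six indices used for richness/evenness screening: Shannon H'
#' (base 2), Pielou evenness H'/log2(S_obs), Simpson 1 - sum(p^2), Chao1
#' (classic estimator, bias-corrected when no doubletons), Faith's
#' phylogenetic diversity (branch length of the minimal rooted subtree
#' spanning observed taxa, including the path to the root), and Strong's
#' dominance index (maximum deviation of the cumulative rank-abundance curve
#' from the uniform line).
#'
#' @param x nonnegative count vector named by taxon.
#' @param tree rooted phylogeny covering the observed taxa; NULL skips Faith.
#' @return named numeric vector `shannon`, `pielou`, `simpson`, `chao1`,
#'   `faith`, `strong`; all NA for an all-zero sample.
#' @export
alpha_indices <- function(x, tree = NULL) {
  out <- c(shannon = NA_real_, pielou = NA_real_, simpson = NA_real_,
           chao1 = NA_real_, faith = NA_real_, strong = NA_real_)
  if (any(x < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (sum(x) == 0) return(out)
  s_obs <- sum(x > 0)
  h <- vegan::diversity(x, index = "shannon", base = 2)
  out["shannon"] <- h
  out["pielou"] <- if (s_obs > 1) h / log2(s_obs) else NA_real_
  out["simpson"] <- vegan::diversity(x, index = "simpson")
  out["chao1"] <- chao1(x)
  out["strong"] <- strong_index(x)
  if (!is.null(tree)) {
    if (is.null(names(x))) stop("counts must be named by taxon for Faith",
                                call. = FALSE)
    comm <- matrix(x, nrow = 1, dimnames = list("s", names(x)))
    out["faith"] <- picante::pd(comm, tree, include.root = TRUE)$PD
  }
  out
}

#' Alpha-diversity table for all samples
#'
#' @param counts taxa x samples count matrix.
#' @param tree optional rooted phylogeny for Faith's PD.
#' @return data.frame with one row per (sample, index) pair: `sample_id`,
#'   `index`, `value`.
#' @export
alpha_diversity <- function(counts, tree = NULL) {
  res <- lapply(colnames(counts), function(s) {
    v <- alpha_indices(setNames(counts[, s], rownames(counts)), tree)
    data.frame(sample_id = s, index = names(v), value = unname(v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' UniFrac beta-diversity
#'
#' Unweighted UniFrac is the fraction of branch length unique to either
#' community among the branch length spanned by both (a presence/absence,
#' qualitative measure); weighted UniFrac sums branch lengths weighted by the
#' absolute difference in the proportion of descendant reads (quantitative;
#' the non-length-normalised variant by default).
#'
#' @param counts taxa x samples matrix; taxa must be tips of `tree`.
#' @param tree rooted phylogeny (see [midpoint_root()]).
#' @param weighted compute weighted UniFrac.
#' @param normalized length-normalise the weighted variant.
#' @return symmetric sample x sample distance matrix with a `metric`
#'   attribute.
#' @export
unifrac <- function(counts, tree, weighted = FALSE, normalized = FALSE) {
  if (!ape::is.rooted(tree))
    stop("tree must be rooted; apply midpoint_root() first", call. = FALSE)
  missing <- setdiff(rownames(counts), tree$tip.label)
  if (length(missing) > 0)
    stop("taxa absent from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(counts, taxa_are_rows = TRUE),
    phyloseq::phy_tree(tree))
  d <- phyloseq::UniFrac(ps, weighted = weighted, normalized = normalized)
  m <- as.matrix(d)
  attr(m, "metric") <- if (weighted) "weighted_unifrac" else "unweighted_unifrac"
  m
}

#' Permutation test of group separation in a distance matrix
#'
#' Compares mean between-group distance against mean within-group distance,
#' with a p-value from permuting group labels. This is an interpretation of
#' feeding a beta-diversity matrix into two-sample testing; it is not a
#' rank-sum test on raw distances (those are not exchangeable).
#'
#' @param d symmetric distance matrix with sample names.
#' @param groups named group labels (two levels) for the samples of `d`.
#' @param n_sim number of label permutations.
#' @param seed integer RNG seed.
#' @return list with `statistic` (mean between - mean within) and `p`.
#' @export
beta_group_test <- function(d, groups, n_sim = 10000L, seed = 1L) {
  groups <- groups[rownames(d)]
  stat <- function(g) {
    same <- outer(g, g, "==")
    ut <- upper.tri(d)
    mean(d[ut & !same]) - mean(d[ut & same])
  }
  obs <- stat(groups)
  set.seed(seed)
  exceed <- sum(vapply(seq_len(n_sim),
                       function(i) stat(sample(groups)) >= obs - 1e-12,
                       logical(1)))
  list(statistic = obs, p = (1 + exceed) / (1 + n_sim))
}
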