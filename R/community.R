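# OTU clustering, library rarefaction, diversity indices, and unweighted
# UniFrac comparison of clone libraries with UPGMA/jackknife support.

#' OTU table constructor
#'
#' @param counts non-negative integer matrix, OTUs in rows, samples in
#'   columns; all-zero rows are dropped.
#' @param cutoff similarity cutoff the OTUs were defined at.
#' @param representatives optional named vector, OTU id -> representative
#'   sequence id.
#' @param membership optional named vector, sequence id -> OTU id.
#' @return object of class `coxl_otu_table`.
#' @export
otu_table_coxl <- function(counts, cutoff = NA_real_,
                           representatives = NULL, membership = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != floor(counts)))
    .stopf("counts must be non-negative integers")
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  structure(list(counts = counts, cutoff = cutoff,
                 representatives = representatives[rownames(counts)],
                 membership = membership),
            class = "coxl_otu_table")
}

#' @export
print.coxl_otu_table <- function(x, ...) {
  cat("OTU table:", nrow(x$counts), "OTUs x", ncol(x$counts),
      "samples", sprintf("(cutoff %.2f)\n", x$cutoff))
  cat("  library sizes:",
      paste(colSums(x$counts), collapse = " "), "\n")
  invisible(x)
}

#' Cluster sequences into OTUs at a similarity cutoff
#'
#' Furthest-neighbour (complete-linkage) agglomeration on the distance
#' `1 - S`, cut at `1 - cutoff`, so every pair inside an OTU is at least
#' `cutoff` similar. The representative of each OTU is its first member in
#' input order. Average linkage is available as an alternative.
#'
#' @param similarity_matrix symmetric similarity matrix with unit diagonal
#'   (e.g. from [pairwise_similarity()]).
#' @param cutoff similarity level defining OTUs, in (0, 1]; 0.90 is the
#'   usual choice for coxL.
#' @param sample_map optional data frame `seq_id`, `sample_id`; defaults to
#'   one sample.
#' @param linkage `"complete"` (default) or `"average"`.
#' @return a [otu_table_coxl()] object.
#' @examples
#' S <- pairwise_similarity(c(a = "AAAA", b = "AAAT", c = "GGCC"))
#' cluster_otus(S, 0.9)
#' @export
cluster_otus <- function(similarity_matrix, cutoff,
                         sample_map = NULL,
                         linkage = c("complete", "average")) {
  linkage <- match.arg(linkage)
  S <- as.matrix(similarity_matrix)
  n <- nrow(S)
  if (n != ncol(S) || max(abs(S - t(S))) > 1e-12 ||
      max(abs(diag(S) - 1)) > 1e-12)
    .stopf("similarity_matrix must be symmetric with unit diagonal")
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 ||
      cutoff > 1)
    .stopf("cutoff must be in (0, 1]")
  ids <- rownames(S)
  if (is.null(ids)) ids <- sprintf("seq%04d", seq_len(n))
  if (n == 1L) {
    memb <- setNames(1L, ids)
  } else {
    hc <- hclust(as.dist(1 - S), method = linkage)
    memb <- cutree(hc, h = 1 - cutoff)
    names(memb) <- ids
  }
  # Relabel clusters by first appearance, representative = first member.
  first <- !duplicated(memb)
  order_map <- setNames(seq_len(sum(first)), memb[first])
  otu_of <- order_map[as.character(memb)]
  otu_ids <- sprintf("OTU%03d", seq_len(max(otu_of)))
  membership <- setNames(otu_ids[otu_of], ids)
  reps <- setNames(ids[first][order(order_map[as.character(memb[first])])],
                   otu_ids)

  samples <- rep("S1", n)
  if (!is.null(sample_map)) {
    stopifnot(all(c("seq_id", "sample_id") %in% names(sample_map)))
    hit <- match(ids, sample_map$seq_id)
    samples[!is.na(hit)] <- sample_map$sample_id[hit[!is.na(hit)]]
  }
  counts <- unclass(table(factor(membership, levels = otu_ids),
                          factor(samples)))
  otu_table_coxl(counts, cutoff = cutoff, representatives = reps,
                 membership = membership)
}

#' Rarefy an OTU table to a fixed library size
#'
#' Normalizes libraries to a common sequencing effort by sampling exactly
#' `n` sequences per sample, uniformly without replacement (e.g. the 24
#' sequences of the smallest library across nine soil stations).
#'
#' @param table a `coxl_otu_table`.
#' @param n target library size; every sample must hold at least `n`.
#' @param seed integer seed, recorded on the result.
#' @return rarefied `coxl_otu_table` (all-zero OTU rows pruned), with
#'   attribute `subsample_seed`.
#' @export
subsample_otu_table <- function(table, n, seed = 1L) {
  stopifnot(inherits(table, "coxl_otu_table"))
  n <- .check_count(n, "n", min = 1L)
  sizes <- colSums(table$counts)
  if (any(sizes < n))
    .stopf("library smaller than n = %d: %s", n,
           paste(colnames(table$counts)[sizes < n], collapse = ", "))
  counts <- .with_scenario_seed(seed, "subsample", {
    apply(table$counts, 2L, function(col) {
      pool <- rep(seq_along(col), col)
      kept <- pool[sample.int(length(pool), n)]
      tabulate(kept, nbins = length(col))
    })
  })
  rownames(counts) <- rownames(table$counts)
  out <- otu_table_coxl(counts, cutoff = table$cutoff,
                        representatives = table$representatives,
                        membership = table$membership)
  attr(out, "subsample_seed") <- as.integer(seed)
  out
}

#' Diversity indices per sample (and optionally pooled per group)
#'
#' Observed richness, Shannon `H' = -sum p_i ln p_i` (natural log) and the
#' Simpson sum `D = sum p_i^2`. Because the literature uses all three
#' Simpson conventions, the dominance form `D`, its complement `1 - D` and
#' the inverse `1/D` are all reported; lower `D` (or higher `1-D`, `1/D`)
#' means less dominance.
#'
#' @param table a `coxl_otu_table`.
#' @param groups optional named vector, sample id -> group label; when
#'   given, pooled per-group indices are appended (flagged in `scope`).
#' @return data frame with `sample_id`, `scope`, `n_sequences`, `richness`,
#'   `shannon_h`, `simpson_d`, `simpson_complement`, `simpson_inverse`.
#' @examples
#' tab <- otu_table_coxl(matrix(c(12, 6, 6), 3, 1,
#'                              dimnames = list(NULL, "S1")))
#' otu_diversity(tab)
#' @export
otu_diversity <- function(table, groups = NULL) {
  stopifnot(inherits(table, "coxl_otu_table"))
  one <- function(counts, id, scope) {
    tot <- sum(counts)
    if (tot == 0) .stopf("empty sample: %s", id)
    p <- counts[counts > 0] / tot
    d <- sum(p^2)
    data.frame(sample_id = id, scope = scope, n_sequences = tot,
               richness = length(p), shannon_h = -sum(p * log(p)),
               simpson_d = d, simpson_complement = 1 - d,
               simpson_inverse = 1 / d, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, lapply(colnames(table$counts), function(s)
    one(table$counts[, s], s, "sample")))
  if (!is.null(groups)) {
    stopifnot(all(colnames(table$counts) %in% names(groups)))
    for (g in unique(groups[colnames(table$counts)])) {
      cols <- colnames(table$counts)[groups[colnames(table$counts)] == g]
      res <- rbind(res, one(rowSums(table$counts[, cols, drop = FALSE]),
                            g, "group"))
    }
  }
  rownames(res) <- NULL
  res
}

# Edge-wise sample incidence: logical matrix (edge x sample), TRUE when any
# leaf below the edge belongs to the sample.
.edge_sample_incidence <- function(tree, sample_of_tip) {
  samples <- sort(unique(sample_of_tip))
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  inc <- matrix(FALSE, nnode, length(samples),
                dimnames = list(NULL, samples))
  inc[cbind(seq_len(ntip), match(sample_of_tip, samples))] <- TRUE
  tr <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1L]; chl <- tr$edge[e, 2L]
    inc[par, ] <- inc[par, ] | inc[chl, ]
  }
  list(edge_inc = inc[tree$edge[, 2L], , drop = FALSE], samples = samples)
}

#' Unweighted UniFrac distances between samples
#'
#' For each pair of samples, the fraction of the tree's branch length that
#' leads exclusively to sequences of one sample, over the branch length
#' covered by the union of both: `(unique branch length) / (union branch
#' length)`. Computed by direct branch enumeration on the rooted input tree.
#'
#' @param tree rooted `phylo` with non-negative branch lengths; leaves are
#'   sequence ids.
#' @param sample_map data frame `seq_id`, `sample_id` assigning each leaf
#'   to a sample. Leaves absent from the map are dropped with a warning;
#'   mapped sequences missing from the tree are an error.
#' @return symmetric distance matrix over samples, values in `[0, 1]`.
#' @export
unifrac_distance <- function(tree, sample_map) {
  stopifnot(inherits(tree, "phylo"),
            all(c("seq_id", "sample_id") %in% names(sample_map)))
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    .stopf("tree must have non-negative branch lengths")
  missing <- setdiff(sample_map$seq_id, tree$tip.label)
  if (length(missing))
    .stopf("mapped sequences not in tree: %s",
           paste(missing, collapse = ", "))
  unmapped <- setdiff(tree$tip.label, sample_map$seq_id)
  if (length(unmapped)) {
    .warnf("excluding %d unmapped leaves", length(unmapped))
    tree <- ape::drop.tip(tree, unmapped)
  }
  sample_of_tip <- sample_map$sample_id[match(tree$tip.label,
                                              sample_map$seq_id)]
  es <- .edge_sample_incidence(tree, sample_of_tip)
  inc <- es$edge_inc
  len <- tree$edge.length
  k <- length(es$samples)
  D <- matrix(0, k, k, dimnames = list(es$samples, es$samples))
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      union_len <- sum(len[inc[, i] | inc[, j]])
      if (union_len <= 0)
        .stopf("zero union branch length between %s and %s",
               es$samples[i], es$samples[j])
      shared <- sum(len[inc[, i] & inc[, j]])
      D[i, j] <- D[j, i] <- (union_len - shared) / union_len
    }
  }
  D
}

# Clades (sets of sample labels) of an hclust tree, as canonical strings.
.hclust_clades <- function(hc) {
  labs <- hc$labels
  sets <- vector("list", nrow(hc$merge))
  out <- character(nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    members <- unlist(lapply(hc$merge[k, ], function(m)
      if (m < 0) labs[-m] else sets[[m]]))
    sets[[k]] <- members
    out[k] <- paste(sort(members), collapse = "|")
  }
  out
}

#' UPGMA dendrogram of samples with jackknife node support
#'
#' Clusters samples by UPGMA (average linkage) on their unweighted UniFrac
#' distances, then estimates node support by jackknifing the sequences:
#' each replicate keeps a random `keep_frac` of all mapped sequences,
#' recomputes UniFrac, re-clusters, and a node's support is the fraction of
#' usable replicates whose tree contains the same sample clade. Replicates
#' that empty a sample are skipped and counted.
#'
#' @param tree rooted `phylo` over sequence leaves.
#' @param sample_map data frame `seq_id`, `sample_id`.
#' @param keep_frac fraction of sequences kept per replicate, in (0, 1].
#' @param reps number of jackknife replicates (>= 1).
#' @param seed integer seed.
#' @return list with `hclust` (full-data UPGMA), `unifrac` (full-data
#'   distance matrix), `support` (data frame `clade`, `support`),
#'   `n_reps_used`, `n_degenerate`.
#' @export
upgma_jackknife <- function(tree, sample_map, keep_frac = 0.75,
                            reps = 100L, seed = 1L) {
  if (!is.numeric(keep_frac) || keep_frac <= 0 || keep_frac > 1)
    .stopf("keep_frac must be in (0, 1]")
  reps <- .check_count(reps, "reps", min = 1L)
  full_d <- unifrac_distance(tree, sample_map)
  hc <- hclust(as.dist(full_d), method = "average")
  clades <- .hclust_clades(hc)
  n_seq <- nrow(sample_map)
  n_keep <- max(2L, floor(keep_frac * n_seq))
  hits <- setNames(numeric(length(clades)), clades)
  used <- 0L; degenerate <- 0L
  .with_scenario_seed(seed, "upgma_jackknife", {
    for (r in seq_len(reps)) {
      keep <- sample_map[sample.int(n_seq, n_keep), , drop = FALSE]
      if (length(unique(keep$sample_id)) <
          length(unique(sample_map$sample_id))) {
        degenerate <- degenerate + 1L
        next
      }
      d_r <- suppressWarnings(unifrac_distance(tree, keep))
      d_r <- d_r[rownames(full_d), colnames(full_d)]
      hc_r <- hclust(as.dist(d_r), method = "average")
      found <- .hclust_clades(hc_r)
      hits[clades %in% found] <- hits[clades %in% found] + 1
      used <- used + 1L
    }
  })
  if (used == 0L) .stopf("all %d jackknife replicates were degenerate", reps)
  list(hclust = hc, unifrac = full_d,
       support = data.frame(clade = clades, support = unname(hits / used),
                            stringsAsFactors = FALSE),
       n_reps_used = used, n_degenerate = degenerate)
}
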