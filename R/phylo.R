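# Reference-anchored MSA, p-distances, neighbor-joining tree, rooting,
# column bootstrap, 762-class annotation and group-monophyly assessment.

#' Build a reference-anchored multiple alignment
#'
#' Each record is globally aligned to the reference domain and its row is
#' the projection of that pairwise alignment onto reference columns:
#' column *j* holds the record residue aligned to reference position *j*
#' (`-` at deletions).  Insertions relative to the reference are discarded,
#' so every row has exactly `nchar(reference)` columns and the reference
#' row (first) is ungapped.  This fixes the column space to reference
#' (E. coli) numbering, consistent with anchor-position semantics.
#'
#' @param records trimmed `protein_records`.
#' @param reference single-row `protein_records`, the trimmed reference
#'   domain (default [pola_reference_domain()]).
#' @param params an [alignment_params()] (global).
#' @return character matrix of class `anchored_msa`: one row per sequence
#'   (reference first), one column per reference position.
#' @export
build_anchored_msa <- function(records, reference = pola_reference_domain(),
                               params = alignment_params()) {
  L <- nchar(reference$residues)
  ref_row <- strsplit(reference$residues, "")[[1]]
  rows <- list()
  rows[[reference$id]] <- ref_row
  for (i in seq_len(nrow(records))) {
    aln <- pairwise_align(reference, records[i, ], params)
    cm <- aln$column_map
    keep <- !is.na(cm$a_pos)
    qchars <- strsplit(records$residues[i], "")[[1]]
    row <- rep("-", L)
    bp <- cm$b_pos[keep]
    row[cm$a_pos[keep][!is.na(bp)]] <- qchars[bp[!is.na(bp)]]
    if (!any(row != "-")) {
      warning("record ", records$id[i],
              " has no aligned columns; excluded from MSA")
      next
    }
    rows[[records$id[i]]] <- row
  }
  msa <- do.call(rbind, rows)
  class(msa) <- c("anchored_msa", class(msa))
  msa
}

#' Pairwise p-distance matrix from an anchored alignment
#'
#' `d(i, j)` is the fraction of mismatched residues over columns where both
#' rows carry a residue.  Pairs sharing fewer than `min_shared_columns`
#' such columns are an error (too little signal for a distance).
#'
#' @param msa an [build_anchored_msa()] matrix.
#' @param min_shared_columns minimum shared non-gap columns (default 100).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(msa, min_shared_columns = 100L) {
  n <- nrow(msa)
  if (n < 3L) stop("need at least 3 sequences for a distance matrix")
  d <- matrix(0, n, n, dimnames = list(rownames(msa), rownames(msa)))
  gap <- msa == "-"
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- !gap[i, ] & !gap[j, ]
      ns <- sum(shared)
      if (ns < min_shared_columns)
        stop("rows ", rownames(msa)[i], " and ", rownames(msa)[j],
             " share only ", ns, " non-gap columns (< ",
             min_shared_columns, ")")
      d[i, j] <- d[j, i] <- sum(msa[i, shared] != msa[j, shared]) / ns
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via \pkg{ape}); NJ is exact on
#' additive distance matrices.  Negative branch lengths are clamped to
#' zero and the total clamped deficit is recorded in the
#' `"clamped_deficit"` attribute.
#'
#' @param d symmetric numeric matrix with zero diagonal and no NaN.
#' @return unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  if (any(is.nan(d)) || any(is.na(d))) stop("NaN/NA in distance matrix")
  if (!isTRUE(all.equal(d, t(d))) || any(abs(diag(d)) > 1e-12))
    stop("distance matrix must be symmetric with zero diagonal")
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  tr <- ape::nj(d)
  deficit <- -sum(tr$edge.length[tr$edge.length < 0])
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped_deficit") <- deficit
  tr
}

#' Root a tree on a leaf's pendant edge
#'
#' Places the root at the midpoint of the pendant edge leading to
#' `leaf_id`.  The unrooted bipartition set is unchanged.
#'
#' @param tree a `phylo` tree.
#' @param leaf_id tip label to root on.
#' @return rooted `phylo` tree.
#' @export
root_on <- function(tree, leaf_id) {
  if (!leaf_id %in% tree$tip.label)
    stop("unknown leaf: ", leaf_id)
  tip <- which(tree$tip.label == leaf_id)
  pend <- which(tree$edge[, 2] == tip)
  plen <- tree$edge.length[pend]
  rt <- ape::root(tree, outgroup = leaf_id, resolve.root = TRUE,
                  edgelabel = TRUE)
  root_node <- ape::Ntip(rt) + 1L
  kids <- which(rt$edge[, 1] == root_node)
  tip_rt <- which(rt$tip.label == leaf_id)
  tip_edge <- kids[rt$edge[kids, 2] == tip_rt]
  other_edge <- setdiff(kids, tip_edge)
  extra <- rt$edge.length[tip_edge] - plen / 2
  rt$edge.length[tip_edge] <- plen / 2
  rt$edge.length[other_edge] <- rt$edge.length[other_edge] + extra
  rt
}

#' Column-bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate, and reports for every internal edge of the input tree
#' the fraction of replicates containing the same bipartition.  Supports
#' are stored as node labels (fractions in `[0, 1]`).
#'
#' @param msa an [build_anchored_msa()] matrix.
#' @param tree the tree to decorate (built from `msa`); if `NULL`, it is
#'   built here.
#' @param n_replicates number of bootstrap replicates (default 100).
#' @param seed integer RNG seed (required).
#' @param min_shared_columns passed to [p_distance_matrix()].
#' @return the tree with per-internal-node `node.label` supports.
#' @export
bootstrap_support <- function(msa, tree = NULL, n_replicates = 100L, seed,
                              min_shared_columns = 100L) {
  if (missing(seed)) stop("seed is required")
  if (n_replicates < 2L) stop("need at least 2 replicates")
  if (is.null(tree))
    tree <- nj_tree(p_distance_matrix(msa, min_shared_columns))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  boots <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cols <- sample.int(ncol(msa), ncol(msa), replace = TRUE)
    boots[[r]] <- nj_tree(p_distance_matrix(msa[, cols, drop = FALSE],
                                            min_shared_columns = 1L))
  }
  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  tree$node.label <- counts / n_replicates
  tree
}

# tip-label set per node (tips and internal nodes) of a phylo tree
node_tip_sets <- function(tree) {
  ntip <- ape::Ntip(tree)
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; child <- po$edge[e, 2]
    sets[[par]] <- c(sets[[par]], sets[[child]])
  }
  sets
}

#' Assess monophyly of 762-class leaf groups
#'
#' For each class, finds the most recent common ancestor (MRCA) of its
#' leaves in the rooted tree and reports the clade size, the number of
#' intruder leaves (clade members not in the group), a verdict
#' (monophyletic iff zero intruders), and the minimal number of complete
#' subclades covering the intruders (the count of maximal all-intruder
#' subtrees inside the MRCA clade).
#'
#' Classes with fewer than two leaves are monophyletic by convention and
#' flagged.
#'
#' @param tree rooted `phylo` tree.
#' @param classes named character vector mapping every leaf to its class.
#' @return data frame, one row per class: `class`, `n_leaves`,
#'   `clade_size`, `n_intruders`, `monophyletic`, `intruder_subclades`,
#'   `flagged`.
#' @export
assess_group_monophyly <- function(tree, classes) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  miss <- setdiff(tree$tip.label, names(classes))
  if (length(miss))
    stop("unmapped leaf/leaves: ", paste(head(miss, 5), collapse = ", "))
  sets <- node_tip_sets(tree)
  out <- lapply(sort(unique(classes[tree$tip.label])), function(cl) {
    grp <- intersect(tree$tip.label, names(classes)[classes == cl])
    if (length(grp) < 2L)
      return(data.frame(class = cl, n_leaves = length(grp),
                        clade_size = length(grp), n_intruders = 0L,
                        monophyletic = TRUE, intruder_subclades = 0L,
                        flagged = TRUE, stringsAsFactors = FALSE))
    mrca <- ape::getMRCA(tree, grp)
    clade <- sets[[mrca]]
    intr <- setdiff(clade, grp)
    # maximal all-intruder subtrees within the MRCA clade
    n_cover <- 0L
    if (length(intr)) {
      all_intr <- vapply(seq_along(sets), function(nd)
        all(sets[[nd]] %in% intr), logical(1))
      # nodes inside the mrca clade: those whose tip set is subset of clade
      inside <- vapply(seq_along(sets), function(nd)
        all(sets[[nd]] %in% clade), logical(1))
      parent <- rep(NA_integer_, length(sets))
      parent[tree$edge[, 2]] <- tree$edge[, 1]
      for (nd in seq_along(sets)) {
        if (!inside[nd] || !all_intr[nd]) next
        p <- parent[nd]
        p_all <- !is.na(p) && inside[p] && all_intr[p]
        if (!p_all) n_cover <- n_cover + 1L
      }
    }
    data.frame(class = cl, n_leaves = length(grp),
               clade_size = length(clade), n_intruders = length(intr),
               monophyletic = length(intr) == 0L,
               intruder_subclades = n_cover, flagged = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write an annotated tree and leaf-annotation table
#'
#' Emits Newick (branch lengths; bootstrap supports, if present, as
#' internal-node labels) plus a TSV mapping each leaf to its 762 class and
#' source, suitable as a generic tree-coloring annotation table.
#'
#' @param tree `phylo` tree.
#' @param signatures signature data frame ([classify_batch()]); must cover
#'   every leaf (the reference may be supplied via `extra`).
#' @param records `protein_records` providing `source` per id.
#' @param newick_path,annotation_path output paths.
#' @param extra optional data frame `id`, `class762`, `source` for leaves
#'   absent from `signatures` (e.g. the reference).
#' @return invisibly, the annotation data frame.
#' @export
annotate_tree <- function(tree, signatures, records, newick_path,
                          annotation_path, extra = NULL) {
  ann <- data.frame(leaf_id = signatures$query_id,
                    class762 = signatures$class762,
                    source = records$source[match(signatures$query_id,
                                                  records$id)],
                    stringsAsFactors = FALSE)
  if (!is.null(extra))
    ann <- rbind(ann, data.frame(leaf_id = extra$id,
                                 class762 = extra$class762,
                                 source = extra$source,
                                 stringsAsFactors = FALSE))
  miss <- setdiff(tree$tip.label, ann$leaf_id)
  if (length(miss))
    stop("unmapped leaf/leaves: ", paste(head(miss, 5), collapse = ", "))
  ann <- ann[match(tree$tip.label, ann$leaf_id), , drop = FALSE]
  rownames(ann) <- NULL
  ape::write.tree(tree, file = newick_path)
  write.table(ann, annotation_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(ann)
}
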