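# Anchored MSA, p-distances, NJ tree, rooting, bootstrap, monophyly.

msa_from_strings <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]]))
  rownames(m) <- names(rows)
  m
}

test_that("anchored MSA projects onto reference columns", {
  refdom <- pola_reference_domain()
  L <- nchar(refdom$residues)

  recs <- protein_records(c("same1", "same2"),
                          rep(refdom$residues, 2))
  msa <- build_anchored_msa(recs, refdom)
  expect_equal(ncol(msa), L)
  expect_equal(nrow(msa), 3L)  # reference first
  expect_true(all(msa != "-"))
  expect_true(all(msa[2, ] == msa[1, ]))

  # a 10-residue insertion is discarded: row length unchanged, content
  # identical to the reference row
  set.seed(12)
  ins <- paste0(substr(refdom$residues, 1, 300), rand_aa(10),
                substr(refdom$residues, 301, L))
  recs2 <- protein_records("withins", ins)
  msa2 <- build_anchored_msa(recs2, refdom)
  expect_equal(ncol(msa2), L)
  expect_equal(paste(msa2["withins", ], collapse = ""), refdom$residues)
})

test_that("p-distances match the column-count oracle", {
  m <- msa_from_strings(a = "AAAAA", b = "AAAAA")
  m <- rbind(m, c = strsplit("AAAAT", "")[[1]])
  d <- p_distance_matrix(m, min_shared_columns = 5)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 0.2)

  # 5 mismatches over 100 shared columns -> 0.05
  set.seed(13)
  r1 <- strsplit(rand_aa(100), "")[[1]]
  r2 <- r1
  flip <- sample(100, 5)
  for (p in flip) r2[p] <- sample(setdiff(AA20_TEST, r2[p]), 1)
  m2 <- rbind(x = r1, y = r2, z = r1)
  expect_equal(p_distance_matrix(m2)["x", "y"], 0.05)

  # random rows vs naive oracle
  m3 <- do.call(rbind, lapply(1:5, function(i) {
    ch <- strsplit(rand_aa(120), "")[[1]]
    ch[sample(120, 10)] <- "-"
    ch
  }))
  rownames(m3) <- paste0("r", 1:5)
  d3 <- p_distance_matrix(m3, min_shared_columns = 10)
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(d3[i, j], oracle_p_dist(m3[i, ], m3[j, ]))
  expect_true(isSymmetric(d3))
  expect_true(all(diag(d3) == 0))

  # insufficient shared columns is an error
  m4 <- msa_from_strings(a = "AA---", b = "---AA", c = "AAAAA")
  expect_error(p_distance_matrix(m4, min_shared_columns = 2), "share")
})

test_that("NJ recovers additive trees exactly", {
  # fixed 4-taxon tree with known branch lengths
  t4 <- ape::read.tree(text = "((a:2,b:3):1,c:4,d:5);")
  d4 <- ape::cophenetic.phylo(t4)
  nj4 <- nj_tree(d4)
  expect_equal(ape::dist.topo(ape::unroot(t4), ape::unroot(nj4)), 0,
               ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(nj4)[rownames(d4), colnames(d4)], d4,
               tolerance = 1e-10)

  # 3 taxa: closed-form three-point branch lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  nj3 <- nj_tree(d3)
  # pendant lengths: a = (3+4-5)/2 = 1, b = (3+5-4)/2 = 2, c = (4+5-3)/2 = 3
  el <- setNames(nj3$edge.length, nj3$tip.label[nj3$edge[, 2]])
  expect_equal(el[["a"]], 1)
  expect_equal(el[["b"]], 2)
  expect_equal(el[["c"]], 3)

  # property: random additive matrices from 4-8 taxon trees round-trip
  set.seed(14)
  for (n in 4:8) {
    tr <- ape::rtree(n, br = function(k) runif(k, 0.5, 2))
    d <- ape::cophenetic.phylo(tr)
    nj <- nj_tree(d)
    expect_equal(ape::cophenetic.phylo(nj)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
  }

  dn <- matrix(c(0, NaN, NaN, 0), 2, 2)
  expect_error(nj_tree(dn), "NaN")
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2,
                              dimnames = list(c("a", "b"), c("a", "b")))),
               "symmetric")
})

test_that("rooting on a leaf preserves the bipartition set", {
  set.seed(15)
  for (k in 1:5) {
    tr <- ape::rtree(7)
    tr$tip.label <- paste0("t", 1:7)
    rt <- root_on(tr, "t3")
    expect_true(ape::is.rooted(rt))
    expect_equal(ape::dist.topo(ape::unroot(rt), ape::unroot(tr)), 0,
                 ignore_attr = TRUE)
    # total tree length unchanged (pendant edge split at its midpoint)
    expect_equal(sum(rt$edge.length), sum(tr$edge.length))
  }
  t4 <- ape::read.tree(text = "((a:1,b:1):1,(c:1,out:1):1);")
  rt <- root_on(ape::unroot(t4), "out")
  sets <- lapply(ape::prop.part(rt), function(i) rt$tip.label[i])
  expect_true(any(vapply(sets, function(s)
    setequal(s, c("a", "b", "c")), logical(1))))
  expect_error(root_on(t4, "nope"), "unknown leaf")
})

test_that("bootstrap supports are deterministic and detect forced splits", {
  set.seed(16)
  # duplicate row forces a cherry with support 1
  base <- strsplit(rand_aa(150), "")[[1]]
  rows <- do.call(rbind, lapply(1:4, function(i) {
    ch <- base
    ch[sample(150, 40)] <- vapply(1:40, function(k)
      sample(AA20_TEST, 1), character(1))
    ch
  }))
  m <- rbind(rows, rows[4, ])  # taxon e duplicates taxon d
  rownames(m) <- c("a", "b", "c", "d", "e")
  tr <- nj_tree(p_distance_matrix(m, min_shared_columns = 10))
  bs <- bootstrap_support(m, tr, n_replicates = 50, seed = 9,
                          min_shared_columns = 10)
  # the d-e cherry bipartition must appear in every replicate
  cherry <- which(vapply(ape::prop.part(bs), function(i)
    setequal(bs$tip.label[i], c("d", "e")) ||
      setequal(bs$tip.label[i], c("a", "b", "c")), logical(1)))
  expect_true(length(cherry) >= 1)
  expect_true(any(bs$node.label[cherry] == 1))

  bs2 <- bootstrap_support(m, tr, n_replicates = 50, seed = 9,
                           min_shared_columns = 10)
  expect_identical(bs$node.label, bs2$node.label)
  expect_error(bootstrap_support(m, tr, n_replicates = 1, seed = 1), "2")
})

test_that("monophyly verdicts match hand-enumerated trees", {
  t1 <- ape::read.tree(text = "((a_F:1,b_F:1):1,(c_L:1,d_L:1):1);")
  cls <- c(a_F = "F", b_F = "F", c_L = "L", d_L = "L")
  rep1 <- assess_group_monophyly(t1, cls)
  expect_true(all(rep1$monophyletic))
  expect_equal(rep1$n_intruders, c(0L, 0L))

  t2 <- ape::read.tree(text = "(((a_F:1,b_L:1):1,c_F:1):1,d_L:1);")
  cls2 <- c(a_F = "F", b_L = "L", c_F = "F", d_L = "L")
  rep2 <- assess_group_monophyly(t2, cls2)
  f <- rep2[rep2$class == "F", ]
  expect_false(f$monophyletic)
  expect_equal(f$n_intruders, 1L)
  expect_equal(f$intruder_subclades, 1L)

  # class with < 2 leaves: monophyletic by convention, flagged
  t3 <- ape::read.tree(text = "((a_F:1,b_F:1):1,c_Y:1);")
  rep3 <- assess_group_monophyly(t3, c(a_F = "F", b_F = "F", c_Y = "Y"))
  y <- rep3[rep3$class == "Y", ]
  expect_true(y$monophyletic)
  expect_true(y$flagged)

  expect_error(assess_group_monophyly(t1, cls[1:3]), "unmapped")
})

test_that("monophyly checker agrees with exhaustive clade enumeration", {
  set.seed(17)
  for (k in 1:12) {
    n <- sample(5:10, 1)
    tr <- ape::rtree(n)
    tr$tip.label <- paste0("t", 1:n)
    classes <- setNames(sample(c("F", "L", "Y"), n, replace = TRUE),
                        tr$tip.label)
    rep <- assess_group_monophyly(tr, classes)
    for (cl in unique(classes)) {
      if (sum(classes == cl) < 2) next
      want <- oracle_monophyly(tr, classes, cl)
      row <- rep[rep$class == cl, ]
      expect_equal(row$monophyletic, want$monophyletic,
                   info = paste("tree", k, "class", cl))
      expect_equal(row$n_intruders, want$n_intruders,
                   info = paste("tree", k, "class", cl))
      expect_equal(row$clade_size, want$clade_size,
                   info = paste("tree", k, "class", cl))
      expect_equal(row$intruder_subclades, want$intruder_subclades,
                   info = paste("tree", k, "class", cl))
    }
  }
})

test_that("annotated trees round-trip through Newick with matching TSV", {
  fam <- small_family(seed = 21)
  cb <- classify_batch(fam$records)
  refdom <- pola_reference_domain()
  msa <- build_anchored_msa(cb$retained, refdom)
  tr <- root_on(nj_tree(p_distance_matrix(msa)), refdom$id)
  nwk <- withr::local_tempfile(fileext = ".nwk")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  ann <- annotate_tree(tr, cb$signatures, fam$records, nwk, tsv,
                       extra = data.frame(id = refdom$id, class762 = "ref",
                                          source = "synthetic"))
  back <- ape::read.tree(nwk)
  expect_setequal(back$tip.label, tr$tip.label)
  tab <- read.delim(tsv, stringsAsFactors = FALSE)
  tab <- tab[tab$leaf_id != refdom$id, ]
  truth_cls <- fam$truth$class762[match(tab$leaf_id, fam$truth$id)]
  expect_equal(tab$class762, truth_cls)

  expect_error(annotate_tree(tr, cb$signatures, fam$records, nwk, tsv),
               "unmapped")
})
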