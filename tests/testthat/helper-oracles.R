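# Independent oracles and fixture builders used across the suite.

AA20_TEST <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
               "M", "F", "P", "S", "T", "W", "Y", "V")

rand_aa <- function(n) paste(sample(AA20_TEST, n, replace = TRUE),
                             collapse = "")

blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  get("BLOSUM62", envir = env)
}

# Exhaustive-recursion global alignment score oracle (memoized on
# suffix-pair + previous-move state).  Gap run of length k scores
# open + (k - 1) * ext.  Independent of the package's DP implementation.
oracle_global_score <- function(a, b, mat = blosum62(), open = -11,
                                ext = -1) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  memo <- new.env(hash = TRUE)
  rec <- function(i, j, s) {
    if (i > n && j > m) return(0)
    key <- paste(i, j, s)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- -Inf
    if (i <= n && j <= m)
      best <- max(best, mat[ca[i], cb[j]] + rec(i + 1L, j + 1L, 0L))
    if (i <= n)
      best <- max(best, (if (s == 1L) ext else open) + rec(i + 1L, j, 1L))
    if (j <= m)
      best <- max(best, (if (s == 2L) ext else open) + rec(i, j + 1L, 2L))
    memo[[key]] <- best
    best
  }
  rec(1L, 1L, 0L)
}

# Local score oracle: best global score over all substring pairs, floored
# at zero.  Exponential in sequence length; use only on short strings.
oracle_local_score <- function(a, b, mat = blosum62(), open = -11,
                               ext = -1) {
  na <- nchar(a); nb <- nchar(b)
  best <- 0
  for (i in seq_len(na)) for (ii in i:na)
    for (j in seq_len(nb)) for (jj in j:nb)
      best <- max(best, oracle_global_score(substr(a, i, ii),
                                            substr(b, j, jj), mat, open,
                                            ext))
  best
}

# Brute-force greedy clustering oracle: same ordering rule, but testing
# every sequence against every existing representative explicitly.
oracle_greedy_cluster <- function(records, min_id = 0.75, min_cov = 0.8) {
  params <- alignment_params(mode = "local")
  ord <- order(-nchar(records$residues), records$id)
  records <- records[ord, , drop = FALSE]
  reps <- character(0)
  assign <- setNames(character(nrow(records)), records$id)
  for (i in seq_len(nrow(records))) {
    hit <- NA_character_
    for (r in reps) {
      aln <- pairwise_align(records[records$id == r, ], records[i, ], params)
      if (aln$identity >= min_id && aln$coverage_a >= min_cov &&
          aln$coverage_b >= min_cov) { hit <- r; break }
    }
    if (is.na(hit)) { reps <- c(reps, records$id[i]); hit <- records$id[i] }
    assign[records$id[i]] <- hit
  }
  assign
}

# Monophyly oracle by exhaustive clade enumeration (ape::prop.part gives
# every internal node's tip set; singletons added explicitly).
oracle_monophyly <- function(tree, classes, cl) {
  grp <- intersect(tree$tip.label, names(classes)[classes == cl])
  pp <- ape::prop.part(tree)
  clades <- lapply(pp, function(idx) tree$tip.label[idx])
  clades <- c(clades, as.list(tree$tip.label))
  is_mono <- any(vapply(clades, function(x) setequal(x, grp), logical(1)))
  # smallest clade containing the whole group
  containing <- clades[vapply(clades, function(x) all(grp %in% x),
                              logical(1))]
  sizes <- vapply(containing, length, 1L)
  mrca_clade <- containing[[which.min(sizes)]]
  intr <- setdiff(mrca_clade, grp)
  # maximal all-intruder clades inside the mrca clade
  inside <- clades[vapply(clades, function(x)
    all(x %in% mrca_clade) && length(x) && all(x %in% intr), logical(1))]
  n_cover <- 0L
  for (k in seq_along(inside)) {
    maximal <- !any(vapply(seq_along(inside), function(j)
      j != k && all(inside[[k]] %in% inside[[j]]) &&
        length(inside[[j]]) > length(inside[[k]]), logical(1)))
    if (maximal) n_cover <- n_cover + 1L
  }
  list(monophyletic = is_mono, n_intruders = length(intr),
       clade_size = length(mrca_clade), intruder_subclades = n_cover)
}

# p-distance oracle: naive column-by-column count
oracle_p_dist <- function(r1, r2) {
  shared <- r1 != "-" & r2 != "-"
  sum(r1[shared] != r2[shared]) / sum(shared)
}

# small planted family used by several files
small_family <- function(seed = 303, ...) {
  generate_family(family_spec(seed = seed,
                              clade_class762 = c("F", "L", "Y"),
                              seqs_per_clade = c(5L, 4L, 3L), ...))
}
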