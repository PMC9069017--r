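# Length/domain filters, domain trimming, greedy clustering, subsampling.

test_that("length filter uses an inclusive 400-residue boundary", {
  set.seed(3)
  recs <- protein_records(c("at", "under"),
                          c(rand_aa(400), rand_aa(399)))
  fl <- filter_length(recs)
  expect_equal(fl$retained$id, "at")
  expect_equal(fl$rejected$id, "under")

  lens <- c(rep(350, 5), rep(450, 7))
  planted <- protein_records(sprintf("p%02d", seq_along(lens)),
                             vapply(lens, rand_aa, character(1)))
  fl <- filter_length(planted)
  expect_equal(nrow(fl$retained), 7L)
  # idempotence: filtering retained output changes nothing
  expect_equal(filter_length(fl$retained)$retained, fl$retained)
})

test_that("domain filter applies inclusive e-value and span thresholds", {
  set.seed(4)
  recs <- protein_records(c("a", "b", "c"),
                          vapply(c(500, 500, 500), rand_aa, character(1)))
  hits <- domain_hits(c("a", "b", "c", "c"),
                      rep("cl02626", 4),
                      c(1e-10, 1e-9, 1e-50, 1e-50),
                      c(1, 1, 1, 50),
                      c(325, 400, 200, 379))
  fd <- filter_domain(recs, hits)
  # a: e-value exactly at threshold, span exactly 325 -> retained
  # b: fails e-value; c: retained via its 330-residue second hit
  expect_setequal(fd$retained$id, c("a", "c"))
  expect_equal(fd$rejected$id, "b")

  bad <- domain_hits("zzz", "cl02626", 1e-50, 1, 400)
  expect_error(filter_domain(recs, bad), "unknown record id")

  # wrong model never qualifies
  wrong <- domain_hits("a", "pfam999", 1e-50, 1, 400)
  expect_equal(nrow(filter_domain(recs, wrong)$retained), 0L)
})

test_that("trimming selects the longest hit, ties to the smaller start", {
  set.seed(5)
  rec <- protein_records("q", rand_aa(600))
  hits <- domain_hits(c("q", "q"), "cl02626", c(1e-50, 1e-50),
                      c(10, 5), c(340, 500))
  tr <- trim_to_domain(rec, hits)
  expect_equal(nchar(tr$residues), 496L)
  expect_equal(tr$residues, substr(rec$residues, 5, 500))

  tie <- domain_hits(c("q", "q"), "cl02626", c(1e-50, 1e-50),
                     c(20, 10), c(344, 334))  # both length 325
  tr <- trim_to_domain(rec, tie)
  expect_equal(attr(tr, "trim_regions")$start, 10L)

  whole <- domain_hits("q", "cl02626", 1e-50, 1, 600)
  expect_equal(trim_to_domain(rec, whole)$residues, rec$residues)

  none <- domain_hits("q", "cl02626", 1e-5, 1, 600)
  expect_error(trim_to_domain(rec, none), "no qualifying")
})

test_that("greedy clustering handles degenerate inputs", {
  set.seed(6)
  s <- rand_aa(200)
  copies <- protein_records(paste0("c", 1:4), rep(s, 4))
  cl <- greedy_cluster(copies)
  expect_equal(length(unique(cl$representative_id)), 1L)
  expect_setequal(cl$member_id, copies$id)

  two <- protein_records(c("u1", "u2"), c(rand_aa(180), rand_aa(190)))
  cl2 <- greedy_cluster(two)
  expect_equal(length(unique(cl2$representative_id)), 2L)
})

test_that("greedy clustering matches the brute-force oracle near the
           identity threshold", {
  set.seed(8)
  base <- rand_aa(150)
  mutate_frac <- function(s, f) {
    ch <- strsplit(s, "")[[1]]
    k <- round(f * length(ch))
    pos <- sample(length(ch), k)
    for (p in pos) ch[p] <- sample(setdiff(AA20_TEST, ch[p]), 1)
    paste(ch, collapse = "")
  }
  # pairwise divergences straddling the 75% identity threshold
  fracs <- c(0, 0.05, 0.15, 0.22, 0.28, 0.35, 0.45, 0.6, 0.8, 0)
  seqs <- vapply(fracs, function(f) mutate_frac(base, f), character(1))
  recs <- protein_records(sprintf("m%02d", 1:10), seqs)
  got <- greedy_cluster(recs)
  want <- oracle_greedy_cluster(recs)
  expect_equal(setNames(got$representative_id, got$member_id)[names(want)],
               want)
  # partition is exhaustive and disjoint
  expect_setequal(got$member_id, recs$id)
  expect_equal(anyDuplicated(got$member_id), 0L)
  # every member satisfies the threshold against its representative
  lp <- alignment_params(mode = "local")
  for (i in seq_len(nrow(got))) {
    aln <- pairwise_align(recs[recs$id == got$representative_id[i], ],
                          recs[recs$id == got$member_id[i], ], lp)
    expect_true(aln$identity >= 0.75 && aln$coverage_a >= 0.8 &&
                  aln$coverage_b >= 0.8)
  }
  # permuting input order leaves the partition unchanged
  perm <- recs[sample(nrow(recs)), ]
  got2 <- greedy_cluster(perm)
  expect_equal(got[order(got$member_id), c("representative_id", "member_id")],
               got2[order(got2$member_id),
                    c("representative_id", "member_id")],
               ignore_attr = TRUE)
})

test_that("stratified subsampling is seeded, capped and exact", {
  reps <- data.frame(
    id = sprintf("r%04d", 1:3050),
    source = "gov",
    class762 = c(rep("F", 1000), rep("L", 1000), rep("Y", 1000),
                 rep("F", 50))[c(1:3000, 3001:3050)],
    stringsAsFactors = FALSE)
  # 3 strata of >= 225 -> 225 each
  reps3 <- reps[1:3000, ]
  sub <- stratified_subsample(reps3, n = 225, seed = 42)
  expect_equal(nrow(sub), 675L)
  expect_equal(as.vector(table(sub$class762)), c(225L, 225L, 225L))

  # same seed identical; different seed differs
  sub_b <- stratified_subsample(reps3, n = 225, seed = 42)
  expect_identical(sub$id, sub_b$id)
  sub_c <- stratified_subsample(reps3, n = 225, seed = 43)
  expect_false(identical(sub$id, sub_c$id))

  # min rule: stratum smaller than n retained wholly
  small <- data.frame(id = paste0("s", 1:50), source = "serc",
                      class762 = "Y", stringsAsFactors = FALSE)
  expect_equal(nrow(stratified_subsample(small, n = 225, seed = 1)), 50L)

  # |sample| = sum over strata of min(n, size)
  mixed <- rbind(reps3, small)
  expect_equal(nrow(stratified_subsample(mixed, n = 225, seed = 1)),
               675L + 50L)

  expect_error(stratified_subsample(small, n = 0, seed = 1), "positive")
  expect_error(stratified_subsample(small, n = 10), "seed")
})
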