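# Synthetic sequence families, hit tables and contig annotations with
# planted truth, so every pipeline stage is testable without downloads.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

#' Specification of a planted PolA family
#'
#' Defaults emulate the study conditions: five clades (two Phe, two Leu,
#' one Tyr, mirroring the Phe I/II, Leu I/II and Tyr groupings) with sizes
#' 13+13, 7+7 and 9 so the planted 762-class counts are F:26, L:14, Y:9
#' (the synthesis panel); modest within-clade divergence against deep
#' between-clade divergence; intact anchors; rare short indels.
#'
#' @param seed integer RNG seed (required).
#' @param clade_class762 character vector, one class (`F`/`L`/`Y`) per
#'   clade.
#' @param seqs_per_clade integer vector parallel to `clade_class762`.
#' @param within_divergence expected substitutions/site within a clade.
#' @param between_divergence expected substitutions/site from the
#'   reference domain to each clade ancestor.
#' @param anchor_mutation_prob probability that an anchor residue is
#'   randomized in a given sequence (default 0: anchors protected).
#' @param indel_rate per-site indel probability (default 0.005).
#' @param indel_mean_len mean indel length (geometric; default 3).
#' @param decoys named integer vector of decoy counts per failure mode:
#'   `short` (fails the length filter), `no_domain` (fails the domain
#'   filter), `bad_anchor` and `random` (fail the signature screen).
#' @return list of class `family_spec`.
#' @export
family_spec <- function(seed,
                        clade_class762 = c("F", "F", "L", "L", "Y"),
                        seqs_per_clade = c(13L, 13L, 7L, 7L, 9L),
                        within_divergence = 0.02,
                        between_divergence = 0.35,
                        anchor_mutation_prob = 0,
                        indel_rate = 0.005,
                        indel_mean_len = 3,
                        decoys = c(short = 0L, no_domain = 0L,
                                   bad_anchor = 0L, random = 0L)) {
  if (missing(seed)) stop("seed is required")
  if (length(clade_class762) < 1L) stop("need at least one clade")
  if (length(seqs_per_clade) != length(clade_class762))
    stop("seqs_per_clade must be parallel to clade_class762")
  if (any(seqs_per_clade < 1L)) stop("empty clade")
  if (!all(clade_class762 %in% c("F", "L", "Y")))
    stop("clade classes must be F, L or Y")
  if (within_divergence < 0 || within_divergence >= 1 ||
      between_divergence < 0 || between_divergence >= 1)
    stop("divergences must lie in [0, 1)")
  if (anchor_mutation_prob < 0 || anchor_mutation_prob > 1)
    stop("anchor_mutation_prob must lie in [0, 1]")
  full <- c(short = 0L, no_domain = 0L, bad_anchor = 0L, random = 0L)
  full[names(decoys)] <- as.integer(decoys)
  structure(list(seed = as.integer(seed), clade_class762 = clade_class762,
                 seqs_per_clade = as.integer(seqs_per_clade),
                 within_divergence = within_divergence,
                 between_divergence = between_divergence,
                 anchor_mutation_prob = anchor_mutation_prob,
                 indel_rate = indel_rate, indel_mean_len = indel_mean_len,
                 decoys = full),
            class = "family_spec")
}

# substitute positions of a residue vector at per-site rate, uniformly over
# the 19 alternatives, never touching `protect` positions
mutate_sites <- function(chars, rate, protect = integer(0)) {
  hit <- which(runif(length(chars)) < rate)
  hit <- setdiff(hit, protect)
  for (p in hit) {
    alt <- setdiff(AA20, chars[p])
    chars[p] <- alt[sample.int(length(alt), 1L)]
  }
  chars
}

# apply random indels, avoiding a +/- margin around protected positions
apply_indels <- function(chars, rate, mean_len, protect, margin = 5L) {
  n_events <- rpois(1, rate * length(chars))
  if (n_events == 0L) return(chars)
  forbidden <- unique(unlist(lapply(protect, function(p)
    seq(max(1L, p - margin), min(length(chars), p + margin)))))
  for (k in seq_len(n_events)) {
    len <- 1L + rpois(1, mean_len - 1)
    pos <- sample.int(length(chars), 1L)
    span <- seq(pos, min(length(chars), pos + len - 1L))
    # protected positions shift under indels; recompute a conservative mask
    if (any(span %in% forbidden)) next
    if (runif(1) < 0.5) {
      chars <- chars[-span]  # deletion
      forbidden <- forbidden - ifelse(forbidden > pos, length(span), 0L)
    } else {
      ins <- AA20[sample.int(20L, len, replace = TRUE)]
      chars <- append(chars, ins, after = pos)
      forbidden <- forbidden + ifelse(forbidden > pos, len, 0L)
    }
  }
  chars
}

#' Generate a planted PolA family with hit table and truth table
#'
#' Evolves the reference Klenow-like domain along a star-of-clades tree:
#' each clade ancestor diverges from the reference at the between-clade
#' rate, each member from its ancestor at the within-clade rate
#' (substitutions uniform over the 19 alternative residues; anchors
#' protected unless `anchor_mutation_prob` fires), the 762 residue is set
#' to the clade's planted class, and short indels are applied away from
#' anchor columns.  Matching domain-hit rows (full-span, e-value 1e-50)
#' are emitted for every record intended to survive; decoys violate
#' exactly their designated filter (short length, failing e-value, one
#' broken catalytic anchor, or an unrelated random sequence).
#'
#' @param spec a [family_spec()].
#' @param reference single-row `protein_records` containing all anchor
#'   positions (default [pola_reference()]).
#' @return list: `records` (`protein_records`), `hits` (domain-hit table),
#'   `truth` (per-sequence data frame: `id`, `clade`, `class762`,
#'   `anchors_intact`, `kind`, `intended_stage`).
#' @export
generate_family <- function(spec, reference = pola_reference()) {
  stopifnot(inherits(spec, "family_spec"))
  b <- pola_reference_domain_bounds()
  anchors_full <- c(688L, 705L, 758L, 762L)
  if (max(anchors_full) > nchar(reference$residues))
    stop("reference lacks anchor positions")
  dom <- strsplit(substr(reference$residues, b["start"], b["end"]), "")[[1]]
  anchors <- anchors_full - b["start"] + 1L  # domain coordinates
  pos762 <- anchors[4]

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  ids <- character(0); seqs <- character(0)
  truth <- list()
  evolve_member <- function(ancestor, class762, mutate_anchor = FALSE) {
    ch <- mutate_sites(ancestor, spec$within_divergence, protect = anchors)
    anchors_intact <- TRUE
    if (mutate_anchor) {
      a <- anchors[sample.int(3L, 1L)]  # break a catalytic anchor
      ch[a] <- setdiff(AA20, ch[a])[sample.int(19L, 1L)]
      anchors_intact <- FALSE
    } else if (spec$anchor_mutation_prob > 0) {
      for (a in anchors) {
        if (runif(1) < spec$anchor_mutation_prob) {
          ch[a] <- setdiff(AA20, ch[a])[sample.int(19L, 1L)]
          anchors_intact <- FALSE
        }
      }
    }
    ch <- apply_indels(ch, spec$indel_rate, spec$indel_mean_len, anchors)
    list(chars = ch, anchors_intact = anchors_intact)
  }

  # hierarchical guide tree: reference -> class ancestor (between-clade
  # divergence) -> clade ancestor (one third of it, within the class) ->
  # member (within-clade divergence).  Same-class clades are therefore
  # nested, so every 762 class is monophyletic in the planted truth.
  class_anc <- list()
  for (cls in unique(spec$clade_class762)) {
    a <- mutate_sites(dom, spec$between_divergence, protect = anchors)
    a[pos762] <- cls
    class_anc[[cls]] <- a
  }
  for (cl in seq_along(spec$clade_class762)) {
    cls <- spec$clade_class762[cl]
    anc <- mutate_sites(class_anc[[cls]], spec$between_divergence / 3,
                        protect = c(anchors, pos762))
    for (s in seq_len(spec$seqs_per_clade[cl])) {
      mem <- evolve_member(anc, cls)
      id <- sprintf("clade%02d_%s_s%03d", cl, cls, s)
      ids <- c(ids, id)
      seqs <- c(seqs, paste(mem$chars, collapse = ""))
      truth[[id]] <- data.frame(id = id, clade = cl, class762 = cls,
                                anchors_intact = mem$anchors_intact,
                                kind = "member",
                                intended_stage = if (mem$anchors_intact)
                                  "retained" else "classify",
                                stringsAsFactors = FALSE)
    }
  }

  add_decoy <- function(id, chars, clade, cls, intact, kind, stage) {
    ids <<- c(ids, id)
    seqs <<- c(seqs, paste(chars, collapse = ""))
    truth[[id]] <<- data.frame(id = id, clade = clade, class762 = cls,
                               anchors_intact = intact, kind = kind,
                               intended_stage = stage,
                               stringsAsFactors = FALSE)
  }
  dk <- spec$decoys
  for (k in seq_len(dk["short"])) {
    # anchors intact but fragment < 400 aa: passes the signature screen,
    # fails the length filter (anchors sit at domain coords 365..439)
    mem <- evolve_member(mutate_sites(dom, spec$between_divergence,
                                      protect = anchors), "F")
    frag <- mem$chars[100:479]
    add_decoy(sprintf("decoy_short_%02d", k), frag, NA_integer_, "F",
              TRUE, "short", "length")
  }
  for (k in seq_len(dk["no_domain"])) {
    mem <- evolve_member(mutate_sites(dom, spec$between_divergence,
                                      protect = anchors), "F")
    add_decoy(sprintf("decoy_nodomain_%02d", k), mem$chars, NA_integer_,
              "F", TRUE, "no_domain", "domain")
  }
  for (k in seq_len(dk["bad_anchor"])) {
    mem <- evolve_member(mutate_sites(dom, spec$between_divergence,
                                      protect = anchors), "F",
                         mutate_anchor = TRUE)
    add_decoy(sprintf("decoy_badanchor_%02d", k), mem$chars, NA_integer_,
              "F", FALSE, "bad_anchor", "classify")
  }
  for (k in seq_len(dk["random"])) {
    ch <- AA20[sample.int(20L, length(dom), replace = TRUE)]
    add_decoy(sprintf("decoy_random_%02d", k), ch, NA_integer_,
              NA_character_, FALSE, "random", "classify")
  }

  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  records <- protein_records(ids, seqs, source = "synthetic",
                             description = paste0("synthetic ", truth$kind))
  # hit table: full-span passing hits, except no_domain decoys (1e-5)
  ev <- ifelse(truth$kind == "no_domain", 1e-5, 1e-50)
  hits <- domain_hits(records$id, "cl02626", ev, 1L,
                      nchar(records$residues))
  list(records = records, hits = hits, truth = truth)
}

#' Default 762-class x helicase association probabilities
#'
#' Row probabilities follow the observed association frequencies of the
#' mined loci: Tyr loci are dominated by the ring-shaped gp4 helicase
#' (7/9), Leu loci by SNF2-like helicases (9/14, plus one RecB/D), and
#' Phe loci split between SNF2 (9/25) and DnaB (7/25) with the remainder
#' lacking a recognizable helicase.
#'
#' @return row-stochastic matrix, rows `F`, `L`, `Y`; columns the helicase
#'   classes plus `none`.
#' @export
default_association_matrix <- function() {
  cols <- c(HELICASE_CLASSES, "none")
  P <- matrix(0, 3, length(cols), dimnames = list(c("F", "L", "Y"), cols))
  P["Y", c("gp4", "none")] <- c(7, 2) / 9
  P["L", c("SNF2", "RecBD", "none")] <- c(9, 1, 4) / 14
  P["F", c("SNF2", "DnaB", "none")] <- c(9, 7, 9) / 25
  P
}

HELICASE_PRODUCTS <- c(gp4 = "ring-shaped gp4 helicase",
                       DnaB = "DnaB-like replicative helicase",
                       SNF2 = "SNF2-like helicase",
                       UvrD = "UvrD helicase",
                       RecBD = "RecB/D type helicase")

#' Generate contig annotations with planted helicase associations
#'
#' Builds one contig per polA locus: eleven ORFs, the polA placed
#' centrally, a helicase ORF drawn from the association matrix placed at a
#' random ORF offset of 1 to 5 (either side), and filler ORFs labeled
#' "hypothetical protein".
#'
#' @param locus_counts named integer vector of locus counts per 762 class
#'   (names among `F`, `L`, `Y`).
#' @param P row-stochastic association matrix (rows = 762 classes present
#'   in `locus_counts`; columns = helicase classes plus `none`); default
#'   [default_association_matrix()].
#' @param seed integer RNG seed (required).
#' @param helicase_assignments optional character vector (recycled per
#'   class in order) that overrides random drawing, for deterministic
#'   fixtures.
#' @return list: `contigs` (annotation data frame), `loci` (data frame
#'   `contig_id`, `pola_orf_id`, `class762`), `truth` (planted helicase
#'   class and offset per contig).
#' @export
generate_contigs <- function(locus_counts, P = default_association_matrix(),
                             seed, helicase_assignments = NULL) {
  if (missing(seed)) stop("seed is required")
  cols <- c(HELICASE_CLASSES, "none")
  if (!all(names(locus_counts) %in% c("F", "L", "Y")))
    stop("locus_counts names must be among F, L, Y")
  if (!identical(colnames(P), cols) ||
      any(P < 0) || any(abs(rowSums(P) - 1) > 1e-9))
    stop("P must be row-stochastic over ", paste(cols, collapse = ", "))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n_orf <- 11L; pola_pos <- 6L
  contigs <- list(); loci <- list(); truth <- list()
  idx <- 0L
  for (cls in names(locus_counts)) {
    n <- locus_counts[[cls]]
    draws <- if (is.null(helicase_assignments))
      sample(cols, n, replace = TRUE, prob = P[cls, ])
    else rep_len(helicase_assignments, n)
    for (k in seq_len(n)) {
      idx <- idx + 1L
      cid <- sprintf("contig_%s_%03d", cls, k)
      products <- rep("hypothetical protein", n_orf)
      products[pola_pos] <- "DNA polymerase I"
      hcls <- draws[k]; offset <- NA_integer_
      if (hcls != "none") {
        offset <- sample(c(-5:-1, 1:5), 1L)
        products[pola_pos + offset] <- HELICASE_PRODUCTS[[hcls]]
      }
      starts <- (seq_len(n_orf) - 1L) * 1050L + 1L
      contigs[[idx]] <- contig_annotations(
        cid, sprintf("%s_orf%02d", cid, seq_len(n_orf)),
        starts, starts + 999L,
        sample(c("+", "-"), n_orf, replace = TRUE), products)
      loci[[idx]] <- data.frame(contig_id = cid,
                                pola_orf_id = sprintf("%s_orf%02d", cid,
                                                      pola_pos),
                                class762 = cls, stringsAsFactors = FALSE)
      truth[[idx]] <- data.frame(contig_id = cid, class762 = cls,
                                 helicase = hcls, offset = offset,
                                 stringsAsFactors = FALSE)
    }
  }
  list(contigs = do.call(rbind, contigs), loci = do.call(rbind, loci),
       truth = do.call(rbind, truth))
}
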