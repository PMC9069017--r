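# Reference-anchored active-site validation and 762-position classification.
#
# Candidates are validated the way PASV-style screens work: each query is
# aligned to the E. coli PolA reference, the residues aligned to the
# E. coli-numbered anchor positions are read off, and the query passes only
# if every catalytic anchor is intact (R688, D705, K758) and the 762
# position carries F, L or Y.

#' Packaged PolA reference sequence
#'
#' A 928-residue synthetic stand-in for the E. coli K-12 DNA polymerase I
#' reference (UniProt P00582 in the literature; the genuine sequence is not
#' redistributed here).  The stand-in carries the canonical anchor residues
#' at the E. coli-numbered positions — R688, D705, K758 and the wild-type
#' Phe at 762 — and its Klenow-like polymerase domain is defined as residues
#' 324 to 928 (the 5'->3' exonuclease domain occupies the first 323
#' residues in E. coli PolA).
#'
#' @return single-row `protein_records`.
#' @export
pola_reference <- function() {
  path <- system.file("extdata", "pola_ref_synthetic.faa",
                      package = "polascreen")
  read_fasta(path, source = "synthetic")
}

#' Domain boundaries of the packaged reference
#' @return named integer vector with `start` and `end` (1-based inclusive).
#' @export
pola_reference_domain_bounds <- function() c(start = 324L, end = 928L)

#' The Klenow-like domain of the packaged reference
#' @return single-row `protein_records` covering reference residues 324-928.
#' @export
pola_reference_domain <- function() {
  ref <- pola_reference()
  b <- pola_reference_domain_bounds()
  protein_records(paste0(ref$id, "_domain"),
                  substr(ref$residues, b["start"], b["end"]),
                  source = "synthetic",
                  description = "Klenow-like polymerase domain (ref 324-928)")
}

#' Residue signature scheme for PolA validation
#'
#' @param reference single-row `protein_records` used as numbering anchor.
#' @param anchor_positions strictly increasing 1-based reference positions.
#' @param required named list mapping each anchor position (as character)
#'   to its admissible residue set.
#' @param score_floor minimum global alignment score; queries at or below
#'   the floor fail validation even with intact anchors (guards against
#'   chance anchor coincidence in unrelated sequences).
#' @return list of class `signature_scheme`.
#' @export
signature_scheme <- function(reference = pola_reference(),
                             anchor_positions = c(688L, 705L, 758L, 762L),
                             required = list("688" = "R", "705" = "D",
                                             "758" = "K",
                                             "762" = c("F", "L", "Y")),
                             score_floor = 0) {
  stopifnot(is.data.frame(reference), nrow(reference) == 1L)
  if (is.unsorted(anchor_positions, strictly = TRUE))
    stop("anchor positions must be strictly increasing")
  if (max(anchor_positions) > nchar(reference$residues))
    stop("anchor position beyond reference length")
  if (!setequal(names(required), as.character(anchor_positions)))
    stop("required residue map must cover exactly the anchor positions")
  structure(list(reference = reference,
                 anchor_positions = as.integer(anchor_positions),
                 required = required, score_floor = score_floor),
            class = "signature_scheme")
}

#' Extract and validate the anchor-residue signature of one query
#'
#' Globally aligns the reference against the query, maps every anchor
#' position through the alignment, and records the query residue found
#' there (`"gap"` when the anchor aligns to a gap).  The query passes when
#' every anchor carries an admissible residue and the alignment score
#' exceeds the scheme's floor.  `class762` reports the residue at the
#' classification position: `"F"`, `"L"`, `"Y"`, `"other"`, or `"gap"`.
#'
#' @param query single-row `protein_records` (or plain string).
#' @param scheme a [signature_scheme()].
#' @param params an [alignment_params()]; must be global mode.
#' @return one-row data frame: `query_id`, one `residueNNN` column per
#'   anchor, `passes`, `class762`, `alignment_score`.
#' @export
extract_signature <- function(query, scheme = signature_scheme(),
                              params = alignment_params()) {
  stopifnot(inherits(scheme, "signature_scheme"))
  if (params$mode != "global")
    stop("signature extraction requires global alignment")
  qid <- if (is.data.frame(query)) query$id else "query"
  aln <- pairwise_align(scheme$reference, query, params)
  qseq <- seq_of(query)
  res <- vapply(scheme$anchor_positions, function(p) {
    qp <- map_reference_position(aln, p)
    if (is.na(qp)) "gap" else substr(qseq, qp, qp)
  }, character(1))
  names(res) <- as.character(scheme$anchor_positions)
  ok <- vapply(names(res), function(p) res[[p]] %in% scheme$required[[p]],
               logical(1))
  passes <- all(ok) && aln$score > scheme$score_floor
  cls_pos <- as.character(max(scheme$anchor_positions))
  cls <- res[[cls_pos]]
  class762 <- if (cls == "gap") "gap"
              else if (cls %in% c("F", "L", "Y")) cls else "other"
  out <- data.frame(query_id = qid, t(res), passes = passes,
                    class762 = class762, alignment_score = aln$score,
                    stringsAsFactors = FALSE)
  names(out)[2:(1 + length(res))] <- paste0("residue", names(res))
  rownames(out) <- NULL
  out
}

#' Classify a batch of queries by anchor signature
#'
#' Classification is per-sequence (pairwise against the reference), so the
#' partition is independent of input order.
#'
#' @param queries `protein_records`.
#' @param scheme a [signature_scheme()].
#' @param params an [alignment_params()].
#' @param ledger optional [stage_ledger()] to append a `classify` stage to.
#' @return list with `retained` and `rejected` record sets, `signatures`
#'   (per-query data frame), `counts` (named vector per 762 class among
#'   retained), and `ledger`.
#' @export
classify_batch <- function(queries, scheme = signature_scheme(),
                           params = alignment_params(), ledger = NULL) {
  if (anyDuplicated(queries$id)) stop("duplicate query ids")
  sig <- do.call(rbind, lapply(seq_len(nrow(queries)), function(i)
    extract_signature(queries[i, ], scheme, params)))
  if (is.null(sig))
    sig <- extract_signature(scheme$reference, scheme, params)[0, ]
  keep <- sig$passes
  counts <- table(factor(sig$class762[keep], levels = c("F", "L", "Y")))
  if (!is.null(ledger))
    ledger <- ledger_add(ledger, "classify", nrow(queries), sum(keep))
  list(retained = queries[keep, , drop = FALSE],
       rejected = queries[!keep, , drop = FALSE],
       signatures = sig,
       counts = setNames(as.integer(counts), names(counts)),
       ledger = ledger)
}

#' Write a signature report TSV
#' @param signatures data frame from [classify_batch()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature_report <- function(signatures, path) {
  write.table(signatures, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
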