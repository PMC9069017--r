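# Length/domain filtering, domain trimming, greedy identity clustering
# within strata, and seeded stratified subsampling.

#' Filtering thresholds
#'
#' All thresholds are inclusive ("at least" semantics): a sequence of
#' exactly `min_length` residues is retained, as is a domain hit of exactly
#' `min_hit_span` residues at exactly `max_evalue`.
#'
#' @param min_length minimum sequence length in residues (default 400).
#' @param min_hit_span minimum domain-hit span in residues (default 325).
#' @param max_evalue e-value significance threshold (default 1e-10).
#' @param domain_model conserved-domain model id that qualifies a hit
#'   (default `"cl02626"`, the DNA_pol_A superfamily).
#' @return list of class `filter_config`.
#' @export
filter_config <- function(min_length = 400L, min_hit_span = 325L,
                          max_evalue = 1e-10, domain_model = "cl02626") {
  stopifnot(min_length > 0, min_hit_span > 0, max_evalue > 0)
  structure(list(min_length = as.integer(min_length),
                 min_hit_span = as.integer(min_hit_span),
                 max_evalue = max_evalue, domain_model = domain_model),
            class = "filter_config")
}

#' Length filter
#' @param records `protein_records`.
#' @param config a [filter_config()].
#' @return list with `retained` and `rejected` record sets.
#' @export
filter_length <- function(records, config = filter_config()) {
  keep <- nchar(records$residues) >= config$min_length
  list(retained = records[keep, , drop = FALSE],
       rejected = records[!keep, , drop = FALSE])
}

qualifying_hits <- function(hits, config, require_span = TRUE) {
  ok <- hits$model_id == config$domain_model & hits$evalue <= config$max_evalue
  if (require_span) ok <- ok & hits$hit_length >= config$min_hit_span
  hits[ok, , drop = FALSE]
}

#' Conserved-domain filter
#'
#' Retains a record iff it has at least one hit to the configured domain
#' model with e-value at or below the threshold and span at or above the
#' minimum.
#'
#' @param records `protein_records`.
#' @param hits domain-hit table ([read_hits_table()] / [domain_hits()]).
#' @param config a [filter_config()].
#' @return list with `retained` and `rejected` record sets.
#' @export
filter_domain <- function(records, hits, config = filter_config()) {
  unknown <- setdiff(hits$query_id, records$id)
  if (length(unknown))
    stop("hit table references unknown record id(s): ",
         paste(head(unknown, 5), collapse = ", "))
  good <- qualifying_hits(hits, config)
  keep <- records$id %in% good$query_id
  list(retained = records[keep, , drop = FALSE],
       rejected = records[!keep, , drop = FALSE])
}

#' Trim records to their longest qualifying domain hit
#'
#' When a record carries multiple significant hits to the domain model, the
#' longest is selected; ties are broken by the smaller start coordinate.
#'
#' @param records `protein_records` that passed [filter_domain()].
#' @param hits domain-hit table.
#' @param config a [filter_config()].
#' @return `protein_records` with residues trimmed to the selected hit
#'   region; an attribute `"trim_regions"` records the coordinates used.
#' @export
trim_to_domain <- function(records, hits, config = filter_config()) {
  regions <- lapply(records$id, function(id) {
    h <- hits[hits$query_id == id, , drop = FALSE]
    h <- qualifying_hits(h, config, require_span = FALSE)
    if (nrow(h) == 0L)
      stop("no qualifying domain hit for record ", id)
    h <- h[order(-h$hit_length, h$query_start), , drop = FALSE]
    h[1L, c("query_start", "query_end")]
  })
  reg <- do.call(rbind, regions)
  too_long <- reg$query_end > nchar(records$residues)
  if (any(too_long))
    stop("hit extends beyond sequence for record ",
         records$id[which(too_long)[1]])
  out <- records
  out$residues <- substr(records$residues, reg$query_start, reg$query_end)
  attr(out, "trim_regions") <- data.frame(id = records$id,
                                          start = reg$query_start,
                                          end = reg$query_end)
  out
}

#' Greedy identity clustering within a stratum
#'
#' CD-HIT-style single-pass clustering: records are sorted by decreasing
#' length (ties by id), then each record joins the first existing cluster
#' (in creation order) whose representative it matches by local alignment
#' at `min_id` identity over at least `min_cov` coverage of both sequences;
#' otherwise it founds a new cluster.  Sorting makes the partition
#' independent of input order.
#'
#' Identity is the fraction of identical residue pairs over all local
#' alignment columns (gap columns included); coverage of each side is the
#' aligned span divided by that sequence's full length ("coverage of query
#' and target" semantics).
#'
#' @param records `protein_records`, all from one (source, 762-class)
#'   stratum.
#' @param stratum optional label stored on the output.
#' @param min_id identity threshold (default 0.75).
#' @param min_cov coverage threshold for both sequences (default 0.8).
#' @param params an [alignment_params()]; coerced to local mode.
#' @return data frame with columns `representative_id`, `member_id`,
#'   `stratum`.
#' @export
greedy_cluster <- function(records, stratum = NA_character_,
                           min_id = 0.75, min_cov = 0.8,
                           params = alignment_params(mode = "local")) {
  params$mode <- "local"
  ord <- order(-nchar(records$residues), records$id)
  records <- records[ord, , drop = FALSE]
  reps <- character(0)
  assign <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    placed <- NA_character_
    for (r in reps) {
      aln <- pairwise_align(records[records$id == r, ], records[i, ], params)
      if (aln$identity >= min_id && aln$coverage_a >= min_cov &&
          aln$coverage_b >= min_cov) {
        placed <- r
        break
      }
    }
    if (is.na(placed)) {
      reps <- c(reps, records$id[i])
      placed <- records$id[i]
    }
    assign[i] <- placed
  }
  out <- data.frame(representative_id = assign, member_id = records$id,
                    stratum = stratum, stringsAsFactors = FALSE)
  out[order(match(out$representative_id, reps), out$member_id), ,
      drop = FALSE]
}

#' Seeded stratified subsampling of cluster representatives
#'
#' Within every (source, 762-class) stratum, draws a uniform sample without
#' replacement of size `min(n, stratum size)`.  Strata are processed in
#' lexicographic order and ids are sorted before sampling, so a given seed
#' yields the same sample on any platform.
#'
#' @param reps data frame with columns `id`, `source`, `class762`.
#' @param n target sample size per stratum (default 225).
#' @param seed integer RNG seed (required).
#' @return subset of `reps` (row order: stratum, then id).
#' @export
stratified_subsample <- function(reps, n = 225L, seed) {
  if (missing(seed)) stop("seed is required")
  n <- as.integer(n)
  if (is.na(n) || n <= 0L) stop("n must be a positive integer")
  stopifnot(all(c("id", "source", "class762") %in% names(reps)))
  key <- paste(reps$source, reps$class762, sep = "|")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  keep_ids <- unlist(lapply(sort(unique(key)), function(k) {
    ids <- sort(reps$id[key == k])
    if (length(ids) <= n) ids else sample(ids, n)
  }), use.names = FALSE)
  out <- reps[match(keep_ids, reps$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
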