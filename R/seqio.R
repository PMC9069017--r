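# Sequence and table I/O plus stage-accounting ledger.

CANONICAL_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                  "M", "F", "P", "S", "T", "W", "Y", "V", "X")

#' Construct a set of protein records
#'
#' The package-wide container for protein sequences is a plain data frame
#' with one row per sequence and columns `id`, `source`, `residues`,
#' `description`.  Residues are upper-case canonical amino acids plus `X`;
#' gap characters are not permitted.
#'
#' @param id character vector of unique, non-empty sequence identifiers.
#' @param residues character vector of amino-acid strings.
#' @param source source label, one of [POLA_SOURCES]; recycled.
#' @param description free-text descriptions; recycled.
#' @return data frame of class `protein_records`.
#' @export
protein_records <- function(id, residues, source = "synthetic",
                            description = "") {
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (length(id) != length(residues))
    stop("id and residues must have equal length")
  if (any(!nzchar(id))) stop("empty sequence id")
  dup <- id[duplicated(id)]
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  if (any(!nzchar(residues))) stop("zero-length residue string")
  source <- rep_len(as.character(source), length(id))
  bad_src <- setdiff(unique(source), POLA_SOURCES)
  if (length(bad_src))
    stop("unknown source label(s): ", paste(bad_src, collapse = ", "))
  bad <- grepl(sprintf("[^%s]", paste(CANONICAL_AA, collapse = "")), residues)
  if (any(bad))
    stop("non-canonical residues in: ",
         paste(head(id[bad], 5), collapse = ", "))
  out <- data.frame(id = id, source = source, residues = residues,
                    description = rep_len(as.character(description),
                                          length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("protein_records", "data.frame")
  out
}

#' Read a protein FASTA file
#'
#' Record ids are the first whitespace-delimited header token.  Residues are
#' upper-cased; terminal `*` stop symbols are stripped; ambiguous or
#' non-canonical residues (B, Z, J, U, O) are converted to `X` with a
#' warning.  Duplicate ids are an error.
#'
#' @param path FASTA file path.
#' @param source source label attached to every record.
#' @return `protein_records` data frame (possibly empty, with a warning).
#' @export
read_fasta <- function(path, source = "synthetic") {
  if (!file.exists(path)) stop("no such file: ", path)
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0L) {
    warning("empty FASTA file: ", path)
    return(protein_records(character(0), character(0))[0, ])
  }
  headers <- names(aas)
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  seqs <- toupper(as.character(aas))
  seqs <- sub("\\*+$", "", seqs)
  seqs <- sub("^\\*+", "", seqs)
  nonc <- grepl("[BZJUO]", seqs)
  if (any(nonc)) {
    warning(sum(nonc), " record(s) with non-canonical residues ",
            "(B/Z/J/U/O) converted to X")
    seqs <- gsub("[BZJUO]", "X", seqs)
  }
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  protein_records(ids, seqs, source = source, description = desc)
}

#' Write protein records to FASTA
#'
#' @param records `protein_records` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  aas <- Biostrings::AAStringSet(setNames(records$residues, records$id))
  Biostrings::writeXStringSet(aas, path, width = 60L)
  invisible(path)
}

#' Read a conserved-domain hit table
#'
#' Parses a BLAST-tabular-style TSV with header columns `query_id`,
#' `model_id`, `evalue`, `query_start`, `query_end` (1-based inclusive
#' residue coordinates).  A derived `hit_length = query_end - query_start +
#' 1` column is added.  Hit tables are consumed, never computed: e-values
#' come from an upstream search tool or the synthetic generator.
#'
#' @param path TSV path.
#' @return data frame of domain hits.
#' @export
read_hits_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read.delim(path, header = TRUE, colClasses = "character",
                    stringsAsFactors = FALSE)
  need <- c("query_id", "model_id", "evalue", "query_start", "query_end")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("hit table missing column(s): ", paste(miss, collapse = ", "))
  ev <- suppressWarnings(as.numeric(raw$evalue))
  qs <- suppressWarnings(as.integer(raw$query_start))
  qe <- suppressWarnings(as.integer(raw$query_end))
  bad <- which(is.na(ev) | is.na(qs) | is.na(qe))
  if (length(bad))
    stop("non-numeric field in hit table at data row ", bad[1])
  domain_hits(raw$query_id, raw$model_id, ev, qs, qe)
}

#' Construct a validated domain-hit table
#'
#' @param query_id,model_id character vectors.
#' @param evalue non-negative numeric vector.
#' @param query_start,query_end 1-based inclusive residue coordinates.
#' @return data frame with derived `hit_length` column.
#' @export
domain_hits <- function(query_id, model_id, evalue, query_start, query_end) {
  bad <- which(query_end < query_start | query_start < 1L)
  if (length(bad))
    stop("invalid hit coordinates (query_end < query_start or start < 1) ",
         "at data row ", bad[1])
  if (any(evalue < 0)) stop("negative e-value")
  data.frame(query_id = as.character(query_id),
             model_id = as.character(model_id),
             evalue = evalue,
             query_start = as.integer(query_start),
             query_end = as.integer(query_end),
             hit_length = as.integer(query_end - query_start + 1L),
             stringsAsFactors = FALSE)
}

#' Stage-accounting ledger
#'
#' A ledger records, for each pipeline stage and (optionally) source, the
#' input, retained and rejected sequence counts.  Conservation
#' (`input = retained + rejected`) is enforced at every append, as is chain
#' consistency: within a source, the input of stage *k+1* must equal the
#' retained count of stage *k*.
#'
#' @return empty ledger data frame.
#' @export
stage_ledger <- function() {
  out <- data.frame(stage = character(0), source = character(0),
                    input = integer(0), retained = integer(0),
                    rejected = integer(0), stringsAsFactors = FALSE)
  class(out) <- c("stage_ledger", "data.frame")
  out
}

#' Append a stage to a ledger
#'
#' @param ledger a [stage_ledger()].
#' @param stage stage name.
#' @param input,retained counts (vectors, parallel to `source`).
#' @param source per-count source label(s); `NA` for pooled counts.
#' @return updated ledger.
#' @export
ledger_add <- function(ledger, stage, input, retained, source = NA) {
  stopifnot(inherits(ledger, "stage_ledger"))
  input <- as.integer(input)
  retained <- as.integer(retained)
  source <- rep_len(as.character(source), length(input))
  if (any(retained > input) || any(retained < 0L) || any(input < 0L))
    stop("ledger counts must satisfy 0 <= retained <= input")
  for (k in seq_along(source)) {
    prev <- if (is.na(source[k])) ledger[is.na(ledger$source), , drop = FALSE]
            else ledger[!is.na(ledger$source) & ledger$source == source[k], ,
                        drop = FALSE]
    if (nrow(prev) && prev$retained[nrow(prev)] != input[k])
      stop("ledger chain broken at stage '", stage, "': input ", input[k],
           " != previous retained ", prev$retained[nrow(prev)])
  }
  add <- data.frame(stage = stage, source = source, input = input,
                    retained = retained, rejected = input - retained,
                    stringsAsFactors = FALSE)
  out <- rbind(as.data.frame(ledger), add)
  class(out) <- c("stage_ledger", "data.frame")
  out
}

#' Final per-source retained counts and grand total
#'
#' Accepts either a [stage_ledger()] (the retained counts of each source's
#' final stage are summed) or a named numeric vector of per-source counts.
#'
#' @param x ledger or named numeric vector.
#' @return list with `per_source` (named integer vector) and `total`.
#' @export
ledger_total <- function(x) {
  if (inherits(x, "stage_ledger")) {
    if (nrow(x) == 0L)
      return(list(per_source = setNames(integer(0), character(0)), total = 0L))
    src <- ifelse(is.na(x$source), "(all)", x$source)
    per <- vapply(split(x$retained, src), function(v) v[length(v)], 1L)
  } else {
    per <- as.integer(x)
    names(per) <- if (is.null(names(x))) as.character(seq_along(x))
                  else names(x)
  }
  list(per_source = per, total = sum(per))
}

#' Write a ledger report to TSV
#' @param ledger a [stage_ledger()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  write.table(as.data.frame(ledger), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
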