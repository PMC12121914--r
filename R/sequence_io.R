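#' Read protein sequences from a FASTA file
#'
#' Parses a (possibly multi-line) FASTA file into a `protein_records`
#' data frame. The record id is the header up to the first whitespace;
#' the full header is retained as `description` (UniProt-style headers).
#'
#' @param path Path to a FASTA file.
#' @param strict If `TRUE`, records are validated against the 20
#'   canonical residues and the first violation aborts with an error;
#'   if `FALSE` (default), records are returned as parsed (use
#'   [validate_records()] to clean them).
#' @return A data frame of class `protein_records` with columns `id`,
#'   `description`, `sequence` and `length`, one row per FASTA entry,
#'   in file order.
#' @seealso [write_fasta()], [validate_records()]
#' @export
read_fasta <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  headers <- names(set)
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    bad <- headers[which(!nzchar(seqs))[1]]
    stop("malformed FASTA '", path, "': entry '", bad,
         "' has an empty sequence")
  }
  ids <- sub("\\s.*$", "", headers)
  recs <- protein_records(ids, seqs, description = headers)
  if (strict) validate_records(recs, strict = TRUE) else recs
}

#' Build a protein_records data frame
#'
#' @param id Character vector of identifiers.
#' @param sequence Character vector of amino-acid sequences (uppercased).
#' @param description Optional full headers; defaults to `id`.
#' @return A `protein_records` data frame (columns `id`, `description`,
#'   `sequence`, `length`).
#' @export
protein_records <- function(id, sequence, description = id) {
  stopifnot(length(id) == length(sequence))
  sequence <- toupper(sequence)
  out <- data.frame(id = as.character(id),
                    description = as.character(description),
                    sequence = sequence,
                    length = nchar(sequence),
                    stringsAsFactors = FALSE)
  class(out) <- c("protein_records", "data.frame")
  out
}

#' Write protein records to FASTA
#'
#' Round-trips with [read_fasta()]: ids and sequences are preserved
#' byte-identically for canonical inputs.
#'
#' @param records A `protein_records` data frame (or anything with `id`,
#'   `sequence` columns).
#' @param path Output file path.
#' @param width Line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- ifelse(records$description == records$id |
                         !nzchar(records$description),
                       records$id, records$description)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Validate records against the canonical amino-acid alphabet
#'
#' The classifier's feature space is defined over the 20 canonical
#' residues, so ambiguous codes (B, X, Z) and other non-canonical
#' characters (U, O, `*`, ...) must be excluded (strict mode, mirroring
#' training-set curation) or stripped (lenient mode, so a proteome-wide
#' screen does not abort on one odd residue).
#'
#' @param records A `protein_records` data frame.
#' @param strict If `TRUE`, the first offending record aborts with an
#'   error naming the record, character and position. If `FALSE`,
#'   non-canonical characters are stripped with a warning; records whose
#'   sequence becomes empty are dropped (also with a warning).
#' @return The validated (possibly cleaned) `protein_records`.
#' @examples
#' recs <- protein_records("p1", "ACDEFGHIKLMNPQRSTVWY")
#' identical(validate_records(recs, strict = TRUE), recs)
#' @export
validate_records <- function(records, strict = TRUE) {
  pat <- "[^ACDEFGHIKLMNPQRSTVWY]"
  hit <- regexpr(pat, records$sequence)
  bad <- which(hit > 0L)
  if (!length(bad)) return(records)
  if (strict) {
    i <- bad[1]
    ch <- substring(records$sequence[i], hit[i], hit[i])
    stop("record '", records$id[i], "' contains non-canonical residue '",
         ch, "' at position ", hit[i], call. = FALSE)
  }
  cleaned <- gsub(pat, "", records$sequence[bad])
  warning(length(bad), " record(s) contained non-canonical residues; ",
          "offending characters stripped", call. = FALSE)
  records$sequence[bad] <- cleaned
  records$length <- nchar(records$sequence)
  empty <- which(records$length == 0L)
  if (length(empty)) {
    warning(length(empty), " record(s) empty after cleaning and dropped: ",
            paste(records$id[empty], collapse = ", "), call. = FALSE)
    records <- records[-empty, , drop = FALSE]
    rownames(records) <- NULL
  }
  records
}

#' Load a labeled dataset from a manifest file
#'
#' The manifest is a plain tab-separated file with a header line and
#' columns `file`, `label`, `partition`: one FASTA file per row, `label`
#' 1 for the positive class and 0 for the negative class, `partition`
#' either `train` or `test`. File paths are resolved relative to the
#' manifest's directory.
#'
#' @param manifest Path to the manifest TSV, or a data frame with the
#'   same three columns.
#' @param partition Optional filter: keep only rows with this partition.
#' @param task Optional task tag stored on the dataset (e.g.
#'   `"TFPM_vs_TFPNM"`).
#' @param strict Validation mode passed through to [validate_records()].
#' @param quiet Suppress the per-file count messages.
#' @return A `labeled_dataset`: list with `records` (`protein_records`),
#'   `labels` (integer 0/1, parallel to records), `partition`, `task`.
#' @export
load_dataset <- function(manifest, partition = NULL, task = NULL,
                         strict = TRUE, quiet = FALSE) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) stop("manifest not found: ", manifest)
    base <- dirname(manifest)
    man <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  } else {
    base <- "."
    man <- as.data.frame(manifest, stringsAsFactors = FALSE)
  }
  need <- c("file", "label", "partition")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (!is.null(partition)) man <- man[man$partition == partition, , drop = FALSE]
  if (!nrow(man)) {
    warning("manifest selects no files; returning an empty dataset",
            call. = FALSE)
    return(labeled_dataset(protein_records(character(), character()),
                           integer(), partition = partition, task = task))
  }
  pieces <- vector("list", nrow(man))
  labels <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    f <- man$file[i]
    if (!file.exists(f)) f <- file.path(base, man$file[i])
    recs <- read_fasta(f)
    recs <- validate_records(recs, strict = strict)
    if (!quiet)
      message(sprintf("%s: %d records (label %s, %s)",
                      man$file[i], nrow(recs), man$label[i], man$partition[i]))
    pieces[[i]] <- recs
    labels[[i]] <- rep(as.integer(man$label[i]), nrow(recs))
  }
  records <- do.call(rbind, pieces)
  rownames(records) <- NULL
  class(records) <- c("protein_records", "data.frame")
  labels <- unlist(labels)
  labeled_dataset(records, labels, partition = partition, task = task)
}

#' Construct a labeled dataset
#'
#' @param records A `protein_records` data frame.
#' @param labels Integer (or logical) vector, 1 = positive class,
#'   parallel to `records`.
#' @param partition Optional `"train"` / `"test"` tag.
#' @param task Optional task tag.
#' @return A `labeled_dataset` object.
#' @export
labeled_dataset <- function(records, labels, partition = NULL, task = NULL) {
  labels <- as.integer(labels)
  if (nrow(records) != length(labels))
    stop("records and labels must have equal length")
  if (length(labels) && !all(labels %in% c(0L, 1L)))
    stop("labels must be binary (0/1)")
  lab_by_id <- split(labels, records$id)
  mixed <- names(lab_by_id)[vapply(lab_by_id, function(v)
    length(unique(v)) > 1L, logical(1))]
  if (length(mixed))
    stop("duplicate id(s) across classes: ", paste(mixed, collapse = ", "))
  structure(list(records = records, labels = labels,
                 partition = partition, task = task),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("Labeled protein dataset: ", nrow(x$records), " records (",
      sum(x$labels == 1L), " positive / ", sum(x$labels == 0L),
      " negative)\n", sep = "")
  if (!is.null(x$partition)) cat("  partition: ", x$partition, "\n", sep = "")
  if (!is.null(x$task)) cat("  task: ", x$task, "\n", sep = "")
  invisible(x)
}
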