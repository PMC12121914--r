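CANONICAL_RESIDUES <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct a reduced amino-acid alphabet scheme
#'
#' A reduction scheme partitions the 20 canonical residues into groups,
#' each written with a single symbol. Reduced-alphabet ("RAAC") encoding
#' collapses physicochemically similar residues so that downstream K-mer
#' features are lower-dimensional and less sparse.
#'
#' @param name Scheme name, e.g. `"Op11"`.
#' @param groups Named list: names are single-character group symbols, values
#'   are strings of the canonical residues belonging to that group. The
#'   order of the list fixes the symbol order used for K-mer indexing.
#' @return An object of class `reduction_scheme` with elements `name`,
#'   `symbols` (ordered), `groups`, `map` (named character vector,
#'   residue -> symbol) and `size` (number of groups).
#' @examples
#' sch <- reduction_scheme("toy", list(H = "ACDEFGHIKLM", P = "NPQRSTVWY"))
#' sch$size
#' @export
reduction_scheme <- function(name, groups) {
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("every group must carry a single-character symbol name")
  symbols <- names(groups)
  if (any(nchar(symbols) != 1L))
    stop("group symbols must be single characters")
  if (anyDuplicated(symbols))
    stop("group symbols must be pairwise distinct")
  members <- lapply(groups, function(g) strsplit(g, "")[[1]])
  all_res <- unlist(members, use.names = FALSE)
  if (anyDuplicated(all_res))
    stop("scheme is not a partition: residue(s) ",
         paste(unique(all_res[duplicated(all_res)]), collapse = ", "),
         " assigned to more than one group")
  missing <- setdiff(CANONICAL_RESIDUES, all_res)
  if (length(missing))
    stop("scheme is not a partition: residue(s) ",
         paste(missing, collapse = ", "), " not assigned to any group")
  extra <- setdiff(all_res, CANONICAL_RESIDUES)
  if (length(extra))
    stop("scheme contains non-canonical residue(s): ",
         paste(extra, collapse = ", "))
  map <- structure(rep(symbols, lengths(members)), names = unlist(members))
  map <- map[CANONICAL_RESIDUES]
  structure(
    list(name = name, symbols = symbols, groups = members,
         map = map, size = length(symbols)),
    class = "reduction_scheme"
  )
}

#' @export
print.reduction_scheme <- function(x, ...) {
  cat("Reduced amino-acid alphabet scheme '", x$name, "' (",
      x$size, " groups)\n", sep = "")
  for (s in x$symbols)
    cat("  ", s, ": ", paste(x$groups[[s]], collapse = ""), "\n", sep = "")
  invisible(x)
}

# The 11-group scheme is the canonical, built-in partition used by the
# TFPM classifier at its optimum. Note the deliberate symbol quirks:
# cysteine maps to symbol 'V' and the {I, V} group to symbol 'I'.
.op11_groups <- list(
  G = "G",
  I = "IV",
  F = "FYW",
  A = "A",
  L = "LM",
  E = "EQRK",
  P = "P",
  N = "ND",
  H = "HS",
  T = "T",
  V = "C"
)

.builtin_schemes <- function() {
  list(
    op11 = reduction_scheme("Op11", .op11_groups),
    # Identity scheme: every residue its own group; featurize at k = 1
    # reduces to classical amino-acid composition.
    op20 = reduction_scheme(
      "Op20",
      structure(as.list(CANONICAL_RESIDUES), names = CANONICAL_RESIDUES)
    )
  )
}

#' Load a reduction scheme by name or from a scheme file
#'
#' `"Op11"` (the canonical 11-group partition) and `"Op20"` (identity) are
#' built in. `"Op5"`, `"Op8"`, `"Op9"` and `"Op13"` are companion schemes
#' shipped as plain-text files under `inst/extdata/schemes/`; they are
#' nested coarsenings/refinements of the 11-group partition, reconstructed
#' along physicochemical similarity (see the package vignette). Any other
#' value is treated as a path to a scheme file with one group per line,
#' `SYMBOL: RESIDUES` (lines starting with `#` are ignored).
#'
#' @param name_or_path Scheme name (case-insensitive) or file path.
#' @return A validated [reduction_scheme].
#' @examples
#' op11 <- load_scheme("Op11")
#' op11$map[["C"]]  # cysteine carries symbol 'V'
#' @export
load_scheme <- function(name_or_path) {
  key <- tolower(name_or_path)
  builtin <- .builtin_schemes()
  if (key %in% names(builtin)) return(builtin[[key]])
  if (key %in% c("op5", "op8", "op9", "op13")) {
    path <- system.file("extdata", "schemes", paste0(key, ".txt"),
                        package = "methylTF")
    if (!nzchar(path))
      stop("bundled scheme file for '", name_or_path, "' not found")
    return(read_scheme_file(path, name = paste0("Op", substring(key, 3))))
  }
  if (!file.exists(name_or_path))
    stop("'", name_or_path, "' is neither a registered scheme nor a file")
  read_scheme_file(name_or_path)
}

#' Read a reduction scheme from a plain-text file
#'
#' @param path File with one group per line as `SYMBOL: RESIDUES`.
#' @param name Optional scheme name; defaults to the file's base name.
#' @return A validated [reduction_scheme].
#' @export
read_scheme_file <- function(path, name = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("scheme file '", path, "' contains no groups")
  parts <- regmatches(lines, regexec("^(\\S+)\\s*:\\s*([A-Za-z]+)$", lines))
  bad <- lengths(parts) != 3L
  if (any(bad))
    stop("malformed scheme line: '", lines[which(bad)[1]], "'")
  symbols <- vapply(parts, `[[`, character(1), 2L)
  residues <- toupper(vapply(parts, `[[`, character(1), 3L))
  groups <- structure(as.list(residues), names = symbols)
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  reduction_scheme(name, groups)
}
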