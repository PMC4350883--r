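# FASTA and Newick I/O.  Parsing is delegated to Biostrings / ape; these
# wrappers add the package's validation contracts and tibble surfaces.

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a text FASTA file.
#' @param aligned If `TRUE` the file is an alignment: all rows must have
#'   equal length and gap characters (`-`) are retained.  If `FALSE`
#'   (default) gaps are an error.
#' @return A tibble with one row per record and columns `id` (first
#'   whitespace-delimited word of the header), `description` (rest of the
#'   header, possibly empty) and `residues` (uppercase).  Records keep
#'   file order.  The `aligned` attribute records the mode used.
#' @export
read_fasta <- function(path, aligned = FALSE) {
  if (!file.exists(path)) stop_precondition(paste0("no such file: ", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop_format(conditionMessage(e)))
  if (length(set) == 0) stop_empty(paste0("empty FASTA file: ", path))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  residues <- toupper(as.character(set))
  if (any(ids == "" | residues == "")) {
    stop_format("FASTA records must have non-empty ids and residues")
  }
  if (aligned) {
    if (length(unique(nchar(residues))) != 1) {
      stop_format("ragged alignment: rows differ in length")
    }
    assert_residues(residues, allow_gap = TRUE)
  } else {
    if (any(grepl("-", residues, fixed = TRUE))) {
      stop_format("gap characters found; pass aligned = TRUE for alignments")
    }
    assert_residues(residues)
  }
  out <- tibble(id = unname(ids), description = unname(desc),
                residues = unname(residues))
  attr(out, "aligned") <- aligned
  out
}

#' Write sequence records to FASTA
#'
#' @param records Tibble with columns `id`, `residues` and optionally
#'   `description`.
#' @param path Output path.  Writes UTF-8, LF line endings.
#' @param width Line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (nrow(records) == 0) stop_empty("no records to write")
  desc <- if ("description" %in% names(records)) records$description
          else rep("", nrow(records))
  header <- ifelse(desc == "", records$id, paste(records$id, desc))
  chunks <- purrr::map2(header, records$residues, function(h, r) {
    body <- substring(r, seq(1, nchar(r), by = width),
                      pmin(seq(1, nchar(r), by = width) + width - 1, nchar(r)))
    c(paste0(">", h), body)
  })
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(unlist(chunks), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write a phylogenetic tree as Newick text
#'
#' @param tree An `ape::phylo` tree with >= 2 leaves, named tips and
#'   non-negative branch lengths.
#' @param path Optional output path; when `NULL` the Newick string is
#'   returned.
#' @param digits Branch-length precision.
#' @return The Newick string (invisibly when `path` is given).
#' @export
write_newick <- function(tree, path = NULL, digits = 10L) {
  if (!inherits(tree, "phylo")) stop_precondition("tree must be a phylo object")
  if (length(tree$tip.label) < 2) stop_precondition("tree needs >= 2 leaves")
  if (any(is.na(tree$tip.label) | tree$tip.label == "")) {
    stop_format("unnamed leaf in tree")
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop_precondition("negative branch lengths")
  }
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(txt)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(txt, con, sep = "\n", useBytes = TRUE)
  invisible(txt)
}

#' Read a Newick tree
#'
#' @param path Path to a Newick file (or a literal Newick string via
#'   `text`).
#' @param text Optional Newick string.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tr)) stop_format("could not parse Newick input")
  tr
}
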