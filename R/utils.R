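# Shared validation helpers and classed error conditions.
#
# Error classes follow a single convention so callers can branch on them:
#   wrky_format_error        malformed or inconsistent input file
#   wrky_precondition_error  argument contract violated
#   wrky_empty_input         an input that must be non-empty is empty
#   wrky_domain_error        numeric argument outside its mathematical domain
#   wrky_degenerate_distance a sequence pair with no comparable sites
#   wrky_config_error        invalid pipeline configuration

stop_format <- function(msg, ...) {
  abort(msg, class = c("wrky_format_error", "wrky_error"), ...)
}
stop_precondition <- function(msg, ...) {
  abort(msg, class = c("wrky_precondition_error", "wrky_error"), ...)
}
stop_empty <- function(msg, ...) {
  abort(msg, class = c("wrky_empty_input", "wrky_error"), ...)
}
stop_domain <- function(msg, ...) {
  abort(msg, class = c("wrky_domain_error", "wrky_error"), ...)
}
stop_degenerate <- function(msg, ...) {
  abort(msg, class = c("wrky_degenerate_distance", "wrky_error"), ...)
}
stop_config <- function(msg, ...) {
  abort(msg, class = c("wrky_config_error", "wrky_error"), ...)
}

assert_residues <- function(x, allow_gap = FALSE, what = "residues") {
  ok <- AA_ALPHABET
  if (allow_gap) ok <- c(ok, "-")
  chars <- unique(unlist(strsplit(x, "", fixed = TRUE)))
  bad <- setdiff(chars, ok)
  if (length(bad) > 0) {
    stop_precondition(sprintf("%s contain invalid characters: %s",
                              what, paste(bad, collapse = ", ")))
  }
  invisible(x)
}

# Split residue strings into a character matrix (rows = sequences).
residue_matrix <- function(residues) {
  n <- nchar(residues)
  if (length(unique(n)) != 1) {
    stop_format("sequences have unequal lengths; expected an alignment")
  }
  matrix(unlist(strsplit(residues, "", fixed = TRUE)),
         nrow = length(residues), byrow = TRUE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
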