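# R protein-WRKY (RW) architecture building and family classification.
#
# Architectures are ordered token strings over the controlled vocabulary
# (TIR, NB-ARC, LRR, B3, NAC, CAMB, MAPKKK, PAH, WRKY(<group>)); the
# shipped grammar encodes the eight published family definitions RW1-RW8
# with optional tokens in brackets.

#' The RW family grammar
#'
#' @param path Optional path to a grammar TSV (columns `family`,
#'   `pattern`, `wrky_wildcard`); defaults to the shipped grammar.
#' @return A tibble with `family`, `tokens` (list of token patterns),
#'   `optional` (list of logicals) and `wrky_wildcard`.
#' @export
rw_grammar <- function(path = NULL) {
  if (is.null(path)) {
    cached <- .wrky_cache$grammar
    if (!is.null(cached)) return(cached)
  }
  used <- path %||% system.file("extdata", "rw_grammar.tsv",
                                package = "wrkyr")
  df <- readr::read_tsv(used, col_types = "cci", progress = FALSE)
  df |>
    mutate(parsed = purrr::map(.data$pattern, function(p) {
      toks <- strsplit(p, " ", fixed = TRUE)[[1]]
      opt <- grepl("^\\[.*\\]$", toks)
      toks <- sub("^\\[(.*)\\]$", "\\1", toks)
      list(tokens = toks, optional = opt)
    })) |>
    mutate(tokens = purrr::map(.data$parsed, "tokens"),
           optional = purrr::map(.data$parsed, "optional"),
           wrky_wildcard = .data$wrky_wildcard == 1L) |>
    select("family", "tokens", "optional", "wrky_wildcard") -> out
  if (is.null(path)) .wrky_cache$grammar <- out
  out
}

#' Build the ordered domain architecture of a protein
#'
#' Rows are sorted by start; overlapping rows (more than 50% mutual
#' overlap) are resolved to the higher score; consecutive LRR rows
#' separated by at most `lrr_gap` residues collapse to one token; WRKY
#' rows are annotated with their group call (N-to-C order), or
#' `UNCLASSIFIED` when no call is available.
#'
#' @param rows Domain-annotation rows of one protein (see
#'   [read_domain_table()]).
#' @param wrky_calls Group calls for the protein's WRKY domains (may be
#'   empty).
#' @param lrr_gap Maximum residue gap for collapsing adjacent LRR rows.
#' @return A tibble with one row per architecture token: `protein_id`,
#'   `position`, `token`, `label`, `group`, `start`, `end`, `score`.
#' @export
build_architecture <- function(rows, wrky_calls = NULL, lrr_gap = 30L) {
  if (nrow(rows) == 0) stop_precondition("no annotation rows")
  if (length(unique(rows$protein_id)) != 1) {
    stop_precondition("rows must share one protein_id")
  }
  if (!is.null(wrky_calls) && nrow(wrky_calls) > 0 &&
      any(wrky_calls$protein_id != rows$protein_id[1])) {
    stop_precondition("wrky_calls must share the rows' protein_id")
  }
  d <- arrange(rows, .data$start, .data$end)
  # Overlap resolution: keep the higher-scoring of two rows that overlap
  # each other by more than half of both lengths.
  keep <- rep(TRUE, nrow(d))
  for (i in seq_len(nrow(d))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(d))) {
      if (j <= i || !keep[j]) next
      ov <- min(d$end[i], d$end[j]) - max(d$start[i], d$start[j]) + 1L
      if (ov <= 0) next
      li <- d$end[i] - d$start[i] + 1L
      lj <- d$end[j] - d$start[j] + 1L
      if (ov > 0.5 * li && ov > 0.5 * lj) {
        if (d$score[j] > d$score[i]) keep[i] <- FALSE else keep[j] <- FALSE
      }
    }
  }
  d <- d[keep, ]
  # Collapse runs of adjacent LRR rows.
  merged <- list()
  for (i in seq_len(nrow(d))) {
    m <- length(merged)
    if (m > 0 && d$domain_label[i] == "LRR" &&
        merged[[m]]$domain_label == "LRR" &&
        (d$start[i] - merged[[m]]$end - 1L) <= lrr_gap) {
      merged[[m]]$end <- max(merged[[m]]$end, d$end[i])
      merged[[m]]$score <- max(merged[[m]]$score, d$score[i])
    } else {
      merged[[m + 1]] <- as.list(d[i, ])
    }
  }
  d <- bind_rows(lapply(merged, as_tibble))
  # Annotate WRKY tokens with their group calls, N-to-C.
  groups <- rep(NA_character_, nrow(d))
  wrky_idx <- which(d$domain_label == "WRKY")
  if (length(wrky_idx) > 0) {
    call_groups <- if (!is.null(wrky_calls) && nrow(wrky_calls) > 0) {
      arrange(wrky_calls, .data$index_in_protein)$group
    } else character(0)
    for (k in seq_along(wrky_idx)) {
      groups[wrky_idx[k]] <- if (k <= length(call_groups)) call_groups[k]
                             else "UNCLASSIFIED"
    }
  }
  tibble(protein_id = d$protein_id, position = seq_len(nrow(d)),
         token = ifelse(d$domain_label == "WRKY",
                        paste0("WRKY(", groups, ")"), d$domain_label),
         label = d$domain_label, group = groups,
         start = d$start, end = d$end, score = d$score)
}

# Does a token sequence match a grammar row?  Optional tokens are
# expanded by brute force (0/1 occurrences); extra tokens fail the match.
match_rule <- function(tokens, rule) {
  opt_idx <- which(rule$optional)
  subsets <- if (length(opt_idx) == 0) list(integer(0)) else {
    masks <- expand.grid(rep(list(c(FALSE, TRUE)), length(opt_idx)))
    lapply(seq_len(nrow(masks)), function(r) opt_idx[unlist(masks[r, ])])
  }
  tok_match <- function(tok, pat) {
    if (tok == pat) return(TRUE)
    if (rule$wrky_wildcard && grepl("^WRKY\\(", tok) &&
        grepl("^WRKY\\(", pat)) {
      # truncated/unclassifiable WRKY domains match any WRKY slot
      return(grepl("UNCLASSIFIED|\\*", tok))
    }
    FALSE
  }
  for (drop in subsets) {
    pat <- rule$tokens[setdiff(seq_along(rule$tokens), drop)]
    if (length(pat) != length(tokens)) next
    if (all(mapply(tok_match, tokens, pat))) return(TRUE)
  }
  FALSE
}

#' Classify an architecture into an RW family
#'
#' Matches the token string against the shipped grammar in family order
#' RW1..RW8.  `NOT_RW` when the architecture lacks a WRKY token or lacks
#' all of TIR/NB-ARC/LRR; unmatched WRKY + R-domain architectures are
#' `RW_NOVEL`.  A single-WRKY(III) TIR architecture matches both RW2 and
#' RW4; a `lineage_hint` (species name) resolves it (strawberry family
#' RW2, soybean RW4), otherwise the candidate pair is reported with
#' `matched_rule = "RW2|RW4"`.  Leading/trailing `OTHER:*` tokens are
#' ignored.
#'
#' @param arch Architecture tibble from [build_architecture()] (one
#'   protein).
#' @param lineage_hint Optional species/lineage token.
#' @param grammar Grammar tibble from [rw_grammar()].
#' @return One-row tibble: `protein_id`, `family`, `matched_rule`,
#'   `candidates` (list), `lineage_hint_used`.
#' @export
classify_rw <- function(arch, lineage_hint = NULL, grammar = rw_grammar()) {
  tokens <- arch$token
  # strict grammar, but leading/trailing OTHER:* tokens are ignored
  while (length(tokens) > 0 && grepl("^OTHER:", tokens[1])) {
    tokens <- tokens[-1]
  }
  while (length(tokens) > 0 && grepl("^OTHER:", tokens[length(tokens)])) {
    tokens <- tokens[-length(tokens)]
  }
  has_wrky <- any(grepl("^WRKY\\(", tokens))
  has_r <- any(tokens %in% c("TIR", "NB-ARC", "LRR"))
  result <- function(family, rule, cand = NULL, hint_used = FALSE) {
    tibble(protein_id = arch$protein_id[1], family = family,
           matched_rule = rule, candidates = list(cand),
           lineage_hint_used = hint_used)
  }
  if (!(has_wrky && has_r)) return(result("NOT_RW", NA_character_))
  hit <- grammar$family[vapply(seq_len(nrow(grammar)), function(i) {
    match_rule(tokens, as.list(grammar[i, ]) |>
                 (\(r) list(tokens = r$tokens[[1]],
                            optional = r$optional[[1]],
                            wrky_wildcard = r$wrky_wildcard))())
  }, logical(1))]
  if (length(hit) == 0) return(result("RW_NOVEL", NA_character_))
  if (length(hit) == 1) return(result(hit, hit))
  if (setequal(hit, c("RW2", "RW4"))) {
    if (!is.null(lineage_hint) && !is.na(lineage_hint)) {
      h <- tolower(lineage_hint)
      if (grepl("strawberry|fragaria", h)) {
        return(result("RW2", "RW2", hint_used = TRUE))
      }
      if (grepl("soybean|glycine", h)) {
        return(result("RW4", "RW4", hint_used = TRUE))
      }
    }
    return(result("RW2|RW4", "RW2|RW4", cand = c("RW2", "RW4")))
  }
  result(hit[1], hit[1], cand = hit)
}

#' Classify RW families across a set of proteins
#'
#' @param arch_all Architecture tibble covering several proteins.
#' @param hints Optional named character vector `protein_id -> lineage
#'   hint`.
#' @param grammar Grammar tibble.
#' @return Tibble of RW calls, one row per protein, class `wrky_rw`.
#' @export
classify_rw_proteins <- function(arch_all, hints = NULL,
                                 grammar = rw_grammar()) {
  out <- arch_all |>
    group_by(.data$protein_id) |>
    dplyr::group_map(function(a, key) {
      a$protein_id <- key$protein_id
      hint <- if (!is.null(hints)) unname(hints[key$protein_id]) else NULL
      classify_rw(a, lineage_hint = hint, grammar = grammar)
    }) |>
    bind_rows()
  class(out) <- c("wrky_rw", class(out))
  out
}
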