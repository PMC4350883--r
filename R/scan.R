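# WRKY domain scanning: signature heptapeptides, zinc fingers, and the
# curation rule that calls a domain only when a signature is followed by
# at least part of a zinc finger.
#
# All offsets in this module are 0-based; spans are half-open.  Output
# writers convert to 1-based inclusive coordinates at the I/O boundary.

one_record <- function(record) {
  if (is.character(record)) {
    return(list(id = names(record) %||% "seq1", residues = unname(record)))
  }
  if (nrow(record) != 1) {
    stop_precondition("expected a single sequence record")
  }
  list(id = record$id, residues = record$residues)
}

#' Scan a protein for WRKY signature heptapeptides
#'
#' Every 7-residue window whose Hamming distance to some library variant
#' is at most `max_mismatches` yields a hit against the closest variant
#' (ties broken by library order, canonical `WRKYGQK` first).  Matching is
#' anchored: the first residue of an accepted window must be `W`.
#' Overlapping hits are deduplicated to the best-scoring (fewest
#' mismatches, then leftmost) one.
#'
#' @param record A one-row tibble with `id` and `residues` (unaligned), or
#'   a plain residue string.
#' @param max_mismatches Maximum Hamming distance, 0-3.
#' @param variants Signature variant library; see [signature_variants()].
#' @return A tibble with columns `protein_id`, `offset` (0-based),
#'   `heptapeptide`, `matched_variant`, `mismatches`, sorted by offset.
#' @export
scan_signatures <- function(record, max_mismatches = 0L,
                            variants = signature_variants()) {
  rec <- one_record(record)
  if (max_mismatches < 0 || max_mismatches > 3) {
    stop_precondition("max_mismatches must be between 0 and 3")
  }
  if (grepl("-", rec$residues, fixed = TRUE)) {
    stop_precondition("residues contain gaps; scanning needs unaligned input")
  }
  empty <- tibble(protein_id = character(0), offset = integer(0),
                  heptapeptide = character(0), matched_variant = character(0),
                  mismatches = integer(0))
  chars <- strsplit(rec$residues, "", fixed = TRUE)[[1]]
  L <- length(chars)
  if (L < 7) return(empty)
  vchars <- lapply(variants, function(v) strsplit(v, "", fixed = TRUE)[[1]])
  anchors <- which(chars == "W")
  anchors <- anchors[anchors <= L - 6]
  if (length(anchors) == 0) return(empty)
  hits <- purrr::map_dfr(anchors, function(i) {
    win <- chars[i:(i + 6)]
    mm <- vapply(vchars, function(v) sum(win != v), integer(1))
    best <- which.min(mm)   # ties -> first in library order
    if (mm[best] > max_mismatches) return(NULL)
    tibble(protein_id = rec$id, offset = i - 1L,
           heptapeptide = paste(win, collapse = ""),
           matched_variant = variants[best], mismatches = mm[best])
  })
  if (nrow(hits) == 0) return(empty)
  # Deduplicate overlapping windows: best score wins, leftmost on ties.
  hits <- arrange(hits, .data$mismatches, .data$offset)
  kept <- integer(0)
  for (k in seq_len(nrow(hits))) {
    if (all(abs(hits$offset[k] - hits$offset[kept]) >= 7L)) {
      kept <- c(kept, k)
    }
  }
  arrange(hits[kept, ], .data$offset)
}

#' Zinc-finger pattern classes and spacing envelopes
#'
#' The default envelopes accept the group-typical spacings:
#' `C2H2_X4` = C-x(4)-C-x(20,28)-H-x(1)-H, `C2H2_X5` = C-x(5)-C-x(20,28)-
#' H-x(1)-H, `C2HC` = C-x(4,7)-C-x(20,28)-H-x(1,3)-C, `FUNGAL` =
#' C-x(6)-C-x(5,30)-H-x(3)-C.  Envelopes are configurable by passing a
#' modified copy of this list to [detect_zinc_finger()].
#'
#' @return Named list of class definitions (`residues`, gap ranges `g1`,
#'   `g2`, `g3`), in precedence order.
#' @export
zinc_finger_classes <- function() {
  list(
    C2H2_X4 = list(residues = c("C", "C", "H", "H"),
                   g1 = 4L, g2 = 20:28, g3 = 1L),
    C2H2_X5 = list(residues = c("C", "C", "H", "H"),
                   g1 = 5L, g2 = 20:28, g3 = 1L),
    C2HC    = list(residues = c("C", "C", "H", "C"),
                   g1 = 4:7, g2 = 20:28, g3 = 1:3),
    FUNGAL  = list(residues = c("C", "C", "H", "C"),
                   g1 = 6L, g2 = 5:30, g3 = 3L)
  )
}

#' Detect zinc-finger motifs downstream of a position
#'
#' Reports, for each pattern class, the maximal match (most chelators,
#' smallest spacing first) at every candidate first-chelator position in
#' `[search_from, search_from + window)`.  A full hit has all four
#' zinc-chelating residues at class-consistent spacing; a partial hit has
#' at least two.
#'
#' @param record One-row tibble (`id`, `residues`) or residue string.
#' @param search_from 0-based index at which the search window starts.
#' @param window Window width (>= 30) within which the finger must start.
#' @param classes Pattern-class definitions; see [zinc_finger_classes()].
#' @return Tibble with columns `protein_id`, `pattern_class`, `start`
#'   (0-based first chelator), `chelator_positions` (list column, 0-based),
#'   `n_chelators`, `last_chelator`, `completeness` (`full`/`partial`).
#' @export
detect_zinc_finger <- function(record, search_from = 0L, window = 60L,
                               classes = zinc_finger_classes()) {
  rec <- one_record(record)
  chars <- strsplit(rec$residues, "", fixed = TRUE)[[1]]
  L <- length(chars)
  if (search_from < 0 || search_from >= L) {
    stop_precondition("search_from outside protein")
  }
  if (window < 30) stop_precondition("window must be >= 30")
  hi <- min(L - 1L, search_from + window - 1L)
  out <- list()
  for (cls in names(classes)) {
    cf <- classes[[cls]]
    r <- cf$residues
    for (p in search_from:hi) {
      if (chars[p + 1] != r[1]) next
      best <- NULL
      for (g1 in cf$g1) {
        c2 <- p + 1L + g1
        if (c2 + 1 > L || chars[c2 + 1] != r[2]) next
        if (is.null(best)) best <- c(p, c2)
        for (g2 in cf$g2) {
          c3 <- c2 + 1L + g2
          if (c3 + 1 > L || chars[c3 + 1] != r[3]) next
          if (length(best) < 3) best <- c(p, c2, c3)
          for (g3 in cf$g3) {
            c4 <- c3 + 1L + g3
            if (c4 + 1 > L || chars[c4 + 1] != r[4]) next
            best <- c(p, c2, c3, c4)
            break
          }
          if (length(best) == 4) break
        }
        if (length(best) == 4) break
      }
      if (!is.null(best) && length(best) >= 2) {
        out[[length(out) + 1]] <- tibble(
          protein_id = rec$id, pattern_class = cls, start = as.integer(p),
          chelator_positions = list(as.integer(best)),
          n_chelators = length(best),
          last_chelator = as.integer(best[length(best)]),
          completeness = if (length(best) == 4) "full" else "partial")
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(protein_id = character(0), pattern_class = character(0),
                  start = integer(0), chelator_positions = list(),
                  n_chelators = integer(0), last_chelator = integer(0),
                  completeness = character(0)))
  }
  bind_rows(out)
}

# Pick the best finger for a signature: full before partial, then leftmost
# start, then the most compact hit (earliest last chelator), then class
# precedence (list order).  Compactness ranks ahead of class precedence so
# that a genuine tight finger is not displaced by a sprawling match of
# another class that happens to share its first chelators.
pick_finger <- function(fingers, classes) {
  prec <- match(fingers$pattern_class, names(classes))
  ord <- order(fingers$completeness != "full", fingers$start,
               fingers$last_chelator, prec, -fingers$n_chelators)
  fingers[ord[1], ]
}

#' Call curated WRKY domains in a protein
#'
#' A domain is called iff a signature hit is followed, within
#' `config$window` residues of its end, by a zinc-finger hit (full or
#' partial).  Signatures lacking any downstream finger are reported as
#' rejected candidates in the `rejected` attribute, for audit, but not as
#' domains.  Domains are ordered N-to-C, indexed from 0, and never
#' overlap.
#'
#' @param record One-row tibble (`id`, `residues`) or residue string.
#' @param config List of options: `max_mismatches` (default 1),
#'   `window` (default 60), `variants`, `classes`.
#' @return Tibble of domains (`protein_id`, `index_in_protein`,
#'   `sig_offset`, `heptapeptide`, `matched_variant`, `mismatches`,
#'   `finger_class`, `completeness`, `chelator_positions`, `span_start`,
#'   `span_end`; spans 0-based half-open), with attribute `rejected`.
#' @export
call_wrky_domains <- function(record, config = list()) {
  rec <- one_record(record)
  max_mm <- config$max_mismatches %||% 1L
  window <- config$window %||% 60L
  variants <- config$variants %||% signature_variants()
  classes <- config$classes %||% zinc_finger_classes()
  sigs <- scan_signatures(record, max_mismatches = max_mm,
                          variants = variants)
  domains <- list()
  rejected <- list()
  last_end <- -1L
  L <- nchar(rec$residues)
  for (k in seq_len(nrow(sigs))) {
    sig <- sigs[k, ]
    if (sig$offset < last_end) next   # would overlap the previous domain
    from <- sig$offset + 7L
    if (from >= L) { rejected[[length(rejected) + 1]] <- sig; next }
    fingers <- detect_zinc_finger(record, search_from = from,
                                  window = window, classes = classes)
    if (nrow(fingers) == 0) {
      rejected[[length(rejected) + 1]] <- sig
      next
    }
    fin <- pick_finger(fingers, classes)
    span_end <- fin$last_chelator + 1L
    domains[[length(domains) + 1]] <- tibble(
      protein_id = rec$id, index_in_protein = length(domains),
      sig_offset = sig$offset, heptapeptide = sig$heptapeptide,
      matched_variant = sig$matched_variant, mismatches = sig$mismatches,
      finger_class = fin$pattern_class, completeness = fin$completeness,
      chelator_positions = fin$chelator_positions,
      span_start = sig$offset, span_end = span_end)
    last_end <- span_end
  }
  out <- if (length(domains)) bind_rows(domains) else
    tibble(protein_id = character(0), index_in_protein = integer(0),
           sig_offset = integer(0), heptapeptide = character(0),
           matched_variant = character(0), mismatches = integer(0),
           finger_class = character(0), completeness = character(0),
           chelator_positions = list(), span_start = integer(0),
           span_end = integer(0))
  attr(out, "rejected") <- if (length(rejected)) bind_rows(rejected) else
    sigs[0, ]
  class(out) <- c("wrky_domains", class(out))
  out
}

#' Scan a whole proteome for WRKY domains
#'
#' Maps [call_wrky_domains()] over a table of sequence records.
#'
#' @param records Tibble from [read_fasta()] (unaligned).
#' @param config See [call_wrky_domains()].
#' @return Tibble of domains across all proteins, with a combined
#'   `rejected` attribute, of class `wrky_domains`.
#' @export
scan_proteome <- function(records, config = list()) {
  per <- purrr::map(seq_len(nrow(records)),
                    function(i) call_wrky_domains(records[i, ], config))
  out <- bind_rows(lapply(per, function(x) { attr(x, "rejected") <- NULL; x }))
  attr(out, "rejected") <- bind_rows(lapply(per, attr, "rejected"))
  class(out) <- c("wrky_domains", class(out))
  out
}

#' Rejected signature candidates from a scan
#' @param x A `wrky_domains` tibble.
#' @return Tibble of signature hits that had no downstream zinc finger.
#' @export
rejected_candidates <- function(x) {
  attr(x, "rejected") %||% tibble()
}
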