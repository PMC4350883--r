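# Group classification of curated WRKY domains.
#
# The rule cascade implements the sequence-level diagnostics: domain
# count, zinc-finger class, signature variant and the IIb motifs
# (QVQR in the finger, DGC just before the signature).  Lineages the
# rules cannot separate (IIa vs IIb; IIc vs IId vs IIe and the algal /
# diplomonad types) are decided by nearest-reference refinement against
# the packaged reference set.

GROUP_LEVELS <- c("I_NT", "I_CT", "IIa", "IIb", "IIc", "IId", "IIe", "III",
                  "III_MOSS_VARIANT", "FUNGAL_TYPE", "ALGAL_SINGLE",
                  "DIPLOMONAD_TYPE", "UNCLASSIFIED")

empty_group_calls <- function() {
  tibble(protein_id = character(0), index_in_protein = integer(0),
         group = character(0), refinable = logical(0), evidence = list(),
         domain_seq = character(0), nearest_reference = character(0),
         nearest_distance = double(0), candidates = list())
}

#' Classify the WRKY domains of one protein by diagnostic rules
#'
#' Rule cascade (domains are re-sorted N-to-C first, so the result is
#' independent of input order):
#' * R1: exactly two C2H2-class domains: first `I_NT`, second `I_CT`.
#' * R2: a single C2HC domain: `III` (`III_MOSS_VARIANT` when the
#'   signature variant is the moss/fungal set).
#' * R3: a single FUNGAL-class finger: `FUNGAL_TYPE`.
#' * R4: a single C2H2_X5 domain with `QVQR` inside the finger (R4a) or
#'   `DGC` within `dgc_window` residues before the signature (R4b):
#'   IIb lineage, reported `IIb`, refinable to `IIa`.
#' * R5: a single C2H2_X4 domain: I/IIc lineage, reported `IIc`,
#'   refinable.
#' Anything else is `UNCLASSIFIED` with the reason in `evidence`.  A
#' `WKKYGHK` signature adds `diplomonad_signature` to the evidence but
#' assigns no group by itself.
#'
#' @param domains `wrky_domains` rows of a single protein.
#' @param residues The protein's residue string (for motif context).
#' @param dgc_window Search window (residues) for the DGC motif before the
#'   signature; default 5.
#' @return A group-call tibble: `protein_id`, `index_in_protein`, `group`,
#'   `refinable`, `evidence` (list), `domain_seq`, `nearest_reference`,
#'   `nearest_distance`, `candidates`.
#' @export
classify_domain_rules <- function(domains, residues, dgc_window = 5L) {
  if (nrow(domains) == 0) stop_precondition("no domains to classify")
  if (length(unique(domains$protein_id)) != 1) {
    stop_precondition("domains must come from a single protein")
  }
  d <- arrange(domains, .data$sig_offset)
  n <- nrow(d)
  seqs <- substring(residues, d$span_start + 1L, d$span_end)
  base <- tibble(protein_id = d$protein_id,
                 index_in_protein = d$index_in_protein,
                 group = NA_character_, refinable = FALSE,
                 evidence = vector("list", n), domain_seq = seqs,
                 nearest_reference = NA_character_,
                 nearest_distance = NA_real_,
                 candidates = vector("list", n))
  note_dip <- function(ev, k) {
    if (d$matched_variant[k] == "WKKYGHK") c(ev, "diplomonad_signature")
    else ev
  }
  if (n == 2 && all(d$finger_class %in% c("C2H2_X4", "C2H2_X5"))) {
    base$group <- c("I_NT", "I_CT")
    base$evidence <- lapply(1:2, function(k) note_dip("R1", k))
    return(base)
  }
  if (n == 1) {
    fc <- d$finger_class[1]
    if (fc == "C2HC") {
      moss <- d$matched_variant[1] %in% c("WKKYGNK", "WKNNGNT")
      base$group <- if (moss) "III_MOSS_VARIANT" else "III"
      base$evidence[[1]] <- note_dip(c("R2", if (moss) "moss_variant_signature"),
                                     1)
      return(base)
    }
    if (fc == "FUNGAL") {
      base$group <- "FUNGAL_TYPE"
      base$evidence[[1]] <- note_dip("R3", 1)
      return(base)
    }
    if (fc == "C2H2_X5") {
      chel <- d$chelator_positions[[1]]
      finger_seq <- substring(residues, chel[1] + 1L,
                              chel[length(chel)] + 1L)
      pre <- substring(residues, max(0L, d$sig_offset[1] - dgc_window) + 1L,
                       d$sig_offset[1])
      ev <- character(0)
      if (grepl("QVQR", finger_seq, fixed = TRUE)) ev <- c(ev, "R4a")
      if (grepl("DGC", pre, fixed = TRUE)) ev <- c(ev, "R4b")
      if (length(ev) > 0) {
        base$group <- "IIb"
        base$refinable <- TRUE
        base$evidence[[1]] <- note_dip(ev, 1)
      } else {
        base$group <- "UNCLASSIFIED"
        base$evidence[[1]] <- note_dip("no_rule:C2H2_X5_without_IIb_motifs", 1)
        base$refinable <- TRUE
      }
      return(base)
    }
    # single C2H2_X4
    base$group <- "IIc"
    base$refinable <- TRUE
    base$evidence[[1]] <- note_dip("R5", 1)
    return(base)
  }
  reason <- if (n == 2) "conflict:two_domains_not_both_C2H2"
            else "unsupported_domain_count"
  base$group <- "UNCLASSIFIED"
  base$evidence <- lapply(seq_len(n), function(k) note_dip(reason, k))
  base
}

# Poisson-corrected distance between a domain and an ungapped reference,
# over aligned non-gap columns.
reference_distance <- function(domain_seq, ref_seq, substitution, gap_open,
                               gap_extend) {
  al <- align_global(domain_seq, ref_seq, substitution, gap_open, gap_extend)
  a <- strsplit(al$aligned_a, "", fixed = TRUE)[[1]]
  b <- strsplit(al$aligned_b, "", fixed = TRUE)[[1]]
  ok <- a != "-" & b != "-" & a != "X" & b != "X"
  if (!any(ok)) return(NA_real_)
  p <- mean(a[ok] != b[ok])
  if (p >= 1) return(Inf)
  -log(1 - p)
}

#' Refine coarse group calls by nearest packaged reference
#'
#' For each refinable call (lineage labels `IIb`, `IIc`, or
#' `UNCLASSIFIED`), the domain is globally aligned to every reference
#' domain, the Poisson-corrected distance is computed over aligned
#' non-gap columns, and the nearest reference's group is assigned.  When
#' the margin between the two nearest references is below `tie_tol` the
#' coarse label is kept and both candidates are recorded.
#'
#' @param calls Group-call tibble from [classify_domain_rules()].
#' @param refs Reference set tibble (`id`, `group`, `residues`); default
#'   [reference_set()].
#' @param tie_tol Absolute tie tolerance on corrected distance.
#' @param substitution,gap_open,gap_extend Alignment scoring; see
#'   [align_global()].
#' @return The calls tibble with `group`, `nearest_reference`,
#'   `nearest_distance`, `candidates` updated.
#' @export
refine_by_reference <- function(calls, refs = reference_set(),
                                tie_tol = 1e-9,
                                substitution = blosum62(),
                                gap_open = -10, gap_extend = -1) {
  if (is.null(refs) || nrow(refs) == 0) {
    stop_precondition("empty reference set")
  }
  for (k in seq_len(nrow(calls))) {
    if (!(calls$refinable[k] || calls$group[k] == "UNCLASSIFIED")) next
    dists <- vapply(seq_len(nrow(refs)), function(j) {
      reference_distance(calls$domain_seq[k], refs$residues[j],
                         substitution, gap_open, gap_extend)
    }, double(1))
    ord <- order(dists)
    best <- ord[1]
    calls$nearest_reference[k] <- refs$id[best]
    calls$nearest_distance[k] <- dists[best]
    if (nrow(refs) > 1 &&
        (dists[ord[2]] - dists[best]) <= tie_tol &&
        refs$group[ord[2]] != refs$group[best]) {
      calls$candidates[[k]] <- refs$group[ord[1:2]]
    } else {
      calls$group[k] <- refs$group[best]
    }
  }
  calls
}

#' Classify all scanned domains of a proteome
#'
#' Applies the rule cascade per protein and (optionally) nearest-reference
#' refinement, returning one call per domain.
#'
#' @param domains `wrky_domains` tibble from [scan_proteome()].
#' @param records Sequence records tibble (`id`, `residues`).
#' @param refine Apply [refine_by_reference()] to refinable calls?
#' @param refs Reference set used when `refine = TRUE`.
#' @param ... Passed to [refine_by_reference()].
#' @return A group-call tibble of class `wrky_groups`.
#' @export
classify_proteome <- function(domains, records, refine = TRUE,
                              refs = reference_set(), ...) {
  if (nrow(domains) == 0) return(structure(empty_group_calls(),
                                           class = c("wrky_groups",
                                                     class(tibble()))))
  res_of <- setNames(records$residues, records$id)
  calls <- domains |>
    group_by(.data$protein_id) |>
    dplyr::group_map(function(d, key) {
      d$protein_id <- key$protein_id
      classify_domain_rules(d, res_of[[key$protein_id]])
    }) |>
    bind_rows()
  if (refine) calls <- refine_by_reference(calls, refs, ...)
  class(calls) <- c("wrky_groups", class(calls))
  calls
}

#' Consensus sequence of an alignment
#'
#' Per column, the most frequent residue is emitted when its frequency
#' (gaps excluded from the numerator but included in the denominator)
#' reaches `threshold`; ties at the top and below-threshold columns give
#' `x`; all-gap columns give `-`.
#'
#' @param alignment Tibble of aligned records (`id`, `residues`) or a
#'   character vector of equal-length gapped rows.
#' @param threshold Consensus threshold in `[0.5, 1]`.
#' @return The consensus residue string.
#' @export
consensus_sequence <- function(alignment, threshold = 0.5) {
  rows <- if (is.character(alignment)) alignment else alignment$residues
  if (length(rows) < 2) stop_precondition("need >= 2 aligned rows")
  if (threshold < 0.5 || threshold > 1) {
    stop_precondition("threshold must be in [0.5, 1]")
  }
  m <- residue_matrix(rows)
  cols <- apply(m, 2, function(col) {
    res <- col[col != "-"]
    if (length(res) == 0) return("-")
    tab <- sort(table(res), decreasing = TRUE)
    freq <- tab[1] / length(col)
    if (freq < threshold) return("x")
    if (length(tab) > 1 && tab[2] == tab[1]) return("x")
    names(tab)[1]
  })
  paste(cols, collapse = "")
}
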