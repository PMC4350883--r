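# Intron mapping and typing.
#
# Introns are located on the protein by cumulative coding bases in
# transcription order: after c bases, an intron falls after residue
# floor(c / 3) with phase c mod 3.  A PR-type intron interrupts at the
# conserved P-R dipeptide between the signature block and the zinc
# finger; a VQR-type intron interrupts at the final R of a V-Q-R /
# Q-V-Q-R match inside the finger.

#' Map a gene model's introns onto protein coordinates
#'
#' @param model One row of the tibble returned by [read_gff3()] (or a
#'   compatible one-row tibble with `gene_id`, `strand`, `protein_id`,
#'   and a `cds` list column of 1-based inclusive segments).
#' @return A tibble with one row per intron in transcription order:
#'   `gene_id`, `protein_id`, `genomic_start`, `genomic_end` (1-based
#'   inclusive), `protein_position` (1-based residue after which the
#'   intron falls), `phase` (0-2).  Empty for single-segment models.
#' @export
protein_coordinates_of_introns <- function(model) {
  seg <- arrange(model$cds[[1]], .data$start)
  k <- nrow(seg)
  empty <- tibble(gene_id = character(0), protein_id = character(0),
                  genomic_start = integer(0), genomic_end = integer(0),
                  protein_position = integer(0), phase = integer(0))
  if (k < 2) return(empty)
  strand <- model$strand
  if (!strand %in% c("+", "-")) stop_precondition("strand must be + or -")
  lens <- seg$end - seg$start + 1L
  order_tx <- if (strand == "+") seq_len(k) else rev(seq_len(k))
  cum <- cumsum(lens[order_tx])
  purrr::map_dfr(seq_len(k - 1), function(i) {
    # Gap after the i-th segment in transcription order, in genomic coords.
    a <- order_tx[i]; b <- order_tx[i + 1]
    lo <- min(a, b); hi <- max(a, b)
    tibble(gene_id = model$gene_id, protein_id = model$protein_id,
           genomic_start = seg$end[lo] + 1L, genomic_end = seg$start[hi] - 1L,
           protein_position = as.integer(cum[i] %/% 3L),
           phase = as.integer(cum[i] %% 3L))
  })
}

#' Map introns for a whole set of gene models
#' @param models Tibble from [read_gff3()].
#' @return Combined intron tibble; see [protein_coordinates_of_introns()].
#' @export
introns_from_models <- function(models) {
  purrr::map_dfr(seq_len(nrow(models)),
                 function(i) protein_coordinates_of_introns(models[i, ]))
}

#' Type one intron relative to one WRKY domain
#'
#' `PR` when the intron interrupts within `anchor_halfwidth` codons of the
#' R of the P-R dipeptide located between the signature end and the first
#' chelator (nearest the finger when several occur); `VQR` when within
#' `anchor_halfwidth` codons of the final R of a `VQR`/`QVQR` match inside
#' the finger (first to last chelator); otherwise `OTHER` inside the
#' domain span +/- `flank` residues, else `NONE`.
#'
#' @param intron One intron row (see [protein_coordinates_of_introns()]).
#' @param domain One `wrky_domains` row from the same protein.
#' @param residues The protein residue string.
#' @param anchor_halfwidth Codon half-window around an anchor; default 2.
#' @param flank Flank (residues) around the domain span for `OTHER`.
#' @return The intron row extended with `type`, `anchor_motif`,
#'   `anchor_offset` (anchor position relative to the signature start).
#' @export
type_intron <- function(intron, domain, residues, anchor_halfwidth = 2L,
                        flank = 10L) {
  if (!is.na(intron$protein_id) && !is.na(domain$protein_id) &&
      intron$protein_id != domain$protein_id) {
    stop_precondition("intron and domain come from different proteins")
  }
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  chel <- domain$chelator_positions[[1]]
  c1 <- chel[1]; clast <- chel[length(chel)]
  sig_end <- domain$sig_offset + 7L
  pp <- intron$protein_position
  out <- intron
  out$type <- "NONE"; out$anchor_motif <- NA_character_
  out$anchor_offset <- NA_integer_

  # PR anchor: P-R dipeptides in the linker, nearest the first chelator.
  pr_pos <- which(chars == "P" & dplyr::lead(chars, default = "") == "R") - 1L
  pr_pos <- pr_pos[pr_pos >= sig_end & (pr_pos + 1L) < c1]
  if (length(pr_pos) > 0) {
    a <- max(pr_pos) + 1L          # 0-based index of the R
    if (abs(pp - (a + 1L)) <= anchor_halfwidth) {
      out$type <- "PR"; out$anchor_motif <- "PR"
      out$anchor_offset <- a - domain$sig_offset
      return(out)
    }
  }
  # VQR anchor: final R of VQR / QVQR inside the finger region.
  finger <- substring(residues, c1 + 1L, clast + 1L)
  m <- gregexpr("QVQR|VQR", finger)[[1]]
  if (m[1] != -1) {
    ends <- as.integer(m) + attr(m, "match.length") - 1L   # 1-based in finger
    rs <- c1 + ends - 1L                                   # 0-based absolute
    for (a in rs) {
      if (abs(pp - (a + 1L)) <= anchor_halfwidth) {
        out$type <- "VQR"; out$anchor_motif <- "VQR"
        out$anchor_offset <- a - domain$sig_offset
        return(out)
      }
    }
  }
  inside <- pp > (domain$span_start - flank) &&
    pp <= (domain$span_end + flank)
  if (inside) out$type <- "OTHER"
  out
}

#' Type all introns of a proteome against its scanned domains
#'
#' Each intron is typed against the enclosing (or nearest) WRKY domain of
#' its protein; introns of proteins without domains are `NONE`.
#'
#' @param introns Intron tibble from [introns_from_models()].
#' @param domains `wrky_domains` tibble from [scan_proteome()].
#' @param records Sequence records (`id`, `residues`).
#' @param ... Passed to [type_intron()].
#' @return Intron tibble extended with `type`, `anchor_motif`,
#'   `anchor_offset`, of class `wrky_introns`.
#' @export
type_proteome_introns <- function(introns, domains, records, ...) {
  res_of <- setNames(records$residues, records$id)
  out <- purrr::map_dfr(seq_len(nrow(introns)), function(i) {
    intr <- introns[i, ]
    dom <- domains[domains$protein_id == intr$protein_id, ]
    if (nrow(dom) == 0) {
      intr$type <- "NONE"; intr$anchor_motif <- NA_character_
      intr$anchor_offset <- NA_integer_
      return(intr)
    }
    # nearest domain by residue distance to the span
    dist <- pmax(dom$span_start + 1L - intr$protein_position,
                 intr$protein_position - dom$span_end, 0L)
    type_intron(intr, dom[which.min(dist), ],
                res_of[[intr$protein_id]], ...)
  })
  class(out) <- c("wrky_introns", class(out))
  out
}
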