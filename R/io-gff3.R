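# Gene models from GFF3.
#
# Coordinate convention: GFF3 is 1-based inclusive on disk and gene-model
# segments are kept 1-based inclusive in the returned tibble (genomic
# coordinates); protein-level coordinates elsewhere in the package are
# 0-based half-open, converted only at this boundary.

#' Read gene models (CDS structure) from a GFF3 file
#'
#' One gene model is built per mRNA (per distinct CDS `Parent`).  CDS
#' segments are stored in ascending genomic order regardless of strand;
#' the strand is recorded so downstream code can process minus-strand
#' models in transcription order.
#'
#' @param path Path to a GFF3 file with CDS features carrying `Parent`
#'   (and optionally `protein_id`) attributes.
#' @return A tibble with one row per model: `gene_id`, `seq_id`, `strand`,
#'   `protein_id`, `cds` (list column of tibbles with `start`, `end`),
#'   `cds_length`, and `incomplete` (`TRUE` when the total CDS length is
#'   not divisible by 3).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop_precondition(paste0("no such file: ", path))
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop_format(conditionMessage(e)))
  cds <- gr[!is.na(gr$type) & gr$type == "CDS"]
  if (length(cds) == 0) stop_empty("no CDS features in GFF3")
  parents <- gr$Parent[!is.na(gr$type) & gr$type == "CDS"]
  n_par <- lengths(parents)
  if (any(n_par == 0)) stop_format("CDS feature without a Parent attribute")
  parent <- vapply(parents, function(p) p[[1]], character(1))
  prot <- if ("protein_id" %in% names(S4Vectors::mcols(cds))) {
    ifelse(is.na(cds$protein_id), parent, cds$protein_id)
  } else parent
  df <- tibble(
    gene_id = parent,
    seq_id = as.character(GenomicRanges::seqnames(cds)),
    strand = as.character(GenomicRanges::strand(cds)),
    protein_id = prot,
    start = GenomicRanges::start(cds),
    end = GenomicRanges::end(cds)
  )
  df |>
    group_by(.data$gene_id) |>
    dplyr::group_modify(function(d, key) {
      if (length(unique(d$strand)) != 1) {
        stop_format(paste0("mixed strands within model ", key$gene_id))
      }
      if (length(unique(d$seq_id)) != 1) {
        stop_format(paste0("multiple sequences within model ", key$gene_id))
      }
      d <- arrange(d, .data$start)
      if (any(d$start > d$end)) stop_format("CDS with start > end")
      if (nrow(d) > 1 && any(d$start[-1] <= d$end[-nrow(d)])) {
        stop_format(paste0("overlapping CDS segments in model ", key$gene_id))
      }
      len <- sum(d$end - d$start + 1)
      tibble(seq_id = d$seq_id[1], strand = d$strand[1],
             protein_id = d$protein_id[1],
             cds = list(tibble(start = d$start, end = d$end)),
             cds_length = len, incomplete = (len %% 3L != 0L))
    }) |>
    ungroup()
}

#' Implied introns of a gene model, in genomic coordinates
#'
#' @param model One row of the tibble returned by [read_gff3()].
#' @return Tibble of 1-based inclusive intron spans (ascending), empty for
#'   single-segment models.
#' @export
genomic_introns <- function(model) {
  seg <- model$cds[[1]]
  if (nrow(seg) < 2) return(tibble(start = integer(0), end = integer(0)))
  tibble(start = seg$end[-nrow(seg)] + 1L, end = seg$start[-1] - 1L)
}
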