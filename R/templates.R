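# Designed WRKY group templates.
#
# These 60-residue domain templates are synthetic: they are designed to
# satisfy the published diagnostic rules for each evolutionary group
# (signature heptapeptide variant, zinc-finger chelator spacing, the IIb
# QVQR/DGC motifs, and the PR / VQR intron anchor positions), not
# transcribed from any real protein.  They serve two roles: as the packaged
# reference set for nearest-reference group refinement, and as the seeds
# from which the synthetic-data generator plants domains.
#
# All templates share one coordinate frame (0-based):
#   0..4    N-flank (IIb carries DGC at 2..4)
#   5..11   signature heptapeptide
#   12..29  linker (PR-lineage groups end it with the P-R intron anchor
#           at 28..29)
#   30..    zinc finger; chelator positions depend on the finger class.
# Sharing the frame means sets of templates are mutually "aligned" without
# an aligner, which keeps the distance-based machinery testable.

#' Signature heptapeptide variant library
#'
#' The default library of WRKY signature variants, canonical variant first:
#' `WRKYGQK` (plants), `WKNNGNT` (fungal type), `WKKYGNK` (moss Group III
#' variant), `WKKYGHK` (diplomonad C-terminal type).
#'
#' @return Character vector of 7-residue signature variants.
#' @export
signature_variants <- function() {
  c("WRKYGQK", "WKNNGNT", "WKKYGNK", "WKKYGHK")
}

# One row per group: template residues plus planted feature coordinates.
template_table <- function() {
  x4 <- function(flank, sig, linker16, f1, f2, f3, pad, pr = TRUE) {
    lnk <- if (pr) paste0(linker16, "PR") else linker16
    list(residues = paste0(flank, sig, lnk, "C", f1, "C", f2, "H", f3, "H", pad),
         finger_class = "C2H2_X4", chelators = c(30L, 35L, 56L, 58L))
  }
  rows <- list(
    I_NT = c(x4("MSSTG", "WRKYGQK", "EVKNSPNALSVLTTSEGQ",
                "SVRK", "AERGLDNPKAVITTFEGKHS", "T", "N", pr = FALSE),
             sig = "WRKYGQK", pr_anchor = NA_integer_),
    I_CT = c(x4("GSSVD", "WRKYGQK", "EVKNSENQLAVITTYE",
                "TVRK", "VERGLDDPKSVITTYEGKHN", "T", "Q"),
             sig = "WRKYGQK", pr_anchor = 30L),
    IIc = c(x4("GASVD", "WRKYGQK", "EVKTSDSQLAVMTTYE",
               "TVRK", "IERGLDEPKSVITTYAGKHN", "T", "Q"),
            sig = "WRKYGQK", pr_anchor = 30L),
    IId = c(x4("AKRAG", "WRKYGQK", "DILDDGYRGNKYAQHK",
               "SVYK", "MRRGNPNPRSVVKTTSEDPS", "S", "E"),
            sig = "WRKYGQK", pr_anchor = 30L),
    IIe = c(x4("TENLE", "WRKYGQK", "APLNDGYAGNKSAQEQ",
               "PVKR", "LQRGSEEPTMLITTYLGSHT", "N", "D"),
            sig = "WRKYGQK", pr_anchor = 30L),
    ALGAL_SINGLE = c(x4("MALGT", "WRKYGQK", "SGNEVADILNRSEDGYKV",
                        "ANRK", "QDNSLPRAVITTSAGEHQTE", "G", "A", pr = FALSE),
                     sig = "WRKYGQK", pr_anchor = NA_integer_),
    DIPLOMONAD_TYPE = c(x4("MEDLG", "WKKYGHK", "TGNEVADMLNKTEDGYRV",
                           "GNRK", "QENSLVRAVITTSAGDHQTE", "G", "S",
                           pr = FALSE),
                        sig = "WKKYGHK", pr_anchor = NA_integer_)
  )
  # Group IIa/IIb: C-X5-C finger, QVQR in the middle of the finger,
  # IIb additionally DGC immediately before the signature.
  x5 <- function(flank, linker18, f1, f2, f3) {
    list(residues = paste0(flank, "WRKYGQK", linker18, "C", f1, "C", f2,
                           "H", f3, "H"),
         finger_class = "C2H2_X5", chelators = c(30L, 36L, 57L, 59L),
         sig = "WRKYGQK", pr_anchor = NA_integer_)
  }
  rows$IIa <- x5("DSSAQ", "SDDGSLVAVKGNEHPKYE",
                 "AEPKV", "GSEDNSAQVQRKGVQGSTHE", "L")
  rows$IIb <- x5("KQDGC", "SDEGSLVAVKANEHPKYD",
                 "AEPRV", "GSEDNTAQVQRKGVQGSAHE", "L")
  # Group III: C2HC finger (C-C-H-C).
  chc <- function(flank, sig, linker16, f1, f2, f3, pad) {
    list(residues = paste0(flank, sig, linker16, "PR", "C", f1, "C", f2,
                           "H", f3, "C", pad),
         finger_class = "C2HC", chelators = c(30L, 35L, 56L, 58L),
         sig = sig, pr_anchor = 30L)
  }
  rows$III <- chc("RDGFA", "WRKYGQK", "QTQVDHLEDDGYRVKL",
                  "GVRK", "PVKRSPRAVVSTLEEDGSVQ", "V", "K")
  rows$III_MOSS_VARIANT <- chc("RDSFA", "WKKYGNK", "QTQVDHLEDDGYRVKL",
                               "GVRK", "PVKRSPRAVVSTLEEDGSIQ", "I", "K")
  # Fungal type: WKNNGNT signature, C-X6-C-H-X3-C finger.
  rows$FUNGAL_TYPE <- list(
    residues = paste0("MSQLE", "WKNNGNT", "QTSVDHLEDNGYKVKLSE",
                      "C", "SAGRKV", "C", "IRGSEYQRGPVKTT", "H", "NSV",
                      "C", "AGT"),
    finger_class = "FUNGAL", chelators = c(30L, 37L, 52L, 56L),
    sig = "WKNNGNT", pr_anchor = NA_integer_)

  purrr::imap_dfr(rows, function(r, g) {
    tibble(group = g, residues = r$residues, finger_class = r$finger_class,
           chelators = list(r$chelators), signature_variant = r$sig,
           sig_offset = 5L,
           pr_anchor = r$pr_anchor %||% NA_integer_,
           vqr_anchor = if (g %in% c("IIa", "IIb")) 48L else NA_integer_)
  })
}

#' WRKY group domain templates
#'
#' Sixty-residue synthetic domain templates, one per evolutionary group,
#' designed to satisfy the group-diagnostic rules (see the package
#' vignette).  Coordinates are 0-based within the template: the signature
#' starts at 5; `pr_anchor`/`vqr_anchor` give the 1-based protein position
#' after which a PR- or VQR-type intron falls when planted.
#'
#' @return A tibble with columns `group`, `residues`, `finger_class`,
#'   `chelators` (list of 0-based positions), `signature_variant`,
#'   `sig_offset`, `pr_anchor`, `vqr_anchor`.
#' @export
wrky_group_templates <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- template_table()
    val
  }
})

# Positions that mutation must never touch: signature window, chelators,
# DGC/QVQR diagnostics and the PR/VQR anchor codons (0-based indices).
template_frozen_positions <- function(group) {
  tpl <- wrky_group_templates()
  r <- tpl[tpl$group == group, ]
  frozen <- c(5:11, r$chelators[[1]])
  if (group == "IIb") frozen <- c(frozen, 2:4)
  if (group %in% c("IIa", "IIb")) frozen <- c(frozen, 44:47)
  if (!is.na(r$pr_anchor)) frozen <- c(frozen, 28:29)
  sort(unique(frozen))
}

#' Packaged reference set of group-labelled WRKY domains
#'
#' The synthetic reference domains used by [refine_by_reference()].  All
#' rows share one 60-column coordinate frame and are therefore returned as
#' an aligned set.
#'
#' @return A tibble with columns `id`, `group`, `residues`.
#' @export
reference_set <- function() {
  tpl <- wrky_group_templates()
  tibble(id = paste0("synthref_", tpl$group), group = tpl$group,
         residues = tpl$residues)
}
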