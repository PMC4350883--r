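# Seeded synthetic data with machine-readable truth tables.
#
# The generator plants group-template domains (see templates.R) inside
# random linkers, emits gene models with introns at the PR/VQR anchor
# codons, and realizes RW architecture witnesses, so that every pipeline
# stage can be tested against known truth without any downloads.
#
# Design constraints baked in:
# * linkers draw from the 19 residues excluding W, so no accidental
#   signature windows arise (all signature variants start with W);
# * point mutations touch only non-diagnostic template positions and
#   substitute from residues excluding W, C and H, so neither decoy
#   signatures nor decoy zinc-chelators are created;
# * everything is deterministic under (spec, seed).

LINKER_ALPHABET <- setdiff(AA_ALPHABET[1:20], "W")
MUTATION_ALPHABET <- setdiff(AA_ALPHABET[1:20], c("W", "C", "H"))

#' Build a synthetic-data specification
#'
#' @param group_counts Named counts of proteins per group.  Group `I`
#'   produces two-domain proteins (I_NT + I_CT); every other name must
#'   match a template group.
#' @param mutation_rate Per-residue substitution probability outside
#'   diagnostic positions, in `[0, 0.2]`.
#' @param linker_length_range Min/max length of the random linkers.
#' @param intron_plan Named counts of gene models per planted intron type
#'   (`PR`, `VQR`, `OTHER`, `NONE`).
#' @param rw_plan Named counts per RW family (`RW1`..`RW8`) and decoys
#'   (`decoy_NLR`, `decoy_WRKY`).
#' @param n_decoys Proteins without any signature added to the proteome.
#' @param seed Integer seed.
#' @return A `wrky_synth_spec` list.
#' @export
synth_spec <- function(group_counts = c(I = 10, IIa = 10, IIb = 10,
                                        IIc = 10, IId = 10, IIe = 10,
                                        III = 10, FUNGAL_TYPE = 10),
                       mutation_rate = 0.05,
                       linker_length_range = c(20L, 80L),
                       intron_plan = c(PR = 50, VQR = 50, OTHER = 20,
                                       NONE = 20),
                       rw_plan = c(RW1 = 1, RW2 = 1, RW3 = 1, RW4 = 1,
                                   RW5 = 1, RW6 = 1, RW7 = 1, RW8 = 1,
                                   decoy_NLR = 2, decoy_WRKY = 2),
                       n_decoys = 10L, seed = 1L) {
  if (any(group_counts < 0) || any(intron_plan < 0) || any(rw_plan < 0)) {
    stop_precondition("counts must be >= 0")
  }
  if (mutation_rate < 0 || mutation_rate > 0.2) {
    stop_precondition("mutation_rate must be in [0, 0.2]")
  }
  known <- c("I", wrky_group_templates()$group)
  bad <- setdiff(names(group_counts), known)
  if (length(bad) > 0) {
    stop_precondition(sprintf("unknown groups: %s", paste(bad, collapse = ", ")))
  }
  structure(list(group_counts = group_counts,
                 mutation_rate = mutation_rate,
                 linker_length_range = as.integer(linker_length_range),
                 intron_plan = intron_plan, rw_plan = rw_plan,
                 n_decoys = as.integer(n_decoys), seed = as.integer(seed)),
            class = "wrky_synth_spec")
}

random_linker <- function(len) {
  paste(sample(LINKER_ALPHABET, len, replace = TRUE), collapse = "")
}

# Mutate a template at non-diagnostic positions only.
mutate_template <- function(residues, frozen, rate) {
  if (rate == 0) return(residues)
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  free <- setdiff(seq_along(chars) - 1L, frozen)
  hit <- free[stats::runif(length(free)) < rate]
  for (i in hit) {
    repl <- sample(setdiff(MUTATION_ALPHABET, chars[i + 1]), 1)
    chars[i + 1] <- repl
  }
  paste(chars, collapse = "")
}

planted_domain <- function(group, rate) {
  tpl <- wrky_group_templates()
  r <- tpl[tpl$group == group, ]
  list(residues = mutate_template(r$residues,
                                  template_frozen_positions(group), rate),
       info = r)
}

#' Generate a synthetic proteome with planted WRKY domains
#'
#' @param spec A [synth_spec()].
#' @return A list with `records` (tibble `id`, `description`, `residues`)
#'   and `truth` (one row per planted domain: `protein_id`, `group`,
#'   `domain_index`, `span_start`, `span_end` (0-based half-open,
#'   signature start to last chelator + 1), `sig_offset`, `finger_class`,
#'   `chelators` list, `pr_anchor`, `vqr_anchor` (1-based protein
#'   positions or `NA`), `template_offset`).
#' @export
generate_proteome <- function(spec) {
  set.seed(spec$seed)
  lo <- spec$linker_length_range[1]; hi <- spec$linker_length_range[2]
  records <- list(); truth <- list()
  emit <- function(id, desc, residues) {
    records[[length(records) + 1]] <<- tibble(id = id, description = desc,
                                              residues = residues)
  }
  truth_row <- function(id, off, dom, index) {
    info <- dom$info
    chel <- info$chelators[[1]] + off
    truth[[length(truth) + 1]] <<- tibble(
      protein_id = id, group = info$group, domain_index = index,
      span_start = off + info$sig_offset,
      span_end = off + max(info$chelators[[1]]) + 1L,
      sig_offset = off + info$sig_offset,
      finger_class = info$finger_class, chelators = list(chel),
      pr_anchor = if (is.na(info$pr_anchor)) NA_integer_ else
        off + info$pr_anchor,
      vqr_anchor = if (is.na(info$vqr_anchor)) NA_integer_ else
        off + info$vqr_anchor,
      template_offset = off)
  }
  for (g in names(spec$group_counts)) {
    for (i in seq_len(spec$group_counts[[g]])) {
      id <- sprintf("%s_%03d", gsub("[^A-Za-z0-9]", "", tolower(g)), i)
      lead <- random_linker(sample(lo:hi, 1))
      if (g == "I") {
        nt <- planted_domain("I_NT", spec$mutation_rate)
        ct <- planted_domain("I_CT", spec$mutation_rate)
        mid <- random_linker(sample(lo:hi, 1))
        trail <- random_linker(sample(lo:hi, 1))
        off_nt <- nchar(lead)
        off_ct <- off_nt + nchar(nt$residues) + nchar(mid)
        emit(id, "synthetic two-domain (Group I) protein",
             paste0(lead, nt$residues, mid, ct$residues, trail))
        truth_row(id, off_nt, nt, 0L)
        truth_row(id, off_ct, ct, 1L)
      } else {
        dom <- planted_domain(g, spec$mutation_rate)
        trail <- random_linker(sample(lo:hi, 1))
        off <- nchar(lead)
        emit(id, sprintf("synthetic %s protein", g),
             paste0(lead, dom$residues, trail))
        truth_row(id, off, dom, 0L)
      }
    }
  }
  for (i in seq_len(spec$n_decoys)) {
    emit(sprintf("decoy_%03d", i), "synthetic decoy (no signature)",
         random_linker(sample((2 * lo):(2 * hi), 1)))
  }
  list(records = bind_rows(records),
       truth = if (length(truth)) bind_rows(truth) else tibble())
}

# Fixed reverse-translation codon table (one codon per residue).
CODON_OF <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
              Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
              K = "AAA", L = "CTT", M = "ATG", F = "TTT", P = "CCT",
              S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

reverse_translate <- function(residues) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  paste0(paste(CODON_OF[chars], collapse = ""), "TAA")
}

revcomp <- function(nt) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(nt, "", fixed = TRUE)[[1]]), collapse = ""))
}

random_nt <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Generate genomes and gene models with planted introns
#'
#' Each selected protein is reverse-translated with a fixed codon table
#' and gets one intron (GT...AG body, length 60-300) inserted so that the
#' interruption falls exactly at the planned anchor residue and phase;
#' every second model is emitted on the minus strand with mirrored
#' coordinates.  The intron plan draws `PR` models from PR-lineage
#' proteins, `VQR` from IIa/IIb proteins, `OTHER`/`NONE` from any
#' domain-bearing protein.
#'
#' @param proteome Result of [generate_proteome()].
#' @param spec The same [synth_spec()].
#' @return A list with `genome` (tibble `id`, `residues` of nucleotide
#'   contigs), `models` (tibble in the [read_gff3()] schema), and
#'   `truth` (tibble `gene_id`, `protein_id`, `type`, `protein_position`,
#'   `phase`, `strand`).
#' @export
generate_gene_models <- function(proteome, spec) {
  set.seed(spec$seed + 1L)
  tr <- proteome$truth
  res_of <- setNames(proteome$records$residues, proteome$records$id)
  pr_ids <- unique(tr$protein_id[!is.na(tr$pr_anchor)])
  vqr_ids <- unique(tr$protein_id[!is.na(tr$vqr_anchor)])
  any_ids <- unique(tr$protein_id)
  plan <- spec$intron_plan
  take <- function(pool, n, used) utils::head(setdiff(pool, used), n)
  used <- character(0)
  sel <- list()
  for (ty in c("PR", "VQR", "OTHER", "NONE")) {
    pool <- switch(ty, PR = pr_ids, VQR = vqr_ids, any_ids)
    ids <- take(pool, plan[[ty]] %||% 0, used)
    used <- c(used, ids)
    if (length(ids) > 0) sel[[ty]] <- ids
  }
  genome <- list(); models <- list(); truth <- list()
  idx <- 0L
  for (ty in names(sel)) {
    for (pid in sel[[ty]]) {
      idx <- idx + 1L
      prot <- res_of[[pid]]
      cand <- tr[tr$protein_id == pid, ]
      drow <- switch(ty,
        PR = cand[!is.na(cand$pr_anchor), ][1, ],
        VQR = cand[!is.na(cand$vqr_anchor), ][1, ],
        cand[1, ])
      pos_phase <- switch(ty,
        PR = c(drow$pr_anchor, 0L),
        VQR = c(drow$vqr_anchor, 0L),
        OTHER = c(drow$span_end - 5L, idx %% 3L),
        NONE = c(max(1L, drow$span_start - 15L), 0L))
      pp <- as.integer(pos_phase[1]); phase <- as.integer(pos_phase[2])
      cds <- reverse_translate(prot)
      cut <- 3L * pp + phase
      ilen <- sample(60:300, 1)
      intron <- paste0("GT", random_nt(ilen - 4L), "AG")
      pad_l <- random_nt(sample(50:150, 1))
      pad_r <- random_nt(sample(50:150, 1))
      contig_plus <- paste0(pad_l, substr(cds, 1, cut), intron,
                            substr(cds, cut + 1, nchar(cds)), pad_r)
      e1 <- c(nchar(pad_l) + 1L, nchar(pad_l) + cut)
      e2 <- c(nchar(pad_l) + cut + nchar(intron) + 1L,
              nchar(pad_l) + cut + nchar(intron) + (nchar(cds) - cut))
      minus <- (idx %% 2L == 0L)
      gid <- paste0("gene_", pid)
      cid <- paste0("ctg_", pid)
      if (minus) {
        Lc <- nchar(contig_plus)
        contig <- revcomp(contig_plus)
        seg <- tibble(start = c(Lc - e2[2] + 1L, Lc - e1[2] + 1L),
                      end = c(Lc - e2[1] + 1L, Lc - e1[1] + 1L))
        strand <- "-"
      } else {
        contig <- contig_plus
        seg <- tibble(start = c(e1[1], e2[1]), end = c(e1[2], e2[2]))
        strand <- "+"
      }
      genome[[length(genome) + 1]] <- tibble(id = cid, description = "",
                                             residues = contig)
      cds_len <- nchar(cds)
      models[[length(models) + 1]] <- tibble(
        gene_id = gid, seq_id = cid, strand = strand, protein_id = pid,
        cds = list(arrange(seg, start)),
        cds_length = cds_len, incomplete = FALSE)
      truth[[length(truth) + 1]] <- tibble(
        gene_id = gid, protein_id = pid, type = ty,
        protein_position = pp, phase = phase, strand = strand)
    }
  }
  list(genome = bind_rows(genome), models = bind_rows(models),
       truth = bind_rows(truth))
}

#' Write gene models as a GFF3 file
#'
#' @param models Tibble in the [read_gff3()] schema.
#' @param path Output path (UTF-8, LF).
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    seg <- arrange(m$cds[[1]], .data$start)
    tx <- if (m$strand == "-") rev(seq_len(nrow(seg))) else seq_len(nrow(seg))
    lens <- seg$end - seg$start + 1L
    cum_before <- cumsum(c(0L, lens[tx]))[seq_len(nrow(seg))]
    phase_tx <- (3L - cum_before %% 3L) %% 3L
    phase <- integer(nrow(seg)); phase[tx] <- phase_tx
    lines <- c(lines,
      sprintf("%s\twrkyr\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;protein_id=%s",
              m$seq_id, min(seg$start), max(seg$end), m$strand, m$gene_id,
              m$protein_id),
      sprintf("%s\twrkyr\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s;protein_id=%s",
              m$seq_id, seg$start, seg$end, m$strand, phase, m$gene_id,
              m$protein_id))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Splice a gene model out of its contig
#'
#' Utility used by tests and the pipeline: extracts and joins the CDS
#' segments in transcription order (reverse complemented on the minus
#' strand).
#'
#' @param model One gene-model row.
#' @param genome Genome tibble (`id`, `residues`).
#' @return The coding nucleotide sequence.
#' @export
splice_cds <- function(model, genome) {
  contig <- genome$residues[genome$id == model$seq_id]
  if (length(contig) != 1) stop_precondition("contig not found")
  seg <- arrange(model$cds[[1]], .data$start)
  parts <- substring(contig, seg$start, seg$end)
  cds <- paste(parts, collapse = "")
  if (model$strand == "-") cds <- revcomp(cds)
  cds
}

rw_species_hint <- c(RW1 = "Arabidopsis thaliana", RW2 = "Fragaria vesca",
                     RW3 = "Arabidopsis thaliana", RW4 = "Glycine max",
                     RW5 = "Oryza sativa", RW6 = "Hordeum vulgare",
                     RW7 = "Gossypium raimondii", RW8 = "Theobroma cacao")

# Canonical witness token lists per family; optional tokens are listed
# with `opt = TRUE` and kept or dropped by a seeded coin.
rw_witness_tokens <- function(family, coin) {
  t <- function(tok, group = NA_character_, opt = FALSE) {
    tibble(token = tok, group = group, optional = opt)
  }
  w <- switch(family,
    RW1 = bind_rows(t("TIR"), t("NB-ARC"), t("LRR"), t("WRKY", "IIe")),
    RW2 = bind_rows(t("TIR"), t("NB-ARC"), t("LRR"), t("WRKY", "III"),
                    t("WRKY", "III", opt = TRUE)),
    RW3 = bind_rows(t("PAH"), t("WRKY", "I_NT"), t("WRKY", "I_CT"),
                    t("NB-ARC"), t("MAPKKK", opt = TRUE)),
    RW4 = bind_rows(t("TIR"), t("NB-ARC"), t("LRR"), t("WRKY", "III")),
    RW5 = bind_rows(t("B3", opt = TRUE), t("LRR"), t("NB-ARC"), t("LRR"),
                    t("WRKY", "IIe")),
    RW6 = bind_rows(t("NB-ARC"), t("LRR"), t("WRKY", "III"),
                    t("WRKY", "III", opt = TRUE), t("NAC", opt = TRUE)),
    RW7 = bind_rows(t("LRR"), t("WRKY", "III"), t("WRKY", "IId"),
                    t("CAMB"), t("WRKY", "IIc")),
    RW8 = bind_rows(t("WRKY", "III"), t("NB-ARC"), t("LRR")),
    decoy_NLR = bind_rows(t("TIR"), t("NB-ARC"), t("LRR")),
    decoy_WRKY = bind_rows(t("WRKY", "IIc")))
  keep <- !w$optional | (stats::runif(nrow(w)) < coin)
  w[keep, c("token", "group")]
}

# Raw annotation names emitted for each token, exercising the shipped
# label-mapping table.
RAW_NAME_OF <- c(TIR = "TIR", `NB-ARC` = "NB-ARC", LRR = "LRR_4", B3 = "B3",
                 NAC = "NAM", CAMB = "CaM_binding", MAPKKK = "Pkinase",
                 PAH = "PAH", WRKY = "WRKY")

#' Generate domain-annotation rows realizing RW architecture witnesses
#'
#' For each requested family, one witness of the grammar is emitted
#' (bracketed optional tokens toggled by a seeded coin); decoys realize
#' NLR-only and WRKY-only proteins.
#'
#' @param spec A [synth_spec()] (`rw_plan` and `seed` are used).
#' @return A list with `rows` (domain-annotation tibble), `calls`
#'   (matching WRKY group calls), and `truth` (tibble `protein_id`,
#'   `family`, `lineage_hint`).
#' @export
generate_rw_table <- function(spec) {
  set.seed(spec$seed + 2L)
  rows <- list(); calls <- list(); truth <- list()
  for (family in names(spec$rw_plan)) {
    for (i in seq_len(spec$rw_plan[[family]])) {
      pid <- sprintf("%s_%02d", tolower(gsub("_", "", family)), i)
      toks <- rw_witness_tokens(family, coin = 0.5)
      start <- 1L
      wrky_count <- 0L
      for (k in seq_len(nrow(toks))) {
        len <- 100L
        rows[[length(rows) + 1]] <- tibble(
          protein_id = pid, raw = RAW_NAME_OF[[toks$token[k]]],
          start = start, end = start + len - 1L,
          score = round(stats::runif(1, 30, 200), 1))
        if (toks$token[k] == "WRKY") {
          calls[[length(calls) + 1]] <- tibble(
            protein_id = pid, index_in_protein = wrky_count,
            group = toks$group[k])
          wrky_count <- wrky_count + 1L
        }
        start <- start + len + 20L
      }
      truth[[length(truth) + 1]] <- tibble(
        protein_id = pid,
        family = if (grepl("^decoy", family)) "NOT_RW" else family,
        lineage_hint = unname(rw_species_hint[family]) %||% NA_character_)
    }
  }
  map <- domain_label_map()
  rows <- bind_rows(rows) |>
    mutate(domain_label = map_domain_label(.data$raw, map)) |>
    select("protein_id", "domain_label", "start", "end", "score")
  list(rows = rows,
       calls = bind_rows(calls),
       truth = bind_rows(truth))
}
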