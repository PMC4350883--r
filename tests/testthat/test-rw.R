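rows_for <- function(pid, labels, starts, ends, scores = NULL) {
  tibble::tibble(protein_id = pid, domain_label = labels,
                 start = starts, end = ends,
                 score = scores %||% rep(50, length(labels)))
}
`%||%` <- function(x, y) if (is.null(x)) y else x

calls_for <- function(pid, groups) {
  tibble::tibble(protein_id = pid,
                 index_in_protein = seq_along(groups) - 1L, group = groups)
}

test_that("architecture building sorts, collapses LRR runs, resolves overlaps", {
  rows <- rows_for("p1", c("TIR", "NB-ARC", "LRR", "LRR", "WRKY"),
                   c(1L, 200L, 500L, 610L, 900L),
                   c(150L, 480L, 600L, 700L, 960L))
  arch <- build_architecture(rows, calls_for("p1", "IIe"))
  expect_equal(arch$token, c("TIR", "NB-ARC", "LRR", "WRKY(IIe)"))

  # out-of-order rows are sorted by start first
  arch2 <- build_architecture(rows[c(4, 1, 5, 2, 3), ],
                              calls_for("p1", "IIe"))
  expect_equal(arch2$token, arch$token)

  # 80% overlap, scores 40 vs 12 -> higher score kept
  ov <- rows_for("p2", c("NB-ARC", "TIR"), c(100L, 120L), c(200L, 220L),
                 scores = c(40, 12))
  archo <- build_architecture(ov, NULL)
  expect_equal(archo$token, "NB-ARC")

  # distant LRR rows do not collapse
  far <- rows_for("p3", c("LRR", "LRR"), c(1L, 200L), c(100L, 300L))
  expect_equal(nrow(build_architecture(far, NULL)), 2)

  expect_error(build_architecture(
    dplyr::bind_rows(rows_for("a", "TIR", 1L, 50L),
                     rows_for("b", "LRR", 1L, 50L)), NULL),
    class = "wrky_precondition_error")
})

test_that("the grammar assigns the eight published families", {
  tok_arch <- function(tokens, groups) {
    labels <- sub("\\(.*", "", tokens)
    tibble::tibble(protein_id = "q", position = seq_along(tokens),
                   token = tokens, label = labels, group = groups,
                   start = seq_along(tokens) * 100L,
                   end = seq_along(tokens) * 100L + 80L, score = 50)
  }
  expect_equal(classify_rw(tok_arch(
    c("TIR", "NB-ARC", "LRR", "WRKY(IIe)"), NA))$family, "RW1")
  expect_equal(classify_rw(tok_arch(
    c("TIR", "NB-ARC", "LRR", "WRKY(III)", "WRKY(III)"), NA))$family, "RW2")
  expect_equal(classify_rw(tok_arch(
    c("PAH", "WRKY(I_NT)", "WRKY(I_CT)", "NB-ARC", "MAPKKK"), NA))$family,
    "RW3")
  expect_equal(classify_rw(tok_arch(
    c("B3", "LRR", "NB-ARC", "LRR", "WRKY(IIe)"), NA))$family, "RW5")
  expect_equal(classify_rw(tok_arch(
    c("LRR", "NB-ARC", "LRR", "WRKY(IIe)"), NA))$family, "RW5")
  expect_equal(classify_rw(tok_arch(
    c("NB-ARC", "LRR", "WRKY(III)"), NA))$family, "RW6")
  expect_equal(classify_rw(tok_arch(
    c("NB-ARC", "LRR", "WRKY(III)", "WRKY(III)", "NAC"), NA))$family, "RW6")
  expect_equal(classify_rw(tok_arch(
    c("LRR", "WRKY(III)", "WRKY(IId)", "CAMB", "WRKY(IIc)"), NA))$family,
    "RW7")
  # truncated WRKY domains match RW7's slots via the wildcard
  expect_equal(classify_rw(tok_arch(
    c("LRR", "WRKY(UNCLASSIFIED)", "WRKY(UNCLASSIFIED)", "CAMB",
      "WRKY(UNCLASSIFIED)"), NA))$family, "RW7")
  expect_equal(classify_rw(tok_arch(
    c("WRKY(III)", "NB-ARC", "LRR"), NA))$family, "RW8")
  # WRKY + R-domain but no rule -> novel
  expect_equal(classify_rw(tok_arch(
    c("LRR", "WRKY(IIc)"), NA))$family, "RW_NOVEL")
  # no WRKY, or no R domain -> NOT_RW
  expect_equal(classify_rw(tok_arch(c("TIR", "NB-ARC", "LRR"), NA))$family,
               "NOT_RW")
  expect_equal(classify_rw(tok_arch(c("WRKY(IIc)"), NA))$family, "NOT_RW")
  # leading/trailing unknown domains are ignored
  expect_equal(classify_rw(tok_arch(
    c("OTHER:Zf-BED", "TIR", "NB-ARC", "LRR", "WRKY(IIe)", "OTHER:DUF123"),
    NA))$family, "RW1")
})

test_that("the RW2/RW4 ambiguity is reported and hint-resolved", {
  arch <- tibble::tibble(protein_id = "q", position = 1:4,
                         token = c("TIR", "NB-ARC", "LRR", "WRKY(III)"),
                         label = c("TIR", "NB-ARC", "LRR", "WRKY"),
                         group = c(NA, NA, NA, "III"),
                         start = c(1L, 200L, 500L, 900L),
                         end = c(150L, 480L, 700L, 960L), score = 50)
  amb <- classify_rw(arch)
  expect_equal(amb$family, "RW2|RW4")
  expect_setequal(amb$candidates[[1]], c("RW2", "RW4"))
  expect_equal(classify_rw(arch, lineage_hint = "Fragaria vesca")$family,
               "RW2")
  expect_equal(classify_rw(arch, lineage_hint = "soybean")$family, "RW4")
  expect_true(classify_rw(arch, lineage_hint = "soybean")$lineage_hint_used)
  # the hint never overrides an unambiguous match
  arch2 <- arch
  arch2$token[4] <- "WRKY(IIe)"
  arch2$group[4] <- "IIe"
  expect_equal(classify_rw(arch2, lineage_hint = "soybean")$family, "RW1")
})

test_that("grammar matching equals a regex oracle over expansions", {
  grammar <- rw_grammar()
  to_regex <- function(tokens, optional) {
    esc <- function(t) gsub("([().|])", "\\\\\\1", t)
    parts <- mapply(function(t, o) {
      if (o) paste0("(?: ", esc(t), ")?") else paste0(" ", esc(t))
    }, tokens, optional)
    paste0("^", paste(parts, collapse = ""), "$")
  }
  arch_strings <- list(
    c("TIR", "NB-ARC", "LRR", "WRKY(IIe)"),
    c("TIR", "NB-ARC", "LRR", "WRKY(III)"),
    c("TIR", "NB-ARC", "LRR", "WRKY(III)", "WRKY(III)"),
    c("B3", "LRR", "NB-ARC", "LRR", "WRKY(IIe)"),
    c("LRR", "NB-ARC", "LRR", "WRKY(IIe)"),
    c("NB-ARC", "LRR", "WRKY(III)", "NAC"),
    c("NB-ARC", "LRR", "WRKY(III)", "WRKY(III)"),
    c("NB-ARC", "LRR", "WRKY(III)", "WRKY(III)", "NAC"),
    c("WRKY(III)", "NB-ARC", "LRR"),
    c("LRR", "WRKY(IIc)"),
    c("PAH", "WRKY(I_NT)", "WRKY(I_CT)", "NB-ARC"))
  for (toks in arch_strings) {
    for (i in seq_len(nrow(grammar))) {
      rule <- list(tokens = grammar$tokens[[i]],
                   optional = grammar$optional[[i]],
                   wrky_wildcard = FALSE)
      got <- wrkyr:::match_rule(toks, rule)
      want <- grepl(to_regex(rule$tokens, rule$optional),
                    paste0(" ", paste(toks, collapse = " ")), perl = TRUE)
      expect_equal(got, want,
                   info = paste(paste(toks, collapse = "-"), "vs",
                                grammar$family[i]))
    }
  }
})

test_that("generated witnesses recover all eight families; decoys never do", {
  spec <- synth_spec(seed = 5)
  rw <- generate_rw_table(spec)
  arch <- rw$rows |>
    dplyr::group_by(protein_id) |>
    dplyr::group_map(function(d, key) {
      d$protein_id <- key$protein_id
      build_architecture(d, rw$calls[rw$calls$protein_id ==
                                       key$protein_id, ])
    }) |>
    dplyr::bind_rows()
  hints <- setNames(rw$truth$lineage_hint, rw$truth$protein_id)
  out <- classify_rw_proteins(arch, hints = hints)
  joined <- dplyr::left_join(rw$truth, out, by = "protein_id")
  expect_equal(joined$family.y, joined$family.x)
  expect_equal(sort(unique(joined$family.y[joined$family.x != "NOT_RW"])),
               paste0("RW", 1:8))
  # regeneration with the same seed is byte-identical
  rw2 <- generate_rw_table(spec)
  expect_identical(rw$rows, rw2$rows)
})
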