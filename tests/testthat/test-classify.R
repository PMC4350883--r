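scan_one <- function(rec) call_wrky_domains(rec, list(max_mismatches = 0))

test_that("rule cascade assigns the diagnostic groups", {
  tpl <- wrky_group_templates()
  cassette <- function(g) tpl$residues[tpl$group == g]

  # two C2H2 domains -> I_NT then I_CT
  rec <- tibble::tibble(id = "g1", residues = paste0(
    "MGG", cassette("I_NT"), strrep("L", 20), cassette("I_CT"), "GG"))
  calls <- classify_domain_rules(scan_one(rec), rec$residues)
  expect_equal(calls$group, c("I_NT", "I_CT"))

  # single C-C-H-C domain -> III
  rec3 <- embed_template("III")
  c3 <- classify_domain_rules(scan_one(rec3), rec3$residues)
  expect_equal(c3$group, "III")
  expect_true("R2" %in% c3$evidence[[1]])

  # moss variant signature on a C2HC domain
  recm <- embed_template("III_MOSS_VARIANT")
  cm <- classify_domain_rules(scan_one(recm), recm$residues)
  expect_equal(cm$group, "III_MOSS_VARIANT")

  # fungal finger
  recf <- embed_template("FUNGAL_TYPE")
  cf <- classify_domain_rules(scan_one(recf), recf$residues)
  expect_equal(cf$group, "FUNGAL_TYPE")

  # X5 finger with DGC and QVQR -> IIb with both rules in evidence
  recb <- embed_template("IIb")
  cb <- classify_domain_rules(scan_one(recb), recb$residues)
  expect_equal(cb$group, "IIb")
  expect_setequal(intersect(cb$evidence[[1]], c("R4a", "R4b")),
                  c("R4a", "R4b"))

  # single X4 -> coarse IIc lineage, refinable
  recc <- embed_template("IId")
  cc <- classify_domain_rules(scan_one(recc), recc$residues)
  expect_equal(cc$group, "IIc")
  expect_true(cc$refinable)

  expect_error(classify_domain_rules(scan_one(
    tibble::tibble(id = "none", residues = "GGGGGG")), "GGGGGG"),
    class = "wrky_precondition_error")
})

test_that("the cascade is invariant to domain input order", {
  tpl <- wrky_group_templates()
  rec <- tibble::tibble(id = "g1", residues = paste0(
    "MGG", tpl$residues[tpl$group == "I_NT"], strrep("L", 20),
    tpl$residues[tpl$group == "I_CT"], "GG"))
  d <- scan_one(rec)
  expect_equal(classify_domain_rules(d[2:1, ], rec$residues)$group,
               classify_domain_rules(d, rec$residues)$group)
})

test_that("refinement maps exact reference copies at distance zero", {
  refs <- reference_set()
  for (g in c("IId", "IIe", "IIa")) {
    seq_g <- refs$residues[refs$group == g]
    call <- tibble::tibble(protein_id = "q", index_in_protein = 0L,
                           group = if (g == "IIa") "IIb" else "IIc",
                           refinable = TRUE, evidence = list("R5"),
                           domain_seq = seq_g,
                           nearest_reference = NA_character_,
                           nearest_distance = NA_real_,
                           candidates = list(NULL))
    ref <- refine_by_reference(call)
    expect_equal(ref$group, g)
    expect_equal(ref$nearest_distance, 0)
  }
  expect_error(refine_by_reference(tibble::tibble(), refs = tibble::tibble()),
               class = "wrky_precondition_error")
})

test_that("a reference tie keeps the coarse label and records candidates", {
  seqs <- reference_set()$residues[reference_set()$group == "IIb"]
  refs <- tibble::tibble(id = c("refA", "refB"), group = c("IIa", "IIb"),
                         residues = c(seqs, seqs))
  call <- tibble::tibble(protein_id = "q", index_in_protein = 0L,
                         group = "IIb", refinable = TRUE,
                         evidence = list("R4a"), domain_seq = seqs,
                         nearest_reference = NA_character_,
                         nearest_distance = NA_real_,
                         candidates = list(NULL))
  out <- refine_by_reference(call, refs = refs)
  expect_equal(out$group, "IIb")
  expect_setequal(out$candidates[[1]], c("IIa", "IIb"))
})

test_that("refinement separates the X4 and X5 lineages under mutation", {
  spec <- synth_spec(group_counts = c(IIc = 100, IId = 100, IIe = 100),
                     mutation_rate = 0.05, n_decoys = 0, seed = 17)
  pr <- generate_proteome(spec)
  dom <- scan_proteome(pr$records, list(max_mismatches = 0))
  calls <- classify_proteome(dom, pr$records, refine = TRUE)
  m <- match(paste(calls$protein_id, calls$index_in_protein),
             paste(pr$truth$protein_id, pr$truth$domain_index))
  acc <- mean(calls$group == pr$truth$group[m])
  expect_gte(acc, 0.95)
})

test_that("rule-separable groups are recovered perfectly at 5% mutation", {
  spec <- synth_spec(group_counts = c(I = 20, IIb = 20, III = 20,
                                      FUNGAL_TYPE = 20),
                     mutation_rate = 0.05, n_decoys = 0, seed = 23)
  pr <- generate_proteome(spec)
  dom <- scan_proteome(pr$records, list(max_mismatches = 0))
  calls <- classify_proteome(dom, pr$records, refine = TRUE)
  m <- match(paste(calls$protein_id, calls$index_in_protein),
             paste(pr$truth$protein_id, pr$truth$domain_index))
  expect_equal(mean(calls$group == pr$truth$group[m]), 1)
})

test_that("consensus respects thresholds, ties and gap conventions", {
  expect_equal(consensus_sequence(c("WRKY", "WRKY", "WRKY")), "WRKY")
  expect_equal(consensus_sequence(c("A", "A", "G", "G"), 0.5), "x")
  expect_equal(consensus_sequence(c("A", "A", "A", "G"), 0.5), "A")
  expect_equal(consensus_sequence(c("-", "-", "-", "-"), 0.5), "-")
  # gaps count in the denominator
  expect_equal(consensus_sequence(c("A", "A", "-", "-"), 0.75), "x")
  # duplicating the alignment leaves the consensus unchanged
  aln <- c("WRKYGQK", "WRKYGEK", "WRKYGQK")
  expect_equal(consensus_sequence(rep(aln, 3), 0.6),
               consensus_sequence(aln, 0.6))
  expect_error(consensus_sequence(c("AB", "A"), 0.5),
               class = "wrky_format_error")
  expect_error(consensus_sequence(c("AB", "AB"), 0.3),
               class = "wrky_precondition_error")
})
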