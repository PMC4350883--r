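test_that("signature scanning finds planted variants", {
  h <- scan_signatures(tibble::tibble(id = "p", residues = "AAAWRKYGQKAAA"),
                       max_mismatches = 0)
  expect_equal(nrow(h), 1)
  expect_equal(h$offset, 3L)
  expect_equal(h$matched_variant, "WRKYGQK")
  expect_equal(h$mismatches, 0L)

  h2 <- scan_signatures(tibble::tibble(id = "f", residues = "MWKNNGNTK"),
                        max_mismatches = 0)
  expect_equal(h2$matched_variant, "WKNNGNT")

  h3 <- scan_signatures(tibble::tibble(id = "m", residues = "GGWRKYGEKGG"),
                        max_mismatches = 1)
  expect_equal(h3$matched_variant, "WRKYGQK")
  expect_equal(h3$mismatches, 1L)
})

test_that("at zero mismatches scanning equals naive substring search", {
  set.seed(21)
  variants <- signature_variants()
  for (rep in 1:20) {
    rec <- random_records(1, len = 120, seed = 100 + rep)
    # plant one variant at a known spot
    v <- sample(variants, 1)
    pos <- sample(0:(120 - 7), 1)
    res <- paste0(substr(rec$residues, 1, pos), v,
                  substr(rec$residues, pos + 8, 120))
    hits <- scan_signatures(tibble::tibble(id = "x", residues = res),
                            max_mismatches = 0)
    naive <- sort(unique(unlist(lapply(variants, function(vv) {
      m <- gregexpr(vv, res, fixed = TRUE)[[1]]
      if (m[1] == -1) integer(0) else as.integer(m) - 1L
    }))))
    # deduplication merges overlapping naive matches; every naive match
    # must be within 6 of a reported hit and all hits must be naive
    expect_true(all(hits$offset %in% naive))
    expect_true(all(vapply(naive, function(p)
      any(abs(hits$offset - p) < 7), logical(1))))
  }
})

test_that("scanning is position-equivariant under prefixing", {
  rec <- embed_template("IIc")
  base <- scan_signatures(rec, 0)
  shifted <- scan_signatures(
    tibble::tibble(id = "s", residues = paste0(strrep("G", 13),
                                               rec$residues)), 0)
  expect_equal(shifted$offset, base$offset + 13L)
})

test_that("uniform random sequences yield no signature hits", {
  recs <- random_records(100, len = 500, seed = 77)
  total <- sum(vapply(seq_len(100), function(i)
    nrow(scan_signatures(recs[i, ], 0)), integer(1)))
  expect_equal(total, 0L)
})

test_that("gapped input is rejected by the scanner", {
  expect_error(scan_signatures(tibble::tibble(id = "g", residues = "WR-KYGQK"),
                               0),
               class = "wrky_precondition_error")
})

test_that("zinc-finger detection recognizes the spacing classes", {
  # C-x4-C ... 23 ... H-x-H
  res <- paste0("C", "AAAA", "C", strrep("G", 23), "H", "A", "H")
  h <- detect_zinc_finger(res, 0, 40)
  full <- h[h$completeness == "full", ]
  expect_true("C2H2_X4" %in% full$pattern_class)
  x4 <- full[full$pattern_class == "C2H2_X4", ]
  expect_equal(x4$chelator_positions[[1]], c(0L, 5L, 29L, 31L))

  # fungal C-x6-C ... H-x3-C
  resf <- paste0("C", "AAAAAA", "C", strrep("G", 10), "H", "AAA", "C")
  hf <- detect_zinc_finger(resf, 0, 30)
  expect_true("FUNGAL" %in% hf$pattern_class[hf$completeness == "full"])

  # deleting the final H leaves a 3-chelator partial
  resp <- paste0("C", "AAAA", "C", strrep("G", 23), "H", "AA")
  hp <- detect_zinc_finger(resp, 0, 40)
  x4p <- hp[hp$pattern_class == "C2H2_X4", ]
  expect_equal(x4p$completeness, "partial")
  expect_equal(x4p$n_chelators, 3L)
})

test_that("domain calling needs a signature followed by a finger", {
  # signature with nothing downstream -> rejected candidate, no domain
  d <- call_wrky_domains(
    tibble::tibble(id = "rej", residues = paste0("GG", "WRKYGQK",
                                                 strrep("A", 40))),
    list(max_mismatches = 0))
  expect_equal(nrow(d), 0)
  expect_equal(nrow(rejected_candidates(d)), 1)

  # two cassettes -> two indexed, non-overlapping domains
  tpl <- wrky_group_templates()
  cassette <- tpl$residues[tpl$group == "IIc"]
  d2 <- call_wrky_domains(
    tibble::tibble(id = "two",
                   residues = paste0("GGG", cassette, strrep("L", 15),
                                     cassette, "GG")),
    list(max_mismatches = 0))
  expect_equal(d2$index_in_protein, c(0L, 1L))
  expect_lt(d2$span_end[1], d2$span_start[2] + 1)

  # spans never overlap across many scans
  spec <- synth_spec(group_counts = c(I = 5, IIb = 5, III = 5),
                     mutation_rate = 0, seed = 9)
  pr <- generate_proteome(spec)
  dom <- scan_proteome(pr$records, list(max_mismatches = 0))
  by_prot <- split(dom, dom$protein_id)
  ok <- vapply(by_prot, function(d) {
    d <- d[order(d$span_start), ]
    nrow(d) < 2 || all(d$span_start[-1] >= d$span_end[-nrow(d)])
  }, logical(1))
  expect_true(all(ok))
})

test_that("scanning a mutation-free synthetic proteome is exact", {
  spec <- synth_spec(group_counts = c(I = 10, IIa = 10, IIb = 10, IIc = 10,
                                      IId = 10, IIe = 5, III = 5),
                     mutation_rate = 0, n_decoys = 10, seed = 1)
  pr <- generate_proteome(spec)
  dom <- scan_proteome(pr$records, list(max_mismatches = 0))
  truth_keys <- paste(pr$truth$protein_id, pr$truth$span_start,
                      pr$truth$span_end)
  found_keys <- paste(dom$protein_id, dom$span_start, dom$span_end)
  expect_setequal(found_keys, truth_keys)   # recall and precision both 1
})
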