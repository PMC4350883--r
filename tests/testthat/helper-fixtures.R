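# Shared fixture builders (everything is generated in code).

# A template domain embedded in fixed linkers.
embed_template <- function(group, lead = "MGGSA", trail = "LLGGS") {
  tpl <- wrky_group_templates()
  tibble::tibble(id = paste0("emb_", group),
                 residues = paste0(lead, tpl$residues[tpl$group == group],
                                   trail))
}

# Random unaligned protein records.
random_records <- function(n, len = 50, seed = 1) {
  set.seed(seed)
  alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "K", "L",
                "M", "F", "P", "S", "T", "W", "Y", "V")
  tibble::tibble(
    id = paste0("r", seq_len(n)),
    description = ifelse(seq_len(n) %% 2 == 0, "random record", ""),
    residues = vapply(seq_len(n), function(i)
      paste(sample(alphabet, len, replace = TRUE), collapse = ""),
      character(1)))
}

# A well-separated two-clade alignment (p within ~0.04, between ~0.5).
two_clade_alignment <- function(n_per_clade = 4, len = 60, seed = 3) {
  set.seed(seed)
  pool1 <- c("A", "D", "E", "F", "G")
  pool2 <- c("K", "L", "M", "N", "P")
  base_a <- paste(sample(pool1, len, TRUE), collapse = "")
  ch <- strsplit(base_a, "")[[1]]
  flip <- sample(len, round(len / 2))
  ch[flip] <- sample(pool2, length(flip), TRUE)
  base_b <- paste(ch, collapse = "")
  mut <- function(s, n_mut) {
    ch <- strsplit(s, "")[[1]]
    i <- sample(length(ch), n_mut)
    ch[i] <- sample(c("S", "T", "V"), n_mut, TRUE)
    paste(ch, collapse = "")
  }
  a <- vapply(seq_len(n_per_clade), function(i) mut(base_a, 2), character(1))
  b <- vapply(seq_len(n_per_clade), function(i) mut(base_b, 2), character(1))
  setNames(c(a, b),
           c(paste0("A", seq_len(n_per_clade)),
             paste0("B", seq_len(n_per_clade))))
}

# One hmmscan domtblout line with the given target/query/envelope/score.
domtblout_line <- function(target, query, env_from, env_to, score) {
  paste(target, "PF00000.1", "300", query, "-", "900", "1e-50",
        format(score), "0.1", "1", "1", "1e-20", "1e-18", "80.0", "0.1",
        "1", "280", as.character(env_from - 5), as.character(env_to + 5),
        as.character(env_from), as.character(env_to), "0.95",
        "description text")
}
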