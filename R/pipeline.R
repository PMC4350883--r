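# End-to-end pipeline: scan -> classify -> introns -> rw -> tree,
# reproducible under a fixed config + seed.

#' Validate a pipeline configuration
#'
#' @param config Named list; see [run_pipeline()].
#' @return The config with defaults filled in; raises a
#'   `wrky_config_error` otherwise.
#' @export
validate_config <- function(config) {
  defaults <- list(max_mismatches = 1L, window = 60L, dgc_window = 5L,
                   refine = TRUE, deletion = "pairwise",
                   min_coverage = NULL, bootstrap = 0L, seed = 1L,
                   out_dir = NULL, fasta = NULL, gff3 = NULL,
                   genome = NULL, domains = NULL, domain_dialect = "tsv",
                   groups = NULL, hints = NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop_config(sprintf("unknown config fields: %s",
                        paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$fasta)) stop_config("config$fasta is required")
  for (f in c("fasta", "gff3", "genome", "domains", "groups")) {
    if (!is.null(cfg[[f]]) && is.character(cfg[[f]]) &&
        !file.exists(cfg[[f]])) {
      stop_config(sprintf("input does not exist: %s = %s", f, cfg[[f]]))
    }
  }
  if (!is.null(cfg$min_coverage) &&
      (cfg$min_coverage < 0 || cfg$min_coverage > 1)) {
    stop_config("min_coverage must be in [0, 1]")
  }
  if (cfg$max_mismatches < 0 || cfg$max_mismatches > 3) {
    stop_config("max_mismatches must be in 0..3")
  }
  if (cfg$bootstrap < 0) stop_config("bootstrap must be >= 0")
  if (!cfg$deletion %in% c("pairwise", "complete")) {
    stop_config("deletion must be 'pairwise' or 'complete'")
  }
  cfg
}

#' Run the full WRKY annotation pipeline
#'
#' Stages run in order: domain scan, group classification (with optional
#' reference refinement), intron mapping/typing (when `gff3` is given),
#' RW architecture classification (when `domains` is given), and a
#' neighbor-joining tree over the called domain sequences (when at least
#' three domains of equal length are available; bootstrap when
#' `bootstrap > 0`).  With `out_dir` set, per-stage TSVs (1-based
#' coordinates), the tree, the summary and the effective config are
#' written.
#'
#' @param config Named list: `fasta` (required path), optional `gff3`,
#'   `domains` (+ `domain_dialect`), `groups` (TSV of external WRKY group
#'   calls, columns `protein_id`, `index_in_protein`, `group`, used for
#'   annotation-only proteins), `hints` (named vector), `out_dir`,
#'   and parameters `max_mismatches`, `window`, `dgc_window`, `refine`,
#'   `deletion`, `min_coverage`, `bootstrap`, `seed`.
#' @return A `wrky_run` list with `domains`, `groups`, `introns`, `rw`,
#'   `tree`, `boot`, `summary`, `config`.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  records <- read_fasta(cfg$fasta)
  scan_cfg <- list(max_mismatches = cfg$max_mismatches, window = cfg$window)
  domains <- scan_proteome(records, scan_cfg)
  groups <- classify_proteome(domains, records, refine = cfg$refine)
  introns <- NULL
  if (!is.null(cfg$gff3)) {
    models <- read_gff3(cfg$gff3)
    introns <- type_proteome_introns(introns_from_models(models),
                                     domains, records)
  }
  rw <- NULL
  if (!is.null(cfg$domains)) {
    rows <- read_domain_table(cfg$domains, dialect = cfg$domain_dialect)
    # group calls for architecture tokens: scanned calls, augmented by an
    # external table for proteins absent from the scanned proteome
    # (e.g. annotation-only records)
    arch_calls <- select(as_tibble(groups), "protein_id",
                         "index_in_protein", "group")
    if (!is.null(cfg$groups)) {
      ext <- readr::read_tsv(cfg$groups, col_types = "cic",
                             progress = FALSE)
      arch_calls <- bind_rows(
        arch_calls, filter(ext, !.data$protein_id %in%
                             arch_calls$protein_id))
    }
    arch <- rows |>
      group_by(.data$protein_id) |>
      dplyr::group_map(function(d, key) {
        d$protein_id <- key$protein_id
        build_architecture(d, arch_calls[arch_calls$protein_id ==
                                           key$protein_id, ])
      }) |>
      bind_rows()
    hints <- cfg$hints
    if (is.character(hints) && length(hints) == 1 && is.null(names(hints)) &&
        file.exists(hints)) {
      ht <- readr::read_tsv(hints, col_types = readr::cols(),
                            progress = FALSE)
      hints <- setNames(ht$lineage_hint, ht$protein_id)
    }
    rw <- classify_rw_proteins(arch, hints = hints)
  }
  tree <- NULL; boot <- NULL
  # Domain sequences of the modal length form the tree's alignment;
  # heterogeneous lengths would need a true aligner, which the pipeline
  # deliberately does not bundle.
  dom_len <- nchar(groups$domain_seq)
  modal <- as.integer(names(sort(table(dom_len), decreasing = TRUE))[1])
  pick <- which(dom_len == modal)
  if (length(pick) >= 3) {
    aln <- setNames(groups$domain_seq[pick],
                    paste0(groups$protein_id[pick], ".",
                           groups$index_in_protein[pick]))
    if (!is.null(cfg$min_coverage)) {
      aln <- site_coverage_filter(aln, cfg$min_coverage)
    }
    if (cfg$bootstrap > 0) {
      boot <- bootstrap_support(aln, n_replicates = cfg$bootstrap,
                                seed = cfg$seed, deletion = cfg$deletion)
      tree <- boot$tree
    } else {
      tree <- suppressWarnings(
        nj_tree(poisson_correct(p_distance(aln, cfg$deletion))))
    }
  }
  summary <- bind_rows(
    tibble(metric = "n_proteins", value = nrow(records)),
    tibble(metric = "n_domains", value = nrow(domains)),
    tibble(metric = "n_rejected_candidates",
           value = nrow(rejected_candidates(domains))),
    groups |> dplyr::count(.data$group) |>
      mutate(metric = paste0("group_", .data$group)) |>
      select(metric, value = "n"),
    if (!is.null(introns)) {
      introns |> dplyr::count(.data$type) |>
        mutate(metric = paste0("intron_", .data$type)) |>
        select(metric, value = "n")
    },
    if (!is.null(rw)) {
      rw |> dplyr::count(.data$family) |>
        mutate(metric = paste0("rw_", .data$family)) |>
        select(metric, value = "n")
    })
  out <- structure(list(domains = domains, groups = groups,
                        introns = introns, rw = rw, tree = tree,
                        boot = boot, summary = summary, config = cfg),
                   class = "wrky_run")
  if (!is.null(cfg$out_dir)) write_run(out, cfg$out_dir)
  out
}

# Write per-stage outputs; protein coordinates become 1-based inclusive.
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dom_out <- run$domains |>
    mutate(sig_start = .data$sig_offset + 1L,
           span_from = .data$span_start + 1L, span_to = .data$span_end) |>
    select("protein_id", "index_in_protein", "sig_start", "heptapeptide",
           "matched_variant", "mismatches", "finger_class", "completeness",
           "span_from", "span_to")
  readr::write_tsv(dom_out, file.path(out_dir, "domains.tsv"),
                   progress = FALSE)
  grp_out <- run$groups |>
    mutate(evidence = purrr::map_chr(.data$evidence,
                                     ~ paste(.x, collapse = ","))) |>
    select("protein_id", "index_in_protein", "group", "evidence",
           "nearest_reference", "nearest_distance")
  readr::write_tsv(grp_out, file.path(out_dir, "groups.tsv"),
                   progress = FALSE)
  if (!is.null(run$introns)) {
    readr::write_tsv(select(run$introns, -dplyr::any_of("anchor_offset")),
                     file.path(out_dir, "introns.tsv"), progress = FALSE)
  }
  if (!is.null(run$rw)) {
    rw_out <- run$rw |>
      mutate(candidates = purrr::map_chr(
        .data$candidates, ~ paste(.x %||% character(0), collapse = "|"))) |>
      select("protein_id", "family", "matched_rule", "candidates",
             "lineage_hint_used")
    readr::write_tsv(rw_out, file.path(out_dir, "rw.tsv"), progress = FALSE)
  }
  if (!is.null(run$tree)) {
    tr <- run$tree; class(tr) <- "phylo"
    write_newick(tr, file.path(out_dir, "tree.nwk"))
  }
  if (!is.null(run$boot)) {
    sup <- run$boot$support |>
      mutate(tips = purrr::map_chr(.data$tips, paste, collapse = "|")) |>
      select("key", "tips", "support")
    readr::write_tsv(sup, file.path(out_dir, "support.tsv"),
                     progress = FALSE)
  }
  readr::write_tsv(run$summary, file.path(out_dir, "summary.tsv"),
                   progress = FALSE)
  cfg <- run$config
  cfg_lines <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    sprintf("%s: %s", k,
            if (is.null(v)) "~" else paste(format(v), collapse = ", "))
  }, character(1))
  con <- file(file.path(out_dir, "config.yaml"), open = "wb")
  writeLines(cfg_lines, con, sep = "\n", useBytes = TRUE)
  close(con)
  invisible(out_dir)
}
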