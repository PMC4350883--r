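# Domain-annotation tables (hmmscan domtblout or plain TSV) and the
# packaged R protein-WRKY catalogue.

#' Domain label mapping table
#'
#' Maps raw domain accessions/names (Pfam-style) to the controlled
#' vocabulary `TIR, NB-ARC, LRR, WRKY, B3, NAC, CAMB, MAPKKK, PAH`.
#' Unmapped names become `OTHER:<raw>`.
#'
#' @param path Optional user TSV (columns `raw`, `label`) appended to the
#'   shipped table; user rows win on conflict.
#' @return A tibble with columns `raw` and `label`.
#' @export
domain_label_map <- function(path = NULL) {
  shipped <- .wrky_cache$label_map
  if (is.null(shipped)) {
    shipped <- readr::read_tsv(
      system.file("extdata", "domain_label_map.tsv", package = "wrkyr"),
      col_types = "cc", progress = FALSE)
    .wrky_cache$label_map <- shipped
  }
  if (!is.null(path)) {
    user <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
    shipped <- bind_rows(user, shipped) |> distinct(.data$raw, .keep_all = TRUE)
  }
  shipped
}

map_domain_label <- function(raw, map) {
  i <- match(raw, map$raw)
  ifelse(is.na(i), paste0("OTHER:", raw), map$label[i])
}

#' Read a domain-annotation table
#'
#' @param path Input file.
#' @param dialect `"domtblout"` (hmmscan per-domain table: target name,
#'   envelope from/to and full-sequence score are used, everything else is
#'   ignored) or `"tsv"` (columns `protein_id`, `domain`, `start`, `end`,
#'   `score`).
#' @param label_map Optional path to a user label-mapping TSV; see
#'   [domain_label_map()].
#' @return A tibble sorted by (`protein_id`, `start`) with columns
#'   `protein_id`, `domain_label` (controlled vocabulary), `start`, `end`
#'   (1-based inclusive protein coordinates) and `score`.
#' @export
read_domain_table <- function(path, dialect = c("tsv", "domtblout"),
                              label_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_precondition(paste0("no such file: ", path))
  map <- domain_label_map(label_map)
  if (dialect == "domtblout") {
    lines <- readLines(path)
    keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
    if (length(keep) == 0) {
      out <- tibble(protein_id = character(0), domain_label = character(0),
                    start = integer(0), end = integer(0), score = double(0))
      return(out)
    }
    rows <- purrr::map(keep, function(i) {
      f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(f) < 22) {
        stop_format(sprintf("malformed domtblout row at line %d", i))
      }
      start <- suppressWarnings(as.integer(f[20]))
      end <- suppressWarnings(as.integer(f[21]))
      score <- suppressWarnings(as.numeric(f[8]))
      if (any(is.na(c(start, end, score)))) {
        stop_format(sprintf("malformed domtblout row at line %d", i))
      }
      tibble(protein_id = f[4], raw = f[1], start = start, end = end,
             score = score)
    })
    df <- bind_rows(rows)
  } else {
    df <- tryCatch(
      readr::read_tsv(path, col_types = readr::cols(
        protein_id = "c", domain = "c", start = "i", end = "i",
        score = "d"), progress = FALSE),
      error = function(e) stop_format(conditionMessage(e)))
    if (nrow(readr::problems(df)) > 0) {
      p <- readr::problems(df)
      stop_format(sprintf("malformed TSV row at line %d", p$row[1] + 1L))
    }
    df <- rename(df, raw = "domain")
  }
  if (nrow(df) > 0 && any(df$start > df$end)) {
    stop_format("domain row with start > end")
  }
  df |>
    mutate(domain_label = map_domain_label(.data$raw, map)) |>
    select("protein_id", "domain_label", "start", "end", "score") |>
    arrange(.data$protein_id, .data$start)
}

#' Write a domain-annotation table as TSV
#' @param rows Tibble from [read_domain_table()] or compatible.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_table <- function(rows, path) {
  out <- rows |>
    mutate(domain = sub("^OTHER:", "", .data$domain_label)) |>
    select("protein_id", "domain", "start", "end", "score")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read the R protein-WRKY gene catalogue
#'
#' The packaged catalogue transcribes the published table of 29
#' R protein-WRKY genes (name, species as printed, gene model, genomic
#' position).  `rw_family` is filled only where the source text states a
#' family; two entries print no coordinate span and carry `NA`.
#'
#' @param path Optional path to a catalogue TSV; default is the packaged
#'   file.
#' @return A tibble with columns `name`, `species`, `gene_model`,
#'   `seq_id`, `start`, `end`, `rw_family`, `notes`.
#' @export
read_rw_catalogue <- function(path = NULL) {
  path <- path %||% system.file("extdata", "rw_catalogue.tsv",
                                package = "wrkyr")
  df <- readr::read_tsv(path, col_types = "cccciicc", progress = FALSE,
                        na = "NA")
  if (anyDuplicated(df$name)) {
    stop_format(sprintf("duplicate catalogue names: %s",
                        paste(df$name[duplicated(df$name)], collapse = ", ")))
  }
  bad <- !is.na(df$start) & !is.na(df$end) & df$start > df$end
  if (any(bad)) stop_format("catalogue span with start > end")
  df
}
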