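# broom-style tidiers for the package's result objects.

#' Tidy a distance object into long pair form
#' @param x A `wrky_dist` object.
#' @param ... Unused.
#' @return Tibble with `item1`, `item2`, `distance`, `comparable_sites`
#'   (upper triangle, one row per pair).
#' @export
tidy.wrky_dist <- function(x, ...) {
  n <- length(x$ids)
  idx <- which(upper.tri(x$d), arr.ind = TRUE)
  tibble(item1 = x$ids[idx[, 1]], item2 = x$ids[idx[, 2]],
         distance = x$d[idx],
         comparable_sites = x$comparable_sites[idx])
}

#' One-row summary of a distance object
#' @param x A `wrky_dist` object.
#' @param ... Unused.
#' @export
glance.wrky_dist <- function(x, ...) {
  up <- x$d[upper.tri(x$d)]
  tibble(n_taxa = length(x$ids), measure = x$measure,
         min_distance = min(up), mean_distance = mean(up),
         max_distance = max(up),
         min_comparable_sites = min(x$comparable_sites[upper.tri(x$d)]))
}

#' Tidy a neighbor-joining tree into an edge table
#' @param x A `wrky_nj` tree.
#' @param ... Unused.
#' @return Tibble with `parent`, `node`, `branch_length`, `label` (tip
#'   label or `NA` for internal nodes).
#' @export
tidy.wrky_nj <- function(x, ...) {
  nt <- length(x$tip.label)
  tibble(parent = x$edge[, 1], node = x$edge[, 2],
         branch_length = x$edge.length,
         label = ifelse(x$edge[, 2] <= nt, x$tip.label[x$edge[, 2]],
                        NA_character_))
}

#' One-row summary of a neighbor-joining tree
#' @param x A `wrky_nj` tree.
#' @param ... Unused.
#' @export
glance.wrky_nj <- function(x, ...) {
  tibble(n_tips = length(x$tip.label), n_internal = x$Nnode,
         total_length = sum(x$edge.length),
         clamped_branches = attr(x, "clamped_branches") %||% 0L)
}

#' Tidy bootstrap results into a support table
#' @param x A `wrky_boot` object.
#' @param ... Unused.
#' @export
tidy.wrky_boot <- function(x, ...) {
  x$support |>
    mutate(n_tips = purrr::map_int(.data$tips, length)) |>
    select("key", "n_tips", "support")
}

#' One-row summary of bootstrap results
#' @param x A `wrky_boot` object.
#' @param ... Unused.
#' @export
glance.wrky_boot <- function(x, ...) {
  tibble(n_replicates = x$n_replicates,
         n_bipartitions = nrow(x$support),
         mean_support = mean(x$support$support),
         min_support = min(x$support$support))
}
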