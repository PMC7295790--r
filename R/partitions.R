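group_ids <- function(x, group) {
  cm <- condition_meta(x)
  ids <- cm$id[!is.na(cm$group) & cm$group == group]
  if (length(ids) == 0L) {
    stop("no condition carries group tag '", group, "'", call. = FALSE)
  }
  ids
}

#' Species isolated by a condition group
#'
#' Union of species over all conditions carrying the given group tag (the
#' `group` column of the condition metadata). Group membership is a single
#' tag per condition; the study's condition groups are disjoint by
#' construction.
#'
#' @param x an `incidence_matrix` whose condition metadata carries group
#'   tags.
#' @param group group tag.
#' @return character vector of species names.
#' @export
group_species <- function(x, group) {
  stopifnot(inherits(x, "incidence_matrix"))
  ids <- group_ids(x, group)
  rownames(x)[rowSums(unclass(x)[, ids, drop = FALSE]) > 0L]
}

#' Overlap partition of species among condition groups
#'
#' Splits the union of species isolated by 2 or 3 condition groups into
#' its Venn regions. Region counts are keyed by membership signature: a
#' string of 0/1 flags in the order of `groups` ("110" = in the first two
#' groups, not the third). For 3 groups the share of the union held by the
#' triple intersection is reported as a percentage (rounded half-up).
#'
#' @param x an `incidence_matrix`.
#' @param groups character vector of 2 or 3 distinct group tags.
#' @return object of class `group_partition`: list with `groups`,
#'   `group_sizes` (per-group species counts), `region_counts` (named
#'   integer vector over non-empty signatures), `union_size`,
#'   `percent_common` (3 groups only).
#' @export
species_partition <- function(x, groups) {
  stopifnot(inherits(x, "incidence_matrix"))
  k <- length(groups)
  if (k < 2L || k > 3L) {
    stop("species_partition supports 2 or 3 groups", call. = FALSE)
  }
  if (anyDuplicated(groups)) stop("group tags must be distinct", call. = FALSE)
  sets <- lapply(groups, function(g) group_species(x, g))
  members <- vapply(sets, function(s) rownames(x) %in% s, logical(nrow(x)))
  in_union <- rowSums(members) > 0L
  sig <- apply(members[in_union, , drop = FALSE], 1L,
               function(b) paste(as.integer(b), collapse = ""))
  all_sigs <- apply(as.matrix(expand.grid(rep(list(0:1), k)))[-1, , drop = FALSE],
                    1L, paste, collapse = "")
  counts <- table(factor(sig, levels = sort(all_sigs)))
  counts <- stats::setNames(as.integer(counts), names(counts))
  union_size <- sum(in_union)
  res <- list(groups = groups,
              group_sizes = stats::setNames(lengths(sets), groups),
              region_counts = counts,
              union_size = union_size)
  if (k == 3L) {
    res$percent_common <- round_half_up(100 * counts[["111"]] / union_size)
  }
  structure(res, class = "group_partition")
}

#' @export
print.group_partition <- function(x, ...) {
  cat(sprintf("Partition of %d species over groups: %s\n", x$union_size,
              paste(sprintf("%s (%d)", x$groups, x$group_sizes),
                    collapse = ", ")))
  print(x$region_counts)
  if (!is.null(x$percent_common)) {
    cat(sprintf("Shared by all three groups: %d (%d%%)\n",
                x$region_counts[["111"]], x$percent_common))
  }
  invisible(x)
}

#' Species a group adds to a baseline, and how many are specific
#'
#' `added` counts the species the `other` group isolated that the
#' `baseline` group did not; `specific` counts how many of those no other
#' group isolated either (`rest` defaults to every remaining group tag in
#' the condition metadata).
#'
#' @param x an `incidence_matrix`.
#' @param baseline,other distinct group tags.
#' @param rest optional character vector of the remaining group tags;
#'   defaults to all tags other than `baseline` and `other`.
#' @return named integer vector `c(added = , specific = )`.
#' @export
added_and_specific <- function(x, baseline, other, rest = NULL) {
  stopifnot(inherits(x, "incidence_matrix"))
  if (is.null(rest)) {
    cm <- condition_meta(x)
    rest <- setdiff(unique(cm$group[!is.na(cm$group)]), c(baseline, other))
  }
  tags <- c(baseline, other, rest)
  if (anyDuplicated(tags)) {
    stop("baseline, other and rest tags must not overlap", call. = FALSE)
  }
  base_sp <- group_species(x, baseline)
  other_sp <- group_species(x, other)
  rest_sp <- unique(unlist(lapply(rest, function(g) group_species(x, g))))
  added <- setdiff(other_sp, base_sp)
  specific <- setdiff(added, rest_sp)
  c(added = length(added), specific = length(specific))
}

#' Compare a species set against an external reference catalogue
#'
#' Counts (and names) the species absent from a reference name list, e.g.
#' a previously published catalogue of species cultured from the human
#' gut. Both sides are normalized the same way as matrix species names
#' (whitespace-collapsed, case-insensitive); no fuzzy matching.
#'
#' @param species character vector of species names.
#' @param catalogue non-empty character vector of reference names (e.g.
#'   read from a one-name-per-line text file).
#' @return list with `novel_count` and `novel_names` (canonical forms of
#'   the species missing from the catalogue).
#' @export
compare_to_catalogue <- function(species, catalogue) {
  if (length(catalogue) == 0L) {
    stop("catalogue must be non-empty", call. = FALSE)
  }
  sp <- normalize_species(species)
  novel <- sp[!duplicated(species_key(sp)) &
                !species_key(sp) %in% species_key(catalogue)]
  list(novel_count = length(novel), novel_names = novel)
}
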