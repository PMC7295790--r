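#' Rank culture conditions by species richness
#'
#' Conditions are sorted by decreasing richness (number of species each
#' isolated on its own); ties are broken by ascending condition id so the
#' ranking is deterministic.
#'
#' @param x an `incidence_matrix`.
#' @param top_k optional positive integer; keep only the `top_k` most
#'   profitable conditions.
#' @return data.frame with columns `condition` and `richness`, best first.
#' @export
rank_by_richness <- function(x, top_k = NULL) {
  stopifnot(inherits(x, "incidence_matrix"))
  r <- richness(x)
  ord <- order(-r, names(r))
  out <- data.frame(condition = names(r)[ord], richness = unname(r[ord]),
                    stringsAsFactors = FALSE)
  if (!is.null(top_k)) {
    if (!is.numeric(top_k) || length(top_k) != 1L || top_k <= 0) {
      stop("top_k must be a positive integer", call. = FALSE)
    }
    out <- utils::head(out, top_k)
  }
  rownames(out) <- NULL
  out
}

#' Marginal species gain of a candidate condition
#'
#' The number of species the candidate grew that no already-selected
#' condition grew — the study's "number of species added and not
#' previously isolated". With an empty selection this equals the
#' candidate's richness.
#'
#' @param x an `incidence_matrix`.
#' @param selected character vector of already-selected condition ids (may
#'   be empty).
#' @param candidate a single condition id not in `selected`.
#' @return non-negative integer count.
#' @export
marginal_gain <- function(x, selected, candidate) {
  stopifnot(inherits(x, "incidence_matrix"), length(candidate) == 1L)
  check_conditions(x, c(selected, candidate))
  if (candidate %in% selected) {
    stop("candidate condition is already selected: ", candidate,
         call. = FALSE)
  }
  m <- unclass(x)
  covered <- if (length(selected) == 0L) {
    rep(FALSE, nrow(m))
  } else {
    rowSums(m[, selected, drop = FALSE]) > 0L
  }
  sum(m[, candidate] == 1L & !covered)
}

#' Greedy condition-panel selection by maximum coverage
#'
#' Iteratively selects the condition adding the most species not yet
#' isolated by any selected condition (greedy maximum coverage / set
#' cover), the procedure by which a large condition set is reduced to a
#' minimal panel preserving captured diversity. The first pick may be
#' forced to a designated seed condition (the study fixed its historically
#' best condition first; as that is also the richest, seeding it equals
#' pure greedy). Selection stops once the covered fraction reaches
#' `target_fraction` or no candidate adds a species; in the latter case
#' the result is flagged `exhausted` rather than raising an error.
#'
#' Tie-breaking is deterministic: at equal marginal gain the condition
#' with larger standalone richness wins, then ascending condition id.
#' Conditions in `force_include` that greedy did not pick are appended
#' after the stopping point (in the order given) with their marginal gain
#' at append time, mirroring the study's manual addition of a selective
#' medium to its recommended panel.
#'
#' @param x an `incidence_matrix`.
#' @param target_fraction coverage target in (0, 1]; default 1 (full
#'   coverage of the matrix's species set).
#' @param seed_condition optional condition id forced as the first pick.
#' @param force_include character vector of condition ids appended after
#'   greedy stopping if not already selected.
#' @return object of class `cover_result`: list with `steps` (data.frame:
#'   `condition`, `marginal_gain`, `richness`, `cumulative_covered`,
#'   `cumulative_fraction`, `forced`), `total_species`, `target_fraction`,
#'   `seeded_first`, `exhausted`.
#' @export
greedy_cover <- function(x, target_fraction = 1, seed_condition = NULL,
                         force_include = character()) {
  stopifnot(inherits(x, "incidence_matrix"))
  if (!is.numeric(target_fraction) || length(target_fraction) != 1L ||
      target_fraction <= 0 || target_fraction > 1) {
    stop("target_fraction must be in (0, 1]", call. = FALSE)
  }
  if (!is.null(seed_condition)) check_conditions(x, seed_condition)
  if (length(force_include) > 0L) check_conditions(x, force_include)

  m <- unclass(x)
  total <- nrow(m)
  rich <- colSums(m)
  ids <- colnames(m)
  covered <- rep(FALSE, total)
  remaining <- ids
  steps <- list()
  exhausted <- FALSE

  repeat {
    if (sum(covered) / total >= target_fraction) break
    if (length(remaining) == 0L) { exhausted <- TRUE; break }
    gains <- colSums(m[!covered, remaining, drop = FALSE])
    if (length(steps) == 0L && !is.null(seed_condition)) {
      pick <- seed_condition
    } else {
      if (max(gains) == 0L) { exhausted <- TRUE; break }
      ord <- order(-gains, -rich[remaining], remaining)
      pick <- remaining[ord[1L]]
    }
    g <- unname(gains[pick])
    covered <- covered | (m[, pick] == 1L)
    steps[[length(steps) + 1L]] <- data.frame(
      condition = pick, marginal_gain = g, richness = unname(rich[pick]),
      cumulative_covered = sum(covered),
      forced = FALSE, stringsAsFactors = FALSE)
    remaining <- setdiff(remaining, pick)
  }

  for (fc in setdiff(force_include, vapply(steps, `[[`, "", "condition"))) {
    g <- sum(m[!covered, fc])
    covered <- covered | (m[, fc] == 1L)
    steps[[length(steps) + 1L]] <- data.frame(
      condition = fc, marginal_gain = g, richness = unname(rich[fc]),
      cumulative_covered = sum(covered),
      forced = TRUE, stringsAsFactors = FALSE)
  }

  steps <- do.call(rbind, steps)
  if (is.null(steps)) {
    steps <- data.frame(condition = character(), marginal_gain = integer(),
                        richness = integer(), cumulative_covered = integer(),
                        forced = logical(), stringsAsFactors = FALSE)
  }
  steps$cumulative_fraction <- steps$cumulative_covered / total
  structure(list(steps = steps, total_species = total,
                 target_fraction = target_fraction,
                 seeded_first = seed_condition, exhausted = exhausted),
            class = "cover_result")
}

#' @export
print.cover_result <- function(x, ...) {
  cat(sprintf("Greedy cover: %d step(s), %d/%d species (%.1f%%), target %.0f%%%s\n",
              nrow(x$steps), max(c(0L, x$steps$cumulative_covered)),
              x$total_species,
              100 * max(c(0, x$steps$cumulative_fraction)),
              100 * x$target_fraction,
              if (x$exhausted) " [exhausted]" else ""))
  print(utils::head(x$steps, 20L))
  invisible(x)
}

#' Exact minimum set cover (small-instance oracle)
#'
#' Exhaustive search for a minimum-cardinality set of conditions whose
#' union is the full species set. Used to validate the greedy heuristic;
#' limited to 20 conditions (2^20 candidate subsets). The witness returned
#' is deterministic: the lexicographically smallest among the optima, with
#' condition ids compared in sorted order.
#'
#' @param x an `incidence_matrix` with at most 20 conditions.
#' @return list with `size` (integer) and `conditions` (character witness).
#' @export
exact_min_cover <- function(x) {
  stopifnot(inherits(x, "incidence_matrix"))
  m <- unclass(x)
  if (ncol(m) > 20L) {
    stop("exact_min_cover is limited to 20 conditions (exhaustive search); got ",
         ncol(m), call. = FALSE)
  }
  ids <- sort(colnames(m))
  m <- m[, ids, drop = FALSE]
  for (k in seq_len(ncol(m))) {
    combos <- utils::combn(ncol(m), k)
    for (j in seq_len(ncol(combos))) {
      S <- combos[, j]
      if (all(rowSums(m[, S, drop = FALSE]) > 0L)) {
        return(list(size = k, conditions = ids[S]))
      }
    }
  }
  stop("no cover exists (unreachable for a valid incidence matrix)",
       call. = FALSE)
}

#' Panel report with cumulative coverage arithmetic
#'
#' Formats a condition panel the way the study's recommended-panel table
#' is printed: one row per selection step with the species added and not
#' previously isolated (marginal gain), the condition's standalone
#' richness, the running cumulative species count and the cumulative
#' percentage of total species (rounded half-up to an integer).
#'
#' The numeric method takes a bare marginal-gain column plus the total
#' species count, so a printed gain sequence can be checked by the same
#' arithmetic the full pipeline uses.
#'
#' @param x a `cover_result`, or a numeric vector of per-step marginal
#'   gains.
#' @param ... passed to methods.
#' @return data.frame, one row per step, with columns `condition` (when
#'   known), `label`, `species_added`, `species_total` (when known),
#'   `cumulative_species`, `cumulative_percent`.
#' @export
panel_report <- function(x, ...) UseMethod("panel_report")

#' @rdname panel_report
#' @param matrix the `incidence_matrix` the cover was produced from
#'   (supplies labels, standalone richness and the total species count).
#' @export
panel_report.cover_result <- function(x, matrix, ...) {
  stopifnot(inherits(matrix, "incidence_matrix"))
  if (x$total_species != nrow(matrix) ||
      !all(x$steps$condition %in% colnames(matrix))) {
    stop("cover result does not match the supplied matrix", call. = FALSE)
  }
  cm <- condition_meta(matrix)
  st <- x$steps
  data.frame(
    condition = st$condition,
    label = cm$label[match(st$condition, cm$id)],
    species_added = st$marginal_gain,
    species_total = st$richness,
    cumulative_species = st$cumulative_covered,
    cumulative_percent = round_half_up(100 * st$cumulative_covered /
                                         x$total_species),
    stringsAsFactors = FALSE
  )
}

#' @rdname panel_report
#' @param total_species total number of species the percentages are taken
#'   against (numeric method only).
#' @export
panel_report.numeric <- function(x, total_species, ...) {
  if (any(x < 0) || any(x != round_half_up(x))) {
    stop("marginal gains must be non-negative integers", call. = FALSE)
  }
  cum <- cumsum(x)
  if (max(cum) > total_species) {
    stop("cumulative gains exceed total_species", call. = FALSE)
  }
  data.frame(
    species_added = as.integer(x),
    cumulative_species = as.integer(cum),
    cumulative_percent = round_half_up(100 * cum / total_species)
  )
}

#' Species accumulation curves: greedy order versus random orders
#'
#' Compares how fast the species count accumulates when conditions are
#' added in greedy (maximum-coverage) order versus uniformly random
#' orders, the standard way to visualize how much a rationalized panel
#' saves. The greedy order is extended past its stopping point with the
#' remaining conditions (by decreasing richness) so every rank is defined.
#'
#' @param x an `incidence_matrix`.
#' @param n_permutations number of random condition orders (>= 1).
#' @param seed integer seed; results are deterministic given the seed.
#' @return data.frame with one row per rank: `rank`, `greedy`,
#'   `random_mean`, `random_min`, `random_max` cumulative species counts.
#' @export
accumulation_curve <- function(x, n_permutations = 100, seed = 1) {
  stopifnot(inherits(x, "incidence_matrix"))
  if (!is.numeric(n_permutations) || n_permutations < 1) {
    stop("n_permutations must be >= 1", call. = FALSE)
  }
  m <- unclass(x)
  nc <- ncol(m)
  cum_for_order <- function(ord) {
    covered <- rep(FALSE, nrow(m))
    out <- integer(nc)
    for (i in seq_len(nc)) {
      covered <- covered | (m[, ord[i]] == 1L)
      out[i] <- sum(covered)
    }
    out
  }
  cov <- greedy_cover(x, target_fraction = 1)
  greedy_order <- cov$steps$condition
  rest <- setdiff(colnames(m), greedy_order)
  if (length(rest) > 0L) {
    r <- richness(x, rest)
    greedy_order <- c(greedy_order, rest[order(-r, rest)])
  }
  greedy_cum <- cum_for_order(match(greedy_order, colnames(m)))

  rand <- with_local_seed(seed, {
    vapply(seq_len(n_permutations),
           function(i) cum_for_order(sample.int(nc)), integer(nc))
  })
  rand <- matrix(rand, nrow = nc)
  data.frame(rank = seq_len(nc), greedy = greedy_cum,
             random_mean = rowMeans(rand),
             random_min = apply(rand, 1, min),
             random_max = apply(rand, 1, max))
}
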