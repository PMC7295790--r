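# Build an incidence_matrix from a plain 0/1 matrix, naming rows/cols if
# the caller did not.
make_im <- function(m, condition_meta = NULL, species_meta = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("sp%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("c%02d", seq_len(ncol(m)))
  incidence_matrix(m, condition_meta = condition_meta,
                   species_meta = species_meta)
}

# Random binary matrix with no all-zero row (rows resampled until hit).
random_im <- function(n_sp, n_cond, p = 0.3) {
  m <- matrix(rbinom(n_sp * n_cond, 1, p), n_sp, n_cond)
  for (i in which(rowSums(m) == 0)) {
    while (sum(m[i, ]) == 0) m[i, ] <- rbinom(n_cond, 1, p)
  }
  make_im(m)
}

# Independent replay of the greedy maximum-coverage rule, written as plain
# loops over explicit species sets (no shared code with greedy_cover).
greedy_oracle <- function(im, target = 1) {
  m <- unclass(im)
  sets <- lapply(seq_len(ncol(m)), function(j) rownames(m)[m[, j] == 1])
  names(sets) <- colnames(m)
  rich <- vapply(sets, length, integer(1))
  covered <- character(0)
  picks <- character(0)
  gains <- integer(0)
  remaining <- names(sets)
  while (length(covered) < nrow(m) * target - 1e-9 && length(remaining) > 0) {
    g <- vapply(remaining, function(id) length(setdiff(sets[[id]], covered)),
                integer(1))
    if (max(g) == 0) break
    best <- remaining[g == max(g)]
    best <- best[rich[best] == max(rich[best])]
    pick <- sort(best)[1]
    picks <- c(picks, pick)
    gains <- c(gains, g[[pick]])
    covered <- union(covered, sets[[pick]])
    remaining <- setdiff(remaining, pick)
  }
  list(picks = picks, gains = gains, covered = length(covered))
}

# Exhaustive best coverage achievable with exactly k conditions.
best_k_coverage <- function(im, k) {
  m <- unclass(im)
  combos <- utils::combn(ncol(m), k)
  max(apply(combos, 2, function(S)
    sum(rowSums(m[, S, drop = FALSE]) > 0)))
}
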