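#' Pearson chi-square test on a 2x2 contingency table
#'
#' Classical Pearson chi-square of independence with 1 degree of freedom:
#' expected counts from the row/column margins, statistic
#' sum((O - E)^2 / E), upper-tail p-value from the chi-square
#' distribution. The Yates continuity correction (|O - E| reduced by 0.5
#' before squaring, floored at 0) is off by default, matching the
#' classical formula.
#'
#' @param table 2x2 matrix of non-negative counts with all margins > 0.
#' @param correction apply the Yates continuity correction?
#' @return object of class `contingency_result`: list with `table`,
#'   `chi2`, `df` (always 1), `p_value`, `correction`.
#' @examples
#' pearson_chi2(matrix(c(127, 22, 232, 232), 2, 2))
#' @export
pearson_chi2 <- function(table, correction = FALSE) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) {
    stop("pearson_chi2 expects a 2x2 table", call. = FALSE)
  }
  if (anyNA(tab) || any(tab < 0)) {
    stop("counts must be non-negative and finite", call. = FALSE)
  }
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    stop("degenerate table: a row or column margin is zero", call. = FALSE)
  }
  expected <- outer(rs, cs) / sum(tab)
  dev <- abs(tab - expected)
  if (correction) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / expected)
  structure(list(table = tab, chi2 = chi2, df = 1L,
                 p_value = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
                 correction = correction),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square%s: X2 = %.4g, df = %d, p = %.3g\n",
              if (x$correction) " (Yates-corrected)" else "",
              x$chi2, x$df, x$p_value))
  print(x$table)
  invisible(x)
}

#' Paired supplemented-versus-unsupplemented condition contrast
#'
#' Compares two disjoint condition arms (e.g. a set of media with rumen
#' fluid against the same media without) on the species each arm's union
#' recovered. Reports each arm's union richness, the species specific to
#' each arm, the shared species, and a Pearson chi-square on the 2x2
#' table `rbind(c(specific_a, shared), c(specific_b, shared))`, testing
#' whether one arm holds a larger proportion of arm-specific species.
#' Arms with identical species sets give chi2 = 0, p = 1 (there is
#' nothing arm-specific to compare).
#'
#' @param x an `incidence_matrix`.
#' @param arm_a,arm_b non-empty, disjoint character vectors of condition
#'   ids.
#' @param correction passed to [pearson_chi2()].
#' @return object of class `paired_contrast`: list with `arm_a`, `arm_b`,
#'   `richness_a`, `richness_b`, `specific_a`, `specific_b`, `shared`,
#'   `species_a`, `species_b`, `test`.
#' @export
paired_supplement_contrast <- function(x, arm_a, arm_b, correction = FALSE) {
  stopifnot(inherits(x, "incidence_matrix"))
  if (length(arm_a) == 0L || length(arm_b) == 0L) {
    stop("both arms must be non-empty", call. = FALSE)
  }
  if (length(intersect(arm_a, arm_b)) > 0L) {
    stop("arms overlap: ", paste(intersect(arm_a, arm_b), collapse = ", "),
         call. = FALSE)
  }
  check_conditions(x, c(arm_a, arm_b))
  m <- unclass(x)
  sa <- rownames(m)[rowSums(m[, arm_a, drop = FALSE]) > 0L]
  sb <- rownames(m)[rowSums(m[, arm_b, drop = FALSE]) > 0L]
  shared <- length(intersect(sa, sb))
  spec_a <- length(setdiff(sa, sb))
  spec_b <- length(setdiff(sb, sa))
  test <- if (spec_a + spec_b == 0L) {
    structure(list(table = matrix(c(0L, 0L, shared, shared), 2L, 2L),
                   chi2 = 0, df = 1L, p_value = 1, correction = correction),
              class = "contingency_result")
  } else {
    pearson_chi2(rbind(c(spec_a, shared), c(spec_b, shared)),
                 correction = correction)
  }
  structure(list(arm_a = arm_a, arm_b = arm_b,
                 richness_a = length(sa), richness_b = length(sb),
                 specific_a = spec_a, specific_b = spec_b, shared = shared,
                 species_a = sa, species_b = sb, test = test),
            class = "paired_contrast")
}

#' @export
print.paired_contrast <- function(x, ...) {
  cat(sprintf("Arm A (%d conditions): %d species (%d specific)\n",
              length(x$arm_a), x$richness_a, x$specific_a))
  cat(sprintf("Arm B (%d conditions): %d species (%d specific)\n",
              length(x$arm_b), x$richness_b, x$specific_b))
  cat(sprintf("Shared: %d species\n", x$shared))
  print(x$test)
  invisible(x)
}

#' Recovery-atmosphere by oxygen-phenotype cross-tabulation
#'
#' Assigns every species to exactly one recovery class — isolated under
#' anaerobic conditions only, aerobic conditions only, or both — by
#' taking the union over same-atmosphere conditions, and crosses that
#' against the species' oxygen phenotype (strict anaerobe, oxygen
#' tolerant, strict aerobe, unknown). Species lacking a phenotype are
#' counted under "unknown", never dropped. Marginal percentages are
#' rounded half-up.
#'
#' @param x an `incidence_matrix` whose condition metadata assigns every
#'   condition an `atmosphere` of "aerobic" or "anaerobic".
#' @return object of class `atmosphere_crosstab`: list with `table`
#'   (recovery class x phenotype counts), `recovery_counts`,
#'   `recovery_percent`, `atmosphere_union` (species count recovered under
#'   each atmosphere, with percentages), `total_species`.
#' @export
atmosphere_crosstab <- function(x) {
  stopifnot(inherits(x, "incidence_matrix"))
  cm <- condition_meta(x)
  bad <- !cm$atmosphere %in% c("aerobic", "anaerobic")
  if (any(bad)) {
    stop("condition(s) without a valid atmosphere attribute: ",
         paste(cm$id[bad], collapse = ", "), call. = FALSE)
  }
  m <- unclass(x)
  ana <- rowSums(m[, cm$id[cm$atmosphere == "anaerobic"], drop = FALSE]) > 0L
  aer <- rowSums(m[, cm$id[cm$atmosphere == "aerobic"], drop = FALSE]) > 0L
  class_lv <- c("anaerobic_only", "aerobic_only", "both")
  recovery <- factor(ifelse(ana & aer, "both",
                            ifelse(ana, "anaerobic_only", "aerobic_only")),
                     levels = class_lv)
  sm <- species_meta(x)
  phen <- sm$oxygen_phenotype
  phen[is.na(phen) | !nzchar(phen)] <- "unknown"
  phen_lv <- c("strict_anaerobe", "oxygen_tolerant", "strict_aerobe", "unknown")
  phen <- factor(ifelse(phen %in% phen_lv, phen, "unknown"), levels = phen_lv)
  tab <- table(recovery = recovery, phenotype = phen)
  total <- nrow(m)
  rec_counts <- stats::setNames(as.integer(table(recovery)), class_lv)
  structure(list(
    table = tab,
    recovery_counts = rec_counts,
    recovery_percent = round_half_up(100 * rec_counts / total),
    atmosphere_union = data.frame(
      atmosphere = c("anaerobic", "aerobic"),
      species = c(sum(ana), sum(aer)),
      percent = round_half_up(100 * c(sum(ana), sum(aer)) / total)),
    total_species = total), class = "atmosphere_crosstab")
}

#' @export
print.atmosphere_crosstab <- function(x, ...) {
  cat(sprintf("Atmosphere recovery of %d species:\n", x$total_species))
  print(x$atmosphere_union)
  cat("Recovery class x oxygen phenotype:\n")
  print(x$table)
  invisible(x)
}
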