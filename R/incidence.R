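#' Normalize species names
#'
#' Species identity throughout the package is normalized exact string match:
#' leading/trailing whitespace trimmed and internal runs of whitespace
#' collapsed to single spaces. Matching is case-insensitive (the first-seen
#' casing is kept as the canonical display form); no fuzzy synonym
#' resolution is attempted.
#'
#' @param x character vector of species names.
#' @return character vector of normalized names.
#' @export
normalize_species <- function(x) {
  gsub("[[:space:]]+", " ", trimws(as.character(x)))
}

species_key <- function(x) tolower(normalize_species(x))

## round half away from zero, the convention used for all printed percentages
round_half_up <- function(x) floor(x + 0.5)

default_condition_meta <- function(ids) {
  data.frame(
    id = ids,
    label = ids,
    atmosphere = "unknown",
    temperature_c = NA_real_,
    supplements = "none",
    pretreatment = "none",
    group = NA_character_,
    stringsAsFactors = FALSE
  )
}

default_species_meta <- function(names) {
  data.frame(
    name = names,
    phylum = "unknown",
    oxygen_phenotype = "unknown",
    is_new_taxon = FALSE,
    accession = NA_character_,
    stringsAsFactors = FALSE
  )
}

# Align a metadata table to the matrix's ids: unreferenced rows dropped with
# a warning, missing ids filled with defaults, original order of `ids` kept.
align_meta <- function(meta, ids, key_col, default_fun, what) {
  if (is.null(meta)) return(default_fun(ids))
  if (is.character(meta) && length(meta) == 1L) {
    meta <- utils::read.delim(meta, stringsAsFactors = FALSE,
                              check.names = FALSE)
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!key_col %in% names(meta)) {
    stop(sprintf("%s metadata lacks required column '%s'", what, key_col),
         call. = FALSE)
  }
  keys <- as.character(meta[[key_col]])
  if (identical(key_col, "name")) {
    keys <- species_key(keys)
    ids_key <- species_key(ids)
  } else {
    ids_key <- ids
  }
  unref <- setdiff(keys, ids_key)
  if (length(unref) > 0L) {
    warning(sprintf("%d %s metadata row(s) reference ids absent from the matrix and were ignored: %s",
                    length(unref), what,
                    paste(utils::head(unref, 5L), collapse = ", ")),
            call. = FALSE)
  }
  out <- default_fun(ids)
  hit <- match(ids_key, keys)
  for (col in setdiff(names(out), key_col)) {
    if (col %in% names(meta)) {
      vals <- meta[[col]][hit]
      keep <- !is.na(hit) & !is.na(vals)
      out[[col]][keep] <- vals[keep]
    }
  }
  if ("is_new_taxon" %in% names(out)) {
    out$is_new_taxon <- as.logical(out$is_new_taxon) %in% TRUE
  }
  if ("temperature_c" %in% names(out)) {
    out$temperature_c <- as.numeric(out$temperature_c)
  }
  out
}

#' Construct a species-by-condition incidence matrix
#'
#' The analysis substrate of the package: a binary matrix with one row per
#' bacterial species and one column per culture condition; cell 1 means the
#' species was isolated at least once under that condition. Duplicate
#' species rows (after name normalization) are merged by logical OR, as are
#' repeated detection records. A condition that grew nothing is legal and
#' kept with richness 0 (conditions are designed a priori); a species with
#' no detections is not (species exist only via isolation) and is rejected.
#'
#' @param x numeric/logical matrix or data.frame with species as rownames
#'   and condition ids as colnames; any value > 0 counts as detected.
#' @param condition_meta optional condition metadata: a data.frame or path
#'   to a TSV with columns `id, label, atmosphere, temperature_c,
#'   supplements` (semicolon-separated list), `pretreatment, group`.
#'   Conditions absent from the table get default attributes
#'   (`unknown`/`none`); unreferenced metadata rows are dropped with a
#'   warning.
#' @param species_meta optional species metadata: a data.frame or path to a
#'   TSV with columns `name, phylum, oxygen_phenotype, is_new_taxon,
#'   accession`.
#' @return an object of class `incidence_matrix`: a 0/1 integer matrix with
#'   `condition_meta` and `species_meta` data.frame attributes.
#' @examples
#' m <- matrix(c(1, 1, 0, 1), 2, 2,
#'             dimnames = list(c("sp a", "sp b"), c("c1", "c2")))
#' im <- incidence_matrix(m)
#' richness(im)
#' @export
incidence_matrix <- function(x, condition_meta = NULL, species_meta = NULL) {
  m <- as.matrix(x)
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("incidence matrix needs species rownames and condition colnames",
         call. = FALSE)
  }
  if (anyNA(m)) stop("incidence matrix contains NA cells", call. = FALSE)
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("incidence cells must be non-negative", call. = FALSE)
  m <- (m > 0) + 0L
  storage.mode(m) <- "integer"

  rn <- normalize_species(rownames(m))
  if (any(!nzchar(rn))) stop("empty species name", call. = FALSE)
  if (any(!nzchar(colnames(m)))) stop("empty condition id", call. = FALSE)
  if (anyDuplicated(colnames(m))) {
    stop("duplicate condition ids: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "),
         call. = FALSE)
  }
  key <- tolower(rn)
  if (anyDuplicated(key)) {
    first <- !duplicated(key)
    merged <- rowsum(m, group = key)                       # counts per key
    merged <- (merged[match(key[first], rownames(merged)), , drop = FALSE] > 0) + 0L
    rownames(merged) <- rn[first]
    m <- merged
    storage.mode(m) <- "integer"
  } else {
    rownames(m) <- rn
  }

  empty <- rowSums(m) == 0L
  if (any(empty)) {
    stop("species with zero incidences are not allowed: ",
         paste(utils::head(rownames(m)[empty], 10L), collapse = ", "),
         call. = FALSE)
  }

  dimnames(m) <- list(rownames(m), colnames(m))  # drop dimnames names
  structure(
    m,
    condition_meta = align_meta(condition_meta, colnames(m), "id",
                                default_condition_meta, "condition"),
    species_meta = align_meta(species_meta, rownames(m), "name",
                              default_species_meta, "species"),
    class = c("incidence_matrix", "matrix", "array")
  )
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat(sprintf("Incidence matrix: %d species x %d conditions, %d detections\n",
              nrow(x), ncol(x), sum(x)))
  atm <- table(condition_meta(x)$atmosphere)
  cat("Atmospheres:", paste(names(atm), atm, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Condition and species metadata accessors
#'
#' @param x an `incidence_matrix`.
#' @return the metadata data.frame carried by the matrix.
#' @export
condition_meta <- function(x) attr(x, "condition_meta")

#' @rdname condition_meta
#' @export
species_meta <- function(x) attr(x, "species_meta")

check_conditions <- function(x, ids) {
  missing <- setdiff(ids, colnames(x))
  if (length(missing) > 0L) {
    stop("unknown condition id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Per-condition species richness
#'
#' Richness of a culture condition is the number of distinct species it
#' isolated — the quantity conditions are ranked by when evaluating their
#' profitability.
#'
#' @param x an `incidence_matrix`.
#' @param condition optional condition id (or vector of ids); if omitted,
#'   richness of every condition is returned.
#' @return named integer vector of species counts.
#' @export
richness <- function(x, condition = NULL) {
  stopifnot(inherits(x, "incidence_matrix"))
  if (is.null(condition)) return(colSums(unclass(x)))
  check_conditions(x, condition)
  colSums(unclass(x)[, condition, drop = FALSE])
}

read_table_checked <- function(path, sep, required, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) {
    stop("empty input file: ", path, call. = FALSE)
  }
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read an incidence matrix from long-format TSV
#'
#' The canonical interchange format: a UTF-8 TSV with header and columns
#' `species` and `condition`, one detection record per row (an optional
#' `count` column is ignored beyond presence). Duplicate records collapse
#' to a single detection.
#'
#' @param path path to the long-format TSV.
#' @param condition_meta,species_meta optional metadata tables or TSV paths
#'   (see [incidence_matrix()]).
#' @return an `incidence_matrix`.
#' @export
read_long_tsv <- function(path, condition_meta = NULL, species_meta = NULL) {
  df <- read_table_checked(path, "\t", c("species", "condition"), "long TSV")
  if (nrow(df) == 0L) stop("long TSV has a header but no records", call. = FALSE)
  sp <- normalize_species(df$species)
  cond <- as.character(df$condition)
  m <- table(factor(species_key(sp), levels = unique(species_key(sp))),
             factor(cond, levels = unique(cond)))
  m <- (unclass(m) > 0) + 0L
  rownames(m) <- sp[!duplicated(species_key(sp))]
  incidence_matrix(m, condition_meta = condition_meta,
                   species_meta = species_meta)
}

#' Read an incidence matrix from wide CSV
#'
#' Wide spreadsheet layout: first column `species`, remaining columns one
#' per condition id, cells 0/1.
#'
#' @inheritParams read_long_tsv
#' @return an `incidence_matrix`.
#' @export
read_wide_csv <- function(path, condition_meta = NULL, species_meta = NULL) {
  df <- read_table_checked(path, ",", "species", "wide CSV")
  if (ncol(df) < 2L) {
    stop("wide CSV needs at least one condition column", call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$species
  incidence_matrix(m, condition_meta = condition_meta,
                   species_meta = species_meta)
}

#' Write an incidence matrix
#'
#' `write_wide_csv()` writes the wide 0/1 CSV; `write_long_tsv()` writes
#' one `species<TAB>condition` record per detection. Both round-trip
#' losslessly through their readers (metadata is written separately with
#' [write_metadata()]).
#'
#' @param x an `incidence_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wide_csv <- function(x, path) {
  stopifnot(inherits(x, "incidence_matrix"))
  df <- data.frame(species = rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_wide_csv
#' @export
write_long_tsv <- function(x, path) {
  stopifnot(inherits(x, "incidence_matrix"))
  idx <- which(unclass(x) == 1L, arr.ind = TRUE)
  df <- data.frame(species = rownames(x)[idx[, 1]],
                   condition = colnames(x)[idx[, 2]],
                   stringsAsFactors = FALSE)
  df <- df[order(match(df$species, rownames(x)),
                 match(df$condition, colnames(x))), ]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the condition and species metadata of a matrix as TSV
#'
#' @param x an `incidence_matrix`.
#' @param condition_path,species_path output TSV paths (either may be NULL
#'   to skip).
#' @return invisibly, a character vector of the paths written.
#' @export
write_metadata <- function(x, condition_path = NULL, species_path = NULL) {
  stopifnot(inherits(x, "incidence_matrix"))
  written <- character()
  if (!is.null(condition_path)) {
    utils::write.table(condition_meta(x), condition_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    written <- c(written, condition_path)
  }
  if (!is.null(species_path)) {
    utils::write.table(species_meta(x), species_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    written <- c(written, species_path)
  }
  invisible(written)
}
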