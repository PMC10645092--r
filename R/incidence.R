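#' Construct a watershed incidence matrix
#'
#' An incidence matrix records which fish species (rows) occur in which lakes
#' (columns) of one watershed, as 0/1 presences. It is the unit at which the
#' null-model analysis runs: row totals are species occupancies, column totals
#' are lake richnesses, and both are held fixed by the null model.
#'
#' @param x binary matrix (species x lakes) with species ids as rownames and
#'   lake ids as colnames, or something coercible to one.
#' @param watershed_id single string identifying the watershed.
#' @param drop_empty drop species rows with no occurrences (with a warning)?
#'   A species counts as present in the watershed only if it occurs in at
#'   least one lake.
#' @return An `incidence_matrix`: an integer matrix with a `watershed_id`
#'   attribute.
#' @examples
#' m <- incidence_matrix(rbind(a = c(1, 0, 1), b = c(0, 1, 1)), "ws1")
#' rowSums(m)
#' @export
incidence_matrix <- function(x, watershed_id, drop_empty = TRUE) {
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("incidence matrix needs species rownames and lake colnames")
  }
  if (!is.character(watershed_id) || length(watershed_id) != 1L || is.na(watershed_id)) {
    stop("'watershed_id' must be a single string")
  }
  storage.mode(x) <- "integer"
  bad <- which(is.na(x) | !(x == 0L | x == 1L), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "non-binary cell in watershed '%s': species '%s', lake '%s'",
      watershed_id, rownames(x)[bad[1L, 1L]], colnames(x)[bad[1L, 2L]]
    ))
  }
  if (anyDuplicated(rownames(x))) {
    stop(sprintf("duplicate species id in watershed '%s': %s", watershed_id,
                 paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", ")))
  }
  if (anyDuplicated(colnames(x))) {
    stop(sprintf("duplicate lake id in watershed '%s': %s", watershed_id,
                 paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", ")))
  }
  if (drop_empty) {
    empty <- rowSums(x) == 0L
    if (any(empty)) {
      warning(sprintf(
        "watershed '%s': dropping %d species with no occurrences: %s",
        watershed_id, sum(empty), paste(rownames(x)[empty], collapse = ", ")
      ))
      x <- x[!empty, , drop = FALSE]
    }
  }
  structure(x, watershed_id = watershed_id,
            class = c("incidence_matrix", class(matrix())))
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat(sprintf("Incidence matrix for watershed '%s': %d species x %d lakes, fill %.2f\n",
              watershed_id(x), nrow(x), ncol(x), mean(x)))
  invisible(x)
}

#' Watershed id of an incidence matrix
#' @param x an `incidence_matrix`.
#' @return The watershed id string.
#' @export
watershed_id <- function(x) attr(x, "watershed_id")

#' Read watershed incidence matrices from CSV
#'
#' Each watershed is one CSV with a leading `species_id` column and one column
#' per lake; cells are 0/1. `path` may be a directory (every `*.csv` inside is
#' one watershed, named after the file) or a two-column manifest CSV with
#' columns `watershed_id,path` (paths resolved relative to the manifest).
#'
#' @param path directory of incidence CSVs, or a manifest CSV.
#' @return List of [incidence_matrix()] objects, named by watershed id.
#'   All-zero species rows are dropped with a warning; non-binary cells and
#'   duplicate ids are errors naming the offending file and cell.
#' @export
read_incidence <- function(path) {
  if (length(path) != 1L || !is.character(path)) stop("'path' must be a single path")
  if (!file.exists(path)) stop(sprintf("input path does not exist: '%s'", path))
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
    if (length(files) == 0L) stop(sprintf("no .csv files found in directory '%s'", path))
    ids <- sub("\\.csv$", "", basename(files))
  } else {
    man <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (!all(c("watershed_id", "path") %in% names(man))) {
      stop(sprintf("manifest '%s' must have columns watershed_id,path", path))
    }
    ids <- as.character(man$watershed_id)
    files <- ifelse(grepl("^(/|[A-Za-z]:)", man$path), man$path,
                    file.path(dirname(path), man$path))
    missing <- !file.exists(files)
    if (any(missing)) {
      stop(sprintf("manifest '%s': missing incidence files: %s", path,
                   paste(files[missing], collapse = ", ")))
    }
  }
  if (anyDuplicated(ids)) stop("duplicate watershed ids in input")
  out <- vector("list", length(files))
  names(out) <- ids
  for (i in seq_along(files)) {
    out[[i]] <- read_incidence_csv(files[i], ids[i])
  }
  out
}

read_incidence_csv <- function(file, watershed_id) {
  df <- read.csv(file, stringsAsFactors = FALSE, check.names = FALSE,
                 colClasses = "character")
  if (names(df)[1L] != "species_id") {
    stop(sprintf("'%s': first column must be 'species_id'", file))
  }
  species <- df[[1L]]
  lakes <- names(df)[-1L]
  cells <- as.matrix(df[, -1L, drop = FALSE])
  parsed <- suppressWarnings(as.numeric(cells))
  bad <- which(is.na(parsed) | !(parsed %in% c(0, 1)))
  if (length(bad) > 0L) {
    ij <- arrayInd(bad[1L], dim(cells))
    stop(sprintf("'%s': non-binary value '%s' at species '%s', lake '%s'",
                 file, cells[bad[1L]], species[ij[1L, 1L]], lakes[ij[1L, 2L]]))
  }
  m <- matrix(as.integer(parsed), nrow = length(species),
              dimnames = list(species, lakes))
  incidence_matrix(m, watershed_id)
}

#' Write an incidence matrix to CSV
#'
#' Inverse of [read_incidence()]: first column `species_id`, one column per
#' lake, 0/1 cells.
#'
#' @param x an `incidence_matrix`.
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
write_incidence <- function(x, file) {
  stopifnot(inherits(x, "incidence_matrix"))
  df <- data.frame(species_id = rownames(x), unclass(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Retain watersheds large enough to randomize
#'
#' Watersheds with fewer than `min_lakes` lakes or fewer than `min_species`
#' species are removed, so every retained incidence matrix has at least a
#' 20 x 20 block to randomize under the fixed-fixed null (the defaults).
#' Species counts are taken after all-zero rows have been dropped, i.e. only
#' species actually occurring in the watershed count.
#'
#' @param matrices list of [incidence_matrix()] objects.
#' @param min_lakes,min_species minimum lake and species counts (inclusive).
#' @return The retained sublist; the decision per watershed is reported via
#'   `message()`. An empty result is an error.
#' @export
filter_watersheds <- function(matrices, min_lakes = 20L, min_species = 20L) {
  stopifnot(is.list(matrices), length(matrices) > 0L)
  keep <- vapply(matrices, function(m) {
    ok <- nrow(m) >= min_species && ncol(m) >= min_lakes
    message(sprintf("watershed '%s': %d species x %d lakes -> %s",
                    watershed_id(m), nrow(m), ncol(m),
                    if (ok) "retained" else "removed"))
    ok
  }, logical(1L))
  out <- matrices[keep]
  if (length(out) == 0L) {
    stop(sprintf("no watershed satisfies >= %d lakes and >= %d species",
                 min_lakes, min_species))
  }
  out
}

#' Check that every occurring species has complete traits
#'
#' @param matrices list of retained incidence matrices.
#' @param traits a complete (post-imputation) trait table.
#' @return `list(matrices, traits)` unchanged; species occurring in any
#'   matrix but missing from the trait table are a hard error listing them.
#' @export
check_coverage <- function(matrices, traits) {
  if (!is.list(matrices) || length(matrices) == 0L) {
    stop("no incidence matrices to check")
  }
  occurring <- unique(unlist(lapply(matrices, rownames)))
  missing <- setdiff(occurring, traits$species_id)
  if (length(missing) > 0L) {
    stop(sprintf("species without trait records: %s",
                 paste(sort(missing), collapse = ", ")))
  }
  incomplete <- traits$species_id[
    traits$species_id %in% occurring &
      (is.na(traits$body_size) | is.na(traits$temp_pref) | is.na(traits$trophic_level))
  ]
  if (length(incomplete) > 0L) {
    stop(sprintf("species with incomplete trait values (impute first?): %s",
                 paste(sort(incomplete), collapse = ", ")))
  }
  list(matrices = matrices, traits = traits)
}
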