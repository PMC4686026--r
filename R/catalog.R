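#' Construct a haplotype catalog
#'
#' A haplotype catalog records, for each named haplotype, its nucleotide (or
#' gap) state at every polymorphic alignment column, using 1-based column
#' coordinates. It is the tabular analogue of a published polymorphic-site
#' table: one row per haplotype, one column per variable site, all invariant
#' columns omitted.
#'
#' @param names Character vector of unique haplotype labels.
#' @param positions Strictly increasing integer vector of 1-based alignment
#'   columns.
#' @param states Character matrix (`length(names)` rows,
#'   `length(positions)` columns) over the alphabet `A`, `C`, `G`, `T`, `-`.
#' @return A tibble of class `haplotype_catalog`: column `haplotype` plus one
#'   character column per position (column name = position).
#' @examples
#' haplotype_catalog(c("a", "b"), c(10L, 20L),
#'                   matrix(c("A", "G", "C", "C"), nrow = 2))
#' @export
haplotype_catalog <- function(names, positions, states) {
  states <- as.matrix(states)
  positions <- as.integer(positions)
  if (length(positions) == 0) abort("catalog needs at least one position")
  if (any(diff(positions) <= 0)) {
    abort("positions must be strictly increasing")
  }
  if (any(positions < 1)) abort("positions are 1-based and must be >= 1")
  if (anyDuplicated(names)) abort("haplotype names must be unique")
  if (nrow(states) != length(names) || ncol(states) != length(positions)) {
    abort("states must be a names x positions matrix")
  }
  bad <- setdiff(unique(as.vector(states)), c("A", "C", "G", "T", "-"))
  if (length(bad) > 0) {
    abort(paste0("illegal catalog state(s): ", paste(bad, collapse = ", "),
                 " (alphabet is A/C/G/T/-)"))
  }
  key <- apply(states, 1, paste, collapse = "")
  if (anyDuplicated(key)) {
    dup <- names[duplicated(key) | duplicated(key, fromLast = TRUE)]
    abort(paste0("haplotypes share identical state vectors: ",
                 paste(dup, collapse = ", ")))
  }
  out <- as_tibble(states, .name_repair = ~ as.character(positions))
  out <- dplyr::bind_cols(tibble(haplotype = as.character(names)), out)
  class(out) <- c("haplotype_catalog", class(out))
  out
}

#' @export
print.haplotype_catalog <- function(x, ...) {
  cat("# Haplotype catalog: ", nrow(x), " haplotypes x ",
      ncol(x) - 1L, " polymorphic positions\n", sep = "")
  NextMethod()
}

#' Catalog accessors
#'
#' `catalog_positions()` returns the 1-based polymorphic alignment columns;
#' `catalog_states()` the haplotype-by-position state matrix with haplotype
#' row names.
#'
#' @param catalog A [haplotype_catalog()].
#' @return An integer vector, or a character matrix.
#' @export
catalog_positions <- function(catalog) {
  as.integer(names(catalog)[-1])
}

#' @rdname catalog_positions
#' @export
catalog_states <- function(catalog) {
  m <- as.matrix(catalog[, -1, drop = FALSE])
  rownames(m) <- catalog$haplotype
  m
}

#' Read or write a polymorphic-site profile table
#'
#' The on-disk layout mirrors the printed table: a header row of 1-based
#' alignment positions, one row per haplotype, and the dot convention in
#' which `.` (or the typographic bullet `•`) means same-state-as the
#' first (reference) haplotype row. `-` is a real gap state, not a dot.
#' `write_profile_table()` re-compresses against the first row, so
#' read-write-read round-trips reproduce every state vector exactly.
#'
#' @param path Path to a tab-separated profile table.
#' @return `read_profile_table()`: a [haplotype_catalog()].
#'   `write_profile_table()`: `path`, invisibly.
#' @examples
#' cat_path <- system.file("extdata", "haplotype_profiles.tsv",
#'                         package = "mthaplostat")
#' lions <- read_profile_table(cat_path)
#' nrow(lions)           # 17 haplotypes
#' length(catalog_positions(lions))  # 31 polymorphic sites
#' @export
read_profile_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0) abort("profile table has no haplotype rows")
  positions <- suppressWarnings(as.integer(names(raw)[-1]))
  if (anyNA(positions)) abort("profile-table header must be integer positions")
  if (any(diff(positions) <= 0)) {
    abort("profile-table positions must be strictly increasing")
  }
  states <- as.matrix(raw[, -1, drop = FALSE])
  states[is.na(states)] <- "."
  states <- toupper(states)
  states[states == "•"] <- "."
  ref <- states[1, ]
  if (any(ref == ".")) abort("reference (first) row may not contain dots")
  for (j in seq_along(positions)) {
    states[states[, j] == ".", j] <- ref[j]
  }
  if (any(states == "N")) abort("'N' is not permitted in catalog profiles")
  haplotype_catalog(raw[[1]], positions, states)
}

#' @rdname read_profile_table
#' @param catalog A [haplotype_catalog()] to write.
#' @export
write_profile_table <- function(catalog, path) {
  m <- catalog_states(catalog)
  ref <- m[1, ]
  if (nrow(m) > 1) {
    for (i in 2:nrow(m)) {
      same <- m[i, ] == ref
      m[i, same] <- "."
    }
  }
  out <- as_tibble(m, .name_repair = ~ colnames(m))
  out <- dplyr::bind_cols(tibble(haplotype = catalog$haplotype), out)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' The packaged lion 12S-16S haplotype catalog
#'
#' Seventeen African-lion mitochondrial 12S-16S haplotypes (H1-H12 from the
#' range-wide literature, Z1-Z5 first observed in Zambia) over the 31
#' polymorphic columns of the 1882-column alignment. Subset with
#' `zambia_only = TRUE` to the eight haplotypes observed in Zambia
#' (H1, H9, H11, Z1-Z5).
#'
#' @param zambia_only If `TRUE`, restrict to the eight Zambian haplotypes.
#' @return A [haplotype_catalog()].
#' @examples
#' lion_haplotype_catalog(zambia_only = TRUE)$haplotype
#' @export
lion_haplotype_catalog <- function(zambia_only = FALSE) {
  path <- system.file("extdata", "haplotype_profiles.tsv",
                      package = "mthaplostat")
  cat <- read_profile_table(path)
  if (zambia_only) {
    keep <- cat$haplotype %in% c("H1", "H9", "H11", "Z1", "Z2", "Z3", "Z4", "Z5")
    cat <- cat[keep, ]
    class(cat) <- unique(c("haplotype_catalog", class(cat)))
  }
  cat
}

#' Expand a catalog profile onto a full-length background sequence
#'
#' Copies the background sequence and overwrites the catalog positions with
#' the haplotype's states. This is the inverse of haplotype calling: calling
#' the returned sequence against the same catalog recovers the haplotype
#' name.
#'
#' @param catalog A [haplotype_catalog()].
#' @param haplotype Name of the profile to expand.
#' @param background A single character string (the full-width aligned
#'   background); its width must cover the largest catalog position.
#' @return A character string of the same width as `background`.
#' @export
profile_to_sequence <- function(catalog, haplotype, background) {
  stopifnot(is.character(background), length(background) == 1)
  pos <- catalog_positions(catalog)
  if (nchar(background) < max(pos)) {
    abort(paste0("background width ", nchar(background),
                 " < max catalog position ", max(pos)))
  }
  i <- match(haplotype, catalog$haplotype)
  if (is.na(i)) abort(paste0("haplotype not in catalog: ", haplotype))
  chars <- strsplit(background, "", fixed = TRUE)[[1]]
  chars[pos] <- catalog_states(catalog)[i, ]
  paste(chars, collapse = "")
}
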