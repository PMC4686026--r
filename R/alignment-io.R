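#' Read an aligned multi-FASTA
#'
#' Reads a pre-aligned FASTA (single-line or wrapped records) into a tidy
#' alignment: one row per sample, all sequences the same width. Residues are
#' upper-cased and must come from the alphabet `A`, `C`, `G`, `T`, `-`, `N`.
#'
#' @param path Path to an aligned FASTA file.
#' @return A tibble of class `aligned_seqs` with columns `sample_id` and
#'   `sequence`, and attribute `n_columns` (the alignment width).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACGT-A", ">s2", "ACGTAA"), fa)
#' aln <- read_alignment(fa)
#' attr(aln, "n_columns")
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) abort("FASTA contains no records")
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sample id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  widths <- Biostrings::width(seqs)
  if (length(unique(widths)) > 1) {
    off <- ids[widths != widths[1]][1]
    abort(paste0("ragged alignment: record '", off, "' has width ",
                 widths[widths != widths[1]][1],
                 ", expected ", widths[1]))
  }
  sequence <- toupper(as.character(seqs))
  bad <- gsub("[ACGTN-]", "", sequence)
  if (any(nchar(bad) > 0)) {
    k <- which(nchar(bad) > 0)[1]
    sym <- substr(bad[k], 1, 1)
    at <- regexpr(sym, sequence[k], fixed = TRUE)
    abort(paste0("illegal residue '", sym, "' in record '", ids[k],
                 "' at column ", at))
  }
  new_alignment(ids, unname(sequence))
}

new_alignment <- function(ids, sequence) {
  stopifnot(length(ids) == length(sequence))
  width <- unique(nchar(sequence))
  stopifnot(length(width) == 1, width >= 1)
  out <- tibble(sample_id = as.character(ids), sequence = sequence)
  attr(out, "n_columns") <- as.integer(width)
  class(out) <- c("aligned_seqs", class(out))
  out
}

#' @export
print.aligned_seqs <- function(x, ...) {
  cat("# Aligned sequences: ", nrow(x), " samples x ",
      attr(x, "n_columns"), " columns\n", sep = "")
  NextMethod()
}

#' Alignment width
#'
#' @param aln An alignment from [read_alignment()] or [generate_study()].
#' @return Integer number of alignment columns.
#' @export
alignment_width <- function(aln) {
  w <- attr(aln, "n_columns")
  if (is.null(w)) w <- unique(nchar(aln$sequence))
  as.integer(w)
}

#' Write an aligned multi-FASTA
#'
#' @param aln An `aligned_seqs` tibble (columns `sample_id`, `sequence`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  x <- Biostrings::BStringSet(setNames(aln$sequence, aln$sample_id))
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read a sample-metadata table
#'
#' Tab-separated with a header; requires columns `sample_id` and `area`,
#' and optionally `region` and `sex`. Region, when absent, is derived from
#' the area code via [area_to_region()]; sex is normalised to `F`, `M` or
#' `U` (unknown).
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `sample_id`, `area`, `region`, `sex`.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- setdiff(c("sample_id", "area"), names(raw))
  if (length(need) > 0) {
    abort(paste0("metadata is missing column(s): ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(raw$sample_id)) {
    abort(paste0("duplicate sample_id(s): ",
                 paste(unique(raw$sample_id[duplicated(raw$sample_id)]),
                       collapse = ", ")))
  }
  bad <- setdiff(unique(raw$area), AREA_CODES)
  if (length(bad) > 0) {
    abort(paste0("unknown area code(s): ", paste(bad, collapse = ", ")))
  }
  region <- if ("region" %in% names(raw)) raw$region else NA_character_
  region <- ifelse(is.na(region), area_to_region(raw$area), region)
  derived <- area_to_region(raw$area)
  if (any(region != derived)) {
    abort("region column disagrees with the area-to-region mapping")
  }
  sex <- if ("sex" %in% names(raw)) raw$sex else NA_character_
  sex <- toupper(substr(ifelse(is.na(sex) | sex == "", "U", sex), 1, 1))
  sex[!sex %in% c("F", "M")] <- "U"
  tibble(sample_id = raw$sample_id, area = raw$area,
         region = region, sex = sex)
}

#' Write a sample-metadata table
#'
#' @param metadata A tibble with columns `sample_id`, `area`, `region`, `sex`.
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(metadata, path) {
  readr::write_tsv(metadata, path, progress = FALSE)
  invisible(path)
}
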