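#' Study sampling design
#'
#' The sampling design drives the synthetic-data generator: per
#' (area x sex x haplotype) sample counts, the alignment width, the
#' background nucleotide composition, and a per-site missingness (`N`)
#' rate. The packaged default reproduces the published Zambian lion
#' study design cell-for-cell: 165 samples (119 males, 45 females, 1 of
#' unknown sex) over five areas (LV 60, CO 14, ZA 3, KF 87, SI 1) and
#' eight haplotypes, on a 1882-column 12S-16S alignment whose background
#' composition matches the study's Zambian haplotypes
#' (C 22.11%, T 22.67%, A 36.64%, G 18.58%).
#'
#' @param counts Long tibble with columns `haplotype`, `area`, `sex`, `n`,
#'   or `NULL` for the packaged default design.
#' @param width Alignment width in columns (default 1882).
#' @param composition Named proportions for `C`, `T`, `A`, `G` background
#'   columns; must sum to 1.
#' @param noise Per-site probability that a non-diagnostic column of a
#'   sample is masked to `N` (default 0).
#' @param noise_diagnostic If `TRUE`, noise may also hit catalog
#'   (diagnostic) columns; by default those stay clean so haplotype calls
#'   are exact.
#' @return A list of class `study_design`.
#' @examples
#' d <- study_design()
#' sum(d$counts$n)  # 165
#' @export
study_design <- function(counts = NULL, width = 1882,
                         composition = c(C = 0.2211, T = 0.2267,
                                         A = 0.3664, G = 0.1858),
                         noise = 0, noise_diagnostic = FALSE) {
  if (is.null(counts)) {
    counts <- design_from_table(system.file("extdata", "study_design.tsv",
                                            package = "mthaplostat"))$counts
  }
  need <- setdiff(c("haplotype", "area", "sex", "n"), names(counts))
  if (length(need) > 0) {
    abort(paste0("design counts need column(s): ", paste(need, collapse = ", ")))
  }
  if (any(counts$n < 0)) abort("design counts must be non-negative")
  if (sum(counts$n) == 0) abort("design has no samples")
  stopifnot(all(sort(names(composition)) == c("A", "C", "G", "T")))
  if (abs(sum(composition) - 1) > 1e-9) abort("composition must sum to 1")
  if (noise < 0 || noise > 1) abort("noise must be in [0, 1]")
  area_to_region(unique(counts$area))  # validates area codes
  structure(list(counts = as_tibble(counts), width = as.integer(width),
                 composition = composition, noise = noise,
                 noise_diagnostic = isTRUE(noise_diagnostic)),
            class = "study_design")
}

#' Read a sampling design from a counts table
#'
#' Rows are haplotypes; columns are `<area>_<sex>` cells (e.g. `LV_F`,
#' `KF_M`, `ZA_U`) holding sample counts, as in the published study's
#' sample table.
#'
#' @param path TSV with a `haplotype` column plus `<area>_<sex>` count
#'   columns.
#' @inheritParams study_design
#' @return A `study_design` list.
#' @export
design_from_table <- function(path, width = 1882,
                              composition = c(C = 0.2211, T = 0.2267,
                                              A = 0.3664, G = 0.1858),
                              noise = 0, noise_diagnostic = FALSE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(
    haplotype = "c", .default = "i"), progress = FALSE)
  if (nrow(raw) == 0 || ncol(raw) < 2) abort("malformed design table")
  if (!"haplotype" %in% names(raw)) abort("design table needs a 'haplotype' column")
  long <- tidyr::pivot_longer(raw, -"haplotype",
                              names_to = c("area", "sex"), names_sep = "_",
                              values_to = "n")
  long <- filter(long, .data$n > 0)
  if (nrow(long) == 0) abort("design table has no positive counts")
  study_design(counts = long, width = width, composition = composition,
               noise = noise, noise_diagnostic = noise_diagnostic)
}

#' Generate a synthetic study dataset
#'
#' Emulates the study's data shape without any sequence download: one
#' random background sequence is drawn from the design's nucleotide
#' composition, each sample's sequence is the background with its
#' haplotype's catalog states written in at the catalog positions
#' ([profile_to_sequence()]), and optional per-site `N` noise is applied
#' outside the diagnostic columns (or everywhere with
#' `noise_diagnostic = TRUE`). Haplotypes therefore differ only at catalog
#' columns, which fixes every downstream statistic exactly at its
#' design value. Fully reproducible from `seed`.
#'
#' @param design A [study_design()] (default: the packaged study design).
#' @param seed Integer seed.
#' @param catalog A [haplotype_catalog()] containing every haplotype named
#'   in the design (default [lion_haplotype_catalog()]).
#' @return A list of class `study_data`: `alignment` (an `aligned_seqs`
#'   tibble), `metadata` (sample table), `catalog`, and `background`.
#' @examples
#' study <- generate_study(seed = 1)
#' nrow(study$alignment)  # 165
#' @export
generate_study <- function(design = study_design(), seed = 1,
                           catalog = lion_haplotype_catalog()) {
  stopifnot(inherits(design, "study_design"))
  missing_h <- setdiff(unique(design$counts$haplotype), catalog$haplotype)
  if (length(missing_h) > 0) {
    abort(paste0("design haplotype(s) not in catalog: ",
                 paste(missing_h, collapse = ", ")))
  }
  pos <- catalog_positions(catalog)
  if (design$width < max(pos)) {
    abort(paste0("alignment width ", design$width,
                 " < max catalog position ", max(pos)))
  }
  withr::with_seed(as.integer(seed), {
    background <- paste(
      sample(names(design$composition), design$width, replace = TRUE,
             prob = design$composition),
      collapse = "")
    per_hap <- setNames(
      vapply(unique(design$counts$haplotype),
             function(h) profile_to_sequence(catalog, h, background),
             character(1)),
      unique(design$counts$haplotype))
    rows <- design$counts[rep(seq_len(nrow(design$counts)),
                              design$counts$n), ]
    n_total <- nrow(rows)
    ids <- sprintf("ZMB%03d", seq_len(n_total))
    sequence <- unname(per_hap[rows$haplotype])
    if (design$noise > 0) {
      open <- if (design$noise_diagnostic) seq_len(design$width) else
        setdiff(seq_len(design$width), pos)
      sequence <- vapply(sequence, function(s) {
        hit <- open[stats::runif(length(open)) < design$noise]
        if (length(hit) > 0) {
          ch <- strsplit(s, "", fixed = TRUE)[[1]]
          ch[hit] <- "N"
          s <- paste(ch, collapse = "")
        }
        s
      }, character(1), USE.NAMES = FALSE)
    }
    metadata <- tibble(sample_id = ids, area = rows$area,
                       region = area_to_region(rows$area), sex = rows$sex)
    structure(list(alignment = new_alignment(ids, sequence),
                   metadata = metadata, catalog = catalog,
                   background = background, seed = as.integer(seed),
                   design = design),
              class = "study_data")
  })
}

#' @export
print.study_data <- function(x, ...) {
  cat("# Synthetic study dataset: ", nrow(x$alignment), " samples x ",
      alignment_width(x$alignment), " columns (seed ", x$seed, ")\n", sep = "")
  print(count(x$metadata, .data$area, .data$region))
  invisible(x)
}
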