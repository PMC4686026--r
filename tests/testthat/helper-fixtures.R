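# Shared fixtures, built in code.

# Published per-area haplotype counts (the study's sample table).
table1_area_counts <- function() {
  list(
    LV = c(H9 = 1, H11 = 19, Z1 = 40),
    CO = c(H11 = 8, Z1 = 6),
    ZA = c(H11 = 1, Z1 = 1, Z2 = 1),
    KF = c(H1 = 1, H9 = 59, H11 = 1, Z1 = 4, Z3 = 15, Z4 = 2, Z5 = 5),
    SI = c(H9 = 1))
}

table1_all_counts <- function() {
  c(H1 = 1, H9 = 61, H11 = 29, Z1 = 51, Z2 = 1, Z3 = 15, Z4 = 2, Z5 = 5)
}

# Expand per-area counts into a per-sample tibble with region labels.
table1_samples <- function() {
  areas <- table1_area_counts()
  purrr::imap_dfr(areas, function(cn, area) {
    tibble::tibble(haplotype = rep(names(cn), cn), area = area)
  }) |>
    dplyr::mutate(region = area_to_region(area),
                  sample_id = sprintf("S%03d", dplyr::row_number()))
}

# A tiny 3-haplotype catalog over 4 positions, for contract tests.
tiny_catalog <- function() {
  haplotype_catalog(
    c("a", "b", "c"), c(5L, 9L, 12L, 20L),
    matrix(c("A", "C", "G", "T",
             "A", "T", "G", "T",
             "A", "T", "G", "-"),
           nrow = 3, byrow = TRUE))
}

write_tmp_fasta <- function(records, width_wrap = NULL) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  lines <- unlist(purrr::imap(records, ~ c(paste0(">", .y), .x)))
  writeLines(lines, path)
  path
}

random_counts <- function(n_haps = 5, max_n = 30) {
  cn <- stats::rpois(n_haps, lambda = max_n / 2) + 1
  stats::setNames(cn, paste0("h", seq_len(n_haps)))
}
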