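state_matrix <- function(x) {
  if (inherits(x, "haplotype_catalog")) {
    m <- catalog_states(x)
    attr(m, "positions") <- catalog_positions(x)
  } else if (inherits(x, "aligned_seqs") ||
             (is.data.frame(x) && all(c("sample_id", "sequence") %in% names(x)))) {
    m <- do.call(rbind, strsplit(x$sequence, "", fixed = TRUE))
    rownames(m) <- x$sample_id
    attr(m, "positions") <- seq_len(ncol(m))
  } else {
    abort("expected a haplotype_catalog or an aligned_seqs tibble")
  }
  m
}

#' Find polymorphic alignment columns
#'
#' A column is polymorphic when at least two distinct non-`N` states occur
#' in it. Works on a full alignment or directly on a haplotype catalog
#' (whose columns are, by construction, the candidate sites).
#'
#' @param x An `aligned_seqs` tibble or a [haplotype_catalog()].
#' @return A tibble with one row per polymorphic column: `position`
#'   (1-based) and `states` (list column of the distinct non-`N` states,
#'   sorted).
#' @examples
#' sites <- find_polymorphic_sites(lion_haplotype_catalog(zambia_only = TRUE))
#' nrow(sites)  # 16
#' @export
find_polymorphic_sites <- function(x) {
  m <- state_matrix(x)
  if (nrow(m) < 2) {
    abort("polymorphism is undefined for fewer than 2 sequences")
  }
  positions <- attr(m, "positions")
  states <- apply(m, 2, function(col) sort(unique(col[col != "N"])),
                  simplify = FALSE)
  poly <- lengths(states) >= 2
  tibble(position = as.integer(positions[poly]),
         states = unname(states[poly]))
}

#' Classify polymorphic columns
#'
#' Assigns each polymorphic column exactly one class: a column in which any
#' haplotype carries a gap is an `indel`; otherwise a column whose states
#' include a purine-pyrimidine pair is a `transversion`; otherwise (all
#' differences purine-purine or pyrimidine-pyrimidine) a `transition`.
#' Indel columns are counted per column, so a two-column deletion
#' contributes two indels.
#'
#' @param sites Output of [find_polymorphic_sites()].
#' @return `sites` with an added `class` column. Use
#'   [polymorphism_counts()] to tally classes.
#' @examples
#' sites <- find_polymorphic_sites(lion_haplotype_catalog(zambia_only = TRUE))
#' polymorphism_counts(classify_polymorphisms(sites))
#' @export
classify_polymorphisms <- function(sites) {
  purine <- c("A", "G")
  pyrimidine <- c("C", "T")
  cls <- purrr::map_chr(sites$states, function(s) {
    if ("-" %in% s) return("indel")
    if (any(s %in% purine) && any(s %in% pyrimidine)) return("transversion")
    "transition"
  })
  mutate(sites, class = cls)
}

#' @rdname classify_polymorphisms
#' @export
polymorphism_counts <- function(sites) {
  if (!"class" %in% names(sites)) sites <- classify_polymorphisms(sites)
  tibble(n_sites = nrow(sites),
         n_transitions = sum(sites$class == "transition"),
         n_transversions = sum(sites$class == "transversion"),
         n_indels = sum(sites$class == "indel"))
}

next_novel_index <- function(names, prefix) {
  pat <- paste0("^", prefix, "([0-9]+)$")
  hits <- grep(pat, names, value = TRUE)
  if (length(hits) == 0) return(1L)
  max(as.integer(sub(pat, "\\1", hits))) + 1L
}

#' Call haplotypes against a catalog
#'
#' Each sample matches a catalog haplotype when its states at every catalog
#' position equal that haplotype's profile. `N` matches nothing: samples
#' carrying `N` at a diagnostic position cannot be resolved and raise an
#' error naming them (in the source study such samples were re-sequenced).
#' Non-matching samples that share a state vector are minted one new
#' haplotype name, numbered in first-seen sample order continuing from the
#' highest index already under `novel_prefix`. A novel haplotype observed
#' only once is flagged `needs_verification` — the study accepted novel
#' haplotypes outright only when seen two or more times, and confirmed
#' singletons by re-sequencing.
#'
#' @param aln An `aligned_seqs` tibble whose width covers the largest
#'   catalog position.
#' @param catalog A [haplotype_catalog()].
#' @param novel_prefix Prefix for minted haplotype names (default `"Z"`).
#' @return A list of class `haplotype_calls`: `assignments` (tibble with
#'   `sample_id`, `haplotype`, `is_novel`, `needs_verification`) and
#'   `catalog` (input catalog plus minted profiles). `tidy()` on the result
#'   returns the assignments.
#' @examples
#' study <- generate_study(seed = 1)
#' calls <- call_haplotypes(study$alignment, study$catalog)
#' dplyr::count(tidy(calls), haplotype)
#' @export
call_haplotypes <- function(aln, catalog, novel_prefix = "Z") {
  if (nrow(aln) == 0) abort("empty alignment")
  pos <- catalog_positions(catalog)
  if (alignment_width(aln) < max(pos)) {
    abort("alignment width does not cover the largest catalog position")
  }
  sm <- do.call(rbind, lapply(strsplit(aln$sequence, "", fixed = TRUE),
                              function(ch) ch[pos]))
  has_n <- apply(sm == "N", 1, any)
  if (any(has_n)) {
    abort(paste0("unresolvable call: 'N' at a diagnostic position in ",
                 "sample(s) ", paste(aln$sample_id[has_n], collapse = ", "),
                 "; drop or re-sequence them"))
  }
  keys <- apply(sm, 1, paste, collapse = "")
  cat_keys <- apply(catalog_states(catalog), 1, paste, collapse = "")
  hit <- match(keys, cat_keys)
  name <- catalog$haplotype[hit]

  is_novel <- is.na(hit)
  out_catalog <- catalog
  if (any(is_novel)) {
    novel_keys <- unique(keys[is_novel])  # first-seen order
    idx <- next_novel_index(catalog$haplotype, novel_prefix)
    minted <- setNames(paste0(novel_prefix, seq_along(novel_keys) + idx - 1L),
                       novel_keys)
    name[is_novel] <- minted[keys[is_novel]]
    new_states <- do.call(rbind, strsplit(novel_keys, "", fixed = TRUE))
    out_catalog <- haplotype_catalog(
      c(catalog$haplotype, unname(minted)),
      pos,
      rbind(catalog_states(catalog), new_states))
  }
  seen <- table(name)
  assignments <- tibble(
    sample_id = aln$sample_id,
    haplotype = name,
    is_novel = is_novel,
    needs_verification = is_novel & unname(as.vector(seen[name]) == 1L))
  structure(list(assignments = assignments, catalog = out_catalog),
            class = "haplotype_calls")
}

#' @exportS3Method generics::tidy
tidy.haplotype_calls <- function(x, ...) x$assignments

#' @export
print.haplotype_calls <- function(x, ...) {
  a <- x$assignments
  cat("# Haplotype calls: ", nrow(a), " samples, ",
      length(unique(a$haplotype)), " haplotypes (",
      sum(a$is_novel), " sample(s) under novel names, ",
      sum(a$needs_verification), " needing verification)\n", sep = "")
  print(dplyr::count(a, .data$haplotype, sort = TRUE))
  invisible(x)
}
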