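#' @noRd
as_hap_counts <- function(data) {
  if (is.data.frame(data)) {
    if (all(c("haplotype", "n") %in% names(data))) {
      counts <- setNames(as.numeric(data$n), data$haplotype)
    } else if ("haplotype" %in% names(data)) {
      tab <- table(data$haplotype)
      counts <- setNames(as.numeric(tab), names(tab))
    } else {
      abort("data must have a 'haplotype' column (optionally with 'n' counts)")
    }
  } else if (is.numeric(data) && !is.null(names(data))) {
    counts <- data
  } else if (is.character(data)) {
    tab <- table(data)
    counts <- setNames(as.numeric(tab), names(tab))
  } else {
    abort("cannot interpret haplotype counts")
  }
  if (any(counts < 0)) abort("negative haplotype counts")
  counts[counts > 0]
}

hap_vector <- function(x) {
  if (is.data.frame(x)) {
    if (!"haplotype" %in% names(x)) abort("data must have a 'haplotype' column")
    as.character(x$haplotype)
  } else {
    as.character(x)
  }
}

#' Haplotype frequencies with sampling standard deviations
#'
#' Relative frequencies `f = n_h / n` with per-haplotype sampling standard
#' deviation `sqrt(f (1 - f) / (n - 1))` (0 when `n = 1`).
#'
#' @param data Per-sample tibble with a `haplotype` column (e.g. the
#'   assignments from [call_haplotypes()]), a tibble of `haplotype` and `n`
#'   counts, or a named count vector.
#' @return A tibble with columns `haplotype`, `n`, `f`, `sd`, one row per
#'   observed haplotype, sorted by decreasing count.
#' @examples
#' haplotype_frequencies(c(H9 = 61, Z1 = 51, H11 = 29))
#' @export
haplotype_frequencies <- function(data) {
  counts <- as_hap_counts(data)
  n <- sum(counts)
  if (n < 1) abort("need at least one sample")
  f <- counts / n
  sd <- if (n > 1) sqrt(f * (1 - f) / (n - 1)) else rep(0, length(f))
  out <- tibble(haplotype = names(counts), n = as.integer(counts),
                f = unname(f), sd = unname(sd))
  arrange(out, dplyr::desc(.data$n), .data$haplotype)
}

#' Unbiased gene diversity and its sampling variance
#'
#' Gene diversity `h = n (1 - sum p^2) / (n - 1)` — the probability that two
#' individuals sampled without replacement carry different haplotypes — with
#' sampling variance
#' `V = 2/(n(n-1)) * ( 2(n-2) (sum p^3 - (sum p^2)^2) + sum p^2 - (sum p^2)^2 )`.
#'
#' @inheritParams haplotype_frequencies
#' @return A one-row tibble: `n`, `n_haplotypes`, `h`, `sd`, and the audit
#'   sums `sum_p2`, `sum_p3`.
#' @examples
#' gene_diversity(c(H1 = 1, H9 = 61, H11 = 29, Z1 = 51,
#'                  Z2 = 1, Z3 = 15, Z4 = 2, Z5 = 5))
#' @export
gene_diversity <- function(data) {
  counts <- as_hap_counts(data)
  n <- sum(counts)
  if (n < 2) abort("gene diversity is undefined for n < 2")
  p <- counts / n
  sp2 <- sum(p^2)
  sp3 <- sum(p^3)
  h <- n * (1 - sp2) / (n - 1)
  V <- 2 / (n * (n - 1)) * (2 * (n - 2) * (sp3 - sp2^2) + sp2 - sp2^2)
  tibble(n = as.integer(n), n_haplotypes = length(counts),
         h = h, sd = sqrt(max(V, 0)), sum_p2 = sp2, sum_p3 = sp3)
}

#' Pairwise distance matrix between haplotypes
#'
#' In `pairwise_differences` mode the distance between two haplotypes is the
#' number of catalog columns at which their states differ (gap vs base
#' counts 1 per column; gap vs gap counts 0). In `identity` mode it is the
#' indicator of name inequality (0/1).
#'
#' @param catalog A [haplotype_catalog()].
#' @param mode `"pairwise_differences"` or `"identity"`.
#' @return A symmetric numeric matrix with haplotype dimnames and zero
#'   diagonal.
#' @examples
#' D <- pairwise_difference_matrix(lion_haplotype_catalog())
#' D["H11", "Z1"]  # 2
#' @export
pairwise_difference_matrix <- function(catalog,
                                       mode = c("pairwise_differences",
                                                "identity")) {
  mode <- match.arg(mode)
  m <- catalog_states(catalog)
  k <- nrow(m)
  D <- matrix(0, k, k, dimnames = list(rownames(m), rownames(m)))
  if (mode == "identity") {
    D[] <- 1
    diag(D) <- 0
  } else {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        D[i, j] <- D[j, i] <- sum(m[i, ] != m[j, ])
      }
    }
  }
  D
}

pair_sum <- function(cx, cy, D) {
  # sum over ordered cross pairs of delta, from per-haplotype counts
  hx <- names(cx); hy <- names(cy)
  sum(outer(cx, cy) * D[hx, hy, drop = FALSE])
}

#' Mean pairwise difference within a population
#'
#' The mean of the haplotype distance over all unordered sample pairs in one
#' population. Under identity distances this equals the unbiased gene
#' diversity of the same counts.
#'
#' @param data Per-sample haplotype labels: a tibble with a `haplotype`
#'   column or a character vector.
#' @param distances A matrix from [pairwise_difference_matrix()] covering
#'   every observed haplotype.
#' @return A single numeric value.
#' @examples
#' D <- pairwise_difference_matrix(lion_haplotype_catalog(), "identity")
#' mean_pairwise_within(rep(c("H9", "H11", "Z1"), c(1, 19, 40)), D)
#' @export
mean_pairwise_within <- function(data, distances) {
  counts <- as_hap_counts(hap_vector(data))
  n <- sum(counts)
  if (n < 2) abort("within-population mean needs n >= 2")
  pair_sum(counts, counts, distances) / 2 / choose(n, 2)
}

#' Between-population mean pairwise difference and Nei's distance
#'
#' `mean_pairwise_between()` averages the haplotype distance over all
#' cross-population sample pairs. `neis_distance()` is the corrected
#' (net) average pairwise difference
#' `d = pi_XY - (pi_X + pi_Y) / 2`, which is zero when both populations
#' share one haplotype composition.
#'
#' @param x,y Per-sample haplotype labels for the two populations (tibbles
#'   with a `haplotype` column, or character vectors).
#' @inheritParams mean_pairwise_within
#' @return A single numeric value.
#' @export
mean_pairwise_between <- function(x, y, distances) {
  cx <- as_hap_counts(hap_vector(x))
  cy <- as_hap_counts(hap_vector(y))
  if (sum(cx) < 1 || sum(cy) < 1) abort("both populations must be non-empty")
  pair_sum(cx, cy, distances) / (sum(cx) * sum(cy))
}

#' @rdname mean_pairwise_between
#' @export
neis_distance <- function(x, y, distances) {
  cx <- as_hap_counts(hap_vector(x))
  cy <- as_hap_counts(hap_vector(y))
  if (identical(cx[sort(names(cx))], cy[sort(names(cy))])) {
    # a population against itself (or an identical composition): self-pairs
    # are excluded, so the cross term equals the within term and d is 0
    return(0)
  }
  pxy <- mean_pairwise_between(x, y, distances)
  pxy - (mean_pairwise_within(x, distances) +
           mean_pairwise_within(y, distances)) / 2
}

#' Nucleotide diversity
#'
#' Mean per-site pairwise difference within a population: the within-
#' population mean pairwise difference (in `pairwise_differences` mode)
#' divided by the alignment width.
#'
#' @inheritParams mean_pairwise_within
#' @param n_columns Alignment width (number of sites).
#' @return A single numeric value.
#' @export
nucleotide_diversity <- function(data, distances, n_columns) {
  if (n_columns < 1) abort("n_columns must be >= 1")
  mean_pairwise_within(data, distances) / n_columns
}

#' Within/between pairwise-difference summary for a set of populations
#'
#' The classic triangular summary: for every population pair the mean
#' between-population pairwise difference and Nei's corrected distance d,
#' and for every population the within-population mean. Populations of one
#' sample have no within-term and yield `NA` for `d` of their pairs.
#'
#' @param data Per-sample tibble with `haplotype` and the grouping column.
#' @param distances Matrix from [pairwise_difference_matrix()].
#' @param group Name of the grouping column (default `"area"`).
#' @return A tibble: `pop_x`, `pop_y`, `n_x`, `n_y`, `pi` (within when
#'   `pop_x == pop_y`), `d` (`NA` on the diagonal).
#' @export
population_distance_summary <- function(data, distances, group = "area") {
  if (!group %in% names(data)) abort(paste0("no column '", group, "' in data"))
  pops <- split(data$haplotype, data[[group]])
  nm <- names(pops)
  grid <- tidyr::expand_grid(pop_x = nm, pop_y = nm)
  grid <- filter(grid, match(.data$pop_x, nm) <= match(.data$pop_y, nm))
  purrr::pmap_dfr(grid, function(pop_x, pop_y) {
    x <- pops[[pop_x]]; y <- pops[[pop_y]]
    if (pop_x == pop_y) {
      pi <- if (length(x) >= 2) mean_pairwise_within(x, distances) else NA_real_
      d <- NA_real_
    } else {
      pi <- mean_pairwise_between(x, y, distances)
      d <- if (length(x) >= 2 && length(y) >= 2) {
        neis_distance(x, y, distances)
      } else {
        NA_real_
      }
    }
    tibble(pop_x = pop_x, pop_y = pop_y,
           n_x = length(x), n_y = length(y), pi = pi, d = d)
  })
}
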