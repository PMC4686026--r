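identity_distances <- function(haplotypes) {
  h <- sort(unique(haplotypes))
  D <- matrix(1, length(h), length(h), dimnames = list(h, h))
  diag(D) <- 0
  D
}

# Core decomposition from a haplotype-by-population count table. Entries of
# D are used directly as squared inter-individual distances (molecular-data
# convention), so SSD_total = (1/2N) * sum over ordered pairs of delta.
amova_core <- function(M, D) {
  Np <- colSums(M)
  N <- sum(Np)
  P <- ncol(M)
  tot <- rowSums(M)
  qf <- function(v) as.numeric(t(v) %*% D[names(v), names(v)] %*% v)
  v_tot <- setNames(tot, rownames(M))
  SSD_total <- qf(v_tot) / (2 * N)
  SSD_within <- sum(vapply(seq_len(P), function(p) {
    v <- setNames(M[, p], rownames(M))
    qf(v) / (2 * Np[p])
  }, numeric(1)))
  SSD_among <- SSD_total - SSD_within
  df_among <- P - 1
  df_within <- N - P
  Vb <- SSD_within / df_within
  n_prime <- (N - sum(Np^2) / N) / (P - 1)
  Va <- (SSD_among / df_among - Vb) / n_prime
  list(SSD_among = SSD_among, SSD_within = SSD_within, SSD_total = SSD_total,
       df_among = df_among, df_within = df_within,
       Va = Va, Vb = Vb, n_prime = n_prime,
       Fst = Va / (Va + Vb), N = N, P = P)
}

amova_crosstab <- function(haplotype, population, D) {
  M <- unclass(table(factor(haplotype, levels = rownames(D)), population))
  storage.mode(M) <- "numeric"
  M
}

#' One-level analysis of molecular variance (AMOVA)
#'
#' Partitions the total molecular variance among samples into an
#' among-population component (Va) and a within-population component (Vb),
#' using the entries of `distances` directly as squared inter-individual
#' distances. With identity distances (0 within a haplotype, 1 between
#' haplotypes) the decomposition reduces to classic haplotype-frequency
#' F-statistics; with pairwise-difference distances it weights haplotype
#' pairs by their number of differing sites. `Fst = Va / (Va + Vb)`.
#' Significance is assessed by permuting individuals among populations
#' (sizes fixed) and recomputing Fst; the p-value is
#' `(1 + #\{Fst* >= Fst\}) / (R + 1)`.
#'
#' @param data Per-sample tibble with a `haplotype` column and the grouping
#'   column.
#' @param group Name of the column defining populations (default
#'   `"region"`).
#' @param distances Symmetric haplotype distance matrix (see
#'   [pairwise_difference_matrix()]). Default `NULL` uses identity
#'   distances over the observed haplotypes.
#' @param permutations Number of label permutations for the test (0 skips
#'   the test).
#' @param seed Integer seed for the permutation test (required when
#'   `permutations > 0` for reproducibility).
#' @param min_n Populations with fewer samples are dropped with a warning
#'   before the analysis (a single sample carries no within-population
#'   information and would skew the result).
#' @return An object of class `amova` with `tidy()`, `glance()` and
#'   `print()` methods.
#' @examples
#' study <- generate_study(seed = 1)
#' calls <- tidy(call_haplotypes(study$alignment, study$catalog))
#' d <- dplyr::left_join(calls, study$metadata, by = "sample_id")
#' fit <- amova(d, group = "region")
#' glance(fit)$Fst  # 0.475
#' @export
amova <- function(data, group = "region", distances = NULL,
                  permutations = 0, seed = NULL, min_n = 1) {
  if (!"haplotype" %in% names(data)) abort("data must have a 'haplotype' column")
  if (!group %in% names(data)) abort(paste0("no column '", group, "' in data"))
  haplotype <- as.character(data$haplotype)
  population <- as.character(data[[group]])
  sizes <- table(population)
  if (any(sizes < min_n)) {
    drop <- names(sizes)[sizes < min_n]
    warn(paste0("dropping population(s) with fewer than ", min_n,
                " sample(s): ", paste(drop, collapse = ", "),
                " (a single sample would skew the result)"))
    keep <- !population %in% drop
    haplotype <- haplotype[keep]
    population <- population[keep]
  }
  if (length(unique(population)) < 2) abort("AMOVA needs at least 2 populations")
  if (length(haplotype) < 3) abort("AMOVA needs at least 3 samples")
  if (is.null(distances)) distances <- identity_distances(haplotype)
  missing_h <- setdiff(unique(haplotype), rownames(distances))
  if (length(missing_h) > 0) {
    abort(paste0("distance matrix lacks haplotype(s): ",
                 paste(missing_h, collapse = ", ")))
  }
  off <- distances[row(distances) != col(distances)]
  mode <- if (all(off %in% c(0, 1))) "identity" else "pairwise_differences"

  M <- amova_crosstab(haplotype, population, distances)
  res <- amova_core(M, distances)
  if (res$Va + res$Vb == 0) abort("Fst undefined: Va + Vb = 0")
  if (res$Va < 0) {
    warn(sprintf("negative among-population variance component (Va = %.5g)",
                 res$Va))
  }
  p_value <- NA_real_
  fst_null <- NULL
  if (permutations > 0) {
    perm <- amova_permutation_test(res$Fst, haplotype, population, distances,
                                   R = permutations, seed = seed)
    p_value <- perm$p_value
    fst_null <- perm$fst_null
  }
  structure(c(res, list(p_value = p_value, permutations = permutations,
                        fst_null = fst_null, mode = mode, group = group,
                        population_sizes = table(population))),
            class = "amova")
}

#' Permutation test for population differentiation
#'
#' Permutes individuals' population labels uniformly at random (population
#' sizes fixed), recomputes Fst for each replicate, and returns
#' `p = (1 + #\{Fst* >= observed\}) / (R + 1)`.
#'
#' @param observed_fst Observed Fst value.
#' @param haplotype,population Per-individual label vectors.
#' @param distances Haplotype distance matrix.
#' @param R Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return List with `p_value` and the vector `fst_null` of permuted Fst
#'   values.
#' @export
amova_permutation_test <- function(observed_fst, haplotype, population,
                                   distances, R = 1000, seed = NULL) {
  if (R < 1) abort("R must be >= 1")
  run <- function() {
    vapply(seq_len(R), function(i) {
      M <- amova_crosstab(haplotype, sample(population), distances)
      amova_core(M, distances)$Fst
    }, numeric(1))
  }
  fst_null <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  # >= with a tolerance so exact ties under integer distances count
  hits <- sum(fst_null >= observed_fst - 1e-12)
  list(p_value = (1 + hits) / (R + 1), fst_null = fst_null)
}

#' @exportS3Method generics::tidy
tidy.amova <- function(x, ...) {
  tibble(
    term = c("Among populations", "Within populations", "Total"),
    df = c(x$df_among, x$df_within, x$df_among + x$df_within),
    SSD = c(x$SSD_among, x$SSD_within, x$SSD_total),
    variance = c(x$Va, x$Vb, x$Va + x$Vb),
    percent = 100 * c(x$Va, x$Vb, x$Va + x$Vb) / (x$Va + x$Vb),
    p_value = c(x$p_value, x$p_value, NA_real_))
}

#' @exportS3Method generics::glance
glance.amova <- function(x, ...) {
  tibble(Fst = x$Fst, Va = x$Va, Vb = x$Vb, n_prime = x$n_prime,
         p_value = x$p_value, n = x$N, n_populations = x$P,
         permutations = x$permutations, mode = x$mode)
}

#' @export
print.amova <- function(x, digits = 3, ...) {
  cat("One-level AMOVA (", x$mode, " distances), ", x$P,
      " populations, N = ", x$N, "\n\n", sep = "")
  tab <- tidy(x)
  tab <- mutate(tab,
                SSD = round(.data$SSD, digits),
                variance = round(.data$variance, 5),
                percent = round(.data$percent, 2))
  print(as.data.frame(tab), row.names = FALSE)
  cat(sprintf("\nFixation index Fst: %.5f\n", x$Fst))
  if (!is.na(x$p_value)) {
    cat(sprintf("Permutation p-value: %s (%d permutations)\n",
                format.pval(x$p_value, digits = 3), x$permutations))
  }
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.amova <- function(object, ...) {
  df <- tidy(object)
  df <- filter(df, .data$term != "Total")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Percent of molecular variance",
                  title = sprintf("AMOVA: Fst = %.3f", object$Fst)) +
    ggplot2::theme_minimal()
}
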