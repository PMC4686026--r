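test_that("haplotype frequencies and their s.d. match the published cells", {
  freq <- haplotype_frequencies(table1_all_counts())
  h9 <- dplyr::filter(freq, haplotype == "H9")
  expect_equal(round(h9$f, 4), 0.3697)
  expect_equal(round(h9$sd, 4), 0.0377)
  z1 <- dplyr::filter(freq, haplotype == "Z1")
  expect_equal(round(z1$f, 4), 0.3091)
  expect_equal(round(z1$sd, 4), 0.0361)
  z3 <- dplyr::filter(freq, haplotype == "Z3")
  expect_equal(round(z3$sd, 4), 0.0224)
  expect_equal(sum(freq$f), 1)
})

test_that("frequency edge cases and invariants hold", {
  one <- haplotype_frequencies(c(only = 7))
  expect_equal(one$f, 1)
  expect_equal(one$sd, 0)
  expect_error(haplotype_frequencies(c(a = -1, b = 3)), "negative")

  withr::with_seed(42, {
    for (i in 1:20) {
      freq <- haplotype_frequencies(random_counts())
      expect_equal(sum(freq$f), 1)
      expect_true(all(freq$sd >= 0))
    }
  })
  # for fixed n the s.d. is maximal near p = 0.5
  n <- 50
  p_grid <- (1:(n - 1)) / n
  sds <- sqrt(p_grid * (1 - p_grid) / (n - 1))
  expect_equal(which.max(sds), n / 2)
  expect_true(all(diff(sds[p_grid <= 0.5]) >= 0))
})

test_that("gene diversity reproduces the overall and pooled regional values", {
  all_zam <- gene_diversity(table1_all_counts())
  expect_equal(round(all_zam$h, 4), 0.7319)
  expect_equal(round(all_zam$sd, 4), 0.0174)

  west <- gene_diversity(c(H1 = 1, H9 = 60, H11 = 1, Z1 = 4,
                           Z3 = 15, Z4 = 2, Z5 = 5))
  expect_equal(round(west$h, 4), 0.5057)
  expect_equal(round(west$sd, 4), 0.0575)
  east <- gene_diversity(c(H9 = 1, H11 = 28, Z1 = 47, Z2 = 1))
  expect_equal(round(east$h, 4), 0.5014)
  expect_equal(round(east$sd, 4), 0.0336)

  mono <- gene_diversity(c(only = 10))
  expect_equal(mono$h, 0)
  expect_equal(mono$sd, 0)
  expect_error(gene_diversity(c(a = 1)), "n < 2")
})

test_that("pairwise-difference matrix matches the in-text and derived counts", {
  D <- pairwise_difference_matrix(lion_haplotype_catalog())
  expect_equal(D["H11", "Z1"], 2)
  expect_equal(D["Z1", "H10"], 1)
  expect_equal(D["H9", "Z4"], 1)
  expect_equal(D["H9", "Z5"], 1)
  expect_equal(D["H9", "H11"], 3)  # columns 841, 1039, 1387

  # brute-force double-loop oracle over the whole catalog
  m <- catalog_states(lion_haplotype_catalog())
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(nrow(m))) {
      expect_equal(D[i, j], sum(m[i, ] != m[j, ]))
    }
  }
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  # triangle inequality on the catalog
  for (i in seq_len(nrow(D))) {
    for (j in seq_len(nrow(D))) {
      expect_true(all(D[i, j] <= D[i, ] + D[, j]))
    }
  }

  I <- pairwise_difference_matrix(lion_haplotype_catalog(), "identity")
  expect_true(all(I %in% c(0, 1)))
  expect_true(all(diag(I) == 0))
  expect_error(pairwise_difference_matrix(lion_haplotype_catalog(), "nope"))
})

test_that("gap handling: gap-gap is 0 differences, gap-base is 1 per column", {
  cat3 <- haplotype_catalog(
    c("x", "y", "z"), c(1L, 2L),
    matrix(c("A", "-",
             "C", "-",
             "A", "C"), nrow = 3, byrow = TRUE))
  D <- pairwise_difference_matrix(cat3)
  expect_equal(D["x", "y"], 1)  # gap-gap column contributes 0
  expect_equal(D["x", "z"], 1)  # gap vs base contributes 1
  expect_equal(D["y", "z"], 2)
})

test_that("within-population means reproduce the published area values", {
  I <- pairwise_difference_matrix(lion_haplotype_catalog(), "identity")
  areas <- table1_area_counts()
  expand <- function(cn) rep(names(cn), cn)
  lv <- mean_pairwise_within(expand(areas$LV), I)
  expect_equal(lv, 819 / 1770)       # = 0.4627...
  expect_equal(round(lv, 2), 0.46)
  expect_equal(round(mean_pairwise_within(expand(areas$CO), I), 2), 0.53)
  expect_equal(round(mean_pairwise_within(expand(areas$KF), I), 2), 0.51)
  expect_equal(mean_pairwise_within(expand(areas$ZA), I), 1.0)
  expect_equal(mean_pairwise_within(rep("H9", 5), I), 0)
  expect_error(mean_pairwise_within("H9", I), "n >= 2")
})

test_that("identity-mode within mean equals gene diversity (algebraic identity)", {
  withr::with_seed(7, {
    for (i in 1:25) {
      cn <- random_counts(n_haps = sample(2:8, 1))
      members <- rep(names(cn), cn)
      I <- identity_matrix <- {
        h <- names(cn); M <- matrix(1, length(h), length(h),
                                    dimnames = list(h, h)); diag(M) <- 0; M
      }
      expect_equal(mean_pairwise_within(members, I),
                   gene_diversity(cn)$h, tolerance = 1e-12)
    }
  })
})

test_that("between-population mean and Nei's d behave and match brute force", {
  I <- pairwise_difference_matrix(lion_haplotype_catalog(), "identity")
  samples <- table1_samples()
  east <- dplyr::filter(samples, region == "eastern")
  west <- dplyr::filter(samples, region == "western")

  # brute-force double loop over all 77 x 88 sample pairs
  brute_between <- mean(outer(east$haplotype, west$haplotype, `!=`))
  expect_equal(mean_pairwise_between(east, west, I), brute_between)
  brute_within <- function(h) {
    d <- outer(h, h, `!=`)
    sum(d[upper.tri(d)]) / choose(length(h), 2)
  }
  brute_d <- brute_between - (brute_within(east$haplotype) +
                                brute_within(west$haplotype)) / 2
  expect_equal(neis_distance(east, west, I), brute_d)

  expect_equal(neis_distance(east, east, I), 0)  # self-distance
  # two monomorphic populations fixed for different haplotypes
  expect_equal(mean_pairwise_between(rep("H9", 4), rep("Z1", 6), I), 1)
  expect_equal(neis_distance(rep("H9", 4), rep("Z1", 6), I), 1)
  expect_error(mean_pairwise_between(character(0), rep("Z1", 2), I),
               "non-empty")
})

test_that("nucleotide diversity agrees with a brute-force sequence scan", {
  expect_equal(nucleotide_diversity(rep("H9", 3),
                                    pairwise_difference_matrix(
                                      lion_haplotype_catalog()), 1882), 0)
  # two samples differing at 2 of 1882 columns
  D2 <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("u", "v"), c("u", "v")))
  expect_equal(nucleotide_diversity(c("u", "v"), D2, 1882), 2 / 1882)

  # synthetic subset oracle: per-pair column differences on real sequences
  study <- generate_study(seed = 5)
  idx <- withr::with_seed(5, sample(165, 40))
  sub <- study$alignment[idx, ]
  calls <- call_haplotypes(
    structure(sub, class = c("aligned_seqs", class(sub)),
              n_columns = 1882L),
    study$catalog)
  m <- do.call(rbind, strsplit(sub$sequence, "", fixed = TRUE))
  tot <- 0
  for (i in 1:39) for (j in (i + 1):40) tot <- tot + sum(m[i, ] != m[j, ])
  brute <- tot / choose(40, 2) / 1882
  D <- pairwise_difference_matrix(study$catalog)
  expect_equal(nucleotide_diversity(tidy(calls), D, 1882), brute)
})

test_that("population distance summary has the triangular layout", {
  samples <- table1_samples()
  D <- pairwise_difference_matrix(lion_haplotype_catalog(), "identity")
  tab <- population_distance_summary(samples, D, group = "area")
  expect_equal(nrow(tab), 5 + choose(5, 2))
  si <- dplyr::filter(tab, pop_x == "SI", pop_y == "SI")
  expect_true(is.na(si$pi))  # single sample: no within term
  lv <- dplyr::filter(tab, pop_x == "LV", pop_y == "LV")
  expect_equal(round(lv$pi, 2), 0.46)
})
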