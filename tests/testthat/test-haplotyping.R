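test_that("polymorphic-site counts match the published catalog summaries", {
  full <- lion_haplotype_catalog()
  zam <- lion_haplotype_catalog(zambia_only = TRUE)
  expect_equal(nrow(find_polymorphic_sites(full)), 31)
  expect_equal(nrow(find_polymorphic_sites(zam)), 16)

  # brute-force column-scan oracle for the Zambian subset
  m <- catalog_states(zam)
  brute <- catalog_positions(zam)[apply(m, 2, function(col)
    length(unique(col)) >= 2)]
  expect_equal(find_polymorphic_sites(zam)$position, brute)
})

test_that("polymorphism classes reproduce the published split", {
  zam <- classify_polymorphisms(find_polymorphic_sites(
    lion_haplotype_catalog(zambia_only = TRUE)))
  expect_equal(polymorphism_counts(zam),
               tibble::tibble(n_sites = 16L, n_transitions = 13L,
                              n_transversions = 1L, n_indels = 2L))
  expect_equal(zam$position[zam$class == "transversion"], 1801L)
  expect_equal(zam$position[zam$class == "indel"], c(928L, 929L))

  full <- classify_polymorphisms(find_polymorphic_sites(
    lion_haplotype_catalog()))
  expect_equal(polymorphism_counts(full),
               tibble::tibble(n_sites = 31L, n_transitions = 28L,
                              n_transversions = 1L, n_indels = 2L))
})

test_that("classification handles the base cases and ignores N", {
  aln <- tibble::tibble(sample_id = c("x", "y", "z"),
                                   sequence = c("AGN", "GGA", "GGA"))
  class(aln) <- c("aligned_seqs", class(aln))
  attr(aln, "n_columns") <- 3L
  sites <- classify_polymorphisms(find_polymorphic_sites(aln))
  # column 1 {A,G}: transition; column 2 monomorphic; column 3 {A} after
  # dropping N: not polymorphic
  expect_equal(sites$position, 1L)
  expect_equal(sites$class, "transition")

  ident <- tibble::tibble(sample_id = c("x", "y"), sequence = c("ACGT", "ACGT"))
  class(ident) <- c("aligned_seqs", class(ident))
  expect_equal(nrow(find_polymorphic_sites(ident)), 0)

  single <- ident[1, ]
  class(single) <- c("aligned_seqs", class(single))
  expect_error(find_polymorphic_sites(single), "fewer than 2")
})

test_that("classification is invariant to row order", {
  full <- lion_haplotype_catalog()
  for (i in 1:5) {
    perm <- full[sample(nrow(full)), ]
    class(perm) <- unique(c("haplotype_catalog", class(perm)))
    expect_equal(
      polymorphism_counts(classify_polymorphisms(find_polymorphic_sites(perm))),
      polymorphism_counts(classify_polymorphisms(find_polymorphic_sites(full))))
  }
})

test_that("calling the noise-free synthetic study recovers every assignment", {
  study <- generate_study(seed = 1)
  calls <- call_haplotypes(study$alignment, study$catalog)
  a <- tidy(calls)
  expect_equal(nrow(a), 165)
  expect_equal(sort(unique(a$haplotype)),
               sort(c("H1", "H9", "H11", "Z1", "Z2", "Z3", "Z4", "Z5")))
  expect_false(any(a$is_novel))
  expect_false(any(a$needs_verification))
  expect_equal(nrow(calls$catalog), nrow(study$catalog))  # no mints
})

test_that("novel haplotypes are minted by the replication rule", {
  catalog <- tiny_catalog()
  bg <- strrep("A", 25)
  seq_a <- profile_to_sequence(catalog, "a", bg)
  novel <- sub("^(.{4})A", "\\1C", seq_a)  # change state at position 5
  aln <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                        sequence = c(seq_a, novel, novel))
  class(aln) <- c("aligned_seqs", class(aln))
  attr(aln, "n_columns") <- 25L

  calls <- call_haplotypes(aln, catalog, novel_prefix = "Z")
  a <- tidy(calls)
  expect_equal(a$haplotype, c("a", "Z1", "Z1"))
  expect_equal(a$is_novel, c(FALSE, TRUE, TRUE))
  expect_false(any(a$needs_verification))  # seen twice: accepted outright
  expect_true("Z1" %in% calls$catalog$haplotype)

  # a singleton novel haplotype is flagged for re-sequencing
  calls1 <- call_haplotypes(aln[1:2, ], catalog, novel_prefix = "Z")
  expect_equal(tidy(calls1)$needs_verification, c(FALSE, TRUE))

  # minted names continue past the highest existing index of the prefix
  study <- generate_study(seed = 2)
  one <- study$alignment[1, ]  # an H9 sample
  class(one) <- c("aligned_seqs", class(one))
  attr(one, "n_columns") <- 1882L
  mutated <- one
  mutated$sequence <- sub("^(.{241})[ACGT]", "\\1T", mutated$sequence)  # col 242
  calls2 <- call_haplotypes(mutated, study$catalog)
  expect_equal(tidy(calls2)$haplotype, "Z6")
})

test_that("N at a diagnostic position is an unresolvable call", {
  catalog <- tiny_catalog()
  bg <- strrep("G", 25)
  s <- profile_to_sequence(catalog, "b", bg)
  s_n <- sub("^(.{8})T", "\\1N", s)  # N at catalog position 9
  aln <- tibble::tibble(sample_id = "bad", sequence = s_n)
  class(aln) <- c("aligned_seqs", class(aln))
  attr(aln, "n_columns") <- 25L
  expect_error(call_haplotypes(aln, catalog), "unresolvable.*bad")
  expect_error(call_haplotypes(aln[0, ], catalog), "empty")
})

test_that("profile_to_sequence writes catalog states and round-trips", {
  catalog <- lion_haplotype_catalog()
  bg <- strrep("A", 1882)
  z2 <- profile_to_sequence(catalog, "Z2", bg)
  expect_equal(substr(z2, 1801, 1801), "T")
  h9 <- profile_to_sequence(catalog, "H9", bg)
  expect_equal(substr(h9, 928, 929), "--")
  expect_error(profile_to_sequence(catalog, "H1", strrep("A", 100)),
               "width")
  expect_error(profile_to_sequence(catalog, "nope", bg), "not in catalog")

  # full round-trip: every cataloged haplotype is called back by name
  seqs <- vapply(catalog$haplotype,
                 function(h) profile_to_sequence(catalog, h, bg),
                 character(1))
  aln <- tibble::tibble(sample_id = names(seqs), sequence = unname(seqs))
  class(aln) <- c("aligned_seqs", class(aln))
  attr(aln, "n_columns") <- 1882L
  calls <- call_haplotypes(aln, catalog)
  expect_equal(tidy(calls)$haplotype, catalog$haplotype)
  expect_false(any(tidy(calls)$is_novel))
})
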