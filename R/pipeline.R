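#' Read a pipeline run configuration
#'
#' Accepts a YAML file (or simple `key: value` text) or a named list.
#' Recognised keys: `fasta`, `metadata`, `catalog` (input paths), `group_by`
#' (`"region"` or `"area"`, default `"region"`), `area_group_by` (grouping
#' for the within-region AMOVA, default `"area"`), `permutations` (default
#' 1000), `seed` (default 1), `out_dir` (default `"mthaplostat_out"`),
#' `epsilon` (median-joining relaxation, default 0).
#'
#' @param config Path to a config file, or a named list.
#' @return A validated named list of class `run_config`.
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(paste0("no such config file: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a list or a path to a YAML file")
  defaults <- list(group_by = "region", permutations = 1000, seed = 1,
                   out_dir = "mthaplostat_out", epsilon = 0)
  for (k in names(defaults)) config[[k]] <- config[[k]] %||% defaults[[k]]
  for (k in c("fasta", "metadata", "catalog")) {
    if (is.null(config[[k]])) abort(paste0("config is missing '", k, "'"))
    if (!file.exists(config[[k]])) {
      abort(paste0("config error: ", k, " file does not exist: ", config[[k]]))
    }
  }
  if (!config$group_by %in% c("region", "area")) {
    abort("group_by must be 'region' or 'area'")
  }
  structure(config, class = c("run_config", "list"))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

log_msg <- function(...) {
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [INFO] ", ...)
}

round_tbl <- function(tbl, digits) {
  mutate(tbl, across(tidyselect::where(is.numeric), ~ round(.x, digits)))
}

#' Run the full haplotype study analysis
#'
#' Orchestrates the pipeline on one dataset: haplotype calling against the
#' catalog, haplotype frequencies and gene diversity (overall, per region
#' and per area), polymorphic-site classification, the within/between
#' pairwise-difference and Nei's-distance summary, the two-region AMOVA
#' (identity distances, with a permutation test) and the within-region
#' among-area AMOVA (pairwise-difference distances; populations of one
#' sample are excluded), and the median-joining network. All outputs are
#' written under `out_dir` together with a JSON manifest carrying the seed
#' and an md5 checksum per output, so a re-run with the same config is
#' byte-identical (timestamps appear only in the log).
#'
#' @param config A [read_run_config()] input: path or named list.
#' @return Invisibly, a list with the manifest and the key fitted objects.
#' @export
run_study_analysis <- function(config) {
  config <- read_run_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  log_msg("reading inputs")
  aln <- stage("read", read_alignment(config$fasta))
  meta <- stage("read", read_sample_metadata(config$metadata))
  catalog <- stage("read", read_profile_table(config$catalog))

  log_msg("calling haplotypes for ", nrow(aln), " samples")
  calls <- stage("call", call_haplotypes(aln, catalog))
  data <- stage("call", left_join(tidy(calls), meta, by = "sample_id"))
  paths$assignments <- file.path(out, "assignments.tsv")
  readr::write_tsv(tidy(calls), paths$assignments, progress = FALSE)
  paths$catalog <- file.path(out, "catalog.tsv")
  write_profile_table(calls$catalog, paths$catalog)

  log_msg("diversity indices")
  freq <- stage("diversity", haplotype_frequencies(data))
  paths$frequencies <- file.path(out, "frequencies.tsv")
  readr::write_tsv(round_tbl(freq, 4), paths$frequencies, progress = FALSE)

  pooled <- gene_diversity(data)
  by_region <- data |>
    group_by(region = .data$region) |>
    dplyr::group_modify(~ gene_diversity(.x)) |>
    ungroup()
  div <- bind_rows(mutate(pooled, region = "all", .before = 1), by_region)
  obs_catalog <- calls$catalog[calls$catalog$haplotype %in% data$haplotype, ]
  class(obs_catalog) <- unique(c("haplotype_catalog", class(obs_catalog)))
  poly <- polymorphism_counts(
    classify_polymorphisms(find_polymorphic_sites(obs_catalog)))
  div <- dplyr::bind_cols(div, poly[rep(1, nrow(div)), ])
  paths$diversity <- file.path(out, "diversity.tsv")
  readr::write_tsv(round_tbl(div, 4), paths$diversity, progress = FALSE)

  log_msg("pairwise distance summaries")
  D_id <- pairwise_difference_matrix(obs_catalog, "identity")
  D_pd <- pairwise_difference_matrix(obs_catalog, "pairwise_differences")
  paths$distances_identity <- file.path(out, "distance_summary_identity.tsv")
  readr::write_tsv(round_tbl(population_distance_summary(data, D_id, "area"), 4),
                   paths$distances_identity, progress = FALSE)
  paths$distances_pairdiff <- file.path(out, "distance_summary_pairdiff.tsv")
  readr::write_tsv(round_tbl(population_distance_summary(data, D_pd, "area"), 4),
                   paths$distances_pairdiff, progress = FALSE)

  log_msg("AMOVA (", config$group_by, ", identity distances, ",
          config$permutations, " permutations)")
  fit <- stage("amova", amova(data, group = config$group_by,
                              permutations = config$permutations,
                              seed = config$seed))
  area_fits <- list()
  for (reg in sort(unique(data$region))) {
    sub <- filter(data, .data$region == reg)
    sub_sizes <- table(sub$area)
    if (sum(sub_sizes >= 2) < 2) {
      # mirrors the study: no among-area Fst where a lone sample would skew it
      log_msg("skipping among-area AMOVA in ", reg,
              ": fewer than two areas with >= 2 samples (",
              paste(names(sub_sizes)[sub_sizes < 2], collapse = ", "),
              " contribute only one sample each)")
      next
    }
    f <- stage("amova",
               withCallingHandlers(
                 amova(sub, group = "area", distances = D_pd, min_n = 2),
                 warning = function(w) {
                   log_msg("  ", conditionMessage(w))
                   invokeRestart("muffleWarning")
                 }))
    area_fits[[reg]] <- f
  }
  amova_tbl <- bind_rows(
    mutate(tidy(fit), analysis = config$group_by, .before = 1),
    purrr::imap_dfr(area_fits,
                    ~ mutate(tidy(.x), analysis = paste0("areas_", .y),
                             .before = 1)))
  paths$amova <- file.path(out, "amova.tsv")
  readr::write_tsv(round_tbl(amova_tbl, 3), paths$amova, progress = FALSE)
  paths$amova_json <- file.path(out, "amova.json")
  jsonlite::write_json(
    c(list(main = as.list(glance(fit))),
      purrr::map(area_fits, ~ as.list(glance(.x)))),
    paths$amova_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  log_msg("median-joining network")
  net <- stage("network",
               median_joining_network(obs_catalog, counts = data,
                                      epsilon = config$epsilon))
  paths$network <- file.path(out, "network_edges.tsv")
  export_network(net, paths$network, format = "edgelist")

  manifest <- list(
    package = "mthaplostat",
    version = as.character(utils::packageVersion("mthaplostat")),
    seed = config$seed,
    group_by = config$group_by,
    permutations = config$permutations,
    n_samples = nrow(data),
    n_haplotypes = length(unique(data$haplotype)),
    fst = fit$Fst,
    outputs = purrr::imap(paths, ~ list(path = .x,
                                        md5 = unname(tools::md5sum(.x)))))
  paths$manifest <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_msg("done: ", length(paths) - 1L, " stage outputs + manifest in ", out)
  invisible(list(manifest = manifest, paths = paths, amova = fit,
                 area_amova = area_fits, network = net, calls = calls,
                 data = data))
}
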