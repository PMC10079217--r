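# Experiment orchestration: presets, replicated runs with manifests,
# serialization, and the cross-treatment summary report.

#' Scale presets
#'
#' `"paper_full"` is the full-scale study condition (1000 pairs, 25000
#' generations, 40 replicate populations; cluster-scale). `"desk_small"` is
#' the workstation-scale condition used throughout the test suite: 100
#' pairs, 500 generations, 10 replicates.
#'
#' @param name `"paper_full"` or `"desk_small"`.
#' @return A list with `name`, `generations`, `n_pairs`, `replicates`.
#' @export
scale_preset <- function(name = c("desk_small", "paper_full")) {
  name <- match.arg(name)
  switch(name,
    paper_full = list(name = name, generations = 25000L, n_pairs = 1000L,
                      replicates = 40L),
    desk_small = list(name = name, generations = 500L, n_pairs = 100L,
                      replicates = 10L)
  )
}

#' Read an experiment configuration from YAML
#'
#' Recognized keys: `generations`, `n_pairs`, `tournament_size`, `mu`,
#' `mutation_sd`, `mutation_center`, `treatment`, `seeds` (vector of master
#' seeds, one per replicate). Unset keys fall back to the
#' [evolution_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with `config` (an [evolution_config()]) and `seeds`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw),
                        c("generations", "n_pairs", "tournament_size", "mu",
                          "mutation_sd", "mutation_center", "treatment"))]
  list(config = do.call(evolution_config, args),
       seeds = as.integer(raw$seeds %||% 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write/read genome matrices as CSV
#'
#' One row per individual, one gene per column (columns `g1`, `g2`, ...),
#' plus a leading `role` column; gene ordering is the [decode_genome()]
#' layout.
#'
#' @param genomes Genome matrix.
#' @param role `"sender"` or `"receiver"`.
#' @param path Output path.
#' @return `path`, invisibly (writer); genome matrix (reader).
#' @export
write_genomes <- function(genomes, role, path) {
  df <- tibble::as_tibble(genomes, .name_repair = ~ paste0("g",
                                                           seq_along(.x)))
  df <- dplyr::bind_cols(tibble::tibble(role = role), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_genomes
#' @export
read_genomes <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  as.matrix(df[, setdiff(names(df), "role")])
}

#' Run a replicated experiment
#'
#' Dispatches [run_evolution()] once per replicate seed, writes per-replicate
#' generation summaries (CSV) and final-population genomes under `out_dir`,
#' and records a manifest (JSON) from which the run can be reproduced
#' bit-for-bit. Refuses to overwrite a directory containing outputs unless
#' they come with a manifest and `overwrite = TRUE`.
#'
#' @param preset A [scale_preset()] (or a list with `generations`, `n_pairs`,
#'   `replicates`).
#' @param treatment One of [treatments()].
#' @param seeds Integer vector of master seeds, one per replicate; defaults
#'   to `1:replicates`.
#' @param out_dir Output directory (created if missing). `NULL` keeps
#'   everything in memory.
#' @param overwrite Allow regeneration over an existing manifest.
#' @param ... Further arguments passed to [evolution_config()].
#' @return A list of class `"run_manifest"` with the config snapshot, seeds,
#'   per-replicate paths and the in-memory histories.
#' @export
run_experiment <- function(preset = scale_preset("desk_small"),
                           treatment = "communication", seeds = NULL,
                           out_dir = NULL, overwrite = FALSE, ...) {
  if (identical(preset$name, "paper_full")) {
    warning("paper_full is a cluster-scale preset (1000 pairs x 25000 ",
            "generations x 40 replicates)", call. = FALSE)
  }
  if (is.null(seeds)) seeds <- seq_len(preset$replicates)
  config <- evolution_config(generations = preset$generations,
                             n_pairs = preset$n_pairs,
                             treatment = treatment, ...)
  paths <- NULL
  if (!is.null(out_dir)) {
    manifest_path <- file.path(out_dir, "manifest.json")
    if (dir.exists(out_dir) && length(list.files(out_dir))) {
      if (!file.exists(manifest_path)) {
        stop("`out_dir` contains files but no manifest; refusing to ",
             "overwrite", call. = FALSE)
      }
      if (!overwrite) {
        stop("`out_dir` already holds a finished run; pass overwrite = TRUE ",
             "to regenerate", call. = FALSE)
      }
    }
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  histories <- purrr::map(seeds, function(s) {
    run_evolution(config, seed = s)
  })
  if (!is.null(out_dir)) {
    paths <- purrr::map_chr(seq_along(seeds), function(i) {
      p <- file.path(out_dir, sprintf("replicate_%03d.csv", seeds[i]))
      readr::write_csv(histories[[i]]$summary, p)
      write_genomes(histories[[i]]$population$senders, "sender",
                    file.path(out_dir,
                              sprintf("final_senders_%03d.csv", seeds[i])))
      write_genomes(histories[[i]]$population$receivers, "receiver",
                    file.path(out_dir,
                              sprintf("final_receivers_%03d.csv", seeds[i])))
      p
    })
  }
  manifest <- structure(list(
    preset = preset, treatment = treatment, seeds = as.integer(seeds),
    config = config[setdiff(names(config), "options")],
    package_version = as.character(utils::packageVersion("dispcomm")),
    paths = paths, completed = TRUE,
    histories = histories
  ), class = "run_manifest")
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest[setdiff(names(manifest), "histories")],
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  }
  manifest
}

#' Final-generation mean performances of a run
#'
#' @param manifest A `"run_manifest"`.
#' @return Numeric vector, one final-generation population mean per
#'   replicate.
#' @export
final_mean_performance <- function(manifest) {
  purrr::map_dbl(manifest$histories, function(h) {
    h$summary$mean_perf[nrow(h$summary)]
  })
}

#' Summary report across the three treatments
#'
#' Tabulates, per treatment, the final mean performance across replicates
#' and the generations-to-exceed-0.2 milestone, and reports the headline
#' contrasts (communication vs no-communication final performance;
#' unconstrained vs constrained speed of crossing 0.2), with an explicit
#' scale caveat. Missing treatments leave gaps rather than failing.
#'
#' @param manifests Named list of `"run_manifest"` objects; names must be
#'   treatments.
#' @return A list of class `"reproduce_report"` with `per_treatment` (tibble)
#'   and `contrasts` (tibble).
#' @export
reproduce_report <- function(manifests) {
  if (!length(manifests)) stop("no manifests given", call. = FALSE)
  if (is.null(names(manifests)) ||
      !all(names(manifests) %in% treatments())) {
    stop("`manifests` must be a named list keyed by treatment",
         call. = FALSE)
  }
  per <- purrr::imap(manifests, function(man, tr) {
    finals <- final_mean_performance(man)
    crossings <- purrr::map_int(man$histories,
                                first_exceeds_threshold_generation)
    tibble::tibble(
      treatment = tr, replicates = length(finals),
      generations = man$preset$generations, n_pairs = man$preset$n_pairs,
      mean_final = mean(finals), sd_final = sd(finals),
      median_crossing = median(crossings, na.rm = TRUE),
      n_crossed = sum(!is.na(crossings))
    )
  }) |> dplyr::bind_rows()
  contrasts <- list()
  if (all(c("communication", "no_communication") %in% names(manifests))) {
    cmp <- compare_treatments(
      final_mean_performance(manifests$communication),
      final_mean_performance(manifests$no_communication))
    contrasts$comm_vs_nocomm <- dplyr::mutate(
      cmp, contrast = "final performance: communication vs no_communication",
      .before = 1)
  }
  if (all(c("communication", "constrained_sender") %in% names(manifests))) {
    gu <- purrr::map_int(manifests$communication$histories,
                         first_exceeds_threshold_generation)
    gc <- purrr::map_int(manifests$constrained_sender$histories,
                         first_exceeds_threshold_generation)
    m <- min(length(gu), length(gc))
    slower <- sum(is.na(gc[seq_len(m)]) & !is.na(gu[seq_len(m)])) +
      sum(gc[seq_len(m)] > gu[seq_len(m)], na.rm = TRUE)
    contrasts$constrained_slower <- tibble::tibble(
      contrast = "replicates where constrained crossed 0.2 later",
      statistic = slower, p_value = NA_real_,
      median_a = median(gu, na.rm = TRUE), median_b = median(gc, na.rm = TRUE),
      direction = NA_real_)
  }
  structure(list(per_treatment = per,
                 contrasts = dplyr::bind_rows(contrasts),
                 caveat = paste("Values computed at the configured scale;",
                                "full-scale magnitudes require the",
                                "paper_full preset.")),
            class = "reproduce_report")
}

#' @export
print.reproduce_report <- function(x, ...) {
  cat("<reproduce_report>\n")
  print(x$per_treatment)
  if (nrow(x$contrasts)) print(x$contrasts)
  cat(x$caveat, "\n")
  invisible(x)
}
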