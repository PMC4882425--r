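#' Read and write FASTA files
#'
#' Thin wrappers over Biostrings that move between FASTA files and tibbles
#' with `id` and `sequence` columns. Record ids are taken as strain ids
#' throughout the package. CRLF input is accepted; output is written with LF.
#'
#' @param path File path.
#' @return `read_fasta()`: a tibble with `id`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (any(Biostrings::width(set) == 0L)) {
    stop("empty sequence record in ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  tibble::tibble(id = ids, sequence = unname(as.character(set)))
}

#' @param records A tibble/data frame with `id` and `sequence` columns.
#' @rdname read_fasta
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::DNAStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a fluctuation-assay count table
#'
#' The TSV must carry columns `strain`, `culture_id`, `selective_count`,
#' `control_count`, `dilution` ('#' lines are comments). Rows are validated
#' (integer counts, unique culture ids within a strain) and split into one
#' [fluctuation_experiment()] per strain.
#'
#' @param path Path to a TSV file.
#' @return A named list of `fluctuation_experiment` objects, one per strain.
#' @export
read_counts_tsv <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  required <- c("strain", "culture_id", "selective_count", "control_count",
                "dilution")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("empty experiment: no count rows", call. = FALSE)
  for (col in c("selective_count", "control_count")) {
    vals <- df[[col]]
    bad <- which(is.na(vals) | vals != as.integer(vals) | vals < 0)
    if (length(bad)) {
      stop("non-integer or negative ", col, " at row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  dup <- df[duplicated(df[c("strain", "culture_id")]), ]
  if (nrow(dup)) {
    stop("duplicate culture_id within strain: ",
         paste(unique(dup$culture_id), collapse = ", "), call. = FALSE)
  }
  split_df <- split(df, df$strain)
  purrr::imap(split_df, function(d, strain) {
    fluctuation_experiment(
      selective_counts = d$selective_count,
      control_counts = d$control_count,
      dilution_factor = d$dilution[1],
      label = strain
    )
  })
}

#' Write a report table as TSV or JSON
#'
#' @param obj A data frame (or a list of `ld_rate_estimate`s, which is tidied
#'   first).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_report <- function(obj, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(obj)) {
    if (inherits(obj, "ld_rate_estimate")) obj <- list(obj)
    obj <- dplyr::bind_rows(purrr::map(obj, function(x) {
      if (inherits(x, "ld_rate_estimate")) tidy(x) else tibble::as_tibble(x)
    }))
  }
  obj <- dplyr::mutate(obj, dplyr::across(dplyr::where(is.list),
                                          ~ purrr::map_chr(.x, paste, collapse = ",")))
  if (format == "tsv") {
    readr::write_tsv(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Run a seeded end-to-end pipeline from a configuration
#'
#' Executes the simulate -> fluctuation -> classify workflow described by a
#' configuration list (or YAML file): simulates fluctuation assays and a
#' suppressor spectrum, estimates rates, classifies and tallies events, and
#' writes TSV reports plus a JSON manifest of all inputs and parameters to
#' `out_dir`. Identical configurations (same seed) reproduce byte-identical
#' reports.
#'
#' @param config A named list or path to a YAML file with fields `seed`,
#'   `out_dir` and optionally `mu`, `C`, `Nt`, `dilution`, `reporter`,
#'   `class_mix`, `n_events`.
#' @return (Invisibly) a list with `rates`, `events`, `tally` and the paths
#'   written.
#' @export
pipeline_run <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed) || is.null(config$out_dir)) {
    stop("config must provide `seed` and `out_dir`", call. = FALSE)
  }
  seed <- as.integer(config$seed)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  mu <- config$mu %||% 26e-6
  C <- config$C %||% 12L
  Nt <- config$Nt %||% 1e6
  dilution <- config$dilution %||% 1e4
  reporter <- config$reporter %||% "4stop"
  n_events <- config$n_events %||% 200L
  class_mix <- unlist(config$class_mix %||%
                        list(contraction = 0.51, expansion = 0.01,
                             recombination = 0, other = 0.48))

  sim <- simulate_fluctuation_assay(C = C, mu = mu, Nt = Nt,
                                    dilution = dilution, seed = seed,
                                    label = reporter)
  rate <- estimate_rate(sim$experiment)
  spec <- simulate_suppressor_spectrum(reporter = reporter,
                                       class_mix = class_mix,
                                       n_events = n_events, seed = seed + 1L)
  classified <- classify_events(spec$events, reference_bp = spec$reference_bp,
                                wildtype_bp = spec$wildtype_bp)
  tl <- tally_events(classified)

  paths <- list(
    rates = file.path(out_dir, "rates.tsv"),
    events = file.path(out_dir, "events.tsv"),
    tally = file.path(out_dir, "tally.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_report(tidy(rate), paths$rates)
  write_report(classified, paths$events)
  write_report(tl, paths$tally)
  manifest <- list(
    package = "ctdlab",
    version = as.character(utils::packageVersion("ctdlab")),
    parameters = list(seed = seed, mu = mu, C = C, Nt = Nt,
                      dilution = dilution, reporter = reporter,
                      n_events = n_events, class_mix = as.list(class_mix)),
    outputs = paths[c("rates", "events", "tally")]
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(rates = rate, events = classified, tally = tl,
                 paths = paths))
}
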