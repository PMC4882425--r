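#' Build a CTD-like repeat construct with known ground truth
#'
#' Concatenates `n_repeats` units drawn by cycling through the library's known
#' units (preserving the library's degeneracy and coding-strand C-over-G
#' bias), flanked by the library anchors. Stop codons are introduced by a
#' Tyr1 -> stop (TAT/TAC -> TAA) substitution in the listed units, the
#' construction of the 4stop reporter.
#'
#' @param n_repeats Number of repeat units (>= 0).
#' @param lib A [ctd_repeat_library()].
#' @param stops_at_units 1-based unit indices receiving a Tyr1 -> stop codon.
#' @param seed Optional seed (the construct itself is deterministic; the seed
#'   is recorded in the truth table for provenance).
#' @return A list with `sequence` (anchored DNA string) and `truth` (a tibble
#'   with `index`, `unit_name`, `sequence`, `has_stop`).
#' @examples
#' fourstop <- build_ctd_construct(26, stops_at_units = 8:11)
#' translate_and_check(decompose_repeats(fourstop$sequence))$functional_repeats
#' @export
build_ctd_construct <- function(n_repeats, lib = ctd_repeat_library(),
                                stops_at_units = integer(0), seed = NULL) {
  n_repeats <- as.integer(n_repeats)
  stopifnot(n_repeats >= 0L)
  stops_at_units <- as.integer(stops_at_units)
  if (length(stops_at_units) &&
      (any(stops_at_units < 1L) || any(stops_at_units > n_repeats))) {
    stop("stop position out of range 1..n_repeats", call. = FALSE)
  }
  idx <- if (n_repeats > 0L) {
    (seq_len(n_repeats) - 1L) %% length(lib$known_units) + 1L
  } else integer(0)
  units <- unname(lib$known_units[idx])
  names_out <- names(lib$known_units)[idx]
  has_stop <- seq_len(n_repeats) %in% stops_at_units
  units[has_stop] <- sub("^TA[TC]", "TAA", units[has_stop])
  truth <- tibble::tibble(
    index = seq_len(n_repeats),
    unit_name = names_out,
    sequence = units,
    has_stop = has_stop
  )
  attr(truth, "seed") <- seed
  list(
    sequence = paste0(lib$left_anchor, paste(units, collapse = ""),
                      lib$right_anchor),
    truth = truth
  )
}

#' Mutate a base construct into a strain panel with planted events
#'
#' Emulates natural panels whose strains differ by whole-unit gains/losses at
#' various positions plus sparse SNPs. Either draws per-strain events from the
#' given probabilities, or (when `n_templates` is set) first builds that many
#' distinct mutated templates and assigns strains to them, so the expected
#' number of architecture groups is known exactly.
#'
#' @param base_seq An anchored repeat construct (e.g. from
#'   [build_ctd_construct()]).
#' @param n_strains Number of strains to emit.
#' @param lib A [ctd_repeat_library()].
#' @param p_unit_loss,p_unit_gain Per-unit probabilities of whole-unit
#'   deletion / tandem duplication per strain.
#' @param p_snp Per-base substitution probability within the repeat span.
#' @param n_templates If not `NULL`, number of distinct architectures; strains
#'   are assigned to templates round-robin so that every template is used.
#' @param seed Integer seed; the single RNG source for the panel.
#' @return A list with `panel` (tibble `strain_id`, `sequence`) and `truth`
#'   (tibble of planted events: `strain_id`, `kind`
#'   (`unit_loss`/`unit_gain`/`snp`), `unit_index` (1-based on the base
#'   construct), `detail`, and for template mode `template`).
#' @export
mutate_panel <- function(base_seq, n_strains, lib = ctd_repeat_library(),
                         p_unit_loss = 0.02, p_unit_gain = 0.01,
                         p_snp = 0.0005, n_templates = NULL, seed = 1L) {
  set.seed(seed)
  base <- decompose_repeats(base_seq, lib)
  units <- base$units$sequence
  nu <- length(units)

  draw_variant <- function(id) {
    ev <- list()
    keep <- rep(TRUE, nu)
    dup <- rep(FALSE, nu)
    for (i in seq_len(nu)) {
      if (stats::runif(1) < p_unit_loss) {
        keep[i] <- FALSE
        ev[[length(ev) + 1L]] <- tibble::tibble(
          strain_id = id, kind = "unit_loss", unit_index = i,
          detail = "unit deleted")
      } else if (stats::runif(1) < p_unit_gain) {
        dup[i] <- TRUE
        ev[[length(ev) + 1L]] <- tibble::tibble(
          strain_id = id, kind = "unit_gain", unit_index = i,
          detail = "unit duplicated in tandem")
      }
    }
    out_units <- list()
    for (i in seq_len(nu)) {
      if (!keep[i]) next
      out_units[[length(out_units) + 1L]] <- units[i]
      if (dup[i]) out_units[[length(out_units) + 1L]] <- units[i]
    }
    out_units <- unlist(out_units) %||% character(0)
    if (p_snp > 0 && length(out_units)) {
      for (j in seq_along(out_units)) {
        uc <- strsplit(out_units[j], "")[[1]]
        hit <- which(stats::runif(length(uc)) < p_snp)
        for (pos in hit) {
          new <- sample(setdiff(c("A", "C", "G", "T"), uc[pos]), 1)
          ev[[length(ev) + 1L]] <- tibble::tibble(
            strain_id = id, kind = "snp", unit_index = j,
            detail = sprintf("offset %d %s>%s", pos - 1L, uc[pos], new))
          uc[pos] <- new
        }
        out_units[j] <- paste(uc, collapse = "")
      }
    }
    list(seq = paste0(base$left_flank, paste(out_units, collapse = ""),
                      base$right_flank),
         events = ev)
  }

  if (is.null(n_templates)) {
    ids <- sprintf("strain%02d", seq_len(n_strains))
    drawn <- purrr::map(ids, draw_variant)
    panel <- tibble::tibble(strain_id = ids,
                            sequence = purrr::map_chr(drawn, "seq"))
    truth <- dplyr::bind_rows(purrr::flatten(purrr::map(drawn, "events")))
  } else {
    stopifnot(n_templates >= 1L, n_templates <= n_strains)
    templates <- list()
    guard <- 0L
    while (length(templates) < n_templates) {
      guard <- guard + 1L
      if (guard > 100L * n_templates) {
        stop("could not draw distinct templates; raise event probabilities",
             call. = FALSE)
      }
      cand <- draw_variant(sprintf("template%02d", length(templates) + 1L))
      seqs <- purrr::map_chr(templates, "seq")
      if (length(templates) == 0L ||
          (!cand$seq %in% seqs && (length(cand$events) > 0L || length(templates) == 0L))) {
        templates[[length(templates) + 1L]] <- cand
      }
    }
    assign <- rep(seq_len(n_templates), length.out = n_strains)
    ids <- sprintf("strain%02d", seq_len(n_strains))
    panel <- tibble::tibble(
      strain_id = ids,
      sequence = purrr::map_chr(templates, "seq")[assign]
    )
    truth <- dplyr::bind_rows(purrr::imap(seq_len(n_strains), function(t_i, s_i) {
      ev <- templates[[assign[s_i]]]$events
      if (length(ev) == 0L) return(NULL)
      dplyr::mutate(dplyr::bind_rows(ev), strain_id = ids[s_i],
                    template = assign[s_i])
    }))
  }
  if (is.null(truth) || nrow(truth) == 0L) {
    truth <- tibble::tibble(strain_id = character(), kind = character(),
                            unit_index = integer(), detail = character())
  }
  list(panel = panel, truth = truth)
}

#' Simulate a Luria-Delbruck fluctuation assay
#'
#' Cultures grow from `N0` to `Nt` cells; mutations arise uniformly over the
#' `Nt - N0` cell divisions at per-division probability `mu`, and each mutant
#' clone expands deterministically (no death, no differential fitness) to
#' `floor(Nt / n)` cells, where `n` is the population size when the mutation
#' arose. This reproduces the Luria-Delbruck clone-size law
#' `P(clone = j) = 1/(j(j+1))` up to O(N0/Nt), so simulated counts follow the
#' same distribution the MSS estimator assumes. Control plates receive a
#' `1/dilution` binomial sample of the culture.
#'
#' @param C Number of parallel cultures (default 12).
#' @param mu Mutation rate per cell per generation.
#' @param Nt Final cells per culture (default `1e6`).
#' @param N0 Initial cells (default 1).
#' @param dilution Control dilution factor (default `1e4`).
#' @param plated_fraction Fraction of each culture plated selectively
#'   (default 1).
#' @param seed Integer seed.
#' @param label Experiment label.
#' @return A list with `experiment` (a [fluctuation_experiment()]) and
#'   `truth` (list with `mu`, `m = mu * (Nt - N0)`, `seed`).
#' @examples
#' sim <- simulate_fluctuation_assay(C = 12, mu = 26e-6, seed = 1)
#' tidy(estimate_rate(sim$experiment))
#' @export
simulate_fluctuation_assay <- function(C = 12L, mu, Nt = 1e6, N0 = 1,
                                       dilution = 1e4, plated_fraction = 1,
                                       seed = 1L, label = "simulated") {
  if (mu * Nt >= 1e3) {
    stop("parameter error: mu * Nt must stay below 1e3", call. = FALSE)
  }
  set.seed(seed)
  m <- mu * (Nt - N0)
  selective <- vapply(seq_len(C), function(i) {
    M <- stats::rpois(1, m)
    if (M == 0L) return(0L)
    n_at <- N0 + stats::runif(M) * (Nt - N0)   # population size at occurrence
    clones <- pmax(1, floor(Nt / n_at))
    total <- sum(clones)
    if (plated_fraction < 1) {
      total <- stats::rbinom(1, size = as.integer(total), prob = plated_fraction)
    }
    as.integer(total)
  }, integer(1))
  control <- stats::rbinom(C, size = as.integer(round(Nt)), prob = 1 / dilution)
  list(
    experiment = fluctuation_experiment(
      selective_counts = selective, control_counts = control,
      dilution_factor = dilution, plated_fraction_selective = plated_fraction,
      label = label),
    truth = list(mu = mu, m = m, seed = seed)
  )
}

#' Simulate a suppressor amplicon-length spectrum
#'
#' Draws event classes from `class_mix` and assigns amplicon lengths quantized
#' to whole 21-bp unit changes: expansions gain 1-22 units (reporter
#' constructs have been observed to expand from 8 up to 30 repeats),
#' contractions lose `contraction_range` units, recombination restores the
#' 26-unit wild-type length (CTD8 reporter only), and `other` sits at the
#' reference length.
#'
#' @param reporter `"CTD8"` or `"4stop"`.
#' @param class_mix Named probabilities over
#'   `expansion`/`contraction`/`recombination`/`other`; must sum to 1.
#' @param n_events Number of colonies to draw.
#' @param lib A [ctd_repeat_library()].
#' @param seed Integer seed.
#' @param flank_bp Non-repeat bases inside the amplicon (default 120).
#' @param expansion_range,contraction_range Unit-change ranges sampled
#'   uniformly for the respective classes.
#' @return A list with `events` (tibble `colony_id`, `strain`, `reporter`,
#'   `amplicon_bp`), `truth` (same plus `true_class`, `true_delta_units`) and
#'   `reference_bp`, `wildtype_bp`.
#' @export
simulate_suppressor_spectrum <- function(reporter = c("CTD8", "4stop"),
                                         class_mix, n_events,
                                         lib = ctd_repeat_library(),
                                         seed = 1L, flank_bp = 120L,
                                         expansion_range = 1:22,
                                         contraction_range = 4:12) {
  reporter <- match.arg(reporter)
  if (abs(sum(class_mix) - 1) > 1e-9) {
    stop("`class_mix` must sum to 1", call. = FALSE)
  }
  set.seed(seed)
  ul <- lib$unit_length
  n_ref_units <- if (reporter == "CTD8") 8L else 26L
  reference_bp <- flank_bp + ul * n_ref_units
  wildtype_bp <- flank_bp + ul * 26L
  classes <- sample(names(class_mix), n_events, replace = TRUE,
                    prob = as.numeric(class_mix))
  delta <- integer(n_events)
  amp <- integer(n_events)
  for (i in seq_len(n_events)) {
    delta[i] <- switch(classes[i],
      expansion = sample(expansion_range, 1),
      contraction = -sample(contraction_range, 1),
      recombination = 26L - n_ref_units,
      other = 0L
    )
    amp[i] <- reference_bp + ul * delta[i]
  }
  events <- tibble::tibble(
    colony_id = sprintf("colony%05d", seq_len(n_events)),
    strain = "simulated", reporter = reporter, amplicon_bp = amp
  )
  truth <- dplyr::mutate(events, true_class = classes,
                         true_delta_units = delta)
  list(events = events, truth = truth,
       reference_bp = reference_bp, wildtype_bp = wildtype_bp)
}
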