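#' Decompose a CTD coding region into 21-bp repeat units
#'
#' Locates the flanking anchors, checks that the repeat span between them is a
#' whole number of units, and tiles it in frame from the end of the left
#' anchor. Each unit is assigned the closest known unit in the library by
#' minimum Hamming distance (ties broken toward the lowest-numbered unit) and
#' its mismatches are reported as SNPs.
#'
#' @param seq An ACGT-only DNA sequence containing the repeat region.
#' @param lib A [ctd_repeat_library()].
#' @param left_anchor,right_anchor Anchor sequences; default to the library's.
#' @param strain_id Identifier carried into the result.
#'
#' @return A `ctd_decomposition`: list with `strain_id`, `units` (a tibble with
#'   columns `index`, `sequence`, `best_match`, `n_snps`, `snps` where `snps`
#'   is a list-column of tibbles `offset`/`ref`/`obs`, offsets 0-based),
#'   `left_flank`, `right_flank` and `n_units`. Re-concatenating
#'   `left_flank`, the unit sequences and `right_flank` reproduces `seq`
#'   exactly.
#' @examples
#' lib <- ctd_repeat_library()
#' seq <- build_ctd_construct(26, lib)$sequence
#' d <- decompose_repeats(seq, lib)
#' d$n_units
#' @export
decompose_repeats <- function(seq, lib = ctd_repeat_library(),
                              left_anchor = lib$left_anchor,
                              right_anchor = lib$right_anchor,
                              strain_id = "seq") {
  check_dna(seq)
  ul <- lib$unit_length

  left_at <- regexpr(left_anchor, seq, fixed = TRUE)[1]
  if (left_at < 0L) {
    stop("anchor error: left anchor not found in sequence", call. = FALSE)
  }
  span_start <- left_at + nchar(left_anchor)      # 1-based, first repeat base
  # first right-anchor occurrence at or after the end of the left anchor
  tail_part <- substring(seq, span_start)
  right_rel <- regexpr(right_anchor, tail_part, fixed = TRUE)[1]
  if (right_rel < 0L) {
    stop("anchor error: right anchor not found after left anchor", call. = FALSE)
  }
  span_end <- span_start + right_rel - 2L          # last repeat base (1-based)

  span <- if (span_end >= span_start) {
    substring(seq, span_start, span_end)
  } else ""
  residue <- nchar(span) %% ul
  if (residue != 0L) {
    stop(sprintf("frame error: repeat span of %d bp is not a multiple of %d (residue %d bp)",
                 nchar(span), ul, residue), call. = FALSE)
  }

  n_units <- nchar(span) %/% ul
  unit_seqs <- if (n_units > 0L) {
    starts <- span_start + (seq_len(n_units) - 1L) * ul
    substring(seq, starts, starts + ul - 1L)
  } else character(0)

  known <- lib$known_units
  known_chars <- strsplit(unname(known), "")
  calls <- purrr::map(unit_seqs, function(u) {
    uc <- strsplit(u, "")[[1]]
    d <- vapply(known_chars, function(k) sum(k != uc), integer(1))
    best <- which.min(d)  # ties: lowest-numbered unit
    ref <- known_chars[[best]]
    mism <- which(ref != uc)
    list(
      best_match = names(known)[best],
      snps = tibble::tibble(
        offset = mism - 1L,
        ref = ref[mism],
        obs = uc[mism]
      )
    )
  })

  units <- tibble::tibble(
    index = seq_len(n_units),
    sequence = unit_seqs,
    best_match = purrr::map_chr(calls, "best_match"),
    n_snps = purrr::map_int(calls, ~ nrow(.x$snps)),
    snps = purrr::map(calls, "snps")
  )

  out <- structure(
    list(
      strain_id = strain_id,
      units = units,
      left_flank = substring(seq, 1L, span_start - 1L),
      right_flank = substring(seq, span_end + 1L),
      n_units = n_units,
      lib = lib
    ),
    class = "ctd_decomposition"
  )
  out
}

#' @export
print.ctd_decomposition <- function(x, ...) {
  cat("<ctd_decomposition>", x$strain_id, "-", x$n_units, "units of",
      x$lib$unit_length, "bp,", sum(x$units$n_snps), "SNP(s) vs library\n")
  invisible(x)
}

#' @export
tidy.ctd_decomposition <- function(x, ...) {
  dplyr::mutate(x$units, strain_id = x$strain_id, .before = 1L)
}

#' Reassemble the input sequence from a decomposition
#'
#' @param decomp A `ctd_decomposition`.
#' @return The original sequence (round-trip identity).
#' @export
reassemble <- function(decomp) {
  paste0(decomp$left_flank, paste(decomp$units$sequence, collapse = ""),
         decomp$right_flank)
}

#' Translate a decomposition unit-by-unit and locate stop codons
#'
#' Each 21-bp unit is translated to a heptad. `functional_repeats` counts the
#' heptads fully preceding the first stop codon (all of them when no stop is
#' present), the quantity that determines viability of the encoded CTD.
#'
#' @param decomp A `ctd_decomposition`.
#' @return A list with `n_heptads`, `n_consensus_heptads`, `first_stop_unit`
#'   (1-based unit index or `NA`), `functional_repeats`, and `heptads` (a
#'   character vector of per-unit translations, `*` marking stops).
#' @examples
#' lib <- ctd_repeat_library()
#' d <- decompose_repeats(build_ctd_construct(26, lib, stops_at_units = 8:11)$sequence, lib)
#' translate_and_check(d)$functional_repeats
#' @export
translate_and_check <- function(decomp) {
  lib <- decomp$lib
  if (lib$unit_length %% 3L != 0L) {
    stop("frame error: unit length not divisible by 3", call. = FALSE)
  }
  heptads <- vapply(decomp$units$sequence, translate_dna, character(1),
                    USE.NAMES = FALSE)
  has_stop <- grepl("*", heptads, fixed = TRUE)
  first_stop_unit <- if (any(has_stop)) which(has_stop)[1] else NA_integer_
  functional <- if (is.na(first_stop_unit)) length(heptads) else first_stop_unit - 1L
  list(
    n_heptads = length(heptads),
    n_consensus_heptads = sum(heptads == lib$heptad_consensus),
    first_stop_unit = first_stop_unit,
    functional_repeats = as.integer(functional),
    heptads = heptads
  )
}
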