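#' Classify suppressor colonies from amplicon lengths
#'
#' Length-based calling of suppressor events against the reporter construct's
#' reference amplicon. Within `tolerance_bp` of the reference the colony is
#' `other` (extragenic or no length change); shorter is a `contraction`;
#' longer is a `recombination` when the band sits at the genomic wild-type
#' length *and* the reporter is `CTD8` (a 4stop recombination band is
#' indistinguishable from the reference by PCR), otherwise an `expansion`.
#' `delta_units` is the signed whole-unit change `round((amplicon - reference)
#' / 21)`.
#'
#' @param events A tibble with at least `amplicon_bp`; optional `colony_id`,
#'   `strain`, `reporter` columns are carried through (a missing `reporter`
#'   defaults to the `reporter` argument).
#' @param reference_bp Reporter construct amplicon length in bp.
#' @param wildtype_bp Genomic 26-repeat amplicon length in bp.
#' @param reporter `"CTD8"` or `"4stop"`; used when `events` has no reporter
#'   column.
#' @param tolerance_bp Band-calling tolerance (default 10, under half a unit).
#' @param unit_length Repeat unit length (default 21).
#' @return The input tibble with `assigned_class` and `delta_units` added.
#' @examples
#' classify_events(tibble::tibble(amplicon_bp = c(666, 750, 582)),
#'                 reference_bp = 666, wildtype_bp = 1044, reporter = "CTD8")
#' @export
classify_events <- function(events, reference_bp, wildtype_bp,
                            reporter = c("CTD8", "4stop"),
                            tolerance_bp = 10, unit_length = 21) {
  if (!is.data.frame(events)) {
    events <- tibble::tibble(amplicon_bp = events)
  }
  if (!"reporter" %in% names(events)) {
    events$reporter <- match.arg(reporter)
  }
  if (any(events$amplicon_bp <= 0) || reference_bp <= 0 || wildtype_bp <= 0) {
    stop("input error: amplicon lengths must be positive", call. = FALSE)
  }
  diffs <- events$amplicon_bp - reference_bp
  near_wt <- abs(events$amplicon_bp - wildtype_bp) <= tolerance_bp
  cls <- dplyr::case_when(
    abs(diffs) <= tolerance_bp ~ "other",
    diffs < -tolerance_bp ~ "contraction",
    near_wt & events$reporter == "CTD8" ~ "recombination",
    TRUE ~ "expansion"
  )
  events$assigned_class <- cls
  events$delta_units <- as.integer(round(diffs / unit_length))
  events
}

#' Tally suppressor event classes per strain and reporter
#'
#' Counts and integer percentages (half-up rounding) per class, as in the
#' published suppressor tables. Totals are always recomputed from the class
#' counts; if the input carries a `total` column that disagrees, a warning
#' surfaces the discrepancy rather than reconciling it.
#'
#' @param events A tibble with `assigned_class` and optionally `strain`,
#'   `reporter` (missing grouping columns are filled with `"all"`).
#' @return A tibble with `strain`, `reporter`, `class`, `count`, `total`,
#'   `percent` (integer).
#' @examples
#' tally_events(tibble::tibble(assigned_class = c("expansion", "other")))
#' @export
tally_events <- function(events) {
  stopifnot(nrow(events) >= 1L)
  if (!"strain" %in% names(events)) events$strain <- "all"
  if (!"reporter" %in% names(events)) events$reporter <- "all"
  if ("total" %in% names(events)) {
    chk <- dplyr::summarise(
      dplyr::group_by(events, .data$strain, .data$reporter),
      n = dplyr::n(), claimed = .data$total[1], .groups = "drop")
    bad <- chk[chk$n != chk$claimed, ]
    if (nrow(bad) > 0L) {
      warning("recomputed totals disagree with the `total` column for: ",
              paste(bad$strain, bad$reporter, sep = "/", collapse = ", "),
              call. = FALSE)
    }
  }
  out <- dplyr::summarise(
    dplyr::group_by(events, .data$strain, .data$reporter,
                    class = .data$assigned_class),
    count = dplyr::n(), .groups = "drop_last")
  out <- dplyr::mutate(out, total = sum(.data$count),
                       percent = as.integer(floor(100 * .data$count /
                                                    .data$total + 0.5)))
  dplyr::ungroup(out)
}

#' Call a deletion junction and its microhomology from a parent/suppressor pair
#'
#' Finds the single contiguous deletion that turns the parent into the
#' suppressor sequence. `microhomology_len` is the overlap of the longest
#' common prefix and suffix (`|P| + |S| - len(suppressor)`), i.e. the number
#' of equivalent one-base shifts of the junction; the reported placement is
#' the leftmost. `flank_homology` additionally reports the longest identity
#' between the sequence immediately 5' of the deletion and the sequence at
#' the start of the retained 3' flank, the homology visible on both sides of
#' the junction.
#'
#' @param parent_seq,suppressor_seq ACGT sequences; the suppressor must be
#'   strictly shorter.
#' @return A tibble with one row: `deletion_start`, `deletion_end` (0-based
#'   half-open on the parent, leftmost placement), `deleted_bp`,
#'   `microhomology_len`, `placement_min`, `placement_max` (range of
#'   equivalent 0-based start positions), `flank_homology`, `flag` (`NA`, or
#'   `"no-deletion"` / `"multi-segment"` with the coordinate columns `NA`).
#' @examples
#' find_deletion_junction("AAATTTCCCGGGTTTAAA", "AAATTTTTTAAA")
#' @export
find_deletion_junction <- function(parent_seq, suppressor_seq) {
  check_dna(c(parent_seq, suppressor_seq))
  lp <- nchar(parent_seq)
  ls <- nchar(suppressor_seq)
  no_call <- function(flag) {
    tibble::tibble(deletion_start = NA_integer_, deletion_end = NA_integer_,
                   deleted_bp = NA_integer_, microhomology_len = NA_integer_,
                   placement_min = NA_integer_, placement_max = NA_integer_,
                   flank_homology = NA_integer_, flag = flag)
  }
  if (ls >= lp) return(no_call("no-deletion"))

  pc <- strsplit(parent_seq, "")[[1]]
  sc <- strsplit(suppressor_seq, "")[[1]]
  p <- common_prefix_len(pc, sc)
  s <- common_suffix_len(pc, sc)
  if (p + s < ls) return(no_call("multi-segment"))

  D <- lp - ls
  overlap <- p + s - ls                 # junction placement ambiguity
  a_min <- ls - s                       # leftmost deletion start (0-based)
  a_max <- p
  a <- a_min
  e <- a + D                            # half-open end on parent

  # longest k for which the k-bp suffix of the retained left flank equals the
  # k-bp prefix of the retained right flank (both read 5'->3')
  fh <- 0L
  for (k in seq_len(min(a, lp - e))) {
    if (identical(pc[(a - k + 1L):a], pc[(e + 1L):(e + k)])) fh <- k
  }

  tibble::tibble(
    deletion_start = a, deletion_end = e, deleted_bp = D,
    microhomology_len = overlap, placement_min = a_min, placement_max = a_max,
    flank_homology = fh, flag = NA_character_
  )
}

common_prefix_len <- function(a, b) {
  n <- min(length(a), length(b))
  if (n == 0L) return(0L)
  neq <- which(a[seq_len(n)] != b[seq_len(n)])
  if (length(neq) == 0L) n else neq[1] - 1L
}

common_suffix_len <- function(a, b) {
  n <- min(length(a), length(b))
  if (n == 0L) return(0L)
  ra <- rev(a)[seq_len(n)]
  rb <- rev(b)[seq_len(n)]
  neq <- which(ra != rb)
  if (length(neq) == 0L) n else neq[1] - 1L
}

#' Check the protein encoded by a suppressor sequence
#'
#' Decomposes the suppressor and delegates to [translate_and_check()].
#'
#' @param suppressor_seq ACGT sequence containing the repeat region.
#' @param lib A [ctd_repeat_library()].
#' @return A list with `functional_repeats` and `all_consensus` (`TRUE` iff
#'   every heptad equals the consensus and no unit carries a stop).
#' @export
check_suppressor_protein <- function(suppressor_seq, lib = ctd_repeat_library()) {
  d <- decompose_repeats(suppressor_seq, lib)
  tc <- translate_and_check(d)
  list(
    functional_repeats = tc$functional_repeats,
    all_consensus = is.na(tc$first_stop_unit) &&
      tc$n_consensus_heptads == tc$n_heptads
  )
}

#' Viability class of a CTD by functional repeat count
#'
#' Fewer than 8 functional repeats cannot support growth; 8-9 give impaired
#' growth; 10 or more grow normally. Thresholds are configurable.
#'
#' @param functional_repeats Non-negative integer(s).
#' @param impaired_min,normal_min Class thresholds (defaults 8 and 10).
#' @return Character vector in `inviable`/`impaired`/`normal`.
#' @examples
#' viability_class(c(7, 8, 10, 26))
#' @export
viability_class <- function(functional_repeats, impaired_min = 8L,
                            normal_min = 10L) {
  stopifnot(all(functional_repeats >= 0))
  dplyr::case_when(
    functional_repeats < impaired_min ~ "inviable",
    functional_repeats < normal_min ~ "impaired",
    TRUE ~ "normal"
  )
}
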