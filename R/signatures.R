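#' Base composition of a region on either strand
#'
#' Exact A/C/G/T counts and fractions. The noncoding strand is the reverse
#' complement, so its counts are the coding strand's with A<->T and C<->G
#' swapped. The CTD coding strand is strongly C-over-G biased; the template
#' strand is correspondingly G-rich.
#'
#' @param seq ACGT DNA sequence (coding-strand orientation).
#' @param region_id Label carried into the result.
#' @param strand `"coding"` or `"noncoding"`.
#' @param on_ambiguity `"error"` to reject non-ACGT letters, `"skip"` to drop
#'   them before counting.
#' @return A tibble with one row per base: `region_id`, `strand`, `base`,
#'   `count`, `fraction`.
#' @examples
#' lib <- ctd_repeat_library()
#' composition_stats(paste(lib$known_units, collapse = ""), region_id = "CTD")
#' @export
composition_stats <- function(seq, region_id = "region",
                              strand = c("coding", "noncoding"),
                              on_ambiguity = c("error", "skip")) {
  strand <- match.arg(strand)
  on_ambiguity <- match.arg(on_ambiguity)
  if (on_ambiguity == "skip") {
    seq <- gsub("[^ACGT]", "", seq)
  } else {
    check_dna(seq)
  }
  if (strand == "noncoding") seq <- reverse_complement(seq)
  chars <- strsplit(seq, "")[[1]]
  counts <- vapply(c("A", "C", "G", "T"), function(b) sum(chars == b), integer(1))
  tibble::tibble(
    region_id = region_id,
    strand = strand,
    base = names(counts),
    count = unname(counts),
    fraction = unname(counts) / max(1L, length(chars))
  )
}

#' Sliding-window G-C and A-T skew profile
#'
#' Windows of `window_bp` at stride `window_bp - overlap_bp`; any trailing
#' partial window is dropped. `G_minus_C` far below zero marks C-rich spans of
#' the given strand, the signature that singles out the CTD repeat region from
#' its genomic surroundings.
#'
#' @param seq ACGT DNA sequence.
#' @param window_bp Window size in bp (default 150).
#' @param overlap_bp Overlap between adjacent windows in bp (default 50).
#' @return A `ctd_skew_profile` tibble with columns `start` (0-based),
#'   `end` (half-open), `G_minus_C`, `A_minus_T`.
#' @examples
#' skew_windows(strrep("ACGT", 120))
#' @export
skew_windows <- function(seq, window_bp = 150L, overlap_bp = 50L) {
  check_dna(seq)
  window_bp <- as.integer(window_bp)
  overlap_bp <- as.integer(overlap_bp)
  if (window_bp <= overlap_bp) {
    stop("parameter error: `window_bp` must exceed `overlap_bp`", call. = FALSE)
  }
  if (nchar(seq) < window_bp) {
    stop("sequence shorter than one window", call. = FALSE)
  }
  step <- window_bp - overlap_bp
  chars <- strsplit(seq, "")[[1]]
  cum <- apply(cbind(G = chars == "G", C = chars == "C",
                     A = chars == "A", T = chars == "T"), 2, cumsum)
  starts0 <- seq.int(0L, nchar(seq) - window_bp, by = step)
  lo <- starts0       # cum index of base before window (0 => zero row)
  hi <- starts0 + window_bp
  cnt <- function(b) cum[hi, b] - ifelse(lo == 0L, 0L, cum[pmax(lo, 1L), b])
  out <- tibble::tibble(
    start = starts0,
    end = starts0 + window_bp,
    G_minus_C = as.integer(cnt("G") - cnt("C")),
    A_minus_T = as.integer(cnt("A") - cnt("T"))
  )
  class(out) <- c("ctd_skew_profile", class(out))
  attr(out, "window_bp") <- window_bp
  attr(out, "overlap_bp") <- overlap_bp
  out
}

#' Find QGRS-style G-quadruplex candidate motifs
#'
#' Scans for motifs of four G-tracts of at least `min_tract` consecutive
#' guanines separated by loops of `min_loop` to `max_loop` bases, within a
#' total span of at most `max_span` bp. All valid tract 4-tuples are
#' enumerated; overlapping candidates are resolved greedily by highest score
#' (sum of tract lengths minus the loop-length spread), leftmost first, so the
#' reported motifs are mutually non-overlapping per strand. Minus-strand
#' motifs are found on the reverse complement and reported in plus-strand
#' coordinates.
#'
#' @param seq ACGT DNA sequence (plus strand).
#' @param strand_mode `"+"`, `"-"` or `"both"`.
#' @param min_tract Minimum G-tract length (default 2).
#' @param n_tracts Number of tracts (default 4).
#' @param min_loop,max_loop Loop-length bounds in bases (defaults 1 and 9,
#'   i.e. loops of fewer than 10 bases and no zero-length loops).
#' @param max_span Maximum motif span in bp (default 45).
#' @return A tibble with columns `start`, `end` (0-based half-open, plus-strand
#'   coordinates), `strand`, `tract_starts`, `tract_lengths` (list-columns),
#'   `loop_lengths` (list-column of 3 integers) and `score`, sorted by start.
#' @examples
#' find_g4_motifs("AAAGGGTTAGGGTTAGGGTTAGGGAA")
#' @export
find_g4_motifs <- function(seq, strand_mode = c("+", "-", "both"),
                           min_tract = 2L, n_tracts = 4L,
                           min_loop = 1L, max_loop = 9L, max_span = 45L) {
  strand_mode <- match.arg(strand_mode)
  check_dna(seq)
  if (min_loop > max_loop) {
    stop("parameter error: `min_loop` exceeds `max_loop`", call. = FALSE)
  }
  strands <- if (strand_mode == "both") c("+", "-") else strand_mode
  res <- purrr::map_dfr(strands, function(st) {
    s <- if (st == "+") seq else reverse_complement(seq)
    hits <- g4_scan_one(s, min_tract, n_tracts, min_loop, max_loop, max_span)
    if (nrow(hits) == 0L) return(hits)
    hits$strand <- st
    if (st == "-") {
      L <- nchar(seq)
      new_start <- L - hits$end
      hits$end <- L - hits$start
      hits$start <- new_start
      hits$tract_starts <- purrr::map2(hits$tract_starts, hits$tract_lengths,
                                       ~ rev(L - (.x + .y)))
      hits$tract_lengths <- purrr::map(hits$tract_lengths, rev)
      hits$loop_lengths <- purrr::map(hits$loop_lengths, rev)
    }
    hits
  })
  if (nrow(res) == 0L) return(empty_g4_tbl())
  dplyr::arrange(dplyr::relocate(res, "start", "end", "strand"), .data$start)
}

empty_g4_tbl <- function() {
  tibble::tibble(start = integer(), end = integer(), strand = character(),
                 tract_starts = list(), tract_lengths = list(),
                 loop_lengths = list(), score = numeric())
}

# single-strand scan: enumerate candidate tracts (all sub-tracts of maximal
# G-runs of length >= min_tract), DFS over ordered 4-tuples under the loop and
# span constraints, then greedy non-overlapping selection by score.
g4_scan_one <- function(seq, min_tract, n_tracts, min_loop, max_loop, max_span) {
  chars <- strsplit(seq, "")[[1]]
  r <- rle(chars == "G")
  run_ends <- cumsum(r$lengths)
  run_starts <- run_ends - r$lengths + 1L
  g_runs <- which(r$values & r$lengths >= min_tract)
  if (length(g_runs) == 0L) return(empty_g4_tbl())

  # candidate tracts as (start0, len)
  cand <- list()
  for (g in g_runs) {
    rs <- run_starts[g]; rl <- r$lengths[g]
    for (len in min_tract:rl) {
      for (s in rs:(rs + rl - len)) {
        cand[[length(cand) + 1L]] <- c(s - 1L, len)  # 0-based start
      }
    }
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]

  hits <- list()
  n_cand <- nrow(cand)
  dfs <- function(chosen) {
    if (length(chosen) == n_tracts) {
      st <- cand[chosen[1], 1]
      en <- cand[chosen[n_tracts], 1] + cand[chosen[n_tracts], 2]
      tl <- cand[chosen, 2]
      loops <- cand[chosen[-1], 1] -
        (cand[chosen[-n_tracts], 1] + cand[chosen[-n_tracts], 2])
      hits[[length(hits) + 1L]] <<- list(
        start = st, end = en, tract_starts = cand[chosen, 1],
        tract_lengths = tl, loop_lengths = loops,
        score = sum(tl) - (max(loops) - min(loops))
      )
      return(invisible())
    }
    last <- chosen[length(chosen)]
    last_end <- cand[last, 1] + cand[last, 2]
    first_start <- cand[chosen[1], 1]
    for (k in seq_len(n_cand)) {
      loop <- cand[k, 1] - last_end
      if (loop < min_loop || loop > max_loop) next
      if (cand[k, 1] + cand[k, 2] - first_start > max_span) next
      dfs(c(chosen, k))
    }
  }
  for (k in seq_len(n_cand)) {
    if (cand[k, 2] + (n_tracts - 1L) * min_tract <= max_span) dfs(k)
  }
  if (length(hits) == 0L) return(empty_g4_tbl())

  tbl <- tibble::tibble(
    start = vapply(hits, `[[`, integer(1), "start"),
    end = vapply(hits, `[[`, integer(1), "end"),
    strand = NA_character_,
    tract_starts = purrr::map(hits, "tract_starts"),
    tract_lengths = purrr::map(hits, "tract_lengths"),
    loop_lengths = purrr::map(hits, "loop_lengths"),
    score = vapply(hits, `[[`, numeric(1), "score")
  )
  tbl <- dplyr::arrange(tbl, dplyr::desc(.data$score), .data$start, .data$end)
  taken <- rep(FALSE, nrow(tbl))
  occupied <- integer(0)
  for (i in seq_len(nrow(tbl))) {
    span <- seq.int(tbl$start[i], tbl$end[i] - 1L)
    if (!any(span %in% occupied)) {
      taken[i] <- TRUE
      occupied <- c(occupied, span)
    }
  }
  dplyr::arrange(tbl[taken, ], .data$start)
}
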