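#' Align repeat architectures across strains at the unit level
#'
#' Progressive unit-level alignment of decomposed repeat regions. Whole units
#' are the alignment symbols: substituting one unit for another costs its
#' Hamming distance times `snp_cost_per_base`, and a unit gap costs
#' `unit_gap_cost`. With the defaults a whole-unit indel is always preferred
#' over four or more coincident SNPs, encoding the rule that repeat-length
#' changes must not be misread as clusters of point mutations.
#'
#' Events are called per column against the column consensus: strains missing
#' a unit that the majority carries get `unit_loss`; strains carrying a unit
#' that only a minority carries get `unit_gain`; base differences from the
#' consensus unit are reported as one `snp` event per (strain, column, offset).
#'
#' @param decomps A list of [decompose_repeats()] results sharing a library.
#' @param unit_gap_cost Cost of gapping one whole unit (default 4).
#' @param snp_cost_per_base Cost per mismatched base (default 1).
#'
#' @return A `ctd_arch_alignment`: list with `strains`, `columns` (a character
#'   matrix, rows = strains, cells = unit sequence or `NA` for a gap),
#'   `matches` (same shape, best-match unit names) and `events` (tibble with
#'   `strain`, `kind` in `unit_gain`/`unit_loss`/`snp`, `column`, `detail`).
#' @examples
#' lib <- ctd_repeat_library()
#' a <- decompose_repeats(build_ctd_construct(26, lib)$sequence, lib, strain_id = "a")
#' b <- decompose_repeats(build_ctd_construct(26, lib)$sequence, lib, strain_id = "b")
#' align_architectures(list(a, b))$events
#' @export
align_architectures <- function(decomps, unit_gap_cost = 4,
                                snp_cost_per_base = 1) {
  stopifnot(length(decomps) >= 2L)
  uls <- vapply(decomps, function(d) d$lib$unit_length, integer(1))
  if (length(unique(uls)) != 1L) {
    stop("library error: decompositions use different unit lengths", call. = FALSE)
  }
  strains <- vapply(decomps, function(d) d$strain_id, character(1))
  lib <- decomps[[1]]$lib

  # rows of the growing alignment: character vectors with NA gaps. A strain
  # whose unit sequence is identical to an already-aligned strain reuses that
  # row's gap pattern, so identical sequences always get identical gapped
  # rows (DP tie-breaking could otherwise place an equivalent gap elsewhere
  # in a run of identical units).
  aln <- matrix(decomps[[1]]$units$sequence, nrow = 1L)
  row_key <- function(r) paste(r[!is.na(r)], collapse = "|")
  for (i in seq_along(decomps)[-1]) {
    units_i <- decomps[[i]]$units$sequence
    prev <- which(vapply(seq_len(nrow(aln)),
                         function(r) row_key(aln[r, ]),
                         character(1)) == paste(units_i, collapse = "|"))
    if (length(prev) > 0L) {
      aln <- rbind(aln, aln[prev[1], ])
    } else {
      aln <- align_row_to_profile(aln, units_i,
                                  unit_gap_cost, snp_cost_per_base)
    }
  }
  rownames(aln) <- strains
  keep <- colSums(!is.na(aln)) > 0L
  aln <- aln[, keep, drop = FALSE]

  matches <- apply(aln, c(1, 2), function(u) {
    if (is.na(u)) NA_character_ else best_match_name(u, lib)
  })

  events <- call_events(aln, strains)
  structure(
    list(strains = strains, columns = aln, matches = matches,
         events = events, lib = lib),
    class = "ctd_arch_alignment"
  )
}

# Needleman-Wunsch of a new unit sequence against the profile of the current
# alignment. Column representative = modal non-gap unit (first seen on ties).
# Traceback prefers diagonal, then a gap in the new row, then a gap column,
# which places indels deterministically.
align_row_to_profile <- function(aln, new_units, gap, snp_cost) {
  reps <- apply(aln, 2, function(col) {
    col <- col[!is.na(col)]
    tab <- table(factor(col, levels = unique(col)))
    names(tab)[which.max(tab)]
  })
  n <- length(reps)
  m <- length(new_units)
  sub <- matrix(0, n, m)
  if (n > 0L && m > 0L) {
    for (i in seq_len(n)) {
      for (j in seq_len(m)) {
        sub[i, j] <- hamming(reps[i], new_units[j]) * snp_cost
      }
    }
  }
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1] <- gap * (0:n)
  S[1, ] <- gap * (0:m)
  ptr <- matrix(0L, n + 1L, m + 1L)  # 1 diag, 2 up (gap in new), 3 left (gap in profile)
  ptr[, 1] <- 2L
  ptr[1, ] <- 3L
  ptr[1, 1] <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cand <- c(S[i, j] + sub[i, j], S[i, j + 1] + gap, S[i + 1, j] + gap)
      k <- which.min(cand)
      S[i + 1, j + 1] <- cand[k]
      ptr[i + 1, j + 1] <- k
    }
  }
  # traceback
  path <- list()
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    k <- ptr[i + 1L, j + 1L]
    if (k == 1L) { path[[length(path) + 1L]] <- c(i, j); i <- i - 1L; j <- j - 1L }
    else if (k == 2L) { path[[length(path) + 1L]] <- c(i, 0L); i <- i - 1L }
    else { path[[length(path) + 1L]] <- c(0L, j); j <- j - 1L }
  }
  path <- rev(path)
  ncol_out <- length(path)
  out <- matrix(NA_character_, nrow(aln) + 1L, ncol_out)
  for (p in seq_along(path)) {
    ci <- path[[p]][1]; cj <- path[[p]][2]
    if (ci > 0L) out[seq_len(nrow(aln)), p] <- aln[, ci]
    if (cj > 0L) out[nrow(aln) + 1L, p] <- new_units[cj]
  }
  out
}

best_match_name <- function(u, lib) {
  uc <- strsplit(u, "")[[1]]
  d <- vapply(strsplit(unname(lib$known_units), ""),
              function(k) sum(k != uc), integer(1))
  names(lib$known_units)[which.min(d)]
}

call_events <- function(aln, strains) {
  rows <- list()
  for (col in seq_len(ncol(aln))) {
    cells <- aln[, col]
    present <- !is.na(cells)
    n_present <- sum(present)
    n_gap <- sum(!present)
    if (n_gap > 0L && n_present >= n_gap) {
      for (s in which(!present)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          strain = strains[s], kind = "unit_loss", column = col,
          detail = "21-bp unit absent")
      }
    } else if (n_present < n_gap) {
      for (s in which(present)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          strain = strains[s], kind = "unit_gain", column = col,
          detail = "21-bp unit present in minority of strains")
      }
    }
    if (n_present > 1L) {
      vals <- cells[present]
      tab <- table(factor(vals, levels = unique(vals)))
      consensus <- names(tab)[which.max(tab)]
      cc <- strsplit(consensus, "")[[1]]
      for (s in which(present)) {
        if (cells[s] != consensus) {
          sc <- strsplit(cells[s], "")[[1]]
          for (off in which(sc != cc)) {
            rows[[length(rows) + 1L]] <- tibble::tibble(
              strain = strains[s], kind = "snp", column = col,
              detail = sprintf("offset %d %s>%s", off - 1L, cc[off], sc[off]))
          }
        }
      }
    }
  }
  if (length(rows) == 0L) {
    tibble::tibble(strain = character(), kind = character(),
                   column = integer(), detail = character())
  } else {
    dplyr::bind_rows(rows)
  }
}

#' @export
print.ctd_arch_alignment <- function(x, ...) {
  cat("<ctd_arch_alignment>", length(x$strains), "strains x",
      ncol(x$columns), "unit columns;", nrow(x$events), "event(s)\n")
  invisible(x)
}

#' @export
tidy.ctd_arch_alignment <- function(x, ...) x$events

#' Group strains by identical repeat architecture
#'
#' Strains whose gapped unit rows are identical (same units, same SNPs, same
#' gaps) share a group.
#'
#' @param alignment A [align_architectures()] result.
#' @return A tibble with columns `strain` and `group` (integer group id, in
#'   order of first appearance).
#' @export
group_architectures <- function(alignment) {
  keys <- apply(alignment$columns, 1, function(r) {
    paste(ifelse(is.na(r), "-", r), collapse = "|")
  })
  tibble::tibble(
    strain = alignment$strains,
    group = as.integer(factor(keys, levels = unique(keys)))
  )
}

#' Count SNP instances in an architecture alignment
#'
#' Counts each (strain, column, offset) SNP occurrence once, so a polymorphism
#' shared by three strains contributes three. Set `per_site = TRUE` to count
#' each (column, offset, base change) site once instead.
#'
#' @param alignment A [align_architectures()] result.
#' @param per_site Count unique sites rather than strain occurrences.
#' @return An integer.
#' @export
count_snps <- function(alignment, per_site = FALSE) {
  snps <- dplyr::filter(alignment$events, .data$kind == "snp")
  if (per_site) {
    nrow(dplyr::distinct(snps, .data$column, .data$detail))
  } else {
    nrow(snps)
  }
}

#' Architecture table of an alignment
#'
#' One row per strain, one column per alignment column; cells are best-match
#' unit names or `-` for a gap (the block diagram as a table).
#'
#' @param alignment A [align_architectures()] result.
#' @return A tibble, first column `strain`.
#' @export
architecture_table <- function(alignment) {
  m <- alignment$matches
  df <- as.data.frame(ifelse(is.na(m), "-", m), stringsAsFactors = FALSE)
  names(df) <- sprintf("col%02d", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(strain = alignment$strains),
                   tibble::as_tibble(df))
}
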