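# Independent brute-force oracles used to cross-check the package's
# implementations. These are written for clarity, not speed, and share no code
# with the functions they check.

# all-frames brute tiler: finds every (left anchor, right anchor) occurrence
# pair, keeps pairs whose inter-anchor span is a whole number of units, and
# tiles naively.
oracle_tile <- function(seq, lib) {
  ul <- lib$unit_length
  find_all <- function(pat) {
    out <- integer(0); from <- 1L
    repeat {
      hit <- regexpr(pat, substring(seq, from), fixed = TRUE)[1]
      if (hit < 0) break
      out <- c(out, from + hit - 1L)
      from <- from + hit
    }
    out
  }
  lefts <- find_all(lib$left_anchor)
  rights <- find_all(lib$right_anchor)
  res <- list()
  for (l in lefts) {
    span_start <- l + nchar(lib$left_anchor)
    for (r in rights) {
      if (r < span_start) next
      span_len <- r - span_start
      if (span_len %% ul != 0L) next
      n <- span_len %/% ul
      units <- if (n > 0) {
        vapply(seq_len(n), function(i) {
          substr(seq, span_start + (i - 1L) * ul, span_start + i * ul - 1L)
        }, character(1))
      } else character(0)
      res[[length(res) + 1L]] <- units
    }
  }
  res
}

# exhaustive pairwise unit alignment: tries every placement of g gaps in the
# shorter unit list against the longer, returns the minimum total cost
# (gap cost per gapped unit + per-base mismatch cost elsewhere) and whether
# any optimal placement needs base mismatches.
oracle_pair_align <- function(units_a, units_b, gap = 4, snp = 1) {
  if (length(units_a) < length(units_b)) {
    tmp <- units_a; units_a <- units_b; units_b <- tmp
  }
  g <- length(units_a) - length(units_b)
  ham <- function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  gap_sets <- utils::combn(length(units_a), g, simplify = FALSE)
  if (g == 0L) gap_sets <- list(integer(0))
  best <- Inf; best_mism <- NA
  for (gs in gap_sets) {
    keep <- setdiff(seq_along(units_a), gs)
    mism <- sum(mapply(ham, units_a[keep], units_b))
    cost <- g * gap + mism * snp
    if (cost < best) { best <- cost; best_mism <- mism }
  }
  list(cost = best, mismatches = best_mism)
}

# dense-grid MSS likelihood maximizer (uses the package pmf only as the
# probability model; the optimization itself is the oracle for mss_mle).
oracle_grid_mle <- function(counts, grid = exp(seq(log(0.01), log(200), length.out = 4000))) {
  kmax <- max(counts)
  ll <- vapply(grid, function(m) {
    p <- ctdlab::ld_pmf(m, kmax)
    sum(log(pmax(p[counts + 1L], 1e-300)))
  }, numeric(1))
  grid[which.max(ll)]
}

# independent Luria-Delbruck Monte-Carlo sampler: Poisson mutations, clone
# sizes by inverse-CDF of the q_j = 1/(j(j+1)) law (P(clone >= j) = 1/j).
oracle_ld_sample <- function(n, m, cap = 1e7) {
  vapply(seq_len(n), function(i) {
    M <- rpois(1, m)
    if (M == 0) return(0)
    sum(pmin(floor(1 / runif(M)), cap))
  }, numeric(1))
}

# exhaustive G4 motif enumerator on short strings: every ordered 4-tuple of
# non-overlapping all-G intervals with tract length >= min_tract, loops in
# [min_loop, max_loop], span <= max_span.
oracle_g4 <- function(seq, min_tract = 2, min_loop = 1, max_loop = 9,
                      max_span = 45) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  tracts <- list()
  for (s in seq_len(L)) {
    for (e in s:L) {
      if (e - s + 1L < min_tract) next
      if (all(chars[s:e] == "G")) {
        tracts[[length(tracts) + 1L]] <- c(s, e)
      } else break
    }
  }
  out <- list()
  nt <- length(tracts)
  if (nt < 4) return(out)
  starts <- vapply(tracts, `[`, integer(1), 1)
  ends <- vapply(tracts, `[`, integer(1), 2)
  # tracts reachable from tract i through one admissible loop
  succ <- lapply(seq_len(nt), function(i) {
    which(starts - ends[i] - 1L >= min_loop & starts - ends[i] - 1L <= max_loop)
  })
  for (i1 in 1:nt) for (i2 in succ[[i1]]) for (i3 in succ[[i2]]) {
    for (i4 in succ[[i3]]) {
      if (ends[i4] - starts[i1] + 1L > max_span) next
      out[[length(out) + 1L]] <- list(
        start = starts[i1] - 1L, end = ends[i4],
        tract_lengths = c(ends[i1] - starts[i1], ends[i2] - starts[i2],
                          ends[i3] - starts[i3], ends[i4] - starts[i4]) + 1L,
        loop_lengths = c(starts[i2] - ends[i1], starts[i3] - ends[i2],
                         starts[i4] - ends[i3]) - 1L
      )
    }
  }
  out
}

# exhaustive deletion-pair oracle: all (start, end) single deletions of the
# parent that reproduce the suppressor, 0-based half-open.
oracle_deletions <- function(parent, sup) {
  lp <- nchar(parent); ls <- nchar(sup)
  D <- lp - ls
  if (D <= 0) return(list())
  hits <- list()
  for (a in 0:ls) {
    cand <- paste0(substr(parent, 1, a), substr(parent, a + D + 1, lp))
    if (cand == sup) hits[[length(hits) + 1L]] <- c(a, a + D)
  }
  hits
}

random_dna <- function(n, probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}
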