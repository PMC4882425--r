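#' Repeat-unit libraries for the CTD coding region
#'
#' A repeat library describes the building blocks of the CTD coding region: the
#' unit length (21 bp, one YSPTSPS heptad), a consensus unit, and a set of
#' named known unit sequences against which observed units are matched.
#'
#' @section The bundled synthetic library:
#' The default library returned by [ctd_repeat_library()] is a *synthetic*
#' stand-in for the S288C repeat set. Its 26 degenerate 21-bp units all encode
#' the YSPTSPS heptad through varied synonymous codons, only two units share
#' the same sequence, and the concatenated coding strand carries the strong
#' cytosine-over-guanine imbalance characteristic of the real locus
#' (225 C : 44 G over 546 bp). It reproduces the degeneracy statistics of the
#' locus, not the literal genomic sequence.
#'
#' @param unit_length Repeat unit length in bp. Must be a multiple of 3.
#' @param consensus_unit Consensus DNA sequence of one unit.
#' @param known_units Named character vector of known unit sequences, each of
#'   `unit_length` bp.
#' @param left_anchor,right_anchor Flanking anchor sequences that delimit the
#'   repeat span and fix the reading frame.
#' @param heptad_consensus Expected translation of `consensus_unit`.
#'
#' @return An object of class `ctd_repeat_library`: a list with elements
#'   `unit_length`, `consensus_unit`, `known_units`, `left_anchor`,
#'   `right_anchor` and `heptad_consensus`.
#' @examples
#' lib <- ctd_repeat_library()
#' lib$unit_length
#' length(lib$known_units)
#' @export
ctd_repeat_library <- function() {
  units <- c(
    "TATTCGCCAACTTCTCCGTCC",
    "TATTCTCCGACTTCGCCATCC",
    "TATTCTCCAACGTCGCCATCC",
    "TACTCGCCAACTTCTCCGTCA",
    "TATTCCCCGACTAGTCCATCC",
    "TATTCTCCTACGTCTCCGTCC",
    "TACTCTCCAACGTCGCCATCA",
    "TATAGCCCAACTTCGCCATCC",
    "TATTCTCCGACGTCTCCATCC",
    "TATTCGCCTACTTCTCCGTCC",
    "TACTCTCCGACTTCTCCGTCA",
    "TATTCCCCAACGTCTCCGTCT",
    "TATAGTCCAACTTCCCCGTCC",
    "TATTCGCCAACCTCTCCGTCT",
    "TACTCACCGACTTCTCCGTCT",
    "TATTCTCCGACTTCCCCATCG",
    "TATTCGCCAACTTCTCCGTCC",
    "TATTCTCCAACTAGTCCGTCC",
    "TATTCTCCAACTTCGCCATCT",
    "TATTCGCCAACTTCTCCATCT",
    "TATTCTCCGACTTCACCATCT",
    "TATTCTCCAACGTCTCCATCT",
    "TATAGTCCAACTTCTCCATCC",
    "TATTCTCCAACTAGTCCATCC",
    "TATTCACCGACTTCTCCATCT",
    "TATTCTCCTACTTCGCCATCT"
  )
  names(units) <- sprintf("r%02d", seq_along(units))
  new_repeat_library(
    unit_length = 21L,
    consensus_unit = "TATTCTCCAACTTCTCCATCC",
    known_units = units,
    left_anchor = "GATGAAGCTCAAGCTGGTTTC",
    right_anchor = "TAAGCTTCTGAAGAAGACAAC",
    heptad_consensus = "YSPTSPS"
  )
}

#' @rdname ctd_repeat_library
#' @export
new_repeat_library <- function(unit_length, consensus_unit, known_units,
                               left_anchor, right_anchor,
                               heptad_consensus = "YSPTSPS") {
  unit_length <- as.integer(unit_length)
  if (unit_length <= 0L || unit_length %% 3L != 0L) {
    stop("`unit_length` must be a positive multiple of 3", call. = FALSE)
  }
  check_dna(c(consensus_unit, known_units, left_anchor, right_anchor))
  if (nchar(consensus_unit) != unit_length ||
      any(nchar(known_units) != unit_length)) {
    stop("all units must have length `unit_length`", call. = FALSE)
  }
  if (is.null(names(known_units)) || any(!nzchar(names(known_units)))) {
    names(known_units) <- sprintf("r%02d", seq_along(known_units))
  }
  if (translate_dna(consensus_unit) != heptad_consensus) {
    stop("`consensus_unit` does not translate to `heptad_consensus`",
         call. = FALSE)
  }
  structure(
    list(
      unit_length = unit_length,
      consensus_unit = consensus_unit,
      known_units = known_units,
      left_anchor = left_anchor,
      right_anchor = right_anchor,
      heptad_consensus = heptad_consensus
    ),
    class = "ctd_repeat_library"
  )
}

#' Read a repeat library from a unit FASTA plus a YAML config
#'
#' The FASTA holds the named known units; the YAML supplies `unit_length`,
#' `consensus_unit`, `left_anchor` and `right_anchor` (and optionally
#' `heptad_consensus`).
#'
#' @param fasta_path Path to a FASTA file of unit sequences.
#' @param config_path Path to a YAML configuration file.
#' @return A `ctd_repeat_library`.
#' @export
read_repeat_library <- function(fasta_path, config_path) {
  recs <- read_fasta(fasta_path)
  cfg <- yaml::read_yaml(config_path)
  for (field in c("unit_length", "consensus_unit", "left_anchor", "right_anchor")) {
    if (is.null(cfg[[field]])) {
      stop("repeat-library config is missing field `", field, "`", call. = FALSE)
    }
  }
  units <- stats::setNames(recs$sequence, recs$id)
  new_repeat_library(
    unit_length = cfg$unit_length,
    consensus_unit = cfg$consensus_unit,
    known_units = units,
    left_anchor = cfg$left_anchor,
    right_anchor = cfg$right_anchor,
    heptad_consensus = cfg$heptad_consensus %||% "YSPTSPS"
  )
}

#' @export
print.ctd_repeat_library <- function(x, ...) {
  cat("<ctd_repeat_library>\n")
  cat("  unit_length:", x$unit_length, "bp\n")
  cat("  known_units:", length(x$known_units),
      sprintf("(%d distinct)", length(unique(x$known_units))), "\n")
  cat("  heptad_consensus:", x$heptad_consensus, "\n")
  cat("  anchors:", x$left_anchor, "...", x$right_anchor, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- small sequence utilities -------------------------------------------------

check_dna <- function(seqs, what = "sequence") {
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    stop("non-ACGT characters in ", what, call. = FALSE)
  }
  invisible(seqs)
}

translate_dna <- function(seq) {
  if (nchar(seq) == 0L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(seq),
                                     if.fuzzy.codon = "error"))
}

#' Reverse complement of a DNA sequence
#'
#' @param seq A character vector of ACGT-only DNA sequences.
#' @return The reverse complement(s), as a character vector.
#' @examples
#' reverse_complement("GGGTTA")
#' @export
reverse_complement <- function(seq) {
  check_dna(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
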