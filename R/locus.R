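# Target locus and edit specification: the geometric frame every design
# operation works in.
#
# Conventions (used package-wide):
#   * The NON-TARGET strand carries the protospacer and the NGG PAM; the
#     SpCas9-H840A nickase nicks it `nick_offset` (default 3) nt 5' of the
#     PAM, i.e. between from-PAM positions 4 and 3.
#   * Spacer/protospacer positions are numbered from the PAM: position 1 is
#     the PAM-proximal base, position 20 (or 21 for a 21G spacer) the
#     5'-most.
#   * PBS position 1 is the PBS 5' end (RTT-adjacent); it pairs the
#     nick-adjacent base of the resected primer strand.

#' Define a target locus
#'
#' @param reference DNA [nuc_seq]: the amplicon/locus, forward strand.
#' @param protospacer_start 0-based start of the 20-nt protospacer footprint
#'   on the forward strand (half-open `[start, start + 20)`). For
#'   `strand = "+"` this is also the protospacer's 5'-most base.
#' @param strand `"+"` if the forward strand is the non-target strand
#'   (protospacer read left to right), `"-"` otherwise.
#' @param min_upstream Required non-target-strand context 5' of the
#'   protospacer, so that long PBSs (which reach beyond from-PAM position
#'   20) and a margin exist. Default 25.
#' @return A `target_locus` object.
#' @export
target_locus <- function(reference, protospacer_start, strand = "+",
                         min_upstream = 25L) {
  reference <- as_nuc(reference)
  if (seq_alphabet(reference) != "DNA") abort("reference must be DNA")
  strand <- match.arg(strand, c("+", "-"))
  protospacer_start <- as.integer(protospacer_start)
  n <- nchar(reference)
  if (protospacer_start < 0L || protospacer_start + 20L > n) {
    abort("protospacer footprint outside the reference")
  }
  nt <- if (strand == "+") as.character(reference)
        else as.character(revcomp(reference))
  ps <- if (strand == "+") protospacer_start else n - protospacer_start - 20L
  if (ps + 23L > n) abort("no room for a PAM 3' of the protospacer")
  pam <- substr(nt, ps + 21L, ps + 23L)
  if (!grepl("^[ACGT]GG$", pam)) {
    abort(sprintf("PAM at the stated coordinate is '%s', expected NGG", pam))
  }
  if (ps < min_upstream) {
    abort(sprintf(
      "reference extends only %d nt 5' of the protospacer (need >= %d)",
      ps, min_upstream))
  }
  structure(list(
    reference = reference,
    protospacer_start = protospacer_start,
    strand = strand,
    nt_strand = nt,          # non-target strand, 5'->3'
    ps = ps,                 # protospacer start on nt_strand (0-based)
    protospacer = substr(nt, ps + 1L, ps + 20L),
    pam = pam
  ), class = "target_locus")
}

#' @export
print.target_locus <- function(x, ...) {
  cat(sprintf(
    "<target_locus> %d nt reference, protospacer @%d (%s)\n  protospacer 5'-%s-3' PAM %s\n",
    nchar(x$reference), x$protospacer_start, x$strand, x$protospacer, x$pam))
  invisible(x)
}

# from-PAM position k -> 0-based index on the non-target strand
from_pam_index <- function(locus, k) locus$ps + 20L - as.integer(k)

# between-base nick coordinate on the non-target strand (0-based: the nick
# sits immediately before this index)
nick_index <- function(locus, nick_offset = 3L) {
  locus$ps + 20L - as.integer(nick_offset)
}

#' Nick coordinate on the forward strand
#'
#' Between-base, 0-based coordinate of the pegRNA nick on the forward
#' strand of the reference, for use with [amplicon_spec()].
#' @param locus A [target_locus].
#' @param nick_offset Distance of the nick from the PAM, in nt. Default 3.
#' @return Integer between-base coordinate.
#' @export
nick_site <- function(locus, nick_offset = 3L) {
  k <- nick_index(locus, nick_offset)
  if (locus$strand == "+") k else nchar(locus$reference) - k
}

#' Specify an intended edit relative to the nick
#'
#' Coordinates count in nucleotides 3' of the nick on the non-target
#' strand: `nick_distance = 1` is the first nucleotide after the nick.
#' Exactly one of `ref`/`alt` may be empty (`""`): empty `ref` is an
#' insertion, empty `alt` a deletion; equal-length non-empty alleles are a
#' substitution.
#'
#' @param nick_distance First edited position, integer >= 1.
#' @param ref Reference allele on the non-target strand (`""` for
#'   insertions).
#' @param alt Replacement allele (`""` for deletions).
#' @return An `edit_spec` object.
#' @examples
#' edit_spec(1, "A", "G")    # substitution
#' edit_spec(1, "", "TT")    # 2-nt insertion
#' edit_spec(2, "CA", "")    # 2-nt deletion
#' @export
edit_spec <- function(nick_distance, ref, alt) {
  nick_distance <- as.integer(nick_distance)
  if (is.na(nick_distance) || nick_distance < 1L) {
    abort("`nick_distance` must be an integer >= 1")
  }
  ref <- toupper(ref); alt <- toupper(alt)
  for (a in c(ref, alt)) {
    if (nzchar(a) && !grepl("^[ACGT]+$", a)) abort("alleles must be DNA")
  }
  if (!nzchar(ref) && !nzchar(alt)) abort("ref and alt cannot both be empty")
  type <- if (!nzchar(ref)) "insertion"
          else if (!nzchar(alt)) "deletion"
          else if (nchar(ref) == nchar(alt)) "substitution"
          else abort("ref/alt of unequal non-zero length: split the edit")
  structure(list(edit_type = type, nick_distance = nick_distance,
                 ref = ref, alt = alt),
            class = "edit_spec")
}

#' @export
print.edit_spec <- function(x, ...) {
  cat(sprintf("<edit_spec> %s @nick+%d: '%s' -> '%s'\n",
              x$edit_type, x$nick_distance, x$ref, x$alt))
  invisible(x)
}

#' Non-target strand 3' of the nick
#'
#' The non-target-strand sequence starting at the first nucleotide after
#' the nick (`nick_distance` 1) and running 5'->3' to the end of the
#' reference, optionally with an edit applied. This is the strand segment
#' the RTT is templated against. Errors if the edit's ref allele does not
#' match the reference.
#'
#' @param locus A [target_locus].
#' @param edit Optional [edit_spec] to apply.
#' @param nick_offset Nick distance from the PAM. Default 3.
#' @return A plain DNA string.
#' @export
downstream_of_nick <- function(locus, edit = NULL, nick_offset = 3L) {
  d <- substr(locus$nt_strand, nick_index(locus, nick_offset) + 1L,
              nchar(locus$nt_strand))
  if (is.null(edit)) return(d)
  t <- edit$nick_distance
  m <- nchar(edit$ref)
  if (m > 0L) {
    found <- substr(d, t, t + m - 1L)
    if (nchar(found) < m || found != edit$ref) {
      abort(sprintf(
        "ref allele mismatch at nick+%d: reference has '%s', edit says '%s'",
        t, found, edit$ref))
    }
  }
  paste0(substr(d, 1L, t - 1L), edit$alt,
         substr(d, t + m, nchar(d)))
}

#' Generate a random target locus
#'
#' Synthetic-locus helper used throughout the test-suite and examples: a
#' random DNA reference with a protospacer + NGG PAM placed so that ample
#' context exists on both sides. Draws from the current RNG stream; wrap in
#' a seed for reproducibility.
#'
#' @param n_upstream Context 5' of the protospacer on the non-target
#'   strand. Default 30.
#' @param n_downstream Context 3' of the PAM. Default 40.
#' @param strand Strand for the locus. Default `"+"`.
#' @return A [target_locus].
#' @export
random_locus <- function(n_upstream = 30L, n_downstream = 40L, strand = "+") {
  nt <- paste0(random_dna(n_upstream), random_dna(20L), "A",
               "GG", random_dna(n_downstream))
  # randomise the PAM N
  substr(nt, n_upstream + 21L, n_upstream + 21L) <- sample(DNA_BASES, 1L)
  if (strand == "+") {
    target_locus(nuc_seq(nt), n_upstream, "+")
  } else {
    ref <- revcomp(nuc_seq(nt))
    target_locus(ref, nchar(ref) - n_upstream - 20L, "-")
  }
}
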