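# pegRNA part construction and assembly. A peg_design holds its parts
# (all RNA) plus the provenance of every modification; the full sequence is
# always recomputed from the parts, never stored.

#' Build the spacer for a locus
#'
#' The spacer is the RNA copy of the 20-nt protospacer on the non-target
#' strand. Under `u6_mode` a G is prepended when the protospacer does not
#' already start with one (U6 polymerase initiation), giving a 21-nt
#' spacer; 21G spacers may tolerate the mismatch-based designs less well,
#' so a warning string is attached.
#'
#' @param locus A [target_locus].
#' @param u6_mode Prepend a 5' G when needed. Default `TRUE`.
#' @return List with `spacer` (RNA [nuc_seq]), `has_appended_5prime_G`,
#'   `warnings` (character vector).
#' @export
build_spacer <- function(locus, u6_mode = TRUE) {
  stopifnot(inherits(locus, "target_locus"))
  spacer <- as.character(to_rna(nuc_seq(locus$protospacer)))
  appended <- FALSE
  warnings <- character()
  if (u6_mode && substr(spacer, 1L, 1L) != "G") {
    spacer <- paste0("G", spacer)
    appended <- TRUE
    warnings <- "21G spacer: appended 5' G may reduce mismatch tolerance"
  }
  list(spacer = nuc_seq(spacer, "RNA"),
       has_appended_5prime_G = appended,
       warnings = warnings)
}

#' Build a primer binding site
#'
#' The PBS (5'->3') is the complement of the non-target strand at from-PAM
#' positions `nick_offset + 1 ... nick_offset + length`, in that order --
#' equivalently the reverse complement, as RNA, of the 3'-terminal `length`
#' nucleotides of the nicked primer strand. PBS position 1 (the 5' end,
#' RTT-adjacent) pairs the nick-adjacent primer base, so `build_pbs(L)` is
#' always a prefix of `build_pbs(L + 1)`.
#'
#' @param locus A [target_locus].
#' @param length PBS length, 1..25.
#' @param nick_offset Nick distance from the PAM. Default 3.
#' @return RNA [nuc_seq].
#' @export
build_pbs <- function(locus, length, nick_offset = 3L) {
  stopifnot(inherits(locus, "target_locus"))
  length <- as.integer(length)
  if (is.na(length) || length < 1L || length > 25L) {
    abort("PBS length must be in 1..25")
  }
  hi <- nick_index(locus, nick_offset)      # 0-based, exclusive on the left
  lo <- hi - length
  if (lo < 0L) abort("PBS length exceeds the available 5' context")
  primer_3p <- substr(locus$nt_strand, lo + 1L, hi)
  to_rna(revcomp(nuc_seq(primer_3p)))
}

#' Build a reverse-transcription template
#'
#' The RTT (RNA, 5'->3') is the reverse complement of the EDITED non-target
#' strand starting at the first base 3' of the nick and extending
#' `rtt_length` edited-sequence nucleotides; reverse-transcribing it from
#' the nick therefore reproduces the edited strand exactly. The right
#' homology arm is whatever extends past the edit, and must be >= 1 nt.
#'
#' @param locus A [target_locus].
#' @param edit An [edit_spec].
#' @param rtt_length RTT length in nt; default
#'   `nick_distance + nchar(alt) + 10` (10-nt homology arm).
#' @param nick_offset Nick distance from the PAM. Default 3.
#' @return RNA [nuc_seq].
#' @export
build_rtt <- function(locus, edit, rtt_length = NULL, nick_offset = 3L) {
  stopifnot(inherits(locus, "target_locus"), inherits(edit, "edit_spec"))
  if (is.null(rtt_length)) {
    rtt_length <- edit$nick_distance + nchar(edit$alt) + 10L
  }
  rtt_length <- as.integer(rtt_length)
  # the edit ends at edited-strand position nick_distance + |alt| - 1; the
  # homology arm is whatever lies beyond it and must be >= 1 nt
  min_len <- edit$nick_distance + nchar(edit$alt)
  if (rtt_length < min_len) {
    abort(sprintf(
      "rtt_length %d too short: edit outside the RTT window (need >= %d)",
      rtt_length, min_len))
  }
  edited <- downstream_of_nick(locus, edit, nick_offset)
  if (nchar(edited) < rtt_length) {
    abort("reference too short 3' of the nick for the requested RTT")
  }
  to_rna(revcomp(nuc_seq(substr(edited, 1L, rtt_length))))
}

#' Assemble a pegRNA from parts
#'
#' Part order 5'->3': spacer, scaffold, RTT, PBS, optional 3' end motif
#' (e.g. an epegRNA pseudoknot, treated as an opaque configured sequence).
#'
#' @param spacer,scaffold,rtt,pbs RNA sequences (strings or [nuc_seq]).
#' @param end_motif Optional RNA 3' motif.
#' @param has_appended_5prime_G Provenance flag from [build_spacer()].
#' @param warnings Character vector of advisory warnings to carry.
#' @return A `peg_design`.
#' @export
assemble_pegrna <- function(spacer, scaffold = default_scaffold(), rtt, pbs,
                            end_motif = NULL,
                            has_appended_5prime_G = FALSE,
                            warnings = character()) {
  parts <- list(spacer = spacer, scaffold = scaffold, rtt = rtt, pbs = pbs)
  parts <- lapply(parts, function(p) {
    p <- as_nuc(p)
    if (seq_alphabet(p) != "RNA") abort("all pegRNA parts must be RNA")
    as.character(p)
  })
  if (!is.null(end_motif)) {
    end_motif <- as.character(to_rna(as_nuc(end_motif)))
  }
  structure(list(
    spacer = parts$spacer,
    has_appended_5prime_G = isTRUE(has_appended_5prime_G),
    scaffold = parts$scaffold,
    rtt = parts$rtt,
    pbs = parts$pbs,
    end_motif = end_motif,
    pbs_original = parts$pbs,       # PBS before any modification
    pbs_modifications = list(),     # list of (kind, position, length, note)
    spacer_mismatches = list(),     # list of (position, ref, alt, class)
    origin = "base",
    warnings = warnings
  ), class = "peg_design")
}

#' Full pegRNA sequence
#'
#' Recomputed concatenation of the parts (spacer + scaffold + RTT + PBS +
#' optional end motif); never stored independently.
#' @param design A `peg_design`.
#' @return RNA [nuc_seq].
#' @export
peg_full_sequence <- function(design) {
  stopifnot(inherits(design, "peg_design"))
  nuc_seq(paste0(design$spacer, design$scaffold, design$rtt, design$pbs,
                 design$end_motif %||% ""), "RNA")
}

#' Split a full pegRNA sequence back into parts
#'
#' Inverse of [peg_full_sequence()] given the part lengths.
#' @param full_sequence RNA sequence.
#' @param lengths Named integer vector with `spacer`, `scaffold`, `rtt`,
#'   `pbs` and optionally `end_motif`.
#' @return Named list of RNA strings.
#' @export
disassemble_pegrna <- function(full_sequence, lengths) {
  full_sequence <- as.character(to_rna(as_nuc(full_sequence)))
  need <- c("spacer", "scaffold", "rtt", "pbs")
  if (!all(need %in% names(lengths))) {
    abort("lengths must name spacer, scaffold, rtt and pbs")
  }
  ord <- c(need, if ("end_motif" %in% names(lengths)) "end_motif")
  lens <- as.integer(lengths[ord])
  if (sum(lens) != nchar(full_sequence)) {
    abort("part lengths do not sum to the sequence length")
  }
  ends <- cumsum(lens)
  starts <- c(1L, head(ends, -1L) + 1L)
  setNames(Map(function(s, e) substr(full_sequence, s, e), starts, ends), ord)
}

#' @export
print.peg_design <- function(x, ...) {
  cat(sprintf(
    "<peg_design '%s'> spacer %d nt | scaffold %d nt | RTT %d nt | PBS %d nt%s\n",
    x$origin, nchar(x$spacer), nchar(x$scaffold), nchar(x$rtt), nchar(x$pbs),
    if (is.null(x$end_motif)) "" else sprintf(" | motif %d nt",
                                              nchar(x$end_motif))))
  if (length(x$pbs_modifications) || length(x$spacer_mismatches)) {
    cat(sprintf("  modifications: %d PBS, %d spacer mismatch(es)\n",
                length(x$pbs_modifications), length(x$spacer_mismatches)))
  }
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  cat("  5'-", as.character(peg_full_sequence(x)), "-3'\n", sep = "")
  invisible(x)
}

#' @describeIn assemble_pegrna tidy method: one row per pegRNA part.
#' @param x A `peg_design`.
#' @param ... Unused.
#' @method tidy peg_design
#' @export
tidy.peg_design <- function(x, ...) {
  parts <- c("spacer", "scaffold", "rtt", "pbs",
             if (!is.null(x$end_motif)) "end_motif")
  tibble(
    part = parts,
    sequence = vapply(parts, function(p) x[[p]], character(1)),
    length = vapply(parts, function(p) nchar(x[[p]]), integer(1))
  )
}

#' Build a complete pegRNA for a locus/edit pair
#'
#' Convenience constructor chaining [build_spacer()], [build_pbs()] and
#' [build_rtt()] into [assemble_pegrna()].
#'
#' @inheritParams build_rtt
#' @param pbs_length PBS length. Default 13.
#' @param scaffold Scaffold RNA. Default [default_scaffold()].
#' @param end_motif Optional 3' motif RNA.
#' @param u6_mode See [build_spacer()].
#' @return A `peg_design`.
#' @export
design_pegrna <- function(locus, edit, pbs_length = 13L, rtt_length = NULL,
                          scaffold = default_scaffold(), end_motif = NULL,
                          u6_mode = TRUE, nick_offset = 3L) {
  sp <- build_spacer(locus, u6_mode = u6_mode)
  assemble_pegrna(
    spacer = sp$spacer, scaffold = scaffold,
    rtt = build_rtt(locus, edit, rtt_length, nick_offset),
    pbs = build_pbs(locus, pbs_length, nick_offset),
    end_motif = end_motif,
    has_appended_5prime_G = sp$has_appended_5prime_G,
    warnings = sp$warnings
  )
}
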