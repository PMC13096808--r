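# Wet-lab encodings of a design: annealed linker oligos for two-step
# Golden Gate cloning (spacer linker, then RTT-PBS extension linker) and a
# forward primer carrying a T7 promoter for in vitro transcription
# templates. All oligo output is DNA; RNA parts are back-transcribed U->T.

ENZYME_SITES <- c(BpiI = "GAAGAC", BsmBI = "CGTCTC")

#' Overhang configuration for Golden Gate linkers
#'
#' Ships with a documented default convention (see
#' `inst/extdata/default_overhangs.yaml`); acceptor plasmids differ, so
#' verify the overhangs against your backbone's digestion products.
#'
#' @param path YAML file with fields `spacer_top_overhang`,
#'   `spacer_bottom_overhang`, `extension_top_overhang`,
#'   `extension_bottom_overhang` (4-nt DNA each) and informational
#'   `spacer_enzyme` / `extension_enzyme` ids.
#' @return An `overhang_config` list.
#' @export
overhang_config <- function(path = NULL) {
  path <- path %||% system.file("extdata", "default_overhangs.yaml",
                                package = "spellpeg")
  cfg <- yaml::read_yaml(path)
  need <- c("spacer_top_overhang", "spacer_bottom_overhang",
            "extension_top_overhang", "extension_bottom_overhang")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    abort(sprintf("overhang config lacks: %s", paste(missing, collapse = ", ")))
  }
  for (nm in need) {
    oh <- toupper(cfg[[nm]])
    if (!grepl("^[ACGT]{4}$", oh)) {
      abort(sprintf("%s must be exactly 4 DNA nt", nm))
    }
    if (oh == as.character(revcomp(nuc_seq(oh)))) {
      abort(sprintf("%s is self-complementary", nm))
    }
    cfg[[nm]] <- oh
  }
  structure(cfg, class = "overhang_config")
}

new_oligo_pair <- function(top, bottom, core, role) {
  structure(list(top = top, bottom = bottom, anneal_core = core,
                 role = role),
            class = "oligo_pair")
}

#' @export
print.oligo_pair <- function(x, ...) {
  cat(sprintf("<oligo_pair %s>\n  top:    5'-%s-3'\n  bottom: 5'-%s-3'\n",
              x$role, x$top, x$bottom))
  invisible(x)
}

check_internal_sites <- function(insert, enzyme) {
  site <- ENZYME_SITES[[enzyme %||% ""]]
  if (is.null(site)) return(invisible())
  rc <- as.character(revcomp(nuc_seq(site)))
  if (grepl(site, insert, fixed = TRUE) || grepl(rc, insert, fixed = TRUE)) {
    warn(sprintf("insert contains an internal %s site; cloning may fail",
                 enzyme))
  }
}

#' Spacer linker oligos
#'
#' Top oligo = spacer top overhang + DNA(spacer); bottom oligo = spacer
#' bottom overhang + reverse complement of DNA(spacer). Annealing the pair
#' leaves the configured 4-nt 5' protrusions for ligation into the
#' digested backbone. A 21G spacer's appended G is encoded verbatim.
#'
#' @param design A `peg_design`.
#' @param cfg An [overhang_config()].
#' @return An `oligo_pair`.
#' @export
spacer_linker_oligos <- function(design, cfg = overhang_config()) {
  stopifnot(inherits(design, "peg_design"), inherits(cfg, "overhang_config"))
  core <- as.character(to_dna(nuc_seq(design$spacer, "RNA")))
  check_internal_sites(core, cfg$spacer_enzyme)
  new_oligo_pair(
    top = paste0(cfg$spacer_top_overhang, core),
    bottom = paste0(cfg$spacer_bottom_overhang,
                    as.character(revcomp(nuc_seq(core)))),
    core = core, role = "spacer")
}

#' Extension (RTT-PBS) linker oligos
#'
#' The insert encodes DNA(RTT + PBS), with the 3' end motif appended when
#' `include_motif` is set (for backbones that do not already carry one).
#' Modified PBSs (deletions, mismatches, scrambles) are encoded verbatim
#' -- no silent repair.
#'
#' @inheritParams spacer_linker_oligos
#' @param include_motif Append `design$end_motif` to the insert.
#'   Default `FALSE`.
#' @return An `oligo_pair`.
#' @export
extension_linker_oligos <- function(design, cfg = overhang_config(),
                                    include_motif = FALSE) {
  stopifnot(inherits(design, "peg_design"), inherits(cfg, "overhang_config"))
  rna <- paste0(design$rtt, design$pbs,
                if (isTRUE(include_motif)) design$end_motif %||% "" else "")
  core <- as.character(to_dna(nuc_seq(rna, "RNA")))
  check_internal_sites(core, cfg$extension_enzyme)
  new_oligo_pair(
    top = paste0(cfg$extension_top_overhang, core),
    bottom = paste0(cfg$extension_bottom_overhang,
                    as.character(revcomp(nuc_seq(core)))),
    core = core, role = "extension")
}

#' In-silico Golden Gate assembly
#'
#' Simulates annealing and ligation of the spacer and extension linker
#' pairs into a virtual backbone carrying the scaffold, and returns the
#' reconstructed pegRNA sequence. Reconstruction must reproduce
#' [peg_full_sequence()] byte-exactly for a correct oligo set; the
#' round trip is the cloning module's correctness check.
#'
#' @param spacer_oligos,extension_oligos `oligo_pair`s.
#' @param cfg The [overhang_config()] used to build them.
#' @param scaffold Scaffold RNA of the virtual backbone.
#' @param end_motif Optional 3' motif contributed by the backbone.
#' @return RNA [nuc_seq] of the assembled pegRNA.
#' @export
golden_gate_assemble <- function(spacer_oligos, extension_oligos,
                                 cfg = overhang_config(),
                                 scaffold = default_scaffold(),
                                 end_motif = NULL) {
  strip <- function(pair, top_oh, bottom_oh) {
    if (substr(pair$top, 1L, 4L) != top_oh ||
        substr(pair$bottom, 1L, 4L) != bottom_oh) {
      abort("oligo overhangs do not match the configuration")
    }
    ins <- substr(pair$top, 5L, nchar(pair$top))
    back <- substr(pair$bottom, 5L, nchar(pair$bottom))
    if (as.character(revcomp(nuc_seq(back))) != ins) {
      abort("top and bottom oligo cores are not complementary")
    }
    ins
  }
  spacer <- strip(spacer_oligos, cfg$spacer_top_overhang,
                  cfg$spacer_bottom_overhang)
  ext <- strip(extension_oligos, cfg$extension_top_overhang,
               cfg$extension_bottom_overhang)
  nuc_seq(paste0(as.character(to_rna(nuc_seq(spacer))), scaffold,
                 as.character(to_rna(nuc_seq(ext))),
                 if (is.null(end_motif)) "" else as.character(to_rna(as_nuc(end_motif)))),
          "RNA")
}

#' T7 in vitro transcription template primer
#'
#' Forward primer = T7 promoter + DNA of the design's first `anneal_len`
#' nucleotides. T7 initiates best on G, so a warning is raised when the
#' first transcribed base is not G.
#'
#' @param design A `peg_design`.
#' @param t7_promoter Promoter DNA. Default the 18-nt minimal T7 promoter
#'   ending at the +1 position.
#' @param anneal_len Annealing length. Default 20.
#' @return DNA [nuc_seq] primer.
#' @export
t7_ivt_template_primer <- function(design,
                                   t7_promoter = "TAATACGACTCACTATAG",
                                   anneal_len = 20L) {
  stopifnot(inherits(design, "peg_design"))
  full <- as.character(peg_full_sequence(design))
  anneal_len <- as.integer(anneal_len)
  if (anneal_len > nchar(full)) abort("anneal_len exceeds the design length")
  if (substr(full, 1L, 1L) != "G") {
    warn("first transcribed base is not G: T7 initiation may be inefficient")
  }
  nuc_seq(paste0(toupper(t7_promoter),
                 as.character(to_dna(nuc_seq(substr(full, 1L, anneal_len), "RNA")))),
          "DNA")
}

#' Oligo order sheet
#'
#' Flattens oligo pairs into a tibble (name, sequence, length) ready for
#' TSV/CSV export.
#'
#' @param ... Named `oligo_pair`s.
#' @return A tibble.
#' @export
oligo_order_sheet <- function(...) {
  pairs <- list(...)
  if (is.null(names(pairs)) || any(!nzchar(names(pairs)))) {
    names(pairs) <- vapply(pairs, function(p) p$role, character(1))
  }
  bind_rows(imap(pairs, function(p, nm) {
    tibble(name = paste0(nm, c("_top", "_bottom")),
           sequence = c(p$top, p$bottom),
           length = nchar(c(p$top, p$bottom)))
  }))
}
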