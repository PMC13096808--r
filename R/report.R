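# Candidate comparison across PBS lengths: one row per candidate with the
# sequence, duplex thermodynamics and complementarity burden, ranked by
# distance from the 37 C Tm guideline.

#' Design report across PBS lengths
#'
#' Builds one pegRNA candidate per requested PBS length and tabulates its
#' PBS sequence, PBS:non-target-strand Tm and dG(37 C), the number of
#' spacer:PBS Watson-Crick pairs, the covered spacer positions and a
#' `rank_tm37` ranking hint (1 = Tm closest to 37 C). Duplicate lengths
#' are deduplicated with a warning. With `spell = TRUE` an extra row holds
#' the default SPELL design (PBS 20, single deletion at position 13).
#'
#' @param locus A [target_locus].
#' @param edit An [edit_spec].
#' @param pbs_lengths Integer vector of PBS lengths. Default `c(7, 10, 13, 17, 20)`.
#' @param rtt_length RTT length (default rule of [build_rtt()]).
#' @param spell Append the default SPELL candidate. Default `FALSE`.
#' @param nick_offset,u6_mode,scaffold Passed to the builders.
#' @param parameter_set_id,salt_mM,strand_conc_nM Passed to [duplex_tm()].
#' @return A `design_report` tibble, one row per candidate.
#' @export
design_report <- function(locus, edit, pbs_lengths = c(7L, 10L, 13L, 17L, 20L),
                          rtt_length = NULL, spell = FALSE,
                          nick_offset = 3L, u6_mode = TRUE,
                          scaffold = default_scaffold(),
                          parameter_set_id = "rna_dna_sugimoto1995",
                          salt_mM = 50, strand_conc_nM = 250) {
  pbs_lengths <- as.integer(pbs_lengths)
  if (anyDuplicated(pbs_lengths)) {
    warn("duplicate PBS lengths requested; deduplicating")
    pbs_lengths <- unique(pbs_lengths)
  }
  row_for <- function(design, label, L) {
    cm <- complementarity_map(design, nick_offset)
    dup <- duplex_tm(design$pbs, parameter_set_id = parameter_set_id,
                     salt_mM = salt_mM, strand_conc_nM = strand_conc_nM)
    cov <- covered_spacer_positions(cm)
    tibble(
      candidate = label,
      pbs_length = nchar(design$pbs),
      pbs = as.character(design$pbs),
      rtt = as.character(design$rtt),
      spacer = as.character(design$spacer),
      tm_celsius = dup$tm_celsius,
      delta_g_kcal_per_mol = dup$delta_g_kcal_per_mol,
      n_paired = attr(cm, "n_paired"),
      covered = if (length(cov))
        paste0(min(cov), "-", max(cov)) else "",
      abs_tm_minus_37 = abs(dup$tm_celsius - 37),
      full_sequence = as.character(peg_full_sequence(design))
    )
  }
  rows <- lapply(pbs_lengths, function(L) {
    d <- design_pegrna(locus, edit, pbs_length = L, rtt_length = rtt_length,
                       scaffold = scaffold, u6_mode = u6_mode,
                       nick_offset = nick_offset)
    row_for(d, sprintf("PBS%d", L), L)
  })
  if (isTRUE(spell)) {
    sd <- make_spell(locus, edit, rtt_length = rtt_length,
                     scaffold = scaffold, u6_mode = u6_mode,
                     nick_offset = nick_offset)
    rows <- c(rows, list(row_for(sd, "SPELL(PBS20,del13)", 20L)))
  }
  out <- bind_rows(rows)
  if (nrow(out)) {
    out$rank_tm37 <- as.integer(rank(out$abs_tm_minus_37,
                                     ties.method = "first"))
  } else {
    out$rank_tm37 <- integer(0)
  }
  structure(out, class = c("design_report", class(out)))
}

#' @describeIn design_report autoplot: Tm against PBS length with the
#'   37 C guideline.
#' @param object A `design_report`.
#' @param ... Unused.
#' @method autoplot design_report
#' @export
autoplot.design_report <- function(object, ...) {
  ggplot(object, aes(x = .data$pbs_length, y = .data$tm_celsius)) +
    geom_hline(yintercept = 37, linetype = "dashed", colour = "grey50") +
    geom_line(colour = "grey70") +
    geom_point(aes(colour = .data$n_paired), size = 2.5) +
    labs(x = "PBS length (nt)", y = "PBS:non-target strand Tm (°C)",
         colour = "spacer:PBS\npairs",
         title = "PBS candidates vs the 37 °C guideline") +
    theme_minimal()
}

#' Write a design report as TSV
#' @param report A `design_report` (or any tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  readr::write_tsv(as_tibble(report), path)
  invisible(path)
}
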