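# Nearest-neighbor duplex thermodynamics for the PBS:non-target-strand
# heteroduplex (and, with the RNA:RNA table, for spacer:PBS pairing).
# Parameter tables are data, not code: they ship as annotated TSV files
# under inst/extdata and are addressed by a parameter_set_id recorded in
# every report. A PBS:non-target-strand Tm near 37 C is a widely used
# design guideline; design_report() ranks candidates by |Tm - 37|.

the_nn_cache <- new.env(parent = emptyenv())

#' Load a nearest-neighbor parameter table
#'
#' @param parameter_set_id `"rna_dna_sugimoto1995"` (RNA:DNA heteroduplex,
#'   the default for PBS:non-target strand) or `"rna_rna_freier1986"`
#'   (RNA:RNA), or a path to a TSV with columns `dinucleotide` (RNA 5'->3',
#'   plus an `init` row), `dh` (kcal/mol) and `ds` (cal/(mol*K)).
#' @return A list with `stacks` (named list of c(dh, ds)), `init`,
#'   and `id`.
#' @export
nn_table <- function(parameter_set_id = "rna_dna_sugimoto1995") {
  if (!is.null(the_nn_cache[[parameter_set_id]])) {
    return(the_nn_cache[[parameter_set_id]])
  }
  path <- if (file.exists(parameter_set_id)) parameter_set_id
  else system.file("extdata", paste0("nn_", parameter_set_id, ".tsv"),
                   package = "spellpeg")
  if (!nzchar(path) || !file.exists(path)) {
    abort(sprintf("unknown nearest-neighbor parameter set '%s'",
                  parameter_set_id))
  }
  raw <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!all(c("dinucleotide", "dh", "ds") %in% names(raw))) {
    abort("parameter file needs columns dinucleotide, dh, ds")
  }
  init_row <- raw$dinucleotide == "init"
  if (!any(init_row)) abort("parameter file lacks an 'init' row")
  tab <- list(
    id = parameter_set_id,
    init = c(dh = raw$dh[init_row][1], ds = raw$ds[init_row][1]),
    stacks = setNames(
      Map(function(h, s) c(dh = h, ds = s),
          raw$dh[!init_row], raw$ds[!init_row]),
      raw$dinucleotide[!init_row])
  )
  the_nn_cache[[parameter_set_id]] <- tab
  tab
}

R_GAS_CAL <- 1.987  # cal/(mol*K)

#' Duplex melting temperature and free energy
#'
#' Two-state nearest-neighbor model for the duplex between an RNA strand
#' (the PBS, 5'->3') and its template strand. dH and dS are summed over
#' the stacks of the table named by `parameter_set_id`, plus initiation.
#' The salt correction dS' = dS + 0.368 (N-1) ln[monovalent] enters the
#' melting temperature, Tm = 1000 dH / (dS' + R ln(CT/4)) - 273.15, for
#' non-self-complementary strands at total strand concentration CT. dG is
#' reported at 37 C at the tables' 1 M NaCl standard state.
#'
#' Mismatches against the provided template are tolerated but their stacks
#' are excluded from the summation and their count is reported; the model
#' is intended for perfect or near-perfect duplexes.
#'
#' @param pbs RNA strand (string or [nuc_seq]), 5'->3'.
#' @param template Template strand 5'->3' (DNA for the default table). If
#'   `NULL`, the perfect complement of `pbs` is used.
#' @param parameter_set_id See [nn_table()].
#' @param salt_mM Monovalent cation concentration. Default 50.
#' @param strand_conc_nM Total strand concentration CT. Default 250.
#' @return A `duplex_report`: one-row tibble with `tm_celsius`,
#'   `delta_g_kcal_per_mol`, `delta_h`, `delta_s`, `n_bp`, `n_mismatch`,
#'   `parameter_set_id`, `salt_mM`, `strand_conc_nM`.
#' @examples
#' duplex_tm("UAGCGUUCCAAGG")
#' @export
duplex_tm <- function(pbs, template = NULL,
                      parameter_set_id = "rna_dna_sugimoto1995",
                      salt_mM = 50, strand_conc_nM = 250) {
  pbs <- to_rna(as_nuc(pbs))
  n <- nchar(pbs)
  if (n < 2L) abort("duplex shorter than 2 bp: no stacks to sum")
  tmpl_alphabet <- if (grepl("rna_rna", parameter_set_id)) "RNA" else "DNA"
  if (is.null(template)) {
    template <- revcomp(if (tmpl_alphabet == "DNA") to_dna(pbs) else pbs)
  }
  template <- as_nuc(template)
  if (nchar(template) != n) {
    abort("pbs and template must have equal length for the paired region")
  }
  # pairing in register, antiparallel: pbs[i] vs template[n - i + 1]
  t_rna <- as.character(to_rna(template))
  p_chr <- strsplit(as.character(pbs), "")[[1]]
  t_chr <- rev(strsplit(t_rna, "")[[1]])
  paired <- complement_base(p_chr, "RNA") == t_chr
  n_mismatch <- sum(!paired)

  tab <- nn_table(parameter_set_id)
  dh <- unname(tab$init["dh"]); ds <- unname(tab$init["ds"])
  for (i in seq_len(n - 1L)) {
    if (paired[i] && paired[i + 1L]) {
      st <- tab$stacks[[paste0(p_chr[i], p_chr[i + 1L])]]
      if (is.null(st)) abort("incomplete stack table")
      dh <- dh + st["dh"]; ds <- ds + st["ds"]
    }
  }
  ds_salt <- ds + 0.368 * (n - 1L) * log(salt_mM / 1000)
  ct <- strand_conc_nM * 1e-9
  tm <- 1000 * dh / (ds_salt + R_GAS_CAL * log(ct / 4)) - 273.15
  # dG37 at the tables' 1 M NaCl standard state (uncorrected entropy):
  # strictly additive in stacks, so longer perfect duplexes are always
  # more stable
  dg37 <- dh - 310.15 * ds / 1000
  out <- tibble(
    tm_celsius = unname(tm),
    delta_g_kcal_per_mol = unname(dg37),
    delta_h = unname(dh), delta_s = unname(ds),
    n_bp = n, n_mismatch = n_mismatch,
    parameter_set_id = tab$id,
    salt_mM = salt_mM, strand_conc_nM = strand_conc_nM
  )
  structure(out, class = c("duplex_report", class(out)))
}

#' @describeIn duplex_tm glance method (the one-row report itself).
#' @param x A `duplex_report`.
#' @param ... Unused.
#' @method glance duplex_report
#' @export
glance.duplex_report <- function(x, ...) as_tibble(unclass(x)[seq_along(x)])
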