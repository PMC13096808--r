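# Independent oracles and fixture builders shared across the test files.
# Every oracle re-derives its answer from raw strings, deliberately
# avoiding the package's register/alignment machinery.

RNA_COMP <- c(A = "U", C = "G", G = "C", U = "A")
DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A")

oracle_revcomp_dna <- function(s) {
  paste(rev(DNA_COMP[strsplit(s, "")[[1]]]), collapse = "")
}

# brute-force spacer:PBS pairing: walk the PBS 5'->3'; PBS position p
# pairs spacer from-PAM position orig(p) + nick_offset, where orig() maps
# through any single deletion (start d, length k) in original coordinates
oracle_pairs <- function(spacer, pbs, nick_offset = 3L,
                         del_start = NULL, del_len = 0L) {
  s_len <- nchar(spacer)
  orig <- seq_len(nchar(pbs) + del_len)
  if (!is.null(del_start)) {
    orig <- orig[-(del_start:(del_start + del_len - 1L))]
  }
  out <- list()
  for (p in seq_len(nchar(pbs))) {
    partner <- orig[p] + nick_offset
    if (partner < 1L || partner > s_len) next
    sp <- substr(spacer, s_len - partner + 1L, s_len - partner + 1L)
    pb <- substr(pbs, p, p)
    out[[length(out) + 1L]] <- data.frame(
      pbs_position = p, spacer_position = partner,
      wc = unname(RNA_COMP[sp]) == pb)
  }
  if (!length(out)) {
    return(data.frame(pbs_position = integer(), spacer_position = integer(),
                      wc = logical()))
  }
  do.call(rbind, out)
}

# exhaustive windowed scan for 20-nt protospacers with an NGG PAM
oracle_protospacers <- function(seq) {
  n <- nchar(seq)
  hits <- list()
  for (i in seq_len(n - 22L)) {
    pam <- substr(seq, i + 20L, i + 22L)
    if (substr(pam, 2L, 3L) == "GG") {
      hits[[length(hits) + 1L]] <- data.frame(start = i - 1L, strand = "+")
    }
  }
  rc <- oracle_revcomp_dna(seq)
  for (i in seq_len(n - 22L)) {
    pam <- substr(rc, i + 20L, i + 22L)
    if (substr(pam, 2L, 3L) == "GG") {
      hits[[length(hits) + 1L]] <-
        data.frame(start = n - (i - 1L) - 20L, strand = "-")
    }
  }
  if (!length(hits)) return(data.frame(start = integer(), strand = character()))
  out <- do.call(rbind, hits)
  out[order(out$start, out$strand), , drop = FALSE]
}

# a locus with a protospacer given PAM-proximal-first (position 1 first)
locus_from_pam_proximal <- function(pam_proximal_bases, upstream = NULL,
                                    downstream = NULL, pam_n = "T") {
  upstream <- upstream %||% strrep("A", 25L)
  downstream <- downstream %||% strrep("C", 30L)
  proto <- paste(rev(pam_proximal_bases), collapse = "")
  nt <- paste0(upstream, proto, pam_n, "GG", downstream)
  target_locus(nuc_seq(nt), nchar(upstream), "+")
}

# deterministic random locus + simple substitution edit
rand_case <- function(pbs_length = 13L, u6_mode = FALSE) {
  loc <- random_locus()
  ref1 <- substr(downstream_of_nick(loc), 1L, 1L)
  alt1 <- setdiff(c("A", "C", "G", "T"), ref1)[1]
  ed <- edit_spec(1L, ref1, alt1)
  list(locus = loc, edit = ed,
       design = design_pegrna(loc, ed, pbs_length = pbs_length,
                              u6_mode = u6_mode))
}

expect_no_wc_beyond <- function(design, from_position) {
  cm <- tidy(complementarity_map(design))
  seg <- cm[cm$pbs_position >= from_position, ]
  testthat::expect_false(any(seg$is_watson_crick))
}
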