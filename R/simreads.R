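# Deterministic synthetic amplicon-read generator. Every read class the
# quantifier must distinguish is emitted with EXACT counts
# (largest-remainder rounding of the requested fractions), so the
# zero-error pipeline recovers the truth table exactly and the error-rate
# robustness of the classifier can be tested separately.

#' Simulate amplicon reads with a known truth table
#'
#' Read classes: the intended edit (fraction `edit_fraction`), one class
#' per row of `indel_spectrum`, and unedited reads for the remainder.
#' Class counts are exact by largest-remainder rounding. Each read is the
#' reference with its class's modification applied, then uniform
#' substitution errors at `error_rate`; by default errors are never placed
#' inside the flank-anchored edit motif of intended-edit reads, so
#' zero-rate exactness extends to the edit caller (set
#' `protect_flanks = FALSE` to lift this). Identical seeds give
#' byte-identical output.
#'
#' @param spec An [amplicon_spec()] with an edit.
#' @param n_reads Number of reads.
#' @param edit_fraction Fraction of reads carrying the intended edit.
#' @param indel_spectrum Tibble with columns `offset` (nt from the first
#'   nick site; 0 = the base immediately 3' of it), `type`
#'   (`"insertion"`/`"deletion"`), `length`, `fraction` and optionally
#'   `with_edit` (also apply the intended edit: the combined class).
#'   `NULL` for none.
#' @param error_rate Per-base substitution error probability. Default 0.
#' @param read_length Truncate reads to this length (`NULL` = full
#'   amplicon).
#' @param seed Mandatory RNG seed.
#' @param protect_flanks Keep errors out of the edit motif of
#'   edit-carrying reads. Default `TRUE`.
#' @return A `sim_reads` object: list with `reads` (tibble `read_id`,
#'   `sequence`, `class`), `truth` (per-class counts and fractions) and
#'   `config`.
#' @examples
#' loc <- with_seed(11, random_locus())
#' ed <- edit_spec(1, substr(downstream_of_nick(loc), 1, 1), "C")
#' sp <- amplicon_spec(loc$reference, nick_site(loc), ed)
#' sim <- simulate_amplicon_reads(sp, n_reads = 100, edit_fraction = 0.25,
#'                                seed = 1)
#' sim$truth
#' @export
simulate_amplicon_reads <- function(spec, n_reads, edit_fraction = 0,
                                    indel_spectrum = NULL, error_rate = 0,
                                    read_length = NULL, seed,
                                    protect_flanks = TRUE) {
  stopifnot(inherits(spec, "amplicon_spec"))
  if (is.null(spec$edit)) abort("simulation needs an amplicon_spec with an edit")
  if (missing(seed)) abort("`seed` is mandatory")
  n_reads <- as.integer(n_reads)
  if (n_reads < 1L) abort("n_reads must be >= 1")
  if (edit_fraction < 0 || edit_fraction > 1) {
    abort("edit_fraction must lie in [0, 1]")
  }
  if (!is.null(indel_spectrum)) {
    indel_spectrum <- as_tibble(indel_spectrum)
    need <- c("offset", "type", "length", "fraction")
    if (!all(need %in% names(indel_spectrum))) {
      abort(sprintf("indel_spectrum needs columns: %s",
                    paste(need, collapse = ", ")))
    }
    if (!"with_edit" %in% names(indel_spectrum)) {
      indel_spectrum$with_edit <- FALSE
    }
  } else {
    indel_spectrum <- tibble(offset = integer(), type = character(),
                             length = integer(), fraction = numeric(),
                             with_edit = logical())
  }
  fracs <- c(edit_fraction, indel_spectrum$fraction)
  if (sum(fracs) > 1 + 1e-12) abort("class fractions sum above 1")

  with_seed(seed, {
    classes <- build_read_classes(spec, indel_spectrum)
    counts <- largest_remainder(c(fracs, 1 - sum(fracs)), n_reads)
    labels <- c("intended_edit", classes$indel_labels, "unedited")
    sequences <- c(list(edited_reference(spec)), classes$indel_seqs,
                   list(spec$reference))
    windows <- c(list(motif_window(spec, 0L)), classes$indel_windows,
                 list(NULL))

    if (!is.null(read_length)) {
      read_length <- as.integer(read_length)
      min_len <- spec$edit_start + nchar(spec$edit$alt) + spec$flank + 10L
      if (read_length < min_len) {
        abort(sprintf(
          "read_length %d shorter than the edit window + 10 (need >= %d)",
          read_length, min_len))
      }
      sequences <- lapply(sequences, function(s)
        substr(s, 1L, min(read_length, nchar(s))))
    }

    class_of <- rep.int(seq_along(labels), counts)
    seqs <- unlist(sequences)[class_of]
    if (error_rate > 0) {
      widths <- nchar(seqs)
      n_err <- rbinom(n_reads, widths, error_rate)
      for (r in which(n_err > 0L)) {
        protected <- if (protect_flanks) windows[[class_of[r]]] else NULL
        allowed <- setdiff(seq_len(widths[r]), protected)
        if (!length(allowed)) next
        at <- allowed[sample.int(length(allowed),
                                 min(n_err[r], length(allowed)))]
        s <- seqs[r]
        for (p in at) {
          cur <- substr(s, p, p)
          substr(s, p, p) <- sample(setdiff(DNA_BASES, cur), 1L)
        }
        seqs[r] <- s
      }
    }
    truth <- tibble(class = labels, n_reads = counts,
                    fraction = counts / n_reads)
    out <- list(
      reads = tibble(read_id = sprintf("read_%07d", seq_len(n_reads)),
                     sequence = seqs,
                     class = labels[class_of]),
      truth = truth,
      config = list(n_reads = n_reads, edit_fraction = edit_fraction,
                    error_rate = error_rate, seed = seed,
                    read_length = read_length,
                    protect_flanks = protect_flanks)
    )
    structure(out, class = "sim_reads")
  })
}

# 1-based positions of the edit motif within an edit-carrying read whose
# upstream coordinates are shifted by `shift` nt (from an indel 5' of the
# edit in a combined-class read)
motif_window <- function(spec, shift) {
  s <- spec$edit_start + shift
  (s - spec$flank + 1L):(s + nchar(spec$edit$alt) + spec$flank)
}

build_read_classes <- function(spec, spectrum) {
  nick <- spec$nick_sites[1]
  labels <- character(0); seqs <- list(); windows <- list()
  if (nrow(spectrum)) {
    for (i in seq_len(nrow(spectrum))) {
      type <- match.arg(spectrum$type[i], c("insertion", "deletion"))
      len <- as.integer(spectrum$length[i])
      off <- as.integer(spectrum$offset[i])
      base <- if (spectrum$with_edit[i]) edited_reference(spec)
              else spec$reference
      pos <- nick + off            # 0-based anchor on the (edited) strand
      if (spectrum$with_edit[i]) {
        # the combined class must keep its edit motif intact, so the extra
        # indel may not touch the flanked span
        lo <- spec$edit_start - spec$flank
        hi <- spec$edit_start + nchar(spec$edit$alt) + spec$flank
        span <- if (type == "deletion") c(pos, pos + len) else c(pos, pos)
        if (span[2] > lo && span[1] < hi) {
          abort(sprintf(
            "with_edit indel at offset %+d intersects the edit motif span", off))
        }
      }
      if (type == "deletion") {
        if (pos < 0L || pos + len > nchar(base)) {
          abort("indel_spectrum deletion outside the amplicon")
        }
        s <- paste0(substr(base, 1L, pos),
                    substr(base, pos + len + 1L, nchar(base)))
        shift <- if (spectrum$with_edit[i] && pos + len <= spec$edit_start)
          -len else 0L
      } else {
        ins <- random_dna(len)
        s <- paste0(substr(base, 1L, pos), ins,
                    substr(base, pos + 1L, nchar(base)))
        shift <- if (spectrum$with_edit[i] && pos <= spec$edit_start)
          len else 0L
      }
      lab <- sprintf("%s%s_at%+d_len%d",
                     if (spectrum$with_edit[i]) "intended_edit_plus_" else "",
                     type, off, len)
      labels <- c(labels, lab)
      seqs <- c(seqs, list(s))
      windows <- c(windows, list(
        if (spectrum$with_edit[i]) motif_window(spec, shift) else NULL))
    }
  }
  list(indel_labels = labels, indel_seqs = seqs, indel_windows = windows)
}

# exact integer apportionment of n among fractions
largest_remainder <- function(fracs, n) {
  exact <- fracs * n
  base <- floor(exact)
  left <- n - sum(base)
  if (left > 0L) {
    ord <- order(exact - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1L
  }
  as.integer(base)
}

#' @export
print.sim_reads <- function(x, ...) {
  cat(sprintf("<sim_reads> %d reads, error rate %g, seed %d\n",
              x$config$n_reads, x$config$error_rate, x$config$seed))
  print(x$truth)
  invisible(x)
}

#' @describeIn simulate_amplicon_reads glance: the per-class truth table.
#' @param x A `sim_reads`.
#' @param ... Unused.
#' @method glance sim_reads
#' @export
glance.sim_reads <- function(x, ...) x$truth

#' Write simulated reads as FASTQ
#'
#' Four-line records, Phred+33, constant quality Q37 (`"F"`).
#' @param sim A `sim_reads` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_fastq <- function(sim, path) {
  stopifnot(inherits(sim, "sim_reads"))
  seqs <- Biostrings::DNAStringSet(setNames(sim$reads$sequence,
                                            sim$reads$read_id))
  quals <- Biostrings::BStringSet(strrep("F", nchar(sim$reads$sequence)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

#' @rdname write_sim_fastq
#' @export
write_truth_tsv <- function(sim, path) {
  readr::write_tsv(sim$truth, path)
  invisible(path)
}
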