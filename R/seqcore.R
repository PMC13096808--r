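# Nucleic-acid primitives shared by every other module. Sequences are plain
# upper-case character scalars carrying a "nuc_seq" class and an "alphabet"
# attribute ("DNA" or "RNA"); all coordinates in the package are 0-based,
# half-open, reported on the forward strand of the provided reference.

DNA_BASES <- c("A", "C", "G", "T")
RNA_BASES <- c("A", "C", "G", "U")

IUPAC_DNA <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

#' Validated nucleic-acid sequence
#'
#' Normalises case and validates the character set against the declared
#' alphabet. `U` in DNA context and `T` in RNA context are rejected rather
#' than silently converted, so alphabet bugs surface at module boundaries.
#' IUPAC ambiguity codes are allowed only in PAM patterns (see
#' [find_protospacers()]), never in sequences.
#'
#' @param bases Character scalar of bases (case-insensitive).
#' @param alphabet `"DNA"` or `"RNA"`. Default guesses from the presence of
#'   U (RNA) vs T (DNA); ambiguity-free sequences without T/U default to DNA.
#' @return A length-1 character vector with class `nuc_seq`.
#' @examples
#' nuc_seq("acgt")
#' nuc_seq("ACGU", "RNA")
#' @export
nuc_seq <- function(bases, alphabet = NULL) {
  if (!is.character(bases) || length(bases) != 1L || is.na(bases)) {
    abort("`bases` must be a single character string.")
  }
  bases <- toupper(bases)
  if (nchar(bases) < 1L) abort("sequence must have length >= 1")
  if (is.null(alphabet)) {
    alphabet <- if (grepl("U", bases, fixed = TRUE)) "RNA" else "DNA"
  }
  alphabet <- match.arg(alphabet, c("DNA", "RNA"))
  ok <- if (alphabet == "DNA") "^[ACGT]+$" else "^[ACGU]+$"
  if (!grepl(ok, bases)) {
    bad <- setdiff(unique(strsplit(bases, "")[[1]]),
                   if (alphabet == "DNA") DNA_BASES else RNA_BASES)
    abort(sprintf("invalid %s character(s): %s", alphabet,
                  paste(bad, collapse = ", ")))
  }
  structure(bases, class = "nuc_seq", alphabet = alphabet)
}

#' @export
print.nuc_seq <- function(x, ...) {
  cat(sprintf("<nuc_seq %s, %d nt> %s\n", seq_alphabet(x), nchar(x),
              as.character(x)))
  invisible(x)
}

#' Alphabet of a sequence
#' @param x A [nuc_seq] or plain string.
#' @return `"DNA"` or `"RNA"`.
#' @export
seq_alphabet <- function(x) {
  attr(x, "alphabet") %||%
    (if (grepl("U", toupper(x), fixed = TRUE)) "RNA" else "DNA")
}

as_nuc <- function(x, alphabet = NULL) {
  if (inherits(x, "nuc_seq") && is.null(alphabet)) return(x)
  nuc_seq(as.character(x), alphabet %||% attr(x, "alphabet"))
}

#' Reverse complement
#'
#' Involution on both alphabets: `revcomp(revcomp(x))` is `x`.
#'
#' @param seq A [nuc_seq] (or plain string; alphabet inferred).
#' @return The reverse complement in the same alphabet.
#' @examples
#' revcomp("AAC")        # "GTT"
#' revcomp(nuc_seq("GAUC", "RNA"))
#' @export
revcomp <- function(seq) {
  seq <- as_nuc(seq)
  al <- seq_alphabet(seq)
  flipped <- if (al == "DNA") chartr("ACGT", "TGCA", as.character(seq))
             else chartr("ACGU", "UGCA", as.character(seq))
  nuc_seq(paste(rev(strsplit(flipped, "")[[1]]), collapse = ""), al)
}

complement_base <- function(base, alphabet = "RNA") {
  if (alphabet == "DNA") chartr("ACGT", "TGCA", base)
  else chartr("ACGU", "UGCA", base)
}

#' DNA/RNA interconversion
#'
#' Pure T<->U substitution; length preserved, round trips are identities.
#'
#' @param seq A [nuc_seq] or plain string.
#' @return The sequence in the other alphabet.
#' @export
to_rna <- function(seq) {
  seq <- as_nuc(seq)
  if (seq_alphabet(seq) == "RNA") return(seq)
  nuc_seq(chartr("T", "U", as.character(seq)), "RNA")
}

#' @rdname to_rna
#' @export
to_dna <- function(seq) {
  seq <- as_nuc(seq)
  if (seq_alphabet(seq) == "DNA") return(seq)
  nuc_seq(chartr("U", "T", as.character(seq)), "DNA")
}

#' Classify a substitution as transition or transversion
#'
#' Transitions keep the purine/pyrimidine class (A<->G, C<->T/U);
#' transversions cross it. The classification is symmetric in its
#' arguments.
#'
#' @param ref_base,alt_base Single bases (DNA or RNA letters).
#' @return `"transition"` or `"transversion"`.
#' @examples
#' classify_substitution("A", "G")  # transition
#' classify_substitution("A", "C")  # transversion
#' @export
classify_substitution <- function(ref_base, alt_base) {
  ref_base <- toupper(ref_base); alt_base <- toupper(alt_base)
  valid <- c(DNA_BASES, "U")
  if (!ref_base %in% valid || !alt_base %in% valid) {
    abort("bases must be one of A, C, G, T, U")
  }
  norm <- function(b) if (b == "U") "T" else b
  if (norm(ref_base) == norm(alt_base)) {
    abort("identical bases do not constitute a substitution")
  }
  purine <- function(b) b %in% c("A", "G")
  if (purine(ref_base) == purine(alt_base)) "transition" else "transversion"
}

#' Transition partner of a base
#' @param base A single base.
#' @param alphabet Output alphabet.
#' @return The unique base related to `base` by a transition.
#' @export
transition_of <- function(base, alphabet = "RNA") {
  base <- toupper(base)
  ty <- if (alphabet == "RNA") "U" else "T"
  out <- switch(chartr("T", "U", base),
                A = "G", G = "A", C = ty, U = "C",
                abort("invalid base"))
  out
}

transversions_of <- function(base, alphabet = "RNA") {
  base <- chartr("T", "U", toupper(base))
  ty <- if (alphabet == "RNA") "U" else "T"
  if (base %in% c("A", "G")) c("C", ty) else c("A", "G")
}

iupac_to_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  unknown <- setdiff(chars, names(IUPAC_DNA))
  if (length(unknown)) {
    abort(sprintf("invalid IUPAC code(s) in PAM pattern: %s",
                  paste(unknown, collapse = ", ")))
  }
  paste(vapply(chars, function(ch) {
    opts <- IUPAC_DNA[[ch]]
    if (nchar(opts) == 1L) opts else paste0("[", opts, "]")
  }, character(1)), collapse = "")
}

#' Locate candidate protospacers
#'
#' Scans both strands for 20-nt protospacers immediately 5' of a PAM match.
#' Hits are reported as the 0-based start of the 20-nt protospacer footprint
#' on the forward strand of the input (half-open interval
#' `[start, start + 20)`); for `-` strand hits the protospacer is read
#' 5'->3' on the reverse strand and the PAM occupies `[start - 3, start)`
#' in forward coordinates.
#'
#' @param seq DNA [nuc_seq], length >= 23.
#' @param pam_pattern IUPAC PAM pattern, default `"NGG"` (SpCas9).
#' @return A tibble with columns `start`, `strand`, `protospacer`, `pam`
#'   (protospacer and PAM given 5'->3' on the hit strand). Zero rows when
#'   nothing matches.
#' @export
find_protospacers <- function(seq, pam_pattern = "NGG") {
  seq <- as_nuc(seq)
  if (seq_alphabet(seq) != "DNA") abort("protospacer search requires DNA")
  n <- nchar(seq)
  plen <- nchar(pam_pattern)
  if (n < 20L + plen) abort("sequence shorter than protospacer + PAM")
  rx <- iupac_to_regex(pam_pattern)
  scan_fwd <- function(s) {
    hits <- integer(0)
    # fixed-width PAM: test every window (gregexpr would skip overlaps)
    for (i in seq_len(nchar(s) - plen + 1L)) {
      if (grepl(rx, substr(s, i, i + plen - 1L))) hits <- c(hits, i)
    }
    hits[hits > 20L] - 21L  # 0-based protospacer starts
  }
  fwd <- scan_fwd(as.character(seq))
  rcseq <- as.character(revcomp(seq))
  rev_rc <- scan_fwd(rcseq)
  rows <- list()
  if (length(fwd)) {
    rows[[1]] <- tibble(
      start = as.integer(fwd), strand = "+",
      protospacer = vapply(fwd, function(s)
        substr(as.character(seq), s + 1L, s + 20L), character(1)),
      pam = vapply(fwd, function(s)
        substr(as.character(seq), s + 21L, s + 20L + plen), character(1))
    )
  }
  if (length(rev_rc)) {
    rows[[2]] <- tibble(
      start = as.integer(n - rev_rc - 20L), strand = "-",
      protospacer = vapply(rev_rc, function(s)
        substr(rcseq, s + 1L, s + 20L), character(1)),
      pam = vapply(rev_rc, function(s)
        substr(rcseq, s + 21L, s + 20L + plen), character(1))
    )
  }
  if (!length(rows)) {
    return(tibble(start = integer(), strand = character(),
                  protospacer = character(), pam = character()))
  }
  arrange(bind_rows(rows), .data$start, .data$strand)
}

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings that return and accept named character
#' vectors of upper-case sequences. Writing wraps at 60 columns.
#'
#' @param path File path.
#' @return `read_fasta()`: named character vector.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(set)), names(set))
}

#' @rdname read_fasta
#' @param seqs Named character vector (or list) of sequences.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- setNames(vapply(seqs, as.character, character(1),
                          USE.NAMES = FALSE), names(seqs))
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    abort("every FASTA record needs a name")
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Evaluate code with a private, seeded RNG stream
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded operations are reproducible in any
#' context without side effects.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @examples
#' with_seed(1, runif(2))
#' @export
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}
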