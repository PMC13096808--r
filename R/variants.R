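# Variant classes that weaken spacer:PBS complementarity: spacer
# mismatches, PBS mismatches, PBS deletions, PBS-end scrambles, their
# combinations, and the fixed-recipe SPELL design (17-20 nt PBS with a
# single-nucleotide deletion, default at PBS position 13). All positions in
# variant specifications are interpreted in the ORIGINAL part's
# coordinates; deletions are applied before mismatches. Placement-rule
# warnings are advisory, never blocking -- measured behaviour has
# exceptions in both directions.

#' Variant specification
#'
#' @param kind One of `"spacer_mismatch"`, `"pbs_mismatch"`,
#'   `"pbs_deletion"`, `"pbs_scramble"`.
#' @param positions Integer vector of positions (numbering per kind:
#'   spacer from-PAM positions, or original PBS coordinates).
#' @param substitution_class `"transition"` or `"transversion"`
#'   (spacer mismatches only).
#' @param deletion_length Deletion length, 1-4 tested range (longer values
#'   allowed with a warning).
#' @param alt_bases Optional explicit replacement bases, overriding the
#'   tie-break rule.
#' @param seed Seed (scramble only).
#' @return A `variant_spec`.
#' @export
variant_spec <- function(kind, positions, substitution_class = NULL,
                         deletion_length = NULL, alt_bases = NULL,
                         seed = NULL) {
  kind <- match.arg(kind, c("spacer_mismatch", "pbs_mismatch",
                            "pbs_deletion", "pbs_scramble"))
  positions <- as.integer(positions)
  if (!length(positions) || anyNA(positions) || any(positions < 1L)) {
    abort("`positions` must be positive integers")
  }
  if (kind == "pbs_deletion") {
    deletion_length <- as.integer(deletion_length %||% 1L)
    if (deletion_length < 1L) abort("deletion_length must be >= 1")
    if (deletion_length > 4L) {
      warn("deletion_length beyond the characterized 1-4 nt range")
    }
  }
  structure(list(kind = kind, positions = positions,
                 substitution_class = substitution_class,
                 deletion_length = deletion_length,
                 alt_bases = alt_bases, seed = seed),
            class = "variant_spec")
}

# ---- low-level application on a peg_design -------------------------------

replace_char <- function(s, i, ch) {
  paste0(substr(s, 1L, i - 1L), ch, substr(s, i + 1L, nchar(s)))
}

# spacer mismatch at from-PAM position `pos`; alt chosen as the unique
# transition, or the transversion that also fails to pair the opposing PBS
# base (alphabetical tie-break), unless given explicitly
apply_spacer_mismatch <- function(design, pos, class = "transition",
                                  alt = NULL, nick_offset = 3L) {
  s_len <- nchar(design$spacer)
  if (pos < 1L || pos > s_len) {
    abort(sprintf("spacer position %d outside 1..%d", pos, s_len))
  }
  idx <- s_len - pos + 1L
  ref <- substr(design$spacer, idx, idx)
  if (is.null(alt)) {
    alt <- if (identical(class, "transition")) {
      transition_of(ref, "RNA")
    } else {
      cand <- transversions_of(ref, "RNA")
      opp <- opposing_pbs_base(design, pos, nick_offset)
      ok <- if (is.na(opp)) cand
            else cand[cand != complement_base(opp, "RNA")]
      if (!length(ok)) ok <- cand
      sort(ok)[1]
    }
  } else {
    alt <- chartr("T", "U", toupper(alt))
    if (alt == ref) abort("alt equals the current spacer base")
  }
  cls <- classify_substitution(chartr("U", "T", ref), chartr("U", "T", alt))
  design$spacer <- replace_char(design$spacer, idx, alt)
  design$spacer_mismatches <- c(design$spacer_mismatches,
                                list(list(position = pos, ref = ref,
                                          alt = alt, class = cls)))
  design
}

# base of the PBS register-paired with spacer position `pos`, or NA
opposing_pbs_base <- function(design, pos, nick_offset = 3L) {
  coords <- pbs_original_coords(design)
  hit <- which(coords + nick_offset == pos)
  if (!length(hit)) return(NA_character_)
  substr(design$pbs, hit[1], hit[1])
}

apply_pbs_mismatch <- function(design, orig_pos, alt = NULL,
                               nick_offset = 3L) {
  coords <- pbs_original_coords(design)
  cur <- match(orig_pos, coords)
  if (is.na(cur)) {
    if (orig_pos > nchar(design$pbs_original)) {
      abort(sprintf("PBS position %d outside the original PBS (length %d)",
                    orig_pos, nchar(design$pbs_original)))
    }
    abort(sprintf("PBS position %d was deleted by a prior modification",
                  orig_pos))
  }
  ref <- substr(design$pbs, cur, cur)
  if (is.null(alt)) {
    # break pairing with the opposing spacer base; alphabetical tie-break
    partner <- orig_pos + nick_offset
    s_len <- nchar(design$spacer)
    sp <- if (partner >= 1L && partner <= s_len) {
      substr(design$spacer, s_len - partner + 1L, s_len - partner + 1L)
    } else NA_character_
    cand <- setdiff(RNA_BASES, ref)
    if (!is.na(sp)) cand <- setdiff(cand, complement_base(sp, "RNA"))
    alt <- sort(cand)[1]
  } else {
    alt <- chartr("T", "U", toupper(alt))
    if (alt == ref) abort("alt equals the current PBS base")
  }
  design$pbs <- replace_char(design$pbs, cur, alt)
  design$pbs_modifications <- c(design$pbs_modifications,
                                list(list(kind = "mismatch",
                                          position = orig_pos, length = 1L,
                                          ref = ref, alt = alt)))
  design
}

apply_pbs_deletion <- function(design, start, length) {
  coords <- pbs_original_coords(design)
  drop_orig <- start:(start + length - 1L)
  cur <- match(drop_orig, coords)
  if (anyNA(cur)) {
    if (any(drop_orig > nchar(design$pbs_original))) {
      abort(sprintf(
        "deletion %d..%d extends past the original PBS (length %d)",
        start, max(drop_orig), nchar(design$pbs_original)))
    }
    abort("deletion overlaps a previously deleted PBS segment")
  }
  if (nchar(design$pbs) - length < 3L) {
    abort("deletion would leave a PBS shorter than 3 nt")
  }
  keep <- setdiff(seq_len(nchar(design$pbs)), cur)
  chars <- strsplit(as.character(design$pbs), "")[[1]]
  design$pbs <- paste(chars[keep], collapse = "")
  design$pbs_modifications <- c(design$pbs_modifications,
                                list(list(kind = "deletion",
                                          position = as.integer(start),
                                          length = as.integer(length))))
  design
}

# ---- variant sets --------------------------------------------------------

new_variant_set <- function(rows, base) {
  out <- bind_rows(rows)
  structure(out, class = c("variant_set", class(out)), base = base)
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("<variant_set> %d variant(s) of a '%s' design\n", nrow(x),
              attr(x, "base")$origin))
  NextMethod()
}

variant_row <- function(id, kind, positions, class, design, base,
                        warnings, nick_offset = 3L, extra = list()) {
  npb <- n_paired(base, nick_offset)
  npv <- n_paired(design, nick_offset)
  full_seq <- as.character(peg_full_sequence(design))
  pbs_chr <- design$pbs
  spacer_chr <- design$spacer
  row <- tibble(
    variant_id = id, kind = kind,
    positions = list(as.integer(positions)),
    class = class %||% NA_character_,
    design = list(design),
    warnings = list(warnings),
    n_paired = npv,
    delta_n_paired = npv - npb,
    pbs = pbs_chr,
    spacer = spacer_chr,
    full_sequence = full_seq
  )
  for (nm in names(extra)) row[[nm]] <- extra[[nm]]
  row
}

#' Spacer mismatch variants
#'
#' One variant per (position, class) pair, with the spacer base replaced by
#' the unique transition partner or a transversion chosen by the tie-break
#' rule (the transversion that also cannot pair the opposing PBS base;
#' alphabetically first when both qualify; override via `alt_bases`).
#' Advisory warnings flag PAM-proximal placements (position <= 10, where
#' mismatches frequently cost efficiency) and placements outside the
#' PBS-complementary region (no benefit expected). Elements of a list
#' `positions` may be integer vectors to place several mismatches in one
#' variant.
#'
#' @param base A `peg_design`.
#' @param positions Integer vector (one variant per position) or list of
#'   integer vectors (one variant per element).
#' @param classes `"transition"`/`"transversion"`, recycled over variants.
#' @param alt_bases Optional explicit replacement bases (recycled), to
#'   reproduce published designs exactly.
#' @param nick_offset Register offset. Default 3.
#' @return A `variant_set` tibble.
#' @export
spacer_mismatch_variants <- function(base, positions,
                                     classes = "transition",
                                     alt_bases = NULL, nick_offset = 3L) {
  stopifnot(inherits(base, "peg_design"))
  if (!is.list(positions)) positions <- as.list(as.integer(positions))
  classes <- rep_len(as.list(classes), length(positions))
  alt_bases <- if (is.null(alt_bases)) rep_len(list(NULL), length(positions))
               else rep_len(as.list(alt_bases), length(positions))
  covered <- covered_spacer_positions(base, nick_offset)
  rows <- pmap(list(positions, classes, alt_bases, seq_along(positions)),
               function(pos, cls, alt, i) {
    d <- base
    for (p in pos) {
      d <- apply_spacer_mismatch(d, p, class = cls, alt = alt,
                                 nick_offset = nick_offset)
    }
    w <- character()
    if (any(pos <= 10L)) {
      w <- c(w, "PAM-proximal mismatch (position <= 10): efficiency frequently decreased")
    }
    if (any(!pos %in% covered)) {
      w <- c(w, "mismatch outside the PBS-complementary region: no benefit expected")
    }
    if (base$has_appended_5prime_G) {
      w <- c(w, "21G spacer: possible reduced mismatch tolerance")
    }
    d$origin <- "spacer_mismatch"
    d$warnings <- c(d$warnings, w)
    variant_row(sprintf("sm_%s_%s", paste(pos, collapse = "."),
                        substr(cls, 1, 2)),
                "spacer_mismatch", pos, cls, d, base, w, nick_offset)
  })
  new_variant_set(rows, base)
}

#' PBS mismatch variants
#'
#' Complement-breaking substitutions in the PBS. A numeric `positions`
#' vector yields one single-mismatch variant per position; a list element
#' with several positions yields one variant with all of them applied
#' simultaneously (the natural design with long PBSs). Variants built on a
#' PBS of 13 nt or shorter carry a short-PBS warning: with short PBSs such
#' mismatches rarely help and mostly reduce efficiency.
#'
#' @inheritParams spacer_mismatch_variants
#' @param positions Original PBS coordinates (1 = 5' end, RTT-adjacent).
#' @return A `variant_set` tibble.
#' @export
pbs_mismatch_variants <- function(base, positions, alt_bases = NULL,
                                  nick_offset = 3L) {
  stopifnot(inherits(base, "peg_design"))
  if (!is.list(positions)) positions <- as.list(as.integer(positions))
  alt_bases <- if (is.null(alt_bases)) rep_len(list(NULL), length(positions))
               else rep_len(as.list(alt_bases), length(positions))
  short_pbs <- nchar(base$pbs) <= 13L
  rows <- pmap(list(positions, alt_bases), function(pos, alt) {
    d <- base
    for (p in pos) d <- apply_pbs_mismatch(d, p, alt = alt,
                                           nick_offset = nick_offset)
    w <- if (short_pbs)
      "short PBS (<= 13 nt): PBS mismatches mostly reduced efficiency"
    else character()
    d$origin <- "pbs_mismatch"
    d$warnings <- c(d$warnings, w)
    variant_row(sprintf("pm_%s", paste(pos, collapse = ".")),
                "pbs_mismatch", pos, NULL, d, base, w, nick_offset)
  })
  new_variant_set(rows, base)
}

#' PBS deletion variants
#'
#' Consecutive deletions over a grid of start positions and lengths
#' (defaults: starts 6-15, lengths 1-4, the characterized space for a
#' 20-nt PBS). Each variant records the intact 5' PBS segment upstream of
#' the deletion; variants whose resulting PBS sequence coincides with an
#' earlier variant's (homopolymer runs) are flagged via `duplicate_of`.
#'
#' @param base A `peg_design`.
#' @param start_positions Original PBS start coordinates. Default `6:15`.
#' @param lengths Deletion lengths. Default `1:4`.
#' @param nick_offset Register offset. Default 3.
#' @return A `variant_set` tibble with `intact_upstream`,
#'   `intact_upstream_length` and `duplicate_of` columns.
#' @export
pbs_deletion_variants <- function(base, start_positions = 6:15,
                                  lengths = 1:4, nick_offset = 3L) {
  stopifnot(inherits(base, "peg_design"))
  start_positions <- as.integer(start_positions)
  lengths <- as.integer(lengths)
  if (any(lengths > 4L)) {
    warn("deletion length beyond the characterized 1-4 nt range")
  }
  L <- nchar(base$pbs)
  if (L < max(start_positions) + max(lengths) - 1L) {
    abort(sprintf(
      "base PBS (%d nt) too short for start %d + length %d",
      L, max(start_positions), max(lengths)))
  }
  grid <- expand.grid(start = start_positions, len = lengths,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$start, grid$len), ]
  rows <- pmap(grid, function(start, len) {
    d <- apply_pbs_deletion(base, start, len)
    d$origin <- "pbs_deletion"
    variant_row(sprintf("del_%d_%d", start, len), "pbs_deletion",
                start:(start + len - 1L), NULL, d, base, character(),
                nick_offset,
                extra = list(
                  deletion_start = as.integer(start),
                  deletion_length = as.integer(len),
                  intact_upstream = substr(as.character(base$pbs), 1L, start - 1L),
                  intact_upstream_length = as.integer(start - 1L)))
  })
  out <- new_variant_set(rows, base)
  first_idx <- match(out$pbs, out$pbs)
  out$duplicate_of <- ifelse(first_idx == seq_len(nrow(out)),
                             NA_character_, out$variant_id[first_idx])
  out
}

#' Build a SPELL pegRNA
#'
#' The streamlined fixed-length recipe: a long (17-20 nt, default 20) PBS
#' carrying a single-nucleotide deletion (default at PBS position 13,
#' leaving a 12-nt intact 5' segment). This trades the per-target PBS
#' length optimization for one fixed design that keeps the extra
#' PBS:non-target-strand pairing while interrupting the inhibitory
#' spacer:PBS register.
#'
#' @inheritParams design_pegrna
#' @param pbs_length Pre-deletion PBS length; values outside 17-20 are
#'   allowed with a warning.
#' @param deletion_position PBS position to delete (original coordinates);
#'   must be `< pbs_length`. Default 13.
#' @return A `peg_design` with `origin = "spell"`.
#' @examples
#' loc <- with_seed(7, random_locus())
#' ed <- edit_spec(1, substr(downstream_of_nick(loc), 1, 1), "A")
#' make_spell(loc, ed)
#' @export
make_spell <- function(locus, edit, pbs_length = 20L, deletion_position = 13L,
                       rtt_length = NULL, scaffold = default_scaffold(),
                       u6_mode = TRUE, nick_offset = 3L) {
  pbs_length <- as.integer(pbs_length)
  deletion_position <- as.integer(deletion_position)
  if (pbs_length < 17L || pbs_length > 20L) {
    warn(sprintf("SPELL is specified for 17-20 nt PBS; got %d", pbs_length))
  }
  if (deletion_position >= pbs_length) {
    abort("deletion_position must be smaller than pbs_length")
  }
  d <- design_pegrna(locus, edit, pbs_length = pbs_length,
                     rtt_length = rtt_length, scaffold = scaffold,
                     u6_mode = u6_mode, nick_offset = nick_offset)
  d <- apply_pbs_deletion(d, deletion_position, 1L)
  d$origin <- "spell"
  d
}

#' Scramble the 3' end of the PBS
#'
#' Replaces PBS positions `>= from_position` with a seeded random
#' permutation of themselves that (a) differs from the original segment
#' and (b) retains zero Watson-Crick pairs in register with the spacer,
#' found by rejection sampling with a bounded retry count. Base
#' composition is preserved by construction.
#'
#' @param base A `peg_design`.
#' @param from_position First PBS position (current coordinates) of the
#'   scrambled segment.
#' @param seed Mandatory RNG seed; identical seeds give identical output.
#' @param max_retries Rejection-sampling bound. Default 500.
#' @param nick_offset Register offset. Default 3.
#' @return A `peg_design` with `origin = "pbs_scramble"`.
#' @export
scramble_pbs_end <- function(base, from_position, seed, max_retries = 500L,
                             nick_offset = 3L) {
  stopifnot(inherits(base, "peg_design"))
  L <- nchar(base$pbs)
  from_position <- as.integer(from_position)
  if (from_position < 1L || from_position > L) {
    abort(sprintf("from_position outside 1..%d", L))
  }
  seg_idx <- from_position:L
  chars <- strsplit(as.character(base$pbs), "")[[1]]
  seg <- chars[seg_idx]
  if (length(unique(seg)) < 2L) {
    abort("segment has a single distinct base: no distinct permutation exists")
  }
  # spacer partners of the segment, via the original-coordinate register
  coords <- pbs_original_coords(base)
  s_len <- nchar(base$spacer)
  partner <- coords[seg_idx] + nick_offset
  sp_base <- ifelse(partner >= 1L & partner <= s_len,
                    vapply(partner, function(k)
                      substr(base$spacer, s_len - k + 1L, s_len - k + 1L),
                      character(1)),
                    NA_character_)
  forbidden <- ifelse(is.na(sp_base), NA_character_,
                      complement_base(sp_base, "RNA"))
  pick <- with_seed(seed, {
    found <- NULL
    for (i in seq_len(max_retries)) {
      cand <- sample(seg)
      if (identical(cand, seg)) next
      hits <- !is.na(forbidden) & cand == forbidden
      if (any(hits)) next
      found <- cand
      break
    }
    found
  })
  if (is.null(pick)) {
    abort(sprintf(
      "no acceptable permutation found in %d tries (segment too short or too constrained)",
      max_retries))
  }
  chars[seg_idx] <- pick
  d <- base
  d$pbs <- paste(chars, collapse = "")
  d$pbs_modifications <- c(d$pbs_modifications,
                           list(list(kind = "scramble",
                                     position = coords[from_position],
                                     length = length(seg_idx),
                                     seed = as.integer(seed))))
  d$origin <- "pbs_scramble"
  d
}

#' Combine variant specifications on one design
#'
#' Applies a list of [variant_spec()]s to a base design: deletions first,
#' then PBS mismatches, then spacer mismatches, with every position
#' interpreted in the ORIGINAL part's coordinates. Output is therefore
#' order-insensitive for non-overlapping specs. Conflicting specs (two
#' edits addressing one position) raise an error naming the collision.
#'
#' @param base A `peg_design`.
#' @param specs List of [variant_spec()] objects (empty list returns the
#'   base unchanged).
#' @param nick_offset Register offset. Default 3.
#' @return A `peg_design` with `origin = "combo"`.
#' @export
combine_variants <- function(base, specs, nick_offset = 3L) {
  stopifnot(inherits(base, "peg_design"))
  if (!length(specs)) return(base)
  if (inherits(specs, "variant_spec")) specs <- list(specs)
  kinds <- vapply(specs, function(s) s$kind, character(1))
  if (any(kinds == "pbs_scramble")) {
    abort("apply scrambles via scramble_pbs_end(), not combine_variants()")
  }
  del <- specs[kinds == "pbs_deletion"]
  pbs_mm <- specs[kinds == "pbs_mismatch"]
  sp_mm <- specs[kinds == "spacer_mismatch"]
  del_pos <- unlist(lapply(del, function(s) {
    unlist(lapply(s$positions, function(p) p:(p + s$deletion_length - 1L)))
  }))
  pbs_pos <- unlist(lapply(pbs_mm, function(s) s$positions))
  sp_pos <- unlist(lapply(sp_mm, function(s) s$positions))
  clash <- c(del_pos[duplicated(del_pos)],
             intersect(del_pos, pbs_pos),
             pbs_pos[duplicated(pbs_pos)])
  if (length(clash)) {
    abort(sprintf("conflicting specs at PBS position(s) %s",
                  paste(sort(unique(clash)), collapse = ", ")))
  }
  if (anyDuplicated(sp_pos)) {
    abort(sprintf("conflicting specs at spacer position(s) %s",
                  paste(sort(unique(sp_pos[duplicated(sp_pos)])),
                        collapse = ", ")))
  }
  d <- base
  for (s in del) {
    for (p in s$positions) d <- apply_pbs_deletion(d, p, s$deletion_length)
  }
  for (s in pbs_mm) {
    alts <- rep_len(s$alt_bases %||% list(NULL), length(s$positions))
    for (i in seq_along(s$positions)) {
      d <- apply_pbs_mismatch(d, s$positions[i], alt = alts[[i]],
                              nick_offset = nick_offset)
    }
  }
  for (s in sp_mm) {
    alts <- rep_len(s$alt_bases %||% list(NULL), length(s$positions))
    for (i in seq_along(s$positions)) {
      d <- apply_spacer_mismatch(d, s$positions[i],
                                 class = s$substitution_class %||% "transition",
                                 alt = alts[[i]], nick_offset = nick_offset)
    }
  }
  d$origin <- "combo"
  d
}

#' Export a variant set
#'
#' `write_variants_tsv()` writes one row per variant (ids, sequences,
#' provenance, pairing burden, warnings); `write_variants_fasta()` writes
#' the full pegRNA sequences as multi-FASTA.
#'
#' @param variants A `variant_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(variants, path) {
  flat <- as_tibble(variants)
  flat$positions <- map_chr(flat$positions, paste, collapse = ",")
  flat$warnings <- map_chr(flat$warnings, paste, collapse = "; ")
  flat$design <- NULL
  readr::write_tsv(flat, path)
  invisible(path)
}

#' @rdname write_variants_tsv
#' @export
write_variants_fasta <- function(variants, path) {
  write_fasta(setNames(variants$full_sequence, variants$variant_id), path)
  invisible(path)
}
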