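test_that("spacer mismatch variants follow the placement-rule warnings", {
  with_seed(601, {
    base <- rand_case(pbs_length = 17)$design
    v <- spacer_mismatch_variants(base, 13)
    expect_equal(nrow(v), 1L)
    expect_length(v$warnings[[1]], 0L)
    expect_equal(v$delta_n_paired, -1L)

    v8 <- spacer_mismatch_variants(base, 8)
    expect_match(v8$warnings[[1]], "PAM-proximal")

    base10 <- rand_case(pbs_length = 10)$design  # covered: 4-13
    v15 <- spacer_mismatch_variants(base10, 15)
    expect_match(v15$warnings[[1]], "outside")
    expect_equal(v15$delta_n_paired, 0L)

    expect_error(spacer_mismatch_variants(base, 25), "outside 1..20")
  })
})

test_that("mismatch classes are realized correctly with the tie-break", {
  with_seed(602, {
    base <- rand_case(pbs_length = 17)$design
    vt <- spacer_mismatch_variants(base, 13, classes = "transition")
    mm <- vt$design[[1]]$spacer_mismatches[[1]]
    expect_equal(mm$class, "transition")
    expect_equal(mm$alt, transition_of(mm$ref, "RNA"))

    vv <- spacer_mismatch_variants(base, 13, classes = "transversion")
    mmv <- vv$design[[1]]$spacer_mismatches[[1]]
    expect_equal(mmv$class, "transversion")
    # the chosen base must not re-pair with the opposing PBS base
    cm <- tidy(complementarity_map(vv$design[[1]]))
    expect_false(cm$is_watson_crick[cm$spacer_position == 13])

    # explicit override wins
    cur <- mm$ref
    forced <- setdiff(c("A", "C", "G", "U"), cur)[1]
    vo <- spacer_mismatch_variants(base, 13, alt_bases = forced)
    expect_equal(vo$design[[1]]$spacer_mismatches[[1]]$alt, forced)
  })
})

test_that("every covered-position mismatch costs exactly one pair", {
  with_seed(603, {
    loc <- random_locus()
    ref1 <- substr(downstream_of_nick(loc), 1, 1)
    ed <- edit_spec(1, ref1, setdiff(c("A", "C", "G", "T"), ref1)[1])
    for (L in seq(4, 20, by = 4)) {
      base <- design_pegrna(loc, ed, pbs_length = L, u6_mode = FALSE)
      covered <- covered_spacer_positions(base)
      v <- suppressWarnings(spacer_mismatch_variants(base, 1:20))
      expect_equal(v$delta_n_paired,
                   ifelse(1:20 %in% covered, -1L, 0L))
    }
  })
})

test_that("PBS mismatches support multi-site variants and short-PBS warning", {
  with_seed(604, {
    base20 <- rand_case(pbs_length = 20)$design
    v <- pbs_mismatch_variants(base20, list(c(5, 9, 13)))
    expect_equal(nrow(v), 1L)
    expect_equal(length(v$design[[1]]$pbs_modifications), 3L)
    expect_length(v$warnings[[1]], 0L)
    # all three register pairs are broken
    expect_equal(v$delta_n_paired, -3L)

    base10 <- rand_case(pbs_length = 10)$design
    v10 <- pbs_mismatch_variants(base10, 5)
    expect_match(v10$warnings[[1]], "short PBS")

    expect_error(pbs_mismatch_variants(base10, 11), "outside")
  })
})

test_that("the deletion grid yields 40 variants with intact-segment records", {
  with_seed(605, {
    base <- rand_case(pbs_length = 20)$design
    v <- pbs_deletion_variants(base)
    expect_equal(nrow(v), 40L)
    d13 <- v[v$variant_id == "del_13_1", ]
    expect_equal(d13$intact_upstream_length, 12L)
    expect_equal(d13$intact_upstream, substr(as.character(base$pbs), 1, 12))
    expect_equal(nchar(d13$pbs), 19L)
    # every variant's sequence differs from the base's
    expect_false(any(v$full_sequence == as.character(peg_full_sequence(base))))
    expect_error(pbs_deletion_variants(rand_case(pbs_length = 10)$design),
                 "too short")
  })
})

test_that("identical deletion products in homopolymer runs are flagged", {
  # PBS with a homopolymer: protospacer positions 4..16 all G -> PBS has a
  # long C run, so adjacent 1-nt deletions give identical sequences
  proto <- c("C", "A", "T", rep("G", 13), "A", "C", "T", "G")
  loc <- locus_from_pam_proximal(proto)
  ed <- edit_spec(1, "T", "A")
  base <- design_pegrna(loc, ed, pbs_length = 20, u6_mode = FALSE)
  v <- pbs_deletion_variants(base, start_positions = 6:8, lengths = 1)
  expect_equal(v$pbs[1], v$pbs[2])
  expect_true(is.na(v$duplicate_of[1]))
  expect_equal(v$duplicate_of[2], v$variant_id[1])
})

test_that("make_spell implements the fixed-length deletion recipe", {
  with_seed(606, {
    case <- rand_case()
    spell <- make_spell(case$locus, case$edit, u6_mode = FALSE)
    expect_equal(spell$origin, "spell")
    expect_equal(nchar(spell$pbs), 19L)
    expect_equal(substr(spell$pbs, 1, 12),
                 as.character(build_pbs(case$locus, 12)))

    s17 <- make_spell(case$locus, case$edit, pbs_length = 17,
                      u6_mode = FALSE)
    expect_equal(nchar(s17$pbs), 16L)
    expect_equal(substr(s17$pbs, 1, 12),
                 as.character(build_pbs(case$locus, 12)))

    expect_warning(make_spell(case$locus, case$edit, pbs_length = 16,
                              u6_mode = FALSE), "17-20")
    expect_error(make_spell(case$locus, case$edit, pbs_length = 18,
                            deletion_position = 18, u6_mode = FALSE),
                 "smaller")
  })
})

test_that("the SPELL intact 5' segment equals build_pbs(d-1) for all valid cases", {
  with_seed(607, {
    case <- rand_case()
    for (L in 17:20) {
      for (d in c(6, 10, 13, L - 1)) {
        sp <- make_spell(case$locus, case$edit, pbs_length = L,
                         deletion_position = d, u6_mode = FALSE)
        expect_equal(substr(sp$pbs, 1, d - 1),
                     as.character(build_pbs(case$locus, d - 1)))
        expect_equal(nchar(sp$pbs), L - 1L)
      }
    }
  })
})

test_that("scrambling is seeded, composition-preserving and non-pairing", {
  with_seed(608, {
    base <- rand_case(pbs_length = 20)$design
    s1 <- scramble_pbs_end(base, 13, seed = 42)
    s2 <- scramble_pbs_end(base, 13, seed = 42)
    expect_identical(as.character(s1$pbs), as.character(s2$pbs))
    expect_false(as.character(s1$pbs) == as.character(base$pbs))
    expect_no_wc_beyond(s1, 13)

    # composition preserved over many random designs
    for (i in 1:50) {
      b <- rand_case(pbs_length = 20)$design
      sc <- tryCatch(scramble_pbs_end(b, 14, seed = i),
                     error = function(e) NULL)
      if (is.null(sc)) next  # segment too constrained: allowed outcome
      expect_equal(sort(strsplit(substr(sc$pbs, 14, 20), "")[[1]]),
                   sort(strsplit(substr(b$pbs, 14, 20), "")[[1]]))
      expect_equal(substr(sc$pbs, 1, 13), substr(b$pbs, 1, 13))
    }
  })
})

test_that("homopolymeric scramble segments error out", {
  proto <- c("C", "A", "T", rep("G", 13), "A", "C", "T", "G")
  loc <- locus_from_pam_proximal(proto)
  base <- design_pegrna(loc, edit_spec(1, "T", "A"), pbs_length = 13,
                        u6_mode = FALSE)
  # the whole 13-nt PBS is a C homopolymer: no distinct permutation
  expect_error(scramble_pbs_end(base, 10, seed = 1), "distinct")
})

test_that("combine applies deletions first in original coordinates", {
  with_seed(609, {
    base <- rand_case(pbs_length = 20)$design
    combo <- combine_variants(base, list(
      variant_spec("pbs_deletion", 13, deletion_length = 1),
      variant_spec("spacer_mismatch", 15, substitution_class = "transition")
    ))
    expect_equal(combo$origin, "combo")
    expect_equal(nchar(combo$pbs), 19L)
    cm <- tidy(complementarity_map(combo))
    expect_false(cm$is_watson_crick[cm$spacer_position == 15])
    # register shifted downstream of the deletion
    expect_equal(attr(complementarity_map(combo), "register_shift"),
                 c(rep(0L, 12), rep(1L, 7)))

    # identity and order-insensitivity
    expect_identical(combine_variants(base, list()), base)
    specs <- list(
      variant_spec("spacer_mismatch", 18),
      variant_spec("pbs_deletion", 13, deletion_length = 2),
      variant_spec("pbs_mismatch", 5))
    a <- combine_variants(base, specs)
    b <- combine_variants(base, rev(specs))
    expect_equal(as.character(peg_full_sequence(a)),
                 as.character(peg_full_sequence(b)))
  })
})

test_that("combine rejects colliding specifications", {
  base <- with_seed(610, rand_case(pbs_length = 20))$design
  expect_error(combine_variants(base, list(
    variant_spec("spacer_mismatch", 15),
    variant_spec("spacer_mismatch", 15))), "spacer position")
  expect_error(combine_variants(base, list(
    variant_spec("pbs_deletion", 13, deletion_length = 2),
    variant_spec("pbs_mismatch", 14))), "PBS position")
  expect_error(combine_variants(base, list(
    variant_spec("pbs_deletion", 12, deletion_length = 2),
    variant_spec("pbs_deletion", 13, deletion_length = 1))), "PBS position")
})

test_that("variant sets export cleanly to TSV and FASTA", {
  with_seed(611, {
    base <- rand_case(pbs_length = 20)$design
    v <- pbs_deletion_variants(base, 6:8, 1)
    tsv <- withr::local_tempfile(fileext = ".tsv")
    fa <- withr::local_tempfile(fileext = ".fasta")
    write_variants_tsv(v, tsv)
    write_variants_fasta(v, fa)
    expect_equal(nrow(readr::read_tsv(tsv, show_col_types = FALSE)), 3L)
    expect_equal(unname(read_fasta(fa)), v$full_sequence)
  })
})
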