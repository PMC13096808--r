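test_that("build_spacer handles U6 5' G appending", {
  up <- strrep("T", 25); down <- strrep("C", 30)
  loc_g <- target_locus(nuc_seq(paste0(up, "G", strrep("A", 19), "TGG", down)), 25)
  sp <- build_spacer(loc_g)
  expect_equal(nchar(sp$spacer), 20L)
  expect_false(sp$has_appended_5prime_G)
  expect_length(sp$warnings, 0L)

  loc_a <- target_locus(nuc_seq(paste0(up, strrep("A", 20), "TGG", down)), 25)
  sp <- build_spacer(loc_a)
  expect_equal(nchar(sp$spacer), 21L)
  expect_equal(as.character(substr(sp$spacer, 1, 2)), "GA")
  expect_true(sp$has_appended_5prime_G)
  expect_match(sp$warnings, "21G")

  sp <- build_spacer(loc_a, u6_mode = FALSE)
  expect_equal(nchar(sp$spacer), 20L)
  expect_false(sp$has_appended_5prime_G)
})

test_that("build_pbs reproduces hand-derived sequences", {
  polyg <- locus_from_pam_proximal(rep("G", 20))
  expect_equal(as.character(build_pbs(polyg, 13)), strrep("C", 13))

  # protospacer positions 1..20 (PAM-proximal first)
  proto <- c("C", "C", "T", "A", "T", "C", "G", "C", "A", "A",
             "G", "G", "T", "T", "C", "C", "A", "C", "T", "G")
  loc <- locus_from_pam_proximal(proto)
  expect_equal(as.character(build_pbs(loc, 13)), "UAGCGUUCCAAGG")
  # independent string oracle: revcomp of the primer's 3'-terminal 13 nt
  nickpos <- nick_site(loc)
  primer_tail <- substr(as.character(loc$reference), nickpos - 12, nickpos)
  expect_equal(as.character(build_pbs(loc, 13)),
               chartr("T", "U", oracle_revcomp_dna(primer_tail)))
})

test_that("build_pbs(L) is a prefix of build_pbs(L+1) and bounds are enforced", {
  with_seed(303, {
    loc <- random_locus()
    for (L in 1:24) {
      expect_equal(as.character(substr(build_pbs(loc, L + 1), 1, L)),
                   as.character(build_pbs(loc, L)))
    }
  })
  expect_error(build_pbs(loc <- with_seed(1, random_locus()), 26), "1..25")
  expect_error(build_pbs(loc, 0), "1..25")
  tight <- target_locus(
    nuc_seq(paste0(strrep("A", 5), strrep("G", 20), "TGG", strrep("C", 30))),
    5, min_upstream = 5)
  expect_error(build_pbs(tight, 25), "5' context")
})

test_that("a 7-nt PBS covers spacer positions 4 through 10", {
  with_seed(304, {
    case <- rand_case(pbs_length = 7)
    expect_equal(covered_spacer_positions(case$design), 4:10)
  })
})

test_that("build_rtt encodes edits so that RT copying reproduces them", {
  with_seed(305, {
    loc <- random_locus()
    d0 <- downstream_of_nick(loc)
    # identity edit: RTT is the reverse complement of the unedited strand
    noop <- edit_spec(1, substr(d0, 1, 1), substr(d0, 1, 1))
    rtt <- build_rtt(loc, noop, rtt_length = 12)
    expect_equal(as.character(rtt),
                 chartr("T", "U", oracle_revcomp_dna(substr(d0, 1, 12))))

    # single-base substitution at nick+1 differs only at the RTT 3' end
    alt1 <- setdiff(c("A", "C", "G", "T"), substr(d0, 1, 1))[1]
    sub1 <- edit_spec(1, substr(d0, 1, 1), alt1)
    rtt_s <- build_rtt(loc, sub1, rtt_length = 12)
    diffs <- which(strsplit(as.character(rtt_s), "")[[1]] !=
                   strsplit(as.character(rtt), "")[[1]])
    expect_equal(diffs, 12L)

    # 2-nt insertion: RT-copy oracle reproduces the insertion
    ins <- edit_spec(1, "", "TT")
    rtt_i <- build_rtt(loc, ins, rtt_length = 14)
    expect_equal(nchar(rtt_i), 14L)
    copied <- oracle_revcomp_dna(as.character(to_dna(rtt_i)))
    expect_equal(copied, substr(downstream_of_nick(loc, ins), 1, 14))
  })
})

test_that("RT-copy oracle holds over random locus/edit pairs", {
  with_seed(306, {
    for (i in 1:100) {
      loc <- random_locus()
      d0 <- downstream_of_nick(loc)
      t <- sample(1:5, 1)
      type <- sample(c("substitution", "insertion", "deletion"), 1)
      ed <- switch(type,
        substitution = {
          m <- sample(1:2, 1)
          ref <- substr(d0, t, t + m - 1)
          alt <- paste(sample(c("A", "C", "G", "T"), m, replace = TRUE),
                       collapse = "")
          if (alt == ref) alt <- chartr("ACGT", "CAGT", ref)
          if (alt == ref) alt <- chartr("ACGT", "GTAC", ref)
          edit_spec(t, ref, alt)
        },
        insertion = edit_spec(t, "", paste(
          sample(c("A", "C", "G", "T"), sample(1:3, 1), replace = TRUE),
          collapse = "")),
        deletion = edit_spec(t, substr(d0, t, t + sample(0:2, 1)), ""))
      L <- t + nchar(ed$alt) + sample(3:10, 1)
      rtt <- build_rtt(loc, ed, rtt_length = L)
      expect_equal(oracle_revcomp_dna(as.character(to_dna(rtt))),
                   substr(downstream_of_nick(loc, ed), 1, L))
    }
  })
})

test_that("build_rtt validates the edit against the reference", {
  loc <- with_seed(1, random_locus())
  d0 <- downstream_of_nick(loc)
  wrong <- setdiff(c("A", "C", "G", "T"), substr(d0, 1, 1))[1]
  expect_error(build_rtt(loc, edit_spec(1, wrong, "A"), 12), "mismatch")
  expect_error(build_rtt(loc, edit_spec(8, substr(d0, 8, 8), "A"),
                         rtt_length = 5), "RTT window")
})

test_that("assembly is additive and disassembly round trips", {
  d <- with_seed(307, rand_case(pbs_length = 13))$design
  expect_equal(nchar(peg_full_sequence(d)), 20 + 76 + 12 + 13)
  motif <- paste(rep("A", 45), collapse = "")
  d2 <- assemble_pegrna(d$spacer, d$scaffold, d$rtt, d$pbs,
                        end_motif = chartr("T", "U", motif))
  expect_equal(nchar(peg_full_sequence(d2)), 121 + 45)

  parts <- disassemble_pegrna(peg_full_sequence(d),
                              c(spacer = nchar(d$spacer), scaffold = 76,
                                rtt = nchar(d$rtt), pbs = nchar(d$pbs)))
  expect_equal(parts$spacer, d$spacer)
  expect_equal(parts$pbs, d$pbs)
  expect_error(assemble_pegrna("", d$scaffold, d$rtt, d$pbs), ".")
})

test_that("minus-strand loci give the same design as their plus twin", {
  with_seed(308, {
    loc_plus <- random_locus(strand = "+")
    ref_rc <- revcomp(loc_plus$reference)
    loc_minus <- target_locus(ref_rc,
                              nchar(ref_rc) - loc_plus$protospacer_start - 20,
                              "-")
    expect_equal(loc_minus$protospacer, loc_plus$protospacer)
    expect_equal(as.character(build_pbs(loc_minus, 13)),
                 as.character(build_pbs(loc_plus, 13)))
    expect_equal(nick_site(loc_minus),
                 nchar(loc_plus$reference) - nick_site(loc_plus))
  })
})

test_that("design_report tabulates candidates with ranking and dedup", {
  with_seed(309, {
    case <- rand_case()
    rep <- design_report(case$locus, case$edit,
                         pbs_lengths = c(7, 10, 13, 17, 20),
                         u6_mode = FALSE)
    expect_equal(nrow(rep), 5L)
    expect_equal(rep$n_paired, c(7L, 10L, 13L, 17L, 17L))
    expect_equal(sort(rep$rank_tm37), 1:5)
    expect_warning(
      rep2 <- design_report(case$locus, case$edit, pbs_lengths = c(7, 7),
                            u6_mode = FALSE),
      "duplicate")
    expect_equal(nrow(rep2), 1L)
    reps <- design_report(case$locus, case$edit, pbs_lengths = integer(0),
                          u6_mode = FALSE)
    expect_equal(nrow(reps), 0L)
    repsp <- design_report(case$locus, case$edit, pbs_lengths = 13,
                           spell = TRUE, u6_mode = FALSE)
    expect_equal(nrow(repsp), 2L)
    expect_equal(repsp$pbs_length[2], 19L)
  })
})
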