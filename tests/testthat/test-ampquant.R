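# shared quantification frame: seeded locus, substitution edit, amplicon
quant_frame <- function(seed = 901, edit_type = "substitution") {
  with_seed(seed, {
    loc <- random_locus()
    d0 <- downstream_of_nick(loc)
    ed <- switch(edit_type,
                 substitution = edit_spec(
                   1, substr(d0, 1, 1),
                   setdiff(c("A", "C", "G", "T"), substr(d0, 1, 1))[1]),
                 insertion = edit_spec(1, "", "T"),
                 deletion = edit_spec(1, substr(d0, 1, 1), ""))
    list(locus = loc,
         spec = amplicon_spec(loc$reference, nick_site(loc), ed))
  })
}

test_that("alignment recovers constructed indels at exact coordinates", {
  qf <- quant_frame()
  spec <- qf$spec
  ref <- spec$reference
  nick <- spec$nick_sites[1]
  # 1-nt deletion of the base right after the nick
  del_read <- paste0(substr(ref, 1, nick), substr(ref, nick + 2, nchar(ref)))
  aln <- align_reads(c(ref, del_read, strrep("ATGC", 25)), spec)
  expect_true(aln$aligned[1])
  expect_equal(nrow(aln$events[[1]]), 0L)
  expect_equal(aln$identity[1], 1)
  expect_true(aln$aligned[2])
  ev <- aln$events[[2]]
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$type, "deletion")
  expect_equal(ev$length, 1L)
  expect_equal(ev$position, nick)
  expect_false(aln$aligned[3])
  expect_error(align_reads(character(0), spec), ".")
})

test_that("the mismatch fast path agrees with full alignment", {
  qf <- quant_frame(902)
  spec <- qf$spec
  ref <- spec$reference
  with_seed(9021, {
    for (i in 1:20) {
      r <- ref
      for (p in sample(nchar(ref), sample(1:3, 1))) {
        substr(r, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(r, p, p)), 1)
      }
      fast <- align_reads(r, spec)
      mm <- sum(strsplit(r, "")[[1]] != strsplit(ref, "")[[1]])
      # the optimal alignment must be gap-free here: pairwiseAlignment's
      # score equals the gap-free score
      sm <- Biostrings::nucleotideSubstitutionMatrix(2, -3, baseOnly = TRUE)
      pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(r),
                                          Biostrings::DNAString(ref),
                                          type = "global",
                                          substitutionMatrix = sm,
                                          gapOpening = 8, gapExtension = 1)
      expect_equal(Biostrings::score(pa),
                   2 * (nchar(ref) - mm) + (-3) * mm)
      expect_equal(nrow(fast$events[[1]]), 0L)
      expect_equal(fast$identity[1], (nchar(ref) - mm) / nchar(ref))
    }
  })
})

test_that("window calls follow the overlap rule at exact boundaries", {
  # period-4 reference: no 1-3 nt deletion placement is ambiguous, so the
  # constructed coordinate is the aligned coordinate
  ref <- strrep("ACGT", 20)
  spec <- amplicon_spec(nuc_seq(ref), 40L, edit_spec(1, "A", "C"))
  ref <- spec$reference
  nick <- spec$nick_sites[1]
  w <- spec$indel_window
  # exhaustive 1-3 nt indels at every offset in [-6, 6] around the nick
  for (len in 1:3) {
    for (off in -6:6) {
      start <- nick + off          # 0-based start of the deleted span
      del_read <- paste0(substr(ref, 1, start),
                         substr(ref, start + len + 1, nchar(ref)))
      calls <- call_reads(align_reads(del_read, spec), spec)
      in_window <- length(intersect(start:(start + len - 1L),
                                    (nick - w):(nick + w - 1L))) > 0
      expect_equal(calls$has_indel_in_window, in_window,
                   info = sprintf("deletion off=%d len=%d", off, len))

      ins_read <- paste0(substr(ref, 1, start), strrep("T", len),
                         substr(ref, start + 1, nchar(ref)))
      calls_i <- call_reads(align_reads(ins_read, spec), spec)
      # alignment may legitimately shift an insertion within a repeat;
      # compare against the aligner's reported coordinate
      ev <- align_reads(ins_read, spec)$events[[1]]
      expect_in <- any(ev$position >= nick - w & ev$position <= nick + w)
      expect_equal(calls_i$has_indel_in_window, expect_in,
                   info = sprintf("insertion off=%d len=%d", off, len))
    }
  }
})

test_that("window calls are invariant under coordinate translation", {
  qf <- quant_frame(904)
  spec <- qf$spec
  pad <- strrep("G", 11)
  ref2 <- paste0(pad, spec$reference)
  spec2 <- amplicon_spec(nuc_seq(ref2), spec$nick_sites + 11L, spec$edit,
                         flank = spec$flank, indel_window = spec$indel_window)
  nick <- spec$nick_sites[1]
  for (off in c(-3, -1, 0, 2)) {
    start <- nick + off
    read1 <- paste0(substr(spec$reference, 1, start),
                    substr(spec$reference, start + 2, nchar(spec$reference)))
    read2 <- paste0(pad, read1)
    c1 <- call_reads(align_reads(read1, spec), spec)
    c2 <- call_reads(align_reads(read2, spec2), spec2)
    expect_equal(c1$has_indel_in_window, c2$has_indel_in_window)
  }
})

test_that("intended-edit detection requires intact flanks", {
  qf <- quant_frame(905)
  spec <- qf$spec
  edited <- spellpeg:::edited_reference(spec)
  calls <- call_reads(align_reads(edited, spec), spec)
  expect_true(calls$has_intended_edit)
  expect_false(calls$has_indel_in_window)

  # an error inside the 5-nt flank kills the strict match
  broken <- edited
  pos <- spec$edit_start - 2L      # inside the left flank (1-based -3)
  substr(broken, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                      substr(broken, pos, pos))[1]
  calls_b <- call_reads(align_reads(broken, spec), spec)
  expect_false(calls_b$has_intended_edit)
})

test_that("quantify implements the printed denominators", {
  qf <- quant_frame(906)
  spec <- qf$spec
  sim <- simulate_amplicon_reads(spec, 10000, edit_fraction = 0.125, seed = 1)
  calls <- call_reads(align_reads(sim, spec), spec)
  q <- quantify(calls, spec)
  expect_equal(q$total_reads, 10000L)
  expect_equal(q$edit_pct, 12.5)
  expect_equal(q$indel_pct, 0)

  # control with 0.5% background
  ctl <- simulate_amplicon_reads(spec, 2000, edit_fraction = 0.005, seed = 2)
  ctl_calls <- call_reads(align_reads(ctl, spec), spec)
  q2 <- quantify(calls, spec, control_calls = ctl_calls)
  expect_equal(q2$edit_pct_bgsub, 12.0)
  q3 <- quantify(calls, spec, transfection_eff = 0.5)
  expect_equal(q3$edit_pct_norm, 25.0)
  expect_error(quantify(calls, spec, transfection_eff = 1.5), "0, 1")
})

test_that("intended insertions separate edit and indel denominators", {
  qf <- quant_frame(907, edit_type = "insertion")
  spec <- qf$spec
  spectrum <- tibble::tibble(offset = 0L, type = "deletion", length = 2L,
                             fraction = 0.1)
  sim <- simulate_amplicon_reads(spec, 1000, edit_fraction = 0.3,
                                 indel_spectrum = spectrum, seed = 3)
  calls <- call_reads(align_reads(sim, spec), spec)
  q <- quantify(calls, spec)
  # the intended 1-nt insertion counts as edit, not as indel background
  expect_equal(q$edit_pct, 30)
  expect_equal(q$indel_pct, 10)
  expect_equal(q$edit_type, "insertion")
})

test_that("background subtraction is linear and sign-preserving", {
  qf <- quant_frame(908)
  spec <- qf$spec
  s1 <- simulate_amplicon_reads(spec, 2000, edit_fraction = 0.05, seed = 4)
  s2 <- simulate_amplicon_reads(spec, 2000, edit_fraction = 0.20, seed = 5)
  c1 <- call_reads(align_reads(s1, spec), spec)
  c2 <- call_reads(align_reads(s2, spec), spec)
  q12 <- quantify(c2, spec, control_calls = c1)
  expect_equal(q12$edit_pct_bgsub,
               quantify(c2, spec)$edit_pct - quantify(c1, spec)$edit_pct)
  # negative after subtraction is reported as-is, flagged
  q21 <- quantify(c1, spec, control_calls = c2)
  expect_lt(q21$edit_pct_bgsub, 0)
  expect_true(q21$negative_after_bgsub)
})

test_that("demultiplexing excludes chimeras and partitions all reads", {
  with_seed(909, {
    a_left <- random_dna(20); a_right <- random_dna(20)
    b_left <- random_dna(20); b_right <- random_dna(20)
    mid <- random_dna(40)
    gene_a <- paste0(a_left, mid, a_right)
    gene_b <- paste0(b_left, mid, b_right)
    chimera <- paste0(a_left, mid, b_right)
    demux <- tibble::tibble(
      gene = c("A", "A", "B", "B"),
      motif = c(substr(a_left, 3, 14), substr(a_right, 3, 14),
                substr(b_left, 3, 14), substr(b_right, 3, 14)),
      window_start = c(1, 55, 1, 55),
      window_end = c(10, 70, 10, 70))
    reads <- tibble::tibble(
      read_id = sprintf("r%03d", 1:210),
      sequence = c(rep(gene_a, 100), rep(gene_b, 100), rep(chimera, 10)))
    res <- demux_gene_specific(reads, demux)
    expect_equal(sum(res$gene == "A", na.rm = TRUE), 100L)
    expect_equal(sum(res$gene == "B", na.rm = TRUE), 100L)
    expect_equal(sum(res$reason == "chimera"), 10L)
    expect_equal(nrow(res), 210L)
    # no read in two genes, none lost
    expect_true(all(res$reason %in% c("assigned", "chimera", "ambiguous",
                                      "no_match")))
    none <- demux_gene_specific(tibble::tibble(read_id = "x",
                                               sequence = strrep("T", 80)),
                                demux)
    expect_equal(none$reason, "no_match")
    expect_error(demux_gene_specific(reads, demux[1:2, ]), "2 genes")
  })
})

test_that("sample sheets wire controls and normalization", {
  qf <- quant_frame(910)
  spec <- qf$spec
  dir <- withr::local_tempdir()
  trt <- simulate_amplicon_reads(spec, 800, edit_fraction = 0.25, seed = 6)
  ctl <- simulate_amplicon_reads(spec, 800, edit_fraction = 0.01, seed = 7)
  write_sim_fastq(trt, file.path(dir, "trt.fastq"))
  write_sim_fastq(ctl, file.path(dir, "ctl.fastq"))
  sheet <- tibble::tibble(
    sample = c("treated", "untransfected"),
    fastq = file.path(dir, c("trt.fastq", "ctl.fastq")),
    control_id = c("untransfected", NA),
    transfection_eff = c(0.5, NA))
  res <- quantify_samples(sheet, spec)
  expect_equal(nrow(res), 2L)
  tr <- res[res$sample == "treated", ]
  expect_equal(tr$edit_pct, 25)
  expect_equal(tr$edit_pct_bgsub, 24)
  expect_equal(tr$edit_pct_norm, 48)
  sheet_bad <- sheet
  sheet_bad$control_id[1] <- "missing"
  expect_error(quantify_samples(sheet_bad, spec), "control id")
})
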