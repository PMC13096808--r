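# Amplicon-sequencing quantification: global alignment against the
# reference amplicon, windowed indel calling around the nick sites,
# flank-anchored intended-edit detection, percentage denominators,
# background subtraction, transfection normalization and gene-specific
# demultiplexing.
#
# Read categories follow the amplicon bookkeeping rules:
#   * aligned reads ARE the total reads (the denominator);
#   * indels are searched within +/- indel_window bp around each nick/cut
#     site -- implemented as ANY overlap of the indel's reference span with
#     the closed window (the conservative reading; configurable);
#   * an intended-edit read contains the edited allele flanked by
#     `flank` exactly matching reference nucleotides on each side;
#   * substitution edits count only intended reads WITHOUT a window indel;
#     insertion/deletion edits count all intended reads, and the indel
#     background is computed from reads whose window indels differ from
#     the intended one.

#' Amplicon quantification frame
#'
#' @param reference DNA amplicon (forward strand).
#' @param nick_sites Integer vector of 0-based between-base nick
#'   coordinates (pegRNA nick, optionally the second nick).
#' @param edit An [edit_spec()] interpreted relative to `nick_sites[1]`,
#'   or `NULL` for indel-only quantification.
#' @param flank Exact-match flank length on each side of the edited
#'   allele. Default 5.
#' @param indel_window Half-width of the indel search window around each
#'   nick. Default 2.
#' @return An `amplicon_spec`.
#' @export
amplicon_spec <- function(reference, nick_sites, edit = NULL, flank = 5L,
                          indel_window = 2L) {
  reference <- as_nuc(reference)
  if (seq_alphabet(reference) != "DNA") abort("reference must be DNA")
  n <- nchar(reference)
  nick_sites <- as.integer(nick_sites)
  if (!length(nick_sites) || any(nick_sites < 1L | nick_sites >= n)) {
    abort("nick_sites must be between-base coordinates inside the reference")
  }
  flank <- as.integer(flank); indel_window <- as.integer(indel_window)
  if (flank < 1L) abort("flank must be >= 1")
  spec <- structure(list(reference = as.character(reference),
                         nick_sites = nick_sites,
                         edit = edit, flank = flank,
                         indel_window = indel_window),
                    class = "amplicon_spec")
  if (!is.null(edit)) {
    stopifnot(inherits(edit, "edit_spec"))
    spec$edit_start <- nick_sites[1] + edit$nick_distance - 1L
    m <- nchar(edit$ref)
    if (m > 0L) {
      found <- substr(spec$reference, spec$edit_start + 1L,
                      spec$edit_start + m)
      if (found != edit$ref) {
        abort(sprintf("edit ref allele '%s' does not match reference '%s'",
                      edit$ref, found))
      }
    }
    if (spec$edit_start - flank < 0L ||
        spec$edit_start + m + flank > n) {
      abort("edited motif plus flanks does not fit the reference")
    }
    spec$search_motif <- edited_motif(spec)
  }
  spec
}

# reference with the intended edit applied
edited_reference <- function(spec) {
  e <- spec$edit; s <- spec$edit_start
  paste0(substr(spec$reference, 1L, s),
         e$alt,
         substr(spec$reference, s + nchar(e$ref) + 1L, nchar(spec$reference)))
}

# the edited allele flanked by `flank` reference nucleotides on each side
edited_motif <- function(spec) {
  e <- spec$edit; s <- spec$edit_start; f <- spec$flank
  paste0(substr(spec$reference, s - f + 1L, s),
         e$alt,
         substr(spec$reference, s + nchar(e$ref) + 1L,
                s + nchar(e$ref) + f))
}

# intended edit as an indel event (NULL for substitutions)
intended_event <- function(spec) {
  e <- spec$edit
  if (is.null(e) || e$edit_type == "substitution") return(NULL)
  if (e$edit_type == "deletion") {
    list(type = "deletion", position = spec$edit_start,
         length = nchar(e$ref))
  } else {
    list(type = "insertion", position = spec$edit_start,
         length = nchar(e$alt))
  }
}

default_align_params <- function() {
  list(match = 2, mismatch = -3, gap_open = 8, gap_extend = 1,
       min_identity = 0.7, type = "global")
}

#' Align reads to the reference amplicon
#'
#' Global alignment with affine gap penalties via
#' `Biostrings::pairwiseAlignment()`, behind two exact shortcuts: unique
#' read sequences are aligned once, and equal-length reads with at most 3
#' mismatches take a gap-free fast path (under the default scoring a
#' substitution costs 5 while the cheapest gapped detour costs
#' 2 x (8 + 1) = 18, so the gap-free alignment is provably optimal there).
#' Reads whose alignment identity falls below `min_identity` are flagged
#' unaligned and excluded from the total; aligned reads are the
#' denominator of every percentage.
#'
#' @param reads A tibble with `read_id` and `sequence`, a character
#'   vector, a `sim_reads` object, or a FASTQ/FASTA file path.
#' @param spec An [amplicon_spec()].
#' @param params Scoring parameters, see `default_align_params()`.
#' @return A tibble: `read_id`, `sequence`, `aligned`, `identity`,
#'   `events` (list of per-read indel tibbles with 0-based reference
#'   `position`, `type`, `length`).
#' @export
align_reads <- function(reads, spec, params = default_align_params()) {
  reads <- as_read_tbl(reads)
  if (!nrow(reads)) abort("no reads supplied")
  params <- modifyList(default_align_params(), params)
  ref <- spec$reference
  uniq <- unique(reads$sequence)
  res <- vector("list", length(uniq))
  n_ref <- nchar(ref)
  ref_chars <- strsplit(ref, "")[[1]]

  needs_full <- logical(length(uniq))
  for (i in seq_along(uniq)) {
    s <- uniq[i]
    if (nchar(s) == n_ref) {
      mm <- sum(strsplit(s, "")[[1]] != ref_chars)
      gap_cost <- 2 * (params$gap_open + params$gap_extend)
      if ((params$match - params$mismatch) * mm < gap_cost) {
        res[[i]] <- list(identity = (n_ref - mm) / n_ref,
                         events = empty_events())
        next
      }
    }
    needs_full[i] <- TRUE
  }
  if (any(needs_full)) {
    idx <- which(needs_full)
    sm <- Biostrings::nucleotideSubstitutionMatrix(
      match = params$match, mismatch = params$mismatch, baseOnly = TRUE)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(uniq[idx]), Biostrings::DNAString(ref),
      type = params$type, substitutionMatrix = sm,
      gapOpening = params$gap_open, gapExtension = params$gap_extend)
    ind <- Biostrings::indel(aln)
    ins <- ind@insertion
    del <- ind@deletion
    n_events <- lengths(ins) + lengths(del)
    nm <- Biostrings::nmatch(aln)
    nmm <- Biostrings::nmismatch(aln)
    aln_len <- nm + nmm + vapply(ins, function(r) sum(r@width), numeric(1)) +
      vapply(del, function(r) sum(r@width), numeric(1))
    # single-indel alignments read straight off the indel ranges
    # (deletions arrive in reference coordinates, insertions in read
    # coordinates, which coincide with the reference between-base
    # coordinate when the indel is alone); anything richer goes through
    # the explicit gapped-string walker
    multi <- n_events > 1L
    pat <- sub <- NULL
    if (any(multi)) {
      pat <- as.character(Biostrings::alignedPattern(aln[multi]))
      sub <- as.character(Biostrings::alignedSubject(aln[multi]))
    }
    k_multi <- 0L
    for (j in seq_along(idx)) {
      if (multi[j]) {
        k_multi <- k_multi + 1L
        res[[idx[j]]] <- walk_alignment(pat[k_multi], sub[k_multi])
      } else {
        ev <- empty_events()
        if (lengths(del)[j] == 1L) {
          r <- del[[j]]
          ev <- tibble(position = r@start - 1L, type = "deletion",
                       length = r@width)
        } else if (lengths(ins)[j] == 1L) {
          r <- ins[[j]]
          ev <- tibble(position = r@start - 1L, type = "insertion",
                       length = r@width)
        }
        res[[idx[j]]] <- list(identity = nm[j] / aln_len[j], events = ev)
      }
    }
  }
  identity <- vapply(res, function(r) r$identity, numeric(1))
  aligned <- identity >= params$min_identity
  pos <- match(reads$sequence, uniq)
  tibble(
    read_id = reads$read_id,
    sequence = reads$sequence,
    aligned = aligned[pos],
    identity = identity[pos],
    events = lapply(pos, function(i)
      if (aligned[i]) res[[i]]$events else empty_events())
  )
}

empty_events <- function() {
  tibble(position = integer(), type = character(), length = integer())
}

# walk a gapped pattern/subject pair and extract indel events with 0-based
# reference coordinates; insertions get the between-base coordinate of
# their insertion point
walk_alignment <- function(pat, sub) {
  p <- strsplit(pat, "")[[1]]
  s <- strsplit(sub, "")[[1]]
  ref_pos <- 0L
  matches <- 0L
  events <- list()
  i <- 1L
  n <- length(p)
  while (i <= n) {
    if (s[i] == "-") {            # insertion in the read
      len <- 0L
      while (i <= n && s[i] == "-") { len <- len + 1L; i <- i + 1L }
      events[[length(events) + 1L]] <-
        list(position = ref_pos, type = "insertion", length = len)
    } else if (p[i] == "-") {     # deletion in the read
      start <- ref_pos
      len <- 0L
      while (i <= n && i >= 1L && p[i] == "-" && s[i] != "-") {
        len <- len + 1L; ref_pos <- ref_pos + 1L; i <- i + 1L
      }
      events[[length(events) + 1L]] <-
        list(position = start, type = "deletion", length = len)
    } else {
      if (p[i] == s[i]) matches <- matches + 1L
      ref_pos <- ref_pos + 1L
      i <- i + 1L
    }
  }
  list(identity = matches / n,
       events = if (length(events)) bind_rows(events) else empty_events())
}

as_read_tbl <- function(reads) {
  if (inherits(reads, "sim_reads")) return(reads$reads)
  if (is_tibble(reads) || is.data.frame(reads)) {
    if (!all(c("read_id", "sequence") %in% names(reads))) {
      abort("read table needs `read_id` and `sequence` columns")
    }
    return(as_tibble(reads)[c("read_id", "sequence")])
  }
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    return(read_fastq(reads))
  }
  if (is.character(reads)) {
    return(tibble(read_id = sprintf("read_%06d", seq_along(reads)),
                  sequence = toupper(reads)))
  }
  abort("unsupported read input")
}

#' Read a FASTQ (or FASTA) file into a read tibble
#' @param path File path; format picked by extension (`.fq`/`.fastq` vs
#'   `.fa`/`.fasta`).
#' @return Tibble with `read_id`, `sequence`.
#' @export
read_fastq <- function(path) {
  fmt <- if (grepl("\\.f(ast)?a$", path, ignore.case = TRUE)) "fasta"
         else "fastq"
  set <- Biostrings::readDNAStringSet(path, format = fmt)
  tibble(read_id = names(set) %||% sprintf("read_%06d", seq_along(set)),
         sequence = as.character(set))
}

# closed overlap test of an event against the +/- w window around nick n.
# Window in base coordinates: the w bases on each side of the nick,
# {n - w, ..., n + w - 1}; insertions use between-base coordinates and
# intersect when n - w <= pos <= n + w.
event_in_window <- function(event, nicks, w) {
  any(vapply(nicks, function(nk) {
    if (event$type == "insertion") {
      event$position >= nk - w && event$position <= nk + w
    } else {
      lo <- event$position
      hi <- event$position + event$length - 1L
      hi >= nk - w && lo <= nk + w - 1L
    }
  }, logical(1)))
}

matches_intended <- function(event, intended, tol = NULL) {
  if (is.null(intended)) return(FALSE)
  tol <- tol %||% intended$length   # alignment placement ambiguity
  event$type == intended$type &&
    event$length == intended$length &&
    abs(event$position - intended$position) <= tol
}

#' Classify aligned reads
#'
#' Applies the windowed indel rule and the flank-anchored intended-edit
#' search to every aligned read.
#'
#' @param alignments Output of [align_reads()].
#' @param spec An [amplicon_spec()].
#' @return A `read_calls` tibble: `read_id`, `aligned`,
#'   `has_indel_in_window`, `n_window_events`, `has_intended_edit`,
#'   `has_nonintended_window_indel`.
#' @export
call_reads <- function(alignments, spec) {
  w <- spec$indel_window
  nicks <- spec$nick_sites
  intended <- intended_event(spec)
  motif <- spec$search_motif

  n <- nrow(alignments)
  has_edit <- if (is.null(motif)) rep(FALSE, n) else {
    alignments$aligned & grepl(motif, alignments$sequence, fixed = TRUE)
  }
  win <- logical(n); nwin <- integer(n); other <- logical(n)
  n_ev <- vapply(alignments$events, nrow, integer(1))
  for (k in which(alignments$aligned & n_ev > 0L)) {
    ev <- alignments$events[[k]]
    in_win <- vapply(seq_len(nrow(ev)), function(i)
      event_in_window(ev[i, ], nicks, w), logical(1))
    win[k] <- any(in_win)
    nwin[k] <- sum(in_win)
    if (win[k]) {
      other[k] <- any(vapply(which(in_win), function(i)
        !(has_edit[k] && matches_intended(ev[i, ], intended)), logical(1)))
    }
  }
  out <- tibble(
    read_id = alignments$read_id,
    aligned = alignments$aligned,
    has_indel_in_window = win,
    n_window_events = nwin,
    has_intended_edit = has_edit,
    has_nonintended_window_indel = other
  )
  structure(out, class = c("read_calls", class(out)))
}

#' Quantify edit and indel frequencies
#'
#' Denominator: aligned reads. For substitution edits, `edit_pct` counts
#' intended-edit reads without a window indel and `indel_pct` all window-
#' indel reads. For insertion/deletion edits, `edit_pct` counts all
#' intended-edit reads and `indel_pct` reads carrying window indels other
#' than the intended one. When control calls (untransfected sample) are
#' supplied, the control's percentages are subtracted; negative
#' background-subtracted values are reported as-is with a flag. A
#' transfection efficiency in (0, 1] divides the background-subtracted
#' edit percentage.
#'
#' @param calls A `read_calls` tibble from [call_reads()].
#' @param spec The [amplicon_spec()].
#' @param control_calls Optional `read_calls` for the untransfected
#'   control.
#' @param transfection_eff Optional scalar in (0, 1].
#' @return A `quant_result`: one-row tibble with counts, raw,
#'   background-subtracted and normalized percentages.
#' @export
quantify <- function(calls, spec, control_calls = NULL,
                     transfection_eff = NULL) {
  raw <- quant_raw(calls, spec)
  edit_bg <- indel_bg <- 0
  if (!is.null(control_calls)) {
    ctl <- quant_raw(control_calls, spec)
    edit_bg <- ctl$edit_pct
    indel_bg <- ctl$indel_pct
  }
  edit_sub <- raw$edit_pct - edit_bg
  indel_sub <- raw$indel_pct - indel_bg
  norm <- NA_real_
  if (!is.null(transfection_eff)) {
    if (!is.numeric(transfection_eff) || transfection_eff <= 0 ||
        transfection_eff > 1) {
      abort("transfection_eff must lie in (0, 1]")
    }
    norm <- edit_sub / transfection_eff
  }
  out <- tibble(
    total_reads = raw$total_reads,
    n_edit = raw$n_edit, n_indel = raw$n_indel,
    edit_pct = raw$edit_pct, indel_pct = raw$indel_pct,
    edit_pct_bgsub = edit_sub, indel_pct_bgsub = indel_sub,
    edit_pct_norm = norm,
    negative_after_bgsub = edit_sub < 0 || indel_sub < 0,
    denominator = "aligned_reads",
    edit_type = spec$edit$edit_type %||% NA_character_
  )
  structure(out, class = c("quant_result", class(out)))
}

quant_raw <- function(calls, spec) {
  stopifnot(inherits(calls, "read_calls") || is.data.frame(calls))
  al <- calls[calls$aligned, , drop = FALSE]
  total <- nrow(al)
  if (total < 1L) abort("no aligned reads to quantify")
  etype <- spec$edit$edit_type %||% "none"
  if (etype == "substitution") {
    n_edit <- sum(al$has_intended_edit & !al$has_indel_in_window)
    n_indel <- sum(al$has_indel_in_window)
  } else if (etype %in% c("insertion", "deletion")) {
    n_edit <- sum(al$has_intended_edit)
    n_indel <- sum(al$has_nonintended_window_indel)
  } else {
    n_edit <- 0L
    n_indel <- sum(al$has_indel_in_window)
  }
  list(total_reads = total, n_edit = n_edit, n_indel = n_indel,
       edit_pct = 100 * n_edit / total,
       indel_pct = 100 * n_indel / total)
}

#' @describeIn quantify glance method (the one-row result).
#' @param x A `quant_result`.
#' @param ... Unused.
#' @method glance quant_result
#' @export
glance.quant_result <- function(x, ...) as_tibble(unclass(x)[seq_along(x)])

#' Gene-specific demultiplexing
#'
#' Assigns each read to a gene only when BOTH of that gene's motifs match
#' within their position windows; reads combining motifs of different
#' genes (template-switch chimeras / non-specific priming) or matching
#' neither are excluded with a reason.
#'
#' @param reads Read input accepted by [align_reads()].
#' @param demux A tibble with columns `gene`, `motif`, `window_start`,
#'   `window_end` (1-based inclusive window of allowed motif start
#'   positions), two rows (motifs) per gene.
#' @return A tibble `read_id`, `gene` (NA when excluded), `reason`
#'   (`"assigned"`, `"chimera"`, `"ambiguous"`, `"no_match"`).
#' @export
demux_gene_specific <- function(reads, demux) {
  reads <- as_read_tbl(reads)
  demux <- as_tibble(demux)
  need <- c("gene", "motif", "window_start", "window_end")
  if (!all(need %in% names(demux))) {
    abort(sprintf("demux table needs columns: %s", paste(need, collapse = ", ")))
  }
  genes <- unique(demux$gene)
  if (length(genes) < 2L) abort("need motif definitions for >= 2 genes")
  counts <- table(demux$gene)
  if (any(counts < 2L)) abort("each gene needs two motifs")
  key <- paste(demux$motif, demux$window_start, demux$window_end)
  if (anyDuplicated(key)) {
    abort("identical motif/window defined twice: assignment would be ambiguous")
  }
  motif_hit <- function(sq, motif, ws, we) {
    hit <- regexpr(motif, sq, fixed = TRUE)[1]
    # any occurrence starting within the window counts
    while (hit != -1L && hit < ws) {
      nxt <- regexpr(motif, substr(sq, hit + 1L, nchar(sq)), fixed = TRUE)[1]
      hit <- if (nxt == -1L) -1L else hit + nxt
    }
    hit != -1L && hit >= ws && hit <= we
  }
  rows <- map(reads$sequence, function(sq) {
    per_gene <- vapply(genes, function(g) {
      m <- demux[demux$gene == g, ]
      sum(vapply(seq_len(nrow(m)), function(i)
        motif_hit(sq, m$motif[i], m$window_start[i], m$window_end[i]),
        logical(1)))
    }, numeric(1))
    full <- genes[per_gene >= 2L]
    partial <- genes[per_gene == 1L]
    if (length(full) == 1L && !length(partial)) {
      list(gene = full, reason = "assigned")
    } else if (length(full) > 1L) {
      list(gene = NA_character_, reason = "ambiguous")
    } else if (length(unique(c(full, partial))) > 1L ||
               (length(full) == 1L && length(partial))) {
      list(gene = NA_character_, reason = "chimera")
    } else if (!length(full)) {
      list(gene = NA_character_, reason = "no_match")
    }
  })
  tibble(read_id = reads$read_id,
         gene = map_chr(rows, "gene"),
         reason = map_chr(rows, "reason"))
}

#' Quantify a sample sheet
#'
#' Runs align/call/quantify for every sample of a sheet, wiring each
#' sample to its untransfected control and transfection efficiency.
#'
#' @param sheet Tibble or TSV path with columns `sample`, `fastq`,
#'   `control_id` (NA/"" for none; must name another sample) and
#'   `transfection_eff` (NA for none).
#' @param spec An [amplicon_spec()].
#' @param params Alignment parameters.
#' @return A tibble of per-sample [quantify()] rows.
#' @export
quantify_samples <- function(sheet, spec, params = default_align_params()) {
  if (is.character(sheet)) sheet <- readr::read_tsv(sheet, show_col_types = FALSE)
  sheet <- as_tibble(sheet)
  need <- c("sample", "fastq")
  if (!all(need %in% names(sheet))) abort("sheet needs `sample` and `fastq`")
  calls <- setNames(lapply(sheet$fastq, function(f)
    call_reads(align_reads(f, spec, params), spec)), sheet$sample)
  rows <- lapply(seq_len(nrow(sheet)), function(i) {
    ctl_id <- sheet$control_id[i] %||% NA
    ctl <- if (!is.null(ctl_id) && !is.na(ctl_id) && nzchar(ctl_id)) {
      if (!ctl_id %in% names(calls)) {
        abort(sprintf("control id '%s' not present in the sample sheet", ctl_id))
      }
      calls[[ctl_id]]
    } else NULL
    te <- suppressWarnings(as.numeric(sheet$transfection_eff[i] %||% NA))
    q <- quantify(calls[[sheet$sample[i]]], spec, control_calls = ctl,
                  transfection_eff = if (is.na(te)) NULL else te)
    mutate(as_tibble(q), sample = sheet$sample[i], .before = 1L)
  })
  bind_rows(rows)
}
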