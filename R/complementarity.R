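# The spacer:PBS complementarity register -- the quantity the whole design
# strategy manipulates. Because the PBS is built as the complement of the
# non-target strand just 5' of the nick, and the spacer is a copy of the
# protospacer, PBS position p is register-paired with spacer position
# p + nick_offset (from-PAM numbering). Deletions in the PBS shift the
# register of everything 3' of them; mismatches break individual pairs but
# leave the register intact.

#' Spacer:PBS complementarity map
#'
#' Computes the pairing register between a design's spacer and PBS and
#' evaluates each pair base-by-base on the actual (possibly modified)
#' sequences. An unmodified PBS position `p` pairs spacer position
#' `p + nick_offset`; downstream of a `k`-nt PBS deletion the register
#' shifts by `+k`. An appended 5' G (spacer position 21) participates like
#' any other position: it is simply the last position reachable by long
#' PBSs -- computed, not special-cased.
#'
#' Note on numbering: with the default `nick_offset = 3` a 7-nt PBS covers
#' spacer positions 4-10. Descriptions of the same geometry elsewhere
#' sometimes quote "positions 3-10" for a 7-nt PBS; that convention counts
#' one more PAM-proximal position than 7 nt can pair and is not used here.
#'
#' @param design A `peg_design`.
#' @param nick_offset Nick distance from the PAM. Default 3.
#' @return A `complementarity_map`: a tibble of pairs (`pbs_position`,
#'   `pbs_original_position`, `spacer_position`, `pbs_base`, `spacer_base`,
#'   `is_watson_crick`) with attributes `n_paired` (count of Watson-Crick
#'   pairs), `covered_spacer_positions` (register-paired spacer positions)
#'   and `register_shift` (per current PBS position).
#' @examples
#' loc <- with_seed(1, random_locus())
#' d <- design_pegrna(loc, edit_spec(1, substr(downstream_of_nick(loc), 1, 1), "A"),
#'                    pbs_length = 17)
#' complementarity_map(d)
#' @export
complementarity_map <- function(design, nick_offset = 3L) {
  stopifnot(inherits(design, "peg_design"))
  nick_offset <- as.integer(nick_offset)
  spacer <- design$spacer
  pbs <- design$pbs
  s_len <- nchar(spacer)
  p_len <- nchar(pbs)

  orig <- pbs_original_coords(design)
  stopifnot(length(orig) == p_len)
  partner <- orig + nick_offset
  shift <- orig - seq_len(p_len)

  keep <- partner >= 1L & partner <= s_len
  pbs_pos <- seq_len(p_len)[keep]
  sp_pos <- partner[keep]
  # spacer string is 5'->3'; from-PAM position k is character s_len - k + 1
  sp_chr <- vapply(sp_pos, function(k)
    substr(spacer, s_len - k + 1L, s_len - k + 1L), character(1))
  pb_chr <- vapply(pbs_pos, function(p) substr(pbs, p, p), character(1))
  wc <- complement_base(sp_chr, "RNA") == pb_chr

  pairs <- tibble(
    pbs_position = pbs_pos,
    pbs_original_position = orig[keep],
    spacer_position = as.integer(sp_pos),
    pbs_base = pb_chr,
    spacer_base = sp_chr,
    is_watson_crick = wc
  )
  structure(pairs,
            class = c("complementarity_map", class(pairs)),
            n_paired = sum(wc),
            covered_spacer_positions = as.integer(sp_pos),
            register_shift = as.integer(shift),
            nick_offset = nick_offset,
            spacer_length = s_len,
            pbs_length = p_len)
}

# Current PBS position -> coordinate in the ORIGINAL (pre-modification)
# PBS. Only deletions shift coordinates; mismatches and scrambles do not.
pbs_original_coords <- function(design) {
  orig_len <- nchar(design$pbs_original)
  coords <- seq_len(orig_len)
  for (mod in design$pbs_modifications) {
    if (identical(mod$kind, "deletion")) {
      drop <- mod$position:(mod$position + mod$length - 1L)
      coords <- setdiff(coords, drop)
    }
  }
  coords
}

#' Number of Watson-Crick spacer:PBS pairs
#' @param design A `peg_design` or a `complementarity_map`.
#' @param nick_offset Passed to [complementarity_map()].
#' @return Integer count.
#' @export
n_paired <- function(design, nick_offset = 3L) {
  cm <- if (inherits(design, "complementarity_map")) design
        else complementarity_map(design, nick_offset)
  attr(cm, "n_paired")
}

#' Spacer positions reached by the PBS register
#' @inheritParams n_paired
#' @return Sorted integer vector of from-PAM spacer positions.
#' @export
covered_spacer_positions <- function(design, nick_offset = 3L) {
  cm <- if (inherits(design, "complementarity_map")) design
        else complementarity_map(design, nick_offset)
  sort(attr(cm, "covered_spacer_positions"))
}

#' @export
print.complementarity_map <- function(x, ...) {
  cov <- sort(attr(x, "covered_spacer_positions"))
  cat(sprintf(
    "<complementarity_map> PBS %d nt vs spacer %d nt: %d Watson-Crick pair(s)\n",
    attr(x, "pbs_length"), attr(x, "spacer_length"), attr(x, "n_paired")))
  if (length(cov)) {
    cat(sprintf("  covered spacer positions: %d..%d%s\n", min(cov), max(cov),
                if (length(cov) == max(cov) - min(cov) + 1L) ""
                else " (with gaps)"))
  }
  NextMethod()
}

#' @describeIn complementarity_map tidy method: the pair table as a plain
#'   tibble.
#' @param x A `complementarity_map`.
#' @param ... Unused.
#' @method tidy complementarity_map
#' @export
tidy.complementarity_map <- function(x, ...) {
  as_tibble(unclass(x)[seq_along(x)])
}

#' @describeIn complementarity_map autoplot: spacer positions vs pairing
#'   state.
#' @param object A `complementarity_map`.
#' @method autoplot complementarity_map
#' @export
autoplot.complementarity_map <- function(object, ...) {
  df <- tidy(object)
  df$state <- ifelse(df$is_watson_crick, "Watson-Crick", "mismatched")
  ggplot(df, aes(x = .data$spacer_position, y = 1, fill = .data$state)) +
    geom_tile(colour = "grey30", height = 0.6) +
    labs(x = "spacer position (1 = PAM-proximal)", y = NULL,
         fill = NULL,
         title = sprintf("spacer:PBS register, %d paired",
                         attr(object, "n_paired"))) +
    theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
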