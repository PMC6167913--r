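#' Beta-sheet propensity classes
#'
#' The five categorical beta-sheet propensity classes of Prevelige & Fasman,
#' which partition the twenty standard amino acids:
#' strong formers \{V,I,M\}; formers \{F,Y,C,T,W,L,Q\}; indifferent
#' \{R,G,A,D\}; breakers \{H,S,K,N,P\}; strong breakers \{E\}.
#'
#' @return A named list of character vectors, one per class label.
#' @export
beta_classes <- function() {
  list(
    strong_former  = c("V", "I", "M"),
    former         = c("F", "Y", "C", "T", "W", "L", "Q"),
    indifferent    = c("R", "G", "A", "D"),
    breaker        = c("H", "S", "K", "N", "P"),
    strong_breaker = c("E")
  )
}

#' Classify an amino acid by beta-sheet propensity
#'
#' @param aa Character vector of one-letter amino-acid codes.
#' @return Character vector of class labels (`strong_former`, `former`,
#'   `indifferent`, `breaker`, `strong_breaker`).
#' @examples
#' beta_class(c("V", "E", "G"))
#' @export
beta_class <- function(aa) {
  cls <- beta_classes()
  lut <- setNames(rep(names(cls), lengths(cls)), unlist(cls))
  aa <- toupper(aa)
  bad <- setdiff(aa, names(lut))
  if (length(bad) > 0) {
    abort(sprintf("non-standard residue(s): %s", paste(unique(bad), collapse = ", ")),
          class = "abloopr_classification_error")
  }
  unname(lut[aa])
}

# Split a loop of length n into stem_n / apex / stem_c.  The apex is the
# central third, rounded outward (length >= ceiling(n/3)); when the flanks
# split unevenly the N-terminal stem takes the extra position.
segment_loop <- function(n, apex_frac = 1 / 3) {
  stopifnot(n >= 3, apex_frac > 0, apex_frac <= 1)
  apex_len <- ceiling(n * apex_frac)
  stem_n <- ceiling((n - apex_len) / 2)
  stem_c <- n - apex_len - stem_n
  rep(c("stem_n", "apex", "stem_c"), times = c(stem_n, apex_len, stem_c))
}

#' Per-residue beta-propensity profile of a CDR-3 loop
#'
#' Classifies every loop position by beta-sheet propensity and segments the
#' loop into an N-terminal stem, a central apex (the central third of the
#' loop, rounded outward) and a C-terminal stem.  Breakers concentrated at
#' the apex with former-rich stems are the hallmark of a hairpin-compatible
#' loop.
#'
#' @param loop_seq A single loop sequence (length >= 3).
#' @param apex_frac Fraction of the loop treated as apex (default one third).
#' @return A tibble with one row per position: `position` (1-based),
#'   `residue`, `class`, `segment`.
#' @examples
#' propensity_profile("VVVEEVVV")
#' @export
propensity_profile <- function(loop_seq, apex_frac = 1 / 3) {
  stopifnot(is.character(loop_seq), length(loop_seq) == 1)
  aa <- strsplit(toupper(loop_seq), "")[[1]]
  if (length(aa) < 3) {
    abort("loop must have at least 3 residues", class = "abloopr_input_error")
  }
  tibble(
    position = seq_along(aa),
    residue = aa,
    class = beta_class(aa),
    segment = segment_loop(length(aa), apex_frac)
  )
}

#' Summary counts of a propensity profile
#'
#' @param profile A tibble from [propensity_profile()].
#' @return A tibble of counts per (segment, class), with zero rows filled in.
#' @export
propensity_summary <- function(profile) {
  grid <- tidyr::expand_grid(
    segment = c("stem_n", "apex", "stem_c"),
    class = names(beta_classes())
  )
  counts <- profile |>
    count(.data$segment, .data$class, name = "n")
  left_join(grid, counts, by = c("segment", "class")) |>
    mutate(n = tidyr::replace_na(.data$n, 0L))
}

#' Fraction of stem residues that are beta-sheet breakers
#'
#' The stem breaker score is the number of breaker plus strong-breaker
#' residues in the two stems divided by the total stem length.  Low scores
#' indicate stems able to sustain anti-parallel beta-sheet hydrogen bonding.
#'
#' @param profile A tibble from [propensity_profile()].
#' @return A single number in \[0, 1\].
#' @examples
#' stem_breaker_score(propensity_profile("VIMHSKVIM"))
#' @export
stem_breaker_score <- function(profile) {
  stems <- profile[profile$segment != "apex", ]
  if (nrow(stems) == 0) {
    abort("zero-length stem: breaker score undefined",
          class = "abloopr_undefined_score_error")
  }
  mean(stems$class %in% c("breaker", "strong_breaker"))
}

#' Propensity profiles for a table of CDR-3 loops
#'
#' Tibble-first wrapper over [propensity_profile()]: profiles every row of an
#' annotated CDR table and adds per-antibody stem breaker scores.
#'
#' @param cdrs A tibble with columns `id`, `chain`, `loop_seq`.
#' @param apex_frac Fraction of the loop treated as apex.
#' @return A tibble of per-residue rows with `id` and `chain` carried along.
#' @export
profile_cdrs <- function(cdrs, apex_frac = 1 / 3) {
  purrr::pmap(cdrs[, c("id", "chain", "loop_seq")], function(id, chain, loop_seq) {
    mutate(propensity_profile(loop_seq, apex_frac), id = id, chain = chain,
           .before = 1)
  }) |> bind_rows()
}
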