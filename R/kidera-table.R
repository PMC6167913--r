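#' The Kidera factor table
#'
#' The ten orthogonal Kidera factors for the twenty standard amino acids.
#' The factors summarise 188 physical amino-acid properties through dimension
#' reduction and are standardized so that, across the twenty residues, each
#' factor has mean approximately zero and unit variance.  The values are the
#' published table of Kidera et al. (1985), J. Protein Chem. 4:23-55.
#'
#' @return A tibble with 20 rows and columns `residue` (one-letter code) and
#'   `kf1` ... `kf10` (dimensionless factor values).
#' @examples
#' kidera_table()
#' @export
kidera_table <- function() {
  res <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  m <- matrix(c(
    -1.56, -1.67, -0.97, -0.27, -0.93, -0.78, -0.20, -0.08,  0.21, -0.48,
     0.22,  1.27,  1.37,  1.87, -1.70,  0.46,  0.92, -0.39,  0.23,  0.93,
     1.14, -0.07, -0.12,  0.81,  0.18,  0.37, -0.09,  1.23,  1.10, -1.73,
     0.58, -0.22, -1.58,  0.81, -0.92,  0.15, -1.52,  0.47,  0.76,  0.70,
     0.12, -0.89,  0.45, -1.05, -0.71,  2.41,  1.52, -0.69,  1.13,  1.10,
    -0.47,  0.24,  0.07,  1.10,  1.10,  0.59,  0.84, -0.71, -0.03, -2.33,
    -1.45,  0.19, -1.61,  1.17, -1.31,  0.40,  0.04,  0.38, -0.35, -0.12,
     1.46, -1.96, -0.23, -0.16,  0.10, -0.11,  1.32,  2.36, -1.66,  0.46,
    -0.41,  0.52, -0.28,  0.28,  1.61,  1.01, -1.85,  0.47,  1.13,  1.63,
    -0.73, -0.16,  1.79, -0.77, -0.54,  0.03, -0.83,  0.51,  0.66, -1.78,
    -1.04,  0.00, -0.24, -1.10, -0.55, -2.05,  0.96, -0.76,  0.45,  0.93,
    -0.34,  0.82, -0.23,  1.70,  1.54, -1.62,  1.15, -0.08, -0.48,  0.60,
    -1.40,  0.18, -0.42, -0.73,  2.00,  1.52,  0.26,  0.11, -1.27,  0.27,
    -0.21,  0.98, -0.36, -1.43,  0.22, -0.81,  0.67,  1.10,  1.71, -0.44,
     2.06, -0.33, -1.15, -0.75,  0.88, -0.45,  0.30, -2.30,  0.74, -0.28,
     0.81, -1.08,  0.16,  0.42, -0.21, -0.43, -1.89, -1.15, -0.97, -0.23,
     0.26, -0.70,  1.21,  0.63, -0.10,  0.21,  0.24, -1.15, -0.56,  0.19,
     0.30,  2.10, -0.72, -1.57, -1.16,  0.57, -0.48, -0.40, -2.30, -0.60,
     1.38,  1.48,  0.80, -0.56,  0.00, -0.68, -0.31,  1.03, -0.05,  0.53,
    -0.74, -0.71,  2.04, -0.40,  0.50, -0.81, -0.40,  0.91,  0.36, -0.28
  ), nrow = 20, byrow = TRUE,
  dimnames = list(res, paste0("kf", 1:10)))
  dplyr::bind_cols(tibble(residue = res), as_tibble(m))
}

#' Encode CDR-3 loops as Kidera feature vectors
#'
#' Aggregates the ten Kidera factors over the residues of the CDR-H3 and
#' CDR-L3 loops of each antibody and concatenates the two ten-dimensional
#' parts into a 20-dimensional physico-chemical descriptor.  Aggregation is
#' the per-factor arithmetic mean by default, which makes descriptors of
#' loops of different lengths directly comparable; `agg = "sum"` gives the
#' length-sensitive alternative.
#'
#' @param cdrs A tibble of extracted CDR-3 regions as returned by
#'   [annotate_cdr3()], with at least columns `id`, `chain` (`"H"`/`"L"`) and
#'   `loop_seq`.  Every `id` must have exactly one H and one L row.
#' @param agg Aggregation over loop residues: `"mean"` (default) or `"sum"`.
#' @param table The Kidera factor table; defaults to [kidera_table()].
#' @return A tibble with one row per antibody: `antibody_id`, then `h3_kf1`
#'   ... `h3_kf10` and `l3_kf1` ... `l3_kf10`.
#' @examples
#' cdrs <- tibble::tibble(
#'   id = c("ab1", "ab1"), chain = c("H", "L"),
#'   loop_seq = c("VIMGDY", "QQSYSTP")
#' )
#' kidera_encode(cdrs)
#' @export
kidera_encode <- function(cdrs, agg = c("mean", "sum"), table = kidera_table()) {
  agg <- match.arg(agg)
  stopifnot(all(c("id", "chain", "loop_seq") %in% names(cdrs)))
  kf <- as.matrix(table[, paste0("kf", 1:10)])
  rownames(kf) <- table$residue
  aggfun <- if (agg == "mean") colMeans else colSums

  part <- function(seq) {
    aa <- strsplit(seq, "")[[1]]
    bad <- setdiff(aa, rownames(kf))
    if (length(bad) > 0) {
      abort(sprintf("residue(s) %s absent from the Kidera table",
                    paste(unique(bad), collapse = ", ")),
            class = "abloopr_encoding_error")
    }
    aggfun(kf[aa, , drop = FALSE])
  }

  ids <- unique(cdrs$id)
  rows <- purrr::map(ids, function(i) {
    sub <- cdrs[cdrs$id == i, ]
    for (ch in c("H", "L")) {
      if (sum(sub$chain == ch) != 1) {
        abort(sprintf("antibody '%s' must have exactly one %s-chain CDR-3", i, ch),
              class = "abloopr_input_error")
      }
    }
    h3 <- part(sub$loop_seq[sub$chain == "H"])
    l3 <- part(sub$loop_seq[sub$chain == "L"])
    if (!all(is.finite(c(h3, l3)))) {
      abort("non-finite Kidera feature", class = "abloopr_encoding_error")
    }
    tibble(antibody_id = i, !!!setNames(as.list(h3), paste0("h3_", names(h3))),
           !!!setNames(as.list(l3), paste0("l3_", names(l3))))
  })
  bind_rows(rows)
}
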