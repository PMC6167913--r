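#' Read a labelled paired-chain FASTA file
#'
#' Reads antibody variable-region sequences from a FASTA file whose headers
#' follow the `id|chain|phenotype` dialect (e.g. `ab1|H|promiscuous`).  Each
#' antibody id must contribute exactly one heavy (`H`) and one light (`L`)
#' entry; phenotype tokens other than `promiscuous` / `non_promiscuous` map
#' to `unknown`.
#'
#' @param path Path to a FASTA file.
#' @return A tibble of antibody records: `id`, `heavy_seq`, `light_seq`,
#'   `phenotype`.
#' @export
read_labelled_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "abloopr_input_error")
  }
  ss <- Biostrings::readAAStringSet(path)
  parts <- stringr::str_split_fixed(names(ss), stringr::fixed("|"), 3)
  if (any(parts[, 1] == "" | parts[, 2] == "")) {
    abort("FASTA headers must follow the 'id|chain|phenotype' dialect",
          class = "abloopr_parse_error")
  }
  entries <- tibble(
    id = parts[, 1],
    chain = parts[, 2],
    phenotype = ifelse(parts[, 3] %in% c("promiscuous", "non_promiscuous"),
                       parts[, 3], "unknown"),
    seq = toupper(as.character(ss))
  )
  bad <- stringr::str_locate(entries$seq, "[^ACDEFGHIKLMNPQRSTVWY]")[, 1]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    abort(sprintf("non-standard residue '%s' at position %d of entry %s|%s",
                  substr(entries$seq[i], bad[i], bad[i]), bad[i],
                  entries$id[i], entries$chain[i]),
          class = "abloopr_parse_error")
  }
  if (!all(entries$chain %in% c("H", "L"))) {
    abort("chain token must be 'H' or 'L'", class = "abloopr_parse_error")
  }
  for (i in unique(entries$id)) {
    sub <- entries[entries$id == i, ]
    if (sum(sub$chain == "H") != 1 || sum(sub$chain == "L") != 1) {
      abort(sprintf("id '%s' must have exactly one H and one L entry", i),
            class = "abloopr_pairing_error")
    }
  }
  heavy <- entries[entries$chain == "H", ]
  light <- entries[entries$chain == "L", ]
  tibble(
    id = heavy$id,
    heavy_seq = heavy$seq,
    light_seq = light$seq[match(heavy$id, light$id)],
    phenotype = heavy$phenotype
  )
}

# Chothia-style residue labels for a CDR-3 loop of a given length.
# Heavy chains use base positions 95..102 with insertions (A, B, C, ...)
# after position 100; light chains use 89..97 with insertions after 95.
# Short loops drop base numbers outward from the loop centre.
chothia_cdr3_labels <- function(n, chain = c("H", "L")) {
  chain <- match.arg(chain)
  base <- if (chain == "H") 95:102 else 89:97
  ins_at <- if (chain == "H") 100L else 95L
  nb <- length(base)
  if (n <= nb) {
    keep_n <- ceiling(n / 2)
    keep_c <- n - keep_n
    labs <- c(head(base, keep_n), tail(base, keep_c))
    return(as.character(labs))
  }
  n_ins <- n - nb
  ins <- paste0(ins_at, LETTERS[seq_len(n_ins)])
  pre <- base[base <= ins_at]
  post <- base[base > ins_at]
  c(as.character(pre), ins, as.character(post))
}

#' Extract a CDR-3 loop by anchor motifs
#'
#' Locates the third complementarity-determining region of a heavy or light
#' variable-domain sequence using the conserved anchor motifs flanking it.
#' For heavy chains the loop comprises the residues strictly between the
#' conserved `C..` motif (the cysteine at Chothia H92 plus two framework
#' residues, typically `CAR`) and the `WG.G` J-segment motif; for light
#' chains, strictly between the conserved cysteine and the `FG.G` motif.
#' If several candidate J-motifs exist the one closest to the C-terminus is
#' used and a warning is raised.  Chothia-style labels with insertion codes
#' are assigned to the loop positions.
#'
#' @param sequence A single variable-domain amino-acid sequence.
#' @param chain `"H"` or `"L"`.
#' @return A one-row tibble: `chain`, `loop_seq`, `length`, `start` (0-based
#'   inclusive), `end` (0-based exclusive), `numbering` (list column of
#'   Chothia labels, one per loop residue).
#' @examples
#' h <- paste0("EVQLVESGGGLVQPGGSLRLSCAASGFTFSSYAMSWVRQAPGKGLEWVSAI",
#'             "SGSGGSTYYADSVKGRFTISRDNSKNTLYLQMNSLRAEDTAVYYCARGDYVMDY",
#'             "WGQGTLVTVSS")
#' extract_cdr3(h, "H")
#' @export
extract_cdr3 <- function(sequence, chain = c("H", "L")) {
  chain <- match.arg(chain)
  seq <- toupper(sequence)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", seq)) {
    abort("sequence contains non-standard residues",
          class = "abloopr_parse_error")
  }
  j_pat <- if (chain == "H") "WG.G" else "FG.G"
  j_hits <- stringr::str_locate_all(seq, j_pat)[[1]]
  if (nrow(j_hits) == 0) {
    abort(sprintf("anchor motif '%s' not found in %s chain", j_pat, chain),
          class = "abloopr_extraction_error")
  }
  if (nrow(j_hits) > 1) {
    warn(sprintf("multiple '%s' anchors; using the most C-terminal", j_pat))
  }
  j_start <- j_hits[nrow(j_hits), "start"]
  # offset from the anchor Cys to the first loop residue: the heavy-chain
  # motif is C plus two framework residues (e.g. CAR), the light-chain
  # anchor is the bare Cys
  cys_gap <- if (chain == "H") 3L else 1L
  cys_pos <- stringr::str_locate_all(seq, "C")[[1]][, "start"]
  cys_pos <- cys_pos[cys_pos + cys_gap + 3 <= j_start]  # loop length >= 3
  if (length(cys_pos) == 0) {
    abort(sprintf("conserved Cys anchor not found before '%s' in %s chain",
                  j_pat, chain),
          class = "abloopr_extraction_error")
  }
  cys <- max(cys_pos)
  start0 <- cys + cys_gap - 1L          # 0-based inclusive
  end0 <- j_start - 1L                  # 0-based exclusive
  loop <- substr(seq, start0 + 1L, end0)
  tibble(
    chain = chain,
    loop_seq = loop,
    length = nchar(loop),
    start = as.integer(start0),
    end = as.integer(end0),
    numbering = list(chothia_cdr3_labels(nchar(loop), chain))
  )
}

#' Annotate CDR-3 loops for a set of antibody records
#'
#' Extracts CDR-H3 and/or CDR-L3 from every record and returns a tidy CDR
#' table suitable for [kidera_encode()] and [profile_cdrs()].
#'
#' @param records A tibble of antibody records (see [read_labelled_fasta()]
#'   or [generate_antibody_set()]).
#' @param chain `"H"`, `"L"` or `"both"` (default).
#' @return A tibble with columns `id`, `phenotype`, `chain`, `loop_seq`,
#'   `length`, `start`, `end`, `numbering`.
#' @export
annotate_cdr3 <- function(records, chain = c("both", "H", "L")) {
  chain <- match.arg(chain)
  chains <- if (chain == "both") c("H", "L") else chain
  purrr::pmap(records[, c("id", "heavy_seq", "light_seq", "phenotype")],
    function(id, heavy_seq, light_seq, phenotype) {
      purrr::map(chains, function(ch) {
        s <- if (ch == "H") heavy_seq else light_seq
        mutate(extract_cdr3(s, ch), id = id, phenotype = phenotype, .before = 1)
      }) |> bind_rows()
    }) |> bind_rows()
}

#' CDR length distribution
#'
#' Histogram of loop lengths over a set of antibody records, together with
#' the mean and median length.
#'
#' @param records A tibble of antibody records.
#' @param chain `"H"` (default) or `"L"`.
#' @param source_label Optional label describing the record set.
#' @return A tibble of `length` / `count` rows with attributes `mean`,
#'   `median`, `total` and `source_label`; class `cdr_length_distribution`.
#' @export
length_distribution <- function(records, chain = c("H", "L"),
                                source_label = "records") {
  chain <- match.arg(chain)
  if (nrow(records) == 0) {
    abort("empty record set", class = "abloopr_input_error")
  }
  cdrs <- annotate_cdr3(records, chain)
  out <- cdrs |>
    count(length = .data$length, name = "count") |>
    arrange(.data$length)
  structure(out,
            class = c("cdr_length_distribution", class(out)),
            mean = mean(cdrs$length),
            median = stats::median(cdrs$length),
            total = nrow(cdrs),
            source_label = source_label)
}

#' Write an annotated CDR table to TSV
#'
#' @param cdrs A tibble from [annotate_cdr3()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cdr_table <- function(cdrs, path) {
  flat <- mutate(cdrs,
                 numbering = purrr::map_chr(.data$numbering, paste, collapse = ","))
  readr::write_tsv(flat, path)
  invisible(path)
}

#' Read an annotated CDR table from TSV
#'
#' @param path Path written by [write_cdr_table()].
#' @return A tibble with the `numbering` list column restored.
#' @export
read_cdr_table <- function(path) {
  flat <- readr::read_tsv(path, show_col_types = FALSE)
  mutate(flat, numbering = stringr::str_split(.data$numbering, ","))
}
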