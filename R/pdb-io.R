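#' Write an ensemble to a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame, standard fixed-width ATOM records with
#' chain identifiers and residue insertion codes, closed by END.
#'
#' @param ensemble A `loop_ensemble`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "loop_ensemble"))
  atoms <- ensemble$atoms
  name_field <- ifelse(nchar(atoms$elety) < 4,
                       sprintf(" %-3s", atoms$elety),
                       atoms$elety)
  elem <- substr(atoms$elety, 1, 1)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(ensemble))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    lines <- sprintf(
      "ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(atoms)), name_field, atoms$resid, atoms$chain,
      atoms$resno, ifelse(atoms$insert == "", " ", atoms$insert),
      ensemble$xyz[f, , 1], ensemble$xyz[f, , 2], ensemble$xyz[f, , 3],
      1.00, 0.00, elem)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file as an ensemble
#'
#' Parses MODEL/ENDMDL blocks into frames; a file without MODEL records
#' yields a single frame.  All models must share the same atom roster (atom
#' name, residue number, insertion code, chain); a mismatch is a format
#' error naming the offending model.  Residue insertion codes are preserved.
#'
#' @param path Path to a PDB file.
#' @return A `loop_ensemble`.
#' @export
read_multimodel_pdb <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "abloopr_input_error")
  }
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) == 0) {
    frame_of <- ifelse(is_atom, 1L, NA_integer_)
  } else {
    frame_of <- findInterval(seq_along(lines), model_starts)
    frame_of[!is_atom | frame_of == 0] <- NA_integer_
  }
  al <- lines[is_atom]
  if (length(al) == 0) {
    abort("no ATOM records found", class = "abloopr_format_error")
  }
  frame <- frame_of[is_atom]
  atoms_all <- tibble(
    frame = frame,
    elety = trimws(substr(al, 13, 16)),
    resid = trimws(substr(al, 18, 20)),
    chain = substr(al, 22, 22),
    resno = as.integer(substr(al, 23, 26)),
    insert = trimws(substr(al, 27, 27)),
    x = as.numeric(substr(al, 31, 38)),
    y = as.numeric(substr(al, 39, 46)),
    z = as.numeric(substr(al, 47, 54))
  )
  frames <- sort(unique(atoms_all$frame))
  roster_key <- function(d) paste(d$elety, d$chain, d$resno, d$insert)
  first <- atoms_all[atoms_all$frame == frames[1], ]
  key1 <- roster_key(first)
  nf <- length(frames)
  xyz <- array(NA_real_, dim = c(nf, nrow(first), 3))
  for (k in seq_len(nf)) {
    d <- atoms_all[atoms_all$frame == frames[k], ]
    if (nrow(d) != nrow(first) || !identical(roster_key(d), key1)) {
      abort(sprintf("atom roster of model %d differs from model 1", frames[k]),
            class = "abloopr_format_error")
    }
    xyz[k, , ] <- as.matrix(d[, c("x", "y", "z")])
  }
  loop_ensemble(xyz, first[, c("elety", "resno", "insert", "chain", "resid")])
}

#' Pool frames from several ensembles
#'
#' Concatenates the frames of ensembles sharing one atom roster, e.g. the
#' per-antibody ensembles of a phenotype group.
#'
#' @param ensembles A list of `loop_ensemble` objects.
#' @return A `loop_ensemble` whose frame count is the sum over the inputs.
#' @export
pool_ensembles <- function(ensembles) {
  stopifnot(length(ensembles) >= 1)
  rosters <- purrr::map(ensembles, function(e)
    paste(e$atoms$elety, e$atoms$chain, e$atoms$resno, e$atoms$insert))
  if (length(unique(purrr::map_chr(rosters, paste, collapse = ";"))) != 1) {
    abort("ensembles must share one atom roster to be pooled",
          class = "abloopr_format_error")
  }
  xyz <- do.call(abind_frames, purrr::map(ensembles, function(e) e$xyz))
  loop_ensemble(xyz, ensembles[[1]]$atoms)
}

# bind arrays along the frame dimension without an abind dependency
abind_frames <- function(...) {
  parts <- list(...)
  na <- dim(parts[[1]])[2]
  total <- sum(vapply(parts, function(p) dim(p)[1], integer(1)))
  out <- array(NA_real_, dim = c(total, na, 3))
  at <- 0
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}
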